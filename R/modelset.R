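# Assembly of the three model tiers for a synthetic genome set: broad
# Pfam-like profiles, per-type profiles, and per-family profiles, each with
# calibrated inclusion cutoffs (and unknown floors for the type tier).

#' Train the three HMM tiers for a synthetic genome set
#'
#' Family profiles are built from each family's seed alignment and
#' calibrated so that every full-length member passes and every member of
#' any other family (plus every decoy) fails. Type profiles are built from a
#' progressive alignment of members across the families of that type
#' (classical, extended and divergent only; atypical and unknown are labels,
#' not models) and calibrated against the decoys, with an unknown floor set
#' below the inclusion cutoff. Broad (Pfam-like) profiles are built from one
#' member per family, one model for the extended tail architecture and one
#' for the core-only architectures.
#'
#' @param gs A `genome_set` from [make_genome_set()].
#' @param margin_family Bit margin for family cutoffs (default 5).
#' @param margin_type Bit margin for type/broad cutoffs (default 1).
#' @param members_per_family_for_seeds Members per family drawn into the
#'   type- and broad-tier seed alignments (default 2).
#' @return A list with `pfam_models`, `type_models` (named by type),
#'   `family_models`, and `cutoffs` (a [type_cutoffs()] for the type tier).
#' @export
train_sdr_models <- function(gs, margin_family = 5, margin_type = 1,
                             members_per_family_for_seeds = 2L) {
  stopifnot(inherits(gs, "genome_set"))
  truth <- gs$truth
  prot <- gs$proteome
  seqs <- setNames(prot$sequence, prot$seq_id)
  full <- truth[!truth$truncated & !is.na(truth$family_id), ]
  decoys <- seqs[truth$seq_id[!is.na(truth$decoy_class)]]
  if (length(decoys) == 0) {
    # calibration needs at least one negative example
    decoys <- c(decoy_a = shuffle_decoy(unname(seqs[full$seq_id[1]])))
  }
  member_seqs <- function(fams) {
    ids <- full$seq_id[full$family_id %in% fams]
    seqs[ids]
  }

  # family tier
  family_models <- map(names(gs$seeds), function(f) {
    hmm <- build_profile(gs$seeds[[f]], model_id = f,
                         model_class = "family_set")
    pos <- member_seqs(f)
    neg <- c(member_seqs(setdiff(unique(full$family_id), f)), decoys)
    if (length(pos) > 0 && length(neg) > 0) {
      hmm$inclusion_cutoff <- calibrate_cutoff(hmm, pos, neg,
                                               margin = margin_family)
    }
    hmm
  })
  names(family_models) <- names(gs$seeds)

  fam_types <- setNames(gs$families$sdr_type, gs$families$family_id)
  pick_seed_members <- function(fams) {
    ids <- unlist(map(fams, function(f) {
      head(full$seq_id[full$family_id == f], members_per_family_for_seeds)
    }))
    seqs[ids]
  }

  # type tier: models only for the structurally defined types present
  type_names <- intersect(c("classical", "extended", "divergent"),
                          unique(fam_types))
  inclusion <- numeric(0)
  floors <- numeric(0)
  type_models <- map(setNames(type_names, type_names), function(ty) {
    fams <- names(fam_types)[fam_types == ty]
    sd_seqs <- pick_seed_members(fams)
    aln <- if (length(sd_seqs) >= 2) progressive_msa(sd_seqs) else {
      gs$seeds[[fams[1]]]
    }
    hmm <- build_profile(aln, model_id = paste0("type_", ty),
                         model_class = "type_set")
    # the inclusion cutoff guarantees the curated representatives pass and
    # the decoys fail; the unknown floor sits just above the decoy ceiling,
    # so weaker members are still safely recognisable as SDRs
    inc <- calibrate_cutoff(hmm, sd_seqs, decoys, margin = margin_type)
    fl <- min(inc - 1, max(map_dbl(decoys, ~ score_profile(hmm, .x))) + 1)
    inclusion[ty] <<- inc
    floors[ty] <<- fl
    hmm$inclusion_cutoff <- inc
    hmm$unknown_floor <- fl
    hmm
  })

  # broad tier: one model per architecture (core vs extended tail)
  ext_fams <- names(fam_types)[fam_types == "extended"]
  core_fams <- setdiff(names(fam_types), ext_fams)
  pfam_models <- list()
  add_broad <- function(id, fams) {
    if (length(fams) == 0) return()
    sd_seqs <- pick_seed_members(fams)
    if (length(sd_seqs) < 2) return()
    hmm <- build_profile(progressive_msa(sd_seqs), model_id = id,
                         model_class = "pfam_set")
    hmm$inclusion_cutoff <- calibrate_cutoff(hmm, sd_seqs, decoys,
                                             margin = margin_type)
    hmm$unknown_floor <- min(
      hmm$inclusion_cutoff - 1,
      max(map_dbl(decoys, ~ score_profile(hmm, .x))) + 1
    )
    pfam_models[[id]] <<- hmm
  }
  add_broad("PFCORE", core_fams)
  add_broad("PFEXT", ext_fams)

  list(
    pfam_models = pfam_models,
    type_models = type_models,
    family_models = family_models,
    cutoffs = type_cutoffs(inclusion = inclusion, unknown_floor = floors)
  )
}
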
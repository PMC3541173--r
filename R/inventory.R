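# The inventory core: three-tier HMM scanning, the decision tree combining
# the tiers (with explicit bit cutoffs and unknown floors), gene-model
# selection at multi-model loci, truncated-protein rescue by the 60-residue /
# >50%-identity rule, single-linkage orphan clustering at E <= 1e-40, and the
# assembly of the main and ambiguous inventories.

#' Type-level score cutoffs
#'
#' Inclusion cutoffs and "unknown" floors, in bits, for the five SDR types.
#' Defaults are the published values (classical 138, extended 108,
#' intermediate 162, divergent 160, complex 140; floors classical 29,
#' extended 75, divergent 100). The default plant configuration drops the
#' intermediate and complex models, which are not found in plants.
#'
#' @param inclusion Named numeric vector of inclusion cutoffs.
#' @param unknown_floor Named numeric vector of lower floors above which a
#'   sequence is still safely an SDR, but untyped.
#' @return A `type_cutoffs` object.
#' @export
type_cutoffs <- function(inclusion = c(classical = 138, extended = 108,
                                       intermediate = 162, divergent = 160,
                                       complex = 140),
                         unknown_floor = c(classical = 29, extended = 75,
                                           divergent = 100)) {
  shared <- intersect(names(inclusion), names(unknown_floor))
  bad <- shared[unknown_floor[shared] >= inclusion[shared]]
  if (length(bad)) {
    abort(paste0("unknown_floor must lie below the inclusion cutoff for: ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(inclusion = inclusion, unknown_floor = unknown_floor),
            class = "type_cutoffs")
}

TYPE_ORDER <- c("classical", "extended", "divergent", "intermediate", "complex")

suffix_to_type <- function(family_id) {
  suf <- substr(family_id, nchar(family_id), nchar(family_id))
  unname(c(C = "classical", E = "extended", D = "divergent",
           U = "unknown", A = "atypical")[suf])
}

#' Scan a proteome against the three HMM tiers
#'
#' Scores every (sequence, model) pair for the broad Pfam-like tier, the
#' type tier, and the family tier, flagging cutoff and floor passes. Family
#' and Pfam-tier models use their own `inclusion_cutoff`; type-tier models
#' use the supplied [type_cutoffs()].
#'
#' @param proteome Tibble with `seq_id`, `sequence` (or named character).
#' @param pfam_models,family_models Lists of `profile_hmm`s with calibrated
#'   `inclusion_cutoff`s.
#' @param type_models Named list of `profile_hmm`s, one per SDR type.
#' @param cutoffs A [type_cutoffs()].
#' @return A tibble `seq_id`, `tier`, `model_id`, `score`, `passes_cutoff`,
#'   `passes_floor`; empty proteome gives an empty table.
#' @export
scan_three_tiers <- function(proteome, pfam_models, type_models, family_models,
                             cutoffs = type_cutoffs()) {
  if (is.character(proteome)) {
    proteome <- tibble(seq_id = names(proteome), sequence = unname(proteome))
  }
  if (length(pfam_models) < 1 || length(type_models) < 1 ||
      length(family_models) < 1) {
    abort("scan_three_tiers: need at least one model per tier")
  }
  if (nrow(proteome) == 0) {
    return(tibble(seq_id = character(), tier = character(),
                  model_id = character(), score = numeric(),
                  passes_cutoff = logical(), passes_floor = logical()))
  }
  score_tier <- function(models, tier) {
    bind_rows(imap(models, function(hmm, nm) {
      scores <- map_dbl(proteome$sequence, ~ score_profile(hmm, .x))
      if (tier == "type_set") {
        type <- if (nzchar(nm) && !is.null(names(models))) nm else hmm$model_id
        cut <- unname(cutoffs$inclusion[type])
        floor <- unname(cutoffs$unknown_floor[type])
      } else {
        cut <- hmm$inclusion_cutoff
        floor <- hmm$unknown_floor
      }
      tibble(seq_id = proteome$seq_id, tier = tier, model_id = hmm$model_id,
             score = scores,
             passes_cutoff = !is.na(cut) & scores >= cut,
             passes_floor = !is.na(floor) & scores >= floor)
    }))
  }
  bind_rows(
    score_tier(pfam_models, "pfam_set"),
    score_tier(type_models, "type_set"),
    score_tier(family_models, "family_set")
  ) |>
    arrange(.data$seq_id, .data$tier, .data$model_id)
}

# map type-tier model_id back to its type name given a named model list
type_of_model <- function(type_models) {
  nm <- names(type_models)
  setNames(nm, map_chr(type_models, "model_id"))
}

#' Decide the verdict for one sequence from its hit-table rows
#'
#' Applies the decision tree: (1) a family-tier pass is directly positive
#' (type from the family's suffix letter); (2) a Pfam-tier pass plus a
#' type-tier pass is positive with the best passing type; (3) a Pfam-tier
#' pass plus a type score at or above its unknown floor is positive with type
#' `"unknown"`; (4) recognition by a single tier defers the sequence: a
#' supplied rescue assignment makes it positive, a whitelist entry makes it
#' positive with the whitelisted type, an exclusion-list entry makes it
#' negative, otherwise it is ambiguous; (5) no recognition is negative.
#' A rescue assignment also upgrades otherwise-negative sequences (truncated
#' proteins missed by every HMM). Type-score ties break classical > extended
#' > divergent.
#'
#' @param hits Hit-table rows for one sequence (see [scan_three_tiers()]),
#'   with type-tier `model_id`s resolvable to types via `type_map`.
#' @param cutoffs A [type_cutoffs()] (already baked into the flags; used for
#'   floor lookups).
#' @param type_map Named character: model_id -> type name for the type tier.
#' @param whitelist Optional tibble `seq_id`, `sdr_type` (and optional
#'   `family_id`) of literature-validated inclusions.
#' @param exclusion Character vector of sequence ids to discard (e.g.
#'   medium-chain dehydrogenase look-alikes).
#' @param rescue Optional one-row tibble from [rescue_truncated()] for this
#'   sequence (`rescued`, `family_id`, `sdr_type`, `homolog_id`).
#' @return A one-row tibble `seq_id`, `verdict`, `sdr_type`, `family_id`,
#'   `family_source`, `evidence`.
#' @export
decide_sdr <- function(hits, cutoffs = type_cutoffs(), type_map = NULL,
                       whitelist = NULL, exclusion = character(),
                       rescue = NULL) {
  sid <- unique(hits$seq_id)
  stopifnot(length(sid) == 1)
  if (!is.null(whitelist) && length(exclusion) &&
      any(whitelist$seq_id %in% exclusion)) {
    abort("configuration error: sequence present in both whitelist and exclusion list")
  }
  hits <- arrange(hits, .data$tier, .data$model_id) # order-stable decisions
  ev <- character(0)
  out <- function(verdict, sdr_type = NA_character_,
                  family_id = NA_character_, family_source = NA_character_) {
    tibble(seq_id = sid, verdict = verdict, sdr_type = sdr_type,
           family_id = family_id, family_source = family_source,
           evidence = paste(ev, collapse = "; "))
  }

  fam <- filter(hits, .data$tier == "family_set", .data$passes_cutoff)
  if (nrow(fam) > 0) {
    best <- fam |> arrange(dplyr::desc(.data$score), .data$model_id) |> slice(1)
    ev <- c(ev, sprintf("family-tier pass: %s score %.1f", best$model_id,
                        best$score))
    return(out("positive", suffix_to_type(best$model_id), best$model_id, "hmm"))
  }

  pfam <- filter(hits, .data$tier == "pfam_set")
  pfam_pass <- any(pfam$passes_cutoff)
  if (pfam_pass) {
    b <- pfam |> filter(.data$passes_cutoff) |>
      arrange(dplyr::desc(.data$score)) |> slice(1)
    ev <- c(ev, sprintf("pfam-tier pass: %s score %.1f", b$model_id, b$score))
  }

  typ <- filter(hits, .data$tier == "type_set")
  if (nrow(typ) > 0 && !is.null(type_map)) {
    typ <- mutate(typ, type = unname(type_map[.data$model_id]))
  } else if (nrow(typ) > 0) {
    typ <- mutate(typ, type = .data$model_id)
  }
  typ_pass <- filter(typ, .data$passes_cutoff)
  if (pfam_pass && nrow(typ_pass) > 0) {
    typ_pass <- typ_pass |>
      mutate(rank = match(.data$type, TYPE_ORDER)) |>
      arrange(dplyr::desc(.data$score), .data$rank)
    b <- slice(typ_pass, 1)
    ev <- c(ev, sprintf("type-tier pass: %s score %.1f", b$type, b$score))
    return(out("positive", b$type))
  }
  typ_floor <- filter(typ, .data$passes_floor)
  if (pfam_pass && nrow(typ_floor) > 0) {
    b <- typ_floor |>
      mutate(rank = match(.data$type, TYPE_ORDER)) |>
      arrange(dplyr::desc(.data$score), .data$rank) |> slice(1)
    ev <- c(ev, sprintf("type floor only: %s score %.1f >= floor", b$type,
                        b$score))
    return(out("positive", "unknown"))
  }

  # how many tiers recognised the sequence at all?
  recognized <- c(
    pfam = pfam_pass,
    type = nrow(typ_pass) > 0 || nrow(typ_floor) > 0,
    family = FALSE # a family pass returned above
  )
  n_rec <- sum(recognized)

  if (!is.null(rescue) && nrow(rescue) == 1 && isTRUE(rescue$rescued)) {
    ev <- c(ev, sprintf("rescued by homology to %s (60-aa segment > 50%% id)",
                        rescue$homolog_id))
    return(out("positive", rescue$sdr_type, rescue$family_id, "rescue"))
  }
  if (n_rec >= 1) {
    ev <- c(ev, paste0("recognized by single tier: ",
                       paste(names(recognized)[recognized], collapse = "+")))
    if (!is.null(whitelist) && sid %in% whitelist$seq_id) {
      w <- whitelist[whitelist$seq_id == sid, ][1, ]
      ev <- c(ev, "whitelisted (structural literature)")
      return(out("positive", w$sdr_type,
                 if ("family_id" %in% names(w)) w$family_id else NA_character_,
                 "whitelist"))
    }
    if (sid %in% exclusion) {
      ev <- c(ev, "exclusion list (distinct structural class)")
      return(out("negative"))
    }
    return(out("ambiguous"))
  }
  ev <- c(ev, "no HMM recognition")
  out("negative")
}

#' Select one gene model per locus
#'
#' Picks the model with the maximum best HMM score; ties go to the maximum
#' local-alignment score against a cross-genome database. When the HMM winner
#' and the alignment winner disagree, the HMM winner is kept provisionally
#' and flagged for manual review.
#'
#' @param models Tibble with `seq_id`, `sequence` for one locus (>= 1 row).
#' @param hits Hit table covering these sequences.
#' @param cross_genome_db Named character vector of sequences from other
#'   genomes (may be empty).
#' @return A list with `chosen` (seq_id) and `flag`
#'   (`NA` or `"manual-review"`).
#' @export
select_gene_model <- function(models, hits, cross_genome_db = character()) {
  stopifnot(nrow(models) >= 1)
  if (nrow(models) == 1) return(list(chosen = models$seq_id, flag = NA_character_))
  best_hmm <- map_dbl(models$seq_id, function(s) {
    sc <- hits$score[hits$seq_id == s]
    if (length(sc)) max(sc) else -Inf
  })
  hmm_winner <- models$seq_id[order(-best_hmm, models$seq_id)][1]
  aln_winner <- NA_character_
  if (length(cross_genome_db) > 0) {
    best_aln <- map_dbl(models$sequence, function(s) {
      max(map_dbl(cross_genome_db, ~ local_align(s, .x)$score))
    })
    aln_winner <- models$seq_id[order(-best_aln, models$seq_id)][1]
  }
  top <- max(best_hmm)
  tied <- models$seq_id[best_hmm == top]
  if (length(tied) > 1 && !is.na(aln_winner) && aln_winner %in% tied) {
    return(list(chosen = aln_winner, flag = NA_character_))
  }
  flag <- if (!is.na(aln_winner) && aln_winner != hmm_winner) {
    "manual-review"
  } else {
    NA_character_
  }
  list(chosen = hmm_winner, flag = flag)
}

#' Rescue unassigned sequences by homology to classified SDRs
#'
#' Aligns each unassigned sequence against every classified positive; hits
#' whose alignment contains a window of `window` columns with identity
#' strictly above `min_identity` qualify, and the sequence inherits the type
#' and family of the best-scoring qualifying homologue (ties by higher
#' segment identity, then lexicographic id).
#'
#' @param unassigned Tibble `seq_id`, `sequence`.
#' @param positives Tibble `seq_id`, `sequence`, `sdr_type`, `family_id`.
#' @param window,min_identity The rescue rule (defaults 60 columns, 0.5).
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return A tibble `seq_id`, `rescued`, `family_id`, `sdr_type`,
#'   `homolog_id`, `score`, `segment_identity`.
#' @export
rescue_truncated <- function(unassigned, positives, window = 60L,
                             min_identity = 0.5, matrix = blosum62(),
                             gap_open = 11, gap_extend = 1) {
  if (nrow(unassigned) == 0 || nrow(positives) == 0) {
    return(tibble(seq_id = character(), rescued = logical(),
                  family_id = character(), sdr_type = character(),
                  homolog_id = character(), score = numeric(),
                  segment_identity = numeric()))
  }
  best_window_identity <- function(aln) {
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    n <- length(ca)
    if (n < window) return(0)
    eq <- as.integer(ca != "-" & cb != "-" & ca == cb)
    cs <- cumsum(c(0L, eq))
    max(cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  }
  bind_rows(map(seq_len(nrow(unassigned)), function(i) {
    q <- unassigned[i, ]
    cand <- map(seq_len(nrow(positives)), function(j) {
      al <- local_align(q$sequence, positives$sequence[j], matrix,
                        gap_open, gap_extend)
      list(j = j, score = al$score, pass = segment_identity_pass(
        al, window, min_identity), seg = best_window_identity(al))
    })
    cand <- keep(cand, ~ .x$pass)
    if (length(cand) == 0) {
      return(tibble(seq_id = q$seq_id, rescued = FALSE,
                    family_id = NA_character_, sdr_type = NA_character_,
                    homolog_id = NA_character_, score = NA_real_,
                    segment_identity = NA_real_))
    }
    ord <- order(-map_dbl(cand, "score"), -map_dbl(cand, "seg"),
                 positives$seq_id[map_int(cand, "j")])
    b <- cand[[ord[1]]]
    p <- positives[b$j, ]
    tibble(seq_id = q$seq_id, rescued = TRUE, family_id = p$family_id,
           sdr_type = p$sdr_type, homolog_id = p$seq_id, score = b$score,
           segment_identity = b$seg)
  }))
}

#' Cluster orphan SDRs into new families by single linkage
#'
#' Orphans (positive sequences with no family assignment) are linked whenever
#' the Karlin-Altschul E-value of their best local alignment is at or below
#' `evalue_threshold`; connected components of >= 2 members become clusters.
#' Each cluster gets a mean pairwise identity from a progressive alignment
#' and a representative: the member with the lowest mean p-distance to the
#' rest (ties lexicographic). Unlinked sequences remain unclassified
#' singletons.
#'
#' @param orphans Tibble `seq_id`, `sequence`.
#' @param evalue_threshold Linking threshold (default 1e-40).
#' @param K,lambda Karlin-Altschul parameters for [karlin_evalue()].
#' @param prefix Cluster-id prefix (clusters get synthetic ids, not
#'   nomenclature names).
#' @return A list with `assignments` (tibble `seq_id`, `cluster_id`; `NA`
#'   for singletons) and `clusters` (tibble `cluster_id`, `n`,
#'   `mean_pairwise_identity`, `representative_id`, `member_ids` list-col).
#' @export
cluster_orphans <- function(orphans, evalue_threshold = 1e-40, K = 0.041,
                            lambda = 0.267, prefix = "NF") {
  n <- nrow(orphans)
  empty <- list(
    assignments = tibble(seq_id = orphans$seq_id,
                         cluster_id = rep(NA_character_, n)),
    clusters = tibble(cluster_id = character(), n = integer(),
                      mean_pairwise_identity = numeric(),
                      representative_id = character(),
                      member_ids = list())
  )
  if (n < 2) return(empty)
  orphans <- arrange(orphans, .data$seq_id)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- local_align(orphans$sequence[i], orphans$sequence[j])
      e <- karlin_evalue(al$score, nchar(orphans$sequence[i]),
                         nchar(orphans$sequence[j]), K, lambda)
      if (e <= evalue_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- map_int(seq_len(n), find)
  sizes <- table(comp)
  cluster_roots <- sort(as.integer(names(sizes)[sizes >= 2]))
  assignments <- tibble(seq_id = orphans$seq_id,
                        cluster_id = NA_character_)
  clusters <- list()
  for (k in seq_along(cluster_roots)) {
    cid <- sprintf("%s%02d", prefix, k)
    idx <- which(comp == cluster_roots[k])
    assignments$cluster_id[idx] <- cid
    msa <- progressive_msa(setNames(orphans$sequence[idx],
                                    orphans$seq_id[idx]))
    d <- p_distance(msa)$d
    off <- d[upper.tri(d)]
    mean_ident <- mean(1 - off, na.rm = TRUE)
    mean_d <- rowMeans(d, na.rm = TRUE) * nrow(d) / (nrow(d) - 1)
    rep_id <- rownames(d)[order(mean_d, rownames(d))][1]
    clusters[[k]] <- tibble(cluster_id = cid, n = length(idx),
                            mean_pairwise_identity = mean_ident,
                            representative_id = rep_id,
                            member_ids = list(orphans$seq_id[idx]))
  }
  list(assignments = assignments,
       clusters = if (length(clusters)) bind_rows(clusters) else empty$clusters)
}

#' Build the full SDR inventory for a genome set
#'
#' Composes the pipeline: scan all three HMM tiers, select one gene model per
#' locus, run the decision tree, rescue truncated proteins against the
#' positives, cluster the remaining orphans, and emit the main and ambiguous
#' lists with per-family per-genome counts and a full evidence trail.
#'
#' @param proteome Tibble `genome`, `locus`, `model`, `seq_id`, `sequence`
#'   (a `genome_set$proteome` works directly).
#' @param pfam_models,type_models,family_models Model lists as in
#'   [scan_three_tiers()].
#' @param cutoffs A [type_cutoffs()].
#' @param whitelist,exclusion See [decide_sdr()].
#' @param window,min_identity Rescue rule parameters.
#' @param evalue_threshold Orphan-clustering threshold.
#' @param cross_genome_selection Use cross-genome alignment scores to break
#'   gene-model ties (slower; default TRUE).
#' @return An `sdr_inventory` with `main`, `ambiguous`, `negative`,
#'   `discarded_models`, `counts` (family x genome tibble), `orphan_clusters`,
#'   and `log` (branch counts).
#' @export
build_inventory <- function(proteome, pfam_models, type_models, family_models,
                            cutoffs = type_cutoffs(), whitelist = NULL,
                            exclusion = character(), window = 60L,
                            min_identity = 0.5, evalue_threshold = 1e-40,
                            cross_genome_selection = TRUE) {
  if (inherits(proteome, "genome_set")) proteome <- proteome$proteome
  if (nrow(proteome) == 0) {
    return(structure(list(
      main = empty_outcomes(), ambiguous = empty_outcomes(),
      negative = empty_outcomes(), discarded_models = empty_outcomes(),
      counts = tibble(family_id = character(), genome = character(),
                      n = integer()),
      orphan_clusters = NULL,
      log = c(positive = 0L, ambiguous = 0L, negative = 0L)
    ), class = "sdr_inventory"))
  }
  proteome <- arrange(proteome, .data$seq_id)
  hit_table <- scan_three_tiers(proteome, pfam_models, type_models,
                                family_models, cutoffs)
  tmap <- type_of_model(type_models)

  # one gene model per locus
  chosen <- proteome |>
    group_by(.data$genome, .data$locus) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) == 1) {
        return(tibble(seq_id = g$seq_id, flag = NA_character_))
      }
      db <- if (cross_genome_selection) {
        other <- proteome[proteome$genome != key$genome, ]
        setNames(other$sequence, other$seq_id)
      } else {
        character()
      }
      sel <- select_gene_model(g, hit_table[hit_table$seq_id %in% g$seq_id, ],
                               db)
      tibble(seq_id = sel$chosen, flag = sel$flag)
    }) |>
    bind_rows()
  selected <- proteome[proteome$seq_id %in% chosen$seq_id, ]
  discarded <- proteome[!proteome$seq_id %in% chosen$seq_id, ]

  decide_all <- function(rescue_tbl = NULL) {
    bind_rows(map(selected$seq_id, function(s) {
      r <- if (!is.null(rescue_tbl)) rescue_tbl[rescue_tbl$seq_id == s, ]
      decide_sdr(hit_table[hit_table$seq_id == s, ], cutoffs, tmap,
                 whitelist, exclusion,
                 rescue = if (!is.null(r) && nrow(r) == 1) r)
    }))
  }
  first_pass <- decide_all()
  positives <- first_pass |>
    filter(.data$verdict == "positive") |>
    left_join(select(selected, "seq_id", "sequence"), by = "seq_id")
  nonpos <- first_pass |> filter(.data$verdict != "positive")
  rescue_tbl <- rescue_truncated(
    selected[selected$seq_id %in% nonpos$seq_id, ],
    positives, window = window, min_identity = min_identity
  )
  outcomes <- decide_all(rescue_tbl)

  # orphan clustering: positives without a family
  orphans <- outcomes |>
    filter(.data$verdict == "positive", is.na(.data$family_id)) |>
    left_join(select(selected, "seq_id", "sequence"), by = "seq_id")
  oc <- cluster_orphans(select(orphans, "seq_id", "sequence"),
                        evalue_threshold = evalue_threshold)
  if (nrow(oc$assignments) > 0) {
    outcomes <- outcomes |>
      left_join(oc$assignments, by = "seq_id") |>
      mutate(
        family_source = ifelse(!is.na(.data$cluster_id), "cluster",
                               .data$family_source),
        family_id = ifelse(!is.na(.data$cluster_id), .data$cluster_id,
                           .data$family_id)
      ) |>
      select(-"cluster_id")
  }

  outcomes <- outcomes |>
    left_join(select(selected, "seq_id", "genome", "locus", "model"),
              by = "seq_id") |>
    left_join(chosen, by = "seq_id") |>
    select("genome", "locus", "model", "seq_id", "verdict", "sdr_type",
           "family_id", "family_source", "evidence", "flag") |>
    arrange(.data$seq_id)

  main <- filter(outcomes, .data$verdict == "positive")
  ambiguous <- filter(outcomes, .data$verdict == "ambiguous")
  negative <- filter(outcomes, .data$verdict == "negative")
  counts <- main |>
    filter(!is.na(.data$family_id)) |>
    count(.data$family_id, .data$genome, name = "n")

  structure(list(
    main = main, ambiguous = ambiguous, negative = negative,
    discarded_models = discarded, counts = counts, orphan_clusters = oc,
    log = c(positive = nrow(main), ambiguous = nrow(ambiguous),
            negative = nrow(negative))
  ), class = "sdr_inventory")
}

empty_outcomes <- function() {
  tibble(genome = character(), locus = character(), model = character(),
         seq_id = character(), verdict = character(), sdr_type = character(),
         family_id = character(), family_source = character(),
         evidence = character(), flag = character())
}

#' @export
print.sdr_inventory <- function(x, ...) {
  cat("<sdr_inventory> main ", nrow(x$main), ", ambiguous ",
      nrow(x$ambiguous), ", negative ", nrow(x$negative), "\n", sep = "")
  invisible(x)
}

#' Write inventory TSVs
#' @param inv An `sdr_inventory`.
#' @param dir Output directory.
#' @return Invisibly, written paths.
#' @export
write_inventory <- function(inv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "inventory_main.tsv")
  p2 <- file.path(dir, "inventory_ambiguous.tsv")
  p3 <- file.path(dir, "orphan_clusters.tsv")
  readr::write_tsv(inv$main, p1)
  readr::write_tsv(inv$ambiguous, p2)
  cl <- inv$orphan_clusters$clusters
  if (!is.null(cl) && nrow(cl) > 0) {
    readr::write_tsv(
      mutate(cl, member_ids = map_chr(.data$member_ids, paste, collapse = ",")),
      p3
    )
  } else {
    readr::write_tsv(tibble(cluster_id = character()), p3)
  }
  invisible(c(p1, p2, p3))
}
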
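# Synthetic proteomes with planted SDR families: the test-bed for the whole
# inventory pipeline. Families descend from a shared superfamily root (so that
# broad, type-level and family-level profiles all have signal to learn),
# members are mutated copies of a family ancestor under BLOSUM62-conditional
# substitution sampling with controlled identity, and the generator plants
# truncations, multi-model loci and motif-free decoys.

SDR_TYPES <- c("classical", "extended", "divergent", "atypical", "unknown")
TYPE_SUFFIX <- c(classical = "C", extended = "E", divergent = "D",
                 atypical = "A", unknown = "U")

CLASSICAL_CORE_LEN <- 250L
EXTENDED_TAIL_LEN <- 100L
COFACTOR_MOTIF <- "GASRGIG"  # Rossmann-fold GxxxGxG dinucleotide-binding site
COFACTOR_POS <- 8L
CATALYTIC_MOTIF <- "YAASK"   # YxxxK catalytic motif
CATALYTIC_POS <- 150L

#' Family specification for the synthetic generator
#'
#' @param family_id Label; by convention it ends in the type suffix letter
#'   (C/E/D/A/U) used throughout the SDR nomenclature.
#' @param sdr_type One of classical, extended, divergent, atypical, unknown.
#' @param ancestor Amino-acid ancestor sequence (non-empty).
#' @param target_identity Fraction in (0, 1]: expected identity of each
#'   member to the ancestor.
#' @param members_per_genome Named nonnegative integer vector (genome id ->
#'   planted member count). Zero marks the family absent from that genome.
#' @param motif_positions Named list of motif index vectors (cofactor,
#'   catalytic); motif columns mutate at a reduced rate.
#' @return A `family_spec` object.
#' @export
family_spec <- function(family_id, sdr_type, ancestor, target_identity,
                        members_per_genome,
                        motif_positions = default_motif_positions(ancestor)) {
  if (!nzchar(ancestor)) abort("invalid family spec: empty ancestor")
  if (target_identity <= 0 || target_identity > 1) {
    abort("invalid family spec: target_identity must be in (0, 1]")
  }
  if (!sdr_type %in% SDR_TYPES) abort("invalid family spec: unknown sdr_type")
  if (any(members_per_genome < 0)) abort("invalid family spec: negative member count")
  structure(list(family_id = family_id, sdr_type = sdr_type,
                 ancestor = toupper(ancestor),
                 target_identity = target_identity,
                 members_per_genome = members_per_genome,
                 motif_positions = motif_positions),
            class = "family_spec")
}

default_motif_positions <- function(ancestor) {
  list(cofactor = COFACTOR_POS:(COFACTOR_POS + nchar(COFACTOR_MOTIF) - 1L),
       catalytic = CATALYTIC_POS:(CATALYTIC_POS + nchar(CATALYTIC_MOTIF) - 1L))
}

# background-frequency random sequence with SDR motifs planted
random_ancestor <- function(len) {
  s <- sample(AA_ORDER, len, replace = TRUE, prob = AA_BACKGROUND)
  s[COFACTOR_POS:(COFACTOR_POS + nchar(COFACTOR_MOTIF) - 1L)] <-
    strsplit(COFACTOR_MOTIF, "")[[1]]
  s[CATALYTIC_POS:(CATALYTIC_POS + nchar(CATALYTIC_MOTIF) - 1L)] <-
    strsplit(CATALYTIC_MOTIF, "")[[1]]
  paste(s, collapse = "")
}

# Mutate a sequence: a fixed count of positions (round(p_sub * n), so the
# realized identity tracks the target tightly; motif positions mutate at a
# motif_factor-reduced rate), substitutions drawn from the BLOSUM62
# conditional excluding the original residue; short indels at rate
# p_indel per site (absent when p_sub is 0 so the identity-1 case is exact).
mutate_sequence <- function(seq, p_sub, motif_positions = list(),
                            motif_factor = 0.1, p_indel = 0.01 * p_sub) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cond <- blosum62_conditional()
  motif_idx <- unique(unlist(map(motif_positions, ~ .x[.x <= n])))
  plain_idx <- setdiff(seq_len(n), motif_idx)
  pick <- function(idx, p) {
    k <- min(length(idx), round(p * length(idx)))
    if (k > 0) sample(idx, k) else integer(0)
  }
  hit <- rep(FALSE, n)
  hit[c(pick(plain_idx, p_sub), pick(motif_idx, p_sub * motif_factor))] <- TRUE
  for (i in which(hit)) {
    orig <- match(chars[i], AA_ORDER)
    if (is.na(orig)) next
    w <- cond[, orig]
    w[orig] <- 0
    chars[i] <- sample(AA_ORDER, 1, prob = w / sum(w))
  }
  if (p_indel > 0) {
    # deletions
    del <- which(runif(n) < p_indel / 2)
    keep <- rep(TRUE, length(chars))
    for (i in del) {
      len <- sample(1:3, 1)
      keep[i:min(i + len - 1, length(chars))] <- FALSE
    }
    chars <- chars[keep]
    # insertions
    ins <- which(runif(length(chars)) < p_indel / 2)
    if (length(ins)) {
      pieces <- character(length(chars))
      for (i in ins) {
        len <- sample(1:3, 1)
        pieces[i] <- paste(sample(AA_ORDER, len, replace = TRUE,
                                  prob = AA_BACKGROUND), collapse = "")
      }
      chars <- as.vector(rbind(chars, pieces))
      chars <- chars[nzchar(chars)]
      chars <- unlist(strsplit(chars, ""))
    }
  }
  paste(chars, collapse = "")
}

#' Generate one synthetic SDR family
#'
#' Emits per-genome member sequences derived from the family ancestor by
#' BLOSUM62-weighted substitutions (motif columns at reduced rate) and sparse
#' short indels, plus a seed alignment of dedicated seed members.
#'
#' @param spec A [family_spec()].
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @param n_seed Number of seed members for the seed alignment (>= 3).
#' @return A list with `seed_aln` (a [seed_alignment()]), `members` (tibble
#'   `genome`, `member`, `sequence`), and `ancestor`.
#' @export
make_family <- function(spec, rng_seed = 1L, n_seed = 6L) {
  stopifnot(inherits(spec, "family_spec"))
  n_seed <- max(3L, n_seed)
  with_seed(rng_seed, {
    p_sub <- 1 - spec$target_identity
    mut <- function() mutate_sequence(spec$ancestor, p_sub, spec$motif_positions)
    seed_seqs <- setNames(
      map_chr(seq_len(n_seed), ~ mut()),
      paste0(spec$family_id, "_seed", seq_len(n_seed))
    )
    seed_aln <- progressive_msa(seed_seqs)
    members <- purrr::imap(spec$members_per_genome, function(k, g) {
      if (k == 0) return(NULL)
      tibble(genome = g, member = seq_len(k),
             sequence = map_chr(seq_len(k), ~ mut()))
    })
    members <- bind_rows(members)
    list(seed_aln = seed_aln, members = members, ancestor = spec$ancestor)
  })
}

#' Default synthetic genome roster
#'
#' One alga, one moss (bryophyte), one lycophyte, and `n_angiosperms`
#' flowering-plant genomes, mirroring the taxon spread of published plant
#' SDR surveys (alga / moss / lycophyte / 4 dicots + 3 monocots).
#'
#' @param n_angiosperms Number of angiosperm genomes (default 7).
#' @return A tibble with columns `genome`, `tier`.
#' @export
default_genome_roster <- function(n_angiosperms = 7L) {
  bind_rows(
    tibble(genome = "alga1", tier = "alga"),
    tibble(genome = "moss1", tier = "bryophyte"),
    tibble(genome = "lyco1", tier = "lycophyte"),
    tibble(genome = paste0("angio", seq_len(n_angiosperms)), tier = "angiosperm")
  )
}

#' Default family specifications over a rooted superfamily hierarchy
#'
#' Builds `n_families` specs whose ancestors descend from a single random
#' superfamily root through per-type intermediate ancestors (so that broad
#' profiles share signal across all families while type-level profiles carry
#' genuine within-type signal). Types cycle over classical/extended with one
#' divergent, one atypical and one unknown family; ids carry the type suffix
#' letter. Target identities are spread over `identity_range`. Extended
#' ancestors carry an additional C-terminal tail domain.
#'
#' @param n_families Number of families (default 10).
#' @param genomes Genome roster tibble (`genome`, `tier`).
#' @param members_per_genome Planted members per genome; recycled across
#'   families, so a vector gives families of different sizes.
#' @param identity_range Range of member-to-ancestor target identities
#'   (default 0.45-0.70).
#' @param rng_seed Integer seed.
#' @param type_root_identity Identity of each type ancestor to the
#'   superfamily root (default 0.6).
#' @param family_root_identity Identity of each family ancestor to its type
#'   ancestor (default 0.5; families within a type are deeply diverged, as
#'   in the real superfamily).
#' @return A list of [family_spec()] objects.
#' @export
default_family_specs <- function(n_families = 10L,
                                 genomes = default_genome_roster(),
                                 members_per_genome = 3L,
                                 identity_range = c(0.45, 0.7),
                                 rng_seed = 1L, type_root_identity = 0.6,
                                 family_root_identity = 0.5) {
  if (n_families < 3) abort("need at least 3 families to cover the type labels")
  with_seed(rng_seed, {
    root_core <- random_ancestor(CLASSICAL_CORE_LEN)
    root_tail <- paste(sample(AA_ORDER, EXTENDED_TAIL_LEN, replace = TRUE,
                              prob = AA_BACKGROUND), collapse = "")
    motifs <- default_motif_positions(root_core)
    type_roots <- map(setNames(SDR_TYPES, SDR_TYPES), function(ty) {
      core <- mutate_sequence(root_core, 1 - type_root_identity, motifs)
      if (ty == "extended") {
        paste0(core, mutate_sequence(root_tail, 1 - type_root_identity))
      } else {
        core
      }
    })
    types <- rep(c("classical", "extended"), length.out = n_families)
    types[3] <- "divergent"
    if (n_families >= 4) types[4] <- "atypical"
    if (n_families >= 5) types[5] <- "unknown"
    idents <- seq(identity_range[1], identity_range[2],
                  length.out = n_families)
    sizes <- rep_len(members_per_genome, n_families)
    map(seq_len(n_families), function(i) {
      anc <- mutate_sequence(type_roots[[types[i]]],
                             1 - family_root_identity, motifs)
      family_spec(
        family_id = sprintf("SF%02d%s", i, TYPE_SUFFIX[[types[i]]]),
        sdr_type = types[i], ancestor = anc, target_identity = idents[i],
        members_per_genome = setNames(rep(sizes[i], nrow(genomes)),
                                      genomes$genome)
      )
    })
  })
}

shuffle_decoy <- function(seq, max_tries = 25L) {
  chars <- strsplit(seq, "")[[1]]
  for (k in seq_len(max_tries)) {
    cand <- paste(sample(chars), collapse = "")
    if (!grepl("Y.{3}K", cand)) return(cand)
  }
  # destroy any residual catalytic motif explicitly
  gsub("Y(.{3})K", "A\\1A", cand)
}

mdr_like_decoy <- function(len = 340L) {
  s <- sample(AA_ORDER, len, replace = TRUE, prob = AA_BACKGROUND)
  s[COFACTOR_POS:(COFACTOR_POS + nchar(COFACTOR_MOTIF) - 1L)] <-
    strsplit(COFACTOR_MOTIF, "")[[1]]
  out <- paste(s, collapse = "")
  gsub("Y(.{3})K", "A\\1A", out)
}

#' Generate a synthetic genome set with truth table
#'
#' Plants every family of `specs` into the genomes it declares, then applies
#' truncation (members replaced by a contiguous fragment of >= 40 residues),
#' adds multi-model loci (an extra, truncated gene model at a locus), and
#' appends decoys: composition-matched residue shuffles of real members
#' (catalytic motif destroyed) and medium-chain-dehydrogenase-like sequences
#' that share only the cofactor motif. Every emitted protein has exactly one
#' truth record.
#'
#' @param specs List of [family_spec()]s (unique family ids).
#' @param genomes Genome roster tibble (`genome`, `tier`).
#' @param decoy_count Total decoys across genomes.
#' @param truncation_rate Per-member probability of truncation.
#' @param multimodel_rate Per-locus probability of a second gene model.
#' @param rng_seed Integer seed; identical seeds give bit-identical output.
#' @param truncation_window Range of truncated fragment lengths.
#' @return A `genome_set` with elements `proteome` (tibble `genome`, `locus`,
#'   `model`, `seq_id`, `sequence`), `truth` (one row per protein), `seeds`
#'   (named list of seed alignments), `families`, `tiers`, `seed`.
#' @export
make_genome_set <- function(specs, genomes = default_genome_roster(),
                            decoy_count = 20L, truncation_rate = 0.1,
                            multimodel_rate = 0.05, rng_seed = 1L,
                            truncation_window = c(40L, 150L)) {
  ids <- map_chr(specs, "family_id")
  if (anyDuplicated(ids)) abort("invalid spec: duplicate family_id")
  if (truncation_rate < 0 || truncation_rate > 1 ||
      multimodel_rate < 0 || multimodel_rate > 1) {
    abort("rates must be in [0, 1]")
  }
  with_seed(rng_seed, {
    seeds <- list()
    rows <- list()
    truth <- list()
    locus_counter <- setNames(rep(0L, nrow(genomes)), genomes$genome)
    next_locus <- function(g) {
      locus_counter[g] <<- locus_counter[g] + 1L
      sprintf("%s_L%03d", g, locus_counter[g])
    }
    fragment <- function(seq) {
      L <- nchar(seq)
      len <- min(sample(truncation_window[1]:truncation_window[2], 1), L - 1L)
      start <- sample(seq_len(L - len + 1L), 1)
      substr(seq, start, start + len - 1L)
    }
    for (k in seq_along(specs)) {
      spec <- specs[[k]]
      fam <- make_family(spec, rng_seed = rng_seed + k)
      seeds[[spec$family_id]] <- fam$seed_aln
      if (nrow(fam$members) == 0) next
      for (r in seq_len(nrow(fam$members))) {
        g <- fam$members$genome[r]
        full <- fam$members$sequence[r]
        locus <- next_locus(g)
        truncated <- runif(1) < truncation_rate
        seq1 <- if (truncated) fragment(full) else full
        sid <- paste(g, locus, "m1", sep = "|")
        rows[[sid]] <- tibble(genome = g, locus = locus, model = "m1",
                              seq_id = sid, sequence = seq1)
        truth[[sid]] <- tibble(
          genome_id = g, locus_id = locus, model_id = "m1", seq_id = sid,
          family_id = spec$family_id, sdr_type = spec$sdr_type,
          truncated = truncated, planted_identity = spec$target_identity,
          decoy_class = NA_character_
        )
        if (runif(1) < multimodel_rate) {
          sid2 <- paste(g, locus, "m2", sep = "|")
          rows[[sid2]] <- tibble(genome = g, locus = locus, model = "m2",
                                 seq_id = sid2, sequence = fragment(full))
          truth[[sid2]] <- tibble(
            genome_id = g, locus_id = locus, model_id = "m2", seq_id = sid2,
            family_id = spec$family_id, sdr_type = spec$sdr_type,
            truncated = TRUE, planted_identity = spec$target_identity,
            decoy_class = NA_character_
          )
        }
      }
    }
    member_pool <- map_chr(rows, ~ .x$sequence[1])
    member_pool <- member_pool[map_lgl(truth, ~ !.x$truncated)]
    if (decoy_count > 0) {
      for (d in seq_len(decoy_count)) {
        g <- genomes$genome[1 + (d - 1) %% nrow(genomes)]
        locus <- next_locus(g)
        cls <- if (d %% 2 == 1) "shuffle" else "mdr_like"
        seq <- if (cls == "shuffle" && length(member_pool) > 0) {
          shuffle_decoy(sample(member_pool, 1))
        } else {
          mdr_like_decoy()
        }
        sid <- paste(g, locus, "m1", sep = "|")
        rows[[sid]] <- tibble(genome = g, locus = locus, model = "m1",
                              seq_id = sid, sequence = seq)
        truth[[sid]] <- tibble(
          genome_id = g, locus_id = locus, model_id = "m1", seq_id = sid,
          family_id = NA_character_, sdr_type = NA_character_,
          truncated = FALSE, planted_identity = NA_real_,
          decoy_class = if (cls == "shuffle" && length(member_pool) > 0)
            "shuffle" else "mdr_like"
        )
      }
    }
    structure(list(
      proteome = bind_rows(rows),
      truth = bind_rows(truth),
      seeds = seeds,
      families = tibble(family_id = ids,
                        sdr_type = map_chr(specs, "sdr_type"),
                        target_identity = map_dbl(specs, "target_identity")),
      tiers = setNames(genomes$tier, genomes$genome),
      seed = rng_seed
    ), class = "genome_set")
  })
}

#' @export
print.genome_set <- function(x, ...) {
  cat("<genome_set> ", nrow(x$proteome), " proteins over ",
      length(x$tiers), " genomes, ", length(x$seeds), " planted families, ",
      sum(!is.na(x$truth$decoy_class)), " decoys\n", sep = "")
  invisible(x)
}

#' Write a genome set to disk
#'
#' One FASTA per genome (headers `genome|locus|model`), the truth table as
#' TSV, and each family's seed alignment as aligned FASTA and Stockholm.
#'
#' @param gs A `genome_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_genome_set <- function(gs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (g in names(gs$tiers)) {
    sub <- dplyr::filter(gs$proteome, .data$genome == g)
    p <- file.path(dir, paste0(g, ".faa"))
    write_fasta(tibble(id = sub$seq_id, sequence = sub$sequence), p)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.tsv")
  readr::write_tsv(gs$truth, tp)
  paths <- c(paths, tp)
  for (f in names(gs$seeds)) {
    pa <- file.path(dir, paste0("seed_", f, ".afa"))
    ps <- file.path(dir, paste0("seed_", f, ".sto"))
    write_alignment_fasta(gs$seeds[[f]], pa)
    write_stockholm(gs$seeds[[f]], ps)
    paths <- c(paths, pa, ps)
  }
  invisible(paths)
}

#' Synthetic family-by-genome expansion matrix
#'
#' Emulates the published family-distribution heat map: background families
#' have small near-constant counts across genomes, while diversified families
#' draw counts whose mean and variance increase from the alga tier toward the
#' angiosperm tier (negative binomial draws).
#'
#' @param n_families Number of families (> 1).
#' @param n_genomes Number of genomes; tiers are assigned alga, bryophyte,
#'   lycophyte, then angiosperm, in order.
#' @param diversified_ids Family ids (of the generated `F01`, `F02`, ...
#'   series) planted as diversified; must be a subset.
#' @param rng_seed Integer seed.
#' @param background_mean Mean count of non-diversified families.
#' @param tier_means Named means of diversified counts per tier.
#' @return A `distribution_matrix` with the planted ids in
#'   `attr(, "diversified")`.
#' @export
make_expansion_matrix <- function(n_families = 49L, n_genomes = 10L,
                                  diversified_ids = sprintf("F%02d", 1:10),
                                  rng_seed = 1L, background_mean = 2,
                                  tier_means = c(alga = 2, bryophyte = 6,
                                                 lycophyte = 12,
                                                 angiosperm = 25)) {
  if (n_families <= 1) abort("invalid spec: n_families must exceed 1")
  fams <- sprintf("F%02d", seq_len(n_families))
  if (!all(diversified_ids %in% fams)) {
    abort("diversified_ids must be a subset of the generated family ids")
  }
  tiers <- c("alga", "bryophyte", "lycophyte",
             rep("angiosperm", max(0, n_genomes - 3)))[seq_len(n_genomes)]
  genomes <- sprintf("G%02d", seq_len(n_genomes))
  with_seed(rng_seed, {
    m <- matrix(0L, n_families, n_genomes, dimnames = list(fams, genomes))
    for (i in seq_len(n_families)) {
      if (fams[i] %in% diversified_ids) {
        mu <- tier_means[tiers]
        m[i, ] <- stats::rnbinom(n_genomes, mu = mu, size = 4)
      } else {
        m[i, ] <- stats::rpois(n_genomes, background_mean)
      }
      if (all(m[i, ] == 0)) m[i, n_genomes] <- 1L # keep every family extant
    }
    structure(list(counts = m, tiers = setNames(tiers, genomes)),
              class = "distribution_matrix",
              diversified = intersect(fams, diversified_ids))
  })
}
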
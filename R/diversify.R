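# Family-by-genome distribution analyses: the distribution matrix behind the
# heat map, occurrence classes over the green-plant taxon hierarchy, and PCA
# of family expansion patterns with an extreme-individual robustness check.

#' Construct a distribution matrix
#'
#' @param counts Nonnegative integer matrix, families as rows, genomes as
#'   columns, with dimnames.
#' @param tiers Named character vector genome -> tier (alga, bryophyte,
#'   lycophyte, angiosperm).
#' @return A `distribution_matrix`.
#' @export
distribution_matrix_from_counts <- function(counts, tiers) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) abort("distribution matrix counts must be nonnegative")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort("duplicate family or genome ids in distribution matrix")
  }
  if (!all(colnames(counts) %in% names(tiers))) {
    abort("every genome column needs a taxon tier")
  }
  structure(list(counts = counts, tiers = tiers[colnames(counts)]),
            class = "distribution_matrix")
}

#' @export
print.distribution_matrix <- function(x, ...) {
  cat("<distribution_matrix> ", nrow(x$counts), " families x ",
      ncol(x$counts), " genomes\n", sep = "")
  invisible(x)
}

#' Family-by-genome distribution matrix from an inventory
#'
#' Each cell counts the main-list members of a family in a genome; row and
#' column sums therefore equal the inventory's per-family and per-genome
#' main-list totals (over family-assigned sequences).
#'
#' @param inv An `sdr_inventory` (see [build_inventory()]).
#' @param tiers Named character vector genome -> tier.
#' @param genomes Optional genome ordering (defaults to `names(tiers)`).
#' @return A `distribution_matrix`.
#' @export
distribution_matrix <- function(inv, tiers, genomes = names(tiers)) {
  stopifnot(inherits(inv, "sdr_inventory"))
  fams <- sort(unique(inv$main$family_id[!is.na(inv$main$family_id)]))
  m <- matrix(0L, nrow = length(fams), ncol = length(genomes),
              dimnames = list(fams, genomes))
  tab <- inv$counts
  for (r in seq_len(nrow(tab))) {
    m[tab$family_id[r], tab$genome[r]] <- tab$n[r]
  }
  distribution_matrix_from_counts(m, tiers)
}

#' Occurrence class of each family over the taxon hierarchy
#'
#' A family present (count > 0 in at least one genome) in the alga tier is
#' `ViridP`; otherwise presence in the bryophyte tier gives `LandP`, in the
#' lycophyte tier `TracheoP`, and angiosperm-only families are `FlowerP`.
#' Presence inferred from algae outside the surveyed genomes can be supplied
#' as an override (`starred`). All-zero rows are an error.
#'
#' @param m A `distribution_matrix`.
#' @param starred_overrides Family ids whose algal presence is known from
#'   genomes outside the matrix; they are labelled `ViridP` and starred.
#' @return A tibble `family_id`, `label`, `starred`.
#' @export
assign_occurrence <- function(m, starred_overrides = character()) {
  stopifnot(inherits(m, "distribution_matrix"))
  zero <- rownames(m$counts)[rowSums(m$counts) == 0]
  if (length(zero)) {
    abort(paste0("empty family row(s): ", paste(zero, collapse = ", ")))
  }
  tier_present <- function(fam, tier) {
    cols <- names(m$tiers)[m$tiers == tier]
    length(cols) > 0 && any(m$counts[fam, cols] > 0)
  }
  bind_rows(map(rownames(m$counts), function(f) {
    starred <- f %in% starred_overrides
    label <- if (tier_present(f, "alga") || starred) {
      "ViridP"
    } else if (tier_present(f, "bryophyte")) {
      "LandP"
    } else if (tier_present(f, "lycophyte")) {
      "TracheoP"
    } else {
      "FlowerP"
    }
    tibble(family_id = f, label = label, starred = starred)
  }))
}

#' Principal component analysis of a distribution matrix
#'
#' Families are the individuals and genomes the variables: the (centered,
#' by default unscaled) family-by-genome count matrix is decomposed so that
#' axis scores separate expanded families and loadings show each genome's
#' contribution. Axes are ordered by decreasing variance; each loading
#' vector's largest-magnitude entry is made positive.
#'
#' @param m A `distribution_matrix` (>= 2 families and >= 2 genomes).
#' @param center,scale Centering/scaling flags passed to the decomposition.
#' @return An `sdr_pca`: `scores` (tibble `family_id`, `PC1`, ...),
#'   `loadings` (tibble `genome`, `PC1`, ...), `variance_pct`, `centering`.
#' @export
pca_distribution <- function(m, center = TRUE, scale = FALSE) {
  stopifnot(inherits(m, "distribution_matrix"))
  x <- m$counts
  if (nrow(x) < 2 || ncol(x) < 2) {
    abort("pca needs at least 2 families and 2 genomes")
  }
  if (all(apply(x, 2, function(c) length(unique(c)) == 1))) {
    abort("degenerate variance: the distribution matrix is constant")
  }
  pr <- prcomp(x, center = center, scale. = scale)
  # sign convention: largest-|.| loading entry positive per axis
  for (k in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[i, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  varpct <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  structure(list(
    scores = bind_cols(tibble(family_id = rownames(x)),
                       as_tibble(pr$x)),
    loadings = bind_cols(tibble(genome = colnames(x)),
                         as_tibble(pr$rotation)),
    variance_pct = varpct,
    centering = list(center = center, scale = scale,
                     center_values = if (isTRUE(center)) pr$center else NULL,
                     scale_values = if (isTRUE(scale)) pr$scale else NULL)
  ), class = "sdr_pca")
}

#' @export
print.sdr_pca <- function(x, ...) {
  cat("<sdr_pca> ", nrow(x$scores), " families, PC1 ",
      sprintf("%.1f%%", x$variance_pct[1]), ", PC2 ",
      sprintf("%.1f%%", x$variance_pct[2] %||% NA), "\n", sep = "")
  invisible(x)
}

#' PCA robustness to the most extreme family
#'
#' Re-runs [pca_distribution()] after removing the family with the largest
#' centered row norm (the extreme individual) and reports the Spearman rank
#' concordance of the first-axis family ordering over the shared families.
#'
#' @param m A `distribution_matrix` with >= 3 families.
#' @param ... Passed to [pca_distribution()].
#' @return A list `full`, `reduced` (both `sdr_pca`), `removed_family`,
#'   `rank_concordance`.
#' @export
pca_robustness <- function(m, ...) {
  stopifnot(inherits(m, "distribution_matrix"))
  if (nrow(m$counts) < 3) abort("pca_robustness needs at least 3 families")
  centered <- sweep(m$counts, 2, colMeans(m$counts))
  extreme <- rownames(m$counts)[which.max(rowSums(centered^2))]
  full <- pca_distribution(m, ...)
  reduced_m <- distribution_matrix_from_counts(
    m$counts[setdiff(rownames(m$counts), extreme), , drop = FALSE], m$tiers
  )
  reduced <- pca_distribution(reduced_m, ...)
  shared <- intersect(full$scores$family_id, reduced$scores$family_id)
  r1 <- rank(full$scores$PC1[match(shared, full$scores$family_id)])
  r2 <- rank(reduced$scores$PC1[match(shared, reduced$scores$family_id)])
  conc <- stats::cor(r1, r2, method = "spearman")
  list(full = full, reduced = reduced, removed_family = extreme,
       rank_concordance = conc)
}

#' Export a distribution matrix as TSV plus a heat-map image
#'
#' The TSV (families as rows, genomes as columns) is the contract and is
#' byte-deterministic; the blue-to-red heat map with white squares for absent
#' families is rendered on a best-effort basis (some headless graphics
#' devices are unavailable).
#'
#' @param m A `distribution_matrix`.
#' @param path Output TSV path; the image gets the same stem with `.png`.
#' @return Invisibly, the vector of written paths.
#' @export
heatmap_export <- function(m, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(paste0("unwritable path: ", dir))
  df <- bind_cols(tibble(family_id = rownames(m$counts)),
                  as_tibble(m$counts))
  readr::write_tsv(df, path)
  written <- path
  img <- sub("\\.tsv$", ".png", path)
  ok <- tryCatch({
    p <- autoplot(m)
    suppressMessages(ggplot2::ggsave(img, p, width = 7, height = 7, dpi = 120))
    TRUE
  }, error = function(e) FALSE)
  if (ok) written <- c(written, img)
  invisible(written)
}

#' Re-read a distribution-matrix TSV
#' @param path TSV written by [heatmap_export()].
#' @param tiers Named character vector genome -> tier.
#' @return A `distribution_matrix`.
#' @export
read_distribution_tsv <- function(path, tiers) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$family_id
  distribution_matrix_from_counts(m, tiers)
}
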
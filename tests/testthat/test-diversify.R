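toy_dm <- function() {
  counts <- matrix(
    c(2, 0, 0, 0,
      3, 2, 0, 1,
      0, 1, 2, 2,
      0, 0, 0, 4,
      1, 1, 1, 20),
    nrow = 5, byrow = TRUE,
    dimnames = list(c("ALGONLY1C", "VIRID1C", "LAND1E", "FLOWER1E", "BIG1C"),
                    c("alga1", "moss1", "lyco1", "angio1"))
  )
  distribution_matrix_from_counts(
    counts, c(alga1 = "alga", moss1 = "bryophyte", lyco1 = "lycophyte",
              angio1 = "angiosperm")
  )
}

test_that("occurrence classes follow the tier hierarchy", {
  occ <- assign_occurrence(toy_dm())
  lab <- setNames(occ$label, occ$family_id)
  expect_equal(unname(lab["ALGONLY1C"]), "ViridP") # present in the alga
  expect_equal(unname(lab["VIRID1C"]), "ViridP")
  expect_equal(unname(lab["LAND1E"]), "LandP")     # absent from the alga
  expect_equal(unname(lab["FLOWER1E"]), "FlowerP") # angiosperm only
  expect_true(all(!occ$starred))
  expect_equal(nrow(occ), 5L) # every family gets exactly one label
})

test_that("starred overrides force ViridP for algal presence known
           elsewhere", {
  occ <- assign_occurrence(toy_dm(), starred_overrides = "LAND1E")
  expect_equal(occ$label[occ$family_id == "LAND1E"], "ViridP")
  expect_true(occ$starred[occ$family_id == "LAND1E"])
})

test_that("an all-zero family row is an error", {
  m <- toy_dm()
  m$counts["VIRID1C", ] <- 0
  expect_error(assign_occurrence(m), "VIRID1C")
})

test_that("the distribution matrix reproduces inventory counts exactly", {
  genomes <- default_genome_roster(1)
  specs <- default_family_specs(n_families = 4, genomes = genomes,
                                members_per_genome = 2, rng_seed = 23)
  gs <- make_genome_set(specs, genomes = genomes, decoy_count = 4,
                        truncation_rate = 0, multimodel_rate = 0,
                        rng_seed = 23)
  models <- train_sdr_models(gs)
  inv <- build_inventory(gs$proteome, models$pfam_models, models$type_models,
                         models$family_models, models$cutoffs,
                         cross_genome_selection = FALSE)
  tiers <- setNames(genomes$tier, genomes$genome)
  dm <- distribution_matrix(inv, tiers)
  truth_counts <- dplyr::count(
    gs$truth[is.na(gs$truth$decoy_class), ], family_id, genome_id
  )
  for (r in seq_len(nrow(truth_counts))) {
    expect_equal(
      dm$counts[truth_counts$family_id[r], truth_counts$genome_id[r]],
      truth_counts$n[r], ignore_attr = TRUE
    )
  }
  # column sums equal per-genome main-list sizes (all assigned here)
  per_genome <- table(inv$main$genome[!is.na(inv$main$family_id)])
  expect_equal(colSums(dm$counts)[names(per_genome)],
               as.numeric(per_genome), ignore_attr = TRUE)
})

test_that("PCA variance fractions are exact in closed form for 2x2", {
  counts <- matrix(c(1, 5, 3, 7), 2, 2,
                   dimnames = list(c("f1", "f2"), c("g1", "g2")))
  dm <- distribution_matrix_from_counts(
    counts, c(g1 = "alga", g2 = "angiosperm")
  )
  p <- pca_distribution(dm)
  ev <- eigen(cov(counts))$values
  expect_equal(p$variance_pct, 100 * ev / sum(ev), tolerance = 1e-9)
  expect_equal(sum(p$variance_pct), 100, tolerance = 1e-9)
})

test_that("PCA agrees with an independent eigendecomposition and
           reconstructs the data", {
  m <- make_expansion_matrix(n_families = 20, n_genomes = 6,
                             diversified_ids = sprintf("F%02d", 1:3),
                             rng_seed = 31)
  p <- pca_distribution(m)
  x <- m$counts
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p$variance_pct, 100 * ev / sum(ev), tolerance = 1e-8)
  # full reconstruction of the centered matrix
  scores <- as.matrix(p$scores[, -1])
  load <- as.matrix(p$loadings[, -1])
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(scores %*% t(load), centered, tolerance = 1e-8,
               ignore_attr = TRUE)
  # loadings orthonormal; sign convention: max-|.| entry positive
  expect_equal(t(load) %*% load, diag(ncol(load)), tolerance = 1e-8,
               ignore_attr = TRUE)
  for (k in seq_len(ncol(load))) {
    expect_gt(load[which.max(abs(load[, k])), k], 0)
  }
})

test_that("a variance-free matrix is a degenerate-variance error", {
  counts <- matrix(2, 3, 3, dimnames = list(paste0("f", 1:3),
                                            paste0("g", 1:3)))
  dm <- distribution_matrix_from_counts(
    counts, setNames(rep("angiosperm", 3), paste0("g", 1:3))
  )
  expect_error(pca_distribution(dm), "degenerate")
})

test_that("robustness analysis removes the extreme family and keeps the
           diversified ranking", {
  m <- make_expansion_matrix(n_families = 49, n_genomes = 10,
                             diversified_ids = sprintf("F%02d", 1:5),
                             rng_seed = 37)
  rob <- pca_robustness(m)
  expect_true(rob$removed_family %in% sprintf("F%02d", 1:5))
  expect_false(rob$removed_family %in% rob$reduced$scores$family_id)
  remaining <- setdiff(sprintf("F%02d", 1:5), rob$removed_family)
  top4 <- rob$reduced$scores$family_id[
    order(-rob$reduced$scores$PC1)][1:4]
  expect_setequal(top4, remaining)
  expect_gte(rob$rank_concordance, -1)
  expect_lte(rob$rank_concordance, 1)
  expect_gt(rob$rank_concordance, 0.8) # expansion ranking is stable here
})

test_that("heat-map export writes a deterministic TSV that round-trips", {
  dm <- toy_dm()
  dir <- tempfile("hm")
  dir.create(dir)
  p <- file.path(dir, "dist.tsv")
  heatmap_export(dm, p)
  dm2 <- read_distribution_tsv(p, dm$tiers)
  expect_equal(dm2$counts, dm$counts)
  b1 <- readBin(p, "raw", file.size(p))
  heatmap_export(dm, p)
  b2 <- readBin(p, "raw", file.size(p))
  expect_identical(b1, b2)
  expect_error(heatmap_export(dm, file.path(dir, "nope", "x.tsv")),
               "unwritable")
})

test_that("autoplot renders heat map and PCA biplot objects", {
  dm <- toy_dm()
  g1 <- autoplot(dm)
  expect_s3_class(g1, "ggplot")
  m <- make_expansion_matrix(n_families = 15, n_genomes = 5,
                             diversified_ids = c("F01", "F02"), rng_seed = 2)
  g2 <- autoplot(pca_distribution(m))
  expect_s3_class(g2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(g1))
  expect_no_error(ggplot2::ggplot_build(g2))
})

test_that("published tables recount to the printed headline numbers", {
  rc <- recount_published_tables()
  expect_equal(rc$n_families, 49L)
  expect_equal(rc$n_hmm_families, 42L)
  expect_equal(rc$n_orphan_families, 7L)
  gt <- rc$genome_totals
  expect_equal(gt$recounted_total, gt$printed_total)
  expect_equal(gt$printed_total[gt$species == "Arabidopsis"], 178)
  expect_equal(gt$printed_total[gt$species == "Soybean"], 315)
  expect_equal(gt$printed_total[gt$species == "Chlamydomonas"], 68)
})
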
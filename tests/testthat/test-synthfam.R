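toy_spec <- function(t = 0.6, mpg = c(alga1 = 2, moss1 = 2),
                     id = "TOY01C", type = "classical", len = 120) {
  set.seed(999)
  anc <- paste(sample(AA20, len, replace = TRUE), collapse = "")
  family_spec(id, type, anc, t, mpg)
}

test_that("invalid family specs are rejected", {
  expect_error(family_spec("F1C", "classical", "", 0.5, c(g = 1)), "ancestor")
  expect_error(family_spec("F1C", "classical", "ACDE", 0, c(g = 1)),
               "target_identity")
  expect_error(family_spec("F1C", "classical", "ACDE", 1.2, c(g = 1)),
               "target_identity")
  expect_error(family_spec("F1C", "weird", "ACDE", 0.5, c(g = 1)), "sdr_type")
  expect_error(family_spec("F1C", "classical", "ACDE", 0.5, c(g = -1)),
               "negative")
})

test_that("identity 1 reproduces the ancestor with a gap-free seed
           alignment", {
  spec <- toy_spec(t = 1)
  fam <- make_family(spec, rng_seed = 4)
  expect_true(all(fam$members$sequence == spec$ancestor))
  expect_false(any(grepl("-", fam$seed_aln$rows)))
  expect_gte(length(fam$seed_aln$rows), 3)
})

test_that("members track the target identity measured by local alignment", {
  spec <- toy_spec(t = 0.5, mpg = c(alga1 = 10, moss1 = 10), len = 200)
  fam <- make_family(spec, rng_seed = 5)
  ids <- vapply(fam$members$sequence,
                function(s) local_align(s, spec$ancestor)$identity, 0)
  expect_equal(mean(ids), 0.5, tolerance = 0.05)
})

test_that("the generator is bit-deterministic under a fixed seed", {
  spec <- toy_spec()
  f1 <- make_family(spec, rng_seed = 11)
  f2 <- make_family(spec, rng_seed = 11)
  expect_identical(f1, f2)
  gs1 <- make_genome_set(list(toy_spec()), decoy_count = 6,
                         truncation_rate = 0.3, rng_seed = 3,
                         genomes = default_genome_roster(1))
  gs2 <- make_genome_set(list(toy_spec()), decoy_count = 6,
                         truncation_rate = 0.3, rng_seed = 3,
                         genomes = default_genome_roster(1))
  expect_identical(gs1$proteome, gs2$proteome)
  expect_identical(gs1$truth, gs2$truth)
})

test_that("truth table and FASTA are mutually complete", {
  genomes <- default_genome_roster(1)
  specs <- default_family_specs(n_families = 4, genomes = genomes,
                                members_per_genome = 2, rng_seed = 2)
  gs <- make_genome_set(specs, genomes = genomes, decoy_count = 6,
                        truncation_rate = 0.2, multimodel_rate = 0.2,
                        rng_seed = 2)
  expect_setequal(gs$proteome$seq_id, gs$truth$seq_id)
  expect_equal(anyDuplicated(gs$truth$seq_id), 0L)
  # zero-decoy, zero-truncation set: everything carries a family
  gs0 <- make_genome_set(specs, genomes = genomes, decoy_count = 0,
                         truncation_rate = 0, multimodel_rate = 0,
                         rng_seed = 2)
  expect_true(all(!is.na(gs0$truth$family_id)))
  expect_true(all(!gs0$truth$truncated))
})

test_that("a family absent from a tier has no members there", {
  genomes <- default_genome_roster(1)
  mpg <- c(alga1 = 0, moss1 = 2, lyco1 = 2, angio1 = 2)
  spec <- family_spec("NOALGA1C", "classical",
                      paste(rep("ACDEFGHIKL", 12), collapse = ""), 0.7, mpg)
  gs <- make_genome_set(list(spec), genomes = genomes, decoy_count = 0,
                        truncation_rate = 0, rng_seed = 1)
  expect_false("alga1" %in% gs$proteome$genome)
})

test_that("truncated members are contiguous fragments of at least 40
           residues", {
  genomes <- default_genome_roster(1)
  specs <- default_family_specs(n_families = 3, genomes = genomes,
                                members_per_genome = 3, rng_seed = 6)
  gs <- make_genome_set(specs, genomes = genomes, decoy_count = 0,
                        truncation_rate = 1, multimodel_rate = 0, rng_seed = 6)
  expect_true(all(gs$truth$truncated))
  expect_true(all(nchar(gs$proteome$sequence) >= 40))
  full_len <- nchar(specs[[1]]$ancestor)
  expect_true(all(nchar(gs$proteome$sequence) < full_len + 60))
})

test_that("decoys lack the catalytic motif and carry no family", {
  genomes <- default_genome_roster(1)
  specs <- default_family_specs(n_families = 3, genomes = genomes,
                                members_per_genome = 2, rng_seed = 8)
  gs <- make_genome_set(specs, genomes = genomes, decoy_count = 10,
                        truncation_rate = 0, rng_seed = 8)
  dec <- gs$truth[!is.na(gs$truth$decoy_class), ]
  expect_equal(nrow(dec), 10L)
  expect_true(all(is.na(dec$family_id)))
  dec_seqs <- gs$proteome$sequence[match(dec$seq_id, gs$proteome$seq_id)]
  expect_false(any(grepl("Y.{3}K", dec_seqs)))
  # medium-chain-like decoys still show the cofactor motif
  mdr <- dec_seqs[dec$decoy_class == "mdr_like"]
  expect_true(all(grepl("GASRGIG", mdr)))
})

test_that("duplicate family ids are rejected", {
  s <- toy_spec()
  expect_error(make_genome_set(list(s, s), genomes = default_genome_roster(1)),
               "duplicate")
})

test_that("genome-set files round-trip through disk", {
  genomes <- default_genome_roster(1)
  specs <- default_family_specs(n_families = 3, genomes = genomes,
                                members_per_genome = 1, rng_seed = 3)
  gs <- make_genome_set(specs, genomes = genomes, decoy_count = 2,
                        truncation_rate = 0, rng_seed = 3)
  dir <- tempfile("gsout")
  paths <- write_genome_set(gs, dir)
  expect_true(all(file.exists(paths)))
  fa <- read_fasta(file.path(dir, "alga1.faa"))
  in_alga <- gs$proteome[gs$proteome$genome == "alga1", ]
  expect_equal(fa$id, in_alga$seq_id)
  expect_equal(fa$sequence, in_alga$sequence)
  aln <- read_stockholm(file.path(dir, paste0("seed_", specs[[1]]$family_id,
                                              ".sto")))
  expect_equal(aln$rows, gs$seeds[[specs[[1]]$family_id]]$rows)
})

test_that("expansion matrix plants diversified families recoverable by PCA", {
  m <- make_expansion_matrix(n_families = 49, n_genomes = 10,
                             diversified_ids = sprintf("F%02d", 1:5),
                             rng_seed = 5)
  expect_true(all(m$counts >= 0))
  expect_identical(m$counts, round(m$counts))
  m2 <- make_expansion_matrix(n_families = 49, n_genomes = 10,
                              diversified_ids = sprintf("F%02d", 1:5),
                              rng_seed = 5)
  expect_identical(m$counts, m2$counts)
  pca <- pca_distribution(m)
  top5 <- pca$scores$family_id[order(-pca$scores$PC1)][1:5]
  expect_setequal(top5, sprintf("F%02d", 1:5))
  expect_error(make_expansion_matrix(n_families = 1), "n_families")
})

test_that("an expansion matrix without diversified families has a weak
           first axis", {
  m <- make_expansion_matrix(n_families = 30, n_genomes = 8,
                             diversified_ids = character(0), rng_seed = 9)
  pca <- pca_distribution(m)
  expect_lt(pca$variance_pct[1], 60)
})
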
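# Decision-tree unit tests drive decide_sdr() with hand-built hit tables
# (scores in bits against the published cutoffs), so each rule fires exactly
# as documented regardless of any trained model.

hit_row <- function(seq_id, tier, model_id, score,
                    cut = NA_real_, floor = NA_real_) {
  tibble::tibble(seq_id = seq_id, tier = tier, model_id = model_id,
                 score = score,
                 passes_cutoff = !is.na(cut) & score >= cut,
                 passes_floor = !is.na(floor) & score >= floor)
}

plant_cutoffs <- type_cutoffs(
  inclusion = c(classical = 138, extended = 108, divergent = 160),
  unknown_floor = c(classical = 29, extended = 75, divergent = 100)
)
tmap <- c(type_classical = "classical", type_extended = "extended",
          type_divergent = "divergent")

test_that("type cutoffs validate floor < inclusion and keep published
           defaults", {
  ct <- type_cutoffs()
  expect_equal(unname(ct$inclusion[c("classical", "extended", "intermediate",
                                     "divergent", "complex")]),
               c(138, 108, 162, 160, 140))
  expect_equal(unname(ct$unknown_floor[c("classical", "extended",
                                         "divergent")]),
               c(29, 75, 100))
  expect_error(type_cutoffs(inclusion = c(classical = 20),
                            unknown_floor = c(classical = 29)), "below")
})

test_that("a family-tier pass is directly positive with the suffix type", {
  hits <- dplyr::bind_rows(
    hit_row("s1", "family_set", "SDR110C", 250, cut = 100),
    hit_row("s1", "pfam_set", "PF1", 10, cut = 50),
    hit_row("s1", "type_set", "type_classical", 20, cut = 138, floor = 29)
  )
  out <- decide_sdr(hits, plant_cutoffs, tmap)
  expect_equal(out$verdict, "positive")
  expect_equal(out$sdr_type, "classical")
  expect_equal(out$family_id, "SDR110C")

  for (case in list(c("SDR108E", "extended"), c("SDR87D", "divergent"),
                    c("SDR75U", "unknown"), c("SDR460A", "atypical"))) {
    h <- hit_row("s1", "family_set", case[1], 250, cut = 100)
    o <- decide_sdr(h, plant_cutoffs, tmap)
    expect_equal(o$verdict, "positive")
    expect_equal(o$sdr_type, case[2])
  }
})

test_that("an atypical family pass wins despite below-floor type scores", {
  hits <- dplyr::bind_rows(
    hit_row("s1", "family_set", "SDR460A", 180, cut = 100),
    hit_row("s1", "pfam_set", "PF1", 5, cut = 50),
    hit_row("s1", "type_set", "type_classical", 3, cut = 138, floor = 29),
    hit_row("s1", "type_set", "type_extended", -2, cut = 108, floor = 75)
  )
  out <- decide_sdr(hits, plant_cutoffs, tmap)
  expect_equal(out$verdict, "positive")
  expect_equal(out$sdr_type, "atypical")
})

test_that("pfam + passing type gives a positive of that type", {
  hits <- dplyr::bind_rows(
    hit_row("s1", "pfam_set", "PF1", 80, cut = 50),
    hit_row("s1", "type_set", "type_classical", 150, cut = 138, floor = 29)
  )
  out <- decide_sdr(hits, plant_cutoffs, tmap)
  expect_equal(out$verdict, "positive")
  expect_equal(out$sdr_type, "classical")
})

test_that("type-score ties break classical > extended > divergent", {
  hits <- dplyr::bind_rows(
    hit_row("s1", "pfam_set", "PF1", 80, cut = 50),
    hit_row("s1", "type_set", "type_extended", 200, cut = 108, floor = 75),
    hit_row("s1", "type_set", "type_classical", 200, cut = 138, floor = 29)
  )
  out <- decide_sdr(hits, plant_cutoffs, tmap)
  expect_equal(out$sdr_type, "classical")
})

test_that("pfam + above-floor type score is positive with type unknown", {
  hits <- dplyr::bind_rows(
    hit_row("s1", "pfam_set", "PF1", 80, cut = 50),
    hit_row("s1", "type_set", "type_classical", 30, cut = 138, floor = 29)
  )
  out <- decide_sdr(hits, plant_cutoffs, tmap)
  expect_equal(out$verdict, "positive")
  expect_equal(out$sdr_type, "unknown")
  expect_match(out$evidence, "floor")
})

test_that("single-tier recognition defers: ambiguous, whitelisted or
           excluded", {
  hits <- hit_row("s1", "pfam_set", "PF1", 80, cut = 50)
  expect_equal(decide_sdr(hits, plant_cutoffs, tmap)$verdict, "ambiguous")

  wl <- tibble::tibble(seq_id = "s1", sdr_type = "atypical")
  o2 <- decide_sdr(hits, plant_cutoffs, tmap, whitelist = wl)
  expect_equal(o2$verdict, "positive")
  expect_equal(o2$sdr_type, "atypical")

  o3 <- decide_sdr(hits, plant_cutoffs, tmap, exclusion = "s1")
  expect_equal(o3$verdict, "negative")

  expect_error(
    decide_sdr(hits, plant_cutoffs, tmap, whitelist = wl, exclusion = "s1"),
    "configuration"
  )
})

test_that("no recognition anywhere is negative; a rescue assignment upgrades
           it", {
  hits <- dplyr::bind_rows(
    hit_row("s1", "pfam_set", "PF1", 4, cut = 50),
    hit_row("s1", "type_set", "type_classical", 6, cut = 138, floor = 29)
  )
  out <- decide_sdr(hits, plant_cutoffs, tmap)
  expect_equal(out$verdict, "negative")
  expect_true(is.na(out$sdr_type))

  resc <- tibble::tibble(seq_id = "s1", rescued = TRUE,
                         family_id = "SDR110C", sdr_type = "classical",
                         homolog_id = "pos1", score = 300,
                         segment_identity = 0.9)
  o2 <- decide_sdr(hits, plant_cutoffs, tmap, rescue = resc)
  expect_equal(o2$verdict, "positive")
  expect_equal(o2$family_id, "SDR110C")
  expect_match(o2$evidence, "rescued")
})

test_that("decisions are stable under hit-table row permutations", {
  set.seed(12)
  hits <- dplyr::bind_rows(
    hit_row("s1", "pfam_set", "PF1", 80, cut = 50),
    hit_row("s1", "pfam_set", "PF2", 60, cut = 50),
    hit_row("s1", "type_set", "type_classical", 150, cut = 138, floor = 29),
    hit_row("s1", "type_set", "type_extended", 120, cut = 108, floor = 75),
    hit_row("s1", "family_set", "SDR65C", 90, cut = 100)
  )
  ref <- decide_sdr(hits, plant_cutoffs, tmap)
  for (k in 1:10) {
    perm <- hits[sample(nrow(hits)), ]
    expect_equal(decide_sdr(perm, plant_cutoffs, tmap), ref)
  }
})

test_that("gene-model selection follows HMM score, then alignment score,
           and flags contradictions", {
  models <- tibble::tibble(seq_id = c("m1", "m2"),
                           sequence = c("MKVLITGASRGIGKAIA", "WWPPQQNNLLRR"))
  hits <- dplyr::bind_rows(
    hit_row("m1", "family_set", "F", 120, cut = 100),
    hit_row("m2", "family_set", "F", 90, cut = 100)
  )
  sel <- select_gene_model(models, hits)
  expect_equal(sel$chosen, "m1")
  expect_true(is.na(sel$flag))

  # HMM tie: the cross-genome alignment decides
  hits_tie <- dplyr::bind_rows(
    hit_row("m1", "family_set", "F", 100, cut = 100),
    hit_row("m2", "family_set", "F", 100, cut = 100)
  )
  db <- c(x = "WWPPQQNNLLRR") # exact match to m2 only
  sel2 <- select_gene_model(models, hits_tie, db)
  expect_equal(sel2$chosen, "m2")
  expect_true(is.na(sel2$flag))

  # disagreement: HMM prefers m1, alignment prefers m2 -> flagged,
  # HMM winner kept provisionally
  sel3 <- select_gene_model(models, hits, db)
  expect_equal(sel3$chosen, "m1")
  expect_equal(sel3$flag, "manual-review")
})

test_that("rescue inherits from the best qualifying homolog only", {
  set.seed(14)
  base_a <- random_protein(150)
  base_b <- random_protein(150)
  positives <- tibble::tibble(
    seq_id = c("pa", "pb"),
    sequence = c(base_a, base_b),
    sdr_type = c("classical", "extended"),
    family_id = c("FAMA1C", "FAMB1E")
  )
  frag80 <- substr(base_a, 20, 99)   # 80-residue exact fragment
  frag50 <- substr(base_a, 20, 69)   # 50-residue exact fragment
  un <- tibble::tibble(seq_id = c("u80", "u50"),
                       sequence = c(frag80, frag50))
  r <- rescue_truncated(un, positives)
  expect_true(r$rescued[r$seq_id == "u80"])
  expect_equal(r$family_id[r$seq_id == "u80"], "FAMA1C")
  expect_false(r$rescued[r$seq_id == "u50"])

  # a fragment matching both families inherits the higher-scoring one
  chim <- paste0(substr(base_a, 1, 80), substr(base_b, 1, 70))
  r2 <- rescue_truncated(tibble::tibble(seq_id = "chim", sequence = chim),
                         positives)
  expect_true(r2$rescued)
  al_a <- local_align(chim, base_a)
  al_b <- local_align(chim, base_b)
  expect_equal(r2$family_id,
               positives$family_id[which.max(c(al_a$score, al_b$score))])
})

test_that("orphan clustering single-links through chains and leaves
           singletons unclassified", {
  set.seed(15)
  base <- random_protein(260)
  mut <- function(s, p) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), round(p * length(ch)))
    ch[idx] <- sample(AA20, length(idx), replace = TRUE)
    paste(ch, collapse = "")
  }
  a <- mut(base, 0.25)
  b <- base
  c <- mut(base, 0.25)
  lone <- random_protein(260)
  orp <- tibble::tibble(seq_id = c("a", "b", "c", "lone"),
                        sequence = c(a, b, c, lone))
  res <- cluster_orphans(orp, evalue_threshold = 1e-40)
  cl <- res$assignments
  expect_equal(length(unique(cl$cluster_id[cl$seq_id %in% c("a", "b", "c")])),
               1L)
  expect_true(is.na(cl$cluster_id[cl$seq_id == "lone"]))
  expect_equal(res$clusters$n, 3L)
  expect_true(res$clusters$representative_id %in% c("a", "b", "c"))
  expect_gt(res$clusters$mean_pairwise_identity, 0.4)
})

test_that("full inventory recovers truth and partitions every sequence", {
  genomes <- default_genome_roster(1)
  specs <- default_family_specs(n_families = 4, genomes = genomes,
                                members_per_genome = 2, rng_seed = 17)
  gs <- make_genome_set(specs, genomes = genomes, decoy_count = 6,
                        truncation_rate = 0, multimodel_rate = 0,
                        rng_seed = 17)
  models <- train_sdr_models(gs)
  inv <- build_inventory(gs$proteome, models$pfam_models, models$type_models,
                         models$family_models, models$cutoffs,
                         cross_genome_selection = FALSE)
  all_ids <- c(inv$main$seq_id, inv$ambiguous$seq_id, inv$negative$seq_id)
  expect_setequal(all_ids, gs$proteome$seq_id)
  expect_equal(anyDuplicated(all_ids), 0L)

  truth <- gs$truth
  planted <- truth[is.na(truth$decoy_class), ]
  got <- inv$main[match(planted$seq_id, inv$main$seq_id), ]
  expect_true(all(got$family_id == planted$family_id, na.rm = TRUE))
  expect_true(all(planted$seq_id %in% inv$main$seq_id))
  decs <- truth$seq_id[!is.na(truth$decoy_class)]
  expect_false(any(decs %in% inv$main$seq_id))

  # per-family counts match the truth table
  cnt <- dplyr::count(planted, family_id, genome_id)
  for (r in seq_len(nrow(cnt))) {
    got_n <- inv$counts$n[inv$counts$family_id == cnt$family_id[r] &
                            inv$counts$genome == cnt$genome_id[r]]
    expect_equal(got_n, cnt$n[r])
  }

  # empty input gives an empty inventory
  inv0 <- build_inventory(gs$proteome[0, ], models$pfam_models,
                          models$type_models, models$family_models,
                          models$cutoffs)
  expect_equal(nrow(inv0$main), 0L)
  expect_equal(sum(inv0$log), 0L)
})

test_that("inventory TSV export writes the three contract files", {
  genomes <- default_genome_roster(1)
  specs <- default_family_specs(n_families = 3, genomes = genomes,
                                members_per_genome = 1, rng_seed = 19)
  gs <- make_genome_set(specs, genomes = genomes, decoy_count = 0,
                        truncation_rate = 0, rng_seed = 19)
  models <- train_sdr_models(gs)
  inv <- build_inventory(gs$proteome, models$pfam_models, models$type_models,
                         models$family_models, models$cutoffs,
                         cross_genome_selection = FALSE)
  dir <- tempfile("inv")
  paths <- write_inventory(inv, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_tsv(paths[1], show_col_types = FALSE)
  expect_equal(nrow(back), nrow(inv$main))
})
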
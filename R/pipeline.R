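# Pipeline configuration and staged driver tying the modules together:
# simulate -> train -> scan -> classify -> phylo -> pca, with artifacts and a
# machine-readable run log on disk for every stage.

#' Pipeline configuration
#'
#' Collects the tunable constants of the inventory pipeline. Defaults are the
#' published values: rescue window 60 residues at >50% identity, orphan
#' E-value threshold 1e-40, 500 bootstrap replicates; type cutoffs are
#' calibrated on the synthetic models during the train stage.
#'
#' @param outdir Output directory for stage artifacts.
#' @param n_families,members_per_genome,decoy_count,truncation_rate,multimodel_rate
#'   Synthetic generator settings (see [make_genome_set()]).
#' @param genomes Genome roster tibble (`genome`, `tier`).
#' @param window,min_identity Rescue rule.
#' @param evalue_threshold Orphan-clustering threshold.
#' @param replicates Bootstrap replicates.
#' @param rng_seed Integer seed for every stochastic stage.
#' @param whitelist Optional tibble `seq_id`, `sdr_type` of forced
#'   inclusions.
#' @param exclusion Character vector of excluded sequence ids.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("sdr_run_"),
                            n_families = 10L,
                            genomes = default_genome_roster(1L),
                            members_per_genome = 3L, decoy_count = 20L,
                            truncation_rate = 0.1, multimodel_rate = 0.05,
                            window = 60L, min_identity = 0.5,
                            evalue_threshold = 1e-40, replicates = 500L,
                            rng_seed = 1L, whitelist = NULL,
                            exclusion = character()) {
  if (window <= 0 || min_identity <= 0 || evalue_threshold <= 0 ||
      replicates <= 0) {
    abort("pipeline_config: thresholds must be positive")
  }
  structure(list(
    outdir = outdir, n_families = n_families, genomes = genomes,
    members_per_genome = members_per_genome, decoy_count = decoy_count,
    truncation_rate = truncation_rate, multimodel_rate = multimodel_rate,
    window = window, min_identity = min_identity,
    evalue_threshold = evalue_threshold, replicates = replicates,
    rng_seed = rng_seed, whitelist = whitelist, exclusion = exclusion
  ), class = "pipeline_config")
}

write_run_log <- function(dir, stage, entries) {
  log <- tibble(key = names(entries),
                value = as.character(unlist(entries)))
  readr::write_tsv(log, file.path(dir, paste0(stage, "_log.tsv")))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic genomes + truth + seeds), `train` (three
#' model tiers with calibrated cutoffs, serialized as profile text), `scan`
#' (three-tier hit table), `classify` (full inventory with rescue and orphan
#' clustering; the run log records the branch counts, which sum to the input
#' size), `phylo` (bootstrap NJ tree of the largest family), `pca`
#' (distribution matrix, heat-map export, PCA scores). Later stages reuse the
#' in-memory state from earlier ones; each writes its artifacts plus a
#' machine-readable log under `config$outdir`. Module errors are rethrown
#' with the stage name attached.
#'
#' @param config A [pipeline_config()].
#' @param subcommand Stage name, or `"all"`.
#' @param state Internal: state list from a previous call.
#' @return Invisibly, the updated state (artifact paths in `state$paths`).
#' @export
run_pipeline <- function(config,
                         subcommand = c("all", "simulate", "train", "scan",
                                        "classify", "phylo", "pca"),
                         state = list()) {
  stopifnot(inherits(config, "pipeline_config"))
  subcommand <- match.arg(subcommand)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (subcommand == "all") {
    c("simulate", "train", "scan", "classify", "phylo", "pca")
  } else {
    subcommand
  }
  for (stage in stages) {
    state <- tryCatch(
      run_stage(stage, config, state),
      error = function(e) {
        abort(paste0("pipeline stage '", stage, "' failed: ",
                     conditionMessage(e)))
      }
    )
  }
  invisible(state)
}

run_stage <- function(stage, config, state) {
  out <- config$outdir
  if (stage == "simulate") {
    specs <- default_family_specs(
      n_families = config$n_families, genomes = config$genomes,
      members_per_genome = config$members_per_genome,
      rng_seed = config$rng_seed
    )
    gs <- make_genome_set(
      specs, genomes = config$genomes, decoy_count = config$decoy_count,
      truncation_rate = config$truncation_rate,
      multimodel_rate = config$multimodel_rate, rng_seed = config$rng_seed
    )
    paths <- write_genome_set(gs, file.path(out, "simulate"))
    write_run_log(out, "simulate", list(
      seed = config$rng_seed, n_families = config$n_families,
      n_proteins = nrow(gs$proteome),
      n_decoys = sum(!is.na(gs$truth$decoy_class))
    ))
    state$gs <- gs
    state$paths <- c(state$paths, paths)
    return(state)
  }
  if (is.null(state$gs)) abort("run the simulate stage first")
  if (stage == "train") {
    models <- train_sdr_models(state$gs)
    mdir <- file.path(out, "models")
    dir.create(mdir, showWarnings = FALSE)
    all_models <- c(models$pfam_models, models$type_models,
                    models$family_models)
    paths <- map_chr(all_models, function(h) {
      p <- file.path(mdir, paste0(h$model_id, ".prof"))
      write_profile(h, p)
      p
    })
    write_run_log(out, "train", list(
      n_models = length(all_models),
      type_cutoffs = paste(names(models$cutoffs$inclusion),
                           round(models$cutoffs$inclusion, 1),
                           sep = "=", collapse = ",")
    ))
    state$models <- models
    state$paths <- c(state$paths, unname(paths))
    return(state)
  }
  if (is.null(state$models)) abort("run the train stage first")
  if (stage == "scan") {
    hits <- scan_three_tiers(state$gs$proteome, state$models$pfam_models,
                             state$models$type_models,
                             state$models$family_models,
                             state$models$cutoffs)
    p <- file.path(out, "hit_table.tsv")
    readr::write_tsv(hits, p)
    write_run_log(out, "scan", list(
      n_scored = nrow(hits),
      n_passing = sum(hits$passes_cutoff)
    ))
    state$hits <- hits
    state$paths <- c(state$paths, p)
    return(state)
  }
  if (stage == "classify") {
    inv <- build_inventory(
      state$gs$proteome, state$models$pfam_models, state$models$type_models,
      state$models$family_models, state$models$cutoffs,
      whitelist = config$whitelist, exclusion = config$exclusion,
      window = config$window, min_identity = config$min_identity,
      evalue_threshold = config$evalue_threshold
    )
    paths <- write_inventory(inv, file.path(out, "inventory"))
    write_run_log(out, "classify", list(
      n_input = nrow(inv$main) + nrow(inv$ambiguous) + nrow(inv$negative),
      positive = unname(inv$log["positive"]),
      ambiguous = unname(inv$log["ambiguous"]),
      negative = unname(inv$log["negative"])
    ))
    state$inventory <- inv
    state$paths <- c(state$paths, paths)
    return(state)
  }
  if (is.null(state$inventory)) abort("run the classify stage first")
  if (stage == "phylo") {
    main <- state$inventory$main
    fam <- names(sort(table(main$family_id), decreasing = TRUE))[1]
    ids <- main$seq_id[!is.na(main$family_id) & main$family_id == fam]
    prot <- state$gs$proteome
    seqs <- setNames(prot$sequence[match(ids, prot$seq_id)], ids)
    seqs <- seqs[nchar(seqs) >= 60] # drop fragments too short to align
    if (length(seqs) < 3) abort("largest family has fewer than 3 usable members")
    msa <- progressive_msa(seqs)
    bt <- bootstrap_support(msa, replicates = config$replicates,
                            rng_seed = config$rng_seed)
    p1 <- file.path(out, paste0("tree_", fam, ".nwk"))
    write_newick(bt, p1)
    p2 <- file.path(out, paste0("tree_", fam, "_supports.tsv"))
    readr::write_tsv(bt$supports, p2)
    write_run_log(out, "phylo", list(
      family = fam, n_tips = length(seqs),
      replicates = config$replicates, skipped = bt$n_skipped
    ))
    state$tree <- bt
    state$paths <- c(state$paths, p1, p2)
    return(state)
  }
  if (stage == "pca") {
    tiers <- setNames(config$genomes$tier, config$genomes$genome)
    dm <- distribution_matrix(state$inventory, tiers)
    p1 <- file.path(out, "distribution_matrix.tsv")
    written <- heatmap_export(dm, p1)
    pca <- pca_distribution(dm)
    p2 <- file.path(out, "pca_scores.tsv")
    p3 <- file.path(out, "pca_loadings.tsv")
    readr::write_tsv(pca$scores, p2)
    readr::write_tsv(pca$loadings, p3)
    occ <- assign_occurrence(dm)
    p4 <- file.path(out, "occurrence.tsv")
    readr::write_tsv(occ, p4)
    write_run_log(out, "pca", list(
      n_families = nrow(dm$counts),
      pc1_variance_pct = round(pca$variance_pct[1], 2),
      pc2_variance_pct = round(pca$variance_pct[2], 2)
    ))
    state$distribution <- dm
    state$pca <- pca
    state$paths <- c(state$paths, written, p2, p3, p4)
    return(state)
  }
  abort(paste0("unknown stage: ", stage))
}
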
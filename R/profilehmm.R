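# Profile hidden Markov models: construction from seed alignments, local
# Viterbi scoring in bits, iterative training against a database, cutoff
# calibration, and a plain-text serialization that round-trips bit-exactly.
#
# Model structure (local mode): M match states with 20-residue emissions;
# insert states I_1..I_{M-1} emitting at background; delete states D_2..D_M.
# Entry is uniform over match states; every match state carries a fixed exit
# probability (the final state exits with probability 1). Scores are maximum
# log-odds (base 2) over all state paths against the background distribution,
# flanking residues free.

PROFILE_EXIT_P <- 0.05

#' Build a profile HMM from a seed alignment
#'
#' Columns whose gap fraction is strictly below `gap_threshold` become match
#' states. Match emissions are relative-frequency estimates regularised with a
#' BLOSUM62-mixture pseudocount of total weight `pseudocount_weight`;
#' transitions are estimated from the observed state paths with Laplace
#' pseudocounts. Insert emissions equal the background.
#'
#' @param aln A [seed_alignment()].
#' @param gap_threshold Gap-fraction threshold for match columns (strict `<`;
#'   a column at exactly the threshold is excluded). Default 0.5.
#' @param pseudocount_weight Positive total pseudocount weight; the default
#'   (5) regularises the small hand-curated seed alignments typical of this
#'   workflow.
#' @param model_id Label for the model.
#' @param model_class One of `"pfam_set"`, `"type_set"`, `"family_set"`.
#' @param inclusion_cutoff Bit-score inclusion cutoff stored on the model
#'   (may be set later with [calibrate_cutoff()]).
#' @param unknown_floor Optional lower bit-score floor (see type models).
#' @return A `profile_hmm` object.
#' @export
build_profile <- function(aln, gap_threshold = 0.5, pseudocount_weight = 5,
                          model_id = "model", model_class = "family_set",
                          inclusion_cutoff = NA_real_,
                          unknown_floor = NA_real_) {
  stopifnot(inherits(aln, "seed_alignment"))
  if (pseudocount_weight <= 0) abort("pseudocount_weight must be positive")
  if (!model_class %in% c("pfam_set", "type_set", "family_set")) {
    abort("model_class must be one of pfam_set, type_set, family_set")
  }
  chars <- do.call(rbind, strsplit(aln$rows, ""))
  gapfrac <- colMeans(chars == "-")
  match_cols <- which(gapfrac < gap_threshold)
  M <- length(match_cols)
  if (M == 0) abort("degenerate model: no column qualifies as a match state")

  cond <- blosum62_conditional()
  emis <- matrix(0, nrow = M, ncol = 20, dimnames = list(NULL, AA_ORDER))
  for (k in seq_len(M)) {
    col <- chars[, match_cols[k]]
    idx <- match(col, AA_ORDER)
    idx <- idx[!is.na(idx)]
    cnt <- tabulate(idx, nbins = 20)
    n <- sum(cnt)
    mix <- if (n > 0) as.vector(cond %*% (cnt / n)) else AA_BACKGROUND
    emis[k, ] <- (cnt + pseudocount_weight * mix) / (n + pseudocount_weight)
  }

  # state paths: M = residue in match column, D = gap in match column,
  # I = residue in a non-match column, attributed to the preceding match state
  cntMM <- cntMI <- cntMD <- cntIM <- cntII <- cntDM <- cntDD <-
    rep(0, max(M - 1, 1))
  is_match <- seq_len(ncol(chars)) %in% match_cols
  midx <- cumsum(is_match) # match-state index per column
  for (r in seq_len(nrow(chars))) {
    prev <- NULL # list(state, j)
    for (cidx in seq_len(ncol(chars))) {
      ch <- chars[r, cidx]
      st <- if (is_match[cidx]) {
        if (ch == "-") "D" else "M"
      } else {
        if (ch == "-") NA_character_ else "I"
      }
      if (is.na(st)) next
      j <- midx[cidx]
      if (!is.null(prev)) {
        pj <- prev$j
        key <- paste0(prev$state, st)
        if (pj >= 1 && pj < M) {
          switch(key,
            MM = cntMM[pj] <- cntMM[pj] + 1,
            MI = cntMI[pj] <- cntMI[pj] + 1,
            MD = cntMD[pj] <- cntMD[pj] + 1,
            IM = cntIM[pj] <- cntIM[pj] + 1,
            II = cntII[pj] <- cntII[pj] + 1,
            DM = cntDM[pj] <- cntDM[pj] + 1,
            DD = cntDD[pj] <- cntDD[pj] + 1)
        }
      }
      # inserts keep the preceding match index; M/D advance it
      prev <- list(state = st, j = j)
    }
  }

  trans <- matrix(NA_real_, nrow = M, ncol = 7,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                          "DM", "DD")))
  if (M > 1) {
    for (j in seq_len(M - 1)) {
      mo <- c(cntMM[j], cntMI[j], cntMD[j]) + 1
      mo <- mo / sum(mo) * (1 - PROFILE_EXIT_P)
      io <- c(cntIM[j], cntII[j]) + 1
      io <- io / sum(io)
      do <- c(cntDM[j], cntDD[j]) + 1
      do <- do / sum(do)
      trans[j, ] <- c(mo, io, do)
    }
  }
  structure(list(
    model_id = model_id, model_class = model_class, match_count = M,
    match_emissions = emis,
    insert_emissions = AA_BACKGROUND,
    transitions = trans,
    entry = rep(1 / M, M),
    exit = c(rep(PROFILE_EXIT_P, max(M - 1, 0)), 1),
    background = AA_BACKGROUND,
    inclusion_cutoff = inclusion_cutoff,
    unknown_floor = unknown_floor
  ), class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("<profile_hmm> ", x$model_id, " [", x$model_class, "], ",
      x$match_count, " match states, cutoff ",
      format(x$inclusion_cutoff), " bits\n", sep = "")
  invisible(x)
}

# log2 pieces handed to the C++ Viterbi kernel
profile_log_parts <- function(hmm) {
  lod <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  tr <- matrix(-Inf, nrow = hmm$match_count, ncol = 7)
  defined <- !is.na(hmm$transitions)
  tr[defined] <- log2(hmm$transitions[defined])
  tr[!is.finite(tr)] <- -1e30
  list(lod = lod, trans = tr, entry = log2(hmm$entry), exit = log2(hmm$exit))
}

#' Score a sequence against a profile HMM
#'
#' Maximum log-odds (base 2, "bits") over all local alignments of the
#' sequence to the model (Viterbi best path) against the background
#' distribution. Ambiguity codes emit at background (contribution 0 bits).
#'
#' @param hmm A `profile_hmm`.
#' @param seq Amino-acid sequence (single string).
#' @return Bit score (may be negative).
#' @export
score_profile <- function(hmm, seq) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    abort("score_profile: sequence must be a non-empty string")
  }
  p <- profile_log_parts(hmm)
  viterbi_score_cpp(encode_seq(seq), p$lod, p$trans, p$entry, p$exit)
}

#' Iteratively train a profile HMM against a sequence database
#'
#' Starting from the seed members, repeatedly: align the current members,
#' build a profile, score the database, and admit every sequence at or above
#' `cutoff` -- until the member set is a fixed point or `max_rounds` is
#' reached. The member set never shrinks and always contains the seeds.
#'
#' @param seed_aln A [seed_alignment()] of the seed members.
#' @param database Named character vector of candidate sequences.
#' @param cutoff Inclusion bit-score cutoff.
#' @param max_rounds Maximum refinement rounds (>= 1).
#' @param ... Passed to [build_profile()].
#' @return A list with `hmm` (trained on the final member alignment),
#'   `members` (character vector of ids), `rounds`, and `converged`.
#' @export
train_iterative <- function(seed_aln, database, cutoff, max_rounds = 10, ...) {
  stopifnot(max_rounds >= 1, is.finite(cutoff))
  if (is.null(names(database))) names(database) <- paste0("db", seq_along(database))
  seed_seqs <- setNames(gsub("-", "", seed_aln$rows), seed_aln$ids)
  members <- seed_seqs
  aln <- seed_aln
  converged <- FALSE
  hmm <- NULL
  rounds <- 0
  for (r in seq_len(max_rounds)) {
    rounds <- r
    hmm <- build_profile(aln, ...)
    scores <- map_dbl(database, ~ score_profile(hmm, .x))
    hits <- database[scores >= cutoff]
    new_members <- c(members, hits[!names(hits) %in% names(members)])
    if (identical(sort(names(new_members)), sort(names(members)))) {
      converged <- TRUE
      break
    }
    members <- new_members
    aln <- progressive_msa(members)
  }
  if (!converged) {
    warn(paste0("train_iterative: not converged after ", max_rounds, " rounds"))
  }
  list(hmm = hmm, members = names(members), rounds = rounds,
       converged = converged)
}

#' Calibrate an inclusion cutoff from positive and decoy scores
#'
#' Returns `min(positive scores) - margin`, floored at
#' `max(decoy scores) + eps`, so that every supplied positive passes and
#' every supplied decoy fails. Overlapping score distributions are an error.
#'
#' @param hmm A `profile_hmm` (scored as-is).
#' @param positives,decoys Character vectors of sequences (>= 1 each).
#' @param margin Nonnegative bit margin subtracted from the weakest positive.
#' @param eps Offset above the strongest decoy.
#' @return The calibrated cutoff in bits.
#' @export
calibrate_cutoff <- function(hmm, positives, decoys, margin = 0, eps = 1e-6) {
  stopifnot(length(positives) >= 1, length(decoys) >= 1, margin >= 0)
  ps <- map_dbl(positives, ~ score_profile(hmm, .x))
  ds <- map_dbl(decoys, ~ score_profile(hmm, .x))
  if (max(ds) >= min(ps)) {
    abort(paste0("calibration failure: max decoy score ", format(max(ds)),
                 " >= min positive score ", format(min(ps))))
  }
  max(min(ps) - margin, max(ds) + eps)
}

#' Write a profile HMM in the package's plain-text format
#'
#' Header lines carry the model id, class, match count and cutoffs; one line
#' per match state follows with emissions and transitions in fixed column
#' order, printed at full double precision so that [read_profile()]
#' round-trips bit-exactly.
#'
#' @param hmm A `profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(hmm, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "PROFILE 1",
    paste0("ID ", hmm$model_id),
    paste0("CLASS ", hmm$model_class),
    paste0("M ", hmm$match_count),
    paste0("CUTOFF ", num(hmm$inclusion_cutoff)),
    paste0("FLOOR ", num(hmm$unknown_floor)),
    paste0("BG ", paste(num(hmm$background), collapse = " ")),
    paste0("INSERT ", paste(num(hmm$insert_emissions), collapse = " ")),
    paste0("AA ", paste(AA_ORDER, collapse = " "))
  )
  for (j in seq_len(hmm$match_count)) {
    tr <- hmm$transitions[j, ]
    lines <- c(lines, paste0(
      "S ", j, " E ", paste(num(hmm$match_emissions[j, ]), collapse = " "),
      " T ", paste(ifelse(is.na(tr), "NA", num(tr)), collapse = " "),
      " N ", num(hmm$entry[j]), " X ", num(hmm$exit[j])
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a profile HMM written by [write_profile()]
#' @param path Path to a profile text file.
#' @return A `profile_hmm`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "PROFILE 1") abort(paste0("not a profile file: ", path))
  field <- function(tag) sub(paste0("^", tag, " "), "",
                             grep(paste0("^", tag, " "), lines, value = TRUE)[1])
  nums <- function(s) as.numeric(strsplit(s, " ")[[1]])
  M <- as.integer(field("M"))
  emis <- matrix(0, M, 20, dimnames = list(NULL, AA_ORDER))
  trans <- matrix(NA_real_, M, 7,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  entry <- numeric(M); exit <- numeric(M)
  for (ln in grep("^S ", lines, value = TRUE)) {
    parts <- strsplit(ln, " ")[[1]]
    j <- as.integer(parts[2])
    epos <- which(parts == "E"); tpos <- which(parts == "T")
    npos <- which(parts == "N"); xpos <- which(parts == "X")
    emis[j, ] <- as.numeric(parts[(epos + 1):(epos + 20)])
    tv <- parts[(tpos + 1):(tpos + 7)]
    trans[j, ] <- suppressWarnings(as.numeric(ifelse(tv == "NA", NA, tv)))
    entry[j] <- as.numeric(parts[npos + 1])
    exit[j] <- as.numeric(parts[xpos + 1])
  }
  structure(list(
    model_id = field("ID"), model_class = field("CLASS"), match_count = M,
    match_emissions = emis,
    insert_emissions = setNames(nums(field("INSERT")), AA_ORDER),
    transitions = trans, entry = entry, exit = exit,
    background = setNames(nums(field("BG")), AA_ORDER),
    inclusion_cutoff = num_or_na(field("CUTOFF")),
    unknown_floor = num_or_na(field("FLOOR"))
  ), class = "profile_hmm")
}

num_or_na <- function(s) suppressWarnings(as.numeric(s))

#' Validate the stochastic structure of a profile HMM
#'
#' Checks that every emission vector, the entry distribution, and every
#' defined outgoing-transition set (match states including their exit
#' probability, insert and delete states) sums to 1 within `tol`.
#'
#' @param hmm A `profile_hmm`.
#' @param tol Tolerance (default 1e-9).
#' @return `TRUE` (invisibly) or an error.
#' @export
validate_profile <- function(hmm, tol = 1e-9) {
  ok <- function(x) abs(sum(x) - 1) <= tol
  M <- hmm$match_count
  if (!all(apply(hmm$match_emissions, 1, ok))) abort("match emissions do not normalise")
  if (!ok(hmm$insert_emissions)) abort("insert emissions do not normalise")
  if (!ok(hmm$background)) abort("background does not normalise")
  if (!ok(hmm$entry)) abort("entry distribution does not normalise")
  if (M > 1) {
    for (j in seq_len(M - 1)) {
      if (!ok(c(hmm$transitions[j, c("MM", "MI", "MD")], hmm$exit[j]))) {
        abort(paste0("match-state ", j, " outgoing set does not normalise"))
      }
      if (!ok(hmm$transitions[j, c("IM", "II")])) {
        abort(paste0("insert-state ", j, " outgoing set does not normalise"))
      }
      if (!ok(hmm$transitions[j, c("DM", "DD")])) {
        abort(paste0("delete-state ", j, " outgoing set does not normalise"))
      }
    }
  }
  if (abs(hmm$exit[M] - 1) > tol) abort("final match state must exit with probability 1")
  invisible(TRUE)
}
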
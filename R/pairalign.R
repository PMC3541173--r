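# Pairwise local alignment, progressive multiple alignment, and the distance
# computations (p-distance with pairwise deletion, Poisson correction) that
# feed truncated-protein rescue, orphan clustering, and tree building.

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' Finds the optimal-score local alignment of two protein sequences under an
#' affine gap model (a gap run of length k costs `gap_open + k * gap_extend`).
#' Ambiguity codes score 0 against anything. If every attainable score is
#' negative the empty alignment (score 0) is returned.
#'
#' @param a,b Amino-acid sequences (single strings).
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A `pairwise_alignment` object with elements `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `identity` (fraction
#'   of aligned columns that match, dual-gap columns impossible by
#'   construction), `aligned_length`, and the start/end coordinates of the
#'   aligned region in each input.
#' @export
local_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                        gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("local_align: empty input sequence")
  ea <- encode_seq(a); eb <- encode_seq(b)
  res <- sw_align_cpp(ea, eb, matrix, gap_open, gap_extend)
  pa <- res$path_a; pb <- res$path_b
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  aligned_a <- paste(ifelse(pa == 0, "-", ca[pmax(pa, 1)]), collapse = "")
  aligned_b <- paste(ifelse(pb == 0, "-", cb[pmax(pb, 1)]), collapse = "")
  ncol <- length(pa)
  ident <- if (ncol == 0) 0 else {
    mean(pa > 0 & pb > 0 & toupper(ca[pmax(pa, 1)]) == toupper(cb[pmax(pb, 1)]) &
           pa != 0 & pb != 0)
  }
  structure(list(
    aligned_a = aligned_a, aligned_b = aligned_b, score = res$score,
    identity = ident, aligned_length = ncol,
    start_a = if (ncol) min(pa[pa > 0]) else NA_integer_,
    end_a = if (ncol) max(pa[pa > 0]) else NA_integer_,
    start_b = if (ncol) min(pb[pb > 0]) else NA_integer_,
    end_b = if (ncol) max(pb[pb > 0]) else NA_integer_
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score ", format(x$score), ", ", x$aligned_length,
      " columns, identity ", sprintf("%.3f", x$identity), "\n", sep = "")
  invisible(x)
}

#' Sliding-window segment identity test (truncated-protein rescue rule)
#'
#' Tests whether some window of exactly `window` alignment columns exceeds
#' `min_identity` (strictly). This is the 60-residue / more-than-50%-identity
#' criterion used to classify short proteins with the family of their closest
#' homologue. Returns `FALSE` when the alignment has fewer than `window`
#' columns. Local alignments never contain dual-gap columns.
#'
#' @param aln A `pairwise_alignment`.
#' @param window Window width in alignment columns (default 60).
#' @param min_identity Identity that must be strictly exceeded (default 0.5).
#' @return `TRUE` or `FALSE`.
#' @export
segment_identity_pass <- function(aln, window = 60L, min_identity = 0.5) {
  if (window <= 0) abort("segment_identity_pass: window must be positive")
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  keep <- !(ca == "-" & cb == "-") # drop dual-gap columns if any
  ca <- ca[keep]; cb <- cb[keep]
  n <- length(ca)
  if (n < window) return(FALSE)
  eq <- as.integer(ca != "-" & cb != "-" & toupper(ca) == toupper(cb))
  cs <- cumsum(c(0L, eq))
  hits <- cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]
  any(hits / window > min_identity)
}

# column score matrix between two profiles (20 x L frequency matrices)
profile_score_matrix <- function(p1, p2, matrix) {
  t(p1) %*% matrix %*% p2
}

profile_of_rows <- function(rows) {
  chars <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(chars)
  p <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA_ORDER, NULL))
  for (j in seq_len(L)) {
    idx <- match(chars[, j], AA_ORDER)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      tab <- tabulate(idx, nbins = 20)
      p[, j] <- tab / nrow(chars) # gaps contribute zero column weight
    }
  }
  p
}

# orientation-canonical merge: profile-profile DP tie-breaks depend on
# argument order, so orient by sequence content to keep the result invariant
# under input permutation
merge_canonical <- function(rows1, rows2, matrix, gap_open, gap_extend) {
  k1 <- paste(sort(gsub("-", "", rows1)), collapse = "|")
  k2 <- paste(sort(gsub("-", "", rows2)), collapse = "|")
  if (k2 < k1) {
    merged <- merge_alignments(rows2, rows1, matrix, gap_open, gap_extend)
    n2 <- length(rows2)
    c(merged[n2 + seq_along(rows1)], merged[seq_len(n2)])
  } else {
    merge_alignments(rows1, rows2, matrix, gap_open, gap_extend)
  }
}

merge_alignments <- function(rows1, rows2, matrix, gap_open, gap_extend) {
  p1 <- profile_of_rows(rows1); p2 <- profile_of_rows(rows2)
  S <- profile_score_matrix(p1, p2, matrix)
  path <- nw_affine_path_cpp(S, gap_open, gap_extend)
  expand <- function(rows, idx) {
    chars <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow = nrow(chars), ncol = length(idx))
    out[, idx > 0] <- chars[, idx[idx > 0], drop = FALSE]
    apply(out, 1, paste, collapse = "")
  }
  c(expand(rows1, path$path_a), expand(rows2, path$path_b))
}

#' Progressive multiple sequence alignment
#'
#' A simplified progressive scheme in the ClustalW tradition: pairwise
#' distances (1 - local-alignment identity) feed an average-linkage guide
#' tree; profiles are merged leaf-to-root with affine-gap profile-profile
#' alignment. Output rows are returned in input order.
#'
#' @param seqs Named character vector (or tibble with `id`, `sequence`) of
#'   >= 2 protein sequences.
#' @param matrix Substitution matrix.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A `seed_alignment` whose rows degap to the input sequences.
#' @export
progressive_msa <- function(seqs, matrix = blosum62(), gap_open = 11,
                            gap_extend = 1) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$id)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  if (n < 2) abort("progressive_msa: need at least 2 sequences")
  if (n == 2) {
    merged <- merge_canonical(seqs[1], seqs[2], matrix, gap_open, gap_extend)
    return(seed_alignment(merged, names(seqs)))
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # orient each pair by content so guide-tree distances are
      # permutation-invariant despite alignment tie-breaks
      pair <- if (seqs[i] <= seqs[j]) c(i, j) else c(j, i)
      al <- local_align(seqs[pair[1]], seqs[pair[2]], matrix, gap_open,
                        gap_extend)
      d[i, j] <- d[j, i] <- 1 - al$identity
    }
  }
  hc <- hclust(as.dist(d), method = "average")
  groups <- map(seq_len(n), function(i) list(rows = unname(seqs[i]), idx = i))
  nodes <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    pick <- function(id) if (id < 0) groups[[-id]] else nodes[[id]]
    g1 <- pick(hc$merge[k, 1]); g2 <- pick(hc$merge[k, 2])
    rows <- merge_canonical(g1$rows, g2$rows, matrix, gap_open, gap_extend)
    nodes[[k]] <- list(rows = rows, idx = c(g1$idx, g2$idx))
  }
  final <- nodes[[n - 1]]
  ord <- order(final$idx)
  seed_alignment(final$rows[ord], names(seqs)[final$idx][ord])
}

new_distance_matrix <- function(m, kind) {
  stopifnot(kind %in% c("p_distance", "poisson"))
  structure(list(ids = rownames(m), d = m, kind = kind),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix> kind=", x$kind, ", ", length(x$ids), " taxa, ",
      sum(is.na(x$d[upper.tri(x$d)])), " undefined pairs\n", sep = "")
  invisible(x)
}

#' p-distance with pairwise deletion
#'
#' For each pair of rows, only columns where both rows carry a residue are
#' compared; the distance is the mismatch fraction over those columns. Pairs
#' with zero comparable columns get `NA` (an undefined-distance marker that
#' downstream tree building refuses rather than imputes).
#'
#' @param msa A `seed_alignment`.
#' @return A `distance_matrix` of kind `"p_distance"` (entries in `[0, 1]`).
#' @export
p_distance <- function(msa) {
  chars <- do.call(rbind, strsplit(msa$rows, ""))
  n <- nrow(chars)
  m <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      m[i, j] <- m[j, i] <- if (!any(ok)) NA_real_ else {
        mean(chars[i, ok] != chars[j, ok])
      }
    }
  }
  new_distance_matrix(m, "p_distance")
}

#' Poisson correction of a p-distance
#'
#' Multiple-hit correction `d = -ln(1 - p)`, in amino-acid substitutions per
#' site. Saturated distances (`p = 1`) are an error: the caller decides
#' whether capping is acceptable.
#'
#' @param p p-distance value(s) in `[0, 1)`; `NA` passes through.
#' @return Corrected distance(s), `>= p` with equality only at 0.
#' @export
poisson_correct <- function(p) {
  bad <- !is.na(p) & (p < 0 | p >= 1)
  if (any(bad)) {
    abort(paste0("poisson_correct: saturated or invalid p-distance (p = ",
                 paste(format(p[bad]), collapse = ", "), ")"))
  }
  -log(1 - p)
}

#' Poisson-correct a whole distance matrix
#' @param d A `distance_matrix` of kind `"p_distance"`.
#' @return A `distance_matrix` of kind `"poisson"`.
#' @export
poisson_distance <- function(d) {
  stopifnot(inherits(d, "distance_matrix"), d$kind == "p_distance")
  new_distance_matrix(apply_keep_dim(d$d, poisson_correct), "poisson")
}

apply_keep_dim <- function(m, f) {
  out <- f(m)
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for a raw alignment score `S`, query
#' length `m` and database length `n`. Default `K` and `lambda` are the
#' conventional gapped BLOSUM62 parameters.
#'
#' @param score Raw alignment score.
#' @param query_len,db_len Positive sequence/database lengths.
#' @param K,lambda Positive Karlin-Altschul parameters.
#' @return The expected number of chance alignments at or above `score`.
#' @export
karlin_evalue <- function(score, query_len, db_len, K = 0.041, lambda = 0.267) {
  if (K <= 0 || lambda <= 0) abort("karlin_evalue: K and lambda must be positive")
  if (query_len <= 0 || db_len <= 0) abort("karlin_evalue: lengths must be positive")
  K * query_len * db_len * exp(-lambda * score)
}
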
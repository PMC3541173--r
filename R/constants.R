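# Amino-acid alphabet, background frequencies, and BLOSUM62-derived tables.
# Residue order follows the classic NCBI substitution-matrix convention.

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Robinson & Robinson background amino-acid frequencies (same residue order).
AA_BACKGROUND <- c(
  0.07805, 0.05129, 0.04487, 0.05364, 0.01925, 0.04264, 0.06295, 0.07377,
  0.02199, 0.05142, 0.09019, 0.05744, 0.02243, 0.03856, 0.05203, 0.07120,
  0.05841, 0.01330, 0.03216, 0.06441
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)
names(AA_BACKGROUND) <- AA_ORDER

.sdr_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix over the 20 standard residues
#'
#' The 20x20 core of the BLOSUM62 scoring matrix shipped with Biostrings,
#' reordered to the package's residue order.
#'
#' @return A 20x20 integer-valued matrix with residue dimnames.
#' @export
blosum62 <- function() {
  if (is.null(.sdr_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .sdr_env$blosum62 <- e$BLOSUM62[AA_ORDER, AA_ORDER]
  }
  .sdr_env$blosum62
}

# Joint residue-pair probabilities implied by BLOSUM62 (q_ab proportional to
# p_a p_b 2^(s_ab/2), renormalised) and the conditional P(a | b) used both for
# substitution sampling in the synthetic generator and for emission
# pseudocounts in profile construction.
blosum62_conditional <- function() {
  if (is.null(.sdr_env$cond)) {
    s <- blosum62()
    q <- outer(AA_BACKGROUND, AA_BACKGROUND) * 2^(s / 2)
    q <- q / sum(q)
    .sdr_env$cond <- sweep(q, 2, colSums(q), "/") # columns: given residue b
  }
  .sdr_env$cond
}

encode_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  chars <- strsplit(toupper(x), "")[[1]]
  idx <- match(chars, AA_ORDER)
  idx[is.na(idx)] <- 0L # ambiguity codes (X, B, Z, ...) score as background
  as.integer(idx)
}

decode_seq <- function(idx) paste(AA_ORDER[idx], collapse = "")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards, so generator calls are reproducible without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}
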
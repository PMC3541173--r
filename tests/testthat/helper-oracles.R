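# Independent oracles used by the unit and acceptance tests. Both mirror the
# documented model semantics from first principles (explicit enumeration)
# rather than the dynamic-programming implementations they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Brute-force local alignment score by enumerating every monotone matching of
# residue positions; unmatched in-between residues are charged as single
# affine gap runs on each side (the cheapest arrangement, which is what an
# optimal path uses). The empty alignment scores 0.
oracle_local_score <- function(a, b, mat, gap_open, gap_extend) {
  ea <- match(strsplit(a, "")[[1]], AA20)
  eb <- match(strsplit(b, "")[[1]], AA20)
  n <- length(ea)
  m <- length(eb)
  best <- 0
  sub <- function(i, j) {
    if (is.na(ea[i]) || is.na(eb[j])) 0 else mat[ea[i], eb[j]]
  }
  rec <- function(i, j, s) {
    best <<- max(best, s)
    if (i < n && j < m) {
      for (i2 in (i + 1):n) {
        for (j2 in (j + 1):m) {
          gi <- i2 - i - 1
          gj <- j2 - j - 1
          pen <- (gi > 0) * (gap_open + gap_extend * gi) +
            (gj > 0) * (gap_open + gap_extend * gj)
          rec(i2, j2, s + sub(i2, j2) - pen)
        }
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) rec(i, j, sub(i, j))
  best
}

# Brute-force profile-HMM local Viterbi score by depth-first enumeration of
# every legal state path: entry at any match state (flanks free), match /
# insert / delete moves with the model's transition costs, exit from any
# match state, at least one match emission.
oracle_viterbi_score <- function(hmm, seq) {
  aa <- colnames(hmm$match_emissions)
  enc <- match(strsplit(seq, "")[[1]], aa)
  enc[is.na(enc)] <- 0L
  L <- length(enc)
  M <- hmm$match_count
  lod <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  tr <- log2(hmm$transitions)
  entry <- log2(hmm$entry)
  exitl <- log2(hmm$exit)
  em <- function(i, j) if (enc[i] == 0) 0 else lod[j, enc[i]]
  best <- -Inf
  go <- function(i, j, acc) {
    best <<- max(best, acc + exitl[j])
    if (j < M) {
      if (i < L) go(i + 1, j + 1, acc + tr[j, "MM"] + em(i + 1, j + 1))
      if (i < L) {
        ins <- function(i2, accI) {
          if (i2 < L) {
            go(i2 + 1, j + 1, accI + tr[j, "IM"] + em(i2 + 1, j + 1))
            ins(i2 + 1, accI + tr[j, "II"])
          }
        }
        ins(i + 1, acc + tr[j, "MI"])
      }
      del <- function(jd, accD) {
        if (jd < M) {
          if (i < L) go(i + 1, jd + 1, accD + tr[jd, "DM"] + em(i + 1, jd + 1))
          del(jd + 1, accD + tr[jd, "DD"])
        }
      }
      del(j + 1, acc + tr[j, "MD"])
    }
  }
  for (i0 in seq_len(L)) {
    for (j0 in seq_len(M)) {
      go(i0, j0, entry[j0] + em(i0, j0))
    }
  }
  best
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# small random seed alignment whose profile has at most max_match states
random_small_alignment <- function(ncol = 4, nrow = 3, gap_p = 0.15) {
  rows <- replicate(nrow, {
    ch <- sample(AA20, ncol, replace = TRUE)
    gaps <- runif(ncol) < gap_p
    ch[gaps] <- "-"
    paste(ch, collapse = "")
  })
  # ensure no all-gap rows and at least one match column
  rows[!grepl("[A-Z]", rows)] <- paste(sample(AA20, ncol, TRUE), collapse = "")
  seed_alignment(rows)
}
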
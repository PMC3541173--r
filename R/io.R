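# Sequence and alignment I/O: FASTA (via Biostrings), Stockholm, and the
# square-TSV distance-matrix export.

#' Read an amino-acid FASTA file
#'
#' Headers are split into an id (first whitespace-delimited token) and a
#' description. Sequences are uppercased and `*` stop symbols are stripped.
#' Records with an empty sequence are rejected with the offending line number.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) abort(paste0("not a FASTA file (no '>' header): ", path))
  if (hdr[1] != 1 && any(nzchar(trimws(lines[seq_len(hdr[1] - 1)])))) {
    abort(paste0("malformed FASTA: sequence before first header at line 1 of ", path))
  }
  ends <- c(hdr[-1] - 1L, length(lines))
  for (k in seq_along(hdr)) {
    body <- lines[seq(hdr[k] + 1L, length.out = max(0L, ends[k] - hdr[k]))]
    if (sum(nchar(gsub("[\\s*]", "", body, perl = TRUE))) == 0) {
      abort(paste0("empty FASTA record at line ", hdr[k], " of ", path))
    }
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(gsub("\\*", "", as.character(ss)))
  full <- names(ss)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  tibble(id = id, description = desc, sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x A tibble with columns `id` and `sequence` (optionally
#'   `description`), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- tibble(id = names(x), sequence = unname(x))
  hdr <- if ("description" %in% names(x) && any(nzchar(x$description))) {
    paste0(">", x$id, ifelse(nzchar(x$description), paste0(" ", x$description), ""))
  } else {
    paste0(">", x$id)
  }
  wrap <- function(s) {
    if (nchar(s) == 0) return("")
    substring(s, seq(1, nchar(s), width), pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
  }
  out <- unlist(map(seq_len(nrow(x)), function(i) c(hdr[i], wrap(x$sequence[i]))))
  writeLines(out, path)
  invisible(path)
}

#' Construct a seed alignment
#'
#' A seed alignment is >= 2 gapped rows of equal length over the amino-acid
#' alphabet plus `-`/`.` gaps and ambiguity codes.
#'
#' @param rows Character vector of aligned (gapped) sequences.
#' @param ids Row labels.
#' @return A `seed_alignment` object.
#' @export
seed_alignment <- function(rows, ids = names(rows)) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  rows <- toupper(gsub("\\.", "-", rows))
  if (length(rows) < 2) abort("a seed alignment needs at least 2 rows")
  if (length(unique(nchar(rows))) != 1) abort("alignment rows differ in length")
  bad <- grepl(paste0("[^-", paste(AA_ORDER, collapse = ""), "XBZJUO]"), rows)
  if (any(bad)) abort("alignment rows contain characters outside the protein alphabet")
  structure(list(ids = as.character(ids), rows = unname(rows)),
            class = "seed_alignment")
}

#' @export
print.seed_alignment <- function(x, ...) {
  cat("<seed_alignment> ", length(x$rows), " rows x ", nchar(x$rows[1]),
      " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file as a seed alignment
#' @param path Path to aligned FASTA.
#' @return A `seed_alignment`.
#' @export
read_alignment_fasta <- function(path) {
  x <- read_fasta_gapped(path)
  seed_alignment(x$sequence, x$id)
}

# like read_fasta but keeps gap characters (alignment input)
read_fasta_gapped <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  tibble(id = sub("\\s.*$", "", names(ss)),
         sequence = toupper(as.character(ss)))
}

#' Write a seed alignment as aligned FASTA
#' @param aln A `seed_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  writeLines(as.vector(rbind(paste0(">", aln$ids), aln$rows)), path)
  invisible(path)
}

#' Read a Stockholm-format alignment
#'
#' Minimal single-block or multi-block Stockholm reader: `#` annotation lines
#' are ignored, `//` terminates the alignment.
#'
#' @param path Path to a Stockholm file.
#' @return A `seed_alignment`.
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# STOCKHOLM", lines[1])) {
    abort(paste0("not a Stockholm file (missing '# STOCKHOLM' header): ", path))
  }
  rows <- list()
  for (ln in lines[-1]) {
    if (grepl("^//", ln)) break
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) abort(paste0("malformed Stockholm line: ", ln))
    rows[[parts[1]]] <- paste0(rows[[parts[1]]] %||% "", parts[2])
  }
  seed_alignment(unlist(rows), names(rows))
}

#' Write a seed alignment in Stockholm format
#' @param aln A `seed_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(aln, path) {
  w <- max(nchar(aln$ids)) + 2L
  writeLines(c("# STOCKHOLM 1.0",
               sprintf("%-*s%s", w, aln$ids, aln$rows),
               "//"), path)
  invisible(path)
}

#' Write a distance matrix as square TSV
#'
#' Undefined entries (pairs with no comparable columns) are written as `NA`.
#'
#' @param d A `distance_matrix` (see [p_distance()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  m <- d$d
  df <- as.data.frame(m)
  readr::write_tsv(dplyr::bind_cols(tibble(id = d$ids), df), path)
  invisible(path)
}

#' Read a square-TSV distance matrix
#' @param path Path written by [write_distance_tsv()].
#' @param kind Distance kind recorded on the result.
#' @return A `distance_matrix`.
#' @export
read_distance_tsv <- function(path, kind = "p_distance") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- df$id
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(ids, ids)
  new_distance_matrix(m, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
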
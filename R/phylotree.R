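# Neighbor-joining trees with bootstrap support, built on the distance
# machinery of pairalign. Tree containers are ape `phylo` objects.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (Q-matrix minimisation, via ape) with two
#' additions: undefined distances abort with the offending pair named, and
#' negative branch-length estimates are clamped to zero with the deficit
#' transferred to the longest sister branch (so path lengths through the
#' join are preserved). For an additive input matrix the output path-length
#' matrix reproduces the input exactly.
#'
#' @param d A `distance_matrix` or a square symmetric numeric matrix with
#'   dimnames.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  m <- if (inherits(d, "distance_matrix")) d$d else d
  if (nrow(m) < 3) abort("neighbor_joining: need at least 3 taxa")
  if (any(is.na(m))) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(paste0("missing distance between '", rownames(m)[idx[1]],
                 "' and '", colnames(m)[idx[2]], "'"))
  }
  tree <- ape::nj(as.dist(m))
  clamp_negative_edges(tree)
}

clamp_negative_edges <- function(tree) {
  for (pass in 1:3) {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      if (tree$edge.length[e] >= 0) next
      parent <- tree$edge[e, 1]
      sibs <- setdiff(which(tree$edge[, 1] == parent), e)
      if (length(sibs)) {
        s <- sibs[which.max(tree$edge.length[sibs])]
        tree$edge.length[s] <- tree$edge.length[s] + tree$edge.length[e]
      }
      tree$edge.length[e] <- 0
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# canonical string for every non-trivial bipartition of an unrooted tree:
# the side NOT containing the first tip (alphabetically), sorted and joined
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- map_chr(pp, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  })
  n <- length(labs)
  keep <- map_lgl(strsplit(out, "\\|"), function(s) {
    length(s) >= 2 && length(s) <= n - 2
  })
  # first element of prop.part is the root clade (all tips) -> dropped by keep
  stats::setNames(out, seq_along(out))[keep]
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the distance matrix
#' and NJ tree for each replicate, and scores each internal branch of the
#' original tree by the percentage of replicates containing the same leaf
#' bipartition. Replicates whose resampled matrix contains undefined (or,
#' for Poisson distances, saturated) entries are skipped and tallied.
#'
#' @param msa A [seed_alignment()].
#' @param replicates Number of bootstrap replicates (default 500).
#' @param rng_seed Integer seed (fixed seed gives identical supports).
#' @param distance_kind `"p_distance"` or `"poisson"`.
#' @return A `phylo_boot` list: `tree` (the original NJ tree with integer
#'   percentage supports as `node.label`), `supports` (tibble `bipartition`,
#'   `count`, `support`), `replicates`, `n_skipped`.
#' @export
bootstrap_support <- function(msa, replicates = 500L, rng_seed = 1L,
                              distance_kind = c("p_distance", "poisson")) {
  stopifnot(replicates >= 1)
  distance_kind <- match.arg(distance_kind)
  dist_of <- function(aln) {
    d <- p_distance(aln)
    if (distance_kind == "poisson") {
      if (any(!is.na(d$d) & d$d >= 1)) return(NULL) # saturated replicate
      d <- poisson_distance(d)
    }
    d
  }
  d0 <- dist_of(msa)
  if (is.null(d0) || any(is.na(d0$d))) {
    abort("bootstrap_support: undefined or saturated distances in the full alignment")
  }
  tree <- neighbor_joining(d0)
  bips <- tree_bipartitions(tree)
  counts <- setNames(rep(0L, length(bips)), bips)
  L <- nchar(msa$rows[1])
  n_skipped <- 0L
  with_seed(rng_seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      chars <- do.call(rbind, strsplit(msa$rows, ""))
      rep_aln <- seed_alignment(apply(chars[, cols, drop = FALSE], 1, paste,
                                      collapse = ""), msa$ids)
      dr <- dist_of(rep_aln)
      if (is.null(dr) || any(is.na(dr$d))) {
        n_skipped <- n_skipped + 1L
        next
      }
      tr <- neighbor_joining(dr)
      rb <- tree_bipartitions(tr)
      hit <- names(counts) %in% rb
      counts[hit] <- counts[hit] + 1L
    }
  })
  denom <- max(replicates - n_skipped, 1L)
  support <- as.integer(round(100 * counts / denom))
  # attach supports to internal nodes
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- sort(tree$tip.label)[1]
  node_bip <- map_chr(pp, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  })
  node_label <- ifelse(node_bip %in% names(counts),
                       as.character(support[match(node_bip, names(counts))]),
                       "")
  tree$node.label <- node_label
  structure(list(
    tree = tree,
    supports = tibble(bipartition = names(counts), count = unname(counts),
                      support = unname(support)),
    replicates = replicates, n_skipped = n_skipped
  ), class = "phylo_boot")
}

#' @export
print.phylo_boot <- function(x, ...) {
  cat("<phylo_boot> ", length(x$tree$tip.label), " tips, ", x$replicates,
      " replicates (", x$n_skipped, " skipped)\n", sep = "")
  invisible(x)
}

quote_newick_label <- function(lab) {
  needs <- grepl("[][ ():;,']", lab) # ']' first so the class parses literally
  ifelse(needs, paste0("'", gsub("'", "''", lab), "'"), lab)
}

#' Write a tree as Newick text
#'
#' Branch lengths are written to 6 decimals; internal-node labels (integer
#' bootstrap supports) are emitted after the closing parenthesis; labels
#' containing spaces or Newick metacharacters are single-quoted.
#'
#' @param tree A `phylo` (or `phylo_boot`).
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  if (inherits(tree, "phylo_boot")) tree <- tree$tree
  ntip <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_node <- function(node, edge_idx) {
    len <- if (has_len && !is.na(edge_idx)) {
      sprintf(":%.6f", tree$edge.length[edge_idx])
    } else {
      ""
    }
    if (node <= ntip) {
      paste0(quote_newick_label(tree$tip.label[node]), len)
    } else {
      ch <- kids[[as.character(node)]]
      inner <- paste(map_chr(ch, ~ fmt_node(tree$edge[.x, 2], .x)),
                     collapse = ",")
      lab <- if (!is.null(tree$node.label)) {
        quote_newick_label(tree$node.label[node - ntip])
      } else {
        ""
      }
      paste0("(", inner, ")", lab, len)
    }
  }
  root <- ntip + 1L
  txt <- paste0(fmt_node(root, NA_integer_), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
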
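# Alignment-level utilities: identity, redundancy reduction, column
# trimming, p-distance neighbor-joining with monophyly checks, and
# per-column information content.

aln_matrix <- function(seqs) {
  if (is.data.frame(seqs)) {
    s <- setNames(seqs$sequence, seqs$protein_id)
  } else {
    s <- seqs
    if (is.null(names(s))) names(s) <- paste0("s", seq_along(s))
  }
  n <- nchar(s)
  if (length(unique(n)) != 1L) stop("sequences are not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(toupper(s), ""))
  rownames(m) <- names(s)
  m
}

#' Pairwise sequence identity over comparable positions
#'
#' Identity = matches / positions where neither sequence has a gap. Gap-gap
#' and gap-residue columns are excluded from the denominator.
#'
#' @param a,b aligned sequences of equal length (strings).
#' @return fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  comp <- !(ca %in% GAP_CHARS) & !(cb %in% GAP_CHARS)
  if (!any(comp)) stop("no comparable (gap-free) positions")
  mean(ca[comp] == cb[comp])
}

#' Greedy redundancy reduction of an aligned sequence set
#'
#' Scans sequences in input order and keeps one unless its identity to an
#' already-kept sequence strictly exceeds `threshold`. Greedy (not clique)
#' filtering: in a chain A~B~C with identity(A,C) <= threshold, A and C are
#' both kept even though B is dropped against A. Deterministic for a given
#' input order.
#'
#' @param seqs named character vector of aligned sequences (or a data.frame
#'   with `protein_id`/`sequence`).
#' @param threshold identity above which a sequence is considered redundant
#'   (default 0.99, i.e. remove >99% identical).
#' @return retained subset, same representation as the input.
#' @export
reduce_redundancy <- function(seqs, threshold = 0.99) {
  df_in <- is.data.frame(seqs)
  s <- if (df_in) setNames(seqs$sequence, seqs$protein_id) else seqs
  kept <- integer(0)
  for (i in seq_along(s)) {
    redundant <- FALSE
    for (j in kept) {
      if (pairwise_identity(s[[i]], s[[j]]) > threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  if (df_in) seqs[kept, , drop = FALSE] else s[kept]
}

#' Remove gap-rich alignment columns
#'
#' Drops columns whose gap fraction strictly exceeds `max_gap_fraction`.
#' A light-weight surrogate for automated alignment trimming; the retained
#' column indices are kept for traceability.
#'
#' @param seqs aligned sequences (named character vector or data.frame).
#' @param max_gap_fraction columns with gap fraction above this are removed.
#' @return list with `alignment` (named character vector) and `col_map`
#'   (original indices of retained columns).
#' @export
trim_columns <- function(seqs, max_gap_fraction = 0.5) {
  m <- aln_matrix(seqs)
  gapfrac <- colMeans(matrix(m %in% GAP_CHARS, nrow = nrow(m)))
  keep <- which(gapfrac <= max_gap_fraction)
  if (length(keep) == 0L) stop("all alignment columns exceeded the gap threshold")
  out <- apply(m[, keep, drop = FALSE], 1, paste0, collapse = "")
  list(alignment = out, col_map = keep)
}

#' p-distance matrix of an aligned sequence set
#'
#' p-distance = 1 - pairwise identity (fraction of differing residues over
#' comparable positions).
#'
#' @param seqs aligned sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(seqs) {
  m <- aln_matrix(seqs)
  s <- apply(m, 1, paste0, collapse = "")
  n <- length(s)
  D <- matrix(0, n, n, dimnames = list(names(s), names(s)))
  if (n > 1L) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- 1 - pairwise_identity(s[[i]], s[[j]])
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper over `ape::nj()` that validates the input and clamps
#' negative branch lengths to zero (with a warning), since NJ can produce
#' them on non-additive matrices.
#'
#' @param D symmetric distance matrix with >= 3 taxa.
#' @return an `ape::phylo` tree (unrooted).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining requires at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(D)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Export a tree in newick format
#' @param tree `ape::phylo` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Test each class for monophyly on an unrooted tree
#'
#' A class is monophyletic iff some edge bipartition isolates exactly that
#' class's leaves (singleton classes are trivially monophyletic).
#'
#' @param tree `ape::phylo` tree.
#' @param labels named character vector mapping every tip label to a class.
#' @return data.frame with `class`, `n_tips`, `monophyletic`.
#' @export
class_monophyly <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(tips %in% names(labels))) {
    stop("unlabeled leaf/leaves: ",
         paste(setdiff(tips, names(labels)), collapse = ", "))
  }
  cls <- unname(labels[tips])
  parts <- ape::prop.part(tree)
  sets <- lapply(parts, function(p) as.integer(sort(p)))
  all_idx <- seq_along(tips)
  classes <- sort(unique(cls))
  mono <- vapply(classes, function(cl) {
    idx <- as.integer(sort(which(cls == cl)))
    if (length(idx) <= 1L || length(idx) == length(tips)) return(TRUE)
    comp <- as.integer(sort(setdiff(all_idx, idx)))
    any(vapply(sets, function(s) identical(s, idx) || identical(s, comp),
               logical(1)))
  }, logical(1))
  data.frame(class = classes,
             n_tips = as.integer(table(factor(cls, levels = classes))),
             monophyletic = mono, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-column information content of an alignment
#'
#' Relative entropy of observed residue frequencies against a background
#' distribution, in bits (logo column heights). Residue heights are
#' `f_aa * IC` and sum to the column IC.
#'
#' @param seqs aligned sequences.
#' @param background named amino-acid frequency vector (default uniform
#'   1/20); must be positive and sum to 1.
#' @param pseudocount Laplace pseudocount added to residue counts
#'   (default 1; use 0 for raw observed frequencies).
#' @return list of class `ccm_conservation` with `ic` (per-column bits) and
#'   `heights` (20 x n_columns matrix).
#' @export
column_information <- function(seqs, background = NULL, pseudocount = 1) {
  m <- aln_matrix(seqs)
  aa <- amino_acids()
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), aa)
  stopifnot(all(aa %in% names(background)), all(background[aa] > 0),
            abs(sum(background[aa]) - 1) < 1e-9)
  bg <- background[aa]
  nc <- ncol(m)
  ic <- numeric(nc)
  heights <- matrix(0, 20, nc, dimnames = list(aa, NULL))
  for (j in seq_len(nc)) {
    col <- m[, j]
    col <- col[col %in% aa]
    if (length(col) == 0L) stop("empty alignment column at position ", j)
    cnt <- table(factor(col, levels = aa))
    f <- (as.numeric(cnt) + pseudocount) /
      (length(col) + 20 * pseudocount)
    terms <- ifelse(f > 0, f * log2(f / bg), 0)
    ic[j] <- max(0, sum(terms))
    heights[, j] <- f * ic[j]
  }
  structure(list(ic = ic, heights = heights), class = "ccm_conservation")
}
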
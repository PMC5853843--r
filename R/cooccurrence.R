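# Cohort-level co-occurrence statistics for CcmK classes: per-class genome
# coverage, pairwise observed/expected ratios under independence, Pearson
# chi-squared tests on 2x2 presence tables, and Venn-region counts.

K_SUPERCLASS <- c("CcmK1", "CcmK2", "CcmK12_unsplit")

default_cooccurrence_classes <- function() {
  c("CcmK1/2", "CcmK3", "CcmK4", "CcmK5", "CcmK6")
}

#' Build a binary genome x class presence matrix
#'
#' CcmK1, CcmK2 and unsplit CcmK1/2 genes all count towards the merged
#' "CcmK1/2" superclass, matching how coverage is reported.
#'
#' @param gene_tables named list of per-genome gene tables (from
#'   [read_gene_table()] / [generate_genomes()]).
#' @param classes classes to tabulate (default CcmK1/2 and CcmK3-6).
#' @return binary matrix (genomes x classes) of class `ccm_presence`.
#' @export
presence_matrix <- function(gene_tables,
                            classes = default_cooccurrence_classes()) {
  genomes <- names(gene_tables)
  m <- matrix(0L, length(genomes), length(classes),
              dimnames = list(genomes, classes))
  for (g in genomes) {
    lab <- gene_tables[[g]]$label
    for (cl in classes) {
      hit <- if (cl == "CcmK1/2") any(lab %in% K_SUPERCLASS) else
        any(lab == cl)
      m[g, cl] <- as.integer(hit)
    }
  }
  structure(m, class = c("ccm_presence", class(m)))
}

#' Per-class genome coverage
#'
#' @param mat binary presence matrix (genomes x classes).
#' @return data.frame with `class`, `n` (genomes with >= 1 gene) and
#'   `percent` (100 n/N, rounded half away from zero to 1 decimal).
#' @export
coverage <- function(mat) {
  N <- nrow(mat)
  if (N == 0L) stop("empty presence matrix")
  n <- colSums(mat)
  data.frame(class = colnames(mat), n = as.integer(n),
             percent = round_half_away(100 * n / N, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expected number of co-occurrences under independence
#'
#' Product of the two relative genome coverages times the cohort size:
#' `n_a * n_b / N` (not rounded).
#'
#' @param n_a,n_b per-class genome counts.
#' @param N number of genomes analysed.
#' @return expected count of genomes carrying both classes.
#' @export
expected_cooccurrence <- function(n_a, n_b, N) {
  if (N <= 0) stop("N must be positive")
  stopifnot(n_a >= 0, n_b >= 0, n_a <= N, n_b <= N)
  n_a * n_b / N
}

#' Observed/expected co-occurrence ratio
#'
#' @param observed genomes carrying both classes.
#' @param expected from [expected_cooccurrence()].
#' @return ratio rounded half away from zero to 2 decimals; exactly 0 when
#'   `observed` is 0; NA when `expected` is 0 (undefined).
#' @export
cooccurrence_ratio <- function(observed, expected) {
  stopifnot(expected >= 0, observed >= 0)
  if (expected == 0) return(NA_real_)
  round_half_away(observed / expected, 2)
}

#' Chi-squared test of association between two classes
#'
#' Pearson chi-squared (df = 1) on the 2x2 presence table
#' (both / A only / B only / neither), by default without Yates continuity
#' correction. A class present in 0% or 100% of genomes gives a degenerate
#' margin: the test is undefined and NA is returned with a warning.
#'
#' @param mat binary presence matrix.
#' @param class_a,class_b column names.
#' @param correct apply the Yates continuity correction?
#' @return list with `chi2`, `p`, `stars` ("ns"/"*"/"**"/"***", NA when
#'   degenerate).
#' @export
chisq_pair <- function(mat, class_a, class_b, correct = FALSE) {
  va <- mat[, class_a]
  vb <- mat[, class_b]
  N <- length(va)
  a <- sum(va == 1 & vb == 1)
  b <- sum(va == 1 & vb == 0)
  c_ <- sum(va == 0 & vb == 1)
  d <- sum(va == 0 & vb == 0)
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    warning("degenerate margin for ", class_a, " vs ", class_b,
            " (0% or 100% coverage); chi-squared undefined")
    return(list(chi2 = NA_real_, p = NA_real_, stars = NA_character_))
  }
  num <- abs(a * d - b * c_)
  if (correct) num <- max(0, num - N / 2)
  chi2 <- N * num^2 / prod(margins)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, stars = stars_from_p(p))
}

#' Full pairwise co-occurrence analysis
#'
#' @param mat binary presence matrix.
#' @param correct Yates correction flag passed to [chisq_pair()].
#' @return list of class `ccm_cooccurrence` with `coverage` (data.frame),
#'   `pairs` (data.frame: class_a, class_b, n_a, n_b, observed, expected,
#'   ratio, chi2, p, stars) and `N`.
#' @export
cooccurrence_analysis <- function(mat, correct = FALSE) {
  N <- nrow(mat)
  cov <- coverage(mat)
  cls <- colnames(mat)
  prs <- combn(cls, 2)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    ca <- prs[1, k]; cb <- prs[2, k]
    n_a <- sum(mat[, ca]); n_b <- sum(mat[, cb])
    obs <- sum(mat[, ca] == 1 & mat[, cb] == 1)
    exp_ <- expected_cooccurrence(n_a, n_b, N)
    ct <- suppressWarnings(chisq_pair(mat, ca, cb, correct))
    data.frame(class_a = ca, class_b = cb, n_a = n_a, n_b = n_b,
               observed = obs, expected = exp_,
               ratio = cooccurrence_ratio(obs, exp_),
               chi2 = ct$chi2, p = ct$p, stars = ct$stars,
               stringsAsFactors = FALSE)
  })
  structure(list(coverage = cov, pairs = do.call(rbind, rows), N = N),
            class = "ccm_cooccurrence")
}

#' Genome counts for every region of the class-combination lattice
#'
#' @param mat binary presence matrix.
#' @param classes subset of columns (at most 6; combinatorial guard).
#' @return data.frame: one 0/1 column per class plus `count`; counts sum
#'   to the number of genomes.
#' @export
venn_counts <- function(mat, classes = colnames(mat)) {
  if (length(classes) > 6L) stop("venn_counts supports at most 6 classes")
  sub <- mat[, classes, drop = FALSE]
  grid <- expand.grid(rep(list(c(0L, 1L)), length(classes)))
  names(grid) <- classes
  grid$count <- apply(grid, 1, function(pat) {
    sum(apply(sub, 1, function(row) all(row == pat[classes])))
  })
  grid
}
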
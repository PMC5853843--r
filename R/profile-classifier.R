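# Position-specific scoring profiles built from per-class seed alignments,
# local-alignment scoring, best-hit class assignment and the length-based
# CcmK1/CcmK2 split.
#
# The reference workflow scores every Pfam00936 protein against one profile
# HMM per class and keeps the best hit. Here each class is represented by
# match-column log-odds emissions with affine gap penalties; raw bit scores
# replace e-values (monotone in -log e-value at fixed database size, so the
# argmax class is identical) and no insert-state emissions are modelled.

#' Classifier configuration
#'
#' @param k2_length_range residue-length bracket labelled CcmK2
#'   (default 100-107).
#' @param k1_length_range residue-length bracket labelled CcmK1
#'   (default 108-118); must start where the CcmK2 bracket ends.
#' @param pseudocount Laplace pseudocount for emission estimates.
#' @param gap_open,gap_extend affine gap penalties in bits.
#' @param min_margin bit-score margin under which an assignment is flagged
#'   ambiguous.
#' @return list of class `ccm_classifier_config`.
#' @export
classifier_config <- function(k2_length_range = c(100L, 107L),
                              k1_length_range = c(108L, 118L),
                              pseudocount = 1,
                              gap_open = 4, gap_extend = 0.5,
                              min_margin = 1) {
  stopifnot(length(k2_length_range) == 2L, length(k1_length_range) == 2L,
            k2_length_range[1] < k2_length_range[2],
            k1_length_range[1] < k1_length_range[2],
            k1_length_range[1] == k2_length_range[2] + 1L,
            pseudocount > 0, gap_open > 0, gap_extend > 0, min_margin >= 0)
  structure(list(k2_length_range = as.integer(k2_length_range),
                 k1_length_range = as.integer(k1_length_range),
                 pseudocount = pseudocount,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_margin = min_margin),
            class = "ccm_classifier_config")
}

#' Build a class profile from a seed alignment
#'
#' Columns with a gap fraction above `max_gap_fraction` are discarded
#' (treated as insert columns, not scored). Emission log-odds are
#' `log2(((count + a) / (n + 20a)) / background_aa)` in bits, with Laplace
#' pseudocount `a` and the background estimated from the pooled seed
#' residues unless supplied.
#'
#' @param seed_alignment aligned sequences (named character vector or
#'   data.frame from `read_fasta(..., keep_gaps = TRUE)`); at least two.
#' @param class_name class the profile represents (e.g. "CcmK3").
#' @param config a [classifier_config()].
#' @param max_gap_fraction gap fraction above which a column is dropped.
#' @param background optional named amino-acid frequency vector override.
#' @return list of class `ccm_profile` with `class_name`, `match_columns`
#'   (20 x C log-odds matrix), `background`, `n_seed`, `col_map`.
#' @export
build_profile <- function(seed_alignment, class_name,
                          config = classifier_config(),
                          max_gap_fraction = 0.5, background = NULL) {
  m <- aln_matrix(seed_alignment)
  if (nrow(m) < 2L) stop("a seed alignment needs at least 2 sequences")
  aa <- amino_acids()
  alpha <- config$pseudocount
  gapfrac <- colMeans(matrix(m %in% GAP_CHARS, nrow = nrow(m)))
  keep <- which(gapfrac <= max_gap_fraction)
  if (length(keep) == 0L) stop("no profile columns survive the gap filter")
  if (is.null(background)) {
    pooled <- m[m %in% aa]
    cnt <- table(factor(pooled, levels = aa))
    background <- setNames((as.numeric(cnt) + alpha) /
                             (length(pooled) + 20 * alpha), aa)
  }
  stopifnot(all(aa %in% names(background)), all(background[aa] > 0),
            abs(sum(background[aa]) - 1) < 1e-9)
  bg <- background[aa]
  cols <- matrix(0, 20, length(keep), dimnames = list(aa, NULL))
  for (k in seq_along(keep)) {
    col <- m[, keep[k]]
    col <- col[col %in% aa]
    n <- length(col)
    cnt <- as.numeric(table(factor(col, levels = aa)))
    cols[, k] <- log2(((cnt + alpha) / (n + 20 * alpha)) / bg)
  }
  structure(list(class_name = class_name, match_columns = cols,
                 background = bg, n_seed = nrow(m), col_map = keep,
                 gap_open = config$gap_open, gap_extend = config$gap_extend),
            class = "ccm_profile")
}

#' @export
print.ccm_profile <- function(x, ...) {
  cat("ccm_profile:", x$class_name, "-", ncol(x$match_columns),
      "match columns from", x$n_seed, "seed sequences\n")
  invisible(x)
}

encode_sequence <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  chars <- chars[!(chars %in% GAP_CHARS)]
  idx <- match(chars, amino_acids())
  idx[is.na(idx)] <- 21L  # 'X'/unknown -> zero-emission catch-all row
  idx
}

#' Score one sequence against one class profile
#'
#' Best local alignment of the sequence against the profile match columns
#' under affine gap penalties, maximising summed log-odds. The local floor
#' guarantees a non-negative bit score.
#'
#' @param sequence amino-acid string (or one-row data.frame with a
#'   `sequence` column); gaps are stripped.
#' @param profile a `ccm_profile`.
#' @return list of class `ccm_score` with `class_name`, `bit_score`,
#'   `aligned_columns` (profile columns consumed by the best local path;
#'   diagnostic), `normalized_score` (bits per profile match column: short
#'   spurious local hits on unrelated sequences would otherwise inflate a
#'   per-path-column average, so the per-profile-column rate is the
#'   comparable one).
#' @export
score_sequence <- function(sequence, profile) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  idx <- encode_sequence(sequence)
  if (length(idx) == 0L) stop("empty sequence")
  S <- rbind(profile$match_columns, X = 0)
  res <- profile_local_align(S, idx, profile$gap_open, profile$gap_extend)
  structure(list(class_name = profile$class_name,
                 bit_score = res$score,
                 aligned_columns = res$columns,
                 normalized_score = res$score / ncol(profile$match_columns)),
            class = "ccm_score")
}

#' Assign a sequence to the best-scoring shell-protein class
#'
#' Scores the sequence against every profile and returns the argmax by bit
#' score. Ties are broken alphabetically for determinism; a winning margin
#' under `min_margin` bits flags the call ambiguous; a sequence scoring at
#' the local-alignment floor (0 bits) on every profile is "Unclassified".
#' Sequences landing in the merged CcmK1/2 profile are split by length via
#' [split_k1k2()].
#'
#' @param sequence amino-acid string.
#' @param profiles list of `ccm_profile` objects (>= 2).
#' @param config a [classifier_config()].
#' @return list with `label` (final), `raw_label` (profile name), `scores`
#'   (named bit-score vector), `margin`, `ambiguous`.
#' @export
assign_class <- function(sequence, profiles, config = classifier_config()) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  nms <- vapply(profiles, `[[`, character(1), "class_name")
  ord <- order(nms)  # alphabetical order makes ties deterministic
  profiles <- profiles[ord]
  nms <- nms[ord]
  scores <- vapply(profiles, function(p) score_sequence(sequence, p)$bit_score,
                   numeric(1))
  names(scores) <- nms
  if (all(scores <= 0)) {
    return(list(label = "Unclassified", raw_label = "Unclassified",
                scores = scores, margin = 0, ambiguous = FALSE))
  }
  top <- which.max(scores)
  margin <- if (length(scores) > 1L) {
    scores[top] - max(scores[-top])
  } else Inf
  raw <- unname(nms[top])
  label <- raw
  if (raw %in% c("CcmK12", "CcmK1/2")) {
    n_res <- length(encode_sequence(sequence))
    label <- split_k1k2(n_res, config)
  }
  list(label = label, raw_label = raw, scores = scores,
       margin = unname(margin),
       ambiguous = unname(margin) < config$min_margin)
}

#' Split the merged CcmK1/2 superclass by sequence length
#'
#' Shorter proteins (100-107 aa) are CcmK2; longer proteins (108-118 aa,
#' carrying the ~10-residue C-terminal extension) are CcmK1. Lengths outside
#' 100-118 cannot be bracketed and return "CcmK12_ambiguous" with a warning.
#'
#' @param length residue count (positive integer).
#' @param config a [classifier_config()].
#' @return one of "CcmK2", "CcmK1", "CcmK12_ambiguous".
#' @export
split_k1k2 <- function(length, config = classifier_config()) {
  stopifnot(length > 0)
  k2 <- config$k2_length_range
  k1 <- config$k1_length_range
  if (length >= k2[1] && length <= k2[2]) return("CcmK2")
  if (length >= k1[1] && length <= k1[2]) return("CcmK1")
  warning("sequence length ", length,
          " outside the CcmK1/CcmK2 annotation brackets")
  "CcmK12_ambiguous"
}

#' Classify a set of protein records
#'
#' Vectorised driver around [assign_class()].
#'
#' @param records data.frame from [read_fasta()].
#' @param profiles list of `ccm_profile` objects.
#' @param config a [classifier_config()].
#' @return data.frame with `protein_id`, `genome_id`, `label`, `raw_label`,
#'   `bit_score`, `margin`, `flags`.
#' @export
classify_sequences <- function(records, profiles,
                               config = classifier_config()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- assign_class(records$sequence[i], profiles, config)
    data.frame(protein_id = records$protein_id[i],
               genome_id = records$genome_id[i],
               label = r$label, raw_label = r$raw_label,
               bit_score = max(r$scores), margin = r$margin,
               flags = if (r$ambiguous) "ambiguous" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read per-class seed alignments from a directory
#'
#' One aligned FASTA per class; the file stem (e.g. `CcmK3.fasta`) is the
#' class name.
#'
#' @param dir directory of aligned FASTA files.
#' @param config a [classifier_config()].
#' @return named list of `ccm_profile` objects.
#' @export
read_seed_profiles <- function(dir, config = classifier_config()) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|afa)$", full.names = TRUE)
  if (length(files) == 0L) stop("no FASTA files in ", dir)
  profs <- lapply(files, function(f) {
    cls <- tools::file_path_sans_ext(basename(f))
    build_profile(read_fasta(f, keep_gaps = TRUE), cls, config)
  })
  names(profs) <- vapply(profs, `[[`, character(1), "class_name")
  profs
}

# Draw a sequence from a profile's implied emission distribution
# (background * 2^log-odds, renormalised per column). Used by the
# synthetic-sequence generator and classifier-recovery tests.
sample_from_profile <- function(profile) {
  aa <- amino_acids()
  probs <- profile$background * 2^profile$match_columns
  probs <- sweep(probs, 2, colSums(probs), "/")
  paste0(apply(probs, 2, function(p) sample(aa, 1, prob = p)), collapse = "")
}
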
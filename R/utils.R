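# Shared helpers: rounding, hashing, seeded evaluation, label vocabulary.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published tables in this field
#' are typically rounded half away from zero (e.g. 0.575 -> 0.58), so all
#' report rounding in ccmshell goes through this helper.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(0.575, 2)  # 0.58
#' round_half_away(-0.125, 2) # -0.13
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-12) / m
}

# djb2-style string hash of a configuration object; used to stamp report
# headers so outputs are traceable to the settings that produced them.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream (used for the deterministic built-in class archetypes).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Amino-acid alphabet used throughout ccmshell
#' @return character vector of the 20 standard one-letter codes.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

GAP_CHARS <- c("-", ".")

#' Annotation labels recognised in gene tables
#'
#' `gene_labels()` returns every label a gene-table row may carry;
#' `carboxysome_labels()` returns the subset treated as carboxysome genes by
#' the locus-assembly rules (RubisCO genes are deliberately excluded: they
#' can flank the MCL but do not define it).
#'
#' @return character vector of labels.
#' @export
gene_labels <- function() {
  c(carboxysome_labels(), "RbcL", "RbcS", "Other")
}

#' @rdname gene_labels
#' @export
carboxysome_labels <- function() {
  c("CcmK1", "CcmK2", "CcmK12_unsplit", "CcmK3", "CcmK4", "CcmK5", "CcmK6",
    "CcmO", "CcmP", "CcmL", "CcmM", "CcmN")
}

# Compact per-gene codes used in locus signatures ("K2-K1-L-M-N-O").
short_label <- function(label) {
  map <- c(CcmK1 = "K1", CcmK2 = "K2", CcmK12_unsplit = "K12",
           CcmK3 = "K3", CcmK4 = "K4", CcmK5 = "K5", CcmK6 = "K6",
           CcmO = "O", CcmP = "P", CcmL = "L", CcmM = "M", CcmN = "N",
           RbcL = "rbcL", RbcS = "rbcS", Other = ".")
  unname(map[label])
}

# Significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds.
stars_from_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}
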
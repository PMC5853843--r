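# Locus assembly from ordinal gene coordinates: group carboxysome genes
# into loci per replicon, identify the main carboxysome locus (MCL), call
# satellites and classify the genomic position of ccmO.
#
# Two distance rules drive the grouping, both measured in intervening
# non-carboxysome genes (ordinal difference minus one):
#   * genes within `satellite_distance` (default 10, inclusive) of another
#     carboxysome gene belong to the same locus region — a gene is a
#     satellite only if no other carboxysome gene lies within 10 ORFs;
#   * inside a region, runs separated by at most `max_insert` (default 1)
#     intervening genes form the locus core used for the signature —
#     single non-carboxysome insertions do not interrupt the MCL.
# Genes in a region but outside its core (gaps 2..satellite_distance) are
# kept as members and flagged "loosely_associated".

#' Locus-assembly configuration
#'
#' @param max_insert intervening non-carboxysome genes tolerated inside a
#'   locus core (default 1; set 0 to forbid insertions).
#' @param satellite_distance ORF distance defining satellites (default 10).
#' @param satellite_inclusive is a gene exactly `satellite_distance`
#'   intervening genes away still "within" (default TRUE)?
#' @return list of class `ccm_assembly_config`.
#' @export
assembly_config <- function(max_insert = 1L, satellite_distance = 10L,
                            satellite_inclusive = TRUE) {
  max_insert <- as.integer(max_insert)
  satellite_distance <- as.integer(satellite_distance)
  stopifnot(max_insert >= 0L, max_insert < satellite_distance)
  structure(list(max_insert = max_insert,
                 satellite_distance = satellite_distance,
                 satellite_inclusive = isTRUE(satellite_inclusive)),
            class = "ccm_assembly_config")
}

#' Assemble carboxysome loci for one genome
#'
#' @param rows gene-table data.frame for a single genome (one element of
#'   [read_gene_table()]'s result).
#' @param config an [assembly_config()].
#' @return list of locus objects (class `ccm_locus`), each with
#'   `genome_id`, `replicon_id`, `members` (gene-table rows), `span`,
#'   `core` (logical index into members), `signature` (dash-joined core
#'   labels), `kind` (NA until [identify_mcl()]), `flags`.
#' @export
assemble_loci <- function(rows, config = assembly_config()) {
  stopifnot(is.data.frame(rows))
  loci <- list()
  for (rep_id in unique(rows$replicon_id)) {
    sub <- rows[rows$replicon_id == rep_id &
                  rows$label %in% carboxysome_labels(), , drop = FALSE]
    if (nrow(sub) == 0L) next
    sub <- sub[order(sub$ordinal), , drop = FALSE]
    gaps <- diff(sub$ordinal) - 1L  # intervening non-carboxysome genes
    thr <- config$satellite_distance
    linked <- if (config$satellite_inclusive) gaps <= thr else gaps < thr
    region <- cumsum(c(1L, as.integer(!linked)))
    for (r in unique(region)) {
      mem <- sub[region == r, , drop = FALSE]
      core <- core_run(mem$ordinal, config$max_insert)
      sig <- paste(short_label(mem$label[core]), collapse = "-")
      loci[[length(loci) + 1L]] <- structure(
        list(genome_id = mem$genome_id[1], replicon_id = rep_id,
             members = mem, span = range(mem$ordinal), core = core,
             signature = sig, kind = NA_character_,
             flags = if (any(!core)) "loosely_associated" else ""),
        class = "ccm_locus")
    }
  }
  loci
}

# Longest run of genes whose successive gaps are all <= max_insert
# (first such run on ties). Returns a logical index.
core_run <- function(ordinals, max_insert) {
  n <- length(ordinals)
  if (n == 1L) return(TRUE)
  tight <- (diff(ordinals) - 1L) <= max_insert
  run_id <- cumsum(c(1L, as.integer(!tight)))
  # deterministic tie-break: first run of maximal length
  lens <- tapply(seq_len(n), run_id, length)
  max_len <- max(lens)
  first_best <- as.integer(names(lens)[which(lens == max_len)[1]])
  run_id == first_best
}

#' @export
print.ccm_locus <- function(x, ...) {
  cat(sprintf("ccm_locus %s/%s [%d..%d] %s (%s)\n", x$genome_id,
              x$replicon_id, x$span[1], x$span[2], x$signature,
              if (is.na(x$kind)) "unassigned" else x$kind))
  invisible(x)
}

locus_core_labels <- function(locus) locus$members$label[locus$core]

is_mcl_candidate <- function(locus) {
  lab <- locus_core_labels(locus)
  any(lab %in% c("CcmK1", "CcmK2", "CcmK12_unsplit")) &&
    all(c("CcmL", "CcmM", "CcmN") %in% lab)
}

#' Identify the main carboxysome locus among a genome's loci
#'
#' The MCL is the unique locus whose core contains at least one ccmK1/2
#' gene and all of ccmL, ccmM, ccmN (ccmK2/L/M/N is the minimum genetic
#' unit). Exactly one candidate sets kinds (`MCL` / `satellite`); zero
#' candidates mark every locus satellite and flag the genome non-beta; two
#' or more candidates are an integrity error.
#'
#' Gene order inside the MCL is validated (K genes before L/M/N; ccmO
#' terminal when present); violations warn but do not error, since rare
#' atypical MCL arrangements exist.
#'
#' @param loci list from [assemble_loci()].
#' @return the input list with `kind` set on every locus; attribute
#'   `mcl_index` gives the MCL position (NA if none).
#' @export
identify_mcl <- function(loci) {
  cand <- which(vapply(loci, is_mcl_candidate, logical(1)))
  if (length(cand) > 1L) {
    stop("integrity error: multiple MCL candidates: ",
         paste(vapply(loci[cand], `[[`, character(1), "signature"),
               collapse = " | "))
  }
  for (i in seq_along(loci)) {
    loci[[i]]$kind <- if (length(cand) == 1L && i == cand) "MCL" else
      "satellite"
  }
  if (length(cand) == 1L) {
    check_mcl_order(loci[[cand]])
  }
  attr(loci, "mcl_index") <- if (length(cand) == 1L) cand else NA_integer_
  attr(loci, "no_mcl") <- length(cand) == 0L
  loci
}

check_mcl_order <- function(mcl) {
  lab <- locus_core_labels(mcl)
  kpos <- which(lab %in% c("CcmK1", "CcmK2", "CcmK12_unsplit"))
  lmn <- which(lab %in% c("CcmL", "CcmM", "CcmN"))
  if (length(kpos) > 0 && length(lmn) > 0 && max(kpos) > min(lmn)) {
    warning("atypical MCL gene order in ", mcl$genome_id,
            ": ccmK gene downstream of ccmL/M/N")
  }
  opos <- which(lab == "CcmO")
  if (length(opos) > 0 && max(opos) != length(lab)) {
    warning("atypical MCL gene order in ", mcl$genome_id,
            ": ccmO not terminal")
  }
  invisible(mcl)
}

#' Classify the genomic position of ccmO for one genome
#'
#' @param loci list from [identify_mcl()] (kinds must be set).
#' @return one of "mcl" (a ccmO gene inside the MCL), "satellite" (ccmO
#'   present only outside the MCL), "absent".
#' @export
classify_ccmO_position <- function(loci) {
  kinds <- vapply(loci, `[[`, character(1), "kind")
  if (length(loci) > 0 && anyNA(kinds)) {
    stop("run identify_mcl() before classify_ccmO_position()")
  }
  has_o <- vapply(loci, function(l) "CcmO" %in% l$members$label, logical(1))
  if (!any(has_o)) return("absent")
  if (any(has_o & kinds == "MCL")) "mcl" else "satellite"
}

#' Assemble and annotate loci for a whole cohort
#'
#' Runs [assemble_loci()] + [identify_mcl()] per genome, catching per-genome
#' integrity errors (e.g. duplicated MCL) so one bad genome does not stop
#' the cohort.
#'
#' @param gene_tables named list of per-genome gene tables.
#' @param config an [assembly_config()].
#' @return list with `loci_by_genome` (named list), `no_mcl` (genome ids
#'   flagged non-beta), `problems` (named character vector of error
#'   messages for genomes excluded from downstream tallies).
#' @export
assemble_cohort <- function(gene_tables, config = assembly_config()) {
  loci_by_genome <- list()
  no_mcl <- character(0)
  problems <- character(0)
  for (g in names(gene_tables)) {
    res <- tryCatch({
      loci <- identify_mcl(assemble_loci(gene_tables[[g]], config))
      if (isTRUE(attr(loci, "no_mcl"))) no_mcl <- c(no_mcl, g)
      loci
    }, error = function(e) e)
    if (inherits(res, "error")) {
      problems[g] <- conditionMessage(res)
    } else {
      loci_by_genome[[g]] <- res
    }
  }
  list(loci_by_genome = loci_by_genome, no_mcl = no_mcl,
       problems = problems)
}

#' Summarise locus types across a cohort
#'
#' Groups identical locus signatures, counts satellite loci per genome and
#' tallies the genomic position of ccmO. Genomes that raised integrity
#' errors are reported but excluded from the tallies.
#'
#' @param cohort result of [assemble_cohort()] (or a named list of
#'   identified locus lists).
#' @return list of class `ccm_locus_summary`: `signature_counts`
#'   (data.frame signature/kind/count), `satellite_counts` (per genome),
#'   `mean_satellites` (1 decimal), `ccmO_positions` (named tally),
#'   `n_genomes`, `no_mcl`, `problems`.
#' @export
summarize_locus_types <- function(cohort) {
  if (!is.list(cohort) || is.null(cohort$loci_by_genome)) {
    cohort <- list(loci_by_genome = cohort, no_mcl = character(0),
                   problems = character(0))
  }
  lbg <- cohort$loci_by_genome
  sig <- character(0); kind <- character(0)
  sat_counts <- integer(0)
  ccmO <- character(0)
  for (g in names(lbg)) {
    loci <- lbg[[g]]
    sig <- c(sig, vapply(loci, `[[`, character(1), "signature"))
    kind <- c(kind, vapply(loci, `[[`, character(1), "kind"))
    sat_counts[g] <- sum(vapply(loci, `[[`, character(1), "kind") ==
                           "satellite")
    ccmO[g] <- classify_ccmO_position(loci)
  }
  key <- paste(sig, kind, sep = "\r")
  tab <- sort(table(key), decreasing = TRUE)
  parts <- strsplit(names(tab), "\r")
  signature_counts <- data.frame(
    signature = vapply(parts, `[[`, character(1), 1),
    kind = vapply(parts, `[[`, character(1), 2),
    count = as.integer(tab), stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    signature_counts = signature_counts,
    satellite_counts = sat_counts,
    mean_satellites = round_half_away(mean(sat_counts), 1),
    ccmO_positions = table(factor(ccmO,
                                  levels = c("mcl", "satellite", "absent"))),
    n_genomes = length(lbg),
    no_mcl = cohort$no_mcl,
    problems = cohort$problems), class = "ccm_locus_summary")
}

#' Flatten a list of loci to a data.frame
#'
#' One row per locus; the shape written by the `loci` command.
#'
#' @param loci_by_genome named list of locus lists (or one locus list).
#' @return data.frame with genome, replicon, span, kind, signature, flags.
#' @export
loci_table <- function(loci_by_genome) {
  if (length(loci_by_genome) > 0 && inherits(loci_by_genome[[1]],
                                             "ccm_locus")) {
    loci_by_genome <- list(loci_by_genome)
  }
  rows <- list()
  for (loci in loci_by_genome) {
    for (l in loci) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = l$genome_id, replicon_id = l$replicon_id,
        span_start = l$span[1], span_end = l$span[2],
        n_members = nrow(l$members), kind = l$kind,
        signature = l$signature, flags = l$flags,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(genome_id = character(), replicon_id = character(),
                      span_start = integer(), span_end = integer(),
                      n_members = integer(), kind = character(),
                      signature = character(), flags = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
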
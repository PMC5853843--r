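# Co-regulation of shell genes with the main carboxysome locus from
# expression matrices: linearization, pairwise Pearson correlation, focal
# gene aggregation and group means.
#
# Gene roles tie matrix rows to the locus architecture:
#   MCL_ccmK       ccmK1/ccmK2 genes inside the MCL
#   MCL_core       ccmL / ccmM / ccmN
#   MCL_ccmO       ccmO when terminal in the MCL
#   satellite_ccmO ccmO when relocated to a satellite locus
#   ccmK3, ccmK4, ccmP   satellite shell genes
#   rbcL, rbcS     RubisCO genes (always excluded from MCL averages)
#   other          everything else

EXPRESSION_ROLES <- c("MCL_ccmK", "MCL_core", "MCL_ccmO", "satellite_ccmO",
                      "ccmK3", "ccmK4", "ccmP", "rbcL", "rbcS", "other")

#' Construct an expression dataset
#'
#' @param values numeric gene x condition matrix with gene rownames; at
#'   least 3 conditions, no missing values.
#' @param roles named character vector mapping genes to roles (see above);
#'   genes without an entry default to "other".
#' @param dataset_id,species_id identifiers (several datasets may share a
#'   species; they are kept separate).
#' @param scale "linear" or "log2".
#' @return list of class `ccm_expression`.
#' @export
expression_dataset <- function(values, roles, dataset_id = "ds1",
                               species_id = dataset_id,
                               scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (ncol(values) < 3L) stop("expression datasets need >= 3 conditions")
  if (anyNA(values)) stop("expression matrix contains missing values")
  full <- setNames(rep("other", nrow(values)), rownames(values))
  roles <- roles[names(roles) %in% rownames(values)]
  bad <- setdiff(unique(roles), EXPRESSION_ROLES)
  if (length(bad) > 0L) {
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(EXPRESSION_ROLES, collapse = ", "))
  }
  full[names(roles)] <- roles
  structure(list(dataset_id = dataset_id, species_id = species_id,
                 scale = scale, values = values, roles = full),
            class = "ccm_expression")
}

#' Convert a log2-scaled dataset to the linear scale
#'
#' Correlations are always computed on the linear scale; log2 datasets are
#' transformed elementwise (`value -> 2^value`) first. Linear datasets pass
#' through unchanged.
#'
#' @param dataset a `ccm_expression`.
#' @return the dataset on the linear scale.
#' @export
linearize <- function(dataset) {
  stopifnot(inherits(dataset, "ccm_expression"))
  if (dataset$scale == "log2") {
    dataset$values <- 2^dataset$values
    dataset$scale <- "linear"
  }
  dataset
}

#' Pearson product-moment correlation with explicit degeneracy handling
#'
#' @param x,y equal-length numeric vectors (>= 3 values).
#' @return r in \[-1, 1\]; NA with a warning if either vector has zero
#'   variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; Pearson correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

mcl_gene_names <- function(dataset) {
  names(dataset$roles)[dataset$roles %in%
                         c("MCL_ccmK", "MCL_core", "MCL_ccmO")]
}

focal_gene_names <- function(dataset, focal) {
  r <- dataset$roles
  switch(focal,
         ccmO = names(r)[r %in% c("MCL_ccmO", "satellite_ccmO")],
         ccmK12 = names(r)[r == "MCL_ccmK"],
         ccmK34 = names(r)[r %in% c("ccmK3", "ccmK4")],
         stop("unknown focal set: ", focal))
}

partner_gene_names <- function(dataset, focal) {
  r <- dataset$roles
  if (focal == "ccmO") {
    # ccmO is compared against MCL ccmKs + ccmL/M/N, never against itself
    names(r)[r %in% c("MCL_ccmK", "MCL_core")]
  } else {
    # "remaining MCL genes": the full MCL, minus the focal genes
    # themselves (handled by the caller) and RubisCO genes (not MCL roles)
    mcl_gene_names(dataset)
  }
}

#' Mean correlation of a focal gene set with MCL genes
#'
#' Linearizes the dataset, computes pairwise Pearson correlations of each
#' focal gene against its MCL partner set, averages over partners per focal
#' gene, then averages over focal genes. Self-pairs are always excluded;
#' with `exclude_focal_pairs = TRUE` (default) pairs inside the focal set
#' (e.g. r(ccmK1, ccmK2)) are excluded as well. RubisCO genes are never
#' partners. Missing or zero-variance partners are skipped with the divisor
#' adjusted and a warning.
#'
#' @param dataset a `ccm_expression`.
#' @param focal "ccmO", "ccmK12" or "ccmK34".
#' @param exclude_focal_pairs drop within-focal-set pairs from the average?
#' @return mean Pearson r (NA if the focal set is absent from the matrix).
#' @export
mean_corr_with_mcl <- function(dataset, focal = c("ccmO", "ccmK12", "ccmK34"),
                               exclude_focal_pairs = TRUE) {
  focal <- match.arg(focal)
  dataset <- linearize(dataset)
  v <- dataset$values
  fg <- intersect(focal_gene_names(dataset, focal), rownames(v))
  if (length(fg) == 0L) return(NA_real_)
  partners_all <- intersect(partner_gene_names(dataset, focal), rownames(v))
  per_focal <- vapply(fg, function(g) {
    partners <- setdiff(partners_all, g)
    if (exclude_focal_pairs) partners <- setdiff(partners, fg)
    if (length(partners) == 0L) stop("empty MCL partner set for gene ", g)
    rs <- vapply(partners, function(p) {
      suppressWarnings(pearson_r(v[g, ], v[p, ]))
    }, numeric(1))
    if (anyNA(rs)) {
      warning("skipping ", sum(is.na(rs)),
              " undefined correlation(s) for gene ", g)
      rs <- rs[!is.na(rs)]
    }
    if (length(rs) == 0L) return(NA_real_)
    mean(rs)
  }, numeric(1))
  mean(per_focal, na.rm = TRUE)
}

#' Per-dataset co-regulation summary
#'
#' @param dataset a `ccm_expression`.
#' @param exclude_focal_pairs see [mean_corr_with_mcl()].
#' @return one-row data.frame: dataset_id, species_id, ccmO_position,
#'   ccmO, ccmK12, ccmK34 (mean Pearson r with MCL genes).
#' @export
coexpression_summary <- function(dataset, exclude_focal_pairs = TRUE) {
  pos <- if (any(dataset$roles == "satellite_ccmO")) "satellite" else
    if (any(dataset$roles == "MCL_ccmO")) "mcl" else "absent"
  data.frame(
    dataset_id = dataset$dataset_id, species_id = dataset$species_id,
    ccmO_position = pos,
    ccmO = mean_corr_with_mcl(dataset, "ccmO", exclude_focal_pairs),
    ccmK12 = mean_corr_with_mcl(dataset, "ccmK12", exclude_focal_pairs),
    ccmK34 = mean_corr_with_mcl(dataset, "ccmK34", exclude_focal_pairs),
    stringsAsFactors = FALSE)
}

#' Aggregate per-dataset correlation values into group means
#'
#' Datasets are grouped by the genomic position of ccmO in their species
#' (mcl vs satellite); group values are arithmetic means of the
#' per-dataset values, rounded half away from zero to 2 decimals. The
#' ccmK1/2 and ccmK3/4 columns are averaged over all datasets.
#'
#' @param summaries data.frame of rows from [coexpression_summary()] (or
#'   equivalent columns `ccmO_position`, `ccmO`, `ccmK12`, `ccmK34`).
#' @return list with `ccmO_mcl_mean`, `ccmO_satellite_mean`,
#'   `ccmK12_overall`, `ccmK34_overall`, `n_datasets`.
#' @export
aggregate_groups <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0,
            all(c("ccmO_position", "ccmO", "ccmK12", "ccmK34") %in%
                  names(summaries)))
  grp_mean <- function(sel, col) {
    if (!any(sel)) {
      warning("empty group for column ", col)
      return(NA_real_)
    }
    round_half_away(mean(summaries[[col]][sel]), 2)
  }
  list(ccmO_mcl_mean = grp_mean(summaries$ccmO_position == "mcl", "ccmO"),
       ccmO_satellite_mean = grp_mean(summaries$ccmO_position == "satellite",
                                      "ccmO"),
       ccmK12_overall = round_half_away(mean(summaries$ccmK12), 2),
       ccmK34_overall = round_half_away(mean(summaries$ccmK34), 2),
       n_datasets = nrow(summaries))
}
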
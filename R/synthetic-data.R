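# Seeded synthetic-data generators: genome gene tables with realistic
# beta-carboxysome locus architectures, class-specific protein families,
# per-class seed alignments and block-correlated expression matrices.
#
# The generator's defaults encode the empirical architecture of
# beta-cyanobacterial genomes: every genome carries one MCL
# (ccmK2 [ccmK1] [ccmK2'] ccmL ccmM ccmN [ccmO]) and a ccmP satellite;
# the ccmK3-ccmK4 satellite pair is present in 206/227 genomes and the two
# genes strictly co-occur; ccmK5 (10/227) occurs only in genomes lacking
# ccmK3/4; ccmK6 (25/227) is independent; ccmO is relocated to a satellite
# locus in 89/227 genomes and terminal in the MCL otherwise.

ARCHETYPE_LENGTHS <- c(CcmK12 = 118L, CcmK3 = 102L, CcmK4 = 104L,
                       CcmK5 = 101L, CcmK6 = 103L, CcmO = 215L,
                       CcmP = 219L, EutM = 97L)
ARCHETYPE_BASE_SEED <- 700936L  # fixed: archetypes are package constants

#' Built-in divergent class archetype sequences
#'
#' One deterministic random amino-acid consensus per shell-protein class
#' (uniform composition, class-specific lengths: BMC-H classes ~100 aa,
#' the tandem-domain BMC-T classes CcmO/CcmP ~215-219 aa, plus the EutM
#' outgroup). Classes are mutually unrelated by construction, emulating the
#' between-class divergence that makes profile classification work, without
#' modelling within-family phylogeny.
#'
#' @param classes subset of the built-in class names.
#' @return named character vector of archetype sequences.
#' @export
class_archetypes <- function(classes = names(ARCHETYPE_LENGTHS)) {
  stopifnot(all(classes %in% names(ARCHETYPE_LENGTHS)))
  aa <- amino_acids()
  out <- vapply(classes, function(cl) {
    i <- match(cl, names(ARCHETYPE_LENGTHS))
    with_seed(ARCHETYPE_BASE_SEED + i, {
      paste0(sample(aa, ARCHETYPE_LENGTHS[[cl]], replace = TRUE),
             collapse = "")
    })
  }, character(1))
  setNames(out, classes)
}

mutate_sequence <- function(s, rate) {
  if (rate == 0) return(s)
  aa <- amino_acids()
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  paste0(ch, collapse = "")
}

#' Cohort specification for the genome generator
#'
#' Defaults are the empirical class frequencies of the 227-genome
#' reference cohort.
#'
#' @param n_genomes cohort size.
#' @param p_k34 probability of the ccmK3-ccmK4 satellite pair (drawn as a
#'   single Bernoulli event: the two genes strictly co-occur).
#' @param p_k5 marginal ccmK5 probability; ccmK5 is only ever drawn in
#'   genomes lacking ccmK3/4 (exclusion enforced exactly).
#' @param p_k6 ccmK6 probability (independent).
#' @param p_ccmO_satellite probability that ccmO sits in a satellite locus
#'   rather than terminating the MCL.
#' @param n_mcl_ccmK_weights weights for 1/2/3 ccmK1/2 genes in the MCL
#'   (default: 5/227 genomes lack ccmK1; most carry the K2-K1 tandem).
#' @param n_filler_range range of total genes per replicon.
#' @param seed default RNG seed (overridable at generation time).
#' @return list of class `ccm_cohort_spec`.
#' @export
cohort_spec <- function(n_genomes = 227L,
                        p_k34 = 206 / 227,
                        p_k5 = 10 / 227,
                        p_k6 = 25 / 227,
                        p_ccmO_satellite = 89 / 227,
                        n_mcl_ccmK_weights = c(5, 192, 30) / 227,
                        n_filler_range = c(140L, 180L),
                        seed = 1L) {
  stopifnot(n_genomes >= 1,
            p_k34 >= 0, p_k34 <= 1, p_k5 >= 0, p_k6 >= 0, p_k6 <= 1,
            p_ccmO_satellite >= 0, p_ccmO_satellite <= 1,
            length(n_mcl_ccmK_weights) == 3L, all(n_mcl_ccmK_weights >= 0),
            n_filler_range[1] <= n_filler_range[2])
  if (p_k5 > 1 - p_k34 + 1e-12) {
    stop("p_k5 cannot exceed 1 - p_k34 (ccmK5 excludes ccmK3/4)")
  }
  structure(list(n_genomes = as.integer(n_genomes), p_k34 = p_k34,
                 p_k5 = p_k5, p_k6 = p_k6,
                 p_ccmO_satellite = p_ccmO_satellite,
                 n_mcl_ccmK_weights = n_mcl_ccmK_weights /
                   sum(n_mcl_ccmK_weights),
                 n_filler_range = as.integer(n_filler_range),
                 seed = as.integer(seed)),
            class = "ccm_cohort_spec")
}

#' Generate a cohort of synthetic gene tables
#'
#' Each genome receives one MCL block, a ccmP satellite, and optional
#' ccmK3-K4 / ccmK5 / ccmK6 / satellite-ccmO blocks, placed on a single
#' linear replicon so that distinct loci are separated by more than
#' `satellite_distance` intervening filler genes. Constraint satisfaction
#' is exact: no generated genome ever violates the K3-K4 co-occurrence or
#' the K5 exclusion.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @param config an [assembly_config()] supplying the satellite distance.
#' @return named list of per-genome gene-table data.frames; attribute
#'   `truth` is a data.frame of the generating features per genome.
#' @export
generate_genomes <- function(spec = cohort_spec(), seed = NULL,
                             config = assembly_config()) {
  set.seed(seed %||% spec$seed)
  gap_min <- config$satellite_distance + 1L  # > satellite_distance intervening
  tables <- vector("list", spec$n_genomes)
  truth <- vector("list", spec$n_genomes)
  names(tables) <- sprintf("genome%04d", seq_len(spec$n_genomes))
  for (gi in seq_len(spec$n_genomes)) {
    gid <- names(tables)[gi]
    n_mclK <- sample(1:3, 1, prob = spec$n_mcl_ccmK_weights)
    mcl_k <- switch(n_mclK, "CcmK2", c("CcmK2", "CcmK1"),
                    c("CcmK2", "CcmK1", "CcmK2"))
    o_satellite <- runif(1) < spec$p_ccmO_satellite
    mcl <- c(mcl_k, "CcmL", "CcmM", "CcmN", if (!o_satellite) "CcmO")
    has_k34 <- runif(1) < spec$p_k34
    has_k5 <- !has_k34 && runif(1) < spec$p_k5 / (1 - spec$p_k34)
    has_k6 <- runif(1) < spec$p_k6
    blocks <- c(list(mcl, "CcmP"),
                if (has_k34) list(c("CcmK3", "CcmK4")),
                if (has_k5) list("CcmK5"),
                if (has_k6) list("CcmK6"),
                if (o_satellite) list("CcmO"))
    blocks <- blocks[sample(length(blocks))]
    nb <- length(blocks)
    n_genes <- sample(spec$n_filler_range[1]:spec$n_filler_range[2], 1)
    slack <- n_genes - sum(lengths(blocks)) - (nb - 1L) * gap_min
    if (slack < 0L) {
      stop("replicon too short (", n_genes, " genes) for ", nb,
           " loci at satellite distance ", config$satellite_distance)
    }
    extra <- as.integer(stats::rmultinom(1, slack, rep(1, nb + 1L)))
    labels <- character(0)
    for (b in seq_len(nb)) {
      labels <- c(labels, rep("Other", extra[b]),
                  if (b > 1L) character(0), blocks[[b]],
                  if (b < nb) rep("Other", gap_min))
    }
    labels <- c(labels, rep("Other", extra[nb + 1L]))
    tables[[gi]] <- data.frame(
      genome_id = gid, replicon_id = "chr1",
      ordinal = seq_along(labels) - 1L,
      gene_id = sprintf("%s_g%04d", gid, seq_along(labels)),
      strand = "+", label = labels, stringsAsFactors = FALSE)
    truth[[gi]] <- data.frame(
      genome_id = gid, n_mcl_ccmK = n_mclK,
      ccmO_position = if (o_satellite) "satellite" else "mcl",
      has_k34 = has_k34, has_k5 = has_k5, has_k6 = has_k6,
      stringsAsFactors = FALSE)
  }
  structure(tables, truth = do.call(rbind, truth))
}

#' Generate synthetic shell-protein sequences
#'
#' Sequences are drawn from their class archetype (or from supplied
#' profiles) and point-mutated at `rate`. CcmK2 sequences take lengths
#' 100-107, CcmK1 108-118 (truncations of the shared CcmK1/2 archetype),
#' so the CcmK1-vs-CcmK2 separation is achievable purely by length.
#'
#' @param n_per_class sequences per class.
#' @param rate per-position substitution probability in \[0, 0.3\].
#' @param classes class names; "CcmK1"/"CcmK2" use the CcmK12 archetype.
#' @param profiles optional named list of `ccm_profile` objects to sample
#'   from instead of the built-in archetypes.
#' @param seed RNG seed.
#' @return data.frame with `protein_id`, `genome_id` (NA), `class`,
#'   `sequence`, `length`.
#' @export
generate_sequences <- function(n_per_class = 10, rate = 0.1,
                               classes = c("CcmK1", "CcmK2", "CcmK3",
                                           "CcmK4", "CcmK5", "CcmK6",
                                           "CcmO", "CcmP", "EutM"),
                               profiles = NULL, seed = 1L) {
  if (rate < 0 || rate > 0.3) stop("substitution rate must be in [0, 0.3]")
  set.seed(seed)
  arch <- class_archetypes()
  rows <- list()
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      if (!is.null(profiles) && cl %in% names(profiles)) {
        s <- sample_from_profile(profiles[[cl]])
      } else {
        base_cl <- if (cl %in% c("CcmK1", "CcmK2")) "CcmK12" else cl
        if (!base_cl %in% names(arch)) stop("no archetype for class ", cl)
        s <- arch[[base_cl]]
        if (cl == "CcmK2") s <- substr(s, 1, sample(100:107, 1))
        if (cl == "CcmK1") s <- substr(s, 1, sample(108:118, 1))
      }
      s <- mutate_sequence(s, rate)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = sprintf("%s_%03d", cl, i), genome_id = NA_character_,
        class = cl, sequence = s, length = nchar(s),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate per-class seed alignments
#'
#' Emulates the curated seed sets the classifier profiles are built from:
#' `n_seed` within-class homologs at low divergence, aligned by
#' construction (shared archetype coordinates; short CcmK1/2 variants are
#' padded with terminal gaps).
#'
#' @param n_seed sequences per class (reference seed sets held 7-29).
#' @param divergence within-class substitution rate.
#' @param classes classes to build (profile names; CcmK1/2 is "CcmK12").
#' @param seed RNG seed.
#' @return named list of named character vectors (aligned sequences).
#' @export
generate_seed_alignments <- function(n_seed = 12, divergence = 0.05,
                                     classes = c("CcmK12", "CcmK3", "CcmK4",
                                                 "CcmK5", "CcmK6", "CcmO",
                                                 "CcmP", "EutM"),
                                     seed = 101L) {
  set.seed(seed)
  arch <- class_archetypes()
  out <- list()
  for (cl in classes) {
    if (!cl %in% names(arch)) stop("no archetype for class ", cl)
    width <- nchar(arch[[cl]])
    seqs <- vapply(seq_len(n_seed), function(i) {
      s <- arch[[cl]]
      if (cl == "CcmK12") {
        # mix of CcmK2- and CcmK1-length variants, gap-padded
        len <- if (i %% 2 == 0) sample(100:107, 1) else sample(108:118, 1)
        s <- substr(s, 1, len)
      }
      s <- mutate_sequence(s, divergence)
      paste0(s, strrep("-", width - nchar(s)))
    }, character(1))
    names(seqs) <- sprintf("%s_seed%02d", cl, seq_len(n_seed))
    out[[cl]] <- seqs
  }
  out
}

#' Write seed alignments as one aligned FASTA per class
#'
#' @param seeds result of [generate_seed_alignments()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_seed_alignments <- function(seeds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(seeds)) {
    df <- data.frame(protein_id = names(seeds[[cl]]),
                     genome_id = NA_character_,
                     sequence = unname(seeds[[cl]]),
                     stringsAsFactors = FALSE)
    write_fasta(df, file.path(dir, paste0(cl, ".fasta")))
  }
  invisible(dir)
}

#' Expression-generator specification
#'
#' Gaussian single-factor model: gene g gets
#' `x_g = baseline + sqrt(rho_g) * f + sqrt(1 - rho_g) * e_g` with one
#' shared latent factor f per condition and unit-variance independent
#' noise, so any two genes with loadings rho_a, rho_b correlate at
#' `sqrt(rho_a * rho_b)` in expectation. MCL genes share `mcl_rho`;
#' satellite genes get per-gene loadings (`satellite_rho`), with satellite
#' ccmO independent (0) by default and ccmK3/ccmK4/ccmP at 0.22 — chosen
#' so their correlation with an mcl_rho = 0.8 MCL is ~0.42, the observed
#' moderate co-regulation of the K3/K4 satellite operon.
#'
#' @param n_conditions number of conditions (>= 3).
#' @param mcl_rho latent-factor correlation among MCL genes in \[0, 1\].
#' @param satellite_rho named loadings for satellite genes.
#' @param ccmO_position "mcl" or "satellite".
#' @param log2_output write the matrix as `log2(x + 1)` and flag the scale?
#' @param baseline additive offset keeping linear values positive.
#' @param seed RNG seed.
#' @return list of class `ccm_expression_spec`.
#' @export
expression_spec <- function(n_conditions = 12L, mcl_rho = 0.8,
                            satellite_rho = c(ccmO = 0, ccmK3 = 0.22,
                                              ccmK4 = 0.22, ccmP = 0.22),
                            ccmO_position = c("mcl", "satellite"),
                            log2_output = FALSE, baseline = 10,
                            seed = 1L) {
  ccmO_position <- match.arg(ccmO_position)
  stopifnot(n_conditions >= 3, mcl_rho >= 0, mcl_rho <= 1,
            all(satellite_rho >= 0), all(satellite_rho <= 1))
  structure(list(n_conditions = as.integer(n_conditions),
                 mcl_rho = mcl_rho, satellite_rho = satellite_rho,
                 ccmO_position = ccmO_position,
                 log2_output = isTRUE(log2_output), baseline = baseline,
                 seed = as.integer(seed)),
            class = "ccm_expression_spec")
}

#' Generate a block-correlated synthetic expression dataset
#'
#' @param spec an [expression_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @param dataset_id,species_id identifiers for the dataset.
#' @return a `ccm_expression` dataset (genes ccmK2/ccmK1/ccmL/ccmM/ccmN,
#'   ccmO, ccmK3/ccmK4/ccmP, rbcL/rbcS) with attribute `truth` recording
#'   the generating loadings.
#' @export
generate_expression <- function(spec = expression_spec(), seed = NULL,
                                dataset_id = "synthetic1",
                                species_id = dataset_id) {
  set.seed(seed %||% spec$seed)
  mcl_o <- spec$ccmO_position == "mcl"
  roles <- c(ccmK2 = "MCL_ccmK", ccmK1 = "MCL_ccmK", ccmL = "MCL_core",
             ccmM = "MCL_core", ccmN = "MCL_core",
             ccmO = if (mcl_o) "MCL_ccmO" else "satellite_ccmO",
             ccmK3 = "ccmK3", ccmK4 = "ccmK4", ccmP = "ccmP",
             rbcL = "rbcL", rbcS = "rbcS")
  sat <- spec$satellite_rho
  loadings <- c(ccmK2 = spec$mcl_rho, ccmK1 = spec$mcl_rho,
                ccmL = spec$mcl_rho, ccmM = spec$mcl_rho,
                ccmN = spec$mcl_rho,
                ccmO = if (mcl_o) spec$mcl_rho else unname(sat["ccmO"]),
                ccmK3 = unname(sat["ccmK3"]), ccmK4 = unname(sat["ccmK4"]),
                ccmP = unname(sat["ccmP"]),
                rbcL = spec$mcl_rho, rbcS = spec$mcl_rho)
  nc <- spec$n_conditions
  f <- rnorm(nc)
  values <- t(vapply(names(loadings), function(g) {
    rho <- loadings[[g]]
    spec$baseline + sqrt(rho) * f + sqrt(1 - rho) * rnorm(nc)
  }, numeric(nc)))
  colnames(values) <- sprintf("cond%03d", seq_len(nc))
  scale <- "linear"
  if (spec$log2_output) {
    values <- log2(values + 1)
    scale <- "log2"
  }
  ds <- expression_dataset(values, roles, dataset_id = dataset_id,
                           species_id = species_id, scale = scale)
  attr(ds, "truth") <- loadings
  ds
}

#' Generate protein sequences for every shell gene of a cohort
#'
#' Gives each Pfam00936/BMC-T gene in the gene tables a sequence of its
#' class so the classifier can be run end-to-end on a simulated cohort.
#' ccmL/M/N (non-Pfam00936) genes get no sequence.
#'
#' @param gene_tables result of [generate_genomes()].
#' @param rate substitution rate.
#' @param seed RNG seed.
#' @return data.frame in [read_fasta()] layout with a `class` column.
#' @export
cohort_proteins <- function(gene_tables, rate = 0.1, seed = 1L) {
  set.seed(seed)
  arch <- class_archetypes()
  shell <- c("CcmK1", "CcmK2", "CcmK3", "CcmK4", "CcmK5", "CcmK6",
             "CcmO", "CcmP")
  rows <- list()
  for (g in names(gene_tables)) {
    tab <- gene_tables[[g]]
    tab <- tab[tab$label %in% shell, , drop = FALSE]
    for (i in seq_len(nrow(tab))) {
      cl <- tab$label[i]
      base_cl <- if (cl %in% c("CcmK1", "CcmK2")) "CcmK12" else cl
      s <- arch[[base_cl]]
      if (cl == "CcmK2") s <- substr(s, 1, sample(100:107, 1))
      if (cl == "CcmK1") s <- substr(s, 1, sample(108:118, 1))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = tab$gene_id[i], genome_id = g, class = cl,
        sequence = mutate_sequence(s, rate), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$length <- nchar(out$sequence)
  out
}
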
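# Readers/writers for FASTA, gene tables, expression matrices and reports,
# plus sequence QC and run configuration.

#' Read protein sequences from a FASTA file
#'
#' A deliberately strict reader: the pipeline's downstream contracts depend
#' on clean identifiers and a closed residue alphabet, so malformed headers
#' and illegal characters are hard errors that name the offending line
#' (Biostrings is silent about both, which is why this reader is bespoke;
#' the round-trip against `Biostrings::readAAStringSet()` is covered in the
#' test suite).
#'
#' Header convention: `>protein_id [genome_id] ...`; the first whitespace
#' token is the protein id, the second (if present) the genome of origin.
#'
#' @param path FASTA file.
#' @param keep_gaps keep alignment gap characters (`-`, `.`)? Default strips
#'   them (unaligned input); seed alignments are read with `keep_gaps = TRUE`.
#' @return data.frame with columns `protein_id`, `genome_id`, `sequence`,
#'   `length` (residues, gaps excluded).
#' @export
read_fasta <- function(path, keep_gaps = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, ";")
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("empty FASTA file: ", path)
    return(empty_protein_frame())
  }
  hdr <- startsWith(lines[idx], ">")
  if (!hdr[1L]) {
    stop("FASTA parse error at line ", idx[1L], ": expected '>' header")
  }
  rec_of <- cumsum(hdr)
  ids <- character(max(rec_of))
  genomes <- character(max(rec_of))
  for (k in which(hdr)) {
    toks <- strsplit(sub("^>", "", lines[idx[k]]), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) {
      stop("FASTA parse error at line ", idx[k], ": empty header")
    }
    ids[rec_of[k]] <- toks[1L]
    genomes[rec_of[k]] <- if (length(toks) >= 2L) toks[2L] else NA_character_
  }
  allowed <- c(amino_acids(), "X", GAP_CHARS, "*")
  seqs <- character(length(ids))
  for (r in seq_along(ids)) {
    body <- idx[rec_of == r & !hdr]
    s <- toupper(paste0(lines[body], collapse = ""))
    chars <- strsplit(s, "")[[1]]
    bad <- which(!(chars %in% allowed))
    if (length(bad) > 0L) {
      # locate the first offending line for the error message
      off <- 0L
      culprit <- body[1L]
      for (b in body) {
        n <- nchar(lines[b])
        if (bad[1L] <= off + n) { culprit <- b; break }
        off <- off + n
      }
      stop("FASTA parse error at line ", culprit, ": illegal residue '",
           chars[bad[1L]], "' in record ", ids[r])
    }
    chars <- chars[chars != "*"]
    if (!keep_gaps) chars <- chars[!(chars %in% GAP_CHARS)]
    seqs[r] <- paste0(chars, collapse = "")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate protein_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- data.frame(protein_id = ids, genome_id = genomes, sequence = seqs,
                    stringsAsFactors = FALSE)
  out$length <- vapply(out$sequence, function(s) {
    sum(!(strsplit(s, "")[[1]] %in% GAP_CHARS))
  }, integer(1), USE.NAMES = FALSE)
  out
}

empty_protein_frame <- function() {
  data.frame(protein_id = character(), genome_id = character(),
             sequence = character(), length = integer(),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(records, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    gid <- records$genome_id[i]
    hdr <- if (is.na(gid)) paste0(">", records$protein_id[i]) else
      paste0(">", records$protein_id[i], " ", gid)
    writeLines(hdr, con)
    s <- records$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Flag low-information sequences by their fraction of 'X' residues
#'
#' Sequences whose fraction of undetermined residues ('X') strictly exceeds
#' `max_x_fraction` are dropped; the curation default of 0.20 removes genes
#' with more than 20% 'X'.
#'
#' @param records data.frame from [read_fasta()].
#' @param max_x_fraction threshold in (0, 1]; strict inequality.
#' @return list with elements `kept` and `dropped` (both data.frames
#'   partitioning the input).
#' @export
qc_filter <- function(records, max_x_fraction = 0.20) {
  stopifnot(is.numeric(max_x_fraction), max_x_fraction > 0,
            max_x_fraction <= 1)
  if (nrow(records) == 0L) return(list(kept = records, dropped = records))
  xfrac <- vapply(records$sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch <- ch[!(ch %in% GAP_CHARS)]
    if (length(ch) == 0L) return(0)
    mean(ch == "X")
  }, numeric(1), USE.NAMES = FALSE)
  drop <- xfrac > max_x_fraction
  list(kept = records[!drop, , drop = FALSE],
       dropped = records[drop, , drop = FALSE])
}

#' Read a per-genome gene table
#'
#' Gene tables give each gene an ordinal index along its replicon; ordinals
#' are the adjacency coordinate used by every distance rule in the locus
#' assembly ("10 open reading frames" is 10 gene units, not base pairs).
#'
#' Required columns: `genome_id`, `replicon_id`, `ordinal` (0-based,
#' consecutive per replicon), `gene_id`, `label`; optional `strand` and
#' logical `pseudo` (pseudogene rows are excluded after validation).
#'
#' @param path TSV file with a header row.
#' @param exclude_genomes genome ids to drop wholesale (e.g. incompletely
#'   sequenced genomes); no automatic completeness rule is applied.
#' @return named list (one entry per genome) of data.frames sorted by
#'   replicon and ordinal.
#' @export
read_gene_table <- function(path, exclude_genomes = character()) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  as_gene_table(df, exclude_genomes = exclude_genomes)
}

#' Validate and group an in-memory gene table
#'
#' @param df data.frame with gene-table columns (see [read_gene_table()]).
#' @param exclude_genomes genome ids to drop.
#' @return named list of per-genome data.frames.
#' @export
as_gene_table <- function(df, exclude_genomes = character()) {
  need <- c("genome_id", "replicon_id", "ordinal", "gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(df$label)) df$label <- "Other"
  df$label[is.na(df$label) | df$label == ""] <- "Other"
  if (is.null(df$strand)) df$strand <- "unknown"
  bad <- setdiff(unique(df$label), gene_labels())
  if (length(bad) > 0L) {
    stop("unknown label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(gene_labels(), collapse = ", "))
  }
  df$ordinal <- as.integer(df$ordinal)
  for (key in unique(paste(df$genome_id, df$replicon_id, sep = "\r"))) {
    sel <- paste(df$genome_id, df$replicon_id, sep = "\r") == key
    ords <- sort(df$ordinal[sel])
    if (anyDuplicated(ords)) {
      stop("gene table integrity error: duplicate ordinal in ",
           gsub("\r", "/", key))
    }
    if (!identical(ords, seq(0L, length.out = length(ords)))) {
      stop("gene table integrity error: ordinals not consecutive from 0 in ",
           gsub("\r", "/", key))
    }
  }
  if (!is.null(df$pseudo)) {
    df <- df[!(df$pseudo %in% c(TRUE, "TRUE", "true", 1)), , drop = FALSE]
    df$pseudo <- NULL
  }
  df <- df[!(df$genome_id %in% exclude_genomes), , drop = FALSE]
  df <- df[order(df$genome_id, df$replicon_id, df$ordinal), , drop = FALSE]
  split(df, df$genome_id)
}

#' Write a gene table (or any data.frame report) as TSV
#'
#' @param gene_tables named list of per-genome data.frames (or one
#'   data.frame).
#' @param path output TSV.
#' @export
write_gene_table <- function(gene_tables, path) {
  df <- if (is.data.frame(gene_tables)) gene_tables else
    do.call(rbind, c(gene_tables, list(make.row.names = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' First column = gene label, remaining columns = conditions.
#'
#' @param path TSV file.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Write a tabular or list result with a traceability header
#'
#' Reports carry `# config_hash=` and `# seed=` comment lines so any output
#' can be traced to the settings that produced it. TSV reports round-trip
#' through [read_report()] to 1e-9; list-like results are written as JSON.
#'
#' @param result data.frame (format "tsv") or list (format "json").
#' @param path output file.
#' @param format "tsv" or "json".
#' @param config optional configuration object to hash into the header.
#' @param seed optional integer seed recorded in the header.
#' @export
write_report <- function(result, path, format = c("tsv", "json"),
                         config = NULL, seed = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    stopifnot(is.data.frame(result))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# ccmshell report",
                 paste0("# config_hash=", config_hash(config)),
                 paste0("# seed=", seed %||% "NA")), con)
    num <- vapply(result, is.numeric, logical(1))
    out <- result
    out[num] <- lapply(out[num], function(x) format(x, digits = 15))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(meta = list(config_hash = config_hash(config),
                       seed = seed %||% NA),
           data = result),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    jsonlite::fromJSON(path)$data
  }
}

#' Assemble a run configuration
#'
#' One bag of settings for a full pipeline run; the hash of this object is
#' stamped into every report header.
#'
#' @param max_x_fraction QC threshold for [qc_filter()].
#' @param classifier a [classifier_config()].
#' @param assembly an [assembly_config()].
#' @param exclude_focal_pairs see [mean_corr_with_mcl()].
#' @param seed integer RNG seed.
#' @param out_dir output directory.
#' @return list of class `ccm_run_config`.
#' @export
run_config <- function(max_x_fraction = 0.20,
                       classifier = classifier_config(),
                       assembly = assembly_config(),
                       exclude_focal_pairs = TRUE,
                       seed = 1L, out_dir = ".") {
  stopifnot(max_x_fraction > 0, is.numeric(seed))
  structure(list(max_x_fraction = max_x_fraction, classifier = classifier,
                 assembly = assembly,
                 exclude_focal_pairs = isTRUE(exclude_focal_pairs),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "ccm_run_config")
}

#' Assign ordinals to a GFF-like coordinate table
#'
#' Converts base-pair coordinates to the ordinal gene index used by ccmshell:
#' genes are sorted by start position within each replicon and numbered from
#' 0. Strand is carried through but ignored by all algorithms.
#'
#' @param df data.frame with `genome_id`, `replicon_id`, `start`, `gene_id`,
#'   optional `strand` and `label`.
#' @return data.frame with an `ordinal` column, gene-table ready.
#' @export
ordinals_from_positions <- function(df) {
  stopifnot(all(c("genome_id", "replicon_id", "start", "gene_id") %in%
                  names(df)))
  df <- df[order(df$genome_id, df$replicon_id, df$start), , drop = FALSE]
  key <- paste(df$genome_id, df$replicon_id, sep = "\r")
  df$ordinal <- as.integer(stats::ave(seq_len(nrow(df)), key,
                                      FUN = seq_along) - 1L)
  df$start <- NULL
  df
}
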
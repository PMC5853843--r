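# Shared fixtures, built once per test run. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# Per-class seed alignments and the profiles built from them.
fx_seeds <- generate_seed_alignments(n_seed = 8, divergence = 0.05,
                                     seed = 4242)
fx_profiles <- lapply(names(fx_seeds), function(cl) {
  build_profile(fx_seeds[[cl]], cl)
})
names(fx_profiles) <- names(fx_seeds)

# Build a one-genome gene table from a sparse ordinal -> label map;
# all other ordinals are filler "Other" genes.
make_gene_rows <- function(labels_at, n = NULL, genome_id = "g1",
                           replicon_id = "chr1") {
  ords <- as.integer(names(labels_at))
  if (is.null(n)) n <- max(ords) + 5L
  lab <- rep("Other", n)
  lab[ords + 1L] <- unlist(labels_at)
  data.frame(genome_id = genome_id, replicon_id = replicon_id,
             ordinal = seq_len(n) - 1L,
             gene_id = sprintf("%s_g%03d", genome_id, seq_len(n)),
             strand = "+", label = lab, stringsAsFactors = FALSE)
}

# labels_at helper: list("10" = "CcmK2", ...) is tedious; build from vectors
at <- function(ordinals, labels) {
  setNames(as.list(labels), as.character(ordinals))
}

# Brute-force locus-region oracle: O(n^2) pairwise ordinal distances plus
# transitive closure. Two carboxysome genes are linked when the number of
# intervening genes between them is <= satellite_distance; connected
# components are locus regions.
oracle_regions <- function(rows, satellite_distance = 10L) {
  sub <- rows[rows$label %in% carboxysome_labels(), , drop = FALSE]
  out <- list()
  for (rep_id in unique(sub$replicon_id)) {
    ords <- sort(sub$ordinal[sub$replicon_id == rep_id])
    k <- length(ords)
    if (k == 0L) next
    adj <- matrix(FALSE, k, k)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        adj[i, j] <- abs(ords[i] - ords[j]) - 1L <= satellite_distance
      }
    }
    # transitive closure (Floyd-Warshall style)
    for (m in seq_len(k)) {
      adj <- adj | (adj[, m] %o% adj[m, ] > 0)
    }
    comp <- rep(NA_integer_, k)
    cid <- 0L
    for (i in seq_len(k)) {
      if (is.na(comp[i])) {
        cid <- cid + 1L
        comp[adj[i, ]] <- cid
      }
    }
    out[[rep_id]] <- split(ords, comp)
  }
  out
}

# Construct a vector with an exact Pearson correlation r to target u,
# via Gram-Schmidt on a helper vector.
vector_with_cor <- function(u, r, helper = seq_along(u)) {
  zu <- as.numeric(scale(u))
  v <- as.numeric(scale(helper))
  v <- v - sum(v * zu) / sum(zu * zu) * zu
  zv <- v / sqrt(sum(v^2) / (length(v) - 1))
  r * zu + sqrt(1 - r^2) * zv
}
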
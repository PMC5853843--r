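# Locus assembly: gap rules, MCL identification, ccmO position calls and
# cohort summaries, checked against a brute-force pairwise-distance oracle.

mcl6 <- c("CcmK2", "CcmK1", "CcmL", "CcmM", "CcmN", "CcmO")

test_that("a contiguous MCL assembles into one locus with its signature", {
  rows <- make_gene_rows(at(10:15, mcl6), n = 30L)
  loci <- assemble_loci(rows)
  expect_length(loci, 1L)
  expect_equal(loci[[1]]$signature, "K2-K1-L-M-N-O")
  expect_equal(loci[[1]]$span, c(10L, 15L))
  expect_equal(loci[[1]]$flags, "")
})

test_that("single non-carboxysome insertions do not interrupt a locus", {
  # K2 K1 L M [Other] N: one insertion, still one locus including N
  rows <- make_gene_rows(at(c(10, 11, 12, 13, 15),
                            c("CcmK2", "CcmK1", "CcmL", "CcmM", "CcmN")),
                         n = 30L)
  loci <- assemble_loci(rows)
  expect_length(loci, 1L)
  expect_equal(loci[[1]]$signature, "K2-K1-L-M-N")
  expect_equal(loci[[1]]$flags, "")

  # with max_insert = 0 the run breaks at the insertion; N is loosely
  # associated with the same region but outside the core
  loci0 <- assemble_loci(rows, assembly_config(max_insert = 0L))
  expect_length(loci0, 1L)
  expect_equal(loci0[[1]]$signature, "K2-K1-L-M")
  expect_equal(loci0[[1]]$flags, "loosely_associated")
})

test_that("distance rules split satellites at the 10-ORF boundary", {
  # ccmO at ordinal 40, nearest carboxysome gene at 25 -> satellite
  rows <- make_gene_rows(at(c(20:24, 60, 40),
                            c(mcl6[1:5], "CcmP", "CcmO")), n = 80L)
  loci <- identify_mcl(assemble_loci(rows))
  expect_length(loci, 3L)
  expect_equal(classify_ccmO_position(loci), "satellite")

  # exactly 10 intervening Others -> still the same locus region
  rows2 <- make_gene_rows(at(c(10, 21), c("CcmK3", "CcmK4")), n = 40L)
  loci2 <- assemble_loci(rows2)
  expect_length(loci2, 1L)
  # 11 intervening -> two satellite loci
  rows3 <- make_gene_rows(at(c(10, 22), c("CcmK3", "CcmK4")), n = 40L)
  expect_length(assemble_loci(rows3), 2L)
})

test_that("genes at gaps 2..10 join the region but not the core", {
  rows <- make_gene_rows(at(c(10, 11, 12, 13, 14, 18),
                            c("CcmK2", "CcmK1", "CcmL", "CcmM", "CcmN",
                              "CcmO")), n = 40L)
  loci <- assemble_loci(rows)
  expect_length(loci, 1L)
  expect_equal(loci[[1]]$signature, "K2-K1-L-M-N")  # O outside the core
  expect_equal(loci[[1]]$flags, "loosely_associated")
  expect_equal(nrow(loci[[1]]$members), 6L)         # but still a member
})

test_that("identify_mcl finds the unique MCL and sets kinds", {
  rows <- make_gene_rows(c(at(10:15, mcl6),
                           at(40:41, c("CcmK3", "CcmK4")),
                           at(60, "CcmP")), n = 80L)
  loci <- identify_mcl(assemble_loci(rows))
  kinds <- vapply(loci, `[[`, character(1), "kind")
  sigs <- vapply(loci, `[[`, character(1), "signature")
  expect_equal(kinds[sigs == "K2-K1-L-M-N-O"], "MCL")
  expect_equal(sum(kinds == "satellite"), 2L)
  expect_equal(classify_ccmO_position(loci), "mcl")

  # minimal genetic unit K2-L-M-N still qualifies
  rows2 <- make_gene_rows(at(10:13, c("CcmK2", "CcmL", "CcmM", "CcmN")),
                          n = 30L)
  loci2 <- identify_mcl(assemble_loci(rows2))
  expect_equal(attr(loci2, "mcl_index"), 1L)

  # genome with only satellite loci -> flagged, no MCL
  rows3 <- make_gene_rows(c(at(10:11, c("CcmK3", "CcmK4")), at(40, "CcmP")),
                          n = 60L)
  loci3 <- identify_mcl(assemble_loci(rows3))
  expect_true(attr(loci3, "no_mcl"))
  expect_equal(classify_ccmO_position(loci3), "absent")

  # duplicated full MCL -> integrity error
  rows4 <- make_gene_rows(c(at(10:15, mcl6), at(50:55, mcl6)), n = 80L)
  expect_error(identify_mcl(assemble_loci(rows4)), "multiple MCL")
})

test_that("atypical MCL gene order warns but does not error", {
  rows <- make_gene_rows(at(10:14, c("CcmM", "CcmK2", "CcmL", "CcmN",
                                     "CcmO")), n = 30L)
  expect_warning(identify_mcl(assemble_loci(rows)), "atypical MCL")
})

test_that("summarize_locus_types tallies signatures and satellites", {
  tabs <- lapply(1:3, function(i) {
    make_gene_rows(c(at(10:15, mcl6), at(40:41, c("CcmK3", "CcmK4")),
                     at(60, "CcmP")), n = 80L,
                   genome_id = paste0("g", i))
  })
  names(tabs) <- paste0("g", 1:3)
  s <- summarize_locus_types(assemble_cohort(tabs))
  expect_equal(s$mean_satellites, 2.0)
  expect_equal(unname(s$ccmO_positions["mcl"]), 3L)
  expect_equal(s$signature_counts$count[
    s$signature_counts$signature == "K2-K1-L-M-N-O"], 3L)

  # a genome with a duplicated MCL surfaces as a problem, not a count
  tabs$g4 <- make_gene_rows(c(at(10:15, mcl6), at(50:55, mcl6)), n = 80L,
                            genome_id = "g4")
  cohort <- assemble_cohort(tabs)
  expect_named(cohort$problems, "g4")
  s2 <- summarize_locus_types(cohort)
  expect_equal(s2$n_genomes, 3L)
  expect_equal(s2$mean_satellites, 2.0)
})

test_that("assembly matches the brute-force pairwise-distance oracle", {
  set.seed(99)
  labels_pool <- carboxysome_labels()
  for (trial in 1:200) {  # 1000 trials run in the acceptance suite
    n <- sample(10:50, 1)
    k <- sample(0:6, 1)
    lab <- rep("Other", n)
    if (k > 0) {
      lab[sample(n, k)] <- sample(labels_pool, k, replace = TRUE)
    }
    rows <- data.frame(genome_id = "g", replicon_id = "c",
                       ordinal = seq_len(n) - 1L,
                       gene_id = as.character(seq_len(n)), strand = "+",
                       label = lab, stringsAsFactors = FALSE)
    loci <- assemble_loci(rows)
    got <- lapply(loci, function(l) sort(l$members$ordinal))
    want <- oracle_regions(rows)[["c"]]
    want <- if (is.null(want)) list() else unname(want)
    expect_equal(got[order(vapply(got, min, 1))],
                 unname(want[order(vapply(want, min, 1))]))
    # partition property: every carboxysome gene in exactly one locus
    expect_equal(as.integer(sort(unlist(got))),
                 sort(rows$ordinal[lab %in% labels_pool]))
  }
})

test_that("distant filler genes never change locus calls", {
  rows <- make_gene_rows(c(at(10:15, mcl6), at(40, "CcmP")), n = 60L)
  base <- loci_table(list(identify_mcl(assemble_loci(rows))))
  # append 30 Other genes far from everything
  rows2 <- make_gene_rows(c(at(10:15, mcl6), at(40, "CcmP")), n = 90L)
  ext <- loci_table(list(identify_mcl(assemble_loci(rows2))))
  expect_equal(ext, base)
})

test_that("satellite count equals total loci minus one for MCL genomes", {
  g <- generate_genomes(cohort_spec(n_genomes = 40, seed = 12))
  cohort <- assemble_cohort(g)
  expect_length(cohort$problems, 0L)
  expect_length(cohort$no_mcl, 0L)
  for (loci in cohort$loci_by_genome) {
    kinds <- vapply(loci, `[[`, character(1), "kind")
    expect_equal(sum(kinds == "MCL"), 1L)
    expect_equal(sum(kinds == "satellite"), length(loci) - 1L)
  }
})
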
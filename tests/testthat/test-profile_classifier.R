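# Profile construction, local-alignment scoring, best-hit assignment and
# the length-based CcmK1/CcmK2 split.

uniform_bg <- setNames(rep(0.05, 20), amino_acids())

test_that("build_profile reproduces hand-computed emission log-odds", {
  # one column A,A,A,G with alpha = 1 and uniform background:
  # score(A) = log2(((3+1)/(4+20)) / 0.05) = log2(10/3)
  aln <- c(s1 = "A", s2 = "A", s3 = "A", s4 = "G")
  p <- build_profile(aln, "toy", background = uniform_bg)
  expect_equal(unname(p$match_columns["A", 1]), log2(10 / 3), tolerance = 1e-12)
  expect_equal(unname(p$match_columns["G", 1]), log2((2 / 24) / 0.05),
               tolerance = 1e-12)

  # two identical sequences: consensus residue maximal in every column
  aln2 <- c(a = "MSIAVG", b = "MSIAVG")
  p2 <- build_profile(aln2, "toy2", background = uniform_bg)
  cons <- strsplit("MSIAVG", "")[[1]]
  for (j in seq_along(cons)) {
    expect_equal(names(which.max(p2$match_columns[, j])), cons[j])
  }

  expect_error(build_profile(c(x = "MSIAVG"), "one"), "at least 2")
})

test_that("gap-rich columns are excluded from match columns", {
  # column 2 is 60% gaps across five sequences -> dropped
  aln <- c(a = "MA", b = "M-", c = "M-", d = "MA", e = "M-")
  p <- build_profile(aln, "gappy", background = uniform_bg)
  expect_equal(ncol(p$match_columns), 1L)
  expect_equal(p$col_map, 1L)
  # all-gap columns everywhere -> error
  expect_error(build_profile(c(a = "--", b = "--"), "allgap",
                             background = uniform_bg),
               "no profile columns")
})

test_that("consensus self-score equals the sum of per-column maxima", {
  p <- fx_profiles$CcmK4
  cons <- paste0(amino_acids()[apply(p$match_columns, 2, which.max)],
                 collapse = "")
  sc <- score_sequence(cons, p)
  expect_equal(sc$bit_score, sum(apply(p$match_columns, 2, max)),
               tolerance = 1e-9)
  expect_equal(sc$aligned_columns, ncol(p$match_columns))
})

test_that("background-drawn sequences score near zero (Monte-Carlo null)", {
  p <- fx_profiles$CcmK3
  set.seed(31)
  norm <- replicate(300, {
    s <- paste0(sample(amino_acids(), 102, replace = TRUE,
                       prob = p$background), collapse = "")
    score_sequence(s, p)$normalized_score
  })
  expect_true(all(norm <= 0.5))
  expect_lt(mean(norm), 0.25)
})

test_that("local alignment score is invariant to background-drawn flanks", {
  p <- fx_profiles$CcmK5
  set.seed(17)
  for (i in 1:10) {
    s <- sample_seq <- gsub("-", "", fx_seeds$CcmK5[[i %% 8 + 1]])
    flank1 <- paste0(sample(amino_acids(), 50, replace = TRUE,
                            prob = p$background), collapse = "")
    flank2 <- paste0(sample(amino_acids(), 50, replace = TRUE,
                            prob = p$background), collapse = "")
    base <- score_sequence(s, p)$bit_score
    expect_equal(score_sequence(paste0(flank1, s), p)$bit_score, base,
                 tolerance = 1e-9)
    expect_equal(score_sequence(paste0(s, flank2), p)$bit_score, base,
                 tolerance = 1e-9)
  }
})

test_that("point mutations away from the consensus never increase the score", {
  p <- fx_profiles$CcmK6
  cons <- paste0(amino_acids()[apply(p$match_columns, 2, which.max)],
                 collapse = "")
  base <- score_sequence(cons, p)$bit_score
  set.seed(23)
  for (i in 1:25) {
    ch <- strsplit(cons, "")[[1]]
    pos <- sample(length(ch), sample(1:5, 1))
    for (j in pos) ch[j] <- sample(setdiff(amino_acids(), ch[j]), 1)
    expect_lte(score_sequence(paste0(ch, collapse = ""), p)$bit_score,
               base + 1e-9)
  }
})

test_that("assign_class picks the best profile and flags ties", {
  set.seed(41)
  s <- sample_from_profile(fx_profiles$CcmK4)
  res <- assign_class(s, fx_profiles)
  expect_equal(res$label, "CcmK4")

  # permuting profile order never changes the label
  res2 <- assign_class(s, rev(fx_profiles))
  expect_equal(res2$label, res$label)
  expect_equal(res2$scores, res$scores[names(res2$scores)])

  # two identical profiles under different names -> exact tie, broken
  # alphabetically, flagged ambiguous
  pa <- fx_profiles$CcmK3; pa$class_name <- "Zed"
  pb <- fx_profiles$CcmK3; pb$class_name <- "Abe"
  s3 <- sample_from_profile(fx_profiles$CcmK3)
  tie <- assign_class(s3, list(pa, pb))
  expect_equal(tie$label, "Abe")
  expect_true(tie$ambiguous)
  expect_equal(tie$margin, 0)

  # a sequence scoring 0 everywhere is Unclassified: use a poly-X string
  unc <- assign_class(strrep("X", 120), fx_profiles)
  expect_equal(unc$label, "Unclassified")

  # outgroup seeds classify as the outgroup, not any CcmK class
  eutm <- gsub("-", "", fx_seeds$EutM[[1]])
  expect_equal(assign_class(eutm, fx_profiles)$label, "EutM")
})

test_that("split_k1k2 brackets lengths at the 107/108 boundary", {
  expect_equal(split_k1k2(105), "CcmK2")
  expect_equal(split_k1k2(110), "CcmK1")
  expect_equal(split_k1k2(107), "CcmK2")
  expect_equal(split_k1k2(108), "CcmK1")
  expect_equal(split_k1k2(100), "CcmK2")
  expect_equal(split_k1k2(118), "CcmK1")
  expect_warning(out <- split_k1k2(95), "brackets")
  expect_equal(out, "CcmK12_ambiguous")
})

test_that("held-out seed sequences self-classify (leave-one-out)", {
  cfg <- classifier_config()
  for (cl in names(fx_seeds)) {
    aln <- fx_seeds[[cl]]
    for (i in seq_len(3)) {  # 3 held-out seeds per class; full LOO in
                             # the acceptance suite
      prof_i <- lapply(names(fx_seeds), function(c2) {
        a <- fx_seeds[[c2]]
        if (c2 == cl) a <- a[-i]
        build_profile(a, c2, cfg)
      })
      res <- assign_class(gsub("-", "", aln[[i]]), prof_i, cfg)
      expect_equal(res$raw_label, cl)
    }
  }
})

test_that("classify_sequences recovers generated classes including K1/K2", {
  s <- generate_sequences(n_per_class = 20, rate = 0.1, seed = 77)
  res <- classify_sequences(s, fx_profiles)
  expect_equal(nrow(res), nrow(s))
  acc <- mean(res$label == s$class)
  expect_gte(acc, 0.95)
  # K1 vs K2 separation comes purely from the length split
  k12 <- s$class %in% c("CcmK1", "CcmK2")
  expect_true(all(res$raw_label[k12] == "CcmK12"))
  expect_equal(res$label[k12], s$class[k12])
})
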
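# Identity, redundancy reduction, column trimming, neighbor joining,
# monophyly and information content.

test_that("pairwise_identity counts matches over comparable positions", {
  expect_equal(pairwise_identity("MSIAVG", "MSIAVG"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("AA--", "AAT-"), 1.0)  # 2 comparable, 2 match
  expect_error(pairwise_identity("---", "AA-"), "no comparable")
  expect_error(pairwise_identity("AA", "AAA"), "equal length")
})

test_that("reduce_redundancy is greedy, order-dependent and documented so", {
  a <- strrep("A", 200)
  b <- paste0(strrep("A", 199), "C")            # 99.5% to a -> dropped
  c_ <- paste0(strrep("A", 197), "CDE")         # 98.5% to a -> kept
  kept <- reduce_redundancy(c(a = a, b = b, c = c_))
  expect_equal(names(kept), c("a", "c"))

  # identical pair: first kept
  kept2 <- reduce_redundancy(c(x = a, y = a))
  expect_equal(names(kept2), "x")

  # all pairwise identities <= threshold: everything kept
  s <- c(p = "AAAA", q = "TTTT", r = "CCCC")
  expect_equal(names(reduce_redundancy(s)), c("p", "q", "r"))

  # kept-vs-kept property: no retained pair exceeds the threshold
  set.seed(3)
  pool <- vapply(1:20, function(i) {
    paste0(sample(amino_acids(), 50, replace = TRUE), collapse = "")
  }, character(1))
  names(pool) <- paste0("s", 1:20)
  kept3 <- reduce_redundancy(pool, threshold = 0.3)
  ids <- combn(seq_along(kept3), 2)
  for (k in seq_len(ncol(ids))) {
    expect_lte(pairwise_identity(kept3[[ids[1, k]]], kept3[[ids[2, k]]]),
               0.3)
  }
})

test_that("trim_columns drops gap-rich columns and is idempotent", {
  aln <- c(a = "MAC", b = "M-C", c = "M-C", d = "MAC", e = "M-C")
  tr <- trim_columns(aln, 0.5)  # column 2 is 60% gaps -> dropped
  expect_equal(unname(tr$alignment), rep("MC", 5))
  expect_equal(tr$col_map, c(1L, 3L))

  gapfree <- c(a = "MSIA", b = "MSVA")
  expect_equal(unname(trim_columns(gapfree)$alignment), unname(gapfree))

  twice <- trim_columns(tr$alignment, 0.5)
  expect_equal(twice$alignment, tr$alignment)

  expect_error(trim_columns(c(a = "--", b = "--"), 0.5), "all alignment")
})

test_that("neighbor joining recovers additive trees exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1)): additive distances
  D <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(D)
  # additivity oracle: the tree's path-length matrix equals D
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  # topology AB | CD
  mono <- class_monophyly(tr, c(A = "ab", B = "ab", C = "cd", D = "cd"))
  expect_true(all(mono$monophyletic))

  # 3 taxa: the unique unrooted resolution
  tr3 <- nj_tree(D[1:3, 1:3])
  expect_equal(ape::Ntip(tr3), 3L)

  # ultrametric equidistant 4 taxa: zero-length internal branch
  De <- matrix(2, 4, 4, dimnames = dimnames(D))
  diag(De) <- 0
  tre <- nj_tree(De)
  internal <- tre$edge[, 2] > ape::Ntip(tre)
  expect_true(all(abs(tre$edge.length[internal]) < 1e-12))

  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  Dn <- D; Dn[1, 2] <- 99
  expect_error(nj_tree(Dn), "not symmetric")
})

test_that("NJ recovers random additive topologies (property)", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    true <- ape::rtree(n)
    D <- ape::cophenetic.phylo(true)
    est <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("class_monophyly detects clades and mixtures", {
  t1 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  m1 <- class_monophyly(t1, c(a1 = "a", a2 = "a", b1 = "b", b2 = "b"))
  expect_true(all(m1$monophyletic))

  t2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  m2 <- class_monophyly(t2, c(a1 = "a", a2 = "a", b1 = "b", b2 = "b"))
  expect_false(any(m2$monophyletic))

  expect_error(class_monophyly(t1, c(a1 = "a")), "unlabeled")
})

test_that("synthetic classes are mostly monophyletic under p-distance NJ", {
  s <- generate_sequences(n_per_class = 10, rate = 0.08,
                          classes = c("CcmK3", "CcmK4", "CcmK5", "CcmK6",
                                      "CcmP"), seed = 21)
  # classes have different archetype lengths; pad to a common width
  width <- max(nchar(s$sequence))
  aln <- vapply(s$sequence, function(x) {
    paste0(x, strrep("-", width - nchar(x)))
  }, character(1))
  names(aln) <- s$protein_id
  D <- p_distance_matrix(aln)
  tr <- nj_tree(D)
  mono <- class_monophyly(tr, setNames(s$class, s$protein_id))
  expect_gte(sum(mono$monophyletic), 4L)
})

test_that("column information content matches closed forms", {
  # 100% one residue, uniform background, no pseudocount: log2(20) bits
  aln <- c(a = "M", b = "M", c = "M", d = "M")
  ic <- column_information(aln, pseudocount = 0)
  expect_equal(ic$ic[1], log2(20), tolerance = 1e-12)
  expect_equal(sum(ic$heights[, 1]), ic$ic[1], tolerance = 1e-12)

  # column matching the background exactly: 0 bits
  bg <- setNames(c(0.5, 0.5, rep(0, 18)), c("A", "C", amino_acids()[-c(1, 2)]))
  bg[bg == 0] <- 1e-12
  bg <- bg / sum(bg)
  ic0 <- column_information(c(a = "A", b = "C"), background = bg,
                            pseudocount = 0)
  expect_lt(ic0$ic[1], 1e-6)

  # dilution with background residues lowers IC (seeded monotonicity)
  set.seed(13)
  conserved <- rep("W", 20)
  diluted <- c(rep("W", 10), sample(amino_acids(), 10, replace = TRUE))
  ic_c <- column_information(setNames(conserved, paste0("s", 1:20)))
  ic_d <- column_information(setNames(diluted, paste0("s", 1:20)))
  expect_gt(ic_c$ic[1], ic_d$ic[1])

  # IC is non-negative and invariant to column order
  aln2 <- c(x = "WM", y = "WV", z = "WM")
  swapped <- c(x = "MW", y = "VW", z = "MW")
  expect_equal(column_information(aln2)$ic,
               rev(column_information(swapped)$ic))
  expect_true(all(column_information(aln2)$ic >= 0))

  expect_error(column_information(c(a = "-", b = "-")), "empty")
})
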
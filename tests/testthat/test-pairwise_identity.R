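test_that("global alignment handles identity and near-identity pairs", {
  sch <- scoring_scheme("nucleotide")
  self <- global_align("ACGT", "ACGT", sch)
  expect_equal(self$n_identical, 4L)
  expect_equal(self$n_aligned_cols, 4L)
  expect_false(grepl("-", self$aligned_a, fixed = TRUE))
  expect_equal(percent_identity(self), 100.0)
  # gap cost (10) exceeds a single mismatch (-4): stays ungapped
  aln <- global_align("ACGT", "ACGA", sch)
  expect_equal(aln$n_aligned_cols, 4L)
  expect_equal(aln$n_identical, 3L)
  expect_equal(aln$score, 3 * 5 - 4)
  expect_equal(percent_identity(aln), 75.0)
  expect_error(global_align("ACGT", "ACGU", sch), "alphabet")
})

test_that("alignment score is symmetric in its arguments", {
  sch <- scoring_scheme("nucleotide")
  set.seed(13)
  for (i in 1:100) {
    a <- random_dna(sample(5:30, 1))
    b <- random_dna(sample(5:30, 1))
    expect_equal(global_align(a, b, sch)$score,
                 global_align(b, a, sch)$score)
  }
})

test_that("affine alignment reduces to the linear-gap DP when open == extend", {
  set.seed(29)
  for (g in c(2, 5)) {
    sch <- scoring_scheme("nucleotide", match = 5, mismatch = -4,
                          gap_open = g, gap_extend = g)
    for (i in 1:100) {
      a <- random_dna(sample(3:30, 1))
      b <- random_dna(sample(3:30, 1))
      expect_equal(global_align(a, b, sch)$score,
                   oracle_nw_linear(a, b, 5, -4, g),
                   info = paste("gap", g, "iter", i))
    }
  }
})

test_that("identity denominators follow their declared conventions", {
  sch <- scoring_scheme("nucleotide")
  aln <- global_align("ACGTACGT", "ACGT", sch)
  expect_equal(aln$n_identical, 4L)
  expect_equal(percent_identity(aln, "aligned"), 100.0)
  expect_equal(percent_identity(aln, "shorter"), 100.0)
  expect_equal(percent_identity(aln, "full"), 50.0)
})

test_that("identity matrices are symmetric and permutation-consistent", {
  set.seed(17)
  seqs <- c(x = random_dna(60), y = random_dna(60), z = random_dna(60))
  m <- build_identity_matrix(nt_seqs = seqs)
  expect_true(validate_identity_matrix(m))
  expect_equal(m$nt["x", "y"], m$nt["y", "x"])
  twin <- build_identity_matrix(nt_seqs = c(a = seqs[["x"]],
                                            b = seqs[["x"]]))
  expect_equal(twin$nt["a", "b"], 100.0)
  perm <- build_identity_matrix(nt_seqs = seqs[c("z", "x", "y")])
  expect_equal(perm$nt[m$labels, m$labels], m$nt)
  expect_error(build_identity_matrix(aa_seqs = c(a = "MKL"),
                                     nt_seqs = c(b = "ATG")), "missing")
})

test_that("the packaged RdRP identity table parses per the journal convention", {
  m <- parse_identity_table(inlv1_identity_table_path())
  expect_equal(m$labels[1:3], c("INLV1", "BARV-1", "HVLV-4"))
  expect_length(m$labels, 18L)
  expect_true(validate_identity_matrix(m))
  # upper triangle = amino acid, lower = nucleotide
  expect_equal(m$aa["INLV1", "BARV-1"], 77.2)
  expect_equal(m$nt["INLV1", "BARV-1"], 69.2)
  expect_equal(m$aa["INLV1", "HVLV-4"], 76.3)
  expect_equal(m$nt["INLV1", "HVLV-4"], 69.0)
  expect_equal(unname(diag(m$aa)), rep(100, 18))
  # genus-level block structure: Centivirus members resemble each other
  # more than any of them resembles a Sandewavirus
  cent <- c("INLV1", "BARV-1", "HVLV-4", "WHCV-1", "WhIV-8")
  sand <- c("SVD1", "TANAV", "BUSV")
  intra <- m$aa[cent, cent][upper.tri(diag(5))]
  cross <- m$aa[cent, sand]
  expect_gt(min(intra), max(cross))
})

test_that("neighbor joining recovers additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    d <- ape::cophenetic.phylo(tr)
    d <- d / (max(d) * 1.25)           # distances in (0, 0.8]
    m <- 100 * (1 - d)
    diag(m) <- 100
    est <- nj_tree(m, "aa")
    expect_equal(phangorn::RF.dist(est, tr), 0, info = paste("iter", i))
  }
})

test_that("three taxa yield the unique star with additive branch lengths", {
  m <- matrix(100, 3, 3, dimnames = list(c("a", "b", "c"),
                                         c("a", "b", "c")))
  m["a", "b"] <- m["b", "a"] <- 90    # d(ab) = 0.10
  m["a", "c"] <- m["c", "a"] <- 80    # d(ac) = 0.20
  m["b", "c"] <- m["c", "b"] <- 86    # d(bc) = 0.14
  tr <- nj_tree(m, "aa")
  expect_equal(ape::Ntip(tr), 3L)
  dm <- ape::cophenetic.phylo(tr)
  expect_equal(dm["a", "b"], 0.10, tolerance = 1e-9)
  expect_equal(dm["a", "c"], 0.20, tolerance = 1e-9)
  expect_equal(dm["b", "c"], 0.14, tolerance = 1e-9)
})

test_that("NJ on the published aa identities groups INLV1 with its clade", {
  m <- parse_identity_table(inlv1_identity_table_path())
  tr <- nj_tree(m, "aa")
  expect_setequal(tr$tip.label, m$labels)
  clade <- smallest_clade_tips(tr, "INLV1")
  expect_true(any(c("BARV-1", "HVLV-4") %in% clade))
  p <- tempfile(fileext = ".nwk")
  write_newick(tr, p)
  back <- ape::read.tree(p)
  expect_setequal(back$tip.label, m$labels)
})
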
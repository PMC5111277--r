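test_that("fisher_z is atanh with clipping at the boundary", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3)) # independent closed form
  r <- seq(-0.99, 0.99, length.out = 100)
  expect_equal(fisher_z(-r), -fisher_z(r)) # odd function
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_true(is.finite(z1))
})

test_that("z variance is 1/(n-3), inflated by 1.06 for Spearman", {
  expect_equal(z_variance(103, "pearson"), 0.01)
  expect_equal(z_variance(103, "spearman"), 0.0106)
  expect_equal(z_variance(4, "pearson"), 1)
  expect_error(z_variance(3, "pearson"), "at least 4 samples")
})

test_that("pair_diff_z standardizes the z difference, second minus first", {
  eq <- pair_diff_z(0.3, 50, 0.3, 50)
  expect_equal(eq$dz, 0)
  expect_equal(eq$p, 1)

  # hand evaluation: atanh(0.5)/sqrt(2/50) and the normal tail
  res <- pair_diff_z(0.5, 53, 0, 53)
  expect_equal(res$dz, -atanh(0.5) / sqrt(2 / 50), tolerance = 1e-12)
  expect_equal(res$dz, -2.7465, tolerance = 1e-4)
  expect_equal(res$p, 0.0060, tolerance = 5e-3)
  expect_equal(res$p, 2 * (1 - pnorm(abs(res$dz))), tolerance = 1e-12)
})

test_that("published per-pair statistics reproduce from printed inputs", {
  # Spearman correlations and per-condition sample sizes as reported for
  # the reference analyses; z-scores must match to within 1% (3-decimal inputs).
  expect_equal(pair_diff_z(-0.076, 816, 0.628, 27, "spearman")$dz,
               3.816, tolerance = 0.01)
  expect_equal(pair_diff_z(-0.012, 816, 0.627, 27, "spearman")$dz,
               3.511, tolerance = 0.01)
  # positive-sign restriction clamps the negative r1 to 0 first
  expect_equal(pair_diff_z(-0.027, 590, 0.227, 254, "spearman", "positive")$dz,
               2.97, tolerance = 0.01)
  expect_equal(pair_diff_z(0.019, 590, 0.227, 254, "spearman", "positive")$dz,
               2.73, tolerance = 0.01)
  expect_equal(pair_diff_z(0.057, 590, 0.252, 254, "spearman", "positive")$dz,
               2.58, tolerance = 0.01)
  expect_equal(pair_diff_z(0.257, 590, 0.01, 254, "spearman", "positive")$dz,
               -3.25, tolerance = 0.01)
})

test_that("sign_type clamps coefficients symmetrically", {
  pos <- pair_diff_z(-0.4, 100, 0.3, 100, sign_type = "positive")
  expect_equal(pos$dz, pair_diff_z(0, 100, 0.3, 100)$dz)
  neg <- pair_diff_z(0.4, 100, -0.3, 100, sign_type = "negative")
  expect_equal(neg$dz, pair_diff_z(0, 100, -0.3, 100)$dz)
})

test_that("swapping conditions negates dz and keeps p_diff", {
  set.seed(14)
  for (i in 1:20) {
    r1 <- runif(1, -0.9, 0.9); r2 <- runif(1, -0.9, 0.9)
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    a <- pair_diff_z(r1, n1, r2, n2)
    b <- pair_diff_z(r2, n2, r1, n1)
    expect_equal(a$dz, -b$dz)
    expect_equal(a$p, b$p)
  }
})

test_that("|dz| is monotone in |z1 - z2| for equal n", {
  z2 <- atanh(seq(0.1, 0.9, by = 0.1))
  dz <- pair_diff_z(rep(0, 9), 50, tanh(z2), 50)$dz
  expect_true(all(diff(abs(dz)) > 0))
})

test_that("classification covers the nine classes and ignores the dz test", {
  expect_equal(classify_pair(0.257, 2e-10, 0.01, 0.87), "+/0")
  expect_equal(classify_pair(-0.076, 0.03, 0.628, 4e-4), "-/+")
  expect_equal(classify_pair(0, 1, 0, 1), "0/0")
  expect_equal(classify_pair(-0.5, 0.001, -0.6, 0.002), "-/-")
  expect_equal(classify_pair(NA, NA, 0.5, 0.01), "NA")
  # alpha is the class threshold: p = 0.04 flips at alpha 0.05 vs 0.01
  expect_equal(classify_pair(0.3, 0.04, 0, 1, alpha = 0.05), "+/0")
  expect_equal(classify_pair(0.3, 0.04, 0, 1, alpha = 0.01), "0/0")
})

test_that("ddcor on identical conditions returns all-zero dz", {
  fx <- two_condition_fixture(5, 20, seed = 31)
  res <- ddcor(fx$expr, fx$design, c("A", "B"), adjust = "none")
  expect_tbl_ddcor(res)
  expect_equal(nrow(res), choose(5, 2))
  expect_equal(res$dz, rep(0, nrow(res)))
  expect_equal(res$p_diff, rep(1, nrow(res)))
  # symmetric classes: condition halves agree
  halves <- strsplit(res$class, "/")
  expect_true(all(vapply(halves, function(h) h[1] == h[2], logical(1))))
})

test_that("a planted differential pair ranks first by |dz|", {
  fx <- planted_pair_fixture(10, 100, rho = 0.8, seed = 41)
  res <- ddcor(fx$expr, fx$design, c("A", "B"), adjust = "none")
  expect_setequal(c(res$gene_a[1], res$gene_b[1]), c("G1", "G2"))
  expect_lt(res$dz[1], 0) # loss of correlation in B
})

test_that("split_gene restricts to one-vs-all pairs", {
  fx <- two_condition_fixture(10, 15, seed = 8)
  res <- ddcor(fx$expr, fx$design, c("A", "B"), adjust = "none", split_gene = "G1")
  expect_equal(nrow(res), 9)
  expect_true(all(res$gene_a == "G1"))
  expect_error(
    ddcor(fx$expr, fx$design, c("A", "B"), split_gene = "nope"),
    "not found"
  )
})

test_that("condition swap negates dz across the whole table", {
  fx <- planted_pair_fixture(6, 40, rho = 0.7, seed = 13)
  a <- ddcor(fx$expr, fx$design, c("A", "B"), adjust = "none")
  b <- ddcor(fx$expr, fx$design, c("B", "A"), adjust = "none")
  key <- function(x) paste(x$gene_a, x$gene_b)
  b <- b[match(key(a), key(b)), ]
  expect_equal(a$dz, -b$dz)
  expect_equal(a$p_diff, b$p_diff)
})

test_that("the table is sorted by |dz| with lexicographic tie-break", {
  fx <- two_condition_fixture(6, 25, seed = 77)
  res <- ddcor(fx$expr, fx$design, c("A", "B"), adjust = "none")
  expect_true(all(diff(abs(res$dz)) <= 1e-15))
  # identical-condition fixture: every dz ties at 0, order is lexicographic
  fx0 <- two_condition_fixture(4, 10, seed = 78)
  res0 <- ddcor(fx0$expr, fx0$design, c("A", "B"), adjust = "none")
  expect_identical(res0$gene_a, sort(res0$gene_a))
})

test_that("the TSV writer mirrors the published column layout", {
  fx <- planted_pair_fixture(10, 30, rho = 0.8, seed = 55)
  res <- ddcor(fx$expr, fx$design, c("A", "B"), n_perm = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ddcor(res, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("GeneA", "GeneB", "Cor1", "pVal1", "Cor2", "pVal2",
                              "zScoreDiff", "pValDiff", "empPVal", "qValue", "Classes"))
  expect_true("NonSig" %in% back$Classes || all(res$sig))
})

test_that("glance and tidy summarize a result table", {
  fx <- planted_pair_fixture(10, 50, rho = 0.8, seed = 19)
  res <- ddcor(fx$expr, fx$design, c("A", "B"), n_perm = 5, seed = 2)
  g <- glance(res)
  expect_equal(g$n_pairs, choose(10, 2))
  expect_equal(g$n_sig, sum(res$sig))
  expect_true(g$pi0 > 0 && g$pi0 <= 1)
  td <- tidy(res)
  expect_false(inherits(td, "tbl_ddcor"))
  expect_equal(nrow(td), nrow(res))
})
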
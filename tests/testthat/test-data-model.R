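test_that("expression files round-trip bit-identically", {
  expr <- toy_expr(3, 4)
  expr$s2[2] <- NA # one missing cell
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, path)
  back <- read_expression(path)
  expect_identical(back$gene, expr$gene)
  expect_identical(as.matrix(back[-1]), as.matrix(expr[-1]))
  expect_equal(sum(is.na(back[-1])), 1)
})

test_that("malformed expression files are hard errors naming the offender", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "G1\t1\t2", "G1\t3\t4"), path)
  expect_error(read_expression(path), "G1")

  writeLines(c("gene\ts1\ts2", "G1\t1\tx", "G2\t3\t4"), path)
  expect_error(read_expression(path), "s2")
})

test_that("design round-trips and can be built from labels", {
  d <- design_from_labels(paste0("s", 1:6), rep(c("A", "B"), each = 3))
  expect_equal(names(d), c("sample", "A", "B"))
  expect_equal(colSums(d[-1]), c(A = 3, B = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(d, path)
  expect_equal(as.data.frame(read_design(path)), as.data.frame(d))
})

test_that("GMT files parse into named sets with categories", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tBP\tG1\tG2\tG3", "setB\tMF\tG2\tG4"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("setA", "setB"))
  expect_equal(sets$setB, c("G2", "G4"))
  expect_equal(unname(attr(sets, "category")), c("BP", "MF"))
  writeLines("broken\tBP", path)
  expect_error(read_gmt(path), "fewer than 3")
})

test_that("zero percentiles leave the matrix untouched", {
  expr <- toy_expr(5, 6)
  expect_equal(filter_genes(expr, central_pct = 0, dispersion_pct = 0), expr,
               ignore_attr = TRUE)
})

test_that("central-tendency filter removes the genes below the quantile", {
  # 8 genes with medians 1..8; bottom 25% quantile (linear interpolation)
  # sits at 2.75, so exactly the 2 lowest-median genes go.
  set.seed(42)
  m <- matrix(rep(1:8, each = 10) + runif(80, -0.1, 0.1), nrow = 8,
              dimnames = list(paste0("G", 1:8), paste0("s", 1:10)))
  meds <- apply(m, 1, median)
  cut <- quantile(meds, 0.25, names = FALSE) # independent brute-force cutoff
  expected_kept <- names(meds)[meds >= cut]
  out <- filter_genes(m, central_pct = 0.25, dispersion_pct = 0)
  expect_identical(rownames(out), expected_kept)
  expect_equal(nrow(out), 6)
})

test_that("constant genes have dispersion index zero and are removed", {
  set.seed(7)
  m <- rbind(
    const = rep(5, 20),
    matrix(rnorm(5 * 20, mean = 10), nrow = 5,
           dimnames = list(paste0("G", 1:5), NULL))
  )
  colnames(m) <- paste0("s", 1:20)
  out <- filter_genes(m, dispersion_pct = 0.1)
  expect_false("const" %in% rownames(out))
})

test_that("filtering is idempotent and preserves gene order", {
  set.seed(11)
  m <- matrix(rexp(30 * 12, rate = 1 / 10), nrow = 30,
              dimnames = list(paste0("G", 1:30), paste0("s", 1:12)))
  once <- filter_genes(m, central_pct = 0.25, dispersion_pct = 0.25)
  cuts <- attr(once, "cutoffs")
  # the realized absolute cutoffs make re-application a no-op
  twice <- filter_genes(once, central_cutoff = cuts[["central"]],
                        dispersion_cutoff = cuts[["dispersion"]])
  expect_equal(once, twice)
  expect_identical(rownames(once), intersect(rownames(m), rownames(once)))
})

test_that("union removes genes failing either filter; intersection only both", {
  set.seed(3)
  m <- matrix(rexp(40 * 15, rate = 1 / 10), nrow = 40,
              dimnames = list(paste0("G", 1:40), paste0("s", 1:15)))
  u <- filter_genes(m, central_pct = 0.25, dispersion_pct = 0.25, combine = "union")
  i <- filter_genes(m, central_pct = 0.25, dispersion_pct = 0.25, combine = "intersection")
  expect_true(nrow(u) <= nrow(i))
  expect_true(all(rownames(u) %in% rownames(i)))
})

test_that("genes with non-positive mean are flagged and removed with warning", {
  set.seed(9)
  m <- rbind(
    neg = rnorm(20, mean = -5),
    matrix(rnorm(5 * 20, mean = 10), nrow = 5,
           dimnames = list(paste0("G", 1:5), NULL))
  )
  colnames(m) <- paste0("s", 1:20)
  expect_warning(out <- filter_genes(m, dispersion_pct = 0.1), "neg")
  expect_false("neg" %in% rownames(out))
})

test_that("removing every gene is a hard error", {
  # G1: high median, low spread; G2: low median, high spread -- the union
  # of a median filter and a dispersion filter takes both.
  m <- rbind(G1 = c(100, 100.1, 99.9, 100), G2 = c(1, 5, 9, 2))
  colnames(m) <- paste0("s", 1:4)
  expect_error(
    filter_genes(m, central_pct = 0.5, dispersion_measure = "sd", dispersion_pct = 0.5),
    "all genes"
  )
})
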
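test_that("the blueprint's truth counts obey the counting identities", {
  spec <- build_pair_spec(seed = 1)
  truth <- spec$truth
  expect_equal(nrow(truth), 152)
  expect_equal(sum(truth$is_differential), 114)
  expect_equal(sum(truth$delta_rho == 1), 38)
  expect_equal(sum(truth$is_differential & truth$delta_rho == 0.5), 76)
  expect_equal(n_pair_tests(600), 179700)
  # identities hold for any pairs-per-class k
  for (k in c(1, 5)) {
    tk <- build_pair_spec(seed = 1, pairs_per_class = k)$truth
    expect_equal(nrow(tk), 8 * k)
    expect_equal(sum(tk$is_differential), 6 * k)
    expect_equal(sum(tk$delta_rho == 1), 2 * k)
  }
})

test_that("designated pairs sit on the super-diagonal of the activated block", {
  spec <- build_pair_spec(seed = 2, n_genes = c(60, 10, 20), pairs_per_class = 7)
  ids <- names(spec$means)
  ia <- match(spec$truth$gene_a, ids)
  ib <- match(spec$truth$gene_b, ids)
  expect_true(all(ib == ia + 1))
  expect_true(all(ib <= 60)) # confined to activated genes
  # non-designated off-diagonals are zero in both conditions (up to the
  # tiny positive-definiteness repair)
  s <- spec$sigma$A
  mask <- matrix(TRUE, nrow(s), ncol(s))
  diag(mask) <- FALSE
  mask[cbind(ia, ib)] <- FALSE
  mask[cbind(ib, ia)] <- FALSE
  expect_lt(max(abs(s[mask]) / max(diag(s))), 1e-6)
})

test_that("gene means are negative-binomial draws floored at one", {
  spec <- build_pair_spec(seed = 3)
  expect_true(all(spec$means >= 1))
  expect_length(spec$means, 600)
  expect_equal(as.vector(table(spec$groups)), c(300, 100, 200))
  # silent genes have much lower average expression
  expect_lt(mean(spec$means[spec$groups == "silent"]),
            mean(spec$means[spec$groups == "activated"]) / 5)
})

test_that("sampled correlations match the planted covariance structure", {
  spec <- build_pair_spec(seed = 4)
  smp <- sample_expression(spec, n_samples = 1000, seed = 5)
  m <- as.matrix(smp$expression[-1])
  rownames(m) <- smp$expression$gene
  expect_equal(dim(m), c(600, 2000))
  a_ids <- smp$design$sample[smp$design$A == 1]
  expect_length(a_ids, 1000)
  ra <- cor(t(m[1:170, a_ids]))
  truth <- spec$truth
  plus_a <- truth[truth$rho1 == 0.5, ]
  obs <- ra[cbind(match(plus_a$gene_a, rownames(ra)), match(plus_a$gene_b, rownames(ra)))]
  # sampling distribution of r at n = 1000: sd ~ 0.024 at rho = 0.5
  expect_true(all(obs > 0.42 & obs < 0.58))
  minus_a <- truth[truth$rho1 == -0.5, ]
  obs_m <- ra[cbind(match(minus_a$gene_a, rownames(ra)), match(minus_a$gene_b, rownames(ra)))]
  expect_true(all(obs_m < -0.42 & obs_m > -0.58))
  # a handful of non-designated pairs stay near zero (null r sd ~ 0.032)
  null_pairs <- cbind(seq(155, 165), seq(157, 167))
  expect_true(all(abs(ra[null_pairs]) < 0.12))
})

test_that("sampling is reproducible given a seed", {
  spec <- build_pair_spec(seed = 6, n_genes = c(30, 10, 20), pairs_per_class = 3)
  s1 <- sample_expression(spec, 10, seed = 7)
  s2 <- sample_expression(spec, 10, seed = 7)
  expect_identical(s1$expression, s2$expression)
})

test_that("positive-definite repair floors the spectrum and fixes a 2x2 case", {
  set.seed(8)
  a <- crossprod(matrix(rnorm(25), 5)) + diag(5) # already PD
  expect_equal(repair_positive_definite(a, tolerance = 0), a, tolerance = 1e-10)

  bad <- matrix(c(1, 1.2, 1.2, 1), 2) # eigenvalues 2.2 and -0.2
  rep2 <- repair_positive_definite(bad, tolerance = 0)
  expect_gte(min(eigen(rep2, symmetric = TRUE)$values), 0)
  expect_lt(abs(rep2[1, 2]), 1.2)
  # by hand: truncating the negative eigenvalue gives off-diagonal 1.1
  expect_equal(rep2[1, 2], 1.1, tolerance = 1e-12)

  expect_error(repair_positive_definite(matrix(1:4, 2)), "symmetric")
  # a larger tolerance floors more of the spectrum
  rep3 <- repair_positive_definite(bad, tolerance = 0.4)
  ev <- eigen(rep3, symmetric = TRUE)$values
  expect_gte(min(ev), 0.4 * max(ev) - 1e-10)
})

test_that("module blueprint realizes the kappa fraction of positions", {
  spec1 <- build_module_spec(kappa = 1, seed = 9)
  expect_equal(nrow(spec1$edges), 2 * 29)
  expect_length(spec1$modules, 2)
  expect_true(all(lengths(spec1$modules) == 30))
  expect_length(intersect(spec1$modules[[1]], spec1$modules[[2]]), 0)

  spec5 <- build_module_spec(kappa = 0.5, seed = 10)
  expect_equal(nrow(spec5$edges), 2 * round(0.5 * 29))

  # condition B carries no within-module correlation
  sB <- spec5$sigma$B
  cB <- cov2cor(sB)
  expect_lt(max(abs(cB[upper.tri(cB)])), 1e-8)
  # condition A carries attenuated but clearly positive planted correlations
  cA <- cov2cor(spec5$sigma$A)
  planted <- cA[cbind(match(spec5$edges$gene_a, rownames(cA)),
                      match(spec5$edges$gene_b, rownames(cA)))]
  expect_true(all(planted > 0.05))
  expect_true(all(planted < 0.9)) # attenuation from the eigenvalue floor
})

test_that("module recovery metrics score detections and the fallback", {
  true <- paste0("g", 1:30)
  universe <- paste0("g", 1:600)
  # nothing detected: pseudo-module of all genes, Jaccard 30/600
  none <- module_recovery_metrics(list(), true, universe)
  expect_equal(none$jaccard, 0.05)
  # perfect detection
  hit <- module_recovery_metrics(list(true), true, universe)
  expect_equal(hit$sensitivity, 1)
  expect_equal(hit$jaccard, 1)
  # true module plus 30 extra genes: sensitivity cap excludes it (size 60),
  # Jaccard is 30/60
  big <- module_recovery_metrics(list(c(true, paste0("g", 101:130))), true, universe)
  expect_equal(big$jaccard, 0.5)
  expect_equal(big$sensitivity, 0)
  big2 <- module_recovery_metrics(list(c(true, paste0("g", 101:130))), true, universe,
                                  max_size_for_sensitivity = 100)
  expect_equal(big2$sensitivity, 1)
})

test_that("roc_auc is the Mann-Whitney concordance with half-ties", {
  expect_equal(roc_auc(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0)), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(TRUE, FALSE, FALSE)), 0)
  expect_equal(roc_auc(c(2, 2), c(TRUE, FALSE)), 0.5)
  set.seed(20)
  scores <- rnorm(10000)
  truth <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  expect_equal(roc_auc(scores, truth), 0.5, tolerance = 0.02)
  expect_equal(roc_auc(scores, truth) + roc_auc(-scores, truth), 1)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "at least one")
})
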
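# Fixtures are generated in code at test time; no data files.

# Small deterministic expression tibble: values are a fixed arithmetic
# pattern so medians/variances are easy to enumerate by hand.
toy_expr <- function(n_genes = 3, n_samples = 4) {
  m <- matrix(as.numeric(seq_len(n_genes * n_samples)), nrow = n_genes,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  tibble::as_tibble(m, rownames = "gene")
}

# Two-condition dataset where condition B applies `transform` to the same
# latent samples as condition A (e.g. identity, or per-gene negation).
two_condition_fixture <- function(n_genes, n_samples, seed,
                                  transform = identity) {
  set.seed(seed)
  a <- matrix(rnorm(n_genes * n_samples), nrow = n_genes)
  b <- transform(a)
  m <- cbind(a, b)
  rownames(m) <- paste0("G", seq_len(n_genes))
  colnames(m) <- paste0("s", seq_len(2 * n_samples))
  list(
    expr = m,
    design = design_from_labels(colnames(m), rep(c("A", "B"), each = n_samples))
  )
}

# No-signal fixture: both conditions iid from the same distribution.
null_fixture <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_samples), nrow = n_genes)
  rownames(m) <- paste0("G", seq_len(n_genes))
  colnames(m) <- paste0("s", seq_len(2 * n_samples))
  list(
    expr = m,
    design = design_from_labels(colnames(m), rep(c("A", "B"), each = n_samples))
  )
}

# Fixture with one planted pair: G1-G2 correlated (rho) in condition A,
# independent in condition B; all other genes iid noise.
planted_pair_fixture <- function(n_genes, n_samples, rho, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n_genes * n_samples), nrow = n_genes)
  a[2, ] <- rho * a[1, ] + sqrt(1 - rho^2) * a[2, ]
  b <- matrix(rnorm(n_genes * n_samples), nrow = n_genes)
  m <- cbind(a, b)
  rownames(m) <- paste0("G", seq_len(n_genes))
  colnames(m) <- paste0("s", seq_len(2 * n_samples))
  list(
    expr = m,
    design = design_from_labels(colnames(m), rep(c("A", "B"), each = n_samples))
  )
}

expect_tbl_ddcor <- function(res) {
  expect_s3_class(res, "tbl_ddcor")
  expect_true(all(c("gene_a", "gene_b", "r1", "p1", "r2", "p2",
                    "dz", "p_diff", "class", "sig") %in% names(res)))
}
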
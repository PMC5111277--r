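# Gene ids g001, g002, ... padded to a fixed width.
gene_ids <- function(n) sprintf("g%0*d", max(3L, nchar(n)), seq_len(n))

# Per-condition correlation targets for each of the 8 planted classes.
# The first symbol is condition A (first-listed), the second condition B.
planted_classes <- c("+/0", "0/+", "-/0", "0/-", "+/-", "-/+", "+/+", "-/-")

class_rho <- function(class, base_rho) {
  sym <- strsplit(class, "/", fixed = TRUE)
  to_rho <- function(s) switch(s, "+" = base_rho, "-" = -base_rho, "0" = 0)
  list(
    rho1 = vapply(sym, function(x) to_rho(x[1]), numeric(1)),
    rho2 = vapply(sym, function(x) to_rho(x[2]), numeric(1))
  )
}

#' Build the pair-level simulation blueprint with ground truth
#'
#' Constructs the structured two-condition covariance benchmark: 600 genes
#' (by default) in three expression groups -- 300 "activated" genes with
#' high mean and high dispersion, 100 "housekeeping" genes with high mean
#' and halved dispersion, and 200 "silent" genes with low mean -- with
#' per-gene means drawn from a negative binomial (dispersion 0.5; means
#' below 1 raised to 1) and per-gene variance mu + d * mu^2. For each of
#' the 8 differential correlation classes that plant a signal
#' (`"+/0"`, `"0/+"`, `"-/0"`, `"0/-"`, `"+/-"`, `"-/+"`, `"+/+"`,
#' `"-/-"`), `pairs_per_class` consecutive
#' super-diagonal positions among the activated genes receive covariance
#' +/- `base_rho` * sqrt(var_i * var_j) per condition; all other
#' off-diagonals are zero. Classes `"+/+"` and `"-/-"` plant equal
#' correlations in both conditions and are therefore not differential: with
#' the default 19 pairs per class the blueprint designates 152 pairs of
#' which 114 are truly differential, 38 with a strong difference
#' (|delta rho| = 1) and 76 with a medium difference (|delta rho| = 0.5).
#' Each condition's correlation structure is passed through
#' [repair_positive_definite()] (relative tolerance 1e-8) on the
#' correlation scale, renormalized to unit diagonal, and then scaled by the
#' per-gene variances.
#'
#' @param seed Optional integer seed.
#' @param n_genes Integer vector of the three group sizes
#'   (activated, housekeeping, silent); default `c(300, 100, 200)`.
#' @param pairs_per_class Designated pairs per class (default 19). Needs
#'   `8 * pairs_per_class + 1` activated genes.
#' @param base_rho Magnitude of the planted correlations (default 0.5).
#' @param nb_dispersion Dispersion of the negative binomial that the gene
#'   means are drawn from (default 0.5).
#' @param mu_expressed,mu_silent Negative-binomial location for the
#'   expressed (activated + housekeeping) and silent groups; defaults 100
#'   and 5.
#' @param dispersion Per-group variance parameter d in var = mu + d * mu^2,
#'   named vector for (activated, housekeeping, silent); default
#'   `c(0.5, 0.25, 0.5)` ("one-fold lower" dispersion for housekeeping).
#' @return A list of class `"pair_sim_spec"`: `means` (named per-gene
#'   means), `sigma` (list of the two repaired covariance matrices),
#'   `groups` (gene group factor), `truth` (tibble: `gene_a`, `gene_b`,
#'   `class`, `rho1`, `rho2`, `delta_rho`, `is_differential`), and the
#'   parameters.
#' @seealso [sample_expression()], [simulate_pair_benchmark()]
#' @export
build_pair_spec <- function(seed = NULL,
                            n_genes = c(300, 100, 200),
                            pairs_per_class = 19,
                            base_rho = 0.5,
                            nb_dispersion = 0.5,
                            mu_expressed = 100,
                            mu_silent = 5,
                            dispersion = c(0.5, 0.25, 0.5)) {
  stopifnot(length(n_genes) == 3, length(dispersion) == 3, pairs_per_class >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_act <- n_genes[1]
  n_total <- sum(n_genes)
  n_designated <- 8 * pairs_per_class
  if (n_act < n_designated + 1) {
    abort("need at least 8 * pairs_per_class + 1 activated genes")
  }

  ids <- gene_ids(n_total)
  groups <- factor(rep(c("activated", "housekeeping", "silent"), n_genes),
                   levels = c("activated", "housekeeping", "silent"))
  mu_group <- rep(c(mu_expressed, mu_expressed, mu_silent), n_genes)
  means <- rnbinom(n_total, mu = mu_group, size = 1 / nb_dispersion)
  means <- pmax(means, 1)
  names(means) <- ids
  d <- rep(dispersion, n_genes)
  vars <- means + d * means^2

  classes <- rep(planted_classes, each = pairs_per_class)
  i <- seq_len(n_designated) # super-diagonal positions (i, i + 1), activated block
  rho <- class_rho(classes, base_rho)
  truth <- tibble::tibble(
    gene_a = ids[i], gene_b = ids[i + 1], class = classes,
    rho1 = rho$rho1, rho2 = rho$rho2,
    delta_rho = abs(rho$rho1 - rho$rho2),
    is_differential = !classes %in% c("+/+", "-/-")
  )

  build_sigma <- function(rho_vec) {
    corr <- diag(n_total)
    corr[cbind(i, i + 1)] <- rho_vec
    corr[cbind(i + 1, i)] <- rho_vec
    dimnames(corr) <- list(ids, ids)
    scale_correlation(corr, vars, tolerance = 1e-8)
  }

  structure(
    list(
      means = means, groups = groups,
      sigma = list(A = build_sigma(rho$rho1), B = build_sigma(rho$rho2)),
      truth = truth,
      params = list(
        n_genes = n_genes, pairs_per_class = pairs_per_class,
        base_rho = base_rho, nb_dispersion = nb_dispersion,
        mu_expressed = mu_expressed, mu_silent = mu_silent,
        dispersion = dispersion
      )
    ),
    class = "pair_sim_spec"
  )
}

#' Sample multivariate-normal expression matrices from a simulation spec
#'
#' Draws `n_samples` samples per condition from MVN(means, sigma_condition)
#' and assembles the combined expression tibble and matching design.
#'
#' @param spec A `"pair_sim_spec"` ([build_pair_spec()]) or
#'   `"module_sim_spec"` ([build_module_spec()]) object.
#' @param n_samples Samples per condition (>= 4).
#' @param seed Optional integer seed.
#' @return A list with `expression` (tibble, genes x 2 * n_samples) and
#'   `design` (tibble; conditions `"A"` and `"B"`).
#' @export
sample_expression <- function(spec, n_samples, seed = NULL) {
  stopifnot(n_samples >= 4)
  if (!is.null(seed)) set.seed(seed)
  draws <- purrr::imap(spec$sigma, function(sig, cond) {
    x <- t(MASS::mvrnorm(n_samples, mu = spec$means, Sigma = sig))
    colnames(x) <- paste0(cond, "_", seq_len(n_samples))
    x
  })
  m <- do.call(cbind, draws)
  design <- design_from_labels(colnames(m), rep(names(spec$sigma), each = n_samples))
  list(expression = expr_as_tibble(m), design = design)
}

#' One-call pair-level benchmark dataset
#'
#' Convenience wrapper: builds the blueprint and samples expression in one
#' reproducible step.
#'
#' @inheritParams sample_expression
#' @param seed Optional integer seed covering both spec construction and
#'   sampling.
#' @param ... Passed to [build_pair_spec()].
#' @return A list with `expression`, `design`, `truth` and `spec`.
#' @export
simulate_pair_benchmark <- function(n_samples, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  spec <- build_pair_spec(seed = NULL, ...)
  smp <- sample_expression(spec, n_samples, seed = NULL)
  list(expression = smp$expression, design = smp$design,
       truth = spec$truth, spec = spec)
}

# Repair a correlation matrix on its own scale, renormalize to unit
# diagonal, then scale by the per-gene variances. Repairing before scaling
# keeps the relative eigenvalue floor meaningful: applied to the
# covariance directly, the floor would be dominated by the most variable
# gene and erase the planted structure.
scale_correlation <- function(corr, vars, tolerance) {
  repaired <- repair_positive_definite(corr, tolerance = tolerance)
  d <- sqrt(diag(repaired))
  repaired <- repaired / tcrossprod(d) # back to unit diagonal
  s <- sqrt(vars)
  out <- repaired * tcrossprod(s)
  dimnames(out) <- dimnames(corr)
  out
}

#' Repair a symmetric matrix to (semi-)positive definiteness
#'
#' Eigendecomposes the matrix, raises every eigenvalue below
#' `tolerance * max(eigenvalue)` to that floor, and reconstructs. With
#' `tolerance = 0` this is the minimal repair (negative eigenvalues
#' truncated at zero); larger tolerances deliberately flatten the low end
#' of the spectrum, which attenuates the realized correlations -- the
#' module benchmark exploits this with tolerance 0.4 and compensates by
#' planting correlations of 0.9.
#'
#' @param m Symmetric numeric matrix.
#' @param tolerance Relative eigenvalue floor in `[0, 1)`.
#' @return A symmetric matrix with minimum eigenvalue >= 0.
#' @export
repair_positive_definite <- function(m, tolerance = 0) {
  if (!isSymmetric(m, tol = 1e-8)) abort("matrix must be symmetric")
  stopifnot(tolerance >= 0, tolerance < 1)
  e <- eigen(m, symmetric = TRUE)
  floor_val <- max(tolerance * max(e$values), 0)
  ev <- pmax(e$values, floor_val)
  out <- e$vectors %*% (ev * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  out
}

#' Build the module-level simulation blueprint
#'
#' Plants `n_modules` disjoint modules of `module_size` genes each among
#' the activated genes. Within each module, a fraction `kappa` (the
#' network connectivity) of the super-diagonal positions -- chosen
#' uniformly at random, `round(kappa * (module_size - 1))` of them -- carry
#' correlation `rho_within` in condition A and none in condition B. Each
#' condition's correlation matrix goes through
#' [repair_positive_definite()] with `pd_tolerance` (default 0.4) before
#' scaling by the gene variances; the aggressive eigenvalue floor
#' deliberately attenuates the realized correlations, and
#' `rho_within = 0.9` compensates. Means, variances and gene groups are
#' built exactly as in [build_pair_spec()].
#'
#' @param kappa Fraction of within-module super-diagonal positions that are
#'   correlated in condition A, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param n_genes Group sizes as in [build_pair_spec()].
#' @param module_size Genes per module (default 30).
#' @param n_modules Number of disjoint modules (default 2).
#' @param rho_within Planted within-module correlation (default 0.9).
#' @param pd_tolerance Relative eigenvalue floor for the repair
#'   (default 0.4).
#' @inheritParams build_pair_spec
#' @return A list of class `"module_sim_spec"`: `means`, `groups`, `sigma`
#'   (two repaired covariance matrices), `modules` (list of gene-id
#'   vectors), `edges` (tibble of the realized correlated positions:
#'   `gene_a`, `gene_b`, `module`), and the parameters.
#' @export
build_module_spec <- function(kappa, seed = NULL,
                              n_genes = c(300, 100, 200),
                              module_size = 30, n_modules = 2,
                              rho_within = 0.9, pd_tolerance = 0.4,
                              nb_dispersion = 0.5,
                              mu_expressed = 100, mu_silent = 5,
                              dispersion = c(0.5, 0.25, 0.5)) {
  stopifnot(kappa >= 0, kappa <= 1, module_size >= 2, n_modules >= 1)
  if (n_genes[1] < module_size * n_modules) {
    abort("not enough activated genes to host the modules")
  }
  if (!is.null(seed)) set.seed(seed)
  n_total <- sum(n_genes)
  ids <- gene_ids(n_total)
  groups <- factor(rep(c("activated", "housekeeping", "silent"), n_genes),
                   levels = c("activated", "housekeeping", "silent"))
  mu_group <- rep(c(mu_expressed, mu_expressed, mu_silent), n_genes)
  means <- pmax(rnbinom(n_total, mu = mu_group, size = 1 / nb_dispersion), 1)
  names(means) <- ids
  d <- rep(dispersion, n_genes)
  vars <- means + d * means^2

  modules <- purrr::map(seq_len(n_modules), function(k) {
    ids[((k - 1) * module_size + 1):(k * module_size)]
  })
  n_pos <- module_size - 1
  n_sel <- round(kappa * n_pos)
  edges <- purrr::imap(modules, function(mod, k) {
    start <- (k - 1) * module_size
    pos <- sort(sample.int(n_pos, n_sel))
    tibble::tibble(gene_a = ids[start + pos], gene_b = ids[start + pos + 1], module = k)
  })
  edges <- dplyr::bind_rows(edges)

  cA <- diag(n_total)
  dimnames(cA) <- list(ids, ids)
  ia <- match(edges$gene_a, ids)
  ib <- match(edges$gene_b, ids)
  cA[cbind(ia, ib)] <- rho_within
  cA[cbind(ib, ia)] <- rho_within
  cB <- diag(n_total)
  dimnames(cB) <- list(ids, ids)

  structure(
    list(
      means = means, groups = groups,
      sigma = list(
        A = scale_correlation(cA, vars, tolerance = pd_tolerance),
        B = scale_correlation(cB, vars, tolerance = pd_tolerance)
      ),
      modules = modules, edges = edges,
      params = list(
        kappa = kappa, n_genes = n_genes, module_size = module_size,
        n_modules = n_modules, rho_within = rho_within,
        pd_tolerance = pd_tolerance
      )
    ),
    class = "module_sim_spec"
  )
}

#' One-call module-level benchmark dataset
#'
#' @inheritParams sample_expression
#' @param kappa Network connectivity, passed to [build_module_spec()].
#' @param seed Optional integer seed covering spec construction and
#'   sampling.
#' @param ... Passed to [build_module_spec()].
#' @return A list with `expression`, `design`, `modules` and `spec`.
#' @export
simulate_module_benchmark <- function(kappa, n_samples, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  spec <- build_module_spec(kappa, seed = NULL, ...)
  smp <- sample_expression(spec, n_samples, seed = NULL)
  list(expression = smp$expression, design = smp$design,
       modules = spec$modules, spec = spec)
}
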
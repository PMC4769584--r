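sim_small <- function(seed = 5, n = 150, m = 200, qtl = c(6, 2, 1)) {
  cfg <- sim_config(n_per_pop = c(n), n_variants = m, n_candidate_genes = 8,
                    gene_size = 6, gene_window = 3, n_qtl_per_tier = qtl,
                    enrichment_scheme = "uniform", seed = seed)
  gs <- sim_genotypes(cfg)
  g <- filter_maf(gs$genotypes, 0.01)
  cl <- sim_classes(g, cfg)
  tr <- sim_qtl(g, cl, cfg)
  ph <- sim_phenotypes(g, tr, cfg, gs$population)
  list(W = standardize_genotypes(g), pheno = ph$pheno, truth = tr, g = g)
}

test_that("Dirichlet proportion draws have the conjugate mean", {
  set.seed(1)
  draws <- t(replicate(10000, sample_mixture_proportions(c(996, 2, 1, 1))))
  expect_true(all(abs(rowMeans(t(draws)) - c(997, 3, 2, 2) / 1004) < 0.01))
  expect_true(all(abs(rowSums(draws) - 1) < 1e-12))
  prior <- t(replicate(5000, sample_mixture_proportions(c(0, 0, 0, 0))))
  expect_true(all(abs(colMeans(prior) - 0.25) < 0.02))
  expect_error(sample_mixture_proportions(c(-1, 0, 0, 0)), "negative")
})

test_that("single-class BayesRC and BayesR give identical chains under one seed", {
  d <- sim_small()
  one_class <- variant_classes(d$W$map$id, rep("all", ncol(d$W$W)))
  frc <- bayesrc_fit(d$pheno, d$W, one_class, n_iter = 300, burn_in = 100,
                     n_chains = 2, seed = 7)
  fr <- bayesr_fit(d$pheno, d$W, n_iter = 300, burn_in = 100,
                   n_chains = 2, seed = 7)
  expect_identical(frc$vbar, fr$vbar)
  expect_identical(frc$pip, fr$pip)
  expect_identical(frc$P, fr$P)
  expect_identical(frc$sigma2_e, fr$sigma2_e)
})

test_that("null data drive the null-component proportion toward one", {
  # with an informative effect scale (sigma2_g on the order the analyst
  # expects for a real trait), noise-only data must concentrate every
  # class's mixture on the null component
  # (classes above the ~1000-variant guidance, so the symmetric Dirichlet
  # prior does not cap the null proportion below the threshold)
  set.seed(2)
  cfg <- sim_config(n_per_pop = c(800), n_variants = 2100,
                    n_candidate_genes = 20, gene_size = 6, gene_window = 3,
                    n_qtl_per_tier = c(0, 0, 0), heritability = 1, seed = 9)
  gs <- sim_genotypes(cfg)
  g <- filter_maf(gs$genotypes, 0.01)
  W <- standardize_genotypes(g)
  ph <- phenotype_table(rnorm(800))  # pure noise
  cl <- variant_classes(W$map$id, rep(c("A", "B"), length.out = ncol(W$W)))
  fit <- bayesrc_fit(ph, W, cl, n_iter = 2000, burn_in = 1000, n_chains = 1,
                     seed = 3, spec = mixture_spec(sigma2_g = 50))
  expect_true(all(fit$P[, 1] > 0.95))
})

test_that("degenerate proportions pin every variant to the null component", {
  d <- sim_small()
  C1 <- matrix(c(1, 0, 0, 0), 1, 4)
  fit <- bayesr_fit(d$pheno, d$W, n_iter = 200, burn_in = 100, n_chains = 1,
                    seed = 1, options = list(fix_p = TRUE, P0 = C1))
  expect_true(all(fit$pip == 0))
  expect_true(all(fit$vbar == 0))
})

test_that("zero-signal symmetry: orthogonal residual favours the null component", {
  # a single variant orthogonal to y: posterior null probability must exceed
  # the flat prior 0.25
  set.seed(4)
  n <- 200
  x <- rnorm(n)
  y <- rnorm(n)
  y <- resid(lm(y ~ x))  # exactly orthogonal
  W <- matrix((x - mean(x)) / sd(x), ncol = 1, dimnames = list(NULL, "v1"))
  ph <- phenotype_table(y)
  fit <- suppressWarnings(
    bayesr_fit(ph, W, n_iter = 2000, burn_in = 500, n_chains = 1,
               seed = 2, spec = mixture_spec(sigma2_g = 50),
               options = list(fix_p = TRUE, P0 = matrix(0.25, 1, 4))))
  # the null component is modal: its occupancy exceeds every other
  # component's (with equal priors and r = 0 all non-null components are
  # log-penalized by -log(1 + tau s)/2, so they sit strictly below it)
  expect_gt(fit$beta[1, 1] / sum(fit$beta), 0.25)
  expect_equal(which.max(fit$beta[1, ]), 1L)
})

test_that("component posterior matches numerical integration on one variant", {
  # exact one-variant marginal likelihood by quadrature, vs the chain's
  # empirical component frequencies
  set.seed(11)
  n <- 50
  x <- scale(rbinom(n, 2, 0.4))[, 1] * sqrt(n / (n - 1))
  x <- (x - mean(x)) / sd(x)
  sigma2_g <- 2
  sigma2_e <- 1
  v_true <- 0.08
  y <- x * v_true + rnorm(n, 0, sqrt(sigma2_e))
  y <- y - mean(y)
  gamma <- c(0, 1e-4, 1e-3, 1e-2)
  marg <- vapply(gamma, function(g) {
    if (g == 0) return(prod(dnorm(y, 0, sqrt(sigma2_e))))
    integrate(function(v) {
      vapply(v, function(vi) prod(dnorm(y, x * vi, sqrt(sigma2_e))) *
               dnorm(vi, 0, sqrt(g * sigma2_g)), numeric(1))
    }, -1, 1, rel.tol = 1e-10)$value
  }, numeric(1))
  oracle <- marg / sum(marg)
  W <- matrix(x, ncol = 1, dimnames = list(NULL, "v1"))
  fit <- bayesr_fit(phenotype_table(y), W, n_iter = 30000, burn_in = 2000,
                    n_chains = 1, seed = 6,
                    spec = mixture_spec(sigma2_g = sigma2_g),
                    options = list(fix_p = TRUE, P0 = matrix(0.25, 1, 4),
                                   fix_sigma_e = TRUE, sigma_e0 = sigma2_e,
                                   fix_b = TRUE, b0 = 0))
  empirical <- fit$beta[1, ] / sum(fit$beta)
  expect_true(all(abs(empirical - oracle) < 0.01))
})

test_that("pinning one non-null component reduces the model to ridge regression", {
  set.seed(12)
  n <- 50; m <- 20
  W <- scale(matrix(rnorm(n * m), n, m))
  colnames(W) <- paste0("v", 1:m)
  beta_true <- rnorm(m, 0, 0.3)
  y <- drop(W %*% beta_true) + rnorm(n)
  y <- y - mean(y)
  sigma2_g <- 10; sigma2_e <- 1
  tau <- 1e-3 * sigma2_g
  fit <- bayesr_fit(phenotype_table(y), W, n_iter = 12000, burn_in = 2000,
                    n_chains = 1, seed = 3,
                    spec = mixture_spec(sigma2_g = sigma2_g),
                    options = list(fix_z = rep(3L, m), fix_sigma_e = TRUE,
                                   sigma_e0 = sigma2_e, fix_b = TRUE, b0 = 0))
  ridge_prec <- crossprod(W) + diag(sigma2_e / tau, m)
  vhat <- solve(ridge_prec, crossprod(W, y))
  post_sd <- sqrt(sigma2_e * diag(solve(ridge_prec)))
  expect_true(all(abs(fit$vbar - vhat) < 0.05 * post_sd))
})

test_that("residual bookkeeping stays consistent with from-scratch recomputation", {
  d <- sim_small(n = 200, m = 300)
  fit <- bayesrc_fit(d$pheno, d$W, NULL, n_iter = 1500, burn_in = 500,
                     n_chains = 1, seed = 8, options = list(check_every = 500))
  expect_lt(fit$max_resid_err, 1e-6)
  # float fallback path (fractional dosages) has the same guarantee
  dosf <- d$g$dosages
  dosf[1, 1] <- 0.5
  Wf <- standardize_genotypes(genotype_matrix(dosf, d$g$map))
  expect_null(Wf$raw_dosages)
  fitf <- bayesrc_fit(d$pheno, Wf, NULL, n_iter = 800, burn_in = 400,
                      n_chains = 1, seed = 8, options = list(check_every = 200))
  expect_lt(fitf$max_resid_err, 1e-6)
})

test_that("integer-dosage and dense-matrix representations agree in distribution", {
  d <- sim_small(n = 150, m = 120, qtl = c(4, 1, 1))
  Wdense <- d$W
  Wdense$raw_dosages <- NULL
  f1 <- bayesr_fit(d$pheno, d$W, n_iter = 2500, burn_in = 500, n_chains = 1,
                   seed = 4)
  f2 <- bayesr_fit(d$pheno, Wdense, n_iter = 2500, burn_in = 500,
                   n_chains = 1, seed = 4)
  # same model, different arithmetic path: posterior means agree closely
  expect_lt(mean(abs(f1$pip - f2$pip)), 0.05)
  expect_lt(abs(f1$sigma2_e - f2$sigma2_e) / f1$sigma2_e, 0.1)
})

test_that("polygenic sampling matches the closed-form ridge with A = I", {
  set.seed(13)
  n <- 80
  sigma2_a <- 4; sigma2_e <- 1
  y <- rnorm(n, 0, sqrt(sigma2_a + sigma2_e))
  y <- y - mean(y)
  W <- matrix(scale(rbinom(n, 2, 0.5)), ncol = 1, dimnames = list(NULL, "v"))
  A <- diag(n)
  fit <- bayesr_fit(phenotype_table(y), W, A = A, n_iter = 8000,
                    burn_in = 1000, n_chains = 1, seed = 5,
                    options = list(fix_b = TRUE, b0 = 0, fix_sigma_e = TRUE,
                                   sigma_e0 = sigma2_e, fix_sigma_a = TRUE,
                                   sigma_a0 = sigma2_a,
                                   fix_z = rep(1L, 1), fix_p = TRUE,
                                   P0 = matrix(c(1, 0, 0, 0), 1, 4)))
  # a | y ~ N(y / (1 + sigma2_e/sigma2_a), ...) elementwise for A = I
  ahat <- y / (1 + sigma2_e / sigma2_a)
  mc_sd <- sqrt(sigma2_e / (1 + sigma2_e / sigma2_a)) / sqrt(500)
  expect_lt(mean(abs(fit$a - ahat)), 6 * mc_sd)
  expect_gt(cor(fit$a, ahat), 0.98)
})

test_that("disabling the pedigree leaves the polygenic values at zero", {
  d <- sim_small()
  fit <- bayesr_fit(d$pheno, d$W, n_iter = 200, burn_in = 100, n_chains = 1,
                    seed = 2)
  expect_true(all(fit$a == 0))
})

test_that("shrinking sigma2_a shrinks the polygenic values", {
  set.seed(14)
  n <- 60
  y <- rnorm(n)
  W <- matrix(scale(rbinom(n, 2, 0.5)), ncol = 1, dimnames = list(NULL, "v"))
  mean_abs_a <- function(s2a) {
    fit <- bayesr_fit(phenotype_table(y), W, A = diag(n), n_iter = 1000,
                      burn_in = 500, n_chains = 1, seed = 5,
                      options = list(fix_sigma_a = TRUE, sigma_a0 = s2a))
    mean(abs(fit$a))
  }
  expect_lt(mean_abs_a(0.0001), mean_abs_a(0.01))
  expect_lt(mean_abs_a(0.01), mean_abs_a(1))
})

test_that("residual variance draws follow the scaled inverse-chi-square", {
  # fixed residuals: freeze everything except sigma2_e and check the
  # posterior mean formula ss / (n - 4) for nu0 = -2
  set.seed(15)
  n <- 40
  y <- rnorm(n, 0, 2)
  y <- y - mean(y)
  W <- matrix(scale(rnorm(n)), ncol = 1, dimnames = list(NULL, "v"))
  fit <- bayesr_fit(phenotype_table(y), W, n_iter = 40000, burn_in = 1000,
                    n_chains = 1, seed = 9,
                    options = list(fix_b = TRUE, b0 = 0,
                                   fix_z = rep(1L, 1), fix_p = TRUE,
                                   P0 = matrix(c(1, 0, 0, 0), 1, 4)))
  ss <- sum(y^2)
  expect_lt(abs(fit$sigma2_e - ss / (n - 4)) / (ss / (n - 4)), 0.05)
  # scale equivariance: doubling every weight doubles the weighted residual
  # sum of squares and hence the draw, draw for draw under a shared seed
  ph2 <- phenotype_table(y, weights = rep(2, n))
  fit2 <- bayesr_fit(ph2, W, n_iter = 40000, burn_in = 1000, n_chains = 1,
                     seed = 9,
                     options = list(fix_b = TRUE, b0 = 0,
                                    fix_z = rep(1L, 1), fix_p = TRUE,
                                    P0 = matrix(c(1, 0, 0, 0), 1, 4)))
  expect_equal(fit2$sigma2_e, 2 * fit$sigma2_e, tolerance = 1e-10)
})

test_that("successive-conditional sampling recovers the priors", {
  # proper variance prior: scaled-inv-chi2(nu0 = 6, s0 = 1), mean 1.5;
  # mixture proportions: Dirichlet(1,1,1,1), mean 0.25
  set.seed(16)
  n <- 30; m <- 15
  W <- scale(matrix(rnorm(n * m), n, m))
  colnames(W) <- paste0("v", 1:m)
  y <- rnorm(n)
  fit <- bayesr_fit(phenotype_table(y), W, n_iter = 6000, burn_in = 0,
                    n_chains = 1, seed = 10,
                    spec = mixture_spec(sigma2_g = 1, nu_e = 6, s2_e0 = 1),
                    options = list(geweke = TRUE, fix_b = TRUE, b0 = 0))
  s2e <- fit$per_chain[[1]]$s2e_trace
  expect_lt(abs(mean(s2e) - 1.5), 0.25)
  Pm <- apply(fit$per_chain[[1]]$P_trace, c(1, 2), mean)
  expect_true(all(abs(Pm - 0.25) < 0.04))
})

test_that("chain summaries pool exactly as documented", {
  fake <- function(acc) list(vbar = acc, pip = acc / 10,
                             comp_freq = matrix(c(1, 0, 0, 0), 1, 4),
                             b = 0, a = 0,
                             P = matrix(acc, 1, 4), beta = matrix(1, 1, 4),
                             sigma2_e = acc, sigma2_a = 0, sigma2_g = 1,
                             n_keep = 100, max_resid_err = 0)
  s <- summarize_chains(lapply(c(0.1, 0.2, 0.3, 0.2, 0.2), fake))
  expect_equal(s$sigma2_e, 0.2)
  expect_equal(s$sigma2_e_spread, sd(c(0.1, 0.2, 0.3, 0.2, 0.2)) / sqrt(5))
  expect_equal(s$vbar, 0.2)
  one <- summarize_chains(list(fake(0.4)))
  expect_equal(one$sigma2_e, 0.4)
  bad <- lapply(c(0.1, 0.2), fake)
  bad[[2]]$n_keep <- 50
  expect_error(summarize_chains(bad), "unequal length")
  # identical seeds give zero cross-chain spread
  d <- sim_small()
  fit <- bayesr_fit(d$pheno, d$W, n_iter = 200, burn_in = 100, n_chains = 3,
                    seed = 1, chain_seeds = c(4, 4, 4))
  expect_equal(fit$sigma2_e_spread, 0)
})

test_that("small classes trigger the class-size caution", {
  d <- sim_small()
  m <- ncol(d$W$W)
  cl <- variant_classes(d$W$map$id,
                        c(rep("tiny", 10), rep("big", m - 10)))
  expect_warning(bayesrc_fit(d$pheno, d$W, cl, n_iter = 100, burn_in = 50,
                             n_chains = 1, seed = 1),
                 "1000 variants")
})

test_that("class maps failing to cover the design are rejected", {
  d <- sim_small()
  cl <- variant_classes(d$W$map$id[-1], rep("a", ncol(d$W$W) - 1))
  expect_error(bayesrc_fit(d$pheno, d$W, cl, n_iter = 100, burn_in = 50),
               "do not cover")
})
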
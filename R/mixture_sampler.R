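#' Mixture specification for the variant-effect model
#'
#' Variant effects are modelled as a mixture of four normals
#' `N(0, gamma_d * sigma2_g)` with `gamma = (0, 0.0001, 0.001, 0.01)`: a null
#' component plus three effect-size tiers. Each annotation class has its own
#' mixture proportions with a symmetric `Dirichlet(1,1,1,1)` prior, so a
#' class only behaves differently if the data support it.
#'
#' `sigma2_g` is treated as fixed. If not given it is resolved at fit time as
#' `h2_prior` times the weighted phenotypic variance. Variance priors for
#' `sigma2_e` and `sigma2_a` are scaled inverse-chi-square; the defaults
#' `nu = -2, scale = 0` are uninformative (posteriors data-dominated), and
#' proper values can be supplied (used e.g. by prior-recovery checks).
#'
#' @param sigma2_g fixed additive genetic variance scale, or `NULL` to derive
#'   from `h2_prior`
#' @param h2_prior prior heritability used to set `sigma2_g` when it is not
#'   given
#' @param gamma the four component variance fractions (first must be 0,
#'   nondecreasing)
#' @param alpha Dirichlet hyperparameters: length-4 vector shared by all
#'   classes, or a `C x 4` matrix
#' @param nu_e,s2_e0 residual-variance prior degrees of freedom and scale
#' @param nu_a,s2_a0 polygenic-variance prior degrees of freedom and scale
#' @param update_sigma_g if `TRUE`, `sigma2_g` is updated from the current
#'   effects instead of staying fixed (off by default)
#' @return a `mixture_spec` list
#' @export
mixture_spec <- function(sigma2_g = NULL, h2_prior = 0.5,
                         gamma = c(0, 1e-4, 1e-3, 1e-2),
                         alpha = c(1, 1, 1, 1),
                         nu_e = -2, s2_e0 = 0, nu_a = -2, s2_a0 = 0,
                         update_sigma_g = FALSE) {
  if (gamma[1] != 0) stop("first mixture component must have zero variance")
  if (any(diff(gamma) < 0)) stop("component variance fractions must be nondecreasing")
  if (any(alpha <= 0)) stop("Dirichlet hyperparameters must be positive")
  structure(list(sigma2_g = sigma2_g, h2_prior = h2_prior, gamma = gamma,
                 alpha = alpha, nu_e = nu_e, s2_e0 = s2_e0, nu_a = nu_a,
                 s2_a0 = s2_a0, update_sigma_g = update_sigma_g),
            class = "mixture_spec")
}

#' One draw of class mixture proportions
#'
#' `P_c ~ Dirichlet(alpha + beta)` where `beta` counts the variants of the
#' class currently in each mixture component.
#'
#' @param beta length-4 nonnegative component counts
#' @param alpha length-4 Dirichlet hyperparameters
#' @return a length-4 proportion vector summing to 1
#' @export
sample_mixture_proportions <- function(beta, alpha = c(1, 1, 1, 1)) {
  stopifnot(length(beta) == length(alpha))
  if (any(beta < 0)) stop("internal state error: negative component count")
  gsamp <- stats::rgamma(length(beta), shape = alpha + beta, rate = 1)
  gsamp / sum(gsamp)
}

resolve_design <- function(W) {
  if (inherits(W, "std_design")) W else {
    stopifnot(is.matrix(W))
    structure(list(W = W, center = NULL, scale = NULL,
                   map = data.frame(chrom = 1L, pos = seq_len(ncol(W)),
                                    id = colnames(W) %||%
                                      paste0("v", seq_len(ncol(W)))),
                   individual_ids = rownames(W)),
              class = "std_design")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

align_classes <- function(classes, ids) {
  if (is.null(classes))
    return(variant_classes(ids, rep("all", length(ids))))
  pos <- match(ids, classes$ids)
  if (anyNA(pos))
    stop("classes do not cover all variants: ",
         paste(utils::head(ids[is.na(pos)], 5), collapse = ", "))
  variant_classes(ids, classes$class_labels[classes$class_index[pos]],
                  if (!is.null(classes$category)) classes$category[pos] else NULL)
}

#' Weighted phenotypic variance after absorbing the fixed effects
#'
#' Weighted residual variance of the phenotype around its weighted
#' least-squares fixed-effect fit; the natural scale for variance priors when
#' phenotypes carry large structural effects (breed offsets, data-type
#' means).
#'
#' @param pheno a [phenotype_table()]
#' @return scalar variance
#' @export
adjusted_variance <- function(pheno) {
  w <- pheno$weights
  fit <- stats::lm.wfit(pheno$X, pheno$y, w)
  sum(w * fit$residuals^2) / sum(w)
}

#' Fit the annotation-class Bayesian mixture model (BayesRC)
#'
#' Gibbs sampler for `y = X b + Z a + W v + e`: per iteration it samples the
#' fixed effects (flat prior, weighted least squares), the polygenic values
#' and their variance when a relationship matrix is supplied, each variant's
#' mixture component and effect in a fresh random permutation, each class's
#' mixture proportions from `Dirichlet(alpha + beta_c)`, and the residual
#' variance from the weighted residual sum of squares. Posterior summaries
#' are post-burn-in means computed within each chain and then averaged
#' across chains.
#'
#' @param pheno a [phenotype_table()]
#' @param W a `std_design` from [standardize_genotypes()] (or a plain
#'   standardized matrix)
#' @param classes a [variant_classes()] covering all variants, or `NULL` for
#'   a single class (which is exactly the no-annotation BayesR model)
#' @param A optional numerator relationship matrix aligned to phenotype rows
#'   (from [a_matrix()]); when omitted the polygenic term is dropped
#' @param spec a [mixture_spec()]
#' @param n_iter,burn_in Gibbs chain length and discarded iterations. The
#'   full-scale analysis convention is 40,000 iterations with 20,000
#'   burn-in over 5 chains; scale down for small data.
#' @param n_chains number of replicate chains
#' @param seed integer seed; chain `k` uses `seed + k - 1` unless
#'   `chain_seeds` is given
#' @param chain_seeds optional explicit per-chain seeds
#' @param options list of debug switches passed to the compiled core
#'   (`fix_b`, `b0`, `fix_p`, `P0`, `fix_z`, `fix_sigma_e`, `sigma_e0`,
#'   `geweke`, `check_every`)
#' @param verbose print per-chain progress
#' @return object of class `bayesrc_fit`; see [summarize_chains()] for the
#'   pooled summary fields
#' @export
bayesrc_fit <- function(pheno, W, classes = NULL, A = NULL,
                        spec = mixture_spec(), n_iter = 40000,
                        burn_in = 20000, n_chains = 5, seed = 1,
                        chain_seeds = NULL, options = list(),
                        verbose = FALSE) {
  stopifnot(inherits(pheno, "pheno_table"))
  sd <- resolve_design(W)
  n <- nrow(sd$W); m <- ncol(sd$W)
  stopifnot(length(pheno$y) == n)
  cl <- align_classes(classes, sd$map$id)
  C <- length(cl$class_labels)
  csize <- tabulate(cl$class_index, C)
  if (any(csize < 50))
    warning("class(es) ", paste(cl$class_labels[csize < 50], collapse = ", "),
            " have < 50 variants; with vague priors, classes of more than",
            " 1000 variants are recommended so the data dominate the posterior")
  alpha <- spec$alpha
  if (is.matrix(alpha)) stopifnot(nrow(alpha) == C, ncol(alpha) == 4)
  else alpha <- matrix(alpha, C, 4, byrow = TRUE)
  sigma2_g <- spec$sigma2_g %||% (spec$h2_prior * adjusted_variance(pheno))
  ped <- list()
  if (!is.null(A)) {
    stopifnot(nrow(A) == n)
    ped <- factorize_a(A, pheno$weights)
  }
  opts <- utils::modifyList(
    list(nu_e = spec$nu_e, s2_e0 = spec$s2_e0, nu_a = spec$nu_a,
         s2_a0 = spec$s2_a0, update_sigma_g = spec$update_sigma_g),
    options)
  if (is.null(chain_seeds)) chain_seeds <- seed + seq_len(n_chains) - 1
  stopifnot(length(chain_seeds) == n_chains)
  chains <- vector("list", n_chains)
  use_raw <- !is.null(sd$raw_dosages)
  ctr <- if (use_raw) sd$center else numeric(m)
  scl <- if (use_raw) sd$scale else numeric(m)
  for (k in seq_len(n_chains)) {
    if (verbose) message("chain ", k, "/", n_chains, " (seed ", chain_seeds[k], ")")
    set.seed(chain_seeds[k])
    chains[[k]] <- .bayesrc_chain_cpp(
      if (use_raw) NULL else sd$W, if (use_raw) sd$raw_dosages else NULL,
      ctr, scl, pheno$y, pheno$X, pheno$weights,
      cl$class_index, C, spec$gamma, sigma2_g, alpha, ped,
      as.integer(n_iter), as.integer(burn_in), opts)
  }
  out <- summarize_chains(chains)
  out$map <- sd$map
  out$classes <- cl
  out$spec <- spec
  out$sigma2_g_fixed <- sigma2_g
  out$n_iter <- n_iter; out$burn_in <- burn_in
  out$chain_seeds <- chain_seeds
  class(out) <- "bayesrc_fit"
  out
}

#' Fit the single-class mixture model (BayesR)
#'
#' BayesR is exactly [bayesrc_fit()] with one variant class: the same code
#' path with `C = 1`, so results under a shared seed are identical by
#' construction.
#'
#' @inheritParams bayesrc_fit
#' @param ... passed to [bayesrc_fit()]
#' @return a `bayesrc_fit` object
#' @export
bayesr_fit <- function(pheno, W, ...) {
  bayesrc_fit(pheno, W, classes = NULL, ...)
}

#' Pool per-chain posterior summaries
#'
#' Post-burn-in means are computed within each chain; the report is their
#' average across chains, with the between-chain spread `SD / sqrt(n_chains)`
#' (a relative-convergence figure, not a standard error).
#'
#' @param chains list of per-chain summaries from the sampler core
#' @return list with pooled `pip`, `vbar`, `comp_freq` (per-variant component
#'   occupancy frequencies), `b`, `a`, `P`, `beta`,
#'   `sigma2_e`, `sigma2_a`, `sigma2_g`, per-chain values in `per_chain`,
#'   spread elements `*_spread`, and `max_resid_err`
#' @export
summarize_chains <- function(chains) {
  stopifnot(length(chains) >= 1)
  nk <- vapply(chains, function(ch) ch$n_keep, numeric(1))
  if (length(unique(nk)) != 1) stop("chains of unequal length")
  avg <- function(name) {
    vals <- lapply(chains, `[[`, name)
    Reduce(`+`, vals) / length(vals)
  }
  s2e <- vapply(chains, `[[`, numeric(1), "sigma2_e")
  list(pip = drop(avg("pip")), vbar = drop(avg("vbar")),
       comp_freq = avg("comp_freq"), b = drop(avg("b")),
       a = drop(avg("a")), P = avg("P"), beta = avg("beta"),
       sigma2_e = mean(s2e),
       sigma2_e_spread = stats::sd(s2e) / sqrt(length(s2e)),
       sigma2_a = mean(vapply(chains, `[[`, numeric(1), "sigma2_a")),
       sigma2_g = mean(vapply(chains, `[[`, numeric(1), "sigma2_g")),
       max_resid_err = max(vapply(chains, `[[`, numeric(1), "max_resid_err")),
       n_chains = length(chains), per_chain = chains)
}

#' @export
#' @method print bayesrc_fit
print.bayesrc_fit <- function(x, ...) {
  cat(sprintf("bayesrc_fit: %d variants, %d class(es), %d chain(s) x %d iterations (%d burn-in)\n",
              length(x$pip), length(x$classes$class_labels), x$n_chains,
              x$n_iter, x$burn_in))
  cat(sprintf("sigma2_e = %.4g  sigma2_a = %.4g  sigma2_g (fixed) = %.4g\n",
              x$sigma2_e, x$sigma2_a, x$sigma2_g_fixed))
  cat("posterior mean mixture proportions per class:\n")
  P <- x$P
  dimnames(P) <- list(x$classes$class_labels,
                      paste0("d", seq_len(ncol(P))))
  print(round(P, 4))
  invisible(x)
}
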
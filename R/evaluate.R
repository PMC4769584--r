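#' Predict genetic values from estimated variant effects
#'
#' `yhat = W_val %*% vbar`, computed per chain and then averaged. The
#' polygenic term is deliberately excluded so predictions transfer to
#' individuals not connected through the pedigree.
#'
#' @param object a `bayesrc_fit`
#' @param W_val a `std_design` for the validation individuals built with the
#'   training centring and scale (see [apply_standardization()]), or a plain
#'   matrix over the same variants
#' @param ... unused
#' @return object of class `bayesrc_prediction`: list with `yhat` (chain
#'   average) and `per_chain` (individuals x chains matrix)
#' @export
predict.bayesrc_fit <- function(object, W_val, ...) {
  sd <- resolve_design(W_val)
  if (!identical(sd$map$id, object$map$id)) {
    missing_ids <- setdiff(object$map$id, sd$map$id)
    if (length(missing_ids))
      stop("validation variants missing: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    sd$W <- sd$W[, match(object$map$id, sd$map$id), drop = FALSE]
  }
  per_chain <- vapply(object$per_chain,
                      function(ch) drop(sd$W %*% ch$vbar),
                      numeric(nrow(sd$W)))
  per_chain <- matrix(per_chain, nrow = nrow(sd$W))
  structure(list(yhat = rowMeans(per_chain), per_chain = per_chain),
            class = "bayesrc_prediction")
}

acc_bias_one <- function(yhat, reference) {
  if (length(yhat) < 3) stop("need at least 3 individuals")
  if (stats::sd(yhat) == 0 || stats::sd(reference) == 0)
    stop("undefined metric: zero variance in predictions or reference")
  c(accuracy = stats::cor(reference, yhat),
    bias = stats::cov(reference, yhat) / stats::var(yhat))
}

#' Accuracy and bias of genomic prediction
#'
#' Accuracy is the Pearson correlation between predictions and the reference
#' values (phenotypes, or true genetic values in simulation); bias is the
#' regression coefficient of the reference on the prediction (1 = unbiased).
#' For a multi-chain prediction, metrics are computed within each chain and
#' reported as the chain mean with spread `SD / sqrt(n_chains)`.
#'
#' @param prediction a `bayesrc_prediction` from [predict.bayesrc_fit()], or
#'   a plain numeric vector of predictions
#' @param reference aligned numeric vector of reference values
#' @return list with `accuracy`, `bias`, `accuracy_spread`, `bias_spread`
#'   and `per_chain` (matrix, when chains are available)
#' @export
accuracy_and_bias <- function(prediction, reference) {
  if (inherits(prediction, "bayesrc_prediction")) {
    stopifnot(nrow(prediction$per_chain) == length(reference))
    per <- apply(prediction$per_chain, 2, acc_bias_one, reference = reference)
    nc <- ncol(per)
    list(accuracy = mean(per["accuracy", ]), bias = mean(per["bias", ]),
         accuracy_spread = stats::sd(per["accuracy", ]) / sqrt(nc),
         bias_spread = stats::sd(per["bias", ]) / sqrt(nc),
         per_chain = per)
  } else {
    stopifnot(length(prediction) == length(reference))
    res <- acc_bias_one(prediction, reference)
    list(accuracy = res[["accuracy"]], bias = res[["bias"]],
         accuracy_spread = NA_real_, bias_spread = NA_real_, per_chain = NULL)
  }
}

truth_flags <- function(truth, ids) {
  if (is.logical(truth)) return(truth)
  if (inherits(truth, "truth_set")) {
    if (length(truth$qtl_ids) == 0)
      stop("empty truth set: calibration requires simulated data with QTL")
    if (is.null(ids)) stop("variant ids needed to align the truth set")
    return(ids %in% truth$qtl_ids)
  }
  stop("truth must be a logical vector or a truth_set")
}

#' Calibration of posterior inclusion probabilities
#'
#' Bins variants by posterior probability of a non-zero effect and reports,
#' per bin, the variant count, the median posterior probability and the
#' observed fraction of true QTL. For a well-calibrated analysis the observed
#' fraction tracks the median posterior probability.
#'
#' @param pip numeric vector of posterior inclusion probabilities
#' @param truth logical per-variant QTL indicator, or a `truth_set` with
#'   `ids` supplied
#' @param ids variant ids aligned with `pip` (needed with a `truth_set`)
#' @param breaks bin edges over `(breaks[1], 1]`; variants at or below the
#'   first edge are not binned
#' @return data.frame with columns `bin`, `n`, `median_pip`, `true_fraction`
#' @export
calibration_table <- function(pip, truth, ids = NULL,
                              breaks = c(0.01, 0.2, 0.4, 0.6, 0.8, 1)) {
  is_qtl <- truth_flags(truth, ids)
  stopifnot(length(is_qtl) == length(pip))
  bin <- cut(pip, breaks = breaks, include.lowest = FALSE)
  out <- data.frame(bin = levels(bin),
                    n = as.integer(table(bin)),
                    median_pip = as.numeric(tapply(pip, bin, stats::median)),
                    true_fraction = as.numeric(tapply(is_qtl, bin, mean)))
  out
}

#' True-QTL discovery counts at posterior-probability thresholds
#'
#' @inheritParams calibration_table
#' @param thresholds posterior-probability thresholds; for each, the number
#'   of true QTL with `pip` strictly above it is reported
#' @return data.frame with columns `threshold`, `n_selected`,
#'   `n_true_qtl`
#' @export
discovery_counts <- function(pip, truth, ids = NULL,
                             thresholds = c(0.01, 0.1, 0.25)) {
  is_qtl <- truth_flags(truth, ids)
  stopifnot(length(is_qtl) == length(pip))
  data.frame(threshold = thresholds,
             n_selected = vapply(thresholds, function(t) sum(pip > t), 0L),
             n_true_qtl = vapply(thresholds, function(t) sum(is_qtl & pip > t), 0L))
}

#' Per-class genetic-architecture summary
#'
#' Mean number and proportion of each class's variants assigned to each
#' non-null mixture component, with fold enrichment relative to the
#' all-variant baseline.
#'
#' @param fit a `bayesrc_fit`
#' @return data.frame with one row per (class, component), columns `class`,
#'   `component`, `class_size`, `mean_count`, `proportion`,
#'   `fold_enrichment`
#' @export
class_architecture <- function(fit) {
  beta <- fit$beta
  labs <- fit$classes$class_labels
  csize <- tabulate(fit$classes$class_index, length(labs))
  K <- ncol(beta)
  overall <- colSums(beta) / sum(csize)
  out <- do.call(rbind, lapply(seq_along(labs), function(c) {
    data.frame(class = labs[c], component = seq_len(K) - 1L,
               class_size = csize[c],
               mean_count = beta[c, ],
               proportion = beta[c, ] / csize[c],
               fold_enrichment = (beta[c, ] / csize[c]) / overall)
  }))
  out[out$component > 0, , drop = FALSE]
}

#' Per-class prediction equations and their accuracy
#'
#' Splits a fit's estimated effects by class, predicts validation genetic
#' values from each class's variants alone, and reports per-chain accuracies.
#'
#' @param fit a `bayesrc_fit`
#' @param W_val validation `std_design` over the fit's variants
#' @param reference aligned reference values
#' @param class_members optional named list of variant-index vectors to use
#'   instead of the fit's own classes
#' @return matrix of accuracies, chains x classes
#' @export
class_predictions <- function(fit, W_val, reference, class_members = NULL) {
  sd <- resolve_design(W_val)
  if (is.null(class_members)) {
    labs <- fit$classes$class_labels
    class_members <- lapply(seq_along(labs),
                            function(c) which(fit$classes$class_index == c))
    names(class_members) <- labs
  }
  out <- sapply(class_members, function(members) {
    vapply(fit$per_chain, function(ch) {
      yh <- drop(sd$W[, members, drop = FALSE] %*% ch$vbar[members])
      if (stats::sd(yh) == 0) NA_real_ else stats::cor(reference, yh)
    }, numeric(1))
  })
  matrix(out, ncol = length(class_members),
         dimnames = list(NULL, names(class_members)))
}

#' Random-gene-set null distribution of per-class prediction accuracy
#'
#' Builds, per replicate, a random set of gene regions matched to the
#' informed analysis, allocates the same class sizes from those regions, and
#' derives per-class prediction equations from a baseline (single-class)
#' fit's estimated effects. The spread of the resulting per-class accuracies
#' is the null against which informed-class accuracies are compared; one
#' accuracy is recorded per replicate and per chain.
#'
#' @param baseline_fit a single-class `bayesrc_fit` whose effects supply the
#'   null prediction equations
#' @param W_val validation `std_design`
#' @param reference aligned reference values
#' @param class_sizes integer vector `c(I, II)`: variants to allocate to the
#'   gene-region classes (the remainder forms class III)
#' @param region_length variants per random gene region
#' @param n_genes gene regions drawn (with replacement) per replicate
#' @param n_replicates number of random gene sets
#' @param seed RNG seed
#' @return list with `accuracy` (array replicate x chain x class) and the
#'   per-replicate region draws in `regions`
#' @export
random_gene_null <- function(baseline_fit, W_val, reference, class_sizes,
                             region_length, n_genes, n_replicates = 10,
                             seed = 1) {
  m <- length(baseline_fit$vbar)
  if (region_length > m) stop("class sizes unmatchable: regions exceed genome")
  set.seed(seed)
  n_chains <- baseline_fit$n_chains
  acc <- array(NA_real_, c(n_replicates, n_chains, 3),
               dimnames = list(NULL, NULL, c("I", "II", "III")))
  regions <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    starts <- sample.int(m - region_length + 1, n_genes, replace = TRUE)
    members <- sort(unique(unlist(lapply(starts, function(s)
      s:(s + region_length - 1)))))
    if (length(members) < sum(class_sizes))
      stop("class sizes unmatchable: draw more or longer gene regions")
    cI <- sample(members, class_sizes[1])
    cII <- sample(setdiff(members, cI), class_sizes[2])
    cIII <- setdiff(seq_len(m), c(cI, cII))
    regions[[r]] <- starts
    accs <- class_predictions(baseline_fit, W_val, reference,
                              class_members = list(I = cI, II = cII, III = cIII))
    acc[r, , ] <- accs
  }
  list(accuracy = acc, regions = regions)
}
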
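#' Configuration for the complex-trait simulator
#'
#' The simulator emulates the structure of a multi-breed dairy-cattle
#' reference population: several populations with drifted allele frequencies,
#' local LD in blocks, variant annotation categories (`NSC`/`REG`/`CHIP`
#' analogues), candidate-gene regions, tiered QTL effects drawn from three
#' normal distributions, a high-heritability trait and a breed (population)
#' offset.
#'
#' @param n_per_pop integer vector of individuals per population. The last
#'   population is conventionally used as a less-related validation set and
#'   the first receives the breed offset.
#' @param n_variants total variants simulated
#' @param n_chrom number of chromosomes (variants split evenly)
#' @param ld_block_length variants per LD block
#' @param within_block_corr latent AR(1) correlation of adjacent variants
#'   within a block, in `[0, 1)`
#' @param drift_sd standard deviation of per-population allele-frequency
#'   drift around the shared base frequency
#' @param base_freq_range range of the shared base alternate-allele frequency
#' @param n_qtl_per_tier QTL counts for the three effect tiers. The full
#'   design uses `c(3485, 500, 15)`; the default is the same 174:25:1 ratio
#'   at 1/20 scale for desk-size genomes.
#' @param tier_variances variances of the three effect tiers as fractions of
#'   the genetic variance scale; must be strictly increasing
#' @param sigma2_g_scale genetic-variance scale multiplying `tier_variances`
#' @param heritability narrow-sense h2 in `(0, 1]` of the simulated trait
#' @param breed_effect `c(mean, sd)` of the normal from which the single
#'   population-1 offset is drawn
#' @param enrichment_scheme QTL placement: `"candidate_gene"` (QTL only
#'   inside candidate-gene regions), `"category_only"` (QTL only on
#'   `NSC`/`REG` category variants genome-wide) or `"uniform"` (anywhere)
#' @param n_candidate_genes number of candidate-gene loci
#' @param gene_size variants per gene body
#' @param gene_window flanking variants on each side counted as the gene
#'   region
#' @param category_probs_in_gene,category_probs_outside probabilities of
#'   `NSC`/`REG`/`CHIP` annotation inside gene bodies and elsewhere
#' @param weights_scheme `"uniform"` (all reliability weights 1) or
#'   `"two_point"` (a bull-like high-reliability subset)
#' @param weights_two_point `c(low, high, prop_high)` for the two-point
#'   weight distribution
#' @param seed integer seed; all stages derive deterministic sub-streams
#' @return a `sim_config` list
#' @export
sim_config <- function(n_per_pop = c(1300, 700, 300),
                       n_variants = 10000,
                       n_chrom = 5,
                       ld_block_length = 50,
                       within_block_corr = 0.95,
                       drift_sd = 0.1,
                       base_freq_range = c(0.05, 0.95),
                       n_qtl_per_tier = c(174, 25, 1),
                       tier_variances = c(1e-4, 1e-3, 1e-2),
                       sigma2_g_scale = 1,
                       heritability = 0.6,
                       breed_effect = c(10, 1),
                       enrichment_scheme = c("candidate_gene", "category_only",
                                             "uniform"),
                       n_candidate_genes = 100,
                       gene_size = 8,
                       gene_window = 4,
                       category_probs_in_gene = c(NSC = 0.4, REG = 0.4, CHIP = 0.2),
                       category_probs_outside = c(NSC = 0.02, REG = 0.55, CHIP = 0.43),
                       weights_scheme = c("uniform", "two_point"),
                       weights_two_point = c(low = 1, high = 10, prop_high = 0.3),
                       seed = 1) {
  enrichment_scheme <- match.arg(enrichment_scheme)
  weights_scheme <- match.arg(weights_scheme)
  if (any(n_qtl_per_tier < 0)) stop("tier counts must be >= 0")
  if (heritability <= 0 || heritability > 1)
    stop("heritability must be in (0, 1]")
  if (any(diff(tier_variances) <= 0))
    stop("tier variances must be strictly increasing")
  if (within_block_corr < 0 || within_block_corr >= 1)
    stop("invalid parameter: within_block_corr must be in [0, 1)")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

stage_seed <- function(cfg, stage) {
  offs <- c(genotypes = 1L, classes = 2L, qtl = 3L, phenotypes = 4L)
  (as.integer(cfg$seed) %% 1000000L) * 1000L + offs[[stage]]
}

#' Simulate multi-population genotypes with local LD
#'
#' Haplotypes are generated from a Gaussian copula: within each LD block a
#' latent AR(1) process with correlation `within_block_corr` is thresholded
#' at the population-specific allele frequency; dosages are the sum of two
#' independent haplotypes. Populations share base frequencies with
#' independent normal drift (`drift_sd`), giving realistic between-population
#' differentiation.
#'
#' @param cfg a [sim_config()]
#' @return list with `genotypes` (a [genotype_matrix()]), `population`
#'   (integer per individual) and `freqs` (per-population allele-frequency
#'   matrix)
#' @export
sim_genotypes <- function(cfg) {
  set.seed(stage_seed(cfg, "genotypes"))
  m <- cfg$n_variants
  npop <- length(cfg$n_per_pop)
  p0 <- stats::runif(m, cfg$base_freq_range[1], cfg$base_freq_range[2])
  freqs <- sapply(seq_len(npop), function(k)
    pmin(pmax(p0 + stats::rnorm(m, 0, cfg$drift_sd), 0.005), 0.995))
  chrom <- rep(seq_len(cfg$n_chrom), each = ceiling(m / cfg$n_chrom))[seq_len(m)]
  pos_in_chrom <- stats::ave(seq_len(m), chrom, FUN = seq_along)
  # AR(1) restarts at block and chromosome boundaries
  new_block <- (pos_in_chrom - 1) %% cfg$ld_block_length == 0
  rho <- cfg$within_block_corr
  n_tot <- sum(cfg$n_per_pop)
  pop <- rep(seq_len(npop), cfg$n_per_pop)
  dos <- matrix(0L, n_tot, m)
  thr <- stats::qnorm(freqs)  # latent threshold; P(z < thr) = freq
  for (k in seq_len(npop)) {
    rows <- which(pop == k)
    nh <- 2L * length(rows)
    zprev <- stats::rnorm(nh)
    hap <- matrix(0L, nh, m)
    for (j in seq_len(m)) {
      if (new_block[j]) z <- stats::rnorm(nh)
      else z <- rho * zprev + sqrt(1 - rho^2) * stats::rnorm(nh)
      hap[, j] <- (z < thr[j, k])
      zprev <- z
    }
    dos[rows, ] <- hap[seq_len(nh / 2), ] + hap[nh / 2 + seq_len(nh / 2), ]
  }
  ids <- sprintf("v%05d", seq_len(m))
  map <- data.frame(chrom = chrom,
                    pos = as.integer(pos_in_chrom * 1000L),
                    id = ids, stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, map,
                       sprintf("p%d_i%04d", pop, stats::ave(pop, pop, FUN = seq_along)))
  list(genotypes = g, population = pop, freqs = freqs)
}

#' Assign annotation categories, candidate genes and analysis classes
#'
#' Candidate-gene loci are placed without overlap (one per equal genome
#' segment, at a random offset). Annotation categories are drawn per variant
#' with an elevated coding-analogue (`NSC`) rate inside gene bodies. Classes
#' follow the enrichment scheme: for `"candidate_gene"`, class `I` holds
#' coding-analogue variants inside gene bodies, class `II` the remaining
#' variants of each gene region (body plus `gene_window` flanking variants),
#' class `III` the rest; for `"category_only"` the classes are the annotation
#' categories themselves; `"uniform"` puts every variant in a single class.
#'
#' @param g a [genotype_matrix()] from [sim_genotypes()]
#' @param cfg a [sim_config()]
#' @return a [variant_classes()] object with attributes `genes` (data.frame
#'   of gene body/region variant index ranges) and `region` (logical vector
#'   marking gene-region membership)
#' @export
sim_classes <- function(g, cfg) {
  set.seed(stage_seed(cfg, "classes"))
  m <- ncol(g$dosages)
  ng <- cfg$n_candidate_genes
  span <- cfg$gene_size + 2 * cfg$gene_window
  seg <- floor(m / ng)
  if (seg < span)
    stop("too many candidate genes for the genome size; reduce n_candidate_genes")
  start_body <- (seq_len(ng) - 1) * seg + cfg$gene_window +
    sample.int(seg - span + 1, ng, replace = TRUE)
  genes <- data.frame(gene = seq_len(ng),
                      body_start = start_body,
                      body_end = start_body + cfg$gene_size - 1,
                      region_start = start_body - cfg$gene_window,
                      region_end = start_body + cfg$gene_size - 1 + cfg$gene_window)
  in_body <- logical(m); in_region <- logical(m)
  for (k in seq_len(ng)) {
    in_body[genes$body_start[k]:genes$body_end[k]] <- TRUE
    in_region[genes$region_start[k]:genes$region_end[k]] <- TRUE
  }
  cats <- character(m)
  cats[in_body] <- sample(names(cfg$category_probs_in_gene), sum(in_body),
                          replace = TRUE, prob = cfg$category_probs_in_gene)
  cats[!in_body] <- sample(names(cfg$category_probs_outside), sum(!in_body),
                           replace = TRUE, prob = cfg$category_probs_outside)
  lab <- switch(cfg$enrichment_scheme,
                uniform = rep("all", m),
                category_only = cats,
                candidate_gene = ifelse(in_body & cats == "NSC", "I",
                                        ifelse(in_region, "II", "III")))
  if (any(table(factor(lab)) == 0) || (cfg$enrichment_scheme == "candidate_gene" &&
                                       length(unique(lab)) < 3))
    stop("empty class; increase n_candidate_genes or gene_size")
  cl <- variant_classes(g$map$id, lab, cats)
  attr(cl, "genes") <- genes
  attr(cl, "region") <- in_region
  cl
}

#' Simulate tiered QTL effects and true genetic values
#'
#' QTL positions are drawn uniformly among the eligible variants of the
#' enrichment scheme; effects for the three tiers are sampled from
#' `N(0, tier_variances[t] * sigma2_g_scale)`. The genetic value of
#' individual `j` is exactly `sum_i x_ij alpha_i` over raw dosages.
#'
#' @param g a [genotype_matrix()]
#' @param classes the [sim_classes()] result
#' @param cfg a [sim_config()]
#' @return a `truth_set` list: `qtl_ids`, `qtl_idx`, `effects`, `tier`,
#'   `genetic_values`, `enrichment` (per-class true-QTL fraction)
#' @export
sim_qtl <- function(g, classes, cfg) {
  set.seed(stage_seed(cfg, "qtl"))
  m <- ncol(g$dosages)
  eligible <- switch(cfg$enrichment_scheme,
                     uniform = seq_len(m),
                     category_only = which(classes$category %in% c("NSC", "REG")),
                     candidate_gene = which(attr(classes, "region")))
  n_qtl <- sum(cfg$n_qtl_per_tier)
  if (n_qtl > length(eligible))
    stop("requested QTL exceed eligible variants (", length(eligible), ")")
  idx <- if (n_qtl > 0) sort(sample(eligible, n_qtl)) else integer(0)
  tier <- integer(0)
  if (n_qtl > 0) {
    tier <- sample(rep(seq_along(cfg$n_qtl_per_tier), cfg$n_qtl_per_tier))
  }
  effects <- stats::rnorm(n_qtl, 0,
                          sqrt(cfg$tier_variances[tier] * cfg$sigma2_g_scale))
  gv <- if (n_qtl > 0) as.numeric(g$dosages[, idx, drop = FALSE] %*% effects)
        else rep(0, nrow(g$dosages))
  is_qtl <- logical(m); is_qtl[idx] <- TRUE
  enr <- tapply(is_qtl, classes$class_labels[classes$class_index], mean)
  structure(list(qtl_ids = g$map$id[idx], qtl_idx = idx, effects = effects,
                 tier = tier, genetic_values = gv,
                 enrichment = enr), class = "truth_set")
}

#' Simulate phenotypes with target heritability and a population offset
#'
#' `y_j = offset(pop_j) + g_j + e_j` where the environmental variance is
#' scaled from the realized genetic-value variance so the target heritability
#' holds per replicate: `var(e) = var(g) (1 - h2) / h2`. A single offset
#' drawn from `N(breed_effect[1], breed_effect[2])` is added to population 1.
#'
#' @param g a [genotype_matrix()] (used for record count only)
#' @param truth a [sim_qtl()] truth set
#' @param cfg a [sim_config()]
#' @param population integer population labels from [sim_genotypes()]
#' @return list with `pheno` (a [phenotype_table()] whose `X` holds an
#'   intercept and population indicators), `population`, `breed_offset` and
#'   `env` (the drawn environmental effects)
#' @export
sim_phenotypes <- function(g, truth, cfg, population) {
  set.seed(stage_seed(cfg, "phenotypes"))
  n <- nrow(g$dosages)
  stopifnot(length(population) == n)
  gv <- truth$genetic_values
  vg <- stats::var(gv)
  h2 <- cfg$heritability
  if (vg == 0 && h2 < 1)
    stop("zero genetic variance: environmental variance undefined for h2 < 1")
  ve <- if (h2 == 1) 0 else vg * (1 - h2) / h2
  env <- stats::rnorm(n, 0, sqrt(ve))
  offset <- stats::rnorm(1, cfg$breed_effect[1], cfg$breed_effect[2])
  y <- gv + env + ifelse(population == 1, offset, 0)
  w <- rep(1, n)
  if (cfg$weights_scheme == "two_point") {
    hi <- stats::runif(n) < cfg$weights_two_point[["prop_high"]]
    w <- ifelse(hi, cfg$weights_two_point[["high"]],
                cfg$weights_two_point[["low"]])
  }
  X <- pop_design(population)
  list(pheno = phenotype_table(y, w, X, ids = g$individual_ids),
       population = population, breed_offset = offset, env = env)
}

#' Tier-consistent mixture variance scale for a simulated study
#'
#' The mixture components place variant-effect variances at fixed fractions
#' `gamma_t` of a reference variance `sigma2_g`. In the full-scale design the
#' QTL counts and tiers satisfy `sum(n_t * gamma_t) ~ 1`, so `sigma2_g`
#' coincides with the trait's additive genetic variance. A scaled-down
#' architecture (fewer QTL at the same tier fractions) breaks that identity;
#' keeping the per-QTL tiers meaningful then requires
#' `sigma2_g = h2 * var_adj(y) / sum(n_t * gamma_t)`, which this helper
#' computes from the training phenotypes and the simulation configuration.
#'
#' @param pheno the training [phenotype_table()]
#' @param cfg the [sim_config()] that generated the trait
#' @return scalar `sigma2_g` to pass to [mixture_spec()]
#' @export
tier_consistent_sigma2_g <- function(pheno, cfg) {
  denom <- sum(cfg$n_qtl_per_tier * cfg$tier_variances)
  if (denom <= 0) denom <- 1
  cfg$heritability * adjusted_variance(pheno) / denom
}

pop_design <- function(population) {
  pops <- sort(unique(population))
  X <- matrix(1, length(population), 1, dimnames = list(NULL, "intercept"))
  for (k in pops[-1])
    X <- cbind(X, stats::setNames(data.frame(as.numeric(population == k)),
                                  paste0("pop", k)))
  as.matrix(X)
}

#' Simulate a full training/validation study
#'
#' Convenience wrapper running [sim_genotypes()], [sim_classes()],
#' [sim_qtl()] and [sim_phenotypes()], applying the training MAF filter,
#' standardizing the training genotypes and carrying the training centring
#' and scale onto the validation set (the last population).
#'
#' @param cfg a [sim_config()]
#' @param maf_threshold training-set MAF exclusion threshold (strict `<`)
#' @param genotypes optional precomputed [sim_genotypes()] result, so several
#'   traits can share one genome
#' @param qtl_cfg optional separate configuration governing QTL placement and
#'   phenotypes, letting the class layout (annotation structure) differ from
#'   the trait architecture — e.g. uninformative classes over a trait whose
#'   QTL are placed uniformly
#' @return list with `train` (std design `W`, `pheno`, row index), `val`
#'   (std design `W`, true genetic values, phenotypes), `classes` (restricted
#'   to analyzed variants), `truth`, `genes`, `population` and the realized
#'   `analyzed_ids`
#' @export
sim_trait <- function(cfg, maf_threshold = 0.002, genotypes = NULL,
                      qtl_cfg = cfg) {
  gsim <- genotypes %||% sim_genotypes(cfg)
  g <- gsim$genotypes
  classes <- sim_classes(g, cfg)
  truth <- sim_qtl(g, classes, qtl_cfg)
  ph <- sim_phenotypes(g, truth, qtl_cfg, gsim$population)
  npop <- length(cfg$n_per_pop)
  tr_rows <- which(gsim$population < npop)
  va_rows <- which(gsim$population == npop)
  g_tr <- genotype_matrix(g$dosages[tr_rows, , drop = FALSE], g$map,
                          g$individual_ids[tr_rows])
  g_tr <- filter_maf(g_tr, maf_threshold)
  keep <- match(g_tr$map$id, g$map$id)
  std_tr <- standardize_genotypes(g_tr)
  g_va <- genotype_matrix(g$dosages[va_rows, keep, drop = FALSE],
                          g$map[keep, , drop = FALSE],
                          g$individual_ids[va_rows])
  std_va <- apply_standardization(g_va, std_tr)
  cl_keep <- variant_classes(classes$ids[keep],
                             classes$class_labels[classes$class_index][keep],
                             classes$category[keep])
  attr(cl_keep, "genes") <- attr(classes, "genes")
  attr(cl_keep, "region") <- attr(classes, "region")[keep]
  pheno_tr <- phenotype_table(ph$pheno$y[tr_rows], ph$pheno$weights[tr_rows],
                              pop_design(gsim$population[tr_rows]))
  list(train = list(W = std_tr, pheno = pheno_tr, rows = tr_rows),
       val = list(W = std_va, genetic_values = truth$genetic_values[va_rows],
                  y = ph$pheno$y[va_rows], rows = va_rows),
       classes = cl_keep, truth = truth, genes = attr(classes, "genes"),
       population = gsim$population, breed_offset = ph$breed_offset,
       analyzed_ids = g_tr$map$id, cfg = cfg)
}
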
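#' Construct a genotype matrix object
#'
#' Container for individual-by-variant allele dosages (counts of the
#' alternate allele, 0/1/2, `NA` for missing) with variant map information.
#'
#' @param dosages numeric matrix, individuals in rows, variants in columns.
#'   Entries must be in `[0, 2]` or `NA`.
#' @param map data.frame with columns `chrom`, `pos` (1-based base pairs) and
#'   `id`, one row per variant. Positions must be sorted within chromosome.
#' @param individual_ids character vector of row identifiers; defaults to the
#'   rownames of `dosages` or `ind1..indN`.
#' @return an object of class `geno_matrix` with elements `dosages`, `map`
#'   and `individual_ids`.
#' @export
genotype_matrix <- function(dosages, map, individual_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(individual_ids)) {
    individual_ids <- rownames(dosages)
    if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(dosages)))
  }
  stopifnot(is.data.frame(map), all(c("chrom", "pos", "id") %in% names(map)),
            nrow(map) == ncol(dosages))
  map$id <- as.character(map$id)
  if (anyDuplicated(map$id)) stop("variant ids must be unique")
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  if (nrow(dosages) > 0 && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  }
  for (ch in unique(map$chrom)) {
    ps <- map$pos[map$chrom == ch]
    if (is.unsorted(ps)) stop("positions must be sorted within chromosome ", ch)
  }
  if (nrow(dosages) > 0) dimnames(dosages) <- list(individual_ids, map$id)
  else colnames(dosages) <- map$id
  structure(list(dosages = dosages, map = map, individual_ids = individual_ids),
            class = "geno_matrix")
}

#' @export
#' @method print geno_matrix
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d variants (%d missing entries)\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
#' @method dim geno_matrix
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset variants of a genotype matrix
#' @param g a [genotype_matrix()] object
#' @param keep integer or logical index over variants
#' @return a `geno_matrix` restricted to the selected variants
#' @export
subset_variants <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$map[keep, , drop = FALSE],
                  g$individual_ids)
}

#' Read genotypes from PLINK, VCF or a plain delimited matrix
#'
#' @param path file path. For `format = "plink"` give the prefix or any of the
#'   `.bed`/`.bim`/`.fam` file names.
#' @param format one of `"matrix"` (header row of variant ids, first column
#'   the individual id), `"vcf"` (diploid GT field), `"plink"`
#'   (variant-major `.bed` with `.bim`/`.fam`).
#' @return a [genotype_matrix()]; missing genotypes are `NA` (use
#'   [impute_mean()] before analysis).
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf", "plink")) {
  format <- match.arg(format)
  switch(format,
         matrix = read_geno_matrix(path),
         vcf    = read_geno_vcf(path),
         plink  = read_geno_plink(path))
}

read_geno_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("parse error in ", path, ": need id column plus variants")
  ids <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(dos)) stop("parse error in ", path, ": non-numeric dosage values")
  vids <- colnames(dos)
  map <- data.frame(chrom = 1L, pos = seq_along(vids), id = vids,
                    stringsAsFactors = FALSE)
  genotype_matrix(dos, map, ids)
}

read_geno_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0) stop("parse error in ", path, ": no GT records")
  # ploidy check: fields must be a/b or a|b (or single '.' for fully missing)
  split_ok <- grepl("^(\\.|[0-9.]([/|][0-9.]))$", gt) | is.na(gt)
  if (!all(split_ok)) {
    bad <- which(!split_ok, arr.ind = TRUE)[1, ]
    stop("unsupported input: non-diploid GT at record ", rownames(gt)[bad[1]])
  }
  alt_count <- function(s) {
    if (is.na(s) || s == ".") return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    al <- suppressWarnings(as.integer(al))
    if (any(al > 1)) stop("unsupported input: multi-allelic genotype code")
    sum(al)
  }
  dos <- matrix(vapply(gt, alt_count, numeric(1)), nrow = nrow(gt))
  fix <- v@fix  # matrix with CHROM/POS/ID columns even for one record
  ids <- fix[, "ID"]
  unnamed <- is.na(ids) | ids == "."
  ids[unnamed] <- paste0(fix[unnamed, "CHROM"], ":", fix[unnamed, "POS"])
  map <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    id = ids, stringsAsFactors = FALSE)
  genotype_matrix(t(dos), map, colnames(gt))
}

plink_prefix <- function(path) sub("\\.(bed|bim|fam)$", "", path)

read_geno_plink <- function(path) {
  prefix <- plink_prefix(path)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("file not found: ", f)
  bimt <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  famt <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(bimt); n <- nrow(famt)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("parse error in ", bed, ": bad magic bytes")
  if (raw[3] != as.raw(0x01))
    stop("parse error in ", bed, ": only variant-major .bed supported")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * m)
    stop("parse error in ", bed, ": size inconsistent with .bim/.fam")
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  # unpack 2-bit genotypes: 00 -> 2 copies of A1 (counted allele),
  # 10 -> 1, 11 -> 0, 01 -> missing
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  # interleave: rows of `codes` currently grouped by bit-pair, reorder
  idx <- as.vector(t(matrix(seq_len(4 * bpv), nrow = bpv)))
  codes <- codes[idx, , drop = FALSE][seq_len(n), , drop = FALSE]
  lut <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  dos <- matrix(lut[codes + 1L], nrow = n, ncol = m)
  map <- data.frame(chrom = bimt[[1]], pos = as.integer(bimt[[4]]),
                    id = as.character(bimt[[2]]), stringsAsFactors = FALSE)
  genotype_matrix(dos, map, as.character(famt[[2]]))
}

#' Write genotypes to a PLINK .bed/.bim/.fam file set
#'
#' Variant-major encoding; the counted allele is written as A1.
#' @param g a [genotype_matrix()]; missing dosages are encoded as missing.
#' @param prefix output path prefix (writes `prefix.bed`, `.bim`, `.fam`).
#' @return invisibly, the prefix
#' @export
write_plink <- function(g, prefix) {
  dos <- g$dosages
  n <- nrow(dos); m <- ncol(dos)
  enc <- matrix(1L, nrow = 4 * ceiling(n / 4), ncol = m)  # pad = missing? use 0 allele
  code <- dos
  code[] <- ifelse(is.na(dos), 1L, c(3L, 2L, 0L)[dos + 1L])
  enc[seq_len(n), ] <- code
  enc[-seq_len(n), ] <- 0L  # padding bits are zero per format
  bpv <- ceiling(n / 4)
  i4 <- matrix(seq_len(4 * bpv), nrow = 4)
  bytes <- enc[i4[1, ], , drop = FALSE] + 4L * enc[i4[2, ], , drop = FALSE] +
    16L * enc[i4[3, ], , drop = FALSE] + 64L * enc[i4[4, ], , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  utils::write.table(
    data.frame(g$map$chrom, g$map$id, 0, g$map$pos, "A", "G"),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(g$individual_ids, g$individual_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Replace missing dosages by the variant mean
#'
#' @param g a [genotype_matrix()]
#' @return a `geno_matrix` with every missing entry replaced by its column's
#'   mean observed dosage.
#' @export
impute_mean <- function(g) {
  dos <- g$dosages
  miss <- is.na(dos)
  if (!any(miss)) return(g)
  nmiss <- colSums(miss)
  if (any(nmiss == nrow(dos)))
    stop("variant entirely missing: ",
         paste(g$map$id[nmiss == nrow(dos)], collapse = ", "))
  cm <- colMeans(dos, na.rm = TRUE)
  j <- which(miss, arr.ind = TRUE)
  dos[miss] <- cm[j[, 2]]
  genotype_matrix(dos, g$map, g$individual_ids)
}

#' Minor allele frequency per variant
#'
#' `maf_j = min(p_j, 1 - p_j)` with `p_j` the alternate-allele frequency
#' `sum(dosage_j) / (2 n)`.
#'
#' @param g a [genotype_matrix()] with no missing entries
#' @return named numeric vector of MAFs in `[0, 0.5]`
#' @export
compute_maf <- function(g) {
  if (nrow(g$dosages) == 0) stop("empty input: no individuals")
  if (anyNA(g$dosages)) stop("resolve missing genotypes before computing MAF")
  p <- colMeans(g$dosages) / 2
  stats::setNames(pmin(p, 1 - p), g$map$id)
}

#' Filter variants by minor allele frequency
#'
#' Exclusion is strict: variants with `MAF < threshold` are dropped, a variant
#' exactly at the threshold is kept. Order is preserved.
#'
#' @param g a [genotype_matrix()]
#' @param threshold MAF threshold in `[0, 0.5]`
#' @return a `geno_matrix` restricted to variants with `MAF >= threshold`
#' @export
filter_maf <- function(g, threshold = 0.002) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 0.5)
    stop("invalid parameter: threshold must be in [0, 0.5]")
  subset_variants(g, compute_maf(g) >= threshold)
}

r2_window_pairs <- function(dos, idx, r2_threshold) {
  # all pairs (a, b) with a < b in position order and r^2 > threshold
  sub <- dos[, idx, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  mono <- sds == 0
  if (any(mono)) {
    warning("monomorphic variant(s) excluded from r2 computation: ",
            paste(colnames(sub)[mono], collapse = ", "))
  }
  keepc <- which(!mono)
  if (length(keepc) < 2) return(NULL)
  cc <- suppressWarnings(stats::cor(sub[, keepc, drop = FALSE]))
  hits <- which(upper.tri(cc) & cc^2 > r2_threshold, arr.ind = TRUE)
  if (nrow(hits) == 0) return(NULL)
  cbind(idx[keepc[hits[, 1]]], idx[keepc[hits[, 2]]])
}

prune_pass <- function(dos, active, subset_idx, window, step, r2_threshold,
                       drop_rule) {
  # slide windows of `window` variants advanced by `step` over subset_idx
  # (already position-ordered); drop_rule(a, b) returns the index to remove
  removed <- logical(ncol(dos))
  repeat_sub <- subset_idx
  starts <- seq(1L, max(1L, length(repeat_sub) - 1L), by = step)
  for (s in starts) {
    idx <- repeat_sub[s:min(s + window - 1L, length(repeat_sub))]
    idx <- idx[active[idx] & !removed[idx]]
    if (length(idx) < 2) next
    prs <- r2_window_pairs(dos, idx, r2_threshold)
    if (is.null(prs)) next
    for (k in seq_len(nrow(prs))) {
      a <- prs[k, 1]; b <- prs[k, 2]
      if (removed[a] || removed[b]) next
      drop <- drop_rule(a, b)
      if (!is.na(drop)) removed[drop] <- TRUE
    }
    if (s + window - 1L >= length(repeat_sub)) break
  }
  removed
}

#' Sliding-window LD pruning with annotation-category priority
#'
#' Removes one member of every variant pair whose squared genotypic (dosage)
#' correlation exceeds `r2_threshold` within windows of `window` adjacent
#' variants advanced in steps of `step` variants. Pruning runs first within
#' each annotation category, then variants of other categories in high LD
#' with an `NSC` variant are removed, and finally `CHIP` variants in high LD
#' with a `REG` variant are removed. Within a category the variant earlier in
#' position order is retained.
#'
#' @param g a [genotype_matrix()], positions sorted within chromosome
#' @param categories character vector per variant (levels `NSC`, `REG`,
#'   `CHIP`), or `NULL` to treat all variants as one category
#' @param r2_threshold squared-correlation threshold (pairs strictly above it
#'   are pruned)
#' @param window window size in variants
#' @param step window advance in variants
#' @return list with elements `genotypes` (pruned `geno_matrix`) and
#'   `removed` (character vector of removed variant ids)
#' @export
prune_ld <- function(g, categories = NULL, r2_threshold = 0.999,
                     window = 500L, step = 50L) {
  if (window < step) stop("invalid parameter: window must be >= step")
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("invalid parameter: r2_threshold must be in (0, 1]")
  m <- ncol(g$dosages)
  if (is.null(categories)) categories <- rep("CHIP", m)
  stopifnot(length(categories) == m)
  dos <- g$dosages
  active <- rep(TRUE, m)
  ord <- order(match(g$map$chrom, unique(g$map$chrom)), g$map$pos)
  first_by_pos <- function(a, b) if (which(ord == a) < which(ord == b)) b else a
  # pass 1: within category
  for (cat in unique(categories)) {
    sub <- ord[categories[ord] == cat]
    if (length(sub) < 2) next
    rem <- prune_pass(dos, active, sub, window, step, r2_threshold,
                      drop_rule = first_by_pos)
    active[rem] <- FALSE
  }
  # pass 2: REG/CHIP vs NSC, then pass 3: CHIP vs REG
  priority_rule <- function(high) {
    function(a, b) {
      ca <- categories[a]; cb <- categories[b]
      if (ca == high && cb != high) return(b)
      if (cb == high && ca != high) return(a)
      NA_integer_
    }
  }
  if (any(categories == "NSC")) {
    rem <- prune_pass(dos, active, ord[active[ord]], window, step,
                      r2_threshold, drop_rule = priority_rule("NSC"))
    active[rem] <- FALSE
  }
  if (any(categories == "REG")) {
    keep_reg_drop_chip <- function(a, b) {
      ca <- categories[a]; cb <- categories[b]
      if (ca == "REG" && cb == "CHIP") return(b)
      if (cb == "REG" && ca == "CHIP") return(a)
      NA_integer_
    }
    rem <- prune_pass(dos, active, ord[active[ord]], window, step,
                      r2_threshold, drop_rule = keep_reg_drop_chip)
    active[rem] <- FALSE
  }
  list(genotypes = subset_variants(g, active),
       removed = g$map$id[!active])
}

#' Centre and standardize genotype dosages
#'
#' Each column is centred and divided by its sample standard deviation so the
#' design matrix `W` has columns of mean 0 and unit variance. The training
#' means and scales are stored for application to validation genotypes.
#'
#' @param g a [genotype_matrix()] with no missing entries
#' @return an object of class `std_design`: list with `W`, `center`, `scale`
#'   and the variant `map`
#' @export
standardize_genotypes <- function(g) {
  if (anyNA(g$dosages)) stop("resolve missing genotypes before standardizing")
  ctr <- colMeans(g$dosages)
  scl <- apply(g$dosages, 2, stats::sd)
  if (any(scl == 0))
    stop("zero-variance variant(s): ", paste(g$map$id[scl == 0], collapse = ", "),
         " (apply a MAF filter first)")
  W <- sweep(sweep(g$dosages, 2, ctr), 2, scl, "/")
  out <- structure(list(W = W, center = ctr, scale = scl, map = g$map,
                        individual_ids = g$individual_ids),
                   class = "std_design")
  # integer dosages admit a compact one-byte representation that the
  # sampler exploits; fractional (imputed) dosages fall back to dense W
  if (all(g$dosages == round(g$dosages)))
    out$raw_dosages <- as.raw(g$dosages)
  out
}

#' Apply training standardization to new genotypes
#'
#' @param g a [genotype_matrix()] of validation individuals covering the
#'   training variants
#' @param sd a `std_design` from [standardize_genotypes()] on the training set
#' @return a `std_design` for the new individuals using the training centre
#'   and scale
#' @export
apply_standardization <- function(g, sd) {
  missing_ids <- setdiff(sd$map$id, g$map$id)
  if (length(missing_ids))
    stop("validation genotypes lack variants: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  pos <- match(sd$map$id, g$map$id)
  dos <- g$dosages[, pos, drop = FALSE]
  if (anyNA(dos)) stop("resolve missing genotypes before standardizing")
  W <- sweep(sweep(dos, 2, sd$center), 2, sd$scale, "/")
  structure(list(W = W, center = sd$center, scale = sd$scale, map = sd$map,
                 individual_ids = g$individual_ids),
            class = "std_design")
}

#' Variant class map for annotation-informed analysis
#'
#' @param ids character vector of variant ids
#' @param class_label character or factor assigning each variant to exactly
#'   one class
#' @param category optional per-variant annotation category tag (e.g. `NSC`,
#'   `REG`, `CHIP`)
#' @return object of class `variant_classes` with `class_index` (1..C),
#'   `class_labels` and `category`
#' @export
variant_classes <- function(ids, class_label, category = NULL) {
  stopifnot(length(ids) == length(class_label))
  f <- factor(class_label)
  if (nlevels(f) < 1 || anyNA(f)) stop("every variant needs exactly one class")
  if (any(table(f) == 0)) stop("each class must be non-empty")
  structure(list(ids = as.character(ids),
                 class_index = as.integer(f),
                 class_labels = levels(f),
                 category = category),
            class = "variant_classes")
}

#' Read a variant class annotation table
#'
#' TSV with columns `variant_id`, `class_label` and optionally `category`.
#' @param path file path
#' @return a [variant_classes()] object
#' @export
read_classes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "class_label") %in% names(tab)))
  variant_classes(tab$variant_id, tab$class_label,
                  if ("category" %in% names(tab)) tab$category else NULL)
}

#' Phenotype records with weights and fixed-effect design
#'
#' @param y numeric trait values (no missing values for training records)
#' @param weights positive per-record reliability weights `w_j`; the residual
#'   covariance is `diag(1/w_j) * sigma2_e`
#' @param X fixed-effect design matrix (defaults to an intercept); redundant
#'   columns are dropped with a warning
#' @param ids optional record identifiers
#' @return object of class `pheno_table`
#' @export
phenotype_table <- function(y, weights = NULL, X = NULL, ids = NULL) {
  n <- length(y)
  if (anyNA(y)) stop("missing phenotypes are not allowed in training records")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, length(weights) == n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    warning("dropping rank-deficient fixed-effect column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  structure(list(y = as.numeric(y), weights = as.numeric(weights), X = X,
                 ids = ids), class = "pheno_table")
}
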
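#' Read a sire/dam pedigree table
#'
#' TSV with columns `id`, `sire`, `dam`; `"0"`, `NA` or empty fields mean
#' unknown parents.
#' @param path file path
#' @return data.frame with character columns `id`, `sire`, `dam` (`NA` for
#'   unknown)
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("id", "sire", "dam") %in% names(tab)))
  clean <- function(x) { x[x %in% c("0", "", "NA") | is.na(x)] <- NA; x }
  data.frame(id = tab$id, sire = clean(tab$sire), dam = clean(tab$dam),
             stringsAsFactors = FALSE)
}

ped_toposort <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]  # NA when unknown / not in table
  placed <- logical(n)
  order_out <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
  }
  if (length(order_out) < n)
    stop("pedigree error: cycle involving ",
         paste(ped$id[!placed], collapse = ", "))
  order_out
}

#' Numerator relationship matrix from a pedigree
#'
#' Tabular-method recursion: `A_ii = 1 + 0.5 A_{s(i),d(i)}` and
#' `A_ij = 0.5 (A_{j,s(i)} + A_{j,d(i)})`, unknown parents contributing zero
#' (founders treated as unrelated and non-inbred). The input row order does
#' not matter; rows are topologically sorted internally and the result is
#' returned in the input id order.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (see
#'   [read_pedigree()])
#' @return symmetric additive-relationship matrix with dimnames = ids
#' @export
a_matrix <- function(ped) {
  if (anyDuplicated(ped$id)) stop("pedigree error: duplicate id")
  for (col in c("sire", "dam")) {
    unknown_parents <- setdiff(stats::na.omit(ped[[col]]), ped$id)
    if (length(unknown_parents))
      stop("pedigree error: parent(s) not in id column: ",
           paste(unknown_parents, collapse = ", "))
  }
  ord <- ped_toposort(ped)
  ids <- ped$id[ord]
  idx <- stats::setNames(seq_along(ids), ids)
  si <- idx[ped$sire[ord]]; di <- idx[ped$dam[ord]]
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      rel <- numeric(i - 1)
      if (!is.na(s)) rel <- rel + 0.5 * A[j, s]
      if (!is.na(d)) rel <- rel + 0.5 * A[j, d]
      A[j, i] <- rel
      A[i, j] <- rel
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A[ped$id, ped$id, drop = FALSE]
}

#' Factorize a relationship matrix for polygenic sampling
#'
#' Cholesky factor of `A`, adding a small diagonal jitter (1e-8, with a
#' message) if the matrix is numerically semi-definite.
#' @param A relationship matrix
#' @param weights per-record residual weights (diagonal of D)
#' @return list with `L` (lower Cholesky of A), `Q`, `lam` (eigenvectors and
#'   eigenvalues of `L' D L`) used by the sampler's polygenic update
#' @export
factorize_a <- function(A, weights = rep(1, nrow(A))) {
  stopifnot(nrow(A) == ncol(A), length(weights) == nrow(A))
  L <- tryCatch(t(chol(A)), error = function(e) NULL)
  if (is.null(L)) {
    message("relationship matrix not positive definite; adding 1e-8 jitter")
    L <- tryCatch(t(chol(A + diag(1e-8, nrow(A)))), error = function(e)
      stop("relationship matrix not positive definite even after jitter"))
  }
  M <- crossprod(L, L * weights)  # L' D L
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  list(L = L, Q = eg$vectors, lam = pmax(eg$values, 0))
}
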
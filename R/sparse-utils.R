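#' @useDynLib calfgrow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import Matrix
#' @importFrom methods as is new
#' @importFrom stats coef cor lm median optimize pnorm pt qnorm quantile rbinom
#'   rnorm runif sd setNames var optim ks.test
#' @importFrom utils read.csv write.csv read.table write.table modifyList
#' @importFrom tools md5sum
NULL

# Sparse symmetric factorization with selected inversion.
#
# Wraps Matrix's CHOLMOD LDL' factorization and the Takahashi recursion so
# that callers can (a) solve, (b) read off log-determinants, and (c) extract
# arbitrary entries of the matrix inverse that fall inside the factor's
# sparsity pattern -- which covers every entry of the original matrix
# pattern, in particular the additive-genetic block needed for REML traces
# and prediction-error variances.

sparse_factor <- function(M) {
  M <- methods::as(Matrix::forceSymmetric(M), "CsparseMatrix")
  ch <- Matrix::Cholesky(M, LDL = TRUE, perm = TRUE, super = FALSE)
  e <- Matrix::expand2(ch)
  L <- e$L1
  d <- e$D@x
  if (any(d <= 0)) {
    stop("system is singular or indefinite (", sum(d <= 0),
         " non-positive pivot(s)): check for confounded fixed effects ",
         "or empty contemporary groups")
  }
  perm <- ch@perm + 1L  # M[perm, perm] = L D L'
  list(ch = ch, L = L, d = d, perm = perm, ipos = Matrix::invPerm(perm),
       n = nrow(M), zx = NULL)
}

sf_solve <- function(fac, b) {
  as.matrix(Matrix::solve(fac$ch, b, system = "A"))
}

sf_logdet <- function(fac) sum(log(fac$d))

# run the Takahashi recursion once; cached on the returned object
sf_selected_inverse <- function(fac) {
  if (is.null(fac$zx)) {
    L <- fac$L
    fac$zx <- .takahashi_ldl(L@p, L@i, L@x, fac$d)
  }
  fac
}

# entries inv(M)[i, j] for index vectors i, j (original ordering)
sf_inv_entries <- function(fac, i, j) {
  stopifnot(!is.null(fac$zx))
  L <- fac$L
  .sp_lookup_sym(L@p, L@i, fac$zx, fac$ipos[i] - 1L, fac$ipos[j] - 1L)
}

# diagonal of inv(M) for a set of indices
sf_inv_diag <- function(fac, idx = seq_len(fac$n)) {
  sf_inv_entries(fac, idx, idx)
}
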
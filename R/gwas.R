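# Single-marker association of sire transmitting abilities on allele
# dosage, permutation-based genome-wide significance, and GREML variance
# partitioning on a genomic relationship matrix.

#' Marker quality control by call rate
#'
#' Retains SNPs genotyped in strictly more than `min_call` of the cohort
#' (a SNP at exactly the threshold is removed).
#'
#' @param g a `calf_genotypes` object ([simulate_genotypes()] or
#'   [read_plink()]).
#' @param min_call call-rate threshold (fraction).
#' @return The filtered object, with a `qc` element listing removed SNPs.
#' @export
marker_qc <- function(g, min_call = 0.90) {
  call_rate <- 1 - colMeans(is.na(g$dosage))
  keep <- call_rate > min_call
  removed <- data.frame(snp = g$map$snp[!keep], call_rate = call_rate[!keep],
                        stringsAsFactors = FALSE)
  g$dosage <- g$dosage[, keep, drop = FALSE]
  g$map <- g$map[keep, , drop = FALSE]
  g$freq <- g$freq[keep]
  g$qc <- list(min_call = min_call, n_removed = sum(!keep), removed = removed)
  g
}

#' Select the genotyped evaluation cohort
#'
#' Bulls with genotypes, born from `born_from` on, with evaluation
#' reliability strictly above `min_rel`.
#'
#' @param evals data frame with `animal`, `reliability`, `birth_date`.
#' @param genotyped character vector of genotyped animal ids.
#' @param min_rel reliability threshold (strict `>`).
#' @param born_from first eligible birth year.
#' @return Character vector of cohort animal ids.
#' @export
select_cohort <- function(evals, genotyped, min_rel = 0.5, born_from = 1991L) {
  if (!length(genotyped)) {
    warning("empty genotyped set; cohort is empty")
    return(character(0))
  }
  yr <- as.integer(format(as.Date(evals$birth_date), "%Y"))
  keep <- evals$reliability > min_rel & !is.na(yr) & yr >= born_from &
    evals$animal %in% genotyped
  evals$animal[keep]
}

#' Single-marker dosage regression
#'
#' For every SNP, ordinary least-squares regression of the phenotype
#' (sires' transmitting abilities) on allele dosage over the bulls with a
#' non-missing genotype: substitution effect `beta`, coefficient of
#' determination `r2` (squared Pearson correlation), and the two-sided
#' t-test p-value on `n - 2` degrees of freedom.  Monomorphic markers are
#' flagged and not tested.
#'
#' @param ta numeric phenotype vector, aligned with the rows of `dosage`.
#' @param dosage bulls x SNPs dosage matrix (0/1/2, `NA` missing), or a
#'   single SNP vector.
#' @return Data frame: `snp`, `n`, `beta`, `r2`, `p`, `monomorphic`.
#' @export
assoc <- function(ta, dosage) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, ncol = 1)
  m <- ncol(dosage)
  snp <- colnames(dosage)
  if (is.null(snp)) snp <- sprintf("SNP%05d", seq_len(m))
  obs <- !is.na(dosage)
  n <- colSums(obs)
  X0 <- dosage; X0[!obs] <- 0
  sy <- as.numeric(crossprod(obs, ta))
  syy <- as.numeric(crossprod(obs, ta^2))
  sx <- colSums(X0)
  sxx <- colSums(X0^2)
  sxy <- as.numeric(crossprod(X0, ta))
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  cxy <- sxy - sx * sy / n
  mono <- vx <= 0 | n < 3
  beta <- ifelse(mono, NA_real_, cxy / vx)
  r2 <- ifelse(mono | vy <= 0, NA_real_, cxy^2 / (vx * vy))
  tt <- sqrt(pmax(n - 2, 0)) * suppressWarnings(sqrt(r2 / (1 - r2)))
  p <- ifelse(mono, NA_real_, 2 * pt(abs(tt), n - 2, lower.tail = FALSE))
  p[!mono & r2 >= 1] <- 0
  data.frame(snp = snp, n = n, beta = beta, r2 = r2, p = p,
             monomorphic = mono, row.names = NULL, stringsAsFactors = FALSE)
}

#' Genome-wide p-values by max-statistic permutation
#'
#' The phenotype vector is permuted `n_perm` times against the genotype
#' matrix; for each permutation the maximum absolute t statistic across all
#' SNPs is recorded.  A SNP's genome-wide p-value is
#' `(1 + #permutation maxima >= observed |t|) / (n_perm + 1)`, which
#' controls the family-wise error rate under the complete null and is
#' floored at `1/(n_perm + 1)`.  A Bonferroni adjustment of the nominal
#' p-values is reported alongside.
#'
#' @param ta phenotype vector.
#' @param g `calf_genotypes` (QC'd).
#' @param n_perm number of permutations (default 10000; values below 100
#'   give a warning about resolution).
#' @param seed integer seed for the permutation stream.
#' @param chunk permutations processed per matrix operation.
#' @return Data frame: `snp`, `t_obs`, `p_nominal`, `p_bonferroni`,
#'   `p_genomewide`; attribute `perm_max` carries the permutation maxima.
#' @export
max_t_permutation <- function(ta, g, n_perm = 10000L, seed = 1L,
                              chunk = 2000L) {
  if (n_perm < 100) warning("n_perm < 100 gives poor p-value resolution")
  dosage <- g$dosage
  obs <- !is.na(dosage)
  n <- colSums(obs)
  X0 <- dosage; X0[!obs] <- 0
  sx <- colSums(X0)
  sxx <- colSums(X0^2)
  vx <- sxx - sx^2 / n
  usable <- vx > 0 & n >= 3
  t_from_y <- function(Y) {
    # Y: bulls x k phenotype matrix; returns k x m |t| matrix
    sy <- crossprod(Y, obs)            # k x m
    syy <- crossprod(Y^2, obs)
    sxy <- crossprod(Y, X0)
    vy <- syy - sy^2 / rep(n, each = nrow(sy))
    cxy <- sxy - sweep(sy, 2, sx / n, "*")
    r2 <- cxy^2 / sweep(vy, 2, vx, "*")
    r2 <- pmin(r2, 1 - 1e-12)
    abs(sqrt(r2 / (1 - r2)) * rep(sqrt(n - 2), each = nrow(r2)))
  }
  t_obs <- drop(t_from_y(matrix(ta, ncol = 1)))
  t_obs[!usable] <- NA_real_
  set.seed(seed)
  perm_max <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    Y <- vapply(seq_len(k), function(i) ta[sample.int(length(ta))],
                numeric(length(ta)))
    Tm <- t_from_y(Y)[, usable, drop = FALSE]
    perm_max[done + seq_len(k)] <- apply(Tm, 1, max)
    done <- done + k
  }
  p_gw <- vapply(t_obs, function(t0)
    if (is.na(t0)) NA_real_ else (1 + sum(perm_max >= t0)) / (n_perm + 1),
    numeric(1))
  df <- n - 2
  p_nom <- 2 * pt(t_obs, df, lower.tail = FALSE)
  out <- data.frame(snp = g$map$snp, t_obs = t_obs, p_nominal = p_nom,
                    p_bonferroni = pmin(p_nom * sum(usable), 1),
                    p_genomewide = p_gw, stringsAsFactors = FALSE)
  attr(out, "perm_max") <- perm_max
  out
}

#' Genomic relationship matrix
#'
#' Two estimators with observed allele frequencies.  `"gcta"` (the default,
#' and the default of the GCTA toolkit) standardizes each SNP:
#' `G_jk = mean_i (x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i (1 - p_i))`, i.e. it
#' assumes equal variance explained per SNP.  `"vanraden1"` pools the
#' denominator: `G = W W' / (2 * sum p_i (1 - p_i))` with `W` the
#' column-centred dosage matrix.  Missing dosages are imputed to the
#' per-SNP mean (zero after centring).  Under Hardy-Weinberg both have
#' diagonals near `1 + F` and row means near zero.
#'
#' @param g `calf_genotypes` (QC'd).
#' @param method `"gcta"` (per-SNP standardization) or `"vanraden1"`.
#' @return List of class `calf_grm`: `G` (bulls x bulls), `freq`,
#'   `n_snps`, `method`.
#' @export
build_grm <- function(g, method = c("gcta", "vanraden1")) {
  method <- match.arg(method)
  X <- g$dosage
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs")
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  W <- sweep(X, 2, 2 * p)
  W[is.na(W)] <- 0
  G <- if (method == "gcta") {
    tcrossprod(sweep(W, 2, sqrt(2 * p * (1 - p)), "/")) / ncol(X)
  } else {
    tcrossprod(W) / (2 * sum(p * (1 - p)))
  }
  structure(list(G = G, freq = p, n_snps = ncol(X), method = method),
            class = "calf_grm")
}

#' GREML: fraction of phenotypic variance captured by all SNPs
#'
#' Single-component REML of `var(y) = G sigma2_g + I sigma2_e` with an
#' intercept, solved exactly through the eigendecomposition of the genomic
#' relationship matrix: the likelihood is profiled on the variance ratio
#' and maximized by 1-D search, and standard errors come from the observed
#' information of `(sigma2_g, sigma2_e)` with the fraction's SE by the
#' delta method.  A non-positive-semi-definite G is bent by shifting its
#' eigenvalues (reported).
#'
#' @param ta phenotype vector (transmitting abilities).
#' @param grm `calf_grm` or a symmetric matrix.
#' @return List: `fraction` (sigma2_g / (sigma2_g + sigma2_e)), `se`,
#'   `sigma2_g`, `sigma2_e`, `se_components`, `loglik`, `bent`.
#' @export
greml <- function(ta, grm) {
  G <- if (inherits(grm, "calf_grm")) grm$G else as.matrix(grm)
  n <- length(ta)
  stopifnot(nrow(G) == n)
  eg <- eigen(G, symmetric = TRUE)
  bent <- FALSE
  if (min(eg$values) < -1e-8 * max(eg$values)) {
    bent <- TRUE
    eg$values <- eg$values - min(eg$values) + 1e-8 * max(eg$values)
  }
  lam <- pmax(eg$values, 1e-12)
  U <- eg$vectors
  ys <- as.numeric(crossprod(U, ta))
  xs <- as.numeric(crossprod(U, rep(1, n)))
  # profiled REML in the rotated basis: V = sigma2_e * (gamma * lam + 1)
  prof <- function(lgamma) {
    gam <- exp(lgamma)
    d <- gam * lam + 1
    xvx <- sum(xs^2 / d)
    bhat <- sum(xs * ys / d) / xvx
    r <- ys - bhat * xs
    ypy <- sum(r^2 / d)
    s2e <- ypy / (n - 1)
    -0.5 * (sum(log(d)) + log(xvx) + (n - 1) * log(s2e) + (n - 1))
  }
  opt <- optimize(prof, c(-20, 20), maximum = TRUE, tol = 1e-10)
  gam <- exp(opt$maximum)
  d <- gam * lam + 1
  xvx <- sum(xs^2 / d)
  bhat <- sum(xs * ys / d) / xvx
  r <- ys - bhat * xs
  s2e <- sum(r^2 / d) / (n - 1)
  s2g <- gam * s2e
  # observed information on (s2g, s2e) by numerical differentiation of the
  # unprofiled restricted likelihood
  ll2 <- function(th) {
    dd <- th[1] * lam + th[2]
    xvx2 <- sum(xs^2 / dd)
    b2 <- sum(xs * ys / dd) / xvx2
    rr <- ys - b2 * xs
    -0.5 * (sum(log(dd)) + log(xvx2) + sum(rr^2 / dd))
  }
  th <- c(s2g, s2e)
  eps <- pmax(th, 1e-6) * 1e-4
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- replace(numeric(2), i, eps[i]); ej <- replace(numeric(2), j, eps[j])
    H[i, j] <- (ll2(th + ei + ej) - ll2(th + ei - ej) -
                  ll2(th - ei + ej) + ll2(th - ei - ej)) / (4 * eps[i] * eps[j])
  }
  vcov <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, 2, 2))
  tot <- s2g + s2e
  grad_frac <- c(s2e, -s2g) / tot^2
  se_frac <- sqrt(max(0, t(grad_frac) %*% vcov %*% grad_frac))
  list(fraction = s2g / tot, se = as.numeric(se_frac),
       sigma2_g = s2g, sigma2_e = s2e,
       se_components = sqrt(pmax(diag(vcov), 0)),
       loglik = opt$objective, bent = bent)
}
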
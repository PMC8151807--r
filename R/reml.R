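# REML estimation of (sigma2_a, sigma2_p, sigma2_e) for the repeatability
# animal model, by EM steps and average-information (AI) Newton steps on the
# sparse mixed-model equations.
#
# Throughout, M denotes the MME coefficient matrix on the "lambda" scale
# (every block divided by sigma2_e), C = M^{-1}, and the restricted
# log-likelihood is, up to a constant,
#
#   -2 l = log|M| + q_a log s2a + q_p log s2p
#          + (n - p - q_a - q_p) log s2e + log|A| + y'Py
#
# with y'Py = (y'y - sol'rhs) / s2e.  The traces needed by both the EM
# updates and the gradient,
#   tr(A^{-1} C^{aa})  and  tr(C^{pp}),
# are computed exactly from the selected inverse of M (Takahashi recursion
# on the sparse LDL' factor), the same quantities a dense inversion would
# give.  Unknown-parent groups enter REML as fixed covariates (expected
# group fractions), keeping A non-singular.

reml_inner <- function(sys, theta) {
  vc <- list(sigma2_a = theta[1], sigma2_p = theta[2], sigma2_e = theta[3])
  mm <- mme_matrix(sys, vc)
  fac <- sparse_factor(mm$M)
  sol <- as.numeric(sf_solve(fac, mm$rhs))
  p <- mm$p; qa <- mm$qa; qp <- mm$qp
  n <- sys$nrec
  uhat <- sol[p + seq_len(qa)]
  phat <- sol[p + qa + seq_len(qp)]
  yy <- sum(sys$y^2)
  ypy_s2e <- yy - sum(sol * mm$rhs)          # = y'Py * s2e
  fac <- sf_selected_inverse(fac)
  # tr(A^{-1} C^{aa}): sum over the nonzero pattern of A^{-1}
  ainv <- methods::as(methods::as(sys$ainv, "generalMatrix"), "TsparseMatrix")
  caa <- sf_inv_entries(fac, p + ainv@i + 1L, p + ainv@j + 1L)
  tr_aicaa <- sum(ainv@x * caa)
  tr_cpp <- sum(sf_inv_diag(fac, p + qa + seq_len(qp)))
  uau <- sum(uhat * as.numeric(sys$ainv %*% uhat))
  pp <- sum(phat^2)
  s2a <- theta[1]; s2p <- theta[2]; s2e <- theta[3]
  m2ll <- sf_logdet(fac) + qa * log(s2a) + qp * log(s2p) +
    (n - p - qa - qp) * log(s2e) + sys$logdetA + ypy_s2e / s2e
  list(sol = sol, uhat = uhat, phat = phat, p = p, qa = qa, qp = qp, n = n,
       ypy_s2e = ypy_s2e, tr_aicaa = tr_aicaa, tr_cpp = tr_cpp,
       uau = uau, pp = pp, loglik = -0.5 * m2ll, mm = mm, fac = fac)
}

reml_em_update <- function(st, theta) {
  s2e <- theta[3]
  c(a = (st$uau + st$tr_aicaa * s2e) / st$qa,
    p = (st$pp + st$tr_cpp * s2e) / st$qp,
    e = st$ypy_s2e / (st$n - st$p))
}

reml_gradient <- function(st, theta) {
  s2a <- theta[1]; s2p <- theta[2]; s2e <- theta[3]
  tr_pva <- (st$qa - (s2e / s2a) * st$tr_aicaa) / s2a
  tr_pvp <- (st$qp - (s2e / s2p) * st$tr_cpp) / s2p
  tr_p <- (st$n - st$p - st$qa - st$qp +
             (s2e / s2a) * st$tr_aicaa + (s2e / s2p) * st$tr_cpp) / s2e
  ypvapy <- st$uau / s2a^2
  ypvppy <- st$pp / s2p^2
  ypvepy <- st$ypy_s2e / s2e^2 -
    (st$uau / s2a + st$pp / s2p) / s2e   # e'e/s2e^2 via y'Py decomposition
  # y'P V_e P y = e'e / s2e^2 with e = y - X b - Za u - Zp p;
  # y'Py = (e'e + u'Ainv u * s2e/s2a + p'p * s2e/s2p)/s2e  =>  rearranged above
  c(a = -0.5 * (tr_pva - ypvapy),
    p = -0.5 * (tr_pvp - ypvppy),
    e = -0.5 * (tr_p - ypvepy))
}

reml_ai_matrix <- function(sys, st, theta) {
  s2a <- theta[1]; s2p <- theta[2]; s2e <- theta[3]
  ehat <- sys$y - as.numeric(sys$X %*% st$sol[seq_len(st$p)]) -
    as.numeric(sys$Za %*% st$uhat) - as.numeric(sys$Zp %*% st$phat)
  Fm <- cbind(a = as.numeric(sys$Za %*% st$uhat) / s2a,
              p = as.numeric(sys$Zp %*% st$phat) / s2p,
              e = ehat / s2e)
  # P f = (f - X bt - Za ut - Zp pt)/s2e with (bt, ut, pt) the MME solution
  # for pseudo-data f
  rhsF <- rbind(Matrix::t(sys$X) %*% Fm, Matrix::t(sys$Za) %*% Fm,
                Matrix::t(sys$Zp) %*% Fm)
  solF <- sf_solve(st$fac, as.matrix(rhsF))
  fitted <- as.matrix(sys$X %*% solF[seq_len(st$p), , drop = FALSE] +
                        sys$Za %*% solF[st$p + seq_len(st$qa), , drop = FALSE] +
                        sys$Zp %*% solF[st$p + st$qa + seq_len(st$qp), , drop = FALSE])
  PF <- (Fm - fitted) / s2e
  0.5 * crossprod(Fm, PF)
}

#' REML variance components for the repeatability animal model
#'
#' Estimates additive-genetic, permanent-environment and residual variances
#' for edited yearling-gain records under the animal model with
#' herd-year-season and age fixed effects, using the pedigree relationship
#' matrix.  Iterations start with EM steps (guaranteed likelihood ascent)
#' and switch to average-information Newton steps; an AI step that leaves
#' the parameter space falls back to EM for that round, and a component
#' collapsing to zero is pinned at a small positive bound and reported.
#' Standard errors come from the inverse AI matrix at convergence.
#'
#' @param records edited record table ([apply_edits()]).
#' @param ped pedigree.
#' @param groups optional unknown-parent group assignment; enters as fixed
#'   group-fraction covariates.
#' @param init optional starting values `c(a, p, e)`; default splits the
#'   phenotypic variance equally.
#' @param algorithm `"AI"` (EM warmup then AI, the default) or `"EM"`.
#' @param max_iter,tol iteration cap and relative-change convergence
#'   tolerance.
#' @param em_warmup number of EM steps before AI updates.
#' @param label analysis label stored on the result.
#' @param verbose print the iteration trace.
#' @return A [new_vc()] object with standard errors, asymptotic covariance,
#'   log-likelihood, and the iteration trajectory in `$trajectory`.
#' @export
reml_estimate <- function(records, ped, groups = NULL, init = NULL,
                          algorithm = c("AI", "EM"), max_iter = 200L,
                          tol = 1e-6, em_warmup = 3L,
                          label = "combined", verbose = FALSE) {
  algorithm <- match.arg(algorithm)
  ped <- ensure_sorted(ped)
  sys <- mme_system(records, ped, groups = groups, group_mode = "covariate")
  sys$logdetA <- sum(log(mendelian_d(ped)))
  vy <- var(sys$y)
  theta <- if (is.null(init)) rep(vy / 3, 3) else unname(init)
  if (length(theta) != 3 || any(theta <= 0)) stop("init must be 3 positive variances")
  lb <- vy * 1e-6
  pinned <- character(0)
  traj <- matrix(NA_real_, max_iter, 5,
                 dimnames = list(NULL, c("sigma2_a", "sigma2_p", "sigma2_e",
                                         "loglik", "step")))
  st <- NULL
  for (it in seq_len(max_iter)) {
    st <- reml_inner(sys, theta)
    use_ai <- algorithm == "AI" && it > em_warmup
    step_kind <- 1  # EM
    theta_new <- NULL
    if (use_ai) {
      gr <- reml_gradient(st, theta)
      AI <- reml_ai_matrix(sys, st, theta)
      dir <- try(solve(AI, gr), silent = TRUE)
      if (!inherits(dir, "try-error") && all(is.finite(dir))) {
        for (damp in 2^-(0:4)) {     # step-halving keeps the step admissible
          cand <- theta + damp * as.numeric(dir)
          if (all(cand > 0)) { theta_new <- cand; step_kind <- 2; break }
        }
      }
    }
    if (is.null(theta_new)) theta_new <- unname(reml_em_update(st, theta))
    low <- theta_new < lb
    if (any(low)) {
      pinned <- union(pinned, c("a", "p", "e")[low])
      theta_new[low] <- lb
    }
    traj[it, ] <- c(theta, st$loglik, step_kind)
    delta <- max(abs(theta_new - theta) / pmax(theta, lb))
    if (verbose)
      message(sprintf("it %3d  [%s]  a=%.2f p=%.2f e=%.2f  logL=%.4f  d=%.2e",
                      it, c("EM", "AI")[step_kind], theta[1], theta[2],
                      theta[3], st$loglik, delta))
    theta <- theta_new
    if (delta < tol) {
      st <- reml_inner(sys, theta)
      AI <- reml_ai_matrix(sys, st, theta)
      vcov <- try(solve(AI), silent = TRUE)
      if (inherits(vcov, "try-error")) vcov <- matrix(NA_real_, 3, 3)
      se <- sqrt(pmax(diag(vcov), 0))
      names(se) <- c("a", "p", "e")
      dimnames(vcov) <- list(c("a", "p", "e"), c("a", "p", "e"))
      out <- new_vc(theta[1], theta[2], theta[3], se = se, vcov = vcov,
                    label = label)
      out$loglik <- st$loglik
      out$iterations <- it
      out$trajectory <- traj[seq_len(it), , drop = FALSE]
      out$pinned <- pinned
      out$converged <- TRUE
      if (length(pinned))
        message("components pinned at lower bound: ", paste(pinned, collapse = ", "))
      return(out)
    }
  }
  cond <- simpleError(sprintf(
    "REML did not converge in %d iterations (last relative change above %g)",
    max_iter, tol))
  cond$trajectory <- traj
  stop(cond)
}

#' Restricted log-likelihood for given variance components
#'
#' Evaluates the REML log-likelihood (up to an additive constant) of the
#' repeatability animal model at fixed variances, using sparse
#' log-determinant identities on the mixed-model equations.  Useful for
#' profiling and grid cross-checks of [reml_estimate()].
#'
#' @inheritParams reml_estimate
#' @param theta numeric `c(sigma2_a, sigma2_p, sigma2_e)`.
#' @return Scalar log-likelihood.
#' @export
reml_loglik <- function(records, ped, theta, groups = NULL) {
  ped <- ensure_sorted(ped)
  sys <- mme_system(records, ped, groups = groups, group_mode = "covariate")
  sys$logdetA <- sum(log(mendelian_d(ped)))
  reml_inner(sys, unname(theta))$loglik
}
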
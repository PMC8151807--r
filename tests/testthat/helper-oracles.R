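# Shared fixtures and independent dense oracles for the property tests.
# Everything here is deliberately naive (tabular A, explicit V = ZGZ' + R
# generalized least squares, dense restricted likelihood) so the sparse
# production paths are checked against straight-line linear algebra.

rand_ped <- function(n, seed, miss = 0) {
  set.seed(seed)
  animal <- sprintf("A%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- rep_len(c("M", "F"), n)
  for (i in 3:n) {
    prev_m <- animal[which(sex[seq_len(i - 1)] == "M")]
    prev_f <- animal[which(sex[seq_len(i - 1)] == "F")]
    if (length(prev_m) && runif(1) > miss) sire[i] <- sample(prev_m, 1)
    if (length(prev_f) && runif(1) > miss) dam[i] <- sample(prev_f, 1)
  }
  data.frame(animal, sire, dam, sex,
             birth_date = as.Date("2000-01-01") + 30 * seq_len(n),
             stringsAsFactors = FALSE)
}

# flat-surface simulation config: equal sexes, no HYS noise, no age curve
flat_cfg <- function(seed, sa, sp, se, ..., mean_yg = 400, hys_sd = 0,
                     age_effects = list(M = c(0, 0, 0), F = c(0, 0, 0))) {
  sim_config(sigma2_a_m = sa, sigma2_a_f = sa, sigma2_p_m = sp,
             sigma2_p_f = sp, sigma2_e_m = se, sigma2_e_f = se,
             mean_yg_m = mean_yg, mean_yg_f = mean_yg, hys_sd = hys_sd,
             age_effects = age_effects, seed = seed, ...)
}

sim_dataset <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  truth <- simulate_true_values(ped, cfg)
  rec <- apply_edits(simulate_weight_records(ped, truth, cfg), ped)$records
  list(ped = ped, truth = truth, rec = rec)
}

# dense GLS oracle for the animal model with PE, per-record weights and
# sex-specific PE variances
dense_gls <- function(sys, vc, w = NULL) {
  if (is.null(w)) w <- rep(1, sys$nrec)
  Za <- as.matrix(sys$Za); Zp <- as.matrix(sys$Zp); X <- as.matrix(sys$X)
  nan <- sys$n_animals
  G <- attr(sys, "A_dense") * vc$sigma2_a
  s2p <- vc$sigma2_p
  pvar <- if (length(s2p) == 1 && is.null(names(s2p))) rep(s2p, ncol(Zp))
          else unname(s2p[sys$pe_sex])
  V <- Za[, seq_len(nan)] %*% G %*% t(Za[, seq_len(nan)]) +
    Zp %*% (pvar * t(Zp)) + diag(vc$sigma2_e / w)
  Vi <- solve(V)
  XtVX <- solve(t(X) %*% Vi %*% X)
  bhat <- XtVX %*% t(X) %*% Vi %*% sys$y
  uhat <- G %*% t(Za[, seq_len(nan)]) %*% Vi %*% (sys$y - X %*% bhat)
  P <- Vi - Vi %*% X %*% XtVX %*% t(X) %*% Vi
  pev <- diag(G - G %*% t(Za[, seq_len(nan)]) %*% P %*% Za[, seq_len(nan)] %*% G)
  list(b = as.numeric(bhat), u = as.numeric(uhat), pev = pev)
}

mme_with_dense_A <- function(rec, ped, ...) {
  sys <- mme_system(rec, ped, ...)
  attr(sys, "A_dense") <- a_matrix(ped)
  sys
}

# dense restricted log-likelihood for homogeneous variances (no groups)
dense_reml_ll <- function(sys, ped, theta) {
  Za <- as.matrix(sys$Za); Zp <- as.matrix(sys$Zp); X <- as.matrix(sys$X)
  G <- a_matrix(ped) * theta[1]
  V <- Za %*% G %*% t(Za) + Zp %*% t(Zp) * theta[2] + diag(nrow(Za)) * theta[3]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            t(sys$y) %*% P %*% sys$y)[1]
}
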
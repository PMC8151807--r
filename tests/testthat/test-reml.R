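test_that("Table-3-style heritability and repeatability arithmetic", {
  combined <- new_vc(591, 622, 488)
  expect_equal(heritability(combined), 591 / 1701)
  expect_equal(repeatability(combined), 1213 / 1701)
  # the printed male total (2102) is off by one from the printed component
  # sum (574 + 1030 + 497 = 2101): component rounding; the printed ratio
  # 0.763 is reproduced either way
  males <- new_vc(574, 1030, 497)
  expect_equal(round(repeatability(males), 3), 0.763)
  females <- new_vc(489, 407, 484)
  expect_equal(repeatability(females), 896 / 1380)
  expect_equal(heritability(new_vc(0, 10, 10)), 0)
  expect_equal(heritability(new_vc(5, 0, 0)), 1)
  # identities
  vc <- new_vc(runif(1, 100, 900), runif(1, 100, 900), runif(1, 100, 900))
  expect_equal(heritability(vc) + (vc$sigma2_p + vc$sigma2_e) / vc_total(vc), 1)
  expect_gte(repeatability(vc), heritability(vc))
  expect_error(heritability(new_vc(0, 0, 0)), "positive")
})

small_reml_data <- function(seed = 11) {
  cfg <- flat_cfg(seed, 500, 300, 400, n_founders = 60, n_generations = 2,
                  n_herds = 2, hys_sd = 6,
                  records_per_animal = c(0, .5, .5, 0, 0))
  sim_dataset(cfg)
}

test_that("EM iterations never decrease the restricted likelihood", {
  dat <- small_reml_data()
  sys <- mme_system(dat$rec, dat$ped, group_mode = "covariate")
  sys$logdetA <- sum(log(calfgrow:::mendelian_d(dat$ped)))
  theta <- c(150, 700, 700)  # start far from truth
  lls <- numeric(12)
  for (i in 1:12) {
    st <- calfgrow:::reml_inner(sys, theta)
    lls[i] <- st$loglik
    theta <- unname(calfgrow:::reml_em_update(st, theta))
  }
  expect_true(all(diff(lls) >= -1e-9))
})

test_that("sparse restricted likelihood equals the dense formula", {
  dat <- small_reml_data(13)
  sys <- mme_system(dat$rec, dat$ped, group_mode = "covariate")
  sys$logdetA <- sum(log(calfgrow:::mendelian_d(dat$ped)))
  for (theta in list(c(500, 300, 400), c(120, 800, 650))) {
    sparse_ll <- calfgrow:::reml_inner(sys, theta)$loglik
    expect_equal(sparse_ll, dense_reml_ll(sys, dat$ped, theta),
                 tolerance = 1e-8)
  }
})

test_that("AI and EM converge to the same optimum, beating a likelihood grid", {
  dat <- small_reml_data(17)
  fit_ai <- reml_estimate(dat$rec, dat$ped, algorithm = "AI", tol = 1e-8)
  fit_em <- reml_estimate(dat$rec, dat$ped, algorithm = "EM", tol = 1e-7,
                          max_iter = 3000)
  expect_true(fit_ai$converged && fit_em$converged)
  expect_equal(fit_ai$sigma2_a, fit_em$sigma2_a, tolerance = 0.01)
  expect_equal(fit_ai$sigma2_p, fit_em$sigma2_p, tolerance = 0.01)
  expect_equal(fit_ai$sigma2_e, fit_em$sigma2_e, tolerance = 0.01)
  # the optimum dominates a coarse grid around it (independent check via
  # the dense likelihood)
  sys <- mme_system(dat$rec, dat$ped, group_mode = "covariate")
  ll_hat <- dense_reml_ll(sys, dat$ped,
                          c(fit_ai$sigma2_a, fit_ai$sigma2_p, fit_ai$sigma2_e))
  for (mult in list(c(1.3, 1, 1), c(0.7, 1, 1), c(1, 1.3, 1), c(1, 0.7, 1),
                    c(1, 1, 1.3), c(1, 1, 0.7))) {
    th <- c(fit_ai$sigma2_a, fit_ai$sigma2_p, fit_ai$sigma2_e) * mult
    expect_lt(dense_reml_ll(sys, dat$ped, th), ll_hat + 1e-6)
  }
})

test_that("a zero additive component is recovered at the boundary", {
  # truth sigma2_a = 0: the median estimate over replicates stays tiny
  ests <- vapply(1:8, function(s) {
    cfg <- flat_cfg(400 + s, 0, 500, 500, n_founders = 150, n_generations = 2,
                    n_herds = 2, hys_sd = 5,
                    records_per_animal = c(0, 1, 0, 0, 0))
    dat <- sim_dataset(cfg)
    fit <- suppressMessages(reml_estimate(dat$rec, dat$ped, tol = 1e-4))
    fit$sigma2_a / vc_total(fit)
  }, numeric(1))
  expect_lt(median(ests), 0.05)
})

test_that("REML recovers simulation truth within confidence bounds", {
  # moderate-size calibration: estimates should sit within ~2 SE of truth
  cfg <- flat_cfg(51, 500, 300, 400, n_founders = 150, n_generations = 2,
                  offspring_per_dam = 3, n_herds = 2, hys_sd = 6,
                  records_per_animal = 2)
  dat <- sim_dataset(cfg)
  fit <- reml_estimate(dat$rec, dat$ped)
  expect_lt(abs(fit$sigma2_a - 500), 3 * fit$se["a"])
  expect_lt(abs(fit$sigma2_p - 300), 3 * fit$se["p"])
  expect_lt(abs(fit$sigma2_e - 400), 3 * fit$se["e"])
})

test_that("interval coverage over replicates is near nominal", {
  # 12 replicates at one condition; >= 9 of 12 truths inside +-2 SE per
  # component (binomial bound for nominal ~95 %)
  hits <- matrix(NA, 12, 3)
  for (s in 1:12) {
    cfg <- flat_cfg(600 + s, 500, 300, 400, n_founders = 100,
                    n_generations = 2, offspring_per_dam = 3, n_herds = 2,
                    hys_sd = 6, records_per_animal = 2)
    dat <- sim_dataset(cfg)
    fit <- suppressMessages(reml_estimate(dat$rec, dat$ped, tol = 1e-5))
    hits[s, ] <- abs(c(fit$sigma2_a, fit$sigma2_p, fit$sigma2_e) -
                       c(500, 300, 400)) <= 2 * fit$se
  }
  expect_gte(min(colSums(hits)), 9)
})

test_that("non-convergence raises an error carrying the trajectory", {
  dat <- small_reml_data(19)
  err <- tryCatch(reml_estimate(dat$rec, dat$ped, algorithm = "EM",
                                max_iter = 3L, tol = 1e-12),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "did not converge")
  expect_true(is.matrix(err$trajectory))
})
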
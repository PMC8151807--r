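fake_geno <- function(X, chr = NULL) {
  m <- ncol(X)
  colnames(X) <- sprintf("SNP%05d", seq_len(m))
  structure(list(dosage = X,
                 map = data.frame(snp = colnames(X),
                                  chr = chr %||% rep(1L, m),
                                  bp = seq_len(m) * 1000L),
                 freq = colMeans(X, na.rm = TRUE) / 2),
            class = "calf_genotypes")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("marker QC applies a strict >90% call-rate rule", {
  set.seed(1)
  X <- matrix(rbinom(200 * 10, 2, 0.4), 200, 10)
  X[1:20, 2] <- NA      # call rate exactly 0.90 -> removed
  X[1:21, 3] <- NA      # 0.895 -> removed
  X[1:19, 4] <- NA      # 0.905 -> retained
  g <- marker_qc(fake_geno(X), min_call = 0.90)
  expect_setequal(g$qc$removed$snp, c("SNP00002", "SNP00003"))
  expect_equal(ncol(g$dosage), 8)
  # no missing data: unchanged
  g2 <- marker_qc(fake_geno(matrix(rbinom(100, 2, 0.5), 50, 2)))
  expect_equal(g2$qc$n_removed, 0)
})

test_that("cohort selection applies strict reliability and birth-year bounds", {
  evals <- data.frame(animal = c("A", "B", "C", "D", "E"),
                      reliability = c(0.5, 0.51, 0.9, 0.9, 0.9),
                      birth_date = as.Date(c("1995-01-01", "1995-01-01",
                                             "1990-12-31", "1991-01-01",
                                             "1995-01-01")))
  got <- select_cohort(evals, genotyped = c("A", "B", "C", "D"))
  expect_setequal(got, c("B", "D"))  # A rel==0.5 out, C born 1990 out, E not genotyped
  expect_warning(out <- select_cohort(evals, genotyped = character(0)), "empty")
  expect_length(out, 0)
})

test_that("assoc matches a hand-computed OLS on an 8-bull fixture", {
  x <- c(0, 1, 2, 1, 0, 2, 1, 1)
  y <- c(2.1, 3.0, 4.2, 2.8, 1.9, 4.5, 3.1, 2.7)
  out <- assoc(y, x)
  beta_hand <- cov(x, y) / var(x)
  r2_hand <- cor(x, y)^2
  t_hand <- cor(x, y) * sqrt(6 / (1 - r2_hand))
  expect_equal(out$beta, beta_hand, tolerance = 1e-12)
  expect_equal(out$r2, r2_hand, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(abs(t_hand), 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # exact linear relation
  lin <- assoc(2 * x + 1, x)
  expect_equal(lin$r2, 1)
  expect_equal(lin$p, 0)
  # monomorphic flagged, not tested
  mono <- assoc(y, rep(2, 8))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$beta))
})

test_that("assoc handles missing dosages per marker and the R2/t identity", {
  set.seed(2)
  X <- matrix(rbinom(300 * 20, 2, 0.3), 300, 20)
  X[sample(length(X), 400)] <- NA
  y <- rnorm(300)
  out <- assoc(y, X)
  expect_equal(out$n, colSums(!is.na(X)))
  k <- 7  # spot-check one marker against stats::lm on complete cases
  cc <- !is.na(X[, k])
  fit <- lm(y[cc] ~ X[cc, k])
  expect_equal(out$beta[k], unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(out$r2[k], summary(fit)$r.squared, tolerance = 1e-10)
  # algebraic identity R2 = t^2/(t^2 + n - 2) for every marker
  tt <- sqrt(out$r2 * (out$n - 2) / (1 - out$r2))
  expect_equal(out$r2, tt^2 / (tt^2 + out$n - 2), tolerance = 1e-10)
})

test_that("null nominal p-values are uniform (KS over 2000 null markers)", {
  set.seed(3)
  g <- simulate_genotypes(geno_sim_config(n_bulls = 150, n_snps = 2000,
                                          seed = 31), rnorm(150))
  p <- assoc(g$ta, g$dosage)$p
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("max-t permutation floors, degenerates and relabels correctly", {
  set.seed(4)
  n <- 60
  x <- rbinom(n, 2, 0.4)
  y <- 2 * (x - mean(x)) + rnorm(n, 0, 0.4)  # overwhelming signal
  X <- cbind(x, matrix(rbinom(n * 5, 2, 0.4), n, 5))
  g <- fake_geno(X)
  pm <- max_t_permutation(y, g, n_perm = 500, seed = 1)
  expect_equal(pm$p_genomewide[1], 1 / 501)          # exceeds all permutations
  expect_true(all(pm$p_genomewide >= pm$p_nominal - 1e-12))
  expect_true(all(pm$p_genomewide >= 1 / 501))

  # single-SNP family: genome-wide p equals the single-marker permutation p
  g1 <- fake_geno(X[, 1, drop = FALSE])
  pm1 <- max_t_permutation(y, g1, n_perm = 500, seed = 9)
  t_perm <- replicate(500, abs(cor(sample(y), X[, 1])))
  # same construction, same convention
  expect_equal(pm1$p_genomewide,
               (1 + sum(t_perm >= abs(cor(y, X[, 1])) - 1e-12)) / 501,
               tolerance = 0.05)

  # joint relabeling of bulls leaves the observed statistics unchanged
  # exactly and the permutation p-values unchanged in distribution
  perm <- sample.int(n)
  g_rel <- fake_geno(X[perm, ])
  pm_rel <- max_t_permutation(y[perm], g_rel, n_perm = 500, seed = 1)
  expect_equal(pm_rel$t_obs, pm$t_obs, tolerance = 1e-10)
  expect_equal(pm_rel$p_genomewide, pm$p_genomewide, tolerance = 0.08)
})

test_that("GRM matches hand arithmetic, clones and HWE expectations", {
  # 4 bulls x 3 SNPs hand fixture
  X <- rbind(c(0, 1, 2), c(1, 1, 0), c(2, 0, 1), c(1, 2, 1))
  p <- colMeans(X) / 2
  W <- sweep(X, 2, 2 * p)
  Ghand_vr <- W %*% t(W) / (2 * sum(p * (1 - p)))
  g_vr <- build_grm(fake_geno(X), method = "vanraden1")
  expect_equal(g_vr$G, Ghand_vr, ignore_attr = TRUE)
  Ws <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  Ghand_std <- Ws %*% t(Ws) / 3
  g_std <- build_grm(fake_geno(X))   # gcta standardization is the default
  expect_equal(g_std$G, Ghand_std, ignore_attr = TRUE)

  # duplicated individual: off-diagonal ~ diagonal
  set.seed(5)
  Xc <- matrix(rbinom(50 * 400, 2, runif(400, 0.1, 0.5)), 50, 400, byrow = TRUE)
  Xc[2, ] <- Xc[1, ]
  gc <- build_grm(fake_geno(Xc))
  expect_equal(gc$G[1, 2], gc$G[1, 1], tolerance = 1e-10)

  # unrelated HWE cohort: diagonal ~ 1, off-diagonal ~ 0
  Xh <- matrix(rbinom(400 * 3000, 2, 0.3), 400, 3000)
  gh <- build_grm(fake_geno(Xh))
  offd <- gh$G[upper.tri(gh$G)]
  expect_lt(abs(mean(diag(gh$G)) - 1), 3 * sd(diag(gh$G)) / sqrt(400))
  # column centring makes every row of G sum to ~0, so the off-diagonal
  # mean sits at -mean(diag)/(n-1), not at 0
  expect_lt(abs(mean(offd) + mean(diag(gh$G)) / 399),
            3 * sd(offd) / sqrt(length(offd)))
})

test_that("greml recovers the null, a grid oracle optimum, and shift invariance", {
  set.seed(6)
  # pure-noise phenotype, unrelated G: fraction ~ 0 within 2 SE
  Xh <- matrix(rbinom(300 * 1500, 2, 0.3), 300, 1500)
  gh <- build_grm(fake_geno(Xh))
  y <- rnorm(300)
  f0 <- greml(y, gh)
  expect_lt(f0$fraction, 2 * f0$se + 0.02)

  # 1-D grid-search oracle on a 50-bull instance
  ta2 <- rnorm(50)
  g2 <- simulate_genotypes(geno_sim_config(n_bulls = 50, n_snps = 300,
                                           n_causal = 300,
                                           causal_r2 = 0.5 / 300, seed = 7), ta2)
  grm2 <- build_grm(g2)
  fit <- greml(g2$ta, grm2)
  grid <- seq(0.001, 0.999, by = 0.0005)
  G <- grm2$G; n <- 50; X1 <- matrix(1, n, 1)
  ll <- vapply(grid, function(h) {
    V <- G * h + diag(n) * (1 - h)
    Vi <- solve(V)
    xvx <- t(X1) %*% Vi %*% X1
    P <- Vi - Vi %*% X1 %*% solve(xvx) %*% t(X1) %*% Vi
    s2 <- (t(g2$ta) %*% P %*% g2$ta) / (n - 1)
    -0.5 * (determinant(V)$modulus + log(xvx) + (n - 1) * log(s2))[1]
  }, numeric(1))
  expect_lt(abs(fit$fraction - grid[which.max(ll)]), 1e-3)

  # invariance to adding a constant to the phenotype
  fit_shift <- greml(g2$ta + 1000, grm2)
  expect_equal(fit_shift$fraction, fit$fraction, tolerance = 1e-6)
})

test_that("single-causal-marker R2 is recovered across replicates", {
  r2s <- vapply(1:25, function(s) {
    ta <- rnorm(1445, 0, 8)
    g <- simulate_genotypes(geno_sim_config(n_bulls = 1445, n_snps = 1,
                                            maf_range = c(0.3, 0.3),
                                            n_causal = 1, causal_r2 = 0.0574,
                                            seed = 2000 + s), ta)
    assoc(g$ta, g$dosage)$r2
  }, numeric(1))
  expect_lt(abs(median(r2s) - 0.0574), 0.01)
})
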
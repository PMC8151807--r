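#' Simulation configuration for pedigree and weight-record generation
#'
#' Collects every knob of the data generator.  Defaults reproduce the
#' structure assumed by the analysis model: repeated weighings (1-5 per
#' animal at ages 150-500 d), herd-year-season contemporary groups, additive
#' genetic and permanent-environment effects with sex-specific variances on
#' the scale of the Israeli Holstein field data, and age effects entering
#' through square-root, linear and quadratic terms.
#'
#' Default variance components are the single-sex REML estimates from the
#' field analysis (males: additive 574, permanent environment 1030,
#' residual 497 kg^2; females: 489, 407, 484 kg^2), and default age
#' coefficients are the corresponding estimated square-root/linear/quadratic
#' effects.  The default distribution of records per animal matches the
#' field record-count table (37% one record, 34% two, 10% three, 6% four,
#' 12% five).
#'
#' @param n_founders number of founder animals (generation 0, unknown parents).
#' @param n_generations number of descendant generations.
#' @param offspring_per_dam offspring per mated dam and generation.
#' @param n_herds number of herds.
#' @param base_year birth year of the founder generation.
#' @param generation_interval years between generations.
#' @param sigma2_a_m,sigma2_p_m,sigma2_e_m male additive, permanent
#'   environment and residual variances, kg^2.
#' @param sigma2_a_f,sigma2_p_f,sigma2_e_f female counterparts, kg^2.
#' @param age_effects list with elements `M` and `F`, each a numeric vector
#'   `c(sqrt, linear, quadratic)` of age coefficients (age centred at 365 d
#'   so the trait mean is interpretable at one year of age).
#' @param hys_sd standard deviation of herd-year-season effects, kg.
#' @param mean_yg_m,mean_yg_f mean yearling gain by sex, kg.
#' @param records_per_animal either a single count in 1..5 or a probability
#'   vector over 1..5.
#' @param missing_parent_rate fraction of non-founder animals whose sire
#'   and/or dam link is erased (they become unknown-parent animals).
#' @param multiple_birth_rate fraction of non-founder animals flagged as
#'   born in a multiple birth.
#' @param seed integer seed; fully determines all generator output.
#' @return A list of class `calf_sim_config`.
#' @export
sim_config <- function(n_founders = 200L,
                       n_generations = 3L,
                       offspring_per_dam = 3L,
                       n_herds = 10L,
                       base_year = 2008L,
                       generation_interval = 2L,
                       sigma2_a_m = 574, sigma2_p_m = 1030, sigma2_e_m = 497,
                       sigma2_a_f = 489, sigma2_p_f = 407, sigma2_e_f = 484,
                       age_effects = list(M = c(32.56, -0.429, -0.00078),
                                          F = c(36.80, -1.636, 0.00068)),
                       hys_sd = 15,
                       mean_yg_m = 461, mean_yg_f = 337,
                       records_per_animal = c(0.3735, 0.3434, 0.1018, 0.0599, 0.1214),
                       missing_parent_rate = 0,
                       multiple_birth_rate = 0,
                       seed = 1L) {
  vars <- c(sigma2_a_m, sigma2_p_m, sigma2_e_m, sigma2_a_f, sigma2_p_f, sigma2_e_f)
  if (any(vars < 0)) stop("variance components must be >= 0")
  if (n_founders < 1) stop("n_founders must be positive")
  if (length(records_per_animal) == 1L) {
    k <- as.integer(records_per_animal)
    if (k < 1L || k > 5L) stop("records_per_animal must lie in 1..5")
    records_per_animal <- replace(numeric(5), k, 1)
  }
  if (length(records_per_animal) != 5L || any(records_per_animal < 0))
    stop("records_per_animal must be a probability vector over 1..5")
  records_per_animal <- records_per_animal / sum(records_per_animal)
  structure(list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    offspring_per_dam = as.integer(offspring_per_dam),
    n_herds = as.integer(n_herds),
    base_year = as.integer(base_year),
    generation_interval = as.integer(generation_interval),
    sigma2_a_m = sigma2_a_m, sigma2_p_m = sigma2_p_m, sigma2_e_m = sigma2_e_m,
    sigma2_a_f = sigma2_a_f, sigma2_p_f = sigma2_p_f, sigma2_e_f = sigma2_e_f,
    age_effects = age_effects, hys_sd = hys_sd,
    mean_yg_m = mean_yg_m, mean_yg_f = mean_yg_f,
    records_per_animal = records_per_animal,
    missing_parent_rate = missing_parent_rate,
    multiple_birth_rate = multiple_birth_rate,
    seed = as.integer(seed)), class = "calf_sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations: founders (all parents unknown) are split evenly
#' between the sexes; in each later generation every female of the previous
#' generation is mated to a randomly drawn male of that generation and
#' produces `offspring_per_dam` offspring of random sex.  Animals are
#' assigned to herds at birth; birth dates fall in the generation's year.
#' A configurable fraction of non-founders has parent links erased, and a
#' configurable fraction is flagged as multiple-birth.
#'
#' @param cfg a [sim_config()].
#' @return Pedigree data frame (`animal`, `sire`, `dam`, `sex`, `birth_date`,
#'   `herd`, `breed_sire`, `multiple_birth`, `generation`), sorted
#'   parents-first.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "calf_sim_config"))
  set.seed(cfg$seed)
  nf <- cfg$n_founders
  rows <- list()
  mk_ids <- function(gen, n) sprintf("G%d_%04d", gen, seq_len(n))
  sexes <- function(n) rep_len(c("M", "F"), n)[sample.int(n)]
  bdate <- function(year, n) as.Date(sprintf("%d-01-01", year)) + sample.int(365, n, replace = TRUE) - 1L
  rows[[1]] <- data.frame(
    animal = mk_ids(0, nf), sire = NA_character_, dam = NA_character_,
    sex = sexes(nf), birth_date = bdate(cfg$base_year, nf),
    herd = sample.int(cfg$n_herds, nf, replace = TRUE),
    breed_sire = "HOL", multiple_birth = FALSE, generation = 0L,
    stringsAsFactors = FALSE)
  for (g in seq_len(cfg$n_generations)) {
    prev <- rows[[g]]
    dams <- prev$animal[prev$sex == "F"]
    sires <- prev$animal[prev$sex == "M"]
    if (!length(dams) || !length(sires)) break
    n_off <- length(dams) * cfg$offspring_per_dam
    dam_of <- rep(dams, each = cfg$offspring_per_dam)
    # one mate per dam and generation, so a dam's brood are full sibs
    sire_of <- rep(sample(sires, length(dams), replace = TRUE),
                   each = cfg$offspring_per_dam)
    year <- cfg$base_year + g * cfg$generation_interval
    off <- data.frame(
      animal = mk_ids(g, n_off), sire = sire_of, dam = dam_of,
      sex = sexes(n_off), birth_date = bdate(year, n_off),
      herd = sample.int(cfg$n_herds, n_off, replace = TRUE),
      breed_sire = "HOL",
      multiple_birth = runif(n_off) < cfg$multiple_birth_rate,
      generation = g, stringsAsFactors = FALSE)
    if (cfg$missing_parent_rate > 0) {
      drop <- runif(n_off) < cfg$missing_parent_rate
      which_drop <- sample(c("sire", "dam", "both"), n_off, replace = TRUE)
      off$sire[drop & which_drop != "dam"] <- NA_character_
      off$dam[drop & which_drop != "sire"] <- NA_character_
    }
    rows[[g + 1L]] <- off
  }
  validate_and_sort(do.call(rbind, rows))
}

#' Simulate true genetic and environmental effects
#'
#' Breeding values follow the pedigree recursion
#' `u = (u_sire + u_dam)/2 + m`, with Mendelian deviation `m` of variance
#' `0.5 * sigma2_a * (1 - (F_s + F_d)/2)` (parental inbreeding from the same
#' relationship algebra the estimation side uses); unknown parents contribute
#' a full founder share.  One underlying value per animal is drawn on the
#' reference (male) scale and expressed on each sex's scale by multiplication
#' with `sqrt(sigma2_a_sex / sigma2_a_m)`, i.e. the genetic correlation
#' between the sexes is 1.  Permanent-environment values are i.i.d. normal
#' per animal with sex-specific variance, and herd-year-season effects are
#' i.i.d. normal per HYS cell (treated as fixed at estimation time).
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cfg the [sim_config()].
#' @return List with `animals` (data frame: `animal`, `u_ref` on the male
#'   scale, `u` on the own-sex scale, `pe`), and `hys` (data frame: `hys`,
#'   `effect`) covering every birth herd-year-season cell of the pedigree.
#' @export
simulate_true_values <- function(ped, cfg) {
  stopifnot(inherits(cfg, "calf_sim_config"))
  ped <- ensure_sorted(ped)
  set.seed(cfg$seed + 1L)
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  f <- inbreeding(ped)
  d <- mendelian_d(ped, f)  # variance of the Mendelian term in sigma2_a units
  s2a <- cfg$sigma2_a_m     # reference scale
  u <- numeric(n)
  m <- rnorm(n, 0, sqrt(d * s2a))
  for (i in seq_len(n)) {
    pa <- 0
    if (!is.na(si[i])) pa <- pa + 0.5 * u[si[i]]
    if (!is.na(di[i])) pa <- pa + 0.5 * u[di[i]]
    u[i] <- pa + m[i]
  }
  f_ratio <- if (cfg$sigma2_a_m > 0) cfg$sigma2_a_f / cfg$sigma2_a_m else 1
  scale_sex <- ifelse(ped$sex == "M", 1, sqrt(f_ratio))
  pe_sd <- ifelse(ped$sex == "M", sqrt(cfg$sigma2_p_m), sqrt(cfg$sigma2_p_f))
  animals <- data.frame(animal = ped$animal, u_ref = u, u = u * scale_sex,
                        pe = rnorm(n, 0, pe_sd), stringsAsFactors = FALSE)
  hys <- unique(data.frame(
    hys = assign_hys(ped$herd, ped$birth_date, ped$sex),
    stringsAsFactors = FALSE))
  hys$effect <- rnorm(nrow(hys), 0, cfg$hys_sd)
  list(animals = animals, hys = hys)
}

#' Simulate repeated weight records
#'
#' For every animal with both parents known (candidate recorded animals),
#' the number of weighings is drawn from the configured distribution and
#' ages uniformly on [150, 500] d.  The latent yearling gain of a record is
#' `mean_sex + HYS + age polynomial + u + pe + e` with a sex-specific
#' residual, and the recorded weight inverts the yearling-gain
#' standardization: `w = 35 + a * (YG - 35) / 365`.
#'
#' @param ped pedigree.
#' @param truth output of [simulate_true_values()].
#' @param cfg the [sim_config()].
#' @return Weight-record data frame (`animal`, `herd`, `weigh_date`,
#'   `weight`, `age`, `sex`) with attribute `latent_yg` carrying the latent
#'   yearling gains for test assertions.
#' @export
simulate_weight_records <- function(ped, truth, cfg) {
  stopifnot(inherits(cfg, "calf_sim_config"))
  ped <- ensure_sorted(ped)
  set.seed(cfg$seed + 2L)
  rec_ok <- !is.na(ped$sire) & !is.na(ped$dam)
  idx <- which(rec_ok)
  if (!length(idx)) stop("no animal has both parents known; nothing to record")
  k <- sample.int(5L, length(idx), replace = TRUE, prob = cfg$records_per_animal)
  row_i <- rep(idx, k)
  nr <- length(row_i)
  age <- floor(runif(nr, 150, 501))
  ord <- order(row_i, age)
  row_i <- row_i[ord]; age <- age[ord]
  sex <- ped$sex[row_i]
  hys <- assign_hys(ped$herd[row_i], ped$birth_date[row_i], sex)
  hys_eff <- truth$hys$effect[match(hys, truth$hys$hys)]
  ae <- cfg$age_effects
  acoef <- do.call(rbind, ae[sex])
  ac <- age - 365
  age_part <- acoef[, 1] * (sqrt(age) - sqrt(365)) + acoef[, 2] * ac + acoef[, 3] * (age^2 - 365^2)
  ti <- match(ped$animal[row_i], truth$animals$animal)
  e_sd <- ifelse(sex == "M", sqrt(cfg$sigma2_e_m), sqrt(cfg$sigma2_e_f))
  mu <- ifelse(sex == "M", cfg$mean_yg_m, cfg$mean_yg_f)
  yg <- mu + hys_eff + age_part + truth$animals$u[ti] + truth$animals$pe[ti] +
    rnorm(nr, 0, e_sd)
  out <- data.frame(animal = ped$animal[row_i], herd = ped$herd[row_i],
                    weigh_date = ped$birth_date[row_i] + age,
                    weight = 35 + age * (yg - 35) / 365,
                    age = age, sex = sex, stringsAsFactors = FALSE)
  attr(out, "latent_yg") <- yg
  out
}

#' Combined-scale validation conditions
#'
#' The simulation configuration used for parameter-recovery validation of
#' the combined-sex analysis: both sexes share the combined-scale variance
#' components (additive 591, permanent environment 622, residual 488 kg^2),
#' one common age curve and equal sex means, so the generative model
#' coincides with the analysis model; about 5,000 recorded animals with two
#' weighings each in roughly 50 herd-year-season cells.
#'
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
validation_config <- function(seed = 1L) {
  ae <- c(32.56, -0.429, -0.00078)
  sim_config(n_founders = 700L, n_generations = 3L, offspring_per_dam = 3L,
             n_herds = 3L, seed = seed, records_per_animal = 2L,
             sigma2_a_m = 591, sigma2_a_f = 591,
             sigma2_p_m = 622, sigma2_p_f = 622,
             sigma2_e_m = 488, sigma2_e_f = 488,
             mean_yg_m = 400, mean_yg_f = 400,
             age_effects = list(M = ae, F = ae))
}

#' Genotype-simulation configuration
#'
#' @param n_bulls number of genotyped bulls.
#' @param n_snps number of biallelic SNPs.
#' @param maf_range interval in (0, 0.5] from which minor-allele frequencies
#'   are drawn uniformly.
#' @param n_causal number of causal SNPs (the first `n_causal` simulated).
#' @param causal_r2 per-causal-SNP fraction of phenotypic variance; recycled
#'   to length `n_causal`; must sum to at most 1.
#' @param missing_rate fraction of dosages set missing, in [0, 1).
#' @param seed integer seed.
#' @return List of class `calf_geno_config`.
#' @export
geno_sim_config <- function(n_bulls = 1445L, n_snps = 1000L,
                            maf_range = c(0.05, 0.5), n_causal = 0L,
                            causal_r2 = numeric(0), missing_rate = 0,
                            seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (n_causal > 0) causal_r2 <- rep_len(causal_r2, n_causal)
  if (sum(causal_r2) > 1) stop("causal_r2 must sum to at most 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) stop("maf_range must lie in (0, 0.5]")
  structure(list(n_bulls = as.integer(n_bulls), n_snps = as.integer(n_snps),
                 maf_range = maf_range, n_causal = as.integer(n_causal),
                 causal_r2 = causal_r2, missing_rate = missing_rate,
                 seed = as.integer(seed)), class = "calf_geno_config")
}

#' Simulate SNP genotypes with effects on transmitting abilities
#'
#' Dosages are drawn binomially at Hardy-Weinberg proportions with
#' independent SNPs.  Causal SNPs receive additive effects scaled so that
#' SNP `k` explains its configured fraction `causal_r2[k]` of the variance
#' of the returned phenotype: the supplied transmitting abilities are
#' rescaled to supply the non-genomic remainder, and the marker terms
#' `beta_k * (x_k - 2 p_k)` are added on top, keeping the total variance at
#' the input level.  With `n_causal = 0` the input vector is returned
#' untouched and every SNP is independent of it.
#'
#' @param gcfg a [geno_sim_config()].
#' @param ta numeric vector of per-bull transmitting abilities (length
#'   `n_bulls`); supplies the phenotypic variance target and the non-marker
#'   part of the phenotype.
#' @return List of class `calf_genotypes`: `dosage` (bulls x SNPs integer
#'   matrix with `NA` for missing), `map` (`snp`, `chr`, `bp`), `freq`
#'   (allele-1 frequencies used), `ta` (phenotype with marker effects
#'   embedded), `effects` (data frame of causal SNP effects).
#' @export
simulate_genotypes <- function(gcfg, ta) {
  stopifnot(inherits(gcfg, "calf_geno_config"))
  if (length(ta) != gcfg$n_bulls) stop("length(ta) must equal n_bulls")
  set.seed(gcfg$seed)
  n <- gcfg$n_bulls; m <- gcfg$n_snps
  p <- runif(m, gcfg$maf_range[1], gcfg$maf_range[2])
  X <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  snp <- sprintf("SNP%05d", seq_len(m))
  map <- data.frame(snp = snp, chr = sort(rep_len(1:29, m)),
                    bp = seq_len(m) * 1000L, stringsAsFactors = FALSE)
  colnames(X) <- snp
  vt <- var(ta)
  effects <- data.frame(snp = character(0), beta = numeric(0), r2 = numeric(0))
  ta_out <- ta
  if (gcfg$n_causal > 0) {
    r2 <- gcfg$causal_r2
    ci <- seq_len(gcfg$n_causal)
    v_dos <- 2 * p[ci] * (1 - p[ci])
    if (any(v_dos <= 0)) stop("causal SNP with degenerate allele frequency")
    beta <- sqrt(r2 * vt / v_dos)
    g_part <- sweep(X[, ci, drop = FALSE], 2, 2 * p[ci]) %*% beta
    resid <- (ta - mean(ta)) * sqrt(max(0, 1 - sum(r2)))
    ta_out <- mean(ta) + as.numeric(g_part) + resid
    effects <- data.frame(snp = snp[ci], beta = beta, r2 = r2)
  }
  if (gcfg$missing_rate > 0) {
    X[runif(n * m) < gcfg$missing_rate] <- NA_integer_
  }
  rownames(X) <- sprintf("BULL%05d", seq_len(n))
  structure(list(dosage = X, map = map, freq = p, ta = ta_out,
                 effects = effects), class = "calf_genotypes")
}
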
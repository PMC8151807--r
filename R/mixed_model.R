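#' Variance-component container
#'
#' @param sigma2_a,sigma2_p,sigma2_e additive, permanent-environment and
#'   residual variances (kg^2).
#' @param se optional named numeric vector of standard errors
#'   (`a`, `p`, `e`).
#' @param vcov optional 3x3 asymptotic covariance matrix of the estimates.
#' @param label analysis label, e.g. `"male"`, `"female"`, `"combined"`.
#' @return List of class `calf_vc`.
#' @export
new_vc <- function(sigma2_a, sigma2_p, sigma2_e, se = NULL, vcov = NULL,
                   label = "combined") {
  if (min(sigma2_a, sigma2_p, sigma2_e) < 0) stop("variances must be >= 0")
  structure(list(sigma2_a = sigma2_a, sigma2_p = sigma2_p,
                 sigma2_e = sigma2_e, se = se, vcov = vcov, label = label),
            class = "calf_vc")
}

#' @exportS3Method base::print
print.calf_vc <- function(x, ...) {
  cat("Variance components (", x$label, ")\n", sep = "")
  comp <- c(a = x$sigma2_a, p = unname(x$sigma2_p[1]), e = unname(x$sigma2_e[1]))
  for (k in names(comp)) {
    cat(sprintf("  sigma2_%s = %.2f", k, comp[k]))
    if (!is.null(x$se)) cat(sprintf(" (SE %.2f)", x$se[k]))
    cat("\n")
  }
  cat(sprintf("  heritability = %.3f, repeatability = %.3f\n",
              heritability(x), repeatability(x)))
  invisible(x)
}

vc_total <- function(vc) vc$sigma2_a + vc$sigma2_p + vc$sigma2_e

#' Heritability from variance components
#'
#' Additive genetic variance divided by the total (additive + permanent
#' environment + residual) variance.
#'
#' @param vc a [new_vc()] object or a list with `sigma2_a`, `sigma2_p`,
#'   `sigma2_e`.
#' @return Fraction in \[0, 1\].
#' @export
heritability <- function(vc) {
  tot <- vc_total(vc)
  if (tot <= 0) stop("total variance must be positive")
  vc$sigma2_a / tot
}

#' Repeatability from variance components
#'
#' (Additive + permanent environment) variance divided by the total; the
#' upper bound on the correlation between repeated records of one animal.
#'
#' @inheritParams heritability
#' @return Fraction in \[0, 1\].
#' @export
repeatability <- function(vc) {
  tot <- vc_total(vc)
  if (tot <= 0) stop("total variance must be positive")
  (vc$sigma2_a + vc$sigma2_p) / tot
}

#' Scale female records onto the male genetic-variance scale
#'
#' First step of the combined-sex evaluation with sex-heterogeneous
#' variances: female yearling gains are multiplied by
#' `sqrt(sigma2_a_male / sigma2_a_female)`, which equalizes the additive
#' genetic variance across the sexes; female permanent-environment and
#' residual variances are carried forward multiplied by the same variance
#' ratio.  The returned per-record weights express each record's residual
#' variance relative to the male residual variance, so the weighted
#' mixed-model equations of [solve_mme()] realize the heterogeneous model
#' on a common scale.  Male records are untouched (weight 1).
#'
#' @param records edited record table (column `sex` coded `"M"`/`"F"`).
#' @param vc_m,vc_f single-sex variance components ([new_vc()]).
#' @return List: `records` (scaled), `weights` (per record), and `report`
#'   with the scaling factor, the scaled female PE and residual variances,
#'   and the combined `sigma2_p` by sex for assembly.
#' @export
scale_female_records <- function(records, vc_m, vc_f) {
  if (vc_f$sigma2_a <= 0) stop("female additive variance must be positive")
  ratio <- vc_m$sigma2_a / vc_f$sigma2_a     # A_m / A_f
  factor <- sqrt(ratio)
  fem <- records$sex == "F"
  records$yg[fem] <- records$yg[fem] * factor
  pe_f_scaled <- vc_f$sigma2_p * ratio
  res_f_scaled <- vc_f$sigma2_e * ratio
  w <- ifelse(fem, vc_m$sigma2_e / res_f_scaled, 1)
  report <- list(factor = factor, ratio = ratio,
                 pe_f_scaled = pe_f_scaled, res_f_scaled = res_f_scaled,
                 residual_ratio = res_f_scaled / vc_m$sigma2_e,
                 sigma2_p = c(M = vc_m$sigma2_p, F = pe_f_scaled))
  list(records = records, weights = w, report = report)
}

#' Shift evaluations to a birth-year genetic base
#'
#' Subtracts the mean EBV of the base cohort (animals born in `base_year`)
#' from every EBV and transmitting ability, so the base cohort averages
#' zero.  Differences between animals are unaffected.
#'
#' @param sol a [solve_mme()] solution.
#' @param base_year calendar birth year defining the base cohort.
#' @return The solution with shifted `ebv`/`ta` and a `base` element.
#' @export
apply_base <- function(sol, base_year = 2015L) {
  stopifnot(inherits(sol, "calf_mme_solution"))
  yr <- as.integer(format(as.Date(sol$ebv$birth_date), "%Y"))
  in_base <- !is.na(yr) & yr == base_year
  if (!any(in_base)) stop("no animals born in base year ", base_year)
  shift <- mean(sol$ebv$ebv[in_base])
  sol$ebv$ebv <- sol$ebv$ebv - shift
  sol$ebv$ta <- transmitting_ability(sol$ebv$ebv)
  sol$base <- list(year = base_year, n = sum(in_base), shift = shift)
  sol
}

#' Reliability from prediction-error variance
#'
#' `rel = 1 - PEV / (sigma2_a * (1 + F))`, clamped to \[0, 1\]; the squared
#' correlation between the EBV and the true breeding value.
#'
#' @param pev prediction-error variance(s).
#' @param sigma2_a additive genetic variance.
#' @param f inbreeding coefficient(s), default 0.
#' @return Reliabilities in \[0, 1\]; `NA` where `pev` is `NA`.
#' @export
reliability <- function(pev, sigma2_a, f = 0) {
  pmin(pmax(1 - pev / (sigma2_a * (1 + f)), 0), 1)
}

#' Transmitting ability
#'
#' Half the estimated breeding value: the expected deviation of an
#' animal's progeny from the population mean.
#'
#' @param ebv estimated breeding value(s), kg.
#' @return TA in kg.
#' @export
transmitting_ability <- function(ebv) ebv / 2

#' Combined-sex genetic evaluation with heterogeneous variances
#'
#' Runs the full evaluation procedure: female records are scaled to the male
#' genetic-variance scale, the mixed-model equations are assembled with
#' sex-specific permanent-environment variances and per-record residual
#' weights, solved sparsely, and the evaluations are expressed on the
#' birth-year base.
#'
#' @param records edited combined-sex record table.
#' @param ped pedigree.
#' @param vc_m,vc_f single-sex variance components.
#' @param groups optional group assignment (default: dataset-2 style rule
#'   computed from the pedigree).
#' @param base_year genetic base birth year (`NULL` to skip).
#' @param pev compute prediction-error variances / reliabilities.
#' @return A `calf_mme_solution` with a `scaling` element.
#' @export
genetic_evaluation <- function(records, ped, vc_m, vc_f,
                               groups = NULL, base_year = NULL, pev = TRUE) {
  ped <- ensure_sorted(ped)
  if (is.null(groups)) groups <- assign_groups(ped, "dataset2")
  sc <- scale_female_records(records, vc_m, vc_f)
  vc <- new_vc(vc_m$sigma2_a, sc$report$sigma2_p, vc_m$sigma2_e,
               label = "combined")
  sys <- mme_system(sc$records, ped, groups = groups, group_mode = "augment")
  sol <- solve_mme(sys, vc, weights = sc$weights, pev = pev)
  if (!is.null(base_year)) sol <- apply_base(sol, base_year)
  sol$scaling <- sc$report
  sol
}
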
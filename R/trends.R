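#' Genetic trend: regression of EBV on birth date
#'
#' Ordinary least squares of estimated breeding values on birth date
#' expressed in fractional years (365.25 d), over animals born on or after
#' `from`.  The slope is invariant to the genetic-base constant.
#'
#' @param ebv numeric EBVs (kg).
#' @param birth_date `Date` (or coercible) birth dates, same length.
#' @param from earliest birth date included.
#' @return List of class `calf_trend`: `slope` (kg/year), `intercept`, `se`
#'   (of the slope), `n`.
#' @export
genetic_trend <- function(ebv, birth_date, from = as.Date("1992-01-01")) {
  birth_date <- as.Date(birth_date)
  keep <- !is.na(ebv) & !is.na(birth_date) & birth_date >= as.Date(from)
  if (sum(keep) < 3) stop("fewer than 3 animals after the birth-date filter")
  yrs <- as.numeric(birth_date[keep]) / 365.25
  fit <- lm(ebv[keep] ~ yrs)
  # suppressed: constructed fixtures can fit exactly, which makes
  # summary.lm warn about the (then ~0) standard error
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 se = se,
                 n = sum(keep)), class = "calf_trend")
}

#' @exportS3Method base::print
print.calf_trend <- function(x, ...) {
  cat(sprintf("trend: %+.3f kg/year (SE %.3f, n = %d)\n", x$slope, x$se, x$n))
  invisible(x)
}

#' Phenotypic trend: regression of near-yearling YG on birth date
#'
#' Per animal, the single record with age closest to 365 d is selected
#' (ties broken toward the earlier record); the yearling gains of those
#' records are regressed on birth date in fractional years.
#'
#' @param records edited record table with `animal`, `yg`, `age`,
#'   `birth_date`.
#' @param from earliest birth date included.
#' @return A `calf_trend` (slope in kg/year), with the selected records as
#'   attribute `selected`.
#' @export
phenotypic_trend <- function(records, from = as.Date("1992-01-01")) {
  sel <- select_record_nearest_365(records)
  out <- genetic_trend(sel$yg, sel$birth_date, from = from)
  attr(out, "selected") <- sel
  out
}

select_record_nearest_365 <- function(records) {
  ix <- unlist(lapply(split(seq_len(nrow(records)), records$animal), function(i) {
    d <- abs(records$age[i] - 365)
    # ties: earlier record (smaller age first, then input order)
    i[order(d, records$age[i], i)][1]
  }), use.names = FALSE)
  records[sort(ix), , drop = FALSE]
}

#' Correlation between two sets of genetic evaluations
#'
#' Pearson correlation of EBVs over the animals present in both
#' evaluations, after a reliability filter (strict `>`).  The filter can be
#' applied to the first table, both, or either, since published comparisons
#' differ in which evaluation's reliability gates the bull list.
#'
#' @param eval_a,eval_b data frames with `animal`, `ebv` and (if filtering)
#'   `reliability`.
#' @param min_reliability reliability threshold (strict).
#' @param filter which table's reliability must exceed the threshold.
#' @return List: `correlation`, `n`.
#' @export
ebv_correlation <- function(eval_a, eval_b, min_reliability = 0.9,
                            filter = c("first", "both", "either")) {
  filter <- match.arg(filter)
  common <- intersect(eval_a$animal, eval_b$animal)
  ia <- match(common, eval_a$animal)
  ib <- match(common, eval_b$animal)
  ra <- if (is.null(eval_a$reliability)) rep(1, length(ia)) else eval_a$reliability[ia]
  rb <- if (is.null(eval_b$reliability)) rep(1, length(ib)) else eval_b$reliability[ib]
  keep <- switch(filter,
                 first = ra > min_reliability,
                 both = ra > min_reliability & rb > min_reliability,
                 either = ra > min_reliability | rb > min_reliability)
  if (sum(keep) < 3) stop("fewer than 3 animals pass the reliability filter")
  list(correlation = cor(eval_a$ebv[ia][keep], eval_b$ebv[ib][keep]),
       n = sum(keep))
}
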
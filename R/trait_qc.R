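#' Yearling weight gain from a weight-at-age record
#'
#' Standardizes a weight taken at `a` days of age to one year of age,
#' assuming a 35 kg birth weight: `YG = 365 * (w - 35) / a + 35`.  At
#' `a = 365` the record is returned unchanged; a record equal to birth
#' weight maps to 35 regardless of age.
#'
#' @param w weight in kg.
#' @param a age in days (> 0).
#' @return Yearling gain in kg.
#' @examples
#' compute_yg(461, 365)  # 461
#' compute_yg(300, 250)  # 421.9
#' @export
compute_yg <- function(w, a) {
  if (any(a <= 0)) stop("age must be positive")
  365 * (w - 35) / a + 35
}

#' Herd-year-season code
#'
#' Two six-month seasons per herd-year, defined relative to the animal's
#' birth date: April-September (`S`) and October-March (`W`).  The winter
#' season is labelled by the calendar year of its October, so January-March
#' births join the previous October's cell and every contemporary group is a
#' contiguous half-year block.  Separate codes are kept per sex, which
#' stands in for a sex-of-calf effect in the model.
#'
#' @param herd herd identifier(s).
#' @param birth_date `Date` (or coercible) birth dates.
#' @param sex `"M"`/`"F"`.
#' @return Character vector of HYS codes, e.g. `"H3_2010S_F"`.
#' @export
assign_hys <- function(herd, birth_date, sex) {
  birth_date <- as.Date(birth_date)
  mon <- as.integer(format(birth_date, "%m"))
  yr <- as.integer(format(birth_date, "%Y"))
  summer <- mon >= 4L & mon <= 9L
  yr[mon <= 3L] <- yr[mon <= 3L] - 1L
  paste0("H", herd, "_", yr, ifelse(summer, "S", "W"), "_", sex)
}

#' Apply the yearling-gain edit rules
#'
#' Converts raw weight records to yearling gains and applies the editing
#' rules in sequence: (1) records of multiple-birth calves are deleted;
#' (2) records of calves with unknown sire or dam are deleted; (3) records
#' at ages outside 150-500 d are deleted; (4) yearling gains outside
#' 150-650 kg are deleted (both windows inclusive at the bounds);
#' (5) optionally, animals with more than five surviving records keep the
#' first four plus the last one ([cap_records_per_animal()]).  Records whose
#' animal is absent from the pedigree are rejected per record.  An audit of
#' counts per rule accompanies the retained table and always reconciles with
#' the input count.
#'
#' @param records weight-record data frame (`animal`, `herd`, `weigh_date`,
#'   `weight`, `age`, optionally `sex`).
#' @param ped pedigree table.
#' @param cap apply the records-per-animal cap (default `TRUE`).
#' @return List with `records` (edited table with `yg`, `hys`, `birth_date`
#'   columns added) and `audit` (data frame of per-rule removal counts).
#' @export
apply_edits <- function(records, ped, cap = TRUE) {
  ped <- ensure_sorted(ped)
  n_in <- nrow(records)
  rec <- records
  pi <- match(rec$animal, ped$animal)
  drop_orphan <- is.na(pi)
  rec <- rec[!drop_orphan, , drop = FALSE]; pi <- pi[!drop_orphan]

  mb <- if (is.null(ped$multiple_birth)) rep(FALSE, nrow(rec)) else
    isTRUE_vec(ped$multiple_birth[pi])
  rec <- rec[!mb, , drop = FALSE]; pi <- pi[!mb]

  unk <- is.na(ped$sire[pi]) | is.na(ped$dam[pi])
  rec <- rec[!unk, , drop = FALSE]; pi <- pi[!unk]

  bad_age <- rec$age < 150 | rec$age > 500
  rec <- rec[!bad_age, , drop = FALSE]; pi <- pi[!bad_age]

  rec$yg <- compute_yg(rec$weight, rec$age)
  bad_yg <- rec$yg < 150 | rec$yg > 650
  rec <- rec[!bad_yg, , drop = FALSE]; pi <- pi[!bad_yg]

  if (is.null(rec$sex)) rec$sex <- ped$sex[pi]
  rec$birth_date <- ped$birth_date[pi]
  rec$hys <- assign_hys(rec$herd, rec$birth_date, rec$sex)

  n_excess <- 0L
  if (cap && nrow(rec)) {
    kept <- cap_records_per_animal(rec)
    n_excess <- nrow(rec) - nrow(kept)
    rec <- kept
  }
  audit <- data.frame(
    rule = c("orphan_animal", "multiple_birth", "unknown_parent",
             "age_window", "yg_window", "excess_records", "retained"),
    n = c(sum(drop_orphan), sum(mb), sum(unk), sum(bad_age), sum(bad_yg),
          n_excess, nrow(rec)))
  stopifnot(sum(audit$n) == n_in)
  rownames(rec) <- NULL
  list(records = rec, audit = audit)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Cap the number of records per animal
#'
#' Animals with more than five valid records keep the four earliest plus the
#' latest record (five in total); animals with five or fewer are untouched.
#' Ties in weigh date are broken by input order, earlier-entered first, so
#' the selection is deterministic.
#'
#' @param records edited record table carrying `animal` and `weigh_date`.
#' @return The capped table, original row order preserved.
#' @export
cap_records_per_animal <- function(records) {
  if (!nrow(records)) return(records)
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$animal), function(ix) {
    if (length(ix) <= 5L) return(ix)
    o <- ix[order(records$weigh_date[ix], ix)]
    rest <- o[-(1:4)]
    last <- rest[records$weigh_date[rest] == max(records$weigh_date[rest])][1]
    c(o[1:4], last)
  }), use.names = FALSE)
  records[sort(keep), , drop = FALSE]
}
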
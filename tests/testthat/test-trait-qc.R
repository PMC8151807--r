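test_that("compute_yg matches hand arithmetic and its identities", {
  expect_equal(compute_yg(461, 365), 461)   # at one year the record is itself
  expect_equal(compute_yg(35, 200), 35)     # birth-weight fixed point
  expect_equal(compute_yg(300, 250), 421.9) # 365*265/250 + 35
  expect_error(compute_yg(300, 0), "positive")

  w <- seq(40, 700, by = 13.7)
  expect_equal(compute_yg(w, 365), w)             # identity at a = 365
  expect_true(all(diff(compute_yg(w, 300)) > 0))  # increasing in w
  a <- seq(150, 500, by = 10)
  expect_true(all(diff(compute_yg(250, a)) < 0))  # decreasing in a for w > 35
})

test_that("assign_hys splits the year into Apr-Sep and Oct-Mar blocks", {
  expect_identical(assign_hys(3, as.Date("2010-05-15"), "F"), "H3_2010S_F")
  expect_identical(assign_hys(3, as.Date("2010-11-15"), "F"), "H3_2010W_F")
  # winter spans the year boundary: Feb 2011 belongs to October 2010's cell
  expect_identical(assign_hys(3, as.Date("2011-02-10"), "M"), "H3_2010W_M")
  expect_identical(assign_hys(3, as.Date("2010-04-01"), "M"), "H3_2010S_M")
  expect_identical(assign_hys(3, as.Date("2010-10-01"), "M"), "H3_2010W_M")
  # sexes get separate cells
  expect_false(assign_hys(1, as.Date("2010-06-01"), "M") ==
                 assign_hys(1, as.Date("2010-06-01"), "F"))
})

make_toy_edit_data <- function() {
  ped <- data.frame(
    animal = c("F1", "F2", "OK", "TWIN", "NOSIRE", "HEAVY"),
    sire = c(NA, NA, "F1", "F1", NA, "F1"),
    dam = c(NA, NA, "F2", "F2", "F2", "F2"),
    sex = c("M", "F", "M", "M", "F", "M"),
    birth_date = as.Date(c("2009-01-01", "2009-01-01", "2010-05-01",
                           "2010-05-01", "2010-05-01", "2010-05-01")),
    multiple_birth = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  # 8 records spanning every rule
  records <- data.frame(
    animal = c("OK", "OK", "TWIN", "NOSIRE", "OK", "OK", "HEAVY", "GHOST"),
    herd = 1,
    weigh_date = as.Date("2010-05-01") + c(365, 200, 365, 365, 149, 501, 365, 365),
    weight = c(400, 250, 400, 400, 200, 600, 700, 400),
    age = c(365, 200, 365, 365, 149, 501, 365, 365))
  list(ped = ped, records = records)
}

test_that("apply_edits partitions a hand-enumerated toy table correctly", {
  d <- make_toy_edit_data()
  out <- apply_edits(d$records, d$ped)
  # retained: OK@365 (yg 400) and OK@200 (yg 427.375); removed: TWIN
  # (multiple birth), NOSIRE (unknown sire), OK@149 + OK@501 (age window),
  # HEAVY (yg 700 > 650), GHOST (not in pedigree)
  expect_identical(sort(paste(out$records$animal, out$records$age)),
                   c("OK 200", "OK 365"))
  expect_equal(out$records$yg[out$records$age == 365], 400)
  expect_equal(out$records$yg[out$records$age == 200], 365 * 215 / 200 + 35)
  au <- setNames(out$audit$n, out$audit$rule)
  expect_equal(unname(au[c("orphan_animal", "multiple_birth", "unknown_parent",
                           "age_window", "yg_window", "retained")]),
               c(1, 1, 1, 2, 1, 2))
  expect_equal(sum(out$audit$n), nrow(d$records))
})

test_that("edit windows are inclusive at their bounds", {
  d <- make_toy_edit_data()
  rec <- data.frame(animal = "OK", herd = 1,
                    weigh_date = as.Date("2011-01-01"),
                    weight = c(150, 650, 149.9, 650.1, 100, 300),
                    age = c(365, 365, 365, 365, 150, 500))
  out <- apply_edits(rec, d$ped)
  # yg at bounds 150 and 650 retained; just outside removed; ages 150 and
  # 500 retained (their ygs: 100kg@150d -> 193.2, 300@500 -> 228.5)
  expect_equal(nrow(out$records), 4)
  expect_setequal(round(out$records$yg, 1), c(150, 650, 193.2, 228.4))
})

test_that("apply_edits is idempotent and audits conserve counts", {
  cfg <- flat_cfg(21, 400, 300, 500, n_founders = 40, n_generations = 2,
                  multiple_birth_rate = 0.1)
  ped <- simulate_pedigree(cfg)
  truth <- simulate_true_values(ped, cfg)
  raw <- simulate_weight_records(ped, truth, cfg)
  e1 <- apply_edits(raw, ped)
  expect_equal(sum(e1$audit$n), nrow(raw))
  e2 <- apply_edits(e1$records, ped)
  expect_equal(e2$records$yg, e1$records$yg)
  expect_equal(nrow(e2$records), nrow(e1$records))
  removed <- e2$audit$n[e2$audit$rule != "retained"]
  expect_true(all(removed == 0))
})

test_that("cap_records_per_animal keeps first four plus last", {
  rec <- data.frame(animal = "A", herd = 1,
                    weigh_date = as.Date("2010-01-01") + seq(0, 300, by = 50),
                    age = seq(160, 460, by = 50))
  out <- cap_records_per_animal(rec)
  expect_equal(out$age, c(160, 210, 260, 310, 460))

  five <- rec[1:5, ]
  expect_identical(cap_records_per_animal(five), five)

  # six records with the last two tied on date: earlier-entered kept
  tie <- data.frame(animal = "B", herd = 1,
                    weigh_date = as.Date("2010-01-01") +
                      c(0, 10, 20, 30, 40, 40),
                    age = c(150, 160, 170, 180, 190, 191))
  out2 <- cap_records_per_animal(tie)
  expect_equal(out2$age, c(150, 160, 170, 180, 190))
})

test_that("cap never exceeds five records nor drops from small animals", {
  set.seed(42)
  rec <- data.frame(
    animal = sample(sprintf("A%d", 1:30), 200, replace = TRUE),
    herd = 1, weigh_date = as.Date("2010-01-01") + sample.int(400, 200, TRUE),
    age = sample(150:500, 200, TRUE))
  out <- cap_records_per_animal(rec)
  cnt_in <- table(rec$animal)
  cnt_out <- table(out$animal)
  expect_true(all(cnt_out <= 5))
  small <- names(cnt_in)[cnt_in <= 5]
  expect_equal(as.integer(cnt_out[small]), as.integer(cnt_in[small]))
})
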
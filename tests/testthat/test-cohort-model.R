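test_that("index formulas reproduce hand-computed values on the fixture", {
  d <- labs20()
  o <- labs20_oracle()
  idx <- compute_indices(d$insulin, d$fbg, d$tg, d$hdl)
  expect_equal(idx$homa_ir, o$homa_ir, tolerance = 1e-12)
  expect_equal(idx$tyg, o$tyg, tolerance = 1e-12)
  expect_equal(idx$tg_hdl, o$tg_hdl, tolerance = 1e-12)
})

test_that("missing insulin yields missing HOMA-IR, never zero", {
  idx <- compute_indices(NA_real_, 100, 150, 50)
  expect_true(is.na(idx$homa_ir))
  expect_false(is.na(idx$tyg))
})

test_that("non-positive lab values are a domain error naming the field", {
  expect_error(compute_indices(8, 0, 150, 50), "fbg")
  expect_error(compute_indices(8, 100, -1, 50), "tg")
  expect_error(compute_indices(8, 100, 150, 0), "hdl")
})

test_that("Friedewald LDL matches the closed form and flags negatives", {
  d <- labs20()
  o <- labs20_oracle()
  expect_equal(friedewald_ldl(d$tchol, d$hdl, d$tg), o$ldl, tolerance = 1e-12)
  expect_warning(v <- friedewald_ldl(120, 45, 500), "negative")
  expect_equal(v, 120 - 45 - 100)
})

test_that("impute_ldl fills only unmeasured, valid entries and marks them", {
  d <- labs20()
  d$ldl <- NA_real_
  d$ldl[1] <- 111
  out <- impute_ldl(d)
  expect_equal(out$ldl[1], 111)
  expect_false(out$ldl_friedewald[1])
  # record 17 has TG > 400, outside the formula's validity range: stays NA
  expect_true(is.na(out$ldl[17]))
  expect_false(out$ldl_friedewald[17])
  valid <- setdiff(seq_len(20), c(1, 17))
  expect_true(all(out$ldl_friedewald[valid]))
  expect_equal(out$ldl[valid], labs20_oracle()$ldl[valid], tolerance = 1e-12)
  # a negative estimate (TCHOL - HDL - TG/5 < 0) is likewise left missing
  neg <- impute_ldl(tibble::tibble(tchol = 120, hdl = 95, tg = 300))
  expect_true(is.na(neg$ldl))
  expect_false(neg$ldl_friedewald)
})

test_that("clinical bins are lower-bound inclusive at every boundary", {
  d <- categorize_clinical(labs20())
  o <- labs20_oracle()
  expect_equal(as.character(d$fbg_cat), o$fbg_cat)
  expect_equal(as.character(d$tg_cat), o$tg_cat)
  expect_equal(as.character(d$hdl_cat), o$hdl_cat)
  # spot boundary semantics explicitly
  b <- categorize_clinical(tibble::tibble(fbg = c(99.999, 100, 125.999, 126),
                                          sbp = c(119, 120, 139, 140),
                                          ldl = c(129, 130, 189, 190)))
  expect_equal(as.character(b$fbg_cat), c("Normal", "Caution", "Caution", "Danger"))
  expect_equal(as.character(b$sbp_cat), c("Normal", "Caution", "Caution", "Danger"))
  expect_equal(as.character(b$ldl_cat), c("Normal", "Caution", "Caution", "Danger"))
})

test_that("categorize_clinical guards against physiologically absurd values", {
  expect_error(categorize_clinical(tibble::tibble(id = 7, fbg = 1e5)), "7")
  expect_error(categorize_clinical(tibble::tibble(fbg = -5)), "guard")
})

test_that("categorize_clinical is idempotent", {
  d1 <- categorize_clinical(labs20())
  d2 <- categorize_clinical(d1)
  expect_identical(d1, d2)
})

test_that("composite outcomes follow the OR of their criteria", {
  d <- impute_ldl(labs20())
  d <- define_outcomes(categorize_clinical(d))
  o <- labs20_oracle()
  expect_equal(as.character(d$diabetes), o$diabetes)
  expect_equal(as.character(d$dyslipidemia), o$dyslipidemia)
})

test_that("a satisfied criterion dominates missing components", {
  d <- tibble::tibble(fbg = c(130, 90), hba1c = c(NA, NA))
  out <- define_outcomes(d)
  expect_equal(as.character(out$diabetes), c("yes", NA))
  expect_equal(unname(attr(out, "outcome_missing")["diabetes"]), 1L)
})

test_that("diagnosis and medication flags feed the outcomes", {
  d <- tibble::tibble(fbg = c(90, 90), hba1c = c(5, 5),
                      dm_diagnosis = c("yes", "no"),
                      dm_medication = c("no", "no"))
  expect_equal(as.character(define_outcomes(d)$diabetes), c("yes", "no"))
})

test_that("obesity indicators use sex-specific waist thresholds", {
  d <- tibble::tibble(sex = c("M", "F", "M", "F"),
                      bmi = c(25, 24.9, 30, 20),
                      wc = c(90, 85, 89.9, 84.9),
                      height = c(180, 160, 170, 172))
  out <- define_outcomes(d)
  expect_equal(as.character(out$obesity_bmi), c("yes", "no", "yes", "no"))
  expect_equal(as.character(out$obesity_wc), c("yes", "yes", "no", "no"))
  expect_equal(as.character(out$obesity_whtr), c("yes", "yes", "yes", "no"))
})

test_that("exclusion cascade removes in order and logs counts", {
  d <- tibble::tibble(
    id = 1:8,
    age = c(45, 39, 70, 50, 55, 60, 44, 52),
    sex = "M",
    fbg = c(100, 100, 100, NA, 100, 100, 100, 100),
    tg = 150, hdl = 50, tchol = 200, insulin = 8,
    cvd_history = c("no", "yes", "no", "no", "yes", "no", "no", "no"),
    cancer_history = "no", kidney_history = c(rep("no", 7), "yes")
  )
  out <- apply_exclusions(d)
  log <- exclusion_log(out)
  expect_equal(log$criterion, c("incomplete_data", "age_outside_range",
                                "disease_history"))
  # id 4 incomplete; ids 2 (age 39, despite cvd) and 3 out of range; 5, 8 history
  expect_equal(log$n_removed, c(1L, 2L, 2L))
  expect_equal(out$id, c(1L, 6L, 7L))
  expect_error(apply_exclusions(dplyr::mutate(d, age = 20)), "empty cohort")
})

test_that("quartile_bin matches type-7 quantiles with boundaries in the lower group", {
  q <- quartile_bin(1:8)
  expect_equal(unname(attr(q, "cuts")), c(2.75, 4.5, 6.25), tolerance = 1e-12)
  expect_equal(as.character(quartile_bin(c(2.75, 2.7500001, 4.5, 6.25, 6.2500001),
                                         cuts = c(2.75, 4.5, 6.25))),
               c("Q1", "Q2", "Q2", "Q3", "Q4"))
  expect_error(quartile_bin(c(1, 2, 3)), "at least 4")
  expect_error(quartile_bin(rep(1, 10)), "degenerate")
})

test_that("add_quartile_groups attaches factors and cut points", {
  d <- derive_indices(labs20())
  out <- add_quartile_groups(d)
  expect_s3_class(out$tyg_q, "factor")
  expect_equal(levels(out$tyg_q), c("Q1", "Q2", "Q3", "Q4"))
  cuts <- attr(out, "quartile_cuts")
  expect_named(cuts, c("homa_ir", "tyg", "tg_hdl"))
  expect_equal(unname(cuts$tyg),
               unname(quantile(d$tyg, c(.25, .5, .75), type = 7)),
               tolerance = 1e-12)
  # every non-missing value classified consistently with its own cuts
  expect_true(all(table(out$tyg_q) > 0))
})

test_that("derive_indices appends columns and waist-to-height ratio", {
  d <- labs20()
  d$wc <- 85; d$height <- 170
  out <- derive_indices(d)
  expect_true(all(c("homa_ir", "tyg", "tg_hdl", "whtr") %in% names(out)))
  expect_equal(out$whtr, rep(0.5, 20))
})
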
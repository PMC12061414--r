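spec_cached <- ir_ground_truth()

test_that("the ground-truth network is a valid DAG with normalized CPTs", {
  expect_s3_class(spec_cached$dag, "bn_dag")
  expect_equal(length(spec_cached$dag$nodes), 17)
  f <- as_bn_fit(spec_cached)
  for (v in f$dag$nodes) {
    expect_true(all(abs(rowSums(f$cpts[[v]]) - 1) < 1e-10), info = v)
    expect_true(all(f$cpts[[v]] >= 0), info = v)
  }
  # the marker chain and its hub are present
  td <- tidy(spec_cached$dag)
  has_arc <- function(a, b) any(td$from == a & td$to == b)
  expect_true(has_arc("tg_hdl_q", "tyg_q"))
  expect_true(has_arc("tyg_q", "homa_ir_q"))
  expect_true(has_arc("fbg_cat", "homa_ir_q"))
  expect_true(has_arc("diabetes", "fbg_cat"))
})

test_that("sampling is reproducible and respects the declared size and design", {
  co1 <- sample_cohort(spec_cached, 500, seed = 3)
  co2 <- sample_cohort(spec_cached, 500, seed = 3)
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 500)
  expect_true(all(c("id", "weight", "stratum", "psu") %in% names(co1)))
  expect_true(all(co1$weight > 0))
  # every PSU lies in exactly one stratum
  map <- unique(co1[, c("stratum", "psu")])
  expect_equal(anyDuplicated(map$psu), 0)
})

test_that("n = 0 yields an empty cohort with the full header", {
  co0 <- sample_cohort(spec_cached, 0, seed = 1)
  expect_equal(nrow(co0), 0)
  expect_true(all(spec_cached$dag$nodes %in% names(co0)))
})

test_that("sampled state frequencies match the root CPTs within 4 SE", {
  co <- sample_cohort(spec_cached, 20000, seed = 17)
  f <- as_bn_fit(spec_cached)
  for (v in c("sex", "diabetes")) {
    pa <- attr(f$cpts[[v]], "parents")
    if (length(pa)) next
    p0 <- f$cpts[[v]][1, 1]
    phat <- mean(as.character(co[[v]]) == f$levels[[v]][1])
    se <- sqrt(p0 * (1 - p0) / nrow(co))
    expect_lt(abs(phat - p0), 4 * se)
  }
})

test_that("emitted continuous labs reproduce the sampled threshold bins exactly", {
  co <- sample_cohort(spec_cached, 1500, seed = 21)
  em <- emit_continuous(co, spec_cached, seed = 22)
  # strip the sampled categories and re-derive from the raw labs alone
  rederived <- categorize_clinical(
    em[, setdiff(names(em), c("fbg_cat", "tg_cat", "hdl_cat", "tchol_cat",
                              "ldl_cat"))])
  for (v in c("fbg_cat", "tg_cat", "hdl_cat", "tchol_cat", "ldl_cat"))
    expect_equal(as.character(rederived[[v]]), as.character(co[[v]]), info = v)
})

test_that("emitted labs reproduce the sampled outcomes and obesity flags exactly", {
  co <- sample_cohort(spec_cached, 1500, seed = 23)
  em <- emit_continuous(co, spec_cached, seed = 24)
  strip <- setdiff(names(em), c("diabetes", "dyslipidemia", "obesity_bmi",
                                "obesity_wc", "obesity_whtr"))
  red <- define_outcomes(categorize_clinical(
    em[, setdiff(strip, c("fbg_cat", "tg_cat", "hdl_cat", "tchol_cat",
                          "ldl_cat"))]))
  for (v in c("diabetes", "dyslipidemia", "obesity_bmi", "obesity_wc",
              "obesity_whtr"))
    expect_equal(as.character(red[[v]]), as.character(co[[v]]), info = v)
})

test_that("emitted HOMA-IR quartile groups match the sampled states exactly", {
  co <- sample_cohort(spec_cached, 1500, seed = 25)
  em <- emit_continuous(co, spec_cached, seed = 26)
  idx <- derive_indices(em)
  hq <- quartile_bin(idx$homa_ir, cuts = spec_cached$cuts$homa_ir)
  expect_equal(as.character(hq), as.character(co$homa_ir_q))
  # TyG / TG-HDL are constrained best-effort emissions (the TG bin and the
  # TyG band can conflict); agreement must still be far above the 0.25 chance
  # rate, and the infeasible cases are accounted for by the generator
  tq <- quartile_bin(idx$tyg, cuts = spec_cached$cuts$tyg)
  expect_gt(mean(as.character(tq) == as.character(co$tyg_q)), 0.6)
  expect_true(all(attr(em, "index_band_misses") >= 0))
})

test_that("ages honor the sampled age group and the study window", {
  co <- sample_cohort(spec_cached, 800, seed = 27)
  em <- emit_continuous(co, spec_cached, seed = 28)
  expect_true(all(em$age >= 40 & em$age <= 69))
  grp <- cut(em$age, breaks = c(-Inf, 50, 60, Inf),
             labels = c("40-49", "50-59", "60-69"), right = FALSE)
  expect_equal(as.character(grp), as.character(co$age_group))
})

test_that("informative weights remain positive and tilt the design", {
  co1 <- sample_cohort(spec_cached, 2000, seed = 29)
  spec_i <- ir_ground_truth(informative_weights = TRUE)
  co2 <- sample_cohort(spec_i, 2000, seed = 29)
  expect_true(all(co2$weight > 0))
  # informative design: weighted and unweighted diabetes prevalence diverge
  wprev <- function(co) weighted.mean(co$diabetes == "yes", co$weight)
  uprev <- function(co) mean(co$diabetes == "yes")
  expect_gt(abs(wprev(co2) - uprev(co2)), abs(wprev(co1) - uprev(co1)) / 2)
})

test_that("cohort CSV round-trips preserve factors and validate", {
  co <- sample_cohort(spec_cached, 120, seed = 31)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 120)
  expect_s3_class(back$fbg_cat, "factor")
  expect_equal(levels(back$fbg_cat), c("Normal", "Caution", "Danger"))
  expect_equal(as.character(back$diabetes), as.character(co$diabetes))
})

test_that("the codebook validates and rejects malformed cohorts", {
  cb <- ir_codebook()
  expect_silent(validate_codebook(cb))
  co <- sample_cohort(spec_cached, 50, seed = 33)
  expect_silent(validate_cohort(co, cb))
  bad <- co
  bad$weight[1] <- -1
  expect_error(validate_cohort(bad, cb), "weight")
  bad2 <- co
  bad2$fbg_cat <- factor(rep("Weird", 50))
  expect_error(validate_cohort(bad2, cb), "fbg_cat")
})
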
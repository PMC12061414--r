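trivial_design <- function(d) {
  d$weight <- 1
  d$stratum <- 1L
  d$psu <- seq_len(nrow(d))
  d
}

test_that("weighted proportions reduce to relative frequencies under unit weights", {
  d <- trivial_design(tibble::tibble(v = factor(c("a", "a", "b", "b", "b"))))
  out <- weighted_proportions(d, "v")
  expect_equal(out$prop, c(2, 3) / 5)
  expect_equal(sum(out$prop), 1)
})

test_that("weighted proportions are invariant to weight rescaling", {
  d <- tibble::tibble(v = factor(rep(c("a", "b", "c"), times = c(5, 3, 2))),
                      weight = c(rep(2, 5), rep(1, 3), rep(4, 2)),
                      stratum = 1L, psu = 1:10)
  p1 <- weighted_proportions(d, "v")$prop
  d$weight <- d$weight * 1000
  p2 <- weighted_proportions(d, "v")$prop
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("Rao-Scott collapses to the Pearson statistic under a trivial design", {
  withr::with_seed(5, {
    d <- trivial_design(tibble::tibble(
      v = factor(sample(c("a", "b", "c"), 200, replace = TRUE)),
      o = factor(sample(c("no", "yes"), 200, replace = TRUE))))
  })
  rs <- rao_scott_chi2(d, "v", "o")
  pear <- suppressWarnings(chisq.test(table(d$v, d$o), correct = FALSE))
  expect_lt(abs(rs$x2 - unname(pear$statistic)), 1e-10)
})

test_that("Rao-Scott detects a strong association under a cluster design", {
  withr::with_seed(6, {
    n <- 400
    v <- sample(c("a", "b"), n, replace = TRUE)
    o <- ifelse(runif(n) < ifelse(v == "a", 0.8, 0.2), "yes", "no")
    d <- tibble::tibble(v = factor(v), o = factor(o),
                        weight = rlnorm(n, 0, 0.3),
                        stratum = rep(1:5, each = 80),
                        psu = rep(1:40, each = 10))
  })
  rs <- rao_scott_chi2(d, "v", "o")
  expect_lt(rs$p_value, 1e-6)
  expect_gt(rs$statistic, 0)
  expect_true(rs$ndf > 0 && rs$ddf > 0)
})

test_that("singleton PSUs error by default and center on request", {
  d <- tibble::tibble(v = factor(rep(c("a", "b"), 10)),
                      o = factor(rep(c("no", "yes"), each = 10)),
                      weight = 1,
                      stratum = c(1L, rep(2L, 19)),
                      psu = c(1L, rep(2:5, length.out = 19)))
  expect_error(rao_scott_chi2(d, "v", "o"), "single PSU")
  rs <- rao_scott_chi2(d, "v", "o", singleton = "center")
  expect_s3_class(rs, "rao_scott")
  expect_match(rs$correction, "centered")
})

test_that("mutual information matches the closed form for a 2x2 joint", {
  # joint (0.4, 0.1, 0.1, 0.4): MI = 0.8 ln 1.6 + 0.2 ln 0.4
  d <- tibble::tibble(
    v = factor(rep(c("a", "a", "b", "b"), times = c(40, 10, 10, 40))),
    o = factor(rep(c("no", "yes", "no", "yes"), times = c(40, 10, 10, 40))),
    weight = 1, stratum = 1L, psu = 1:100)
  mi <- weighted_mutual_information(d, "v", "o")
  closed <- 0.8 * log(1.6) + 0.2 * log(0.4)
  expect_equal(mi$mi_nats, closed, tolerance = 1e-12)
  expect_equal(mi$h_outcome, log(2), tolerance = 1e-12)
  expect_equal(mi$normalized_pct, 100 * closed / log(2), tolerance = 1e-10)
})

test_that("mutual information is symmetric, non-negative, and entropy-bounded", {
  withr::with_seed(8, {
    d <- tibble::tibble(
      v = factor(sample(c("a", "b", "c"), 300, replace = TRUE)),
      o = factor(sample(c("no", "yes"), 300, replace = TRUE)),
      weight = rlnorm(300), stratum = 1L, psu = 1:300)
  })
  m1 <- weighted_mutual_information(d, "v", "o")$mi_nats
  m2 <- weighted_mutual_information(d, "o", "v")$mi_nats
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_gte(m1, 0)
  expect_lte(m1, log(2) + 1e-12)
})

test_that("single-level outcome is an error for mutual information", {
  d <- tibble::tibble(v = factor(c("a", "b")), o = factor(c("yes", "yes")),
                      weight = 1, stratum = 1L, psu = 1:2)
  expect_error(weighted_mutual_information(d, "v", "o"), "level")
})

test_that("AUC matches pairwise enumeration with ties and weights", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c("no", "yes", "no", "yes"))$auc, 0.75)
  # ties count one half
  expect_equal(roc_auc(c(1, 2, 2, 3), c("no", "no", "yes", "yes"))$auc, 0.875)
  # weighted enumeration: num = 2*1 + 1*1 + 1*3 = 6, denom = 3 * 4
  expect_equal(roc_auc(c(1, 2, 3, 4), c("no", "yes", "no", "yes"),
                       weights = c(1, 2, 3, 1))$auc, 0.5)
})

test_that("AUC agrees with the pROC reference implementation", {
  withr::with_seed(9, {
    x <- rnorm(150)
    y <- ifelse(runif(150) < plogis(1.2 * x), "yes", "no")
  })
  ours <- roc_auc(x, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = x,
                                        levels = c("no", "yes"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("the ROC curve starts at (0,0), ends at (1,1), and is monotone", {
  withr::with_seed(10, {
    x <- rnorm(80)
    y <- ifelse(runif(80) < plogis(x), "yes", "no")
  })
  cur <- roc_auc(x, y)$curve
  expect_equal(cur$fpr[1], 0)
  expect_equal(cur$tpr[1], 0)
  expect_equal(cur$fpr[nrow(cur)], 1)
  expect_equal(cur$tpr[nrow(cur)], 1)
  expect_true(all(diff(cur$fpr) >= 0))
  expect_true(all(diff(cur$tpr) >= 0))
})

test_that("tidy/glance methods return tibbles for survey results", {
  d <- trivial_design(tibble::tibble(
    v = factor(rep(c("a", "b"), 25)), o = factor(rep(c("no", "yes"), each = 25))))
  td <- tidy(rao_scott_chi2(d, "v", "o"))
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("statistic", "p_value") %in% names(td)))
  ra <- roc_auc(c(1, 2, 3, 4), c("no", "yes", "no", "yes"))
  expect_true("auc" %in% names(glance(ra)))
})
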
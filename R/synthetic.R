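# ---- ground-truth network construction ------------------------------------

# Build a CPT matrix (parent configs x child levels, first parent varying
# fastest) from a function mapping one parent configuration (named character
# vector) to a probability vector.
build_cpt <- function(child_levels, parents, parent_levels, f) {
  if (!length(parents)) {
    probs <- matrix(f(character(0)), 1, length(child_levels))
  } else {
    grid <- expand.grid(parent_levels[parents], KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    probs <- t(apply(grid, 1, function(row) f(setNames(as.character(row), parents))))
  }
  probs <- probs / rowSums(probs)
  colnames(probs) <- child_levels
  attr(probs, "parents") <- parents
  probs
}

# discretized-normal distribution over r ordered levels centred at `center`
# (0-based scale)
ord_probs <- function(center, r, spread = 0.8) {
  p <- exp(-((seq_len(r) - 1 - center)^2) / (2 * spread^2))
  p / sum(p)
}

#' Ground-truth network and generator settings for a KNHANES-like cohort
#'
#' Constructs the reference Bayesian network used by the synthetic cohort
#' generator: 17 categorical analysis variables over a DAG containing the
#' sequential marker chain TG/HDL ratio -> TyG index -> HOMA-IR, FBG as a
#' parent of all three marker quartile nodes and a child of diabetes, the
#' lipid variables and age as parents of dyslipidemia, the obesity
#' indicators as parents of the HOMA-IR quartile node, and a small set of
#' demographic/behavioral arcs. Conditional distributions are deliberately
#' strong (large total-variation shifts between parent levels) so that
#' structure recovery from realistic sample sizes is feasible, and marginals
#' are anchored to the prevalences typical of a 40-69-year-old health-survey
#' population.
#'
#' @param seed Unused placeholder for API symmetry (the construction is
#'   deterministic); kept so callers can treat all generator entry points
#'   uniformly.
#' @param n_strata,psus_per_stratum Survey design dimensions (defaults 17
#'   strata of 20 PSUs).
#' @param informative_weights If `TRUE`, survey weights depend on age and
#'   sex (for sensitivity analyses); by default weights are independent of
#'   all variables, mean 1.
#' @return An object of class `ground_truth_spec`: `dag`, `cpts`, `levels`,
#'   `nlev`, reference quartile `cuts` for the three markers, emission bin
#'   ranges, and the design settings.
#' @export
ir_ground_truth <- function(seed = NULL, n_strata = 17, psus_per_stratum = 20,
                            informative_weights = FALSE) {
  lv <- list(
    sex = c("M", "F"),
    age_group = c("40-49", "50-59", "60-69"),
    smoking = c("no", "yes"),
    drinking = c("no", "yes"),
    obesity_bmi = c("no", "yes"),
    obesity_wc = c("no", "yes"),
    obesity_whtr = c("no", "yes"),
    diabetes = c("no", "yes"),
    fbg_cat = c("Normal", "Caution", "Danger"),
    tg_cat = c("Normal", "Caution", "Danger"),
    hdl_cat = c("Normal", "Danger"),
    tchol_cat = c("Normal", "Caution", "Danger"),
    ldl_cat = c("Normal", "Caution", "Danger"),
    dyslipidemia = c("no", "yes"),
    tg_hdl_q = c("Q1", "Q2", "Q3", "Q4"),
    tyg_q = c("Q1", "Q2", "Q3", "Q4"),
    homa_ir_q = c("Q1", "Q2", "Q3", "Q4")
  )
  arcs <- rbind(
    c("sex", "smoking"), c("sex", "drinking"),
    c("age_group", "obesity_bmi"),
    c("obesity_bmi", "obesity_wc"), c("sex", "obesity_wc"),
    c("obesity_bmi", "obesity_whtr"),
    c("age_group", "diabetes"), c("obesity_bmi", "diabetes"),
    c("diabetes", "fbg_cat"),
    c("smoking", "tg_cat"), c("sex", "hdl_cat"), c("tchol_cat", "ldl_cat"),
    c("tg_cat", "dyslipidemia"), c("hdl_cat", "dyslipidemia"),
    c("tchol_cat", "dyslipidemia"), c("ldl_cat", "dyslipidemia"),
    c("age_group", "dyslipidemia"),
    c("fbg_cat", "tg_hdl_q"), c("fbg_cat", "tyg_q"), c("fbg_cat", "homa_ir_q"),
    c("tg_hdl_q", "tyg_q"), c("tyg_q", "homa_ir_q"),
    c("obesity_bmi", "homa_ir_q"), c("obesity_wc", "homa_ir_q"),
    c("obesity_whtr", "homa_ir_q")
  )
  dag <- bn_dag(names(lv), arcs)

  lvnum <- function(cfg, v) match(cfg[[v]], lv[[v]])  # 1-based level index
  cpt <- function(child, parents, f) build_cpt(lv[[child]], parents, lv, f)

  cpts <- list(
    sex = cpt("sex", character(0), function(cfg) c(0.50, 0.50)),
    age_group = cpt("age_group", character(0), function(cfg) c(0.37, 0.37, 0.26)),
    smoking = cpt("smoking", "sex", function(cfg)
      if (cfg[["sex"]] == "M") c(0.55, 0.45) else c(0.93, 0.07)),
    drinking = cpt("drinking", "sex", function(cfg)
      if (cfg[["sex"]] == "M") c(0.30, 0.70) else c(0.60, 0.40)),
    obesity_bmi = cpt("obesity_bmi", "age_group", function(cfg) {
      p <- c(0.20, 0.46, 0.72)[lvnum(cfg, "age_group")]
      c(1 - p, p)
    }),
    obesity_wc = cpt("obesity_wc", c("obesity_bmi", "sex"), function(cfg) {
      p <- if (cfg[["sex"]] == "M") c(0.10, 0.70) else c(0.40, 0.96)
      p <- p[lvnum(cfg, "obesity_bmi")]
      c(1 - p, p)
    }),
    obesity_whtr = cpt("obesity_whtr", "obesity_bmi", function(cfg) {
      p <- c(0.35, 0.90)[lvnum(cfg, "obesity_bmi")]
      c(1 - p, p)
    }),
    diabetes = cpt("diabetes", c("age_group", "obesity_bmi"), function(cfg) {
      base <- c(0.03, 0.14, 0.32)[lvnum(cfg, "age_group")]
      p <- min(base + 0.30 * (lvnum(cfg, "obesity_bmi") - 1), 0.95)
      c(1 - p, p)
    }),
    fbg_cat = cpt("fbg_cat", "diabetes", function(cfg)
      if (cfg[["diabetes"]] == "yes") c(0.05, 0.37, 0.58) else c(0.65, 0.35, 0.00)),
    tg_cat = cpt("tg_cat", "smoking", function(cfg)
      if (cfg[["smoking"]] == "yes") c(0.40, 0.25, 0.35) else c(0.72, 0.15, 0.13)),
    hdl_cat = cpt("hdl_cat", "sex", function(cfg)
      if (cfg[["sex"]] == "M") c(0.70, 0.30) else c(0.97, 0.03)),
    tchol_cat = cpt("tchol_cat", character(0), function(cfg) c(0.52, 0.34, 0.14)),
    ldl_cat = cpt("ldl_cat", "tchol_cat", function(cfg)
      switch(cfg[["tchol_cat"]],
             Normal = c(0.85, 0.14, 0.01),
             Caution = c(0.45, 0.45, 0.10),
             Danger = c(0.12, 0.48, 0.40))),
    dyslipidemia = cpt("dyslipidemia",
                       c("tg_cat", "hdl_cat", "tchol_cat", "ldl_cat", "age_group"),
                       function(cfg) {
      forced <- cfg[["tg_cat"]] == "Danger" || cfg[["hdl_cat"]] == "Danger" ||
        cfg[["tchol_cat"]] == "Danger" || cfg[["ldl_cat"]] == "Danger"
      if (forced) return(c(0, 1))
      p <- 0.05 + 0.28 * (cfg[["tg_cat"]] == "Caution") +
        0.26 * (cfg[["tchol_cat"]] == "Caution") +
        0.24 * (cfg[["ldl_cat"]] == "Caution") +
        c(0, 0.22, 0.40)[lvnum(cfg, "age_group")]
      p <- min(p, 0.97)
      c(1 - p, p)
    }),
    tg_hdl_q = cpt("tg_hdl_q", "fbg_cat", function(cfg)
      switch(cfg[["fbg_cat"]],
             Normal = c(0.45, 0.30, 0.15, 0.10),
             Caution = c(0.20, 0.30, 0.30, 0.20),
             Danger = c(0.05, 0.15, 0.30, 0.50))),
    tyg_q = cpt("tyg_q", c("fbg_cat", "tg_hdl_q"), function(cfg) {
      center <- 0.80 * (lvnum(cfg, "tg_hdl_q") - 1) +
        0.95 * (lvnum(cfg, "fbg_cat") - 1)
      ord_probs(min(center, 3.2), 4, spread = 0.75)
    }),
    homa_ir_q = cpt("homa_ir_q",
                    c("fbg_cat", "tyg_q", "obesity_bmi", "obesity_wc", "obesity_whtr"),
                    function(cfg) {
      center <- 0.60 * (lvnum(cfg, "tyg_q") - 1) +
        0.60 * (lvnum(cfg, "fbg_cat") - 1) +
        0.50 * (lvnum(cfg, "obesity_bmi") - 1) +
        0.48 * (lvnum(cfg, "obesity_wc") - 1) +
        0.45 * (lvnum(cfg, "obesity_whtr") - 1)
      ord_probs(min(center, 3.4), 4, spread = 0.75)
    })
  )
  # CPT rows must live in the row order cpt_config_grid/cfg_index expect:
  # first parent fastest; build_cpt's expand.grid already does that.
  spec <- structure(list(
    dag = dag,
    cpts = cpts,
    levels = lv,
    nlev = setNames(lengths(lv), names(lv)),
    cuts = list(homa_ir = c(1.15, 1.75, 2.79),
                tyg = c(8.22, 8.66, 9.11),
                tg_hdl = c(1.37, 2.27, 3.83)),
    bins = list(
      fbg = list(Normal = c(76, 100), Caution = c(100, 126), Danger = c(126, 280)),
      tg = list(Normal = c(40, 150), Caution = c(150, 200), Danger = c(200, 600)),
      hdl = list(Normal = c(40.5, 95), Danger = c(22, 39.9)),
      tchol = list(Normal = c(120, 200), Caution = c(200, 240), Danger = c(240, 340)),
      ldl = list(Normal = c(50, 130), Caution = c(130, 190), Danger = c(190, 250)),
      bmi = list(no = c(18.5, 25), yes = c(25, 38)),
      homa_ir = list(Q1 = c(0.25, 1.15), Q2 = c(1.15, 1.75),
                     Q3 = c(1.75, 2.79), Q4 = c(2.79, 11)),
      tyg = list(Q1 = c(7.2, 8.22), Q2 = c(8.22, 8.66),
                 Q3 = c(8.66, 9.11), Q4 = c(9.11, 10.6)),
      tg_hdl = list(Q1 = c(0.45, 1.37), Q2 = c(1.37, 2.27),
                    Q3 = c(2.27, 3.83), Q4 = c(3.83, 16))
    ),
    n_strata = n_strata,
    psus_per_stratum = psus_per_stratum,
    weight_sdlog = 0.35,
    informative_weights = informative_weights
  ), class = "ground_truth_spec")
  # structural sanity: every CPT row sums to one
  stopifnot(all(vapply(spec$cpts, function(m) max(abs(rowSums(m) - 1)), 0) < 1e-12))
  spec
}

#' @export
print.ground_truth_spec <- function(x, ...) {
  cat("<ground_truth_spec> ", length(x$dag$nodes), " nodes, ",
      nrow(x$dag$arcs), " arcs, ", x$n_strata, " strata x ",
      x$psus_per_stratum, " PSUs\n", sep = "")
  invisible(x)
}

# view a ground-truth spec as a fitted network (for sampling and queries)
as_bn_fit <- function(spec) {
  structure(list(dag = spec$dag, cpts = spec$cpts, levels = spec$levels,
                 nlev = spec$nlev, alpha = 0),
            class = "bn_fit", uniform_rows = 0L)
}

#' Sample a categorical survey cohort from a ground-truth network
#'
#' Ancestral sampling along a topological order of the ground-truth DAG,
#' followed by attachment of survey design columns: records are spread
#' uniformly over strata and PSUs-within-strata, and weights are drawn from
#' a log-normal with mean 1 (independent of all variables unless the spec
#' requests informative weights, in which case weights are tilted by age
#' group and sex and rescaled to mean 1). Identical `(spec, n, seed)`
#' reproduce the table bit for bit.
#'
#' @param spec A `ground_truth_spec` from [ir_ground_truth()].
#' @param n Number of records (>= 0).
#' @param seed Integer seed.
#' @return A cohort tibble: `id`, the categorical analysis columns, and
#'   `weight`, `stratum`, `psu`.
#' @export
sample_cohort <- function(spec, n = 8195, seed = 1L) {
  stopifnot(inherits(spec, "ground_truth_spec"), n >= 0)
  fbn <- as_bn_fit(spec)
  cols <- c("id", spec$dag$nodes, "weight", "stratum", "psu")
  if (n == 0) {
    out <- c(list(id = integer()),
             setNames(lapply(spec$dag$nodes, function(v)
               factor(character(), levels = spec$levels[[v]])), spec$dag$nodes),
             list(weight = numeric(), stratum = character(), psu = character()))
    return(tibble::as_tibble(out)[, cols])
  }
  with_local_seed(seed, {
    sim <- sample_network(fbn, n)
    df <- as.data.frame(lapply(spec$dag$nodes, function(v)
      factor(spec$levels[[v]][sim$S[, v]], levels = spec$levels[[v]])),
      col.names = spec$dag$nodes)
    stratum <- sample(sprintf("st%02d", seq_len(spec$n_strata)), n, replace = TRUE)
    psu <- paste0(stratum, "_psu",
                  sprintf("%02d", sample.int(spec$psus_per_stratum, n, replace = TRUE)))
    w <- rlnorm(n, meanlog = -spec$weight_sdlog^2 / 2, sdlog = spec$weight_sdlog)
    if (spec$informative_weights) {
      tilt <- c("40-49" = 1.3, "50-59" = 1.0, "60-69" = 0.7)[as.character(df$age_group)] *
        ifelse(df$sex == "F", 1.15, 0.85)
      w <- w * tilt
      w <- w / mean(w)
    }
    out <- tibble::as_tibble(df)
    out$id <- seq_len(n)
    out$weight <- w
    out$stratum <- stratum
    out$psu <- psu
    out[, cols]
  })
}

# draw uniformly in [lo, hi) per record (vectorized over interval bounds)
runif_in <- function(lo, hi) lo + runif(length(lo)) * (hi - lo)

bin_bounds <- function(spec, var, states) {
  b <- spec$bins[[var]]
  lo <- vapply(as.character(states), function(s) b[[s]][1], 0)
  hi <- vapply(as.character(states), function(s) b[[s]][2], 0)
  list(lo = lo, hi = hi)
}

#' Emit continuous measurements consistent with sampled categorical states
#'
#' Adds raw laboratory and anthropometric columns to a sampled cohort such
#' that re-deriving the threshold-based categories with
#' [categorize_clinical()] and the composite outcomes with
#' [define_outcomes()] reproduces the sampled states exactly. Diagnosis /
#' medication flags are set wherever a sampled outcome is not already
#' implied by an emitted laboratory criterion, and lab values that would
#' contradict a sampled "no" outcome are constrained away (e.g. LDL in its
#' Caution bin is kept below 160 mg/dL for records without dyslipidemia).
#'
#' The continuous marker values are matched to the sampled quartile states
#' against the spec's fixed reference cut points: HOMA-IR exactly (insulin
#' is free given FBG), TyG and TG/HDL best-effort (TG and HDL are drawn
#' inside the intersection of their clinical bin and the quartile band where
#' that intersection is non-empty; the count of unmatched records is
#' reported in the `"index_band_misses"` attribute).
#'
#' @param cohort A cohort from [sample_cohort()].
#' @param spec The `ground_truth_spec` that generated it.
#' @param seed Integer seed.
#' @return The cohort with continuous columns (`age`, `height`, `insulin`,
#'   `fbg`, `tg`, `hdl`, `tchol`, `ldl`, `hba1c`, `sbp`, `dbp`, `bmi`, `wc`)
#'   and flag columns appended.
#' @export
emit_continuous <- function(cohort, spec, seed = 1L) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  n <- nrow(cohort)
  if (n == 0) return(cohort)
  with_local_seed(seed, {
    out <- cohort
    # age uniform within its group
    age_lo <- c("40-49" = 40, "50-59" = 50, "60-69" = 60)[as.character(out$age_group)]
    out$age <- floor(runif_in(age_lo, age_lo + 10))

    # labs constrained to their sampled clinical bins
    b <- bin_bounds(spec, "fbg", out$fbg_cat); out$fbg <- runif_in(b$lo, b$hi)
    b <- bin_bounds(spec, "tchol", out$tchol_cat); out$tchol <- runif_in(b$lo, b$hi)

    # LDL: Caution bin straddles the 160 mg/dL dyslipidemia criterion; keep
    # non-dyslipidemic records below it
    b <- bin_bounds(spec, "ldl", out$ldl_cat)
    cap <- ifelse(out$dyslipidemia == "no" & out$ldl_cat == "Caution", 160, b$hi)
    out$ldl <- runif_in(b$lo, pmin(b$hi, cap))

    # TG inside its bin, pulled toward the TyG quartile band where feasible
    bt <- bin_bounds(spec, "tg", out$tg_cat)
    qb <- bin_bounds(spec, "tyg", out$tyg_q)
    tg_lo <- pmax(bt$lo, 2 * exp(qb$lo) / out$fbg)
    tg_hi <- pmin(bt$hi, 2 * exp(qb$hi) / out$fbg)
    feasible <- tg_lo < tg_hi
    out$tg <- ifelse(feasible, runif_in(tg_lo, pmax(tg_lo, tg_hi)),
                     runif_in(bt$lo, bt$hi))
    tyg_miss <- sum(!feasible)

    # HDL inside its bin, pulled toward the TG/HDL quartile band
    bh <- bin_bounds(spec, "hdl", out$hdl_cat)
    rb <- bin_bounds(spec, "tg_hdl", out$tg_hdl_q)
    hdl_lo <- pmax(bh$lo, out$tg / rb$hi)
    hdl_hi <- pmin(bh$hi, out$tg / rb$lo)
    feas_h <- hdl_lo < hdl_hi
    out$hdl <- ifelse(feas_h, runif_in(hdl_lo, pmax(hdl_lo, hdl_hi)),
                      runif_in(bh$lo, bh$hi))
    ratio_miss <- sum(!feas_h)

    # insulin back-solved so HOMA-IR lands exactly in its quartile band
    hb <- bin_bounds(spec, "homa_ir", out$homa_ir_q)
    homa <- runif_in(hb$lo, hb$hi)
    out$insulin <- 405 * homa / out$fbg

    # anthropometrics: BMI in its bin; height then WC so that both the WC
    # bin and the WHtR >= 0.5 state hold simultaneously
    bb <- bin_bounds(spec, "bmi", out$obesity_bmi)
    out$bmi <- runif_in(bb$lo, bb$hi)
    male <- as.character(out$sex) == "M"
    wc_lo <- ifelse(male, ifelse(out$obesity_wc == "yes", 90, 72),
                          ifelse(out$obesity_wc == "yes", 85, 62))
    wc_hi <- ifelse(male, ifelse(out$obesity_wc == "yes", 118, 90),
                          ifelse(out$obesity_wc == "yes", 112, 85))
    h_min <- ifelse(male, 150, 145)
    h_max <- ifelse(male, 195, 180)
    whtr_yes <- out$obesity_whtr == "yes"
    # whtr yes: wc >= h/2 -> h <= 2*wc_hi; whtr no: wc < h/2 -> h > 2*wc_lo
    h_lo <- pmax(h_min, ifelse(whtr_yes, h_min, 2 * wc_lo + 0.2))
    h_hi <- pmin(h_max, ifelse(whtr_yes, 2 * wc_hi - 0.2, h_max))
    bad_h <- h_lo >= h_hi
    h_lo[bad_h] <- h_min[bad_h]; h_hi[bad_h] <- h_max[bad_h]
    out$height <- runif_in(h_lo, h_hi)
    wlo <- pmax(wc_lo, ifelse(whtr_yes, out$height / 2, wc_lo))
    whi <- pmin(wc_hi, ifelse(whtr_yes, wc_hi, out$height / 2 - 0.1))
    bad_w <- wlo >= whi
    out$wc <- runif_in(wlo, pmax(wlo + 0.1, whi))
    anthro_miss <- sum(bad_h | bad_w)

    # HbA1c: below the 6.5% diabetes criterion unless diabetes is sampled
    diab <- out$diabetes == "yes"
    fbg_danger <- out$fbg_cat == "Danger"
    out$hba1c <- ifelse(diab & fbg_danger, runif_in(rep(6.6, n), rep(9.5, n)),
                        runif_in(rep(5.0, n), rep(6.4, n)))

    # blood pressure (not constrained by any sampled node)
    out$sbp <- runif_in(rep(95, n), rep(175, n))
    out$dbp <- runif_in(rep(60, n), rep(104, n))

    # flags reconcile sampled outcomes with emitted labs
    yn <- function(x) factor(ifelse(x, "yes", "no"), levels = c("no", "yes"))
    lab_dysl <- out$tg_cat == "Danger" | out$hdl_cat == "Danger" |
      out$tchol_cat == "Danger" | out$ldl >= 160
    out$lipid_diagnosis <- yn(out$dyslipidemia == "yes" & !lab_dysl)
    out$lipid_medication <- yn(rep(FALSE, n))
    lab_diab <- fbg_danger | out$hba1c >= 6.5
    out$dm_diagnosis <- yn(diab & !lab_diab)
    out$dm_medication <- yn(rep(FALSE, n))
    out$htn_diagnosis <- yn(rep(FALSE, n))
    out$htn_medication <- yn(rep(FALSE, n))
    for (h in c("cvd_history", "cancer_history", "kidney_history"))
      out[[h]] <- yn(rep(FALSE, n))

    attr(out, "index_band_misses") <- c(tyg = tyg_miss, tg_hdl = ratio_miss,
                                        anthropometry = anthro_miss)
    out
  })
}

# minimum over parents of the mean adjacent-level total-variation shift of a
# CPT; used to verify the generator's "strong CPT" guarantee
cpt_parent_tv <- function(spec, node) {
  cptm <- spec$cpts[[node]]
  pa <- attr(cptm, "parents")
  if (!length(pa)) return(numeric(0))
  nl <- spec$nlev[pa]
  grid <- as.matrix(expand.grid(lapply(nl, seq_len), KEEP.OUT.ATTRS = FALSE))
  out <- setNames(numeric(length(pa)), pa)
  for (j in seq_along(pa)) {
    tvs <- c()
    for (row in seq_len(nrow(grid))) {
      cfg <- grid[row, ]
      if (cfg[j] >= nl[j]) next
      cfg2 <- cfg; cfg2[j] <- cfg[j] + 1
      i1 <- cfg_index(matrix(cfg, 1), nl)
      i2 <- cfg_index(matrix(cfg2, 1), nl)
      tvs <- c(tvs, 0.5 * sum(abs(cptm[i1, ] - cptm[i2, ])))
    }
    out[j] <- mean(tvs)
  }
  out
}
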
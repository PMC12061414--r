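#' Compute the three insulin-resistance surrogate indices
#'
#' Computes, per participant, HOMA-IR = insulin (uIU/mL) x FBG (mg/dL) / 405,
#' the triglyceride-glucose index TyG = ln(TG (mg/dL) x FBG (mg/dL) / 2), and
#' the TG/HDL ratio = TG (mg/dL) / HDL (mg/dL).
#'
#' A missing insulin value yields a missing HOMA-IR (never zero); non-positive
#' FBG, TG or HDL is a domain error naming the offending field.
#'
#' @param insulin Fasting insulin, uIU/mL (may contain `NA`).
#' @param fbg Fasting blood glucose, mg/dL; must be > 0.
#' @param tg Triglycerides, mg/dL; must be > 0.
#' @param hdl HDL cholesterol, mg/dL; must be > 0.
#' @return A tibble with columns `homa_ir`, `tyg`, `tg_hdl`.
#' @examples
#' compute_indices(insulin = 8.1, fbg = 100, tg = 150, hdl = 50)
#' @export
compute_indices <- function(insulin, fbg, tg, hdl) {
  for (nm in c("fbg", "tg", "hdl")) {
    v <- get(nm)
    if (any(!is.na(v) & v <= 0))
      stop("non-positive values in '", nm, "': indices undefined", call. = FALSE)
  }
  tibble::tibble(
    homa_ir = insulin * fbg / 405,
    tyg = log(tg * fbg / 2),
    tg_hdl = tg / hdl
  )
}

#' Add the IR indices to a cohort table
#'
#' Pipe-friendly wrapper around [compute_indices()]: reads the `insulin`,
#' `fbg`, `tg` and `hdl` columns and appends `homa_ir`, `tyg`, `tg_hdl`
#' (plus `whtr = wc / height` when both are present).
#'
#' @param cohort A cohort tibble with raw lab columns.
#' @return The cohort with index columns appended.
#' @export
derive_indices <- function(cohort) {
  idx <- compute_indices(cohort[["insulin"]] %||% rep(NA_real_, nrow(cohort)),
                         cohort$fbg, cohort$tg, cohort$hdl)
  out <- dplyr::bind_cols(cohort[setdiff(names(cohort), names(idx))], idx)
  if (all(c("wc", "height") %in% names(out)) && !("whtr" %in% names(cohort)))
    out$whtr <- out$wc / out$height
  tibble::as_tibble(out)
}

#' Friedewald estimate of LDL cholesterol
#'
#' LDL = TCHOL - HDL - TG/5, applied only where measured LDL is absent.
#' Negative estimates (possible at extreme TG) are retained and flagged with a
#' warning rather than rejected.
#'
#' @param tchol Total cholesterol, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param tg Triglycerides, mg/dL.
#' @return Numeric vector of estimated LDL, mg/dL.
#' @examples
#' friedewald_ldl(200, 50, 150) # 120
#' @export
friedewald_ldl <- function(tchol, hdl, tg) {
  out <- tchol - hdl - tg / 5
  if (any(!is.na(out) & out < 0))
    warning("negative Friedewald LDL estimate(s) retained", call. = FALSE)
  out
}

#' Fill unmeasured LDL via the Friedewald formula
#'
#' The estimate is only applied where it is valid: records with TG > 400
#' mg/dL (outside the formula's validity range) or a negative estimate keep
#' a missing LDL, which the exclusion cascade then treats as incomplete
#' data.
#'
#' @param cohort A cohort tibble with `tchol`, `hdl`, `tg` and optionally
#'   `ldl` columns.
#' @return The cohort with `ldl` completed where the formula is valid and a
#'   logical `ldl_friedewald` column marking imputed entries.
#' @export
impute_ldl <- function(cohort) {
  if (!("ldl" %in% names(cohort))) cohort$ldl <- NA_real_
  miss <- is.na(cohort$ldl)
  cohort$ldl_friedewald <- miss
  if (any(miss)) {
    est <- suppressWarnings(friedewald_ldl(cohort$tchol[miss],
                                           cohort$hdl[miss], cohort$tg[miss]))
    est[!is.na(est) & (est < 0 | cohort$tg[miss] > 400)] <- NA_real_
    cohort$ldl[miss] <- est
    cohort$ldl_friedewald <- cohort$ldl_friedewald & !is.na(cohort$ldl)
  }
  cohort
}

# Clinical bin definitions: breaks are lower-bound inclusive (value == named
# threshold falls in the higher bin, e.g. FBG 126 -> Danger).
clinical_bins <- function() {
  list(
    sbp   = list(breaks = c(120, 140), labels = c("Normal", "Caution", "Danger")),
    dbp   = list(breaks = c(80, 90),   labels = c("Normal", "Caution", "Danger")),
    fbg   = list(breaks = c(100, 126), labels = c("Normal", "Caution", "Danger")),
    hba1c = list(breaks = c(5.7, 6.4), labels = c("Normal", "Caution", "Danger")),
    hdl   = list(breaks = 40,          labels = c("Danger", "Normal")),
    tg    = list(breaks = c(150, 200), labels = c("Normal", "Caution", "Danger")),
    tchol = list(breaks = c(200, 240), labels = c("Normal", "Caution", "Danger")),
    ldl   = list(breaks = c(130, 190), labels = c("Normal", "Caution", "Danger"))
  )
}

#' Assign clinical categories from continuous measurements
#'
#' Maps each available clinical measurement to its Normal/Caution/Danger (or
#' binary) category using the standard cut-offs: SBP <120/120-139/>=140 mmHg,
#' DBP <80/80-89/>=90, FBG <100/100-125/>=126 mg/dL, HbA1c <5.7/5.7-6.3/>=6.4
#' percent, HDL <40 (Danger), TG <150/150-199/>=200, TCHOL <200/200-239/>=240,
#' LDL <130/130-189/>=190 mg/dL. Every boundary is lower-bound inclusive of
#' the named threshold. Also adds `age_group` (40-49/50-59/60-69) when `age`
#' is present. Categories already present for variables whose raw measurement
#' is absent are left untouched, so the operation is idempotent.
#'
#' @param cohort A cohort tibble with raw measurement columns.
#' @param guard_mult Physiological guard: values outside `[0, guard_mult x
#'   top threshold]` raise a validation error listing the offending record
#'   ids. Default 10.
#' @return The cohort with `*_cat` (and `age_group`) columns appended.
#' @export
categorize_clinical <- function(cohort, guard_mult = 10) {
  bins <- clinical_bins()
  ids <- cohort[["id"]] %||% seq_len(nrow(cohort))
  for (v in names(bins)) {
    if (!(v %in% names(cohort))) next
    x <- cohort[[v]]
    hi <- guard_mult * max(bins[[v]]$breaks)
    bad <- !is.na(x) & (x < 0 | x > hi)
    if (any(bad))
      stop("values of '", v, "' outside guard range [0, ", hi, "] for record(s): ",
           paste(head(ids[bad], 10), collapse = ", "), call. = FALSE)
    cohort[[paste0(v, "_cat")]] <- cut(
      x, breaks = c(-Inf, bins[[v]]$breaks, Inf),
      labels = bins[[v]]$labels, right = FALSE
    )
    # binary HDL bin has Danger below the cut; relabel to declared order
    if (v == "hdl")
      cohort$hdl_cat <- factor(as.character(cohort$hdl_cat),
                               levels = c("Normal", "Danger"))
  }
  if ("age" %in% names(cohort) && !("age_group" %in% names(cohort))) {
    cohort$age_group <- cut(cohort$age, breaks = c(-Inf, 50, 60, Inf),
                            labels = c("40-49", "50-59", "60-69"), right = FALSE)
  }
  tibble::as_tibble(cohort)
}

or_criteria <- function(...) {
  comps <- list(...)
  comps <- comps[!vapply(comps, is.null, TRUE)]
  if (!length(comps)) return(NULL)
  m <- do.call(cbind, comps)
  any_yes <- rowSums(m, na.rm = TRUE) > 0
  all_na <- rowSums(!is.na(m)) == 0
  any_na <- rowSums(is.na(m)) > 0
  out <- ifelse(any_yes, "yes", ifelse(any_na, NA, "no"))
  out[all_na] <- NA
  out
}

flag_yes <- function(cohort, nm) {
  if (nm %in% names(cohort)) as.character(cohort[[nm]]) == "yes" else NULL
}

#' Derive the composite clinical outcomes
#'
#' Each outcome is the logical OR of its guideline criteria:
#' * diabetes: FBG >= 126 mg/dL, HbA1c >= 6.5%, physician diagnosis, or
#'   anti-diabetic medication/insulin therapy;
#' * dyslipidemia: TCHOL >= 240, LDL >= 160, HDL <= 40, TG >= 200 mg/dL,
#'   diagnosis, or lipid-lowering medication;
#' * hypertension: SBP >= 140 mmHg, DBP >= 90 mmHg, diagnosis, or medication;
#' * obesity: BMI >= 25 kg/m2; WC >= 90 cm (males) / >= 85 cm (females);
#'   WHtR >= 0.5.
#'
#' A record satisfying any observed criterion is "yes" even when other
#' components are missing; a record with all components missing gets a
#' missing outcome (count reported via the `outcome_missing` attribute).
#'
#' @param cohort A cohort tibble with raw measurements and optional
#'   diagnosis/medication flag columns (`dm_diagnosis`, `dm_medication`,
#'   `lipid_diagnosis`, `lipid_medication`, `htn_diagnosis`,
#'   `htn_medication`).
#' @return The cohort with `diabetes`, `dyslipidemia`, `hypertension`,
#'   `obesity_bmi`, `obesity_wc`, `obesity_whtr` columns appended as
#'   yes/no factors.
#' @export
define_outcomes <- function(cohort) {
  gcol <- function(nm) if (nm %in% names(cohort)) cohort[[nm]] else NULL
  ge <- function(x, thr) if (is.null(x)) NULL else x >= thr
  le <- function(x, thr) if (is.null(x)) NULL else x <= thr

  diab <- or_criteria(ge(gcol("fbg"), 126), ge(gcol("hba1c"), 6.5),
                      flag_yes(cohort, "dm_diagnosis"),
                      flag_yes(cohort, "dm_medication"))
  dysl <- or_criteria(ge(gcol("tchol"), 240), ge(gcol("ldl"), 160),
                      le(gcol("hdl"), 40), ge(gcol("tg"), 200),
                      flag_yes(cohort, "lipid_diagnosis"),
                      flag_yes(cohort, "lipid_medication"))
  htn <- or_criteria(ge(gcol("sbp"), 140), ge(gcol("dbp"), 90),
                     flag_yes(cohort, "htn_diagnosis"),
                     flag_yes(cohort, "htn_medication"))
  yn <- function(x) if (is.null(x)) NULL else factor(x, levels = c("no", "yes"))
  if (!is.null(diab)) cohort$diabetes <- yn(diab)
  if (!is.null(dysl)) cohort$dyslipidemia <- yn(dysl)
  if (!is.null(htn)) cohort$hypertension <- yn(htn)

  if ("bmi" %in% names(cohort))
    cohort$obesity_bmi <- yn(ifelse(is.na(cohort$bmi), NA,
                                    ifelse(cohort$bmi >= 25, "yes", "no")))
  if (all(c("wc", "sex") %in% names(cohort))) {
    thr <- ifelse(as.character(cohort$sex) == "M", 90, 85)
    cohort$obesity_wc <- yn(ifelse(is.na(cohort$wc), NA,
                                   ifelse(cohort$wc >= thr, "yes", "no")))
  }
  whtr <- if ("whtr" %in% names(cohort)) cohort$whtr
          else if (all(c("wc", "height") %in% names(cohort))) cohort$wc / cohort$height
          else NULL
  if (!is.null(whtr))
    cohort$obesity_whtr <- yn(ifelse(is.na(whtr), NA,
                                     ifelse(whtr >= 0.5, "yes", "no")))

  missing_counts <- vapply(intersect(c("diabetes", "dyslipidemia", "hypertension"),
                                     names(cohort)),
                           function(v) sum(is.na(cohort[[v]])), 0L)
  attr(cohort, "outcome_missing") <- missing_counts
  tibble::as_tibble(cohort)
}

#' Apply the study exclusion cascade
#'
#' Removes records in this order, logging counts per criterion:
#' 1. incomplete survey/examination data (missing values among
#'    `complete_vars`);
#' 2. age outside `age_range` (default 40-69 years inclusive);
#' 3. history of cardiovascular disease (stroke, myocardial infarction,
#'    angina), cancer, or kidney disease.
#'
#' Overlapping records are attributed to the first matching criterion.
#'
#' @param cohort A cohort tibble.
#' @param age_range Inclusive age window, default `c(40, 69)`.
#' @param complete_vars Columns required to be non-missing; defaults to the
#'   core lab/anthropometric analysis variables present in the cohort.
#' @return The retained cohort, with the exclusion log available via
#'   [exclusion_log()].
#' @export
apply_exclusions <- function(cohort, age_range = c(40, 69),
                             complete_vars = NULL) {
  if (is.null(complete_vars))
    complete_vars <- intersect(
      c("age", "sex", "fbg", "tg", "hdl", "tchol", "ldl", "insulin", "bmi", "wc",
        "height"),
      names(cohort))
  n0 <- nrow(cohort)
  log <- tibble::tibble(criterion = character(), n_removed = integer(),
                        n_remaining = integer())
  add_log <- function(log, crit, removed, remaining)
    dplyr::bind_rows(log, tibble::tibble(criterion = crit,
                                         n_removed = as.integer(removed),
                                         n_remaining = as.integer(remaining)))

  keep <- if (length(complete_vars)) complete.cases(cohort[, complete_vars, drop = FALSE])
          else rep(TRUE, nrow(cohort))
  log <- add_log(log, "incomplete_data", sum(!keep), sum(keep))
  cohort <- cohort[keep, , drop = FALSE]

  in_age <- !is.na(cohort$age) & cohort$age >= age_range[1] & cohort$age <= age_range[2]
  log <- add_log(log, "age_outside_range", sum(!in_age), sum(in_age))
  cohort <- cohort[in_age, , drop = FALSE]

  hist_cols <- intersect(c("cvd_history", "cancer_history", "kidney_history"),
                         names(cohort))
  has_hist <- rep(FALSE, nrow(cohort))
  for (h in hist_cols)
    has_hist <- has_hist | (!is.na(cohort[[h]]) & as.character(cohort[[h]]) == "yes")
  log <- add_log(log, "disease_history", sum(has_hist), sum(!has_hist))
  cohort <- cohort[!has_hist, , drop = FALSE]

  if (nrow(cohort) == 0)
    stop("empty cohort after exclusions (started with ", n0, " records)",
         call. = FALSE)
  out <- tibble::as_tibble(cohort)
  attr(out, "exclusion_log") <- log
  out
}

#' Retrieve the exclusion log attached by [apply_exclusions()]
#' @param cohort A cohort returned by [apply_exclusions()].
#' @return A tibble with `criterion`, `n_removed`, `n_remaining`.
#' @export
exclusion_log <- function(cohort) attr(cohort, "exclusion_log")

#' Bin a continuous marker into quartile groups
#'
#' Cut points are the unweighted empirical quartiles of the supplied values
#' (linear interpolation between closest ranks, i.e. `stats::quantile()` type
#' 7). Labels follow the convention Q1 (<= first quartile), Q2 (first to
#' second), Q3 (second to third), Q4 (> third quartile): boundary values fall
#' in the lower group.
#'
#' @param values Numeric vector (>= 4 finite values, >= 4 distinct).
#' @param cuts Optional externally supplied cut points `c(q1, q2, q3)`;
#'   when given, the empirical quartiles are not computed.
#' @return A factor with levels Q1..Q4 and attribute `"cuts"`.
#' @examples
#' quartile_bin(1:8)
#' @export
quartile_bin <- function(values, cuts = NULL) {
  finite <- values[is.finite(values)]
  if (is.null(cuts)) {
    if (length(finite) < 4)
      stop("need at least 4 finite values to form quartiles", call. = FALSE)
    cuts <- unname(quantile(finite, probs = c(0.25, 0.5, 0.75), type = 7))
  }
  if (any(diff(cuts) < 0)) stop("quartile cuts must be non-decreasing", call. = FALSE)
  if (cuts[1] == cuts[3])
    stop("degenerate quartiles: fewer than 4 distinct values", call. = FALSE)
  lab <- ifelse(is.na(values), NA_character_,
         ifelse(values <= cuts[1], "Q1",
         ifelse(values <= cuts[2], "Q2",
         ifelse(values <= cuts[3], "Q3", "Q4"))))
  out <- factor(lab, levels = c("Q1", "Q2", "Q3", "Q4"))
  attr(out, "cuts") <- cuts
  out
}

#' Add quartile-group columns for the three IR indices
#'
#' @param cohort A cohort with `homa_ir`, `tyg`, `tg_hdl` columns (see
#'   [derive_indices()]).
#' @return The cohort with `homa_ir_q`, `tyg_q`, `tg_hdl_q` factors appended;
#'   the cut points are stored in the `"quartile_cuts"` attribute.
#' @export
add_quartile_groups <- function(cohort) {
  cuts <- list()
  for (v in c("homa_ir", "tyg", "tg_hdl")) {
    if (!(v %in% names(cohort))) next
    qv <- quartile_bin(cohort[[v]])
    cohort[[paste0(v, "_q")]] <- qv
    cuts[[v]] <- attr(qv, "cuts")
  }
  out <- tibble::as_tibble(cohort)
  attr(out, "quartile_cuts") <- cuts
  out
}
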
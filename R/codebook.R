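#' Variable registry for an insulin-resistance marker cohort
#'
#' The codebook is the single source of truth for the variables an analysis
#' uses: their roles (`continuous`, `categorical`, `outcome`, `design`),
#' ordered category levels, measurement units, and the derivation rule that
#' produced each derived column. All categorical bins follow the clinical
#' cut-offs used for KNHANES-style metabolic analyses (see
#' [categorize_clinical()]).
#'
#' @return A tibble with one row per variable: `name`, `role`, `levels`
#'   (list-column of ordered level labels, `NULL` for continuous), `units`,
#'   `derivation` (rule identifier or `NA`).
#' @examples
#' cb <- ir_codebook()
#' cb[cb$role == "design", ]
#' @export
ir_codebook <- function() {
  lv <- function(...) list(c(...))
  ncd <- c("Normal", "Caution", "Danger")
  yn <- c("no", "yes")
  qq <- c("Q1", "Q2", "Q3", "Q4")
  entries <- list(
    # raw continuous measurements
    list("age",      "continuous",  NULL, "years",   NA),
    list("height",   "continuous",  NULL, "cm",      NA),
    list("insulin",  "continuous",  NULL, "uIU/mL",  NA),
    list("fbg",      "continuous",  NULL, "mg/dL",   NA),
    list("tg",       "continuous",  NULL, "mg/dL",   NA),
    list("hdl",      "continuous",  NULL, "mg/dL",   NA),
    list("tchol",    "continuous",  NULL, "mg/dL",   NA),
    list("ldl",      "continuous",  NULL, "mg/dL",   "friedewald_when_missing"),
    list("hba1c",    "continuous",  NULL, "%",       NA),
    list("sbp",      "continuous",  NULL, "mmHg",    NA),
    list("dbp",      "continuous",  NULL, "mmHg",    NA),
    list("bmi",      "continuous",  NULL, "kg/m2",   NA),
    list("wc",       "continuous",  NULL, "cm",      NA),
    # derived indices
    list("homa_ir",  "continuous",  NULL, "unitless", "insulin*fbg/405"),
    list("tyg",      "continuous",  NULL, "ln units", "ln(tg*fbg/2)"),
    list("tg_hdl",   "continuous",  NULL, "ratio",    "tg/hdl"),
    list("whtr",     "continuous",  NULL, "ratio",    "wc/height"),
    # demographics / behaviors
    list("sex",      "categorical", c("M", "F"), "", NA),
    list("age_group","categorical", c("40-49", "50-59", "60-69"), "", "age bins"),
    list("smoking",  "categorical", yn, "", ">=5 packs lifetime or current"),
    list("drinking", "categorical", yn, "", ">=1 per month"),
    # clinical categories
    list("fbg_cat",   "categorical", ncd, "", "fbg <100 / 100-125 / >=126"),
    list("tg_cat",    "categorical", ncd, "", "tg <150 / 150-199 / >=200"),
    list("hdl_cat",   "categorical", c("Normal", "Danger"), "", "hdl >=40 / <40"),
    list("tchol_cat", "categorical", ncd, "", "tchol <200 / 200-239 / >=240"),
    list("ldl_cat",   "categorical", ncd, "", "ldl <130 / 130-189 / >=190"),
    list("hba1c_cat", "categorical", ncd, "", "hba1c <5.7 / 5.7-6.3 / >=6.4"),
    list("sbp_cat",   "categorical", ncd, "", "sbp <120 / 120-139 / >=140"),
    list("dbp_cat",   "categorical", ncd, "", "dbp <80 / 80-89 / >=90"),
    # obesity indicators
    list("obesity_bmi",  "categorical", yn, "", "bmi >= 25"),
    list("obesity_wc",   "categorical", yn, "", "wc >= 90 (M) / >= 85 (F)"),
    list("obesity_whtr", "categorical", yn, "", "whtr >= 0.5"),
    # index quartile groups
    list("homa_ir_q", "categorical", qq, "", "quartiles of homa_ir"),
    list("tyg_q",     "categorical", qq, "", "quartiles of tyg"),
    list("tg_hdl_q",  "categorical", qq, "", "quartiles of tg_hdl"),
    # diagnosis / medication / history flags
    list("dm_diagnosis",    "categorical", yn, "", NA),
    list("dm_medication",   "categorical", yn, "", NA),
    list("lipid_diagnosis", "categorical", yn, "", NA),
    list("lipid_medication","categorical", yn, "", NA),
    list("htn_diagnosis",   "categorical", yn, "", NA),
    list("htn_medication",  "categorical", yn, "", NA),
    list("cvd_history",     "categorical", yn, "", NA),
    list("cancer_history",  "categorical", yn, "", NA),
    list("kidney_history",  "categorical", yn, "", NA),
    # composite outcomes
    list("diabetes",     "outcome", yn, "", "FBG>=126 | HbA1c>=6.5 | dx | med"),
    list("dyslipidemia", "outcome", yn, "", "TCHOL>=240 | LDL>=160 | HDL<=40 | TG>=200 | dx | med"),
    list("hypertension", "outcome", yn, "", "SBP>=140 | DBP>=90 | dx | med"),
    # survey design
    list("weight",  "design", NULL, "", NA),
    list("stratum", "design", NULL, "", NA),
    list("psu",     "design", NULL, "", NA)
  )
  out <- tibble::tibble(
    name = vapply(entries, `[[`, "", 1),
    role = vapply(entries, `[[`, "", 2),
    levels = lapply(entries, `[[`, 3),
    units = vapply(entries, `[[`, "", 4),
    derivation = vapply(entries, function(e) as.character(e[[5]]), "")
  )
  validate_codebook(out)
  out
}

#' Validate a codebook
#'
#' Checks the structural invariants of a variable registry: unique names,
#' at least two unique level labels per categorical entry, and the `design`
#' role appearing exactly for `weight`, `stratum` and `psu`.
#'
#' @param codebook A codebook tibble as returned by [ir_codebook()].
#' @return The codebook, invisibly, if valid; otherwise an error.
#' @export
validate_codebook <- function(codebook) {
  stopifnot(is.data.frame(codebook),
            all(c("name", "role", "levels") %in% names(codebook)))
  if (anyDuplicated(codebook$name))
    stop("codebook variable names must be unique: ",
         paste(unique(codebook$name[duplicated(codebook$name)]), collapse = ", "))
  bad_role <- setdiff(codebook$role, c("continuous", "categorical", "outcome", "design"))
  if (length(bad_role)) stop("unknown codebook role(s): ", paste(bad_role, collapse = ", "))
  cat_rows <- codebook$role %in% c("categorical", "outcome")
  for (i in which(cat_rows)) {
    lv <- codebook$levels[[i]]
    if (length(lv) < 2)
      stop("categorical variable '", codebook$name[i], "' needs >= 2 levels")
    if (anyDuplicated(lv))
      stop("duplicate level labels in '", codebook$name[i], "'")
  }
  des <- sort(codebook$name[codebook$role == "design"])
  if (!identical(des, sort(c("weight", "stratum", "psu"))))
    stop("design role must appear exactly for weight, stratum, psu")
  invisible(codebook)
}

#' Validate a cohort table against a codebook
#'
#' Checks that survey weights are strictly positive, categorical values fall
#' within their declared levels, participant ids are unique, and every PSU
#' label nests within exactly one stratum.
#'
#' @param cohort A participant-level tibble.
#' @param codebook A codebook tibble; defaults to [ir_codebook()].
#' @param id Name of the participant id column (default `"id"`); ignored if
#'   absent.
#' @return The cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort, codebook = ir_codebook(), id = "id") {
  stopifnot(is.data.frame(cohort))
  if (id %in% names(cohort) && anyDuplicated(cohort[[id]]))
    stop("duplicate participant ids")
  if ("weight" %in% names(cohort)) {
    w <- cohort$weight
    if (any(!is.finite(w)) || any(w <= 0)) stop("all survey weights must be > 0")
  }
  cat_vars <- codebook$name[codebook$role %in% c("categorical", "outcome")]
  for (v in intersect(cat_vars, names(cohort))) {
    lv <- codebook$levels[[match(v, codebook$name)]]
    vals <- as.character(cohort[[v]])
    bad <- setdiff(unique(vals[!is.na(vals)]), lv)
    if (length(bad))
      stop("values outside declared levels for '", v, "': ",
           paste(bad, collapse = ", "))
  }
  if (all(c("stratum", "psu") %in% names(cohort))) {
    nest <- unique(cohort[, c("stratum", "psu")])
    if (anyDuplicated(nest$psu))
      stop("each PSU label must nest within exactly one stratum")
  }
  invisible(cohort)
}

#' Write / read a codebook as YAML
#'
#' @param codebook A codebook tibble.
#' @param path File path.
#' @return `write_codebook()` returns `path` invisibly; `read_codebook()`
#'   returns a codebook tibble.
#' @export
write_codebook <- function(codebook, path) {
  entries <- lapply(seq_len(nrow(codebook)), function(i) {
    list(name = codebook$name[i], role = codebook$role[i],
         levels = as.list(codebook$levels[[i]]),
         units = codebook$units[i],
         derivation = if (is.na(codebook$derivation[i])) NULL else codebook$derivation[i])
  })
  yaml::write_yaml(list(variables = entries), path)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  raw <- yaml::read_yaml(path)$variables
  out <- tibble::tibble(
    name = vapply(raw, `[[`, "", "name"),
    role = vapply(raw, `[[`, "", "role"),
    levels = lapply(raw, function(e) {
      lv <- unlist(e$levels)
      if (length(lv)) as.character(lv) else NULL
    }),
    units = vapply(raw, function(e) e$units %||% "", ""),
    derivation = vapply(raw, function(e) as.character(e$derivation %||% NA), "")
  )
  validate_codebook(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
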
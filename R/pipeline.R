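#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default. All
#' randomness derives from `seed`; re-running with one config reproduces the
#' report exactly.
#'
#' @param cohort Optional cohort tibble or path to a delimited cohort file;
#'   when `NULL` a synthetic cohort is generated.
#' @param codebook Codebook tibble (default [ir_codebook()]).
#' @param spec Ground-truth spec for synthetic generation (default
#'   [ir_ground_truth()]).
#' @param n Synthetic cohort size (default 8195, echoing the size of a
#'   typical 40-69-year-old survey analysis population).
#' @param seed Master integer seed.
#' @param bootstrap_B Bootstrap iterations for arc strengths (production
#'   default 1000; tests use 100-200).
#' @param threshold Model-averaging inclusion threshold (default 0.75).
#' @param score Structure-learning score, `"aic"` (default) or `"loglik"`.
#' @param query_method `"lw"` (default) or `"rejection"`.
#' @param n_samples Particles per conditional-probability query.
#' @param alpha CPT smoothing for the refitted network.
#' @param scenario_extra Extra conditioning variable for the stratified
#'   scenario grids (default `"obesity_bmi"`).
#' @param use_sampled_categories For synthetic cohorts, learn the network on
#'   the sampled categorical states (default `TRUE`) rather than on
#'   categories re-derived from emitted continuous labs.
#' @param out_dir Optional directory for report artifacts.
#' @return A list of class `ir_config`.
#' @export
pipeline_config <- function(cohort = NULL, codebook = ir_codebook(),
                            spec = ir_ground_truth(), n = 8195, seed = 1L,
                            bootstrap_B = 1000L, threshold = 0.75,
                            score = "aic", query_method = "lw",
                            n_samples = 1e5, alpha = 1,
                            scenario_extra = "obesity_bmi",
                            use_sampled_categories = TRUE, out_dir = NULL) {
  stopifnot(threshold > 0, threshold <= 1, bootstrap_B >= 1)
  structure(list(cohort = cohort, codebook = codebook, spec = spec, n = n,
                 seed = seed, bootstrap_B = bootstrap_B, threshold = threshold,
                 score = score, query_method = query_method,
                 n_samples = n_samples, alpha = alpha,
                 scenario_extra = scenario_extra,
                 use_sampled_categories = use_sampled_categories,
                 out_dir = out_dir),
            class = "ir_config")
}

#' Categorical analysis variables present in a cohort
#'
#' Returns, in a fixed order, the subset of the network's analysis
#' variables (demographics, obesity flags, clinical categories, outcomes,
#' and marker quartile groups) that exist as columns of `cohort` — the node
#' set used for structure learning.
#'
#' @param cohort A cohort tibble.
#' @return A character vector of column names.
#' @export
bn_node_set <- function(cohort) {
  intersect(c("sex", "age_group", "smoking", "drinking",
              "obesity_bmi", "obesity_wc", "obesity_whtr",
              "diabetes", "fbg_cat", "tg_cat", "hdl_cat", "tchol_cat",
              "ldl_cat", "dyslipidemia", "tg_hdl_q", "tyg_q", "homa_ir_q"),
            names(cohort))
}

#' Survey-weighted descriptive tables with Rao-Scott tests
#'
#' For each categorical variable, tabulates raw counts and weighted
#' proportions by each outcome and attaches the Rao-Scott chi-square
#' p-value — the Table-1/2-style summary of a survey cohort.
#'
#' @param cohort A derived cohort tibble with design columns.
#' @param vars Character vector of variables to summarise (default: the BN
#'   node set minus the outcomes).
#' @param outcomes Outcomes to stratify by (default diabetes and
#'   dyslipidemia).
#' @param singleton Passed to [rao_scott_chi2()].
#' @return A tibble: `variable`, `outcome`, `level`, outcome level columns
#'   of `n (prop)`, and `p_value`.
#' @export
describe_cohort <- function(cohort, vars = NULL,
                            outcomes = c("diabetes", "dyslipidemia"),
                            singleton = "center") {
  outcomes <- intersect(outcomes, names(cohort))
  if (is.null(vars)) vars <- setdiff(bn_node_set(cohort), outcomes)
  purrr::map_dfr(outcomes, function(oc) {
    purrr::map_dfr(vars, function(v) {
      tab <- weighted_proportions(cohort, v, by = oc)
      p <- rao_scott_chi2(cohort, v, oc, singleton = singleton)$p_value
      tab$variable <- v
      tab$outcome <- oc
      tab$p_value <- p
      names(tab)[names(tab) == v] <- "level"
      names(tab)[names(tab) == oc] <- "outcome_level"
      tab[, c("variable", "outcome", "outcome_level", "level", "n", "wsum",
              "prop", "p_value")]
    })
  })
}

#' Marker performance comparison: mutual information and AUC
#'
#' For each IR marker and outcome, computes the weighted mutual information
#' of the marker's quartile grouping with the outcome (raw nats and the
#' uncertainty coefficient as a percentage) and the weighted AUC of the
#' continuous marker value, then ranks markers within outcome by AUC.
#'
#' @param cohort A derived cohort with continuous `homa_ir`, `tyg`, `tg_hdl`
#'   columns, their quartile groups, outcomes, and a `weight` column.
#' @param outcomes Outcomes to score against.
#' @return A tibble: `marker`, `outcome`, `mi_nats`, `mi_pct`, `auc`,
#'   `rank_auc`, `rank_mi`.
#' @export
compare_markers <- function(cohort, outcomes = c("diabetes", "dyslipidemia")) {
  outcomes <- intersect(outcomes, names(cohort))
  markers <- intersect(c("homa_ir", "tyg", "tg_hdl"), names(cohort))
  w <- cohort[["weight"]] %||% rep(1, nrow(cohort))
  out <- purrr::map_dfr(outcomes, function(oc) {
    purrr::map_dfr(markers, function(m) {
      qv <- paste0(m, "_q")
      mi <- weighted_mutual_information(cohort, qv, oc)
      roc <- roc_auc(cohort[[m]], cohort[[oc]], w)
      tibble::tibble(marker = m, outcome = oc, mi_nats = mi$mi_nats,
                     mi_pct = mi$normalized_pct, auc = roc$auc)
    })
  })
  out %>%
    dplyr::group_by(.data$outcome) %>%
    dplyr::mutate(rank_auc = rank(-.data$auc, ties.method = "min"),
                  rank_mi = rank(-.data$mi_pct, ties.method = "min")) %>%
    dplyr::ungroup()
}

#' Run the full marker-network analysis pipeline
#'
#' Executes, in order: cohort acquisition (file, tibble, or seeded synthetic
#' generation with continuous emission), derivation (LDL completion, index
#' computation, clinical categorization, outcome definition, exclusions,
#' quartile binning), survey-weighted description, marker comparison
#' (MI/AUC), bootstrap structure learning, threshold model averaging, CPT
#' refit, Markov blankets of the three markers, and conditional-probability
#' scenario grids. Returns everything as an in-memory report and optionally
#' writes text artifacts (JSON summary, delimited tables, DOT graph).
#'
#' @param config An `ir_config` from [pipeline_config()].
#' @return A list of class `ir_report`: `cohort`, `exclusions`,
#'   `description`, `markers`, `strengths`, `dag`, `fit`, `blankets`,
#'   `scenarios`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ir_config"))
  synthetic <- is.null(config$cohort)
  if (synthetic) {
    cohort <- sample_cohort(config$spec, config$n, seed = child_seed(config$seed, 1))
    cohort <- emit_continuous(cohort, config$spec, seed = child_seed(config$seed, 2))
    sampled_cats <- cohort[, bn_node_set(cohort), drop = FALSE]
  } else {
    cohort <- if (is.character(config$cohort)) read_cohort(config$cohort, config$codebook)
              else config$cohort
    sampled_cats <- NULL
  }

  # derivation layer (works for user data and for emitted synthetic labs)
  derived <- cohort
  if ("tchol" %in% names(derived)) derived <- impute_ldl(derived)
  if (all(c("fbg", "tg", "hdl") %in% names(derived))) {
    derived <- derive_indices(derived)
    # synthetic cohorts already carry their sampled categorical state, which
    # stays authoritative; only user data is categorized from raw labs here
    if (!synthetic) {
      derived <- categorize_clinical(derived)
      derived <- define_outcomes(derived)
      derived <- apply_exclusions(derived)
      derived <- add_quartile_groups(derived)
    }
  }
  excl <- exclusion_log(derived)

  description <- describe_cohort(derived)
  markers <- compare_markers(derived)

  bn_data <- if (synthetic && config$use_sampled_categories) sampled_cats
             else derived[, bn_node_set(derived), drop = FALSE]
  strengths <- bootstrap_arc_strength(bn_data, B = config$bootstrap_B,
                                      seed = child_seed(config$seed, 3),
                                      kind = config$score)
  avg <- model_average(strengths, config$threshold, nodes = names(bn_data))
  fit <- fit_cpts(avg, bn_data, alpha = config$alpha)

  idx_nodes <- intersect(c("homa_ir_q", "tyg_q", "tg_hdl_q"), avg$nodes)
  blankets <- setNames(lapply(idx_nodes, function(v) markov_blanket(avg, v)),
                       idx_nodes)

  scen <- list()
  k <- 10
  for (oc in intersect(c("diabetes", "dyslipidemia"), avg$nodes)) {
    for (m in idx_nodes) {
      k <- k + 1
      scen[[paste(oc, m, sep = ".")]] <- scenario_table(
        fit, m, oc, n_samples = config$n_samples,
        method = config$query_method, seed = child_seed(config$seed, k))
    }
  }
  extra <- config$scenario_extra
  if (!is.null(extra) && extra %in% avg$nodes) {
    for (m in intersect(c("tyg_q", "homa_ir_q"), idx_nodes)) {
      k <- k + 1
      scen[[paste("diabetes", m, extra, sep = ".")]] <- scenario_table(
        fit, m, "diabetes", extra = extra, n_samples = config$n_samples,
        method = config$query_method, seed = child_seed(config$seed, k))
    }
  }

  report <- structure(list(
    cohort = derived, exclusions = excl, description = description,
    markers = markers, strengths = strengths, dag = avg, fit = fit,
    blankets = blankets, scenarios = dplyr::bind_rows(scen, .id = "scenario"),
    provenance = list(seed = config$seed, n = nrow(derived),
                      bootstrap_B = config$bootstrap_B,
                      threshold = config$threshold, score = config$score,
                      query_method = config$query_method,
                      n_samples = config$n_samples, alpha = config$alpha,
                      synthetic = synthetic)
  ), class = "ir_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.ir_report <- function(x, ...) {
  cat("<ir_report> n =", nrow(x$cohort), "| arcs =", nrow(x$dag$arcs),
      "| B =", x$provenance$bootstrap_B, "\n")
  cat("Markov blankets:\n")
  for (v in names(x$blankets))
    cat("  ", v, ": ", paste(x$blankets[[v]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write report artifacts as plain text
#'
#' Emits `report.json` (provenance, marker metrics, blankets, scenario
#' estimates), delimited tables for the description, strengths and
#' scenarios, the averaged DAG in DOT format, and the exclusion log (JSON
#' lines), into `dir`.
#'
#' @param report An `ir_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$description, file.path(dir, "description.csv"),
                   row.names = FALSE)
  utils::write.csv(report$markers, file.path(dir, "markers.csv"),
                   row.names = FALSE)
  utils::write.csv(tidy(report$strengths), file.path(dir, "arc_strengths.csv"),
                   row.names = FALSE)
  utils::write.csv(report$scenarios, file.path(dir, "scenarios.csv"),
                   row.names = FALSE)
  write_dag_dot(report$dag, file.path(dir, "network.dot"), report$strengths)
  if (!is.null(report$exclusions))
    write_exclusion_log(report$exclusions, file.path(dir, "exclusions.jsonl"))
  write_bn(report$fit, file.path(dir, "fitted_network.yaml"))
  summary <- list(
    provenance = report$provenance,
    markers = report$markers,
    blankets = report$blankets,
    arcs = tidy(report$dag),
    scenarios = report$scenarios
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
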
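#' Fit conditional probability tables on a DAG
#'
#' Maximum-likelihood (optionally Laplace-smoothed) estimation of
#' `P(V | parents(V))` for every node: each CPT entry is
#' `(N_jk + alpha) / (N_j + alpha r)`. With `alpha = 0`, a parent
#' configuration never observed in the data gets a uniform row and is flagged
#' (so queries never silently emit undefined probabilities).
#'
#' @param dag A `bn_dag`.
#' @param data A data frame of categorical columns covering the DAG's nodes.
#' @param alpha Smoothing pseudo-count, >= 0 (default 0 = MLE).
#' @param levels Optional declared level sets (see [encode_discrete()]).
#' @return An object of class `bn_fit`: the DAG plus one CPT per node
#'   (matrix of parent configurations x node levels; the first parent varies
#'   fastest across rows), declared levels, and the count of uniform-filled
#'   rows in attribute `uniform_rows`.
#' @export
fit_cpts <- function(dag, data, alpha = 0, levels = NULL) {
  stopifnot(inherits(dag, "bn_dag"), alpha >= 0)
  enc <- encode_discrete(data[, dag$nodes, drop = FALSE], levels)
  cpts <- list()
  uniform_rows <- 0L
  for (v in dag$nodes) {
    pa <- dag_parents(dag, v)
    r <- enc$nlev[[v]]
    counts <- cpp_cpt_counts(enc$X[, v], r, enc$X[, pa, drop = FALSE],
                             as.integer(enc$nlev[pa]))
    nj <- rowSums(counts)
    probs <- (counts + alpha) / (nj + alpha * r)
    empty <- nj + alpha * r == 0
    if (any(empty)) {
      probs[empty, ] <- 1 / r
      uniform_rows <- uniform_rows + sum(empty)
    }
    colnames(probs) <- enc$levels[[v]]
    attr(probs, "parents") <- pa
    cpts[[v]] <- probs
  }
  structure(list(dag = dag, cpts = cpts, levels = enc$levels,
                 nlev = enc$nlev, alpha = alpha),
            class = "bn_fit", uniform_rows = uniform_rows)
}

#' @export
print.bn_fit <- function(x, ...) {
  cat("<bn_fit> ", length(x$dag$nodes), " nodes, ", nrow(x$dag$arcs),
      " arcs, alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.bn_fit <- function(x, ...) {
  purrr::map_dfr(names(x$cpts), function(v) {
    cpt <- x$cpts[[v]]
    pa <- attr(cpt, "parents")
    cfg <- cpt_config_grid(x, v)
    out <- tibble::as_tibble(cpt[, , drop = FALSE])
    out <- tidyr::pivot_longer(dplyr::bind_cols(cfg, out),
                               cols = dplyr::all_of(colnames(cpt)),
                               names_to = "level", values_to = "prob")
    dplyr::bind_cols(tibble::tibble(node = v)[rep(1, nrow(out)), , drop = FALSE], out)
  })
}

#' @export
glance.bn_fit <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$dag$nodes), n_arcs = nrow(x$dag$arcs),
    n_parameters = sum(vapply(names(x$cpts), function(v)
      (x$nlev[[v]] - 1) * nrow(x$cpts[[v]]), 0)),
    alpha = x$alpha, uniform_rows = attr(x, "uniform_rows")
  )
}

# grid of parent configurations matching CPT row order (first parent fastest)
cpt_config_grid <- function(fbn, v) {
  pa <- attr(fbn$cpts[[v]], "parents")
  if (!length(pa)) return(tibble::tibble(.rows = 1))
  g <- expand.grid(lapply(fbn$levels[pa], identity),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(g)
}

# map a matrix of parent codes (n x k) to 1-based CPT row indices
cfg_index <- function(codes, nlev_pa) {
  if (!NCOL(codes) || is.null(codes)) return(rep(1L, NROW(codes)))
  idx <- rep(1L, nrow(codes))
  mult <- 1L
  for (j in seq_len(ncol(codes))) {
    idx <- idx + (codes[, j] - 1L) * mult
    mult <- mult * nlev_pa[j]
  }
  idx
}

query_result <- function(estimate, se, n_eff, method, seed = NA) {
  tibble::tibble(prob = estimate, se = se,
                 n_eff = n_eff, method = method, seed = seed)
}

check_assignment <- function(fbn, assignment, what) {
  for (v in names(assignment)) {
    if (!(v %in% fbn$dag$nodes)) stop("unknown ", what, " variable: ", v)
    if (!(assignment[[v]] %in% fbn$levels[[v]]))
      stop("unknown level '", assignment[[v]], "' for ", what, " variable ", v)
  }
  invisible(TRUE)
}

#' Exact conditional-probability query by joint enumeration
#'
#' Computes `P(event | evidence)` by summing the factorized joint
#' distribution over all completions of the non-evidence variables. Intended
#' as the reference oracle for [sampled_query()]; guarded to networks whose
#' full state space does not exceed 2^20 joint configurations.
#'
#' @param fbn A `bn_fit`.
#' @param event Named list `variable = level` (conjunction).
#' @param evidence Named list `variable = level` (conjunction, may be empty).
#' @return A one-row tibble: `prob`, `se` (0),
#'   `n_eff` (completions enumerated), `method`, `seed`.
#' @export
exact_query <- function(fbn, event, evidence = list()) {
  stopifnot(inherits(fbn, "bn_fit"))
  check_assignment(fbn, event, "event")
  check_assignment(fbn, evidence, "evidence")
  nodes <- fbn$dag$nodes
  sizes <- vapply(nodes, function(v)
    if (v %in% names(evidence)) 1 else as.double(fbn$nlev[[v]]), 0)
  if (prod(sizes) > 2^20)
    stop("state space too large for exact enumeration; use sampled_query()")
  grids <- lapply(nodes, function(v) {
    if (v %in% names(evidence)) match(evidence[[v]], fbn$levels[[v]])
    else seq_len(fbn$nlev[[v]])
  })
  names(grids) <- nodes
  S <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  joint <- rep(1, nrow(S))
  for (v in nodes) {
    pa <- attr(fbn$cpts[[v]], "parents")
    cfg <- cfg_index(S[, pa, drop = FALSE], fbn$nlev[pa])
    joint <- joint * fbn$cpts[[v]][cbind(cfg, S[, v])]
  }
  pe <- sum(joint)
  if (pe <= 0) stop("evidence has probability zero: conditional undefined")
  match_event <- rep(TRUE, nrow(S))
  for (v in names(event))
    match_event <- match_event & (S[, v] == match(event[[v]], fbn$levels[[v]]))
  query_result(sum(joint[match_event]) / pe, 0, nrow(S), "exact")
}

# ancestral sampling of n joint configurations; evidence (named codes) is
# clamped when lw = TRUE, accumulating likelihood weights
sample_network <- function(fbn, n, evidence_codes = integer(), lw = FALSE) {
  nodes <- topo_sort(fbn$dag)
  S <- matrix(0L, n, length(fbn$dag$nodes),
              dimnames = list(NULL, fbn$dag$nodes))
  w <- rep(1, n)
  for (v in nodes) {
    pa <- attr(fbn$cpts[[v]], "parents")
    cfg <- cfg_index(S[, pa, drop = FALSE], fbn$nlev[pa])
    probs <- fbn$cpts[[v]][cfg, , drop = FALSE]
    if (lw && v %in% names(evidence_codes)) {
      code <- evidence_codes[[v]]
      S[, v] <- code
      w <- w * probs[, code]
    } else {
      r <- fbn$nlev[[v]]
      cum <- probs
      if (r > 1) for (k in 2:r) cum[, k] <- cum[, k - 1] + probs[, k]
      u <- runif(n)
      code <- rep(r, n)
      if (r > 1) for (k in (r - 1):1) code[u <= cum[, k]] <- k
      S[, v] <- code
    }
  }
  list(S = S, w = w)
}

#' Monte-Carlo conditional-probability query
#'
#' Estimates `P(event | evidence)` on a fitted network by simulation, in the
#' style of cpquery: either likelihood weighting (default; evidence clamped,
#' samples weighted by the evidence CPT entries) or rejection sampling
#' (ancestral samples filtered on the evidence).
#'
#' @inheritParams exact_query
#' @param n_samples Number of simulated particles (default 1e5).
#' @param method `"lw"` (likelihood weighting, default) or `"rejection"`.
#' @param seed Integer seed for reproducibility.
#' @return A one-row tibble: `prob`, `se`, `n_eff`,
#'   `method`, `seed`.
#' @export
sampled_query <- function(fbn, event, evidence = list(), n_samples = 1e5,
                          method = c("lw", "rejection"), seed = NULL) {
  stopifnot(inherits(fbn, "bn_fit"), n_samples >= 1)
  method <- match.arg(method)
  check_assignment(fbn, event, "event")
  check_assignment(fbn, evidence, "evidence")
  ev_codes <- vapply(names(evidence), function(v)
    match(evidence[[v]], fbn$levels[[v]]), 0L)
  with_local_seed(seed, {
    if (method == "lw") {
      sim <- sample_network(fbn, n_samples, ev_codes, lw = TRUE)
      W <- sum(sim$w)
      if (W <= 0) stop("zero total likelihood weight; increase n_samples ",
                       "or check the evidence")
      e <- event_indicator(fbn, sim$S, event)
      p <- sum(sim$w * e) / W
      se <- sqrt(sum((sim$w * (e - p))^2)) / W
      n_eff <- W^2 / sum(sim$w^2)
      query_result(p, se, n_eff, "lw", seed %||% NA)
    } else {
      sim <- sample_network(fbn, n_samples)
      keep <- rep(TRUE, n_samples)
      for (v in names(ev_codes)) keep <- keep & (sim$S[, v] == ev_codes[[v]])
      m <- sum(keep)
      if (m == 0) stop("no samples matched the evidence; increase n_samples")
      e <- event_indicator(fbn, sim$S[keep, , drop = FALSE], event)
      p <- mean(e)
      query_result(p, sqrt(p * (1 - p) / m), m, "rejection", seed %||% NA)
    }
  })
}

event_indicator <- function(fbn, S, event) {
  e <- rep(TRUE, nrow(S))
  for (v in names(event))
    e <- e & (S[, v] == match(event[[v]], fbn$levels[[v]]))
  as.numeric(e)
}

#' Conditional-probability scenario grid for an IR marker
#'
#' Computes `P(outcome = yes | marker quartile = Qk)` for k = 1..4 and,
#' when `extra` is supplied, the same probabilities additionally stratified
#' by each level of the extra variable (e.g. obesity or hypertension) — the
#' scenario analysis used to compare markers on a fitted network.
#'
#' @param fbn A `bn_fit` containing the quartile variable and the outcome.
#' @param index Name of the marker quartile node (e.g. `"tyg_q"`).
#' @param outcome Name of the outcome node (e.g. `"diabetes"`).
#' @param extra Optional name of an additional conditioning node.
#' @param outcome_level Outcome level queried (default `"yes"`).
#' @param n_samples,method,seed Passed to [sampled_query()]; with
#'   `method = "exact"` the enumeration oracle is used instead.
#' @return A tibble with one row per scenario: the conditioning levels plus
#'   the query-result columns.
#' @export
scenario_table <- function(fbn, index, outcome, extra = NULL,
                           outcome_level = "yes", n_samples = 1e5,
                           method = c("lw", "rejection", "exact"),
                           seed = NULL) {
  method <- match.arg(method)
  check_node(fbn$dag, c(index, outcome, extra))
  qs <- fbn$levels[[index]]
  extras <- if (is.null(extra)) NA_character_ else fbn$levels[[extra]]
  grid <- expand.grid(quartile = qs, extra_level = extras,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    ev <- setNames(list(grid$quartile[i]), index)
    if (!is.null(extra)) ev[[extra]] <- grid$extra_level[i]
    res <- if (method == "exact") {
      exact_query(fbn, setNames(list(outcome_level), outcome), ev)
    } else {
      sampled_query(fbn, setNames(list(outcome_level), outcome), ev,
                    n_samples = n_samples, method = method,
                    seed = child_seed(seed, i))
    }
    dplyr::bind_cols(tibble::tibble(index = index, quartile = grid$quartile[i],
                                    extra = extra %||% NA_character_,
                                    extra_level = grid$extra_level[i],
                                    outcome = outcome), res)
  })
  class(rows) <- c("scenario_table", class(rows))
  rows
}
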
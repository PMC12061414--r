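#' Encode a discrete dataset as an integer matrix
#'
#' Converts factor/character columns to 1-based integer codes with a declared
#' level set per column. Declared levels matter for scoring: a level that
#' never occurs still counts toward the parameter penalty.
#'
#' @param data A data frame of categorical columns (factor or character).
#' @param levels Optional named list of declared level vectors; defaults to
#'   the factor levels (or sorted unique values) observed per column.
#' @return A list with `X` (integer matrix, named columns), `levels` (named
#'   list) and `nlev` (named integer vector).
#' @export
encode_discrete <- function(data, levels = NULL) {
  stopifnot(is.data.frame(data))
  nms <- names(data)
  lv <- lapply(nms, function(v) {
    if (!is.null(levels) && v %in% names(levels)) as.character(levels[[v]])
    else if (is.factor(data[[v]])) base::levels(data[[v]])
    else sort(unique(as.character(data[[v]])))
  })
  names(lv) <- nms
  X <- matrix(0L, nrow(data), length(nms), dimnames = list(NULL, nms))
  for (j in seq_along(nms)) {
    codes <- match(as.character(data[[nms[j]]]), lv[[j]])
    if (anyNA(codes))
      stop("column '", nms[j], "' has missing values or values outside declared levels")
    X[, j] <- codes
  }
  list(X = X, levels = lv, nlev = setNames(lengths(lv), nms))
}

# Local score on an encoded dataset. Returns the log-likelihood or AIC
# (loglik minus number of free parameters, maximization convention).
local_score_encoded <- function(enc, node, parents, kind = c("aic", "loglik"),
                                rows = NULL) {
  kind <- match.arg(kind)
  nms <- colnames(enc$X)
  res <- cpp_local_loglik(enc$X, match(node, nms), enc$nlev[[node]],
                          match(parents, nms),
                          as.integer(enc$nlev[parents]),
                          if (is.null(rows)) integer(0) else as.integer(rows))
  ll <- res$loglik
  if (kind == "loglik") return(ll)
  ll - (enc$nlev[[node]] - 1) * res$q
}

#' Decomposable local score of a node given a parent set
#'
#' The log-likelihood term is `sum_jk N_jk log(N_jk / N_j)` over parent
#' configurations `j` and node states `k` (with `0 log 0 = 0`); the AIC score
#' subtracts the number of free parameters `(r - 1) q`, where `r` is the
#' node's declared level count and `q` the number of declared parent
#' configurations. Both are maximization scores.
#'
#' @param data A data frame of categorical columns.
#' @param node Name of the child variable.
#' @param parents Character vector of parent names (may be empty).
#' @param kind `"aic"` (default) or `"loglik"`.
#' @param levels Optional declared level sets (see [encode_discrete()]).
#' @return A numeric scalar.
#' @examples
#' d <- data.frame(a = c("y", "y", "y", "n"))
#' local_score(d, "a", character(), kind = "loglik") # 3 log .75 + log .25
#' @export
local_score <- function(data, node, parents = character(), kind = c("aic", "loglik"),
                        levels = NULL) {
  if (node %in% parents) stop("a node cannot be its own parent")
  enc <- encode_discrete(data[, unique(c(node, parents)), drop = FALSE], levels)
  local_score_encoded(enc, node, parents, match.arg(kind))
}

#' Decomposable network score of a DAG
#'
#' Sum over nodes of [local_score()] with each node's parent set in the DAG.
#'
#' @param dag A `bn_dag` whose nodes are columns of `data`.
#' @param data A data frame of categorical columns.
#' @param kind `"aic"` (default) or `"loglik"`.
#' @param levels Optional declared level sets.
#' @return A numeric scalar.
#' @export
network_score <- function(dag, data, kind = c("aic", "loglik"), levels = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(dag, "bn_dag"))
  if (!all(dag$nodes %in% names(data)))
    stop("dag nodes must all be columns of the data")
  enc <- encode_discrete(data[, dag$nodes, drop = FALSE], levels)
  sum(vapply(dag$nodes,
             function(v) local_score_encoded(enc, v, dag_parents(dag, v), kind),
             0))
}

# A memoizing score cache over (node, parent set) keys for one encoded
# dataset. Hits are exact replays of the original computation.
make_score_cache <- function(enc, kind, rows = NULL) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(node, parents) {
    key <- paste0(node, "|", paste(sort(parents), collapse = ","))
    v <- cache[[key]]
    if (is.null(v)) {
      v <- local_score_encoded(enc, node, parents, kind, rows)
      cache[[key]] <- v
    }
    v
  }
}
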
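# transitive closure (paths of length >= 1) of a logical adjacency matrix
transitive_closure <- function(A) {
  R <- A
  repeat {
    Rn <- R | ((R %*% A) > 0)
    if (identical(Rn, R)) return(R)
    R <- Rn
  }
}

arcs_to_matrix <- function(arcs) {
  if (is.null(arcs) || NROW(arcs) == 0)
    return(matrix(character(), ncol = 2))
  arcs <- as.matrix(arcs)
  storage.mode(arcs) <- "character"
  arcs
}

#' Learn a Bayesian-network structure by greedy hill-climbing
#'
#' Starts from the empty graph (plus any whitelist arcs) and repeatedly
#' applies the best strictly score-improving single-arc move (add, delete,
#' or reverse) until no legal move improves the score. The returned graph is
#' a single-move local optimum. Ties in move selection are broken
#' deterministically: add < delete < reverse, then lexicographic (from, to)
#' node names, so runs are bit-reproducible.
#'
#' @param data A data frame of categorical columns (the nodes).
#' @param kind Score: `"aic"` (default) or `"loglik"`.
#' @param whitelist Optional two-column matrix of arcs that must be present
#'   (never deleted or reversed).
#' @param blacklist Optional two-column matrix of arcs that may never be
#'   added.
#' @param max_iter Maximum number of accepted moves (default 500); if
#'   exhausted the result carries `attr(, "converged") = FALSE`.
#' @param levels Optional declared level sets (see [encode_discrete()]).
#' @return A `bn_dag` with attributes `score` (final network score),
#'   `trace` (score after each accepted move) and `converged`.
#' @export
hill_climb <- function(data, kind = c("aic", "loglik"), whitelist = NULL,
                       blacklist = NULL, max_iter = 500L, levels = NULL) {
  kind <- match.arg(kind)
  enc <- encode_discrete(data, levels)
  hc_engine(enc, kind, arcs_to_matrix(whitelist), arcs_to_matrix(blacklist),
            max_iter)
}

hc_engine <- function(enc, kind, wl, bl, max_iter = 500L, rows = NULL) {
  nodes <- colnames(enc$X)
  p <- length(nodes)
  sc <- make_score_cache(enc, kind, rows)
  nr <- rank(nodes)  # lexicographic rank for tie-breaking

  A <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  WL <- matrix(FALSE, p, p)
  if (nrow(wl)) {
    WL[cbind(match(wl[, 1], nodes), match(wl[, 2], nodes))] <- TRUE
    A <- A | WL
    if (any(diag(transitive_closure(A)))) stop("whitelist arcs form a cycle")
  }
  BL <- matrix(FALSE, p, p)
  if (nrow(bl))
    BL[cbind(match(bl[, 1], nodes), match(bl[, 2], nodes))] <- TRUE

  pa_of <- function(j) nodes[A[, j]]
  cur <- vapply(seq_len(p), function(j) sc(nodes[j], pa_of(j)), 0)
  gain_add <- matrix(NA_real_, p, p)
  gain_del <- matrix(NA_real_, p, p)
  refresh_target <- function(y) {
    pay <- pa_of(y)
    for (x in seq_len(p)) {
      if (x == y) next
      if (A[x, y]) {
        gain_add[x, y] <<- NA_real_
        gain_del[x, y] <<- sc(nodes[y], setdiff(pay, nodes[x])) - cur[y]
      } else {
        gain_add[x, y] <<- sc(nodes[y], c(pay, nodes[x])) - cur[y]
        gain_del[x, y] <<- NA_real_
      }
    }
  }
  for (y in seq_len(p)) refresh_target(y)

  eps <- 1e-9
  trace <- sum(cur)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    R <- transitive_closure(A)
    cand <- list()
    # additions: x -> y legal if absent, not blacklisted, no path y => x
    ok_add <- !A & !BL & !t(R) & !diag(TRUE, p)
    idx <- which(ok_add & gain_add > eps, arr.ind = TRUE)
    if (nrow(idx))
      cand[[length(cand) + 1]] <- cbind(idx, type = 1, gain = gain_add[idx])
    # deletions: existing non-whitelist arcs
    ok_del <- A & !WL
    idx <- which(ok_del & gain_del > eps, arr.ind = TRUE)
    if (nrow(idx))
      cand[[length(cand) + 1]] <- cbind(idx, type = 2, gain = gain_del[idx])
    # reversals: x -> y becomes y -> x
    arcs_idx <- which(A & !WL, arr.ind = TRUE)
    if (nrow(arcs_idx)) {
      rg <- rep(NA_real_, nrow(arcs_idx))
      for (k in seq_len(nrow(arcs_idx))) {
        x <- arcs_idx[k, 1]; y <- arcs_idx[k, 2]
        if (BL[y, x]) next
        g <- gain_del[x, y] + gain_add_rev(sc, nodes, A, cur, x, y)
        if (g <= eps) next
        A2 <- A; A2[x, y] <- FALSE
        R2 <- transitive_closure(A2)
        if (R2[x, y]) next  # another path x => y blocks the reversal
        rg[k] <- g
      }
      keep <- !is.na(rg)
      if (any(keep))
        cand[[length(cand) + 1]] <- cbind(arcs_idx[keep, , drop = FALSE],
                                          type = 3, gain = rg[keep])
    }
    if (!length(cand)) { converged <- TRUE; break }
    cand <- do.call(rbind, cand)
    best <- max(cand[, "gain"])
    top <- cand[cand[, "gain"] >= best - eps, , drop = FALSE]
    ord <- order(top[, "type"], nr[top[, "row"]], nr[top[, "col"]])
    mv <- top[ord[1], ]
    x <- mv[["row"]]; y <- mv[["col"]]
    if (mv[["type"]] == 1) {
      A[x, y] <- TRUE
      cur[y] <- sc(nodes[y], pa_of(y))
      refresh_target(y)
    } else if (mv[["type"]] == 2) {
      A[x, y] <- FALSE
      cur[y] <- sc(nodes[y], pa_of(y))
      refresh_target(y)
    } else {
      A[x, y] <- FALSE
      A[y, x] <- TRUE
      cur[y] <- sc(nodes[y], pa_of(y))
      cur[x] <- sc(nodes[x], pa_of(x))
      refresh_target(y)
      refresh_target(x)
    }
    trace <- c(trace, sum(cur))
  }
  arcs <- which(A, arr.ind = TRUE)
  g <- bn_dag(nodes, cbind(nodes[arcs[, 1]], nodes[arcs[, 2]]))
  attr(g, "score") <- sum(cur)
  attr(g, "trace") <- trace
  attr(g, "converged") <- converged
  g
}

# gain of adding arc y -> x (used by reversal moves); reads the cache
gain_add_rev <- function(sc, nodes, A, cur, x, y) {
  pax <- nodes[A[, x]]
  sc(nodes[x], c(pax, nodes[y])) - cur[x]
}

#' Exhaustive search over all labeled DAGs (<= 5 nodes)
#'
#' Enumerates every labeled DAG on the data's columns, scores each by the
#' decomposable network score, and returns the global optimum. Serves as the
#' independent oracle for [hill_climb()]. Ties are resolved in favor of the
#' lexicographically smallest arc set.
#'
#' @inheritParams hill_climb
#' @return A `bn_dag` with attributes `score` and `n_dags` (number of DAGs
#'   enumerated: 3 for 2 nodes, 25 for 3, 543 for 4, 29281 for 5).
#' @export
exhaustive_search <- function(data, kind = c("aic", "loglik"), levels = NULL) {
  kind <- match.arg(kind)
  enc <- encode_discrete(data, levels)
  nodes <- colnames(enc$X)
  p <- length(nodes)
  if (p > 5) stop("exhaustive search limited to 5 nodes")
  sc <- make_score_cache(enc, kind)
  # score table: node i (1-based) x parent bitmask over nodes
  tab <- matrix(-Inf, p, 2^p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    subsets <- c(list(integer(0)), unlist(lapply(seq_along(others), function(k)
      utils::combn(others, k, simplify = FALSE)), recursive = FALSE))
    for (s in subsets) {
      m <- sum(2^(s - 1))
      tab[i, m + 1] <- sc(nodes[i], nodes[s])
    }
  }
  res <- cpp_exhaustive(tab, p)
  masks <- res$best_masks
  arcsets <- lapply(masks, function(m) mask_to_arcs(m, p, nodes))
  pick <- order(vapply(arcsets, arcset_key, ""))[1]
  g <- bn_dag(nodes, arcsets[[pick]])
  attr(g, "score") <- res$best_score
  attr(g, "n_dags") <- res$n_dags
  g
}

# decode cpp_exhaustive's arc-mask (bit order: for(i) for(j != i))
mask_to_arcs <- function(mask, p, nodes) {
  from <- character(0); to <- character(0)
  b <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    if (bitwAnd(as.integer(mask / 2^b), 1L) == 1L) {
      from <- c(from, nodes[i]); to <- c(to, nodes[j])
    }
    b <- b + 1
  }
  cbind(from, to)
}

arcset_key <- function(arcs) {
  if (!NROW(arcs)) return("")
  paste(sort(paste(arcs[, 1], arcs[, 2], sep = ">")), collapse = "|")
}
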
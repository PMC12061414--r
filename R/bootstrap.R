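#' Bootstrap arc strengths for structure learning
#'
#' Draws `B` nonparametric bootstrap resamples of the rows (size `n`, with
#' replacement), learns a network on each with [hill_climb()], and tabulates
#' for every unordered node pair the adjacency strength (fraction of
#' bootstrap networks containing the pair in either direction) and the
#' direction fraction for `from -> to`. A resample in which some variable
#' collapses to a single observed level is redrawn (the event is counted in
#' the `redraws` attribute). Resampling is unweighted by default; set
#' `use_weights = TRUE` to resample proportionally to survey weights as a
#' sensitivity analysis.
#'
#' @inheritParams hill_climb
#' @param B Number of bootstrap iterations (>= 1).
#' @param seed Integer seed; the same `(data, B, seed)` triple reproduces the
#'   table exactly.
#' @param use_weights If `TRUE`, resample with probability proportional to a
#'   `weight` column in `data` (which is then excluded from the nodes).
#' @return A tibble of class `arc_strength` with columns `from`, `to`
#'   (lexicographic `from < to`), `strength`, `direction`, and attributes
#'   `B`, `seed`, `redraws`.
#' @export
bootstrap_arc_strength <- function(data, B = 200L, seed = 1L,
                                   kind = c("aic", "loglik"),
                                   whitelist = NULL, blacklist = NULL,
                                   max_iter = 500L, levels = NULL,
                                   use_weights = FALSE) {
  kind <- match.arg(kind)
  stopifnot(B >= 1)
  w <- NULL
  if (use_weights) {
    if (!("weight" %in% names(data))) stop("use_weights requires a 'weight' column")
    w <- data$weight
  }
  nodes_df <- data[, setdiff(names(data), c("weight", "stratum", "psu", "id")),
                   drop = FALSE]
  enc <- encode_discrete(nodes_df, levels)
  nodes <- colnames(enc$X)
  p <- length(nodes)
  n <- nrow(enc$X)
  wl <- arcs_to_matrix(whitelist); bl <- arcs_to_matrix(blacklist)

  adj <- matrix(0, p, p, dimnames = list(nodes, nodes))
  redraws <- 0L
  with_local_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE, prob = w)
        degen <- vapply(seq_len(p), function(j) {
          x <- enc$X[idx, j]
          all(x == x[1])
        }, TRUE)
        if (!any(degen)) break
        redraws <- redraws + 1L
      }
      g <- hc_engine(enc, kind, wl, bl, max_iter, rows = idx)
      if (nrow(g$arcs))
        adj[g$arcs] <- adj[g$arcs] + 1
    }
  })
  pairs <- t(utils::combn(sort(nodes), 2))
  out <- tibble::tibble(
    from = pairs[, 1], to = pairs[, 2],
    strength = (adj[pairs] + adj[pairs[, c(2, 1), drop = FALSE]]) / B,
    direction = adj[pairs] / B
  )
  class(out) <- c("arc_strength", class(out))
  attr(out, "B") <- as.integer(B)
  attr(out, "seed") <- seed
  attr(out, "redraws") <- redraws
  out
}

#' Average bootstrap networks into a consensus DAG
#'
#' Keeps every unordered pair whose adjacency strength meets `threshold`,
#' orients it by the majority direction fraction (exact ties go to the
#' lexicographically smaller orientation and are recorded), and, if the
#' oriented graph happens to be cyclic, repeatedly drops the kept arc with
#' the smallest adjacency strength until it is acyclic.
#'
#' @param strengths An `arc_strength` table from [bootstrap_arc_strength()].
#' @param threshold Minimum adjacency strength in `(0, 1]`; default 0.75.
#' @param nodes Optional full node set for the returned DAG; defaults to all
#'   nodes appearing in `strengths`.
#' @return A `bn_dag`; attributes `dropped` (arcs removed during cycle
#'   repair) and `direction_ties` record the repairs.
#' @export
model_average <- function(strengths, threshold = 0.75, nodes = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(nodes)) nodes <- sort(unique(c(strengths$from, strengths$to)))
  kept <- strengths[strengths$strength >= threshold, , drop = FALSE]
  ties <- character(0)
  if (nrow(kept)) {
    fwd <- kept$direction > kept$strength / 2
    tie <- abs(kept$direction - kept$strength / 2) < 1e-12
    if (any(tie)) {
      ties <- paste(kept$from[tie], kept$to[tie], sep = "->")
      fwd[tie] <- TRUE  # from < to lexicographically by construction
    }
    arcs <- cbind(ifelse(fwd, kept$from, kept$to),
                  ifelse(fwd, kept$to, kept$from))
    ord <- order(-kept$strength)
    arcs <- arcs[ord, , drop = FALSE]
    str_ord <- kept$strength[ord]
  } else {
    arcs <- matrix(character(), ncol = 2)
    str_ord <- numeric(0)
  }
  dropped <- character(0)
  repeat {
    g <- try(bn_dag(nodes, arcs), silent = TRUE)
    if (!inherits(g, "try-error")) break
    k <- nrow(arcs)  # weakest kept arc is last (sorted by strength)
    dropped <- c(dropped, paste(arcs[k, 1], arcs[k, 2], sep = "->"))
    arcs <- arcs[-k, , drop = FALSE]
    str_ord <- str_ord[-k]
  }
  attr(g, "dropped") <- dropped
  attr(g, "direction_ties") <- ties
  attr(g, "threshold") <- threshold
  g
}

#' @export
tidy.arc_strength <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("from", "to", "strength", "direction")])
}

#' @export
glance.arc_strength <- function(x, ...) {
  tibble::tibble(B = attr(x, "B"), n_pairs = nrow(x),
                 n_strong = sum(x$strength >= 0.75),
                 redraws = attr(x, "redraws"))
}
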
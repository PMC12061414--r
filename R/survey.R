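#' Survey-weighted cross-tabulation
#'
#' Tabulates a categorical variable (optionally by an outcome) with raw
#' counts and weighted proportions: each cell proportion is the weighted cell
#' total divided by the weighted total of its margin (the `by` group, or the
#' whole cohort when `by` is `NULL`).
#'
#' @param cohort A cohort tibble with a `weight` column.
#' @param var Name of the categorical variable (string).
#' @param by Optional name of the grouping outcome (string).
#' @param weight Name of the weight column (default `"weight"`).
#' @return A tibble with `var` level, optional `by` level, `n` (raw count),
#'   `wsum` (weighted total), `prop` (weighted proportion within margin).
#' @export
weighted_proportions <- function(cohort, var, by = NULL, weight = "weight") {
  stopifnot(var %in% names(cohort), weight %in% names(cohort))
  d <- cohort[, c(var, by, weight)]
  names(d) <- c("var", if (!is.null(by)) "by", "w")
  d <- d[stats::complete.cases(d), , drop = FALSE]
  grp <- if (is.null(by)) "var" else c("by", "var")
  out <- d %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::summarise(n = dplyr::n(), wsum = sum(.data$w), .groups = "drop")
  if (is.null(by)) {
    tot <- sum(out$wsum)
    if (tot <= 0) stop("zero total weight in margin")
    out$prop <- out$wsum / tot
  } else {
    out <- out %>%
      dplyr::group_by(.data$by) %>%
      dplyr::mutate(prop = .data$wsum / sum(.data$wsum)) %>%
      dplyr::ungroup()
    if (any(!is.finite(out$prop))) stop("zero total weight in a margin")
  }
  names(out)[seq_along(grp)] <- c(if (!is.null(by)) by, var)
  out
}

#' Rao-Scott chi-square test for complex survey data
#'
#' Pearson chi-square test of independence on the survey-weighted
#' proportions, with the second-order Rao-Scott correction: the design-based
#' covariance of the cell proportions is estimated by stratified-cluster
#' linearization, generalized design effects are the eigenvalues of the
#' multinomial-inverse times design covariance on the space of independence
#' contrasts, and the corrected statistic is referred to an F distribution
#' with Satterthwaite degrees of freedom (Thomas-Rao F).
#'
#' With equal weights and every record its own PSU in a single stratum, the
#' uncorrected weighted statistic equals the classical Pearson chi-square.
#'
#' @param cohort A cohort tibble.
#' @param var,outcome Names of the two categorical variables (strings).
#' @param weight,stratum,psu Names of the design columns. Missing `stratum` /
#'   `psu` columns default to one stratum and per-record PSUs.
#' @param singleton How to handle a stratum with a single PSU: `"error"`
#'   (default) or `"center"` (contribution centered at the grand mean of PSU
#'   totals, logged in the descriptor).
#' @return An object of class `rao_scott` with elements `statistic` (F),
#'   `ndf`, `ddf`, `p_value`, `x2` (uncorrected weighted Pearson),
#'   `delta_bar`, `a2` (eigenvalue dispersion), `eigenvalues` and
#'   `correction` (descriptor string).
#' @export
rao_scott_chi2 <- function(cohort, var, outcome, weight = "weight",
                           stratum = "stratum", psu = "psu",
                           singleton = c("error", "center")) {
  singleton <- match.arg(singleton)
  stopifnot(var %in% names(cohort), outcome %in% names(cohort))
  w <- if (weight %in% names(cohort)) cohort[[weight]] else rep(1, nrow(cohort))
  st <- if (stratum %in% names(cohort)) as.character(cohort[[stratum]])
        else rep("s1", nrow(cohort))
  cl <- if (psu %in% names(cohort)) as.character(cohort[[psu]])
        else as.character(seq_len(nrow(cohort)))
  x <- droplevels(factor(cohort[[var]]))
  y <- droplevels(factor(cohort[[outcome]]))
  ok <- !is.na(x) & !is.na(y) & !is.na(w)
  x <- x[ok]; y <- y[ok]; w <- w[ok]; st <- st[ok]; cl <- cl[ok]
  n <- length(x)
  R <- nlevels(x); C <- nlevels(y)
  if (R < 2 || C < 2) stop("both variables need at least two observed levels")

  cell <- (as.integer(y) - 1L) * R + as.integer(x)  # RC cells, column-major
  W <- sum(w)
  phat <- as.vector(tapply(w, factor(cell, levels = seq_len(R * C)), sum))
  phat[is.na(phat)] <- 0
  phat <- phat / W
  P <- matrix(phat, R, C)
  prow <- rowSums(P); pcol <- colSums(P)
  E <- outer(prow, pcol)
  x2 <- n * sum(ifelse(E > 0, (P - E)^2 / E, 0))

  # linearized influence of each record on the cell-proportion vector
  d <- (R - 1) * (C - 1)
  Y <- matrix(0, n, R * C)
  Y[cbind(seq_len(n), cell)] <- 1
  Z <- (w / W) * sweep(Y, 2, phat)  # n x RC

  # cluster totals within strata
  key <- paste(st, cl, sep = "\r")
  ztot <- rowsum(Z, key)
  st_of <- sub("\r.*", "", rownames(ztot))
  Vhat <- matrix(0, R * C, R * C)
  grand_mean <- colMeans(ztot)
  for (h in unique(st_of)) {
    rows <- which(st_of == h)
    nh <- length(rows)
    if (nh < 2) {
      if (singleton == "error")
        stop("stratum '", h, "' has a single PSU; set singleton = 'center'")
      dev <- ztot[rows, , drop = FALSE] -
        matrix(grand_mean, 1, R * C)[rep(1, nh), , drop = FALSE]
      Vhat <- Vhat + crossprod(dev)
      next
    }
    dev <- sweep(ztot[rows, , drop = FALSE], 2, colMeans(ztot[rows, , drop = FALSE]))
    Vhat <- Vhat + nh / (nh - 1) * crossprod(dev)
  }
  V0 <- (diag(phat) - tcrossprod(phat)) / n

  # Jacobian of the independence contrasts h_ij = p_ij - p_i+ p_+j,
  # i = 1..R-1, j = 1..C-1
  H <- matrix(0, d, R * C)
  rowidx <- function(i, j) (j - 1) * R + i
  k <- 0
  for (j in seq_len(C - 1)) for (i in seq_len(R - 1)) {
    k <- k + 1
    for (l in seq_len(C)) for (m in seq_len(R)) {
      val <- (m == i) * (l == j) - (m == i) * pcol[j] - (l == j) * prow[i]
      H[k, rowidx(m, l)] <- val
    }
  }
  Dmat <- MASS::ginv(H %*% V0 %*% t(H)) %*% (H %*% Vhat %*% t(H))
  lambda <- Re(eigen(Dmat, only.values = TRUE)$values)
  lambda <- pmax(lambda, 0)
  delta_bar <- mean(lambda)
  a2 <- if (delta_bar > 0) sum((lambda - delta_bar)^2) / (d * delta_bar^2) else 0
  nu <- d / (1 + a2)
  Fstat <- if (sum(lambda) > 0) x2 / sum(lambda) else 0
  df_design <- length(unique(key)) - length(unique(st_of))
  ddf <- max(nu * df_design, 1e-8)
  p_value <- stats::pf(Fstat, nu, ddf, lower.tail = FALSE)

  structure(list(
    statistic = Fstat, ndf = nu, ddf = ddf, p_value = p_value,
    x2 = x2, delta_bar = delta_bar, a2 = a2, eigenvalues = lambda,
    correction = paste0("second-order Rao-Scott (Thomas-Rao F); ",
                        "first-order deff ", signif(delta_bar, 4),
                        "; eigenvalue CV^2 ", signif(a2, 4),
                        if (singleton == "center") "; singleton PSUs centered at grand mean" else ""),
    var = var, outcome = outcome, n = n
  ), class = "rao_scott")
}

#' @export
print.rao_scott <- function(x, ...) {
  cat("Rao-Scott chi-square:", x$var, "x", x$outcome, "\n")
  cat(sprintf("  F = %.4f on (%.2f, %.2f) df, p = %.4g\n",
              x$statistic, x$ndf, x$ddf, x$p_value))
  cat("  uncorrected weighted X2 =", format(x$x2), "\n")
  invisible(x)
}

#' @export
tidy.rao_scott <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, ndf = x$ndf, ddf = x$ddf,
                 p_value = x$p_value, x2 = x$x2, delta_bar = x$delta_bar,
                 correction = x$correction)
}

#' Survey-weighted mutual information
#'
#' Plug-in mutual information (natural log) over the weighted joint
#' distribution of two categorical variables,
#' `MI = sum p(x, y) ln[p(x, y) / (p(x) p(y))]` with zero cells contributing
#' zero, plus the uncertainty coefficient `100 MI / H(outcome)` as a
#' percentage of the outcome's entropy.
#'
#' @inheritParams rao_scott_chi2
#' @param base Logarithm base (default `exp(1)`; affects `mi` only, the
#'   normalized percentage is base-invariant).
#' @return A one-row tibble: `mi_nats`, `normalized_pct`, `h_outcome`.
#' @export
weighted_mutual_information <- function(cohort, var, outcome,
                                        weight = "weight", base = exp(1)) {
  w <- if (weight %in% names(cohort)) cohort[[weight]] else rep(1, nrow(cohort))
  x <- factor(cohort[[var]]); y <- factor(cohort[[outcome]])
  ok <- !is.na(x) & !is.na(y) & !is.na(w)
  x <- droplevels(x[ok]); y <- droplevels(y[ok]); w <- w[ok]
  if (nlevels(y) < 2) stop("outcome has a single observed level: entropy undefined")
  J <- as.matrix(xtabs(w ~ x + y)) / sum(w)
  px <- rowSums(J); py <- colSums(J)
  lg <- function(z) log(z, base = base)
  mi <- sum(ifelse(J > 0, J * lg(J / outer(px, py)), 0))
  h <- -sum(ifelse(py > 0, py * lg(py), 0))
  tibble::tibble(mi_nats = mi * log(base), normalized_pct = 100 * mi / h,
                 h_outcome = h)
}

#' Survey-weighted ROC curve and AUC
#'
#' AUC as the weighted Mann-Whitney statistic with ties counted one half;
#' the curve gives the weighted empirical (FPR, TPR) at every distinct
#' score threshold (classification rule: score >= threshold is positive).
#'
#' @param scores Numeric marker values (higher = more positive).
#' @param labels Binary outcome; `positive` names the positive level.
#' @param weights Optional survey weights (default equal).
#' @param positive Positive label (default `"yes"`; for 0/1 labels use `1`).
#' @return An object of class `ir_roc`: `auc` plus a `curve` tibble
#'   (`threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels, weights = NULL, positive = "yes") {
  if (is.null(weights)) weights <- rep(1, length(scores))
  ok <- !is.na(scores) & !is.na(labels) & !is.na(weights)
  scores <- scores[ok]; labels <- labels[ok]; weights <- weights[ok]
  pos <- as.character(labels) == as.character(positive)
  wpos_tot <- sum(weights[pos]); wneg_tot <- sum(weights[!pos])
  if (wpos_tot <= 0 || wneg_tot <= 0)
    stop("both classes must be present with positive total weight")
  ord <- order(scores)
  s <- scores[ord]; p <- pos[ord]; w <- weights[ord]
  grp <- cumsum(c(TRUE, diff(s) > 0))
  wpos_g <- rowsum(w * p, grp)[, 1]
  wneg_g <- rowsum(w * (!p), grp)[, 1]
  cum_neg_below <- c(0, cumsum(wneg_g))[seq_along(wneg_g)]
  auc <- sum(wpos_g * (cum_neg_below + 0.5 * wneg_g)) / (wpos_tot * wneg_tot)
  thr <- rev(s[!duplicated(grp)])
  tpr <- rev(1 - c(0, cumsum(wpos_g))[seq_along(wpos_g)] / wpos_tot)
  fpr <- rev(1 - cum_neg_below / wneg_tot)
  curve <- tibble::tibble(threshold = unname(c(Inf, thr)),
                          fpr = unname(c(0, fpr)), tpr = unname(c(0, tpr)))
  structure(list(auc = auc, curve = curve), class = "ir_roc")
}

#' @export
print.ir_roc <- function(x, ...) {
  cat("<ir_roc> AUC =", format(x$auc, digits = 4), "with",
      nrow(x$curve), "curve points\n")
  invisible(x)
}

#' @export
tidy.ir_roc <- function(x, ...) x$curve

#' @export
glance.ir_roc <- function(x, ...) tibble::tibble(auc = x$auc)
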
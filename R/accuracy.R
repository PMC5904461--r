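## Threshold-dependent and threshold-independent prediction-accuracy
## measures for presence/absence models, classical and spatially
## corrected.
##
## The spatial variants judge each prediction against the "neighbourhood
## envelope" of the actual value: the interval spanned by the 0/1 actual
## a_i and its mean a*_i over the 3x3 queen neighbourhood.  The effective
## actual for cell i is the value inside [min(a_i, a*_i), max(a_i, a*_i)]
## closest to the prediction.  A false presence adjacent to observed
## presences is then partially excused (its envelope reaches up to a*_i),
## while one far away is not (envelope collapses to {0}); predictions
## identical to the actuals are always scored perfectly, because a_i
## itself is an endpoint of the envelope.  With spatial = FALSE every
## measure reduces exactly to its classical (textbook) counterpart.

#' Neighbourhood-smoothed actual values
#'
#' Replaces each 0/1 actual by the unweighted mean of the actuals over the
#' 3x3 queen neighbourhood of its cell (the cell itself included), using
#' only observed cells.  The result lies in [0, 1] and carries the spatial
#' context of each observation.
#'
#' @param actuals 0/1 vector of observed presence/absence.
#' @param coord two-column matrix of integer cell coordinates (x, y).
#' @param window odd neighbourhood side length (default 3).
#' @return numeric vector in [0, 1].
#' @export
smooth_actuals <- function(actuals, coord, window = 3) {
  if (!all(actuals %in% c(0, 1)))
    stop("'actuals' must be coded 0/1", call. = FALSE)
  coord <- check_coords(coord, length(actuals))
  if (window %% 2 != 1 || window < 1)
    stop("'window' must be odd and positive", call. = FALSE)
  r <- (window - 1L) %/% 2L
  cols <- coord[, 1L] - min(coord[, 1L]) + 1L
  rows <- coord[, 2L] - min(coord[, 2L]) + 1L
  nr <- max(rows) + 2L * r; nc <- max(cols) + 2L * r
  val <- matrix(0, nr, nc); obs <- matrix(0, nr, nc)
  idx <- cbind(rows + r, cols + r)
  val[idx] <- actuals; obs[idx] <- 1
  ssum <- matrix(0, nr, nc); scnt <- matrix(0, nr, nc)
  for (dy in -r:r) for (dx in -r:r) {
    ssum <- ssum + shift_mat(val, dy, dx)
    scnt <- scnt + shift_mat(obs, dy, dx)
  }
  ssum[idx] / scnt[idx]
}

shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 - dy):min(nr, nr - dy)
  cs <- max(1, 1 - dx):min(nc, nc - dx)
  out[rs, cs] <- m[rs + dy, cs + dx]
  out
}

# linear agreement weights for the 4-class ordinal table
kappa_weightmat <- function() {
  i <- matrix(1:4, 4, 4); j <- t(i)
  1 - abs(i - j) / 3
}

# chance-corrected weighted agreement on a c x c contingency table
weighted_kappa <- function(counts, w) {
  n <- sum(counts)
  po <- sum(w * counts) / n
  pe <- sum(w * tcrossprod(rowSums(counts), colSums(counts))) / n^2
  (po - pe) / (1 - pe)
}

# classes 1..4 by the cut points {t/2, t, (1+t)/2}, half-open upward
cut4 <- function(p, t) {
  findInterval(p, c(t / 2, t, (1 + t) / 2)) + 1L
}

# effective actual: the point of the neighbourhood envelope
# [min(a, a*), max(a, a*)] closest to the prediction
envelope_actual <- function(actuals, astar, predictions) {
  pmin(pmax(predictions, pmin(actuals, astar)), pmax(actuals, astar))
}

#' Threshold-dependent accuracy measures (kappa, sensitivity, specificity)
#'
#' With \code{spatial = FALSE}: the classical 2x2 confusion matrix at the
#' chosen threshold, Cohen's kappa, sensitivity and specificity.  With
#' \code{spatial = TRUE}: predictions and the effective actuals (the point
#' of the neighbourhood envelope \eqn{[\min(a, a^*), \max(a, a^*)]}
#' closest to the prediction, \eqn{a^*} from [smooth_actuals()]) are
#' mapped into four ordinal classes by the cut points
#' \eqn{\{t/2,\; t,\; (1+t)/2\}}, tabulated in a 4x4 table and scored by a
#' weighted Cohen's kappa with linear agreement weights
#' \eqn{w_{ij} = 1 - |i-j|/3}, crediting near misses; sensitivity and
#' specificity come from collapsing classes \{3, 4\} to "positive".
#' Predictions identical to the actuals always give kappa 1; because
#' chance agreement with a neighbour also earns partial credit, the
#' chance-level value of the spatial kappa is slightly above 0.
#'
#' @param actuals 0/1 vector (or pass \code{data}).
#' @param predictions probability vector in [0, 1].
#' @param coord integer lattice coordinates.
#' @param data optional two-column data frame (actuals, predictions), as an
#'   alternative to the two vectors.
#' @param threshold classification threshold in (0, 1).
#' @param spatial logical switch between spatially corrected and classical
#'   measures.
#' @param window neighbourhood size for the smoothing.
#' @return list with the confusion matrix \code{cm}, \code{kappa},
#'   \code{sensitivity}, \code{specificity}, and the settings.
#' @export
th_dep <- function(actuals = NULL, predictions = NULL, coord, data = NULL,
                   threshold = 0.5, spatial = TRUE, window = 3) {
  if (!is.null(data)) { actuals <- data[[1L]]; predictions <- data[[2L]] }
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)", call. = FALSE)
  if (any(predictions < 0 | predictions > 1))
    stop("'predictions' must be probabilities in [0, 1]", call. = FALSE)
  if (!all(actuals %in% c(0, 1)))
    stop("'actuals' must be coded 0/1", call. = FALSE)
  if (spatial) {
    astar <- smooth_actuals(actuals, coord, window)
    a <- envelope_actual(actuals, astar, predictions)
    ca <- cut4(a, threshold); cp <- cut4(predictions, threshold)
    cm <- matrix(0L, 4, 4,
                 dimnames = list(actual = 1:4, predicted = 1:4))
    for (i in seq_along(ca)) cm[ca[i], cp[i]] <- cm[ca[i], cp[i]] + 1L
    w <- kappa_weightmat()
    kap <- weighted_kappa(cm, w)
    tp <- sum(cm[3:4, 3:4]); fn <- sum(cm[3:4, 1:2])
    tn <- sum(cm[1:2, 1:2]); fp <- sum(cm[1:2, 3:4])
  } else {
    pa <- as.integer(predictions >= threshold)
    cm <- matrix(c(sum(actuals == 0 & pa == 0), sum(actuals == 0 & pa == 1),
                   sum(actuals == 1 & pa == 0), sum(actuals == 1 & pa == 1)),
                 2, 2, byrow = TRUE,
                 dimnames = list(actual = 0:1, predicted = 0:1))
    kap <- weighted_kappa(cm, diag(2))
    tp <- cm[2, 2]; fn <- cm[2, 1]; tn <- cm[1, 1]; fp <- cm[1, 2]
  }
  list(cm = cm, kappa = kap,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
       threshold = threshold, spatial = spatial,
       weightmat = if (spatial) kappa_weightmat())
}

#' Threshold-independent accuracy measures (ROC, AUC, TSS)
#'
#' Sweeps the classification threshold over the midpoints of the sorted
#' unique predictions (plus 0 and 1) and accumulates sensitivity and
#' specificity at each.  With \code{spatial = FALSE} this is the classical
#' empirical ROC with trapezoidal AUC and the maximum true skill statistic
#' TSS = max(sensitivity + specificity - 1).  With \code{spatial = TRUE} a
#' soft confusion matrix is used, built from the neighbourhood envelope of
#' the actuals: a predicted-positive cell contributes
#' \eqn{\max(a, a^*)} to the true positives and the remainder to the false
#' positives, a predicted-negative cell contributes
#' \eqn{1 - \min(a, a^*)} to the true negatives and the remainder to the
#' false negatives.  Predictions displaced by one cell from an observed
#' presence patch therefore still earn credit, and the spatial
#' sensitivity and specificity are never below their classical values.
#'
#' @inheritParams th_dep
#' @param plot_roc draw the ROC curve.
#' @return list of class \code{"roc_spatial"} with \code{thresholds},
#'   \code{sensitivity}, \code{specificity}, \code{AUC}, \code{TSS}.
#' @export
th_indep <- function(actuals = NULL, predictions = NULL, coord, data = NULL,
                     spatial = TRUE, window = 3, plot_roc = FALSE) {
  if (!is.null(data)) { actuals <- data[[1L]]; predictions <- data[[2L]] }
  if (any(predictions < 0 | predictions > 1))
    stop("'predictions' must be probabilities in [0, 1]", call. = FALSE)
  if (!all(actuals %in% c(0, 1)))
    stop("'actuals' must be coded 0/1", call. = FALSE)
  if (length(unique(actuals)) < 2L)
    stop("AUC undefined: actuals are all one class", call. = FALSE)
  if (spatial) {
    astar <- smooth_actuals(actuals, coord, window)
    a_hi <- pmax(actuals, astar)   # envelope top: credit for positives
    a_lo <- pmin(actuals, astar)   # envelope bottom: excuse for negatives
  } else {
    a_hi <- a_lo <- actuals
  }
  u <- sort(unique(predictions))
  th <- c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1)
  sens <- numeric(length(th)); spec <- numeric(length(th))
  for (i in seq_along(th)) {
    pos <- predictions >= th[i]
    tp <- sum(a_hi[pos]); fp <- sum(1 - a_hi[pos])
    fn <- sum(a_lo[!pos]); tn <- sum(1 - a_lo[!pos])
    sens[i] <- tp / (tp + fn)
    spec[i] <- tn / (tn + fp)
  }
  # order points from (0,0) to (1,1) in ROC space, endpoints included
  x <- c(0, rev(1 - spec), 1)
  y <- c(0, rev(sens), 1)
  auc <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  tss <- max(sens + spec - 1)
  out <- structure(list(thresholds = th, sensitivity = sens,
                        specificity = spec, AUC = auc, TSS = tss,
                        spatial = spatial),
                   class = "roc_spatial")
  if (plot_roc) plot(out)
  out
}

#' @export
print.roc_spatial <- function(x, ...) {
  cat(if (x$spatial) "Spatially corrected" else "Classical",
      "ROC summary\n")
  cat("AUC:", round(x$AUC, 4), "  max TSS:", round(x$TSS, 4), "\n")
  invisible(x)
}

#' @export
plot.roc_spatial <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = if (x$spatial) "spatial ROC" else "ROC", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
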
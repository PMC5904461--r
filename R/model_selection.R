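## Backward stepwise selection and all-subsets multimodel inference for
## spatial GEE and wavelet models, plus relative variable importance
## across wavelet scales.  GEE models are compared by QIC, wavelet models
## by AIC (or AICc on request).

model_criterion <- function(fit, AICc = FALSE) {
  if (inherits(fit, "spat_gee")) fit$ic$qic
  else if (AICc) fit$ic$aicc else fit$ic$aic
}

criterion_name <- function(object, AICc = FALSE) {
  if (inherits(object, "spat_gee")) "QIC" else if (AICc) "AICc" else "AIC"
}

# refit a spatial model on a new formula, reusing the stored settings
refit_model <- function(object, formula, data) {
  a <- object$refit_args
  if (inherits(object, "spat_gee")) {
    gee(formula, family = a$family, data = data, coord = a$coord,
        corstr = a$corstr, cluster = a$cluster, scale_fix = a$scale_fix,
        fixed_a = a$fixed_a, moran = a$moran, control = a$control,
        compute_ac = FALSE)
  } else if (object$kind == "wrm") {
    wrm(formula, family = a$family, data = data, coord = a$coord,
        level = a$level, wavelet = a$wavelet, wtrafo = a$wtrafo,
        pad = a$pad, scale_fix = a$scale_fix, control = a$control,
        compute_ac = FALSE)
  } else {
    scale_wmrr(formula, family = a$family, data = data, coord = a$coord,
               scale = a$scale, detail = a$detail, wavelet = a$wavelet,
               wtrafo = a$wtrafo, pad = a$pad, scale_fix = a$scale_fix,
               control = a$control, compute_ac = FALSE)
  }
}

# A term blocks removal of any main effect whose symbol occurs in it
# (e.g. race stays while I(race^2) or race:smoke remains); a compound term
# is itself blocked by any strictly larger compound over a superset of its
# variables.
removable_terms <- function(labels) {
  vars <- lapply(labels, function(l) all.vars(stats::as.formula(paste("~", l))))
  is_bare <- vapply(seq_along(labels), function(i)
    length(vars[[i]]) == 1L && labels[[i]] == vars[[i]], logical(1))
  keep <- logical(length(labels))
  for (i in seq_along(labels)) {
    blocked <- FALSE
    for (j in seq_along(labels)) {
      if (i == j) next
      if (is_bare[i]) {
        if (vars[[i]] %in% vars[[j]]) { blocked <- TRUE; break }
      } else if (all(vars[[i]] %in% vars[[j]]) &&
                 length(vars[[j]]) > length(vars[[i]])) {
        blocked <- TRUE; break
      }
    }
    keep[i] <- !blocked
  }
  labels[keep]
}

drop_term_formula <- function(formula, term) {
  tt <- stats::terms(formula)
  labels <- setdiff(attr(tt, "term.labels"), term)
  resp <- deparse(formula[[2L]])
  stats::reformulate(if (length(labels)) labels else "1",
                     response = resp,
                     intercept = attr(tt, "intercept") == 1L)
}

#' Backward stepwise model selection for spatial regressions
#'
#' Starting from a fitted full model (GEE or wavelet-revised), repeatedly
#' evaluates all single-term deletions that respect the hierarchy of
#' variables -- a main effect is never removed while any interaction or
#' polynomial containing it remains -- and removes the deletion with the
#' lowest criterion (QIC for GEE, AIC/AICc for wavelet models), stopping
#' when no deletion improves the criterion.  Only backward selection is
#' supported.
#'
#' @param object a \code{"spat_gee"} or \code{"spat_wrm"} fit.
#' @param data the data frame the model was fitted on.
#' @param AICc use AICc instead of AIC (wavelet models only).
#' @param trace print progress.
#' @return list with \code{model} (the selected formula) and \code{steps}
#'   (a data frame logging each deletion).
#' @export
step_spatial <- function(object, data, AICc = FALSE, trace = FALSE) {
  formula <- object$formula
  crit_cur <- model_criterion(object, AICc)
  cname <- criterion_name(object, AICc)
  log <- data.frame(step = 0L, deleted = "<full>", criterion = crit_cur,
                    stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    labels <- attr(stats::terms(formula), "term.labels")
    cand <- removable_terms(labels)
    if (length(cand) == 0L) break
    crits <- vapply(cand, function(tm) {
      f2 <- drop_term_formula(formula, tm)
      fit2 <- tryCatch(refit_model(object, f2, data),
                       error = function(e) NULL,
                       warning = function(w) suppressWarnings(
                         refit_model(object, f2, data)))
      if (is.null(fit2)) Inf else model_criterion(fit2, AICc)
    }, numeric(1))
    best <- which.min(crits)
    if (trace)
      cat(sprintf("step %d: best deletion '%s' %s %.3f (current %.3f)\n",
                  step_i + 1L, cand[best], cname, crits[best], crit_cur))
    if (!is.finite(crits[best]) || crits[best] >= crit_cur) break
    step_i <- step_i + 1L
    formula <- drop_term_formula(formula, cand[best])
    crit_cur <- crits[best]
    log <- rbind(log, data.frame(step = step_i, deleted = cand[best],
                                 criterion = crit_cur))
    if (length(attr(stats::terms(formula), "term.labels")) == 0L) break
  }
  list(model = formula, steps = log, criterion = cname)
}

subset_formulas <- function(formula) {
  tt <- stats::terms(formula)
  labels <- attr(tt, "term.labels")
  p <- length(labels)
  if (p > 12L)
    stop("more than 12 candidate terms; all-subsets enumeration refused",
         call. = FALSE)
  resp <- deparse(formula[[2L]])
  sets <- lapply(seq_len(2L^p) - 1L, function(mask)
    labels[bitwAnd(mask, 2L^(seq_len(p) - 1L)) > 0L])
  lapply(sets, function(s)
    stats::reformulate(if (length(s)) s else "1", response = resp))
}

mmi_core <- function(object, data, AICc = FALSE) {
  forms <- subset_formulas(object$formula)
  cname <- criterion_name(object, AICc)
  rows <- lapply(forms, function(f) {
    fit <- tryCatch(suppressWarnings(refit_model(object, f, data)),
                    error = function(e) NULL)
    labels <- attr(stats::terms(f), "term.labels")
    data.frame(model = if (length(labels))
                 paste(labels, collapse = " + ") else "1",
               k = length(labels) + 1L,
               criterion = if (is.null(fit)) NA_real_
                           else model_criterion(fit, AICc),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$terms <- lapply(forms, function(f)
    attr(stats::terms(f), "term.labels"))
  if (anyNA(tab$criterion))
    warning(sum(is.na(tab$criterion)),
            " subset fit(s) failed; excluded from the weights")
  ok <- !is.na(tab$criterion)
  tab$delta <- tab$criterion - min(tab$criterion, na.rm = TRUE)
  w <- exp(-tab$delta / 2)
  w[!ok] <- NA
  tab$weight <- w / sum(w, na.rm = TRUE)
  # sort by criterion; ties favour fewer terms, then lexical order
  ord <- order(tab$criterion, tab$k, tab$model, na.last = TRUE)
  tab <- tab[ord, c("model", "terms", "k", "criterion", "delta", "weight")]
  rownames(tab) <- NULL
  attr(tab, "criterion_name") <- cname
  class(tab) <- c("mmi_table", "data.frame")
  tab
}

#' @export
print.mmi_table <- function(x, digits = 3, ...) {
  cat("Multimodel inference table (criterion:",
      attr(x, "criterion_name"), ")\n")
  y <- x[, c("model", "k", "criterion", "delta", "weight")]
  y$criterion <- round(y$criterion, digits)
  y$delta <- round(y$delta, digits)
  y$weight <- round(y$weight, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Multimodel inference for spatial GEE fits
#'
#' Fits every subset of the model terms (intercept always included),
#' scores each by QIC and returns the table of deltas and Akaike weights.
#'
#' @inheritParams step_spatial
#' @return a \code{"mmi_table"} data frame sorted by criterion.
#' @export
mmi_gee <- function(object, data) {
  if (!inherits(object, "spat_gee")) stop("'object' must be a spat_gee fit")
  mmi_core(object, data)
}

#' Multimodel inference for wavelet multiresolution regressions
#'
#' All-subsets inference at one wavelet scale: every term subset is
#' refitted by [scale_wmrr()] at the given \code{scale} and \code{detail}
#' setting and scored by AIC (or AICc).
#'
#' @inheritParams step_spatial
#' @param scale wavelet scale at which the subsets are refitted.
#' @param detail regress on detail (\code{TRUE}) or smooth components.
#' @param trace print the resulting table.
#' @return a \code{"mmi_table"} data frame.
#' @export
mmi_wmrr <- function(object, data, scale = 1, detail = TRUE, AICc = FALSE,
                     trace = FALSE) {
  if (!inherits(object, "spat_wrm")) stop("'object' must be a spat_wrm fit")
  object$kind <- "wmrr"
  object$refit_args$scale <- scale
  object$refit_args$detail <- detail
  out <- mmi_core(object, data, AICc)
  if (trace) print(out)
  out
}

#' Relative variable importance across wavelet scales
#'
#' For each scale \code{1..maxlevel}, runs all-subsets multimodel
#' inference on scale-specific multiresolution regressions and sums the
#' Akaike weights of the models containing each variable.  The resulting
#' matrix (variables x scales, values in [0, 1]) shows at which spatial
#' resolution each predictor carries support.
#'
#' @inheritParams scale_wmrr
#' @param maxlevel deepest scale examined.
#' @param AICc use AICc instead of AIC.
#' @param trace print the per-scale model tables.
#' @return list of class \code{"rvi_result"}: \code{rvi} matrix and the
#'   per-scale \code{tables}.
#' @export
rvi <- function(formula, family = "gaussian", data, coord, maxlevel = 3,
                detail = TRUE, wavelet = "haar", wtrafo = "dwt",
                pad = list(padform = "mean", padzone = 1), AICc = FALSE,
                trace = FALSE) {
  if (maxlevel < 1) stop("'maxlevel' must be >= 1", call. = FALSE)
  labels <- attr(stats::terms(formula), "term.labels")
  rvi_mat <- matrix(NA_real_, length(labels), maxlevel,
                    dimnames = list(labels, paste0("scale", seq_len(maxlevel))))
  tables <- vector("list", maxlevel)
  for (s in seq_len(maxlevel)) {
    full <- scale_wmrr(formula, family, data, coord, scale = s,
                       detail = detail, wavelet = wavelet, wtrafo = wtrafo,
                       pad = pad, compute_ac = FALSE)
    tab <- mmi_wmrr(full, data, scale = s, detail = detail, AICc = AICc)
    if (trace) { cat("-- scale", s, "--\n"); print(tab) }
    for (v in labels)
      rvi_mat[v, s] <- sum(tab$weight[vapply(tab$terms, function(tm)
        v %in% tm, logical(1))], na.rm = TRUE)
    tables[[s]] <- tab
  }
  structure(list(rvi = rvi_mat, tables = tables),
            class = "rvi_result")
}

#' @export
print.rvi_result <- function(x, ...) {
  cat("Relative variable importance by scale\n")
  print(round(x$rvi, 3))
  invisible(x)
}

#' @export
plot.rvi_result <- function(x, ...) {
  m <- x$rvi
  graphics::matplot(t(m), type = "b", pch = 16, lty = 1,
                    xlab = "scale", ylab = "relative importance",
                    ylim = c(0, 1), ...)
  graphics::legend("topright", legend = rownames(m), col = seq_len(nrow(m)),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
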
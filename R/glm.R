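## Baseline GLM fitting (via stats::glm) packaged with the residual types,
## dispersion and information criteria the spatial models report, plus the
## quasi-likelihood information criterion (QIC, Pan's trace form) used for
## GEE model comparison.

#' Fit a baseline (non-spatial) GLM on lattice data
#'
#' Ordinary GLM with canonical link, returned in the same shape as the
#' spatial fits so that residual autocorrelation profiles can be compared.
#' Dispersion is the Pearson moment estimate
#' \eqn{\hat\phi = \sum r_i^2 / (n - k)} (fixed at 1 for binomial/Poisson
#' when \code{scale_fix = TRUE}).
#'
#' @param formula model formula.
#' @param family \code{"gaussian"}, \code{"binomial"} or \code{"poisson"}.
#' @param data data frame with the model variables.
#' @param coord optional integer lattice coordinates; when given, the
#'   Moran's I profile of the Pearson residuals is attached.
#' @param scale_fix logical; fix the dispersion at 1.
#' @param moran list with \code{lim1}, \code{lim2}, \code{dmax} controlling
#'   the residual correlogram.
#' @return an object of class \code{"spat_glm"}.
#' @export
glm_lattice <- function(formula, family = "gaussian", data, coord = NULL,
                        scale_fix = FALSE,
                        moran = list(lim1 = 0, lim2 = 1, dmax = 10)) {
  fam <- get_family(family)
  des <- build_design(formula, data)
  check_response(des$y, fam)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, family = fam, data = data,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  converged <- fit$converged && !separated
  if (separated)
    warning("perfect or quasi-perfect separation; fit flagged as ",
            "non-converged", call. = FALSE)
  if (!fit$converged) warning("GLM did not converge", call. = FALSE)
  mu <- as.numeric(stats::fitted(fit))
  y <- des$y
  n <- length(y); k <- length(stats::coef(fit))
  rp <- (y - mu) / sqrt(fam$variance(mu))
  phi <- if (fam$family == "gaussian" || !scale_fix)
    sum(rp^2) / (n - k) else 1
  if (fam$family != "gaussian" && scale_fix) phi <- 1
  rp_out <- if (fam$family == "gaussian") rp / sqrt(phi) else rp
  ic <- aic_calc(formula, family = fam, data = data, mu = mu)
  ac <- NULL
  if (!is.null(coord))
    ac <- acfft(coord, rp, moran$lim1 %||% 0, moran$lim2 %||% 1,
                moran$dmax %||% 10)
  structure(list(coefficients = stats::coef(fit),
                 se = summary(fit)$coefficients[, 2L],
                 fitted = mu,
                 residuals = list(raw = y - mu, pearson = rp_out,
                                  normalized = rp_out),
                 dispersion = phi, ic = ic,
                 ac_glm = ac, ac_model = ac,
                 converged = converged,
                 n_iter = fit$iter,
                 family = fam$family, formula = formula,
                 X = stats::model.matrix(fit), y = y, n = n, k = k),
            class = "spat_glm")
}

#' @export
print.spat_glm <- function(x, ...) {
  cat("Non-spatial GLM (", x$family, ")\n", sep = "")
  print(round(x$coefficients, 4))
  cat("AIC:", round(x$ic$aic, 2), " AICc:", round(x$ic$aicc, 2), "\n")
  invisible(x)
}

#' Log likelihood, AIC and AICc for fitted mean values
#'
#' Evaluates the exact log likelihood of a GLM-family model at supplied
#' fitted means, independent of how those means were obtained (GLM, GEE,
#' WRM or a scale-specific multiresolution regression).  For the Gaussian
#' family the error variance is profiled out as the mean squared error and
#' counts as one extra parameter.  \eqn{AIC = -2\ell + 2k};
#' \eqn{AICc = AIC + 2k(k+1)/(n-k-1)}.
#'
#' @param formula model formula (determines the parameter count k).
#' @param family model family.
#' @param data data frame with the response.
#' @param mu vector of fitted mean values.
#' @return list with \code{loglik}, \code{aic}, \code{aicc}, \code{k},
#'   \code{n}.
#' @export
aic_calc <- function(formula, family = "gaussian", data, mu) {
  fam <- get_family(family)
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  check_response(y, fam)
  n <- length(y)
  if (length(mu) != n) stop("'mu' and response lengths differ", call. = FALSE)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  k <- ncol(X)
  ll <- switch(fam$family,
    gaussian = {
      s2 <- mean((y - mu)^2)
      k <- k + 1L  # profiled error variance
      sum(stats::dnorm(y, mu, sqrt(s2), log = TRUE))
    },
    poisson = sum(stats::dpois(y, mu, log = TRUE)),
    binomial = sum(stats::dbinom(y, 1L, mu, log = TRUE)))
  aic <- -2 * ll + 2 * k
  if (n - k - 1 <= 0)
    stop("AICc undefined: n - k - 1 <= 0", call. = FALSE)
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  list(loglik = ll, aic = aic, aicc = aicc, k = k, n = n)
}

# quasi-likelihood under independence at fitted means (phi = 1 scale;
# the dispersion enters QIC through the trace term's covariances)
quasi_loglik <- function(y, mu, family, phi = 1) {
  switch(family,
         gaussian = -sum((y - mu)^2) / (2 * phi),
         poisson = sum(y * log(mu) - mu) / phi,
         binomial = sum(y * log(mu) + (1 - y) * log(1 - mu)) / phi)
}

#' Quasi-likelihood information criterion (QIC)
#'
#' Pan's QIC for a GEE fit:
#' \deqn{QIC = -2 Q(\hat\beta; I) + 2\,\mathrm{tr}(\hat\Omega_I^{-1} \hat V_r)}
#' where \eqn{Q} is the quasi-likelihood under the independence working
#' model evaluated at the GEE fitted means, \eqn{\hat\Omega_I} the
#' model-based (independence) information and \eqn{\hat V_r} the robust
#' covariance of the coefficient estimates.
#'
#' @param fit a \code{"spat_gee"} fit (or any object carrying \code{X},
#'   \code{y}, \code{fitted}, \code{family}, \code{dispersion} and
#'   \code{vcov_robust}).
#' @param independence_fit optional independence fit on the same data and
#'   terms; its dispersion is used for the independence information when
#'   supplied.
#' @return list with \code{qic}, \code{quasi_lik} and the \code{trace}
#'   penalty term.
#' @export
qic_calc <- function(fit, independence_fit = NULL) {
  y <- fit$y; mu <- fit$fitted; X <- fit$X
  fam <- get_family(fit$family)
  phi <- if (!is.null(independence_fit)) independence_fit$dispersion
         else fit$dispersion
  Q <- quasi_loglik(y, mu, fam$family, phi = 1)
  # canonical links: D = A X, so the independence information (the inverse
  # of the model-based covariance Omega_I) is X' A X / phi
  A <- fam$variance(mu)
  info_i <- crossprod(X, X * A) / phi
  if (rcond(info_i) < .Machine$double.eps * 100)
    stop("independence information matrix is singular", call. = FALSE)
  penalty <- 2 * sum(diag(info_i %*% fit$vcov_robust))
  list(qic = -2 * Q + penalty, quasi_lik = Q, trace = penalty / 2)
}
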
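## Generalised estimating equations for lattice data.
##
## The working variance is V = phi * A^{1/2} R A^{1/2}.  Four working
## correlation structures are supported:
##   independence - R = I; identical to a GLM.
##   fixed        - R_ij = a^{d_ij}, an isotropic power function whose base a
##                  is adapted (once, then frozen) to the Moran's I
##                  correlogram of the GLM's Pearson residuals.
##   exchangeable / quadratic - block-diagonal R over non-overlapping
##                  cluster x cluster tiles of the grid; within-block
##                  parameters are moment-estimated, either all equal
##                  (exchangeable) or equal at equal within-block distance
##                  (quadratic), alternating with coefficient updates.
## Coefficients come from Fisher scoring on the estimating equations;
## uncertainty from the robust sandwich (blocks as clusters) where block
## structure exists, and from the model-based covariance for corstr="fixed"
## (a single full-rank correlation block admits no sandwich).

solve_chol <- function(C, v) backsolve(C, backsolve(C, v, transpose = TRUE))

# shrink a correlation matrix towards the identity until positive definite
ensure_pd <- function(R, eps = 1e-6) {
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < eps) {
    w <- (eps - ev) / (1 - ev + eps)
    R <- (1 - w) * R + w * diag(nrow(R))
    warning("working correlation not positive definite; shrunk towards identity",
            call. = FALSE)
  }
  R
}

# least-squares fit of rho(d) = a^d to a residual correlogram.  Bins with
# no pairs (NaN) are dropped and the remaining bins get distances 1..m in
# order, so the bin holding the nearest-neighbour pairs is always d = 1
# regardless of the lim1/lim2 choice.  Fallback: the first usable bin
# value, clamped to [0, 0.99].
fit_power_base <- function(rho) {
  ok <- is.finite(rho)
  if (!any(ok)) return(0)
  rho <- rho[ok]
  d <- seq_along(rho)
  obj <- function(a) sum((rho - a^d)^2)
  a <- tryCatch(stats::optimize(obj, c(0, 0.99))$minimum,
                error = function(e) NA_real_)
  if (!is.finite(a)) a <- min(max(rho[1L], 0), 0.99)
  a
}

#' Lag-one Moran's I
#'
#' Convenience wrapper around [acfft()] measuring Moran's I over the
#' nearest-neighbour pairs only (Euclidean distance in [0, 1.01), i.e. the
#' 4-neighbourhood of the lattice).
#'
#' @inheritParams acfft
#' @return a single number.
#' @export
moran_lag1 <- function(coord, f) acfft(coord, f, 0, 1.01, 1)$moran_i[1L]

# Fisher scoring with frozen (or externally updated) block correlations.
# blocks: list of row-index vectors; chols: matching upper Cholesky factors.
gee_score_fit <- function(y, X, fam, blocks, chols, beta0,
                          tol = 1e-8, maxit = 50) {
  beta <- beta0
  conv <- FALSE; it <- 0L
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- fam$linkinv(eta)
    A <- fam$variance(mu)
    we <- fam$mu.eta(eta)
    U <- X * (we / sqrt(A))
    s <- (y - mu) / sqrt(A)
    p <- ncol(X)
    omega <- matrix(0, p, p); rhs <- numeric(p)
    for (b in seq_along(blocks)) {
      ii <- blocks[[b]]
      Ub <- U[ii, , drop = FALSE]
      RiU <- solve_chol(chols[[b]], Ub)
      omega <- omega + crossprod(Ub, RiU)
      rhs <- rhs + crossprod(RiU, s[ii])
    }
    delta <- drop(solve(omega, rhs))
    beta <- beta + delta
    if (max(abs(delta) / pmax(abs(beta), 1e-4)) < tol) { conv <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- fam$linkinv(eta)
  A <- fam$variance(mu)
  we <- fam$mu.eta(eta)
  U <- X * (we / sqrt(A))
  s <- (y - mu) / sqrt(A)
  p <- ncol(X)
  omega <- matrix(0, p, p); meat <- matrix(0, p, p)
  for (b in seq_along(blocks)) {
    ii <- blocks[[b]]
    Ub <- U[ii, , drop = FALSE]
    RiU <- solve_chol(chols[[b]], Ub)
    omega <- omega + crossprod(Ub, RiU)
    sc <- crossprod(RiU, s[ii])
    meat <- meat + tcrossprod(sc)
  }
  list(beta = beta, mu = mu, omega = omega, meat = meat,
       converged = conv, n_iter = it)
}

#' Spatial generalised estimating equations on a lattice
#'
#' Fits a GLM-family regression whose residual dependence across grid cells
#' is modelled through a working correlation structure (see Details of the
#' class description above the function in the source, and the package
#' vignette).  \code{corstr = "independence"} reproduces the ordinary GLM;
#' \code{"fixed"} uses an isotropic power correlation \eqn{a^{d}} adapted to
#' the residual autocorrelation of the comparison GLM; \code{"exchangeable"}
#' and \code{"quadratic"} use block-diagonal working correlations over
#' \code{cluster} x \code{cluster} tiles with moment-estimated parameters.
#'
#' @param formula model formula.
#' @param family \code{"gaussian"}, \code{"binomial"} or \code{"poisson"}
#'   (canonical links).
#' @param data data frame with the model variables.
#' @param coord two-column matrix of integer cell coordinates (x, y).
#' @param corstr working correlation structure.
#' @param cluster tile side length for the clustered structures (2, 3 or 4).
#' @param scale_fix logical; fix the dispersion at 1 instead of the Pearson
#'   moment estimate.
#' @param fixed_a optional value in \eqn{[0, 1)} for the power base of
#'   \code{corstr = "fixed"}, bypassing the correlogram fit (freezing a
#'   known working correlation).
#' @param moran list (\code{lim1}, \code{lim2}, \code{dmax}) controlling the
#'   residual correlograms.
#' @param control list with \code{tol} and \code{maxit} for Fisher scoring.
#' @param compute_ac logical; attach residual autocorrelation profiles of
#'   the comparison GLM and of this model (normalised residuals).
#' @return an object of class \code{"spat_gee"} with coefficients, robust
#'   and model-based standard errors, fitted values, raw/Pearson/normalised
#'   residuals, the QIC, the working correlation parameters and residual
#'   correlograms.
#' @examples
#' sim <- sim_count_grid(n_side = 12, seed = 1)
#' m <- gee(count ~ pollution + exposure, family = "poisson",
#'          data = sim$data, coord = sim$coords, corstr = "fixed")
#' summary(m)
#' @export
gee <- function(formula, family = "gaussian", data, coord,
                corstr = c("fixed", "independence", "exchangeable",
                           "quadratic"),
                cluster = 3, scale_fix = FALSE, fixed_a = NULL,
                moran = list(lim1 = 0, lim2 = 1, dmax = 10),
                control = list(tol = 1e-8, maxit = 50),
                compute_ac = TRUE) {
  corstr <- match.arg(corstr)
  fam <- get_family(family)
  des <- build_design(formula, data)
  y <- des$y; X <- des$X
  check_response(y, fam)
  n <- length(y); k <- ncol(X)
  if (n < 4) stop("at least 4 observations are required", call. = FALSE)
  coord <- check_coords(coord, n)
  if (!cluster %in% 2:4) stop("'cluster' must be 2, 3 or 4", call. = FALSE)
  lim1 <- moran$lim1 %||% 0; lim2 <- moran$lim2 %||% 1
  dmax <- moran$dmax %||% 10

  glm0 <- glm_lattice(formula, fam, data, coord = if (compute_ac) coord,
                      scale_fix = scale_fix, moran = moran)

  refit_args <- list(family = fam$family, coord = coord, corstr = corstr,
                     cluster = cluster, scale_fix = scale_fix,
                     fixed_a = fixed_a, moran = moran, control = control)

  if (corstr == "independence") {
    mu <- glm0$fitted
    A <- fam$variance(mu)
    we <- fam$mu.eta(drop(X %*% glm0$coefficients))
    U <- X * (we / sqrt(A))
    s <- (y - mu) / sqrt(A)
    omega <- crossprod(U)
    meat <- crossprod(U * s)
    oi <- solve(omega)
    vc_rob <- oi %*% meat %*% oi
    fit <- list(beta = glm0$coefficients, mu = mu, omega = omega,
                converged = glm0$converged, n_iter = glm0$n_iter)
    rp <- (y - mu) / sqrt(A)
    phi <- glm0$dispersion
    out <- new_spat_gee(fit$beta, glm0$se, vc_rob,
                        phi * oi, mu, y, X, des$terms, fam, phi,
                        resid_norm = if (fam$family == "gaussian")
                          rp / sqrt(phi) else rp,
                        corstr = corstr, corpars = list(),
                        converged = fit$converged, n_iter = fit$n_iter,
                        formula = formula, refit_args = refit_args)
  } else if (corstr == "fixed") {
    if (n > 20000)
      stop("corstr = \"fixed\" needs an n x n correlation matrix; for n > ",
           "20000 use the clustered structures (exchangeable/quadratic)",
           call. = FALSE)
    a <- fixed_a
    if (is.null(a)) {
      rp0 <- with(glm0, residuals$pearson)
      ac0 <- acfft(coord, rp0, lim1, lim2, dmax)
      a <- fit_power_base(ac0$moran_i)
    } else if (a < 0 || a >= 1) {
      warning("'fixed_a' outside [0, 1); clamped")
      a <- min(max(a, 0), 0.99)
    }
    D <- as.matrix(stats::dist(coord))
    R <- ensure_pd(a^D)
    C <- chol(R)
    fit <- gee_score_fit(y, X, fam, list(seq_len(n)), list(C),
                         beta0 = glm0$coefficients,
                         tol = control$tol %||% 1e-8,
                         maxit = control$maxit %||% 50)
    rp <- (y - fit$mu) / sqrt(fam$variance(fit$mu))
    phi <- if (scale_fix && fam$family != "gaussian") 1 else
      sum(rp^2) / (n - k)
    vc_naive <- phi * solve(fit$omega)
    rn <- drop(backsolve(C, rp, transpose = TRUE))  # L^{-1} r, R = L L'
    out <- new_spat_gee(fit$beta, sqrt(diag(vc_naive)), vc_naive, vc_naive,
                        fit$mu, y, X, des$terms, fam, phi,
                        resid_norm = if (fam$family == "gaussian")
                          rn / sqrt(phi) else rn,
                        corstr = corstr, corpars = list(a = a),
                        converged = fit$converged, n_iter = fit$n_iter,
                        formula = formula, refit_args = refit_args)
  } else {
    ## clustered: exchangeable or quadratic tiles
    bx <- (coord[, 1L] - min(coord[, 1L])) %/% cluster
    by <- (coord[, 2L] - min(coord[, 2L])) %/% cluster
    bid <- interaction(bx, by, drop = TRUE)
    blocks <- split(seq_len(n), bid)
    dmat_b <- lapply(blocks, function(ii)
      as.matrix(stats::dist(coord[ii, , drop = FALSE])))
    # global within-tile distance classes (quadratic)
    dkeys <- sort(unique(round(unlist(lapply(dmat_b, function(d)
      d[upper.tri(d)])), 8)))
    beta <- glm0$coefficients
    alphas <- if (corstr == "exchangeable") c(alpha = 0) else
      stats::setNames(rep(0, length(dkeys)), format(dkeys))
    phi <- 1
    tol_out <- 1e-6
    fit <- NULL
    for (outer in seq_len(25L)) {
      Rb <- lapply(dmat_b, function(d) {
        R <- diag(nrow(d))
        if (nrow(d) > 1L) {
          if (corstr == "exchangeable") {
            R[] <- alphas[[1L]]; diag(R) <- 1
          } else {
            key <- match(round(d, 8), dkeys)
            R[] <- ifelse(is.na(key), 0, alphas[key])
            diag(R) <- 1
          }
        }
        R
      })
      chols <- lapply(Rb, function(R)
        chol(suppressWarnings(ensure_pd(R))))
      fit <- gee_score_fit(y, X, fam, blocks, chols, beta0 = beta,
                           tol = control$tol %||% 1e-8,
                           maxit = control$maxit %||% 50)
      rp <- (y - fit$mu) / sqrt(fam$variance(fit$mu))
      phi <- if (scale_fix && fam$family != "gaussian") 1 else
        sum(rp^2) / (n - k)
      ## moment update of the within-block correlation parameters
      if (corstr == "exchangeable") {
        num <- 0; den <- 0
        for (b in seq_along(blocks)) {
          rb <- rp[blocks[[b]]]
          nb <- length(rb)
          if (nb > 1L) {
            num <- num + (sum(rb)^2 - sum(rb^2)) / 2
            den <- den + nb * (nb - 1L) / 2
          }
        }
        new_al <- c(alpha = if (den > 0) num / (den * phi) else 0)
      } else {
        sums <- rep(0, length(dkeys)); cnts <- rep(0, length(dkeys))
        for (b in seq_along(blocks)) {
          rb <- rp[blocks[[b]]]
          if (length(rb) > 1L) {
            d <- dmat_b[[b]]
            ut <- upper.tri(d)
            key <- match(round(d[ut], 8), dkeys)
            pr <- tcrossprod(rb)[ut]
            for (q in seq_along(key)) {
              sums[key[q]] <- sums[key[q]] + pr[q]
              cnts[key[q]] <- cnts[key[q]] + 1
            }
          }
        }
        new_al <- stats::setNames(
          ifelse(cnts > 0, sums / (pmax(cnts, 1) * phi), 0), format(dkeys))
      }
      new_al <- pmin(pmax(new_al, -0.95), 0.95)
      dpar <- max(abs(new_al - alphas), max(abs(fit$beta - beta)))
      alphas <- new_al; beta <- fit$beta
      if (dpar < tol_out) break
    }
    vc_naive <- phi * solve(fit$omega)
    oi <- solve(fit$omega)
    vc_rob <- oi %*% fit$meat %*% oi
    rp <- (y - fit$mu) / sqrt(fam$variance(fit$mu))
    rn <- rp
    Rb <- lapply(dmat_b, function(d) {
      R <- diag(nrow(d))
      if (nrow(d) > 1L) {
        if (corstr == "exchangeable") { R[] <- alphas[[1L]]; diag(R) <- 1 }
        else {
          key <- match(round(d, 8), dkeys)
          R[] <- ifelse(is.na(key), 0, alphas[key]); diag(R) <- 1
        }
      }
      R
    })
    for (b in seq_along(blocks)) {
      C <- chol(suppressWarnings(ensure_pd(Rb[[b]])))
      rn[blocks[[b]]] <- drop(backsolve(C, rp[blocks[[b]]],
                                        transpose = TRUE))
    }
    out <- new_spat_gee(fit$beta, sqrt(diag(vc_rob)), vc_rob, vc_naive,
                        fit$mu, y, X, des$terms, fam, phi,
                        resid_norm = if (fam$family == "gaussian")
                          rn / sqrt(phi) else rn,
                        corstr = corstr,
                        corpars = list(alphas = alphas, cluster = cluster),
                        converged = fit$converged, n_iter = fit$n_iter,
                        formula = formula, refit_args = refit_args)
  }

  out$ic <- c(qic_calc(out), list(aic = glm0$ic$aic))
  out$ac_glm <- glm0$ac_glm
  out$ac_model <- if (compute_ac)
    acfft(coord, out$residuals$normalized, lim1, lim2, dmax) else NULL
  out$glm_fit <- glm0
  if (!out$converged)
    warning("GEE Fisher scoring did not converge", call. = FALSE)
  out
}

new_spat_gee <- function(beta, se, vcov_robust, vcov_naive, mu, y, X, terms,
                         fam, phi, resid_norm, corstr, corpars, converged,
                         n_iter, formula, refit_args) {
  rp <- (y - mu) / sqrt(fam$variance(mu))
  if (fam$family == "gaussian") rp <- rp / sqrt(phi)
  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 se = stats::setNames(drop(se), colnames(X)),
                 vcov_robust = vcov_robust, vcov_naive = vcov_naive,
                 fitted = mu,
                 residuals = list(raw = y - mu, pearson = rp,
                                  normalized = resid_norm),
                 dispersion = phi, corstr = corstr, corpars = corpars,
                 converged = converged, n_iter = n_iter,
                 family = fam$family, formula = formula, terms = terms,
                 X = X, y = y, n = length(y), k = ncol(X),
                 refit_args = refit_args),
            class = "spat_gee")
}

#' Predict method for spatial GEE fits
#'
#' Mean predictions \eqn{g^{-1}(X_{new}\hat\beta)}; coordinates play no
#' role at prediction time.
#'
#' @param object a \code{"spat_gee"} fit.
#' @param newdata data frame with the model covariates.
#' @param ... unused.
#' @export
predict.spat_gee <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict_via_terms(object, newdata)
}

predict_via_terms <- function(object, newdata) {
  tt <- stats::delete.response(object$terms)
  missing <- setdiff(all.vars(tt), names(newdata))
  if (length(missing))
    stop("newdata is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  fam <- get_family(object$family)
  drop(fam$linkinv(X %*% object$coefficients[colnames(X)]))
}

#' @export
print.spat_gee <- function(x, ...) {
  cat("Spatial GEE (", x$family, ", corstr = ", x$corstr, ")\n", sep = "")
  print(round(x$coefficients, 4))
  cat("QIC:", round(x$ic$qic, 2), "\n")
  invisible(x)
}

#' Summarise a spatial GEE fit
#'
#' @param object a \code{"spat_gee"} fit.
#' @param printAutoCorPars print the working-correlation parameters.
#' @param ... unused.
#' @export
summary.spat_gee <- function(object, printAutoCorPars = FALSE, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, qic = object$ic$qic,
              dispersion = object$dispersion, corstr = object$corstr,
              corpars = object$corpars, converged = object$converged,
              family = object$family, ac_glm = object$ac_glm,
              ac_model = object$ac_model,
              printAutoCorPars = printAutoCorPars)
  class(out) <- "summary.spat_gee"
  out
}

#' @export
print.summary.spat_gee <- function(x, ...) {
  cat("Spatial GEE, family", x$family, ", corstr =", x$corstr, "\n")
  if (!x$converged) cat("** Fisher scoring did NOT converge **\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("QIC:", round(x$qic, 3), "  dispersion:", round(x$dispersion, 4), "\n")
  if (x$printAutoCorPars && length(x$corpars)) {
    cat("Working correlation parameters:\n")
    print(lapply(x$corpars, round, 4))
  }
  if (!is.null(x$ac_glm)) {
    fin <- is.finite(x$ac_glm$moran_i)
    cat("Residual Moran's I (GLM):  ",
        round(utils::head(x$ac_glm$moran_i[fin], 5), 3), "\n")
    cat("Residual Moran's I (GEE):  ",
        round(utils::head(x$ac_model$moran_i[is.finite(x$ac_model$moran_i)],
                          5), 3), "\n")
  }
  invisible(x)
}
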
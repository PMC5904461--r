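## Seeded generators for spatially autocorrelated lattice data.
##
## Spatial structure is produced by Gaussian-kernel smoothing of white
## noise (range parameter = kernel standard deviation in cell units),
## standardised to zero mean and unit variance.  This is cheap, fully
## seeded and sufficient for the autocorrelation properties the package's
## tests rely on; it is not a parametric covariance model.

# linear (non-circular) separable Gaussian blur; the input is extended by
# reflection so every output cell sees a full kernel
gauss_blur <- function(m, range) {
  if (range < 0.25) return(m)
  r <- ceiling(3 * range)
  kk <- stats::dnorm(-r:r, sd = range)
  kk <- kk / sum(kk)
  nr <- nrow(m); nc <- ncol(m)
  ri <- mirror_index(seq_len(nr + 2L * r) - r, nr)
  ci <- mirror_index(seq_len(nc + 2L * r) - r, nc)
  z <- m[ri, ci, drop = FALSE]
  z <- apply(z, 2L, function(col) stats::filter(col, kk, sides = 2L))
  z <- t(apply(z, 1L, function(row) stats::filter(row, kk, sides = 2L)))
  z[(r + 1L):(r + nr), (r + 1L):(r + nc)]
}

standardize <- function(m) (m - mean(m)) / stats::sd(as.numeric(m))

# standardised Gaussian-kernel smoothing of an n x n white-noise field;
# the noise is generated on an enlarged grid so no edge is kernel-starved
smooth_gauss_field <- function(n_side, ac_range) {
  if (ac_range < 0.25) {
    f <- matrix(stats::rnorm(n_side^2), n_side, n_side)
  } else {
    r <- ceiling(3 * ac_range)
    big <- n_side + 2L * r
    z <- matrix(stats::rnorm(big^2), big, big)
    kk <- stats::dnorm(-r:r, sd = ac_range)
    kk <- kk / sum(kk)
    z <- apply(z, 2L, function(col) stats::filter(col, kk, sides = 2L))
    z <- t(apply(z, 1L, function(row) stats::filter(row, kk, sides = 2L)))
    f <- z[(r + 1L):(r + n_side), (r + 1L):(r + n_side)]
  }
  standardize(f)
}

#' Simulate spatially autocorrelated counts on a grid
#'
#' Generates a fully observed \code{n_side} x \code{n_side} lattice with
#' two spatially autocorrelated covariates and a GLM-family response built
#' from known ground-truth coefficients plus a smooth spatial random field:
#' \deqn{\eta = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + u,\qquad
#'       u = \sigma_u(\rho\, \tilde s_1 + \sqrt{1-\rho^2}\, \tilde s_0)}
#' The covariates are Gaussian-kernel-smoothed white noise with range
#' \code{ac_range}, so they retain fine-scale (detail) variation on top of
#' their smooth component.  \eqn{\tilde s_1} is a further-blurred (range
#' \code{2 * ac_range}, standardised) copy of the first covariate's field
#' and \eqn{\tilde s_0} an equally smooth independent field, so the random
#' field is always smoother than the covariates.  The confounder strength
#' \eqn{\rho} controls how strongly the unobserved field is correlated
#' with the \emph{smooth part} of the first covariate: \eqn{\rho = 0}
#' gives a pure (unconfounded) spatial random effect whose only effect is
#' residual autocorrelation, while \eqn{\rho = 1} biases naive slope
#' estimates for \eqn{x_1} upward -- the fine-scale detail of \eqn{x_1},
#' which the smooth confounder does not share, is what spatially informed
#' estimators can still exploit.
#'
#' @param n_side grid side length (>= 8).
#' @param betas intercept and two slopes (ground truth).
#' @param covar_names names for the two covariates.
#' @param response_name column name of the response.
#' @param ac_range Gaussian kernel standard deviation (cells) of the
#'   spatial smoothing; near 0 gives white noise.
#' @param field_sd standard deviation \eqn{\sigma_u} of the spatial random
#'   field on the linear-predictor scale.
#' @param confounder_strength \eqn{\rho \in [0, 1]}.
#' @param family response family (\code{"poisson"}, \code{"gaussian"} or
#'   \code{"binomial"}); Gaussian errors have unit variance.
#' @param seed integer seed fixing all randomness.
#' @return list with \code{data} (data frame: response, covariates, x, y),
#'   \code{coords}, and \code{truth} (betas, the random field, settings).
#' @examples
#' sim <- sim_count_grid(n_side = 12, seed = 42)
#' head(sim$data)
#' @export
sim_count_grid <- function(n_side = 24, betas = c(0.5, 0.3, -0.4),
                           covar_names = c("pollution", "exposure"),
                           response_name = "count",
                           ac_range = 1, field_sd = 0.8,
                           confounder_strength = 0,
                           family = "poisson", seed = 1) {
  stopifnot(n_side >= 8, length(betas) == 3L,
            confounder_strength >= 0, confounder_strength <= 1)
  fam <- get_family(family)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  s1 <- smooth_gauss_field(n_side, ac_range)
  s2 <- smooth_gauss_field(n_side, ac_range)
  s0 <- smooth_gauss_field(n_side, ac_range)
  rho <- confounder_strength
  blur_range <- max(2 * ac_range, 0.5)
  u1 <- standardize(gauss_blur(s1, blur_range))
  u0 <- standardize(gauss_blur(s0, blur_range))
  u <- field_sd * (rho * u1 + sqrt(1 - rho^2) * u0)
  x1 <- as.numeric(s1); x2 <- as.numeric(s2)
  eta <- betas[1L] + betas[2L] * x1 + betas[3L] * x2 + as.numeric(u)
  y <- switch(fam$family,
              poisson = stats::rpois(n_side^2, exp(eta)),
              gaussian = eta + stats::rnorm(n_side^2),
              binomial = stats::rbinom(n_side^2, 1L, stats::plogis(eta)))
  grid <- expand.grid(x = seq_len(n_side), y = seq_len(n_side))
  d <- data.frame(y, x1, x2, grid$x, grid$y)
  names(d) <- c(response_name, covar_names, "x", "y")
  list(data = d, coords = as.matrix(grid[, c("x", "y")]),
       truth = list(betas = betas, field = u, eta = eta,
                    settings = list(n_side = n_side, ac_range = ac_range,
                                    field_sd = field_sd,
                                    confounder_strength = rho,
                                    family = fam$family, seed = seed)))
}

#' Simulate counts on an exactly dyadic square grid
#'
#' Same generating model as [sim_count_grid()] but with defaults tailored
#' to multiresolution demonstrations: a fully observed square grid whose
#' side is a power of two (so dyadic upscaling is exact) and covariates
#' named \code{aridity} and \code{land_use}.
#'
#' @inheritParams sim_count_grid
#' @export
sim_dyadic_grid <- function(n_side = 32, betas = c(0.5, 0.3, -0.4),
                            covar_names = c("aridity", "land_use"),
                            response_name = "count",
                            ac_range = 1, field_sd = 0.8,
                            confounder_strength = 0,
                            family = "poisson", seed = 1) {
  if (bitwAnd(n_side, n_side - 1L) != 0L)
    stop("'n_side' must be a power of two", call. = FALSE)
  sim_count_grid(n_side, betas, covar_names, response_name, ac_range,
                 field_sd, confounder_strength, family, seed)
}

#' Simulate clustered presence/absence data with probability predictions
#'
#' Generates a smooth random field, thresholds it at the
#' \code{1 - prevalence} quantile to obtain spatially clustered presences,
#' and derives a probability prediction surface from the same field,
#' optionally displaced by \code{shift_cells} columns (with wrap-around).
#' The displacement creates "near misses": predictions wrong in place but
#' right in neighbourhood, which spatial accuracy measures credit and
#' classical ones do not.
#'
#' @inheritParams sim_count_grid
#' @param prevalence target fraction of presences.
#' @param shift_cells integer displacement of the prediction surface.
#' @param steepness slope of the logistic map from field to probability.
#' @return list with \code{data} (data frame: actuals, predictions, x, y),
#'   \code{coords} and \code{truth}.
#' @export
sim_presence_preds <- function(n_side = 20, prevalence = 0.3, ac_range = 1,
                               shift_cells = 0, steepness = 10, seed = 1) {
  stopifnot(n_side >= 8, prevalence > 0, prevalence < 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  g <- smooth_gauss_field(n_side, ac_range)
  q <- stats::quantile(g, 1 - prevalence, names = FALSE)
  actuals <- as.integer(g >= q)
  sh <- shift_cells %% n_side
  gs <- if (sh > 0) g[, c((sh + 1L):n_side, 1L:sh), drop = FALSE] else g
  predictions <- stats::plogis(steepness * (gs - q))
  grid <- expand.grid(x = seq_len(n_side), y = seq_len(n_side))
  d <- data.frame(actuals = as.numeric(actuals),
                  predictions = as.numeric(predictions),
                  x = grid$x, y = grid$y)
  list(data = d, coords = as.matrix(grid[, c("x", "y")]),
       truth = list(field = g, threshold = q,
                    settings = list(n_side = n_side, prevalence = prevalence,
                                    ac_range = ac_range,
                                    shift_cells = shift_cells,
                                    steepness = steepness, seed = seed)))
}

#' Write a simulated data set to disk
#'
#' Writes the tabular records as CSV and the ground-truth sidecar
#' (coefficients and settings) as JSON next to it.
#'
#' @param sim result of one of the generators.
#' @param file path of the CSV file to write.
#' @export
write_sim <- function(sim, file) {
  utils::write.csv(sim$data, file, row.names = FALSE)
  truth <- sim$truth
  truth$field <- NULL; truth$eta <- NULL  # keep the sidecar small
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(truth, sub("\\.csv$", "", file) %+% "_truth.json",
                         auto_unbox = TRUE, digits = NA)
  invisible(file)
}

`%+%` <- function(a, b) paste0(a, b)

# save/restore the RNG state so generators do not disturb the caller's stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
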
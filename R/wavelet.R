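## Separable 2-D wavelet machinery: decimated (dwt) and maximal-overlap
## (modwt) pyramid transforms for the haar and d4 (Daubechies extremal
## phase, 4-tap) families, with periodic boundary treatment.  Boundary
## artefacts are controlled by the embedding pad zone, not by the filters.
##
## Components are returned as reconstructed full-resolution fields
## (multiresolution analysis), so values at observation cells are well
## defined even for the decimated transform.

wave_filter <- function(wavelet = c("haar", "d4")) {
  wavelet <- match.arg(wavelet)
  h <- switch(wavelet,
              haar = c(1, 1) / sqrt(2),
              d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) /
                (4 * sqrt(2)))
  M <- length(h)
  g <- (-1)^(seq_len(M) - 1L) * rev(h)  # quadrature mirror filter
  list(h = h, g = g, M = M)
}

wrap1 <- function(i, n) ((i - 1L) %% n) + 1L

## ---- decimated DWT, one level, periodic ----------------------------------
# analysis: a[k] = sum_m h[m] x[(2(k-1)+m) mod N]; synthesis is the
# transpose of the (orthogonal) analysis matrix.

dwt_analyze_vec <- function(x, h, g) {
  n <- length(x); k <- n %/% 2L
  a <- numeric(k); d <- numeric(k)
  base <- 2L * (seq_len(k) - 1L)
  for (m in seq_along(h)) {
    idx <- wrap1(base + m, n)
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(a = a, d = d)
}

dwt_synthesize_vec <- function(a, d, h, g) {
  k <- length(a); n <- 2L * k
  y <- numeric(n)
  base <- 2L * (seq_len(k) - 1L)
  for (m in seq_along(h)) {
    idx <- wrap1(base + m, n)
    y[idx] <- y[idx] + h[m] * a + g[m] * d
  }
  y
}

# apply a 1-D step to every column of a matrix
dwt_analyze_cols <- function(X, h, g) {
  n <- nrow(X); k <- n %/% 2L
  A <- matrix(0, k, ncol(X)); D <- matrix(0, k, ncol(X))
  base <- 2L * (seq_len(k) - 1L)
  for (m in seq_along(h)) {
    idx <- wrap1(base + m, n)
    A <- A + h[m] * X[idx, , drop = FALSE]
    D <- D + g[m] * X[idx, , drop = FALSE]
  }
  list(A = A, D = D)
}

dwt_synthesize_cols <- function(A, D, h, g) {
  k <- nrow(A); n <- 2L * k
  Y <- matrix(0, n, ncol(A))
  base <- 2L * (seq_len(k) - 1L)
  for (m in seq_along(h)) {
    idx <- wrap1(base + m, n)
    Y[idx, ] <- Y[idx, , drop = FALSE] + h[m] * A + g[m] * D
  }
  Y
}

dwt_step_2d <- function(X, h, g) {
  rows <- dwt_analyze_cols(X, h, g)                  # filter along y (rows)
  la <- dwt_analyze_cols(t(rows$A), h, g)            # then along x (cols)
  ld <- dwt_analyze_cols(t(rows$D), h, g)
  list(ll = t(la$A), lh = t(la$D), hl = t(ld$A), hh = t(ld$D))
}

dwt_istep_2d <- function(ll, lh, hl, hh, h, g) {
  A <- t(dwt_synthesize_cols(t(ll), t(lh), h, g))
  D <- t(dwt_synthesize_cols(t(hl), t(hh), h, g))
  dwt_synthesize_cols(A, D, h, g)
}

## ---- MODWT (a trous), one level, periodic --------------------------------
# level-j filters are h/sqrt(2) upsampled by 2^(j-1); analysis by circular
# correlation, synthesis by circular convolution; their sum is the identity.

modwt_analyze_cols <- function(X, ht, gt, stride) {
  n <- nrow(X)
  A <- matrix(0, n, ncol(X)); D <- matrix(0, n, ncol(X))
  base <- seq_len(n)
  for (m in seq_along(ht)) {
    idx <- wrap1(base + stride * (m - 1L), n)
    A <- A + ht[m] * X[idx, , drop = FALSE]
    D <- D + gt[m] * X[idx, , drop = FALSE]
  }
  list(A = A, D = D)
}

modwt_synthesize_cols <- function(A, D, ht, gt, stride) {
  n <- nrow(A)
  Y <- matrix(0, n, ncol(A))
  base <- seq_len(n)
  for (m in seq_along(ht)) {
    idx <- wrap1(base - stride * (m - 1L), n)
    Y <- Y + ht[m] * A[idx, , drop = FALSE] + gt[m] * D[idx, , drop = FALSE]
  }
  Y
}

modwt_step_2d <- function(X, ht, gt, stride) {
  rows <- modwt_analyze_cols(X, ht, gt, stride)
  la <- modwt_analyze_cols(t(rows$A), ht, gt, stride)
  ld <- modwt_analyze_cols(t(rows$D), ht, gt, stride)
  list(ll = t(la$A), lh = t(la$D), hl = t(ld$A), hh = t(ld$D))
}

modwt_istep_2d <- function(ll, lh, hl, hh, ht, gt, stride) {
  A <- t(modwt_synthesize_cols(t(ll), t(lh), ht, gt, stride))
  D <- t(modwt_synthesize_cols(t(hl), t(hh), ht, gt, stride))
  modwt_synthesize_cols(A, D, ht, gt, stride)
}

## ---- pyramid forward / selective inverse ---------------------------------

max_wave_level <- function(side, wavelet, wtrafo) {
  M <- wave_filter(wavelet)$M
  if (wtrafo == "dwt") {
    lev <- 0L; s <- side
    while (s >= M && s %% 2L == 0L) { lev <- lev + 1L; s <- s %/% 2L }
    lev
  } else {
    lev <- 0L
    while (2L^lev * (M - 1L) < side) lev <- lev + 1L
    lev
  }
}

check_level <- function(side, level, wavelet, wtrafo) {
  mx <- max_wave_level(side, wavelet, wtrafo)
  if (level < 1 || level != round(level))
    stop("'level' must be a positive integer", call. = FALSE)
  if (level > mx)
    stop("level ", level, " too deep for a ", side, "x", side, " grid with ",
         wavelet, "/", wtrafo, " (maximum ", mx, ")", call. = FALSE)
  invisible(mx)
}

# full pyramid to depth L; keeps every subband so components can be rebuilt
wave_pyramid <- function(mat, level, wavelet = "haar", wtrafo = "dwt") {
  wtrafo <- match.arg(wtrafo, c("dwt", "modwt"))
  f <- wave_filter(wavelet)
  check_level(nrow(mat), level, wavelet, wtrafo)
  sub <- vector("list", level)
  ll <- mat
  for (j in seq_len(level)) {
    st <- if (wtrafo == "dwt") dwt_step_2d(ll, f$h, f$g)
          else modwt_step_2d(ll, f$h / sqrt(2), f$g / sqrt(2), 2L^(j - 1L))
    sub[[j]] <- st[c("lh", "hl", "hh")]
    ll <- st$ll
  }
  list(sub = sub, ll = ll, level = level, wavelet = wavelet,
       wtrafo = wtrafo, side = nrow(mat))
}

# invert the pyramid keeping only chosen content:
#   ll_at  - level whose LL (smooth) is kept, or 0 to drop all smooth
#   detail - named list level -> character subset of c("lh","hl","hh")
wave_rebuild <- function(pyr, ll_keep = TRUE, details_keep = integer(0),
                         orient = c("lh", "hl", "hh")) {
  f <- wave_filter(pyr$wavelet)
  L <- pyr$level
  zero_like <- function(m) matrix(0, nrow(m), ncol(m))
  cur <- if (ll_keep) pyr$ll else zero_like(pyr$ll)
  for (j in rev(seq_len(L))) {
    sb <- pyr$sub[[j]]
    use <- j %in% details_keep
    lh <- if (use && "lh" %in% orient) sb$lh else zero_like(sb$lh)
    hl <- if (use && "hl" %in% orient) sb$hl else zero_like(sb$hl)
    hh <- if (use && "hh" %in% orient) sb$hh else zero_like(sb$hh)
    cur <- if (pyr$wtrafo == "dwt") dwt_istep_2d(cur, lh, hl, hh, f$h, f$g)
           else modwt_istep_2d(cur, lh, hl, hh, f$h / sqrt(2), f$g / sqrt(2),
                               2L^(j - 1L))
  }
  cur
}

# smooth component at a given level, reconstructed on the full grid
smooth2d <- function(mat, level, wavelet = "haar", wtrafo = "dwt") {
  pyr <- wave_pyramid(mat, level, wavelet, wtrafo)
  wave_rebuild(pyr, ll_keep = TRUE)
}

#' Two-dimensional wavelet multiresolution decomposition
#'
#' Decomposes the matrix of a [embed_lattice()] frame into reconstructed
#' detail components (three orientation sub-bands per level, plus their sum)
#' and smooth components for levels \code{1..max_level}.  The components
#' telescope: \code{smooth(s) == smooth(s+1) + detail(s+1)}, and
#' \code{smooth(L) + sum of details} reproduces the input (perfect
#' reconstruction).
#'
#' @param frame a \code{"lattice_frame"} (or a plain square matrix with a
#'   power-of-two side).
#' @param wavelet wavelet family, \code{"haar"} or \code{"d4"}.
#' @param wtrafo transform type: decimated \code{"dwt"} or maximal-overlap
#'   \code{"modwt"} (undecimated, translation invariant).
#' @param max_level decomposition depth; defaults to the deepest level the
#'   grid and filter allow.
#' @return list of class \code{"decomp2d"} with elements \code{details}
#'   (per level: \code{lh}, \code{hl}, \code{hh}, \code{total}),
#'   \code{smooths}, and the transform settings.
#' @export
decompose2d <- function(frame, wavelet = "haar", wtrafo = "dwt",
                        max_level = NULL) {
  mat <- if (inherits(frame, "lattice_frame")) frame$matrix else frame
  if (nrow(mat) != ncol(mat) || bitwAnd(nrow(mat), nrow(mat) - 1L) != 0L)
    stop("'frame' must be square with a power-of-two side", call. = FALSE)
  wtrafo <- match.arg(wtrafo, c("dwt", "modwt"))
  if (is.null(max_level)) max_level <- max_wave_level(nrow(mat), wavelet, wtrafo)
  pyr <- wave_pyramid(mat, max_level, wavelet, wtrafo)
  details <- vector("list", max_level)
  smooths <- vector("list", max_level)
  for (s in seq_len(max_level)) {
    comp <- lapply(c("lh", "hl", "hh"), function(o)
      wave_rebuild(pyr, ll_keep = FALSE, details_keep = s, orient = o))
    names(comp) <- c("lh", "hl", "hh")
    comp$total <- comp$lh + comp$hl + comp$hh
    details[[s]] <- comp
    smooths[[s]] <- wave_rebuild(pyr, ll_keep = TRUE,
                                 details_keep = if (s < max_level)
                                   (s + 1L):max_level else integer(0))
  }
  structure(list(details = details, smooths = smooths, wavelet = wavelet,
                 wtrafo = wtrafo, max_level = max_level),
            class = "decomp2d")
}

#' High-pass wavelet filtering of a gridded variable
#'
#' Embeds the variable, removes the smooth (low-frequency) component of its
#' wavelet decomposition at the given level and returns the detail part at
#' the observation cells.  Smaller \code{level} removes more: the strongest
#' reduction of spatial autocorrelation is obtained at \code{level = 1}.
#'
#' @inheritParams upscale
#' @param values numeric vector of observations.
#' @param level positive integer filtering level.
#' @return numeric vector (detail components at observation cells, original
#'   record order).
#' @export
filter_highpass <- function(values, coord, level = 1, wavelet = "haar",
                            wtrafo = "dwt",
                            pad = list(padform = "mean", padzone = 1)) {
  fr <- embed_lattice(values, coord, pad)
  sm <- smooth2d(fr$matrix, level, wavelet, wtrafo)
  (fr$matrix - sm)[fr$index_map]
}

#' Extract a single-scale wavelet component of a gridded variable
#'
#' Returns, at the observation cells, either the detail component at scale
#' \code{s} (fluctuations at exactly that resolution) or the smooth
#' component at scale \code{s} (everything coarser).
#'
#' @inheritParams filter_highpass
#' @param scale positive integer scale level.
#' @param detail logical: detail (\code{TRUE}) or smooth (\code{FALSE})
#'   component.
#' @return numeric vector in original record order.
#' @export
extract_component <- function(values, coord, scale = 1, detail = TRUE,
                              wavelet = "haar", wtrafo = "dwt",
                              pad = list(padform = "mean", padzone = 1)) {
  fr <- embed_lattice(values, coord, pad)
  sm_s <- smooth2d(fr$matrix, scale, wavelet, wtrafo)
  out <- if (detail) {
    sm_prev <- if (scale == 1) fr$matrix else
      smooth2d(fr$matrix, scale - 1L, wavelet, wtrafo)
    sm_prev - sm_s           # telescoping: detail(s) = smooth(s-1) - smooth(s)
  } else sm_s
  out[fr$index_map]
}

#' Whitened wavelet-domain residuals for autocorrelation diagnosis
#'
#' Reconstructed (cell-space) high-pass residuals are a projection onto the
#' detail subspace and therefore carry negative short-range correlation
#' even when a model is perfect.  For a calibrated diagnostic this function
#' returns instead the \emph{decimated orthonormal DWT detail coefficients}
#' of a residual field for levels \code{1..level}: under a correct model
#' with independent (standardised) residuals these coefficients are exactly
#' uncorrelated, so their Moran's I is centred at \eqn{-1/(m-1)}, while
#' spatial structure the filter failed to remove still correlates them.
#' Each coefficient is placed at a representative cell of its dyadic block
#' (the block's smooth slot stays empty), so the result can be fed straight
#' into [acfft()].  Coefficients of blocks containing no observed cell are
#' dropped.
#'
#' @inheritParams filter_highpass
#' @param values residual vector (standardise before calling if the model
#'   is heteroscedastic).
#' @return list with \code{values} (coefficients) and \code{coord}
#'   (their representative cells).
#' @export
wavelet_coef_resid <- function(values, coord, level = 1, wavelet = "haar",
                               pad = list(padform = "mean", padzone = 1)) {
  fr <- embed_lattice(values, coord, pad)
  pyr <- wave_pyramid(fr$matrix, level, wavelet, "dwt")
  side <- nrow(fr$matrix)
  occ <- matrix(FALSE, side, side)
  occ[fr$index_map] <- TRUE
  vals <- numeric(0); cc <- matrix(0, 0, 2)
  for (l in seq_len(level)) {
    # OR-pool occupancy to the block grid of this level
    occ <- occ[seq(1, nrow(occ), 2), , drop = FALSE] |
      occ[seq(2, nrow(occ), 2), , drop = FALSE]
    occ <- occ[, seq(1, ncol(occ), 2), drop = FALSE] |
      occ[, seq(2, ncol(occ), 2), drop = FALSE]
    sb <- pyr$sub[[l]]
    bs <- 2L^l                      # block side in cells
    half <- bs %/% 2L
    idx <- which(occ, arr.ind = TRUE)
    if (nrow(idx)) {
      r0 <- (idx[, 1] - 1L) * bs + 1L
      c0 <- (idx[, 2] - 1L) * bs + 1L
      for (o in list(list(m = sb$lh, dr = 0L, dc = half),
                     list(m = sb$hl, dr = half, dc = 0L),
                     list(m = sb$hh, dr = half, dc = half))) {
        vals <- c(vals, o$m[idx])
        cc <- rbind(cc, cbind(c0 + o$dc, r0 + o$dr))  # (x, y) order
      }
    }
  }
  # map matrix rows/cols back to the caller's coordinate system
  list(values = vals,
       coord = cbind(x = cc[, 1] + min(coord[, 1]) - 1L,
                     y = cc[, 2] + min(coord[, 2]) - 1L))
}

#' Wavelet variance and covariance by scale level
#'
#' Computes, for each decomposition level, the wavelet variance of every
#' model variable and the wavelet covariance of the response with each
#' covariate, from the wavelet coefficients of the (internally centred)
#' embedded fields.  The d4 family with the maximal-overlap transform is
#' the default, being mathematically the most appropriate choice for this
#' purpose.  With \code{wtrafo = "modwt"} the per-level variances and the
#' final smooth energy add up exactly to the total variance of the field
#' (energy decomposition).
#'
#' @param formula model formula; \code{- 1} may be used since the intercept
#'   plays no role here.
#' @param data data frame holding the model variables.
#' @param coord integer lattice coordinates (x, y).
#' @param wavelet,wtrafo wavelet family and transform (defaults d4/modwt).
#' @param max_level depth; defaults to the deepest admissible level.
#' @param pad padding specification, see [embed_lattice()].
#' @return list of class \code{"wavelet_varcov"}: \code{variance} (levels x
#'   variables), \code{covariance} (levels x covariates, response paired
#'   with each covariate), \code{smooth_energy} per variable.
#' @export
wavelet_varcov <- function(formula, data, coord, wavelet = "d4",
                           wtrafo = "modwt", max_level = NULL,
                           pad = list(padform = "mean", padzone = 1)) {
  vars <- stats::get_all_vars(formula, data)
  coord <- check_coords(coord, nrow(vars))
  fr0 <- embed_lattice(scale(vars[[1L]], scale = FALSE)[, 1L], coord, pad)
  side <- nrow(fr0$matrix)
  if (is.null(max_level)) max_level <- max_wave_level(side, wavelet, wtrafo)
  ncell <- side^2
  pyrs <- lapply(vars, function(v) {
    fr <- embed_lattice(v - mean(v), coord, pad)
    wave_pyramid(fr$matrix, max_level, wavelet, wtrafo)
  })
  lev_energy <- function(p1, p2) vapply(seq_len(max_level), function(j)
    (sum(p1$sub[[j]]$lh * p2$sub[[j]]$lh) +
     sum(p1$sub[[j]]$hl * p2$sub[[j]]$hl) +
     sum(p1$sub[[j]]$hh * p2$sub[[j]]$hh)) / ncell, numeric(1))
  variance <- sapply(pyrs, function(p) lev_energy(p, p))
  variance <- matrix(variance, nrow = max_level,
                     dimnames = list(level = seq_len(max_level),
                                     names(vars)))
  covariance <- NULL
  if (length(vars) > 1L) {
    covariance <- sapply(pyrs[-1L], function(p) lev_energy(pyrs[[1L]], p))
    covariance <- matrix(covariance, nrow = max_level,
                         dimnames = list(level = seq_len(max_level),
                                         names(vars)[-1L]))
  }
  smooth_energy <- vapply(pyrs, function(p) sum(p$ll^2) / ncell, numeric(1))
  structure(list(variance = variance, covariance = covariance,
                 smooth_energy = smooth_energy, wavelet = wavelet,
                 wtrafo = wtrafo, max_level = max_level, n_cells = ncell),
            class = "wavelet_varcov")
}
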
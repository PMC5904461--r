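#' @keywords internal
"_PACKAGE"

## Shared input checks ------------------------------------------------------

# Coordinates are integer cell indices on a regular lattice, one observation
# per cell. Returned as a 2-column integer matrix (x, y).
check_coords <- function(coord, n = NULL) {
  coord <- as.matrix(coord)
  if (ncol(coord) != 2L)
    stop("'coord' must have two columns (x, y)", call. = FALSE)
  if (!is.numeric(coord) || anyNA(coord))
    stop("'coord' must be numeric and free of missing values", call. = FALSE)
  if (max(abs(coord - round(coord))) > 1e-8)
    stop("coordinates must be integer grid-cell indices", call. = FALSE)
  coord <- round(coord)
  if (anyDuplicated(paste(coord[, 1L], coord[, 2L])))
    stop("duplicate coordinates: one observation per grid cell is required",
         call. = FALSE)
  if (!is.null(n) && nrow(coord) != n)
    stop("'coord' and data lengths differ", call. = FALSE)
  storage.mode(coord) <- "integer"
  colnames(coord) <- c("x", "y")
  coord
}

check_pad <- function(pad) {
  padform <- pad$padform %||% "mean"
  padzone <- pad$padzone %||% 1
  padform <- match.arg(padform, c("mean", "zeros", "mirror"))
  if (!is.numeric(padzone) || length(padzone) != 1L || padzone < 1)
    stop("'padzone' must be a single number >= 1", call. = FALSE)
  list(padform = padform, padzone = padzone)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## GLM family plumbing ------------------------------------------------------

# Canonical-link families only: identity / logit / log.
get_family <- function(family) {
  if (inherits(family, "family")) {
    fam <- family
  } else {
    family <- match.arg(family, c("gaussian", "binomial", "poisson"))
    fam <- switch(family,
                  gaussian = stats::gaussian(),
                  binomial = stats::binomial(),
                  poisson  = stats::poisson())
  }
  if (!fam$family %in% c("gaussian", "binomial", "poisson"))
    stop("family must be gaussian, binomial or poisson", call. = FALSE)
  fam
}

check_response <- function(y, fam) {
  if (fam$family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial responses must be coded 0/1", call. = FALSE)
  if (fam$family == "poisson" &&
      (any(y < 0) || max(abs(y - round(y))) > 1e-8))
    stop("poisson responses must be non-negative counts", call. = FALSE)
  invisible(y)
}

# Design matrix + response from a formula, with a rank check that names the
# offending columns instead of silently aliasing them.
build_design <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(y = as.numeric(y), X = X, terms = attr(mf, "terms"))
}
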
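## Embedding scattered lattice observations into padded dyadic squares.
##
## Wavelet transforms need a 2^J x 2^J matrix, so observations indexed by
## integer cell coordinates are placed into the smallest dyadic square that
## holds padzone times the bounding box, and the remaining cells are filled
## with a predefined value (zeros, the mean, or mirror-reflected values at
## the boundaries).

#' Embed lattice observations in a padded dyadic square matrix
#'
#' Places one variable, observed at integer grid-cell coordinates, into the
#' smallest \eqn{2^J \times 2^J} matrix whose side is at least
#' \code{padzone} times the larger coordinate extent.  Cells without an
#' observation are filled according to \code{padform}: \code{"zeros"},
#' \code{"mean"} (mean of the observed values) or \code{"mirror"}
#' (reflection of the observed bounding box outward, boundaries acting like
#' mirrors).  Unobserved cells \emph{inside} the bounding box are always
#' filled with the pad value, never interpolated.
#'
#' @param values numeric vector of observations.
#' @param coord two-column matrix or data frame of integer cell coordinates
#'   (x, y); one observation per cell.
#' @param pad list with elements \code{padform} (one of \code{"mean"},
#'   \code{"zeros"}, \code{"mirror"}; default \code{"mean"}) and
#'   \code{padzone} (expansion factor \eqn{\ge 1} for the padding frame).
#' @return An object of class \code{"lattice_frame"}: a list with the square
#'   \code{matrix}, the \code{index_map} (row/column of each observation),
#'   the dyadic level \code{J} and the coordinate \code{origin}.
#' @examples
#' fr <- embed_lattice(1:4, cbind(c(1, 1, 2, 2), c(1, 2, 1, 2)),
#'                     pad = list(padform = "zeros", padzone = 1))
#' fr$matrix
#' all.equal(extract_lattice(fr), 1:4)
#' @export
embed_lattice <- function(values, coord,
                          pad = list(padform = "mean", padzone = 1)) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite", call. = FALSE)
  coord <- check_coords(coord, length(values))
  pad <- check_pad(pad)
  origin <- c(min(coord[, 1L]), min(coord[, 2L]))
  cols0 <- coord[, 1L] - origin[1L] + 1L   # x -> columns
  rows0 <- coord[, 2L] - origin[2L] + 1L   # y -> rows, increasing y
  ext <- c(max(cols0), max(rows0))
  side_needed <- ceiling(pad$padzone * max(ext))
  J <- max(0L, ceiling(log2(side_needed)))
  side <- 2L^J

  fill <- switch(pad$padform,
                 zeros = 0,
                 mean = mean(values),
                 mirror = mean(values))  # interior holes under mirror
  m <- matrix(fill, nrow = side, ncol = side)
  m[cbind(rows0, cols0)] <- values

  if (pad$padform == "mirror") {
    # reflect the observed bounding box outward (half-sample symmetric);
    # interior holes keep the mean fill set above
    er <- max(rows0); ec <- max(cols0)
    core <- m[seq_len(er), seq_len(ec), drop = FALSE]
    ridx <- mirror_index(seq_len(side), er)
    cidx <- mirror_index(seq_len(side), ec)
    m <- core[ridx, cidx, drop = FALSE]
    m[cbind(rows0, cols0)] <- values  # padding never alters observed cells
  }

  structure(list(matrix = m,
                 index_map = cbind(row = rows0, col = cols0),
                 J = J, origin = origin, n = length(values),
                 pad = pad),
            class = "lattice_frame")
}

# half-sample symmetric reflection of 1..e onto arbitrary indices
mirror_index <- function(i, e) {
  k <- (i - 1L) %% (2L * e)
  ifelse(k < e, k + 1L, 2L * e - k)
}

#' Extract observed values from a lattice frame
#'
#' Inverse of [embed_lattice()]: returns the observation values in their
#' original record order, untouched by any padding.
#'
#' @param frame a \code{"lattice_frame"} object.
#' @return numeric vector of length \code{frame$n}.
#' @export
extract_lattice <- function(frame) {
  if (!inherits(frame, "lattice_frame"))
    stop("'frame' must be a lattice_frame", call. = FALSE)
  if (is.null(frame$index_map) || nrow(frame$index_map) == 0L)
    stop("frame has an empty index map", call. = FALSE)
  frame$matrix[frame$index_map]
}

#' Render a variable at a coarser dyadic resolution
#'
#' Embeds a gridded variable in a dyadic square and returns the smooth
#' (slowly varying) component of its 2-D wavelet decomposition at the given
#' level, reconstructed on the full grid.  \code{scale = 0} returns the raw
#' embedded matrix.  Upscaling can be pictured as a gradual two-dimensional
#' enlargement of the cell size.
#'
#' @inheritParams embed_lattice
#' @param f numeric vector of the variable to upscale.
#' @param scale non-negative integer resolution level (0 = raw data).
#' @param wavelet \code{"haar"} or \code{"d4"}.
#' @param wtrafo \code{"dwt"} or \code{"modwt"}.
#' @param plot if \code{TRUE}, draw the matrix as a grey-scale image
#'   (values increasing black to white).
#' @return the \eqn{2^J \times 2^J} matrix of the smooth component
#'   (invisibly when \code{plot = TRUE}).
#' @export
upscale <- function(f, coord, scale = 0, wavelet = "haar", wtrafo = "dwt",
                    pad = list(padform = "mean", padzone = 1), plot = FALSE) {
  fr <- embed_lattice(f, coord, pad)
  if (scale < 0 || scale != round(scale))
    stop("'scale' must be a non-negative integer", call. = FALSE)
  if (scale > fr$J)
    stop("'scale' exceeds the dyadic depth J = ", fr$J, call. = FALSE)
  out <- if (scale == 0) fr$matrix else
    smooth2d(fr$matrix, level = scale, wavelet = wavelet, wtrafo = wtrafo)
  if (plot) {
    graphics::image(t(out), col = grDevices::grey.colors(64, 0, 1), axes = FALSE,
                    main = paste("level", scale))
    return(invisible(out))
  }
  out
}
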
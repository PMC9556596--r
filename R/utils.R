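## Internal helpers shared across modules.
##
## Image convention used throughout the package: a frame is a numeric matrix
## with dim = c(height, width); rows index y (downwards), columns index x
## (rightwards). Coordinates inside R are 1-based (x = column, y = row);
## all JSON interchange is 0-based, x rightward, y downward.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round to the nearest odd integer (at least 1)
#' @param x numeric
#' @return integer vector of odd values
#' @keywords internal
round_to_odd <- function(x) {
  lo <- 2L * as.integer(floor((x - 1) / 2)) + 1L
  hi <- lo + 2L
  out <- ifelse(abs(x - lo) <= abs(hi - x), lo, hi)
  pmax(out, 1L)
}

## Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Pixel-centre coordinate grids for an H x W image.
coord_grids <- function(h, w) {
  list(x = matrix(rep(seq_len(w), each = h), h, w),
       y = matrix(rep(seq_len(h), times = w), h, w))
}

## Vectorised bilinear sampling of img (H x W) at fractional coordinates
## (xs, ys), 1-based. Out-of-domain samples return `fill` (scalar or vector
## recycled to length(xs)).
bilinear_sample <- function(img, xs, ys, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  out <- rep_len(fill, length(xs))
  ok <- xs >= 1 & xs <= w & ys >= 1 & ys <= h & is.finite(xs) & is.finite(ys)
  if (!any(ok)) return(out)
  x <- xs[ok]; y <- ys[ok]
  x0 <- pmin(floor(x), w - 1); x0 <- pmax(x0, 1)
  y0 <- pmin(floor(y), h - 1); y0 <- pmax(y0, 1)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * h + y0
  v <- (1 - fx) * (1 - fy) * img[i00] +
       fx       * (1 - fy) * img[i00 + h] +
       (1 - fx) * fy       * img[i00 + 1] +
       fx       * fy       * img[i00 + h + 1]
  out[ok] <- v
  out
}

## Polyline length in pixels: sum of Euclidean steps between consecutive
## vertices of an n x 2 matrix (x, y). Single vertex => 0.
polyline_length_px <- function(coords) {
  if (is.null(coords) || nrow(coords) < 2) return(0)
  d <- diff(coords)
  sum(sqrt(rowSums(d^2)))
}

## Run-length encode a logical matrix for JSON interchange (column-major).
mask_to_rle <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), values = as.integer(r$values), lengths = r$lengths)
}

rle_to_mask <- function(x) {
  v <- inverse.rle(list(values = as.logical(x$values),
                        lengths = as.integer(x$lengths)))
  matrix(v, nrow = x$dim[1], ncol = x$dim[2])
}

#' Centroid of a logical mask
#'
#' @param mask logical matrix.
#' @return numeric pair `c(x, y)` in 1-based pixel units.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) stop("cannot take the centroid of an empty mask")
  h <- nrow(mask)
  y <- ((idx - 1) %% h) + 1
  x <- ((idx - 1) %/% h) + 1
  c(mean(x), mean(y))
}

## Rasterise a segment between two points with ~1 px steps (includes both
## endpoints); returns an n x 2 matrix of unique integer (x, y) pixels.
raster_line <- function(p0, p1) {
  n <- max(2, ceiling(max(abs(p1 - p0))) + 1)
  t <- seq(0, 1, length.out = n)
  xy <- cbind(round(p0[1] + t * (p1[1] - p0[1])),
              round(p0[2] + t * (p1[2] - p0[2])))
  xy[!duplicated(xy), , drop = FALSE]
}

## Normalised 1-D Gaussian weights at the given offsets.
gaussian_weights <- function(offsets, sigma) {
  w <- exp(-offsets^2 / (2 * sigma^2))
  w / sum(w)
}

## Signed area of a closed polygon (x, y with y pointing down). Positive for
## screen-clockwise orbits.
polygon_signed_area <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name))
  invisible(x)
}
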
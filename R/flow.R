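## PIV actin-flow pipeline: windowed zero-normalised cross-correlation
## displacement estimation, correlation-threshold filtering, masked
## Gaussian spatial interpolation, temporal smoothing, divergence by
## central differences, retrograde/anterograde classification and
## region-wise flow summaries.

#' PIV configuration
#'
#' Window sizes are given as physical areas and converted to the nearest
#' odd pixel side (`side = round_to_odd(sqrt(area) / pixel_size)`); the
#' search margin is split symmetrically around the source window. The
#' defaults are the standard operating point of the method: source and
#' search areas of 1.4 and 2.4 square micrometres, a cross-correlation
#' cut-off c0 of 0.5, a spatial Gaussian of size 6 um (sigma 1.2 um) and a
#' temporal Gaussian of length 20 s (sigma 10 s).
#'
#' @param pixel_size_um pixel edge in micrometres.
#' @param frame_interval_s frame interval in seconds.
#' @param source_area_um2 source-window area (default 1.4).
#' @param search_area_um2 search-window area (default 2.4); must convert to
#'   a strictly larger pixel window than the source.
#' @param corr_threshold_c0 minimum kept cross-correlation coefficient,
#'   in (0, 1) (default 0.5).
#' @param spatial_kernel_um,spatial_sigma_um spatial interpolation kernel
#'   size and sigma (defaults 6 and 1.2 um).
#' @param temporal_kernel_s,temporal_sigma_s temporal smoothing kernel
#'   length and sigma (defaults 20 and 10 s).
#' @param grid_stride_px spacing of source-window centres (default: the
#'   source window side).
#' @param subpixel logical; apply 3-point parabolic refinement of the
#'   integer argmax (off by default).
#' @param source_side_px,search_side_px explicit odd pixel sides,
#'   overriding the area conversion (for tests and large-displacement
#'   fixtures).
#' @return an object of class `piv_config`.
#' @export
piv_config <- function(pixel_size_um, frame_interval_s,
                       source_area_um2 = 1.4, search_area_um2 = 2.4,
                       corr_threshold_c0 = 0.5,
                       spatial_kernel_um = 6, spatial_sigma_um = 1.2,
                       temporal_kernel_s = 20, temporal_sigma_s = 10,
                       grid_stride_px = NULL, subpixel = FALSE,
                       source_side_px = NULL, search_side_px = NULL) {
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  if (corr_threshold_c0 <= 0 || corr_threshold_c0 >= 1)
    stop("'corr_threshold_c0' must lie in (0, 1)")
  src <- as.integer(source_side_px %||%
                      round_to_odd(sqrt(source_area_um2) / pixel_size_um))
  sea <- as.integer(search_side_px %||%
                      round_to_odd(sqrt(search_area_um2) / pixel_size_um))
  if (sea <= src)
    stop("search window must strictly contain the source window")
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 source_area_um2 = source_area_um2,
                 search_area_um2 = search_area_um2,
                 corr_threshold_c0 = corr_threshold_c0,
                 spatial_kernel_um = spatial_kernel_um,
                 spatial_sigma_um = spatial_sigma_um,
                 temporal_kernel_s = temporal_kernel_s,
                 temporal_sigma_s = temporal_sigma_s,
                 source_side_px = src, search_side_px = sea,
                 margin_px = (sea - src) %/% 2L,
                 grid_stride_px = as.integer(grid_stride_px %||% src),
                 subpixel = isTRUE(subpixel)),
            class = "piv_config")
}

#' @export
print.piv_config <- function(x, ...) {
  cat(sprintf(
    "piv_config: source %d px, search %d px (margin %d), c0 %.2f, stride %d\n",
    x$source_side_px, x$search_side_px, x$margin_px, x$corr_threshold_c0,
    x$grid_stride_px))
  cat(sprintf("  spatial kernel %g um (sigma %g), temporal %g s (sigma %g)\n",
              x$spatial_kernel_um, x$spatial_sigma_um, x$temporal_kernel_s,
              x$temporal_sigma_s))
  invisible(x)
}

#' Dense per-pixel velocity field
#'
#' @param u,v velocity component matrices (um/min; u along x, v along y).
#' @param valid logical matrix marking pixels with a defined velocity.
#' @param corr optional per-pixel correlation coefficients.
#' @param frame_index index of the first frame of the pair.
#' @return an object of class `flow_field`.
#' @export
flow_field <- function(u, v, valid, corr = NULL, frame_index = 1L) {
  stopifnot(all(dim(u) == dim(v)), all(dim(u) == dim(valid)))
  if (any(!is.finite(u[valid])) || any(!is.finite(v[valid])))
    stop("velocities must be finite where valid")
  structure(list(u = u, v = v, valid = valid, corr = corr,
                 frame_index = as.integer(frame_index)),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  sp <- sqrt(x$u[x$valid]^2 + x$v[x$valid]^2)
  cat(sprintf(
    "flow_field (frame %d): %d/%d px valid, mean speed %.3g um/min\n",
    x$frame_index, sum(x$valid), length(x$valid),
    if (length(sp)) mean(sp) else NA))
  invisible(x)
}

## Zero-normalised (Pearson) cross-correlation of two equally sized patches.
.zncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

#' Sparse PIV displacement estimates for one frame pair
#'
#' On a regular grid of source-window centres inside the cell mask, the
#' source patch of `frame_t` is compared against every integer shift that
#' keeps it inside the search patch of `frame_t1`; the displacement is the
#' shift maximising the zero-normalised cross-correlation coefficient.
#' Argmax ties are broken by the smallest displacement magnitude, then
#' lexicographically by (dy, dx). Estimates with a maximum coefficient at
#' or below `c0` are discarded. Velocities are returned in um/min.
#'
#' @param frame_t,frame_t1 consecutive frames (numeric matrices, same
#'   shape).
#' @param cell_mask logical matrix; only grid centres inside it are used.
#' @param cfg a [piv_config()].
#' @return data.frame with columns `x`, `y` (grid centre, px), `dx_px`,
#'   `dy_px` (displacement, px/frame), `u`, `v` (um/min), `corr`.
#' @export
piv_frame_pair <- function(frame_t, frame_t1, cell_mask, cfg) {
  stopifnot(inherits(cfg, "piv_config"), is.matrix(frame_t))
  if (!all(dim(frame_t) == dim(frame_t1)))
    stop("frames must have the same shape")
  if (!any(cell_mask)) stop("empty cell mask")
  h <- nrow(frame_t); w <- ncol(frame_t)
  hs <- cfg$source_side_px %/% 2L
  m <- cfg$margin_px
  lo <- 1L + hs + m
  if (lo > w - hs - m || lo > h - hs - m)
    stop("search window larger than the image")
  xs <- seq.int(lo, w - hs - m, by = cfg$grid_stride_px)
  ys <- seq.int(lo, h - hs - m, by = cfg$grid_stride_px)
  shifts <- expand.grid(dx = -m:m, dy = -m:m)
  shifts <- shifts[order(shifts$dx^2 + shifts$dy^2, shifts$dy, shifts$dx), ]
  scale <- cfg$pixel_size_um * 60 / cfg$frame_interval_s
  res <- list()
  for (cy in ys) for (cx in xs) {
    if (!cell_mask[cy, cx]) next
    src <- frame_t[(cy - hs):(cy + hs), (cx - hs):(cx + hs)]
    best <- -Inf; bdx <- 0L; bdy <- 0L
    cmap <- numeric(nrow(shifts))
    for (k in seq_len(nrow(shifts))) {
      dx <- shifts$dx[k]; dy <- shifts$dy[k]
      tgt <- frame_t1[(cy + dy - hs):(cy + dy + hs),
                      (cx + dx - hs):(cx + dx + hs)]
      cc <- .zncc(src, tgt)
      cmap[k] <- if (is.na(cc)) -Inf else cc
      if (cmap[k] > best) { best <- cmap[k]; bdx <- dx; bdy <- dy }
    }
    if (!is.finite(best) || best <= cfg$corr_threshold_c0) next
    ddx <- as.numeric(bdx); ddy <- as.numeric(bdy)
    if (cfg$subpixel) {
      sub1 <- function(cm1, c0, cp1) {
        den <- cm1 - 2 * c0 + cp1
        if (!is.finite(den) || den >= 0) 0 else 0.5 * (cm1 - cp1) / den
      }
      getc <- function(dx, dy) {
        k <- which(shifts$dx == dx & shifts$dy == dy)
        if (length(k) == 1) cmap[k] else NA_real_
      }
      if (abs(bdx) < m) ddx <- bdx + sub1(getc(bdx - 1L, bdy), best,
                                          getc(bdx + 1L, bdy))
      if (abs(bdy) < m) ddy <- bdy + sub1(getc(bdx, bdy - 1L), best,
                                          getc(bdx, bdy + 1L))
    }
    res[[length(res) + 1]] <- data.frame(
      x = cx, y = cy, dx_px = ddx, dy_px = ddy,
      u = ddx * scale, v = ddy * scale, corr = best)
  }
  if (length(res) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), dx_px = numeric(0),
                      dy_px = numeric(0), u = numeric(0), v = numeric(0),
                      corr = numeric(0)))
  do.call(rbind, res)
}

#' Interpolate sparse PIV estimates to a dense in-mask field
#'
#' Normalised Gaussian-weighted average of the kept estimates at every
#' in-mask pixel; weights are renormalised over the available estimates and
#' the kernel is truncated at the stated size (radius = size / 2). Pixels
#' farther than the kernel radius from every estimate are flagged invalid.
#' Zero kept estimates yield an all-invalid field, not an error.
#'
#' @param estimates data.frame from [piv_frame_pair()].
#' @param cell_mask logical matrix.
#' @param cfg a [piv_config()].
#' @param frame_index frame index stored in the result.
#' @return a [flow_field()].
#' @export
interpolate_dense <- function(estimates, cell_mask, cfg, frame_index = 1L) {
  stopifnot(inherits(cfg, "piv_config"))
  h <- nrow(cell_mask); w <- ncol(cell_mask)
  U <- matrix(0, h, w); V <- matrix(0, h, w)
  W <- matrix(0, h, w); C <- matrix(0, h, w)
  radius <- cfg$spatial_kernel_um / 2 / cfg$pixel_size_um
  sigma <- cfg$spatial_sigma_um / cfg$pixel_size_um
  r <- ceiling(radius)
  if (nrow(estimates) > 0) {
    off <- expand.grid(dx = -r:r, dy = -r:r)
    off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
    wk <- exp(-(off$dx^2 + off$dy^2) / (2 * sigma^2))
    for (i in seq_len(nrow(estimates))) {
      x <- estimates$x[i] + off$dx; y <- estimates$y[i] + off$dy
      ok <- x >= 1 & x <= w & y >= 1 & y <= h
      ij <- cbind(y[ok], x[ok])
      U[ij] <- U[ij] + wk[ok] * estimates$u[i]
      V[ij] <- V[ij] + wk[ok] * estimates$v[i]
      C[ij] <- C[ij] + wk[ok] * estimates$corr[i]
      W[ij] <- W[ij] + wk[ok]
    }
  }
  valid <- W > 0 & cell_mask
  U[valid] <- U[valid] / W[valid]; U[!valid] <- 0
  V[valid] <- V[valid] / W[valid]; V[!valid] <- 0
  C[valid] <- C[valid] / W[valid]; C[!valid] <- 0
  flow_field(U, V, valid, corr = C, frame_index = frame_index)
}

#' Temporal Gaussian smoothing of a flow-field series
#'
#' Per-pixel Gaussian convolution over time with the configured kernel
#' length and sigma, renormalised at the series ends; invalid samples are
#' excluded from the weight sum. A pixel is valid in the output if any
#' contributing frame was valid there.
#'
#' @param field_series list of [flow_field()]s at uniform spacing.
#' @param cfg a [piv_config()].
#' @return list of smoothed [flow_field()]s, same length.
#' @export
temporal_smooth <- function(field_series, cfg) {
  stopifnot(inherits(cfg, "piv_config"))
  n <- length(field_series)
  if (n <= 1) return(field_series)
  dt <- cfg$frame_interval_s
  kmax <- floor(cfg$temporal_kernel_s / 2 / dt)
  offs <- -kmax:kmax
  wts <- exp(-(offs * dt)^2 / (2 * cfg$temporal_sigma_s^2))
  out <- vector("list", n)
  for (t in seq_len(n)) {
    U <- 0 * field_series[[t]]$u; V <- U; W <- U
    for (j in seq_along(offs)) {
      s <- t + offs[j]
      if (s < 1 || s > n) next
      f <- field_series[[s]]
      U <- U + wts[j] * f$u * f$valid
      V <- V + wts[j] * f$v * f$valid
      W <- W + wts[j] * f$valid
    }
    valid <- W > 0
    U[valid] <- U[valid] / W[valid]
    V[valid] <- V[valid] / W[valid]
    out[[t]] <- flow_field(U, V, valid, corr = field_series[[t]]$corr,
                           frame_index = field_series[[t]]$frame_index)
  }
  out
}

#' Divergence of a flow field by central differences
#'
#' `div = (u[x+1] - u[x-1]) / (2 dx) + (v[y+1] - v[y-1]) / (2 dy)`,
#' defined only where all four axis neighbours are valid. With velocities
#' in um/min and the pixel size in um the divergence is in 1/min.
#'
#' @param field a [flow_field()].
#' @param pixel_size_um pixel calibration.
#' @return an object of class `divergence_map` with elements `div`
#'   (numeric matrix, 0 where undefined) and `valid`.
#' @export
flow_divergence <- function(field, pixel_size_um) {
  stopifnot(inherits(field, "flow_field"))
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  h <- nrow(field$u); w <- ncol(field$u)
  div <- matrix(0, h, w)
  valid <- matrix(FALSE, h, w)
  ix <- 2:(w - 1); iy <- 2:(h - 1)
  vv <- field$valid
  ok <- vv[iy, ix - 1] & vv[iy, ix + 1] & vv[iy - 1, ix] & vv[iy + 1, ix]
  dudx <- (field$u[iy, ix + 1] - field$u[iy, ix - 1]) / (2 * pixel_size_um)
  dvdy <- (field$v[iy + 1, ix] - field$v[iy - 1, ix]) / (2 * pixel_size_um)
  d <- dudx + dvdy
  d[!ok] <- 0
  div[iy, ix] <- d
  valid[iy, ix] <- ok
  structure(list(div = div, valid = valid,
                 frame_index = field$frame_index),
            class = "divergence_map")
}

#' @export
print.divergence_map <- function(x, ...) {
  cat(sprintf("divergence_map (frame %d): %d valid px, mean %.3g /min\n",
              x$frame_index, sum(x$valid),
              if (any(x$valid)) mean(x$div[x$valid]) else NA))
  invisible(x)
}

#' Classify flow direction relative to cell motion
#'
#' A flow vector correlates with the instantaneous motion direction by the
#' cosine of the angle between them: negative cosine = retrograde,
#' positive = anterograde; zero-magnitude flow or an exactly perpendicular
#' vector is unclassified.
#'
#' @param field a [flow_field()].
#' @param motion_vector nonzero motion vector (um/min pair).
#' @return character matrix with entries `"retrograde"`, `"anterograde"`,
#'   `"unclassified"` (invalid pixels are `NA`).
#' @export
classify_direction <- function(field, motion_vector) {
  stopifnot(inherits(field, "flow_field"))
  if (sqrt(sum(motion_vector^2)) == 0) stop("motion vector is zero")
  dot <- field$u * motion_vector[1] + field$v * motion_vector[2]
  out <- matrix(NA_character_, nrow(field$u), ncol(field$u))
  out[field$valid] <- "unclassified"
  out[field$valid & dot < 0] <- "retrograde"
  out[field$valid & dot > 0] <- "anterograde"
  out
}

#' Default "strong flow" speed threshold
#'
#' Half of the 95th percentile of the valid in-mask flow speeds of the
#' whole movie.
#'
#' @param field_series list of [flow_field()]s.
#' @return speed threshold in um/min.
#' @export
strong_flow_threshold <- function(field_series) {
  sp <- unlist(lapply(field_series, function(f)
    sqrt(f$u[f$valid]^2 + f$v[f$valid]^2)))
  if (length(sp) == 0) return(Inf)
  0.5 * stats::quantile(sp, 0.95, names = FALSE)
}

#' Occurrence of strong actin flows per region class
#'
#' For every frame and region class, the fraction of region pixels whose
#' valid flow speed reaches the threshold; frame fractions are then
#' averaged within 1-minute bins.
#'
#' @param field_series list of [flow_field()]s.
#' @param regions a [region_set()].
#' @param frame_interval_s frame interval in seconds.
#' @param strong_speed_threshold_um_per_min speed cut-off; default
#'   [strong_flow_threshold()] of the series (recorded in the output).
#' @return list with `per_frame` (data.frame: frame, region, fraction),
#'   `per_minute` (data.frame: minute, region, fraction) and `threshold`.
#' @export
flow_occurrence <- function(field_series, regions, frame_interval_s,
                            strong_speed_threshold_um_per_min = NULL) {
  stopifnot(inherits(regions, "region_set"))
  thr <- strong_speed_threshold_um_per_min %||%
    strong_flow_threshold(field_series)
  masks <- region_masks(regions)
  classes <- list(cables = masks$cables, protrusions = masks$protrusions)
  rows <- list()
  for (t in seq_along(field_series)) {
    f <- field_series[[t]]
    sp <- sqrt(f$u^2 + f$v^2)
    for (nm in names(classes)) {
      m <- classes[[nm]]
      if (!any(m)) next   # empty region class: absent, not zero
      frac <- sum(f$valid[m] & sp[m] >= thr) / sum(m)
      rows[[length(rows) + 1]] <- data.frame(frame = t, region = nm,
                                             fraction = frac)
    }
  }
  per_frame <- if (length(rows)) do.call(rbind, rows)
               else data.frame(frame = integer(0), region = character(0),
                               fraction = numeric(0))
  if (nrow(per_frame)) {
    minute <- floor((per_frame$frame - 1) * frame_interval_s / 60)
    per_minute <- stats::aggregate(fraction ~ minute + region,
                                   cbind(per_frame, minute = minute), mean)
  } else per_minute <- data.frame(minute = integer(0), region = character(0),
                                  fraction = numeric(0))
  list(per_frame = per_frame, per_minute = per_minute, threshold = thr)
}

#' Rose histogram of flow angles relative to a protrusion axis
#'
#' Angles are measured in a frame where the protrusion axis maps to 90
#' degrees (anterograde, out of the cell) and its opposite to 270 degrees
#' (retrograde); zero vectors are excluded. Bins are `[lo, hi)` over
#' `[0, 360)`.
#'
#' @param field a [flow_field()].
#' @param region_mask logical matrix restricting the pixels counted.
#' @param protrusion_axis nonzero axis vector (pointing out of the cell).
#' @param bins number of angular bins (default 24).
#' @return list with `counts` (length `bins`) and `breaks_deg`
#'   (length `bins + 1`).
#' @export
angle_histogram <- function(field, region_mask, protrusion_axis, bins = 24) {
  stopifnot(inherits(field, "flow_field"))
  if (sqrt(sum(protrusion_axis^2)) == 0) stop("protrusion axis is zero")
  a <- protrusion_axis / sqrt(sum(protrusion_axis^2))
  sel <- field$valid & region_mask
  u <- field$u[sel]; v <- field$v[sel]
  nz <- (u^2 + v^2) > 0
  u <- u[nz]; v <- v[nz]
  breaks <- seq(0, 360, length.out = bins + 1)
  if (length(u) == 0)
    return(list(counts = integer(bins), breaks_deg = breaks))
  dot <- u * a[1] + v * a[2]
  crs <- u * a[2] - v * a[1]   # y points down; sign chosen so that the
                               # angle increases counter-clockwise on screen
  ang <- (90 + atan2(crs, dot) * 180 / pi) %% 360
  bin <- pmin(findInterval(ang, breaks, rightmost.closed = FALSE), bins)
  list(counts = tabulate(bin, nbins = bins), breaks_deg = breaks)
}

#' Correlation between actin network sinks and a second channel
#'
#' Spearman rank correlation between the per-frame mean negative
#' divergence over cable pixels and the per-frame mean second-channel
#' (e.g. myosin) intensity over the same pixels.
#'
#' @param div_series list of `divergence_map`s.
#' @param second_channel_series list of matrices (same length).
#' @param cable_mask logical matrix.
#' @return list with `rho`, `n` and `defined` (FALSE when a series is
#'   constant and the rank correlation is undefined).
#' @export
sink_signal_correlation <- function(div_series, second_channel_series,
                                    cable_mask) {
  n <- length(div_series)
  if (n != length(second_channel_series) || n < 3)
    stop("need two series of equal length >= 3")
  x <- vapply(div_series, function(d) {
    m <- cable_mask & d$valid
    if (!any(m)) NA_real_ else mean(-d$div[m])
  }, 0)
  y <- vapply(second_channel_series, function(fr) mean(fr[cable_mask]), 0)
  if (anyNA(x) || anyNA(y)) stop("divergence undefined on the cable mask")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, n = n, defined = FALSE))
  list(rho = stats::cor(x, y, method = "spearman"), n = n, defined = TRUE)
}
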
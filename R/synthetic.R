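## Synthetic border-cell clusters with exact ground truth.
##
## The generator emulates a compact 6-10 cell cluster as imaged in a single
## confocal plane after background subtraction: a disk-shaped main body rimmed
## by a bright supracellular actin cable (with controllable dim gaps),
## finger-like protrusions, radial cell-cell contact lines, multiplicative
## speckle texture advected by a prescribed flow field, whole-group drift,
## exponential photobleaching and additive Gaussian noise. Every quantity the
## downstream pipeline measures is known exactly by construction.

.default_region_intensity <- function() {
  list(background = 0, body = 110, cable = 200, protrusion = 150,
       contact = 130, gap = 30)
}

.default_myosin_intensity <- function() {
  list(background = 0, body = 40, cable = 240, protrusion = 20,
       contact = 60, gap = 20)
}

#' Specification of a synthetic border-cell time-lapse
#'
#' Collects every parameter of the synthetic generator. Identical specs
#' (including `seed`) produce bit-identical images and ground truth.
#'
#' @param image_size_px integer pair `c(width, height)`.
#' @param pixel_size_um pixel edge in micrometres (default 0.2, a typical
#'   confocal sampling for a 63x objective).
#' @param frame_interval_s frame interval in seconds (default 10).
#' @param n_frames number of frames (>= 1).
#' @param n_cells number of border cells arranged around the cluster centre.
#' @param cluster_radius_um radius of the main body disk in micrometres.
#' @param protrusions data frame (or list coercible to one) with columns
#'   `base_angle_deg`, `length_um`, `width_um`; one row per finger-like
#'   protrusion (0 rows for none). Angles are measured in image coordinates
#'   (x rightward, y downward, clockwise on screen).
#' @param cable_gap_fraction fraction of the rim length occupied by broken
#'   cable sections, in \[0, 1\].
#' @param region_intensity named list of base fluorescence levels (arbitrary
#'   counts) for `background`, `body`, `cable`, `protrusion`, `contact` and
#'   `gap` (the dim level inside broken sections). Missing entries take the
#'   defaults.
#' @param flow_model one of `"none"`, `"translation"`, `"retrograde"`,
#'   `"centripetal"`, `"sink"`.
#' @param flow_magnitude_um_per_min flow speed in micrometres per minute;
#'   for `"sink"` it is the rate constant k in 1/min of v(r) = -k r.
#' @param group_velocity_um_per_min numeric pair: rigid drift of the whole
#'   group, micrometres per minute.
#' @param bleach_tau_s photobleaching time constant in seconds, or `NULL`
#'   for no bleaching.
#' @param noise_sd standard deviation of additive Gaussian noise (counts).
#' @param channels character vector of channel names; `"actin"` and
#'   optionally `"myosin"` (a myosin-like channel enriched on the cable).
#' @param myosin_intensity like `region_intensity`, for the myosin channel.
#' @param seed integer seed driving all randomness of the generator.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size_px = c(160, 160),
                           pixel_size_um = 0.2,
                           frame_interval_s = 10,
                           n_frames = 3,
                           n_cells = 6,
                           cluster_radius_um = 7,
                           protrusions = data.frame(base_angle_deg = 0,
                                                    length_um = 4,
                                                    width_um = 2),
                           cable_gap_fraction = 0,
                           region_intensity = list(),
                           flow_model = c("none", "translation", "retrograde",
                                          "centripetal", "sink"),
                           flow_magnitude_um_per_min = 0,
                           group_velocity_um_per_min = c(0, 0),
                           bleach_tau_s = NULL,
                           noise_sd = 0,
                           channels = "actin",
                           myosin_intensity = list(),
                           seed = 1L) {
  flow_model <- match.arg(flow_model)
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  stopifnot_scalar_pos(cluster_radius_um, "cluster_radius_um")
  if (length(image_size_px) != 2 || any(image_size_px < 16))
    stop("'image_size_px' must be a pair of integers >= 16")
  if (n_frames < 1) stop("'n_frames' must be >= 1")
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  if (!is.numeric(cable_gap_fraction) || cable_gap_fraction < 0 ||
      cable_gap_fraction > 1)
    stop("'cable_gap_fraction' must lie in [0, 1]")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (!is.null(bleach_tau_s)) stopifnot_scalar_pos(bleach_tau_s, "bleach_tau_s")
  if (length(group_velocity_um_per_min) != 2)
    stop("'group_velocity_um_per_min' must be a pair")
  if (!all(channels %in% c("actin", "myosin")))
    stop("channels must be drawn from 'actin', 'myosin'")
  protrusions <- as.data.frame(protrusions)
  if (nrow(protrusions) > 0) {
    need <- c("base_angle_deg", "length_um", "width_um")
    if (!all(need %in% names(protrusions)))
      stop("'protrusions' needs columns base_angle_deg, length_um, width_um")
    if (any(protrusions$length_um <= 0) || any(protrusions$width_um <= 0))
      stop("protrusion lengths and widths must be positive")
  }
  ri <- utils::modifyList(.default_region_intensity(), region_intensity)
  mi <- utils::modifyList(.default_myosin_intensity(), myosin_intensity)
  if (any(unlist(ri) < 0) || any(unlist(mi) < 0))
    stop("region intensities must be nonnegative")
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 n_cells = as.integer(n_cells),
                 cluster_radius_um = cluster_radius_um,
                 protrusions = protrusions,
                 cable_gap_fraction = cable_gap_fraction,
                 region_intensity = ri,
                 myosin_intensity = mi,
                 flow_model = flow_model,
                 flow_magnitude_um_per_min = flow_magnitude_um_per_min,
                 group_velocity_um_per_min = as.numeric(group_velocity_um_per_min),
                 bleach_tau_s = bleach_tau_s,
                 noise_sd = noise_sd,
                 channels = channels,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: %dx%d px (%.3g um/px), %d frame(s) @ %.3g s, %d cells\n",
    x$image_size_px[1], x$image_size_px[2], x$pixel_size_um, x$n_frames,
    x$frame_interval_s, x$n_cells))
  cat(sprintf("  %d protrusion(s), gap fraction %.3g, flow %s (%.3g), seed %d\n",
              nrow(x$protrusions), x$cable_gap_fraction, x$flow_model,
              x$flow_magnitude_um_per_min, x$seed))
  invisible(x)
}

## Normalise an angle (deg) into [0, 360).
.wrap360 <- function(a) ((a %% 360) + 360) %% 360

## Is angle a (deg) inside the arc [lo, hi] (deg, possibly wrapping)?
.angle_in <- function(a, lo, hi) {
  a <- .wrap360(a - lo); hi <- .wrap360(hi - lo)
  a <= hi
}

## Deterministic placement of `n_gaps` equal gaps (total `total_deg`) on the
## circle, avoiding `forbidden` (list of c(lo, hi) arcs, deg). Returns a list
## of c(lo, hi) gap arcs. Greedy: each gap at the centre of the largest
## remaining free arc.
.place_gaps <- function(total_deg, n_gaps, forbidden) {
  if (n_gaps == 0 || total_deg <= 0) return(list())
  g <- total_deg / n_gaps
  ## complement of the forbidden arcs within [0, 360), splitting wrapping
  ## arcs and merging overlaps first
  iv <- list()
  for (f in forbidden) {
    s <- .wrap360(f[1]); len <- f[2] - f[1]
    if (s + len <= 360) iv[[length(iv) + 1]] <- c(s, s + len)
    else {
      iv[[length(iv) + 1]] <- c(s, 360)
      iv[[length(iv) + 1]] <- c(0, s + len - 360)
    }
  }
  if (length(iv) == 0) {
    free <- list(c(0, 360))
  } else {
    iv <- iv[order(vapply(iv, `[`, 0, 1))]
    merged <- list(iv[[1]])
    for (i in seq_along(iv)[-1]) {
      last <- merged[[length(merged)]]
      if (iv[[i]][1] <= last[2]) merged[[length(merged)]] <-
          c(last[1], max(last[2], iv[[i]][2]))
      else merged[[length(merged) + 1]] <- iv[[i]]
    }
    free <- list()
    cursor <- 0
    for (m in merged) {
      if (m[1] - cursor > 1e-9) free[[length(free) + 1]] <- c(cursor, m[1])
      cursor <- max(cursor, m[2])
    }
    if (360 - cursor > 1e-9) free[[length(free) + 1]] <- c(cursor, 360)
  }
  gaps <- list()
  for (k in seq_len(n_gaps)) {
    lens <- vapply(free, function(f) f[2] - f[1], 0)
    j <- which.max(lens)
    if (lens[j] < g + 4)
      stop("cannot place cable gaps: rim too crowded by protrusions/contacts")
    c0 <- (free[[j]][1] + free[[j]][2]) / 2
    gaps[[k]] <- c(c0 - g / 2, c0 + g / 2)
    left <- c(free[[j]][1], c0 - g / 2 - 2)
    right <- c(c0 + g / 2 + 2, free[[j]][2])
    free[[j]] <- NULL
    if (diff(left) > 0) free[[length(free) + 1]] <- left
    if (diff(right) > 0) free[[length(free) + 1]] <- right
  }
  gaps
}

#' Build the exact cluster geometry implied by a synthetic spec
#'
#' Constructs the body disk, protrusion masks, the closed cable rim
#' polyline partitioned into per-cell arcs with broken (gap) sections
#' totalling `cable_gap_fraction` of the rim length, radial contact
#' polylines from each inter-cell junction to the cluster centre, the
#' landmark set a human would have clicked (junction points in clockwise
#' order starting beside the leader protrusion, plus contact endpoints),
#' and the true morphometrics of the rasterised geometry.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `ground_truth` with elements `spec`,
#'   `region_set`, `landmarks`, `true_metrics`, `centroid_series_um`,
#'   `bleach_curve`, plus internal geometry (`centre_px`, `rim_radius_px`,
#'   auxiliary masks) used by the renderer.
#' @export
build_geometry <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  w <- spec$image_size_px[1]; h <- spec$image_size_px[2]
  px <- spec$pixel_size_um
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  R <- spec$cluster_radius_um / px
  g <- coord_grids(h, w)
  dx <- g$x - cx; dy <- g$y - cy
  r2 <- dx^2 + dy^2
  body <- r2 <= R^2

  ## --- protrusions -------------------------------------------------------
  np <- nrow(spec$protrusions)
  prot <- matrix(0L, h, w)
  prot_axes <- matrix(0, np, 2)
  for (i in seq_len(np)) {
    p <- spec$protrusions[i, ]
    a <- p$base_angle_deg * pi / 180
    u <- c(cos(a), sin(a))
    prot_axes[i, ] <- u
    L <- p$length_um / px
    wd <- p$width_um / px
    tipr <- R + L
    if (cx + abs(u[1]) * (tipr + wd / 2) > w - 1 ||
        cy + abs(u[2]) * (tipr + wd / 2) > h - 1 ||
        cx - abs(u[1]) * (tipr + wd / 2) < 2 ||
        cy - abs(u[2]) * (tipr + wd / 2) < 2)
      stop(sprintf("protrusion %d (angle %g deg) exceeds image bounds",
                   i, p$base_angle_deg))
    proj <- dx * u[1] + dy * u[2]
    perp <- abs(-dx * u[2] + dy * u[1])
    shaft <- proj >= R - 2 & proj <= tipr & perp <= wd / 2
    tip <- (dx - tipr * u[1])^2 + (dy - tipr * u[2])^2 <= (wd / 2)^2 &
      proj > tipr
    m <- (shaft | tip) & !body & prot == 0L
    prot[m] <- i
  }
  grp <- body | prot > 0L

  ## --- junctions and rim polyline ---------------------------------------
  nc <- spec$n_cells
  a0 <- if (np > 0) spec$protrusions$base_angle_deg[1] - 180 / nc else 0
  junctions <- .wrap360(a0 + (seq_len(nc) - 1) * 360 / nc)
  ## the cable band runs 2-7 px inside the body edge (a ~1 um bundle; a
  ## thin body-level margin stays outside it, as the cell cortex extends
  ## past the bundle); the truth polyline follows the band centre
  Rrim <- R - 4.5
  nstep <- max(64, ceiling(2 * pi * Rrim / 0.35))
  theta <- a0 + (0:(nstep - 1)) * 360 / nstep      # clockwise on screen
  rim_xy <- cbind(round(cx + Rrim * cos(theta * pi / 180)),
                  round(cy + Rrim * sin(theta * pi / 180)))
  keep <- !duplicated(rim_xy)
  rim_xy <- rim_xy[keep, , drop = FALSE]
  rim_theta <- theta[keep]

  ## --- gap placement -----------------------------------------------------
  forbidden <- list()
  for (i in seq_len(np)) {
    half <- asin(min(1, (spec$protrusions$width_um[i] / px / 2 + 2) / Rrim)) *
      180 / pi + 4
    b <- spec$protrusions$base_angle_deg[i]
    forbidden[[length(forbidden) + 1]] <- c(b - half, b + half)
  }
  for (j in junctions)
    forbidden[[length(forbidden) + 1]] <- c(j - 8, j + 8)
  n_gaps <- if (spec$cable_gap_fraction > 0)
    max(1L, as.integer(floor(spec$cable_gap_fraction / 0.1 + 0.5 + 1e-9)))
  else 0L
  gaps <- .place_gaps(spec$cable_gap_fraction * 360, n_gaps, forbidden)

  vert_broken <- rep(FALSE, nrow(rim_xy))
  for (gp in gaps)
    vert_broken <- vert_broken | .angle_in(rim_theta, gp[1], gp[2])

  ## --- per-cell arcs and cable segments ----------------------------------
  rel <- .wrap360(rim_theta - a0)
  cell_of <- pmin(nc, floor(rel / (360 / nc)) + 1)
  ## segment lengths come from the continuous circle (angular share of the
  ## circumference): the polyline coords are its rasterisation, but arc
  ## lengths summed over jagged pixel steps would over-count unevenly
  nv <- nrow(rim_xy)
  rel_next <- rel[c(2:nv, 1)]; rel_prev <- rel[c(nv, 1:(nv - 1))]
  width_deg <- (.wrap360(rel_next - rel) + .wrap360(rel - rel_prev)) / 2
  um_per_deg <- 2 * pi * Rrim * px / 360

  run_id <- cumsum(c(TRUE, diff(cell_of) != 0 | diff(vert_broken) != 0))
  cable_segments <- list(); broken_segments <- list()
  for (rid in unique(run_id)) {
    idx <- which(run_id == rid)
    seg <- list(cell = cell_of[idx[1]],
                intact = !vert_broken[idx[1]],
                coords = rim_xy[idx, , drop = FALSE],
                length_um = sum(width_deg[idx]) * um_per_deg)
    if (seg$intact) cable_segments[[length(cable_segments) + 1]] <- seg
    else broken_segments[[length(broken_segments) + 1]] <- seg
  }

  ## --- contacts and landmarks --------------------------------------------
  centre <- c(cx, cy)
  contacts <- list(); contact_endpoints <- list(); boundary_points <- NULL
  for (j in junctions) {
    ## junction clicks land on the body edge, not on the band centre
    pj <- c(cx + (R - 1) * cos(j * pi / 180), cy + (R - 1) * sin(j * pi / 180))
    pin <- c(cx + (Rrim - 3) * cos(j * pi / 180),
             cy + (Rrim - 3) * sin(j * pi / 180))
    contacts[[length(contacts) + 1]] <- raster_line(round(pin), round(centre))
    contact_endpoints[[length(contact_endpoints) + 1]] <-
      list(start = round(pin), end = round(centre))
    boundary_points <- rbind(boundary_points, round(pj))
  }
  landmarks <- list(boundary_points = boundary_points,
                    contact_endpoints = contact_endpoints)

  ## --- auxiliary masks for rendering -------------------------------------
  band <- r2 > (R - 7)^2 & r2 <= (R - 2)^2
  ang <- .wrap360(atan2(dy, dx) * 180 / pi)
  gap_band <- matrix(FALSE, h, w)
  for (gp in gaps) gap_band <- gap_band | (band & .angle_in(ang, gp[1], gp[2]))
  contact_mask <- polylines_to_mask(contacts, c(h, w), halfwidth = 2,
                                    clip = body)

  ## --- true metrics -------------------------------------------------------
  broken_len <- sum(vapply(broken_segments, function(s) s$length_um, 0))
  total_len <- broken_len + sum(vapply(cable_segments, function(s) s$length_um, 0))
  frac <- sum(prot > 0) / sum(grp)
  disc <- if (total_len > 0) broken_len / total_len else 0
  v <- spec$group_velocity_um_per_min
  true_metrics <- list(
    protrusion_area_fraction = frac,
    cable_discontinuity = disc,
    protrusion_count = np,
    total_area_um2 = sum(grp) * px^2,
    speed_um_per_min = sqrt(sum(v^2)),
    category = classify_group(frac, disc))

  c0 <- mask_centroid(grp) * px
  tt <- 0:(spec$n_frames - 1)
  centroids <- cbind(c0[1] + tt * v[1] * spec$frame_interval_s / 60,
                     c0[2] + tt * v[2] * spec$frame_interval_s / 60)
  bleach <- if (is.null(spec$bleach_tau_s)) rep(1, spec$n_frames)
            else exp(-tt * spec$frame_interval_s / spec$bleach_tau_s)

  rs <- region_set(body_mask = body, protrusions = prot,
                   cable_segments = cable_segments,
                   broken_segments = broken_segments,
                   contacts = contacts, cell_count = nc,
                   pixel_size_um = px)
  structure(list(spec = spec, region_set = rs, landmarks = landmarks,
                 true_metrics = true_metrics,
                 centroid_series_um = centroids, bleach_curve = bleach,
                 centre_px = centre, rim_radius_px = Rrim,
                 body_radius_px = R, junction_angles_deg = junctions,
                 gap_arcs_deg = gaps, prot_axes = prot_axes,
                 cable_band = band, gap_band = gap_band,
                 contact_mask = contact_mask, group_mask = grp),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  m <- x$true_metrics
  cat(sprintf(
    "ground_truth: frac %.3f, disc %.3f, %d protrusion(s), %.1f um2, %s\n",
    m$protrusion_area_fraction, m$cable_discontinuity, m$protrusion_count,
    m$total_area_um2, m$category))
  invisible(x)
}

#' Exact flow fields implied by a synthetic spec
#'
#' Returns the per-frame-pair velocity fields (`n_frames - 1` of them) of
#' the prescribed flow model, in micrometres per minute, zero outside the
#' body-plus-protrusion mask:
#' * `translation`: uniform `(magnitude, 0)`;
#' * `retrograde`: anti-parallel to each protrusion axis inside that
#'   protrusion's mask;
#' * `centripetal`: unit vectors toward the rim centroid on cable-band
#'   pixels, scaled to the magnitude;
#' * `sink`: `v(r) = -k r` about the cluster centre, `k` in 1/min;
#' * `none`: all zero.
#'
#' @param spec a [synthetic_spec()].
#' @param truth the matching [build_geometry()] output.
#' @return list of `flow_field` objects of length `max(n_frames - 1, 0)`.
#' @export
ground_truth_flow <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "ground_truth"))
  w <- spec$image_size_px[1]; h <- spec$image_size_px[2]
  px <- spec$pixel_size_um
  g <- coord_grids(h, w)
  dx <- (g$x - truth$centre_px[1]) * px
  dy <- (g$y - truth$centre_px[2]) * px
  mag <- spec$flow_magnitude_um_per_min
  msk <- truth$group_mask
  u <- matrix(0, h, w); v <- matrix(0, h, w)
  if (spec$flow_model == "translation") {
    u[msk] <- mag
  } else if (spec$flow_model == "retrograde") {
    for (i in seq_len(nrow(spec$protrusions))) {
      m <- truth$region_set$protrusions == i
      u[m] <- -mag * truth$prot_axes[i, 1]
      v[m] <- -mag * truth$prot_axes[i, 2]
    }
  } else if (spec$flow_model == "centripetal") {
    m <- truth$cable_band
    r <- sqrt(dx^2 + dy^2); r[r == 0] <- 1
    u[m] <- -mag * dx[m] / r[m]
    v[m] <- -mag * dy[m] / r[m]
  } else if (spec$flow_model == "sink") {
    u[msk] <- -mag * dx[msk]
    v[msk] <- -mag * dy[msk]
  }
  n <- max(spec$n_frames - 1, 0)
  lapply(seq_len(n), function(t)
    flow_field(u = u, v = v, valid = msk, frame_index = t))
}

## Base (speckle-free) intensity image of one channel.
.base_image <- function(truth, intensity) {
  rs <- truth$region_set
  base <- matrix(intensity$background, nrow(rs$body_mask), ncol(rs$body_mask))
  base[rs$body_mask] <- intensity$body
  base[truth$contact_mask] <- intensity$contact
  base[truth$cable_band] <- intensity$cable
  base[truth$gap_band] <- intensity$gap
  base[rs$protrusions > 0] <- intensity$protrusion
  base
}

#' Render a synthetic fluorescence time-lapse
#'
#' Frame 1 is the per-region base intensity multiplied by a frozen,
#' multiplicative speckle texture (per-pixel log-normal, clipped to
#' \[0.7, 1.5\] so foreground and background stay threshold-separable).
#' Each subsequent frame is the previous frame advected by the prescribed
#' flow (backward bilinear warping; out-of-domain samples take the region
#' base intensity), translated by the group velocity, multiplied by the
#' photobleaching step `exp(-dt/tau)`, plus seeded Gaussian noise clamped
#' at zero.
#'
#' @param spec a [synthetic_spec()].
#' @param truth the matching [build_geometry()] output.
#' @return a [timelapse_stack()] with one array per requested channel.
#' @export
render_timelapse <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "ground_truth"))
  w <- spec$image_size_px[1]; h <- spec$image_size_px[2]
  px <- spec$pixel_size_um
  dt_min <- spec$frame_interval_s / 60
  flows <- ground_truth_flow(spec, truth)
  vg_px <- spec$group_velocity_um_per_min * dt_min / px
  step_decay <- if (is.null(spec$bleach_tau_s)) 1
                else exp(-spec$frame_interval_s / spec$bleach_tau_s)
  g <- coord_grids(h, w)

  channels <- with_seed(spec$seed + 1L, {
    out <- list()
    for (ch in spec$channels) {
      intensity <- if (ch == "myosin") spec$myosin_intensity
                   else spec$region_intensity
      base <- .base_image(truth, intensity)
      speckle <- matrix(pmin(pmax(exp(stats::rnorm(h * w, 0, 0.18)), 0.7), 1.5),
                        h, w)
      arr <- array(0, c(h, w, spec$n_frames))
      fr <- base * speckle
      if (spec$noise_sd > 0)
        fr <- pmax(fr + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w), 0)
      arr[, , 1] <- fr
      prev <- fr
      for (t in seq_len(spec$n_frames - 1)) {
        fl <- flows[[min(t, length(flows))]]
        d_px_x <- fl$u * dt_min / px + vg_px[1]
        d_px_y <- fl$v * dt_min / px + vg_px[2]
        sx <- g$x - d_px_x; sy <- g$y - d_px_y
        warped <- matrix(bilinear_sample(prev, as.vector(sx), as.vector(sy),
                                         fill = NA), h, w)
        oob <- is.na(warped)
        if (any(oob)) warped[oob] <- base[oob] * truth$bleach_curve[t]
        fr <- warped * step_decay
        if (spec$noise_sd > 0)
          fr <- pmax(fr + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w), 0)
        arr[, , t + 1] <- fr
        prev <- fr
      }
      out[[ch]] <- arr
    }
    out
  })
  timelapse_stack(channels, pixel_size_um = px,
                  frame_interval_s = spec$frame_interval_s,
                  background_subtracted = TRUE)
}

#' Convenience wrapper: geometry + flows + rendered stack
#'
#' @param spec a [synthetic_spec()].
#' @return list with `truth` (including `flow_series`) and `stack`.
#' @export
simulate_cluster <- function(spec) {
  truth <- build_geometry(spec)
  truth$flow_series <- ground_truth_flow(spec, truth)
  stack <- render_timelapse(spec, truth)
  list(truth = truth, stack = stack)
}

## Protrusion rows sized so the rasterised protrusion-area fraction lands
## near `target_frac` for a disk of radius R_um: per-protrusion area
## A = f/(1-f) * pi R^2 / n, finger area ~ w L + pi w^2/8 (half-disc tip).
.protrusions_for_fraction <- function(target_frac, base_angles_deg, width_um,
                                      R_um) {
  n <- length(base_angles_deg)
  if (n == 0 || target_frac <= 0)
    return(data.frame(base_angle_deg = numeric(0), length_um = numeric(0),
                      width_um = numeric(0)))
  A <- target_frac / (1 - target_frac) * pi * R_um^2 / n
  L <- pmax((A - pi * width_um^2 / 8) / width_um, width_um / 2)
  data.frame(base_angle_deg = base_angles_deg, length_um = L,
             width_um = width_um)
}

#' Canonical synthetic fixtures
#'
#' Named specs covering the study conditions exercised by the test suite:
#' `"tight"` (5% protrusion area, 5% discontinuity), `"loose"` (30%/30%),
#' `"balanced"` (15%/15%, drifting at 0.5 um/min), `"translation_pair"`
#' (uniform 3 px/frame flow for displacement recovery),
#' `"sink_pair"` (v = -k r, k = 0.5/min, dual channel) and
#' `"bleach_stack"` (static, tau = 300 s).
#'
#' @param name fixture name.
#' @return a [synthetic_spec()].
#' @export
fixture_spec <- function(name = c("tight", "loose", "balanced",
                                  "translation_pair", "sink_pair",
                                  "bleach_stack")) {
  name <- match.arg(name)
  R <- 7
  switch(name,
    tight = synthetic_spec(
      n_frames = 3, cluster_radius_um = R,
      protrusions = .protrusions_for_fraction(0.05, 0, 2, R),
      cable_gap_fraction = 0.05, noise_sd = 2, seed = 101L),
    loose = synthetic_spec(
      n_frames = 3, cluster_radius_um = R,
      protrusions = .protrusions_for_fraction(0.30, c(0, 120, 240), 3.2, R),
      cable_gap_fraction = 0.30, noise_sd = 2, seed = 102L),
    balanced = synthetic_spec(
      n_frames = 5, frame_interval_s = 24, cluster_radius_um = R,
      protrusions = .protrusions_for_fraction(0.15, c(0, 180), 2.4, R),
      cable_gap_fraction = 0.15,
      group_velocity_um_per_min = c(0.5, 0), noise_sd = 2, seed = 103L),
    translation_pair = synthetic_spec(
      n_frames = 2, frame_interval_s = 10, cluster_radius_um = R,
      protrusions = data.frame(base_angle_deg = numeric(0),
                               length_um = numeric(0),
                               width_um = numeric(0)),
      flow_model = "translation", flow_magnitude_um_per_min = 3.6,
      noise_sd = 0, seed = 104L),
    sink_pair = synthetic_spec(
      n_frames = 2, frame_interval_s = 10, cluster_radius_um = R,
      protrusions = data.frame(base_angle_deg = numeric(0),
                               length_um = numeric(0),
                               width_um = numeric(0)),
      flow_model = "sink", flow_magnitude_um_per_min = 0.5,
      channels = c("actin", "myosin"), noise_sd = 0, seed = 105L),
    bleach_stack = synthetic_spec(
      n_frames = 10, frame_interval_s = 30, cluster_radius_um = R,
      bleach_tau_s = 300, noise_sd = 0, seed = 106L))
}

#' Write the canonical fixture suite to disk
#'
#' Renders each [fixture_spec()] and writes, per fixture, one multi-page
#' 16-bit TIFF per channel, the ground truth as JSON and the landmarks as
#' JSON, plus a `manifest.json` listing every artefact with its MD5 hash.
#'
#' @param out_dir writable output directory (created if missing).
#' @return the manifest, invisibly (a named list, one entry per fixture).
#' @export
make_fixture_suite <- function(out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir)
  names <- c("tight", "loose", "balanced", "translation_pair", "sink_pair",
             "bleach_stack")
  manifest <- list()
  for (nm in names) {
    spec <- fixture_spec(nm)
    sim <- simulate_cluster(spec)
    files <- list()
    for (ch in names(sim$stack$channels)) {
      f <- file.path(out_dir, sprintf("%s_%s.tif", nm, ch))
      write_stack(sim$stack, f, channel = ch)
      files[[paste0("tiff_", ch)]] <- basename(f)
    }
    gt_file <- file.path(out_dir, paste0(nm, "_truth.json"))
    write_ground_truth(sim$truth, gt_file)
    files$ground_truth <- basename(gt_file)
    lm_file <- file.path(out_dir, paste0(nm, "_landmarks.json"))
    write_landmarks(sim$truth$landmarks, lm_file)
    files$landmarks <- basename(lm_file)
    hashes <- as.list(tools::md5sum(file.path(out_dir, unlist(files))))
    names(hashes) <- unlist(files)
    manifest[[nm]] <- list(files = files, md5 = hashes,
                           true_metrics = sim$truth$true_metrics,
                           seed = spec$seed)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
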
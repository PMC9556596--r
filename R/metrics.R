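## Scalar morphometrics and intensity read-outs of a border-cell group,
## photobleaching correction, and the tight/loose/balanced classification.

#' Relative mean intensity per subcellular region class
#'
#' Mean pixel intensity of each region class (contacts, cables,
#' protrusions) divided by the mean intensity over the whole group mask,
#' making the values comparable across frames and movies. Summed (not
#' mean) intensities per class are returned as well for ratio read-outs.
#' An empty region class yields `NA` ("absent"), never zero.
#'
#' @param frame background-subtracted numeric matrix.
#' @param regions a [region_set()].
#' @return list with `relative` (named numeric: contacts, cables,
#'   protrusions), `total` (named summed intensities) and `group_mean`.
#' @export
region_mean_intensity <- function(frame, regions) {
  stopifnot(is.matrix(frame), inherits(regions, "region_set"))
  masks <- region_masks(regions)
  gmask <- group_mask(regions)
  gmean <- mean(frame[gmask])
  one <- function(m) if (!any(m)) NA_real_ else mean(frame[m]) / gmean
  tot <- function(m) if (!any(m)) NA_real_ else sum(frame[m])
  list(relative = c(contacts = one(masks$contacts),
                    cables = one(masks$cables),
                    protrusions = one(masks$protrusions)),
       total = c(contacts = tot(masks$contacts),
                 cables = tot(masks$cables),
                 protrusions = tot(masks$protrusions)),
       group_mean = gmean)
}

#' Cable share of total peripheral F-actin signal
#'
#' Ratio of the summed cable intensity to the summed peripheral (cable +
#' protrusion) intensity.
#'
#' @param per_region output of [region_mean_intensity()] (or a list with a
#'   `total` element holding `cables` and `protrusions` sums).
#' @return number in \[0, 1\].
#' @export
cable_periphery_ratio <- function(per_region) {
  tot <- per_region$total
  cab <- tot[["cables"]]; pro <- tot[["protrusions"]]
  if (is.na(cab)) cab <- 0
  if (is.na(pro)) pro <- 0
  if (cab + pro == 0) stop("cable and protrusion totals are both zero")
  cab / (cab + pro)
}

#' Cable discontinuity of a region set
#'
#' Length ratio between the total broken cable sections and the total rim
#' (all cable plus broken sections).
#'
#' @param regions a [region_set()] (or a `cable_trace`).
#' @return number in \[0, 1\].
#' @export
cable_discontinuity <- function(regions) {
  stopifnot(inherits(regions, "region_set") || inherits(regions, "cable_trace"))
  broken <- sum(vapply(regions$broken_segments, function(s) s$length_um, 0))
  intact <- sum(vapply(regions$cable_segments, function(s) s$length_um, 0))
  if (broken + intact <= 0) stop("rim has zero total length")
  broken / (broken + intact)
}

#' Morphometrics of a region set
#'
#' @param regions a [region_set()].
#' @param pixel_size_um pixel calibration (defaults to the one stored in
#'   the region set).
#' @return list with `protrusion_area_fraction`, `protrusion_count`,
#'   `total_area_um2`.
#' @export
morphology_summary <- function(regions, pixel_size_um = regions$pixel_size_um) {
  stopifnot(inherits(regions, "region_set"))
  prot_px <- sum(regions$protrusions > 0)
  body_px <- sum(regions$body_mask)
  list(protrusion_area_fraction = prot_px / (prot_px + body_px),
       protrusion_count = max(0L, max(regions$protrusions)),
       total_area_um2 = (prot_px + body_px) * pixel_size_um^2)
}

#' Migration speed from a centroid series
#'
#' Euclidean distance between the group centroid at the first and third
#' time points, divided by the elapsed time, expressed in micrometres per
#' minute. With `sliding = TRUE` the same two-interval rule is applied at
#' every start frame, giving a speed series for time-lapse plots.
#'
#' @param centroid_series_um n x 2 matrix of centroids in micrometres.
#' @param frame_interval_s frame interval in seconds.
#' @param sliding return a sliding-window series instead of a scalar.
#' @return speed in um/min (scalar, or vector of length n - 2).
#' @export
migration_speed <- function(centroid_series_um, frame_interval_s,
                            sliding = FALSE) {
  centroid_series_um <- as.matrix(centroid_series_um)
  n <- nrow(centroid_series_um)
  if (n < 3) stop("migration speed needs at least 3 time points")
  stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  speed_at <- function(i) {
    d <- sqrt(sum((centroid_series_um[i + 2, ] - centroid_series_um[i, ])^2))
    d / (2 * frame_interval_s) * 60
  }
  if (sliding) vapply(seq_len(n - 2), speed_at, 0) else speed_at(1)
}

#' Correct exponential photobleaching of a time-lapse stack
#'
#' Fits the frame-mean series of each channel to `A exp(-t / tau)` by least
#' squares on the log means, then divides each frame by its fitted relative
#' decay. A non-decaying (or brightening) stack is returned unchanged with
#' the decay flagged absent.
#'
#' @param stack a [timelapse_stack()] with at least 3 frames.
#' @return list with `stack` (corrected), `tau_s` (named per channel; `NA`
#'   where no decay was fitted) and `corrected` (logical per channel).
#' @export
bleach_correct <- function(stack) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nt <- n_frames(stack)
  if (nt < 3) stop("bleach correction needs at least 3 frames")
  t_s <- (seq_len(nt) - 1) * stack$frame_interval_s
  tau <- stats::setNames(rep(NA_real_, length(stack$channels)),
                         names(stack$channels))
  corrected <- stats::setNames(rep(FALSE, length(stack$channels)),
                               names(stack$channels))
  out <- stack
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    means <- apply(a, 3, mean)
    if (any(means <= 0)) stop("nonpositive frame means in channel ", ch)
    fit <- stats::lm(log(means) ~ t_s)
    slope <- stats::coef(fit)[[2]]
    if (slope < 0) {
      tau[ch] <- -1 / slope
      decay <- exp(-t_s / tau[ch])
      for (t in seq_len(nt)) a[, , t] <- a[, , t] / decay[t]
      out$channels[[ch]] <- a
      corrected[ch] <- TRUE
    }
  }
  list(stack = out, tau_s = tau, corrected = corrected)
}

#' Assign cells to front / middle / rear positions
#'
#' Projects cell centroids onto the motion axis and splits them into
#' terciles of the projected coordinate: the highest third (furthest along
#' the motion direction) is the front. With fewer than 3 cells the maximal
#' projection is front and the minimal one rear.
#'
#' @param cell_centroids n x 2 matrix of centroids (any consistent unit).
#' @param motion_direction nonzero direction vector of group motion.
#' @return character vector of labels `"front"`, `"middle"`, `"rear"`.
#' @export
assign_cell_positions <- function(cell_centroids, motion_direction) {
  cell_centroids <- as.matrix(cell_centroids)
  n <- nrow(cell_centroids)
  if (n < 1) stop("need at least one cell")
  if (sqrt(sum(motion_direction^2)) == 0) stop("motion vector is zero")
  u <- motion_direction / sqrt(sum(motion_direction^2))
  proj <- drop(cell_centroids %*% u)
  if (n == 1) return("front")
  if (n == 2) {
    out <- c("rear", "front")[rank(proj, ties.method = "first")]
    return(out)
  }
  br <- stats::quantile(proj, c(1 / 3, 2 / 3), type = 7)
  as.character(ifelse(proj > br[2], "front",
                      ifelse(proj <= br[1], "rear", "middle")))
}

#' Per-frame group metrics for a movie
#'
#' Runs the region extraction and morphometric read-outs on each frame of
#' a (background-subtracted, optionally bleach-corrected) stack and
#' returns one row per frame with the columns of the standard metrics
#' table. The migration speed (first-to-third-frame rule) and the category
#' are computed from the whole series and repeated on each row.
#'
#' @param stack a [timelapse_stack()].
#' @param landmarks landmark list (see [extract_regions()]).
#' @param movie_id identifier written into the first column.
#' @param channel channel used for segmentation and intensities.
#' @param cfg a [classifier_config()].
#' @param ... passed to [extract_regions()].
#' @return data.frame with columns movie_id, frame,
#'   protrusion_area_fraction, cable_discontinuity, protrusion_count,
#'   total_area_um2, speed_um_per_min, category, intensity_contacts,
#'   intensity_cables, intensity_protrusions.
#' @export
group_metrics <- function(stack, landmarks, movie_id = "movie",
                          channel = 1, cfg = classifier_config(), ...) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nt <- n_frames(stack)
  px <- stack$pixel_size_um
  rows <- vector("list", nt)
  centroids <- matrix(NA_real_, nt, 2)
  for (t in seq_len(nt)) {
    fr <- get_frame(stack, t, channel)
    regions <- extract_regions(fr, landmarks, px, ...)
    centroids[t, ] <- mask_centroid(group_mask(regions)) * px
    morph <- morphology_summary(regions)
    disc <- cable_discontinuity(regions)
    inten <- region_mean_intensity(fr, regions)
    rows[[t]] <- data.frame(
      movie_id = movie_id, frame = t - 1L,
      protrusion_area_fraction = morph$protrusion_area_fraction,
      cable_discontinuity = disc,
      protrusion_count = morph$protrusion_count,
      total_area_um2 = morph$total_area_um2,
      speed_um_per_min = NA_real_,
      category = classify_group(morph$protrusion_area_fraction, disc, cfg),
      intensity_contacts = inten$relative[["contacts"]],
      intensity_cables = inten$relative[["cables"]],
      intensity_protrusions = inten$relative[["protrusions"]],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (nt >= 3)
    df$speed_um_per_min <- migration_speed(centroids, stack$frame_interval_s)
  df
}
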
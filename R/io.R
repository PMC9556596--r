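## File formats: multi-page TIFF stacks (16-bit counts for images, 32-bit
## float planes for flow fields), JSON for landmarks / region sets / ground
## truth / manifests, YAML for run configuration. All JSON coordinates are
## 0-based pixel indices, x rightward, y downward; R-side coordinates are
## 1-based.

.COORD_NOTE <- "0-based pixel indices, x rightward, y downward"

#' Read a multi-page TIFF time-lapse
#'
#' Pages are read in stored order; pixel values are returned as 16-bit
#' counts. Calibration is attached from the arguments (configuration wins
#' over whatever the TIFF tags may claim; microscopy tag dialects are
#' advisory at best).
#'
#' @param path TIFF file.
#' @param pixel_size_um,frame_interval_s calibration to attach.
#' @param channel_name name for the single channel read (default "actin").
#' @return a [timelapse_stack()].
#' @export
read_stack <- function(path, pixel_size_um, frame_interval_s,
                       channel_name = "actin") {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("inconsistent page shapes in ", path)
  arr <- array(0, c(dims[[1]][1], dims[[1]][2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- round(pages[[t]] * 65535)
  ch <- stats::setNames(list(arr), channel_name)
  timelapse_stack(ch, pixel_size_um, frame_interval_s)
}

#' Write one channel of a stack as a multi-page 16-bit TIFF
#'
#' Counts are rounded to integers and clipped to \[0, 65535\].
#'
#' @param stack a [timelapse_stack()] (or a numeric array / matrix).
#' @param path output file.
#' @param channel channel name or index.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, channel = 1) {
  arr <- if (inherits(stack, "timelapse_stack")) stack$channels[[channel]]
         else stack
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  pages <- lapply(seq_len(dim(arr)[3]), function(t)
    pmin(pmax(round(arr[, , t]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read / write landmark files
#'
#' JSON layout: `{"coordinate_system": ..., "boundary_points": [[x, y],
#' ...], "contacts": [[[x, y], [x, y]], ...]}` with 0-based coordinates.
#' In R, landmarks are a list with `boundary_points` (n x 2 matrix,
#' 1-based) and `contact_endpoints` (list of `list(start, end)`).
#'
#' @param path JSON file.
#' @return landmark list.
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  bp <- matrix(as.numeric(unlist(j$boundary_points)), ncol = 2,
               byrow = !is.matrix(j$boundary_points)) + 1
  if (is.matrix(j$boundary_points)) bp <- j$boundary_points + 1
  list(boundary_points = bp, contact_endpoints = .contacts_from_json(j$contacts))
}

## Contact endpoint pairs from JSON, whether jsonlite simplified them into
## an n x 2 x 2 array or left a list of 2 x 2 point pairs (0-based in, 1-based
## out).
.contacts_from_json <- function(carr) {
  ce <- list()
  if (is.null(carr)) return(ce)
  if (is.array(carr) && length(dim(carr)) == 3) {
    for (i in seq_len(dim(carr)[1]))
      ce[[i]] <- list(start = carr[i, 1, ] + 1, end = carr[i, 2, ] + 1)
  } else if (is.list(carr)) {
    for (i in seq_along(carr)) {
      m <- matrix(as.numeric(unlist(carr[[i]])), ncol = 2, byrow = TRUE)
      ce[[i]] <- list(start = m[1, ] + 1, end = m[2, ] + 1)
    }
  }
  ce
}

#' @rdname read_landmarks
#' @param landmarks landmark list to write.
#' @export
write_landmarks <- function(landmarks, path) {
  j <- list(coordinate_system = .COORD_NOTE,
            boundary_points = unname(as.matrix(landmarks$boundary_points)) - 1,
            contacts = lapply(landmarks$contact_endpoints, function(ep)
              list(as.numeric(ep$start) - 1, as.numeric(ep$end) - 1)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.segment_to_json <- function(s) {
  out <- list(cell = s$cell, intact = s$intact,
              length_um = s$length_um,
              mean_intensity = s$mean_intensity %||% NULL,
              coords = unname(s$coords) - 1)
  if (!is.null(s$band_coords)) out$band_coords <- unname(s$band_coords) - 1
  out
}

.segment_from_json <- function(s) {
  as_xy <- function(m) matrix(as.numeric(unlist(m)), ncol = 2,
                              byrow = !is.matrix(m)) + 1
  out <- list(cell = as.integer(s$cell), intact = isTRUE(s$intact),
              coords = as_xy(s$coords),
              length_um = as.numeric(s$length_um),
              mean_intensity = if (is.null(s$mean_intensity)) NULL
                               else as.numeric(s$mean_intensity))
  if (!is.null(s$band_coords)) out$band_coords <- as_xy(s$band_coords)
  out
}

#' Read / write a region set as JSON
#'
#' Masks are stored run-length encoded (column-major); polylines as
#' ordered 0-based pixel coordinate lists.
#'
#' @param path JSON file.
#' @return a [region_set()].
#' @export
read_region_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  body <- rle_to_mask(j$body_mask)
  prot <- matrix(inverse.rle(list(values = as.integer(j$protrusions$values),
                                  lengths = as.integer(j$protrusions$lengths))),
                 nrow = j$protrusions$dim[1], ncol = j$protrusions$dim[2])
  segs <- function(x) if (is.null(x) || length(x) == 0) list()
                      else lapply(x, .segment_from_json)
  cj <- j$contacts %||% list()
  contacts <- lapply(cj, function(cc)
    matrix(as.numeric(unlist(cc$coords)), ncol = 2,
           byrow = !is.matrix(cc$coords)) + 1)
  region_set(body_mask = body, protrusions = prot,
             cable_segments = segs(j$cable_segments),
             broken_segments = segs(j$broken_segments),
             contacts = contacts,
             cell_count = as.integer(j$cell_count),
             pixel_size_um = as.numeric(j$pixel_size_um))
}

#' @rdname read_region_set
#' @param regions a [region_set()] to write.
#' @export
write_region_set <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  prle <- rle(as.vector(regions$protrusions))
  j <- list(coordinate_system = .COORD_NOTE,
            body_mask = mask_to_rle(regions$body_mask),
            protrusions = list(dim = dim(regions$protrusions),
                               values = as.integer(prle$values),
                               lengths = prle$lengths),
            cable_segments = lapply(regions$cable_segments, .segment_to_json),
            broken_segments = lapply(regions$broken_segments, .segment_to_json),
            contacts = lapply(regions$contacts, function(cc) {
              cm <- matrix(as.numeric(cc), nrow = nrow(cc), ncol = ncol(cc))
              list(coords = cm - 1,
                   mean_intensity = attr(cc, "mean_intensity") %||% NULL,
                   area_um2 = attr(cc, "area_um2") %||% NULL)
            }),
            cell_count = regions$cell_count,
            pixel_size_um = regions$pixel_size_um)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read ground truth of a synthetic cluster
#'
#' @param truth a `ground_truth` from [build_geometry()] (optionally with
#'   `flow_series`).
#' @param path JSON file.
#' @return `path` invisibly; `read_ground_truth()` returns a list with
#'   `true_metrics`, `landmarks`, `centroid_series_um`, `bleach_curve` and
#'   the serialised `region_set`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  rs_tmp <- tempfile(fileext = ".json")
  write_region_set(truth$region_set, rs_tmp)
  rs_json <- jsonlite::read_json(rs_tmp, simplifyVector = TRUE)
  unlink(rs_tmp)
  j <- list(coordinate_system = .COORD_NOTE,
            true_metrics = truth$true_metrics,
            landmarks = list(
              boundary_points = unname(as.matrix(
                truth$landmarks$boundary_points)) - 1,
              contacts = lapply(truth$landmarks$contact_endpoints,
                                function(ep) list(as.numeric(ep$start) - 1,
                                                  as.numeric(ep$end) - 1))),
            centroid_series_um = unname(as.matrix(truth$centroid_series_um)),
            bleach_curve = truth$bleach_curve,
            junction_angles_deg = truth$junction_angles_deg,
            region_set = rs_json)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  rs_tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(j$region_set, rs_tmp, auto_unbox = TRUE, digits = NA)
  rs <- read_region_set(rs_tmp)
  unlink(rs_tmp)
  bp <- j$landmarks$boundary_points
  lm <- list(boundary_points = (if (is.matrix(bp)) bp else
               matrix(unlist(bp), ncol = 2, byrow = TRUE)) + 1,
             contact_endpoints = .contacts_from_json(j$landmarks$contacts))
  list(true_metrics = as.list(j$true_metrics), landmarks = lm,
       centroid_series_um = j$centroid_series_um,
       bleach_curve = j$bleach_curve,
       junction_angles_deg = j$junction_angles_deg,
       region_set = rs)
}

#' Write a flow field as a 4-plane 32-bit float TIFF with JSON sidecar
#'
#' Planes are u, v (um/min), valid (0/1) and corr. Each plane is stored
#' min-max normalised (TIFF float storage is only well defined on
#' \[0, 1\]); the per-plane ranges live in the sidecar and are restored on
#' read.
#'
#' @param field a [flow_field()].
#' @param path output TIFF path (sidecar gets extension `.json`).
#' @param cfg optional [piv_config()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_flow_field <- function(field, path, cfg = NULL) {
  stopifnot(inherits(field, "flow_field"))
  planes <- list(field$u, field$v, field$valid * 1,
                 field$corr %||% (field$valid * 0))
  ranges <- lapply(planes, range)
  norm <- lapply(planes, function(p) {
    r <- range(p)
    if (r[2] > r[1]) (p - r[1]) / (r[2] - r[1]) else p * 0
  })
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, compression = "none")
  side <- sub("\\.tiff?$", ".json", path)
  meta <- list(planes = c("u_um_per_min", "v_um_per_min", "valid", "corr"),
               plane_ranges = ranges,
               coordinate_system = .COORD_NOTE,
               frame_index = field$frame_index)
  if (!is.null(cfg)) meta$piv_config <- unclass(cfg)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_flow_field
#' @export
read_flow_field <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  side <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(side)) stop("missing flow-field sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  pr <- meta$plane_ranges
  planes <- lapply(seq_along(pages), function(i) {
    r <- if (is.matrix(pr)) as.numeric(pr[i, ]) else as.numeric(pr[[i]])
    if (r[2] > r[1]) r[1] + pages[[i]] * (r[2] - r[1]) else pages[[i]] * 0 + r[1]
  })
  flow_field(u = planes[[1]], v = planes[[2]], valid = planes[[3]] > 0.5,
             corr = planes[[4]], frame_index = meta$frame_index %||% 1L)
}

## ---- run configuration -----------------------------------------------

.known_config_keys <- function() {
  list(top = c("input", "landmarks", "out_dir", "pixel_size_um",
               "frame_interval_s", "channel", "seed", "log_level",
               "piv", "classifier", "segmentation"),
       piv = c("source_area_um2", "search_area_um2", "corr_threshold_c0",
               "spatial_kernel_um", "spatial_sigma_um", "temporal_kernel_s",
               "temporal_sigma_s", "grid_stride_px", "subpixel",
               "source_side_px", "search_side_px"),
       classifier = c("tight_max_protrusion_frac", "tight_max_discontinuity",
                      "loose_min_protrusion_frac", "loose_min_discontinuity"),
       segmentation = c("opening_radius_um", "min_protrusion_area_um2",
                        "cable_intensity_threshold", "snap_dist_px",
                        "contact_half_width_px"))
}

#' Read / write a run configuration (YAML)
#'
#' Unknown keys are rejected; a configuration round-trips losslessly
#' (load, save, load gives an equal object).
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- .known_config_keys()
  bad <- setdiff(names(cfg), known$top)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in c("piv", "classifier", "segmentation")) {
    if (is.null(cfg[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (length(bad))
      stop("unknown config key(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  cfg
}

#' @rdname read_run_config
#' @param cfg configuration list to write.
#' @export
write_run_config <- function(cfg, path) {
  known <- .known_config_keys()
  bad <- setdiff(names(cfg), known$top)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write pipeline outputs and a hashed manifest
#'
#' Writes the metrics table as CSV (fixed column order), each flow field
#' as a float TIFF + sidecar, the region set as JSON, and a
#' `manifest.json` listing every artefact with its MD5 content hash.
#'
#' @param metrics data.frame from [group_metrics()] (possibly empty).
#' @param flows optional list of [flow_field()]s.
#' @param regions optional [region_set()].
#' @param out_dir output directory (created if missing).
#' @param cfg optional [piv_config()] recorded in the flow sidecars.
#' @return the manifest (named list file -> md5), invisibly.
#' @export
write_outputs <- function(metrics, flows = NULL, regions = NULL, out_dir,
                          cfg = NULL) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir)
  cols <- c("movie_id", "frame", "protrusion_area_fraction",
            "cable_discontinuity", "protrusion_count", "total_area_um2",
            "speed_um_per_min", "category", "intensity_contacts",
            "intensity_cables", "intensity_protrusions")
  if (is.null(metrics) || nrow(metrics) == 0)
    metrics <- stats::setNames(
      data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
  metrics <- metrics[, cols]
  files <- character(0)
  f <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, f, row.names = FALSE)
  files <- c(files, f)
  for (i in seq_along(flows %||% list())) {
    f <- file.path(out_dir, sprintf("flow_%03d.tif", i))
    write_flow_field(flows[[i]], f, cfg = cfg)
    files <- c(files, f, sub("\\.tif$", ".json", f))
  }
  if (!is.null(regions)) {
    f <- file.path(out_dir, "regions.json")
    write_region_set(regions, f)
    files <- c(files, f)
  }
  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
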
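#' Labelled subcellular regions of a border-cell cluster
#'
#' Container tying together the decomposition of a cluster image: the main
#' body mask, labelled protrusion masks, per-cell cable segments along the
#' peripheral rim (flagged intact or broken), inner cell-cell contact
#' polylines, and the cell count. Produced either by the segmentation stage
#' ([extract_regions()]) or by the synthetic generator ([build_geometry()]),
#' which makes the two directly comparable in tests.
#'
#' Cable and broken segments each are lists with elements `cell` (1-based
#' cell index), `intact` (logical), `coords` (n x 2 matrix of 1-based x, y
#' pixel vertices in clockwise rim order), `length_um` and (when traced from
#' an image) `mean_intensity`. Together the segments tile the rim polyline
#' exactly once.
#'
#' @param body_mask logical matrix, main body.
#' @param protrusions integer matrix of protrusion labels (0 = none).
#' @param cable_segments list of intact cable segments.
#' @param broken_segments list of broken cable segments.
#' @param contacts list of contact polylines (each an n x 2 coords matrix,
#'   optionally with attributes `mean_intensity` and `area_um2`).
#' @param cell_count integer number of border cells.
#' @param pixel_size_um pixel calibration in micrometres.
#' @return an object of class `region_set`.
#' @export
region_set <- function(body_mask, protrusions, cable_segments = list(),
                       broken_segments = list(), contacts = list(),
                       cell_count = length(cable_segments),
                       pixel_size_um = 1) {
  stopifnot(is.logical(body_mask) || all(body_mask %in% c(0, 1)))
  body_mask <- matrix(as.logical(body_mask), nrow(body_mask), ncol(body_mask))
  if (!all(dim(protrusions) == dim(body_mask)))
    stop("body_mask and protrusions must have identical dimensions")
  if (any(body_mask & protrusions > 0))
    stop("body mask and protrusion masks must be disjoint")
  structure(list(body_mask = body_mask,
                 protrusions = protrusions,
                 cable_segments = cable_segments,
                 broken_segments = broken_segments,
                 contacts = contacts,
                 cell_count = as.integer(cell_count),
                 pixel_size_um = pixel_size_um),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set:", sum(x$body_mask), "body px,",
      length(setdiff(unique(as.vector(x$protrusions)), 0L)), "protrusion(s),",
      length(x$cable_segments), "intact +", length(x$broken_segments),
      "broken cable segment(s),", length(x$contacts), "contact(s),",
      x$cell_count, "cells\n")
  invisible(x)
}

#' Group mask of a region set
#'
#' Union of the main body and all protrusion masks.
#' @param regions a [region_set()].
#' @return logical matrix.
#' @export
group_mask <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  regions$body_mask | regions$protrusions > 0
}

## Rasterise a list of polyline segments into a logical mask, dilating each
## vertex by `halfwidth` pixels (square structuring element by default, or a
## Euclidean disc with shape = "disc") and clipping to `clip` when given.
polylines_to_mask <- function(segments, dim, halfwidth = 1, clip = NULL,
                              shape = c("box", "disc")) {
  shape <- match.arg(shape)
  m <- matrix(FALSE, dim[1], dim[2])
  for (seg in segments) {
    coords <- if (is.list(seg) && !is.null(seg$coords)) seg$coords else seg
    if (is.null(coords) || nrow(coords) == 0) next
    for (d in -halfwidth:halfwidth) for (e in -halfwidth:halfwidth) {
      if (shape == "disc" && d^2 + e^2 > halfwidth^2) next
      x <- coords[, 1] + d; y <- coords[, 2] + e
      ok <- x >= 1 & x <= dim[2] & y >= 1 & y <= dim[1]
      m[cbind(y[ok], x[ok])] <- TRUE
    }
  }
  if (!is.null(clip)) m <- m & clip
  m
}

#' Pixel masks for the three subcellular region classes
#'
#' Converts the polyline representation of cables and contacts into pixel
#' masks for intensity measurements: the cable mask is a band of the given
#' half-width around the intact cable polylines clipped to the body; the
#' contact mask is a ribbon around each contact polyline clipped to the
#' body; the protrusion mask is the union of protrusion labels.
#'
#' @param regions a [region_set()].
#' @param cable_halfwidth_px,contact_halfwidth_px band half-widths in pixels.
#' @return named list of logical masks: `cables`, `contacts`, `protrusions`.
#' @export
region_masks <- function(regions, cable_halfwidth_px = 1,
                         contact_halfwidth_px = 2) {
  stopifnot(inherits(regions, "region_set"))
  d <- dim(regions$body_mask)
  ## segments traced from an image carry the exact band pixels that were
  ## sampled; fall back to dilating the polyline otherwise
  cab <- matrix(FALSE, d[1], d[2])
  for (s in regions$cable_segments) {
    if (!is.null(s$band_coords))
      cab <- cab | polylines_to_mask(list(s$band_coords), d, 0)
    else
      cab <- cab | polylines_to_mask(list(s), d, cable_halfwidth_px)
  }
  list(cables = cab & regions$body_mask,
       contacts = polylines_to_mask(regions$contacts, d,
                                    contact_halfwidth_px,
                                    clip = regions$body_mask),
       protrusions = regions$protrusions > 0)
}
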
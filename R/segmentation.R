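## Decomposition of a cluster image into the three subcellular F-actin
## regions: finger-like protrusions, the peripheral supracellular cable
## (with its broken sections) and inner cell-cell contacts. The split
## between protrusions and main body uses a morphological opening; the
## cable is traced along the body boundary between clicked landmarks and
## split into intact/broken runs by a relative intensity threshold;
## contacts are brightest paths between clicked endpoints.

#' Project a z-stack to a single frame
#'
#' @param zstack numeric array `H x W x Z` (or a list of matrices).
#' @param method `"max"` (default, maximum-intensity projection) or
#'   `"mean"`.
#' @return numeric `H x W` matrix.
#' @export
project_zstack <- function(zstack, method = c("max", "mean")) {
  method <- match.arg(method)
  if (is.list(zstack)) zstack <- simplify2array(zstack)
  if (is.matrix(zstack)) zstack <- array(zstack, c(dim(zstack), 1L))
  if (length(dim(zstack)) != 3 || dim(zstack)[3] < 1)
    stop("'zstack' must be a non-empty H x W x Z array")
  planes <- lapply(seq_len(dim(zstack)[3]), function(k) zstack[, , k])
  if (method == "max") Reduce(pmax, planes)
  else Reduce(`+`, planes) / length(planes)
}

#' Subtract the camera/stage background from a frame
#'
#' Subtracts the mean intensity of an area without sample and clamps
#' negative values at zero.
#'
#' @param frame numeric matrix.
#' @param bg either `"auto"` (mean of the lowest decile of pixel values) or
#'   a rectangle `c(x0, y0, x1, y1)` in 1-based pixel coordinates that must
#'   lie outside the group mask when one is supplied.
#' @param group_mask optional logical matrix; an explicit rectangle
#'   overlapping it is an error.
#' @return background-subtracted matrix (attribute `background` records the
#'   subtracted level).
#' @export
subtract_background <- function(frame, bg = "auto", group_mask = NULL) {
  stopifnot(is.matrix(frame))
  if (identical(bg, "auto")) {
    q <- stats::quantile(frame, 0.10)
    bgval <- mean(frame[frame <= q])
  } else {
    if (!is.numeric(bg) || length(bg) != 4)
      stop("'bg' must be \"auto\" or a rectangle c(x0, y0, x1, y1)")
    x <- sort(bg[c(1, 3)]); y <- sort(bg[c(2, 4)])
    if (x[1] < 1 || y[1] < 1 || x[2] > ncol(frame) || y[2] > nrow(frame))
      stop("background rectangle lies outside the image")
    if (!is.null(group_mask) && any(group_mask[y[1]:y[2], x[1]:x[2]]))
      stop("background rectangle overlaps the group mask")
    bgval <- mean(frame[y[1]:y[2], x[1]:x[2]])
  }
  out <- pmax(frame - bgval, 0)
  attr(out, "background") <- bgval
  out
}

## Largest connected component of a logical mask (8-connectivity).
.largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Segment the cell group from a background-subtracted frame
#'
#' Otsu threshold, hole filling, then the largest connected component.
#'
#' @param frame background-subtracted numeric matrix.
#' @return logical group mask.
#' @export
segment_group <- function(frame) {
  stopifnot(is.matrix(frame))
  mx <- max(frame)
  if (!is.finite(mx) || mx <= 0) stop("empty foreground: frame has no signal")
  norm <- frame / mx
  th <- EBImage::otsu(norm, range = c(0, 1))
  fg <- norm > th
  if (!any(fg)) stop("empty foreground after thresholding")
  filled <- EBImage::fillHull(EBImage::bwlabel(fg)) > 0
  .largest_component(filled)
}

#' Split a group mask into main body and labelled protrusions
#'
#' The main body is the largest component of the morphological opening of
#' the mask with a disc of the given radius; protrusions are the connected
#' components of the remainder with at least the minimum area, labelled in
#' decreasing area order. Smaller residues are merged back into the body,
#' so body and protrusions always partition the input mask.
#'
#' @param mask logical group mask.
#' @param pixel_size_um pixel calibration.
#' @param opening_radius_um disc radius of the opening (default 2 um).
#' @param min_protrusion_area_um2 minimum protrusion area (default 5 um2).
#' @return list with `body_mask` (logical), `protrusions` (integer label
#'   matrix) and `n_protrusions`.
#' @export
decompose_protrusions <- function(mask, pixel_size_um,
                                  opening_radius_um = 2,
                                  min_protrusion_area_um2 = 5) {
  stopifnot(is.matrix(mask))
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!any(mask)) stop("empty mask")
  r_px <- max(1L, as.integer(round(opening_radius_um / pixel_size_um)))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  opened <- EBImage::opening(mask, brush) > 0
  if (!any(opened))
    stop("opening erased the whole mask; try a smaller opening_radius_um")
  body <- .largest_component(opened)
  residue <- mask & !body
  lab <- EBImage::bwlabel(residue)
  prot <- matrix(0L, nrow(mask), ncol(mask))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0]) * pixel_size_um^2
    keep <- which(areas >= min_protrusion_area_um2)
    keep <- keep[order(areas[keep], decreasing = TRUE)]
    for (i in seq_along(keep)) prot[lab == keep[i]] <- i
    body <- body | (residue & prot == 0L)   # small residues back into body
  } else body <- body | residue
  list(body_mask = body, protrusions = prot,
       n_protrusions = max(prot))
}

#' Ordered boundary polyline of a mask
#'
#' Largest-object contour as an n x 2 (x, y) matrix, 1-based, oriented
#' clockwise on screen (y pointing down).
#' @param mask logical matrix.
#' @return n x 2 coordinate matrix.
#' @export
boundary_polyline <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (length(oc) == 0) stop("mask has no boundary")
  coords <- oc[[which.max(vapply(oc, nrow, 0L))]]
  xy <- cbind(coords[, 2] + 1, coords[, 1] + 1)   # (row0, col0) -> (x, y)
  if (polygon_signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), ,
                                            drop = FALSE]
  xy
}

## Inward unit normals of a closed boundary polyline (central-difference
## tangents; the sign is chosen so that a 2-px step along the normal lands
## inside the mask).
.boundary_normals <- function(xy, mask) {
  n <- nrow(xy)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, n, 2)
  clamp <- function(p) c(min(max(p[1], 1), w), min(max(p[2], 1), h))
  for (i in seq_len(n)) {
    ip <- if (i == 1) n else i - 1
    inx <- if (i == n) 1 else i + 1
    tg <- xy[inx, ] - xy[ip, ]
    len <- sqrt(sum(tg^2))
    if (len == 0) next
    nrm <- c(-tg[2], tg[1]) / len
    p <- clamp(round(xy[i, ] + 2 * nrm))
    if (!mask[p[2], p[1]]) nrm <- -nrm
    out[i, ] <- nrm
  }
  out
}

## Pull each boundary vertex `offset` pixels inward along its normal; the
## peripheral actin bundle runs just inside the cell edge, so the cable is
## sampled there.
.pull_inward <- function(xy, mask, offset, normals = NULL) {
  if (offset <= 0) return(xy)
  if (is.null(normals)) normals <- .boundary_normals(xy, mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- xy
  for (i in seq_len(nrow(xy))) {
    cand <- round(xy[i, ] + offset * normals[i, ])
    cand[1] <- min(max(cand[1], 1), w); cand[2] <- min(max(cand[2], 1), h)
    if (mask[cand[2], cand[1]]) out[i, ] <- cand
  }
  out
}

## Band intensity across the rim: mean of the 3 pixels sampled at offsets
## (offset - 1, offset, offset + 1) along the inward normal of each vertex.
## Sampling across (not along) the rim keeps intact/broken transitions
## sharp in the tangential direction.
.band_profile_intensity <- function(frame, xy, normals, offset) {
  h <- nrow(frame); w <- ncol(frame)
  vapply(seq_len(nrow(xy)), function(i) {
    vals <- vapply(-1:1, function(k) {
      p <- round(xy[i, ] + (offset + k) * normals[i, ])
      frame[min(max(p[2], 1), h), min(max(p[1], 1), w)]
    }, 0)
    mean(vals)
  }, 0)
}

## Merge runs shorter than min_run into their neighbours (speckle denoising
## of the intact/broken labelling along the rim).
.merge_short_runs <- function(labels, min_run = 3L) {
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1) return(labels)
    short <- which(r$lengths < min_run)
    if (length(short) == 0) return(labels)
    j <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    labels[starts[j]:ends[j]] <- !r$values[j]
  }
}

#' Trace the supracellular cable along the body boundary
#'
#' Splits the clockwise boundary polyline of the body mask at the clicked
#' landmarks (snapped to the boundary) into per-cell arcs, then labels
#' maximal runs of boundary pixels whose local rim intensity (3x3 band
#' mean) reaches `cable_intensity_threshold` times the group mean as intact
#' cable segments, and runs below it as broken sections. Runs shorter than
#' 3 boundary pixels are absorbed into their neighbours before labelling.
#'
#' @param frame background-subtracted numeric matrix.
#' @param body_mask logical main-body mask.
#' @param landmarks list with `boundary_points` (n x 2 matrix of clicked
#'   (x, y) junctions, clockwise, starting beside the leader protrusion).
#' @param pixel_size_um pixel calibration.
#' @param cable_intensity_threshold fraction of the group-mean intensity
#'   (default 0.5).
#' @param snap_dist_px maximum landmark-to-boundary distance (default 3).
#' @param band_offset_px how far inside the boundary the cable band is
#'   sampled (default 4 px; the peripheral bundle runs just inside the
#'   cell edge).
#' @return object of class `cable_trace`: lists `cable_segments` and
#'   `broken_segments` (see [region_set()]), `threshold`, `rim_length_um`.
#' @export
trace_cables <- function(frame, body_mask, landmarks, pixel_size_um,
                         cable_intensity_threshold = 0.5,
                         snap_dist_px = 3, band_offset_px = 4) {
  stopifnot(is.matrix(frame), is.matrix(body_mask))
  pts <- landmarks$boundary_points
  if (is.null(pts) || nrow(pts) < 1) stop("landmarks have no boundary points")
  xy <- boundary_polyline(body_mask)
  nvert <- nrow(xy)
  idx <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d2 <- (xy[, 1] - pts[i, 1])^2 + (xy[, 2] - pts[i, 2])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > snap_dist_px)
      stop(sprintf("landmark %d is %.1f px from the body boundary (max %g)",
                   i, sqrt(d2[j]), snap_dist_px))
    idx[i] <- j
  }
  ## rotate the polyline so it starts at the first landmark
  shift <- idx[1] - 1L
  ord <- ((seq_len(nvert) - 1L + shift) %% nvert) + 1L
  xy <- xy[ord, , drop = FALSE]
  idx <- ((idx - 1L - shift) %% nvert) + 1L
  idx <- sort(idx)
  n_cells <- length(idx)

  normals <- .boundary_normals(xy, body_mask)
  xy_in <- .pull_inward(xy, body_mask, band_offset_px, normals)
  intens <- .band_profile_intensity(frame, xy, normals, band_offset_px)
  thr <- cable_intensity_threshold * mean(frame[body_mask])
  ## the exact pixels sampled across the band, kept with each segment so
  ## intensity read-outs average over the same band
  band_pts <- lapply(seq_len(nvert), function(i) {
    t(vapply(-1:1, function(k) {
      p <- round(xy[i, ] + (band_offset_px + k) * normals[i, ])
      c(min(max(p[1], 1), ncol(frame)), min(max(p[2], 1), nrow(frame)))
    }, c(0, 0)))
  })
  cell_of <- rep(n_cells, nvert)
  for (k in seq_len(n_cells - 1))
    cell_of[idx[k]:(idx[k + 1] - 1L)] <- k
  if (n_cells >= 1) cell_of[idx[n_cells]:nvert] <- n_cells
  intact <- .merge_short_runs(intens >= thr)

  run_id <- cumsum(c(TRUE, diff(cell_of) != 0 | diff(intact) != 0))
  cable_segments <- list(); broken_segments <- list()
  for (rid in unique(run_id)) {
    vi <- which(run_id == rid)
    seg <- list(cell = cell_of[vi[1]],
                intact = intact[vi[1]],
                coords = xy_in[vi, , drop = FALSE],
                band_coords = do.call(rbind, band_pts[vi]),
                length_um = polyline_length_px(xy[vi, , drop = FALSE]) *
                  pixel_size_um,
                mean_intensity = mean(intens[vi]))
    if (seg$intact) cable_segments[[length(cable_segments) + 1]] <- seg
    else broken_segments[[length(broken_segments) + 1]] <- seg
  }
  total <- sum(vapply(c(cable_segments, broken_segments),
                      function(s) s$length_um, 0))
  structure(list(cable_segments = cable_segments,
                 broken_segments = broken_segments,
                 threshold = thr, rim_length_um = total,
                 n_cells = n_cells),
            class = "cable_trace")
}

#' @export
print.cable_trace <- function(x, ...) {
  cat(sprintf(
    "cable_trace: %d intact + %d broken segment(s) over %d cells, rim %.1f um\n",
    length(x$cable_segments), length(x$broken_segments), x$n_cells,
    x$rim_length_um))
  invisible(x)
}

## 8-connected shortest (minimum-cost) path between two in-mask pixels.
## Edge cost = step length x mean of the endpoint pixel costs, plus a tiny
## pull toward the straight chord so that cost ties resolve geometrically.
.brightest_path <- function(frame, mask, p0, p1) {
  h <- nrow(frame); w <- ncol(frame)
  cost <- 1 / (1 + frame)
  ## distance of every pixel to the chord p0-p1 (0 when p0 == p1)
  g <- coord_grids(h, w)
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  dchord <- if (len == 0) sqrt((g$x - p0[1])^2 + (g$y - p0[2])^2)
            else abs(v[2] * (g$x - p0[1]) - v[1] * (g$y - p0[2])) / len
  cost <- cost + 1e-6 * dchord
  idx <- which(mask)
  vid <- matrix(NA_integer_, h, w)
  vid[idx] <- seq_along(idx)
  ys <- ((idx - 1) %% h) + 1; xs <- ((idx - 1) %/% h) + 1
  edges <- NULL; weights <- NULL
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nx <- xs + d[1]; ny <- ys + d[2]
    ok <- nx >= 1 & nx <= w & ny >= 1 & ny <= h
    ok[ok] <- mask[cbind(ny[ok], nx[ok])]
    if (!any(ok)) next
    a <- vid[cbind(ys[ok], xs[ok])]
    b <- vid[cbind(ny[ok], nx[ok])]
    step <- sqrt(sum(d^2))
    wgt <- step * (cost[cbind(ys[ok], xs[ok])] + cost[cbind(ny[ok], nx[ok])]) / 2
    edges <- c(edges, rbind(a, b))
    weights <- c(weights, wgt)
  }
  gph <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  s <- vid[p0[2], p0[1]]; t <- vid[p1[2], p1[1]]
  if (s == t) return(matrix(p0, 1, 2))
  sp <- igraph::shortest_paths(gph, from = s, to = t, weights = weights)
  path <- as.integer(sp$vpath[[1]])
  cbind(xs[path], ys[path])
}

#' Label cell-cell contacts from clicked endpoint pairs
#'
#' For each endpoint pair, finds the brightest path between the endpoints
#' (minimum-cost path with pixel cost `1/(1 + intensity)`; cost ties are
#' broken toward the straight chord), dilates it to a ribbon of the given
#' half-width (Euclidean disc) clipped to the body mask, and reports mean
#' intensity and area per contact.
#'
#' @param frame background-subtracted numeric matrix.
#' @param body_mask logical main-body mask.
#' @param contact_endpoints list of `list(start = c(x, y), end = c(x, y))`
#'   pairs (or 2 x 2 matrices, rows = start/end); both points must lie
#'   inside the body mask.
#' @param pixel_size_um pixel calibration.
#' @param half_width_px ribbon half-width in pixels (default 2).
#' @return list of contact polylines (n x 2 coords matrices) with
#'   attributes `mean_intensity`, `area_um2` and `mask`.
#' @export
label_contacts <- function(frame, body_mask, contact_endpoints,
                           pixel_size_um, half_width_px = 2) {
  stopifnot(is.matrix(frame), is.matrix(body_mask))
  out <- list()
  for (i in seq_along(contact_endpoints)) {
    ep <- contact_endpoints[[i]]
    if (is.matrix(ep)) ep <- list(start = ep[1, ], end = ep[2, ])
    p0 <- round(as.numeric(ep$start)); p1 <- round(as.numeric(ep$end))
    for (p in list(p0, p1))
      if (p[1] < 1 || p[2] < 1 || p[1] > ncol(frame) || p[2] > nrow(frame) ||
          !body_mask[p[2], p[1]])
        stop(sprintf("contact %d endpoint (%d, %d) is outside the body mask",
                     i, p[1], p[2]))
    path <- .brightest_path(frame, body_mask, p0, p1)
    ribbon <- polylines_to_mask(list(path), dim(frame),
                                halfwidth = half_width_px,
                                clip = body_mask, shape = "disc")
    attr(path, "mean_intensity") <- mean(frame[ribbon])
    attr(path, "area_um2") <- sum(ribbon) * pixel_size_um^2
    attr(path, "mask") <- ribbon
    out[[i]] <- path
  }
  out
}

#' Full semi-automatic region extraction for one frame
#'
#' Chains [segment_group()], [decompose_protrusions()], [trace_cables()]
#' and [label_contacts()] into a [region_set()], mirroring the
#' three-step workflow: automatic group/protrusion decomposition plus
#' landmark-guided cable and contact labelling.
#'
#' @param frame background-subtracted numeric matrix.
#' @param landmarks list with `boundary_points` and `contact_endpoints`.
#' @param pixel_size_um pixel calibration.
#' @param opening_radius_um,min_protrusion_area_um2 see
#'   [decompose_protrusions()].
#' @param cable_intensity_threshold,snap_dist_px see [trace_cables()].
#' @param contact_half_width_px see [label_contacts()].
#' @return a [region_set()].
#' @export
extract_regions <- function(frame, landmarks, pixel_size_um,
                            opening_radius_um = 2,
                            min_protrusion_area_um2 = 5,
                            cable_intensity_threshold = 0.5,
                            snap_dist_px = 3,
                            contact_half_width_px = 2) {
  msk <- segment_group(frame)
  dec <- decompose_protrusions(msk, pixel_size_um, opening_radius_um,
                               min_protrusion_area_um2)
  tr <- trace_cables(frame, dec$body_mask, landmarks, pixel_size_um,
                     cable_intensity_threshold, snap_dist_px)
  contacts <- if (length(landmarks$contact_endpoints %||% list()) > 0)
    label_contacts(frame, dec$body_mask, landmarks$contact_endpoints,
                   pixel_size_um, contact_half_width_px)
  else list()
  region_set(body_mask = dec$body_mask, protrusions = dec$protrusions,
             cable_segments = tr$cable_segments,
             broken_segments = tr$broken_segments,
             contacts = contacts, cell_count = tr$n_cells,
             pixel_size_um = pixel_size_um)
}
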
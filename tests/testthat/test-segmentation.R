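## Segmentation: projection, background, group mask, protrusion/body split,
## cable tracing, contact labelling.

test_that("z-projection matches the per-pixel definition", {
  z1 <- array(runif(25), c(5, 5, 1))
  expect_identical(project_zstack(z1), z1[, , 1])

  z2 <- array(c(rep(0, 25), rep(5, 25)), c(5, 5, 2))
  expect_true(all(project_zstack(z2) == 5))
  expect_true(all(project_zstack(z2, "mean") == 2.5))

  set.seed(3)
  z <- array(rnorm(5 * 6 * 4), c(5, 6, 4))
  expect_equal(project_zstack(z), apply(z, 1:2, max))
  expect_equal(project_zstack(z, "mean"), apply(z, 1:2, mean))

  expect_error(project_zstack(array(0, c(2, 2, 0))), "non-empty")
})

test_that("background subtraction recovers the clean signal", {
  expect_true(all(subtract_background(matrix(7, 10, 10),
                                      bg = c(1, 1, 3, 3)) == 0))

  set.seed(4)
  signal <- matrix(0, 20, 20); signal[8:14, 8:14] <- runif(49, 10, 30)
  frame <- signal + 50
  out <- subtract_background(frame, bg = c(1, 1, 5, 5))
  expect_equal(out, signal, ignore_attr = TRUE)

  gm <- signal > 0
  expect_error(subtract_background(frame, bg = c(7, 7, 12, 12),
                                   group_mask = gm), "overlaps")
  ## auto mode on a frame dominated by background
  out2 <- subtract_background(frame, bg = "auto")
  expect_equal(attr(out2, "background"), 50)
})

test_that("group segmentation recovers the exact synthetic mask", {
  spec <- synthetic_spec(noise_sd = 0, cable_gap_fraction = 0.1, seed = 7)
  sim <- simulate_cluster(spec)
  msk <- segment_group(get_frame(sim$stack, 1))
  expect_identical(msk, sim$truth$group_mask)

  ## two clusters: the larger one wins
  fr <- matrix(0, 60, 60)
  fr[10:30, 10:30] <- 100   # 441 px
  fr[40:50, 40:50] <- 100   # 121 px
  msk2 <- segment_group(fr)
  expect_true(all(msk2[10:30, 10:30]))
  expect_false(any(msk2[40:50, 40:50]))

  expect_error(segment_group(matrix(0, 10, 10)), "empty foreground")
})

test_that("protrusion decomposition obeys its area bookkeeping", {
  px <- 0.2
  g <- expand.grid(y = 1:80, x = 1:80)
  disk <- matrix((g$x - 40)^2 + (g$y - 40)^2 <= 20^2, 80, 80)
  dec <- decompose_protrusions(disk, px)
  expect_equal(dec$n_protrusions, 0)
  expect_identical(dec$body_mask, disk)

  ## disk plus an 8 x 2 um finger, opening radius 2 um -> one protrusion
  finger <- matrix(g$x > 60 & g$x <= 60 + 40 & abs(g$y - 40) <= 5, 80, 80)
  mask <- disk | finger
  dec <- decompose_protrusions(mask, px, opening_radius_um = 2)
  expect_equal(dec$n_protrusions, 1)
  expect_identical(dec$body_mask | dec$protrusions > 0, mask)
  expect_false(any(dec$body_mask & dec$protrusions > 0))

  expect_error(decompose_protrusions(finger & g$x > 95, px),
               "empty mask")
  tiny <- matrix(FALSE, 40, 40); tiny[20, 20] <- TRUE
  expect_error(decompose_protrusions(tiny, px, opening_radius_um = 2),
               "smaller")
})

test_that("opening-based split equals the brute-force opening on small masks", {
  set.seed(9)
  m <- matrix(FALSE, 48, 48)
  m[12:36, 12:36] <- TRUE
  m[20:24, 37:46] <- TRUE
  m[cbind(sample(12:36, 15, TRUE), sample(12:36, 15, TRUE))] <- TRUE
  brush <- EBImage::makeBrush(9, "disc")
  expect_identical(EBImage::opening(m, brush) > 0, oracle_opening(m, brush))
})

test_that("loose fixture protrusions are recovered with matched labels", {
  sim <- simulate_cluster(fixture_spec("loose"))
  msk <- segment_group(get_frame(sim$stack, 1))
  dec <- decompose_protrusions(msk, 0.2)
  expect_equal(dec$n_protrusions, 3)
  for (i in 1:3) {
    rec <- dec$protrusions == i
    ovl <- vapply(1:3, function(j)
      mask_overlap(rec, sim$truth$region_set$protrusions == j), 0)
    expect_gte(max(ovl), 0.8)
  }
})

test_that("cable tracing splits the rim at landmarks and finds gaps", {
  ## uniformly bright rim: one intact segment per cell, zero broken length
  sim <- simulate_cluster(synthetic_spec(noise_sd = 0, seed = 21,
    protrusions = data.frame(base_angle_deg = numeric(0),
                             length_um = numeric(0), width_um = numeric(0))))
  fr <- get_frame(sim$stack, 1)
  tr <- trace_cables(fr, sim$truth$region_set$body_mask,
                     sim$truth$landmarks, 0.2)
  expect_length(tr$cable_segments, 6)
  expect_length(tr$broken_segments, 0)

  ## ~10% dim gap: broken fraction 0.10 within a few rim pixels
  spec <- synthetic_spec(noise_sd = 0, cable_gap_fraction = 0.10, seed = 22,
    protrusions = data.frame(base_angle_deg = numeric(0),
                             length_um = numeric(0), width_um = numeric(0)))
  sim <- simulate_cluster(spec)
  regions <- extract_regions(get_frame(sim$stack, 1), sim$truth$landmarks, 0.2)
  expect_lt(abs(cable_discontinuity(regions) - 0.10), 0.02)

  ## tight fixture: per-cell segment counts equal the ground truth
  sim <- simulate_cluster(fixture_spec("tight"))
  regions <- extract_regions(get_frame(sim$stack, 1), sim$truth$landmarks, 0.2)
  count_per_cell <- function(segs, nc) {
    out <- integer(nc)
    for (s in segs) out[s$cell] <- out[s$cell] + 1L
    out
  }
  rec <- count_per_cell(c(regions$cable_segments, regions$broken_segments), 6)
  tru <- count_per_cell(c(sim$truth$region_set$cable_segments,
                          sim$truth$region_set$broken_segments), 6)
  expect_identical(rec, tru)

  ## a landmark far from the boundary is reported by index
  badlm <- sim$truth$landmarks
  badlm$boundary_points[2, ] <- c(5, 5)
  expect_error(
    trace_cables(get_frame(sim$stack, 1),
                 segment_group(get_frame(sim$stack, 1)), badlm, 0.2),
    "landmark 2")
})

test_that("rim segments tile the boundary exactly once", {
  sim <- simulate_cluster(fixture_spec("balanced"))
  regions <- extract_regions(get_frame(sim$stack, 1), sim$truth$landmarks, 0.2)
  segs <- c(regions$cable_segments, regions$broken_segments)
  n_seg_vertices <- sum(vapply(segs, function(s) nrow(s$coords), 0L))
  xy <- boundary_polyline(regions$body_mask)
  expect_equal(n_seg_vertices, nrow(xy))
})

test_that("contact labelling follows the brightest ridge", {
  frame <- matrix(1, 30, 30); frame[15, ] <- 100
  msk <- matrix(TRUE, 30, 30)
  p <- label_contacts(frame, msk, list(list(start = c(3, 15),
                                            end = c(27, 15))), 0.2)
  expect_true(all(p[[1]][, 2] == 15))

  ## coincident endpoints: single-pixel contact, Euclidean-disc ribbon
  p2 <- label_contacts(frame, msk, list(list(start = c(10, 10),
                                             end = c(10, 10))), 0.2)
  expect_equal(nrow(p2[[1]]), 1)
  expect_equal(attr(p2[[1]], "area_um2"), 13 * 0.2^2)

  ## zero intensity: ties broken toward the straight chord
  p3 <- label_contacts(matrix(0, 40, 40), matrix(TRUE, 40, 40),
                       list(list(start = c(5, 5), end = c(35, 20))), 0.2)
  v <- c(30, 15)
  d <- abs(v[2] * (p3[[1]][, 1] - 5) - v[1] * (p3[[1]][, 2] - 5)) /
    sqrt(sum(v^2))
  expect_lt(max(d), 1)

  expect_error(
    label_contacts(frame, frame > 50, list(list(start = c(1, 1),
                                                end = c(15, 15))), 0.2),
    "outside the body mask")
})

test_that("a 90-degree rotation rotates all recovered regions", {
  sim <- simulate_cluster(fixture_spec("balanced"))
  fr <- get_frame(sim$stack, 1)
  h <- nrow(fr)
  lm <- sim$truth$landmarks
  reg1 <- extract_regions(fr, lm, 0.2)

  fr_rot <- rot90_cw(fr)
  lm_rot <- list(
    boundary_points = rot90_cw_xy(lm$boundary_points, h),
    contact_endpoints = lapply(lm$contact_endpoints, function(ep)
      list(start = rot90_cw_xy(rbind(ep$start), h)[1, ],
           end = rot90_cw_xy(rbind(ep$end), h)[1, ])))
  reg2 <- extract_regions(fr_rot, lm_rot, 0.2)

  expect_gte(mask_overlap(rot90_cw(reg1$body_mask), reg2$body_mask), 0.95)
  n1 <- max(reg1$protrusions); n2 <- max(reg2$protrusions)
  expect_equal(n1, n2)
  for (i in seq_len(n1)) {
    rot_i <- rot90_cw(reg1$protrusions == i)
    ovl <- vapply(seq_len(n2), function(j)
      mask_overlap(rot_i, reg2$protrusions == j), 0)
    expect_gte(max(ovl), 0.95)
  }
})
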
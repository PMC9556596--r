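## PIV displacement estimation, interpolation, smoothing, divergence,
## direction classification and flow summaries.

test_cfg <- function(...) piv_config(pixel_size_um = 0.2,
                                     frame_interval_s = 10, ...)

test_that("identical frames give zero displacement at full correlation", {
  set.seed(41)
  f <- matrix(100 * exp(rnorm(60 * 60, 0, 0.3)), 60, 60)
  est <- piv_frame_pair(f, f, matrix(TRUE, 60, 60), test_cfg())
  expect_gt(nrow(est), 10)
  expect_true(all(est$dx_px == 0 & est$dy_px == 0))
  expect_true(all(abs(est$corr - 1) < 1e-12))
})

test_that("integer translations are recovered exactly", {
  pr <- speckle_pair(64, 64, dx = 3, dy = 0)
  cfg <- test_cfg(source_side_px = 5L, search_side_px = 13L)
  est <- piv_frame_pair(pr$f1, pr$f2, matrix(TRUE, 64, 64), cfg)
  expect_gt(nrow(est), 20)
  expect_true(all(est$dx_px == 3 & est$dy_px == 0))
  expect_true(all(est$corr > 0.999))
  ## px/frame -> um/min conversion: 3 px * 0.2 um * 60/10 s
  expect_equal(est$u, rep(3 * 0.2 * 6, nrow(est)))

  pr2 <- speckle_pair(64, 64, dx = -2, dy = 4, seed = 13)
  est2 <- piv_frame_pair(pr2$f1, pr2$f2, matrix(TRUE, 64, 64), cfg)
  expect_true(all(est2$dx_px == -2 & est2$dy_px == 4))
})

test_that("windowed estimates equal the brute-force ZNCC oracle", {
  set.seed(47)
  f1 <- matrix(100 * exp(rnorm(48 * 48, 0, 0.3)), 48, 48)
  f2 <- matrix(100 * exp(rnorm(48 * 48, 0, 0.3)), 48, 48)
  ## correlated mixture so coefficients span the threshold
  f2 <- 0.6 * f1 + 0.4 * f2
  cfg <- test_cfg(source_side_px = 7L, search_side_px = 13L,
                  grid_stride_px = 5L)
  est <- piv_frame_pair(f1, f2, matrix(TRUE, 48, 48), cfg)
  expect_gt(nrow(est), 5)
  hs <- 3L; m <- 3L
  for (i in seq_len(nrow(est))) {
    o <- oracle_piv_point(f1, f2, est$x[i], est$y[i], hs, m)
    expect_equal(c(est$dx_px[i], est$dy_px[i]), c(o$dx, o$dy))
    expect_lt(abs(est$corr[i] - o$corr), 1e-9)
  }
})

test_that("uncorrelated noise frames are rejected at c0 = 0.5", {
  set.seed(42)
  f1 <- matrix(runif(120 * 120), 120, 120)
  f2 <- matrix(runif(120 * 120), 120, 120)
  cfg <- test_cfg()
  n_candidates <- length(seq.int(4, 120 - 3, by = cfg$grid_stride_px))^2
  est <- piv_frame_pair(f1, f2, matrix(TRUE, 120, 120), cfg)
  expect_lt(nrow(est) / n_candidates, 0.10)
})

test_that("dense interpolation averages with normalised Gaussian weights", {
  msk <- matrix(TRUE, 40, 40)
  cfg <- test_cfg()
  est <- data.frame(x = c(10, 14, 30), y = c(10, 30, 20),
                    dx_px = 0, dy_px = 0, u = 2, v = 1, corr = 0.9)
  fld <- interpolate_dense(est, msk, cfg)
  expect_true(all(fld$u[fld$valid] == 2))
  expect_true(all(fld$v[fld$valid] == 1))

  ## single estimate: valid only within the kernel radius (3 um = 15 px)
  est1 <- est[1, ]
  fld1 <- interpolate_dense(est1, msk, cfg)
  g <- expand.grid(y = 1:40, x = 1:40)
  d <- sqrt((g$x - 10)^2 + (g$y - 10)^2)
  expect_true(all(fld1$valid[d > 15.5]) == FALSE)
  expect_true(all(fld1$valid[d <= 14.5]))
  expect_true(all(fld1$u[fld1$valid] == 2))

  ## two estimates, symmetric about the midpoint: arithmetic mean
  est2 <- data.frame(x = c(14, 26), y = c(20, 20), dx_px = 0, dy_px = 0,
                     u = c(1, 3), v = c(-2, 6), corr = 0.9)
  fld2 <- interpolate_dense(est2, msk, cfg)
  expect_equal(fld2$u[20, 20], 2)
  expect_equal(fld2$v[20, 20], 2)

  ## zero kept estimates: all-invalid field, not an error
  none <- est2[integer(0), ]
  fld0 <- interpolate_dense(none, msk, cfg)
  expect_false(any(fld0$valid))
})

test_that("temporal smoothing is a normalised low-pass filter", {
  cfg <- test_cfg()
  const <- replicate(4, uniform_field(1.5, -0.5), simplify = FALSE)
  sm <- temporal_smooth(const, cfg)
  for (f in sm) {
    expect_true(all(abs(f$u - 1.5) < 1e-12))
    expect_true(all(abs(f$v + 0.5) < 1e-12))
  }

  ## impulse: spread, but every output is a convex combination
  imp <- list(uniform_field(0, 0), uniform_field(1, 0), uniform_field(0, 0))
  sm2 <- temporal_smooth(imp, cfg)
  expect_gt(sm2[[1]]$u[1, 1], 0)
  expect_lt(sm2[[2]]$u[1, 1], 1)
  expect_true(all(vapply(sm2, function(f) f$u[1, 1], 0) <= 1))

  ## alternating series: amplitude strictly reduced
  alt <- list(uniform_field(1, 0), uniform_field(-1, 0), uniform_field(1, 0),
              uniform_field(-1, 0))
  sm3 <- temporal_smooth(alt, cfg)
  mid <- vapply(sm3[2:3], function(f) abs(f$u[1, 1]), 0)
  expect_true(all(mid < 1))
})

test_that("central-difference divergence is exact for linear fields", {
  h <- 20; w <- 20; px <- 0.5
  g <- list(x = matrix(rep(1:w, each = h), h, w),
            y = matrix(rep(1:h, w), h, w))
  valid <- matrix(TRUE, h, w)

  unif <- flow_field(matrix(3, h, w), matrix(-2, h, w), valid)
  dv <- flow_divergence(unif, px)
  expect_true(all(dv$div[dv$valid] == 0))

  a <- 0.7; b <- -0.3
  lin <- flow_field(a * g$x * px, b * g$y * px, valid)
  dv2 <- flow_divergence(lin, px)
  expect_true(all(abs(dv2$div[dv2$valid] - (a + b)) < 1e-12))

  ## linearity on shared valid pixels
  f1 <- flow_field(matrix(rnorm(h * w), h, w), matrix(rnorm(h * w), h, w),
                   valid)
  f2 <- flow_field(matrix(rnorm(h * w), h, w), matrix(rnorm(h * w), h, w),
                   valid)
  al <- 2.5; be <- -1.25
  combo <- flow_field(al * f1$u + be * f2$u, al * f1$v + be * f2$v, valid)
  d1 <- flow_divergence(f1, px); d2 <- flow_divergence(f2, px)
  dc <- flow_divergence(combo, px)
  expect_equal(dc$div[dc$valid],
               al * d1$div[dc$valid] + be * d2$div[dc$valid])
})

test_that("retrograde and anterograde labels follow the motion cosine", {
  fld <- flow_field(matrix(c(-1, 1, 0, 0), 2, 2),
                    matrix(c(0, 0, 1, 0), 2, 2),
                    matrix(TRUE, 2, 2))
  lab <- classify_direction(fld, c(1, 0))
  expect_identical(lab[1, 1], "retrograde")
  expect_identical(lab[2, 1], "anterograde")
  expect_identical(lab[1, 2], "unclassified")  # perpendicular
  expect_identical(lab[2, 2], "unclassified")  # zero vector
  expect_error(classify_direction(fld, c(0, 0)), "zero")

  ## negating the motion vector swaps the two labels at every pixel
  set.seed(8)
  big <- flow_field(matrix(rnorm(400), 20, 20), matrix(rnorm(400), 20, 20),
                    matrix(TRUE, 20, 20))
  l1 <- classify_direction(big, c(0.4, -1))
  l2 <- classify_direction(big, -c(0.4, -1))
  expect_identical(l1 == "retrograde", l2 == "anterograde")
  expect_identical(l1 == "anterograde", l2 == "retrograde")
})

test_that("flow occurrence counts the strong-flow area fraction", {
  truth <- build_geometry(fixture_spec("tight"))
  rs <- truth$region_set
  masks <- region_masks(rs)
  h <- nrow(rs$body_mask); w <- ncol(rs$body_mask)
  valid <- matrix(TRUE, h, w)

  fast <- flow_field(matrix(2, h, w), matrix(0, h, w), valid)
  occ <- flow_occurrence(list(fast), rs, 10,
                         strong_speed_threshold_um_per_min = 1)
  expect_true(all(occ$per_frame$fraction == 1))

  slow <- flow_field(matrix(0.1, h, w), matrix(0, h, w), valid)
  occ0 <- flow_occurrence(list(slow), rs, 10,
                          strong_speed_threshold_um_per_min = 1)
  expect_true(all(occ0$per_frame$fraction == 0))

  ## exactly half of the cable region above threshold
  u <- matrix(0, h, w)
  cab <- which(masks$cables)
  u[cab[seq_len(floor(length(cab) / 2))]] <- 2
  half <- flow_field(u, matrix(0, h, w), valid)
  occh <- flow_occurrence(list(half), rs, 10,
                          strong_speed_threshold_um_per_min = 1)
  cable_frac <- occh$per_frame$fraction[occh$per_frame$region == "cables"]
  expect_equal(cable_frac, floor(length(cab) / 2) / length(cab))
})

test_that("angle histograms put anterograde at 90 and retrograde at 270", {
  h <- 10; w <- 10
  msk <- matrix(TRUE, h, w)
  axis <- c(1, 1) / sqrt(2)
  along <- flow_field(matrix(axis[1], h, w), matrix(axis[2], h, w), msk)
  hst <- angle_histogram(along, msk, axis)
  expect_equal(sum(hst$counts), h * w)
  bin90 <- findInterval(90, hst$breaks_deg)
  expect_equal(hst$counts[bin90], h * w)

  against <- flow_field(matrix(-axis[1], h, w), matrix(-axis[2], h, w), msk)
  hst2 <- angle_histogram(against, msk, axis)
  bin270 <- findInterval(270, hst2$breaks_deg)
  expect_equal(hst2$counts[bin270], h * w)

  zero <- flow_field(matrix(0, h, w), matrix(0, h, w), msk)
  expect_equal(sum(angle_histogram(zero, msk, axis)$counts), 0)
})

test_that("sink-signal correlation is a rank correlation with guards", {
  set.seed(51)
  h <- 12; w <- 12
  cable <- matrix(FALSE, h, w); cable[4:9, 4:9] <- TRUE
  divs <- lapply(1:6, function(i) {
    f <- flow_field(matrix(rnorm(h * w, sd = i), h, w),
                    matrix(rnorm(h * w, sd = i), h, w),
                    matrix(TRUE, h, w))
    flow_divergence(f, 0.2)
  })
  ## second channel constructed as the per-frame mean negative divergence
  ch <- lapply(divs, function(d) {
    m <- cable & d$valid
    matrix(mean(-d$div[m]), h, w)
  })
  out <- sink_signal_correlation(divs, ch, cable)
  expect_true(out$defined)
  expect_equal(out$rho, 1)

  ## independent noise series: weak correlation
  set.seed(52)
  divs2 <- lapply(1:50, function(i) {
    f <- flow_field(matrix(rnorm(h * w), h, w), matrix(rnorm(h * w), h, w),
                    matrix(TRUE, h, w))
    flow_divergence(f, 0.2)
  })
  ch2 <- lapply(1:50, function(i) matrix(runif(h * w), h, w))
  out2 <- sink_signal_correlation(divs2, ch2, cable)
  expect_lt(abs(out2$rho), 0.3)

  ## constant myosin series: undefined, flagged
  ch3 <- lapply(1:6, function(i) matrix(1, h, w))
  out3 <- sink_signal_correlation(divs, ch3, cable)
  expect_false(out3$defined)
  expect_true(is.na(out3$rho))
})

test_that("the rendered sink movie yields the analytic divergence", {
  sim <- simulate_cluster(fixture_spec("sink_pair"))
  f1 <- get_frame(sim$stack, 1); f2 <- get_frame(sim$stack, 2)
  mask <- sim$truth$group_mask
  cfg <- test_cfg(source_side_px = 5L, search_side_px = 13L)
  est <- piv_frame_pair(f1, f2, mask, cfg)
  fld <- interpolate_dense(est, mask, cfg)
  dv <- flow_divergence(fld, 0.2)
  interior <- EBImage::erode(mask, EBImage::makeBrush(21, "disc")) > 0
  sel <- dv$valid & interior
  k <- fixture_spec("sink_pair")$flow_magnitude_um_per_min
  expect_lt(abs(mean(dv$div[sel]) - (-2 * k)) / (2 * k), 0.25)
})
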
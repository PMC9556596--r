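## Morphometrics, intensities, bleach correction, classification.

fake_segment <- function(cell, intact, length_um) {
  list(cell = cell, intact = intact,
       coords = cbind(seq_len(2), 1), length_um = length_um)
}

fake_region_set <- function(broken_um, intact_um) {
  body <- matrix(FALSE, 10, 10); body[3:8, 3:8] <- TRUE
  region_set(body_mask = body, protrusions = matrix(0L, 10, 10),
             cable_segments = lapply(intact_um, fake_segment,
                                     cell = 1, intact = TRUE),
             broken_segments = lapply(broken_um, fake_segment,
                                      cell = 1, intact = FALSE),
             cell_count = 1, pixel_size_um = 1)
}

test_that("classification follows the printed band edges", {
  expect_identical(classify_group(0.05, 0.05), "tight")
  expect_identical(classify_group(0.30, 0.30), "loose")
  expect_identical(classify_group(0.15, 0.15), "balanced")
  expect_identical(classify_group(0.05, 0.30), "unclassified")

  ## inclusivity at the exact edges
  expect_identical(classify_group(0.10, 0.05), "unclassified") # not tight
  expect_identical(classify_group(0.05, 0.08), "tight")        # disc <= 8%
  expect_identical(classify_group(0.25, 0.25), "unclassified") # not loose
  expect_identical(classify_group(0.26, 0.25), "loose")        # disc >= 25%
  expect_identical(classify_group(0.10, 0.081), "balanced")
  expect_identical(classify_group(0.25, 0.249), "balanced")

  ## every point of the unit square gets exactly one category
  grid <- expand.grid(f = seq(0, 1, by = 0.02), d = seq(0, 1, by = 0.02))
  cats <- classify_group(grid$f, grid$d)
  expect_true(all(cats %in% c("tight", "loose", "balanced", "unclassified")))
  expect_length(cats, nrow(grid))

  expect_error(classifier_config(tight_max_protrusion_frac = 0.3,
                                 loose_min_protrusion_frac = 0.2),
               "below loose")
})

test_that("relative region intensities are normalised by the group mean", {
  truth <- build_geometry(fixture_spec("tight"))
  uniform <- matrix(5, 160, 160)
  ri <- region_mean_intensity(uniform, truth$region_set)
  expect_equal(unname(ri$relative), rep(1, 3))

  ## generator with a 3:1 cable:protrusion contrast is recovered within 5%
  spec <- synthetic_spec(noise_sd = 0, seed = 31,
                         region_intensity = list(cable = 300,
                                                 protrusion = 100))
  sim <- simulate_cluster(spec)
  fr <- get_frame(sim$stack, 1)
  regions <- extract_regions(fr, sim$truth$landmarks, 0.2)
  ri <- region_mean_intensity(fr, regions)
  ratio <- ri$relative[["cables"]] / ri$relative[["protrusions"]]
  expect_lt(abs(ratio - 3) / 3, 0.05)

  ## empty class flagged absent, not zero
  rs0 <- fake_region_set(numeric(0), c(10))
  ri0 <- region_mean_intensity(matrix(1, 10, 10), rs0)
  expect_true(is.na(ri0$relative[["protrusions"]]))
})

test_that("cable/periphery ratio uses summed intensities", {
  expect_equal(cable_periphery_ratio(list(total = c(cables = 12,
                                                    protrusions = 0))), 1)
  expect_equal(cable_periphery_ratio(list(total = c(cables = 7,
                                                    protrusions = 7))), 0.5)
  expect_error(cable_periphery_ratio(list(total = c(cables = 0,
                                                    protrusions = 0))),
               "both zero")

  sim <- simulate_cluster(fixture_spec("balanced"))
  fr <- get_frame(sim$stack, 1)
  regions <- extract_regions(fr, sim$truth$landmarks, 0.2)
  ri <- region_mean_intensity(fr, regions)
  masks <- region_masks(regions)
  hand <- sum(fr[masks$cables]) /
    (sum(fr[masks$cables]) + sum(fr[masks$protrusions]))
  expect_equal(cable_periphery_ratio(ri), hand)
})

test_that("cable discontinuity is the broken length fraction", {
  expect_equal(cable_discontinuity(fake_region_set(numeric(0), c(50, 50))), 0)
  expect_equal(cable_discontinuity(fake_region_set(c(30, 70), numeric(0))), 1)
  expect_equal(cable_discontinuity(fake_region_set(c(20), c(30, 50))), 0.2)
  expect_error(cable_discontinuity(fake_region_set(numeric(0), numeric(0))),
               "zero total")
})

test_that("morphology summary reports areas in physical units", {
  rs <- fake_region_set(numeric(0), c(10))
  m <- morphology_summary(rs)
  expect_equal(m$protrusion_area_fraction, 0)
  expect_equal(m$protrusion_count, 0)

  body <- matrix(FALSE, 40, 40); body[1:30, 1:30] <- TRUE   # 900 px
  prot <- matrix(0L, 40, 40); prot[31:40, 1:10] <- 1L       # 100 px
  rs2 <- region_set(body, prot, cell_count = 1, pixel_size_um = 0.5)
  m2 <- morphology_summary(rs2)
  expect_equal(m2$protrusion_area_fraction, 0.1)
  expect_equal(m2$protrusion_count, 1)
  expect_equal(m2$total_area_um2, 1000 * 0.25)
})

test_that("migration speed uses the first and third time points", {
  stat <- matrix(c(3, 3, 3, 5, 5, 5), 3, 2)
  expect_equal(migration_speed(stat, 10), 0)

  ## 6 um in 10 min (two 300-s intervals) -> 0.6 um/min
  cents <- rbind(c(0, 0), c(3, 0), c(6, 0))
  expect_equal(migration_speed(cents, 300), 0.6)
  expect_error(migration_speed(cents[1:2, ], 300), "at least 3")

  ## rigid rotation leaves speed unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_lt(abs(migration_speed(cents %*% t(R), 300) -
                migration_speed(cents, 300)), 1e-9)

  ## sliding variant
  cents4 <- rbind(c(0, 0), c(3, 0), c(6, 0), c(6, 4))
  sl <- migration_speed(cents4, 300, sliding = TRUE)
  expect_length(sl, 2)
  expect_equal(sl[1], 0.6)
  expect_equal(sl[2], 0.5)   # |(6,4)-(3,0)| = 5 um over 10 min
})

test_that("bleach correction fits tau and flattens the frame means", {
  const <- timelapse_stack(list(actin = array(7, c(8, 8, 5))), 0.2, 30)
  bc <- bleach_correct(const)
  expect_true(is.na(bc$tau_s[["actin"]]))
  expect_false(bc$corrected[["actin"]])
  expect_identical(bc$stack$channels$actin, const$channels$actin)

  sim <- simulate_cluster(fixture_spec("bleach_stack"))
  bc <- bleach_correct(sim$stack)
  expect_lt(abs(bc$tau_s[["actin"]] - 300) / 300, 0.05)
  means <- apply(bc$stack$channels$actin, 3, mean)
  expect_lt((max(means) - min(means)) / mean(means), 0.01)

  ## brightening stack returned unchanged, flagged
  up <- array(rep(1:5, each = 16), c(4, 4, 5))
  bright <- timelapse_stack(list(actin = up), 0.2, 30)
  bc2 <- bleach_correct(bright)
  expect_false(bc2$corrected[["actin"]])
  expect_identical(bc2$stack$channels$actin, up)

  bad <- timelapse_stack(list(actin = array(0, c(4, 4, 3))), 0.2, 30)
  expect_error(bleach_correct(bad), "nonpositive")
})

test_that("front/middle/rear assignment projects onto the motion axis", {
  cents <- rbind(c(0, 0), c(5, 0), c(10, 0))
  expect_identical(assign_cell_positions(cents, c(1, 0)),
                   c("rear", "middle", "front"))
  expect_identical(assign_cell_positions(cents, c(-1, 0)),
                   c("front", "middle", "rear"))
  expect_identical(assign_cell_positions(rbind(c(2, 2)), c(0, 1)), "front")
  expect_identical(assign_cell_positions(rbind(c(0, 0), c(1, 1)), c(1, 0)),
                   c("rear", "front"))
  expect_error(assign_cell_positions(cents, c(0, 0)), "zero")

  ## reversing the motion vector swaps front and rear exactly
  set.seed(12)
  pts <- matrix(rnorm(18), 9, 2)
  a <- assign_cell_positions(pts, c(0.3, -1.2))
  b <- assign_cell_positions(pts, -c(0.3, -1.2))
  expect_identical(a == "front", b == "rear")
  expect_identical(a == "rear", b == "front")
})

test_that("per-movie metrics table has the standard columns", {
  sim <- simulate_cluster(fixture_spec("tight"))
  df <- group_metrics(sim$stack, sim$truth$landmarks, movie_id = "t1")
  expect_identical(names(df),
    c("movie_id", "frame", "protrusion_area_fraction", "cable_discontinuity",
      "protrusion_count", "total_area_um2", "speed_um_per_min", "category",
      "intensity_contacts", "intensity_cables", "intensity_protrusions"))
  expect_equal(nrow(df), 3)
  expect_true(all(df$category == "tight"))
  expect_lt(df$speed_um_per_min[1], 0.05)
})
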
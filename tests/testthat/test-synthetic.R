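test_that("analytic shape truths match closed forms", {
  s <- make_shape("sphere", list(r_nm = 1000))
  expect_equal(s$volume_true_um3, 4 * pi / 3)
  expect_equal(s$sa_true_um2, 4 * pi)
  # degenerate spheroid falls through to the sphere path
  e <- make_shape("ellipsoid", list(a_nm = 1000, c_nm = 1000, axis = c(0, 0, 1)))
  expect_equal(e$volume_true_um3, s$volume_true_um3)
  expect_equal(e$sa_true_um2, s$sa_true_um2)
  expect_identical(e$sa_truth_kind, "exact")
  # prolate spheroid area: closed form sanity (a=b=1, c=2 um)
  p <- make_shape("spheroid", list(a_nm = 1000, c_nm = 2000, axis = c(1, 0, 0)))
  ecc <- sqrt(1 - 0.25)
  expect_equal(p$sa_true_um2, 2 * pi * (1 + 2 / ecc * asin(ecc)), tolerance = 1e-12)

  expect_error(make_shape("sphere", list(r_nm = 40)),
               class = "mitomorph_resolution_error")
})

test_that("digitized truth consistency: measured volume within 3% of analytic truth", {
  set.seed(5)
  for (cls in c("sphere", "spheroid", "tube")) {
    for (v_target in c(0.5, 1.2)) {
      p <- mitomorph:::draw_shape_params(cls, v_target)
      sh <- make_shape(if (cls == "tube") "branched_tube" else cls, p)
      expect_equal(compute_volume(sh$mask), sh$volume_true_um3, tolerance = 0.03,
                   label = paste(cls, v_target))
    }
  }
})

test_that("measured surface area tracks exact truths closely and composite truths loosely", {
  set.seed(6)
  p <- mitomorph:::draw_shape_params("spheroid", 0.8)
  sh <- make_shape("spheroid", p)
  expect_equal(compute_surface_area(sh$mask), sh$sa_true_um2, tolerance = 0.05)
  pt <- mitomorph:::draw_shape_params("tube", 0.8)
  st <- make_shape("branched_tube", pt)
  expect_equal(compute_surface_area(st$mask), st$sa_true_um2, tolerance = 0.15)
  expect_identical(st$sa_truth_kind, "composite")
})

test_that("cristae planting hits the requested density and morphology structure", {
  m <- ball_mask(0.62) # ~1 um^3
  pc <- plant_cristae(m, 0.25, "lamellar")
  expect_true(pc$realized_density >= 0.225 && pc$realized_density <= 0.275)
  expect_equal(pc$realized_density, sum(pc$labels > 0) / sum(m)) # recorded exactly
  expect_gt(pc$n_cristae, 1)
  # cristae strictly inside the mitochondrion
  expect_true(all(m[pc$labels > 0]))

  expect_error(plant_cristae(m, 0, "lamellar"), class = "mitomorph_parameter_error")
  expect_error(plant_cristae(m, 0.7, "lamellar"), class = "mitomorph_parameter_error")
  tiny <- array(FALSE, c(4, 5, 5)); tiny[2:3, 2:4, 2:4] <- TRUE
  expect_error(plant_cristae(tiny, 0.5, "lamellar"),
               class = "mitomorph_infeasible_error")

  isl <- plant_cristae(m, 0.2, "island")
  expect_gte(isl$n_cristae, 3) # fragmented by construction for mitos > 0.5 um^3
  circ <- plant_cristae(m, 0.15, "circular")
  expect_gt(circ$n_cristae, 0)
  expect_true(all(m[circ$labels > 0]))
})

test_that("generation is deterministic: same spec and seed, identical outputs", {
  spec <- cohort_spec(n_animals = 1, n_objects = 4, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$truth$volume_true_um3, b$truth$volume_true_um3)
  expect_identical(a$scores, b$scores)
  for (src in names(a$volumes)) {
    expect_identical(a$volumes[[src]]$mito$grid, b$volumes[[src]]$mito$grid)
    expect_identical(a$volumes[[src]]$cristae$grid, b$volumes[[src]]$cristae$grid)
  }
  # regenerating the truth table alone reproduces it exactly
  expect_identical(sample_cohort_truth(spec)$volume_true_um3, a$truth$volume_true_um3)
})

test_that("streaming simulate-and-measure matches the two-step generate/measure path", {
  spec <- cohort_spec(n_animals = 1, n_objects = 7, seed = 77)
  stream <- simulate_and_measure(spec, chunk_size = 3)
  coh <- generate_cohort(spec)
  two_step <- measure_cohort(coh)
  # centroids live in the packed volume's frame, which differs by layout
  drop_pos <- function(t) dplyr::select(t, -dplyr::starts_with("centroid"))
  expect_equal(drop_pos(stream$mito), drop_pos(two_step$mito))
  expect_equal(stream$cristae, two_step$cristae)
  expect_equal(stream$summaries, two_step$summaries)
  expect_identical(stream$scores, coh$scores)
})

test_that("raising the cristae-density multiplier raises cohort mean density", {
  base <- cohort_spec(n_animals = 1, n_objects = 6, seed = 9,
                      cristae_density_multiplier = 0.5)
  up <- cohort_spec(n_animals = 1, n_objects = 6, seed = 9,
                    cristae_density_multiplier = 0.9)
  d_lo <- generate_cohort(base)$truth
  d_hi <- generate_cohort(up)$truth
  expect_gt(mean(d_hi$density_realized[d_hi$group == "aged"]),
            mean(d_lo$density_realized[d_lo$group == "aged"]))
})

test_that("planted group effects land in the study's directions on measured tables", {
  coh <- generate_cohort(cohort_spec(n_animals = 2, n_objects = 10, seed = 19))
  meas <- measure_cohort(coh)
  mm <- meas$mito
  mean_by <- function(tbl, col) tapply(tbl[[col]], tbl$group, mean, na.rm = TRUE)
  for (col in c("volume_um3", "surface_area_um2", "perimeter_um", "mci")) {
    mb <- mean_by(mm, col)
    expect_gt(mb["aged"], mb["adult"])
  }
  expect_lt(mean_by(mm, "sphericity")["aged"], mean_by(mm, "sphericity")["adult"])
  cr <- dplyr::filter(meas$cristae, parent_mito_id > 0)
  expect_lt(mean_by(cr, "norm_volume")["aged"], mean_by(cr, "norm_volume")["adult"])
})

test_that("cohort spec validation rejects malformed mixes and multipliers", {
  expect_error(cohort_spec(shape_mix = c(sphere = 0.5, spheroid = 0.2, tube = 0.2)))
  expect_error(cohort_spec(volume_multiplier = 0))
})
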
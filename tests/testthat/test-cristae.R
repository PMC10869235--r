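make_pair <- function(cristae_g, mito_g, spacing = c(10, 10, 50)) {
  list(cristae = label_volume(cristae_g, spacing, "t"),
       mito = label_volume(mito_g, spacing, "t"))
}

test_that("cristae are assigned by plurality overlap with threshold and tie-break", {
  d <- c(6, 6, 12)
  mito <- array(0L, d); mito[2:5, 2:5, 2:6] <- 7L
  cr <- array(0L, d); cr[3:4, 3:4, 3:4] <- 1L
  p <- make_pair(cr, mito)
  asg <- assign_cristae(p$cristae, p$mito)
  expect_identical(asg$parent_mito_id, 7L)
  expect_identical(asg$overlap_fraction, 1.0)

  # 60/40 split across mitos 1 and 2
  mito2 <- array(0L, d); mito2[2:5, 2:5, 2:6] <- 1L; mito2[2:5, 2:5, 7:11] <- 2L
  cr2 <- array(0L, d); cr2[3, 3, 4:8] <- 1L # 3 voxels in mito 1, 2 in mito 2
  asg2 <- assign_cristae(label_volume(cr2), label_volume(mito2), min_overlap = 0.5)
  expect_identical(asg2$parent_mito_id, 1L)
  expect_equal(asg2$overlap_fraction, 3 / 5)

  # crista entirely in background stays unassigned
  cr3 <- array(0L, d); cr3[1, 1, 12] <- 1L
  asg3 <- assign_cristae(label_volume(cr3), label_volume(mito))
  expect_identical(asg3$parent_mito_id, 0L)

  # exact 50/50 tie breaks toward the lower mito id
  cr4 <- array(0L, d); cr4[3, 3, 5:8] <- 1L # 2 voxels in each
  asg4 <- assign_cristae(label_volume(cr4), label_volume(mito2))
  expect_identical(asg4$parent_mito_id, 1L)

  # registration mismatch
  expect_error(assign_cristae(label_volume(array(0L, c(2, 2, 2))), label_volume(mito)),
               class = "mitomorph_registration_error")
})

test_that("label permutation permutes but never changes the assignment", {
  coh <- tiny_cohort(seed = 41, n_objects = 4)
  pair <- coh$volumes[[1]]
  asg <- assign_cristae(pair$cristae, pair$mito)
  # swap mito labels 1 <-> 2
  g <- pair$mito$grid
  swapped <- g
  swapped[g == 1L] <- 2L; swapped[g == 2L] <- 1L
  asg2 <- assign_cristae(pair$cristae, label_volume(swapped, pair$mito$spacing, "t"))
  remap <- function(x) ifelse(x == 1L, 2L, ifelse(x == 2L, 1L, x))
  expect_identical(remap(asg$parent_mito_id), asg2$parent_mito_id)
  expect_equal(asg$overlap_fraction, asg2$overlap_fraction)
})

test_that("normalized metrics divide by parent volume and scale linearly", {
  crista <- tibble::tibble(object_id = 1L, volume_um3 = 0.01,
                           surface_area_um2 = 0.3, perimeter_um = 0.5)
  parent <- tibble::tibble(object_id = 9L, volume_um3 = 1.0)
  rec <- normalized_metrics(crista, parent)
  expect_equal(rec$norm_volume, 0.01)
  expect_equal(rec$norm_area, 0.3)
  expect_equal(rec$norm_perimeter, 0.5)

  parent2 <- tibble::tibble(object_id = 9L, volume_um3 = 2.0)
  rec2 <- normalized_metrics(crista, parent2)
  expect_equal(c(rec2$norm_volume, rec2$norm_area, rec2$norm_perimeter),
               c(rec$norm_volume, rec$norm_area, rec$norm_perimeter) / 2)

  expect_error(normalized_metrics(crista, tibble::tibble(object_id = 0L, volume_um3 = 0)),
               class = "mitomorph_unassigned_error")
})

test_that("per-mitochondrion summaries conserve volume and handle edge cases", {
  mito <- tibble::tibble(object_id = 1L, volume_um3 = 1.0)
  kids <- tibble::tibble(volume_um3 = c(0.1, 0.15))
  s <- summarize_mito(mito, kids)
  expect_equal(s$cristae_density, 0.25)
  expect_equal(s$matrix_volume_um3, 0.75)
  expect_identical(s$n_cristae, 2L)

  s0 <- summarize_mito(mito, NULL)
  expect_equal(s0$cristae_density, 0)
  expect_equal(s0$matrix_volume_um3, 1.0)

  expect_error(summarize_mito(mito, tibble::tibble(volume_um3 = c(0.6, 0.5))),
               class = "mitomorph_inconsistency_error")
})

test_that("measured cristae density recovers the planted density on phantoms", {
  coh <- tiny_cohort(seed = 51, n_objects = 5)
  meas <- measure_cohort(coh, min_voxels = 5)
  joined <- dplyr::inner_join(meas$summaries, coh$truth,
                              by = c("source_id", "mito_id" = "object_id"))
  expect_true(all(abs(joined$cristae_density - joined$density_realized) <
                    pmax(0.05 * joined$density_realized, 0.01)))
  # conservation for every row, at most one ulp of double rounding
  resid <- abs(joined$matrix_volume_um3 + joined$total_cristae_volume_um3 -
                 joined$mito_volume_um3)
  expect_true(all(resid <= 2 * .Machine$double.eps * joined$mito_volume_um3))
})
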
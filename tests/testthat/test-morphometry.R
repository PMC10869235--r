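test_that("voxel-exact volume matches hand arithmetic", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(compute_volume(one, c(10, 10, 50)), 5.0e-6)

  expect_equal(compute_volume(block_mask(0.1, 0.1, 0.1)), 1e-3)

  expect_error(compute_volume(array(FALSE, c(2, 2, 2))),
               class = "mitomorph_degenerate_error")
})

test_that("volume equals a brute-force triple-loop voxel count", {
  set.seed(2)
  m <- array(runif(20^3) < 0.3, c(20, 20, 20))
  n <- 0
  for (z in 1:20) for (y in 1:20) for (x in 1:20) if (m[z, y, x]) n <- n + 1
  expect_equal(compute_volume(m, c(10, 10, 50)), n * 5000 / 1e9)
})

test_that("digitized sphere volume and surface area approach analytic truth", {
  m <- ball_mask(0.5)
  expect_equal(compute_volume(m), 4 / 3 * pi * 0.5^3, tolerance = 0.02)
  expect_equal(compute_surface_area(m), 4 * pi * 0.5^2, tolerance = 0.05)
})

test_that("axis-aligned 1 um cube surface area is close to 6 um^2 on isotropic grid", {
  m <- block_mask(1, 1, 1, spacing = c(10, 10, 10))
  expect_equal(compute_surface_area(m, c(10, 10, 10)), 6, tolerance = 0.05)
})

test_that("mesh area is bounded above by voxel-face area for convex shapes", {
  for (m in list(ball_mask(0.4), block_mask(0.5, 0.5, 0.5))) {
    mesh <- compute_surface_area(m)
    faces <- mitomorph:::voxel_face_area(array(as.integer(m), dim(m)), dim(m),
                                         c(50, 10, 10)) / 1e6
    expect_lt(mesh, faces)
  }
})

test_that("single-voxel object falls back to voxel-face area with a warning", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_warning(sa <- compute_surface_area(one, c(10, 10, 50)),
                 class = "mitomorph_single_voxel_warning")
  expect_equal(sa, 2 * (10 * 10 + 10 * 50 + 10 * 50) / 1e6)
})

test_that("slice perimeter recovers analytic circle and square contours", {
  # single-slice circle r = 1 um (z thickness one voxel)
  circ <- make_shape("sphere", list(r_nm = 1000), c(10, 10, 50))$mask
  mid <- which.max(apply(circ, 1, sum))
  one_slice <- circ[mid, , , drop = FALSE]
  dim(one_slice) <- c(1, dim(circ)[2], dim(circ)[3])
  p <- compute_perimeter(one_slice, c(10, 10, 50))
  expect_equal(p, 2 * pi, tolerance = 0.03)
  # reducers coincide for a single-slice object
  expect_equal(p, compute_perimeter(one_slice, c(10, 10, 50), "sum"))
  expect_equal(p, compute_perimeter(one_slice, c(10, 10, 50), "max"))

  sq <- block_mask(1, 1, 0.05)
  expect_equal(compute_perimeter(sq, c(10, 10, 50)), 4, tolerance = 0.03)
})

test_that("sphericity and MCI reproduce closed forms and their algebraic identity", {
  expect_equal(sphericity(4 * pi / 3, 4 * pi), 1.0)
  expect_equal(mci(4 * pi / 3, 4 * pi), 9 / (4 * pi))
  a <- 2.3
  expect_equal(sphericity(a^3, 6 * a^2), (pi / 6)^(1 / 3), tolerance = 1e-12)
  expect_equal(mci(a^3, 6 * a^2), 216 / (16 * pi^2), tolerance = 1e-12)
  # exact scale invariance on analytic inputs
  expect_equal(sphericity(2 * 1.7, 2^(2 / 3) * 5.1), sphericity(1.7, 5.1))
  expect_equal(mci(8 * 1.7, 4 * 5.1), mci(1.7, 5.1))
  # identity over random positive pairs
  set.seed(5)
  V <- runif(200, 1e-3, 10); SA <- runif(200, 1e-2, 100)
  expect_true(all(abs(mci(V, SA) * sphericity(V, SA)^3 - 9 / (4 * pi)) < 1e-12))
  expect_error(sphericity(-1, 2), class = "mitomorph_domain_error")
  expect_error(mci(1, 0), class = "mitomorph_domain_error")
})

test_that("extract_objects handles label mode, component mode and speck filtering", {
  pts <- list(matrix(c(2, 2, 2), 1), matrix(c(5, 5, 5), 1))
  v <- lv_from_points(pts, c(7, 7, 7))
  objs <- extract_objects(v, min_voxels = 1)
  expect_identical(nrow(objs), 2L)
  objs2 <- extract_objects(v, min_voxels = 2)
  expect_identical(nrow(objs2), 0L)
  expect_identical(attr(objs2, "n_dropped"), 2L)

  # two touching blobs under one label: one object in both modes
  g <- array(0L, c(5, 5, 7)); g[2:4, 2:4, 2:3] <- 1L; g[2:4, 2:4, 4:5] <- 1L
  v2 <- label_volume(g)
  expect_identical(nrow(extract_objects(v2, "labels", 1)), 1L)
  expect_identical(nrow(extract_objects(v2, "connected_components", 1)), 1L)

  # boundary flag
  gb <- array(0L, c(4, 4, 4)); gb[1, 2, 2] <- 1L; gb[3, 3, 3] <- 2L
  ob <- extract_objects(label_volume(gb), min_voxels = 1)
  expect_identical(ob$touches_boundary, c(TRUE, FALSE))
})

test_that("26-connected labelling agrees with a brute-force flood-fill oracle", {
  set.seed(7)
  for (rep in 1:3) {
    m <- array(runif(10 * 11 * 12) < 0.25, c(10, 11, 12))
    lab <- mitomorph:::cc_label_3d(array(as.integer(m), dim(m)), dim(m))
    oracle <- flood_fill_oracle(m)
    expect_identical(max(lab), max(oracle))
    # same partition: component memberships agree up to label permutation
    expect_identical(length(unique(split(oracle[m], lab[m]))), max(lab))
    for (k in seq_len(max(lab))) {
      expect_identical(length(unique(oracle[lab == k])), 1L)
    }
  }
})

test_that("splitting a label into two parts conserves summed volume exactly", {
  m <- ball_mask(0.3)
  whole <- compute_volume(m)
  cut <- dim(m)[3] %/% 2
  left <- m; left[, , (cut + 1):dim(m)[3]] <- FALSE
  right <- m; right[, , 1:cut] <- FALSE
  expect_identical(compute_volume(left) + compute_volume(right), whole)
})

test_that("volume and surface errors shrink with increasing digitized radius", {
  sp <- c(10, 10, 10)
  errs <- sapply(c(80, 160, 320), function(r_nm) {
    m <- make_shape("sphere", list(r_nm = r_nm), sp)$mask
    c(v = abs(compute_volume(m, sp) / (4 / 3 * pi * (r_nm / 1e3)^3) - 1),
      sa = abs(compute_surface_area(m, sp) / (4 * pi * (r_nm / 1e3)^2) - 1))
  })
  expect_true(all(diff(errs["v", ]) <= 0))
  expect_true(all(diff(errs["sa", ]) <= 0))
})

test_that("halving the voxel spacing changes sphericity and MCI by < 5%", {
  p <- list(a_nm = 300, c_nm = 600, axis = c(0.36, 0.48, 0.8))
  vals <- lapply(list(c(20, 20, 50), c(10, 10, 25)), function(sp) {
    m <- make_shape("spheroid", p, sp)$mask
    v <- compute_volume(m, sp); sa <- compute_surface_area(m, sp)
    c(psi = sphericity(v, sa), mci = mci(v, sa))
  })
  expect_lt(abs(vals[[2]]["psi"] / vals[[1]]["psi"] - 1), 0.05)
  expect_lt(abs(vals[[2]]["mci"] / vals[[1]]["mci"] - 1), 0.05)
})

test_that("measure_all emits one valid row per object and an empty table for empty input", {
  empty <- label_volume(array(0L, c(4, 4, 4)))
  expect_identical(nrow(measure_all(empty)), 0L)

  coh <- tiny_cohort(seed = 31, n_objects = 6)
  v <- coh$volumes[[1]]$mito
  tbl <- measure_all(v)
  expect_identical(nrow(tbl), 6L)
  expect_true(all(tbl$ok))
  expect_true(all(tbl$volume_um3 > 0 & tbl$surface_area_um2 > 0 & tbl$perimeter_um > 0))
  expect_identical(tbl$object_id, sort(tbl$object_id))
  # volume invariant: exact voxel count times voxel volume
  expect_identical(tbl$volume_um3, tbl$voxel_count * prod(v$spacing) / 1e9)
  # identity holds for every emitted row at machine precision
  expect_true(all(abs(tbl$mci * tbl$sphericity^3 - 9 / (4 * pi)) < 1e-12))
})

test_that("branched tubes score higher MCI and lower sphericity than spheres of equal volume", {
  set.seed(13)
  sph <- make_shape("sphere", list(r_nm = (3 * 0.3e9 / (4 * pi))^(1 / 3)))
  tube <- make_shape("branched_tube", mitomorph:::draw_shape_params("tube", 0.3))
  metr <- lapply(list(sph, tube), function(s) {
    v <- compute_volume(s$mask); sa <- compute_surface_area(s$mask)
    c(mci = mci(v, sa), psi = sphericity(v, sa))
  })
  expect_gt(metr[[2]]["mci"], metr[[1]]["mci"])
  expect_lt(metr[[2]]["psi"], metr[[1]]["psi"])
})
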
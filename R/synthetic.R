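#' Specification for a synthetic two-group cohort
#'
#' Defines the conditions the phantom generator emulates: two age groups
#' ("adult", "aged"), `n_animals` animals per group and `n_objects`
#' mitochondria per animal on an anisotropic voxel grid. Aged-group effects
#' are induced mechanistically: volumes are drawn from a lognormal scaled
#' by `volume_multiplier` with log-sd scaled by `dispersion_multiplier`;
#' the branched-tube odds are scaled by `elongation_multiplier` (driving
#' sphericity down and MCI up through geometry, not by perturbing metrics);
#' planted cristae density is scaled by `cristae_density_multiplier`; and
#' the cristae-score distribution follows the density shift because scores
#' are linked to pooled density quantiles (plus the optional additive
#' `score_shift`).
#'
#' @param n_animals Animals per group.
#' @param n_objects Mitochondria per animal (3 x 100 approximates a
#'   ~300-object age cohort).
#' @param spacing Voxel spacing `(sx, sy, sz)` nm.
#' @param shape_mix Adult-group fractions for sphere / spheroid /
#'   branched-tube shape families (must sum to 1).
#' @param volume_multiplier,dispersion_multiplier,elongation_multiplier,cristae_density_multiplier
#'   Aged-group effect multipliers (all > 0; 1 = no effect).
#' @param score_shift Additive shift applied to aged consensus scores
#'   before clamping to 1-4 (default 0: the score effect is carried by the
#'   density linkage).
#' @param median_volume_um3,sdlog Adult lognormal volume parameters.
#' @param mean_density,sd_density Adult planted cristae density (fraction of
#'   mitochondrial volume).
#' @param seed Integer seed fixing every downstream draw.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_animals = 3, n_objects = 100, spacing = c(10, 10, 50),
                        shape_mix = c(sphere = 0.50, spheroid = 0.35, tube = 0.15),
                        volume_multiplier = 1.6, dispersion_multiplier = 1.5,
                        elongation_multiplier = 2.5,
                        cristae_density_multiplier = 0.6, score_shift = 0,
                        median_volume_um3 = 0.25, sdlog = 0.55,
                        mean_density = 0.30, sd_density = 0.06, seed = 42) {
  if (abs(sum(shape_mix) - 1) > 1e-9) abort("shape_mix fractions must sum to 1.")
  mult <- c(volume_multiplier, dispersion_multiplier, elongation_multiplier,
            cristae_density_multiplier)
  if (any(mult <= 0)) abort("effect multipliers must be > 0.")
  structure(list(
    n_animals = n_animals, n_objects = n_objects, spacing = spacing,
    shape_mix = shape_mix, volume_multiplier = volume_multiplier,
    dispersion_multiplier = dispersion_multiplier,
    elongation_multiplier = elongation_multiplier,
    cristae_density_multiplier = cristae_density_multiplier,
    score_shift = score_shift,
    median_volume_um3 = median_volume_um3, sdlog = sdlog,
    mean_density = mean_density, sd_density = sd_density, seed = as.integer(seed)
  ), class = "cohort_spec")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

orthonormal_frame <- function() {
  e3 <- random_unit_vector()
  h <- if (abs(e3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- h - sum(h * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  list(e1 = e1, e2 = e2, e3 = e3)
}

# exact spheroid surface area (semi-axes a = b, c), nm^2
spheroid_area <- function(a, c) {
  if (abs(c - a) < 1e-9 * a) return(4 * pi * a^2)
  if (c > a) { # prolate
    e <- sqrt(1 - a^2 / c^2)
    2 * pi * a^2 * (1 + c / (a * e) * asin(e))
  } else { # oblate
    e <- sqrt(1 - c^2 / a^2)
    2 * pi * a^2 * (1 + (1 - e^2) / e * atanh(e))
  }
}

# Draw the geometric parameters for one object of target volume V (um^3).
draw_shape_params <- function(class, volume_um3) {
  V <- volume_um3 * NM3_PER_UM3 # nm^3
  if (class == "sphere") {
    list(r_nm = (3 * V / (4 * pi))^(1 / 3))
  } else if (class == "spheroid") {
    q <- runif(1, 1.4, 2.6) # prolate aspect: oval mitochondria
    a <- (3 * V / (4 * pi * q))^(1 / 3)
    list(a_nm = a, c_nm = q * a, axis = random_unit_vector())
  } else { # branched tube
    alpha <- runif(1, 8, 14) # total skeleton length in units of radius
    r <- (V / (pi * (4 / 3 + alpha)))^(1 / 3)
    w <- runif(3, 0.2, 0.5); w <- w / sum(w)
    lens <- pmax(w * alpha * r, 2 * r)
    fr <- orthonormal_frame()
    th <- c(0, 2 * pi / 3, 4 * pi / 3) + runif(1, 0, 2 * pi)
    wob <- runif(3, -pi / 12, pi / 12)
    dirs <- lapply(1:3, function(i)
      cos(wob[i]) * (cos(th[i]) * fr$e1 + sin(th[i]) * fr$e2) + sin(wob[i]) * fr$e3)
    list(r_nm = r, lengths_nm = lens, dirs = dirs)
  }
}

#' Digitize one synthetic shape with analytic ground truth
#'
#' Shape families: `sphere` (radius `r_nm`), `spheroid` (semi-axes `a_nm` =
#' b, `c_nm` along unit vector `axis`; exact closed-form surface area) and
#' `branched_tube` (three capsule branches of radius `r_nm` and lengths
#' `lengths_nm` along unit `dirs` from a common joint; branch axes are laid
#' out near-planar at ~120 degrees so the exact union volume
#' \eqn{V = 4\pi r^3/3 + \pi r^2 \sum L_i} applies; the attached surface
#' area is a capsule-composition estimate and is flagged as such).
#'
#' @param class `"sphere"`, `"spheroid"`, `"ellipsoid"` (alias of spheroid)
#'   or `"branched_tube"`.
#' @param params Named list of parameters (see above; an `ellipsoid` with
#'   `a_nm == c_nm` degenerates to the sphere path).
#' @param spacing `(sx, sy, sz)` nm.
#' @return List: `mask` (3D logical array, `(z, y, x)`), `volume_true_um3`,
#'   `sa_true_um2`, `sa_truth_kind` (`"exact"` or `"composite"`).
#' @export
make_shape <- function(class = c("sphere", "spheroid", "ellipsoid", "branched_tube", "tube"),
                       params, spacing = c(10, 10, 50)) {
  class <- match.arg(class)
  if (class == "ellipsoid") class <- "spheroid"
  if (class == "tube") class <- "branched_tube"
  sx <- spacing[1]; sy <- spacing[2]; sz <- spacing[3]
  if (class == "sphere") {
    r <- params$r_nm
    check_resolution(c(r, r, r) * 2, spacing)
    ext <- c(r, r, r)
  } else if (class == "spheroid") {
    a <- params$a_nm; cc <- params$c_nm
    if (abs(a - cc) < 1e-12) return(make_shape("sphere", list(r_nm = a), spacing))
    check_resolution(c(2 * a, 2 * a, 2 * a), spacing) # conservative: smallest extent 2a
    u0 <- params$axis
    ext <- sqrt(a^2 + (cc^2 - a^2) * u0^2) # extent along each world axis (x, y, z)
  } else {
    r <- params$r_nm
    check_resolution(c(2 * r, 2 * r, 2 * r), spacing)
    ends <- mapply(function(d, L) d * L, params$dirs, params$lengths_nm)
    ext <- pmax(apply(abs(ends), 1, max) + r, 1.5 * r) # per-axis (x, y, z)
  }
  nxyz <- 2 * ceiling(ext / c(sx, sy, sz)) + 5
  nx <- nxyz[1]; ny <- nxyz[2]; nz <- nxyz[3]
  cx <- (nx - 1) / 2 * sx; cy <- (ny - 1) / 2 * sy; cz <- (nz - 1) / 2 * sz
  xs <- (0:(nx - 1)) * sx - cx; ys <- (0:(ny - 1)) * sy - cy; zs <- (0:(nz - 1)) * sz - cz
  if (class == "sphere") {
    r <- params$r_nm
    d2 <- outer(outer(zs^2, ys^2, "+"), xs^2, "+")
    mask <- d2 <= r^2
    truth <- list(V = 4 / 3 * pi * r^3, SA = 4 * pi * r^2, kind = "exact")
  } else if (class == "spheroid") {
    a <- params$a_nm; cc <- params$c_nm; u <- params$axis # u in (x, y, z)
    zz <- rep(zs, times = ny * nx)
    yy <- rep(rep(ys, each = nz), times = nx)
    xx <- rep(xs, each = nz * ny)
    s <- xx * u[1] + yy * u[2] + zz * u[3]
    r2 <- xx^2 + yy^2 + zz^2
    mask <- array((s / cc)^2 + (r2 - s^2) / a^2 <= 1, c(nz, ny, nx))
    truth <- list(V = 4 / 3 * pi * a^2 * cc, SA = spheroid_area(a, cc), kind = "exact")
  } else {
    r <- params$r_nm
    zz <- rep(zs, times = ny * nx)
    yy <- rep(rep(ys, each = nz), times = nx)
    xx <- rep(xs, each = nz * ny)
    inside <- rep(FALSE, length(zz))
    for (i in seq_along(params$dirs)) {
      u <- params$dirs[[i]]; L <- params$lengths_nm[i]
      s <- clamp(xx * u[1] + yy * u[2] + zz * u[3], 0, L)
      d2 <- (xx - s * u[1])^2 + (yy - s * u[2])^2 + (zz - s * u[3])^2
      inside <- inside | d2 <= r^2
    }
    mask <- array(inside, c(nz, ny, nx))
    truth <- list(V = 4 / 3 * pi * r^3 + pi * r^2 * sum(params$lengths_nm),
                  SA = 2 * pi * r * sum(params$lengths_nm) + 4 * pi * r^2,
                  kind = "composite")
  }
  list(mask = mask, volume_true_um3 = truth$V / NM3_PER_UM3,
       sa_true_um2 = truth$SA / NM2_PER_UM2, sa_truth_kind = truth$kind)
}

check_resolution <- function(extent_nm_xyz, spacing) {
  if (any(extent_nm_xyz < 2 * spacing)) {
    abort("shape smaller than 2 voxels along some axis at this spacing.",
          class = "mitomorph_resolution_error")
  }
}

#' Plant cristae inside a mitochondrion mask
#'
#' Cristae voxels are placed strictly inside the mitochondrion (one 6-voxel
#' erosion models the boundary membrane clearance). Morphologies:
#' `lamellar` — stacked slabs perpendicular to x, slab thickness and gap
#' chosen so the realized volume fraction best matches `density`;
#' `circular` — an interior shell intersected with the slab stacking,
#' giving annular cross-sections; `island` — small scattered ellipsoidal
#' blobs accumulated until the target density is reached.
#'
#' @param mask 3D logical mitochondrion mask, `(z, y, x)`.
#' @param density Target cristae volume fraction, in (0, 0.6].
#' @param morphology `"lamellar"`, `"circular"` or `"island"`.
#' @param spacing `(sx, sy, sz)` nm (used for blob sizing only).
#' @return List: `labels` (integer array, one label per crista instance),
#'   `realized_density` (exact voxel-count fraction), `n_cristae`.
#' @export
plant_cristae <- function(mask, density, morphology = c("lamellar", "circular", "island"),
                          spacing = c(10, 10, 50)) {
  morphology <- match.arg(morphology)
  if (!(density > 0 && density <= 0.6)) {
    abort("cristae density must lie in (0, 0.6].", class = "mitomorph_parameter_error")
  }
  mask <- as_mask(mask)
  d <- dim(mask)
  total <- sum(mask)
  er <- erode6(array(as.integer(mask), d), d, 1L) > 0L
  f_e <- sum(er) / total
  if (f_e <= density) {
    abort("requested cristae density infeasible for this (tiny) mitochondrion.",
          class = "mitomorph_infeasible_error", f_e = f_e)
  }
  planted <- switch(morphology,
    lamellar = slab_select(er, total, density),
    circular = {
      depth <- 1L
      shell <- er & !(erode6(array(as.integer(er), d), d, depth) > 0L)
      while (sum(shell) / total < density && depth < 4L) {
        depth <- depth + 1L
        shell <- er & !(erode6(array(as.integer(er), d), d, depth) > 0L)
      }
      if (sum(shell) / total < density) {
        abort("requested cristae density infeasible for circular morphology.",
              class = "mitomorph_infeasible_error", f_e = sum(shell) / total)
      }
      slab_select(shell, total, density)
    },
    island = island_select(er, total, density, spacing)
  )
  labels <- cc_label_3d(array(as.integer(planted), d), d)
  list(labels = labels, realized_density = sum(planted) / total,
       n_cristae = max(labels))
}

# choose periodic x-slabs of `base` voxels whose fraction of `total` best
# matches `density`; searches thickness, gap and phase
slab_select <- function(base, total, density) {
  d <- dim(base)
  cnt <- apply(base, 3, sum)
  best <- NULL; best_err <- Inf
  for (t in 2:4) for (g in 1:30) {
    p <- t + g
    for (phase in 0:(p - 1)) {
      sel <- ((seq_len(d[3]) - 1 + phase) %% p) < t
      f <- sum(cnt[sel]) / total
      err <- abs(f - density)
      if (err < best_err) { best_err <- err; best <- sel }
    }
  }
  out <- base
  out[, , !best] <- FALSE
  out
}

island_select <- function(er, total, density, spacing) {
  d <- dim(er)
  target <- density * total
  centers <- which(er)
  planted <- array(FALSE, d)
  rz <- 1L
  ry <- max(2L, round(40 / spacing[2]))
  rx <- max(2L, round(40 / spacing[1]))
  guard <- 0L
  while (sum(planted) < target && guard < 10000L) {
    guard <- guard + 1L
    c0 <- centers[sample.int(length(centers), 1)]
    z <- (c0 - 1) %% d[1] + 1
    rest <- (c0 - 1) %/% d[1]
    y <- rest %% d[2] + 1
    x <- rest %/% d[2] + 1
    zr <- max(1, z - rz):min(d[1], z + rz)
    yr <- max(1, y - ry):min(d[2], y + ry)
    xr <- max(1, x - rx):min(d[3], x + rx)
    blob <- outer(outer(((zr - z) / (rz + 0.5))^2, ((yr - y) / (ry + 0.5))^2, "+"),
                  ((xr - x) / (rx + 0.5))^2, "+") <= 1
    planted[zr, yr, xr] <- planted[zr, yr, xr] | (blob & er[zr, yr, xr])
  }
  planted
}

#' Draw the pre-digitization ground truth for a whole cohort
#'
#' Stage one of the generator: every per-object parameter (group, animal,
#' shape class, analytic volume and surface-area truth, planted cristae
#' density target, cristae morphology) is drawn here, before any
#' voxelization. This table is the sampling distribution the phantoms
#' realise, and is what fast statistical calibration experiments (e.g.
#' type-I error replicates) operate on.
#'
#' @param spec A [cohort_spec()].
#' @return `GroundTruthTable` tibble, one row per object.
#' @export
sample_cohort_truth <- function(spec) {
  set.seed(spec$seed)
  rows <- list()
  for (group in c("adult", "aged")) {
    aged <- group == "aged"
    meanlog <- log(spec$median_volume_um3 * if (aged) spec$volume_multiplier else 1)
    sdl <- spec$sdlog * if (aged) spec$dispersion_multiplier else 1
    mix <- spec$shape_mix
    if (aged) {
      odds <- mix["tube"] / (1 - mix["tube"]) * spec$elongation_multiplier
      t_new <- odds / (1 + odds)
      scale_rest <- (1 - t_new) / (1 - mix["tube"])
      mix <- c(sphere = unname(mix["sphere"] * scale_rest),
               spheroid = unname(mix["spheroid"] * scale_rest), tube = unname(t_new))
    }
    dens_mean <- spec$mean_density * if (aged) spec$cristae_density_multiplier else 1
    morph_probs <- if (aged) c(lamellar = 0.5, island = 0.3, circular = 0.2)
                   else c(lamellar = 0.9, island = 0.05, circular = 0.05)
    for (animal in seq_len(spec$n_animals)) {
      n <- spec$n_objects
      cls <- sample(names(mix), n, replace = TRUE, prob = mix)
      vols <- clamp(rlnorm(n, meanlog, sdl), 0.03, 4)
      dens <- clamp(rnorm(n, dens_mean, spec$sd_density), 0.05, 0.55)
      morph <- sample(names(morph_probs), n, replace = TRUE, prob = morph_probs)
      params <- lapply(seq_len(n), function(i)
        draw_shape_params(if (cls[i] == "tube") "tube" else cls[i], vols[i]))
      sa <- vapply(seq_len(n), function(i) {
        p <- params[[i]]
        switch(cls[i],
               sphere = 4 * pi * p$r_nm^2,
               spheroid = spheroid_area(p$a_nm, p$c_nm),
               tube = 2 * pi * p$r_nm * sum(p$lengths_nm) + 4 * pi * p$r_nm^2) / NM2_PER_UM2
      }, 0.0)
      animal_label <- paste0(group, "_", animal)
      src_label <- paste0(group, "_m", animal)
      rows[[length(rows) + 1]] <- tibble(
        group = group, animal = animal_label, source_id = src_label,
        object_id = seq_len(n), shape_class = cls,
        volume_true_um3 = vols, sa_true_um2 = sa,
        sa_truth_kind = ifelse(cls == "tube", "composite", "exact"),
        density_target = dens, cristae_morphology = morph,
        shape_params = params, seed = spec$seed
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a full synthetic cohort of label volumes
#'
#' Stage two: digitizes every object from [sample_cohort_truth()] on the
#' anisotropic grid, plants cristae instances inside each mitochondrion,
#' packs the objects of each animal into one pair of co-registered label
#' volumes (mitochondria + cristae), links consensus cristae scores to the
#' pooled quantiles of realized density and simulates three blinded raters
#' per object. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory; when given, per-animal volumes are
#'   written as NRRD pairs plus `ground_truth.csv` and `scores.csv`.
#' @param rater_sd Probability mass for a blinded rater deviating +-1 level
#'   from the consensus truth (default 0.15 each side).
#' @return List: `volumes` (named by source_id; each `$mito`, `$cristae`
#'   [label_volume()]s), `truth` tibble (with realized densities and score
#'   truth), `scores` rater-level tibble, `groups` source-to-group map,
#'   `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL, rater_sd = 0.15) {
  truth <- sample_cohort_truth(spec)
  truth$density_realized <- NA_real_
  truth$n_cristae <- NA_integer_
  volumes <- list()
  for (src in unique(truth$source_id)) {
    built <- build_animal_volumes(truth, which(truth$source_id == src), spec)
    truth <- built$truth
    volumes[[src]] <- built$volumes
  }
  out <- finalize_cohort(truth, spec, rater_sd)
  out$volumes <- volumes
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

# digitize + plant cristae + pack one animal's objects into a volume pair;
# `ids` are the mitochondrion labels to write (defaults to the truth table's
# per-animal object ids), `crista_offset` the id base for crista instances
build_animal_volumes <- function(truth, sel, spec, ids = truth$object_id[sel],
                                 crista_offset = 0L) {
  src <- truth$source_id[sel[1]]
  shapes <- vector("list", length(sel))
  cristae <- vector("list", length(sel))
  for (j in seq_along(sel)) {
    i <- sel[j]
    cls <- if (truth$shape_class[i] == "tube") "branched_tube" else truth$shape_class[i]
    sh <- make_shape(cls, truth$shape_params[[i]], spec$spacing)
    pc <- plant_cristae_relaxed(sh$mask, truth$density_target[i],
                                truth$cristae_morphology[i], spec$spacing)
    shapes[[j]] <- sh$mask
    cristae[[j]] <- pc$labels
    truth$density_realized[i] <- pc$realized_density
    truth$n_cristae[i] <- pc$n_cristae
  }
  pk <- pack_objects(lapply(shapes, dim))
  mito_grid <- array(0L, pk$dims)
  cristae_grid <- array(0L, pk$dims)
  for (j in seq_along(sel)) {
    o <- pk$offsets[[j]]; dm <- dim(shapes[[j]])
    zi <- o[1] + seq_len(dm[1]); yi <- o[2] + seq_len(dm[2]); xi <- o[3] + seq_len(dm[3])
    mito_grid[zi, yi, xi][shapes[[j]]] <- as.integer(ids[j])
    cr <- cristae[[j]]
    hit <- cr > 0L
    cristae_grid[zi, yi, xi][hit] <- cr[hit] + crista_offset
    crista_offset <- crista_offset + max(cr)
  }
  list(truth = truth, crista_offset = crista_offset,
       volumes = list(mito = label_volume(mito_grid, spec$spacing, src),
                      cristae = label_volume(cristae_grid, spec$spacing, src)))
}

# score linkage (pooled density quantiles -> 1..4) and blinded-rater simulation
finalize_cohort <- function(truth, spec, rater_sd) {
  br <- quantile(truth$density_realized, c(0.25, 0.5, 0.75), names = FALSE)
  sc <- findInterval(truth$density_realized, br) + 1L
  sc <- as.integer(clamp(sc + ifelse(truth$group == "aged", spec$score_shift, 0), 1, 4))
  truth$score_true <- sc
  scores <- purrr::map_dfr(1:3, function(r) {
    jitter <- sample(c(-1L, 0L, 1L), nrow(truth), replace = TRUE,
                     prob = c(rater_sd, 1 - 2 * rater_sd, rater_sd))
    tibble(source_id = truth$source_id, object_id = truth$object_id,
           rater_id = paste0("rater_", r),
           score = as.integer(clamp(truth$score_true + jitter, 1L, 4L)))
  }) |>
    dplyr::arrange(.data$source_id, .data$object_id, .data$rater_id)
  groups <- dplyr::distinct(truth[, c("source_id", "group")])
  list(truth = truth, scores = scores, groups = groups, spec = spec)
}

#' Simulate and measure a cohort one animal at a time
#'
#' Streaming variant of [generate_cohort()] + [measure_cohort()] for
#' study-scale runs: each animal's volume pair is built, measured and
#' discarded before the next, so peak memory stays at one animal. Results
#' are identical to the two-step path for the same spec (measurement
#' consumes no randomness).
#'
#' @param spec A [cohort_spec()].
#' @param min_voxels,min_overlap Measurement options (see [measure_cohort()]).
#' @param rater_sd Rater deviation probability (see [generate_cohort()]).
#' @return List: `mito`, `cristae`, `summaries` measured tables (as from
#'   [measure_cohort()]) plus `truth`, `scores`, `groups`, `spec`.
#' @export
simulate_and_measure <- function(spec, min_voxels = 10, min_overlap = 0.5,
                                 rater_sd = 0.15, chunk_size = 25) {
  truth <- sample_cohort_truth(spec)
  truth$density_realized <- NA_real_
  truth$n_cristae <- NA_integer_
  acc <- list()
  for (src in unique(truth$source_id)) {
    sel_all <- which(truth$source_id == src)
    chunks <- split(sel_all, ceiling(seq_along(sel_all) / chunk_size))
    crista_offset <- 0L
    parts <- vector("list", length(chunks))
    for (ci in seq_along(chunks)) {
      built <- build_animal_volumes(truth, chunks[[ci]], spec,
                                    crista_offset = crista_offset)
      truth <- built$truth
      crista_offset <- built$crista_offset
      pair <- built$volumes
      mito <- dplyr::filter(measure_all(pair$mito, min_voxels = min_voxels), .data$ok)
      cr <- dplyr::filter(measure_all(pair$cristae, min_voxels = min_voxels), .data$ok)
      asg <- assign_cristae(pair$cristae, pair$mito, min_overlap = min_overlap)
      rec <- cristae_records(cr, mito, asg)
      summ <- summarize_cristae_by_mito(mito, rec)
      parts[[ci]] <- list(mito = mito, cristae = rec, summaries = summ)
      rm(pair, built); gc(FALSE)
    }
    acc[[src]] <- list(mito = purrr::map_dfr(parts, "mito"),
                       cristae = purrr::map_dfr(parts, "cristae"),
                       summaries = purrr::map_dfr(parts, "summaries"))
  }
  fin <- finalize_cohort(truth, spec, rater_sd)
  lab <- function(tbl) {
    tbl <- dplyr::left_join(tbl, fin$groups, by = "source_id")
    dplyr::mutate(tbl, animal = .data$source_id, .after = "group")
  }
  list(mito = lab(purrr::map_dfr(acc, "mito")),
       cristae = lab(purrr::map_dfr(acc, "cristae")),
       summaries = lab(purrr::map_dfr(acc, "summaries")),
       truth = fin$truth, scores = fin$scores, groups = fin$groups, spec = spec)
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (src in names(cohort$volumes)) {
    write_label_volume(cohort$volumes[[src]]$mito, file.path(dir, paste0(src, "_mito.nrrd")))
    write_label_volume(cohort$volumes[[src]]$cristae, file.path(dir, paste0(src, "_cristae.nrrd")))
  }
  truth_flat <- dplyr::select(cohort$truth, -"shape_params")
  readr::write_csv(truth_flat, file.path(dir, "ground_truth.csv"), progress = FALSE)
  readr::write_csv(cohort$scores, file.path(dir, "scores.csv"), progress = FALSE)
  invisible(dir)
}

# Generator-internal planting: fall back to lamellar, then to a reduced
# density, when the requested (density, morphology) pair is infeasible for a
# small or thin mitochondrion; a mitochondrion too small for any cristae
# gets an all-zero crista label array.
plant_cristae_relaxed <- function(mask, density, morphology, spacing) {
  try_plant <- function(d, m) {
    tryCatch(plant_cristae(mask, d, m, spacing),
             mitomorph_infeasible_error = function(e) e)
  }
  res <- try_plant(density, morphology)
  if (inherits(res, "condition") && morphology != "lamellar") {
    res <- try_plant(density, "lamellar")
  }
  if (inherits(res, "condition")) {
    d2 <- 0.8 * (res$f_e %||% 0)
    res <- if (d2 > 0.02) try_plant(d2, "lamellar") else res
  }
  if (inherits(res, "condition")) {
    d <- dim(as_mask(mask))
    res <- list(labels = array(0L, d), realized_density = 0, n_cristae = 0L)
  }
  res
}

# shelf-pack object bounding boxes in the (y, x) plane with a common z slab
pack_objects <- function(dims_list, margin = 3L) {
  n <- length(dims_list)
  hs <- vapply(dims_list, function(d) d[2] + margin, 0L)  # y footprint
  ws <- vapply(dims_list, function(d) d[3] + margin, 0L)  # x footprint
  W <- max(max(ws), ceiling(sqrt(sum(as.numeric(hs) * ws)) * 1.15))
  ord <- order(hs, decreasing = TRUE)
  offsets <- vector("list", n)
  cur_y <- margin; cur_x <- margin; row_h <- 0L
  for (i in ord) {
    if (cur_x + ws[i] > W + margin) { # new shelf
      cur_y <- cur_y + row_h
      cur_x <- margin
      row_h <- 0L
    }
    offsets[[i]] <- c(margin, cur_y, cur_x)
    cur_x <- cur_x + ws[i]
    row_h <- max(row_h, hs[i])
  }
  nz <- max(vapply(dims_list, function(d) d[1], 0L)) + 2L * margin
  ny <- cur_y + row_h + margin
  nx <- W + 2L * margin
  list(offsets = offsets, dims = c(nz, as.integer(ny), as.integer(nx)))
}

#' Empirical type-I error of the two-group comparison under the null
#'
#' Runs seeded replicates of the generator's truth-stage sampling with all
#' effect multipliers set to 1 (identical distributions in both groups) and
#' counts how often [compare_groups()] on the analytic per-object volume
#' rejects at alpha. Calibrates the statistical layer without voxelization.
#'
#' @param n_reps Number of replicates.
#' @param n_objects Objects per group per replicate.
#' @param alpha Significance level.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List: `rate`, `n_reps`, `rejections`.
#' @export
null_calibration <- function(n_reps = 200, n_objects = 50, alpha = 0.05, seed = 1) {
  rej <- vapply(seq_len(n_reps), function(r) {
    spec <- cohort_spec(n_animals = 1, n_objects = n_objects,
                        volume_multiplier = 1, dispersion_multiplier = 1,
                        elongation_multiplier = 1, cristae_density_multiplier = 1,
                        seed = seed + r)
    tr <- sample_cohort_truth(spec)
    cg <- compare_groups(tr$volume_true_um3[tr$group == "adult"],
                         tr$volume_true_um3[tr$group == "aged"],
                         labels = c("adult", "aged"), metric = "volume_true_um3")
    cg$p_value < alpha
  }, TRUE)
  list(rate = mean(rej), n_reps = n_reps, rejections = sum(rej))
}
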
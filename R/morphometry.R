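#' Sphericity of a 3D object
#'
#' \eqn{\psi = \pi^{1/3} (6V)^{2/3} / SA}: 1 for a perfect sphere (the
#' isoperimetric maximiser), smaller for elongated or branched shapes.
#' Scale-invariant: doubling linear size leaves it unchanged.
#'
#' @param volume Volume (any unit, consistently with `surface_area`).
#' @param surface_area Surface area in the squared unit of `volume^(2/3)`.
#' @return Dimensionless sphericity, vectorized.
#' @seealso [mci()] for the complementary complexity measure; the two are
#'   algebraically linked by `mci * sphericity^3 = 9/(4*pi)`.
#' @export
sphericity <- function(volume, surface_area) {
  check_positive(volume, surface_area)
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface_area
}

#' Mitochondrial complexity index (MCI)
#'
#' \eqn{MCI = SA^3 / (16 \pi^2 V^2)}, a scale-invariant shape-complexity
#' measure that grows with surface elaboration and branching relative to
#' volume; 9/(4\eqn{\pi}) \eqn{\approx} 0.716 for a sphere. Objects with the
#' same shape but different sizes share the same MCI.
#'
#' @inheritParams sphericity
#' @return Dimensionless MCI, vectorized.
#' @export
mci <- function(volume, surface_area) {
  check_positive(volume, surface_area)
  surface_area^3 / (16 * pi^2 * volume^2)
}

check_positive <- function(volume, surface_area) {
  if (any(!is.finite(volume)) || any(!is.finite(surface_area)) ||
      any(volume <= 0) || any(surface_area <= 0)) {
    abort("volume and surface area must be finite and > 0.",
          class = "mitomorph_domain_error")
  }
}

#' Voxel-exact object volume
#'
#' @param mask 3D logical/0-1 array, `(z, y, x)` order.
#' @param spacing `(sx, sy, sz)` in nm.
#' @return Volume in \eqn{\mu m^3} (voxel count times voxel volume, exact).
#' @export
compute_volume <- function(mask, spacing = c(10, 10, 50)) {
  mask <- as_mask(mask)
  n <- sum(mask)
  if (n == 0) abort("empty mask.", class = "mitomorph_degenerate_error")
  n * prod(spacing) / NM3_PER_UM3
}

as_mask <- function(mask) {
  if (inherits(mask, "label_volume")) mask <- mask$grid > 0
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    abort("mask must be a 3D array.", class = "mitomorph_shape_error")
  }
  mask > 0
}

pad_array <- function(mask, pad) {
  d <- dim(mask)
  out <- array(0, d + 2 * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- mask
  out
}

#' Iso-surface area of a voxelized object
#'
#' The binary occupancy is smoothed with a small spacing-aware Gaussian
#' (default sigma 1 voxel per axis) and the 0.5-level iso-surface is meshed
#' by marching tetrahedra on the anisotropically scaled grid; the returned
#' value is the summed triangle area. Smoothing suppresses the staircase
#' overestimate of meshing raw binary data (about +36% for digitized spheres)
#' to a few percent. For objects thin enough that smoothing drops the field
#' below the 0.5 level, the raw binary field is meshed instead, and a single
#' voxel falls back to its voxel-face area; both fallbacks raise a warning.
#'
#' @inheritParams compute_volume
#' @param sigma_voxels Gaussian sigma per axis in voxels (scalar).
#' @return Surface area in \eqn{\mu m^2}; deterministic for fixed input.
#' @export
compute_surface_area <- function(mask, spacing = c(10, 10, 50), sigma_voxels = 1) {
  mask <- as_mask(mask)
  n <- sum(mask)
  if (n == 0) abort("empty mask.", class = "mitomorph_degenerate_error")
  sp_zyx <- as.numeric(spacing[c(3, 2, 1)])
  if (n == 1) {
    warn("single-voxel object: surface area from voxel faces.",
         class = "mitomorph_single_voxel_warning")
    return(voxel_face_area(array(as.integer(mask), dim(mask)), dim(mask), sp_zyx) / NM2_PER_UM2)
  }
  pad <- ceiling(3 * sigma_voxels) + 1
  f <- pad_array(mask, pad)
  sm <- gauss_smooth_3d(f, dim(f), rep(sigma_voxels, 3))
  area <- mtetra_area(sm, dim(f), sp_zyx, 0.5)
  if (area <= 0) {
    warn("object too thin for smoothed meshing; using raw binary iso-surface.",
         class = "mitomorph_thin_object_warning")
    area <- mtetra_area(f, dim(f), sp_zyx, 0.5)
  }
  area / NM2_PER_UM2
}

#' Slice-wise perimeter of a voxelized object
#'
#' For each z-slice containing the object, the boundary length of the 2D
#' cross-section is measured as the polygonal contour at the 0.5 level of
#' the Gaussian-smoothed slice (marching squares via
#' [grDevices::contourLines()]), scaled by the in-plane spacing; the
#' per-slice lengths are then reduced across slices by `reducer`
#' (default mean). Slices whose smoothed field never reaches 0.5 fall back
#' to the raw binary contour.
#'
#' The slice-wise mean is the package's operational definition of an
#' object's "perimeter"; `sum` and `max` are exposed for sensitivity
#' analyses.
#'
#' @inheritParams compute_surface_area
#' @param reducer One of `"mean"`, `"sum"`, `"max"`.
#' @return Perimeter in \eqn{\mu m}.
#' @export
compute_perimeter <- function(mask, spacing = c(10, 10, 50),
                              reducer = c("mean", "sum", "max"), sigma_voxels = 1) {
  reducer <- match.arg(reducer)
  mask <- as_mask(mask)
  if (sum(mask) == 0) abort("empty mask.", class = "mitomorph_degenerate_error")
  sx <- spacing[1]; sy <- spacing[2]
  zs <- which(apply(mask, 1, any))
  lens <- vapply(zs, function(z) slice_contour_length(mask[z, , ], sx, sy, sigma_voxels), 0.0)
  lens <- lens[lens > 0]
  if (length(lens) == 0) return(0)
  out <- switch(reducer, mean = mean(lens), sum = sum(lens), max = max(lens))
  out / NM_PER_UM
}

slice_contour_length <- function(m, sx, sy, sigma_voxels = 1) {
  pad <- ceiling(3 * sigma_voxels) + 1
  d <- dim(m)
  f <- matrix(0, d[1] + 2 * pad, d[2] + 2 * pad)
  f[pad + seq_len(d[1]), pad + seq_len(d[2])] <- m
  a <- array(f, c(1L, dim(f)))
  sm <- gauss_smooth_3d(a, dim(a), c(0, sigma_voxels, sigma_voxels))
  g <- array(sm, dim(a))[1, , ]
  len <- contour_length(g, sy, sx)
  if (len == 0) len <- contour_length(f, sy, sx) # thin sliver: raw contour
  len
}

contour_length <- function(g, s_row, s_col) {
  cl <- grDevices::contourLines(x = (seq_len(nrow(g)) - 1) * s_row,
                                y = (seq_len(ncol(g)) - 1) * s_col,
                                z = g, levels = 0.5)
  if (length(cl) == 0) return(0)
  sum(vapply(cl, function(cc) sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)), 0.0))
}

#' Extract per-object masks from a label volume
#'
#' In `labels` mode each distinct nonzero label is one object; in
#' `connected_components` mode the 26-connected components of the foreground
#' are relabelled (1..K in scan order). Objects smaller than `min_voxels`
#' are dropped and counted in the `n_dropped` attribute. `touches_boundary`
#' flags objects with any voxel on the grid boundary.
#'
#' @param vol A [label_volume()].
#' @param mode `"labels"` or `"connected_components"`.
#' @param min_voxels Minimum voxel count to keep an object (default 10,
#'   suppressing segmentation specks).
#' @return Tibble with `object_id`, `voxel_count`, `touches_boundary`,
#'   centroid (nm), bbox columns and a `mask` list-column of cropped logical
#'   arrays plus an `offset_zyx` list-column (0-based crop origin);
#'   attribute `n_dropped` counts sub-threshold objects.
#' @export
extract_objects <- function(vol, mode = c("labels", "connected_components"),
                            min_voxels = 10) {
  stopifnot(inherits(vol, "label_volume"))
  mode <- match.arg(mode)
  if (min_voxels < 1) abort("`min_voxels` must be >= 1.", class = "mitomorph_parameter_error")
  grid <- vol$grid
  if (mode == "connected_components") {
    grid <- cc_label_3d(array(as.integer(grid > 0L), dim(grid)), dim(grid))
  }
  st <- label_stats_cpp(grid, dim(grid))
  st <- as_tibble(st)
  dropped <- sum(st$n_voxels < min_voxels)
  st <- st[st$n_voxels >= min_voxels, , drop = FALSE]
  d <- dim(grid)
  sp <- vol$spacing
  out <- purrr::pmap(st, function(label, n_voxels, cz, cy, cx, z0, z1, y0, y1, x0, x1) {
    sub <- grid[(z0 + 1):(z1 + 1), (y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
    list(
      object_id = label,
      voxel_count = as.integer(n_voxels),
      touches_boundary = z0 == 0L || y0 == 0L || x0 == 0L ||
        z1 == d[1] - 1L || y1 == d[2] - 1L || x1 == d[3] - 1L,
      centroid_z_nm = cz * sp["z"], centroid_y_nm = cy * sp["y"], centroid_x_nm = cx * sp["x"],
      mask = array(sub == label, dim(sub)),
      offset_zyx = c(z0, y0, x0)
    )
  })
  tbl <- tibble(
    object_id = purrr::map_int(out, "object_id"),
    voxel_count = purrr::map_int(out, "voxel_count"),
    touches_boundary = purrr::map_lgl(out, "touches_boundary"),
    centroid_z_nm = purrr::map_dbl(out, "centroid_z_nm"),
    centroid_y_nm = purrr::map_dbl(out, "centroid_y_nm"),
    centroid_x_nm = purrr::map_dbl(out, "centroid_x_nm"),
    mask = purrr::map(out, "mask"),
    offset_zyx = purrr::map(out, "offset_zyx")
  )
  attr(tbl, "n_dropped") <- dropped
  tbl
}

#' Measure every object in a label volume
#'
#' Runs the full per-object morphometry battery — voxel-exact volume,
#' iso-surface area, slice-wise perimeter, sphericity and MCI — and returns
#' one row per object, ordered by `object_id`. Per-object failures are
#' captured as flagged rows (`ok = FALSE`) rather than aborting the batch.
#'
#' @inheritParams extract_objects
#' @param perimeter_reducer Reducer across slices (see [compute_perimeter()]).
#' @param include_boundary Keep objects touching the grid boundary (default
#'   TRUE; they stay flagged via `touches_boundary`).
#' @param sigma_voxels Smoothing sigma for surface/perimeter estimation.
#' @return A metrics tibble with columns `source_id`, `object_id`,
#'   `voxel_count`, `volume_um3`, `surface_area_um2`, `perimeter_um`,
#'   `sphericity`, `mci`, centroids (nm), `touches_boundary`, `ok`.
#' @export
measure_all <- function(vol, mode = c("labels", "connected_components"),
                        min_voxels = 10, perimeter_reducer = "mean",
                        include_boundary = TRUE, sigma_voxels = 1) {
  objs <- extract_objects(vol, mode, min_voxels)
  if (!include_boundary) objs <- objs[!objs$touches_boundary, , drop = FALSE]
  if (nrow(objs) == 0) {
    return(tibble(source_id = character(), object_id = integer(),
                  voxel_count = integer(), volume_um3 = double(),
                  surface_area_um2 = double(), perimeter_um = double(),
                  sphericity = double(), mci = double(), ok = logical(),
                  centroid_z_nm = double(), centroid_y_nm = double(),
                  centroid_x_nm = double(), touches_boundary = logical()))
  }
  sp <- unname(vol$spacing)
  rows <- purrr::map(seq_len(nrow(objs)), function(i) {
    m <- objs$mask[[i]]
    tryCatch({
      v <- compute_volume(m, sp)
      sa <- suppressWarnings(compute_surface_area(m, sp, sigma_voxels))
      pe <- compute_perimeter(m, sp, perimeter_reducer, sigma_voxels)
      tibble(volume_um3 = v, surface_area_um2 = sa, perimeter_um = pe,
             sphericity = sphericity(v, sa), mci = mci(v, sa), ok = TRUE)
    }, error = function(e) {
      tibble(volume_um3 = NA_real_, surface_area_um2 = NA_real_,
             perimeter_um = NA_real_, sphericity = NA_real_, mci = NA_real_, ok = FALSE)
    })
  })
  res <- dplyr::bind_cols(
    tibble(source_id = vol$source_id, object_id = objs$object_id,
           voxel_count = objs$voxel_count),
    dplyr::bind_rows(rows),
    objs[, c("centroid_z_nm", "centroid_y_nm", "centroid_x_nm", "touches_boundary")]
  )
  dplyr::arrange(res, .data$object_id)
}
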
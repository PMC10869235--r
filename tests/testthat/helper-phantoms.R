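# Shared fixtures: all phantoms are built in code, no files.

# digitized ball of radius r_um, centered, padded
ball_mask <- function(r_um, spacing = c(10, 10, 50)) {
  make_shape("sphere", list(r_nm = r_um * 1e3), spacing)$mask
}

# axis-aligned solid block of physical size (lx, ly, lz) um
block_mask <- function(lx_um, ly_um, lz_um, spacing = c(10, 10, 50), pad = 6) {
  nvox <- round(c(lz_um * 1e3 / spacing[3], ly_um * 1e3 / spacing[2],
                  lx_um * 1e3 / spacing[1]))
  m <- array(FALSE, nvox + 2 * pad)
  m[pad + seq_len(nvox[1]), pad + seq_len(nvox[2]), pad + seq_len(nvox[3])] <- TRUE
  m
}

# tiny label volume from a list of voxel coordinate matrices (z, y, x), 1-based
lv_from_points <- function(points_by_label, dims, spacing = c(10, 10, 50), source_id = "test") {
  g <- array(0L, dims)
  for (lab in seq_along(points_by_label)) {
    p <- points_by_label[[lab]]
    g[cbind(p[, 1], p[, 2], p[, 3])] <- lab
  }
  label_volume(g, spacing, source_id)
}

# brute-force 26-connected labelling by repeated voxel scans (small grids only)
flood_fill_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] > 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      z <- (cur - 1) %% d[1] + 1
      y <- ((cur - 1) %/% d[1]) %% d[2] + 1
      x <- (cur - 1) %/% (d[1] * d[2]) + 1
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        zz <- z + dz; yy <- y + dy; xx <- x + dx
        if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3]) next
        q <- zz + d[1] * (yy - 1) + d[1] * d[2] * (xx - 1)
        if (mask[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# small fully-specified cohort for integration-style tests
tiny_cohort <- function(seed = 11, n_objects = 5, n_animals = 1) {
  generate_cohort(cohort_spec(n_animals = n_animals, n_objects = n_objects, seed = seed))
}
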
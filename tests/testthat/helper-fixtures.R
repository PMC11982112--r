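# Shared fixtures and independent oracles, built in code.

# rasterize a filled disk of radius r px, centred
raster_disk <- function(r, pad = 5) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  xy <- expand.grid(row = seq_len(n), col = seq_len(n))
  matrix(as.integer((xy$row - c0)^2 + (xy$col - c0)^2 <= r^2), n, n)
}

# rasterize a filled axis-aligned rectangle len x wid px
raster_rect <- function(len, wid, pad = 5) {
  m <- matrix(0L, wid + 2 * pad, len + 2 * pad)
  m[pad + seq_len(wid), pad + seq_len(len)] <- 1L
  m
}

# rasterize a filled axis-aligned ellipse (semi-axes a along x, b along y)
raster_ellipse <- function(a, b, pad = 5) {
  nr <- 2 * (b + pad) + 1
  nc <- 2 * (a + pad) + 1
  r0 <- b + pad + 1; c0 <- a + pad + 1
  xy <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  inside <- ((xy$col - c0) / a)^2 + ((xy$row - r0) / b)^2 <= 1
  matrix(as.integer(inside), nr, nc)
}

# brute-force voxelization oracle for a spheroid: semi-axis a along the
# rotation axis, semi-axis b across it (independent of the distance-map
# estimator: counts unit voxels inside the generating solid)
voxel_spheroid_volume <- function(a, b) {
  g <- expand.grid(
    x = seq(-a - 1, a + 1, by = 1),
    y = seq(-b - 1, b + 1, by = 1),
    z = seq(-b - 1, b + 1, by = 1)
  )
  sum((g$x / a)^2 + (g$y / b)^2 + (g$z / b)^2 <= 1)
}

# a low-noise taxon with effectively fixed dimensions
fixed_taxon <- function(name = "probe", family = "needle",
                        length_um = 60, width_um = 3, ...) {
  taxon_model(name, family, length_um = length_um, width_um = width_um,
              size_spread = 1e-6, ...)
}

# hand-built profile: sharp thermal layer over near-isothermal water,
# flat irradiance spectrum of the given magnitude at every depth
convective_test_profile <- function(ed_value = 20,
                                    depths = seq(0.5, 17.5, 0.5)) {
  temp <- ifelse(depths <= 2, 0.5 + (3.2 - 0.5) * depths / 2,
                 3.2 + 0.003 * (depths - 2))
  prof <- tibble::tibble(
    time = as.POSIXct("2015-02-15 12:00:00", tz = "UTC"),
    depth_m = depths, temp_c = temp, cond_s_m = 0.005, pres_dbar = depths
  )
  for (l in c(398.76, 500, 600, 700.04)) {
    prof[[paste0("ed_", l)]] <- ed_value
  }
  prof
}

# gaussian feature-space training data for classifier tests: two or more
# classes separated by `sep` standard deviations in two feature columns
gaussian_features <- function(n_per_class = 60, classes = c("A", "B"),
                              sep = 4, seed = 1) {
  withr::with_seed(seed, {
    purrr::imap_dfr(setNames(seq_along(classes) - 1, classes),
      function(k, nm) {
        tibble::tibble(
          image_id = sprintf("%s_%03d", nm, seq_len(n_per_class)),
          class = nm,
          area_um2 = rnorm(n_per_class, 100 + k * sep * 10, 10),
          perimeter_um = rnorm(n_per_class, 50 + k * sep * 5, 5),
          elongation = rexp(n_per_class, 1) + 1
        )
      })
  })
}
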
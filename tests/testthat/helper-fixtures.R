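# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# default phantom voxelized at the package's desk-scale grid
fx_default_phantom <- function() fixture("default_phantom", function() {
  spec <- phantom_spec()
  g <- grid_def(c(96L, 96L, 96L), 1.5)
  list(spec = spec,
       ed = voxelize_phase(spec, "ED", g),
       es = voxelize_phase(spec, "ES", g),
       grid = g)
})

# small single-slice water disk for projector tests
fx_disk_slice <- function(radius = 30, hu_in = 0, hu_out = -1000,
                          centre = c(0, 0)) {
  g <- grid_def(c(96L, 96L, 1L), c(1.5, 1.5, 1.5))
  w <- lvdose:::voxel_world_coords(g)
  hu <- ifelse((w[, 1] - centre[1])^2 + (w[, 2] - centre[2])^2 <= radius^2,
               hu_in, hu_out)
  image_volume(array(hu, g$n), g$spacing, g$origin)
}

fx_geometry <- function() scan_geometry(192L, 1.0, 180L, quiet = TRUE)

# numeric-integration oracle for the truncated-ellipsoid cavity volume:
# stacked-disk quadrature along the long axis at fine dz
oracle_trunc_volume <- function(a, c, f, dz = 0.01) {
  z <- seq(-c, f * c, by = dz)
  r2 <- pmax(1 - (z / c)^2, 0) * a^2
  sum(pi * r2 * dz)
}

# hand-built SAX view (annulus) for metric unit tests: blood disk of radius
# r_endo inside a myocardial ring out to r_epi, on a 1 mm pixel grid
fx_ring_view <- function(r_endo, r_epi, npix = 121L, sp = 1.0) {
  off <- (seq_len(npix) - (npix + 1) / 2) * sp
  d2 <- outer(off^2, off^2, "+")
  list(kind = "short-axis",
       labels = matrix(ifelse(d2 <= r_endo^2, 2L,
                              ifelse(d2 <= r_epi^2, 1L, 0L)), npix, npix),
       blood_frac = matrix(as.numeric(d2 <= r_endo^2), npix, npix),
       myo_frac = matrix(as.numeric(d2 > r_endo^2 & d2 <= r_epi^2),
                         npix, npix),
       pixel_spacing_mm = sp)
}

# hand-built long-axis view with a rectangular blood pool spanning
# `length_px` rows
fx_long_view <- function(length_px, npix = 121L, sp = 1.0, width_px = 21L) {
  bf <- matrix(0, npix, npix)
  r0 <- (npix - length_px) %/% 2
  c0 <- (npix - width_px) %/% 2
  bf[r0 + seq_len(length_px), c0 + seq_len(width_px)] <- 1
  list(kind = "long-axis", blood_frac = bf,
       myo_frac = matrix(0, npix, npix), pixel_spacing_mm = sp)
}

fx_view_set <- function(l2ch, lplax) {
  structure(list(views = list("2CH" = l2ch, "PLAX" = lplax)),
            class = "view_set")
}
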
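# Analytic phantom builders used across the suite. Voxel i (1-based)
# has world coordinate (i - 1) * spacing, matching the package default
# affine.

make_sphere_mask <- function(r, spacing = c(1, 1, 1), pad = 4) {
  d <- ceiling(2 * r / spacing) + 2 * pad
  ctr <- (d - 1) / 2 * spacing
  x <- (seq_len(d[1]) - 1) * spacing[1] - ctr[1]
  y <- (seq_len(d[2]) - 1) * spacing[2] - ctr[2]
  z <- (seq_len(d[3]) - 1) * spacing[3] - ctr[3]
  g <- outer(outer(x^2, y^2, `+`), z^2, `+`) <= r^2
  hematoma_mask(g, spacing = spacing)
}

make_box_mask <- function(side_vox = 20, pad = 4, spacing = c(1, 1, 1)) {
  d <- rep(side_vox + 2 * pad, 3)
  g <- array(0L, d)
  g[(pad + 1):(pad + side_vox), (pad + 1):(pad + side_vox),
    (pad + 1):(pad + side_vox)] <- 1L
  hematoma_mask(g, spacing = spacing)
}

# Axis-aligned ellipsoid given semi-axes in grid order (x = LR,
# y = AP, z = SI).
make_ellipsoid_grid <- function(semi, grid_shape, spacing = c(1, 1, 1),
                                center = NULL) {
  if (is.null(center)) center <- (grid_shape - 1) / 2 * spacing
  x <- ((seq_len(grid_shape[1]) - 1) * spacing[1] - center[1]) / semi[1]
  y <- ((seq_len(grid_shape[2]) - 1) * spacing[2] - center[2]) / semi[2]
  z <- ((seq_len(grid_shape[3]) - 1) * spacing[3] - center[3]) / semi[3]
  g <- outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
  hematoma_mask(g, spacing = spacing)
}
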
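# shared fixtures; everything here is deterministic and cheap

lossless_air <- acoustic_medium("air", 343, 1.2, 0, 1)
lossless_tissue <- acoustic_medium("tissue", 1489, 950, 0, 1)
lossless_fluid <- acoustic_medium("fluid", 1500, 1000, 0, 1)

# one shared analytic full-band sweep of the validation configuration
# (computed lazily, reused across test files)
validation_sweep_cache <- new.env()
validation_sweep <- function() {
  if (is.null(validation_sweep_cache$sweep)) {
    topo <- nested_sphere_phantom(f = 1000)
    grid <- interior_grid(topo$surfaces[[2]], 0.015)
    model <- layered_sphere_from_topology(topo)
    bands <- twelfth_octave_grid()
    validation_sweep_cache$sweep <-
      sweep_inner_sphere(model, bands$frequencies, grid)
    validation_sweep_cache$grid <- grid
    validation_sweep_cache$model <- model
  }
  validation_sweep_cache
}

# tetrahedron as a closed, outward-oriented surface mesh
tetra_mesh <- function(scale = 1, shift = c(0, 0, 0)) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * scale
  v <- sweep(v, 2, shift, `+`)
  tr <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surface_mesh(v, tr, label = "tet")
}
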
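# Shared fixtures, memoized so expensive FEM solves run once per test session.
.fixtures <- new.env(parent = emptyenv())

fix_geom <- function() vf_geometry(profile = "rescaled")

# Small 9-configuration dataset (1 x 3 x 3 subgrid, coarse mesh, 2 modes)
fix_small_dataset <- function() {
  if (is.null(.fixtures$small_ds)) {
    grid <- vf_material_grid(Et_values = 2e3,
                             gap_values = c(10e3, 20e3, 40e3))
    ds <- generate_dataset(grid, fix_geom(), resolution = c(6, 4, 6),
                           n_modes = 2, split_seed = 7)
    .fixtures$small_ds <- match_modes(ds)
  }
  .fixtures$small_ds
}

# One moderately resolved FEM solve of a non-mid-grid configuration,
# shared by loss/Rayleigh tests.
fix_reference_solution <- function() {
  if (is.null(.fixtures$ref_sol)) {
    geom <- fix_geom()
    mat <- vf_material(1e3, 10e3, 5e3)
    aux <- vf_elastic_aux()
    sol <- fem_modal_analysis(geom, mat, resolution = c(10, 6, 10),
                              n_modes = 2, aux = aux)
    .fixtures$ref_sol <- list(
      geom = geom, mat = mat, aux = aux, sol = sol, mesh = sol$mesh,
      Cb = build_layer_elasticity(mat$Et, mat$gap_body, aux, "body")$C_voigt,
      Cc = build_layer_elasticity(mat$Et, mat$gap_cover, aux, "cover")$C_voigt
    )
  }
  .fixtures$ref_sol
}

fix_small_network <- function(width = 16, depth = 2, encoder_width = 8,
                              seed = 1) {
  init_network(
    network_spec("custom", width = width, depth = depth, omega0 = 5,
                 encoder_width = encoder_width),
    fix_geom(), vf_material_grid(), seed = seed
  )
}

random_interior_points <- function(n, geom, seed = 1) {
  set.seed(seed)
  cbind(runif(n, 0, geom$D), runif(n, 0, geom$T_thick), runif(n, 0, geom$L))
}
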
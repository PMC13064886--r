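# vfpinn

Physics-informed neural networks for in vacuo vocal fold eigenmodes.

## The problem

Small-amplitude vocal fold vibration is modeled as a linear elastic
eigenvalue problem on a layered rectangular prism: a soft *cover* layer over
a stiffer *body* layer, both transversely isotropic with the
anterior–posterior direction as the symmetry axis. The fold is clamped on
its lateral, anterior, and posterior faces and traction-free elsewhere; the
eigenpairs (λ, u) of

∇·σ(u) = −λ ρ u,  λ = (2π f)²

give the natural frequencies f and mode shapes u. The material space is
spanned by the transverse Young's modulus Et and the anterior–posterior
shear moduli of body and cover (with E_AP = 4 G_AP).

The package provides

- a **finite element reference solver**: structured trilinear hexahedral
  mesh with a node plane on the body–cover interface, consistent
  stiffness/mass assembly, sparse generalized eigensolver — used to generate
  modal datasets over a grid of 75 material configurations; and
- a **physics-informed neural network**: a SiLU material encoder feeding a
  sinusoidal representation network (SIREN) that learns one vibration mode
  as a smooth displacement field jointly over the material space, trained
  with a composite loss (PDE residual, boundary/interface conditions,
  Rayleigh-quotient eigenvalue penalty, cosine mode-shape penalty). Once
  trained, it predicts modes of unseen material configurations without
  re-solving the eigenproblem.

See the vignette `vignettes/eigenmode-pinn.Rmd` for the full method
description.

## Worked example

Reference frequencies for the configuration Et = 2 kPa, G_AP body/cover =
20/10 kPa on the rescaled depth profile:

```r
library(vfpinn)
geom <- vf_geometry(profile = "rescaled")
mat <- vf_material(2e3, 20e3, 10e3)
sol <- fem_modal_analysis(geom, mat, resolution = c(16, 8, 16), n_modes = 4)
round(sol$frequency_hz, 2)
#> [1]  84.09 100.90 114.63 133.31
```

Generate a small modal dataset over a 1×3×3 material subgrid and inspect
the fundamental frequencies:

```r
grid <- vf_material_grid(Et_values = 2e3, gap_values = c(10e3, 20e3, 40e3))
ds <- generate_dataset(grid, geom, resolution = c(6, 4, 6), n_modes = 2,
                       split_seed = 7)
ds <- match_modes(ds)
ds$grid[, c("config_id", "split")]
#>       config_id      split
#> 1 Et2_Gb10_Gc10 validation
#> 2 Et2_Gb10_Gc20      train
#> 3 Et2_Gb10_Gc40      train
#> 4 Et2_Gb20_Gc10      train
#> 5 Et2_Gb20_Gc20      train
#> 6 Et2_Gb20_Gc40      train
#> 7 Et2_Gb40_Gc10      train
#> 8 Et2_Gb40_Gc20 validation
#> 9 Et2_Gb40_Gc40      train
round(ds$frequency_hz[, 1], 2)
#> [1]  74.47  83.82  90.25  89.71 103.09 113.70 105.21 122.91 143.26
```

Train a small PINN on mode 1 of this dataset and evaluate it on the held-out
configurations (takes a few minutes on one CPU):

```r
cfg <- train_config(
  mode_index = 1, epochs = 1500, lr = 2e-4,
  n_interior = 600, n_per_face = 64, n_interface = 48,
  seed_init = 42, seed_sample = 42,
  network = network_spec("custom", width = 32, depth = 3, omega0 = 5,
                         encoder_width = 16)
)
tr <- train_mode(ds, cfg)
ev <- evaluate_mode(tr, ds, 1, split = "validation")
ev$summary
```

This exact study is part of the test suite (the scaled-down end-to-end
recovery test), which asserts mean relative eigenfrequency error below 10%
and mean cosine above 0.9 on the held-out configurations.

The full-scale study (75 configurations, 4×128 network) uses the same API,
or the command-line interface in `inst/cli/vfpinn.R`
(`generate-dataset` / `train` / `evaluate` / `predict`).

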
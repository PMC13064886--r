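test_that("network initialization follows the sinusoidal-layer weight ranges", {
  spec <- network_spec("custom", width = 32, depth = 3, omega0 = 5,
                       encoder_width = 16)
  net <- init_network(spec, fix_geom(), vf_material_grid(), seed = 9)
  d_in <- 3 + 16
  W1 <- net$hidden[[1]]$W
  expect_equal(dim(W1), c(32, d_in))
  expect_lte(max(abs(W1)), 1 / d_in)
  r <- sqrt(6 / 32) / 5
  expect_lte(max(abs(net$hidden[[2]]$W)), r)
  expect_lte(max(abs(net$out$W)), r)
  expect_true(all(net$hidden[[1]]$b == 0))
  # paper preset dimensions
  ps <- network_spec("paper")
  expect_equal(ps$width, 128)
  expect_equal(ps$depth, 4)
  expect_equal(ps$omega0, 5)
  expect_equal(ps$encoder_width, 64)
})

test_that("weight packing and unpacking round-trip exactly", {
  net <- fix_small_network(seed = 3)
  theta <- vfpinn:::.net_pack(net)
  set.seed(1)
  theta2 <- theta + rnorm(length(theta), sd = 0.01)
  net2 <- vfpinn:::.net_unpack(net, theta2)
  expect_equal(vfpinn:::.net_pack(net2), theta2)
  expect_equal(vfpinn:::.net_pack(vfpinn:::.net_unpack(net, theta)), theta)
})

test_that("material encoding is deterministic and warns on extrapolation", {
  net <- fix_small_network()
  m <- vf_material(2e3, 20e3, 10e3)
  e1 <- encode_materials(net, m)
  e2 <- encode_materials(net, c(2e3, 20e3, 10e3))
  expect_identical(e1$encoding, e2$encoding)
  expect_equal(unname(e1$m_norm), c(1 / 3, 19 / 39, 9 / 39),
               tolerance = 1e-12)
  expect_warning(encode_materials(net, c(8e3, 20e3, 10e3)), "extrapolates")
})

test_that("analytic spatial derivatives match central finite differences", {
  net <- fix_small_network(width = 24, depth = 3, seed = 5)
  g <- fix_geom()
  # keep points away from the boundary so FD stencils stay inside
  set.seed(6)
  X <- cbind(runif(20, 0.1 * g$D, 0.9 * g$D),
             runif(20, 0.1 * g$T_thick, 0.9 * g$T_thick),
             runif(20, 0.1 * g$L, 0.9 * g$L))
  m <- vf_material(2e3, 20e3, 10e3)
  an <- predict_displacement(net, X, m, deriv = 2L)
  fd <- fd_network_derivs(net, X, m, step_norm = 1e-4)
  expect_lt(max(abs(an$grad - fd$grad)) / max(abs(fd$grad)), 1e-5)
  expect_lt(max(abs(an$hess - fd$hess)) / max(abs(fd$hess)), 1e-3)
})

test_that("compiled and reference differentiation backends agree to machine precision", {
  net <- fix_small_network(width = 20, depth = 3, seed = 7)
  g <- fix_geom()
  X <- random_interior_points(30, g, seed = 8)
  m <- vf_material(2e3, 40e3, 20e3)
  old <- options(vfpinn.backend = "r")
  on.exit(options(old), add = TRUE)
  fr <- vfpinn:::.net_forward(net, X, m, deriv = 2L, want_cache = TRUE)
  options(vfpinn.backend = "cpp")
  fc <- vfpinn:::.net_forward(net, X, m, deriv = 2L, want_cache = TRUE)
  expect_equal(fc$u, fr$u, tolerance = 1e-13)
  expect_equal(fc$grad, fr$grad, tolerance = 1e-12)
  expect_equal(fc$hess, fr$hess, tolerance = 1e-10)
  set.seed(9)
  ubar <- matrix(rnorm(90), 30, 3)
  gbar <- array(rnorm(270), c(30, 3, 3))
  hbar <- array(rnorm(540), c(30, 3, 6))
  br <- vfpinn:::.net_backward(net, fr$cache, ubar, gbar, hbar)
  bc <- vfpinn:::.net_backward(net, fc$cache, ubar, gbar, hbar)
  expect_lt(max(abs(br - bc)) / max(abs(br)), 1e-12)
  # hessian-only adjoints must still propagate first-derivative state
  br2 <- vfpinn:::.net_backward(net, fr$cache, ubar, NULL, hbar)
  bc2 <- vfpinn:::.net_backward(net, fc$cache, ubar, NULL, hbar)
  expect_lt(max(abs(br2 - bc2)) / max(abs(br2)), 1e-12)
})

test_that("forward evaluation is reproducible and batch-consistent", {
  net <- fix_small_network(seed = 2)
  g <- fix_geom()
  X <- random_interior_points(10, g, seed = 3)
  m <- vf_material(1e3, 10e3, 10e3)
  a <- predict_displacement(net, X, m, deriv = 2L)
  b <- predict_displacement(net, X, m, deriv = 2L)
  expect_identical(a$u, b$u)
  expect_identical(a$hess, b$hess)
  # evaluating point-by-point matches the batched evaluation
  row3 <- predict_displacement(net, X[3, , drop = FALSE], m, deriv = 1L)
  expect_equal(drop(row3$u), a$u[3, ], tolerance = 1e-12)
  expect_equal(row3$grad[1, , ], a$grad[3, , ], tolerance = 1e-12)
})

test_that("stress pipeline applies the layer stiffness to network strains", {
  net <- fix_small_network(seed = 4)
  g <- fix_geom()
  X <- random_interior_points(5, g, seed = 5)
  m <- vf_material(2e3, 20e3, 10e3)
  C <- build_layer_elasticity(m$Et, m$gap_cover, layer = "cover")$C_voigt
  out <- displacement_jacobian_and_stress(net, X, m, C)
  expect_equal(out$strain, grad_to_strain(out$grad), tolerance = 1e-14)
  expect_equal(out$stress, out$strain %*% t(C), tolerance = 1e-10)
})

test_that("network checkpoints round-trip through portable JSON", {
  net <- fix_small_network(width = 12, depth = 2, seed = 6)
  g <- fix_geom()
  X <- random_interior_points(7, g, seed = 7)
  m <- vf_material(4e3, 30e3, 20e3)
  path <- tempfile(fileext = ".json")
  save_network(net, path, mode_index = 2L, meta = list(run = "test"))
  net2 <- load_network(path, geom = g)
  expect_equal(predict_displacement(net2, X, m)$u,
               predict_displacement(net, X, m)$u, tolerance = 1e-12)
  expect_equal(attr(net2, "mode_index"), 2L)
  unlink(path)
})
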
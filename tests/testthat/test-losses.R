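test_that("closed-form loss values hold exactly", {
  u <- c(1, 0, 2, -1)
  expect_equal(cosine_loss(u, u), 0)
  expect_equal(cosine_loss(u, -u), 2)
  expect_equal(cosine_loss(c(1, 0), c(0, 1)), 1)
  expect_error(cosine_loss(u, rep(0, 4)), "degenerate")
  expect_error(cosine_loss(u, u[1:2]), "length")
  expect_equal(eigenvalue_loss(2, 1), 1)
  expect_equal(eigenvalue_loss(5, 5), 0)
  expect_equal(eigenvalue_loss(0.5, 1), 0.25)
  expect_error(eigenvalue_loss(1, -1), "positive")
})

test_that("constant and linear analytic fields behave as designed", {
  g <- fix_geom()
  cl <- sample_collocation(g, 200, 20, 20, seed = 13)
  fc <- field_constant(c(0.5, 0, 0))
  out <- fc(cl$interior$points, deriv = 2L)
  expect_true(all(out$u[, 1] == 0.5))
  expect_true(all(out$grad == 0))
  A <- matrix(c(0, 0.2, 0, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  fl <- field_linear(A)
  lo <- fl(cl$interior$points, deriv = 2L)
  expect_equal(lo$u[, 1], 0.2 * cl$interior$points[, 2], tolerance = 1e-14)
  expect_true(all(lo$grad[, 1, 2] == 0.2))
  expect_true(all(lo$hess == 0))
})

test_that("PDE residual matches an independent tensor-contraction oracle on a polynomial field", {
  g <- fix_geom()
  C <- build_layer_elasticity(2e3, 20e3, layer = "body")$C_voigt
  rho <- 1030
  lambda <- 2e5
  # smooth polynomial field and its exact derivatives (scaled to the prism)
  sx <- 1 / g$D; sy <- 1 / g$T_thick; sz <- 1 / g$L
  u_fun <- function(x) {
    c(0.3 * (sx * x[1])^2 + 0.1 * (sy * x[2]) * (sz * x[3]),
      -0.2 * (sy * x[2])^2 + 0.05 * (sx * x[1]) * (sz * x[3]),
      0.15 * (sz * x[3])^2 - 0.08 * (sx * x[1]) * (sy * x[2]))
  }
  set.seed(14)
  pts <- random_interior_points(20, g, seed = 14)
  # field evaluator with analytic u, grad, hess
  field <- function(points, deriv = 0L, side = "both") {
    N <- nrow(points)
    u <- t(apply(points, 1, u_fun))
    grad <- array(0, c(N, 3, 3))
    grad[, 1, 1] <- 0.6 * sx^2 * points[, 1]
    grad[, 1, 2] <- 0.1 * sy * sz * points[, 3]
    grad[, 1, 3] <- 0.1 * sy * sz * points[, 2]
    grad[, 2, 1] <- 0.05 * sx * sz * points[, 3]
    grad[, 2, 2] <- -0.4 * sy^2 * points[, 2]
    grad[, 2, 3] <- 0.05 * sx * sz * points[, 1]
    grad[, 3, 1] <- -0.08 * sx * sy * points[, 2]
    grad[, 3, 2] <- -0.08 * sx * sy * points[, 1]
    grad[, 3, 3] <- 0.3 * sz^2 * points[, 3]
    hess <- array(0, c(N, 3, 6))      # pairs 11, 22, 33, 23, 13, 12
    hess[, 1, 1] <- 0.6 * sx^2
    hess[, 1, 4] <- 0.1 * sy * sz
    hess[, 2, 2] <- -0.4 * sy^2
    hess[, 2, 5] <- 0.05 * sx * sz
    hess[, 3, 3] <- 0.3 * sz^2
    hess[, 3, 6] <- -0.08 * sx * sy
    list(u = u, grad = grad, hess = hess)
  }
  colloc <- list(interior = list(points = pts,
                                 layer = rep("body", nrow(pts)),
                                 weight = rep(1, nrow(pts))),
                 geom = g)
  scale <- 1  # compare raw residuals through the loss value
  loss <- pde_residual_loss(field, C, C, rho, lambda, colloc, scale = scale)
  res_or <- oracle_residual(u_fun, C, rho, lambda, pts, h = 1e-5)
  expect_equal(loss, mean(res_or^2), tolerance = 1e-3)
})

test_that("Rayleigh quotient is exactly scale invariant and exact for constant-strain fields", {
  g <- fix_geom()
  cl <- sample_collocation(g, 3000, 30, 30, seed = 15)
  Cb <- build_layer_elasticity(2e3, 20e3, layer = "body")$C_voigt
  Cc <- build_layer_elasticity(2e3, 10e3, layer = "cover")$C_voigt
  rho <- 1030
  A <- matrix(c(0.1, 0.3, 0, 0.2, -0.1, 0.05, 0, 0.4, 0.25), 3, 3,
              byrow = TRUE)
  f1 <- field_linear(A)
  f2 <- field_linear(7 * A)
  r1 <- rayleigh_quotient(f1, Cb, Cc, rho, cl)
  r2 <- rayleigh_quotient(f2, Cb, Cc, rho, cl)
  expect_equal(r1$lambda_rq, r2$lambda_rq, tolerance = 1e-12)
  # strain-energy integral is quadrature-exact for a constant strain
  eps <- c(A[1, 1], A[2, 2], A[3, 3], A[2, 3] + A[3, 2],
           A[1, 3] + A[3, 1], A[1, 2] + A[2, 1])
  v <- layer_volumes(g)
  V_exact <- v[["cover"]] * drop(eps %*% Cc %*% eps) +
    v[["body"]] * drop(eps %*% Cb %*% eps)
  expect_equal(r1$V, V_exact, tolerance = 1e-10)
  expect_error(rayleigh_quotient(field_constant(c(0, 0, 0)), Cb, Cc, rho, cl),
               "degenerate")
})

test_that("boundary losses vanish for fields that satisfy the respective conditions", {
  g <- fix_geom()
  cl <- sample_collocation(g, 100, 30, 20, seed = 16)
  Cb <- build_layer_elasticity(1e3, 10e3, layer = "body")$C_voigt
  Cc <- build_layer_elasticity(1e3, 5e3, layer = "cover")$C_voigt
  # a constant field has zero tractions everywhere but violates the clamp
  fc <- field_constant(c(0.3, -0.2, 0.1))
  expect_equal(neumann_loss(fc, Cb, Cc, cl), 0)
  expect_gt(dirichlet_loss(fc, cl), 0)
  # identical layer stiffness and a smooth field: zero interface jumps
  net <- fix_small_network(seed = 8)
  fn <- field_from_network(net, vf_material(2e3, 20e3, 20e3))
  expect_equal(interface_loss(fn, Cb, Cb, cl), 0, tolerance = 1e-18)
  # differing stiffness: the traction jump of a sheared field is positive
  A <- matrix(0, 3, 3); A[3, 1] <- 0.5   # du_z/dx shear across the interface
  expect_gt(interface_loss(field_linear(A), Cb, Cc, cl), 0)
})

test_that("loss breakdown composes its terms with the supplied weights", {
  ref <- fix_reference_solution()
  cl <- sample_collocation(ref$geom, 1500, 60, 40, seed = 17)
  field <- field_from_fem(ref$mesh, ref$sol$modes[, 1])
  u_true <- field(cl$surface$points)$u
  w <- c(pde = 2, dirichlet = 1, neumann = 0.5, interface = 1,
         eigenvalue = 3, cosine = 1)
  lb <- loss_breakdown(field, ref$Cb, ref$Cc, ref$mat$density, cl,
                       lambda_true = ref$sol$lambda[1], u_true = u_true,
                       weights = w)
  manual <- 2 * lb$pde + lb$dirichlet + 0.5 * lb$neumann + lb$interface +
    3 * lb$eigenvalue + lb$cosine
  expect_equal(lb$total, manual, tolerance = 1e-12)
  expect_error(vfpinn:::.check_weights(c(pde = -1)), "non-negative")
  # weight vector completion keeps unspecified terms at one
  full <- vfpinn:::.check_weights(c(cosine = 5))
  expect_equal(full[["cosine"]], 5)
  expect_equal(full[["pde"]], 1)
})

test_that("FEM field evaluator reproduces nodal values and one-sided interface gradients", {
  ref <- fix_reference_solution()
  mesh <- ref$mesh
  v <- ref$sol$modes[, 1]
  field <- field_from_fem(mesh, v)
  # exact at the nodes
  idx <- c(1, 57, 211)
  out <- field(mesh$nodes[idx, , drop = FALSE])
  Un <- matrix(v, ncol = 3, byrow = TRUE)
  expect_equal(out$u, Un[idx, ], tolerance = 1e-9)
  # one-sided gradients differ at the interface for a layered mode
  pts <- cbind(ref$geom$Dc, ref$geom$T_thick / 3, ref$geom$L / 3)
  gb <- field(pts, deriv = 1L, side = "body")$grad
  gc <- field(pts, deriv = 1L, side = "cover")$grad
  expect_gt(max(abs(gb - gc)), 0)
  # displacement itself is continuous across the interface
  ub <- field(pts, deriv = 0L, side = "body")$u
  uc <- field(pts, deriv = 0L, side = "cover")$u
  expect_equal(ub, uc, tolerance = 1e-6)
})
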
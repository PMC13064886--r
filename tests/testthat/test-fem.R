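test_that("structured mesh places a node plane on the layer interface", {
  g <- fix_geom()
  mesh <- build_mesh(g, c(10, 6, 10))
  expect_true(any(abs(mesh$xgrid - g$Dc) < 1e-15))
  # interface nodes all sit at x = Dc
  expect_true(all(abs(mesh$nodes[mesh$node_sets$interface, 1] - g$Dc) < 1e-15))
  # element layer tags split at nx_cover columns
  expect_equal(sum(mesh$layer == "cover"), mesh$nx_cover * 6 * 10)
  expect_equal(nrow(mesh$hex), prod(mesh$resolution))
  expect_equal(nrow(mesh$nodes), prod(mesh$resolution + 1L))
  # cover columns: round(nx Dc / D) clamped
  expect_equal(mesh$nx_cover, max(1L, round(10 * g$Dc / g$D)))
  expect_error(build_mesh(g, c(2, 2, 2)), "too coarse")
})

test_that("element stiffness and mass match a direct tensor-contraction oracle", {
  C <- build_layer_elasticity(2e3, 20e3, layer = "body")$C_voigt
  em <- vfpinn:::.hex_element_matrices(C, 1030, 1e-3, 0.7e-3, 1.5e-3)
  or <- oracle_hex_matrices(C, 1030, 1e-3, 0.7e-3, 1.5e-3)
  expect_equal(em$K, or$K, tolerance = 1e-10)
  expect_equal(em$M, or$M, tolerance = 1e-10)
  # rigid translation produces no elastic force
  for (comp in 1:3) {
    u <- rep(0, 24); u[seq(comp, 24, by = 3)] <- 1
    expect_lt(max(abs(em$K %*% u)), 1e-9 * max(abs(em$K)))
    # consistent mass preserves total element mass per component
    expect_equal(drop(u %*% em$M %*% u), 1030 * 1e-3 * 0.7e-3 * 1.5e-3,
                 tolerance = 1e-12)
  }
})

test_that("assembled matrices are symmetric, mass-consistent, and stiffness is positive definite on free DOFs", {
  g <- fix_geom()
  mesh <- build_mesh(g, c(6, 4, 6))
  Cb <- build_layer_elasticity(2e3, 20e3, layer = "body")$C_voigt
  Cc <- build_layer_elasticity(2e3, 10e3, layer = "cover")$C_voigt
  km <- assemble_km(mesh, Cb, Cc, 1030)
  expect_lt(max(abs(km$K - Matrix::t(km$K))), 1e-8)
  expect_lt(max(abs(km$M - Matrix::t(km$M))), 1e-15)
  # rigid translation: zero elastic energy, total mass rho * V
  ndof <- nrow(km$K)
  ux <- rep(c(1, 0, 0), ndof / 3)
  expect_lt(abs(as.numeric(ux %*% (km$K %*% ux))), 1e-6 * max(abs(km$K)))
  expect_equal(as.numeric(ux %*% (km$M %*% ux)),
               1030 * layer_volumes(g)[["total"]], tolerance = 1e-10)
  fx <- fixed_dofs(mesh)
  free <- setdiff(seq_len(ndof), fx)
  ch <- try(chol(as.matrix(km$K[free, free])), silent = TRUE)
  expect_false(inherits(ch, "try-error"))
})

test_that("small constrained eigenproblem matches an independent dense assembly and solve", {
  g <- fix_geom()
  mesh <- build_mesh(g, c(4, 3, 4))
  Cb <- build_layer_elasticity(2e3, 20e3, layer = "body")$C_voigt
  Cc <- build_layer_elasticity(2e3, 10e3, layer = "cover")$C_voigt
  rho <- 1030
  km <- assemble_km(mesh, Cb, Cc, rho)
  fx <- fixed_dofs(mesh)
  sol <- solve_modes(km$K, km$M, fx, 3)

  # oracle: dense global assembly from the oracle element matrices
  ndof <- 3L * nrow(mesh$nodes)
  K <- matrix(0, ndof, ndof)
  M <- matrix(0, ndof, ndof)
  hy <- diff(mesh$ygrid[1:2]); hz <- diff(mesh$zgrid[1:2])
  for (e in seq_len(nrow(mesh$hex))) {
    lay <- mesh$layer[e]
    conn <- mesh$hex[e, ]
    hx <- mesh$nodes[conn[2], 1] - mesh$nodes[conn[1], 1]
    em <- oracle_hex_matrices(if (lay == "cover") Cc else Cb, rho, hx, hy, hz)
    edof <- as.vector(rbind(3 * (conn - 1) + 1, 3 * (conn - 1) + 2,
                            3 * (conn - 1) + 3))
    K[edof, edof] <- K[edof, edof] + em$K
    M[edof, edof] <- M[edof, edof] + em$M
  }
  free <- setdiff(seq_len(ndof), fx)
  A <- solve(M[free, free], K[free, free])
  lam_or <- sort(Re(eigen(A, only.values = TRUE)$values))[1:3]
  expect_equal(sol$lambda, lam_or, tolerance = 1e-8)
})

test_that("axially constrained isotropic rod recovers the closed-form quarter-wave frequency", {
  # rod along z, fixed at z = 0, all transverse motion suppressed:
  # f1 = c / (4 L) with c = sqrt(E / rho)
  g <- vf_geometry(T_thick = 4e-3, Db = 4e-3, Dc = 2e-3, L = 0.1)
  mesh <- build_mesh(g, c(3, 2, 40))
  E <- 1e4; rho <- 1000
  C <- isotropic_stiffness(E, 0)
  km <- assemble_km(mesh, C, C, rho)
  ndof <- 3L * nrow(mesh$nodes)
  xy_dofs <- sort(c(seq(1, ndof, by = 3), seq(2, ndof, by = 3)))
  anchor_z <- 3L * (mesh$node_sets$anterior - 1L) + 3L
  fixed <- sort(unique(c(xy_dofs, anchor_z)))
  sol <- solve_modes(km$K, km$M, fixed, 1)
  f_exact <- sqrt(E / rho) / (4 * g$L)
  expect_lt(abs(sol$frequency_hz[1] - f_exact) / f_exact, 0.01)
})

test_that("eigenpairs satisfy the Rayleigh identity, normalization, and sign convention", {
  ref <- fix_reference_solution()
  km <- assemble_km(ref$mesh, ref$Cb, ref$Cc, ref$mat$density)
  fx <- fixed_dofs(ref$mesh)
  sol <- ref$sol
  expect_true(all(diff(sol$lambda) >= 0))
  for (m in 1:2) {
    v <- sol$modes[, m]
    rq <- as.numeric(v %*% (km$K %*% v)) / as.numeric(v %*% (km$M %*% v))
    expect_equal(rq, sol$lambda[m], tolerance = 1e-8)
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
    expect_true(all(v[fx] == 0))
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_equal(sol$frequency_hz, sqrt(sol$lambda) / (2 * pi))
})

test_that("modal solves are deterministic and the convenience pipeline matches the manual path", {
  g <- fix_geom()
  mat <- vf_material(2e3, 20e3, 10e3)
  a <- fem_modal_analysis(g, mat, resolution = c(6, 4, 6), n_modes = 2)
  b <- fem_modal_analysis(g, mat, resolution = c(6, 4, 6), n_modes = 2)
  expect_identical(a$lambda, b$lambda)
  expect_identical(a$modes, b$modes)
  aux <- vf_elastic_aux()
  mesh <- build_mesh(g, c(6, 4, 6))
  km <- assemble_km(
    mesh,
    build_layer_elasticity(mat$Et, mat$gap_body, aux, "body")$C_voigt,
    build_layer_elasticity(mat$Et, mat$gap_cover, aux, "cover")$C_voigt,
    mat$density
  )
  manual <- solve_modes(km$K, km$M, fixed_dofs(mesh), 2)
  expect_equal(a$lambda, manual$lambda, tolerance = 1e-12)
  expect_error(solve_modes(km$K, km$M, fixed_dofs(mesh), 1e6), "n_modes")
})
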
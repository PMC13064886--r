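#' Field evaluators
#'
#' The loss operations accept a *field evaluator*: a function
#' `f(points, deriv = 0, side = c("both", "cover", "body"))` returning a list
#' with `u` (N x 3) and, for `deriv >= 1`, `grad` (N x 3 x 3), and for
#' `deriv = 2`, `hess` (N x 3 x 6, pair order 11, 22, 33, 23, 13, 12). The
#' `side` argument matters only at the body--cover interface, where one-sided
#' gradients differ for fields with weak discontinuities (e.g. FEM modes); a
#' single smooth network returns the same values for both sides.
#'
#' @param net,material Network and material configuration.
#' @return A field evaluator closure.
#' @export
field_from_network <- function(net, material) {
  force(net); force(material)
  function(points, deriv = 0L, side = "both") {
    .net_forward(net, points, material, deriv = deriv)
  }
}

#' @rdname field_from_network
#' @param u0 Constant displacement 3-vector.
#' @export
field_constant <- function(u0) {
  force(u0)
  function(points, deriv = 0L, side = "both") {
    N <- nrow(points)
    out <- list(u = matrix(u0, N, 3, byrow = TRUE))
    if (deriv >= 1L) out$grad <- array(0, c(N, 3, 3))
    if (deriv >= 2L) out$hess <- array(0, c(N, 3, 6))
    out
  }
}

#' @rdname field_from_network
#' @param A 3x3 matrix; the linear field is `u(x) = A x + b0`.
#' @param b0 Offset 3-vector.
#' @export
field_linear <- function(A, b0 = c(0, 0, 0)) {
  force(A); force(b0)
  function(points, deriv = 0L, side = "both") {
    N <- nrow(points)
    out <- list(u = points %*% t(A) + matrix(b0, N, 3, byrow = TRUE))
    if (deriv >= 1L) {
      g <- array(0, c(N, 3, 3))
      for (i in 1:3) for (j in 1:3) g[, i, j] <- A[i, j]
      out$grad <- g
    }
    if (deriv >= 2L) out$hess <- array(0, c(N, 3, 6))
    out
  }
}

#' Trilinear field evaluator for a FEM nodal displacement vector
#'
#' Interpolates a nodal displacement vector (3 DOF per node) of a structured
#' mesh at arbitrary points. Displacements and first derivatives come from the
#' trilinear shape functions of the containing element (one-sided at the
#' interface via `side`); second derivatives, which a piecewise-trilinear
#' field does not possess pointwise, are estimated by central finite
#' differences of the interpolant at the mesh scale (`hess_step` element
#' sizes), recovering the smooth underlying mode's curvature to second order.
#'
#' @param mesh A [build_mesh()] result.
#' @param mode_vec Full DOF vector (length 3 * n_nodes).
#' @param hess_step Finite-difference step in units of the element size.
#' @return A field evaluator closure.
#' @export
field_from_fem <- function(mesh, mode_vec, hess_step = 1.0) {
  Unod <- matrix(mode_vec, ncol = 3, byrow = TRUE)
  xg <- mesh$xgrid; yg <- mesh$ygrid; zg <- mesh$zgrid
  nnx <- mesh$dims[1]; nny <- mesh$dims[2]
  nid <- function(i, j, k) i + (j - 1L) * nnx + (k - 1L) * nnx * nny

  interp <- function(points, deriv, side) {
    N <- nrow(points)
    px <- points[, 1]
    if (side == "cover") px <- pmin(px, mesh$geom$Dc) - 1e-12 * mesh$geom$D
    if (side == "body") px <- pmax(px, mesh$geom$Dc) + 1e-12 * mesh$geom$D
    ix <- findInterval(px, xg, all.inside = TRUE)
    iy <- findInterval(points[, 2], yg, all.inside = TRUE)
    iz <- findInterval(points[, 3], zg, all.inside = TRUE)
    hx <- xg[ix + 1L] - xg[ix]
    hy <- yg[iy + 1L] - yg[iy]
    hz <- zg[iz + 1L] - zg[iz]
    tx <- (points[, 1] - xg[ix]) / hx
    ty <- (points[, 2] - yg[iy]) / hy
    tz <- (points[, 3] - zg[iz]) / hz
    u <- matrix(0, N, 3)
    grad <- if (deriv >= 1L) array(0, c(N, 3, 3)) else NULL
    for (sx in 0:1) for (sy in 0:1) for (sz in 0:1) {
      ids <- nid(ix + sx, iy + sy, iz + sz)
      fx <- if (sx == 1) tx else 1 - tx
      fy <- if (sy == 1) ty else 1 - ty
      fz <- if (sz == 1) tz else 1 - tz
      dfx <- (if (sx == 1) 1 else -1) / hx
      dfy <- (if (sy == 1) 1 else -1) / hy
      dfz <- (if (sz == 1) 1 else -1) / hz
      w <- fx * fy * fz
      un <- Unod[ids, , drop = FALSE]
      u <- u + un * w
      if (deriv >= 1L) {
        wx <- dfx * fy * fz; wy <- fx * dfy * fz; wz <- fx * fy * dfz
        for (i in 1:3) {
          grad[, i, 1] <- grad[, i, 1] + un[, i] * wx
          grad[, i, 2] <- grad[, i, 2] + un[, i] * wy
          grad[, i, 3] <- grad[, i, 3] + un[, i] * wz
        }
      }
    }
    list(u = u, grad = grad)
  }

  geom <- mesh$geom
  lo <- c(0, 0, 0); hi <- c(geom$D, geom$T_thick, geom$L)
  h_elem <- c(min(diff(xg)), min(diff(yg)), min(diff(zg)))

  function(points, deriv = 0L, side = "both") {
    out <- interp(points, deriv, side)
    if (deriv >= 2L) {
      N <- nrow(points)
      hess <- array(0, c(N, 3, 6))
      h <- hess_step * h_elem
      # clamp stencil centers so all samples stay inside the prism
      ctr <- points
      for (ax in 1:3) {
        ctr[, ax] <- pmin(pmax(ctr[, ax], lo[ax] + h[ax]), hi[ax] - h[ax])
      }
      shift <- function(p, ax, s) { p[, ax] <- p[, ax] + s; p }
      u0 <- interp(ctr, 0L, side)$u
      for (pr in 1:6) {
        a <- .d2_pairs[[pr]][1]; b <- .d2_pairs[[pr]][2]
        if (a == b) {
          up <- interp(shift(ctr, a, h[a]), 0L, side)$u
          um <- interp(shift(ctr, a, -h[a]), 0L, side)$u
          hess[, , pr] <- (up - 2 * u0 + um) / h[a]^2
        } else {
          upp <- interp(shift(shift(ctr, a, h[a]), b, h[b]), 0L, side)$u
          upm <- interp(shift(shift(ctr, a, h[a]), b, -h[b]), 0L, side)$u
          ump <- interp(shift(shift(ctr, a, -h[a]), b, h[b]), 0L, side)$u
          umm <- interp(shift(shift(ctr, a, -h[a]), b, -h[b]), 0L, side)$u
          hess[, , pr] <- (upp - upm - ump + umm) / (4 * h[a] * h[b])
        }
      }
      out$hess <- hess
    }
    out
  }
}

# 18 x 3 coefficient matrix mapping flattened second derivatives
# (column (k-1)*6 + pair) to the stress-divergence components:
# div_i = sum_{k,pair} coef[(k-1)*6 + pair, i] * d2u_k[pair]
.divergence_coef <- function(C_voigt) {
  Cf <- voigt_to_tensor(C_voigt)
  coef <- matrix(0, 18, 3)
  for (i in 1:3) for (k in 1:3) for (pr in 1:6) {
    a <- .d2_pairs[[pr]][1]; b <- .d2_pairs[[pr]][2]
    coef[(k - 1) * 6 + pr, i] <- if (a == b) {
      Cf[i, a, k, a]
    } else {
      Cf[i, a, k, b] + Cf[i, b, k, a]
    }
  }
  coef
}

.flatten_hess <- function(hess) {
  N <- dim(hess)[1]
  out <- matrix(0, N, 18)
  for (k in 1:3) for (pr in 1:6) out[, (k - 1) * 6 + pr] <- hess[, k, pr]
  out
}

# traction components from Voigt stress rows and unit normals (N x 3)
.traction <- function(sig, normal) {
  cbind(
    sig[, 1] * normal[, 1] + sig[, 6] * normal[, 2] + sig[, 5] * normal[, 3],
    sig[, 6] * normal[, 1] + sig[, 2] * normal[, 2] + sig[, 4] * normal[, 3],
    sig[, 5] * normal[, 1] + sig[, 4] * normal[, 2] + sig[, 3] * normal[, 3]
  )
}

#' Mean squared Navier--Cauchy residual at interior collocation points
#'
#' The frequency-domain residual is
#' `R_i = d_j (C_ijkl d_l u_k) + rho lambda u_i` (constant C within each
#' layer), nondimensionalized by `scale = L_char^2 / E_ref` so that loss terms
#' are comparable in magnitude. The loss is the mean of `R_i^2` over points
#' and components, with each point's layer selecting its stiffness.
#'
#' @param field A field evaluator.
#' @param C_body,C_cover 6x6 Voigt stiffnesses (Pa).
#' @param density Mass density (kg/m^3).
#' @param lambda Squared angular frequency (rad^2/s^2), supplied externally
#'   (typically the current Rayleigh-quotient estimate).
#' @param colloc A [sample_collocation()] result (interior part used).
#' @param scale Residual nondimensionalization; default `L_char^2 / E_ref`
#'   with `L_char` the largest prism dimension and `E_ref` the transverse
#'   Young's modulus implied by `C_cover`.
#' @return Scalar loss (>= 0).
#' @export
pde_residual_loss <- function(field, C_body, C_cover, density, lambda, colloc,
                              scale = NULL) {
  pts <- colloc$interior$points
  lay <- colloc$interior$layer
  if (is.null(lay)) stop("interior points lack layer tags")
  if (is.null(scale)) scale <- .default_residual_scale(colloc$geom, C_cover, C_body)
  out <- field(pts, deriv = 2L)
  D2 <- .flatten_hess(out$hess)
  resid <- matrix(0, nrow(pts), 3)
  for (lname in c("cover", "body")) {
    idx <- which(lay == lname)
    if (length(idx) == 0) next
    coef <- .divergence_coef(if (lname == "cover") C_cover else C_body)
    resid[idx, ] <- D2[idx, , drop = FALSE] %*% coef
  }
  resid <- scale * (resid + density * lambda * out$u)
  mean(resid^2)
}

.default_residual_scale <- function(geom, C_cover, C_body = NULL) {
  L_char <- max(geom$D, geom$T_thick, geom$L)
  L_char^2 / .stiffness_scale(C_cover, C_body)
}

# a robust stiffness magnitude for nondimensionalization (largest entry over
# the supplied layer stiffnesses)
.stiffness_scale <- function(C_voigt, C2 = NULL) {
  max(abs(C_voigt), if (is.null(C2)) 0 else abs(C2))
}

# nondimensional tractions: t_hat = t * L_char / C_max, so that a field with
# u = O(1) and gradients O(1) per normalized length yields t_hat = O(1)
.traction_scale <- function(geom, C_cover, C_body = NULL) {
  max(geom$D, geom$T_thick, geom$L) / .stiffness_scale(C_cover, C_body)
}

#' Rayleigh quotient of a displacement field
#'
#' Estimates the squared angular frequency as the ratio of elastic strain
#' energy to kinetic-energy density,
#' `lambda_RQ = (sum w eps' C eps) / (sum w rho |u|^2)`, with layer-wise
#' stiffness and the volume-consistent quadrature weights of the stratified
#' collocation set.
#'
#' @inheritParams pde_residual_loss
#' @return Object of class `vf_rayleigh`: list with `lambda_rq` (rad^2/s^2),
#'   `V` (strain energy per unit modal normalization), `T_int` (kinetic
#'   density integral, before multiplication by omega^2), and per-layer point
#'   counts.
#' @export
rayleigh_quotient <- function(field, C_body, C_cover, density, colloc) {
  pts <- colloc$interior$points
  lay <- colloc$interior$layer
  w <- colloc$interior$weight
  out <- field(pts, deriv = 1L)
  eps <- grad_to_strain(out$grad)
  q <- numeric(nrow(pts))
  for (lname in c("cover", "body")) {
    idx <- which(lay == lname)
    if (length(idx) == 0) next
    Cv <- if (lname == "cover") C_cover else C_body
    e <- eps[idx, , drop = FALSE]
    q[idx] <- rowSums((e %*% Cv) * e)
  }
  V <- sum(w * q)
  T_int <- sum(w * density * rowSums(out$u^2))
  if (T_int <= 0) stop("degenerate-field error: zero kinetic energy")
  structure(
    list(lambda_rq = V / T_int, V = V, T_int = T_int,
         n_cover = sum(lay == "cover"), n_body = sum(lay == "body")),
    class = "vf_rayleigh"
  )
}

#' Boundary-condition losses
#'
#' `dirichlet_loss` is the mean squared displacement on the mechanically
#' fixed faces (lateral, anterior, posterior); `neumann_loss` the mean squared
#' traction on the free faces (medial, inferior, superior), nondimensionalized
#' by the reference stiffness; `interface_loss` the mean squared displacement
#' jump plus mean squared nondimensional traction jump across the body--cover
#' plane, where each side's traction uses its own stiffness with the shared
#' normal (cover-to-body, +x).
#'
#' @inheritParams pde_residual_loss
#' @param t_scale Traction nondimensionalization factor (1/Pa); tractions are
#'   multiplied by it before squaring. Defaults to `L_char / C_max` with
#'   `L_char` the largest prism dimension and `C_max` the largest stiffness
#'   entry over both layers, so that an O(1) displacement field yields O(1)
#'   nondimensional tractions.
#' @return Scalar loss (>= 0).
#' @export
dirichlet_loss <- function(field, colloc) {
  sel <- colloc$surface$face %in% fixed_faces()
  if (!any(sel)) stop("no fixed-face surface points present")
  u <- field(colloc$surface$points[sel, , drop = FALSE], deriv = 0L)$u
  mean(u^2)
}

#' @rdname dirichlet_loss
#' @export
neumann_loss <- function(field, C_body, C_cover, colloc, t_scale = NULL) {
  sel <- which(colloc$surface$face %in% free_faces())
  if (length(sel) == 0) stop("no free-face surface points present")
  pts <- colloc$surface$points[sel, , drop = FALSE]
  nrm <- colloc$surface$normal[sel, , drop = FALSE]
  if (is.null(nrm)) stop("surface points lack normals")
  if (is.null(t_scale)) t_scale <- .traction_scale(colloc$geom, C_cover, C_body)
  lay <- classify_point(pts, colloc$geom)
  out <- field(pts, deriv = 1L)
  eps <- grad_to_strain(out$grad)
  sig <- matrix(0, nrow(pts), 6)
  for (lname in c("cover", "body")) {
    idx <- which(lay == lname)
    if (length(idx) == 0) next
    Cv <- if (lname == "cover") C_cover else C_body
    sig[idx, ] <- eps[idx, , drop = FALSE] %*% Cv
  }
  tr <- .traction(sig, nrm) * t_scale
  mean(tr^2)
}

#' @rdname dirichlet_loss
#' @export
interface_loss <- function(field, C_body, C_cover, colloc, t_scale = NULL) {
  pts <- colloc$interface$points
  nrm <- colloc$interface$normal
  if (is.null(nrm)) stop("interface points lack normals")
  if (is.null(t_scale)) t_scale <- .traction_scale(colloc$geom, C_cover, C_body)
  plus <- field(pts, deriv = 1L, side = "body")
  minus <- field(pts, deriv = 1L, side = "cover")
  jump_u <- mean((plus$u - minus$u)^2)
  sig_p <- grad_to_strain(plus$grad) %*% C_body
  sig_m <- grad_to_strain(minus$grad) %*% C_cover
  dtr <- (.traction(sig_p, nrm) - .traction(sig_m, nrm)) * t_scale
  jump_u + mean(dtr^2)
}

#' Eigenvalue discrepancy loss
#'
#' Normalized squared discrepancy between the Rayleigh-quotient eigenvalue and
#' the reference eigenvalue: `((lambda_rq - lambda_true) / lambda_true)^2`.
#'
#' @param lambda_rq Rayleigh-quotient eigenvalue (rad^2/s^2) or a
#'   [rayleigh_quotient()] result.
#' @param lambda_true Reference eigenvalue (rad^2/s^2), must be positive.
#' @return Scalar loss (>= 0).
#' @export
eigenvalue_loss <- function(lambda_rq, lambda_true) {
  if (inherits(lambda_rq, "vf_rayleigh")) lambda_rq <- lambda_rq$lambda_rq
  if (!is.finite(lambda_true) || lambda_true <= 0) {
    stop("lambda_true must be strictly positive")
  }
  ((lambda_rq - lambda_true) / lambda_true)^2
}

#' Cosine mode-shape loss
#'
#' `1 - cos(theta)` between the stacked predicted and reference displacement
#' vectors; invariant to the overall magnitude of either field. Lies in
#' \[0, 2\]; the signed form is used during training (the reference sign is
#' fixed by the FEM sign convention), while evaluation metrics report the
#' absolute cosine.
#'
#' @param u_pred,u_true Numeric vectors (or N x 3 matrices, stacked
#'   column-major) over the same evaluation points.
#' @return Scalar in \[0, 2\].
#' @export
cosine_loss <- function(u_pred, u_true) {
  u_pred <- as.numeric(u_pred); u_true <- as.numeric(u_true)
  if (length(u_pred) != length(u_true)) stop("vectors must share length")
  np <- sqrt(sum(u_pred^2)); nt <- sqrt(sum(u_true^2))
  if (np == 0 || nt == 0) stop("degenerate-field error: zero-norm input")
  1 - sum(u_pred * u_true) / (np * nt)
}

#' Composite loss breakdown for one configuration
#'
#' Evaluates every term of the composite training loss for one material
#' configuration and field: PDE residual, Dirichlet, Neumann and interface
#' losses, the eigenvalue penalty (using the field's own Rayleigh-quotient
#' eigenvalue), and the cosine mode-shape penalty on surface points. The total
#' is the weighted sum (default weights all 1, matching an unweighted sum of
#' terms).
#'
#' @inheritParams pde_residual_loss
#' @param lambda_true Reference eigenvalue (rad^2/s^2).
#' @param u_true Reference displacements at the surface evaluation points
#'   (N_surface x 3 matrix or stacked vector).
#' @param weights Named numeric weights for `pde`, `dirichlet`, `neumann`,
#'   `interface`, `eigenvalue`, `cosine`.
#' @return Object of class `vf_loss_breakdown`: the six terms, `lambda_rq`,
#'   `total`, `weights`.
#' @export
loss_breakdown <- function(field, C_body, C_cover, density, colloc,
                           lambda_true, u_true,
                           weights = default_loss_weights(), scale = NULL) {
  weights <- .check_weights(weights)
  rq <- rayleigh_quotient(field, C_body, C_cover, density, colloc)
  terms <- c(
    pde = pde_residual_loss(field, C_body, C_cover, density, rq$lambda_rq,
                            colloc, scale = scale),
    dirichlet = dirichlet_loss(field, colloc),
    neumann = neumann_loss(field, C_body, C_cover, colloc),
    interface = interface_loss(field, C_body, C_cover, colloc),
    eigenvalue = eigenvalue_loss(rq$lambda_rq, lambda_true),
    cosine = cosine_loss(field(colloc$surface$points, deriv = 0L)$u, u_true)
  )
  structure(
    c(as.list(terms),
      list(lambda_rq = rq$lambda_rq, total = sum(weights * terms),
           weights = weights)),
    class = "vf_loss_breakdown"
  )
}

#' Default (unweighted) composite-loss weights
#' @return Named numeric vector of ones.
#' @export
default_loss_weights <- function() {
  c(pde = 1, dirichlet = 1, neumann = 1, interface = 1, eigenvalue = 1,
    cosine = 1)
}

.check_weights <- function(weights) {
  full <- default_loss_weights()
  full[names(weights)] <- weights
  if (any(full < 0)) stop("loss weights must be non-negative")
  full
}

#' @export
print.vf_loss_breakdown <- function(x, ...) {
  cat("<vf_loss_breakdown>\n")
  for (nm in c("pde", "dirichlet", "neumann", "interface", "eigenvalue", "cosine")) {
    cat(sprintf("  %-10s %.6g\n", nm, x[[nm]]))
  }
  cat(sprintf("  total      %.6g (lambda_rq = %.6g)\n", x$total, x$lambda_rq))
  invisible(x)
}
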
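#' Material configuration for one body--cover vocal fold model
#'
#' Bundles the three free stiffness parameters of a body--cover configuration
#' (transverse Young's modulus shared by both layers and one anterior--posterior
#' shear modulus per layer) together with the derived AP Young's moduli
#' \eqn{E_{AP} = 4 G_{AP}} and the tissue density.
#'
#' @param Et Transverse Young's modulus (Pa), shared by body and cover.
#' @param gap_body AP shear modulus of the body layer (Pa).
#' @param gap_cover AP shear modulus of the cover layer (Pa).
#' @param density Mass density (kg/m^3); default 1030.
#'
#' @return An object of class `vf_material` with fields `Et`, `gap_body`,
#'   `gap_cover`, `eap_body`, `eap_cover`, `density`.
#' @export
#' @examples
#' m <- vf_material(Et = 2e3, gap_body = 20e3, gap_cover = 10e3)
#' m$eap_cover / m$gap_cover  # 4
vf_material <- function(Et, gap_body, gap_cover, density = 1030) {
  if (!is.numeric(Et) || Et <= 0) stop("Et must be strictly positive")
  if (!is.numeric(gap_body) || gap_body <= 0) stop("gap_body must be strictly positive")
  if (!is.numeric(gap_cover) || gap_cover <= 0) stop("gap_cover must be strictly positive")
  if (!is.numeric(density) || density <= 0) stop("density must be strictly positive")
  structure(
    list(
      Et = Et, gap_body = gap_body, gap_cover = gap_cover,
      eap_body = 4 * gap_body, eap_cover = 4 * gap_cover,
      density = density
    ),
    class = "vf_material"
  )
}

#' @export
print.vf_material <- function(x, ...) {
  cat(sprintf(
    "<vf_material> Et = %g kPa, GAP body/cover = %g/%g kPa, rho = %g kg/m^3\n",
    x$Et / 1e3, x$gap_body / 1e3, x$gap_cover / 1e3, x$density
  ))
  invisible(x)
}

#' Material parameter grid of the body--cover study
#'
#' The study grid crosses the transverse Young's modulus with one AP shear
#' modulus per layer: Et in {1, 2, 4} kPa and GAP in {1, 10, 20, 30, 40} kPa
#' for body and cover independently, giving 3 x 5 x 5 = 75 configurations.
#'
#' @param Et_values Transverse Young's moduli (Pa).
#' @param gap_values AP shear moduli (Pa), used for both layers.
#' @param density Mass density (kg/m^3).
#' @return A data.frame with one row per configuration (`config_id`, `Et`,
#'   `gap_body`, `gap_cover`) ordered Et-major.
#' @export
vf_material_grid <- function(Et_values = c(1e3, 2e3, 4e3),
                             gap_values = c(1e3, 10e3, 20e3, 30e3, 40e3),
                             density = 1030) {
  if (length(Et_values) == 0 || length(gap_values) == 0) stop("grids must be non-empty")
  g <- expand.grid(
    gap_cover = gap_values, gap_body = gap_values, Et = Et_values,
    KEEP.OUT.ATTRS = FALSE
  )
  g <- g[, c("Et", "gap_body", "gap_cover")]
  g$density <- density
  g$config_id <- sprintf(
    "Et%g_Gb%g_Gc%g", g$Et / 1e3, g$gap_body / 1e3, g$gap_cover / 1e3
  )
  rownames(g) <- NULL
  g[, c("config_id", "Et", "gap_body", "gap_cover", "density")]
}

#' Auxiliary elastic constants not fixed by the study parameterization
#'
#' The body--cover layers are transversely isotropic with the plane of isotropy
#' perpendicular to the AP (z) axis. The study varies Et and GAP and ties
#' EAP = 4 GAP; the remaining constants of the constitutive law are set here:
#' the in-plane Poisson ratio `nu_t` (default 0.499, near-incompressible in the
#' transverse plane) and the axial (AP-to-plane) Poisson ratio `nu_zp`
#' (default 0, keeping the stiffness matrix positive definite over the whole
#' stiffness grid where GAP >> Et).
#'
#' @param nu_t In-plane Poisson ratio, -1 < nu_t < 1.
#' @param nu_zp Axial Poisson ratio (contraction of the isotropy plane under AP
#'   stress).
#' @return A list of class `vf_elastic_aux`.
#' @export
vf_elastic_aux <- function(nu_t = 0.499, nu_zp = 0) {
  if (nu_t <= -1 || nu_t >= 1) stop("nu_t must lie in (-1, 1)")
  structure(list(nu_t = nu_t, nu_zp = nu_zp), class = "vf_elastic_aux")
}

# Voigt index order used everywhere: (11, 22, 33, 23, 13, 12),
# engineering shear strains (gamma = 2 eps) in strain vectors.
.voigt_pairs <- cbind(
  i = c(1L, 2L, 3L, 2L, 1L, 1L),
  j = c(1L, 2L, 3L, 3L, 3L, 2L)
)

#' Build the transversely isotropic stiffness matrix of one layer
#'
#' Constructs the 6x6 Voigt stiffness matrix (order 11, 22, 33, 23, 13, 12,
#' engineering shears) for a transversely isotropic layer whose axis of
#' symmetry is the AP (z) direction. The compliance matrix is assembled from
#' Et (in-plane Young's modulus), EAP = 4 gap (axial Young's modulus),
#' gap (axial shear modulus), the in-plane shear modulus
#' Gt = Et / (2 (1 + nu_t)), and the two Poisson ratios in `aux`; the
#' stiffness is its inverse.
#'
#' @param Et Transverse (in-plane) Young's modulus, Pa.
#' @param gap AP shear modulus of the layer, Pa.
#' @param aux Auxiliary constants from [vf_elastic_aux()].
#' @param layer `"body"` or `"cover"` (metadata only).
#' @return An object of class `vf_elasticity`: list with `C_voigt` (6x6, Pa),
#'   `layer`, `isotropy_axis` (the AP unit vector c(0,0,1)), and the inputs.
#' @export
#' @examples
#' C <- build_layer_elasticity(2e3, 10e3, layer = "cover")
#' C$C_voigt[4, 4]  # equals gap
build_layer_elasticity <- function(Et, gap, aux = vf_elastic_aux(),
                                   layer = c("cover", "body")) {
  layer <- match.arg(layer)
  if (Et <= 0 || gap <= 0) stop("moduli must be strictly positive")
  eap <- 4 * gap
  nu_t <- aux$nu_t
  nu_zp <- aux$nu_zp
  gt <- Et / (2 * (1 + nu_t))
  S <- matrix(0, 6, 6)
  S[1, 1] <- S[2, 2] <- 1 / Et
  S[3, 3] <- 1 / eap
  S[1, 2] <- S[2, 1] <- -nu_t / Et
  S[1, 3] <- S[3, 1] <- S[2, 3] <- S[3, 2] <- -nu_zp / eap
  S[4, 4] <- S[5, 5] <- 1 / gap
  S[6, 6] <- 1 / gt
  C <- tryCatch(solve(S), error = function(e) {
    stop("material-stability error: compliance matrix is singular for the ",
         "given aux parameters")
  })
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("material-stability error: stiffness matrix not positive definite ",
         "(min eigenvalue ", format(min(ev)), "); check aux Poisson ratios")
  }
  structure(
    list(
      C_voigt = C, layer = layer, isotropy_axis = c(0, 0, 1),
      Et = Et, gap = gap, eap = eap, aux = aux
    ),
    class = "vf_elasticity"
  )
}

#' Isotropic Lame stiffness matrix (Voigt)
#'
#' Reference stiffness for an isotropic solid, used for degeneration checks and
#' closed-form oracles.
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio.
#' @return 6x6 Voigt stiffness matrix.
#' @export
isotropic_stiffness <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

#' Expand a Voigt stiffness matrix to the full fourth-order tensor
#'
#' @param C_voigt Symmetric 6x6 stiffness matrix (order 11,22,33,23,13,12).
#' @return A 3x3x3x3 array with minor symmetries C[i,j,k,l] = C[j,i,k,l] =
#'   C[i,j,l,k] and major symmetry C[i,j,k,l] = C[k,l,i,j].
#' @export
voigt_to_tensor <- function(C_voigt) {
  if (!isTRUE(all.equal(C_voigt, t(C_voigt), tolerance = 1e-12))) {
    stop("C_voigt must be symmetric")
  }
  vid <- matrix(c(1L, 6L, 5L, 6L, 2L, 4L, 5L, 4L, 3L), 3, 3)
  Cf <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    Cf[i, j, k, l] <- C_voigt[vid[i, j], vid[k, l]]
  }
  Cf
}

#' Contract a full stiffness tensor back to Voigt form
#'
#' Inverse of [voigt_to_tensor()]; exact round trip for tensors with the
#' required symmetries.
#'
#' @param Cf 3x3x3x3 stiffness array.
#' @return 6x6 Voigt stiffness matrix.
#' @export
tensor_to_voigt <- function(Cf) {
  C <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6) {
    C[a, b] <- Cf[.voigt_pairs[a, 1], .voigt_pairs[a, 2],
                  .voigt_pairs[b, 1], .voigt_pairs[b, 2]]
  }
  C
}

#' Stress from engineering strain in Voigt convention
#'
#' @param C_voigt 6x6 stiffness matrix.
#' @param eps_eng Length-6 engineering strain vector (or N x 6 matrix), order
#'   (11, 22, 33, 2*e23, 2*e13, 2*e12).
#' @return Stress in Voigt order, same shape as input.
#' @export
voigt_stress <- function(C_voigt, eps_eng) {
  if (is.matrix(eps_eng)) eps_eng %*% t(C_voigt) else drop(C_voigt %*% eps_eng)
}

#' Convert a displacement gradient to an engineering strain matrix
#'
#' @param grad N x 3 x 3 array, `grad[p, i, j]` = du_i/dx_j at point p.
#' @return N x 6 matrix of engineering strains in Voigt order.
#' @keywords internal
grad_to_strain <- function(grad) {
  cbind(
    grad[, 1, 1], grad[, 2, 2], grad[, 3, 3],
    grad[, 2, 3] + grad[, 3, 2],
    grad[, 1, 3] + grad[, 3, 1],
    grad[, 1, 2] + grad[, 2, 1]
  )
}
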
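#' Structured hexahedral mesh of the body--cover prism
#'
#' Builds an axis-aligned 8-node hexahedral mesh whose depth grid always places
#' a node plane on the body--cover interface x = Dc, so no element straddles
#' the two layers. The number of depth element columns assigned to the cover is
#' `round(nx * Dc / D)` clamped to at least 1, with the remainder (at least 2)
#' in the body; each layer's columns are uniform within the layer.
#'
#' @param geom A [vf_geometry()].
#' @param resolution Integer triple `c(nx, ny, nz)`: elements along depth,
#'   thickness and AP length.
#' @return Object of class `vf_mesh`: `nodes` (N x 3, m), `hex` (E x 8 node
#'   indices, VTK corner order), `layer` (length E, `"cover"`/`"body"`),
#'   `node_sets` (face tag -> node ids, plus `interface`), `dims` (node counts
#'   per axis), `nx_cover`, `geom`, `resolution`.
#' @export
build_mesh <- function(geom, resolution) {
  stopifnot(length(resolution) == 3)
  nx <- as.integer(resolution[1]); ny <- as.integer(resolution[2])
  nz <- as.integer(resolution[3])
  if (any(c(nx, ny, nz) < 1)) stop("resolution must be at least 1 per axis")
  nx_cover <- max(1L, as.integer(round(nx * geom$Dc / geom$D)))
  nx_body <- nx - nx_cover
  if (nx_body < 2L) {
    stop("resolution too coarse to separate layers: need >= 1 cover and >= 2 ",
         "body element columns in depth (got ", nx_cover, " + ", nx_body, ")")
  }
  xg <- c(seq(0, geom$Dc, length.out = nx_cover + 1),
          seq(geom$Dc, geom$D, length.out = nx_body + 1)[-1])
  yg <- seq(0, geom$T_thick, length.out = ny + 1)
  zg <- seq(0, geom$L, length.out = nz + 1)
  nnx <- nx + 1L; nny <- ny + 1L; nnz <- nz + 1L

  nodes <- as.matrix(expand.grid(x = xg, y = yg, z = zg, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (j - 1L) * nnx + (k - 1L) * nnx * nny

  ei <- rep(seq_len(nx), times = ny * nz)
  ej <- rep(rep(seq_len(ny), each = nx), times = nz)
  ek <- rep(seq_len(nz), each = nx * ny)
  hex <- cbind(
    nid(ei, ej, ek), nid(ei + 1L, ej, ek),
    nid(ei + 1L, ej + 1L, ek), nid(ei, ej + 1L, ek),
    nid(ei, ej, ek + 1L), nid(ei + 1L, ej, ek + 1L),
    nid(ei + 1L, ej + 1L, ek + 1L), nid(ei, ej + 1L, ek + 1L)
  )
  layer <- ifelse(ei <= nx_cover, "cover", "body")

  idx <- expand.grid(i = seq_len(nnx), j = seq_len(nny), k = seq_len(nnz))
  ids <- nid(idx$i, idx$j, idx$k)
  node_sets <- list(
    medial    = ids[idx$i == 1L],
    lateral   = ids[idx$i == nnx],
    inferior  = ids[idx$j == 1L],
    superior  = ids[idx$j == nny],
    anterior  = ids[idx$k == 1L],
    posterior = ids[idx$k == nnz],
    interface = ids[idx$i == nx_cover + 1L]
  )

  structure(
    list(nodes = nodes, hex = hex, layer = layer, node_sets = node_sets,
         dims = c(nnx, nny, nnz), nx_cover = nx_cover, geom = geom,
         resolution = c(nx, ny, nz),
         xgrid = xg, ygrid = yg, zgrid = zg),
    class = "vf_mesh"
  )
}

# Shape function derivative tables for the 8-node brick at the 2x2x2 Gauss
# points. Returns list with N (8 x 8: gauss x node) and dN (per gauss: 3 x 8
# physical derivatives for an element of size hx, hy, hz).
.hex_quadrature <- function(hx, hy, hz) {
  g <- 1 / sqrt(3)
  corners <- cbind(
    xi   = c(-1, 1, 1, -1, -1, 1, 1, -1),
    eta  = c(-1, -1, 1, 1, -1, -1, 1, 1),
    zeta = c(-1, -1, -1, -1, 1, 1, 1, 1)
  )
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  detJ <- hx * hy * hz / 8
  N <- matrix(0, 8, 8)
  dN <- vector("list", 8)
  for (q in 1:8) {
    xi <- gp[q, 1]; eta <- gp[q, 2]; zeta <- gp[q, 3]
    d <- matrix(0, 3, 8)
    for (a in 1:8) {
      sa <- corners[a, ]
      N[q, a] <- (1 + xi * sa[1]) * (1 + eta * sa[2]) * (1 + zeta * sa[3]) / 8
      d[1, a] <- sa[1] * (1 + eta * sa[2]) * (1 + zeta * sa[3]) / 8 * (2 / hx)
      d[2, a] <- (1 + xi * sa[1]) * sa[2] * (1 + zeta * sa[3]) / 8 * (2 / hy)
      d[3, a] <- (1 + xi * sa[1]) * (1 + eta * sa[2]) * sa[3] / 8 * (2 / hz)
    }
    dN[[q]] <- d
  }
  list(N = N, dN = dN, detJ = detJ)
}

# 24x24 element stiffness and mass for an axis-aligned brick, full 2x2x2
# Gauss quadrature, Voigt order (11,22,33,23,13,12), engineering shears.
.hex_element_matrices <- function(C_voigt, density, hx, hy, hz) {
  quad <- .hex_quadrature(hx, hy, hz)
  K <- matrix(0, 24, 24)
  M <- matrix(0, 24, 24)
  for (q in 1:8) {
    d <- quad$dN[[q]]
    B <- matrix(0, 6, 24)
    Nm <- matrix(0, 3, 24)
    for (a in 1:8) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- d[1, a]
      B[2, c0 + 2] <- d[2, a]
      B[3, c0 + 3] <- d[3, a]
      B[4, c0 + 2] <- d[3, a]; B[4, c0 + 3] <- d[2, a]
      B[5, c0 + 1] <- d[3, a]; B[5, c0 + 3] <- d[1, a]
      B[6, c0 + 1] <- d[2, a]; B[6, c0 + 2] <- d[1, a]
      Nm[1, c0 + 1] <- quad$N[q, a]
      Nm[2, c0 + 2] <- quad$N[q, a]
      Nm[3, c0 + 3] <- quad$N[q, a]
    }
    K <- K + crossprod(B, C_voigt %*% B) * quad$detJ
    M <- M + density * crossprod(Nm) * quad$detJ
  }
  list(K = K, M = M)
}

#' Assemble global stiffness and mass matrices
#'
#' Assembles sparse symmetric stiffness and mass matrices for the structured
#' body--cover mesh, using the cover stiffness for cover-tagged elements and
#' the body stiffness otherwise. Because the mesh is axis-aligned and uniform
#' within each layer, one element matrix per layer is computed and scattered.
#'
#' @param mesh A [build_mesh()] result.
#' @param C_body,C_cover 6x6 Voigt stiffness matrices (Pa).
#' @param density Mass density (kg/m^3).
#' @return List with sparse symmetric `K` and `M` (3 DOF per node, DOF id
#'   `3 (node - 1) + component`).
#' @export
assemble_km <- function(mesh, C_body, C_cover, density) {
  hy <- diff(mesh$ygrid[1:2]); hz <- diff(mesh$zgrid[1:2])
  hx_cover <- diff(mesh$xgrid[1:2])
  hx_body <- diff(mesh$xgrid[(mesh$nx_cover + 1):(mesh$nx_cover + 2)])
  em <- list(
    cover = .hex_element_matrices(C_cover, density, hx_cover, hy, hz),
    body = .hex_element_matrices(C_body, density, hx_body, hy, hz)
  )
  ndof <- 3L * nrow(mesh$nodes)
  ii <- integer(0); jj <- integer(0); kx <- numeric(0); mx <- numeric(0)
  for (lay in c("cover", "body")) {
    els <- which(mesh$layer == lay)
    if (length(els) == 0) next
    conn <- mesh$hex[els, , drop = FALSE]
    # element DOF table: E x 24
    edof <- matrix(0L, length(els), 24)
    for (a in 1:8) {
      edof[, 3 * a - 2] <- 3L * (conn[, a] - 1L) + 1L
      edof[, 3 * a - 1] <- 3L * (conn[, a] - 1L) + 2L
      edof[, 3 * a] <- 3L * (conn[, a] - 1L) + 3L
    }
    rloc <- rep(1:24, times = 24)
    cloc <- rep(1:24, each = 24)
    ii <- c(ii, as.vector(t(edof)[rloc, ]))
    jj <- c(jj, as.vector(t(edof)[cloc, ]))
    kx <- c(kx, rep(as.vector(em[[lay]]$K), length(els)))
    mx <- c(mx, rep(as.vector(em[[lay]]$M), length(els)))
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kx, dims = c(ndof, ndof))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = mx, dims = c(ndof, ndof))
  list(K = Matrix::forceSymmetric((K + Matrix::t(K)) / 2),
       M = Matrix::forceSymmetric((M + Matrix::t(M)) / 2))
}

#' DOF indices of fixed-face nodes
#'
#' @param mesh A [build_mesh()] result.
#' @param faces Face tags whose nodes are fully constrained; defaults to the
#'   mechanically fixed lateral, anterior and posterior faces.
#' @return Integer vector of constrained DOF indices.
#' @export
fixed_dofs <- function(mesh, faces = fixed_faces()) {
  nodes <- sort(unique(unlist(mesh$node_sets[faces])))
  sort(c(3L * (nodes - 1L) + 1L, 3L * (nodes - 1L) + 2L, 3L * (nodes - 1L) + 3L))
}

# Dense symmetric-definite generalized eigensolve K v = lambda M v via
# Cholesky of M; returns ascending eigenvalues and vectors.
.dense_geneig <- function(K, M) {
  R <- chol(M)                               # M = R'R
  A <- forwardsolve(t(R), K)                 # R^-T K
  A <- t(forwardsolve(t(R), t(A)))           # R^-T K R^-1
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  ord <- order(e$values)
  list(values = e$values[ord],
       vectors = backsolve(R, e$vectors[, ord, drop = FALSE]))
}

#' Smallest generalized eigenpairs of the constrained modal problem
#'
#' Solves K u = lambda M u on the free DOFs (Dirichlet DOFs removed by
#' row/column elimination) for the smallest `n_modes` eigenvalues. Small
#' systems are solved densely; larger systems use subspace (block inverse)
#' iteration with a sparse Cholesky factorization of the constrained K, which
#' is positive definite once the fixed faces remove all rigid-body motion.
#'
#' @param K,M Global sparse symmetric matrices from [assemble_km()].
#' @param fixed Integer vector of constrained DOF indices.
#' @param n_modes Number of modes requested.
#' @param tol Relative eigenvalue convergence tolerance.
#' @param seed Seed for the random start block of the subspace iteration.
#' @param max_iter Iteration cap; non-convergence raises an error.
#' @return List with `lambda` (ascending, rad^2/s^2), `frequency_hz`, and
#'   `modes` (full-length DOF vectors, zeros at fixed DOFs, unit Euclidean
#'   norm, largest-magnitude component positive).
#' @export
solve_modes <- function(K, M, fixed, n_modes, tol = 1e-10, seed = 1L,
                        max_iter = 80L) {
  ndof <- nrow(K)
  free <- setdiff(seq_len(ndof), fixed)
  if (n_modes < 1 || n_modes > length(free)) {
    stop("n_modes must be between 1 and the number of free DOFs")
  }
  Kf <- K[free, free]
  Mf <- M[free, free]
  nf <- length(free)

  if (nf <= 300) {
    e <- .dense_geneig(as.matrix(Kf), as.matrix(Mf))
    lam <- e$values[seq_len(n_modes)]
    V <- e$vectors[, seq_len(n_modes), drop = FALSE]
  } else {
    q <- min(2L * n_modes + 8L, nf)
    set.seed(seed)
    X <- matrix(stats::rnorm(nf * q), nf, q)
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kf), LDL = FALSE, perm = TRUE)
    lam_old <- rep(Inf, n_modes)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Y <- as.matrix(Matrix::solve(ch, Mf %*% X, system = "A"))
      Kp <- crossprod(Y, as.matrix(Kf %*% Y))
      Mp <- crossprod(Y, as.matrix(Mf %*% Y))
      Kp <- (Kp + t(Kp)) / 2; Mp <- (Mp + t(Mp)) / 2
      e <- .dense_geneig(Kp, Mp)
      X <- Y %*% e$vectors
      lam <- e$values[seq_len(n_modes)]
      if (max(abs(lam - lam_old) / pmax(abs(lam), 1e-300)) < tol) {
        converged <- TRUE
        break
      }
      lam_old <- lam
    }
    if (!converged) {
      stop("subspace iteration did not converge in ", max_iter,
           " iterations (last eigenvalues: ", paste(signif(lam, 6), collapse = ", "), ")")
    }
    V <- X[, seq_len(n_modes), drop = FALSE]
  }

  modes <- matrix(0, ndof, n_modes)
  for (m in seq_len(n_modes)) {
    v <- V[, m]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    modes[free, m] <- v
  }
  list(lambda = lam, frequency_hz = sqrt(pmax(lam, 0)) / (2 * pi), modes = modes)
}

#' One-call FEM modal analysis of a body--cover configuration
#'
#' Convenience pipeline: build layer stiffnesses from the material
#' configuration, mesh the prism, assemble, constrain the fixed faces and
#' solve for the lowest modes.
#'
#' @param geom A [vf_geometry()].
#' @param material A [vf_material()].
#' @param resolution Elements per axis, see [build_mesh()].
#' @param n_modes Number of modes.
#' @param aux Auxiliary elastic constants, see [vf_elastic_aux()].
#' @param mesh Optional prebuilt mesh (overrides `resolution`).
#' @param seed Eigensolver start seed.
#' @return List with `lambda`, `frequency_hz`, `modes` (as [solve_modes()]),
#'   plus `mesh` and `material`.
#' @export
fem_modal_analysis <- function(geom, material, resolution = c(10, 6, 10),
                               n_modes = 10, aux = vf_elastic_aux(),
                               mesh = NULL, seed = 1L) {
  if (is.null(mesh)) mesh <- build_mesh(geom, resolution)
  Cb <- build_layer_elasticity(material$Et, material$gap_body, aux, "body")
  Cc <- build_layer_elasticity(material$Et, material$gap_cover, aux, "cover")
  km <- assemble_km(mesh, Cb$C_voigt, Cc$C_voigt, material$density)
  sol <- solve_modes(km$K, km$M, fixed_dofs(mesh), n_modes, seed = seed)
  sol$mesh <- mesh
  sol$material <- material
  sol
}
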
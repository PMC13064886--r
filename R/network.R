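#' Network architecture specification
#'
#' The displacement network is a SiLU material encoder feeding a SIREN
#' backbone: the three material parameters (min-max normalized over the
#' training grid) pass through two fully connected SiLU layers; the encoding
#' is concatenated with the spatial coordinates (affinely mapped to
#' \[-1, 1\]^3) and fed to a stack of sinusoidal layers
#' `sin(omega0 * (W h + b))` followed by a linear 3-component output head.
#' The `"paper"` preset is 4 hidden layers x 128 units with omega0 = 5 and a
#' width-64 encoder.
#'
#' @param preset `"paper"` or `"custom"`.
#' @param width Hidden width of the SIREN backbone.
#' @param depth Number of sinusoidal hidden layers.
#' @param omega0 Frequency scale of the sinusoidal activations.
#' @param encoder_width Width of the two SiLU encoder layers.
#' @return Object of class `vf_network_spec`.
#' @export
network_spec <- function(preset = c("paper", "custom"), width = 128, depth = 4,
                         omega0 = 5, encoder_width = 64) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    width <- 128; depth <- 4; omega0 <- 5; encoder_width <- 64
  }
  stopifnot(width >= 1, depth >= 1, omega0 > 0, encoder_width >= 1)
  structure(
    list(preset = preset, width = width, depth = depth, omega0 = omega0,
         encoder_width = encoder_width),
    class = "vf_network_spec"
  )
}

.silu <- function(x) x / (1 + exp(-x))
.silu_deriv <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

#' Initialize network weights
#'
#' SIREN initialization: the first sinusoidal layer draws weights from
#' U(-1/fan_in, 1/fan_in); deeper sinusoidal layers and the output head from
#' U(-sqrt(6/fan_in)/omega0, sqrt(6/fan_in)/omega0). Encoder layers use
#' Glorot-uniform. Normalization constants (domain box, material ranges over
#' the training grid) are stored with the weights so inference is
#' self-contained.
#'
#' @param spec A [network_spec()].
#' @param geom A [vf_geometry()] fixing the spatial normalization box.
#' @param grid Material grid data.frame (columns `Et`, `gap_body`,
#'   `gap_cover`) fixing the material min-max normalization.
#' @param seed Integer init seed.
#' @return Object of class `vf_network`: weights + spec + normalization.
#' @export
init_network <- function(spec, geom, grid, seed = 1L) {
  set.seed(seed)
  we <- spec$encoder_width
  w <- spec$width
  d_in <- 3L + we
  glorot <- function(nout, nin) {
    r <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nout * nin, -r, r), nout, nin)
  }
  siren_first <- function(nout, nin) {
    r <- 1 / nin
    matrix(stats::runif(nout * nin, -r, r), nout, nin)
  }
  siren_hidden <- function(nout, nin, omega0) {
    r <- sqrt(6 / nin) / omega0
    matrix(stats::runif(nout * nin, -r, r), nout, nin)
  }
  enc <- list(
    W1 = glorot(we, 3L), b1 = numeric(we),
    W2 = glorot(we, we), b2 = numeric(we)
  )
  hidden <- vector("list", spec$depth)
  hidden[[1]] <- list(W = siren_first(w, d_in), b = numeric(w))
  if (spec$depth > 1) {
    for (l in 2:spec$depth) {
      hidden[[l]] <- list(W = siren_hidden(w, w, spec$omega0), b = numeric(w))
    }
  }
  out <- list(W = siren_hidden(3L, w, spec$omega0), b = numeric(3L))
  m_rng <- rbind(
    lo = c(min(grid$Et), min(grid$gap_body), min(grid$gap_cover)),
    hi = c(max(grid$Et), max(grid$gap_body), max(grid$gap_cover))
  )
  colnames(m_rng) <- c("Et", "gap_body", "gap_cover")
  structure(
    list(
      spec = spec, enc = enc, hidden = hidden, out = out,
      norm = list(
        x_lo = c(0, 0, 0), x_hi = c(geom$D, geom$T_thick, geom$L),
        m_lo = m_rng["lo", ], m_hi = pmax(m_rng["hi", ], m_rng["lo", ] + 1e-12)
      ),
      seed = seed
    ),
    class = "vf_network"
  )
}

# flatten weights to a numeric vector / restore from one
.net_pack <- function(net) {
  unlist(list(net$enc$W1, net$enc$b1, net$enc$W2, net$enc$b2,
              lapply(net$hidden, function(h) list(h$W, h$b)),
              net$out$W, net$out$b), use.names = FALSE)
}

.net_unpack <- function(net, theta) {
  take <- local({
    pos <- 0L
    function(template) {
      n <- length(template)
      v <- theta[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (is.matrix(template)) matrix(v, nrow(template), ncol(template)) else v
    }
  })
  net$enc$W1 <- take(net$enc$W1); net$enc$b1 <- take(net$enc$b1)
  net$enc$W2 <- take(net$enc$W2); net$enc$b2 <- take(net$enc$b2)
  for (l in seq_along(net$hidden)) {
    net$hidden[[l]]$W <- take(net$hidden[[l]]$W)
    net$hidden[[l]]$b <- take(net$hidden[[l]]$b)
  }
  net$out$W <- take(net$out$W); net$out$b <- take(net$out$b)
  net
}

.material_vec <- function(material) {
  if (inherits(material, "vf_material")) {
    c(material$Et, material$gap_body, material$gap_cover)
  } else {
    stopifnot(length(material) == 3)
    as.numeric(material)
  }
}

#' Encode material parameters
#'
#' Runs the two-layer SiLU encoder on min-max normalized material parameters.
#' Parameters outside the training range trigger an extrapolation warning but
#' are still encoded.
#'
#' @param net A [init_network()] object.
#' @param material A [vf_material()] or numeric `c(Et, gap_body, gap_cover)`.
#' @return List with `encoding` (vector), `m_norm`, and cached pre-activations
#'   (used by the training backward pass).
#' @export
encode_materials <- function(net, material) {
  m <- .material_vec(material)
  rng <- net$norm$m_hi - net$norm$m_lo
  mn <- ifelse(rng > 0, (m - net$norm$m_lo) / rng, 0.5)
  if (any(mn < -1e-9 | mn > 1 + 1e-9)) {
    warning("material parameters outside the training grid range; ",
            "encoding extrapolates")
  }
  a1 <- drop(net$enc$W1 %*% mn) + net$enc$b1
  h1 <- .silu(a1)
  a2 <- drop(net$enc$W2 %*% h1) + net$enc$b2
  e <- .silu(a2)
  list(encoding = e, m_norm = mn, a1 = a1, h1 = h1, a2 = a2)
}

# index pairs for unique second derivatives, Voigt-compatible order
.d2_pairs <- list(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(2L, 3L), c(1L, 3L), c(1L, 2L))

# Differentiation backend: "cpp" (compiled, default) or "r" (pure-R
# reference). Both produce identical results; the R path documents the
# algorithm and serves as the equality oracle in tests.
.net_backend <- function() {
  b <- getOption("vfpinn.backend", "cpp")
  if (!b %in% c("cpp", "r")) stop("vfpinn.backend must be 'cpp' or 'r'")
  b
}

# Core forward pass. X: N x 3 physical coordinates (m). deriv in 0:2.
# Returns u (N x 3), grad (N x 3 x 3, grad[p,i,j] = du_i/dx_j, physical),
# hess (N x 3 x 6, unique pairs in .d2_pairs order, physical), and the cache
# needed by .net_backward when want_cache = TRUE.
.net_forward <- function(net, X, material, deriv = 0L, want_cache = FALSE) {
  if (.net_backend() == "cpp") {
    .net_forward_cpp(net, X, material, deriv, want_cache)
  } else {
    .net_forward_r(net, X, material, deriv, want_cache)
  }
}

.net_forward_cpp <- function(net, X, material, deriv = 0L, want_cache = FALSE) {
  stopifnot(is.matrix(X), ncol(X) == 3)
  N <- nrow(X)
  scl <- 2 / (net$norm$x_hi - net$norm$x_lo)
  Xn <- sweep(sweep(X, 2, net$norm$x_lo, "-"), 2, scl, "*") - 1
  encc <- encode_materials(net, material)
  Z <- cbind(Xn, matrix(encc$encoding, N, length(encc$encoding), byrow = TRUE))
  Ws <- lapply(net$hidden, `[[`, "W")
  bs <- lapply(net$hidden, `[[`, "b")
  fw <- .siren_forward_cpp(Ws, bs, net$out$W, net$out$b, Z,
                           net$spec$omega0, as.integer(deriv), want_cache)
  grad <- NULL; hess <- NULL
  if (deriv >= 1L) {
    grad <- array(0, c(N, 3, 3))
    for (j in 1:3) grad[, , j] <- fw$Gout[[j]] * scl[j]
  }
  if (deriv >= 2L) {
    hess <- array(0, c(N, 3, 6))
    for (pr in 1:6) {
      a <- .d2_pairs[[pr]][1]; bb <- .d2_pairs[[pr]][2]
      hess[, , pr] <- fw$Sout[[pr]] * (scl[a] * scl[bb])
    }
  }
  res <- list(u = fw$U, grad = grad, hess = hess)
  if (want_cache) {
    res$cache <- list(cpp = fw$cache, enc = encc, scl = scl,
                      deriv = deriv, N = N, backend = "cpp")
  }
  res
}

.net_forward_r <- function(net, X, material, deriv = 0L, want_cache = FALSE) {
  stopifnot(is.matrix(X), ncol(X) == 3)
  N <- nrow(X)
  w0 <- net$spec$omega0
  L <- net$spec$depth
  scl <- 2 / (net$norm$x_hi - net$norm$x_lo)
  Xn <- sweep(sweep(X, 2, net$norm$x_lo, "-"), 2, scl, "*") - 1

  encc <- encode_materials(net, material)
  d_in <- 3L + length(encc$encoding)
  Z <- cbind(Xn, matrix(encc$encoding, N, length(encc$encoding), byrow = TRUE))

  H <- vector("list", L); CC <- vector("list", L)
  P <- vector("list", L); G <- vector("list", L)
  Q <- vector("list", L); S <- vector("list", L)
  IN <- Z
  GIN <- NULL; SIN <- NULL
  for (l in seq_len(L)) {
    W <- net$hidden[[l]]$W; b <- net$hidden[[l]]$b
    A <- IN %*% t(W)
    A <- A + rep(b, each = N)
    H[[l]] <- sin(w0 * A)
    CC[[l]] <- cos(w0 * A)
    if (deriv >= 1L) {
      P[[l]] <- vector("list", 3)
      G[[l]] <- vector("list", 3)
      for (j in 1:3) {
        P[[l]][[j]] <- if (l == 1L) {
          matrix(W[, j], N, nrow(W), byrow = TRUE)
        } else {
          GIN[[j]] %*% t(W)
        }
        G[[l]][[j]] <- w0 * CC[[l]] * P[[l]][[j]]
      }
    }
    if (deriv >= 2L) {
      Q[[l]] <- vector("list", 6)
      S[[l]] <- vector("list", 6)
      for (pr in 1:6) {
        a <- .d2_pairs[[pr]][1]; bb <- .d2_pairs[[pr]][2]
        Q[[l]][[pr]] <- if (l == 1L) {
          matrix(0, N, nrow(W))
        } else {
          SIN[[pr]] %*% t(W)
        }
        S[[l]][[pr]] <- -w0^2 * H[[l]] * P[[l]][[a]] * P[[l]][[bb]] +
          w0 * CC[[l]] * Q[[l]][[pr]]
      }
    }
    IN <- H[[l]]
    if (deriv >= 1L) GIN <- G[[l]]
    if (deriv >= 2L) SIN <- S[[l]]
  }

  Wo <- net$out$W; bo <- net$out$b
  U <- H[[L]] %*% t(Wo)
  U <- U + rep(bo, each = N)
  grad <- NULL; hess <- NULL
  if (deriv >= 1L) {
    grad <- array(0, c(N, 3, 3))
    for (j in 1:3) grad[, , j] <- (G[[L]][[j]] %*% t(Wo)) * scl[j]
  }
  if (deriv >= 2L) {
    hess <- array(0, c(N, 3, 6))
    for (pr in 1:6) {
      a <- .d2_pairs[[pr]][1]; bb <- .d2_pairs[[pr]][2]
      hess[, , pr] <- (S[[L]][[pr]] %*% t(Wo)) * (scl[a] * scl[bb])
    }
  }
  res <- list(u = U, grad = grad, hess = hess)
  if (want_cache) {
    res$cache <- list(Z = Z, H = H, CC = CC, P = P, G = G, Q = Q, S = S,
                      enc = encc, scl = scl, deriv = deriv, N = N,
                      backend = "r")
  }
  res
}

# Reverse pass through the forward-mode graph. Adjoints are with respect to
# the PHYSICAL-space outputs of .net_forward: ubar (N x 3), gradbar
# (N x 3 x 3 or NULL), hessbar (N x 3 x 6 or NULL). Returns the gradient of
# the scalar loss with respect to every trainable parameter, packed in the
# same order as .net_pack.
.net_backward <- function(net, cache, ubar, gradbar = NULL, hessbar = NULL) {
  if (identical(cache$backend, "cpp")) {
    .net_backward_cpp(net, cache, ubar, gradbar, hessbar)
  } else {
    .net_backward_r(net, cache, ubar, gradbar, hessbar)
  }
}

.net_backward_cpp <- function(net, cache, ubar, gradbar = NULL, hessbar = NULL) {
  scl <- cache$scl
  L <- net$spec$depth
  slab <- function(arr, k) {
    s <- arr[, , k]
    if (!is.matrix(s)) s <- matrix(s, nrow = cache$N)
    s
  }
  Gout_bar <- if (!is.null(gradbar)) {
    lapply(1:3, function(j) slab(gradbar, j) * scl[j])
  } else NULL
  Sout_bar <- if (!is.null(hessbar)) {
    lapply(1:6, function(pr) {
      a <- .d2_pairs[[pr]][1]; b <- .d2_pairs[[pr]][2]
      slab(hessbar, pr) * (scl[a] * scl[b])
    })
  } else NULL
  if (!is.matrix(ubar)) ubar <- matrix(ubar, cache$N, 3)
  bw <- .siren_backward_cpp(cache$cpp, ubar, Gout_bar, Sout_bar)
  ebar <- colSums(bw$Zbar[, 4:ncol(bw$Zbar), drop = FALSE])

  encc <- cache$enc
  a2bar <- ebar * .silu_deriv(encc$a2)
  W2_bar <- outer(a2bar, encc$h1)
  h1bar <- drop(crossprod(net$enc$W2, a2bar))
  a1bar <- h1bar * .silu_deriv(encc$a1)
  W1_bar <- outer(a1bar, encc$m_norm)

  unlist(list(W1_bar, a1bar, W2_bar, a2bar,
              lapply(seq_len(L), function(l) list(bw$W_bar[[l]],
                                                  as.numeric(bw$b_bar[[l]]))),
              bw$Wo_bar, as.numeric(bw$bo_bar)), use.names = FALSE)
}

.net_backward_r <- function(net, cache, ubar, gradbar = NULL, hessbar = NULL) {
  N <- cache$N
  w0 <- net$spec$omega0
  L <- net$spec$depth
  scl <- cache$scl
  Wo <- net$out$W
  use_g <- !is.null(gradbar)
  use_s <- !is.null(hessbar)
  if (use_g && cache$deriv < 1L) stop("cache lacks first-derivative state")
  if (use_s && cache$deriv < 2L) stop("cache lacks second-derivative state")
  # second derivatives are built from first-derivative state, so first-order
  # adjoints must propagate whenever second-order ones are seeded
  has_g <- use_g || use_s

  Gout_bar <- if (use_g) lapply(1:3, function(j) gradbar[, , j] * scl[j]) else NULL
  Sout_bar <- if (use_s) {
    lapply(1:6, function(pr) {
      a <- .d2_pairs[[pr]][1]; b <- .d2_pairs[[pr]][2]
      hessbar[, , pr] * (scl[a] * scl[b])
    })
  } else NULL

  HL <- cache$H[[L]]
  Wo_bar <- crossprod(ubar, HL)
  bo_bar <- colSums(ubar)
  if (use_g) {
    for (j in 1:3) Wo_bar <- Wo_bar + crossprod(Gout_bar[[j]], cache$G[[L]][[j]])
  }
  if (use_s) {
    for (pr in 1:6) Wo_bar <- Wo_bar + crossprod(Sout_bar[[pr]], cache$S[[L]][[pr]])
  }

  Hbar <- ubar %*% Wo
  Gbar <- if (use_g) {
    lapply(Gout_bar, function(gb) gb %*% Wo)
  } else if (has_g) {
    lapply(1:3, function(j) matrix(0, N, ncol(Wo)))
  } else NULL
  Sbar <- if (use_s) lapply(Sout_bar, function(sb) sb %*% Wo) else NULL

  W_bar <- vector("list", L)
  b_bar <- vector("list", L)
  for (l in L:1) {
    H <- cache$H[[l]]; CCl <- cache$CC[[l]]
    W <- net$hidden[[l]]$W
    Pl <- if (cache$deriv >= 1L) cache$P[[l]] else NULL
    Ql <- if (cache$deriv >= 2L) cache$Q[[l]] else NULL

    Cbar <- matrix(0, N, ncol(H))
    Qbar <- NULL
    Pbar <- NULL
    if (has_g) {
      Pbar <- lapply(1:3, function(j) w0 * CCl * Gbar[[j]])
    }
    if (use_s) {
      Qbar <- vector("list", 6)
      for (pr in 1:6) {
        a <- .d2_pairs[[pr]][1]; b <- .d2_pairs[[pr]][2]
        sb <- Sbar[[pr]]
        Qbar[[pr]] <- w0 * CCl * sb
        term <- -w0^2 * H * sb
        Pbar[[a]] <- Pbar[[a]] + term * Pl[[b]]
        Pbar[[b]] <- Pbar[[b]] + term * Pl[[a]]
        Hbar <- Hbar + sb * (-w0^2 * Pl[[a]] * Pl[[b]])
        Cbar <- Cbar + sb * (w0 * Ql[[pr]])
      }
    }
    if (has_g) {
      for (j in 1:3) Cbar <- Cbar + Gbar[[j]] * (w0 * Pl[[j]])
    }
    Abar <- Hbar * (w0 * CCl) + Cbar * (-w0 * H)

    INl <- if (l == 1L) cache$Z else cache$H[[l - 1L]]
    Wb <- crossprod(Abar, INl)
    if (!is.null(Pbar)) {
      if (l == 1L) {
        for (j in 1:3) Wb[, j] <- Wb[, j] + colSums(Pbar[[j]])
      } else {
        for (j in 1:3) Wb <- Wb + crossprod(Pbar[[j]], cache$G[[l - 1L]][[j]])
      }
    }
    if (use_s && l > 1L) {
      for (pr in 1:6) Wb <- Wb + crossprod(Qbar[[pr]], cache$S[[l - 1L]][[pr]])
    }
    W_bar[[l]] <- Wb
    b_bar[[l]] <- colSums(Abar)

    if (l > 1L) {
      Hbar <- Abar %*% W
      if (has_g) Gbar <- lapply(Pbar, function(pb) pb %*% W)
      if (use_s) Sbar <- lapply(Qbar, function(qb) qb %*% W)
    } else {
      Zbar <- Abar %*% W
      ebar <- colSums(Zbar[, 4:ncol(Zbar), drop = FALSE])
    }
  }

  # encoder backward
  encc <- cache$enc
  a2bar <- ebar * .silu_deriv(encc$a2)
  W2_bar <- outer(a2bar, encc$h1)
  b2_bar <- a2bar
  h1bar <- drop(crossprod(net$enc$W2, a2bar))
  a1bar <- h1bar * .silu_deriv(encc$a1)
  W1_bar <- outer(a1bar, encc$m_norm)
  b1_bar <- a1bar

  unlist(list(W1_bar, b1_bar, W2_bar, b2_bar,
              lapply(seq_len(L), function(l) list(W_bar[[l]], b_bar[[l]])),
              Wo_bar, bo_bar), use.names = FALSE)
}

#' Predict the displacement field
#'
#' Evaluates the network displacement (nondimensional) at physical coordinates
#' for one material configuration. With `deriv >= 1` also returns the spatial
#' Jacobian (exact, by analytic forward-mode differentiation through the
#' sinusoidal layers) and with `deriv = 2` the unique second derivatives.
#'
#' @param net A [init_network()] object.
#' @param X N x 3 matrix of points (m).
#' @param material A [vf_material()] or numeric triple.
#' @param deriv 0, 1 or 2.
#' @return List with `u` (N x 3); `grad` (N x 3 x 3, `grad[p,i,j]` =
#'   du_i/dx_j in 1/m units of physical coordinates) when `deriv >= 1`;
#'   `hess` (N x 3 x 6, pair order 11, 22, 33, 23, 13, 12) when `deriv = 2`.
#' @export
predict_displacement <- function(net, X, material, deriv = 0L) {
  out <- .net_forward(net, X, material, deriv = deriv)
  out[c("u", "grad", "hess")]
}

#' Displacement Jacobian, strain and stress at a point batch
#'
#' @param net A [init_network()] object.
#' @param X N x 3 matrix of points (m); all points must share one layer.
#' @param material A [vf_material()] or numeric triple.
#' @param C_voigt 6x6 stiffness of the layer the points belong to.
#' @return List with `grad` (N x 3 x 3), `strain` (N x 6 engineering Voigt)
#'   and `stress` (N x 6 Voigt, Pa).
#' @export
displacement_jacobian_and_stress <- function(net, X, material, C_voigt) {
  out <- .net_forward(net, X, material, deriv = 1L)
  eps <- grad_to_strain(out$grad)
  list(grad = out$grad, strain = eps, stress = voigt_stress(C_voigt, eps))
}

#' Save / load network weights as portable text
#'
#' The checkpoint is a JSON file holding the flattened weight vector, the
#' architecture spec, normalization constants, the mode index the weights were
#' trained for, and free-form metadata.
#'
#' @param net A [init_network()] object (possibly trained).
#' @param path Output file.
#' @param mode_index Mode the weights belong to.
#' @param meta Optional named list of run metadata.
#' @return `path` invisibly.
#' @export
save_network <- function(net, path, mode_index = NA_integer_, meta = list()) {
  obj <- list(
    spec = unclass(net$spec),
    norm = lapply(net$norm, as.numeric),
    theta = .net_pack(net),
    mode_index = mode_index,
    meta = meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @param geom Geometry used to rebuild the normalization box (stored values
#'   take precedence; pass the geometry the run used).
#' @export
load_network <- function(path, geom = vf_geometry()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(network_spec, c(list(preset = "custom"),
                                  obj$spec[c("width", "depth", "omega0", "encoder_width")]))
  grid <- data.frame(Et = obj$norm$m_lo[1], gap_body = obj$norm$m_lo[2],
                     gap_cover = obj$norm$m_lo[3])
  net <- init_network(spec, geom, grid, seed = 1L)
  net$norm$x_lo <- as.numeric(obj$norm$x_lo)
  net$norm$x_hi <- as.numeric(obj$norm$x_hi)
  net$norm$m_lo <- as.numeric(obj$norm$m_lo)
  net$norm$m_hi <- as.numeric(obj$norm$m_hi)
  net <- .net_unpack(net, as.numeric(obj$theta))
  attr(net, "mode_index") <- obj$mode_index
  net
}
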
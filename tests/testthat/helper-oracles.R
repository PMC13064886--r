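# Independent oracles, coded along different derivation paths than the
# package implementation.

# Dense 24x24 element stiffness/mass for an axis-aligned brick by direct
# index summation over the full fourth-order stiffness tensor (no B-matrix):
# K[3(a-1)+i, 3(b-1)+k] = sum_q detJ sum_{j,l} C[i,j,k,l] dN_a/dx_j dN_b/dx_l
oracle_hex_matrices <- function(C_voigt, density, hx, hy, hz) {
  vid <- matrix(c(1, 6, 5, 6, 2, 4, 5, 4, 3), 3, 3)
  Cf <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    Cf[i, j, k, l] <- C_voigt[vid[i, j], vid[k, l]]
  }
  g <- 1 / sqrt(3)
  sgn <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  K <- matrix(0, 24, 24)
  M <- matrix(0, 24, 24)
  detJ <- hx * hy * hz / 8
  for (qx in c(-g, g)) for (qy in c(-g, g)) for (qz in c(-g, g)) {
    Nv <- numeric(8)
    D <- matrix(0, 8, 3)
    for (a in 1:8) {
      s <- sgn[a, ]
      Nv[a] <- (1 + qx * s[1]) * (1 + qy * s[2]) * (1 + qz * s[3]) / 8
      D[a, 1] <- s[1] * (1 + qy * s[2]) * (1 + qz * s[3]) / 8 * 2 / hx
      D[a, 2] <- (1 + qx * s[1]) * s[2] * (1 + qz * s[3]) / 8 * 2 / hy
      D[a, 3] <- (1 + qx * s[1]) * (1 + qy * s[2]) * s[3] / 8 * 2 / hz
    }
    for (a in 1:8) for (b in 1:8) {
      for (i in 1:3) for (k in 1:3) {
        kv <- 0
        for (j in 1:3) for (l in 1:3) {
          kv <- kv + Cf[i, j, k, l] * D[a, j] * D[b, l]
        }
        K[3 * (a - 1) + i, 3 * (b - 1) + k] <-
          K[3 * (a - 1) + i, 3 * (b - 1) + k] + kv * detJ
        if (i == k) {
          M[3 * (a - 1) + i, 3 * (b - 1) + k] <-
            M[3 * (a - 1) + i, 3 * (b - 1) + k] + density * Nv[a] * Nv[b] * detJ
        }
      }
    }
  }
  list(K = K, M = M)
}

# Navier-Cauchy residual of an analytic field by direct tensor contraction
# with finite-difference second derivatives (independent of the package's
# divergence-coefficient path).
oracle_residual <- function(u_fun, C_voigt, density, lambda, points,
                            h = 1e-6) {
  vid <- matrix(c(1, 6, 5, 6, 2, 4, 5, 4, 3), 3, 3)
  Cf <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    Cf[i, j, k, l] <- C_voigt[vid[i, j], vid[k, l]]
  }
  res <- matrix(0, nrow(points), 3)
  for (p in seq_len(nrow(points))) {
    x <- points[p, ]
    d2 <- array(0, c(3, 3, 3))  # d2[k, j, l] = d^2 u_k / dx_j dx_l
    for (j in 1:3) for (l in 1:3) {
      if (j == l) {
        xp <- x; xp[j] <- xp[j] + h
        xm <- x; xm[j] <- xm[j] - h
        d2[, j, l] <- (u_fun(xp) - 2 * u_fun(x) + u_fun(xm)) / h^2
      } else {
        xpp <- x; xpp[j] <- xpp[j] + h; xpp[l] <- xpp[l] + h
        xpm <- x; xpm[j] <- xpm[j] + h; xpm[l] <- xpm[l] - h
        xmp <- x; xmp[j] <- xmp[j] - h; xmp[l] <- xmp[l] + h
        xmm <- x; xmm[j] <- xmm[j] - h; xmm[l] <- xmm[l] - h
        d2[, j, l] <- (u_fun(xpp) - u_fun(xpm) - u_fun(xmp) + u_fun(xmm)) /
          (4 * h^2)
      }
    }
    for (i in 1:3) {
      acc <- 0
      for (j in 1:3) for (k in 1:3) for (l in 1:3) {
        acc <- acc + Cf[i, j, k, l] * d2[k, j, l]
      }
      res[p, i] <- acc + density * lambda * u_fun(x)[i]
    }
  }
  res
}

# Central finite differences of a network's displacement field (physical
# coordinates); step given on the normalized [-1, 1] domain.
fd_network_derivs <- function(net, X, material, step_norm = 1e-4) {
  hs <- step_norm * (net$norm$x_hi - net$norm$x_lo) / 2
  N <- nrow(X)
  ev <- function(P) predict_displacement(net, P, material, deriv = 0L)$u
  grad <- array(0, c(N, 3, 3))
  for (j in 1:3) {
    Xp <- X; Xp[, j] <- Xp[, j] + hs[j]
    Xm <- X; Xm[, j] <- Xm[, j] - hs[j]
    grad[, , j] <- (ev(Xp) - ev(Xm)) / (2 * hs[j])
  }
  pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  hess <- array(0, c(N, 3, 6))
  u0 <- ev(X)
  for (pr in 1:6) {
    a <- pairs[[pr]][1]; b <- pairs[[pr]][2]
    if (a == b) {
      Xp <- X; Xp[, a] <- Xp[, a] + hs[a]
      Xm <- X; Xm[, a] <- Xm[, a] - hs[a]
      hess[, , pr] <- (ev(Xp) - 2 * u0 + ev(Xm)) / hs[a]^2
    } else {
      Xpp <- X; Xpp[, a] <- Xpp[, a] + hs[a]; Xpp[, b] <- Xpp[, b] + hs[b]
      Xpm <- X; Xpm[, a] <- Xpm[, a] + hs[a]; Xpm[, b] <- Xpm[, b] - hs[b]
      Xmp <- X; Xmp[, a] <- Xmp[, a] - hs[a]; Xmp[, b] <- Xmp[, b] + hs[b]
      Xmm <- X; Xmm[, a] <- Xmm[, a] - hs[a]; Xmm[, b] <- Xmm[, b] - hs[b]
      hess[, , pr] <- (ev(Xpp) - ev(Xpm) - ev(Xmp) + ev(Xmm)) /
        (4 * hs[a] * hs[b])
    }
  }
  list(grad = grad, hess = hess)
}
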
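#' Body--cover prism geometry
#'
#' The computational domain is a rectangular prism in the coordinate frame
#' x = medial-to-lateral depth in [0, Dc + Db] (cover on the medial side,
#' interface plane at x = Dc), y = inferior-to-superior in [0, T],
#' z = anterior-to-posterior in [0, L]; origin at the medial-inferior-anterior
#' corner. Lateral (x = Dc + Db), anterior (z = 0) and posterior (z = L) faces
#' are mechanically fixed; medial, inferior and superior faces are free.
#'
#' Two depth profiles ship with the package: `"printed"` (Db = 60 mm,
#' Dc = 15 mm) and `"rescaled"` (Db = 6.0 mm, Dc = 1.5 mm), which places the
#' total depth in the usual anatomical range; both keep T = 4.5 mm and
#' L = 17 mm.
#'
#' @param T_thick Medial-surface (inferior-superior) thickness, m.
#' @param Db Body depth, m.
#' @param Dc Cover depth, m.
#' @param L Anterior-posterior length, m.
#' @param profile Convenience preset; explicit dimensions override it.
#' @return Object of class `vf_geometry` with fields `T_thick`, `Db`, `Dc`,
#'   `L`, `D` (total depth) and `profile`.
#' @export
#' @examples
#' g <- vf_geometry(profile = "rescaled")
#' g$D  # 7.5 mm total depth
vf_geometry <- function(T_thick = NULL, Db = NULL, Dc = NULL, L = NULL,
                        profile = c("printed", "rescaled")) {
  profile <- match.arg(profile)
  def <- switch(profile,
    printed  = list(T_thick = 4.5e-3, Db = 60e-3, Dc = 15e-3, L = 17e-3),
    rescaled = list(T_thick = 4.5e-3, Db = 6.0e-3, Dc = 1.5e-3, L = 17e-3)
  )
  g <- list(
    T_thick = if (is.null(T_thick)) def$T_thick else T_thick,
    Db = if (is.null(Db)) def$Db else Db,
    Dc = if (is.null(Dc)) def$Dc else Dc,
    L = if (is.null(L)) def$L else L
  )
  if (any(unlist(g) <= 0)) stop("all dimensions must be strictly positive")
  g$D <- g$Db + g$Dc
  g$profile <- profile
  structure(g, class = "vf_geometry")
}

#' @export
print.vf_geometry <- function(x, ...) {
  cat(sprintf(
    "<vf_geometry %s> T = %g mm, Dc = %g mm, Db = %g mm, L = %g mm\n",
    x$profile, x$T_thick * 1e3, x$Dc * 1e3, x$Db * 1e3, x$L * 1e3
  ))
  invisible(x)
}

#' Layer volumes of the prism
#' @param geom A [vf_geometry()].
#' @return Named vector with `cover`, `body`, `total` volumes in m^3.
#' @export
layer_volumes <- function(geom) {
  a <- geom$T_thick * geom$L
  c(cover = a * geom$Dc, body = a * geom$Db, total = a * geom$D)
}

#' Classify points into body or cover layer
#'
#' A point belongs to the cover iff its depth coordinate x is at most Dc
#' (the interface plane itself is assigned to the cover).
#'
#' @param p Numeric length-3 vector or N x 3 matrix of points (m).
#' @param geom A [vf_geometry()].
#' @return Character vector of `"cover"` / `"body"` tags.
#' @export
classify_point <- function(p, geom) {
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  tol <- 1e-12
  inside <- p[, 1] >= -tol & p[, 1] <= geom$D + tol &
    p[, 2] >= -tol & p[, 2] <= geom$T_thick + tol &
    p[, 3] >= -tol & p[, 3] <= geom$L + tol
  if (!all(inside)) stop("point outside the body-cover prism")
  ifelse(p[, 1] <= geom$Dc, "cover", "body")
}

.face_tags <- c("medial", "lateral", "inferior", "superior", "anterior", "posterior")

#' Outward unit normal of a prism face
#'
#' @param face One of `"medial"`, `"lateral"`, `"inferior"`, `"superior"`,
#'   `"anterior"`, `"posterior"`.
#' @return Outward unit 3-vector.
#' @export
face_normal <- function(face) {
  switch(face,
    medial    = c(-1, 0, 0),
    lateral   = c(1, 0, 0),
    inferior  = c(0, -1, 0),
    superior  = c(0, 1, 0),
    anterior  = c(0, 0, -1),
    posterior = c(0, 0, 1),
    stop("unknown face tag: ", face)
  )
}

#' Faces with essential (fixed) and natural (traction-free) conditions
#' @return Character vectors of face tags.
#' @export
fixed_faces <- function() c("lateral", "anterior", "posterior")

#' @rdname fixed_faces
#' @export
free_faces <- function() c("medial", "inferior", "superior")

#' Sample collocation, surface and interface points
#'
#' Interior points are stratified by layer: the total count is split between
#' cover and body proportionally to layer volume (rounded, remainder to the
#' body), each stratum is sampled uniformly within its layer, and each point
#' carries the quadrature weight (stratum volume / stratum count) so that
#' layer-wise Monte Carlo integrals are exactly volume-consistent. Surface
#' points are uniform per face with outward normals attached; interface points
#' are uniform on the body--cover plane x = Dc with normal pointing from cover
#' into body.
#'
#' @param geom A [vf_geometry()].
#' @param n_interior Total interior point count.
#' @param n_per_face Points per prism face.
#' @param n_interface Points on the interface plane.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Object of class `vf_collocation`: list with `interior` (list:
#'   `points` N x 3, `layer`, `weight`), `surface` (list: `points`, `face`,
#'   `normal` N x 3), `interface` (list: `points`, `normal`), `seed`, `geom`.
#' @export
sample_collocation <- function(geom, n_interior, n_per_face, n_interface, seed) {
  if (n_interior < 1 || n_per_face < 1 || n_interface < 1) {
    stop("all point counts must be positive")
  }
  vols <- layer_volumes(geom)
  n_cover <- round(n_interior * vols[["cover"]] / vols[["total"]])
  n_cover <- max(min(n_cover, n_interior - 1), 1)
  n_body <- n_interior - n_cover

  set.seed(seed)
  runif3 <- function(n, lo, hi) {
    cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]),
          stats::runif(n, lo[3], hi[3]))
  }
  pc <- runif3(n_cover, c(0, 0, 0), c(geom$Dc, geom$T_thick, geom$L))
  pb <- runif3(n_body, c(geom$Dc, 0, 0), c(geom$D, geom$T_thick, geom$L))
  interior <- list(
    points = rbind(pc, pb),
    layer = c(rep("cover", n_cover), rep("body", n_body)),
    weight = c(
      rep(vols[["cover"]] / n_cover, n_cover),
      rep(vols[["body"]] / n_body, n_body)
    )
  )

  face_box <- function(face) {
    lo <- c(0, 0, 0); hi <- c(geom$D, geom$T_thick, geom$L)
    switch(face,
      medial    = { hi[1] <- 0 },
      lateral   = { lo[1] <- geom$D },
      inferior  = { hi[2] <- 0 },
      superior  = { lo[2] <- geom$T_thick },
      anterior  = { hi[3] <- 0 },
      posterior = { lo[3] <- geom$L }
    )
    list(lo = lo, hi = hi)
  }
  sp <- vector("list", 6)
  for (k in seq_along(.face_tags)) {
    b <- face_box(.face_tags[k])
    sp[[k]] <- runif3(n_per_face, b$lo, b$hi)
  }
  surface <- list(
    points = do.call(rbind, sp),
    face = rep(.face_tags, each = n_per_face),
    normal = do.call(rbind, lapply(rep(.face_tags, each = n_per_face), face_normal))
  )

  pi_ <- runif3(n_interface, c(geom$Dc, 0, 0), c(geom$Dc, geom$T_thick, geom$L))
  interface <- list(
    points = pi_,
    normal = matrix(rep(c(1, 0, 0), n_interface), ncol = 3, byrow = TRUE)
  )

  structure(
    list(interior = interior, surface = surface, interface = interface,
         seed = seed, geom = geom),
    class = "vf_collocation"
  )
}

#' Write a collocation set to a directory of CSV files with a JSON manifest
#'
#' @param colloc A [sample_collocation()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collocation <- function(colloc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  int <- data.frame(colloc$interior$points)
  names(int) <- c("x", "y", "z")
  int$layer <- colloc$interior$layer
  int$weight <- colloc$interior$weight
  utils::write.csv(int, file.path(dir, "interior.csv"), row.names = FALSE)
  surf <- data.frame(colloc$surface$points, colloc$surface$normal)
  names(surf) <- c("x", "y", "z", "nx", "ny", "nz")
  surf$face <- colloc$surface$face
  utils::write.csv(surf, file.path(dir, "surface.csv"), row.names = FALSE)
  ifc <- data.frame(colloc$interface$points)
  names(ifc) <- c("x", "y", "z")
  utils::write.csv(ifc, file.path(dir, "interface.csv"), row.names = FALSE)
  meta <- list(
    seed = colloc$seed,
    geometry = unclass(colloc$geom)
  )
  jsonlite::write_json(meta, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
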
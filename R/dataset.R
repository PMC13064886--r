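#' Generate the reference modal dataset over a material grid
#'
#' Runs one FEM modal solve per material configuration of the grid on a shared
#' mesh and assembles the reference dataset that supervises the network:
#' ascending eigenfrequencies and unit-normalized nodal eigenmodes per
#' configuration, together with a seeded by-configuration 80/20
#' train/validation split.
#'
#' @param grid Data.frame from [vf_material_grid()] (or same columns).
#' @param geom A [vf_geometry()].
#' @param resolution Mesh resolution, see [build_mesh()].
#' @param n_modes Modes per configuration.
#' @param split_seed Seed for the configuration shuffle of the split.
#' @param aux Auxiliary elastic constants.
#' @param train_frac Training fraction (default 0.8).
#' @param verbose Print progress.
#' @return Object of class `vf_dataset`: `grid` (with `split` column),
#'   `lambda` (config x mode), `frequency_hz`, `modes` (list of DOF matrices),
#'   `mesh`, `geom`, `aux`, `n_modes`, `split_seed`.
#' @export
generate_dataset <- function(grid, geom, resolution = c(10, 6, 10),
                             n_modes = 10, split_seed = 1L,
                             aux = vf_elastic_aux(), train_frac = 0.8,
                             verbose = FALSE) {
  if (nrow(grid) == 0) stop("empty material grid")
  mesh <- build_mesh(geom, resolution)
  fixed <- fixed_dofs(mesh)
  nc <- nrow(grid)
  lambda <- matrix(NA_real_, nc, n_modes)
  freq <- matrix(NA_real_, nc, n_modes)
  modes <- vector("list", nc)
  names(modes) <- grid$config_id
  for (ci in seq_len(nc)) {
    mat <- vf_material(grid$Et[ci], grid$gap_body[ci], grid$gap_cover[ci],
                       density = if ("density" %in% names(grid)) grid$density[ci] else 1030)
    sol <- tryCatch(
      fem_modal_analysis(geom, mat, n_modes = n_modes, aux = aux, mesh = mesh),
      error = function(e) {
        stop("FEM solve failed for configuration ", grid$config_id[ci], ": ",
             conditionMessage(e))
      }
    )
    lambda[ci, ] <- sol$lambda
    freq[ci, ] <- sol$frequency_hz
    modes[[ci]] <- sol$modes
    if (verbose) {
      message(sprintf("[%d/%d] %s  f1 = %.2f Hz", ci, nc, grid$config_id[ci],
                      sol$frequency_hz[1]))
    }
  }
  grid$split <- split_configurations(nc, train_frac, split_seed)
  structure(
    list(grid = grid, lambda = lambda, frequency_hz = freq, modes = modes,
         mesh = mesh, geom = geom, aux = aux, n_modes = n_modes,
         split_seed = split_seed),
    class = "vf_dataset"
  )
}

#' Seeded train/validation split by configuration
#'
#' Shuffles the configuration indices with a seeded permutation and assigns
#' the first `round(train_frac * n)` (at least one) to the training split, the
#' rest to validation. The split is by whole configuration, never by point.
#'
#' @param n Number of configurations (or a data.frame whose rows are counted).
#' @param train_frac Training fraction.
#' @param seed Integer shuffle seed.
#' @return Character vector of `"train"` / `"validation"` tags, length `n`.
#' @export
split_configurations <- function(n, train_frac = 0.8, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 1) stop("need at least one configuration")
  if (train_frac <= 0 || train_frac > 1) stop("train_frac must be in (0, 1]")
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- max(round(train_frac * n), 1L)
  split <- rep("validation", n)
  split[perm[seq_len(n_train)]] <- "train"
  split
}

#' @export
print.vf_dataset <- function(x, ...) {
  cat(sprintf(
    "<vf_dataset> %d configurations (%d train / %d validation), %d modes, mesh %s\n",
    nrow(x$grid), sum(x$grid$split == "train"),
    sum(x$grid$split == "validation"), x$n_modes,
    paste(x$mesh$resolution, collapse = "x")
  ))
  invisible(x)
}

#' Modal assurance criterion between two mode vectors
#'
#' `MAC(u, v) = (u'v)^2 / ((u'u)(v'v))`; lies in \[0, 1\] by Cauchy--Schwarz.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
mac <- function(u, v) {
  sum(u * v)^2 / (sum(u^2) * sum(v^2))
}

#' Align mode ordering across configurations by MAC matching
#'
#' Eigenvalue ordering can swap between configurations as material parameters
#' change. This reorders each configuration's modes to match an anchor
#' configuration: anchor modes are processed in ascending index order (lowest
#' mode has priority) and each greedily claims the unassigned mode with the
#' highest MAC, ties broken by frequency order.
#'
#' @param dataset A [generate_dataset()] result.
#' @param anchor Config id (or index) to match against; defaults to the first
#'   training configuration.
#' @return The dataset with reordered `modes`, `lambda`, `frequency_hz`, plus
#'   `mac_tables` (per config: MAC matrix anchor x config, pre-matching) and
#'   `permutations`.
#' @export
match_modes <- function(dataset, anchor = NULL) {
  grid <- dataset$grid
  if (is.null(anchor)) anchor <- which(grid$split == "train")[1]
  if (is.character(anchor)) anchor <- match(anchor, grid$config_id)
  if (is.na(anchor)) stop("anchor configuration not found")
  A <- dataset$modes[[anchor]]
  nm <- dataset$n_modes
  mac_tables <- vector("list", nrow(grid))
  perms <- matrix(NA_integer_, nrow(grid), nm)
  for (ci in seq_len(nrow(grid))) {
    B <- dataset$modes[[ci]]
    if (nrow(B) != nrow(A)) stop("mesh mismatch between configurations")
    Mt <- matrix(0, nm, nm)
    for (i in seq_len(nm)) for (j in seq_len(nm)) Mt[i, j] <- mac(A[, i], B[, j])
    mac_tables[[ci]] <- Mt
    taken <- rep(FALSE, nm)
    perm <- integer(nm)
    for (i in seq_len(nm)) {
      cand <- which(!taken)
      best <- cand[Mt[i, cand] == max(Mt[i, cand])]
      perm[i] <- min(best)  # tie-break: lowest frequency order
      taken[perm[i]] <- TRUE
    }
    perms[ci, ] <- perm
    dataset$modes[[ci]] <- B[, perm, drop = FALSE]
    dataset$lambda[ci, ] <- dataset$lambda[ci, perm]
    dataset$frequency_hz[ci, ] <- dataset$frequency_hz[ci, perm]
  }
  dataset$mac_tables <- mac_tables
  dataset$permutations <- perms
  dataset$anchor <- anchor
  dataset
}

#' Cross-configuration cosine statistics of reference modes
#'
#' Absolute cosine correlation of one mode's displacement field over all
#' unordered pairs of configurations in a split, quantifying how structurally
#' stable that mode shape is under material variation (low-order modes are
#' stable, higher-order modes decorrelate).
#'
#' @param dataset A [generate_dataset()] result.
#' @param mode Mode index.
#' @param split `"train"` (default), `"validation"` or `"all"`.
#' @param node_subset Optional node ids to restrict the comparison to (e.g. a
#'   surface node set); default all nodes.
#' @return List with `median`, `mean`, `n_pairs`, and the pairwise values.
#' @export
cross_config_cosine_stats <- function(dataset, mode, split = "train",
                                      node_subset = NULL) {
  sel <- if (split == "all") seq_len(nrow(dataset$grid)) else
    which(dataset$grid$split == split)
  if (length(sel) < 2) stop("need at least two configurations in the split")
  vecs <- lapply(sel, function(ci) {
    v <- dataset$modes[[ci]][, mode]
    if (!is.null(node_subset)) {
      dofs <- as.vector(rbind(3 * (node_subset - 1) + 1,
                              3 * (node_subset - 1) + 2,
                              3 * (node_subset - 1) + 3))
      v <- v[dofs]
    }
    v
  })
  np <- length(vecs)
  vals <- numeric(0)
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    vi <- vecs[[i]]; vj <- vecs[[j]]
    vals <- c(vals, abs(sum(vi * vj)) / sqrt(sum(vi^2) * sum(vj^2)))
  }
  list(median = stats::median(vals), mean = mean(vals),
       n_pairs = length(vals), values = vals)
}

#' Persist / load a modal dataset as a plain-text directory
#'
#' Writes a JSON manifest (grid, split, geometry, resolution, seeds) plus one
#' CSV of frequencies and one CSV of stacked mode vectors per configuration.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Target directory.
#' @return `dir` invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "modes"), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    geometry = unclass(dataset$geom),
    aux = unclass(dataset$aux),
    resolution = dataset$mesh$resolution,
    n_modes = dataset$n_modes,
    split_seed = dataset$split_seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(dataset$grid, file.path(dir, "grid.csv"), row.names = FALSE)
  freq <- as.data.frame(dataset$frequency_hz)
  names(freq) <- paste0("mode", seq_len(dataset$n_modes))
  freq <- cbind(config_id = dataset$grid$config_id, freq)
  utils::write.csv(freq, file.path(dir, "frequencies_hz.csv"), row.names = FALSE)
  for (ci in seq_len(nrow(dataset$grid))) {
    utils::write.csv(
      as.data.frame(dataset$modes[[ci]]),
      file.path(dir, "modes", paste0(dataset$grid$config_id[ci], ".csv")),
      row.names = FALSE
    )
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  geom <- vf_geometry(
    T_thick = manifest$geometry$T_thick, Db = manifest$geometry$Db,
    Dc = manifest$geometry$Dc, L = manifest$geometry$L
  )
  aux <- vf_elastic_aux(manifest$aux$nu_t, manifest$aux$nu_zp)
  grid <- utils::read.csv(file.path(dir, "grid.csv"), stringsAsFactors = FALSE)
  mesh <- build_mesh(geom, manifest$resolution)
  freq <- utils::read.csv(file.path(dir, "frequencies_hz.csv"))
  fm <- as.matrix(freq[, -1, drop = FALSE])
  dimnames(fm) <- NULL
  modes <- lapply(grid$config_id, function(id) {
    m <- as.matrix(utils::read.csv(file.path(dir, "modes", paste0(id, ".csv"))))
    dimnames(m) <- NULL
    m
  })
  names(modes) <- grid$config_id
  structure(
    list(grid = grid, lambda = (2 * pi * fm)^2, frequency_hz = fm,
         modes = modes, mesh = mesh, geom = geom, aux = aux,
         n_modes = manifest$n_modes, split_seed = manifest$split_seed),
    class = "vf_dataset"
  )
}

#' Export a mode shape as a legacy VTK unstructured grid
#'
#' @param mesh A [build_mesh()] result.
#' @param mode_vec Full DOF displacement vector.
#' @param path Output `.vtk` file.
#' @param name Point-data array name.
#' @return `path` invisibly.
#' @export
write_mode_vtk <- function(mesh, mode_vec, path, name = "displacement") {
  U <- matrix(mode_vec, ncol = 3, byrow = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "body-cover vocal fold mode shape", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nrow(mesh$nodes)), con)
  utils::write.table(format(mesh$nodes, digits = 9, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  ne <- nrow(mesh$hex)
  writeLines(sprintf("CELLS %d %d", ne, 9 * ne), con)
  utils::write.table(cbind(8L, mesh$hex - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  writeLines(sprintf("POINT_DATA %d", nrow(mesh$nodes)), con)
  writeLines(sprintf("VECTORS %s double", name), con)
  utils::write.table(format(U, digits = 9, scientific = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
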
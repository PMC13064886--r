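#' Training configuration
#'
#' Collects everything a per-mode training run needs: mode index, epochs,
#' optimizer settings (Adam with cosine learning-rate decay by default),
#' collocation counts, seeds, loss weights and the network architecture.
#' Defaults follow the full-scale study setup (3000 epochs, 4x128 SIREN);
#' tests and examples pass smaller values.
#'
#' @param mode_index 1-based mode the network is trained for.
#' @param epochs Number of epochs (full-batch over training configurations).
#' @param lr Adam learning rate.
#' @param lr_schedule `"cosine"` (decay to `lr_min`) or `"constant"`.
#' @param lr_min Final learning rate of the cosine schedule.
#' @param betas Adam moment decay rates.
#' @param n_interior,n_per_face,n_interface Collocation counts.
#' @param seed_init,seed_sample Seeds for network init and collocation.
#' @param weights Loss weights, see [default_loss_weights()].
#' @param detach_lambda If TRUE the PDE residual treats the current
#'   Rayleigh-quotient eigenvalue as a constant (no gradient through it);
#'   default FALSE (full displacement-frequency coupling).
#' @param network A [network_spec()].
#' @param resample_every Resample collocation every k epochs (0 = fixed set).
#' @param log_every Record the loss breakdown every k epochs (1 = always).
#' @return Object of class `vf_train_config`.
#' @export
train_config <- function(mode_index = 1L, epochs = 3000L, lr = 1e-4,
                         lr_schedule = c("cosine", "constant"), lr_min = 1e-6,
                         betas = c(0.9, 0.999), n_interior = 2000L,
                         n_per_face = 250L, n_interface = 200L,
                         seed_init = 1L, seed_sample = 1L,
                         weights = default_loss_weights(),
                         detach_lambda = FALSE,
                         network = network_spec("paper"),
                         resample_every = 0L, log_every = 1L) {
  stopifnot(mode_index >= 1, epochs >= 1)
  structure(
    list(mode_index = as.integer(mode_index), epochs = as.integer(epochs),
         lr = lr, lr_schedule = match.arg(lr_schedule), lr_min = lr_min,
         betas = betas, n_interior = as.integer(n_interior),
         n_per_face = as.integer(n_per_face),
         n_interface = as.integer(n_interface),
         seed_init = as.integer(seed_init),
         seed_sample = as.integer(seed_sample),
         weights = .check_weights(weights), detach_lambda = detach_lambda,
         network = network, resample_every = as.integer(resample_every),
         log_every = as.integer(log_every)),
    class = "vf_train_config"
  )
}

# Precompute everything training needs for one material configuration.
.prep_config_data <- function(dataset, ci, mode_index, colloc) {
  grid <- dataset$grid
  mat <- vf_material(grid$Et[ci], grid$gap_body[ci], grid$gap_cover[ci],
                     density = if ("density" %in% names(grid)) grid$density[ci] else 1030)
  Cb <- build_layer_elasticity(mat$Et, mat$gap_body, dataset$aux, "body")$C_voigt
  Cc <- build_layer_elasticity(mat$Et, mat$gap_cover, dataset$aux, "cover")$C_voigt
  mode_vec <- dataset$modes[[ci]][, mode_index]
  ref_field <- field_from_fem(dataset$mesh, mode_vec)
  u_true_s <- ref_field(colloc$surface$points, deriv = 0L)$u
  list(
    config_id = grid$config_id[ci], material = mat,
    Cb = Cb, Cc = Cc,
    coef_b = .divergence_coef(Cb), coef_c = .divergence_coef(Cc),
    density = mat$density, stiff_ref = .stiffness_scale(Cc, Cb),
    lambda_true = dataset$lambda[ci, mode_index],
    u_true_s = u_true_s, u_true_vec = as.numeric(u_true_s),
    mode_vec = mode_vec
  )
}

# Composite loss and weight gradient for one configuration (fused path).
# Returns list(terms, lambda_rq, total, grad) with grad packed like .net_pack.
.config_loss_grad <- function(net, cd, colloc, weights, detach_lambda = FALSE,
                              scale = NULL, want_grad = TRUE) {
  geom <- colloc$geom
  L_char <- max(geom$D, geom$T_thick, geom$L)
  if (is.null(scale)) scale <- L_char^2 / cd$stiff_ref
  t_scale <- L_char / cd$stiff_ref
  idx_c <- which(colloc$interior$layer == "cover")
  idx_b <- which(colloc$interior$layer == "body")
  wq <- colloc$interior$weight
  rho <- cd$density

  fw_i <- .net_forward(net, colloc$interior$points, cd$material, deriv = 2L,
                       want_cache = want_grad)
  fw_s <- .net_forward(net, colloc$surface$points, cd$material, deriv = 1L,
                       want_cache = want_grad)
  fw_f <- .net_forward(net, colloc$interface$points, cd$material, deriv = 1L,
                       want_cache = want_grad)

  Ni <- nrow(colloc$interior$points)
  # --- Rayleigh quotient ---
  eps_i <- grad_to_strain(fw_i$grad)
  Ceps <- matrix(0, Ni, 6)
  Ceps[idx_c, ] <- eps_i[idx_c, , drop = FALSE] %*% cd$Cc
  Ceps[idx_b, ] <- eps_i[idx_b, , drop = FALSE] %*% cd$Cb
  q <- rowSums(Ceps * eps_i)
  V <- sum(wq * q)
  T_int <- rho * sum(wq * rowSums(fw_i$u^2))
  if (!is.finite(T_int) || T_int <= 0) stop("degenerate-field error: zero kinetic energy")
  lam <- V / T_int

  # --- PDE residual ---
  D2 <- .flatten_hess(fw_i$hess)
  divg <- matrix(0, Ni, 3)
  divg[idx_c, ] <- D2[idx_c, , drop = FALSE] %*% cd$coef_c
  divg[idx_b, ] <- D2[idx_b, , drop = FALSE] %*% cd$coef_b
  resid <- scale * (divg + rho * lam * fw_i$u)
  L_pde <- mean(resid^2)

  # --- Dirichlet / Neumann ---
  fix_sel <- which(colloc$surface$face %in% fixed_faces())
  free_sel <- which(colloc$surface$face %in% free_faces())
  U_fix <- fw_s$u[fix_sel, , drop = FALSE]
  L_dir <- mean(U_fix^2)

  lay_s <- classify_point(colloc$surface$points[free_sel, , drop = FALSE], geom)
  eps_s <- grad_to_strain(fw_s$grad)[free_sel, , drop = FALSE]
  sig_s <- matrix(0, length(free_sel), 6)
  sc <- which(lay_s == "cover"); sb <- which(lay_s == "body")
  sig_s[sc, ] <- eps_s[sc, , drop = FALSE] %*% cd$Cc
  sig_s[sb, ] <- eps_s[sb, , drop = FALSE] %*% cd$Cb
  nrm_s <- colloc$surface$normal[free_sel, , drop = FALSE]
  tr_s <- .traction(sig_s, nrm_s) * t_scale
  L_neu <- mean(tr_s^2)

  # --- interface (continuous network: displacement jump identically 0) ---
  eps_f <- grad_to_strain(fw_f$grad)
  dsig <- eps_f %*% (cd$Cb - cd$Cc)
  nrm_f <- colloc$interface$normal
  dtr <- .traction(dsig, nrm_f) * t_scale
  L_ifc <- mean(dtr^2)

  # --- data-driven terms ---
  L_eig <- ((lam - cd$lambda_true) / cd$lambda_true)^2
  u_pred_vec <- as.numeric(fw_s$u)
  np <- sqrt(sum(u_pred_vec^2)); nt <- sqrt(sum(cd$u_true_vec^2))
  if (np == 0 || nt == 0) stop("degenerate-field error: zero-norm mode")
  cosv <- sum(u_pred_vec * cd$u_true_vec) / (np * nt)
  L_cos <- 1 - cosv

  terms <- c(pde = L_pde, dirichlet = L_dir, neumann = L_neu,
             interface = L_ifc, eigenvalue = L_eig, cosine = L_cos)
  total <- sum(weights * terms)
  out <- list(terms = terms, total = total, lambda_rq = lam)
  if (!want_grad) return(out)

  # ---------- adjoints ----------
  w <- weights
  # lambda adjoint: eigenvalue loss + (unless detached) the rho*lam*u term
  lam_bar <- w[["eigenvalue"]] * 2 * (lam - cd$lambda_true) / cd$lambda_true^2
  r_bar <- w[["pde"]] * 2 * resid / length(resid)
  if (!detach_lambda) {
    lam_bar <- lam_bar + sum(r_bar * (scale * rho * fw_i$u))
  }
  V_bar <- lam_bar / T_int
  T_bar <- -lam_bar * lam / T_int

  # interior adjoints
  ubar_i <- T_bar * 2 * rho * wq * fw_i$u + r_bar * (scale * rho * lam)
  epsbar_i <- (2 * V_bar * wq) * Ceps
  gradbar_i <- .strain_adjoint_to_grad(epsbar_i)
  d2bar <- matrix(0, Ni, 18)
  d2bar[idx_c, ] <- (scale * r_bar[idx_c, , drop = FALSE]) %*% t(cd$coef_c)
  d2bar[idx_b, ] <- (scale * r_bar[idx_b, , drop = FALSE]) %*% t(cd$coef_b)
  hessbar_i <- array(0, c(Ni, 3, 6))
  for (k in 1:3) for (pr in 1:6) hessbar_i[, k, pr] <- d2bar[, (k - 1) * 6 + pr]

  # surface adjoints
  Ns <- nrow(colloc$surface$points)
  ubar_s <- matrix(0, Ns, 3)
  ubar_s[fix_sel, ] <- w[["dirichlet"]] * 2 * U_fix / length(U_fix)
  cos_grad <- -(cd$u_true_vec / (np * nt) - cosv * u_pred_vec / np^2)
  ubar_s <- ubar_s + w[["cosine"]] * matrix(cos_grad, Ns, 3)

  trbar <- w[["neumann"]] * 2 * tr_s / length(tr_s)
  sigbar_s <- .traction_adjoint_to_stress(trbar, nrm_s) * t_scale
  epsbar_s_free <- matrix(0, length(free_sel), 6)
  epsbar_s_free[sc, ] <- sigbar_s[sc, , drop = FALSE] %*% cd$Cc
  epsbar_s_free[sb, ] <- sigbar_s[sb, , drop = FALSE] %*% cd$Cb
  epsbar_s <- matrix(0, Ns, 6)
  epsbar_s[free_sel, ] <- epsbar_s_free
  gradbar_s <- .strain_adjoint_to_grad(epsbar_s)

  # interface adjoints
  dtrbar <- w[["interface"]] * 2 * dtr / length(dtr)
  dsigbar <- .traction_adjoint_to_stress(dtrbar, nrm_f) * t_scale
  epsbar_f <- dsigbar %*% (cd$Cb - cd$Cc)
  gradbar_f <- .strain_adjoint_to_grad(epsbar_f)

  g <- .net_backward(net, fw_i$cache, ubar_i, gradbar_i, hessbar_i) +
    .net_backward(net, fw_s$cache, ubar_s, gradbar_s, NULL) +
    .net_backward(net, fw_f$cache, matrix(0, nrow(colloc$interface$points), 3),
                  gradbar_f, NULL)
  out$grad <- g
  out
}

# map an engineering-strain adjoint (N x 6) back to a gradient adjoint
.strain_adjoint_to_grad <- function(epsbar) {
  N <- nrow(epsbar)
  gb <- array(0, c(N, 3, 3))
  gb[, 1, 1] <- epsbar[, 1]
  gb[, 2, 2] <- epsbar[, 2]
  gb[, 3, 3] <- epsbar[, 3]
  gb[, 2, 3] <- epsbar[, 4]; gb[, 3, 2] <- epsbar[, 4]
  gb[, 1, 3] <- epsbar[, 5]; gb[, 3, 1] <- epsbar[, 5]
  gb[, 1, 2] <- epsbar[, 6]; gb[, 2, 1] <- epsbar[, 6]
  gb
}

# map a traction adjoint (N x 3) to a Voigt stress adjoint (N x 6)
.traction_adjoint_to_stress <- function(trbar, normal) {
  cbind(
    trbar[, 1] * normal[, 1],
    trbar[, 2] * normal[, 2],
    trbar[, 3] * normal[, 3],
    trbar[, 2] * normal[, 3] + trbar[, 3] * normal[, 2],
    trbar[, 1] * normal[, 3] + trbar[, 3] * normal[, 1],
    trbar[, 1] * normal[, 2] + trbar[, 2] * normal[, 1]
  )
}

#' Train the displacement network for one mode
#'
#' Full-batch Adam minimization of the composite loss summed over the training
#' configurations of the dataset: for every configuration and epoch the
#' network field is evaluated on a shared collocation set, the
#' Rayleigh-quotient eigenvalue is computed from the field itself (gradients
#' flow through both energies unless `detach_lambda`), and the PDE, boundary,
#' interface, eigenvalue and cosine penalties are accumulated.
#'
#' @param dataset A [generate_dataset()] result (mode-matched or raw).
#' @param config A [train_config()].
#' @param verbose Print progress every 10% of epochs.
#' @return Object of class `vf_training`: `net` (trained), `history`
#'   (data.frame of per-epoch loss terms summed over configurations),
#'   `config`, `colloc`, and `train_ids`.
#' @export
train_mode <- function(dataset, config = train_config(), verbose = FALSE) {
  mode_index <- config$mode_index
  if (mode_index > dataset$n_modes) {
    stop("dataset does not contain mode ", mode_index)
  }
  geom <- dataset$geom
  colloc <- sample_collocation(geom, config$n_interior, config$n_per_face,
                               config$n_interface, seed = config$seed_sample)
  train_ids <- which(dataset$grid$split == "train")
  if (length(train_ids) == 0) stop("no training configurations in the dataset")
  cds <- lapply(train_ids, .prep_config_data, dataset = dataset,
                mode_index = mode_index, colloc = colloc)
  net <- init_network(config$network, geom, dataset$grid[train_ids, ],
                      seed = config$seed_init)
  theta <- .net_pack(net)
  m1 <- numeric(length(theta)); m2 <- numeric(length(theta))
  b1 <- config$betas[1]; b2 <- config$betas[2]
  eps_adam <- 1e-8
  term_names <- c("pde", "dirichlet", "neumann", "interface", "eigenvalue",
                  "cosine")
  history <- matrix(NA_real_, config$epochs, length(term_names) + 2)
  colnames(history) <- c("epoch", term_names, "total")
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    if (config$resample_every > 0L && ep > 1L &&
        (ep - 1L) %% config$resample_every == 0L) {
      colloc <- sample_collocation(geom, config$n_interior, config$n_per_face,
                                   config$n_interface,
                                   seed = config$seed_sample + ep)
      cds <- lapply(train_ids, .prep_config_data, dataset = dataset,
                    mode_index = mode_index, colloc = colloc)
    }
    gsum <- numeric(length(theta))
    tsum <- numeric(length(term_names)); names(tsum) <- term_names
    total <- 0
    for (cd in cds) {
      res <- .config_loss_grad(net, cd, colloc, config$weights,
                               detach_lambda = config$detach_lambda)
      gsum <- gsum + res$grad
      tsum <- tsum + res$terms
      total <- total + res$total
    }
    if (!is.finite(total) || any(!is.finite(gsum))) {
      stop("non-finite loss at epoch ", ep,
           "; aborting (last finite total: ",
           if (ep > 1) signif(history[ep - 1, "total"], 6) else "none", ")")
    }
    step <- step + 1L
    lr_t <- if (config$lr_schedule == "cosine") {
      config$lr_min + (config$lr - config$lr_min) *
        (1 + cos(pi * (ep - 1) / config$epochs)) / 2
    } else config$lr
    m1 <- b1 * m1 + (1 - b1) * gsum
    m2 <- b2 * m2 + (1 - b2) * gsum^2
    mhat <- m1 / (1 - b1^step)
    vhat <- m2 / (1 - b2^step)
    theta <- theta - lr_t * mhat / (sqrt(vhat) + eps_adam)
    net <- .net_unpack(net, theta)
    history[ep, ] <- c(ep, tsum, total)
    if (verbose && (ep %% max(1L, config$epochs %/% 10L) == 0L)) {
      message(sprintf("epoch %d/%d  total = %.5g  (cos %.4f, eig %.4g)",
                      ep, config$epochs, total, tsum[["cosine"]],
                      tsum[["eigenvalue"]]))
    }
  }
  structure(
    list(net = net, history = as.data.frame(history), config = config,
         colloc = colloc, train_ids = train_ids,
         mode_index = mode_index),
    class = "vf_training"
  )
}

#' Evaluate a trained network (or any field provider) against the dataset
#'
#' For every configuration of the chosen split, draws a fresh seeded
#' collocation set, computes the Rayleigh-quotient eigenfrequency of the
#' predicted field, and the absolute cosine correlation between predicted and
#' reference displacements on surface points.
#'
#' @param predictor A trained `vf_training`, a `vf_network`, or a function
#'   `function(material) -> field evaluator` (e.g. for oracle checks).
#' @param dataset The reference dataset.
#' @param mode_index Mode to evaluate.
#' @param split `"validation"` (default), `"train"` or `"all"`.
#' @param n_points Interior points of the evaluation collocation draw.
#' @param seed Seed of the evaluation draw.
#' @return List with `records` (data.frame: config, f_true, f_pred, relative
#'   error %, cosine) and `summary` (mean relative error %, mean cosine).
#' @export
evaluate_mode <- function(predictor, dataset, mode_index,
                          split = "validation", n_points = 4000L,
                          seed = 99L) {
  ids <- if (split == "all") seq_len(nrow(dataset$grid)) else
    which(dataset$grid$split == split)
  if (length(ids) == 0) stop("empty split: ", split)
  make_field <- if (inherits(predictor, "vf_training")) {
    function(mat) field_from_network(predictor$net, mat)
  } else if (inherits(predictor, "vf_network")) {
    function(mat) field_from_network(predictor, mat)
  } else if (is.function(predictor)) {
    predictor
  } else stop("unsupported predictor")
  colloc <- sample_collocation(dataset$geom, n_points,
                               max(50L, n_points %/% 8L), 50L, seed = seed)
  recs <- lapply(ids, function(ci) {
    grid <- dataset$grid
    mat <- vf_material(grid$Et[ci], grid$gap_body[ci], grid$gap_cover[ci],
                       density = if ("density" %in% names(grid)) grid$density[ci] else 1030)
    Cb <- build_layer_elasticity(mat$Et, mat$gap_body, dataset$aux, "body")$C_voigt
    Cc <- build_layer_elasticity(mat$Et, mat$gap_cover, dataset$aux, "cover")$C_voigt
    field <- make_field(mat)
    rq <- rayleigh_quotient(field, Cb, Cc, mat$density, colloc)
    f_pred <- sqrt(rq$lambda_rq) / (2 * pi)
    f_true <- dataset$frequency_hz[ci, mode_index]
    u_pred <- as.numeric(field(colloc$surface$points, deriv = 0L)$u)
    ref_field <- field_from_fem(dataset$mesh, dataset$modes[[ci]][, mode_index])
    u_ref <- as.numeric(ref_field(colloc$surface$points, deriv = 0L)$u)
    cosv <- abs(sum(u_pred * u_ref)) /
      (sqrt(sum(u_pred^2)) * sqrt(sum(u_ref^2)))
    data.frame(
      config_id = grid$config_id[ci], split = grid$split[ci],
      mode = mode_index, f_true_hz = f_true, f_pred_hz = f_pred,
      rel_error_pct = 100 * abs(f_pred - f_true) / f_true,
      cosine = cosv, stringsAsFactors = FALSE
    )
  })
  records <- do.call(rbind, recs)
  list(
    records = records,
    summary = c(mean_rel_error_pct = mean(records$rel_error_pct),
                mean_cosine = mean(records$cosine))
  )
}

#' Per-mode evaluation and reference-mode stability reports
#'
#' Builds a per-mode validation report (one row per evaluated configuration
#' plus split means) and the cross-configuration cosine statistics of the
#' reference modes over the training split.
#'
#' @param dataset The reference dataset.
#' @param eval_results Named list: mode index (as character) -> result of
#'   [evaluate_mode()].
#' @param modes Mode indices for the reference-stability table; defaults to
#'   all dataset modes.
#' @return List with `table1` (data.frame of per-config records and means) and
#'   `table2` (data.frame: mode, median and mean cross-configuration cosine;
#'   NA when fewer than two training configurations exist).
#' @export
report_tables <- function(dataset, eval_results = list(),
                          modes = seq_len(dataset$n_modes)) {
  table1 <- NULL
  if (length(eval_results)) {
    rows <- lapply(eval_results, function(er) er$records)
    table1 <- do.call(rbind, rows)
    means <- do.call(rbind, lapply(eval_results, function(er) {
      data.frame(mode = er$records$mode[1],
                 mean_rel_error_pct = er$summary[["mean_rel_error_pct"]],
                 mean_cosine = er$summary[["mean_cosine"]])
    }))
    attr(table1, "means") <- means
  }
  n_train <- sum(dataset$grid$split == "train")
  table2 <- do.call(rbind, lapply(modes, function(k) {
    if (n_train < 2) {
      data.frame(mode = k, median_cosine = NA_real_, mean_cosine = NA_real_,
                 n_pairs = 0L)
    } else {
      st <- cross_config_cosine_stats(dataset, k, split = "train")
      data.frame(mode = k, median_cosine = st$median, mean_cosine = st$mean,
                 n_pairs = st$n_pairs)
    }
  }))
  list(table1 = table1, table2 = table2)
}
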
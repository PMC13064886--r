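test_that("fused loss gradient matches finite differences of the composite loss", {
  ds <- fix_small_dataset()
  colloc <- sample_collocation(ds$geom, 80, 12, 10, seed = 19)
  cd <- vfpinn:::.prep_config_data(ds, 1, 1, colloc)
  net <- init_network(network_spec("custom", width = 8, depth = 2, omega0 = 5,
                                   encoder_width = 4),
                      ds$geom, ds$grid, seed = 20)
  w <- default_loss_weights()
  res <- vfpinn:::.config_loss_grad(net, cd, colloc, w)
  theta <- vfpinn:::.net_pack(net)
  set.seed(21)
  idx <- sample(length(theta), 30)
  h <- 1e-6
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    lp <- vfpinn:::.config_loss_grad(vfpinn:::.net_unpack(net, tp), cd, colloc,
                                     w, want_grad = FALSE)$total
    lm <- vfpinn:::.config_loss_grad(vfpinn:::.net_unpack(net, tm), cd, colloc,
                                     w, want_grad = FALSE)$total
    fd <- (lp - lm) / (2 * h)
    expect_lt(abs(res$grad[i] - fd),
              1e-5 * max(abs(fd), 1e-3))
  }
  # detaching the eigenvalue changes gradients but not the loss value
  det <- vfpinn:::.config_loss_grad(net, cd, colloc, w, detach_lambda = TRUE)
  expect_equal(det$total, res$total, tolerance = 1e-12)
  expect_gt(max(abs(det$grad - res$grad)), 0)
})

test_that("training reduces the composite loss on a one-configuration problem", {
  ds <- fix_small_dataset()
  one <- ds
  keep <- which(ds$grid$split == "train")[1]
  one$grid <- ds$grid[keep, , drop = FALSE]
  one$grid$split <- "train"
  one$modes <- ds$modes[keep]
  one$lambda <- ds$lambda[keep, , drop = FALSE]
  one$frequency_hz <- ds$frequency_hz[keep, , drop = FALSE]
  cfg <- train_config(mode_index = 1, epochs = 150, lr = 1e-3,
                      n_interior = 150, n_per_face = 20, n_interface = 15,
                      seed_init = 22, seed_sample = 23,
                      network = network_spec("custom", width = 16, depth = 2,
                                             omega0 = 5, encoder_width = 8))
  tr <- train_mode(one, cfg)
  expect_s3_class(tr, "vf_training")
  expect_equal(nrow(tr$history), 150)
  expect_lt(tr$history$total[150], tr$history$total[1])
  expect_true(all(is.finite(tr$history$total)))
})

test_that("training is deterministic under fixed seeds", {
  ds <- fix_small_dataset()
  cfg <- train_config(mode_index = 1, epochs = 5, lr = 1e-3,
                      n_interior = 100, n_per_face = 15, n_interface = 10,
                      seed_init = 24, seed_sample = 25,
                      network = network_spec("custom", width = 12, depth = 2,
                                             omega0 = 5, encoder_width = 6))
  a <- train_mode(ds, cfg)
  b <- train_mode(ds, cfg)
  expect_equal(a$history$total[1], b$history$total[1], tolerance = 1e-12)
  expect_equal(a$history$total[5], b$history$total[5], tolerance = 1e-12)
  expect_equal(vfpinn:::.net_pack(a$net), vfpinn:::.net_pack(b$net),
               tolerance = 1e-12)
})

test_that("training stays finite without eigenvalue supervision", {
  ds <- fix_small_dataset()
  w <- default_loss_weights()
  w["eigenvalue"] <- 0
  cfg <- train_config(mode_index = 1, epochs = 30, lr = 1e-3,
                      n_interior = 100, n_per_face = 15, n_interface = 10,
                      seed_init = 26, seed_sample = 27, weights = w,
                      network = network_spec("custom", width = 12, depth = 2,
                                             omega0 = 5, encoder_width = 6))
  tr <- train_mode(ds, cfg)
  expect_true(all(is.finite(tr$history$total)))
  expect_true(all(tr$history$eigenvalue * 0 == 0))
})

test_that("teacher-forcing with the exact reference modes evaluates nearly perfectly", {
  ds <- fix_small_dataset()
  oracle <- function(mat) {
    ci <- which(ds$grid$Et == mat$Et & ds$grid$gap_body == mat$gap_body &
                  ds$grid$gap_cover == mat$gap_cover)
    field_from_fem(ds$mesh, ds$modes[[ci]][, 1])
  }
  ev <- evaluate_mode(oracle, ds, 1, split = "all", n_points = 4000)
  expect_true(all(ev$records$rel_error_pct < 2))
  expect_true(all(ev$records$cosine > 0.999))
  expect_true(all(ev$records$f_pred_hz > 0))
  expect_true(all(ev$records$cosine <= 1 + 1e-12))
  expect_equal(ev$summary[["mean_rel_error_pct"]],
               mean(ev$records$rel_error_pct))
  expect_error(evaluate_mode(oracle, ds, 1, split = "nope"), "empty")
})

test_that("report tables assemble evaluation records and reference-mode stability", {
  ds <- fix_small_dataset()
  oracle <- function(mat) {
    ci <- which(ds$grid$config_id == sprintf("Et%g_Gb%g_Gc%g", mat$Et / 1e3,
                                             mat$gap_body / 1e3,
                                             mat$gap_cover / 1e3))
    field_from_fem(ds$mesh, ds$modes[[ci]][, 1])
  }
  ev <- evaluate_mode(oracle, ds, 1, split = "validation", n_points = 1000)
  rep <- report_tables(ds, list(`1` = ev), modes = 1:2)
  expect_equal(nrow(rep$table1), sum(ds$grid$split == "validation"))
  expect_equal(nrow(rep$table2), 2)
  expect_true(all(rep$table2$n_pairs == choose(7, 2)))
  # single training configuration: stability statistics are flagged n/a
  one <- ds
  one$grid$split <- c("train", rep("validation", 8))
  rep1 <- report_tables(one, modes = 1)
  expect_true(is.na(rep1$table2$median_cosine))
  expect_equal(rep1$table2$n_pairs, 0L)
})
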
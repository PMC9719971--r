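test_that("combined loss reproduces hand-computed values and limits", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)   # [[1,2],[3,4]] rowwise
  xh <- matrix(c(1, 3, 2, 0), 2, 2)
  l <- combined_loss(x, xh, y = 5, yhat = 3, task = "los")
  expect_equal(attr(l, "lr"), 2)     # sqrt(16/4)
  expect_equal(attr(l, "ls"), 2)
  expect_equal(as.numeric(l), 4)
  # perfect reconstruction and prediction
  expect_equal(as.numeric(combined_loss(x, x, y = 5, yhat = 5, task = "los")), 0)
  # fully masked batch: reconstruction contributes nothing
  l2 <- combined_loss(x, xh, y = 1, yhat = 0.5, task = "mortality",
                      mask = matrix(0, 2, 2), weights = c(1, 2))
  expect_equal(attr(l2, "lr"), 0)
  expect_equal(as.numeric(l2), 2 * (-log(0.5)))
})

test_that("R and compiled losses agree on random batches", {
  set.seed(2)
  p <- abxsc:::init_encoder_params(5, 3, 4, 3, seed = 1)
  p$wy <- rnorm(3)
  xs <- lapply(c(3, 5), function(T) matrix(rnorm(5 * T), 5, T))
  ts <- lapply(xs, function(x) x[1:3, , drop = FALSE] + rnorm(length(x[1:3, ])))
  ms <- lapply(ts, function(t) matrix(rbinom(length(t), 1, 0.8), nrow(t)))
  for (task in c(0L, 1L)) {
    y <- if (task == 1L) c(1, 0) else c(4, 7)
    res <- abxsc:::cpp_loss_grad(p, xs, ts, ms, y, task, 1, 1, FALSE)
    expect_equal(res$loss, res$lr + res$ls)
    # the supervised component recomputed through R-side encode + head
    zs <- sapply(xs, function(x) abxsc:::cpp_encode(p, x))
    yraw <- drop(crossprod(zs, p$wy)) + p$by
    ls_ref <- if (task == 0L) sqrt(mean((y - yraw)^2)) else {
      pr <- plogis(yraw)
      mean(-y * log(pr) - (1 - y) * log(1 - pr))
    }
    expect_equal(res$ls, ls_ref, tolerance = 1e-12)
  }
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  p <- abxsc:::init_encoder_params(4, 2, 3, 2, seed = 7)
  p$wy <- rnorm(2); p$by <- 0.3
  xs <- list(matrix(rnorm(12), 4, 3), matrix(rnorm(8), 4, 2))
  ts <- list(matrix(rnorm(6), 2, 3), matrix(rnorm(4), 2, 2))
  ms <- list(matrix(rbinom(6, 1, 0.7), 2, 3), matrix(1, 2, 2))
  for (task in c(0L, 1L)) {
    y <- if (task == 1L) c(1, 0) else c(2.5, -1)
    g <- abxsc:::cpp_loss_grad(p, xs, ts, ms, y, task, 1, 0.7, TRUE)$grads
    f <- function(pp) abxsc:::cpp_loss_grad(pp, xs, ts, ms, y, task, 1, 0.7,
                                            FALSE)$loss
    for (nm in names(p)) {
      n_chk <- min(5L, length(p[[nm]]))
      for (ii in seq_len(n_chk)) {
        eps <- 1e-5
        p1 <- p; p1[[nm]][ii] <- p1[[nm]][ii] + eps
        p2 <- p; p2[[nm]][ii] <- p2[[nm]][ii] - eps
        num <- (f(p1) - f(p2)) / (2 * eps)
        ana <- if (nm == "by") g$by else g[[nm]][ii]
        expect_equal(ana, num, tolerance = 1e-4,
                     label = paste("grad", nm, ii))
      }
    }
  }
})

test_that("encoder configuration is validated", {
  expect_error(encoder_config("los", num_layers = 2), "single-layer")
  expect_error(encoder_config("los", embedding_dim = 1))
  expect_error(encoder_config("survival"))
  expect_equal(encoder_config("los")$selection_metric, "rmse")
  expect_equal(encoder_config("mortality")$selection_metric, "auroc")
})

test_that("training records history, selects the epoch-best model, and is deterministic", {
  ds <- tiny_dataset()
  cfg <- encoder_config("los", embedding_dim = 6, hidden_size = 12,
                        epochs = 2, batch_size = 16, seed = 9)
  m <- tiny_model()
  expect_equal(nrow(m$history), 2L)
  expect_equal(m$best_metric, min(m$history$val_metric))
  expect_equal(m$best_epoch, which.min(m$history$val_metric))
  m2 <- train_autoencoder(ds, cfg)
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)
})

test_that("day embeddings are causal, shaped, and range-checked", {
  ds <- tiny_dataset()
  m <- tiny_model()
  sid <- names(ds$stays)[which(vapply(ds$stays, function(t) length(t$days),
                                      1L) >= 3)][1]
  tl <- ds$stays[[sid]]
  z <- encode_day(m, tl, 2)
  expect_length(z, m$config$embedding_dim)
  expect_true(all(is.finite(z)))
  # two stays identical through day t but divergent later embed identically
  tl2 <- tl
  tl2$features_norm[3, ] <- tl2$features_norm[3, ] + 5
  expect_identical(encode_day(m, tl2, 2), z)
  expect_false(identical(encode_day(m, tl2, 3), encode_day(m, tl, 3)))
  expect_error(encode_day(m, tl, length(tl$days) + 1L), "outside stay")
  expect_error(encode_day(m, tl, 0), "outside stay")
})

test_that("the linear head maps embeddings to outcome scale", {
  m <- tiny_model()
  E <- m$config$embedding_dim
  # zero embedding returns the (rescaled) bias
  expect_equal(head_predict(m, rep(0, E)),
               m$params$by * m$label_scale + m$label_center)
  expect_error(head_predict(m, rep(0, E + 1)), "dimension")
  # mortality head returns probabilities
  ds <- tiny_dataset()
  mm <- train_autoencoder(ds, encoder_config("mortality", embedding_dim = 6,
                                             hidden_size = 12, epochs = 1,
                                             batch_size = 16, seed = 5))
  set.seed(1)
  pr <- head_predict(mm, matrix(rnorm(6 * 20, sd = 3), 6, 20))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("save/load round-trips to bit-identical embeddings", {
  ds <- tiny_dataset()
  m <- tiny_model()
  f <- tempfile(fileext = ".rds")
  save_encoder(m, f)
  m2 <- load_encoder(f)
  tl <- ds$stays[[1]]
  expect_identical(encode_day(m2, tl, 1), encode_day(m, tl, 1))
  expect_identical(head_predict(m2, encode_day(m2, tl, 1)),
                   head_predict(m, encode_day(m, tl, 1)))
  unlink(f)
})

test_that("training reduces reconstruction loss below random initialisations", {
  co <- simulate_cohort(sim_config(n_stays = 60, missing_rate = 0,
                                   severity_noise_sd = 0.05, seed = 77))
  ds <- preprocess_cohort(co$events, co$abx, co$labels,
                          split = split_spec(seed = 78), quiet = TRUE)
  inp <- abxsc:::build_model_inputs(ds)
  lr_of <- function(params) {
    abxsc:::cpp_loss_grad(params, inp$xs, inp$targets, inp$masks,
                          rep(0, length(inp$xs)), 0L, 1, 0, FALSE)$lr
  }
  m <- train_autoencoder(ds, encoder_config("los", embedding_dim = 8,
                                            hidden_size = 16, epochs = 6,
                                            batch_size = 16, seed = 80,
                                            loss_weights = c(1, 0.2)))
  trained_lr <- lr_of(m$params)
  D_in <- nrow(inp$xs[[1]]); D_r <- nrow(inp$targets[[1]])
  untrained <- vapply(1:10, function(s) {
    lr_of(abxsc:::init_encoder_params(D_in, D_r, 16, 8, seed = 100 + s))
  }, numeric(1))
  expect_true(all(trained_lr < untrained))
})

test_that("the supervised head beats the mean-label baseline on learnable data", {
  co <- simulate_cohort(sim_config(n_stays = 400, seed = 55))
  ds <- preprocess_cohort(co$events, co$abx, co$labels,
                          split = split_spec(seed = 56), quiet = TRUE)
  m <- train_autoencoder(ds, encoder_config("los", embedding_dim = 16,
                                            hidden_size = 32, epochs = 8,
                                            seed = 57))
  val_labels <- vapply(ds$stays[ds$split$val], function(t) t$los_label, 1)
  train_labels <- vapply(ds$stays[ds$split$train], function(t) t$los_label, 1)
  baseline <- sqrt(mean((val_labels - mean(train_labels))^2))
  expect_lt(m$best_metric, baseline)
})

test_that("a separable mortality cohort yields high validation AUROC", {
  co <- simulate_cohort(sim_config(n_stays = 800, mortality_severity_coef = 3,
                                   mortality_frailty_coef = 1.5, seed = 42))
  ds <- preprocess_cohort(co$events, co$abx, co$labels,
                          split = split_spec(seed = 43), quiet = TRUE)
  m <- train_autoencoder(ds, encoder_config("mortality", embedding_dim = 16,
                                            hidden_size = 32, epochs = 8,
                                            seed = 44))
  expect_gt(m$best_metric, 0.85)
})
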
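#' Configuration of the supervised sequence autoencoder
#'
#' One model is trained per outcome task. The encoder is a single-layer
#' bi-directional LSTM; the concatenated final hidden states are projected to
#' the embedding, which feeds both a reversing LSTM decoder (reconstruction)
#' and a linear outcome head. Training minimises
#' `w_r * Lr + w_s * Ls`, where `Lr` is the RMSE over observed reconstruction
#' cells and `Ls` is the head's RMSE (LOS) or binary cross-entropy
#' (mortality). After each epoch the validation selection metric (RMSE for
#' LOS, AUROC for mortality) is evaluated and the epoch-best model is kept.
#'
#' @param task `"los"` or `"mortality"`.
#' @param embedding_dim embedding size (>= 2).
#' @param hidden_size LSTM hidden units per direction.
#' @param num_layers recurrent layers; only 1 is supported.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size (stays).
#' @param epochs training epochs (default 50).
#' @param loss_weights numeric `(w_r, w_s)`, both non-negative.
#' @param seed RNG seed for initialisation and batch shuffling.
#' @param selection_metric validation metric; defaults to `"rmse"` for LOS
#'   and `"auroc"` for mortality.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(task = c("los", "mortality"),
                           embedding_dim = 32L, hidden_size = 64L,
                           num_layers = 1L, learning_rate = 1e-3,
                           batch_size = 32L, epochs = 50L,
                           loss_weights = c(1, 1), seed = 1L,
                           selection_metric = NULL) {
  task <- match.arg(task)
  if (num_layers != 1L) {
    stop("only single-layer (per direction) recurrent encoders are supported")
  }
  stopifnot(embedding_dim >= 2, hidden_size >= 2, epochs >= 1,
            learning_rate > 0, batch_size >= 1,
            length(loss_weights) == 2L, all(loss_weights >= 0))
  if (is.null(selection_metric)) {
    selection_metric <- if (task == "los") "rmse" else "auroc"
  }
  structure(list(task = task, embedding_dim = as.integer(embedding_dim),
                 hidden_size = as.integer(hidden_size),
                 num_layers = 1L, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 loss_weights = as.numeric(loss_weights),
                 seed = as.integer(seed),
                 selection_metric = selection_metric),
            class = "encoder_config")
}

# Model input layout: [normalised features (D); missing indicators (D);
# antibiotic status; cumulative treatment length / 21; re-treatment flag].
# Age is one of the feature columns. Reconstruction targets the D feature
# channels on observed cells only.
build_input_matrix <- function(tl, max_days = 21) {
  Xf <- t(tl$features_norm)                   # D x T
  Mm <- t(tl$missing_mask)
  T_i <- ncol(Xf)
  extra <- rbind(abx = tl$abx_status,
                 cum = tl$cum_treatment_len / max_days,
                 retreat = rep(as.numeric(tl$retreatment), T_i))
  rbind(Xf, Mm, extra)
}

build_model_inputs <- function(dataset) {
  stays <- dataset$stays
  xs <- lapply(stays, build_input_matrix)
  targets <- lapply(stays, function(tl) t(tl$features_norm))
  masks <- lapply(stays, function(tl) 1 - t(tl$missing_mask))
  list(xs = xs, targets = targets, masks = masks,
       y_los = vapply(stays, function(tl) tl$los_label, numeric(1)),
       y_mort = vapply(stays, function(tl) as.numeric(tl$mortality_label),
                       numeric(1)),
       ids = names(stays))
}

init_encoder_params <- function(din, dr, H, E, seed) {
  with_seed(seed, {
    gl <- function(nr, nc) {
      matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
    }
    b4 <- function() {
      b <- rep(0, 4 * H)
      b[(H + 1):(2 * H)] <- 1  # forget-gate bias
      b
    }
    list(Wx_f = gl(4 * H, din), Wh_f = gl(4 * H, H), b_f = b4(),
         Wx_b = gl(4 * H, din), Wh_b = gl(4 * H, H), b_b = b4(),
         Wz = gl(E, 2 * H), bz = rep(0, E),
         Wx_d = gl(4 * H, E), Wh_d = gl(4 * H, H), b_d = b4(),
         Wo = gl(dr, H), bo = rep(0, dr),
         wy = rep(0, E), by = 0)
  })
}

#' Combined reconstruction + supervised loss
#'
#' Reference implementation of the training objective:
#' `w_r * Lr + w_s * Ls`, with `Lr` the RMSE between reconstruction and
#' input over observed (unmasked) cells and `Ls` the RMSE between label and
#' head output for the LOS task or the binary cross-entropy for mortality.
#'
#' @param x,xhat input and reconstruction: matrices (or lists of matrices)
#'   of identical shape, aligned in original time order.
#' @param y,yhat labels and head outputs (mortality: probabilities).
#' @param task `"los"` or `"mortality"`.
#' @param weights `(w_r, w_s)`.
#' @param mask optional 0/1 matrix (or list) marking cells that enter `Lr`
#'   (1 = observed); defaults to all cells.
#' @return scalar loss, with attributes `lr` and `ls`.
#' @export
combined_loss <- function(x, xhat, y, yhat, task = c("los", "mortality"),
                          weights = c(1, 1), mask = NULL) {
  task <- match.arg(task)
  if (is.matrix(x)) x <- list(x)
  if (is.matrix(xhat)) xhat <- list(xhat)
  if (!is.null(mask) && is.matrix(mask)) mask <- list(mask)
  if (is.null(mask)) mask <- lapply(x, function(m) array(1, dim(m)))
  sse <- 0; nobs <- 0
  for (i in seq_along(x)) {
    r <- (x[[i]] - xhat[[i]]) * mask[[i]]
    sse <- sse + sum(r^2)
    nobs <- nobs + sum(mask[[i]])
  }
  lr <- if (nobs > 0) sqrt(sse / nobs) else 0
  ls <- if (task == "los") {
    sqrt(mean((y - yhat)^2))
  } else {
    p <- pmin(1 - 1e-7, pmax(1e-7, yhat))
    mean(-y * log(p) - (1 - y) * log(1 - p))
  }
  if (!is.finite(lr) || !is.finite(ls)) {
    stop("non-finite loss (Lr=", lr, ", Ls=", ls, ")")
  }
  structure(weights[1] * lr + weights[2] * ls, lr = lr, ls = ls)
}

#' Train a task-specific supervised sequence autoencoder
#'
#' Trains on the dataset's training stays (the oversampled mortality index
#' for the mortality task, the raw index for LOS), evaluating the selection
#' metric on the validation stays after every epoch and returning the
#' epoch-best model.
#'
#' @param dataset an `abx_dataset` from [preprocess_cohort()].
#' @param config an [encoder_config()].
#' @param quiet suppress the per-epoch log line.
#' @return an `abx_encoder`: parameters, config, per-epoch history
#'   (`epoch, loss, lr, ls, val_metric`), `best_epoch`, and the frozen
#'   feature/stats reference.
#' @export
train_autoencoder <- function(dataset, config, quiet = TRUE) {
  stopifnot(inherits(dataset, "abx_dataset"), inherits(config, "encoder_config"))
  inp <- build_model_inputs(dataset)
  train_ids <- if (config$task == "mortality") dataset$mortality_index
               else dataset$split$train
  val_ids <- dataset$split$val
  if (length(val_ids) == 0L) stop("empty validation set")
  y_all <- if (config$task == "los") inp$y_los else inp$y_mort
  names(y_all) <- inp$ids
  task_code <- if (config$task == "los") 0L else 1L
  # the LOS label is standardised (training-set stats) inside the supervised
  # loss so Ls and the reconstruction RMSE share a comparable scale; the
  # head's day-scale output is recovered through the stored transform
  if (config$task == "los") {
    label_center <- mean(y_all[dataset$split$train])
    label_scale <- sd(y_all[dataset$split$train])
    if (!is.finite(label_scale) || label_scale == 0) label_scale <- 1
    y_all <- (y_all - label_center) / label_scale
  } else {
    label_center <- 0; label_scale <- 1
  }

  D_in <- nrow(inp$xs[[1L]])
  D_r <- nrow(inp$targets[[1L]])
  params <- init_encoder_params(D_in, D_r, config$hidden_size,
                                config$embedding_dim, config$seed)
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  wr <- config$loss_weights[1L]; ws <- config$loss_weights[2L]

  val_xs <- inp$xs[val_ids]
  val_y <- y_all[val_ids]

  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                        ls = numeric(), val_metric = numeric())
  best <- NULL; best_metric <- NA_real_; best_epoch <- NA_integer_
  better <- if (config$selection_metric == "rmse") {
    function(a, b) is.na(b) || a < b
  } else {
    function(a, b) is.na(b) || a > b
  }

  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(train_ids)
      nb <- ceiling(length(ord) / config$batch_size)
      ep_loss <- ep_lr <- ep_ls <- 0
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * config$batch_size + 1L):
                     min(bi * config$batch_size, length(ord))]
        res <- cpp_loss_grad(params, inp$xs[idx], inp$targets[idx],
                             inp$masks[idx], unname(y_all[idx]), task_code,
                             wr, ws, TRUE)
        g <- res$grads
        step <- step + 1L
        for (nm in names(params)) {
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g[[nm]]
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - b1^step)
          vhat <- adam_v[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
        w <- length(idx) / length(ord)
        ep_loss <- ep_loss + res$loss * w
        ep_lr <- ep_lr + res$lr * w
        ep_ls <- ep_ls + res$ls * w
      }
      zv <- vapply(val_xs, function(x) {
        drop(crossprod(params$wy, cpp_encode(params, x))) + params$by
      }, numeric(1))
      vm <- if (config$task == "los") {
        sqrt(mean((val_y - zv)^2)) * label_scale  # day scale
      } else {
        auroc(val_y, plogis(zv))
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = ep_loss, lr = ep_lr,
                                  ls = ep_ls, val_metric = vm))
      if (!quiet) {
        message(sprintf("epoch %d: loss %.4f (Lr %.4f, Ls %.4f), val %s %.4f",
                        ep, ep_loss, ep_lr, ep_ls, config$selection_metric, vm))
      }
      if (better(vm, best_metric)) {
        best_metric <- vm; best_epoch <- ep
        best <- params
      }
    }
  })

  model <- list(params = best, config = config, history = history,
                best_epoch = best_epoch, best_metric = best_metric,
                feature_names = dataset$feature_names,
                stats = dataset$stats,
                label_center = label_center, label_scale = label_scale,
                input_dim = D_in, recon_dim = D_r)
  class(model) <- "abx_encoder"
  model
}

#' @export
print.abx_encoder <- function(x, ...) {
  cat("<abx_encoder> task=", x$config$task,
      " H=", x$config$hidden_size, " E=", x$config$embedding_dim,
      " best epoch ", x$best_epoch, " (", x$config$selection_metric,
      " = ", signif(x$best_metric, 4), ")\n", sep = "")
  invisible(x)
}

#' Embed one patient-day
#'
#' Computes the embedding of `stay` at day `t` from days `1..t` only (the
#' representation "considers the patient's past"; later days cannot leak in).
#'
#' @param model an `abx_encoder`.
#' @param stay a `stay_timeline` (normalised, from an `abx_dataset`).
#' @param day day index `1 <= t <= T_i`.
#' @return numeric embedding vector of length `embedding_dim`.
#' @export
encode_day <- function(model, stay, day) {
  stopifnot(inherits(model, "abx_encoder"))
  X <- build_input_matrix(stay)
  if (day < 1 || day > ncol(X)) {
    stop("day ", day, " outside stay of length ", ncol(X), call. = FALSE)
  }
  drop(cpp_encode_prefixes(model$params, X, day))
}

#' Predict the outcome from embeddings with the linear head
#'
#' @param model an `abx_encoder`.
#' @param z embedding vector, or matrix with embeddings in columns.
#' @return numeric predictions; probabilities in `[0, 1]` for mortality.
#' @export
head_predict <- function(model, z) {
  stopifnot(inherits(model, "abx_encoder"))
  if (is.vector(z)) z <- matrix(z, ncol = 1L)
  if (nrow(z) != length(model$params$wy)) {
    stop("embedding dimension ", nrow(z), " does not match model (",
         length(model$params$wy), ")", call. = FALSE)
  }
  out <- drop(crossprod(z, model$params$wy)) + model$params$by
  if (model$config$task == "mortality") plogis(out)
  else out * model$label_scale + model$label_center
}

#' Save / load a trained encoder
#'
#' Round-trips are bit-identical: a reloaded model produces exactly the same
#' embeddings and predictions.
#'
#' @param model an `abx_encoder`.
#' @param path file path.
#' @return `load_encoder` returns the model; `save_encoder` the path,
#'   invisibly.
#' @export
save_encoder <- function(model, path) {
  stopifnot(inherits(model, "abx_encoder"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "abx_encoder"))
  model
}
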
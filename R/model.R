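# The compact dense regressor.
#
# The corrector is a fully connected network small enough for a
# microcontroller: at most 100 trainable parameters, ReLU hidden layers,
# linear output. Because no deep-learning runtime is needed for networks
# this size, the forward pass, backpropagation, Adam optimizer, Glorot
# initialization, L2 kernel regularization and early stopping are
# implemented here directly with matrix operations; this also keeps the
# arithmetic identical to the streaming emulation.

#' Architecture of the compact dense regressor
#'
#' @param m Heart-rate window size.
#' @param k Acceleration window count; the input dimension is `m + 3k`.
#' @param hidden_units Integer vector of hidden-layer widths (possibly
#'   empty for a single linear layer). All hidden layers use ReLU; the
#'   single output unit is linear.
#' @return An object of class `hr_model_spec`.
#' @export
#' @examples
#' count_parameters(model_spec(5, 3, c(5, 3)))
model_spec <- function(m, k, hidden_units = integer()) {
  m <- check_count(m, "m"); k <- check_count(k, "k")
  if (length(hidden_units) > 0) {
    hidden_units <- vapply(seq_along(hidden_units), function(i) {
      check_count(hidden_units[i], sprintf("hidden_units[%d]", i))
    }, integer(1))
  }
  structure(
    list(m = m, k = k, hidden_units = as.integer(hidden_units),
         input_dim = m + 3L * k, output_dim = 1L),
    class = "hr_model_spec"
  )
}

#' @export
print.hr_model_spec <- function(x, ...) {
  cat(sprintf("<hr_model_spec> m=%d k=%d input=%d hidden=[%s] -> 1 (%d parameters)\n",
              x$m, x$k, x$input_dim,
              paste(x$hidden_units, collapse = ","),
              count_parameters(x)))
  invisible(x)
}

layer_dims <- function(spec) {
  c(spec$input_dim, spec$hidden_units, spec$output_dim)
}

#' Count the trainable parameters of a spec
#'
#' Each dense layer from `d_in` to `d_out` units contributes
#' `(d_in + 1) * d_out` parameters (kernel plus bias).
#'
#' @param spec An [model_spec()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  dims <- layer_dims(spec)
  sum((dims[-length(dims)] + 1L) * dims[-1L])
}

#' Training configuration
#'
#' Defaults follow the training recipe the corrector was developed with:
#' Adam with starting learning rate 0.001, batch size 16, L2 factor 0.01 on
#' kernels only, and a 70/10/20 train/validation/test split. The epoch
#' budget uses early stopping on validation MAE with best-weight restore.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param l2_factor L2 penalty coefficient applied to kernels (not biases).
#' @param max_epochs Upper bound on training epochs.
#' @param patience Epochs without validation-MAE improvement before
#'   stopping.
#' @param seed Seed controlling initialization and minibatch shuffling.
#' @param split Train/validation/test fractions, summing to 1.
#' @return A list of class `hr_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 16,
                         l2_factor = 0.01, max_epochs = 500, patience = 50,
                         seed = 0, split = c(0.7, 0.1, 0.2)) {
  check_scalar_number(learning_rate, "learning_rate", min = 0, strict = TRUE)
  batch_size <- check_count(batch_size, "batch_size")
  check_scalar_number(l2_factor, "l2_factor", min = 0)
  max_epochs <- check_count(max_epochs, "max_epochs")
  patience <- check_count(patience, "patience", min = 0L)
  if (length(split) != 3L || any(split <= 0) ||
      abs(sum(split) - 1) > 1e-8) {
    abort("`split` must be three positive fractions summing to 1.",
          class = "frugalhr_parameter_error")
  }
  structure(
    list(learning_rate = learning_rate, batch_size = batch_size,
         l2_factor = l2_factor, max_epochs = max_epochs,
         patience = patience, seed = as.integer(seed),
         split = as.numeric(split)),
    class = "hr_train_config"
  )
}

# Glorot-uniform kernels, zero biases. The caller seeds the output bias
# with the training-target mean so optimization starts at a sensible
# prediction scale instead of crawling from zero to ~90 BPM.
init_layers <- function(spec) {
  dims <- layer_dims(spec)
  lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]; fan_out <- dims[l + 1L]
    limit <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(runif(fan_in * fan_out, -limit, limit),
                    nrow = fan_in, ncol = fan_out),
         b = numeric(fan_out))
  })
}

#' Forward pass of the dense regressor
#'
#' Applies the network to already-normalized feature vectors: ReLU
#' (`max(0, x)`) on every hidden layer, linear output.
#'
#' @param model An `hr_model` (or any list with a `layers` element of
#'   kernel/bias pairs).
#' @param x Numeric vector of length `input_dim`, or a matrix with one row
#'   per input vector.
#' @return Numeric vector of predictions (BPM).
#' @export
nn_forward <- function(model, x) {
  layers <- model$layers
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(layers[[1]]$W)) {
    abort(sprintf("Input has %d features but the model expects %d.",
                  ncol(x), nrow(layers[[1]]$W)),
          class = "frugalhr_shape_error")
  }
  a <- x
  n_layers <- length(layers)
  for (l in seq_len(n_layers)) {
    z <- a %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(a), length(layers[[l]]$b), byrow = TRUE)
    a <- if (l < n_layers) pmax(z, 0) else z
  }
  as.numeric(a[, 1])
}

#' Leakage-free train/validation/test split of feature rows
#'
#' Splits each participant's record sequence into contiguous time blocks in
#' the order train, validation, test (earliest data trains, latest tests)
#' and assigns each feature row to the block that contains its entire
#' window span. Rows straddling a block boundary are discarded, so the
#' three sets share no underlying record. A participant whose record count
#' cannot populate all three blocks is assigned wholly to the training set
#' with a warning.
#'
#' @param rows Feature rows from [build_feature_rows()].
#' @param fractions Train/validation/test fractions summing to 1.
#' @return A list of class `hr_split` with tibbles `train`, `validation`,
#'   `test` and the count `n_discarded` of boundary-straddling rows.
#' @export
split_rows <- function(rows, fractions = c(0.7, 0.1, 0.2)) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three positive values summing to 1.",
          class = "frugalhr_parameter_error")
  }
  parts <- split(rows, rows$participant_id)
  assign_one <- function(d) {
    n <- max(d$.record)
    b1 <- floor(fractions[1] * n)
    b2 <- floor((fractions[1] + fractions[2]) * n)
    set <- rep(NA_character_, nrow(d))
    set[d$.record <= b1] <- "train"
    set[d$.first_record > b1 & d$.record <= b2] <- "validation"
    set[d$.first_record > b2] <- "test"
    if (!all(c("train", "validation", "test") %in% set)) {
      warn(sprintf(
        "Participant %s has too few rows for a three-way split; assigned wholly to train.",
        d$participant_id[1]))
      set <- rep("train", nrow(d))
    }
    d$.split <- set
    d
  }
  out <- dplyr::bind_rows(lapply(parts, assign_one))
  structure(
    list(train = dplyr::select(out[which(out$.split == "train"), ], -".split"),
         validation = dplyr::select(out[which(out$.split == "validation"), ], -".split"),
         test = dplyr::select(out[which(out$.split == "test"), ], -".split"),
         n_discarded = sum(is.na(out$.split))),
    class = "hr_split"
  )
}

# One epoch of minibatch Adam; returns updated state.
adam_epoch <- function(state, x, y, config, epoch) {
  n <- nrow(x)
  order <- sample.int(n)
  batches <- split(order, ceiling(seq_along(order) / config$batch_size))
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-7
  for (idx in batches) {
    xb <- x[idx, , drop = FALSE]
    yb <- y[idx]
    nb <- length(idx)
    layers <- state$layers
    n_layers <- length(layers)
    # Forward with cache.
    a_list <- vector("list", n_layers + 1L)
    z_list <- vector("list", n_layers)
    a_list[[1]] <- xb
    for (l in seq_len(n_layers)) {
      z <- a_list[[l]] %*% layers[[l]]$W +
        matrix(layers[[l]]$b, nb, length(layers[[l]]$b), byrow = TRUE)
      z_list[[l]] <- z
      a_list[[l + 1L]] <- if (l < n_layers) pmax(z, 0) else z
    }
    yhat <- a_list[[n_layers + 1L]][, 1]
    if (any(!is.finite(yhat))) {
      abort(sprintf("Training diverged (non-finite loss) at epoch %d.", epoch),
            class = "frugalhr_divergence_error", epoch = epoch)
    }
    # Backward: MSE loss + L2 on kernels.
    dz <- matrix(2 * (yhat - yb) / nb, ncol = 1)
    for (l in rev(seq_len(n_layers))) {
      dW <- crossprod(a_list[[l]], dz) + 2 * config$l2_factor * layers[[l]]$W
      db <- colSums(dz)
      if (l > 1L) {
        da <- dz %*% t(layers[[l]]$W)
        dz <- da * (z_list[[l - 1L]] > 0)
      }
      state$t_step <- if (l == n_layers) state$t_step + 1L else state$t_step
      # Adam moment updates.
      mW <- state$mom[[l]]$mW <- beta1 * state$mom[[l]]$mW + (1 - beta1) * dW
      vW <- state$mom[[l]]$vW <- beta2 * state$mom[[l]]$vW + (1 - beta2) * dW^2
      mb <- state$mom[[l]]$mb <- beta1 * state$mom[[l]]$mb + (1 - beta1) * db
      vb <- state$mom[[l]]$vb <- beta2 * state$mom[[l]]$vb + (1 - beta2) * db^2
      t_ <- state$t_step
      corr1 <- 1 - beta1^t_; corr2 <- 1 - beta2^t_
      state$layers[[l]]$W <- layers[[l]]$W -
        lr * (mW / corr1) / (sqrt(vW / corr2) + eps)
      state$layers[[l]]$b <- layers[[l]]$b -
        lr * (mb / corr1) / (sqrt(vb / corr2) + eps)
    }
  }
  state
}

#' Train the compact dense regressor
#'
#' Fits the network with minibatch Adam on the mean-squared-error loss plus
#' an L2 penalty on the kernels, tracking per-epoch train/validation MSE
#' and MAE. Training stops early when the validation MAE has not improved
#' for `patience` epochs and the weights of the best validation-MAE epoch
#' are restored. Fully deterministic for a fixed `config$seed`.
#'
#' @param spec A [model_spec()].
#' @param train_rows,val_rows Feature rows (unnormalized); normalization is
#'   fitted on `train_rows` and bundled with the model.
#' @param config A [train_config()].
#' @param normalization Optional pre-fitted `hr_norm_stats` (otherwise
#'   fitted from `train_rows`).
#' @return An object of class `hr_model`: layers (kernel/bias pairs), the
#'   spec, bundled normalization stats, training history tibble and the
#'   index of the restored best epoch.
#' @export
train_model <- function(spec, train_rows, val_rows, config = train_config(),
                        normalization = NULL) {
  stopifnot(inherits(spec, "hr_model_spec"))
  if (nrow(train_rows) == 0 || nrow(val_rows) == 0) {
    abort("Training and validation sets must be non-empty.",
          class = "frugalhr_empty_input_error")
  }
  norm <- normalization %||% fit_normalization(train_rows)
  cols <- feature_cols(spec$m, spec$k)
  x_tr <- unname(feature_matrix(apply_normalization(train_rows, norm), cols))
  x_va <- unname(feature_matrix(apply_normalization(val_rows, norm), cols))
  y_tr <- train_rows$target
  y_va <- val_rows$target
  if (ncol(x_tr) != spec$input_dim) {
    abort(sprintf("Rows provide %d features but the spec expects %d.",
                  ncol(x_tr), spec$input_dim),
          class = "frugalhr_shape_error")
  }

  set.seed(config$seed)
  state <- list(layers = init_layers(spec), t_step = 0L)
  # Output bias starts at the training-target mean: heart rates live far
  # from zero, and Adam steps are bounded by the learning rate, so a
  # zero-initialized output would spend most of the epoch budget climbing
  # to the right scale rather than learning to denoise.
  n_layers_total <- length(state$layers)
  state$layers[[n_layers_total]]$b[] <- mean(y_tr)
  state$mom <- lapply(state$layers, function(ly) {
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })

  history <- vector("list", config$max_epochs)
  best_mae <- Inf; best_layers <- state$layers; best_epoch <- 0L
  wait <- 0L
  model_tmp <- list(layers = state$layers)
  for (epoch in seq_len(config$max_epochs)) {
    state <- adam_epoch(state, x_tr, y_tr, config, epoch)
    model_tmp$layers <- state$layers
    p_tr <- nn_forward(model_tmp, x_tr)
    p_va <- nn_forward(model_tmp, x_va)
    history[[epoch]] <- tibble(
      epoch = epoch,
      train_mse = mse(y_tr, p_tr), train_mae = mae(y_tr, p_tr),
      val_mse = mse(y_va, p_va), val_mae = mae(y_va, p_va)
    )
    if (history[[epoch]]$val_mae < best_mae) {
      best_mae <- history[[epoch]]$val_mae
      best_layers <- state$layers
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience && config$patience > 0L) break
    }
  }

  structure(
    list(spec = spec, layers = best_layers, norm_stats = norm,
         config = config, history = dplyr::bind_rows(history),
         best_epoch = best_epoch,
         n_train = nrow(train_rows), n_val = nrow(val_rows)),
    class = "hr_model"
  )
}

#' Train with repeats and keep the best model by validation MAE
#'
#' Applies the repeat methodology of the tuning stage to a single
#' architecture: trains `repeats` models differing only in the
#' initialization/shuffling seed (`config$seed`, `config$seed + 1`, ...)
#' and returns the one with the lowest best-epoch validation MAE. This
#' guards the deployed model against an occasional poor initialization.
#'
#' @inheritParams train_model
#' @param repeats Number of training repeats.
#' @return The selected `hr_model`, with the per-repeat validation MAEs in
#'   attribute `"repeat_val_mae"`.
#' @export
train_repeats <- function(spec, train_rows, val_rows, config = train_config(),
                          repeats = 5, normalization = NULL) {
  repeats <- check_count(repeats, "repeats")
  fits <- vector("list", repeats)
  val_mae <- rep(NA_real_, repeats)
  for (r in seq_len(repeats)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    fits[[r]] <- tryCatch(
      train_model(spec, train_rows, val_rows, cfg,
                  normalization = normalization),
      frugalhr_divergence_error = function(e) NULL
    )
    if (!is.null(fits[[r]])) {
      val_mae[r] <- fits[[r]]$history$val_mae[fits[[r]]$best_epoch]
    }
  }
  if (all(is.na(val_mae))) {
    abort("All training repeats diverged.",
          class = "frugalhr_divergence_error")
  }
  best <- fits[[which.min(val_mae)]]
  attr(best, "repeat_val_mae") <- val_mae
  best
}

#' @export
print.hr_model <- function(x, ...) {
  h <- x$history[x$best_epoch, ]
  cat(sprintf(
    "<hr_model> m=%d k=%d hidden=[%s], %d parameters; best epoch %d/%d: train MAE %.3f, validation MAE %.3f BPM\n",
    x$spec$m, x$spec$k, paste(x$spec$hidden_units, collapse = ","),
    count_parameters(x$spec), x$best_epoch, nrow(x$history),
    h$train_mae, h$val_mae))
  invisible(x)
}

#' Predict corrected heart rates for feature rows
#'
#' Normalizes the feature columns with the model's bundled training-set
#' statistics and applies the forward pass.
#'
#' @param object An `hr_model`.
#' @param newdata Feature-row tibble (unnormalized) or a numeric matrix of
#'   already-normalized feature vectors.
#' @param ... Unused.
#' @return Numeric vector of corrected heart rates (BPM).
#' @export
predict.hr_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(nn_forward(object, newdata))
  x <- feature_matrix(apply_normalization(newdata, object$norm_stats),
                      object$norm_stats$features)
  nn_forward(object, x)
}

#' @export
tidy.hr_model <- function(x, ...) {
  out <- lapply(seq_along(x$layers), function(l) {
    W <- x$layers[[l]]$W
    b <- x$layers[[l]]$b
    dplyr::bind_rows(
      tibble(layer = l, parameter = "kernel",
             row = as.integer(row(W)), col = as.integer(col(W)),
             value = as.numeric(W)),
      tibble(layer = l, parameter = "bias",
             row = NA_integer_, col = seq_along(b), value = b)
    )
  })
  dplyr::bind_rows(out)
}

#' @export
glance.hr_model <- function(x, ...) {
  h <- x$history[x$best_epoch, ]
  tibble(
    n_parameters = count_parameters(x$spec),
    m = x$spec$m, k = x$spec$k,
    hidden = paste(x$spec$hidden_units, collapse = ","),
    epochs_trained = nrow(x$history), best_epoch = x$best_epoch,
    train_mae = h$train_mae, validation_mae = h$val_mae,
    train_mse = h$train_mse, validation_mse = h$val_mse,
    n_train = x$n_train, n_validation = x$n_val
  )
}

# Full-precision numeric serialization so weights round-trip bit-exactly.
num_to_chr <- function(x) sprintf("%.17g", x)
chr_to_num <- function(x) as.numeric(x)

#' Export and reload portable model weights
#'
#' `write_weights()` stores the layer kernels and biases, the architecture
#' and the bundled normalization statistics in a single JSON document;
#' doubles are serialized with 17 significant digits so a reload reproduces
#' predictions bit-exactly. `read_weights()` reverses it.
#'
#' @param model An `hr_model`.
#' @param path JSON file path.
#' @return `write_weights()`: `path`, invisibly. `read_weights()`: an
#'   `hr_model` (without training history).
#' @export
write_weights <- function(model, path) {
  stopifnot(inherits(model, "hr_model"))
  doc <- list(
    format_version = 1L,
    spec = list(m = model$spec$m, k = model$spec$k,
                hidden_units = model$spec$hidden_units),
    layers = lapply(model$layers, function(ly) {
      list(W = apply(ly$W, c(1, 2), num_to_chr), b = num_to_chr(ly$b),
           dim = dim(ly$W))
    }),
    normalization = list(
      mean = num_to_chr(model$norm_stats$mean),
      inv_std = num_to_chr(model$norm_stats$inv_std),
      constant = model$norm_stats$constant,
      features = model$norm_stats$features
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  doc <- jsonlite::read_json(path)
  spec <- model_spec(doc$spec$m, doc$spec$k,
                     as.integer(unlist(doc$spec$hidden_units)))
  layers <- lapply(doc$layers, function(ly) {
    d <- as.integer(unlist(ly$dim))
    # kernels are serialized row-major (array of rows)
    list(W = matrix(chr_to_num(unlist(ly$W)), nrow = d[1], ncol = d[2],
                    byrow = TRUE),
         b = chr_to_num(unlist(ly$b)))
  })
  feats <- as.character(unlist(doc$normalization$features))
  norm <- structure(
    list(mean = stats::setNames(chr_to_num(unlist(doc$normalization$mean)),
                                feats),
         inv_std = stats::setNames(
           chr_to_num(unlist(doc$normalization$inv_std)), feats),
         constant = stats::setNames(
           as.logical(unlist(doc$normalization$constant)), feats),
         features = feats),
    class = "hr_norm_stats")
  structure(
    list(spec = spec, layers = layers, norm_stats = norm, config = NULL,
         history = NULL, best_epoch = NA_integer_,
         n_train = NA_integer_, n_val = NA_integer_),
    class = "hr_model"
  )
}

#' Export weights as C-style static array initializers
#'
#' Writes the kernels, biases and normalization constants as text
#' `static const float` initializers, mirroring how the corrector is
#' embedded in device firmware. No compilation is attempted.
#'
#' @param model An `hr_model`.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
export_c_arrays <- function(model, path) {
  stopifnot(inherits(model, "hr_model"))
  fmt_vec <- function(v) paste(sprintf("%.9gf", v), collapse = ", ")
  lines <- c(sprintf("/* dense corrector m=%d k=%d hidden=[%s] */",
                     model$spec$m, model$spec$k,
                     paste(model$spec$hidden_units, collapse = ",")))
  for (l in seq_along(model$layers)) {
    W <- model$layers[[l]]$W
    lines <- c(lines,
               sprintf("static const float W%d[%d][%d] = {", l, nrow(W), ncol(W)),
               paste0("  {", apply(W, 1, fmt_vec), "},"),
               "};",
               sprintf("static const float b%d[%d] = {%s};", l,
                       length(model$layers[[l]]$b),
                       fmt_vec(model$layers[[l]]$b)))
  }
  lines <- c(lines,
             sprintf("static const float norm_mean[%d] = {%s};",
                     length(model$norm_stats$mean), fmt_vec(model$norm_stats$mean)),
             sprintf("static const float norm_inv_std[%d] = {%s};",
                     length(model$norm_stats$inv_std), fmt_vec(model$norm_stats$inv_std)))
  writeLines(lines, path)
  invisible(path)
}
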
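test_that("parameter counting matches the closed form and enumeration", {
  expect_identical(count_parameters(model_spec(5, 3, c(5, 3))), 97L)
  # single linear layer: d + 1
  expect_identical(count_parameters(model_spec(2, 1)), (2L + 3L) + 1L)
  # (4+1)*2 + (2+1)*1 = 13
  expect_identical(count_parameters(model_spec(1, 1, 2)), 13L)
  # closed form equals exhaustive enumeration of allocated weight entries
  # for every architecture on the default tuning grid
  grid <- enumerate_grid(tuning_grid())
  set.seed(104)
  for (i in sample(nrow(grid), 40)) {
    spec <- grid$spec[[i]]
    layers <- frugalhr:::init_layers(spec)
    n_alloc <- sum(vapply(layers, function(l) length(l$W) + length(l$b),
                          numeric(1)))
    expect_identical(count_parameters(spec), as.integer(n_alloc))
  }
})

test_that("the forward pass implements ReLU hidden layers, linear output", {
  al <- contiguous_aligned(20)
  rows <- build_feature_rows(al, 1, 1)
  spec <- model_spec(1, 1, 2)
  zero <- constant_model(spec, rows)
  x <- matrix(rnorm(8), 2, 4)
  expect_identical(nn_forward(zero, x), c(0, 0))

  # hand-crafted weights: unit passes x1 through ReLU, output sums
  m <- zero
  m$layers[[1]]$W[1, 1] <- 1
  m$layers[[2]]$W[1, 1] <- 1
  expect_identical(nn_forward(m, c(-1, 0, 0, 0)), 0)  # max(0, -1) = 0
  expect_identical(nn_forward(m, c(2, 0, 0, 0)), 2)   # max(0, 2) = 2
  expect_error(nn_forward(m, c(1, 2)), class = "frugalhr_shape_error")
})

test_that("the forward pass agrees with a loop-based oracle on random specs", {
  set.seed(105)
  for (rep in 1:100) {
    m <- sample(1:7, 1); k <- sample(1:5, 1)
    n_hidden <- sample(0:2, 1)
    hidden <- if (n_hidden > 0) sample(1:6, n_hidden, replace = TRUE) else integer()
    spec <- model_spec(m, k, hidden)
    layers <- frugalhr:::init_layers(spec)
    x <- rnorm(spec$input_dim, sd = 2)
    expect_equal(nn_forward(list(layers = layers), x),
                 forward_oracle(layers, x), tolerance = 1e-6)
  }
})

test_that("the split yields contiguous leakage-free blocks per participant", {
  al <- contiguous_aligned(100)
  r1 <- build_feature_rows(al, 1, 1)
  sp <- split_rows(r1)
  expect_identical(vapply(sp[c("train", "validation", "test")], nrow,
                          integer(1)),
                   c(train = 70L, validation = 10L, test = 20L))
  expect_identical(sp$n_discarded, 0L)

  # m = 5: four straddling rows discarded at each internal boundary
  r5 <- build_feature_rows(al, 5, 1)
  sp5 <- split_rows(r5)
  expect_identical(sp5$n_discarded, 8L)
  # the sets share no underlying record
  expect_lt(max(sp5$train$.record), min(sp5$validation$.first_record))
  expect_lt(max(sp5$validation$.record), min(sp5$test$.first_record))

  # two participants are split independently
  al2 <- dplyr::bind_rows(contiguous_aligned(100, "pA"),
                          contiguous_aligned(50, "pB"))
  sp2 <- split_rows(build_feature_rows(al2, 1, 1))
  for (p in c("pA", "pB")) {
    expect_true(p %in% sp2$train$participant_id)
    expect_true(p %in% sp2$test$participant_id)
  }

  # a participant too small for three blocks goes wholly to train
  al3 <- contiguous_aligned(6, "tiny")
  expect_warning(sp3 <- split_rows(build_feature_rows(al3, 5, 3)),
                 "too few rows")
  expect_identical(nrow(sp3$validation), 0L)
  expect_identical(nrow(sp3$train), 2L)
})

test_that("training is deterministic for a fixed seed", {
  al <- small_cohort_aligned(1)
  sp <- split_rows(build_feature_rows(al, 2, 1))
  cfg <- train_config(max_epochs = 15, patience = 15, seed = 3)
  f1 <- train_model(model_spec(2, 1, 3), sp$train, sp$validation, cfg)
  f2 <- train_model(model_spec(2, 1, 3), sp$train, sp$validation, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$layers, f2$layers)
})

test_that("training recovers a noiseless affine relation", {
  set.seed(106)
  hr <- rnorm(400, 100, 20)
  al <- contiguous_aligned(400, hr = hr)   # hr_ref = hr_device - 5
  rows <- build_feature_rows(al, 1, 1)
  sp <- split_rows(rows)
  # the affine map needs an output scale of tens of BPM; a larger step
  # size reaches it quickly on this noiseless task
  fit <- train_model(model_spec(1, 1, 3), sp$train, sp$validation,
                     train_config(learning_rate = 0.01, l2_factor = 0,
                                  max_epochs = 300, patience = 100, seed = 1))
  pred <- predict(fit, sp$test)
  expect_lt(mae(sp$test$target, pred), 0.5)
  # closed-form least squares on the same relation is the oracle bound
  ols <- lm(target ~ h1, data = sp$train)
  ols_mae <- mae(sp$test$target,
                 predict(ols, newdata = sp$test))
  expect_lt(ols_mae, 1e-9)         # the relation is exactly affine
  expect_lt(mae(sp$test$target, pred), 0.5)
})

test_that("validation error improves on a learnable task", {
  al <- small_cohort_aligned(1)
  sp <- split_rows(build_feature_rows(al, 2, 1))
  fit <- train_model(model_spec(2, 1, 3), sp$train, sp$validation,
                     train_config(max_epochs = 40, patience = 40, seed = 2))
  expect_lt(min(fit$history$val_mae), fit$history$val_mae[1])
  expect_identical(fit$best_epoch, which.min(fit$history$val_mae))
})

test_that("training with a runaway learning rate reports divergence", {
  al <- contiguous_aligned(60)
  sp <- split_rows(build_feature_rows(al, 1, 1))
  expect_error(
    train_model(model_spec(1, 1, 2), sp$train, sp$validation,
                train_config(learning_rate = 1e300, max_epochs = 30,
                             patience = 30, seed = 0)),
    class = "frugalhr_divergence_error")
})

test_that("repeat training keeps the best model by validation MAE", {
  al <- small_cohort_aligned(1)
  sp <- split_rows(build_feature_rows(al, 2, 1))
  cfg <- train_config(max_epochs = 10, patience = 10, seed = 5)
  best <- train_repeats(model_spec(2, 1, 2), sp$train, sp$validation, cfg,
                        repeats = 3)
  vals <- attr(best, "repeat_val_mae")
  expect_length(vals, 3)
  expect_equal(best$history$val_mae[best$best_epoch], min(vals))
})

test_that("weights round-trip through JSON bit-exactly", {
  al <- small_cohort_aligned(1)
  sp <- split_rows(build_feature_rows(al, 2, 2))
  fit <- train_model(model_spec(2, 2, c(3, 2)), sp$train, sp$validation,
                     train_config(max_epochs = 8, patience = 8, seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_weights(fit, path)
  back <- read_weights(path)
  expect_identical(back$layers, fit$layers)
  expect_identical(back$norm_stats$mean, fit$norm_stats$mean)
  x <- sp$test
  expect_identical(predict(back, x), predict(fit, x))
})

test_that("C-array export writes one initializer per layer", {
  al <- contiguous_aligned(30)
  rows <- build_feature_rows(al, 1, 1)
  m <- constant_model(model_spec(1, 1, 2), rows, fill = 0.5)
  path <- withr::local_tempfile(fileext = ".c")
  export_c_arrays(m, path)
  txt <- readLines(path)
  expect_length(grep("^static const float W", txt), 2)
  expect_length(grep("^static const float b", txt), 2)
  expect_true(any(grepl("norm_inv_std", txt)))
})

test_that("tidy and glance summarize a fitted model", {
  al <- small_cohort_aligned(1)
  sp <- split_rows(build_feature_rows(al, 1, 1))
  fit <- train_model(model_spec(1, 1, 2), sp$train, sp$validation,
                     train_config(max_epochs = 5, patience = 5, seed = 0))
  td <- tidy(fit)
  expect_identical(sum(!is.na(td$value)), 13L)  # 13 parameters
  expect_identical(nrow(td), 13L)
  gl <- glance(fit)
  expect_identical(gl$n_parameters, 13L)
  expect_identical(gl$best_epoch, fit$best_epoch)
  expect_true(gl$validation_mae > 0)
})
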
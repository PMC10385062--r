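test_that("grid enumeration yields exactly the advertised architectures", {
  grid <- enumerate_grid(tuning_grid())
  expect_identical(nrow(grid), 648L)
  key <- with(grid, paste(m, k, first_units, extra_layers, extra_units))
  expect_identical(anyDuplicated(key), 0L)
  # 4 * 3 * 6 * (1 + 4 + 4)
  expect_identical(nrow(grid), 4L * 3L * 6L * (1L + 4L + 4L))

  single <- tuning_grid(hr_window = 5, accel_window = 3,
                        first_hidden_units = 5,
                        additional_hidden_layers = 0,
                        additional_hidden_units = 1)
  expect_identical(nrow(enumerate_grid(single)), 1L)

  small <- tuning_grid(hr_window = c(1, 3), accel_window = 1,
                       first_hidden_units = 1:2,
                       additional_hidden_layers = 0:1,
                       additional_hidden_units = 1:2)
  expect_identical(nrow(enumerate_grid(small)), 12L)  # 2*1*2*(1+2)
})

test_that("grid cardinality matches brute-force enumeration", {
  count_oracle <- function(g) {
    seen <- character()
    for (m in g$hr_window) for (k in g$accel_window)
      for (f in g$first_hidden_units) for (L in g$additional_hidden_layers)
        for (u in g$additional_hidden_units) {
          key <- paste(m, k, f, L, if (L == 0) "-" else u)
          seen <- union(seen, key)
        }
    length(seen)
  }
  set.seed(107)
  for (rep in 1:10) {
    g <- tuning_grid(
      hr_window = sample(1:8, sample(1:3, 1)),
      accel_window = sample(1:5, sample(1:2, 1)),
      first_hidden_units = seq_len(sample(1:4, 1)),
      additional_hidden_layers = 0:sample(0:2, 1),
      additional_hidden_units = seq_len(sample(1:3, 1)))
    expect_identical(nrow(enumerate_grid(g)), as.integer(count_oracle(g)))
  }
})

test_that("every spec carries the hidden layout its grid cell describes", {
  grid <- enumerate_grid(tuning_grid(hr_window = 3, accel_window = 1,
                                     first_hidden_units = 2,
                                     additional_hidden_layers = 0:2,
                                     additional_hidden_units = 3))
  layouts <- lapply(grid$spec, function(s) s$hidden_units)
  expect_identical(layouts, list(2L, c(2L, 3L), c(2L, 3L, 3L)))
  expect_identical(grid$n_parameters,
                   vapply(grid$spec, count_parameters, integer(1)))
})

test_that("the grid search trains repeats-per-spec and sorts by validation MAE", {
  al <- small_cohort_aligned(1)
  specs <- enumerate_grid(tuning_grid(hr_window = c(1, 2), accel_window = 1,
                                      first_hidden_units = 2,
                                      additional_hidden_layers = 0,
                                      additional_hidden_units = 1))
  cfg <- train_config(max_epochs = 8, patience = 8, seed = 11)
  res <- run_grid_search(specs, al, cfg, repeats = 2)
  expect_identical(nrow(res), 2L)
  expect_true(all(lengths(res$repeat_train_mae) == 2))
  expect_true(all(lengths(res$repeat_val_mae) == 2))
  expect_false(is.unsorted(res$val_mae))
  expect_true(all(res$n_failed == 0L))

  # a duplicated spec reproduces identical aggregates under fixed seeds
  dup <- specs[c(1, 1), ]
  res_dup <- run_grid_search(dup, al, cfg, repeats = 2)
  expect_identical(res_dup$val_mae[1], res_dup$val_mae[2])
  expect_identical(res_dup$train_mae[1], res_dup$train_mae[2])
})

test_that("tuning never touches the test block", {
  al <- small_cohort_aligned(1)
  specs <- enumerate_grid(tuning_grid(hr_window = 1, accel_window = 1,
                                      first_hidden_units = 2,
                                      additional_hidden_layers = 0,
                                      additional_hidden_units = 1))
  cfg <- train_config(max_epochs = 6, patience = 6, seed = 9)
  res_before <- run_grid_search(specs, al, cfg, repeats = 1)

  # corrupt every record that can only reach the test block; results of
  # the search must be bit-identical
  n <- nrow(al)
  b2 <- floor(0.8 * n)
  al_corrupt <- al
  idx <- seq(b2 + 2, n)   # +1 past the boundary so no train/val window sees it
  al_corrupt$hr_device[idx] <- al_corrupt$hr_device[idx] + 1000
  al_corrupt$hr_ref[idx] <- 40
  res_after <- run_grid_search(specs, al_corrupt, cfg, repeats = 1)
  expect_identical(res_after$val_mae, res_before$val_mae)
  expect_identical(res_after$train_mae, res_before$train_mae)
})

test_that("final selection trades MAE tolerance for parameter count", {
  mk <- function(m, k, hidden, val) {
    tibble::tibble(m = m, k = k,
                   spec = list(model_spec(m, k, hidden)),
                   n_parameters = count_parameters(model_spec(m, k, hidden)),
                   val_mae = val)
  }
  # single result: itself
  one <- mk(5, 3, c(5, 3), 8.0)
  expect_identical(select_final(one)$hidden_units, c(5L, 3L))

  # equal MAE, 97 vs 150 parameters: the smaller model wins
  two <- dplyr::bind_rows(mk(5, 3, c(5, 3), 8.0),   # 97 params
                          mk(7, 5, c(5, 3), 8.0))   # 137 params
  picked <- select_final(two)
  expect_identical(count_parameters(picked), 97L)

  # tolerance 0: exact argmin even if larger
  three <- dplyr::bind_rows(mk(5, 3, c(5, 3), 8.2),
                            mk(7, 5, c(5, 3), 8.0))
  picked0 <- select_final(three, mae_tolerance = 0)
  expect_identical(picked0$m, 7L)
  # within tolerance 0.3 the smaller model is preferred again
  expect_identical(count_parameters(select_final(three, 0.3)), 97L)

  # ties on parameters break to fewer layers
  four <- dplyr::bind_rows(mk(1, 1, c(2, 2), 8.0),  # 19 params, 2 layers
                           mk(1, 1, 3, 8.0))        # 19 params, 1 layer
  expect_identical(length(select_final(four)$hidden_units), 1L)
})
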
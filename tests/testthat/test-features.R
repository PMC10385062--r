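test_that("acceleration magnitude is the Euclidean norm", {
  expect_identical(accel_magnitude(0, 0, 0), 0)
  expect_identical(accel_magnitude(3, 4, 0), 5)
  expect_identical(accel_magnitude(1, 2, 2), 3)
  expect_equal(accel_magnitude(c(3, 1), c(4, 2), c(0, 2)), c(5, 3))
  expect_error(accel_magnitude(NaN, 0, 0), class = "frugalhr_domain_error")
})

test_that("window summaries follow the sort-and-index conventions", {
  s <- summarize_window(5)
  expect_equal(unlist(s[c("med", "mx", "iqr")]), c(med = 5, mx = 5, iqr = 0))
  s <- summarize_window(c(1, 2, 3, 4, 5))
  expect_equal(unlist(s[c("med", "mx", "iqr")]), c(med = 3, mx = 5, iqr = 2))
  s <- summarize_window(c(2, 2, 2, 2))
  expect_equal(unlist(s[c("med", "mx", "iqr")]), c(med = 2, mx = 2, iqr = 0))
  expect_error(summarize_window(numeric(0)),
               class = "frugalhr_empty_window_error")
})

test_that("window summaries match an independent sort-and-index oracle", {
  oracle <- function(a) {
    s <- a[order(a)]
    n <- length(s)
    med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    c(med = med, mx = s[n],
      iqr = s[floor(0.75 * (n - 1)) + 1] - s[floor(0.25 * (n - 1)) + 1])
  }
  set.seed(101)
  for (rep in 1:50) {
    a <- runif(sample(1:30, 1), 0, 3)
    got <- summarize_window(a)
    expect_equal(unlist(got[c("med", "mx", "iqr")]), oracle(a))
  }
})

test_that("window summaries are permutation-invariant and scale-equivariant", {
  set.seed(102)
  for (rep in 1:25) {
    a <- runif(sample(2:20, 1), 0, 2)
    base <- unlist(summarize_window(a)[c("med", "mx", "iqr")])
    perm <- unlist(summarize_window(sample(a))[c("med", "mx", "iqr")])
    expect_identical(base, perm)
    c_ <- runif(1, 0.1, 10)
    scaled <- unlist(summarize_window(c_ * a)[c("med", "mx", "iqr")])
    expect_equal(scaled, c_ * base)
  }
})

test_that("feature vectors have length m + 3k in statistic-grouped order", {
  al <- contiguous_aligned(10)
  r11 <- build_feature_rows(al, 1, 1)
  expect_identical(
    grep("^(h|amed|amax|aiqr)[0-9]+$", names(r11), value = TRUE),
    c("h1", "amed1", "amax1", "aiqr1"))
  r53 <- build_feature_rows(al, 5, 3)
  expect_length(feature_cols(5, 3), 14)
  expect_identical(
    grep("^(h|amed|amax|aiqr)[0-9]+$", names(r53), value = TRUE),
    c(paste0("h", 1:5), paste0("amed", 1:3), paste0("amax", 1:3),
      paste0("aiqr", 1:3)))
  # 10 contiguous records, m=5, k=3 -> 10 - max(5,3) + 1 = 6 rows
  expect_identical(nrow(r53), 6L)
})

test_that("feature windows hold the right readings and summaries", {
  al <- tiny_aligned()
  rows <- build_feature_rows(al, 2, 2)
  # segment 1 (3 records) hosts two windows; segment 2 (2 records) one
  expect_identical(nrow(rows), 3L)
  expect_identical(rows$segment_id, c(1L, 1L, 2L))
  s1 <- rows[rows$segment_id == 1L, ]
  # newest reading is h_m; oldest is h_1
  expect_equal(s1$h2, c(82, 84))
  expect_equal(s1$h1, c(80, 82))
  expect_equal(rows$hr_device, rows$h2)
  # a_k summarizes the current window, a_1 the previous one
  s2 <- summarize_window(al$accel_mags[[2]])
  s3 <- summarize_window(al$accel_mags[[3]])
  expect_equal(s1$amed2, c(s2$med, s3$med))
  expect_equal(s1$amax1[2], s2$mx)
  expect_equal(s1$aiqr2[2], s3$iqr)
  expect_equal(rows$target, c(81, 85, 93))
})

test_that("feature rows never span segment boundaries", {
  al <- tiny_aligned()
  rows <- build_feature_rows(al, 2, 1)
  expect_true(all(rows$segment_id %in% c(1L, 2L)))
  # segment 2 has 2 records -> exactly 1 row with m=2
  expect_identical(sum(rows$segment_id == 2L), 1L)
  # no row's span may cross the segment boundary at record 3|4
  expect_false(any(rows$.first_record <= 3 & rows$.record >= 4))
})

test_that("the strictly-past heart-rate window excludes the current reading", {
  al <- contiguous_aligned(10)
  rows <- build_feature_rows(al, 3, 1, include_current = FALSE)
  expect_identical(nrow(rows), 7L)  # needs m = 3 predecessors
  i <- rows$.record
  expect_equal(rows$h3, al$hr_device[i - 1])
  expect_equal(rows$h1, al$hr_device[i - 3])
})

test_that("empty acceleration windows reuse the previous summary", {
  al <- contiguous_aligned(4)
  al$accel_mags[[3]] <- numeric(0)
  rows <- build_feature_rows(al, 1, 1)
  s2 <- summarize_window(al$accel_mags[[2]])
  expect_equal(rows$amed1[rows$.record == 3], s2$med)
})

test_that("normalization standardizes train rows and round-trips", {
  al <- contiguous_aligned(40)
  rows <- build_feature_rows(al, 3, 2)
  stats <- fit_normalization(rows)
  normed <- apply_normalization(rows, stats)
  x <- as.matrix(normed[stats$features])
  expect_true(all(abs(colMeans(x)) < 1e-9))
  live <- !stats$constant
  expect_true(all(abs(apply(x[, live, drop = FALSE], 2, var) - 1) < 1e-9))
  # targets untouched
  expect_identical(normed$target, rows$target)
  # algebraic inverse recovers the original features
  back <- invert_normalization(normed, stats)
  expect_equal(as.matrix(back[stats$features]),
               as.matrix(rows[stats$features]), tolerance = 1e-9)
})

test_that("zero-variance features are flagged and map to zero", {
  al <- contiguous_aligned(10)
  al$accel_mags <- lapply(seq_len(10), function(i) c(2, 2, 2))
  rows <- build_feature_rows(al, 1, 1)
  stats <- fit_normalization(rows)
  expect_true(stats$constant[["amed1"]])
  expect_identical(stats$inv_std[["amed1"]], 1)
  normed <- apply_normalization(rows, stats)
  expect_true(all(normed$amed1 == 0))
})

test_that("normalization and window parameters are validated", {
  al <- contiguous_aligned(10)
  rows <- build_feature_rows(al, 1, 1)
  expect_error(fit_normalization(rows[1, ]),
               class = "frugalhr_insufficient_data_error")
  expect_error(build_feature_rows(al, 0, 1),
               class = "frugalhr_parameter_error")
  expect_error(build_feature_rows(al, 1, -1),
               class = "frugalhr_parameter_error")
})
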
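# Mapping metrics against from-scratch oracles, aggregation order, the
# printed-table Mean helper, and the least-squares baseline.

test_that("mse/cossim/pcorr match direct evaluation and their invariances", {
  y <- c(1, 2, 3)
  expect_identical(mse(y, y), 0)
  expect_equal(mse(y, c(2, 2, 2)), 2 / 3)
  set.seed(61)
  a <- rnorm(40)
  expect_equal(mse(3 * a, 3 * (a + 0.1)), 9 * mse(a, a + 0.1))

  expect_equal(cossim(a, a), 1)
  expect_equal(cossim(a, -a), -1)
  expect_identical(cossim(c(1, 0), c(0, 1)), 0)
  expect_warning(v <- cossim(rep(0, 4), 1:4), "zero-norm")
  expect_true(is.na(v))

  b <- rnorm(40)
  expect_equal(pcorr(a, 2.5 * a + 7), 1, tolerance = 1e-12)
  expect_equal(pcorr(a, -a + 3), -1, tolerance = 1e-12)
  expect_warning(pcorr(rep(1, 5), 1:5), "zero-variance")
  for (rep in 1:25) {
    y1 <- rnorm(50)
    y2 <- rnorm(50)
    # from-scratch covariance / sd oracle
    ref <- mean((y1 - mean(y1)) * (y2 - mean(y2))) /
      (sqrt(mean((y1 - mean(y1))^2)) * sqrt(mean((y2 - mean(y2))^2)))
    expect_equal(pcorr(y1, y2), ref, tolerance = 1e-10)
    # scale/offset invariances
    expect_equal(pcorr(y1, y2), pcorr(3 * y1 + 1, 0.5 * y2 - 2),
                 tolerance = 1e-10)
    expect_equal(cossim(y1, y2), cossim(2 * y1, 5 * y2), tolerance = 1e-10)
    loop_cos <- sum(y1 * y2) / (sqrt(sum(y1^2)) * sqrt(sum(y2^2)))
    expect_equal(cossim(y1, y2), loop_cos, tolerance = 1e-10)
  }
})

test_that("evaluate_mapping aggregates sensors -> segments -> subjects", {
  set.seed(62)
  Y1 <- matrix(rnorm(64 * 2), 64, 2)
  Y2 <- matrix(rnorm(64 * 2), 64, 2)
  E1 <- Y1 + matrix(rnorm(64 * 2, sd = 0.3), 64, 2)
  E2 <- Y2 + matrix(rnorm(64 * 2, sd = 0.3), 64, 2)
  rep2 <- evaluate_mapping(list(list(Y1, E1), list(Y2, E2)))
  # loop oracle over the two pairs
  seg_vals <- sapply(list(list(Y1, E1), list(Y2, E2)), function(p) {
    c(mean(c(mse(p[[1]][, 1], p[[2]][, 1]), mse(p[[1]][, 2], p[[2]][, 2]))),
      mean(c(pcorr(p[[1]][, 1], p[[2]][, 1]), pcorr(p[[1]][, 2], p[[2]][, 2]))),
      mean(c(cossim(p[[1]][, 1], p[[2]][, 1]), cossim(p[[1]][, 2], p[[2]][, 2]))))
  })
  expect_equal(unname(rep2$cohort_mean),
               unname(rowMeans(seg_vals)), tolerance = 1e-12)
  # identity mapping: (0, 1, 1)
  perfect <- evaluate_mapping(list(list(Y1, Y1), list(Y2, Y2)))
  expect_equal(unname(perfect$cohort_mean), c(0, 1, 1))
  # single pair, single sensor reduces to the scalar ops
  one <- evaluate_mapping(list(list(Y1[, 1, drop = FALSE],
                                    E1[, 1, drop = FALSE])))
  expect_equal(unname(one$cohort_mean["PCORR"]), pcorr(Y1[, 1], E1[, 1]))
  # order invariance
  swapped <- evaluate_mapping(list(list(Y2, E2), list(Y1, E1)))
  expect_equal(swapped$cohort_mean, rep2$cohort_mean)
})

test_that("mean_of_column reproduces printed-table aggregation", {
  tabs <- reference_cohort_tables()
  expect_identical(mean_of_column(tabs$ied_counts$n_ied, 1), 366.8)
  expect_identical(mean_of_column(tabs$mapping$MSE, 3), 0.014)
  expect_identical(mean_of_column(c(1, 2, 3), 1), 2)
  expect_identical(mean_of_column(c(0.25, 0.25), 1), 0.3) # half away from zero
  expect_identical(mean_of_column(c(-0.25, -0.25), 1), -0.3)
  expect_error(mean_of_column(numeric(0)), "empty")
})

test_that("lsq_baseline recovers noiseless linear mixtures and satisfies the normal equations", {
  set.seed(63)
  W <- default_mixing(20, 12, width = 0.6)
  train <- lapply(1:8, function(i) {
    Y <- matrix(rnorm(64 * 12), 64, 12)
    list(Y %*% t(W), Y) # scalp = mix(Y), noiseless
  })
  Ytest <- matrix(rnorm(64 * 12), 64, 12)
  est <- lsq_baseline(train, Ytest %*% t(W))
  pcs <- vapply(1:12, function(j) pcorr(Ytest[, j], est[, j]), numeric(1))
  expect_true(all(pcs > 0.99))
  # residual orthogonality on random data (normal equations)
  train2 <- lapply(1:5, function(i)
    list(matrix(rnorm(64 * 6), 64, 6), matrix(rnorm(64 * 3), 64, 3)))
  X <- do.call(rbind, lapply(train2, `[[`, 1))
  Y <- do.call(rbind, lapply(train2, `[[`, 2))
  fit_est <- lsq_baseline(train2, lapply(train2, `[[`, 1))
  R <- Y - do.call(rbind, fit_est)
  expect_lt(max(abs(crossprod(cbind(1, X), R))), 1e-8)
  # fewer samples than regressors: minimum-norm path, no crash
  small <- list(list(matrix(rnorm(4 * 6), 4, 6), matrix(rnorm(4 * 2), 4, 2)))
  expect_message(out <- lsq_baseline(small, small[[1]][[1]]),
                 "minimum-norm")
  expect_identical(dim(out), c(4L, 2L))
})

test_that("write_metric_table appends a Mean row consistent with mean_of_column", {
  df <- data.frame(subject = c("S1", "S2", "S3"),
                   MSE = c(0.01, 0.02, 0.04), PCORR = c(0.2, 0.4, 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_table(df, path, rounding = c(3, 2))
  back <- utils::read.csv(path)
  expect_identical(back$subject[4], "Mean")
  expect_equal(back$MSE[4], mean_of_column(df$MSE, 3))
  expect_equal(back$PCORR[4], mean_of_column(df$PCORR, 2))
})
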
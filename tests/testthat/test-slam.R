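slam_df <- function(sigma, delta, arm = "ctrl", a0 = NULL,
                    times = c(0, 1, 2, 4), reps = 3) {
  df <- expand.grid(time_h = times, rep = seq_len(reps))
  cur <- slam_model_curves(df$time_h, sigma, delta, a0 = a0, arm = arm)
  df$count <- cur$f_old + cur$f_new
  df$ntr <- ifelse(df$count > 0, cur$f_new / df$count, 0)
  df
}

test_that("model curves satisfy the steady-state identities", {
  t <- c(0, 0.5, 1, 2, 4, 8)
  cur <- slam_model_curves(t, sigma = 10, delta = 0.5, arm = "ctrl")
  expect_equal(cur$f_new[1], 0)
  expect_equal(cur$f_old[1], 20)
  # conservation at steady state: old + new = sigma/delta for all t
  expect_equal(cur$f_old + cur$f_new, rep(20, length(t)))
  # limits
  late <- slam_model_curves(100, 10, 0.5, arm = "ctrl")
  expect_equal(late$f_new, 20, tolerance = 1e-10)
  expect_equal(late$f_old, 0, tolerance = 1e-10)
  expect_error(slam_model_curves(1, 10, 0), "delta")
  expect_error(slam_model_curves(1, 10, 0.5, arm = "aux"), "a0")
})

test_that("the closed form solves the synthesis-degradation ODE", {
  set.seed(101)
  for (k in 1:20) {
    sigma <- stats::runif(1, 1, 50)
    delta <- stats::runif(1, 0.05, 2)
    a0 <- stats::runif(1, 0, 100)
    sol <- deSolve::lsoda(c(a = a0), times = c(0, 1.7, 4),
                          func = function(t, y, p) list(sigma - delta * y),
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    closed <- (a0 - sigma / delta) * exp(-sol[, "time"] * delta) +
      sigma / delta
    expect_lt(max(abs(sol[, "a"] - closed) / pmax(closed, 1e-6)), 1e-8)
  }
})

test_that("median-of-ratios size factors behave canonically", {
  m <- matrix(c(10, 20, 10, 20, 10, 20), nrow = 2)
  expect_equal(unname(size_factors_median_of_ratios(m)), c(1, 1, 1))
  m2 <- m
  m2[, 2] <- m2[, 2] * 2
  expect_equal(unname(size_factors_median_of_ratios(m2)[2]),
               2 * size_factors_median_of_ratios(m2)[1],
               ignore_attr = TRUE)
  # ratios to the per-gene geometric mean are scale-free, so a common
  # rescaling of the whole matrix leaves the factors unchanged
  expect_equal(size_factors_median_of_ratios(7 * m2),
               size_factors_median_of_ratios(m2))
  expect_error(size_factors_median_of_ratios(matrix(0, 2, 2)),
               "all-positive")
})

test_that("size factors agree with the DESeq2 reference", {
  skip_if_not_installed("DESeq2")
  set.seed(103)
  m <- matrix(stats::rnbinom(600, size = 10, mu = 100), ncol = 6)
  expect_equal(unname(size_factors_median_of_ratios(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-4)
})

test_that("levels derive from counts and NTR with exact conservation", {
  df <- slam_df(10, 0.5)
  lev <- slam_levels(df)
  expect_equal(lev$g_new + lev$g_old, df$count)
  bad <- df
  bad$ntr[1] <- 1.5
  expect_error(slam_levels(bad))
})

test_that("noiseless kinetics are recovered exactly in both arms", {
  fc <- fit_slam_control(slam_df(10, 0.5))
  expect_equal(fc$sigma, 10, tolerance = 1e-3)
  expect_equal(fc$delta, 0.5, tolerance = 1e-3)
  expect_true(fc$converged)
  fa <- fit_slam_auxin(slam_df(2, 0.5, arm = "aux", a0 = 100))
  expect_equal(fa$sigma, 2, tolerance = 1e-3)
  expect_equal(fa$delta, 0.5, tolerance = 1e-3)
  expect_equal(fa$a0, 100)
  # a0 is the mean of the t = 0 old-RNA replicates
  df <- slam_df(2, 0.5, arm = "aux", a0 = 100)
  df$count[df$time_h == 0] <- c(90, 100, 110)
  expect_equal(fit_slam_auxin(df)$a0, 100)
  # the exclusion list always holds the late new-RNA points
  expect_setequal(unique(fa$excluded$time_h), c(2, 4))
})

test_that("degenerate designs fail loudly", {
  df0 <- slam_df(10, 0.5, times = 0)
  expect_error(fit_slam_control(df0), "single time point")
  flat <- slam_df(10, 0.5)
  flat$ntr <- 0
  flat$count <- 20  # old RNA constant: no decay information
  f <- fit_slam_control(flat)
  expect_false(f$converged)
  expect_true(f$at_bound)
})

test_that("synthesis-rate fold changes are computed between arms", {
  fc <- fit_slam_control(slam_df(8, 0.4))
  fa <- fit_slam_auxin(slam_df(1, 0.4, arm = "aux", a0 = 20))
  rr <- net_rate_ratio(fa, fc)
  expect_equal(rr$ratio, 8, tolerance = 1e-3)
  expect_equal(rr$log2_ratio, 3, tolerance = 1e-3)
  rr2 <- net_rate_ratio(fc, fc)
  expect_equal(rr2$ratio, 1, tolerance = 1e-6)
})
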
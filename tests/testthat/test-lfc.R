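test_that("the fold-change density matches its closed form and symmetry", {
  expect_equal(dlfc(0, 1, 1), log(2) / 4)
  for (ab in list(c(1, 1), c(2, 5), c(10, 10))) {
    total <- stats::integrate(function(x) dlfc(x, ab[1], ab[2]),
                              -40, 40, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  x <- seq(-5, 5, by = 0.25)
  expect_equal(dlfc(x, 2, 7), dlfc(-x, 7, 2))
  expect_error(dlfc(0, -1, 2), "alpha")
})

test_that("dlfc is the push-forward of a Beta through the log2-odds map", {
  set.seed(31)
  for (ab in list(c(2, 5), c(10, 10))) {
    p <- stats::rbeta(1e5, ab[1], ab[2])
    x <- log2(p / (1 - p))
    ks <- suppressWarnings(
      stats::ks.test(x, function(q) plfc(q, ab[1], ab[2])))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("the piecewise trend is continuous and saturates at b", {
  expect_equal(piecewise_trend(1:10, 0.5, 0, 3), rep(0.5, 10))
  expect_equal(piecewise_trend(10, 0, -0.1, 5), -0.5)
  b <- 4.3
  eps <- 1e-9
  expect_equal(piecewise_trend(b - eps, 1, -0.2, b),
               piecewise_trend(b + eps, 1, -0.2, b), tolerance = 1e-6)
})

test_that("the profile likelihood behaves as the model dictates", {
  a <- window_vector("g", "body", 1000, rep(10, 12))
  cc <- window_vector("g", "body", 1000, rep(10, 12))
  # equal counts: likelihood of l = 0 beats any shifted profile
  expect_gt(lfc_loglik(0, a, cc), lfc_loglik(0.5, a, cc))
  expect_gt(lfc_loglik(0, a, cc), lfc_loglik(-0.5, a, cc))
  # halving dds flattens the implied density (lower peak at the mode)
  one_a <- window_vector("g", "body", 1000, 100)
  one_c <- window_vector("g", "body", 1000, 100)
  expect_gt(lfc_loglik(0, one_a, one_c, dds = 1),
            lfc_loglik(0, one_a, one_c, dds = 0.5))
  # single window closed form
  expect_equal(lfc_loglik(0, one_a, one_c, dds = 1),
               dlfc(0, 100.5 + 1, 100.5 + 1, log = TRUE))
  miss <- window_vector("g", "body", 1000, rep(1, 3), rep(TRUE, 3))
  expect_error(lfc_loglik(0, miss, miss), "missing")
})

test_that("noiseless generative profiles are recovered by fit_lfc", {
  i <- 1:90
  cc <- window_vector("g", "body", 1000, rep(100, 90))
  a <- window_vector("g", "body", 1000,
                     round(100 * 2^(-0.03 * pmin(i, 60))))
  f <- fit_lfc(a, cc)
  expect_equal(f$s, -0.03, tolerance = 0.1)
  expect_equal(f$b, 60, tolerance = 5)
  ident <- fit_lfc(cc, cc)
  expect_lt(abs(ident$s), 1e-3)
  expect_lt(abs(ident$o), 0.05)
  short <- window_vector("g", "body", 1000, rep(5, 5))
  expect_error(fit_lfc(short, short), "8 non-missing")
})

test_that("a coarse grid search never beats the optimizer", {
  set.seed(41)
  for (rep in 1:3) {
    L <- 20
    i <- 1:L
    av <- stats::rnbinom(L, size = 10, mu = 150 * 2^(-0.05 * i))
    cv <- stats::rnbinom(L, size = 10, mu = 150)
    a <- window_vector("g", "body", 1000, av)
    cc <- window_vector("g", "body", 1000, cv)
    f <- fit_lfc(a, cc)
    grid <- expand.grid(o = seq(-1, 1, by = 0.25),
                        s = seq(-0.15, 0.05, by = 0.01),
                        b = c(5, 10, 15, 20))
    grid_ll <- max(apply(grid, 1, function(g)
      lfc_loglik(piecewise_trend(i, g[1], g[2], g[3]), a, cc,
                 dds = f$dds)))
    expect_gte(f$loglik + 1e-6, grid_ll)
  }
})

test_that("slope recovery and CI coverage hold across genes under NB noise", {
  # genes whose fit passes the accurate-fit gate (the defect CI below
  # 1 %/kb, the inclusion rule used for all downstream reporting); on
  # null genes the unrestricted global MLE can place a spurious early
  # turning point whose steep short-segment slope the gate screens out
  set.seed(53)
  res <- NULL
  for (s_true in c(0, -0.01, -0.03)) {
    one <- replicate(60, {
      L <- 90
      i <- 1:L
      av <- stats::rnbinom(L, size = 10, mu = 300 * 2^(s_true * i))
      cv <- stats::rnbinom(L, size = 10, mu = 300)
      f <- tryCatch(fit_lfc(window_vector("g", "body", 1000, av),
                            window_vector("g", "body", 1000, cv)),
                    error = function(e) NULL)
      if (is.null(f)) return(c(NA, NA, NA))
      c(f$s - s_true, f$accurate,
        f$ci_s[1] <= s_true && s_true <= f$ci_s[2])
    })
    res <- cbind(res, one)
  }
  acc <- res[2, ] == 1
  expect_gt(sum(acc, na.rm = TRUE), 60)
  expect_lt(stats::median(abs(res[1, acc]), na.rm = TRUE), 0.005)
  coverage <- mean(res[3, acc] == 1, na.rm = TRUE)
  expect_gte(coverage, 0.85)
  expect_lte(coverage, 1)
})

test_that("slope-to-defect conversion follows the survival algebra", {
  expect_equal(processivity_defect(-log2(1.02)), 2)
  expect_equal(processivity_defect(0), 0)
  expect_equal(processivity_defect(-0.0139), 0.968, tolerance = 1e-3)
  expect_equal(processivity_defect(-0.0139, signed = TRUE), -0.959,
               tolerance = 1e-3)
})
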
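test_that("both estimators are exact on noiseless piecewise-linear series", {
  for (jump in c(0, 5)) {
    d <- piecewise_series(jump)
    fp <- fit_rdd(y ~ month, d, cutoff = 6, method = "parametric")
    fl <- fit_rdd(y ~ month, d, cutoff = 6, method = "local", bandwidth = 3)
    expect_equal(fp$estimate, jump, tolerance = 1e-10)
    expect_equal(fl$estimate, jump, tolerance = 1e-10)
    expect_equal(fp$right_limit - fp$left_limit, fp$estimate,
                 tolerance = 1e-12)
    expect_equal(fl$right_limit - fl$left_limit, fl$estimate,
                 tolerance = 1e-12)
    # left limit is the trend evaluated at the cutoff month, pre-award side
    expect_equal(fp$left_limit, 1 + 2 * 6, tolerance = 1e-10)
  }
  # a quadratic trend is exact for the order-2 parametric fit
  d2 <- piecewise_series(7)
  d2$y <- d2$y + 0.3 * d2$month^2
  f2 <- fit_rdd(y ~ month, d2, cutoff = 6, method = "parametric", order = 2)
  expect_equal(f2$estimate, 7, tolerance = 1e-8)
})

test_that("parametric order-1 equals full-width uniform local linear", {
  set.seed(77)
  d <- piecewise_series(3, n_per_month = 6)
  d$y <- d$y + rnorm(nrow(d), sd = 4)
  fp <- fit_rdd(y ~ month, d, cutoff = 6, method = "parametric", order = 1,
                cluster = "physician_id")
  fl <- fit_rdd(y ~ month, d, cutoff = 6, method = "local", bandwidth = 50,
                kernel = "uniform", cluster = "physician_id")
  expect_equal(fl$estimate, fp$estimate, tolerance = 1e-10)
  expect_equal(fl$std_error, fp$std_error, tolerance = 1e-10)
  expect_equal(fl$left_limit, fp$left_limit, tolerance = 1e-10)
})

test_that("jump estimates are translation- and scale-equivariant", {
  set.seed(78)
  d <- piecewise_series(4)
  d$y <- d$y + rnorm(nrow(d))
  for (meth in c("parametric", "local")) {
    f0 <- fit_rdd(y ~ month, d, 6, method = meth)
    d1 <- transform(d, y = y + 1000)
    f1 <- fit_rdd(y ~ month, d1, 6, method = meth)
    expect_equal(f1$estimate, f0$estimate, tolerance = 1e-8)
    d2 <- transform(d, y = y * 2.5)
    f2 <- fit_rdd(y ~ month, d2, 6, method = meth)
    expect_equal(f2$estimate, 2.5 * f0$estimate, tolerance = 1e-8)
    expect_equal(f2$std_error, 2.5 * f0$std_error, tolerance = 1e-8)
  }
})

test_that("p-values follow the two-sided normal reference", {
  set.seed(79)
  d <- piecewise_series(1)
  d$y <- d$y + rnorm(nrow(d))
  f <- fit_rdd(y ~ month, d, 6, cluster = "physician_id")
  expect_equal(f$p_value, 2 * pnorm(-abs(f$estimate / f$std_error)),
               tolerance = 1e-12)
  expect_true(f$p_value >= 0 && f$p_value <= 1)
})

test_that("cluster argument forms are interchangeable", {
  set.seed(80)
  d <- piecewise_series(2)
  d$y <- d$y + rnorm(nrow(d))
  f1 <- fit_rdd(y ~ month, d, 6, cluster = "physician_id")
  f2 <- fit_rdd(y ~ month, d, 6, cluster = ~physician_id)
  f3 <- fit_rdd(y ~ month, d, 6, cluster = d$physician_id)
  expect_equal(f1$std_error, f2$std_error, tolerance = 1e-12)
  expect_equal(f1$std_error, f3$std_error, tolerance = 1e-12)
})

test_that("insufficient support near the cutoff is a clear error", {
  d <- piecewise_series(1, months = 4:8)
  expect_error(fit_rdd(y ~ month, d, 6, method = "parametric", order = 3),
               "left")
  expect_error(fit_rdd(y ~ month, d, 6, method = "local", bandwidth = 1),
               "minimal feasible bandwidth")
  expect_error(fit_rdd(y ~ month, d, 6, method = "local", bandwidth = -2),
               "positive")
})

test_that("predict reproduces the fitted piecewise regression function", {
  d <- piecewise_series(5)
  fp <- fit_rdd(y ~ month, d, 6, method = "parametric")
  mm <- c(2, 5.5, 6, 9)
  expect_equal(predict(fp, mm), 1 + 2 * mm + 5 * (mm >= 6),
               tolerance = 1e-8)
  fl <- fit_rdd(y ~ month, d, 6, method = "local", bandwidth = 3)
  expect_equal(predict(fl, c(5, 6)), c(11, 18), tolerance = 1e-8)
})

test_that("single-seed simulation lands near the generating jump", {
  cfg <- tiny_config(n_treated = 120L, n_control_pool = 120L, seed = 33L)
  pan <- simulate_panel(cfg)
  fl <- as.data.frame(pan)[pan$treated == 1 & pan$month_index >= 1, ]
  f <- fit_rdd(views ~ month_index, fl, 6, cluster = "physician_id",
               method = "parametric")
  expect_lt(abs(f$estimate - cfg$jump_views), 5 * f$std_error)
  expect_identical(f$n_obs, nrow(fl))
  expect_identical(f$n_clusters, 120L)
})

test_that("differential effect subtracts the two group jumps", {
  d_t <- piecewise_series(5); d_c <- piecewise_series(2)
  ft <- fit_rdd(y ~ month, d_t, 6, outcome_label = "views",
                group_label = "treated")
  fc <- fit_rdd(y ~ month, d_c, 6, outcome_label = "views",
                group_label = "control")
  de <- differential_effect(ft, fc)
  expect_equal(de$estimate, 3, tolerance = 1e-9)
  expect_equal(de$estimate, ft$estimate - fc$estimate)
  expect_equal(de$std_error, sqrt(ft$std_error^2 + fc$std_error^2))
  # identical fits: zero effect, SE = sqrt(2) x the common SE
  de0 <- differential_effect(ft, ft)
  expect_equal(de0$estimate, 0)
  expect_equal(de0$std_error, sqrt(2) * ft$std_error)
  # incompatible fits are refused
  f_loc <- fit_rdd(y ~ month, d_c, 6, method = "local",
                   outcome_label = "views")
  expect_error(differential_effect(ft, f_loc), "method mismatch")
  f_pat <- fit_rdd(y ~ month, d_c, 6, outcome_label = "patients")
  expect_error(differential_effect(ft, f_pat), "outcome mismatch")
})

test_that("lag scan finds a noiseless delayed jump exactly", {
  d <- piecewise_series(0)
  d$y <- 1 + 2 * d$month + 5 * (d$month >= 7)   # jump one month after cutoff
  sc <- scan_lag(y ~ month, d, cutoff = 6, max_lag = 3)
  expect_identical(sc$best_lag, 1L)
  expect_identical(nrow(sc$profile), 4L)
  expect_equal(sc$profile$estimate[sc$profile$lag == 1], 5, tolerance = 1e-8)
  expect_equal(sc$best_fit$estimate, 5, tolerance = 1e-8)
  expect_error(scan_lag(y ~ month, d, cutoff = 6, max_lag = 5), "max_lag")
})
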
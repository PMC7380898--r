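test_that("generator is a pure function of its configuration", {
  cfg <- tiny_config(seed = 99L)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  # and it leaves the caller's RNG stream untouched
  set.seed(5); before <- rnorm(3)
  set.seed(5); invisible(simulate_panel(cfg)); after <- rnorm(3)
  expect_identical(before, after)
  # a different seed gives a different panel
  p3 <- simulate_panel(tiny_config(seed = 100L))
  expect_false(identical(p1$views, p3$views))
})

test_that("exact-count assignment treats exactly n_treated physicians", {
  pan <- simulate_panel(synth_config(n_treated = 346, n_control_pool = 3000,
                                     seed = 2L))
  base <- pan[pan$month_index == 0, ]
  expect_identical(sum(base$treated), 346L)
  expect_identical(nrow(base), 3346L)
})

test_that("panel satisfies its structural invariants", {
  pan <- simulate_panel(tiny_config(seed = 4L, lag_months = 2L))
  months <- split(pan$month_index, pan$physician_id)
  expect_true(all(vapply(months, function(m)
    length(m) == 12L && setequal(m, 0:11), logical(1))))
  expect_true(all(vapply(split(pan$treated, pan$physician_id),
                         function(v) length(unique(v)) == 1L, logical(1))))
  expect_identical(pan$post, as.integer(pan$month_index >= 6))
  for (v in c("thank", "gift", "article", "patients", "views"))
    expect_true(all(pan[[v]] >= 0), label = paste(v, ">= 0"))
  prs0 <- pan$prs[pan$month_index == 0]
  expect_true(all(prs0 >= 0 & prs0 <= 5))
})

test_that("infeasible configurations are rejected with a named invariant", {
  expect_error(synth_config(n_treated = 100, n_control_pool = 50),
               "n_control_pool")
  expect_error(synth_config(cutoff_index = 6, lag_months = 6),
               "lag_months")
  expect_error(synth_config(score_weights = c(prs = 1)), "score_weights")
})

test_that("with no jumps and no selection the two groups share one law", {
  null_w <- c(prs = 0, thank = 0, gift = 0, contr = 0, article = 0)
  diffs_v <- diffs_p <- numeric(40)
  for (i in seq_len(40)) {
    pan <- simulate_panel(tiny_config(
      n_treated = 40L, n_control_pool = 40L, jump_patients = 0,
      jump_views = 0, score_weights = null_w, seed = 500L + i))
    at_cut <- pan[pan$month_index == 6, ]
    diffs_v[i] <- mean(at_cut$views[at_cut$treated == 1]) -
      mean(at_cut$views[at_cut$treated == 0])
    diffs_p[i] <- mean(at_cut$patients[at_cut$treated == 1]) -
      mean(at_cut$patients[at_cut$treated == 0])
  }
  expect_lt(abs(mean(diffs_v)), 3 * stats::sd(diffs_v) / sqrt(40))
  expect_lt(abs(mean(diffs_p)), 3 * stats::sd(diffs_p) / sqrt(40))
})

test_that("selection on observables imbalances the covariates", {
  pan <- simulate_panel(tiny_config(n_treated = 100L, n_control_pool = 500L,
                                    seed = 7L))
  base <- panel_baseline(pan)
  asds <- vapply(ohc_covariates(), function(v)
    absolute_standardized_difference(base[[v]][base$treated == 1],
                                     base[[v]][base$treated == 0]),
    numeric(1))
  expect_gt(max(asds), 0.1)
})

test_that("marginal_changes splits a cumulative series into state + changes", {
  expect_equal(marginal_changes(c(100, 100, 100)), c(100, 0, 0))
  # thank-you-letter cumulative series: 139.3 -> 145.9 -> 152.3
  expect_equal(marginal_changes(c(139.3, 145.9, 152.3)),
               c(139.3, 6.6, 6.4), tolerance = 1e-12)
  set.seed(31)
  x <- cumsum(runif(12, 0, 10))
  expect_equal(cumsum(marginal_changes(x)), x, tolerance = 1e-12)
  # matrix form: one row per physician
  m <- rbind(a = c(1, 3, 6), b = c(10, 10, 9))
  expect_warning(out <- marginal_changes(m), "non-monotone")
  expect_equal(unname(out), rbind(c(1, 2, 3), c(10, 0, -1)))
  expect_error(marginal_changes(5), "at least 2")
  expect_silent(marginal_changes(c(5, 4), warn_negative = FALSE))
})

test_that("panel CSV and synth-config files round-trip", {
  cfg <- tiny_config(seed = 12L, lag_months = 1L,
                     score_threshold = 5.25)
  pan <- simulate_panel(cfg)
  f <- tempfile(fileext = ".csv")
  write_panel_csv(pan, f)
  back <- read_panel_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(pan), tolerance = 1e-12)
  expect_identical(attr(back, "cutoff_index"), attr(pan, "cutoff_index"))

  g <- tempfile(fileext = ".txt")
  write_synth_config(cfg, g)
  cfg2 <- read_synth_config(g)
  expect_equal(cfg2$score_weights, cfg$score_weights)
  expect_equal(cfg2$score_threshold, cfg$score_threshold)
  expect_identical(cfg2$n_treated, cfg$n_treated)
  expect_identical(cfg2$lag_months, cfg$lag_months)
  expect_identical(as.data.frame(simulate_panel(cfg2)), as.data.frame(pan))
  unlink(c(f, g))
})
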
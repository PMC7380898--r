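test_that("each treated unit pairs with its nearest available control", {
  m <- match_nearest(c(a = 0.6), c(u = 0.1, v = 0.59))
  expect_identical(m$pairs$control_id, "v")
  expect_equal(m$pairs$distance, 0.01, tolerance = 1e-12)
  # exact-PS twins pair at distance zero when no caliper is set
  tw <- match_nearest(c(t1 = 0.3, t2 = 0.7), c(c1 = 0.3, c2 = 0.7, c3 = 0.5))
  expect_equal(tw$pairs$distance, c(0, 0))
  expect_setequal(tw$pairs$control_id, c("c1", "c2"))
})

test_that("degenerate matching inputs are rejected", {
  expect_error(match_nearest(numeric(0), c(a = 0.5)), "empty treated")
  expect_error(match_nearest(c(a = 0.5), numeric(0)), "empty control")
  expect_error(match_nearest(c(a = 0.5), c(b = 0.4), caliper = 0),
               "caliper")
  expect_error(match_nearest(c(a = 0.5), c(b = 0.4), caliper = -1),
               "caliper")
})

test_that("greedy matcher agrees with the brute-force oracle", {
  set.seed(42)
  for (i in 1:40) {
    nt <- sample(1:10, 1)
    nc <- sample(1:20, 1)
    # two-decimal scores force frequent exact ties
    ps_t <- stats::setNames(round(runif(nt), 2), sprintf("T%02d", 1:nt))
    ps_c <- stats::setNames(round(runif(nc), 2), sprintf("C%02d", 1:nc))
    nm <- sample(1:2, 1)
    cal <- if (i %% 3 == 0) 0.15 else NULL
    got <- match_nearest(ps_t, ps_c, n_matches = nm, caliper = cal)
    want <- oracle_greedy_match(ps_t, ps_c, n_matches = nm, caliper = cal)
    expect_identical(got$pairs[, c("treated_id", "control_id")], want$pairs)
    expect_identical(got$unmatched_treated, want$unmatched)
  }
})

test_that("matching respects cardinality and without-replacement rules", {
  set.seed(9)
  ps_t <- stats::setNames(runif(25), sprintf("T%02d", 1:25))
  ps_c <- stats::setNames(runif(40), sprintf("C%02d", 1:40))
  m <- match_nearest(ps_t, ps_c, n_matches = 1, caliper = 0.05)
  expect_identical(nrow(m$pairs) + length(m$unmatched_treated), 25L)
  expect_false(anyDuplicated(m$pairs$control_id) > 0)
  expect_true(all(m$pairs$distance <= 0.05))
  m2 <- match_nearest(ps_t, ps_c, n_matches = 2)
  expect_lte(nrow(m2$pairs), 2L * 25L)
  expect_false(anyDuplicated(m2$pairs$control_id) > 0)
})

test_that("absolute standardized difference matches its definition", {
  expect_equal(absolute_standardized_difference(c(2, 4), c(1, 3)),
               1 / sqrt(2), tolerance = 1e-12)
  expect_equal(absolute_standardized_difference(c(1, 2, 3), c(3, 2, 1)), 0)
  # symmetric and scale-invariant
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20, 1)
  expect_equal(absolute_standardized_difference(a, b),
               absolute_standardized_difference(b, a))
  expect_equal(absolute_standardized_difference(3.7 * a, 3.7 * b),
               absolute_standardized_difference(a, b), tolerance = 1e-12)
  expect_error(absolute_standardized_difference(rep(1, 5), rep(1, 5),
                                                label = "gift"),
               "gift")
  expect_error(absolute_standardized_difference(1, c(1, 2)), "at least 2")
})

test_that("a treated set matched to identical twins balances exactly", {
  cfg <- tiny_config(n_treated = 20L, n_control_pool = 20L, seed = 15L)
  pan <- simulate_panel(cfg)
  base <- panel_baseline(pan)
  # rebuild the pool as exact copies of the treated physicians
  tr_rows <- pan[pan$treated == 1, ]
  copy <- tr_rows
  copy$physician_id <- sub("^P", "Q", copy$physician_id)
  copy$treated <- 0L
  twin <- rbind(tr_rows, copy)
  attr(twin, "cutoff_index") <- attr(pan, "cutoff_index")
  class(twin) <- class(pan)
  tb <- panel_baseline(twin)
  ps <- stats::setNames(rep(seq(0.2, 0.8, length.out = 20), 2),
                        tb$physician_id)
  m <- match_nearest(ps[tb$treated == 1], ps[tb$treated == 0])
  rep <- balance_report(twin, ps, m)
  expect_true(all(rep$asd_after < 1e-12))
  expect_identical(rep$covariate, c(ohc_covariates(), "ps"))
})

test_that("matching on the fitted PS improves covariate balance", {
  st <- matched_flows(tiny_config(n_treated = 80L, n_control_pool = 600L,
                                  seed = 21L))
  rep <- balance_report(st$panel, st$ps, st$match)
  expect_lt(mean(rep$asd_after), mean(rep$asd_before))
  expect_lt(mean(rep$asd_after[rep$covariate != "ps"]), 0.1)
  # unknown identifiers in the match are refused
  bad <- st$match
  bad$pairs$control_id[1] <- "NOSUCH"
  expect_error(balance_report(st$panel, st$ps, bad), "NOSUCH")
})
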
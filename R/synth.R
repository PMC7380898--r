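#' Simulate a physician-month panel
#'
#' Generates a balanced synthetic panel with the structure assumed by the
#' honorary-title study design: 12 monthly records per physician (month 0 is
#' the initial cumulative state; months 1--11 carry marginal monthly
#' changes), five pre-treatment covariates, two monthly service-volume
#' outcomes, selection-on-observables treatment assignment, a linear
#' pre-trend and an additive outcome jump at `cutoff_index + lag_months`
#' for treated physicians.
#'
#' Physicians share a latent "quality" factor that correlates all five
#' covariates and both outcome levels, so that treatment (assigned through a
#' weighted covariate score) is confounded with the outcomes until matching
#' removes the imbalance.  Consultation counts are negative-binomial around
#' their mean; view counts are rounded log-normal (right-skewed), with the
#' log-normal mean parameterized so the arithmetic mean equals the intended
#' trend.  An additive physician random intercept on each outcome induces
#' the within-physician correlation that motivates cluster-robust inference
#' downstream.
#'
#' The generator is a pure function of `config`: the same configuration
#' (including its `seed`) always returns the identical panel, and the
#' caller's RNG state is left untouched.
#'
#' @param config A [synth_config()] object.
#' @return A `physician_panel`: a long-format data frame with columns
#'   `physician_id`, `month_index`, `prs`, `thank`, `gift`, `contr`,
#'   `article`, `patients`, `views`, `treated`, `post`, carrying attributes
#'   `cutoff_index` and `n_physicians`.
#' @examples
#' pan <- simulate_panel(synth_config(n_treated = 20, n_control_pool = 60,
#'                                    seed = 42))
#' table(pan$treated[pan$month_index == 0])
#' @export
simulate_panel <- function(config) {
  validate_synth_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_treated + config$n_control_pool
  cutoff <- config$cutoff_index
  jump_at <- cutoff + config$lag_months
  w <- config$score_weights[ohc_covariates()]

  q <- stats::rnorm(n)                       # latent physician quality

  # month-0 cumulative states (Table-2-scale magnitudes)
  prs0     <- pmin(5, pmax(0, 4.5 + 0.15 * q + stats::rnorm(n, 0, 0.10)))
  thank0   <- round(exp(log(120)   + 0.35 * q + stats::rnorm(n, 0, 0.35)))
  gift0    <- round(exp(log(600)   + 0.35 * q + stats::rnorm(n, 0, 0.40)))
  contr0   <- round(exp(log(80000) + 0.30 * q + stats::rnorm(n, 0, 0.35)), 1)
  article0 <- round(exp(log(50)    + 0.30 * q + stats::rnorm(n, 0, 0.50)))
  x0 <- cbind(prs = prs0, thank = thank0, gift = gift0,
              contr = contr0, article = article0)

  latent <- drop(x0 %*% w) + stats::rlogis(n)
  if (is.na(config$score_threshold)) {
    treated <- as.integer(rank(-latent, ties.method = "first") <=
                            config$n_treated)
  } else {
    treated <- as.integer(latent > config$score_threshold)
  }

  # monthly covariate marginals (months 1..11), quality-linked drifts
  nm <- n * 11L
  q11 <- rep(q, times = 11L)
  prs_m     <- stats::rnorm(nm, mean = 0.003 * q11, sd = 0.006)
  # keep the cumulative rating-score path inside [0, 5]: clamp the running
  # sum and re-derive the marginals
  prs_cum <- matrix(prs_m, nrow = n, ncol = 11L)
  prs_cum <- prs0 + t(apply(prs_cum, 1L, cumsum))
  prs_cum <- pmin(pmax(prs_cum, 0), 5)
  prs_m <- as.vector(cbind(prs_cum[, 1L] - prs0,
                           t(apply(prs_cum, 1L, diff))))
  thank_m   <- stats::rpois(nm, lambda = pmax(4   + 1.5 * q11, 0.2))
  gift_m    <- stats::rpois(nm, lambda = pmax(15  + 6.0 * q11, 0.5))
  contr_m   <- round(pmax(stats::rnorm(nm, mean = 2500 + 900 * q11, sd = 400),
                          0))
  article_m <- stats::rpois(nm, lambda = pmax(1 + 0.3 * q11, 0.05))

  # outcomes: month-0 cumulative states, then monthly flows with trend + jump
  alpha_p <- stats::rnorm(n, 0, config$physician_effect_sd[["patients"]])
  alpha_v <- stats::rnorm(n, 0, config$physician_effect_sd[["views"]])
  patients0 <- round(exp(log(5000) + 0.25 * q + stats::rnorm(n, 0, 0.30)))
  views0    <- round(exp(log(4e6)  + 0.30 * q + stats::rnorm(n, 0, 0.40)))

  t11 <- rep(1:11, each = n)                 # month index for flow months
  jumped <- rep(treated, times = 11L) * as.integer(t11 >= jump_at)
  mu_p <- pmax(120 + 40 * q11 + rep(alpha_p, 11L) +
                 config$pre_trend_slope[["patients"]] * (t11 - 1) +
                 config$jump_patients * jumped, 1)
  patients_m <- stats::rnbinom(nm, size = config$noise_dispersion[["patients"]],
                               mu = mu_p)
  sdl <- config$noise_dispersion[["views"]]
  mu_v <- pmax(160000 + 40000 * q11 + rep(alpha_v, 11L) +
                 config$pre_trend_slope[["views"]] * (t11 - 1) +
                 config$jump_views * jumped, 1000)
  views_m <- round(stats::rlnorm(nm, meanlog = log(mu_v) - sdl^2 / 2,
                                 sdlog = sdl))

  ids <- sprintf("P%05d", seq_len(n))
  # rows ordered physician-major, month-minor
  stack12 <- function(m0, m11) {            # n-vector + (n x 11 col-block)
    mat <- cbind(m0, matrix(m11, nrow = n, ncol = 11L))
    as.vector(t(mat))
  }
  panel <- data.frame(
    physician_id = rep(ids, each = 12L),
    month_index  = rep(0:11, times = n),
    prs      = stack12(prs0, prs_m),
    thank    = stack12(thank0, thank_m),
    gift     = stack12(gift0, gift_m),
    contr    = stack12(contr0, contr_m),
    article  = stack12(article0, article_m),
    patients = stack12(patients0, patients_m),
    views    = stack12(views0, views_m),
    treated  = rep(treated, each = 12L),
    post     = as.integer(rep(0:11, times = n) >= cutoff),
    stringsAsFactors = FALSE
  )
  attr(panel, "cutoff_index") <- cutoff
  attr(panel, "n_physicians") <- n
  class(panel) <- c("physician_panel", "data.frame")
  panel
}

#' Convert a cumulative series to initial state plus marginal changes
#'
#' Month 0 passes through as the initial cumulative state; every later month
#' becomes the change from the previous month, so that
#' `initial + cumsum(marginals)` reconstructs the cumulative series exactly.
#' A non-monotone cumulative count series yields negative marginals and a
#' warning (not an error: rating-score series legitimately decrease).
#'
#' @param x Numeric vector (one physician's cumulative values by month) or a
#'   matrix with one row per physician and one column per month.
#' @param warn_negative Warn when any marginal change is negative.
#' @return Same shape as `x`: initial state followed by marginal changes.
#' @examples
#' marginal_changes(c(139.3, 145.9, 152.3))  # 139.3, 6.6, 6.4
#' @export
marginal_changes <- function(x, warn_negative = TRUE) {
  if (is.matrix(x)) {
    if (ncol(x) < 2L)
      stop("cumulative series needs at least 2 time points", call. = FALSE)
    out <- cbind(x[, 1L], t(apply(x, 1L, diff)))
    dimnames(out) <- dimnames(x)
  } else {
    if (length(x) < 2L)
      stop("cumulative series needs at least 2 time points", call. = FALSE)
    out <- c(x[1L], diff(x))
  }
  if (warn_negative && any(out[-1L] < 0 & is.finite(out[-1L])))
    warning("non-monotone cumulative series: negative marginal change(s)",
            call. = FALSE)
  out
}

#' Write / read the long-format panel CSV
#'
#' Plain UTF-8 CSV with a header row and the canonical column order
#' `physician_id, month_index, prs, thank, gift, contr, article, patients,
#' views, treated, post`.  On reading, the cutoff month is recovered from
#' the `post` flag.
#'
#' @param panel A `physician_panel` data frame.
#' @param path File path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns a `physician_panel`.
#' @export
write_panel_csv <- function(panel, path) {
  cols <- panel_columns()
  missing <- setdiff(cols, names(panel))
  if (length(missing))
    stop("panel is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(as.data.frame(panel)[cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  missing <- setdiff(panel_columns(), names(panel))
  if (length(missing))
    stop("panel CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  post_months <- panel$month_index[panel$post == 1]
  attr(panel, "cutoff_index") <-
    if (length(post_months)) min(post_months) else NA_integer_
  attr(panel, "n_physicians") <- length(unique(panel$physician_id))
  class(panel) <- c("physician_panel", "data.frame")
  panel
}

panel_columns <- function() {
  c("physician_id", "month_index", ohc_covariates(),
    "patients", "views", "treated", "post")
}

#' Month-0 baseline (pre-treatment snapshot) of a panel
#'
#' One row per physician holding the cumulative initial state of the five
#' covariates; this is the covariate table the propensity stage fits on.
#'
#' @param panel A `physician_panel`.
#' @return Data frame with one row per physician.
#' @export
panel_baseline <- function(panel) {
  out <- as.data.frame(panel)[panel$month_index == 0,
                              c("physician_id", ohc_covariates(), "treated")]
  rownames(out) <- NULL
  out
}

#' @export
print.physician_panel <- function(x, ...) {
  n <- attr(x, "n_physicians")
  base <- x[x$month_index == 0, ]
  cat(sprintf(
    "Physician-month panel: %d physicians x 12 months (%d rows)\n",
    if (is.null(n)) length(unique(x$physician_id)) else n, nrow(x)))
  cat(sprintf("  treated: %d; cutoff month index: %s\n",
              sum(base$treated), format(attr(x, "cutoff_index"))))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
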
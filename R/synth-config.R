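#' Covariate names used throughout the package
#'
#' The five pre-treatment covariates measured for every physician: profile
#' rating score (`prs`), thank-you letters (`thank`), virtual gifts (`gift`),
#' platform contribution score (`contr`) and articles posted (`article`).
#'
#' @return Character vector of length 5.
#' @export
ohc_covariates <- function() c("prs", "thank", "gift", "contr", "article")

#' Configuration of the synthetic physician-month panel generator
#'
#' Describes the full data-generating process for a synthetic online-health-
#' community panel: 12 monthly observations per physician, an award cutoff
#' month, selection-on-observables treatment assignment through a latent
#' covariate score, and additive jumps in the outcome series at (or lagged
#' after) the cutoff for treated physicians.
#'
#' Treatment assignment uses a latent index
#' \eqn{s_i = w'x_i + \epsilon_i} with standard-logistic noise
#' \eqn{\epsilon_i}.  When `score_threshold` is `NA` (default) the
#' `n_treated` physicians with the largest latent scores are treated, so the
#' treated count is exact; when a finite threshold is given, treatment is
#' `s_i > threshold`, which makes the true assignment probability exactly
#' `plogis(w'x - threshold)` (the logistic model the propensity stage fits)
#' at the price of a random treated count.
#'
#' @param n_treated Number of treated physicians (award recipients).
#' @param n_control_pool Number of never-treated physicians in the matching
#'   pool.  Must be at least `n_treated`.
#' @param cutoff_index First post-award month index (0-based; default 6,
#'   i.e. the seventh month of the panel).
#' @param score_weights Named numeric vector: one weight per covariate (on
#'   the raw covariate scale) in the latent assignment score.
#' @param score_threshold `NA` for exact-count assignment, or a finite
#'   latent-score threshold for Bernoulli-logistic assignment.
#' @param jump_patients,jump_views Additive level shift in the monthly
#'   consultation / home-page-view series of treated physicians, starting at
#'   month `cutoff_index + lag_months`.  Outcome units per month.
#' @param lag_months Delay, in months, between the cutoff and the outcome
#'   jump.  `lag_months + cutoff_index` must leave post-jump months in the
#'   panel (at most 11).
#' @param pre_trend_slope Named numeric (`patients`, `views`): common linear
#'   drift of the monthly outcome means, outcome units per month.
#' @param physician_effect_sd Named numeric (`patients`, `views`): SD of the
#'   additive physician-level random intercept on each outcome, inducing
#'   within-physician correlation.
#' @param noise_dispersion Named numeric: `patients` is the negative-binomial
#'   size parameter of the consultation counts (smaller = more overdispersed);
#'   `views` is the log-scale SD of the log-normal view counts.
#' @param seed Integer seed; the generator is a pure function of the config.
#'
#' @return An object of class `synth_config` (a validated list).
#' @seealso [simulate_panel()]
#' @examples
#' cfg <- synth_config(n_treated = 50, n_control_pool = 200, seed = 7)
#' cfg
#' @export
synth_config <- function(n_treated = 346,
                         n_control_pool = 3000,
                         cutoff_index = 6,
                         score_weights = c(prs = 0.8, thank = 0.004,
                                           gift = 8e-4, contr = 6e-6,
                                           article = 0.008),
                         score_threshold = NA_real_,
                         jump_patients = 20,
                         jump_views = 80000,
                         lag_months = 0,
                         pre_trend_slope = c(patients = -3, views = -4000),
                         physician_effect_sd = c(patients = 30, views = 30000),
                         noise_dispersion = c(patients = 10, views = 0.3),
                         seed = 1L) {
  cfg <- list(n_treated = as.integer(n_treated),
              n_control_pool = as.integer(n_control_pool),
              cutoff_index = as.integer(cutoff_index),
              score_weights = score_weights,
              score_threshold = as.numeric(score_threshold),
              jump_patients = as.numeric(jump_patients),
              jump_views = as.numeric(jump_views),
              lag_months = as.integer(lag_months),
              pre_trend_slope = pre_trend_slope,
              physician_effect_sd = physician_effect_sd,
              noise_dispersion = noise_dispersion,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_treated < 1L)
    stop("invalid synth_config: n_treated must be >= 1", call. = FALSE)
  if (cfg$n_control_pool < cfg$n_treated)
    stop("invalid synth_config: n_control_pool (", cfg$n_control_pool,
         ") < n_treated (", cfg$n_treated,
         ") violates the matching-feasibility invariant", call. = FALSE)
  if (cfg$cutoff_index < 1L || cfg$cutoff_index > 11L)
    stop("invalid synth_config: cutoff_index must be in 1..11", call. = FALSE)
  if (cfg$lag_months < 0L)
    stop("invalid synth_config: lag_months must be >= 0", call. = FALSE)
  if (cfg$lag_months + cfg$cutoff_index > 11L)
    stop("invalid synth_config: lag_months + cutoff_index exceeds the last ",
         "panel month (11)", call. = FALSE)
  cov <- ohc_covariates()
  if (!all(cov %in% names(cfg$score_weights)))
    stop("invalid synth_config: score_weights must be named for all of: ",
         paste(cov, collapse = ", "), call. = FALSE)
  for (fld in c("pre_trend_slope", "physician_effect_sd", "noise_dispersion"))
    if (!all(c("patients", "views") %in% names(cfg[[fld]])))
      stop("invalid synth_config: ", fld,
           " must be named for 'patients' and 'views'", call. = FALSE)
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic panel configuration\n")
  cat(sprintf("  physicians: %d treated + %d control pool\n",
              x$n_treated, x$n_control_pool))
  cat(sprintf("  cutoff month index: %d; outcome-jump lag: %d month(s)\n",
              x$cutoff_index, x$lag_months))
  cat(sprintf("  jumps: patients %+g, views %+g per month\n",
              x$jump_patients, x$jump_views))
  thr <- if (is.na(x$score_threshold)) "exact-count (top latent scores)"
         else sprintf("latent threshold %g", x$score_threshold)
  cat("  assignment:", thr, "\n")
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Write / read a synthetic-panel configuration as a flat key-value file
#'
#' Plain-text serialization: one `key: value` line per field; vector fields
#' are comma-separated `name=value` entries.
#'
#' @param cfg A [synth_config()] object.
#' @param path File path.
#' @return `write_synth_config` returns `path` invisibly;
#'   `read_synth_config` returns a `synth_config`.
#' @export
write_synth_config <- function(cfg, path) {
  validate_synth_config(cfg)
  fmt <- function(v) {
    if (length(v) > 1L || !is.null(names(v)))
      paste(sprintf("%s=%.15g", names(v), unname(v)), collapse = ",")
    else sprintf("%.15g", v)
  }
  lines <- vapply(names(unclass(cfg)),
                  function(k) paste0(k, ": ", fmt(cfg[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  keys <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals <- vapply(kv, function(p) trimws(p[2]), character(1))
  parse_val <- function(s) {
    if (identical(s, "NA")) return(NA_real_)
    if (grepl("=", s, fixed = TRUE)) {
      parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
      v <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
      names(v) <- vapply(parts, function(p) trimws(p[1]), character(1))
      v
    } else as.numeric(s)
  }
  args <- lapply(vals, parse_val)
  names(args) <- keys
  do.call(synth_config, args)
}
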
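#' Differential treatment effect: treated jump minus control jump
#'
#' The difference-in-discontinuities: the treated group's estimated jump at
#' the cutoff minus the matched control group's, with standard error
#' combined under independence of the two group fits,
#' `SE = sqrt(SE_t^2 + SE_c^2)`.  This nets out any platform-wide level
#' shift common to both groups at the award date, leaving the effect
#' attributable to the honorary title.
#'
#' @param treated_fit,control_fit `rdd_fit` objects for the same outcome and
#'   method; mismatched labels are an error.
#' @return An object of class `rdd_differential` with `estimate`,
#'   `std_error`, `p_value`, the two group fits and the labels.
#' @export
differential_effect <- function(treated_fit, control_fit) {
  stopifnot(inherits(treated_fit, "rdd_fit"), inherits(control_fit, "rdd_fit"))
  if (!identical(treated_fit$method, control_fit$method))
    stop("method mismatch between fits: '", treated_fit$method, "' vs '",
         control_fit$method, "'", call. = FALSE)
  if (!is.null(treated_fit$outcome) && !is.null(control_fit$outcome) &&
      !identical(treated_fit$outcome, control_fit$outcome))
    stop("outcome mismatch between fits: '", treated_fit$outcome, "' vs '",
         control_fit$outcome, "'", call. = FALSE)
  est <- treated_fit$estimate - control_fit$estimate
  se <- sqrt(treated_fit$std_error^2 + control_fit$std_error^2)
  z <- est / se
  structure(list(
    estimate = est,
    std_error = se,
    p_value = 2 * stats::pnorm(-abs(z)),
    outcome = treated_fit$outcome,
    method = treated_fit$method,
    lag_months_applied = 0L,
    treated_fit = treated_fit,
    control_fit = control_fit
  ), class = "rdd_differential")
}

#' @export
print.rdd_differential <- function(x, ...) {
  cat(sprintf("Differential treatment effect (%s%s)\n",
              if (!is.null(x$outcome)) paste0(x$outcome, ", ") else "",
              x$method))
  cat(sprintf("  treated jump %.6g - control jump %.6g = %.6g\n",
              x$treated_fit$estimate, x$control_fit$estimate, x$estimate))
  cat(sprintf("  SE %.6g, p = %.3g", x$std_error, x$p_value))
  if (x$lag_months_applied > 0L)
    cat(sprintf("  (cutoff shifted by %d month(s))", x$lag_months_applied))
  cat("\n")
  invisible(x)
}

#' Scan for a lagged discontinuity
#'
#' Re-fits the chosen RDD estimator with the cutoff shifted by 0, 1, ...,
#' `max_lag` months and reports the full profile of jump estimates.  The
#' best lag is the shift maximizing the absolute standardized jump
#' `|estimate| / SE` (ties go to the smallest lag), mirroring the empirical
#' observation that an award's effect can surface with a delay.
#'
#' @inheritParams fit_rdd
#' @param max_lag Largest shift, in months, to try.  Every shifted cutoff
#'   must leave enough months on its right for the chosen estimator.
#' @param ... Further arguments passed to [fit_rdd()] (`order`, `bandwidth`,
#'   `kernel`, `cluster`, labels).
#' @return An object of class `rdd_lag_scan`: `profile` (data frame with
#'   `lag`, `cutoff_used`, `estimate`, `std_error`, `z`, `p_value`),
#'   `best_lag`, `best_fit`, and the per-lag `fits` list.
#' @export
scan_lag <- function(formula, data, cutoff, max_lag,
                     method = c("parametric", "local"), ...) {
  method <- match.arg(method)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("max_lag must be >= 0", call. = FALSE)
  mf <- stats::model.frame(formula, data)
  months <- sort(unique(mf[[2L]]))
  # the largest shifted cutoff still needs >= 2 months at or above it
  if (sum(months >= cutoff + max_lag) < 2L)
    stop(sprintf(paste0("max_lag %d pushes the shifted cutoff to %g, ",
                        "leaving fewer than 2 months on its right"),
                 max_lag, cutoff + max_lag), call. = FALSE)
  fits <- lapply(0:max_lag, function(l)
    fit_rdd(formula, data, cutoff = cutoff + l, method = method, ...))
  prof <- data.frame(
    lag = 0:max_lag,
    cutoff_used = cutoff + (0:max_lag),
    estimate = vapply(fits, `[[`, numeric(1), "estimate"),
    std_error = vapply(fits, `[[`, numeric(1), "std_error"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"))
  prof$z <- prof$estimate / prof$std_error
  best <- which.max(abs(prof$z))      # which.max returns the first maximum
  structure(list(profile = prof[, c("lag", "cutoff_used", "estimate",
                                    "std_error", "z", "p_value")],
                 best_lag = prof$lag[best],
                 best_fit = fits[[best]],
                 fits = fits,
                 method = method,
                 cutoff = cutoff),
            class = "rdd_lag_scan")
}

#' @export
print.rdd_lag_scan <- function(x, ...) {
  cat(sprintf("Lag scan (%s RDD, base cutoff %g):\n", x$method, x$cutoff))
  prof <- x$profile
  prof$estimate <- signif(prof$estimate, 6)
  prof$std_error <- signif(prof$std_error, 6)
  prof$z <- round(prof$z, 3)
  prof$p_value <- signif(prof$p_value, 3)
  print.data.frame(prof, row.names = FALSE)
  cat(sprintf("best lag: %d month(s) (max |estimate|/SE)\n", x$best_lag))
  invisible(x)
}

#' @export
plot.rdd_lag_scan <- function(x, ...) {
  prof <- x$profile
  plot(prof$lag, abs(prof$z), type = "b", pch = 19,
       xlab = "lag (months)", ylab = "|estimate| / SE", ...)
  graphics::abline(v = x$best_lag, lty = 3)
  invisible(x)
}
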
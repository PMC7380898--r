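#' Sharp regression-discontinuity fit at the award month
#'
#' Estimates the discontinuity (level jump) in a monthly outcome series at a
#' cutoff month.  The running variable is the integer month index centered
#' at the cutoff, `u = month - cutoff`; the first post-award month is the
#' cutoff month itself (`u >= 0`).
#'
#' Two estimators are provided:
#' \describe{
#'   \item{`parametric`}{a global polynomial of degree `order` with separate
#'     coefficients on each side of the cutoff plus a post-cutoff indicator:
#'     \eqn{y = a + \tau D + \sum_k b_k u^k + \sum_k c_k D u^k + e},
#'     estimated by least squares; the jump estimate is \eqn{\hat\tau}.}
#'   \item{`local`}{kernel-weighted local-linear regression: a single
#'     weighted fit of `y ~ D * u` using only months within `bandwidth` of
#'     the cutoff, weighted by `kernel((u)/bandwidth)`; the jump is the
#'     difference of the two fitted intercepts at the cutoff.}
#' }
#' Both are estimated as one regression so the standard error of the jump
#' coefficient can be made cluster-robust by physician
#' (`sandwich::vcovCL`), which accounts for repeated monthly observations
#' of the same physician.  p-values use the two-sided normal reference.
#'
#' @param formula `outcome ~ month` (one response, one running variable).
#' @param data Data frame of physician-month rows from a single group
#'   (treated or control).
#' @param cutoff Cutoff value of the running variable.
#' @param method `"parametric"` or `"local"`.
#' @param order Polynomial degree for the parametric fit (default 1).
#' @param bandwidth Window half-width, in months, for the local fit
#'   (default 3).
#' @param kernel `"triangular"` (default), `"uniform"` or `"epanechnikov"`.
#' @param cluster Cluster identifier for robust standard errors: a one-sided
#'   formula (e.g. `~ physician_id`), a column name, or a vector of length
#'   `nrow(data)`.  Default: each row is its own cluster
#'   (heteroskedasticity-robust only).
#' @param outcome_label,group_label Optional labels carried into the fit for
#'   bookkeeping (used by [differential_effect()] compatibility checks).
#' @return An object of class `rdd_fit`: `estimate` (the jump,
#'   outcome units per month), `std_error`, `p_value`, `left_limit`,
#'   `right_limit` (fitted expectations approaching the cutoff from either
#'   side; `estimate = right_limit - left_limit`), `n_obs`, `n_clusters`,
#'   `coefficients`, `vcov`, and the method metadata.
#' @examples
#' d <- data.frame(month = rep(1:11, each = 5))
#' d$y <- 1 + 2 * d$month + 5 * (d$month >= 6)
#' fit_rdd(y ~ month, d, cutoff = 6)$estimate   # 5
#' @export
fit_rdd <- function(formula, data, cutoff,
                    method = c("parametric", "local"),
                    order = 1L, bandwidth = 3, kernel = "triangular",
                    cluster = NULL, outcome_label = NULL,
                    group_label = NULL) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  if (ncol(mf) != 2L)
    stop("formula must be 'outcome ~ running_variable'", call. = FALSE)
  y <- mf[[1L]]
  t <- mf[[2L]]
  cl <- resolve_cluster(cluster, data)
  u <- t - cutoff
  D <- as.numeric(u >= 0)

  if (method == "parametric") {
    order <- as.integer(order)
    need <- order + 1L
    n_left <- length(unique(u[u < 0]))
    n_right <- length(unique(u[u >= 0]))
    if (n_left < need)
      stop(sprintf(paste0("insufficient months on the left of the cutoff: ",
                          "%d distinct, need >= %d for polynomial order %d"),
                   n_left, need, order), call. = FALSE)
    if (n_right < need)
      stop(sprintf(paste0("insufficient months on the right of the cutoff: ",
                          "%d distinct, need >= %d for polynomial order %d"),
                   n_right, need, order), call. = FALSE)
    dd <- data.frame(y = y, D = D)
    for (k in seq_len(order)) {
      dd[[paste0("u", k)]] <- u^k
      dd[[paste0("Du", k)]] <- D * u^k
    }
    fit <- stats::lm(y ~ ., data = dd)
    keep <- rep(TRUE, length(y))
    meta <- list(polynomial_order = order)
  } else {
    if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
    w <- kernel_weight(u / bandwidth, kernel)
    keep <- w > 0
    n_left <- length(unique(u[keep & u < 0]))
    n_right <- length(unique(u[keep & u >= 0]))
    if (n_left < 2L || n_right < 2L) {
      side <- if (n_left < 2L) "left" else "right"
      stop(sprintf(paste0("bandwidth %g leaves %d distinct month(s) with ",
                          "positive weight on the %s of the cutoff (need ",
                          ">= 2); minimal feasible bandwidth is %g"),
                   bandwidth, min(n_left, n_right), side,
                   minimal_bandwidth(u, kernel)), call. = FALSE)
    }
    dd <- data.frame(y = y[keep], D = D[keep], u = u[keep], w = w[keep])
    cl <- cl[keep]
    fit <- stats::lm(y ~ D * u, data = dd, weights = w)
    meta <- list(bandwidth_months = bandwidth, kernel = kernel)
  }

  # degenerate (noiseless) fits trip summary.lm's perfect-fit warning inside
  # the sandwich bread; the covariance itself is still well defined
  vc <- withCallingHandlers(
    sandwich::vcovCL(fit, cluster = cl),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  est <- unname(stats::coef(fit)["D"])
  se <- sqrt(vc["D", "D"])
  z <- est / se
  left <- unname(stats::coef(fit)["(Intercept)"])
  out <- c(list(
    estimate = est,
    std_error = se,
    p_value = 2 * stats::pnorm(-abs(z)),
    left_limit = left,
    right_limit = left + est,
    n_obs = sum(keep),
    n_clusters = length(unique(cl)),
    method = method,
    cutoff = cutoff,
    coefficients = stats::coef(fit),
    vcov = vc,
    outcome = outcome_label,
    group = group_label,
    call = match.call()
  ), meta)
  class(out) <- "rdd_fit"
  out
}

kernel_weight <- function(v, kernel) {
  switch(kernel,
         triangular = pmax(1 - abs(v), 0),
         uniform = as.numeric(abs(v) <= 1),
         epanechnikov = pmax(0.75 * (1 - v^2), 0),
         stop("unknown kernel '", kernel, "'", call. = FALSE))
}

# smallest bandwidth giving >= 2 positively weighted distinct months per side
minimal_bandwidth <- function(u, kernel) {
  lf <- sort(unique(abs(u[u < 0])))
  rt <- sort(unique(u[u >= 0]))
  if (length(lf) < 2L || length(rt) < 2L) return(Inf)
  h <- max(lf[2L], rt[2L])
  if (kernel == "triangular") h + 1 else h   # triangular weight is 0 at |u|=h
}

resolve_cluster <- function(cluster, data) {
  if (is.null(cluster)) return(seq_len(nrow(data)))
  if (inherits(cluster, "formula")) {
    v <- all.vars(cluster)
    return(interaction(data[v], drop = TRUE))
  }
  if (is.character(cluster) && length(cluster) == 1L &&
      cluster %in% names(data))
    return(data[[cluster]])
  if (length(cluster) != nrow(data))
    stop("cluster must match the number of rows in 'data'", call. = FALSE)
  cluster
}

#' @export
print.rdd_fit <- function(x, ...) {
  lab <- paste0(
    if (!is.null(x$outcome)) paste0(x$outcome, ", ") else "",
    if (!is.null(x$group)) paste0(x$group, " group, ") else "")
  cat(sprintf("Sharp RDD fit (%s%s) at cutoff %g\n", lab, x$method, x$cutoff))
  if (x$method == "parametric")
    cat(sprintf("  polynomial order %d on each side\n", x$polynomial_order))
  else
    cat(sprintf("  %s kernel, bandwidth %g months\n", x$kernel,
                x$bandwidth_months))
  cat(sprintf("  jump estimate: %.6g (SE %.6g, p = %.3g)\n",
              x$estimate, x$std_error, x$p_value))
  cat(sprintf("  limits at cutoff: left %.6g -> right %.6g\n",
              x$left_limit, x$right_limit))
  cat(sprintf("  n = %d observations in %d clusters\n",
              x$n_obs, x$n_clusters))
  invisible(x)
}

#' @export
coef.rdd_fit <- function(object, ...) object$coefficients

#' @export
vcov.rdd_fit <- function(object, ...) object$vcov

#' @export
summary.rdd_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.rdd_fit"
  out
}

#' @export
print.summary.rdd_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (cluster-robust):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Predicted regression function of an RDD fit
#'
#' Evaluates the fitted conditional-mean function at given months (on the
#' original running-variable scale).  For the local fit, months outside the
#' bandwidth are extrapolations of the two local lines.
#'
#' @param object An `rdd_fit`.
#' @param months Numeric vector of running-variable values.
#' @param ... Unused.
#' @return Numeric vector of fitted expectations.
#' @export
predict.rdd_fit <- function(object, months, ...) {
  u <- months - object$cutoff
  D <- as.numeric(u >= 0)
  b <- object$coefficients
  if (object$method == "parametric") {
    yhat <- b[["(Intercept)"]] + b[["D"]] * D
    for (k in seq_len(object$polynomial_order))
      yhat <- yhat + b[[paste0("u", k)]] * u^k + b[[paste0("Du", k)]] * D * u^k
  } else {
    yhat <- b[["(Intercept)"]] + b[["D"]] * D + b[["u"]] * u +
      b[["D:u"]] * D * u
  }
  unname(yhat)
}

#' Plot monthly means and the fitted discontinuity
#'
#' @param x An `rdd_fit`.
#' @param data,formula The data and formula used for the fit (monthly means
#'   are recomputed from them for display).
#' @param ... Passed to [plot()].
#' @export
plot.rdd_fit <- function(x, data = NULL, formula = NULL, ...) {
  if (!is.null(data) && !is.null(formula)) {
    mf <- stats::model.frame(formula, data)
    mm <- tapply(mf[[1L]], mf[[2L]], mean)
    months <- as.numeric(names(mm))
    plot(months, mm, pch = 19, xlab = "month index", ylab = "monthly mean",
         ...)
  } else {
    months <- seq(x$cutoff - 5, x$cutoff + 5, by = 0.1)
    plot(NA, xlim = range(months), ylim = range(predict(x, months)),
         xlab = "month index", ylab = "fitted outcome", ...)
  }
  lf <- seq(min(months), x$cutoff - 1e-9, length.out = 50)
  rt <- seq(x$cutoff, max(months), length.out = 50)
  graphics::lines(lf, predict(x, lf), col = "steelblue", lwd = 2)
  graphics::lines(rt, predict(x, rt), col = "firebrick", lwd = 2)
  graphics::abline(v = x$cutoff - 0.5, lty = 3)
  invisible(x)
}
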
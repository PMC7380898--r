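#' Fit a logistic propensity-score model by maximum likelihood
#'
#' Estimates the probability of receiving the honorary title from
#' pre-treatment covariates with a plain logistic regression, fitted by
#' Newton--Raphson with step-halving (an iteratively reweighted scheme).
#' The log-likelihood is non-decreasing across iterations; convergence is
#' declared when the score (gradient) max-norm falls below `tol`.
#' Perfect separation is detected (all treated fitted arbitrarily close to
#' 1 and all controls to 0 while the likelihood keeps climbing) and flagged
#' rather than silently penalized: the object then carries
#' `converged = FALSE`, `separated = TRUE` and the coefficients at the last
#' iterate.
#'
#' @param x A formula such as `treated ~ prs + thank + gift + contr +
#'   article` (with `data`), or a numeric covariate matrix (with `y`).
#' @param ... Passed to methods.
#' @return An object of class `propensity_model` with components
#'   `coefficients` (intercept first), `covariate_names`, `converged`,
#'   `separated`, `n_iterations`, `log_likelihood`, `loglik_trace`, `vcov`
#'   (inverse observed information), `fitted`, `n`, `n_treated`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
#' d$treated <- rbinom(200, 1, plogis(0.5 * d$x1 - d$x2))
#' fit <- fit_propensity(treated ~ x1 + x2, d)
#' summary(fit)
#' @export
fit_propensity <- function(x, ...) UseMethod("fit_propensity")

#' @rdname fit_propensity
#' @param data Data frame holding the formula variables.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @export
fit_propensity.formula <- function(x, data, tol = 1e-8, max_iter = 100L, ...) {
  mf <- stats::model.frame(x, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- logistic_newton(X, y, tol = tol, max_iter = max_iter)
  fit$formula <- x
  fit$terms <- attr(mf, "terms")
  fit
}

#' @rdname fit_propensity
#' @param y Binary treatment flags (0/1), one per row of the matrix.
#' @export
fit_propensity.default <- function(x, y, tol = 1e-8, max_iter = 100L, ...) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (anyNA(x) || anyNA(y))
    stop("missing values in covariates or treatment flags", call. = FALSE)
  X <- cbind("(Intercept)" = 1, x)
  logistic_newton(X, y, tol = tol, max_iter = max_iter)
}

# Newton-Raphson / IRLS core on a design matrix that already has a constant
logistic_newton <- function(X, y, tol = 1e-8, max_iter = 100L) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)))
    stop("treatment flags must be binary 0/1", call. = FALSE)
  if (all(y == 1))
    stop("degenerate input: all physicians are treated (treated == 1 for ",
         "every row); the logistic likelihood is unbounded", call. = FALSE)
  if (all(y == 0))
    stop("degenerate input: all physicians are controls (treated == 0 for ",
         "every row); the logistic likelihood is unbounded", call. = FALSE)

  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  ll <- logistic_loglik(X, y, beta)
  trace <- ll
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  H <- crossprod(X) / 4      # information at beta = 0, placeholder

  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    pr <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - pr))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    wt <- pmax(pr * (1 - pr), 1e-12)
    H <- crossprod(X, X * wt)
    delta <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-10 * max(diag(H)), p), grad))
    # step-halving: never let the log-likelihood decrease
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- logistic_loglik(X, y, cand)
      if (ll_new >= ll - 1e-12 || step < 2^-30) break
      step <- step / 2
    }
    if (ll_new < ll) break   # no ascent step found: stop at current iterate
    beta <- beta + step * delta
    ll <- ll_new
    trace <- c(trace, ll)
    pr <- stats::plogis(drop(X %*% beta))
    if (min(pr[y == 1]) > 1 - 1e-6 && max(pr[y == 0]) < 1e-6) {
      separated <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  pr <- stats::plogis(eta)
  wt <- pmax(pr * (1 - pr), 1e-12)
  H <- crossprod(X, X * wt)
  vc <- tryCatch(solve(H), error = function(e)
    solve(H + diag(1e-10 * max(diag(H)), p)))
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    covariate_names = setdiff(colnames(X), "(Intercept)"),
    converged = converged && !separated,
    separated = separated,
    n_iterations = iter,
    log_likelihood = logistic_loglik(X, y, beta),
    loglik_trace = trace,
    vcov = vc,
    fitted = pr,
    y = y,
    n = n,
    n_treated = sum(y == 1)
  ), class = "propensity_model")
}

# overflow-safe bernoulli log-likelihood: sum y*eta - log(1 + exp(eta))
logistic_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

#' Predict propensity scores
#'
#' @param object A `propensity_model`.
#' @param newdata Data frame (formula fits) or covariate matrix/data frame
#'   with columns matching `object$covariate_names`.  Omitted: returns the
#'   fitted scores.
#' @param ... Unused.
#' @return Probabilities strictly inside (0, 1).
#' @export
predict.propensity_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (!is.null(object$terms)) {
    needed <- all.vars(stats::delete.response(object$terms))
  } else {
    needed <- object$covariate_names
  }
  have <- colnames(newdata)
  missing <- setdiff(needed, have)
  if (length(missing))
    stop("covariate columns do not match the fitted model; missing: ",
         paste(missing, collapse = ", "),
         if (length(setdiff(have, needed)))
           paste0("; extra: ", paste(setdiff(have, needed), collapse = ", ")),
         call. = FALSE)
  if (!is.null(object$terms)) {
    tt <- stats::delete.response(object$terms)
    X <- stats::model.matrix(tt, stats::model.frame(tt, as.data.frame(newdata),
                                                    na.action = stats::na.fail))
  } else {
    X <- cbind("(Intercept)" = 1,
               as.matrix(as.data.frame(newdata)[, object$covariate_names,
                                                drop = FALSE]))
  }
  pr <- stats::plogis(drop(X %*% object$coefficients[colnames(X)]))
  # clamp away from exact 0/1 so downstream logits stay finite
  pmin(pmax(pr, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' @export
coef.propensity_model <- function(object, ...) object$coefficients

#' @export
vcov.propensity_model <- function(object, ...) object$vcov

#' @export
logLik.propensity_model <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients), class = "logLik")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Logistic propensity-score model\n")
  cat(sprintf("  n = %d physicians (%d treated), logLik = %.3f\n",
              x$n, x$n_treated, x$log_likelihood))
  if (x$separated)
    cat("  WARNING: perfect separation detected; coefficients are the last\n",
        "  Newton iterate and diverge with further iterations\n", sep = "")
  else
    cat(sprintf("  converged in %d iterations\n", x$n_iterations))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
summary.propensity_model <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, model = object)
  class(out) <- "summary.propensity_model"
  out
}

#' @export
print.summary.propensity_model <- function(x, ...) {
  print(x$model)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}
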
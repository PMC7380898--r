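#' Greedy nearest-neighbour propensity-score matching without replacement
#'
#' Pairs each treated physician with the `n_matches` closest untreated
#' physicians by absolute propensity-score distance.  Matching is greedy and
#' without replacement: treated units are processed in descending propensity
#' score (hardest to match first), each consuming its nearest still-available
#' controls; among equidistant controls the lowest identifier wins, so the
#' result is deterministic.  With a caliper, controls farther than `caliper`
#' in PS distance are ineligible; a treated unit that cannot obtain all
#' `n_matches` eligible controls is left unmatched (and listed in
#' `unmatched_treated`).
#'
#' @param ps_treated Named numeric vector of propensity scores for treated
#'   physicians (names are identifiers).
#' @param ps_control Named numeric vector for the control pool.
#' @param n_matches Controls per treated unit (default 1 = one-to-one).
#' @param caliper Maximum PS distance for a valid pair, strictly positive,
#'   or `NULL` (default) for no caliper.
#' @return An object of class `ps_match`: `pairs` (data frame with
#'   `treated_id`, `control_id`, `ps_treated`, `ps_control`, `distance`),
#'   `n_matches`, `caliper`, `unmatched_treated`, `n_treated`, `n_control`.
#' @examples
#' m <- match_nearest(c(a = 0.6), c(u = 0.1, v = 0.59))
#' m$pairs
#' @export
match_nearest <- function(ps_treated, ps_control, n_matches = 1L,
                          caliper = NULL) {
  if (length(ps_treated) == 0L)
    stop("empty treated set", call. = FALSE)
  if (length(ps_control) == 0L)
    stop("empty control set", call. = FALSE)
  if (!is.null(caliper) && caliper <= 0)
    stop("caliper must be strictly positive (got ", caliper, ")",
         call. = FALSE)
  n_matches <- as.integer(n_matches)
  if (n_matches < 1L) stop("n_matches must be >= 1", call. = FALSE)
  if (is.null(names(ps_treated)))
    names(ps_treated) <- paste0("T", seq_along(ps_treated))
  if (is.null(names(ps_control)))
    names(ps_control) <- paste0("C", seq_along(ps_control))

  # process treated in descending PS; ties broken by ascending identifier
  t_ord <- order(-ps_treated, names(ps_treated))
  c_ids <- names(ps_control)
  # pre-sort controls by identifier so which/head tie-breaks pick lowest id
  c_ord <- order(c_ids)
  psc <- ps_control[c_ord]
  c_ids <- c_ids[c_ord]
  available <- rep(TRUE, length(psc))

  pair_t <- character(0); pair_c <- character(0)
  pair_pst <- numeric(0); pair_psc <- numeric(0)
  unmatched <- character(0)
  for (i in t_ord) {
    pst <- ps_treated[i]
    d <- abs(psc - pst)
    ok <- available
    if (!is.null(caliper)) ok <- ok & (d <= caliper)
    idx <- which(ok)
    if (length(idx) < n_matches) {
      unmatched <- c(unmatched, names(ps_treated)[i])
      next
    }
    # stable order: distance, then identifier (already id-sorted)
    pick <- idx[order(d[idx])][seq_len(n_matches)]
    available[pick] <- FALSE
    pair_t <- c(pair_t, rep(names(ps_treated)[i], n_matches))
    pair_c <- c(pair_c, c_ids[pick])
    pair_pst <- c(pair_pst, rep(unname(pst), n_matches))
    pair_psc <- c(pair_psc, unname(psc[pick]))
  }
  pairs <- data.frame(treated_id = pair_t, control_id = pair_c,
                      ps_treated = pair_pst, ps_control = pair_psc,
                      distance = abs(pair_pst - pair_psc),
                      stringsAsFactors = FALSE)
  # report pairs in treated-id order for readability
  pairs <- pairs[order(pairs$treated_id, pairs$control_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n_matches = n_matches, caliper = caliper,
                 unmatched_treated = sort(unmatched),
                 n_treated = length(ps_treated),
                 n_control = length(ps_control)),
            class = "ps_match")
}

#' @export
print.ps_match <- function(x, ...) {
  cat(sprintf(
    "Propensity-score match: %d treated, %d controls, 1:%d without replacement\n",
    x$n_treated, x$n_control, x$n_matches))
  cat(sprintf("  matched treated: %d; unmatched: %d%s\n",
              x$n_treated - length(x$unmatched_treated),
              length(x$unmatched_treated),
              if (is.null(x$caliper)) "" else
                sprintf("; caliper = %g", x$caliper)))
  if (nrow(x$pairs))
    cat(sprintf("  PS distance: median %.4g, max %.4g\n",
                stats::median(x$pairs$distance), max(x$pairs$distance)))
  invisible(x)
}

#' Absolute standardized difference between two groups
#'
#' The unit-free covariate-balance diagnostic: the absolute difference in
#' group means divided by the square root of the average of the two sample
#' variances (denominator n-1), i.e.
#' \deqn{ASD = |\bar x_T - \bar x_C| / \sqrt{(s^2_T + s^2_C)/2}.}
#' Symmetric under group exchange and invariant to rescaling both groups.
#'
#' @param x_treat,x_control Numeric vectors (each of length >= 2).
#' @param label Optional covariate name used in error messages.
#' @return A non-negative scalar.
#' @examples
#' absolute_standardized_difference(c(2, 4), c(1, 3))  # 1/sqrt(2)
#' @export
absolute_standardized_difference <- function(x_treat, x_control,
                                             label = NULL) {
  if (length(x_treat) < 2L || length(x_control) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  v <- (stats::var(x_treat) + stats::var(x_control)) / 2
  if (!is.finite(v) || v <= 0)
    stop("zero pooled variance",
         if (!is.null(label)) paste0(" for covariate '", label, "'"),
         ": the standardized difference is undefined", call. = FALSE)
  abs(mean(x_treat) - mean(x_control)) / sqrt(v)
}

#' Covariate balance before and after matching
#'
#' Computes the absolute standardized difference for each of the five
#' baseline covariates (month-0 cumulative state) and for the propensity
#' score itself, comparing treated physicians against the full control pool
#' (before matching) and against the matched controls (after).
#'
#' @param panel A `physician_panel`.
#' @param ps Named vector of propensity scores for every physician in the
#'   panel (names = `physician_id`).
#' @param match A [match_nearest()] result whose identifiers appear in the
#'   panel.
#' @return A `balance_report`: data frame with one row per covariate (plus
#'   `ps`) and columns `covariate`, `mean_treated`, `var_treated`,
#'   `mean_pool`, `var_pool`, `asd_before`, `mean_matched`, `var_matched`,
#'   `asd_after`.
#' @export
balance_report <- function(panel, ps, match) {
  base <- panel_baseline(panel)
  ids <- base$physician_id
  unknown <- setdiff(c(match$pairs$treated_id, match$pairs$control_id), ids)
  if (length(unknown))
    stop("match refers to physician id(s) absent from the panel: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  if (is.null(names(ps))) names(ps) <- ids
  base$ps <- unname(ps[base$physician_id])

  treat <- base[base$treated == 1, ]
  pool <- base[base$treated == 0, ]
  matched_t <- treat[treat$physician_id %in% match$pairs$treated_id, ]
  matched_c <- base[base$physician_id %in% match$pairs$control_id, ]

  vars <- c(ohc_covariates(), "ps")
  rows <- lapply(vars, function(v) {
    data.frame(
      covariate = v,
      mean_treated = mean(treat[[v]]), var_treated = stats::var(treat[[v]]),
      mean_pool = mean(pool[[v]]), var_pool = stats::var(pool[[v]]),
      asd_before = absolute_standardized_difference(treat[[v]], pool[[v]],
                                                    label = v),
      mean_matched = mean(matched_c[[v]]),
      var_matched = stats::var(matched_c[[v]]),
      asd_after = absolute_standardized_difference(matched_t[[v]],
                                                   matched_c[[v]], label = v),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("balance_report", "data.frame")
  out
}

#' @export
print.balance_report <- function(x, digits = 4, ...) {
  cat("Covariate balance (absolute standardized differences)\n")
  show <- data.frame(covariate = x$covariate,
                     asd_before = round(x$asd_before, digits),
                     asd_after = round(x$asd_after, digits))
  print.data.frame(show, row.names = FALSE)
  cat(sprintf("mean ASD: %.4f before -> %.4f after matching\n",
              mean(x$asd_before), mean(x$asd_after)))
  invisible(x)
}

#' Write match pairs / balance report as tidy CSV
#'
#' @param x A `ps_match` or `balance_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_match_csv <- function(x, path) {
  stopifnot(inherits(x, "ps_match"))
  utils::write.csv(x$pairs[, c("treated_id", "control_id")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_match_csv
#' @export
write_balance_csv <- function(x, path) {
  stopifnot(inherits(x, "balance_report"))
  utils::write.csv(as.data.frame(x)[, c("covariate", "asd_before",
                                        "asd_after")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
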
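#' Configuration of the end-to-end analysis pipeline
#'
#' Bundles every tunable of the analysis: the input panel (either a CSV path
#' or a [synth_config()] to simulate from — exactly one of the two),
#' matching parameters, RDD parameters and output options.
#'
#' @param synth A [synth_config()], or `NULL` when reading a CSV.
#' @param panel_csv Path to a long-format panel CSV, or `NULL`.
#' @param cutoff_index Cutoff month; defaults to the panel's own cutoff.
#' @param n_matches Controls matched per treated physician.
#' @param caliper Optional propensity-score caliper (`NULL` = none; `"auto"`
#'   = 0.2 x SD of the logit propensity score, the conventional choice).
#' @param order Polynomial order of the parametric RDD.
#' @param bandwidth,kernel Local-linear RDD window (months) and kernel.
#' @param max_lag Largest lag scanned for a delayed discontinuity.
#' @param log_transform Analyze `log1p` of the outcomes instead of raw
#'   counts (off by default; estimates are then on the log scale).
#' @param output_dir Directory for run artifacts (`NULL` = write nothing).
#' @param seed Overrides the synth config's seed when given.
#' @param verbose Emit one progress message per stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, panel_csv = NULL,
                            cutoff_index = NULL, n_matches = 1L,
                            caliper = NULL, order = 1L, bandwidth = 3,
                            kernel = "triangular", max_lag = 3L,
                            log_transform = FALSE, output_dir = NULL,
                            seed = NULL, verbose = TRUE) {
  if (is.null(synth) == is.null(panel_csv))
    stop("exactly one of 'synth' or 'panel_csv' must be given",
         call. = FALSE)
  if (!is.null(synth)) {
    validate_synth_config(synth)
    if (!is.null(seed)) synth$seed <- as.integer(seed)
  }
  structure(list(synth = synth, panel_csv = panel_csv,
                 cutoff_index = cutoff_index,
                 n_matches = as.integer(n_matches), caliper = caliper,
                 order = as.integer(order), bandwidth = bandwidth,
                 kernel = kernel, max_lag = as.integer(max_lag),
                 log_transform = isTRUE(log_transform),
                 output_dir = output_dir, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Validate a physician-month panel against the schema invariants
#'
#' Checks, rule by rule: required columns present; every physician has
#' exactly the 12 months 0--11; the treated flag is binary and constant
#' within physician; `post` is binary and equals `month_index >= cutoff`;
#' count variables are non-negative; the month-0 rating score lies in
#' [0, 5] and its reconstructed cumulative series stays in [0, 5].
#'
#' @param panel A `physician_panel` data frame or a path to a panel CSV.
#' @return An object of class `panel_validation`: a data frame of `rule`,
#'   `pass`, `detail` rows with attribute `all_pass`.
#' @export
validate_panel <- function(panel) {
  if (is.character(panel)) panel <- read_panel_csv(panel)
  rules <- list()
  add <- function(rule, pass, detail = "") {
    rules[[length(rules) + 1L]] <<- data.frame(rule = rule, pass = pass,
                                               detail = detail,
                                               stringsAsFactors = FALSE)
  }
  missing <- setdiff(panel_columns(), names(panel))
  add("required columns", length(missing) == 0L,
      if (length(missing)) paste("missing:", paste(missing, collapse = ", "))
      else "")
  if (length(missing)) {
    out <- do.call(rbind, rules)
    attr(out, "all_pass") <- FALSE
    class(out) <- c("panel_validation", "data.frame")
    return(out)
  }

  by_id <- split(panel$month_index, panel$physician_id)
  bad_bal <- names(by_id)[!vapply(by_id, function(m)
    length(m) == 12L && setequal(m, 0:11), logical(1))]
  add("balanced panel (12 months 0-11 per physician)",
      length(bad_bal) == 0L,
      if (length(bad_bal)) paste("unbalanced physician(s):",
                                 paste(utils::head(bad_bal, 5L),
                                       collapse = ", ")) else "")

  add("treated flag binary", all(panel$treated %in% c(0, 1)))
  add("post flag binary", all(panel$post %in% c(0, 1)))

  tr_by_id <- split(panel$treated, panel$physician_id)
  bad_tr <- names(tr_by_id)[vapply(tr_by_id, function(v)
    length(unique(v)) > 1L, logical(1))]
  add("treated constant within physician", length(bad_tr) == 0L,
      if (length(bad_tr)) paste("varies for:",
                                paste(utils::head(bad_tr, 5L),
                                      collapse = ", ")) else "")

  cutoff <- attr(panel, "cutoff_index")
  if (is.null(cutoff) || is.na(cutoff))
    cutoff <- suppressWarnings(min(panel$month_index[panel$post == 1]))
  post_ok <- is.finite(cutoff) &&
    all(panel$post == as.integer(panel$month_index >= cutoff))
  add("post consistent with a single cutoff month", isTRUE(post_ok),
      if (!isTRUE(post_ok)) "post != 1[month_index >= cutoff]" else
        sprintf("cutoff_index = %d", as.integer(cutoff)))

  counts <- c("thank", "gift", "article", "patients", "views")
  neg <- counts[vapply(counts, function(v) any(panel[[v]] < 0), logical(1))]
  add("count variables non-negative", length(neg) == 0L,
      if (length(neg)) paste("negative values in:",
                             paste(neg, collapse = ", ")) else "")

  prs0 <- panel$prs[panel$month_index == 0]
  add("month-0 rating score within [0, 5]",
      all(prs0 >= 0 & prs0 <= 5))
  prs_cum_ok <- all(vapply(split(panel[order(panel$month_index), ],
                                 panel$physician_id[order(panel$month_index)]),
                           function(d) {
                             cs <- cumsum(d$prs)
                             all(cs >= -1e-6 & cs <= 5 + 1e-6)
                           }, logical(1)))
  add("reconstructed cumulative rating score within [0, 5]", prs_cum_ok)

  out <- do.call(rbind, rules)
  rownames(out) <- NULL
  attr(out, "all_pass") <- all(out$pass)
  class(out) <- c("panel_validation", "data.frame")
  out
}

#' @export
print.panel_validation <- function(x, ...) {
  cat("Panel validation:",
      if (attr(x, "all_pass")) "PASS" else "FAIL", "\n")
  df <- as.data.frame(x)
  df$pass <- ifelse(df$pass, "ok", "FAIL")
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Run the full honorary-title analysis pipeline
#'
#' Executes the study design end to end, in order: obtain the panel
#' (simulate or read), validate it, fit the logistic propensity model on
#' the month-0 covariate snapshot, match treated to pool controls 1:N on
#' the propensity score, compute the balance report, restrict estimation to
#' treated plus matched controls, fit the four RDD cells per outcome
#' (group x method) on the monthly-flow months (1--11), form differential
#' effects, and scan for lagged discontinuities.  The report is a
#' deterministic function of the configuration.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `ohc_run_report` holding the propensity model,
#'   match, balance report, the `rdd_fits` list (8 cells), `differentials`,
#'   `lag_scans` and a provenance block (seed, config hash, version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message("[ohctitle] ", sprintf(...))

  if (!is.null(config$synth)) {
    say("simulating panel (seed %d)", config$synth$seed)
    panel <- simulate_panel(config$synth)
  } else {
    say("reading panel from %s", config$panel_csv)
    panel <- read_panel_csv(config$panel_csv)
  }
  val <- validate_panel(panel)
  if (!attr(val, "all_pass")) {
    bad <- as.data.frame(val)[!val$pass, ]
    stop("panel failed validation:\n",
         paste(sprintf("  - %s%s", bad$rule,
                       ifelse(nzchar(bad$detail),
                              paste0(" (", bad$detail, ")"), "")),
               collapse = "\n"), call. = FALSE)
  }
  cutoff <- if (!is.null(config$cutoff_index)) config$cutoff_index
            else attr(panel, "cutoff_index")

  base <- panel_baseline(panel)
  say("fitting propensity model on %d physicians", nrow(base))
  ps_form <- stats::reformulate(ohc_covariates(), response = "treated")
  psm <- fit_propensity(ps_form, base)
  ps <- stats::setNames(predict(psm, base), base$physician_id)

  caliper <- config$caliper
  if (identical(caliper, "auto"))
    caliper <- 0.2 * stats::sd(stats::qlogis(ps))
  treated_ids <- base$physician_id[base$treated == 1]
  control_ids <- base$physician_id[base$treated == 0]
  say("matching %d treated against %d pool controls (1:%d)",
      length(treated_ids), length(control_ids), config$n_matches)
  match <- match_nearest(ps[treated_ids], ps[control_ids],
                         n_matches = config$n_matches, caliper = caliper)
  balance <- balance_report(panel, ps, match)
  say("balance: mean ASD %.3f -> %.3f", mean(balance$asd_before),
      mean(balance$asd_after))

  keep_ids <- c(treated_ids, unique(match$pairs$control_id))
  flows <- as.data.frame(panel)[panel$physician_id %in% keep_ids &
                                  panel$month_index >= 1, ]
  if (config$log_transform) {
    flows$patients <- log1p(flows$patients)
    flows$views <- log1p(flows$views)
  }

  outcomes <- c("patients", "views")
  groups <- c(treated = 1, control = 0)
  methods <- c("parametric", "local")
  fits <- list()
  for (oc in outcomes) {
    for (g in names(groups)) {
      d <- flows[flows$treated == groups[[g]], ]
      for (m in methods) {
        say("RDD: %s / %s / %s (n = %d)", oc, g, m, nrow(d))
        fits[[paste(oc, g, m, sep = ".")]] <-
          fit_rdd(stats::reformulate("month_index", response = oc), d,
                  cutoff = cutoff, method = m, order = config$order,
                  bandwidth = config$bandwidth, kernel = config$kernel,
                  cluster = "physician_id", outcome_label = oc,
                  group_label = g)
      }
    }
  }
  diffs <- list()
  for (oc in outcomes)
    for (m in methods)
      diffs[[paste(oc, m, sep = ".")]] <-
        differential_effect(fits[[paste(oc, "treated", m, sep = ".")]],
                            fits[[paste(oc, "control", m, sep = ".")]])

  scans <- list()
  if (config$max_lag > 0L) {
    for (oc in outcomes)
      for (g in names(groups)) {
        d <- flows[flows$treated == groups[[g]], ]
        scans[[paste(oc, g, sep = ".")]] <-
          scan_lag(stats::reformulate("month_index", response = oc), d,
                   cutoff = cutoff, max_lag = config$max_lag,
                   method = "parametric", order = config$order,
                   cluster = "physician_id", outcome_label = oc,
                   group_label = g)
      }
  }

  cfg_for_hash <- config
  cfg_for_hash$verbose <- NULL
  report <- structure(list(
    propensity = psm,
    match = match,
    balance = balance,
    rdd_fits = fits,
    differentials = diffs,
    lag_scans = scans,
    cutoff_index = cutoff,
    n_treated = length(treated_ids),
    n_control_pool = length(control_ids),
    config = config,
    provenance = list(
      seed = if (!is.null(config$synth)) config$synth$seed else NA_integer_,
      config_hash = fnv1a_hash(paste(deparse(cfg_for_hash),
                                     collapse = "\n")),
      package_version = as.character(utils::packageVersion("ohctitle")))
  ), class = "ohc_run_report")

  if (!is.null(config$output_dir)) {
    say("writing artifacts to %s", config$output_dir)
    write_run_report(report, config$output_dir,
                     panel = if (!is.null(config$synth)) panel else NULL)
  }
  report
}

#' Tabulate the eight RDD cells of a run report
#'
#' One row per outcome x group x method, mirroring the conventional results
#' layout: estimate, cluster-robust SE, number of physician-month
#' observations used, and the two-sided p-value.
#'
#' @param report An `ohc_run_report`.
#' @return A data frame with columns `outcome`, `group`, `method`,
#'   `estimate`, `std_error`, `n_obs`, `p_value`.
#' @export
rdd_results_table <- function(report) {
  stopifnot(inherits(report, "ohc_run_report"))
  rows <- lapply(report$rdd_fits, function(f)
    data.frame(outcome = f$outcome, group = f$group, method = f$method,
               estimate = f$estimate, std_error = f$std_error,
               n_obs = f$n_obs, p_value = f$p_value,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the artifacts of a pipeline run to a directory
#'
#' Writes `matches.csv`, `balance.csv`, `rdd_results.csv`,
#' `differential.csv`, `lag_scan.csv`, a plain-text `report.txt`, and
#' `panel.csv` when a simulated panel is supplied.
#'
#' @param report An `ohc_run_report`.
#' @param dir Output directory (created if needed).
#' @param panel Optional simulated panel to include.
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir, panel = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(panel)) write_panel_csv(panel, file.path(dir, "panel.csv"))
  write_match_csv(report$match, file.path(dir, "matches.csv"))
  write_balance_csv(report$balance, file.path(dir, "balance.csv"))
  utils::write.csv(rdd_results_table(report),
                   file.path(dir, "rdd_results.csv"), row.names = FALSE,
                   quote = FALSE)
  dif <- do.call(rbind, lapply(report$differentials, function(d)
    data.frame(outcome = d$outcome, method = d$method, estimate = d$estimate,
               std_error = d$std_error, p_value = d$p_value,
               stringsAsFactors = FALSE)))
  utils::write.csv(dif, file.path(dir, "differential.csv"),
                   row.names = FALSE, quote = FALSE)
  if (length(report$lag_scans)) {
    lag <- do.call(rbind, lapply(names(report$lag_scans), function(k) {
      p <- report$lag_scans[[k]]$profile
      cbind(data.frame(cell = k, stringsAsFactors = FALSE), p)
    }))
    utils::write.csv(lag, file.path(dir, "lag_scan.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  writeLines(utils::capture.output(print(report)),
             file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.ohc_run_report <- function(x, ...) {
  cat("=== Honorary-title service-volume analysis ===\n")
  cat(sprintf("panel: %d treated, %d pool controls; cutoff month %d\n",
              x$n_treated, x$n_control_pool, x$cutoff_index))
  cat(sprintf("matched controls: %d (unmatched treated: %d)\n",
              length(unique(x$match$pairs$control_id)),
              length(x$match$unmatched_treated)))
  cat(sprintf("balance: mean ASD %.3f before -> %.3f after\n\n",
              mean(x$balance$asd_before), mean(x$balance$asd_after)))
  tab <- rdd_results_table(x)
  tab$estimate <- signif(tab$estimate, 6)
  tab$std_error <- signif(tab$std_error, 6)
  tab$p_value <- signif(tab$p_value, 3)
  cat("RDD jump estimates (cluster-robust SEs):\n")
  print.data.frame(tab, row.names = FALSE)
  cat("\nDifferential treatment effects (treated - control jump):\n")
  for (d in x$differentials)
    cat(sprintf("  %-9s %-11s %12.6g  (SE %.6g, p = %.3g)\n",
                d$outcome, d$method, d$estimate, d$std_error, d$p_value))
  if (length(x$lag_scans)) {
    cat("\nBest lag by cell (months):\n")
    for (k in names(x$lag_scans))
      cat(sprintf("  %-18s %d\n", k, x$lag_scans[[k]]$best_lag))
  }
  cat(sprintf("\nprovenance: seed %s, config %s, version %s\n",
              format(x$provenance$seed), x$provenance$config_hash,
              x$provenance$package_version))
  invisible(x)
}

# polynomial rolling hash over a character string, as hex; all intermediate
# values stay below 2^53 so double arithmetic is exact
fnv1a_hash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
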
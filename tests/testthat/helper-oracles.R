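# shared fixtures and independent oracles, built in code at test time

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_treated = 30L, n_control_pool = 120L, seed = 1L)
  do.call(synth_config, utils::modifyList(defaults, args))
}

# independent brute-force re-implementation of greedy nearest-available-
# neighbour matching without replacement: plain loops, no vectorized
# shortcuts shared with the package implementation
oracle_greedy_match <- function(ps_t, ps_c, n_matches = 1L, caliper = NULL) {
  ord <- order(-ps_t, names(ps_t))       # descending PS, ties by id
  used <- character(0)
  pairs <- list()
  unmatched <- character(0)
  for (i in ord) {
    chosen <- character(0)
    for (k in seq_len(n_matches)) {
      best <- NA_character_
      bestd <- Inf
      for (cn in sort(names(ps_c))) {    # ascending id => lowest id wins ties
        if (cn %in% used || cn %in% chosen) next
        d <- abs(ps_c[[cn]] - ps_t[[i]])
        if (!is.null(caliper) && d > caliper) next
        if (d < bestd) { best <- cn; bestd <- d }
      }
      if (is.na(best)) break
      chosen <- c(chosen, best)
    }
    if (length(chosen) < n_matches) {
      unmatched <- c(unmatched, names(ps_t)[i])
    } else {
      used <- c(used, chosen)
      pairs[[length(pairs) + 1L]] <-
        data.frame(treated_id = names(ps_t)[i], control_id = chosen,
                   stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(treated_id = character(0), control_id = character(0))
  pairs <- pairs[order(pairs$treated_id, pairs$control_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched = sort(unmatched))
}

# noiseless piecewise-linear physician-month series with a known jump
piecewise_series <- function(jump, cutoff = 6, slope = 2, intercept = 1,
                             n_per_month = 4, months = 1:11) {
  d <- expand.grid(physician_id = sprintf("P%02d", seq_len(n_per_month)),
                   month = months, stringsAsFactors = FALSE)
  d$y <- intercept + slope * d$month + jump * (d$month >= cutoff)
  d
}

# single-seed run of the synthetic pipeline up to the matched flow months
matched_flows <- function(cfg) {
  pan <- simulate_panel(cfg)
  base <- panel_baseline(pan)
  psm <- fit_propensity(treated ~ prs + thank + gift + contr + article, base)
  ps <- stats::setNames(predict(psm, base), base$physician_id)
  tid <- base$physician_id[base$treated == 1]
  cid <- base$physician_id[base$treated == 0]
  m <- match_nearest(ps[tid], ps[cid])
  keep <- c(tid, m$pairs$control_id)
  flows <- as.data.frame(pan)[pan$physician_id %in% keep &
                                pan$month_index >= 1, ]
  list(panel = pan, baseline = base, ps = ps, match = m, flows = flows)
}
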
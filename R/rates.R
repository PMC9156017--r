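#' Evolutionary rate in substitutions per generation
#'
#' The per-replicate rate is the number of accepted substitutions divided by
#' the number of tracked (post-burn-in) generations; because one generation
#' is one attempted substitution at one site, this equals
#' (substitutions/site) / (generations/site) and is comparable across
#' domains of different length. Under the uniform null the expectation is
#' 20/21: the replacement is drawn uniformly from 21 states, so with
#' probability 1/21 the current residue is redrawn and no substitution
#' occurs.
#'
#' @param traces List of [run_replicate()] traces for one mode.
#' @return List with `rate` (mean across replicates), `sd`, `per_replicate`,
#'   and `n_replicates`.
#' @export
evolutionary_rate <- function(traces) {
  if (inherits(traces, "evolution_trace")) traces <- list(traces)
  stopifnot(length(traces) > 0)
  per <- vapply(traces, function(tr) {
    stopifnot(inherits(tr, "evolution_trace"))
    g <- tracked_generations(tr)
    if (g == 0L) stop("trace has no tracked generations")
    mean(tr$accepted)
  }, numeric(1L))
  list(rate = mean(per),
       sd = if (length(per) > 1L) stats::sd(per) else NA_real_,
       per_replicate = per, n_replicates = length(per))
}

#' Allowed divergence of a constrained regime
#'
#' The evolutionary rate of a constrained model (CE or IE) as a percentage
#' of the unconstrained uniform-null rate: how much sequence change the
#' constraints allow relative to neutral expectation. Its complement,
#' `100 - allowed_divergence`, is the fraction of attempted replacement
#' mutations purged by purifying selection.
#'
#' @param rate_model Substitutions/generation under the constrained model.
#' @param rate_ue Substitutions/generation under the uniform null (> 0).
#' @return Percentage (scalar).
#' @export
allowed_divergence <- function(rate_model, rate_ue) {
  if (!is.numeric(rate_ue) || rate_ue <= 0)
    stop("rate_ue must be positive")
  100 * rate_model / rate_ue
}

#' Decompose purifying selection into local and epistasis-only parts
#'
#' The purged fraction under CE measures the combined purifying selection
#' from couplings and fields; the purged fraction under IE measures the part
#' from local site preferences alone; their difference is the purifying
#' selection due solely to pairwise epistasis. The identity
#' `combined_sel = local_sel + pairwise_sel` holds exactly.
#'
#' @param rate_ce,rate_ie,rate_ue Substitutions/generation under each
#'   regime, computed on matched replicates. Rate objects from
#'   [evolutionary_rate()] are accepted.
#' @return List with `combined_sel`, `local_sel`, `pairwise_sel` (purged
#'   percentages) and `prop_pairwise` (`pairwise_sel / combined_sel`, `NA`
#'   when `combined_sel <= 0`).
#' @export
selection_decomposition <- function(rate_ce, rate_ie, rate_ue) {
  as_rate <- function(x) if (is.list(x)) x$rate else x
  rate_ce <- as_rate(rate_ce); rate_ie <- as_rate(rate_ie)
  rate_ue <- as_rate(rate_ue)
  combined_sel <- 100 - allowed_divergence(rate_ce, rate_ue)
  local_sel <- 100 - allowed_divergence(rate_ie, rate_ue)
  pairwise_sel <- combined_sel - local_sel
  list(combined_sel = combined_sel, local_sel = local_sel,
       pairwise_sel = pairwise_sel,
       prop_pairwise = if (combined_sel > 0) pairwise_sel / combined_sel
                       else NA_real_)
}

#' Rate summary across matched regimes
#'
#' Convenience wrapper computing, from matched replicates, the per-mode
#' rates, allowed divergence and purged fraction relative to the uniform
#' null, and the purifying-selection decomposition. Rates are averaged over
#' replicates before the ratio is taken (ratio of means, not mean of
#' ratios).
#'
#' @param matched Matched replicates from [run_matched_replicates()]
#'   carrying CE, IE and UE traces.
#' @return An object of class `"rate_summary"`: a list with `rates` (a
#'   data.frame: mode, rate, sd, allowed_divergence, purged) and
#'   `decomposition` from [selection_decomposition()].
#' @export
rate_summary <- function(matched) {
  modes <- c("CE", "IE", "UE")
  r <- lapply(modes, function(m) evolutionary_rate(mode_traces(matched, m)))
  names(r) <- modes
  allowed <- vapply(modes, function(m) allowed_divergence(r[[m]]$rate,
                                                          r$UE$rate),
                    numeric(1L))
  out <- list(
    rates = data.frame(
      mode = modes,
      rate = vapply(r, `[[`, numeric(1L), "rate"),
      sd = vapply(r, `[[`, numeric(1L), "sd"),
      allowed_divergence = allowed,
      purged = 100 - allowed,
      row.names = NULL),
    decomposition = selection_decomposition(r$CE, r$IE, r$UE),
    n_replicates = r$UE$n_replicates)
  class(out) <- "rate_summary"
  out
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("Evolutionary rates (", x$n_replicates, " replicates)\n", sep = "")
  print(transform(x$rates, rate = round(rate, 4), sd = round(sd, 4),
                  allowed_divergence = round(allowed_divergence, 1),
                  purged = round(purged, 1)))
  d <- x$decomposition
  cat(sprintf("purifying selection: combined %.1f%% = local %.1f%% + pairwise %.1f%% (pairwise share %.1f%%)\n",
              d$combined_sel, d$local_sel, d$pairwise_sel,
              100 * d$prop_pairwise))
  invisible(x)
}

#' Per-site substitution rates
#'
#' The substitution rate of a site is its per-test acceptance probability:
#' the ratio of the mean number of generations between substitution
#' attempts at the site to the mean number of generations between accepted
#' substitutions. Algebraically this interval ratio reduces to
#' accepts/tests when events are pooled, which is the default computation;
#' the explicit interval ratio is retained as a cross-check because the two
#' differ when a site's trailing interval is censored (interval estimates
#' are numerically fragile at rarely-accepting sites).
#'
#' @param traces List of [run_replicate()] traces for one mode.
#' @param method `"counts"` (pooled accepts/tests, default),
#'   `"intervals_pooled"` (intervals pooled across replicates before the
#'   ratio), or `"intervals_by_replicate"` (interval ratio per replicate,
#'   then averaged across replicates where defined).
#' @return Data.frame of class `"per_site_rates"` with columns `site`,
#'   `tests`, `accepts`, `rate` (`NA` for sites never tested in any
#'   replicate; 0, flagged via `never_accepted`, for sites tested but never
#'   accepting).
#' @export
per_site_rates <- function(traces, method = c("counts", "intervals_pooled",
                                              "intervals_by_replicate")) {
  method <- match.arg(method)
  if (inherits(traces, "evolution_trace")) traces <- list(traces)
  stopifnot(length(traces) > 0)
  n <- traces[[1L]]$n_sites
  tests <- rep(0L, n)
  accepts <- rep(0L, n)
  for (tr in traces) {
    tests <- tests + tabulate(tr$site, nbins = n)
    accepts <- accepts + tabulate(tr$site[tr$accepted], nbins = n)
  }
  rate <- switch(method,
    counts = ifelse(tests > 0, accepts / tests, NA_real_),
    intervals_pooled = interval_rate(traces, n, by_replicate = FALSE),
    intervals_by_replicate = interval_rate(traces, n, by_replicate = TRUE))
  out <- data.frame(site = seq_len(n), tests = tests, accepts = accepts,
                    rate = rate,
                    never_tested = tests == 0L,
                    never_accepted = tests > 0L & accepts == 0L)
  class(out) <- c("per_site_rates", "data.frame")
  out
}

# mean(test interval) / mean(accept interval) per site; intervals are gaps
# between consecutive events within a replicate (trailing censored interval
# dropped), pooled across replicates or averaged per replicate.
interval_rate <- function(traces, n, by_replicate) {
  per_site <- function(tr) {
    test_gap <- vector("list", n)
    acc_gap <- vector("list", n)
    for (s in seq_len(n)) {
      tg <- which(tr$site == s)
      ag <- tg[tr$accepted[tg]]
      test_gap[[s]] <- diff(tg)
      acc_gap[[s]] <- diff(ag)
    }
    list(test = test_gap, acc = acc_gap)
  }
  gaps <- lapply(traces, per_site)
  if (by_replicate) {
    rates <- sapply(gaps, function(g) vapply(seq_len(n), function(s) {
      if (length(g$test[[s]]) == 0 || length(g$acc[[s]]) == 0)
        return(NA_real_)
      mean(g$test[[s]]) / mean(g$acc[[s]])
    }, numeric(1L)))
    rates <- matrix(rates, nrow = n)
    rowMeans(rates, na.rm = TRUE)
  } else {
    vapply(seq_len(n), function(s) {
      tg <- unlist(lapply(gaps, function(g) g$test[[s]]))
      ag <- unlist(lapply(gaps, function(g) g$acc[[s]]))
      if (length(tg) == 0 || length(ag) == 0) return(NA_real_)
      mean(tg) / mean(ag)
    }, numeric(1L))
  }
}
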
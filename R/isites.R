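#' Invariant-site curves across replicates
#'
#' For each tracked generation `g`, counts the invariant sites (I-sites) of
#' each replicate: `I_all(g)` is the number of sites with no accepted
#' substitution in generations `1..g` (a site that substitutes away and back
#' to its reference residue is not invariant), and `I_adj(g)` additionally
#' requires the site to have been selected for a substitution attempt at
#' least once in `1..g`, removing sites that only look invariant because
#' they were never tested. Counts are exact per replicate, then summarized
#' as mean and standard deviation per generation.
#'
#' @param traces List of [run_replicate()] traces for one mode, all of the
#'   same length and number of sites.
#' @param n_sites Number of sites; taken from the traces when `NULL`.
#' @return An object of class `"isite_curve"`: `generation`, matrices
#'   `i_all` and `i_adj` (replicates x generations), their per-generation
#'   `*_mean` and `*_sd`, `n_sites`, `n_replicates`, `mode`.
#' @export
isite_curve <- function(traces, n_sites = NULL) {
  if (inherits(traces, "evolution_trace")) traces <- list(traces)
  stopifnot(length(traces) > 0)
  lens <- vapply(traces, tracked_generations, integer(1L))
  if (length(unique(lens)) != 1L)
    stop("traces differ in tracked length: ", paste(unique(lens), collapse = ", "))
  ns <- unique(vapply(traces, function(t) t$n_sites, integer(1L)))
  if (length(ns) != 1L) stop("traces differ in number of sites")
  if (is.null(n_sites)) n_sites <- ns else stopifnot(n_sites == ns)
  g_max <- lens[1L]

  i_all <- matrix(0L, length(traces), g_max)
  i_adj <- matrix(0L, length(traces), g_max)
  for (r in seq_along(traces)) {
    cnt <- isite_counts_one(traces[[r]], n_sites, g_max)
    i_all[r, ] <- cnt$i_all
    i_adj[r, ] <- cnt$i_adj
  }
  structure(
    list(generation = seq_len(g_max),
         i_all = i_all, i_adj = i_adj,
         i_all_mean = colMeans(i_all), i_all_sd = col_sd(i_all),
         i_adj_mean = colMeans(i_adj), i_adj_sd = col_sd(i_adj),
         n_sites = n_sites, n_replicates = length(traces),
         mode = traces[[1L]]$mode),
    class = "isite_curve")
}

# Per-replicate curves from the first tested / first accepted generation of
# every site; O(n_sites + generations).
isite_counts_one <- function(trace, n_sites, g_max) {
  first_test <- rep.int(g_max + 1L, n_sites)
  first_acc <- rep.int(g_max + 1L, n_sites)
  ord <- rev(seq_len(g_max))
  first_test[trace$site[ord]] <- ord  # earliest write wins via reverse order
  acc_idx <- rev(which(trace$accepted))
  first_acc[trace$site[acc_idx]] <- acc_idx
  # number of sites whose first accept / first test falls at each generation
  acc_at <- tabulate(first_acc, nbins = g_max)
  test_at <- tabulate(first_test, nbins = g_max)
  n_acc <- cumsum(acc_at)              # sites substituted by generation g
  n_tested <- cumsum(test_at)          # sites tested at least once by g
  # tested-by-g sites whose first accept came later than g; an accept is
  # itself a test, so first_test <= first_acc always
  tested_not_acc <- n_tested - cumsum(tabulate(pmax(first_test, first_acc),
                                               nbins = g_max))
  list(i_all = n_sites - n_acc, i_adj = tested_not_acc)
}

col_sd <- function(m) {
  if (nrow(m) < 2L) return(rep(NA_real_, ncol(m)))
  apply(m, 2L, stats::sd)
}

#' @export
print.isite_curve <- function(x, ...) {
  cat("I-site curve (", x$mode, "): ", x$n_replicates, " replicates, ",
      length(x$generation), " generations, ", x$n_sites, " sites\n", sep = "")
  g_show <- unique(round(seq(1, length(x$generation), length.out = 5)))
  print(data.frame(generation = g_show,
                   I_all = round(x$i_all_mean[g_show], 2),
                   I_adj = round(x$i_adj_mean[g_show], 2)))
  invisible(x)
}

#' Decompose excess I-sites into combined, local, and epistasis-only parts
#'
#' Subtracts the uniform-null (UE) expectation from the CE and IE curves:
#' the combined effect of couplings and fields is the CE excess over UE, the
#' local effect is the IE excess over UE, and their difference is the part
#' attributable to pairwise epistasis alone. The identity
#' `pairwise = combined - local` holds exactly at every grid point.
#' Computed separately on `I_all` and `I_adj` counts.
#'
#' @param ce,ie,ue [isite_curve()]s for the three modes on an identical
#'   generation grid.
#' @return A data.frame of class `"excess_decomposition"` with columns
#'   `generation`, `statistic` (`"I_all"`/`"I_adj"`), `combined`, `local`,
#'   `pairwise` (site-count differences), their `_frac` counterparts
#'   (divided by `n_sites`), and `prop_pairwise` (`pairwise / combined`,
#'   `NA` where `combined <= 0`).
#' @export
excess_decomposition <- function(ce, ie, ue) {
  stopifnot(inherits(ce, "isite_curve"), inherits(ie, "isite_curve"),
            inherits(ue, "isite_curve"))
  if (!identical(ce$generation, ie$generation) ||
      !identical(ce$generation, ue$generation))
    stop("I-site curves are not on the same generation grid")
  if (ce$n_sites != ie$n_sites || ce$n_sites != ue$n_sites)
    stop("I-site curves disagree on the number of sites")
  n <- ce$n_sites
  one <- function(stat) {
    f <- paste0(stat, "_mean")
    combined <- ce[[f]] - ue[[f]]
    local <- ie[[f]] - ue[[f]]
    pairwise <- combined - local
    data.frame(
      generation = ce$generation,
      statistic = if (stat == "i_all") "I_all" else "I_adj",
      combined = combined, local = local, pairwise = pairwise,
      combined_frac = combined / n, local_frac = local / n,
      pairwise_frac = pairwise / n,
      prop_pairwise = ifelse(combined > 0, pairwise / combined, NA_real_))
  }
  out <- rbind(one("i_all"), one("i_adj"))
  attr(out, "n_sites") <- n
  class(out) <- c("excess_decomposition", "data.frame")
  out
}

#' Excess decomposition at matched evolutionary time
#'
#' Evaluates the I-site excess decomposition at fixed amounts of elapsed
#' time expressed in generations per site; grid point `t` corresponds to
#' generation `round(t * n_sites)`.
#'
#' @param matched Matched replicates from [run_matched_replicates()] (must
#'   carry CE, IE and UE traces).
#' @param time_grid Increasing positive values of generations/site.
#' @return An `"excess_decomposition"` data.frame with a `time` column
#'   (generations/site) replacing the per-generation grid.
#' @export
time_matched_excess <- function(matched, time_grid = c(1, 2, 3, 4)) {
  stopifnot(all(time_grid > 0), !is.unsorted(time_grid, strictly = TRUE))
  curves <- lapply(c(CE = "CE", IE = "IE", UE = "UE"),
                   function(m) isite_curve(mode_traces(matched, m)))
  n <- curves$CE$n_sites
  gens <- as.integer(round(time_grid * n))
  g_max <- length(curves$CE$generation)
  if (any(gens > g_max))
    stop("time grid requires generation ", max(gens),
         " but only ", g_max, " were tracked")
  dec <- excess_decomposition(curves$CE, curves$IE, curves$UE)
  out <- dec[dec$generation %in% gens, , drop = FALSE]
  out$time <- time_grid[match(out$generation, gens)]
  rownames(out) <- NULL
  attr(out, "n_sites") <- n
  class(out) <- c("excess_decomposition", "data.frame")
  out
}

#' Excess decomposition at matched sequence divergence
#'
#' Compares regimes at equal realized divergence rather than equal elapsed
#' time: for each replicate and mode, the evaluation generation is the first
#' at which cumulative accepted substitutions per site reach the grid value
#' `d` (no interpolation; counts are integers). I-site counts are read at
#' that generation, averaged across replicates, and decomposed as in
#' [excess_decomposition()]. Replicates in which some mode never reaches `d`
#' are excluded from that grid point and counted.
#'
#' @inheritParams time_matched_excess
#' @param divergence_grid Increasing positive values of substitutions/site.
#' @return An `"excess_decomposition"` data.frame with columns `divergence`,
#'   `statistic`, the decomposition columns, and `n_used` / `n_excluded`
#'   replicate counts per grid point.
#' @export
divergence_matched_excess <- function(matched, divergence_grid = c(1, 2, 3, 4)) {
  stopifnot(length(matched) > 0, all(divergence_grid > 0),
            !is.unsorted(divergence_grid, strictly = TRUE))
  modes <- c("CE", "IE", "UE")
  traces <- lapply(modes, function(m) mode_traces(matched, m))
  names(traces) <- modes
  n <- traces$CE[[1L]]$n_sites
  n_rep <- length(matched)

  # per replicate and mode: I-count vectors and cumulative divergence
  counts <- lapply(traces, function(trs) {
    g_max <- tracked_generations(trs[[1L]])
    lapply(trs, function(tr) {
      c(isite_counts_one(tr, n, g_max),
        list(divergence = cumsum(tr$accepted) / n))
    })
  })

  rows <- list()
  for (d in divergence_grid) {
    # generation at which each replicate first reaches divergence d, per mode
    gen_at <- matrix(NA_integer_, n_rep, length(modes),
                     dimnames = list(NULL, modes))
    for (m in modes) {
      gen_at[, m] <- vapply(counts[[m]], function(x) {
        g <- which(x$divergence >= d)
        if (length(g) == 0) NA_integer_ else g[1L]
      }, integer(1L))
    }
    use <- stats::complete.cases(gen_at)
    if (!any(use))
      stop("no replicate reaches divergence ", d, " in every mode")
    for (stat in c("i_all", "i_adj")) {
      m_at <- sapply(modes, function(m) {
        mean(mapply(function(x, g) x[[stat]][g],
                    counts[[m]][use], gen_at[use, m]))
      })
      combined <- m_at["CE"] - m_at["UE"]
      local <- m_at["IE"] - m_at["UE"]
      pairwise <- combined - local
      rows[[length(rows) + 1L]] <- data.frame(
        divergence = d,
        statistic = if (stat == "i_all") "I_all" else "I_adj",
        combined = combined, local = local, pairwise = pairwise,
        combined_frac = combined / n, local_frac = local / n,
        pairwise_frac = pairwise / n,
        prop_pairwise = if (combined > 0) pairwise / combined else NA_real_,
        n_used = sum(use), n_excluded = n_rep - sum(use))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_sites") <- n
  class(out) <- c("excess_decomposition", "data.frame")
  out
}
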
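#' Simulation protocol configuration
#'
#' A simulation replicate runs for `total_generations` single-site Gibbs
#' updates; one generation is one attempted substitution at one randomly
#' chosen site. The first `burn_in` generations bring the chain to steady
#' state and are discarded; the sequence at the end of burn-in becomes the
#' reference against which site invariance is scored.
#'
#' @param total_generations Total Gibbs updates per replicate (default 30000).
#' @param burn_in Generations discarded as burn-in (default 5000).
#' @param n_replicates Number of independent replicates (default 500).
#' @param master_seed Seed from which every per-replicate, per-mode stream
#'   seed is derived deterministically.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(total_generations = 30000L, burn_in = 5000L,
                              n_replicates = 500L, master_seed = 1L) {
  total_generations <- as.integer(total_generations)
  burn_in <- as.integer(burn_in)
  n_replicates <- as.integer(n_replicates)
  stopifnot(burn_in >= 0, burn_in < total_generations, n_replicates >= 1)
  structure(
    list(total_generations = total_generations, burn_in = burn_in,
         n_replicates = n_replicates, master_seed = as.integer(master_seed)),
    class = "simulation_config")
}

#' One Gibbs evolution step
#'
#' Draws a site uniformly, then replaces its residue by a draw from the
#' single-site conditional distribution under the given mode (inverse-CDF
#' sampling with one uniform variate). The drawn state may equal the current
#' one, in which case the site was tested but not substituted
#' (`accepted = FALSE`).
#'
#' Randomness may be supplied explicitly (`site`, `u`) for stream control, or
#' left `NULL` to draw from the session RNG. This is the reference R path;
#' [run_replicate()] uses an equivalent compiled loop.
#'
#' @inheritParams conditional_distribution
#' @param site Optional site index (1-based); drawn uniformly when `NULL`.
#' @param u Optional uniform variate in (0, 1) for the residue draw.
#' @return List with `seq` (updated sequence) and `record` (a one-row
#'   data.frame: `site`, `before`, `proposed`, `accepted`).
#' @export
gibbs_step <- function(seq, model, mode = "CE", site = NULL, u = NULL) {
  stopifnot(inherits(model, "potts_model"))
  if (is.null(site)) site <- sample.int(model$n_sites, 1L)
  if (is.null(u)) u <- stats::runif(1L)
  p <- conditional_distribution(seq, site, model, mode)
  proposed <- which(cumsum(p) >= u * sum(p))[1L]
  before <- seq[site]
  seq[site] <- proposed
  list(seq = seq,
       record = data.frame(site = site, before = before, proposed = proposed,
                           accepted = proposed != before))
}

#' Run one evolution replicate
#'
#' Executes the full protocol under one mode: `total_generations` Gibbs
#' updates, with the site visited at each generation taken from a dedicated
#' site-selection stream (seeded by `site_seed`) and the residue draws from a
#' separate residue stream (`residue_seed`). Keeping the two streams separate
#' is what allows the identical site series to be replayed under CE, IE and
#' UE dynamics, whose residue draws would otherwise desynchronize the
#' generator. Each generation consumes exactly one variate from each stream.
#'
#' @inheritParams gibbs_step
#' @param start_seq Starting sequence; defaults to the model's native
#'   sequence.
#' @param config A [simulation_config()] (only `total_generations` and
#'   `burn_in` are used here).
#' @param site_seed,residue_seed Integer seeds for the two streams.
#' @return An object of class `"evolution_trace"`: a list with `mode`,
#'   `n_sites`, `reference_sequence` (state at end of burn-in), vectors
#'   `site`, `before`, `proposed`, `accepted` over the tracked generations,
#'   `final_sequence`, and the protocol parameters.
#' @export
run_replicate <- function(model, start_seq = NULL, config = simulation_config(),
                          mode = "CE", site_seed = 1L, residue_seed = 2L) {
  stopifnot(inherits(model, "potts_model"),
            inherits(config, "simulation_config"))
  mode <- check_mode(mode)
  if (is.null(start_seq)) start_seq <- model$native_sequence
  if (is.null(start_seq))
    stop("no start_seq given and the model has no native sequence")
  start_seq <- validate_sequence(start_seq, model$n_sites, model$n_states)
  streams <- replicate_streams(model$n_sites, config$total_generations,
                               site_seed, residue_seed)
  res <- potts_gibbs_cpp(model$J, model$h, model$n_sites, model$n_states,
                         start_seq - 1L, mode_code(mode),
                         streams$sites - 1L, streams$u,
                         config$burn_in, 0L)
  new_trace(res, mode, model$n_sites, config, site_seed, residue_seed)
}

replicate_streams <- function(n_sites, total, site_seed, residue_seed) {
  set.seed(as.integer(site_seed))
  sites <- sample.int(n_sites, total, replace = TRUE)
  set.seed(as.integer(residue_seed))
  u <- stats::runif(total)
  list(sites = sites, u = u)
}

new_trace <- function(res, mode, n_sites, config, site_seed, residue_seed) {
  structure(
    list(mode = mode, n_sites = n_sites,
         reference_sequence = res$reference + 1L,
         site = res$site + 1L, before = res$before + 1L,
         proposed = res$proposed + 1L, accepted = res$accepted,
         final_sequence = res$final + 1L,
         total_generations = config$total_generations,
         burn_in = config$burn_in,
         site_seed = site_seed, residue_seed = residue_seed),
    class = "evolution_trace")
}

#' @export
print.evolution_trace <- function(x, ...) {
  g <- length(x$accepted)
  cat("Evolution trace (", x$mode, "): ", x$n_sites, " sites, ",
      g, " tracked generations (burn-in ", x$burn_in, ")\n", sep = "")
  cat("  substitutions accepted:", sum(x$accepted),
      sprintf("(rate %.4f)\n", mean(x$accepted)))
  invisible(x)
}

#' Number of tracked (post-burn-in) generations in a trace
#' @param trace An `evolution_trace`.
#' @return Integer count.
#' @export
tracked_generations <- function(trace) {
  stopifnot(inherits(trace, "evolution_trace"))
  length(trace$accepted)
}

#' Replay a trace from its reference sequence
#'
#' Applies the accepted substitutions in order to the reference sequence;
#' the result must equal the simulator's final state exactly (an internal
#' consistency check on the trace format).
#'
#' @param trace An `evolution_trace`.
#' @return Integer sequence of length `n_sites`.
#' @export
replay_trace <- function(trace) {
  stopifnot(inherits(trace, "evolution_trace"))
  seq <- trace$reference_sequence
  acc <- which(trace$accepted)
  # later accepted events at the same site overwrite earlier ones
  if (length(acc) > 0)
    seq[trace$site[acc]] <- trace$proposed[acc]
  seq
}

#' Run matched CE/IE/UE replicates
#'
#' For each replicate, one site-selection stream seed is derived from
#' `(master_seed, replicate_id)` and shared by all requested modes, so the
#' identical series of sites is tested for substitution at every generation
#' across regimes; each mode receives its own residue stream. All runs start
#' from the same starting sequence. Seeds are drawn from a table generated
#' up front, so results do not depend on execution order.
#'
#' @inheritParams run_replicate
#' @param modes Character vector of regimes to run (default all three).
#' @return A list of `"matched_replicate"` objects, each holding
#'   `replicate_id` and a named list `traces` with one
#'   [run_replicate()] trace per mode.
#' @export
run_matched_replicates <- function(model, start_seq = NULL,
                                   config = simulation_config(),
                                   modes = c("CE", "IE", "UE")) {
  stopifnot(inherits(model, "potts_model"),
            inherits(config, "simulation_config"))
  modes <- vapply(modes, check_mode, character(1L))
  if (anyDuplicated(modes)) stop("modes must be distinct")
  if (is.null(start_seq)) start_seq <- model$native_sequence
  if (is.null(start_seq))
    stop("no start_seq given and the model has no native sequence")
  seeds <- derive_seed_table(config$master_seed, config$n_replicates)
  lapply(seq_len(config$n_replicates), function(r) {
    traces <- lapply(modes, function(m) {
      run_replicate(model, start_seq, config, m,
                    site_seed = seeds[r, "site"],
                    residue_seed = seeds[r, m])
    })
    names(traces) <- modes
    structure(list(replicate_id = r, traces = traces),
              class = "matched_replicate")
  })
}

# One row per replicate: a shared site-stream seed plus one residue-stream
# seed per mode, all drawn up front from the master seed.
derive_seed_table <- function(master_seed, n_replicates) {
  set.seed(as.integer(master_seed))
  m <- matrix(sample.int(.Machine$integer.max - 1L, n_replicates * 4L),
              nrow = n_replicates,
              dimnames = list(NULL, c("site", "CE", "IE", "UE")))
  m
}

#' Extract all traces for one mode from matched replicates
#'
#' @param matched List of matched replicates from [run_matched_replicates()].
#' @param mode One of `"CE"`, `"IE"`, `"UE"`.
#' @return List of `evolution_trace` objects.
#' @export
mode_traces <- function(matched, mode) {
  mode <- check_mode(mode)
  lapply(matched, function(m) {
    tr <- m$traces[[mode]]
    if (is.null(tr)) stop("matched replicates carry no ", mode, " trace")
    tr
  })
}
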
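#' Specification for a synthetic Potts model
#'
#' Describes the statistical structure of a randomly generated Potts model:
#' a sparse set of strongly coupled site pairs on top of heterogeneous
#' per-site fields, mimicking the contact-driven coupling maps of real
#' protein domain families where a minority of site pairs carry most of the
#' coupling weight.
#'
#' Defaults are sized so that a full matched CE/IE/UE replicate runs in
#' seconds: 60 sites over the 21-state amino-acid-plus-gap alphabet, with
#' 10% of site pairs coupled and coupling and field entries drawn at unit
#' standard deviation.
#'
#' @param n_sites Number of sites (alignment columns).
#' @param n_states Number of states per site; 21 for production, small
#'   values are useful for exhaustive-enumeration tests.
#' @param coupling_density Fraction of the `n(n-1)/2` site pairs that
#'   receive a nonzero coupling block.
#' @param coupling_scale Standard deviation of nonzero coupling entries.
#' @param field_scale Standard deviation of field entries.
#' @param seed RNG seed; generation is fully reproducible given the spec.
#' @return An object of class `"synthetic_model_spec"`.
#' @export
synthetic_model_spec <- function(n_sites = 60L, n_states = 21L,
                                 coupling_density = 0.1,
                                 coupling_scale = 1.0, field_scale = 1.0,
                                 seed = 1L) {
  stopifnot(n_sites >= 1, n_states >= 2,
            coupling_density >= 0, coupling_density <= 1,
            coupling_scale >= 0, field_scale >= 0)
  structure(
    list(n_sites = as.integer(n_sites), n_states = as.integer(n_states),
         coupling_density = coupling_density,
         coupling_scale = coupling_scale, field_scale = field_scale,
         seed = as.integer(seed)),
    class = "synthetic_model_spec")
}

#' Generate a synthetic Potts model
#'
#' Draws a random Potts model matching a [synthetic_model_spec()]:
#' `round(density * n(n-1)/2)` site pairs are chosen uniformly at random and
#' given i.i.d. normal coupling blocks (symmetrized by construction,
#' `J[i,j,a,b] == J[j,i,b,a]`); all field entries are i.i.d. normal.
#'
#' @param spec A [synthetic_model_spec()].
#' @return A [potts_model()] without a native sequence attached; see
#'   [generate_native_sequence()].
#' @export
generate_potts_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_model_spec"))
  n <- spec$n_sites
  q <- spec$n_states
  set.seed(spec$seed)
  J <- array(0, dim = c(n, n, q, q))
  n_pairs_all <- n * (n - 1L) / 2L
  n_pairs <- round(spec$coupling_density * n_pairs_all)
  if (n_pairs > 0 && spec$coupling_scale > 0) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    chosen <- pairs[sample.int(n_pairs_all, n_pairs), , drop = FALSE]
    for (k in seq_len(n_pairs)) {
      i <- chosen[k, 1L]; j <- chosen[k, 2L]
      block <- matrix(stats::rnorm(q * q, 0, spec$coupling_scale), q, q)
      J[i, j, , ] <- block
      J[j, i, , ] <- t(block)
    }
  }
  h <- matrix(stats::rnorm(n * q, 0, spec$field_scale), n, q)
  potts_model(J, h)
}

#' Generate a model-compatible native sequence
#'
#' Produces a starting sequence that sits at a local maximum of the
#' Hamiltonian log weight: beginning from a uniformly random sequence,
#' single-site greedy ascent (sites visited in seed-randomized sweeps, ties
#' broken toward the lowest state index) is applied until no single-site
#' change increases the log weight. This stands in for the annotated family
#' reference sequence of a real domain model: a high-fitness sequence
#' consistent with the model that generated it.
#'
#' @param model A [potts_model()].
#' @param seed RNG seed for the random start and sweep order.
#' @return Integer state vector of length `n_sites` (values in `1..q`).
#' @export
generate_native_sequence <- function(model, seed = 1L) {
  stopifnot(inherits(model, "potts_model"))
  n <- model$n_sites
  q <- model$n_states
  set.seed(as.integer(seed))
  seq <- sample.int(q, n, replace = TRUE)
  repeat {
    changed <- FALSE
    for (site in sample.int(n)) {
      # conditional log weights rank single-site variants of the sequence
      p <- conditional_distribution(seq, site, model, "CE")
      best <- which.max(p)
      if (p[best] > p[seq[site]]) {
        seq[site] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  seq
}
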
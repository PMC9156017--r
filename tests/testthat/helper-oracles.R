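# Brute-force oracles and tiny-fixture builders, kept deliberately naive and
# independent of the package's vectorized/compiled paths.

tiny_random_model <- function(n, q, seed, density = 1, coupling_scale = 1,
                              field_scale = 1) {
  generate_potts_model(synthetic_model_spec(
    n_sites = n, n_states = q, coupling_density = density,
    coupling_scale = coupling_scale, field_scale = field_scale, seed = seed))
}

# double-loop Hamiltonian log weight
brute_log_weight <- function(seq, model) {
  n <- model$n_sites
  total <- 0
  for (i in seq_len(n)) {
    total <- total + model$h[i, seq[i]]
    if (i < n) for (j in (i + 1L):n)
      total <- total + model$J[i, j, seq[i], seq[j]]
  }
  total
}

# all q^n sequences (rows) with their normalized Boltzmann probabilities
enumerate_joint <- function(model) {
  n <- model$n_sites
  q <- model$n_states
  seqs <- as.matrix(expand.grid(rep(list(seq_len(q)), n)))
  lw <- apply(seqs, 1L, brute_log_weight, model = model)
  w <- exp(lw - max(lw))
  list(sequences = seqs, prob = w / sum(w))
}

# conditional of one site from the enumerated joint
joint_conditional <- function(joint, seq, site) {
  n <- ncol(joint$sequences)
  others <- setdiff(seq_len(n), site)
  keep <- rep(TRUE, nrow(joint$sequences))
  for (j in others) keep <- keep & joint$sequences[, j] == seq[j]
  p <- joint$prob[keep]
  states <- joint$sequences[keep, site]
  out <- numeric(max(joint$sequences))
  out[states] <- p
  out / sum(out)
}

# direct per-generation re-scan of a trace: for every g, which sites have an
# accepted event in 1..g, and which were tested in 1..g
oracle_isite <- function(trace, n_sites) {
  n_sites <- as.integer(n_sites)
  g_max <- length(trace$accepted)
  i_all <- integer(g_max)
  i_adj <- integer(g_max)
  for (g in seq_len(g_max)) {
    acc_sites <- unique(trace$site[seq_len(g)][trace$accepted[seq_len(g)]])
    tested <- unique(trace$site[seq_len(g)])
    i_all[g] <- n_sites - length(acc_sites)
    i_adj[g] <- length(setdiff(tested, acc_sites))
  }
  list(i_all = i_all, i_adj = i_adj)
}

# hand-built trace for analysis-layer tests
fake_trace <- function(site, accepted, n_sites,
                       before = NULL, proposed = NULL, mode = "UE") {
  g <- length(site)
  n_sites <- as.integer(n_sites)
  if (is.null(before)) before <- rep(1L, g)
  if (is.null(proposed)) proposed <- ifelse(accepted, before + 1L, before)
  structure(
    list(mode = mode, n_sites = n_sites,
         reference_sequence = rep(1L, n_sites),
         site = as.integer(site), before = as.integer(before),
         proposed = as.integer(proposed), accepted = as.logical(accepted),
         final_sequence = rep(1L, n_sites),
         total_generations = g, burn_in = 0L,
         site_seed = NA_integer_, residue_seed = NA_integer_),
    class = "evolution_trace")
}

fake_matched <- function(traces_by_mode, replicate_id = 1L) {
  structure(list(replicate_id = replicate_id, traces = traces_by_mode),
            class = "matched_replicate")
}
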
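test_that("the compiled conditional matches the R reference path", {
  for (seed in 1:4) {
    m <- tiny_random_model(5, 4, seed)
    set.seed(seed + 50)
    s <- sample.int(4, 5, replace = TRUE)
    site <- sample.int(5, 1)
    for (mode in c("CE", "IE", "UE")) {
      p_cpp <- pottsevol:::potts_conditional_cpp(
        m$J, m$h, m$n_sites, m$n_states, s - 1L, site - 1L,
        pottsevol:::mode_code(mode))
      expect_equal(p_cpp, conditional_distribution(s, site, m, mode),
                   tolerance = 1e-12)
    }
  }
})

test_that("replicates are deterministic and traces replay exactly", {
  m <- tiny_random_model(8, 5, 1, density = 0.3)
  start <- generate_native_sequence(m, 2)
  cfg <- simulation_config(total_generations = 400, burn_in = 0,
                           n_replicates = 1, master_seed = 1)
  t1 <- run_replicate(m, start, cfg, "UE", site_seed = 5, residue_seed = 6)
  t2 <- run_replicate(m, start, cfg, "UE", site_seed = 5, residue_seed = 6)
  expect_identical(t1, t2)
  expect_identical(replay_trace(t1), t1$final_sequence)
  # accepted flag is exactly "proposed differs from before"
  expect_identical(t1$accepted, t1$proposed != t1$before)
  # burn_in = 0: the reference is the start itself
  expect_identical(t1$reference_sequence, start)

  cfg2 <- simulation_config(total_generations = 400, burn_in = 100,
                            n_replicates = 1, master_seed = 1)
  t3 <- run_replicate(m, start, cfg2, "CE", site_seed = 7, residue_seed = 8)
  expect_length(t3$accepted, 300)
  expect_identical(replay_trace(t3), t3$final_sequence)
})

test_that("all-zero parameters make the three regimes bit-identical", {
  m0 <- potts_model(array(0, c(6, 6, 4, 4)), matrix(0, 6, 4))
  start <- rep(1L, 6)
  cfg <- simulation_config(total_generations = 200, burn_in = 20,
                           n_replicates = 1, master_seed = 1)
  tr <- lapply(c("CE", "IE", "UE"), function(md)
    run_replicate(m0, start, cfg, md, site_seed = 3, residue_seed = 4))
  for (f in c("reference_sequence", "site", "before", "proposed", "accepted",
              "final_sequence")) {
    expect_identical(tr[[1]][[f]], tr[[2]][[f]])
    expect_identical(tr[[1]][[f]], tr[[3]][[f]])
  }
})

test_that("UE acceptance rate sits at 20/21 within Monte-Carlo error", {
  m <- tiny_random_model(10, 21, 3, density = 0)
  cfg <- simulation_config(total_generations = 30000, burn_in = 0,
                           n_replicates = 1, master_seed = 1)
  tr <- run_replicate(m, rep(1L, 10), cfg, "UE", site_seed = 9,
                      residue_seed = 10)
  p <- 20 / 21
  se <- sqrt(p * (1 - p) / 30000)
  expect_lt(abs(mean(tr$accepted) - p), 3 * se)
})

test_that("matched replicates share the site stream but not residue draws", {
  m <- tiny_random_model(10, 6, 4, density = 0.2)
  start <- generate_native_sequence(m, 5)
  cfg <- simulation_config(total_generations = 300, burn_in = 0,
                           n_replicates = 3, master_seed = 77)
  matched <- run_matched_replicates(m, start, cfg)
  for (r in matched) {
    expect_identical(r$traces$CE$site, r$traces$IE$site)
    expect_identical(r$traces$CE$site, r$traces$UE$site)
  }
  # different replicates test different site series
  expect_false(identical(matched[[1]]$traces$CE$site,
                         matched[[2]]$traces$CE$site))
  # rerunning the whole set is statistic-identical
  matched2 <- run_matched_replicates(m, start, cfg)
  expect_identical(matched, matched2)
})

test_that("the site stream is shared through burn-in as well", {
  m <- tiny_random_model(10, 6, 4, density = 0.2)
  start <- generate_native_sequence(m, 5)
  burn <- simulation_config(total_generations = 300, burn_in = 120,
                            n_replicates = 1, master_seed = 77)
  none <- simulation_config(total_generations = 300, burn_in = 0,
                            n_replicates = 1, master_seed = 77)
  with_burn <- run_matched_replicates(m, start, burn)[[1]]
  no_burn <- run_matched_replicates(m, start, none)[[1]]
  # the tracked tail of the no-burn-in run is the full burn-in run's series
  expect_identical(no_burn$traces$CE$site[121:300], with_burn$traces$CE$site)
  expect_identical(no_burn$traces$UE$site[121:300], with_burn$traces$UE$site)
})

test_that("single Gibbs steps behave at the degenerate limits", {
  # N = 1, UE: acceptance probability 20/21
  m1 <- tiny_random_model(1, 21, 6, density = 0)
  set.seed(11)
  acc <- replicate(4000, gibbs_step(c(1L), m1, "UE")$record$accepted)
  p <- 20 / 21
  expect_lt(abs(mean(acc) - p), 3 * sqrt(p * (1 - p) / 4000))

  # overwhelming field on the current state: never substituted
  m2 <- tiny_random_model(3, 4, 7, density = 0)
  m2$h[2, ] <- c(1000, 0, 0, 0)
  set.seed(12)
  for (k in 1:50) {
    st <- gibbs_step(c(3L, 1L, 2L), m2, "CE", site = 2)
    expect_false(st$record$accepted)
  }
})

test_that("long-run CE acceptance matches the enumerated stationary rate", {
  # expected per-step acceptance under stationarity:
  # 1 - sum_seq pi(seq) * (1/N) * sum_site P(seq_site | rest)
  m <- tiny_random_model(3, 3, 8)
  joint <- enumerate_joint(m)
  stay <- 0
  for (k in seq_len(nrow(joint$sequences))) {
    s <- joint$sequences[k, ]
    for (site in 1:3) {
      p <- conditional_distribution(s, site, m, "CE")
      stay <- stay + joint$prob[k] * (1 / 3) * p[s[site]]
    }
  }
  expected <- 1 - stay

  cfg <- simulation_config(total_generations = 110000, burn_in = 10000,
                           n_replicates = 1, master_seed = 1)
  tr <- run_replicate(m, rep(1L, 3), cfg, "CE", site_seed = 13,
                      residue_seed = 14)
  n <- tracked_generations(tr)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(tr$accepted) - expected), 3 * se)
})

test_that("configuration and input validation catch protocol errors", {
  expect_error(simulation_config(total_generations = 100, burn_in = 100))
  expect_error(simulation_config(n_replicates = 0))
  m <- tiny_random_model(4, 3, 9)
  cfg <- simulation_config(total_generations = 10, burn_in = 0,
                           n_replicates = 1)
  expect_error(run_replicate(m, c(1L, 1L), cfg, "CE"), "length")
  expect_error(run_replicate(m, NULL, cfg, "CE"), "native")
})
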
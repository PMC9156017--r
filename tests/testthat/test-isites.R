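test_that("I-site curves match hand-checkable traces", {
  # no accepted events: I_all stays at N, I_adj counts distinct tested sites
  tr <- fake_trace(site = c(2, 3, 2, 4), accepted = rep(FALSE, 4), n_sites = 5)
  cv <- isite_curve(list(tr))
  expect_identical(cv$i_all[1, ], rep(5L, 4))
  expect_identical(cv$i_adj[1, ], c(1L, 2L, 2L, 3L))

  # substitute away at g1, reject at g2, substitute back at g3:
  # the returning site is never invariant again
  tr <- fake_trace(site = c(1, 2, 1), accepted = c(TRUE, FALSE, TRUE),
                   n_sites = 3,
                   before = c(1L, 1L, 2L), proposed = c(2L, 1L, 1L))
  cv <- isite_curve(list(tr))
  expect_identical(cv$i_all[1, ], c(2L, 2L, 2L))
  expect_identical(cv$i_adj[1, ], c(0L, 1L, 1L))
})

test_that("curves agree with the direct per-generation re-scan oracle", {
  m <- tiny_random_model(12, 21, 1, density = 0)
  cfg <- simulation_config(total_generations = 300, burn_in = 50,
                           n_replicates = 1, master_seed = 1)
  for (mode in c("UE", "IE")) {
    tr <- run_replicate(m, rep(1L, 12), cfg, mode, site_seed = 31,
                        residue_seed = 32)
    cv <- isite_curve(list(tr))
    orc <- oracle_isite(tr, 12)
    expect_identical(as.integer(cv$i_all[1, ]), orc$i_all)
    expect_identical(as.integer(cv$i_adj[1, ]), orc$i_adj)
  }
})

test_that("I-site curve invariants hold on simulated traces", {
  m <- tiny_random_model(15, 21, 2, density = 0.2)
  start <- generate_native_sequence(m, 3)
  cfg <- simulation_config(total_generations = 2000, burn_in = 100,
                           n_replicates = 4, master_seed = 5)
  for (mode in c("CE", "UE")) {
    cv <- isite_curve(lapply(seq_len(4), function(r)
      run_replicate(m, start, cfg, mode, site_seed = 100 + r,
                    residue_seed = 200 + r)))
    for (r in 1:4) {
      expect_true(all(diff(cv$i_all[r, ]) <= 0))
      expect_true(all(cv$i_adj[r, ] <= cv$i_all[r, ]))
      expect_true(all(cv$i_adj[r, ] >= 0) && all(cv$i_all[r, ] <= 15))
    }
    # every site eventually tested: the two counts converge
    expect_identical(cv$i_adj[, 1900], cv$i_all[, 1900])
  }
})

test_that("mean UE decay follows the closed-form expectation", {
  # each generation one of N sites is tested, substituted w.p. 20/21
  n <- 20L
  m <- tiny_random_model(n, 21, 4, density = 0)
  cfg <- simulation_config(total_generations = 500, burn_in = 0,
                           n_replicates = 500, master_seed = 6)
  seeds <- pottsevol:::derive_seed_table(6, 500)
  cv <- isite_curve(lapply(seq_len(500), function(r)
    run_replicate(m, rep(1L, n), cfg, "UE", site_seed = seeds[r, "site"],
                  residue_seed = seeds[r, "UE"])))
  for (g in c(25L, 100L, 250L, 500L)) {
    p_surv <- (1 - (1 / n) * (20 / 21))^g
    expected <- n * p_surv
    # binomial SE of the mean count; robust where the empirical SD degenerates
    se <- sqrt(n * p_surv * (1 - p_surv) / 500)
    expect_lt(abs(cv$i_all_mean[g] - expected), 3 * se + 1e-9)
  }
})

test_that("excess decomposition arithmetic and flags are exact", {
  mk_curve <- function(i_all, i_adj, n_sites, mode) {
    structure(list(
      generation = seq_along(i_all),
      i_all = matrix(i_all, 1), i_adj = matrix(i_adj, 1),
      i_all_mean = i_all, i_all_sd = rep(NA_real_, length(i_all)),
      i_adj_mean = i_adj, i_adj_sd = rep(NA_real_, length(i_adj)),
      n_sites = n_sites, n_replicates = 1L, mode = mode),
      class = "isite_curve")
  }
  ue <- mk_curve(c(20, 15), c(18, 14), 20, "UE")
  ie <- mk_curve(c(23, 18), c(21, 17), 20, "IE")
  ce <- mk_curve(c(30, 25), c(28, 24), 20, "CE")
  ex <- excess_decomposition(ce, ie, ue)
  a <- ex[ex$statistic == "I_all", ]
  expect_equal(a$combined, c(10, 10))
  expect_equal(a$local, c(3, 3))
  expect_equal(a$pairwise, c(7, 7))
  expect_equal(a$prop_pairwise, c(0.7, 0.7))
  expect_equal(a$combined_frac, c(0.5, 0.5))

  # identical curves: all components zero, the proportion flagged undefined
  ex0 <- excess_decomposition(ue, ue, ue)
  expect_true(all(ex0$combined == 0) && all(ex0$pairwise == 0))
  expect_true(all(is.na(ex0$prop_pairwise)))

  # the identity pairwise = combined - local is exact everywhere
  expect_identical(ex$pairwise, ex$combined - ex$local)
  expect_error(excess_decomposition(ce, ie, mk_curve(c(20, 15, 10),
                                                     c(18, 14, 9), 20, "UE")),
               "grid")
})

test_that("time-matched excess agrees exactly with the per-generation curves", {
  m <- tiny_random_model(10, 8, 7, density = 0.3)
  start <- generate_native_sequence(m, 8)
  cfg <- simulation_config(total_generations = 60, burn_in = 10,
                           n_replicates = 6, master_seed = 9)
  matched <- run_matched_replicates(m, start, cfg)
  tm <- time_matched_excess(matched, c(1, 2, 4))
  expect_setequal(tm$generation, c(10, 20, 40))
  expect_identical(tm$time[tm$generation == 40][1], 4)

  curves <- lapply(c(CE = "CE", IE = "IE", UE = "UE"),
                   function(x) isite_curve(mode_traces(matched, x)))
  full <- excess_decomposition(curves$CE, curves$IE, curves$UE)
  for (g in c(10, 20, 40)) for (st in c("I_all", "I_adj")) {
    expect_identical(
      tm$combined[tm$generation == g & tm$statistic == st],
      full$combined[full$generation == g & full$statistic == st])
  }
  expect_error(time_matched_excess(matched, c(1, 10)), "tracked")
})

test_that("divergence matching reads counts at the first crossing", {
  # hand-built: N = 10, one accepted event per generation
  tr <- fake_trace(site = rep(1:10, 2), accepted = rep(TRUE, 20), n_sites = 10)
  # first generation with cumulative accepted / N >= 1 is generation 10
  div <- cumsum(tr$accepted) / 10
  expect_identical(which(div >= 1)[1], 10L)
  matched <- list(fake_matched(list(CE = tr, IE = tr, UE = tr)))
  dm <- divergence_matched_excess(matched, 1)
  expect_true(all(dm$combined == 0) && all(dm$pairwise == 0))
  expect_identical(dm$n_used, rep(1L, 2))

  expect_error(divergence_matched_excess(matched, c(1, 50)), "50")
})

test_that("zero-parameter regimes show no divergence-matched excess", {
  m0 <- potts_model(array(0, c(8, 8, 5, 5)), matrix(0, 8, 5))
  cfg <- simulation_config(total_generations = 250, burn_in = 25,
                           n_replicates = 1, master_seed = 1)
  # same site AND residue streams: the three regimes are the same chain
  tr <- lapply(c(CE = "CE", IE = "IE", UE = "UE"), function(md)
    run_replicate(m0, rep(1L, 8), cfg, md, site_seed = 41, residue_seed = 42))
  dm <- divergence_matched_excess(list(fake_matched(tr)), c(1, 2))
  expect_true(all(dm$combined == 0))
  expect_true(all(dm$local == 0))
  expect_true(all(dm$pairwise == 0))
  expect_true(all(dm$n_excluded == 0))
})

test_that("strong couplings leave a positive epistasis-only excess at matched divergence", {
  spec <- synthetic_model_spec(n_sites = 25, coupling_density = 0.15,
                               coupling_scale = 1.2, seed = 31)
  m <- generate_potts_model(spec)
  m$native_sequence <- generate_native_sequence(m, 32)
  cfg <- simulation_config(total_generations = 800, burn_in = 100,
                           n_replicates = 25, master_seed = 33)
  matched <- run_matched_replicates(m, config = cfg)
  dm <- divergence_matched_excess(matched, c(1, 2))
  adj <- dm[dm$statistic == "I_adj", ]
  expect_true(all(adj$pairwise > 0))
  expect_true(all(adj$prop_pairwise > 0))
})
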
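---
title: "Simulating domain evolution under a Potts Hamiltonian: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating domain evolution under a Potts Hamiltonian: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pottsevol)
```

## The model

A protein domain family is described by a Potts model over $N$ alignment
columns and $q = 21$ states (the 20 amino acids plus the alignment gap
"`-`", treated as an ordinary state). The probability of a sequence
$a = (a_1, \dots, a_N)$ is

$$
P(a \mid J, h) \;=\; \frac{1}{Z}\exp\Big(\sum_{i<j} J_{ij}(a_i, a_j)
 + \sum_i h_i(a_i)\Big),
$$

where $J_{ij}(\cdot,\cdot)$ are pairwise site couplings (epistasis),
$h_i(\cdot)$ are local site-specific residue preferences, and $Z$ is a
partition function that is never computed: all dynamics depend only on
energy differences. `hamiltonian_log_weight()` evaluates the exponent;
`frobenius_coupling_map()` summarizes each $q \times q$ coupling block by
its Frobenius norm, the usual picture of which site pairs interact.

Couplings are stored as a full symmetric four-index array with both the
$(i,j)$ and $(j,i)$ blocks populated, $J_{ij}(a,b) = J_{ji}(b,a)$; the
Hamiltonian sums over $i<j$ only, while the single-site conditional sums
over all $j \neq i$. This redundancy avoids triangular-index bookkeeping;
symmetry is enforced at construction, where residual asymmetry above
$10^{-8}$ raises a warning before symmetrization.

## Three nested evolutionary regimes

Sequence evolution is a single-site Gibbs sampler: each *generation*, one
site is chosen uniformly at random and its residue is redrawn from the
conditional distribution of the $q$ states given the rest of the sequence.
Three nested regimes share this machinery (`nest_model()`,
`conditional_distribution()`):

* **CE** (coupled evolution): conditionals
  $\propto \exp\!\big(h_i(a) + \sum_{j\neq i} J_{ij}(a, a_j)\big)$ —
  epistasis and local preferences;
* **IE** (independent evolution): $J \equiv 0$, conditionals
  $\propto \exp(h_i(a))$ — local preferences only;
* **UE** (uniform evolution): $J \equiv h \equiv 0$ — the neutral null,
  every state $1/q$.

The redrawn state may equal the current one: the site was *tested* but not
substituted. Under UE this happens with probability $1/21$, so the null
substitution rate is exactly $20/21 \approx 0.952$ per generation — the
yardstick against which constrained regimes are measured.

Because one generation is one attempted substitution at one site, elapsed
time in *generations/site* is generations divided by $N$, and realized
*divergence* is accepted substitutions divided by $N$.

## Matched randomness

To compare regimes the simulator must test the same positions in the same
order under CE, IE and UE. A single shared RNG would desynchronize: the
residue draw consumes randomness differently in each regime. The
construction in `run_matched_replicates()` therefore gives each replicate
one *site stream* (shared by all three regimes, through burn-in and
beyond) and one *residue stream per regime*, with every generation
consuming exactly one variate from each stream (inverse-CDF residue
sampling from a single uniform). All stream seeds come from a table drawn
up front from the master seed, so results are independent of execution
order and trivially parallelizable.

Each replicate runs `total_generations` updates (default 30,000); the
first `burn_in` (default 5,000) bring the chain to steady state under each
regime's own dynamics and are discarded — under UE this fully randomizes
the sequence, which is the intended null. The sequence at the end of
burn-in is the *reference* for everything that follows, and each
post-burn-in generation is recorded in full (site tested, residue before,
residue drawn, accepted flag), so any statistic can be recomputed from the
trace; `replay_trace()` checks the record reproduces the final state
exactly.

## Invariant sites and the excess decomposition

A site is *invariant* at generation $g$ (`isite_curve()`'s `I_all`) if no
accepted substitution has touched it in generations $1..g$ — substituting
away and back does not restore invariance. `I_adj` additionally requires
the site to have been tested at least once, separating "conserved under
selection" from "never challenged". `I_adj` rises toward `I_all` as every
site gets tested, and `I_all` is non-increasing.

Subtracting the UE expectation isolates what the constraints add:

* combined effect: CE $-$ UE,
* local effect: IE $-$ UE,
* pairwise-epistasis-only effect: (CE $-$ UE) $-$ (IE $-$ UE) = CE $-$ IE,

computed per generation on replicate means (`excess_decomposition()`),
with the identity `pairwise = combined - local` holding exactly by
construction. The same decomposition is evaluated at matched elapsed time
(`time_matched_excess()`; grid in generations/site, generation
$= \mathrm{round}(t N)$) and at matched realized divergence
(`divergence_matched_excess()`): for each replicate and regime, the first
generation at which cumulative substitutions/site reach the grid value.
The first-crossing rule uses no interpolation — counts are integers and
any interpolation rule would be an invention; replicates that never reach
a divergence level in some regime are excluded from that grid point and
reported in `n_excluded`. Excess fractions are reported relative to $N$
(fraction of sites); the alternative normalization relative to the UE
count can be formed from the emitted columns. Headline statistics default
to `I_adj`, which removes the never-tested artifact, but `I_all` rows are
always emitted alongside.

## Rates and purifying selection

`evolutionary_rate()` is accepted substitutions per tracked generation,
per replicate, then averaged. `allowed_divergence()` expresses a
constrained regime's rate as a percentage of the UE rate; its complement
is the fraction of attempted replacements purged by purifying selection.
`selection_decomposition()` splits the CE purged fraction into the part
explained by local preferences (the IE purged fraction) and the remainder
attributable to epistasis alone; again the identity is exact. Ratios are
taken on replicate-averaged rates (ratio of means, not mean of ratios),
matching how a single summary rate per regime is naturally quoted.

`per_site_rates()` gives each site's substitution rate as its per-test
acceptance probability. The defining quantity is an interval ratio — mean
generations between tests over mean generations between accepts — but
pooled over events this reduces algebraically to accepts/tests, which is
the default because the interval form is fragile at rarely-accepting
sites (the trailing censored interval, and sites with fewer than two
accepts, bias it). Both interval orderings (pooled across replicates, and
per-replicate ratios averaged) are available as cross-check methods.
Sites never tested are flagged `never_tested` (rate `NA`); tested sites
with no accepts are flagged `never_accepted` (rate 0).

## The synthetic generator

`generate_potts_model()` emulates the statistical shape of real
domain-family parameters: a sparse minority of site pairs
(`coupling_density`, default 0.1) carry dense normal coupling blocks
(`coupling_scale`, default 1), over heterogeneous normal fields
(`field_scale`, default 1), $q = 21$. The defaults were chosen once as a
realistic regime — sparse contacts, coupling weight comparable to field
weight — and sized (`n_sites = 60`) so that a full matched triple runs in
seconds. `generate_native_sequence()` produces the starting sequence as a
single-site greedy ascent from a random start to a local maximum of the
log weight (sweep order seed-randomized, ties to the lowest state index):
exact ground-state search is intractable at realistic $N$, and what the
protocol needs is only a model-compatible high-fitness start, standing in
for a family's annotated reference sequence.

What the generator does *not* emulate: the contact-map geometry of real
structures (its coupled pairs are uniformly placed), phylogenetic
correlation between replicates (all replicates are independent lineages),
and any gap-state idiosyncrasy (the gap is statistically identical to the
other 20 states). Tests passing on synthetic models therefore demonstrate
the correctness of the machinery and the qualitative phenomenology —
coupling-induced invariant sites, reduced allowed divergence, rate
heterogeneity — not the parameter values of any real family, which
require the published per-family parameter files
(`inst/scripts/convert_mat_to_json.py` converts them,
`inst/scripts/reproduce_domain.R` runs the identical pipeline on them).

## Numerical choices

* Conditionals are computed in log space with max-subtraction before
  exponentiation; no clipping of $J$ or $h$, so arbitrarily strong
  (effectively frozen) sites are handled exactly.
* Residue draws use inverse-CDF sampling: the first state whose cumulative
  weight reaches the uniform variate. This makes every regime consume one
  variate per generation and makes draws reproducible across
  implementations of the same conditional.
* The compiled sampling path is verified against an independent R
  implementation and, on exhaustively enumerable models
  ($N \le 4$, $q \le 4$), against conditionals of the explicit joint
  distribution (agreement to $10^{-10}$) and the Boltzmann distribution of
  a $10^6$-step chain (chi-square on states thinned to every 10th
  generation, since consecutive Gibbs states are autocorrelated).
* The model JSON container writes doubles at 17 significant digits, so a
  save/load round trip is bit-exact.

## Problem sizes

The test suite exercises exhaustive oracles at $N \le 4$, $q \le 4$;
distributional checks at $N$ = 20–60 with 30,000-generation runs for rate
calibration; matched-replicate analyses at $N$ = 25–60 with 60–500
replicates and 900–3,000 generations; and a $1.01 \times 10^6$-step chain
for the stationarity check. These sizes give Monte-Carlo errors well
inside each assertion's tolerance while keeping the full suite under a
minute. Production analyses of real families use the protocol defaults
(500 replicates, 30,000 generations, 5,000 burn-in).

## A small worked run

```{r example, eval = FALSE}
spec <- synthetic_model_spec(n_sites = 60, seed = 1)
cfg <- simulation_config(total_generations = 3000, burn_in = 500,
                         n_replicates = 100, master_seed = 1)
bundle <- run_pipeline(synthetic_spec = spec, config = cfg,
                       time_grid = 1:4, divergence_grid = 1:2)
bundle$rates
plot(bundle$curves$CE)
```

## Known limitations

Single-lineage simulation only: no phylogeny, so nothing here speaks to
among-lineage rate correlation. No codon or nucleotide layer — mutation is
directly at the amino-acid level, as the parameter models are. Parameters
are inputs: the package performs no coupling inference from alignments,
and the Frobenius map is a visualization, not a contact predictor. The
paired significance tests used in the validation suite assume
across-replicate independence, which the seed construction guarantees,
but within-replicate generation-to-generation dependence means
per-generation bands in the I-site curves are descriptive (one SD across
replicates), not simultaneous confidence bands.
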
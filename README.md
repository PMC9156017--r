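# pottsevol

Simulation and analysis of protein domain sequence evolution under a Potts
Hamiltonian, separating what pairwise epistasis contributes to molecular
evolution from what site-specific residue preferences contribute.

## The problem

Alignment columns of real protein families show strong substitution-rate
heterogeneity, including invariant sites (I-sites) that never change over
long evolutionary windows. Two distinct kinds of sequence constraint can
produce this: a site's own residue preferences, and epistatic coupling to
the residues at other sites. `pottsevol` disentangles them by evolving
sequences under a Potts model

$$P(a \mid J, h) = \tfrac{1}{Z}\exp\Big(\textstyle\sum_{i<j} J_{ij}(a_i,a_j)
+ \sum_i h_i(a_i)\Big)$$

over $N$ sites and 21 states (20 amino acids + the `-` gap), with
single-site Gibbs updates: each generation one random site's residue is
redrawn from its conditional distribution given the rest of the sequence.
Three nested regimes are run with a *shared site-selection random stream*,
so the same positions are challenged in the same order:

| regime | parameters | meaning |
|---|---|---|
| CE | $J$, $h$ | epistasis + local preferences |
| IE | $h$ only | local preferences only |
| UE | none | neutral null; substitution rate exactly 20/21 per generation |

From matched replicates the package computes I-site trajectories
(`I_all`, and `I_adj` which requires a site to have been tested),
the excess-I-site decomposition — combined (CE−UE), local (IE−UE), and
pairwise-epistasis-only (their difference) — at matched time or matched
divergence, evolutionary rates, the *allowed divergence* of each
constrained regime relative to the null and its purged complement, the
decomposition of purifying selection into local and epistasis-only parts,
and per-site substitution-rate profiles. It is aimed at molecular
evolution researchers studying rate heterogeneity, site invariance and
epistatic constraint.

A synthetic-model generator (sparse strong coupling blocks, heterogeneous
fields, greedy-ascent native sequences) makes every analysis reproducible
without external parameter files; published per-family parameter MAT files
can be converted with `inst/scripts/convert_mat_to_json.py` and analyzed
at full scale with `inst/scripts/reproduce_domain.R`.

## Worked example

```r
library(pottsevol)

spec <- synthetic_model_spec(n_sites = 60, seed = 1)   # 21 states, 10% coupled pairs
cfg <- simulation_config(total_generations = 3000, burn_in = 500,
                         n_replicates = 100, master_seed = 1)
bundle <- run_pipeline(synthetic_spec = spec, config = cfg,
                       time_grid = 1:4, divergence_grid = 1:2)
bundle$rates
#> Evolutionary rates (100 replicates)
#>   mode   rate     sd allowed_divergence purged
#> 1   CE 0.4281 0.0234               45.0   55.0
#> 2   IE 0.8960 0.0064               94.1    5.9
#> 3   UE 0.9523 0.0047              100.0    0.0
#> purifying selection: combined 55.0% = local 5.9% + pairwise 49.1% (pairwise share 89.2%)
```

The UE null evolves at 0.9523 substitutions/generation (theory: 20/21 ≈
0.952). Local preferences alone purge 5.9% of attempted replacements;
adding epistasis purges 55.0%, so for this model 89.2% of the purifying
selection is attributable to pairwise coupling alone.

```r
subset(bundle$time_matched, statistic == "I_adj")[
  , c("time", "combined", "local", "pairwise", "prop_pairwise")]
#>  time combined local pairwise prop_pairwise
#>     1    17.21  1.35    15.86     0.9215572
#>     2    20.78  1.21    19.57     0.9417709
#>     3    19.63  0.83    18.80     0.9577178
#>     4    17.47  0.35    17.12     0.9799657
```

At 1–4 generations/site, constraint keeps an excess of 17–21 of the 60
sites invariant relative to the neutral null (`combined`), almost all of
it due to epistasis rather than local preferences, and the epistatic share
(`prop_pairwise`) grows with elapsed time. `plot(bundle$curves$CE)` draws
the I-site trajectories with across-replicate bands;
`plot_coupling_map(bundle$model)` shows the Frobenius-norm coupling map.

See `vignettes/potts-evolution-methods.Rmd` for the model, the matched
random-stream construction, and every numerical choice.

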
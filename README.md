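# killitox

From larval killifish behavior and brain expression to cohort-level risk.

Sublethal exposure to neurotoxicants such as methylmercury (MeHg) and the
dioxin-like PCB congener PCB126 alters how larval fish swim and feed long
before it kills them. Whether those alterations matter for a *population*
is a different question: a larva that swims a little less or handles prey a
little slower may grow more slowly, stay small — and therefore vulnerable
to predators — longer, and die at a higher rate. `killitox` implements the
full computational chain that connects the measurable endpoints to that
population-relevant outcome, for a two-population Atlantic killifish
(*Fundulus heteroclitus*) design: a reference population (SCO) and a
PCB-tolerant population from a contaminated site (NBH), each with control
and exposed treatment groups.

The chain, and the package modules that implement it:

1. **Synthetic assay data** (`gen_trajectory`, `gen_vmr_trajectory`,
   `gen_feeding_events`, `gen_counts`) — multi-state movement trajectories
   with state-dependent gamma step lengths and von Mises turning angles,
   alternating light/dark (visual motor response, VMR) records, Poisson/
   Bernoulli feeding events, and negative-binomial count matrices with
   planted fold-changes. Every downstream stage is testable without any
   data download.
2. **Behavior endpoints** (`endpoint_table`, `total_distance`,
   `detect_bouts`, `turning_angles`, `startle_magnitude`,
   `feeding_endpoints`) — the per-larva endpoint catalogue (distance, time
   swimming, bout counts/durations, step-length and turning-angle
   summaries, startle, five feeding metrics), overall and per assay period.
3. **Movement HMM** (`fit_movement_hmm`, `decode_states`,
   `hmm_behavior_endpoints`) — a 3-state (slow/medium/fast) hidden Markov
   model of swimming. Observations per frame are a step length
   `s_t ~ Gamma(k_z, theta_z)` and a turning angle
   `a_t ~ vonMises(mu_z, kappa_z)` conditionally independent given the
   state `z_t`, which follows a first-order Markov chain with transition
   matrix `Gamma`. Fitting is Baum-Welch EM pooled across larvae (shared
   parameters, independent chains), with jittered restarts; the forward,
   backward and Viterbi recursions run in compiled code.
4. **Trend calls** (`compare_behavior`, `de_test`, `bh_adjust`,
   `gene_set_test`) — every endpoint and gene is summarised over the five
   ordered treatment comparisons as Pos/Neg/NS: behavior through a Bayesian
   two-arm comparison (95% credible interval of the mean difference, sign
   from back-transformed means), genes through per-gene negative binomial
   GLMs with library-size offsets at a false discovery rate of 0.05, gene
   sets through direction-aware hypergeometric over-representation.
5. **Pattern concordance** (`encode_trend_vector`, `group_by_pattern`,
   `match_gene_behavior`) — genes and behaviors are matched when their
   trend vectors across the comparisons are identical ("original") or
   exactly sign-flipped ("opposite").
6. **Individual-based model** (`run_cohort`, `derive_multipliers`,
   `ibm_config`) — 2500 individual larvae per replicate are tracked daily
   from hatch to juvenile stage (15 mm) or 100 days, 10 replicates per
   scenario, spring and summer. Daily prey encounters follow a
   search-volume model, `lambda = D * pi RD^2 * SS * t_f` (prey density,
   reactive distance, swim speed, foraging time); intake is capture- and
   handling-limited and capped by an allometric maximum consumption; growth
   is bioenergetic, `dW = e_a C - R(W, T)` with temperature-scaled
   allometric respiration; mortality combines size-dependent predation
   `mu(L) = a L^b` (b < 0) with a starvation threshold. Treatment effects
   enter *only* through four behavior-derived multipliers (swim speed,
   capture success, handling time, reactive distance), so the simulated
   survival and growth differences are direct translations of the assay
   effects.

## Worked example

```r
library(killitox)

# simulate one larva, fit the movement HMM, inspect the fit
tr <- gen_trajectory(hmm_params(), n_steps = 5000, seed = 1)
total_distance(tr)            # 2295.2 mm
fit <- fit_movement_hmm(hmm_series(tr), n_states = 3, n_restarts = 3, seed = 1)
fit
#> Movement HMM fit: 3 states, 1 series, loglik -5968.54 (converged, 29 EM iterations)
#> Transition matrix:
#>          slow medium   fast
#> slow   0.8320 0.1322 0.0357
#> medium 0.1090 0.7845 0.1065
#> fast   0.0495 0.1692 0.7814
#> Step length mean (mm): 0.08212 0.352 1.136

# cohort consequences of PCB126-degraded foraging behavior
cfg <- ibm_config(); sc <- scenario("spring")
cohort_summary(run_cohort(cfg, sc, seed = 1, population = "SCO"))
#> control: 1.27% survival, 0.367 mm/d
cohort_summary(run_cohort(cfg, sc, default_multipliers()[["SCO-PCB"]],
                          seed = 1, population = "SCO"))
#> PCB126:  0.18% survival, 0.208 mm/d
```

The generating transition matrix behind the fit has diagonal
(0.85, 0.80, 0.80); the fitted values above recover it to within ~0.02 from
5000 frames. The cohort numbers read: under control behavior about 1.3% of
larvae reach the juvenile stage within 100 days growing ~0.37 mm/day, while
the PCB-style multiplier set (slower swimming, poorer capture, longer
handling, shorter reactive distance) collapses survival roughly sevenfold
and nearly halves survivor growth.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that run the whole
chain on simulated data and write tables under `results/`:

    01_simulate_data.R        assay + expression inputs for all 5 treatments
    02_behavior_endpoints.R   per-larva endpoint catalogue
    03_movement_hmm.R         per-treatment HMM fits + decoded endpoints
    04_trend_calls.R          Pos/Neg/NS calls for behaviors, genes, gene sets
    05_pattern_concordance.R  pattern groups and gene-behavior matches
    06_cohort_ibm.R           replicated cohort simulations, both seasons

Run them in order with `Rscript analysis/01_simulate_data.R` etc.

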
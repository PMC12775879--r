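# coalabc

Coalescent simulation and approximate Bayesian computation (ABC) for
uniparental phylogeography.

## The problem

Mitogenomes and the male-specific region of the Y chromosome (MSY) are
haploid, non-recombining markers, which makes them the workhorses for
reconstructing how domestic-animal lineages spread between continents.
The motivating application is the dispersal of an African domestic-pig
mitochondrial lineage whose carriers span a European source region
(`EUR`), western Africa (`WA`) and eastern Africa (`EA`): did the lineage
enter western Africa first and spread east (`EUR -> WA -> EA`), or enter
eastern Africa first and spread west (`EUR -> EA -> WA`)? Answering that
requires simulating competing serial-founder histories, summarising
sequence data into low-dimensional statistics, and comparing scenarios by
ABC — plus a variant-filtering chain to turn raw Y-chromosome calls into
analysis-ready hemizygous sequences.

`coalabc` provides, in one tested package:

* a backward-in-time **coalescent simulator** for multi-population
  divergence scenarios (pairwise coalescence rate `k(k-1)/(2*NE)`,
  instantaneous backward merges at times `t1 < t2`) with **HKY** mutation
  (rate `mu` per site per generation, transition/transversion `kappa`,
  arbitrary base frequencies, finite sites);
* the standard **summary statistics**: mean pairwise differences,
  segregating sites, rarest-allele moments, haplotype count/diversity
  `h = n/(n-1) (1 - sum p_i^2)`, nucleotide diversity, Hudson-style
  `F_ST = (pi_between - pi_within)/pi_between`;
* **Tajima's D** and an exact **Fu's Fs**
  (`Fs = ln(S'/(1-S'))`, `S' = Pr(K >= K_obs | theta = pi_hat)` under the
  Ewens sampling distribution via Stirling numbers), each with
  1000-coalescent-simulation p-values;
* the **ABC machinery**: MAD normalisation, rejection, scenario posteriors
  by the direct (kept-fraction) and multinomial-logistic methods,
  Beaumont-style local-linear parameter adjustment, RMAE precision
  diagnostics (flagging values > 0.2), PCA pre-evaluation of the
  scenario–prior combination, and posterior-predictive goodness-of-fit;
* the **MSY chain**: depth-ratio sexing, the four-step hemizygous filter
  (drop females; missing rate < 5%; minor allele frequency >= 0.001; no
  heterozygous calls), and DDX3Y/AMELY/UTY gene extraction and
  concatenation;
* **haplogroup frequency** summaries with the field's one-decimal
  rounding convention.

## Worked example

```r
library(coalabc)

# the two competing dispersal scenarios, priors and mutation model
scenarios <- e2_scenarios(n_eur = 10, n_wa = 10, n_ea = 6)
priors    <- e2_priors()           # mu ~ U(1e-8, 1e-7); NE, t1 < t2 priors
model     <- e2_mutation_model(sequence_length = 2000)

# reference table: 2,000 simulated datasets per scenario
tab <- build_reference_table(scenarios, priors, model,
                             n_sims_per_scenario = 2000, rng_seed = 7)

# a pseudo-observed dataset with known history (scenario 1) ...
pod <- simulate_dataset(scenarios[[1]], priors, model, rng_seed = 99,
                        variant_only = TRUE)
obs <- compute_statvector(pod$alignment, c("EUR", "WA", "EA"))

# ... and ABC model choice on it
mc <- abc_model_choice(tab, obs)
print(mc$direct, digits = 3)
#>    scenario  prob lower upper
#> 1 EUR_WA_EA 0.491 0.460 0.522
#> 2 EUR_EA_WA 0.509 0.478 0.540
```

The posterior hovers near 0.5: at these conditions the two serial-founder
topologies predict nearly identical statistic distributions, which is
exactly the behaviour reported for the real mitogenome data. Parameter
estimation under the winning scenario, in contrast, is well calibrated:

```r
est <- abc_estimate(tab, obs, priors = priors, scenario_id = "EUR_WA_EA",
                    config = abc_config(n_keep = 200))
est[est$parameter %in% c("t1", "t2"), c("parameter", "median", "q2.5", "q97.5")]
#>   parameter  median     q2.5 q97.5
#> 4        t1 2770.66  844.245  4000
#> 5        t2 5318.25 2588.272  8000
round(pod$params[c("t1", "t2")], 1)
#>     t1     t2
#> 3970.3 4298.5
```

Both true values fall inside their 95% credible intervals; over 100 such
pseudo-observed datasets the intervals cover the truth at close to the
nominal rate, while the RMAE diagnostic flags the single-locus time
estimates as imprecise (RMAE > 0.2) — the published caveat for this kind
of data.

Summary statistics on a toy alignment:

```r
t1 <- seq_alignment(c("ACGTACGT", "ACGTACGA", "ACGAACGT", "ACGTACGT"))
mean_pairwise_differences(t1)  #> 1
haplotype_stats(t1)            #> K 3.0000000, h 0.8333333
tajimas_d(t1)                  #> -0.7098962
fus_fs(t1)                     #> -0.8873032
```

The analysis workflow in `analysis/01_simulate_reference.R` ...
`06_haplogroup_frequencies.R` replays the whole study pipeline on
synthetic data, writing its tables under `results/`.

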
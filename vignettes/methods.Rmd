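---
title: "Coalescent simulation and ABC inference for uniparental phylogeography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent simulation and ABC inference for uniparental phylogeography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalabc)
```

# What this package models

`coalabc` implements the computational machinery for reconstructing the
dispersal history of a uniparentally inherited, non-recombining locus — a
mitogenome or the male-specific region of the Y chromosome (MSY) — sampled
from several geographically structured populations. The motivating setting
is the colonisation history of an African domestic-pig mitochondrial
lineage whose carriers live in a European source region (`EUR`), western
Africa (`WA`) and eastern Africa (`EA`). Two serial-founder histories
compete: the lineage entered western Africa first and spread east
(`EUR -> WA -> EA`), or entered eastern Africa first and spread west
(`EUR -> EA -> WA`). Scenario choice and parameter estimation are done by
approximate Bayesian computation (ABC) against coalescent simulations.

# The coalescent simulator

## Demography

Backward in time, each population of haploid effective size $N_E$ (the
effective number of gene copies; mitochondria and MSY are haploid, so no
factor of two appears) runs a standard coalescent: $k$ active lineages
coalesce at rate $k(k-1)/(2 N_E)$ per generation. The only demographic
events are instantaneous merges: at time $t$ the surviving lineages of the
founded population join its source (forward in time, a founder event
without a size change). A scenario with populations `EUR`, `WA`, `EA` and
merges at $t_1 < t_2$ is a serial-founder history. Population sizes are
constant between events; growth and bottlenecks are deliberately out of
scope because the competing histories under study use constant sizes.
Migration after divergence, recombination and selection are likewise not
modelled.

A merge whose source population has no surviving lineages is a no-op, and
scenario construction verifies that exactly one ancestral population
remains after all events, so every simulation ends in a single root.

## Mutation

Sequences of length $L$ evolve under the HKY substitution model: base
frequencies $\pi_A,\pi_C,\pi_G,\pi_T$ and a transition/transversion
parameter $\kappa$. The ancestral sequence is drawn from the base
frequencies; mutation events fall on each branch as a Poisson process with
rate $\mu L \times \text{branch length}$ ($\mu$ is the per-site,
per-generation rate), each event hits a uniformly chosen site and the base
is replaced according to the HKY rates conditional on a change
(transitions weighted by $\kappa$). Multiple hits at a site are allowed
(finite sites); an `infinite_sites = TRUE` shortcut assigns each event a
fresh site and is used only in tests of the event process itself.

Two numerical caveats are documented rather than hidden. First, the
conditional-on-change jump chain holds the per-site event rate at $\mu$
regardless of the current base; with unequal base frequencies its
stationary composition deviates slightly from $\pi$ — the deviation is
second-order in the per-site substitution load and is invisible at the
study's regime ($\mu \le 10^{-7}$, tree depths of $10^3$–$10^4$
generations, so $\ll 0.01$ substitutions per site), but it matters if the
simulator is pushed to saturation. With equal base frequencies the chain
is exactly stationary for any $\kappa$. Second, at high load the observed
diversity falls below the infinite-sites expectation $2 N_E \mu$ because
of multiple hits; the calibration tests therefore run at realistic,
unsaturated loads.

## Performance representation

Simulated alignments can be returned *variant-only*: a matrix holding just
the mutated columns plus the declared total length $L$, with the omitted
columns monomorphic by construction. Every statistic in the package is
written against that convention (difference counts use stored columns,
per-site denominators use $L$), and a dedicated test verifies that
variant-only and fully expanded alignments give identical statistic
vectors. This is what makes $4\times10^4$ simulations of 2 kb alignments a
minutes-scale computation in pure R.

## Priors and reproducibility

Parameter priors are uniform or log-uniform with order constraints
enforced by whole-vector resampling (`t1 < t2`). The mutation-rate prior
is uniform on $10^{-8}$–$10^{-7}$ per site per generation. The
effective-size and time priors default to documented placeholders chosen
once as plausible for a domestic-animal mitochondrial lineage on a
Holocene timescale: $N_E \sim U(100, 10^4)$ gene copies per population,
$t_1 \sim U(40, 4000)$ and $t_2 \sim U(40, 8000)$ generations. With a
generation time of 2.5 years (configurable; used only to convert reports
to ka) these spans cover roughly 0.1–20 ka, bracketing the divergence
dates discussed for this system. All of them are user-overridable through
`e2_priors()` or a YAML scenario configuration.

Reference tables derive one seed per row from the root seed up front, so
tables are bit-identical across runs and any row can be regenerated in
isolation from its stored `row_seed`.

# Summary statistics

The ABC statistic panel follows the one-sample/two-sample convention for
sequence data. Per population: mean pairwise differences, and the mean and
variance of the copy number of the rarest base across segregating sites.
Per population pair: haplotype count of the pooled sample, segregating
sites, mean pairwise differences, and Hudson-style
$F_{ST} = (\pi_B - \pi_W)/\pi_B$ computed from mean pairwise differences
(negative estimates clipped to zero). Sites containing `N` or `-` are
excluded pairwise; nucleotide diversity divides by the mean pairwise
compared length. Haplotypes are exact string matches on the cleaned
matrix. The rarest-allele variance uses the population denominator $S$
(these are descriptive moments of a dataset, not estimators of a
population quantity); the `"S-1"` denominator is available as an option.

Degenerate situations use explicit sentinels rather than NaNs: when no
site segregates the rarest-allele moments are recorded as 0, and when
between-population diversity is zero $F_{ST}$ is recorded as 0; both carry
a flag that propagates into a `flag_degenerate` column of the reference
table. Tajima's $D$ and Fu's $F_s$ are report-only statistics and never
enter the ABC distance, so sentinels cannot contaminate inference.

# Neutrality tests

Tajima's $D$ uses the standard 1989 constants. Fu's $F_s$ is computed
exactly: $S' = \Pr(K \ge K_{obs} \mid \theta = \hat\pi)$ under the Ewens
sampling distribution, with unsigned Stirling numbers of the first kind
evaluated in log space (a log-sum-exp recurrence, cached per sample size),
and $F_s = \ln(S'/(1-S'))$. $K_{obs} = 1$ yields the $-\infty$ sentinel.
Significance is assessed by the conventional 1000 coalescent simulations:
a neutral constant-size null calibrated to the observed $\hat\pi$, with
the *lower-tail* fraction reported, because these tests are used to detect
population expansion (an excess of rare variants and haplotypes drives
both statistics negative). Whether the original analyses were one- or
two-tailed is not stated in their description; the lower tail is the
expansion-detection convention and is what the calibration test checks
(p-values drawn from their own null are uniform by the
Kolmogorov–Smirnov test).

# ABC machinery

* **Normalisation** — every statistic column is divided by its median
  absolute deviation over the table (SD optional). Zero-scale columns
  carry no distance information and are dropped with a warning. At the
  small-$L$ study conditions the per-population rarest-allele variance is
  usually dropped this way (most simulated datasets have too few
  segregating sites for a nonzero variance), which is the normalisation
  behaving as designed, not a failure.
* **Rejection** — Euclidean distance on the normalised panel, ties broken
  by row index. Default retention: the nearest $500 \times$
  (number of scenarios) rows for model choice and the nearest 1% for
  parameter estimation; both configurable, since the original tool's
  settings are not reported. Ranking is pooled across scenarios.
* **Direct posterior** — the kept-fraction per scenario with a binomial
  normal-approximation CI.
* **Logistic posterior** — multinomial logistic regression of the scenario
  label on the normalised statistics over the kept rows, evaluated at the
  observed point; CIs by the delta method on the class probabilities.
  Near-separated fits (runaway coefficients) are refitted with a small
  ridge penalty and flagged.
* **Local-linear adjustment** — Beaumont-style regression of each
  parameter on the statistics with Epanechnikov weights (bandwidth = the
  largest kept distance); adjusted draws are the prediction at the
  observed point plus residuals. Strictly positive parameters are adjusted
  on the log scale and back-transformed, which prevents negative times and
  sizes; adjusted draws are clamped to the prior support with a count of
  clamps reported. Rank-deficient designs — and kept sets without a margin
  of at least five simulations over the number of covariates, whose
  near-saturated fits would collapse the posterior onto the regression
  prediction — fall back to rejection-only summaries, flagged in the
  `adjustment` column.
* **RMAE** — per parameter, the median over pseudo-observed datasets
  (PODs) of $|\hat\theta - \theta|/|\theta|$, with values above 0.2
  flagged as imprecise. PODs with a zero true value are excluded per
  parameter and counted.
* **Prior-scenario pre-evaluation** — PCA of the normalised simulated
  statistics; the observed vector is declared inside the cloud when it
  falls within the axis-aligned 1st–99th percentile box of the first two
  components. This is an operational stand-in for the usual visual check.
* **Goodness-of-fit** — posterior-predictive replication: datasets are
  simulated from the posterior draws, and the score is the fraction of
  replicate distances to the predictive cloud centre at least as large as
  the observed distance.

# What the validation experiments show — and what they cannot

The test suite calibrates the simulator against closed-form coalescent
expectations (mean TMRCA, $E[\pi] = 2 N_E \mu$, Watterson's $E[S]$),
checks every statistic against brute-force oracles, and verifies the
neutrality p-value machinery against its own null.

The scenario-recovery experiment deserves an honest note. At the study
conditions (2 kb of sequence, samples of 10/10/6, both scenarios sharing
symmetric priors), the two serial-founder topologies predict
almost-identical joint distributions of the statistic panel: the only
structural asymmetries are the sample sizes and which African population
hosts the other's lineages between $t_1$ and $t_2$. A strong non-parametric
classifier trained directly on 40,000 simulated statistic vectors separates
the scenarios barely above chance, so *no* posterior method can recover the
generating scenario much more often than ~55–65% of the time at these
conditions — and the analysis of the real mitogenome data reported a
posterior of essentially 0.5 for the winning scenario. The recovery
experiment in this package reproduces exactly that behaviour. The
credible-interval coverage of the local-linear estimates, by contrast, is
close to nominal, and the RMAE diagnostics correctly flag the
divergence-time estimates as imprecise — which is the published caveat for
this system.

Synthetic data cannot establish that the real data's haplogroup structure,
saturation level or sequencing artifacts are handled; passing tests show
the machinery is internally correct and calibrated, not that any
particular historical conclusion is right.

# The MSY chain

Sex is assigned from depth-of-coverage ratios: males carry one X and one
Y, so a sample is called male when its Y/autosome depth ratio is at least
0.25 and its X/autosome ratio is below 0.75; female when Y/autosome is
below 0.125 and X/autosome at least 0.75; anything else — including zero
autosomal depth — is unassigned. The thresholds are explicit parameters
because the original depth cutoffs are not published; the defaults sit
halfway between the hemizygous and diploid expectations (0.5 and 1.0)
with a buffer zone.

The variant filter runs in the published order: (1) drop female samples;
(2) drop sites with a missing-genotype rate of 5% or more among retained
males; (3) drop sites with minor allele frequency below 0.001 (computed on
non-missing, non-heterozygous male calls; monomorphic sites go here);
(4) drop sites with any heterozygous male call — at a hemizygous locus a
heterozygous diploid call is an artifact, and whole sites are removed
rather than individual genotypes (genotype-level masking is available as
an option at concatenation time via the missing-fill flag). Statistical
imputation of missing genotypes is out of scope; concatenation fills
missing calls with `N` or the site's majority allele. Gene extraction
keeps sites inside the DDX3Y/AMELY/UTY intervals (1-based inclusive,
VCF-style) and concatenates alleles in interval order then position order.

# Problem sizes used by the packaged experiments

The packaged validation runs use 20,000 simulations per scenario at
$L = 2000$ bp with 100 PODs per experiment (the acceptance script scales
to 10,000 and 50 to replay faster); the coalescent calibration uses
20,000 replicates at $n = 20$; the neutrality calibration uses 200 trials
of 1000 simulations each. The full study design — one million simulations
per scenario at the complete 14,979 bp mitogenome — is a straight
parameter change (`n_sims_per_scenario`, `sequence_length`) and streams to
disk via `build_reference_table(file = ...)` so the table need not be
memory-resident.
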
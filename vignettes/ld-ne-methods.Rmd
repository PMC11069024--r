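---
title: "LD-based Ne estimation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-based Ne estimation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ldner)
```

This vignette is the package's own account of the science it implements:
the model behind each estimator, the parameters a user can move and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the places where the design was genuinely open
and a choice had to be made. It states no empirical result that the test
suite or the acceptance script does not itself compute.

## 1. The model

An isolated Wright–Fisher population of effective size $N_e$ generates
linkage disequilibrium between loci by drift. For two loci with
recombination fraction $c$, the stationary expectation of the squared
allelic correlation under monoecious random mating is, in the composite
(dosage) form the package measures,

$$E[\hat r^2] \;=\; \frac{(1-c)^2 + c^2}{2 N_e\, c\,(2-c)} \;+\;
E_{\mathrm{samp}}(S),$$

which reduces to $1/(4N_e c)$ for tightly linked loci (the familiar
Sved-type limit) and to $1/(3N_e)$ at $c = 1/2$ (unlinked loci). The
second term is what a finite sample of $S$ diploids adds even without
any drift signal.

### 1.1 The pair statistic

With unphased genotypes the gametic $r$ is not observable; the package
uses the Burrows composite: for each locus pair, the squared Pearson
correlation of dosage vectors over pairwise-complete individuals,
multiplied by $(S_p/(S_p-1))^2$ where $S_p$ is the pair's complete
sample size. The factor is the small-sample bias correction that the
classical LD–Ne tools apply to the Burrows covariance. It matters more
than it looks: the null expectation of the *plain* squared Pearson
correlation is $1/(S-1)$ at every $S$, whereas the adopted sampling
calibration

$$E_{\mathrm{samp}}(S) = \begin{cases}
1/S + 3.19/S^2 & S \ge 30\\
0.0018 + 0.907/S + 4.44/S^2 & S < 30
\end{cases}$$

equals $(1/(S-1)) \cdot (S/(S-1))^2$ to four decimals at every $S$ we
checked — i.e. it calibrates the *bias-corrected* composite, not the
plain correlation. Pairing plain Pearson $r^2$ with this calibration
over-subtracts and inflates $\hat N_e$ by roughly 1.5-fold at $S = 50$;
with the factor in place the parameter-recovery tests in the suite
recover a simulated $N = 100$ with a geometric-mean estimate near 100.
User-facing summaries (`pairwise_r2()`) report both the bounded plain
statistic (`mean_r2`, guaranteed in $[0,1]$) and the adjusted value the
estimators consume (`mean_r2_adj`).

### 1.2 The unlinked (contemporary) estimator

`estimate_ne_unlinked()` averages the adjusted $\hat r^2$ over
between-chromosome pairs (recombination fraction fixed at $1/2$),
subtracts $E_{\mathrm{samp}}(\tilde S)$ at the harmonic-mean
pairwise-complete sample size $\tilde S$ (harmonic, because the
sampling term is convex in $1/S$), and inverts the drift quadratic:

$$\hat N_e = \frac{1/3 + \sqrt{1/9 - 2.76\,\hat r^2{}'}}{2 \hat r^2{}'}
\quad (S \ge 30), \qquad
\hat N_e = \frac{0.308 + \sqrt{0.308^2 - 2.08\,\hat r^2{}'}}{2 \hat r^2{}'}
\quad (S < 30).$$

Two degenerate regions need a convention:

* $\hat r^2{}' \le 0$: no drift signal distinguishable from sampling
  noise; the point estimate is $+\infty$ with a flag, matching the
  `Inf` convention of published LD–Ne tables.
* discriminant $< 0$: $\hat r^2{}'$ exceeds the maximum the forward
  relation can produce (about $0.040$ in the large-$S$ regime). This
  arises in practice under strong *mixture* LD — e.g. pooling two
  long-diverged gene pools — where the data imply a drastically
  **small** apparent $N_e$, not a large one. The estimate therefore
  saturates at the invertible floor (the peak of the forward relation,
  $\approx 4.1$ diploids for $S \ge 30$, $\approx 3.4$ below) and the
  `saturated` flag is set. Mapping this case to $+\infty$ instead would
  invert the documented direction of the Wahlund bias; the package
  deliberately departs from that convention.

Confidence intervals are a delete-one jackknife over individuals (not
loci). The jackknife variance is computed on the $\hat r^2{}'$ scale,
where a normal approximation is defensible, and the endpoints are
pushed through the inversion; since the inversion is unbounded, a
non-invertible endpoint is reported as `Inf`. With heavy pseudo-
replication (every locus participates in many pairs) the jackknife over
individuals is the honest axis of resampling.

### 1.3 The trajectory (recent-history) estimator

`estimate_ne_trajectory()` bins within-chromosome pairs by
recombination fraction (Haldane transform of the map distance), applies
the same sampling correction per bin, inverts the Weir–Hill form above
per bin, and references bin $b$ to $t_b = 1/(2\bar c_b)$ generations
ago: loosely linked pairs inform recent $N_e$, tightly linked pairs
older $N_e$. The pure Sved inversion $(1/\hat r^2{}' - 1)/(4\bar c)$ is
exported as `sved_ne()` and agrees with the Weir–Hill inversion for
small $c$, but under-predicts the composite $r^2$ by ~1.5-fold for
$c \gtrsim 0.15$; using it for the recent-window bins fails the
package's own parameter-recovery tests, which is why the trajectory op
uses `weir_hill_ne()`. This simplified binned trajectory deliberately
replaces the genetic-algorithm trajectory fit of genome-scale tools; it
shares the timescale logic but not the fitting machinery, so findings
about those tools' trajectory artefacts translate only qualitatively.

## 2. Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `min_pair_S` | 10 individuals | below ~10 complete genotypes a pair's $r^2$ is wildly unstable; skipped pairs are counted, never silently used |
| `max_pairs_per_bin` | 50,000 pairs | caps cost on dense panels; subsampled with an explicit seed, mirroring the per-chromosome SNP caps of genome-scale tools |
| `bin_edges` | 12 log-spaced bins on $[0.001, 0.5]$ | log spacing equalizes information across the LD decay curve; pairs below $c = 0.001$ carry deep-history signal the desk-scale simulator cannot calibrate |
| `min_pairs_per_bin` | 100 | thinner bins are dropped with a warning rather than reported as noise |
| singleton filter | on in pipelines | rare alleles upwardly bias $N_e$; a singleton is one copy among the $2\times$ non-missing individuals (a single heterozygote is a singleton) |
| MAF filter | off | not required by this family of estimators and can cause a small upward bias; a warning says so whenever a positive threshold is used |
| `chr` correction | $y = 0.098 + 0.219\ln(\mathrm{Chr})$ | divisor for estimates that mix physically linked pairs; **skipped** (with a message) for unlinked-policy estimates, which already exclude within-chromosome pairs |
| sparse-data threshold | 300 SNPs/chromosome | validator warning level, bracketed by observed failure (~250/scaffold) vs success (~670/scaffold) of genome-scale tools; the tools' true internal criterion is not published, so it is configurable |
| `n_replicates` | 50 | standard resampling depth for experiment designs; the test suite runs scaled-down profiles (4–10) with correspondingly loose tolerances |

## 3. What the simulator emulates — and what it does not

`simulate_population()` implements the idealized population the
estimator calibration assumes: discrete generations, monoecious random
mating with selfing allowed (each parent drawn uniformly with
replacement, so selfing probability $1/N$), diploid gametes built by a
per-locus Markov walk whose switch probabilities are Haldane transforms
of map intervals (parity-equivalent to Poisson crossovers), standing
variation initialized in linkage equilibrium at
Uniform(0.05, 0.95) frequencies, and no mutation during the run.

Defaults that encode the stated world:

* **Burn-in** `min(4 N, 500)` generations: enough for LD at
  $c \ge 0.01$ to approach drift–recombination stationarity at desk
  scale; configurable because real datasets arrive with their own
  (unknown) history.
* **Each chromosome 1 Morgan** by default — the convention map-free
  tools assume — with bp positions generated at 1 cM = 1 Mb purely for
  I/O realism (bp carries order, nothing more).
* **Two demes**: founded from one ancestral frequency pool, diverged in
  isolation for `divergence_burnin` generations, then
  `burnin_generations` of contact with per-parent-draw migration
  probability `migration_rate`. Founders carry ancestry $Q \in \{0,1\}$
  and offspring inherit the parental mean, so $Q$ is *pedigree*
  ancestry — a proxy for the model-based cluster membership of
  admixture software, close in spirit but not numerically identical.
  With zero migration $Q$ stays exactly in $\{0,1\}$, which the tests
  exploit.

Not emulated: overlapping generations, age or stage structure, seed
banks, selection, non-equilibrium mutation, genotyping error, and —
except through the optional `het_factor` of `inject_missing()`, which
inflates heterozygote missingness to probe depth-dependent genotype
loss — any non-random missingness mechanism. A green test therefore
establishes that the estimator behaves as designed *in the idealized
regime it was calibrated for*; it does not certify accuracy for
species with life-history departures from Wright–Fisher, where the
quantity recovered drifts toward the effective number of breeders or a
neighbourhood size rather than generational $N_e$.

## 4. Experiment designs

`run_experiment()` applies one perturbation at several levels,
`n_replicates` times per level with seeds derived deterministically per
(level, replicate), estimates Ne for each perturbed dataset
(singleton-filtered by default), and summarizes each level by
`exp(mean(log(x)))` with 95% percentile intervals. Conventions fixed
for reproducibility:

* quantiles are type-7 (sort-and-linearly-interpolate);
* infinite estimates are excluded from geometric means and reported as
  a per-level count (their handling is otherwise undocumented in the
  literature this follows);
* the ancestry-gradient design standardizes every threshold subset to
  the size of the smallest subset, so sample size is not confounded
  with admixture level; the `pooled` level combines both demes at the
  same standardized size;
* a level whose perturbation is infeasible (an empty ancestry stratum,
  a subsample larger than the population) is marked failed with its
  reason and the run continues.

The fragmentation design re-analyzes one fixed genotype matrix under
maps that split each true chromosome into equal blocks renumbered as
pseudo-chromosomes, each rescaled to 1 Morgan with genetic positions
proportional to bp — exactly the assumption a map-free tool makes about
scaffolds. Fragmentation misclassifies truly linked pairs as
between-"chromosome" pairs, so the unlinked estimator absorbs excess
LD and is dragged downward, and the error grows with the fragmentation
factor; the acceptance suite asserts the accuracy loss and *reports*
the signed direction without asserting it, because full-trajectory
fitting tools are documented to move in the opposite (upward)
direction through a different mechanism (loss of loosely linked pairs
from their recent-Ne window).

## 5. Numerical and I/O choices

* **Seeds.** One root seed per run; child streams are derived by an
  integer hash (`derive_seed()`) per operator invocation, all below
  $2^{31}$. Seeded helpers save and restore the caller's RNG state.
* **Pair enumeration.** Exhaustive when the candidate count is modest
  (so small problems are exactly reproducible and oracle-checkable);
  uniform rejection sampling above ~3M candidates, then capped
  per class/bin.
* **Pair means.** The mean $\hat r^2$ is unweighted across retained
  pairs — simpler and exactly reproducible by a brute-force oracle — a
  recorded deviation from tools that weight pairs internally.
* **Missing data.** The missing sentinel is `NA`, never 0: dosage 0 is
  a valid homozygote. Monomorphic loci are flagged and dropped with
  counts, never silently used.
* **PED/MAP dialect.** PLINK-style text; six lead columns with neutral
  placeholders; missing genotype = `0 0`; cM written as Morgans × 100.
  On reading, dosage counts the ASCII-second allele among those
  observed at the locus, so round trips are exact for polymorphic loci
  and monomorphic loci come back as dosage 0 (they are filtered before
  estimation anyway).
* **VCF subset.** GT-only, biallelic, diploid; `./.` is missing; phase
  separators ignored; multiallelic and non-diploid records skipped and
  counted. Genetic positions are filled from bp at 1 cM = 1 Mb — the
  1-Morgan-per-chromosome convention again — and contigs are mapped to
  integer ids in order of appearance.
* **Display rounding** is one decimal (round-half-even) in printed
  reports; full precision is kept internally and in serialized output.
  `Inf` serializes as the string `"Inf"` in both TSV and JSON.

## 6. Known limitations

* The calibration constants are the published random-mating fits; the
  package does not re-derive them, and their small-$S$ regime is an
  empirical fit whose error grows below $S \approx 10$.
* The trajectory estimator assumes a constant-$N$ interpretation per
  bin; demographic change shows up as disagreement across bins, not as
  a fitted trajectory.
* Pedigree-$Q$ and model-based $Q$ agree qualitatively, not
  quantitatively; ancestry-gradient results translate to
  admixture-software thresholds only approximately.
* The jackknife CI underestimates uncertainty when pairs are few and
  highly overlapping (pseudoreplication); the replicate percentile
  intervals of the experiment harness are the more honest spread
  measure at desk scale.
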
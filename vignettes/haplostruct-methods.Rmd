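---
title: "Models and methods behind haplostruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haplostruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`haplostruct` analyses aligned, non-recombining (typically mitochondrial)
DNA sampled across localities: who is connected to whom, how genetic
variation partitions over geography, and what demographic history left
its mark on the sequences. This vignette explains the models, the
conventions and the genuinely open design choices; it is the package's
methodological record. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Data model and filtering

An alignment (`aln`) is a character matrix over `{A, C, G, T, N, -}`
with unique individual ids; a population map (`popmap`) assigns each
individual to a sampling locality and optionally a regional group. All
statistics operate on a single consistent site set: `drop_gap_sites()`
removes every column containing a gap or `N` in any sequence
(complete deletion). We chose complete deletion over pairwise deletion
because haplotype identity must be an equivalence relation — with
pairwise deletion two sequences can each "match" a third yet differ from
one another. The analysed length `L` after filtering is reported next
to every per-site quantity so the identity `d = pi * L` stays auditable.

Two further conventions:

* Haplotype identity is exact string equality after gap-column removal;
  `N` never matches anything because `N`-containing columns are already
  gone under the default policy.
* Localities with fewer than `min_n = 5` individuals are excluded from
  population-level statistics (pairwise Phi_ST, AMOVA); they still
  contribute to pooled diversity, networks and demographic analyses.
  Single-individual localities yield `NA`-flagged diversity rows rather
  than zeros, so regional averages are never silently deflated.

## Diversity statistics

For a sample of `n` sequences: `S` counts polymorphic columns, `H` the
distinct haplotypes, `h` is Nei's unbiased gene diversity
`n/(n-1) * (1 - sum p_i^2)`, `d` the mean number of pairwise differing
sites, and `pi = d / L`. The pooled "total" row is a pooled-sample
statistic by default; an unweighted mean of per-locality values is
available (`pooled = "mean"`) because published summary tables use
either convention.

## Distances

Between-sequence distances use Tamura–Nei (1993) with optional gamma
rate heterogeneity. The gamma correction is by term substitution: each
`-log(w)` in the closed form becomes `alpha * (w^(-1/alpha) - 1)`,
which converges to the logarithm as `alpha` grows. Sites outside
`{A,C,G,T}` in either sequence are skipped. When a logarithm or power
argument is non-positive the pair is *saturated*: the model cannot fit,
and the pair is flagged rather than clamped — callers choose between an
error listing the pairs and a raw p-distance fallback. The substitution
model and `alpha` are configuration inputs (default TN93,
`alpha = 0.5`) recorded in the run manifest, since model selection
itself is out of scope. The implementation is validated in the test
suite against `ape::dist.dna` to 1e-9 with and without gamma.

## AMOVA, Phi statistics and permutation tests

The hierarchical analysis of molecular variance partitions the total
sum of squared molecular distances into among-group, among-population-
within-group and within-population components, using the standard
unbalanced-design coefficients, and forms the fixation indices

* `Phi_CT = sigma_a / sigma_T`,
* `Phi_SC = sigma_b / (sigma_b + sigma_c)`,
* `Phi_ST = (sigma_a + sigma_b) / sigma_T`,

which always satisfy `(1 - Phi_ST) = (1 - Phi_CT)(1 - Phi_SC)`.

**Metric convention.** The sum of squares is built from *squared
Euclidean* distances. For DNA sequences the number of differing sites
is itself the squared Euclidean distance (each differing site
contributes `1 = 1^2`), and the substitution-model-corrected matrix is
its model-scale analogue. The supplied distance matrix is therefore
used as-is (`squared = TRUE`, the convention of the classical AMOVA
worked examples); `squared = FALSE` squares a linear distance first. We
verified by simulation that re-squaring difference-derived distances
inflates Phi_ST relative to the island-model expectation, while the
as-is convention recovers it exactly.

Negative variance components (possible in unbalanced or weakly
structured designs) are reported as computed and flagged, never
truncated, so indices remain comparable with standard software output.

Significance uses permutation tests with `p = (b + 1)/(B + 1)` — the
smallest attainable p is positive, and the observed arrangement counts
as one realisation. Schemes follow the standard mapping: `Phi_ST`
permutes individuals among populations; `Phi_SC` permutes individuals
among populations within their group; `Phi_CT` permutes whole
populations among groups. For tiny designs an exhaustive enumeration
over all distinct label arrangements is available (`exact = TRUE`).
Pairwise Phi_ST matrices are corrected for multiple testing by
Benjamini–Hochberg FDR.

## Median-joining networks and inverse-origin weights

The network module implements the median-joining principle: starting
from the observed haplotypes, quasi-median (Steiner) sequences built
from node triplets — per-site majority state, enumerating all three
states where the triplet is fully discordant — are added greedily while
they reduce the weighted minimum-spanning-tree cost; median vectors
whose removal leaves the cost unchanged are pruned; and the reported
network is the epsilon-relaxed minimum spanning network (the union of
all minimum spanning trees at `epsilon = 0`). Construction runs on the
polymorphic columns only, which changes nothing (constant columns carry
zero distance) and keeps the search fast. Tie-breaks among equal-gain
candidates are lexicographic on the sequence, so node ids are
deterministic. On every fixture small enough for exhaustive
Steiner-point search (up to 6 haplotypes over 8 sites) the greedy
construction attains the optimal network cost; this is asserted in the
test suite.

Sites are weighted by the inverse of their inferred number of origins:
a site mutating on one network edge keeps the base weight 90; a site
mutating on `r >= 2` distinct edges gets `90 / r`. Because the origin
counts require a network and the network depends on the weights, the
default procedure is two-pass — build under uniform weights, count
origins on that network (median vectors included), rebuild under the
inverse-origin weights. The iteration count is a convention, not a
derived quantity; with homoplasy-free data the second pass is a fixed
point of the first.

`epsilon` defaults to 0 (the most parsimonious network); increasing it
adds near-minimal alternative connections and can only grow the edge
set.

## Mismatch distributions and the sudden-expansion model

The observed mismatch distribution is the histogram of pairwise
difference counts. Under an instantaneous expansion from scaled size
`theta0` to `theta1` at time `tau = 2ut` mutational units ago, the
probability of observing `i` differences between two sequences is

F_i = F^(i, theta1) + exp(-tau (theta1 + 1)/theta1) *
      sum_{j=0}^{i} tau^j / j! * [F^(i-j, theta0) - F^(i-j, theta1)],

with the equilibrium law `F^(i, theta) = theta^i / (1 + theta)^(i+1)`.
At `tau = 0` this reduces to the equilibrium geometric form; with
`theta0 = 0` and `theta1 -> Inf` it approaches Poisson(`tau`). Both
limits are asserted numerically (1e-9 and 1e-3). The convolution is
evaluated in vectorised form and the geometric terms in log space, so
wide supports stay finite.

Parameters are estimated by least squares: the SSD between observed
relative frequencies and model probabilities, evaluated on the observed
support trimmed of trailing zeros (making SSD invariant to zero
padding), is minimised by Nelder–Mead from 20 scattered restarts within
`tau in [0, 4 * max_diff]` and `theta in [0, 10 * d]`. `theta1` is
estimated freely; equivalence with other least-squares implementations
is claimed at the level of SSD minimisation, not iterate-for-iterate.

The SSD goodness-of-fit p-value and the 95% CI of `tau` come from
parametric resampling: coalescent samples of the observed size are
simulated under the fitted expansion history (a single-deme genealogy
with the matching instantaneous size change, infinite-sites mutations),
each replicate is refitted (warm-started at the observed fit plus
scattered restarts), and `p = (b + 1)/(B + 1)` counts replicates with
SSD at least the observed; the CI is the percentile interval of the
refitted `tau`. `B` defaults to 10,000; reduced values are used in
tests and examples, with sizes stated below.

## Neutrality tests

Tajima's `D` uses the canonical constants and is undefined (flagged) at
`S = 0`. Fu's `Fs` is `ln(S'/(1 - S'))` with
`S' = P(K >= k_obs | theta = d)` under the Ewens sampling distribution;
the probabilities use unsigned Stirling numbers of the first kind over
the rising factorial, computed in log space with stable log-sum-exp so
samples of several hundred sequences remain exact. For `n <= 8` the
implementation agrees with an exact integer-arithmetic enumeration to
1e-12.

Significance for both tests comes from neutral coalescent simulation —
`theta = S/a1` (Watterson) for `D`, `theta = d` for `Fs` — with
lower-tail p-values, since the biological signal of interest (recent
expansion) is an excess of rare variants. Note Fu's convention: `Fs` is
deemed significant at the 5% level when its simulation p is below 0.02.
A closed-form (beta-approximation) alternative is deliberately not
included; the simulation null keeps the pipeline self-contained.

## Expansion dating

`t = tau / (2u)` generations, with `u = mu * s` the whole-fragment
mutation rate per generation. The per-site rate `mu` derives from an
interspecific divergence rate quoted in percent per site per million
years (default 0.52) times the generation time (default 2 years).
Whether a divergence rate (which accumulates along two lineages) should
be halved into a per-lineage mutation rate is ambiguous in practice;
the default applies it un-halved, because with the package's defaults
that convention yields Pleistocene-scale dates of the magnitude this
kind of data produces, and a `halve_rate` flag implements the other
convention — switching it exactly doubles `t`, and doubling `s` exactly
halves it. CI endpoints transform identically to the point estimate.

## Haplogroup clustering

The clustering module is a deliberately simple *surrogate* for
Bayesian linkage-model clustering: haplotypes (weighted by their
counts) are partitioned to maximise an independent-sites
Dirichlet-multinomial marginal likelihood over the polymorphic-site
nucleotide counts with a symmetric prior `alpha = 0.25` per nucleotide.
The number of clusters is chosen by the maximum marginal likelihood
itself — the Occam factor of the marginal likelihood is the only
complexity penalty. The search is randomised greedy reassignment with
`runs x replicates` restarts per candidate K (defaults 10 x 6, K up to
22). This model ignores linkage between sites, so its acceptance is
defined by planted-partition recovery (adjusted Rand index 1 on
well-separated plants across seeds), not by reproducing the membership
any specific linkage-aware program would report.

## The synthetic-data generator

`simulate_coalescent()` draws a haploid structured-coalescent genealogy
and drops Poisson mutations on its branches over a finite-sites
sequence (so homoplasy exists and the network reweighting rule is
genuinely exercised), with either uniform (JC) or transition-biased
substitutions. Conventions:

* Time is in units of `N` generations; `theta = 2 N mu_locus` is the
  per-locus scaled mutation rate, so `tau_sim = 2ut` conversions
  round-trip with the dating module, and the expansion epoch sits at
  coalescent time `tau/theta`.
* `migration` is `M = 2Nm`. Each lineage migrates at rate
  `(M/2) * (d-1)/d` with a uniformly chosen target deme. The `(d-1)/d`
  finite-island correction makes the classical expectation
  `Phi_ST = 1/(1 + 2Nm)` exact for any number of demes `d` (the
  uncorrected many-deme convention gives `1/(1 + 2M)` at `d = 2`).
* `migration = 0` with several demes is rejected unless a `merge_time`
  is given, at which all demes join one ancestral pool — this is how
  deep-vicariance scenarios (bimodal mismatch distributions) are
  simulated.

What the generator emulates: island-model structure, localities down to
a handful of individuals, sudden expansions, deep splits, finite-sites
homoplasy. What it does not: recombination, selection, serial sampling,
rate variation among sites, sequencing error, or alignment uncertainty.
Passing tests on synthetic data therefore validate the estimators under
their own model assumptions; they cannot certify robustness to
misalignment or selection on real data.

## Validation experiments and their sizes

The test suite runs these stochastic checks (sizes chosen to keep the
suite at desk scale; all seeds fixed):

* neutral-coalescent calibration: mean `d` within 3 MC standard errors
  of `theta` (400 reps), mean `S` within 3 SE of `theta * a1` (500
  reps);
* island-model recovery: 500 two-deme replicates at
  `2Nm in {0.25, 1, 4}` with `theta = 5`, 600 sites, n = 20 per deme.
  Per-replicate Phi_ST ratios carry a small downward Jensen bias (the
  mean of a ratio is below the ratio of means at this replication
  level), so recovery is asserted on the pooled estimator
  `mean(sigma_b)/mean(sigma_b + sigma_c)` — the standard multilocus
  form, consistent for the coalescent expectation — within 3
  bootstrap SEs of `1/(1 + 2Nm)`;
* expansion-time recovery: 100 replicates at `tau* = 4`
  (`theta0 = 0.5`, `theta1 = 10`, n = 50), bootstrap CIs at B = 200,
  requiring >= 90% coverage of the planted value;
* Tajima's D null: 2000 neutral replicates (n = 20, theta = 5), mean
  within 0.15 of zero;
* network optimality: exhaustive Steiner search on all fixtures with
  <= 6 haplotypes.

`scripts/acceptance.R` re-runs scaled versions of the same experiments
from a fresh seed and writes the resulting numbers as JSON.

## Known limitations

* The AMOVA permutation loop is plain R; designs of a few hundred
  individuals with 10,000 permutations take minutes, not seconds.
* The median-joining search is greedy; optimality is proven only at the
  scale where exhaustive search is feasible, matching how such networks
  are used in practice.
* The sudden-expansion SSD surface has a flat ridge between `tau` and
  `theta1` for single samples; point estimates of `tau` are noisy and
  should be read together with their bootstrap CI.
* The clustering surrogate treats sites as independent; haplogroup
  labels on strongly recombining or deeply linked data are heuristic.
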
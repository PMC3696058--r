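# haplostruct

Population-genetic analysis of aligned mitochondrial DNA sampled across
localities — the kind of dataset behind marine phylogeography studies,
where a few hundred individuals from dozens of sampling sites are
sequenced for one or two mtDNA fragments (e.g. COI, 16S) and the
questions are: how much variation is there, how is it structured in
space, and what demographic history produced it?

The package implements the full workflow as tested, reusable R
functions:

* **Diversity** — polymorphic sites *S*, haplotypes *H*, Nei's
  haplotype diversity *h*, nucleotide diversity *π*, mean pairwise
  differences *d*, per locality and pooled.
* **Distances** — Tamura–Nei (TN93) with optional gamma rate
  heterogeneity (term-substitution form), with explicit saturation
  flagging.
* **Structure** — pairwise Φ<sub>ST</sub> and hierarchical AMOVA. The
  total sum of squared molecular distances is partitioned into
  among-group, among-population and within-population variance
  components σ²<sub>a</sub>, σ²<sub>b</sub>, σ²<sub>c</sub>, and the
  fixation indices are
  Φ<sub>CT</sub> = σ²<sub>a</sub>/σ²<sub>T</sub>,
  Φ<sub>SC</sub> = σ²<sub>b</sub>/(σ²<sub>b</sub>+σ²<sub>c</sub>),
  Φ<sub>ST</sub> = (σ²<sub>a</sub>+σ²<sub>b</sub>)/σ²<sub>T</sub>,
  with permutation p-values ((b+1)/(B+1), 10,000 replicates by
  default) and Benjamini–Hochberg FDR correction across pairs.
* **Networks** — median-joining haplotype networks with quasi-median
  (Steiner) vectors and the inverse-origin weighting rule: a site
  mutating once keeps weight 90, a site with *r* independent origins
  gets 90/*r*; two-pass build → reweight → rebuild.
* **Demography** — observed mismatch distributions; least-squares fit
  of the sudden-expansion model (τ, θ₀, θ₁); SSD goodness-of-fit and
  95% CI of τ by parametric coalescent resampling; Tajima's *D* and
  Fu's *F*s with simulation-based significance; expansion dating by
  *t* = τ/2*u* with *u* = µ·*s*.
* **Haplogroups** — Dirichlet-multinomial clustering of haplotypes and
  per-locality haplogroup frequency tables.
* **Simulation** — a structured-coalescent generator (island-model
  migration, optional sudden expansion, finite-sites mutation) that
  writes FASTA + population map + truth JSON, so every stage can be
  validated on data with known parameters.

`run_full_analysis()` orchestrates everything from a single
configuration (R object or YAML) into a directory of CSV/JSON/GraphML
outputs plus a manifest that reproduces the run bit-for-bit. A thin
command-line wrapper lives in `exec/haplostruct`.

## Worked example

Simulate three demes (n = 12 each, θ = 5, 2Nm = 1, 600 bp) and run the
core analyses:

```r
library(haplostruct)

cfg <- sim_config(demes = 3, sample_sizes = c(12, 12, 12), theta = 5,
                  migration = 1, sequence_length = 600, seed = 7)
ds  <- simulate_coalescent(cfg)
aln <- drop_gap_sites(ds$aln)

diversity_summary(aln, ds$pm)
#>   locality  N  S  H         h          pi         d
#> 1       D1 12 17  8 0.8939394 0.010277778  6.166667
#> 2       D2 12 14  6 0.8787879 0.006186869  3.712121
#> 3       D3 12 62  7 0.9090909 0.033282828 19.969697
#> 4    total 36 81 20 0.9603175 0.042809524 25.685714

d  <- pairwise_distance_matrix(aln, subst_model_config("TN93", gamma_shape = 0.5))
pairwise_phi_st(d, ds$pm, n_perm = 1000, seed = 1)
#> Pairwise Phi_ST over 3 localities (1000 permutations)
#>        D1     D2     D3
#> D1 0.0000 0.3841 0.7228
#> D2 0.3841 0.0000 0.7556
#> D3 0.7228 0.7556 0.0000

amova(d, ds$pm,
      grouping_scheme("two_groups", c(D1 = "G1", D2 = "G1", D3 = "G2")),
      n_perm = 1000, seed = 2)
#> AMOVA (grouping: two_groups)
#>              source df     SSD variance percent
#>        among groups  1 0.54644 0.031905  73.354
#>   among populations  1 0.03595 0.002215   5.092
#>  within populations 33 0.30938 0.009375  21.554
#>               total 35 0.89177 0.043495 100.000
#> Fixation indices:
#>  phi_CT  phi_SC  phi_ST
#> 0.73354 0.19109 0.78446
#> Permutation p-values (1000 replicates):
#>   phi_CT   phi_SC   phi_ST
#> 0.320700 0.000999 0.000999
```

Reading this: deme D3 is strongly differentiated (pairwise
Φ<sub>ST</sub> ≈ 0.72–0.76, significant after FDR), and a grouping that
isolates it puts 73% of the molecular variance among groups. Note the
Φ<sub>CT</sub> p-value *cannot* be small here — permuting 3 populations
between 2 groups admits only 3 distinct arrangements, a structural
limit of the test on tiny designs, reported honestly by the (b+1)/(B+1)
convention.

Demography on the pooled (structured!) sample:

```r
obs <- mismatch_observed(aln)
fit <- fit_sudden_expansion(obs, n = nrow(aln), seed = 3)
fit$tau_ci <- tau_confidence_interval(fit, B = 200, seed = 4)
fit
#> Sudden-expansion fit: tau = 55.492, theta0 = 0.000, theta1 = 63.782, SSD = 0.03825
#> tau 95% CI: 18.964-69.852

tajimas_d(aln, n_null = 500, seed = 5)$D   #  1.163 (p = 0.922)
fus_fs(aln, n_null = 500, seed = 6)$Fs     #  2.062 (p = 0.792)
```

Both neutrality statistics are *positive* and non-significant — the
expected signature of population subdivision rather than expansion,
exactly what this simulated history should produce. On
expansion-simulated data (see `sim_config(expansion = ...)`) the same
statistics come out predominantly negative.

Dating converts a fitted τ into years given a fragment length,
generation time and divergence rate:

```r
time_since_expansion(5, s = 338, generation_time = 2, divergence_rate = 0.52)
#> Time since expansion: 711198 generations = 1.422 Myr
#> u = 3.515e-06 per fragment per generation (un-halved divergence rate)
```

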
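# gutbrain

Paired pre/post analysis of resting-state EEG biomarkers and gut-microbiome
composition for dietary-intervention studies, with a synthetic paired-cohort
generator that makes every stage testable against known ground truth.

The package is written for researchers running small within-subject
intervention cohorts — the setting where each participant contributes one
EEG recording and one stool sample before and after an intervention — who
need the full quantitative chain in one reproducible place: signal
preprocessing, connectivity and complexity biomarkers, paired
nonparametric inference with false-discovery control, microbiome
diversity and shift statistics, and a gut–brain correlation screen.

## What it computes

**Functional connectivity.** Welch cross-spectra (1-s Hanning windows, 50%
overlap) give the coherency C<sub>ij</sub>(f) = S<sub>ij</sub> /
√(S<sub>ii</sub> S<sub>jj</sub>); the band-level connectivity weight is the
mean of |Im C<sub>ij</sub>(f)| over in-band bins (imaginary coherence,
insensitive to zero-lag volume conduction). Each band's 21×21 matrix — 210
electrode pairs — is read as a weighted graph from which global efficiency
(mean inverse shortest-path length), per-node local efficiency
(neighbor-subgraph efficiency), and weighted transitivity
Σ(w<sub>ij</sub>w<sub>ih</sub>w<sub>jh</sub>)<sup>1/3</sup> / Σk<sub>i</sub>(k<sub>i</sub>−1)
are derived.

**Nonlinear complexity**, per channel on 8-s, 200-Hz epochs: Katz fractal
dimension log₁₀n / (log₁₀n + log₁₀(d/L)); quadratic sample entropy
SampEn(m=2, r=0.2·SD) + ln(2r·SD); quantile-graph mean jump length over
Q=8 amplitude quantiles; and natural-visibility-graph index complexity
GIC = 4c(1−c) from the largest adjacency eigenvalue.

**Paired inference.** Wilcoxon signed-rank per feature on d = pre − post
(so increases carry negative z), exact for n ≤ 12 and tie-corrected normal
beyond; Benjamini–Hochberg within each (metric, band) family for the four
nonlinear metrics at q < 0.10, raw p = 0.05 elsewhere.

**Microbiome.** Bias-corrected Chao1, Shannon, Gini–Simpson;
Bray–Curtis and Jaccard distances with PCoA (negative eigenvalues
reported); Kruskal–Wallis and permutation PERMANOVA between conditions;
per-rank taxon shift reports in the percent-change convention
100·(post − pre)/pre of condition-mean relative abundances.

**Correlation screen.** Kendall tau-b between per-subject EEG deltas and
taxon abundance deltas, BH over the grid, Spearman follow-up only for
pairs with uncorrected p < 0.001.

## Worked example

Simulate a 12-subject cohort whose alpha-band coupling between the first
two channels strengthens by 50% after the intervention, then test the
coupled pair:

```r
library(gutbrain)

spec <- eeg_sim_spec(
  n_subjects = 12, n_channels = 4, duration = 60,
  band_components = tibble::tibble(center = c(2, 10), amplitude = c(15, 25)),
  couplings = tibble::tibble(ch_i = 1, ch_j = 2, band = "alpha",
                             lag = pi / 2, strength = 0.5),
  effect = list(coupling = 1.5), seed = 42)
cohort <- simulate_eeg_cohort(spec)

w <- vapply(cohort$recording, function(r)
  icoh(welch_cross_spectra(rereference_car(r)), "alpha")$W[1, 2], numeric(1))
wilcoxon_signed_rank(pre = w[cohort$condition == "pre"],
                     post = w[cohort$condition == "post"])
#> # A tibble: 1 × 7
#>       n n_zero w_plus     z        p direction method
#>   <int>  <int>  <dbl> <dbl>    <dbl> <chr>     <chr>
#> 1    12      0      0 -3.06 0.000488 increase  exact
```

All twelve subjects' pair iCOH rose (w_plus = 0, the exact two-sided
p-value 2/2¹² ≈ 0.0005), and the negative z marks it as an increase — the
injected coupling effect is recovered. The microbiome side works the same
way: a 3.48-fold increase injected into a rare taxon is recovered as a
≈ +250% relative shift:

```r
tt <- simulate_taxa_tables(microbiome_sim_spec(
  n_subjects = 13, depth = 1e5,
  base_proportions = c(0.001, rep(0.999 / 9, 9)),
  fold_changes = c(3.48, rep(1, 9)),
  overdispersion = Inf, seed = 7))
taxon_shifts(tt, "species")[1, c("taxon", "mean_pre", "mean_post", "pct_change", "p")]
#> # A tibble: 1 × 5
#>   taxon    mean_pre mean_post pct_change       p
#>   <chr>       <dbl>     <dbl>      <dbl>   <dbl>
#> 1 Species1 0.000991   0.00351       254. 0.00147
```

`run_pipeline(run_config(...))` chains every stage — preprocess,
connectivity, complexity, paired stats, diversity, shifts, correlation —
and writes each stage's tibble as TSV plus a JSON run manifest; reruns
under the same seeds are byte-identical. A thin command-line wrapper with
`simulate` and `run-all` subcommands lives at `inst/cli/gutbrain.R`.

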
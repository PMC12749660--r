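---
title: "Methods: paired EEG biomarkers, microbiome shifts, and their correlation"
author: "gutbrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired EEG biomarkers, microbiome shifts, and their correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutbrain)
```

`gutbrain` analyzes paired pre/post intervention cohorts that combine
resting-state EEG with gut-microbiome count tables: it quantifies functional
connectivity and nonlinear signal complexity per subject and condition, tests
each feature with paired nonparametric statistics, summarizes microbiome
diversity and per-taxon shifts, and screens for monotone associations between
per-subject EEG changes and taxon abundance changes. This vignette records
the models, the parameter choices and their rationale, the numerical
decisions, and what the bundled synthetic cohorts do and do not establish.

## EEG preprocessing

Recordings are channels-by-samples matrices in microvolts with 10-20 labels
(21 channels expected; modern temporal names T7/T8/P7/P8 are mapped to the
legacy T3/T4/T5/T6). The processing chain is:

1. **Common average reference.** Every sample has the instantaneous
   cross-channel mean subtracted. CAR is used for *all* metrics here. More
   elaborate reference schemes (surface Laplacian, artifact subspace
   reconstruction, wavelet-ICA) are published third-party procedures and are
   deliberately out of scope; CAR keeps the package self-contained. Absolute
   connectivity levels depend on the reference, but every downstream
   contract — symmetry, bounds, paired statistics — is reference-agnostic.
2. **Zero-phase FIR band-pass.** Hamming-window FIR filters with transition
   width `max(1 Hz, 10% of the lower band edge)` and order `3.3 fs / width`.
   The filter is applied through its squared magnitude response in the
   frequency domain — the exact forward–backward equivalent at `O(n log n)`
   cost. Because the squared response halves the single-pass edge gain, the
   design edges are widened by 20% of the transition width so the two-pass
   response sits near half power at the nominal band edges; the seven
   canonical bands (delta 1–3, theta 3–7, alpha 7–12, beta1 12–18, beta2
   18–24, beta3 24–30, gamma 30–45 Hz) then tile broadband energy to within
   a few percent. Edge wraparound contaminates roughly one filter length at
   each end of the recording, as with any forward–backward scheme.
3. **Epoching for complexity metrics.** Signals are low-passed at 80 Hz
   (80% of the target Nyquist), resampled 500 → 200 Hz by exact Fourier
   interpolation (the ratio is a non-integer 2/5, so classical decimation
   does not apply), and cut into non-overlapping 8-s epochs of exactly 1600
   samples; trailing remainders are dropped. An optional amplitude screen
   removes epochs whose peak absolute amplitude exceeds a threshold, a
   simple stand-in for artifact-correction pipelines.

Connectivity is computed on the continuous CAR signal at the native rate;
only the four complexity metrics use the 200-Hz epochs.

## Connectivity: imaginary coherence and weighted network metrics

Cross-spectral densities come from Welch's method: 1-s Hanning-tapered
segments with 50% overlap, each linearly detrended. Coherency is the
normalized cross-spectrum $C_{ij}(f) = S_{ij}(f) / \sqrt{S_{ii} S_{jj}}$,
and the connectivity weight for a band is the arithmetic mean of
$|\mathrm{Im}\,C_{ij}(f)|$ over the in-band frequency bins. The imaginary
part vanishes for zero-lag mixing, which is what makes it robust to volume
conduction on scalp EEG; the package's tests exercise exactly this property
(a zero-lag mixture has high coherence but near-zero imaginary coherence,
while a quadrature pair drives it to 1). Band summarization by the
arithmetic mean of bins is a package choice; nothing downstream depends on
the particular reduction.

A finite-sample caveat documented by the tests: with $K$ averaged segments
the imaginary-coherence estimate of *independent* signals concentrates
around $\sqrt{1/(\pi K)}$, about 0.05 for 60 s of data at these Welch
settings. Uncoupled simulations therefore sit at this bias floor rather
than at zero; the floor halves when the recording is four times longer.

The 21-channel montage yields $21 \cdot 20 / 2 = 210$ electrode pairs. The
band matrix `W` is read as a weighted undirected graph with no thresholding
(edge length `1/w`), and three Rubinov–Sporns-style metrics are derived:

* **Global efficiency** — mean inverse shortest-path length over ordered
  pairs; unreachable pairs contribute zero.
* **Local efficiency** — per node, the global efficiency of the subgraph
  induced by its positive-weight neighbors; nodes with fewer than two
  neighbors score zero.
* **Transitivity** — $\sum_{i,j,h}(w_{ij} w_{ih} w_{jh})^{1/3} /
  \sum_i k_i (k_i - 1)$ with $k_i$ the positive-weight degree.

Shortest paths go through `igraph`; the metric formulas themselves are
implemented here and verified against exhaustive Floyd–Warshall and
triple-enumeration oracles on random graphs. Note that only global
efficiency is monotone under edge additions; local efficiency and
transitivity can legitimately *decrease* when a pendant edge enlarges
neighbor subgraphs or the connected-triple count, and the tests pin down a
counterexample.

## Nonlinear complexity metrics

All four are computed per 8-s, 200-Hz epoch per channel and band, then
averaged over epochs (excluding epochs a metric flags).

**Katz fractal dimension.** With curve length $L = \sum_k |x_{k+1} - x_k|$,
extent $d = \max_k |x_k - x_1|$ and $n$ = number of steps,
$FD = \log_{10} n / (\log_{10} n + \log_{10}(d/L))$. The ordinate-only
reading is used for both $L$ and $d$: it makes the metric invariant under
positive affine rescaling (so microvolt units and per-subject gain drop
out of pre/post contrasts) and gives a straight line $d = L$, hence FD
exactly 1, with constant signals defined as 1. Abscissa-inclusive variants
change absolute values but not contrasts.

**Quadratic sample entropy.** SampEn$(m, r_{abs})$ by Chebyshev template
matching with self-matches excluded, at $m = 2$ and
$r_{abs} = 0.2 \times \mathrm{SD}$ of the epoch — standard sample-entropy
practice when the source does not state the parameters. QSE adds
$\ln(2 r_{abs})$, which removes the tolerance dependence; the result is in
nats of the signal's amplitude units. Zero-variance epochs and epochs with
no template matches return `NA` and are excluded from the epoch average
rather than polluting it.

**Quantile-graph mean jump.** Samples are assigned to $Q = 8$ empirical
quantiles (type-7 boundaries; boundary ties go to the lower quantile;
heavily tied data may leave a quantile empty), consecutive samples define a
directed transition graph, and the summary is the mean of $|a - b|$ over
all observed transitions — equivalently the occupancy-weighted
row-normalized formulation when occupancy is taken over transition
origins. $Q$ is configurable; the default 8 balances resolution against
occupancy at 1600 samples per epoch.

**Visibility-graph index complexity.** The *natural* visibility criterion
links samples that see each other over all intermediate samples (strict
inequality, so collinear runs contribute only the path edges); this matches
the line-of-sight description rather than the horizontal variant. The
summary maps the largest adjacency eigenvalue onto $[0,1]$ via
$c = (\lambda_{max} - 2\cos(\pi/(n+1))) / (n - 1 - 2\cos(\pi/(n+1)))$ and
$GIC = 4c(1-c)$; a monotone ramp gives the bare path graph whose
$\lambda_{max}$ is the lower anchor, hence GIC 0. Adjacency construction
and entropy counting are compiled (Rcpp) because the $O(n^2)$ loops over
1600-sample epochs are the hot path. $\lambda_{max}$ uses a dense
symmetric eigensolver up to 400 nodes (exact even for the nearly
degenerate path-graph spectrum) and ARPACK above that, with the start
vector pinned so repeated runs are byte-identical.

## Paired statistics

Every feature — 21 electrodes per complexity metric and for local
efficiency, 210 pairs for iCOH, one global value for GE and transitivity —
is tested with the Wilcoxon signed-rank test on per-subject pre/post
values. Differences are taken as `pre - post`, so an increase after the
intervention carries a **negative z**, matching the reporting convention
the package mirrors. Zero differences are dropped, midranks handle ties,
and the variance is tie-corrected. For 12 or fewer retained pairs the
two-sided p-value is exact (full enumeration of the $2^n$ sign
assignments); beyond that the normal approximation without continuity
correction is used — the regime of a 50-subject cohort. The tests verify
that exact and approximate p-values agree on significance calls in over
95% of random instances at the crossover sizes.

Benjamini–Hochberg correction is applied within each (metric, band) family,
and only for the four nonlinear complexity metrics — each nonlinear metric
is corrected separately, while iCOH pair counts and the network metrics are
reported with raw p-values only. Thresholds default to raw `alpha = 0.05`
and `q < 0.10`. A calibration fact worth knowing: under a global null, BH
at level `q` makes at least one false discovery with probability exactly
`q` (Simes), so about one null cohort in ten shows a spurious
FDR-significant feature; the test suite measures this.

## Microbiome analysis

Count tables carry six-rank lineage strings and a paired manifest. Raw
counts are never rarefied; relative abundances are used throughout.

* **Alpha diversity**: bias-corrected Chao1
  $S_{obs} + F_1(F_1 - 1)/(2(F_2 + 1))$ (robust when doubletons are
  absent), Shannon entropy in nats (configurable reading documented here:
  natural log), and Gini–Simpson $1 - \sum p_i^2$. Pre vs post comparisons
  use Kruskal–Wallis with conditions as independent groups, as the named
  procedure specifies; each index is its own correction family, so q equals
  p. When every sample has identical index values the statistic is defined
  as H = 0, p = 1 (the reference implementation returns 0/0 there).
* **Beta diversity**: Bray–Curtis on relative abundances and classic
  presence/absence Jaccard, via `vegan`. PERMANOVA partitions squared
  distances into between/within-condition components; the p-value counts
  permuted pseudo-F values at least as large as the observed one, with a
  fixed seed. PCoA reports negative eigenvalues rather than dropping them.
* **Taxon shifts**: counts are collapsed at each requested rank, and each
  taxon gets the mean relative abundance per condition and the percent
  change `100 (post - pre) / pre` of those condition means — the
  condition-level convention used by hierarchical percent charts. Taxa
  absent before and present after are flagged *emergent* instead of
  dividing by zero. A per-taxon paired Wilcoxon p accompanies the shift
  where defined.

## EEG–microbiome correlation screen

Per-subject deltas (post − pre) of the nonlinear EEG features are
correlated against per-taxon relative-abundance deltas with Kendall's
tau-b — the tie-corrected variant, chosen because taxa deltas contain ties
at zero. For nine or fewer subjects the p-value is exact by enumeration of
all orderings; beyond that the tie-corrected normal approximation is used,
which keeps reported p-values at attainable floors rather than spurious
zeros. BH correction runs over the full grid of tested pairs (pairs with
fewer than five complete subjects stay in the grid as `NA` and are excluded
from the family, whose size is reported for audit). Pairs with uncorrected
Kendall `p < 0.001` — and only those — are re-evaluated with Spearman's
rank correlation as an exploratory follow-up.

## Synthetic cohorts: what they emulate and what they do not

The EEG generator synthesizes each channel as a sum of narrowband
Gaussian processes (Gaussian spectral bumps, standard deviation
`max(1, 0.1 x center)` Hz — roughly the width of a resting alpha peak)
plus `1/f` background noise shaped in the spectral domain, all determined
by one seed. Cross-channel coupling replaces a fraction of the target's
in-band component with a phase-shifted copy of the source component:
`sqrt(1 - s^2) own + s shifted`. This variance-preserving mix was chosen
over a purely additive copy because it gives the analytically predictable
band iCOH of `s sin(lag)` — strength 0 leaves channels independent,
strength 1 with a quadrature lag drives iCOH to 1 — which is what makes
injected effects recoverable with known ground truth. Subject-level
realism comes from log-normal amplitude jitter (sigma 0.1) and coupling
jitter (sigma 0.15) shared between a subject's two recordings, so paired
contrasts see genuine between-subject variance; the post condition applies
multiplicative effect factors to coupling strength, amplitudes, or noise.
Defaults follow the acquisition they emulate: 21 channels, 500 Hz, 60-s
recordings, a resting-like component mix with dominant alpha.

The taxa generator draws each subject's pre-condition composition from a
Dirichlet centered on the base proportions (concentration =
overdispersion; infinity pins every subject to the base), multiplies by
per-taxon fold changes and renormalizes for the post condition, and
samples multinomial reads at fixed depth. A 3.48-fold increase of a rare
taxon therefore shows up as roughly a +248% relative shift after
renormalization, within multinomial sampling error.

Neither generator models volume conduction, blink/EMG artifacts,
nonstationarity, compositional interactions between taxa, or sequencing
bias. Passing tests on these cohorts demonstrate that the estimators
recover known effects under the stated noise model — not that real EEG or
16S data satisfy that model.

## Problem sizes and numerical notes

The test suite runs the statistical calibrations at 1000 null feature
cohorts (21 features, 50 subjects), 200 null PERMANOVA draws (199
permutations each), and 10 replicate EEG cohorts of 50 subjects at 60 s
and 4 channels for the effect-recovery check; these sizes give stable
rates while keeping the suite comfortably fast on one CPU. Exhaustive
oracles cap at 8 nodes (graphs), 12 subjects (signed-rank enumeration), 9
subjects (Kendall enumeration), and 64 samples (cubic visibility scans).
Visibility comparisons are floating-point strict, so ramp fixtures use
exactly representable increments. Fourier resampling assumes the signal
is already band-limited below the target Nyquist, which the 80-Hz
anti-alias filter guarantees.

## Known limitations

* Absolute connectivity and complexity levels depend on referencing and
  filtering choices; only paired contrasts are designed to be comparable
  across pipelines.
* The Kruskal–Wallis and PERMANOVA stages treat conditions as independent
  groups (the named procedures); subject pairing informs only the Wilcoxon
  and correlation stages.
* The imaginary-coherence bias floor (~0.05 at 60 s) means weak couplings
  below the floor are not detectable at short recording lengths.
* EDF ingest is not provided; recordings enter as numeric-matrix TSV plus a
  JSON sidecar, or via the simulator.
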
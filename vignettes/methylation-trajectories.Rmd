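---
title: "Methylation trajectories of in-vitro neuronal differentiation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methyltraj)
```

# The analysis problem

Differentiating induced pluripotent stem cells (iPSCs) into neurons
reorganizes the DNA methylome. Profiling the same line at a handful of
stages (iPSC, neural precursor, maturing neurons) on an EPIC-style array
yields a small-sample time course — here 4 stages x 4 technical
replicates, with some samples lost to quality control — over hundreds of
thousands of CpG probes. `methyltraj` implements the full path from raw
methylated/unmethylated intensities to an *epigenetic trajectory
signature*: the set of loci whose methylation changes progressively along
an inferred differentiation pseudotime, together with epigenetic-age
predictions, enrichment analyses, and the topology of the regulatory
network connecting the signature genes.

Every stage is driven by a synthetic-data generator that emulates the
assumed experimental design, so the package's claims are tested end to end
without any external download.

# Preprocessing model

**Beta values.** Methylation at a probe is summarized as
$\beta = M/(M + U + 100)$, with $M$ and $U$ the methylated and
unmethylated channel intensities; the offset 100 is the array ecosystem's
convention and regularizes low-intensity probes toward 0.

**Quality control.** Two sample-level checks run before anything else: a
median-intensity check (a sample fails when the median of either channel
falls below `min_median`; scanners and chemistries vary, so this threshold
is a required argument with no pretended universal default) and the
p-filter (a sample fails when more than `sample_frac` = 1% of its probes
have detection p above 0.05). Probes are assessed only afterwards, among
surviving samples: detection p failing in more than 1% of samples, or bead
counts below 3 in more than 5% of samples. Order matters — a probe should
not be discarded because of a sample that is itself being discarded.

**Normalization.** The dasen scheme normalizes the two Infinium probe
chemistries separately: per sample, the type-I background is shifted onto
the type-II background, the shift being the difference of the 5th
percentiles of the two chemistries' intensities; then methylated and
unmethylated intensities are quantile-normalized across samples within
each probe type (via `limma::normalizeQuantiles`), and beta values are
recomputed. The original implementation's smoothed position-dependent
background fit is deliberately simplified to a single per-sample quantile
shift — replicating another package's internals bit for bit is a non-goal,
and the quantile-normalization step, which dominates the result, is exact.

**Probe exclusion.** Probes with common (>5% minor-allele-frequency) SNPs
within 10 bp of the single-base extension and probes known to
cross-hybridize are dropped before analysis, as is standard for this
array.

# Epigenetic clocks

A clock is a sparse linear predictor over CpGs,
$m = c_0 + \sum_i c_i \beta_i$, with optional output transform. The
pan-tissue transform is the piecewise inverse
$(1 + a)\,e^{m} - 1$ for $m < 0$ and $(1 + a)\,m + a$ otherwise
(maturity parameter $a = 20$ years), continuous and strictly increasing
with lower limit $-1$ year. Ages in years are converted to the fetal
scale as $\mathrm{days} = 365.25 \cdot \mathrm{years} + 280$; no single
convention for these constants exists in the field, so a Julian year and
a 280-day full-term gestation are the package's documented choice (they
matter only at day-level resolution). Clock CpGs missing
from a matrix are skipped and counted rather than imputed — the tolerant
behavior users of `agep`-style predictors expect — with a `strict` switch
to error instead. Stage differences in predicted age are tested by
one-way ANOVA followed by Tukey's HSD (Tukey–Kramer standard errors under
unbalanced groups), which for two groups reduces exactly to the
pooled-variance t-test.

# Pseudotime inference

The most variable loci are selected by median absolute deviation: the top
`ceiling(fraction * n)` probes at `fraction = 0.05`. The MAD includes the
1.4826 normal-consistency constant; any positive constant gives the same
ranking, so the selection is insensitive to this choice. The ceiling rule
is what uniquely maps a top-5% cut of 837,018 probes to 41,851 selected
loci. Ties at the cutoff are broken lexicographically by probe id so the
selection is deterministic.

Samples are embedded by PCA on mean-centered but *unscaled* probes
(scaling would equalize exactly the variance differences that carry the
signal), and the trajectory is fitted in the first two components:

1. k-means with `k = 4` clusters (matching the number of stages; exposed
   as a parameter) and 10 restarts under a fixed seed;
2. the exact shortest open Hamiltonian path through the k cluster
   centers, found by exhaustive enumeration (k is capped at 8, where
   enumeration is trivial);
3. a principal curve in the Hastie–Stuetzle sense, initialized at the
   ordered-center polyline: alternate projecting samples onto the current
   curve and refitting each coordinate by a cubic smoothing spline
   (df <= 4 — with only ~14 samples a light smoother is forced) against
   arc-length, until the relative improvement in total squared projection
   distance falls below 1e-4 or 50 iterations;
4. pseudotime = projected arc-length, min-max scaled to [0, 1].

The alternating iteration is not guaranteed monotone, so the
implementation keeps the best iterate seen and stops as soon as an
iteration fails to improve; the recorded distance path is therefore
non-increasing by construction. A principal curve has no preferred
direction; `orient_pseudotime()` flips it when the anchor stage (the
pluripotent one) averages above 0.5, an idempotent convention.

# The trajectory scan

Pseudotime is rounded to two decimals (half-up, so the discretized grid
is unambiguous) and each locus's beta values are regressed
on it with a penalized cubic regression spline, basis dimension 4
including the intercept — with 14 samples a small basis is forced — and
the smoothing parameter chosen per locus by GCV on a shared lambda grid.
Because the design matrix is identical across loci, hat matrices are
computed once per lambda and applied to all loci at once; a genome-scale
scan is a handful of matrix products rather than 10^5 model fits, and the
vectorized fits are verified in the tests against `mgcv::gam` and a
scalar reference implementation.

**Inference.** The penalized fit supplies the fitted curve, its effective
degrees of freedom, and the end-to-end change
$\Delta = \hat f(1) - \hat f(0)$ used to call each significant locus
hypo- or hypermethylated. The p-value, however, comes from the exact
F-test of the *full unpenalized* basis against the intercept-only model
(df 3 and n-4). Referencing the F statistic to GCV-selected effective
degrees of freedom is seriously anticonservative at this sample size
(null Kolmogorov–Smirnov distance from uniform ~0.18 in our calibration
runs, and ~0.09 even for mgcv's specialized approximation), which would
destroy family-wise error control; the fixed-basis test is exactly
calibrated under Gaussian noise (observed KS ~0.007) and costs little
power at the effect sizes of interest. Selection is Bonferroni at
`alpha / n_tests` with `<=` at the threshold. By construction
`n_hypo + n_hyper` always equals the signature size (an exact zero
$\Delta$ is called hyper, with a warning; it is a measure-zero event).

Significant loci are grouped into 9 shape modules by Ward-linkage
hierarchical clustering of the z-scored fitted curves, with module labels
ordered by the mean pseudotime of fastest change so labels are
reproducible across runs. Ward clustering is the package's documented
choice of module-discovery method, and the module count is exposed.

# Enrichment

Genomic-feature enrichment (gene-region groups; CpG-island relations)
uses the 2x2 table of signature membership against the *tested* loci (the
MAD-selected universe) — enrichment should be conditional on what was
eligible for testing; the whole-array universe is also supported, since
practice varies on this point. The odds ratio is the sample
cross-product and the p-value the two-sided Fisher exact test (sum of
hypergeometric probabilities no larger than the observed table's, with
the conventional 1e-7 tie tolerance). Multi-valued region annotations are
collapsed to one group per probe by the promoter-favoring precedence
TSS200 > TSS1500 > 5'UTR > 1stExon > Body > 3'UTR > intergenic.

Gene-set enrichment corrects for the uneven number of probes per gene:
genes with more probes have more chances to carry a significant probe.
Each gene's selection probability is estimated by a moving average of the
significance indicator over genes ordered by probe count, then averaged
within tied counts so the estimate is a genuine function of the count
(without this, ties leak significance ordering and the no-bias case fails
to reduce to the central hypergeometric). Per set, the in-set/out-of-set
mean selection probabilities give an odds parameter for the Wallenius
noncentral hypergeometric, whose upper tail is the p-value; q-values are
Benjamini–Hochberg. The Wallenius integral is evaluated after a
substitution that turns it into a Beta-kernel expectation via the
quantile transform, which stays stable even for universes of thousands of
genes where the naive integrand concentrates on a vanishing interval.
With all odds equal it agrees with the central hypergeometric to 1e-8.

# Network topology

The directed regulatory network is consumed as an edge list (self-loops
dropped, duplicate directed pairs collapsed before anything is counted).
Strongly connected components come from igraph; the analysis focuses on
the unique nontrivial SCC, the sub-network in which every gene is
reachable from every other. Metrics follow the Cytoscape NetworkAnalyzer
conventions the field reports: in/out-degree by directed edge counting;
betweenness on the directed graph normalized by $(N-1)(N-2)$; clustering
coefficient $2e_v/(k_v(k_v-1))$ and neighborhood connectivity (mean
neighbor degree) on the undirected projection. "Hub" ranking is by total
degree with betweenness and then lexicographic tie-breaks. Since the
curated network behind the published 60-gene SCC is proprietary, the
package ships a deterministic *synthetic* stand-in
(`synthetic_regulatory_network()`, also under `inst/extdata/`) with the
same scale — 398 genes, 622 interactions, a unique 60-gene/158-interaction
SCC whose hub has in-degree 7 and out-degree 20 — for worked examples and
tests; its wiring is a construction, not curated biology, so
wiring-dependent metrics (clustering coefficient, neighborhood
connectivity) are reported but carry no claim of matching any real
network.

# The synthetic-data generator

`simulate_beta_dataset()` emulates the study conditions: 4 stages x 4
technical replicates; a latent time per sample, equal within stage up to
Gaussian jitter (SD 0.01 — within-stage variability of technical
replicates is poorly characterized, so this is a free parameter chosen
to keep samples distinguishable; jitter is reflected at the boundaries
rather than clamped so no two samples tie exactly); 5% of probes planted
on one of 9 trajectory templates (monotone ramps, early drop, late rise,
sigmoids, transients, rise-to-plateau) with beta-scale amplitude 0.4 over
a random baseline; the rest flat. Noise is Gaussian on the logit scale
(SD `noise_sd`, default 0.03) and transformed back, keeping beta values
strictly inside (0, 1) without clipping artifacts — array noise is
heteroscedastic in exactly this bounded way, and it is what makes the
zero-noise limit well defined.

`simulate_intensities()` inverts the beta definition around a lognormal
total intensity (mean 5000), adds chemistry-specific backgrounds, and
plants `n_failing_samples = 2` earliest-stage samples with 3% of normal
intensity and inflated detection p-values, so the QC defaults flag
exactly those samples (the tests assert set equality across seeds).
`simulate_annotation()` draws region/CGI categories with EPIC-like
frequencies and lets associated loci be tilted by per-category odds, so
enrichment odds ratios have known targets. `simulate_network()` plants a
single SCC (cycle plus chords) inside an acyclic periphery;
`simulate_clock()` places coefficients on linearly increasing loci so the
noiseless prediction equals a chosen linear function of latent time. One
global seed derives independent child seeds per generator, so components
are reproducible both jointly and separately.

**What the generator does not emulate:** chip/batch spatial effects, probe
cross-hybridization structure, correlated neighborhoods of CpGs,
biological replicate variability (the study itself used technical
replicates), and realistic gene-set structure. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
model, not robustness to every artifact of real array data.

# Numerical choices and scales

* Problem sizes in the routine tests are scaled to what the statistics
  require, not the array's full size: 10^4 probes for calibration runs
  (family-wise error over 200 replicate null datasets, KS uniformity at
  10^4 null loci), 20 seeds for pseudotime recovery, and a single
  837,018-probe matrix only where the selection arithmetic itself is the
  point. The vectorized scan makes each 10^4-locus replicate a
  sub-second operation.
* k-means degeneracy (an empty cluster) triggers a restart with a new
  child seed, up to 10 times, then errors — determinism under a fixed
  seed is preserved.
* Quantile normalization is skipped, with a warning, for a probe type
  with fewer than 2 probes; shifted intensities are floored just above
  zero.
* Fisher's test uses the relative tie tolerance 1e-7, matching
  `stats::fisher.test`; the implementation is a direct `dhyper` sum and
  is checked against both full enumeration and `fisher.test`.
* Loci with (near-)constant methylation get p-value 1 with a warning
  rather than a failed fit.

# Known limitations

* The principal curve is non-branching by design; bifurcating
  differentiation would need a different method.
* With 14 samples the spline basis is necessarily small; sharp features
  narrower than roughly a quarter of the pseudotime axis blur into the
  nearest representable shape, and module assignment degrades gracefully
  (but measurably) as noise grows.
* The Bonferroni criterion is deliberately conservative; no FDR
  alternative is offered for locus selection.
* Epigenetic-age prediction assumes the supplied clock's CpGs behave in
  the new data as in its training data; the package only ships synthetic
  clocks, with real coefficient files consumed in the same CSV schema.
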
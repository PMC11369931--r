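---
title: "Tree topology of leakage-corrected envelope networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree topology of leakage-corrected envelope networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megtree)
```

## The analysis in one paragraph

Resting-state MEG/EEG functional networks are often summarized by the
minimum spanning tree (MST) of a connectivity matrix: with unique weights
the MST is a unique, loopless backbone with exactly `N - 1` links, so tree
metrics can be compared across subjects without the density-matching
confounds of thresholded graphs. `megtree` implements this pipeline for
epoched, band-limited recordings: per-epoch connectivity by amplitude
envelope correlation with pairwise leakage correction (AEC-c), per-epoch
maximum-connectivity spanning trees, global tree metrics averaged across
epochs, and a statistical battery relating those metrics to a continuous
plasma biomarker (p-tau231, pg/ml) in a cohort with and without a family
history of Alzheimer's disease (FH+/FH-). A seeded synthetic-cohort
generator with planted envelope coupling makes every stage testable
without access to recordings.

## Connectivity: AEC-c

For two band-limited signals $x, y$ within one epoch, plain amplitude
envelope correlation (AEC) is the Pearson correlation of their Hilbert
envelopes. Source-reconstructed signals share instantaneous (zero-lag)
components through volume conduction and beamformer leakage, which inflates
AEC spuriously. The leakage-corrected variant orthogonalizes the pair at
zero lag before enveloping: with $\epsilon_{y|x}$ the residual of the
least-squares projection of $y$ on $x$,

$$\mathrm{AEC\text{-}c}(x,y) = \tfrac12\left[
  \mathrm{corr}\big(\mathrm{env}(\epsilon_{y|x}), \mathrm{env}(x)\big) +
  \mathrm{corr}\big(\mathrm{env}(\epsilon_{x|y}), \mathrm{env}(y)\big)
\right].$$

Design choices the literature leaves open, fixed here:

* **Signed averaging.** The two directed correlations are averaged
  arithmetically and no absolute value is taken; the MST stage consumes
  ranks, and negatives rank naturally below positives.
* **Collinearity convention.** If a residual is (numerically) zero —
  duplicated channels, constant signals — the pair's AEC-c is defined as 0
  with a warning, so one degenerate pair cannot abort a cohort run.
* **No envelope post-processing.** Envelopes are neither log-transformed
  nor downsampled nor low-passed before correlation, and epochs are used
  in full (no edge trimming).

Orthogonalization at short epoch lengths removes a *randomly estimated*
projection (the sample zero-lag correlation of independent band-limited
signals over 4 s has an sd around 0.2), which attenuates per-epoch AEC-c
relative to the true envelope correlation. This is a property of the
estimator, not a bug; quantitative recovery checks in the tests therefore
use long (120 s) single epochs, where the planted envelope correlation is
recovered within a few hundredths.

## Filtering and envelopes

Band-pass filtering uses a linear-phase FIR (order 450, Hann window,
`signal::fir1`) applied twice, forward and backward, so the effective
response is the squared magnitude with exactly zero phase. Epochs are
mirror-padded with up to 2000 samples per side; shorter epochs truncate the
padding (logged). The default implementation multiplies the padded
spectrum by $|H(\omega)|^2$ — the exact frequency-domain form of the
two-pass — because the simulation studies filter hundreds of thousands of
epochs; a literal time-domain path (`method = "conv"`) is retained and the
two agree to machine precision in the tests.

One caveat worth knowing: a 450th-order FIR resolves a band only when the
transition width ($\approx 3 f_s / \mathrm{order}$) is small relative to
the bandwidth. At 1000 Hz the alpha band (8–13 Hz) is narrower than the
transition width, so the response is dome-shaped with unity gain anchored
at the band center; at the 250 Hz test scale all three canonical bands are
resolved essentially flat. Pass-band identity checks therefore run at
250 Hz.

Envelopes are the magnitude of the FFT-based analytic signal, per region
and epoch.

## Trees and their metrics

Each epoch's AEC-c matrix yields one spanning tree via Kruskal's algorithm
on *descending* connectivity (equivalently, ascending reciprocal weight for
positive entries): the tree keeps the strongest backbone. Verbal
descriptions of this construction in the applied literature sometimes mix
"ascending order" with "strongest link first"; the maximize-connectivity
convention is the one under which the published anchor values (79 links on
80 nodes, star/path limits) hold, and is adopted here. Zero and negative
entries rank strictly below all positive entries, which avoids the
undefined reciprocal of non-positive weights; ties break deterministically
by lexicographic edge index, so results are reproducible even without the
unique-weight assumption.

For a tree with $N$ nodes, $m = N - 1$ links, $L$ leaves (degree-1 nodes),
hop diameter $d$ and maximum betweenness $BC_{\max}$:

$$LF = L/m, \qquad D = d/m, \qquad TH = \frac{L}{2\,m\,BC_{\max}}.$$

Betweenness of node $v$ is the fraction of unordered node pairs (excluding
$v$) whose unique tree path crosses $v$, normalized by
$(N-1)(N-2)/2$ — this normalization is what makes $TH = 0.5$ exact for a
star. Anchors: a star has $LF = 1$, $d = 2$, $TH = 0.5$; a path has
$L = 2$, $D = 1$, $TH \to 0$. The diameter is hop-based (link counts), not
weighted. Per-epoch metrics are averaged arithmetically into one value per
subject, band and metric.

## The statistical battery

Given a cohort table (one row per subject: group label, biomarker, and the
epoch-averaged $LF$, $D$, $TH$ per band), `runAssociationBattery()` runs:

1. whole-sample Pearson correlations of each band × metric against the
   biomarker — one Benjamini–Hochberg family of 9 tests at $q = 0.1$;
2. the same correlations within each group — a single pooled family of 18;
3. per band × metric, a comparison of the two group correlations by
   Fisher's r-to-z with $p = 1 - \Phi(|z|)$;
4. a TH–LF correlation within groups, only where a within-group TH result
   is significant (TH is non-monotone in topology, so its sign is
   interpreted through its co-movement with LF);
5. demographic screens when covariates exist (biomarker vs age/education,
   biomarker by sex, sex by group).

Conventions fixed by recomputation against published summary tables:
the two-sample t is pooled-variance Student (a pooled recomputation from
the printed group summaries reproduces the printed statistic exactly,
t = 0.792); the chi-square drops the continuity correction; the Fisher
comparison is *one-tailed* — the one-tailed form reproduces the printed
comparison column (0.269, 0.007, 0.471, 0.073) at group sizes 54/22 where
the two-tailed form does not; and the "significance threshold" reported
alongside an FDR family is the largest raw p in the rejection set. BH
adjusted values come from `stats::p.adjust(method = "BH")`; a brute-force
step-up implementation serves as the oracle in the tests, not as the
implementation.

## The synthetic cohort generator

No public recordings accompany the analysis this package implements, so the
generator plants known structure:

* **Envelopes.** Each region's amplitude envelope in a band is
  $\sqrt{c}\,E_{\mathrm{shared}} + \sqrt{1-c}\,E_i$ with i.i.d. smooth
  positive processes $E$ (low-passed rectified Gaussian noise, mean 1,
  sd 0.35, floored at 0.05). The pairwise envelope correlation between any
  two regions is then the planted coupling $c$ exactly, in expectation.
  The modulation cutoff defaults to a quarter of the bandwidth (1 Hz for
  theta, 1.25 Hz for alpha, 4.25 Hz for beta) — slow, MEG-like amplitude
  dynamics.
* **Carriers.** Constant-modulus frequency-modulated oscillations whose
  instantaneous frequency wanders slowly inside the band, with independent
  random phase trajectories per region. Because $|$analytic signal$| = 1$
  for such carriers, the measured Hilbert envelope equals the planted
  envelope; with noise carriers the carrier's own Rayleigh envelope
  fluctuations would attenuate the planted correlation several-fold.
  Independent phases keep zero-lag signal correlations negligible, so the
  leakage-correction step is exercised but not dominant.
* **Biomarker.** Subject couplings are
  $\mathcal N(c_0, \sigma_c)$ truncated to $[0.01, 0.95]$, and the
  biomarker is linear-plus-Gaussian in the coupling deviation, floored at
  1 pg/ml. Defaults ($c_0 = 0.35$, $\sigma_c = 0.12$, slope 500 pg/ml,
  noise sd 104 pg/ml, intercept 381.696 pg/ml) put the planted
  biomarker–coupling correlation at 0.50 (`plantedCorrelation()`), on the
  biomarker scale of the study cohort.

With *uniform* coupling the expected connectivity matrix is flat, yet
higher coupling still produces more star-like trees: the sampled
correlation matrix contains a rank-one perturbation
$\sqrt{c(1-c)}(a_i + a_j)$ from the finite-sample covariances $a_i$
between each region's private envelope and the shared envelope, and its
magnitude relative to pairwise noise grows as $\sqrt{c/(1-c)}$. Regions
with large $a_i$ become hubs, so leaf fraction rises with coupling — the
mechanism the end-to-end recovery test detects.

What the generator does **not** emulate: 1/f spectra, forward/inverse
modelling, sensor noise, head movement, regionally heterogeneous coupling.
Passing tests demonstrate correctness of the estimators and the planted
monotone link, not realism of MEG microstructure.

## Problem sizes and numerical choices

Full-scale geometry (80 regions, 30 epochs × 4096 samples at 1000 Hz,
76 subjects, 54 FH+) is the default `cohortSpec()`; the package's own
simulation studies run the scaled-down profile (`scaledCohortSpec()`:
20 subjects, 10 regions, 10 epochs × 512 samples at 250 Hz) and, for the
end-to-end recovery study, 76 subjects × 8 regions × 10 epochs × 512
samples at 250 Hz in the alpha band with 100 replicate cohorts — chosen as
the smallest geometry at which the planted-sign recovery rate clears its
margin comfortably. The null calibration uses 100 replicate cohorts of 20
subjects with `effectSize = 0` across all three bands.

Other numerical conventions: epochs of 4096 samples at 1000 Hz are taken
literally (4.096 s); MST ties break lexicographically; `TH` requires
$N \ge 3$ (guaranteeing $BC_{\max} > 0$); quantitative null bounds on
AEC-c are evaluated in the beta band because the sampling sd of an
envelope correlation scales with the square root of the envelope
decorrelation time ($\sim 1/$bandwidth), making the widest band the one
where a 0.05 bound at 120 s is attainable at all.

## Limitations

* AEC-c at 4-s epochs is noticeably attenuated relative to the planted
  envelope correlation (random orthogonalization at short windows); rank
  structure, which the MST uses, is preserved.
* The battery implements unadjusted Pearson correlations; covariate
  adjustment (age, sex, education) is out of scope.
* Node-level (regional) hub statistics are not reported — only global tree
  metrics.
* The one-tailed Fisher comparison convention is inferred from printed
  values, not from a stated formula.
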
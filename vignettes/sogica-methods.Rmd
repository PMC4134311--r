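---
title: "Group spatial ICA network comparison: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group spatial ICA network comparison: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sogica` compares intrinsic connectivity networks (ICNs) between two
groups of subjects scanned during naturalistic stimulation. This
vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the
synthetic cohort does and does not emulate, and the design choices made
where the method description left the design open.

## The analysis model

Each subject contributes a 4-D BOLD series $X \in \mathbb{R}^{T \times V}$
(time by voxel). After preprocessing, spatial ICA models the data as
$X \approx A S$, where the rows of $S$ are statistically independent
*spatial maps* and the columns of $A$ their time courses. In the spatial
orientation the voxels are the samples: ICNs are sparse, spatially
reproducible patterns, so their maps are strongly non-Gaussian, which is
the contrast ICA exploits.

The per-subject pipeline is:

1. **Scan trimming** — the first 2 volumes are dropped (T1 saturation).
2. **Motion QC** — translations and rotations (converted to worst-case
   surface displacement at a 65-mm lever arm) must stay below half a
   voxel. Motion *correction* is deliberately not re-estimated: the
   synthetic data carry none, and the rule, not the estimator, is what
   the analysis depends on.
3. **Voxel-wise linear detrending** — the least-squares line is removed
   per voxel; temporal means are retained.
4. **Spatial smoothing** — isotropic Gaussian, FWHM 6 mm
   ($\sigma = \mathrm{FWHM} / 2\sqrt{2\ln 2}$ per axis), reflective
   borders (the description is silent on border handling; reflection
   avoids edge attenuation).
5. **Nuisance regression** — white-matter and CSF covariates are the
   mean series inside the supplied masks; every voxel is replaced by the
   residual of its regression on `[intercept, WM, CSF]`. Residuals are
   orthogonal to the covariates at machine precision. Whether this
   regression belongs before or inside the ICA step was left open; it is
   implemented as a pre-ICA regression and can be switched off
   (`regress_nuisance = FALSE`) to defer it.
6. **Whitening and FastICA** — PCA retains 30 dimensions (the model
   order; the retained PCA dimension was unstated and is taken equal to
   the IC count), scaled to identity covariance over voxels. Components
   are extracted by deflation with the tanh fixed point
   $w \leftarrow E[z\,g(w^\top z)] - E[g'(w^\top z)]\,w$, Gram–Schmidt
   orthogonalisation, and convergence when
   $|\langle w_{new}, w_{old}\rangle| > 1 - 10^{-5}$. Initial directions
   come from a seeded generator; non-converged components are restarted
   (bounded) and flagged. Maps are Z-scaled (zero mean, unit variance in
   the analysis mask), so voxel values read as within-network
   connectivity strength; the sign ambiguity is resolved by flipping
   maps to positive skewness.

## Group stage

Components are pooled across subjects and clustered by mutual spatial
similarity (distance $1 - |r|$) with constrained average linkage: no
cluster may hold two components of the same subject; inadmissible merges
are skipped. This realises the self-organising group-ICA idea in a fully
deterministic form — the cited method's simulated-annealing refinement
is intentionally omitted so that reruns are bit-identical and the
one-IC-per-subject contract is testable. Cluster maps (mean of
sign-aligned member Z maps) are matched to network templates by spatial
correlation, greedily by descending $|r|$, one component per template,
acceptance threshold $r_{min} = 0.25$ (no threshold was stated; 0.25 is
far above the null correlation scale of $\approx V^{-1/2}$ on tens of
thousands of voxels and well below any genuine network match, which in
practice sits above 0.6). The template-first ordering
(`match_then_cluster`) is also supported because the stated order of
matching and clustering is ambiguous; the clustering-first route is the
default.

Templates are synthesised from the published peak-coordinate tables of
the four observed networks (DMN, SN, FPN, VN) as sums of Gaussian nodes;
the three never-observed networks (AN, CEN, SMN) get synthetic templates
at literature-typical peaks, used only as negative probes. The original
templates are not redistributable; provenance is recorded on each
template object.

## Inference

Per network, the subject Z maps enter a voxel-wise one-way two-group
ANOVA; the signed companion statistic is the pooled two-sample t
(EDp − HC), with $t^2 = F$ identically. No covariates are included (none
were described at this stage). Familywise control uses cluster-extent
thresholding: the voxel threshold is $p < 0.005$ two-sided, and the
minimum cluster extent comes from a Monte Carlo null — fill the mask
with unit Gaussian noise, smooth with a Gaussian of FWHM 1.842 voxels
(the stated spatial-correlation kernel, used directly rather than
re-estimated from residuals), re-standardise within the mask, threshold,
record the largest suprathreshold 26-connected cluster; over 5000
iterations the minimum extent is the smallest $k$ with
$P(\max \ge k) \le 0.05$.

ROI summaries (subject mean Z inside each surviving cluster) are
compared with the classical pooled two-tailed t; behavioural scores
likewise. Brain–behaviour association is an uncorrected Pearson
correlation, as in the emulated analysis.

### A note on the published 22-voxel extent

With the stated parameters (FWHM 1.842 voxels, $p<0.005$, 5000
iterations, $\alpha<0.05$) on a whole-brain 3-mm mask of ~59k voxels
(the original mask size is unprinted), both this implementation and an
independent scipy-based simulation give a minimum extent of 16–17
voxels, with $P(\max \ge 22) \approx 0.004$ — far inside the null. The
published value of 22 voxels would require an effective smoothness of
roughly 2.4–2.5 voxels FWHM, which is plausible for data actually
smoothed at 6 mm on a 3-mm grid (intrinsic smoothness exceeds the
nominal kernel) but is not what the stated kernel parameter produces.
The package reports what the stated algorithm yields; the discrepancy is
surfaced rather than absorbed.

## The synthetic cohort

The generator exists so every stage is testable with known ground truth.
It emulates: two groups (16 vs 19), 210 volumes at TR = 2 s, a 3-mm
grid over a −60..60 / −90..70 / −40..75 mm box with an ellipsoidal brain
mask (simulation happens directly in a common space; spatial
normalisation is out of scope). Four networks (DMN, SN, FPN, VN) are
planted as sums of Gaussian nodes (SD = radius/2, default radius 8 mm —
node extent is nowhere stated) at the published peak coordinates, each
driven by a unit-variance time course of Gaussian noise low-pass
filtered below 0.1 Hz (the conventional ICN band; the original
frequency content is unreported). Rank-1 nuisance terms (WM and CSF
signals confined to their masks), a rank-1 linear drift and i.i.d.
Gaussian noise complete the model; with zero noise the data matrix rank
is exactly networks + nuisance + drift.

Parameters that matter, with defaults and grounds:

* `noise_sd = 0.35` (vs unit signal at a node peak). Chosen so that the
  generator's design contract holds: every planted network — including
  the single-node visual network, the hardest case — is recovered by
  per-subject FastICA with $|r| \ge 0.9$. This emulates the high ICN
  SNR of movie-viewing data after 6-mm smoothing.
* `loading_jitter_sd = 0.4`: between-subject relative spread of node
  loadings. The published ROI summaries imply coefficients of variation
  of roughly 0.5–1.0; 0.4 is at the favourable end of that range.
* Group effects: multipliers 0.55 (deficit) / 1.45 (excess) vs 1.0 at
  the five reported nodes (mPFC, PCC/PCUN, left IPL in DMN; right
  insula deficit and dorsal ACC excess in SN). With jitter 0.4 this
  plants standardised node effects of ≈1.1 SD, matching the printed
  between-group differences (d ≈ 0.95–1.16).
* Behavioural scores are independent Gaussians at the printed group
  means/SDs, except the planted coupling (ρ = 0.6) between the left-IPL
  DMN loading and the SAI-E excitation score within the patient group,
  which anchors the brain–behaviour correlation analysis.
* Physiology: 100-Hz tumescence cuff pressure around 80 mmHg with a
  sigmoid rise (onset 20 s, τ = 4 s) to a plateau of 10.32 % (HC) or
  0.81 % (EDp) of baseline; cardiac R-peak trains at 75.4 / 74
  beats/min; respiratory sinusoids at ~15 cycles/min. The printed
  respiratory unit (0.68 ± 0.10 "cycles/min") is dimensionally
  implausible for resting breathing, so the generator states its unit
  explicitly and plants a physiologically sensible rate.

What the generator does **not** emulate: scanner artefacts, motion,
physiological aliasing into BOLD, slice-timing effects, structural
anatomy, or spatially structured noise. Passing tests therefore show
that the chain of estimators recovers known planted structure under
idealised noise — not that the pipeline is robust to real-data
artefacts.

### Percent-change convention

The tumescence reduction block-averages the 100-Hz trace to one value
per TR, removes the least-squares slope while retaining the series mean,
and expresses values relative to a baseline taken as the mean of the
first 10 s of the down-sampled raw trace (the cuff is inflated to a
known pressure before acquisition, so the opening window is a meaningful
reference; no baseline was named in the original description, and using
the whole-series mean would force every run average to zero). Retaining
the series mean is what lets a planted plateau of +10 % be reported as
≈ +10 %; the cost is that an additive drift moves the reported mean
through the baseline window, while the detrended *shape* of the series
is trend-invariant. Both properties are asserted in the tests.

## Numerical and degenerate-input choices

* Whitening reduces the retained dimension (with a warning) when the
  data rank is below the request; constant data are rejected.
* Zero within-group variance at a voxel yields statistic 0 plus a flag
  rather than NaN.
* Collinear WM/CSF covariates (|r| > 0.999) drop the CSF column with a
  warning.
* Clustering ties are broken by the lowest (subject, component) pair;
  there is no random initialisation anywhere in the group stage.
* All randomness flows from one master seed through a counter-based
  fan-out (`derive_seed`), so stages can be re-run independently and
  whole runs are byte-reproducible.

## Problem sizes used by the test suite

The suite exercises the full default cohort (35 subjects, 210 volumes,
3-mm grid, 30 ICs) once, end to end, for network identification. The
replicated group-difference experiment runs ten cohorts at a reduced
size chosen to keep replication affordable: full group sizes (16 + 19),
4-mm grid, 60 volumes, 8 ICs, with the cluster-extent threshold
recomputed for that mask. Error-rate calibration uses 500 null cohorts
(familywise rate) and 1000 null pairs (correlation type-I rate); the
null simulation for the published-extent reproduction runs at 500
iterations in the suite and 5000 in `scripts/acceptance.R`.

## Known limitations

* At planted effects of ≈1 SD — the size the published ROI summaries
  imply — cluster-corrected voxel-wise detection of ≥4 of the 5 planted
  nodes succeeds in only about half of replicate cohorts (per-node
  detection probability ≈0.6 at the p<0.005 gate with n = 16/19). A
  single-cohort positive finding at this effect size is therefore
  selection-favoured; the replication experiment in the test suite
  reports the honest rate.
* The published 22-voxel extent is not reproducible from the stated
  smoothness (see above).
* sogICA is realised without the annealing refinement of the cited
  clustering method; with well-separated planted sources the constrained
  average linkage recovers the same partition, but on real data the two
  can differ.
* The t-field smoothness of real group maps is estimated here by the
  stated kernel, not from residuals; on real data a residual-based
  estimate would be preferable.
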
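---
title: "Quantifying condensate formation and dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condensate formation and dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puncta)
```

# The problem

Cells concentrate RNA and RNA-binding proteins into membraneless
condensates: nuclear repeat-RNA foci, cytoplasmic stress granules (SGs)
and P-bodies. In disease models of myotonic dystrophy type 1, expanded
CUG-repeat RNA sequesters the splicing factor MBNL1 into nuclear foci and
changes how SGs and P-bodies assemble, exchange material and disperse.
Establishing such effects quantitatively requires a chain of image and
time-series analyses: segmenting puncta, measuring how much of a protein's
signal they hold, scoring colocalisation and granule-granule contacts,
fitting FRAP recoveries, timing SG assembly and disassembly, and gating
statistical tests on normality. `puncta` implements that chain as a tested,
reusable package, together with a synthetic-microscopy generator so every
stage can be validated against known ground truth without access to raw
imaging data.

# The synthetic scene generator

`generate_scene()` renders fields of cells with elliptical nuclei (DAPI
channel), a uniform cytoplasmic baseline per channel, and condensates as
Gaussian spots with Poisson shot noise and Gaussian read noise applied
last. It is the testbed the rest of the package is validated on, and its
defaults are the study conditions the test-suite claims refer to:

* **Voxels** are anisotropic, `(z, y, x) = (0.5, 0.1, 0.1)` µm, matching
  0.5 µm optical sectioning at ~0.1 µm lateral sampling.
* **Spot model.** A condensate of nominal radius $r$ is an isotropic
  Gaussian with $\sigma = r / \sqrt{2\ln 2}$ truncated at $3\sigma$, so its
  *half-maximum radius* equals $r$. This convention makes a half-maximum
  segmentation threshold recover objects at their nominal size, which is
  what links the generator's geometry (docking gaps, radii) to what the
  detector sees. The PSF adds in quadrature
  ($\sigma_{\mathrm{eff}}^2 = \sigma^2 + \sigma_{\mathrm{psf}}^2$).
* **Intensities and noise.** Condensate peaks (default 800 counts over a
  cytoplasm baseline of 60) with shot noise plus read noise of sd 10 give
  spot SNR well above 5, the regime the detection-recovery claims are made
  for. Nothing is claimed about near-threshold SNR.
* **Docking geometry.** A docked P-body centre is placed at
  $r_{SG} + r_{PB} + g$ from its partner SG with the surface gap $g$
  uniform on $[0, 0.1]$ µm; undocked P-bodies keep at least 0.8 µm of
  surface clearance from every SG. The two populations are therefore
  unambiguous for a contact criterion of one voxel, exercising the docking
  detector on both sides of its decision boundary.
* **Separation.** Non-docked objects keep 0.6 µm surface separation by
  default. Segmentation masks extend beyond the nominal radius (to
  ~1.4–1.6 r at typical thresholds), so smaller separations would merge
  adjacent masks and make counting claims meaningless. Cytoplasmic objects
  also keep $1.6 r + 0.1$ µm clear of the nuclear surface so that masks
  never graze the nucleus by construction; objects *inside* the nucleus
  are the intended targets of the exclusion rule.
* **Determinism.** Every generator is a pure function of its spec and
  seed; the master seed expands into independent per-component sub-streams
  (`derive_seed()`), so adding draws to one component never perturbs
  another.

Ground truth records every rendered object with its *actually deposited*
photon sum (exact under truncation), the docked pairs, per-cell photon
totals, and the cell/nucleus masks.

What the generator does **not** emulate: textured or moving cells,
non-uniform diffuse pools, out-of-focus light, chromatic shifts, spectral
bleed-through, or clustered/overlapping condensates. Tests passing on
these scenes show the *computations* are correct under the stated model;
they do not certify performance on real micrographs with those
complications.

# Segmentation

Objects are identified per channel by Otsu's method: the threshold
maximises the between-class variance $w_0 w_1 (\mu_0 - \mu_1)^2$ over 255
interior bin edges of the observed range, computed on the exact data
partition (not binned moments), with ties broken to the lowest maximising
edge. The implementation is checked against an independent exhaustive
search in the test-suite. Because candidate edges are affine-covariant,
segmentation masks are invariant under positive affine rescaling of the
intensities.

Supra-threshold voxels are labelled by connected components (full
26/8-connectivity by default — puncta are compact; configurable to
face connectivity), and components below `min_size_voxels` (4 in 2D, 8 in
3D; not dictated by any published setting, exposed in the API) are
discarded. Nuclei are segmented from the DAPI channel with Otsu plus
per-plane hole filling and a minimum nuclear size; any object sharing at
least one voxel with the nuclear mask is removed entirely (any-overlap
rule), which is idempotent by construction. Cell assignment uses the
nearest nucleus centroid, the only option available when only nuclei are
counterstained.

# Condensate metrics

* `percent_signal_in_objects()` computes
  $100 \cdot \sum_{\mathrm{objects}} I / \sum_{\mathrm{cell}} I$ on
  background-corrected intensities. Background semantics matter: for
  percent-of-total metrics the diffuse pool **is** signal, so the default
  correction is `"none"` (appropriate when the camera offset is zero or
  already subtracted); a `"modal"` option subtracts the modal non-object
  intensity inside the cell and a numeric option subtracts a known level.
  Corrected values are clamped at zero, so the in-object and out-of-object
  shares still sum to exactly 100.
* `per_object_pearson()` is the standard Pearson coefficient over each
  object's voxels, flagged undefined for constant channels, and invariant
  under positive affine rescaling of either channel.
* `docking_events()` declares an (SG, P-body) pair docked when the minimum
  Chebyshev distance between their voxel sets is at most
  `max_gap_voxels + 1` — i.e. the masks touch after `max_gap_voxels`
  dilations. The default gap of 1 voxel is a package decision ("docking"
  has no published quantitative definition); it is symmetric in its two
  arguments and counts each pair once.
* `classify_body_content()` scores an object positive for a protein when
  its mean intensity exceeds `enrichment_factor` (default 1.5, a package
  default, reported with all outputs) times the median non-object
  intensity of its cell.

# FRAP processing and the one-phase association model

A trace carries 3 pre-bleach and 25 post-bleach frames by default, with
adaptive timestamps: post-bleach intervals start at 0.25 s and grow by
22% per frame. Adaptive sampling is what makes a 28-frame series cover
both sub-second exchange and plateaus tens of seconds out; with a uniform
0.5 s interval a half-time of 4 s would never approach its plateau inside
the series.

`correct_and_normalize()` subtracts the background ROI, divides by the
background-corrected reference ROI scaled to its pre-bleach mean (double
normalisation; skipped with a flag when no reference exists — the package
deliberately does not invent a photobleach model from the bleached trace
itself), then maps the first post-bleach value to exactly 0% and the
highest pre-bleach value to exactly 100%. Both anchors are exact in
floating point. Traces whose first post-bleach value exceeds 80% of the
pre-bleach mean are flagged `insufficient_bleach` (the protocol aims at
~50% bleaching efficiency).

`fit_one_phase()` fits
$$Y = Y_0 + (\mathrm{plateau} - Y_0)\,(1 - e^{-Kx})$$
to the post-bleach points by bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`), with $x = 0$ at the first post-bleach frame, $Y_0$
free in $[-20, 20]$, plateau in $[0, 150]$, $K \in (0, 10]$ s$^{-1}$.
Start values: $Y_0$ = first post value, plateau = mean of the last three
points, $K = \ln 2 /$ (time to half of the apparent plateau, crude scan).
It reports the mobile fraction $F_m = \mathrm{plateau} - Y_0$ and
half-time $t_{1/2} = \ln 2 / K$ (the identity $t_{1/2} K = \ln 2$ holds to
machine precision for every fit). An all-zero post-bleach series is a
converged immobile result with $K$ flagged undefined; non-convergence and
negative rates are flagged, never returned silently. Group summaries
exclude non-converged fits and fits with $R^2 < 0.5$, listing the reasons;
no value-based outlier trimming is applied.

**A known bias of max-anchored normalisation.** Anchoring 100% at the
*maximum* of $n_{\mathrm{pre}} = 3$ noisy pre-bleach frames biases the
denominator upward by $\approx 0.85\,\sigma$ (the expected maximum of
three Gaussian draws), shrinking every fitted amplitude by
$\approx 0.85\,\sigma / (d \cdot P)$ where $d$ is the bleach depth and $P$
the pre-bleach level. At 5% frame noise and 50% bleach depth this is an
8% relative shrinkage — a property of the published normalisation
convention itself, not of the fitting, and it vanishes at zero noise. The
package implements the convention faithfully and documents the bias
rather than smoothing the pre-bleach frames away from it. In the
simulator, noise is applied to the bleached point ROI only; background
and reference ROIs average many pixels and are treated as noiseless.
`noise_sd` is expressed as a fraction of the pre-bleach intensity level.

# Assembly and disassembly kinetics

Definitions are deliberately literal:

* **Formation time**: the earliest time point at which at least five SGs
  are detected (threshold configurable). Cells that never reach the
  threshold are censored, never reported as 0; formation time is monotone
  non-increasing in the threshold.
* **Dispersal time**: the first time point with zero SGs in a series that
  begins with SGs present; a transient zero wins even if SGs recur.
* **Population curve**: per time point, the fraction of cells with at
  least one SG; timestamps are used as recorded with no interpolation, and
  mismatched grids are refused.
* **Normalisation to control**: values are expressed as a percentage of
  the control-group mean, which maps the control mean to exactly 100%.

The time-lapse simulator draws per-cell onset and dispersal times from
truncated normal distributions and Poisson-jitters a piecewise-linear
count trajectory (frames every 3 min by default). Negative onsets model
recovery experiments that begin with granules already present. The
condition-contrast checks use 25 cells per arm with onset means 18 vs
32 min (sd 5–6 min) and dispersal means 60 vs 40 min (sd 10 min) —
effect sizes a live-imaging experiment of this design could plausibly
resolve — and verify by sign test that delayed formation and earlier
dispersal are recovered.

# Statistical decision logic

`dagostino_pearson_k2()` is an own implementation of the omnibus
normality test: the D'Agostino (1970) skewness transform and the
Anscombe–Glynn (1983) kurtosis transform combine as
$K^2 = Z_{g_1}^2 + Z_{g_2}^2 \sim \chi^2_2$. The small-sample transforms
are undefined below $n = 8$, which is enforced. The test suite verifies
Type-I calibration at $\alpha = 0.05$ (2000 null replicates), power
against exponential samples, and agreement with an independent reference
implementation to $10^{-6}$.

`compare_groups()` reproduces the gate used throughout the analyses: all
groups pass K2 at $\alpha = 0.05$ → pooled-variance t-test (2 groups) or
one-way ANOVA; any failure → Mann–Whitney U or Kruskal–Wallis. The
decision trace records every verdict, and selection is a pure function of
those verdicts. All tests are two-sided; no multiple-testing correction
is applied by default (apply `p.adjust()` downstream if required).

`sample_size_anova()` inverts the noncentral-F power function
($\lambda = f^2 k n$, $F_{k-1,\,k(n-1)}$) for Cohen's $f$; for two groups
it coincides with the two-sided t-test at $d = 2f$. At the conventional
medium effect $f = 0.25$, $\alpha = 0.05$ and 90% power it returns 86 per
group for two groups. `coefficient_of_variation()` is
$100\,s/\bar{x}$ with the sample ($n-1$) standard deviation — the
definition stated for the summaries it feeds; note that some summaries in
the literature labelled "variance" have the magnitude of a CV.

# Prion-like domain scan

`scan_prld()` runs a two-state HMM over the amino-acid sequence: one
state emits residues with the composition of experimentally characterised
yeast prion domains, the other with human reference-proteome frequencies
(tables vendored in `inst/extdata/prld_composition.tsv`, normalised on
load). The prion-like self-transition is $1 - 1/\mathrm{core\_length}$
(core length 30 by default, so the expected prion-state dwell matches the
core), and the background expected segment length is 500 residues — a
package choice of the order of a protein between low-complexity regions;
domain calls are insensitive to it over a wide range because the
emission log-odds of Q/N-rich stretches dominate. Per-residue prion-like
probabilities come from posterior (forward–backward) decoding, not a
Viterbi paint, because the downstream rule is a continuous probability
track cut at 0.5: domains are maximal runs with posterior > 0.5, reported
in 1-based inclusive coordinates with their length in amino acids. `X` is
tolerated and scored neutrally; other non-standard letters are rejected
with their positions listed. This is a PLAAC-style scan: it reproduces the
model family and decision rule, but exact per-residue agreement with any
particular released parameter set is not claimed, and no proteome-scale
optimisation or PAPA/FoldIndex scoring is attempted.

# Numerical choices and degenerate inputs

* Constant images are a "degenerate histogram" error for Otsu; a constant
  DAPI channel yields an empty nuclear mask with a warning (segmentation
  proceeds without exclusion).
* An object whose two channels are constant has an undefined Pearson r —
  flagged and excluded from summaries, never coerced to 0.
* A trace whose pre-bleach maximum equals its first post-bleach value is
  a "no bleach detected" error.
* Missing voxel-size metadata downgrades physical sizes to voxel counts
  with a warning flag.
* All tie-breaks are documented: lowest Otsu edge, first time point for
  kinetics, first-zero for dispersal.

# Problem sizes used by the test-suite

The validation suite runs on 160×160 two-cell scenes (100 scenes for
detection recovery), 200+ objects per correlation level for
colocalisation calibration, 50 traces per cell of the
$F_m \times t_{1/2} \times$ noise grid for FRAP recovery, 25 cells per
arm for the kinetics contrast, and 2000 replicates for normality
calibration — sizes chosen so the whole suite completes in a few minutes
on one CPU while keeping Monte-Carlo error well inside the asserted
tolerances.

# Known limitations

* The generator's optical model is a Gaussian PSF; no depth-dependent
  blur or deconvolution artefacts.
* Cell assignment by nearest nucleus fails for multinucleate or densely
  packed cells.
* The docking criterion is resolution-dependent: one voxel of gap at
  0.1 µm sampling. Use `max_gap_voxels` to match other samplings.
* The FRAP chain assumes an unbleached reference ROI for photobleach
  correction; without one the correction is skipped and flagged rather
  than estimated from the bleached trace.
* The PrLD scanner's composition tables are fixed; organism-specific
  backgrounds other than human are not bundled.
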
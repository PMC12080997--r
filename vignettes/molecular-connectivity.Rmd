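---
title: "Molecular connectivity from dynamic PET: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular connectivity from dynamic PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

Molecular connectivity (MC) treats the frame-to-frame fluctuations of a
receptor or transporter tracer's binding potential as a network signal, in
direct analogy to how resting-state functional connectivity (FC) treats
BOLD fluctuations. The substrate is the non-displaceable binding potential

$$\mathrm{BP_{ND}} = \frac{V_T - V_{ND}}{V_{ND}} = \mathrm{DVR} - 1,$$

computed *framewise* as the instantaneous target-to-reference activity
ratio minus one. This identification of the activity ratio with the
distribution-volume ratio is only valid at secular equilibrium, which is
why the package assumes a bolus-plus-constant-infusion protocol: the bolus
carries `k_bol` minutes' worth of infusion (38.7 min by default), tuned so
that the plasma level — and with it the reference-tissue activity — is
flat over the analysis window. `framewise_bpnd()` therefore never
estimates $V_T$ or $V_{ND}$ separately; full kinetic modelling (SRTM,
Logan) is deliberately out of scope. The reference region defaults to
cerebellar grey matter (`"Cer"`), configurable per call.

Regional series are extracted in voxel space against an integer-labelled
atlas on the same grid (`extract_regional_timeseries()`): no resampling,
registration, or smoothing is performed, because the package operates on
pre-aligned data. The packaged parcellation has 48 hemisphere-resolved
regions (23 bilateral pairs plus the midline periaqueductal gray and
septum); the `position` column of the region table fixes the ordering of
every matrix the package produces.

## Discarding and detrending

The first 20 minutes of each scan are dominated by perfusion and uptake
kinetics rather than binding and are discarded (`discard_min = 20`). The
remaining DVR−1 series still carries slow uptake trends that would inflate
correlations, so each region is detrended by subtracting a least-squares
piecewise-linear fit with knots every 20 minutes aligned to the retained
window. Two variants are provided because the choice is genuinely open:

* **continuous linear spline** (default): pieces share values at the
  knots. Independent segments create artificial jumps at segment
  boundaries, which inflate correlations in short sliding windows that
  straddle a knot; continuity avoids this.
* **independent per-segment lines** (`continuous = FALSE`): exactly zeroes
  any per-segment linear structure, at the cost of knot discontinuities.

Residuals have zero mean per region, and the fit is a linear projection,
so detrending is idempotent to numerical tolerance. Retained spans
shorter than two knot intervals fall back to a single-line fit with a
warning.

## Connectomes and edge statistics

`subject_connectome()` computes all pairwise Pearson correlations and
variance-stabilizes them with Fisher's $z = \operatorname{arctanh}(r)$.
Numerical choices:

* correlations are clipped to $\pm(1 - 10^{-7})$ before `arctanh` so all
  entries are finite;
* the diagonal is zero by convention, and symmetry is enforced exactly;
* zero-variance regions (possible in degenerate synthetic inputs) yield
  zero edges with a warning rather than an error.

Group inference (`group_connectome()`) is a per-edge one-sample t-test of
$z$ against zero across subjects with Bonferroni correction over the
$R(R-1)/2$ unique edges. Bonferroni was chosen over resampling-based FWE
because it is assumption-light and conservative; on null cohorts the
family-wise error rate stays at or below the nominal level. Masking
subthreshold edges to zero is a display convention (`apply_fwe_mask()`);
stored $z$ values are never altered.

Sliding-window analysis uses 20-minute windows stepping 5 minutes between
20 and 80 minutes by default (nine windows). The step size is a package
choice (configurable down to one frame); window membership is by frame
midpoint in the half-open interval $[s, s+L)$, which is unambiguous for
1-minute frames. Network strength is the mean Fisher-z over unique
within-network edges (node strength: a member's mean edge to the other
members); means rather than sums keep networks of different sizes
comparable. Time-resolved strengths are tested per window against the
first (baseline) window with paired t-tests, Benjamini–Hochberg-corrected
across windows, plus a single baseline-vs-final-window test.

## Small-world analysis

The paper-level claim "small-world coefficient > 1" implies the
Humphries–Gurney formulation, which is what `small_world_coefficient()`
implements: $\sigma = (C/C_{rand})/(L/L_{rand})$ with degree-preserving
double-edge-swap null graphs ($10\,|E|$ swaps per draw, 100 draws by
default). Design choices:

* **proportional thresholding**: the top `density` fraction (default
  0.25) of positive-z edges is kept, so PET and fMRI connectomes are
  compared at equal sparsity; negative edges are excluded first. Exactly
  $\lceil \text{density} \cdot R(R-1)/2 \rceil$ edges are retained, with
  ties broken by a fixed region-pair ordering so results are
  deterministic.
* **unweighted metrics**: $C$ is the mean nodal clustering coefficient
  (nodes with fewer than two neighbours contribute zero); $L$ is the
  characteristic path length on the largest connected component
  (disconnected pairs are excluded by construction).

Because thresholding depends only on edge ranking, $\sigma$ is invariant
to monotone transformations of the weights. The group-level test is a
one-sided one-sample t-test of subject $\sigma$ values against 1.

## Spatial group ICA

`group_spatial_ica()` implements a generic symmetric fixed-point ICA
(logcosh contrast, tolerance $10^{-6}$, at most 1000 iterations,
deterministic seeded initialization) on temporally concatenated,
voxelwise-standardized subject series restricted to the 30–80 min window,
after PCA reduction to the requested model order. Spatial maps are
z-scored over in-mask voxels and sign-flipped to positive skewness;
thresholding at $|z| \ge 1.96$ (two-sided $p \le 0.05$) is applied only
for display/reporting. The intended PET input is the voxelwise DVR−1
series (reference-normalized, detrended), which makes components
binding-driven; BOLD uses the preprocessed signal over the same window.

Two properties matter when interpreting recovery tests. First, whitening
constrains estimated spatial maps to be mutually orthogonal, so planted
patterns are only recoverable with high fidelity when their spatial
overlap with each other is small relative to the mask — two patterns that
tile the mask between them are a single spatial contrast and cannot be
separated into two components. Second, voxelwise standardization
equalizes variance across voxels, so voxels carrying only noise are
amplified to unit variance; recovery accuracy therefore improves with the
amount of concatenated data rather than with raw signal amplitude. The
packaged recovery check plants two disjoint 60-voxel patterns in a
1200-voxel mask (amplitude 3 against unit noise, four 120-frame
subjects), conditions under which recovered components match the planted
maps with $|r| > 0.97$. On full simulated cohorts, correlation against
*binary* network-membership maps is intrinsically lower (≈0.7–0.9)
because member voxels also carry region-private fluctuations; component
*assignment* remains correct.

## Challenge analysis

Static uptake images are voxelwise sums of the frames whose midpoints
fall in a window — baseline 30–40 min, early effect 50–60 min, late
effect 70–80 min — each scaled to a whole-brain mean of one (the
normalization applied before between-period statistics; its precise form
is a package choice). `effect_tmap()` computes a voxelwise *unpaired*
two-sample t by default, matching the stated design, with a paired
variant behind a flag since the periods are within-subject; FWE control
is Bonferroni over in-mask voxels (stricter than random-field
approaches). Regional summaries are means and SDs of voxel t-scores in
table order. `regional_mc_strength_change()` quantifies per-region MC
change as the paired t (post minus baseline) of each region's global
strength — its mean Fisher-z to all other regions — so planted reductions
are negative in both the binding and connectivity change vectors compared
by `bp_change_vs_mc_change()`.

Displacement onsets are timed by `detect_onset()` as the half-drop
crossing between the baseline level and the final plateau, with linear
interpolation between frames. Because planted occupancy curves share one
rise shape, the difference of half-drop times between two networks equals
their planted onset delay.

## The synthetic cohort generator

`simulate_cohort()` encodes the study conditions: 80 one-minute PET
frames, 2400 BOLD volumes (TR 2 s), a cerebellar reference following the
bolus-plus-infusion tissue curve, 48 regions with configured baseline
BP$_{ND}$, and — when a challenge is configured — displacement at 40 min.
Regional PET activity is
$\mathrm{ref}(t)\,(1 + \mathrm{BP}_r(t)) + \varepsilon$ with

$$\mathrm{BP}_r(t) = \mathrm{BP}^0_r\,(1 - \mathrm{occ}_r(t))\,(1 + f_r(t)),$$

where $f_r$ mixes a shared per-network latent AR(1) factor with a private
AR(1) term: $f_r = \sigma_f(\sqrt{\rho}\,u_{n(r)} + \sqrt{1-\rho}\,e_r)$.
Generator defaults and their rationale:

* **fluctuation scale** `fluctuation_sd = 0.1` (10% relative BP
  fluctuations) and **coupling** `network_coupling = 0.6`: yield
  within-network correlations around 0.5 after measurement noise,
  comparable to what ROI connectivity studies report.
* **PET noise** `noise_sd = 0.02`: Gaussian with SD proportional to
  activity divided by $\sqrt{\text{frame duration}}$, a standard
  counting-noise proxy; projection-domain simulation is out of scope.
* **occupancy curves**: truncated-logistic, exactly zero before onset,
  monotone, reaching 95% of plateau within 10 min. Subcortical members
  plateau at 0.4 immediately after the challenge; salience members at 0.3
  with a 10-min onset delay; all other regions receive a background
  occupancy graded by baseline binding
  (`0.15 * BP_r / max(BP)`), reflecting that displacement is strongest
  where binding is highest. The curve's functional form is a package
  choice; only the onset timing is a protocol fact.
* **connectivity reduction**: occupancy rescales BP but leaves
  correlations unchanged, so drug-induced MC change is planted
  separately: the shared-factor coupling is scaled down after the
  challenge (default 50% for the subcortical network, 15% salience; BOLD
  analogues 5% and 20%).
* **baseline BP$_{ND}$** is high in the subcortical SERT regions (2.2–3),
  moderate in salience regions (1.2–1.8), low elsewhere, with a mild 3%
  right-hemisphere asymmetry so every region carries a distinct value.
  These are illustrative configuration values, not empirical claims.
* **BOLD**: the same latent-factor construction at TR resolution with
  AR(1) innovations; no hemodynamic response convolution (resting-state
  only).

With `make_images = TRUE`, regional series are painted into a toy block
atlas (one rectangular block per region plus a reference block) with 5%
multiplicative voxel noise. The toy volume is a geometric stand-in for
tests and simulations, not an anatomical atlas.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: anatomy-faithful geometry and
partial-volume effects, PET reconstruction and scatter physics,
plasma-pharmacokinetic drug modelling, motion and physiological
confounds, and the spatial preprocessing (realignment, normalization,
smoothing) that real pipelines perform upstream of this package.

## Problem sizes and runtime choices

The shipped test-suite works at desk scale: cohorts of 2–30 subjects,
48-region series of 60–80 frames, 200-replicate null calibrations,
100-replicate power checks at the challenge cohort size (n = 11), and
20-seed ICA recovery on 1200-voxel masks. These sizes were chosen so the
whole suite completes in a few minutes while keeping Monte-Carlo margins
interpretable; all of them are parameters, not limits.

## Known limitations

* Framewise DVR−1 is undefined off equilibrium; applying the package to
  bolus-only acquisitions will fold uptake kinetics into the
  "fluctuations" even after detrending.
* Bonferroni FWE over voxels/edges is conservative for spatially or
  anatomically correlated data.
* The ICA model order is user-set; no MDL/AIC estimation is provided.
* Paired designs are supported for t-maps, but the default follows the
  unpaired two-sample formulation.
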
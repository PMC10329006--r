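---
title: "Quantifying chromosome dynamics in oocyte meiosis I"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosome dynamics in oocyte meiosis I}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiotrack)
```

## The problem

During female meiosis I in *C. elegans*, six bivalents — pairs of
holocentric homologous chromosomes — must orient along the spindle long
axis, congress to the metaphase plate, and segregate their homologs to
opposite spindle poles. Errors produce aneuploid eggs. Live two-channel 3D
time-lapse imaging (chromatin plus tubulin) makes these events measurable,
but turning 4D image stacks into per-chromosome statements ("this bivalent
was misoriented at anaphase onset and later co-segregated") requires a
chain of quantitative steps: spot detection, tracking, a per-frame spindle
reference frame, metric time series, calibrated thresholds, and fate
rules. `meiotrack` implements that chain, together with a ground-truthed
simulator used to validate every step.

## The spindle reference frame and its metrics

All chromosome metrics are expressed in a frame rebuilt at every timepoint
from the two pole positions $A$ and $B$ (the spindle rotates and shortens,
so the frame is never reused across frames):

* unit long axis $u = (B - A)/\lVert B - A\rVert$, midpoint
  $m = (A + B)/2$; the **equator** is the plane through $m$ normal to $u$.
* **Orientation**: with the bivalent axis $v$ = vector from homolog 1 to
  homolog 2 (centroids), $\theta_{\mathrm{lab}} =
  \arccos(v \cdot u / \lVert v\rVert)$ in degrees. The label-free
  **folded** angle $\theta = \min(\theta_{\mathrm{lab}},
  180° - \theta_{\mathrm{lab}}) \in [0°, 90°]$ is what thresholds use;
  $\theta_{\mathrm{lab}}$, with homolog 1 fixed as the homolog nearer pole
  A at the first tracked frame, is what reversion detection uses
  (persistent crossings of 90°, i.e. the homologs swapping pole-facing
  identity).
* **Congression**: $d_{\mathrm{eq}} = |(c - m)\cdot u|$ for the bivalent
  centroid $c$ (mean of the homolog centroids).
* **Axial compaction**: $d_{\mathrm{ax}} = \lVert (c - m) - ((c - m)\cdot
  u)\,u \rVert$, the distance to the long axis. By construction
  $d_{\mathrm{eq}}^2 + d_{\mathrm{ax}}^2 = \lVert c - m \rVert^2$, which
  the tests verify to $10^{-9}$ against brute-force point-to-plane and
  point-to-line formulas.
* **Oscillation**: $|d_{\mathrm{eq}}(t + \Delta t) - d_{\mathrm{eq}}(t)|$
  with a one-frame (10 s) lag.
* **Stretching**: homolog length (between a homolog's two endpoint
  markers), inter-homolog distance (between homolog centroids) and
  bivalent length. The bivalent length is defined here as the maximum
  pairwise distance among the four endpoints — the end-to-end extent —
  because the underlying data model is point markers, not segmented
  shapes.

The centroid used for $d_{\mathrm{eq}}$/$d_{\mathrm{ax}}$ is the
homolog-centroid mean; an intensity-weighted centroid would need dense
segmentation, which the point-track data model deliberately avoids.

## Thresholds and their calibration

The reference thresholds are 22.5° for orientation, 0.5 µm for
congression, and 1.6 µm for axial compaction. They are reproduced by
`calibrate_thresholds()` as the *mean over control oocytes of the
per-oocyte maximum* — of the folded angle at the anaphase-onset frame, and
of the two distances over a metaphase window (−100..0 s; the window is a
package decision, the source protocol says only "in metaphase"). Whether
the average should run over per-oocyte or per-chromosome maxima is not
specified by the protocol; the package implements per-oocyte maxima, and
per-chromosome maxima can be obtained by treating each bivalent as its own
cohort unit. Threshold comparisons are inclusive (`<=`); boundary ties are
measure-zero on real data, and the convention is fixed so proportions are
exactly reproducible.

## Anaphase fates, ploidy and onset

Fates are called from signed equator coordinates $s(t) = (p - m)\cdot u$
per homolog. Defaults: checkpoint at +60 s, call at +120 s, segregated
band $|s| \ge 2$ µm, lagging band $|s| < 1$ µm. A homolog lags when it is
still inside the lagging band at the checkpoint while at least half the
homologs of the oocyte have cleared the segregated band. At the call time:
same side and both segregated → **co-segregating**; opposite sides, both
segregated, no lagging → **normal**; a laggard that ends opposite its
partner → **lagging, correct**; a laggard that ends on the partner's side
or never leaves the band → **lagging, mis-segregated**. A configuration
matching none of these (a final position between the two bands) is
reported as *uncallable* rather than forced into a category, and excluded
from ploidy with a warning. An oocyte is euploid iff no bivalent
co-segregated or mis-segregated. The band widths and times are package
decisions (the source workflow judged fates by eye from movies); all are
exposed in `classification_config()`.

Anaphase onset is detected from the inter-homolog distance: cohesion
release produces a jump, found as the first per-oocyte median increment
exceeding the median plus 5 MADs of the pre-jump increments. Because the
first *elevated* frame is one frame after the last cohesive frame, the
detector is validated to ±1 frame against simulator truth.

The angle–fate association is a logistic regression of the binary
mis-segregation indicator on the folded angle at onset, with significance
from a seeded label-permutation test on |slope| (default 10,000
permutations) rather than a Wald test: cohorts have dozens of bivalents,
where the permutation reference is exact under exchangeability and immune
to separation. Complete separation is flagged; the reported slope is then
a finite surrogate of an infinite maximum-likelihood estimate, and the
permutation p-value remains valid.

## Image processing

Spot detection is scale-normalized Laplacian-of-Gaussian filtering on
anisotropic voxels, with scales starting at $\sigma = d_{\min}/(2\sqrt 3)$
for the 0.8 µm detection diameter. Three numerical guards matter in
practice and are part of the contract:

* smoothing is floored at 0.8 voxel per axis — at a 0.3–0.4 µm Z step the
  nominal sigma is below one voxel and would pass shot noise straight into
  the Laplacian;
* maxima inside the filter support of the volume boundary are discarded
  (padded convolution inflates the response at corners);
* non-maximum suppression uses the larger of the two candidate diameters,
  absorbing the weak large-scale "bridge" response that appears midway
  between two resolved blobs, and a 10-MAD response floor removes noise
  maxima.

Positions are refined to sub-voxel precision by intensity-weighted
centroids. Voxel centres sit at `origin + (index + 0.5) * spacing`
(0-based). Poles come either from user-supplied points (relabelled A/B by
nearest-previous-position so identities persist) or from
intensity-weighted PCA of the denoised tubulin channel: the long axis is
the first principal axis (an error is raised if the intensity distribution
is near-spherical — "no spindle axis"), initial pole estimates are the
2nd/98th intensity-weighted percentiles of the projections, then each is
refined by a local weighted centroid, which removes the inward bias of the
percentile along a cloud-shaped spindle.

Linking is greedy mutual-nearest-neighbour with a per-frame displacement
budget (default 1 µm/frame) and gap closing with linear prediction up to 2
frames: with 14 well-separated objects per frame, global optimization
buys nothing, and the contract enforced by tests is agreement with
simulator ground truth. Homologs are paired into bivalents by exact
minimum-total-distance perfect matching (12 points, enumerable) at the
earliest frame where all 12 are observed — before congression, when
intra-bivalent distances are unambiguously the smallest; pairing at the
compacted plate is demonstrably unsafe. An edits table (spot deletions,
track remaps) can be applied after linking, standing in for interactive
curation.

## Fluorescence quantification

`measure_roi()` supports single-plane means and sum-Z projections (mean
or integrated, since total-amount readouts need sums), `linescan()`
averages across an odd pixel width perpendicular to the line with bilinear
interpolation, and `normalize_series()` computes
$(I - B)/B$ — invariant to detector gain, not to additive offsets — then
divides by the maximum background-normalized control value, so a control
series peaks at exactly 1. Background ROIs are user-supplied cytoplasmic
regions; no automatic background estimation is attempted.

## The simulator

`simulate_cohort()` generates the data the analysis assumes, with known
answers. It is kinematic phenomenology, not a force-balance model:

* **Acquisition**: 30 Z-planes at 0.3 µm every 10 s; 63 frames spanning
  −500..+120 s around onset by default; XY pixel 0.11 µm (a typical
  spinning-disk sampling; not specified by the source protocol).
* **Pre-onset dynamics**: first-order (discrete Ornstein–Uhlenbeck)
  relaxation — chosen because the approach to the plate is constrained and
  non-oscillatory, so an inertial term would add nothing. The folded
  angle relaxes toward 0 at `k_orient` = 0.02 s⁻¹ once the oocyte's
  spindle has bipolarized (time drawn from N(−350 s, 40 s) in controls); a
  preset fraction of bivalents never relax (persistent misorientation).
  The equator distance relaxes at `k_congress` = 0.015 s⁻¹ toward a
  per-bivalent plate offset with additive noise `sigma_pos` = 0.05 µm.
  None of these rates are stated in the source; they are realism choices
  fixed once, and with them the calibration emerges near the reference
  values (≈20°, ≈0.47 µm, ≈1.5 µm at seed 1) without being programmed in.
* **Plate geometry**: lateral anchors form a jittered rosette (one
  central bivalent, five on a ring) that compacts to 60 % of its radius by
  onset. The rosette keeps bivalents in exclusive territories so homologs
  of different bivalents stay optically resolvable — the property the
  tracking layer depends on and which the real spotting workflow enforced
  by manual curation.
* **Stretching**: bivalent length ramps up by `dL` = 0.4 µm between −150 s
  and −50 s, split between the inter-homolog distance (dL/2) and the
  homolog lengths (dL/2 each) so the end-to-end extent grows by exactly
  dL. Endpoint markers sit at ±L/2 along the bivalent axis.
* **Anaphase**: at onset, homologs separate toward their facing poles at
  `v_push + v_pull` = 0.04 µm/s, saturating at a per-homolog depth of
  2.8–3.8 µm from the equator (so trajectories stay inside a renderable
  volume and pole-proximal chromosomes do not collapse onto one point).
  Each bivalent's fate is drawn with
  $P(\text{mis}) = \mathrm{logistic}(\beta_0 + \beta_1\,\theta_{onset})$;
  mis-segregations split between co-segregation and mis-segregating
  laggards, and a small fraction of correct segregations lag before
  resolving at +70 s. With `v_push = v_pull = 0` (combined-loss preset)
  the drawn categories are latent: nothing separates, and the classifier
  correctly reports what the movie shows.
* **Noise**: positional noise enters the state dynamics (`sigma_pos` per
  frame) and as independent measurement noise (0.5 `sigma_pos`) on stored
  marker positions; the bivalent itself stays rigid.

Presets `control`, `knl1_null`, `lateral_loss`, `endon_loss` and
`combined_loss` mirror the perturbation series qualitatively:
kinetochore-null has 35 % persistently misoriented bivalents, a loose
plate, and a steep angle–fate link; lateral-loss delays bipolarization to
−120 s and recovers; end-on-loss removes the stretch ramp and pulling and
widens the plate while segregating accurately (with frequent correctly
resolving laggards).

`render_stack()` turns tracks into two-channel voxel data: Gaussian blobs
for homologs, pole blobs plus an elongated pole-to-pole Gaussian for the
tubulin channel, and Poisson-plus-read noise scaled so the blob peak over
the noise standard deviation at the peak equals the requested SNR.

**What the simulator does not emulate** — and what passing tests therefore
do not show about real data: chromosome shape (rigid point constellations
only, no bent or entangled bivalents), spindle rotation and skew relative
to the imaging axes, photobleaching and depth-dependent attenuation,
background structure from cytoplasmic autofluorescence, and the early
prometaphase period when no spindle axis exists. Real recordings also
break the rosette's resolvability guarantee, which is why the original
workflow included manual spot curation; the `edits` hook exists for
exactly that.

## Problem sizes

The tests and the acceptance script use cohorts of 2–20 oocytes, movies of
16–63 frames, and rendered volumes of roughly 55 × 30 × 18 voxels at 0.15
µm XY / 0.4 µm Z sampling — sizes chosen so the full suite and the
acceptance run each complete in about a minute while every statistical
check retains enough events (e.g. 120 bivalents per classification cohort,
100–200 cohorts for the association error rates) to be meaningful.

## Known limitations

* Fate calling assumes the movie reaches +120 s; shorter recordings yield
  "uncallable", not a guess.
* The onset detector needs an actual cohesion-release jump; slow ramps
  raise an error asking for an explicit onset.
* Pole finding from tubulin assumes a bipolar spindle; no attempt is made
  to handle monopolar or multipolar figures.
* Detection assumes blob-like chromatin signals at the 0.8 µm scale;
  heavily overlapping chromosomes merge, and the linker reports the
  resulting fragments honestly rather than inventing continuity.
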
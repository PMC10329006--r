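# meiotrack

Quantitative analysis of 4D chromosome dynamics in oocyte meiosis I.

During the first meiotic division of *C. elegans* oocytes, six bivalents
(pairs of holocentric homologous chromosomes) orient along the spindle
long axis, congress to the metaphase plate, and segregate their homologs
to opposite poles; failures of this program generate aneuploid eggs.
`meiotrack` turns two-channel 3D time-lapse recordings (chromatin +
tubulin) — or tabulated XYZT point tracks — into per-chromosome,
per-timepoint statements about that program, and ships a ground-truthed
synthetic cohort simulator against which every stage of the pipeline is
validated.

## What it computes

All metrics live in a per-frame spindle reference frame built from the
two pole positions $A, B$: unit axis $u = (B-A)/\lVert B-A\rVert$,
equator plane through the midpoint $m$ perpendicular to $u$. Per bivalent
and frame:

* orientation angle $\theta = \arccos(v\cdot u/\lVert v\rVert)$ between
  the inter-homolog axis $v$ and $u$ (labeled form in [0°, 180°] for
  reversion detection, folded form in [0°, 90°] for thresholding);
* congression distance $d_{eq} = |(c-m)\cdot u|$ and axial-compaction
  distance $d_{ax} = \lVert(c-m) - ((c-m)\cdot u)u\rVert$ of the bivalent
  centroid $c$;
* oscillation $|d_{eq}(t+10\,\mathrm{s}) - d_{eq}(t)|$;
* stretching metrics: homolog lengths, inter-homolog distance, bivalent
  end-to-end length.

Per-timepoint state is classified against thresholds (defaults 22.5°,
0.5 µm, 1.6 µm) that can be re-calibrated on any control cohort as the
mean of per-oocyte maxima. Anaphase fates (normal / co-segregating /
lagging-correct / lagging-mis-segregated) and oocyte ploidy are called
from signed equator coordinates, anaphase onset is detected from the
cohesion-release jump in inter-homolog distance, and the association
between the angle at onset and mis-segregation is quantified by logistic
regression with a permutation test. Image stacks are processed by
anisotropic Laplacian-of-Gaussian spot detection, tubulin-PCA pole
finding, mutual-nearest-neighbour track linking with gap closing, and
exact minimum-distance homolog pairing.

## Worked example

Simulate a kinetochore-null-like cohort, compute metrics, classify, and
test the angle–fate association:

```r
library(meiotrack)

cfg <- cohort_config(n_oocytes = 5, preset = genotype_preset("knl1_null"),
                     seed = 42)
sim <- simulate_cohort(cfg)
met <- compute_metrics(sim$tracks)

cls <- classify_timepoints(met, classification_config())
subset(cls$proportions, time_s == 0)
#>  time_s     metric n_defined n_below proportion
#>       0  compacted        30      30  1.0000000
#>       0 congressed        30      18  0.6000000
#>       0   oriented        30      22  0.7333333

fc <- classify_fates(sim$tracks)
table(fc$fates$category)
#>        co_segregating       lagging_correct lagging_missegregated
#>                     4                     3                     3
#>                normal
#>                    20
table(fc$oocytes$ploidy)
#> aneuploid   euploid
#>         4         1

assoc <- angle_fate_association(fc$fates, n_perm = 999, seed = 1)
sprintf("slope = %.3f per degree, permutation p = %.3f",
        assoc$slope, assoc$p_perm)
#> "slope = 0.072 per degree, permutation p = 0.043"
```

At anaphase onset only 73% of this mutant cohort's bivalents are within
the 22.5° orientation threshold and 60% within the 0.5 µm congression
threshold; 10 of 30 bivalents mis-segregate or lag, 4 of 5 oocytes end
aneuploid, and mis-segregation probability rises by
`exp(10 * 0.072) ≈ 2`-fold odds per 10° of misorientation at onset. The
simulator's ground truth (`sim$truth`) lets you check every one of those
calls; `onset_detect(met)` recovers the anaphase onset frame to within
one frame.

Rendered-image workflows start from `render_stack()` /
`write_stack()` and come back to tracks with `track_stack()`;
`plot_colorcoded()` draws the standard proportion-coloured metric-vs-time
panels.

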
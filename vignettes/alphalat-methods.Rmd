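---
title: "Alpha lateralization and midfrontal theta: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha lateralization and midfrontal theta: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In cued visual search, spatial attention shifts the balance of posterior
alpha-band (8–12 Hz) power between the hemispheres: power drops
contralateral to the attended hemifield and rises ipsilateral to it, a
signature of target enhancement and distractor suppression. `alphalat`
implements the full analysis chain for experiments that cross **spatial
cueing** (an informative cue pointing at the upcoming target side with
100% validity, versus an uninformative cue) with **feature-based
distraction** (a distractor whose color similarity to the target is
parametrically varied over four levels, D1 most similar to D4 least).
The package asks, on simulated cohorts with known ground truth, the same
questions the paradigm asks of human data:

1. Does the informative cue induce pretarget alpha lateralization?
2. Does lateralization re-emerge *after* stimulus onset, and in which
   cue-by-similarity conditions?
3. When target selection fails to lateralize (uninformative cue, highly
   similar distractor), does midfrontal theta (4–6 Hz) rise instead,
   as a signature of reactive conflict control?
4. Do participants with weaker post-stimulus lateralization under high
   similarity pay a larger reaction-time "distractor cost"?

Because no public recordings exist for this design, the package pairs the
analysis chain with a synthetic-EEG cohort generator whose condition
structure embodies those effects. Every stage of the pipeline is therefore
testable against a known truth: the statistics should recover all and only
the injected effects.

## The synthetic cohort

### Design

The trial schedule crosses cue presence (2) with distractor similarity
(4); each of the 8 cells holds 108 trials by default (864 per subject),
balanced over target sides and the three target letters, with the
distractor letter never equal to the target letter. Trial types are
pseudorandomized in passes — each pass holds every distinct
cue-by-distractor-by-side-by-letter type once — and the target shape
alternates every 48-trial block. When a cell size is not divisible by the
6 side-by-letter types, the excess is assigned round-robin in a fixed
order, so schedules are deterministic given a seed.

### Behavior

Reaction times are drawn from a log-normal moment-matched to each cell's
mean and SD. The default cell means reconstruct the 2 × 4 table from its
printed marginals: per-distractor means (910.2, 875.2, 803.6, 798.8 ms
for D1–D4) and per-distractor cue benefits (159.8, 126.3, 51.5, 46.9 ms),
via `cell = marginal ∓ benefit/2`. The trial-level SD defaults to 200 ms,
a typical single-trial RT spread for speeded discrimination; the paper
reports only between-subject SEMs, so the within-cell spread is the
package's choice. Accuracy is Bernoulli per cell (defaults average 87.9%
correct with a similarity effect that is larger on uncued trials), and an
eye-movement flag is Bernoulli(0.071) independent of condition — the flag
is metadata for the rejection logic; no ocular voltage is simulated,
since artifact correction is out of scope.

### Signal model

Each trial is the sum of:

* **1/f^β background noise** per channel (β = 1 by default), generated by
  FFT amplitude shaping of white noise, plus a rank-2 spatially shared
  component (40% of the channel noise RMS) so that channels are
  correlated as in real recordings;
* an **ongoing posterior alpha oscillation** (10 Hz, amplitude 1.2 noise
  units) with phase drawn uniformly per trial and channel. Random phase
  makes the activity *induced* rather than evoked: per-trial power
  carries it, while the across-trial average tends to zero;
* **condition-specific lateralization**: inside a condition's effect
  window(s) the alpha amplitude is scaled by `1 + a` ipsilateral and
  `1 − a` contralateral to the target (default a = 0.25), with 100-ms
  raised-cosine ramps. Windows follow the reported effects: cued trials
  −1050–0 ms pretarget; cued/low-similarity 350–500 ms post-target;
  cued/high 0–150 and 450–750 ms; uncued/low 500–900 ms; uncued/high
  none;
* a **midfrontal theta burst** (5 Hz, amplitude 0.9) at 700–1250 ms
  post-target, on uncued high-similarity (D1/D2) trials only.

Effect sizes in signal units are nowhere stated in the literature for
this paradigm; the defaults were calibrated once so that the full
pipeline at 16 subjects recovers the complete pattern of significant and
null contrasts with high power, and are not revisited. Between-subject
variability enters as a log-normal multiplier (SD 0.2 on the log scale)
on each subject's asymmetries and theta amplitude.

### Brain–behavior coupling

A latent standard-normal trait `z` per subject ("distraction
susceptibility") couples behavior to physiology: it adds
`coupling_rt × z` ms (default 40) to the uncued D1/D2 reaction-time
means and scales the uncued/low alpha asymmetry by
`exp(coupling_alpha × z)` (default 0.4). Subjects with larger distractor
costs therefore show *relatively* less high-similarity lateralization
(the high-minus-low difference becomes more negative), which is what the
negative rank correlation between cost and lateralization difference
measures. Setting both couplings to zero severs the link.

### What the generator does not emulate

Volume conduction and realistic forward models, ocular/muscle artifacts,
non-stationary noise, evoked (phase-locked) components, and channel-level
artifacts are all absent. Passing the recovery tests therefore shows the
*statistical chain* is sound — it does not certify performance against
the artifact structure of real recordings.

## Time–frequency decomposition

Power is estimated per trial with a sliding Hann window whose length
adapts to frequency, ΔT = 3/f (three cycles). Implementation details that
matter:

* the window length is rounded to the nearest odd sample count and
  centered on the output timepoint, so time stamps are exact;
* the estimate is a single-frequency discrete Fourier projection of the
  tapered segment — mathematically the f-bin of a windowed DFT without
  computing unused bins. Power is scaled by `(2/Σw)²` so a unit
  sinusoid at f has power ≈ 1; since all downstream quantities are
  baseline-relative, any fixed scale cancels;
* the output grid defaults to 50-ms steps anchored at target onset, and
  frequencies to 1-Hz steps — bands (8–12, 4–6 Hz) are fixed by the
  analysis, grids are common practice at this window length;
* timepoints whose window overruns the epoch are masked `NA`
  ("mark-undefined"); masks propagate through baseline normalization,
  band averaging and into the cluster statistics, so edge-contaminated
  estimates are never tested.

Baseline normalization is the relative change
`(power − baseline)/baseline`, with the baseline averaged over trials
and baseline timepoints within a subject-by-condition unit *before*
division — this matches a single "average power at baseline" and avoids
the instability of per-trial division. Alpha uses a 400-ms precue window
(−2.2 to −1.8 s, ending 100 ms before the earliest possible cue onset at
−1.7 s); theta uses −700 to −300 ms pretarget, because the wider theta
windows (750 ms at 4 Hz) would leak cue- and target-evoked activity into
a precue baseline.

## Hemisphere flip-and-pool and the lateralization index

Trials with left-sided targets are mirrored across the sagittal midline
(channel values exchanged within mirror pairs; midline channels fixed)
and pooled with right-target trials. In the pooled frame the right
hemisphere is ipsilateral and the left contralateral to the target. The
lateralization contrast is then a paired comparison of each subject's
condition map against its own mirror image, and the lateralization index
is mean(ipsi) − mean(contra) over a channel-by-time selection.

As in the original analysis, the index's channels and window are taken
from the significant uncued/low-similarity post-target cluster — a
selection that is circular by construction (the same data select and
quantify). The package inherits this deliberately for comparability and
offers `index_selection = list(channels=, window=)` for an independent
a-priori selection; when no cluster is significant it falls back to the
posterior group in 0.5–0.9 s.

The by-eye outlier exclusion of the original correlation analysis is
replaced by a deterministic rule: a point is flagged when its robust z
score (|x − median| / MAD, scaled) exceeds 3 on either axis, and the
Spearman correlation is always reported both with and without flagged
points.

## Cluster-based permutation testing

The spatio-temporal cluster test controls the family-wise error over
channels × timepoints:

1. a dependent-samples t map across subjects, thresholded two-sided at
   pointwise p < 0.05 (`t₀.₉₇₅,n−1`) — the convention of the cluster
   method when no threshold is reported;
2. supra-threshold points of equal sign grouped by connectivity: same
   channel and adjacent timepoint, or same timepoint and spatially
   neighboring channel (neighborhood = planar distance graph of the
   layout);
3. cluster mass = sum of member t values (the common default for the
   "maximum cluster-level statistic");
4. the null distribution of the maximum |mass| built by flipping the
   sign of each subject's condition difference — algebraically identical
   to swapping that subject's condition labels — 1000 times;
5. Monte Carlo p = (count of null maxima ≥ |mass| + 1)/(n_perm + 1); the
   +1 keeps the test valid at finite permutation counts. When 2^n ≤
   n_perm the full sign assignment set is enumerated instead, making the
   test exact and seed-free.

Zero-variance points (possible in degenerate synthetic data) become
signed infinities and count as supra-threshold with their sign. The
cue-by-lateralization interaction is tested as the paired cluster test on
difference-of-differences (lateralized-minus-mirrored per cue type) —
the minimal construction consistent with a paired cluster test, since no
formula is reported for it. Theta contrasts pool left- and right-target
trials without mirroring.

## Behavioral statistics

Trials are rejected when incorrect or flagged for eye movement.
Participants are screened in a single pass on pre-exclusion group
statistics: (a) overall accuracy strictly below the group mean − 2 SD
excludes; (b) absence of a basic similarity effect excludes — the
trial-level Welch t test of correct-trial RTs D1 vs D4 must be
significant (two-sided p < 0.05) with mean(D1) > mean(D4); following the
stated procedure this is a trial-level ("independent-samples") test
within subject, not a between-subject test; (c) the cue-benefit t test is
reported but never excludes. The 2 × 4 repeated-measures ANOVA is the
classical within-subject sums-of-squares decomposition, each effect
tested against its effect-by-subject interaction, without sphericity
correction (none is reported and the printed degrees of freedom are
uncorrected). Pairwise contrasts are Bonferroni-corrected by multiplying
raw p values by the family size and capping at 1. Chance level for the
three-alternative letter report is exactly 1/3 (the printed "33.4%" is a
rounding); a guesser who first eliminates the letter seen in the
distractor chooses between two letters, one of which is the target —
exactly 1/2. The package adopts 1/2 for the "knows the distractor letter"
reading and exposes both.

## Numerical and design choices

* **Layout**: a 34-channel 10/20 master table; `build_layout(n)` takes a
  symmetric subset in a fixed priority order that always contains the
  posterior (parieto-occipital) and midfrontal groups. The neighbor graph
  uses a planar distance threshold, chosen adaptively
  (`max(1.6 × median, 1.01 × max)` of nearest-neighbor distances) so no
  sensor is isolated at any size. No channel sets are published for the
  original figures; the groups are this package's documented choice.
* **Determinism**: every stochastic stage takes a seed; cohort-level
  seeds derive per-subject child seeds (`cohort_plan()`), so cohorts can
  be generated subject-by-subject (bounded memory) yet reproduce
  `simulate_cohort()` exactly.
* **Noise generation** runs its FFTs at the next 5-smooth length and
  truncates, with an analytic Parseval scale so the RMS is exact in
  expectation.
* **Problem sizes**: the recovery analyses in the tests and the
  acceptance script run the full design (16 subjects, 108 trials/cell)
  on a 16-channel layout, the validity simulations use 12 subjects ×
  16 channels × 40 timepoints × 500 permutations, and the correlation
  sign checks use 12-subject, 24-trial/cell, 8-channel cohorts — sizes
  chosen to make a desk-scale run of the whole suite practical while
  keeping every test at the design's full statistical structure.
* **Container format**: epochs are stored as a documented directory
  (JSON metadata + TSV trial table + raw little-endian float64
  voltages), with a version tag checked on read.

## Known limitations

The effect windows are injected as amplitude modulations of an ongoing
oscillation, so recovered cluster extents shrink slightly relative to
the injected windows (ramps, window smearing ΔT = 3/f, and the 50-ms
grid). The cluster test's reported t values are cluster masses and are
not comparable across layouts with different channel counts. The
similarity screen is underpowered at small trials-per-cell counts; with
cells below ~50 trials, simulated cohorts lose subjects to the screen
exactly as an underpowered human study would.
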
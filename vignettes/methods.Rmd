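---
title: "Methods: compartmental Ca2+ imaging analysis at the Drosophila NMJ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmental Ca2+ imaging analysis at the Drosophila NMJ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmjCa)
```

## Overview

nmjCa implements the quantitative analysis of genetically encoded Ca2+
indicator recordings (GCaMP in the cytosol and postsynaptic compartment,
ER-lumen GCaMP variants, mitochondrial CEPIA) at *Drosophila* larval
neuromuscular junctions, together with static confocal ER-marker
quantification and the statistical comparison scheme used on per-larva
datapoints. Every stage can be exercised against synthetic data with
known ground truth, so the package is testable end to end without any
imaging hardware or downloads.

The processing chain for one evoked recording is:

1. rolling-ball background subtraction of the movie (disc radius 50 px);
2. translation registration against the first frame, restricted to an
   NMJ ROI, iterated if needed;
3. ROI mean-fluorescence extraction (whole NMJ, boutons, or all
   mitochondria);
4. photobleach correction: a power curve $PC(x) = a\,x^b$ is fitted to
   the pre-stimulation frames by ordinary least squares on
   $\log F$ versus $\log x$, and the whole trace is divided by it;
5. a 5-frame centred rolling average;
6. $\Delta F/F$ as the corrected trace minus 1;
7. evoked features: resting $F$ (the fitted curve immediately before
   stimulation), maximum raw $F$, $\Delta F$, the post-onset
   $\Delta F/F$ extrema, time to peak, and times from peak to 50% and
   100% recovery.

Resting (unstimulated) recordings instead pass to the miniature-event
detector; static two-channel confocal images pass to the
Intermodes-threshold puncta quantification.

## Photobleach model

Bleaching is modelled as a power law over the frame index,
$PC(x) = a x^b$ with $x = i + 1$ for the 0-based frame index $i$, so the
curve is defined at the first frame (the offset is a documented,
configurable parameter). The fit is the closed-form log-log ordinary
least squares solution: it is exact on a noiseless power law,
deterministic, and scale-equivariant (multiplying the trace by $c$
multiplies $a$ by $c$ and leaves $b$ unchanged). Division by the fitted
curve is applied to the entire time course, not only the fitted window.
Pre-stimulation values must be strictly positive; non-positive values
are an error rather than silently dropped.

$\Delta F/F$ is computed as the bleach-corrected trace minus one. With
the baseline divided out this is algebraically the fractional change
relative to the (bleach-free) baseline; the pipeline applies the 5-frame
rolling average to the corrected trace before feature extraction, in the
order the processing chain lists them.

Two windowing choices are deliberately explicit because they are easy
to get subtly wrong: the rolling average uses a centred window that
shrinks symmetrically at the trace edges (no invented padding values),
and the post-stimulation minimum (the ER release dip) is searched in a
fixed window from stimulation onset to onset + 2 s (parameter
`minDffWindow`).

The 100%-recovery time needs a numeric criterion the source procedure
leaves qualitative; we use first return to within $k\sigma$ of the
pre-stimulation corrected baseline with $k = 1$ by default
(`noiseBandK`).

## The synthetic forward model

`simulateTrace()` renders

$$F_i = a (i+1)^b \left[1 + s\,r(t_i) + \textstyle\sum_k m_k(t_i)\right]
  + \epsilon_i$$

with genotype scale $s$ (1 for wild type; the mutant preset is 0.5,
matching evoked responses reduced to about half), the compartment
kernel $r(t)$, Poisson miniature events $m_k$ (instantaneous rise,
exponential decay with $\tau = 0.2$ s, truncated-normal amplitudes) and
Gaussian read noise (default SD 2% of the baseline $a$), optionally
replaced by Poisson shot noise. Acquisition defaults mirror the study
conditions: 10 frames/s for ER and mitochondrial recordings, 50
frames/s for cytosolic and postsynaptic ones; a 5 s pre-stimulation
baseline (the baseline length is our choice - the protocols do not state
one) followed by a 2 s stimulus train.

Kernel shapes per compartment:

* **cytosol / postsynaptic** - a saturating first-order rise during the
  train to `peakDff`, then exponential decay. The peak therefore sits
  exactly at the end of the train, where the derivative changes sign
  discontinuously. We initially used an alpha-function convolved with
  the train envelope, but that form is continuously differentiable at
  the peak, which puts the maximum on a noise-dominated plateau and
  makes "time to peak" ill-defined at frame resolution; recorded train
  responses peak at stimulus offset, which the piecewise form captures.
  The default rise constant (2 s) keeps summation visibly ramping over
  a 2 s train.
* **er** - a negative release dip of amplitude `dipAmp` at onset,
  decaying with `dipTau`, plus a slow positive uptake component (the
  same convolved difference-of-exponentials form with slow constants)
  peaking after the train.
* **mito** - fast saturating rise to `peakDff`, fast partial decline to
  `plateauFraction * peakDff`, then a slow return to baseline with
  `slowTau` (default 45 s, i.e. recovery on the better-than-40-seconds
  time scale).

`simulateMovie()` renders boutons as 2-D Gaussian spots whose per-frame
brightness follows independent trace simulations, with optional
integer-pixel whole-field drift and flat background; the ground truth
records per-frame shifts and each bouton's clean generating trace.
`simulateStaticPair()` renders a marker channel (dim tubule field plus
bright puncta) and a uniform reference channel inside an elliptical NMJ
mask. Puncta are sharp-edged discs rather than Gaussian spots so that
ground-truth pixel membership is unambiguous for classification
scoring, and the puncta level is independent of the tubule level so the
partition logic (whole NMJ vs puncta vs remainder) can be exercised
under tubule-intensity manipulations.

What the generator deliberately does not emulate: optics (no PSF or
bleed-through), muscle-contraction artifacts, sub-pixel drift, z-drift
or focus loss, and EMCCD gain statistics beyond optional Poisson shot
noise. Passing tests therefore demonstrate correctness of the
*computations* under the stated forward model, not robustness to every
artifact of real recordings.

`simulateCohort()` stacks the trace pipeline into a study design:
per-larva lognormal amplitude effects (SD 0.1 on the log scale),
a saturating frequency response $f/(f + f_{50})$ with $f_{50} = 20$ Hz
across the within-subject stimulation-frequency factor, and optional
multiplicative setup gains for batch-normalization tests.

## Miniature-event detection

The study counted minis manually; the detector automates the count and
is validated purely against synthetic ground truth. Candidates are
local maxima of the median-centred $\Delta F/F$ trace exceeding
`thresholdSigma` (default 3) robust SDs. The noise SD is the smaller of
a lower-tail MAD (negative excursions are event-free, since minis are
positive-going) and a first-difference MAD (stable even when events
blanket the trace). Acceptance requires: amplitude at least the
threshold above a 5-frame median local baseline taken just before the
rise; a rise of at least the threshold within two frames (minis rise
much faster than they decay); and corroboration on a 5-frame smoothed
copy at its own noise scale (real events persist across frames, single
noise samples do not). Peaks closer than `minSeparation` (default
0.2 s) are merged unless a half-threshold valley or a fresh
full-threshold one-frame rise separates them, so the separation acts as
a duplicate guard rather than a hard dead time. Event times are pinned
to the steepest-rise frame.

Two limits are inherent at 50 frames/s with 0.2 s event decay: events
falling within about one frame of each other cannot be counted
separately (about 4% of events at a 2 Hz rate), and on near-empty
traces the count floor is the detector's false-positive rate rather
than a relative bias. The test suite encodes both limits explicitly.

Frequency is reported as events per second over a 5 s scoring window by
default, with a 20 s counting interval for the maximum-amplitude
readout, both parameters.

## Static quantification

The Intermodes threshold iteratively smooths a 256-bin histogram
(running mean of 3 bins, the 8-bit convention of the source tool, cap
10,000 iterations) until at most two local maxima remain and returns
the midpoint of the two modes, mapped back to intensity units for image
input. Histograms whose two surviving peaks are not separated by a
pronounced valley (valley above half the lower peak) are rejected as
unimodal: without this check a pure-noise histogram frequently
stabilizes at two adjacent ripples and yields a meaningless split. When
thresholding fails inside `punctaPartition()`, a degenerate result with
zero puncta area is returned instead of an error so control images flow
through batch analyses.

Object sizes use 8-connectivity connected-component labelling
(implemented in the package; the installed image library's labelling is
4-connected, which splits diagonally touching objects). Ratiometric
intensities divide the marker mean by the reference mean over the same
pixels, making them invariant to any common gain.

## Preprocessing choices

Rolling-ball background estimation is grayscale morphological opening
with a disc structuring element, computed exactly via the decomposition
of the disc into horizontal chords with sliding minima/maxima
(O(radius x pixels x log radius) per frame). It never produces negative
output and never increases a pixel.

Registration is translation-only (the stabilizer it models is a
translation tool): integer shifts maximizing masked cross-correlation
with the first frame, computed by FFT, searched within `maxShift`
pixels. Vacated pixels are filled with the frame median - a neutral
fill that does not bias ROI means at edges. A frame whose best
alignment still correlates below `minCorrelation` (default 0.2) with
the reference raises an `uncorrectable_motion` error. The QC residual is
the mean absolute frame-to-reference difference inside the ROI
normalized by the ROI mean, with a default threshold of 0.2; the
original discards were made by eye, so the threshold is our
construction, and the residual is meaningful on unstimulated segments
(an evoked transient inflates it for reasons that have nothing to do
with motion). NMJs with fewer than three usable ROIs are discarded
entirely, matching the rule that one or two remaining
boutons/mitochondria are not analyzable.

## Statistics

The unit of replication is the larva: per-NMJ values are averaged into
one larval datapoint first. Route selection: Shapiro-Wilk on every
group at $\alpha = 0.05$; all groups normal leads to Student's t
(pooled variance; Welch available as an option) or, for the
genotype x frequency design, a mixed-effects repeated-measures analysis
(REML, per-larva random intercept, Satterthwaite degrees of freedom,
type-III tests), which tolerates unbalanced larva counts and missing
cells. Non-normal data go to Mann-Whitney U (exact when the smaller
group has at most 8 observations and no ties; otherwise the normal
approximation with tie correction) or Kruskal-Wallis. Levene's test is
computed and reported but does not drive routing, mirroring the stated
procedure; whether variance failures should trigger Welch corrections
is left as an explicit option rather than silent behaviour. Post-hoc:
Tukey HSD for all-pairs comparisons, Dunnett for planned
each-versus-control comparisons, both on estimated marginal means.

Three normalizations used for figures are provided: division by the
control-group mean (control maps to 1), per-batch division by the
batch's control mean (removes multiplicative setup gains so batches
pool), and the paired-timecourse normalization that scales both mean
traces by $100 / (\max - \min)$ of the control trace, pinning the
control range at exactly 100.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on simulated
data at desk scale: 200 noisy traces for feature-recovery statistics,
50 traces (about 500 events) for detector scoring, 100 null traces for
the false-positive rate, cohorts of 10-20 larvae per genotype across
four stimulation frequencies with 40-100 repetitions for the
mixed-design detection rate, and 15-frame movies for registration
checks. All randomness flows from explicit integer seeds through
per-stream sub-seeds; rerunning any simulation with the same
configuration is bit-identical.

## Known limitations

* The registration model has no rotation, scaling or sub-pixel
  component; it undoes exactly the class of drift the generator (and
  the modelled stabilizer) produces.
* The mini detector's operating characteristics are calibrated against
  the synthetic event shape (fast rise, 0.2 s decay); real indicator
  kinetics that rise over many frames would need the rise-sharpness
  criterion relaxed.
* The Intermodes rule assumes an intensity histogram that is bimodal
  after smoothing; heavily skewed unimodal images are rejected rather
  than force-split.
* Resting-fluorescence comparisons can be run on raw or
  background-subtracted movies; both paths are exposed because the
  choice is not fixed by the modelled procedure.
* The "responding area" of a postsynaptic field is taken to be the
  supplied NMJ ROI; no data-driven responding-area segmentation is
  attempted.
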
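---
title: "Quantifying movement coordination in dyadic conversations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying movement coordination in dyadic conversations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dyadcoord)
library(dplyr)
```

## The problem

When two people talk, their body movements are not independent: heads nod
in response to one another, postures drift in loose synchrony, and the
stability of this coordination is itself informative about the quality of
the interaction. Video mediation perturbs the coupling channel — the
partner is seen with a transmission latency and its variability (jitter) —
and the question is how to quantify the effect on coordination from
nothing more than pose-tracked video.

`dyadcoord` implements that measurement chain. The raw material is a
pose-keypoint time series per participant (OpenPose-style JSON or a flat
CSV of `frame, keypoint, x, y, confidence`) at a known frame rate,
typically 20 frames per second. Two keypoints carry the analysis: the nose
tip **P0**, a proxy for head movement, and the mid-shoulder/neck point
**P1**, a torso reference. Everything downstream is built from these two.

## Preprocessing

Pose estimators lose keypoints. A recording is *excluded* when the missing
fraction of either required keypoint exceeds a configurable threshold
(default 0.10: recordings with a few percent missing are clearly usable,
recordings missing double-digit percentages of their frames are not, and
the default sits between the two regimes). Surviving gaps are filled by
linear interpolation (nearest-value extension at the edges), and a running
median filter with window 5 removes single-frame estimator glitches. Both
edge rules — nearest-value extension and a truncated median window — were
chosen to preserve series length; with a 5-frame window at 20 fps any
reasonable edge policy affects only a tenth of a second per end.

The *scale* of a person's movement is the mean Euclidean P0–P1 distance,
computed **after** cleaning so that a single wild estimate cannot corrupt
the normaliser. All mobility statistics are expressed relative to this
scale, which makes them invariant to camera distance and resolution.

## Individual mobility

Three unitless statistics summarise one participant in one condition:

* horizontal mobility $= \mathrm{SD}(x_{P0}) / \overline{\|P0-P1\|}$ —
  overall movement;
* vertical mobility $= \mathrm{SD}(y_{P0}) / \overline{\|P0-P1\|}$ —
  dominated by nodding gestures;
* their ratio, overall movement relative to nodding (undefined and
  reported `NA` when the vertical SD is zero).

The SD is the sample SD by default (`sd_mode = "population"` is
available); the difference is a factor $\sqrt{n/(n-1)}$, negligible at
thousands of frames but made explicit rather than silent.

## From positions to direction states

Coordination is defined on the *direction* of head movement, not its
amplitude: each frame-to-frame displacement of P0 is normalised to unit
length. Frames with exactly zero displacement map to the zero vector and
are flagged; stillness is treated as its own state rather than inheriting
the previous direction. A zero-phase (forward–backward) Butterworth
low-pass filter (order 2, cutoff 2 Hz by default) then smooths the two
components independently. Zero-phase filtering matters here: a causal
filter would lag each partner's signal, biasing the apparent lead–lag
structure between them. The components are *not* re-normalised after
smoothing — a smoothed direction with norm below 1 encodes locally
inconsistent motion, which is information, not error. Because
`signal::filtfilt` applies no edge padding, the filter runs on a
mirror-extended copy of the series and the extension is discarded; the
startup transient therefore falls outside the data.

Each component is then embedded by time delay: row $t$ of the embedding is
$(s_t, s_{t+\tau}, \dots, s_{t+(m-1)\tau})$ with delay $\tau = 7$ frames
and dimension $m = 4$ per coordinate by default, and the x and y
embeddings are concatenated into 8-column state vectors. The delay and
dimension defaults are global pipeline constants; for new data they can be
re-derived with `ami_delay()` (first local minimum of the average mutual
information, equal-width histogram estimator with 16 bins) and
`fnn_dimension()` (Kennel false-nearest-neighbour criterion, `rtol = 10`,
`atol = 2`, acceptance below 1%). Two numerical details are worth noting:
the AMI first-minimum rule is applied to the raw estimated curve, so on
short noisy series the returned lag inherits estimator wobble (use a few
thousand frames when selecting parameters); and exactly periodic series
produce duplicate embedded states equal up to floating-point error, which
a naive distance-ratio test misreads as false neighbours —
`fnn_dimension()` treats distances below $10^{-8}\,\mathrm{SD}$ as
coincident.

## Cross-recurrence at a fixed recurrence rate

The cross-recurrence matrix marks every pair $(i, j)$ where participant
A's state at time $i$ lies within $\varepsilon$ of participant B's state
at time $j$ (Euclidean distance). Rather than fixing $\varepsilon$,
the pipeline fixes the *recurrence rate*: $\varepsilon$ is the empirical
10% quantile of all pairwise distances, per matrix, so that exactly 10% of
entries are recurrent up to ties. This normalises the statistics across
dyads and conditions whose raw distance scales differ — at the price that
the recurrence rate itself is a control, never an outcome. For continuous
distances the achieved rate equals the target exactly; under ties it can
exceed it by at most the probability mass of the tied value, and a matrix
whose distances are all identical is rejected as degenerate.

No Theiler window is applied: in *cross*-recurrence the two series come
from different people, and the main diagonal (simultaneous movement) is
the most interesting region, not an artifact.

From the binary matrix, maximal runs of recurrent points are counted along
every diagonal (all offsets) and down every column, keeping runs of at
least `lmin` (diagonal) and `vmin` (vertical) points — both default 10
frames, i.e. half a second at 20 fps. With raw counts $c(l)$:

$$\mathrm{DET} = \frac{\sum_{l \ge l_{min}} l\,c(l)}{\sum_{l \ge 1} l\,c(l)},
\qquad
L = \frac{\sum_{l \ge l_{min}} l\,c(l)}{\sum_{l \ge l_{min}} c(l)},
\qquad
\mathrm{ENTR} = -\sum_{l \ge l_{min}} p(l) \ln p(l)$$

with $p(l)$ normalised over the counted lines, plus $L_{max}$, and the
vertical-line analogues LAM and TT. Determinism (DET) is the fraction of
recurrent points in sustained coordination episodes; L and Lmax are the
mean and maximum episode length in frames; ENTR (in nats) is the
complexity of the episode-length distribution; LAM and TT describe
episodes where one partner's state persists. Statistics over an empty set
of counted lines are 0 (DET, LAM, Lmax, ENTR) or `NA` (L, TT). Border
runs are counted at their observed length. Entropy normalisation over
counted lines (rather than over all lines) was chosen because the
statistic is meant to describe the distribution of the episodes actually
counted; either convention is internally consistent, but they differ, so
the choice is stated.

`diagonal_rr_profile()` is a lag diagnostic on top of the same matrix: the
recurrence rate per diagonal offset. A transmission latency between the
partners moves recurrence mass off the main diagonal, and the profile's
peak recovers the imposed lag.

```{r crqa-example}
cfg <- scenario_preset("remote", duration_s = 30, coupling = 0.9, seed = 42)
pair <- simulate_dyad(cfg, dyad_id = "demo", condition = "remote_mirror")
emb <- lapply(pair, function(tr) {
  embed_direction(lowpass(direction_field(preprocess_track(tr))))
})
rm <- recurrence_matrix(emb[[1]], emb[[2]])
rm
rqa_stats(rm) |> select(DET:TT)
```

## Condition contrasts

The study design behind the pipeline is a 2 × 2 within-dyad design:
remote vs live conversation, with vs without a self-view ("mirror").
`build_table()` dummy-codes the condition label into `remote` and
`no_mirror` indicators; `fit_mixed_model()` fits

$$y \sim 1 + \mathrm{remote} + \mathrm{no\_mirror} + (1 \mid \mathrm{unit})$$

by maximum likelihood (`lme4`), with the unit being the participant for
individual-level mobility and the dyad for dyad-level recurrence
statistics. ML rather than REML is used so the reported Wald $z$ and
normal $p$ values are the conventional pairing; a singular fit (zero
random-intercept variance) is legal, flagged, and reported with
$\sigma = 0$. No multiple-testing correction is applied. The paired
Student's $t$ between the two remote conditions uses $df = n - 1$ on the
within-unit differences; identical inputs return $t = 0$ rather than
erroring, while a nonzero constant difference has no estimable variance
and errors.

## The synthetic dyad generator

There is no bundled recording corpus; `simulate_dyad()` generates the
dyadic structure the pipeline assumes, end to end through the same
ingestion path as real data (`write_track()` / `read_keypoints()`):

* **Posture sway** — band-limited Gaussian drift per axis (white noise
  through a second-order low-pass at `sway_cutoff_hz`, rescaled to SD
  `sway_sd` = 5 px): stationary and mean-reverting, like the slow
  repositioning of a seated speaker.
* **Nods** — vertical damped-sinusoid bursts (frequency `nod_freq`,
  about three visible cycles, amplitude `nod_amplitude` ×
  `exaggeration`) arriving as a Poisson process at `nod_rate` per second.
  Overlapping nods superpose additively.
* **Coupling** — with probability `coupling`, each spontaneous nod of one
  partner triggers a response nod in the other after
  `response_delay_frames` plus Gaussian jitter (`jitter_frames`);
  responses do not chain, so the event process stays stable.
* **Missing data** — `inject_missing()` knocks out whole frames
  independently at a configurable rate, emulating detection failures.

Two presets encode the conditions of interest: `"face_to_face"` (response
delay 2 frames, no jitter, natural amplitude) and `"remote"` (delay 8
frames, jitter SD 2 frames, nods exaggerated ×1.3 — camera-aware speakers
amplify their gestures).

Two generator time scales are deliberately tied to the analysis window.
The minimum counted line is 0.5 s, so *detectable* coordination episodes
must last at least that long: the default nod frequency is 0.8 Hz, whose
half-cycle (0.625 s) keeps a pair of phase-locked nods above the counting
threshold. Conversely the idiosyncratic sway must *not* produce long
chance lines: its default cutoff of 1.5 Hz makes the sway direction
decorrelate within a few frames, below the threshold. An early version of
the generator used an Ornstein–Uhlenbeck *position* process instead;
its increments are nearly white, the normalised step directions were
noise, and the zero-phase filter collapsed them into a tight cluster of
near-zero-norm states that absorbed the entire fixed 10% recurrence
budget — chance recurrence then dominated genuine nod coordination. The
band-limited sway keeps the direction field coherent at unit scale and
restores the property the generator exists to provide: determinism that
grows with the coupling probability.

What the generator does **not** emulate: speech and turn-taking, gaze,
posture mirroring, hand gestures, pixel quantisation of the pose
estimator, and any within-conversation non-stationarity (fatigue, topic
changes). Tests passing on synthetic data therefore certify the
measurement chain — not that real conversations behave like the
generator.

## Problem sizes and determinism

The package's own test battery runs the generator at 15–60 s per
recording (300–1200 frames, recurrence matrices up to roughly
1200 × 1200); dose-response and latency-recovery properties average over
20–40 seeded replicates, and mixed-model recovery over 50 simulated
design tables. These sizes give stable Monte-Carlo averages (the
measured latency-recovery rate, for instance, is ~82% against a 75%
requirement) while keeping a full run in the order of a minute. Every
stochastic step takes an explicit seed; `simulate_dyad()` saves and
restores the global RNG state, so identical configurations give
byte-identical tracks, and `run_pipeline()` derives per-recording
sub-seeds from the single configured seed.

## Known limitations

* The fixed-RR threshold makes recurrence statistics comparable across
  matrices but discards overall proximity information; RR itself must
  never be interpreted as an outcome.
* Line counting treats the matrix border naively (runs truncated by the
  border are counted at observed length), which slightly biases L and
  Lmax downward for short recordings.
* The AMI/FNN parameter-selection heuristics are estimator-noisy on short
  series and are meant for parameter *selection* on long recordings, not
  as per-recording statistics.
* Mobility SDs assume a stationary seated posture; a participant who
  walks away mid-recording will inflate them meaninglessly.
* The paired $t$ helper assumes exchangeable pairs; it is the caller's
  job to pair observations by participant.
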
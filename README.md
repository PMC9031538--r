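# dyadcoord

Movement-coordination analysis for dyadic conversations, from pose-keypoint
time series to cross-recurrence statistics and condition contrasts.

## What it does

Two people in conversation coordinate their body movements — heads nod in
response to one another, postures drift in loose synchrony — and video
mediation (latency, jitter, the sight of one's own image) perturbs that
coupling. `dyadcoord` measures it. Starting from per-frame pose keypoints
(OpenPose-style JSON or flat CSV; nose tip P0 and mid-shoulder point P1 at
a known frame rate), the package:

1. **cleans** each recording — exclusion when too many frames are missing,
   linear interpolation of gaps, running median filtering — and normalises
   by each person's mean P0–P1 distance;
2. computes **individual mobility**: horizontal and vertical SD of the
   head position divided by the body scale, and their ratio (vertical
   mobility tracks nodding gestures);
3. quantifies **interpersonal coordination** with cross-recurrence
   quantification analysis (cRQA) of head-movement *direction*: unit
   frame-to-frame displacement vectors, zero-phase Butterworth smoothing,
   time-delay embedding (delay 7, dimension 4 per coordinate, x/y
   concatenated into 8-dimensional states), and a recurrence matrix
   thresholded per matrix to a fixed 10% recurrence rate. From maximal
   diagonal/vertical line structures (minimum length 10 frames = 0.5 s) it
   reports

   DET = Σ<sub>l≥lmin</sub> l·c(l) / Σ<sub>l≥1</sub> l·c(l),  
   L = Σ<sub>l≥lmin</sub> l·c(l) / Σ<sub>l≥lmin</sub> c(l),  
   ENTR = −Σ p(l) ln p(l),  Lmax,  and the vertical-line analogues LAM and TT;

4. fits the **condition contrasts** `y ~ 1 + remote + no_mirror +
   (1 | unit)` by maximum likelihood (`lme4`), with Wald z/p reporting,
   plus a paired Student's t between the two remote conditions;
5. **simulates** coupled dyads (posture sway, Poisson nod bursts,
   probabilistic response nods with transmission latency and jitter,
   gesture exaggeration, missing frames) so the whole chain is testable
   without video data.

Everything is tibble-in / tibble-out and pipe-friendly; fitted contrasts
have `tidy()`/`glance()` methods and the result objects have `autoplot()`
methods.

## Worked example

Simulate one strongly coupled "remote" dyad (30 s at 20 fps, response
latency 8 frames, jitter 2, exaggerated nods) and run the chain by hand:

```r
library(dyadcoord)
library(dplyr)

cfg <- scenario_preset("remote", duration_s = 30, coupling = 0.9, seed = 42)
pair <- simulate_dyad(cfg, dyad_id = "demo", condition = "remote_mirror")

mobility(preprocess_track(pair$a))
#> # A tibble: 1 × 6
#>   dyad_id participant_id condition     horizontal vertical hv_ratio
#>   <chr>   <chr>          <chr>              <dbl>    <dbl>    <dbl>
#> 1 demo    A              remote_mirror     0.0628    0.105    0.599

emb <- lapply(pair, function(tr) {
  embed_direction(lowpass(direction_field(preprocess_track(tr))))
})
rm <- recurrence_matrix(emb[[1]], emb[[2]])
rm
#> <recurrence_matrix> 578 x 578, rr = 0.1000 (target 0.1), epsilon = 1.582682

rqa_stats(rm) |> select(DET:TT)
#> # A tibble: 1 × 6
#>     DET  ENTR     L  Lmax     LAM    TT
#>   <dbl> <dbl> <dbl> <int>   <dbl> <dbl>
#> 1 0.297  3.05  17.8    61 0.00452  10.1
```

Vertical mobility (0.105) exceeds horizontal (0.063): this dyad nods more
than it shifts, as the exaggerated remote preset should produce. About 30%
of recurrent points lie in sustained (≥ 0.5 s) coordination episodes
(DET), lasting 17.8 frames on average and up to 61 frames (~3 s). The lag
structure of the coupling is visible in the diagonal profile:

```r
prof <- diagonal_rr_profile(rm, 15)
prof$offset[which.max(prof$rr)]
#> [1] 7
```

— close to the imposed 8-frame transmission latency (the peak is
symmetric in sign because both partners respond to each other).

A full simulated study — 6 dyads × 4 conditions (remote/live ×
mirror/no-mirror), preprocessing, mobility, cRQA and mixed models — is one
call:

```r
res <- run_pipeline(pipeline_config(list(
  input = list(simulate = list(n_dyads = 6, duration_s = 60)),
  seed = 1)))
tidy(res$models$rqa_DET)
#> # A tibble: 3 × 5
#>   term        estimate std_error      z         p
#>   <chr>          <dbl>     <dbl>  <dbl>     <dbl>
#> 1 (Intercept)  0.239     0.00923 25.9   7.26e-148
#> 2 remote       0.0500    0.0104   4.82  1.45e-  6
#> 3 no_mirror   -0.00860   0.0104  -0.828 4.08e-  1
```

(The generator's two presets differ in latency, jitter and nod
exaggeration; the mirror manipulation is not modelled, so `no_mirror`
effects in simulated studies are null by construction.) With an output
directory, `run_pipeline(cfg, out_dir = "out")` also writes
`mobility.csv`, `rqa.csv`, per-model CSVs, a run log and a provenance
sidecar (config hash + seed) that fully determines a rerun.

See `vignette("movement-coordination")` for the model, parameter and
design discussion.

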
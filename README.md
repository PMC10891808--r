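# pentrack

Multi-object tracking for livestock-pen video, built for the failure modes
that matter in a pen: **miss detections**, **occlusion by static objects**
(a camera stand), and **occlusion by other animals**. The package is
detector-agnostic — it consumes per-frame bounding-box streams in
MOTChallenge CSV format and never touches pixels.

At its core is a customized tracking algorithm (CTA): an IOU tracker with an
n-frame history buffer and three re-identification mechanisms. Base
association is Hungarian assignment on cost `1 - IOU(track, detection)`.
When a cow goes undetected, its identity is recovered by, in order:

1. re-attachment of unmatched detections to stored boxes of unseen IDs at
   `IOU >= 0.5` (miss detection);
2. a count gate — when previously tracked IDs `P_ID` exceed the detection
   count `D_ID - 1`, absent IDs become miss records; a freshly minted track
   overlapping a record's box is deleted and the missing ID reassigned
   (object occlusion);
3. an occlusion list — an ID that vanished while overlapping another track
   at `IOU >= 0.25` reclaims, at the same threshold, the first new track
   that appears over the occlusion site (cow-cow occlusion).

Around the CTA sit seven reference trackers behind one interface (SORT,
a Deep SORT association core with a pluggable appearance hook, a modified
Deep SORT re-identification rule, ByteTrack-style two-stage association,
centroid, centroid + Kalman, plain IOU), detection-stream cleanup (box-area
band `[5000, 30000]` px² and region-of-interest masking), MOT16-style
evaluation (`MOTA = 1 − (ΣFN + ΣFP + ΣIDS)/ΣGT`, detection accuracy
`(TP + TN)/(TP + FP + TN + FN)`), and a seeded synthetic pen-scenario
generator that reproduces all three failure modes without video.

## Worked example

Simulate a degraded five-minute stream (8 cows, 10 fps, 2% dropout, both
occlusion types), clean it with the area filter, track it with the CTA and
with SORT, and score both against the simulator's ground truth:

```r
library(pentrack)

sc   <- simulate_scenario(sim_config(n_cows = 8, n_frames = 3000, seed = 1))
dets <- area_noise_filter(sc$dets)          # drops all non-cow-sized boxes

cta  <- track_stream(tracker("cta"),  dets, n_frames = 3000)
sort <- track_stream(tracker("sort"), dets, n_frames = 3000)

s1 <- score_stream(cta,  sc$gt)
s2 <- score_stream(sort, sc$gt)
cat("CTA  MOTA:", round2(s1$mota), " distinct IDs:", length(unique(cta$id)), "\n")
cat("SORT MOTA:", round2(s2$mota), " distinct IDs:", length(unique(sort$id)), "\n")
```

```
CTA  MOTA: 99.95  distinct IDs: 8
SORT MOTA: 93.25  distinct IDs: 26
```

Eight cows were simulated, so the CTA's 8 distinct IDs mean zero identity
inflation across every dropout and occlusion in the stream
(`id_increment_count(cta, 8)` is 0), while SORT minted 18 superfluous IDs;
the MOTA gap comes from the frames SORT loses around each gap. The three
scripted presets isolate one failure mode each and make the contrast
minimal:

```r
sc14 <- simulate_scenario(preset("fig14_miss"))
id_increment_count(track_stream(tracker("cta"), sc14$dets, 30), 4)   # 0
id_increment_count(track_stream(tracker("iou"), sc14$dets, 30), 4)   # 1
```

## Command-line use

```sh
inst/scripts/pentrack simulate --preset fig16_object_occlusion --seed 7 --out scenario/
inst/scripts/pentrack track    --tracker cta --dets scenario/det.txt --out result.txt
inst/scripts/pentrack evaluate --pred result.txt --gt scenario/gt.txt
inst/scripts/pentrack compare  --dets scenario/det.txt --gt scenario/gt.txt
```

`compare` runs all eight trackers on one stream and prints a per-tracker
GT/FP/FN/IDS/MOTA summary table.

See `vignettes/pen-tracking-methods.Rmd` for the algorithm details, the
synthetic-pen motion model, threshold rationale, and known limitations.
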
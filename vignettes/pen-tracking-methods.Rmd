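---
title: "Tracking cattle through miss detections and occlusions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking cattle through miss detections and occlusions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentrack)
```

## The problem

A fixed overhead camera watches a calving pen holding a small herd (four to
eight cows) for hours at a time. A segmentation detector proposes per-frame
bounding boxes; the tracking task is to attach a persistent identity to each
cow so that behavior (and ultimately calving onset) can be read off the
trajectories. Three things routinely break naive trackers in this setting:

* **miss detections** — a cow present in the pen yields no box for a frame
  or a few frames;
* **occlusion by static objects** — a cow walks behind the camera stand and
  its detection disappears for several frames, reappearing displaced;
* **occlusion by other cows** — the smaller of two overlapping cows is
  swallowed by the larger one's box and re-emerges somewhere nearby.

A tracker that associates boxes frame-to-frame by intersection-over-union
(IOU) alone mints a fresh track ID at every such gap. Because the herd is
fixed, every superfluous ID is an error a human would never make; the count
of distinct IDs beyond the herd size (`id_increment_count()`) is therefore
the package's headline failure measure, alongside MOTA.

## The customized tracking algorithm

The CTA (`tracker("cta")`) is an IOU tracker with an n-frame memory and
three resolution mechanisms applied, in order, after base Hungarian
association on `1 - IOU`:

1. **Miss-detection re-identification.** Every frame, each track's last
   detection-backed box is folded into a history buffer. Under the default
   `block_refresh` mode the buffer accumulates for `n_history = 20` frames,
   then is cleared and reseeded with the current frame. A detection that
   base association leaves unmatched is compared against the stored boxes
   of currently unseen IDs; the best pair at IOU >= `reid_iou` (default
   0.5) reattaches the stored ID instead of minting a new one.
2. **Object-occlusion resolution.** When the number of previously tracked
   IDs exceeds the detection count minus one, each absent ID becomes a miss
   record carrying its last box and miss duration. If a fresh track is
   minted while miss records are outstanding, the IOU between the fresh box
   and each record is recalculated; the fresh track is deleted and the
   best-overlapping record's ID reassigned. Any overlap qualifies, because
   in a closed pen a brand-new track appearing on top of a recorded miss is
   almost surely the missing animal; a track with no overlap to any record
   keeps its fresh ID, which is how a genuinely new animal entering the pen
   is still admitted.
3. **Cow-occlusion resolution.** An ID that vanishes while overlapping
   another current track at IOU >= `occlusion_iou` enters an occlusion
   list with its last box. A fresh track overlapping a list entry at
   `occlusion_iou` or above takes over that entry's ID (highest IOU first).

The three mechanisms are deliberately disjoint, which both keeps the
algorithm predictable and makes ablation meaningful
(`cta.disable_{miss,object_occ,cow_occ}`): mechanism 2 skips pairs that the
history buffer could still resolve at `reid_iou` — those belong to
mechanism 1 — and skips IDs on the occlusion list, which belong to
mechanism 3. Without this scoping, disabling one mechanism would be
silently compensated by another and the per-mechanism ablation contrast
(each flag strictly increases the ID count on its own scenario family)
would be unobservable.

Missing IDs are *coasted* while their miss record lives: the stored box is
re-emitted flagged `status = "lost"`, so the output stream stays continuous
through short gaps. This mirrors the algorithm's bookkeeping, which
reinserts a missing ID into the current list while it is undetected, and it
is what downstream evaluation sees as continued coverage. Records and
occlusion entries expire after `n_history` frames: a cow hidden longer than
the window is genuinely lost and will return under a new identity — the
known limitation of the approach, inherited deliberately (long mutual
overlaps are not resolvable from boxes alone).

### Threshold choices

* `reid_iou = 0.5`: the community-standard IOU match level; a re-detected
  stationary cow overwhelmingly clears it, a displaced one fails it and
  falls through to mechanisms 2-3.
* `occlusion_iou = 0.25`: deliberately looser than `reid_iou`. A cow
  emerging from behind another is necessarily displaced from where it
  vanished; demanding 0.5 against the stored occlusion box would reject
  nearly every true re-emergence and the mechanism would never fire. 0.25
  still demands substantial spatial coherence with the occlusion site.
* `n_history = 20` (two seconds at 10 fps): the flow-chart refresh
  interval; 8 is the documented alternative and both are config presets.
  Ties anywhere (equal IOU, equal cost) resolve toward the lower track ID,
  so every run is deterministic.

## The seven comparison trackers

The same per-frame contract (`tracker_step()`) drives seven reference
algorithms: plain IOU association (`iou`, memory-less, `max_age = 0` by
default); greedy nearest-centroid matching (`centroid`); the same with a
constant-velocity Kalman prediction (`centroid_kalman`); SORT (`sort`:
7-state box Kalman filter — center, area, aspect ratio held constant, plus
velocities — Hungarian IOU association, `max_age = 1`, `min_hits = 3`, the
canonical settings); a Deep-SORT-style association core (`deepsort`:
age-ordered matching cascade, `max_age = 30`, with a pluggable appearance
hook — no trained cow embedding exists, so the hook defaults to off and the
cascade runs on IOU; tests inject a ground-truth oracle to exercise it);
the modified re-identification variant (`modified_deepsort`: on a detection
frame loss, stored boxes overlapping pairwise at IOU >= 0.9 keep their
boxes and IDs into the next step); and a two-stage score-split associator
(`bytetrack`: high-score detections match first, low-score ones may extend
but never spawn tracks).

Noise covariances for the Kalman filters follow the community SORT
settings; none are stated in the source material, and all are
config-exposed. The aspect-ratio-constant state layout intentionally
reproduces the known width-estimation weakness of that filter under shape
change.

## Evaluation

`score_stream()` implements MOT16-style scoring: per frame, Hungarian
matching of predictions to ground truth on `1 - IOU` rejected below 0.5
IOU (the MOT16 convention; the match threshold is an argument), unmatched
ground truth counting as FN, unmatched predictions as FP, and an identity
switch whenever a ground-truth identity's matched track ID differs from its
most recently matched one. `mota()` and `detection_accuracy()` are the
standard closed forms, reported as percentages with half-up two-decimal
rounding for display (`round2()`); raw values are kept internally.

## The synthetic pen

`simulate_scenario()` emulates the recording setting rather than the
pixels: a 2048 x 2048 overhead view, pen region (339, 261, 1330, 1592), 10
frames per second, cow boxes with areas inside [5000, 30000] px^2 (sampled
with margin so +/-2 px corner jitter cannot leave the band), spurious
non-cow detections with areas outside the band, per-cow detection dropout
(default 2% per frame), a 150 x 150 px camera-stand zone at pen center, and
cow-cow suppression of the smaller box when ground-truth IOU exceeds 0.3.

The motion model encodes how pen cattle actually move, because the error
structure of every tracker depends on it:

* **rest/walk alternation** — cows rest (mean 80 frames) and walk short
  bouts (mean 20 frames) at up to 5 px/frame, so most dropout gaps occur on
  stationary animals;
* **site fidelity** — waypoints stay within a 350 px home range, with one
  in five bouts an excursion across the pen (feeding/watering); excursions
  are what carry cows past the camera stand and through other cows' areas,
  so both occlusion types occur but remain transient;
* **solid bodies** — a step never pushes two boxes past 0.45 IOU; overhead
  views show partial occlusion, not interpenetration, and cows steer around
  or wait for each other. Bedding sites keep the whole box clear of the
  stand zone and off herd mates;
* **intermittent suppression** — an occluded cow's detection drops with
  per-frame probability 0.75, giving geometric gap lengths (mean 4 frames,
  hard-capped at `max_gap = 12`), the few-frame gap regime of the scripted
  scenarios. Setting the probability to 1 recovers deterministic
  suppression.

Every suppression and every noise detection is logged in the event log, so
tests can assert exact accounting. One seeded generator drives a scenario;
the global RNG state is saved and restored around it.

The three `preset()` scenarios are scripted, not random: a 2-frame in-place
miss (resolved by mechanism 1); a 6-frame suppression at the stand zone
spanning frames 16-21, which straddles the 20-frame buffer refresh at frame
21 so only mechanism 2 can resolve it; and a double cow-occlusion with
displaced re-emergence at IOU about 0.43 against the vanish box — below
`reid_iou`, above `occlusion_iou` — so only mechanism 3 resolves it. The
presets are simultaneously the documentation of which mechanism owns which
failure mode and the fixtures for the ablation tests.

### What passing tests do and do not show

The simulator produces boxes, not images: it cannot show that a real
detector's errors look like independent dropouts, nor that real cow motion
matches the rest/walk model, nor anything about appearance features. What
it does show is conditional: *given* detection streams whose gaps stay
within the history window and whose re-appearances are spatially coherent,
the CTA maintains the herd's identities where memory-less trackers mint
new ones. The long-stream check runs 8 cows for 3,000 frames (five minutes
at 10 fps — a deliberately desk-sized stand-in for multi-hour recordings,
with problem sizes chosen so the whole suite runs in minutes), asserting
CTA MOTA at or above 99% and a strict ordering over SORT on the identical
stream in both MOTA and distinct-ID count. Absolute accuracies from the
original farm recordings are not reproducible without those videos and are
out of scope; the worked-example tables verify the metric arithmetic
instead.

## Numerical and degenerate-input choices

* Boxes are half-open `(x1, y1, x2, y2)` floats; MOT files use
  `(left, top, width, height)` and the conversion is exact. Internal frame
  indices are 1-based, matching both R and the MOT file convention.
* The Hungarian solver is the O(n^3) shortest-augmenting-path formulation,
  validated against factorial enumeration up to 7 x 7; rectangular inputs
  solve on the transposed orientation, 0 x k inputs return all-unmatched.
* Kalman covariance is re-symmetrized after every update; a non-positive
  predicted box scale freezes the scale velocity, and recovered boxes clamp
  area to >= 1 px^2.
* Area-filter boundaries are inclusive (`th1 <= area <= th2`), with an
  `inclusive = FALSE` switch.
* Zero-detection frames are valid steps everywhere and drive aging logic.

## Known limitations

Identity recovery is geometric only; two cows swapping places while both
are suppressed will swap identities, and occlusions outlasting the history
window lose the animal. The appearance hook exists for detectors that can
supply embeddings, but no embedding ships with the package. The simulator's
noise model (uniform spurious boxes outside the cow-area band) is a
caricature of people and vehicles adequate for testing the area filter,
nothing more.
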
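---
title: "Tracking multiple unmarked mice: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking multiple unmarked mice: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind `mousetrackr`, the
parameters that matter, what the synthetic generator does and does not
emulate, and the design decisions taken where the problem left the design
open. It states no empirical result beyond what the package's test suite
and `scripts/acceptance.R` themselves compute.

## The tracking-by-detection model

The package assumes a fixed overhead camera over a square open-field
arena (default 32 cm side), recording a small group (1–4) of dark mice on
a bright floor at 60 Hz. Tracking is decomposed into per-frame
*detection* (which pixels belong to an animal) and frame-to-frame
*association* (which detection is which animal). Detection is treated as
a pluggable black box: the bundled detector is a threshold segmenter, and
externally computed instance masks — e.g. from a neural instance
segmentation model — can be supplied as VIA 2.x polygon JSON and drive
exactly the same association machinery. This keeps everything downstream
of detection testable without any GPU model.

### Detection (bundled segmenter)

Foreground is `intensity < threshold` (fixed cut at 160 of 255 by
default, or Otsu), labelled with 8-connected components — 4-connectivity
would split thin diagonal limb configurations — and filtered to
`[min_area_px, max_area_px]` (defaults 500 and unbounded, sized for
~8 cm animals at 20 px/cm). Two animals in physical contact merge into
one blob; the pipeline deliberately does not split merged blobs, so a
contact frame simply yields fewer detections and is handled downstream
as a miss. Detected contours can be post-processed for display and
annotation exchange: disk dilation by `expand_px = 5` px and
Ramer–Douglas–Peucker simplification at `rdp_epsilon = 1.5` px. The
simplified polygon is cosmetic; the pixel mask, not the polygon, feeds
the fingerprint stage, so simplification can never perturb identity
assignment.

The closed-contour RDP adaptation splits the ring at its two mutually
farthest vertices and simplifies each open chain by the classic
recursion (keep the interior vertex farthest from the endpoint chord iff
its perpendicular distance exceeds ε). Simplification operates on vertex
*indices*, so output vertices always appear in input order; exact ties in
the farthest-vertex search keep the first candidate in scan order; a
fully collinear contour degenerates to its two extreme vertices and is
flagged. With the strict `> ε` recursion, ε = 0 preserves any vertex not
exactly collinear with its chord, and vertex count is non-increasing
in ε.

### Appearance fingerprints

Each detection is summarized by a correlogram: a joint histogram over
(pixel-pair distance, pixel-pair intensity sum). The mask is first
*buffered* — `dilation_iters = 10` iterations of a 3×3 dilation, then a
7×7 Gaussian blur of the mask thresholded at > 0 — so the crop keeps a
ring of context around the animal; the blur-of-mask formulation grows
support by the kernel half-width and keeps the image intensities
themselves untouched. The crop is downscaled by integer block averaging
(`downscale = 4`) over included pixels only, and converted to grayscale
(luma weights 0.299/0.587/0.114) if needed. Then every unordered pair
{p, q} of included pixels contributes one count at bin

    ( min(⌊d / max_dist_px · n_dist_bins⌋, n_dist_bins − 1),
      ⌊(I(p) + I(q)) / 511 · n_sum_bins⌋ )

with 32 × 32 bins, a distance domain of [0, 64] downscaled pixels with an
overflow bin, and an intensity-sum domain of [0, 510]. Self-pairs are
excluded: they carry no relational information and would add a d = 0
spike proportional to area. Counts are normalized to unit mass, making
patches of different sizes comparable — without normalization the mean
absolute histogram difference is dominated by patch size and cross-frame
comparison breaks. Histogram binning and normalization are exposed as
configuration because reasonable alternatives exist; the defaults were
fixed once from the geometry above (quarter-scale crops of ~160 px
animals have pair distances well inside 64) and are exercised as-is by
every test. Distances between pixel pairs are invariant to translation
and to lattice rotations by 90°, which the test suite verifies exactly.

Two fingerprints are compared by the mean absolute bin difference —
symmetric, zero iff equal, and at most 2/(32·32) for normalized inputs.
The pair enumeration is O(k²) in the included-pixel count; the inner loop
is compiled (Rcpp), and an optional `max_pairs` cap takes a seeded
uniform subsample of pairs for very large regions (off by default:
quarter-scale crops of mouse-sized regions enumerate fully in
milliseconds).

### Identity assignment

IDs are seeded on the first frame with at least `n_mice` detections (the
n largest by area, ordered by centroid y then x; earlier frames are
logged and skipped). Every later frame builds the full dissimilarity
matrix between each ID's reference fingerprint and each detection, sorts
all (ID, detection) pairs ascending, and accepts pairs greedily while
both sides are free, stopping at `min(n_mice, n_detections)`. This
sorted-list greedy rule is implemented exactly as specified — it is *not*
the optimal-sum bipartite assignment, and the tests pin a matrix where
the two differ. Exact dissimilarity ties break by lowest ID then lowest
detection index, for determinism. Matched IDs update their reference
fingerprint to the new detection (adjacent-frame comparison, not a
running average — appearance drifts with pose, and the previous frame is
the best-matched reference); unmatched IDs keep their last real
fingerprint until they reappear. Surplus detections are ignored purely by
losing the greedy competition; there is no motion model, no trajectory
smoothing, and no occlusion reasoning by design.

### Correction

Correction runs in the order fill → warn → (human review) → swap:

* **fill_misses.** A missing (frame, ID) slot is filled by copying the
  ID's most recent record (coordinates and area held constant — a causal
  carry-forward, not interpolation, matching the idea of re-using the
  previous prediction). Gaps longer than `max_gap` (default 60 frames,
  i.e. 1 s at 60 Hz) are *structural*, not sporadic: they are reported
  and left open rather than papered over.
* **detect_warnings.** On the filled table, for each consecutive frame
  pair and each ID i, a warning fires iff some other ID's position at
  N+1 is strictly closer to i's position at N than i's own new position.
  Strictness matters: an exact tie is geometrically ambiguous, and
  over-warning is the costlier failure for a human-in-the-loop step. The
  per-ID reading of "shortest among all ID pairs" is adopted (warn i when
  some j beats i for i's own previous position); on the canonical
  two-animal exchange both readings coincide. With one animal the rule is
  vacuous. Warnings are advisory only — most flag fast motion rather
  than real switches, so auto-swapping on a warning would corrupt tracks.
* **apply_swaps.** A directive `(frame, id_a, id_b)` exchanges the two
  labels from that frame to the end — the irreversible-switch semantics.
  Applying the same directive twice is the identity. Invalid directives
  are skipped with their errors collected so one typo cannot void a
  correction session.

### Analytics

All analytics use the arithmetic mean of mask pixel coordinates
("geometric center") at full resolution, converted by a single isotropic
px/cm calibration from the arena side length (the camera is assumed
overhead and distortion-free; lens correction is out of scope).
Cumulative travel distance sums raw per-frame steps with no smoothing or
minimum-step floor — a floor would silently change the reported numbers.
Proximity uses strict `distance < 6 cm` between centers; a pair sitting
at exactly 6.0 cm is not proximate. Filled frames carry coordinates and
count toward proximity by default (`exclude_filled = TRUE` removes
them); their carry-forward steps have zero length, so they never inflate
travel distance.

## The synthetic generator

`synth_scene()` emulates the recording geometry the pipeline targets:
a 640 px (32 cm at 20 px/cm) bright arena (intensity 230, Gaussian noise
SD 5), 60 Hz, with elliptical animals of 8 cm body length and 0.4 aspect
ratio — the relative animal/arena scale of a 1080p overhead rig at desk
size. Animal intensity is a per-animal base level (evenly spaced over
40–90) times a seeded multiplicative texture field (amplitude 0.35, 4 px
cells) fixed in the body frame and rotated with heading, so correlograms
are informative but not trivially constant, as with real fur patterns.
Motion is a seeded random walk (per-frame step |N(3, 1.5)| px capped at
8 px — about 9 cm/s mean speed, a realistic exploring pace; heading SD
0.4 rad) with reflecting walls and ellipse-level collision avoidance
keeping ≥ 3 px clearance, so blobs never merge and side-by-side animals
can still approach to ~3.2 cm — inside the 6 cm proximity threshold.

Two error modes can be injected, mirroring the failure modes the
correction stage exists for. A *miss* omits an animal from the render of
one frame (ground truth logs the slot). An *irreversible ID switch* is
injected by exchanging two animals' appearance (texture and base
intensity) from a chosen frame onward: an appearance-based tracker then
persistently swaps the two predicted identities relative to the
position-continuous true animals. A positional teleport would not work
here — the tracker follows appearance, so only an appearance exchange
reproduces this failure mode.

What the generator does **not** emulate: partial occlusion and merged
blobs (contact is excluded by the collision model), fur/limb/pose
detail, shadows and illumination gradients, motion blur, and infrared
night-recording noise. Consequently, passing tests demonstrate the
correctness of the association, correction and analytics machinery on
exact detections — they do not certify detector robustness on real
video, where detection quality dominates.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, origin top-left, x rightward, y downward,
  floats for centroids; frames are matrices on [0, 255].
* Calibration is exact (`px → cm → px` below 1e-9 px); CSV flags are
  serialized 0/1 to be locale-proof.
* A detection with fewer than two included pixels yields the zero
  correlogram (`total_pairs = 0`); an empty mask is an error.
* An empty frame leaves all IDs unmatched; tracking aborts with the
  maximum simultaneous detection count only if *no* frame ever shows
  `n_mice` detections.
* Manifest hashes (MD5 of each artifact) contain no timestamps, so
  identical config + seed reproduce byte-identical runs.

## Problem sizes used in tests

Unit tests run on 160 px arenas (5 px/cm, ~40 × 16 px animals, tens of
frames) — small enough to make brute-force oracles (all-pairs
enumeration, naive dilation, recursive RDP) practical. The end-to-end
acceptance checks run at the native scale: 640 px arena, three animals,
600 frames (10 s at 60 Hz), which one CPU core tracks in about two
minutes. `scripts/acceptance.R` uses the same native scale for its two
scenes.

## Known limitations

* Detection and association are strictly per-frame; long occlusions or
  detector failures beyond `max_gap` frames leave documented gaps rather
  than guesses, and re-identification after a long gap relies on the
  stale reference fingerprint.
* The greedy rule can mis-assign when two animals' fingerprints are
  closer to each other than to themselves across a frame pair — exactly
  the event the tracking-warning rule is designed to surface.
* Video-file input is supported as PNG image sequences; containerized
  video should be exported to frames first.
* The bundled threshold detector assumes dark animals on a bright floor;
  for any other contrast regime, supply detections via the detector
  interface or VIA JSON.
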
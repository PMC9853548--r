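# mousetrackr

Marker-less tracking of multiple mice in top-view open-field video, with
semi-automated error correction and social-behavior analytics.

## The problem

Social behavior of laboratory mice — who travels how far, who spends time
near whom — has to be measured on *groups* of animals, but unmarked
littermates (e.g. black C57BL/6 mice on a white 32 cm arena floor) are
visually near-identical, and any physical marker (dye, implants) risks
changing the behavior under study. `mousetrackr` implements a
tracking-by-detection pipeline for this setting:

1. **Detection.** Each frame is segmented independently into animal mask
   regions. The bundled detector is a classical dark-on-bright threshold
   segmenter (8-connected components with an area filter); any external
   detector can be plugged in instead, either as an R function or as
   polygon annotations in VGG Image Annotator (VIA 2.x) JSON. Contour
   post-processing (5 px disk expansion, Ramer–Douglas–Peucker
   simplification with ε = 1.5) matches common annotation practice.
2. **Tracking.** Each detection is summarized by a *correlogram
   fingerprint*: the mask is buffered (10 iterations of 3×3 dilation, a
   7×7 Gaussian blur of the mask thresholded at > 0), the frame is cropped
   to the buffered support, downscaled to quarter size, and every
   unordered pair of included pixels {p, q} contributes its Euclidean
   distance d and intensity sum s = I(p) + I(q) to a normalized 32 × 32
   histogram h(d, s). Fingerprints are compared by the mean absolute bin
   difference, and identities are carried frame-to-frame by sorting all
   (ID, detection) dissimilarities in ascending order and assigning
   greedily; with n mice, n contours get IDs and surplus detections are
   ignored.
3. **Correction.** Sporadic detection misses are filled by carrying the
   last record forward (gaps longer than `max_gap` are reported instead).
   A *tracking warning* is emitted for ID i at frame N+1 whenever some
   other ID's new position is strictly closer to i's old position than
   i's own — the signature of a candidate identity switch. Warnings are
   advisory; confirmed irreversible switches are repaired by human swap
   directives that exchange two labels from a frame onward.
4. **Analysis.** From the corrected table: per-animal cumulative travel
   distance (cm), per-pair center distance (cm), and cumulative proximity
   time — seconds with pair distance strictly below 6 cm.

A seeded synthetic arena generator (`synth_scene()`) renders textured
elliptical animals with exact ground truth and controllable error
injection, so the whole pipeline is testable end to end without any
recorded video.

## Worked example

```r
library(mousetrackr)

# a 3-mouse, 10-second (600-frame) synthetic recording
scene  <- synth_scene(n_mice = 3, n_frames = 600, seed = 1)
cfg    <- mt_config(n_mice = 3)
tracks <- track_video(frame_stream(scene), cfg)
corr   <- correct_tracks(tracks)
print(evaluate_tracks(corr$table, scene_truth(scene)))
#> Tracking evaluation vs ground truth
#>   misses:        0.000% of slots
#>   ID switches:   0
#>   centroid error: max 0.000 cm, mean 0.000 cm
#>   error < 0.5 cm: 100.0%   < 1.5 cm: 100.0%

cum <- cumulative_distance(corr$table, 0)
cum$cum_cm[600]          # total distance traveled by mouse #0
#> [1] 91.18281
pt <- proximity_time(corr$table, 0, 1)
pt$cum_s[600]            # seconds mice #0 and #1 spent < 6 cm apart
#> [1] 1.1
```

On this clean scene every detection is pixel-exact, so the tracker keeps
all three identities for all 600 frames with zero misses and zero
switches; mouse #0 covers ~91 cm in 10 s and spends 1.1 s proximate to
mouse #1. With injected errors (see the vignette) the correction stage
fills the misses and the warning rule flags the injected identity switch
at its exact frame.

A thin command-line front end is included:

```sh
exec/mousetrack run --config run.cfg --out-dir out/
```

with subcommands `synth`, `track`, `correct`, `analyze`, `evaluate`,
`run`; the config file is flat `key = value` text (see `?load_config`).

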
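---
title: "Vessel analytics for coronary angiography sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel analytics for coronary angiography sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiotrack)
```

## The problem

Conventional coronary angiography records a contrast-filled coronary tree as
a short 2-D projection sequence (typically 15 frames/s). Two findings matter
clinically: *stenosis*, a focal narrowing of the lumen, and the *myocardial
bridge*, a congenital band of myocardium overlying a coronary segment that
compresses it during systole. On angiography a bridge shows as the "milking
effect": the same vessel segment narrows and re-opens periodically with the
cardiac cycle, so no single frame is diagnostic — the finding lives in the
*sequence*.

`angiotrack` implements the analytics downstream of vessel segmentation.
Its input contract starts at per-frame binary vessel masks (the output of
any segmentation method); producing those masks is out of scope. From the
masks it extracts centerlines, describes vessel segments, builds a per-frame
vessel tree, matches vessels across frames, quantifies and grades stenoses,
and flags bridges from periodic narrowing along a vessel track.

## Skeletonization and keypoints

Masks are thinned with the two-subiteration Zhang–Suen scheme. With `p2`
the pixel directly above the centre and `p3..p9` clockwise, a foreground
pixel is deleted when `2 <= N(p1) <= 6`, `S(p1) = 1`, and — in the first
subiteration — `p2*p4*p6 = 0` and `p4*p6*p8 = 0` (second subiteration:
`p2*p4*p8 = 0` and `p2*p6*p8 = 0`). `N` counts foreground 8-neighbours and
`S` counts `0→1` transitions around the ring. Deletions within a
subiteration are simultaneous; the loop stops when a full pass deletes
nothing. A subsequent single sequential pass removes staircase corner
pixels (a pixel with neighbours directly above and to the left, or above
and to the right), guarded by a simple-point check so a component is never
disconnected.

Endpoints are skeleton pixels with exactly one neighbour. Intersections
must satisfy `N(p1) >= 3` together with the four triple-sum conditions
`p3+p4+p5 <= 1`, `p5+p6+p7 <= 1`, `p7+p8+p9 <= 1`, `p9+p2+p3 <= 1`.

Two realities of thinned rasters required engineering around this
definition:

* **The triple-sum conditions are incomplete.** A fork whose two arms exit
  through diagonally adjacent ring positions (say `p5` and `p6`) violates
  one triple no matter which junction pixel you test, so some genuine
  bifurcations contain *no* qualifying pixel. We therefore detect
  *junction clusters* — 8-connected groups of pixels with `N >= 3` that
  contain at least one pixel with crossing number `S >= 3` — and, when a
  cluster holds no triple-sum pixel, report the `S >= 3` pixel nearest the
  cluster centroid instead. Clusters that do contain qualifying pixels are
  deduplicated to the centroid-nearest one.
* **`N >= 3` alone over-fires.** An isolated staircase corner has three
  neighbours, two of which belong to the same branch; its crossing number
  is 2. Requiring `S >= 3` somewhere in the cluster separates true forks
  from these corners. On seeded phantom trees this rule recovers every
  bifurcation one-to-one within 3 px.

Paths are traced between junction clusters; each junction pixel is shared
by its incident paths but excluded from their lengths. Tiny 1–2 px arcs
that merely bridge pixels of the same cluster (thinning leaves such loops
at forks) are absorbed into the cluster. Burrs — paths shorter than 6 px
*with at least one free end* — are removed; interior junction-to-junction
arcs are never burrs. Finally the deleted set is scanned and any component
that reconnects two endpoints of the deburred skeleton lying within 2 px
of a former intersection is restored, re-joining vessels wrongly split by
burr removal.

## Segment description

The diameter at a centerline pixel is measured along the normal of a local
least-squares line fit through a 5-pixel window (`min Σ(ax_i + b − y_i)²`,
axes swapped when the window is numerically vertical). From the pixel the
normal is marched in both directions in 0.25 px steps with bilinear
interpolation of the mask; the edge is the 0.5 crossing, refined linearly,
with a 50 px cap per side. The diameter is the distance between the two
exits. Samples within 2 px of an intersection are skipped — the two-edge
assumption fails at a fork; the margin is our choice. Each segment then
carries its ordered path, start and end coordinates (canonically oriented
so the start is the endpoint Manhattan-closer to the image origin — the
matching and tree stages both need a consistent orientation), its pixel
length, and its diameter profile.

On straight phantom vessels of widths 3–11 px at 0–90°, the measured
diameters stay within 1 px of truth on average and agree with an exact
distance-transform oracle within 1.5 px at over 99% of samples. Note one
documented pathology: two-subiteration thinning erodes limbs oriented at
exactly 45°, so the skeleton of a long straight diagonal vessel is
noticeably shorter than the vessel. Curved vessels are barely affected.

## Vessel tree

The catheter enters near the upper-left image corner, so the root segment
is the one whose start minimizes the Manhattan distance to the origin
(ties: smaller y, then x). Construction is breadth-first: a segment becomes
a child when the Manhattan distance from the parent's end to its start is
at most 10 px (inclusive, so the threshold value itself is attainable); at most three children are kept (the three nearest), matching the
observed maximum branching of coronary trees. Children are ordered by the
sign of `V = (x2−x1)(y3−y2) − (y2−y1)(x3−x2)` evaluated in image
coordinates (y down): `V > 0` puts the first point first. Because both
children *start* on the shared junction pixel, the ordering uses a
representative point 12 px along each child instead of the start itself.
Collinear ties order by ascending x then y. Unattached segments become
extra roots of a forest (robustness to segmentation dropouts). IDs are
assigned in breadth-first order, so smaller IDs are earlier-developing
vessels and IDs never decrease with tree level.

## Matching and tracks

Two segments from different frames are the same vessel when
`d_s < 65`, `d_e < 65` and `rate > 0.80`, where `d_s`/`d_e` are Manhattan
distances between the start and end points and `rate` is the shorter over
the longer length. The comparisons are strict inequalities; the thresholds
live in the configuration because they depend on frame rate. When several
pairs compete, assignment is globally greedy by ascending `d_s + d_e`
(deterministic and order-independent), each segment matched at most once.
Unmatched segments retry against the second and third following frames; a
segment already matched is not rematched. Chains of matches become tracks.

## Stenosis and bridges

Profiles are smoothed with the trailing moving average
`y(k) = mean(x(k−N_w+1..k))`; the window shrinks near the left edge. The
window length defaults to `N_w = 5`, matching the line-fit scale, and is
exposed in the configuration.

A stenosis candidate is a local minimum of the smoothed profile: for
non-peripheral (non-leaf) vessels the single global minimum of the whole
profile; for peripheral vessels all local minima except in the distal 20%
of the path, where vessels naturally taper. The expected healthy diameter
is the mean of the nearest flanking local maxima `D_f`, `D_b` (a profile
boundary counts as a maximum when the profile is monotone towards it), and

```
P = (1 − 2 D_min / (D_f + D_b)) × 100%.
```

Grades follow the clinical bands, lower-inclusive: 30–50% mild (label 0),
50–70% moderate (1), ≥70% severe (2); below 30% the vessel is reported
normal (mis-called mild cases in practice fall into this class).

A track is called a myocardial bridge when either rule fires (checked in
this order, tracks shorter than 4 members never fire):

* **Stenosis variation** — max − min of the per-frame stenosis degree
  ≥ 0.25 with the extreme frames at least 3 apart. Degrees are fractions
  (0–1) of the per-frame most-severe candidate, with no 30% floor.
* **Diameter ratio** — min/max of the per-frame mean diameter ≤ 0.75 with
  the extreme frames at least 3 apart. This covers long lesions where the
  whole vessel thins and no focal candidate exists.

The frame gap is the inclusive `>= 3`; extrema take their first
occurrence, which for a periodic lesion of period ≥ 6 frames always spans
at least half a period.

## The phantom generator

Real angiograms and their expert annotations are not shippable, so
validation runs on a synthetic phantom whose statistical structure matches
what the pipeline assumes: branching trees of vessels 3–15 px wide, rigid
inter-frame translation bounded well below the 65 px matching threshold,
raised-cosine focal narrowings, and periodic narrowings following
`width(t) = base × (1 − severity × (1 + cos(2πt/period))/2)` — degree
oscillating between 0 and the programmed severity, emulating the milking
effect at roughly one cardiac cycle per 12 frames at 15 frames/s. Vessels
are rendered by stamping a disc of diameter equal to the local width at
every 1 px centerline sample, which keeps the width analytically known;
rendering is deterministic given the spec.

Layout helpers generate seeded study cases. `random_tree_spec()` grows a
root from the upper-left corner with internal nodes always branching into
two or three children — a single-child chain leaves no skeleton junction,
so the two vessels would (correctly) merge into one segment and truth
counts would be unrecoverable by construction — with clearance checks
keeping non-adjacent arms at least the sum of half-widths plus 5 px apart.
`bridge_case_spec()` builds one long *curved* vessel (two ~55 px legs with
a 12–20° bend): coronary segments are curved in reality, and the curve
also avoids the 45°-alignment erosion pathology described above. Lesions
sit mid-vessel (position 0.4–0.6, extent 24 px).

What the phantom does **not** emulate: X-ray texture and noise,
segmentation errors, vessel overlap and crossings (a stated limitation of
the whole approach), foreshortening, or non-rigid cardiac deformation.
Passing the phantom suites therefore validates the *analytics* — the
geometry, matching and rule logic — not robustness to segmentation
failures on clinical images.

## Numerical choices and degenerate inputs

* Coordinates are x = column, y = row, 0-based, origin top-left,
  everywhere in the package.
* Tie-breaks are always deterministic (smaller y, then x), making the
  whole pipeline reproducible bit-for-bit; repeated runs on the same masks
  give identical reports.
* An empty mask yields an empty skeleton, zero segments and a valid empty
  report; a frame failing skeletonization is skipped with a warning and
  the sequence continues.
* Vessels clipped at the image border are rendered clipped and their truth
  records flag the clipped endpoints.
* A cyclic skeleton component with no keypoints is emitted as a single
  closed path with a warning.
* Diameter samples whose normal never exits the mask within 50 px (e.g.
  inside blobs) are dropped as missing; a segment with no valid samples is
  dropped with a warning rather than poisoning the frame.

## Problem sizes used in the shipped validation

The test-suite and acceptance-script phantom studies use 112–224 px
images, trees of 5 segments (two bifurcations), sequences of 4–12 frames,
20 seeded replicates per suite, and the 5 widths × 5 angles diameter grid.
These sizes give stable rates while keeping a full validation run around a
minute on one CPU; all of them scale up by passing larger specs to the
same functions.

## Known limitations

* Overlapping or crossing vessels are not disambiguated; a crossing
  becomes a spurious 4-way junction.
* Diameters are in pixels; millimetre calibration is out of scope.
* The Zhang–Suen 45° erosion shortens perfectly straight diagonal vessels;
  keypoints and diameters are unaffected but the distal-most few pixels of
  such vessels are not profiled.
* Bridge detection assumes the lesioned vessel is tracked across at least
  4 frames; severe segmentation dropouts break the track and the finding.
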
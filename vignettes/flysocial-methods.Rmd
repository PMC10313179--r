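---
title: "Methods: tracking, event logic, and behavior metrics in flysocial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking, event logic, and behavior metrics in flysocial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysocial)
```

## What the package computes

`flysocial` quantifies social behavior in groups of *Drosophila* from
per-frame object detections — the kind of output a trained object
detector produces from overhead chamber video: one box per fly body, one
per head, and optionally boxes for labeled behavior events (chasing,
unilateral wing extension "singing", mounting). The package links those
detections into identity-stable trajectories, derives typed behavior
events, aggregates chase relations into chaining records, and reports
the standard readouts of fly social behavior: behavior indexes,
courtship index, chaining index, two-choice preference, social space,
encounter counts, foraging visits and dwell, and locomotion states.

Because raw video and detector weights are outside the package's scope,
an agent-based arena simulator generates detection streams with complete
ground truth (identities, scripted events, chain structure). Every
guarantee the test suite makes is stated against that simulator.

## Identity tracking: greedy distance-sort

Tracking-by-detection links independent per-frame detections into
trajectories. The linker implements a greedy *distance-sort* rule:

1. In the first populated frame, IDs `1..k` are assigned by ascending
   `(y, x)` of the body centroid. The ordering is arbitrary in
   principle; a fixed rule makes runs reproducible.
2. In each later frame, all candidate (track, detection) pairs with
   centroid distance at most `gate_px` (default 30 px) are sorted by
   ascending distance and accepted greedily while both sides are free —
   each fly inherits the ID of its nearest neighbour in the previous
   frame. Ties break by detection `(y, x)`, then track id.
3. A track with no match *coasts*: it emits a point at its last
   observed position, flagged `observed = FALSE`, indefinitely — the ID
   stays parked until the fly reappears. There is no coasting timeout.
4. Residual identity switches (e.g. when two flies cross within a
   frame step) are repaired with explicit corrections: a correction
   `(frame, id_a, id_b)` swaps the two identities from that frame
   onward and is its own inverse, so a mistaken correction is undone by
   repeating it.

Greedy global distance-sort was chosen over per-track nearest neighbour
because it is order-independent given the tie rules, deterministic, and
— whenever all inter-fly gaps exceed twice the maximum per-frame
displacement — provably identical to the per-frame optimal (Hungarian)
assignment. The test suite checks that equivalence against
`scipy.optimize.linear_sum_assignment` on 100 simulated 13-fly,
1,000-frame scenarios.

Headings come from head boxes: each head box is assigned to the body
box it overlaps most (at least `head_overlap_min = 0.25` of the head
area; ties go to the nearest centroid), and the heading is the angle of
the body-to-head vector in a y-up mathematical frame, in (−π, π]. The
simulator places head boxes 3 px ahead of the body centroid: with the
12 × 6 px body box this keeps the head/body overlap fraction at or
above 0.5 for every heading direction, whereas a larger offset would
zero the overlap for vertically-heading flies and defeat the assignment
rule.

## Behavior events

Two routes produce events; both yield the same typed half-open
intervals `[start_frame, end_frame)` with an actor and optional target.

**Detector-labeled boxes.** A `chase`/`mount` box is attributed to the
two tracks it overlaps most (overlap as a fraction of each body box);
the chase actor is the member whose heading points toward the other. A
`wing_ext` box is attributed to its single best-overlapping track, with
the nearest fly inside the singer's heading cone as optional target.
Consecutive same-pair frames merge into intervals.

**Kinematic classification.** Without detector event boxes, chases
("following") are classified from trajectories. For an ordered pair
(actor, target) at one frame the instantaneous predicate holds iff

* gap ≤ `d_max_mm` (default 5 mm),
* actor speed ≥ `v_min_mm_s` (default 2 mm/s), and
* |heading − bearing to target| ≤ `align_max_rad` (default π/6).

A fly is the actor of at most one chase per frame; conflicts resolve by
smallest gap, then smallest alignment angle. Interruptions up to
`merge_gap_frames` (default 5) are bridged, and runs of at least
`min_frames` (default 15, i.e. 0.5 s at 30 fps) become events. The
thresholds are package conventions — detector-based systems need none —
and all are exposed through `chase_params()`. Frames without an
assigned head fall back to the direction of motion; a stationary,
heading-less frame is unclassifiable. Speed at frame *f* is the
displacement from *f* to *f + 1* (the last frame reuses the preceding
step), so a constant-velocity track is classified uniformly.

## Chaining

Chaining — males forming chains or rings, each courting the fly ahead —
is scored per frame from the directed chase graph (one edge per active
chase, actor → target). The criterion "two or more chase events sharing
a structure" is formalized as: the *weakly connected components with at
least two edges* are the chain components, and the per-frame chain
count is

> B(d) = Σ over chain components (|component fly set| − 1).

This formalization satisfies three constraints simultaneously: two
chasers of one target form a chain (count 2); any chain component
involves at least three flies, matching the assay definition of
chaining as "at least three flies engaged in courtship"; and a closed
ring or path spanning all N flies yields exactly N − 1, the maximum
B(max) used by the behavior index. A single isolated chase edge is
never chaining. Components are computed with igraph; the test suite
re-derives them with an independent union-find enumeration on ~1,000
random digraphs.

Whether the original counting rule was per component, per edge, or per
fly is not recoverable from a one-line criterion; the component
formalization is this package's documented choice, and both the
`B(d)/B(max)` index and the time-based index ("% of frames with at
least one chain component") are reported so either convention is
available downstream.

## Behavior indexes

The behavior index normalizes a per-frame detected event count by its
maximum possible value:

> Index = B(d) / B(max) × 100 %,

with B(max) = N for chasing and singing (every fly can act at once) and
B(max) = N − 1 for chaining. Five simultaneous chases in a 10-fly group
give 50 %; a closed ring of 10 gives 100 %. The index is computed per
frame and averaged over the clip — the worked examples are snapshot
counts, but real clips span minutes, so a time aggregate is needed; the
per-frame series is retained for rug plots. Counts exceeding B(max)
(possible with noisy detector input) are capped with a warning so the
index is ≤ 100 by construction. Undefined ratios — a preference with no
courtship, an index over zero frames — are reported as missing values,
never as 0, because 0 is a meaningful outcome.

## Descriptive metrics

All millimetre thresholds convert through `mm_per_px`; defaults are
package conventions (`metric_params()`), not measured constants.

| metric | definition | key defaults |
|---|---|---|
| courtship index | % of observed frames the fly acts in any courtship event | — |
| social space | per-fly nearest-neighbour distance (mm); neighbours within radius | radius 5 mm |
| encounters | maximal runs of pair gap ≤ radius lasting ≥ min frames | 5 mm, 15 frames |
| foraging | visits = in-ROI runs ≥ 30 frames (gaps < 15 merged); dwell = total in-ROI time | 1 s visits at 30 fps |
| locomotion | resting ≤ 0.5 mm/s < walking ≤ 10 mm/s < running; jump = single-frame displacement ≥ 4 body lengths | body 2.5 mm |

Foraging dwell deliberately counts *all* in-ROI frames, so a brief
entry too short to be a visit still contributes dwell. Coasting frames
classify as resting — a lost fly is overwhelmingly a stationary fly
under the coasting rule.

## The arena simulator

The simulator emulates an overhead view of a circular chamber (default
4 cm diameter at 0.05 mm/px, 30 fps). Free flies perform a Gaussian
random walk (per-axis σ, clamped at 3σ, reflected at the wall); the
clamp bounds the per-frame displacement so that well-separated
scenarios can *guarantee* the separation precondition of the tracking
equivalence property rather than satisfy it only in expectation. An
optional per-fly tether confines each fly to a territory around a grid
home — the configuration used for those scenarios.

Scripted directives override free motion. Chases and rings are realised
as orbital motion: members sit on a shared circle and rotate at
constant tangential speed, the follower trailing by a fixed chord with
its heading locked on its target. The geometry makes the kinematic
chase predicate hold by construction for any duration — the gap is the
chord, the speed is the tangential speed, and the alignment deviation
is asin(chord/2r), kept below the π/6 threshold by the default chord
50 px on radius 80 px (chases) and the 10-member ring on radius 100 px
— and an orbit never meets the chamber wall. `dir_goto_food()` walks a
fly straight into the food region where it stays; `dir_decapitated()`
pins a static, headless courtship target, emulating the two-choice
assay's decapitated stimulus flies.

Detection noise is a per-(fly, frame) dropout probability and Gaussian
centroid jitter. All randomness derives from the script seed, and
repeated simulation of the same script is byte-identical on disk.

What the simulator does **not** emulate: occlusion and box merging when
flies touch, detector confidence variation, wing-posture geometry,
copulation, and any appearance information. Passing tests therefore
demonstrate the correctness of the linking/event/metric logic under the
stated motion model, not detector robustness on real video.

## Worked-example fixtures and problem sizes

`make_worked_examples()` builds the two canonical scenarios: fixture A,
a 10-fly group with 5 simultaneous scripted chase pairs (expected
chasing index exactly 50 %), and fixture B, a 10-fly closed ring
(chasing index 100 %, chain count 9 = N − 1 every frame, chaining index
100 %). Both are noiseless and fully scripted, so their indexes are
duration-invariant; the package runs them at 900 frames (30 s at
30 fps), long enough to exercise run-merging and short enough that the
full simulate → track → classify → metrics pipeline completes in
seconds. Tracking-equivalence checks use 13 flies × 1,000 frames × 100
scenarios; geometry and chaining property checks use ~1,000 random
cases each.

## Numerical choices and edge cases

* Ties in the greedy match sort break by detection `(y, x)`, then track
  id; first-frame IDs order by `(y, x)` — all outputs are deterministic.
* Coordinates are image coordinates (origin top-left, y down, pixels,
  0-based frames); headings are reported in the y-up mathematical frame.
* Track CSV headings serialise at 6 decimals (≈ 6e-7 rad resolution);
  all other numerics serialise at full precision (`%.17g`) so
  write→read is the identity.
* Empty inputs are contracts, not errors: an empty detection stream
  yields an empty track set; an empty frame yields coasting; a frame
  with no chase edges yields chain count 0.
* `fixed_population = TRUE` (default) freezes the track set at the
  first populated frame; surplus detections are dropped and counted, so
  detection counts always reconcile exactly.

## Known limitations

* The kinematic chase classifier is a surrogate for a trained event
  detector; its thresholds shape sensitivity and are deliberately
  exposed rather than tuned.
* Greedy linking is only guaranteed optimal under the separation
  condition; dense interactions need the correction workflow.
* Chain components are scored per frame independently; no temporal
  smoothing of chain membership is applied.
* Rendering returns numeric tables plus ggplot objects; rasterised
  images depend on the graphics backend and are not part of any
  contract — the tables are authoritative.
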
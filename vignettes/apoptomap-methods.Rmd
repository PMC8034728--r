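---
title: "Mapping apoptosis in space and time: the models behind apoptomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping apoptosis in space and time: the models behind apoptomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoptomap)
```

# The measurement problem

Tumor-on-chip cultures embed cancer cells in a 3D collagen gel inside a
microfluidic chamber and image them live for two to three days, typically one
frame per hour. With the cancer cells carrying a red vital pre-stain and a
caspase-3/7 reporter that turns green at apoptosis onset, each recording
contains, in principle, the time and place of every cancer-cell death. In
practice extracting them requires solving four linked problems: finding and
following the cells, deciding per cell when (if ever) the reporter switched
on, turning per-cell death calls into population kinetics, and deciding
whether deaths beget nearby deaths — i.e. whether cytotoxicity is
*transmissible* — rather than striking at random. `apoptomap` implements that
chain end to end, together with a seeded simulator that generates
ground-truthed recordings so every stage is testable without microscope data.

Conventions used throughout: images are `D1 x D2 x T` arrays indexed
`(y = row, x = column, t = frame)`, all 1-based; physical parameters are
given in micrometres and hours and converted through a `calibration()`
(defaults 0.645 um/px, 1 h/frame, matching hourly acquisition with a 5x
objective); intensities are non-negative floats and are never rescaled
between frames.

# Localization and tracking

Cells are localized per frame in the red channel: the frame is binarized by
Otsu's criterion and a circular Hough transform (CHT) is run over an imposed
radius range (`tracking_config(radius_min_px, radius_max_px)`, default 4–8
px). The accumulator for radius $r$ is the convolution of the mask's edge
image with a one-pixel ring of radius $r$, normalized by ring size, so an
accumulator value is the fraction of a circle's perimeter present; peaks
above `min_votes` (default 0.35, tolerant of partially fused outlines) become
detections after non-maximum suppression with minimum separation
`radius_min_px`. The Otsu threshold itself is computed exactly on the raw
intensity values — every midpoint between consecutive sorted unique values is
scored by between-class variance — rather than on a binned histogram, and the
same routine later thresholds the pooled reporter traces.

Tracks are built frame-to-frame by optimal assignment: the cost of linking a
track to a detection is the squared displacement, pairs farther apart than
`gating_px` (default three maximal radii — slow-moving cancer cells at hourly
sampling) are forbidden, and each point can also remain unmatched at cost
`gating_px^2`. The resulting square problem is solved exactly with a
Jonker–Volgenant shortest-augmenting-path solver written for this package (no
linear-assignment solver is part of the dependency stack); a brute-force
enumeration oracle checks it in the tests. Unmatched detections found a new
track; a track missed for more than `max_gap_frames` (default 2) terminates;
shorter dropouts are bridged by linear interpolation of position and radius,
so each track covers a contiguous frame range. Tracks deliberately continue
after a cell's death — the red stain persists, and the kinetics need dead
cells to remain localized.

# The reporter trace and death calling

For each track point a 31 px square ROI (about 20 um) is centered on the
detected position in the green channel. The foreground is the detected cell
disk; the background is the annulus between the cell disk and a neighborhood
circle of radius `bg_radius_factor` (default 2) times the experiment-average
cell radius, clipped to the ROI and the frame. The annulus reading — rather
than a neighborhood disk that includes the cell — is the only choice that
makes foreground and background disjoint, and is recorded here as a design
decision. With $\mu^{F}(t)$ and $\mu^{B}(t)$ the foreground and background
means, the normalized trace is

$$\mu(t) \;=\; \frac{\mu^{F}(t) - \mu^{B}(t)}{\mu^{B}(t)}
\;-\; \min_{t' \in F}\frac{\mu^{F}(t') - \mu^{B}(t')}{\mu^{B}(t')},$$

so every trace has minimum exactly zero and apoptosis onset appears as a
sustained jump. Frames whose background mean falls below
`epsilon_bg * max(green)` (default $10^{-6}$) would make the ratio explode;
they are flagged and filled by linear interpolation from neighboring frames
instead of propagating.

One threshold `th` per video is estimated by pooling *all* time samples of
*all* traces into a single multiset and applying the exact Otsu routine; a
cell is called dead at the *first* frame where $\mu(t) > th$. The call is
definitive: a later dip below the threshold (reporter bleaching) does not
retract it.

# Population kinetics

Moving from the cell-centric to the time-centric view, for each frame $t$:

* $N_{ap}(t)$ — death events in the closed trailing window
  $[t - T_{LAG},\, t]$ (spanning $T_{LAG}+1$ frames);
* $N_{track}(t)$ — tracks existing at $t$ whose death has not yet been
  called. Defining living tracks through the called death frame, rather than
  through the instantaneous comparison $\mu(t) < th$, keeps the accounting
  identity "dead + living = present" exact even if a trace dips back under
  the threshold after its definitive first crossing; the two definitions
  coincide whenever the reporter persists after onset, which is the imaging
  model here;
* $N_{avg}(t)$ — mean of $N_{track}$ over the same trailing window;
* apoptosis rate $O(t) = 100\, N_{ap}(t) / N_{avg}(t)$, in percent per
  $T_{LAG}$ window, reported from $t = T_{LAG}+1$ onward where the window is
  complete;
* overall survival $OS(t) = 100\, N_{avg2}(t) / \mathrm{ref}$, where
  $N_{avg2}$ is the living count smoothed over $\{t-1, t, t+1\}$ and the
  reference is the mean living count over the first three frames.

`t_lag_hours` is configured in hours and converted through the calibration;
10 h suits accuracy benchmarking against manual counts, 4 h resolves
kinetics. With a constant per-frame death hazard $h$, the expected rate is
$E[O] \approx 100\,(T_{LAG}+1)\,h$; the acceptance suite recovers a
programmed 0.5 %/h hazard through exactly this relation.

# The death map and the potential of death induction

Each called death seeds a binary disk (the cell's detected disk at death) at
its death frame in an otherwise empty video $MD$. The map then evolves by

$$M(\cdot,\cdot,t) \;=\; \Psi_{B_r}\!\big(M(\cdot,\cdot,t-1)\big) + MD(\cdot,\cdot,t),
\qquad M(\cdot,\cdot,1) = MD(\cdot,\cdot,1),$$

where $\Psi_{B_r}$ is grayscale morphological erosion (minimum filter) by the
disk $B_r = \{(x,y): x^2+y^2 \le r^2\}$, with pixels outside the frame
counting as background zero. Erosion shrinks a disk's radius by $r$ per
frame, so an isolated death of radius $r_0$ leaves a *wake* surviving
$\lceil r_0/r \rceil$ frames (plus at most one frame of rasterization slack).
The default $r$ is one third of the experiment-average cell radius, rounded
up (`wake_radius()`), making an average wake last at least three hourly
frames. Because the recursion is literally additive, a fresh death landing on
a surviving wake yields map values above 1; the seed video itself stays
binary (same-frame overlaps are unioned).

Squared wake intensities are then aggregated over a forward window of
$\tilde T$ frames,

$$MC(x,y,t) = \sum_{t'=t}^{t+\tilde T} M(x,y,t')^2, \qquad t \le T - \tilde T,$$

and each $MC$ frame decomposes into *death objects*: 8-connected components
of its non-zero support. For objects $s_i$ with mean map values $m_i$ and
boundary centroids (mean coordinates of pixels with a 4-neighbor outside the
object) $c_i$, the potential of death induction is

$$P_{death}(t) \;=\; \frac{1}{2\,|S(t)|}\sum_{i<j}
\frac{m_i + m_j}{\bar d(s_i, s_j)},$$

with $\bar d$ the Euclidean distance between boundary centroids divided by
the largest dimension of the evaluated region. $P_{death}$ is zero with
fewer than two objects, grows when deaths are intense (through $m$) and
crowded (through $1/\bar d$), and doubles-halves exactly with rigid scaling
of the pattern — the properties the test suite asserts. Degenerate pairs
with coincident centroids (possible for nested objects after window
clipping) are skipped with a warning rather than contributing infinity.

The statistic is evaluated inside square sliding windows of 283 um
(`window_um`), tiled with stride one window side and the last row/column
anchored to the frame edge — the minimal covering of the field; objects are
re-extracted inside each window, $\bar d$ is normalized by the window side,
and the per-frame summary is the mean over windows holding at least one
object (`aggregate = "max"` is available; the mean is the default reading of
per-field curves). $\tilde T$ defaults to 16 h, the value calibrated by the
chain-of-death analysis below; windows straddling tile boundaries are
clipped per window, the implemented reading of an unspecified detail.

## Chains of death

Every death event seeds a chain: events within 10 seed radii of the seed's
death position join if their death time is within `chain_t_lag_hours` of the
latest member (the "within" reading of an ambiguous "at a temporal distance
equal to"; chains are grown greedily in death-time order, and absorbed
events still seed their own chains). The chain's total duration is the
seed's *induction interval*; its distribution over an experiment motivates
the default $\tilde T = 16$ h, which covers the vast majority of intervals.

# The simulator and what passing tests mean

`simulate_video()` renders what the pipeline assumes: disk-shaped cells
(hard disks with a 1 px Gaussian-smoothed edge — approximate circularity is
all the CHT needs) drifting as reflected Brownian motion
(`drift_px_per_frame`, default 0.4 px), frozen at death; a red channel where
the pre-stain persists after death; a green channel where each dead cell's
disk ramps to `green_peak` over `green_rise_frames` frames and persists;
Gaussian noise (`noise_sd` 5) on a constant background (20) with cell peaks
(180) far above 5 noise SDs; integer-rounded frames so a fixed seed
reproduces stacks bit-exactly. The default field — 512 x 512 px, 48 hourly
frames, ~100 cells of radius ~6 px — keeps a full pipeline run at
minutes-scale while leaving the field sparse, as in a 3D gel seeded at
moderate density.

Death processes: an explicit schedule; a constant per-frame hazard (default
0.5 %/h, a realistic basal apoptosis level); or a contagion model in which a
cell's hazard switches from `base_rate` to `boost_rate` while any death
younger than `lag_frames` lies within `capture_radius_px`, optionally
ignited by index deaths at a fixed frame. The frozen comparison conditions
in `death_pattern_conditions()` — 250 cells on a 200 x 200 px field at
2 um/px, 48 frames, constant hazard 0.4 %/h versus contagion (base
0.02 %/h, boost 1.5 %/h, capture 40 px, lag 10) — put the contagion process
in its growth phase for the whole recording, emulating a cytotoxic response
that intensifies with time. Two regimes were rejected while designing the
generator (before any assertion was frozen): strong-boost/short-lag
contagion burns out early and *decreases* the potential over time, and
clustered placements tighter than an event diameter merge into single
connected objects — both degenerate emulations of the conditions being
modeled. Cluster spread therefore defaults to a few cell diameters (16 px at
4 px event radius) in the clustered-versus-random comparison.

What the simulator does *not* model: photobleaching, flat-field and
illumination drift, cell division, unstained co-cultured populations
(invisible to the method by design), z-resolved structure of the gel, and
point-spread-accurate optics. Passing the closed-loop tests therefore shows
the pipeline correctly inverts its own imaging model at realistic SNR and
density — not that it is robust to every artifact of real microscopy.

# Numerical choices and edge cases

* Frames with too few distinct intensities (constant frames, single-valued
  trace pools) raise degenerate-input errors rather than guessing a
  threshold.
* The rate $O(t)$ is `NA` where the window holds no living tracks and before
  `t = T_LAG + 1`; survival needs at least 3 frames and a non-zero starting
  reference.
* Erosion radius, $\tilde T$, window side and chain lag are configured in
  physical units and converted once through the calibration; the erosion
  structuring element and seed disks use the same $x^2+y^2 \le r^2$
  rasterization.
* The demonstration scenario `three_death_demo()` (three deaths at 2, 9 and
  11 h, $\tilde T = 6$) fixes arbitrary positions — the first death far from
  a closely spaced later pair — and the tests assert orderings of the
  resulting series segments (zero / rise / rise / decay), not values.
* Problem sizes in the test and acceptance runs (a 512 x 512 x 48 full-scale
  recovery run, a 600-cell hazard cohort, 10–20 replicates of the
  200 x 200 pattern comparisons) were chosen as the smallest sizes at which
  the binomial and regression error bars are decisively smaller than the
  effects being measured.

# Known limitations

Detection assumes near-circular, well-separated cells; heavily confluent
fields fuse into blobs the CHT will under-segment. Tracking has no
mitosis/splitting logic. Death typing is single-class (caspase-positive
apoptosis); necrosis is invisible. The map analysis is 2D — a projection of
the 3D gel — and the potential of death induction is a descriptive
statistic: it separates transmissible from random death patterns but does
not model the diffusion of the underlying signals.
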
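---
title: "Classifying Morris Water Maze swimming paths segment by segment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Morris Water Maze swimming paths segment by segment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimpath)
```

## The problem

In the Morris Water Maze (MWM) a rodent swims in a circular pool (here 2 m
diameter) searching for a hidden platform (12 cm diameter). Classical
summaries — escape latency, path length — compress a 90-second trial into a
single number, and whole-trial classifiers force one behavioural label onto
paths that plainly mix several strategies: an animal may hug the wall,
detach, scan the centre, and finally circle the platform, all in one trial.

`swimpath` classifies behaviour *below* the trial level. Trajectories are
cut into overlapping segments of constant arc length, each segment is
summarised by eight dimensionless features, segments are grouped by a
semi-supervised clustering guided by a small set of manual labels, and the
segment classes are folded back onto the path so that every stretch of
swimming receives a behavioural class. Eight stereotyped classes are used:
thigmotaxis, incursion, scanning, focused search, chaining response,
self-orienting, scanning surroundings, and target scanning.

## Segmentation

A trajectory of arc length $L$ is cut into windows of constant arc length
$d$ placed at offsets $0, s, 2s, \dots$ where $s = d(1-\mathrm{overlap})$
is the *minimum path interval* — both the spacing of the windows and the
resolution of the final class sequence. Defaults follow the classification
setups this package emulates: $d$ = 250 cm or 300 cm with 70% or 90%
overlap, i.e. steps of 75, 90, or 25 cm. Two boundary rules close the
design space:

* the final window is anchored to the path end whenever the leftover
  beyond the last regular window exceeds $s/2$ (guaranteeing full
  coverage, which the coverage metric presumes), and smaller leftovers are
  absorbed by the last regular window to avoid a near-duplicate segment;
* window endpoints are interpolated linearly between samples, so the
  actual window length tracks $d$ to within one inter-sample spacing.

Paths shorter than $d$ — direct swims to the platform — are not segmented;
they are flagged and carried through the pipeline as unclassified.

## Features

Each segment yields eight dimensionless values (`compute_features`):
median and interquartile range of the distance to the arena centre
(normalised by the arena radius $R$), *focus* $f = 1 - 4A/(\pi d^2)$ with
$A$ the area of the minimum enclosing ellipse, target proximity (arc
fraction within 6 platform radii of the platform), ellipse eccentricity,
maximum loop length (longest self-intersecting sub-path over segment
length), inner radius variation (IQR over median of distances to the
ellipse centre), and central displacement (ellipse centre offset over
$R$). Dimensionless features keep the classification insensitive to small
segment-length variations, which the test suite checks as a regression
guard.

Numerical conventions, chosen once and used everywhere:

* quartiles use linear interpolation between order statistics (type 7);
* the minimum enclosing ellipse is computed by a Khachiyan-type
  minimum-volume-ellipsoid iteration with away steps, run on the convex
  hull and finished by rescaling so that containment is exact; default
  relative tolerance $10^{-4}$;
* collinear segments get a degenerate ellipse with $b = 10^{-3} a$ so that
  focus, eccentricity and inner radius stay finite;
* focus is clipped to $[0, 1]$ (the raw formula can dip below zero when
  the enclosing ellipse is large relative to the arc);
* inner radius variation of an all-coincident segment is defined as 0;
* central displacement is measured to the **arena** centre — that is what
  identifies paths concentric with the arena (chaining response) — with a
  `reference = "platform"` switch for the alternative convention;
* loop length is measured through the intersection points, from the
  crossing on the earlier edge through the intermediate vertices to the
  crossing on the later edge; adjacent edges sharing a vertex never count.

A note on focus: with a fixed arc length, $f = 0$ corresponds to an
enclosing ellipse of area $\pi (d/2)^2$, not to a circular swim of
circumference $d$ (which gives $f = 1 - 1/\pi^2 \approx 0.9$). The formula
is the authority; loose verbal glosses of it are not.

## Labels, constraints, clustering

A small fraction of segments (5–12% in practice) is labelled by hand;
segments showing traits of two behaviours may carry multiple labels and
are thereby excluded from constraint generation and cluster-class mapping
(they still count for reporting). Feature columns are min-max rescaled to
$[0,1]$; every labelled pair closer than $d_{max} = 0.25$ in that space
generates a must-link (same class) or cannot-link (different class)
constraint. The cutoff keeps the constraint count manageable without
materially changing the fit.

Clustering is MPCK-means: k-means with pairwise constraints and
per-cluster metric learning. We restrict the learned metrics to diagonal
weights — full matrices are underdetermined at realistic label counts —
and make constraint-violation penalties metric-independent, scaled by the
pair distance (a violated must-link costs more the farther the pair, a
violated cannot-link more the closer). With that choice the diagonal
metric update has a closed form and the objective is provably
non-increasing at every iteration, which the tests assert directly.
Centroids are initialised by farthest-point sampling from a seeded random
start; an emptied cluster is re-seeded at the point farthest from its
centroid; `w_violation` defaults to 10 in rescaled-feature units.

Clustering runs in two stages. Stage 1 uses cannot-link constraints only:
the feature space is not cleanly separable, several clusters can
legitimately share one class, and must-links across such clusters damage
the fit. Stage 2 revisits each stage-1 cluster that ended *undefined*
(mixed or insufficient labels) and is large enough (at least twice
`min_split_size`, default 10), and re-clusters its points in isolation
with both constraint kinds, targeting one more cluster than the number of
label classes present. Subdivision only adds clusters and softens the
dependence on the initial cluster count $k_1$. The value of $k_1$ is
chosen by sweeping a grid (`sweep_k1`): coverage is the main criterion,
and when cross-validation is enabled the selection maximises coverage
among the candidates whose held-out error rate stays within a factor
(default 2) of the sweep minimum — the held-out split tunes the cluster
count as well as estimating the error, and a high-coverage clustering
bought with misclassification is rejected.

### Mapping clusters to classes

A cluster maps to a class only if all its (single-)labels agree and there
are at least $m(n)$ of them for cluster size $n$:

$$m(n) = \lceil \max(2,\; p_{min} n,\; \gamma (1 + \log_{10} n)^2)
\rceil, \qquad \gamma = 0.7,\; p_{min} = 0.01 .$$

The intended behaviour of the quorum is fixed: small clusters must earn
their class with a larger label *proportion*, the proportion decreases
with cluster size, and it never falls below 1%. Within those constraints
the functional form is a design choice, kept behind a replaceable
`quorum_fn` strategy. We use a label *count* that grows with the squared
log of the cluster size (about 3 labels for a 10-segment cluster, 7 at
100, 12 at 1000) with the 1% proportional floor taking over for large
clusters, and never fewer than two corroborating labels. The calibration
target is the method's working regime: with 10–15% of segments labelled,
a typical cluster of 75–250 segments holds 8–25 labels, so pure clusters
clear the quorum comfortably while mixed clusters rarely scrape together
7–9 unanimous labels — leaving roughly a fifth to a third of segments in
undefined clusters, whose loss the segment overlap absorbs. A form that
demands a fixed large proportion of every cluster would instead require
labelling 30%+ of all data — incompatible with the labelling economy the
method exists to enable — while a bare 2–3-label quorum lets mixed
clusters slip through on a lucky handful of agreeing labels. Everything
else is controlled by the two
published dials: raising $\gamma$ buys fewer classification errors at the
cost of more undefined clusters; $p_{min}$ sets the large-cluster floor.

### Validation

`cross_validate` runs a 10-fold scheme over the labelled segments: each
fold is withheld from both constraint generation and class mapping, and
its segments are scored against the class of the cluster they fall in.
The headline error follows the convention #incorrect / #correct (mean
over folds); the conventional rate #incorrect / (#incorrect + #correct)
and the class-by-class confusion matrix are reported alongside. Coverage —
the fraction of total segmented path length lying in intervals overlapped
by at least one classified segment — is the primary model-selection
criterion, with 90% as the working target.

## From segment classes to path classes

The path is discretised into intervals of one step $s$. Each interval
collects votes from the classified segments overlapping it: segment $j$
of class $k$ contributes $w_k\, e^{-d_{ij}^2 / (2\sigma^2)}$, where
$d_{ij}$ is the segment-centre-to-interval distance in interval units and
$\sigma = 4$. The kernel form is a pluggable strategy; the Gaussian is the
default. The class weight $w_k = L_{max}/L_{max,k}$ — longest run of
consecutive same-class segments over the longest run of class $k$ —
protects transient behaviours (a single self-orienting turn) from being
outvoted by long-lasting ones (thigmotaxis). Run lengths are computed
per trajectory and maximised over the whole classification when one is
available: computed purely within a path, a single stray misclassified
segment would receive the maximal weight and contaminate its whole
neighbourhood, whereas cohort-wide run lengths give genuine transient
classes their boost while keeping stray segments at moderate weight.
Ties go to the class of the nearest segment centre, then to the previous
interval's class (temporal smoothness).

Independent classifications of the same trials (same segment length,
different overlap) can be merged: matched segments that agree keep their
class, defined-vs-defined conflicts are discarded to undefined, and a
defined class beats an undefined partner, since undefined encodes absence
of information rather than disagreement.

## Group statistics

Per trial, the package reports arc length per strategy (undefined
intervals excluded), the number of strategy switches, and within-trial
transition matrices over consecutive distinct defined classes (undefined
intervals are bridged, not treated as a class; the diagonal is
structurally absent and each non-empty row normalises to 1). Group
comparisons use a Friedman rank test with average ranks and the standard
tie correction (fully tied data give statistic 0, p = 1); base R's
implementation, which omits the correction, serves as the independent
cross-check on tie-free tables. The default blocking treats the matched
trials as blocks and the group per-trial medians as treatments; an
alternative animal-pairing blocking is available behind a flag, and
neither is asserted as canonical since a two-group-over-trials design
admits both readings.

## The synthetic generator

Real MWM recordings cannot ship with a package, so every stage is
exercised on synthetic cohorts (`generate_cohort`): two groups of
animals, trials grouped into days, 90 s trials sampled at 25 Hz in a 2 m
arena with a 12 cm platform 50 cm from the centre, released near the
wall — the design of the kind of experiment this package targets
(defaults: 27 control and 30 stressed animals, 12 trials). Each trial
concatenates 2–4 behaviour bouts drawn from a learning-stage schedule
(wall-bound strategies early, platform-directed search late), with
self-orienting bouts kept short because the behaviour is a transient
single turn.

Each behaviour is a correlated random walk with a class-specific steering
rule: a radial band near the wall (thigmotaxis at $r > 0.85R$), an
oscillating band with inward excursions (incursion), free diffusion with
wall avoidance (scanning), strong attraction to a small random area away
from the platform region (focused search — the class searches *other*
parts of the arena), an annulus at the platform's distance from the wall
(chaining response), a fixed-rate full turn (self-orienting), straight
passes aimed through and beyond the platform region (scanning
surroundings), and tight orbits around the platform (target scanning).
The group contrast is a speed multiplier (default 1.15) plus a dwell
multiplier (default 1.8) on the weights of the three low-efficiency
strategies in the stressed group; both at 1 give an exact null. Parameter
defaults were set so that the eight classes are separable in feature
space (mean silhouette above 0.2, asserted in the tests) yet overlap at
bout transitions, which is precisely what exercises the undefined-cluster
machinery.

What the generator does *not* model: biophysical swimming dynamics,
learning within the generator (bout schedules are drawn, not earned),
tracker noise and dropouts, or platform-contact trial termination.
Passing the recovery tests therefore demonstrates that the pipeline
recovers known structure under realistic geometry and sampling — not that
any particular animal dataset would be classified with the same accuracy.

## Problem sizes and determinism

The package-level checks run at deliberately chosen sizes: the recovery
experiment uses a 16-animal × 6-trial cohort (about 7 000 segments at
250 cm / 90% overlap) with 10% labels and a $k_1$ sweep over 20–40 in
steps of 5 gated by 3-fold cross-validation; the type-I-error
calibration uses 200 replicate null cohorts
of 6 + 6 animals × 12 trials of 8 s, comparing per-trial path length.
Every stochastic step — cohort generation, label sampling, clustering
initialisation, fold assignment — flows from a single integer seed, and
fits are bit-reproducible given (data, parameters, seed).

## Known limitations

* MPCK-means finds a local optimum; different seeds give different local
  optima, which is why coverage-based selection over $k_1$ (and in
  practice over seeds) is part of the procedure.
* The quorum form and the interval kernel are calibrated conventions, not
  fitted quantities; both sit behind strategy arguments so alternatives
  can be swapped in without touching the pipeline.
* Interval classes near bout boundaries are intrinsically ambiguous: a
  250 cm window straddling a transition belongs to two behaviours at
  once. The overlap-vote design averages these out but cannot resolve
  them below the step resolution.
* The Friedman blocking for two groups over matched trials is
  under-determined; both offered blockings are defensible and can
  disagree on borderline effects.
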
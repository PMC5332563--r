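---
title: "Segmenting and tracking budding yeast with star-shaped active contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and tracking budding yeast with star-shaped active contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starseg)
```

## The problem

Long-term single-cell experiments with budding yeast in microfluidic
monolayers stand or fall with the quality of segmentation and tracking.
Identity errors compound: if each frame-to-frame assignment is correct with
probability $\rho$, a trace of $n$ frames is entirely correct only with
probability $\rho^n$. At $\rho = 0.99$ a 100-frame trace is reliable only
`r round(100 * trace_correctness_probability(0.99, 100))`% of the time —
per-link accuracy must be extreme before multi-hour movies yield usable
lineally resolved data. Every design choice in this package serves that
goal.

`starseg` works on brightfield images and exploits three facts about how
yeast cells look in that modality: (i) cell interiors are darker than the
background, (ii) the cell border carries a strong intensity gradient, and
(iii) in crowded colonies the space between cells is brighter than the
background (halos). The package covers the whole chain: preprocessing,
seeded contour growth, rank-and-overlap filtering, frame-to-frame
assignment with a neighbourhood-preserving correction, benchmark metrics,
parameter learning, and a synthetic movie generator with exact ground
truth.

## The contour model

A cell contour is a *star-shaped polygon*: a fixed centre plus $N$ radii
along equally spaced rays (36 by default). This parametrisation — polar
active contours, also known as active rays — cannot self-intersect by
construction and reduces each control point's freedom to one dimension,
which keeps energy minimisation cheap. The snake energy has three terms,

$$E = E_\text{image} + E_\text{shape} + E_\text{surface},$$

* $E_\text{image}$: a length-normalised line integral along the polygon of
  $w_\text{border}(1 - B(p)) + w_\text{gradient}\,C(p)$, where $B$ is the
  edge-strength image and $C$ the background-subtracted image. It is low
  when the contour follows strong edges over dark pixels.
* $E_\text{shape}$: an area bias
  $w_\text{area}\,((A - A_\text{exp})/A_\text{exp})^2$ that favours cells
  near the expected area $A_\text{exp}$, plus a regularity penalty
  $\kappa \sum_j (R_{j+1} - R_j)^2 / \bar R^2$ (circular sum). The
  quadratic form of the area bias is the simplest symmetric penalty that
  "prefers a typical cell size" without forbidding outliers.
* $E_\text{surface}$: interior evidence — the mean over the polygon's
  interior pixels of $w_\text{content}(1 - \text{content}) +
  w_\text{border-in}\cdot\text{border}$. Interiors should look like cell
  content and should not contain cell-border response. This term is what
  keeps crowded clumps from being under- or over-segmented when the
  contour evidence alone is ambiguous. We normalise by interior area
  (a mean, not a sum) so that the term does not trivially grow with cell
  size; the weights slot also keeps an unused `w_term` entry so a
  line-termination term can be added without changing the interface.

During deformation the centre never moves and each ray's radius is chosen
by minimising a one-dimensional approximation of $E$ along the ray (tip
boundary cost + running interior mean + a per-ray area bias that treats
the snake as a circle), computed in a single cumulative pass. Ties break
towards the smaller radius. The raw per-ray argmins are then regularised:
at most three passes of a circular moving average with the relative change
between adjacent radii clamped to 33%. The exact three-term energy is
evaluated once on the final contour. A seed whose rays mostly leave the
image yields a `degenerate` snake which the filters discard.

## The per-frame pipeline

Helper images come first: the background is estimated by grey-scale
morphological closing with a disc larger than any cell (closing, because
cells are *darker* than their surround) followed by Gaussian smoothing;
the clean image is the raw minus background, re-centred at 0.5; the
foreground mask is an Otsu threshold on the darkness image with hole
filling and small-object removal; the border image is the Sobel gradient
magnitude of the smoothed clean image; the content image is the smoothed
darkness restricted to the foreground. The exact filter chain is
deliberately configurable (`preprocess_params()`) — these are pragmatic
reconstructions of standard practice, not a claim that this specific
chain is canonical.

Seeds are placed at local minima of the smoothed border image inside the
foreground (cell interiors are flat, so edge response dips at centres),
at local maxima of the content image, and — when a previous frame is
available — at its detections' centroids. Minima shallower than 5% of the
smoothed image's dynamic range are discarded; they are numerical ripples,
not cells. Each seed grows a snake; its centroid then re-seeds one more
growth (a single relocation round buys most of the benefit at bounded
cost). Candidates pass hard filters (area within
$[0.2, 4] \cdot A_\text{exp}$, at least 60% of the interior inside the
foreground mask, non-degenerate), are ranked by energy plus soft penalties
for area deviation and foreground deficit, and accepted greedily in rank
order, rejecting any candidate overlapping an accepted interior by more
than 30% of the smaller area. Later iterations re-seed only the
not-yet-covered foreground (plus at most two random seeds per uncovered
blob, from a seeded RNG), so the accepted set only ever grows; iteration
stops at 98% coverage, at an empty seed set, or after 4 rounds.

## Tracking

Frame-to-frame correspondence is a linear assignment problem over an
augmented square cost matrix: association costs
$d/d_\text{max} + \lambda_s\,|A_i - A_j|/(A_i + A_j)$ (forbidden beyond
$d_\text{max} = 40$ px), and appearance/disappearance costs
$\lambda_b (1 + d_\text{border}/d_\text{cap})$ that make interior
appearances expensive and border crossings cheap. The solver is an exact
Jonker–Volgenant shortest-augmenting-path implementation written for this
package (its optimality is tested against exhaustive enumeration on
hundreds of random instances).

Clumped cells move together, so after a first solve each cell's expected
displacement is estimated as the mean displacement of its $k = 4$ nearest
assigned neighbours, and association costs are lowered by
$\mu\,e^{-\|v_{ij} - \bar v_i\|/\sigma}$ (clamped at zero, forbidden
entries untouched; $\mu$ defaults to half the median finite association
cost, $\sigma = 5$ px). Solving and adjusting alternate — the adjustment
is always applied to the *original* matrix using the latest assignment —
until the assignment stabilises or 5 rounds pass. This neighbourhood-
preserving correction is what survives collective colony drift that
defeats a pure independent-motion model. Gaps are deliberately not
bridged: a cell missing for one frame gets a fresh identity, because only
consecutive-frame assignment is defined and silent gap closure is a
common source of invisible identity errors.

## Evaluation

Metrics deliberately work on cell centres, not pixels. Per frame, result
and ground-truth cells match when they are mutual nearest neighbours
closer than `max_dist` (default 8 px at a 512×512 scale — about half a
typical cell radius; the threshold is configurable because annotation
conventions differ). Segmentation precision/recall/F follow, with
*facultative* ground-truth cells (edge cells, questionable objects)
removed from both numerator and denominator so that algorithms are
neither penalised nor rewarded for them. Tracking is scored on *links* —
a cell's presence in two consecutive frames; a result link is correct
when both endpoints match ground-truth detections of the same identity.
Long-term tracking applies the same logic to a single link from the first
to the last frame. The two can disagree in either direction: a swap that
later swaps back ruins four links but no long-term identity, which is why
both are reported.

## Parameter learning

The delicate parameters are the energy weights. Given ground-truth
contours, `contour_cost()` grows a few snakes from seeds jittered around
each contour's centroid (3 seeds within 3 px by default) and returns the
root mean square of all contour match measures, where the match measure
is the Jaccard distance $1 - A(S_\gamma \cap S_\theta)/A(S_\gamma \cup
S_\theta)$ on rasterised interiors — bounded, zero at identity, and
indifferent to parametrisation. `ranking_cost()` instead grows many
candidates per contour, lets the ranking pick one, and scores the picks —
so it measures the ranking weights, with `select = "random"`/`"best"`
baselines available for paired comparisons under a common seed.

Costs are minimised by box-constrained simulated annealing: geometric
cooling from $T_0 = 1$ by 0.95 per step, Gaussian proposals at 5% of each
bound range, reflection at the bounds, best-so-far always retained (an
anytime algorithm — the result is never worse than the initial point).
The budget is counted in cost evaluations, not wall-clock time, so runs
are deterministic under a seed; the default is 500 evaluations. At
substantially reduced budgets the schedule spends most of its time above
the exploitation temperature, so budgets below roughly 150 evaluations
give noticeably less reliable recovery from poor starting points — the
package's own acceptance experiments use 150.

## The synthetic generator

`render_movie()` draws near-round ellipses (axis ratio at most 1.3,
matching yeast roundness) with a flat dark interior (0.35), a thin darker
rim (0.15), a bright halo (0.90) on a 0.70 background, and additive
Gaussian noise ($\sigma = 0.02$) — the three brightfield facts above, in
their simplest faithful form. Cells move by colony drift plus per-cell
jitter with pairwise-repulsion overlap resolution; divisions bud a
daughter at half the mother's radius that grows 5% per frame; cells
whose centre is within one radius of the frame edge are flagged
facultative. Frames, label masks, the ground-truth table and the lineage
table are generated together and are exactly consistent; everything is a
deterministic function of the scene seed. `make_benchmark_suite()` fixes
seven deterministic scenes (sparse cells, a small colony, a translating
colony, two colonies, merging colonies, a divisions-heavy scene, one
large dense colony) at 256–320 px frame sizes and 3–10 frames, the
problem sizes the package's tests and acceptance experiments use.

What the generator does *not* emulate matters for interpreting green
tests: there is no optical point-spread function, no defocus ring
structure beyond the single halo, no illumination drift, no debris, and
contrast is stronger and noise weaker than in difficult real acquisitions.
Passing on these scenes demonstrates the algorithms' correctness and
their behaviour under crowding, drift and division — it does not certify
performance on any particular microscope's output, which is what the
configurable preprocessing and the parameter learning are for.

## Numerical choices and edge cases

* Coordinates are 0-based `(x, y)` with pixel centres at integers; images
  are matrices in `[0, 1]` (any bit depth is normalised on load).
* Star polygons are rasterised exactly (polar chord test per pixel);
  an interior that rasterises to zero pixels is an error, not a zero.
* Constant images yield an empty foreground and no seeds rather than
  errors; blank frames segment to an empty detection table.
* Argmin ties during deformation break towards the smaller radius;
  ranking ties break towards larger area, then input order; equal-cost
  assignments resolve to the first pairing in index order (the solver is
  deterministic).
* `d_max` forbids associations outright (`Inf`), so the solver can never
  trade a forbidden association against appearance costs.
* All randomness (seeding strategies, learning, the generator) flows
  through explicit integer seeds, and package functions restore the
  caller's RNG state.

## Known limitations

Rod-shaped cells violate the star-shape assumption. Mother–daughter
lineage is not inferred (divisions simply appear as new identities), gaps
are not bridged, and tracking parameters are not learned — learning
covers contour and ranking parameters only. The evaluation is centre-based
by design and will not detect small boundary errors.
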
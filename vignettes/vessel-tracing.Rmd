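---
title: "Separating retinal vessel networks into rooted trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating retinal vessel networks into rooted trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesseltrace)
```

## The model

Retinal vessels form a set of disjoint rooted trees: each tree enters the
retina at the optic disk and branches outward, but in a 2-D fundus
projection trees cross each other, so a binary segmentation of the
vasculature is one connected tangle. The tracing problem is to assign every
piece of vessel to the tree it belongs to.

`vesseltrace` treats this as semi-supervised node labeling on a graph. The
skeleton of the mask decomposes into *segments* (maximal chains of
2-neighbor skeleton pixels bounded by terminals or branchings); segments
are the graph's nodes, and segments sharing a junction are mutually
connected, so a junction with $m$ incident segments contributes an
$m$-clique. Terminals inside the optic-disk region are *roots*; the number
of trees equals the number of roots, and tracing becomes propagating root
labels across the graph:

$$Y^{(t+1)} = \alpha\, S\, Y^{(t)} + (1-\alpha)\, Y^{(0)},\qquad
  S = D^{-1/2} W D^{-1/2},$$

with $W$ a symmetric non-negative affinity over segments (zero diagonal),
$D$ its degree diagonal, $Y^{(0)}$ one-hot on root rows and zero elsewhere,
and $\alpha \in (0,1)$. For $\alpha < 1$ the spectral radius of $\alpha S$
is below one, so the iteration converges to
$(1-\alpha)(I-\alpha S)^{-1}Y^{(0)}$; the package implements both the
iteration and the closed form, and tests them against each other. Labels
are hardened by row-wise argmax; rootless components stay unassigned.

All contextual knowledge lives in $W$. With $\theta \in [0^\circ,
180^\circ)$ the angle between the outward orientations of two segment ends
at a junction ($180^\circ$ = straight continuation), three shape functions
are used ($k = 5$, $\theta_c = 80^\circ$):

$$f_1(\theta) = \begin{cases}
 -\sin^k\theta & \theta < \theta_c\\
 -\sin^k\theta_c & \theta_c \le \theta < \theta^*\\
 k\cos\theta & \theta^* \le \theta < 180^\circ
\end{cases}\qquad
f_2(\theta) = k\cos\theta,\qquad f_3(\theta) = k + k\sin\theta,$$

and edge weights are $e^{-f_i(\theta)}$, so smoother continuations always
get larger affinity. For the $\theta^*$ breakpoint we take $\theta^* =
\arccos(-\sin^k\theta_c / k)$ (about $100.7^\circ$ at the defaults), the
unique value making $f_1$ continuous — the superficially plausible
alternative of halving the argument jumps by more than 1.3 at $k=5$ and is
rejected; a `theta_star` override exists for exploration.

Junction cliques are weighted by size. Ordinary 3-cliques (branchings) use
$e^{-f_1}$ on surviving edges. 3-cliques that could only be ordered by the
deadlock rule hide either a vessel terminating on another (case B) or a
crossover wrongly skeletonized into two 3-cliques (case C, connector
$\le$ `C_critical` = 10 px); in both, the two surviving edges to the
pre-ordered member are contrasted — $e^{-f_1}$ for the better-aligned pair,
$e^{+f_1}$ for the other. 4-cliques pair their four junction-entry pixels
by the unique chord pairing that intersects inside the convex hull; the
paired segments get $e^{-f_2}$, everything else $e^{-f_3}$ (for obtuse
angles every favorable weight dominates every unfavorable one, which the
tests verify by grid sweep). 5/6-cliques seed two groups with the two
highest-order members and attach each remaining member to the seed with
the larger junction angle; in-group edges get $e^{-f_1}$, cross-group
$e^{+f_1}$ — the $e^{+f_1}$ choice (weights $\le 1$ rather than a hard
zero) keeps the matrix pattern symmetric with the 3-clique rule and is
configurable in spirit: a hard zero changes results only marginally
because $e^{+f_1}\le 1 \ll e^{k}$.

## Ordering and simplification

The modified Shreve scheme assigns every leaf segment order $\mu = 1$ and
lets orders flow rootward: a $k$-clique fires once $k-2$ (two for
3/4-cliques, three for 5, four for 6) of its non-root members are ordered,
and every still-unordered member receives the sum of the incoming orders.
Root segments never act as incoming, so propagation stops there; on a
crossover-free tree the root's order is exactly the leaf count (the classic
Shreve magnitude), which the suite checks on 1000 random trees. Junctions
with only two incident segments — which arise after spur removal — pass
the order through unchanged.

Two situations stall the flow. A 3-clique with a single ordered member
(order $\mu$) is a *deadlock*: among all such cliques, the one whose two
unordered members meet at the smallest angle fires first and both receive
$\mu + 1$; ties break on the junction's (row, col). If neither a clique
rule nor the deadlock rule applies but some clique still has an ordered
member, the package fires the first such clique in scan order with
$\max(\mu) + 1$ — an extension needed for skeletons whose topology falls
outside the clean taxonomy; pure rootless cycles raise an error instead.
When more members are ordered than a rule's arity (possible in crossover
chains), the earliest-ordered ones act as incoming.

Simplification then prunes each clique to the complete bipartite edge set
between its maximal-order members ($V_{CH}$) and the rest, removing
sibling-sibling redundancy. Cliques whose members all tie keep their edges
with a warning. Simplification runs before weight assembly, so $W$'s
sparsity pattern is the simplified edge set.

## Skeletonization choices

Thinning uses the Guo–Hall two-subiteration scheme rather than Zhang–Suen:
the latter erodes the free ends of near-diagonal strokes by 15+ pixels,
displacing vessel terminals away from the disk region (measured directly
during development; Guo–Hall keeps tips within ~1.5 px at every
orientation). A redundant-pixel pass then deletes pixels whose 2–3
neighbors form a single 8-connected blob — the staircase/triangle
thickenings that would otherwise masquerade as branching pixels — leaving
a minimal skeleton; junction centers (neighbors in two or more blobs) and
endpoints are untouched by construction. Mutually adjacent branching
pixels are merged into one junction at their centroid, since thick
junction blobs routinely classify as several branching pixels. The radius
at a skeleton pixel is the Euclidean distance-transform value of the
original mask (checked against an exhaustive nearest-background search on
random blobs).

Spur removal deletes connector segments bounded by two 3-way junctions
when they are short (`C_critical` = 10 px) and lie at a small acute line
angle to their flanking branches (β, mean over the two junctions of the
smallest such angle, $\le$ `beta_critical` = 70°), then merges the two
junctions into the 4-way crossover they came from. Restricting the rule to
3-way/3-way junction pairs is deliberate: it makes the repair exactly
inverse to the known artifact and caps the merged junction at four
members, so cascaded merges can never produce an unsupported (7+) junction.
The pass iterates to a fixed point, hence is idempotent.

Orientation estimation without an intensity image uses centered chain
secants (window 5 px) averaged over the last 10 points of the end, with a
linear extrapolation of the direction trend to the end index — on a
30-pixel-radius quarter circle the plain mean lags the endpoint tangent by
about 9° (half the averaged arc) while the extrapolated estimate is within
1°. With an image, per-point directions come instead from the eigenvector
of the smaller-magnitude eigenvalue of the Gaussian-scale Hessian
(σ = 2 px), sign-aligned with the secants. Antiparallel directions are
capped at 179.999° to respect the half-open domain of $f_1$.

## The synthetic generator

Real ground truth for tracing is scarce, so the generator builds scenes
with known per-pixel tree identity. Each tree is a recursive binary
structure: a trunk along a given axis, children deviating by angles drawn
from 20–40°, branch lengths decaying geometrically (factor 0.78), and mild
per-step curvature jitter; the leaf count is drawn from the complexity
class (LOW 2–5, MEDIUM 5–10, HIGH 11–16), and since a tree's Shreve root
order equals its leaf count, the class directly controls ordering
complexity. Trees are fanned counter-clockwise around a central disk with
separation γ, trunks starting just inside the disk boundary so each tree
contributes exactly one root; when $n\gamma > 360^\circ$ the separation
wraps to $360^\circ/n$ (a consequence: the spread-angle benchmark's five
largest γ settings all realize 45° at 8 trees, so spread-driven difficulty
is only observable at smaller tree counts). Scenes render at 512×512 with
3-px strokes by default; trees that would leave the canvas are rescaled
with a warning. Crossing pixels keep the identity of every owning tree.

What the generator does *not* emulate: intensity/texture (scenes are
binary, so Hessian orientations go unexercised end-to-end), vessel width
variation along branches, segmentation noise (broken or merged branches),
and the hand-drawn building blocks of the original benchmark — absolute
accuracy numbers on these scenes therefore do not transfer to fundus data;
directional comparisons (parameter ablations) are the intended use.

## Controlled experiments and their problem sizes

`benchmark_simplification()` regenerates the tree-count benchmark
(3–12 trees, γ = 30°, a third of trees per complexity class, ten 512×512
images per count) and traces each image under three configurations: the
full pipeline at $k=5$, without graph simplification, and at $k=1$.
Accuracy is the fraction of segments assigned to their majority-overlap
truth tree under the best label correspondence (maximum-weight bipartite
matching) — a segment-level proxy, not the DIADEM topology score. At these
settings dropping $k$ to 1 costs about one accuracy point on average,
while toggling simplification alone is accuracy-neutral within noise: the
un-simplified graph still receives every clique-rule weight, and the edges
simplification removes carry either tiny ($e^{-f_3}$) or same-tree
sibling weights. A topology-sensitive score penalizes those extra edges
much harder than per-segment accuracy does, which is worth keeping in mind
when comparing ablations across metrics.

`disjoint_scenes()` draws 2–3 tree scenes at maximal spread and keeps those
whose rendered trees share no pixel and contribute one root each
(re-drawing otherwise — this enforces the experiment's stated premise, not
a result); on such scenes tracing must be and is exact, since every
component contains exactly one root. `crossover_experiment()` traces
two-vessel crossings at angles uniform in 60–120°; each vessel anchors in
its own small root disc placed slightly inward from the stroke tip
(skeleton tips round off by a few pixels even under Guo–Hall).

## Degenerate inputs and numerical conventions

All-zero masks, masks with values outside {0,1}, skeletons with no root
terminal, and junctions with seven or more incident segments raise
immediate errors (the weight taxonomy stops at 6-cliques). Degenerate
4-clique geometry (three collinear entry pixels) falls back to angle-based
pairing with a warning. One-pixel segments take their orientation from the
junction geometry. Isolated nodes produce zero rows in $S$ and stay
unassigned unless they are roots. The propagation stopping norm is
Frobenius; convergence tolerance 1e-5, iteration cap 10000. Label ties
break toward the strongest-affinity neighbor, then the lowest label id;
root rows are re-asserted at assignment time rather than clamped during
iteration.

Self-intersections inside one traced tree (its own branches crossing) are
resolved before SWC export by a maximum-angle spanning tree rooted at the
root segment: each edge carries its junction angle and the spanning tree
keeps the smoothest continuations, so a conflicted segment stays attached
to the chain it continues best. This is a global formulation of the
attach-to-the-larger-angle rule and guarantees acyclicity by
construction; trees that were already acyclic pass through
unchanged.

## Segmentation fusion

The appendix-style fusion consumes three masks of one scene: a balanced
(highest-F1) segmentation as backbone, a high-recall one, and an
unsupervised one that keeps close parallel vessels separate. Per-segment
median diameters (twice the distance-transform radius) are summarized by
their mean $d_m$ and standard deviation: backbone segments thinner than
$d_m$ are replaced from the high-recall skeleton (where small branches
survive unbroken), segments thicker than $d_m + \mathrm{sd}$ from the
unsupervised skeleton (where merged parallel pairs are separated; all
matching thin candidates are taken). Correspondence between skeletons is by overlap within a 2-px dilation
band, at
least half the shorter segment; replacement endpoints snap to the nearest
retained skeleton pixel within 3 px. Remaining disconnected components are
bridged by fitting a cubic in the component's principal-axis frame and
extending it 1 px at a time (30-px budget, straight-line fallback below 4
pixels); bridge radii are inverse-distance convex combinations of the two
donor endpoints, so they stay within the donor range, and a failed bridge
leaves the component untouched — the component count never increases.

## Known limitations

Junctions of 7+ segments abort rather than guess. The ordering's overshoot and residual-deadlock extensions are
pragmatic heuristics beyond the clean clique taxonomy; in dense multi-crossing regions (several 4/5-cliques connected
by very short segments) the ordering-derived $V_{CH}$ can disagree with
the geometric pairing and simplification may sever a true continuation —
the main residual error mode on crowded scenes. Orientation in binary mode
relies on chain geometry only; 2-px-scale stubs give noisy angles. The
evaluation metric scores segments, not tree topology, and is insensitive
to errors that merely add redundant edges.
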
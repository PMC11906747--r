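---
title: "Graph-based stripe calling and loop-extrusion simulation: methods"
author: "stripekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based stripe calling and loop-extrusion simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripekit)
```

## The problem

Architectural stripes are the flare-shaped patterns on chromatin contact
maps produced when one loop-extrusion anchor stays fixed (typically at a
CTCF site) while the other translocates. Heatmap-based callers need a dense,
smooth signal; sparse assays such as HiChIP instead yield discrete loop
calls. `stripekit` calls stripes directly from a loop set: a stripe is a
vertex of the loop-interaction graph together with a chain of partners on
one side of it.

## The interaction graph

All anchor coordinates are binned at a working resolution (default 5 kb,
the resolution loop callers typically emit). Binned anchors that share at
least 1 bp are merged transitively into one vertex; bins that merely touch
do not merge (coordinates are 0-based half-open throughout, so touching
intervals share no base). A vertex's position is the integer floor of its
span midpoint. Loops whose anchors fall in two different vertices become
edges; parallel loops collapse into one edge whose weight is the number of
collapsed loop records, and loops falling entirely inside one vertex are
dropped (their count is reported). The graph is built per chromosome;
ties between equal positions (impossible within a chromosome, but guarded)
break by span start, then vertex id, so construction is deterministic and
invariant to input order.

## Candidate stripes and their per-leaf metrics

Every vertex $v_0$ with at least one downstream neighbour anchors a
horizontal candidate; every vertex with an upstream neighbour anchors a
vertical one. The neighbours on that side are the candidate's *leaves*
$v_1, \dots, v_k$, ordered by ascending distance. For leaf $i$:

* **Stripe length** $d_i = |pos(v_i) - pos(v_0)|$, clamped to at least
  1 kb. Equidistant leaves (possible only through clamping) are pushed up
  by one clamp unit so $d$ is strictly ascending.
* **Relative gap** $g_i = -\ln\!\big((d_i - d_{i-1})/d_i\big)$ with
  $d_0 = 0$; the difference is also clamped at 1 kb so the logarithm is
  always finite. $g_1$ is identically 0. The natural logarithm is used; the
  gap quantile below is rank-based and therefore base-invariant, and only
  the termination threshold (configurable) is base-sensitive.
* **Gap quantile** $q_{gap,i}$: the inclusive empirical CDF of $g_i$
  within the pool of *all* gap values of *all* candidates in the dataset,
  both directions, all chromosomes. Values lie in $(0, 1]$.
* **Stripe score**: the running quadratic mean
  $\sqrt{\tfrac1i \sum_{j \le i} q_{gap,j}^2}$ — the cumulative quality of
  the stripe up to leaf $i$.
* **Cross score**: each leaf potentially belongs to two orthogonal
  stripes. The cross score of $v_i$ in direction $D$ is the ratio of its
  stripe score in $D$ to the stripe score, within the orthogonal candidate
  anchored at $v_i$, at the slot occupied by $v_0$ (that slot exists
  because the edge $(v_0, v_i)$ does). The denominator is clamped below at
  $10^{-9}$.

A stripe ends at leaf $i$ if $g_{i+1}$ drops below 0.05 (default), or with
the last leaf. The quantile pool is computed once, before trimming and
merging, and not recomputed afterwards.

## Merging, filtering, selection

Two *adjacent* same-direction stripes are merged when their domains
(anchor to farthest trimmed leaf) overlap by at least 1 bp, their anchor
regions are at most 10 kb apart, and their lengths differ by no more than
200 kb; merging repeats to a fixed point. Requiring anchor proximity is a
deliberate reading of "adjacent": with domain overlap alone, two distant
stripes whose domains happen to overlap (for instance a stripe anchored at
a domain boundary and another anchored 200 kb inside it) would collapse
into one call, which destroys exactly the colocalized fine structure the
graph approach is meant to expose. After a merge the surviving anchor is
the one nearer the diagonal extreme (smaller coordinate for horizontal
stripes, larger for vertical); distances, gaps, quantiles and stripe
scores are recomputed from the surviving anchor over the pooled leaves.
Cross-score denominators are retained per leaf from the candidate each
leaf came from, because the orthogonal candidate anchored at an absorbed
leaf need not contain the merged anchor (no edge is guaranteed); the
numerators are recomputed.

Final selection keeps stripes with at least 2 leaves, length at least
20 kb, terminal stripe score at least 0.45 and mean cross score over the
trimmed leaves at least 0.9. All four thresholds are configuration fields
(`stripe_call_config()`).

## Overlap and annotation statistics

Two loops overlap when, after extending the query loop's anchors by a
tolerance (15 kb is the usual choice) on both sides, both anchor pairs
share at least 1 bp. Overlap matrices report, per ordered set pair, the
percentage of row-set loops with at least one match in the column set;
one-to-many matches count once, so the matrix is asymmetric by design.
Stripes overlap when they share orientation and their anchor regions are
at most 10 kb apart, measured edge to edge (midpoint distance would
penalise wide anchor clusters). Striping domains overlap when they share
1 bp after symmetric expansion; the expansion defaults to 10 kb, a value
chosen for consistency with the stripe-anchor rule, and is exposed because
conventions differ. The colocalization fraction is the proportion of
stripes whose domain lies fully inside the strictly larger domain of
another stripe. Loops are annotated Promoter–Promoter when both anchors
intersect a promoter, otherwise Enhancer–Promoter when one anchor carries
an enhancer and the other a promoter; PP takes precedence for anchors
carrying both labels.

## CTCF orientation

Motif hits arrive with log2-scale scores and a pointing direction ("right"
= downstream; a flag inverts the convention since strand symbols are not
standardised across motif scanners). The probability that an anchor's
motif content points right is

$$P_{right} = \frac{\sum_{\text{right hits}} 2^{score}}
                   {\sum_{\text{all hits}} 2^{score}},$$

computed after subtracting the maximum score (which cancels exactly and
keeps the powers finite). A simpler presence test — any hit scoring at
least 7.0 — is also exposed. For loop-level classification each anchor is
discretised to its majority orientation at 0.5 (ties to "right"): a
right-pointing left anchor facing a left-pointing right anchor is
*convergent*, the canonical configuration at extrusion-anchored loops.

## The loop-extrusion simulator

The simulator is a 1D lattice Monte Carlo model: `n_monomers` polymer
beads (default 1000, at 5 kb per bead), on which extruders occupy leg
pairs $(l, r)$, $0 \le l < r < n$. The energy is

$$E = -c_{fold} \sum_{\text{extruders}} \ln(r - l)
      \; + \; c_{cross} \cdot \#\{\text{crossing pairs}\},$$

where two loops cross when $l_i < l_j < r_i < r_j$. The folding term
rewards loop growth, the crossing term (default 10) suppresses
pseudo-knotted configurations while leaving nesting free; extruders may
share a monomer, keeping the sampler ergodic. Each sweep, every extruder
proposes a ±1 move of one random leg, accepted by Metropolis at the
current temperature; the fast class (default 5 extruders vs 100 slow)
makes 10 proposals per sweep. With a small per-sweep probability (default
0.002) an extruder unbinds and proposes rebinding at a uniform loading
site with legs $(x, x+1)$, also Metropolis-accepted, so the temperature
parametrises the rebinding probability. The temperature anneals linearly
from 4 to 1 over the run (8×10⁴ sweeps by default); states are sampled
every 400 sweeps after a 4×10⁴-sweep burn-in, yielding exactly 100
samples. All randomness flows through R's RNG, so a seed reproduces a run
bit for bit; the C++ core's incremental energy bookkeeping is checked
against an independent R implementation of $E$.

CTCF barriers act kinetically, not energetically: at a barrier monomer a
leg attempting to *leave* in the blocked direction is vetoed with
probability equal to the barrier strength (left-moving legs are blocked by
right-pointing motifs and vice versa, which anchors convergent loops);
landing on a barrier is free. Strength-1 barriers are therefore strictly
impassable, and legs pin exactly at the barrier monomer, placing contact
weight at the barrier position. Barrier strengths derive from anchor
orientation probabilities as $c_{bind} \cdot P_{right}$ (left block) and
$c_{bind} \cdot P_{left}$ (right block), clamped to $[0,1]$.

The contact map counts each sampled extruder at $(l, r)$ and its
transpose, optionally adding a $1/|i-j|$ polymer background scaled to a
chosen fraction of the loop weight. This 1D aggregation deliberately
replaces a 3D polymer reconstruction stage (inverse-distance heatmaps from
molecular dynamics), which is out of scope here; the map is a sufficient
substrate for the validation metrics (Pearson correlation restricted to
loop pixels; Spearman correlation of Gaussian-smoothed maps over the upper
triangle) and for exporting recurrent leg pairs as a BEDPE loop set that
feeds straight back into the stripe caller.

### Choices where the design was open

* **Folding/crossing coefficients.** Only qualitative guidance exists for
  these ("defaults" of external software); we default to
  $c_{fold}=1$, $c_{cross}=10$. Demonstrations that require barriers to
  visibly anchor loops (convergent-pair corner enrichment, stripe
  emergence) run in a *strong-folding regime*, $c_{fold}=5$: with
  $c_{fold}=1$ the outward drift near the annealing temperatures (4→1) is
  a ~3% acceptance bias, too weak to hold a leg at a wall, and corner
  pixels stay empty. The regime switch changes pinning sharpness, not the
  mechanism.
* **Annealing schedule**: linear between the stated endpoints.
* **Fast class**: implemented as proposal multiplicity (10 per sweep), the
  simplest mechanism that makes one population diffuse faster.
* **Demonstration scales**: the barrier demonstrations use 100-monomer
  lattices, 16–20×10³ sweeps with sampling confined to the cool tail of
  the schedule, and 2–4 extruders; small extruder counts matter because
  the crossing penalty otherwise lets a second extruder stack one monomer
  off the wall and claim the longer extent.

## Synthetic fixtures

`make_stripe_loopset()` emulates what a loop caller emits over a
stripe-rich chromosome: each planted stripe is a bin-aligned anchor with
4–6 leaves whose gaps are `resolution × (1 + Geometric)` with mean 10 kb;
anchors are one resolution unit wide and grid-aligned (as binned loop
calls are). Noise loops draw one anchor uniformly over a 250 Mb
chromosome (the scale of the largest human chromosome) and a span
resampled from the planted leaf offsets, so detection cannot key on span
alone. The chromosome is named `chr_sim` to avoid accidental mixing with
real data. Generators are pure functions of spec and seed.

What the fixtures do *not* emulate: the distance-dependent background
contact frequency of real Hi-C/HiChIP, peak-anchored loop enrichment, and
anchor-width heterogeneity. Passing the planted-recovery tests therefore
shows the pipeline recovers chain structure against unstructured
background, not performance on real libraries.

A known quantitative consequence: uniformly placed noise anchors
occasionally share a 5 kb bin (or attach to a planted leaf from its far
side), and every such vertex with two same-side partners is — by the
algorithm's own definition — a legitimate candidate stripe. Because the
gap pool contains one $g_1 = 0$ per candidate, the pooled zeros compress
all quantiles into roughly $[0.8, 1]$, so the 0.45/0.9 thresholds reject
almost none of these two-leaf coincidences. At the fixture's default
density this costs roughly 3–4 spurious calls per 20 planted stripes
(recall stays at ~1.0, precision lands near 0.8). On real data the loop
set is peak-anchored rather than uniform and the thresholds were tuned to
that regime; for the fixtures we report the measured operating point
rather than re-tuning anything toward it.

## Numerical and degenerate-input behaviour

Empty loop files are an error only if they contain data lines and none is
valid; inter-chromosomal and malformed records are skipped and counted.
An empty loop set yields an empty stripe table with a warning. A quantile
pool is never empty when a candidate exists (every candidate contributes
$g_1$); a degenerate all-zero pool gives every leaf $q = 1$. Cross-score
denominators are clamped at $10^{-9}$; distances and gap differences at
1 kb. The overlap matrix reports `NA` for empty row sets, as do the
colocalization fraction and the 3D-peak fraction for empty inputs.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script work at deliberately small
scales: fixtures of 6–20 planted stripes (~300 loops) on the 250 Mb
simulated chromosome, overlap oracles on 500-loop sets, lattices of
60–400 monomers, and 10–50 replicate seeds per statistical claim. These
sizes were chosen so each claim is testable in seconds on one CPU while
remaining in the regime where the asymptotic statements (diffusion
scaling, enrichment ratios, recovery rates) already hold.
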
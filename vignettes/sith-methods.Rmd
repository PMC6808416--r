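---
title: "Measuring spliceomic intratumor heterogeneity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spliceomic intratumor heterogeneity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceith)
```

## The model

Intratumor heterogeneity (ITH) — the coexistence of distinct cell
subpopulations within one tumor — leaves a footprint in the spliceome:
subclones diverge in their usage of alternative donor and acceptor sites.
`spliceith` scores this footprint from splice-junction read counts alone.
The design is deliberately annotation-free: cancer transcriptomes are rich
in intron retention, splice-site mutations and novel junctions that defeat
transcript-level quantification, whereas a junction table from a spliced
aligner captures them all as coordinates.

The score compares a tumor sample P to a normal reference Q of the same
tissue. Normal tissue has innate splicing heterogeneity of its own;
measuring divergence *from the normal* rather than absolute entropy
subtracts that baseline, leaving the perturbation acquired during cancer
progression.

**Splicing units.** A splice junction is an intron: chromosome, 1-based
inclusive coordinates of its first and last intronic base (the STAR
convention, kept everywhere internally so the input dialect needs no
conversion), and a strand class `+`, `-` or unknown (`.`). Junctions
sharing a splice-site coordinate — donor *or* acceptor — on the same
chromosome and strand class are grouped transitively: units are the
connected components of the graph whose vertices are splice-site
coordinates and whose edges are junctions. The transitive rule matters: a
junction that shares its donor with one neighbour and its acceptor with
another must land in a single unit, so that units partition the junction
set. Strand classes never merge, because antisense overlapping genes share
coordinates without sharing splicing events.

**Usage distributions.** Within unit $k$, the counts over its $N_k$
member junctions are normalized to $P_k(i) = \mathrm{CNT}_k(i) / \sum_j
\mathrm{CNT}_k(j)$ — the fraction of reads supporting each alternative
site. A unit with counts $(5, 3, 2)$ has usage $(0.5, 0.3, 0.2)$.

**Harmonization and pseudo-counts.** Units are built on the union of both
samples' observed junctions, so unit $k$ denotes the same intronic region
in both. A site observed in only one sample appears with count 0 in the
other and receives a pseudo-count equal to $1/100$ of the *patching
sample's own* unit total (the denominator is configurable). Sites observed
in both samples are left untouched, and normalization happens after
patching. Two readings of "the corresponding splicing unit's total" are
possible — the patched sample's or the other sample's; we use the patched
sample's own total, which keeps the pseudo-count on that sample's own
scale and reproduces the worked count chain
$(5,3,2)/(4,0,6) \rightarrow (4,0.1,6)$.

**Divergence and the score.** Per unit, the Jensen–Shannon divergence
with base-2 logarithms:
$$\mathrm{JSD}(P_k, Q_k) = \tfrac12\,\mathrm{KLD}(P_k \| M_k) +
  \tfrac12\,\mathrm{KLD}(Q_k \| M_k), \qquad M_k = \tfrac{P_k + Q_k}{2},$$
with $\mathrm{KLD}(P\|M) = \sum_i P(i)\log_2 (P(i)/M(i)) \ge 0$ and the
$0\log 0 = 0$ convention. Base-2 logs bound each unit's divergence in
$[0, 1]$: 0 means identical usage, 1 disjoint usage. The sITH score is the
arithmetic mean over the $L$ usable units,
$$\mathrm{sITH}(P, Q) = \frac1L \sum_{k=1}^{L} \mathrm{JSD}(P_k, Q_k),$$
symmetric in $P$ and $Q$ and again in $[0,1]$. With a panel of normal
references, the per-reference scores are averaged (`sith_multi_ref()`).

## Tunable parameters

* `min_members` (default 2, junctions per unit). A singleton unit has a
  one-point usage distribution whose divergence is identically 0; keeping
  such units can only dilute the mean, so they are dropped by default. Set
  `min_members = 1` to keep them.
* `min_reads` (default 1, reads per unit per sample). A unit wholly
  unobserved in one sample cannot be pseudo-counted — the pseudo-count is
  a fraction of that sample's unit total, which is zero — so it is dropped
  and tallied under `absent_in_one_sample` rather than scored.
* `pseudo_denom` (default 100). The pseudo-count is `unit total / denom`.
* Log base is fixed at 2 so that unit divergences and sITH live on the
  interpretable $[0,1]$ scale.
* A sITH of a pair with zero usable units is reported as `NA` (an explicit
  undefined state), never as a silent 0; the per-reason drop tallies are
  part of every result.

The entropy measures share the same unit machinery: `transcript_entropy()`
is the mean base-2 Shannon entropy of per-gene isoform fractions, and
`intron_entropy()` the mean usage entropy over splicing units, filtered
with the same `min_members`/`min_reads` so both measures see identical
unit sets. The log base for the entropies is a package choice (base 2, for
consistency); the correlation between the two measures is base-invariant.

## What the synthetic data emulate

The package ships a generator so that the method's designed behaviours can
be exercised without any external sequencing data.

**Normal profiles** (`generate_normal_profile()`): `n_units` independent
splicing units (default 300), each a shared-donor group of 2–5 alternative
junctions, with usage drawn from a symmetric Dirichlet (concentration 1 =
uniform on the simplex) and integer counts drawn multinomially at a
Poisson total depth (mean 200 reads per unit). Draws are conditioned on at
least two junctions being observed, so every emitted unit survives the
default filters.

**Cell profiles** (`perturb_profile()`): a synthetic cancer cell moves
each unit's usage toward an independently drawn Dirichlet target with
mixing weight `perturbation` (default 0.8), and carries the *exact
expected* counts `usage × unit total`, deliberately fractional: the
perturbation models usage drift between clones, not sequencing noise, and
keeping counts exact makes the strength parameter the only signal dial.
An optional `novel_rate` adds tumor-specific junctions absent from the
normal (off by default).

**Mixtures** (`synthesize_mixture()`): a bulk sample of designed
heterogeneity level $i$ blends $i$ cells into the normal at 1% each,
$$\mathrm{MIX}(j) = \mathrm{NT}(j)\,(1 - i/100) +
  \sum_{l=1}^{i} \mathrm{SC}(l, j)/100,$$
exactly, per junction, over the union of junction sets; counts stay
fractional because the mixture is defined on count arithmetic, not on
resampled reads. `run_mixture_experiment()` generates one normal template,
a pool of 39 distinct cells, and for each level $i = 1..39$ and each of 10
replicates scores a random $i$-cell mixture against the normal — 390 rows
whose Spearman correlation of level vs sITH is the experiment's readout.
More cells mixed means more subclonal diversity by construction, so sITH
should rise with the level; it does, and the correlation exceeds 0.95
under the default parameters.

**Entropy validation** (`run_entropy_experiment()`): can heterogeneity
measured per intron stand in for heterogeneity measured per whole
transcript? Each synthetic gene carries 2–5 isoforms and 3 splicing
units; within a unit every isoform supports exactly one member junction
and every junction is supported by at least one isoform (a random
surjection). Junction usage is therefore a *coarsening* of isoform usage:
some isoform pairs are indistinguishable in a given intron, exactly the
reason the two measures correlate well but not perfectly on real gene
structures. Samples draw a heterogeneity level $h \in [0,1]$: the
representative isoform gets weight $1-h$, the minor isoforms split $h$ by
a uniform Dirichlet draw, and unit counts are the exact expected counts at
depth 1000. The default experiment is 20 random gene pools × 10 samples =
200 samples; the Pearson correlation between `transcript_entropy` (on the
fractions) and `intron_entropy` (on the derived junctions) is the readout.

**What the generator does not model**, and hence what passing tests do
not show about real data: single-cell dropout and coverage limits,
sequencing and alignment noise in junction discovery, correlated usage
across units on the same transcript, expression-level differences between
units (all units share one depth scale), and clonal evolutionary structure
among the cells (cells are independent perturbations of one ancestor).
Real-data scores also depend on aligner settings upstream of the junction
table.

## Numerical choices

* The printed form of the KLD carries a sign ambiguity in some sources; a
  negative-signed KLD would be $\le 0$ and incompatible with a $[0,1]$
  JSD, so the standard non-negative form is used throughout.
* $0 \log 0 \equiv 0$; per-unit JSD values are clamped to $[0,1]$ to
  absorb last-bit floating-point excursions at the boundaries.
* The grouped (vectorized) sITH pipeline is tested to agree with the
  unit-by-unit composition of the scalar operations to $10^{-12}$, and
  the JSD against an independent entropy-form oracle
  $H(M) - (H(P)+H(Q))/2$ to $10^{-12}$ (absolute).
* All generators are pure functions of their seeds, restore the caller's
  RNG state, and derive sub-seeds from a single master seed, so every
  experiment table is bit-reproducible.
* Problem sizes used by the shipped experiments — 300 units × depth 200 ×
  390 mixtures, and 200 entropy samples — were chosen as the smallest
  scales at which the designed effects are comfortably resolved; both
  experiments complete in well under a minute each on a laptop core
  (the mixture experiment in roughly half a minute).

## Known limitations

* sITH is a relative measure: it requires at least one normal reference of
  the matched tissue, and its absolute scale depends on unit filtering and
  sequencing depth, so scores are best compared within a cohort processed
  identically.
* Units are purely coordinate-derived; a coordinate chain can in principle
  link junctions of two adjacent genes into one unit. No annotation-based
  splitting is attempted.
* Whether singleton units should count toward $L$ is not settled;
  `min_members` exposes both behaviours (default: drop).
* The per-unit JSD is reported without any significance assessment;
  differential-splicing calling is out of scope.
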
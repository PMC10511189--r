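---
title: "Phylogenetic diversity maximization and the option value of biodiversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic diversity maximization and the option value of biodiversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdoption)
```

## The question

Biodiversity's "option value" is its capacity to supply benefits that are
unknown or unexploited today. Phylogenetic diversity (PD) — the summed
branch lengths connecting a species set on a phylogeny — is the standard
proxy for feature diversity, and hence a candidate proxy for option value:
if distinct lineages carry distinct features, conserving more PD should
conserve a wider variety of potential future uses.

`pdoption` implements a testable version of this argument. Species sets are
selected to maximize PD *with no knowledge of recorded uses*, and their
performance at capturing species with known uses (food, materials,
medicine, pets) is compared against null strategies: uniform random sets,
extinction-risk-weighted sets, risk-composition-controlled sets, and sets
prioritized by functional distinctiveness. If naive PD maximization
captures more utilized species than chance, that is evidence that PD would
also have captured today's benefits before they were known — the option
value link.

## Metrics

**Rooted Faith PD.** `pd(tree, taxa)` sums the lengths of all edges on
paths from the taxa to the root, each edge once. The rooted convention is a
deliberate choice: it makes PD of the full tip set equal the tree's total
branch length and makes the fair-proportion partition exact. The package's
greedy maximizer, ED scores and dispersion nulls all share this convention,
so PD bookkeeping is consistent across modules.

**Fair-proportion ED.** `fair_proportion_ed()` divides each edge's length
equally among its descendant tips and sums per tip. The conservation
identity (ED sums to total branch length) holds to floating-point accuracy
and is enforced by tests on a thousand random trees. Across a tree
ensemble, `ed_table()` reports the per-species median (the median over an
even number of trees is the mean of the two central values).

**EDGE.** `edge_score(ed, rl)` is `ln(1 + ED) + GE ln 2`, with the
global-endangerment ladder LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, EW = 5.
Extending the ladder to EW = 5 keeps EDGE consistent with the Red List
Index weights used by the risk-weighted sampler (VU = 2 ... EW = 5).
Data-deficient species have no defined GE; the package refuses to score
them rather than guess, and drops them from threatened-species universes.

**Dispersion SES.** `dispersion_ses()` asks whether a labeled species set
spans more or less PD than random sets of equal size. The null shuffles
species names across the tips of a fixed topology — equivalent to drawing
uniform tip sets of the same size — and the standardized effect size
`(PD_obs − mean_null) / sd_null` is computed per tree and averaged over the
ensemble. Negative values indicate phylogenetic clumping. Tiers use
standard-normal two-sided quantiles: `*` at 1.96, `**` at 2.576, `***` at
3.891.

## Selection strategies

`greedy_max_pd()` grows a set by always adding the species with the largest
PD increment. On trees this greedy procedure is *exactly optimal* for every
set size — the test suite verifies equality against exhaustive subset
enumeration on two hundred small trees — so "PD-maximizing set" means
exactly that. Two design choices matter:

* **Ties are broken at random (seeded).** On ultrametric trees every tip is
  equidistant from the root, so the first pick is always a tie; random
  tie-breaking is what makes replicate PD-maximizing sets differ while all
  attaining the same PD. Rank-based selection (`rank_select()`, used for
  ED/EDGE/FDist rankings) instead breaks ties lexicographically, because a
  published ranking is a single list.
* **A `secured` baseline.** For threatened-species prioritization, LC and
  NT species are treated as already conserved: their subtree counts as
  covered, and the greedy algorithm maximizes the *gain* in PD among
  threatened (VU/EN/CR/EW) candidates on top of that baseline.

Sample sizes are fractions of the universe, converted to counts by
round-half-up; the rule is exposed in one place (`round_half_up`) because
floor-vs-round changes published set sizes (e.g. 5% of 1491 species is 74
or 75 depending on the rule).

The stochastic comparators are `sample_weighted()` (sequential draws
without replacement, probability proportional to weight — used with Red
List Index weights or FDist scores) and `sample_rl_controlled()` (random
sets whose Red List composition matches a template PD-maximizing set
exactly, category by category).

## The synthetic study system

Real analyses of this kind rest on posterior tree samples and Red List
use-and-trade records. The generator replaces both so that every stage is
testable from code alone:

* **Trees** are pure-birth (Yule) simulations, grown forward until `n`
  lineages exist plus an `Exp(nλ)` tail, hence ultrametric with expected
  depth `Σ_{k=2}^{n} 1/(λk)` — a closed form the tests verify. Pure birth
  was chosen over birth–death because the analysis needs a realistic tree
  shape, not extinction dynamics, and the closed-form depth gives a sharp
  oracle.
* **Use labels** are drawn with an exact quota `round_half_up(prevalence ×
  n_tips)` and a clumping knob in [0, 1]: 0 draws tips uniformly, 1 takes
  the tips of the smallest clade that can hold the quota (trimmed by
  topological proximity to the clade root), and intermediate values fill
  that fraction of the quota from the clade scheme. The knob is calibrated
  behaviorally: uniform labels give dispersion SES centered on 0, fully
  clumped labels read as significantly clumped in essentially every
  replicate.
* **Red List categories** are i.i.d. multinomial draws. The default mix
  (LC 0.70, NT 0.09, VU 0.08, EN 0.05, CR 0.024, EW 0.001, DD 0.055) puts
  about 15% of species in threatened categories, matching the avian
  profile.
* **FDist** is a linear blend of standardized median ED with noise made
  exactly orthogonal to ED in-sample, so the realized Pearson correlation
  equals the configured target (default 0.11, the weak ED–functional
  distinctiveness association reported for birds), then shifted to be
  nonnegative. Default prevalences mirror the avian utilization profile
  (pets ~0.40 and strongly clumped; food ~0.145; materials ~0.012 and
  medicine ~0.006, both dispersed).
* **Seeds.** One master seed; every sub-step (each tree, each category's
  labels, the FDist noise, every replicate selection) derives its own
  stream by fixed offsets, so any sub-experiment is reproducible in
  isolation and identical configs give byte-identical output files.

## What the synthetic tests do and do not show

The generator reproduces the *structure* of the real inputs (tree shape,
prevalence, clumping, risk composition, weak ED–FDist correlation), not
their full biology. One consequence deserves emphasis.

For any fixed selection set *S* and a label set *L* placed uniformly at
random on *n* tips, the expected overlap is |S||L|/n regardless of how *S*
was chosen. Uniform labels therefore cannot prefer *any* selection
strategy: with the clumping knob at 0, greedy-PD capture SES is centered on
zero by construction, and the package's pipeline experiments confirm this
(mean SES ≈ 0 over replicates). A positive PD advantage for dispersed
benefit categories — the pattern reported for real birds and plants —
requires labels that are *biased toward evolutionarily distinct species*
(empirically, utilized species have elevated ED), which is an ED–label
association, not mere non-clumping. The clumping knob moves the label set
from uniform toward concentrated, so it can attenuate or reverse a PD
advantage (clumped, prevalent labels such as the "pets" regime yield
non-significant SES, which the pipeline reproduces), but it cannot create
the positive effect at its dispersed end. Demonstrating the positive link
on synthetic data would need an explicit distinctiveness-biased labeling
mode; this is a known limitation of the present generator, kept as-is so
that the null behavior of the pipeline remains exactly calibrated.

## Statistical layer

Capture counts are summarized per strategy × fraction × category with
empirical 95% intervals (2.5/97.5 percentiles of replicate counts —
counts are discrete and skewed at small sizes, so no normal approximation
is used). Strategy comparisons use SES against the configured null
strategy's count distribution. Order-level overrepresentation uses
uniform random sets of the observed category size; verdicts use type-1
empirical percentiles, with degenerate nulls (an order holding every
species, or upper ≤ lower) reported as `ns` since they carry no signal.
ED/FDist comparisons use Kruskal–Wallis with Dunn's pairwise z tests
(pooled ranks, tie-corrected, Holm-adjusted — Holm chosen as a
conservative, order-preserving default), Welch t tests for utilized vs
non-utilized comparisons, and Pearson correlation for ED vs FDist. The
Dunn implementation is validated against the two-group identity with the
Kruskal–Wallis statistic.

## Problem sizes

The packaged experiments run at desk scale, chosen once: ensembles of 5–10
trees of 100–200 tips for pipeline experiments, 1000-shuffle dispersion
nulls, 1000-replicate null strategies, 200 small trees for the greedy
optimality sweep, and 30 replicates per pipeline regime. These sizes keep
the full suite fast while leaving every estimate's Monte Carlo error well
inside the asserted tolerances; all of them scale up by changing arguments,
not code.

## Degenerate inputs and numerical choices

Branch lengths are required (PD is undefined without them); zero-length
branches and polytomies are accepted, as posterior samples contain both. A
basal polytomy is indistinguishable in Newick from an unrooted tree, so the
representation root is taken as the root rather than rejected. Greedy
tie-detection uses a relative tolerance of 1e-12 on the PD increment.
Tip labels and species ids are matched after trimming whitespace and
replacing underscores with spaces — stated explicitly because Newick
dialects differ. The dispersion null refuses degenerate label sets (empty
or all tips), and `ses_report()` refuses a zero null standard deviation
rather than returning infinities.
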
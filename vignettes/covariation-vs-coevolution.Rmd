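---
title: "Covariation versus coevolution: models, decomposition, and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariation versus coevolution: models, decomposition, and benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevar)
```

# The question

Covariation between alignment columns — two positions whose residues
co-occur more often than expected — is routinely read as evidence of
molecular coevolution: substitutions at one site changing the selective
forces at the other, producing coordinated (same-branch) double
substitutions. `coevar` implements the machinery needed to test that
reading: an exact model of what coevolutionary selection does to a pair of
sites, tree-aware parsimony that counts where single and double changes
actually fall, and structural context that offers a rival explanation
(shared burial and low rate) for the covariation signal.

# The two-site coevolution model

## States, mutation, selection

Each site of a pair is binary, so the joint chain lives on
(00, 01, 10, 11). The mutational process changes one site at a time,
moving a site to state 0 at rate $\pi_0$ and to state 1 at rate $\pi_1$
($\pi_0 + \pi_1 = 1$); the instantaneous rate of simultaneous double
changes is exactly zero, as in codon models. Selection favours the
matched states 00 and 11 over the mismatched 01 and 10 by a selection
strength $S$ (effective population size times selective coefficient;
$S = 0$ is neutrality). Each mutational rate is multiplied by the haploid
fixation factor

$$ f(S) \;=\; \frac{S}{1 - e^{-S}}, $$

with $+S$ for transitions into {00, 11} and $-S$ for transitions into
{01, 10}. `fixation_factor()` evaluates $f$ with a series expansion for
$|S| < 10^{-6}$ so the neutral limit $f(0) = 1$ is exact;
`build_qcoevo()` assembles the generator, and `build_qmut()` is its
$S = 0$ special case. Mutation rate and population size never appear
separately: they are absorbed into $S$ and the time unit.

## Derived quantities

The stationary distribution weighs the mutational frequencies of each
joint character by its relative fixation probability,
$\pi_{00} \propto \pi_0^2 f(S)$, $\pi_{01} = \pi_{10} \propto \pi_0\pi_1
f(-S)$, $\pi_{11} \propto \pi_1^2 f(S)$, normalised to one
(`stationary_distribution()`); the chain is reversible with respect to it,
which the test suite checks to $10^{-10}$ for positive and negative $S$.

`relative_rate()` is defined constructively — total rate
$-\sum_i \pi_i Q_{ii}$ of the coevolving chain at its stationary
distribution divided by the same quantity for the independent chain — and
is verified against the closed form $2Se^{-S}/(1-e^{-2S})$ that holds at
$\pi_0 = \pi_1 = 1/2$. We deliberately define the quantity by the
construction rather than by a transcribed formula, because the
construction is unambiguous.

`change_class_probs()` classifies start/end states over time $t$ drawn
from the stationary distribution using $P(t) = e^{Qt}$: the probability
mass on identical states, on states differing at one site, and at both
sites. `single_fraction()` is the share of observable changes that are
single-site. Time is measured in expected substitutions of the neutral
pair process, and all shipped results use $\pi_0 = \pi_1 = 1/2$, the most
favourable case for detecting coevolution through covariation.

At $S = 2$, $t = 1$ the single fraction is
`r round(100 * single_fraction(pair_model_params(2, 1)), 1)`% — even
under selection strong enough to halve the substitution rate, what one
observes is overwhelmingly single changes. That is the *coevolution
paradox*: the selection strength needed to generate many coordinated
double changes suppresses the substitution rate so far that nothing is
left to observe.

## Numerics

$P(t)$ is computed by eigendecomposition of the symmetrised generator
$D_\pi^{1/2} Q D_\pi^{-1/2}$ (exact for a reversible chain, and stable for
the stiff generators at large $|S|$, where rates span four orders of
magnitude); when no valid stationary distribution is available the code
falls back to scaling-and-squaring. Rows are renormalised and negative
entries below $10^{-12}$ clipped. The test suite cross-checks against an
independent matrix-exponential implementation at $10^{-9}$.

# Covariation statistics

All information measures use log base 2, so MI of a pair of identical
even-split binary columns is exactly 1 bit. Frequencies are raw counts
(no pseudocounts, no sequence weighting). Gaps are handled by
pairwise-complete deletion: for each pair, rows gapped in either column
are dropped and marginals recomputed — the least surprising convention,
keeping each pair's joint table internally consistent.

Available per-pair scores: `mutual_information()`, the joint-entropy
normalisation `mi_over_joint_entropy()`, the average-product correction
`mip()` (which removes the shared background component and is tested to
zero out alignments with uniform pairwise MI), a permutation-null
correction `mi_adj()` (MI minus the mean MI over seeded row-shuffles of
one column — a documented stand-in, not a re-derivation of any published
formula), and `chi_square_pair()` (no continuity correction; cells with
zero expectation skipped). Invariant columns are removed before
covariation analysis (`filter_invariant_columns()`), because a column
with at most one non-gap symbol cannot covary. Externally computed scores
(direct-coupling or sparse-inverse-covariance predictors) are consumed
from `i j score` tables via `read_external_scores()` — never re-derived —
with last-wins duplicate handling and index validation.

# Parsimony decomposition on the tree

`fitch_count()` / `fitch_assign()` implement Fitch small parsimony,
generalised to multifurcations by the Hartigan state-count rule (the node
set is the set of states present in the maximal number of child sets).
Gaps and ambiguity codes are missing data: they contribute the full state
set and never force a change; zero-length branches still count as
branches, since branch classification is topological.

Because most-parsimonious reconstructions are not unique, the
reconstruction is made deterministic: in the top-down pass a node keeps
its parent's state whenever that state is in its set, and otherwise takes
the alphabetically smallest member. This choice (rather than, say, random
tie-breaking) makes every downstream count reproducible; the suite
verifies that the implied change count always equals the Fitch minimum,
and that the minimum itself matches exhaustive enumeration over all
ancestral assignments on trees of up to six leaves.

For a pair of columns, `pair_branch_changes()` reports:

* `n_single_branches` / `n_double_branches` — branches where exactly one,
  or both, sites change, classified from the two per-site reconstructions
  (the default; a `classify = "joint"` switch classifies from the
  joint-character reconstruction instead, since the literature does not
  fix this choice);
* `mp_ind` — parsimony without coevolution: the sum of the two
  independent Fitch minima (a count of changes);
* `mp_dep` — parsimony assuming coevolution: the number of branches with
  any change for the joint character over the product alphabet (a count
  of branches), never larger than `mp_ind`.

`single_double_ratio()` ranks pairs by single:double branch ratio with
explicit sentinels (no doubles → `Inf`, ranked last when selecting
smallest; no changes at all → excluded). `site_rate_proxy()` (Fitch count
over total tree length) stands in for maximum-likelihood site rates when
no external rate table is supplied; rate tables estimated elsewhere can
be passed straight into the evaluation layer.

`parsimony_pair_table()` computes all of this for every pair at once,
with a vectorised joint-character Fitch pass (state sets as bitmasks,
all pairs advanced together through one postorder traversal).

# Structural context

Contacts are defined by minimum heavy-atom distance below a threshold
(default 10 Å; a configurable minimum sequence separation, default 0,
accommodates benchmark conventions that exclude near-diagonal pairs).
Accessibility comes either from Naccess-style `.rsa` files (the relative
all-atom column, parsed positionally and tolerating blank chains) or from
an internal Shrake–Rupley approximation (fixed golden-spiral sphere
points, van der Waals radii by element, water probe 1.4 Å, normalised by
the Tien et al. theoretical maximum per residue type) — an approximation
documented as such, not a re-implementation of Naccess. Burial classes:
completely buried at exactly 0% relative accessibility, core below 10%,
exposed otherwise; the crisp 0% rule is what makes
"completely-buried pair" counts well defined. Pair accessibility is the
volume-weighted mean using Zamyatnin mean residue volumes.

# Evaluation

Predictions are the top $k = \lfloor L/5 \rfloor$ pairs (minimum 1) under
each metric, covariation scores ranked largest-first and
evolution-based predictors (mean rate, rate difference, `mp_ind`,
`mp_dep`, single:double ratio) smallest-first, ties broken by ascending
pair indices. Precision is successes over predictions. The random
expectation is the percentile interval of the statistic over 1,000
resamples of $k$ pairs drawn with replacement from the scored pair
universe (bootstrap, not permutation), seeded and reproducible.
`best_covariation_meta()` takes the pointwise maximum across covariation
metrics' precision curves. Selected-versus-control comparisons use
two-sided Mann–Whitney tests with Benjamini–Hochberg FDR across families;
the control is the remaining pairs (an equal-size random control is a
documented alternative reading of the benchmark description — "rest of
pairs" is the default here).

One consequence of parsimony- and rate-based selection is worth naming:
those metrics are defined for *all* column pairs, including invariant
sites that covariation can never score. The pipeline therefore evaluates
each metric on its own defined universe, and precision of the full
universe equals the contact density exactly.

# The synthetic benchmark

## What the generator emulates

`synthetic_config()` defaults describe a moderately diverged, curated
protein family of the size used in phylogeny-based covariation studies:
32 sequences; a Yule topology with exponential branch lengths whose
expected total is 10 neutral substitutions (enough divergence for the
parsimony proxy to separate slow from average sites, while individual
draws vary realistically); 60–100 binary sites with gamma-distributed
rate multipliers of shape 0.5 (strong among-site heterogeneity, mean 1);
optional coevolving pairs simulated jointly under the selection model at
chosen $S$; and a pseudo-structure in which the radial order of sites is
a $\rho$-weighted blend of the rate rank with uniform noise.

Simulation is exact (event-driven Gillespie, no discretisation), with a
complete truth log: every jump on every branch, per-pair true single- and
double-change branch counts, true rate multipliers, and the column
shuffle. The suite verifies the simulator against the analytic
change-class probabilities at 20,000 replicates and confirms no logged
jump ever changes both sites.

The structure places one pseudo-residue per column in a sphere sized at
protein-like overall density (one residue per ~135 Å³) with radius
growing as the square root of the radial percentile — a stylised dense
hydrophobic core under a sparser surface shell. Relative accessibility is
a monotone function of the radial percentile with the innermost 15% of
sites completely buried; contacts are centre distances below 8 Å. At
$\rho = 1$ burial order is exactly rate order; at $\rho = 0$ they are
independent.

## What passing benchmarks do and do not show

The generator reproduces the statistical *mechanisms* the analysis
targets — rate heterogeneity, rate-coupled burial, selection-driven
double changes — but real data differ in ways the benchmarks cannot
probe: 20-letter alphabets, indels and alignment error, non-stationary
composition, tree estimation error, and real packing geometry (the
square-root radial profile expresses the core/surface contrast more
cleanly than real structures do). Green benchmarks mean the pipeline
recovers designed signals and stays calibrated under the null; they are
not a claim about any particular protein family.

## Benchmark conditions

`run_synthetic_benchmark()` runs three study conditions used by the
acceptance suite:

* **Recovery** ($\rho = 0.9$, 100 sites, no coevolving pairs): the
  smallest-mean-rate predictor's precision at $\lfloor L/5 \rfloor$
  should clear the 95% random band — low rate → buried → in contact, the
  rival explanation of covariation's structural success. Asserted on the
  mean over 20 replicate datasets and as an above-band majority, because
  a single replicate's verdict at these sizes turns on one draw.
* **Null** ($\rho = 0$, $S = 0$, 50 replicates): every metric's precision
  should fall inside its band in at least 90% of replicates.
* **Paradox** (ten embedded pairs at $S = 4$ among 40 independent sites,
  50 replicates): truly coevolving pairs show a *higher* pooled
  double-change branch fraction than matched independent pairs (sign
  test) while making *fewer* total changes — the paradox signature.
  $S = 4$ was chosen from the theory: the relative rate is 0.147, low
  enough that within-branch compensation dominates, while a tree of
  total length 10 still yields on the order of one observable event per
  pair.

# Degenerate inputs and edge policies

All-gap columns and all-invariant alignments produce warnings or typed
errors rather than silent results; `single_fraction()` refuses $t = 0$;
the band refuses $k$ larger than the universe; selection caps $k$ at the
number of scored pairs with a warning; degenerate all-tied Mann–Whitney
input returns $p = 1$ with a flag. Every random routine takes an explicit
seed, and the pipeline derives per-stage substreams from one master seed
so that stage outputs are individually reproducible.

# Known limitations

* The model is binary; amino-acid state space is deliberately out of
  scope (the qualitative conclusions are argued to transfer, but the
  package does not demonstrate it).
* `mi_adj()` is a generic permutation-null correction, not a
  re-implementation of any specific published adjustment.
* The internal accessibility is a coarse Shrake–Rupley approximation;
  studies matching published buried-pair censuses should supply Naccess
  `.rsa` files.
* The selection strength $S$ is never estimated from data; the package
  only simulates and analyses at known $S$.
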
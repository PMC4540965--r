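# coevar

Is amino-acid covariation evidence of molecular coevolution? `coevar` is an
R package for asking that question quantitatively. It combines three things:

1. **An exact two-site binary coevolution model.** Each site of a pair takes
   states {0, 1}; the joint chain over (00, 01, 10, 11) mutates one site at
   a time, and selection of strength *S* (the product of effective
   population size and selective coefficient) rescales each substitution
   rate by the haploid fixation factor

   S / (1 − e^(−S)),

   applied with +S for transitions into the favoured states {00, 11} and −S
   into the disfavoured {01, 10}. The package computes the generator, its
   stationary distribution, the relative substitution rate of the coevolving
   pair versus independent sites (closed form 2S·e^(−S)/(1 − e^(−2S)) at
   equal frequencies), and the probabilities of observing no, single, or
   double differences after time *t* via P(t) = exp(Qt).

2. **An empirical decomposition pipeline.** Covariation statistics per
   column pair (MI in bits, MI/H(X,Y), the average-product correction MIp,
   a permutation-null MI correction, chi-square), readers for external
   contact-predictor score tables, Fitch–Hartigan parsimony that classifies
   every branch of a phylogeny as a single-change or double-change branch
   (MP_ind counts changes with sites independent; MP_dep counts branches
   with any change for the joint character), structure context (minimum
   heavy-atom distances, contact maps, Naccess-style `.rsa` parsing or an
   internal Shrake–Rupley accessibility, burial classes, volume-weighted
   pair accessibility), and precision evaluation of top-L/5 selections
   against 95% bootstrap random-expectation bands.

3. **A seeded synthetic-data generator.** Yule trees, exact event-driven
   (Gillespie) simulation of independent sites with gamma rate
   heterogeneity and of coevolving pairs under the selection model, and
   pseudo-structures in which burial tracks low evolutionary rate with a
   tunable coupling, so the whole pipeline can be benchmarked end to end
   against known truth.

The central phenomenon the package exposes is the *coevolution paradox*:
selection strong enough to force compensatory double changes suppresses the
pair's substitution rate so much that those changes are rarely observable —
so covariation signal mostly reflects slowly evolving, buried residue
pairs, not coordinated substitutions.

## Worked example

```r
library(coevar)

# Theory: how much single vs double change does coevolution produce?
run_model_curves(s_values = c(0, 2, 4), t_values = 1.0)
#   S relative_rate t    p_none  p_single   p_double single_fraction
# 1 0     1.0000000 1 0.4677735 0.4323324 0.09989410       0.8123090
# 2 2     0.5514411 1 0.7305322 0.1947920 0.07467577       0.7228768
# 3 4     0.1465743 1 0.9384661 0.0347681 0.02676579       0.5650237
```

At moderate selection (S = 2) the pair's rate has already dropped to 55% of
the independent-sites rate, yet 72% of the changes you can observe after
t = 1 are still single-site differences — coevolution mostly slows sites
down rather than producing coordinated changes.

```r
# Empirics on a synthetic family with rate-coupled burial
cfg <- synthetic_config(n_leaves = 32, n_independent_sites = 60,
                        coevolving_S = c(4, 4), rho = 0.9, seed = 21)
sim <- simulate_alignment(cfg)
cp <- sim$truth$coevolving_pairs
counts <- pair_branch_changes(
  sim$tree,
  setNames(sim$alignment[, cp$col_i[2]], rownames(sim$alignment)),
  setNames(sim$alignment[, cp$col_j[2]], rownames(sim$alignment)))
counts
# Pair changes: 0 single-change, 1 double-change branches (MP_ind = 2, MP_dep = 1)
```

A truly coevolving pair: very few changes in total (the rate suppression —
this dataset's *other* embedded pair shows no changes at all over 32
sequences), and what changes exist sit on the same branch. `run_dataset_analysis()`
assembles the full per-pair table (covariation + parsimony + rate + contact
labels) and reports each metric's precision at k = floor(L/5) against its
bootstrap random band; `run_synthetic_benchmark()` repeats that over
replicate simulated datasets.

A command-line front end over the same functions ships in
`inst/cli/coevar.R` with subcommands `model-curves`, `simulate`, `score`,
`parsimony`, and `evaluate`.

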
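# Fitch/Hartigan parsimony: counts against exhaustive enumeration,
# deterministic reconstructions, and the pair single/double decomposition.

test_that("newick reading validates input", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(length(tr$tip.label), 4)
  expect_equal(nrow(tr$edge), 6)
  expect_error(read_newick(text = "((A,B);"), "parse")
  aln <- alignment(c(A = "01", B = "01", C = "10", X = "10"))
  expect_error(validate_tree_alignment(tr, aln), "D")
  expect_error(validate_tree_alignment(tr, aln), "X")
})

test_that("fitch count handles trivial and missing-data cases", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(fitch_count(tr, c(A = "x", B = "x", C = "x", D = "x")), 0L)
  expect_equal(fitch_count(tr, c(A = "a", B = "a", C = "b", D = "b")), 1L)
  # missing data add no constraint
  expect_equal(fitch_count(tr, c(A = "a", B = "-", C = "b", D = "b")), 1L)
  expect_equal(fitch_count(tr, c(A = "a", B = NA, C = NA, D = "a")), 0L)
})

test_that("fitch count equals exhaustive enumeration on random instances", {
  set.seed(101)
  for (r in 1:250) {
    n <- sample(3:6, 1)
    tr <- random_small_tree(n)
    col <- random_column(tr, n_states = sample(2:3, 1),
                         p_missing = sample(c(0, 0.2), 1))
    if (all(is.na(col))) next
    expect_identical(fitch_count(tr, col),
                     brute_force_parsimony(tr, col[tr$tip.label]))
  }
})

test_that("fitch count matches an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(202)
  for (r in 1:40) {
    tr <- random_small_tree(sample(5:12, 1))
    col <- random_column(tr, n_states = 2)
    dat <- phangorn::phyDat(matrix(col[tr$tip.label], ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = c("1", "2"))
    expect_equal(fitch_count(tr, col),
                 as.integer(phangorn::fitch(tr, dat)))
  }
})

test_that("fitch count is invariant to child order and multifurcations work", {
  a <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  b <- read_newick(text = "((D:1,C:1):1,(B:1,A:1):1);")
  col <- c(A = "x", B = "y", C = "x", D = "y")
  expect_identical(fitch_count(a, col), fitch_count(b, col))
  # multifurcation: star tree of 5 leaves, 3 states
  star <- read_newick(text = "(A:1,B:1,C:1,D:1,E:1);")
  col5 <- c(A = "1", B = "1", C = "2", D = "2", E = "3")
  expect_identical(fitch_count(star, col5),
                   brute_force_parsimony(star, col5[star$tip.label]))
})

test_that("deterministic reconstruction achieves the parsimony minimum", {
  set.seed(303)
  for (r in 1:150) {
    tr <- random_small_tree(sample(3:6, 1))
    col <- random_column(tr, n_states = sample(2:3, 1),
                         p_missing = sample(c(0, 0.2), 1))
    if (all(is.na(col))) next
    a <- fitch_assign(tr, col)
    expect_identical(attr(a, "changes"), fitch_count(tr, col))
  }
  # tie at the root resolves alphabetically
  tr <- read_newick(text = "(A:1,B:1);")
  a <- fitch_assign(tr, c(A = "z", B = "a"))
  expect_identical(unname(a[3]), "a")
})

test_that("the balanced split tree yields one double change at the root", {
  fx <- fig_tree_a()
  counts <- pair_branch_changes(fx$tree, fx$colA, fx$colB)
  expect_identical(counts$n_double_branches, 1L)
  expect_identical(counts$n_single_branches, 0L)
  expect_identical(counts$mp_dep, 1L)
  expect_identical(counts$mp_ind, 2L)
  # same classification from the joint-character reconstruction
  joint <- pair_branch_changes(fx$tree, fx$colA, fx$colB, classify = "joint")
  expect_identical(joint$n_double_branches, 1L)
})

test_that("pair decomposition is consistent on random instances", {
  set.seed(404)
  for (r in 1:120) {
    tr <- random_small_tree(sample(4:6, 1))
    a <- random_column(tr, 2)
    b <- random_column(tr, 2)
    counts <- pair_branch_changes(tr, a, b)
    # mp_ind is exactly the sum of the two independent minima
    expect_identical(counts$mp_ind,
                     fitch_count(tr, a) + fitch_count(tr, b))
    # the joint character's minimum never exceeds the independent total
    expect_lte(counts$mp_dep, counts$mp_ind)
    # mp_dep equals the exhaustive joint-character minimum
    joint <- paste(a[tr$tip.label], b[tr$tip.label], sep = "|")
    expect_identical(counts$mp_dep,
                     brute_force_parsimony(tr, joint))
    # branch classification accounts for all per-site changes
    expect_identical(counts$n_single_branches + 2L * counts$n_double_branches,
                     counts$mp_ind)
  }
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  const <- c(A = "0", B = "0", C = "0", D = "0")
  z <- pair_branch_changes(tr, const, const)
  expect_identical(unlist(z, use.names = FALSE), rep(0L, 4))
})

test_that("single:double ratio uses the stated sentinels", {
  mk <- function(s, d) structure(list(n_single_branches = s,
                                      n_double_branches = d),
                                 class = "pair_change_counts")
  expect_equal(single_double_ratio(mk(3L, 1L)), 3)
  expect_identical(single_double_ratio(mk(4L, 0L)), Inf)
  expect_identical(single_double_ratio(mk(0L, 0L)), NA_real_)
})

test_that("parsimony rate proxy is changes per unit tree length", {
  tr <- read_newick(text = "((A:0.5,B:0.5):0.5,(C:0.25,D:0.25):0.0);")
  col <- c(A = "0", B = "1", C = "0", D = "1")
  expect_equal(site_rate_proxy(tr, col),
               fitch_count(tr, col) / sum(tr$edge.length))
  expect_equal(site_rate_proxy(tr, c(A = "0", B = "0", C = "0", D = "0")), 0)
  tr0 <- tr; tr0$edge.length <- rep(0, nrow(tr0$edge))
  expect_error(site_rate_proxy(tr0, col), "zero total length")
})

test_that("coincidental double changes on independent pairs stay at chance", {
  # under S = 0 the per-branch double-change fraction among changed
  # branches should not exceed a binomial band around the product of the
  # per-site change probabilities
  set.seed(505)
  cfg <- synthetic_config(n_leaves = 16, n_independent_sites = 2,
                          total_length = 4, gamma_shape = 100, seed = 1)
  # equal branch lengths so per-branch change probabilities are exchangeable
  tr <- random_small_tree(16)
  tr$edge.length <- rep(4 / nrow(tr$edge), nrow(tr$edge))
  n_double <- n_branch <- 0
  p_site <- numeric(0)
  for (r in 1:200) {
    cfg$seed <- r
    sim <- simulate_alignment(cfg, tree = tr)
    counts <- pair_branch_changes(sim$tree,
                                  stats::setNames(sim$alignment[, 1],
                                                  rownames(sim$alignment)),
                                  stats::setNames(sim$alignment[, 2],
                                                  rownames(sim$alignment)))
    ne <- nrow(sim$tree$edge)
    n_branch <- n_branch + ne
    n_double <- n_double + counts$n_double_branches
    chg <- counts$n_single_branches + 2 * counts$n_double_branches
    p_site <- c(p_site, chg / (2 * ne))
  }
  p_hat <- mean(p_site)^2
  se <- sqrt(p_hat * (1 - p_hat) / n_branch)
  expect_lte(n_double / n_branch, p_hat + 4 * se)
})
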
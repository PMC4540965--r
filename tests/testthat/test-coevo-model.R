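# The analytic two-site model: fixation scaling, generator structure,
# stationarity, reversibility, transition probabilities, and the
# observable change-class decomposition.

test_that("fixation factor matches its closed form and limit", {
  expect_equal(fixation_factor(0), 1)
  expect_equal(fixation_factor(5), 5 / (1 - exp(-5)), tolerance = 1e-12)
  expect_equal(fixation_factor(-5), fixation_factor(5) * exp(-5),
               tolerance = 1e-12)
  # continuous through the series branch near 0
  expect_equal(fixation_factor(1e-7), fixation_factor(1.0000001e-6),
               tolerance = 1e-6)
  # strictly increasing, positive
  grid <- seq(-10, 10, by = 0.5)
  vals <- fixation_factor(grid)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0))
  expect_error(fixation_factor(Inf), "finite")
  expect_error(fixation_factor(NA_real_), "finite")
})

test_that("generators have the required structure for many parameters", {
  for (S in c(-3, 0, 0.5, 2, 5, 10)) {
    for (pi0 in c(0.5, 0.3)) {
      p <- pair_model_params(S = S, t = 1, pi0 = pi0)
      Q <- build_qcoevo(p)
      expect_true(validate_rate_matrix4(Q))
      expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_identical(Q["00", "11"], 0)
      expect_identical(Q["01", "10"], 0)
    }
  }
})

test_that("S = 0 recovers the independent mutational generator exactly", {
  for (pi0 in c(0.5, 0.25, 0.7)) {
    Qm <- build_qmut(pi0)
    Q0 <- build_qcoevo(pair_model_params(S = 0, t = 1, pi0 = pi0))
    expect_equal(Qm, Q0)
  }
  # even frequencies: every allowed off-diagonal 0.5, exit rates 1
  Qm <- build_qmut(0.5)
  off <- Qm; diag(off) <- NA
  expect_equal(sort(unique(off[!is.na(off) & off > 0])), 0.5)
  expect_equal(diag(Qm), rep(-1, 4), ignore_attr = TRUE)
  expect_error(build_qmut(0.6, 0.6), "sum to 1")
})

test_that("coevolutionary rates carry the fixation scaling", {
  Q <- build_qcoevo(pair_model_params(S = 5, t = 1))
  expect_equal(Q["00", "01"], 0.5 * fixation_factor(-5), tolerance = 1e-12)
  expect_equal(Q["01", "00"], 0.5 * fixation_factor(5), tolerance = 1e-12)
  expect_equal(Q["00", "01"], 0.016959, tolerance = 1e-4)
  expect_equal(Q["01", "00"], 2.516959, tolerance = 1e-6)
})

test_that("stationary distribution is the left null vector and reversible", {
  for (S in c(-2, 0, 1, 5, 8)) {
    for (pi0 in c(0.5, 0.35)) {
      p <- pair_model_params(S = S, t = 1, pi0 = pi0)
      Q <- build_qcoevo(p)
      pi <- stationary_distribution(p)
      expect_equal(sum(pi), 1, tolerance = 1e-12)
      expect_equal(as.numeric(pi %*% Q), rep(0, 4), tolerance = 1e-12)
      # detailed balance over all 12 ordered pairs
      D <- pi * Q
      expect_lt(max(abs(D - t(D))), 1e-10)
    }
  }
  expect_equal(stationary_distribution(pair_model_params(0, 1)),
               rep(0.25, 4), tolerance = 1e-12, ignore_attr = TRUE)
  pi5 <- stationary_distribution(pair_model_params(5, 1))
  expect_equal(unname(pi5[c("00", "11")]), rep(0.49665, 2), tolerance = 1e-4)
  expect_equal(unname(pi5[c("01", "10")]), rep(0.00335, 2), tolerance = 1e-2)
})

test_that("relative rate equals its closed form and decreases with S", {
  expect_equal(relative_rate(pair_model_params(0, 1)), 1, tolerance = 1e-12)
  for (S in c(0.5, 1, 2, 5, 10)) {
    closed <- 2 * S * exp(-S) / (1 - exp(-2 * S))
    expect_equal(relative_rate(pair_model_params(S, 1)), closed,
                 tolerance = 1e-10)
  }
  expect_equal(relative_rate(pair_model_params(5, 1)), 0.0674,
               tolerance = 1e-3)
  grid <- vapply(0:10, function(S) relative_rate(pair_model_params(S, 1)),
                 numeric(1))
  expect_true(all(diff(grid) < 0))
})

test_that("transition probabilities are stochastic and reach equilibrium", {
  Q <- build_qcoevo(pair_model_params(2, 1))
  expect_equal(transition_probabilities(Q, 0), diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (t in c(0.01, 0.5, 2, 20)) {
    P <- transition_probabilities(Q, t)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(P >= 0 & P <= 1))
  }
  pi <- stationary_distribution(pair_model_params(2, 1))
  P <- transition_probabilities(Q, 500)
  for (i in 1:4) expect_equal(unname(P[i, ]), unname(pi), tolerance = 1e-6)
  expect_error(transition_probabilities(Q, -1), "non-negative")
})

test_that("matrix exponential agrees with an independent implementation", {
  skip_if_not_installed("Matrix")
  for (S in c(0, 2, 5)) for (pi0 in c(0.5, 0.3)) for (t in c(0.3, 1.7)) {
    Q <- build_qcoevo(pair_model_params(S, 1, pi0 = pi0))
    P_ref <- as.matrix(Matrix::expm(Q * t))
    expect_equal(unname(transition_probabilities(Q, t)), unname(P_ref),
                 tolerance = 1e-9)
  }
})

test_that("change-class probabilities sum to one and reduce at S = 0", {
  expect_equal(unclass(change_class_probs(pair_model_params(2, 0))),
               list(p_none = 1, p_single = 0, p_double = 0),
               tolerance = 1e-12)
  for (t in c(0.2, 0.7, 1.5, 2.5)) {
    cc <- change_class_probs(pair_model_params(0, t))
    ref <- independent_change_probs(t)
    expect_equal(cc$p_single, unname(ref["p_single"]), tolerance = 1e-8)
    expect_equal(cc$p_double, unname(ref["p_double"]), tolerance = 1e-8)
  }
  for (S in c(0, 2, 6)) for (t in c(0.1, 1, 3)) {
    cc <- change_class_probs(pair_model_params(S, t))
    expect_equal(cc$p_none + cc$p_single + cc$p_double, 1,
                 tolerance = 1e-10)
    expect_true(all(unlist(cc) >= 0 & unlist(cc) <= 1))
  }
  # p_double grows with time at fixed S
  for (S in c(0, 2, 5)) {
    pd <- vapply(seq(0.1, 2.5, by = 0.3), function(t)
      change_class_probs(pair_model_params(S, t))$p_double, numeric(1))
    expect_true(all(diff(pd) > 0))
  }
})

test_that("single-change mass splits evenly between state classes at pi = 1/2", {
  # detailed-balance consequence: single changes leaving favoured states
  # carry the same probability mass as those leaving suboptimal states
  p <- pair_model_params(3, 1.2)
  Q <- build_qcoevo(p)
  pi <- stationary_distribution(p)
  P <- transition_probabilities(Q, p$t, pi = pi)
  st <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  fav <- c(TRUE, FALSE, FALSE, TRUE)
  from_fav <- from_sub <- 0
  for (i in 1:4) for (j in 1:4) {
    if (sum(st[i, ] != st[j, ]) != 1) next
    if (fav[i]) from_fav <- from_fav + pi[i] * P[i, j]
    else from_sub <- from_sub + pi[i] * P[i, j]
  }
  expect_equal(unname(from_fav), unname(from_sub), tolerance = 1e-10)
})

test_that("single fraction behaves across time and errors at t = 0", {
  expect_error(single_fraction(pair_model_params(2, 0)), "undefined")
  expect_equal(single_fraction(pair_model_params(2, 1)), 0.7228768,
               tolerance = 1e-6)
  # doubles are second order: fraction tends to 1 as t -> 0
  expect_gt(single_fraction(pair_model_params(0, 0.01)), 0.99)
  sf <- vapply(seq(0.1, 2.5, by = 0.3), function(t)
    single_fraction(pair_model_params(2, t)), numeric(1))
  expect_true(all(diff(sf) < 0))
})

test_that("parameter validation rejects bad input", {
  expect_error(pair_model_params(S = Inf, t = 1), "finite")
  expect_error(pair_model_params(S = 1, t = -1), "non-negative")
  expect_error(pair_model_params(S = 1, t = 1, pi0 = 0.7, pi1 = 0.7),
               "sum to 1")
})
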
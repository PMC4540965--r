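# Two-site binary coevolution model: a reversible 4-state continuous-time
# Markov chain over the joint states (00, 01, 10, 11) in which mutation
# proposes single-site changes and selection of strength S rescales the
# substitution rate by the haploid fixation factor. States 00/11 are the
# selectively favoured pair, 01/10 the equally disfavoured pair.

PAIR_STATES <- c("00", "01", "10", "11")

# 4 x 2 matrix of site states (rows follow PAIR_STATES order)
pair_state_matrix <- function() {
  matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L), nrow = 4, byrow = TRUE,
         dimnames = list(PAIR_STATES, c("site1", "site2")))
}

#' Model parameters for the two-site coevolution process
#'
#' Bundles the selection strength `S` (product of effective population size
#' and selective coefficient; its sign gives the direction of selection and
#' `S = 0` is the independent-sites process), the evolutionary time `t` in
#' expected substitutions of the neutral pair process, and the mutational
#' state frequencies `pi0`, `pi1`. Population size and mutation rate enter
#' only through `S` and the time scale and have no separate parameters.
#'
#' @param S Selection strength (finite, dimensionless).
#' @param t Evolutionary time, `t >= 0`.
#' @param pi0,pi1 Mutational frequencies of states 0 and 1; must sum to 1.
#' @return An object of class `"pair_model_params"`.
#' @examples
#' pair_model_params(S = 2, t = 1)
#' @export
pair_model_params <- function(S, t = 1, pi0 = 0.5, pi1 = 1 - pi0) {
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S))
    stop_invalid("'S' must be a single finite number")
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop_invalid("'t' must be a single non-negative number")
  if (abs(pi0 + pi1 - 1) > 1e-8)
    stop_invalid("state frequencies must sum to 1 (got pi0 + pi1 = %g)",
                 pi0 + pi1)
  if (pi0 <= 0 || pi1 <= 0)
    stop_invalid("state frequencies must be strictly positive")
  structure(list(S = S, t = t, pi0 = pi0, pi1 = pi1),
            class = "pair_model_params")
}

as_pair_model_params <- function(x) {
  if (inherits(x, "pair_model_params")) x else
    stop_invalid("expected a 'pair_model_params' object")
}

#' @export
print.pair_model_params <- function(x, ...) {
  cat(sprintf("Two-site coevolution parameters: S = %g, t = %g, pi = (%g, %g)\n",
              x$S, x$t, x$pi0, x$pi1))
  invisible(x)
}

#' Selection-dependent fixation factor
#'
#' The factor `S / (1 - exp(-S))` by which selection of strength `S`
#' rescales a mutation's substitution rate in a haploid population
#' (diffusion approximation). Continuously extended to 1 at `S = 0`;
#' strictly increasing in `S` and positive everywhere.
#'
#' @param S Selection strength(s); finite numeric vector.
#' @return Positive numeric vector of the same length.
#' @examples
#' fixation_factor(0)   # 1
#' fixation_factor(5)   # ~5.034
#' @export
fixation_factor <- function(S) {
  if (!is.numeric(S) || any(!is.finite(S)))
    stop_invalid("'S' must be finite numeric")
  out <- numeric(length(S))
  small <- abs(S) < 1e-6
  # series of S/(1 - e^-S) about 0: 1 + S/2 + S^2/12 + O(S^4)
  out[small] <- 1 + S[small] / 2 + S[small]^2 / 12
  out[!small] <- S[!small] / (1 - exp(-S[!small]))
  out
}

check_frequencies <- function(pi0, pi1) {
  if (!is.numeric(pi0) || !is.numeric(pi1) || abs(pi0 + pi1 - 1) > 1e-8)
    stop_invalid("frequencies must sum to 1")
  if (pi0 <= 0 || pi1 <= 0) stop_invalid("frequencies must be positive")
  invisible(TRUE)
}

#' Mutational generator for two independent binary sites
#'
#' Rate matrix over the joint states (00, 01, 10, 11) in which each site
#' mutates independently towards state 0 at rate `pi0` and towards state 1
#' at rate `pi1`. Only single-site changes have non-zero rate: the
#' instantaneous double-change entries (00 to 11 and 01 to 10) are exactly 0.
#'
#' @param pi0,pi1 Mutational state frequencies, summing to 1.
#' @return A 4x4 generator matrix with `dimnames` `PAIR_STATES`.
#' @examples
#' build_qmut(0.5, 0.5)
#' @export
build_qmut <- function(pi0 = 0.5, pi1 = 1 - pi0) {
  check_frequencies(pi0, pi1)
  build_qcoevo(pair_model_params(S = 0, t = 0, pi0 = pi0, pi1 = pi1))
}

#' Coevolutionary generator for a pair of binary sites
#'
#' Builds the 4-state generator in which each single-site mutational rate
#' from [build_qmut()] is multiplied by [fixation_factor()] of `+S` for
#' transitions into the favoured states (00, 11) and of `-S` for
#' transitions into the disfavoured states (01, 10). `S = 0` recovers the
#' independent-sites generator exactly.
#'
#' @param params A [pair_model_params()] object.
#' @return A 4x4 generator matrix (rows sum to 0, forbidden double-change
#'   entries exactly 0).
#' @examples
#' build_qcoevo(pair_model_params(S = 2))
#' @export
build_qcoevo <- function(params) {
  p <- as_pair_model_params(params)
  pis <- c(p$pi0, p$pi1)
  favoured <- c(TRUE, FALSE, FALSE, TRUE)          # 00, 01, 10, 11
  st <- pair_state_matrix()
  Q <- matrix(0, 4, 4, dimnames = list(PAIR_STATES, PAIR_STATES))
  f_pos <- fixation_factor(p$S)
  f_neg <- fixation_factor(-p$S)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    diff <- st[i, ] != st[j, ]
    if (sum(diff) != 1L) next                      # double changes forbidden
    new_state <- st[j, which(diff)]
    Q[i, j] <- pis[new_state + 1L] * if (favoured[j]) f_pos else f_neg
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Validate a 4-state pair generator
#'
#' Checks the structural invariants of the joint-pair rate matrix: fixed
#' state order, non-negative off-diagonals, zero row sums, and exactly zero
#' instantaneous double-change entries.
#'
#' @param Q A 4x4 numeric matrix.
#' @param tol Numeric tolerance for the row-sum check.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_rate_matrix4 <- function(Q, tol = 1e-10) {
  if (!is.matrix(Q) || !all(dim(Q) == c(4, 4)))
    stop_invalid("'Q' must be a 4x4 matrix")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop_invalid("off-diagonal rates must be non-negative")
  if (any(abs(rowSums(Q)) > tol)) stop_invalid("generator rows must sum to 0")
  if (Q[1, 4] != 0 || Q[4, 1] != 0 || Q[2, 3] != 0 || Q[3, 2] != 0)
    stop_invalid("instantaneous double-change entries must be exactly 0")
  invisible(TRUE)
}

#' Stationary distribution of the coevolutionary pair process
#'
#' The equilibrium frequencies of the joint states: mutational frequencies
#' of each joint character weighted by the relative fixation probability of
#' being in a favoured (00, 11) versus disfavoured (01, 10) configuration,
#' normalised to sum to 1. Satisfies `pi %*% Q = 0` for [build_qcoevo()].
#'
#' @param params A [pair_model_params()] object.
#' @return Named numeric vector of length 4 over (00, 01, 10, 11).
#' @examples
#' stationary_distribution(pair_model_params(S = 5))
#' @export
stationary_distribution <- function(params) {
  p <- as_pair_model_params(params)
  v <- c(p$pi0 * p$pi0 * fixation_factor(p$S),
         p$pi0 * p$pi1 * fixation_factor(-p$S),
         p$pi1 * p$pi0 * fixation_factor(-p$S),
         p$pi1 * p$pi1 * fixation_factor(p$S))
  names(v) <- PAIR_STATES
  v / sum(v)
}

#' Relative substitution rate of the coevolving pair process
#'
#' Total rate of the coevolutionary process at its own stationary
#' distribution divided by that of the independent-sites process at its
#' stationary distribution (each rate is `-sum(pi_i * Q_ii)`). Equals 1 at
#' `S = 0` and, for equal state frequencies, the closed form
#' `2 S exp(-S) / (1 - exp(-2S))`.
#'
#' @param params A [pair_model_params()] object.
#' @return Scalar in (0, 1] for `S >= 0`.
#' @examples
#' relative_rate(pair_model_params(S = 5))  # ~0.0674
#' @export
relative_rate <- function(params) {
  p <- as_pair_model_params(params)
  Q <- build_qcoevo(p)
  Qm <- build_qcoevo(pair_model_params(0, 0, p$pi0, p$pi1))
  pim <- stationary_distribution(pair_model_params(0, 0, p$pi0, p$pi1))
  rate_co <- -sum(stationary_distribution(p) * diag(Q))
  rate_mut <- -sum(pim * diag(Qm))
  rate_co / rate_mut
}

#' Transition probabilities of a pair generator
#'
#' Computes `P(t) = exp(Q t)`. When the stationary distribution `pi` is
#' supplied (or derivable) and `Q` is reversible with respect to it, the
#' exponential is taken through the symmetric eigendecomposition of
#' `diag(sqrt(pi)) Q diag(1/sqrt(pi))`, which is exact and stable for the
#' stiff generators that arise at large `S`; otherwise a uniformization /
#' scaling-and-squaring fallback is used.
#'
#' @param Q A 4x4 (or n x n) generator matrix.
#' @param t Non-negative time.
#' @param pi Optional stationary distribution for the reversible path.
#' @return Row-stochastic matrix of the same dimension as `Q`.
#' @export
transition_probabilities <- function(Q, t, pi = NULL) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop_invalid("'t' must be a single non-negative number")
  n <- nrow(Q)
  if (is.null(pi)) pi <- numeric_stationary(Q)
  if (!is.null(pi) && reversible_wrt(Q, pi)) {
    s <- sqrt(pi)
    Sym <- (Q * s) / rep(s, each = n)          # diag(s) Q diag(1/s), symmetric
    Sym <- (Sym + t(Sym)) / 2
    e <- eigen(Sym, symmetric = TRUE)
    ES <- e$vectors %*% (exp(e$values * t) * t(e$vectors))
    P <- (ES / s) * rep(s, each = n)           # diag(1/s) expm(Sym t) diag(s)
  } else {
    P <- expm_ss(Q * t)
  }
  P[P < 0 & P > -1e-12] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

# left null vector of Q (stationary distribution), or NULL if degenerate
numeric_stationary <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  v <- Re(e$vectors[, i])
  if (any(!is.finite(v))) return(NULL)
  v <- v / sum(v)
  if (any(v < -1e-8)) return(NULL)
  pmax(v, 1e-300)
}

reversible_wrt <- function(Q, pi, tol = 1e-8) {
  D <- pi * Q                                  # pi_i Q_ij
  max(abs(D - t(D))) < tol * max(1, max(abs(D)))
}

# plain scaling-and-squaring Taylor fallback (A = Q*t already scaled by time)
expm_ss <- function(A, order = 12L) {
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  k <- max(0L, ceiling(log2(max(nrm, 1e-16))) + 1L)
  As <- A / 2^k
  P <- diag(n); term <- diag(n)
  for (m in seq_len(order)) {
    term <- term %*% As / m
    P <- P + term
  }
  for (m in seq_len(k)) P <- P %*% P
  P
}

#' Probabilities of no, single, and double observable change
#'
#' Over a time `t`, classifies the joint start/end states drawn from the
#' coevolutionary stationary distribution by whether they differ at no,
#' exactly one, or both sites: `p_none = sum_i pi_i P(t)_ii`, `p_single`
#' sums ordered state pairs differing at one site, `p_double` those
#' differing at both. The three probabilities sum to 1.
#'
#' @param params A [pair_model_params()] object (uses its `S` and `t`).
#' @return Object of class `"change_class_probs"`: list with `p_none`,
#'   `p_single`, `p_double`.
#' @examples
#' change_class_probs(pair_model_params(S = 2, t = 1))
#' @export
change_class_probs <- function(params) {
  p <- as_pair_model_params(params)
  Q <- build_qcoevo(p)
  pi <- stationary_distribution(p)
  P <- transition_probabilities(Q, p$t, pi = pi)
  st <- pair_state_matrix()
  ndiff <- matrix(0L, 4, 4)
  for (i in 1:4) for (j in 1:4) ndiff[i, j] <- sum(st[i, ] != st[j, ])
  W <- pi * P                                  # pi_i P_ij
  out <- list(p_none = sum(W[ndiff == 0L]),
              p_single = sum(W[ndiff == 1L]),
              p_double = sum(W[ndiff == 2L]))
  class(out) <- "change_class_probs"
  out
}

#' @export
print.change_class_probs <- function(x, ...) {
  cat(sprintf("P(no change) = %.6f, P(single) = %.6f, P(double) = %.6f\n",
              x$p_none, x$p_single, x$p_double))
  invisible(x)
}

#' Fraction of observable changes that are single-site
#'
#' `p_single / (p_single + p_double)` at the model's stationary
#' distribution. Undefined at `t = 0`, where no change can be observed.
#'
#' @param params A [pair_model_params()] object.
#' @return Scalar in `[0, 1]`.
#' @examples
#' single_fraction(pair_model_params(S = 2, t = 1))  # ~0.723
#' @export
single_fraction <- function(params) {
  p <- as_pair_model_params(params)
  if (p$t <= 0)
    stop_invalid("single_fraction is undefined at t = 0 (no observable change)")
  cc <- change_class_probs(p)
  denom <- cc$p_single + cc$p_double
  if (denom <= 0)
    stop_invalid("no observable change probability mass at these parameters")
  cc$p_single / denom
}
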
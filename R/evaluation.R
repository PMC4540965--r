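# Pair selection, precision against contact labels, bootstrap
# random-expectation bands, and selected-vs-control comparisons.

#' Select the top-scoring column pairs under a metric
#'
#' Ranks the pair table by a metric in the stated direction and returns the
#' selection set. The standard benchmark size is `floor(L / 5)` pairs (with
#' a minimum of 1), where `L` is the protein length; pass `L` via
#' `l_over_5` to use it. Pairs with `NA`/`NaN` scores are skipped; `Inf`
#' sorts last under `"smallest"` and first under `"largest"`. Ties are
#' broken by ascending `(i, j)`.
#'
#' @param table A [pair_score_table()]-style `data.frame` with `i`, `j`.
#' @param metric Column name to rank by.
#' @param k Number of pairs to select.
#' @param l_over_5 Protein length `L`; when given, `k = max(1, floor(L/5))`.
#' @param direction `"largest"` (covariation scores) or `"smallest"`
#'   (rate/parsimony predictors).
#' @return `data.frame` of the selected rows with attributes `metric`,
#'   `direction`, `k`.
#' @export
select_top_pairs <- function(table, metric, k = NULL, l_over_5 = NULL,
                             direction = c("largest", "smallest")) {
  direction <- match.arg(direction)
  if (!metric %in% names(table)) stop_invalid("unknown metric '%s'", metric)
  if (is.null(k)) {
    if (is.null(l_over_5)) stop_invalid("supply 'k' or 'l_over_5'")
    k <- max(1L, floor(l_over_5 / 5))
  }
  if (k < 1) stop_invalid("'k' must be >= 1")
  x <- table[[metric]]
  usable <- which(!is.na(x) & !is.nan(x))
  if (k > length(usable)) {
    warning(sprintf("only %d scored pairs available; capping k = %d",
                    length(usable), k), call. = FALSE)
    k <- length(usable)
  }
  sgn <- if (direction == "largest") -1 else 1
  ord <- usable[order(sgn * x[usable], table$i[usable], table$j[usable])]
  sel <- table[ord[seq_len(k)], , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "metric") <- metric
  attr(sel, "direction") <- direction
  attr(sel, "k") <- k
  sel
}

#' Precision of a prediction set against contact labels
#'
#' Successes / predictions, where a success is a predicted pair labelled as
#' a structural contact.
#'
#' @param predictions `data.frame` with `i`, `j` (a [select_top_pairs()]
#'   result).
#' @param contacts `data.frame` with `i`, `j`, `contact` covering every
#'   predicted pair.
#' @return Scalar in `[0, 1]`.
#' @export
precision <- function(predictions, contacts) {
  if (nrow(predictions) == 0L)
    stop_invalid("precision is undefined for an empty prediction set")
  key <- function(d) paste(pmin(d$i, d$j), pmax(d$i, d$j))
  lab <- contacts$contact[match(key(predictions), key(contacts))]
  if (any(is.na(lab)))
    stop_invalid("%d predicted pair(s) lack a contact label",
                 sum(is.na(lab)))
  mean(lab)
}

#' Best-covariation meta curve
#'
#' The pointwise maximum of several per-metric precision curves on a shared
#' `k` grid: for each prediction-set size it reports the highest precision
#' any covariation measure achieved.
#'
#' @param curves List of `data.frame`s, each with columns `k`, `precision`
#'   on the same `k` grid.
#' @return `data.frame` with `k` and the envelope `precision`.
#' @export
best_covariation_meta <- function(curves) {
  if (length(curves) == 0L) stop_invalid("need at least one curve")
  ks <- lapply(curves, function(c) c$k)
  if (!all(vapply(ks, identical, logical(1), ks[[1]])))
    stop_invalid("curves are not on a shared k grid")
  prec <- do.call(cbind, lapply(curves, function(c) c$precision))
  data.frame(k = ks[[1]], precision = apply(prec, 1, max))
}

#' Bootstrap confidence interval of the random expectation
#'
#' Resamples `k` pairs from the pair universe with replacement `n_reps`
#' times, evaluates the statistic on each resample, and returns the
#' percentile interval — the band a metric must leave before its selection
#' can be called better than random.
#'
#' @param statistic_fn Function of a vector of sampled pair values (e.g.
#'   `mean` of contact labels for precision).
#' @param pair_universe Vector of per-pair values to resample.
#' @param k Resample size.
#' @param n_reps Bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; the interval is reproducible given the seed.
#' @return Named vector `c(lo, hi)`.
#' @export
bootstrap_random_expectation <- function(statistic_fn, pair_universe, k,
                                         n_reps = 1000L, level = 0.95,
                                         seed = 1L) {
  if (k > length(pair_universe))
    stop_invalid("k (%d) exceeds pair universe size (%d)", k,
                 length(pair_universe))
  stats_v <- with_seed(seed, vapply(seq_len(n_reps), function(r) {
    statistic_fn(sample(pair_universe, k, replace = TRUE))
  }, numeric(1)))
  a <- (1 - level) / 2
  q <- stats::quantile(stats_v, c(a, 1 - a), names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Median comparison of selected versus control values
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of the values of
#' a metric in the selected pairs against a control sample (the remaining
#' pairs, or an equal-size random draw). Degenerate all-tied input returns
#' p = 1 with a flag instead of erroring.
#'
#' @param selected,control Non-empty numeric vectors.
#' @return List with `median_selected`, `median_control`, `p_value`,
#'   `degenerate`.
#' @export
median_comparison <- function(selected, control) {
  if (length(selected) == 0L || length(control) == 0L)
    stop_invalid("both samples must be non-empty")
  degenerate <- length(unique(c(selected, control))) == 1L
  p <- if (degenerate) 1 else
    suppressWarnings(stats::wilcox.test(selected, control,
                                        exact = FALSE)$p.value)
  list(median_selected = stats::median(selected),
       median_control = stats::median(control),
       p_value = p, degenerate = degenerate)
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' @param p Numeric vector of p-values from per-family comparisons.
#' @return FDR-adjusted p-values via [stats::p.adjust()] (method `"BH"`).
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Mean and absolute difference of a pair's site rates
#'
#' The two evolution-based pair predictors: the mean rate (slow pairs) and
#' the absolute rate difference (rate similarity).
#'
#' @param rate_i,rate_j Non-negative site rates (vectorised).
#' @return `data.frame` with `rate_mean` and `rate_abs_diff`.
#' @export
pair_rate_stats <- function(rate_i, rate_j) {
  if (any(rate_i < 0 | rate_j < 0)) stop_invalid("rates must be >= 0")
  data.frame(rate_mean = (rate_i + rate_j) / 2,
             rate_abs_diff = abs(rate_i - rate_j))
}

#' Pearson correlation of site rates and entropies
#'
#' @param rates,entropies Equal-length numeric vectors, `n >= 3`, each with
#'   non-zero variance.
#' @return Pearson R.
#' @export
rate_entropy_correlation <- function(rates, entropies) {
  if (length(rates) != length(entropies) || length(rates) < 3L)
    stop_invalid("need equal-length vectors with n >= 3")
  if (stats::sd(rates) == 0 || stats::sd(entropies) == 0)
    stop_invalid("correlation undefined: zero variance")
  stats::cor(rates, entropies)
}
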
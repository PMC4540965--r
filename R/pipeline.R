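# Orchestration: the model curves behind the theory figure, the per-dataset
# decomposition (covariation + parsimony + rate + structure), and the
# seeded synthetic end-to-end benchmark.

#' Model curves: relative rate and change classes over a parameter grid
#'
#' Evaluates the analytic model over a grid of selection strengths and a
#' list of times, producing the data behind the rate/single-fraction
#' curves.
#'
#' @param s_values Numeric vector of selection strengths.
#' @param t_values Numeric vector of positive times.
#' @param pi0 Mutational frequency of state 0.
#' @param out Optional TSV path to write the table to.
#' @return `data.frame` with columns `S`, `relative_rate`, `t`, `p_none`,
#'   `p_single`, `p_double`, `single_fraction`.
#' @export
run_model_curves <- function(s_values, t_values, pi0 = 0.5, out = NULL) {
  if (length(s_values) == 0L || length(t_values) == 0L)
    stop_invalid("empty parameter grid")
  if (any(t_values <= 0)) stop_invalid("'t_values' must be positive")
  rows <- list()
  for (S in s_values) {
    rr <- relative_rate(pair_model_params(S = S, t = 1, pi0 = pi0))
    for (t in t_values) {
      p <- pair_model_params(S = S, t = t, pi0 = pi0)
      cc <- change_class_probs(p)
      rows[[length(rows) + 1L]] <- data.frame(
        S = S, relative_rate = rr, t = t, p_none = cc$p_none,
        p_single = cc$p_single, p_double = cc$p_double,
        single_fraction = cc$p_single / (cc$p_single + cc$p_double))
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}

# ranking direction per metric: evolution-based predictors rank smallest
# first, covariation scores largest first
metric_direction <- function(metric) {
  smallest <- c("rate_mean", "rate_abs_diff", "mp_ind", "mp_dep", "sd_ratio")
  if (metric %in% smallest) "smallest" else "largest"
}

#' Parsimony decomposition for every column pair of an alignment
#'
#' Computes the per-pair single/double branch classification, `mp_ind`,
#' `mp_dep`, and the single:double ratio for all column pairs at once,
#' reusing one deterministic reconstruction per column and a vectorised
#' joint-character Fitch pass for `mp_dep`. Equivalent to calling
#' [pair_branch_changes()] on every pair, but much faster.
#'
#' @param tree A `"phylo"` tree.
#' @param aln A `"coevar_aln"` alignment whose rownames match the tree.
#' @param columns Original 1-based column indices to report.
#' @param mp_dep Set `FALSE` to skip the joint-character pass.
#' @return `data.frame` with columns `i`, `j`, `n_single`, `n_double`,
#'   `mp_ind`, `sd_ratio`, and (optionally) `mp_dep`.
#' @export
parsimony_pair_table <- function(tree, aln,
                                 columns = seq_len(ncol(aln)),
                                 mp_dep = TRUE) {
  L <- ncol(aln)
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  fc <- integer(L)
  chg <- matrix(FALSE, n_edge, L)
  codes <- matrix(NA_integer_, n_tip, L)
  n_states <- integer(L)
  for (m in seq_len(L)) {
    col <- stats::setNames(aln[, m], rownames(aln))
    fc[m] <- fitch_count(tree, col)
    a <- fitch_assign(tree, col)
    chg[, m] <- a[tree$edge[, 1]] != a[tree$edge[, 2]]
    st <- tip_states(tree, col)
    alpha <- column_alphabet(st)
    if (length(alpha) == 0L) alpha <- "?"
    codes[, m] <- match(st, alpha)
    n_states[m] <- length(alpha)
  }
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  chA <- chg[, pairs[, 1], drop = FALSE]
  chB <- chg[, pairs[, 2], drop = FALSE]
  n_single <- colSums(chA != chB)
  n_double <- colSums(chA & chB)
  sd_ratio <- ifelse(n_double == 0L & n_single == 0L, NA_real_,
                     ifelse(n_double == 0L, Inf, n_single / n_double))
  out <- data.frame(i = columns[pairs[, 1]], j = columns[pairs[, 2]],
                    n_single = as.integer(n_single),
                    n_double = as.integer(n_double),
                    mp_ind = fc[pairs[, 1]] + fc[pairs[, 2]],
                    sd_ratio = sd_ratio)
  if (mp_dep) out$mp_dep <- joint_fitch_counts(tree, codes, n_states, pairs)
  out
}

#' Full per-dataset pair decomposition
#'
#' Assembles the central pair table for one dataset: covariation metrics on
#' variable-column pairs, parsimony single/double decomposition and rate
#' statistics on all pairs (parsimony-based analyses deliberately include
#' invariant sites, which covariation cannot see), and, when a structure is
#' available, contact labels. Then, for each metric, selects the top
#' `floor(L/5)` pairs, computes precision against contacts with a bootstrap
#' random-expectation band, and compares the selected values of companion
#' quantities against the remaining pairs.
#'
#' @param aln A `"coevar_aln"` alignment.
#' @param tree Optional `"phylo"` tree with leaves matching the alignment.
#' @param contacts Optional `data.frame(i, j, contact)` of structural
#'   labels keyed by alignment columns.
#' @param rates Optional per-column rate vector (length `ncol(aln)`); when
#'   absent and a tree is given, the parsimony rate proxy is used.
#' @param accessibility Optional per-column accessibility vector for
#'   median-accessibility comparisons.
#' @param covariation_metrics Metrics passed to [pair_score_table()].
#' @param k Selection size; default `floor(L/5)`, minimum 1.
#' @param n_boot,seed Bootstrap replicates and master seed.
#' @return List with `pair_table`, `selections` (per metric), `evaluation`
#'   (per-metric precision and band, when contacts given), `comparisons`
#'   (median accessibility selected vs rest, when accessibility given),
#'   and `log` (filtering bookkeeping).
#' @export
run_dataset_analysis <- function(aln, tree = NULL, contacts = NULL,
                                 rates = NULL, accessibility = NULL,
                                 covariation_metrics = c("mi", "mi_over_hxy",
                                                         "mip", "chi2"),
                                 k = NULL, n_boot = 1000L, seed = 1L) {
  L <- ncol(aln)
  if (is.null(k)) k <- max(1L, floor(L / 5))
  if (!is.null(tree)) validate_tree_alignment(tree, aln)
  flt <- filter_invariant_columns(aln)
  log <- list(n_columns = L, n_variable = length(flt$kept),
              n_invariant_removed = L - length(flt$kept))
  # master grid of all pairs in original coordinates
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  tab <- data.frame(i = pairs[, 1], j = pairs[, 2])
  if (length(flt$kept) >= 2L) {
    cov_tab <- pair_score_table(flt$alignment, columns = flt$kept,
                                metrics = covariation_metrics,
                                seed = derive_seed(seed, "mi_adj"))
    tab <- merge(tab, cov_tab, by = c("i", "j"), all.x = TRUE, sort = FALSE)
  }
  if (!is.null(tree)) {
    par_tab <- parsimony_pair_table(tree, aln)
    tab <- merge(tab, par_tab, by = c("i", "j"), all.x = TRUE, sort = FALSE)
    if (is.null(rates))
      rates <- vapply(seq_len(L), function(m)
        site_rate_proxy(tree, stats::setNames(aln[, m], rownames(aln))),
        numeric(1))
  }
  if (!is.null(rates)) {
    if (length(rates) != L) stop_invalid("'rates' must have one entry per column")
    rs <- pair_rate_stats(rates[tab$i], rates[tab$j])
    tab$rate_mean <- rs$rate_mean
    tab$rate_abs_diff <- rs$rate_abs_diff
  }
  if (!is.null(contacts)) {
    key <- function(d) paste(pmin(d$i, d$j), pmax(d$i, d$j))
    tab$contact <- contacts$contact[match(key(tab), key(contacts))]
  }
  tab <- tab[order(tab$i, tab$j), , drop = FALSE]
  rownames(tab) <- NULL
  log$n_pairs <- nrow(tab)
  metric_cols <- setdiff(names(tab), c("i", "j", "h_i", "h_j", "contact",
                                       "n_single", "n_double"))
  selections <- list(); evaluation <- list(); comparisons <- list()
  for (m in metric_cols) {
    n_ok <- sum(!is.na(tab[[m]]))
    if (n_ok < k) next
    sel <- suppressWarnings(
      select_top_pairs(tab, m, k = k, direction = metric_direction(m)))
    selections[[m]] <- sel[, c("i", "j", m)]
    if (!is.null(contacts)) {
      universe <- tab$contact[!is.na(tab[[m]]) & !is.na(tab$contact)]
      prec <- precision(sel, tab)
      band <- bootstrap_random_expectation(mean, universe, k,
                                           n_reps = n_boot,
                                           seed = derive_seed(seed,
                                                              paste0("boot_", m)))
      evaluation[[m]] <- data.frame(metric = m, k = k, precision = prec,
                                    rand_lo = band["lo"], rand_hi = band["hi"],
                                    row.names = NULL)
    }
    if (!is.null(accessibility)) {
      sel_key <- paste(sel$i, sel$j)
      all_key <- paste(tab$i, tab$j)
      wacc <- (accessibility[tab$i] + accessibility[tab$j]) / 2
      in_sel <- all_key %in% sel_key
      ok <- !is.na(wacc) & !is.na(tab[[m]])
      comparisons[[m]] <- median_comparison(wacc[ok & in_sel],
                                            wacc[ok & !in_sel])
    }
  }
  evaluation <- if (length(evaluation)) do.call(rbind, evaluation) else NULL
  list(pair_table = tab, selections = selections, evaluation = evaluation,
       comparisons = comparisons, k = k, log = log)
}

#' Synthetic end-to-end benchmark
#'
#' Repeatedly generates a dataset from the configuration (alignment + tree
#' + rate-coupled synthetic structure), runs the full pair decomposition,
#' and records each metric's precision at `floor(L/5)` against its 95%
#' bootstrap random band, plus the coevolution-paradox statistics (pooled
#' double-change branch fraction and total change counts of the true
#' coevolving pairs versus independent pairs).
#'
#' @param config A [synthetic_config()]; its `rho`, `coevolving_S`, sizes
#'   and thresholds define the study conditions.
#' @param n_replicates Number of replicate datasets.
#' @param seed Master seed; replicate r uses a derived substream.
#' @param evaluate_metrics If `FALSE`, skip the per-metric precision
#'   evaluation and only compute the paradox statistics (faster).
#' @return List with `metrics` (`data.frame`: replicate, metric, k,
#'   precision, rand_lo, rand_hi, inside) and `paradox` (`data.frame` per
#'   replicate: pooled double fraction and mean total changes for
#'   coevolving and independent pairs).
#' @export
run_synthetic_benchmark <- function(config, n_replicates = 50L, seed = 1L,
                                    evaluate_metrics = TRUE) {
  metrics_rows <- list(); paradox_rows <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("replicate", r))
    sim <- simulate_alignment(cfg)
    L <- ncol(sim$alignment)
    # burial couples to the true per-column rate; a coevolving column's
    # rate is the model-predicted relative rate at its S
    true_rates <- sim$truth$site_rates
    if (nrow(sim$truth$coevolving_pairs)) {
      for (p in seq_len(nrow(sim$truth$coevolving_pairs))) {
        pp <- sim$truth$coevolving_pairs[p, ]
        rr <- relative_rate(pair_model_params(S = pp$S, t = 1, pi0 = cfg$pi0))
        true_rates[c(pp$col_i, pp$col_j)] <- rr
      }
    }
    struct <- synthetic_structure(true_rates, cfg$rho,
                                  seed = derive_seed(cfg$seed, "structure"),
                                  threshold = cfg$contact_threshold)
    if (evaluate_metrics) {
      res <- run_dataset_analysis(sim$alignment, tree = sim$tree,
                                  contacts = struct$contacts,
                                  seed = derive_seed(cfg$seed, "analysis"))
      if (!is.null(res$evaluation)) {
        ev <- res$evaluation
        ev$replicate <- r
        ev$inside <- ev$precision >= ev$rand_lo & ev$precision <= ev$rand_hi
        metrics_rows[[r]] <- ev
      }
    }
    cp <- sim$truth$coevolving_pairs
    if (nrow(cp)) {
      coev <- lapply(seq_len(nrow(cp)), function(p)
        pair_branch_changes(sim$tree,
                            stats::setNames(sim$alignment[, cp$col_i[p]],
                                            rownames(sim$alignment)),
                            stats::setNames(sim$alignment[, cp$col_j[p]],
                                            rownames(sim$alignment))))
      ind_cols <- setdiff(seq_len(L), c(cp$col_i, cp$col_j))
      ind_pairs <- with_seed(derive_seed(cfg$seed, "indpairs"), {
        replicate(nrow(cp), sort(sample(ind_cols, 2)), simplify = FALSE)
      })
      ind <- lapply(ind_pairs, function(pr)
        pair_branch_changes(sim$tree,
                            stats::setNames(sim$alignment[, pr[1]],
                                            rownames(sim$alignment)),
                            stats::setNames(sim$alignment[, pr[2]],
                                            rownames(sim$alignment))))
      pool <- function(lst) {
        s <- sum(vapply(lst, `[[`, integer(1), "n_single_branches"))
        d <- sum(vapply(lst, `[[`, integer(1), "n_double_branches"))
        tot <- mean(vapply(lst, `[[`, integer(1), "mp_ind"))
        c(single = s, double = d,
          double_fraction = if (s + d > 0) d / (s + d) else NA_real_,
          mean_total_changes = tot)
      }
      pc <- pool(coev); pi_ <- pool(ind)
      paradox_rows[[r]] <- data.frame(
        replicate = r,
        coev_double_fraction = pc["double_fraction"],
        ind_double_fraction = pi_["double_fraction"],
        coev_mean_total_changes = pc["mean_total_changes"],
        ind_mean_total_changes = pi_["mean_total_changes"],
        row.names = NULL)
    }
  }
  list(metrics = if (length(metrics_rows)) do.call(rbind, metrics_rows) else NULL,
       paradox = if (length(paradox_rows)) do.call(rbind, paradox_rows) else NULL)
}
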
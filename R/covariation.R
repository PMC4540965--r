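# Column-pair covariation statistics. All information measures use log base
# 2 (bits), so an even two-state split has entropy 1 and a pair of identical
# even-split columns has the interpretable maximum MI of 1 bit. Gaps are
# handled by pairwise-complete deletion: for each pair, rows with a gap in
# either column are excluded, and marginals are recomputed on the kept rows.

drop_gaps <- function(col) col[col != GAP]

# joint count table over pairwise-complete rows (fast tabulate-based core
# shared by the MI-family and chi-square statistics)
joint_counts <- function(colA, colB) {
  la <- sort(unique(colA)); lb <- sort(unique(colB))
  ia <- match(colA, la); ib <- match(colB, lb)
  tab <- matrix(tabulate(ia + (ib - 1L) * length(la),
                         nbins = length(la) * length(lb)),
                nrow = length(la), dimnames = list(la, lb))
  tab
}

#' Shannon entropy of an alignment column
#'
#' Entropy in bits of the non-gap symbol frequencies.
#'
#' @param col Character vector of symbols for one column.
#' @return Entropy in bits.
#' @export
column_entropy <- function(col) {
  x <- drop_gaps(col)
  if (length(x) == 0L) stop_invalid("column contains only gaps")
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# rows where both columns are non-gap; errors if fewer than `min_n`
complete_rows <- function(colA, colB, min_n = 2L) {
  if (length(colA) != length(colB))
    stop_invalid("columns must have equal length")
  ok <- colA != GAP & colB != GAP
  if (sum(ok) < min_n)
    stop_invalid("fewer than %d rows where both columns are non-gap", min_n)
  ok
}

#' Mutual information between two alignment columns
#'
#' `sum p(x,y) log2(p(x,y) / (p(x) p(y)))` over pairwise-complete rows,
#' with frequencies taken as raw counts / n (no pseudocounts). Bounded by
#' `0 <= MI <= min(H_A, H_B)`.
#'
#' @param colA,colB Character vectors of symbols (equal length).
#' @return MI in bits.
#' @export
mutual_information <- function(colA, colB) {
  ok <- complete_rows(colA, colB)
  tab <- joint_counts(colA[ok], colB[ok])
  n <- sum(tab)
  pj <- tab / n
  px <- rowSums(pj); py <- colSums(pj)
  e <- outer(px, py)
  nz <- pj > 0
  mi <- sum(pj[nz] * log2(pj[nz] / e[nz]))
  max(mi, 0)    # clip tiny negative rounding
}

#' MI normalised by the joint entropy
#'
#' `MI / H(X, Y)` on the pairwise-complete rows; lies in `[0, 1]` and
#' corrects MI for the entropy of the pair. Undefined when both columns are
#' constant (such pairs are removed upstream by [filter_invariant_columns()]).
#'
#' @param colA,colB Character vectors of symbols.
#' @return Scalar in `[0, 1]`.
#' @export
mi_over_joint_entropy <- function(colA, colB) {
  ok <- complete_rows(colA, colB)
  tab <- joint_counts(colA[ok], colB[ok])
  pj <- tab / sum(tab)
  nz <- pj > 0
  hxy <- -sum(pj[nz] * log2(pj[nz]))
  if (hxy <= 0) stop_invalid("joint entropy is zero (both columns constant)")
  mutual_information(colA, colB) / hxy
}

#' Average-product correction of an MI matrix
#'
#' `MIp(a, b) = MI(a, b) - MI(a, .) * MI(b, .) / <MI>`, where `MI(a, .)` is
#' the mean MI of column a with all other columns and `<MI>` the mean over
#' all pairs. Removes the shared background component (phylogeny, column
#' entropy) from the raw MI signal.
#'
#' @param mi_matrix Symmetric matrix of pairwise MI (diagonal ignored).
#' @return Matrix of the same shape with the corrected scores.
#' @export
mip <- function(mi_matrix) {
  n <- nrow(mi_matrix)
  if (n < 3L) stop_invalid("APC needs at least 3 columns")
  M <- mi_matrix
  diag(M) <- 0
  col_mean <- colSums(M) / (n - 1)
  overall <- sum(M) / (n * (n - 1))
  if (overall <= 0) stop_invalid("degenerate alignment: mean MI is zero")
  apc <- outer(col_mean, col_mean) / overall
  out <- mi_matrix - apc
  diag(out) <- NA_real_
  out
}

#' Permutation-null corrected MI
#'
#' MI minus the mean MI of `n_shuffles` row-permuted replicates of the
#' second column. This is a background-noise correction in the spirit of
#' published shuffle-null MI adjustments; the exact published formula is
#' not re-derived here.
#'
#' @param colA,colB Character vectors of symbols.
#' @param n_shuffles Number of permutation replicates (0 returns raw MI).
#' @param seed Integer seed; output is reproducible given the seed.
#' @return Corrected MI (may be negative).
#' @export
mi_adj <- function(colA, colB, n_shuffles = 20L, seed = 1L) {
  if (!is.numeric(n_shuffles) || n_shuffles < 0)
    stop_invalid("'n_shuffles' must be >= 0")
  base_mi <- mutual_information(colA, colB)
  if (n_shuffles == 0) return(base_mi)
  null_mi <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    mutual_information(colA, sample(colB))
  }, numeric(1)))
  base_mi - mean(null_mi)
}

#' Pearson chi-square statistic for a column pair
#'
#' `sum (O - E)^2 / E` over cells of the pairwise-complete joint table,
#' with expectations from the product of marginals scaled to n. No
#' continuity correction; cells with zero expectation are skipped.
#'
#' @param colA,colB Character vectors of symbols.
#' @return Non-negative statistic.
#' @export
chi_square_pair <- function(colA, colB) {
  ok <- complete_rows(colA, colB)
  tab <- joint_counts(colA[ok], colB[ok])
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  use <- E > 0
  sum((tab[use] - E[use])^2 / E[use])
}

#' All-pairs covariation score table
#'
#' Computes every internal metric for each unordered column pair of an
#' alignment and returns the pipeline's central exchange format: one row per
#' pair `(i, j)`, `i < j` in the supplied (original) column numbering.
#'
#' @param aln A `"coevar_aln"` matrix (typically already passed through
#'   [filter_invariant_columns()]).
#' @param columns Original 1-based column indices to report (defaults to
#'   `1:ncol(aln)`); must have the alignment's number of columns.
#' @param metrics Character subset of
#'   `c("mi", "mi_over_hxy", "mip", "mi_adj", "chi2")`.
#' @param n_shuffles,seed Passed to [mi_adj()].
#' @return A `data.frame` with columns `i`, `j`, `h_i`, `h_j` and one column
#'   per requested metric.
#' @export
pair_score_table <- function(aln, columns = seq_len(ncol(aln)),
                             metrics = c("mi", "mi_over_hxy", "mip", "chi2"),
                             n_shuffles = 20L, seed = 1L) {
  metrics <- match.arg(metrics,
                       c("mi", "mi_over_hxy", "mip", "mi_adj", "chi2"),
                       several.ok = TRUE)
  L <- ncol(aln)
  if (length(columns) != L) stop_invalid("'columns' must match ncol(aln)")
  if (L < 2L) stop_invalid("need at least 2 columns")
  ent <- vapply(seq_len(L), function(j) column_entropy(aln[, j]), numeric(1))
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  np <- nrow(pairs)
  mi_m <- matrix(NA_real_, L, L)
  out <- data.frame(i = columns[pairs[, 1]], j = columns[pairs[, 2]],
                    h_i = ent[pairs[, 1]], h_j = ent[pairs[, 2]])
  need_mi <- any(c("mi", "mip", "mi_over_hxy") %in% metrics)
  mi_v <- hxy_v <- chi_v <- adj_v <- rep(NA_real_, np)
  for (r in seq_len(np)) {
    a <- aln[, pairs[r, 1]]; b <- aln[, pairs[r, 2]]
    if (need_mi) {
      m <- mutual_information(a, b)
      mi_v[r] <- m
      mi_m[pairs[r, 1], pairs[r, 2]] <- mi_m[pairs[r, 2], pairs[r, 1]] <- m
    }
    if ("mi_over_hxy" %in% metrics) hxy_v[r] <- mi_over_joint_entropy(a, b)
    if ("chi2" %in% metrics) chi_v[r] <- chi_square_pair(a, b)
    if ("mi_adj" %in% metrics)
      adj_v[r] <- mi_adj(a, b, n_shuffles = n_shuffles,
                         seed = derive_seed(seed, paste0("mi_adj", r)))
  }
  if ("mi" %in% metrics) out$mi <- mi_v
  if ("mi_over_hxy" %in% metrics) out$mi_over_hxy <- hxy_v
  if ("mip" %in% metrics) {
    mp <- mip(mi_m)
    out$mip <- mp[cbind(pairs[, 1], pairs[, 2])]
  }
  if ("mi_adj" %in% metrics) out$mi_adj <- adj_v
  if ("chi2" %in% metrics) out$chi2 <- chi_v
  out
}

#' Read an external covariation score table
#'
#' Parses whitespace- or comma-delimited files of `i j score` rows (1-based
#' residue indices), the common output shape of external direct-coupling
#' and sparse-inverse-covariance contact predictors. Scores are consumed,
#' never re-derived.
#'
#' @param path File path. Lines starting with `#` are skipped.
#' @param name Metric name for the returned column (e.g. `"psicov"`).
#' @param n_columns Optional alignment length; indices are validated
#'   against it when given.
#' @param i_col,j_col,score_col 1-based field positions in each row.
#' @return `data.frame` with columns `i`, `j`, `<name>`; duplicate pairs are
#'   resolved last-wins with a warning; self-pairs are rejected.
#' @export
read_external_scores <- function(path, name = "external", n_columns = NULL,
                                 i_col = 1L, j_col = 2L, score_col = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  ii <- jj <- ss <- numeric(length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    fields <- strsplit(trimws(lines[ln]), "[,[:space:]]+")[[1]]
    sc <- if (is.null(score_col)) length(fields) else score_col
    vals <- suppressWarnings(as.numeric(fields[c(i_col, j_col, sc)]))
    if (length(fields) < max(i_col, j_col, sc) || any(is.na(vals)))
      stop_invalid("malformed score row at line %d: '%s'", ln, lines[ln])
    if (vals[1] == vals[2])
      stop_invalid("self-pair (i = j = %d) at line %d", vals[1], ln)
    if (vals[1] %% 1 != 0 || vals[2] %% 1 != 0 || vals[1] < 1 || vals[2] < 1)
      stop_invalid("indices must be positive integers at line %d", ln)
    if (!is.null(n_columns) && max(vals[1:2]) > n_columns)
      stop_invalid("index %d out of range (alignment has %d columns) at line %d",
                   max(vals[1:2]), n_columns, ln)
    ii[k] <- min(vals[1:2]); jj[k] <- max(vals[1:2]); ss[k] <- vals[3]
  }
  out <- data.frame(i = as.integer(ii), j = as.integer(jj), value = ss)
  key <- paste(out$i, out$j)
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate pair(s) in %s; keeping last occurrence",
                    sum(duplicated(key)), path), call. = FALSE)
    out <- out[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  out <- out[order(out$i, out$j), , drop = FALSE]
  names(out)[3] <- name
  rownames(out) <- NULL
  out
}

#' Merge external scores into a pair score table
#'
#' @param table A [pair_score_table()] data.frame.
#' @param external Output of [read_external_scores()].
#' @return `table` with the external metric column added (NA where the
#'   external file has no entry for a pair).
#' @export
add_external_scores <- function(table, external) {
  name <- setdiff(names(external), c("i", "j"))
  m <- merge(table, external, by = c("i", "j"), all.x = TRUE, sort = FALSE)
  m[order(m$i, m$j), , drop = FALSE]
}
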
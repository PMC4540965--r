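# Small parsimony on rooted trees (ape "phylo" objects) via the
# Fitch/Hartigan algorithm, generalized to multifurcations: at each internal
# node the state set is the set of states present in the maximal number of
# child sets, and the change count increases by (number of children - that
# maximum). Gaps and ambiguity codes are missing data and contribute the
# full state set (no constraint). State sets are integer bitmasks over the
# column's observed alphabet.

#' Read a Newick tree
#'
#' Thin validated wrapper around [ape::read.tree()]. Branch lengths are
#' preserved; trees without them get unit lengths with a warning. The tree
#' is used rooted at ape's basal node, which is deterministic for a given
#' Newick string.
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param text Optional Newick string instead of a file.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch({
    if (!is.null(text)) ape::read.tree(text = text) else {
      if (!file.exists(path)) stop_invalid("tree file not found: %s", path)
      ape::read.tree(path)
    }
  }, error = function(e)
    stop_invalid("failed to parse Newick input: %s", conditionMessage(e)))
  if (is.null(tr)) stop_invalid("failed to parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stop_invalid("duplicate leaf labels: %s",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                       collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; using unit lengths", call. = FALSE)
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  if (any(tr$edge.length < 0)) stop_invalid("negative branch lengths")
  tr
}

#' Check that tree leaves match alignment identifiers
#'
#' @param tree A `"phylo"` tree.
#' @param aln A `"coevar_aln"` matrix.
#' @return `TRUE` invisibly; errors listing offenders on mismatch.
#' @export
validate_tree_alignment <- function(tree, aln) {
  only_tree <- setdiff(tree$tip.label, rownames(aln))
  only_aln <- setdiff(rownames(aln), tree$tip.label)
  if (length(only_tree) || length(only_aln))
    stop_invalid(
      "leaf/identifier mismatch; only in tree: [%s]; only in alignment: [%s]",
      paste(only_tree, collapse = ", "), paste(only_aln, collapse = ", "))
  invisible(TRUE)
}

# column -> character vector ordered by tree$tip.label; NA for missing/gap
tip_states <- function(tree, column) {
  if (!is.null(names(column))) {
    miss <- setdiff(tree$tip.label, names(column))
    if (length(miss))
      stop_invalid("column lacks states for leaves: %s",
                   paste(miss, collapse = ", "))
    column <- column[tree$tip.label]
  } else if (length(column) != length(tree$tip.label)) {
    stop_invalid("unnamed column must have one state per leaf")
  }
  column[column %in% c(GAP, "?", "X", "N/A")] <- NA_character_
  as.character(column)
}

# children list and postorder node sequence for a phylo tree
tree_topology <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  kids <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  po <- ape::reorder.phylo(tree, "postorder")$edge[, 1]
  list(n_tip = n_tip, n_node = n_node, children = kids,
       internal_postorder = unique(po), root = n_tip + 1L)
}

# Bottom-up Fitch/Hartigan pass. Returns list(count, sets) where sets is an
# integer bitmask per node over `alphabet`.
fitch_up <- function(tree, states, alphabet, topo = tree_topology(tree)) {
  k <- length(alphabet)
  if (k > 30L) stop_invalid("alphabet too large for bitmask parsimony (%d)", k)
  full <- bitwShiftL(1L, k) - 1L
  sets <- integer(topo$n_node)
  idx <- match(states, alphabet)
  sets[seq_len(topo$n_tip)] <-
    ifelse(is.na(idx), full, bitwShiftL(1L, idx - 1L))
  count <- 0L
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  for (v in topo$internal_postorder) {
    ch <- topo$children[[v]]
    cover <- integer(k)
    for (c in ch) {
      has <- bitwAnd(sets[c], bits) != 0L
      cover <- cover + has
    }
    K <- max(cover)
    sets[v] <- sum(bits[cover == K])
    count <- count + (length(ch) - K)
  }
  list(count = count, sets = sets, full = full)
}

column_alphabet <- function(states) {
  a <- sort(unique(states[!is.na(states)]))
  if (length(a) == 0L) character(0) else a
}

# Vectorised Fitch/Hartigan over many joint characters at once: counts the
# minimum joint-character changes for every column pair in `pairs`.
# `codes` is an n_tip x L integer matrix of per-column state codes (NA =
# missing); `n_states` gives each column's alphabet size. Joint alphabets
# are capped at 30 states (bitmask width).
joint_fitch_counts <- function(tree, codes, n_states, pairs) {
  topo <- tree_topology(tree)
  np <- nrow(pairs)
  ka <- n_states[pairs[, 1]]; kb <- n_states[pairs[, 2]]
  kj <- ka * kb
  if (any(kj > 30L))
    stop_invalid("joint alphabet too large for bitmask parsimony")
  full <- bitwShiftL(1L, kj) - 1L
  M <- matrix(0L, np, topo$n_node)
  for (tip in seq_len(topo$n_tip)) {
    a <- codes[tip, pairs[, 1]]; b <- codes[tip, pairs[, 2]]
    joint <- (a - 1L) * kb + b                      # 1-based joint code
    M[, tip] <- ifelse(is.na(joint), full, bitwShiftL(1L, joint - 1L))
  }
  counts <- integer(np)
  max_k <- max(kj)
  bits <- bitwShiftL(1L, seq_len(max_k) - 1L)
  for (v in topo$internal_postorder) {
    ch <- topo$children[[v]]
    cover <- matrix(0L, np, max_k)
    for (c in ch) for (s in seq_len(max_k))
      cover[, s] <- cover[, s] + (bitwAnd(M[, c], bits[s]) != 0L)
    K <- do.call(pmax, lapply(seq_len(max_k), function(s) cover[, s]))
    counts <- counts + (length(ch) - K)
    newmask <- integer(np)
    for (s in seq_len(max_k))
      newmask <- newmask + bits[s] * (cover[, s] == K)
    M[, v] <- newmask
  }
  counts
}

#' Minimum parsimony change count for one column
#'
#' Fitch/Hartigan small-parsimony count of the minimum number of state
#' changes needed to explain the leaf states on the tree. Gaps are missing
#' data and contribute no constraint; a column with fewer than two observed
#' states costs 0.
#'
#' @param tree A `"phylo"` tree.
#' @param column Character vector of leaf states, named by tip label or in
#'   `tree$tip.label` order; `-`, `?`, and `NA` are missing.
#' @return Non-negative integer.
#' @export
fitch_count <- function(tree, column) {
  states <- tip_states(tree, column)
  alphabet <- column_alphabet(states)
  if (length(alphabet) <= 1L) return(0L)
  fitch_up(tree, states, alphabet)$count
}

#' Deterministic most-parsimonious ancestral assignment
#'
#' One most-parsimonious reconstruction: bottom-up Fitch/Hartigan state
#' sets, then a top-down pass that keeps the parent's state whenever it is
#' in the node's set and otherwise takes the alphabetically smallest member
#' (the root also takes its set's alphabetically smallest state). Missing
#' leaves inherit the parent's state, so they imply no change.
#'
#' @inheritParams fitch_count
#' @return Character vector of states for all nodes (tips first, then
#'   internal nodes, in ape numbering), with attribute `"changes"` giving
#'   the implied change count.
#' @export
fitch_assign <- function(tree, column) {
  states <- tip_states(tree, column)
  topo <- tree_topology(tree)
  alphabet <- column_alphabet(states)
  assign <- character(topo$n_node)
  if (length(alphabet) == 0L) alphabet <- "?"
  if (length(alphabet) == 1L) {
    assign[] <- alphabet
    attr(assign, "changes") <- 0L
    return(assign)
  }
  up <- fitch_up(tree, states, alphabet, topo)
  bits <- bitwShiftL(1L, seq_along(alphabet) - 1L)
  pick <- function(set, preferred = NULL) {
    if (!is.null(preferred)) {
      pb <- bits[match(preferred, alphabet)]
      if (bitwAnd(set, pb) != 0L) return(preferred)
    }
    alphabet[which(bitwAnd(set, bits) != 0L)[1]]   # alphabetically smallest
  }
  # preorder: parents before children
  preorder <- rev(topo$internal_postorder)
  assign[topo$root] <- pick(up$sets[topo$root])
  for (v in preorder) {
    for (c in topo$children[[v]]) {
      if (c <= topo$n_tip && is.na(states[c])) {
        assign[c] <- assign[v]                      # missing tip: no change
      } else if (c <= topo$n_tip) {
        assign[c] <- states[c]
      } else {
        assign[c] <- pick(up$sets[c], preferred = assign[v])
      }
    }
  }
  changes <- sum(assign[tree$edge[, 1]] != assign[tree$edge[, 2]])
  attr(assign, "changes") <- as.integer(changes)
  assign
}

#' Parsimony decomposition of a column pair into single and double changes
#'
#' Reconstructs ancestral states for the two columns and classifies every
#' branch: a double-change branch has changes at both sites, a
#' single-change branch at exactly one. `mp_ind` is the sum of the two
#' independent Fitch minima (parsimony without coevolution, counting
#' changes); `mp_dep` treats the pair as one joint character over the
#' product alphabet and counts branches with any change (parsimony assuming
#' coevolution, counting branches).
#'
#' @param tree A `"phylo"` tree.
#' @param colA,colB Leaf state vectors as in [fitch_count()].
#' @param classify `"per-site"` (default) classifies branches from the two
#'   per-site reconstructions; `"joint"` classifies them from the
#'   joint-character reconstruction.
#' @return Object of class `"pair_change_counts"`: list with
#'   `n_single_branches`, `n_double_branches`, `mp_ind`, `mp_dep`.
#' @export
pair_branch_changes <- function(tree, colA, colB,
                                classify = c("per-site", "joint")) {
  classify <- match.arg(classify)
  sA <- tip_states(tree, colA)
  sB <- tip_states(tree, colB)
  joint <- ifelse(is.na(sA) | is.na(sB), NA_character_, paste(sA, sB, sep = "|"))
  names(joint) <- tree$tip.label
  mp_ind <- fitch_count(tree, colA) + fitch_count(tree, colB)
  mp_dep <- fitch_count(tree, stats::setNames(joint, tree$tip.label))
  if (classify == "per-site") {
    aA <- fitch_assign(tree, colA)
    aB <- fitch_assign(tree, colB)
    chA <- aA[tree$edge[, 1]] != aA[tree$edge[, 2]]
    chB <- aB[tree$edge[, 1]] != aB[tree$edge[, 2]]
  } else {
    aJ <- fitch_assign(tree, joint)
    from <- strsplit(aJ[tree$edge[, 1]], "|", fixed = TRUE)
    to <- strsplit(aJ[tree$edge[, 2]], "|", fixed = TRUE)
    chA <- vapply(seq_along(from), function(e) from[[e]][1] != to[[e]][1],
                  logical(1))
    chB <- vapply(seq_along(from), function(e) from[[e]][2] != to[[e]][2],
                  logical(1))
  }
  out <- list(n_single_branches = as.integer(sum(xor(chA, chB))),
              n_double_branches = as.integer(sum(chA & chB)),
              mp_ind = as.integer(mp_ind),
              mp_dep = as.integer(mp_dep))
  class(out) <- "pair_change_counts"
  out
}

#' @export
print.pair_change_counts <- function(x, ...) {
  cat(sprintf(
    "Pair changes: %d single-change, %d double-change branches (MP_ind = %d, MP_dep = %d)\n",
    x$n_single_branches, x$n_double_branches, x$mp_ind, x$mp_dep))
  invisible(x)
}

#' Ratio of single- to double-change branches
#'
#' Ranking statistic for the tree-aware coevolution predictor: pairs with
#' the smallest ratio show the strongest excess of same-branch double
#' changes. Returns `Inf` when there are singles but no doubles (ranked
#' last when selecting smallest) and `NA` when there are no changes at all
#' (excluded from ranking).
#'
#' @param counts A `"pair_change_counts"` object.
#' @return Numeric scalar, `Inf`, or `NA`.
#' @export
single_double_ratio <- function(counts) {
  s <- counts$n_single_branches
  d <- counts$n_double_branches
  if (d == 0L && s == 0L) return(NA_real_)
  if (d == 0L) return(Inf)
  s / d
}

#' Parsimony-based evolutionary rate proxy for one column
#'
#' Fitch change count divided by total tree length: a crude per-site rate
#' usable when no maximum-likelihood rate table is supplied.
#'
#' @inheritParams fitch_count
#' @return Non-negative scalar (changes per unit branch length).
#' @export
site_rate_proxy <- function(tree, column) {
  tl <- sum(tree$edge.length)
  if (!is.finite(tl) || tl <= 0) stop_invalid("tree has zero total length")
  fitch_count(tree, column) / tl
}
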
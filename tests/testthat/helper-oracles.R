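# Independent oracles and fixture builders used across the suite. The
# oracles deliberately use brute force / closed forms, never the package's
# own computational path.

# Exhaustive small-parsimony minimum: enumerate every state assignment to
# internal nodes (and to missing-data tips, which are unconstrained) and
# take the minimum number of changed edges.
brute_force_parsimony <- function(tree, states, alphabet = NULL) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  if (is.null(alphabet)) alphabet <- sort(unique(states[!is.na(states)]))
  if (length(alphabet) <= 1L) return(0L)
  free <- c(which(is.na(states)), (n_tip + 1L):n_node)
  grid <- as.matrix(expand.grid(rep(list(alphabet), length(free)),
                                stringsAsFactors = FALSE))
  assign_full <- matrix(rep(c(states, rep(NA_character_, tree$Nnode)),
                            each = nrow(grid)),
                        nrow = nrow(grid))
  assign_full[, free] <- grid
  changes <- rowSums(assign_full[, tree$edge[, 1], drop = FALSE] !=
                     assign_full[, tree$edge[, 2], drop = FALSE])
  as.integer(min(changes))
}

# random rooted binary tree with n leaves and unit branch lengths
random_small_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n_leaves))
  tr
}

random_column <- function(tree, n_states = 2L, p_missing = 0) {
  states <- as.character(seq_len(n_states))
  col <- sample(states, length(tree$tip.label), replace = TRUE)
  if (p_missing > 0)
    col[stats::runif(length(col)) < p_missing] <- NA_character_
  stats::setNames(col, tree$tip.label)
}

# balanced 8-leaf tree whose left clade is all state-pair 00 and right all
# 11: the canonical single-double-change-at-the-root construction
fig_tree_a <- function() {
  tr <- read_newick(
    text = "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  col <- stats::setNames(c("0", "0", "0", "0", "1", "1", "1", "1"),
                         c("a", "b", "c", "d", "e", "f", "g", "h"))
  list(tree = tr, colA = col, colB = col)
}

# tiny alignment constructor from per-sequence strings
aln_from <- function(...) {
  seqs <- c(...)
  names(seqs) <- paste0("s", seq_along(seqs))
  alignment(seqs)
}

# closed-form change-class probabilities for two independent binary sites
# with equal frequencies: per site P(differ) = (1 - exp(-t)) / 2
independent_change_probs <- function(t) {
  q <- (1 - exp(-t)) / 2
  c(p_none = (1 - q)^2, p_single = 2 * q * (1 - q), p_double = q^2)
}
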
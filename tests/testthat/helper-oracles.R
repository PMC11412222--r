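# Independent oracles and random-instance generators for the test suite.
# These deliberately re-derive quantities by different algorithms than the
# package (exhaustive enumeration, Sankoff cost vectors, subset search) so
# that agreement is informative.

# Exhaustive small-parsimony minimum: try every assignment of a single state
# to every internal node. `sets` is a list over tip indices of integer state
# vectors; an empty vector means the tip is free (missing/inapplicable).
brute_fitch <- function(tree, sets) {
  states <- sort(unique(unlist(sets)))
  if (length(states) < 2L) return(0L)
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(states), n_int)))
  cost <- numeric(nrow(grid))
  for (r in seq_len(nrow(tree$edge))) {
    u <- tree$edge[r, 1]
    v <- tree$edge[r, 2]
    su <- grid[, u - n_tip]
    if (v <= n_tip) {
      allowed <- sets[[v]]
      if (length(allowed) == 0L) next
      cost <- cost + !(su %in% allowed)
    } else {
      cost <- cost + (su != grid[, v - n_tip])
    }
  }
  as.integer(min(cost))
}

# Uniform-cost Sankoff dynamic program (cost vectors over observed states).
sankoff_steps <- function(tree, sets) {
  states <- sort(unique(unlist(sets)))
  if (length(states) < 2L) return(0L)
  n_tip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  big <- 1e9
  cost <- matrix(0, n_tip + tree$Nnode, length(states))
  for (i in seq_len(n_tip)) {
    s <- sets[[i]]
    if (length(s) > 0L) cost[i, ] <- ifelse(states %in% s, 0, big)
  }
  for (p in unique(tree$edge[, 1])) {
    kids <- tree$edge[tree$edge[, 1] == p, 2]
    acc <- numeric(length(states))
    for (kk in kids) {
      ck <- cost[kk, ]
      acc <- acc + pmin(ck, min(ck) + 1)
    }
    cost[p, ] <- acc
  }
  as.integer(min(cost[n_tip + 1L, ]))
}

# Independent minimum-steps: smallest state subset hitting every observed
# cell, found by plain subset search on lists.
naive_min_steps <- function(sets) {
  sets <- Filter(function(s) length(s) > 0L, sets)
  if (length(sets) == 0L) return(0L)
  uni <- sort(unique(unlist(sets)))
  for (h in seq_along(uni)) {
    for (combo in utils::combn(uni, h, simplify = FALSE)) {
      if (all(vapply(sets, function(s) any(s %in% combo), logical(1)))) {
        return(h - 1L)
      }
    }
  }
}

# Naive placement: scores every attachment with the Sankoff oracle and the
# subset-search minima, then ranks by ascending summed concave fit.
naive_place <- function(backbone, m, fossil, k) {
  refs <- enumerate_attachments(backbone)
  fits <- vapply(refs, function(rf) {
    aug <- attach_fossil(backbone, rf, fossil)
    sets <- column_sets(aug, m)
    tot <- 0
    for (j in seq_len(m$n_chars)) {
      col <- lapply(sets, `[[`, j)
      s <- sankoff_steps(aug, col)
      mm <- naive_min_steps(col)
      tot <- tot + (s - mm) / ((s - mm) + k)
    }
    tot
  }, numeric(1))
  ord <- order(fits, refs, method = "radix")
  sorted <- unname(fits[ord])
  # same tie-grouping rule as the package: relative tolerance on the group head
  rank <- integer(length(ord))
  g <- 1L
  for (i in seq_along(ord)) {
    if (i > 1L && sorted[i] - sorted[g] > 1e-9 * max(1, abs(sorted[g]))) g <- i
    rank[i] <- g
  }
  list(refs = refs[ord], fits = sorted, rank = rank)
}

# per-tip list of per-character state vectors for a tree against a matrix
column_sets <- function(tree, m) {
  idx <- match(tree$tip.label, m$taxa)
  lapply(idx, function(i) {
    lapply(seq_len(m$n_chars), function(j) {
      if (m$kind[i, j] == "observed") fossilplace::cell_states(m, m$taxa[i], j)
      else integer(0)
    })
  })
}

# Random cell: observed singleton, polymorphic pair, or unobserved.
random_cell <- function(n_states, p_missing = 0.15, p_poly = 0.15,
                        p_inapplicable = 0.05) {
  u <- stats::runif(1)
  if (u < p_missing) return("?")
  if (u < p_missing + p_inapplicable) return("-")
  if (u < p_missing + p_inapplicable + p_poly && n_states >= 2) {
    return(sort(sample.int(n_states, 2) - 1L))
  }
  sample.int(n_states, 1) - 1L
}

random_morpho_matrix <- function(n_taxa, n_chars, n_states = 3) {
  taxa <- paste0("tax", seq_len(n_taxa))
  cells <- lapply(seq_len(n_taxa), function(i) {
    lapply(seq_len(n_chars), function(j) random_cell(n_states))
  })
  morpho_matrix(taxa, cells)
}

# matrix column as a tip-indexed set list for a given tree
tree_column <- function(tree, m, j) {
  idx <- match(tree$tip.label, m$taxa)
  lapply(idx, function(i) {
    if (m$kind[i, j] == "observed") fossilplace::cell_states(m, m$taxa[i], j)
    else integer(0)
  })
}
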
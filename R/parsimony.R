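#' Implied-weights scoring configuration
#'
#' Settings for the Goloboff-style concave weighting of homoplasy. Each
#' character contributes a fit penalty `f = e / (e + k)` where `e` is its
#' extra steps (observed minus minimum conceivable) and `k` the concavity
#' constant; the tree score is the sum of fits, minimized. Larger `k`
#' penalizes homoplasy more gently and approaches equal-weights parsimony.
#'
#' @param k Concavity constant, a positive real. Default 12, the customary
#'   choice for morphological matrices of this size.
#' @param score_kind `"implied_fit_total"` (default) ranks trees by the summed
#'   concave fit; `"raw_length"` ranks by total Fitch length (the equal-weights
#'   limit).
#' @return An object of class `iw_config`.
#' @export
iw_config <- function(k = 12, score_kind = c("implied_fit_total", "raw_length")) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("concavity constant k must be a positive number", call. = FALSE)
  }
  structure(list(k = as.numeric(k), score_kind = match.arg(score_kind)),
            class = "iw_config")
}

#' Concave implied-weights fit of a character
#'
#' `implied_fit(e, k) = e / (e + k)`: zero for a homoplasy-free character and
#' strictly increasing, concave, and bounded below 1 in the extra steps `e`.
#'
#' @param e Extra steps (observed minus minimum), non-negative; vectorized.
#' @param k Concavity constant, positive.
#' @return Numeric vector of fits in `[0, 1)`.
#' @export
#' @examples
#' implied_fit(0, 12)   # 0
#' implied_fit(13, 12)  # 0.52
implied_fit <- function(e, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("concavity constant k must be a positive number", call. = FALSE)
  }
  if (any(e < 0)) stop("extra steps must be non-negative", call. = FALSE)
  e / (e + k)
}

# ---- engine ----------------------------------------------------------------

# Hartigan's generalization of the Fitch small-parsimony pass, vectorized
# across characters. `tipmask` is an n_tip x n_chars integer bitmask matrix
# aligned with tree$tip.label; mask 0 means "no observed state" and is
# expanded to the full ambiguity set of that column (the union of the states
# observed anywhere in it). At each internal node and for each state, the
# number of children whose optimal sets contain the state is counted; with
# maximum count M over states and d children, the node adds d - M steps and
# keeps the argmax states. Exact for multifurcations and ambiguous tips.
hartigan_lengths <- function(tree, tipmask) {
  n_tip <- length(tree$tip.label)
  n_chars <- ncol(tipmask)
  if (n_tip < 1L || is.null(tree$edge)) stop("empty tree", call. = FALSE)
  tree <- stats::reorder(tree, "postorder")

  full <- rep(0L, n_chars)
  for (i in seq_len(n_tip)) full <- bitwOr(full, tipmask[i, ])
  n_observed <- colSums(tipmask > 0L)
  uninformative <- n_observed < 2L
  full[full == 0L] <- 1L  # dummy state for all-unobserved columns
  S <- max(1L, ceiling(log2(max(full) + 1)))

  masks <- matrix(0L, n_tip + tree$Nnode, n_chars)
  masks[seq_len(n_tip), ] <- tipmask
  for (i in seq_len(n_tip)) {
    z <- masks[i, ] == 0L
    if (any(z)) masks[i, z] <- full[z]
  }

  steps <- numeric(n_chars)
  edges <- tree$edge
  parents <- unique(edges[, 1])  # postorder: children before parents
  for (p in parents) {
    kid_nodes <- edges[edges[, 1] == p, 2]
    d <- length(kid_nodes)
    km <- masks[kid_nodes, , drop = FALSE]
    cnts <- vector("list", S)
    best <- integer(n_chars)
    for (s in seq_len(S) - 1L) {
      bit <- bitwShiftL(1L, s)
      cnt <- colSums(matrix(bitwAnd(as.integer(km), bit) != 0L, nrow = d))
      cnts[[s + 1L]] <- cnt
      gt <- cnt > best
      best[gt] <- cnt[gt]
    }
    node_mask <- integer(n_chars)
    for (s in seq_len(S) - 1L) {
      node_mask <- node_mask + bitwShiftL(1L, s) * (cnts[[s + 1L]] == best)
    }
    masks[p, ] <- node_mask
    steps <- steps + (d - best)
  }
  steps[uninformative] <- 0
  as.integer(steps)
}

# build the tip bitmask matrix for a tree from a matrix, matching labels
tip_masks <- function(tree, m) {
  idx <- match(normalize_label(tree$tip.label), normalize_label(m$taxa))
  if (anyNA(idx)) {
    stop("tip absent from matrix: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  m$mask[idx, , drop = FALSE]
}

#' Fitch parsimony length of one character on a tree
#'
#' Minimum number of state changes over all assignments of single states to
#' internal nodes, for an unordered character. Multi-state (polymorphic or
#' ambiguous) cells are treated as "any member of the set"; missing and
#' inapplicable cells contribute the full ambiguity set. Polytomies are
#' scored exactly via Hartigan's multifurcating generalization of the Fitch
#' pass.
#'
#' @param tree A `phylo` object.
#' @param column Named list, one entry per tip: an integer vector of state
#'   codes for an observed cell (length > 1 for polymorphism), or `NULL` /
#'   `integer(0)` / `"?"` / `"-"` for an unobserved cell.
#' @return Integer: the parsimony length.
#' @export
#' @examples
#' tr <- parse_tree("((A,B),(C,D));")
#' fitch_length(tr, list(A = 0, B = 0, C = 1, D = 1))  # 1
fitch_length <- function(tree, column) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (!all(labs %in% names(column))) {
    stop("tip without a cell: ",
         paste(setdiff(labs, names(column)), collapse = ", "), call. = FALSE)
  }
  mask <- vapply(labs, function(l) {
    cl <- column[[l]]
    if (is.null(cl) || identical(cl, "?") || identical(cl, "-")) 0L
    else mask_from_states(cl)
  }, integer(1))
  hartigan_lengths(tree, matrix(mask, ncol = 1))
}

#' Minimum conceivable steps of a character on any tree
#'
#' The smallest Fitch length the column can achieve over all tree topologies
#' on its taxa: one less than the size of a minimum hitting set of the
#' observed state sets (so polymorphic cells never inflate the minimum),
#' floored at zero. This is the `m` of the homoplasy excess `e = s - m`.
#'
#' @param column A list of integer state-code vectors, one per taxon; empty
#'   vectors (or `NULL`, `"?"`, `"-"`) mark unobserved cells.
#' @return Integer minimum number of steps.
#' @export
#' @examples
#' min_steps(list(0, 1, 2))       # 2
#' min_steps(list(c(0, 1), 0, 1)) # 1
min_steps <- function(column) {
  masks <- vapply(column, function(cl) {
    if (is.null(cl) || identical(cl, "?") || identical(cl, "-")) 0L
    else mask_from_states(cl)
  }, integer(1))
  min_steps_masks(masks)
}

# minimum hitting set size - 1 on bitmask-encoded observed sets
min_steps_masks <- function(masks) {
  obs <- unique(masks[masks > 0L])
  if (length(obs) == 0L) return(0L)
  if (Reduce(bitwAnd, obs) != 0L) return(0L)  # one state covers all cells
  universe <- states_from_mask(Reduce(bitwOr, obs))
  for (h in 2:length(universe)) {
    combos <- utils::combn(universe, h)
    for (c_i in seq_len(ncol(combos))) {
      cm <- mask_from_states(combos[, c_i])
      if (all(bitwAnd(obs, cm) > 0L)) return(h - 1L)
    }
  }
  length(universe) - 1L
}

#' Score a tree against a character matrix under implied weights
#'
#' Computes, per character, the observed Fitch length `s`, the minimum
#' conceivable steps `m` (on the tree's tip set), the homoplasy excess
#' `e = s - m`, and the concave fit `f = e/(e + k)`; and totals them.
#' Characters with fewer than two observed tips carry no signal and score
#' `s = m = e = f = 0`. The tree may be rooted or unrooted; the score depends
#' only on the unrooted topology. Inapplicable cells are scored as missing
#' (full ambiguity); the cell kinds are preserved upstream so alternative
#' policies remain possible.
#'
#' @param tree A `phylo` whose tips are all taxa of `m` (a subset is fine).
#' @param m A [morpho_matrix()].
#' @param cfg An [iw_config()].
#' @return An object of class `tree_score`: list with `per_character`
#'   (data.frame of `char`, `s`, `m`, `e`, `f`), `total_fit`, `total_length`,
#'   `score` (the ranking total selected by `score_kind`), and `k`.
#' @export
tree_score <- function(tree, m, cfg = iw_config()) {
  stopifnot(inherits(tree, "phylo"), inherits(m, "morpho_matrix"),
            inherits(cfg, "iw_config"))
  tm <- tip_masks(tree, m)
  s <- hartigan_lengths(tree, tm)
  mins <- vapply(seq_len(ncol(tm)), function(j) min_steps_masks(tm[, j]),
                 integer(1))
  e <- s - mins
  f <- implied_fit(e, cfg$k)
  per <- data.frame(char = seq_len(ncol(tm)), s = s, m = mins, e = e, f = f)
  structure(
    list(per_character = per,
         total_fit = sum(f),
         total_length = sum(s),
         score = if (cfg$score_kind == "raw_length") sum(s) else sum(f),
         k = cfg$k,
         score_kind = cfg$score_kind),
    class = "tree_score"
  )
}

#' @export
print.tree_score <- function(x, ...) {
  cat("<tree_score> length ", x$total_length, ", implied-weights fit ",
      format(x$total_fit, digits = 6), " (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Export a per-character score table as TSV
#'
#' @param x A [tree_score()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_score_table <- function(x, path) {
  stopifnot(inherits(x, "tree_score"))
  utils::write.table(x$per_character, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
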
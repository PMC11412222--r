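#' Parse a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that strips square-bracket comments,
#' validates tip-label uniqueness, and errors (rather than warns) on malformed
#' input. Branch lengths, if present, are retained but ignored by all scoring
#' functions: the placement analysis is parsimony-only. Polytomies are
#' preserved.
#'
#' @param text Newick string, or `file` may be given instead.
#' @param file Optional path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_tree <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- gsub("\\[[^]\\[]*\\]", "", text)
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop_parse("fossilplace_newick_error", "malformed Newick: ",
               substr(text, 1, 60))
  }
  if (anyDuplicated(tr$tip.label)) {
    stop_parse("fossilplace_duplicate_taxon_error",
               "duplicate tip label: ",
               paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

# Tip indices descending from the child node of every edge, as a list aligned
# with the rows of tree$edge.
edge_tip_sets <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  for (r in seq_len(nrow(tree$edge))) {
    par <- tree$edge[r, 1]
    chi <- tree$edge[r, 2]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  list(tree = tree, sets = lapply(tree$edge[, 2], function(ch) sets[[ch]]))
}

# Canonical identifier for the bipartition a tip subset induces on `all_tips`:
# the side NOT containing the reference tip (the lexicographically smallest
# label), labels sorted and joined with "|". Stable across rerooting and
# across attach/prune cycles.
canonical_ref <- function(tip_labels, all_tips) {
  tip_labels <- normalize_label(tip_labels)
  all_tips <- normalize_label(all_tips)
  ref_tip <- sort(all_tips, method = "radix")[1L]
  if (ref_tip %in% tip_labels) {
    tip_labels <- setdiff(all_tips, tip_labels)
  }
  paste(sort(tip_labels, method = "radix"), collapse = "|")
}

# Table of distinct unrooted edges: one row per EdgeRef with the postorder
# edge row realizing it. For a binary rooted tree the two edges flanking the
# root collapse to a single unrooted edge (identical bipartition), so only
# the first is kept.
edge_table <- function(tree) {
  ets <- edge_tip_sets(tree)
  tree <- ets$tree
  labs <- tree$tip.label
  refs <- vapply(
    ets$sets,
    function(s) canonical_ref(labs[s], labs),
    character(1)
  )
  keep <- !duplicated(refs)
  data.frame(
    ref = refs[keep],
    edge_row = which(keep),
    child = tree$edge[keep, 2],
    stringsAsFactors = FALSE
  ) -> tab
  attr(tab, "tree") <- tree
  attr(tab, "clades") <- lapply(which(keep), function(r) sort(labs[ets$sets[[r]]]))
  tab
}

#' Enumerate the distinct edges of a tree as stable references
#'
#' Each edge of the unrooted topology gets one `EdgeRef`: the sorted,
#' `|`-joined tip labels of the bipartition side away from the
#' lexicographically smallest tip. A binary rooted input contributes a single
#' reference for the two branches flanking its root (they are one unrooted
#' edge). For a binary unrooted tree with `n` tips this yields `2n - 3`
#' references; each is a candidate fossil attachment point.
#'
#' @param tree A `phylo` object with at least 2 tips.
#' @return Character vector of edge references, in postorder.
#' @export
#' @examples
#' enumerate_attachments(parse_tree("((A,B),(C,D));"))  # 5 edges
enumerate_attachments <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) {
    stop("backbone must have at least 2 tips", call. = FALSE)
  }
  edge_table(tree)$ref
}

#' Write a Newick tree with per-branch annotations
#'
#' Serializes the tree with annotation strings attached to chosen edges,
#' identified by the references of [enumerate_attachments()]. Two conventions
#' are supported: `mode = "label"` writes the annotation as the node label of
#' the internal node below the branch and, for terminal branches, appends it
#' to the tip name separated by `sep`; `mode = "comment"` writes a structured
#' `[&annot=...]` comment after the subtree instead. Unannotated edges are
#' left unlabeled.
#'
#' @param tree A `phylo` object.
#' @param ann Named character vector: `names(ann)` are edge references,
#'   values the annotation strings. May be empty.
#' @param mode `"label"` (default) or `"comment"`.
#' @param sep Separator between tip name and annotation in label mode.
#' @param path Optional output file.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_annotated_tree <- function(tree, ann = character(0),
                                 mode = c("label", "comment"), sep = "|",
                                 path = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  tab <- edge_table(tree)
  tree <- attr(tab, "tree")
  if (length(ann) > 0) {
    unknown <- setdiff(names(ann), tab$ref)
    if (length(unknown) > 0) {
      stop("unknown edge reference: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  # annotation indexed by child node of the kept edge realizing each ref
  node_ann <- rep(NA_character_, length(tree$tip.label) + tree$Nnode)
  if (length(ann) > 0) {
    node_ann[tab$child[match(names(ann), tab$ref)]] <- unname(ann)
  }

  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1],
                                       levels = seq_len(n_tip + tree$Nnode)))
  fmt_label <- function(x) gsub("\\s+", "_", x)
  fmt <- function(node) {
    a <- node_ann[node]
    if (node <= n_tip) {
      lab <- fmt_label(tree$tip.label[node])
      if (!is.na(a)) {
        lab <- if (mode == "label") paste0(lab, sep, a)
               else paste0(lab, "[&annot=", a, "]")
      }
      lab
    } else {
      inner <- paste(vapply(kids[[node]], fmt, character(1)), collapse = ",")
      tail <- if (is.na(a)) ""
              else if (mode == "label") fmt_label(a)
              else paste0("[&annot=", a, "]")
      paste0("(", inner, ")", tail)
    }
  }
  root <- n_tip + 1L
  out <- paste0(fmt(root), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Attach a fossil tip to an edge of the backbone
#'
#' Subdivides the chosen branch with a new degree-3 node bearing the fossil
#' as a tip; the relationships among the backbone's own taxa are unchanged.
#' Branch lengths, being irrelevant to parsimony scoring, are dropped from
#' the result.
#'
#' @param backbone A `phylo` object.
#' @param edge An edge reference from [enumerate_attachments()].
#' @param fossil New tip label; must not already be a backbone tip.
#' @return A `phylo` with one more tip.
#' @export
attach_fossil <- function(backbone, edge, fossil) {
  stopifnot(inherits(backbone, "phylo"))
  if (normalize_label(fossil) %in% normalize_label(backbone$tip.label)) {
    stop("taxon '", fossil, "' is already a tip of the backbone", call. = FALSE)
  }
  tab <- edge_table(backbone)
  i <- match(edge, tab$ref)
  if (is.na(i)) stop("unknown edge reference: ", edge, call. = FALSE)
  tr <- attr(tab, "tree")
  tr$edge.length <- rep(1, nrow(tr$edge))
  out <- phytools::bind.tip(tr, tip.label = fossil, edge.length = 1,
                            where = tab$child[i], position = 0.5)
  out$edge.length <- NULL
  out
}
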
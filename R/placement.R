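#' Score every attachment of a fossil on a fixed backbone
#'
#' The relationships among the backbone's (extant) taxa are held fixed; only
#' the fossil moves. Each edge of the unrooted backbone is subdivided in turn
#' by a new node bearing the fossil tip, the augmented topology is scored with
#' [tree_score()], and the per-edge scores are ranked (lower is better: the
#' implied-weights fit is a homoplasy penalty). Edges whose scores agree
#' within a relative tolerance share a rank, and all edges tied for the best
#' score form the argmax set — a fossil with no codable characters therefore
#' ties across every edge.
#'
#' @param backbone A `phylo` of extant taxa; every tip must be a matrix taxon.
#' @param m A [morpho_matrix()] containing the backbone taxa and the fossil.
#' @param fossil Fossil taxon label; must be in `m` and not in the backbone.
#' @param cfg An [iw_config()] (concavity constant and score kind).
#' @param tie_tol Relative tolerance within which two totals count as tied.
#' @param restrict_to Optional list of character vectors of tip labels; when
#'   given, the ranking is filtered to edges lying within one of these clades
#'   (every tip on the edge's far side from the reference bipartition is in
#'   the clade). Useful to exclude, e.g., deep interfamilial branches.
#' @return An object of class `placement_result`: `table` (data.frame with
#'   one row per edge: `edge_ref`, `clade`, `total_fit`, `total_length`,
#'   `rank`, `tie`), `per_edge` (named list of [tree_score()] objects),
#'   `argmax_set`, `backbone_score`, `fossil`, `k_used`, `score_kind`,
#'   `tie_tol`, and `backbone`.
#' @export
#' @examples
#' bb <- parse_tree("((A,B),(C,D));")
#' m <- parse_matrix("A 00\nB 01\nC 11\nD 11\nF 01\n")
#' res <- place_fossil(bb, m, "F")
#' res$argmax_set
place_fossil <- function(backbone, m, fossil, cfg = iw_config(),
                         tie_tol = 1e-9, restrict_to = NULL) {
  stopifnot(inherits(backbone, "phylo"), inherits(m, "morpho_matrix"))
  fos_n <- normalize_label(fossil)
  if (!fos_n %in% normalize_label(m$taxa)) {
    stop("fossil '", fossil, "' not found in the matrix", call. = FALSE)
  }
  if (fos_n %in% normalize_label(backbone$tip.label)) {
    stop("fossil '", fossil, "' is already a backbone tip", call. = FALSE)
  }
  tab <- edge_table(backbone)
  clades <- attr(tab, "clades")
  refs <- tab$ref

  per_edge <- vector("list", length(refs))
  names(per_edge) <- refs
  for (i in seq_along(refs)) {
    aug <- attach_fossil(backbone, refs[i], fossil)
    per_edge[[i]] <- tree_score(aug, m, cfg)
  }
  backbone_score <- tree_score(backbone, m, cfg)

  totals <- vapply(per_edge, function(ts) ts$score, numeric(1))
  fits <- vapply(per_edge, function(ts) ts$total_fit, numeric(1))
  lens <- vapply(per_edge, function(ts) ts$total_length, numeric(1))
  clade_desc <- vapply(clades, function(cl) paste(cl, collapse = ","),
                       character(1))

  keep <- rep(TRUE, length(refs))
  if (!is.null(restrict_to)) {
    if (!is.list(restrict_to)) restrict_to <- list(restrict_to)
    restrict_to <- lapply(restrict_to, normalize_label)
    keep <- vapply(clades, function(cl) {
      cl <- normalize_label(cl)
      any(vapply(restrict_to, function(cc) all(cl %in% cc), logical(1)))
    }, logical(1))
    if (!any(keep)) stop("clade restriction excludes every edge", call. = FALSE)
  }

  ord <- order(totals[keep], refs[keep], method = "radix")
  ranked_refs <- refs[keep][ord]
  ranked_tot <- totals[keep][ord]
  rank <- integer(length(ord))
  grp_start <- 1L
  for (i in seq_along(ord)) {
    if (i > 1L &&
        ranked_tot[i] - ranked_tot[grp_start] >
          tie_tol * max(1, abs(ranked_tot[grp_start]))) {
      grp_start <- i
    }
    rank[i] <- grp_start
  }
  tie <- rank %in% rank[duplicated(rank)]
  argmax_set <- ranked_refs[rank == 1L]

  table <- data.frame(
    edge_ref = unname(ranked_refs),
    clade = unname(clade_desc[keep][ord]),
    total_fit = unname(fits[keep][ord]),
    total_length = unname(lens[keep][ord]),
    rank = rank,
    tie = tie,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = table,
         per_edge = per_edge,
         argmax_set = argmax_set,
         backbone_score = backbone_score,
         fossil = fossil,
         k_used = cfg$k,
         score_kind = cfg$score_kind,
         tie_tol = tie_tol,
         backbone = backbone),
    class = "placement_result"
  )
}

#' @export
print.placement_result <- function(x, ...) {
  cat("<placement_result> fossil '", x$fossil, "' on ",
      nrow(x$table), " candidate edges (k = ", x$k_used, ")\n", sep = "")
  cat("  backbone fit ", format(x$backbone_score$total_fit, digits = 6),
      "; best attachment fit ", format(min(x$table$total_fit), digits = 6),
      "\n", sep = "")
  cat("  argmax set (", length(x$argmax_set), " edge",
      if (length(x$argmax_set) != 1) "s", "):\n", sep = "")
  for (r in utils::head(x$argmax_set, 5)) cat("    ", r, "\n", sep = "")
  if (length(x$argmax_set) > 5) cat("    ...\n")
  invisible(x)
}

#' Export a placement result as a TSV table and an annotated Newick tree
#'
#' The table carries one row per candidate edge with full-precision scores;
#' the Newick tree carries the total fit of each attachment, formatted to
#' `digits` decimal places, as a branch label on the corresponding backbone
#' edge (the figure-style "score above each branch" display).
#'
#' @param r A [place_fossil()] result.
#' @param prefix Optional path prefix; when given, writes
#'   `<prefix>.placements.tsv` and `<prefix>.annotated.nwk`.
#' @param digits Decimal places for the Newick branch labels.
#' @param mode Annotation convention passed to [write_annotated_tree()].
#' @return Invisibly, a list with `table`, `newick`, and (if written) `files`.
#' @export
report_placements <- function(r, prefix = NULL, digits = 2,
                              mode = c("label", "comment")) {
  stopifnot(inherits(r, "placement_result"))
  mode <- match.arg(mode)
  tab <- r$table
  out_tab <- tab
  out_tab$total_fit <- sprintf("%.12g", tab$total_fit)
  out_tab$tie <- ifelse(tab$tie, "yes", "no")
  ann <- stats::setNames(sprintf(paste0("%.", digits, "f"), tab$total_fit),
                         tab$edge_ref)
  newick <- write_annotated_tree(r$backbone, ann, mode = mode)
  files <- NULL
  if (!is.null(prefix)) {
    tsv <- paste0(prefix, ".placements.tsv")
    nwk <- paste0(prefix, ".annotated.nwk")
    utils::write.table(out_tab, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(newick, nwk)
    files <- c(tsv = tsv, nwk = nwk)
  }
  invisible(list(table = out_tab, newick = newick, files = files))
}
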
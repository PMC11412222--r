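#' Discrete morphological character matrix
#'
#' Container for a taxa-by-characters grid of discrete cells. Each cell is
#' either *observed* (a non-empty set of integer state codes; a set of size
#' greater than one records polymorphism or ambiguity), *missing* (`?`), or
#' *inapplicable* (`-`). The three kinds are kept distinct throughout so that
#' downstream scoring policies (e.g. treating inapplicable as missing) remain
#' explicit choices rather than parse-time information loss.
#'
#' Internally the observed state sets are stored as an integer bitmask matrix
#' (bit *i* set means state *i* is in the set) alongside a parallel matrix of
#' cell kinds; state codes run from 0 to 30.
#'
#' @param taxa Character vector of unique taxon labels (at least one).
#' @param cells A list of rows, one per taxon, each a list of `n_chars` cells.
#'   A cell is an integer vector of state codes (possibly length > 1 for
#'   polymorphism), the string `"?"` for missing, or `"-"` for inapplicable.
#' @param state_labels Optional list of per-character annotations.
#'
#' @return An object of class `morpho_matrix` with fields `taxa`, `n_chars`,
#'   `mask` (integer bitmask matrix), `kind` (character matrix with entries
#'   `"observed"`, `"missing"`, `"inapplicable"`), and `state_labels`.
#' @seealso [parse_matrix()], [count_applicable()]
#' @export
#' @examples
#' m <- morpho_matrix(
#'   taxa = c("A", "B"),
#'   cells = list(list(0L, 1L), list("?", c(0L, 1L)))
#' )
#' count_applicable(m, "B")
morpho_matrix <- function(taxa, cells, state_labels = NULL) {
  taxa <- as.character(taxa)
  if (length(taxa) < 1L) stop("matrix needs at least one taxon", call. = FALSE)
  if (anyDuplicated(taxa)) {
    stop_parse("fossilplace_duplicate_taxon_error",
               "duplicate taxon label: ",
               paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  if (length(cells) != length(taxa)) {
    stop_parse("fossilplace_dimension_error",
               "got ", length(cells), " rows for ", length(taxa), " taxa")
  }
  n_chars <- if (length(cells) > 0L) length(cells[[1L]]) else 0L
  lens <- vapply(cells, length, integer(1))
  if (any(lens != n_chars)) {
    stop_parse("fossilplace_dimension_error",
               "rows differ in length: ", paste(unique(lens), collapse = ", "))
  }
  mask <- matrix(0L, length(taxa), n_chars, dimnames = list(taxa, NULL))
  kind <- matrix("missing", length(taxa), n_chars, dimnames = list(taxa, NULL))
  for (i in seq_along(taxa)) {
    row <- cells[[i]]
    for (j in seq_len(n_chars)) {
      cl <- row[[j]]
      if (identical(cl, "?")) {
        kind[i, j] <- "missing"
      } else if (identical(cl, "-")) {
        kind[i, j] <- "inapplicable"
      } else {
        kind[i, j] <- "observed"
        mask[i, j] <- mask_from_states(cl)
        if (mask[i, j] == 0L) stop("observed cell must have >= 1 state", call. = FALSE)
      }
    }
  }
  new_morpho_matrix(taxa, mask, kind, state_labels)
}

# low-level constructor used internally (mask/kind already built)
new_morpho_matrix <- function(taxa, mask, kind, state_labels = NULL) {
  structure(
    list(taxa = taxa, n_chars = ncol(mask), mask = mask, kind = kind,
         state_labels = state_labels),
    class = "morpho_matrix"
  )
}

#' @export
print.morpho_matrix <- function(x, ...) {
  cat("<morpho_matrix> ", length(x$taxa), " taxa x ", x$n_chars, " characters\n",
      sep = "")
  n_miss <- sum(x$kind == "missing")
  n_inap <- sum(x$kind == "inapplicable")
  n_poly <- sum(x$kind == "observed" & n_bits(x$mask) > 1L)
  cat("  missing: ", n_miss, "  inapplicable: ", n_inap,
      "  polymorphic: ", n_poly, "\n", sep = "")
  cat("  taxa: ", paste(utils::head(x$taxa, 6), collapse = ", "),
      if (length(x$taxa) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.morpho_matrix <- function(x) c(length(x$taxa), x$n_chars)

# row index for a taxon, matching after label normalization
taxon_index <- function(m, taxon) {
  i <- match(normalize_label(taxon), normalize_label(m$taxa))
  if (is.na(i)) stop("unknown taxon: ", taxon, call. = FALSE)
  i
}

#' States of a single cell
#'
#' @param m A [morpho_matrix()].
#' @param taxon Taxon label.
#' @param char 1-based character index.
#' @return Integer vector of state codes (empty for missing/inapplicable).
#' @export
cell_states <- function(m, taxon, char) {
  states_from_mask(m$mask[taxon_index(m, taxon), char])
}

#' Kind of a single cell
#'
#' @inheritParams cell_states
#' @return `"observed"`, `"missing"` or `"inapplicable"`.
#' @export
cell_kind <- function(m, taxon, char) {
  unname(m$kind[taxon_index(m, taxon), char])
}

#' Count characters codable for a taxon
#'
#' The number of cells in the taxon's row that carry an observed state, i.e.
#' are neither missing (`?`) nor inapplicable (`-`). For a fossil this is the
#' usual "characters successfully coded" completeness figure.
#'
#' @param m A [morpho_matrix()].
#' @param taxon Taxon label (matched after trimming quotes and mapping
#'   underscores to spaces).
#' @return Integer count in `0..n_chars`.
#' @export
#' @examples
#' m <- parse_matrix("A 01?-\nB 0101\n")
#' count_applicable(m, "A")  # 2
count_applicable <- function(m, taxon) {
  sum(m$kind[taxon_index(m, taxon), ] == "observed")
}
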
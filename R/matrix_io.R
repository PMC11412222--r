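#' Parse a discrete character matrix
#'
#' Reads a NEXUS-style `CHARACTERS`/`DATA` block (interleaved or not) or, as a
#' fallback, a bare whitespace-delimited block with one `taxon states` row per
#' line. State symbols are single digits; `?` marks missing data, `-` marks
#' inapplicable cells, and both `{..}` and `(..)` group the states of a
#' polymorphic/ambiguous cell. The missing and gap symbols can be overridden
#' by a NEXUS `FORMAT missing= gap=` statement. Whitespace and line wrapping
#' inside a row are ignored; square-bracket comments are stripped.
#'
#' Failures raise classed conditions: `fossilplace_dimension_error` when
#' declared and parsed sizes disagree, `fossilplace_duplicate_taxon_error` for
#' repeated labels, and `fossilplace_symbol_error` for symbols outside the
#' alphabet.
#'
#' @param text A length-1 string containing the block, or a character vector
#'   of lines.
#' @return A [morpho_matrix()].
#' @seealso [write_matrix()], [read_matrix()]
#' @export
#' @examples
#' m <- parse_matrix("A 0101\nB 01?1\nC {01}1-0\n")
#' cell_kind(m, "B", 3)     # "missing"
#' cell_states(m, "C", 1)   # 0 1
parse_matrix <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- strip_nexus_comments(lines)
  if (any(grepl("^\\s*#NEXUS", lines, ignore.case = TRUE)) ||
      any(grepl("\\bMATRIX\\b", lines, ignore.case = TRUE))) {
    parse_matrix_nexus(lines)
  } else {
    parse_matrix_bare(lines)
  }
}

strip_nexus_comments <- function(lines) {
  # remove [...] comments; they may span lines but do not nest in practice
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]\\[]*\\]", "", txt)
  unlist(strsplit(txt, "\n", fixed = TRUE))
}

parse_matrix_nexus <- function(lines) {
  joined <- paste(lines, collapse = "\n")
  ntax <- nexus_number(joined, "ntax")
  nchar <- nexus_number(joined, "nchar")
  missing_sym <- nexus_symbol(joined, "missing") %||% "?"
  gap_sym <- nexus_symbol(joined, "gap") %||% "-"

  # the matrix body runs from the MATRIX keyword to the next bare ';'
  m <- regexpr("\\bMATRIX\\b", joined, ignore.case = TRUE)
  if (m == -1L) stop_parse("fossilplace_dimension_error", "no MATRIX block found")
  body <- substring(joined, m + attr(m, "match.length"))
  end <- regexpr(";", body, fixed = TRUE)
  if (end == -1L) stop_parse("fossilplace_dimension_error", "MATRIX block not terminated by ';'")
  body <- substring(body, 1L, end - 1L)

  rows <- parse_matrix_body(strsplit(body, "\n", fixed = TRUE)[[1L]],
                            missing_sym, gap_sym, declared_nchar = nchar)
  check_dims(rows, ntax, nchar)
  morpho_matrix(names(rows), unname(rows))
}

parse_matrix_bare <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  rows <- parse_matrix_body(lines, "?", "-", declared_nchar = NULL,
                            allow_continuation = FALSE)
  check_dims(rows, NULL, NULL)
  morpho_matrix(names(rows), unname(rows))
}

nexus_number <- function(txt, key) {
  m <- regmatches(txt, regexpr(paste0("(?i)\\b", key, "\\s*=\\s*[0-9]+"), txt, perl = TRUE))
  if (length(m) == 0L) return(NULL)
  as.integer(sub(".*=\\s*", "", m))
}

nexus_symbol <- function(txt, key) {
  m <- regmatches(txt, regexpr(paste0("(?i)\\b", key, "\\s*=\\s*\\S"), txt, perl = TRUE))
  if (length(m) == 0L) return(NULL)
  sub(paste0("(?i).*", key, "\\s*=\\s*"), "", m, perl = TRUE)
}

# Tokenize the matrix body. Each non-blank line normally starts with a taxon
# label followed by state symbols; a line made entirely of state symbols is a
# wrapped continuation of the preceding taxon's row. A label seen again marks
# an interleaved block continuing that taxon (unless its row is already
# complete, which is reported as a duplicate).
parse_matrix_body <- function(lines, missing_sym, gap_sym, declared_nchar,
                              allow_continuation = TRUE) {
  rows <- list()
  current <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    tok <- split_label(ln)
    label <- tok$label
    data <- tok$rest
    if (is.null(label)) {
      if (!allow_continuation || is.null(current)) {
        stop_parse("fossilplace_symbol_error",
                   "data line with no preceding taxon label: ", substr(ln, 1, 40))
      }
      label <- current
    } else if (!is.null(rows[[label]])) {
      if (!is.null(declared_nchar) && length(rows[[label]]) < declared_nchar) {
        # interleaved continuation
      } else {
        stop_parse("fossilplace_duplicate_taxon_error",
                   "duplicate taxon label: ", label)
      }
    }
    cells <- tokenize_cells(data, missing_sym, gap_sym)
    rows[label] <- list(c(rows[[label]], cells))
    current <- label
  }
  if (length(rows) == 0L) {
    stop_parse("fossilplace_dimension_error", "no matrix rows found")
  }
  rows
}

# Split a matrix line into (label, data). The label is a leading quoted string
# or a token containing at least one character outside the data alphabet;
# otherwise the whole line is data (a wrapped continuation).
split_label <- function(ln) {
  qm <- regexpr("^(['\"])(.*?)\\1", ln)
  if (qm == 1L) {
    lab <- regmatches(ln, qm)
    return(list(label = gsub("^['\"]|['\"]$", "", lab),
                rest = substring(ln, attr(qm, "match.length") + 1L)))
  }
  first <- sub("\\s.*$", "", ln)
  if (grepl("[^0-9?{}()\\s-]", first)) {
    list(label = first, rest = sub("^\\S+\\s*", "", ln))
  } else {
    list(label = NULL, rest = ln)
  }
}

tokenize_cells <- function(data, missing_sym, gap_sym) {
  chars <- strsplit(data, "", fixed = FALSE)[[1L]]
  cells <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch == missing_sym) {
      cells[[length(cells) + 1L]] <- "?"
      i <- i + 1L
    } else if (ch == gap_sym) {
      cells[[length(cells) + 1L]] <- "-"
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      cells[[length(cells) + 1L]] <- as.integer(ch)
      i <- i + 1L
    } else if (ch == "{" || ch == "(") {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      states <- integer(0)
      while (j <= n && chars[j] != close) {
        if (grepl("^[0-9]$", chars[j])) {
          states <- c(states, as.integer(chars[j]))
        } else if (!grepl("^[\\s,]$", chars[j], perl = TRUE)) {
          stop_parse("fossilplace_symbol_error",
                     "unknown symbol '", chars[j], "' in polymorphism group")
        }
        j <- j + 1L
      }
      if (j > n) stop_parse("fossilplace_symbol_error", "unterminated '", ch, "' group")
      if (length(states) == 0L) {
        stop_parse("fossilplace_symbol_error", "empty polymorphism group")
      }
      cells[[length(cells) + 1L]] <- sort(unique(states))
      i <- j + 1L
    } else {
      stop_parse("fossilplace_symbol_error", "unknown symbol '", ch, "'")
    }
  }
  cells
}

check_dims <- function(rows, declared_ntax, declared_nchar) {
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) > 1L) {
    stop_parse("fossilplace_dimension_error",
               "rows differ in length: ",
               paste(paste0(names(lens), "=", lens), collapse = ", "))
  }
  if (!is.null(declared_nchar) && lens[[1L]] != declared_nchar) {
    stop_parse("fossilplace_dimension_error",
               "declared nchar=", declared_nchar, " but rows have ", lens[[1L]],
               " cells")
  }
  if (!is.null(declared_ntax) && length(rows) != declared_ntax) {
    stop_parse("fossilplace_dimension_error",
               "declared ntax=", declared_ntax, " but found ", length(rows),
               " rows")
  }
  invisible(rows)
}

#' Write a character matrix as a NEXUS DATA block
#'
#' Emits the same dialect [parse_matrix()] accepts; the round trip is lossless
#' for cell kinds and state sets. Polymorphic cells are written as `{..}`
#' groups; labels containing whitespace are written with underscores.
#'
#' @param m A [morpho_matrix()].
#' @param path Optional file path; when given the text is also written there.
#' @return The NEXUS text, invisibly when `path` is given.
#' @export
write_matrix <- function(m, path = NULL) {
  stopifnot(inherits(m, "morpho_matrix"))
  labels <- gsub("\\s+", "_", m$taxa)
  width <- max(nchar(labels), 0L) + 2L
  syms <- sort(unique(unlist(lapply(as.integer(m$mask), states_from_mask))))
  if (length(syms) == 0L) syms <- 0L
  rows <- character(length(m$taxa))
  for (i in seq_along(m$taxa)) {
    cells <- character(m$n_chars)
    for (j in seq_len(m$n_chars)) {
      cells[j] <- switch(m$kind[i, j],
        missing = "?",
        inapplicable = "-",
        observed = {
          st <- states_from_mask(m$mask[i, j])
          if (length(st) == 1L) as.character(st)
          else paste0("{", paste(st, collapse = ""), "}")
        }
      )
    }
    rows[i] <- sprintf("%-*s%s", width, labels[i], paste(cells, collapse = ""))
  }
  text <- paste(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(m$taxa), m$n_chars),
    sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;",
            paste(syms, collapse = " ")),
    "  MATRIX",
    paste0("    ", rows),
    "  ;",
    "END;",
    ""
  ), collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Read a character matrix from a file
#'
#' @param path Path to a NEXUS or bare whitespace-delimited matrix file.
#' @return A [morpho_matrix()].
#' @export
read_matrix <- function(path) {
  parse_matrix(readLines(path, warn = FALSE))
}
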
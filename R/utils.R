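# Internal helpers shared across modules.

# Taxon labels are matched between matrix and tree after stripping surrounding
# quotes and mapping underscores to spaces (the usual NEXUS/Newick mismatch).
normalize_label <- function(x) {
  x <- gsub("^['\"]|['\"]$", "", x)
  gsub("_", " ", x, fixed = TRUE)
}

# Bitmask encoding of observed state sets: bit i (from 0) set <=> state i
# present. Mask 0 is the sentinel for "no observed state" (missing or
# inapplicable); the cell kind disambiguates the two.
MAX_STATE <- 30L

mask_from_states <- function(states) {
  if (length(states) == 0L) return(0L)
  states <- as.integer(states)
  if (any(states < 0L | states > MAX_STATE)) {
    stop("state codes must lie in 0..", MAX_STATE, call. = FALSE)
  }
  sum(bitwShiftL(1L, unique(states)))
}

states_from_mask <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:MAX_STATE)) != 0L) - 1L
}

n_bits <- function(mask) {
  # population count, vectorized over small masks
  out <- integer(length(mask))
  m <- as.integer(mask)
  while (any(m != 0L)) {
    out <- out + bitwAnd(m, 1L)
    m <- bitwShiftR(m, 1L)
  }
  out
}

# Distinct condition classes so callers can distinguish parse failures.
stop_parse <- function(class, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "fossilplace_parse_error", "error", "condition"),
    list(message = paste0(...), call = call)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[fossilplace] ", ...)
}
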
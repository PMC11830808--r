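# Internal helpers shared across modules.

# Folding key used for alias lookup: case-insensitive, whitespace and
# punctuation collapsed, so "Hoffmann-La Roche AG" and "hoffmann la roche ag"
# hit the same alias entry.
fold_key <- function(x) {
  x <- tolower(trimws(x))
  gsub("[^a-z0-9]+", "", x)
}

# Tokens treated as missing when parsing year/revenue/logical fields.
.na_tokens <- c("", "na", "n/a", "none", "-", ".", "null")

is_na_token <- function(x) {
  tolower(trimws(x)) %in% .na_tokens
}

# Parse a character vector to numeric; returns list(value, ok).
# NA tokens become NA with ok = TRUE; anything else non-numeric has ok = FALSE.
parse_num <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  ok <- rep(TRUE, length(x))
  live <- !is_na_token(x) & !is.na(x)
  val <- suppressWarnings(as.numeric(x[live]))
  out[live] <- val
  ok[live] <- !is.na(val)
  list(value = out, ok = ok)
}

parse_logical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  ok <- is_na_token(x) | !is.na(out)
  list(value = out, ok = ok)
}

# Split a ";"-delimited multi-value cell into a trimmed character vector.
split_multi <- function(x) {
  if (is.na(x) || is_na_token(x)) return(character(0))
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

join_multi <- function(x) paste(x, collapse = "; ")

# Derive a stream-specific RNG seed from a master seed, kept inside the
# 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((abs(seed) * 7919 + stream * 104729) %% 2147483587L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
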
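# internal helpers shared across modules

#' @noRd
.msg <- function(...) message("[regulonet] ", ...)

# Upper-case, trimmed gene symbols; NA and "" are invalid.
#' @noRd
.normSymbols <- function(x, what = "gene symbol") {
  x <- toupper(trimws(as.character(x)))
  if (any(is.na(x) | x == ""))
    stop("empty or missing ", what, " encountered", call. = FALSE)
  x
}

#' @noRd
.assertFlag <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' @noRd
.assertCount <- function(x, name, min = 1L) {
  .assertFlag(is.numeric(x) && length(x) == 1L && !is.na(x) &&
                x >= min && x == floor(x),
              sprintf("'%s' must be a single integer >= %d", name, min))
}

#' @noRd
.assertFraction <- function(x, name, lo = 0, hi = 1) {
  .assertFlag(is.numeric(x) && length(x) == 1L && !is.na(x) &&
                x >= lo && x <= hi,
              sprintf("'%s' must be a single number in [%g, %g]", name, lo, hi))
}

#' @noRd
.assertPositive <- function(x, name) {
  .assertFlag(is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0,
              sprintf("'%s' must be a single positive number", name))
}

# Deterministic TSV writer: fixed quoting/NA conventions so repeated runs are
# byte-identical.
#' @noRd
.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
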
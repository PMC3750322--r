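#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||%
NULL

# All package errors carry class c("gsf_error_<kind>", "gsf_error", ...)
# so callers can branch on the kind programmatically.
gsf_abort <- function(kind, msg, ...) {
  rlang::abort(msg, class = c(paste0("gsf_error_", kind), "gsf_error"), ...)
}

gsf_warn <- function(kind, msg) {
  rlang::warn(msg, class = c(paste0("gsf_warning_", kind), "gsf_warning"))
}

# glob -> regex (supports * and ?), anchored
glob_to_regex <- function(glob) {
  rx <- gsub("([.\\\\+^$(){}\\[\\]|])", "\\\\\\1", glob)
  rx <- gsub("\\*", ".*", rx)
  rx <- gsub("\\?", ".", rx)
  paste0("^", rx, "$")
}

# strict numeric parser: plain or scientific notation, no thousands
# separators; "" and "NA" give NA. Errors name the offending line.
parse_numeric_cells <- function(x, line_nos, what, allow_na = TRUE) {
  x <- trimws(x)
  is_na <- x == "" | x == "NA"
  ok <- grepl("^[+-]?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?$", x)
  bad <- !is_na & !ok
  if (any(bad)) {
    i <- which(bad)[1L]
    gsf_abort("malformed_value",
      sprintf("line %d: cannot parse %s value '%s' (plain or scientific notation required)",
              line_nos[i], what, x[i]))
  }
  if (!allow_na && any(is_na)) {
    i <- which(is_na)[1L]
    gsf_abort("missing_m",
      sprintf("line %d: missing value in required column %s", line_nos[i], what))
  }
  out <- rep(NA_real_, length(x))
  out[!is_na] <- as.numeric(x[!is_na])
  out
}

# bit-exact round-trip decimal representation (17 significant digits)
num_to_chr <- function(x) {
  out <- rep("NA", length(x))
  fin <- !is.na(x)
  long <- sprintf("%.17g", x[fin])
  # trim digits where fewer already round-trip, for readable output
  short <- sprintf("%.15g", x[fin])
  keep_short <- as.numeric(short) == x[fin]
  long[keep_short] <- short[keep_short]
  out[fin] <- long
  out
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

read_text_lines <- function(file) {
  if (length(file) == 1L && !grepl("[\n\t]", file) && file.exists(file)) {
    readLines(file, warn = FALSE, encoding = "UTF-8")
  } else {
    unlist(strsplit(paste(file, collapse = "\n"), "\n", fixed = TRUE))
  }
}
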
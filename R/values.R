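# Cell values of the character matrix: a numeric interval (possibly with a
# published mean/sd/n), a category token, or an explicit unknown. Unknown is
# a first-class state ("-" in the comparative table), never 0 or "".

#' Numeric interval value
#'
#' Represents one numeric cell: a range `[lo, hi]` with optional published
#' mean, standard deviation and sample size. A point measurement is stored
#' as `lo == hi`. A published mean lying outside `[lo, hi]` is tolerated
#' with a warning (printed tables round), not an error.
#'
#' @param lo,hi Interval endpoints, `lo <= hi`.
#' @param mean,sd,n Optional published summary statistics.
#' @return An object of class `cact_value`, kind `"numeric"`.
#' @export
#' @examples
#' num_value(485, 806)
#' num_value(22.8)  # point value
num_value <- function(lo, hi = lo, mean = NA_real_, sd = NA_real_,
                      n = NA_integer_) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!is.finite(lo) || !is.finite(hi)) stop("interval endpoints must be finite")
  if (lo > hi) stop(sprintf("inverted interval: lo (%g) > hi (%g)", lo, hi))
  mean <- as.numeric(mean)
  if (is.finite(mean) && (mean < lo || mean > hi)) {
    warning(sprintf("mean %g outside range [%g, %g] (rounding in source table?)",
                    mean, lo, hi))
  }
  structure(list(kind = "numeric", lo = lo, hi = hi, mean = mean,
                 sd = as.numeric(sd), n = as.integer(n)),
            class = "cact_value")
}

#' Categorical value
#'
#' @param token Category token (e.g. `"smooth"`, `"present"`).
#' @return An object of class `cact_value`, kind `"category"`.
#' @export
cat_value <- function(token) {
  token <- tolower(trimws(as.character(token)))
  if (length(token) != 1L || is.na(token) || !nzchar(token))
    stop("category token must be a single non-empty string")
  structure(list(kind = "category", category = token), class = "cact_value")
}

#' Explicit unknown value
#'
#' The "-" entries of the comparative table load as this value: the
#' character was not recorded. Unknown is distinct from the category
#' `"absent"`.
#'
#' @return An object of class `cact_value`, kind `"unknown"`.
#' @export
unknown_value <- function() {
  structure(list(kind = "unknown"), class = "cact_value")
}

#' Test for the unknown value
#' @param v A `cact_value`.
#' @return `TRUE` if `v` is the explicit unknown.
#' @export
is_unknown <- function(v) {
  inherits(v, "cact_value") && identical(v$kind, "unknown")
}

#' @export
print.cact_value <- function(x, ...) {
  cat(format_value(x), "\n")
  invisible(x)
}

# one-line rendering used by print methods and CSV writing
format_value <- function(v) {
  switch(v$kind,
    unknown  = "unknown",
    category = v$category,
    numeric  = if (v$lo == v$hi) format_num(v$lo)
               else paste0(format_num(v$lo), "-", format_num(v$hi)))
}

format_num <- function(x) format(x, trim = TRUE, scientific = FALSE)

# Parse one CSV cell into a cact_value. `kind` comes from the registry.
# Unknown markers: "-", en dash, "", "unknown", "NA". Intervals: "lo-hi"
# with hyphen or en dash; "x"/"×" separators (two-axis fenestrae) also
# accepted. Values are positive lengths/ratios, so "-" is unambiguous.
parse_cell <- function(cell, kind, taxon = "?", column = "?") {
  raw <- trimws(as.character(cell))
  raw_norm <- chartr("–×", "-x", raw)  # en dash -> hyphen, times -> x
  if (is.na(raw) || raw_norm %in% c("-", "", "unknown", "NA", "na"))
    return(unknown_value())
  if (identical(kind, "categorical")) return(cat_value(raw_norm))
  parts <- strsplit(raw_norm, "[-x]")[[1]]
  parts <- trimws(parts[nzchar(trimws(parts))])
  nums <- suppressWarnings(as.numeric(parts))
  if (length(nums) %in% c(1L, 2L) && !anyNA(nums)) {
    if (length(nums) == 1L) return(num_value(nums))
    return(num_value(min(nums), max(nums)))
  }
  stop(sprintf("malformed cell '%s' (taxon %s, column %s)", raw, taxon, column))
}
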
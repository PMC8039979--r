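# Publication-style summaries and the derived ratios (de Man indices)
# used throughout cyst-nematode descriptions.

#' Summarize raw measurements
#'
#' @param values Numeric vector of per-specimen measurements; all finite
#'   and strictly positive, at least one value.
#' @return An object of class `summary_stats`: n, mean, sd (sample sd,
#'   n-1 denominator; 0 for n = 1), min, max.
#' @export
#' @examples
#' summary_stats(c(2, 4))  # mean 3, sd sqrt(2)
summary_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("no values to summarize")
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(values <= 0)) stop("values must be strictly positive")
  s <- if (length(values) == 1L) 0 else stats::sd(values)
  structure(list(n = length(values), mean = mean(values), sd = s,
                 min = min(values), max = max(values)),
            class = "summary_stats")
}

#' Round half away from zero
#'
#' Comparisons against printed tables use commercial (half-up) rounding,
#' not R's round-half-even: 9.95 at 1 decimal prints as 10.0.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a summary in table style
#'
#' Produces the conventional `mean ± sd (min-max)` block of morphometric
#' tables, rounded half-up at a fixed number of decimals. Machine output
#' uses a plain hyphen as the range separator.
#'
#' @param s A `summary_stats` object.
#' @param decimals Decimal places (>= 0).
#' @return A string such as `"571.2 ± 79.1 (511.0-761.0)"`.
#' @export
format_summary <- function(s, decimals = 1) {
  stopifnot(inherits(s, "summary_stats"), decimals >= 0)
  f <- function(x) formatC(round_half_up(x, decimals), format = "f",
                           digits = decimals)
  sprintf("%s ± %s (%s-%s)", f(s$mean), f(s$sd), f(s$min), f(s$max))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d: %s\n", x$n, format_summary(x)))
  invisible(x)
}

# measurement-name aliases accepted by derived_indices()
.index_inputs <- list(
  body_length  = c("body_length", "j2_length"),
  body_width   = c("body_width", "j2_width", "max_body_width"),
  pharynx_length = "pharynx_length",
  tail_length  = "tail_length",
  anal_diam    = c("anal_diam", "anal_body_diam"),
  mb           = c("mb", "median_bulb_distance"),
  hyaline_length = c("hyaline_length", "hyaline"),
  length       = c("length", "cyst_length", "egg_length"),
  width        = c("width", "cyst_width", "egg_width")
)

#' Derived morphometric indices (de Man ratios)
#'
#' Computes every index whose inputs are present; absent inputs yield
#' `NA` rather than an error, so partial measurement sheets are usable.
#' Indices: `a` = body length / max body width, `b` = body length /
#' pharynx length, `c` = body length / tail length, `c_prime` = tail
#' length / body diameter at anus, `l_over_mb` = body length / median
#' bulb distance, `tl_over_h` = tail length / hyaline length,
#' `hyaline_fraction` = hyaline length / tail length, `lw_ratio` =
#' length / width (cysts or eggs, via generic `length`/`width` inputs).
#'
#' Indices computed from published means rather than per-specimen raw data
#' are approximations: a ratio of means is not the mean of ratios. When
#' raw data are available, compute indices per specimen and summarize.
#'
#' @param obs Named numeric vector or list of measurements
#'   (micrometres). Accepted names: `body_length` (or `j2_length`),
#'   `body_width` (`j2_width`), `pharynx_length`, `tail_length`,
#'   `anal_diam`, `mb`, `hyaline_length`, `length`, `width`.
#' @return An object of class `derived_indices`.
#' @export
#' @examples
#' derived_indices(c(body_length = 538.5, tail_length = 54.1))$c  # ~9.95
derived_indices <- function(obs) {
  obs <- unlist(as.list(obs))
  if (is.null(names(obs))) stop("measurements must be named")
  get <- function(key) {
    hit <- intersect(.index_inputs[[key]], names(obs))
    if (length(hit) == 0L) return(NA_real_)
    v <- as.numeric(obs[[hit[1]]])
    if (!is.finite(v) || v < 0) stop("measurement '", hit[1],
                                     "' must be positive")
    v
  }
  ratio <- function(num, den, den_name) {
    if (is.na(num) || is.na(den)) return(NA_real_)
    if (den == 0) stop("zero denominator: ", den_name)
    num / den
  }
  bl <- get("body_length"); tl <- get("tail_length"); hy <- get("hyaline_length")
  structure(list(
    a = ratio(bl, get("body_width"), "body_width"),
    b = ratio(bl, get("pharynx_length"), "pharynx_length"),
    c = ratio(bl, tl, "tail_length"),
    c_prime = ratio(tl, get("anal_diam"), "anal_diam"),
    l_over_mb = ratio(bl, get("mb"), "mb"),
    tl_over_h = ratio(tl, hy, "hyaline_length"),
    hyaline_fraction = ratio(hy, tl, "tail_length"),
    lw_ratio = ratio(get("length"), get("width"), "width")
  ), class = "derived_indices")
}

#' @export
print.derived_indices <- function(x, ...) {
  for (id in names(unclass(x))) {
    v <- x[[id]]
    if (!is.na(v)) cat(sprintf("  %-18s %.3f\n", id, v))
  }
  invisible(x)
}

#' Hyaline portion of the tail as a percentage
#'
#' @param tail Tail length (um).
#' @param hyaline Hyaline portion length (um); must satisfy
#'   `0 < hyaline <= tail`.
#' @return `100 * hyaline / tail`.
#' @export
#' @examples
#' hyaline_percent(54.1, 25.8)  # ~47.7, "about 48%" of tail length
hyaline_percent <- function(tail, hyaline) {
  stopifnot(is.finite(tail), is.finite(hyaline))
  if (hyaline <= 0) stop("hyaline length must be positive")
  if (tail <= 0) stop("tail length must be positive")
  if (hyaline > tail) stop("hyaline portion (", hyaline,
                           ") exceeds tail length (", tail, ")")
  100 * hyaline / tail
}

#' Read a raw measurement sheet
#'
#' One row per specimen, one column per character id, first column
#' `specimen_id` (created from row numbers when absent).
#'
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty measurement sheet: ", path)
  if (!"specimen_id" %in% names(df))
    df <- cbind(specimen_id = paste0("s", seq_len(nrow(df))), df)
  df
}

#' Morphometric summary block from a measurement sheet
#'
#' Summarizes every numeric column of a per-specimen sheet into the
#' `mean ± sd (min-max)` convention, one row per character.
#'
#' @param df Data frame from [read_measurements()].
#' @param decimals Decimal places for formatting.
#' @return Data frame with columns character, n, summary.
#' @export
morpho_table <- function(df, decimals = 1) {
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  rows <- lapply(num_cols, function(cc) {
    v <- df[[cc]][is.finite(df[[cc]])]
    s <- summary_stats(v)
    data.frame(character = cc, n = s$n,
               summary = format_summary(s, decimals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
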
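# Multi-access (polyclave) identification: score any subset of observed
# characters against every species in the matrix and rank candidates, or
# compare two species character-by-character as a differential diagnosis.
#
# Numeric similarity is a containment coefficient: taxonomic ranges are
# envelopes, specimens are samples, so a precise specimen lying inside a
# broad reference range scores 1.

#' Interval-overlap score of an observation against a reference range
#'
#' For a point observation: 1 inside the reference, otherwise a linear
#' decay `max(0, 1 - d/w)` where `d` is the distance to the nearest
#' endpoint and `w` the reference width. For an interval observation: the
#' containment coefficient `|obs ∩ ref| / |obs|`. Zero-width observations
#' fall back to the point rule; a zero-width reference scores 1 on exact
#' match and 0 otherwise.
#'
#' @param obs Numeric of length 1 (point) or 2 (interval), or a numeric
#'   `cact_value`.
#' @param ref Numeric length-2 reference interval or numeric `cact_value`.
#' @return A score in `[0, 1]`.
#' @export
#' @examples
#' overlap_score(25, c(23, 26))          # 1
#' overlap_score(c(20, 32), c(31, 36))   # 1/12
overlap_score <- function(obs, ref) {
  as_iv <- function(x, what) {
    if (inherits(x, "cact_value")) {
      if (x$kind != "numeric") stop(what, " must be numeric")
      return(c(x$lo, x$hi))
    }
    x <- as.numeric(x)
    if (length(x) == 1L) x <- c(x, x)
    if (length(x) != 2L || anyNA(x)) stop(what, " must have length 1 or 2")
    if (x[1] > x[2]) stop("inverted ", what, " interval")
    x
  }
  o <- as_iv(obs, "obs"); r <- as_iv(ref, "ref")
  if (o[1] == o[2]) {                       # point rule
    p <- o[1]
    if (p >= r[1] && p <= r[2]) return(1)
    w <- r[2] - r[1]
    if (w == 0) return(0)
    d <- if (p < r[1]) r[1] - p else p - r[2]
    return(max(0, 1 - d / w))
  }
  inter <- min(o[2], r[2]) - max(o[1], r[1])
  max(0, inter) / (o[2] - o[1])
}

score_one_taxon <- function(obs_values, profile) {
  shared <- intersect(names(obs_values), names(profile$values))
  per <- lapply(shared, function(id) {
    ov <- obs_values[[id]]; rv <- profile$values[[id]]
    if (is_unknown(rv) || is_unknown(ov))
      return(list(character = id, score = NA_real_, basis = "skipped-unknown"))
    if (rv$kind == "category" || ov$kind == "category") {
      if (rv$kind != ov$kind)
        return(list(character = id, score = NA_real_, basis = "skipped-unknown"))
      return(list(character = id,
                  score = as.numeric(identical(ov$category, rv$category)),
                  basis = "category"))
    }
    list(character = id, score = overlap_score(ov, rv), basis = "overlap")
  })
  scores <- vapply(per, `[[`, numeric(1), "score")
  used <- sum(!is.na(scores))
  list(aggregate = if (used > 0) mean(scores, na.rm = TRUE) else NA_real_,
       n_used = used,
       n_skipped_unknown = sum(is.na(scores)),
       breakdown = per)
}

#' Rank candidate species for a specimen
#'
#' Scores the observation against every taxon: numeric characters by
#' [overlap_score()], categoricals 1/0 on match, reference unknowns
#' skipped (missing data, not absence) and counted. The aggregate is the
#' unweighted mean of available character scores; `n_used` makes sparse
#' matches visibly weak. Candidates sort by aggregate descending, ties
#' broken alphabetically.
#'
#' @param obs A `specimen_observation`.
#' @param matrix A `cactodera_matrix`.
#' @param weights Optional named numeric vector of per-character weights
#'   (default: unweighted).
#' @return An object of class `candidate_scores`: a data frame (taxon,
#'   aggregate, n_used, n_skipped_unknown) with per-character breakdowns
#'   in `attr(, "breakdown")`.
#' @export
score_candidates <- function(obs, matrix, weights = NULL) {
  stopifnot(inherits(obs, "specimen_observation"),
            inherits(matrix, "cactodera_matrix"))
  res <- lapply(matrix$taxa, function(p) {
    r <- score_one_taxon(obs$values, p)
    if (!is.null(weights) && r$n_used > 0) {
      sc <- vapply(r$breakdown, `[[`, numeric(1), "score")
      ids <- vapply(r$breakdown, `[[`, character(1), "character")
      w <- ifelse(ids %in% names(weights), weights[ids], 1)
      keep <- !is.na(sc)
      r$aggregate <- sum(sc[keep] * w[keep]) / sum(w[keep])
    }
    r
  })
  if (all(vapply(res, function(r) r$n_used, integer(1)) == 0L))
    stop("observation shares no scorable character with the matrix")
  df <- data.frame(
    taxon = names(res),
    aggregate = vapply(res, `[[`, numeric(1), "aggregate"),
    n_used = vapply(res, `[[`, integer(1), "n_used"),
    n_skipped_unknown = vapply(res, `[[`, integer(1), "n_skipped_unknown"),
    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-ifelse(is.na(df$aggregate), -Inf, df$aggregate), df$taxon)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "breakdown") <- lapply(res, `[[`, "breakdown")[df$taxon]
  class(df) <- c("candidate_scores", class(df))
  df
}

#' @export
print.candidate_scores <- function(x, n = 5, ...) {
  cat("ranked candidates (top", min(n, nrow(x)), "of", nrow(x), "):\n")
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE,
                   digits = 3)
  invisible(x)
}

#' Pairwise diagnostic characters for two species
#'
#' Classifies every character shared by two taxa: numeric ranges as
#' `disjoint` (no common point), `low-overlap` (overlap shorter than
#' `low_overlap` of the smaller range) or `overlapping`; categoricals as
#' `categorical-differs` / `categorical-same`; `unknown` when either side
#' is unrecorded. Diagnostic verdicts (`disjoint`, `categorical-differs`)
#' are listed first, then `low-overlap`.
#'
#' @param taxon_a,taxon_b Taxon names (any form [resolve_taxon()] accepts).
#' @param matrix A `cactodera_matrix`.
#' @param low_overlap Low-overlap threshold as a fraction of the smaller
#'   range (default 0.25, chosen so a marginal overlap such as fenestral
#'   diameters 20–32 vs 31–36 µm is still flagged).
#' @return An object of class `diagnostic_report`.
#' @export
#' @examples
#' m <- load_matrix("cactodera_v1")
#' diagnostic_characters("C. tianzhuensis", "C. cacti", m)
diagnostic_characters <- function(taxon_a, taxon_b, matrix,
                                  low_overlap = 0.25) {
  a <- resolve_taxon(matrix, taxon_a); b <- resolve_taxon(matrix, taxon_b)
  pa <- matrix$taxa[[a]]; pb <- matrix$taxa[[b]]
  shared <- intersect(names(pa$values), names(pb$values))
  rows <- lapply(shared, function(id) {
    va <- pa$values[[id]]; vb <- pb$values[[id]]
    if (is_unknown(va) || is_unknown(vb))
      return(data.frame(character = id, verdict = "unknown",
                        a = format_value(va), b = format_value(vb),
                        stringsAsFactors = FALSE))
    if (va$kind == "category") {
      verdict <- if (identical(va$category, vb$category))
        "categorical-same" else "categorical-differs"
      return(data.frame(character = id, verdict = verdict,
                        a = format_value(va), b = format_value(vb),
                        stringsAsFactors = FALSE))
    }
    inter <- min(va$hi, vb$hi) - max(va$lo, vb$lo)
    verdict <- if (inter < 0) "disjoint" else {
      small <- min(va$hi - va$lo, vb$hi - vb$lo)
      frac <- if (small == 0) as.numeric(inter >= 0) else inter / small
      if (frac < low_overlap) "low-overlap" else "overlapping"
    }
    data.frame(character = id, verdict = verdict,
               a = format_value(va), b = format_value(vb),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rank <- match(df$verdict, c("disjoint", "categorical-differs",
                              "low-overlap", "overlapping",
                              "categorical-same", "unknown"))
  df <- df[order(rank, df$character), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(taxon_a = a, taxon_b = b, characters = df,
                 low_overlap = low_overlap),
            class = "diagnostic_report")
}

#' Diagnostic characters only
#'
#' @param report A `diagnostic_report`.
#' @return The subset of rows with verdict `disjoint`,
#'   `categorical-differs` or `low-overlap`.
#' @export
diagnostic_subset <- function(report) {
  stopifnot(inherits(report, "diagnostic_report"))
  df <- report$characters
  df[df$verdict %in% c("disjoint", "categorical-differs", "low-overlap"), ,
     drop = FALSE]
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("%s vs %s\n", x$taxon_a, x$taxon_b))
  for (i in seq_len(nrow(x$characters)))
    cat(sprintf("  %-20s %-20s (%s vs %s)\n",
                x$characters$character[i], x$characters$verdict[i],
                x$characters$a[i], x$characters$b[i]))
  invisible(x)
}
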
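# The dichotomous key to the genus as an executable decision graph.
#
# The printed key tests a mixture of means ("Mean stylet length of J2s >=
# 26 um"), plain thresholds and ranges, while the comparative matrix
# stores ranges. Evaluation is therefore three-valued (Kleene): a
# predicate is yes when the profile wholly satisfies it, no when it wholly
# violates it, and ambiguous when the interval straddles the test or the
# character is unrecorded. On ambiguity both leads are explored, so a
# traversal returns the full set of species the data cannot exclude.

TRI_YES <- "yes"; TRI_NO <- "no"; TRI_AMB <- "ambiguous"

# Kleene conjunction: no dominates, else ambiguous dominates yes.
kleene_and <- function(values) {
  if (any(values == TRI_NO)) TRI_NO
  else if (any(values == TRI_AMB)) TRI_AMB
  else TRI_YES
}

#' Load a dichotomous key from JSON
#'
#' The schema is a rooted acyclic decision graph: couplets with exactly
#' two leads, each lead a conjunction of predicates and an outcome that is
#' either a terminal taxon or the id of the next couplet. See
#' `inst/extdata/cactodera_v1/key.json` for the bundled example.
#'
#' @param path Path to a key JSON file.
#' @return An object of class `cact_key`.
#' @export
load_key <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  couplets <- lapply(x$couplets, function(cp) {
    if (length(cp$leads) != 2L)
      stop("couplet ", cp$id, " must have exactly two leads")
    leads <- lapply(cp$leads, function(ld) {
      preds <- lapply(ld$predicates, function(p) {
        p$threshold <- if (is.character(p$threshold)) p$threshold
                       else as.numeric(unlist(p$threshold))
        p
      })
      out <- ld$outcome
      type <- if (!is.null(out$taxon)) "taxon" else "couplet"
      list(predicates = preds,
           outcome = list(type = type,
                          value = if (type == "taxon") out$taxon
                                  else as.integer(out$couplet)))
    })
    list(id = as.integer(cp$id), leads = leads)
  })
  names(couplets) <- vapply(couplets, function(cp) as.character(cp$id),
                            character(1))
  key <- structure(list(version = x$version %||% "unversioned",
                        root = as.integer(x$root), couplets = couplets),
                   class = "cact_key")
  dang <- dangling_couplets(key)
  if (length(dang)) stop("key has leads pointing to missing couplets: ",
                         paste(dang, collapse = ", "))
  key
}

dangling_couplets <- function(key) {
  refs <- unlist(lapply(key$couplets, function(cp)
    vapply(cp$leads, function(ld)
      if (ld$outcome$type == "couplet") ld$outcome$value else NA_integer_,
      integer(1))))
  refs <- refs[!is.na(refs)]
  setdiff(as.character(refs), names(key$couplets))
}

#' The bundled key to species of Cactodera
#'
#' A repaired, machine-readable form of the printed sixteen-couplet key:
#' root couplet 1, all seventeen species reachable. The printed lead
#' numbering after couplet 10 is typeset wrongly; the repairs are recorded
#' in the errata file returned by [key_errata()].
#'
#' @return An object of class `cact_key`.
#' @export
bundled_key <- function() {
  load_key(cact_data_path("key.json"))
}

#' Machine-readable errata of the printed key
#'
#' @return Data frame with columns id, kind, where, printed,
#'   interpretation, note.
#' @export
key_errata <- function() {
  jsonlite::fromJSON(cact_data_path("key_errata.json"))
}

#' Evaluate one key predicate against a profile or observation
#'
#' Numeric predicates with `basis = "range"` answer yes when the profile
#' interval wholly satisfies the relation, no when it wholly violates it,
#' and ambiguous when it straddles. With `basis = "mean"` the published
#' mean is used when stored; otherwise the interval midpoint serves as a
#' proxy and the result carries attribute `proxy = TRUE` so audits stay
#' honest. Categorical predicates answer yes/no on a recorded category and
#' ambiguous on unknown.
#'
#' @param predicate List with fields `character`, `relation` (one of
#'   `lt`, `le`, `gt`, `ge`, `eq-category`, `in-range`), `threshold`
#'   (number, length-2 interval, or category token) and `basis`
#'   (`"mean"` or `"range"`).
#' @param profile A `taxon_profile` or `specimen_observation`.
#' @param registry Character registry (the predicate's character must
#'   exist in it).
#' @return `"yes"`, `"no"` or `"ambiguous"`, with logical attribute
#'   `proxy`.
#' @export
eval_predicate <- function(predicate, profile, registry = bundled_registry()) {
  id <- predicate$character
  if (!id %in% registry$id) stop("character not in registry: ", id)
  v <- profile$values[[id]]
  tri <- function(value, proxy = FALSE) structure(value, proxy = proxy)
  if (is.null(v) || is_unknown(v)) return(tri(TRI_AMB))

  if (predicate$relation == "eq-category") {
    if (v$kind != "category") stop("numeric value given for categorical test on ", id)
    return(tri(if (identical(v$category, tolower(predicate$threshold)))
      TRI_YES else TRI_NO))
  }
  if (v$kind != "numeric")
    stop("categorical value given for numeric test on ", id)
  t <- predicate$threshold
  lo <- v$lo; hi <- v$hi

  if (identical(predicate$basis, "mean")) {
    proxy <- FALSE
    m <- v$mean
    if (!is.finite(m)) {
      m <- (lo + hi) / 2
      proxy <- lo != hi  # a point value is its own mean
    }
    val <- switch(predicate$relation,
      lt = m < t[1], le = m <= t[1], gt = m > t[1], ge = m >= t[1],
      `in-range` = m >= t[1] && m <= t[2],
      stop("unsupported relation: ", predicate$relation))
    return(tri(if (val) TRI_YES else TRI_NO, proxy))
  }

  res <- switch(predicate$relation,
    lt = if (hi < t[1]) TRI_YES else if (lo >= t[1]) TRI_NO else TRI_AMB,
    le = if (hi <= t[1]) TRI_YES else if (lo > t[1]) TRI_NO else TRI_AMB,
    gt = if (lo > t[1]) TRI_YES else if (hi <= t[1]) TRI_NO else TRI_AMB,
    ge = if (lo >= t[1]) TRI_YES else if (hi < t[1]) TRI_NO else TRI_AMB,
    `in-range` = if (lo >= t[1] && hi <= t[2]) TRI_YES
                 else if (hi < t[1] || lo > t[2]) TRI_NO else TRI_AMB,
    stop("unsupported relation: ", predicate$relation))
  tri(res)
}

#' Traverse the key with a profile or specimen
#'
#' Depth-first traversal from the root. Leads evaluating no are pruned;
#' leads evaluating yes or ambiguous are explored (so on an ambiguous
#' couplet both branches are followed). A couplet where both leads are no
#' is recorded as a dead end, not an error. The trace records every
#' predicate decision, including proxy-mean flags.
#'
#' @param key A `cact_key`.
#' @param profile A `taxon_profile` or `specimen_observation`.
#' @param registry Character registry.
#' @return An object of class `key_traversal`: `terminals` (list of
#'   taxon/path/trace), `dead_ends`, and `status` (`"unique"`,
#'   `"ambiguous-multiple"` or `"dead-end"`).
#' @export
#' @examples
#' m <- load_matrix("cactodera_v1")
#' tr <- traverse_key(bundled_key(), m$taxa[["C. estonica"]], m$registry)
#' tr$status
traverse_key <- function(key, profile, registry = bundled_registry()) {
  stopifnot(inherits(key, "cact_key"))
  terminals <- list(); dead_ends <- list()

  rec <- function(cid, path, trace) {
    if (cid %in% path) stop("cycle detected at couplet ", cid)
    cp <- key$couplets[[as.character(cid)]]
    if (is.null(cp)) stop("lead points to missing couplet ", cid)
    path <- c(path, cid)
    lead_info <- lapply(cp$leads, function(ld) {
      evals <- lapply(ld$predicates, eval_predicate, profile = profile,
                      registry = registry)
      vals <- vapply(evals, as.character, character(1))
      list(value = kleene_and(vals),
           predicates = data.frame(
             character = vapply(ld$predicates, `[[`, character(1), "character"),
             relation = vapply(ld$predicates, `[[`, character(1), "relation"),
             value = vals,
             proxy = vapply(evals, function(e) isTRUE(attr(e, "proxy")),
                            logical(1)),
             stringsAsFactors = FALSE))
    })
    lead_vals <- vapply(lead_info, `[[`, character(1), "value")
    explored <- which(lead_vals != TRI_NO)
    if (length(explored) == 0L) {
      dead_ends[[length(dead_ends) + 1L]] <<- list(couplet = cid, path = path,
                                                   leads = lead_info)
      return(invisible())
    }
    for (i in explored) {
      step <- list(couplet = cid, lead = i, value = lead_vals[i],
                   predicates = lead_info[[i]]$predicates)
      out <- cp$leads[[i]]$outcome
      if (out$type == "taxon") {
        terminals[[length(terminals) + 1L]] <<-
          list(taxon = out$value, path = path, trace = c(trace, list(step)))
      } else {
        rec(out$value, path, c(trace, list(step)))
      }
    }
    invisible()
  }
  rec(key$root, integer(0), list())

  status <- if (length(terminals) == 1L) "unique"
            else if (length(terminals) > 1L) "ambiguous-multiple"
            else "dead-end"
  structure(list(terminals = terminals, dead_ends = dead_ends,
                 status = status),
            class = "key_traversal")
}

#' @export
print.key_traversal <- function(x, ...) {
  cat("key traversal:", x$status, "\n")
  for (t in x$terminals)
    cat(sprintf("  %-22s via couplets %s\n", t$taxon,
                paste(t$path, collapse = " > ")))
  if (length(x$dead_ends))
    for (d in x$dead_ends)
      cat(sprintf("  dead end at couplet %d (path %s)\n", d$couplet,
                  paste(d$path, collapse = " > ")))
  invisible(x)
}

#' Audit a key against a character matrix
#'
#' Runs every taxon's own matrix row through the key and classifies it as
#' CONSISTENT (its own terminal is the only one reached), AMBIGUOUS
#' (reached along with others) or MISROUTED (not reached: dead end or
#' wrong terminal). MISROUTED findings are cross-referenced against the
#' bundled errata where the erratum note names the taxon. Structural
#' checks (acyclicity, reachability, dangling leads, taxon coverage,
#' unused characters) are reported alongside.
#'
#' @param key A `cact_key`.
#' @param matrix A `cactodera_matrix`.
#' @param errata Optional errata data frame (see [key_errata()]) used to
#'   annotate MISROUTED findings; pass `NULL` to skip.
#' @return An object of class `key_audit`: `$audit` (one row per taxon)
#'   and `$structure`.
#' @export
validate_key <- function(key, matrix, errata = key_errata()) {
  stopifnot(inherits(key, "cact_key"), inherits(matrix, "cactodera_matrix"))

  outcome_taxa <- unlist(lapply(key$couplets, function(cp)
    vapply(cp$leads, function(ld)
      if (ld$outcome$type == "taxon") ld$outcome$value else NA_character_,
      character(1))))
  outcome_taxa <- outcome_taxa[!is.na(outcome_taxa)]

  reach <- character(0); stack <- key$root; cyclic <- FALSE
  parent_chain <- function(cid, seen) {
    if (cid %in% seen) { cyclic <<- TRUE; return(invisible()) }
    reach <<- union(reach, as.character(cid))
    cp <- key$couplets[[as.character(cid)]]
    if (is.null(cp)) return(invisible())
    for (ld in cp$leads)
      if (ld$outcome$type == "couplet")
        parent_chain(ld$outcome$value, c(seen, cid))
    invisible()
  }
  parent_chain(key$root, integer(0))

  used_chars <- unique(unlist(lapply(key$couplets, function(cp)
    lapply(cp$leads, function(ld)
      vapply(ld$predicates, `[[`, character(1), "character")))))

  structure_report <- list(
    n_couplets = length(key$couplets),
    acyclic = !cyclic,
    dangling = dangling_couplets(key),
    unreachable = setdiff(names(key$couplets), reach),
    taxa_not_in_matrix = setdiff(outcome_taxa, names(matrix$taxa)),
    taxa_without_terminal = setdiff(names(matrix$taxa), outcome_taxa),
    unused_characters = setdiff(matrix$registry$id, used_chars)
  )

  rows <- lapply(names(matrix$taxa), function(tx) {
    tr <- traverse_key(key, matrix$taxa[[tx]], matrix$registry)
    hits <- vapply(tr$terminals, `[[`, character(1), "taxon")
    n <- length(tr$terminals)
    own <- match(tx, hits)
    status <- if (!is.na(own)) {
      if (n == 1L) "CONSISTENT" else "AMBIGUOUS"
    } else "MISROUTED"
    path <- if (!is.na(own))
      paste(tr$terminals[[own]]$path, collapse = ">")
    else if (length(tr$dead_ends))
      paste0("dead-end@", tr$dead_ends[[1]]$couplet)
    else ""
    proxy <- any(vapply(tr$terminals, function(t)
      any(vapply(t$trace, function(s) any(s$predicates$proxy), logical(1))),
      logical(1)))
    err <- ""
    if (status == "MISROUTED" && !is.null(errata) && nrow(errata)) {
      hit <- errata$kind == "data-conflict" &
        grepl(tx, paste(errata$interpretation, errata$note),
              ignore.case = TRUE, fixed = FALSE)
      err <- paste(errata$id[hit], collapse = ",")
    }
    data.frame(taxon = tx, status = status, n_terminals = n, path = path,
               proxy_mean = proxy, erratum = err, stringsAsFactors = FALSE)
  })
  structure(list(audit = do.call(rbind, rows), structure = structure_report),
            class = "key_audit")
}

#' @export
print.key_audit <- function(x, ...) {
  cat(sprintf("key audit: %d couplets, acyclic = %s\n",
              x$structure$n_couplets, x$structure$acyclic))
  if (length(x$structure$dangling))
    cat("  DANGLING leads ->", paste(x$structure$dangling, collapse = ", "), "\n")
  if (length(x$structure$taxa_without_terminal))
    cat("  taxa without terminal:",
        paste(x$structure$taxa_without_terminal, collapse = ", "), "\n")
  print(x$audit, row.names = FALSE)
  invisible(x)
}
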
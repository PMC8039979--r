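# Shared fixtures: the bundled objects loaded once, plus tiny hand-built
# registries/keys for edge-case tests.

bundled <- local({
  m <- load_matrix("cactodera_v1")
  list(matrix = m, key = bundled_key(), registry = m$registry)
})

toy_registry <- function() {
  df <- data.frame(
    id = c("len", "surface"),
    label = c("Length", "Surface"),
    stage = c("J2", "egg"),
    kind = c("numeric", "categorical"),
    units = c("um", ""),
    categories = c("", "smooth;punctate"),
    stringsAsFactors = FALSE)
  class(df) <- c("cact_registry", class(df))
  df
}

# two-couplet toy key over the toy registry
toy_key_json <- function(dangling = FALSE) {
  sprintf('{
    "version": "toy", "root": 1,
    "couplets": [
      {"id": 1, "leads": [
        {"predicates": [{"character": "surface", "relation": "eq-category",
                         "threshold": "smooth", "basis": "range"}],
         "outcome": {"couplet": %d}},
        {"predicates": [{"character": "surface", "relation": "eq-category",
                         "threshold": "punctate", "basis": "range"}],
         "outcome": {"taxon": "B"}}]},
      {"id": 2, "leads": [
        {"predicates": [{"character": "len", "relation": "lt",
                         "threshold": 50, "basis": "range"}],
         "outcome": {"taxon": "A"}},
        {"predicates": [{"character": "len", "relation": "ge",
                         "threshold": 50, "basis": "range"}],
         "outcome": {"taxon": "C"}}]}
    ]}', if (dangling) 9L else 2L)
}

load_toy_key <- function(dangling = FALSE) {
  p <- withr::local_tempfile(fileext = ".json", .local_envir = parent.frame())
  writeLines(toy_key_json(dangling), p)
  load_key(p)
}

# brute-force traversal oracle: enumerate every root-to-terminal path and
# keep those whose every lead evaluates yes. Valid only for profiles with
# no ambiguous predicate; independent of the recursive engine.
enumerate_terminals <- function(key, profile, registry) {
  paths <- list()
  walk <- function(cid, acc) {
    cp <- key$couplets[[as.character(cid)]]
    for (i in seq_along(cp$leads)) {
      lead <- cp$leads[[i]]
      step <- list(couplet = cid, lead = i)
      if (lead$outcome$type == "taxon")
        paths[[length(paths) + 1L]] <<- c(acc, list(step))
      else walk(lead$outcome$value, c(acc, list(step)))
    }
  }
  walk(key$root, list())
  hits <- character(0)
  for (p in paths) {
    ok <- TRUE
    for (s in p) {
      lead <- key$couplets[[as.character(s$couplet)]]$leads[[s$lead]]
      vals <- vapply(lead$predicates, function(pr)
        as.character(eval_predicate(pr, profile, registry)), character(1))
      stopifnot(all(vals %in% c("yes", "no")))  # oracle precondition
      if (any(vals == "no")) { ok <- FALSE; break }
    }
    if (ok) {
      last <- p[[length(p)]]
      hits <- c(hits,
                key$couplets[[as.character(last$couplet)]]$leads[[last$lead]]$outcome$value)
    }
  }
  sort(unique(hits))
}

# fully-informed random observation covering every key character, as point
# values/categories, so no predicate is ambiguous
random_full_observation <- function(registry) {
  vals <- list(
    cyst_lw_ratio = runif(1, 0.9, 3),
    eggshell_surface = sample(c("smooth", "punctate"), 1),
    stylet_length = runif(1, 15, 32),
    tail_length = runif(1, 25, 70),
    hyaline_length = runif(1, 3, 32),
    fenestral_diam = runif(1, 9, 60),
    j2_length = runif(1, 330, 630),
    cyst_length = runif(1, 280, 1020),
    cyst_width = runif(1, 90, 630),
    b_ratio = runif(1, 2.5, 5),
    dgo = runif(1, 2, 7),
    vulval_denticles = sample(c("present", "absent"), 1),
    vulval_cone = sample(c("distinct", "indistinct"), 1),
    stylet_knob_shape = sample(c("concave", "convex"), 1))
  specimen_observation("rand", vals)
}
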
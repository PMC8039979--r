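# Character registry, taxon profiles, the comparative matrix, and user
# specimen observations. The bundled dataset "cactodera_v1" carries the
# seventeen-species comparative table, the type-population morphometrics
# table, the dichotomous key graph and its errata.

BUNDLED_VERSION <- "cactodera_v1"

# alias -> canonical; single recorded synonymy (spelling variant)
TAXON_ALIASES <- c("c. wessi" = "C. weissi")

cact_data_path <- function(..., version = BUNDLED_VERSION) {
  p <- system.file("extdata", version, ..., package = "cactkey")
  if (!nzchar(p)) stop("bundled data file not found: ", paste(..., sep = "/"))
  p
}

#' Bundled character registry
#'
#' One row per character: id, label, life stage (`cyst`, `J2`, `egg`),
#' kind (`numeric`/`categorical`), units (`um`, `ratio`, or `""` for
#' categoricals) and the allowed category tokens (`;`-separated).
#'
#' @param path Optional path to a registry CSV; default is the bundled one.
#' @return A `data.frame` with class `cact_registry` prepended.
#' @export
bundled_registry <- function(path = cact_data_path("characters.csv")) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("id", "label", "stage", "kind", "units", "categories")
  if (!all(need %in% names(reg))) stop("registry is missing columns: ",
                                       paste(setdiff(need, names(reg)), collapse = ", "))
  if (anyDuplicated(reg$id)) stop("duplicate character ids in registry")
  bad_num <- reg$kind == "numeric" & !reg$units %in% c("um", "ratio")
  if (any(bad_num)) stop("numeric characters must have units 'um' or be flagged ",
                         "'ratio': ", paste(reg$id[bad_num], collapse = ", "))
  bad_cat <- reg$kind == "categorical" & !nzchar(reg$categories)
  if (any(bad_cat)) stop("categorical characters must enumerate categories: ",
                         paste(reg$id[bad_cat], collapse = ", "))
  class(reg) <- c("cact_registry", class(reg))
  reg
}

registry_categories <- function(registry, id) {
  tolower(strsplit(registry$categories[registry$id == id], ";")[[1]])
}

#' Construct a taxon profile
#'
#' @param taxon Species name.
#' @param values Named list of [num_value()], [cat_value()] or
#'   [unknown_value()] entries, keyed by character id.
#' @param citation Free-text provenance.
#' @param note Optional data note.
#' @return An object of class `taxon_profile`.
#' @export
taxon_profile <- function(taxon, values, citation = "", note = "") {
  stopifnot(is.character(taxon), length(taxon) == 1L, is.list(values))
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("profile values must be named by character id")
  ok <- vapply(values, inherits, logical(1), what = "cact_value")
  if (!all(ok)) stop("profile values must be cact_value objects")
  structure(list(taxon = taxon, values = values, citation = citation,
                 note = note), class = "taxon_profile")
}

#' Construct a specimen observation
#'
#' Numeric entries may be a single point measurement or a length-2 range
#' (multi-individual samples); character entries are category tokens.
#'
#' @param specimen_id Identifier string.
#' @param values Named list/vector of measurements keyed by character id.
#' @param stage Optional life-stage annotation.
#' @return An object of class `specimen_observation`.
#' @export
#' @examples
#' specimen_observation("s1", list(tail_length = 54, eggshell_surface = "smooth"))
specimen_observation <- function(specimen_id, values, stage = NA_character_) {
  stopifnot(is.character(specimen_id), length(specimen_id) == 1L)
  values <- as.list(values)
  if (length(values) == 0L) stop("at least one character must be observed")
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("observation values must be named by character id")
  vals <- lapply(values, function(v) {
    if (inherits(v, "cact_value")) return(v)
    if (is.character(v) || is.factor(v)) return(cat_value(as.character(v)))
    v <- as.numeric(v)
    if (length(v) == 1L) num_value(v)
    else if (length(v) == 2L) num_value(min(v), max(v))
    else stop("numeric observation entries must have length 1 or 2")
  })
  structure(list(specimen_id = specimen_id, values = vals, stage = stage),
            class = "specimen_observation")
}

#' Load a character matrix
#'
#' Reads the bundled seventeen-species comparative matrix
#' (`source = "cactodera_v1"`) or a user CSV/JSON file in the documented
#' dialect. CSV: one row per taxon; interval cells `lo-hi` (hyphen or en
#' dash accepted on read, hyphen on write); `-` marks unknown. JSON files
#' carry registry, taxa and version and round-trip all fields.
#'
#' @param source Bundled dataset name or a file path.
#' @param registry Character registry used to validate a CSV (defaults to
#'   the bundled registry; ignored for JSON, which embeds its own).
#' @param format `"csv"` or `"json"`; inferred from the extension if `NULL`.
#' @return An object of class `cactodera_matrix`.
#' @export
#' @examples
#' m <- load_matrix("cactodera_v1")
#' length(m$taxa)          # 17
#' matrix_value(m, "C. thornei", "cyst_length")
load_matrix <- function(source = BUNDLED_VERSION, registry = NULL,
                        format = NULL) {
  if (identical(source, BUNDLED_VERSION) || identical(source, "bundled")) {
    path <- cact_data_path("matrix.csv")
    version <- BUNDLED_VERSION
    format <- "csv"
  } else {
    path <- source
    version <- sub("\\.[^.]*$", "", basename(path))
    if (!file.exists(path)) stop("no such file: ", path)
  }
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (file.info(path)$size == 0) stop("empty file: ", path)
  if (format == "json") return(matrix_from_json(path))
  if (is.null(registry)) registry <- bundled_registry()

  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) stop("empty matrix file (no data rows): ", path)
  if (!"taxon" %in% names(df)) stop("matrix CSV must have a 'taxon' column")
  if (anyDuplicated(df$taxon))
    stop("duplicate taxon: ", df$taxon[duplicated(df$taxon)][1])
  char_cols <- setdiff(names(df), c("taxon", "citation", "note"))
  missing_chars <- setdiff(char_cols, registry$id)
  if (length(missing_chars))
    stop("columns not in registry: ", paste(missing_chars, collapse = ", "))

  taxa <- lapply(seq_len(nrow(df)), function(i) {
    vals <- lapply(char_cols, function(cc) {
      kind <- registry$kind[registry$id == cc]
      v <- parse_cell(df[[cc]][i], kind, taxon = df$taxon[i], column = cc)
      if (v$kind == "category") {
        allowed <- registry_categories(registry, cc)
        if (!v$category %in% allowed)
          stop(sprintf("taxon %s, column %s: category '%s' not in {%s}",
                       df$taxon[i], cc, v$category,
                       paste(allowed, collapse = ", ")))
      }
      v
    })
    names(vals) <- char_cols
    taxon_profile(df$taxon[i], vals,
                  citation = if ("citation" %in% names(df)) df$citation[i] else "",
                  note = if ("note" %in% names(df)) df$note[i] else "")
  })
  names(taxa) <- df$taxon
  new_matrix(registry, taxa, version)
}

new_matrix <- function(registry, taxa, version) {
  structure(list(version = version, registry = registry, taxa = taxa,
                 aliases = TAXON_ALIASES),
            class = "cactodera_matrix")
}

#' Resolve a taxon name
#'
#' Case-insensitive; accepts `"C. thornei"`, `"Cactodera thornei"`,
#' trailing `"n. sp."`, and the recorded alias `"C. wessi"` for
#' `"C. weissi"`.
#'
#' @param matrix A `cactodera_matrix`.
#' @param name Taxon name in any accepted form.
#' @return The canonical taxon name.
#' @export
resolve_taxon <- function(matrix, name) {
  norm <- tolower(trimws(name))
  norm <- sub("^cactodera\\s+", "c. ", norm)
  norm <- sub("^c\\.?\\s*", "c. ", norm)
  norm <- sub("\\s+n\\.\\s*sp\\.?$", "", norm)
  norm <- gsub("\\s+", " ", norm)
  if (norm %in% names(matrix$aliases)) return(unname(matrix$aliases[norm]))
  hit <- match(norm, tolower(names(matrix$taxa)))
  if (is.na(hit)) stop("unknown taxon: ", name)
  names(matrix$taxa)[hit]
}

#' Look up one matrix cell
#'
#' @inheritParams resolve_taxon
#' @param character Character id (see [bundled_registry()]).
#' @return A `cact_value`.
#' @export
matrix_value <- function(matrix, name, character) {
  taxon <- resolve_taxon(matrix, name)
  if (!character %in% matrix$registry$id)
    stop("unknown character id: ", character)
  v <- matrix$taxa[[taxon]]$values[[character]]
  if (is.null(v)) unknown_value() else v
}

#' Write a character matrix
#'
#' CSV writes one row per taxon with `lo-hi` interval cells (plain hyphen)
#' and `-` for unknown; it drops published means/sds, so use JSON when full
#' round-trip fidelity is needed. `load_matrix(write_matrix(m, p))` is the
#' identity on all fields for JSON, and on ranges/categories/unknowns for
#' CSV.
#'
#' @param matrix A `cactodera_matrix`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; inferred from the extension if `NULL`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, format = NULL) {
  stopifnot(inherits(matrix, "cactodera_matrix"))
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    jsonlite::write_json(matrix_to_list(matrix), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
    return(invisible(path))
  }
  char_cols <- unique(unlist(lapply(matrix$taxa, function(p) names(p$values))))
  rows <- lapply(matrix$taxa, function(p) {
    cells <- vapply(char_cols, function(cc) {
      v <- p$values[[cc]]
      if (is.null(v) || is_unknown(v)) "-" else format_value(v)
    }, character(1))
    c(taxon = p$taxon, cells, citation = p$citation, note = p$note)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write matrix to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

matrix_to_list <- function(matrix) {
  list(
    version = matrix$version,
    registry = lapply(seq_len(nrow(matrix$registry)), function(i)
      as.list(matrix$registry[i, c("id", "label", "stage", "kind", "units",
                                   "categories")])),
    taxa = lapply(unname(matrix$taxa), function(p) list(
      taxon = p$taxon, citation = p$citation, note = p$note,
      values = lapply(p$values, function(v) {
        out <- unclass(v)
        if (v$kind == "numeric") out[!vapply(out, function(f)
          length(f) == 1 && is.na(f), logical(1))] else out
      })))
  )
}

matrix_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$taxa) || length(x$taxa) == 0L)
    stop("empty or malformed JSON matrix: ", path)
  reg <- do.call(rbind, lapply(x$registry, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  class(reg) <- c("cact_registry", class(reg))
  taxa <- lapply(x$taxa, function(t) {
    vals <- lapply(t$values, function(v) {
      switch(v$kind,
        unknown  = unknown_value(),
        category = cat_value(v$category),
        numeric  = num_value(v$lo, v$hi,
                             mean = v$mean %||% NA_real_,
                             sd = v$sd %||% NA_real_,
                             n = v$n %||% NA_integer_),
        stop("unknown value kind in JSON: ", v$kind))
    })
    taxon_profile(t$taxon, vals, citation = t$citation %||% "",
                  note = t$note %||% "")
  })
  names(taxa) <- vapply(taxa, `[[`, character(1), "taxon")
  if (anyDuplicated(names(taxa)))
    stop("duplicate taxon: ", names(taxa)[duplicated(names(taxa))][1])
  new_matrix(reg, taxa, x$version %||% "unversioned")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a specimen observation against a registry
#'
#' Reporting operation: returns warnings, never errors and never mutates
#' the input. Flags unknown character ids, categories outside the
#' enumeration, and nonpositive numeric values.
#'
#' @param obs A `specimen_observation`.
#' @param registry A character registry (see [bundled_registry()]).
#' @return Character vector of warnings (length 0 when clean).
#' @export
validate_observation <- function(obs, registry = bundled_registry()) {
  stopifnot(inherits(obs, "specimen_observation"))
  warnings <- character(0)
  for (id in names(obs$values)) {
    v <- obs$values[[id]]
    if (!id %in% registry$id) {
      warnings <- c(warnings, sprintf("unknown character id '%s'", id))
      next
    }
    kind <- registry$kind[registry$id == id]
    if (v$kind == "category") {
      if (kind != "categorical") {
        warnings <- c(warnings,
                      sprintf("'%s' is numeric but a category was given", id))
      } else {
        allowed <- registry_categories(registry, id)
        if (!v$category %in% allowed)
          warnings <- c(warnings,
                        sprintf("'%s' = '%s' not among allowed categories {%s}",
                                id, v$category, paste(allowed, collapse = ", ")))
      }
    } else if (v$kind == "numeric") {
      if (kind != "numeric")
        warnings <- c(warnings,
                      sprintf("'%s' is categorical but a number was given", id))
      else if (v$lo <= 0)
        warnings <- c(warnings, sprintf("'%s' nonpositive (%g)", id, v$lo))
    }
  }
  warnings
}

#' Type-population morphometrics table
#'
#' The bundled mean / sd / range / n table for the type population of
#' *C. tianzhuensis* (cyst, J2 and egg characters; holotype column where
#' published). Used by the derived-ratio examples and the acceptance
#' script.
#'
#' @return A `data.frame` with columns stage, character, holotype, mean,
#'   sd, lo, hi, n, note.
#' @export
load_type_morphometrics <- function() {
  df <- utils::read.csv(cact_data_path("type_morphometrics.csv"),
                        stringsAsFactors = FALSE)
  for (cc in c("holotype", "mean", "sd", "lo", "hi")) df[[cc]] <- as.numeric(df[[cc]])
  df$n <- as.integer(df$n)
  df
}

#' @export
print.cactodera_matrix <- function(x, ...) {
  cat(sprintf("Cactodera character matrix '%s': %d taxa, %d registered characters\n",
              x$version, length(x$taxa), nrow(x$registry)))
  cat("taxa:", paste(names(x$taxa), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat(x$taxon, if (nzchar(x$citation)) paste0("  [", x$citation, "]"), "\n")
  for (id in names(x$values))
    cat(sprintf("  %-18s %s\n", id, format_value(x$values[[id]])))
  invisible(x)
}

#' @export
print.specimen_observation <- function(x, ...) {
  cat("specimen", x$specimen_id, "\n")
  for (id in names(x$values))
    cat(sprintf("  %-18s %s\n", id, format_value(x$values[[id]])))
  invisible(x)
}
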
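test_that("bundled matrix loads 17 taxa with verbatim table cells", {
  m <- bundled$matrix
  expect_length(m$taxa, 17L)
  expect_identical(m$version, "cactodera_v1")

  cell <- function(tx, ch) matrix_value(m, tx, ch)
  v <- cell("C. thornei", "cyst_length")
  expect_equal(c(v$lo, v$hi), c(485, 806))
  expect_equal(c(cell("C. thornei", "cyst_width")$lo,
                 cell("C. thornei", "cyst_width")$hi), c(286, 581))
  expect_equal(c(cell("C. tianzhuensis", "fenestral_diam")$lo,
                 cell("C. tianzhuensis", "fenestral_diam")$hi), c(20, 32))
  expect_equal(c(cell("C. tianzhuensis", "hyaline_length")$lo,
                 cell("C. tianzhuensis", "hyaline_length")$hi), c(22, 29))
  expect_equal(c(cell("C. estonica", "cyst_lw_ratio")$lo,
                 cell("C. estonica", "cyst_lw_ratio")$hi), c(2.0, 2.4))
  expect_equal(c(cell("C. rosae", "hyaline_length")$lo,
                 cell("C. rosae", "hyaline_length")$hi), c(4, 8))
  expect_equal(c(cell("C. cacti", "dgo")$lo, cell("C. cacti", "dgo")$hi),
               c(2.9, 4.4))
  expect_equal(c(cell("C. weissi", "stylet_length")$lo,
                 cell("C. weissi", "stylet_length")$hi), c(20, 22))
  expect_identical(cell("C. thornei", "eggshell_surface")$category, "punctate")
  expect_identical(cell("C. radicale", "vulval_denticles")$category, "absent")
  # two-axis fenestrae stored as intervals
  expect_equal(c(cell("C. acnidae", "fenestral_diam")$lo,
                 cell("C. acnidae", "fenestral_diam")$hi), c(30, 33))
  expect_equal(c(cell("C. torreyanae", "fenestral_diam")$lo,
                 cell("C. torreyanae", "fenestral_diam")$hi), c(20, 26))
})

test_that("bundled matrix file is pinned by checksum", {
  path <- system.file("extdata", "cactodera_v1", "matrix.csv",
                      package = "cactkey")
  expect_identical(unname(tools::md5sum(path)),
                   "19c6d9a776f500234ef98aff3a8413ec")
})

test_that("unknown is distinct from absent", {
  m <- bundled$matrix
  expect_true(is_unknown(matrix_value(m, "C. acnidae", "vulval_denticles")))
  expect_true(is_unknown(matrix_value(m, "C. evansi", "vulval_denticles")))
  expect_identical(matrix_value(m, "C. salina", "vulval_denticles")$category,
                   "absent")
  expect_true(is_unknown(matrix_value(m, "C. rosae", "dgo")))
})

test_that("taxon name resolution is tolerant and alias-aware", {
  m <- bundled$matrix
  expect_identical(resolve_taxon(m, "c. THORNEI"), "C. thornei")
  expect_identical(resolve_taxon(m, "Cactodera thornei"), "C. thornei")
  expect_identical(resolve_taxon(m, "C. tianzhuensis n. sp."),
                   "C. tianzhuensis")
  expect_identical(resolve_taxon(m, "C. wessi"), "C. weissi")
  expect_error(resolve_taxon(m, "C. nonexistens"), "unknown taxon")
})

test_that("write/load round-trips matrices in both formats", {
  m <- bundled$matrix
  jp <- withr::local_tempfile(fileext = ".json")
  write_matrix(m, jp)
  m2 <- load_matrix(jp)
  expect_length(m2$taxa, 17L)
  for (tx in names(m$taxa)) {
    expect_identical(m2$taxa[[tx]]$citation, m$taxa[[tx]]$citation)
    for (id in names(m$taxa[[tx]]$values))
      expect_equal(m2$taxa[[tx]]$values[[id]], m$taxa[[tx]]$values[[id]],
                   info = paste(tx, id))
  }
  cp <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, cp)
  m3 <- load_matrix(cp, registry = m$registry)
  for (tx in names(m$taxa))
    for (id in names(m$taxa[[tx]]$values))
      expect_equal(m3$taxa[[tx]]$values[[id]], m$taxa[[tx]]$values[[id]],
                   info = paste(tx, id))
  # unknowns survive as unknowns, not zeros
  expect_true(is_unknown(matrix_value(m3, "C. acnidae", "vulval_denticles")))
})

test_that("single-taxon matrix writes one data row plus header", {
  m <- bundled$matrix
  m$taxa <- m$taxa["C. thornei"]
  p <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, p)
  expect_length(readLines(p), 2L)
})

test_that("malformed inputs are rejected without partial results", {
  p <- withr::local_tempfile(fileext = ".csv")
  file.create(p)
  expect_error(load_matrix(p), "empty")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,cyst_length", "C. x,1-2", "C. x,3-4"), dup)
  expect_error(load_matrix(dup), "duplicate taxon")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,cyst_length", "C. x,abc"), bad)
  expect_error(load_matrix(bad), "malformed cell")

  badcat <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,eggshell_surface", "C. x,shiny"), badcat)
  expect_error(load_matrix(badcat), "not in \\{")
})

test_that("value constructors enforce their invariants", {
  expect_error(num_value(5, 3), "inverted")
  expect_warning(num_value(1, 2, mean = 3), "outside range")
  v <- num_value(7)
  expect_equal(c(v$lo, v$hi), c(7, 7))
  expect_error(cat_value(""), "non-empty")
  expect_error(specimen_observation("s", list()), "at least one")
})

test_that("validate_observation reports, never errors", {
  reg <- bundled$registry
  ok <- specimen_observation("s", list(eggshell_surface = "smooth"))
  expect_length(validate_observation(ok, reg), 0L)

  bad <- specimen_observation("s", list(eggshell_surface = "shiny",
                                        stylet_length = -3,
                                        made_up_char = 1))
  w <- validate_observation(bad, reg)
  expect_length(w, 3L)
  expect_true(any(grepl("smooth, punctate", w)))    # names allowed categories
  expect_true(any(grepl("nonpositive", w)))
  expect_true(any(grepl("unknown character id", w)))
  # input not mutated
  expect_identical(bad$values$stylet_length$lo, -3)
})
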
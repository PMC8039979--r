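test_that("bundled key has 16 two-lead couplets reaching all 17 taxa", {
  k <- bundled$key
  expect_length(k$couplets, 16L)
  expect_identical(k$root, 1L)
  expect_true(all(vapply(k$couplets, function(cp) length(cp$leads) == 2L,
                         logical(1))))
  out <- unlist(lapply(k$couplets, function(cp)
    lapply(cp$leads, function(ld)
      if (ld$outcome$type == "taxon") ld$outcome$value else NULL)))
  expect_setequal(out, names(bundled$matrix$taxa))
  # couplet 1 first lead terminates in C. estonica, couplet 16 splits
  # C. weissi from C. tianzhuensis
  expect_identical(k$couplets[["1"]]$leads[[1]]$outcome$value, "C. estonica")
  expect_setequal(vapply(k$couplets[["16"]]$leads,
                         function(ld) ld$outcome$value, character(1)),
                  c("C. weissi", "C. tianzhuensis"))
})

test_that("eval_predicate implements three-valued interval logic", {
  reg <- bundled$registry
  m <- bundled$matrix
  p_egg <- list(character = "eggshell_surface", relation = "eq-category",
                threshold = "punctate", basis = "range")
  expect_equal(as.character(eval_predicate(p_egg, m$taxa[["C. thornei"]], reg)),
               "yes")
  expect_equal(as.character(eval_predicate(p_egg, m$taxa[["C. tianzhuensis"]],
                                           reg)), "no")
  # recorded smooth eggshell answers the punctate test with a definite no
  expect_equal(as.character(eval_predicate(p_egg, m$taxa[["C. acnidae"]], reg)),
               "no")
  # unrecorded category -> ambiguous
  p_cone <- list(character = "vulval_cone", relation = "eq-category",
                 threshold = "distinct", basis = "range")
  expect_equal(as.character(eval_predicate(p_cone, m$taxa[["C. cacti"]], reg)),
               "ambiguous")
})

test_that("range, mean-proxy and missing-data cases evaluate correctly", {
  reg <- bundled$registry
  prof <- taxon_profile("T", list(
    tail_length = num_value(47, 59),
    fenestral_diam = num_value(20, 32),
    dgo = num_value(4.0, 6.5),
    stylet_length = num_value(23, 26, mean = 24.9)))

  p_mean <- list(character = "tail_length", relation = "ge", threshold = 40,
                 basis = "mean")
  r <- eval_predicate(p_mean, prof, reg)
  expect_equal(as.character(r), "yes")      # midpoint 53 >= 40
  expect_true(attr(r, "proxy"))             # no stored mean -> proxy flagged

  p_mean2 <- list(character = "stylet_length", relation = "ge", threshold = 26,
                  basis = "mean")
  r2 <- eval_predicate(p_mean2, prof, reg)
  expect_equal(as.character(r2), "no")      # stored mean 24.9 used
  expect_false(attr(r2, "proxy"))

  p_straddle <- list(character = "fenestral_diam", relation = "lt",
                     threshold = 25, basis = "range")
  expect_equal(as.character(eval_predicate(p_straddle, prof, reg)), "ambiguous")

  p_inrange <- list(character = "dgo", relation = "in-range",
                    threshold = c(4.5, 5.6), basis = "range")
  expect_equal(as.character(eval_predicate(p_inrange, prof, reg)), "ambiguous")

  p_missing <- list(character = "b_ratio", relation = "lt", threshold = 3.5,
                    basis = "range")
  expect_equal(as.character(eval_predicate(p_missing, prof, reg)), "ambiguous")

  p_bad <- list(character = "no_such", relation = "lt", threshold = 1,
                basis = "range")
  expect_error(eval_predicate(p_bad, prof, reg), "not in registry")
})

test_that("the new species keys out uniquely along 1>2>11>14>15>16", {
  m <- bundled$matrix
  tr <- traverse_key(bundled$key, m$taxa[["C. tianzhuensis"]], m$registry)
  expect_identical(tr$status, "unique")
  expect_identical(tr$terminals[[1]]$taxon, "C. tianzhuensis")
  expect_equal(tr$terminals[[1]]$path, c(1L, 2L, 11L, 14L, 15L, 16L))
})

test_that("C. estonica terminates at couplet 1; all-unknown reaches all 17", {
  m <- bundled$matrix
  tr <- traverse_key(bundled$key, m$taxa[["C. estonica"]], m$registry)
  expect_identical(tr$status, "unique")
  expect_identical(tr$terminals[[1]]$taxon, "C. estonica")
  expect_equal(tr$terminals[[1]]$path, 1L)

  blank <- taxon_profile("blank", list(cyst_length = unknown_value()))
  tr2 <- traverse_key(bundled$key, blank, m$registry)
  expect_identical(tr2$status, "ambiguous-multiple")
  expect_setequal(vapply(tr2$terminals, `[[`, character(1), "taxon"),
                  names(m$taxa))
})

test_that("traversal is deterministic and bounded", {
  m <- bundled$matrix
  obs <- specimen_observation("s", list(eggshell_surface = "smooth",
                                        tail_length = 54))
  t1 <- traverse_key(bundled$key, obs, m$registry)
  t2 <- traverse_key(bundled$key, obs, m$registry)
  expect_identical(t1, t2)
  expect_true(all(vapply(t1$terminals, function(t) length(t$path) <= 16,
                         logical(1))))
})

test_that("validate_key audits every taxon and links errata", {
  aud <- validate_key(bundled$key, bundled$matrix)
  a <- aud$audit
  expect_equal(nrow(a), 17L)
  expect_true(aud$structure$acyclic)
  expect_length(aud$structure$dangling, 0L)
  expect_length(aud$structure$unreachable, 0L)
  expect_length(aud$structure$taxa_without_terminal, 0L)

  row <- function(tx) a[a$taxon == tx, ]
  expect_identical(row("C. rosae")$status, "CONSISTENT")
  expect_identical(row("C. rosae")$path, "1>2>3>5>9>10")
  expect_identical(row("C. thornei")$path, "1>2>3>4")
  # every MISROUTED finding traces to a documented erratum
  mis <- a[a$status == "MISROUTED", ]
  expect_true(all(nzchar(mis$erratum)))
  err <- key_errata()
  expect_true(all(unlist(strsplit(mis$erratum, ",")) %in% err$id))
})

test_that("a lead pointing to a missing couplet is a structural error", {
  expect_error(load_toy_key(dangling = TRUE), "missing couplets: 9")
})

test_that("toy key traverses, dead-ends are data", {
  reg <- toy_registry()
  k <- load_toy_key()
  a_obs <- specimen_observation("s", list(surface = "smooth", len = 30))
  tr <- traverse_key(k, a_obs, reg)
  expect_identical(tr$status, "unique")
  expect_identical(tr$terminals[[1]]$taxon, "A")

  # len exactly on neither side after a contradictory profile: force a
  # dead end with an interval wholly violating both leads of couplet 2
  dead <- taxon_profile("d", list(surface = cat_value("smooth")))
  k2 <- k
  k2$couplets[["2"]]$leads[[1]]$predicates[[1]]$threshold <- 10
  k2$couplets[["2"]]$leads[[2]]$predicates[[1]]$relation <- "gt"
  k2$couplets[["2"]]$leads[[2]]$predicates[[1]]$threshold <- 90
  dd <- traverse_key(k2, specimen_observation("s", list(surface = "smooth",
                                                        len = 50)), reg)
  expect_identical(dd$status, "dead-end")
  expect_length(dd$dead_ends, 1L)
  expect_equal(dd$dead_ends[[1]]$couplet, 2L)
})

test_that("traversal equals the brute-force oracle on unambiguous profiles", {
  withr::local_seed(42)
  m <- bundled$matrix
  for (i in 1:60) {
    obs <- random_full_observation(m$registry)
    tr <- traverse_key(bundled$key, obs, m$registry)
    mine <- sort(unique(vapply(tr$terminals, `[[`, character(1), "taxon")))
    oracle <- enumerate_terminals(bundled$key, obs, m$registry)
    expect_identical(mine, oracle)
  }
})

test_that("adding information never enlarges the terminal set", {
  withr::local_seed(11)
  m <- bundled$matrix
  for (i in 1:40) {
    full <- random_full_observation(m$registry)
    ids <- names(full$values)
    keep <- sample(ids, sample(seq_along(ids), 1))
    partial <- specimen_observation("p", full$values[keep])
    n_partial <- length(traverse_key(bundled$key, partial, m$registry)$terminals)
    extra <- setdiff(ids, keep)
    if (length(extra) == 0) next
    more <- specimen_observation("q", full$values[c(keep, extra[1])])
    n_more <- length(traverse_key(bundled$key, more, m$registry)$terminals)
    expect_lte(n_more, n_partial)
  }
})
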
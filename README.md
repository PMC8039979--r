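# cactkey

Identification toolkit for cyst-forming nematodes of the genus
*Cactodera* (Nematoda: Heteroderinae).

## The problem

*Cactodera* currently holds seventeen species, separated by a handful of
cyst, second-stage juvenile (J2) and egg characters: cyst length, width
and L/W ratio, fenestral diameter, presence of vulval denticles, J2 body,
stylet, tail and hyaline-tail lengths, the dorsal pharyngeal gland
opening (DGO), and whether the eggshell is smooth or punctate. Published
descriptions summarize these as ranges and `mean ± sd (range)` tables,
and the genus has a printed dichotomous key — but ranges overlap, keys
test means that the comparative tables do not tabulate, and characters
are often missing. `cactkey` makes this taxonomy executable and honest
about those gaps. It is aimed at plant-nematologists and diagnosticians
who have partial measurements of cysts or J2s and want a defensible
identification, and at taxonomists who want to audit a key against the
data it claims to summarize.

## What it computes

* **Comparative matrix** — all seventeen species' character ranges and
  categories as versioned, machine-readable data (`load_matrix()`), with
  explicit unknowns (`–` cells), interval cells, and round-trip CSV/JSON
  I/O.
* **Dichotomous key engine** — the printed sixteen-couplet key as a
  rooted acyclic decision graph. Predicates are evaluated with
  three-valued (Kleene) logic against interval data: *yes* when the
  profile wholly satisfies a test, *no* when it wholly violates it,
  *ambiguous* when it straddles or the character is unrecorded; on
  ambiguity both leads are explored. Mean tests against range-only rows
  use the interval midpoint and are flagged `proxy`. `validate_key()`
  audits every species against its own row; irreducible conflicts are
  shipped as machine-readable errata, not silently repaired.
* **Polyclave (multi-access) identification** — `score_candidates()`
  ranks all species by interval-overlap similarity: for an observed
  interval *o* and reference range *r*, the containment coefficient
  |*o* ∩ *r*| / |*o*|; for a point, 1 inside *r* and max(0, 1 − d/w)
  outside. Aggregate is the unweighted mean over scored characters.
  `diagnostic_characters()` reports the per-character differential
  (disjoint / low-overlap / overlapping / categorical-differs).
* **Morphometrics** — `summary_stats()` / `format_summary()` produce the
  `mean ± sd (range)` convention (sample sd, half-up rounding);
  `derived_indices()` computes the de Man ratios a, b, c, c′ plus L/MB,
  TL/H and length/width ratios; `hyaline_percent()` the hyaline fraction
  of the tail.
* **Sequence divergence** — `pairwise_divergence()` and
  `divergence_table()` count differences on pre-aligned ITS / 28S D2-D3
  sequences (pairwise gap deletion by default) and format them in the
  conventional `"8 bp (98.93%)"` style. No alignment or tree inference
  is performed.
* **Simulators** — `simulate_specimens()` (uniform strict-interior or
  truncated-normal draws inside published ranges) and
  `simulate_alignment()` (sequences with exactly known differences)
  provide ground truth for testing.

## Worked example

```r
library(cactkey)
m <- load_matrix("cactodera_v1")

obs <- specimen_observation("field-01", list(
  eggshell_surface = "smooth", vulval_denticles = "present",
  tail_length = 54, hyaline_length = 26, stylet_length = 24.5,
  j2_length = 540, cyst_lw_ratio = 1.3, dgo = 4.9))

score_candidates(obs, m)
#> ranked candidates (top 3 of 17 ):
#>            taxon aggregate n_used n_skipped_unknown
#>  C. tianzhuensis     1.000      8                 0
#>       C. thornei     0.848      8                 0
#>      C. radicale     0.828      8                 0

traverse_key(bundled_key(), obs, m$registry)
#> key traversal: unique
#>   C. tianzhuensis        via couplets 1 > 2 > 11 > 14 > 15 > 16
```

Every observed character of this specimen falls inside
*C. tianzhuensis*'s published ranges (aggregate 1.000 over 8 characters);
the runner-up *C. thornei* loses mainly on its punctate eggshell and
larger fenestra. The dichotomous key, traversed with the same data,
reaches the same species through six couplets. The differential against
the closest species shows which characters actually separate them:

```r
diagnostic_characters("C. tianzhuensis", "C. thornei", m)
#> C. tianzhuensis vs C. thornei
#>   eggshell_surface     categorical-differs  (smooth vs punctate)
#>   fenestral_diam       low-overlap          (20-32 vs 31-36)
#>   cyst_length          overlapping          (511-761 vs 485-806)
#>   ...
```

Derived ratios from the type-population means reproduce the published
table at printed precision:

```r
tm <- load_type_morphometrics()
di <- derived_indices(c(body_length = 538.5, tail_length = 54.1,
                        anal_diam = 13.8, mb = 77.8, hyaline_length = 25.8))
round_half_up(c(c = di$c, c_prime = di$c_prime, tl_over_h = di$tl_over_h,
                l_over_mb = di$l_over_mb), 1)
#>         c   c_prime tl_over_h l_over_mb
#>      10.0       3.9       2.1       6.9
hyaline_percent(54.1, 25.8)   # 47.7 -> "about 48%" of tail length
```

## Command line

A thin CLI over the same functions ships in `inst/cli/cactkey.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "cactkey.R", package = "cactkey"))')" key-validate
```

Subcommands: `identify`, `compare`, `key-path`, `key-validate`,
`summarize`, `divergence`, `simulate-specimens`, `simulate-alignment`.

See `vignettes/cactkey-methods.Rmd` for the model, its assumptions,
numerical choices, and known limitations (including two documented key
errata where a species' own published ranges contradict the printed
key's mean thresholds).
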
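---
title: "Methods: executable taxonomy for the genus Cactodera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: executable taxonomy for the genus Cactodera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cactkey)
```

## The data model

Cyst-nematode taxonomy summarizes each species as per-character
*ranges* (occasionally `mean ± sd (range)`) over three life stages:
the cyst (the tanned body wall of the dead female), the infective
second-stage juvenile (J2), and the egg. `cactkey` stores each cell of
the comparative matrix as one of three explicit states:

* a numeric interval `[lo, hi]` (point values as `lo == hi`), with
  optional published mean/sd/n;
* a category token from a per-character enumeration
  (e.g. `smooth`/`punctate`, `present`/`absent`);
* **unknown** — the `–` of printed tables. Unknown is never conflated
  with `absent`: "vulval denticles –" means *not recorded*, and every
  downstream computation (key evaluation, similarity scoring) treats it
  as missing data rather than as a zero or a negative observation.

All lengths are micrometres; ratios are dimensionless. The bundled
`cactodera_v1` dataset carries the seventeen-species matrix, the
type-population morphometrics of *C. tianzhuensis*, the dichotomous key
graph, and a machine-readable errata file. Two printed cells give the
fenestra as two axes ("30 × 33", "20 × 26"); they are stored as the
interval between the axes, since every consumer of the value needs only
an interval. The spelling variant *C. wessi* is resolved to
*C. weissi* through an alias table.

Two categorical characters used by the key but absent from the
comparative table — stylet-knob anterior surface (concave/convex) and
vulval-cone prominence (distinct/indistinct) — are in the registry with
values only where a description or the key itself states them; all
other species hold explicit unknowns. This keeps the key executable
without inventing data.

## Morphometric summaries and ratios

`summary_stats()` implements the table convention: arithmetic mean,
*sample* standard deviation (n − 1 denominator — the convention is not
stated in descriptions, but it is the standard for morphometric tables),
and extremes; `format_summary()` renders `mean ± sd (lo-hi)` with a
plain hyphen in machine output. Rounding for comparison against printed
values is **half-up** (`round_half_up()`), not R's banker's rounding:
recomputing the printed ratios from the printed means (c = 538.5/54.1,
c′ = 54.1/13.8, TL/H = 54.1/25.8, L/MB = 538.5/77.8, egg L/W =
117.9/51.3, cyst L/Diam. = 571.2/454.3) reproduces the printed 10.0,
3.9, 2.1, 6.9, 2.3, 1.3 only under half-up rounding.

A ratio of means is not the mean of per-specimen ratios: from the
printed means, index a = 538.5/23.2 ≈ 23.2, while the table's
per-specimen mean is 23.4. The API therefore computes indices per
specimen whenever raw data are given; matrix-level ratios are labelled
approximate. Index b (body/pharynx) is supported but can never be
recomputed from the bundled table, which does not tabulate pharynx
length. One further pinned discrepancy: the holotype L/Diam. prints
1.23 although 531/429 rounds to 1.24; the bundled table keeps the
printed value with a note rather than recomputing.

## The key engine

The printed key is sixteen couplets, two leads each, mixing three kinds
of test: explicit mean tests ("Mean stylet length of J2s ≥ 26 µm"),
plain thresholds ("fenestral diam. < 20 µm") and range tests ("tail
length = 48–64 µm"). The comparative matrix stores ranges. Evaluation
is therefore three-valued:

* **range basis** (plain thresholds and range tests): *yes* if the
  profile interval wholly satisfies the relation, *no* if it wholly
  violates it, *ambiguous* if it straddles;
* **mean basis** (leads that print "mean"): the stored mean when
  present, else the interval **midpoint** as a proxy — every proxy use
  is flagged in the trace, so an audit can distinguish "the data say
  so" from "the midpoint says so";
* categorical: yes/no on a recorded token, ambiguous on unknown.

Leads conjoin predicates with Kleene logic (no dominates, else
ambiguous dominates yes). Traversal prunes *no* leads and explores
everything else, so an under-specified profile widens the terminal set
instead of guessing; a profile with no information reaches all
seventeen species. Dead ends (both leads *no*) are reported as a
status, not raised: the audit needs them as findings.

### Repairs and errata

The printed key's lead numbering after couplet 10 is typeset wrongly
(couplet 11's first lead points to itself). The bundled graph is a
reconstruction — 11 → {12, 14}, …, 16 → {*C. weissi*,
*C. tianzhuensis*} — fixed unambiguously by the terminal species, and
every repair is a record in `key_errata()`. Two conflicts are *data*
conflicts and are deliberately not repaired, because repairing them
would require inventing unpublished means:

* **E4** — couplet 6 demands mean cyst width ≤ 325 µm for *C. solani*,
  whose tabulated range 204–505 µm has midpoint 354.5; its own row
  dead-ends, and the audit reports MISROUTED with the erratum id.
* **E7** — couplet 1 tests mean L/W ≥ 2; *C. torreyanae*'s range
  1.4–2.9 has midpoint 2.15 and is routed to *C. estonica*.

The shipped audit is therefore: 14 species CONSISTENT, *C. cacti*
AMBIGUOUS (couplet 7 tests the b ratio, which the matrix does not
tabulate, and a straddling fenestral diameter — both leads stay open
and *C. milleri* is reached as well), and the two documented MISROUTED
findings above. Couplet 14's "DGO = 4.5–5.6 µm" against the new
species' published 4.0–6.5 µm is evaluated as a range test with
ambiguity allowed (E3); whether a mean test was intended is unknowable.

### What the key cannot do

Because several mean thresholds fall *inside* published ranges, an
individual specimen measured honestly within its species' ranges can
misroute (a *C. rosae* cyst with L/W 2.05 keys to *C. estonica*) or
dead-end (a *C. tianzhuensis* J2 with DGO 4.2 µm dies at couplet 14).
The test suite asserts these counterexamples as documented behavior.
This is a property of the printed key, not of the engine — and it is
the reason the polyclave identifier below, not the key, is the
recommended tool for single specimens.

## Polyclave identification

Similarity is a containment coefficient: for an observed interval *o*
against a reference range *r*, |*o* ∩ *r*|/|*o*|; a point observation
scores 1 inside the range and decays linearly at rate 1/width(*r*)
outside, clipped at 0. Containment (not Jaccard) because taxonomic
ranges are envelopes and specimens are samples: a precise specimen
inside a broad range is a perfect match. Categoricals score 1/0;
unknown reference cells are skipped and counted (`n_skipped_unknown`),
not penalized — `–` is missing data. The aggregate is the unweighted
mean over scored characters (the literature gives no character
weights; a weighting hook exists but defaults off), ties break
alphabetically, and `n_used` is reported so sparse matches are visibly
weak.

The differential-diagnosis report classifies shared characters as
disjoint, low-overlap (overlap < 25% of the smaller range — the
default is chosen so that the marginal fenestral overlap 20–32 vs
31–36 µm between the new species and *C. thornei* is still flagged),
overlapping, or categorical-differs/same. The published claim that the
new species has a "smaller" cyst L/W than *C. weissi* (1.1–1.6 vs
1.2–2.3) is in fact a broad overlap and is reported as such.

## Sequence divergence

`pairwise_divergence()` counts mismatching columns of pre-aligned
sequences. Default gap policy is pairwise deletion — the conventional
basis for "N bp difference" reports in nematode taxonomy; the
alternative counts residue-vs-gap columns as differences (gap–gap
columns are always excluded). N and IUPAC codes compare as exact
symbols. Identity prints to two decimals (`"8 bp (98.93%)"`).
Reproducing published GenBank-derived percentages would require the
external accessions and the original alignment/trimming pipeline and is
out of scope; the module is validated against brute-force counts on
constructed alignments with known ground truth.

## Simulators and what a green test establishes

`simulate_specimens()` draws numeric characters inside the published
interval — uniformly on the interval shrunk by 0.1% of its width per
end (strict interiority), or truncated-normal with mean at the midpoint
and sd = width/6 (≈ 99.7% of the untruncated mass in range, a mild
default) — and copies categoricals. Generation is deterministic under
the stated seed. The generator emulates *range membership only*: real
populations are not uniform, characters co-vary (large J2s have long
tails), and measurement error is not modelled. A green recovery test
(true species ranked first in ≥ 90% of fully-observed strict-interior
draws) therefore establishes that the published ranges separate the
species under ideal sampling — not field-accuracy of identification
from partial, error-prone measurements.

`simulate_alignment()` plants an exact number of substitutions relative
to sequence 1, giving the divergence suite a hand-countable oracle.

## Numerical choices

* Half-up rounding at printed precision for all comparisons against
  printed values; full precision kept internally.
* Sample sd (n − 1); sd of a single observation reported as 0 (the
  "all values equal" reading of a singleton).
* Kleene conjunction for multi-predicate leads; ambiguous explores both
  branches; traversal terminates because the graph is acyclic (checked)
  and each path visits a couplet at most once (cycle guard).
* Tie-breaks in candidate ranking are alphabetical, making output
  deterministic.
* Zero-width intervals fall back to point rules in overlap scoring; a
  zero-width reference matches only exactly.

## Known limitations

* The key audit is honest rather than clean: two MISROUTED species with
  documented errata (above). Do not "fix" them without a published
  mean.
* Matrix-level mean tests use midpoints; for skewed published ranges
  (e.g. *C. solani* cyst width) the midpoint is a poor mean estimate.
* The polyclave score is a similarity, not a likelihood; no
  probabilistic calibration is implied.
* Divergence arithmetic assumes the input alignment is correct and
  makes no claim of reproducing accession-based published values.
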
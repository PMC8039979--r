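# cactodera_v1 data schema

- `characters.csv` — character registry: `id,label,stage,kind,units,categories`.
  `stage` ∈ {cyst, J2, egg}; `kind` ∈ {numeric, categorical}; `units` is
  `um` or `ratio` for numerics, empty for categoricals; `categories` is a
  `;`-separated enumeration for categoricals.
- `matrix.csv` — one row per taxon. Cells: numeric interval `lo-hi`
  (hyphen on write; hyphen or en dash accepted on read), point value `x`,
  category token, or `-` for unknown (not recorded — distinct from the
  category `absent`). Trailing `citation` and `note` columns are free
  text. JSON matrices (via `write_matrix(..., format = "json")`) embed
  registry, version and full value objects and round-trip all fields.
- `type_morphometrics.csv` — type-population `mean/sd/lo/hi/n` per
  character (holotype column where published). Lengths in µm.
- `key.json` — decision graph: `root` couplet id and `couplets[]`, each
  with integer `id` and exactly two `leads`. A lead is a conjunction of
  `predicates` (`character`, `relation` ∈ {lt, le, gt, ge, eq-category,
  in-range}, `threshold` (number, [lo, hi], or token), `basis` ∈ {mean,
  range}) and an `outcome` (`{"taxon": name}` or `{"couplet": id}`).
- `key_errata.json` — list of `{id, kind, where, printed, interpretation,
  note}` records: graph repairs of the printed key's garbled lead
  numbering, and data conflicts that are reported (not repaired) by the
  audit.
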
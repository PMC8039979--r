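[
  {
    "id": "E1",
    "kind": "graph-repair",
    "where": "couplet 11",
    "printed": "Mean J2s tail length < 40 um ... 11 (self-reference)",
    "interpretation": "first lead repaired to point to couplet 12, second lead to couplet 14",
    "note": "the smooth-eggshell subtree splits into C. amaranthi/C. torreyanae/C. salina (short tail) vs C. acnidae/C. radicale/C. weissi/C. tianzhuensis (long tail); the printed target numbers are typeset wrongly but the species membership fixes the structure"
  },
  {
    "id": "E2",
    "kind": "graph-repair",
    "where": "couplets 11-16",
    "printed": "lead target numbering after couplet 10 cannot be read literally",
    "interpretation": "the bundled graph is a reconstruction: 11 -> {12, 14}, 12 -> {C. amaranthi, 13}, 13 -> {C. torreyanae, C. salina}, 14 -> {15, C. acnidae}, 15 -> {16, C. radicale}, 16 -> {C. weissi, C. tianzhuensis}",
    "note": "labelled as reconstruction; every terminal species matches the printed key"
  },
  {
    "id": "E3",
    "kind": "data-conflict",
    "where": "couplet 14, first lead",
    "printed": "DGO = 4.5-5.6 um",
    "interpretation": "evaluated as a range test with ambiguity allowed",
    "note": "C. tianzhuensis DGO spans 4.0-6.5 um, which straddles 4.5-5.6; whether a mean test was intended is unknowable, so the lead evaluates to ambiguous for that row and both leads are explored"
  },
  {
    "id": "E4",
    "kind": "data-conflict",
    "where": "couplet 6, second lead",
    "printed": "mean cyst width <= 325 um ... C. solani",
    "interpretation": "under the midpoint proxy for untabulated means, C. solani's own comparative-matrix row (cyst width 204-505, midpoint 354.5) fails this lead and the row dead-ends",
    "note": "the original-description mean presumably satisfies the printed bound, but only the range is tabulated; the audit reports C. solani as MISROUTED (dead-end) with this erratum id rather than silently repairing the key"
  },
  {
    "id": "E7",
    "kind": "data-conflict",
    "where": "couplet 1",
    "printed": "Cyst generally two times or more longer than wide, mean L/W ratio = 2.3 ... C. estonica / mean L/W ratio = 1.1-1.8 ... 2",
    "interpretation": "under the midpoint proxy for untabulated means, C. torreyanae's comparative-matrix L/W range 1.4-2.9 (midpoint 2.15) satisfies the mean >= 2 lead and is routed to C. estonica instead of couplet 2",
    "note": "the original-description mean presumably lies in the printed 1.1-1.8 band, but only the range is tabulated; the audit reports C. torreyanae as MISROUTED with this erratum id rather than silently repairing the key"
  },
  {
    "id": "E5",
    "kind": "spelling",
    "where": "diagnosis text",
    "printed": "C. wessi",
    "interpretation": "alias of C. weissi",
    "note": "the comparative matrix and the key both spell C. weissi; name resolution accepts either"
  },
  {
    "id": "E6",
    "kind": "note",
    "where": "couplet 4, first lead",
    "printed": "fenestral diam. = 23-41 um ... C. thornei",
    "interpretation": "no conflict: the comparative matrix gives C. thornei fenestral diameter 31-36 um, contained in 23-41",
    "note": "recorded because the wide printed envelope admits other species' fenestrae; the couplet still separates on tail and hyaline lengths"
  }
]
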
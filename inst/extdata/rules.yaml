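# Subfamily rule cascade for plant MIP/aquaporin classification.
#
# Rules are evaluated top-down; the first rule whose `any` block matches wins.
# A clause (one entry under `any`) is an AND over profile fields; each field
# lists the allowed residues/motifs, where a trailing "*" means prefix match.
# Fields: h2 h5 le1 le2 (ar/R filter), npa_lb npa_le (NPA motifs),
# p1..p5 (Froger positions).
#
# Order is part of the contract: PIP must precede TIP (both are Y/W-free vs
# Y/W-bearing at P4/P5), and TIP must precede the P4==Y catch-all for SIP.
cascade:
  - label: PIP
    any:
      - {h2: ["F"], h5: ["H"], le1: ["T"], le2: ["R"]}
  - label: NIP
    any:
      - {p5: ["I", "L", "M"]}
  - label: XIP
    any:
      - {p2: ["C"]}
      - {npa_lb: ["S*", "NPV", "NPI"]}
  - label: TIP
    any:
      - {p4: ["Y"], h2: ["H", "N"]}
  - label: SIP
    any:
      - {p4: ["Y"]}

# Subgroup rules, applied after subfamily assignment. `missing_ok: true`
# lets a clause match an incomplete profile when every observed field agrees
# (at least one field must be observed); used for truncated XIPs that retain
# only part of the ar/R filter.
subgroups:
  XIP:
    missing_ok: true
    rules:
      - label: XIP1
        any:
          - {h2: ["V"], h5: ["F"], le1: ["V"], le2: ["R"]}
      - label: XIP2
        any:
          - {h2: ["I"], h5: ["F"], le1: ["V"], le2: ["R"]}
      - label: XIP3
        any:
          - {h2: ["V"], h5: ["Y"], le1: ["A"], le2: ["R"]}
  NIP:
    missing_ok: false
    rules:
      - label: NIP I
        any:
          - {h2: ["W"], h5: ["V", "A"], le1: ["A"], le2: ["R"]}
      - label: NIP III
        any:
          - {h2: ["G"], h5: ["S"], le1: ["G"], le2: ["R"]}
      - label: NIP II
        any:
          - {npa_lb: ["NPS", "NPV"]}
          - {npa_le: ["NPS", "NPV"]}
          - {h2: ["A", "T"]}
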
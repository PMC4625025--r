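# mipannot

Annotation and functional prediction for plant aquaporin (MIP) gene
families.

Aquaporins — major intrinsic proteins (MIPs) — are channel proteins that
passively transport water and small solutes (glycerol, urea, boric acid,
silicic acid, NH₃, CO₂, H₂O₂) across membranes. Plant genomes carry large
MIP families organised into subfamilies (PIP, TIP, NIP, SIP, XIP), and a
handful of residues govern what each channel conducts:

- the **dual NPA motifs** at the N-termini of the two half-helices in
  loops LB and LE (variants such as NPS, NPV, SPT occur in NIPs, XIPs and
  SIPs);
- the **aromatic/arginine (ar/R) selectivity filter** — four residues
  (H2, H5, LE1, LE2) forming the narrowest pore constriction;
- **Froger's positions** P1–P5, discriminating glycerol-transporting
  aquaglyceroporins (GlpF-like: aromatic P1, acidic P2, basic P3, proline
  P4, non-aromatic P5) from water-selective channels (AqpZ-like);
- nine **specificity-determining positions** (SDP1–SDP9) per non-aqua
  substrate, each with an allowed-residue set; a profile matching every
  set is a *typical* transporter of that substrate, a single substitution
  flags a *novel* candidate.

`mipannot` turns these observations into a reproducible pipeline for
anyone annotating an MIP family in a newly sequenced plant genome:
global alignment of each protein to a reference template and read-off of
the diagnostic residues, a transparent rule-cascade classifier into the
five subfamilies (plus NIP I/II/III and XIP1–3 subgroups), substrate
prediction by SDP rule matching with novel-variant flagging, gene
exon–intron statistics, sequence-derived molecular weight and
isoelectric point, and RPKM-based tissue expression summaries. A
synthetic-data generator with known ground truth makes every stage
testable offline. The package ships the castor bean (*Ricinus communis*)
family — 37 proteins across the five subfamilies — as plain-text
fixtures.

All user-facing functions take data frames and return tibbles, so
pipelines compose with the pipe.

## Worked example

Classify the packaged castor bean family and summarise it:

```r
library(mipannot)
library(dplyr)

rep <- family_report()   # packaged fixtures by default
rep$subfamily_counts
#> # A tibble: 5 × 2
#>   subfamily     n
#>   <chr>     <int>
#> 1 NIP           8
#> 2 PIP          10
#> 3 SIP           4
#> 4 TIP           9
#> 5 XIP           6

tidy(rep$summary) |>
  select(subfamily, n, pi_mean, gene_len_min, gene_len_max)
#> # A tibble: 5 × 5
#>   subfamily     n pi_mean gene_len_min gene_len_max
#> 1 NIP           8    8.44         1258         4934
#> 2 PIP          10    7.89         1185         2665
#> 3 SIP           4    9.79          705         4822
#> 4 TIP           9    5.63          871         1300
#> 5 XIP           6    7.63          727         1827
```

The census (10 PIPs, 9 TIPs, 8 NIPs, 6 XIPs, 4 SIPs, 37 in total), the
subfamily mean pI values and the gene-span extrema (705–4934 bp) are the
family's published characteristics, recomputed here from the packaged
tables by the rule cascade and the summary statistics.

Substrate prediction for one NIP:

```r
obs   <- readr::read_tsv(mip_fixture("table3_profiles.tsv"),
                         col_types = readr::cols(.default = "c"))
rules <- load_substrate_rules(mip_fixture("table3_rules.tsv"))
match_sdp_table(filter(obs, protein_id == "RcNIP5;1"), rules) |>
  select(-deviations)
#> # A tibble: 3 × 5
#>   substrate  protein_id category n_deviations n_missing
#> 1 boric acid RcNIP5;1   TYPICAL             0         0
#> 2 H2O2       RcNIP5;1   TYPICAL             0         0
#> 3 urea       RcNIP5;1   TYPICAL             0         0
```

RcNIP5;1 matches the typical boric acid, H₂O₂ and urea transporter SDP
sets — the basis for calling it a candidate transporter of all three.

Sequence-level annotation starts from FASTA instead:

```r
fam <- gen_family(n_per_subfamily = 2, mutation_rate = 0.2, seed = 1)
out <- annotate_fasta(fam$seqs)   # align, extract, classify, predict
all(out$classification$subfamily == fam$truth$subfamily)
#> [1] TRUE
```

## Fixtures and configuration

`mip_fixture()` lists the packaged plain-text data: the castor bean
gene-model and diagnostic-profile tables, SDP rule and observation
tables, a synthetic reference template with its named diagnostic
positions (`positions_synthetic.tsv`), and the classification cascade
(`rules.yaml`). The template, position table and rule cascade are
configuration — any curated replacement with the same schema can be
passed to `align_to_template()`, `extract_profile()` and
`classify_profiles()`.
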
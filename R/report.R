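#' Annotate a protein FASTA end to end
#'
#' The full annotation pipeline over a FASTA of candidate MIP proteins:
#' global alignment to the reference template, diagnostic-residue
#' extraction, subfamily/subgroup classification, NPA typing, Froger
#' water-vs-glycerol calling, SDP substrate prediction and phosphosite
#' flagging. Deterministic given identical inputs and configuration.
#'
#' @param fasta path to a protein FASTA, or a sequence tibble from
#'   [read_fasta()].
#' @param template,positions reference template and position table (see
#'   [default_template()]).
#' @param rules classification cascade (see [load_rules()]).
#' @param substrate_rules substrate rule tibble (see
#'   [load_substrate_rules()]); the packaged rule set by default.
#' @param out_dir optional directory; when given, `classification.tsv`,
#'   `substrates.tsv` and `profiles.tsv` are written there.
#' @inheritParams match_sdp
#' @return a list of tibbles: `profiles` (extracted diagnostic residues),
#'   `classification` (id, subfamily, subgroup, fired rule, Froger call,
#'   NPA types, ar/R string, phosphosite flags), `substrates` (one row
#'   per protein and substrate).
#' @export
annotate_fasta <- function(fasta, template = default_template(),
                           positions = default_positions(),
                           rules = default_rules(),
                           substrate_rules = NULL,
                           max_novel_deviations = 1,
                           out_dir = NULL) {
  seqs <- if (is.data.frame(fasta)) fasta else read_fasta(fasta)
  if (is.null(substrate_rules)) {
    substrate_rules <- load_substrate_rules(mip_fixture("table3_rules.tsv"))
  }
  maps <- purrr::map(seq_len(nrow(seqs)), function(i) {
    align_to_template(seqs[i, ], template)
  })
  profiles <- purrr::map(maps, extract_profile, positions = positions) |>
    bind_rows()
  classified <- classify_profiles(profiles, rules)
  extras <- purrr::map(seq_len(nrow(classified)), function(i) {
    row <- classified[i, ]
    fr <- froger_class(row)
    np <- npa_type(row)
    ph <- flag_phosphosites(maps[[i]], positions)
    tibble(froger_call = fr$call,
           npa_lb_type = np[["lb"]], npa_le_type = np[["le"]],
           arr = arr_report(row)$arr,
           phos_conserved = paste(ph$site[ph$conserved], collapse = ","))
  }) |>
    bind_rows()
  classification <- bind_cols(
    classified[c("protein_id", "subfamily", "subgroup", "fired_rule")],
    extras
  )
  substrates <- purrr::map(seq_len(nrow(classified)), function(i) {
    predict_substrates(classified[i, ], substrate_rules,
                       max_novel_deviations = max_novel_deviations) |>
      mutate(protein_id = classified$protein_id[i], .before = 1)
  }) |>
    bind_rows()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(classification,
                     file.path(out_dir, "classification.tsv"))
    readr::write_tsv(select(substrates, -"deviations"),
                     file.path(out_dir, "substrates.tsv"))
    readr::write_tsv(profiles, file.path(out_dir, "profiles.tsv"))
  }
  list(profiles = profiles, classification = classification,
       substrates = substrates)
}

#' Family census report from profile and gene-model tables
#'
#' Profile-only pipeline over tabular inputs (no sequences needed): rule
#' cascade classification plus the per-subfamily and global statistics of
#' [family_summary()]. Defaults to the packaged castor bean fixtures.
#'
#' @param profiles_path profile TSV (see [load_profiles()]).
#' @param gene_models_path gene-model TSV or GFF3
#'   (see [load_gene_models()]).
#' @param rules classification cascade.
#' @return a list: `classification` (classified profile tibble),
#'   `subfamily_counts` (tibble subfamily/n), `summary`
#'   (a [family_summary()] object).
#' @export
family_report <- function(profiles_path = mip_fixture("table2.tsv"),
                          gene_models_path = mip_fixture("table1.tsv"),
                          rules = default_rules()) {
  profiles <- load_profiles(profiles_path)
  genes <- load_gene_models(gene_models_path)
  classified <- classify_profiles(profiles, rules)
  counts <- count(classified, .data$subfamily, name = "n")
  list(classification = classified,
       subfamily_counts = counts,
       summary = family_summary(classified, genes))
}
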
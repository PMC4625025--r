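#' Read protein sequences from a FASTA file
#'
#' Reads amino-acid FASTA into a tibble with one row per record. Residues are
#' upper-cased; trailing translation stops (`*`) are stripped with a warning.
#' Sequences may contain the 20 standard residues plus `X`.
#'
#' @param path FASTA file.
#' @return a tibble with columns `id`, `description`, `residues`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence id '%s' in %s",
                  ids[anyDuplicated(ids)], path))
  }
  residues <- toupper(as.character(set))
  if (any(grepl("\\*", residues))) {
    warn("stripping '*' stop characters from sequences")
    residues <- gsub("\\*", "", residues)
  }
  if (any(grepl("[-.]", residues))) {
    abort("gap characters are not allowed in input sequences")
  }
  if (any(nchar(residues) < 1)) abort("zero-length sequence after cleanup")
  bad <- !grepl(sprintf("^[%sX]+$", paste(AA_STANDARD, collapse = "")),
                residues)
  if (any(bad)) {
    abort(sprintf("sequence '%s' contains non-amino-acid characters",
                  ids[which(bad)[1]]))
  }
  tibble(id = unname(ids), description = unname(desc),
         residues = unname(residues))
}

#' Write protein sequences to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` restores `x`,
#' and writing the result of [read_fasta()] reproduces the file byte for
#' byte (60-column wrapping).
#'
#' @param seqs tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param path output file.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  header <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  lines <- purrr::map2(header, seqs$residues, function(h, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Load diagnostic-residue profiles from a table
#'
#' Reads a TSV of per-protein diagnostic features: the ar/R selectivity
#' filter (`h2`, `h5`, `le1`, `le2`), the two NPA motifs (`npa_lb`,
#' `npa_le`), Froger's positions (`p1`..`p5`) and, optionally,
#' specificity-determining positions (`sdp1`..`sdp9`), protein length,
#' molecular weight, isoelectric point and pass-through localization
#' annotations. `-` encodes an unobserved value and is read as `NA`.
#'
#' The packaged castor bean fixture is available as
#' `load_profiles(mip_fixture("table2.tsv"))`.
#'
#' @param path TSV file.
#' @return a tibble with one row per protein.
#' @export
load_profiles <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = character())
  mandatory <- c("protein_id", ARR_FIELDS, "npa_lb", "npa_le", FROGER_FIELDS)
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0) {
    abort(sprintf("profile table %s lacks mandatory column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) return(profile_tibble(df))
  df <- mutate(df, across(-"protein_id", ~ dplyr::na_if(.x, "-")))
  res_cols <- intersect(c(ARR_FIELDS, FROGER_FIELDS, SDP_FIELDS), names(df))
  for (col in res_cols) {
    vals <- df[[col]]
    bad <- !is.na(vals) & !(vals %in% AA_STANDARD)
    if (any(bad)) {
      abort(sprintf("unknown amino-acid letter '%s' at row %d, column '%s'",
                    vals[which(bad)[1]], which(bad)[1], col))
    }
  }
  for (col in intersect(c("npa_lb", "npa_le"), names(df))) {
    vals <- df[[col]]
    bad <- !is.na(vals) & nchar(vals) != 3
    if (any(bad)) {
      abort(sprintf("NPA motif must be 3 letters at row %d, column '%s'",
                    which(bad)[1], col))
    }
  }
  profile_tibble(df)
}

# coerce the numeric metadata columns of a profile table, preserving order
profile_tibble <- function(df) {
  num_cols <- intersect(c("length_aa", "mw_kda", "pi", "tm"), names(df))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  if ("pi" %in% names(df) && any(!is.na(df$pi) &
                                 (df$pi <= 0 | df$pi >= 14))) {
    abort("pI values must lie strictly between 0 and 14")
  }
  as_tibble(df)
}

#' Load gene models from a tabular file or GFF3
#'
#' Accepts either a simple TSV (columns `gene_id`, `scaffold`, `strand`,
#' `gene_len`, `cds_len`, `intron_count`, the shape of a family census
#' table) or a GFF3 with `gene`, `exon` and `CDS` features, from which the
#' same per-locus quantities are computed (gene span from the `gene`
#' feature, CDS length as the sum of CDS widths, intron count as number of
#' exons minus one). Coordinates are 1-based closed intervals.
#'
#' The packaged castor bean fixture is
#' `load_gene_models(mip_fixture("table1.tsv"))`; `gene_len` there is the
#' start-to-stop-codon span, so `gene_len - cds_len` is the total intron
#' length.
#'
#' @param path TSV or GFF3 file.
#' @return a tibble with columns `gene_id`, `scaffold`, `strand`,
#'   `gene_len`, `cds_len`, `intron_count`.
#' @export
load_gene_models <- function(path) {
  first <- readLines(path, n = 1)
  df <- if (grepl("^##gff", first) || grepl("\\.gff3?$", path)) {
    gene_models_from_gff3(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(
      gene_id = "c", scaffold = "c", strand = "c",
      gene_len = "i", cds_len = "i", intron_count = "i"
    ))
  }
  validate_gene_models(df)
}

gene_models_from_gff3 <- function(path) {
  cols <- c("seqid", "source", "type", "start", "end",
            "score", "strand", "phase", "attributes")
  gff <- readr::read_tsv(path, comment = "#", col_names = cols,
                         col_types = "ccciicccc")
  attr_field <- function(x, key) {
    m <- stringr::str_match(x, sprintf("(?:^|;)\\s*%s=([^;]+)", key))[, 2]
    m
  }
  genes <- filter(gff, .data$type == "gene")
  genes$gene_id <- attr_field(genes$attributes, "ID")
  feat <- filter(gff, .data$type %in% c("exon", "CDS"))
  feat$gene_id <- attr_field(feat$attributes, "Parent")
  per_gene <- feat |>
    group_by(.data$gene_id, .data$type) |>
    summarise(len = sum(.data$end - .data$start + 1), nfeat = n(),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "type", values_from = c("len", "nfeat"))
  out <- genes |>
    mutate(gene_len = .data$end - .data$start + 1L) |>
    select("gene_id", scaffold = "seqid", "strand", "gene_len") |>
    left_join(per_gene, by = "gene_id") |>
    mutate(cds_len = as.integer(.data$len_CDS),
           intron_count = as.integer(.data$nfeat_exon - 1L)) |>
    select("gene_id", "scaffold", "strand", "gene_len", "cds_len",
           "intron_count")
  out
}

validate_gene_models <- function(df) {
  needed <- c("gene_id", "gene_len", "cds_len", "intron_count")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(sprintf("gene model table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(df$gene_len < 0 | df$cds_len < 0)) {
    abort("negative gene or CDS length")
  }
  if (any(df$cds_len < 3)) abort("cds_len must be at least 3")
  bad <- df$cds_len > df$gene_len
  if (any(bad)) {
    abort(sprintf("cds_len exceeds gene_len for %s",
                  df$gene_id[which(bad)[1]]))
  }
  if (any(df$intron_count < 0)) abort("negative intron count")
  as_tibble(df)
}

#' Load substrate specificity rules
#'
#' Reads a TSV of substrate rules, one row per substrate, with nine
#' slash-separated allowed-residue sets at the specificity-determining
#' positions SDP1..SDP9 (e.g. `T/V` at SDP1 of the boric-acid rule). The
#' packaged castor bean rule set
#' (`load_substrate_rules(mip_fixture("table3_rules.tsv"))`) covers NH3,
#' boric acid, CO2, H2O2, silicic acid and urea.
#'
#' @param path TSV file with columns `substrate`, `sdp1`..`sdp9`.
#' @return a tibble with column `substrate` and list-columns `sdp1`..`sdp9`
#'   holding character vectors of allowed residues.
#' @export
load_substrate_rules <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  missing <- setdiff(c("substrate", SDP_FIELDS), names(df))
  if (length(missing) > 0) {
    abort(sprintf("rule table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  for (col in SDP_FIELDS) {
    sets <- stringr::str_split(df[[col]], stringr::fixed("/"))
    empty <- purrr::map_lgl(sets, ~ length(.x) == 0 || any(!nzchar(.x)))
    if (any(empty) || anyNA(df[[col]])) {
      abort(sprintf("empty allowed-residue set at row %d, column '%s'",
                    which(empty | is.na(df[[col]]))[1], col))
    }
    purrr::walk(sets, assert_residues, context = col, allow_na = FALSE)
    df[[col]] <- sets
  }
  as_tibble(df)
}

#' Extract one substrate rule's allowed sets
#'
#' @param rules a rules tibble from [load_substrate_rules()].
#' @param substrate substrate name.
#' @return a named list `SDP1`..`SDP9` of allowed residue vectors.
#' @export
rule_allowed <- function(rules, substrate) {
  row <- rules[rules$substrate == substrate, ]
  if (nrow(row) != 1) abort(sprintf("no unique rule for '%s'", substrate))
  setNames(purrr::map(SDP_FIELDS, ~ row[[.x]][[1]]), toupper(SDP_FIELDS))
}
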
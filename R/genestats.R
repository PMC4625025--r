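# average residue masses (Da) and water; ionizable-group pKa values
# (EMBOSS-style), both documented in the methods vignette
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153
PKA_POSITIVE <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEGATIVE <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

#' Per-gene structure metrics
#'
#' Adds intron bookkeeping to a gene-model table. `gene_len` is the
#' start-to-stop-codon span (UTRs excluded), so the total intron length is
#' `gene_len - cds_len`; the mean intron length is that total divided by
#' the intron count (NA for intronless genes).
#'
#' @param gene_models a tibble from [load_gene_models()].
#' @return the input with `total_intron_len` and `mean_intron_len`
#'   appended.
#' @export
gene_metrics <- function(gene_models) {
  validate_gene_models(gene_models)
  mutate(gene_models,
         total_intron_len = .data$gene_len - .data$cds_len,
         mean_intron_len = ifelse(.data$intron_count > 0,
                                  .data$total_intron_len /
                                    .data$intron_count, NA_real_))
}

#' Per-subfamily and family-wide summary statistics
#'
#' Summarises protein properties (length, molecular weight, isoelectric
#' point) and gene architecture (span, intron counts) per subfamily and
#' across the family. Mean pI is presented rounded half away from zero to
#' two decimals; everything else is exact. The family-wide mean intron
#' length averages per intron (total intron length over all genes divided
#' by total intron count).
#'
#' @param profiles a profile tibble with `protein_id`, `length_aa`,
#'   `mw_kda`, `pi`.
#' @param gene_models a gene-model tibble whose `gene_id`s match the
#'   profile `protein_id`s.
#' @param labels optional tibble (`protein_id`, `subfamily`); when absent
#'   the profiles' own `subfamily` column is used.
#' @return an object of class `mip_family_summary`: a list with
#'   `per_subfamily` and `global` tibbles. `tidy()` returns the former,
#'   `glance()` the latter.
#' @examples
#' profiles <- load_profiles(mip_fixture("table2.tsv")) |> classify_profiles()
#' genes <- load_gene_models(mip_fixture("table1.tsv"))
#' family_summary(profiles, genes)
#' @export
family_summary <- function(profiles, gene_models, labels = NULL) {
  if (!is.null(labels)) {
    profiles <- profiles |>
      select(-dplyr::any_of("subfamily")) |>
      left_join(labels, by = "protein_id")
  }
  if (!"subfamily" %in% names(profiles) || anyNA(profiles$subfamily)) {
    abort("every profile needs a subfamily label (run classify_profiles)")
  }
  orphans <- c(setdiff(profiles$protein_id, gene_models$gene_id),
               setdiff(gene_models$gene_id, profiles$protein_id))
  if (length(orphans) > 0) {
    abort(sprintf("profile/gene id sets differ; orphans: %s",
                  paste(orphans, collapse = ", ")))
  }
  joined <- left_join(profiles,
                      gene_metrics(gene_models),
                      by = c(protein_id = "gene_id"))
  per <- joined |>
    group_by(.data$subfamily) |>
    summarise(
      n = n(),
      length_aa_min = min(.data$length_aa),
      length_aa_max = max(.data$length_aa),
      mw_min = min(.data$mw_kda), mw_max = max(.data$mw_kda),
      pi_mean = round_half_up(mean(.data$pi), 2),
      gene_len_min = min(.data$gene_len),
      gene_len_max = max(.data$gene_len),
      intron_counts = list(table(.data$intron_count)),
      .groups = "drop"
    )
  global <- summarise(
    joined,
    n_genes = n(),
    length_aa_max = max(.data$length_aa),
    gene_len_min = min(.data$gene_len),
    gene_len_max = max(.data$gene_len),
    mean_intron_len = sum(.data$total_intron_len) /
      sum(.data$intron_count)
  )
  structure(list(per_subfamily = per, global = global),
            class = "mip_family_summary")
}

#' @export
print.mip_family_summary <- function(x, ...) {
  cat("<mip_family_summary>\n")
  print(x$per_subfamily)
  print(x$global)
  invisible(x)
}

#' @rdname family_summary
#' @param x a `mip_family_summary`.
#' @param ... unused.
#' @method tidy mip_family_summary
#' @export
tidy.mip_family_summary <- function(x, ...) x$per_subfamily

#' @rdname family_summary
#' @method glance mip_family_summary
#' @export
glance.mip_family_summary <- function(x, ...) x$global

#' Molecular weight and isoelectric point from sequence
#'
#' Molecular weight is the sum of average residue masses plus one water,
#' in kDa. The isoelectric point is the root of the peptide net-charge
#' equation (Henderson-Hasselbalch sums over the termini and the
#' ionizable side chains D, E, C, Y, H, K, R with the package's pKa
#' table), found by bisection on pH 0..14 to within 1e-4.
#'
#' @param seqs a sequence tibble from [read_fasta()] (standard residues
#'   only; `X` is an error here).
#' @return a tibble with `id`, `length_aa`, `mw_kda`, `pi`.
#' @export
protein_properties <- function(seqs) {
  purrr::map(seq_len(nrow(seqs)), function(i) {
    chars <- strsplit(seqs$residues[i], "")[[1]]
    assert_residues(chars, sprintf("sequence '%s'", seqs$id[i]),
                    allow_na = FALSE, allow_x = FALSE)
    tibble(id = seqs$id[i],
           length_aa = length(chars),
           mw_kda = (sum(AA_AVG_MASS[chars]) + WATER_MASS) / 1000,
           pi = isoelectric_point(chars))
  }) |>
    bind_rows()
}

#' Net charge of a peptide at a given pH
#'
#' @param chars character vector of residues.
#' @param ph pH value(s).
#' @return net charge (same length as `ph`).
#' @export
peptide_charge <- function(chars, ph) {
  counts <- table(factor(chars, levels = AA_STANDARD))
  vapply(ph, function(p) {
    pos <- 1 / (1 + 10^(p - PKA_POSITIVE["Nterm"])) +
      sum(counts[c("K", "R", "H")] /
            (1 + 10^(p - PKA_POSITIVE[c("K", "R", "H")])))
    neg <- 1 / (1 + 10^(PKA_NEGATIVE["Cterm"] - p)) +
      sum(counts[c("D", "E", "C", "Y")] /
            (1 + 10^(PKA_NEGATIVE[c("D", "E", "C", "Y")] - p)))
    pos - neg
  }, numeric(1))
}

isoelectric_point <- function(chars, tol = 1e-4) {
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (peptide_charge(chars, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
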
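# canonical diagnostic signatures planted per subfamily: the ar/R filter,
# NPA motifs, Froger positions and one representative SDP string each,
# mirroring the canonical members of the five plant subfamilies
SUBFAMILY_SIGNATURES <- list(
  PIP = list(arr = c("F", "H", "T", "R"), npa = c("NPA", "NPA"),
             froger = c("E", "S", "A", "F", "W"),
             sdp = c("T", "I", "H", "P", "E", "L", "L", "T", "P"),
             phos = c("S", "S")),
  TIP = list(arr = c("H", "I", "A", "V"), npa = c("NPA", "NPA"),
             froger = c("T", "S", "A", "Y", "W"),
             sdp = c("H", "P", "F", "F", "L", "A", "G", "S", "N"),
             phos = c("S", "A")),
  NIP = list(arr = c("W", "V", "A", "R"), npa = c("NPA", "NPA"),
             froger = c("F", "S", "A", "Y", "I"),
             sdp = c("F", "K", "F", "T", "A", "D", "L", "E", "T"),
             phos = c("A", "S")),
  XIP = list(arr = c("V", "F", "V", "R"), npa = c("SPT", "NPA"),
             froger = c("M", "C", "A", "F", "W"),
             sdp = c("A", "G", "L", "V", "S", "H", "F", "V", "P"),
             phos = c("S", "A")),
  SIP = list(arr = c("A", "A", "P", "N"), npa = c("NPA", "NPA"),
             froger = c("Q", "V", "A", "Y", "W"),
             sdp = c("H", "P", "F", "A", "L", "P", "G", "S", "N"),
             phos = c("T", "A"))
)

signature_positions <- function(positions) {
  # every named diagnostic column; these are never mutated
  positions$index
}

planted_residues <- function(sig, positions) {
  plant <- c(
    setNames(sig$arr, c("H2", "H5", "LE1", "LE2")),
    setNames(strsplit(sig$npa[1], "")[[1]], paste0("NPA_LB", 1:3)),
    setNames(strsplit(sig$npa[2], "")[[1]], paste0("NPA_LE", 1:3)),
    setNames(sig$froger, paste0("P", 1:5)),
    setNames(sig$sdp, paste0("SDP", 1:9)),
    setNames(sig$phos, c("PHOS1", "PHOS2"))
  )
  plant[intersect(names(plant), positions$name)]
}

#' Generate a synthetic MIP family with known ground truth
#'
#' Builds `n_per_subfamily` sequences per subfamily on the reference
#' template backbone: the subfamily's diagnostic signature (ar/R filter,
#' NPA motifs, Froger positions, SDPs, phosphosites) is planted at the
#' named template coordinates, and every non-diagnostic position is
#' mutated independently with probability `mutation_rate` to a uniformly
#' drawn different residue. Diagnostic columns are never mutated, so a
#' correct template mapping recovers the planted profile exactly.
#' Regeneration with the same seed is byte-identical.
#'
#' @param n_per_subfamily sequences per subfamily.
#' @param mutation_rate per-site background mutation probability, in
#'   \[0, 0.5).
#' @param seed integer seed for the generator stream.
#' @param template,positions reference template and position table.
#' @return a list with `seqs` (sequence tibble) and `truth` (tibble:
#'   `id`, `subfamily`, planted residues per diagnostic field, `seed`).
#' @export
gen_family <- function(n_per_subfamily = 2, mutation_rate = 0.1,
                       seed = 1, template = default_template(),
                       positions = default_positions()) {
  if (mutation_rate < 0 || mutation_rate >= 0.5) {
    abort("mutation_rate must lie in [0, 0.5)")
  }
  backbone <- strsplit(template$residues, "")[[1]]
  keep <- signature_positions(positions)
  free <- setdiff(seq_along(backbone), keep)
  withr::with_seed(seed, {
    rows <- purrr::map(SUBFAMILIES, function(fam) {
      sig <- SUBFAMILY_SIGNATURES[[fam]]
      plant <- planted_residues(sig, positions)
      purrr::map(seq_len(n_per_subfamily), function(k) {
        s <- backbone
        s[positions$index[match(names(plant), positions$name)]] <- plant
        mut <- free[runif(length(free)) < mutation_rate]
        s[mut] <- purrr::map_chr(s[mut], function(old) {
          sample(setdiff(AA_STANDARD, old), 1)
        })
        list(id = sprintf("SYN_%s_%d", fam, k), subfamily = fam,
             residues = paste(s, collapse = ""))
      })
    })
    rows <- purrr::flatten(rows)
    seqs <- tibble(
      id = purrr::map_chr(rows, "id"),
      description = sprintf("synthetic %s family member",
                            purrr::map_chr(rows, "subfamily")),
      residues = purrr::map_chr(rows, "residues")
    )
    truth <- tibble(
      id = seqs$id,
      subfamily = purrr::map_chr(rows, "subfamily"),
      arr = purrr::map_chr(rows, function(r)
        paste(SUBFAMILY_SIGNATURES[[r$subfamily]]$arr, collapse = "-")),
      npa_lb = purrr::map_chr(rows, function(r)
        SUBFAMILY_SIGNATURES[[r$subfamily]]$npa[1]),
      npa_le = purrr::map_chr(rows, function(r)
        SUBFAMILY_SIGNATURES[[r$subfamily]]$npa[2]),
      froger = purrr::map_chr(rows, function(r)
        paste(SUBFAMILY_SIGNATURES[[r$subfamily]]$froger, collapse = "-")),
      sdp = purrr::map_chr(rows, function(r)
        paste(SUBFAMILY_SIGNATURES[[r$subfamily]]$sdp, collapse = "-")),
      seed = seed
    )
    list(seqs = seqs, truth = truth)
  })
}

#' Generate synthetic gene models
#'
#' Draws intron counts from an architecture mix (a named probability
#' vector over intron numbers; the default mirrors the packaged family's
#' architecture spectrum) and intron lengths from a shifted lognormal
#' (minimum 46 bp, mean a few hundred bp), then sets
#' `gene_len = cds_len + sum(intron lengths)` so the gene-model
#' invariants hold by construction.
#'
#' @param n number of genes.
#' @param architecture_mix named numeric vector of intron-count
#'   probabilities (names are intron counts).
#' @param seed integer seed.
#' @return a gene-model tibble (as from [load_gene_models()]).
#' @export
gen_gene_models <- function(n,
                            architecture_mix = c("0" = 3, "1" = 5,
                                                 "2" = 10, "3" = 9,
                                                 "4" = 10) / 37,
                            seed = 1) {
  stopifnot(n >= 1, abs(sum(architecture_mix) - 1) < 1e-8)
  withr::with_seed(seed, {
    intron_count <- as.integer(sample(names(architecture_mix), n,
                                      replace = TRUE,
                                      prob = architecture_mix))
    cds_len <- 3L * sample(209:310, n, replace = TRUE)
    intron_total <- purrr::map_int(intron_count, function(k) {
      if (k == 0) return(0L)
      as.integer(sum(46 + round(stats::rlnorm(k, log(250), 0.7))))
    })
    tibble(
      gene_id = sprintf("SYNGENE_%03d", seq_len(n)),
      scaffold = sprintf("scaffold%04d", sample(1000:9999, n,
                                                replace = TRUE)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      gene_len = cds_len + intron_total,
      cds_len = cds_len,
      intron_count = intron_count
    )
  })
}

#' Generate synthetic counts with planted expression structure
#'
#' Draws a gene-by-tissue count matrix with two kinds of planted ground
#' truth: dominant isoforms (a gene taking a fixed share of its
#' subfamily's expected counts in every tissue) and tissue-specific genes
#' (expected counts zero outside one tissue). Counts are
#' negative-binomial around the expected values; `noise = 0` degenerates
#' to the rounded expectations, making planted structure exactly
#' recoverable.
#'
#' @param genes tibble with `gene_id`, `subfamily` and `transcript_len`.
#' @param tissues character vector of tissue names.
#' @param dominance named numeric vector, gene_id -> share of its
#'   subfamily's expected counts (shares must leave room for the other
#'   members; sum per subfamily <= 1).
#' @param specificity named character vector, gene_id -> the single
#'   tissue it is expressed in.
#' @param noise negative-binomial dispersion (variance
#'   `mu + noise * mu^2`); 0 for deterministic counts.
#' @param seed integer seed.
#' @param subfamily_depth expected family counts per subfamily and
#'   tissue.
#' @param lib_size per-tissue library size (total clean reads).
#' @return a list with `es` (an [expression_set()]) and `truth` (list of
#'   the planted `dominance`, `specificity`, `seed`).
#' @export
gen_counts <- function(genes,
                       tissues = c("leaf", "flower", "endosperm_II_III",
                                   "endosperm_V_VI", "seed"),
                       dominance = NULL, specificity = NULL,
                       noise = 0.05, seed = 1,
                       subfamily_depth = 20000, lib_size = 1e6) {
  stopifnot(all(c("gene_id", "subfamily", "transcript_len") %in%
                  names(genes)))
  if (!is.null(dominance)) {
    per <- tapply(dominance, genes$subfamily[match(names(dominance),
                                                   genes$gene_id)], sum)
    if (any(per > 1)) abort("dominance shares sum above 1 in a subfamily")
  }
  withr::with_seed(seed, {
    mu <- matrix(0, nrow(genes), length(tissues),
                 dimnames = list(genes$gene_id, tissues))
    for (fam in unique(genes$subfamily)) {
      members <- genes$gene_id[genes$subfamily == fam]
      dom <- dominance[names(dominance) %in% members]
      rest <- setdiff(members, names(dom))
      rest_share <- (1 - sum(dom)) / max(length(rest), 1)
      share <- c(dom, setNames(rep(rest_share, length(rest)), rest))
      mu[members, ] <- share[members] * subfamily_depth
    }
    for (g in names(specificity)) {
      mu[g, setdiff(tissues, specificity[[g]])] <- 0
    }
    counts <- if (noise > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / noise),
             nrow(mu), ncol(mu), dimnames = dimnames(mu))
    } else {
      round(mu)
    }
    es <- expression_set(
      counts,
      setNames(genes$transcript_len, genes$gene_id),
      setNames(rep(lib_size, length(tissues)), tissues)
    )
    list(es = es,
         truth = list(dominance = dominance, specificity = specificity,
                      expected = mu, seed = seed))
  })
}
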
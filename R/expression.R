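#' Construct a gene-by-tissue expression set
#'
#' A light container for RNA-seq read counts over a gene family: an
#' integer count matrix (genes x tissues), per-gene transcript lengths
#' (bp) and per-tissue library sizes (total clean reads; the library may
#' contain reads outside the family, so column sums need not reach the
#' library size).
#'
#' @param counts matrix of non-negative counts, dimnames gene x tissue.
#' @param transcript_len named numeric vector of transcript lengths (bp).
#' @param lib_size named numeric vector of per-tissue library sizes.
#' @return an object of class `mip_expression_set`.
#' @export
expression_set <- function(counts, transcript_len, lib_size) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  transcript_len <- transcript_len[rownames(counts)]
  lib_size <- lib_size[colnames(counts)]
  if (anyNA(transcript_len) || any(transcript_len <= 0)) {
    abort("every gene needs a positive transcript length")
  }
  if (anyNA(lib_size)) abort("every tissue needs a library size")
  structure(list(counts = counts, transcript_len = transcript_len,
                 lib_size = lib_size),
            class = "mip_expression_set")
}

#' @export
print.mip_expression_set <- function(x, ...) {
  cat(sprintf("<mip_expression_set> %d genes x %d tissues (lib sizes %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(format(x$lib_size, big.mark = ","), collapse = ", ")))
  invisible(x)
}

#' @rdname expression_set
#' @param x a `mip_expression_set`.
#' @param ... unused.
#' @return `tidy()`: a long tibble with `gene_id`, `tissue`, `count`,
#'   `transcript_len`, `lib_size`, `rpkm`.
#' @method tidy mip_expression_set
#' @export
tidy.mip_expression_set <- function(x, ...) {
  r <- rpkm(x)
  as_tibble(as.table(x$counts), .name_repair = "minimal") |>
    setNames(c("gene_id", "tissue", "count")) |>
    mutate(transcript_len = x$transcript_len[.data$gene_id],
           lib_size = x$lib_size[.data$tissue],
           rpkm = r[cbind(.data$gene_id, .data$tissue)])
}

#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `rpkm = counts * 1e9 / (lib_size * transcript_len)`.
#'
#' @param es a [expression_set()].
#' @return a numeric matrix of RPKM values, same shape as the counts.
#' @export
rpkm <- function(es) {
  stopifnot(inherits(es, "mip_expression_set"))
  if (any(es$lib_size <= 0)) abort("library sizes must be positive")
  sweep(sweep(es$counts * 1e9, 2, es$lib_size, "/"),
        1, es$transcript_len, "/")
}

#' Log-transformed expression matrix
#'
#' `log10(rpkm + pseudocount)`, the transform used for expression
#' heatmaps.
#'
#' @param rpkm_mat an RPKM matrix from [rpkm()].
#' @param pseudocount positive offset (default 1, so RPKM 0 maps to 0).
#' @return a matrix of the same shape.
#' @export
log_heatmap_matrix <- function(rpkm_mat, pseudocount = 1) {
  if (pseudocount <= 0) abort("pseudocount must be positive")
  log10(rpkm_mat + pseudocount)
}

#' Quality-filter FASTQ reads
#'
#' Applies the read-cleaning cascade used for expression libraries, in
#' order, each read counted once: (a) trim everything from the first
#' adaptor occurrence onward; a read left empty is removed as
#' adaptor-only; (b) remove reads whose fraction of ambiguous bases (N)
#' strictly exceeds 10%; (c) remove low-quality reads in which strictly
#' more than 50% of bases have Phred quality <= 5. Order of surviving
#' reads is preserved.
#'
#' @param fastq_path input FASTQ.
#' @param adaptor adaptor sequence (exact match); `NULL` disables
#'   trimming.
#' @param out_path optional path for the kept reads (FASTQ).
#' @param phred_offset quality encoding offset (33 for Sanger/Illumina
#'   1.8+).
#' @param max_n_rate,max_low_q_rate,low_q removal thresholds (strict
#'   inequalities).
#' @return a list with `kept` (tibble `id`, `sequence`, `quality`) and
#'   `report` (one-row tibble: `input`, `kept`, `removed_adaptor`,
#'   `removed_n_rate`, `removed_low_quality`).
#' @export
filter_reads <- function(fastq_path, adaptor = NULL, out_path = NULL,
                         phred_offset = 33L, max_n_rate = 0.10,
                         max_low_q_rate = 0.50, low_q = 5L) {
  reads <- tryCatch(
    # the reader emits a benign note about dropped metadata columns
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq_path)),
    error = function(e) {
      abort(sprintf("malformed FASTQ record in %s: %s",
                    fastq_path, conditionMessage(e)))
    })
  seqs <- as.character(reads)
  quals <- as.character(Biostrings::quality(reads))
  ids <- names(reads) %||% as.character(seq_along(reads))
  status <- character(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    q <- quals[i]
    if (!is.null(adaptor)) {
      hit <- regexpr(adaptor, s, fixed = TRUE)
      if (hit > 0) {
        s <- substr(s, 1, hit - 1)
        q <- substr(q, 1, hit - 1)
      }
    }
    seqs[i] <- s
    quals[i] <- q
    n <- nchar(s)
    status[i] <- if (n == 0) {
      "removed_adaptor"
    } else if (stringr::str_count(s, "N") / n > max_n_rate) {
      "removed_n_rate"
    } else if (mean(utf8ToInt(q) - phred_offset <= low_q) > max_low_q_rate) {
      "removed_low_quality"
    } else {
      "kept"
    }
  }
  kept <- tibble(id = ids, sequence = seqs,
                 quality = quals)[status == "kept", ]
  if (!is.null(out_path)) {
    out <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(kept$sequence, kept$id)),
      Biostrings::PhredQuality(kept$quality))
    Biostrings::writeQualityScaledXStringSet(out, out_path)
  }
  report <- tibble(
    input = length(seqs),
    kept = sum(status == "kept"),
    removed_adaptor = sum(status == "removed_adaptor"),
    removed_n_rate = sum(status == "removed_n_rate"),
    removed_low_quality = sum(status == "removed_low_quality")
  )
  list(kept = kept, report = report)
}

#' Tissue-level expression summary
#'
#' Summarises an RPKM matrix the way family expression surveys report it:
#' per tissue, the number of detected genes (RPKM strictly above
#' `detect_threshold`) and per-subfamily RPKM totals; per gene and
#' tissue, the gene's share of its subfamily's RPKM total (shares within
#' a subfamily sum to 1 wherever the total is positive); and per gene,
#' the tissue of maximal expression.
#'
#' @param rpkm_mat an RPKM matrix from [rpkm()].
#' @param labels tibble with `gene_id` and `subfamily` covering every
#'   gene.
#' @param detect_threshold detection cut-off on RPKM (strict; default 0,
#'   i.e. any signal counts as detected).
#' @return a list of tibbles: `detected` (tissue, n_detected),
#'   `subfamily_totals` (tissue, subfamily, total_rpkm), `shares`
#'   (gene_id, tissue, subfamily, rpkm, share), `gene_max_tissue`
#'   (gene_id, tissue, rpkm).
#' @export
expression_summary <- function(rpkm_mat, labels, detect_threshold = 0) {
  missing <- setdiff(rownames(rpkm_mat), labels$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("no subfamily label for gene(s): %s",
                  paste(missing, collapse = ", ")))
  }
  long <- as_tibble(as.table(rpkm_mat), .name_repair = "minimal") |>
    setNames(c("gene_id", "tissue", "rpkm")) |>
    left_join(labels[c("gene_id", "subfamily")], by = "gene_id")
  detected <- long |>
    group_by(.data$tissue) |>
    summarise(n_detected = sum(.data$rpkm > detect_threshold),
              .groups = "drop")
  subfamily_totals <- long |>
    group_by(.data$tissue, .data$subfamily) |>
    summarise(total_rpkm = sum(.data$rpkm), .groups = "drop")
  shares <- long |>
    group_by(.data$tissue, .data$subfamily) |>
    mutate(share = if (sum(.data$rpkm) > 0)
      .data$rpkm / sum(.data$rpkm) else NA_real_) |>
    ungroup() |>
    select("gene_id", "tissue", "subfamily", "rpkm", "share")
  gene_max <- long |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$rpkm), .data$tissue, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("gene_id", "tissue", "rpkm")
  list(detected = detected, subfamily_totals = subfamily_totals,
       shares = shares, gene_max_tissue = gene_max)
}

#' Expression heatmap
#'
#' `log10(RPKM + pseudocount)` heatmap of a family expression set, rows
#' ordered by average-linkage hierarchical clustering on Euclidean
#' distance of the log values.
#'
#' @param es a [expression_set()].
#' @param pseudocount passed to [log_heatmap_matrix()].
#' @return a ggplot object.
#' @export
plot_expression_heatmap <- function(es, pseudocount = 1) {
  m <- log_heatmap_matrix(rpkm(es), pseudocount)
  ord <- if (nrow(m) > 2) {
    stats::hclust(stats::dist(m), method = "average")$order
  } else {
    seq_len(nrow(m))
  }
  long <- as_tibble(as.table(m), .name_repair = "minimal") |>
    setNames(c("gene_id", "tissue", "log10_rpkm")) |>
    mutate(gene_id = factor(.data$gene_id,
                            levels = rownames(m)[ord]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tissue, y = .data$gene_id,
                                     fill = .data$log10_rpkm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "darkgreen", high = "red",
                                 name = "log10(RPKM+1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_expression_heatmap
#' @param object a `mip_expression_set`.
#' @param ... passed on.
#' @method autoplot mip_expression_set
#' @export
autoplot.mip_expression_set <- function(object, ...) {
  plot_expression_heatmap(object, ...)
}
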
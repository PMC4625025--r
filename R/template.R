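#' Packaged synthetic reference template and its diagnostic positions
#'
#' The package ships a synthetic PIP-like reference template (290 residues,
#' canonical diagnostic residues planted at fixed coordinates) together with
#' a position table naming each diagnostic site: the two NPA half-helix
#' motifs (`NPA_LB1..3`, `NPA_LE1..3`), the ar/R filter (`H2`, `H5`, `LE1`,
#' `LE2`), Froger's positions (`P1`..`P5`), the nine specificity-determining
#' positions (`SDP1`..`SDP9`) and two phosphosites (`PHOS1`, `PHOS2`). Real
#' analyses can substitute any curated template plus position table with the
#' same column schema (`name`, `index`, 1-based).
#'
#' @return `default_template()`: a one-row sequence tibble as from
#'   [read_fasta()]. `default_positions()` / `load_positions()`: a tibble
#'   with columns `name` and `index`.
#' @export
default_template <- function() {
  read_fasta(mip_fixture("template_synthetic.fasta"))
}

#' @rdname default_template
#' @export
default_positions <- function() {
  load_positions(mip_fixture("positions_synthetic.tsv"))
}

#' @rdname default_template
#' @param path TSV with columns `name` (unique) and `index` (1-based).
#' @param template_length optional template length to validate indices
#'   against.
#' @export
load_positions <- function(path, template_length = NULL) {
  pos <- readr::read_tsv(path, col_types = readr::cols(name = "c",
                                                       index = "i"))
  if (anyDuplicated(pos$name)) abort("duplicate position names")
  if (any(pos$index < 1)) abort("position indices must be >= 1")
  if (!is.null(template_length) && any(pos$index > template_length)) {
    abort("position index beyond template length")
  }
  pos
}

#' Globally align a query protein to the reference template
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps: a gap of
#' length L costs `gap_open + L * gap_extend`) of one query against the
#' template, returning the gapped pair plus an index map from every
#' template position to the aligned query position (`NA` where the
#' template column is deleted in the query). Named diagnostic positions
#' are then read off the map with [extract_profile()].
#'
#' @param query,template one-row sequence tibbles (see [read_fasta()]) or
#'   named lists with `id` and `residues`.
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @param substitution substitution matrix name understood by Biostrings.
#' @return an object of class `mip_alignment`: a list with `query_id`,
#'   `template_id`, `aligned_query`, `aligned_template`, `score` and
#'   `index_map` (integer vector of template length).
#' @export
align_to_template <- function(query, template = default_template(),
                              gap_open = 10, gap_extend = 0.5,
                              substitution = "BLOSUM62") {
  q <- as_seqrecord(query)
  t <- as_seqrecord(template)
  if (grepl("[-.]", q$residues) || grepl("[-.]", t$residues)) {
    abort("sequences must not contain gap characters")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q$residues), Biostrings::AAString(t$residues),
    type = "global", substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  aq <- as.character(Biostrings::alignedPattern(aln))
  at <- as.character(Biostrings::alignedSubject(aln))
  structure(
    list(query_id = q$id, template_id = t$id,
         aligned_query = aq, aligned_template = at,
         score = Biostrings::score(aln),
         index_map = alignment_index_map(at, aq)),
    class = "mip_alignment"
  )
}

as_seqrecord <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    list(id = x$id, residues = x$residues)
  } else {
    stopifnot(!is.null(x$id), !is.null(x$residues))
    x[c("id", "residues")]
  }
}

# map template index -> query index (NA where template column is gapped in
# the query); strictly increasing over non-NA entries by construction
alignment_index_map <- function(aligned_template, aligned_query) {
  tc <- strsplit(aligned_template, "")[[1]]
  qc <- strsplit(aligned_query, "")[[1]]
  t_i <- cumsum(tc != "-")
  q_i <- cumsum(qc != "-")
  keep <- tc != "-"
  map <- rep(NA_integer_, sum(keep))
  both <- keep & qc != "-"
  map[t_i[both]] <- q_i[both]
  map
}

#' @export
print.mip_alignment <- function(x, ...) {
  cat(sprintf("<mip_alignment> %s vs template %s (score %.1f, %d/%d template positions mapped)\n",
              x$query_id, x$template_id, x$score,
              sum(!is.na(x$index_map)), length(x$index_map)))
  invisible(x)
}

query_residue_at <- function(map, template_index) {
  qi <- map$index_map[template_index]
  if (is.na(qi)) return(NA_character_)
  q <- gsub("-", "", map$aligned_query)
  substr(q, qi, qi)
}

#' Read diagnostic residues off a template alignment
#'
#' Extracts the query residue at every named template position of a
#' position table, assembling a one-row diagnostic profile: ar/R filter
#' residues, the two NPA motifs as 3-letter strings, Froger's positions and
#' SDPs. Positions deleted in the query yield `NA`; an NPA motif is `NA` if
#' any of its three columns is unmapped.
#'
#' @param map an alignment from [align_to_template()].
#' @param positions a position table (see [default_positions()]).
#' @return a one-row tibble with `protein_id`, `h2`, `h5`, `le1`, `le2`,
#'   `npa_lb`, `npa_le`, `p1`..`p5` and `sdp1`..`sdp9` (when the position
#'   table names them).
#' @export
extract_profile <- function(map, positions = default_positions()) {
  stopifnot(inherits(map, "mip_alignment"))
  if (any(positions$index > length(map$index_map))) {
    abort("position table refers beyond the template length")
  }
  at <- function(name) {
    idx <- positions$index[positions$name == name]
    if (length(idx) != 1) return(NA_character_)
    query_residue_at(map, idx)
  }
  motif <- function(prefix) {
    res <- purrr::map_chr(paste0(prefix, 1:3), at)
    if (anyNA(res)) NA_character_ else paste(res, collapse = "")
  }
  out <- tibble(
    protein_id = map$query_id,
    h2 = at("H2"), h5 = at("H5"), le1 = at("LE1"), le2 = at("LE2"),
    npa_lb = motif("NPA_LB"), npa_le = motif("NPA_LE"),
    p1 = at("P1"), p2 = at("P2"), p3 = at("P3"),
    p4 = at("P4"), p5 = at("P5")
  )
  if (any(grepl("^SDP", positions$name))) {
    for (k in 1:9) out[[paste0("sdp", k)]] <- at(paste0("SDP", k))
  }
  out
}

#' Flag conserved phosphorylation sites
#'
#' Reports, for each named phosphosite of the position table (`PHOS1`,
#' `PHOS2`), whether the aligned query residue is phosphorylatable. A
#' serine-to-threonine substitution counts as conserved.
#'
#' @inheritParams extract_profile
#' @return a tibble with columns `site`, `residue`, `conserved` (TRUE iff
#'   the residue is S or T).
#' @export
flag_phosphosites <- function(map, positions = default_positions()) {
  stopifnot(inherits(map, "mip_alignment"))
  phos <- filter(positions, grepl("^PHOS", .data$name))
  res <- purrr::map_chr(phos$index, function(i) query_residue_at(map, i))
  tibble(site = phos$name, residue = res,
         conserved = !is.na(res) & res %in% c("S", "T"))
}
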
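#' Type the two NPA half-helix motifs
#'
#' Labels each of the two NPA motifs of a profile as `CANONICAL` (exactly
#' `NPA`), `VARIANT:<motif>` (e.g. `VARIANT:NPS`), or `NA` when the motif
#' is unobserved.
#'
#' @param profile a one-row profile tibble with `npa_lb` and `npa_le`.
#' @return a named character vector with elements `lb` and `le`.
#' @export
npa_type <- function(profile) {
  stopifnot(nrow(profile) == 1)
  lab <- function(motif) {
    if (is.na(motif)) return(NA_character_)
    if (nchar(motif) != 3) abort("NPA motif must have exactly 3 letters")
    if (motif == "NPA") "CANONICAL" else paste0("VARIANT:", motif)
  }
  c(lb = lab(profile$npa_lb), le = lab(profile$npa_le))
}

#' Classify Froger's positions as glycerol- or water-channel-like
#'
#' Glycerol facilitators (GlpF-like aquaglyceroporins) carry an aromatic
#' residue at P1, an acidic residue at P2, a basic residue at P3, a
#' proline at P4 and a non-aromatic residue at P5; pure water channels
#' (AqpZ-like) show the complementary pattern. Each position is scored
#' `GLP_LIKE` or `AQP_LIKE` accordingly and the overall call is
#' `GLYCEROL_TYPE` (all five GLP-like), `WATER_TYPE` (none), `MIXED`
#' (one to four) or `INCOMPLETE` (any position unobserved). The chemical
#' classes are configurable; by default aromatic is F/W/Y (histidine
#' excluded), acidic D/E, basic K/R/H.
#'
#' @param profile a one-row profile tibble with `p1`..`p5`.
#' @param aromatic,acidic,basic residue classes used by the per-position
#'   tests.
#' @return a list with `call` and `per_position` (named character vector
#'   P1..P5).
#' @export
froger_class <- function(profile,
                         aromatic = c("F", "W", "Y"),
                         acidic = c("D", "E"),
                         basic = c("K", "R", "H")) {
  stopifnot(nrow(profile) == 1)
  p <- purrr::map_chr(FROGER_FIELDS, ~ profile[[.x]] %||% NA_character_)
  glp <- c(p[1] %in% aromatic,
           p[2] %in% acidic,
           p[3] %in% basic,
           identical(p[4], "P"),
           !is.na(p[5]) && !(p[5] %in% aromatic))
  per <- ifelse(is.na(p), NA_character_, ifelse(glp, "GLP_LIKE", "AQP_LIKE"))
  names(per) <- toupper(FROGER_FIELDS)
  call <- if (anyNA(p)) {
    "INCOMPLETE"
  } else {
    n <- sum(glp)
    if (n == 0) "WATER_TYPE" else if (n == 5) "GLYCEROL_TYPE" else "MIXED"
  }
  list(call = call, per_position = per)
}

#' Match an SDP profile against one substrate rule
#'
#' Compares nine observed specificity-determining residues against a
#' substrate's allowed sets. Observed residues outside the allowed set are
#' deviations; unobserved positions count as missing and never as
#' deviations. The category is `TYPICAL` (no deviations, nothing missing),
#' `NOVEL_CANDIDATE` (at most `max_novel_deviations` deviations,
#' generalising the practice of flagging single substitutions as novel
#' variants of a transporter type), `NO_MATCH` (more deviations), or
#' `INCOMPLETE` (no deviations but missing positions).
#'
#' @param profile_sdp named character vector `SDP1`..`SDP9` (NA for
#'   unobserved), or a one-row tibble with columns `sdp1`..`sdp9`.
#' @param rule a named list `SDP1`..`SDP9` of allowed residue vectors
#'   (see [rule_allowed()]), or a one-row slice of a rules tibble.
#' @param max_novel_deviations deviation count still reported as a novel
#'   candidate.
#' @return a one-row tibble: `category`, `n_deviations`, `n_missing` and a
#'   list-column `deviations` (tibble with `position`, `observed`,
#'   `allowed`).
#' @export
match_sdp <- function(profile_sdp, rule, max_novel_deviations = 1) {
  sdp <- as_sdp_vector(profile_sdp)
  allowed <- as_sdp_rule(rule)
  obs_ok <- purrr::imap_lgl(allowed, function(set, name) {
    v <- sdp[[name]]
    is.na(v) || v %in% set
  })
  miss <- is.na(unlist(sdp))
  dev_pos <- names(allowed)[!obs_ok]
  deviations <- tibble(
    position = dev_pos,
    observed = unlist(sdp)[dev_pos],
    allowed = purrr::map_chr(allowed[dev_pos], paste, collapse = "/")
  )
  n_dev <- nrow(deviations)
  category <- if (n_dev == 0) {
    if (any(miss)) "INCOMPLETE" else "TYPICAL"
  } else if (n_dev <= max_novel_deviations) {
    "NOVEL_CANDIDATE"
  } else {
    "NO_MATCH"
  }
  tibble(category = category, n_deviations = n_dev,
         n_missing = sum(miss), deviations = list(deviations))
}

as_sdp_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    if (!all(SDP_FIELDS %in% names(x))) {
      return(setNames(as.list(rep(NA_character_, 9)),
                      toupper(SDP_FIELDS)))
    }
    x <- setNames(as.character(x[1, SDP_FIELDS]), toupper(SDP_FIELDS))
  }
  names(x) <- toupper(names(x))
  stopifnot(all(toupper(SDP_FIELDS) %in% names(x)))
  as.list(x[toupper(SDP_FIELDS)])
}

as_sdp_rule <- function(rule) {
  if (is.data.frame(rule)) {
    stopifnot(nrow(rule) == 1)
    rule <- setNames(purrr::map(SDP_FIELDS, ~ rule[[.x]][[1]]),
                     toupper(SDP_FIELDS))
  }
  names(rule) <- toupper(names(rule))
  stopifnot(all(toupper(SDP_FIELDS) %in% names(rule)))
  purrr::walk(rule, function(set) {
    if (length(set) == 0) abort("rule has an empty allowed set")
  })
  rule[toupper(SDP_FIELDS)]
}

#' Predict transported substrates for one profile
#'
#' Matches a profile's SDP residues against every substrate rule and
#' returns one row per substrate, ordered by match quality (TYPICAL, then
#' NOVEL_CANDIDATE, NO_MATCH, INCOMPLETE; ties by substrate name). A
#' profile with no SDP observations yields all-INCOMPLETE.
#'
#' @param profile a one-row profile tibble (columns `sdp1`..`sdp9`, which
#'   may be absent or NA).
#' @param rules a rules tibble from [load_substrate_rules()].
#' @inheritParams match_sdp
#' @return a tibble with columns `substrate`, `category`, `n_deviations`,
#'   `n_missing`, `deviations`.
#' @export
predict_substrates <- function(profile, rules = NULL,
                               max_novel_deviations = 1) {
  if (is.null(rules)) {
    rules <- load_substrate_rules(mip_fixture("table3_rules.tsv"))
  }
  if (nrow(rules) == 0) {
    return(tibble(substrate = character(), category = character(),
                  n_deviations = integer(), n_missing = integer(),
                  deviations = list()))
  }
  out <- purrr::map(seq_len(nrow(rules)), function(i) {
    res <- match_sdp(profile, rules[i, ],
                     max_novel_deviations = max_novel_deviations)
    mutate(res, substrate = rules$substrate[i], .before = 1)
  }) |>
    bind_rows()
  rank <- c(TYPICAL = 1, NOVEL_CANDIDATE = 2, NO_MATCH = 3, INCOMPLETE = 4)
  arrange(out, rank[.data$category], .data$substrate)
}

#' Match a table of per-substrate SDP observations
#'
#' For a long table of observed SDP residues (one row per protein and
#' substrate, the shape of
#' `load_profiles`-style fixtures like `mip_fixture("table3_profiles.tsv")`),
#' matches each row against its own substrate's rule and reports the
#' category and any deviating positions.
#'
#' @param sdp_table tibble with columns `substrate`, `protein_id`,
#'   `sdp1`..`sdp9`.
#' @param rules a rules tibble from [load_substrate_rules()].
#' @inheritParams match_sdp
#' @return the input keyed columns plus `category`, `n_deviations`,
#'   `n_missing` and the `deviations` list-column.
#' @export
match_sdp_table <- function(sdp_table, rules, max_novel_deviations = 1) {
  purrr::map(seq_len(nrow(sdp_table)), function(i) {
    row <- sdp_table[i, ]
    res <- match_sdp(row, rules[rules$substrate == row$substrate, ],
                     max_novel_deviations = max_novel_deviations)
    bind_cols(row[c("substrate", "protein_id")], res)
  }) |>
    bind_rows()
}

#' Describe a profile's ar/R selectivity filter
#'
#' @param profile a one-row profile tibble.
#' @return a one-row tibble with `protein_id` (when present), `arr` (the
#'   dash-joined H2-H5-LE1-LE2 string, `-` marking unobserved residues)
#'   and `pip_typical` (TRUE iff the filter is the PIP-universal F-H-T-R).
#' @export
arr_report <- function(profile) {
  stopifnot(nrow(profile) == 1)
  res <- purrr::map_chr(ARR_FIELDS, ~ profile[[.x]] %||% NA_character_)
  arr <- paste(ifelse(is.na(res), "-", res), collapse = "-")
  tibble(protein_id = profile$protein_id %||% NA_character_,
         arr = arr, pip_typical = identical(arr, "F-H-T-R"))
}
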
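#' Subfamily and subgroup rule cascade
#'
#' The classifier is an ordered cascade of residue rules over the
#' diagnostic profile: the first rule whose clauses match assigns the
#' subfamily. The cascade is configuration, not code: it ships as
#' `rules.yaml` (see `mip_fixture("rules.yaml")`) and any file with the
#' same schema can be substituted. Rule order is part of the contract
#' (PIP is tested before TIP, and TIP before the P4-based SIP catch-all).
#'
#' @param path YAML cascade definition.
#' @return a named list with elements `cascade` (ordered subfamily rules)
#'   and `subgroups` (per-subfamily subgroup rules).
#' @export
load_rules <- function(path) {
  rules <- yaml::read_yaml(path)
  stopifnot(is.list(rules$cascade), length(rules$cascade) > 0)
  rules
}

#' @rdname load_rules
#' @export
default_rules <- function() {
  load_rules(mip_fixture("rules.yaml"))
}

# one clause = AND over fields; allowed values support a trailing "*"
# prefix wildcard. missing_ok relaxes to: all observed fields agree and at
# least one is observed.
clause_matches <- function(row, clause, missing_ok = FALSE) {
  hits <- purrr::imap_lgl(clause, function(allowed, field) {
    v <- row[[field]]
    if (is.null(v) || is.na(v)) return(NA)
    allowed <- as.character(allowed)
    pref <- endsWith(allowed, "*")
    any(allowed[!pref] == v) ||
      any(startsWith(v, sub("\\*$", "", allowed[pref])))
  })
  if (missing_ok) {
    any(!is.na(hits)) && all(hits[!is.na(hits)])
  } else {
    all(!is.na(hits)) && all(hits)
  }
}

clause_evidence <- function(row, clause) {
  tibble(position = names(clause),
         residue = purrr::map_chr(names(clause),
                                  ~ row[[.x]] %||% NA_character_))
}

apply_cascade <- function(row, cascade, missing_ok = FALSE) {
  for (rule in cascade) {
    for (clause in rule$any) {
      if (clause_matches(row, clause, missing_ok = missing_ok)) {
        return(list(label = rule$label,
                    fired_rule = describe_clause(rule$label, clause),
                    evidence = clause_evidence(row, clause)))
      }
    }
  }
  list(label = "UNCLASSIFIED", fired_rule = NA_character_,
       evidence = tibble(position = character(), residue = character()))
}

describe_clause <- function(label, clause) {
  sprintf("%s[%s]", label,
          paste(names(clause),
                purrr::map_chr(clause, ~ paste(.x, collapse = "|")),
                sep = "=", collapse = ","))
}

#' Assign one profile to an aquaporin subfamily
#'
#' Runs the rule cascade on a single diagnostic profile. With the default
#' rules this is: (1) PIP iff the ar/R filter is F-H-T-R; (2) NIP iff
#' Froger P5 is I, L or M; (3) XIP iff Froger P2 is C, or the first NPA
#' motif starts with S or is NPV/NPI; (4) TIP iff P4 is Y and H2 is H or
#' N; (5) SIP iff P4 is Y; otherwise UNCLASSIFIED (including the
#' all-missing profile).
#'
#' @param profile a one-row profile tibble (see [load_profiles()] or
#'   [extract_profile()]).
#' @param rules a cascade from [load_rules()].
#' @return a list (rule trace) with `label`, `fired_rule` and an
#'   `evidence` tibble of the residues the winning clause inspected.
#' @seealso [classify_profiles()] for the data-frame-first version.
#' @export
assign_subfamily <- function(profile, rules = default_rules()) {
  stopifnot(nrow(profile) == 1)
  apply_cascade(as.list(profile), rules$cascade)
}

#' Assign a subgroup within a subfamily
#'
#' Applies the subgroup rules of the cascade configuration. With the
#' default rules, XIPs resolve to XIP1/XIP2/XIP3 by their ar/R filter
#' (V-F-V-R, I-F-V-R, V-Y-A-R; missing-tolerant so that a truncated
#' profile retaining only part of the filter still places, first match in
#' rule order winning), and NIPs resolve to NIP I (W-V-A-R or W-A-A-R),
#' NIP III (G-S-G-R) or NIP II (NPS/NPV motifs or H2 in A/T). Subfamilies
#' without profile-level subgroup rules return "UNASSIGNED"; numbered
#' subgroups there require a reference set
#' (see [assign_subgroup_by_reference()]).
#'
#' @inheritParams assign_subfamily
#' @param subfamily the subfamily label the profile was assigned.
#' @return a subgroup label (character scalar).
#' @export
assign_subgroup <- function(profile, subfamily, rules = default_rules()) {
  if (identical(subfamily, "UNCLASSIFIED")) {
    abort("cannot assign a subgroup to an UNCLASSIFIED profile")
  }
  sub <- rules$subgroups[[subfamily]]
  if (is.null(sub)) return("UNASSIGNED")
  missing_ok <- isTRUE(sub$missing_ok)
  res <- apply_cascade(as.list(profile), sub$rules, missing_ok = missing_ok)
  if (res$label == "UNCLASSIFIED") "UNASSIGNED" else res$label
}

#' Classify a table of diagnostic profiles
#'
#' Data-frame-first wrapper over [assign_subfamily()] and
#' [assign_subgroup()]: one call classifies every row.
#'
#' @param profiles a profile tibble (one row per protein).
#' @param rules a cascade from [load_rules()].
#' @return the input with columns `subfamily`, `subgroup`, `fired_rule`
#'   and a list-column `evidence` appended.
#' @examples
#' load_profiles(mip_fixture("table2.tsv")) |>
#'   classify_profiles() |>
#'   dplyr::count(subfamily)
#' @export
classify_profiles <- function(profiles, rules = default_rules()) {
  traces <- purrr::map(seq_len(nrow(profiles)), function(i) {
    tr <- assign_subfamily(profiles[i, ], rules)
    tr$subgroup <- if (tr$label == "UNCLASSIFIED") NA_character_ else
      assign_subgroup(profiles[i, ], tr$label, rules)
    tr
  })
  mutate(profiles,
         subfamily = purrr::map_chr(traces, "label"),
         subgroup = purrr::map_chr(traces, "subgroup"),
         fired_rule = purrr::map_chr(traces, "fired_rule"),
         evidence = purrr::map(traces, "evidence"))
}

#' Pairwise identity distance matrix
#'
#' Global-alignment fractional identity for every sequence pair
#' (matches / alignment columns; a global pairwise alignment has no
#' dual-gap columns), returned as the distance 1 - identity.
#'
#' @param seqs a sequence tibble (>= 2 rows) from [read_fasta()].
#' @inheritParams align_to_template
#' @return a symmetric numeric matrix with zero diagonal, dimnames the
#'   sequence ids, entries in \[0, 1\].
#' @export
identity_matrix <- function(seqs, gap_open = 10, gap_extend = 0.5,
                            substitution = "BLOSUM62") {
  n <- nrow(seqs)
  if (n < 2) abort("identity_matrix needs at least 2 sequences")
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs$residues[i]),
        Biostrings::AAString(seqs$residues[j]),
        type = "global", substitutionMatrix = substitution,
        gapOpening = gap_open, gapExtension = gap_extend)
      a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      cols <- !(a == "-" & b == "-")
      ident <- sum(a == b & a != "-") / sum(cols)
      d[i, j] <- d[j, i] <- 1 - ident
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining (Saitou-Nei Q-criterion, via [ape::nj()])
#' with a post-pass that clamps negative branch lengths to zero and moves
#' the deficit onto the sister edge, preserving leaf-to-leaf path lengths
#' where possible. For additive distances the generating tree is recovered
#' exactly.
#'
#' @param d a symmetric distance matrix with zero diagonal and dimnames.
#' @return an object of classes `mip_nj` and `phylo`.
#' @seealso [write_newick()], [tidy.mip_nj()], [glance.mip_nj()]
#' @export
nj_tree <- function(d) {
  if (!isSymmetric(unname(d))) abort("distance matrix must be symmetric")
  if (nrow(d) < 3) abort("neighbor-joining needs at least 3 taxa")
  tree <- ape::nj(d)
  tree <- clamp_negative_edges(tree)
  class(tree) <- c("mip_nj", class(tree))
  tree
}

# move negative edge length onto the sister edge (same parent node)
clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sisters <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sisters) > 0) {
      tree$edge.length[sisters[1]] <- tree$edge.length[sisters[1]] + deficit
      if (tree$edge.length[sisters[1]] < 0) {
        tree$edge.length[sisters[1]] <- 0
      }
    }
  }
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` (or `mip_nj`) object.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  class(tree) <- "phylo"
  s <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Tidy a neighbor-joining tree
#'
#' @param x a tree from [nj_tree()].
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per edge (`parent`, `node`,
#'   `length`, `label` for leaf edges). `glance()`: a one-row tibble with
#'   `n_leaves`, `n_edges`, `total_length`.
#' @method tidy mip_nj
#' @export
tidy.mip_nj <- function(x, ...) {
  labels <- c(x$tip.label, rep(NA_character_, x$Nnode))
  tibble(parent = x$edge[, 1], node = x$edge[, 2],
         length = x$edge.length, label = labels[x$edge[, 2]])
}

#' @rdname tidy.mip_nj
#' @method glance mip_nj
#' @export
glance.mip_nj <- function(x, ...) {
  tibble(n_leaves = length(x$tip.label),
         n_edges = nrow(x$edge),
         total_length = sum(x$edge.length))
}

#' Numbered subgroups by nearest reference neighbor
#'
#' PIP and TIP numbered subgroups (PIP1 vs PIP2, TIP1..TIP5) are not
#' decidable from the diagnostic profile alone; given a labelled reference
#' set, each query adopts the subgroup of its nearest reference by global
#' alignment identity, provided that identity reaches `threshold`
#' (otherwise "UNASSIGNED").
#'
#' @param seqs query sequence tibble.
#' @param reference reference sequence tibble.
#' @param reference_subgroups character vector of subgroup labels, one per
#'   reference row.
#' @param threshold minimum fractional identity to the nearest reference.
#' @return a tibble with columns `id`, `subgroup`, `nearest_reference`,
#'   `identity`.
#' @export
assign_subgroup_by_reference <- function(seqs, reference,
                                         reference_subgroups,
                                         threshold = 0.55) {
  stopifnot(nrow(reference) == length(reference_subgroups))
  all <- bind_rows(seqs, reference)
  d <- identity_matrix(all)
  idm <- 1 - d[seqs$id, reference$id, drop = FALSE]
  best <- apply(idm, 1, which.max)
  tibble(
    id = seqs$id,
    subgroup = ifelse(idm[cbind(seq_len(nrow(seqs)), best)] >= threshold,
                      reference_subgroups[best], "UNASSIGNED"),
    nearest_reference = reference$id[best],
    identity = idm[cbind(seq_len(nrow(seqs)), best)]
  )
}
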
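# Independent oracles used by the tests; these deliberately avoid the code
# paths they check.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# exhaustive global alignment score with affine gaps (gap of length L costs
# open + L * ext), by recursion over all monotone alignments; tractable for
# sequences of length <= ~7
bf_align_score <- function(a, b, open = 10, ext = 0.5, mat = blosum62) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      best <- max(best,
                  -(ext + if (prev != "D") open else 0) + rec(i + 1, j, "D"))
    }
    if (j <= m) {
      best <- max(best,
                  -(ext + if (prev != "I") open else 0) + rec(i, j + 1, "I"))
    }
    best
  }
  rec(1, 1, "M")
}

# design matrix of a topology: column e is the indicator of edge e lying on
# the path between a leaf pair (obtained by setting one edge to length 1)
topology_design <- function(tree) {
  pairs <- t(combn(sort(tree$tip.label), 2))
  X <- matrix(0, nrow(pairs), nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    tr <- tree
    tr$edge.length <- rep(0, nrow(tr$edge))
    tr$edge.length[e] <- 1
    cp <- ape::cophenetic.phylo(tr)
    X[, e] <- cp[pairs]
  }
  list(pairs = pairs, X = X)
}

# brute-force least-squares tree: fit branch lengths on every unrooted
# topology and return the one with the smallest residual sum of squares
ls_best_tree <- function(d) {
  labs <- sort(rownames(d))
  topos <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  best <- NULL
  best_rss <- Inf
  for (k in seq_along(topos)) {
    tr <- topos[[k]]  # [[ restores tip labels from the multiPhylo attribute
    tr$edge.length <- rep(0, nrow(tr$edge))
    des <- topology_design(tr)
    y <- d[des$pairs]
    fit <- stats::lm.fit(des$X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      tr$edge.length <- fit$coefficients
      best <- tr
    }
  }
  list(tree = best, rss = best_rss)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# random tree with positive branch lengths and its additive distance matrix
random_additive_matrix <- function(n_leaves, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_leaves, rooted = FALSE,
                     br = function(k) runif(k, 0.05, 1))
    list(tree = tr, d = ape::cophenetic.phylo(tr))
  })
}

write_test_fastq <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    c(paste0("@", r$id), r$seq, "+", r$qual)
  }))
  writeLines(lines, path)
  path
}
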
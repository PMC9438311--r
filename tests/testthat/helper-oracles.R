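# Independent oracles used by the alignment and parsimony tests. These are
# deliberately written as naive memoised recursions / exhaustive
# enumerations, sharing no code with the package implementations.

# scoring identical in convention to the sticky aligner: meta symbols are
# integers >= 100, meta-meta scores meta_bonus, meta-base is forbidden
nw_brute_score <- function(a, b, match = 1, mismatch = -1, gap = -2,
                           meta_bonus = 10) {
  memo <- new.env(hash = TRUE)
  pair <- function(x, y) {
    mx <- x >= 100; my <- y >= 100
    if (mx && my) return(meta_bonus)
    if (mx || my) return(-Inf)
    if (x == y) match else mismatch
  }
  rec <- function(i, j) {
    key <- paste(i, j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == 0 && j == 0) 0
    else if (i == 0) j * gap
    else if (j == 0) i * gap
    else max(rec(i - 1, j - 1) + pair(a[i], b[j]),
             rec(i - 1, j) + gap,
             rec(i, j - 1) + gap)
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}

# exhaustive Sankoff: enumerate every assignment of internal-node states
sankoff_brute <- function(tree, leaf_states, state_set = NULL) {
  n_tip <- length(tree$tip.label)
  obs <- leaf_states[tree$tip.label]
  if (is.null(state_set))
    state_set <- seq(min(obs, na.rm = TRUE), max(obs, na.rm = TRUE))
  n_int <- tree$Nnode
  grid <- do.call(expand.grid, rep(list(state_set), n_int))
  edges <- tree$edge
  best <- Inf
  best_assign <- NULL
  for (r in seq_len(nrow(grid))) {
    st <- c(obs, as.numeric(grid[r, ]))
    cost <- 0
    for (k in seq_len(nrow(edges))) {
      p <- st[edges[k, 1]]; c_ <- st[edges[k, 2]]
      if (is.na(c_)) next  # missing leaf: zero cost
      cost <- cost + abs(p - c_)
    }
    if (cost < best) { best <- cost; best_assign <- st }
  }
  list(cost = unname(best), states = best_assign)
}

# exhaustive lower-tail hypergeometric: P(X <= q) by enumerating subsets
hyper_lower_enum <- function(q, m, N, k) {
  sum(vapply(0:q, function(x)
    choose(m, x) * choose(N - m, k - x), 0)) / choose(N, k)
}

# plain Smith-Waterman score via Biostrings (affine: gap of length L costs
# gapOpening + L * gapExtension, matching the package convention)
sw_biostrings_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = 4, gap_ext = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  Biostrings::pairwiseAlignment(a, b, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = gap_open,
                                gapExtension = gap_ext,
                                scoreOnly = TRUE)
}

random_dna_str <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
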
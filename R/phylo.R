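#' Kimura two-parameter distance
#'
#' With transition proportion `P` and transversion proportion `Q` over the
#' counted sites, `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. Columns
#' containing gaps or ambiguity codes are excluded from the counts.
#'
#' @param a,b equal-length aligned sequences (character strings), or `a`
#'   may be a numeric transition proportion and `b` the transversion
#'   proportion.
#' @return the K2P distance (substitutions per site).
#' @export
kimura2p <- function(a, b) {
  if (is.character(a)) {
    stopifnot(nchar(a) == nchar(b))
    ea <- encode_dna(a); eb <- encode_dna(b)
    ok <- ea > 0L & eb > 0L
    n <- sum(ok)
    if (n == 0) stop("no comparable sites")
    purine <- function(x) x == 1L | x == 3L
    diffs <- ok & ea != eb
    ts <- sum(diffs & purine(ea) == purine(eb))
    tv <- sum(diffs) - ts
    P <- ts / n; Q <- tv / n
  } else {
    P <- a; Q <- b
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(structure(class = c("intronevo_saturation", "error", "condition"),
                   list(message = sprintf(
                     "K2P saturation (P=%.3f, Q=%.3f)", P, Q),
                     call = sys.call(-1))))
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix from pooled exon alignments
#'
#' For every species pair, exon sequences of shared single-copy families are
#' globally aligned (plain Needleman-Wunsch, no meta-symbols) and the
#' transition/transversion counts pooled across families before applying the
#' K2P formula. Saturated pairs are excluded with a warning (entry `NA`).
#'
#' @param files per-species list with `gff` and `fasta` paths.
#' @param family_table data frame `family_id`, `species`, `gene_id`.
#' @param min_coverage minimal fraction (or count if > 1) of species in
#'   which a family must be single-copy.
#' @param max_families cap on the number of families pooled (an evenly
#'   spaced deterministic subset is used); keeps the quadratic alignment
#'   cost bounded while leaving tens of kilobases of aligned exon per pair.
#' @param scoring alignment scoring (match, mismatch, gap).
#' @return object of class `k2p_dist`: list with `d` (symmetric distance
#'   matrix, zero diagonal), `sites` (aligned-site counts), `species`.
#' @export
distance_matrix <- function(files, family_table, min_coverage = 1.0,
                            max_families = 24L,
                            scoring = list(match = 1, mismatch = -1,
                                           gap = -2)) {
  species <- names(files)
  n_sp <- length(species)
  need <- if (min_coverage > 1) min_coverage else
    ceiling(min_coverage * n_sp)
  cnt <- table(family_table$family_id, family_table$species)
  fams <- sort(rownames(cnt)[rowSums(cnt == 1) >= need])
  if (length(fams) == 0) stop("no family passes coverage")
  if (length(fams) > max_families)
    fams <- fams[unique(round(seq(1, length(fams),
                                  length.out = max_families)))]

  gene_lookup <- setNames(family_table$gene_id,
                          paste(family_table$species,
                                family_table$family_id, sep = "\r"))
  # spliced exon sequence (integer-coded) per species x family
  spliced <- lapply(species, function(sp) {
    tset <- read_annotation(files[[sp]]$gff, species = sp)
    seqs <- exon_seqs_by_transcript(tset, files[[sp]]$fasta)
    gene_by_tr <- tapply(tset$exons$gene, tset$exons$transcript,
                         function(x) x[1])
    out <- lapply(seqs, function(s) encode_dna(paste(s, collapse = "")))
    names(out) <- unname(gene_by_tr[names(seqs)])
    out
  })
  names(spliced) <- species

  d <- matrix(0, n_sp, n_sp, dimnames = list(species, species))
  sites <- matrix(0, n_sp, n_sp, dimnames = list(species, species))
  for (i in seq_len(n_sp - 1)) {
    for (j in (i + 1):n_sp) {
      ts <- tv <- ns <- 0
      for (f in fams) {
        gi <- gene_lookup[paste(species[i], f, sep = "\r")]
        gj <- gene_lookup[paste(species[j], f, sep = "\r")]
        if (is.na(gi) || is.na(gj)) next
        si <- spliced[[species[i]]][[gi]]
        sj <- spliced[[species[j]]][[gj]]
        if (is.null(si) || is.null(sj)) next
        cc <- .nw_pair_counts_cpp(si, sj, scoring$match, scoring$mismatch,
                                  scoring$gap)
        ts <- ts + cc$transitions; tv <- tv + cc$transversions
        ns <- ns + cc$sites
      }
      if (ns == 0) stop("no shared aligned sites for pair ",
                        species[i], "/", species[j])
      dij <- tryCatch(kimura2p(ts / ns, tv / ns),
                      intronevo_saturation = function(e) {
                        warning("saturated pair ", species[i], "/",
                                species[j], "; set to NA")
                        NA_real_
                      })
      d[i, j] <- d[j, i] <- dij
      sites[i, j] <- sites[j, i] <- ns
    }
  }
  out <- list(d = d, sites = sites, species = species)
  class(out) <- "k2p_dist"
  out
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \code{ape::nj}); negative branch
#' lengths are clamped to zero with a warning.
#'
#' @param dm a `k2p_dist` or a symmetric numeric matrix.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  m <- if (inherits(dm, "k2p_dist")) dm$d else as.matrix(dm)
  stopifnot(nrow(m) >= 3)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix is not symmetric")
  tree <- ape::nj(m)
  if (any(tree$edge.length < 0)) {
    warning("clamping ", sum(tree$edge.length < 0),
            " negative branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Root a tree on the branch separating an outgroup
#'
#' The root is placed at the midpoint of the branch between the outgroup
#' (which must form a clade) and the remaining species; internal node ids
#' are then assigned deterministically in post-order.
#'
#' @param tree an unrooted `phylo`.
#' @param outgroup character vector of outgroup species.
#' @return a rooted `phylo` with node labels `nd01`, `nd02`, ...
#' @export
root_tree <- function(tree, outgroup) {
  stopifnot(all(outgroup %in% tree$tip.label))
  rt <- tryCatch(ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
                 error = function(e)
                   stop("outgroup is not a clade in the tree: ",
                        conditionMessage(e)))
  n_tip <- length(rt$tip.label)
  root <- n_tip + 1L
  kids <- rt$edge[rt$edge[, 1] == root, 2]
  if (length(kids) != 2) stop("outgroup does not define a single split")
  side <- lapply(kids, function(k) sort(rt$tip.label[descendant_tips(rt, k)]))
  og <- sort(outgroup)
  if (!identical(side[[1]], og) && !identical(side[[2]], og))
    stop("outgroup is not a clade in the tree")
  # bisect the split branch: equalise the two root edges
  ei <- which(rt$edge[, 1] == root)
  tot <- sum(rt$edge.length[ei])
  rt$edge.length[ei] <- tot / 2
  label_nodes(rt)
}
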
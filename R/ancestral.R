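#' Discretise an intron length to its 10*log2 size state
#'
#' Round-half-even of `10 * log2(length)`; invertible to within one
#' discretisation step by [decode_size()].
#'
#' @param length_bp intron length(s) in bp (>= 1).
#' @return integer state(s).
#' @export
discretize_size <- function(length_bp) {
  if (any(length_bp < 1)) stop("length must be >= 1")
  as.integer(round(10 * log2(length_bp)))
}

#' @rdname discretize_size
#' @param state integer size state(s).
#' @export
decode_size <- function(state) 2 ^ (state / 10)

BIG <- 1e9

#' Sankoff maximum-parsimony reconstruction of discretised intron sizes
#'
#' Bottom-up dynamic program over the integer state lattice spanning the
#' observed states plus a margin, with transition cost `|parent - child|`;
#' top-down backtrace chooses minimal-cost states, breaking ties toward the
#' state closest to the parent's chosen state and then toward the smallest
#' state (at the root: smallest state). Missing leaves contribute all-zero
#' cost vectors.
#'
#' @param tree rooted `phylo` with node labels (see [root_tree()]).
#' @param leaf_states matrix (introns x species; columns named by species)
#'   of integer states, `NA` for missing; or a named vector for one intron.
#' @param margin lattice margin beyond the observed state range.
#' @return list with `states` (introns x nodes matrix; node columns are
#'   `c(tip labels, node labels)`), `cost` (total parsimony cost per
#'   intron), and `lattice`.
#' @export
sankoff_reconstruct <- function(tree, leaf_states, margin = 10L) {
  if (is.null(dim(leaf_states)))
    leaf_states <- matrix(leaf_states, 1,
                          dimnames = list(NULL, names(leaf_states)))
  species <- tree$tip.label
  stopifnot(all(species %in% colnames(leaf_states)))
  S_obs <- leaf_states[, species, drop = FALSE]
  n_int <- nrow(S_obs)
  n_tip <- length(species)
  n_nodes <- n_tip + tree$Nnode
  obs_cnt <- rowSums(!is.na(S_obs))
  if (any(obs_cnt == 0))
    warning(sum(obs_cnt == 0), " intron(s) with no observed leaves skipped")
  usable <- obs_cnt >= 1
  rng <- range(S_obs, na.rm = TRUE)
  lattice <- seq.int(rng[1] - margin, rng[2] + margin)
  S <- length(lattice)

  tree_po <- ape::reorder.phylo(tree, "postorder")
  edges <- tree_po$edge
  root <- n_tip + 1L

  # cost matrices C[[node]]: S x n_int
  C <- vector("list", n_nodes)
  for (i in seq_len(n_tip)) {
    m <- matrix(BIG, S, n_int)
    st <- S_obs[, i]
    hit <- !is.na(st)
    m[, !hit] <- 0            # missing leaf: zero cost vector
    if (any(hit))
      m[cbind(match(st[hit], lattice), which(hit))] <- 0
    C[[i]] <- m
  }
  for (k in (n_tip + 1):n_nodes) C[[k]] <- matrix(0, S, n_int)

  # min-convolution with |ds| cost: forward/backward pass over the lattice
  dist_transform <- function(m) {
    for (s in 2:S) m[s, ] <- pmin(m[s, ], m[s - 1, ] + 1)
    for (s in (S - 1):1) m[s, ] <- pmin(m[s, ], m[s + 1, ] + 1)
    m
  }
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; child <- edges[k, 2]
    C[[par]] <- C[[par]] + dist_transform(C[[child]])
  }

  # backtrace
  assign_mat <- matrix(NA_integer_, n_int, n_nodes)
  root_cost <- C[[root]]
  cost <- apply(root_cost, 2, min)
  root_idx <- max.col(-t(root_cost), ties.method = "first")
  assign_mat[, root] <- lattice[root_idx]
  pre <- rev(seq_len(nrow(edges)))
  A <- (S + 1)^2
  for (k in pre) {
    par <- edges[k, 1]; child <- edges[k, 2]
    sp <- assign_mat[, par]
    absd <- abs(outer(lattice, sp, "-"))
    key <- C[[child]] * A + absd * (S + 1) +
      matrix(seq_len(S), S, n_int)
    idx <- max.col(-t(key), ties.method = "first")
    assign_mat[, child] <- lattice[idx]
  }
  # leaves keep their observed states where present
  for (i in seq_len(n_tip)) {
    hit <- !is.na(S_obs[, i])
    assign_mat[hit, i] <- S_obs[hit, i]
  }
  assign_mat[!usable, ] <- NA_integer_
  cost[!usable] <- NA_real_
  colnames(assign_mat) <- c(species, tree$node.label)
  rownames(assign_mat) <- rownames(leaf_states)
  list(states = assign_mat, cost = cost, lattice = lattice)
}

#' Cumulative intron-size change along the tree
#'
#' For every node, the cumulative branch-length distance from the root and
#' the cumulative mean (over introns) change in size state from the root.
#'
#' @param recon result of [sankoff_reconstruct()].
#' @param tree the rooted tree used for the reconstruction.
#' @return data frame: node, dist_root, mean_change, is_tip.
#' @export
branch_changes <- function(recon, tree) {
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  root <- n_tip + 1L
  dist_root <- numeric(n_nodes)
  tree_po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(tree_po$edge)))
  for (k in pre) {
    par <- tree_po$edge[k, 1]; child <- tree_po$edge[k, 2]
    dist_root[child] <- dist_root[par] + tree_po$edge.length[k]
  }
  st <- recon$states
  rootname <- tree$node.label[1]
  root_states <- st[, c(tree$tip.label, tree$node.label)[root]]
  mean_change <- vapply(seq_len(n_nodes), function(nd) {
    mean(st[, nd] - root_states, na.rm = TRUE)
  }, 0)
  data.frame(node = c(tree$tip.label, tree$node.label),
             dist_root = dist_root, mean_change = mean_change,
             is_tip = seq_len(n_nodes) <= n_tip)
}

gauss_kernel <- function(sd, trunc = 4) {
  r <- ceiling(trunc * sd)
  k <- exp(-((-r:r)^2) / (2 * sd^2))
  k / sum(k)
}

conv1 <- function(v, kern) {
  r <- (length(kern) - 1) / 2
  vp <- c(rep(0, r), v, rep(0, r))
  out <- stats::filter(vp, kern, sides = 2)
  as.numeric(out[(r + 1):(r + length(v))])
}

# zero-padded convolution renormalised by the in-window kernel mass, so
# peaks near the grid boundary are not pulled inward
conv1_norm <- function(v, kern) {
  conv1(v, kern) / conv1(rep(1, length(v)), kern)
}

#' Mode lines of the joint ancestral vs extant size distribution
#'
#' Builds the 2-D histogram of (ancestral state, extant state) on the
#' integral state grid for introns longer than `min_bp`, standardises each
#' ancestral-state column to mean 0 / sd 1, applies a separable Gaussian
#' blur (sd in states, kernel truncated at 4 sd), extracts the local maxima
#' of each column, joins peaks across adjacent columns into lines
#' (interpolating across gaps of up to three empty columns), and smooths
#' each line with a normal kernel.
#'
#' @param anc_states integer ancestral states (one per intron) at the
#'   reference ancestor node.
#' @param extant_states integer extant states for one species or clade
#'   summary.
#' @param extant_lengths extant lengths in bp (for the `> min_bp` filter);
#'   defaults to `decode_size(extant_states)`.
#' @param blur_sd Gaussian blur sd in states.
#' @param min_bp introns at or below this extant size are excluded.
#' @param taxon label attached to the result.
#' @param join_tol maximal state distance when chaining peaks between
#'   neighbouring columns.
#' @return list of mode lines, each a data frame (anc_state, extant_state);
#'   attribute `taxon`.
#' @export
mode_lines <- function(anc_states, extant_states, extant_lengths = NULL,
                       blur_sd = 6, min_bp = 75, taxon = NA_character_,
                       join_tol = 8) {
  if (is.null(extant_lengths)) extant_lengths <- decode_size(extant_states)
  keep <- !is.na(anc_states) & !is.na(extant_states) &
    extant_lengths > min_bp
  a <- anc_states[keep]; e <- extant_states[keep]
  if (length(a) == 0) return(structure(list(), taxon = taxon))
  ar <- range(a); er <- range(e)
  acol <- seq.int(ar[1], ar[2]); erow <- seq.int(er[1], er[2])
  H <- matrix(0, length(erow), length(acol))
  tab <- table(factor(e, levels = erow), factor(a, levels = acol))
  H[] <- as.numeric(tab)
  col_n <- colSums(H)
  # column-wise standardisation (columns with data only)
  for (j in which(col_n > 0)) {
    v <- H[, j]
    s <- sd(v)
    H[, j] <- if (!is.na(s) && s > 0) (v - mean(v)) / s else 0
  }
  kern <- gauss_kernel(blur_sd)
  H <- apply(H, 2, conv1_norm, kern = kern)
  if (is.null(dim(H))) H <- matrix(H, nrow = length(erow))
  H <- t(apply(H, 1, conv1_norm, kern = kern))
  if (is.null(dim(H)) || nrow(H) != length(erow))
    H <- matrix(H, nrow = length(erow), ncol = length(acol))
  # per-column local maxima
  peaks_by_col <- lapply(seq_along(acol), function(j) {
    if (col_n[j] == 0) return(integer(0))
    v <- H[, j]
    n <- length(v)
    if (n < 3) return(which.max(v))
    p <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
    if (length(p) == 0) p <- which.max(v)
    p
  })
  # chain peaks into lines
  lines <- list()   # each: list(cols, rows, last_col)
  for (j in seq_along(acol)) {
    for (p in peaks_by_col[[j]]) {
      attached <- FALSE
      if (length(lines)) {
        cand <- which(vapply(lines, function(L)
          j - L$last_col >= 1 && j - L$last_col <= 4 &&
            abs(L$rows[length(L$rows)] - p) <= join_tol, TRUE))
        if (length(cand)) {
          dists <- vapply(cand, function(ci)
            abs(lines[[ci]]$rows[length(lines[[ci]]$rows)] - p), 0)
          ci <- cand[which.min(dists)]
          if (lines[[ci]]$last_col < j) {
            lines[[ci]]$cols <- c(lines[[ci]]$cols, j)
            lines[[ci]]$rows <- c(lines[[ci]]$rows, p)
            lines[[ci]]$last_col <- j
            attached <- TRUE
          }
        }
      }
      if (!attached)
        lines[[length(lines) + 1]] <- list(cols = j, rows = p, last_col = j)
    }
  }
  out <- lapply(lines, function(L) {
    anc <- acol[L$cols]
    ext <- erow[L$rows]
    if (length(anc) > 2) {
      # interpolate across gaps, then smooth along the line
      full <- seq.int(min(anc), max(anc))
      ext_f <- approx(anc, ext, xout = full)$y
      ext_f <- conv1(ext_f, gauss_kernel(2)) /
        conv1(rep(1, length(ext_f)), gauss_kernel(2))
      data.frame(anc_state = full, extant_state = ext_f)
    } else data.frame(anc_state = anc, extant_state = ext)
  })
  structure(out, taxon = taxon)
}

#' Proportion of minimised introns per ancestral-size bin
#'
#' For each bin of ancestral size state, the fraction of introns whose
#' extant length lies within the minimised window (default 76-100 bp).
#' Empty bins are reported as `NA`, not zero.
#'
#' @param anc_states integer ancestral states, one per intron.
#' @param extant_lengths extant lengths (bp) in the species of interest.
#' @param window minimised length window in bp (inclusive).
#' @param bin_width ancestral bin width in states (10 = one log2 unit).
#' @return data frame: bin_lo, bin_hi (states), n, proportion.
#' @export
minimised_proportion <- function(anc_states, extant_lengths,
                                 window = c(76, 100), bin_width = 10L) {
  keep <- !is.na(anc_states) & !is.na(extant_lengths)
  a <- anc_states[keep]; x <- extant_lengths[keep]
  if (length(a) == 0) stop("no introns")
  lo <- floor(min(a) / bin_width) * bin_width
  hi <- ceiling((max(a) + 1) / bin_width) * bin_width
  breaks <- seq.int(lo, hi, by = bin_width)
  bin <- cut(a, breaks = breaks, right = FALSE)
  minim <- x >= window[1] & x <= window[2]
  n <- as.vector(table(bin))
  prop <- as.vector(tapply(minim, bin, mean))
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             n = n, proportion = ifelse(n == 0, NA_real_, prop))
}
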
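#' Per-gene length statistic: largest clade-minimal intron length
#'
#' For each reference intron, the minimum length across the clade species
#' with data; for each gene, the maximum of those minima. Genes without any
#' intron data in the clade are excluded with a warning.
#'
#' @param orthology an `orthology_table` from [build_orthology()].
#' @param clade character vector of clade species (>= 2 present in the
#'   table).
#' @return named numeric vector: gene (family) -> statistic (bp).
#' @export
gene_length_statistic <- function(orthology, clade) {
  m <- orthology$lengths
  clade <- intersect(clade, colnames(m))
  stopifnot(length(clade) >= 2)
  sub <- m[, clade, drop = FALSE]
  nobs <- rowSums(!is.na(sub))
  mins <- suppressWarnings(apply(sub, 1, min, na.rm = TRUE))
  mins[nobs == 0] <- NA_real_
  gene <- sub("^(.*):\\d+$", "\\1", rownames(m))
  val <- tapply(mins, gene, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  drop <- is.na(val)
  if (any(drop))
    warning(sum(drop), " gene(s) without clade intron data excluded")
  out <- val[!drop]
  setNames(as.numeric(out), names(out))
}

#' Nested-set depletion scan of functional terms
#'
#' Genes are ordered by a length statistic; for every threshold `T` the
#' nested set is the genes with value `<= T`, and for every term the
#' lower-tail hypergeometric depletion probability
#' `P(X <= q)` is computed with `q` term members in the set, `m` members
#' overall, `k` set size, `N` genes total, together with
#' `log2(observed/expected)`. Terms with fewer than `min_m` member genes
#' (among genes with a statistic) are skipped.
#'
#' @param gene_values named vector from [gene_length_statistic()].
#' @param term_table data frame `gene_id`, `term_id`.
#' @param thresholds ascending thresholds (bp); defaults to every distinct
#'   observed gene value, downsampled to at most `max_thresholds`.
#' @param min_m minimal term size (default 5).
#' @param max_thresholds cap on the threshold grid (default 512).
#' @return object of class `depletion_scan`: list with `curves` (long data
#'   frame term, threshold, threshold_log2, k, q, m, N, p, log2_obs_exp),
#'   `minima` (per-term threshold of minimal p), `n_terms_tested`.
#' @export
nested_depletion_scan <- function(gene_values, term_table,
                                  thresholds = NULL, min_m = 5L,
                                  max_thresholds = 512L) {
  genes <- names(gene_values)
  N <- length(genes)
  if (is.null(thresholds)) {
    thresholds <- sort(unique(gene_values))
    if (length(thresholds) > max_thresholds)
      thresholds <- thresholds[unique(round(seq(1, length(thresholds),
                                                length.out =
                                                  max_thresholds)))]
  }
  stopifnot(!is.unsorted(thresholds))
  tt <- term_table[term_table$gene_id %in% genes, , drop = FALSE]
  terms <- split(tt$gene_id, tt$term_id)
  terms <- terms[vapply(terms, length, 0L) >= min_m]
  if (length(terms) < 2) stop("fewer than 2 usable terms")
  ord_val <- sort(gene_values)
  k_at <- findInterval(thresholds, ord_val)   # |{gene: value <= T}|
  curves <- lapply(names(terms), function(te) {
    members <- unique(terms[[te]])
    mvals <- sort(gene_values[members])
    m <- length(mvals)
    q <- findInterval(thresholds, mvals)
    k <- k_at
    p <- phyper(q, m, N - m, k)
    exp_q <- k * m / N
    data.frame(term = te, threshold = thresholds,
               threshold_log2 = log2(thresholds),
               k = k, q = q, m = m, N = N, p = p,
               log2_obs_exp = log2(q / exp_q))
  })
  curves <- do.call(rbind, curves)
  curves <- curves[curves$k >= 1, , drop = FALSE]
  minima <- do.call(rbind, lapply(split(curves, curves$term), function(d) {
    i <- which.min(d$p)
    data.frame(term = d$term[1], threshold = d$threshold[i],
               threshold_log2 = d$threshold_log2[i], min_p = d$p[i],
               k = d$k[i], q = d$q[i], m = d$m[1])
  }))
  rownames(minima) <- NULL
  out <- list(curves = curves, minima = minima,
              n_terms_tested = length(terms))
  class(out) <- "depletion_scan"
  out
}

#' Random-intron control gene set
#'
#' Samples introns from the orthology without replacement and returns the
#' genes owning them, reproducibly under a seed. Used to verify that a
#' depletion signal follows gene length, not gene sampling.
#'
#' @param orthology an `orthology_table`.
#' @param n_introns number of introns to sample.
#' @param seed integer seed.
#' @return character vector of gene (family) ids.
#' @export
random_gene_control <- function(orthology, n_introns, seed = 1L) {
  keys <- rownames(orthology$lengths)
  stopifnot(n_introns <= length(keys))
  set.seed(seed)
  picked <- sample(keys, n_introns)
  sort(unique(sub("^(.*):\\d+$", "\\1", picked)))
}
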
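#' Discretise intron sizes into integral log2 bins
#'
#' @param x intron lengths in bp.
#' @return integer bin per intron (`floor(log2(x))`).
#' @export
log2_bins <- function(x) as.integer(floor(log2(x)))

entropy_counts <- function(n) {
  p <- n[n > 0] / sum(n)
  -sum(p * log2(p))
}

#' Shannon entropy (bits) of a discrete sample
#'
#' Plug-in (maximum-likelihood) estimator in log base 2.
#'
#' @param x discrete values (factors, integers, bins).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(x) entropy_counts(table(x))

#' Plug-in mutual information between two species' intron sizes
#'
#' Maximum-likelihood mutual information (bits) of the discretised joint
#' distribution over shared orthologous introns. The default bin scheme is
#' integral log2 length bins, matching the log2 analysis scale; pass
#' `bin_scheme = "none"` when the inputs are already discrete.
#'
#' @param a,b paired observations (lengths in bp, or discrete values with
#'   `bin_scheme = "none"`); pairs with `NA` in either are dropped.
#' @param bin_scheme `"log2"` or `"none"`.
#' @param min_n minimal number of complete pairs (default 100).
#' @return mutual information in bits.
#' @export
mutual_information <- function(a, b, bin_scheme = "log2", min_n = 100L) {
  bin_scheme <- match.arg(bin_scheme, c("log2", "none"))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < min_n)
    stop("too few paired introns (", length(a), " < ", min_n, ")")
  if (bin_scheme == "log2") { a <- log2_bins(a); b <- log2_bins(b) }
  ha <- entropy_counts(table(a))
  hb <- entropy_counts(table(b))
  hab <- entropy_counts(table(a, b))
  max(ha + hb - hab, 0)
}

#' Permutation test for intron-size mutual information
#'
#' Permutes one margin and recomputes the plug-in MI; the p-value uses the
#' add-one estimator `p = (1 + #{MI_perm >= MI_obs}) / (n_perm + 1)`, so it
#' is never exactly zero and has resolution `1/(n_perm+1)`.
#'
#' @inheritParams mutual_information
#' @param n_perm number of random permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return list with `mi` (bits), `p_value`, `n`, `n_perm`.
#' @export
mi_permutation_test <- function(a, b, bin_scheme = "log2",
                                n_perm = 10000L, seed = 1L,
                                min_n = 100L) {
  bin_scheme <- match.arg(bin_scheme, c("log2", "none"))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < min_n)
    stop("too few paired introns (", length(a), " < ", min_n, ")")
  if (bin_scheme == "log2") { a <- log2_bins(a); b <- log2_bins(b) }
  fa <- factor(a); fb <- factor(b)
  ia <- as.integer(fa); ib <- as.integer(fb)
  na <- nlevels(fa); nb <- nlevels(fb)
  n <- length(ia)
  ha <- entropy_counts(tabulate(ia, na))
  hb <- entropy_counts(tabulate(ib, nb))
  joint <- function(iaa, ibb)
    entropy_counts(tabulate(iaa + (ibb - 1L) * na, na * nb))
  mi_obs <- max(ha + hb - joint(ia, ib), 0)
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    mi_p <- ha + hb - joint(ia, ib[sample.int(n)])
    if (mi_p >= mi_obs - 1e-12) hits <- hits + 1L
  }
  list(mi = mi_obs, p_value = (1 + hits) / (n_perm + 1),
       n = n, n_perm = n_perm)
}

#' Quantile cross-prediction of intron size between clades
#'
#' Among introns whose reference-clade median length exceeds a threshold,
#' the fraction whose target-clade median exceeds the target clade's own
#' 50th and 95th percentiles, with log2 observed/expected ratios (expected
#' 0.5 and 0.05 under independence).
#'
#' @param ref_median,target_median per-intron median lengths (bp) over each
#'   clade's species; pairs with `NA` dropped.
#' @param threshold_log2 log2 length threshold applied to the reference
#'   clade medians.
#' @return list: `n_above`, `frac50`, `frac95`, `log2_obs_exp50`,
#'   `log2_obs_exp95`, and the target percentile cutoffs used.
#' @export
quantile_cross_prediction <- function(ref_median, target_median,
                                      threshold_log2) {
  ok <- !is.na(ref_median) & !is.na(target_median)
  r <- ref_median[ok]; t <- target_median[ok]
  q50 <- quantile(t, 0.5, names = FALSE)
  q95 <- quantile(t, 0.95, names = FALSE)
  sel <- log2(r) > threshold_log2
  if (sum(sel) < 20)
    warning("only ", sum(sel), " introns above threshold")
  frac50 <- mean(t[sel] > q50)
  frac95 <- mean(t[sel] > q95)
  list(n_above = sum(sel), frac50 = frac50, frac95 = frac95,
       log2_obs_exp50 = log2(frac50 / 0.5),
       log2_obs_exp95 = log2(frac95 / 0.05),
       target_q50 = q50, target_q95 = q95)
}

#' Size-partitioned correlation of intron sizes between two species
#'
#' Pairs where both introns are at least `floor_bp` long are restricted to
#' the reference species' 99th percentile (outlier control); the remaining
#' log2 size range of the reference is split at its midpoint into two
#' equal-range sets, and the Pearson correlation of log2 sizes is computed
#' within each. Sizes are constrained for the reference species only.
#'
#' @param ref,partner paired intron lengths (bp).
#' @param floor_bp minimal length in both species (default 76).
#' @param cap_quantile upper quantile bound on the reference (default 0.99).
#' @param min_n minimal pairs per set.
#' @return list: `r_short`, `r_long`, `ratio` (`r_long / r_short`),
#'   `unreliable` (`TRUE` when `|r_short| < 0.05`), `split_log2`, `n_short`,
#'   `n_long`.
#' @export
size_partition_correlations <- function(ref, partner, floor_bp = 76,
                                        cap_quantile = 0.99, min_n = 30L) {
  ok <- !is.na(ref) & !is.na(partner) & ref >= floor_bp &
    partner >= floor_bp
  r <- log2(ref[ok]); p <- log2(partner[ok])
  cap <- quantile(r, cap_quantile, names = FALSE)
  keep <- r <= cap
  r <- r[keep]; p <- p[keep]
  lo <- log2(floor_bp)
  mid <- (lo + cap) / 2
  short <- r < mid
  if (sum(short) < min_n || sum(!short) < min_n)
    stop("a partition holds fewer than ", min_n, " pairs")
  r_short <- cor(r[short], p[short])
  r_long <- cor(r[!short], p[!short])
  list(r_short = r_short, r_long = r_long, ratio = r_long / r_short,
       unreliable = abs(r_short) < 0.05, split_log2 = mid,
       n_short = sum(short), n_long = sum(!short))
}
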
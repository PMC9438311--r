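rank_filter_idx <- function(introns, rank_filter) {
  switch(match.arg(rank_filter, c("all", "first", "later")),
         all = rep(TRUE, nrow(introns)),
         first = introns$rank == 1L,
         later = introns$rank > 1L)
}

#' Gaussian-kernel density of log2 intron size
#'
#' @param introns an intron catalogue (one species) from
#'   [extract_introns()], or any data frame with `length` and `rank`.
#' @param rank_filter `"all"`, `"first"` (rank 1) or `"later"` (rank > 1).
#' @param bandwidth Gaussian kernel standard deviation in log2 units.
#'   The default (0.25) resolves the minimal-intron peak from a trough at
#'   around 256 bp without over-smoothing.
#' @param grid_range,grid_n log2-size grid (default 2^4..2^20, 512 points).
#' @param min_n minimum intron count after filtering.
#' @return object of class `size_density`: list with `species`, `grid`
#'   (log2 sizes), `density` (normalised to integrate to 1 over the grid),
#'   `rank_filter`, `n`.
#' @export
size_density <- function(introns, rank_filter = "all", bandwidth = 0.25,
                         grid_range = c(4, 20), grid_n = 512L, min_n = 50L) {
  keep <- rank_filter_idx(introns, rank_filter)
  x <- log2(introns$length[keep])
  sp <- unique(introns$species)
  if (length(x) < min_n)
    stop("too few introns (", length(x), ") for species ",
         paste(sp, collapse = ","))
  d <- density(x, bw = bandwidth, from = grid_range[1], to = grid_range[2],
               n = grid_n)
  y <- d$y
  step <- diff(d$x[1:2])
  area <- sum((y[-1] + y[-length(y)]) / 2) * step
  y <- y / area
  out <- list(species = if (length(sp) == 1) sp else NA_character_,
              grid = d$x, density = y, rank_filter = rank_filter,
              bandwidth = bandwidth, n = length(x))
  class(out) <- "size_density"
  out
}

#' Locate the antimode (trough) of a bimodal size density
#'
#' Finds the two highest local maxima of the density inside `[lo, hi]` and
#' returns the log2 size at which the density is minimal between them, or
#' `NA` if the density has fewer than two peaks in the window.
#'
#' @param dens a `size_density`.
#' @param lo,hi log2-size window searched for peaks.
#' @param min_peak_frac local maxima below this fraction of the window's
#'   maximal density are ignored (guards against floating-point ripple in
#'   the far tails).
#' @return log2 size of the antimode, or `NA_real_` if unimodal.
#' @export
find_antimode <- function(dens, lo = 4, hi = 20, min_peak_frac = 0.01) {
  stopifnot(inherits(dens, "size_density"), lo < hi)
  g <- dens$grid; y <- dens$density
  w <- which(g >= lo & g <= hi)
  if (length(w) < 3) return(NA_real_)
  yi <- y[w]
  n <- length(yi)
  peak <- which(yi[2:(n - 1)] > yi[1:(n - 2)] &
                yi[2:(n - 1)] >= yi[3:n]) + 1L
  peak <- peak[yi[peak] >= min_peak_frac * max(yi)]
  if (length(peak) < 2) return(NA_real_)
  top2 <- peak[order(-yi[peak])][1:2]
  a <- min(top2); b <- max(top2)
  if (b - a < 2) return(NA_real_)
  seg <- (a + 1):(b - 1)
  g[w[seg[which.min(yi[seg])]]]
}

#' Fraction of introns shorter than a threshold
#'
#' Strict `<` at the threshold.
#'
#' @param introns intron catalogue.
#' @param threshold_bp threshold in base pairs (>= 1).
#' @param rank_filter `"all"`, `"first"` or `"later"`.
#' @return proportion in `[0, 1]`.
#' @export
fraction_below <- function(introns, threshold_bp = 256, rank_filter = "all") {
  stopifnot(threshold_bp >= 1)
  keep <- rank_filter_idx(introns, rank_filter)
  x <- introns$length[keep]
  if (length(x) == 0) stop("no introns after filtering")
  mean(x < threshold_bp)
}

#' Species quality filter on implausibly short introns
#'
#' Retains species whose fraction of introns shorter than `min_bp` is at
#' most `max_fraction` (the boundary is inclusive: exactly `max_fraction`
#' passes).
#'
#' @param catalogue combined intron catalogue across species.
#' @param min_bp,max_fraction QC thresholds (defaults 32 bp, 2.5%).
#' @return character vector of included species.
#' @export
qc_species_filter <- function(catalogue, min_bp = 32, max_fraction = 0.025) {
  stopifnot(nrow(catalogue) > 0)
  frac <- tapply(catalogue$length < min_bp, catalogue$species, mean)
  names(frac)[frac <= max_fraction]
}
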
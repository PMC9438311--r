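default_local_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = -4, gap_ext = -1)
}

#' Recursive non-overlapping local alignment
#'
#' Finds the optimal Smith-Waterman local alignment between a seed and a
#' partner sequence, masks the aligned seed interval with a sentinel symbol
#' and recurses until the best score drops below `min_score`. Seed intervals
#' of the reported hits are therefore pairwise disjoint; partner intervals
#' may overlap. A gap of length L costs `|gap_open| + L * |gap_ext|`.
#'
#' @param seed,partner DNA sequences (character strings).
#' @param scoring list `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @param min_score smallest reportable alignment score (default 20, the
#'   score of a 20 bp exact match).
#' @param max_space maximal search space `nchar(seed) * nchar(partner)`;
#'   larger pairs raise an error (callers skip and log them).
#' @return data frame: round, score, seed_start, seed_end, partner_start,
#'   partner_end (1-based inclusive); zero rows if nothing reaches
#'   `min_score`.
#' @export
recursive_local_align <- function(seed, partner,
                                  scoring = default_local_scoring(),
                                  min_score = 20, max_space = 1e8) {
  l1 <- nchar(seed); l2 <- nchar(partner)
  if (as.numeric(l1) * l2 > max_space)
    stop("search space ", l1, " x ", l2, " exceeds max_space")
  a <- encode_dna(seed); b <- encode_dna(partner)
  hits <- list()
  round <- 0L
  repeat {
    h <- .sw_top_hit_cpp(a, b, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_ext)
    if (h$score < min_score) break
    round <- round + 1L
    hits[[round]] <- data.frame(round = round, score = h$score,
                                seed_start = h$a_start, seed_end = h$a_end,
                                partner_start = h$b_start,
                                partner_end = h$b_end)
    a[h$a_start:h$a_end] <- -1L   # sentinel: mismatches everything
  }
  if (length(hits) == 0)
    return(data.frame(round = integer(), score = numeric(),
                      seed_start = integer(), seed_end = integer(),
                      partner_start = integer(), partner_end = integer()))
  do.call(rbind, hits)
}

#' Select intron sets by clade length profile
#'
#' Labels reference-anchored introns by their minimal length across a clade:
#' `long` (clade minimum >= `long_bp`, all such introns), `med`
#' (lowest-variance `n_per_set` introns with clade minimum in
#' `(med_bp, long_bp)`), `short_lowvar` and `short_rand` (clade minimum in
#' `[short_bp, med_bp)`; lowest-variance and seeded-random samples), and
#' `ctl` (clade median < `med_bp` but reference length > `long_bp`,
#' seeded-random sample). Sets smaller than `n_per_set` use all members
#' with a warning.
#'
#' @param orthology an `orthology_table`.
#' @param clade clade species used for the length profile.
#' @param n_per_set target set size (the paper-scale default is 2000;
#'   cohort-scale analyses use smaller values).
#' @param long_bp,med_bp,short_bp class boundaries (1024/256/90 bp).
#' @param seed seed for the random samples.
#' @return named list of character vectors of intron keys (`family:rank`).
#' @export
select_intron_sets <- function(orthology, clade, n_per_set = 2000L,
                               long_bp = 1024, med_bp = 256, short_bp = 90,
                               seed = 1L) {
  m <- orthology$lengths
  clade <- intersect(clade, colnames(m))
  stopifnot(length(clade) >= 2)
  sub <- m[, clade, drop = FALSE]
  nobs <- rowSums(!is.na(sub))
  cmin <- suppressWarnings(apply(sub, 1, min, na.rm = TRUE))
  cmed <- apply(sub, 1, median, na.rm = TRUE)
  cvar <- apply(log2(sub), 1, function(v)
    if (sum(!is.na(v)) >= 2) var(v, na.rm = TRUE) else Inf)
  cmin[nobs == 0] <- NA
  ref_len <- m[, orthology$reference]
  keys <- rownames(m)
  ok <- !is.na(cmin)

  take_lowvar <- function(idx) {
    idx <- idx[order(cvar[idx], keys[idx])]
    head(idx, n_per_set)
  }
  take_rand <- function(idx, s) {
    if (length(idx) <= n_per_set) return(idx)
    set.seed(s)
    sort(sample(idx, n_per_set))
  }
  long_i <- which(ok & cmin >= long_bp)
  med_i <- which(ok & cmin > med_bp & cmin < long_bp)
  short_i <- which(ok & cmin >= short_bp & cmin < med_bp)
  ctl_i <- which(ok & cmed < med_bp & !is.na(ref_len) & ref_len > long_bp)
  sets <- list(long = long_i,
               med = take_lowvar(med_i),
               short_lowvar = take_lowvar(short_i),
               short_rand = take_rand(short_i, seed),
               ctl = take_rand(ctl_i, seed + 1L))
  small <- names(sets)[vapply(sets, length, 0L) < n_per_set]
  small <- setdiff(small, "long")
  if (length(small))
    warning("set(s) smaller than requested n: ",
            paste(small, collapse = ", "))
  lapply(sets, function(i) keys[i])
}

#' Count genome loci matching a sequence (k-mer seeded)
#'
#' For each query, k-mers sampled at a fixed stride are matched exactly
#' against the genome; matches are clustered by diagonal into candidate
#' loci, and loci whose k-mer support covers at least `min_cov` of the query
#' length are counted. The query's own source locus counts once.
#'
#' @param seqs character vector of query sequences.
#' @param genome `DNAStringSet` or FASTA path.
#' @param k k-mer size (default 31).
#' @param stride sampling stride along the query (default 10).
#' @param min_cov minimal covered fraction of the query (default 0.5).
#' @return integer vector of locus counts (0 when even the query's own
#'   k-mers fail to match, e.g. for sequences the counter cannot anchor).
#' @export
count_genome_hits <- function(seqs, genome, k = 31L, stride = 10L,
                              min_cov = 0.5) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  vapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(0L)
    starts <- unique(c(seq(1L, L - k + 1L, by = stride), L - k + 1L))
    kmers <- substring(s, starts, starts + k - 1L)
    diag_hits <- list()
    for (i in seq_along(kmers)) {
      mt <- Biostrings::vmatchPattern(kmers[i], genome)
      pos <- unlist(lapply(mt, Biostrings::start), use.names = FALSE)
      if (length(pos))
        diag_hits[[length(diag_hits) + 1L]] <-
          data.frame(spos = starts[i], diag = pos - starts[i])
    }
    if (length(diag_hits) == 0) return(0L)
    dh <- do.call(rbind, diag_hits)
    dh <- dh[order(dh$diag, dh$spos), , drop = FALSE]
    brk <- c(0L, which(diff(dh$diag) > k), nrow(dh))
    n_loci <- 0L
    for (ci in seq_len(length(brk) - 1L)) {
      cl <- dh[(brk[ci] + 1L):brk[ci + 1L], , drop = FALSE]
      covered <- length(unique(cl$spos)) * stride
      if (covered >= min_cov * L) n_loci <- n_loci + 1L
    }
    n_loci
  }, 0L, USE.NAMES = FALSE)
}

#' Repeat filter on seed sequences
#'
#' Removes sequences the genome hit counter reports at more than two loci
#' (repeats) or at none at all (unanchorable, e.g. simple repeats);
#' sequences at one or two loci are retained.
#'
#' @param counts integer locus counts, e.g. from [count_genome_hits()].
#' @return logical vector: keep.
#' @export
repeat_filter <- function(counts) counts >= 1L & counts <= 2L

#' Fit the search-space null model for local alignment scores
#'
#' Least-squares fit of `log(S_max)` on `log(search space)` over control
#' points (top scores of non-orthologous seeds against each orthologue
#' set); the residual cutoff is the 95th percentile of the control
#' residuals. Natural logs are used; the scale choice cancels in the
#' percentile flagging.
#'
#' @param scores control top scores (> 0).
#' @param spaces search spaces (`l_seed * sum(l_partners)`).
#' @param min_points minimal number of control points (default 50).
#' @param cutoff_quantile residual percentile (default 0.95).
#' @return object of class `conservation_null`: list `intercept`, `slope`,
#'   `cutoff`, `residuals`, `n`.
#' @export
fit_null_model <- function(scores, spaces, min_points = 50L,
                           cutoff_quantile = 0.95) {
  ok <- !is.na(scores) & !is.na(spaces) & scores > 0 & spaces > 0
  if (sum(ok) < min_points)
    stop("only ", sum(ok), " control points (need ", min_points, ")")
  x <- log(spaces[ok]); y <- log(scores[ok])
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  out <- list(intercept = unname(fit$coefficients[1]),
              slope = unname(fit$coefficients[2]),
              cutoff = quantile(res, cutoff_quantile, names = FALSE),
              residuals = res, n = sum(ok))
  class(out) <- "conservation_null"
  out
}

#' Flag conserved orthologue sets against the null model
#'
#' @param scores per-orthologue-set top scores (max over partner species);
#'   `NA` marks sets with no alignable partner (reported as no-data).
#' @param spaces matching search spaces.
#' @param model a `conservation_null`.
#' @param labels set label per entry (e.g. long/med/short/ctl).
#' @return list with `calls` (data frame label, score, space, residual,
#'   flagged) and `proportions` (per label: flagged fraction over sets with
#'   data, plus counts).
#' @export
conservation_calls <- function(scores, spaces, model, labels) {
  pred <- model$intercept + model$slope * log(spaces)
  resid <- log(pmax(scores, 1)) - pred
  flagged <- resid > model$cutoff
  calls <- data.frame(label = labels, score = scores, space = spaces,
                      residual = resid, flagged = flagged)
  props <- do.call(rbind, lapply(split(calls, calls$label), function(d) {
    has <- !is.na(d$score)
    data.frame(label = d$label[1], n = nrow(d), n_data = sum(has),
               flagged = sum(d$flagged[has]),
               proportion = if (any(has)) mean(d$flagged[has]) else NA_real_)
  }))
  rownames(props) <- NULL
  list(calls = calls, proportions = props)
}

# intron sequences in transcription orientation for one species, keyed
# "<gene>:<rank>" (gene ids are species-local)
intron_sequences <- function(files, catalogue, sp) {
  genome <- Biostrings::readDNAStringSet(files[[sp]]$fasta)
  chrom_seq <- setNames(as.character(genome),
                        sub("\\s.*$", "", names(genome)))
  d <- catalogue[catalogue$species == sp, , drop = FALSE]
  seqs <- substring(chrom_seq[d$chrom], d$start, d$end)
  neg <- d$strand == "-"
  seqs[neg] <- vapply(seqs[neg], revcomp, "")
  setNames(seqs, paste0(d$gene, ":", d$rank))
}

#' Conservation scan over orthologous intron sets
#'
#' End-to-end driver: selects intron sets by clade length profile, aligns
#' each reference (seed) intron against its orthologues in the partner
#' species and records the top score per orthologue set; builds matched
#' controls by aligning a non-orthologous reference intron of similar
#' length (nearest length within 25%) against the same partners; removes
#' repeat-like seeds with the genome hit counter; fits the search-space
#' null model on the controls and flags orthologue sets whose residual
#' exceeds the 95th control percentile.
#'
#' @param files per-species `gff`/`fasta` paths (as in an `intron_cohort`).
#' @param orthology an `orthology_table`.
#' @param catalogue cohort-wide intron catalogue.
#' @param family_table family table (family_id, species, gene_id).
#' @param clade species whose minimal lengths define the sets.
#' @param partners partner species aligned against the seeds (default: the
#'   clade).
#' @param n_per_set set size passed to [select_intron_sets()].
#' @param scoring,min_score,max_space see [recursive_local_align()].
#' @param seed RNG seed for set sampling.
#' @param skip_repeat_filter set `TRUE` to skip the genome hit counting
#'   (the synthetic cohort has unique-sequence introns; counting is then
#'   pure overhead).
#' @return list with `sets`, `calls`, `proportions`, `model`, `controls`.
#' @export
scan_conservation <- function(files, orthology, catalogue, family_table,
                              clade, partners = clade, n_per_set = 200L,
                              scoring = default_local_scoring(),
                              min_score = 20, max_space = 1e8, seed = 1L,
                              skip_repeat_filter = FALSE) {
  ref <- orthology$reference
  sets <- select_intron_sets(orthology, clade, n_per_set = n_per_set,
                             seed = seed)
  keys <- unique(unlist(sets))
  labels_of <- rep(names(sets), lengths(sets))
  names(labels_of) <- unlist(sets)

  gene_lookup <- setNames(family_table$gene_id,
                          paste(family_table$species,
                                family_table$family_id, sep = "\r"))
  ref_seqs <- intron_sequences(files, catalogue, ref)
  partner_seqs <- lapply(setdiff(partners, ref), function(sp)
    intron_sequences(files, catalogue, sp))
  names(partner_seqs) <- setdiff(partners, ref)

  key_fam <- sub("^(.*):\\d+$", "\\1", keys)
  key_rank <- as.integer(sub("^.*:(\\d+)$", "\\1", keys))
  seed_key <- paste0(gene_lookup[paste(ref, key_fam, sep = "\r")], ":",
                     key_rank)
  seed_seq <- unname(ref_seqs[seed_key])
  seed_len <- nchar(seed_seq)

  # non-orthologous control seed: nearest reference intron length within
  # 25%, from a different family
  ref_all_len <- nchar(ref_seqs)
  # names are "<gene>:<rank>" with gene "<species>.<family>"
  ref_all_fam <- sub(":.*$", "", sub("^[^.]*\\.", "", names(ref_seqs)))
  pick_control <- function(i) {
    len <- seed_len[i]
    cand <- which(ref_all_fam != key_fam[i] &
                    abs(ref_all_len - len) <= 0.25 * len)
    if (length(cand) == 0)
      cand <- which(ref_all_fam != key_fam[i])
    cand[order(abs(ref_all_len[cand] - len),
               names(ref_seqs)[cand])][1]
  }

  m_orth <- orthology$matches
  top_score <- function(seedseq, fam, rank) {
    best <- NA_real_; space <- 0
    enc_seed <- encode_dna(seedseq)
    for (sp in names(partner_seqs)) {
      g <- gene_lookup[paste(sp, fam, sep = "\r")]
      hit <- m_orth$family == fam & m_orth$rank_ref == rank &
        m_orth$species == sp
      if (!any(hit)) next
      pr <- m_orth$rank_partner[which(hit)[1]]
      pseq <- partner_seqs[[sp]][paste0(g, ":", pr)]
      if (is.na(pseq)) next
      if (as.numeric(nchar(seedseq)) * nchar(pseq) > max_space) next
      space <- space + nchar(pseq)
      h <- .sw_top_hit_cpp(enc_seed, encode_dna(pseq),
                           scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_ext)
      if (is.na(best) || h$score > best) best <- h$score
    }
    c(score = best, space = as.numeric(nchar(seedseq)) * space)
  }

  n <- length(keys)
  obs <- matrix(NA_real_, n, 2, dimnames = list(keys, c("score", "space")))
  ctl <- matrix(NA_real_, n, 2, dimnames = list(keys, c("score", "space")))
  for (i in seq_len(n)) {
    obs[i, ] <- top_score(seed_seq[i], key_fam[i], key_rank[i])
    ci <- pick_control(i)
    ctl[i, ] <- top_score(unname(ref_seqs[ci]), key_fam[i], key_rank[i])
  }

  keep <- rep(TRUE, n)
  if (!skip_repeat_filter) {
    counts <- count_genome_hits(seed_seq,
                                files[[ref]]$fasta)
    keep <- repeat_filter(counts)
  }
  ok_ctl <- keep & !is.na(ctl[, "score"]) & ctl[, "space"] > 0
  model <- fit_null_model(pmax(ctl[ok_ctl, "score"], 1),
                          ctl[ok_ctl, "space"])
  use <- keep & !is.na(obs[, "score"]) & obs[, "space"] > 0
  res <- conservation_calls(obs[use, "score"], obs[use, "space"], model,
                            labels_of[keys[use]])
  list(sets = sets, calls = res$calls, proportions = res$proportions,
       model = model,
       controls = data.frame(key = keys[ok_ctl],
                             score = ctl[ok_ctl, "score"],
                             space = ctl[ok_ctl, "space"]))
}
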
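default_sticky_scoring <- function() {
  list(match = 1, mismatch = -1, gap = -2, meta_bonus = 10)
}

# exon sequences of every canonical transcript, in transcription order
# (reverse-complemented on '-'), as a list of character vectors
exon_seqs_by_transcript <- function(tset, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  chrom_seq <- setNames(as.character(genome),
                        sub("\\s.*$", "", names(genome)))
  ex <- tset$exons
  lapply(split(ex, ex$transcript), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$end > nchar(chrom_seq[d$chrom[1]])))
      stop("exon outside contig bounds for transcript ", d$transcript[1])
    seqs <- substring(chrom_seq[d$chrom[1]], d$start + 1L, d$end)
    if (d$strand[1] == "-") seqs <- rev(vapply(seqs, revcomp, ""))
    unname(seqs)
  })
}

#' Build a sticky transcript: spliced exons with intron meta-symbols
#'
#' The spliced exonic sequence of the canonical transcript with one
#' meta-symbol inserted at each exon-exon boundary. Meta-symbols carry the
#' intron rank but are rank-agnostic during alignment scoring; removing them
#' recovers the spliced transcript exactly.
#'
#' @param exon_seqs character vector of exon sequences in transcription
#'   order (from `exon_seqs_by_transcript`), or a single-transcript
#'   `transcript_set` together with `genome`.
#' @param genome optional genome (`DNAStringSet` or FASTA path) when
#'   `exon_seqs` is a `transcript_set`.
#' @param id transcript identifier.
#' @return object of class `sticky_transcript`: list with `symbols`
#'   (integer-coded sequence; values >= 100 are meta-symbols 100 + rank),
#'   `id`, and `n_introns`.
#' @export
make_sticky <- function(exon_seqs, genome = NULL, id = NA_character_) {
  if (inherits(exon_seqs, "transcript_set")) {
    lst <- exon_seqs_by_transcript(exon_seqs, genome)
    if (length(lst) != 1)
      stop("make_sticky on a transcript_set requires exactly one transcript")
    id <- names(lst)
    exon_seqs <- lst[[1]]
  }
  n_ex <- length(exon_seqs)
  enc <- lapply(exon_seqs, encode_dna)
  sym <- integer(0)
  for (e in seq_len(n_ex)) {
    sym <- c(sym, enc[[e]])
    if (e < n_ex) sym <- c(sym, 100L + e)
  }
  out <- list(symbols = sym, id = id, n_introns = n_ex - 1L)
  class(out) <- "sticky_transcript"
  out
}

#' Globally align two sticky transcripts and pair their introns
#'
#' Needleman-Wunsch over the extended alphabet: meta-symbols aligned to each
#' other score `meta_bonus`, meta-to-base pairing is forbidden, bases score
#' match/mismatch, gaps are linear. Introns whose meta-symbols align to each
#' other are reported as orthologous rank pairs.
#'
#' @param a,b `sticky_transcript` objects.
#' @param scoring list with `match`, `mismatch`, `gap`, `meta_bonus`.
#' @return list with `score` and `pairs` (data frame `rank_a`, `rank_b`).
#' @export
sticky_align <- function(a, b, scoring = default_sticky_scoring()) {
  stopifnot(inherits(a, "sticky_transcript"),
            inherits(b, "sticky_transcript"),
            length(a$symbols) > 0, length(b$symbols) > 0)
  # canonical argument order, so that ties in the DP traceback resolve
  # identically for (a,b) and (b,a) and the matched pairs are symmetric
  key <- function(s) paste(length(s$symbols),
                           paste(s$symbols, collapse = ","))
  flip <- key(b) < key(a)
  if (flip) { tmp <- a; a <- b; b <- tmp }
  res <- .nw_sticky_cpp(a$symbols, b$symbols, scoring$match,
                        scoring$mismatch, scoring$gap, scoring$meta_bonus)
  ra <- a$symbols[res$meta_a] - 100L
  rb <- b$symbols[res$meta_b] - 100L
  if (flip) list(score = res$score,
                 pairs = data.frame(rank_a = rb, rank_b = ra))
  else list(score = res$score,
            pairs = data.frame(rank_a = ra, rank_b = rb))
}

#' Reference-anchored intron orthology across a cohort
#'
#' Families are filtered to those single-copy in at least a fraction
#' `min_species` of the species; each retained non-reference transcript is
#' sticky-aligned to its reference orthologue and the aligned meta-symbols
#' define the intron orthology.
#'
#' @param files named list (per species) with `gff` and `fasta` paths, as in
#'   the `files` element of an `intron_cohort`.
#' @param family_table data frame `family_id`, `species`, `gene_id`.
#' @param reference reference species id.
#' @param min_species minimal fraction (or, if > 1, count) of species in
#'   which a family must be single-copy.
#' @param scoring sticky alignment scoring (see [sticky_align()]).
#' @param catalogue optional precomputed catalogue (from
#'   [cohort_catalogue()]); computed if missing.
#' @return object of class `orthology_table`: list with `lengths` (matrix,
#'   rows = reference introns `family:rank`, columns = species, `NA` where
#'   absent), `matches` (long data frame family, rank_ref, species,
#'   rank_partner, length), `reference`.
#' @export
build_orthology <- function(files, family_table, reference,
                            min_species = 0.75,
                            scoring = default_sticky_scoring(),
                            catalogue = NULL) {
  species <- names(files)
  stopifnot(reference %in% species)
  n_sp <- length(species)
  need <- if (min_species > 1) min_species else ceiling(min_species * n_sp)

  # single-copy filter
  cnt <- table(family_table$family_id, family_table$species)
  single_in <- rowSums(cnt == 1)
  fams <- rownames(cnt)[single_in >= need]
  ref_fams <- unique(family_table$family_id[
    family_table$species == reference])
  missing_ref <- setdiff(fams, ref_fams)
  if (length(missing_ref)) {
    warning(length(missing_ref),
            " family(ies) lack a reference gene; skipped")
    fams <- setdiff(fams, missing_ref)
  }
  fams <- sort(fams)

  gene_of <- function(sp, fam) {
    g <- family_table$gene_id[family_table$species == sp &
                                family_table$family_id == fam]
    if (length(g) == 1) g else NA_character_
  }

  # per species: read annotation + genome once, build sticky transcripts
  sticky_of <- function(sp) {
    tset <- read_annotation(files[[sp]]$gff, species = sp)
    seqs <- exon_seqs_by_transcript(tset, files[[sp]]$fasta)
    gene_by_tr <- tapply(tset$exons$gene, tset$exons$transcript,
                         function(x) x[1])
    stk <- lapply(names(seqs), function(tr)
      make_sticky(seqs[[tr]], id = tr))
    names(stk) <- unname(gene_by_tr[names(seqs)])
    stk
  }
  ref_sticky <- sticky_of(reference)

  if (is.null(catalogue)) {
    catalogue <- do.call(rbind, lapply(species, function(sp)
      extract_introns(read_annotation(files[[sp]]$gff, species = sp))))
  }
  len_lookup <- setNames(catalogue$length,
                         paste(catalogue$species, catalogue$gene,
                               catalogue$rank, sep = "\r"))
  len_of <- function(sp, gene, rank) {
    v <- len_lookup[paste(sp, gene, rank, sep = "\r")]
    if (is.na(v)) NA_integer_ else unname(v)
  }

  rows <- list()
  ref_keys <- character(0)
  ref_lens <- list()
  for (f in fams) {
    rg <- gene_of(reference, f)
    stk <- ref_sticky[[rg]]
    if (is.null(stk) || stk$n_introns == 0) next
    keys <- paste0(f, ":", seq_len(stk$n_introns))
    ref_keys <- c(ref_keys, keys)
    for (r in seq_len(stk$n_introns))
      ref_lens[[paste0(f, ":", r)]] <- len_of(reference, rg, r)
  }
  mat <- matrix(NA_real_, length(ref_keys), n_sp,
                dimnames = list(ref_keys, species))
  for (k in ref_keys)
    mat[k, reference] <- ref_lens[[k]]

  match_rows <- list()
  for (sp in setdiff(species, reference)) {
    stk_sp <- sticky_of(sp)
    for (f in fams) {
      rg <- gene_of(reference, f)
      sg <- gene_of(sp, f)
      if (is.na(sg)) next
      a <- ref_sticky[[rg]]; b <- stk_sp[[sg]]
      if (is.null(a) || is.null(b) || a$n_introns == 0) next
      al <- sticky_align(a, b, scoring)
      if (nrow(al$pairs) == 0) next
      for (i in seq_len(nrow(al$pairs))) {
        rr <- al$pairs$rank_a[i]; rp <- al$pairs$rank_b[i]
        key <- paste0(f, ":", rr)
        len <- len_of(sp, sg, rp)
        mat[key, sp] <- len
        match_rows[[length(match_rows) + 1L]] <-
          data.frame(family = f, rank_ref = rr, species = sp,
                     rank_partner = rp, length = len)
      }
    }
  }
  matches <- if (length(match_rows)) do.call(rbind, match_rows) else
    data.frame(family = character(), rank_ref = integer(),
               species = character(), rank_partner = integer(),
               length = integer())
  out <- list(lengths = mat, matches = matches, reference = reference,
              families = fams)
  class(out) <- "orthology_table"
  out
}
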
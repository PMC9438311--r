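#' Read a genome annotation and select canonical transcripts
#'
#' Parses GFF3 or GTF (via \code{rtracklayer::readGFF}) and returns the exon
#' structures of one canonical transcript per gene. Internal coordinates are
#' 0-based half-open; the conversion from the 1-based inclusive file format
#' happens here and only here.
#'
#' @param path GFF3 or GTF file (plain or gzipped).
#' @param species species identifier attached to every record.
#' @param canonical_policy `"flag-else-longest"` (default; use a
#'   `canonical=1` attribute when present, otherwise the transcript with the
#'   longest total exonic span), `"flag"` (flagged transcripts only), or
#'   `"longest"` (ignore flags). Ties broken by transcript id.
#' @return object of class `transcript_set`: a list with `exons` (data frame
#'   gene, transcript, chrom, strand, start, end — 0-based half-open, sorted
#'   genomically within transcript) and `species`.
#' @export
read_annotation <- function(path, species = NA_character_,
                            canonical_policy = "flag-else-longest") {
  canonical_policy <- match.arg(canonical_policy,
                                c("flag-else-longest", "flag", "longest"))
  g <- as.data.frame(rtracklayer::readGFF(path))
  ex <- g[g$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stop("no exon features in ", path)
  # transcript parentage: GFF3 Parent or GTF transcript_id
  tid <- if ("Parent" %in% names(ex) && any(lengths(ex$Parent) > 0)) {
    vapply(ex$Parent, function(p) as.character(p)[1], "")
  } else if ("transcript_id" %in% names(ex)) {
    as.character(ex$transcript_id)
  } else stop("exon features carry no transcript parentage")
  mr <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tr_id <- if ("ID" %in% names(mr) && !all(is.na(mr$ID))) as.character(mr$ID)
           else as.character(mr$transcript_id)
  gene_of <- if ("Parent" %in% names(mr) && any(lengths(mr$Parent) > 0)) {
    vapply(mr$Parent, function(p) as.character(p)[1], "")
  } else if ("gene_id" %in% names(mr)) as.character(mr$gene_id)
  else tr_id
  canon <- if ("canonical" %in% names(mr)) {
    !is.na(mr$canonical) & as.character(mr$canonical) == "1"
  } else rep(FALSE, nrow(mr))
  tr <- data.frame(transcript = tr_id, gene = gene_of, canonical = canon,
                   stringsAsFactors = FALSE)
  exdf <- data.frame(transcript = tid,
                     chrom = as.character(ex$seqid),
                     strand = as.character(ex$strand),
                     start = ex$start - 1L,   # to 0-based half-open
                     end = ex$end,
                     stringsAsFactors = FALSE)
  exdf <- exdf[exdf$transcript %in% tr$transcript, , drop = FALSE]
  span <- tapply(exdf$end - exdf$start, exdf$transcript, sum)
  tr$span <- as.numeric(span[tr$transcript])
  tr <- tr[!is.na(tr$span), , drop = FALSE]
  pick <- vapply(split(tr, tr$gene), function(d) {
    use <- switch(canonical_policy,
                  "flag" = d[d$canonical, , drop = FALSE],
                  "longest" = d,
                  "flag-else-longest" =
                    if (any(d$canonical)) d[d$canonical, , drop = FALSE]
                    else d)
    if (nrow(use) == 0) return(NA_character_)
    use <- use[order(-use$span, use$transcript), , drop = FALSE]
    use$transcript[1]
  }, "")
  pick <- pick[!is.na(pick)]
  if (length(pick) == 0) stop("no canonical transcripts selected from ", path)
  keep <- exdf[exdf$transcript %in% pick, , drop = FALSE]
  gene_map <- setNames(names(pick), pick)
  keep$gene <- gene_map[keep$transcript]
  keep <- keep[order(keep$transcript, keep$start), , drop = FALSE]
  rownames(keep) <- NULL
  out <- list(exons = keep, species = species)
  class(out) <- "transcript_set"
  out
}

#' Extract the intron catalogue from canonical transcripts
#'
#' For consecutive exons `[a,b)` and `[c,d)` with `b <= c` an intron of
#' length `c - b` is recorded. Ranks run 5'->3' in transcription order
#' (reversed relative to genomic order on the minus strand). Zero-length
#' introns (abutting exons) are dropped with a warning; introns shorter than
#' 32 bp are kept but flagged, as a QC signal.
#'
#' @param tset a `transcript_set` from [read_annotation()].
#' @return data frame with one row per intron: species, gene, transcript,
#'   rank, length, log2_length, chrom, start, end (1-based inclusive),
#'   strand, short_flag.
#' @export
extract_introns <- function(tset) {
  stopifnot(inherits(tset, "transcript_set"))
  ex <- tset$exons
  res <- lapply(split(ex, ex$transcript), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    n <- nrow(d)
    if (n >= 2 && any(d$start[-1] < d$end[-n])) {
      warning("overlapping exons; transcript ", d$transcript[1], " rejected")
      return(NULL)
    }
    if (n < 2) return(NULL)
    s0 <- d$end[-n]; e0 <- d$start[-1]
    len <- e0 - s0
    rank <- if (d$strand[1] == "-") rev(seq_len(n - 1)) else seq_len(n - 1)
    out <- data.frame(species = tset$species, gene = d$gene[1],
                      transcript = d$transcript[1], rank = rank,
                      length = len, chrom = d$chrom[1],
                      start = s0 + 1L, end = e0, strand = d$strand[1])
    if (any(out$length == 0)) {
      warning("dropping ", sum(out$length == 0), " zero-length intron(s) in ",
              d$transcript[1])
      out <- out[out$length > 0, , drop = FALSE]
    }
    out
  })
  cat <- do.call(rbind, res)
  if (is.null(cat))
    cat <- data.frame(species = character(), gene = character(),
                      transcript = character(), rank = integer(),
                      length = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character())
  rownames(cat) <- NULL
  cat$log2_length <- log2(cat$length)
  cat$short_flag <- cat$length < 32L
  cat
}

#' Total genome size from a FASTA file
#'
#' Sum of all record lengths, ambiguity characters included. Transparently
#' reads gzip-compressed files.
#'
#' @param path FASTA file.
#' @return total number of bases.
#' @export
genome_size <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0) stop("empty FASTA: ", path)
  sum(as.numeric(Biostrings::width(dna)))
}

#' Intron catalogues for every species of a cohort
#'
#' Convenience wrapper running [read_annotation()] and [extract_introns()]
#' over all annotation files of a simulated cohort.
#'
#' @param cohort an `intron_cohort` from [simulate_cohort()].
#' @return one data frame of intron records across species.
#' @export
cohort_catalogue <- function(cohort) {
  stopifnot(inherits(cohort, "intron_cohort"))
  do.call(rbind, lapply(cohort$species, function(sp) {
    extract_introns(read_annotation(cohort$files[[sp]]$gff, species = sp))
  }))
}
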
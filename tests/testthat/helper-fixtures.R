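# tiny in-code annotation/genome fixtures

write_toy_gff <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# a two-exon gene on the given strand: exons (1-based) 1-100 and 201-300
toy_gene_gff <- function(strand = "+", extra = character()) {
  write_toy_gff(c(
    sprintf("chr1\ttoy\tgene\t1\t300\t.\t%s\t.\tID=g1", strand),
    sprintf("chr1\ttoy\tmRNA\t1\t300\t.\t%s\t.\tID=t1;Parent=g1;canonical=1",
            strand),
    sprintf("chr1\ttoy\texon\t1\t100\t.\t%s\t.\tID=t1.e1;Parent=t1", strand),
    sprintf("chr1\ttoy\texon\t201\t300\t.\t%s\t.\tID=t1.e2;Parent=t1",
            strand),
    extra))
}

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names(seqs)
  Biostrings::writeXStringSet(dna, path)
  path
}

# small shared cohort for cross-module tests (built once per test run)
.test_env <- new.env()
small_cohort <- function() {
  if (is.null(.test_env$cohort)) {
    cfg <- sim_config(n_families = 60L, seed = 42L)
    .test_env$cohort <- simulate_cohort(cfg,
                                        dir = file.path(tempdir(),
                                                        "test_cohort"))
    .test_env$catalogue <- cohort_catalogue(.test_env$cohort)
  }
  list(cohort = .test_env$cohort, catalogue = .test_env$catalogue)
}
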
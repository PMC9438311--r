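test_that("a two-exon gene parses into one canonical transcript", {
  tset <- read_annotation(toy_gene_gff("+"), species = "sp")
  expect_s3_class(tset, "transcript_set")
  expect_equal(nrow(tset$exons), 2)
  # 0-based half-open internally
  expect_equal(tset$exons$start, c(0L, 200L))
  expect_equal(tset$exons$end, c(100L, 300L))
})

test_that("minus-strand genes give identical exon intervals", {
  plus <- read_annotation(toy_gene_gff("+"))$exons
  minus <- read_annotation(toy_gene_gff("-"))$exons
  expect_equal(minus$start, plus$start)
  expect_equal(minus$end, plus$end)
})

test_that("canonical policies pick flagged vs longest transcripts", {
  # two transcripts: t1 flagged, two exons; t2 unflagged but longer span
  gff <- write_toy_gff(c(
    "chr1\ttoy\tgene\t1\t500\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1;canonical=1",
    "chr1\ttoy\texon\t1\t100\t.\t+\t.\tID=t1.e1;Parent=t1",
    "chr1\ttoy\texon\t201\t300\t.\t+\t.\tID=t1.e2;Parent=t1",
    "chr1\ttoy\tmRNA\t1\t500\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\ttoy\texon\t1\t500\t.\t+\t.\tID=t2.e1;Parent=t2"))
  expect_equal(unique(read_annotation(gff)$exons$transcript), "t1")
  expect_equal(unique(read_annotation(
    gff, canonical_policy = "longest")$exons$transcript), "t2")
  expect_equal(unique(read_annotation(
    gff, canonical_policy = "flag")$exons$transcript), "t1")
})

test_that("introns come from exon gaps with hand-counted lengths", {
  introns <- extract_introns(read_annotation(toy_gene_gff("+"),
                                             species = "sp"))
  expect_equal(nrow(introns), 1)
  expect_equal(introns$length, 100L)   # bases 101..200
  expect_equal(introns$rank, 1L)
  expect_equal(introns$start, 101L)
  expect_equal(introns$end, 200L)
  expect_equal(introns$log2_length, log2(100))
})

test_that("single-exon transcripts yield no introns", {
  gff <- write_toy_gff(c(
    "chr1\ttoy\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1;canonical=1",
    "chr1\ttoy\texon\t1\t100\t.\t+\t.\tID=t1.e1;Parent=t1"))
  expect_equal(nrow(extract_introns(read_annotation(gff))), 0)
})

test_that("rank order reverses on the minus strand", {
  lines <- c(
    "chr1\ttoy\tgene\t1\t500\t.\t-\t.\tID=g1",
    "chr1\ttoy\tmRNA\t1\t500\t.\t-\t.\tID=t1;Parent=g1;canonical=1",
    "chr1\ttoy\texon\t1\t100\t.\t-\t.\tID=t1.e1;Parent=t1",
    "chr1\ttoy\texon\t201\t300\t.\t-\t.\tID=t1.e2;Parent=t1",
    "chr1\ttoy\texon\t401\t500\t.\t-\t.\tID=t1.e3;Parent=t1")
  introns <- extract_introns(read_annotation(write_toy_gff(lines)))
  # genomically-last gap (301..400) is transcribed first on '-'
  expect_equal(introns$rank[introns$start == 301], 1L)
  expect_equal(introns$rank[introns$start == 101], 2L)
})

test_that("overlapping exons reject the transcript with a warning", {
  lines <- c(
    "chr1\ttoy\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1;canonical=1",
    "chr1\ttoy\texon\t1\t150\t.\t+\t.\tID=t1.e1;Parent=t1",
    "chr1\ttoy\texon\t100\t300\t.\t+\t.\tID=t1.e2;Parent=t1")
  tset <- read_annotation(write_toy_gff(lines))
  expect_warning(out <- extract_introns(tset), "overlapping")
  expect_equal(nrow(out), 0)
})

test_that("genome_size sums record lengths, with Ns and gzip", {
  fa <- write_toy_fasta(c(a = random_dna_str(1000),
                          b = paste0(random_dna_str(2300), "NNNNNNNNNNNNNNN",
                                     random_dna_str(30))))
  expect_equal(genome_size(fa), 3345)
  gz <- paste0(fa, ".gz")
  writeLines(readLines(fa), gzfile(gz))
  expect_equal(genome_size(gz), 3345)
  empty <- write_toy_fasta(character())
  expect_error(genome_size(empty))
})

test_that("exon plus intron lengths equal the transcript span (cohort)", {
  sc <- small_cohort()
  cat1 <- sc$catalogue[sc$catalogue$species == sc$cohort$species[1], ]
  tset <- read_annotation(sc$cohort$files[[sc$cohort$species[1]]]$gff,
                          species = sc$cohort$species[1])
  ex <- tset$exons
  for (tr in unique(ex$transcript)[1:20]) {
    d <- ex[ex$transcript == tr, ]
    span <- max(d$end) - min(d$start)
    exlen <- sum(d$end - d$start)
    inlen <- sum(cat1$length[cat1$transcript == tr])
    expect_equal(exlen + inlen, span)
  }
})

test_that("extracted intron lengths match the generator truth exactly", {
  sc <- small_cohort()
  tru <- sc$cohort$truth$orthology
  cat_all <- sc$catalogue
  cat_all$family <- sub("^[^.]*\\.", "", cat_all$gene)
  m <- merge(cat_all, tru, by = c("species", "family", "rank"))
  expect_equal(nrow(m), nrow(tru))
  expect_identical(sum(m$length.x != m$length.y), 0L)
})
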
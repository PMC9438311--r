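sticky_from <- function(...) make_sticky(c(...), id = "toy")

test_that("make_sticky splices exons around rank-carrying meta-symbols", {
  s <- sticky_from("ACGT", "GGCC")
  expect_equal(length(s$symbols), 9)
  expect_equal(s$symbols[5], 101L)    # meta for intron rank 1
  expect_equal(s$n_introns, 1L)
  # removing metas recovers the spliced transcript
  expect_equal(intronevo:::decode_dna(s$symbols[s$symbols < 100]), "ACGTGGCC")
  expect_equal(sticky_from("ACGT")$n_introns, 0L)
})

test_that("make_sticky honours strand on a toy genome", {
  fa <- write_toy_fasta(c(chr1 = paste0(
    "ACGT", paste(rep("T", 6), collapse = ""), "GGCC")))
  gff <- write_toy_gff(c(
    "chr1\ttoy\tgene\t1\t14\t.\t-\t.\tID=g1",
    "chr1\ttoy\tmRNA\t1\t14\t.\t-\t.\tID=t1;Parent=g1;canonical=1",
    "chr1\ttoy\texon\t1\t4\t.\t-\t.\tID=t1.e1;Parent=t1",
    "chr1\ttoy\texon\t11\t14\t.\t-\t.\tID=t1.e2;Parent=t1"))
  s <- make_sticky(read_annotation(gff), genome = fa)
  # transcription order on '-': revcomp(GGCC), meta, revcomp(ACGT)
  expect_equal(intronevo:::decode_dna(s$symbols[s$symbols < 100]), "GGCCACGT")
  expect_equal(which(s$symbols >= 100), 5L)
  expect_equal(s$symbols[5] - 100L, 1L)
})

test_that("self-alignment pairs every intron with itself", {
  s <- make_sticky(c("ACGTACGT", "GGCCTTAA", "CACACACA"), id = "x")
  al <- sticky_align(s, s)
  expect_equal(al$pairs$rank_a, 1:2)
  expect_equal(al$pairs$rank_b, 1:2)
})

test_that("a missing intron leaves only that reference intron unmatched", {
  a <- make_sticky(c("ACGTACGTAC", "GGCCTTAAGG", "CACACACACA"), id = "a")
  b <- make_sticky(c("ACGTACGTAC", "GGCCTTAAGGCACACACACA"), id = "b")
  al <- sticky_align(a, b)
  expect_equal(al$pairs$rank_a, 1L)
  expect_equal(al$pairs$rank_b, 1L)
})

test_that("introns shifted by two bases still pair", {
  a <- make_sticky(c("ACGTACGTAC", "GGCCTTAAGG"), id = "a")
  b <- make_sticky(c("ACGTACGT", "ACGGCCTTAAGG"), id = "b")
  al <- sticky_align(a, b)
  expect_equal(nrow(al$pairs), 1)
  expect_equal(al$pairs$rank_a, 1L)
  expect_equal(al$pairs$rank_b, 1L)
})

test_that("sticky scores equal brute-force recursion on random toys", {
  set.seed(7)
  for (rep in 1:500) {
    n <- sample(1:15, 1); m <- sample(1:15, 1)
    mk <- function(k) {
      v <- sample(1:4, k, replace = TRUE)
      n_meta <- min(rbinom(1, 2, 0.4), k - 1)
      if (n_meta > 0 && k > 1) {
        pos <- sort(sample(2:k, n_meta))
        v[pos] <- 100L + seq_len(n_meta)
      }
      v
    }
    a <- mk(n); b <- mk(m)
    got <- intronevo:::.nw_sticky_cpp(a, b, 1, -1, -2, 10)$score
    expect_equal(got, nw_brute_score(a, b))
  }
})

test_that("matched pairs are symmetric and never pair bases with metas", {
  set.seed(8)
  for (rep in 1:100) {
    mk <- function() {
      ex <- replicate(sample(2:4, 1), random_dna_str(sample(5:15, 1)))
      make_sticky(ex, id = "r")
    }
    a <- mk(); b <- mk()
    ab <- sticky_align(a, b)
    ba <- sticky_align(b, a)
    expect_equal(ab$pairs$rank_a, ba$pairs$rank_b)
    expect_equal(ab$pairs$rank_b, ba$pairs$rank_a)
    # meta pairs only ever reference meta symbols (ranks are positive)
    if (nrow(ab$pairs)) {
      expect_true(all(ab$pairs$rank_a >= 1))
      expect_true(all(ab$pairs$rank_b >= 1))
    }
  }
})

test_that("zero-divergence cohort orthology is perfectly recovered", {
  cfg <- sim_config(n_families = 15L, subst_rate = 0, log2_sigma = 0,
                    log2_drift_contracted = 0, seed = 9L)
  co <- simulate_cohort(cfg, dir = tempfile("zd"))
  fam <- read.delim(file.path(co$dir, "families.tsv"))
  orth <- build_orthology(co$files, fam, co$reference)
  expect_true(all(orth$matches$rank_ref == orth$matches$rank_partner))
  n_true <- sum(co$truth$orthology$species != co$reference)
  expect_equal(nrow(orth$matches), n_true)
  # zero noise and drift: every species keeps the root lengths
  tru <- co$truth$orthology
  root_len <- tru$length[tru$species == co$species[1]]
  for (sp in co$species[-1])
    expect_equal(tru$length[tru$species == sp], root_len)
})

test_that("min_species drops families below the single-copy threshold", {
  sc <- small_cohort()
  co <- sc$cohort
  fam <- read.delim(file.path(co$dir, "families.tsv"))
  fam_drop <- fam[!(fam$family_id == fam$family_id[1] &
                      fam$species == co$species[2]), ]
  orth <- build_orthology(co$files, fam_drop, co$reference,
                          min_species = 1.0, catalogue = sc$catalogue)
  expect_false(fam$family_id[1] %in% orth$families)
  orth2 <- build_orthology(co$files, fam_drop, co$reference,
                           min_species = 0.75, catalogue = sc$catalogue)
  expect_true(fam$family_id[1] %in% orth2$families)
})
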
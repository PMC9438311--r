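test_that("self-alignment covers the sequence, then falls under threshold", {
  set.seed(51)
  s <- random_dna_str(200)
  hits <- recursive_local_align(s, s)
  expect_equal(hits$score[1], 200)
  expect_equal(c(hits$seed_start[1], hits$seed_end[1]), c(1, 200))
  expect_equal(c(hits$partner_start[1], hits$partner_end[1]), c(1, 200))
})

test_that("a planted 50-mer is recovered inside the top hit", {
  set.seed(52)
  core <- random_dna_str(50)
  a <- paste0(random_dna_str(225), core, random_dna_str(225))
  b <- paste0(random_dna_str(100), core, random_dna_str(350))
  hits <- recursive_local_align(a, b)
  top <- hits[1, ]
  planted <- 226:275
  overlap <- length(intersect(top$seed_start:top$seed_end, planted))
  expect_gte(overlap / 50, 0.9)
})

test_that("two disjoint plants give two disjoint seed hits", {
  set.seed(53)
  c1 <- random_dna_str(40); c2 <- random_dna_str(40)
  a <- paste0(random_dna_str(100), c1, random_dna_str(100), c2,
              random_dna_str(100))
  b <- paste0(random_dna_str(50), c2, random_dna_str(200), c1,
              random_dna_str(30))
  hits <- recursive_local_align(a, b, min_score = 25)
  expect_gte(nrow(hits), 2)
  # pairwise disjoint seed intervals, non-increasing scores
  iv <- Map(seq, hits$seed_start, hits$seed_end)
  for (i in seq_along(iv))
    for (j in seq_len(i - 1))
      expect_equal(length(intersect(iv[[i]], iv[[j]])), 0)
  expect_true(all(diff(hits$score) <= 0))
  covered <- unlist(iv)
  expect_gte(length(intersect(covered, c(101:140, 241:280))) / 80, 0.8)
})

test_that("round-1 scores equal an independent local aligner (100 pairs)", {
  set.seed(54)
  for (rep in 1:100) {
    a <- random_dna_str(sample(50:200, 1))
    b <- random_dna_str(sample(50:200, 1))
    got <- recursive_local_align(a, b, min_score = 1)
    want <- sw_biostrings_score(a, b)
    if (nrow(got) == 0) expect_lt(want, 1)
    else expect_equal(got$score[1], as.numeric(want))
  }
})

test_that("oversized search spaces are refused", {
  expect_error(recursive_local_align(random_dna_str(100),
                                     random_dna_str(100),
                                     max_space = 1e3), "search space")
})

test_that("set selection follows the clade length profile", {
  keys <- c("F1:1", "F2:1", "F3:1", "F4:1")
  m <- cbind(ref = c(1500, 500, 2000, 150),
             c1 = c(1500, 500, 120, 150),
             c2 = c(1600, 600, 110, 160),
             c3 = c(1400, 550, 130, 140))
  rownames(m) <- keys
  orth <- structure(list(lengths = m, reference = "ref"),
                    class = "orthology_table")
  suppressWarnings(
    sets <- select_intron_sets(orth, c("c1", "c2", "c3"), n_per_set = 10))
  expect_true("F1:1" %in% sets$long)       # clade min 1400 >= 1024
  expect_true("F2:1" %in% sets$med)        # clade min 500 in (256,1024)
  expect_true("F3:1" %in% sets$ctl)        # clade median 120, ref 2000
  expect_true("F4:1" %in% sets$short_lowvar)
  suppressWarnings(
    sets2 <- select_intron_sets(orth, c("c1", "c2", "c3"), n_per_set = 10))
  expect_identical(sets, sets2)            # seeded determinism
})

test_that("the genome hit counter separates unique from repeated loci", {
  set.seed(55)
  uniq <- random_dna_str(200)
  rep7 <- random_dna_str(150)
  genome <- Biostrings::DNAStringSet(paste0(
    random_dna_str(500), uniq, random_dna_str(300),
    paste(rep(paste0(rep7, random_dna_str(20)), 7), collapse = ""),
    random_dna_str(300)))
  counts <- count_genome_hits(c(uniq, rep7, random_dna_str(100)), genome)
  expect_equal(counts[1], 1L)
  expect_gte(counts[2], 7L)
  expect_equal(counts[3], 0L)
  keep <- repeat_filter(counts)
  expect_identical(keep, c(TRUE, FALSE, FALSE))
})

test_that("the null model recovers a constructed power law", {
  set.seed(56)
  space <- 10 ^ runif(500, 4, 8)
  score <- 3 * space ^ 0.3 * exp(rnorm(500, 0, 0.25))
  nm <- fit_null_model(score, space)
  expect_lt(abs(nm$slope - 0.3), 0.05)
  # by construction ~5% of control residuals exceed the cutoff
  expect_lt(abs(mean(nm$residuals > nm$cutoff) - 0.05), 0.01)
  # noise-free controls: all residuals (and the cutoff) collapse to zero
  nm0 <- fit_null_model(3 * space ^ 0.3, space)
  expect_lt(max(abs(nm0$residuals)), 1e-10)
  expect_lt(abs(nm0$cutoff), 1e-10)
  expect_error(fit_null_model(score[1:10], space[1:10]), "control points")
})

test_that("null-drawn orthologous scores are flagged at the nominal rate", {
  set.seed(57)
  space <- 10 ^ runif(500, 4, 8)
  draw <- function(sp) 3 * sp ^ 0.3 * exp(rnorm(length(sp), 0, 0.25))
  nm <- fit_null_model(draw(space), space)
  obs_space <- 10 ^ runif(500, 4, 8)
  calls <- conservation_calls(draw(obs_space), obs_space, nm,
                              rep("null", 500))
  expect_lt(abs(calls$proportions$proportion - 0.05), 0.02)
  # no-data entries stay NA rather than unflagged
  calls2 <- conservation_calls(c(NA, draw(obs_space[1])), obs_space[1:2],
                               nm, c("x", "x"))
  expect_true(is.na(calls2$calls$flagged[1]))
  expect_equal(calls2$proportions$n_data, 1)
})
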
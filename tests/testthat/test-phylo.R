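test_that("K2P closed form and degenerate cases", {
  expect_equal(kimura2p("ACGTACGT", "ACGTACGT"), 0)
  # 100 sites, 10 transitions, no transversions
  expect_equal(kimura2p(0.1, 0), -0.5 * log(0.8), tolerance = 1e-10)
  expect_error(kimura2p(0.5, 0.3), class = "intronevo_saturation")
  expect_error(kimura2p(0, 0.6), class = "intronevo_saturation")
  # gap/N columns excluded: distance from clean columns only
  expect_equal(kimura2p("ACGNACGT", "ACGTACGT"), 0)
})

test_that("K2P is monotone in the transition proportion", {
  q <- 0.05
  p <- seq(0, 0.4, by = 0.01)
  d <- vapply(p, kimura2p, 0, b = q)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= 0))
})

test_that("K2P estimates recover the simulated distance", {
  # evolve a long sequence for total path 0.2 at ts/tv = 2 and re-estimate
  set.seed(3)
  L <- 30000L
  root <- sample.int(4L, L, replace = TRUE)
  a <- intronevo:::k2p_step(root, t = 1, rate = 0.1, tstv = 2)
  b <- intronevo:::k2p_step(root, t = 1, rate = 0.1, tstv = 2)
  d <- kimura2p(intronevo:::decode_dna(a), intronevo:::decode_dna(b))
  expect_equal(d, 0.2, tolerance = 0.02)
})

test_that("pooled counts drive the pairwise distance", {
  # families (10,0)/100 and (0,10)/100 pool to P = Q = 0.05
  expect_equal(kimura2p(10 / 200, 10 / 200),
               -0.5 * log(1 - 0.15) - 0.25 * log(0.9))
})

test_that("NJ recovers a hand-built additive 4-taxon tree", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  dm <- ape::cophenetic.phylo(tr)
  nj1 <- neighbor_joining(dm)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), nj1), 0)
  got <- ape::cophenetic.phylo(nj1)
  expect_equal(got[rownames(dm), colnames(dm)], dm, tolerance = 1e-10)
})

test_that("three taxa give the closed-form star lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(len["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(len["C"]), (4 + 5 - 3) / 2)
})

test_that("NJ reconstructs random additive trees exactly (100 reps)", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(tr)
    nj1 <- neighbor_joining(dm)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), nj1), 0)
    got <- ape::cophenetic.phylo(nj1)
    expect_equal(got[rownames(dm), colnames(dm)], dm, tolerance = 1e-8)
  }
})

test_that("asymmetric matrices are rejected", {
  d <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d), "symmetric")
})

test_that("outgroup rooting bisects the separating branch", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:3);")
  rt <- root_tree(tr, "D")
  expect_true(ape::is.rooted(rt))
  n_tip <- length(rt$tip.label)
  kids <- rt$edge[rt$edge[, 1] == n_tip + 1L, 2]
  lens <- rt$edge.length[match(kids, rt$edge[, 2])]
  expect_equal(lens[1], lens[2])   # bisection
  # D's pendant path is preserved in total
  coph <- ape::cophenetic.phylo(rt)
  expect_equal(coph["A", "D"], 5)
  # determinism of node ids
  rt2 <- root_tree(tr, "D")
  expect_identical(rt$node.label, rt2$node.label)
  expect_identical(rt$edge, rt2$edge)
})

test_that("a non-clade outgroup is rejected", {
  tr <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_error(root_tree(tr, c("A", "B")), "clade|split")
})

test_that("cohort distances track true tree path lengths", {
  sc <- small_cohort()
  co <- sc$cohort
  fam <- read.delim(file.path(co$dir, "families.tsv"))
  dm <- distance_matrix(co$files, fam, max_families = 12L)
  tp <- ape::cophenetic.phylo(co$tree) * co$config$subst_rate
  sp <- rownames(dm$d)
  expect_gt(cor(dm$d[upper.tri(dm$d)], tp[sp, sp][upper.tri(tp)]), 0.98)
  expect_true(all(diag(dm$d) == 0))
  # NJ on these distances recovers the generating topology
  nj1 <- neighbor_joining(dm)
  expect_equal(phangorn::RF.dist(nj1, ape::unroot(co$tree)), 0)
  rt <- root_tree(nj1, co$outgroup)
  mrca_lab <- rt$node.label[ape::getMRCA(rt, co$contracted) -
                              length(rt$tip.label)]
  expect_true(setequal(
    rt$tip.label[intronevo:::descendant_tips(
      rt, ape::getMRCA(rt, co$contracted))],
    co$contracted))
})
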
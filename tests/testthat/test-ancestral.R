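test_that("size discretisation is exact on powers of two and rounds 76", {
  expect_identical(discretize_size(1024), 100L)
  expect_identical(discretize_size(256), 80L)
  expect_identical(discretize_size(76), 62L)   # 62.48 rounds down
  expect_error(discretize_size(0.5), ">= 1")
  # invertible within one discretisation step
  for (L in c(76, 100, 256, 1000, 5000)) {
    s <- discretize_size(L)
    expect_lte(abs(10 * log2(decode_size(s)) - s), 0.5)
  }
})

quartet <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
quartet <- intronevo:::label_nodes(quartet)

test_that("constant characters reconstruct at zero cost", {
  st <- c(A = 80, B = 80, C = 80, D = 80)
  rec <- sankoff_reconstruct(quartet, st)
  expect_equal(unname(rec$cost), 0)
  expect_true(all(rec$states == 80))
})

test_that("the split quartet reproduces the hand-derived optimum", {
  st <- c(A = 60, B = 60, C = 100, D = 100)
  rec <- sankoff_reconstruct(quartet, st)
  expect_equal(unname(rec$cost), 40)
  sts <- rec$states[1, ]
  # internal nodes take their clade's state; root ties resolve to the
  # smallest state
  lab_ab <- quartet$node.label[ape::getMRCA(quartet, c("A", "B")) - 4]
  lab_cd <- quartet$node.label[ape::getMRCA(quartet, c("C", "D")) - 4]
  root_lab <- quartet$node.label[1]
  expect_equal(unname(sts[lab_ab]), 60)
  expect_equal(unname(sts[lab_cd]), 100)
  expect_equal(unname(sts[root_lab]), 60)
  # brute-force agreement
  bf <- sankoff_brute(quartet, st)
  expect_equal(unname(rec$cost), bf$cost)
})

test_that("a missing leaf reduces to the induced subtree", {
  st <- c(A = 60, B = 70, C = 100, D = NA)
  rec <- sankoff_reconstruct(quartet, st)
  bf <- sankoff_brute(quartet, st, state_set = 60:100)
  expect_equal(unname(rec$cost), bf$cost)
})

test_that("Sankoff cost equals exhaustive enumeration on random trees", {
  set.seed(21)
  for (rep in 1:200) {
    n <- sample(3:6, 1)
    tr <- intronevo:::label_nodes(ape::rtree(n))
    states <- sample(60:67, n, replace = TRUE)
    names(states) <- tr$tip.label
    if (rep %% 7 == 0) states[sample(n, 1)] <- NA
    if (all(is.na(states))) next
    rec <- sankoff_reconstruct(tr, states)
    bf <- sankoff_brute(tr, states, state_set = 60:67)
    expect_equal(unname(rec$cost), bf$cost)
    # the returned assignment achieves the optimal cost
    edge_cost <- 0
    sts <- rec$states[1, c(tr$tip.label, tr$node.label)]
    for (k in seq_len(nrow(tr$edge))) {
      p <- sts[tr$edge[k, 1]]; ch <- sts[tr$edge[k, 2]]
      tip <- tr$edge[k, 2] <= n
      if (tip && is.na(states[tr$edge[k, 2]])) next
      edge_cost <- edge_cost + abs(p - ch)
    }
    expect_equal(unname(edge_cost), bf$cost)
  }
})

test_that("reconstruction ignores child order and translates linearly", {
  set.seed(22)
  tr <- intronevo:::label_nodes(ape::rtree(6))
  states <- matrix(sample(60:100, 60, replace = TRUE), 10,
                   dimnames = list(NULL, tr$tip.label))
  rec <- sankoff_reconstruct(tr, states)
  # child-order permutation: rotate the edges of the root
  tr2 <- ape::rotate(tr, 7)
  tr2$node.label <- tr$node.label
  rec2 <- sankoff_reconstruct(tr2, states)
  expect_equal(rec$cost, rec2$cost)
  expect_equal(rec$states[, tr$node.label],
               rec2$states[, tr$node.label])
  # adding a constant shifts every reconstructed state by that constant
  rec3 <- sankoff_reconstruct(tr, states + 7L)
  expect_equal(rec3$states, rec$states + 7L)
  expect_equal(rec3$cost, rec$cost)
  # chosen states stay inside the observed hull
  expect_true(all(rec$states >= min(states) & rec$states <= max(states)))
})

test_that("branch changes are zero at the root and track leaf states", {
  st <- c(A = 60, B = 60, C = 100, D = 100)
  rec <- sankoff_reconstruct(quartet, st)
  bc <- branch_changes(rec, quartet)
  root_lab <- quartet$node.label[1]
  expect_equal(bc$dist_root[bc$node == root_lab], 0)
  expect_equal(bc$mean_change[bc$node == root_lab], 0)
  expect_equal(bc$mean_change[bc$node == "C"], 40)
  expect_equal(bc$mean_change[bc$node == "A"], 0)
  expect_equal(bc$dist_root[bc$node == "A"], 2)
})

test_that("mode lines recover a diagonal identity relationship", {
  set.seed(23)
  anc <- rep(70:110, each = 40)
  ext <- anc + round(rnorm(length(anc), 0, 3))
  ml <- mode_lines(anc, ext, extant_lengths = rep(1000, length(anc)))
  main <- ml[[which.max(vapply(ml, nrow, 0L))]]
  # boundary columns are pulled inward by the one-sided blur; judge the
  # interior of the line
  core <- main[main$anc_state >= 76 & main$anc_state <= 104, ]
  dev <- core$extant_state - core$anc_state
  expect_lt(max(abs(dev)), 2.5)
})

test_that("mode lines split a constructed bimodal relationship", {
  set.seed(24)
  anc <- rep(80:110, each = 60)
  low <- round(rnorm(length(anc) / 2, 62, 2.5))
  high <- anc[seq(2, length(anc), 2)] + round(rnorm(length(anc) / 2, 0, 2.5))
  anc2 <- c(anc[seq(1, length(anc), 2)], anc[seq(2, length(anc), 2)])
  ext2 <- c(low, high)
  ml <- mode_lines(anc2, ext2, extant_lengths = rep(1000, length(anc2)))
  ml <- ml[vapply(ml, nrow, 0L) >= 10]
  expect_gte(length(ml), 2)
  mean_ext <- vapply(ml, function(d) mean(d$extant_state), 0)
  flat <- ml[[which.min(mean_ext)]]
  diag_ <- ml[[which.max(mean_ext)]]
  expect_lt(max(abs(flat$extant_state - 62)), 6)
  expect_lt(mean(abs(diag_$extant_state - diag_$anc_state)), 6)
})

test_that("a single occupied cell gives a one-point line", {
  ml <- mode_lines(rep(90L, 5), rep(95L, 5),
                   extant_lengths = rep(1000, 5))
  expect_equal(length(ml), 1)
  expect_equal(ml[[1]]$anc_state, 90)
  expect_equal(ml[[1]]$extant_state, 95)
})

test_that("minimised proportions hit the trivial limits", {
  anc <- rep(c(70L, 90L, 110L), each = 50)
  all80 <- minimised_proportion(anc, rep(80, 150))
  expect_true(all(all80$proportion[all80$n > 0] == 1))
  none <- minimised_proportion(anc, rep(2000, 150))
  expect_true(all(none$proportion[none$n > 0] == 0))
  # empty bins are NA, not zero
  sparse <- minimised_proportion(c(rep(60L, 10), rep(95L, 10)),
                                 rep(80, 20))
  gap <- sparse[sparse$n == 0, ]
  expect_true(all(is.na(gap$proportion)))
})
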
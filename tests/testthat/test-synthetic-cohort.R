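test_that("an explicit newick is echoed and random trees are reproducible", {
  cfg <- sim_config(n_species = 3, tree_shape = "((A:1,B:1):1,C:2);",
                    contracted_clade = c("A", "B"), outgroup = "C")
  tr <- simulate_species_tree(cfg)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(sort(tr$edge.length), sort(c(1, 1, 1, 2)))
  cfg2 <- sim_config(tree_shape = "random-birth", seed = 5)
  t1 <- simulate_species_tree(cfg2)
  t2 <- simulate_species_tree(cfg2)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("the contracted clade is monophyletic with the requested leaves", {
  cfg <- sim_config(tree_shape = "random-birth", seed = 6)
  tr <- simulate_species_tree(cfg)
  con <- attr(tr, "contracted")
  expect_length(con, 5)
  mrca <- ape::getMRCA(tr, con)
  expect_setequal(tr$tip.label[intronevo:::descendant_tips(tr, mrca)], con)
  # a non-monophyletic request errors
  cfg_bad <- sim_config(n_species = 4,
                        tree_shape = "((A:1,B:1):1,(C:1,D:1):1);",
                        contracted_clade = c("A", "C"), outgroup = "B")
  expect_error(simulate_species_tree(cfg_bad), "monophyletic")
})

test_that("identical config and seed give byte-identical cohort files", {
  cfg <- sim_config(n_families = 6L, seed = 77L)
  d1 <- tempfile("c_a"); d2 <- tempfile("c_b")
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  for (f in list.files(d1)) {
    h1 <- tools::md5sum(file.path(d1, f))
    h2 <- tools::md5sum(file.path(d2, f))
    expect_identical(unname(h1), unname(h2))
  }
})

test_that("zero-rate evolution leaves orthologous exons identical", {
  cfg <- sim_config(n_families = 5L, subst_rate = 0, seed = 78L)
  co <- simulate_cohort(cfg, dir = tempfile("zr"))
  s1 <- co$species[1]; s2 <- co$species[8]
  t1 <- read_annotation(co$files[[s1]]$gff, species = s1)
  t2 <- read_annotation(co$files[[s2]]$gff, species = s2)
  e1 <- intronevo:::exon_seqs_by_transcript(t1, co$files[[s1]]$fasta)
  e2 <- intronevo:::exon_seqs_by_transcript(t2, co$files[[s2]]$fasta)
  fam1 <- sub("\\.t1$", "", sub("^[^.]*\\.", "", names(e1)))
  fam2 <- sub("\\.t1$", "", sub("^[^.]*\\.", "", names(e2)))
  for (f in fam1) {
    a <- paste(e1[[which(fam1 == f)]], collapse = "")
    b <- paste(e2[[which(fam2 == f)]], collapse = "")
    expect_identical(a, b)
    expect_equal(kimura2p(a, b), 0)
  }
})

test_that("drift shifts contracted means by the expected amount", {
  # floors far below the sizes so reflection never engages: the pure
  # Brownian shift is then the drift times the path length
  cfg <- sim_config(n_families = 120L, log2_drift_contracted = -1.5,
                    log2_sigma = 0.2, seed = 79L,
                    size_model = list(
                      free_headroom = c(offset = 4, mean = 1, sd = 0.3),
                      retained_headroom = c(offset = 4, mean = 1, sd = 0.3)))
  tree <- simulate_species_tree(cfg)
  co <- simulate_cohort(cfg, tree, dir = tempfile("dr"))
  anc <- co$truth$ancestral
  leaf_means <- tapply(anc$log2_size[anc$node %in% co$species],
                       anc$node[anc$node %in% co$species], mean)
  con_mean <- mean(leaf_means[co$contracted])
  bg_mean <- mean(leaf_means[setdiff(co$species, co$contracted)])
  # mean drift path length over contracted leaves
  mrca <- ape::getMRCA(tree, co$contracted)
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  stem_edge <- which(tree$edge[, 2] == mrca)
  stem_top <- depth[mrca] - tree$edge.length[stem_edge]
  paths <- depth[match(co$contracted, tree$tip.label)] - stem_top
  expected <- cfg$log2_drift_contracted * mean(paths)
  expect_equal(con_mean - bg_mean, expected, tolerance = 0.2 * abs(expected))
})

test_that("class floors hold in truth tables and in written files", {
  sc <- small_cohort()
  co <- sc$cohort
  cls <- co$truth$class
  oc <- co$truth$orthology
  ret <- cls$intron_id[cls$class == "retained"]
  expect_true(all(oc$length[oc$intron_id %in% ret] >=
                    co$config$retained_floor_bp))
  expect_true(all(oc$length >= co$config$floor_bp))
  cat_all <- sc$catalogue
  expect_true(all(cat_all$length >= co$config$floor_bp))
})

test_that("contracted free introns pile up at the minimal size", {
  sc <- small_cohort()
  co <- sc$cohort
  cls <- co$truth$class
  oc <- co$truth$orthology
  free_ids <- cls$intron_id[cls$class == "free"]
  con <- oc[oc$species %in% co$contracted & oc$intron_id %in% free_ids, ]
  expect_gt(mean(con$length >= 76 & con$length <= 100), 0.25)
})

test_that("a planted element longer than retained introns is refused", {
  cfg <- sim_config(n_families = 5L, element_len_bp = 5000L, seed = 80L)
  expect_error(simulate_cohort(cfg, dir = tempfile("el")),
               "element_len_bp")
})
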
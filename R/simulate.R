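#' Configuration for a synthetic multi-species intron cohort
#'
#' Builds the parameter set for [simulate_species_tree()] and
#' [simulate_cohort()]. The generator emulates a clade of genomes in which
#' intron lengths evolve multiplicatively (Brownian motion on the log2
#' scale) along a rooted species tree, with a designated "contracted" clade
#' experiencing a negative drift in log2 intron size, and a hard reflecting
#' lower boundary representing the minimal functional intron size.
#'
#' Two intron classes are simulated. Free introns may contract down to a
#' per-intron minimal size whose distribution starts at `floor_bp` (76 bp);
#' length-retained introns have minimal sizes bounded below by
#' `retained_floor_bp` (1024 bp) and carry a planted conserved sequence
#' element shared across species. Genes are assigned to classes so that the
#' intron-level retained fraction matches `retained_fraction`; a subset of
#' functional terms is planted preferentially on retained-class genes.
#'
#' @param n_species number of species (>= 3).
#' @param tree_shape `"default"` (a fixed 12-taxon topology with a 2-species
#'   outgroup, 5 background species and a 5-species contracted clade),
#'   `"random-birth"` (random subtrees grafted so the contracted clade is
#'   monophyletic by construction), or an explicit newick string.
#' @param contracted_clade character vector of species labels forming the
#'   contracted clade. Defaults to `C1..C5` for the built-in shapes.
#' @param outgroup species used to root; defaults to `O1`,`O2`.
#' @param n_families number of single-copy gene families.
#' @param introns_per_gene list with `mean` and `dispersion` of the (shifted)
#'   negative-binomial intron count per gene (minimum 1).
#' @param retained_fraction proportion of introns in the length-retained
#'   class (0..1).
#' @param log2_drift_contracted mean change in log2 intron size per unit
#'   branch length on contracted-clade branches (negative).
#' @param log2_sigma Brownian step scale (log2 units per sqrt unit branch
#'   length).
#' @param floor_bp,retained_floor_bp minimal intron sizes (bp) for the free
#'   and retained classes; lower bounds of the per-intron floor draws.
#' @param ts_tv_ratio transition/transversion ratio for exon evolution.
#' @param subst_rate substitutions per site per unit branch length.
#' @param element_len_bp,element_identity length of the conserved element
#'   planted in every retained intron, and the per-base probability that a
#'   species' copy keeps the master base.
#' @param n_terms,planted_terms total number of functional terms and how
#'   many are planted on retained-class genes.
#' @param term_size mean number of member genes per term.
#' @param exon_len_range exon length range (uniform draw, bp).
#' @param spacer_bp intergenic spacer length on the single chromosome.
#' @param size_model list of internal size-distribution parameters (per-class
#'   floor spreads, root headroom above floor, retained-gene purity); see
#'   the package vignette for their meaning and defaults.
#' @param seed integer random seed; identical config + seed gives
#'   byte-identical output files.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_species = 12L,
                       tree_shape = "default",
                       contracted_clade = NULL,
                       outgroup = NULL,
                       n_families = 200L,
                       introns_per_gene = list(mean = 7.5, dispersion = 6),
                       retained_fraction = 0.3,
                       log2_drift_contracted = -3,
                       log2_sigma = 0.2,
                       floor_bp = 76L,
                       retained_floor_bp = 1024L,
                       ts_tv_ratio = 2,
                       subst_rate = 0.06,
                       element_len_bp = 120L,
                       element_identity = 0.9,
                       n_terms = 40L,
                       planted_terms = 5L,
                       term_size = 18L,
                       exon_len_range = c(90L, 200L),
                       spacer_bp = 500L,
                       size_model = list(),
                       seed = 1L) {
  stopifnot(n_species >= 3, retained_fraction >= 0, retained_fraction <= 1,
            floor_bp >= 1, retained_floor_bp >= floor_bp,
            element_identity >= 0, element_identity <= 1)
  sm <- list(
    # fraction of a strong retained-class gene's introns that are
    # themselves retained; the remainder are "sub-retained" free introns
    # with intermediate minimal sizes
    retained_gene_purity = 0.8,
    # fraction of retained-class genes that are "weak": all their introns
    # are sub-retained (no intron at the retained floor), so their largest
    # clade-minimal length sits just above the short/long class boundary
    weak_fraction = 0.25,
    # half-normal spread (log2) of free-intron floors above floor_bp
    short_floor_sd = 0.55,
    # probability that the first (rank 1) intron of a free-class gene is
    # sub-retained rather than short; models the longer first introns
    # observed in canonical transcripts (promoter-proximal regulation)
    first_subret_prob = 0.5,
    # sub-retained free floors: per-gene centre uniform over [lo, hi]
    # (log2) with a small per-intron jitter (gene-level size constraint)
    subret_center = c(lo = 8.45, hi = 9.6),
    subret_jitter = 0.1,
    # half-normal spread of retained floors above retained_floor_bp
    retained_floor_sd = 0.2,
    # root log2 size = floor + offset + |N(mean, sd)| per class; chosen so
    # unconstrained (background) genomes order the classes short <
    # sub-retained < retained, as the cross-clade prediction expects
    free_headroom = c(offset = 1.2, mean = 2.2, sd = 0.7),
    subret_headroom = c(offset = 0.8, mean = 1.4, sd = 0.6),
    retained_headroom = c(offset = 1.0, mean = 1.8, sd = 0.7),
    # Euler step for the reflected Brownian branch simulation; small
    # enough that the reflection boundary layer (~|drift| * dt) is thin
    # relative to the 76-100 bp minimised window (0.39 log2 units)
    dt = 0.01)
  sm[names(size_model)] <- size_model
  cfg <- list(n_species = as.integer(n_species), tree_shape = tree_shape,
              contracted_clade = contracted_clade, outgroup = outgroup,
              n_families = as.integer(n_families),
              introns_per_gene = introns_per_gene,
              retained_fraction = retained_fraction,
              log2_drift_contracted = log2_drift_contracted,
              log2_sigma = log2_sigma,
              floor_bp = as.integer(floor_bp),
              retained_floor_bp = as.integer(retained_floor_bp),
              ts_tv_ratio = ts_tv_ratio, subst_rate = subst_rate,
              element_len_bp = as.integer(element_len_bp),
              element_identity = element_identity,
              n_terms = as.integer(n_terms),
              planted_terms = as.integer(planted_terms),
              term_size = as.integer(term_size),
              exon_len_range = as.integer(exon_len_range),
              spacer_bp = as.integer(spacer_bp),
              size_model = sm, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

DEFAULT_TREE <- paste0(
  "((O1:0.5,O2:0.5):0.3,((N1:0.5,(N2:0.45,(N3:0.2,(N4:0.18,N5:0.18):0.05)",
  ":0.2):0.1):0.2,((C1:0.7,(C2:0.6,C3:0.6):0.15):0.4,(C4:0.65,C5:0.65)",
  ":0.5):0.6):0.2);")

# deterministic post-order internal node labels
label_nodes <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  ord <- unique(tree$edge[, 1])         # internal nodes in post-order
  lab <- character(tree$Nnode)
  lab[ord - n_tip] <- sprintf("nd%02d", seq_along(ord))
  tree$node.label <- lab
  tree
}

#' Simulate (or echo) the rooted species tree of a synthetic cohort
#'
#' @param config a [sim_config()] object.
#' @return an `ape` `phylo` tree, rooted, with positive branch lengths,
#'   deterministic post-order internal node labels, and attributes
#'   `contracted` and `outgroup` holding the species subsets.
#' @export
simulate_species_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  shape <- config$tree_shape
  if (identical(shape, "default")) {
    tree <- ape::read.tree(text = DEFAULT_TREE)
    contracted <- config$contracted_clade %||% paste0("C", 1:5)
    outgroup <- config$outgroup %||% c("O1", "O2")
  } else if (identical(shape, "random-birth")) {
    n_con <- length(config$contracted_clade %||% paste0("C", 1:5))
    n_out <- 2L
    n_bg <- config$n_species - n_con - n_out
    stopifnot(n_bg >= 1, n_con >= 2)
    scale_depth <- function(tr, depth) {
      tr$edge.length <- tr$edge.length * depth /
        max(ape::node.depth.edgelength(tr))
      tr
    }
    rsub <- function(n, labels, depth) {
      tr <- if (n == 1) {
        structure(list(edge = matrix(c(2L, 1L), 1), tip.label = labels,
                       edge.length = depth, Nnode = 1L), class = "phylo")
      } else scale_depth(ape::rphylo(n, birth = 1, death = 0), depth)
      tr$tip.label <- labels
      tr
    }
    bg <- rsub(n_bg, paste0("N", seq_len(n_bg)), 0.7)
    con <- rsub(n_con, config$contracted_clade %||% paste0("C", seq_len(n_con)),
                1.35)
    out <- rsub(n_out, paste0("O", seq_len(n_out)), 0.5)
    graft <- function(a, b, stem_a, stem_b) {
      ta <- ape::write.tree(a); tb <- ape::write.tree(b)
      ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                    sub(";$", "", ta), stem_a,
                                    sub(";$", "", tb), stem_b))
    }
    ingroup <- graft(bg, con, 0.2, 0.6)
    tree <- graft(out, ingroup, 0.3, 0.2)
    contracted <- con$tip.label
    outgroup <- out$tip.label
  } else {
    tree <- ape::read.tree(text = shape)
    contracted <- config$contracted_clade
    outgroup <- config$outgroup
  }
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  stopifnot(all(tree$edge.length > 0))
  if (!is.null(contracted) && length(contracted) >= 2) {
    mrca <- ape::getMRCA(tree, contracted)
    desc <- tree$tip.label[descendant_tips(tree, mrca)]
    if (!setequal(desc, contracted))
      stop("requested contracted_clade is not monophyletic in the tree")
  }
  tree <- label_nodes(tree)
  attr(tree, "contracted") <- contracted
  attr(tree, "outgroup") <- outgroup
  tree
}

descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

# nodes (indices) inside the contracted clade, including its MRCA; the edge
# leading INTO each of these nodes carries the contraction drift (so the
# stem branch of the clade is included)
contracted_nodes <- function(tree, contracted) {
  if (is.null(contracted) || length(contracted) < 2) return(integer())
  mrca <- ape::getMRCA(tree, contracted)
  all_desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    c(node, unlist(lapply(kids, all_desc)))
  }
  all_desc(mrca)
}

# reflected Brownian step simulation for one branch, vectorised over introns
reflect_bm <- function(x, floor_log2, t, drift, sigma, dt) {
  nstep <- max(1L, ceiling(t / dt))
  h <- t / nstep
  for (k in seq_len(nstep)) {
    x <- x + drift * h + sigma * sqrt(h) * rnorm(length(x))
    x <- floor_log2 + abs(x - floor_log2)
  }
  x
}

# K2P substitution sampling along one branch for an integer-coded sequence
k2p_step <- function(seq_int, t, rate, tstv) {
  if (rate <= 0 || t <= 0) return(seq_int)
  alpha <- rate * tstv / (tstv + 1)
  beta <- rate / (2 * (tstv + 1))
  e4b <- exp(-4 * beta * t)
  e2ab <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e4b - 0.5 * e2ab
  p_tv <- 0.5 * (1 - e4b)
  u <- runif(length(seq_int))
  ts_partner <- c(3L, 4L, 1L, 2L)
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  out <- seq_int
  i_ts <- u < p_ts
  i_t1 <- !i_ts & u < p_ts + p_tv / 2
  i_t2 <- !i_ts & !i_t1 & u < p_ts + p_tv
  out[i_ts] <- ts_partner[seq_int[i_ts]]
  out[i_t1] <- tv1[seq_int[i_t1]]
  out[i_t2] <- tv2[seq_int[i_t2]]
  out
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Generates per-species genome FASTA and GFF3 annotation, a single-copy
#' gene-family table, a gene-to-functional-term table, and truth tables
#' (orthology, ancestral log2 sizes at every tree node, intron classes,
#' planted-element coordinates, planted term assignment). Each gene has one
#' canonical transcript on a single chromosome; genes are separated by
#' fixed-length random spacers. Intron log2 sizes evolve as reflected
#' Brownian motion with clade-specific drift; exon sequences evolve under a
#' Kimura two-parameter model; intron background sequence is species-private
#' (treated as diverged beyond recognition) except for the conserved
#' elements planted in retained introns.
#'
#' @param config a [sim_config()] object.
#' @param tree tree from [simulate_species_tree()]; simulated if `NULL`.
#' @param dir output directory (created if needed).
#' @return (invisibly) a list of class `intron_cohort` with elements
#'   `config`, `tree`, `species`, `reference`, `dir`, `files` (per-species
#'   gff/fasta paths), and `truth` (data frames: `orthology`, `ancestral`,
#'   `class`, `elements`, `terms`, plus per-intron metadata `introns`).
#' @export
simulate_cohort <- function(config, tree = NULL, dir = tempfile("cohort")) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tree)) tree <- simulate_species_tree(config)
  set.seed(config$seed + 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- config$size_model
  n_tip <- length(tree$tip.label)
  species <- tree$tip.label
  contracted <- attr(tree, "contracted")
  # reference species: a non-contracted, non-outgroup species whose introns
  # keep ancestral lengths (the role the reference genome plays in the
  # cohort analyses)
  bg <- setdiff(species, c(contracted, attr(tree, "outgroup")))
  reference <- if (length(bg)) sort(bg)[1] else sort(species)[1]

  ## ---- gene/intron skeleton -------------------------------------------
  nf <- config$n_families
  fam <- sprintf("F%04d", seq_len(nf))
  ipg <- config$introns_per_gene
  size_nb <- ipg$dispersion
  mu_nb <- max(ipg$mean - 1, 0.01)
  n_introns_gene <- 1L + rnbinom(nf, mu = mu_nb, size = size_nb)
  total_introns <- sum(n_introns_gene)
  intron_gene <- rep(seq_len(nf), n_introns_gene)
  intron_rank <- sequence(n_introns_gene)
  intron_id <- paste0(fam[intron_gene], ":", intron_rank)

  # gene classes: retained-class genes hold the retained introns. Strong
  # retained genes mix retained introns (fraction = purity) with
  # sub-retained free introns; weak retained genes carry sub-retained
  # introns only, so their largest clade-minimal length falls just above
  # the short/long class boundary.
  purity <- sm$retained_gene_purity
  wfrac <- sm$weak_fraction
  g_frac <- min(1, config$retained_fraction / ((1 - wfrac) * purity))
  retained_gene <- runif(nf) < g_frac
  weak_gene <- retained_gene & runif(nf) < wfrac
  strong_gene <- retained_gene & !weak_gene
  is_retained <- strong_gene[intron_gene] & runif(total_introns) < purity
  is_subret <- retained_gene[intron_gene] & !is_retained
  # longer first introns: rank-1 introns of free-class genes promoted to
  # the sub-retained floor band with configured probability
  first_up <- !retained_gene[intron_gene] & intron_rank == 1L &
    runif(total_introns) < sm$first_subret_prob
  is_subret <- is_subret | first_up
  subclass <- ifelse(is_retained, "retained",
                     ifelse(is_subret, "subretained", "short"))

  ## ---- per-intron floors and root sizes -------------------------------
  fl <- numeric(total_introns)
  l2floor <- log2(config$floor_bp)
  l2rfloor <- log2(config$retained_floor_bp)
  fl[subclass == "short"] <-
    l2floor + abs(rnorm(sum(subclass == "short"), 0, sm$short_floor_sd))
  sc <- sm$subret_center
  gene_center <- runif(nf, sc["lo"], sc["hi"])
  fl[is_subret] <- pmin(pmax(gene_center[intron_gene[is_subret]] +
                               rnorm(sum(is_subret), 0, sm$subret_jitter),
                             sc["lo"] - 0.1), sc["hi"] + 0.1)
  fl[is_retained] <-
    l2rfloor + abs(rnorm(sum(is_retained), 0, sm$retained_floor_sd))
  fh <- sm$free_headroom; rh <- sm$retained_headroom
  sh <- sm$subret_headroom
  headroom <- fh["offset"] + abs(rnorm(total_introns, fh["mean"], fh["sd"]))
  headroom[is_subret] <-
    sh["offset"] + abs(rnorm(sum(is_subret), sh["mean"], sh["sd"]))
  headroom[is_retained] <-
    rh["offset"] + abs(rnorm(sum(is_retained), rh["mean"], rh["sd"]))
  root_log2 <- fl + headroom

  ## ---- evolve log2 sizes along the tree -------------------------------
  tree_po <- ape::reorder.phylo(tree, "postorder")
  root <- n_tip + 1L
  con_nodes <- contracted_nodes(tree, contracted)
  n_nodes <- n_tip + tree$Nnode
  vals <- matrix(NA_real_, n_nodes, total_introns)
  vals[root, ] <- root_log2
  # preorder = reversed postorder edge list
  edges <- tree_po$edge[rev(seq_len(nrow(tree_po$edge))), , drop = FALSE]
  elens <- tree_po$edge.length[rev(seq_len(nrow(tree_po$edge)))]
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; child <- edges[k, 2]
    drift <- if (child %in% con_nodes) config$log2_drift_contracted else 0
    vals[child, ] <- reflect_bm(vals[par, ], fl, elens[k], drift,
                                config$log2_sigma, sm$dt)
  }
  leaf_len <- matrix(0L, n_tip, total_introns,
                     dimnames = list(species, NULL))
  for (i in seq_len(n_tip))
    leaf_len[i, ] <- as.integer(round(2 ^ vals[i, ]))

  if (any(is_retained) &&
      config$element_len_bp > min(leaf_len[, is_retained]))
    stop("element_len_bp exceeds the shortest retained intron")

  ## ---- exon structure and sequences -----------------------------------
  exr <- config$exon_len_range
  exon_lens <- lapply(n_introns_gene + 1L, function(k)
    sample(seq(exr[1], exr[2]), k, replace = TRUE))
  strand_gene <- ifelse(runif(nf) < 0.5, "+", "-")
  # root exon sequence per gene (concatenated exons, transcription order)
  root_exonseq <- lapply(exon_lens, function(l)
    sample.int(4L, sum(l), replace = TRUE))
  # evolve concatenated exon sequences; keep only what we still need
  node_seq <- vector("list", n_nodes)
  node_seq[[root]] <- root_exonseq
  leaf_seq <- vector("list", n_tip)
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; child <- edges[k, 2]
    t <- elens[k]
    evolved <- lapply(node_seq[[par]], k2p_step, t = t,
                      rate = config$subst_rate, tstv = config$ts_tv_ratio)
    if (child <= n_tip) leaf_seq[[child]] <- evolved
    else node_seq[[child]] <- evolved
  }

  ## ---- planted conserved elements -------------------------------------
  ret_idx <- which(is_retained)
  master <- lapply(ret_idx, function(i)
    sample.int(4L, config$element_len_bp, replace = TRUE))
  names(master) <- as.character(ret_idx)

  ## ---- write per-species genomes + annotations ------------------------
  files <- list()
  elem_rows <- vector("list", n_tip * max(1, length(ret_idx)))
  er <- 0L
  ord_gene <- seq_len(nf)   # gene order along the chromosome (shared)
  for (si in seq_len(n_tip)) {
    sp <- species[si]
    lens_sp <- leaf_len[si, ]
    # per-species intron sequences; elements planted into retained introns
    pool <- random_dna(sum(lens_sp))
    offs <- cumsum(c(0, lens_sp))
    intron_seqs <- substring(pool, offs[-length(offs)] + 1L, offs[-1L])
    for (ii in ret_idx) {
      L <- lens_sp[ii]; el <- config$element_len_bp
      pos <- sample.int(L - el + 1L, 1L)
      m <- master[[as.character(ii)]]
      keep <- runif(el) < config$element_identity
      mut <- m
      if (any(!keep)) {
        # substitute to a different base, so identity is exactly as set
        shift <- sample.int(3L, sum(!keep), replace = TRUE)
        mut[!keep] <- ((m[!keep] - 1L + shift) %% 4L) + 1L
      }
      s <- intron_seqs[ii]
      intron_seqs[ii] <- paste0(substr(s, 1, pos - 1), decode_dna(mut),
                                substr(s, pos + el, L))
      er <- er + 1L
      elem_rows[[er]] <- data.frame(intron_id = intron_id[ii], species = sp,
                                    start = pos, end = pos + el - 1L)
    }
    # assemble chromosome and GFF3
    chrom_parts <- character(0)
    gff <- vector("list", nf)
    pos <- 0L
    for (gi in ord_gene) {
      spacer <- random_dna(config$spacer_bp)
      ii <- which(intron_gene == gi)
      # split the evolved concatenated exon sequence back into exons
      cuts <- cumsum(c(0, exon_lens[[gi]]))
      gseq_int <- leaf_seq[[si]][[gi]]
      exon_strs <- vapply(seq_along(exon_lens[[gi]]), function(e)
        decode_dna(gseq_int[(cuts[e] + 1):cuts[e + 1]]), "")
      n_ex <- length(exon_strs)
      body <- exon_strs[1]
      if (n_ex > 1)
        for (e in 2:n_ex)
          body <- paste0(body, intron_seqs[ii[e - 1]], exon_strs[e])
      strand <- strand_gene[gi]
      body_genomic <- if (strand == "-") revcomp(body) else body
      gstart <- pos + config$spacer_bp + 1L
      gend <- gstart + nchar(body) - 1L
      # exon coordinates in transcription order, then mapped to genome
      tx_starts <- integer(n_ex); tx_ends <- integer(n_ex)
      at <- 0L
      for (e in seq_len(n_ex)) {
        tx_starts[e] <- at + 1L
        tx_ends[e] <- at + exon_lens[[gi]][e]
        at <- tx_ends[e]
        if (e < n_ex) at <- at + lens_sp[ii[e]]
      }
      if (strand == "+") {
        ex_s <- gstart + tx_starts - 1L; ex_e <- gstart + tx_ends - 1L
      } else {
        ex_e <- gend - tx_starts + 1L; ex_s <- gend - tx_ends + 1L
      }
      o <- order(ex_s)
      gid <- paste0(sp, ".", fam[gi]); tid <- paste0(gid, ".t1")
      gff[[gi]] <- data.frame(
        seqid = "chr1",
        source = "intronevo",
        type = c("gene", "mRNA", rep("exon", n_ex)),
        start = c(gstart, gstart, ex_s[o]),
        end = c(gend, gend, ex_e[o]),
        score = ".", strand = strand, phase = ".",
        attributes = c(sprintf("ID=%s", gid),
                       sprintf("ID=%s;Parent=%s;canonical=1", tid, gid),
                       sprintf("ID=%s.e%d;Parent=%s", tid, seq_len(n_ex),
                               tid)[o]))
      chrom_parts <- c(chrom_parts, spacer, body_genomic)
      pos <- gend
    }
    chrom <- paste0(c(chrom_parts, random_dna(config$spacer_bp)),
                    collapse = "")
    fa <- file.path(dir, paste0(sp, ".fa"))
    gf <- file.path(dir, paste0(sp, ".gff3"))
    dna <- Biostrings::DNAStringSet(chrom)
    names(dna) <- "chr1"
    Biostrings::writeXStringSet(dna, fa)
    gff_all <- do.call(rbind, gff)
    con <- file(gf, "wb")
    writeLines("##gff-version 3", con)
    write.table(gff_all, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    close(con)
    files[[sp]] <- list(fasta = fa, gff = gf)
  }

  ## ---- companion tables ------------------------------------------------
  fam_tab <- data.frame(
    family_id = rep(fam, each = n_tip),
    species = rep(species, nf),
    gene_id = paste0(rep(species, nf), ".", rep(fam, each = n_tip)))
  write.table(fam_tab, file.path(dir, "families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # term table: planted terms sample long-intron genes (retained-class
  # genes plus free-class genes whose promoted first intron lies above the
  # class boundary), null terms sample all genes uniformly
  has_promoted <- tabulate(intron_gene[first_up], nf) > 0
  ret_genes <- fam[retained_gene | has_promoted]
  terms <- sprintf("T%03d", seq_len(config$n_terms))
  planted <- seq_len(config$planted_terms)
  term_rows <- lapply(seq_len(config$n_terms), function(ti) {
    m <- max(5L, rbinom(1, 2L * config$term_size, 0.5))
    pool <- if (ti %in% planted) ret_genes else fam
    m <- min(m, length(pool))
    data.frame(gene_id = sort(sample(pool, m)), term_id = terms[ti],
               planted = as.integer(ti %in% planted))
  })
  term_tab <- do.call(rbind, term_rows)
  write.table(term_tab, file.path(dir, "terms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## ---- truth tables ----------------------------------------------------
  orth <- data.frame(intron_id = rep(intron_id, n_tip),
                     family = rep(fam[intron_gene], n_tip),
                     rank = rep(intron_rank, n_tip),
                     species = rep(species, each = total_introns),
                     length = as.vector(t(leaf_len)))
  node_names <- c(species, tree$node.label)
  anc <- data.frame(intron_id = rep(intron_id, n_nodes),
                    node = rep(node_names, each = total_introns),
                    log2_size = as.vector(t(vals)))
  cls <- data.frame(intron_id = intron_id,
                    class = ifelse(is_retained, "retained", "free"),
                    subclass = subclass, floor_log2 = fl,
                    root_log2 = root_log2,
                    family = fam[intron_gene], rank = intron_rank)
  elems <- if (er > 0) do.call(rbind, elem_rows[seq_len(er)]) else
    data.frame(intron_id = character(), species = character(),
               start = integer(), end = integer())
  for (nm in c("orthology", "ancestral", "class", "elements")) {
    obj <- switch(nm, orthology = orth, ancestral = anc, class = cls,
                  elements = elems)
    write.table(obj, file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ape::write.tree(tree, file.path(dir, "species_tree.nwk"))

  out <- list(config = config, tree = tree, species = species,
              reference = reference, contracted = contracted,
              outgroup = attr(tree, "outgroup"), dir = dir, files = files,
              truth = list(orthology = orth, ancestral = anc, class = cls,
                           elements = elems, terms = term_tab,
                           introns = data.frame(
                             intron_id = intron_id,
                             family = fam[intron_gene], rank = intron_rank,
                             retained_gene = retained_gene[intron_gene])))
  class(out) <- "intron_cohort"
  invisible(out)
}
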
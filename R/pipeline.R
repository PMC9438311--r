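pipeline_version <- function() {
  as.character(utils::packageVersion("intronevo"))
}

config_hash <- function(config) {
  # stable content hash without external digest dependencies
  s <- paste(deparse(config), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", h)
}

write_stage_table <- function(df, path, hash) {
  con <- file(path, "wb")
  writeLines(sprintf("# intronevo %s config=%s", pipeline_version(), hash),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the full intron-size evolution pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order: cohort simulation, intron
#' cataloguing, size distributions and QC, intron orthology, K2P distances
#' and the neighbour-joining tree, Sankoff ancestral sizes and branch
#' changes, size-association statistics, the functional-term depletion
#' scan, and the intron sequence-conservation scan. Every output table is
#' written under `out_dir` with a header carrying the package version and a
#' config hash; two runs with identical config and seeds produce
#' byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param n_perm permutations for the MI test.
#' @param conservation_n set size for the conservation scan.
#' @param conservation_partners partner species for the conservation scan
#'   (default: the whole contracted clade).
#' @param max_distance_families families pooled for the K2P distances.
#' @param stages character vector of stage names to run (default all, in
#'   order); a stage whose prerequisite was not run raises an error naming
#'   the missing stage.
#' @return (invisibly) a list with the stage results and a `summary` list
#'   of headline statistics.
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = tempfile("introverse_run"),
                         n_perm = 1000L, conservation_n = 80L,
                         conservation_partners = NULL,
                         max_distance_families = 24L,
                         stages = c("simulate", "catalog", "distributions",
                                    "orthology", "tree", "ancestry",
                                    "associate", "deplete", "conserve")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  write_sim_config(config, file.path(out_dir, "config.yaml"))
  res <- list()
  need <- function(what) {
    if (is.null(res[[what]]))
      stop("stage '", what, "' required but was not run")
    res[[what]]
  }

  if ("simulate" %in% stages) {
    res$simulate <- simulate_cohort(config,
                                    dir = file.path(out_dir, "cohort"))
  }
  if ("catalog" %in% stages) {
    cohort <- need("simulate")
    res$catalog <- cohort_catalogue(cohort)
    write_stage_table(res$catalog, file.path(out_dir, "catalogue.tsv"),
                      hash)
  }
  if ("distributions" %in% stages) {
    cat <- need("catalog")
    cohort <- need("simulate")
    qc <- qc_species_filter(cat)
    anti <- vapply(cohort$species, function(sp) {
      d <- size_density(cat[cat$species == sp, ])
      find_antimode(d, 5, 14)
    }, 0)
    frac <- vapply(cohort$species, function(sp)
      fraction_below(cat[cat$species == sp, ], 256), 0)
    gsz <- vapply(cohort$species, function(sp)
      genome_size(cohort$files[[sp]]$fasta), 0)
    res$distributions <- data.frame(species = cohort$species,
                                    antimode_log2 = anti,
                                    fraction_below_256 = frac,
                                    genome_size = gsz,
                                    qc_pass = cohort$species %in% qc)
    write_stage_table(res$distributions,
                      file.path(out_dir, "distributions.tsv"), hash)
  }
  if ("orthology" %in% stages) {
    cohort <- need("simulate")
    fam <- read.delim(file.path(cohort$dir, "families.tsv"))
    res$orthology <- build_orthology(cohort$files, fam, cohort$reference,
                                     catalogue = need("catalog"))
    lm_ <- res$orthology$lengths
    write_stage_table(data.frame(intron = rownames(lm_), lm_,
                                 check.names = FALSE),
                      file.path(out_dir, "orthology.tsv"), hash)
  }
  if ("tree" %in% stages) {
    cohort <- need("simulate")
    fam <- read.delim(file.path(cohort$dir, "families.tsv"))
    res$dist <- distance_matrix(cohort$files, fam,
                                max_families = max_distance_families)
    nj_tree <- neighbor_joining(res$dist)
    res$tree <- root_tree(nj_tree, cohort$outgroup)
    ape::write.tree(res$tree, file.path(out_dir, "nj_tree.nwk"))
    write_stage_table(data.frame(species = rownames(res$dist$d),
                                 res$dist$d, check.names = FALSE),
                      file.path(out_dir, "k2p_distances.tsv"), hash)
  }
  if ("ancestry" %in% stages) {
    orth <- need("orthology"); tree <- need("tree")
    states <- discretize_size(orth$lengths)
    dim(states) <- dim(orth$lengths)
    dimnames(states) <- dimnames(orth$lengths)
    res$ancestry <- sankoff_reconstruct(tree, states)
    res$branch_changes <- branch_changes(res$ancestry, tree)
    write_stage_table(res$branch_changes,
                      file.path(out_dir, "branch_changes.tsv"), hash)
  }
  if ("associate" %in% stages) {
    orth <- need("orthology"); cohort <- need("simulate")
    cat <- need("catalog")
    qc <- qc_species_filter(cat)
    con <- intersect(cohort$contracted, qc)
    bg <- intersect(setdiff(cohort$species,
                            c(cohort$contracted, cohort$outgroup)), qc)
    m <- orth$lengths
    mi <- mi_permutation_test(m[, bg[1]], m[, bg[2]], n_perm = n_perm,
                              seed = config$seed)
    cmed <- apply(m[, con, drop = FALSE], 1, median, na.rm = TRUE)
    bmed <- apply(m[, bg, drop = FALSE], 1, median, na.rm = TRUE)
    qcp <- quantile_cross_prediction(cmed, bmed, threshold_log2 = 10)
    res$associate <- list(mi = mi, cross_prediction = qcp)
    write_stage_table(data.frame(statistic = c("mi_bits", "mi_p",
                                               "frac50", "frac95"),
                                 value = c(mi$mi, mi$p_value, qcp$frac50,
                                           qcp$frac95)),
                      file.path(out_dir, "association.tsv"), hash)
  }
  if ("deplete" %in% stages) {
    orth <- need("orthology"); cohort <- need("simulate")
    terms <- read.delim(file.path(cohort$dir, "terms.tsv"))
    gv <- gene_length_statistic(orth, cohort$contracted)
    res$depletion <- nested_depletion_scan(gv, terms)
    write_stage_table(res$depletion$minima,
                      file.path(out_dir, "depletion_minima.tsv"), hash)
  }
  if ("conserve" %in% stages) {
    orth <- need("orthology"); cohort <- need("simulate")
    fam <- read.delim(file.path(cohort$dir, "families.tsv"))
    res$conservation <- scan_conservation(
      cohort$files, orth, need("catalog"), fam, cohort$contracted,
      partners = conservation_partners %||% cohort$contracted,
      n_per_set = conservation_n, seed = config$seed,
      skip_repeat_filter = TRUE)
    write_stage_table(res$conservation$proportions,
                      file.path(out_dir, "conservation.tsv"), hash)
  }
  res$summary <- list(config_hash = hash, out_dir = out_dir)
  invisible(res)
}
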
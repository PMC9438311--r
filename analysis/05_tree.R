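#!/usr/bin/env Rscript
# Kimura two-parameter distances from pooled pairwise exon alignments,
# neighbour-joining tree, outgroup rooting; compared with the generating
# topology.

library(intronevo)
cohort <- readRDS("results/cohort.rds")
families <- read.delim(file.path(cohort$dir, "families.tsv"))

dm <- distance_matrix(cohort$files, families)
tree <- root_tree(neighbor_joining(dm), cohort$outgroup)
saveRDS(list(dist = dm, tree = tree), "results/tree.rds")
write.table(data.frame(species = rownames(dm$d), dm$d, check.names = FALSE),
            "results/k2p_distances.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ape::write.tree(tree, "results/nj_tree.nwk")

tp <- ape::cophenetic.phylo(cohort$tree) * cohort$config$subst_rate
sp <- rownames(dm$d)
cat("distance vs true path-length correlation:",
    round(cor(dm$d[upper.tri(dm$d)], tp[sp, sp][upper.tri(tp)]), 4), "\n")
if (requireNamespace("phangorn", quietly = TRUE))
  cat("Robinson-Foulds distance to the true topology:",
      phangorn::RF.dist(ape::unroot(tree), ape::unroot(cohort$tree)), "\n")
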
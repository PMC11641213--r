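#!/usr/bin/env Rscript
# Nei (1972) genetic distances, UPGMA dendrogram, and PCoA. The
# population-level tree summarizes the three provinces; the
# individual-level tree of all 416 accessions is cut into five clusters,
# mirroring how the published analysis grouped its germplasms.

library(ssrpop)

gm <- read_genalex("results/panel.genalex.csv")

# population level
fp <- allele_frequencies(gm, by = "population")
dp <- nei_distance(fp)
cat("Nei distance between populations:\n")
print(round(unclass(dp), 4))
to_newick(upgma(dp), "results/tree_populations.nwk")

# individual level: distance, tree, five clusters
fi <- allele_frequencies(gm, by = "individual")
di <- nei_distance(fi)
tr <- upgma(di)
to_newick(tr, "results/tree_individuals.nwk")
cl <- cut_clusters(tr, 5L)
write.csv(data.frame(id = names(cl), pop = as.character(gm$pop),
                     cluster = as.integer(cl)),
          "results/clusters_k5.csv", row.names = FALSE)
cat("\nFive-cluster cut of the individual UPGMA tree (sizes):\n")
print(table(cluster = cl, pop = gm$pop))

pc <- pcoa(di, axes = 2L)
write.csv(data.frame(id = rownames(pc$coordinates), pc$coordinates,
                     pop = as.character(gm$pop)),
          "results/pcoa_individuals.csv", row.names = FALSE)
cat(sprintf("\nPCoA axes 1-2 explain %.1f%% + %.1f%% of the positive inertia\n",
            pc$percent[1L], pc$percent[2L]))
cat("\nWrote results/tree_*.nwk, results/clusters_k5.csv,",
    "results/pcoa_individuals.csv\n")
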
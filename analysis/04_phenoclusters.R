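#!/usr/bin/env Rscript
# Stage 4: hierarchical clustering of the QMS vectors (distance =
# 1 - uncentered Pearson correlation, average linkage) and the
# phenocluster cut at similarity > 0.73.

suppressMessages(library(morphoscreen))
qms <- read_table_full("results/qms.csv")
qms <- qms[qms$condition != "mock", ]

dendro <- hierarchical_cluster(qms)
clusters <- cut_phenoclusters(dendro, threshold = 0.73)
write_table_full(clusters, "results/phenoclusters.csv")
write_newick(dendro, "results/qms_dendrogram.nwk")
om <- ordered_matrix(dendro, qms)
write_table_full(cbind(condition = rownames(om), as.data.frame(om)),
                 "results/qms_ordered_heatmap.csv")

n_multi <- sum(table(clusters$cluster) > 1)
n_single <- sum(table(clusters$cluster) == 1)
cat(sprintf("Phenoclusters at PCC > 0.73: %d multigene, %d singleton(s).\n",
            n_multi, n_single))
print(clusters)
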
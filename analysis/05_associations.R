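#!/usr/bin/env Rscript
# Stage 5: differential expression of features across tumour profiles.
#
# Wilcoxon rank-sum tests of each feature against the five semantic flags,
# the three driver-gene labels, and pairwise histology groups (with a
# Kruskal-Wallis omnibus), plus Spearman correlation with ordinal grade.
# The up/down/ns arrow matrix mirrors the development cohort's injected
# effects (EGFR shift on kurtosis; grade link on longhem).

suppressPackageStartupMessages(library(ctrad))

feats <- read.csv("results/features_cohort_a.csv")
clin <- read.csv("scratch/cohort_a/clinical.csv")

tab <- association_table(feats, clin, alpha = 0.05)
write.csv(tab, "results/associations.csv", row.names = FALSE)
write.csv(as.data.frame(association_matrix(tab)),
          "results/association_matrix.csv")
omni <- attr(tab, "omnibus")
if (!is.null(omni)) write.csv(omni, "results/histology_omnibus.csv",
                              row.names = FALSE)

sig <- tab[tab$direction != "ns", ]
cat(sprintf("%d of %d feature x profile tests significant at 0.05\n",
            nrow(sig), nrow(tab)))
for (k in seq_len(nrow(sig))) {
  cat(sprintf("  %-20s %-28s %-5s p=%.3g effect=%.3g\n", sig$feature[k],
              sig$profile[k], paste0(sig$direction[k], sig$stars[k]),
              sig$p_value[k], sig$effect[k]))
}
cat("wrote results/associations.csv, association_matrix.csv\n")
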
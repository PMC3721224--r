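#!/usr/bin/env Rscript
# Delineate chemogroups: Bray-Curtis resemblance over the feature table,
# group-average (UPGMA) clustering, and a cut at 50% similarity.

suppressPackageStartupMessages(library(chemotypemap))

ft <- read_feature_table("results/feature_table.csv")
d <- resemblance_matrix(ft)
write.csv(round(similarity_matrix(d), 4), "results/similarity_pct.csv")

hc <- upgma(d)
dendrogram_newick(hc, "results/dendrogram.nwk")
cg <- cut_dendrogram(hc, similarity_pct = 50)
write.csv(cg, "results/chemogroups.csv", row.names = FALSE)

cat("Chemogroups at the 50% similarity cut:\n")
for (g in unique(cg$group))
  cat("  ", g, ": ", paste(cg$sample_id[cg$group == g], collapse = " "),
      "\n", sep = "")
sim <- similarity_matrix(d)
for (g in unique(cg$group)) {
  ids <- cg$sample_id[cg$group == g]
  if (length(ids) > 1) {
    sub <- sim[ids, ids]
    cat("  within-", g, " similarity >= ",
        sprintf("%.1f%%", min(sub[upper.tri(sub)])), "\n", sep = "")
  }
}
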
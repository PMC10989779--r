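# Serum metabolome: feature filtering, OPLS-DA with VIP ranking, the
# per-metabolite time-association model, six-cluster trajectory
# clustering, and per-cluster chemical composition.

source(file.path("analysis", "00_common.R"))

tab <- load_metabolome()
filt <- filter_features(tab)
message(sprintf("kept %d of %d features (%d low-presence, %d unannotated removed)",
                ncol(filt$mat), ncol(tab$mat),
                attr(filt, "removal_log")["low_presence"],
                attr(filt, "removal_log")["unannotated"]))

op <- opls_da(filt, groups = factor(filt$metadata$dph))
write_tsv(data.frame(metabolite = names(op$vip), vip = op$vip),
          "metabolome_vip.tsv")
message(sprintf("P1 explains %.1f%% of intensity variation; %d metabolites exceed VIP 1.5",
                100 * op$explained[1], sum(op$vip > 1.5)))

assoc <- glm_time_association(filt)
write_tsv(assoc, "metabolome_time_association.tsv")
message(sprintf("%d of %d metabolites associated with time (FDR < 0.05)",
                sum(assoc$associated), nrow(assoc)))

assoc_tab <- structure(list(
  mat = filt$mat[, assoc$metabolite[assoc$associated], drop = FALSE],
  metadata = filt$metadata, annotation = filt$annotation),
  class = "metabolite_table")
cl <- cluster_trajectories(assoc_tab, k = 6)
write_tsv(data.frame(metabolite = names(cl$cluster), cluster = cl$cluster),
          "metabolome_clusters.tsv")
write_tsv(data.frame(cluster = rownames(cl$centers), cl$centers,
                     check.names = FALSE), "metabolome_cluster_centers.tsv")
comp <- cluster_composition(cl$cluster, filt$annotation)
write_tsv(comp, "metabolome_cluster_composition.tsv")
for (k in sort(unique(comp$cluster))) {
  lead <- comp[comp$cluster == k, ][1, ]
  message(sprintf("cluster %s: %d metabolites, led by %s (%.0f%%)",
                  k, sum(comp$count[comp$cluster == k]), lead$superclass,
                  100 * lead$proportion))
}
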
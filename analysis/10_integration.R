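# Microbe-metabolite integration: per segment x domain, a low-rank
# softmax co-occurrence model links QMP microbial abundances to serum
# metabolite intensities in the matched bird and day; the top 1% of
# conditional probabilities form the interaction set.

source(file.path("analysis", "00_common.R"))

tab <- load_metabolome()
filt <- filter_features(tab)
assoc <- glm_time_association(filt)
assoc_tab <- structure(list(
  mat = filt$mat[, assoc$metabolite[assoc$associated], drop = FALSE],
  metadata = filt$metadata, annotation = filt$annotation),
  class = "metabolite_table")
cl <- cluster_trajectories(assoc_tab, k = 6)

scored <- list()
for (dom in domains) {
  d <- load_domain(dom)
  for (sg in unique(d$qmp$metadata$segment)) {
    sub <- ft_subset(d$qmp, samples = d$qmp$metadata$segment == sg)
    key <- sprintf("SR_B%02d_D%02d", sub$metadata$bird, sub$metadata$dph)
    ok <- key %in% rownames(filt$mat)
    fit <- mmvec_fit(sub$mat[ok, , drop = FALSE],
                     filt$mat[key[ok], , drop = FALSE],
                     latent_dim = 3, epochs = 300,
                     seed = stage_seed(SEED, paste0("mmvec_", sg, dom)))
    P <- fit$probs
    scored[[paste(sg, dom)]] <- data.frame(
      microbe = paste(sg, dom, rep(rownames(P), ncol(P)), sep = "|"),
      genus = rep(rownames(P), ncol(P)),
      metabolite = rep(colnames(P), each = nrow(P)),
      probability = as.vector(P),
      stratum = paste(sg, dom), stringsAsFactors = FALSE)
  }
}
all_scores <- do.call(rbind, scored)
sel <- select_top(all_scores, 0.01)
write_tsv(sel$selected, "interactions_top1pct.tsv")

strata <- stats::setNames(all_scores$stratum, all_scores$microbe)
clusters <- stats::setNames(cl$cluster, names(cl$cluster))
in_clustered <- all_scores$metabolite %in% names(clusters)
sel_cl <- sel
sel_cl$selected <- sel$selected[sel$selected$metabolite %in%
                                  names(clusters), ]
rt <- ratio_table(sel_cl, all_scores[in_clustered, ], strata, clusters)
write_tsv(rt, "interaction_ratio_table.tsv")
best <- rt[which.max(rt$percent), ]
message(sprintf("closest connections: %s with cluster %s (%.2f%% of pairs retained)",
                best$stratum, best$cluster, best$percent))

net <- interaction_network(sel, filt$annotation)
write_tsv(net$key_taxa, "interaction_key_taxa.tsv")
write_tsv(net$metabolite_categories, "interaction_metabolite_categories.tsv")
message("top key taxa: ",
        paste(head(net$key_taxa$genus, 5), collapse = ", "))
message("metabolite categories: ",
        paste(sprintf("%s (%d)", head(net$metabolite_categories$superclass, 3),
                      head(net$metabolite_categories$count, 3)),
              collapse = ", "))
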
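# Genus-genus partial-Spearman co-occurrence networks per segment
# (bacteria and fungi pooled, conditioned on sampling day), their
# topology, keystone taxa, generalist/specialist edges, sign ratios, and
# the QMP-vs-RMP correlation-consistency cross-tabulation.

source(file.path("analysis", "00_common.R"))

d <- lapply(domains, load_domain)
names(d) <- domains
segments <- unique(d$bacteria$qmp$metadata$segment)

nets <- list(); consistency <- list()
for (sg in segments) {
  ids <- d$bacteria$qmp$metadata$sample_id[
    d$bacteria$qmp$metadata$segment == sg]
  pool_q <- do.call(cbind, lapply(d, function(x)
    x$qmp$mat[ids, , drop = FALSE]))
  pool_r <- do.call(cbind, lapply(d, function(x)
    x$rmp$mat[ids, , drop = FALSE]))
  md <- d$bacteria$qmp$metadata[match(ids, d$bacteria$qmp$metadata$sample_id), ]
  ftq <- prevalence_filter(feature_table(pool_q, md, mode = "counts"))
  shared <- colnames(ftq$mat)
  ftr <- feature_table(pool_r[, shared], md, mode = "counts")
  net_q <- build_network(ftq, mode = "QMP", segment = sg)
  net_r <- build_network(ftr, mode = "RMP", segment = sg)
  nets[[sg]] <- net_q
  cc <- qmp_rmp_consistency(net_q, net_r)
  consistency[[sg]] <- cc
  write_tsv(net_q$edges, paste0("network_qmp_", sg, ".tsv"))
  message(sprintf("%s: %d edges (QMP); QMP-RMP consistency %.1f%%",
                  sg, nrow(net_q$edges), cc$consistency))
}

topo <- do.call(rbind, lapply(segments, function(sg) {
  t <- topology(nets[[sg]]); t$segment <- sg; t
}))
write_tsv(topo, "network_topology.tsv")
message("most complex network: ",
        topo$segment[which.max(topo$edges)], " (",
        max(topo$edges), " edges, clustering ",
        round(topo$clustering[which.max(topo$edges)], 2), ")")

keys <- do.call(rbind, lapply(segments, function(sg) {
  k <- keystone(nets[[sg]], 10); k$segment <- sg; k
}))
write_tsv(keys, "network_keystone.tsv")

sh <- edge_sharing(nets)
write_tsv(data.frame(segment = names(sh$proportions),
                     specialist_share = sh$proportions),
          "network_edge_sharing.tsv")

sr <- do.call(rbind, lapply(segments, function(sg) {
  s <- sign_ratio(nets[[sg]]); s$segment <- sg; s
}))
write_tsv(sr, "network_sign_ratio.tsv")
message(sprintf("%.1f%% of vertices show more positive than negative interactions",
                100 * mean(sr$dominance == "positive")))
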
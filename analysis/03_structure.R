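# Community structure: Shannon diversity, adjacent-time-point turnover,
# ordination, QMP-vs-RMP Procrustes agreement, and the marginal variance
# partition over bird, segment and day.

source(file.path("analysis", "00_common.R"))

for (dom in domains) {
  d <- load_domain(dom)
  div <- data.frame(sample_id = rownames(d$qmp$mat),
                    shannon = apply(d$qmp$mat, 1, shannon))
  write_tsv(cbind(div, d$qmp$metadata[match(div$sample_id,
                                            d$qmp$metadata$sample_id),
                                      c("segment", "dph")]),
            paste0("shannon_", dom, ".tsv"))

  adj <- do.call(rbind, lapply(unique(d$qmp$metadata$segment), function(sg) {
    a <- adjacent_time_dissimilarity(d$qmp, sg); a$segment <- sg; a
  }))
  write_tsv(adj, paste0("adjacent_time_bray_", dom, ".tsv"))
  first <- tapply(adj$dissimilarity, adj$interval, median)
  message(dom, ": highest adjacent-time turnover in interval ",
          names(which.max(first)), " (median ",
          round(max(first), 2), ")")

  dmx <- bray_curtis_matrix(d$qmp)
  vp <- variance_partition(dmx, d$qmp$metadata, c("bird", "segment", "dph"),
                           n_perm = 199, seed = stage_seed(SEED, "vp"))
  vp$mode <- "QMP"
  vpr <- variance_partition(bray_curtis_matrix(d$rmp), d$rmp$metadata,
                            c("bird", "segment", "dph"),
                            n_perm = 199, seed = stage_seed(SEED, "vp"))
  vpr$mode <- "RMP"
  both <- rbind(vp, vpr); both$domain <- dom
  write_tsv(both, paste0("variance_partition_", dom, ".tsv"))
  message(dom, ": segment explains ",
          round(100 * vp$R2[vp$factor == "segment"], 1),
          "% (QMP) vs ", round(100 * vpr$R2[vpr$factor == "segment"], 1),
          "% (RMP) of community variance")

  pq <- pcoa(dmx, k = 3)
  pr <- pcoa(bray_curtis_matrix(d$rmp), k = 3)
  pt <- protest_compare(pq$coords, pr$coords, n_perm = 499,
                        seed = stage_seed(SEED, "protest"))
  message(dom, ": QMP-RMP Procrustes m12 = ", round(pt$m12, 3),
          " (p = ", pt$p_value, ")")
}
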
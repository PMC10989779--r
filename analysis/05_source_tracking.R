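# EM source tracking: how much of each posterior segment's community is
# contributed by its adjacent anterior segment (same bird, same day).

source(file.path("analysis", "00_common.R"))

truth <- read_tsv("truth_transmission.tsv", DATA_DIR)

for (dom in domains) {
  d <- load_domain(dom)
  contrib <- adjacent_segment_contribution(
    d$counts, c("duodenum", "jejunum", "ileum", "cecum"),
    max_iter = 500, tol = 1e-9)
  contrib$domain <- dom
  write_tsv(contrib, paste0("adjacent_contribution_", dom, ".tsv"))
  means <- aggregate(proportion ~ sink_segment, contrib, mean)
  for (i in seq_len(nrow(means))) {
    pair <- truth$proportion[grepl(paste0("->", means$sink_segment[i]),
                                   truth$pair)]
    message(sprintf(
      "%s: %s receives %.2f from its anterior segment (planted %.2f)",
      dom, means$sink_segment[i], means$proportion[i], pair))
  }
}
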
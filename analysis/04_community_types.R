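# Dirichlet multinomial mixture community typing on binned log-transformed
# absolute abundances, with Laplace-based selection of the number of types.

source(file.path("analysis", "00_common.R"))

for (dom in domains) {
  d <- load_domain(dom)
  binned <- discretize_absolute(d$qmp)
  sel <- dmm_select(binned, 2:6, seed = stage_seed(SEED, "dmm"))
  write_tsv(sel$criteria, paste0("dmm_criteria_", dom, ".tsv"))
  write_tsv(data.frame(sample_id = rownames(d$qmp$mat),
                       type = sel$best_fit$assignment,
                       max_responsibility = apply(sel$best_fit$resp, 1, max)),
            paste0("community_types_", dom, ".tsv"))
  freq <- community_type_frequency(sel$best_fit, d$qmp$metadata)
  write_tsv(freq, paste0("community_type_frequency_", dom, ".tsv"))
  message(dom, ": Laplace selects ", sel$best_k, " community types")
  top <- freq[freq$dph > 1, ]
  for (sg in unique(top$segment)) {
    f <- top[top$segment == sg, ]
    lead <- f$type[which.max(tapply(f$freq, f$type, mean)[
      as.character(f$type)])]
    message("  ", sg, ": dominant type after hatch = ", lead)
  }
}
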
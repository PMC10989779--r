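# Generate the synthetic longitudinal study: 10 birds x 4 gut segments x
# 8 days posthatch, bacterial and fungal communities with qPCR-style
# loads, a phylogeny per domain, and a time-course serum metabolome with
# planted trajectory clusters and microbe-metabolite couplings.

source(file.path("analysis", "00_common.R"))

cfg <- sim_config(seed = stage_seed(SEED, "simulate"))
sim <- simulate_microbiome(cfg)
met <- simulate_metabolome(cfg, sim)

for (dom in domains) {
  write_feature_table(sim$tables[[dom]],
                      file.path(DATA_DIR, paste0("counts_", dom, ".tsv")))
  ape::write.tree(sim$trees[[dom]],
                  file.path(DATA_DIR, paste0("tree_", dom, ".nwk")))
}
write_tsv(sim$loads, "loads.tsv", DATA_DIR)
write_tsv(sim$truth$occurrence, "truth_occurrence.tsv", DATA_DIR)
write_tsv(sim$truth$community_type, "truth_community_type.tsv", DATA_DIR)
write_tsv(sim$truth$source_proportions, "truth_transmission.tsv", DATA_DIR)
write_tsv(met$truth, "truth_metabolome.tsv", DATA_DIR)
write_tsv(data.frame(sample_id = rownames(met$table$mat),
                     met$table$mat, check.names = FALSE),
          "metabolome_intensities.tsv", DATA_DIR)
write_tsv(met$table$metadata, "metabolome_metadata.tsv", DATA_DIR)
write_tsv(met$table$annotation, "metabolome_annotation.tsv", DATA_DIR)

message(sprintf(
  "simulated %d bacterial and %d fungal samples, %d metabolite features",
  n_samples(sim$tables$bacteria), n_samples(sim$tables$fungi),
  ncol(met$table$mat)))
message("cecal bacterial load spans ",
        paste(round(range(log10(sim$loads$load[
          sim$loads$domain == "bacteria" &
            grepl("cecum", sim$loads$sample_id)])), 1), collapse = " - "),
        " log10 copies/g across the 42 days")
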
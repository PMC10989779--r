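# Calibrate the qPCR standard curve, back-calculate per-sample loads from
# Ct values, and convert relative profiles into absolute (QMP) tables.

source(file.path("analysis", "00_common.R"))

# a perfect-efficiency 10^3..10^8 dilution series as the calibration
lg <- 3:8
curve <- fit_standard_curve(lg, 40 - log10(2)^-1 * lg)
print(curve)

for (dom in domains) {
  d <- load_domain(dom)
  # loads recomputed from the recorded Ct values match the table
  back <- ct_to_load(curve, d$loads_df$ct,
                     dilution_factor = d$loads_df$dilution_factor,
                     sample_weight = d$loads_df$weight)
  stopifnot(max(abs(back$load - d$loads_df$load) / d$loads_df$load) < 1e-9)
  write_feature_table(d$qmp, file.path(OUT_DIR, paste0("qmp_", dom, ".tsv")))
  message(sprintf(
    "%s: QMP row sums match measured loads to %.1e relative error",
    dom, max(abs(rowSums(d$qmp$mat) - d$loads[rownames(d$qmp$mat)]) /
               d$loads[rownames(d$qmp$mat)])))
}
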
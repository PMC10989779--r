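# Longitudinal occurrence patterns: per-genus presence trajectories under
# the 9-of-10-birds presence rule, classified into colonization /
# disappearance / core / irregular, with cross-segment intersections.

source(file.path("analysis", "00_common.R"))

truth <- read_tsv("truth_occurrence.tsv", DATA_DIR)

for (dom in domains) {
  d <- load_domain(dom)
  pc <- pattern_census(d$qmp)
  write_tsv(pc$trajectories, paste0("occurrence_", dom, ".tsv"))
  m <- merge(pc$trajectories, truth[truth$domain == dom, ],
             by.x = c("segment", "genus"), by.y = c("segment", "taxon"))
  message(sprintf("%s: %.1f%% of genus x segment trajectories match the planted category",
                  dom, 100 * mean(m$category.x == m$category.y)))
  print(pc$census)
  four_way <- pc$intersections$core[[paste(
    unique(pc$trajectories$segment), collapse = "&")]]
  message(dom, ": core genera shared by all four segments: ",
          if (length(four_way)) paste(four_way, collapse = ", ") else "none")
}
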
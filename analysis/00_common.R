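# Shared setup for the numbered analysis scripts. Each script can be run
# from the repository root after 01_simulate.R has produced results/data/.

library(qmpflow)

SEED <- 7
DATA_DIR <- file.path("results", "data")
OUT_DIR <- "results"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

domains <- c("bacteria", "fungi")

write_tsv <- function(df, name, dir = OUT_DIR) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

read_tsv <- function(name, dir = OUT_DIR)
  utils::read.table(file.path(dir, name), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)

# load the simulated study written by 01_simulate.R
load_domain <- function(dom) {
  counts <- read_feature_table(
    file.path(DATA_DIR, paste0("counts_", dom, ".tsv")), mode = "counts")
  loads_df <- read_tsv("loads.tsv", DATA_DIR)
  loads_df <- loads_df[loads_df$domain == dom, ]
  loads <- stats::setNames(loads_df$load, loads_df$sample_id)
  rmp <- to_relative(counts)
  list(counts = counts, loads = loads, loads_df = loads_df, rmp = rmp,
       qmp = qmp_transform(rmp, loads),
       tree = ape::read.tree(file.path(DATA_DIR,
                                       paste0("tree_", dom, ".nwk"))))
}

load_metabolome <- function() {
  mat <- as.matrix(read_tsv("metabolome_intensities.tsv", DATA_DIR)[, -1])
  ids <- read_tsv("metabolome_intensities.tsv", DATA_DIR)$sample_id
  rownames(mat) <- ids
  structure(list(
    mat = mat,
    metadata = read_tsv("metabolome_metadata.tsv", DATA_DIR),
    annotation = read_tsv("metabolome_annotation.tsv", DATA_DIR)),
    class = "metabolite_table")
}
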
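# Shared fixtures: generated in code, cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# full default simulated study (the study-design conditions), seed 11
default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(seed = 11)
    .fixture_env$cfg <- cfg
    .fixture_env$sim <- simulate_microbiome(cfg)
  }
  list(config = .fixture_env$cfg, sim = .fixture_env$sim)
}

# small, fast configuration: same design axes, fewer taxa/metabolites
small_config <- function(seed = 5, ...) {
  defaults <- list(
    n_taxa = c(bacteria = 24, fungi = 16),
    pattern_spec = list(
      bacteria = c(colonization = 6, disappearance = 2,
                   core = 4, irregular = 12),
      fungi = c(colonization = 4, disappearance = 2,
                core = 2, irregular = 8)),
    n_metabolites = 60, n_unknown_features = 10,
    block_n_microbes = 2, block_n_metabolites = 5,
    seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# tiny hand-built feature table
tiny_ft <- function(mat = NULL, mode = "counts") {
  if (is.null(mat)) {
    mat <- matrix(c(5, 3, 2,
                    1, 8, 1,
                    4, 4, 2), 3, 3, byrow = TRUE,
                  dimnames = list(paste0("s", 1:3), paste0("t", 1:3)))
  }
  md <- data.frame(sample_id = rownames(mat),
                   bird = seq_len(nrow(mat)),
                   segment = "cecum",
                   dph = 1,
                   domain = "bacteria", stringsAsFactors = FALSE)
  feature_table(mat, md, mode = mode)
}

# QMP tables + pattern census against truth for one domain of a sim
occurrence_agreement <- function(sim, dom) {
  l <- sim$loads[sim$loads$domain == dom, ]
  q <- qmp_transform(to_relative(sim$tables[[dom]]),
                     stats::setNames(l$load, l$sample_id))
  pc <- pattern_census(q)
  occ <- sim$truth$occurrence
  m <- merge(pc$trajectories, occ[occ$domain == dom, ],
             by.x = c("segment", "genus"), by.y = c("segment", "taxon"))
  mean(m$category.x == m$category.y)
}

# adjusted Rand index (independent of any clustering package)
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
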
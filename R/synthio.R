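#' Configuration for the synthetic longitudinal gut-microbiome study
#'
#' Builds the parameter set for a simulated study emulating a longitudinal,
#' multi-segment broiler-gut design: 10 birds sampled at 8 days posthatch
#' (DPH) in four gut segments, with bacterial and fungal communities,
#' qPCR-style total loads rising to a plateau by 7 DPH, segment-specific
#' community types, partial transmission between adjacent segments, planted
#' longitudinal occurrence patterns, and a serum metabolome in six
#' trajectory clusters partially coupled to microbe blocks.
#'
#' Load curves are logistic in time, L(t) = K / (1 + exp(-r (t - t0))),
#' with carrying capacity K in copies/g, rate r per day and inflection day
#' t0, multiplied by per-sample lognormal noise. Defaults place bacterial
#' loads at 1e8 (duodenum) to 1e10 (cecum) copies/g with the plateau
#' reached by 7 DPH, and fungal loads two to three orders lower with the
#' ileum above the cecum.
#'
#' @param n_birds birds per time point (default 10)
#' @param segments ordered gut segments, anterior to posterior
#' @param timepoints strictly increasing sampling days posthatch
#' @param n_taxa named integer vector: taxa per domain
#' @param n_community_types named integer vector: Dirichlet-multinomial
#'   community types per domain (5 bacterial, 4 fungal by default)
#' @param load_curve nested list `load_curve[[domain]][[segment]]` each with
#'   K, r, t0; see Details
#' @param load_sdlog lognormal noise sd (natural log) on loads
#' @param transmission named vector of adjacent-segment mixing proportions
#'   in [0,1], names like "jejunum->ileum"
#' @param pattern_spec nested list per domain with integer counts
#'   colonization / disappearance / core / irregular summing to the
#'   domain's n_taxa
#' @param dm_precision Dirichlet precision (sum of alpha) around community
#'   centroids; lower = more overdispersion
#' @param pattern_floor minimum centroid relative abundance granted to
#'   pattern (colonization/disappearance/core) taxa so that their planted
#'   presence clears the detection limit
#' @param detection_limit absolute detection threshold in copies/g; cells
#'   below it are zeroed before count sampling (models the qPCR standard
#'   curve's lowest calibrated point)
#' @param mean_depth mean sequencing depth per sample
#' @param n_metabolites serum metabolite features (annotated)
#' @param n_unknown_features extra unannotated features (removed by the
#'   metabolome filter)
#' @param metab_cluster_weights relative sizes of the six trajectory
#'   clusters among time-associated metabolites
#' @param metab_flat_fraction fraction of metabolites with no time trend
#' @param metab_amplitude trajectory amplitude in log10-intensity units
#' @param metab_noise_sd residual sd on log10 intensities
#' @param coupling strength in [0,1] of the planted microbe-metabolite
#'   coupling (linear on log scale)
#' @param n_coupled_blocks number of planted microbe-metabolite blocks
#' @param block_n_microbes,block_n_metabolites block sizes
#' @param seed integer master seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(
    n_birds = 10,
    segments = c("duodenum", "jejunum", "ileum", "cecum"),
    timepoints = c(1, 4, 7, 14, 21, 28, 35, 42),
    n_taxa = c(bacteria = 120, fungi = 80),
    n_community_types = c(bacteria = 5, fungi = 4),
    load_curve = NULL,
    load_sdlog = 0.5,
    transmission = c("duodenum->jejunum" = 0.1,
                     "jejunum->ileum" = 0.5,
                     "ileum->cecum" = 0.1),
    pattern_spec = list(
      bacteria = c(colonization = 30, disappearance = 8,
                   core = 12, irregular = 70),
      fungi = c(colonization = 15, disappearance = 12,
                core = 10, irregular = 43)),
    dm_precision = 500,
    pattern_floor = 0.006,
    detection_limit = 1e3,
    mean_depth = 2e4,
    n_metabolites = 1000,
    n_unknown_features = 80,
    metab_cluster_weights = c(22, 318, 143, 24, 97, 37),
    metab_flat_fraction = 0.4,
    metab_amplitude = 1.0,
    metab_noise_sd = 0.25,
    coupling = 0.9,
    n_coupled_blocks = 2,
    block_n_microbes = 8,
    block_n_metabolites = 25,
    seed = 1L) {
  if (is.null(load_curve)) {
    load_curve <- list(
      bacteria = list(
        duodenum = list(K = 1e8,  r = 1.5, t0 = 3.5),
        jejunum  = list(K = 5e8,  r = 1.5, t0 = 3.5),
        ileum    = list(K = 1e9,  r = 1.5, t0 = 3.5),
        cecum    = list(K = 1e10, r = 1.5, t0 = 3.5)),
      fungi = list(
        duodenum = list(K = 1e7,  r = 2.0, t0 = 2),
        jejunum  = list(K = 2e7,  r = 2.0, t0 = 2),
        ileum    = list(K = 5e7,  r = 2.0, t0 = 2),
        cecum    = list(K = 2e7,  r = 2.0, t0 = 2)))
    load_curve <- lapply(load_curve, function(d) d[segments])
  }
  cfg <- list(n_birds = n_birds, segments = segments,
              timepoints = timepoints, n_taxa = n_taxa,
              n_community_types = n_community_types,
              load_curve = load_curve, load_sdlog = load_sdlog,
              transmission = transmission, pattern_spec = pattern_spec,
              dm_precision = dm_precision, pattern_floor = pattern_floor,
              detection_limit = detection_limit, mean_depth = mean_depth,
              n_metabolites = n_metabolites,
              n_unknown_features = n_unknown_features,
              metab_cluster_weights = metab_cluster_weights,
              metab_flat_fraction = metab_flat_fraction,
              metab_amplitude = metab_amplitude,
              metab_noise_sd = metab_noise_sd,
              coupling = coupling, n_coupled_blocks = n_coupled_blocks,
              block_n_microbes = block_n_microbes,
              block_n_metabolites = block_n_metabolites,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_birds >= 1, length(cfg$segments) >= 1)
  if (any(diff(cfg$timepoints) <= 0))
    stop("timepoints must be strictly increasing")
  if (any(cfg$transmission < 0 | cfg$transmission > 1))
    stop("transmission proportions must lie in [0,1]")
  for (dom in names(cfg$n_taxa)) {
    ps <- cfg$pattern_spec[[dom]]
    if (is.null(ps) || sum(ps) != cfg$n_taxa[[dom]])
      stop("pattern_spec counts for ", dom, " must sum to n_taxa (",
           cfg$n_taxa[[dom]], ")")
  }
  if (any(cfg$n_taxa <= 0) || cfg$mean_depth <= 0)
    stop("counts must be positive")
  invisible(cfg)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

logistic_load <- function(t, p) p$K / (1 + exp(-p$r * (t - p$t0)))

sample_id_of <- function(bird, segment, dph)
  sprintf("B%02d_%s_D%02d", bird, segment, dph)

#' Simulate the longitudinal multi-segment microbiome with ground truth
#'
#' For each domain (bacteria, fungi): community-type centroids are drawn,
#' every (segment, day) stratum is assigned a dominant type (all segments
#' share one "hatch" type at the first day, then types become segment
#' specific), each sample's relative profile is a Dirichlet draw around its
#' type centroid mixed with the same bird's adjacent anterior segment in the
#' configured proportion, planted occurrence patterns zero colonizing taxa
#' before their onset (and disappearing taxa after their offset), total
#' loads follow the logistic curve times lognormal noise, cells whose
#' absolute abundance falls below the detection limit are zeroed, and
#' counts are drawn multinomially at the sample's sequencing depth.
#'
#' A random coalescent tree with the domain's taxa as tips is generated per
#' domain for phylogenetic null models.
#'
#' @param config a [sim_config()]
#' @return list with `tables` (counts feature_table per domain), `loads`
#'   (data.frame: sample_id, domain, load, true_load, weight, ct),
#'   `curves` (the standard_curve per domain used to emit Ct values),
#'   `trees` (ape phylo per domain), and `truth` (ground-truth labels:
#'   community types, source proportions, occurrence categories with
#'   onsets/offsets, load curve parameters)
#' @export
simulate_microbiome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  domains <- names(config$n_taxa)
  segs <- config$segments
  tps <- config$timepoints
  nb <- config$n_birds

  tables <- list(); trees <- list(); loads_all <- list()
  truth_type <- list(); truth_occ <- list()
  curves <- list()

  for (dom in domains) {
    J <- config$n_taxa[[dom]]
    K <- config$n_community_types[[dom]]
    taxa <- sprintf("%s_g%03d", substr(dom, 1, 1), seq_len(J))
    ps <- config$pattern_spec[[dom]]
    category <- rep(names(ps), times = ps)
    category <- sample(category)  # shuffle which taxon gets which pattern
    names(category) <- taxa
    onset <- stats::setNames(rep(NA_real_, J), taxa)
    offset <- stats::setNames(rep(NA_real_, J), taxa)
    col_idx <- which(category == "colonization")
    dis_idx <- which(category == "disappearance")
    onset[col_idx] <- sample(tps[2:5], length(col_idx), replace = TRUE)
    offset[dis_idx] <- sample(tps[3:6], length(dis_idx), replace = TRUE)

    # community-type centroids: a lognormal backbone shared across types
    # plus type-specific dominant taxa; pattern taxa get an abundance floor
    backbone <- stats::rlnorm(J, meanlog = 0, sdlog = 1.2)
    centroids <- matrix(0, K, J, dimnames = list(NULL, taxa))
    dominants <- split(sample(which(category == "irregular")),
                       rep_len(seq_len(K), sum(category == "irregular")))
    for (k in seq_len(K)) {
      v <- backbone * stats::rlnorm(J, 0, 0.4)
      v[dominants[[k]]] <- v[dominants[[k]]] * 40
      v <- v / sum(v)
      fl <- config$pattern_floor
      pat <- category != "irregular"
      v[pat] <- pmax(v[pat], fl)
      centroids[k, ] <- v / sum(v)
    }

    # type assignment per (segment, dph): one shared type at hatch, then
    # segment-specific types (cycled when segments outnumber types)
    type_of <- function(seg, t) {
      if (t == tps[1]) return(1L)
      si <- match(seg, segs)
      2L + ((si - 1L) %% (K - 1L))  # types 2..K cycled over segments
    }

    # per-sample relative profiles (pre-transmission)
    base_prof <- array(NA_real_,
                       dim = c(nb, length(segs), length(tps), J))
    for (b in seq_len(nb)) for (si in seq_along(segs)) {
      for (ti in seq_along(tps)) {
        k <- type_of(segs[si], tps[ti])
        base_prof[b, si, ti, ] <-
          rdirichlet1(centroids[k, ] * config$dm_precision)
      }
    }
    # occurrence-pattern masking on the pre-transmission profiles:
    # colonizers are zeroed before onset, disappearing taxa after offset,
    # irregular taxa flicker independently of time
    for (ti in seq_along(tps)) {
      t <- tps[ti]
      off_now <- which(!is.na(onset) & t < onset)
      gone_now <- which(!is.na(offset) & t >= offset)
      irr <- which(category == "irregular")
      for (b in seq_len(nb)) {
        # irregular taxa flicker at the bird level (carriage), so a taxon
        # dropped in one bird is absent from all of that bird's segments
        # and cannot re-enter a posterior segment through transmission
        drop_irr <- irr[stats::runif(length(irr)) < 0.3]
        for (si in seq_along(segs)) {
          v <- base_prof[b, si, ti, ]
          v[off_now] <- 0
          v[gone_now] <- 0
          v[drop_irr] <- 0
          base_prof[b, si, ti, ] <- v / sum(v)
        }
      }
    }
    # transmission mixing along the segment chain, anterior to posterior:
    # each segment receives the adjacent anterior segment's realized
    # (post-masking) community in the configured proportion
    mixed <- base_prof
    for (si in seq_along(segs)[-1]) {
      key <- paste0(segs[si - 1], "->", segs[si])
      m <- if (key %in% names(config$transmission))
        config$transmission[[key]] else 0
      if (m > 0)
        mixed[, si, , ] <- (1 - m) * base_prof[, si, , ] +
          m * mixed[, si - 1, , ]
    }

    # loads, detection limit, counts
    curve <- structure(list(slope = -1 / log10(2), intercept = 40,
                            r_squared = 1, efficiency = 100, domain = dom,
                            range_log10 = c(3, 8),
                            range_ct = 40 + (-1 / log10(2)) * c(8, 3)),
                       class = "standard_curve")
    curves[[dom]] <- curve
    rows <- list(); counts <- list(); meta_rows <- list()
    load_rows <- list()
    for (b in seq_len(nb)) for (si in seq_along(segs)) {
      for (ti in seq_along(tps)) {
        id <- sample_id_of(b, segs[si], tps[ti])
        lc <- config$load_curve[[dom]][[segs[si]]]
        true_load <- logistic_load(tps[ti], lc)
        load <- true_load * stats::rlnorm(1, 0, config$load_sdlog)
        p <- mixed[b, si, ti, ]
        aa <- p * load
        p[aa < config$detection_limit] <- 0
        # pattern taxa in their planted "present" phase are clamped just
        # above the detection limit so planted occurrence is guaranteed
        t <- tps[ti]
        active <- (category == "core") |
          (category == "colonization" & !is.na(onset) & t >= onset) |
          (category == "disappearance" & !is.na(offset) & t < offset)
        clamp <- 1.5 * config$detection_limit / load
        p[active] <- pmax(p[active], clamp)
        if (sum(p) == 0) p[which.max(aa)] <- 1
        p <- p / sum(p)
        depth <- max(1000, round(stats::rlnorm(1, log(config$mean_depth), 0.2)))
        cnt <- as.vector(stats::rmultinom(1, depth, p))
        counts[[length(counts) + 1]] <- cnt
        meta_rows[[length(meta_rows) + 1]] <- data.frame(
          sample_id = id, bird = b, segment = segs[si], dph = tps[ti],
          domain = dom, stringsAsFactors = FALSE)
        weight <- round(stats::runif(1, 0.1, 0.3), 3)
        copies_rxn <- load * weight / 100  # dilution factor 100
        load_rows[[length(load_rows) + 1]] <- data.frame(
          sample_id = id, domain = dom, load = load, true_load = true_load,
          weight = weight, dilution_factor = 100,
          ct = curve$intercept + curve$slope * log10(copies_rxn),
          stringsAsFactors = FALSE)
        rows[length(rows) + 1] <- id
        truth_type[[length(truth_type) + 1]] <- data.frame(
          sample_id = id, domain = dom,
          community_type = type_of(segs[si], tps[ti]),
          stringsAsFactors = FALSE)
      }
    }
    mat <- do.call(rbind, counts)
    rownames(mat) <- unlist(rows)
    colnames(mat) <- taxa
    md <- do.call(rbind, meta_rows)
    phylum <- sprintf("p__%sP%d", toupper(substr(dom, 1, 1)),
                      rep_len(1:6, J))
    lineage <- sprintf("d__%s;%s;c__;o__;f__F%03d;g__%s",
                       paste0(toupper(substr(dom, 1, 1)), substring(dom, 2)),
                       phylum, rep_len(1:30, J), taxa)
    tables[[dom]] <- feature_table(mat, md, taxonomy = lineage,
                                   mode = "counts")
    loads_all[[dom]] <- do.call(rbind, load_rows)
    tree <- ape::rcoal(J, tip.label = sample(taxa))
    trees[[dom]] <- tree
    truth_occ[[dom]] <- do.call(rbind, lapply(segs, function(sg)
      data.frame(domain = dom, taxon = taxa, segment = sg,
                 category = unname(category), onset = unname(onset),
                 offset = unname(offset), stringsAsFactors = FALSE)))
  }

  source_truth <- data.frame(
    pair = names(config$transmission),
    proportion = unname(config$transmission), stringsAsFactors = FALSE)

  list(tables = tables,
       loads = do.call(rbind, loads_all),
       curves = curves,
       trees = trees,
       truth = list(
         community_type = do.call(rbind, truth_type),
         source_proportions = source_truth,
         occurrence = do.call(rbind, truth_occ),
         detection_limit = config$detection_limit,
         load_curve = config$load_curve))
}

metab_templates <- list(
  "monotone-up"   = function(u) u,
  "monotone-down" = function(u) 1 - u,
  "step-up"       = function(u) as.numeric(u > 0),
  "step-down"     = function(u) as.numeric(u == 0),
  "up-then-down"  = function(u) 1 - abs(2 * u - 1),
  "gradual-down"  = function(u) (1 - u)^2,
  "flat"          = function(u) rep(0.5, length(u)))

#' Simulate the time-course serum metabolome
#'
#' Each metabolite's mean log10-intensity trajectory follows one of six
#' templates (monotone-up, monotone-down, step-up after the first day,
#' step-down after the first day, up-then-down, gradual-down) scaled by
#' `metab_amplitude`, plus Gaussian noise on the log scale; a configurable
#' fraction is flat (no time association). Designated metabolite blocks are
#' additionally coupled, linearly on the log scale, to the standardized
#' log-abundance of designated cecal microbe blocks in the matched bird and
#' day, planting microbe-metabolite co-occurrence. A set of unannotated
#' features is appended so the metabolome filtering step has work to do.
#'
#' @param config a [sim_config()]
#' @param sim the result of [simulate_microbiome()] on the same config
#'   (needed for the coupled blocks); may be NULL for an uncoupled
#'   metabolome
#' @return list with `table` (a `metabolite_table`: intensities on the
#'   linear scale, sample metadata, chemical-taxonomy annotation) and
#'   `truth` (cluster label, template, coupled-block membership per
#'   metabolite, and the coupled microbe sets)
#' @export
simulate_metabolome <- function(config, sim = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  tps <- config$timepoints
  nb <- config$n_birds
  nm <- config$n_metabolites
  ids <- as.vector(t(outer(seq_len(nb), tps,
                           function(b, t) sprintf("SR_B%02d_D%02d", b, t))))
  meta <- data.frame(
    sample_id = ids,
    bird = rep(seq_len(nb), each = length(tps)),
    dph = rep(tps, times = nb), stringsAsFactors = FALSE)
  if (nm == 0) {
    emptab <- structure(list(
      mat = matrix(0, nrow(meta), 0,
                   dimnames = list(meta$sample_id, character(0))),
      metadata = meta,
      annotation = data.frame(metabolite = character(0),
                              superclass = character(0),
                              class = character(0),
                              subclass = character(0))),
      class = "metabolite_table")
    return(list(table = emptab,
                truth = data.frame(metabolite = character(0),
                                   cluster = integer(0),
                                   template = character(0),
                                   coupled_block = integer(0))))
  }
  mets <- sprintf("met%04d", seq_len(nm))
  n_flat <- round(config$metab_flat_fraction * nm)
  n_assoc <- nm - n_flat
  w <- config$metab_cluster_weights
  sizes <- floor(w / sum(w) * n_assoc)
  rem <- n_assoc - sum(sizes)
  if (rem > 0) sizes[order(-(w / sum(w) * n_assoc - sizes))[seq_len(rem)]] <-
      sizes[order(-(w / sum(w) * n_assoc - sizes))[seq_len(rem)]] + 1
  cluster <- c(rep(seq_len(6), times = sizes), rep(0L, n_flat))
  cluster <- sample(cluster)
  names(cluster) <- mets
  # cluster shapes: 1 and 3 rise, 2 jumps up after hatch, 4 drops after
  # hatch, 5 rises then falls, 6 declines gradually
  templates <- c("monotone-up", "step-up", "monotone-down", "step-down",
                 "up-then-down", "gradual-down")
  template_of <- ifelse(cluster == 0, "flat", templates[pmax(cluster, 1)])
  u <- (seq_along(tps) - 1) / (length(tps) - 1)

  superclasses <- c("Lipids and lipid-like molecules",
                    "Organic acids and derivatives",
                    "Benzenoids",
                    "Organoheterocyclic compounds",
                    "Organic oxygen compounds",
                    "Phenylpropanoids and polyketides",
                    "Nucleosides, nucleotides, and analogues")
  # planted chemistry: cluster 1 benzenoid-heavy, 2-3 lipid-heavy,
  # 4 organic-acid-heavy, 6 organic-oxygen-heavy
  sc_probs <- function(cl) {
    p <- rep(1, length(superclasses))
    if (cl == 1) p[3] <- 8
    if (cl %in% c(2, 3)) p[1] <- 8
    if (cl == 4) p[2] <- 8
    if (cl == 6) p[5] <- 8
    p / sum(p)
  }
  superclass <- vapply(cluster, function(cl)
    sample(superclasses, 1, prob = sc_probs(cl)), character(1))

  # coupled blocks: cecal bacterial genera with stable presence
  blocks <- list()
  coupled_block <- stats::setNames(rep(0L, nm), mets)
  if (!is.null(sim) && config$n_coupled_blocks > 0) {
    occ <- sim$truth$occurrence
    stable <- unique(occ$taxon[occ$domain == "bacteria" &
                                 occ$category == "core"])
    assoc_mets <- names(cluster)[cluster > 0]
    avail <- stable
    for (bl in seq_len(config$n_coupled_blocks)) {
      mi <- utils::head(avail, config$block_n_microbes)
      avail <- setdiff(avail, mi)
      mm <- sample(assoc_mets, config$block_n_metabolites)
      assoc_mets <- setdiff(assoc_mets, mm)
      coupled_block[mm] <- bl
      blocks[[bl]] <- list(microbes = mi, metabolites = mm,
                           segment = "cecum", domain = "bacteria")
    }
  }

  base <- stats::runif(nm, 5, 7)
  amp <- config$metab_amplitude
  logmat <- matrix(NA_real_, nrow(meta), nm,
                   dimnames = list(meta$sample_id, mets))
  # microbe block signal per (bird, dph)
  block_z <- NULL
  if (length(blocks)) {
    cec <- sim$tables$bacteria
    qmp_cec <- qmp_transform(
      cec, stats::setNames(sim$loads$load, sim$loads$sample_id)[
        sim$loads$domain == "bacteria"])
    block_z <- lapply(blocks, function(bl) {
      idx <- paste0("B", sprintf("%02d", meta$bird), "_cecum_D",
                    sprintf("%02d", meta$dph))
      v <- log10(1 + rowMeans(qmp_cec$mat[idx, bl$microbes, drop = FALSE]))
      as.vector(scale(v))
    })
  }
  ti_of <- match(meta$dph, tps)
  for (j in seq_len(nm)) {
    f <- metab_templates[[template_of[j]]]
    mu <- base[j] + amp * f(u)[ti_of]
    if (coupled_block[j] > 0)
      mu <- mu + config$coupling * block_z[[coupled_block[j]]]
    logmat[, j] <- mu + stats::rnorm(nrow(meta), 0, config$metab_noise_sd)
  }
  mat <- 10^logmat

  ann <- data.frame(
    metabolite = mets, superclass = superclass,
    class = paste0(substr(superclass, 1, 3), "_class",
                   rep_len(1:4, nm)),
    subclass = paste0("sub", rep_len(1:8, nm)),
    stringsAsFactors = FALSE)

  # unannotated extras with scattered missingness
  nu <- config$n_unknown_features
  if (nu > 0) {
    umat <- matrix(10^stats::rnorm(nrow(meta) * nu, 5, 1), nrow(meta), nu,
                   dimnames = list(meta$sample_id,
                                   sprintf("unk%04d", seq_len(nu))))
    zero_mask <- matrix(stats::runif(length(umat)) < 0.5, nrow(umat))
    umat[zero_mask] <- 0
    mat <- cbind(mat, umat)
    ann <- rbind(ann, data.frame(
      metabolite = colnames(umat), superclass = "unknown",
      class = "unknown", subclass = "unknown", stringsAsFactors = FALSE))
  }

  tab <- structure(list(mat = mat, metadata = meta, annotation = ann),
                   class = "metabolite_table")
  truth <- data.frame(metabolite = mets, cluster = unname(cluster),
                      template = unname(template_of),
                      coupled_block = unname(coupled_block),
                      stringsAsFactors = FALSE)
  list(table = tab, truth = truth, blocks = blocks)
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table: %d samples x %d features (%d annotated)\n",
              nrow(x$mat), ncol(x$mat),
              sum(x$annotation$superclass != "unknown")))
  invisible(x)
}

#' Simulate counts from a Dirichlet-multinomial mixture
#'
#' Small simulator used to validate community typing: K components with
#' distinct dominant taxa, samples drawn p ~ Dirichlet(alpha_k), counts ~
#' Multinomial(depth, p).
#'
#' @param n samples
#' @param n_taxa taxa
#' @param k components
#' @param depth reads per sample
#' @param precision Dirichlet precision (sum of alpha) per component
#' @param separation fold enrichment of each component's dominant taxa
#' @param seed RNG seed
#' @return list with `counts` (n x n_taxa), `labels` (true component per
#'   sample), `alpha` (K x n_taxa component parameters)
#' @export
simulate_dm_mixture <- function(n, n_taxa, k, depth = 5e4, precision = 30,
                                separation = 20, seed = 1) {
  set.seed(seed)
  taxa <- sprintf("t%03d", seq_len(n_taxa))
  dominants <- split(seq_len(n_taxa),
                     rep_len(seq_len(k), n_taxa))
  alpha <- matrix(1, k, n_taxa, dimnames = list(NULL, taxa))
  for (kk in seq_len(k)) {
    v <- rep(1, n_taxa)
    v[dominants[[kk]]] <- separation
    alpha[kk, ] <- v / sum(v) * precision
  }
  labels <- sort(rep_len(seq_len(k), n))
  counts <- t(vapply(labels, function(kk)
    as.vector(stats::rmultinom(1, depth, rdirichlet1(alpha[kk, ]))),
    numeric(n_taxa)))
  dimnames(counts) <- list(sprintf("s%03d", seq_len(n)), taxa)
  list(counts = counts, labels = labels, alpha = alpha)
}
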
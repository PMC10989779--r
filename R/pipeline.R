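#' Derive a stage seed from the master seed
#'
#' Each pipeline stage draws its randomness from its own seed derived by
#' hashing the stage name into the master seed, so re-running any subset
#' of stages reproduces the full run's results bit for bit.
#'
#' @param master integer master seed
#' @param stage stage name
#' @return integer seed (< 2^31)
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 1009 + h * 7919) %% 2147483647)
}

#' Run the full synthetic-data pipeline
#'
#' Simulates the study (microbiome + loads + metabolome), then executes
#' the analysis stages in dependency order: QMP transform, community
#' structure (diversity, adjacent-time turnover, variance partition),
#' community typing, source tracking, assembly null models, occurrence
#' patterns, co-occurrence networks with the QMP/RMP consistency
#' cross-tab, metabolome modelling, and microbe-metabolite integration.
#' Stage outputs are written as TSV under `out_dir` together with a JSON
#' manifest recording parameters and per-stage seeds. Problem sizes of the
#' heavier stages (assembly pairs, permutations, epochs) are configurable.
#'
#' @param out_dir output directory (created)
#' @param seed master seed
#' @param config optional [sim_config()] (default built from the seed)
#' @param stages character vector of stages to run (default all)
#' @param n_null null draws for assembly statistics
#' @param max_pairs cap on assembly pairs per segment
#' @param n_perm permutations for PERMANOVA
#' @param dmm_k_range candidate community-type counts
#' @param mmvec_epochs training epochs for the co-occurrence model
#' @return invisible list of stage results (also serialised to out_dir)
#' @export
run_pipeline <- function(out_dir, seed = 1, config = NULL,
                         stages = c("simulate", "quantify", "structure",
                                    "commtypes", "sourcetrack", "assembly",
                                    "occurrence", "conetwork", "metabolome",
                                    "integrate"),
                         n_null = 199, max_pairs = 30, n_perm = 199,
                         dmm_k_range = 2:6, mmvec_epochs = 200) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config)) config <- sim_config(seed = stage_seed(seed, "simulate"))
  res <- list()
  manifest <- list(seed = seed, created = format(Sys.time(), "%Y-%m-%d"),
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  tsv <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ## simulate
  sim <- simulate_microbiome(config)
  met <- simulate_metabolome(config, sim)
  res$sim <- sim; res$met <- met
  tsv(sim$loads, "loads.tsv")
  for (dom in names(sim$tables)) {
    write_feature_table(sim$tables[[dom]],
                        file.path(out_dir, paste0("counts_", dom, ".tsv")))
    ape::write.tree(sim$trees[[dom]],
                    file.path(out_dir, paste0("tree_", dom, ".nwk")))
  }
  tsv(sim$truth$occurrence, "truth_occurrence.tsv")
  tsv(sim$truth$community_type, "truth_community_type.tsv")
  tsv(met$truth, "truth_metabolome.tsv")
  note("simulate", seed = config$seed)
  if (!"quantify" %in% stages) {
    # every analysis stage consumes QMP/RMP tables
    dependent <- setdiff(stages, c("simulate", "sourcetrack", "assembly"))
    if (length(dependent))
      message("stages skipped (quantify disabled): ",
              paste(dependent, collapse = ", "))
    stages <- intersect(stages, c("simulate", "sourcetrack", "assembly"))
  }

  ## quantify: QMP + RMP per domain
  qmp <- list(); rmp <- list()
  if ("quantify" %in% stages) {
    for (dom in names(sim$tables)) {
      lds <- sim$loads[sim$loads$domain == dom, ]
      rmp[[dom]] <- to_relative(sim$tables[[dom]])
      qmp[[dom]] <- qmp_transform(rmp[[dom]],
                                  stats::setNames(lds$load, lds$sample_id))
      write_feature_table(qmp[[dom]],
                          file.path(out_dir, paste0("qmp_", dom, ".tsv")))
    }
    res$qmp <- qmp; res$rmp <- rmp
    note("quantify", domains = names(qmp))
  }

  ## structure
  if ("structure" %in% stages) {
    st_seed <- stage_seed(seed, "structure")
    div <- do.call(rbind, lapply(names(qmp), function(dom) {
      data.frame(sample_id = rownames(qmp[[dom]]$mat), domain = dom,
                 shannon = apply(qmp[[dom]]$mat, 1, shannon),
                 stringsAsFactors = FALSE)
    }))
    tsv(div, "shannon.tsv")
    adj <- do.call(rbind, lapply(names(qmp), function(dom)
      do.call(rbind, lapply(config$segments, function(sg) {
        d <- adjacent_time_dissimilarity(qmp[[dom]], sg)
        d$domain <- dom; d$segment <- sg; d
      }))))
    tsv(adj, "adjacent_time_bray.tsv")
    vp <- do.call(rbind, lapply(names(qmp), function(dom) {
      dm <- bray_curtis_matrix(qmp[[dom]])
      v <- variance_partition(dm, qmp[[dom]]$metadata,
                              c("bird", "segment", "dph"),
                              n_perm = n_perm, seed = st_seed)
      v$domain <- dom; v$mode <- "QMP"
      v2 <- variance_partition(bray_curtis_matrix(rmp[[dom]]),
                               rmp[[dom]]$metadata,
                               c("bird", "segment", "dph"),
                               n_perm = n_perm, seed = st_seed)
      v2$domain <- dom; v2$mode <- "RMP"
      rbind(v, v2)
    }))
    tsv(vp, "variance_partition.tsv")
    pro <- do.call(rbind, lapply(names(qmp), function(dom) {
      pq <- pcoa(bray_curtis_matrix(qmp[[dom]]), k = 3)
      pr <- pcoa(bray_curtis_matrix(rmp[[dom]]), k = 3)
      pt <- protest_compare(pq$coords, pr$coords, n_perm = n_perm,
                            seed = st_seed)
      data.frame(domain = dom, m12 = pt$m12, p_value = pt$p_value)
    }))
    tsv(pro, "qmp_rmp_protest.tsv")
    res$structure <- list(diversity = div, adjacent = adj,
                          variance = vp, protest = pro)
    note("structure", n_perm = n_perm, seed = st_seed)
  }

  ## community types
  if ("commtypes" %in% stages) {
    ct_seed <- stage_seed(seed, "commtypes")
    ct <- lapply(names(qmp), function(dom) {
      binned <- discretize_absolute(qmp[[dom]])
      sel <- dmm_select(binned, dmm_k_range, seed = ct_seed)
      freq <- community_type_frequency(sel$best_fit, qmp[[dom]]$metadata)
      tsv(data.frame(sample_id = rownames(qmp[[dom]]$mat),
                     type = sel$best_fit$assignment),
          paste0("community_types_", dom, ".tsv"))
      list(selection = sel, freq = freq)
    })
    names(ct) <- names(qmp)
    res$commtypes <- ct
    note("commtypes", k_range = dmm_k_range, seed = ct_seed,
         best_k = vapply(ct, function(x) x$selection$best_k, numeric(1)))
  }

  ## source tracking
  if ("sourcetrack" %in% stages) {
    src <- lapply(names(sim$tables), function(dom) {
      contrib <- adjacent_segment_contribution(sim$tables[[dom]],
                                               config$segments,
                                               max_iter = 500, tol = 1e-9)
      contrib$domain <- dom
      contrib
    })
    src <- do.call(rbind, src)
    tsv(src, "adjacent_contribution.tsv")
    res$sourcetrack <- src
    note("sourcetrack", pairs = nrow(src))
  }

  ## assembly
  if ("assembly" %in% stages) {
    as_seed <- stage_seed(seed, "assembly")
    asm <- do.call(rbind, lapply(names(sim$tables), function(dom) {
      a <- assembly_pairwise(sim$tables[[dom]], sim$trees[[dom]],
                             n_null = n_null, seed = as_seed,
                             max_pairs = max_pairs)
      a$domain <- dom
      a
    }))
    tsv(asm, "assembly_pairs.tsv")
    summ <- summarize_processes(asm, by = "domain")
    tsv(summ, "assembly_summary.tsv")
    res$assembly <- list(pairs = asm, summary = summ)
    note("assembly", n_null = n_null, max_pairs = max_pairs, seed = as_seed)
  }

  ## occurrence
  if ("occurrence" %in% stages) {
    occ <- lapply(names(qmp), function(dom) pattern_census(qmp[[dom]]))
    names(occ) <- names(qmp)
    for (dom in names(occ))
      tsv(occ[[dom]]$trajectories, paste0("occurrence_", dom, ".tsv"))
    res$occurrence <- occ
    note("occurrence", presence_min = 9, absence_max = 1)
  }

  ## co-occurrence networks
  if ("conetwork" %in% stages) {
    nets_q <- list(); nets_r <- list(); cons <- list()
    for (sg in config$segments) {
      # pool bacteria and fungi into one table per segment
      tabs <- lapply(names(qmp), function(dom)
        ft_subset(qmp[[dom]], samples = qmp[[dom]]$metadata$segment == sg))
      ids <- rownames(tabs[[1]]$mat)
      mat <- do.call(cbind, lapply(tabs, function(t)
        t$mat[ids, , drop = FALSE]))
      md <- tabs[[1]]$metadata
      ftq <- feature_table(mat, md, mode = "counts")
      fq <- prevalence_filter(ftq)
      nets_q[[sg]] <- build_network(fq, mode = "QMP", segment = sg)
      tabs_r <- lapply(names(rmp), function(dom)
        ft_subset(rmp[[dom]], samples = rmp[[dom]]$metadata$segment == sg))
      matr <- do.call(cbind, lapply(tabs_r, function(t)
        t$mat[ids, , drop = FALSE]))
      ftr <- feature_table(matr, md, mode = "counts")
      fr <- prevalence_filter(ftr)
      fr <- ft_subset(fr, taxa = intersect(colnames(fq$mat),
                                           colnames(fr$mat)))
      fq2 <- ft_subset(fq, taxa = colnames(fr$mat))
      nets_r[[sg]] <- build_network(fr, mode = "RMP", segment = sg)
      cons[[sg]] <- qmp_rmp_consistency(build_network(fq2, mode = "QMP",
                                                      segment = sg),
                                        nets_r[[sg]])
      tsv(nets_q[[sg]]$edges, paste0("network_qmp_", sg, ".tsv"))
    }
    topo <- do.call(rbind, lapply(names(nets_q), function(sg) {
      t <- topology(nets_q[[sg]]); t$segment <- sg; t
    }))
    tsv(topo, "network_topology.tsv")
    sharing <- edge_sharing(nets_q)
    res$conetwork <- list(qmp = nets_q, rmp = nets_r,
                          consistency = cons, topology = topo,
                          sharing = sharing)
    note("conetwork", consistency = vapply(cons, function(x)
      x$consistency, numeric(1)))
  }

  ## metabolome
  if ("metabolome" %in% stages) {
    filt <- filter_features(met$table)
    assoc <- glm_time_association(filt)
    assoc_tab <- structure(list(
      mat = filt$mat[, assoc$metabolite[assoc$associated], drop = FALSE],
      metadata = filt$metadata, annotation = filt$annotation),
      class = "metabolite_table")
    clus <- cluster_trajectories(assoc_tab, k = 6)
    comp <- cluster_composition(clus$cluster, filt$annotation)
    op <- opls_da(filt, groups = factor(filt$metadata$dph))
    tsv(assoc, "metabolite_time_association.tsv")
    tsv(data.frame(metabolite = names(clus$cluster),
                   cluster = clus$cluster), "metabolite_clusters.tsv")
    res$metabolome <- list(filtered = filt, association = assoc,
                           clusters = clus, composition = comp, opls = op)
    note("metabolome", n_kept = ncol(filt$mat),
         n_associated = sum(assoc$associated))
  }

  ## integrate
  if ("integrate" %in% stages && !is.null(res$metabolome)) {
    in_seed <- stage_seed(seed, "integrate")
    met_mat <- res$metabolome$filtered$mat
    met_meta <- res$metabolome$filtered$metadata
    scored <- list()
    for (sg in config$segments) for (dom in names(qmp)) {
      sub <- ft_subset(qmp[[dom]],
                       samples = qmp[[dom]]$metadata$segment == sg)
      key <- sprintf("SR_B%02d_D%02d", sub$metadata$bird, sub$metadata$dph)
      ok <- key %in% rownames(met_mat)
      fit <- mmvec_fit(sub$mat[ok, , drop = FALSE],
                       met_mat[key[ok], , drop = FALSE],
                       epochs = mmvec_epochs, seed = in_seed)
      P <- fit$probs
      scored[[paste(sg, dom)]] <- data.frame(
        microbe = paste(sg, dom, rep(rownames(P), times = ncol(P)),
                        sep = "|"),
        genus = rep(rownames(P), times = ncol(P)),
        metabolite = rep(colnames(P), each = nrow(P)),
        probability = as.vector(P),
        stratum = paste(sg, dom), stringsAsFactors = FALSE)
    }
    all_scores <- do.call(rbind, scored)
    sel <- select_top(all_scores, fraction = 0.01)
    net <- interaction_network(sel, res$metabolome$filtered$annotation)
    tsv(sel$selected, "interactions_top.tsv")
    res$integrate <- list(selection = sel, network = net,
                          scores = all_scores)
    note("integrate", epochs = mmvec_epochs, seed = in_seed,
         n_selected = nrow(sel$selected))
  }

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
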
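#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' betaMNTD = 0.5 * [ sum_i f_i min_j d(i,j) + sum_j f_j min_i d(j,i) ]
#' where i runs over taxa of one community, j over the other, d is the
#' patristic (branch-length) distance, and f are relative abundances
#' (abundance-weighted) or 1/richness (unweighted).
#'
#' @param comm_i,comm_j named nonnegative abundance vectors; names must be
#'   tips of `tree` (or rows of `dist_mat`)
#' @param tree an ape phylo tree (ignored when `dist_mat` given)
#' @param abundance_weighted weight by relative abundance (default TRUE)
#' @param dist_mat optional precomputed patristic distance matrix (use
#'   [cophenetic_matrix()]); much faster for repeated calls
#' @return betaMNTD (phylogenetic distance units)
#' @export
beta_mntd <- function(comm_i, comm_j, tree = NULL, abundance_weighted = TRUE,
                      dist_mat = NULL) {
  if (is.null(dist_mat)) {
    if (is.null(tree)) stop("need a tree or a distance matrix")
    dist_mat <- cophenetic_matrix(tree)
  }
  ti <- names(comm_i)[comm_i > 0]
  tj <- names(comm_j)[comm_j > 0]
  missing <- setdiff(c(ti, tj), rownames(dist_mat))
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  d_ij <- dist_mat[ti, tj, drop = FALSE]
  near_i <- apply(d_ij, 1, min)
  near_j <- apply(d_ij, 2, min)
  if (abundance_weighted) {
    fi <- comm_i[ti] / sum(comm_i[ti])
    fj <- comm_j[tj] / sum(comm_j[tj])
  } else {
    fi <- rep(1 / length(ti), length(ti))
    fj <- rep(1 / length(tj), length(tj))
  }
  0.5 * (sum(fi * near_i) + sum(fj * near_j))
}

#' Patristic distance matrix of a tree
#' @param tree ape phylo
#' @return symmetric tip-by-tip matrix of branch-length distances
#' @export
cophenetic_matrix <- function(tree) stats::cophenetic(tree)

#' beta nearest taxon index (betaNTI)
#'
#' z-score of the observed betaMNTD against a null distribution obtained
#' by shuffling taxon labels across the tips of the tree (taxa-label
#' randomisation over the species pool), holding abundances fixed.
#' |betaNTI| > 2 is the conventional signature of selection-driven
#' (deterministic) assembly.
#'
#' @inheritParams beta_mntd
#' @param n_null null draws (>= 99)
#' @param seed RNG seed
#' @param pool taxa over which labels are shuffled (default: all rows of
#'   the distance matrix)
#' @return list with beta_mntd_obs, beta_nti, null_mean, null_sd
#' @export
beta_nti <- function(comm_i, comm_j, tree = NULL, n_null = 999, seed = NULL,
                     abundance_weighted = TRUE, dist_mat = NULL,
                     pool = NULL) {
  if (n_null < 99) stop("n_null must be at least 99")
  if (is.null(dist_mat)) dist_mat <- cophenetic_matrix(tree)
  if (is.null(pool)) pool <- rownames(dist_mat)
  if (!is.null(seed)) set.seed(seed)
  obs <- beta_mntd(comm_i, comm_j, abundance_weighted = abundance_weighted,
                   dist_mat = dist_mat)
  nulls <- vapply(seq_len(n_null), function(b) {
    perm <- sample(pool)
    dm <- dist_mat[pool, pool]
    dimnames(dm) <- list(perm, perm)
    beta_mntd(comm_i, comm_j, abundance_weighted = abundance_weighted,
              dist_mat = dm)
  }, numeric(1))
  s <- stats::sd(nulls)
  z <- if (s == 0) NA_real_ else (obs - mean(nulls)) / s
  if (s == 0) warning("null betaMNTD has zero spread; betaNTI undefined")
  list(beta_mntd_obs = obs, beta_nti = z,
       null_mean = mean(nulls), null_sd = s)
}

#' Species pool for the Raup-Crick null model
#'
#' Per-taxon occurrence frequencies and mean relative abundances over a set
#' of communities (typically all samples of one gut segment).
#'
#' @param mat samples x taxa abundance matrix (or feature_table)
#' @return list with `occ` (occurrence frequency) and `rel` (mean relative
#'   abundance), both named by taxon
#' @export
species_pool <- function(mat) {
  if (inherits(mat, "feature_table")) mat <- mat$mat
  occ <- colMeans(mat > 0)
  rel <- colMeans(mat / pmax(rowSums(mat), .Machine$double.eps))
  list(occ = occ, rel = rel)
}

#' Bray-Curtis-based Raup-Crick index (RC_Bray)
#'
#' Null communities preserve each observed community's richness and total
#' abundance: taxa are drawn (without replacement) with probability
#' proportional to their pool occurrence frequency, then filled to the
#' observed total by a multinomial over the drawn taxa weighted by pool
#' mean relative abundances. RC_Bray = 2 [ P(null BC < obs BC) +
#' 0.5 P(null BC = obs BC) ] - 1, in [-1, 1]; values below -0.95 indicate
#' less turnover than expected by chance (homogenizing dispersal), above
#' +0.95 more (dispersal limitation).
#'
#' @param comm_i,comm_j named count vectors
#' @param pool a [species_pool()] covering all taxa present in the pair
#' @param n_null null draws
#' @param seed RNG seed
#' @return RC_Bray in [-1, 1]
#' @export
rc_bray <- function(comm_i, comm_j, pool, n_null = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- names(pool$occ)
  pres <- c(names(comm_i)[comm_i > 0], names(comm_j)[comm_j > 0])
  if (length(setdiff(pres, taxa)))
    stop("pool is missing taxa: ",
         paste(setdiff(pres, taxa), collapse = ", "))
  vi <- stats::setNames(numeric(length(taxa)), taxa)
  vj <- vi
  vi[names(comm_i)] <- comm_i
  vj[names(comm_j)] <- comm_j
  obs <- bray_curtis(vi, vj)
  rich <- c(sum(comm_i > 0), sum(comm_j > 0))
  tot <- c(sum(comm_i), sum(comm_j))
  occ <- pmax(pool$occ, 1e-12)
  rel <- pmax(pool$rel, 1e-12)
  draw_null <- function(r, n) {
    r <- min(r, length(taxa))
    chosen <- sample(taxa, r, prob = occ)
    counts <- stats::rmultinom(1, max(round(n), r),
                               rel[chosen] / sum(rel[chosen]))[, 1]
    v <- stats::setNames(numeric(length(taxa)), taxa)
    v[chosen] <- counts
    v
  }
  nulls <- vapply(seq_len(n_null), function(b)
    bray_curtis(draw_null(rich[1], tot[1]), draw_null(rich[2], tot[2])),
    numeric(1))
  2 * (mean(nulls < obs - 1e-12) + 0.5 * mean(abs(nulls - obs) <= 1e-12)) - 1
}

process_levels <- c("heterogeneous_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated")

#' Classify a community pair into an ecological assembly process
#'
#' Two-step rule: |betaNTI| >= 2 indicates selection (betaNTI < -2
#' heterogeneous, > 2 homogeneous under the default convention); otherwise
#' RC_Bray decides between dispersal limitation (> 0.95), homogenizing
#' dispersal (< -0.95) and undominated (|RC| <= 0.95). Boundary values
#' (betaNTI exactly +-2) fall to the adjacent selection class; RC exactly
#' +-0.95 falls to undominated.
#'
#' The default `convention = "caption"` maps betaNTI < -2 to heterogeneous
#' selection. The widely used alternative (`"stegen"`) swaps the two
#' selection labels; choose explicitly when comparing against other work.
#'
#' @param beta_nti finite z-score
#' @param rc_bray RC index in [-1,1]; may be NA when |beta_nti| >= 2
#' @param convention "caption" (default) or "stegen"
#' @return one of heterogeneous_selection, homogeneous_selection,
#'   dispersal_limitation, homogenizing_dispersal, undominated
#' @export
classify_process <- function(beta_nti, rc_bray = NA,
                             convention = c("caption", "stegen")) {
  convention <- match.arg(convention)
  if (!is.finite(beta_nti)) stop("beta_nti must be finite")
  lo <- "heterogeneous_selection"; hi <- "homogeneous_selection"
  if (convention == "stegen") { lo <- "homogeneous_selection"
                                hi <- "heterogeneous_selection" }
  if (beta_nti <= -2) return(lo)
  if (beta_nti >= 2) return(hi)
  if (!is.finite(rc_bray))
    stop("|betaNTI| < 2 requires an RC_Bray value")
  if (rc_bray > 0.95) return("dispersal_limitation")
  if (rc_bray < -0.95) return("homogenizing_dispersal")
  "undominated"
}

#' Pairwise assembly analysis within groups
#'
#' Runs betaNTI (and, where |betaNTI| < 2, RC_Bray) for all within-group
#' sample pairs and classifies each pair. Pairs are formed within the
#' grouping variable (by default the gut segment, across all days); the
#' species pool for RC_Bray is the group's own samples.
#'
#' @param table counts feature_table (single domain)
#' @param tree ape phylo over the table's taxa
#' @param group_by metadata column defining pair groups (default
#'   "segment")
#' @param n_null null draws per statistic
#' @param seed RNG seed
#' @param max_pairs optional cap: a random subset of pairs per group
#'   (keeps large designs tractable); NULL = all pairs
#' @param convention passed to [classify_process()]
#' @return data.frame: group, sample_i, sample_j, beta_mntd, beta_nti,
#'   rc_bray, process
#' @export
assembly_pairwise <- function(table, tree, group_by = "segment",
                              n_null = 999, seed = 1, max_pairs = NULL,
                              convention = "caption") {
  dist_mat <- cophenetic_matrix(tree)
  md <- table$metadata
  set.seed(seed)
  out <- list()
  for (g in unique(md[[group_by]])) {
    ids <- md$sample_id[md[[group_by]] == g]
    sub <- table$mat[ids, , drop = FALSE]
    pool <- species_pool(sub)
    prs <- utils::combn(ids, 2)
    if (!is.null(max_pairs) && ncol(prs) > max_pairs)
      prs <- prs[, sample(ncol(prs), max_pairs), drop = FALSE]
    for (pi in seq_len(ncol(prs))) {
      ci <- sub[prs[1, pi], ]; cj <- sub[prs[2, pi], ]
      bn <- beta_nti(ci, cj, n_null = n_null, dist_mat = dist_mat)
      rc <- NA_real_
      if (is.finite(bn$beta_nti) && abs(bn$beta_nti) < 2)
        rc <- rc_bray(ci, cj, pool, n_null = n_null)
      out[[length(out) + 1]] <- data.frame(
        group = g, sample_i = prs[1, pi], sample_j = prs[2, pi],
        beta_mntd = bn$beta_mntd_obs, beta_nti = bn$beta_nti,
        rc_bray = rc,
        process = if (is.finite(bn$beta_nti))
          classify_process(bn$beta_nti, rc, convention) else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Summarise assembly processes into fractions
#'
#' Per-group fractions of the five processes (summing to 1) plus the
#' deterministic share (both selection processes) and stochastic share
#' (dispersal limitation, homogenizing dispersal, undominated).
#'
#' @param results data.frame from [assembly_pairwise()] (needs `process`;
#'   `group` optional)
#' @param by optional grouping column name (default "group" when present)
#' @return data.frame: group, each process fraction, deterministic,
#'   stochastic
#' @export
summarize_processes <- function(results, by = NULL) {
  if (!nrow(results)) stop("empty results")
  if (is.null(by)) by <- if ("group" %in% names(results)) "group" else NULL
  split_f <- if (is.null(by)) factor(rep("all", nrow(results)))
             else factor(results[[by]])
  rows <- lapply(levels(split_f), function(g) {
    pr <- results$process[split_f == g & !is.na(results$process)]
    if (!length(pr)) {
      warning("group ", g, " has no classified pairs; omitted")
      return(NULL)
    }
    fr <- table(factor(pr, levels = process_levels)) / length(pr)
    data.frame(group = g, t(as.matrix(fr)),
               deterministic = sum(fr[1:2]), stochastic = sum(fr[3:5]),
               n_pairs = length(pr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
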
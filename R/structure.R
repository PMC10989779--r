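#' Shannon diversity index
#'
#' H = -sum p_i log p_i over nonzero proportions. Natural log by default;
#' the base is configurable because conventions differ across fields.
#'
#' @param abundances nonnegative numeric vector with positive sum
#' @param base logarithm base (default `exp(1)` for nats)
#' @return H >= 0; 0 iff a single taxon carries all abundance
#' @export
shannon <- function(abundances, base = exp(1)) {
  if (any(abundances < 0)) stop("abundances must be nonnegative")
  s <- sum(abundances)
  if (s <= 0) stop("Shannon index undefined for an all-zero vector")
  p <- abundances[abundances > 0] / s
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' sum|x - y| / sum(x + y); a semimetric in [0, 1] (0 for identical
#' communities, 1 for disjoint supports).
#'
#' @param x,y nonnegative vectors of equal length
#' @return dissimilarity in [0, 1]
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be nonnegative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined when both vectors are all zero")
  sum(abs(x - y)) / tot
}

#' All-pairs Bray-Curtis distance matrix
#'
#' @param table feature_table (any mode) or numeric matrix (samples x taxa)
#' @return symmetric matrix of dissimilarities with zero diagonal
#' @export
bray_curtis_matrix <- function(table) {
  mat <- if (inherits(table, "feature_table")) table$mat else table
  as.matrix(vegan::vegdist(mat, method = "bray"))
}

#' Bray-Curtis dissimilarity between samples at adjacent time points
#'
#' For each consecutive pair of sampling days within one gut segment, all
#' cross-time sample-pair dissimilarities are computed, giving the
#' per-interval turnover distribution (high early intervals indicate rapid
#' community change after hatch).
#'
#' @param table feature_table with `segment` and `dph` metadata columns
#' @param segment segment to analyse
#' @return data.frame with interval label, the two days, sample ids, and
#'   the dissimilarity of each cross-time pair
#' @export
adjacent_time_dissimilarity <- function(table, segment) {
  md <- table$metadata
  keep <- md$segment == segment
  if (!any(keep)) stop("no samples in segment ", segment)
  md <- md[keep, , drop = FALSE]
  mat <- table$mat[md$sample_id, , drop = FALSE]
  days <- sort(unique(md$dph))
  if (length(days) < 2) stop("need at least two time points in segment")
  out <- list()
  for (k in seq_len(length(days) - 1)) {
    a <- md$sample_id[md$dph == days[k]]
    b <- md$sample_id[md$dph == days[k + 1]]
    if (!length(a) || !length(b)) {
      warning("interval ", days[k], "-", days[k + 1],
              " skipped: a time point has no samples")
      next
    }
    pairs <- expand.grid(i = a, j = b, stringsAsFactors = FALSE)
    d <- mapply(function(i, j) bray_curtis(mat[i, ], mat[j, ]),
                pairs$i, pairs$j)
    out[[length(out) + 1]] <- data.frame(
      interval = paste0(days[k], "-", days[k + 1]),
      dph_from = days[k], dph_to = days[k + 1],
      sample_i = pairs$i, sample_j = pairs$j,
      dissimilarity = unname(d), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Principal coordinate analysis (classical MDS)
#'
#' Classical scaling of the double-centred squared-distance matrix.
#' Negative eigenvalues (Bray-Curtis is a semimetric) are reported, axes
#' are ordered by eigenvalue, and for Euclidean-embeddable inputs the
#' coordinates reproduce the distances.
#'
#' @param dm symmetric distance matrix (matrix or dist)
#' @param k number of axes to return (default all positive-eigenvalue axes)
#' @return list with `coords` (samples x axes), `eig` (all eigenvalues),
#'   `rel_eig` (share of the positive eigenvalue sum)
#' @export
pcoa <- function(dm, k = NULL) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(dm)
  # Gower double-centering of -0.5 * D^2, then eigendecomposition
  B <- -0.5 * dm^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))   # = A - rowmean - colmean + grandmean
  B <- (B + t(B)) / 2
  ev <- eigen(B, symmetric = TRUE)
  eig <- ev$values
  npos <- sum(eig > 1e-8 * max(abs(eig), 1))
  if (is.null(k)) k <- max(npos, 1)
  k <- min(k, npos)
  coords <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig[seq_len(k)], 0)), k)
  dimnames(coords) <- list(rownames(dm), paste0("PCo", seq_len(k)))
  list(coords = coords, eig = eig,
       rel_eig = if (any(eig > 0)) eig / sum(eig[eig > 0]) else eig * 0)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-factor pseudo-F test on a distance matrix (Anderson 2001). Among-
#' and within-group sums of squared distances give R^2 = SS_among/SS_total
#' and F = (SS_among/(a-1)) / (SS_within/(n-a)); the p-value is
#' (1 + #{permuted F >= observed F}) / (1 + n_perm) under random relabeling.
#'
#' @param dm symmetric distance matrix
#' @param factor_vec grouping factor, one level per sample (>= 2 groups,
#'   each with >= 2 samples)
#' @param n_perm number of label permutations (default 999)
#' @param seed RNG seed for the permutations
#' @param permutations optional explicit permutation matrix (rows =
#'   permuted index vectors), e.g. the complete enumeration for exact tests
#' @return list with R2, F, p_value, df, and the permutation F values
#' @export
permanova <- function(dm, factor_vec, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  g <- factor(factor_vec)
  if (length(g) != n) stop("factor length must match distance matrix")
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("every group needs at least two samples")
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_of <- function(grp) {
    sw <- 0
    for (lev in levels(grp)) {
      idx <- which(grp == lev)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        sw <- sw + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    sw
  }
  a <- nlevels(g)
  ss_w <- ss_within_of(g)
  ss_a <- ss_total - ss_w
  f_obs <- (ss_a / (a - 1)) / (ss_w / (n - a))
  if (is.null(permutations)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    permutations <- t(replicate(n_perm, sample.int(n)))
  }
  f_perm <- apply(permutations, 1, function(idx) {
    gp <- g[idx]
    sw <- ss_within_of(gp)
    sa <- ss_total - sw
    (sa / (a - 1)) / (sw / (n - a))
  })
  list(R2 = ss_a / ss_total, F = f_obs,
       p_value = (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + nrow(permutations)),
       df = c(among = a - 1, within = n - a),
       f_perm = f_perm)
}

#' Marginal variance partition across several factors
#'
#' Runs a one-factor PERMANOVA per metadata factor and reports each
#' factor's marginal R^2 — the share of community variance it explains on
#' its own (factors are not adjusted for one another).
#'
#' @param dm distance matrix
#' @param metadata data.frame of factors (one column per factor)
#' @param factors character vector of column names to test
#' @param n_perm,seed passed to [permanova()]
#' @return data.frame with factor, R2, F, p_value
#' @export
variance_partition <- function(dm, metadata, factors, n_perm = 999,
                               seed = NULL) {
  res <- lapply(seq_along(factors), function(i) {
    f <- factors[i]
    pv <- permanova(dm, metadata[[f]], n_perm = n_perm,
                    seed = if (is.null(seed)) NULL else seed + i)
    data.frame(factor = f, R2 = pv$R2, F = pv$F, p_value = pv$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Procrustes comparison of two ordinations (protest)
#'
#' Symmetric Procrustes superimposition (translation, rotation/reflection,
#' scaling) of two sample configurations, with the correlation
#' m12 = sqrt(1 - ss) and a permutation p-value obtained by shuffling the
#' rows of the second configuration (vegan's protest contract). Per-sample
#' residuals are the distances between matched points after superimposition.
#'
#' @param coords_a,coords_b numeric matrices, same samples in the same
#'   order (>= 3 samples)
#' @param n_perm permutations for the p-value
#' @param seed RNG seed
#' @return list with m12, ss, p_value, residuals (named per sample)
#' @export
protest_compare <- function(coords_a, coords_b, n_perm = 999, seed = NULL) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b))
    stop("configurations must have the same samples in the same order")
  if (nrow(coords_a) < 3) stop("need at least 3 samples")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  pt <- vegan::protest(coords_a, coords_b, permutations = n_perm,
                       symmetric = TRUE)
  res <- stats::residuals(pt)
  names(res) <- rownames(coords_a)
  list(m12 = sqrt(1 - pt$ss), ss = pt$ss, p_value = pt$signif,
       residuals = res, n_perm = n_perm)
}
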
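#' Filter metabolite features
#'
#' Two-step feature filtering: (1) keep features present (nonzero) in more
#' than `min_presence` of samples (strict inequality); (2) drop features
#' without a database annotation (superclass "unknown").
#'
#' @param table a `metabolite_table`
#' @param min_presence strict presence fraction (default 0.30)
#' @return filtered `metabolite_table`; attribute "removal_log" records
#'   counts per removal reason
#' @export
filter_features <- function(table, min_presence = 0.30) {
  pres <- colMeans(table$mat > 0)
  low <- pres <= min_presence + 1e-12
  unk <- table$annotation$superclass[
    match(colnames(table$mat), table$annotation$metabolite)] == "unknown"
  keep <- !low & !unk
  out <- structure(list(
    mat = table$mat[, keep, drop = FALSE],
    metadata = table$metadata,
    annotation = table$annotation[
      table$annotation$metabolite %in% colnames(table$mat)[keep], ,
      drop = FALSE]),
    class = "metabolite_table")
  attr(out, "removal_log") <- c(low_presence = sum(low),
                                unannotated = sum(unk & !low),
                                kept = sum(keep))
  out
}

#' OPLS-DA with VIP ranking
#'
#' Orthogonal partial least-squares discriminant analysis: group labels
#' are dummy-coded into a multi-response Y, `n_orth` Y-orthogonal
#' components are filtered from the (unit-variance-scaled, log10(1+x)
#' transformed) intensity matrix, and a multi-response PLS (NIPALS) with
#' one predictive component per independent response dimension is fitted
#' to the filtered matrix. VIP combines the predictive weights with each
#' component's explained Y sum of squares; by construction the mean
#' squared VIP over metabolites equals 1, and VIP > 1.5 is the
#' conventional cutoff for discriminative features.
#'
#' @param table `metabolite_table` or numeric matrix (samples x
#'   metabolites, raw intensities)
#' @param groups factor of group labels per sample (>= 2 groups, each with
#'   >= 2 samples)
#' @param n_orth orthogonal components to remove (default 1)
#' @param scaling "uv" (unit variance, default) or "none"
#' @param log_transform apply log10(1 + x) first (default TRUE)
#' @return object of class `opls_result`: scores (predictive, P1 first),
#'   ortho_scores, vip (named), weights, explained (share of X variation
#'   per predictive component), dropped (constant metabolites)
#' @export
opls_da <- function(table, groups, n_orth = 1,
                    scaling = c("uv", "none"), log_transform = TRUE) {
  scaling <- match.arg(scaling)
  X <- if (inherits(table, "metabolite_table")) table$mat else table
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  if (nrow(X) != length(groups)) stop("groups must match samples")
  if (log_transform) X <- log10(1 + X)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped))
    warning(length(dropped), " constant metabolite(s) dropped")
  X <- X[, sds > 0, drop = FALSE]
  X <- scale(X, center = TRUE, scale = (scaling == "uv"))
  Y <- stats::model.matrix(~ groups - 1)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(X); p <- ncol(X)
  ss_x_total <- sum(X^2)

  nipals_comp <- function(X, Y) {
    u <- Y[, which.max(colSums(Y^2))]
    for (it in 1:500) {
      w <- crossprod(X, u)[, 1]; w <- w / sqrt(sum(w^2))
      t_ <- X %*% w
      q <- crossprod(Y, t_)[, 1] / sum(t_^2)
      u_new <- Y %*% q / sum(q^2)
      if (sum((u_new - u)^2) < 1e-12 * sum(u^2)) { u <- u_new; break }
      u <- u_new
    }
    list(w = w, t = as.vector(t_), q = q)
  }

  # orthogonal filtering (Trygg-style, multi-response): the candidate
  # loading is orthogonalised against the span of ALL predictive weight
  # vectors so no between-group direction is removed
  A <- min(nlevels(groups) - 1, p, n - 1)
  pls_weights <- function(X, Y, A) {
    W <- NULL; Xa <- X; Ya <- Y
    for (a in seq_len(A)) {
      cmp <- nipals_comp(Xa, Ya)
      pl <- crossprod(Xa, cmp$t)[, 1] / sum(cmp$t^2)
      W <- cbind(W, cmp$w)
      Xa <- Xa - cmp$t %*% t(pl)
      Ya <- Ya - cmp$t %*% t(cmp$q)
    }
    W
  }
  To <- NULL; Po <- NULL; Wo <- NULL
  Xf <- X
  for (a in seq_len(n_orth)) {
    c1 <- nipals_comp(Xf, Y)
    pload <- crossprod(Xf, c1$t)[, 1] / sum(c1$t^2)
    Wspan <- pls_weights(Xf, Y, A)
    w_orth <- pload - Wspan %*% solve(crossprod(Wspan),
                                      crossprod(Wspan, pload))
    w_orth <- as.vector(w_orth)
    nw <- sqrt(sum(w_orth^2))
    if (nw < 1e-10) break
    w_orth <- w_orth / nw
    t_orth <- Xf %*% w_orth
    p_orth <- crossprod(Xf, t_orth)[, 1] / sum(t_orth^2)
    Xf <- Xf - t_orth %*% t(p_orth)
    To <- cbind(To, as.vector(t_orth)); Po <- cbind(Po, p_orth)
    Wo <- cbind(Wo, w_orth)
  }

  # predictive PLS on the filtered matrix
  Tp <- matrix(0, n, A); W <- matrix(0, p, A); Q <- matrix(0, ncol(Y), A)
  ssy <- numeric(A)
  Xa <- Xf; Ya <- Y
  for (a in seq_len(A)) {
    cmp <- nipals_comp(Xa, Ya)
    pload <- crossprod(Xa, cmp$t)[, 1] / sum(cmp$t^2)
    Tp[, a] <- cmp$t; W[, a] <- cmp$w; Q[, a] <- cmp$q
    ssy[a] <- sum(cmp$t^2) * sum(cmp$q^2)
    Xa <- Xa - cmp$t %*% t(pload)
    Ya <- Ya - cmp$t %*% t(cmp$q)
  }
  vip <- sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(X)
  expl <- vapply(seq_len(A), function(a) {
    pl <- crossprod(Xf, Tp[, a])[, 1] / sum(Tp[, a]^2)
    sum((Tp[, a] %*% t(pl))^2) / ss_x_total
  }, numeric(1))
  colnames(Tp) <- paste0("P", seq_len(A))
  rownames(Tp) <- rownames(X)
  structure(list(scores = Tp, ortho_scores = To, vip = vip,
                 weights = W, q = Q, explained = expl, groups = groups,
                 dropped = dropped, n_orth = if (is.null(To)) 0 else ncol(To)),
            class = "opls_result")
}

#' @export
print.opls_result <- function(x, ...) {
  cat(sprintf(
    "opls_result: %d predictive + %d orthogonal components, %d metabolites; P1 explains %.1f%% of X\n",
    ncol(x$scores), x$n_orth, length(x$vip), 100 * x$explained[1]))
  invisible(x)
}

#' Per-metabolite time association (linear model, FDR)
#'
#' For every metabolite, a linear model of log10(1 + intensity) on
#' sampling day as a categorical factor; the omnibus F-test asks whether
#' mean intensity differs across days at all (the observed trajectory
#' shapes are non-monotone, so day enters as a factor, not a slope).
#' P-values are Benjamini-Hochberg adjusted across metabolites.
#'
#' @param table `metabolite_table` or intensity matrix
#' @param dph numeric vector of days per sample (taken from the table's
#'   metadata when omitted)
#' @param fdr adjusted-p threshold for the `associated` flag
#' @param log_transform apply log10(1 + x) (default TRUE)
#' @return data.frame: metabolite, F, p, p_adj, associated
#' @export
glm_time_association <- function(table, dph = NULL, fdr = 0.05,
                                 log_transform = TRUE) {
  X <- if (inherits(table, "metabolite_table")) table$mat else table
  if (is.null(dph)) dph <- table$metadata$dph
  if (length(unique(dph)) < 2) stop("need at least two distinct days")
  if (log_transform) X <- log10(1 + X)
  g <- factor(dph)
  n <- nrow(X); a <- nlevels(g)
  gm <- rowsum(X, g) / as.vector(table(g))       # group means (a x p)
  grand <- colMeans(X)
  ssb <- colSums(as.vector(table(g)) * sweep(gm, 2, grand)^2)
  sst <- colSums(sweep(X, 2, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  Fstat <- (ssb / (a - 1)) / (ssw / (n - a))
  p <- stats::pf(Fstat, a - 1, n - a, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1   # strictly constant metabolite
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(metabolite = colnames(X), F = Fstat, p = p, p_adj = p_adj,
             associated = p_adj < fdr, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cluster metabolite trajectories
#'
#' Mean trajectory per metabolite over days, z-scored per metabolite, then
#' agglomerative hierarchical clustering (Euclidean distance, complete
#' linkage) cut at k clusters — the trajectory-shape clustering behind
#' "six metabolite clusters".
#'
#' @param table `metabolite_table` or intensity matrix (typically already
#'   restricted to time-associated metabolites)
#' @param dph days per sample
#' @param k number of clusters (default 6)
#' @param log_transform apply log10(1 + x) (default TRUE)
#' @param linkage hclust method (default "complete")
#' @param profile "day_means" (default: cluster per-day mean trajectories,
#'   matching the column structure of a day-grouped heatmap) or "samples"
#'   (cluster full per-sample profiles)
#' @return list: cluster (named integer), centers (k x days mean z-scored
#'   trajectories), hclust, trajectories (metabolite x day z-scores)
#' @export
cluster_trajectories <- function(table, dph = NULL, k = 6,
                                 log_transform = TRUE,
                                 linkage = "complete",
                                 profile = c("day_means", "samples")) {
  profile <- match.arg(profile)
  X <- if (inherits(table, "metabolite_table")) table$mat else table
  if (is.null(dph)) dph <- table$metadata$dph
  if (ncol(X) < k) stop("k exceeds the number of metabolites")
  if (log_transform) X <- log10(1 + X)
  g <- factor(dph, levels = sort(unique(dph)))
  prof <- if (profile == "day_means")
    t(rowsum(X, g) / as.vector(table(g)))         # metabolites x days
  else t(X)                                       # metabolites x samples
  sds <- apply(prof, 1, stats::sd)
  z <- (prof - rowMeans(prof)) / ifelse(sds > 0, sds, 1)
  d <- stats::dist(z)
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = k)
  if (max(d) < 1e-12 || length(unique(cl)) < k)
    warning("degenerate clustering: trajectories do not support k ",
            "distinct clusters")
  centers <- rowsum(z, cl) / as.vector(table(cl))
  if (profile == "day_means") colnames(centers) <- levels(g)
  list(cluster = cl, centers = centers, hclust = hc, trajectories = z)
}

#' Chemical composition of trajectory clusters
#'
#' Per-cluster counts and proportions of metabolite chemical superclasses.
#'
#' @param clusters named integer vector (metabolite -> cluster), e.g.
#'   `cluster_trajectories()$cluster`
#' @param annotation data.frame with metabolite and superclass columns
#' @return data.frame: cluster, superclass, count, proportion
#' @export
cluster_composition <- function(clusters, annotation) {
  sc <- annotation$superclass[match(names(clusters),
                                    annotation$metabolite)]
  df <- as.data.frame(table(cluster = clusters, superclass = sc),
                      stringsAsFactors = FALSE)
  names(df)[3] <- "count"
  df <- df[df$count > 0 | TRUE, ]
  tot <- stats::ave(df$count, df$cluster, FUN = sum)
  df$proportion <- ifelse(tot > 0, df$count / tot, 0)
  df[order(df$cluster, -df$count), ]
}
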
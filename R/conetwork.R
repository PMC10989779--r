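#' Prevalence filter for network inclusion
#'
#' Keeps genera present (nonzero) in at least `min_prevalence` of samples;
#' the boundary is inclusive (a genus in exactly 30% of samples is kept).
#'
#' @param table feature_table
#' @param min_prevalence fraction in (0, 1], default 0.30
#' @return filtered feature_table
#' @export
prevalence_filter <- function(table, min_prevalence = 0.30) {
  prev <- colMeans(table$mat > 0)
  keep <- prev >= min_prevalence - 1e-12
  if (!any(keep))
    warning("no genus meets the prevalence threshold; empty table")
  ft_subset(table, taxa = keep)
}

#' Partial Spearman correlation
#'
#' All variables are rank-transformed; ranks of x and y are residualised
#' on the ranks of the covariates and the Pearson correlation of the
#' residuals is the partial Spearman rho (equivalently the recursive
#' partial-correlation formula). The p-value uses the t distribution with
#' n - 2 - k degrees of freedom (k = number of covariates).
#'
#' @param x,y numeric vectors
#' @param covariates optional numeric vector/matrix/data.frame of
#'   conditioning variables
#' @return list: rho, p_value, n, df
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  k <- 0
  rx <- rank(x); ry <- rank(y)
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    if (nrow(Z) != n) stop("covariates must match x in length")
    k <- ncol(Z)
    Zr <- apply(Z, 2, rank)
    q <- qr(cbind(1, Zr))
    rx <- qr.resid(q, rx)
    ry <- qr.resid(q, ry)
  }
  if (n < 5 || n - 2 - k < 1) stop("need at least 5 complete observations")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant variable after ranking; correlation undefined, ",
            "treated as nonsignificant")
    return(list(rho = NA_real_, p_value = 1, n = n, df = n - 2 - k))
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- rho * sqrt(df / max(1 - rho^2, 1e-15))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tval), df), n = n, df = df)
}

#' Build a partial-Spearman co-occurrence network
#'
#' Tests all genus pairs (after [prevalence_filter()]), adjusts p-values by
#' Benjamini-Hochberg across all pairs in the network, and retains edges
#' with adjusted p <= alpha, signed by the sign of rho. All pairs share the
#' conditioning set, so partial correlations are computed in one pass via
#' the correlation matrix of covariate-residualised ranks.
#'
#' The conditioning set is a modelling choice with real consequences:
#' `condition = "dph"` (default) ranks sampling day into the covariates to
#' suppress correlations driven purely by shared developmental time;
#' "none" gives plain Spearman networks.
#'
#' @param table feature_table (prevalence-filtered; QMP or RMP)
#' @param mode provenance label stored on the network ("QMP"/"RMP";
#'   defaults to the table's mode)
#' @param condition "dph", "none", or "custom"
#' @param covariates matrix/data.frame when condition = "custom"
#' @param alpha BH-adjusted significance threshold (default 0.05)
#' @param segment provenance label
#' @return object of class `co_network`: edges data.frame (genus_a,
#'   genus_b, rho, p, p_adj, sign), vertices, and provenance fields
#' @export
build_network <- function(table, mode = NULL, condition = c("dph", "none",
                                                            "custom"),
                          covariates = NULL, alpha = 0.05, segment = NA) {
  condition <- match.arg(condition)
  mat <- table$mat
  n <- nrow(mat)
  if (n < 5) stop("need at least 5 samples")
  if (is.null(mode)) mode <- table$mode
  Z <- switch(condition,
              dph = matrix(table$metadata$dph, ncol = 1),
              none = NULL,
              custom = { if (is.null(covariates))
                stop("condition = 'custom' needs covariates")
                as.matrix(covariates) })
  k <- if (is.null(Z)) 0 else ncol(Z)
  R <- apply(mat, 2, rank)
  if (!is.null(Z)) {
    Zr <- apply(Z, 2, rank)
    R <- qr.resid(qr(cbind(1, Zr)), R)
  }
  sds <- apply(R, 2, stats::sd)
  const <- sds == 0
  if (any(const))
    warning(sum(const), " genus/genera constant after ranking; their ",
            "correlations are treated as nonsignificant")
  C <- suppressWarnings(stats::cor(R))
  df <- n - 2 - k
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  rho <- C[pairs]
  tval <- rho * sqrt(df / pmax(1 - rho^2, 1e-15))
  p <- 2 * stats::pt(-abs(tval), df)
  bad <- const[pairs[, 1]] | const[pairs[, 2]] | !is.finite(rho)
  p[bad] <- 1; rho[bad] <- NA
  p_adj <- stats::p.adjust(p, method = "BH")
  edges <- data.frame(
    genus_a = colnames(mat)[pairs[, 1]],
    genus_b = colnames(mat)[pairs[, 2]],
    rho = rho, p = p, p_adj = p_adj,
    sign = ifelse(is.na(rho), NA, ifelse(rho > 0, "positive", "negative")),
    retained = p_adj <= alpha & !bad,
    stringsAsFactors = FALSE)
  structure(list(
    vertices = colnames(mat),
    edges = edges[edges$retained, setdiff(names(edges), "retained")],
    all_pairs = edges,
    segment = segment, mode = mode,
    conditioning = if (condition == "dph") "rank(dph)" else condition,
    alpha = alpha, n_samples = n),
    class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf(
    "co_network [%s%s]: %d vertices, %d significant edges (BH <= %g, conditioning: %s)\n",
    x$mode, if (is.na(x$segment)) "" else paste0(", ", x$segment),
    length(x$vertices), nrow(x$edges), x$alpha, x$conditioning))
  invisible(x)
}

co_network_graph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("genus_a", "genus_b")], directed = FALSE,
    vertices = data.frame(name = net$vertices))
  igraph::delete_vertices(g, igraph::degree(g) == 0)
}

#' Topology summary of a co-occurrence network
#'
#' Metrics on the unweighted, undirected graph of retained edges (isolated
#' vertices dropped): vertex and edge counts, global clustering as the
#' average of local clustering coefficients (degree < 2 vertices
#' contribute 0), average (unnormalised) betweenness, and average
#' separation — the mean shortest-path length over reachable pairs only.
#'
#' @param net a `co_network`
#' @return data.frame with vertices, edges, clustering, avg_betweenness,
#'   avg_separation
#' @export
topology <- function(net) {
  if (!nrow(net$edges))
    return(data.frame(vertices = 0, edges = 0, clustering = 0,
                      avg_betweenness = 0, avg_separation = 0,
                      empty = TRUE))
  g <- co_network_graph(net)
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[igraph::degree(g) < 2] <- 0
  data.frame(
    vertices = igraph::vcount(g),
    edges = igraph::ecount(g),
    clustering = mean(loc),
    avg_betweenness = mean(igraph::betweenness(g, normalized = FALSE)),
    avg_separation = igraph::mean_distance(g, unconnected = TRUE),
    empty = FALSE)
}

#' Keystone taxa: top-degree vertices
#'
#' Ranks vertices by degree in the retained-edge graph; ties are broken by
#' higher summed |rho| over incident edges, then lexically by genus name.
#'
#' @param net a `co_network`
#' @param top_n how many to return (all vertices if fewer)
#' @return data.frame: genus, degree, strength (summed |rho|), rank
#' @export
keystone <- function(net, top_n = 10) {
  if (!nrow(net$edges)) stop("network has no edges")
  e <- net$edges
  gen <- unique(c(e$genus_a, e$genus_b))
  deg <- vapply(gen, function(g)
    sum(e$genus_a == g) + sum(e$genus_b == g), integer(1))
  strength <- vapply(gen, function(g)
    sum(abs(e$rho[e$genus_a == g | e$genus_b == g])), numeric(1))
  ord <- order(-deg, -strength, gen)
  out <- data.frame(genus = gen[ord], degree = deg[ord],
                    strength = strength[ord],
                    stringsAsFactors = FALSE)[seq_len(min(top_n,
                                                          length(gen))), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

edge_keys <- function(net) {
  e <- net$edges
  if (!nrow(e)) return(character(0))
  paste(pmin(e$genus_a, e$genus_b), pmax(e$genus_a, e$genus_b), sep = "|")
}

#' Generalist and specialist edges across segment networks
#'
#' An edge's identity is the unordered genus pair (sign ignored). Edges
#' present in exactly one segment network are specialists; edges in two or
#' more are generalists.
#'
#' @param nets named list of >= 2 `co_network` objects (one per segment)
#' @return list with `edges` (data.frame: edge, n_networks, label,
#'   networks) and `proportions` (per network: specialist share)
#' @export
edge_sharing <- function(nets) {
  if (length(nets) < 2) stop("need at least two networks")
  keys <- lapply(nets, edge_keys)
  all_keys <- unique(unlist(keys))
  counts <- vapply(all_keys, function(k)
    sum(vapply(keys, function(v) k %in% v, logical(1))), integer(1))
  membership <- vapply(all_keys, function(k)
    paste(names(nets)[vapply(keys, function(v) k %in% v, logical(1))],
          collapse = ","), character(1))
  edges <- data.frame(edge = all_keys, n_networks = counts,
                      label = ifelse(counts > 1, "generalist", "specialist"),
                      networks = membership, stringsAsFactors = FALSE)
  props <- vapply(names(nets), function(nm) {
    kk <- keys[[nm]]
    if (!length(kk)) return(NA_real_)
    mean(edges$label[match(kk, edges$edge)] == "specialist")
  }, numeric(1))
  list(edges = edges, proportions = props)
}

#' Per-vertex negative/positive interaction ratio
#'
#' log10 of the ratio of negative to positive incident edges, with a 0.5
#' pseudocount on both counts so the log stays finite; positive values
#' flag vertices dominated by negative interactions. Isolated vertices are
#' omitted.
#'
#' @param net a `co_network`
#' @return data.frame: genus, degree, n_positive, n_negative, log10_ratio,
#'   dominance
#' @export
sign_ratio <- function(net) {
  e <- net$edges
  gen <- unique(c(e$genus_a, e$genus_b))
  rows <- lapply(gen, function(g) {
    inc <- e[e$genus_a == g | e$genus_b == g, ]
    np <- sum(inc$sign == "positive"); nn <- sum(inc$sign == "negative")
    data.frame(genus = g, degree = nrow(inc), n_positive = np,
               n_negative = nn,
               log10_ratio = log10((nn + 0.5) / (np + 0.5)),
               dominance = ifelse(nn > np, "negative", "positive"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' QMP vs RMP correlation-consistency cross-tabulation
#'
#' Every genus pair tested in both networks is categorised Pos (retained
#' with rho > 0), Neg (retained with rho < 0) or NS (not retained) in each
#' mode; the 3x3 cross-tab counts pairs, and consistency is the diagonal
#' share as a percentage. Cells can also be read as percentages of all
#' compared pairs.
#'
#' @param net_qmp,net_rmp `co_network` objects built on the same genus
#'   universe (restricted to the intersection otherwise, with a warning)
#' @return list: `table` (3x3 counts, QMP rows x RMP columns),
#'   `percent` (total-normalised percentages), `consistency` (percent)
#' @export
qmp_rmp_consistency <- function(net_qmp, net_rmp) {
  cat_of <- function(net) {
    ap <- net$all_pairs
    key <- paste(pmin(ap$genus_a, ap$genus_b),
                 pmax(ap$genus_a, ap$genus_b), sep = "|")
    cats <- ifelse(!ap$retained | is.na(ap$rho), "NS",
                   ifelse(ap$rho > 0, "Pos", "Neg"))
    stats::setNames(cats, key)
  }
  a <- cat_of(net_qmp); b <- cat_of(net_rmp)
  if (!setequal(names(a), names(b))) {
    warning("genus universes differ; restricting to shared pairs")
    shared <- intersect(names(a), names(b))
    a <- a[shared]; b <- b[shared]
  }
  b <- b[names(a)]
  lv <- c("Pos", "Neg", "NS")
  tab <- table(factor(a, lv), factor(b, lv), dnn = c("QMP", "RMP"))
  total <- sum(tab)
  list(table = tab,
       percent = 100 * tab / total,
       row_percent = 100 * tab / pmax(rowSums(tab), 1),
       consistency = 100 * sum(diag(tab)) / total,
       n_pairs = total)
}
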
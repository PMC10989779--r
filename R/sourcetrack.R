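#' EM microbial source tracking for one sink community
#'
#' The sink's counts are modelled as a multinomial whose taxon
#' probabilities are a convex mixture of source relative-abundance
#' profiles, sum_k alpha_k * gamma_k, optionally including an "unknown"
#' source whose profile is estimated from sink mass unexplained by the
#' observed sources. EM alternates per-read source responsibilities
#' (E-step) and mixing-proportion updates (M-step); the unknown profile is
#' always re-estimated from its assigned reads. With `reestimate_sources =
#' TRUE`, the known source profiles are also re-estimated jointly from
#' their own counts plus assigned sink reads (full FEAST behaviour); the
#' default keeps them fixed at the observed proportions (with a 1e-8
#' pseudocount), which is deterministic and easier to reason about.
#'
#' @param sink_counts integer vector over taxa
#' @param source_counts matrix, one row per source, columns matching
#'   `sink_counts` (same taxon order)
#' @param include_unknown include an unknown source (default TRUE)
#' @param reestimate_sources jointly re-estimate source profiles
#' @param max_iter,tol EM controls (tol on the log-likelihood)
#' @return object of class `source_estimate`: proportions (named, summing
#'   to 1), gamma (profiles used), ll_trace, converged
#' @export
feast_em <- function(sink_counts, source_counts, include_unknown = TRUE,
                     reestimate_sources = FALSE, max_iter = 3000,
                     tol = 1e-11) {
  x <- as.numeric(sink_counts)
  if (sum(x) == 0) stop("sink community is all zero")
  if (is.null(dim(source_counts)))
    source_counts <- matrix(source_counts, nrow = 1)
  if (ncol(source_counts) != length(x))
    stop("sink and sources must share the same taxon index")
  m <- nrow(source_counts)
  src_names <- rownames(source_counts)
  if (is.null(src_names)) src_names <- paste0("source", seq_len(m))
  if (any(rowSums(source_counts) <= 0))
    stop("every source needs positive sequencing depth")

  gamma <- sweep(source_counts + 1e-8, 1, rowSums(source_counts + 1e-8), "/")
  if (include_unknown) {
    # initialise the unknown profile from sink mass not covered by sources
    p_sink <- x / sum(x)
    resid <- pmax(p_sink - colSums(gamma) / m, 0)
    if (sum(resid) == 0) resid <- rep(1 / length(x), length(x))
    gamma <- rbind(gamma, unknown = resid / sum(resid))
    src_names <- c(src_names, "unknown")
    m <- m + 1
  }
  alpha <- rep(1 / m, m)

  ll_of <- function(alpha, gamma) {
    p <- colSums(alpha * gamma)
    sum(x[x > 0] * log(p[x > 0]))
  }
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step: responsibility of source k for reads of taxon j
    num <- alpha * gamma                    # m x J
    p <- colSums(num)
    r <- sweep(num, 2, pmax(p, 1e-300), "/")
    # M-step
    assigned <- r %*% x                      # expected reads per source
    alpha <- as.vector(assigned) / sum(x)
    if (include_unknown) {
      w <- r[m, ] * x
      if (sum(w) > 0) gamma[m, ] <- w / sum(w)
    }
    if (reestimate_sources && nrow(source_counts) >= 1) {
      for (k in seq_len(nrow(source_counts))) {
        w <- source_counts[k, ] + r[k, ] * x
        gamma[k, ] <- (w + 1e-8) / sum(w + 1e-8)
      }
    }
    ll_trace <- c(ll_trace, ll_of(alpha, gamma))
    if (it > 1 &&
        abs(ll_trace[it] - ll_trace[it - 1]) < tol * abs(ll_trace[it])) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    proportions = stats::setNames(alpha, src_names),
    gamma = gamma, ll_trace = ll_trace, converged = converged),
    class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat("source_estimate:",
      paste(sprintf("%s=%.3f", names(x$proportions), x$proportions),
            collapse = ", "), "\n")
  invisible(x)
}

#' Contribution of the adjacent anterior gut segment to each sink segment
#'
#' For every bird x day with a complete set of segments, each posterior
#' segment in turn is treated as the sink and all other segments of the
#' same bird and day as sources (plus an unknown source); only the mixing
#' proportion attributed to the adjacent anterior segment is reported. The
#' first segment has no anterior source and yields no rows.
#'
#' @param table counts feature_table with bird/segment/dph metadata
#'   (single domain)
#' @param segments ordered segment labels, anterior to posterior
#' @param include_unknown passed to [feast_em()]
#' @param ... passed to [feast_em()]
#' @return data.frame: bird, dph, sink_segment, source_segment, proportion,
#'   unknown (the unknown-source share)
#' @export
adjacent_segment_contribution <- function(
    table, segments = c("duodenum", "jejunum", "ileum", "cecum"),
    include_unknown = TRUE, ...) {
  md <- table$metadata
  out <- list()
  for (b in unique(md$bird)) for (t in unique(md$dph)) {
    ids <- md$sample_id[md$bird == b & md$dph == t]
    segs_here <- md$segment[match(ids, md$sample_id)]
    for (si in seq_along(segments)[-1]) {
      sink_seg <- segments[si]
      ant_seg <- segments[si - 1]
      if (!(sink_seg %in% segs_here) || !(ant_seg %in% segs_here)) {
        message("bird ", b, " DPH ", t, ": segment missing, sink ",
                sink_seg, " skipped")
        next
      }
      sink_id <- ids[segs_here == sink_seg]
      src_segs <- setdiff(intersect(segments, segs_here), sink_seg)
      src_ids <- ids[match(src_segs, segs_here)]
      est <- feast_em(table$mat[sink_id, ],
                      table$mat[src_ids, , drop = FALSE] |>
                        (\(mm) {rownames(mm) <- src_segs; mm})(),
                      include_unknown = include_unknown, ...)
      out[[length(out) + 1]] <- data.frame(
        bird = b, dph = t, sink_segment = sink_seg,
        source_segment = ant_seg,
        proportion = unname(est$proportions[ant_seg]),
        unknown = if (include_unknown)
          unname(est$proportions["unknown"]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}
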
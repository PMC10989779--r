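#' Low-rank softmax model of microbe-metabolite co-occurrence
#'
#' Estimates conditional co-occurrence probabilities
#' P(metabolite j | microbe i) = softmax_j(U_i . V_j + b_j) from paired
#' samples: per sample, microbe "tokens" are weighted by the sample's
#' microbe proportions and predict the sample's metabolite relative
#' intensities under a multinomial likelihood. Collapsing over samples,
#' each microbe i acquires a target metabolite distribution (the
#' proportion-weighted average of the metabolite profiles of the samples
#' it occurs in) and the low-rank parameterisation shares information
#' across microbes. Trained by full-batch gradient descent with
#' backtracking (the loss never increases); deterministic under a fixed
#' seed.
#'
#' @param microbe_counts samples x microbes matrix (counts or QMP values;
#'   only within-sample proportions matter)
#' @param metabolite_intensities samples x metabolites matrix (same
#'   samples, same order)
#' @param latent_dim embedding dimension (0 = bias-only baseline)
#' @param epochs gradient steps (default 500)
#' @param learning_rate initial step size
#' @param seed RNG seed for initialisation
#' @return object of class `interaction_matrix`: probs (microbes x
#'   metabolites, rows sum to 1), U, V, b, loss (trace)
#' @export
mmvec_fit <- function(microbe_counts, metabolite_intensities,
                      latent_dim = 3, epochs = 500, learning_rate = 0.1,
                      seed = 1) {
  Xm <- as.matrix(microbe_counts)
  Ym <- as.matrix(metabolite_intensities)
  if (nrow(Xm) != nrow(Ym))
    stop("microbe and metabolite tables must share samples")
  if (latent_dim < 0) stop("latent_dim must be >= 0")
  I <- ncol(Xm); J <- ncol(Ym)
  W <- Xm / pmax(rowSums(Xm), .Machine$double.eps)   # microbe proportions
  Yp <- Ym / pmax(rowSums(Ym), .Machine$double.eps)  # metabolite proportions
  ci <- colSums(W)                                    # total microbe weight
  Ybar <- crossprod(W, Yp)                            # I x J weighted targets
  Ybar <- Ybar / pmax(rowSums(Ybar), .Machine$double.eps)

  set.seed(seed)
  U <- if (latent_dim > 0)
    matrix(stats::rnorm(I * latent_dim, 0, 0.1), I) else NULL
  V <- if (latent_dim > 0)
    matrix(stats::rnorm(J * latent_dim, 0, 0.1), J) else NULL
  b <- stats::rnorm(J, 0, 0.01)

  softmax_rows <- function(M) {
    M <- M - apply(M, 1, max)
    E <- exp(M)
    E / rowSums(E)
  }
  logits <- function() {
    M <- matrix(b, I, J, byrow = TRUE)
    if (latent_dim > 0) M <- M + tcrossprod(U, V)
    M
  }
  loss_of <- function(P) -sum(ci * rowSums(Ybar * log(pmax(P, 1e-300))))

  lr <- learning_rate
  P <- softmax_rows(logits())
  loss <- loss_of(P)
  trace <- loss
  for (ep in seq_len(epochs)) {
    G <- ci * (P - Ybar)
    repeat {
      if (latent_dim > 0) {
        U_new <- U - lr * (G %*% V)
        V_new <- V - lr * crossprod(G, U)
      } else { U_new <- NULL; V_new <- NULL }
      b_new <- b - lr * colSums(G)
      M <- matrix(b_new, I, J, byrow = TRUE)
      if (latent_dim > 0) M <- M + tcrossprod(U_new, V_new)
      P_new <- softmax_rows(M)
      l_new <- loss_of(P_new)
      if (is.finite(l_new) && l_new <= loss + 1e-12) break
      lr <- lr / 2
      if (lr < 1e-10)
        stop("training diverged; lower the learning rate")
    }
    U <- U_new; V <- V_new; b <- b_new; P <- P_new; loss <- l_new
    trace <- c(trace, loss)
  }
  dimnames(P) <- list(colnames(Xm), colnames(Ym))
  structure(list(probs = P, U = U, V = V, b = b, loss = trace,
                 latent_dim = latent_dim),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf(
    "interaction_matrix: %d microbes x %d metabolites (rank %d), final loss %.4f\n",
    nrow(x$probs), ncol(x$probs), x$latent_dim, utils::tail(x$loss, 1)))
  invisible(x)
}

#' Select the top fraction of microbe-metabolite interactions
#'
#' Global ranking of all (microbe, metabolite) conditional probabilities;
#' the top `fraction` (default 1%) are retained as putative positive
#' co-occurrences. The retained count is ceiling(fraction * n_pairs); ties
#' at the cutoff are broken by stable (microbe, metabolite) ordering.
#'
#' @param interactions an `interaction_matrix`, or a data.frame with
#'   microbe, metabolite, probability columns (e.g. several segments'
#'   results concatenated)
#' @param fraction in (0, 1]
#' @return object of class `interaction_selection`: data.frame microbe,
#'   metabolite, probability (+ any extra columns), ordered by descending
#'   probability
#' @export
select_top <- function(interactions, fraction = 0.01) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (inherits(interactions, "interaction_matrix")) {
    P <- interactions$probs
    df <- data.frame(
      microbe = rep(rownames(P), times = ncol(P)),
      metabolite = rep(colnames(P), each = nrow(P)),
      probability = as.vector(P), stringsAsFactors = FALSE)
  } else df <- as.data.frame(interactions)
  ord <- order(-df$probability, df$microbe, df$metabolite)
  df <- df[ord, , drop = FALSE]
  n_keep <- ceiling(fraction * nrow(df))
  sel <- df[seq_len(n_keep), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(selected = sel, n_total = nrow(df), fraction = fraction),
            class = "interaction_selection")
}

#' Retained-interaction ratios per stratum
#'
#' Percent of retained (top-fraction) pairs among all pairs within each
#' (microbe stratum x metabolite cluster) cell — e.g. segment-and-domain
#' by trajectory cluster.
#'
#' @param selection an `interaction_selection`
#' @param all_pairs data.frame of every scored pair with microbe,
#'   metabolite columns (needed to count stratum totals); pass the
#'   concatenated per-segment score table
#' @param microbe_strata named character vector microbe -> stratum label
#'   (e.g. "jejunum fungi")
#' @param metabolite_clusters named vector metabolite -> cluster
#' @return data.frame: stratum, cluster, retained, total, percent
#' @export
ratio_table <- function(selection, all_pairs, microbe_strata,
                        metabolite_clusters) {
  lab <- function(df) {
    st <- microbe_strata[df$microbe]
    cl <- metabolite_clusters[df$metabolite]
    if (any(is.na(st))) stop("unlabelled microbe(s): ",
                             paste(unique(df$microbe[is.na(st)]), collapse = ", "))
    if (any(is.na(cl))) stop("unlabelled metabolite(s): ",
                             paste(unique(df$metabolite[is.na(cl)]), collapse = ", "))
    paste(st, cl, sep = "\r")
  }
  tot <- table(lab(all_pairs))
  ret <- table(lab(selection$selected))
  keys <- names(tot)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(stratum = parts[, 1], cluster = parts[, 2],
                    retained = as.integer(ifelse(keys %in% names(ret),
                                                 ret[keys], 0)),
                    total = as.integer(tot),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$retained / out$total
  out[order(out$stratum, out$cluster), ]
}

#' Bipartite interaction network and key taxa
#'
#' Merges retained interactions into one bipartite microbe-metabolite
#' graph, ranks microbes by degree (key taxa), and counts retained
#' metabolites per chemical category.
#'
#' @param selection an `interaction_selection`
#' @param annotation optional data.frame (metabolite, superclass) for the
#'   category bars
#' @return list: graph (igraph, bipartite), key_taxa (data.frame genus,
#'   degree), metabolite_categories (data.frame superclass, count)
#' @export
interaction_network <- function(selection, annotation = NULL) {
  sel <- selection$selected
  if (!nrow(sel)) stop("empty selection")
  # segment-specific microbes with the same genus merge into one vertex
  micro <- if ("genus" %in% names(sel)) sel$genus else sel$microbe
  edges <- unique(data.frame(microbe = micro, metabolite = sel$metabolite,
                             stringsAsFactors = FALSE))
  verts <- data.frame(
    name = c(unique(edges$microbe), unique(edges$metabolite)),
    type = c(rep(FALSE, length(unique(edges$microbe))),
             rep(TRUE, length(unique(edges$metabolite)))))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  deg <- table(edges$microbe)
  key <- data.frame(genus = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  key <- key[order(-key$degree, key$genus), ]
  rownames(key) <- NULL
  cats <- NULL
  if (!is.null(annotation)) {
    sc <- annotation$superclass[match(unique(sel$metabolite),
                                      annotation$metabolite)]
    tb <- table(sc)
    cats <- data.frame(superclass = names(tb), count = as.integer(tb),
                       stringsAsFactors = FALSE)
    cats <- cats[order(-cats$count), ]
    rownames(cats) <- NULL
  }
  list(graph = g, key_taxa = key, metabolite_categories = cats)
}
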
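#' Discretize an absolute-abundance table for community typing
#'
#' Community typing of QMP data uses binned log-transformed absolute
#' abundances: each cell becomes round(log10(1 + copies/g)), an integer
#' "order of magnitude" count suitable for a Dirichlet-multinomial model.
#'
#' @param table feature_table in QMP mode (or nonnegative numeric matrix)
#' @return integer matrix (samples x taxa)
#' @export
discretize_absolute <- function(table) {
  mat <- if (inherits(table, "feature_table")) {
    if (table$mode != "QMP") stop("discretize_absolute expects a QMP table")
    table$mat
  } else table
  if (any(mat < 0)) stop("absolute abundances must be nonnegative")
  m <- round(log10(1 + mat))
  storage.mode(m) <- "integer"
  m
}

dm_logdensity <- function(x, alpha) {
  # log Dirichlet-multinomial density per sample, up to the multinomial
  # coefficient (constant across mixture components)
  A <- sum(alpha)
  n_i <- rowSums(x)
  lgamma(A) - lgamma(n_i + A) +
    rowSums(lgamma(sweep(x, 2, alpha, "+"))) - sum(lgamma(alpha))
}

log_row_normalize <- function(lw) {
  m <- apply(lw, 1, max)
  w <- exp(lw - m)
  s <- rowSums(w)
  list(resp = w / s, loglik = sum(log(s) + m))
}

dm_alpha_update <- function(x, alpha, w) {
  # Weighted fixed-point update of the Dirichlet-multinomial parameter
  # (an MM step: each application cannot decrease the weighted likelihood)
  A <- sum(alpha)
  n_i <- rowSums(x)
  denom <- sum(w * (digamma(n_i + A) - digamma(A)))
  if (denom <= 0) return(alpha)
  num <- colSums(w * (digamma(sweep(x, 2, alpha, "+")) -
                        rep(digamma(alpha), each = nrow(x))))
  pmax(alpha * num / denom, 1e-4)
}

#' Fit a Dirichlet multinomial mixture (DMM) by EM
#'
#' Community types are the components of a finite mixture whose components
#' are Dirichlet-compound multinomials. The E-step computes per-sample
#' responsibilities from component DM log-likelihoods; the M-step updates
#' mixture weights and each component's alpha vector by Minka's fixed-point
#' iteration (an MM update, so the observed-data log-likelihood is
#' non-decreasing across EM iterations).
#'
#' @param x integer matrix (samples x taxa) of counts or binned
#'   log-abundances (see [discretize_absolute()]), or a counts-mode
#'   feature_table
#' @param k number of mixture components (>= 1, <= n samples)
#' @param seed RNG seed (initialisation)
#' @param max_iter maximum EM iterations
#' @param tol absolute convergence tolerance on the log-likelihood
#' @param init "kmeans" (log-proportion k-means) or "random"
#' @return object of class `dmm_model`: pi (mixture weights), alpha
#'   (k x taxa), resp (n x k responsibilities), assignment (hard labels),
#'   loglik, ll_trace, converged, and the model-selection criteria
#'   `laplace` (Laplace approximation to the negative log model evidence)
#'   and `bic`
#' @export
dmm_fit <- function(x, k, seed = 1, max_iter = 200, tol = 1e-4,
                    init = c("kmeans", "random")) {
  init <- match.arg(init)
  if (inherits(x, "feature_table")) x <- x$mat
  if (any(x %% 1 != 0))
    stop("dmm_fit needs integer counts; for QMP tables run ",
         "discretize_absolute() first")
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(x)) stop("k exceeds the number of samples")
  x <- x[, colSums(x) > 0, drop = FALSE]
  n <- nrow(x); J <- ncol(x)
  set.seed(seed)

  # initial responsibilities
  if (k == 1) {
    resp <- matrix(1, n, 1)
  } else if (init == "kmeans") {
    lp <- log1p(x / rowSums(x) * 1e4)
    km <- tryCatch(stats::kmeans(lp, centers = k, nstart = 3),
                   error = function(e) NULL)
    lab <- if (is.null(km)) sample.int(k, n, replace = TRUE) else km$cluster
    resp <- 0.1 / (k - 1) + 0.9 * outer(lab, seq_len(k), "==")
    resp <- resp / rowSums(resp)
  } else {
    resp <- matrix(stats::rgamma(n * k, 1), n, k)
    resp <- resp / rowSums(resp)
  }

  alpha <- matrix(NA_real_, k, J, dimnames = list(NULL, colnames(x)))
  props <- x / pmax(rowSums(x), 1)
  for (kk in seq_len(k)) {
    w <- resp[, kk]
    pbar <- colSums(w * props) / sum(w)
    alpha[kk, ] <- pmax(pbar, 1e-6) * 30
  }
  pi_k <- colMeans(resp)

  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lw <- vapply(seq_len(k), function(kk)
      log(pi_k[kk]) + dm_logdensity(x, alpha[kk, ]), numeric(n))
    if (n == 1) lw <- matrix(lw, 1, k)
    norm <- log_row_normalize(lw)
    resp <- norm$resp
    ll_trace <- c(ll_trace, norm$loglik)
    if (it > 1 && abs(ll_trace[it] - ll_trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    pi_k <- pmax(colMeans(resp), 1e-12)
    pi_k <- pi_k / sum(pi_k)
    for (kk in seq_len(k))
      for (inner in 1:3)
        alpha[kk, ] <- dm_alpha_update(x, alpha[kk, ], resp[, kk])
  }
  loglik <- ll_trace[length(ll_trace)]

  # Laplace approximation to the negative log model evidence, computed in
  # the log-alpha parameterisation with a diffuse Gaussian prior on
  # lambda = log(alpha) (sd^2 = 10). Per component the Hessian of the
  # negative log posterior is diagonal-plus-rank-one, so its determinant
  # comes from the matrix determinant lemma; the k-1 free mixture weights
  # contribute a BIC-style 0.5 log(n) each.
  sigma2 <- 10
  P <- k * J + (k - 1)
  log_det <- 0
  neg_log_prior <- 0
  n_i <- rowSums(x)
  for (kk in seq_len(k)) {
    a <- alpha[kk, ]
    A <- sum(a)
    w <- resp[, kk]
    d_alpha <- colSums(w * (rep(trigamma(a), each = n) -
                              trigamma(sweep(x, 2, a, "+"))))
    cc <- sum(w * (trigamma(n_i + A) - trigamma(A)))  # <= 0
    d_lambda <- pmax(a^2 * d_alpha, 0) + 1 / sigma2
    corr <- 1 + cc * sum(a^2 / d_lambda)
    log_det <- log_det + sum(log(d_lambda)) + log(max(corr, 1e-3))
    neg_log_prior <- neg_log_prior +
      sum(0.5 * log(2 * pi * sigma2) + log(a)^2 / (2 * sigma2))
  }
  laplace <- -loglik + neg_log_prior + 0.5 * log_det +
    0.5 * (k - 1) * log(n) - (P / 2) * log(2 * pi)
  bic <- -2 * loglik + P * log(n)

  structure(list(
    k = k, pi = pi_k, alpha = alpha, resp = resp,
    assignment = max.col(resp), loglik = loglik, ll_trace = ll_trace,
    converged = converged, laplace = laplace, bic = bic),
    class = "dmm_model")
}

#' @export
print.dmm_model <- function(x, ...) {
  cat(sprintf(
    "dmm_model: k = %d, loglik = %.2f, laplace = %.2f, bic = %.2f (%s)\n",
    x$k, x$loglik, x$laplace, x$bic,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Select the number of community types
#'
#' Fits the DMM for each candidate k with multiple restarts (keeping the
#' best log-likelihood per k) and selects the k minimising the Laplace
#' approximation to the negative model evidence; BIC is reported alongside.
#'
#' @param x integer matrix or counts feature_table (see [dmm_fit()])
#' @param k_range candidate component counts
#' @param seed RNG seed
#' @param n_restarts random restarts per k (the first uses k-means init)
#' @param ... passed to [dmm_fit()]
#' @return list with `best_k`, `best_fit`, `criteria` (data.frame per k),
#'   and all kept fits
#' @export
dmm_select <- function(x, k_range, seed = 1, n_restarts = 3, ...) {
  if (!length(k_range)) stop("k_range must be nonempty")
  fits <- list()
  for (k in k_range) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      f <- tryCatch(
        dmm_fit(x, k, seed = seed + 1000 * r,
                init = if (r == 1) "kmeans" else "random", ...),
        error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$loglik > best$loglik))
        best <- f
    }
    if (is.null(best)) {
      warning("all restarts failed for k = ", k, "; k skipped")
      next
    }
    fits[[as.character(k)]] <- best
  }
  if (!length(fits)) stop("no candidate k could be fitted")
  crit <- data.frame(
    k = as.integer(names(fits)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    laplace = vapply(fits, function(f) f$laplace, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)))
  rownames(crit) <- NULL
  best_k <- crit$k[which.min(crit$laplace)]
  list(best_k = best_k, best_fit = fits[[as.character(best_k)]],
       criteria = crit, fits = fits)
}

#' Community-type frequencies by segment and day
#'
#' Cross-tabulates hard community-type assignments over the segment x DPH
#' grid — the spatiotemporal distribution of types.
#'
#' @param model a fitted `dmm_model`
#' @param metadata data.frame aligned with the fitted samples, with
#'   `segment` and `dph` columns
#' @return data.frame segment, dph, type, count, freq
#' @export
community_type_frequency <- function(model, metadata) {
  stopifnot(nrow(metadata) == nrow(model$resp))
  df <- data.frame(segment = metadata$segment, dph = metadata$dph,
                   type = model$assignment)
  agg <- as.data.frame(table(df$segment, df$dph, df$type),
                       stringsAsFactors = FALSE)
  names(agg) <- c("segment", "dph", "type", "count")
  agg$dph <- as.numeric(agg$dph); agg$type <- as.integer(agg$type)
  tot <- stats::ave(agg$count, agg$segment, agg$dph, FUN = sum)
  agg$freq <- ifelse(tot > 0, agg$count / tot, 0)
  agg[order(agg$segment, agg$dph, agg$type), ]
}
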
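test_that("Shannon index matches hand-evaluated identities", {
  expect_equal(shannon(rep(1, 8)), log(8))
  expect_equal(shannon(c(1, 0, 0)), 0)
  expect_equal(shannon(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(shannon(c(1, 1, 1, 1), base = 2), 2)
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(shannon(c(-1, 2)), "nonnegative")
  # agrees with the standard community-ecology implementation
  set.seed(3)
  v <- rpois(20, 5)
  expect_equal(shannon(v), unname(vegan::diversity(v)), tolerance = 1e-12)
})

test_that("Bray-Curtis matches its definition and the vegan implementation", {
  expect_equal(bray_curtis(c(1, 2), c(1, 2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(1, 2, 3), c(3, 2, 1)), 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all zero")
  set.seed(4)
  m <- matrix(rpois(40, 10), 4, 10)
  mine <- sapply(2:4, function(i) bray_curtis(m[1, ], m[i, ]))
  ref <- as.matrix(vegan::vegdist(m, "bray"))[1, 2:4]
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
})

test_that("adjacent-time dissimilarities enumerate all cross-time pairs", {
  mat <- cbind(a = rep(5, 20), b = rep(2, 20))
  rownames(mat) <- sprintf("s%02d", 1:20)
  md <- data.frame(sample_id = rownames(mat), bird = rep(1:10, 2),
                   segment = "ileum", dph = rep(c(1, 4), each = 10))
  ft <- feature_table(mat, md, mode = "counts")
  d <- adjacent_time_dissimilarity(ft, "ileum")
  expect_equal(nrow(d), 100)             # 10 x 10 cross pairs
  expect_true(all(d$interval == "1-4"))
  expect_true(all(d$dissimilarity == 0)) # identical communities
})

test_that("the largest planted compositional shift has the highest turnover", {
  set.seed(8)
  days <- c(1, 4, 7, 14)
  mk <- function(center) t(sapply(1:6, function(i)
    rmultinom(1, 1000, center)[, 1]))
  c1 <- c(10, 1, 1, 1); c2 <- c(1, 1, 1, 10)  # big shift 1 -> 4
  centers <- list(c1, c2, c2, c2)
  mat <- do.call(rbind, lapply(seq_along(days), function(k) mk(centers[[k]])))
  rownames(mat) <- sprintf("s%02d", seq_len(nrow(mat)))
  colnames(mat) <- paste0("t", 1:4)
  md <- data.frame(sample_id = rownames(mat),
                   bird = rep(1:6, length(days)), segment = "cecum",
                   dph = rep(days, each = 6))
  ft <- feature_table(mat, md, mode = "counts")
  d <- adjacent_time_dissimilarity(ft, "cecum")
  med <- tapply(d$dissimilarity, d$interval, median)
  expect_equal(names(which.max(med)), "1-4")
})

test_that("principal coordinates reproduce Euclidean geometry", {
  set.seed(1)
  pts <- matrix(rnorm(24), 12, 2,
                dimnames = list(sprintf("s%02d", 1:12), NULL))
  D <- as.matrix(dist(pts))
  pc <- pcoa(D)
  expect_lt(max(abs(as.matrix(dist(pc$coords)) - D)), 1e-8)
  # three equidistant samples: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D3) <- 0
  pc3 <- pcoa(D3)
  pos <- pc3$eig[pc3$eig > 1e-8]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)
  # duplicated sample lands on coincident coordinates
  D4 <- as.matrix(dist(rbind(pts, pts[1, , drop = FALSE])))
  pc4 <- pcoa(D4)
  expect_lt(max(abs(pc4$coords[1, ] - pc4$coords[13, ])), 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("permanova matches an exact enumeration oracle on a tiny design", {
  set.seed(2)
  m <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  D <- as.matrix(dist(m))
  g <- rep(c("a", "b"), each = 3)
  # brute-force oracle: independent F computation over all 720 orderings
  f_oracle <- function(D, g) {
    n <- length(g); d2 <- D^2
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      sub <- d2[idx, idx]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  f_obs <- f_oracle(D, g)
  p_exact <- mean(apply(perms, 1, function(idx) f_oracle(D, g[idx])) >=
                    f_obs - 1e-12)
  # the shared +1 correction cancels when the identity permutation is
  # inside the enumerated set, so compare the raw exceedance fractions
  pv <- permanova(D, g, permutations = perms)
  expect_equal(pv$F, f_obs, tolerance = 1e-12)
  expect_equal(pv$p_value, (1 + p_exact * nrow(perms)) / (1 + nrow(perms)),
               tolerance = 1e-12)
  # and agrees with the reference implementation
  ref <- vegan::adonis2(as.dist(D) ~ g, permutations = 99)
  expect_equal(pv$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(pv$F, ref$F[1], tolerance = 1e-10)
})

test_that("permanova null and separated cases behave as expected", {
  set.seed(10)
  mat <- matrix(rep(c(3, 1, 4, 1, 5), 8), 8, 5, byrow = TRUE)
  D <- as.matrix(dist(mat + matrix(rnorm(40, 0, 1e-6), 8)))
  rownames(D) <- colnames(D) <- paste0("s", 1:8)
  g <- rep(c("a", "b"), each = 4)
  pv <- permanova(D, g, n_perm = 199, seed = 1)
  expect_lt(pv$R2, 0.35)
  expect_gt(pv$p_value, 0.2)
  # perfectly separated groups reach the minimal achievable p
  m2 <- rbind(matrix(rnorm(50, 0, 0.01), 10), matrix(rnorm(50, 50, 0.01), 10))
  D2 <- as.matrix(dist(m2)); rownames(D2) <- colnames(D2) <- paste0("s", 1:20)
  pv2 <- permanova(D2, rep(c("a", "b"), each = 10), n_perm = 199, seed = 1)
  expect_equal(pv2$p_value, 1 / 200, tolerance = 1e-12)
  expect_error(permanova(D2, rep("a", 20)), "two groups")
})

test_that("permanova p-values are calibrated under label shuffling", {
  set.seed(77)
  pvals <- replicate(400, {
    m <- matrix(rnorm(30), 10, 3)
    D <- as.matrix(dist(m)); rownames(D) <- colnames(D) <- paste0("s", 1:10)
    permanova(D, sample(rep(c("a", "b"), each = 5)), n_perm = 99)$p_value
  })
  # super-uniform: P(p <= t) <= t (up to Monte-Carlo error)
  for (t in c(0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= t), t + 2.5 * sqrt(t * (1 - t) / 400))
})

test_that("marginal variance partition is bounded for balanced factors", {
  fx <- default_sim()
  tab <- fx$sim$tables$fungi
  keep <- tab$metadata$segment %in% c("ileum", "cecum")
  sub <- ft_subset(tab, samples = keep)
  D <- bray_curtis_matrix(sub)
  vp <- variance_partition(D, sub$metadata, c("segment", "dph"),
                           n_perm = 99, seed = 3)
  expect_equal(nrow(vp), 2)
  expect_true(all(vp$R2 >= 0 & vp$R2 <= 1))
  expect_lte(sum(vp$R2), 1)
})

test_that("protest recognises rotated, scaled and mirrored configurations", {
  set.seed(5)
  A <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  B <- 3 * A %*% R + 5
  pt <- protest_compare(A, B, n_perm = 199, seed = 1)
  expect_equal(pt$m12, 1, tolerance = 1e-8)
  expect_lt(max(pt$residuals), 1e-8)
  # reflection is allowed: a mirror image matches as well as a rotation
  Bm <- B %*% diag(c(-1, 1))
  ptm <- protest_compare(A, Bm, n_perm = 199, seed = 1)
  expect_equal(ptm$m12, 1, tolerance = 1e-8)
  # symmetric in its arguments
  C <- matrix(rnorm(40), 20, 2)
  expect_equal(protest_compare(A, C, n_perm = 99, seed = 2)$m12,
               protest_compare(C, A, n_perm = 99, seed = 2)$m12,
               tolerance = 1e-8)
  expect_error(protest_compare(A, B[1:10, ]), "same samples")
})

test_that("protest stays null-calibrated for unrelated configurations", {
  set.seed(6)
  hits <- replicate(20, {
    A <- matrix(rnorm(100), 50, 2)
    B <- matrix(rnorm(100), 50, 2)
    protest_compare(A, B, n_perm = 199)$p_value > 0.05
  })
  expect_gte(mean(hits), 0.9)
})
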
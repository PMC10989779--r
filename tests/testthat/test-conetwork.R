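ft_from_mat <- function(mat, dph = NULL) {
  md <- data.frame(sample_id = rownames(mat),
                   bird = seq_len(nrow(mat)), segment = "cecum",
                   dph = if (is.null(dph)) rep(1, nrow(mat)) else dph,
                   stringsAsFactors = FALSE)
  feature_table(mat, md, mode = "counts")
}

test_that("the 30% prevalence boundary is inclusive", {
  mat <- matrix(0, 10, 3, dimnames = list(paste0("s", 1:10),
                                          c("g3", "g2", "g10")))
  mat[1:3, "g3"] <- 1   # exactly 30%
  mat[1:2, "g2"] <- 1   # 20%
  mat[, "g10"] <- 1     # 100%
  ft <- ft_from_mat(mat)
  f <- prevalence_filter(ft, 0.30)
  expect_setequal(colnames(f$mat), c("g3", "g10"))
})

test_that("partial Spearman matches the recursive closed-form oracle", {
  set.seed(1)
  n <- 60
  z <- rnorm(n)
  x <- 2 * z + rnorm(n, 0, 0.5)
  y <- -1.5 * z + rnorm(n, 0, 0.5)
  ps <- partial_spearman(x, y, covariates = z)
  # closed form on the marginal Spearman correlations
  r_xy <- cor(x, y, method = "spearman")
  r_xz <- cor(x, z, method = "spearman")
  r_yz <- cor(y, z, method = "spearman")
  oracle <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(ps$rho, oracle, tolerance = 1e-10)
  expect_lt(abs(ps$rho), 0.4)           # dependence explained by z
  expect_gt(abs(r_xy), 0.6)             # but marginally strong
  # rank invariance: any strictly increasing transform gives rho = 1
  ps2 <- partial_spearman(x, exp(x))
  expect_equal(ps2$rho, 1, tolerance = 1e-12)
  # empty conditioning set reduces to plain Spearman
  ps3 <- partial_spearman(x, y)
  expect_equal(ps3$rho, r_xy, tolerance = 1e-12)
  expect_warning(out <- partial_spearman(x, rep(1, n)), "constant")
  expect_equal(out$p_value, 1)
})

test_that("Benjamini-Hochberg matches a brute-force oracle exactly", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(2)
  for (n in c(1, 7, 100, 1000)) {
    p <- runif(n)^2
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-15)
    expect_identical(stats::p.adjust(p, "BH") <= 0.05,
                     bh_oracle(p) <= 0.05)
  }
})

test_that("planted correlated blocks are recovered as edges", {
  set.seed(3)
  n <- 80
  z <- rnorm(n)
  block <- sapply(1:5, function(i) 1.2 * z + rnorm(n, 0, 0.7)) # rho ~ 0.7
  noise <- matrix(rnorm(n * 15), n)
  mat <- exp(cbind(block, noise))
  dimnames(mat) <- list(paste0("s", 1:n), sprintf("g%02d", 1:20))
  net <- build_network(ft_from_mat(mat), condition = "none")
  blk_pairs <- t(combn(sprintf("g%02d", 1:5), 2))
  keys <- paste(net$edges$genus_a, net$edges$genus_b)
  hit <- apply(blk_pairs, 1, function(pr)
    paste(pr[1], pr[2]) %in% keys | paste(pr[2], pr[1]) %in% keys)
  expect_gte(mean(hit), 0.8)
  expect_true(all(net$edges$p_adj <= 0.05))
  expect_true(all(abs(net$edges$rho) <= 1))
})

test_that("equal loads make QMP and RMP networks identical", {
  set.seed(4)
  counts <- matrix(rpois(50 * 12, 20) + 1, 50, 12,
                   dimnames = list(paste0("s", 1:50),
                                   sprintf("g%02d", 1:12)))
  ft <- ft_from_mat(counts)
  rmp <- to_relative(ft)
  qmp <- qmp_transform(rmp, stats::setNames(rep(1, 50), rownames(counts)))
  net_r <- build_network(rmp, condition = "none")
  net_q <- build_network(qmp, condition = "none")
  expect_equal(net_q$edges$rho, net_r$edges$rho, tolerance = 1e-12)
  expect_equal(net_q$edges$genus_a, net_r$edges$genus_a)
})

test_that("topology metrics match hand-evaluated toy graphs", {
  tri_edges <- data.frame(genus_a = c("a", "b", "a"),
                          genus_b = c("b", "c", "c"),
                          rho = 0.9, p = 0, p_adj = 0, sign = "positive")
  tri <- structure(list(vertices = c("a", "b", "c"), edges = tri_edges,
                        segment = NA, mode = "QMP"), class = "co_network")
  t1 <- topology(tri)
  expect_equal(t1$clustering, 1.0)
  expect_equal(t1$avg_separation, 1.0)
  expect_equal(t1$avg_betweenness, 0)
  path_edges <- tri_edges[1:2, ]            # a-b, b-c
  p3 <- structure(list(vertices = c("a", "b", "c"), edges = path_edges,
                       segment = NA, mode = "QMP"), class = "co_network")
  t2 <- topology(p3)
  expect_equal(t2$clustering, 0.0)
  expect_equal(t2$avg_separation, 4 / 3)
  # middle vertex lies on the single a-c shortest path
  g <- qmpflow:::co_network_graph(p3)
  expect_equal(unname(igraph::betweenness(g)[["b"]]), 1)
  # empty network reports zeros with a flag
  e0 <- structure(list(vertices = "a", edges = tri_edges[0, ],
                       segment = NA, mode = "QMP"), class = "co_network")
  expect_true(topology(e0)$empty)
})

test_that("keystone ranking uses degree with deterministic tie-breaks", {
  star <- data.frame(genus_a = "hub", genus_b = paste0("leaf", 1:5),
                     rho = 0.8, p = 0, p_adj = 0, sign = "positive")
  net <- structure(list(vertices = c("hub", paste0("leaf", 1:5)),
                        edges = star, segment = NA, mode = "QMP"),
                   class = "co_network")
  k <- keystone(net, top_n = 3)
  expect_equal(k$genus[1], "hub")
  expect_equal(k$degree[1], 5)
  # all-equal degrees: lexical order decides
  ring <- data.frame(genus_a = c("x", "y", "z"), genus_b = c("y", "z", "x"),
                     rho = 0.5, p = 0, p_adj = 0, sign = "positive")
  netr <- structure(list(vertices = c("x", "y", "z"), edges = ring,
                         segment = NA, mode = "QMP"), class = "co_network")
  expect_equal(keystone(netr, 3)$genus, c("x", "y", "z"))
})

test_that("edge sharing separates specialists from generalists", {
  mk <- function(a, b) structure(
    list(vertices = unique(c(a, b)),
         edges = data.frame(genus_a = a, genus_b = b, rho = 0.5, p = 0,
                            p_adj = 0, sign = "positive"),
         segment = NA, mode = "QMP"), class = "co_network")
  nets <- list(duodenum = mk(c("a", "c"), c("b", "d")),
               jejunum = mk("a", "b"),
               ileum = mk("b", "a"))       # order-insensitive identity
  sh <- edge_sharing(nets)
  lab <- stats::setNames(sh$edges$label, sh$edges$edge)
  expect_equal(unname(lab[["a|b"]]), "generalist")
  expect_equal(unname(lab[["c|d"]]), "specialist")
  expect_equal(unname(sh$proportions[["duodenum"]]), 0.5)
  expect_error(edge_sharing(nets[1]), "two networks")
})

test_that("sign ratios keep the log finite via pseudocounts", {
  e <- data.frame(genus_a = rep("v", 5), genus_b = paste0("w", 1:5),
                  rho = 0.5, p = 0, p_adj = 0, sign = "positive")
  net <- structure(list(vertices = c("v", paste0("w", 1:5)), edges = e,
                        segment = NA, mode = "QMP"), class = "co_network")
  sr <- sign_ratio(net)
  v <- sr[sr$genus == "v", ]
  expect_lt(v$log10_ratio, 0)
  expect_equal(v$log10_ratio, log10(0.5 / 5.5))
  # equal counts balance to zero
  e2 <- e; e2$sign <- rep(c("positive", "negative"), c(2, 3))[1:5]
  e2$sign <- c("positive", "positive", "negative", "negative", "negative")
  net2 <- structure(list(vertices = net$vertices, edges = e2,
                         segment = NA, mode = "QMP"), class = "co_network")
  sr2 <- sign_ratio(net2)
  expect_gt(sr2$log10_ratio[sr2$genus == "v"], 0)
  e3 <- e[1:2, ]; e3$sign <- c("positive", "negative")
  net3 <- structure(list(vertices = net$vertices, edges = e3,
                         segment = NA, mode = "QMP"), class = "co_network")
  expect_equal(sign_ratio(net3)$log10_ratio[1], 0)
})

test_that("self-comparison yields perfect correlation consistency", {
  set.seed(5)
  mat <- exp(matrix(rnorm(40 * 10), 40, 10,
                    dimnames = list(paste0("s", 1:40),
                                    sprintf("g%02d", 1:10))))
  net <- build_network(ft_from_mat(mat), condition = "none")
  cc <- qmp_rmp_consistency(net, net)
  expect_equal(cc$consistency, 100)
  expect_equal(sum(cc$table), choose(10, 2))
})

test_that("varying loads create compositional artifacts that QMP avoids", {
  set.seed(6)
  n <- 60
  load <- 10^seq(3, 7, length.out = n)      # 10,000-fold load sweep
  aa <- cbind(const = rep(1e3, n),
              sapply(1:4, function(i) load * runif(n, 0.24, 0.26)))
  colnames(aa) <- c("const", paste0("bloom", 1:4))
  rownames(aa) <- paste0("s", 1:n)
  ra <- aa / rowSums(aa)
  ft_q <- ft_from_mat(aa)
  ft_r <- ft_from_mat(ra)
  expect_warning(net_q <- build_network(ft_q, mode = "QMP",
                                        condition = "none"), "constant")
  net_r <- build_network(ft_r, mode = "RMP", condition = "none")
  cc <- qmp_rmp_consistency(net_q, net_r)
  # the constant taxon picks up spurious negative RMP correlations with
  # the bloomers, so off-diagonal (QMP-NS, RMP-Neg) mass appears
  expect_gt(cc$table["NS", "Neg"], 0)
  expect_lt(cc$consistency, 100)
})
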
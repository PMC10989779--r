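met_table <- function(mat, dph, ann = NULL) {
  if (is.null(ann))
    ann <- data.frame(metabolite = colnames(mat),
                      superclass = "Lipids and lipid-like molecules",
                      class = "c", subclass = "s",
                      stringsAsFactors = FALSE)
  structure(list(mat = mat,
                 metadata = data.frame(sample_id = rownames(mat),
                                       bird = seq_len(nrow(mat)),
                                       dph = dph),
                 annotation = ann),
            class = "metabolite_table")
}

test_that("feature filtering applies the strict presence and annotation rules", {
  n <- 10
  mat <- matrix(1, n, 3,
                dimnames = list(paste0("s", 1:n), c("keep", "rare", "unk")))
  mat[4:10, "rare"] <- 0     # present in exactly 30% -> dropped (strict >)
  ann <- data.frame(metabolite = colnames(mat),
                    superclass = c("Benzenoids", "Benzenoids", "unknown"),
                    class = "c", subclass = "s")
  tab <- met_table(mat, rep(c(1, 7), 5), ann)
  f <- filter_features(tab)
  expect_equal(colnames(f$mat), "keep")
  log <- attr(f, "removal_log")
  expect_equal(unname(log["low_presence"]), 1)
  expect_equal(unname(log["unannotated"]), 1)
})

test_that("VIP is normalised and flags planted discriminative metabolites", {
  set.seed(1)
  n <- 40; p <- 60
  grp <- rep(c("a", "b"), each = n / 2)
  mat <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), sprintf("m%03d", 1:p)))
  mat[grp == "b", 1:10] <- mat[grp == "b", 1:10] + 2  # 2 SD shift
  res <- opls_da(10^mat, grp)
  expect_equal(mean(res$vip^2), 1, tolerance = 1e-8)
  top10 <- names(sort(res$vip, decreasing = TRUE))[1:10]
  expect_setequal(top10, sprintf("m%03d", 1:10))
  expect_true(all(res$vip[1:10] > 1.5))
  # P1 separates the groups
  f_sep <- summary(aov(res$scores[, 1] ~ grp))[[1]]$`F value`[1]
  expect_gt(f_sep, 50)
})

test_that("shuffled group labels collapse the separation", {
  set.seed(2)
  n <- 40; p <- 60
  grp <- rep(c("a", "b"), each = n / 2)
  mat <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), sprintf("m%03d", 1:p)))
  mat[grp == "b", 1:10] <- mat[grp == "b", 1:10] + 2
  res_true <- opls_da(10^mat, grp)
  res_perm <- opls_da(10^mat, sample(grp))
  f_of <- function(r, g) summary(aov(r$scores[, 1] ~ g))[[1]]$`F value`[1]
  expect_gt(f_of(res_true, grp) / max(f_of(res_perm, sample(grp)), 1), 5)
  # permuted VIPs no longer concentrate on the planted set
  topperm <- names(sort(res_perm$vip, decreasing = TRUE))[1:10]
  expect_lt(length(intersect(topperm, sprintf("m%03d", 1:10))), 8)
})

test_that("predictive scores are stable in the orthogonal component count", {
  set.seed(3)
  n <- 90; p <- 20
  grp <- rep(c("a", "b", "c"), each = 30)
  mat <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), sprintf("m%03d", 1:p)))
  mat[grp == "b", 1:5] <- mat[grp == "b", 1:5] + 5
  mat[grp == "c", 6:10] <- mat[grp == "c", 6:10] + 5
  r1 <- opls_da(10^mat, grp, n_orth = 1)
  r2 <- opls_da(10^mat, grp, n_orth = 2)
  expect_gte(abs(cor(r1$scores[, 1], r2$scores[, 1])), 0.999)
  expect_error(opls_da(10^mat, c(rep("a", 89), "b")), "2 samples")
})

test_that("time association finds planted changes and stays calibrated", {
  set.seed(4)
  n_per <- 10; days <- c(1, 4, 7, 14)
  dph <- rep(days, each = n_per)
  p <- 400
  mat <- matrix(rnorm(length(dph) * p), length(dph), p,
                dimnames = list(paste0("s", seq_along(dph)),
                                sprintf("m%04d", 1:p)))
  # 20 planted step changes of 3 SD from day 7 on
  mat[dph >= 7, 1:20] <- mat[dph >= 7, 1:20] + 3
  # one strictly constant metabolite
  mat[, p] <- 0
  res <- glm_time_association(10^mat - 1, dph)
  expect_true(all(res$associated[1:20]))
  expect_equal(res$p[res$metabolite == sprintf("m%04d", p)], 1)
  # null features: raw p below 0.05 near the nominal rate
  null_p <- res$p[21:(p - 1)]
  expect_gt(mean(null_p < 0.05), 0.02)
  expect_lt(mean(null_p < 0.05), 0.09)
  # BH agrees with p.adjust on the same vector
  expect_equal(res$p_adj, stats::p.adjust(res$p, "BH"), tolerance = 1e-12)
  expect_error(glm_time_association(10^mat, rep(1, length(dph))),
               "two distinct")
})

test_that("trajectory clustering recovers planted templates", {
  set.seed(5)
  days <- c(1, 4, 7, 14, 21, 28, 35, 42)
  n_rep <- 6
  dph <- rep(days, each = n_rep)
  u <- (seq_along(days) - 1) / (length(days) - 1)
  shapes <- list(up = u, down = 1 - u,
                 step_up = as.numeric(u > 0), step_down = as.numeric(u == 0),
                 mid = 1 - abs(2 * u - 1), late_down = (1 - u)^2)
  per <- 20
  mats <- lapply(seq_along(shapes), function(k) {
    mu <- 3 * shapes[[k]][match(dph, days)]
    sapply(seq_len(per), function(i) mu + rnorm(length(dph), 0, 0.2))
  })
  mat <- do.call(cbind, mats)
  dimnames(mat) <- list(paste0("s", seq_along(dph)),
                        sprintf("m%03d", seq_len(ncol(mat))))
  truth <- rep(seq_along(shapes), each = per)
  cl <- cluster_trajectories(10^mat, dph, k = 6)
  expect_gte(rand_index_adj(cl$cluster, truth), 0.9)
  # a monotone-up metabolite sits in the cluster whose centre tracks time
  up_cl <- cl$cluster[["m001"]]
  rho_by_cluster <- apply(cl$centers, 1, function(ctr)
    cor(ctr, seq_along(days), method = "spearman"))
  expect_equal(unname(which.max(rho_by_cluster)), up_cl)
  # determinism: identical input order, identical result
  cl2 <- cluster_trajectories(10^mat, dph, k = 6)
  expect_identical(cl$cluster, cl2$cluster)
})

test_that("per-sample profile clustering is available and consistent", {
  set.seed(8)
  days <- c(1, 4, 7, 14)
  dph <- rep(days, each = 5)
  up <- 2 * (match(dph, days) - 1) / 3
  mat <- cbind(sapply(1:6, function(i) up + rnorm(20, 0, 0.1)),
               sapply(1:6, function(i) rev(up) + rnorm(20, 0, 0.1)))
  dimnames(mat) <- list(paste0("s", 1:20), paste0("m", 1:12))
  cl_means <- cluster_trajectories(10^mat, dph, k = 2)
  cl_samp <- cluster_trajectories(10^mat, dph, k = 2, profile = "samples")
  expect_gte(rand_index_adj(cl_means$cluster, cl_samp$cluster), 0.99)
  expect_equal(ncol(cl_samp$trajectories), 20)
})

test_that("degenerate clustering input is flagged", {
  days <- c(1, 4, 7, 14)
  mat <- matrix(5, 8, 10, dimnames = list(paste0("s", 1:8),
                                          paste0("m", 1:10)))
  expect_warning(cl <- cluster_trajectories(mat, rep(days, 2), k = 3),
                 "degenerate")
  expect_error(cluster_trajectories(mat[, 1:2], rep(days, 2), k = 6),
               "exceeds")
})

test_that("cluster chemistry proportions sum to one per cluster", {
  cl <- c(m1 = 1, m2 = 1, m3 = 2)
  ann <- data.frame(metabolite = c("m1", "m2", "m3"),
                    superclass = c("Benzenoids", "Lipids", "Lipids"))
  comp <- cluster_composition(cl, ann)
  sums <- tapply(comp$proportion, comp$cluster, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(comp$proportion[comp$cluster == 2 &
                                 comp$superclass == "Lipids"], 1)
})

test_that("the planted lipid-heavy clusters surface in the composition", {
  fx <- default_sim()
  met <- simulate_metabolome(fx$config, fx$sim)
  truth <- met$truth
  assoc <- truth$metabolite[truth$cluster > 0]
  comp <- cluster_composition(
    stats::setNames(truth$cluster[truth$cluster > 0], assoc),
    met$table$annotation)
  lipid <- comp[comp$superclass == "Lipids and lipid-like molecules", ]
  heavy <- lipid$proportion[lipid$cluster %in% c(2, 3)]
  other <- lipid$proportion[lipid$cluster %in% c(1, 4, 6)]
  expect_gt(min(heavy), max(other))
})
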
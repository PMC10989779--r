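test_that("a perfect-efficiency dilution series is recovered exactly", {
  lg <- 3:8
  ct <- 40 - log10(2)^-1 * lg    # doubling per cycle
  cv <- fit_standard_curve(lg, ct)
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(cv$slope, -3.3219, tolerance = 1e-4)
  expect_equal(cv$efficiency, 100, tolerance = 0.1)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_equal(cv$range_log10, c(3, 8))
})

test_that("curve fitting needs three distinct concentrations", {
  expect_error(fit_standard_curve(c(3, 3, 3), c(30, 30.1, 29.9)),
               "3 distinct")
  expect_error(fit_standard_curve(c(3, 4), c(30, 27)), "3 distinct")
})

test_that("slope is recovered under measurement noise", {
  set.seed(42)
  slopes <- replicate(100, {
    lg <- rep(3:8, each = 2)
    ct <- 38 - 3.4 * lg + stats::rnorm(length(lg), 0, 0.1)
    fit_standard_curve(lg, ct)$slope
  })
  expect_lt(abs(mean(slopes) + 3.4), 0.05)
  expect_true(all(abs(slopes + 3.4) < 0.15))
})

test_that("ct_to_load inverts the calibration line", {
  cv <- fit_standard_curve(3:8, 40 - 3.5 * (3:8))
  # Ct at the low end of the curve corresponds to 10^3 copies exactly
  r <- suppressWarnings(ct_to_load(cv, cv$intercept + cv$slope * 3,
                                   dilution_factor = 1, sample_weight = 1))
  expect_equal(r$copies, 1e3, tolerance = 1e-9)
  # linear in the dilution factor
  r1 <- ct_to_load(cv, 26, dilution_factor = 50, sample_weight = 0.2)
  r2 <- ct_to_load(cv, 26, dilution_factor = 100, sample_weight = 0.2)
  expect_equal(r2$load, 2 * r1$load, tolerance = 1e-12)
  expect_error(ct_to_load(cv, 26, dilution_factor = 1, sample_weight = 0),
               "positive")
})

test_that("copies -> Ct -> copies round trip is exact across the range", {
  cv <- fit_standard_curve(3:8, 41 - 3.32 * (3:8))
  copies <- 10^seq(3, 8, length.out = 50)
  ct <- cv$intercept + cv$slope * log10(copies)
  back <- ct_to_load(cv, ct, dilution_factor = 1, sample_weight = 1)
  expect_true(all(abs(back$copies - copies) / copies < 1e-10))
  expect_false(any(back$extrapolated))
  expect_warning(
    out <- ct_to_load(cv, cv$intercept + cv$slope * 9,
                      dilution_factor = 1, sample_weight = 1),
    "calibrated range")
  expect_true(out$extrapolated)
})

test_that("qmp_transform scales proportions by the measured load", {
  mat <- matrix(c(0.5, 0.3, 0.2), 1, dimnames = list("s1", paste0("t", 1:3)))
  ft <- feature_table(mat, data.frame(sample_id = "s1"), mode = "RMP")
  q <- qmp_transform(ft, c(s1 = 1e6))
  expect_equal(unname(q$mat[1, ]), c(5e5, 3e5, 2e5))
  expect_equal(q$mode, "QMP")
  # unit loads leave the numbers unchanged
  q1 <- qmp_transform(ft, c(s1 = 1))
  expect_equal(q1$mat, ft$mat)
  expect_error(qmp_transform(ft, c(other = 1e6)), "s1")
})

test_that("relative and absolute changes can disagree in sign", {
  # a taxon whose share falls while total load rises: its absolute
  # abundance still rises — the compositional discordance QMP resolves
  mat <- rbind(early = c(0.6, 0.4), late = c(0.4, 0.6))
  colnames(mat) <- c("taxA", "taxB")
  ft <- feature_table(mat, data.frame(sample_id = c("early", "late")),
                      mode = "RMP")
  q <- qmp_transform(ft, c(early = 1e5, late = 1e6))
  expect_lt(mat["late", "taxA"], mat["early", "taxA"])      # RA falls
  expect_gt(q$mat["late", "taxA"], q$mat["early", "taxA"])  # AA rises
  expect_equal(unname(q$mat[, "taxA"]), c(6e4, 4e5))
})

test_that("QMP conserves loads and round-trips back to RMP", {
  fx <- default_sim()
  for (dom in names(fx$sim$tables)) {
    l <- fx$sim$loads[fx$sim$loads$domain == dom, ]
    loads <- stats::setNames(l$load, l$sample_id)
    rmp <- to_relative(fx$sim$tables[[dom]])
    q <- qmp_transform(rmp, loads)
    rel_err <- abs(rowSums(q$mat) - loads[rownames(q$mat)]) /
      loads[rownames(q$mat)]
    expect_lt(max(rel_err), 1e-6)
    back <- to_relative(q)
    expect_equal(back$mat, rmp$mat, tolerance = 1e-12)
  }
})

test_that("taxon collapse sums within rank and preserves totals", {
  mat <- matrix(c(3, 7, 2,
                  1, 2, 10), 2, 3, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("asv1", "asv2", "asv3")))
  tax <- c("d__B;p__P1;c__;o__;f__F1;g__GenX",
           "d__B;p__P1;c__;o__;f__F1;g__GenX",
           "d__B;p__P2;c__;o__;f__Nectriaceae;g__")
  ft <- feature_table(mat, data.frame(sample_id = c("s1", "s2")),
                      taxonomy = tax, mode = "counts")
  g <- collapse_taxa(ft, "genus")
  expect_equal(unname(g$mat[, "GenX"]), c(10, 3))
  # genus-less lineage falls back to its deepest named ancestor
  expect_true("f_Nectriaceae" %in% colnames(g$mat))
  expect_equal(rowSums(g$mat), rowSums(ft$mat))
  # collapsing an already-genus-level table changes nothing
  tax_g <- c("g__GenX", "g__GenY")
  ft_g <- feature_table(mat[, 1:2], data.frame(sample_id = c("s1", "s2")),
                        taxonomy = tax_g, mode = "counts")
  g2 <- collapse_taxa(ft_g, "genus")
  expect_equal(unname(g2$mat), unname(ft_g$mat))
})

test_that("optional hooks: copy-number correction, rarefaction, imputation", {
  mat <- matrix(c(40, 10,
                  20, 30), 2, 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("tA", "tB")))
  md <- data.frame(sample_id = c("s1", "s2"), segment = "cecum",
                   dph = c(7, 7))
  ft <- feature_table(mat, md, mode = "counts")
  # tA carries 4 marker copies per cell, tB one: correction rebalances
  q <- qmp_transform(ft, c(s1 = 1e6, s2 = 1e6),
                     copy_number = c(tA = 4, tB = 1))
  expect_equal(unname(q$mat["s1", ]), 1e6 * c(10, 10) / 20)
  expect_error(qmp_transform(ft, c(s1 = 1, s2 = 1),
                             copy_number = c(tA = 4)), "every taxon")
  # rarefaction equalises depth before proportions
  mat2 <- rbind(s1 = c(1000, 1000), s2 = c(39, 1))
  colnames(mat2) <- c("tA", "tB")
  ft2 <- feature_table(mat2, md, mode = "counts")
  q2 <- qmp_transform(ft2, c(s1 = 100, s2 = 100), rarefy = TRUE, seed = 4)
  expect_equal(unname(rowSums(q2$mat)), c(100, 100))
  # a missing load is imputed from the segment x day group only on request
  big <- matrix(5, 4, 2, dimnames = list(paste0("s", 1:4), c("tA", "tB")))
  md4 <- data.frame(sample_id = paste0("s", 1:4), segment = "ileum",
                    dph = 14)
  ft4 <- feature_table(big, md4, mode = "counts")
  loads3 <- c(s1 = 1e4, s2 = 1e6, s3 = 1e5)
  expect_error(qmp_transform(ft4, loads3), "s4")
  expect_message(q4 <- qmp_transform(ft4, loads3, impute_missing = TRUE),
                 "geometric mean")
  expect_equal(unname(rowSums(q4$mat)["s4"]), exp(mean(log(loads3))))
})

test_that("feature_table validates its invariants", {
  mat <- matrix(c(1, -1), 1, 2,
                dimnames = list("s1", c("a", "b")))
  expect_error(feature_table(mat, data.frame(sample_id = "s1")),
               "negative value at sample 's1', taxon 'b'")
  m2 <- matrix(c(0.5, 0.4), 1, 2, dimnames = list("s1", c("a", "b")))
  expect_error(feature_table(m2, data.frame(sample_id = "s1"),
                             mode = "RMP"), "sum to 1")
  m3 <- matrix(c(2, 2), 1, 2, dimnames = list("s1", c("a", "b")))
  expect_error(feature_table(m3, data.frame(sample_id = "s1"),
                             mode = "QMP", loads = c(s1 = 5)),
               "equal loads")
})
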
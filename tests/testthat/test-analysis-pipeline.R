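test_that("median/IQR summaries interpolate between order statistics", {
  s <- summarize_median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(s, list(median = 3, q25 = 2, q75 = 4))
  expect_equal(summarize_median_iqr(5), list(median = 5, q25 = 5, q75 = 5))
  expect_error(summarize_median_iqr(numeric(0)), "no values")
  set.seed(10)
  for (i in 1:10) {
    x <- rnorm(sample(2:40, 1))
    s <- summarize_median_iqr(x)
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    expect_equal(c(s$q25, s$median, s$q75), q)
  }
})

test_that("signed-rank test matches exhaustive sign enumeration", {
  # oracle: enumerate all 2^n sign assignments of |d|
  exact_p <- function(d, alternative) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% r
    switch(alternative,
           greater = mean(v_all >= v_obs),
           less = mean(v_all <= v_obs),
           two_sided = min(1, 2 * min(mean(v_all >= v_obs),
                                      mean(v_all <= v_obs))))
  }
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), alternative = "greater")$p, 0.125)
  expect_equal(exact_p(c(1, 2, 3), "greater"), 0.125)
  set.seed(4)
  for (i in 1:8) {
    d <- rnorm(sample(4:9, 1))  # continuous: no ties, exact path applies
    for (alt in c("greater", "less", "two_sided")) {
      expect_equal(wilcoxon_signed_rank(d, alternative = alt)$p,
                   exact_p(d, alt), tolerance = 1e-12,
                   info = paste("alt =", alt, "n =", length(d)))
    }
  }
})

test_that("signed-rank test drops zero differences and handles degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_warning(out <- wilcoxon_signed_rank(x, x), "zero")
  expect_equal(out$p, 1)
  out <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3), alternative = "greater")
  expect_equal(out$n, 3)
  expect_equal(out$p, 0.125)
})

test_that("paired t-test matches the closed-form statistic", {
  out <- paired_t_test(c(2, 1), c(1, 2))
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  set.seed(5)
  x <- rnorm(12)
  y <- rnorm(12)
  out <- paired_t_test(x, y, alternative = "less")
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(out$t, t_oracle)
  expect_equal(out$p, pt(t_oracle, length(d) - 1))
  # shift invariance
  out2 <- paired_t_test(x + 5, y + 5, alternative = "less")
  expect_equal(out2$t, out$t)
  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
})

test_that("normality test is calibrated on its own null and bounded", {
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 5")
  set.seed(6)
  rejections <- 0
  for (i in 1:200) {
    out <- ks_normality(rnorm(100, 3, 0.6))
    expect_gte(out$D, 0)
    expect_lte(out$D, 1)
    if (out$p < 0.01) rejections <- rejections + 1
  }
  # size of the test near its nominal 1% level
  expect_lte(rejections, 8)
})

test_that("a reduced experiment grid is complete, flagged and deterministic", {
  res <- .reduced_grid_results()
  radii <- c(2, 3, 4)
  fracs <- c("-50/-50", "-60/-40", "-70/-30", "-80/-20", "-90/-10")
  # 5 fractionalizations x 2 paradigms + ring(micc+coactivation) + single
  per_radius_min <- 5 * 2 + 3
  expect_gte(nrow(res), per_radius_min * length(radii))
  for (p in c("micc", "interleaving")) {
    for (f in fracs) {
      expect_equal(sum(res$paradigm == p & res$setting == f), length(radii))
    }
  }
  # absent-VTA cells are flagged, not dropped
  il <- res[res$paradigm == "interleaving", ]
  expect_false(any(is.na(il$vta2_absent)))
  expect_true(all(is.na(il$intersection_volume_mm3[il$vta2_absent])))
  # deterministic rerun of a one-cell grid
  cfg <- grid_config(target_radii = 3,
                     fractionalizations = standard_distributions()["-70/-30"],
                     include_ring = FALSE, include_single = FALSE,
                     model = test_model())
  expect_identical(as.data.frame(run_grid(cfg)), as.data.frame(run_grid(cfg)))
})

test_that("report tables render medians, IQRs and absent-cell sentinels", {
  res <- .reduced_grid_results()
  dir <- withr::local_tempdir()
  paths <- report_tables(res, dir)
  expect_true(all(file.exists(file.path(
    dir, c("grid_results.csv", "table_deviation.csv", "table_overlap.csv",
           "table_volume.csv", "table_amplitude.csv", "table_current.csv")))))
  dev <- read.csv(file.path(dir, "table_deviation.csv"), check.names = FALSE)
  expect_equal(nrow(dev), 2)
  expect_equal(ncol(dev), 6)  # paradigm + 5 fractionalizations
  expect_match(dev[1, "-60/-40"], "^[0-9.]+ \\([0-9.]+-[0-9.]+\\)$")
  ov <- read.csv(file.path(dir, "table_overlap.csv"), check.names = FALSE)
  # -90/-10 never forms VTA 2 at small radii; intersection cells may be absent
  expect_true(all(ov[3, -1] != "" | ov[3, -1] == "---"))
  cur <- read.csv(file.path(dir, "table_current.csv"), check.names = FALSE)
  expect_false("intersection" %in% cur$setting)
})
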
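test_that("default dataset has the configured record and group structure", {
  ds <- generate_impedance_dataset(seed = 7)
  expect_equal(nrow(ds), 980)
  sizes <- table(paste(ds$lead, ds$level, ds$visit))
  expect_equal(sum(sizes == 3), 326)
  expect_equal(sum(sizes == 2), 1)
  expect_true(all(ds$impedance_kohm > 0.3))
  expect_true(all(ds$electrode %in% 1:3))
  expect_true(all(ds$visit %in% 1:7))
  expect_equal(length(unique(ds$subject)), 12)
  expect_equal(length(unique(ds$lead)), 24)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_impedance_dataset(seed = 42)
  b <- generate_impedance_dataset(seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_impedance_dataset(seed = 43)
  expect_false(identical(a$impedance_kohm, c$impedance_kohm))
})

test_that("sample mean lies within the config-derived standard-error bound", {
  cfg <- impedance_config()
  ds <- generate_impedance_dataset(cfg, seed = 7)
  # AR(1) visit correlation inflates the variance of the grand mean over
  # independent sampling: per 7-visit series, sum_{j,k} rho^|j-k| / 7
  rho <- cfg$visit_correlation
  v <- cfg$n_visits
  inflation <- sum(rho^abs(outer(1:v, 1:v, "-"))) / v
  se <- cfg$sd_kohm * sqrt(inflation / nrow(ds))
  expect_lt(abs(mean(ds$impedance_kohm) - cfg$mean_kohm), 3 * se)
})

test_that("infeasible missingness is rejected", {
  expect_error(impedance_config(complete_groups = 400), "infeasible")
})

test_that("dataset round-trips through CSV", {
  ds <- generate_impedance_dataset(seed = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_impedance_csv(ds, p)
  back <- read_impedance_csv(p)
  write_impedance_csv(back, p2)
  expect_identical(readLines(p), readLines(p2))  # CSV -> dataset -> CSV
  strip <- function(d) data.frame(unclass(d)[names(ds)])
  expect_equal(strip(ds), strip(back), tolerance = 1e-12)
})

test_that("pair and ring permutation counts match the counting identities", {
  ds <- generate_impedance_dataset(seed = 7)
  pairs <- enumerate_pair_permutations(ds)
  rings <- enumerate_ring_permutations(ds)
  expect_equal(nrow(pairs), 1958)
  expect_equal(nrow(rings), 978)
  # identities against exhaustive group enumeration
  sizes <- table(paste(ds$lead, ds$level, ds$visit))
  expect_equal(nrow(pairs), sum(sizes * (sizes - 1)))
  expect_equal(nrow(rings), 3 * sum(sizes == 3))
  # one complete group contributes 6 ordered pairs, a 2-electrode group 2
  g1 <- ds[paste(ds$lead, ds$level, ds$visit) == names(sizes)[sizes == 3][1], ]
  expect_equal(nrow(enumerate_pair_permutations(g1)), 6)
  expect_equal(nrow(enumerate_ring_permutations(g1)), 3)
  g2 <- g1[1:2, ]
  expect_equal(nrow(enumerate_pair_permutations(g2)), 2)
  expect_equal(nrow(enumerate_ring_permutations(g2)), 0)
  # empty dataset contributes nothing
  empty <- ds[0, ]
  expect_equal(nrow(enumerate_pair_permutations(empty)), 0)
  expect_equal(nrow(enumerate_ring_permutations(empty)), 0)
})

test_that("clinical-scenario currents honour the energy-model orderings", {
  ds <- generate_impedance_dataset(seed = 7)
  settings <- data.frame(
    setting = c("ring", "-50/-50", "-70/-30"),
    target_radius = 3,
    total_amplitude = c(2.8, 2.0, 1.9),
    f_primary = c(34, 50, 70),
    f_secondary = c(33, 50, 30),
    f_tertiary = c(33, 0, 0)
  )
  out <- clinical_scenario_currents(ds, settings)
  # MICC mean below interleaving mean in every two-electrode setting
  for (s in c("-50/-50", "-70/-30")) {
    m <- out$mean_uA[out$setting == s & out$paradigm == "micc"]
    i <- out$mean_uA[out$setting == s & out$paradigm == "interleaving"]
    expect_lt(m, i)
  }
  # coactivation at or below MICC for uniform settings, per permutation
  set.seed(1)
  pairs <- enumerate_pair_permutations(ds)
  a <- 2.0 * c(0.5, 0.5)
  for (k in sample(nrow(pairs), 50)) {
    z <- c(pairs$z_a[k], pairs$z_b[k])
    expect_lte(current_draw_coactivation(2.0, z),
               current_draw_micc(a, z) + 1e-9)
  }
  # permutation counts flow through
  expect_equal(out$n[out$setting == "ring" & out$paradigm == "micc"], 978)
  expect_equal(out$n[out$setting == "-50/-50" & out$paradigm == "micc"], 1958)
  # equal-impedance degenerate dataset reproduces the deterministic value
  ds3 <- ds
  ds3$impedance_kohm <- 3
  out3 <- clinical_scenario_currents(ds3, settings)
  ring3 <- out3[out3$setting == "ring" & out3$paradigm == "micc", ]
  expect_equal(ring3$sd_uA, 0)
  expect_equal(ring3$mean_uA,
               current_draw_micc(2.8 * c(0.34, 0.33, 0.33), rep(3, 3)))
})
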
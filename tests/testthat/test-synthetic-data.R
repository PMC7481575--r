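test_that("simulated genotype panels have the requested shape and missingness", {
  cfg <- sim_config(487, 6122, list(env_spec("E1")), seed = 11,
                    marker_missing_rate = 0.1)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g), c(487L, 6122L))
  expect_true(abs(mean(is.na(g)) - 0.1) < 0.01)
  expect_true(all(unclass(g) %in% c(0L, 1L, 2L) | is.na(g)))

  g0 <- simulate_genotypes(sim_config(50, 100, list(env_spec("E1")),
                                      marker_missing_rate = 0, seed = 2))
  expect_false(anyNA(g0))
})

test_that("empirical allele frequencies respect a tight MAF range", {
  cfg <- sim_config(2000, 200, list(env_spec("E1")),
                    maf_range = c(0.3, 0.3), het_rate = 0.05,
                    marker_missing_rate = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  freq <- colMeans(unclass(g)) / 2
  maf <- pmin(freq, 1 - freq)
  expect_true(all(abs(maf - 0.3) < 0.05))
})

test_that("invalid simulation configurations are rejected", {
  e1 <- list(env_spec("E1"))
  expect_error(sim_config(1, 100, e1), "n_lines")
  expect_error(sim_config(10, 100, e1, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(10, 100, e1, maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(env_spec("E1", h2_plot = 1), "h2_plot")
  expect_error(env_spec("E1", h2_plot = 0), "h2_plot")
})

test_that("breeding values realize the target genetic correlation structure", {
  cfg <- sim_config(1000, 2000, list(env_spec("A"), env_spec("B")), seed = 3,
                    marker_missing_rate = 0)
  g <- simulate_genotypes(cfg)
  # independence case
  tr_id <- simulate_breeding_values(g, diag(2), c(0.1, 0.1), seed = 4)
  r_id <- cor(tr_id$breeding_values[, 1], tr_id$breeding_values[, 2])
  expect_lt(abs(r_id), 3 / sqrt(1000))
  # correlated case: Fisher-z interval at n = 1000 is well inside [0.5, 0.7]
  gc <- matrix(c(1, 0.6, 0.6, 1), 2)
  tr <- simulate_breeding_values(g, gc, c(0.1, 0.1), seed = 4)
  r <- cor(tr$breeding_values[, 1], tr$breeding_values[, 2])
  expect_gt(r, 0.5)
  expect_lt(r, 0.7)
})

test_that("single-environment breeding-value variance matches sigma_g2", {
  # Monte-Carlo over 20 effect draws on one genotype panel
  cfg <- sim_config(1000, 5000, list(env_spec("A")), seed = 9,
                    marker_missing_rate = 0)
  g <- simulate_genotypes(cfg)
  vars <- vapply(1:20, function(s) {
    tr <- simulate_breeding_values(g, matrix(1), 0.2, seed = s)
    var(tr$breeding_values[, 1])
  }, 0)
  expect_lt(abs(mean(vars) - 0.2) / 0.2, 0.15)
})

test_that("non-PSD genetic correlation matrices are rejected by eigenvalue", {
  cfg <- sim_config(50, 100, list(env_spec("A"), env_spec("B")), seed = 1)
  g <- simulate_genotypes(cfg)
  bad <- matrix(c(1, 0.8, 0.9, 1), 2)         # asymmetric
  expect_error(simulate_breeding_values(g, bad, c(0.1, 0.1)), "symmetric")
  bad2 <- matrix(c(1, 1.2, 1.2, 1), 2)        # indefinite
  expect_error(simulate_breeding_values(g, bad2, c(0.1, 0.1)),
               "eigenvalue")
})

test_that("noise-free trials return environment mean plus breeding value", {
  cfg <- sim_config(40, 120, list(env_spec("E1", 5, h2_plot = 1 - 1e-9)),
                    seed = 6, marker_missing_rate = 0,
                    block_effect_sd = 0, rep_effect_sd = 0,
                    trial_effect_sd = 0)
  met <- simulate_met(cfg)
  expected <- 5 + met$truth$breeding_values[met$records$line, 1]
  expect_equal(met$records$yield, unname(expected), tolerance = 1e-4)
})

test_that("record counts and replication match the design", {
  cfg <- sim_config(60, 80, list(env_spec("A"), env_spec("B")), seed = 8,
                    n_reps = 2)
  met <- simulate_met(cfg)
  expect_equal(nrow(met$records), 60 * 2 * 2)
  per <- table(met$records$line, met$records$env)
  expect_true(all(per == 2))
  expect_error(
    simulate_trial(met$truth, sim_config(60, 80,
                                         list(env_spec("A"), env_spec("B")),
                                         seed = 8, n_blocks_per_rep = 100)),
    "n_blocks_per_rep")
})

test_that("plot-error variance is set from the per-plot heritability", {
  # h2_plot = 0.5, sigma_g2 = 0.2  =>  plot error variance 0.2
  vhat <- vapply(1:10, function(s) {
    cfg <- sim_config(250, 60, list(env_spec("E1", 5, 0.5, sigma_g2 = 0.2)),
                      seed = s, marker_missing_rate = 0,
                      block_effect_sd = 0, rep_effect_sd = 0,
                      trial_effect_sd = 0)
    met <- simulate_met(cfg)
    resid <- met$records$yield - 5 -
      met$truth$breeding_values[met$records$line, 1]
    var(resid)
  }, 0)
  expect_lt(abs(mean(vhat) - 0.2) / 0.2, 0.10)
})

test_that("a fixed seed reproduces records byte-identically", {
  cfg <- sim_config(30, 60, list(env_spec("A")), seed = 42,
                    marker_missing_rate = 0.05)
  m1 <- simulate_met(cfg)
  m2 <- simulate_met(cfg)
  expect_identical(m1$records, m2$records)
  expect_identical(unclass(m1$genotypes), unclass(m2$genotypes))
})

test_that("noisy simulations yield lower heritability estimates than clean ones", {
  for (s in 1:3) {
    lo <- sim_single(s, n = 150, m = 500, h2_plot = 0.1)
    hi <- sim_single(s, n = 150, m = 500, h2_plot = 0.8)
    h_lo <- estimate_h2(lo$met$records, lo$G, n_reps = 2)$h2
    h_hi <- estimate_h2(hi$met$records, hi$G, n_reps = 2)$h2
    expect_lt(h_lo, h_hi)
  }
})
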
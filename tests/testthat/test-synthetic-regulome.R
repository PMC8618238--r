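test_that("deterministic assignment gives exact category counts and balanced signs", {
  cfg <- generator_config(frac_single = 0.30, frac_double = 0.10,
                          frac_triple = 0.05)
  tr <- generate_truth(1000, cfg, seed = 3)
  n_tf <- rowSums(cbind(tr$effect_daf16, tr$effect_skn1, tr$effect_hsf1) != 0)
  expect_equal(sum(n_tf == 1), 300)
  expect_equal(sum(n_tf == 2), 100)
  expect_equal(sum(n_tf == 3), 50)
  # 1:1 activator:repressor balance per TF, within 1 for odd totals
  for (eff in list(tr$effect_daf16, tr$effect_skn1, tr$effect_hsf1)) {
    expect_lte(abs(sum(eff > 0) - sum(eff < 0)), 1)
  }
  expect_true(all(is.finite(tr$baseline_log2)))
  expect_true(all(tr$dispersion >= 0))
  expect_true(all(tr$length_bp >= 1))
})

test_that("stochastic assignment hits the configured fraction in distribution", {
  cfg <- generator_config(frac_single = 0.30, frac_double = 0,
                          frac_triple = 0, assignment = "stochastic")
  tr <- generate_truth(1000, cfg, seed = 11)
  n_single <- sum(rowSums(cbind(tr$effect_daf16, tr$effect_skn1,
                                tr$effect_hsf1) != 0) == 1)
  # central 99.9% binomial(1000, 0.3) interval
  lo <- qbinom(0.0005, 1000, 0.3)
  hi <- qbinom(0.9995, 1000, 0.3)
  expect_gte(n_single, lo)
  expect_lte(n_single, hi)
})

test_that("invalid generator fractions are rejected", {
  expect_error(generator_config(frac_single = -0.1), "non-negative")
  expect_error(generator_config(frac_single = 0.6, frac_double = 0.5),
               "sum")
})

test_that("same seed and config reproduce truth and counts bit-identically", {
  cfg <- generator_config()
  t1 <- generate_truth(300, cfg, seed = 5)
  t2 <- generate_truth(300, cfg, seed = 5)
  expect_identical(t1, t2)
  des <- default_design()
  s1 <- simulate_counts(t1, des, seed = 9)
  s2 <- simulate_counts(t2, des, seed = 9)
  expect_identical(s1$counts$counts, s2$counts$counts)
  s3 <- simulate_counts(t1, des, seed = 10)
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("expected counts follow the log-linear model", {
  tr <- generate_truth(4, generator_config(frac_single = 0, frac_double = 0,
                                           frac_triple = 0,
                                           frac_riis_direct = 0), seed = 1)
  tr$effect_daf16 <- c(2, 0, 0, 0)
  des <- default_design()
  mu <- expected_mu(tr, des, rule = "additive")
  # effect_daf16 = +2, activity 1 in rIIS-C vs residual 0.1 in daf16i
  r <- mu[1, "rIIS-C_r1"] / mu[1, "rIIS-daf16i_r1"]
  expect_equal(r, 2^(2 - 0.2))
  # with full knockdown (residual 0) the ratio is exactly 4
  des0 <- default_design(residual_knockdown = 0)
  mu0 <- expected_mu(tr, des0, rule = "additive")
  expect_equal(mu0[1, "rIIS-C_r1"] / mu0[1, "rIIS-daf16i_r1"], 4)
  # untargeted genes identical across rIIS groups
  expect_equal(mu[2, "rIIS-C_r1"], mu[2, "rIIS-skn1i_r1"])
})

test_that("Poisson limit recovers per-gene means", {
  cfg <- generator_config(frac_single = 0, frac_double = 0, frac_triple = 0,
                          frac_riis_direct = 0, dispersion = 0,
                          baseline_log2_sd = 1)
  tr <- generate_truth(200, cfg, seed = 21)
  des <- default_design(replicates = 4)
  sim <- simulate_counts(tr, des, seed = 21)
  mu <- 2^tr$baseline_log2
  ns <- ncol(sim$counts$counts)
  mc_se <- sqrt(mu / ns)  # Poisson variance = mean
  dev <- abs(rowMeans(sim$counts$counts) - mu)
  expect_true(all(dev <= 5 * mc_se))
})

test_that("negative-binomial draws match the mean-dispersion variance law", {
  tr <- data.frame(gene_id = "g1", baseline_log2 = log2(100),
                   effect_daf16 = 0, effect_skn1 = 0, effect_hsf1 = 0,
                   riis_direct_log2 = 0, dispersion = 0.05, length_bp = 1000,
                   stringsAsFactors = FALSE)
  # 12000 replicate draws of one gene via a one-group design
  des <- default_design(replicates = 12000)[1:12000, ]
  sim <- simulate_counts(tr, des, seed = 8)
  x <- as.numeric(sim$counts$counts[1, ])
  v_expected <- 100 + 0.05 * 100^2
  expect_lt(abs(var(x) - v_expected) / v_expected, 0.10)
})

test_that("daf16_dominant clipping lets DAF-16 set the sign", {
  tr <- data.frame(gene_id = "g1", baseline_log2 = 10,
                   effect_daf16 = 1, effect_skn1 = -3, effect_hsf1 = -3,
                   riis_direct_log2 = 0, dispersion = 0.05, length_bp = 1000,
                   stringsAsFactors = FALSE)
  des <- default_design()
  des$a_hsf1[des$group == "rIIS-C"] <- 1  # all activities 1
  mu_dom <- expected_mu(tr, des, rule = "daf16_dominant")
  total_effect <- log2(mu_dom[1, "rIIS-C_r1"]) - 10
  expect_gt(total_effect, 0)
  # additive rule would be negative
  mu_add <- expected_mu(tr, des, rule = "additive")
  expect_lt(log2(mu_add[1, "rIIS-C_r1"]) - 10, 0)
})

test_that("under daf16_dominant every DAF-16 target's rIIS direction matches its sign", {
  tr <- generate_truth(2000, generator_config(), seed = 13)
  des <- default_design()
  mu <- expected_mu(tr, des, rule = "daf16_dominant")
  g_c <- des$sample_id[des$group == "C"][1]
  g_r <- des$sample_id[des$group == "rIIS-C"][1]
  tgt <- tr$effect_daf16 != 0
  riis_dir <- sign(log2(mu[tgt, g_r] / mu[tgt, g_c]) -
                     tr$riis_direct_log2[tgt])
  expect_true(all(riis_dir == sign(tr$effect_daf16[tgt])))
})

test_that("unknown combination rule and bad designs error", {
  tr <- generate_truth(10, generator_config(), seed = 1)
  expect_error(simulate_counts(tr, default_design(), "nonsense"),
               "arg")
  bad <- default_design()
  bad$library_size <- 0
  expect_error(simulate_counts(tr, bad), "library_size")
})
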
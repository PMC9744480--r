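test_that("simulated genotype frequencies concentrate at HWE proportions", {
  n <- 1e5
  sites <- simulate_genotypes(n, 0.5, seed = 51)
  g <- sites$g[[1]]
  het <- mean(g == 1L)
  # binomial 3-sigma band around 2p(1-p) = 0.5
  expect_lt(abs(het - 0.5), 3 * sqrt(0.5 * 0.5 / n))
  for (p in c(0.1, 0.3)) {
    s <- simulate_genotypes(n, p, seed = 52)
    g <- s$g[[1]]
    probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- c(mean(g == 0L), mean(g == 1L), mean(g == 2L))
    expect_true(all(abs(obs - probs) < 3 * sqrt(probs * (1 - probs) / n) + 1e-12))
  }
})

test_that("genotype simulation is deterministic given its seed", {
  a <- simulate_genotypes(200, c(0.05, 0.2, 0.4), seed = 53)
  b <- simulate_genotypes(200, c(0.05, 0.2, 0.4), seed = 53)
  expect_identical(a$g, b$g)
  expect_error(simulate_genotypes(10, c(0.5, 1.2)), "strictly in")
  expect_error(simulate_genotypes(10, 0), "strictly in")
})

test_that("monomorphic policies drop or redraw as asked", {
  local_quiet()
  # an extremely rare allele at tiny n: usually monomorphic
  dropped <- simulate_genotypes(10, 1e-4, seed = 54, monomorphic = "drop")
  expect_s3_class(dropped, "gvd_sites")
  expect_true(nrow(dropped) %in% c(0L, 1L))  # empty list is allowed, no error
  redrawn <- simulate_genotypes(50, 0.02, seed = 55, monomorphic = "redraw")
  expect_identical(nrow(redrawn), 1L)
  expect_false(is_monomorphic(redrawn))
})

test_that("carrier-shift phenotype has the promised structure", {
  # null model: pure noise
  sites <- simulate_genotypes(500, 0.2, seed = 56)
  y0 <- simulate_phenotype(sites, carrier_effect = 0, noise_sd = 1, seed = 57)
  y0b <- withr::with_seed(57, rnorm(500, 0, 1))
  expect_equal(y0, y0b)

  # noiseless limit: exactly two trait values split by carrier status
  yn <- simulate_phenotype(sites, carrier_effect = -1, noise_sd = 0, seed = 58)
  expect_identical(sort(unique(yn)), c(-1, 0))
  carriers <- sites$g[[1]] > 0
  expect_identical(yn == -1, carriers)

  # heterozygotes and 1/1 homozygotes are shifted equally
  big <- simulate_genotypes(1e5, 0.3, seed = 59)
  y <- simulate_phenotype(big, carrier_effect = -1, noise_sd = 1, seed = 60)
  carriers <- big$g[[1]] > 0
  diff <- mean(y[carriers]) - mean(y[!carriers])
  se <- sqrt(1 / sum(carriers) + 1 / sum(!carriers))
  expect_lt(abs(diff - (-1)), 3 * se)

  expect_error(simulate_phenotype(sites[0, ]), "at least one causal site")
})

test_that("additive effect model counts causal sites carried", {
  calls <- cbind(c("0/1", "0/0", "1/1"), c("0/1", "0/0", "0/0"))
  sites <- genotype_sites(calls)
  y <- simulate_phenotype(sites, carrier_effect = -1, noise_sd = 0,
                          effect_model = "additive")
  expect_equal(y, c(-2, 0, -1))
  yc <- simulate_phenotype(sites, carrier_effect = -1, noise_sd = 0,
                           effect_model = "carrier")
  expect_equal(yc, c(-1, 0, -1))
})

test_that("power_experiment is reproducible and respects degenerate alpha", {
  local_quiet()
  a <- power_experiment(n = 120, freqs = c(0.1, 0.2), replicates = 4, B = 49,
                        alpha = 0.2, master_seed = 61)
  b <- power_experiment(n = 120, freqs = c(0.1, 0.2), replicates = 4, B = 49,
                        alpha = 0.2, master_seed = 61)
  expect_identical(a$p_values, b$p_values)
  expect_identical(a$rejections, b$rejections)
  always <- power_experiment(n = 60, freqs = 0.2, replicates = 3, B = 19,
                             alpha = 1, master_seed = 62)
  expect_identical(always$rejections, always$replicates)
  expect_true(all(glance(always)$rate == 1))
})

test_that("power increases with the carrier effect size on a fixed panel", {
  local_quiet()
  rates <- vapply(c(0, -1.5), function(eff) {
    pw <- power_experiment(n = 300, freqs = c(0.05, 0.1), carrier_effect = eff,
                           noise_sd = 1, replicates = 20, B = 199,
                           alpha = 0.05, master_seed = 63)
    pw$rejections / pw$replicates
  }, numeric(1))
  expect_gt(rates[2], rates[1])
})
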
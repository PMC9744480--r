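test_that("q_statistic matches hand-derived two-individual cases", {
  y <- center_phenotype(c(1, -1))
  # oracle y' X y with g = (1, 0), mu = 0.5 gives 1
  expect_equal(q_statistic(y, genotype_site(c("0/1", "0/0"))), 1)
  # oracle with g = (2, 0), mu = 1 gives 4
  expect_equal(q_statistic(y, genotype_site(c("1/1", "0/0"))), 4)
  y0 <- center_phenotype(c(0, 0, 0))
  expect_equal(q_statistic(y0, genotype_site(c("0/1", "1/1", "0/0"))), 0)
})

test_that("r_statistic matches hand-derived two-individual cases", {
  y <- center_phenotype(c(1, -1))
  # oracle y' IBS y with IBS = [[2,1],[1,2]] gives 2
  expect_equal(r_statistic(y, genotype_site(c("0/1", "0/0"))), 2)
  # IBS = [[2,0],[0,2]] gives 4
  expect_equal(r_statistic(y, genotype_site(c("1/1", "0/0"))), 4)
  y0 <- center_phenotype(c(0, 0, 0))
  expect_equal(r_statistic(y0, genotype_site(c("0/1", "1/1", "0/0"))), 0)
})

test_that("statistics validate their inputs", {
  y <- center_phenotype(c(1, -1, 0))
  s <- genotype_site(c("0/1", "0/0"))
  expect_error(q_statistic(y, s), "sample size")
  expect_error(r_statistic(y, s), "sample size")
  raw <- c(1, 2, 5)  # not centered
  expect_error(q_statistic(raw, genotype_site(c("0/1", "0/0", "1/1"))),
               "not centered")
})

test_that("weight schemes resolve as documented", {
  sites <- random_sites(10, l = 3L)
  expect_equal(resolve_weights(sites, weight_scheme("uniform")), rep(1, 3))
  expect_equal(resolve_weights(sites, "uniform"), rep(1, 3))
  expect_equal(
    resolve_weights(sites, weight_scheme("custom", weights = c(0.5, 2, 0))),
    c(0.5, 2, 0)
  )
  # Beta(1,1) density is 1 everywhere on (0,1)
  expect_equal(
    resolve_weights(sites, weight_scheme("beta", shape1 = 1, shape2 = 1)),
    rep(1, 3)
  )
  # Beta(1,25) at the site MAFs, the conventional rare-variant weighting
  maf <- pmin(sites$p, 1 - sites$p)
  expect_equal(
    resolve_weights(sites, weight_scheme("beta", shape1 = 1, shape2 = 25)),
    dbeta(maf, 1, 25)
  )
  expect_error(weight_scheme("custom", weights = c(1, -1)), "nonnegative")
  expect_error(
    resolve_weights(sites, weight_scheme("custom", weights = c(1, 2))),
    "2 weights for 3 sites"
  )
})

test_that("kernel_statistic is the weighted sum of per-site statistics", {
  y <- center_phenotype(c(1, -1))
  s1 <- genotype_site(c("0/1", "0/0"))
  sites <- genotype_sites(cbind(c("0/1", "0/0"), c("1/1", "0/0")))

  one <- kernel_statistic(y, s1, kernel = "GRM")
  expect_equal(one$S, q_statistic(y, s1))

  both <- kernel_statistic(y, sites, kernel = "GRM")
  expect_equal(both$S, 5)  # 1 + 4 from the per-site cases

  twice <- kernel_statistic(y, dplyr::bind_rows(s1, s1), kernel = "GRM")
  expect_equal(twice$S, 2 * q_statistic(y, s1))

  wtd <- kernel_statistic(y, sites, kernel = "IBS",
                          weights = weight_scheme("custom", weights = c(0.5, 2)))
  expect_equal(wtd$S, 0.5 * 2 + 2 * 4)
  expect_equal(wtd$S, sum(wtd$per_site$weight * wtd$per_site$statistic))

  expect_error(kernel_statistic(y, s1[0, ], kernel = "GRM"), "at least one site")
})

test_that("tidy and glance expose the per-site and summary views", {
  y <- center_phenotype(c(1, -1, 2, -2))
  sites <- random_sites(4, l = 3L)
  ks <- kernel_statistic(y, sites, kernel = "IBS")
  td <- tidy(ks)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 3L)
  expect_true(all(c("chrom", "pos", "statistic", "weight", "contribution")
                  %in% names(td)))
  gl <- glance(ks)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$S, ks$S)
})

test_that("O(n) statistics equal the brute-force matrix oracle", {
  # the central equivalence: y'Xy = y'Gy = (y'b + 2y'c)^2 and
  # y'IBSy = 2(y'a)^2 + 2(y'c)^2, checked on random instances
  set.seed(101)
  for (trial in 1:200) {
    n <- sample(2:50, 1)
    sites <- random_sites(n, l = sample(1:4, 1))
    y <- random_y(n)
    qf <- q_statistic(y, sites)
    rf <- r_statistic(y, sites)
    for (k in seq_len(nrow(sites))) {
      qo <- quadratic_form(y, grm_matrix(sites[k, ]))
      go <- quadratic_form(y, g_matrix(sites[k, ]))
      ro <- quadratic_form(y, ibs_matrix(sites[k, ]))
      expect_lt(abs(qf[k] - qo) / max(abs(qo), abs(qf[k]), 1), 1e-9)
      expect_lt(abs(qf[k] - go) / max(abs(go), abs(qf[k]), 1), 1e-9)
      expect_lt(abs(rf[k] - ro) / max(abs(ro), abs(rf[k]), 1), 1e-9)
    }
  }
})

test_that("statistics obey the quadratic scale law", {
  set.seed(5)
  for (trial in 1:20) {
    n <- sample(3:30, 1)
    sites <- random_sites(n, l = 2L)
    y <- random_y(n)
    lambda <- runif(1, -3, 3)
    expect_equal(q_statistic(lambda * y, sites), lambda^2 * q_statistic(y, sites),
                 tolerance = 1e-12)
    expect_equal(r_statistic(lambda * y, sites), lambda^2 * r_statistic(y, sites),
                 tolerance = 1e-12)
  }
})

test_that("rare-variant identity: R equals 2Q exactly when no 1/1 present", {
  set.seed(6)
  for (trial in 1:500) {
    n <- sample(2:40, 1)
    calls <- sample(c("0/0", "0/1"), n, replace = TRUE)
    s <- genotype_site(calls)
    y <- random_y(n)
    q <- q_statistic(y, s)
    r <- r_statistic(y, s)
    expect_lt(abs(r - 2 * q) / max(abs(r), 1e-300), 1e-12)
  }
})

test_that("permuting phenotype and genotypes together leaves statistics unchanged", {
  set.seed(8)
  for (trial in 1:20) {
    n <- sample(3:40, 1)
    calls <- matrix(sample(c("0/0", "0/1", "1/1"), n * 3, replace = TRUE), n)
    sites <- genotype_sites(calls)
    y <- random_y(n)
    perm <- sample.int(n)
    sites_p <- genotype_sites(calls[perm, , drop = FALSE])
    expect_equal(q_statistic(y[perm], sites_p), q_statistic(y, sites))
    expect_equal(r_statistic(y[perm], sites_p), r_statistic(y, sites))
    expect_equal(kernel_statistic(y[perm], sites_p, "IBS")$S,
                 kernel_statistic(y, sites, "IBS")$S)
  }
})

test_that("monomorphic sites contribute exactly zero", {
  y <- random_y(12)
  ref <- genotype_site(rep("0/0", 12))
  alt <- genotype_site(rep("1/1", 12))
  het <- genotype_site(rep("0/1", 12))
  expect_identical(q_statistic(y, ref), 0)
  expect_identical(q_statistic(y, alt)[1] == 0 ||
                     q_statistic(y, alt)[1] < 1e-25, TRUE)
  expect_identical(r_statistic(y, ref), 0)
  # all-heterozygote sites are monomorphic in neither allele but still inert
  expect_lt(q_statistic(y, het), 1e-25)
  expect_lt(r_statistic(y, het), 1e-25)
})
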
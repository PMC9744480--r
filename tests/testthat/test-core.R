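test_that("center_phenotype subtracts the mean and validates input", {
  expect_equal(as.numeric(center_phenotype(c(1, 3))), c(-1, 1))
  expect_equal(as.numeric(center_phenotype(c(0, 0, 0))), c(0, 0, 0))
  expect_equal(as.numeric(center_phenotype(c(5, 7, 9))), c(-2, 0, 2))

  set.seed(11)
  for (n in c(2, 5, 97)) {
    y <- center_phenotype(rnorm(n, mean = 50, sd = 9))
    expect_lt(abs(mean(y)), 1e-12)
  }

  expect_error(center_phenotype(c(1)), "at least 2")
  expect_error(center_phenotype(c(1, NA)), "non-finite")
  expect_error(center_phenotype(c(1, Inf)), "non-finite")
  expect_error(center_phenotype(letters[1:3]), "numeric")
})

test_that("genotype_value maps calls to alternative-allele counts", {
  expect_identical(genotype_value(c("0/0", "0/1", "1/1")), c(0L, 1L, 2L))
  # phase and separator do not matter
  expect_identical(genotype_value(c("1/0", "0|1", "1|0", "0|0", "1|1")),
                   c(1L, 1L, 1L, 0L, 2L))
  expect_error(genotype_value("./."), "invalid")
  expect_error(genotype_value("0/2"), "invalid")
  expect_error(genotype_value("2/2"), "invalid")
})

test_that("genotype_site builds consistent indicator vectors", {
  s <- genotype_site(c("0/0", "0/1", "1/1"), chrom = "11", pos = 64360996,
                     rsid = "rs552232030")
  expect_identical(s$a[[1]], c(1L, 0L, 0L))
  expect_identical(s$b[[1]], c(0L, 1L, 0L))
  expect_identical(s$c[[1]], c(0L, 0L, 1L))
  expect_identical(s$g[[1]], c(0L, 1L, 2L))
  expect_equal(s$p, 0.5)
  expect_equal(s$mu, 1)

  s2 <- genotype_site(c("0/1", "0/1", "0/0", "0/0"))
  expect_equal(s2$p, 0.25)
  expect_equal(s2$mu, 0.5)

  mono <- genotype_site(c("0/0", "0/0"))
  expect_identical(mono$g[[1]], c(0L, 0L))
  expect_equal(mono$p, 0)
})

test_that("genotype sites satisfy the indicator invariants on random panels", {
  set.seed(42)
  for (trial in 1:25) {
    n <- sample(2:40, 1)
    s <- random_sites(n, l = 3L)
    for (k in seq_len(nrow(s))) {
      a <- s$a[[k]]; b <- s$b[[k]]; c <- s$c[[k]]; g <- s$g[[k]]
      expect_identical(a + b + c, rep(1L, n))          # partition of individuals
      expect_identical(g, b + 2L * c)                  # genotype value identity
      expect_equal(sum(g), 2 * n * s$p[k])             # allele count vs frequency
      expect_equal(s$mu[k], 2 * s$p[k])
      expect_equal(s$mu[k], sum(g) / n)
    }
  }
})

test_that("calls -> site -> calls round trip is exact", {
  set.seed(7)
  for (trial in 1:20) {
    n <- sample(2:30, 1)
    calls <- sample(c("0/0", "0/1", "1/1"), n, replace = TRUE)
    s <- genotype_site(calls)
    expect_identical(site_calls(s), calls)
    s2 <- genotype_site(site_calls(s))
    expect_identical(s2$a, s$a)
    expect_identical(s2$b, s$b)
    expect_identical(s2$c, s$c)
    expect_identical(s2$g, s$g)
  }
})

test_that("is_monomorphic flags p == 0 and p == 1 only", {
  s <- dplyr::bind_rows(
    genotype_site(c("0/0", "0/0", "0/0")),
    genotype_site(c("1/1", "1/1")),
    genotype_site(c("0/0", "0/1"))
  )
  class(s) <- c("gvd_sites", setdiff(class(s), "gvd_sites"))
  expect_identical(is_monomorphic(s), c(TRUE, TRUE, FALSE))
})

test_that("missing-call policies behave as documented", {
  calls <- c("0/0", "./.", "0/1")
  expect_error(genotype_site(calls, chrom = "7", pos = 123),
               "individual 2 at 7:123")
  expect_warning(dropped <- genotype_site(calls, missing = "drop_site"),
                 "dropping site")
  expect_identical(nrow(dropped), 0L)
  imputed <- genotype_site(calls, missing = "ref_impute")
  expect_identical(imputed$g[[1]], c(0L, 0L, 1L))
  # half-calls are missing under every policy
  expect_error(genotype_site(c("0/0", "./1")), "missing")
})
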
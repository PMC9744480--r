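# Shared fixture builders. Everything is generated in code; no data files.

# A random centered phenotype of length n.
random_y <- function(n) center_phenotype(rnorm(n))

# A random multi-site panel: calls drawn uniformly over the three genotypes
# (polymorphism not guaranteed — callers that need it should filter).
random_sites <- function(n, l = 1L) {
  genotype_sites(matrix(sample(c("0/0", "0/1", "1/1"), n * l, replace = TRUE),
                        nrow = n))
}

# Oracle-path aggregate statistic: explicit matrices + naive quadratic form.
oracle_S <- function(y, sites, kernel, w = rep(1, nrow(sites))) {
  per <- vapply(seq_len(nrow(sites)), function(k) {
    K <- if (kernel == "GRM") grm_matrix(sites[k, ]) else ibs_matrix(sites[k, ])
    quadratic_form(y, K)
  }, numeric(1))
  sum(w * per)
}

local_quiet <- function(env = parent.frame()) {
  withr::local_options(list(rlib_message_verbosity = "quiet"), .local_envir = env)
}
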
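## High-level entry points behind the command-line tool. Each reads or
## simulates data, runs the statistics, writes result artifacts that echo
## the full effective configuration (including every seed), and returns
## its results invisibly. The `exec/gvdtest` script is a thin dispatcher
## over these functions.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Run a kernel association test on files
#'
#' Reads genotypes (VCF) and a phenotype table, computes the aggregate
#' kernel statistic and its permutation p-value, and writes
#' `<out_prefix>.json` (full results and configuration) and
#' `<out_prefix>.tsv` (one-row summary). Defaults follow the reference
#' analysis profile: one million permutations at significance level
#' 5e-6 — scale `B` down for interactive use.
#'
#' @param vcf Path to the genotype VCF.
#' @param phenotype Path to the phenotype table (see [read_phenotype()]).
#' @param out_prefix Prefix for output files.
#' @param kernel `"GRM"` or `"IBS"`.
#' @param weights A [weight_scheme()], or `NULL` to use `weights_file`.
#' @param weights_file Optional per-site weight table (see [read_weights()]).
#' @param B Number of permutations.
#' @param alpha Significance level.
#' @param seed Permutation seed (`NULL`: drawn and recorded).
#' @param missing Missing-genotype policy for the VCF reader.
#' @param region Optional VCF region filter.
#' @return Invisibly, a list with the `gvd_kernel` and `gvd_perm` results,
#'   the rejection decision, and the paths written.
#' @export
run_test <- function(vcf, phenotype, out_prefix = "gvdtest",
                     kernel = c("GRM", "IBS"), weights = weight_scheme("uniform"),
                     weights_file = NULL, B = 1e6, alpha = 5e-6, seed = NULL,
                     missing = c("error", "drop_site", "ref_impute"),
                     region = NULL) {
  kernel <- match.arg(kernel)
  missing <- match.arg(missing)
  geno <- read_vcf(vcf, region = region, missing = missing)
  y <- read_phenotype(phenotype, geno$individual_ids)
  if (!is.null(weights_file)) weights <- read_weights(weights_file, geno$sites)
  if (is.null(seed)) seed <- draw_seed()

  ks <- kernel_statistic(y, geno$sites, kernel = kernel, weights = weights)
  pt <- permutation_test(y, geno$sites, kernel = kernel, weights = weights,
                         B = B, seed = seed, keep_null = FALSE)
  decision <- reject_null(pt, alpha)

  config <- list(
    subcommand = "test", vcf = vcf, phenotype = phenotype,
    region = region, kernel = kernel,
    weights = if (!is.null(weights_file)) weights_file else weights$kind,
    B = as.integer(B), alpha = alpha, seed = as.integer(seed),
    missing_policy = missing, n = pt$n, n_sites = pt$n_sites
  )
  json_path <- paste0(out_prefix, ".json")
  tsv_path <- paste0(out_prefix, ".tsv")
  write_json_file(list(config = config,
                       kernel_statistic = result_record(ks),
                       permutation_test = result_record(pt),
                       reject_null = decision),
                  json_path)
  write_result(pt, tsv_path, format = "tsv")
  inform(sprintf("%s kernel: S = %.6g, p = %.6g (B = %d) -> %s",
                 kernel, ks$S, pt$p_value, pt$B,
                 if (decision) "reject" else "do not reject"))
  invisible(list(kernel_statistic = ks, permutation = pt,
                 reject = decision, paths = c(json_path, tsv_path)))
}

#' Simulate a cohort and write it to files
#'
#' Simulates Hardy-Weinberg genotypes and a carrier-shift phenotype, and
#' writes `<out_prefix>.vcf`, `<out_prefix>.pheno.tsv` and a
#' `<out_prefix>.sim.json` sidecar recording every parameter and seed, so
#' the run can be reproduced exactly.
#'
#' @inheritParams simulate_genotypes
#' @inheritParams simulate_phenotype
#' @param out_prefix Prefix for output files.
#' @param genotype_seed,phenotype_seed Seeds (`NULL`: drawn and recorded).
#' @return Invisibly, a list with the sites, raw phenotype, and paths.
#' @export
run_simulate <- function(out_prefix = "gvdsim", n = 2504,
                         freqs = default_site_freqs(), carrier_effect = -1.0,
                         noise_sd = 1.0, genotype_seed = NULL,
                         phenotype_seed = NULL,
                         effect_model = c("carrier", "additive"),
                         monomorphic = c("drop", "redraw")) {
  effect_model <- match.arg(effect_model)
  monomorphic <- match.arg(monomorphic)
  if (is.null(genotype_seed)) genotype_seed <- draw_seed()
  if (is.null(phenotype_seed)) phenotype_seed <- draw_seed()
  sites <- simulate_genotypes(n, freqs, seed = genotype_seed,
                              monomorphic = monomorphic)
  if (nrow(sites) == 0L) {
    abort("all simulated sites were monomorphic; nothing to write.")
  }
  ids <- sprintf("ind%0*d", nchar(as.character(n)), seq_len(n))
  raw <- simulate_phenotype(sites, carrier_effect = carrier_effect,
                            noise_sd = noise_sd, seed = phenotype_seed,
                            effect_model = effect_model)
  vcf_path <- paste0(out_prefix, ".vcf")
  pheno_path <- paste0(out_prefix, ".pheno.tsv")
  sidecar_path <- paste0(out_prefix, ".sim.json")
  write_vcf(sites, vcf_path, individual_ids = ids)
  write_phenotype(raw, pheno_path, individual_ids = ids)
  write_json_file(list(
    subcommand = "simulate", n = as.integer(n), site_freqs = freqs,
    carrier_effect = carrier_effect, noise_sd = noise_sd,
    genotype_seed = as.integer(genotype_seed),
    phenotype_seed = as.integer(phenotype_seed),
    effect_model = effect_model, monomorphic_policy = monomorphic,
    n_sites_written = nrow(sites),
    n_sites_dropped = attr(sites, "n_dropped") %||% 0L
  ), sidecar_path)
  inform(sprintf("wrote %d site(s) for %d individuals to %s / %s",
                 nrow(sites), n, vcf_path, pheno_path))
  invisible(list(sites = sites, phenotype = raw, individual_ids = ids,
                 paths = c(vcf_path, pheno_path, sidecar_path)))
}

#' Run a power experiment and write the summary table
#'
#' Runs [power_experiment()] for one or both kernels under a shared master
#' seed and writes (optionally) a TSV table with one row per kernel:
#' kernel, replicates, rejections, alpha, B, n, seeds.
#'
#' @inheritParams power_experiment
#' @param kernels Character vector of kernels to run.
#' @param out Optional output TSV path.
#' @return A tibble with one row per kernel (invisibly if `out` is given).
#' @export
run_power <- function(kernels = c("GRM", "IBS"), n = 2504,
                      freqs = default_site_freqs(), carrier_effect = -1.0,
                      noise_sd = 1.0, B = 999L, alpha = 0.01,
                      replicates = 10L, master_seed = NULL,
                      resimulate_genotypes = FALSE,
                      effect_model = c("carrier", "additive"), out = NULL) {
  kernels <- match.arg(kernels, c("GRM", "IBS"), several.ok = TRUE)
  effect_model <- match.arg(effect_model)
  if (is.null(master_seed)) master_seed <- draw_seed()
  rows <- purrr::map(kernels, function(k) {
    glance(power_experiment(
      n = n, freqs = freqs, carrier_effect = carrier_effect,
      noise_sd = noise_sd, kernel = k, B = B, alpha = alpha,
      replicates = replicates, master_seed = master_seed,
      resimulate_genotypes = resimulate_genotypes, effect_model = effect_model
    ))
  })
  tab <- dplyr::bind_rows(rows)
  if (!is.null(out)) {
    write.table(as.data.frame(tab), out, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    return(invisible(tab))
  }
  tab
}

#' Verify the O(n) statistics against the brute-force oracle
#'
#' Draws random instances (sample size uniform on `[2, n]`, uniformly
#' random genotype calls, random centered phenotype), computes the per-site
#' and aggregate statistics through the O(n) path, recomputes them through
#' the explicit-matrix oracle, and reports the maximum relative
#' discrepancy. Intended both as a self-test command and as the engine of
#' the equivalence test-suite.
#'
#' @param n Maximum sample size per instance (the command-line wrapper
#'   refuses n > 5000 to guard against accidental quadratic blowup).
#' @param n_sites Maximum number of sites per instance.
#' @param trials Number of random instances.
#' @param seed RNG seed.
#' @param tol Relative tolerance for a pass.
#' @param corrupt Test hook: a perturbation added to every fast statistic,
#'   to confirm the check detects discrepancies. Leave at 0.
#' @return A list with `max_rel`, `trials`, `pass`, and (on failure) the
#'   first failing instance (`y`, calls, statistics) for replay.
#' @export
run_oracle_check <- function(n = 50, n_sites = 5, trials = 1000, seed = 1,
                             tol = 1e-9, corrupt = 0) {
  if (n < 2) abort("`n` must be >= 2.")
  max_rel <- 0
  failing <- NULL
  with_seed(seed, {
    for (t in seq_len(trials)) {
      ni <- sample(2:n, 1L)
      l <- sample.int(n_sites, 1L)
      calls <- matrix(sample(c("0/0", "0/1", "1/1"), ni * l, replace = TRUE),
                      nrow = ni)
      sites <- genotype_sites(calls)
      y <- center_phenotype(rnorm(ni))
      q_fast <- q_statistic(y, sites) + corrupt
      r_fast <- r_statistic(y, sites) + corrupt
      q_oracle <- vapply(seq_len(l), function(k) {
        quadratic_form(y, grm_matrix(sites[k, ])) }, numeric(1))
      r_oracle <- vapply(seq_len(l), function(k) {
        quadratic_form(y, ibs_matrix(sites[k, ])) }, numeric(1))
      rel <- max(rel_diff(q_fast, q_oracle), rel_diff(r_fast, r_oracle))
      if (rel > max_rel) max_rel <- rel
      if (rel > tol && is.null(failing)) {
        failing <- list(trial = t, y = as.numeric(y), calls = calls,
                        q_fast = q_fast, q_oracle = q_oracle,
                        r_fast = r_fast, r_oracle = r_oracle)
      }
    }
  })
  list(max_rel = max_rel, trials = as.integer(trials),
       pass = max_rel <= tol, failing = failing)
}
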
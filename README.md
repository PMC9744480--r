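# gvdtest

Kernel association statistics for rare-variant analysis, computed by
**genotype value decomposition**: the per-site quadratic forms used by
SKAT-style tests are obtained from a handful of inner products in O(n)
time per site, without ever building an n×n kernel matrix. For a cohort of
10,000 individuals the GRM or IBS kernel has 10⁸ entries per site;
`gvdtest` never allocates it.

The package is for statistical geneticists running gene- or region-level
association tests of a quantitative trait against sets of (typically rare)
biallelic variants, and for anyone who wants a small, fully seeded,
file-to-file permutation-testing tool for such tests.

## The statistics

Let `y` be the centered phenotype vector (`Σᵢ yᵢ = 0`) and, at site *k*,
let `a`, `b`, `c` be the binary indicator vectors of homozygous-reference,
heterozygous and homozygous-alternative individuals (`a + b + c = 1`), with
genotype values `g = b + 2c` and mean `μ = 2p`.

* **GRM kernel.** The per-site genetic-relationship matrix is
  `X[i,j] = (gᵢ − μ)(gⱼ − μ)`. Because `yᵀ1 = 0`, the quadratic form
  collapses to

  `Q = yᵀXy = (yᵀg)² = (yᵀb + 2·yᵀc)²`.

* **IBS kernel.** The identity-by-state matrix counts shared alleles:
  `IBS = 2aaᵀ + 1bᵀ + b1ᵀ + 2ccᵀ`. The rank-one heterozygote terms vanish
  against centered `y`, leaving

  `R = yᵀIBS·y = 2(yᵀa)² + 2(yᵀc)²`,  with `yᵀa = −(yᵀb + yᵀc)`.

Multi-site statistics are weighted sums `S = Σₖ wₖQₖ` (or `Σₖ wₖRₖ`) with
uniform, Beta-density-at-MAF, or custom weights. Both per-site statistics
are *exact* — identical to the explicit-matrix quadratic forms, which the
package also ships (`grm_matrix()`, `ibs_matrix()`, `quadratic_form()`) as
an independent brute-force oracle. p-values come from a seeded permutation
engine that resamples `y` without replacement and recomputes `S` through
the same O(n) path, with the add-one estimator
`p = (count_ge + 1)/(B + 1)`.

A Hardy–Weinberg genotype simulator plus carrier-shift phenotype model
(carriers of ≥1 alternative allele at ≥1 causal site shifted by −1.0 trait
units, Normal(0, 1) environmental noise by default) supports calibration
and power studies end to end.

## Worked example

Simulate a 2,504-individual cohort at seven rare sites, write it to
VCF + TSV, and test it with the GRM kernel:

```r
library(gvdtest)

sim <- run_simulate("cohort", n = 2504, genotype_seed = 7, phenotype_seed = 8)
#> dropped 2 monomorphic site(s) of 7.
#> wrote 5 site(s) for 2504 individuals to cohort.vcf / cohort.pheno.tsv

res <- run_test("cohort.vcf", "cohort.pheno.tsv", out_prefix = "grm",
                kernel = "GRM", B = 9999, alpha = 5e-6, seed = 9)
#> GRM kernel: S = 1380.73, p = 0.0001 (B = 9999) -> do not reject

glance(res$permutation)
#> # A tibble: 1 × 8
#>   kernel     S     B count_ge p_value  seed     n n_sites
#> 1 GRM    1381.  9999        0  0.0001     9  2504       5

tidy(res$kernel_statistic)
#> # A tibble: 5 × 7
#>   chrom   pos rsid         p statistic weight contribution
#> 1 1         2 sim2  0.000799      10.8      1         10.8
#> 2 1         4 sim4  0.00160      125.       1        125.
#> 3 1         5 sim5  0.00220      147.       1        147.
#> 4 1         6 sim6  0.00300      261.       1        261.
#> 5 1         7 sim7  0.00559      836.       1        836.
```

Two of the seven requested sites came out monomorphic at these rare
frequencies and were dropped, mirroring how monomorphic sites are excluded
from real call sets. The observed aggregate statistic S = 1380.7 was larger
than all 9,999 permuted statistics, so the add-one p-value is
1/10,000 = 1e-4 — strong evidence at conventional levels, but not below
the genome-wide level α = 5×10⁻⁶ used for the decision here (that level
needs B ≈ 10⁶, the default of `run_test()`).

The same pipeline is available from the shell via the installed script:

```sh
Rscript $(Rscript -e 'cat(find.package("gvdtest"))')/exec/gvdtest \
  test --vcf cohort.vcf --pheno cohort.pheno.tsv --B 9999 --seed 9
```

Subcommands: `test`, `simulate`, `power`, `oracle-check`
(plus `--version` / `--cite`).

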
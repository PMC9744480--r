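---
title: "Methods: kernel statistics by genotype value decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel statistics by genotype value decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvdtest)
```

## The model

A SKAT-style region test of a quantitative trait against a set of
biallelic variants uses a statistic of the form $S = y^\top K y$, where
$y$ is the length-$n$ phenotype vector, centered so that $y^\top 1 = 0$,
and $K$ is an $n \times n$ kernel matrix built from genotypes. `gvdtest`
supports the two classical kernels, summed over sites $k = 1..l$ with
nonnegative weights $w_k$:

* the **GRM** (genetic relationship matrix) kernel, whose per-site matrix
  is $X_k[i,j] = (g_k(i) - \mu_k)(g_k(j) - \mu_k)$ with $g_k$ the
  alternative-allele count (0, 1, 2) and $\mu_k = 2 p_k$ its mean;
* the **IBS** (identity by state) kernel, whose per-site matrix counts the
  alleles two individuals share (0, 1, or 2).

The package's core observation is a decomposition of the genotype column
into three binary indicator vectors — $a_k$ (homozygous reference),
$b_k$ (heterozygous), $c_k$ (homozygous alternative), with
$a_k + b_k + c_k = 1$ and $g_k = b_k + 2 c_k$ — under which both per-site
quadratic forms collapse to a few inner products once $y$ is centered:

$$Q_k = y^\top X_k y = (y^\top b_k + 2\, y^\top c_k)^2,$$
$$R_k = y^\top \mathrm{IBS}_k\, y = 2 (y^\top a_k)^2 + 2 (y^\top c_k)^2,
  \qquad y^\top a_k = -(y^\top b_k + y^\top c_k).$$

The centering is what kills the cross terms: $X_k$'s rank-one mean
corrections and the IBS matrix's heterozygote terms
$1 b_k^\top + b_k 1^\top$ are all annihilated by $y^\top 1 = 0$. These are
identities, not approximations — the O($n$) statistics are bit-for-bit the
same quantities as the explicit-matrix quadratic forms, up to floating
point. The multi-site statistic is $S = \sum_k w_k Q_k$ (or
$\sum_k w_k R_k$), and its null distribution is estimated by permuting $y$.

Assumptions worth stating: sites are biallelic, diploid and autosomal
(calls `0/0`, `0/1`/`1/0`, `1/1`; `/` and `|` are equivalent since only
allele counts enter); the phenotype is quantitative and exchangeable
across individuals under the null (what the permutation test relies on);
no covariates are adjusted for. Hardy–Weinberg equilibrium is *not*
required by any statistic — it enters only the simulator. No HWE test is
performed on input data.

## The brute-force oracle

`grm_matrix()`, `g_matrix()`, `ibs_matrix()` and `quadratic_form()` build
the explicit matrices entry by entry and evaluate $y^\top K y$ with a
naive O($n^2$) double loop. They are deliberately free of the algebraic
shortcuts above, so agreement between the two paths is a genuine
two-route check, and the test suite (and the `oracle-check` subcommand)
drives thousands of randomized comparisons through it. The IBS matrix can
be built two independent ways — pairwise shared-allele lookup, or the
rank-structured sum $2 a a^\top + 1 b^\top + b 1^\top + 2 c c^\top$ — and
the tests require the two constructions to agree bit-for-bit. The
command-line wrapper caps the oracle at $n \le 5000$ to guard against
accidental quadratic blowups; the library functions accept any $n$.

## Tunable parameters

* **Weights** (`weight_scheme()`): `uniform` (default, $w_k = 1$ — an
  unweighted analysis, which is also what the power study below uses);
  `beta`, the Beta($a_1, a_2$) density evaluated at each site's minor
  allele frequency — the conventional rare-variant choice is
  Beta(1, 25), offered but never applied silently; `custom`, explicit
  nonnegative per-site weights (from a file in the CLI, with unmatched
  sites an error rather than a silent drop).
* **Permutations `B`** (default 999 in `power_experiment()`, $10^6$ in
  `run_test()`): the add-one estimator $p = (\#\{S^{(b)} \ge S\} + 1)/(B+1)$
  has granularity $1/(B+1)$, so `B` must comfortably exceed $1/\alpha$;
  $10^6$ supports the genome-wide level $\alpha = 5\times10^{-6}$
  (one region among $\sim 10^4$ tests).
* **Carrier effect** (default $-1.0$ trait units, e.g. µg/dL) and
  **noise SD** (default $1.0$): the simulator's trait model; see below.
* **Site frequencies** (`default_site_freqs()`): seven alternative-allele
  frequencies from $2\times10^{-4}$ to $5\times10^{-3}$, spanning expected
  minor-allele counts of roughly 1–25 in a cohort of $n = 2504$ — the
  shape of a typical rare-coding-variant panel.

## The permutation engine

Permuting the phenotype is equivalent to applying the inverse permutation
to every genotype vector, and cheaper, so only $y$ is resampled; each of
the $B$ permutations is an independent uniform draw without replacement
from R's Mersenne–Twister stream under the recorded seed, and each
permuted $S$ is recomputed through the same O($n$) inner-product path as
the observed one (cost O($n\,l$) per permutation; internally permutations
are processed in chunks as matrix–matrix products, which changes nothing
about the result — a test asserts chunk-size invariance). Ties count
toward rejection (`count_ge` uses $\ge$), and the add-one form keeps the
p-value valid and strictly positive. Decisions use $p \le \alpha$;
$\alpha = 1$ is accepted as a degenerate always-reject level so that
calibration code can exercise the decision path. Seeds are never global
state: every seeded function restores the caller's RNG stream, and a seed
that was drawn rather than supplied is still recorded in the output.

## The simulator

`simulate_genotypes()` draws each individual's genotype value at a site
with frequency $p$ as Binomial(2, $p$) — exactly the Hardy–Weinberg
proportions $(1-p)^2, 2p(1-p), p^2$. Monomorphic realizations are dropped
by default (mirroring the monomorphic-site exclusion applied to real call
sets; an empty panel is a legal outcome at very rare frequencies) or
redrawn on request. `simulate_phenotype()` shifts carriers — individuals
with at least one alternative allele at at least one causal site — by the
carrier effect *once* (heterozygotes and alternative homozygotes equally),
then adds Normal(0, noise SD) noise. The single-shift (dominant,
collapsed-across-sites) reading is the default because the trait model is
stated in terms of carrier status, not allele dosage; a per-site
`additive` mode (one shift per causal site carried) is available behind a
flag for the other reading. Genotype and phenotype seeds are separate so a
genotype panel can be held fixed while phenotype noise is redrawn across
replicates — the design `power_experiment()` uses by default, which
matches studies whose genotypes come from a fixed reference panel.

What the simulator does **not** emulate: linkage disequilibrium between
sites (sites are drawn independently; real rare-variant panels are often
correlated), population structure or relatedness, genotyping error and
missingness, and case–control ascertainment. Tests passing on simulated
data therefore validate the *statistics and their calibration under
exchangeability*, not robustness to structure or LD — on real data with
related individuals the permutation null itself would be questionable.

## Numerical choices

* All statistics are computed in double precision. Aggregation uses
  `sum()`, which accumulates in extended (long-double) precision — the
  compensated-summation behavior wanted for many-site stability without a
  hand-rolled loop.
* $y^\top a$ is evaluated as $-(y^\top b + y^\top c)$. One consequence is
  exactness of the rare-variant identity: at a site with no `1/1`
  individuals, $y^\top c = 0$ identically, so $R = 2 (y^\top b)^2 = 2Q$
  holds to the last bit, not just asymptotically.
* Oracle-equivalence checks use a scale-aware relative discrepancy,
  $|f - o| / \max(|f|, |o|, 1)$: quadratic forms that are zero in exact
  arithmetic come back from the O($n^2$) double loop as O(machine-eps)
  roundoff, where a bare relative error is meaningless. Above magnitude 1
  this is the ordinary relative error; the pass threshold is $10^{-9}$.
* Monomorphic homozygous-reference sites give exactly $Q = R = 0$ (all
  inner products are over zero vectors); all-heterozygote or
  all-alternative sites give O(eps$^2$) values, which the same comparison
  treats as zero.
* Centering subtracts the sample mean once; `center_phenotype()`
  guarantees $|\bar y| < 10^{-12}$ and downstream functions refuse
  visibly uncentered input rather than silently re-centering.

## Problem sizes in the test suite

The suite's randomized checks use sizes chosen to exercise the math, not
the hardware: oracle equivalence on 1,000 instances with $n \in [2, 50]$
(the O($n^2$) oracle is the binding cost); the rare-variant identity on
500 instances; null calibration with $n = 500$, five polymorphic sites
(frequencies 0.01–0.2), $B = 999$, $\alpha = 0.05$ and 500 replicates,
judged against the exact binomial 99% interval; and the power comparison
on the default seven-rare-site panel at $n = 2504$, effect $-1.0$, noise
SD 1.0, $\alpha = 0.01$, $B = 999$, 100 replicates per kernel, requiring
power above the matched null rate and no GRM–IBS difference by chi-square
at 5%. The linearity check times the aggregate statistic at
$n = 10^3, 10^4, 10^5$ (10 sites) and requires a log–log slope below 1.5;
the slope lands well under 1 because per-call overhead dominates at small
$n$.

## Known limitations

* No asymptotic p-values (chi-square mixtures / eigenvalue methods):
  permutation only. At genome-wide $\alpha$ this means large `B`; no
  adaptive early stopping or tail importance sampling is implemented.
* No covariate adjustment and no binary-trait variance weighting; the
  phenotype enters only through centering.
* Dosages (DS/GP), sex-chromosome ploidy, multiallelic sites and
  half-calls are out of scope: multiallelic records are skipped with a
  count, half-calls are missing under every policy.
* Missing genotypes are never imputed silently: the default policy is an
  error naming the site and individual, with explicit `drop_site` and
  `ref_impute` alternatives, because any imputation changes $Q$ and $R$.
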
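---
title: "Compressed genotype matrix algebra and single-step SNP BLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed genotype matrix algebra and single-step SNP BLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentagen)
```

## The problem

Genomic evaluations in animal breeding repeatedly multiply the centered SNP
matrix

$$Z = M - 2\,\mathbf{1}\,p',$$

or its transpose, by a narrow real matrix $\Lambda$. Here
$M \in \{0,1,2\}^{n_g \times n_s}$ holds allele dosages of $n_g$ genotyped
animals at $n_s$ biallelic markers and $p$ is the vector of allele frequencies
of the counted allele, so $2p_j$ is the expected dosage and the subtraction
centers each column. Because the centering term $2\,\mathbf{1}p'\Lambda$ is a
cheap rank-one update,

$$Z\Lambda = M\Lambda - 2 \cdot \mathbf{1}(p'\Lambda), \qquad
  Z'\tilde\Lambda = M'\tilde\Lambda - 2 \cdot p(\mathbf{1}'\tilde\Lambda),$$

the real work is multiplying the *integer* matrix $M$, which is stored
compressed (2 bits per genotype in PLINK 1 files) and cannot be handed to
BLAS without inflation. This package implements a lookup-table algorithm for
exactly this product and uses it inside a matrix-free iterative solver for
single-step SNP BLUP (ssSNPBLUP) mixed model equations.

## The 5codes packing and table-lookup multiplication

A vector of five dosages $m \in \{0,1,2\}^5$ takes one of $3^5 = 243$ values,
so it fits in one byte:

$$\mathrm{key}(m) = m_1 3^0 + m_2 3^1 + m_3 3^2 + m_4 3^3 + m_5 3^4 .$$

Compared with 2-bit packing this costs 1.6 instead of 2 bits per genotype —
80% of the memory whenever no padding occurs (marker counts divisible by 40
leave no partial bytes on either side). For one column $\lambda$ of $\Lambda$
and one block of five markers, all 243 possible partial dot products
$m'\lambda_{(5)}$ are precomputed into a table; each individual then
contributes a single table lookup per block. Centering can be folded into the
tables — entry $k$ stores $\mathrm{decode}(k)'\lambda_{(5)} -
2\,p_{(5)}'\lambda_{(5)}$ — which both saves an extra pass and avoids
accumulating the subtraction separately:

```{r tables}
lam5 <- c(0.3, -1.2, 0.4, 0.0, 2.0)
p5 <- c(0.1, 0.5, 0.25, 0.4, 0.3)
tab <- build_lookup_table(lam5, p5, centered = TRUE)
tab[1]                       # key 0 = all-zero genotypes: -2 * sum(p5 * lam5)
tab[encode_key(c(1, 0, 2, 0, 1)) + 1]
```

The transposed product $M'\tilde\Lambda$ uses the same machinery on a
separately stored packing of $M'$ (five contiguous *individuals* per byte).
Storing the transpose explicitly doubles genotype memory but avoids an
on-the-fly transpose; at 1.6 bits per entry this is rarely the binding
constraint. For the transposed *centered* product the correction
$2\,p(\mathbf{1}'\tilde\Lambda)$ depends on the output row's frequency, so it
is applied as a rank-one update rather than inside the tables.

Long computations are split into contiguous blocks of key columns, partial
results are accumulated per block group and summed once at the end in fixed
group order. The `chunks` argument exposes that reduction contract: any chunk
count reproduces the single-chunk result to within last-digit rounding, which
the tests pin at $10^{-12}$.

### Missing genotypes

The 243-state key space assumes complete data, so missing calls are packed as
dosage 0 and carried in a sparse index set. Two corrections are exposed:

* `mean_impute` (default): a missing entry contributes 0 to $Z$ — the
  $-2p_j\lambda_j$ that the packed path implicitly added is removed by a
  sparse post-correction of $+2 p_j \lambda_{j\cdot}$ per missing entry. This
  is the standard single-step convention (a missing genotype is replaced by
  its population mean $2p_j$).
* `zero_dosage`: the literal packed value stands, i.e. $z = -2p_j$ at missing
  positions.

Which convention production solvers use is implementation-dependent, so both
are provided; all equivalence tests run under both.

A separate path, `packed_bed_times()`, evaluates the same products directly on
the 2-bit PLINK codes (a 256-entry byte table extracting four dosages at a
time), mirroring how bitmask-extraction kernels operate on the native format.
`reference_dense_multiply()` literally inflates $M$ and calls `%*%`; it is the
oracle every packed path is verified against, at a relative tolerance of
$10^{-10}$ over randomized instances spanning $n_g, n_s \le 200$, widths up to
10 and missing rates up to 20%.

## Single-step SNP BLUP

The observation model is

$$y = Xb + \begin{pmatrix} W_n & 0 \\ 0 & W_g \end{pmatrix}
  \begin{pmatrix} u_n \\ u_g \end{pmatrix} + e,$$

with $u_g = a_g + Zg$: the breeding values of genotyped animals decompose
into residual polygenic effects $a_g$ and SNP effects $g$. The joint
precision of $(u_n, u_g, g)$ is

$$\Sigma^{-1} = \begin{pmatrix}
  A^{nn} & A^{ng} & 0 \\
  A^{gn} & A^{gg} + (\tfrac1w - 1) A_{gg}^{-1} & -\tfrac1w A_{gg}^{-1} Z \\
  0 & -\tfrac1w Z' A_{gg}^{-1} & \tfrac1w Z' A_{gg}^{-1} Z + \tfrac{m}{1-w} I
\end{pmatrix} \sigma_u^{-2},$$

where $A^{nn}, A^{ng}, A^{gn}, A^{gg}$ are blocks of the sparse inverse of
the pedigree relationship matrix, $A_{gg}$ is the genotyped submatrix of $A$
itself, $m = 2\sum_j p_j(1 - p_j)$, $w \in (0,1)$ is the proportion of
additive variance assigned to residual polygenic effects, and $\sigma_u^2$
the additive variance. Every piece of $\Sigma^{-1}v$ is cheap without
assembling anything dense:

* the $A^{\cdot\cdot}$ blocks are sparse (Henderson's rules add at most nine
  entries per animal);
* $A_{gg}^{-1} v = A^{gg} v - A^{gn} (A^{nn})^{-1} A^{ng} v$, with
  $(A^{nn})^{-1}$ applied by forward/backward substitution against a Cholesky
  factor computed once;
* $Zv$ and $Z'v$ are the lookup-table products above.

Henderson's mixed model equations for $\theta = (b, u_n, u_g, g)$, multiplied
through by $\sigma_e^2$ so no data term carries a variance ratio, are

$$\big(T'T + \sigma_e^2\,\mathrm{blockdiag}(0, \Sigma^{-1})\big)\,\hat\theta
  = T'y, \qquad T = [\,X \mid W_n \mid W_g \mid 0\,].$$

The SNP-effect block enters the equations only through $\Sigma^{-1}$; total
breeding values of genotyped animals are read off directly as $\hat u_g$. The
system is solved with preconditioned conjugate gradient, stopping on the
squared relative residual $\lVert r\rVert^2/\lVert T'y\rVert^2 < 10^{-13}$ by
default.

### Numerical choices

* **Preconditioner.** The exact diagonal of $T'T$ plus the cheap diagonals of
  $\sigma_e^2 \Sigma^{-1}$: $\mathrm{diag}(A^{nn})$, $\mathrm{diag}(A^{gg})$
  and the constant $m/(1-w)$ for the SNP block, all scaled by
  $\sigma_e^2/\sigma_u^2$. The diagonal of $\tfrac1w Z'A_{gg}^{-1}Z$ would
  cost a full pass over the genotypes and is omitted — this slows convergence
  slightly but cannot change the solution. Fixed-effect diagonals are floored
  at $10^{-8}$ so an unused level cannot produce a zero preconditioner entry.
* **Stopping rule and accuracy.** A squared relative residual of $10^{-13}$
  is a relative residual of about $3\times10^{-7}$; against a dense direct
  solve of the identical equations the blocks agree to better than $10^{-5}$
  relative on the reference study (400 animals, 1000 SNPs). Loosening the
  tolerance to $10^{-10}$ (relative residual $10^{-5}$) leaves the solution
  stable at roughly the $10^{-3}$-to-$10^{-4}$ block scale, in line with the
  preconditioned conditioning of the system — tighter agreement should not be
  expected from the stopping rule alone.
* **Inbreeding.** `build_a_inverse()` uses exact Mendelian-sampling variances
  from tabular-method inbreeding coefficients by default; the classical
  non-inbred $\alpha \in \{2, 4/3, 1\}$ shortcut is available and exact on
  inbreeding-free pedigrees. Unknown parents are coded 0.
* **Rank deficiency.** Cell-means coding is used for the generator's fixed
  effects, so its systems are full rank. User-supplied $X$ may be rank
  deficient; PCG then converges on the consistent normal equations, and
  estimability of individual fixed-effect contrasts is the caller's
  responsibility.
* **Degenerate inputs.** Monomorphic or all-missing SNPs are kept
  ($p_j \in \{0,1\}$ or $0$ with a warning); an entirely monomorphic panel
  makes $m = 0$ and is rejected. A pedigree listing offspring before parents
  is reordered with a warning; cycles and self-parenting are errors.

## What the generator emulates

`simulate_study()` produces, deterministically per seed: a multi-generation
random-mating pedigree (founders with unknown parents, alternating sexes);
genotypes by Mendelian gene dropping from founder haplotypes whose allele
frequencies are uniform on `maf_range`; missing calls at a fixed rate;
phenotypes from the observation model above with SNP effects
$g \sim N(0, (1-w)\sigma_u^2/m)$ and polygenic values drawn through the
Cholesky factor of the tabular $A$ (identity shortcut when all animals are
founders; the tabular route is $O(n^3)$ and capped at 2000 animals).

Gene dropping — rather than independent genotype sampling — is what makes the
pedigree and genomic relationships mutually consistent, which the single-step
parameter-recovery checks require. Defaults are chosen as a realistic
desk-scale breeding population: 80 founders plus four generations of 80
(400 animals), 1000 SNPs, founder frequencies in $[0.05, 0.5]$, the youngest
half genotyped, 1% missing calls, $w = 0.2$ (a common residual-polygenic
setting in routine evaluations), unit variances, trait-matrix width 10.

The generator deliberately does **not** emulate linkage disequilibrium, chip
ascertainment, selection, or imputation artefacts. Passing tests therefore
demonstrate algebraic correctness of the kernels and solver and statistical
sanity of the simulation (Mendelian segregation proportions, variance
calibration of $\mathrm{var}(Zg)$ against $(1-w)\sigma_u^2$, frequency
recovery), not predictive performance on real livestock data.

## Problem sizes used in the checks

All verification is desk-scale by design: randomized multiply instances up to
$200 \times 200$ with widths up to 10; pedigrees up to 500 animals for the
sparse-inverse identity; the solver study at 400 animals / 1000 SNPs against
a dense direct solve; segregation checks on 10,000 trios and variance
calibration on 2000 genotyped founders. These sizes keep every oracle exactly
computable; nothing in the algebra is size-dependent.

## Limitations

* Univariate, homogeneous-residual models only; no multi-trait extension.
* No GPU or SIMD kernels: this is a numerically faithful reference
  implementation in R; throughput benchmarking against optimized native code
  is out of scope (an informational `bench` CLI subcommand is included).
* The 5codes key space excludes missing states by construction; datasets that
  are mostly missing make the sparse-correction path the dominant cost.
* `tabular_a()`, and everything that depends on it (inbreeding, the
  generator's polygenic draw, dense oracles), is quadratic in memory and
  capped at 2000 animals.
```{r session, include = FALSE}
sessionInfo()
```
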
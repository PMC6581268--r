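---
title: "PCA of SNP matrices: codings, variants, and biplots"
author: "snppca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCA of SNP matrices: codings, variants, and biplots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snppca)
```

# The problem

A biallelic SNP matrix — Individuals in rows, SNPs in columns, entries 0/1 —
is a two-way factorial layout. "Running PCA" on such a matrix is not one
method: every analysis implicitly makes three choices that change what the
graph can show.

1. **Graph kind.** A monoplot shows only Individuals (or only SNPs); a
   biplot shows both and is the only graph that can display the joint
   SNP-by-Individual structure.
2. **SNP coding.** Each SNP's polarity (which allele is written 1) is
   arbitrary. Coding the *rare* (minor) allele 1 orients every SNP the same
   way; coding the common allele 1, a per-SNP mixture, or a VCF-style
   reference coding are the alternatives.
3. **Transform before the SVD.** Centering by SNPs, by Individuals, both
   (double centering), standardizing either axis, or subtracting only the
   grand mean — six variants with different biological content in their
   components.

This package implements the full decision space, with double-centered PCA
(DC-PCA), rare-allele-as-1 coding, and biplots as the recommended defaults,
plus the ANOVA machinery needed to interpret any of the other choices.

# Model and notation

Write $D_{rc}$ for the entry of Individual $r$ and SNP $c$, $\mu$ for the
grand mean, $\mu_r$ and $\mu_c$ for the row and column means. The two-way
decomposition

$$D_{rc} = \mu + (\mu_r - \mu) + (\mu_c - \mu) + \theta_{rc}$$

splits the data into the grand mean, Individual main effects, SNP main
effects, and the SNP-by-Individual (S×I) interaction $\theta_{rc}$. The
three sources are orthogonal: `threeSourceAnova()` books their sums of
squares (SS) and degrees of freedom (df), with
$SS_{SNPs} = R\sum_c(\mu_c-\mu)^2$ on $C-1$ df,
$SS_{Ind} = C\sum_r(\mu_r-\mu)^2$ on $R-1$ df, and the interaction on
$(R-1)(C-1)$ df. For 0/1 data the main effects are allele frequencies:
$\mu_c$ is SNP $c$'s frequency of the allele coded 1, and $\mu_r$ is
Individual $r$'s mean across SNPs.

DC-PCA applies the SVD to the double-centered matrix:

$$D_{rc} = \mu_r + \mu_c - \mu + \sum_n \lambda_n \gamma_{rn} \delta_{cn}
  + \rho_{rc},$$

with singular values $\lambda_n$ (so $\lambda_n^2$ is component $n$'s SS),
unit eigenvectors $\gamma$ (Individuals) and $\delta$ (SNPs), and residual
$\rho$. Its components are interaction principal components (IPCs): pure
S×I information, nothing else. Scores are reported as
$\lambda^{1/2}\gamma$ and $\lambda^{1/2}\delta$ on both axes
(`scaling = "symmetric_sqrt"`), so the product of an Individual score and a
SNP score estimates that cell's interaction directly; an
`"axis_principal"` mode ($\lambda\gamma$) is available when a monoplot
should preserve inter-Individual distances.

## Degrees of freedom

Multiplicative terms receive Gollob-style df: component $k$ of a
double-centered decomposition gets $p + n - 1 - 2k$ df ($p$ SNPs, $n$
Individuals), a singly centered or standardized decomposition
$p + n - 2k$, and a grand-mean-centered one $p + n + 1 - 2k$; the residual
closes the source df. For a 635 × 1341 matrix this gives IPC1 df 1973 and,
after seven IPCs, an interaction residual of 835791 df — the bookkeeping
`dcPcaAnova()` prints and the test suite pins.

## The augmented ANOVA table

Every variant other than DC-PCA decomposes a *mixture* of sources
(SNP-centered PCA, for instance, decomposes Individual main effects plus
interaction). Whether PC1 of such an analysis shows population structure or
merely allele-frequency differences is an empirical question, answered by
`augmentedAnova()`: each PC's rank-1 matrix of expected values
$\lambda_n\gamma_n\delta_n'$ is itself subjected to the three-source ANOVA,
splitting the PC's SS into main-effect and interaction portions; the
residual matrix is partitioned the same way. Because the singular vectors
are orthogonal, the portion columns add up exactly to the source SS for the
singly centered and standardized variants. For the grand-mean-centered
variant each component's rank-1 matrix can carry a nonzero grand mean whose
cross-terms do not cancel, so there the S×I portion absorbs the
(analytically small) mean term and column closure is only approximate —
an intrinsic property of that transform, not a numerical artifact.
`classifyPcOutcomes()` labels each PC main-dominated,
interaction-dominated, or mixed; the mixed cutoff (minority portion above
20% of the PC's SS) is a configurable convention, chosen so that a
roughly 30/70 split counts as mixed. Portion columns need not decrease
monotonically across PCs even though the total component SSs do.

## AMMI

When main effects are of interest, `fitAmmi()` keeps them: grand mean and
both main-effect vectors additively, interaction by the same SVD as DC-PCA
(the two analyses share one ANOVA table). The AMMI1 biplot
(`ammi1Coordinates()`) puts main effects on the abscissa — Individuals at
$\mu_r$, SNPs at $\mu_c$, a vertical reference at $\mu$ — and IPC1 on the
ordinate. The abscissa carries 100% of both main effects and none of the
interaction; the ordinate carries the largest share of interaction any
single axis can. Because the axes hold different kinds of information,
AMMI1 is exempt from the equal-scale rule that applies to
component-vs-component plots. The abscissa plots means rather than
deviations by default (a flag switches), matching the natural
"mean frequency of the rare allele" axis reading.

## Coding polarity: what is and is not invariant

Flipping SNP polarities multiplies rows of the SNP-centered matrix by ±1,
which leaves Individual scores unchanged up to per-component sign — exact
immunity for SNP-centered and SNP-standardized PCA (standardization is
unaffected because variances are polarity-invariant). Double centering
breaks the argument: the Individual-centering projector does not commute
with the sign flips. In practice the damage is bounded by the size of the
Individual main effects; when their SS is small relative to the interaction
SS, DC-PCA Individual scores are *virtually* immune (per-component absolute
correlations above 0.99 in our property tests), though never exactly. Both
facts are asserted as property-style tests. One caveat the tests respect:
per-component comparisons are only meaningful for components with separated
singular values — inside a near-degenerate noise bulk, eigenvector rotation
is unconstrained no matter the coding.

Complementary codings (rare1 vs common1) reflect every column about its
mean, so all six variants' ANOVA tables are identical between them — also a
frozen test. What *changes* under coding is the biplot geometry: flipping a
SNP's polarity sends its point (approximately) through the origin, so mixed
codings scatter what would be a coherent SNP cloud. The sign convention for
components (largest-magnitude SNP eigenvector entry positive) is arbitrary
but fixed, so repeated runs and figures are comparable.

# Correspondence analysis and the arranged matrix

`caDecompose()` implements CA (reciprocal averaging) by SVD of the
standardized residuals of the independence model,
$S = \mathrm{diag}(r)^{-1/2}(P - rc')\,\mathrm{diag}(c)^{-1/2}$ with
$P = X/\mathrm{total}$, which excludes the trivial margins axis by
construction and bounds singular values by 1. Standard coordinates divide
the singular vectors by the square roots of the margins. A power-method
path (`method = "power"`, tolerance 1e-10, at most 10000 iterations,
deterministic ramp start) computes just the first axis and is verified to
match the SVD route to 1e-8.

`arrangeByCa1()` permutes rows and columns by ranked CA1 scores. For data
driven by one dominant gradient this concentrates the 1s along the
diagonal — the matrix-seriation view of the same structure a PCA arch
hints at. Direction is fixed by a reproducibility convention (the first
arranged row's 1s must sit at a smaller mean column rank than the last
row's); CA1 ties break by original index. The arrangement is meaningful
under rare1 coding only (a warning is issued otherwise — complementing
half the columns destroys the diagonal pattern rather than the analysis,
so the function reports rather than refuses). `diagonalConcentration()`
quantifies the pattern with
$1 - 2\sum v_{ij}\,|\tilde r_i - \tilde c_j| / \sum v_{ij}$ on normalized
ranks (1 = perfectly diagonal) and calibrates it against a
within-column-permutation null: shuffling each SNP's column independently
and re-arranging destroys real joint structure, so an observed statistic
exceeding all null replicates is evidence the displayed diagonal is not an
artifact of the ordering itself. Structureless inputs (zero standardized
residuals) keep their received order with a warning, which makes the
statistic equal to its own null — the correct degenerate behavior.

# Group schemes for coherent biplots

Two complementary routes color both panels with one biological meaning:

- `snpGroupsFromIndividualGroups()` transfers expert Individual groups to
  SNPs by assigning each SNP the group with the highest within-group
  frequency of its rare allele. Ties go to the larger group, then to the
  lexicographically first name, and are reported — ties are rare in real
  data but the rule must be deterministic.
- `quantileGroupsByOrder()` cuts an axis into contiguous CA1-order blocks
  of size ⌊N/k⌋ with the remainder appended to the last block
  (635 lines in 5 groups: five blocks of 127; 1341 SNPs: four of 268 plus
  one of 269).

`anomalyReport()` lists items whose expert label disagrees with the
majority label of their CA1 neighborhood — candidates for expert
re-review, reported but never auto-relabeled.

# Synthetic data: what the generators emulate

**`diagonalBandMatrix()`** builds the single-gradient archetype: entry
$(r,c)$ is 1 when the normalized positions differ by at most
`bandWidth/nSnp` (band width is in SNP-column units; the default half-width
of 3 columns on a 20 × 24 matrix makes the structure visually obvious),
plus optional independent flip noise, recoded rare1 post hoc. DC-PCA of
such data shows the arch (horseshoe): the gradient bends into a curve in
the IPC1–IPC2 plane, with matched Individuals and SNPs pointing in the same
direction from the origin under rare1 and the SNP arch rotating ~180°
under common1.

One empirical subtlety the test suite documents: for hard 0/1 bands the
arch's ends *involute* (bend inward), so IPC1 is not monotone along the
gradient and IPC2 is a two-valued function of IPC1. A quadratic regression
of IPC2 on IPC1 therefore tops out near $R^2 \approx 0.7$ over this whole
matrix family; the robust statement of the arch — IPC2 is a strong
single-curvature quadratic in gradient *position* — is what the unit tests
assert ($R^2 > 0.6$ at the defaults, observed ≈ 0.74).

**`structuredBernoulli()`** draws independent Bernoulli entries with
$\pi_{rc} = \mathrm{clamp}(\mathrm{base} + a_r + b_c + g_r h_c,\;
\varepsilon, 1-\varepsilon)$, $\varepsilon = 0.02$, scaling the effect
vectors so each structural source hits a requested expected share of the
total SS. Effect vectors are balanced ±1 patterns in random order: they
minimize the peak of the rank-1 interaction surface for a given SS (no
clamp spikes) and correspond to the canonical discrete
population-structure signal — two diverged subpopulations with a
differentiated SNP block. The base probability defaults to 0.5, which
maximizes the feasible share region; polarity is arbitrary before
recoding, so nothing is lost. Requests whose worst-case aligned effects
exceed the probability headroom saturate the clamp and are rejected
(above 10% of cells affected) — an inherent feasibility bound of bounded
probabilities, not a tunable. The generating truth (a, b, g, h, π) is
returned for parameter-recovery checks.

Neither generator emulates linkage disequilibrium, coalescent ancestry,
missing data, or genotyping error; passing tests on them demonstrates the
algebraic and geometric behavior of the methods, not robustness to those
real-data features.

# Numerical choices

- Centering identities asserted at 1e-9 absolute; SS table comparisons at
  3 printed decimals; energy conservation at 1e-6 relative.
- Standard deviations use the $n-1$ denominator.
- Monomorphic SNPs are a hard error for standardized variants and CA
  (zero variance / zero structure), and are listed by `validateGenotypes()`
  so callers can drop them first.
- Frequency-0.5 ties have no rare allele: recoding leaves them unflipped
  and reports them, making rare1/common1 recodes exact complements only
  away from ties.
- Missing values are a hard error at read time (these analyses assume
  complete matrices); the reader names the offending cell.
- The SVD is computed by LAPACK via `svd()`; only the requested components
  are materialized in the result object.

# Test and verification sizes

The suite cross-checks `snpPca()` against brute-force eigendecomposition
of the cross-product matrix on random matrices up to 8 × 8, `caDecompose()`
against both an eigendecomposition oracle and `vegan::cca()`, and
`threeSourceAnova()` against `stats::aov()` on a 5 × 6 layout. Property
suites use 100-trial polarity sweeps on 12 × 18 matrices, 10-trial DC
near-immunity sweeps on 60 × 240 matrices, and 99-replicate randomization
nulls on 20 × 24 bands; the whole suite runs in a few seconds on one CPU.
These sizes were chosen as the smallest at which the asymptotic claims
(noise-share expectations, near-immunity) are clearly separated from
finite-size effects.

# Known limitations

- The dataset anchors from the published oat analysis (a 635 × 1341
  matrix) are asserted only when a user supplies that matrix under
  `inst/extdata/`; it is journal supplementary material and too large to
  ship here.
- Augmented-table column closure is approximate (mean-term leakage) for
  the grand-mean-centered variant, as explained above.
- No sparse or randomized SVD path: matrices are assumed to fit in memory
  densely. The power method covers the "first axis only, linear cost"
  case for CA.
- Diploid 0/1/2 support covers coding conversion
  (`recodeDiploidRare2()`); the PCA/ANOVA machinery treats such matrices
  as numeric without dominance modeling.
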
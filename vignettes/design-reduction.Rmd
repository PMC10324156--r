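---
title: "Iterative reduction of stepped wedge designs: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative reduction of stepped wedge designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swreduce)
```

## The statistical model

`swreduce` works at the design stage of a standard stepped wedge cluster
randomised trial with repeated cross-sectional sampling: different
subjects are measured in each period, `m` per measured cluster-period,
and one cluster is randomised to each of the `K = T - 1` treatment
sequences. The outcome for subject `i` of cluster `k` in period `j` is
modelled as

$$Y_{kji} = \mu + \beta_j + X_{kj}\theta + \gamma_{kj} + \epsilon_{kji},$$

with fixed categorical period effects $\beta_j$ ($\beta_1 = 0$), a single
treatment effect $\theta$, cluster-period random effects
$\gamma_k \sim N_T(0, \tau^2 R)$ and independent errors
$\epsilon_{kji} \sim N(0, \sigma_\epsilon^2)$. The matrix $R$ carries the
intracluster correlation structure:

* **discrete-time decay**: $R_{js} = r^{|j-s|}$ — correlation between two
  subjects in the same cluster decays geometrically with the number of
  periods between their measurements; `r` is the cluster autocorrelation
  (CAC);
* **exchangeable**: $r = 1$, $R$ a matrix of ones — equivalent to a single
  cluster random intercept;
* **block-exchangeable**: unit diagonal, constant `r` off the diagonal —
  a one-parameter compromise in which within- and between-period
  correlations differ but do not decay.

The within-period ICC is $\rho = \tau^2 / (\tau^2 + \sigma_\epsilon^2)$.

### Standardisation convention

The package fixes the total outcome variance at 1, so $\tau^2 = \rho$
and $\sigma_\epsilon^2 = 1 - \rho$. Design variances therefore refer to
outcomes in total-SD units and the `effect_size` parameter is the
standardised effect. This convention is the natural one for design work
(only $\rho$, $r$, `m` and the schematic matter for relative precision,
and power depends on the effect only through $\theta/\sqrt{var}$); users
with raw-scale effects should divide by the anticipated outcome SD.

## Design variance for incomplete designs

Cluster-period means $\bar Y_{kj}$ are sufficient for $\theta$ under this
model; their within-cluster covariance is
$V = (\sigma_\epsilon^2/m) I_{T\times T} + \tau^2 R$. For an incomplete
design each cluster contributes only its observed periods, encoded by a
selection matrix $Z_k$ (identity with unobserved rows deleted), giving
covariance block $V_k$ and treatment vector $X_k$. The GLS variance is

$$var(\hat\theta) = \Big\{ \sum_k X_k' V_k^{-1} X_k -
  \Big(\sum_k Z_k' V_k^{-1} X_k\Big)'
  \Big(\sum_k Z_k' V_k^{-1} Z_k\Big)^{-1}
  \Big(\sum_k Z_k' V_k^{-1} X_k\Big) \Big\}^{-1},$$

which reduces to the familiar complete-design expression when every cell
is observed (`sw_vartheta_complete()`; the package tests verify agreement
to 1e-10 relative and equality with the independently-coded
Hussey–Hughes closed form for the exchangeable case).

Numerical choices, in order of consequence:

* **Empty periods are dropped, not fatal.** Late in a removal path whole
  periods can lose all their measurements. Such periods carry no period
  effect parameter, so their rows/columns are deleted from
  $\sum_k Z_k'V_k^{-1}Z_k$ before inversion. Treating them as
  singularities would truncate the removal path prematurely: for the 4×5
  exchangeable example it is exactly this situation that allows the path
  to continue from the 6-cell staircase to the 4-cell minimally viable
  design.
* **Non-estimability is a value, not an exception.** The removal
  algorithm evaluates many candidate designs that destroy estimability;
  these return `estimable = FALSE` with infinite variance. Estimability
  fails when the period-effect information matrix is (near-)singular —
  detected by `rcond < 1e-12` — or when the bracketed scalar is below
  `1e-12` relative to its leading term. The relative 1e-12 threshold is
  two orders above double-precision noise at these problem sizes;
  genuinely estimable designs on the tested paths sit many orders of
  magnitude above it.
* **Solves, not inverses, where it matters.** Per-cluster blocks use
  Cholesky factorisations; the only explicit inverse is the per-cluster
  $V_k^{-1}$ needed to accumulate the information sums, which is
  symmetric PD by construction (eigenvalues at least
  $\sigma_\epsilon^2/m$).

A degenerate corner worth knowing: `T = 2` means a single cluster whose
treatment indicator coincides with the period-2 effect, so even the
complete design is non-estimable; `sw_reduce()` refuses it with an
explanatory error. `T = 3` is the smallest wedge with a removal path.

## Information content and the removal algorithm

Reflecting the schematic through its centre maps cell $(k, j)$ to
$(K+1-k, T+1-j)$; in a skew-symmetric design these centrosymmetric
partners carry complementary treatment labels and contribute equally to
the precision of $\hat\theta$. Cells are therefore removed in
centrosymmetric *pairs*, which preserves both centrosymmetry of the
observation mask and skew-symmetry of the observed design at every step
(both are asserted after every removal).

The information content of pair $A$ in design $D$ is
$IC_D(A) = var_{D[A]}(\hat\theta)/var_D(\hat\theta) \ge 1$. It is
computed by direct re-evaluation of the variance on the reduced design —
at $T \le 30$ an entire removal path costs well under a minute, and the
direct route eliminates the class of bugs that incremental rank-update
formulas invite. (The precision of a reduced design equals that of its
parent plus a non-positive constant; the tests assert this monotonicity
but the package does not exploit the constant computationally.)

`sw_reduce()` iterates: compute the IC of every remaining pair, remove
the pair with minimum finite IC, record variance, precision loss and
power; stop when every remaining pair has infinite IC (no removal keeps
$\theta$ estimable) or no pairs remain. Two decisions were genuinely
open:

* **Tie tolerance.** The exchangeable structure produces mathematically
  exact IC ties that differ in the last floating-point bits, so ICs
  within relative `1e-9` are treated as tied. The gap between true ties
  (relative differences below 1e-12) and genuinely distinct ICs (above
  1e-6 in all examined traces) is wide, so the path is insensitive to
  the exact threshold within that window.
* **Tie-break order.** Among tied pairs, the pair whose top-left member
  is smallest in cluster-major (cluster, then period) lexicographic
  order is removed — "closest to the top-left corner of the schematic".
  Period-major ordering is the other defensible reading; it changes only
  the order in which symmetric twins are removed, not the variance
  trajectory, for the configurations shipped in the tests.

Precision loss of a reduced design is the relative drop in precision,
$100(1 - var_{D_0}/var_{D_l})$ %, and power uses the two-sided normal
approximation $100\,\Phi(|\theta|/\sqrt{var} - z_{1-\alpha/2})$ % — the
opposite-tail term ($< 10^{-4}$ percentage points at conventional
powers) is omitted and no degrees-of-freedom correction is applied,
consistent with correlations being treated as known at the design stage.

## What the example configurations show

```{r example}
cfg <- sw_config(periods = 5, m = 90, rho = 0.14,
                 structure = "exchangeable", effect_size = 0.25)
trace <- sw_reduce(cfg)
round(as.data.frame(trace)[, c("iteration", "n_cells_remaining",
                               "precision_loss_pct", "power_pct")], 2)
```

Precision loss stays below 15% until half of the cells are gone, then
jumps sharply when the algorithm is forced to take the information-rich
cells: under exchangeability the off-diagonal corners act as "hot-spots"
(they anchor the long-range within-cluster comparisons), while under
discrete-time decay their correlation with the switch-adjacent cells has
decayed and the jump is milder. The half-removed designs resemble
staircase designs — each cluster measured in a run of periods around its
switch, sometimes plus the first/final periods — and are nearly as
powerful as the complete design.

`sw_sweep()` runs the same paths over a grid of configurations
(defaults: T ∈ {5, 10}, m ∈ {10, 100}, ρ ∈ {0.01, 0.05, 0.15},
r ∈ {1, 0.95, 0.8}; 36 configurations) and reports precision loss where
20%, 50% and 80% of cells have been removed. Pairs come out two cells at
a time, so a checkpoint is matched by the *first* design at or past it:
exact for 20 cells (2/5/8 pairs), while for 90 cells the 50% checkpoint
falls at 23 pairs = 51.11% removed. Checkpoints beyond the minimally
viable design are flagged `reached = FALSE` rather than treated as
errors.

## The simulator, and what passing tests do and do not show

`sw_simulate()` draws replicate trials directly from the mixed model
above (cluster-period random effects via the Cholesky factor of
$\tau^2 R$, individual errors aggregated into mean errors with variance
$\sigma_\epsilon^2/m$), and `sw_gls_fit()` estimates $\theta$ from one
replicate by solving the stacked GLS normal equations — an estimation
route independent of the per-cluster Schur-complement variance formula.
The test suite uses 20,000 replicates of a small incomplete design
(T = 4, m = 5, ρ = 0.1, r = 0.9) and checks the empirical variance of
$\hat\theta$ against the analytic value within three Monte-Carlo
standard errors, and 4,000 replicates for the covariance of
cluster-period means.

The simulator emulates exactly the assumptions of the design
calculations: equal cluster-period sizes, Gaussian outcomes, known
correlation parameters, categorical period effects, no treatment effect
heterogeneity. Real trials violate several of these — unequal cell
sizes, binary or skewed outcomes, uncertain ρ and r, effect
heterogeneity (which breaks the centrosymmetric equal-information
property itself). Passing tests therefore certify the design algebra
and the algorithm, not robustness of a chosen incomplete design to
model misspecification; a sensitivity sweep over ρ and r (for which
`sw_sweep()` is the tool) is the minimum due diligence before adopting
a reduced design.

## Known limitations

* One cluster per sequence (`K = T - 1`); replicated sequences,
  transition periods, cohort sampling with within-subject correlation,
  unequal cluster-period sizes and binary outcomes are out of scope.
* The removal algorithm is greedy: each step is optimal given the
  current design, but the path as a whole is not guaranteed to dominate
  every design of the same size.
* Power is a normal approximation; with very few clusters a
  t-correction would be less optimistic.
* IC values are reported for pairs; single-cell information content is
  not computed.
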
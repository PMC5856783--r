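---
title: "Comparing samples of networks: the model behind netanova"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing samples of networks: the model behind netanova}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netanova)
```

`netanova` tests whether several groups of labeled networks share the same
mean network and, when they do not, searches for the subnetwork that carries
the difference. This vignette is the package's own account of the method:
the statistic and its assumptions, how the normalization constant is
calibrated, how the searches and the auxiliary procedures are defined, which
knobs matter, and what the bundled simulator does and does not emulate.

## Networks as data points

All networks live on one fixed, ordered node set of size $n$; a network is
its adjacency matrix $A \in [0,1]^{n \times n}$, symmetric with zero
diagonal (binary networks use $\{0,1\}$). The only geometry imposed on this
space is the edit distance

$$d(G_1, G_2) = \sum_{i<j} \lvert A_1(i,j) - A_2(i,j)\rvert,$$

the number of links by which two binary networks differ. Three derived
quantities carry the whole method:

* the **mean network** $\mathcal{M}$, the entrywise average of the sample's
  adjacency matrices, whose entries are link proportions $\hat p_{ij}$;
* the **average distance** $\bar d_G(H)$ of a sample around a fixed network
  $H$ (which may be weighted, e.g. a mean network);
* the **variability** $\sigma = \bar d_G(\mathcal{M})$. For binary samples
  $\sigma = 2\sum_{i<j}\hat p_{ij}(1-\hat p_{ij})$ *exactly*; the test suite
  asserts this identity at tolerance $10^{-9}$. For weighted samples the
  identity is not exact and the package does not assume it.

Mean networks are kept in full double precision; matrices are validated on
entry (symmetry tolerance $10^{-8}$, zero diagonal, entries in $[0,1]$;
values outside $[0,1]$ are rejected rather than clipped, since the weighted
extension of the edit distance is defined only there). Directed networks
are rejected.

## The test statistic

For groups $i = 1..m$ of sizes $n_i \ge 2$ (pooled size $n$), the
unnormalized contrast is

$$S = \sqrt{m}\sum_{i=1}^m \sqrt{n_i}\left(\frac{n_i}{n_i-1}
\bar d_{G^i}(\mathcal{M}_i) - \frac{n}{n-1}\,\bar d_{G}(\mathcal{M}_i)\right),$$

where $\bar d_{G^i}$ averages over group $i$ only and $\bar d_G$ over the
pooled sample **including** group $i$ (the pooled reading of the notation),
both around group $i$'s mean network. The bias factors $n_i/(n_i-1)$ and
$n/(n-1)$ make $\mathbb{E}(S) = 0$ exactly under the null hypothesis that
all groups share one mean network; this is why every group must contain at
least two networks. The test statistic is $T = S/a$ with $a$ the null
standard deviation of $S$; under the null $T$ is asymptotically standard
normal, and any group difference drives it negative, so the test is
one-sided on the lower tail (default $\alpha = 0.05$, reject when
$T < -1.645$). Because every term of $S$ is a sum over unordered node
pairs, $S$ decomposes edge-wise; the identification machinery below depends
on this.

## Calibrating the constant $a$

Two calibrations are provided (`calibration()`):

**Analytic** (binary networks). Under the null with independent
Bernoulli($p_e$) links, the per-edge group terms of $S$ are exactly
quadratic polynomials in the centered group-mean deviations, so the
finite-sample variance of $S$ has a closed form in binomial moments; the
package evaluates it with the pooled link proportions plugged in. The test
suite validates this closed form against brute-force Monte Carlo simulation
of a single edge. The constant actually used is the *asymptotic truncation*
of that variance: writing the exact variance as
$V(\tau) = V_0 + V_1/\tau + V_2/\tau^2 + \cdots$ in a group-size scaling
$\tau$, the calibration keeps $V_0 + V_1$, estimated by Richardson
extrapolation of the exact formula at $\tau = 1, 2, 4$. The dropped
remainder is what makes the *published* statistic slightly over-dispersed in
small samples — with three groups of $K = 10$ networks the null SD of $T$
is about 1.07–1.10 rather than 1 (an acceptance test pins it in
$[1.0, 1.2]$), converging to 1 as $K$ grows (the suite checks SD
$\in [0.9, 1.1]$ at $K = 50$ over 2000 null replicates). Using the exact
finite-sample variance instead would standardize $T$ almost perfectly even
at $K = 10$; the truncated form is kept because it is the behaviour of the
statistic as published. p-values use the normal approximation; fits flag
`small_sample = TRUE` when the smallest group is below 30.

The analytic route assumes independent links across pairs under the null.
The simulator satisfies this by construction; real connectivity networks
need not, which is one reason the second calibration exists.

**Permutation.** $a$ is the standard deviation of $S$ over $B \ge 100$
random relabelings of the pooled sample (default $B = 500$, seedable,
bit-reproducible). This is assumption-free, exchangeability being exactly
what the null asserts, and it is the only mode for weighted networks. The
suite checks the two calibrations agree within 10% on null binary data; a
degenerate pooled sample (no link varies) raises a calibration error in
either mode — the test is undefined there, not zero.

## Identifying the differing subnetwork

The restricted statistic $T_{\tilde V}$ is the same $T$ computed on the
subnetworks induced by a node subset $\tilde V$ (or on a fixed link subset),
with $a$ **recalibrated on the restricted data** — both the observed $S$ and
the analytic variance are sums over the retained edges, so restriction is a
subset-sum and the values stay null-standardized, hence comparable across
subset sizes. This choice (rather than reusing the full-network $a$) is
deliberate: with a fixed denominator the per-size minima can only creep
downward as subsets grow and the stopping rule below loses its meaning; in
simulation the fixed-denominator variant systematically selects oversized
subnetworks.

For each size $j$, $T_j$ is the minimum of $T_{\tilde V}$ over all
$\binom{n}{j}$ subsets when that count is within the evaluation budget
(default $2\times10^5$; for the package's 16-node layouts the entire path
$j = 2..16$ is exhaustive, 65,534 subsets), and otherwise a deterministic
greedy forward selection from the best pair refined by single-node swap
hill-climbing. Exhaustive enumeration is vectorized: per size, the
within-subset edge sums of $S$ and of the variance are obtained by one
matrix product against a cached node-membership matrix. Ties between
subsets are broken lexicographically, so results are independent of node
input order. Subsets on which the restricted calibration is degenerate are
treated as non-informative ($T = +\infty$). The selected size is

$$\tilde\jmath = \max\{\, j \ge 3 : T_j - T_{j-1} < -g \,\},$$

taken literally also for non-monotone paths, with "no qualifying $j$"
reported as an explicit no-subnetwork outcome rather than an error. The
threshold $g$ is a user parameter, default $0.25$; it should shrink with
sample size, but no general formula is imposed — in practice one also reads
the $T_j$ curve (`autoplot()`) like a scree plot. Link-set search
(`best_link_set()`) faces a $2^{n(n-1)/2}$ space, so it is greedy
forward/backward only and documented as approximate; node search is the
recommended identification route.

## The link-wise comparator

`links_test()` is the baseline the ANOVA is measured against: for every
node pair, a $\chi^2$ homogeneity test (no continuity correction) on the
$m \times 2$ table of link presence counts; pairs whose link is present in
all or absent from all networks carry no information and receive $p = 1$ by
convention, and only informative pairs enter the Benjamini–Hochberg
multiplicity. The groups are declared different when at least one link
survives BH at level $\alpha$. The $\chi^2$ choice (over, say, Fisher) is
the standard $m$-sample proportions test and behaves smoothly under
permutation; the suite verifies the power *ordering* — the network ANOVA
dominates the links test on the planted model — which is the qualitative
claim that any reasonable proportion test reproduces.

## From correlation matrices to networks, and W₃

Per-subject correlation matrices are binarized by two criteria: a fixed
correlation threshold $\rho$ (positive branch keeps $\ge \rho$, negative
branch $\le \rho$; $\rho = 0$ is rejected as ambiguous), or a fixed number
of links $L$ (the $L$ largest, or most negative, correlations; ties broken
by absolute value then lexicographic pair order, so the result always has
exactly $L$ links). Fixed-$\rho$ networks are nested in $\rho$ and
fixed-$L$ networks in $L$, which the suite asserts.

Because any single threshold is arbitrary, `t_over_grid()` scans four
branches — $\rho_+$, $\rho_-$, $L_+$, $L_-$ — and `w3_statistic()` counts,
per branch, grid points with $T < -3$ (a level a standard normal exceeds
with probability 0.00135), taking $W_3$ as the minimum count over branches:
an effect is only credited if it shows up robustly under *every* way of
building the networks. Defaults: 10 points per branch, $\rho_+$ spanning
0.05–0.5 (mirrored negatively), $L$ branches spanning 5–50% of all pairs —
the grids are configurable and only implicitly constrained by the worked
branch counts they must be able to produce. The null distribution of $W_3$
comes from resampling: group labels are permuted without replacement
(keeping each subject's matrix intact and the group sizes fixed), the
thresholded networks being built once and reused; a with-replacement
bootstrap of subjects is available behind a flag. Grid points whose
networks are degenerate yield `NA` and never count toward $\Delta$. The Ψ
network (`psi_network()`) is the entrywise mean absolute deviation of the
group mean networks from their across-group average — zero exactly where
the means agree. `group_by_tertiles()` reproduces the Low/Medium/High
grouping of a covariate at the 33.3% percentiles (type-1 quantiles, ties
assigned downward deterministically; constant covariates are an error).

## The geometric simulator

`geometric_model()` links each node pair independently with probability
$e^{-\lambda d(i,j)}$ on a 2-D layout; a planted node subset uses a
group-specific decay rate $\lambda_i$, so groups differ only inside the
planted subnetwork. The bundled `scalp16` layout is a synthetic 16-channel
EEG-style montage (unit nearest-neighbour spacing; rows Fp1 Fp2 / F7 F3 F4
F8 / T3 C3 C4 T4 / T5 P3 P4 T6 / O1 O2) with the six frontal electrodes
planted; real electrode coordinates can be supplied via `network_layout()`.
Default decay rates are $\lambda = 1/0.8/0.6$ (the "weak" operating point)
with $1/0.66/0.5$ as the stronger variant used by the identification
study — at the weak contrast the per-size search is dominated by selection
noise and no stable size-selection regime exists, while the strong contrast
yields modal size 6 with exact recovery of the planted set whenever size 6
is selected.

The simulator emulates *localized* group differences with independent
links — the setting where the analytic calibration is exact — and none of
the features of real connectivity data: dependent edges, subject-level
heterogeneity beyond link probabilities, unlocalized or global
modifications, measurement artefacts. Passing the simulation suite
therefore validates the machinery and its calibration contract, not
performance on any particular real dataset; for real data the permutation
calibration and the $W_3$ robustness analysis are the conservative path.

Experiment harnesses (`power_experiment()`, `type1_experiment()`,
`identification_experiment()`) derive one sub-seed per replicate from a
single user seed, making every experiment bit-reproducible. Problem sizes
used by the bundled acceptance runs: power at 500 replicates (three groups
of $K \in \{30, 100\}$ networks on 16 nodes), null calibration at 2000
replicates ($K \in \{10, 30\}$), identification at 50 replicates with the
exhaustive path — about half a minute in total; published replicate counts
(10,000; 50) are the defaults users can restore at leisure.

## Known limitations

* The normal approximation for $T$ is anti-conservative below group sizes
  of about 30 (null SD $\approx 1.07$–$1.1$ at $K = 10$); fits carry a
  `small_sample` flag, and the permutation calibration does not remove this
  (it estimates the SD of $S$, not the shape of $T$).
* Exact recovery of a weakly-expressed planted subnetwork at small $K$ is
  intrinsically hard: the per-size minimizer's selection noise lets mixed
  subsets undercut the true set, so the selected size scatters. The
  identification experiment reports size histograms and conditional
  recovery so this regime is visible rather than averaged away.
* The analytic calibration assumes independent links under the null; use
  the permutation mode when that is implausible.
* $g$ has no automatic sample-size adaptation; treat the default 0.25 as a
  starting point and inspect the $T_j$ curve.
* Node sets must match exactly across subjects; there is no registration or
  matching of differing parcellations.
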
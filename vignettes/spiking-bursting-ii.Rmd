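---
title: "Integrated information in the spiking–bursting model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated information in the spiking–bursting model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeburst)
```

## The model and its assumptions

`spikeburst` analyzes a binary vector process $\xi(t)$ over $N$ nodes in
discrete time bins. Its generative structure is a two-layer combination
$M = \{V, S\}$:

* a hidden, system-wide **dichotomous component** $V$ that is *spiking*
  with probability $p_s$ and *bursting* with probability $p_b = 1 - p_s$,
  time-correlated between the two analysis times;
* a **spontaneous spiking component** $S$: while $V$ is spiking, the
  observed word $x$ is drawn from a distribution $s_x$ over the $2^N$
  words, independently across time; while $V$ is bursting, $x$ is the
  all-ones word.

This is the minimal discrete abstraction of neuron–astrocyte dynamics in
which a slow glial variable intermittently locks the whole network into a
burst, on top of temporally unstructured background spiking. The one-time
law is $p(x \neq \mathbf{1}) = p_s s_x$, $p(\mathbf{1}) = p_s s_1 + p_b$,
where $s_1$ (the probability of a spontaneous *system-wide simultaneous
spike*) is the single number through which the spiking table enters every
information quantity. Two-time joints follow from the $2\times2$ table of
$V$ and the factorization $s_{xy} = s_x s_y$.

Two modelling assumptions matter for interpretation:

1. **Single-lag specification.** The model fixes the pair distribution at
   one analysis lag $\tau$ only. All exact tables and closed forms are
   statements about that lag; nothing is implied about other lags.
2. **Stationarity,** which forces the $2\times2$ table of $V$ to be
   symmetric ($p_{sb} = p_{bs}$).

## Parameters

| parameter | meaning | range | notes |
|---|---|---|---|
| $p_s$ | probability of the spontaneous (spiking) state | $(0, 1)$ | boundary values are degenerate |
| $\varepsilon$ | scaling-invariant time-correlation parameter, $p_{ss} = p_s^2(1+\varepsilon)$ | $[0,\, p_b/p_s]$ | $\varepsilon = \rho\, p_b/p_s$ with $\rho$ the Pearson time-delayed correlation; negative correlations are not supported |
| $s_x$ | spontaneous word distribution | simplex over $2^N$ words | independent-node constructor available |
| $s_1$ | spontaneous all-ones probability | $[0, 1]$ | derived from $s_x$ |

All informations are in bits (base-2 logarithms, $\{q\} = -q\log_2 q$,
$\{0\} = 0$). The admissibility constraint $p_s \le 1/(1+\varepsilon)$
(equivalently $\varepsilon \le p_b/p_s$) is exactly the non-negativity of
the off-diagonal cell $p_{sb}$; the boundary is admitted and corresponds
to a perfectly persistent hidden state.

The parameterization is deliberately redundant: bursts and system-wide
simultaneous spikes are indistinguishable in realizations, so the
one-parameter scaling $s'_{x\neq\mathbf 1} = s_x/\alpha$,
$1 - s_1' = (1-s_1)/\alpha$, $p_s' = \alpha p_s$,
$p'_{s's'} = \alpha^2 p_{ss}$ leaves the observable process unchanged.
`scaling_transform()` implements it, `admissible_alpha()` reports the
valid interval, and $\varepsilon$ is the natural correlation parameter
precisely because it is invariant under this scaling.

## Information measures

*Whole-minus-sum.* For states $x = \xi(t)$, $y = \xi(t+\tau)$ and a
bipartition $AB$,
$\Phi_\mathrm{eff}(AB) = I_{xy} - I_{x_A y_A} - I_{x_B y_B}$, and
$\Phi = \Phi_\mathrm{eff}(AB_\mathrm{MIB})$ where the minimum-information
bipartition minimizes $\Phi_\mathrm{eff}/\min\{H(x_A), H(x_B)\}$ over all
$2^{N-1}-1$ bipartitions (exhaustive enumeration, capped at $N \le 12$ by
default). Everything reduces to the universal function
$I_0(p_s, \varepsilon)$ — the mutual information of the dichotomous
component — through $I_{xy} = I_0((1-s_1)p_s, \varepsilon)$ and the
analogous subsystem expressions with $s_A$, $s_B$.

*Sign analysis.* Under spatially independent spiking,
$\Phi_\mathrm{eff} = f(s_A)$ with
$f(s) = I_0((1-s_1)p_s) - I_0((1-s)p_s) - I_0((1-s_1/s)p_s)$ on
$s_1 < s < 1$, symmetric under $s \mapsto s_1/s$. The symmetric-point
value $g(s_1) = f(\sqrt{s_1})$ controls the sign of $\Phi$: $g$ is
negative at $s_1 = 0$, tends to $+0$ as $s_1 \to 1$, and (numerically)
crosses zero exactly once, at the threshold `s1min_exact()`. In the
weak-correlation limit
$I_0 \approx \varepsilon^2/(2\ln 2)\,(p_s/(1-p_s))^2$, so
$g(s_1) = 0$ reduces to the quadratic
$(\sqrt2-1)\,p_s u^2 - u + (\sqrt2-1)(1-p_s) = 0$ in $u = \sqrt{s_1}$
(`s1min_asymptotic()`), whose $p_s \to 0$ limit $3 - 2\sqrt2 \approx 0.17$
is the universal supremum of the threshold. Both measures scale as
$\varepsilon^2$ in this regime, which leaves the sign — and hence the
threshold — unaffected by $\varepsilon$.

*Decoder-based.* $\Phi^*(AB) = I_{xy} - I^*(AB)$, where $I^*$ maximizes
over a scalar decoding exponent $\beta \ge 0$ the mismatched-decoding
objective built from the factorized conditional
$q_{AB}(y|x) = p(y_A|x_A)\,p(y_B|x_B)$. $\Phi^*$ is non-negative by
construction and is evaluated here (as in comparative practice) on the
symmetric bipartition of an even-$N$ equal-node system, where
$\Phi_\mathrm{eff} = g(s_1)$ exactly.

## Numerical choices

* **Cancellation-stable $I_0$.** The defining entropy-difference form of
  $I_0$ loses all significant digits when its first argument is small
  (the result is $O(\varepsilon^2 p_s^2)$ while individual entropies are
  $O(p_s \log p_s)$ — catastrophic already near $p_s \sim 10^{-5}$, which
  the $s_1 \to 1$ limits probe). `i0()` therefore evaluates the
  algebraically identical Kullback–Leibler arrangement
  $\sum_{ij} p_{ij} \log_2\!\big(p_{ij}/(p_i p_j)\big)$ with `log1p`;
  tests pin it against generic mutual information of the $2\times2$
  table at $10^{-12}$.
* **Degenerate parameters.** $s_1 = 1$, $p_s \in \{0, 1\}$ or
  $\varepsilon = 0$ give zero mutual information identically; table
  builders accept them and the closed forms return 0 via an internal
  continuity extension of $I_0$ (argument 0 or 1 $\mapsto$ 0 bits) rather
  than evaluating $0\log 0$.
* **Zero-entropy normalization.** The MIB normalization is undefined for
  a zero-entropy subsystem; such bipartitions are excluded from the
  argmin (treated as $+\infty$), and if all are excluded $\Phi = 0$ with
  a `degenerate` flag. Ties break to the smallest canonical A-mask, and
  enumeration order makes this deterministic.
* **Root finding.** `s1min_exact()` scans $g$ on a $10^{-3}$-step grid,
  log-refined near 0 down to $10^{-12}$ because the root falls below
  $10^{-3}$ as $p_s \to 1$; it requires exactly one sign change (an
  anomaly error otherwise — uniqueness is verified over the full
  $p_s \in [0.01, 0.99]$, $\rho \in [0.01, 1]$ grid at step 0.01 in the
  test suite, but is not proven) and polishes the bracket with
  `uniroot()` to $10^{-12}$. The same guard logic protects `f_curve()`
  analyses from the unproven possibility of five or more extrema.
* **$\beta$ maximization.** The objective is evaluated in the log domain
  (column-wise log-sum-exp): $q(y|x)^\beta$ underflows at moderate
  $\beta$ already for $N = 6$. The search covers $[0, 100]$ with a
  log-spaced-plus-linear grid of 64 points, refines the best bracket with
  `optimize()` to $10^{-8}$ in $\beta$, and keeps the larger of grid and
  refined values — the admissible $\beta$ range and the unimodality of
  the objective are not specified by the theory, so the grid acts as a
  safeguard rather than an assumption. The objective is exactly 0 at
  $\beta = 0$, which anchors $I^* \ge 0$.
* **Probability hygiene.** Generated tables are validated to sum to 1
  within $10^{-12}$; round-off in $[-10^{-12}, 0)$ is clamped to 0.
  User-supplied tables get a looser $10^{-8}$ gate and exact
  renormalization.
* **Word encoding.** Node $i$ is bit $i-1$ of the word index (node 1 =
  least significant); labels print node 1 leftmost. This is fixed and
  shared by tables, realizations and bipartition masks.
* **Weak-correlation validity flag.** The approximation's applicability
  region is encoded as the strict inequalities $|\varepsilon| < 1$ and
  $p_s < 1/(1+|\varepsilon|)$; these are hard boundaries of the estimate,
  and how much margin "much less than" requires is left to the user (the
  flag is informational, never blocking).

## The simulator: what it does and does not emulate

The model constrains only the single-lag pair distribution of $V$. The
simulator realizes the **minimal first-order Markov completion**: a
stationary two-state chain started from $(p_s, p_b)$ with stay
probabilities $p_{ss}/p_s$ and $p_{bb}/p_b$, whose one-step joint equals
the exact $2\times2$ table. Consequences:

* empirical analysis defaults to $\tau = 1$; at larger lags the chain's
  effective correlation decays geometrically, and lag-$\tau$ analysis of
  simulated data reflects the chain, not the single-lag table re-imposed
  at $\tau$;
* burst labeling ambiguity never arises in analysis, because all measures
  use raw observed words.

Spiking words are drawn per-node for independent tables and by
inverse-CDF over the $2^N$ table otherwise; identical seeds give
identical realizations. What the generator deliberately does **not**
emulate: continuous-time burst durations, sub-bin spike timing, spatial
patterns within bursts, and causal coupling between the spiking and
bursting subsystems. Passing plug-in convergence tests therefore shows
estimator correctness on the model's own stationary statistics, not
fidelity to any particular biological recording.

Plug-in estimates carry the usual positive bias of entropy-based
quantities, of order $2^{2N}/T$ cells per mutual information; the
convergence checks in the test suite use $N = 3$, $T = 10^5$ (total
variation $\le 0.01$ against the exact tables) and seed replication where
spread matters. These sizes were chosen as the smallest at which the
multinomial sampling error is comfortably below the quantities being
checked.

## Design choices where the theory is open

* **MIB tie-breaking and zero-entropy handling** (above) are this
  package's conventions; the defining formula specifies neither.
* **$\beta$ domain $[0, 100]$** with grid verification: the theory does
  not state an admissible range or uniqueness of the maximizer. For all
  interior parameters explored, the maximizer lies well inside (typically
  $\beta \in (0.7, 1)$).
* **Positivity conditions for correlated spiking** are reported
  directionally only: with positive spatial correlation
  ($s_1 > s_A s_B$) effective information is bounded above by the
  independent-case $f(s_A)$, so only necessary-condition logic survives;
  with negative correlation, only sufficient-condition logic. `"auto"`
  mode detects independence by comparing $s_1$ with $s_A s_B$ across
  bipartitions at $10^{-9}$.
* **Per-figure sweep grids** default to logarithmic spacing near
  $s_1 = 0$ (where the sign transition lives) and linear spacing near 1.

## Known limitations

* Negative time correlations ($\varepsilon < 0$) are rejected; the
  closed-form analysis is developed for $\varepsilon \ge 0$ only.
* Exhaustive bipartition enumeration limits exact MIB search to
  $N \le 12$ (configurable); no heuristic search is provided.
* Uniqueness of the $g$ sign change and the at-most-three-extrema
  property of $f$ are verified numerically on a dense grid, not proven;
  the code raises anomaly errors rather than silently picking a root if
  either fails.
* $\Phi^*$ is computed for a supplied bipartition (by default the
  symmetric one in sweeps, or the whole-minus-sum MIB in empirical
  analysis); a dedicated $\Phi^*$-MIB search is intentionally out of
  scope.

## A compact session

```{r example}
m <- spiking_bursting_model(independent_spike_table(rep(0.1^(1/6), 6)),
                            ps = 0.6, eps = 0.1)
r <- mib_phi(m)
r
phi_star(m, bipartition(1:3, 6))
c(exact = s1min_exact(0.6, 0.1), asymptotic = s1min_asymptotic(0.6))
```

The symmetric 3|3 bipartition reproduces `g(s1)` exactly:

```{r gcheck}
all.equal(effective_information(m, bipartition(1:3, 6)), g_fn(0.1, 0.6, 0.1))
```
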
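---
title: "Rank tests for non-decreasing ordered alternatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank tests for non-decreasing ordered alternatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktmb)
```

## The problem

Many clinical and epidemiological group factors are ordinal: tumour stages,
dose levels, exposure categories. With $k \ge 3$ independent samples
$x_{i1}, \dots, x_{in_i}$ from continuous distributions $F_i$, the question
is rarely "are the groups different?" but "does the response increase with
the group order?". The hypotheses are

$$H_0: F_1 = F_2 = \cdots = F_k \qquad \text{vs} \qquad
  H_1: F_1 \ge F_2 \ge \cdots \ge F_k,$$

with at least one strict inequality — group 1 stochastically smallest. The
group order is part of the hypothesis: `ktmb` never sorts labels for you,
and every reader/constructor demands the order explicitly, because a
silently mis-ordered factor is precisely the failure mode these tests are
meant to expose.

## The statistics

All five tests in the battery are rank statistics built either from
pairwise comparisons or from *k-tuplets* (one observation drawn from each
group; there are $N^* = \prod_i n_i$ of them).

* **KTMB** — the package's core statistic. For a tuplet
  $(x_1, \dots, x_k)$, let $R(x_i)$ be the rank of $x_i$ within the tuplet.
  The kernel counts correctly placed observations,
  $h(x_1,\dots,x_k) = \sum_i I\{R(x_i) = i\}$ — the number of fixed points
  of the tuplet's rank permutation — and
  $T = \sum_{\text{tuplets}} h$. A tie-free kernel value lies in
  $\{0,\dots,k\} \setminus \{k-1\}$ (a permutation cannot fix exactly
  $k - 1$ points). Under $H_0$ the kernel has mean 1 and variance 1 (the
  fixed-point distribution of a uniform permutation), so
  $E_0[T] = \prod_i n_i$.
* **TM** — same tuplet sum with the ascending-indicator kernel
  $I\{x_1 \le \cdots \le x_k,\ \text{at least one strict}\}$.
* **KTP** — tuplet sum of the Spearman rank correlation between the
  within-tuplet ranks and the group indices $1,\dots,k$.
* **JT / MJT** — sums of pairwise Mann–Whitney counts
  $U_{lm} = \#\{x_{la} < x_{mb}\}$ over $l < m$, unweighted (JT) or
  weighted by $m - l$ (MJT).

Each is location-free and invariant under strictly increasing
transformations of the response.

## Exact null distributions and moments

Under $H_0$ with continuous data, conditioning on the pooled ranks makes
every assignment of ranks $1..N$ to groups (respecting the sizes) equally
likely — there are $N!/(n_1! \cdots n_k!)$ such rank partitions.

`enumerate_null_pmf()` visits every partition and tallies the exact PMF.
Probabilities are stored as integer counts over the common denominator, so
they are exact rationals and sum to one identically. For the design
$(2,1,1)$, for example, the KTMB statistic has support
$\{0,1,2,3,4,6\}$ with counts $(2,3,4,1,1,1)/12$, mean $2$ and variance
$8/3$.

Full enumeration scales as the partition count, so
`exact_null_moments()` provides exact moments for arbitrary sizes by a
covariance decomposition: the variance of a tuplet sum is the sum of
$\mathrm{Cov}(h_a, h_b)$ over ordered tuplet pairs, and that covariance
depends only on the set $S$ of coordinates where the two tuplets share an
observation. Pairs sharing nothing are independent; for each non-empty
$S$ the covariance is an exact average over the $(2k - |S|)!$ relative
orderings of the pair's distinct observations, and the number of pairs
with pattern $S$ is $\prod_{i \in S} n_i \prod_{i \notin S} n_i(n_i-1)$.
The per-pattern enumeration is memoised per $(k, S, \text{kernel})$, and
the whole decomposition is validated against full enumeration across a
grid of designs (all size vectors with $N \le 9$, $k \in \{3,4\}$ and at
most $10^4$ partitions — comfortably covering every shape class at desk
scale) to $10^{-10}$.

JT and MJT use closed forms: the classical
$E_0 = (N^2 - \sum n_i^2)/4$,
$V_0 = [N^2(2N+3) - \sum n_i^2(2n_i+3)]/72$ for JT, and for MJT the exact
pairwise Mann–Whitney covariances
($n_l n_m (n_l + n_m + 1)/12$ on the diagonal, $\pm n_a n_b n_c / 12$ for
counts sharing one group, sign depending on whether the shared group sits
on the same side of both comparisons). Both are verified against
enumeration for every shape with $N \le 7$ in the test suite. We chose the
closed form over a Monte Carlo default for MJT because it is exact, instant
and independently checkable.

`mc_null_moments()` is the seeded Monte Carlo fallback for designs beyond
both exact engines (in practice only $k > 5$, where the heaviest
tie-pattern enumeration would need $(2k-1)!$ orderings).

## Inference: asymptotic and calibrated decisions

`ordered_trend_test()` standardizes the observed statistic,
$z = (T - E_0[T])/\sqrt{V_0[T]}$, and reports the one-sided upper-tail
normal p-value, rejecting when $z \ge z_{1-\alpha}$. No continuity
correction is applied. This is the right large-sample tool, but rank
statistics are discrete, and at small sizes the plain normal rule is
*anticonservative* for the tuple statistics: the test suite computes its
exact size from the enumerated null PMF and finds it well above the
nominal level already at three groups of three.

The simulation engine therefore defaults to the calibrated small-sample
rule (`decision = "exact"` in `estimate_power()`): the canonical
randomized exact level-$\alpha$ test, which rejects when $T > c$ and with
probability $\gamma$ when $T = c$, where $c$ and $\gamma \in [0,1)$ solve
$P_0(T > c) + \gamma P_0(T = c) = \alpha$. `null_critical_region()` builds
$(c, \gamma)$ from the enumerated null PMF when the partition count allows
(up to $5 \times 10^4$ by default) and from a seeded Monte Carlo null
sample of $10^5$ rank partitions otherwise. This rule holds the type-I
error at $\alpha$ exactly regardless of discreteness — which is what a
power study must do for its power columns to be comparable across tests —
and it converges to the asymptotic rule as $N$ grows. The asymptotic rule
remains available as `decision = "asymptotic"` for studying the normal
approximation itself.

## The simulation engine

`power_scenario()` encodes the study conditions of the package's
reference simulation design: the location-shift model
$X_{ij} = \theta_i + \varepsilon_{ij}$ with $\varepsilon_{ij}$ iid
log-F$(d_1, d_2)$ — the natural logarithm of an F variate, with
$(d_1, d_2)$ read as (numerator, denominator) degrees of freedom. Equal
df give a symmetric error distribution (if $X \sim F(d,d)$ then
$1/X \sim F(d,d)$, so $\log X$ is symmetric about 0); the pairs
$(2, 4.5)$, $(4.5, 4.5)$ and $(10, 4.5)$ span right-skewed to
left-skewed noise. The study grid uses $k = 3$ and $4$, group sizes 4,
5, 8 and 10, location shifts $\theta_i \in \{0, 0.25, 0.5, 0.75, 1,
1.25\}$ (including deliberately mis-ordered patterns such as
$(0.25, 0.75, 0)$), $\alpha = 0.05$ and 10,000 replicates per scenario —
defaults chosen to match the reference design, not tuning knobs.

Replicates are seeded by a counter scheme on (base seed, scenario id,
replicate index), so any replicate can be regenerated in isolation and
scenarios can be distributed without shared state; all requested tests
see the same simulated datasets, which sharply reduces the Monte Carlo
variance of power *differences*. `dp_metrics()` reports the two relative
power summaries used to compare the tests: the gain of KTMB over TM,
$(\mathrm{KTMB} - \mathrm{TM})/\mathrm{TM}$, and the loss against the
best competitor, $(\min(\mathrm{KTP}, \mathrm{JT}, \mathrm{MJT},
\mathrm{TM}) - \mathrm{KTMB})/\mathrm{KTMB}$, both as percentages.

What the generator emulates — and what it does not: continuous responses
(ties have probability zero), identically shaped groups differing only in
location, and independence throughout. Real ordinal-outcome data can
carry ties, heteroscedasticity and cluster structure; passing tests under
this generator demonstrate correctness of the statistics, moments and
calibration under the location-shift model, not robustness to those
departures. Ties in observed data are handled deterministically
(min-ranks for KTMB, non-strict chain for TM, average ranks for KTP,
strict comparisons for JT/MJT) and always flagged with a warning, since
the null theory assumes they are absent.

## Numerical choices

* Tuple enumeration is lexicographic in the index vectors and capped at
  $10^7$ tuplets (`options(ktmb.tuple_budget=)`); exceeding it is an error
  naming the flag, never a silent grind.
* Full-PMF enumeration is capped at $10^6$ partitions; the automatic
  moment policy prefers enumeration up to $10^4$ partitions and the
  tie-pattern decomposition beyond (both exact; the decomposition is
  orders of magnitude cheaper), Monte Carlo only past the $k \le 5$
  tie-pattern cap.
* A degenerate tuplet (all values tied) scores 0 under the KTP kernel:
  zero rank variance carries no trend evidence.
* Randomization at the critical value uses one uniform draw per test per
  replicate from the replicate's own seeded stream.
* All user-facing Monte Carlo routines take and record an explicit seed
  and restore the session RNG state on exit.

## Limitations

* One-sided, non-decreasing alternatives only; umbrella or two-sided
  orderings are out of scope, as are MJT weights other than $m - l$.
* P-values from `ordered_trend_test()` are asymptotic; for very small
  designs, read them against the exact PMF (or use the calibrated
  critical region) rather than at face value.
* Exact conditional p-values by permutation of the observed data are not
  provided; inference follows the null-moment standardization.
* The tie-pattern engine is exact but enumeration-based; $k > 5$ falls
  back to Monte Carlo moments with a warning.
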
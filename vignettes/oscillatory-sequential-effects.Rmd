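---
title: "Modeling sequential effects as oscillatory mode-locking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sequential effects as oscillatory mode-locking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fareyscan)
```

## The model

In a two-alternative forced-choice task the two response fingers act as a
pair of coupled oscillators: each button press-and-release is one cycle, and
the randomized stimulus sequence is a driving signal that demands an R or an
L cycle on every trial. `fareyscan` treats the relative phase $\phi \in
[0,1)$ of the two fingers as evolving under a discretized
Haken–Kelso–Bunz (HKB) circle map,

$$\phi_{n+1} = \phi_n + \Omega - \frac{K}{2\pi}\,
  \bigl(1 + A\cos 2\pi\phi_n\bigr)\,\sin 2\pi\phi_n \pmod 1,$$

whose coupling term equals $\sin 2\pi\phi + (A/2)\sin 4\pi\phi$ — the
standard two-attractor HKB gradient with an in-phase attractor at $\phi = 0$
and an antiphase attractor at $\phi = 1/2$ whose relative prominence is $A$.

* $\Omega$ (dimensionless) is the driving frequency ratio. Here it is the
  decimal value of a trial history's Farey fraction.
* $K \ge 0$ is the coupling strength between the fingers. Default 0.95:
  strong coupling produces wide Arnold tongues and a connected staircase,
  which is what makes the model's latency predictions sharp.
* $A \in [0,1]$ weights the antiphase attractor. Default 0.85: just below
  the threshold at which antiphase coordination stabilizes outright, so
  alternation-related resonances are available but not dominant.

The **rotation number** $\rho = p/q$ (average rotations per iteration)
summarizes the entrainment a drive $\Omega$ produces; plotted over a grid of
$\Omega$ it forms the Devil's staircase whose plateau at $p/q$ is that
ratio's Arnold tongue. `rotation_number()` seeds $\phi_0$ uniformly at
random, iterates with the modulus-1 operator disabled, and averages the
per-iteration phase advance over the final `n_avg` steps,
$(\phi_N - \phi_{N-n_\mathrm{avg}})/n_\mathrm{avg}$, with the preceding
iterations discarded as transient. Averaging *increments* rather than raw
unwrapped phases is the only reading under which the average has a
rotation-number interpretation; raw unwrapped phases grow like
$n\rho$ and their mean depends on the window location, not the dynamics.
Defaults — 10,000 iterations, final 2,500 averaged, grid $0$ to $1$ in
steps of $0.001$ — match the bifurcation-surface recipe (10,000 iterations,
final 100 phases retained, 1,000 drive values).

### Chaos at the default parameters, and what the staircase tests can show

At $K = 0.95$, $A = 0.85$ the map is **non-invertible**: the coupling term's
slope reaches $K(1+A) \approx 1.76 > 1$. The dynamics are therefore chaotic
in the windows where neighboring Arnold tongues overlap (empirically
$\Omega \approx 0.19$–$0.30$ and its mirror image), and three textbook
properties of the staircase hold only for invertible (subcritical)
parameter sets, $K(1+A) < 1$:

1. monotonicity of $\rho(\Omega)$,
2. the odd-coupling symmetry $\rho(\Omega) + \rho(1-\Omega) = 1$ at the
   single-orbit level, and
3. seed-independence of $\rho$ (uniqueness of the rotation number).

The package's property tests assert all three at $K = 0.4$, where they are
theorems. At the chaotic defaults the computed staircase shows genuine
dips of up to $\approx 0.08$ in the overlap windows, and basins depend on
the seed phase. One concrete consequence: the drive $\Omega = 0.618$ (the
golden ratio) lies inside the 2/3 tongue's basin at these parameters — every
random seed phase yields $\rho = 2/3$, not the Fibonacci-quotient
$8/13 \approx 0.615$ that a subcritical map would lock to; orbits with
$\rho \approx 8/13$ appear near $\Omega \approx 0.610$ instead. The
acceptance test that states the textbook shape properties at the default
parameters documents these violations rather than hiding them.

The **circular mean** used to summarize retained bifurcation phases respects
the adjacency of 0 and 1 (mean resultant vector at angles $2\pi\phi$); an
exact 0 is reported as 1, the same convention used to wrap L-leading drive
values.

## Trial histories on the Farey tree

A trial history is the ordered stimulus identities of the current and up to
four preceding trials, oldest first, and R-leading histories (those starting
with R) name nodes of the Farey tree grown from seeds 0/1 and 1/1 by the
mediant operation $(a/b) \oplus (c/d) = (a+c)/(b+d)$. The root (history
"R") is 1/2; appending a more recent R descends toward the lower bracketing
parent and L toward the upper, so e.g. R, RR, RRR, RRRL visits 1/2, 1/3,
1/4, 2/7. Sorting nodes ascending by level and descending by magnitude
within level assigns each node a rank whose binary digits spell its history
under 1 → R, 0 → L (2/7 ranks 14th, binary 1110 = RRRL; 8/13 ranks 21st,
binary 10101 = RLRLR). Note the digit convention is deliberately the
reverse of many popular Farey-tree accounts, which letter branches by
left/right position on the diagram; both printed anchors pin the convention
used here. L-leading histories live on the right half of the Stern–Brocot
tree and are obtained by duality: swap letters, resolve, take the
reciprocal (LL → RR → 1/3 → 3/1). Their values exceed 1; since the map's
dynamics repeat for each integer increase in $\Omega$, `history_omega()`
wraps them modulo 1 with exact 0 reported as 1.

```{r farey}
tree <- build_farey_tree(5)
subset(tree, history %in% c("RRRL", "RLRLR"))
golden_path(5)
```

## Scanning trial streams

`analyze_streams()` classifies windows by **stimulus** identity (the
response the stimulus demands), not the registered response — otherwise an
erroneous trial could never be a member of a named sequence type, and the
unique-error bookkeeping below would be incoherent. All overlapping windows
count: six correct R trials contain six "R", five "RR", …, two "RRRRR"
occurrences.

* **Mean RTs** use only occurrences whose members are *all* correct and all
  inside the censorship bounds (default 200–980 ms, applied to every member
  trial). The default `terminal` mode averages each valid occurrence's
  final-member RT — the sequential-effects convention of conditioning trial
  $n$'s latency on its history. An `all` mode pooling every member RT is
  provided because either reading of "mean response times were computed
  using the responses from the sequences" is defensible.
* **Unique-error rates** divide the number of *distinct* erroneous member
  trials by member observations counted with multiplicity
  ($|h| \times n_\mathrm{occ}$); 56 distinct errors across 185 length-5
  occurrences give $56/925 = 0.0605$.
* Per participant, the 31 means are unit-normalized,
  $(\bar X_i - \min)/(\max - \min)$; the grand table averages normalized
  means and error rates across participants, dropping (with a warning)
  participants missing a history. Missing values propagate as `NA`, never
  zero, and are deleted pairwise in the statistics with the effective $n$
  used in the degrees of freedom.

Streams are analyzed as single contiguous runs per participant; buffer
trials are removed upstream via `read_trials(drop_first_n = )`.

## The inferential battery

Every Pearson-type report carries the exact conversion
$F = r^2\,\mathrm{df}_2/(1-r^2)$ with $\mathrm{df}_1 = 1$ and upper-tail
$p$ from the $F$ distribution; no multiple-testing correction is applied.

The **binary-rank Spearman test** pairs, within each tree level, the
magnitude-descending binary ranks with the descending ranks of the error
rates (average ranks at ties). Levels have different sizes, so both rank
vectors are rescaled to $[0,1]$ within each level before concatenation;
this is the construction under which perfect within-level agreement gives
$\rho = 1$, full within-level reversal gives $\rho = -1$, and the
single-node level 1 — whose rank cannot vary — naturally drops out, which
is why one extra degree of freedom is subtracted: $\mathrm{df}_2 = n - 3$,
i.e. $F(1, 28)$ for the 31 histories. A `global` scheme (joint ranking,
$\mathrm{df}_2 = n - 2$) is retained for sensitivity analyses. Paired
history contrasts report the squared paired-$t$ statistic as
$F(1, n-1)$ with the honest effective degrees of freedom; `partial_r2()`
residualizes response and predictor on the other predictor to decompose
staircase versus bifurcation-surface contributions.

## The synthetic generator

No behavioral data ship with the package, so `simulate_streams()` plants
exactly the two relationships the battery tests, and nothing else:

* RTs: $\beta_0 + \beta_1\,\rho(\Omega_w) + \mathcal N(0, \sigma)$, clipped
  to the censorship bounds (clipping, not resampling, so the scanner's
  censorship path is exercised), where $\Omega_w$ is the drive of the
  depth-5 stimulus window ending at the trial (R-leading ratio, or wrapped
  L-leading value; trials before depth 5 use the root 1/2).
* Errors: probability
  $\mathrm{logit}^{-1}\!\bigl(\mathrm{logit}(p_0) + \gamma\,(q - 2)\bigr)$
  with $q$ the window ratio's denominator, offset so $p_0$ is the rate at
  the root denominator 2.

Defaults — 8 participants × 4,000 trials, $\beta_0 = 450$ ms,
$\beta_1 = 200$ ms, $\sigma = 30$ ms, $p_0 = 0.05$, $\gamma = 0.15$,
bias $2/3$ for the repetition/alternation-biased schedules — produce mean
RTs spanning roughly 450–650 ms and error rates from 5% to ~20% across
denominators 2–13, the ranges typical of speeded two-choice data. They are
the package's fixed study conditions, not tuning knobs.

One structural caveat documented here because it bounds what recovery can
show: the generator sets each trial's RT from its *depth-5* window, while
the scanner also averages *shorter* histories, whose occurrences mix
depth-5 contexts. With $\sigma = 0$ the scanned means therefore equal the
staircase values **exactly for the 16 depth-5 histories** (the recovery
tests assert $r = 1$ there, to floating-point tolerance), while the 15
shorter histories are context-weighted staircase averages (empirically
$r \approx 0.95$ over all 31). No per-trial generative rule can make all 31
overlapping history means hit the staircase simultaneously in a finite
stream. Real data differ from the generator in further ways the tests
cannot probe: RT distributions are right-skewed, not Gaussian; errors are
fast and history-dependent, not conditionally independent; and practice,
fatigue, and drift are absent.

Problem sizes used by the test suite and recovery checks: the full-grid
(0.001) staircase; default-config recovery for the $r^2 \ge 0.6$ check; 20
seeded replicates at 4 participants × 1,000 trials for the
denominator-slope sign check, a size at which the planted slope is reliably
detected while the whole suite stays quick.

## Numerical conventions and edge cases

* All randomness descends from single integer seeds; staircases, surfaces,
  and simulated streams are bit-reproducible.
* Staircase lookups use the nearest grid point; at the default 0.001 step
  the drive discrepancy is at most 0.0005.
* Unit normalization raises a degenerate-range error when all means are
  equal (e.g. $\beta_1 = \sigma = 0$) rather than silently returning zeros.
* A perfect correlation reports $F = \infty$ with $p = 0$ flagged rather
  than overflowing; a zero-variance paired difference likewise.
* The circular mean raises an error on a zero resultant vector (e.g. four
  equispaced phases) where no direction is defined.
* Ratios are exact integer pairs; decimals are rounded only at
  presentation (3 decimals matches the printed drive values).

## Limitations

The package analyzes the discrete map only — no continuous-time HKB ODE
integration, no Lyapunov/chaos tests, no Arnold-tongue tracing in the
$(\Omega, K)$ plane — and its statistics deliberately mirror a fixed
analysis recipe (hard censorship, unweighted grand means, pairwise
deletion) rather than offering a general mixed-model framework. Empirical
claims about human data require human data; everything the test suite
establishes is conditional on the generator's stated structure.
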
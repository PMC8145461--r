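---
title: "A discrete-time switching model of gene expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete-time switching model of gene expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifsgene)
```

## The model and its assumptions

`ifsgene` simulates the expression of a single self-regulating gene through
three molecular stages.  The gene is a binary telegraph variable
$i \in \{0, 1\}$; while it is fixed, the concentrations of pre-mRNA
($\xi_1$), mature mRNA ($\xi_2$) and protein ($\xi_3$) evolve by one linear
update per time step $\delta$:

$$
\xi_1' = R\,i + a\,\xi_1,\qquad
\xi_2' = C\,\xi_1 + b\,\xi_2,\qquad
\xi_3' = P\,\xi_2 + c\,\xi_3,
$$

with retention factors $a = 1 - C - \mu_{PR}$, $b = 1 - \mu_R$,
$c = 1 - \mu_P$.  The model is *concentration-valued*: molecule levels are
real numbers, and the only stochasticity is the gene switching.  Within a
constant-gene segment the dynamics are exactly deterministic — there is no
birth–death noise, no cell division, and no delay; the per-step formulation
aggregates all reactions occurring within one interval of length $\delta$.

Three structural assumptions are enforced at construction time:

* all six rates are strictly positive;
* the per-step loss fractions are below one
  ($0 < C + \mu_{PR} < 1$, $0 < \mu_R + P < 1$, $0 < \mu_P < 1$), since a
  step cannot remove more molecules than are present.  The mRNA bound
  couples $\mu_R$ and $P$ as printed even though only $\mu_R$ enters $b$;
  we enforce the bound exactly in that form;
* $a$, $b$, $c$ are pairwise distinct.  Repeated retention factors produce
  confluent (polynomial-times-geometric) modes; these degenerate cases are
  rejected with an error rather than handled by a separate closed form,
  because the model class we implement excludes them.  What happens at
  exact equality is an open modelling question we deliberately do not
  answer numerically.

With the gene held constant the solution is a sum of three geometric modes
plus a constant (`mode_decomposition()`), the active steady state is
$w = (R/(C+\mu_{PR}),\ RC/((C+\mu_{PR})\mu_R),\ PCR/((C+\mu_{PR})\mu_R\mu_P))$,
and the two flows are mirror images through $w/2$:
$\pi_0(t, w - \xi) = w - \pi_1(t, \xi)$.  The box
$[0, w_1] \times [0, w_2] \times [0, w_3]$ is invariant for every switching
pattern, which is why all bounded diagnostics are run inside it.

### Clocks and times

The internal clock of every simulator is the integer step index $n$;
physical time $t = n\delta$ appears only in the output tables.  This keeps
long trajectories free of floating-point drift in $t$.  The closed-form
flow `gene_flow()` accepts arbitrary real $t \ge 0$ (the geometric modes
interpolate continuously between steps); the one-step map `gene_step()` is
integer-only.  Both are exposed because the attractor geometry lives on the
real-time flow while the stochastic process lives on the step grid.

## Reduced coordinates and the IFS

A triangular linear substitution (implemented exactly as
`to_reduced()` / `from_reduced()`) conjugates both one-step maps to
diagonal affine contractions
$S_i(x) = (a x_1 + u_1 i,\ b x_2 + u_2 i,\ c x_3 + u_3 i)$ with
$u = \big(\tfrac{1}{(a-c)(a-b)},\ \tfrac{1}{(b-a)(b-c)},\ \tfrac{1}{(c-a)(c-b)}\big)$.
Both maps contract Euclidean distance by $\max\{a, b, c\} < 1$, so the pair
is an iterated function system with a unique compact invariant set $K$.
$S_0$ fixes the origin, $S_1$ fixes
$v = u/(1 - (a, b, c))$ componentwise.  For the canonical factors
$(1/2, 3/4, 2/3)$ used throughout the tests, $u = (24, 48, -72)$ and
$v = (48, 192, -216)$.

## Two switching semantics

The package treats two descriptions of the random gene as first-class,
clearly labelled mechanisms, because they are *not* numerically identical
and the exact correspondence between their parametrizations is open.

**(A) Per-step place-dependent probabilities** (`simulate_ifs_process()`).
At every step a gene state $j$ is drawn with probabilities
$p_0(x)$, $p_1(x)$ evaluated at the current point, the map with that $j$ is
applied, and the gene coordinate is set to $j$.  The draw ignores the
current gene state — a biologically odd but deliberate convention,
implemented as specified by the transition kernel
$P(x, B) = p_0(x)\mathbf 1_B(S_0 x) + p_1(x)\mathbf 1_B(S_1 x)$.  This is
the default CLI semantics and the configuration used for the reference
stochastic simulation (`ifs_fixture("rational")`, with
$p_0(x) = 1/(2(1+|x|^2))$).

**(B) Intensity-driven jumps** (`simulate_jump_process()`).  State-dependent
hazards $q_0$, $q_1$ drive the time to the next switch through the discrete
life-span function

$$
\Phi_{x_0}(t) = \exp\Big\{-\sum_{s=0}^{\lfloor t\rfloor - 1}
q_i\big(\pi_i(s, x_0)\big)\Big\},
$$

the normative law of the package.  The exact per-step product
$\prod_s (1 - q_i(\pi_i(s, x_0)))$ is provided separately
(`survival_product()`) for exactness checks; the two agree to
$O(t\,q_{\max}^2)$ when the hazards are small.  Switch times are sampled by
inverse-CDF search on the integer grid (draw $U$, return the smallest $n$
with $F(n) \ge U$), which is exact for the discrete law — no rejection
sampling.  The floor convention makes $F$ a right-continuous step function
constant on $[n, n+1)$; $\Phi(t) = 1$ for $t < 1$, so the first switch
always happens at a strictly positive step.  At a switch step the molecule
state is the deterministic flow endpoint and the recorded gene state is
already flipped; the next segment restarts from there.

**The bridge.**  The only relation between the two parametrizations that
the product form supports is "switch away from $i$ with probability
$q_i(x)$", implemented by `switch_semantics_bridge()`.  Under this rule the
first-switch law of the per-step simulator equals `survival_product()`
exactly.  But the bridged rule depends on the current gene state whenever
$q_0 \ne q_1$, whereas semantics (A) is $i$-independent by construction;
the returned object flags this (`i_dependent`) rather than hiding it.  The
hypotheses behind uniqueness of the invariant measure (probabilities
Hölder continuous and uniformly $\ge \delta_0 > 0$) are the user's
responsibility: `probability_pair()` and `intensity_pair()` spot-check
claimed bounds on a deterministic $10\times10\times10$ grid of the
invariant box and *warn* on violation instead of erroring, since a grid
check can neither prove nor refute the hypothesis.

## Measures and convergence diagnostics

The transfer operator $T f(x) = p_0(x) f(S_0 x) + p_1(x) f(S_1 x)$ and its
dual push-forward on finitely supported measures are implemented exactly:
each atom splits in two, and with pruning disabled the duality
$\int f\, d(F\nu) = \int Tf\, d\nu$ holds to rounding error (the $n$-fold
push-forward of a point mass enumerates all $2^n$ composition words, which
the tests verify against an independent enumeration).  Pruning removes
atoms below $10^{-12}$ relative mass and renormalizes.

Convergence in distribution is monitored with the **energy distance**
$2\,\mathbb E|X-Y| - \mathbb E|X-X'| - \mathbb E|Y-Y'|$ between weighted
samples (unhalved convention: two point masses at $x$, $y$ give
$2|x-y|$).  Energy distance metrizes weak convergence on bounded sets, and
the dynamics are confined to a compact box; unlike the Hausdorff metric it
compares distributions, not just supports.  The `diagnose_convergence()`
check launches chains from two distant starts (the origin and the active
steady state) and compares their empirical measures at sample sizes
$10^2, 10^3, 10^4$.  Because a single chain pair is dominated by
Monte-Carlo noise once the distance reaches its floor, the diagnostic
averages the distances over five independent chain pairs and requires the
averaged sequence to decrease; the chain length $10^4$ keeps the full
diagnostic within seconds while leaving an order of magnitude between
successive distances.

## The invariant set and membership

Two switches reach every point of the support: composing three
constant-gene flow segments in reduced coordinates and substituting
$x := a^{t_3}$, $y := a^{t_2+t_3}$, $z := a^{t_1+t_2+t_3}$ parametrizes the
solid invariant set $A$ over the ordered simplex $1 \ge x \ge y \ge z \ge 0$:

$$
\big(v_1(x - y + z),\;
v_2(x^{e_b} - y^{e_b} + z^{e_b}),\;
v_3(x^{e_c} - y^{e_c} + z^{e_c})\big),
\qquad e_b = \log_a b,\ e_c = \log_a c .
$$

The complementary parametrization $v - A = A$ is implemented as
`attractor_point_alt()` and the identity between the two is tested at
machine precision.  The boundary consists of the two one-switch surfaces
$A_0$ (through the origin, $z = 0$) and $A_1 = v - A_0$ (through $v$,
$x = 1$).  At the simplex boundary we use the continuity convention
$0^e := 0$ for $e > 0$.

**Membership is sample-based.**  Inverting the parametrization would
require solving three coupled monotone power equations; instead
`attractor_membership()` tests nearest-neighbour distance against a
deterministic grid cloud (`attractor_cloud()`, default $101$ levels per
axis, 176 851 points on the ordered simplex).  The tolerance scale is the
*average image-space grid spacing*: each coordinate of the parametrization
sweeps a range of $|v_k|$ across the $n-1$ grid intervals, so the
per-axis spacing is estimated as $|v_k| h$ with $h = 1/(n-1)$, and the
cloud's `resolution` is the Euclidean norm of the three.  The default
membership tolerance is $3\times$ this resolution.  The estimate is an
average: local spacing near the simplex corner (where the power maps are
steepest) can exceed it by a factor of $2$–$3$, which is why the
closure-under-dynamics test uses the $3\times$ default while boundary
points, which are images of on-grid-like parameters, are held to
$2\times$.  The nearest-neighbour kernel is a small C++ branch-and-bound on
the widest coordinate axis; brute force at $10^5 \times 1.8\cdot 10^5$
pairs would dominate the test budget.

Note the chaos-game orbit is the *integer-time* object: it is a discrete
subset of the real-time solid $A$, and membership of the orbit in $A$ is a
containment check, not an equality of sets.  Coverage in the other
direction (how densely the discrete orbit fills $A$) is not characterized
here.

## Synthetic data: what the generator emulates

The package generates all of its own data; there is no external input.
The canonical fixtures pin the study conditions used throughout tests and
documentation:

* `canonical` — $\delta = 1$, $R = 1$, $\mu_{PR} = C = \mu_R = 1/4$,
  $P = \mu_P = 1/3$ (factors $a = 1/2$, $b = 3/4$, $c = 2/3$, steady state
  $w = (2,2,2)$);
* `chaos` — the reduced system with those factors, chaos game from the
  origin with constant probabilities $1/2$ and $10^5$ iterations;
* `rational` — the `canonical` kinetics with the rational rule
  $p_0(x) = 1/(2(1+|x|^2))$ started from $(1/2, 1/2, 1/2)$.

Simulated trajectories reproduce the hybrid process faithfully, but they
inherit every idealization of the model: deterministic kinetics between
switches, real-valued concentrations, memoryless place-dependent switching
and a single gene copy.  Passing tests therefore certify the mathematics
of the switching system, not agreement with single-cell measurements —
real expression data carry molecular noise, cell-cycle effects and
measurement error that this generator deliberately does not emulate.

## Numerical choices

* Closed-form-vs-iteration comparisons use relative tolerance $10^{-9}$
  (absolute $10^{-12}$): double-precision accumulation over the $\le 10^5$
  steps exercised in tests stays well inside this.
* Exact identities (telescoping of the product survival, mirror symmetry
  of the two parametrizations, $T$-duality) are asserted at
  $10^{-12}$-scale tolerances.
* Hutchinson iteration deduplicates points on a uniform grid (default side
  $10^{-4}$ in reduced coordinates) to bound the $2^n$ growth; convergence
  in the Hausdorff metric is insensitive to sub-resolution detail.  A
  configurable point budget turns runaway growth into an error.
* Chaos-game burn-in defaults to $10^3$ steps: the contraction constant is
  $\max\{a,b,c\}$, so the initial condition's influence after burn-in is
  below $(3/4)^{1000}$ for the canonical factors.
* Jump sampling caps the search at $10^6$ steps and raises a typed error
  carrying the residual survival probability, so callers can distinguish
  "no jump yet" from failure.
* All stochastic functions take an explicit seed and are pure functions of
  (configuration, seed); tests assert byte-identical reruns.
* Test problem sizes (orbits of $10^4$–$10^5$ points, $10^4$ jump-process
  replicates, grid clouds of $\le 1.8\cdot10^5$ points) were chosen so the
  full suite completes in well under a minute while keeping Monte-Carlo
  standard errors an order of magnitude below every asserted margin.

## Known limitations

* Degenerate rate combinations (equal retention factors) are rejected, not
  solved; the confluent closed forms are out of scope.
* The bridge between intensity-driven and per-step switching is the only
  one derivable from the product-form survival; the model itself does not
  specify the correspondence, and the two simulators differ in their
  step-boundary convention (the jump simulator updates molecules with the
  pre-switch gene, the per-step simulator with the freshly drawn one).
* Membership in the invariant set is resolved only to the grid tolerance;
  minimality of the support (no proper invariant subset) is a statement
  about the process that sampling cannot verify.
* Apparent bimodality of marginals over the invariant set can be inspected
  through histograms of simulated orbits, but the package attaches no
  pass/fail criterion to it; whether the stationary distribution is
  genuinely bimodal for some parameter regions is open.
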
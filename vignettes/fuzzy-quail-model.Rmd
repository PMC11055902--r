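---
title: "A fuzzy bobwhite-quail population model under g-division"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fuzzy bobwhite-quail population model under g-division}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbqpop)
```

## The model

`fbqpop` implements a third-order rational difference-equation model of
bobwhite quail population dynamics,

$$x_{n+1} = A + B x_n + \frac{x_n}{x_{n-1} x_{n-2}}, \qquad n = 0, 1, \dots$$

in which the parameter $A$ (a process-error level absorbed into the
per-season growth balance), the threshold-density parameter $B$, and the
three initial population sizes $x_{-2}, x_{-1}, x_0$ are **positive fuzzy
numbers** rather than point values. Survey counts of quail populations
carry substantial observation and preprocessing error; representing the
inputs as fuzzy numbers propagates that ambiguity through the recursion
instead of discarding it. The model's delayed density dependence (two
preceding generations in the denominator) reflects the multi-season
population structure of the species.

The headline qualitative result is that, under explicit parameter
conditions, every positive (fuzzy) trajectory returns to one fixed fuzzy
equilibrium regardless of how small the starting population is — the
dynamics exhibit no Allee-type extinction threshold.

## Alpha-cut representation

A fuzzy number is stored by the endpoints of its $\alpha$-cuts on a shared
grid of membership levels: $[x]_\alpha = [L(\alpha), R(\alpha)]$, with $L$
nondecreasing, $R$ nonincreasing, $L \le R$, and $L(0) > 0$ for model
inputs. The default grid has 101 uniform levels including 0 (the support)
and 1 (the core): the theory quantifies over all $\alpha \in (0, 1]$ while
tabulated results use 5 levels, and a dense uniform grid subsumes both.
The $\alpha = 0$ entry stores the support endpoints (the closure of the
union of the positive-level cuts), which for the parametric families used
here coincides with the limit of the cut formulas at $\alpha \to 0$.

Inputs are usually **parabolic fuzzy numbers**: membership
$1 - ((x - c)/s)^2$ on $[c - s, c + s]$, with $\alpha$-cut
$[c - s\sqrt{1-\alpha},\, c + s\sqrt{1-\alpha}]$. They are a smooth,
symmetric upgrade of triangular fuzzy numbers; `alpha_cut()` evaluates
their cuts exactly at any level, so tabulation does not depend on the grid
resolution.

## g-division and the two cases

Addition, positive scaling and multiplication of positive fuzzy numbers
act endpoint-wise per level. Division uses the *generalized (g-)
division*, defined through the multiplicative identities
$[H] = [P][W]$ or $[P] = [H][W]^{-1}$, whichever yields a proper fuzzy
number. For positive operands the dichotomy is decided by the sign of
$H_l P_r - H_r P_l$ across levels:

* **Case I** ($H_l P_r \le H_r P_l$ everywhere):
  $W = [H_l/P_l,\; H_r/P_r]$;
* **Case II** (the reverse strict inequality):
  $W = [H_r/P_r,\; H_l/P_l]$.

The g-quotient is never wider than the Zadeh extension-principle quotient
$[H_l/P_r, H_r/P_l]$, which is why it is preferred for difference
equations: the extension principle inflates the support at every step,
while g-division can keep the ambiguity of the solution commensurate with
the ambiguity of the inputs. `compare_division()` makes this visible on
any scenario.

**Tie handling.** The strict "Case II at every level" reading makes
Case II unreachable for any input whose core is a single point, because
the comparison degenerates to equality at $\alpha = 1$. We therefore
classify by *sign uniformity with neutral ties*: all differences $\le 0$
gives Case I (an all-tie comparison — crisp data — also resolves to
Case I), all $\ge 0$ with at least one strict excess gives Case II, and
genuinely mixed signs raise an error naming the offending levels rather
than silently mixing the two endpoint assignments. The same convention
applies to the per-step case classification of the model
(`classify_case()`).

## Endpoint recursions and simulation modes

Applying the arithmetic per level turns the fuzzy recursion into endpoint
systems. Under Case I the endpoints decouple — each obeys the crisp
recursion $y_{n+1} = p + a y_n + y_n/(y_{n-1} y_{n-2})$ with
$(p, a) = (A_l, B_l)$ on the left and $(A_r, B_r)$ on the right. Under
Case II the quotient term cross-couples them:
$L' = A_l + B_l L + R/(R_1 R_2)$ and $R' = A_r + B_r R + L/(L_1 L_2)$.

`fbqp_simulate()` offers four modes:

* `auto` — classify each step and apply the matching recursion (the
  operational generalization; the source analyses treat each case
  globally);
* `case1` / `case2` — force one recursion throughout, reproducing the
  global analyses exactly;
* `zadeh` — replace the quotient with the extension-principle division,
  for comparison.

In `auto` and `zadeh` modes every iterate must be a proper fuzzy number
and the run errors otherwise. In the force modes the endpoint systems are
iterated as such: when the data's actual case differs from the forced one
the iterates can transiently stop being proper fuzzy numbers (on the
reference scenario, forcing Case I lets the left quotient
$1/(0.55 \cdot 0.65)$ overshoot the right endpoints around steps 3–5)
before both endpoint sequences settle onto the forced-case equilibrium.
The trajectory records a per-step `valid` flag instead of aborting, since
those endpoint systems are exactly what the corresponding convergence
analyses study. Iterates beyond $10^{12}$ in magnitude set a divergence
flag and stop the run: outside the stability regions the recursion can
blow up geometrically, and continuing to overflow serves no purpose.

## Equilibria and stability

All equilibria are closed-form; no root finding is involved, and every
returned equilibrium is checked in tests against its fixed-point equation
to $10^{-12}$.

* Crisp / Case I per level:
  $\bar y = \dfrac{p + \sqrt{p^2 + 4(1-a)}}{2(1-a)}$, applied with the
  left and right parameter endpoints.
* Case II per level: the coupled system
  $y = p + ay + 1/z,\; z = q + bz + 1/y$ with
  $(p,a,q,b) = (A_l, B_l, A_r, B_r)$ has the unique positive solution
  $$\tilde y = \frac{pq - (b-a) + \sqrt{(pq + a - b)^2 + 4pq(1-a)}}{2q(1-a)},$$
  and symmetrically for $\tilde z$; `fuzzy_equilibrium_case2()` evaluates
  the equivalent direct endpoint form.

Linearizing the crisp recursion about $\bar y$ gives
$y_{n+1} - (a + G) y_n + G y_{n-1} + G y_{n-2} = 0$ with
$G = 1/\bar y^2$; asymptotic stability holds when $a + 3G < 1$, for which
$3p^2 > 4(1-a)$ is a convenient sufficient condition
(`linearization_case1()`).

For the coupled system, `jacobian_case2()` builds the $6 \times 6$
linearization $T$ and certifies stability by finding a weighted maximum
norm below 1: with $G_\varepsilon = \mathrm{diag}(1, \varepsilon, \dots,
\varepsilon^5)$ and $\varepsilon$ in the admissible interval
$\left( \sqrt[6]{\tfrac{(1-b)\,p^2}{(1-a)\,q^2}},\, 1 \right)$
(nonempty iff $p^2/(1-a) < q^2/(1-b)$), it computes
$\|G_\varepsilon T G_\varepsilon^{-1}\|_\infty$. The default
$\varepsilon$ is the interval midpoint, overridable. The norm is *not*
monotone in $\varepsilon$ — the $b$-row's weighted sum grows with
$\varepsilon$ and can cross 1 near the upper end — so the certificate is
reported at the chosen $\varepsilon$ only.

## Condition checkers: literal by default

`check_conditions()` evaluates the sufficient condition sets of the
boundedness and convergence results per level, *literally as stated*.
Two quirks deserve flagging rather than silent repair:

1. The Case-I sets bound the right endpoint of $A$ by 1
   ($A_{r,0} < 1$) even though their growth conditions push $A$ above 1,
   and the reference scenario itself has $A_{r,0} = 2$. The literal
   reading is the default; `alternate = TRUE` substitutes the reading
   that bounds $B$ instead, and the report records which was used.
2. Strict cross-endpoint inequalities (e.g. $(1-B_r)A_l^2 <
   (1-B_l)A_r^2$) necessarily degenerate to equality at $\alpha = 1$ for
   single-point cores. Such conditions are marked `degenerate_at_core`,
   and `conditions_pass_interior()` offers the pass notion that ignores
   the uninformative core-level tie. The regime-constrained scenario
   generator uses that notion.

## The scenario generators

`fbqp_example_scenario()` is the reference parameterization: parabolic
$A$ with center 1.75 and spread 0.25 (support $[1.5, 2]$), $B$ with
center 0.25 and spread 0.10, and unit-centered initial sizes with spreads
0.25, 0.35, 0.45 — a stable growth environment with a pessimistic
natural growth rate and progressively more uncertain recent counts. Its
equilibrium tables, envelopes and convergence behaviour are the package's
regression anchors.

`random_scenario()` rejection-samples parabolic tuples inside a named
regime until the corresponding condition set passes (or fails, for
`"unstable"`). The sampling windows were fixed once as representative:
the literal Case-I convergence regime forces $A < 1$, which drags the
growth conditions toward strong density dependence, so $A$ is drawn
around 0.72–0.92 and $B$ around 0.78–0.95 with small spreads; the
Case-II regime samples the reference scenario's neighbourhood
($A$ in 1.4–2.2, $B$ in 0.10–0.35, moderate spreads); the unstable
regime draws both parameters small so every growth condition fails.
Sampling is deterministic given `seed` and the accepted draw records its
attempt count.

What the generator emulates — and what it does not: scenarios are
symmetric parabolic inputs on one grid, i.e. exactly the class of inputs
the closed-form theory addresses. Real survey data would yield asymmetric,
possibly multimodal membership functions, observation error correlated
across seasons, and parameters that drift over time; none of that is
represented, so passing tests demonstrate correctness of the implemented
dynamics, not adequacy of the parametric family for any particular field
dataset.

## Numerical choices

* **Grid**: 101 uniform levels by default; all per-level arithmetic is
  vectorized. Tables are evaluated from exact parametric cuts, so their
  accuracy is grid-independent.
* **Metric**: $D(H, P) = \sup_\alpha \max(|H_l - P_l|, |H_r - P_r|)$ is
  approximated by the grid maximum — exact whenever the endpoint
  discrepancy attains its extremum on the grid, which holds for
  parabolic families (at the support).
* **Tie tolerance**: case classification and g-division use an absolute
  tolerance of $10^{-12}$ times the operand scale; iterate validation
  uses $10^{-10}$ relative slack to absorb harmless floating-point
  jitter without masking genuine endpoint crossings.
* **Display rounding**: tables round half-up to 4 decimals (matching the
  tabulated presentation); raw values are what the functions return.
  Printed equilibrium cells reproduce to within $1.5 \times 10^{-4}$ —
  the tabulated source rounds intermediate cuts, perturbing the fourth
  decimal. Two tabulated Case-II rows (the $\alpha = 0.25$ row and the
  core-level parameter cells) are internally inconsistent with the
  parametric cut formulas under any reading and are excluded from
  regression; the core-level equilibrium value itself is kept, as it
  verifies.
* **Envelope constants**: the tabulated Case-I envelope adds the initial
  value $x_{-2,l}$ on the left and $x_{0,r}$ on the right where the
  analysis writes "the third iterate"; `bound_case1()` therefore takes
  its additive constant from the caller, and `reproduce_table()`
  documents the per-side choices that reproduce the tabulated numbers.
  Envelope cells are reported, not asserted.
* **Problem sizes**: convergence demonstrations run the reference
  scenario for $10^4$ steps on the 101-level grid; the stability-region
  sweeps run 100 scenarios for 2000 steps on a 21-level grid, ample for
  the geometric contraction rates involved (worst observed rate
  $\approx 0.98$ per step needs $\sim 700$ steps to reach $10^{-6}$).

## A worked run

```{r example}
s <- fbqp_example_scenario(alpha_grid(101))
tr <- fbqp_simulate(s, 200, mode = "auto")
eq <- fuzzy_equilibrium_case2(s$A, s$B)
tail(trajectory_distance(tr, eq$value), 1)
reproduce_table(fbqp_example_scenario(alpha_grid(5)), case = "CASE_II")
```

## Known limitations

* Only interval-valued $\alpha$-cuts (fuzzy-convex numbers) are
  supported; no gH-difference or subtraction is provided because the
  model never needs one.
* The generalized family
  $x_{n+1} = A + Bx_n + C x_n / (D + \prod_k x_{n-k}^{p_k})$ is
  simulated in crisp form only; its fuzzy theory is outside scope.
* Mixed-sign g-division across levels is an error by design; there is no
  per-level case mixing, as that would leave the defining identities of
  the division unsatisfied as stated.
* No fitting to survey data: scenarios are specified, not estimated.
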
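---
title: "Conditional activity: detecting temporally-correlated binding fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional activity: detecting temporally-correlated binding fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condact)
```

## The problem

Cooperative binding networks — a handful of DNA sites bound competitively by
transcription factors and RNA polymerase — are usually summarised by their
thermodynamic equilibrium: which configurations are occupied, and how strongly
sites covary. But cooperativity *stabilises* the dominant configurations, so
equilibrium correlation measures such as the mutual information are small
exactly when cooperativity is strong: the information they can carry is
bounded by the sites' entropies, and stable sites have almost none. The
interesting biology often lives in the *rare fluctuations away* from the
stable configuration — in the lambda switch, the rare unbinding cascades that
let RNA polymerase reach the lytic promoter. Those fluctuations leave a
signature not in the equilibrium occupancies but in the *timing* of binding
events: after one site moves, another site's next move comes much sooner than
its typical interval. The conditional activity quantifies exactly that.

## The model

A **microstate** assigns one configuration to every binding site (the first
configuration of every site is `empty`; the others name the bound ligand).
Steric exclusion rules delete forbidden joint assignments. Free energies are
strictly additive over **energy terms**: a term with a single
(site, configuration) condition is an intrinsic binding energy, a
two-assignment term is a pairwise cooperativity, and longer conditions encode
multi-site stabilisation such as DNA-looping octamers. All energies are in
kcal/mol.

At temperature $T$ and ligand concentrations $[s]$ (molar, of the binding
species — dimers for CI and Cro; monomer–dimer equilibria are not modelled),
microstate $i$ has equilibrium probability

$$K_i = \frac{1}{Z} e^{-\Delta G_i / RT} \prod_s [s]^{\,n_{is}},$$

with $n_{is}$ the number of bound molecules of species $s$ and
$R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$. The default temperature is
310 K. Weights are accumulated in log space with max-subtraction, so energy
spreads of hundreds of kcal/mol do not overflow; the normalisation tolerance
used in checks is $10^{-12}$.

Kinetics are inferred from the thermodynamics: every allowed transition is a
single binding or unbinding event (substitution of one ligand for another is
two transitions), every binding event shares one diffusion-limited rate $D$,
and detailed balance fixes each unbinding rate as $q_{ij} = D K_j / K_i$.
$D$ defaults to 1 inverse time unit; it sets the (arbitrary) time scale and
cancels from the conditional activity, which the test suite verifies to
$10^{-9}$ under $D \to 10D$.

### The phage-lambda instance

`lambda_model()` builds the nine-site switch: operators
$O_{R1..3}, O_{L1..3}$ (empty/CI$_2$/Cro$_2$) and promoters
$P_R, P_{RM}, P_L$ (empty/RNAP). The promoter–operator overlaps are
$P_R \leftrightarrow \{O_{R1}, O_{R2}\}$, $P_{RM} \leftrightarrow \{O_{R3}\}$,
$P_L \leftrightarrow \{O_{L1}, O_{L2}\}$; descriptions of this geometry
disagree between sources (some swap the two right-complex promoters), and we
fixed the convention above because it is the one consistent with the
established right-operator map, with the observed $P_{RM}$–$O_{R3}$
anticorrelation, and with the 40-state right-complex count. Both promoters of
the right complex may carry RNAP simultaneously. The exclusions cut the
unconstrained $3^6 \cdot 2^3 = 5832$ assignments down to
$40 \times 30 = 1200$ microstates.

The package deliberately ships **no numerical energy values**: the
quantitative lambda literature keeps these in collected parameter sets
(Santillán & Mackey 2004; Darling et al. 2000; Reinitz & Vaisnys 1990), and
transcription errors here would be silent and consequential. The shipped
parameter file is schema-complete with a provenance slot per value;
`pathway_report()` refuses placeholder values unless `allow_placeholder`
is set (placeholders then count as 0 kcal/mol, which is useful only for
structural checks). Lysogenic and lytic conditions are fixed concentration
presets — protein production and degradation dynamics, which would *generate*
those concentrations, are outside the model's scope, as is the transcriptional
(rather than binding) cooperativity of CI on $P_{RM}$ activity.

## The conditional activity

Let $T(a,t)$ be the $t$-th transition time of site $a$ within an observation
window of length $\tau$, and $W(a,T)$ the time from $T$ to $a$'s next
transition. The **persistence time** is half the mean squared waiting time,

$$\tau_p[a] = \frac{1}{2\tau} \sum_t W(a, T(a,t))^2,$$

which for a long stationary record converges to the mean residual time
$E[W^2]/2E[W]$ seen by a random observer (the inspection paradox). The
**exchange time** of $a$ following $b$ pairs each waiting interval of $b$
with the residual time of $a$ at its end:

$$\tau_x[a \leftarrow b] = \frac{1}{\tau} \sum_{t=1}^{N(b)-1}
  W(a, T(b,t+1))\, W(b, T(b,t)).$$

The **conditional activity** is
$CA[a \leftarrow b] = -\log_{10}(\tau_x[a \leftarrow b] / \tau_p[a])$:
zero when $a$ and $b$ are independent (the exchange time then *is* the
residual-life mean), zero for a Poisson transition process, positive when a
transition of $b$ hastens $a$'s next transition, and asymmetric in $(a,b)$
because it respects time-ordering. Note that "Markovian at the site level"
is not quite sufficient for zero self-CA: a two-state site with unequal
rates $k_1 \ne k_2$ has
$\tau_x/\tau_p = 2k_1k_2/(k_1^2+k_2^2) < 1$, hence a small positive
$CA[a\leftarrow a]$; only the equal-rate (Poisson-interval) case vanishes
exactly. The estimators make no attempt to force that case to zero.

### Estimator conventions

The sum in $\tau_p$ nominally includes the last recorded transition, whose
waiting time is undefined at the record's end; we sum to $N(a)-1$
(equivalently define the final $W$ as 0), the convention under which
$\tau_p$ converges to the residual-life mean. Both estimators are normalised
by the common observation-window duration rather than per-site last-event
times, so empirical and analytic normalisations agree in the long-record
limit. Cross terms whose next $a$-event lies beyond the window are dropped
and counted, with a warning when more than 1% of terms are lost. Duplicate
timestamps in imported event files are rejected outright — coincident events
have measure zero in a continuous-time model, so they indicate an export
problem.

Standard errors come from a joint non-overlapping block bootstrap: the
window is cut into 50 equal subwindows, per-subwindow partial sums of the
persistence and exchange terms are accumulated, and whole subwindows are
resampled with replacement. Terms of a point process are serially
correlated, so a plain bootstrap over terms would understate the error.

## Analytic computation from the rate matrix

The conditional activity is sensitive to rare events, so simulation-based
estimates converge slowly; the package therefore also computes it exactly
from the generator. For site $a$, split the generator's off-diagonal into
$Q^a$ (transitions that leave $a$'s configuration unchanged; diagonal keeps
the *full* exit rates) and $R^a$ (transitions that change it). Each
connected component of the masked transition graph shares one configuration
of $a$, so $Q^a$ is block diagonal and each block is a proper absorbing-chain
generator. With the fundamental matrix $N^a = -(Q^a)^{-1}$:

* $B^a = N^a R^a$ is the first-passage distribution over the states entered
  when $a$ next changes (rows sum to 1, which the implementation verifies
  per block);
* $K^a_i \propto \sum_j K_j (R^a)_{ji}$ is the stationary distribution just
  after an $a$-transition;
* $\tau^a = K^a N^a \mathbf 1$ is the mean interval between $a$-transitions,
  and equals the reciprocal of $a$'s total stationary flux;
* $\tau_p[a] = (K^a N^a N^a \mathbf 1)/\tau^a$, using
  $E[T] = N^a\mathbf 1$ and $E[T^2]/2 = N^a N^a \mathbf 1$;
* $\tau_x[a \leftarrow b] = (K^b N^b B^b\, m^a)/\tau^b$ with
  $m^a = N^a \mathbf 1$, by the occupation-time identity
  $E_i[\text{time in } j \cdot 1(\text{absorb at } k)] = (N^b)_{ij}(B^b)_{jk}$.

One plausible rendering of the exchange-time contraction interposes an extra
post-transition weight $K^a_k$ between $B^b$ and $m^a$. That variant is
implemented behind `form = "printed"` for comparison, but it is **not** the
default: on the two-state chain it breaks the closed form
$\tau_x = 2/(k_1+k_2)$, and across coupled fixtures only the occupation-time
contraction reproduces the event-series estimator that the Gillespie
simulations validate. The simulation oracle is the arbiter, and it picks the
default form.

Numerically, every contraction is evaluated by per-block dense LU solves
against the needed right-hand sides (the ones vector, the $a$-exit rates,
and the two transposed solves for $K^aN^a$ and $K^aN^aN^a$); no fundamental
matrix is formed explicitly. Blocks whose condition estimate exceeds
$10^{12}$ trigger a warning naming the block and its rate spread. A site
with zero flux under a condition (e.g. its only ligand at zero
concentration) yields `NA` cells with a recorded reason rather than an
exception; a block with no site-changing exit raises a targeted error naming
the frozen subspace. Analytic CA values below $10^{-9}$ in magnitude are
reported as exact zeros.

## Simulation

`simulate()` on a rate matrix runs the exact Gillespie algorithm
(exponential holding times, jump targets proportional to rates) in compiled
code using R's own RNG, so `set.seed()`/`seed =` reproduce trajectories
bit-for-bit. By default the initial state is drawn from the equilibrium
distribution, making the record stationary from time zero so estimators need
no burn-in; fixed starts with an explicit `burn_in` are supported. Stopping
is by whichever of `t_max` or `n_events` comes first. Projection to per-site
event series is exact: each microstate jump changes exactly one site.

## What the toy generators emulate — and what they do not

The fixture models (`make_fixture()`: single site, independent pair,
cooperative pair, blocker pair, nearest-neighbour chain) are chosen so that
every pipeline stage has a closed-form or product-structure oracle:
two-state alternating-rate chains give exact $\tau_p$, $\tau_x$;
independent products force $CA = 0$ and $MI = 0$; the blocker pair
reproduces the promoter–operator overlap motif with a hand-computable
anticorrelation. They share the real system's *structure* (discrete
configurations, detailed balance, steric exclusion, additive cooperativity)
but none of its *scale*: real operator networks have larger state spaces,
rate constants spanning many orders of magnitude, and measurement noise in
any experimental event record (the estimators assume exact event times).
Passing tests on fixtures therefore validates the estimators and the
algebra, not the biological parameterisation — which is exactly why the
lambda energy values are an explicit user input.

Problem sizes in the shipped tests and acceptance script were chosen so the
closed-form targets are resolved well inside the Monte-Carlo error:
$10^6$ events for single-pair checks and $10^7$ events for the cell-wise
comparison of the analytic and empirical CA matrices on a 10-state coupled
model (3 sites, two cooperativities, one exclusion), with agreement judged
in units of the block-bootstrap standard error.

## Known limitations

* Binding rates are assumed equal across all transitions ($D$); real
  association rates differ between species and sites. The conditional
  activity is exactly invariant to the overall scale but not to *relative*
  rate differences, which this model cannot express.
* The analytic path stores the generator densely (up to a configurable
  ~5000-state cap) and LU-solves blocks densely; far larger models need
  sparse or iterative solvers.
* Event records must already be discrete binding events; inferring events
  from raw traces (e.g. fluorescence) is out of scope.
* The lambda instance treats lysogenic/lytic protein concentrations as fixed
  inputs; it cannot switch pathways, only quantify the fluctuation structure
  within one.
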
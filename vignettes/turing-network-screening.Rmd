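---
title: "Screening signaling networks for diffusion-driven patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening signaling networks for diffusion-driven patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turingnets)
```

## The model

`turingnets` screens small signaling networks for the capacity to form
periodic spatial patterns by a diffusion-driven (Turing) instability. A
network has $N$ nodes — diffusible nodes model secreted molecules
(ligands, extracellular inhibitors), non-diffusible nodes model
cell-autonomous components (receptors, kinases, transcription factors)
whose diffusion coefficient is exactly zero — and $k$ regulatory edges.
Each edge $(i \leftarrow j)$ is a first-order kinetic rate: the Jacobian
cell $J_{ij} = \partial \dot x_i / \partial x_j$, positive for an
activation and negative for an inhibition. Diagonal cells are
self-regulations (typically clearance) and count toward $k$. Around a
homogeneous steady state, spatial mode $q$ of the linearized
reaction-diffusion system is governed by

$$ \dot{\hat x}_q = (J - q^2 D)\, \hat x_q, \qquad D = \mathrm{diag}(d_1, \dots, d_N), $$

with $d_i = 0$ for non-diffusible nodes. The system is *Turing unstable*
when the homogeneous state is stable ($q = 0$: all eigenvalues of $J$ in
the left half-plane, decided with the Routh–Hurwitz inequalities on the
characteristic-polynomial coefficients $a_1, \dots, a_N$) while some
mode $q > 0$ grows.

## The two instability notions

`is_turing_unstable()` exposes two readings of "some mode grows":

* **`mode = "any"`** accepts every growing mode: oscillatory (complex)
  growth rates, and growth that persists in the $q \to \infty$ limit.
  That limit is governed by the sub-Jacobian of the non-diffusible
  nodes, $J_{NN}$: when a stable $J$ has an unstable $J_{NN}$, local
  positive feedback among immobile factors retains and amplifies
  perturbations at arbitrarily short wavelengths for *every* combination
  of diffusion coefficients (the "capacitor" mechanism). The
  `type3_capacitor` fixture is a ready-made example.
* **`mode = "band"`** (the screening default) asks for a
  finite-wavelength stationary Turing band: $J_{NN}$ must not be
  unstable, so the dispersion relation closes again at large $q$ and a
  wavelength is selected, and the determinant channel must open at a
  finite $q$ — $a_N(q^2) < 0$, which for a system stable at $q = 0$
  guarantees a growing *real* (non-oscillatory) mode there, because the
  remaining factor of the characteristic polynomial keeps
  negative-real-part roots while $a_1(q^2)$ grows with $q^2$.

The screen classifies with the band notion: it is the criterion under
which the catalog counts of the screening pipeline are reproducible
and budget-stable on the reference systems, and it corresponds to patterns with a well-defined
wavelength, which is what the simulator confirms. A marginal
non-diffusible block (spectral abscissa exactly 0, e.g. a signaling node
with no self-edge) is allowed: its growth tends to zero as
$q \to \infty$, so the fastest-growing mode is still at finite $q$.

## The pipeline

`run_pipeline()` executes six steps: (1) enumerate all
$\binom{N^2}{k}$ edge subsets compatible with forced/forbidden-edge
constraints; (2) keep networks that are strongly connected once
self-loops are removed (this also removes isolated and pure read-out
nodes, which cannot take part in feedback); (3) de-duplicate isomorphic
networks with a canonical key, the lexicographically minimal adjacency
bit string over node permutations that preserve the
diffusible/non-diffusible classes *and* the constraint structure (brute
force over at most $N! \le 120$ permutations); (4) keep sign
assignments (topologies; $2^k$ per network) for which some sampled rate
set is Routh–Hurwitz stable; (5) keep topologies for which some sampled
(rates, diffusion) is band-unstable under the requested diffusion
regime and matches any required phase relations; (6) classify each
surviving network's diffusivity requirement, predict phases, and
estimate robustness.

In the step-count table the topology column counts raw sign assignments
through step 4. At step 5–6 it counts the *distinct phase signatures*
each surviving network realizes: sign assignments related by flipping
the sign of a node's deviations (a similarity transformation
$J \mapsto SJS$, $S = \mathrm{diag}(\pm 1)$) have identical spectra and
describe the same reaction-diffusion behavior with relabeled phases, so
the catalog's natural unit at the pattern-derivation step is one entry
per achievable phase pattern; a network can realize at most $2^{N-1}$
of them. All raw surviving sign assignments are retained in the catalog
entries.

## Sampling decisions

Stability and capability are *existence* questions per topology. They
are decided by Monte-Carlo search with a default budget of 20,000
parameter draws per topology per search, batched (2,500 draws at a
time) and vectorized through closed-form principal-minor expansions of
the characteristic polynomial, with early exit at the first confirmed
witness. Both conditions are scale-free — replacing $(J, D)$ by
$(sJ, sD)$ rescales every growth rate by $s$ — so the existence
decisions depend only on rate *ratios*. Draws therefore mix 50% uniform
magnitudes in $(0, 0.5]$ with 50% log-uniform magnitudes over three
decades (and similarly for diffusion coefficients in the free regime):
uniform-only draws systematically miss Turing regions that need widely
separated rates, and the stable-topology count of the 3-node catalog
saturates only with the mixed proposal. The *robustness* estimator, by
contrast, measures the volume of the Turing space inside the unit
parameter box — rates uniform in $(-0.5, 0.5)$ restricted to the
topology's signs, diffusion coefficients uniform in $(0, 1)$ — and
therefore uses pure uniform draws; it reports the Monte-Carlo fraction
with its binomial standard error and seed.

The spatial instability test evaluates the determinant channel on a
fixed logarithmic grid of 64 values of $q^2$ in $[10^{-3}, 10^3]$, plus
the analytic $q \to \infty$ limit through $J_{NN}$. The grid bounds are
generous for rates of order $\le 0.5$ and diffusion ratios within four
orders of magnitude; `dispersion()` additionally refines the growth
maximum by golden-section search for wavelength and phase read-out.
Witnesses (the concrete $(J, D)$ pairs) are stored in the catalog with
the search seed and replay deterministically.

## Type I / II / III classification

The diffusivity requirement of a topology is defined by what a *single*
pattern-forming rate set tolerates:

* **Type III** (unconstrained diffusivity): some rate set patterns for
  *every* combination of positive diffusion coefficients. For two
  diffusible nodes this is decided exactly: substituting
  $x = q^2 d_v$, $y = q^2 d_w$ makes the determinant channel bilinear,
  $f(x, y) = c_{00} + c_{10} x + c_{01} y + c_{11} x y$ with
  $c_{00} < 0$ under stability, and "every ray direction reaches
  $f > 0$" reduces to closed-form sign conditions on the coefficients
  (`c11 > 0`; or `c11 = 0` with a nonnegative, nonzero linear part; or
  `c11 < 0` with `c01 >= 0` and `c10 > 2 sqrt(c11 c00)`). Structural
  zeros of these coefficients reappear numerically as roundoff of
  either sign, so the comparisons use degree-scaled tolerances. With
  more than two diffusible nodes a probe set of ratio spreads is used
  instead. Under `criterion = "any"` the capacitor certificate (stable
  $J$, unstable $J_{NN}$) decides Type III directly.
* **Type II** (equal diffusivities allowed): not Type III, but some
  rate set patterns with all $d_i$ equal.
* **Type I** (differential diffusivity required): everything else.

A network's label is the best label over its surviving topologies.
Probing finitely many ratios with independently re-drawn rates cannot
make this distinction — in a Type II network *every* ratio is feasible
for *some* rates (e.g. the receptor-inhibition variant of the extended
Nodal/Lefty system patterns at a ratio of 0.01 with suitably chosen
clearances), which is exactly why the shared-rate-set definition above
is the discriminating one.

## Constraints

`constraint_set()` carries the experimental knowledge of a screen:
forced and forbidden edges, fixed signs, fixed rate values (measured
clearance rate constants enter as `value_constraints`; the
`nodal_lefty` fixture leaves them free on purpose, since they are
quantitative inputs a user should supply), fixed diffusion
coefficients, required phase relations between named nodes, and two
structural shortcuts: `no_diffusible_to_diffusible` (secreted signals
interact only through cell-autonomous factors) and
`diffusible_self_inhibition` (self-edges on secreted signals represent
clearance and must be inhibitory). Phase constraints act as a filter on
witnesses: a topology survives step 5 only if some witness's predicted
phase pattern satisfies every required relation.

Two fixture-level choices deserve a note. In the `nodal_lefty` fixture
the inhibitor's outgoing edges are sign-constrained negative wherever
they land: both candidate mechanisms are inhibitions of the activator
branch, and leaving the sign free admits an activating variant that
changes the receptor-level network's classification. In the `yeast_ip`
fixture the receptor-signaling node `u` is activated only by its
ligands: its self-edge and a synthase input (`u<-u`, `u<-z`) are
excluded, because every other candidate interaction in that circuit is
transcriptional and acts on the hormones and the synthase. With these
constraints the screen returns 16 candidate circuits (5 Type I, 3
Type II, 8 Type III), and the catalog contains the engineered
receptor-feedback circuit — whose two decay self-edges must sit on the
hormone and the synthase; the algebra rules out the alternative
placements, since no full cycle cover exists and the determinant
condition $a_4 > 0$ cannot hold — as a Type II entry.

## Phases, simulation, and what the generator does not capture

The predicted phase pattern of a surviving topology is the sign vector
of the dominant eigenvector of $J - q_*^2 D$ at the fastest-growing
wave number, normalized so the first diffusible node is positive; nodes
sharing a sign peak together. For band instabilities the dominant root
at the open determinant channel is real, so the read-out is
well-defined.

`simulate_rd()` confirms predictions with explicit finite differences:
forward Euler, zero-flux boundaries, 3-point (1D) or 5-point (2D)
Laplacians, time step checked against the diffusion CFL bound
$\Delta t \le h^2 / (2 \max d_i \cdot \mathrm{dims})$. Kinetics are the
clamped-linear construction: the reaction term is the linear form
clamped to $[-s, s]$ ($s = 1$ by default) and the deviation fields
saturate at $\pm s$, so trajectories are bounded by construction while
the linearization at the origin recovers $J$ exactly — the property the
screen certifies. This is a deliberate minimal construction, not a
mechanistic kinetic model: it reproduces linear wavelength selection
(the spatial spectrum peaks within one bin of the dispersion argmax
while amplitudes are still moderate), growth rates (within ~10% at
small noise), and phase relations, but saturated long-time patterns
slowly coarsen, and no positivity of absolute concentrations, cell
growth, or mechanochemical coupling is represented. Passing simulation
tests therefore validate the *linear* predictions of the screen, not
any particular biochemical implementation.

## Problem sizes and reproducibility

The default test and acceptance runs use the full 3-node catalog
(84 networks, 1,600 sign assignments) and the constrained screens at
the default 20,000-draw budget; the unconstrained 4-node catalog
(11,440 networks) is exercised through its graph filters and through
re-verification of sampled survivors, since the full stability screen
of its 76,416 sign assignments is a bulk computation that adds no
methodological coverage. Five-node screens are supported when
constraints keep the per-network topology count under `max_topologies`
(the `bsw_five_node` fixture is an example with one free edge). Every
search derives a per-(network, topology) sub-seed from the master seed,
so catalogs are bit-reproducible for a given config and seed, and
recorded witnesses replay.

## Known limitations

* Degrees $N > 5$ are unsupported: the Abel–Ruffini theorem bars
  general closed-form root criteria, and the degree-5 Routh array is
  the practical boundary for this kind of screen.
* Existence decisions by sampling have one-sided error: a topology can
  be missed (never falsely admitted, since every witness is verified
  algebraically). Budget-doubling stability of the catalog counts is
  part of the acceptance suite.
* The band/any distinction matters for capacitor systems: they are
  reported Turing-unstable by `mode = "any"` but excluded from the
  banded catalogs because they select no finite wavelength in the
  linear theory.
* Robustness compares volumes inside one fixed parameter box; it is a
  relative measure for ranking topologies, not an absolute probability
  about any biological system.
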
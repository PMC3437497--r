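---
title: "Modelling structure-function relations in Wilson-Cowan brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling structure-function relations in Wilson-Cowan brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Each cortical area is a Wilson-Cowan pair: an excitatory-like activity $u$
and an inhibitory-like activity $v$ coupled through a logistic firing-rate
function $f(x) = 1/(1+e^{-x})$,

$$\dot u_i = -u_i + f\!\Big(c_1 u_i - c_2 v_i + P
  + \varepsilon \sum_j w_{ij} u_j\Big), \qquad
  \dot v_i = -v_i + f\big(c_3 u_i - c_4 v_i + Q\big),$$

with the classical constants $c_1 = c_2 = c_3 = 10$, $c_4 = -2$. We write
the sigmoid arguments in the standard excitatory-minus-inhibitory form
($c_1 u - c_2 v$, $c_3 u - c_4 v$); with $c_4 = -2$ the $v$-population
therefore receives $+2v$ self-feedback. This is the unique sign placement,
at these constants, for which the node has a Hopf bifurcation inside the
explored window (an all-plus convention forces $\det J < 0$ whenever
$\operatorname{tr} J = 0$, so no oscillation could ever arise), and it
reproduces the expected bifurcation skeleton: a limit-cycle region bounded
by Hopf and saddle-node curves in the $(P, Q)$ plane, with one or three
rest states elsewhere.

$P$ and $Q$ are background drives to the two populations and are the axes
of every experiment here ($P \in (-6, 6)$, $Q \in (-12, 0)$). The
structural connectivity (SC) is a binary directed matrix $b$ with
$b_{ij} = 1$ meaning a link from node $j$ to node $i$; rows are normalized
($w_{ij} = b_{ij} / \sum_k b_{ik}$) so every connected node receives unit
total input, and the coupling strength is $\varepsilon = 1$ unless stated.

## Simulation protocol

Integration is Euler-Maruyama with step $dt = 0.1$: the deterministic drift
plus additive white Gaussian noise on $u$ only, independent across nodes
and steps. The noise parameter is a diffusion amplitude: an increment is
`noise_sigma * sqrt(dt) * xi`, so variance accumulates at
`noise_sigma^2` per unit time. The default `noise_sigma = 0.1` makes that
rate 0.01, the standard reading of a white noise of variance 0.01; the
amplitude-0.01 alternative is so weak that unstable-synchrony regimes stay
coherent over practical run lengths, which defeats the purpose the noise
serves (letting the system find its stable solutions). Runs last
$T = 10{,}000$ time units by default with the first 1000 discarded; the
test-scale preset uses $T = 3000$ with a 300 time-unit transient, which is
past the slowest transients we observe (oscillation onset takes tens of
time units; module-level locking a few hundred). Initial conditions are
uniform on $(0, 1)$ per node; an optional quenched per-node jitter of $P$
(uniform on a configurable interval, drawn once per run) models mild node
heterogeneity. All randomness flows through R's RNG, so a seed makes runs
bit-identical, including inside the compiled integrator.

The forward flow maps the box $[-0.25, 1.25]^2$ into itself, so noise-free
trajectories are bounded; the integrator still aborts with diagnostics if
any state exceeds 10 in magnitude (it never should).

## Functional connectivity

Two measures, both computed from the $u$-series after transient removal:

* **Pearson correlation** of every series pair.
* **Mean phase coherence**: instantaneous phases come from the angle of the
  analytic signal (FFT half-spectrum method) of each mean-centred series;
  entry $(i,j)$ is $|\langle e^{i(\phi_i(t)-\phi_j(t))}\rangle_t|$. The
  mean-centring is necessary because the analytic-signal phase of a
  nonzero-mean signal is ill-defined; the first and last 5% of samples are
  excluded from the average to suppress boundary ringing (configurable).

Correlation is signed and penalizes anti-phase locking; phase coherence is
1 for any fixed lag. The two therefore diverge exactly where oscillators
lock away from in-phase, and both are reported throughout.

## Graph measures and SC-FC agreement

The FC matrix is binarized by keeping the $K$ largest off-diagonal values,
$K$ chosen so the density matches the SC (ties broken lexicographically so
results are deterministic). The directed SC is symmetrized by OR (a link in
either direction counts) for all comparisons with the symmetric FC; AND is
available. Metrics: average shortest-path length $L$ (BFS, averaged over
connected pairs only, with the disconnected fraction reported rather than
an infinite or penalized value, so $L$ stays comparable across the plane
where binarized FC may fragment), average local clustering $C$ (nodes of
degree < 2 contribute 0), and the small-world index
$\sigma = \gamma/\lambda$ with $\gamma = C/C_{\mathrm{rand}}$,
$\lambda = L/L_{\mathrm{rand}}$ against a seeded ensemble of 100 $G(n,m)$
graphs (a sampled reference, not a closed form, because $n \approx 12$-$47$
is small). SC-FC agreement is the Jaccard coefficient of the off-diagonal
link sets. The chance level of agreement is estimated by redrawing the
comparison network's edge positions uniformly (100 seeded permutations).

## Phase reduction

The affine change of variables $x = c_1 u - c_2 v + P$,
$y = c_3 u - c_4 v + Q$ puts the node in a form where coupling enters the
$\dot x$ equation additively as $\varepsilon \sum_j w_{ij} f(x_j)$. For a
$T$-periodic solution of the transformed node:

1. **Limit cycle**: long transient (500 time units) under `lsoda` with a
   compiled right-hand side, period from mean-level upward crossings of $x$
   (linear interpolation of crossing times), orbit resampled at $M$ uniform
   points ($M = 2048$ for headline numbers, 1024 in maps; the $H'(0)$ sign
   is stable from $M = 256$). Amplitude below $10^{-4}$ is reported as an
   explicit no-limit-cycle outcome, since much of the window is quiescent.
2. **Adjoint**: the phase response $Z$ solves $\dot Z = -J(t)^\top Z$ with
   $Z \cdot F = 1/T$ (phase in cycles). The periodic initial direction is
   the left eigenvector of the monodromy matrix for the trivial Floquet
   multiplier; a few backward RK4 passes over the stored orbit polish it
   (backward time contracts the nontrivial mode by the Floquet multiplier
   per period), and the samples are then normalized pointwise. Fixed-step
   RK4 on the orbit's own grid (stages land on half-grid samples) proved
   far more robust here than adaptive integration through an interpolated
   Jacobian; the residual spread of $Z \cdot F$ before normalization is
   kept as a quality diagnostic and sits near $10^{-10}$.
3. **Interaction function**:
   $H(\theta) = \frac{1}{T}\int_0^T Z_x(s)\, f(x(s+\theta T))\, ds$, and
   its slope at zero lag by direct quadrature,
   $H'(0) = \int_0^T Z_x f'(x) \dot x \, ds$ - no differentiation of
   sampled data; a spectral derivative of the sampled $H$ is the
   cross-check and agrees to ~$10^{-6}$ relative.

$H'(0) > 0$ makes in-phase locking of a coupled pair (and of a globally
coupled network) stable; the synchrony Jacobian
$\varepsilon H'(0)(w_{ij} - \delta_{ij}\sum_k w_{ik})$ always has a zero
eigenvalue (free common phase) and, for uniform all-to-all weights
$w_{ij} = 1/N$, nonzero eigenvalues $-1$ (in units of $\varepsilon H'(0)$)
with multiplicity $N-1$. Under row normalization $c = 1/(N-1)$ the repeated
eigenvalue is $-N/(N-1)$ instead; both are negative, so the stability
verdict is identical, and the scaled-units option makes such algebraic
checks scale-free.

Within the canonical window the map of $H'(0)$ shows a central stable
region with two unstable (negative) lobes at the lower-left and upper-right
of the limit-cycle region; at the three reference points
$(-2.5, -8.5)$, $(-1.5, -6)$, $(2.5, -3.5)$ the signs are $(-, +, -)$.
The first and third points are exchanged by an exact symmetry of the model
($u \to 1-u$, $v \to 1-v$ with accordingly reflected drives), which the
pipeline reproduces to five digits - a useful end-to-end consistency check.
Periods across the oscillatory region are a few to ~15 time units on a
coarse grid and diverge near the saddle-node boundary, passing through
40-60 in a narrow strip (e.g. near $P = 3.1$, $Q = -6$).

## Parameter-plane sweeps

A sweep simulates every $(P, Q)$ grid point with a per-point seed derived
deterministically from a base seed and the grid index (any point can be
reproduced standalone), estimates both FC measures, binarizes at the SC
density, computes the graph metrics against one shared random reference,
records the Jaccard agreement, and joins the $H'(0)$ map. The test-scale
default is a 13 x 13 grid (increment 1.0) with $T = 3000$ and a 12-node
modular SC (3 modules of 4), sized so a full sweep takes about two minutes
on one core; the publication-scale 49 x 49 / $T = 10^4$ / 47-node setting
is the `preset = "paper"` configuration of the same machinery.
`compare_with_theory()` then contrasts mean agreement over
$H'(0) > 0$ versus $H'(0) < 0$ points and reports the point-biserial
association, for the Jaccard agreement and the small-world index.

## The synthetic cortex fixture

`synthetic_cortex_fixture()` stands in for an empirical macaque
connectome: 47 nodes, five planted communities (within-community link
probability 0.6, between 0.08, density ~0.18), directed, connected, fully
seeded. It emulates the size, density and modular tendency of cortical
connectivity but none of its empirical specifics - no hierarchy, no
distance-dependent wiring, no reciprocity bias beyond what the planted
blocks induce. Results on it demonstrate the machinery on a realistic
scale; they are not statements about any real cortex.

## Known limitations

* The weak-coupling theory is exact only as $\varepsilon \to 0$. At the
  working coupling $\varepsilon = 1$ the mean input $\approx 0.5$ shifts
  each node's operating point by about $+0.5$ in effective $P$, and in
  small fully connected modules the unstable-synchrony regimes settle into
  noisy near-in-phase motion rather than the anti-phase clusters predicted
  pairwise. Residual within-module dependence then keeps density-matched
  agreement above chance even where $H'(0) < 0$: theory-simulation
  correspondence at $\varepsilon = 1$ is an inequality of means across the
  plane, not point-wise zero agreement. At $\varepsilon \lesssim 0.3$ the
  pairwise predictions hold sharply (anti-phase locking where
  $H'(0) < 0$, in-phase where $H'(0) > 0$).
* Axonal delays are deliberately absent; they would enter the reduced
  description as phase shifts of $H$ and can reverse stability verdicts.
* The Euler-Maruyama step $dt = 0.1$ resolves the short (~5 time-unit)
  periods at first order: measured periods carry a few percent bias that
  halving $dt$ halves. Sign-level conclusions are insensitive to this.
* Path-based measures on binarized FC inherit the usual caveats of
  interpreting "paths" in a statistical-dependence graph.
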
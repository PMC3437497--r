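# scfc

Functional connectivity (FC) — the pattern of statistical dependence
between the activities of brain areas — only partly reflects the anatomy
(structural connectivity, SC) that couples those areas. `scfc` implements a
complete modelling chain for asking *when* function mirrors structure: a
network of Wilson–Cowan neural-mass oscillators coupled by a binary
directed connectome, FC estimation from the simulated activity, graph-
theoretic characterization of the resulting functional networks, and a
weakly-coupled-oscillator phase reduction that predicts, from single-node
dynamics alone, the parameter regimes where FC recovers the SC. It is
aimed at computational neuroscientists studying structure–function
coupling and its breakdown (e.g. as a candidate mechanism for FC
randomization in disease).

## The model

Each area is a Wilson–Cowan pair $(u_i, v_i)$ with logistic firing rate
$f(x) = 1/(1+e^{-x})$:

$$\dot u_i = -u_i + f\Big(c_1 u_i - c_2 v_i + P + \varepsilon \textstyle\sum_j w_{ij} u_j\Big),
\qquad \dot v_i = -v_i + f\big(c_3 u_i - c_4 v_i + Q\big),$$

with $c_{1,2,3} = 10$, $c_4 = -2$, row-normalized weights $w$, coupling
$\varepsilon = 1$, and background drives $(P, Q)$ as the experimental
axes. Integration is Euler–Maruyama ($dt = 0.1$) with weak additive noise
on $u$. FC is measured by Pearson correlation and by mean phase coherence
$R_{ij} = |\langle e^{i(\phi_i - \phi_j)}\rangle_t|$ with phases from the
analytic signal. FC matrices are binarized at the SC's density and
compared to the (OR-symmetrized) SC by the Jaccard coefficient of their
link sets; small-worldness is $\gamma/\lambda$ against a matched
Erdős–Rényi ensemble.

The theory side reduces each oscillating node to a phase: the package
computes the limit cycle, the adjoint phase-response vector $Z$
(normalized $Z \cdot F = 1/T$), and the pairwise phase interaction
function $H(\theta)$ with its slope $H'(0)$ by direct quadrature. Where
$H'(0) > 0$, linked oscillators pull into phase and FC tends to match the
SC; where $H'(0) < 0$, synchrony is unstable and the agreement degrades.

## Worked example

```r
library(scfc)

# theory: phase reduction at (P, Q) = (-1.5, -6)
pr <- phase_reduction(wc_params(-1.5, -6))
glance(pr)
#>       P     Q period H_prime_0 H_prime_0_spectral synchrony_stable
#> 1  -1.5    -6   4.69    0.0428             0.0428 TRUE

# simulation: 3 fully connected modules of 4 nodes
sc  <- modular_sc(3, 4)
cfg <- sim_config(t_total = 3000, t_transient = 300, seed = 1)
ts  <- drop_transient(simulate_network(sc, wc_params(-1.5, -6), cfg))
fc  <- mean_phase_coherence_fc(ts)

scb <- sc_to_binary(sc)
net <- binarize_to_density(fc, scb$m / (scb$n * (scb$n - 1) / 2))
jaccard_similarity(scb, net)
#> [1] 1
small_world_index(net, random_reference(net$n, net$m, seed = 1))
#>   L C L_rand C_rand lambda gamma sw_index disconnected_pair_fraction
#> 1 1 1   2.07   0.23  0.482  4.35     9.02                      0.727
```

The node oscillates with period ≈ 4.7 time units and $H'(0) = +0.043 > 0$:
synchrony within connected groups is stable. The simulated FC, thresholded
to the structural density, then reproduces the modular anatomy exactly
(Jaccard 1); the three functional cliques give path length and clustering
of 1 within modules and a strongly modular (small-world index ≈ 9,
disconnected fraction 0.73) functional topology. Rerunning at
$(-2.5, -8.5)$, where $H'(0) = -0.082 < 0$, degrades the agreement.

Sweeps over the whole $(P, Q)$ plane and the theory map come from one call
each:

```r
res <- run_sweep(sweep_config(modular_sc(3, 4), base_seed = 1))
compare_with_theory(res)   # mean Jaccard, H'(0) > 0 vs < 0, per FC measure
autoplot(res)              # agreement heat maps
autoplot(hprime_map())     # stability of the synchronous state
```

A thin command-line wrapper with subcommands `simulate`, `fc`, `metrics`,
`hprime-map`, `sweep` and `compare` is installed at
`system.file("cli", "scfc", package = "scfc")`.

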
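---
title: "Charge blockiness and the conformations of Markov polyampholytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge blockiness and the conformations of Markov polyampholytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyample)
```

## The model

A polyampholyte (PA) is a flexible chain of $N$ monomers of size $a$ in a
salt-free $\Theta$ solvent. A fraction $f$ of the monomers is ionic, spaced
equidistantly along the backbone, each carrying charge $\pm e$. The strength
of electrostatics is set by the reduced Bjerrum length $u = l_B/a$.
Everything in this package works in reduced units: $a = 1$, $k_BT = 1$,
$e = 1$.

The quenched sign sequence follows a first-order Markov process. The
conditional probability that an ionic monomer repeats the sign of its
predecessor is $p_{++} = p_{--} = (1+\lambda)/2$, which keeps the ensemble
statistically neutral; $\lambda \in [-1, 1]$ is the second eigenvalue of the
transition table. Runs of like signs are geometric, so the mean net charge of
a block of consecutive like charges is $1 + \Lambda$ with

$$\Lambda = \frac{1+\lambda}{1-\lambda},$$

the *blockiness*: $\Lambda = 0$ for strict alternation, $1$ for independent
random signs, and $\Lambda \to \infty$ as sequences become single-signed.
Although each chain is neutral on average, a single realization carries a
characteristic net charge $Q \simeq \sqrt{fN\Lambda}$; the exact finite-$N$
variance is

$$\mathrm{Var}(Q) = n\,\frac{1+\lambda}{1-\lambda}
  - \frac{2\lambda\,(1-\lambda^{n})}{(1-\lambda)^2}, \qquad n = fN,$$

which the test suite verifies against exhaustive enumeration over all $2^n$
sign sequences for $n \le 14$.

## Globule interior and the Rayleigh ratio

Oppositely charged monomers attract, collapsing long chains into globules
whose density depends on the sequence class:

* nearly alternating ($\Lambda < \Lambda_{a/r} = u\sqrt{f}$): dipole
  attractions against three-body repulsion give $\phi_a = u^2 f^{3/2}$;
* essentially random ($\Lambda_{a/r} < \Lambda < \Lambda_{r/hb}$): charged
  concentration blobs form a correlated melt with $\phi_r = u f \Lambda$;
* highly blocky ($\Lambda > \Lambda_{r/hb} = u^{-2/3} f^{-1/3}$): the blob
  charge saturates at the electrostatic-blob charge $q_e = f(uf^2)^{-2/3}$
  and the density levels off at $\phi_{hb} = (uf^2)^{1/3}$, independent of
  $\Lambda$.

`globule_density()` evaluates $\phi = \max(\phi_a, \min(\phi_r, \phi_{hb}))$,
which reproduces all three branches and is continuous at both crossovers
because every prefactor is set to exactly one (see "Numerical conventions").

A globule of radius $R = (N/\phi)^{1/3}$ carrying charge $Q$ is destabilized
when the Coulomb self-energy $u Q^2/R$ exceeds the surface energy
$(R/\xi)^2$, $\xi = 1/\phi$. Their ratio, returned by `rayleigh_ratio()`,
reduces to $I = uf\Lambda/\phi$: negligible for alternating chains, exactly
$1$ throughout the random regime (two opposing tendencies compensate), and
large for blocky chains, which split into many-bead pearl necklaces.

## Five regimes

`classify_regime()` assigns the blockiness to one of five regimes separated
by $\Lambda_{a/r}$, $\Lambda_{r/hb}$,
$\Lambda_{b/s} = u^{-4/9} f^{1/9} N^{1/3}$, and $\Lambda_{PE} = fN$:

| regime | conformation | charge location |
|---|---|---|
| I | spherical globule | (negligible) |
| II | necklace, about one bead | beads |
| III | many-bead necklace | beads |
| IV | necklace | strings |
| V | stretched polyelectrolyte | whole chain |

`predict_conformation()` evaluates the full observable set per regime —
chain size $R$, bead count $N_\mathrm{bead}$, bead/string masses, bead
diameter, string length, necklace length, and the bead/string charges. The
boundary $\Lambda_{b/s}$ follows from the triple equality of bead charge,
block charge, and ionic monomers per string, $Q/N_\mathrm{bead} \simeq
\Lambda \simeq f m_\mathrm{str}$; there the bead count peaks, rising
linearly in III and falling as $\Lambda^{-1/2}$ in IV, while the bead charge
drops discontinuously by $(N/g_e)^{1/9}$ — asserted, not smoothed.

```{r}
p <- scaling_params(u = 1, f = 1/16, N = 1e4, Lambda = 1)
regime_boundaries(p)
predict_conformation(p)
```

## Numerical conventions

* **Unit prefactors.** Scaling theory fixes laws only up to $O(1)$ factors.
  Setting every prefactor to one makes branch intersections coincide exactly
  with the crossover formulas, so continuity checks in the tests are exact
  identities rather than approximate ones.
* **Half-open intervals.** Regimes are `[boundary, next)`, left-closed; a
  value exactly on a boundary belongs to the higher regime.
* **Caps with warnings.** $\phi$ is capped at 1 (dense limit outside the
  theory), the characteristic charge at $fN$ (a chain cannot carry more),
  and the regime-II string mass at $N$ (the raw law exceeds the chain length
  in the marginal corner $uf\Lambda < N^{-1/2}$, where the theory's own
  assumption $m_\mathrm{str} \ll m_\mathrm{bead}$ fails).
* **Collapsed boundaries.** For parameter sets with $u^2 f \ge 1$ the scales
  no longer separate ($\Lambda_{a/r} \ge \Lambda_{r/hb}$); classification
  warns and proceeds against the running maximum of the boundaries.

## The necklace free energy

`necklace_free_energy()` scores a necklace of $n$ beads and $n$ strings
carrying the characteristic charge $Q$ split by a fraction
$q_\mathrm{str}$: bead Coulomb self-energy $uQ_\mathrm{bead}^2/D$, bead
surface energy $(D/\xi)^2$, string surface/stretching energy
$l_\mathrm{str}/\xi$, bead–bead repulsion $uQ_\mathrm{bead}^2/l_\mathrm{str}$
(counted $n-1$ times), and string Coulomb self-energy
$uQ_\mathrm{str}^2/l_\mathrm{str}$. Strings are one concentration blob
thick, $m_\mathrm{str} = l_\mathrm{str}\xi$, and monomers are conserved.
Two constraints encode the quenched sequence statistics: a string can carry
at most one uncompensated block, $Q_\mathrm{str} \le \Lambda$, and no more
charge than its ionic content, $Q_\mathrm{str} \le f m_\mathrm{str}$.

The design was genuinely open here: the migration boundary can be obtained
variationally in closed form, but rather than committing to one algebraic
route, `minimize_necklace()` scans a dense $(n, q_\mathrm{str})$ grid
(string mass minimized internally by a log grid plus local refinement) and
`charge_migration_crossing()` locates where the optimal string-charge
fraction crosses $1/2$. For $u = f = 1$, $N = 10^4$ the crossing lands at
about half of the closed-form $\Lambda_{b/s}$ — the agreement the acceptance
test asserts at the factor-of-three level appropriate for unit-prefactor
scaling estimates.

## The coarse-grained simulator

`run_langevin()` integrates a single bead-spring chain with the BAOAB
Langevin scheme. Defaults, all overridable in `sim_config()`:

* **Bonds**: FENE with $k = 30$, $R_0 = 1.5$ (Kremer–Grest values).
* **Excluded volume**: Lennard-Jones, $\sigma = 1$, cutoff $2.5$,
  energy-shifted at the cutoff, with $\varepsilon = 0.34$ — a well depth
  near the $\Theta$ point so that the uncharged backbone is close to ideal,
  making the charge-driven physics the only large effect.
* **Coulomb**: $u q_i q_j / r_{ij}$ over all charged pairs, open boundaries,
  direct $O(N^2)$ sum (appropriate for one isolated chain), $u = 1$ by
  default.
* **Integration**: $dt = 0.01$ (enforced stability bound), friction
  $\gamma = 1$, bit-reproducible noise (mt19937_64 with a hand-rolled
  Box–Muller transform, so a seed fixes the trajectory exactly).
* **Initialization**: self-avoiding random walk; the equilibration window is
  discarded and flagged if the Rg running mean still drifts by more than 10%
  over its last third.

For validation the bond model can be switched to a harmonic spring with
$k = 3$, $r_0 = 0$ and all pair forces off, giving an ideal Gaussian chain
whose $\langle R_g^2\rangle = b^2(N^2-1)/(6N)$ is known exactly — the
simulator oracle used in the tests, together with equipartition
($\tfrac12 k_BT$ per degree of freedom within 2%) and force/energy
consistency against a numerical gradient ($10^{-5}$ relative).

## Pearl detection

`detect_beads()` builds the contact graph (edges where $r_{ij} < 1.5$,
backbone neighbors excluded so a taut string is not a one-dimensional
cluster) and takes connected components; components with at least
`min_bead_size` monomers (default 4; for dilute charge use
$\max(4, g_e)$, since strings are one electrostatic blob thick) are beads.
The descriptor partitions monomers exhaustively, and charge bookkeeping is
exact integer arithmetic. No operational bead criterion is unique: any
quantitative bead count is cutoff-sensitive, which is why the analysis
functions expose both knobs and the tests probe them on constructed
geometries (`make_fixture("ideal_necklace")`) where the expected answer is
known by construction.

## What the synthetic conditions do and do not show

The generator's defaults are the study conditions of the scaled-down
fixed-charge experiment: `pipeline_fig4_scaled()` conditions Markov
sequences on an exact net charge $Q = 20$ at $N = 256$, $f = 1$, compares
$\lambda \in \{-0.5, 0, 0.5\}$ over 8 independent seeds each, with
$4\times10^4$ equilibration and $6\times10^4$ production steps per run.
Fixing $Q$ isolates the correlation-attraction effect of blockiness from the
charge-imbalance effect, and the ensemble-mean gyration radius decreases
monotonically with $\lambda$. These problem sizes resolve the ordering
robustly; they are far from the asymptotic scaling limit, so the pipeline
tests the *trend*, not the exponents. Likewise the Markov generator emulates
idealized two-letter charge sequences: real intrinsically disordered
proteins have composition constraints, partial charges, and higher-order
correlations that the model deliberately omits (`charges_from_protein()`
maps real sequences onto the two-letter alphabet, losing exactly that
information).

## Known limitations

* No salt, no counterion condensation, no solvent-quality deviations from
  $\Theta$, single chains only (no coacervation).
* Scaling predictions carry unknown $O(1)$ prefactors; only ratios, trends,
  and crossover locations are meaningful, not absolute magnitudes.
* The quenched-disorder question — how individual sequence realizations
  scatter around ensemble-mean predictions near the III/IV transition —
  is sampled (every generated sequence is one realization) but not
  theorized.
* The free-energy minimizer shares the scaling theory's unit-prefactor
  convention; its crossover location is meaningful only up to an $O(1)$
  factor, which is how the tests treat it.
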
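---
title: "Damped driven elastic networks: model, parameters and design choices"
author: "anmdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Damped driven elastic networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anmdyn)
```

## The model

`anmdyn` treats a protein as a Cα elastic network: one node per residue at
its Cα position, Hookean springs of uniform stiffness $\gamma$ between all
node pairs closer than a cutoff $r_c$. The elastic energy of this network
has the standard anisotropic-network-model (ANM) Hessian: for a spring
$(i, j)$ of equilibrium length $r_{ij}$ the off-diagonal $3\times3$ block
is $-\gamma\, \hat r_{ij}\hat r_{ij}^{\mathsf T}$ (outer product of the
unit bond vector), and diagonal blocks are minus the sum of the row's
off-diagonal blocks, which makes rigid translations and infinitesimal
rotations cost no energy.

Two ingredients turn this static picture into quantitative dynamics:

* **Mass.** Each node carries the average mass of its residue type
  (a built-in 20-entry table, in amu), giving a diagonal mass matrix
  $[M]$. The generalized eigenproblem
  $([H] - \omega_n^2 [M])\,\delta_n = 0$ is solved as the ordinary
  symmetric problem on $M^{-1/2} H M^{-1/2}$ and back-transformed so the
  mode matrix is mass-orthonormal. Frequencies come out in physical units
  (the low end of a protein-sized network sits in the GHz range for
  calibrated $\gamma$ values of order 0.1 N/m).
* **Damping.** Each internal mode $n$ gets a dimensionless damping ratio
  $\xi_n \in (0, 1)$ (underdamped regime). A single scalar applied to all
  modes is the default; the data model accepts a per-mode vector. The
  modal damping matrix is never formed explicitly — the decoupled
  single-degree-of-freedom equations are solved analytically.

Forcing is a pattern $\{F\}$ of 3N independent components drawn uniformly
from $(-10^{-10}, +10^{-10})$ N — random in space, harmonic in time,
$F(t) = F\sin(\omega_F t)$. The per-mode analytic solution with a resting
start ($p_n(0) = \dot p_n(0) = 0$) is the sum of a decaying transient at
the damped frequency $\omega_{d,n} = \omega_n\sqrt{1-\xi_n^2}$ and a
steady harmonic at $\omega_F$; the phase uses the two-argument
arctangent, $\phi_n = -\mathrm{atan2}(2\xi_n\beta_n,\, 1-\beta_n^2)$, so
it passes continuously through resonance ($0$ at $\beta_n \to 0$,
$-\pi/2$ at $\beta_n = 1$, $-\pi$ as $\beta_n \to \infty$). The transient
constant $B_n = (\xi_n\omega_n A_n - C_n\omega_F\cos\phi_n)/\omega_{d,n}$
carries the *forcing* frequency in its second term; this is what the
resting initial conditions demand, and the test suite verifies the full
solution against an independent `deSolve` integration of the coupled
second-order system in coordinate space.

Rigid modes are excluded from every response sum: the static response is
the generalized pseudo-inverse over internal modes, and a random force's
net push/torque would otherwise produce ballistic center-of-mass drift,
which is not part of internal deformation.

## Parameters that matter

| parameter | units | default | notes |
|---|---|---|---|
| cutoff $r_c$ | Å | 15 | inclusive comparison ($\le r_c$); 12–15 Å is the conventional range for Cα ANMs |
| spring constant $\gamma$ | N/m | calibrated | `calibrate_gamma()` matches mean computed to mean experimental B-factor; computed B $\propto 1/\gamma$, so calibration is one rescaling |
| temperature $T$ | K | 300 | enters only the B-factor formula; the calibrated $\gamma$ scales linearly with the assumed $T$ |
| damping ratio $\xi$ | – | none (must be given) | $0 < \xi < 1$ enforced; study values 0.001 / 0.01 / 0.1 |
| force amplitude | N | $10^{-10}$ | per-component uniform bound; overlap is amplitude-invariant, RMSD is not |
| forcing frequency $f_F$ | THz | — | scans default to 500 points in 0.001–0.5 THz (`scan_preset("paper")`), 25 points for `"desk"` |
| time grid | ps | $\Delta t = T_F/100$ | duration = transient window + 10 forcing cycles |

The transient window defaults to five damping times of the softest mode,
$5/(\xi\,\omega_7)$, capped at 2000 ps.

## The evaluation window

The maximum overlap reported by `frequency_scan()` depends strongly on
*when* you look. Two windows are supported:

* `transient_ps = "auto"` (default): maxima are taken over ten forcing
  cycles *after* the transient window — the steady-state view.
* `transient_ps = 0`: maxima over ten forcing cycles *from rest*.

The distinction is physical, not cosmetic. The softest mode's transient
decays over $1/(\xi\omega_7)$, which at $\xi = 0.01$ and GHz-range
$\omega_7$ is thousands of picoseconds. Within a long post-transient
window, forcing at *any* frequency — even far above the spectrum — has
had time to ring up the soft mode, so overlaps with a hinge-like change
are high everywhere and the frequency dependence flattens. Scored over
ten cycles from rest, the soft mode only responds appreciably when the
forcing is near-resonant with it, and the low-frequency preference of
collective conformational changes emerges cleanly. The acceptance script
and the end-to-end hinge test therefore score from rest; steady-state
scoring remains the scan default for flexibility studies where start-up
effects are a nuisance.

## What the synthetic fixtures emulate

`make_diatomic()` is the textbook two-mass oscillator: one internal mode
at $\omega = \sqrt{2\gamma/m}$ exactly, and — being collinear — five
rather than six rigid modes (rotation about the bond axis stores no
elastic energy). It anchors the frequency scale, the resonance
amplification closed form $1/(2\xi)$ and the zero-mode bookkeeping.

`make_hinge()` emulates a hinged two-domain protein with a known
open→closed transition: two compact random lobes, each anchored through
a deterministic base triangle to a 3-node-plus-one neck cluster, the
closed partner generated by rigidly rotating one lobe about the neck.
Geometry details are load-bearing:

* every lobe attaches to *at least three non-collinear* external points —
  a lobe tied to one or two points (or to collinear ones, e.g. a straight
  neck) could pivot freely, producing spurious zero-energy mechanisms;
* the neck cluster is wide in $z$ and narrow in $y$, which stiffens
  out-of-plane bending and torsion and leaves the in-plane bend — the
  direction of the constructed closing rotation — as the softest internal
  mode. Generation verifies this (overlap of mode 7 with the change must
  exceed that of a mid-spectrum mode) and re-draws the lobes with an
  incremented seed otherwise; the accepted seed is recorded on the
  fixture.

One consequence of least-squares superposition is worth knowing: with
equal-sized lobes, the Kabsch fit splits the hinge rotation between both
lobes and relocates the effective rotation axes into them, so the
superposed displacement field is *not* localized on the rotated lobe —
the neck can move most. This is correct behaviour of the standard
alignment, and the same effect operates on real open/closed crystal
pairs.

What the fixtures do **not** emulate: secondary-structure connectivity
(no chain topology — lobes are point clouds), heterogeneous residue
masses (fixtures use one mass), crystal-environment contributions to
B-factors, anharmonicity, and solvent memory effects. Tests passing on
these fixtures validate the machinery — network assembly, eigensolutions,
the analytic response, the metrics — not the biological fidelity of any
particular protein prediction.

`make_synthetic_bfactors()` closes the calibration loop: it generates an
"experimental" B-factor column from the network's own fluctuation formula
at a known $\gamma^\*$, optionally degraded by multiplicative lognormal
noise (`noise_fraction` is the sdlog). Noise-free, `calibrate_gamma()`
recovers $\gamma^\*$ to floating-point accuracy; at 20% noise the
recovered value is biased only by the lognormal mean factor
$e^{\sigma^2/2}\approx 1.02$, well inside the 5% the tests demand.

## Numerical choices

* **Units.** All linear algebra is SI (kg, m, s, N/m); interfaces are Å,
  amu, ps, THz, Å². One conversion table, used everywhere.
* **Zero modes.** An eigenvalue counts as zero when
  $\lambda < 10^{-8}\lambda_{\max}$. Exactly six are required (five when
  all nodes are collinear, detected by the rank of the centered
  coordinates); any other count raises a degeneracy error reporting the
  eigenvalues around the threshold — this catches under-constrained
  geometries (floppy necks) rather than silently absorbing them.
* **Eigen-solver.** Dense symmetric `eigen()`; for the intended problem
  sizes ($3N \lesssim 3000$) this is simpler and more robust than
  sparse/partial solvers.
* **Spring-constant rescaling.** For uniform springs the mode shapes are
  $\gamma$-independent and $\omega_n^2 \propto \gamma$, so
  `rescale_gamma()` converts a decomposition exactly without re-solving —
  calibration costs one eigensolve.
* **Cutoff** comparison is inclusive ($\le r_c$), fixed for
  reproducibility.
* **Altloc resolution** keeps the highest-occupancy conformer, ties to
  the first listed. Residues lacking a Cα are skipped with a warning;
  non-standard residue names fall back to the mean residue mass with a
  warning.
* **Undefined overlaps.** Frames with displacement norm below
  $10^{-6}$ Å are reported as missing, not zero — the overlap is
  undefined at $u = 0$.
* **Degenerate-subspace caveat.** Individual rigid-mode vectors are not
  unique (six-fold degenerate eigenvalue); only the subspace is. Tests
  and internal projections always treat the rigid modes as a block.
* **RNG isolation.** Every stochastic input (force patterns, fixture
  lobes, B-factor noise) draws from a private Mersenne-Twister stream
  seeded per object, leaving the session RNG untouched; seeds are
  recorded on the objects and in every output header.

## Problem sizes

The test suite runs on toy clouds of 5–10 nodes (where the coupled ODE
oracle is cheap and every quantity can be brute-forced), the diatomic,
and hinge fixtures of 26 nodes; scan tests use a handful of grid points.
The acceptance script uses the 26-node hinge with the 125-point desk
grid. These sizes make the whole pipeline — including the independent
`deSolve` integration — run in seconds while exercising every code path;
nothing in the implementation is specific to small systems, and the
dense eigensolve is the only step with cubic cost in $3N$.

## Known limitations

* Uniform $\gamma$ only; distance-weighted spring variants
  ($\gamma \propto r^{-p}$) are out of scope.
* Underdamped analytic solutions only ($\xi < 1$); overdamped and
  critically damped regimes, and stochastic (Langevin) forcing, are not
  implemented. Whether real protein modes are under- or overdamped in
  solvent is an open question in the literature; this package adopts the
  underdamped working hypothesis.
* Linear springs and small-amplitude theory: near resonance at low
  $\xi$ the computed amplitudes exceed the regime in which the harmonic
  expansion is strictly valid. The amplification numbers should be read
  as a linear-response statement, not literal ångström excursions.
* B-factor calibration assumes experimental B-factors reflect internal
  fluctuations only; crystal contacts, rigid-body disorder and
  refinement artifacts violate this to varying degrees, and the
  undocumented temperature convention makes $\gamma$ (and all absolute
  frequencies) meaningful only relative to the assumed $T$.
* The conformational-change vector depends on the node pairing
  (chain id + residue number intersection) and on which residues are
  resolved in both crystal forms; a few unpaired residues shift overlap
  values at the second decimal.
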
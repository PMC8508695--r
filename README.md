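# anmdyn

Dynamic harmonic perturbation response of protein elastic network models.

## The problem

Coarse-grained elastic network models (ENMs) predict protein
conformational changes from the reference structure alone, classically in
one of two ways: by comparing individual normal modes of the anisotropic
network model (ANM) with the observed open→closed displacement, or by
computing the *static* linear response to applied forces
(perturbation-response scanning). `anmdyn` combines the two: it augments
the Cα ANM with explicit mass and viscous damping matrices and solves the
full equations of motion

$$[M]\,\ddot u(t) + [C]\,\dot u(t) + [H]\,u(t) = \{F\}\sin(\omega_F t),$$

where $[H]$ is the ANM Hessian (uniform spring constant $\gamma$, cutoff
$r_c$), $[M]$ the diagonal residue-mass matrix, and $\{F\}$ a force
pattern that is random in space but harmonic in time. In the
mass-orthonormal modal basis ($\Delta^{\mathsf T}M\Delta = I$,
$\Delta^{\mathsf T}H\Delta = \mathrm{diag}(\omega_n^2)$) the system
decouples into damped driven oscillators with the analytic underdamped
solution

$$p_n(t) = e^{-\xi_n\omega_n t}\left[A_n\cos(\omega_{d,n}t) +
  B_n\sin(\omega_{d,n}t)\right] + C_n\sin(\omega_F t + \phi_n),$$

$$C_n = \frac{\delta_n^{\mathsf T}F}
 {\omega_n^2\sqrt{(1-\beta_n^2)^2 + (2\xi_n\beta_n)^2}},\qquad
 \phi_n = -\operatorname{atan2}(2\xi_n\beta_n,\,1-\beta_n^2),\qquad
 \beta_n = \omega_F/\omega_n,$$

with $A_n, B_n$ fixed by a resting start. The trajectory
$u(t) = \sum_n p_n(t)\,\delta_n$ is then scored against the observed
conformational change $\{CC\}$ (from Kabsch superposition of the two
crystal forms) via the time-dependent overlap
$O(t) = |u(t)^{\mathsf T}CC|\,/\,(\lVert u(t)\rVert\,\lVert CC\rVert)$,
per-frame RMSD and its dynamic amplification over the static response,
trajectory PCA, the Tama–Sanejouand collectivity of the change, and a
step-direction cosine measure of motion non-linearity. The spring
constant is calibrated so that the mean thermal B-factor predicted from
the internal modes matches the mean experimental B-factor.

Who is it for: structural bioinformaticians studying low-frequency
protein dynamics and open/closed transitions of hinged multi-domain
proteins (periplasmic binding proteins, lactoferrin, lipases, ...), and
anyone needing a clean, unit-carrying ANM with mass, damping and
frequency information in physical units (THz, N/m, Å², ps).

## Worked example

A synthetic two-lobe hinge whose open and closed forms differ by a known
20° closing rotation stands in for a real open/closed crystal pair (for
real proteins, start from `read_structure("xxxx.pdb")` instead):

```r
library(anmdyn)

fx   <- make_hinge(nodes_per_lobe = 8, hinge_angle = 20, seed = 1)
open <- make_synthetic_bfactors(fx$open, gamma = 0.1, noise_fraction = 0.2)

cal <- calibrate_gamma(open, cutoff = 15, temperature = 300)
cal$gamma
#> [1] 0.1013001

modes <- cal$modes
modes
#> Modal decomposition: 78 modes ( 6 rigid )
#>   lowest non-rigid frequency: 8.129 GHz
#>   highest frequency: 0.5272 THz
#>   gamma: 0.1013001 N/m

overlap(modes$modes[, 7], fx$cc)   # softest mode vs open->closed change
#> [1] 0.9718649
collectivity(fx$cc)
#> [1] 0.4626371

pat  <- random_force_pattern(open$n, seed = 42)
exc  <- harmonic_excitation(pat, freq_thz = modes$freq_thz[7], damping = 0.01)
traj <- synthesize_trajectory(modes, exc, transient_ps = 0, cycles = 10)
os   <- overlap_series(traj, fx$cc)
c(max_overlap = os$max, at_ps = os$t_max_ps)
#> max_overlap       at_ps
#>   0.9742925  77.4961314

dynamic_amplification(traj, static_response(modes, pat))
#> [1] 23.15457
```

Reading the numbers: calibration recovers the generating spring constant
(0.1 N/m) to within the injected 20% B-factor noise; the softest internal
mode lies in the GHz range and aligns with the constructed hinge change
(overlap 0.97); driving the network at that frequency with a *random*
force pattern produces a trajectory that repeatedly passes within
overlap 0.97 of the closed form, with a ~23× dynamic amplification of
the RMSD over the same forces applied statically. `frequency_scan()`
repeats this over a frequency × damping × force-pattern grid
(`scan_preset("desk")` or the full `"paper"` grid), and
`cosine_nonlinearity()` / `pca_conformations()` characterize the
curvilinear geometry of the motion.

## Command line

```sh
inst/cli/anmdyn fixture --recipe hinge --out h          # writes h_open.pdb, h_closed.pdb
inst/cli/anmdyn modes   --pdb h_open.pdb --calibrate --out h
inst/cli/anmdyn respond --pdb h_open.pdb --calibrate --frequency 0.008 --seed 3 --out h
inst/cli/anmdyn analyze --trajectory h_trajectory.csv --open h_open.pdb \
                        --closed h_closed.pdb --out h
inst/cli/anmdyn scan    --pdb h_open.pdb --closed h_closed.pdb --calibrate --out h
```

Every run writes its results next to a fully resolved `_config.yaml`.

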
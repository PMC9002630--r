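---
title: "Simulating 13C homonuclear mixing under fast MAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating 13C homonuclear mixing under fast MAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spinmix)
```

## The problem

Assigning methyl 1H/13C resonances of Ile, Leu and Val residues in
immobilized (solid-state) proteins requires transferring 13C polarization
from the methyl carbon across several bonds to the backbone Calpha — for
leucine, the Cdelta1 -> Cgamma -> Cbeta -> Calpha pathway. Under magic-angle
spinning (MAS), this transfer is driven by an RF mixing scheme that
recouples either the scalar (J) couplings (TOBSY symmetry sequences;
WALTZ-16, DIPSI-3 and FLOPSY-16 — referred to collectively as TOCSY
schemes) or the dipolar couplings (finite-pulse RFDR, adiabatic DREAM).
Which scheme performs best depends strongly on the spinning frequency, the
static field, the RF amplitude and the 13C topology of the side chain.
spinmix simulates these transfers from first principles: it builds the
secular rotating-frame Hamiltonian of a small spin system, propagates the
density operator through the exact piecewise-constant RF program of each
scheme, and powder-averages the transfer efficiency over crystallite
orientations.

## The model

For `L` spins the simulation works in the full `2^L` Hilbert space. The
rotating-frame Hamiltonian contains, per crystallite orientation:

* isotropic shift offsets `2 pi (delta_i - delta_carrier) nu_0i Iz_i`,
  with the 13C carrier at 38 ppm by default (middle of the aliphatic band)
  and the 1H carrier on resonance with the mean proton shift;
* the chemical-shift anisotropy as a time-dependent `Iz` term whose
  spatial factor is the lab-frame zz component of the traceless shift
  tensor under MAS — an exact five-term Fourier series in the rotor phase
  whose static term vanishes at the magic angle;
* homonuclear dipolar couplings in the secular form
  `omega_D(t) (2 IzSz - (I+S- + I-S+)/2)` and heteronuclear ones as
  `omega_D(t) 2 IzSz`, with `b/2pi = -(mu0/4pi) gamma_i gamma_j hbar / r^3`
  computed from the embedded geometries (about -2.12 kHz for a bonded CC
  pair at 1.53 A); motional scaling factors (1/3 for the methyl proton) are
  stored separately and applied at Hamiltonian build time;
* homonuclear J couplings as the full `2 pi J (I . S)` and heteronuclear
  ones in the weak-coupling form `2 pi J IzSz`;
* the RF field `2 pi nu_1 (Ix cos phi + Iy sin phi)` on the 13C spins only.

No relaxation or chemical exchange is included anywhere: the simulated
efficiencies are coherent-limit values, upper bounds for experiments.

All frames are connected by ZYZ active rotations: tensor PAS -> molecule
(per-tensor Euler angles) -> crystallite/rotor (powder angles
`{alpha, beta, gamma}`, with gamma outermost, i.e. about the rotor axis)
-> laboratory (rotor tilted by the magic angle, spinning at `nu_r`).

## The integrator

RF programs are tables of piecewise-constant segments. Each segment is
subdivided so that no sub-step exceeds `tau_R / steps_per_rotor_period`
(default 32, the floor value; all Hamiltonian coefficients are sampled at
sub-step midpoints). Within a sub-step the propagator is built by symmetric
(Strang) operator splitting:

1. all single-spin terms (offset + CSA + RF) are exponentiated *exactly* as
   SU(2) rotations — this places the largest terms (RF up to 100+ kHz,
   offsets up to tens of kHz) in the exactly-treated factor;
2. the coupling terms are applied exactly as well: all zz parts merge into
   one diagonal phase pass, and each homonuclear flip-flop part is an exact
   2x2 rotation within its zero-quantum block (the flip-flop commutes with
   the pair's own zz term);
3. the two half-width single-spin factors of adjacent sub-steps are
   composed at the 2x2 level before touching the propagator matrix.

Every factor is unitary, so the overall propagator is unitary to machine
precision regardless of step size; the splitting error is second order in
the sub-step and, at the default resolution, changes powder-averaged
efficiencies by well under 0.5% upon doubling `steps_per_rotor_period`
(this is asserted in the test suite, together with agreement against a
dense midpoint-Hamiltonian eigendecomposition reference propagator that is
implemented independently in R). This split design is what makes full
MAS-frequency scans of a six-spin system tractable on a single core; a
dense eigendecomposition per sub-step would be about an order of magnitude
slower at dimension 64.

For cyclic schemes the propagator over the least common period of the
program cycle and the rotor period (one cycle for TOBSY/WALTZ/RFDR; three
cycles = 652 rotor periods for DIPSI-3, whose 217.33 tau_R supercycle is
not an integer) is computed once per crystallite and repeatedly applied,
with observable snapshots after every cycle. FLOPSY-16 (188.448 tau_R) is
treated by explicit stepwise propagation. Mixing times that are not
multiples of the cycle fall back to stepwise propagation with a notice.

## The RF programs

* **TOBSY C9(1,n)**: nine POST elements (90, 360, 270 degrees; middle pulse
  phase-inverted) over `n` rotor periods, element phases stepped by
  `2 pi / 9`; the symmetry fixes `nu_1 = (2*9/n) nu_r` and requires
  `n = 9p +/- 3`. The phase increment applies to the whole element, the
  standard convention for these symmetry classes.
* **WALTZ-16 / DIPSI-3**: the canonical composite-pulse supercycles
  (`Q Qbar Qbar Q`, `R Rbar Rbar R`) encoded as flip-angle data constants,
  rotor-synchronized via `tau_90 = tau_R`, i.e. `nu_1 = nu_r / 4`.
* **FLOPSY-16**: the element table ships as a data file. The included file
  is a clearly-labelled synthetic stand-in that reproduces the documented
  aggregate structure of the element (8 elements of 23.556 tau_90,
  alternating +-x phases); users holding the original published table can
  point `flopsy16(element_file = ...)` at it. FLOPSY is therefore exercised
  structurally, not used for quantitative claims.
* **RFDR**: one pi pulse of width `1/(2 nu_1)` centered in each rotor
  period, xy8 phase cycling over 8 rotor periods; requires
  `nu_1 > nu_r / 2`.
* **DREAM**: a tangent amplitude sweep through the HORROR condition
  `nu_1 = nu_r / 2`, discretized into 1000 equal steps (doubling the step
  count changes final transfers by far less than 0.5%); defaults are
  modulation depth `nu_r / 5`, effective coupling 1 kHz and mean RF
  `nu_r / 2`, with increasing amplitude selecting the transfer direction.

All schemes start with phase x; a global phase offset parameter exists and
defaults to zero.

## DREAM initial and detection operators

The DREAM block acts on spin-locked single-quantum coherence rather than on
longitudinal polarization. The simulator therefore initializes the source
operator along the instantaneous effective field of the source spin at
`t = 0` (RF amplitude `nu_1(0)` along x, offset along z) and detects the
destination operator along the effective field at `t = tau`, reporting
*signed* efficiencies — DREAM cross peaks come out negative, as they do in
experiments. A plain `Iz` mode (`dream_mode = "iz"`) is available for
comparison. Because the sweep shape depends on the total mixing time, a
DREAM "buildup" re-runs one full sweep per grid point.

## Powder averaging

Crystallite `{alpha, beta}` pairs come from the REPULSION algorithm
(electrostatic repulsion of points on the sphere; the package ships its own
optimizer plus precomputed 66-, 168- and 616-point sets generated with it,
seed 42) or from the ZCW construction; `gamma` is sampled regularly
(11 angles for reference runs, 6 for the coarse grid). The reference grid
is 168 x 11 = 1848 orientations; six-spin scans default to the reduced
66 x 6 grid, which changes the alanine buildup maximum by less than 3%
(asserted in the tests). Gamma averaging is always explicit — no
gamma-encoding shortcut is used. The only randomness in the package is the
REPULSION starting configuration for non-embedded set sizes; propagation is
fully deterministic.

## Embedded model systems

* **alanine_4spin** — Halpha-Calpha-Cbeta-Hbeta on an idealized geometry
  (C-C 1.53 A, C-H 1.09 A, tetrahedral angles), J(CC) = 33 Hz,
  J(HC) = 145 Hz, one methyl proton retained with its H-C dipolar coupling
  scaled by 1/3 (fast methyl rotation). Shifts are typical solid-state
  alanine values (Ca 50.8, Cb 19.8, Ha 3.8, Hb 1.4 ppm). Reference field
  14.1 T (600 MHz 1H), the field of the corresponding model experiments.
* **leucine_c6 / leucine_c5** — exclusively-carbon C', Ca, Cb, Cg, Cd1
  (, Cd2) on a canonical mt rotamer built from ideal internal coordinates;
  one-bond J = 33 Hz (50 Hz for Ca-C'), two-bond J = 3 Hz, longer-range J
  neglected; all 15 (10) dipolar couplings from the geometry. The linear C5
  variant is the exact induced subsystem without Cd2, emulating the
  12C-D3-labelled methyl branch of a linearized isotopomer. Reference field
  18.8 T (800 MHz 1H).

Chemical shifts for the leucine system default to canonical values
(C' 176, Ca 55, Cb 40, Cg 25, Cd1 23, Cd2 21 ppm) and CSA parameters to
literature-typical magnitudes (aliphatic 13C: 20 ppm, eta 0.5; carbonyl:
-76 ppm, eta 0.6; 1H: 5 ppm), all overridable through `make_system()`.
These stand in for unpublished experimental values; the simulated
observables of interest (multi-bond transfer, bandwidth limitations,
topology effects) depend on the shift dispersion pattern rather than on
exact positions, but exact per-site agreement with any particular
experiment should not be expected. The PAS orientations of all shift
tensors default to the molecule axes; in a powder this mainly affects
cross-terms, not leading-order behavior.

## What the study-level drivers compute

* `buildup_series()` — efficiency versus mixing time with the optimum
  (global maximum of |efficiency| over the grid, default step one program
  cycle, default range 0-50 ms, 0-25 ms for DREAM and alanine).
* `mas_scan()` — buildup optimum versus spinning frequency with
  `nu_1` tied to `nu_r` by each scheme's rule (30-200 kHz by default).
* `b0_scan()` — buildup optimum versus static field at fixed `nu_r` and
  fixed RF, probing the effective 13C bandwidth of a scheme.
* `robustness_map()` — efficiency at the fixed unperturbed optimal mixing
  time under RF amplitude scaling or symmetric offset displacement. The
  package's robustness criterion is 50% retention of the unperturbed
  efficiency; with it, TOBSY tolerates about 5% RF miscalibration while
  DIPSI-3 survives 10% comfortably, and C9(1,24) retains its two-spin
  transfer up to a 15 kHz offset difference at 55 kHz MAS.
* `compare_topologies()` — the linear/branched optimal-efficiency ratio
  for the leucine Cdelta1 -> Calpha transfer. At 100 kHz MAS the J-based
  schemes gain substantially from linearization (DIPSI-3 close to
  three-fold in this implementation), while the dipolar-based schemes
  profit only marginally; the exact gain per scheme is sensitive to the
  stand-in shifts and CSA above.

A typical session:

```{r example}
leu <- make_system("leucine_c6")
cfg <- sim_config(b0_proton_mhz = 800, nu_r = 55.5e3,
                  powder = powder_set("repulsion", 66, 6),
                  max_mixing_time = 0.05)
bs <- buildup_series(leu, "rfdr", cfg, source = "CD1", dest = "CA",
                     nu_1 = 100e3)
bs$eff_opt    # maximal CD1 -> CA transfer efficiency
plot_buildup(bs$curve)
```

## Problem sizes and numerical choices

The default problem sizes are those of the reference conditions: the full
168 x 11 powder grid for the four-spin alanine simulations, the reduced
66 x 6 grid for six-spin leucine runs and scans, 32 integration sub-steps
per rotor period, and mixing-time grids stepping by one program cycle.
With the split-operator backend a full leucine MAS scan (18 spinning
frequencies x 396 crystallites x a 48-rotor-period cycle) completes in a
few minutes on one core. Tests exercising qualitative properties
(robustness orderings, DREAM monotonicity, field-scan trends) use smaller
ZCW grids (e.g. 21 x 3), which is sufficient because those assertions
compare large, powder-stable effects.

Tie-breaks and degenerate inputs: optimum detection takes the first grid
point attaining the maximum of |efficiency|; a single-point grid returns
that point; a zero-length mixing time gives the exact initial condition
(source 1, everything else 0). Orientation weights are renormalized to
sum to one; an isotropic (zero-anisotropy) tensor contributes no MAS
modulation at all.

## What the synthetic systems do and do not show

The embedded systems reproduce the *coherent* spin physics of methyl
side-chain transfers: recoupling conditions and scaling factors, bandwidth
and offset effects, RF-inhomogeneity sensitivity, dipolar truncation, and
the branched-versus-linear topology effect. They deliberately omit
relaxation (T2, T1rho, spin diffusion), proton baths beyond the explicit
spins (the leucine systems are carbons-only, as a six-spin-plus-protons
Hilbert space is intractable), structural variability of couplings and
shifts, and pulse transients. Passing tests therefore validate the
simulator and the coherent-limit predictions, not quantitative agreement
with any measured spectrum; experimentally, incoherent effects reduce all
efficiencies and reorder schemes in proton-rich systems.

## Known limitations

* Spin systems beyond ~7 spins are impractical (exponential state space).
* No 1H decoupling during mixing, no cross-polarization dynamics, no
  second-order (proton-driven) recoupling schemes.
* The FLOPSY-16 element table is a synthetic timing stand-in (see above).
* Heteronuclear J uses the weak-coupling secular form; for directly bonded
  H-C pairs under fast MAS this is the standard approximation.
* The DREAM detection convention (effective-field projection) is a
  documented choice; experiments detect after a subsequent z-filter, which
  can scale signed amplitudes.
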
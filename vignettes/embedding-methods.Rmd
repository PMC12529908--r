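---
title: "Hybrid-in-GGA embedding with local basis reduction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-in-GGA embedding with local basis reduction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

lessemb computes closed-shell molecular energies with a hybrid density
functional applied to a chemically active subsystem embedded in a GGA
description of the full molecule.  The total energy is

$$
E \;=\; E_{LL}[D^{AB}] \;-\; E_{LL}[D^{A}] \;+\; E_{HL}[\tilde D^{A}]
\;+\; \mathrm{Tr}\!\left\{(\tilde D^{A}-D^{A})\,v_{\mathrm{emb}}\right\},
$$

where $LL$/$HL$ denote the low- and high-level functionals (typically
PBE / PBE0), $D^{AB}$ is the converged low-level density of the whole
system, $D^{A}$ the density of the active orbitals selected from the
localized low-level occupied space, and $\tilde D^{A}$ the re-optimized
active density.  The embedding potential
$v_{\mathrm{emb}} = (J + V_{xc} - c_{\mathrm{HFx}}K)[D^{AB}] -
(J + V_{xc} - c_{\mathrm{HFx}}K)[D^{A}]$ (low-level quantities) is a fixed
one-electron operator added to the high-level core Hamiltonian, and the
trace term is the matching first-order correction.  When the two
functionals coincide, the construction collapses identically to the full
SCF energy; the test suite asserts this to $10^{-8}\,E_h$.

Orthogonality of the relaxed active orbitals to the frozen environment is
enforced either by the Huzinaga operator
$H = \tilde F - S D^B \tilde F - \tilde F D^B S$ (the default) or by a
level-shift projector $\tilde F + \alpha\, S D^B S$.  Two conventions for
$D^B$ circulate; lessemb uses the $S$-idempotent per-spin density
$C_B C_B^{\mathsf T}$, for which the active-environment coupling block of
$H$ vanishes identically — with the spin-traced density ($2C_BC_B^{\mathsf T}$)
the coupling block equals $-\tilde F_{AB}$ and the embedded SCF cannot
reach a commuting fixed point.  Numerically the Huzinaga eigenproblem is
solved in the $S$-orthogonal complement of the environment span, on which
$H$ and $\tilde F$ act identically; this is the same constrained
stationarity condition written in a basis where sign-flipped environment
solutions cannot enter the aufbau (for anionic systems the environment
HOMO can have $\varepsilon_B > 0$, and $-\varepsilon_B$ would otherwise
land below the active virtuals).  In projector mode the full space is kept
— the finite-$\alpha$ error is physical, decays as $1/\alpha$, and the
suite checks monotone convergence to the Huzinaga result over
$\alpha = 10^3, 10^4, 10^5\,E_h$.

The embedded solver occupies, among its eigenvectors, the `n_act` states
with the largest projection onto the *initial* active-orbital span
(maximum-overlap selection) rather than the `n_act` lowest.  The two
coincide whenever the embedded gap is healthy, but an embedded anionic
head group can have a near-zero gap, and strict aufbau then flips the
occupation pattern every iteration and never converges.  The
maximum-overlap rule is deterministic and targets precisely the state the
method defines — the high-level solution continuously connected to the
low-level active orbitals; with it, same-functional embedding reproduces
the full SCF energy on every fixture, including the anions.  Plain
(non-embedded) SCF keeps ordinary aufbau.

## Orbital localization and selection

The low-level occupied orbitals are localized with Pipek–Mezey Jacobi
sweeps in the Mulliken metric, consistent with the Mulliken-based active
selection.  A localized orbital is active when its summed gross Mulliken
population on the active atoms reaches `tau_sel`.  The default
`tau_sel = 0.4` is a deliberate choice for border bonds: a σ-bond orbital
cut by the active/environment boundary carries roughly half its population
on each side, and 0.4 pulls such borderline orbitals into the active set
rather than freezing them.  SPADE-type selection is not implemented.

## Basis reduction

*AO reduction.*  Net Mulliken populations
$q_\mu = \sum_i (C^A_{\mu i})^2 S_{\mu\mu}$ of the active orbitals select
the retained functions ($q_\mu > \varepsilon_{AO}$, default $10^{-4}$),
extended to whole shells.  The low-level SCF is never redone: truncation
only affects the operators entering the embedded run.  In the reduced
metric both orbital sets are Löwdin-canonically re-orthonormalized;
environment orbitals whose overlap eigenvalue drops below `tau_drop` are
removed, and the retained environment span is projected out of the active
orbitals, which are then *symmetrically* re-orthonormalized — the
symmetric (rather than Gram–Schmidt) choice keeps the result independent
of basis ordering.  The drop cutoff matters: it must remove only
*numerically unrepresentable* environment orbitals (`tau_drop = 1e-3` by
default).  A looser cutoff — say, dropping any orbital that loses half
its norm — removes orbitals whose density is still substantially
representable in the kept basis; their regions then lose Pauli exclusion
and the embedded SCF collapses active orbitals into deep tail states.
Keeping a marginal environment orbital is always safe, since canonical
orthogonalization renormalizes it.  An active orbital below `tau_drop` is a hard error:
the truncation threshold is too aggressive for the requested active
space.  Nuclear and point-charge attraction integrals are always kept for
all centers; only the basis shrinks, never the physics.

*Auxiliary reduction.*  Three schemes reduce the density-fitting basis of
the high-level run:

- **NAF** — natural auxiliary functions: eigenvectors of
  $W_{PQ} = \sum_{\mu i} J^P_{\mu i} J^Q_{\mu i}$ built from the
  *active-orbital half-transformed* three-center integrals (an AO-only $W$
  would retain a larger space), retaining singular values above
  $\varepsilon_{\mathrm{NAF}}$ (default $5\times10^{-4}\,E_h$).
- **Generalized Mulliken charges** —
  $\hat q_P = \sum_{\bar Q} N_{P\bar Q}^2 S^{DF}_{PP}$ over the retained
  NAF columns; auxiliary shells with any $\hat q > \varepsilon_{\mathrm{Mull}}$
  (default 0.3) survive.
- **LDF domains** — per active localized orbital, atoms with a Löwdin
  charge above 0.05 (computed with $S^{1/2}$ of the *full* AO basis, since
  the domains are built before any truncation) form the primary domain;
  auxiliary shells of angular momentum $\ell$ on atom $B$ are added when
  $\sqrt{\max_{\mu\in A,\nu\in B}(\mu\nu|\mu\nu)} \cdot
  \sqrt{\max_{P\in B_\ell}(P|P)} > \varepsilon_{\mathrm{dom}}$
  (default $2.0\,E_h$) for any primary atom $A$.  The printed form of this
  criterion is ambiguous between product/ratio and root placements; the
  product-of-roots reading is used because it carries $E_h$ units matching
  the recommended threshold, and every limit test is monotone under any of
  the readings.  The final fitting set is the union over active orbitals,
  so one fixed basis serves both Coulomb and exchange and the SCF stays
  exactly variational (asserted by finite-difference orbital-rotation
  gradients).

Subset schemes (Mulliken, LDF) refit in the reduced metric
$(P|Q)^{-1}_{\mathrm{sub}}$; NAF transforms the full-metric integrals by
the retained columns.  All three converge to the unreduced result as
their threshold goes to zero, which the acceptance tests assert to
$10^{-8}\,E_h$.

## Density-fitted SCF engine

The two-center metric is Cholesky-factorized ($L = U^{-1}$ with
$(P|Q) = U^{\mathsf T}U$, never an explicit inverse), with an
eigenvalue-floored spectral fallback at $10^{-10}$.  Transformed integrals
$J^P_{\mu\nu} = \sum_Q (\mu\nu|Q) L_{QP}$ are held either **in-core** — per
AO shell $S$, with $P$ fastest, $\mu \in S$ in the middle, $\nu$ slowest,
storing only $(\nu, S)$ blocks whose
$J^S_\nu = \max_{\mu\in S}\max_P |J^P_{\mu\nu}|$ reaches the screening
threshold (default $10^{-10}$; screening is applied after the basis
reductions, which provide the dominant savings) — or produced blockwise in
**integral-direct** mode.  Both modes assemble Coulomb and exchange
shellwise from the identical screened map and agree to $10^{-10}$ in every
Fock element.  An in-core request beyond the configured memory budget
fails with the required and available byte counts, suggesting direct mode.

Convergence uses CDIIS (subspace 8, oldest entries pruned whenever the
extrapolation system's condition deteriorates) with damped first
iterations, to $\|FDS - SDF\|_\max < 10^{-7}$ and
$|\Delta E| < 10^{-9}\,E_h$.  The initial guess is a superposition of
spherically averaged fractional-occupation atomic Hartree–Fock densities,
cached per element and basis; the embedded run starts from the truncated,
re-orthogonalized active orbitals.  Incremental Fock builds are not
implemented.  The closed-shell factor convention is fixed once —
$F^K_{\mu\nu} = -c_{\mathrm{HFx}} \sum_{iP} J^P_{\mu i}J^P_{\nu i}$ over
doubly occupied columns with $D = 2CC^{\mathsf T}$, two-electron energy
$\tfrac12\mathrm{Tr}\,D(F^J + F^K)$ — and pinned by the four-center
Hartree–Fock oracle test.

## Integral backend and numerical choices

No quantum-chemistry integral library is available to R, so the backend
is part of the package: a McMurchie–Davidson engine over contracted
spherical Gaussians (s, p, d) supplying overlap, kinetic, nuclear and
point-charge attraction, two-/three-center Coulomb integrals, diagonal
$(\mu\nu|\mu\nu)$ blocks for the domain criterion, and — for test oracles
on tiny systems only — full four-center tensors.  Everything downstream
talks to the backend through one handle, so the engine is replaceable.
Internally all quantities are atomic units; XYZ input is Ångström
(1 Å = 1.8897259886 Bohr).  Cartesian d components are contracted to
equal-norm real solid harmonics and every contracted function is
renormalized against the computed overlap diagonal, so unit diagonals are
exact by construction.  Point-charge–point-charge interaction is excluded
from all reported energies: it is a constant of the MM layer.

The bundled bases are STO-3G (H, He, C, N, O) and a split-valence
double-zeta set `"dz"` (6-31G parameters for H, C, N, O; an uncontracted
even-tempered double-zeta-quality set for Cl, since no third-row
split-valence data is bundled).  Auxiliary sets are generated per element
as even-tempered progressions spanning twice the AO exponent range, with
angular momenta up to $\min(2\ell_{\max}^{AO}, 2)$ and one extra shell for
hydrogen; `"autoaux-dense"` tightens the progression for oracle tests
where the fitting residual itself is measured.  Because the fitting basis
is generated rather than tabulated, all accuracy statements in the tests
are *internally referenced* (reduced versus unreduced runs sharing the
same fitting construction), mirroring how the reduction errors are defined
in the first place.

Exchange–correlation uses PBE (and PBE0 as $0.25\,K + 0.75$ PBE exchange
+ PBE correlation) on a Becke-partitioned molecular grid:
Murray–Handy–Laming radial maps scaled by Bragg–Slater radii and
Gauss–Legendre × uniform-φ angular product grids, at three levels
(35×10, 60×16, 100×24 radial×polar points; the angular grid is halved on
the innermost third of the radial points).  Level 2 is the production
default; level 1 is the desk-scale setting used by the test suite and the
acceptance script, whose target quantities are differences between runs
sharing one grid, so quadrature error cancels to well below the reported
figures.  Functional derivatives ($v_\rho$, $v_\sigma$) are obtained by
complex-step differentiation of the PBE energy density — exact to machine
precision, with no finite-difference cancellation — and the suite checks
$\mathrm{Tr}(\Delta D\,V_{xc})$ against the energy response.  Densities
below $10^{-12}$ a.u. are skipped.

## What the fixtures emulate — and what they do not

The fixture module generates idealized, optimizer-free, deterministic
geometries: zig-zag alkyl-chain acids and their carboxylates (the n = 10
member is a 32-atom decanoic-acid analogue), an S$_\mathrm{N}$2 quartet
(chloroalkane + OH⁻ → alkanol + Cl⁻), butadiene/ethene as a compact
π-system stand-in, and well-separated monomer dimers for separability
limits.  These are quasi-one-dimensional molecules with a single border
bond, chosen so that every stage — localization, selection, truncation,
the three auxiliary schemes, both storage modes — is exercised at desk
scale.  Passing tests on them demonstrates the *internal consistency and
limiting behaviour* of the approximations; they do not probe
three-dimensional active regions with many border bonds, mixed basis
sets, or systems of hundreds of atoms, where retention fractions and
absolute speedups will differ.  Geometric realism is irrelevant to the
measured quantities, because every comparison is method-versus-method on
the same geometry.

## Acceptance computation

`scripts/acceptance.R` rebuilds the n = 10 chain-acid pair at double-zeta
level, runs PBE0-in-PBE embedding with AO reduction only
($\varepsilon_{AO} = 10^{-4}$) as the internal reference, repeats the
deprotonation energy with each auxiliary scheme at its recommended
threshold ($\varepsilon_{\mathrm{NAF}} = 5\times10^{-4}\,E_h$,
$\varepsilon_{\mathrm{dom}} = 2.0\,E_h$,
$\varepsilon_{\mathrm{Mull}} = 0.3$), and reports the largest absolute
reaction-energy deviation in kcal/mol.  The low-level state, partition,
and embedding potential are computed once per species and shared across
the four high-level runs — the reduction schemes only ever touch the
high-level calculation.

## Known limitations

Closed-shell molecules only; no analytic gradients; no wave-function
high levels; s–d angular momenta (f-function bases are rejected); the
checkpoint container is RDS rather than HDF5; the CLI sweep operates on a
single geometry (reaction sweeps use `run_sweep()` from R).  Active-orbital
counts reported by other embedding codes for a given system depend on
their localizer and selection threshold, so orbital counts are not
expected to match across implementations, only the converged energies'
limiting behaviour.
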
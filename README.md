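# lessemb

Hybrid-DFT-quality energies at near-GGA cost for closed-shell molecules,
by embedding a hybrid-functional description of a chemically active
subsystem inside a GGA description of the full system, with aggressive —
but systematically improvable — reduction of the atomic-orbital and
density-fitting basis sets of the embedded calculation.

The package is aimed at method developers and computational chemists who
want a compact, fully inspectable R implementation of
projection/Huzinaga-type DFT-in-DFT embedding: every stage, from Gaussian
integrals to the final energy assembly, is in this package and covered by
oracle tests.

## The method

The total energy is assembled from one cheap full-system calculation and
one small embedded calculation:

    E = E_LL[D^AB] − E_LL[D^A] + E_HL[D̃^A] + Tr{(D̃^A − D^A) v_emb}

The low-level (LL, e.g. PBE) occupied orbitals are localized
(Pipek–Mezey) and partitioned by Mulliken population on the active atoms;
the active orbitals are then re-optimized with the high-level functional
(HL, e.g. PBE0) under the frozen environment, with orthogonality enforced
by the Huzinaga operator `H = F − S D^B F − F D^B S` (or a level-shift
projector `F + α S D^B S`).  The embedded step is accelerated by

- **AO reduction** — net Mulliken populations `q_μ = Σ_i (C^A_μi)² S_μμ`
  select the retained shells (`ε_AO`, default `1e-4`), with Löwdin
  re-orthogonalization and dropping of unrepresentable environment
  orbitals;
- three **auxiliary-basis reductions** for the density fitting of the
  embedded Fock builds: natural auxiliary functions (`ε_NAF = 5e-4` Eh),
  generalized Mulliken charges on fitting functions (`ε_Mull = 0.3`), and
  local density-fitting shell domains from Löwdin charges plus
  Cauchy–Schwarz extension (`ε_dom = 2.0` Eh);
- an **in-core** screened storage layout for the transformed three-center
  integrals (or an equivalent integral-direct mode).

External point charges (QM/MM style) enter the core Hamiltonian and the
nuclear repulsion.  A McMurchie–Davidson integral engine (s–d shells),
PBE/PBE0 on a Becke molecular grid, bundled STO-3G and split-valence
double-zeta bases, and even-tempered auto-generated fitting bases make
the package self-contained.

## Worked example

Deprotonation of a propanoic-acid analogue with PBE0 embedded in PBE,
AO reduction plus LDF-domain fitting reduction:

```r
library(lessemb)

fx  <- build_chain_acid(3, ao_basis = "dz")   # acid + carboxylate pair
cfg <- less_config(eps_ao = 1e-4, aux_scheme = "ldf", grid_level = 1)

run <- run_embedding(fx$acid, fx$active_acid, cfg)
print(run)
```

which prints (energies in Hartree; wall times omitted):

```
# lessemb embedding report (energies in Hartree)
E_LL_full   = -267.9981308740
E_LL_act    = -223.3639299071
E_HL_act    = -223.3293400626
E_corr      = -0.0300201195
E_total     = -267.9935611490
n_active_mo = 16
n_env_mo    = 4
ao_retention_pct  = 100.00
aux_retention_pct = 85.75
dropped_env_mos   = 0
low_scf_iters  = 14
high_scf_iters = 14
aux_scheme = ldf
mode = incore
```

`E_LL_full` is the full-system PBE energy, `E_HL_act − E_LL_act` the
hybrid correction of the active subsystem, `E_corr` the first-order
embedding-potential trace, and `E_total` their assembly — the
hybrid-in-GGA estimate of the full PBE0 energy.  16 of the 20 occupied
orbitals are active (a short chain leaves only the methyl tail frozen,
and every AO shell stays above the `eps_ao` population cut); the LDF
domains still discard 14 % of the fitting functions.  On the longer
n = 10 chain the same settings keep ~60 % of the AOs and ~31 % of the
fitting basis.  Repeating on `fx$anion` and differencing gives the
deprotonation energy; with `aux_scheme = "none"` as reference, the
LDF-reduced reaction energy deviates by well under 0.1 kcal/mol
(1 Eh = 627.509474 kcal/mol).

A shell driver with the same surface ships in `inst/cli`:

```sh
lessemb run --geom mol.xyz --active 1,2,5-9 --ll pbe --hl pbe0 \
            --eps-ao 1e-4 --aux-scheme ldf --eps-dom 2.0 --mode incore
```

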
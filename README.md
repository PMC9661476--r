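# ttrstab

Quantitative analysis of transthyretin (TTR) kinetic stabilizers.

Destabilizing mutations or ageing can cause the homotetrameric transport
protein TTR to dissociate, misfold and aggregate into amyloid (ATTR
amyloidosis). Small molecules that occupy the two thyroxine (T4) binding
sites at the tetramer's dimer-dimer interface raise the kinetic barrier to
dissociation. Characterizing such stabilizers combines several quantitative
stages, and `ttrstab` implements that analysis chain end to end for
computational chemists and protein biochemists working on this system:

- **MD binding-energy bookkeeping** — predicted binding energies from
  ensemble-averaged molecular-dynamics components,
  ΔG_bind = ΔE_gp + 2·ΔG_L-solv with
  ΔE_gp = E_TTR + 2·E_L − E_TTR·2L (positive = favorable in this
  convention), plus ligand ranking, hydrogen/halogen-bond contact
  frequencies with element-dependent cutoffs (3.0 Å; 3.5 Å for Cl), frame
  sampling, and structural metrics (inter-ligand carbonyl-carbon depth,
  Ser117 O–O interface distances).
- **Two-site ITC model** — the binding polynomial
  Z = 1 + K₁[L] + K₁K₂[L]², mass-balance equilibrium solving, thermogram
  forward simulation under an injection protocol with displacement
  bookkeeping, and Levenberg–Marquardt fitting with or without
  cooperativity (cooperativity index c = 4K₂/K₁; c = 1 for two identical
  independent sites).
- **Thermodynamic bookkeeping** — ΔG = RT·ln K_d and ΔG = ΔH + (−TΔS)
  conversions with table-level consistency validation.
- **Stability and plasma assay statistics** — urea-dissociation kinetics
  (355/335 fluorescence normalization, mono-exponential fit, protection %),
  turbidity aggregation/inhibition %, cell viability %, IEF tetramer
  stabilization %, T4 binding competition, and solubility averaging.
- **Seeded synthetic-data generators** for every stage, so the whole
  pipeline round-trips without instrument data.

## Worked example

Rank the tolcapone analogue series by predicted binding energy and verify
the ITC thermodynamics, then simulate and refit a titration:

```r
library(ttrstab)

rank_ligands(md_energy_table())[, c("rank", "ligand", "dG_bind")]
#>  rank    ligand dG_bind
#>     1      M-23    84.4
#>     2      M-21    74.0
#>     3      M-17    68.0
#>     4 tolcapone    59.7
#>     5      M-20    57.0
#>     6      M-14    55.4

all(validate_thermo_table(itc_thermo_table())$pass)
#> [1] TRUE

# M-23-like noncooperative binder: 6.2 nM per-site Kd, dH = -16.6 kcal/mol,
# titrated as 100 uM ligand into 5 uM TTR, 19 x 2 uL injections at 25 C
prot <- titration_protocol()
m <- two_site_noncooperative(kd_micro = 6.2e-9, dH = -16.6)
tg <- simulate_thermogram(m, prot)
fit <- fit_thermogram(tg, prot, mode = "noncooperative")
itc_fit_parameters(fit)[c("kd_nM", "dH_kcal")]
#> $kd_nM
#> [1] 6.2
#>
#> $dH_kcal
#> [1] -16.6
```

The ranking puts M-23 first (84.4 kcal/mol): its hydroxyl gains a buried
hydrogen bond to Ser117 on top of the tolcapone scaffold's contacts, which
is also why its measured per-site K_d (6.2 nM) is more than 5-fold tighter
than tolcapone's (34 nM). The noiseless simulate-then-fit round trip
recovers the generating parameters to machine precision, confirming the
forward model and the fitter agree.

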
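---
title: "Models and methods in ttrstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ttrstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttrstab)
```

`ttrstab` implements the quantitative chain used to design and validate
small-molecule kinetic stabilizers of transthyretin (TTR): binding-energy
bookkeeping over molecular-dynamics ensembles, a two-site binding model for
isothermal titration calorimetry (ITC), and the statistics of the
stabilization, aggregation and plasma assays. This vignette is the
package's account of those models: what is assumed, what is tunable, and
where the numerical edges are.

## MD binding-energy bookkeeping

The predicted binding energy of a ligand that occupies both T4 sites of
the tetramer is

$$\Delta G_{bind} = \Delta E_{gp} + 2\,\Delta G_{L\text{-}solv}, \qquad
\Delta E_{gp} = E_{TTR} + 2E_{L} - E_{TTR\cdot 2L},$$

where the three energies are ensemble means over frames sampled from the
tail of a production trajectory and $\Delta G_{L\text{-}solv}$ is the
continuum solvation free energy of the free ligand. The scheme assumes the
complex and the free receptor have approximately equal solvation energies,
so only ligand desolvation enters. **Sign convention:** larger positive
$\Delta G_{bind}$ means stronger predicted binding — the opposite of the
negative-$\Delta G$ convention of the ITC tables; `binding_energy()`
documents this prominently because the two scales coexist in any
stabilizer campaign.

`sample_frames(total_ns, window_ns, n_frames)` samples at the *end* of
each stride interval, so the final frame is always included and
`sample_frames(150, 140, 140)` yields 11, 12, ..., 150 ns — the
even-sampling rule for "the last window" of a trajectory.

Contact statistics use a distance-only criterion on heavy-atom
donor–acceptor distances: a frame is in contact at $d \le$ 3.0 Å, raised
to 3.5 Å when the ligand partner atom is chlorine (halogen bonds are
longer than hydrogen bonds). No angular filter is applied; with
distance-only reporting the frequencies are upper bounds on
angle-filtered ones. The mean contact distance is averaged over contact
frames by default (`mean_over = "contact"`), matching common trajectory
post-processing reports; `mean_over = "all"` switches to all-frames
averaging. `rank_ligands()` breaks ties lexicographically by ligand name
so orderings are deterministic.

Structural metrics (inter-ligand carbonyl-carbon distance, Ser117 O–O
distances between chains A–C and B–D) are plain Euclidean distances on
labeled coordinate frames read as-is in Å; frames are assumed pre-imaged
(no periodic-boundary correction). Both metrics are invariant under rigid
motion, which the tests verify with random orthogonal transforms.

## Thermodynamic bookkeeping

$\Delta G = RT \ln K_d$ with $R = 1.9872\times10^{-3}$ kcal mol$^{-1}$
K$^{-1}$, $T$ defaulting to 298.15 K (the titration temperature) and an
implicit 1 M standard state. `validate_thermo_table()` checks each row of
a results table twice: the decomposition $\Delta H + (-T\Delta S)$ must
reproduce $\Delta G$ within 0.05 kcal/mol (absorbing one-decimal
rounding), and $RT\ln K_d$ must reproduce it within 0.08 kcal/mol
(absorbing two-significant-figure rounding of $K_d$; e.g. a 31 nM constant
evaluates to $-10.24$ kcal/mol against a printed $-10.3$). Whether a
published table derived its $\Delta G$ column from $RT\ln K_d$ or from the
enthalpy/entropy sum is generally unknowable, so both checks are run with
separate tolerances rather than guessing.

## Two-site ITC model

The TTR tetramer has two T4 sites. Ligation states are weighted by the
binding polynomial

$$Z = 1 + K_1 [L] + K_1 K_2 [L]^2,$$

with macroscopic stepwise association constants $K_1, K_2$ (M$^{-1}$) and
stepwise enthalpies $\Delta H_1, \Delta H_2$. For two identical
independent sites with microscopic association constant $k$, the
statistical factors give $K_1 = 2k$, $K_2 = k/2$ and
$\Delta H_1 = \Delta H_2$; the cooperativity index $c = 4K_2/K_1$ is then
exactly 1, with $c < 1$ indicating negative cooperativity.

Results tables conventionally report *per-site* stepwise dissociation
constants. `two_site_cooperative(kd1, kd2, ...)` therefore applies the
statistical factors on conversion ($K_1 = 2/k_{d1}$,
$K_2 = 1/(2 k_{d2})$), so the index reduces to $c = k_{d1}/k_{d2}$ and
$k_{d1} = k_{d2}$ recovers the noncooperative identity. For a
tafamidis-like binder with $k_{d1} = 9.9$ nM and $k_{d2} = 260$ nM this
gives $c = 0.038$.

**Equilibrium.** Free ligand solves the mass balance
$L_{tot} = [L] + P_{tot}\,\nu([L])$ with
$\nu = (K_1[L] + 2K_1K_2[L]^2)/Z$, whose residual is strictly increasing
in $[L]$. The solver is a safeguarded Newton iteration bracketed on
$[0, L_{tot}]$, run until the mass-balance residual is below
$10^{-12} L_{tot}$ *and* the bracket is below $10^{-12}$ relative to the
root itself — the second clause matters when free ligand is orders of
magnitude below total ligand (tight binders in protein excess). All
residual terms are bounded by $L_{tot}$, so the floating-point floor sits
near $10^{-15} L_{tot}$ and the criterion is attainable. The test suite
checks the solver against an independent pure-bisection oracle on 1,000
random parameter draws at $10^{-10}$ relative tolerance.

**Thermogram simulation.** Injections follow the instantaneous
displacement convention of perfusion cells: injecting $dV$ into cell
volume $V_0$ first dilutes all cell concentrations by $(1 - dV/V_0)$, then
the injected ligand mixes in. The cumulative binding heat is
$Q_i = V_0 P_i (F_1 \Delta H_1 + F_2(\Delta H_1 + \Delta H_2))$ and the
per-injection heat applies the displaced-volume correction

$$q_i = \left[Q_i - Q_{i-1} + \frac{dV_i}{V_0}\,
\frac{Q_i + Q_{i-1}}{2}\right] \frac{1}{c_{syr}\,dV_i} + q_{dil},$$

normalized per mole of injectant, with a constant dilution-heat offset
$q_{dil}$. Alternative injection conventions differ by terms of order
$(dV/V_0)^2 \approx 10^{-4}$, below fit noise. A corollary worth knowing:
at saturation the heats approach $q_{dil}$ only to within a residual
displacement term of order $(dV/V_0)\,c_{cell}\,|2\Delta H|/c_{syr}$
(about 0.006 kcal/mol under the default protocol), not exactly.

The default protocol mirrors the experimental design: 200 µL cell
(Auto-iTC200 class), 5 µM protein, 100 µM ligand syringe, 19 × 2 µL
injections at 25 °C. Nineteen injections carry the molar ratio to ~4,
past saturation of both sites; the count is configurable.

**Fitting.** `fit_thermogram()` minimizes weighted squared residuals of
the per-injection heats by Levenberg–Marquardt (`minpack.lm::nls.lm`),
with association constants optimized as $\log_{10} K$ and a deterministic
multi-start (5 starts spread over affinity decades around the cell
concentration) to avoid local minima. Noncooperative mode imposes the
statistical-factor identity and fits $(\log_{10} k, \Delta H, q_{dil})$;
cooperative mode frees both constants and enthalpies. The first injection
can be excluded (`drop_first`, common ITC practice; default include).
Degenerate all-zero thermograms are an error; non-convergence is flagged
on the returned object rather than thrown.

**What the fits can and cannot determine.** Noiseless simulate-then-refit
round trips recover generating parameters to better than $10^{-6}$
relative in both modes — the forward model and fitter are consistent. With
1% Gaussian noise at the default protocol, a 50-replicate study (the
problem size used throughout the validation suite) recovers the
noncooperative $K_d$ and $\Delta H$ with median estimates within 2% and
0.1% of truth, and the cooperative $k_{d2}$, $\Delta H_1$, $\Delta H_2$
similarly well, with negative cooperativity ($c \ll 1$) cleanly detected.
The cooperative **first-site** constant is different: $k_{d1} = 9.9$ nM at
5 µM protein corresponds to a Wiseman $c$-parameter near 1000, far beyond
the classical identifiable window (roughly 1–1000). The first-site
transition is effectively stoichiometric, the likelihood is nearly flat in
$k_{d1}$, and its sampling distribution is strongly right-skewed: the
median fitted value sits ~16% above truth, and individual replicates can
be off several-fold *with residual sums below those at the generating
parameters*. This is an information limit of the experimental design at
these concentrations, not an optimizer defect; first-site constants this
tight need lower protein concentrations or displacement titrations, both
outside the scope of this package.

## Stability and plasma assay statistics

**Urea dissociation.** The 355/335 Trp fluorescence ratio is normalized
from the folded minimum to the unfolded maximum (96 h denaturation
control): $f(t) = (r - r_f)/(r_u - r_f)$, clipped to $[0,1]$ and invariant
under common affine rescaling of ratios and references. Because tetramer
dissociation is the rate-limiting step and monomers unfold in
milliseconds, the unfolded fraction is modeled as a single exponential to
a plateau, $f(t) = p\,(1 - e^{-kt})$ — an interpretation, since published
time courses are typically shown without an equation. Protection is the
plateau complement, $100(1-p)$, matching the phrasing "protected X% of
molecules"; the alternative end-time definition $1 - f(t_{end})$ differs
only before the plateau is reached. A flat zero trace returns full
protection with the rate reported as 0 (unidentified).

**Aggregation.** Turbidity at 340 nm with compound-blank correction
(some compounds absorb at 340 nm):
$100\,(A_{sample} - A_{cblank})/(A_{control} - A_{bblank})$. The buffer
blank is subtracted from the control by symmetry with the stated
compound-blank correction. Negative corrected values — instrument noise
near complete inhibition — are clipped to 0 with a warning rather than an
error. Inhibition is the floored complement, so the two sum to 100 when
neither is clipped.

**Plasma metrics.** IEF stabilization is computed per donor
(treated and control lanes from the same donor), then summarized as
mean ± SEM: $100\,(\rho_t - \rho_c)/\rho_c$ on tetramer/total ratios,
which makes it scale-invariant in raw band intensities. The T4 competition
statistic normalizes the TTR-bound fraction TTR/(TBG+ALB+TTR) to the
negative control, with displacement $100(1-f)$. Cross-compound comparison
uses standard one-way ANOVA with Tukey contrasts — ordinary statistics,
not a contribution of this package. Solubility reporting rounds half away
from zero to 3 decimals (base R's round-half-even would turn 0.0445 into
0.044, which is not how assay tables are printed).

## Synthetic-data generators

Each generator is a bit-reproducible function of (parameters, seed); the
RNG state is saved and restored around every call, so no global state
leaks. Defaults encode the study conditions of the assays they emulate:
the ITC generator uses the titration protocol above; the unfolding
generator maps fractions back to 355/335 ratios through declared reference
values; the contact generator draws Bernoulli contacts at the target
frequency with distances uniform in $(cutoff - 0.5, cutoff]$ and
$(cutoff, cutoff + 2]$; the toy tetramer places Ser117 OG atoms and two
ligand carbonyl carbons so the requested interface distances hold exactly
and survive the PDB write/read loop to the format's $10^{-3}$ Å precision.

The aggregation generator links binding to aggregation by taking the
aggregation-competent species to be the fully unliganded tetramer:
noiseless aggregation is proportional to the equilibrium fraction $F_0$ at
each total compound concentration. This is fixture logic — a
mechanism-motivated model (ligand occupancy blocks the
dissociation-competent state), not an empirical claim — and it guarantees
the dose–response is monotone non-increasing before noise.

What the generators deliberately do not emulate: raw instrument signals
(thermal-power traces, gel images, emission spectra), baseline drift,
correlated noise, pipetting errors, or active-fraction uncertainty.
Passing round-trip tests therefore demonstrates internal consistency of
the analysis chain — that each analyzer inverts its generator — not that
the chain is robust to every artifact of real instrument data.

## Known limitations

- The hydrogen-bond criterion is distance-only; no angular term.
- No heat-capacity ($\Delta C_p$) modeling; one temperature throughout.
- No global multi-experiment ITC fitting, and no raw-power integration;
  inputs are integrated per-injection heats.
- First-site constants of very tight cooperative binders are not
  identifiable at standard cell concentrations (see above).
- Densitometry inputs are assumed background-subtracted net band volumes.
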
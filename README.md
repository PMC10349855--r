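# nmrflex

Integrative NMR/SAXS/ITC modeling of flexible multidomain protein–RNA
complexes.

Multidomain RNA-binding proteins — tandem RRMs, RanBP2-type zinc
fingers and their kin, connected by long flexible linkers — bind
single-stranded RNA through the cooperation of individually weak
domains. Characterizing how the domains arrange around the RNA takes
several solution techniques at once, and `nmrflex` implements the
computational workflow that ties them together, for structural
biologists who have the spectra integrated and peak-picked and need to
get from tabulated observables to a restraint-driven structural model:

- **CSP analysis** — combined amide chemical shift perturbations
  `Δδ = sqrt(ΔδH² + (0.2·ΔδN)²)` from free/bound peak tables, strict
  `Δδ > 0.08` ppm binding-site selection, and ambiguous 4 ± 1 Å
  protein–RNA distance restraints over heavy atoms.
- **¹⁵N relaxation** — mono-exponential R1/R1ρ fitting with
  duplicate-delay errors, offset correction
  `R1ρ = R1 cos²θ + R2 sin²θ`, rotational correlation times from
  `τc = sqrt(6·R2/R1 − 7)/(4π·νN)` and from molecular weight
  (0.6 ns/kDa), with domain-wise averages.
- **PRE restraints** — I_para/I_dia ratios → Γ₂ (exact inversion of
  `ratio = R2·e^(−Γ₂t)/(R2+Γ₂)`) → distances via Solomon–Bloembergen
  `r = [K/Γ₂·(4τc + 3τc/(1+ωH²τc²))]^(1/6)`, classified into
  upper/quantitative/lower flat-bottom restraints with error-aware
  thresholds, plus back-calculation from coordinates.
- **Conformer sampling** — random phi/psi linker randomization with
  rigid domains under the 10 % steric-energy acceptance rule.
- **Restraint annealing** — three-stage Metropolis simulated annealing
  in torsion space against PRE + ambiguous CSP restraints (r⁻⁶-summed
  effective distances), coordinate-descent polish, low-energy ensemble
  selection with pairwise backbone RMSD statistics.
- **SAXS** — Debye curves from residue-bead models, Guinier fits
  (q·Rg < 1.3), p(r)/Dmax from models and from curves (regularized
  non-negative indirect transform), and reduced-χ² model-vs-data
  fitting.
- **ITC** — one-site isotherm simulation with exact injection
  bookkeeping, Levenberg–Marquardt fitting of (KD, ΔH, N), and
  `ΔG = RT·ln KD`, `−TΔS = ΔG − ΔH`.
- **Synthetic data** — toy three-domain protein–RNA complexes with
  known ground truth and forward-simulated observables for every
  module, driving end-to-end parameter-recovery tests.

## Worked example

```r
library(nmrflex)

## CSP for one residue of a titration
free  <- data.frame(residue_number = 265, dH_ppm = 8.10, dN_ppm = 118.4)
bound <- data.frame(residue_number = 265, dH_ppm = 8.13, dN_ppm = 118.6)
computeCsp(free, bound)
#>   residue_number delta_delta
#> 1            265        0.05
```

A ¹H shift change of 0.03 ppm and an ¹⁵N change of 0.2 ppm combine to
Δδ = 0.05 ppm — below the 0.08 ppm cutoff, so residue 265 would not
enter the binding-site set at this titration point.

```r
## a PRE rate of 50 s^-1 at tauc 8.4 ns, 600.13 MHz
gamma2ToDistance(50, tauc = 8.4, field_1H = 600.13)
#> distance: 14.22 A

## binding thermodynamics at 25 C for KD = 127 nM, dH = -19.1 kcal/mol
bindingThermodynamics(0.127e-6, -19.1)
#> dG = -9.41 kcal/mol, -TdS = 9.69 kcal/mol
```

The Γ₂ = 50 s⁻¹ amide sits 14.2 Å from the unpaired electron — a
quantitative restraint. The ITC numbers show strong enthalpy-driven
binding paying a 9.7 kcal/mol entropic penalty, the signature of a
flexible protein rigidifying around its RNA.

```r
## the synthetic toy complex: bound vs apo compaction
truth <- makeToyComplex(toyComplexSpec())
truth$conformer
#> Conformer: 320 atoms, 2 chains (A,R), 83 residues
apo <- makeToyComplex(toyComplexSpec(mode = "apo"))
dmax(pofrFromModel(truth$conformer))  # 81.8 A
dmax(pofrFromModel(apo$conformer))    # 154.0 A
```

The RNA-bound toy is far more compact than the open apo state, the
behaviour the SAXS module is asked to detect. The full chain —
observables → restraints → pool → annealing → ensemble — is wrapped by
`recoveryExperiment()` and, for file-based inputs, by `runPipeline()`;
see the methods vignette (`vignettes/methods.Rmd`) for the models,
defaults and design decisions.

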
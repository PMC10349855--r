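---
title: "Integrative modeling of flexible multidomain protein-RNA complexes: methods and design"
author: "nmrflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Many RNA-binding proteins are built from several small domains (RRMs,
zinc fingers) connected by long flexible linkers. Each domain alone binds
its RNA element weakly; in the complex the domains can cooperate, and the
question is how they arrange in space around a single-stranded RNA. No
single technique answers this: crystallography captures rigid modules,
solution NMR reports per-residue binding surfaces (chemical shift
perturbations, CSPs), linker dynamics and tumbling (15N relaxation), and
long-range distances (paramagnetic relaxation enhancement, PRE), SAXS
reports the overall envelope, and ITC the binding thermodynamics.
`nmrflex` implements the computational side of this integrative workflow:
it converts the spectroscopic observables into distance restraints,
samples linker conformations with rigid domains, refines conformers
against the restraints by simulated annealing, and validates the
resulting ensemble against SAXS, with a one-site ITC module for the
thermodynamics. A synthetic-data module builds toy multidomain
protein-RNA systems with known ground truth so every stage can be tested
by parameter recovery.

# Models and conventions

## Coordinates and domain partitions

Structures are `Conformer` objects: an ordered atom table with chain,
residue and atom labels and coordinates in Angstrom, read and written as
fixed-column PDB (reading through `bio3d`; alternate locations reduce to
the first occurrence, insertion codes are rejected). A
`DomainPartition` names residue segments as `rigid` or `flexible`. All
conformational moves are backbone phi/psi rotations of flexible-segment
residues, right-handed, in degrees, relative to the input geometry
(0 = identity), propagating to all atoms C-terminal of the rotated bond
within the same chain. This convention preserves covalent geometry and
rigid-domain internal structure exactly, which the tests assert to
1e-6 Angstrom.

## CSP mapping

Combined amide perturbations use the standard two-dimension form
`sqrt(ddH^2 + (alpha*ddN)^2)` with `alpha = 0.2` compensating the wider
15N dispersion. Binding-site residues are selected by a strict
`delta > 0.08` ppm threshold (boundary values excluded). Residues visible
in only one state (e.g. broadened beyond detection on binding) cannot
yield a CSP; they are omitted from the profile and reported in an
attribute so the analyst can treat them separately. Selected residues
become ambiguous restraints: a flat-bottom 4 +/- 1 Angstrom target
between the heavy atoms of the residue and the heavy atoms of any of the
listed RNA nucleotides, evaluated on the r^-6-summed effective distance
(the NOE convention, `(sum r^-6)^(-1/6)`); a nearest-atom alternative
would be config-level work for the evaluator, but the r^-6 sum is smooth
and dominates correctly in the near-contact regime.

## 15N relaxation and tumbling

Per-residue R1 and R1rho rates come from mono-exponential least squares
(`minpack.lm`), with duplicate delays providing the intensity
uncertainty: sigma_I is the RMS of half the within-pair differences,
entering the fit weights, so the covariance standard error of the rate
already carries the duplicate scatter. R1rho is corrected to R2 with
`R1rho = R1 cos^2(theta) + R2 sin^2(theta)`, `theta = atan(nu1/dnu)`;
corrections with `sin^2(theta) < 0.25` are flagged unreliable. The
rotational correlation time uses the isotropic estimator
`tauc = sqrt(6 R2/R1 - 7) / (4 pi nuN)`, valid for `R2/R1 > 7/6`. For
expectations from size alone the package uses the empirical rule
`tauc ~ 0.6 ns/kDa` at 25 C in water — a deliberate, prominently
documented simplification chosen because it reproduces the standard
textbook anchor points (8.4 ns at 14 kDa, 6.5 ns at 10.9 kDa, 1.9 ns at
3.2 kDa) to the one-decimal precision at which such estimates are
quoted.

## PRE restraints

Intensity ratios `I_para/I_dia` convert to the paramagnetic rate Gamma2
by inverting `ratio = R2 exp(-Gamma2 t) / (R2 + Gamma2)` (unique root,
bisection to 1e-8; the diamagnetic `R2` and the transverse evolution
time `t` are required user parameters — `t` is instrument-dependent and
not recoverable from the tables themselves). Gamma2 converts to distance
through the Solomon-Bloembergen relation

    r = [ K/Gamma2 * (4 tauc + 3 tauc / (1 + wH^2 tauc^2)) ]^(1/6)

with `K = 1.23e-32 cm^6 s^-2` and `wH` the 1H Larmor angular frequency.
Classification into restraint classes follows the usual protocol
defaults, all config-exposed: ratios below 0.15 give upper-bound-only
restraints (distance below the detection floor), ratios above 0.85 give
lower bounds only, and the window between gives quantitative flat-bottom
restraints at target +/- 4 Angstrom. When a profile carries per-ratio
errors, a ratio whose error interval crosses a cut takes the less
informative class. This conservatism matters in practice: a distal
residue with a true ratio near 1 can fluctuate below 0.85 by noise
alone, and classifying it quantitatively would fabricate a tight
20-30 Angstrom target that contradicts the structure by tens of
Angstroms. The spin label's unpaired electron is placed at a fixed
6 Angstrom offset from the attachment residue's CA along the CA->CB
direction — a single effective position rather than a rotamer ensemble,
matching the semi-rigid resolution of the modeling; the amide proton is
proxied by the backbone N at pseudo-atomic resolution.

## Conformer sampling

`generatePool()` reproduces the randomization protocol: for each run,
every flexible residue in N-to-C order receives one uniformly random
(phi, psi) proposal, accepted only if the molecule-wide steric energy
does not rise more than 10 percent above the energy at the start of that
run (a fixed per-run reference, not a continuously re-based one — the
more conservative reading of a "starting energy" rule), followed by a
short greedy steric minimization; runs whose final backbone violates the
3.0 Angstrom bond sanity check are rejected. The steric term is a purely
repulsive quartic, `sum k (rmin - r)^4` for `r < rmin` with `rmin` the
sum of element van der Waals radii, excluding same- and
adjacent-residue pairs; there is no attractive term because the rule
only penalizes clashes. For speed the molecule-wide score uses one bead
per residue (CA, and one bead per nucleotide); `vdwEnergy()` exposes the
same functional form at any atom selection.

## Restraint-driven annealing

Refinement is Metropolis Monte Carlo in torsion space over the flexible
linker, with a three-stage cooling schedule (default temperature-like
scales 30 -> 6 -> 1 in energy units, 600/400/250 steps, move amplitudes
60/20/6 degrees) followed by a deterministic cyclic coordinate descent
over all linker torsions with a step ladder from 16 down to 0.5 degrees
and a fixed proposal budget (12000 by default), so a run that converges
slowly stops at a predictable cost and is then discarded by the
energy-ranked ensemble selection. Inside the annealer, energies are
evaluated incrementally — a torsion move changes only the terms with
exactly one endpoint in the rotated atom set — and the incremental
evaluator is asserted against the reference `restraintEnergy()` by the
test suite.
The energy is the weighted sum of the flat-bottom PRE term (harmonic
outside the bounds), the ambiguous CSP term on effective distances, and
the bead-level steric term; the decomposition sums exactly to the total.
Because moves are torsion rotations, rigid-body degrees of freedom are
implied rather than explicit — domains move as rigid bodies *through*
the linker — and covalent geometry can never be broken, so no bonded
restoration term is needed (its weight exists in the `EnergyModel` for
completeness and reports zero). The engine returns the lowest-energy
conformer visited, so annealing never ends above its start. The
`10 lowest energy` members of an annealed set form the reported
ensemble, with mean/SD of all pairwise backbone C-alpha RMSDs after
superposition on the rigid segments; ties break by input order (stable
sort on provenance).

The schedule defaults were set on the package's toy systems: large
first-stage amplitudes let the linker cross between docking basins while
the restraint funnel is steep, and the coordinate descent — not the
Monte Carlo — does the final convergence work. On the standard toy this
combination converges the restraint energy to within a few units of the
ground-truth energy in nearly every run; longer Monte Carlo stages
without the descent polish were consistently worse per CPU second.

## SAXS

Model curves use the Debye double sum over one bead per residue at the
heavy-atom centroid with effective per-residue weights (approximate
electron counts per residue type; uniform weights available), with a
series guard for sinc at small argument. This rank-orders conformers
and validates envelopes at desk scale; it is *not* comparable in
absolute chi-square terms to spherical-harmonics engines with hydration
shells (CRYSOL-class), and the package makes no claim at that level.
Guinier fits are weighted linear regressions of ln I on q^2 with
iterative range reduction until `q_max * Rg < 1.3`. For globular
particles the Guinier, p(r)-based and coordinate radii then agree to
within a few percent; for strongly elongated particles (including the
bound toy complex) the Guinier estimate is systematically low by
5-8 percent even on noiseless data — the approximation's textbook
behaviour, pinned by a unit test so it is never mistaken for an
estimator bug. `pofrFromModel()`
histograms exact pair distances (exact Dmax; Rg from the unbinned second
moment). `pofrFromCurve()` is a regularized indirect transform:
non-negative least squares (`pracma::lsqnonneg`) on an r-grid with a
second-difference smoothness penalty scaled relative to the data term
(`lambda = 0.05` default); its reduced chi-square is reported and a
value above 10 flags a misfit, which is how a grossly wrong trial Dmax
surfaces to the analyst — Dmax selection from experimental curves stays
analyst-in-the-loop, as in practice. Model-vs-data comparison
interpolates the model onto the experimental grid and fits scale and
offset in closed form, with `chi^2 = (1/(N-1)) sum ((c I_m + b - I_e)/
sigma)^2` (offset switchable off).

## ITC

The one-site model uses exact stepwise injection bookkeeping: each
injection dilutes the cell contents by `(1 - v/V0)` and adds titrant;
bound ligand comes from the binding quadratic; the heat of injection i
is the difference in cell heat content plus the displaced-volume
correction `(v_i/V0) * (Q_i + Q_{i-1})/2`. Heats are in kcal, R =
1.987e-3 kcal/(mol K), T defaults to 298.15 K. Fitting is
Levenberg-Marquardt over (log KD, dH, N) with a multi-start over a log
KD grid; N can be fixed for low-c-value data, mirroring how weak
binders are handled in practice. `bindingThermodynamics()` computes
`dG = RT ln KD` and `-TdS = dG - dH`, so the closure `dG = dH + (-TdS)`
is exact by construction. A reference table of duplicate ITC
measurements for the RBM5 construct series ships with the package
(`itcReferenceTable()`); recomputing `-TdS` from each replicate's
(KD, dH) reproduces the tabulated value within 0.05 kcal/mol for every
free-stoichiometry replicate, except one entry whose tabulated sign is
inconsistent with its own (KD, dH) pair — its magnitude closes — and
the table flags it.

# The synthetic toy and what it does (and does not) show

`makeToyComplex()` builds a pseudo-atomic (N/CA/C + CB) three-domain
protein: two rigid modules (18 and 8 residues) joined by a short rigid
linker (7 residues) — emulating an RRM coupled tightly to a zinc
finger — and a third rigid domain (18 residues) connected through a
20-residue flexible linker. Rigid domains are alpha-helix-like coils
(2.3 Angstrom radius, 1.5 Angstrom rise), which gives them genuine
three-dimensional extent; early rod-like toys made the third domain's
orientation nearly unobservable to distance restraints. In the bound
mode the flexible linker makes a U-turn so the third domain packs
antiparallel against the first module across a ~12 Angstrom groove, and
a 12-mer RNA bead chain (P/C4/N1 per nucleotide) threads the groove,
its 5' end emerging near the zinc-finger module and its 3' half
contacting the third domain — the compact arrangement the workflow is
meant to recover. The apo mode is fully extended and has strictly
larger Dmax, so binding-induced compaction is a structural property of
the fixtures, not an assertion about noise.

Simulated observables follow each module's forward model: PRE ratios
from the Solomon-Bloembergen chain for four label sites (one in the
first domain, three across the third — the layout used experimentally
for such systems), with 5 percent relative ratio noise by default; peak
tables whose CSP exceeds the 0.08 threshold exactly for residues whose
CA lies within 7 Angstrom of an RNA bead (CSPs are treated purely as
binding-surface labels; no chemical-shift physics is modeled); decay
tables on the standard delay grids with duplicates at 2 percent
intensity noise, with per-domain tumbling times (13 ns modules, 5 ns
linker) consistent with the R2/R1 estimator by construction; a Debye
SAXS curve at 2 percent noise; and a one-site isotherm (KD 133 nM,
dH -19.1 kcal/mol, N 1; 26 x 1.5 uL injections into a 200 uL cell at
10 uM, c ~ 75) with 0.1 ucal heat noise.

The headline experiment (`recoveryExperiment()`) runs the whole chain:
simulate at 5 percent PRE noise, rebuild restraints (the error-aware
classification described above), generate a 40-member randomized pool,
anneal the 12 members with lowest initial restraint energy, select the
10 lowest final energies, and measure the backbone C-alpha RMSD of the
ensemble centroid to the ground truth. Across 20 independent seeds the
centroid lands within 3 Angstrom in at least 80 percent of runs
(typically 2.2-2.9 Angstrom). Problem sizes (40-member pools, 12
annealed members, the default schedule) were chosen as the smallest at
which this experiment is stable run-to-run.

What passing does *not* show: the toy has ideal geometry, a single
conformation, no intermediate-exchange line broadening, no label
rotamer averaging, no RNA flexibility, and noise that is independent
and Gaussian. Real systems violate all of these; on real data the same
pipeline yields an ensemble whose spread must be interpreted against
the restraint density, and the SAXS chi-square is the external check.

# Degenerate inputs and numerical choices

Strict thresholds exclude boundary values (CSP selection). Ratios >= 1
return Gamma2 = 0 flagged `no-effect`; ratios <= 0 return Inf flagged
`lower-bound-only`. Non-convergent decay fits are flagged and excluded
downstream rather than guessed. The Guinier fit errors out when no
range satisfies the q*Rg rule. sinc(x) switches to its series below
1e-6. The indirect transform enforces p(r) >= 0 by construction
(non-negative least squares), not by clipping. Annealing with an empty
violated set leaves the energy at zero. PDB writing refuses > 99999
atoms; multi-model files carry pools and ensembles.

# Known limitations

Isotropic tumbling only (no diffusion tensors, no model-free analysis);
single effective spin-label position; no ensemble-averaged PRE for
exchanging states; residue-bead SAXS without hydration shell; one-site
ITC only; the energy scale of the annealer is package-defined and not
comparable to any molecular-mechanics force field. The pipeline treats
the RNA and the first rigid module as a fixed frame — appropriate when
a high-resolution structure anchors that module, which is the use case
it was built for.
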
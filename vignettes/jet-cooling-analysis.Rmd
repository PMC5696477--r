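---
title: "Interpreting jet-cooled conformer spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting jet-cooled conformer spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jetcool)
```

## The problem

Supersonic-jet single-molecule spectroscopy freezes a laser-desorbed
molecular ensemble from several hundred kelvin to ~10 K in microseconds.
The expansion is far too fast for conformational equilibration across any
appreciable barrier, so the conformer set recorded by double-resonance
spectroscopy is neither the high-temperature equilibrium ensemble nor the
10 K one. `jetcool` models the experiment as a two-step process:

1. the ensemble equilibrates at an effective pre-expansion temperature
   `t_eff` (default 450 K, the scale set by laser-desorption kinetics);
2. during cooling, population moves only across *low* barriers; each group
   of conformers connected by low barriers (a kinetic basin) collapses onto
   its local free-energy minimum (the sink), whose final abundance is the
   sum of the group's `t_eff` populations.

A sink is predicted observable when its pooled population exceeds an
8% threshold, the empirical signal-to-noise floor of the double-resonance
experiments this model targets.

## Populations

Relative free energies are `G_i(T) = e_rel_i + g_corr_i(T)`, re-referenced
to the ensemble minimum; populations are Boltzmann weights with
`kB = 1.98720425864083e-3` kcal mol⁻¹ K⁻¹ (CODATA-derived; the constant is
fixed rather than configurable so that population tables are reproducible
to the last digit). Exponentials are stabilised by subtracting the minimum
free energy first. Free-energy corrections supplied on a temperature grid
are interpolated linearly and held constant outside the grid — corrections
vary smoothly with temperature, and constant extrapolation avoids
manufacturing spurious entropy outside the data. Degenerate conformers are
kept distinct; no symmetry-number weighting is applied.

The *conformer-of-interest* filter retains the union of the ten lowest
electronic energies and everything exceeding 1% population at any grid
temperature up to 450 K (default grid 10–450 K in steps of 10 K). Both
rules matter: low-energy folded conformers dominate cold ensembles, while
high-entropy extended conformers only appear hot.

## Structural typing

Each conformer gets a four-part label
`<terminus>-<backbone>(<fold>)-<swing>/<orientation>`:

* **Backbone**: the second residue's (φ₂, ψ₂) pair is assigned to the
  nearest of six canonical centres on the torus — γ_L(−84, 68),
  γ_D(84, −68), β(−180, 180), ε_L(−75, 160), ε_D(75, −160), α_L(60, 45) —
  with periodic wrapping. γ classes are folded (F), the rest extended (E).
  The centre values are fixed constants of this package, chosen to match
  the conformer-letter convention used for capped amino acids; nothing in
  the pipeline is sensitive to their exact placement because observed
  conformers sit deep inside their wells. ψ₂ is measured to the carboxyl
  *hydroxyl* oxygen; the choice is arbitrary but consistent between the
  classifier and the geometry builder.
* **Swing**: χ₁ (N–Cα–Cβ–Cγ) is mapped to the nearest of +180 (g+),
  +60 (g−) and −60 (a); ties resolve in the order g+, g−, a. This literal
  mapping (g+ at *anti*) departs from common gauche nomenclature but is the
  convention of the reference data this package reproduces.
* **Terminus**: B when the amine donates to the peptide carbonyl
  (`N_1_H···OC_PB` present without `N_PB_H···N_1`), otherwise A1/A2 by the
  sign of the amino-swing dihedral (first amino hydrogen about the N–Cα
  bond; positive ⇒ A1). Conformers with neither diagnostic bond are typed
  `U` and excluded from barrier prediction.
* **Orientation**: the sign of a residue-specific dihedral — the phenol
  hydroxyl dihedral when a side-chain OH exists, the ring-twist χ₂
  otherwise. The quadruples are auto-detected from perceived atom roles and
  can be overridden per conformer.

Hydrogen bonds are geometric: a polar H (bonded to N/O within 1.2 Å) within
an inclusive 2.8 Å of an N/O acceptor or an aromatic-ring centroid. The
H···acceptor distance (not donor···acceptor) is used because the reference
label grammar names the hydrogen explicitly. Contacts spanning three or
fewer covalent bonds are excluded; without that rule every carboxyl group
reports its own intramolecular O–H···O=C contact, which the field does not
count as a hydrogen bond. For fused ring systems (indole) only the centroid
nearest the hydrogen is tested, so a single N–H···π contact is never
double-counted.

## Barrier classes and pooling

Barriers classify as low (≤ 2 kcal/mol), high (≥ 8) or medium (between).
Both boundaries are inclusive on the side of their class and configurable;
the inclusive reading of "≤ 2" was adopted where the prose is ambiguous.
When no computed barrier is available the class is predicted from the two
structural types: different folds, or two different folded backbones, are
high (a strong H-bond must break); extended conformers with different
side-chain types are medium (steric hindrance); only same-side-chain
conversions — terminus rotations and β/ε/α exchanges of an extended
backbone — are low. Explicit barrier values always override predictions,
because measured exceptions (e.g. lowered barriers in the presence of an
N_PB–H···π contact) are known.

Pooling takes the connected components of the low-barrier graph, sums each
component's `t_eff` populations, and assigns the total to the component's
sink: the argmin of the 10 K free energies, with ties broken by electronic
energy and then lexicographic id. Medium and high edges carry zero flux —
no partial conversion is modelled, matching the assumption that those
conversions are negligible during the expansion; a rate model is
deliberately out of scope. When reference free energies are published only
as figure profiles, `pool_populations()` accepts designated sinks instead
of numeric values; the packaged tyrosyl-glycine groups use this mechanism.

Sensitivity: the default `t_eff` of 450 K carries roughly ±50 K
uncertainty. Re-running `populations_vs_T()` across 400–500 K changes
pooled percentages by a few points without reordering the observable set,
which is why the package treats `t_eff` as a single scalar argument rather
than a distribution.

## Spectra

Harmonic frequencies are multiplied by a single scaling factor
(`scale_factors`: 0.9602 for B3LYP/6-31G**, 0.943 for M062X/6-31G**).
Calibration against experiment uses the ratio of means — chosen over least
squares so that scaling reproduces the experimental mean exactly, which is
the property the calibrated factor is quoted with. Because the modes
entering a calibration are an experimental identification, the function
takes explicit matched lists rather than discovering correspondences.
Broadening sums Lorentzians `I (Γ/2)² / ((ν−ν₀)² + (Γ/2)²)` with a 20 cm⁻¹
default FWHM. Assignment scoring pairs lines by mode label when labels
exist (erroring on unmatched labels), otherwise positionally in frequency
order, and reports mean and maximum absolute deviation; reported values are
rounded half-up to integer cm⁻¹ to match how band positions are printed,
with raw floats retained.

## Synthetic ensembles and the toy geometry builder

`generate_ensemble()` draws an ensemble with the structure real aromatic
dipeptides show: a few folded low-energy conformers (each its own basin)
and extended families sharing a side-chain type (each family one basin).
Extended conformers receive an entropic free-energy advantage growing
linearly with temperature (default 1.5 kcal/mol at the top of the grid),
reproducing the characteristic inversion from folded-dominated cold
ensembles to extended-dominated hot ones. Barriers are drawn from
class-respecting intervals — low within a family, medium between extended
families, high to and among folded conformers — so the ground-truth basins
are known by construction and pooled fractions must be recovered exactly,
not approximately. Defaults (one folded conformer; families of 4, 3, 6
and 7; 4 kcal/mol energy spread) mirror the group sizes of the packaged
tyrosyl-glycine ensemble. What the generator does *not* emulate: realistic
energy landscapes, correlated barriers, or conformers whose barrier class
violates the type rules — passing recovery tests therefore demonstrates the
pooling machinery, not the type heuristic's accuracy on real molecules.

`build_dipeptide_geometry()` places atoms by internal coordinates (ideal
bond lengths/angles, polar hydrogens only) and realises requested torsions
to numerical precision, which makes classifier round-trips exact. One
geometric fact is worth recording: with ideal geometry, an *anti* χ₁
(the literal "g+" mapping) puts the aromatic centroid more than 3.1 Å from
any amino hydrogen, so a single toy geometry cannot be simultaneously "g+"
and exhibit an amino-to-ring π bond. Real conformers manage both through
angle strain the toy model omits. The test fixtures therefore separate the
two properties: the H-bond-network fixture uses χ₁ = −30° to fold the ring
over the amine, while the type-label fixture uses χ₁ = 175°.

## Numerical choices and limitations

* Energies are relative kcal/mol throughout; hartree input is converted by
  627.5094740631 and re-referenced at read time.
* Population tables print entries below 1% as an em dash; the underlying
  matrix keeps full precision, and all arithmetic uses it.
* The 37-row reference table is a packaged fixture with a pinned checksum.
  Its unprinted sub-1% entries are treated as zero when pooling, which is
  why one basin pools to ~14% where ~18% is expected when the full
  ensemble is available — the package reports what the printed rows
  support rather than interpolating missing members.
* Problem sizes used in the test-suite property checks (random graphs of
  ≤ 12 nodes, ensembles of ~20 conformers, three seeds) keep the full
  suite in seconds while exercising every branch; the algorithms are
  O(n²) in conformer count and handle hundreds of conformers comfortably.
* Quantum-chemistry computation is out of scope: the package consumes
  tabulated energies, corrections, barriers and frequencies, and does not
  parse native QM output files.
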
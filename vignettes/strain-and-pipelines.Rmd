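---
title: "Methods: streaming SD pipelines and conformational strain analysis"
author: "sdpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: streaming SD pipelines and conformational strain analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpipe)
```

# Scope

sdpipe is a toolkit for the two workhorse activities of small-molecule
informatics groups: moving annotated structures through
filter-and-compute pipelines, and judging whether a 3D binding pose is
conformationally strained. The package treats the MDL structure-data
(SD) file as the universal interchange format: every operation is a
transformer from a stream of SD records to a stream of SD records, so
operations compose in-process exactly as the equivalent command-line
programs compose under UNIX pipes.

This vignette documents the models and the numerical and design
choices. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

# Streaming SD input/output

The reader is incremental: records are parsed one at a time as the
consumer pulls them, so a pipeline over a million-record file holds
one record in memory per stage. The contract is round-trip fidelity
on what matters scientifically: title, atom/bond counts and orders,
charges, and the *ordered* list of data fields with values preserved
verbatim (including multi-line values). The writer emits a canonical
serialization, so `write -> read -> write` is byte-stable; this is
what makes compiled shell pipelines byte-comparable with in-process
runs.

Deliberate restrictions: only the V2000 dialect is supported (V3000
input raises an error); long field values are written unwrapped; data
headers are accepted in both the plain and the indexed form but only
`> <name>` is written; line endings are normalized to `"\n"`.

# Scaffold tagging

Series assignment applies an ordered list of SMARTS definitions (a
tag set) to each molecule and writes the first match, all matches, or
both, into data fields (`StructureTag` / `AllStructureTags` by
default, `"; "`-separated for the all-matches field, duplicate tag
names reported once). Order is the user's tool for expressing
priority: a generic pattern placed first wins over a more specific
pattern placed later, which lets users assign series without
authoring exclusion logic in SMARTS. Substructure matching is
delegated to OpenBabel (through ChemmineR/ChemmineOB) with its
default aromaticity model; no kekulization pass is applied. Molecules
the matcher cannot handle (including data-only records) pass through
untagged with a warning, and no field is written for clean
non-matches.

# Property calculation and dependency resolution

Calculators are declared in an XML registry. Each `<property>`
element names its dependencies (`requiredCalculators`), whether
dependency outputs survive into the final file
(`keepRequiredCalculators`), and an optional `progAggregateID`.
Resolution:

1. expands the transitive dependency closure of the request
   (depth-first, with in-progress marks for cycle detection);
2. merges calculators sharing a `progAggregateID` into a single step,
   so a multi-descriptor program runs once however many of its
   outputs are requested;
3. orders steps topologically, breaking ties by registry declaration
   order — plans are therefore deterministic, which the compile/run
   equivalence tests rely on;
4. marks the outputs of dependency-only calculators as transient and
   strips them after the last step, unless some dependent asks to
   keep them (keeping wins over dropping: retaining a field is never
   incorrect).

A dependency between two members of one aggregate group would
collapse onto the merged step itself; such registries are rejected as
cycles rather than silently reordered. The shipped builtins are MW,
N+O acceptor and NH+OH donor counts, rotatable bonds, an OpenBabel
lipophilicity estimate standing in the cLogP role, and the
rule-of-five violation count (MW > 500, cLogP > 5, donors > 5,
acceptors > 10). Numeric fields are written with two decimals.

# Pipelines, compilation, multiplexing

A pipeline is an ordered list of stages; running it is the left-fold
of the stage transforms over a lazy stream, and compiling it joins
the stages' command texts with `" \\\n | "`. The command-line
interface (`inst/cli/sdpipe.R`, a thin dispatcher over the exported
functions) makes the compiled text executable: the same input fed to
the shell pipe must produce byte-identical SD output to the
in-process run, and the test suite asserts exactly that.

The multiplexer parallelizes stages whose output records each depend
on one input record. Records are numbered and dealt round-robin to
forked workers (chunk size one record, the smallest unit, to balance
load); with `preserveOrder = TRUE` outputs are reassembled into input
order, otherwise worker outputs are concatenated and only the record
multiset is guaranteed. Failures are fail-fast and report the
offending record's ordinal.

# The force field

No R-accessible toolkit in the package's dependency set exposes
programmatic force-field minimization with user-defined restraints,
and the flat-bottom constrained minimization *is* the core of the
strain protocol, so sdpipe ships its own compact gas-phase
molecular-mechanics force field (C++ via Rcpp, analytic gradients,
verified against finite differences in the tests):

* harmonic bond stretches, reference lengths from single-bond
  covalent radii with bond-order contraction factors
  (k = 600 kcal/mol/A^2);
* cosine-harmonic angle bends (smooth at linearity), reference angles
  by hybridization: 109.47 degrees for sp3 (104.5 for divalent O/S),
  120 for sp2, 180 for sp (k = 60 kcal/mol);
* periodic torsions keyed on the central bond: 3-fold staggered
  wells for sp3-sp3 (0.16 kcal/mol per atom pair), 2-fold planar
  wells for sp2-sp2 and aromatic bonds (2.5 kcal/mol per pair), a
  shallow 6-fold term for mixed rotors;
* Lennard-Jones 12-6 interactions with UFF van der Waals parameters
  for pairs three or more bonds apart, 1-4 pairs scaled by 0.5;
* no explicit electrostatics and no solvation model.

These choices reproduce the qualitative torsional physics the
protocol depends on — ethane relaxes to staggered rotamers, butane's
anti rotamer beats gauche by roughly 0.9 kcal/mol, aromatic systems
stay planar — while remaining fully self-contained. The published
strain statistics for PDB ligand sets were computed with MMFF94S plus
a solvation model; absolute energies from this force field are **not**
comparable to those numbers, and no such comparison is attempted
anywhere in the package. Strain energies are differences within one
molecule evaluated under one consistent model, which is the quantity
the protocol needs.

Minimization runs a short damped steepest-descent warm-up (per-step
displacement capped at 0.05 A) before L-BFGS-B with analytic
gradients (`pgtol = 1e-3`, energies converged to ~1e-4 kcal/mol).
The warm-up keeps minimizations inside the basin of the starting
geometry; without it, quasi-Newton steps from strained starts
occasionally hop rotamer barriers, which would blur the "local
minimum closest to the input" concept.

# The strain protocol

For one 3D input pose, `analyzeStrain()` retains:

* the **input** (single-point energy, RMSD 0 by definition);
* the **local minimum**: unconstrained minimization started from the
  input — our reading of "the minimum closest to the input";
* four **constrained minima**, one per flat-bottom radius (defaults
  0.2, 0.6, 1.0, 1.4 A), tracing how much energy is recovered per
  Angstrom of allowed relaxation;
* the **global minimum** from an ensemble search;
* any additional ensemble minima that are **Pareto-optimal** in the
  (RMSD-to-input, energy) plane.

The flat-bottom restraint is a per-atom positional well: zero penalty
within the radius of the atom's input position, harmonic outside.
Per-atom wells (rather than a restraint on the aggregate RMSD) are
what standard minimizers implement natively. The default force
constant is 5000 kcal/mol/A^2 — effectively a hard wall. A soft
constant (the 10 kcal/mol/A^2 one might first try) lets atoms drift
0.15-0.25 A past the nominal radius under the internal forces of a
strained pose, destroying the interpretation of the radius as a
relaxation budget; with the stiff default, a 0.01 A radius confines
relaxation below 0.1 A RMSD on the package's fixture poses. Reported
energies always exclude the restraint term, so constrained minima are
energy-comparable across radii, and the nested-feasible-region
property (energy non-increasing with radius) is asserted in the
tests at a 0.05 kcal/mol tolerance.

The global-minimum search enumerates conformers by torsion-driving:
every rotatable bond (single, acyclic, both ends non-terminal heavy
atoms) is driven to the staggered rotamers (-60/60/180 degrees;
0/180 for conjugated bonds; 120-degree offsets from the input for
mixed rotors), each candidate is augmented with polar-hydrogen (OH/NH
terminal rotor) variants on a 120-degree grid (capped at 81 variants),
and everything — input included — is minimized. The candidate set is
capped at `maxEnsemble = 500` geometries; when the torsion grid
exceeds the cap, a seeded subsample is taken, so results are
deterministic for a fixed seed (default 42). Torsion enumeration
replaces the stochastic/commercial conformer generators used in
production settings; for the <= 7-rotor molecules this package
targets, the staggered grid covers the rotamer space the minimizer
needs as starting points.

All retained conformers are aligned to the input by Kabsch
superposition on heavy atoms, with symmetry correction: graph
automorphisms of the element- and hydrogen-count-colored heavy-atom
skeleton (enumerated with igraph's VF2, capped at 10000) are tried
and the best-fitting atom mapping wins, so a flipped phenyl ring does
not inflate the RMSD. `rmsdToInput` is always the post-alignment
value.

`strainAtThreshold(profile, t)` is the energy of the lowest-energy
retained conformer within `t` Angstrom of the input, relative to the
global minimum; the input itself qualifies at every threshold, so the
statistic is defined for all `t >= 0` and is monotone non-increasing
(a minimum over nested sets). `flagStrained()` applies the decision
rule used in structure-based design triage: flag a pose whose strain
at 0.4 A of allowed relaxation strictly exceeds 4 kcal/mol.

Pareto retention uses weak dominance ((<=, <=) with at least one
strict) and drops exact duplicates (an already-retained point beats
an identical candidate). The implementation is a sort-and-sweep over
the staircase front; the tests compare it against an independent
quadratic pairwise filter on random point sets up to n = 200.

# Synthetic data

All test inputs are generated in code. 3D geometries come from a
deterministic embedding: the OpenBabel structure-diagram generator
supplies a 2D layout with explicit hydrogens (the 3D builder in this
OpenBabel build is either stochastic or emits zero coordinates,
neither of which a reproducible test suite can use), the layout is
lifted out of plane with small seeded Gaussian z-displacements,
relaxed with the package force field, and polished to the global
rotamer, so an unperturbed fixture is a strain-free reference
geometry. The same SMILES always yields the same coordinates.

`makeStrainedPose()` adds zero-mean Gaussian noise to every
coordinate of such a reference geometry. The default scale, 0.15 A,
was chosen once as the magnitude of crystallographic coordinate
uncertainty for small-molecule ligands at better than 2 A resolution
— the input regime of the strain protocol. Two properties of this
generator matter for interpreting test results. First, noised poses
carry large single-point strain (bond lengths are perturbed) but
relax back to their source rotamer within a few tenths of an
Angstrom, so strain at 0.4 A relaxation is near zero by
construction — the generator emulates coordinate noise, not the
genuinely strained rotamer states of protein-bound ligands. Tests on
these fixtures therefore exercise the machinery (cardinality,
monotonicity, restraint behavior, alignment) rather than reproduce
field strain distributions. Second, rotamer-level strain is exercised
separately and exactly, by driving butane to its eclipsed torsion and
comparing the recovered strain against an exhaustive 10-degree
torsion-scan oracle under the same force field.

The fixture pool (methane through a <= 7-rotor ibuprofen-like acid)
stays within the molecular-weight and rotor bounds typical of the
ligand sets this kind of analysis is applied to (MW < 500, < 7
rotatable bonds).

# Degenerate inputs and edge policies

* Data-only records (fields without a molblock) are legal; they pass
  through pipelines and are warned about (and left untagged) by
  structure-dependent stages.
* A record whose molecule lacks explicit hydrogens is rejected by
  force-field setup with a named-atom error, as is any element
  outside the parameter tables.
* Ring bonds cannot be torsion-driven; `setTorsion()` refuses them.
* In tag tables, an unknown set name lists the available sets; an
  invalid SMARTS names its row.
* One-to-many joins in `mergeTab()` resolve to the first table row
  (with a warning); a merged column colliding with an existing field
  overwrites it in place (with a warning).
* Multiplexing a stage not marked record-independent is an error, as
  is `workers < 1`.

# Problem sizes

The shipped test suite and acceptance script run on deliberately
small problems: pool molecules up to ~33 atoms and 4-5 rotors,
ensembles capped at 500 minimizations, 10 analyzed poses for the
monotonicity checks, 200 random registries, Pareto sets up to n =
200, and 500-record round-trip files. A full strain analysis of the
largest fixture takes on the order of 15 seconds on one CPU; the
others take a few seconds or less.

# Known limitations

* The force field has no electrostatics, no out-of-plane term beyond
  the sp2 torsion network, and generic force constants; hydrogen
  bonding and conjugation subtleties (e.g. amide planarity) are only
  roughly represented. Energies are internally consistent, not
  transferable.
* Aromatic perception trusts the input molblock's bond orders
  (Kekule or aromatic type 4).
* Symmetry correction colors atoms by element and hydrogen count
  only; stereochemistry-aware matching is not attempted.
* The torsion-driving ensemble misses ring-conformer flexibility
  (chair/boat interconversions) entirely; molecules whose strain
  lives in saturated rings will have it underestimated.
* `compilePipeline()` targets a local POSIX shell; remote execution
  is out of scope.
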
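---
title: "Hydrogen-bond energetics of 3_10- and alpha-helices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrogen-bond energetics of 3_10- and alpha-helices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixhb)
```

## The scientific problem

Backbone hydrogen bonds hold helices together, but the energy of one
H-bond inside a helix is not an observable: the donor and acceptor are
covalently wired to the rest of the chain, and any attempt to cut the bond
out changes everything around it. `helixhb` implements the analysis
toolchain for a fragment-based answer to this question on capped
oligoalanine helices, Ace-(Ala)~n~-Nme: the 3~10~-helix (backbone
H-bonds between the C=O of residue *i* and the N–H of residue *i*+3)
and, for comparison, the alpha-helix (*i* to *i*+4).

The package covers the full chain of desk-scale steps: building the helix
models, enumerating and measuring their H-bonds, combining fragment
energies with the negative-fragmentation formula, computing a
point-charge/Lennard-Jones H-bond energy, doing the matching algebra on
volumetric electron-density grids, and turning atomic charges into local
group dipoles. The quantum-chemistry engine itself is out of scope by
design: wherever a DFT result is needed it enters as data (an energy
table, a cube file, a charge table), and synthetic generators provide
algebraically exact stand-ins so every stage runs and is validated without
one.

## Helix construction: the ideal-geometry surrogate

`build_capped_polyalanine()` places atoms by internal coordinates (NeRF
chain extension) with every alanine at the same backbone dihedrals —
(&phi;, &psi;) = (−49°, −26°) for the 3~10~ preset, (−57°, −47°) for the
alpha preset — and planar trans peptide bonds (&omega; = 180°, the only
sensible default for an unstrained backbone). The caps are residues: the
acetyl group occupies index 0 and donates a C=O acceptor, the N-methyl
amide occupies index *n*+1 and donates an N–H donor. That bookkeeping is
what makes an Ace-(Ala)~n~-Nme model carry exactly *n*−1 H-bonds at
offset 3 (one to six for *n* = 2..7) and *n*−2 at offset 4.

Bond lengths and angles are fixed at standard peptide library values
(Engh–Huber-style averages: N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å,
C=O 1.231 Å, N–H 1.010 Å, &tau;(N–CA–C) 111.2°, and so on). They live in
one `geometry_params()` table so the whole geometry model can be swapped
in one place. This *ideal-geometry surrogate* replaces structures relaxed
by electronic-energy minimization with dihedrals held fixed, which are not
tabulated anywhere and cannot be regenerated without a DFT engine. The
choice has consequences discussed at the end of this vignette.

Sign conventions were the one genuinely dangerous spot in the builder:
dihedral measurement follows IUPAC (validated against an independent
structural-biology library on random point sets), the placement routine is
its exact inverse (re-measured dihedrals reproduce the targets to
10^−13^ degrees; the builder promises 10^−6^), and the side-chain torsion
offset about the N–CA axis is chosen to give L-alanine (the
CB–CA–N–C torsion of a built residue is about −122.5°, matching real
L-Ala residues in deposited structures). The &pm;180° dihedral boundary is
reported as −180° (the range is [−180°, 180°)).

## Hydrogen-bond topology and positional classes

Pairing is purely topological — (*i*, *i*+offset) over all residues
including the caps — with no distance or angle cutoff: in these
constrained helices the H-bond network is defined by the fold, not
detected from geometry. Per pair the package reports the O···H distance
and the C–O···N–H torsion (the dihedral over the four atoms C, O, N, H).

Positional classes follow the helix ends: the first and last pairs are
*terminal*, the pairs immediately inside them *adjacent*, the rest
*inner*. A two-pair model is the degenerate case: each pair is terminal
*and* adjacent to the other terminal pair, so both contribute to both
groups in the class statistics (single-pair models are terminal only).
Spread statistics are population standard deviations (n in the
denominator); with the printed reference values rounded to two decimals,
the sample/population distinction is invisible, and the choice is recorded
here rather than load-bearing.

## The negative fragmentation formula and the backend contract

The H-bond energy of a pair is extracted from four total energies:

$$E_{HB} = E_{sys} - E_{\bar A} - E_{\bar D} + E_{\bar{A} \cup \bar{D}}$$

the entire system, the system lacking the acceptor group (the carbonyl C
and O of the acceptor residue), the system lacking the donor group (the
amide N and H of the donor residue), and the system lacking both.
`make_nfa_fragments()` builds the four structures; each severed bond is
capped by a hydrogen placed along the former bond vector (C–H 1.090 Å on
carbon, N–H 1.010 Å on nitrogen), so fragments keep the parent's atom
count, all shared atoms keep bit-identical coordinates, and the two
deletions commute atom for atom. Deleting exactly the C=O / N–H atoms
(rather than whole peptide units) is the minimal-perturbation reading of
"lacking the acceptor group"; the deletion boundary is isolated in one
function and swappable if a different fragmentation convention is wanted.

Model hierarchy: `extract_model()` derives, for any pair, the single-turn
model ST (the acceptor-to-donor window with the pair residues collapsed
into Ace/Nme caps: Ace-(Ala)~2~-Nme at offset 3), the minimal-H-bond
model MH (two separated N-methylacetamide molecules carrying the acceptor
and donor peptide groups, 12 atoms each), and the extended single-turn
models ST~EC~/ST~EN~/ST~ECN~/ST~E2N~ (window grown by one residue
C-terminally, N-terminally, both, or two N-terminally). All of them
inherit their atom coordinates from the parent helix exactly; only the new
cap hydrogens are placed fresh.

Energies come from an *energy backend*: any deterministic
`evaluate(structure) -> kcal/mol` function. DFT total energies would be
one backend (imported via `load_energy_table()`, with hartree values
converted at 627.5094740631 kcal/mol per hartree); the package ships a
molecular-mechanics backend and the synthetic generator.

## The MM backend and the peptide-group pair energy

Two distinct MM quantities exist and should not be confused:

* `mm_pair_energy()` — the *definition* of the MM H-bond energy: Coulomb
  plus Lennard-Jones over the 4 × 4 cross pairs between the acceptor
  peptide group (C, O, N, H) and the donor peptide group, no intra-group
  terms, no cutoff, no 1–4 scaling (the groups are at least five bonds
  apart in every model used).
* `mm_backend()` — a total-energy function for the NFA pipeline: all
  pairs of parameterized atoms, excluding pairs inside the same peptide
  unit (the C=O of residue *i* with the N–H of residue *i*+1), whose
  separation is fixed by covalent bonding. Only backbone C, O, N and
  amide H carry parameters; aliphatic atoms and cap hydrogens are inert.
  Like a quantum-chemical total energy, its absolute value is not
  meaningful — only NFA combinations of it are. The same-unit exclusion
  is a *role* rule, not a bond-graph rule, so it is unchanged by fragment
  deletion and the spectator terms cancel exactly in the four-term
  combination.

For any pairwise-additive backend the NFA isolates exactly the
interaction between the two deleted groups — for the MH model, the direct
acceptor-C=O/donor-N–H arithmetic, which the pipeline reproduces to below
10^−10^ kcal/mol (a cross-check of the fragment machinery, the backend,
and the combination at once). The flip side is a real scientific
statement: a pairwise force field shows *no* difference between the WH,
ST and MH hierarchies and *no* cooperativity with helix length; the
spread between those models is precisely the many-body electronic effect
that makes the quantum-chemical analysis interesting.

Parameters are the published ff99SB backbone values, embedded as
constants: charges N −0.4157, H 0.2719, C 0.5973, O −0.5679 e (acetyl
carbonyl C 0.5972), Lennard-Jones r~min~/2 and &epsilon; per role with
Lorentz–Berthelot combination, and the AMBER electrostatic constant
332.0522173 kcal·Å/(mol·e²). The alternative constant 332.0636 differs by
under 0.004%, far below the comparison tolerances; the choice follows the
force-field convention the charges were fitted with.

## Density-grid algebra

`density_grid` objects carry cube-file semantics: origin and axis step
vectors in Bohr, values in atomic units, z-fastest file order. The same
four-term combination applied voxelwise (`combine_nfa_density()`) gives
the density change on H-bond formation; second differences between model
systems (`density_difference()`) expose depolarization. Grids must agree
in shape exactly and in origin/axes within 10^−8^ Bohr — cube headers are
printed to six decimals, so bitwise equality across writers would be too
strict, while anything looser would hide real mismatches.
`grid_integral()` is the plain Riemann sum (values × |det axes|);
`isosurface_voxel_stats()` counts voxels beyond &pm;iso, the numerical
proxy for the contour surfaces used to visualize density changes (typical
levels 10^−3^ a.u. for the primary change, 1.5 × 10^−4^ a.u. for second
differences). Cube reading rejects the negative-atom-count
molecular-orbital dialect explicitly, and writing is idempotent after the
first round trip (values reproduce to &le;10^−5^ relative, the 5-digit
format precision).

## Local dipoles and the ratio table

The local dipole of a backbone group is the two-point form
&mu; = &frac12;(q~first~ − q~second~)(r~first~ − r~second~), with
(first, second) = (C, O) for carbonyls and (H, N) for amides, converted
to Debye at 4.803205 D per e·Å. It depends only on the charge difference
and the bond vector, hence is translation invariant and rotates
covariantly — both asserted as tests. Charges are inputs (file or
synthetic); no wavefunction partitioning is performed.

`dipole_ratio_table()` arranges per-pair norms of several models into the
published summary layout: per-model averages and model-over-model ratio
rows. The ratio row's average cell is computed as the *mean of per-pair
ratios* by default. The alternative (ratio of the two averages) agrees at
four decimals for some cells and differs in the fourth for others; since
the published table does not state its convention, both are implemented
and the default is the one that reproduces every summary cell checked in
the tests. Values are kept unrounded internally and rounded to four
decimals only for display and comparisons.

## Synthetic data: what it emulates and what it does not

The three generators produce fixtures with the algebraic structure the
analysis assumes:

* `gen_fragment_energies()` — quadruples with
  E~sys~ = E~&#256;~ + E~D̄~ − E~&#256;&cup;D̄~ + E~designed~. Baselines are
  drawn on the binary grid of the designed value's ulp and bounded so
  every partial sum stays inside the exactly representable range; the
  four-term combination then cancels *without rounding* and the designed
  energy is recovered bit-exactly. That bound caps the baseline half-width
  at 0.5 kcal/mol — no information is lost, because the combination is
  invariant under uniform shifts, so baseline magnitude is pure
  decoration.
* `gen_synthetic_cubes()` — four density fields obeying the same
  identity around a designed density change built from Gaussian blobs
  (e.g. a positive lobe near the acceptor oxygen, a negative one near the
  donor hydrogen). All fields are quantized to multiples of 2^−55^ a.u.
  (&asymp;2.8 × 10^−17^, far below any density of interest) for the same
  bit-exactness; the returned designed field is the quantized one the
  pipeline is expected to reproduce. Blob centers outside the box warn
  rather than error.
* `gen_charge_sets()` — inverts the two-point dipole formula on the
  actual model geometry, so designed norms are recovered to floating-point
  rounding (&le;10^−10^ D demanded, &asymp;10^−16^ achieved).

All generators are deterministic under a seed, and their outputs are
written in the same formats the real pipeline reads (TSV, cube), so the
parsers are exercised too. What they deliberately do **not** emulate is
quantum-chemical *content*: no exchange-correlation physics, no
basis-set structure, no realistic density magnitudes. Passing the
synthetic suite shows the algebra, bookkeeping and I/O are right; it says
nothing about whether a particular DFT functional reproduces experiment.

## Problem sizes and runtime

Everything is desk scale by construction: the full study set is 12
helices (42 H-bond pairs), fragment sets are &le;84 atoms, and the grid
fixtures are 21³–41³ voxels. The complete test suite, including the
acceptance checks, runs in seconds; the acceptance script rebuilds both
helix series and recomputes every reported number from scratch in under a
minute. These sizes are the study's own: they match the systems the
analysis was designed around, not a downscaled stand-in for something
larger.

## Known limitations, and the surrogate's systematic offsets

The one structural approximation with visible consequences is the
ideal-geometry surrogate. A helix built from fixed internal coordinates
at exact dihedrals is perfectly screw-symmetric: all pairs of a series
have identical geometry, the per-class distance spreads collapse to zero,
and the positional effects that relaxation creates (longer H-bonds in the
pairs adjacent to the terminals, torsion scatter along the helix) cannot
appear. Quantitatively, on the reference study's own axes:

* 3~10~ O···H distance: 1.827 Å uniform, versus 2.05 &pm; 0.04 Å on
  relaxed structures (adjacent-class reference 2.08 &pm; 0.03 Å);
* alpha O···H distance: 2.105 Å versus 2.30 &pm; 0.07 Å;
* mean MM H-bond energy: −5.20 kcal/mol versus −4.95 (3~10~) and
  −5.30 versus −4.24 kcal/mol (alpha).

The direction is systematic and physically transparent: constrained
relaxation opens bond angles to relieve the tight helical contacts,
lengthening the H-bonds by roughly 0.2 Å and weakening the point-charge
energies correspondingly (the effect is strongest for the alpha series,
whose reference H-bonds are longest). The geometry constants were fixed
from standard libraries before any comparison and are deliberately left
there: tuning bond angles per helix type until published distance
statistics reappear would manufacture agreement the model does not own.
The package therefore reports the surrogate numbers as what they are, and
the acceptance checks that assume relaxed-structure geometry fail
honestly at their stated tolerances (distances beyond the &pm;0.15 Å
band by 0.05–0.10 Å; the alpha MM mean beyond &pm;0.5 kcal/mol by
0.56). Supplying relaxed coordinates through `read_pdb()` removes the
surrogate entirely: every downstream stage is geometry-agnostic.

Other limitations are scope boundaries rather than approximations: no
geometry optimization, no solvent, no residues other than alanine, no
side-chain or bifurcated H-bonds, no figure rendering, and no statistics
beyond Pearson r and least squares — each of these is either a data
import (and handled by the table/cube/charge readers) or outside what
this analysis needs.
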
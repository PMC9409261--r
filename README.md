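# helixhb

Hydrogen-bond energetics of 3₁₀- and α-helical peptides: helix model
construction, fragment-based H-bond energy decomposition, molecular-mechanics
H-bond energies, electron-density grid algebra, and local-dipole
depolarization analysis.

## What this is for

The energy of one backbone hydrogen bond inside a helix is not directly
computable: the C=O acceptor and N–H donor are covalently linked through the
chain. The negative fragmentation approach (NFA, a variant of the molecular
tailoring approach) extracts it from four total energies,

    E_HB = E_sys − E_Ā − E_D̄ + E_Ā∪D̄

where the four systems are the full structure, the structure lacking the
acceptor C=O, the structure lacking the donor N–H, and the structure lacking
both (severed bonds capped with hydrogens). The same four-term combination
applied to electron-density grids gives the density change on H-bond
formation, Δρ_HB = ρ_sys − ρ_Ā − ρ_D̄ + ρ_Ā∪D̄.

`helixhb` implements this analysis for capped oligoalanine helices,
Ace-(Ala)ₙ-Nme: 3₁₀-helices (H-bond i → i+3, φ = −49°, ψ = −26°) and
α-helices (i → i+4, φ = −57°, ψ = −47°). It is aimed at computational
chemists and structural bioinformaticians who want the desk-scale half of
such a study — model building, H-bond geometry, fragment construction,
combination algebra, MM reference energies (AMBER ff99SB peptide-group
charges and Lennard-Jones terms), cube-file handling, and Hirshfeld-charge
local dipoles μ⃗ = ½(q₁ − q₂)(r⃗₁ − r⃗₂) — with the DFT engine abstracted
behind a backend: quantum-chemical results enter as plain-text energy
tables, cube files, or charge tables, and synthetic generators provide
algebraically exact fixtures for every stage.

The package is organised as an analysis workflow: every computation lives in
the package (`R/`), and the numbered scripts under `analysis/` run the study
end to end, writing tables under `results/`.

## Worked example

```r
library(helixhb)

wh <- build_helix("310", 4)        # Ace-(Ala)4-Nme at phi = -49, psi = -26
wh
#> <peptide_structure> WH_3-10-4: 52 atoms, 6 residues (n_ala = 4)
#>   construction targets: phi = -49, psi = -26, omega = 180 deg

pairs <- classify_pair_position(detect_hbond_pairs(wh, 3))
pairs[, c("label", "acceptor_res", "donor_res", "class")]
#>   label acceptor_res donor_res    class
#> 1   4-1            0         3 terminal
#> 2   4-2            1         4 adjacent
#> 3   4-3            2         5 terminal
```

Three i → i+3 H-bonds: the Ace cap (residue 0) donates the first acceptor,
the Nme cap (residue 5) the last donor, and the middle pair 4-2 is
"adjacent" — sandwiched between the two terminal pairs. The per-pair MM
H-bond energy (peptide-group Coulomb + Lennard-Jones, 16 cross pairs):

```r
mm_hbond_energies(wh)[, c("pair", "class", "e_mm")]
#>   pair    class      e_mm
#> 1  4-1 terminal -5.197171
#> 2  4-2 adjacent -5.196481
#> 3  4-3 terminal -5.196481
```

About −5.2 kcal/mol per bond; the values are nearly identical because the
ideal-geometry helix is perfectly screw-symmetric (the tiny spread is the
acetyl-vs-alanine carbonyl charge difference). Running the NFA with the MM
backend across the whole-helix (WH), single-turn (ST), and minimal-H-bond
(MH) models:

```r
tab <- hbond_energy_pipeline(wh, c("WH", "ST", "MH"), mm_backend())
round(xtabs(e_hb ~ pair + kind, tab), 4)
#>      kind
#> pair       MH      ST      WH
#>   4-1 -1.7588 -1.7588 -1.7588
#>   4-2 -1.7588 -1.7588 -1.7592
#>   4-3 -1.7588 -1.7588 -1.7592
```

For a pairwise force field the NFA isolates the bare C=O···H–N interaction,
so all three models agree to the charge-assignment detail — the spread
between WH, ST and MH observed with quantum-chemical backends is exactly the
many-body depolarization effect such force fields cannot represent. That
effect is analysed from charge data with the dipole tools
(`local_group_dipole()`, `dipole_ratio_table()`; see
`analysis/05_dipoles.R`, which reproduces the published depolarization
ratio table from its per-pair Hirshfeld dipole norms).

## The analysis workflow

```sh
Rscript analysis/01_build_models.R        # 12 helix models -> PDB + summary
Rscript analysis/02_hbond_geometry.R      # distances/torsions, class statistics
Rscript analysis/03_mm_energies.R         # peptide-group MM energies; NFA(MM) hierarchy
Rscript analysis/04_nfa_synthetic.R       # designed-fixture validation; cube round trips
Rscript analysis/05_dipoles.R             # depolarization ratio tables
Rscript analysis/06_length_dependence.R   # energy vs helix length; comparison stats
```

Each script prints what it found and writes CSV/PDB/cube artifacts under
`results/`.

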
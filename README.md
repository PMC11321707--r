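# silafract

Fractal-cluster metrics and NMR observables for peptide/counterion
self-assemblies that template biomimetic silica formation.

Diatom-derived silaffin peptides (R5, synSil-1A1) self-assemble into
supramolecular templates when counterions (phosphate, long-chain
polyamines) bridge their charged side chains; silica then nucleates on the
template surface, coats it, and precipitates, so the template's size and
dimensionality set the morphology of the solid nanoparticles. The templates
are hierarchical — trimeric peptide building blocks aggregating into
fractal colloids — and this package quantifies exactly that picture.

## What it computes

**Fractal-cluster metrics** of coarse-grained bead assemblies, per frame or
averaged over trajectory windows:

- mass-weighted radius of gyration `Rg`; hydrodynamic radius via
  `Rh = Rg / 1.1`
- molecular volume `V_mol = kappa * Mw` (kappa = 1.21 ų/Da)
- compactness `phi = V_mol / ((4/3) pi Rg³)`
- contact valency `v`: mean number of peptide partners per monomer, from a
  chain-chain contact graph (4.5 Å surface cutoff, counterion bridges
  reported separately)
- fractal dimension `d_f = 3 / (1 - log(phi) / log(v))`, plus an
  independent mass-radius estimator (slope of log N(<r) vs log r) as an
  oracle

**NMR observables**: chemical shift perturbations
(`sqrt((wa*dA)² + (wb*dB)²)`), intensity ratios I/I0 and residual dissolved
fractions, per-residue exponential decay rates of real-time silicification
traces with robust surface/core classification (median + 3 MAD),
Stejskal-Tanner DOSY fits (`I = I0 exp(-D g² γ² δ² (Δ - δ/3) )`) and
Stokes-Einstein radii (`Rh = kB T / (6 pi eta D)`), and transverse
relaxation rates.

**Scattering**: exact Debye curves from bead coordinates
(`I(q) = Σ fi fj sin(q rij)/(q rij)`), Guinier fits, and one-level Beaucage
unified fits.

**Synthetic data with ground truth**: trimer building blocks (one bead per
residue), assemblies of controlled morphology (linear / planar / compact /
dla) with calibrated contact valency, HSQC-like peak tables, DOSY decays,
two-rate kinetic traces with a dissolved plateau, and density-matched
crowded boxes (`d = 9 m u / (4 pi Rh³)`). Everything is seeded and
bit-reproducible; a JSON manifest records the ground truth.

I/O: multi-model PDB (CRYST1 boxes, HETATM counterions, a documented
two-character chain extension beyond 26 chains), multi-frame XYZ with a CSV
topology sidecar, and typed CSV tables for peaks, DOSY series and kinetic
traces.

## Worked example

```r
library(silafract)

block <- generate_building_block(r5_block(), seed = 1)
block
#> <assembly_frame> 63 beads (57 peptide, 6 counterion), 3 peptide chains
rg_to_rh(compute_rg(block, block$chain == "A")) / 10  # monomer Rh, nm
#> [1] 0.767

asm <- aggregate_assembly(
  block, morphology_spec("compact", n_blocks = 20, target_valency = 4,
                         seed = 1))
analyze_trajectory(trajectory(asm), window = "all")
#> <fractal_metrics> window all over 1 frame(s)
#>    metric         mean sd
#>        Rg 4.019905e+01  0
#>  Mw_total 1.197162e+05  0
#>     V_mol 1.448566e+05  0
#>       phi 5.323562e-01  0
#>   valency 4.100000e+00  0
#>       d_f 2.073528e+00  0

mass_radius_dimension(asm)$estimate   # independent dimension estimate
#> [1] 2.70

ser <- synth_dosy_series(stokes_einstein_d(1.3), noise_sd = 0.01, seed = 1)
stokes_einstein_radius(fit_stejskal_tanner(ser)$D)  # nm
#> [1] 1.297
```

Reading: a compact 20-block assembly of the R5 trimer has `Rg` ≈ 40 Å with
about 4 peptide contacts per monomer; its fractal dimension is ≈ 2.1 by the
compactness-valency formula and ≈ 2.7 by direct mass-radius counting, both
on the compact side of the scale, and a simulated 1.3 nm particle's DOSY
decay fits back to 1.30 nm. Linear and planar assemblies built from the
same block land near 1 and 2 in the mass-radius estimate.

A command-line wrapper with the same capabilities ships in
`inst/cli/silafract.R`:

```sh
Rscript inst/cli/silafract.R generate --kind assembly --mode compact \
  --n_blocks 20 --seed 1 --out runs/asm
Rscript inst/cli/silafract.R analyze-assembly --traj runs/asm/assembly.pdb \
  --out runs/metrics
```

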
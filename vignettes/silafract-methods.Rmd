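---
title: "Fractal-cluster metrics and NMR observables for peptide silica templates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal-cluster metrics and NMR observables for peptide silica templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silafract)
```

## The scientific problem

Diatom-derived silaffin peptides such as R5 (the 19-mer SSKKSGSYSGSKGSKRRIL)
and its fully post-translationally modified analog synSil-1A1 self-assemble
in solution when multivalent counterions — inorganic phosphate for R5,
long-chain polyamines (LCPA) for synSil-1A1 — bridge their charged side
chains. The resulting supramolecular complexes act as templates for
biomimetic silica: silica nucleates on the template surface, coats it, and
precipitates, so the size and dimensionality of the solution-state template
predetermine the morphology of the solid nanoparticles.

The templates are built hierarchically: three peptides and their bridging
counterions form a stable trimeric building block, and the blocks assemble
further into large colloids that are structurally similar across length
scales, i.e. fractal. A fractal object is summarised by its fractal
dimension $d_f$ — around 1 for rod-like, 2 for sheet-like, 3 for compact
spherical organization.

silafract implements the quantitative toolbox for this system:

* **fractal-cluster metrics** of bead assemblies (radius of gyration,
  compactness, per-monomer contact valency, $d_f$),
* **NMR observables** that report on assembly and silicification (chemical
  shift perturbations, intensity ratios, residual dissolved fractions,
  per-residue decay rates, diffusion coefficients and hydrodynamic radii),
* **small-angle scattering** (Debye curves, Guinier and Beaucage fits) as an
  orthogonal size measure, and
* a **synthetic-data generator** that produces every input stream with known
  ground truth, so each stage of the analysis is validated by parameter
  recovery rather than by eye.

## The fractal-cluster formalism

For a cluster of total peptide mass $M_w$ (Da) with mass-weighted radius of
gyration $R_g$, the molecular volume is taken proportional to mass,

$$V_{mol} = \kappa M_w, \qquad \kappa = 1.21\ \text{\AA}^3/\text{Da},$$

the standard protein specific-volume prefactor (0.73 cm$^3$/g). The
compactness compares this volume with the gyration sphere,

$$\varphi = \frac{V_{mol}}{\tfrac{4}{3}\pi R_g^3},$$

and the fractal dimension combines compactness with the mean contact
valency $v$ (the number of distinct peptide partners per monomer):

$$d_f = \frac{3}{1 - \log\varphi / \log v}.$$

Its limits orient the scale: a maximally compact object ($\varphi = 1$) has
$d_f = 3$ regardless of valency, and looser packing ($\varphi < 1$, the
regime of extended aggregates) lowers $d_f$ toward sheet- and rod-like
values; rods have large $R_g$, hence small $\varphi$, hence small $d_f$.
For $\varphi > 1$ (denser than the gyration sphere, as for tightly packed
globules) the formula exceeds 3 and the value is reported with an
`out-of-range` flag rather than clipped; $\varphi \to v$ is a pole and is
flagged undefined, as are $v \le 1$ and $\varphi \le 0$, so batch analyses
never throw.

Contacts are geometric: two chains are in contact when any bead pair
approaches within a cutoff of their surfaces (centre distance minus the sum
of bead radii). The cutoff defaults to 4.5 Å, a conventional heavy-atom
contact criterion; it is exposed everywhere. Valency counts distinct
partners by default because the formalism speaks of contacts "per monomer";
a bead-pair-count mode (`mean_valency(g, "pairs")`) is provided for
sensitivity analysis. Counterion beads never contribute peptide–peptide
contacts; counterion bridges (one counterion touching two chains) are
reported separately.

An independent estimator guards the formula-based $d_f$: the
**mass–radius dimension**, the slope of $\log N(<r)$ against $\log r$,
where $N(<r)$ counts beads within radius $r$ of the cluster centre. The two
routes share no code and no assumptions, so their agreement in rank order
across morphologies is a meaningful cross-check.

Numerical choices for the mass–radius estimator:

* counts are centred on the bead nearest the centre of mass — for
  ring- or shell-like clusters the centre of mass can fall into a void,
  which would undercount small radii;
* the fit window runs from the smallest fractal scale to the cluster
  $R_g$. For assemblies built from rigid blocks the lower bound is
  $1.25 \times$ the block $R_g$: below the building-block scale the counts
  probe intra-block chain structure, not aggregation scaling. For plain
  bead clusters the lower bound is twice the bead radius.

With these choices the estimator recovers 1.0–1.1 for generated linear
assemblies, 2.0–2.2 for planar and 2.8–3.1 for compact ones (50 blocks;
see `test-acceptance.R`), close to the nominal dimensionalities.

## The synthetic-data generator

The generator emulates the study conditions of a peptide/counterion
silicification experiment. Its defaults are the conditions under which the
package's properties are tested; they are chosen once and documented here.

**Building blocks.** One bead per residue (radius 3.0 Å; counterion beads
2.0 Å) on a compact helix with 5 Å bonds; this coarse-graining level puts a
19-residue monomer at $R_g \approx 8.4$ Å, i.e. $R_h = R_g/1.1 \approx
0.77$ nm, matching the sub-nm scale measured for disordered peptide
monomers by diffusion NMR. Three chains are placed around a common axis so
that all pairs are in contact, and counterion beads bridge the linker
sites — for R5 the arginine pair of the C-terminal RRIL motif and the
N-terminal SKKS motif, the two phosphate traps. Placement retries until no
two beads overlap below 0.8 × the sum of their radii; infeasible linker
specifications raise a placement error after bounded retries.

**Assemblies.** `n_blocks` randomly oriented copies of the block are placed
on a connected scaffold: a line (`linear`), a hexagonal plane (`planar`),
an fcc packing (`compact`), or a random-walk attachment cluster (`dla`).
The inter-block spacing is then calibrated by bisection so the mean contact
valency matches `target_valency` (default 4: two intra-block partners plus
about two inter-block partners). Because the same target is used for every
morphology, the generated assemblies reproduce the observation that contact
numbers stay constant while dimensionality varies — in the 20-seed suite the
mode means differ by under 4%. An unreachable target degrades to a warning
plus the achieved valency.

**Peak tables.** A reference table draws amide-proton shifts around
8.3 ppm and nitrogen shifts around 119 ppm; the perturbed table adds a
chosen per-residue shift profile and attenuates intensities by the bound
fraction, with an optional boost for surface residues that stay flexible on
the assembly surface. Residual-fraction presets follow the measured values:
0.17 for R5 with 25 mM silicic acid, 0.20/0.09 for synSil-1A1 at low/high
LCPA, and 0.007/0.0001 for the assembly equilibria.

**DOSY.** Integrals follow the Stejskal–Tanner attenuation
$I(g) = I_0 \exp(-D \gamma^2 g^2 \delta^2 (\Delta - \delta/3))$ over a
128-point linear gradient ramp from 0 to 0.1 T/m with a 60 ms diffusion
delay. The gradient pulse length $\delta$ defaults to 15 ms, the value that
attenuates nm-scale species to roughly 10–30% residual signal at the 0.1 T/m
maximum — the attenuation depth a spectroscopist tunes for at setup.
Diffusion coefficients convert to hydrodynamic radii by Stokes–Einstein,
$R_h = k_B T / (6\pi\eta D)$, hard-wired to the spherical model; water
viscosity defaults to 0.8937 mPa s at 298.15 K with no D2O co-solvent
correction.

**Kinetics.** Real-time silicification is modelled per residue as a
single exponential decaying to a residual plateau,
$I_r(t) = (1-p)\,e^{-k_r t} + p$: surface residues (for R5 the RRIL motif,
residues 16–19, adjacent to the silica nucleation sites) decay with
`surface_rate`, core residues with `core_rate`. The single-exponential-plus-
plateau form is this package's generative choice; the corresponding
experiments are routinely fitted with exponentials but no generating model
is implied by the data. Defaults: 181 time points over 7 h (one spectrum
every 140 s), core rate $10^{-3}\,$s$^{-1}$, surface rate twice that,
plateau 0.17.

**Crowded boxes.** The density matched to the trimer hydrodynamic radius is
$d = 9 m u/(4\pi R_h^3)$ (three peptides of mass $m$ in a sphere of radius
$R_h$; $u$ the atomic mass unit in grams). For R5 ($m = 2013.3$ Da,
$R_h = 1.3$ nm) this evaluates to 1.09 g/mL. The function reports the
formula's value and the cubic edge holding `n_peptides` at that density;
no external density value is imposed.

**Determinism.** Every generator takes a seed; per-stream child seeds are
derived from the master seed so streams are independent, and a
`ground_truth_manifest` records everything needed to regenerate a dataset
bit-identically.

## NMR observables

Chemical shift perturbations are the weighted Euclidean distance between
peak positions, $\mathrm{CSP} = \sqrt{(w_a\Delta\delta_a)^2 +
(w_b\Delta\delta_b)^2}$ with the common conventions $w_N = 0.14$ against
$^1$H and $w_C = 0.30$, $w_N = 0.14$ for carbon–nitrogen pairs; the weights
are arguments, since conventions differ between groups. $^1$H–$^{31}$P
tables reuse the proton path with a configurable second-dimension weight
(0.14 by default; no established convention exists for phosphorus).
Residues missing from either table are flagged absent rather than treated
as zero, and intensity ratios below a configurable detection floor are
flagged `below_detection`, mirroring residues that broaden beyond detection
inside large assemblies. The residual dissolved fraction is the arithmetic
mean of the detected per-residue ratios (a median option exists).

Decay-rate fitting uses `minpack.lm` Levenberg–Marquardt least squares of
$I(t) = A e^{-kt} + B$ with a deterministic multistart around a log-linear
initial estimate; constant traces short-circuit to $k = 0$ exactly, and
non-convergence is flagged per residue rather than thrown. Surface/core
classification applies the conventional robust outlier cut: rates above
median + 3 MAD are surface, rates within ±3 MAD are core, anything else
(including failed fits) undetermined. A 1-MAD band was considered and
rejected: with tightly clustered fitted rates it mislabels the expected
~7% tail of core residues even on clean data, which no threshold should.

## Scattering

`debye_curve` evaluates the exact Debye double sum
$I(q) = \sum_{ij} f_i f_j \sin(q r_{ij})/(q r_{ij})$ (unit or mass form
factors; O($n^2$), exact — validated against a literal double loop to
$10^{-10}$). Guinier analysis fits $\ln I$ against $q^2$, iteratively
shrinking the window until $q_{max} R_g \le 1.3$ (the spherical rule;
`assembly_scattering` tightens it to 1.0, the appropriate limit for
elongated particles). When even the minimal window violates the limit the
curve has no resolvable Guinier regime and is flagged instead of fitted.

The one-level Beaucage unified fit,
$I(q) = G e^{-q^2R_g^2/3} + B\,[\mathrm{erf}(qR_g/\sqrt6)^3/q]^P$, is
solved in log space by profiling over the power-law exponent $P$ (fitting
$G, R_g, B$ at each $P$ on a fixed grid, which is far better conditioned
than the full four-parameter problem), adding a pure-Guinier candidate for
curves without a power-law regime, preferring among near-tied candidates
the one consistent with the Guinier $R_g$, and finally releasing all four
parameters. On synthetic one-level data the parameters are recovered to
better than 1%; on Debye curves of generated assemblies evaluated over the
aggregation window $qR_g \in [0.25, 3]$ the Beaucage $R_g$ agrees with the
direct $R_g$ to a few percent for all three morphologies, and the fitted
$P$ is lower for linear than for compact assemblies, as expected for mass
fractals. Beyond $qR_g \approx 3$ the curves show particle-scale
oscillations and intra-block structure that a one-level model does not
describe, which is why the analysis window stops there.

## Problem sizes and what the tests do (and do not) show

The validation suite uses 50-block assemblies (2850 peptide beads) over 20
seeds per morphology for dimension recovery, 128-point DOSY series at 1%
noise over 50 seeds, 19-residue kinetic trace sets at 1% noise over 50
seeds, and 20-block assemblies for scattering consistency; these sizes give
stable statistics while keeping a full run in minutes on one CPU.

The generator produces geometrically ideal, rigid, monodisperse assemblies
with Gaussian noise. It does not emulate conformational exchange,
polydispersity, solvent effects, force-field physics, silica chemistry, or
spectral artefacts (overlap, baseline, phasing). Passing recovery tests
therefore demonstrates that the analysis chain is correct and
well-conditioned under its stated assumptions — not that those assumptions
hold for any particular experimental system.

Known limitations: orthorhombic boxes only; periodic unwrapping assumes
clusters smaller than half the box; the Guinier/Beaucage route reports a
scattering-weighted size that differs from the mass-weighted $R_g$ for
strongly anisotropic or polydisperse particles; and $d_f$ from compactness
and valency inherits the contact-cutoff convention, so only comparisons at
a fixed cutoff are meaningful.

## Worked example

```{r example, eval = FALSE}
block <- generate_building_block(r5_block(), seed = 1)
asm <- aggregate_assembly(
  block, morphology_spec("compact", n_blocks = 20, target_valency = 4,
                         seed = 1))
analyze_trajectory(trajectory(asm), window = "all")
mass_radius_dimension(asm)$estimate

ser <- synth_dosy_series(stokes_einstein_d(1.3), noise_sd = 0.01, seed = 1)
stokes_einstein_radius(fit_stejskal_tanner(ser)$D)
```

The compact 20-block assembly above yields $\varphi \approx 0.53$, valency
$\approx 4.1$, $d_f \approx 2.1$ by the compactness–valency formula and
$\approx 2.7$ by mass–radius counting, and the DOSY round trip returns
$R_h = 1.30$ nm for a 1.3 nm particle; the same numbers are printed by the
README example and recomputed by `scripts/acceptance.R`.
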
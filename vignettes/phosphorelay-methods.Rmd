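---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models and procedures, the tunable parameters with their defaults and
rationale, what the synthetic generators emulate (and do not), and the
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Scientific setting

Hybrid histidine kinases (HHKs) carry a C-terminal receiver (Rec) domain
and perform an *intramolecular* His-to-Asp phosphotransfer between their
DHp four-helix bundle and that Rec domain, the first step of a
His-Asp-His-Asp phosphorelay. The package provides the computational
stages needed to analyse such systems: rigid-body structural comparison,
template-based modeling of the phosphotransfer-competent DHp/Rec
arrangement, interface and crystal-lattice analysis, family-level sequence
conservation and covariation, and backbone-NMR chemical-shift analytics.
Every stage runs on seeded synthetic fixtures; deposited structures and
shift tables can be supplied locally through the same public functions
(the package never downloads).

## Structure handling

Structures are plain data frames of atom records plus cell/symmetry
metadata (`Structure`). Author residue numbering is canonical throughout,
because all residue identities of interest (active His and Asp, interface
residues) are conventionally quoted in author numbering. Hydrogens are
excluded from all counts and geometry by default; deposited
crystallographic models are heavy-atom.

*Alternate locations.* All altloc copies are retained on read. Selections
resolve to one conformer per atom site, by default the highest-occupancy
conformer with ties going to label `A` — downstream geometry needs a
single conformer. `summarize_structure()` counts every deposited record
once (so altloc duplicates each count) and reports the deduplicated site
count alongside, making both counting conventions available.

*Symmetry.* Operators are taken from the file when present (`REMARK 290`
or mmCIF equivalent positions); otherwise a bundled operator table covers
common settings, including the monoclinic body-centred setting `I 1 2 1`.
`expand_symmetry()` enumerates operator-plus-lattice copies with any atom
within a contact radius; the identity copy is excluded.

## Superposition

`kabsch_fit()` is the closed-form SVD solution for the least-squares
proper rotation; degenerate (collinear) inputs are rejected. Tests verify
optimality against a dense random-rotation oracle, exact inversion of
known transforms, RMSD symmetry, and invariance under pre-rotation, all
at 1e-9.

`iterative_superpose()` repeats fit-then-prune, dropping residue pairs
whose post-fit CA-CA distance exceeds `max(cutoff_factor * rmsd,
abs_cutoff)`. Published RMSD-over-N-positions figures for Rec-domain
comparisons come from tools whose pruning rules are not stated, so the
defaults (`cutoff_factor = 2.0`, `abs_cutoff = 3.5` A, `max_iter = 10`)
are this package's declared convention, chosen to approximate typical
retained counts, and are exposed as arguments.

Residue pairing is either positional (`ranges` mode) or by global
end-gap-free sequence alignment (BLOSUM62, gap open 10 / extend 0.5),
delegated to `Biostrings::pairwiseAlignment`. No structure-alignment
discovery is attempted: anchor helices are always named by the user.

## Template grafting

`graft_complex()` implements three steps: (1) fit the kinase domain's
anchor CA atoms (the interface halves of the DHp helices) onto the
template's corresponding chain; (2) fit the Rec domain via its alpha-1
helix onto the template's Rec partner; (3) reassemble the transformed
copies into one structure. No side-chain adjustment of any kind is made;
the model is a rigid placement whose quality is then *measured*, not
optimized:

* `count_interdomain_clashes()` — default criterion: main-chain + CB
  heavy atoms closer than 3.0 A. The literature statement being emulated
  is qualitative ("no clashes"), so the numeric cutoff is a declared
  default, and near-misses (3.0-3.5 A) are listed separately so the
  sensitivity of the call is visible.
* `measure_transfer_geometry()` — printed His-Asp transfer distances do
  not name atoms; the default convention is His NE2 to Asp CG, with the
  minimum over the carboxylate oxygens reported alongside. Both numbers
  are always available so either reading can be compared.
* Anchor extents are user configuration. The shipped worked configuration
  (`inst/extdata/cckA_graft_config.json`) records the implementer's
  reading of the helix extents for the CckA/ChpT case and says so in the
  file itself.

## Interfaces and solvent accessibility

SASA is Shrake-Rupley sphere-point sampling with probe 1.4 A and 960
points per atom by default (92 minimum); van der Waals radii come from a
bundled element table with a warned fallback. 960 points puts the
isolated-sphere error well under 1% and doubling the count moves totals
by under 0.5% on the test fixtures.

Buried interface area uses the declared convention `(SASA_A + SASA_B -
SASA_AB) / 2`; because published "interface area" numbers may follow
either the averaged or the per-side definition, the per-side burials are
reported in the same object. Crystal-contact scanning composes symmetry
expansion with this area computation and sorts mates by buried area.

Residue contacts are minimum heavy-atom distances including side chains
(a CB-only view can be had through selections); the two-threshold 6/8 A
convention matches how covariation hits are usually read against a
structural model. Salt bridges are Asp/Glu side-chain O to Arg/Lys
side-chain N within 4.0 A (His optional, off by default, since the
charge-reversal analyses of interest involve R/E-class residues).

## Conservation and differential conservation

Column profiles are weighted (position-independent redundancy weights at
0.8 identity) and pseudocounted (0.5 total mass, uniform background —
the logo pipelines being emulated do not state their normalization, so
the simplest convention is declared). Information content is
`(log2 20 - H) * (1 - gap fraction)` bits. Columns map to residue numbers
through a named reference row plus offset, so outputs use the numbering
of the protein under study.

A column is "conserved" in a family when its top frequency reaches
`t_cons = 0.7` — a declared surrogate for the unstated shading criterion
of published two-family logo comparisons. Gap fraction above 0.5 excludes
a column (variable linkers should not generate calls). Conserved in both
families with the same consensus is `shared`; conserved in one (or in
both with different consensus) is family-specific.

Motif scanning (`FxSGY`-type patterns, classes in brackets) runs on the
consensus of the ungapped reference columns and reports per-sequence
support, so a motif call carries its own evidence level.

## Covariation

The in-package scorer is mutual information with average-product
correction, z-standardized over retained pairs. This is a deliberate,
documented stand-in for pseudolikelihood direct-coupling analysis: MI-APC
is transparent, dependency-free, exactly testable against a
direct-summation oracle (the suite requires 1e-10 agreement), and
adequate for the planted-coupling recovery this package's analyses need.
The published "score above 3.0" threshold is interpreted as z > 3.0 —
the original score scale is not recoverable — and
`read_coupling_table()` accepts an externally computed coupling table so
the distance-agreement analysis can be run verbatim on scores from a
heavier engine.

Gap handling is pairwise-complete (rows gapped at either column are
dropped for that pair), which keeps joint and marginal frequencies
consistent. The agreement report classifies peaks as red (< 6 A), black
(< 8 A) or miss against model distances and reports precision per class;
charge-reversal statistics classify the joint table into (+,-) / (-,+)
fractions with `balance = min/max`, so a balanced reversible ion pair
scores near 1.

## NMR shift analytics

The amide perturbation is `sqrt(dH^2 + (dN/5)^2)`; the 1/5 nitrogen
scaling is fixed by the formula, and the two significance tiers default
to 0.2 and 0.4 ppm (figure-legend convention; configurable). Combined
secondary shifts are `(dCA - dCA_rc) - (dCB - dCB_rc)` against a bundled
random-coil table (plain CSV; the test suite uses synthetic tables so no
literature value is load-bearing). Glycine contributes only its CA term
and is flagged.

The 1-2-1 smoother uses weights (1, 2, 1)/4 in the interior; at ends and
next to gaps the weights are renormalized over available neighbours (an
edge point becomes `(2x_i + x_nb)/3`), and values are never mixed across
a gap or a numbering break. The end rule is not stated in the emulated
methods text; this one is fixed and tested.

Propensity calls on the smoothed series — runs of at least 4 residues at
or above +0.7 ppm are helix, at least 3 at or below -0.7 ppm are strand —
are declared surrogates for a by-eye classification; they are what the
synthetic recovery tests exercise. HetNOE values below 0.65 flag ps-ns
mobility. Line widths come from a least-squares Gaussian fit with
moment-based starts; FWHM = 2 sqrt(2 ln 2) sigma.

## Synthetic generators: what they emulate

Each generator draws from a stream derived from `(seed, generator name)`,
so outputs are bit-reproducible and adding generators does not shift
existing fixtures; the caller's RNG state is untouched.

* `make_helix_domain()` builds ideal helices from internal coordinates
  (phi -57, psi -47), giving 1.5 A rise / 100 degree twist — enough
  realism for superposition, clash and SASA geometry.
* `make_graft_scenario()` states a world of two rigid helical domains in
  van der Waals contact (axis separation 9.5 A), donors scrambled by
  recorded random transforms, optional isotropic coordinate noise. It
  does **not** emulate conformational change, so a green graft test
  establishes correct rigid recovery, not biological validity of a
  modeled complex.
* `simulate_msa()` samples rows independently: default column profiles
  concentrate 60% on one residue (a moderately conserved family core);
  planted pairs are drawn jointly (e.g. 50/50 R/E vs E/R, the
  charge-reversed ion-pair signature) with a coupling strength (0.9 in
  the acceptance scenario) mixing joint and independent draws; motif
  rows carry the full pattern with the stated fidelity. Phylogenetic
  correlation between rows is deliberately absent — identity weighting
  is tested separately on constructed duplicates.
* `simulate_shift_pair()` builds random-coil tables plus helical-segment
  offsets (+2.1/-0.9 ppm CA/CB, i.e. combined +3, a typical well-formed
  helix) with 0.3 ppm carbon noise, and plants an amide perturbation
  cluster (0.45/1.0 ppm H/N over five residues, clearing the strong
  tier) with amide noise one tenth of the carbon noise. It does not
  emulate exchange broadening or missing assignments beyond explicit
  gaps.

## Numerical choices and degenerate inputs

Kabsch rejects < 3 or collinear points; pruning refuses to drop below 3
pairs and names the iteration. SASA requires >= 92 sphere points.
Covariation refuses effective sequence numbers below 20. Empty
selections from residue ranges warn rather than error (they are a
legitimate query). Ties in altloc occupancy go to label `A`;
tie-breaking in consensus calls is alphabetical through the fixed
amino-acid order.

## Known limitations

* MI-APC is not a substitute for pseudolikelihood DCA on real families
  with strong phylogenetic structure; import externally computed scores
  for serious coupling work.
* The bundled space-group table covers common settings only; files with
  explicit symmetry records are preferred.
* Secondary-structure propensity thresholds are calibrated on the
  synthetic world, not on a shift database.
* Coordinate-derived regression numbers against deposited structures
  (atom counts, lattice interface bounds, published RMSD/retained-count
  and His-Asp distances) require locally supplied structure files; the
  suite does not assert them because the test environment performs no
  downloads. The public functions plus the shipped grafting
  configuration are the supported route to reproduce them.
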
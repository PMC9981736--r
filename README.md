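# phosphorelay

Structural and sequence analytics for histidine-kinase phosphorelays.

Hybrid histidine kinases (HHKs) carry a C-terminal receiver (Rec) domain
and transfer a phosphoryl group intramolecularly from the histidine of
their DHp four-helix bundle to a conserved aspartate on that Rec domain
(His → Asp, the first hop of a His-Asp-His-Asp phosphorelay). Assessing
whether a proposed DHp/Rec arrangement is phosphotransfer-competent, and
whether sequence evolution supports it, takes several kinds of analysis
that this package implements as one tested toolkit for structural
bioinformaticians and NMR spectroscopists:

* **Structure I/O and symmetry** — PDB/mmCIF reading/writing, atom
  selections (CA, main-chain + Cβ, side chain), altloc resolution,
  crystallographic symmetry expansion, atom-count/B-factor summaries.
* **Superposition** — Kabsch least-squares fitting
  (`argmin_{R,t} Σ‖R x_i + t − y_i‖²` via SVD), residue matching by
  sequence alignment or ranges, iterative outlier-pruned RMSD.
* **Template grafting** — build a DHp/Rec complex by anchoring each
  domain onto its counterpart in a template phosphotransfer complex
  (interface helices as anchors, no side-chain adjustment), then measure
  His–Asp transfer distance and main-chain + Cβ clashes.
* **Interfaces** — Shrake–Rupley SASA, buried area
  `(SASA_A + SASA_B − SASA_AB)/2`, crystal-contact scans, salt bridges,
  residue contact maps at 6/8 Å.
* **Alignment profiling** — information content
  `IC = (log₂20 − H)·(1 − gap)`, two-family differential conservation,
  FxSGY ("FATGUY") motif scanning.
* **Covariation** — mutual information with average-product correction
  `MIc(i,j) = MI(i,j) − MĪ(i)MĪ(j)/MĪ`, z-standardized, with pair
  substitution tables, charge-reversal balance, and
  covariation-vs-distance precision against a structural model.
* **NMR shifts** — amide CSP `ΔΔ(HN) = √(Δδ_H² + (Δδ_N/5)²)` with
  0.2/0.4 ppm tiers, secondary shifts `Δδ_Cα − Δδ_Cβ` vs random coil
  with 1-2-1 smoothing, HetNOE mobility flags, Gaussian line-width
  (FWHM = 2√(2 ln 2)·σ) fitting.
* **Synthetic data** — seeded generators for every stage (ideal helices,
  graft scenarios with known transforms, alignments with planted
  couplings/motifs, shift-table pairs with planted perturbations), so
  the whole pipeline is testable offline.

## Worked example

Build a synthetic grafting scenario, rebuild the complex from scrambled
domains, and check its steric and covariation support:

```r
library(phosphorelay)

sc <- make_graft_scenario(seed = 1)          # two helix domains in contact
m  <- graft_complex(sc$template, list(
  list(structure = sc$donors$A, anchor = sc$anchors$A),
  list(structure = sc$donors$B, anchor = sc$anchors$B)))
m
#> CompositeModel from template 'template': 2 components
#>   chain A <- donorA (anchor 'helix A', rmsd 0.000 A)
#>   chain B <- donorB (anchor 'helix B', rmsd 0.000 A)

count_interdomain_clashes(m, "A", "B")
#> ClashReport (mainchain+CB, cutoff 3.0 A): 0 clashes, 0 near-misses

interface_area(m$assembly, "A", "B", n_points = 480)
#> InterfaceReport: buried area 118.7 A^2 (per side 119.0 / 118.4)
```

The anchor rmsd of 0 says each scrambled donor was placed back exactly;
0 clashes at the 3.0 Å main-chain + Cβ criterion means the rebuilt
arrangement is sterically plausible; ~119 Å² is the buried area of the
two-helix contact.

Covariation and CSP on planted synthetic truths:

```r
aln <- simulate_msa(seed = 1, couplings = list(
  list(i = 5, j = 40, states = list(c("R", "E"), c("E", "R")),
       probs = c(0.5, 0.5), strength = 0.9)))
head(top_couplings(covariation_scores(aln, weights = rep(1, 500))), 1)
#>   col_i col_j number_i number_j       mi        z
#> 1     5    40        5       40 1.450222 36.27602

sp <- simulate_shift_pair(seed = 1)          # 5-residue perturbation cluster
table(csp(sp$ref, sp$mod)$class)
#>   none medium strong
#>    115      0      5
```

The planted R/E ↔ E/R pair (columns 5/40) dominates the coupling map at
z ≈ 36, and exactly the five perturbed residues are classed `strong`
(ΔΔ ≥ 0.4 ppm).

To run the same machinery on deposited structures, supply local files:
`inst/extdata/cckA_graft_config.json` is a worked configuration grafting
a hybrid kinase's DHp and Rec domains onto a ChpT/CtrA-Rec template via
`run_pipeline()`.

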
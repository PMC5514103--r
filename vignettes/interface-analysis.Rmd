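---
title: "Quantifying antibody-antigen interfaces: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying antibody-antigen interfaces: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package computes

Checkpoint-blockade antibodies such as atezolizumab and durvalumab work by
occluding the receptor-binding face of PD-L1. Given crystal structures of
antigen-antibody (or receptor-ligand) complexes, `abitope` quantifies that
mechanism: how much surface each partner buries, which atomic contacts hold
the interface together, which antigen residues constitute each epitope and
how epitopes overlap with the receptor-binding site, how much the Fab
constant module swings about its elbow between crystallographically
independent copies, why a homologous antigen (PD-L2) is not recognized, and
whether known N-glycosylation sites fall near an epitope.

All quantities derive from heavy-atom coordinates alone. The structures
this kind of analysis targets are typically determined at 2.5-3.5 A, where
hydrogen positions are not observed; every criterion in the package is
therefore deliberately hydrogen-free.

## Solvent-accessible surface area

The SASA engine is a Shrake-Rupley sampler: atom `i` with van der Waals
radius `r_i` is expanded by the probe radius (default 1.4 A, a water
molecule), `n` test points are placed on the expanded sphere, and the
accessible fraction is the fraction of points not inside any neighboring
expanded sphere. The per-atom area is `(accessible / n) * 4 pi (r_i +
probe)^2`. Neighbor lookup uses a cell-list spatial binning, verified in
the test suite against an all-pairs oracle.

Three numerical choices matter:

* **Point set.** Points come from a deterministic golden-angle spiral
  lattice (no random numbers anywhere), so results are exactly
  reproducible and carry no seed. The default is `n_points = 960`.
* **Lattice orientation.** Each atom's lattice is re-oriented so that its
  pole points at the nearest neighboring atom. The dominant occlusion
  boundary then runs along the lattice's equal-area stratification, where
  the cap-area estimate is most accurate. The verification battery
  measures the effect: the worst two-sphere error against the exact
  spherical-cap solution drops from about 0.7% (fixed lattice, worst
  orientation) to under 0.1%, and whole-model SASA becomes insensitive to
  rigid motions to better than 0.1%. The orientation rule is a pure
  function of the configuration, so determinism is preserved.
* **Radii.** Publications rarely state the radii their interface numbers
  assume. The package pins one explicit Chothia-style table
  (`inst/extdata/vdw_radii.tsv`: trigonal/aromatic C 1.76, tetrahedral C
  1.87, N 1.65, O 1.40, S 1.85 A, element fallbacks for anything else)
  and records the table name in every result, making comparisons
  reproducible and their tolerance explicit. Alternative tables can be
  supplied as TSV config files.

Waters and HETATM ligands are excluded from SASA and buried-area
computations unless selected explicitly; published protein-protein burial
figures follow that convention.

An exact two-intersecting-spheres solution
(`analytic_two_sphere_sasa()`) ships as an independent oracle: for center
distance `d` and expanded radii `R1, R2`, the buried cap on sphere 1 has
height `h1 = R1 - (d^2 + R1^2 - R2^2) / 2d`, removing area `2 pi R1 h1`.
Containment and separation limits are handled exactly; the equal-sphere
coincidence limit tends to half the isolated area per sphere.

## Buried surface area and interface residues

Buried area is the SASA lost on complexation, summed over both partners:

    BSA = SASA(A alone) + SASA(B alone) - SASA(A+B)

so a receptor-ligand interface that buries ~1000 A^2 per side reports
~2000 A^2 — the convention in which published interface sizes for these
complexes (1,624-2,106 A^2) are quoted. Per-chain contributions divide
one side's buried area among its chains (heavy vs light, for a Fab), and
per-residue SASA losses define the interface membership:

a residue is an interface residue when its SASA loss exceeds
`dsasa_min` (default 0.1 A^2) **or** it has any cross-side heavy-atom
pair within the vdW cutoff. The union rule keeps contact-making residues
whose burial happens to be negligible.

## Contact typing

Contacts are typed by distance on heavy atoms, using residue-specific
donor/acceptor and charged-group tables:

| category | rule | default cutoff |
|---|---|---|
| salt bridge | Arg NE/NH1/NH2, Lys NZ, His ND1/NE2 vs Asp OD1/OD2, Glu OE1/OE2, OXT | 4.0 A |
| hydrogen bond | donor-acceptor N/O/S pair (backbone N donates, backbone O accepts) | 3.5 A |
| van der Waals | any remaining cross-side heavy-atom pair | 4.0 A |
| water bridge | water O within cutoff of >= 1 polar atom on each side | 3.5 A |

Precedence is salt bridge > hydrogen bond > vdW, so each atom pair lands
in exactly one category; two or more charged pairs between one residue
pair constitute a bidentate salt bridge. A donor-angle proxy is
deliberately absent by default: without hydrogens any angle term would be
a modeling assumption, and the cutoffs above are configurable,
surfaced in every report, and acknowledged as the main source of
disagreement when reproducing published contact counts. Aromatic
stacking and alkyl-pi interactions are not classified separately; they
fall under vdW and are described, not modeled.

## Epitopes, regions and cross-complex comparison

Epitopes are the antigen-side interface residues, labelled by region from
a config map of strand/loop ranges (the packaged map covers the IgSF
V-set domain of human PD-L1, aa 18-134, with boundaries that are an
editorial choice — depositions print none). Complexes of the same
antigen are compared by author numbering, so no alignment is needed
within one antigen; `epitope_overlap()` reports intersections, unions and
Jaccard indices, erroring when sets disagree on residue identity at a
shared position (a sign they come from different antigens).

`superpose_on_antigen()` places complexes in a common frame by a Kabsch
fit of antigen CA atoms over the residue numbers common to all inputs.
The Kabsch implementation enforces a proper rotation (reflection
corrected via the determinant sign) and rejects collinear point sets.
`loop_deviation()` superposes two antigens on everything *except* the
region of interest, then reports per-residue CA displacement over that
region — isolating genuine loop plasticity from rigid-body differences.

## Fab elbow swing

Crystallographically independent Fab copies differ mainly by rotation of
the constant module about the V-C elbow. The package quantifies this as:
superpose copy pairs on variable-region CA atoms, Kabsch-fit the constant
regions, and report the rotation angle of the residual transform,
maximized over pairs. Published descriptions of elbow flexibility rarely
formalize the measure; this residual-rotation definition is one
reasonable choice, recovers constructed hinge rotations to numerical
precision (the battery measures < 1e-10 degrees of error over 0-90
degrees), is symmetric in the pair order, and is invariant to global
rigid motions of any copy. Only the magnitude is reported; V/C residue
ranges are config, not detected.

## Homolog cross-reactivity and glycosylation

Why does an antibody bind PD-L1 but not PD-L2? The package's answer
mirrors the structural argument: superpose the homolog onto the complexed
antigen and ask whether any homolog side chain collides with the
antibody.

* `structural_alignment()` pairs homolog residues iteratively: seed from
  a Needleman-Wunsch sequence alignment (linear gaps, deterministic
  diagonal-then-up tie-breaking, verified against exhaustive enumeration),
  then alternate a Kabsch fit on current CA pairs with re-pairing of
  mutually nearest CA atoms within 3.5 A, keeping only
  sequence-order-preserving pairs (longest increasing subsequence), until
  stable (at most 20 rounds). Order preservation prevents
  topology-violating pairings on beta-sandwich folds.
* `graft_clash_scan()` carries the homolog's own side-chain coordinates
  through the superposition — no rotamer rebuilding, matching how such
  overlays are actually inspected — and reports heavy-atom pairs with
  vdW overlap `r_i + r_j - d` above 0.4 A (configurable). A self-graft
  (identical residue) is the control and must report zero clashes.
* `find_sequons()` scans N-X-[S/T] (X != P) motifs with overlapping
  matches, reporting author numbering via an offset;
  `glyco_epitope_distance()` measures each glycosylated Asn side chain's
  minimum heavy-atom distance to the epitope and flags sites beyond 10 A
  (or absent from the crystallized construct) as independent of antibody
  binding.

## The synthetic fixture generator

Every stage is testable without downloading coordinates, via generators
whose ground truth is known by construction:

* `make_sphere_cluster()` — uniform pseudo-atoms with an exact all-pairs
  distance list (neighbor-search oracle; single atoms give the
  closed-form isolated-sphere SASA).
* `make_toy_complex()` — two chains built from idealized residue
  templates (real atom names: SER OG, ARG NH1/NH2, LYS NZ, ASP OD1 ...)
  so the typing tables are exercised. Each planted contact is realized
  at its target distance and the construction is *audited*: if any
  unintended cross-chain pair enters the widest detection cutoff, the
  generator errors instead of returning a fixture with silent extra
  contacts. Geometrically unsatisfiable requests (distances below 2 A,
  bidentate salt bridges closer than flanking-atom geometry permits) are
  rejected.
* `make_hinged_fab()` — two-domain CA traces with a constant-domain
  rotation of known magnitude about the junction.
* `make_homolog_pair()` — an antigen/partner complex plus a homolog with
  a Trp substitution whose ring tip is placed at exactly the requested
  vdW overlap with the nearest partner atom.

Generators are deterministic per seed (byte-identical PDB output), use a
private RNG stream that leaves the caller's `.Random.seed` untouched, and
round-trip through the PDB writer. They are geometric test instruments,
not physically realistic folds: no backbone stereochemistry, no
crystallographic noise, no alternate conformations, no realistic water
networks. Passing the battery therefore demonstrates the *correctness of
the geometry and typing machinery*, not robustness to real-world model
error; on deposited structures the main sensitivity is the choice of
radii and cutoffs, which is why both are pinned config with recorded
provenance.

## Degenerate inputs and tie-breaks

* Alternate locations: the highest-occupancy conformer is kept, ties
  broken by altloc letter order; resolution never changes residue counts.
* Multi-model files: first model by default, selectable.
* Kabsch: fewer than 3 pairs, or collinear points, error out.
* Contained spheres: the inner sphere reports zero area.
* Needleman-Wunsch traceback prefers diagonal, then the gap consuming the
  first sequence — one deterministic optimum among ties.
* Structural pairing that collapses below 3 pairs raises a convergence
  error rather than returning a meaningless transform.

## Problem sizes and verification battery

The test suite and the acceptance script run entirely on synthetic
fixtures at desk scale, chosen to exercise every code path while keeping
a full run in tens of seconds: 500-atom clusters for neighbor-search
equivalence (20 seeds), 50 seeded toy complexes for exact
planted-inventory recovery, 200 random sequence pairs up to length 7 for
alignment optimality, hinge angles across 0-90 degrees, and graft
controls at +1.0/-1.0 A planted overlap. The battery writes its measured
quantities (errors, rates, counts) as JSON via `scripts/acceptance.R`.

Reproducing published interface statistics for the deposited complexes
(PD-L1/atezolizumab 5X8L, PD-L1/durvalumab 5X8M, PD-1/PD-L1 4ZQK,
PD-1/PD-L2 3BOV) additionally requires those coordinate files in the
local structure cache (`options(abitope.cache = ...)`); the package never
fetches from the network, and the corresponding acceptance checks fail
with an explicit message until the cache is populated. For 5X8L, whose
asymmetric unit holds five copies of the complex, per-copy values are
computed and the spread reported alongside the copy closest to the
published figure, since publications do not state which copy (or average)
their single quoted numbers describe.

## Known limitations

* Chain role inference for arbitrary depositions
  (`infer_fab_complexes()`) is a size-and-contact heuristic; the
  heavy/light call labels the larger contact contributor as heavy and
  should be checked against the deposition when chain identity matters.
* Contact counts are cutoff-sensitive; published inventories whose
  criteria are unstated may differ by one or two hydrogen bonds at the
  default 3.5 A.
* No symmetry-mate generation: analyses see the asymmetric unit as
  deposited.
* No pi-stacking classifier, no hydrogen placement, no Lee-Richards or
  analytic multi-sphere SASA (the two-sphere closed form is an oracle,
  not an engine).
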
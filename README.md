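# abitope

Structural analysis of antigen–antibody and receptor–ligand interfaces
from PDB/mmCIF coordinate files, written for structural immunologists who
want the numbers behind a complex structure — how much surface an antibody
buries on its antigen, which contacts hold the interface, what the epitope
is and how it overlaps a receptor-binding site, how flexible the Fab elbow
is, and why a close homolog of the antigen escapes recognition. The
motivating system is PD-L1 bound by the therapeutic checkpoint-blockade
antibodies (atezolizumab, durvalumab) versus its receptor PD-1 and its
paralog PD-L2, but every operation is generic.

## What it computes

**Solvent-accessible surface area** (Shrake–Rupley): for atom *i* with
van der Waals radius *r<sub>i</sub>* and probe radius *p* (1.4 Å),

    SASA_i = (accessible points / n) · 4π (r_i + p)²

using a deterministic golden-angle spiral lattice (default *n* = 960, no
RNG) re-oriented per atom toward its nearest neighbor, which keeps the
discretization error of buried caps below ~0.1 %. Radii come from a
pinned Chothia-style table recorded in every result.

**Buried surface area**, in the convention of the structural literature
(total over both partners):

    BSA = SASA(A) + SASA(B) − SASA(A∪B)

with per-chain contributions (heavy vs light) and interface residues
defined by ΔSASA > 0.1 Å² ∪ {any cross-side heavy-atom pair ≤ 4 Å}.

**Typed contacts** on heavy atoms (no hydrogens are assumed at typical
resolutions): salt bridges (charged N···O ≤ 4 Å, bidentate when a residue
pair forms ≥ 2), hydrogen bonds (donor–acceptor ≤ 3.5 Å), van der Waals
contacts (≤ 4 Å, everything untyped), and water-mediated bridges (water O
≤ 3.5 Å from polar atoms of both sides). Precedence salt bridge >
hydrogen bond > vdW; each atom pair is reported once.

**Epitope comparison**: Kabsch superposition onto a common antigen frame,
region labelling from a strand/loop map (an IgSF V-set map for PD-L1 ships
with the package), set algebra and Jaccard overlap across binders,
core-superposed loop deviations, Fab elbow swing as the residual rotation
of the constant module after a variable-module fit, and antigen copy
counts per asymmetric unit.

**Cross-reactivity and glycosylation**: iterative structure-based residue
pairing of antigen homologs (Needleman–Wunsch seeded, mutually-nearest CA
re-pairing, sequence-order preserving), steric-clash scanning of a homolog
side chain grafted into the antibody complex (overlap
*r<sub>i</sub>* + *r<sub>j</sub>* − *d* > 0.4 Å), N-X-[S/T] sequon
scanning, and glyco-site-to-epitope distances.

A synthetic fixture generator (`make_sphere_cluster`, `make_toy_complex`,
`make_hinged_fab`, `make_homolog_pair`) plants geometry with analytically
known ground truth so the whole pipeline is verifiable offline.

## Worked example

```r
library(abitope)

tc <- make_toy_complex(seed = 1)     # planted: 1 H-bond, bidentate salt
print(tc$model)                      # bridge, 1 vdW contact, 1 water bridge
#> structure_model 'toy_complex_seed1': 53 atoms, 9 residues, 3 chains
#>   roles: A=antigen B=heavy W=water

ct <- contact_table(tc$model, list(role = "antigen"), list(role = "heavy"))
ct$table
#>    residue_a  residue_b   atoms distance_A      category water_id
#> 1 antigen_R2 heavy_E102 NH1-OE1        3.5   salt_bridge
#> 2 antigen_R2 heavy_E102 NH2-OE2        3.5   salt_bridge
#> 3 antigen_S1 heavy_S101   OG-OG        2.9 hydrogen_bond
#> 4 antigen_A3 heavy_A103   CB-CB        3.8           vdw
#> 5 antigen_S4 heavy_G104    OG-O        2.9  water_bridge   W|501|

buried_area(tc$model, list(role = "antigen"), list(role = "heavy"))
#> interface_summary: BSA 171 A^2 (3 + 3 interface residues)
```

The contact inventory recovers exactly what the generator planted: a
bidentate Arg–Glu salt bridge (two charged pairs at 3.5 Å between one
residue pair), a Ser–Ser hydrogen bond at 2.9 Å, an apolar CB–CB contact
at 3.8 Å typed as van der Waals, and one crystallographic water bridging
a Ser hydroxyl to a backbone carbonyl across the interface. The 171 Å²
buried area is the total SASA loss over both chains at these four
contact points.

For a deposited complex the same calls apply after role assignment, e.g.

```r
m <- read_structure("pdl1_fab.pdb",
                    role_spec = c(A = "antigen", H = "heavy", L = "light"))
m <- assign_radii(m)
buried_area(m, list(role = "antigen"), list(role = c("heavy", "light")))
epitope_set(m, "my_antibody")        # region-labelled epitope residues
```

and `run_interface_report()` / the `inst/scripts/abitope` CLI drive the
full pipeline (interface summaries, contact TSVs, epitope overlap,
elbow tables, cross-reactivity and glyco sections) from a YAML config.

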
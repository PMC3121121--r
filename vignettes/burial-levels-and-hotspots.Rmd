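---
title: "Burial levels, deeply buried atomic contacts, and hot-spot prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burial levels, deeply buried atomic contacts, and hot-spot prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Alanine-scanning mutagenesis identifies *hot-spot* residues: interfacial
residues whose substitution by alanine raises the binding free energy of a
protein-protein complex by at least 2.0 kcal/mol. Hot spots are usually
buried, so solvent accessible surface area (SASA) is a popular predictor —
but SASA cannot distinguish a *slightly* buried residue (usually not a hot
spot) from a *deeply* buried one (very often a hot spot). This package
implements a graph descriptor, the **burial level**, that captures depth
rather than mere inaccessibility, and an SVM classifier built on counts of
deeply buried interfacial atomic contacts.

## The model

**Atomic contact graph.** Heavy atoms of the complex are nodes. Two atoms
are in contact when (i) their Voronoi cells share a facet — equivalently
they are joined by an edge of the 3D Delaunay tessellation — and (ii) their
distance is strictly below $r_i + r_j + 2.75$ Å, the sum of the van der
Waals radii plus the diameter of a water molecule. The Voronoi condition
removes "through-space" pairs that are geometrically blocked by intervening
atoms; without it the graph would be a trivial discretisation of Euclidean
distance. Crystallographic waters that are themselves buried are retained
as ordinary nodes: they are immobilised parts of the complex and deepen the
burial of the atoms they shelter.

**Burial level.** An atom is *exposed* when its SASA is at least
10.0 Å² (boundary inclusive), otherwise *buried*. The burial level of an
atom is the length of the shortest path in the contact graph from the atom
to its nearest exposed atom. Operationally a pseudo node representing bulk
solvent is connected to exactly the exposed atoms and unit-weight shortest
paths are taken from it, minus one; with unit weights breadth-first search
and Dijkstra coincide, and the two formulations (pseudo-node vs minimum
over exposed sources) agree on every graph, which the test suite checks.
Exposed atoms have level 0, their buried neighbours level 1, and adjacent
atoms can differ by at most one level. A residue's burial level is the mean
over its heavy atoms; a contact's burial level is the smaller of its two
endpoint levels.

**Features and classifier.** When a residue is mutated to alanine, the
atoms beyond the alanine remainder {N, CA, C, O, CB, OXT} disappear; the
interfacial contacts they formed are *directly broken*. Each such contact
is typed: **Type I** if one endpoint is positively and the other negatively
charged (salt-bridge-like), otherwise **Type II** if one is a hydrogen-bond
donor and the other an acceptor (hydrogen-bond-like), otherwise
**Type III**. Precedence is I > II > III and exclusive; a positive/acceptor
pairing that is not positive/negative falls through to the donor-acceptor
test. Counts are binned by contact burial level into bands 0, 1, 2, ≥3
(Type I merges ≥2 into one band — deeply buried salt bridges are rare). The
deeply-buried feature set is

$$\big(\mathrm{RBL},\; C(I,\geq 2),\; C(II,2),\; C(II,\geq 3),\;
C(III,2),\; C(III,\geq 3)\big)$$

where RBL is the residue burial level; the all-contacts variant appends the
band-0 and band-1 counts for 12 features. A radial-basis SVM classifies
residues as hot spots, evaluated under nested leave-one-out
cross-validation: for each held-out mutation, cost and gamma are selected
by a grid search scored with stratified 5-fold F1 *on the training part
only*, the model is refit and the held-out record predicted. Held-out
labels are never read before prediction (an explicit anti-leakage test
flips one and checks the prediction is unchanged).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| probe radius | 1.4 | Å | water probe, the NACCESS convention |
| exposure threshold | 10.0 | Å² | published cutoff; boundary inclusive |
| contact padding | 2.75 | Å | water diameter, water-free contact criterion |
| ddG threshold | 2.0 | kcal/mol | published hot-spot definition; inclusive |
| sphere points | 960 | — | Shrake–Rupley resolution (see below) |
| cost grid | $2^{-5}..2^{15}$ | — | canonical libsvm grid, step $2^2$ |
| gamma grid | $2^{-15}..2^{3}$ | — | canonical libsvm grid, step $2^2$ |

Grid-search ties are broken toward smaller cost, then smaller gamma.
Features are scaled to $[0,1]$ with training-fold minima/maxima only, the
standard SVM practice, applied inside the fold so the nested protocol is
preserved.

## Numerical choices

* **SASA.** Computed by a vectorised Shrake–Rupley implementation on a
  deterministic golden-spiral point lattice (960 points/atom by default).
  At that resolution the isolated-sphere area is exact, two-sphere overlap
  agrees with the closed-form spherical-cap area to < 0.2 Å², and areas are
  rigid-motion invariant to < 0.1 Å² at 20 000 points (the invariance
  test's resolution). An optional import path for per-atom `.asa` files is
  not provided; areas are always computed.
* **Water pruning order.** Exposure is computed once on the full complex
  including all waters; exposed waters are then removed in a single pass
  and the remaining flags are reused for the graph. No fixed-point
  iteration: the single-pass reading is the simplest consistent one, and
  `build_contact_graph(include_waters = FALSE)` supports sensitivity
  analysis of the waters' role.
* **Delaunay tessellation.** Computed by Qhull (via SciPy's
  `scipy.spatial.Delaunay`), the same program family cited for the original
  computation. Degenerate inputs (coplanar or cospherical points) error
  with advice to enable the deterministic jitter mode (uniform ±10⁻⁶ Å,
  fixed seed). Plain convex-hull Delaunay is used; no bounding construction
  is added.
* **Strict gate.** The distance condition is strict: a pair at exactly
  $r_i + r_j + 2.75$ Å is *not* a contact.
* **Unreachable pockets.** Atoms with no path to an exposed atom get an
  `Inf` sentinel and a warning; they are excluded from residue means, and a
  residue that is entirely unreachable is an error.
* **Degenerate folds.** If an outer training fold collapses to one class,
  the held-out record receives the majority prediction with a warning.
  F1 is defined as 0 when there are no true-positive predictions.

## Synthetic generators and what they do (and do not) show

The package validates itself on three generators whose ground truth is
produced by an independent brute-force pipeline (exhaustive
empty-circumsphere Delaunay, iterative-relaxation shortest paths, randomly
oriented SASA points) that shares no code with the production path.

* `make_lattice_block()` — jittered cubic lattices of carbons with
  reference burial levels. Oracle-equality tests run at 3×3×3 and 4×4×3
  (the brute-force Delaunay oracle is $O(n^5)$, so reference sizes are kept
  below ~50 atoms; the production path itself handles thousands).
* `make_toy_complex()` — two-chain mini-complexes with planted typed
  contacts at a requested burial band: a side-chain atom (LYS NZ, SER OG or
  LEU CD1) contacts `n` partner atoms (ASP OD1, GLY O, GLY CA) across the
  interface, wrapped in concentric carbon shells (radii 5.2/9.5/13.8 Å;
  inner shells at 2.2 Å spacing so no probe fits through, the outermost at
  4.0 Å spacing so its atoms stay above the exposure threshold). Planted
  counts are recovered exactly by the pipeline.
* `make_feature_dataset()` — Gaussian two-class feature tables with a
  controllable centroid separation in σ units; counts are rounded and
  clipped at zero. At separation 5 the nested LOOCV recovers labels with
  F1 ≥ 0.95; at separation 0 or under label permutation F1 collapses
  toward the class-prevalence baseline.

These fixtures exercise the machinery, not protein physics: lattices and
shells are far denser and more regular than real packing, pseudo-residues
are single atoms, and no conformational change is modelled. Passing tests
demonstrate correctness of the graph/count/protocol computations, not
predictive performance on real complexes — that evidence comes from the
deposited-structure worked examples, which require the PDB entries to be
available locally.

* Problem sizes used by the validation suite: 50 random graphs (8–40
  atoms), two lattice oracles, 20 planted complexes, a 125-record LOOCV
  benchmark and a 20-permutation null on a 48-record benchmark with a
  reduced 3×3 grid (the full 110-point grid on 20 permutations would add
  nothing but runtime).

## Design choices where the published description is open

* The list of atoms removed by alanine substitution is read as "everything
  beyond {N, CA, C, O, CB}", the alanine remainder; OXT is added to the
  survivor set since the chain terminus survives mutation.
* The chemistry dictionary (charged atoms, donors, acceptors) is a
  standard reconstruction shipped as an editable CSV
  (`inst/extdata/atom_classes.csv`), so a different classification can be
  swapped in without code changes. Backbone N is treated as a donor
  uniformly (including proline — a simplification).
* Van der Waals radii are element-keyed (C 1.87, N 1.65, O 1.40, S 1.85,
  P 1.90 Å), Chothia-lineage values, also replaceable via CSV.
* "Van der Waals radius plus the water diameter" is read pairwise:
  $d < r_i + r_j + 2.75$ — a single radius cannot apply to a pair.
* Interface residues are defined by the graph (≥ 1 interfacial contact); a
  ΔSASA criterion is available via `interface_residues(method = "dsasa")`.
* Alternate locations resolve to the highest-occupancy conformer, ties by
  altloc letter, for a deterministic single-conformer graph. Non-water
  heteroatoms are excluded unless explicitly included. Insertion codes are
  part of residue identity; only the first MODEL is read.
* Waters never count as interfacial contact partners (they carry no chain
  side); they affect features only by deepening burial levels.

## A worked example

```{r, eval = FALSE}
library(dbac)

# a synthetic complex with two deep and two shallow planted residues
tc <- make_toy_complex(data.frame(type = c("II", "III", "II", "III"),
                                  band = c(2, 2, 0, 0), n = c(4, 5, 1, 1)))
x <- tc$structure
sasa <- compute_sasa(x)
exposed <- label_exposure(sasa)
x2 <- prune_exposed_waters(x, exposed)
graph <- build_contact_graph(x2, exposed)
burial <- atom_burial_levels(graph)
feature_table(x2, graph, burial,
              residues = data.frame(chain = "A", resno = 1:4))

# classification under the nested protocol
d <- make_feature_dataset(25, 100, separation = 5, seed = 0)
cv <- dbac_cv(d$x, d$y, seed = 0)
evaluate(cv$predicted, d$y)
```

## Limitations

* Only directly broken contacts are modelled; contacts lost or formed by
  conformational rearrangement are out of scope, which depresses
  sensitivity for hot spots that act through backbone motion.
* The Type I/II definitions are contact-graph pairings, not geometrically
  validated salt bridges or hydrogen bonds (no angle or distance criteria
  beyond the contact gate).
* Hydrogens are never placed; protonation states are not predicted; mmCIF
  is not parsed; no assembly/symmetry expansion is performed.
* The dataset-level published performance (F1 ≈ 0.62 over 258 curated
  mutations in 13 complexes) requires the curated mutation corpus and all
  deposited structures; the package reproduces the evaluation layer and
  the per-residue worked examples, not the full curation.
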
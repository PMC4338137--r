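---
title: "Pocket fluctuations, exemplars, and inhibitor selectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pocket fluctuations, exemplars, and inhibitor selectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Many protein–protein interactions that drive disease have no obvious
small-molecule binding site in the unbound crystal structure: the surface at
the interaction site is flat or convex. Yet selective inhibitors exist for
some of these targets. Under a conformational-selection model, the ligand
does not create its site — it captures a transiently open, "cryptic" pocket
that the protein already visits in its thermal ensemble. If two paralogous
proteins visit *different* pocket shapes, a ligand complementary to a pocket
unique to one paralog will inhibit only that paralog, even when the proteins
are otherwise very similar.

`pocketeer` operationalises this picture in five stages:

1. **Pocket detection** — label a grid around user-chosen *target residues*
   and measure the *deep volume* of any pocket there.
2. **Target selection** — choose the target residues automatically from a
   per-residue interface energy table.
3. **Biased ensemble generation** — Metropolis Monte Carlo with an energy
   bonus proportional to deep pocket volume, producing ensembles of
   pocket-containing conformations, plus an unbiased baseline and an
   energy-window filter.
4. **Exemplars** — summarise the pocket of each conformation as a
   pseudo-ligand ("the perfect ligand for this pocket"): hydrogen-bond
   probes complementary to the protein's surface polar groups plus a greedy
   hydrophobic fill.
5. **Selectivity analytics** — Gaussian-overlap alignment of exemplars,
   distance matrices, MDS pocket maps, distinctness, per-reference Z-score
   rows, and ROC evaluation against known binding data.

# Pocket detection

Detection is local, Ligsite-style. A cubic grid (default edge 24 Å, spacing
0.5 Å) is centred on the unit-mass centre of mass of one or two target
residues. Grid points within the van der Waals radius of any atom are
labelled *protein*, the rest *solvent*. Along seven lattice directions
(three axes, four body diagonals), maximal runs of solvent points bounded by
protein points at both ends are *pocket* candidates; a point bounded in at
least `min_bounded_directions` (default 1) directions becomes pocket.
Pocket points strictly farther than the burial distance (2.5 Å) from every
remaining solvent point form the *deep pocket* — the well-sequestered,
druggability-relevant volume. "Strictly" matters: a point exactly 2.5 Å
from solvent is not deep, and the test suite pins this boundary.

Pocket points are clustered by 26-neighbour connectivity; clusters with no
point within (atom radius + 1.0 Å) of a target-residue atom are discarded,
so detection reports only the pocket at the site of interest. Volumes are
point counts times the cell volume, so they are quantised at
`spacing^3`; with the 0.5 Å default this is far below chemical relevance,
and coarser sampling grids (below) trade this quantisation for speed.

Design choices the underlying idea leaves open, fixed here: grid spacing
0.5 Å; the classic 7-direction scan set; one bounded direction sufficing;
target contact defined by a one-grid-shell tolerance (1.0 Å); burial
measured by exact Euclidean distance between cell centres (the engine uses
an exact distance transform, and an equivalent ball-scan in the sampler's
fast path). No segment-length cap and no minimum cluster size are applied;
both exist as parameters.

# Target residue selection

Given a table of per-residue contributions to the binding free energy of the
protein–protein interface (ΔΔG per residue, e.g. from computational alanine
scanning — producing that table is outside this package's scope), every
unordered pair of listed residues is scored: centre a 24 Å cube at the
pair's atom centre of mass and sum the ΔΔG of every residue with at least
one atom in the cube. The full ranking is returned (descending captured
ΔΔG, ties broken lexicographically) because analyses sometimes also use the
runner-up pair. Negative entries are summed as-is by default; a clipping
flag exists. Centre of mass uses unit masses — deterministic and
independent of element bookkeeping.

# The stand-in conformational energy and the biased sampler

The package's claim of interest is the *biasing mechanism and the
downstream analytics*, not any particular all-atom force field. The
conformational energy is therefore a documented stand-in with a pluggable
interface:

* an **elastic network**: `k_el * (d_ij - d_ij_ref)^2` over all reference
  atom pairs within 10 Å (`k_el` default 0.02 units/Å²), and
* **soft-sphere repulsion**: a quartic penalty `k_rep * (1 - d/c)^4` inside
  the contact distance `c = r_i + r_j`, applied to *non-bonded* pairs —
  pairs not in the elastic contact list. This reading makes the energy
  exactly zero at the reference conformation for any reference geometry,
  which anchors the energy scale; pairs distant in the reference but driven
  into a clash still pay the penalty.

`k_el = 0.02` sets the thermal fluctuation amplitude at temperature 1 to
roughly half an ångström per atom — large enough that pocket volume
fluctuates visibly (the regime the method targets: pockets that open
transiently), small enough that the fold is preserved. The Metropolis
acceptance rate under the default single-atom jitter (σ = 0.3 Å) is then
35–40%, in the standard efficient range for random-walk samplers.

Sampling is Metropolis Monte Carlo over two move types: single-atom
Gaussian jitter and rigid rotation of a local group (all atoms within 4 Å
of a picked atom) by a small random angle. Both proposals are symmetric, so
plain Metropolis acceptance is correct; the suite verifies this by sampling
a two-atom harmonic dimer at zero bias and comparing the distance
distribution against the closed-form Boltzmann law (the radial density
`r² exp(-k (r-d0)²/T)`) with a Kolmogorov–Smirnov statistic.

The biased objective is `E' = E + c · V_deep` with `c = -0.25` energy
units per Å³: larger deep pockets are rewarded. The deep volume is
re-measured on a grid re-anchored at the current target centre of mass at
every step. For this inner loop the grid uses 1.0 Å spacing (24 Å edge):
the ~1 Å³ quantisation is negligible against typical deep volumes of tens
of Å³, and the evaluation stays under a millisecond. Output conformations
get their exemplars from the full-resolution 0.5 Å grid.

Each output conformation is the endpoint of an independent trajectory
(default 2000 steps, seeds `base + index`), its energy re-evaluated
*without* the bias. Because biased conformations are not drawn from a
Boltzmann distribution, ensembles are cleaned with an energy window: keep
biased conformations whose unbiased energy is at most `median(unbiased
ensemble) + 15` units. The window's reference point is a design decision
("within 15 units of the unbiased ensemble" names a distribution, not a
point); the median is the default and `min`/`max` are available.

# Exemplars

Exemplars translate a pocket into the language of ligands, with exactly
three pharmacophore classes: donor, acceptor, hydrophobe.

1. For every protein surface donor/acceptor group (typed from a residue
   table: backbone amide and carbonyl, Ser/Thr/Tyr hydroxyls, Lys/Arg
   amines, Asp/Glu carboxylates, Asn/Gln amides, His ring nitrogens, Trp
   NE1; directions idealised from bonded-neighbour geometry, explicit amide
   H used when present), the ideal hydrogen-bond partner location is placed
   2.9 Å along the group's direction. The probe is kept if its nearest grid
   point is not protein and a pocket or deep-pocket point lies within one
   grid spacing; its feature is the *complement* of the protein group.
2. The deep volume is filled with hydrophobic pseudo-carbons greedily:
   candidate sites are deep grid points ordered by burial depth (distance
   to the nearest solvent point, descending; ties by grid index), and a
   site is accepted if it keeps all pairwise exemplar distances ≥ 1.7 Å.
   Polar probes participate in the spacing constraint, which also forces
   near-duplicate probes (e.g. from a group typed as both donor and
   acceptor) to be thinned to the spacing limit.
3. Exemplar atoms are single-linkage clustered at 5 Å; the component whose
   centroid is closest to the target-pair centre is kept (ties to the
   larger component), so two small pockets flanking the target residues
   merge into one exemplar while unrelated far-away volume is dropped.
   Keeping all components is available as a flag.

Polar probes may occupy any pocket volume while hydrophobes are restricted
to deep volume — the reading that honours both "exemplars are built from
the deep volume" and "if this location lies within the pocket" for polar
partners. Exemplar Gaussian radii are 1.70 Å (hydrophobe) and 1.50 Å
(polar). Files round-trip in a PDB-like format with the feature encoded in
the residue name (HPH/DON/ACC) and the radius in the occupancy column.

# Comparing exemplars

Shape similarity uses the Grant–Pickup first-order Gaussian model: each
atom is a spherical Gaussian with amplitude p = 2.828 and exponent chosen
so an isolated atom's Gaussian volume equals its hard-sphere volume; the
overlap of two sets is the analytic sum over atom pairs (no higher-order
corrections). *Color* (chemistry) overlap restricts the sum to
donor–donor and acceptor–acceptor pairs with a fixed 1.0 Å color radius —
hydrophobes shape the volume but carry no color, which concentrates the
chemistry term on hydrogen-bonding patterns. Both restrictions are
configurable.

Alignment maximises `shape + 0.5 · color` over the six rigid degrees of
freedom: centroids are superposed, the four proper principal-axes sign
combinations plus four seeded random rotations give starting poses
(degenerate inertia adds further random starts), and each start is refined by a derivative-free
Nelder–Mead simplex (≤ 300 evaluations, relative tolerance 1e-4) in a
compiled inner loop. The suite checks that the refined optimum is never
worse than an exhaustive 10°-step rotation search.

Scores at the final pose: shape Tanimoto `O_AB / (O_AA + O_BB - O_AB)`,
color Tanimoto likewise on color overlaps, TanimotoCombo their sum in
[0, 2], and the **exemplar distance** `2 - TanimotoCombo`. The numeric
definition of "distance" is a documented assumption (the underlying idea
names only a ROCS-style comparison); TanimotoCombo is the conventional
choice that uses both shape and chemistry. The distance is evaluated in
both alignment directions and the smaller value kept, making it symmetric
to optimiser tolerance (≤ 5e-3 in practice).

# Selectivity analytics

* **Distance matrix**: all-vs-all exemplar distances (zero diagonal,
  values in [0, 2]).
* **MDS**: classical (Torgerson) scaling via the double-centred
  squared-distance matrix; deterministic axis signs (first loaded
  coordinate positive). Euclidean-realizable inputs are reproduced to
  numerical precision; general exemplar-distance matrices are projected in
  rank 2 for maps.
* **Distinctness** of a conformation = (distance to the nearest pocket of
  any *other* family member) − (distance to the nearest *other* pocket of
  its own ensemble). Large positive values flag pockets unique to one
  protein — candidate selectivity handles. No deduplication of
  near-identical conformations is applied.
* **Selectivity rows**: for a reference pocket exemplar (or a typed ligand
  conformer — the ligand-vs-ensemble mode), take the minimum distance into
  each protein's ensemble and normalise across the row as Z-scores with the
  *population* SD; rows without variation are flagged and zeroed. Low Z
  predicts inhibition.
* **ROC**: binding classes collapse to a binary problem (strongest binders
  vs non-binders; intermediate classes excluded). AUC via the rank-sum
  identity; p-value from the tie-corrected normal approximation of the
  one-sided Mann–Whitney test. Spearman correlation between two similarity
  matrices is computed tie-aware over upper triangles.

# Synthetic fixtures and what they do (and do not) show

Real cryptic-pocket studies need deposited structures, interface energy
calculations and large-scale sampling. The package instead ships a
deterministic generator whose ground truth is known by construction:

* `make_shell_protein()` builds a pseudo-protein ball of sulfur-sized atoms
  on an FCC lattice (nearest-neighbour distance 2.2 Å, fixed generic
  rotation). FCC gives two guarantees at once: the configured minimum
  pairwise spacing, and a *sealed* surface — the largest lattice interstice
  is 0.707 × 2.2 ≈ 1.56 Å from the nearest atom, inside the 1.8 Å atom
  radius, so no solvent scan line can tunnel into the body. A convex ball
  therefore has exactly zero deep volume, which the acceptance suite
  asserts. The wall defaults to a solid ball so carves cannot break through
  into an interior void.
* `carve_pocket()` subtracts a cylinder or sphere; deeper and wider carves
  strictly increase deep volume. `decorate_pocket()` embeds two-atom
  pseudo-side-chains (Lys-like donor, Asp-like acceptor, Ser-like both)
  pointing into the cavity so exemplars acquire polar probes.
* `make_family()` builds the three-protein study system: proteins P1 and P2
  carry the shared pocket A (3 Å × 5.5 Å cylinder, donor decorations),
  P3 carries the distinct pocket B (4.5 Å × 3.5 Å cylinder, acceptor
  decorations), plus per-protein coordinate jitter (σ = 0.1 Å) so family
  members are not identical. The truth table has six (reference, protein)
  cells, three binders.

The desk-scale validation: ensembles of 50 conformations per protein
(300-step trajectories), exemplars per conformation, and the selectivity
rows recover the truth table with ROC AUC 1.0 while distinctness ranks P3's
pocket-B conformers at the top of the family. This demonstrates that the
machinery — bias, detection, exemplars, alignment, normalisation — is
internally consistent and recovers planted signal. It does *not*
demonstrate performance on real proteins: pseudo-protein pockets are rigid
and well-separated in shape space, whereas real cryptic pockets are
shallower, noisier, and confounded by backbone plasticity. Problem sizes
in the tests (ensemble sizes, trajectory lengths, atom counts) were chosen
as the smallest at which the planted effects are unambiguous.

# Numerical choices and degenerate inputs

* Determinism everywhere: fixed seeds thread through fixture jitter,
  trajectories (`seed + index`), and alignment random starts; ties in
  greedy fills, cluster ordering and pair rankings break lexicographically.
  Identical inputs give byte-identical outputs.
* The burial threshold is strict (`>`), and the spacing/burial ratio is
  chosen so the boundary is exactly representable in floating point at the
  defaults.
* Alignment of collinear or single-atom sets (zero inertia axes) falls back
  to seeded random rotation starts with a message.
* Empty results are errors where the contract says so (no pocket at the
  target site, empty exemplar, empty unbiased ensemble, single-conformation
  proteins in distinctness) and empty-but-valid values elsewhere (a probe
  set may be empty; a detection may retain zero clusters).
* Rows with zero variance in selectivity Z-scoring are flagged
  (`no_variation`) and set to zero rather than propagating NaN.

# Known limitations

* The stand-in energy has no solvation, electrostatics or torsional
  chemistry; conclusions about *real* energetic accessibility of pockets
  require re-running the sampler against a physical force field behind the
  same interface.
* Exemplar chemistry is three-class; aromatic/charged interactions are
  folded into hydrophobe/polar.
* The sampler's conformations are not Boltzmann-weighted — by design, as
  the energy-window filter exists precisely to re-admit only conformations
  plausibly reachable by the unbiased ensemble.
* Detection is local to target residues; the package deliberately has no
  whole-surface pocket ranking.
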
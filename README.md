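# pocketeer

Cryptic-pocket detection, biased conformational ensembles, and
exemplar-based prediction of small-molecule inhibitor selectivity across
protein families.

## The problem

Protein–protein interactions are hard drug targets because the unbound
interaction surface often lacks a deep pocket. Under conformational
selection, inhibitors bind transiently open ("cryptic") pockets that the
protein samples spontaneously — and two close paralogs can sample
*different* pockets, which is a route to selective inhibition. `pocketeer`
asks, for each member of a protein family: *which pocket shapes does your
ensemble visit, and is any of them complementary to this ligand?*

## The method in brief

* **Pocket detection** (Ligsite-style): a grid around one or two target
  residues is labelled protein/solvent; solvent segments bounded by protein
  become pocket; pocket points more than 2.5 Å from any solvent point form
  the **deep volume** V_deep (Å³), the druggability-relevant observable.
* **Target selection**: all pairs of interfacial residues are scored by the
  summed per-residue binding energy ΔΔG_res captured by a 24 Å cube at the
  pair's centre of mass; the best pair anchors the grid.
* **Biased sampling**: Metropolis Monte Carlo on a stand-in energy
  (soft-sphere + elastic network) with the pocket-opening bias

  E' = E + c · V_deep,  c = −0.25 units/Å³,

  one independent trajectory per output conformation, and a filter keeping
  conformations within 15 units of the unbiased ensemble's median energy.
* **Exemplars**: each pocket is summarised as the "perfect ligand" —
  hydrogen-bond donor/acceptor probes placed 2.9 Å along the protein's
  surface polar groups into the pocket, plus greedy hydrophobic fill of the
  deep volume at ≥ 1.7 Å spacing, single-linkage clustered at 5 Å.
* **Comparison**: Gaussian-overlap alignment (Grant–Pickup model,
  Nelder–Mead rigid refinement from principal-axes starts) yields shape and
  color (donor/acceptor) Tanimotos; the **exemplar distance** is
  2 − TanimotoCombo ∈ [0, 2].
* **Selectivity analytics**: all-vs-all distance matrices, classical MDS
  pocket maps, per-conformation **distinctness**
  (d_nearest-other-protein − d_nearest-own-ensemble), per-reference Z-score
  rows (population SD), ROC/Mann–Whitney evaluation, Spearman rank-matrix
  correlation.

A deterministic synthetic-fixture module (FCC pseudo-proteins with carved,
polar-decorated pockets and known ground truth) exercises every stage
without any external downloads.

## Worked example

```r
library(pocketeer)

# a carved pseudo-protein with a 3 A x 5.5 A channel
op <- carve_cylinder(c(0, 0, 1), radius = 3, depth = 5.5)
s  <- assign_radii(decorate_pocket(carve_pocket(make_shell_protein(), op),
                                   op, kind = "lys", n = 2))
tg <- rim_targets(s, op)

det <- detect_pockets(s, tg)
det
#> <pocket_detection> 1 retained cluster(s), total deep volume 37.75 A^3

ex <- build_exemplar(s, tg, label = "cup")
ex
#> <exemplar> 10 atoms (hydrophobe 8, donor 0, acceptor 2), deep volume 37.75 A^3
```

The two Lys-like donors lining the cavity produce two complementary
acceptor probes; eight hydrophobes fill the remaining deep volume. A second,
wider-but-shallower pocket is a different shape, and alignment quantifies
that:

```r
opB <- carve_cylinder(c(0, 0, -1), radius = 4.5, depth = 3.5)
sB  <- assign_radii(decorate_pocket(carve_pocket(make_shell_protein(), opB),
                                    opB, kind = "asp", n = 3))
exB <- build_exemplar(sB, rim_targets(sB, opB), label = "dish")

exemplar_distance(ex, ex)   # identical pockets
#> [1] 0
exemplar_distance(ex, exB)  # different shape and chemistry
#> [1] 1.290413
```

End to end, the three-protein family (P1 and P2 share pocket A; P3 alone
has pocket B) is recovered from sampled ensembles:

```r
rep <- run_pipeline("report", pipeline_config(seed = 1,
                                              n_conformations = 50,
                                              steps = 300))
rep$auc
#> [1] 1
head(rep$distinctness, 3)$group
#> [1] "P3" "P3" "P3"
```

Low Z-scores appear exactly at the truth-table binders (reference A for
P1/P2, reference B for P3), the ROC over the six cells reaches AUC 1.0, and
the most distinct pockets in the family all belong to P3 — the desk-scale
analogue of finding a selectivity handle.

A thin command-line wrapper with `pockets`, `targets`, `exemplar`,
`compare`, `sample`, `fixtures` and `pipeline` subcommands ships at
`inst/scripts/pocketeer`.

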
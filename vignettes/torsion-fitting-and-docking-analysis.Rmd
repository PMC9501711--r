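---
title: "Torsion force-field fitting and docking post-analysis with dockfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsion force-field fitting and docking post-analysis with dockfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockfit)
```

dockfit implements the computational chain used when a small ligand --
typically a catecholamine binding a G-protein-coupled receptor -- is
parameterized for molecular mechanics from quantum-mechanical (QM)
torsional scans, validated by dihedral free-energy profiles, and then
characterized by docking post-analysis.  This vignette explains the models
behind each stage, the parameters that matter, and the design decisions
taken where the methods literature leaves choices open.

## The torsional stage of force-field derivation

A force field assigns each rotatable dihedral $\theta$ an explicit
torsional potential.  Because a QM scan energy $E_{QM}(\theta)$ also
contains the intramolecular Coulomb and Lennard-Jones (LJ) interactions
that the force field already models elsewhere, the explicit term must be
fitted to the *residual*

$$E_{res}(\theta_i) = E_{QM}(\theta_i) - E_{nb}(\mathbf{x}_i), \qquad
E_{nb} = \sum_{(i,j)} s_{ij}\left[\frac{k\, q_i q_j}{\varepsilon_r r_{ij}}
 + 4\epsilon_{ij}\left(\frac{\sigma_{ij}^{12}}{r_{ij}^{12}} -
 \frac{\sigma_{ij}^6}{r_{ij}^6}\right)\right],$$

where the pair sum runs over atoms three or more bonds apart, $s_{ij}$ is
0.5 for 1-4 pairs (the OPLS convention) and 1 otherwise, $k =
332.0636\ \mathrm{kcal\,\mathring{A}\,mol^{-1}e^{-2}}$, and both
$\sigma_{ij}$ and $\epsilon_{ij}$ use geometric-mean combining.  Pair
classes (`excluded_12`, `excluded_13`, `scaled_14`, `full`) come
deterministically from bond-graph shortest paths (`build_exclusions()`).

The residual, shifted so its minimum is zero, is fitted by ordinary linear
least squares on the alternating OPLS cosine basis

$$V(\theta) = \sum_{n=1}^{N} \tfrac{1}{2} V_n \left[1 + (-1)^{n+1}
\cos n\theta\right] + c,$$

with default order $N = 4$ and a free constant $c$.  The cosine-series
form is the field's standard; the alternating-sign OPLS variant was chosen
because the surrounding force field is OPLS-AA.  Weighting is uniform by
default; Boltzmann weighting at a user temperature (down-weighting
high-energy scan points, as torsional fitting programs often do) is
available but off by default because it changes fitted coefficients only
when the model is mis-specified, and silently so.  Scans whose angles
alias a basis function produce a conditioning error rather than a silent
pseudo-inverse.  Dihedrals that practitioners refine by hand are
expressed as explicit coefficient `overrides`, which are substituted after
the fit and flagged in `tidy()` output -- no automatic refinement
heuristic is invented.

```{r}
mol <- make_toy_ligand("catechol_amine_like")
truth <- fourier_torsion(c(2.1, -1.4, 3.3, 0.8))
scan <- make_scan(mol, mol$dihedrals$gamma, truth)
fit <- fit_fourier(residual_profile(scan, mol), max_order = 4)
tidy(fit)
```

Scan conformations are taken as given (rigid rotations of a reference
geometry, or externally relaxed structures supplied by the user); the
package never re-optimizes geometry.  Internally all angles are radians
and conversions are centralized; the public API is degrees.  Energies are
kcal/mol for nonbonded terms and kJ/mol for torsional and free-energy
profiles, converted with the exact factor 1 kcal = 4.184 kJ.

## Validation by Boltzmann inversion

A fitted torsion is validated by comparing it against the Helmholtz
free-energy profile implied by a conformational ensemble:

$$\Delta A(\theta) = -k_B T \ln\left(\rho(\theta) / \rho_0\right),$$

with $\rho$ the binned dihedral density and $\rho_0$ its *maximum* binned
value (not a smoothed mode), so $\Delta A \ge 0$ with a zero at the modal
bin.  Bins with zero counts are reported as `NA` -- "no sampling found
for that geometry" -- and are never imputed or treated as zero.  The
default bin width is 5 degrees, matching the smoothness of typical
published profiles; bins are centred on multiples of the width so a
single bin straddles the $\pm 180^\circ$ seam and wrap-around mass is
never lost.  $k_B T$ is computed as $RT$ with
$R = 8.31446\ \mathrm{J\,mol^{-1}K^{-1}}$ and reported in kJ/mol.

For closed-loop validation the package draws samples *exactly* from the
Boltzmann density of a known potential by inverse-CDF sampling on a
0.1-degree grid (`sample_dihedral_trajectory()`), which is deterministic
given a seed.  This deliberately replaces Markov-chain sampling: the test
then isolates the inversion machinery from sampler convergence.  At
$10^6$ samples and 5-degree bins the reconstruction RMSE of a
several-kJ/mol potential is well below 0.15 kJ/mol (the suite checks
RMSE decreasing over $10^3$-$10^5$ samples and the 0.15 bound at
$10^6$).  Differences between a QM energy profile and a $\Delta A$
profile from a real simulation additionally contain entropic
contributions; the package reports the numerical discrepancy only and
attaches no interpretation.

## Docking post-analysis

Pose ensembles from multi-run docking are processed with the conventions
of the AutoDock virtual-screening tools:

* **Clustering** (`cluster_poses()`): poses sorted by increasing binding
  free energy (ties broken by lower run id, then pose id); the best pose
  seeds cluster 1, and each pose joins the first cluster whose *seed* is
  within the RMSD tolerance (default 2.0 A), else seeds a new cluster.
  Membership is tested against seeds, not centroids, which is what
  energy-ranked docking clustering does; cluster lists are therefore
  energy-sorted and every seed is its cluster's minimum-energy member.
  In-place RMSD (no superposition) is the default because docking poses
  share a fixed receptor frame; superimposed RMSD -- a determinant-corrected
  Kabsch fit, never a reflection -- is available for
  conformation-only comparisons and is never larger than the in-place
  value.  Atom correspondence is by index; a symmetry-equivalent mapping
  (e.g. the 2-fold catechol ring flip) can be applied by the caller, but
  automatic symmetry perception is not attempted.
* **Run consistency** (`consistency_check()`): results are consistent
  when at least 70% of independent runs have a best pose *strictly*
  within 0.5 A of the overall best pose.  Both numbers are configurable;
  the inequality is strict because the rule is stated as "< 0.5 A".
* **Grid arithmetic** (`grid_edge()`): a docking grid of $n$ points per
  axis at spacing $h$ spans $nh$ -- 50 points at 0.375 A give an
  18.75 A box -- and the edge-to-$R_g$ ratio is checked against a
  recommended minimum (default 2.9).  The radius of gyration is
  unweighted over the supplied atoms by default (the convention used for
  ligand sizing in grid setup); a mass-weighted variant is available via
  `weights`.

**Affinity conversions** (`dg_to_pkd()`, `pkd_to_dg()`): a binding free
energy $\Delta G$ (kcal/mol) at temperature $T$ maps to an inhibition
constant and affinity as

$$K_i = e^{\Delta G / RT}, \qquad pK_d = -\log_{10} K_i =
-\frac{\Delta G}{RT \ln 10},$$

with $R = 1.98720 \times 10^{-3}\ \mathrm{kcal\,mol^{-1}K^{-1}}$ and
default $T = 298.15$ K.  Published docking papers sometimes print the
formula as $\Delta G = -RT \ln K_i$, but their tabulated numbers (e.g.
$-12.5$ kcal/mol paired with $pK_d$ 9.2) require the sign convention
above; dockfit follows the numbers.  Because experimental catecholamine
affinities are measured at 310.15 K while docking energies are evaluated
at 298.15 K, `temperature_adjusted_pkd()` offers two documented modes:
the conventional `"offset"` (default, +0.2 pK$_d$ units) and
`"rescale"` (fixed $\Delta G$, $T$ re-substituted), which *lowers* the
affinity for favourable energies.  The two disagree by construction --
the +0.2 correction is not derivable from the conversion formula -- so
the mode is an explicit, recorded choice rather than a hidden rule.

## Interaction profiling

Geometric rules in the spirit of protein-ligand interaction profilers,
reduced to what published distance tables support:

* **Hydrogen bonds**: donor-acceptor *heavy-atom* distance only,
  compatible iff $d \le 3.5$ A (inclusive).  The threshold is inferred
  from published boundary behaviour (3.5 A entries classified
  compatible, 3.6 A not); an angle criterion is deliberately omitted
  because distance tables report no angles.  A $10^{-9}$ A guard keeps
  constructed geometries sitting exactly on the threshold from being
  misclassified by floating-point noise.  With a pair dictionary the
  detector measures exactly the named pairs in order, reporting pairs
  whose ligand group is absent (e.g. no beta-OH in L-DOPA) as *absent*
  rather than zero; without one it enumerates donor-acceptor pairs within
  an 8 A search radius.
* **Hydrophobic contacts**: carbon/sulfur atoms not bonded to N/O, pairs
  within 4.0 A (the common profiler convention, since no cutoff is
  printed alongside published contact counts), aggregated per residue.
* **Contact fractions**: a residue is in contact in a frame when any
  ligand atom is within 5.0 A of any of its atoms; the profile is the
  per-residue fraction of frames in contact.  Residues are keyed by
  (chain, number, name) so multi-chain receptors survive aggregation.

All cutoffs are inclusive, so counts and fractions are non-decreasing in
their cutoffs.

## The synthetic-data generators

Published structures and trajectories behind analyses of this kind are
rarely deposited, so the package ships seeded generators for every input
class, each emitting its ground truth:

* `make_toy_ligand()`: idealized-geometry templates (1.54 A C-C, 1.43 A
  C-O, 1.47 A C-N, 1.40 A aromatic) -- a butane-like chain and a
  catechol-amine-like ligand with flagged hydroxyls, amino nitrogen,
  carboxylate and a beta-OH toggle.  These are geometry/energy test
  articles; no chemical accuracy is claimed.
* `make_scan()`: scan conformations by rigid rotation; "QM" energies as
  known truth + nonbonded background + optional Gaussian noise.
* `sample_dihedral_trajectory()`: exact Boltzmann sampling (above).
* `make_pose_ensemble()`: clusters of rigid translational jitter around
  displaced copies of a reference pose, guaranteeing intra-cluster spread
  and inter-cluster separation so planned cluster sizes are recoverable
  exactly; plans with overlapping clusters are rejected.
* `make_binding_site()`: pseudo-receptor atoms placed by exact sphere
  intersection (1-3 constraints per atom) so prescribed donor-acceptor
  distances are realized to $10^{-6}$ A, with triangle-violating plans
  rejected.  The pseudo-ligand layout places the catechol meta/para
  anchor oxygens 5.0 A apart -- wider than a real catechol (~2.7 A) --
  because some published distance pairs sharing one receptor atom are
  inconsistent with the narrower separation; the site is a measurement
  stand-in, not a chemical model.

What the generators do *not* emulate: QM electronic structure, the
docking search itself, solvent, membranes, or correlated MD dynamics.
Passing closed-loop tests therefore demonstrates the correctness of the
analysis chain, not the realism of any physical model upstream of it.

## Numerical choices and degenerate inputs

* Angles live in $(-180, 180]$ with the IUPAC torsion sign convention;
  exactly $-180$ wraps to $+180$.
* Torsions with collinear bonded triples, superpositions of collinear
  subsets, empty atom subsets, all-zero densities, empty pose ensembles
  and sub-0.1 A nonbonded contacts ("clashes") all raise typed errors
  rather than returning numbers.
* Atom indices are 1-based throughout, R's native convention.
* Validation problem sizes: coefficient recovery on 36-point scans (100
  random ground truths), inversion at up to $10^6$ samples, clustering
  against an independent oracle on 200 random ensembles of up to 20
  poses, and 1000 random conformation pairs for the RMSD inequalities.

## Known limitations

* Hydrogen-bond classification ignores donor-hydrogen geometry entirely;
  a 3.4 A pair with a hopeless angle still counts.
* One cell of the published compatibility table used for regression is
  internally inconsistent with any distance threshold (a 2.8 A pair
  classified as not compatible); the package reproduces the distance rule
  and reports the disagreement rather than special-casing the cell.
* Clustering is greedy and order-dependent by design (it mirrors the
  docking tools' behaviour); it is not a globally optimal partition.
* PDB output carries three decimals, so coordinate round trips are exact
  only to $10^{-3}$ A.
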
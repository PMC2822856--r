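---
title: "Structure-based prediction of peptide binding to MHC class II: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based prediction of peptide binding to MHC class II: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhc2struct)
```

## The problem

MHC class II molecules present peptides to CD4+ T cells. Their open-ended
binding groove accommodates peptides of 13--25 residues through a 9-residue
binding core whose side chains occupy pockets 1--9; pocket 1 of
HLA-DRB1\*0101, for example, prefers large hydrophobic residues. Sequence
based predictors of peptide:MHC-II binding need large sets of measured
affinities per allele, which exist for only a few alleles. `mhc2struct`
implements the complementary *ab initio* strategy: predictors parameterised
from three-dimensional structure alone, with no binding data. Three scoring
functions are provided, together with the machinery to evaluate any of them
against IC50 measurements.

It should be said up front that this class of methods discriminates binders
from non-binders significantly better than chance but clearly worse than
modern data-driven predictors; the package exists to make the approach
reproducible and testable, not to claim competitive accuracy.

## The statistical pair potential

The potential treats each residue as a single interaction centre and scores
the spatial proximity of amino-acid pairs by how unusual it is relative to
a type-independent expectation. For amino acids $a,b$ at binned centroid
distance $k$,

$$ u(a, b, k) \;=\; -\ln
   \frac{P_\mathrm{obs}(k \mid a, b)}{P_\mathrm{exp}(k)}, $$

where $P_\mathrm{obs}$ is the fraction of observed $(a,b)$ pairs falling in
bin $k$ and $P_\mathrm{exp}(k)$ is the pooled distance distribution of all
pairs (the homogeneity assumption $P(k \mid a,b) = P(k)$ under the null).
With this sign convention favourable interactions are negative, so an
attractive pair such as lysine--aspartate shows a well at short distance.
A complex is scored by summing $u$ over all peptide-residue x MHC-residue
pairs within a cutoff; the reported ranking score is the negated sum so
that larger means stronger predicted binding.

Counting conventions:

* **Interaction centres.** Three reduction schemes are supported: `CA`
  (alpha carbon), `CB` (beta carbon, with a virtual beta carbon constructed
  for glycine) and `CM` (unweighted mean of the heavy side-chain atoms,
  which for alanine is the beta carbon itself). `CM` with a 7.5 Angstrom
  scoring cutoff is the default, the combination that performed best in
  benchmark calibrations of this family of potentials.
* **Sequence separation.** Within a chain, only pairs separated by at
  least 10 positions (`separation_min = 10`, i.e. separations greater
  than 9) enter the counts, so the statistics reflect non-local packing
  rather than covalent neighbourhood. Pairs across chains of one structure
  are counted without a separation filter, since inter-chain contacts are
  exactly what the scoring step evaluates.
* **Binning.** Distances are binned at 0.25 Angstrom up to a counting
  range of 20 Angstrom by `floor(d / width)`; a distance exactly on a bin
  edge goes to the upper bin, and distances at or beyond the range are
  ignored.

### Numerical fallbacks

Three situations need explicit rules:

* **Steric region.** Any query below 1.0 Angstrom returns a fixed steric
  penalty of 2.0, and bins lying wholly below the cutoff store that value.
  Bins that straddle the cutoff keep their derived value; the query-level
  rule governs, so sub-steric distances are always penalised.
* **Zero-observation bins.** A bin where other pair types were observed
  but $(a,b)$ was not would give $u = +\infty$; it is capped at $+3.0$,
  approximately the repulsion corresponding to a 0.05 pseudo-ratio and
  symmetric in magnitude with the deepest wells one sees in practice.
* **Empty bins.** Bins with no observations of any type carry no
  information and score 0.

### The virtual beta carbon

Glycine has no side-chain heavy atoms, and occasional residues in real
files lack side-chain coordinates. Both cases fall back to a virtual beta
carbon placed 1.522 Angstrom from the alpha carbon, making equal angles of
110.5 degrees with the N--CA and C--CA bonds, on the side of the backbone
plane that gives the L-configuration. The construction uses only N, CA and
C positions. Glycine under `CM` uses this point silently (keeping all
residues scoreable); non-glycine fallbacks emit a warning because they
indicate an incomplete model.

## The contact-map PSSM

The second predictor assumes (i) core residues interact independently with
the MHC molecule and (ii) the probability of amino acid $s$ at core
position $i$ is proportional to the number of atomic contacts it makes
there in solved complexes. Matrix entries are

$$ \mathrm{score}(s, i) \;=\; \ln\big(p(i,s) + r\big), \qquad r = 0.05, $$

where $r$ prevents underflow at $p = 0$: every unobserved cell equals
$\ln 0.05 = -3.00$ at two decimals. $r$ is added to every cell, not only
the zero ones, which keeps the transform smooth; since observed
probabilities are contact enrichments that can exceed 1, scores above zero
are legitimate. With a single structure per allele, $p(i,s) = N(s,i)/w$
for the amino acid observed at position $i$ (zero for all others), where
$N(s,i)$ is its contact count and $w$ is the average number of contacts
per core residue. With several structures,

$$ p(i,s) \;=\; \frac{Q(i,s)}{\sum_{s' \in E(i)} Q(i,s')}
   \cdot \frac{N_{av}(s,i)}{N_{av}}, $$

the product of how often $s$ occupies position $i$ across the cores
($Q$, normalised over the observed set $E(i)$) and its mean contact count
relative to the grand mean. The two forms agree when the same structure is
duplicated, a consistency the test suite asserts. The exact algebraic
composition of the multi-structure probability is a reconstruction from
the quantities the method defines; it is the only dimensionally consistent
combination of them, but other weightings are conceivable.

### Contact geometries

Published contact analyses rarely state their full geometric criteria, so
the package fixes its own and exposes them as configuration
(`contact_params()`):

| schema | criterion |
|---|---|
| `dist4` | any heavy-atom pair at <= 4.0 Angstrom |
| `hb` | N/O--N/O heavy-atom pair at <= 3.5 Angstrom (no angular term; hydrogens are absent from crystal structures) |
| `hb_vdw` | `hb`, plus pairs within the sum of Bondi van der Waals radii (C 1.70, N 1.55, O 1.52, S 1.80) + 0.5 Angstrom |
| `hb_vdw_phob` | `hb_vdw`, plus carbon--carbon pairs at <= 4.5 Angstrom |

An atom pair is counted once however many criteria it satisfies, and a
residue's contact count is the number of atom pairs its atoms participate
in. The schemas nest by construction (`hb` is a subset of `hb_vdw`, which
is a subset of `hb_vdw_phob`). Because the defaults are this package's
calibration, contact counts for real complexes are structurally plausible
rather than an exact reproduction of any previously published tally.

## The packaged matrices

Two 20 x 9 matrices for HLA-DRB1\*0101 ship in `inst/extdata` and load by
name:

* `contact_dr0101` -- the contact-map PSSM derived from six crystal
  structures of peptide:HLA-DRB1\*0101 complexes (natural-log units;
  unobserved cells are exactly -3.00).
* `md_dr0101` -- binding free-energy differences relative to alanine, in
  kcal/mol, from MM-PBSA evaluation of snapshots of a molecular-dynamics
  simulation of a peptide:HLA-DRB1\*0101 complex. Positive values favour
  binding (phenylalanine and tryptophan dominate pocket 1, consistent with
  the known pocket-1 preference), and the alanine reference row is zero.
  The simulation and free-energy machinery that produced this matrix are
  outside the package's scope; only its output is packaged.

Both matrices are scanned the same way: every 9-mer window of a peptide is
scored as the sum of its nine position values, and the maximum window is
the predicted binding core (ties resolve to the leftmost offset; peptides
shorter than nine residues are rejected rather than padded). For all six
packaged crystal complexes the scan of the crystallised source peptide
recovers the crystallographic core -- each core consists entirely of
observed cells, while every competing window hits at least one -3.00 cell.

## Evaluation machinery

Peptides with measured IC50 below 1000 nM are classified binders; the
boundary value itself is a non-binder (the convention of the benchmark
this threshold comes from). The ROC curve sweeps the score cutoff from
highest to lowest; the AUC is computed as the normalised Mann--Whitney
statistic with ties credited 0.5, which equals the trapezoidal area under
the tie-aware curve. Its standard error uses the Hanley--McNeil closed
form with $Q_1 = A/(2-A)$ and $Q_2 = 2A^2/(1+A)$:

$$ \mathrm{se}(A) = \sqrt{\frac{A(1-A) + (n_+ - 1)(Q_1 - A^2)
   + (n_- - 1)(Q_2 - A^2)}{n_+ n_-}}. $$

```{r hanley}
round(hanley_se(c(0.682, 0.667, 0.621), 2939, 943), 3)
```

For correlation against affinities, IC50 values are mapped to
$1 - \ln(\mathrm{IC50}) / \ln(50000)$ clamped to $[0,1]$, the conventional
normalisation in this literature; the constant is a parameter because the
transform is not standardised across studies.

## Synthetic data: what it emulates and what it does not

All structural fixtures are generated, seeded, in code:

* **Toy complexes** (`make_toy_complex`) place an idealised peptide
  backbone with residues spaced 12 Angstrom apart and position MHC
  pseudo-atoms so that each peptide residue participates in exactly the
  requested number of sub-4-Angstrom atom pairs (each placed atom touches
  only the residue's backbone oxygen; all other MHC atoms stay at least 6
  Angstrom away). This makes contact counts exactly controllable, which
  real structures never are.
* **Training chains** (`make_potential_training_set`) draw residue
  centroids uniformly at random in a sphere whose radius scales with chain
  length (default 300--460 residues, the length range typical of the
  globular single-chain structures such potentials are trained on) so
  density stays constant, with sequences drawn independently of geometry.
  Distances are then independent of residue type, the null model under
  which the derived potential tends to zero everywhere. With
  `type_dependent = TRUE`, residue pairs closer than 5 Angstrom are
  converted to lysine--aspartate with a probability calibrated so the
  short-range rate of that pair is an exact multiple (default 2) of its
  overall rate; conversions swap types with carriers elsewhere in the
  chain so composition is preserved, and the calibration corrects for the
  short pairs' own contribution to the overall rate (computed at the
  default 20 Angstrom counting range). The derived potential must then
  show a short-range well of depth $-\ln 2$.
* **Affinity datasets** (`make_affinity_dataset`) draw binder and
  non-binder scores from unit-variance Gaussians separated by $d$, giving
  a closed-form expected AUC of $\Phi(d/\sqrt2)$, with IC50 values placed
  strictly on the correct side of the threshold.

What passing these tests shows is that the algorithms implement their
definitions exactly and recover planted statistical signal at the
predicted magnitude. What it does not show is predictive accuracy on real
peptides: the generators have no excluded volume, no chain connectivity in
the training sets, no rotamers, and contact counts that are cleaner than
any crystal structure. Claims about real-data performance require the real
benchmark sets, which are deliberately out of scope.

### Test problem sizes

The null-model and enrichment checks use 200 chains of 300--460 residues
and evaluate the potential on 5-Angstrom bins; at that size every
populated amino-acid-pair cell holds thousands of counts, so the sampling
noise of $u$ (roughly $1/\sqrt{n}$ per cell) sits well below the 0.1
assertion band across all ~800 populated cells. Oracle-equivalence suites
use 100 random ROC datasets up to n = 500 against quadratic pair counting,
1000 random peptides against naive window enumeration, and exhaustive
double loops for pair counting and complex scoring on small synthetic
inputs.

## Trajectory utilities

Multi-model PDB files serve as the container for molecular-dynamics
snapshots. `superpose` implements the least-squares rigid superposition
(Kabsch, via singular value decomposition, with the determinant sign
corrected so the rotation is always proper); `trajectory_rmsd` superposes
each frame's backbone (CA, C, N, O) onto a reference and reports the
post-fit RMSD; `backbone_rmsf` computes per-residue fluctuations about the
across-frame mean, averaged over the four backbone atoms. RMSF requires
frames already superposed onto a common reference -- the package does not
silently re-fit, because the choice of superposition selection (whole
backbone vs MHC-only) materially changes per-residue fluctuations, and the
test suite demonstrates the sensitivity rather than hiding it. The
superposition selection is therefore an explicit argument.

## Design decisions taken where the problem was open

* Sign convention of the pair potential: $u = -\ln(P_\mathrm{obs}/P_\mathrm{exp})$,
  so minima are attractive; both the raw pseudo-energy and its negation
  (for ranking) are returned.
* $P_\mathrm{exp}$ is the pooled all-pair bin distribution from the same
  count table, not an external reference state.
* Insertion codes order alphabetically after the bare residue number;
  hetero-residues (including selenomethionine) are dropped rather than
  remapped.
* Alternate locations resolve to the highest-occupancy copy, ties to
  altloc `A`.
* First-model-only parsing by default; trajectory mode is opt-in.
* Tie-breaking in core scanning is leftmost-wins.
* Scoring a complex consumes a user-supplied 3D model. The upstream
  protocol of building several homology models per peptide register and
  averaging their scores is documented but intentionally not implemented;
  it requires an external modelling engine.

## Known limitations

* The contact geometric criteria are this package's calibration; absolute
  contact counts on real structures depend on them.
* The multi-structure PSSM probability composition is a reconstruction
  (see above).
* No mmCIF parsing, hydrogen placement or symmetry expansion.
* The packaged matrices cover HLA-DRB1\*0101 only; other alleles need
  user-supplied structures or matrices.
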
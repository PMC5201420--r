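---
title: "Inter-protein coevolution from organism-paired alignments: methods and design"
author: "paircoev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-protein coevolution from organism-paired alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircoev)
```

# The problem

When two protein families form a physical complex, residue pairs at the
interaction interface tend to substitute in a correlated way across
evolution: a destabilising change on one side is compensated by a change on
the other. Given one multiple sequence alignment (MSA) per family, those
couplings become detectable once the two alignments are concatenated
row-by-row so that each row holds the two proteins *of the same organism*.
`paircoev` implements that whole workflow for membrane-protein complexes of
the kind exemplified by the twin-arginine translocase (Tat), where a small
single-TMH subunit (the TatA family, with its TatA/TatB/TatA-basal
paralog subsets) docks onto a polytopic partner (TatC):

1. read and filter the per-family alignments (anchor residues such as the
   invariant TatA-family hinge glycine or the TatC signal-binding
   glutamate),
2. pair by organism, concatenate, de-duplicate,
3. redundancy-weight rows and estimate coupling strength for every column
   pair with three methodologically distinct scorers,
4. correct for background with the average product correction (APC),
   threshold at k standard deviations above the mean, and intersect the
   methods' top predictions,
5. filter contacts that are impossible given the membrane topology,
   classify the remainder against a reference structure, and export the
   survivors as docking restraints,
6. partition the family into phylogenetic subsets, filter them by organism
   co-occurrence, and summarise per-subset conservation as sequence-logo
   information content.

Because public sequence databases move and published contact predictors
are external binaries, the package validates itself against a fully
deterministic synthetic generator that plants known couplings, subfamilies
and contamination, with complete ground truth.

# Pairing model

Pairing is by exact string equality of the parsed organism identifier
(UniProt `OX=` taxid by default; `OS=` or a custom capture pattern are
supported). No taxonomy-aware merging is attempted. When an organism
carries paralogs in both families, **all cross-product pairs** are formed —
each family-A entry concatenated to each same-organism family-B entry —
and rows with an identical concatenated residue string are then collapsed
to one. A `pairing = "best_one"` switch instead keeps the single pair most
similar to the family consensus, for users who want strict 1:1 matching.
The stage order is: anchor filter, then pairing (which drops partnerless
rows), then de-duplication; a family MSA can be de-duplicated up front by
pairing it against itself if the other order is wanted. Every stage records
its drop count in a provenance table, and input rows always equal output
rows plus drops.

Anchor rules are given in alignment coordinates (1-based);
`reference_column()` maps a residue number of an ungapped reference
sequence (the usual way such residues are cited) to its alignment column.
A gap at an anchor column fails the rule: a gapped position cannot carry an
invariant residue.

# Statistical model

## Weights and frequencies

Rows are down-weighted for phylogenetic redundancy in the standard way:
row weight $w_r = 1/|\{r': \mathrm{id}(r, r') \ge \theta\}|$ with
$\theta = 0.8$ by default, identity computed over the full concatenated row
with the gap as a 21st symbol, and $M_\mathrm{eff} = \sum_r w_r$.
Frequencies use the 21-state alphabet (20 residues + gap; `X` is pooled
with the gap since it carries no residue identity) with pseudocount
$\lambda$ (default $0.5\,M_\mathrm{eff}$):

$$f_i(a) = \frac{\lambda/q + \sum_r w_r [x_{ri} = a]}{\lambda + M_\mathrm{eff}},
  \qquad
  f_{ij}(a,b) = \frac{\lambda/q^2 + \sum_r w_r [x_{ri} = a][x_{rj} = b]}{\lambda + M_\mathrm{eff}}.$$

## Three scorers

* **Mean-field DCA** (`score_mfdca`): the covariance
  $C_{(i,a),(j,b)} = f_{ij}(a,b) - f_i(a) f_j(b)$ is built over $q-1 = 20$
  states per column (the gap is the dropped reference state — standard DCA
  practice) and inverted; the coupling score of a column pair is the
  Frobenius norm of the corresponding $20 \times 20$ block of the negated
  inverse after shifting the block to zero-sum gauge. The pseudocount makes
  the covariance positive definite; an optional ridge is exposed for
  pathological inputs.
* **Sparse inverse covariance** (`score_sparse_l1`): the same covariance,
  but the inverse is estimated under an L1 penalty by graphical-lasso block
  coordinate descent (compiled, warm-started, approximate inner solves).
  Scoring is shared with the mean-field path. The default penalty is
  $\rho = \overline{|C_\mathrm{offdiag}|}$ (about $10^{-3}$ on amino-acid
  indicator covariances): this is the scale at which soft-thresholding
  actually sparsifies the solution (~4% nonzero couplings, convergence in a
  few sweeps). A penalty orders of magnitude below that scale leaves the
  problem effectively unpenalised — dense, slow, and equivalent to the
  mean-field answer — so the package deliberately defaults to the
  within-scale choice; $\rho$ remains a parameter. Convergence is declared
  when the mean absolute change of the working covariance in a sweep drops
  below $3 \times 10^{-2} \cdot \overline{|C_\mathrm{offdiag}|}$; with
  approximate inner solves the change plateaus slightly below this, and at
  the stop point scores correlate at ~0.98 with the fully converged
  solution while ranking the same top pairs.
* **Mutual information** (`score_mutual_information`): weighted MI in bits,
  $\sum_{ab} f_{ij}(a,b) \log_2 \frac{f_{ij}(a,b)}{f_i(a) f_j(b)}$, by
  default from unpseudocounted frequencies. MI is a purely local statistic
  and doubles as a closed-form oracle (identical two-state uniform columns
  carry exactly 1 bit).

The three scorers answer the "methodologically distinct algorithms"
requirement of a consensus analysis: a global mean-field model, a global
sparse-regularised model, and a local model-free statistic.

## APC, precision, thresholds, consensus

The average product correction subtracts
$\bar{s}_i \, \bar{s}_j / \bar{s}$ from each raw score, the means taken
over all finite entries of the matrix. Coupling matrices carry an `NA`
diagonal, so their means run over off-diagonal entries; for a full matrix
(diagonal present) the correction cancels a rank-one matrix exactly. Both
behaviors are intentional and tested — the former is what the pipeline
uses, the latter is the analytic sanity check.

The precision reported per pair is explicitly a *pseudo-precision*: a
logistic map of the z-score of the APC value over all scored pairs
(centre 3, scale 1 by default). A calibrated probability of being a true
contact would need labelled structures; raw and APC scores are therefore
always carried alongside, and every threshold can be computed on either.

Significance thresholds follow the "k standard deviations above the mean"
convention: population (not sample) SD, pairs at or exactly on the
threshold flagged significant, with the population selectable as all
pairs, inter-chain pairs only (k = 6 is the conventional choice there), or
intra-chain pairs only (k = 7 for whole-dataset thresholds). Intra-chain
pairs closer than 5 positions are excluded from rankings by default —
they reflect backbone adjacency, not tertiary contacts — while inter-chain
pairs have no separation filter. `consensus_contacts()` intersects the
top-n pairs of each scorer and annotates per-method ranks.

# Topology filter and structural classification

Membrane geometry enters as a per-residue coordinate along the membrane
normal (z), read from a membrane-oriented PDB (Cα records) and/or a plain
(chain, position, z) table; the table wins where both are given, and
per-chain offsets reconcile author numbering with alignment coordinates.
A predicted contact is kept only if its residues are **strictly less than
15 Å apart along z** — subunits cannot touch across the bilayer. Removed
contacts stay in the output, labelled, so plots can show both populations.

Contacts mapped onto a structure are classified:
`spurious` if dz > 15 Å (this rule is evaluated first: such a pair is
impossible under any conformation, whatever its 3D distance);
otherwise `consistent` if the Cα–Cα distance is ≤ 12 Å,
`alternative_conformer` for (12, 20] Å, and `inter_subunit_candidate`
above 20 Å. A contact at dz exactly 15 is *not* spurious (the rule says
"greater than 15") yet *is* removed by the keep-filter (strictly "less
than 15"); the two boundary behaviors follow each rule's own wording and
are kept as documented, deliberate choices. Contacts in the 12–15 Å dz
range fall through to the distance bins — the z rule only fires above
15 Å.

# Phylogenetic subsets and logos

Family subsets (e.g. TatA vs TatB vs TatA-basal) are obtained by distance
methods on fractional identity over a chosen column region (both-gap
columns unscored): neighbour joining (negative branch lengths clamped to
zero) or UPGMA, then either `k_groups` — remove the k−1 longest internal
edges and take components, a reproducible surrogate for assigning subsets
by eye on a cladogram — or an ultrametric height cut. Co-occurrence
filtering keeps only members whose organism also appears in a partner
subset (the "only genuine three-component systems" criterion), and
`cooccurrence_stats()` reports directed percentages between subsets, with
an empty source subset reported as undefined rather than 0.

Logo statistics use the 20-letter alphabet with gaps excluded from the
numerator (WebLogo-style), reporting per-column coverage and
$IC = \log_2 20 - H$ bits; an all-gap column has no defined IC. The
Miller–Madow small-sample correction is available but off by default,
matching common logo practice.

# The synthetic generator

`simulate_paired_msa()` generates the study conditions the analysis
assumes, not a maximally realistic protein family:

* a shared species tree (Yule, birth rate 1, or a star), organism IDs
  emitted in UniProt `OX=` headers;
* an ancestral concatenated sequence evolved down the tree, substitutions
  independent per column at `mutation_rate` (default 0.05 per unit branch
  length — giving, on a 500-leaf Yule tree, the 40–70% pairwise identity
  band typical of a curated family alignment, and an
  $M_\mathrm{eff}/N$ ratio near 0.1);
* planted compensatory couplings: at a pair with strength $s$, a
  substitution at one member is followed with probability $s$ by a fixed
  residue bijection applied at the partner. This gives tunable, analysable
  covariation at desk scale; it is deliberately *not* a Potts sampler, so
  absolute coupling magnitudes are not calibrated to any real family —
  only ordering and recovery properties are meaningful;
* invariant anchor columns (a hinge-glycine analogue in chain A at column
  2, a glutamate analogue in chain B), excluded from mutation;
* optional deep subfamilies: independent Yule subtrees normalised to unit
  height and joined by stems of length 3, each subfamily stamped with a
  distinct residue motif after evolution (paralog subfamilies are deep,
  well-separated clades — the regime in which subset analysis is
  meaningful at all);
* contamination applied last, to disjoint organisms, with deterministic
  counts (`round(rate × n)`): verbatim duplicate rows, rows whose partner
  record is deleted (this doubles as the co-occurrence dial: a 0.1
  unpaired rate means 90% of organisms with an A protein also have a B
  protein), and anchor violations. Accidental duplicates arising from
  evolution are resolved deterministically so that pipeline provenance
  counts can be compared to truth flags *exactly*.

Everything is driven by one seed; identical configurations produce
byte-identical files. What passing tests on this generator do **not**
show: robustness to alignment errors, indels (alignments are gapless by
construction), non-stationary substitution processes, or the LG/WAG-like
exchangeabilities of real proteins.

`make_toy_geometry()` builds a matching toy membrane geometry — a helical
Cα trace per chain spanning z ∈ [−20, 20] Å, planted pairs placed within
8 Å and dz < 15, decoys at dz > 15 — so the topology filter and classifier
can be exercised against known answers.

# Numerical choices and degenerate inputs

* Frequencies with $\lambda = 0$ on a single row reproduce exact empirical
  counts; marginal consistency of pair and single frequencies holds to
  1e-12 and is tested.
* A zero-variance score population makes the k-SD threshold equal the
  common value; with the "at or above" flagging convention every pair is
  then flagged, deterministically.
* An all-zero score matrix has no defined APC (grand mean 0); the raw
  matrix is returned with a warning.
* Ties in rankings are broken by (i, j) order, so consensus sets are
  deterministic.
* Covariance inversion failures raise an error that names the remedy
  (increase $\lambda$ or the ridge); glasso non-convergence raises an
  error carrying sweep diagnostics.

# Problem sizes

The validation suite and the acceptance script run, as the package's
standard study conditions: 500 organisms with chains of 30 + 60 columns
and 5 planted inter-chain pairs at $s = 0.9$ (recovery, null control at
$s = 0$, and three-method consensus; 3–5 replicate seeds), 300 sequences
for 3-subfamily recovery, and 200–500 organisms for contamination
bookkeeping. These sizes were chosen so that each property is measured on
a problem large enough for the asymptotics to bite (e.g. $M_\mathrm{eff}$
≈ 45 after weighting at N = 500) while a full validation run completes in
a few minutes on one core.

# Known limitations

* The pseudo-precision is a monotone rescaling, not a calibrated
  probability; compare runs by APC score when in doubt.
* The sparse scorer's approximate convergence trades a last ~2% of score
  correlation for an order of magnitude in wall time; `tol`, `max_sweeps`
  and `inner_max` expose the trade.
* `height_cut` subsetting assumes an ultrametric (UPGMA) tree; on an
  unrooted NJ tree use `k_groups`.
* Restraint export writes unambiguous per-pair restraints (CASP RR or a
  chain-qualified table); ambiguous/group restraints are out of scope.
* The generator's contamination model flags each row with a single cause;
  overlapping contamination of one organism is deliberately not generated,
  which is what makes exact provenance reconciliation possible.
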
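---
title: "LoCoHD: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LoCoHD: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The metric

Most structure-comparison scores (RMSD, GDT, lDDT, TM-score) compare
coordinates or distance matrices and are blind to chemistry: a lysine
swinging into a pocket and an isoleucine doing the same are equivalent
displacements. The local composition Hellinger distance (LoCoHD) compares
instead *what chemistry surrounds a point*. A structure is first mapped to a
cloud of **primitive atoms** — points labeled from a small chemical alphabet
— and the environment of an anchor atom $i$ is summarized at every radius
$r$ by its **distance-dependent environmental composition** (DDEC)
$\Phi_i(r)$: the fraction of each primitive type among the cloud atoms
within $r$ of the anchor (anchor included, so $\Phi_i$ is defined for all
$r \ge 0$). Two anchors are compared by

$$\mathrm{LoCoHD}_{ij} \;=\; \int_0^\infty w(r)\,
  H\!\left(\Phi_i(r), \Phi_j(r)\right)\,\mathrm{d}r ,$$

where $H(p,q) = \sqrt{\tfrac12 \sum_k (\sqrt{p_k}-\sqrt{q_k})^2}$ is the
Hellinger distance between the two composition vectors and $w$ is a
probability density over radii. Because $H \in [0,1]$ and $w$ integrates to
1, the score is in $[0,1]$; because $H$ is a metric and the score is a fixed
positive mixture of metrics evaluated radius by radius, LoCoHD is a
pseudo-metric on environments (symmetry and the triangle inequality are
property-tested over random environments).

Compositions only change when the growing sphere crosses an atom, so the
integrand is piecewise constant. With the merged neighbor distances of both
environments $r_1 < \dots < r_{N-1}$ (duplicates collapsed), $r_0 = 0$,
$r_N = \infty$, the package evaluates the exact closed form
$\sum_n H_n\,(W(r_{n+1}) - W(r_n))$ with $W$ the cumulative weight and
$W(\infty) = 1$. On the interval above $r_n$ the compositions count atoms at
distance $\le r_n$ — the convention forced by the published worked example,
where $\Phi(4\,\text{Å})$ already counts an atom at $3\,\text{Å}$. The same
example fixes two more conventions adopted here: the anchor counts in its
own composition at every radius, and under hetero-residue filtering
(dropping neighbors from the anchor's own residue, which would otherwise
add a residue-type-dependent similarity bias at short range) the anchor
itself is exempt.

## Tunable parameters

* **Weight function** — only the uniform family ships: $w$ constant on
  $[w_{\min}, w_{\max}]$, default $3$–$10$ Å, the setting used for every
  published analysis. Below ~3 Å covalent geometry dominates and
  environments are trivially similar; beyond ~10 Å the environment stops
  being "local". The contract accepts any cumulative-form weight, so other
  families can be added without touching the scoring code.
* **Truncation radius** — default $w_{\max}$. Atoms beyond the support
  upper bound cannot change the score (they only extend intervals of zero
  weight); this is asserted as a test property, so truncating exactly at
  $w_{\max}$ is safe and cheap.
* **Typing scheme** — `FA` types every heavy atom over
  {O_neg, O_neu, N_pos, N_neu, C_ali, C_aro, S}; `CG` maps chemical groups
  to single sites over {AmideC, OH, Pos, Neg, Aro, Ali, S}, some of them
  group centroids (e.g. the Asp carboxylate O pair, the Trp rings — one
  site per ring). `+Cent` variants add a per-residue heavy-atom-centroid
  pseudo-atom, which is what makes *any* residue comparable to *any* other
  (centroid anchors), and is required by the model-quality, trajectory and
  random-pair protocols.
* **Anchors** — `all_primitive` (ensembles of the same protein) or
  `centroid` (cross-residue comparisons).

Only example assignments of the typing tables were ever published (Glu
side-chain O → O_neg, Ser hydroxyl O → O_neu, the Trp 5-ring group, the Asp
carboxylate group). The full 20-residue tables shipped in
`inst/extdata/typing_{fa,cg}.tsv` are therefore this package's own,
documented completion, built on standard pH-7 protonation chemistry:
Arg/Lys positive, Asp/Glu (and the C-terminal carboxylate O/OXT pair)
negative, His neutral and treated as aromatic, amide N/O neutral, FA
backbone and carbonyl carbons C_ali (FA has no carbonyl-carbon type). The
published "serine Oδ" is read as the serine hydroxyl oxygen (PDB name OG).
Exact numeric parity with the original implementation on full structures
can therefore not be assumed; the tables are plain-text data and fully
overridable (`scheme_file`), so an alternative published table can be
dropped in without code changes. Group sites are computed from whichever
member atoms are present (≥ 1), keeping truncated experimental side chains
usable; incomplete groups are reported.

## Workflows

* **Ensembles** — every structure against every other at every primitive
  anchor ($M \cdot N(N-1)/2$ scores), yielding per-anchor $N \times N$
  matrices, their mean matrix, and per-anchor means. RMSD matrices use the
  same primitive-atom coordinates under Kabsch/SVD superposition with the
  determinant correction (a `ca_only` flag exists for comparison), and
  complete-linkage clustering (`stats::hclust`) cuts either at a threshold
  or at a fixed $k$.
* **Model vs reference** — chains are paired by global sequence alignment
  (match +1 / mismatch −1 / gap −2; greedy assignment by score, minimum
  identity 0.3), structures pruned to their common residue/atom inventory,
  residues scored through centroid anchors, and externally computed
  per-residue scores (e.g. lDDT — never computed here) joined by residue
  identity. Residues without an external value are dropped from the
  summary statistics and counted, not zero-filled.
* **Trajectories** — each strided frame against a reference frame at
  centroid anchors. Bimodality screening uses Sarle's coefficient
  $\beta = (\gamma^2 + 1)/\kappa$ with divisor-$n$ central moments and
  *non-excess* kurtosis; the published uniform-distribution reference
  0.555 ($= 5/9$) forces both conventions (excess kurtosis would make the
  uniform denominator negative). The reference frame's self-comparison is
  identically zero by construction and is not a draw from the anchor's
  score distribution, so the ranking excludes it.
* **Random residue pairs** — the structure list is shuffled (seeded),
  successive disjoint structure pairs are taken, and each residue of the
  smaller structure is paired injectively (without replacement) with a
  random residue of the larger. Scores are fitted with a maximum-likelihood
  Beta distribution (moment start, relative tolerance $10^{-8}$); the KS
  statistic is computed against the fitted law *without* a refitting
  correction — matching the published usage — which makes the p-values
  anti-conservative; they should be read as descriptive. The per-type-pair
  descriptor table reports mean, median, SD (divisor $n-1$), min, max and a
  confidence half-width $1.6449 \cdot s/\sqrt{n}$: the published CI column
  is reproduced cell for cell by this rule (a shipped regression test over
  all ten printed rows), which is how the ambiguous caption "two sided
  confidence intervals … with a 95% upper confidence bound" was resolved.

## Numerical choices

* Breakpoints coinciding across the two environments merge into a single
  breakpoint; ties within one environment are stably sorted in cloud order
  (compositions are order-free, so this only stabilizes output bytes).
* The validation oracle integrates $\int w\,H\,\mathrm{d}r$ numerically on
  a partition no coarser than $10^{-3}$ Å that is additionally split at
  every neighbor distance, evaluating the integrand at cell midpoints with
  an independent dense-comparison counting routine. For a piecewise
  constant integrand this refined midpoint rule is exact to floating
  precision; a blind $10^{-3}$ grid would carry $O(10^{-4})$ error per
  breakpoint and could never certify the $10^{-6}$ agreement that the test
  suite demands.
* Alternate locations keep the highest-occupancy conformer (ties: first
  altloc id); non-canonical residues (including MSE) are removed, not
  remapped; an optional policy flag drops zero-occupancy atoms — the
  removal of "disordered elements" from reference structures has no
  published criterion, so exact preprocessing parity is not guaranteed.
* Spearman correlations are undefined (NA), never 0, on constant input.
  Beta-fit input at exactly 0 or 1 is clipped inward by $10^{-9}$ with a
  warning.
* Degenerate compositions cannot occur: the anchor guarantees a non-empty
  sphere at every radius.

## Synthetic data: what a green test establishes

The fixture generator emulates only what the algorithms consume: correct
PDB records, correct atom names, residues in plausible relative positions,
Gaussian coordinate noise, rigidly shifted sub-domains (planted clusters)
and a side-chain displacement from a chosen frame on (planted two-state
switch). Side chains are placeholders at approximate geometry, not
rotamers; noise is iid and isotropic, unlike correlated thermal motion;
nothing is energy-minimized. Green planted-truth tests therefore establish
algorithmic correctness (recovery of structure the generator put in), not
biophysical validity on real ensembles. Conversely the published values
that depend on downloaded PDB/PED/CASP sets and on the authors' full typing
tables (extreme random-pair scores 5.38%/79.23%, E5 ensemble medians
7.4%/15.1%, the Gag-Pol LoCoHD–RMSD Spearman 0.24, the CASP14 AlphaFold2
median prm-LoCoHD 0.0814) ship only as a documented tolerance-band audit
(`parity_targets()` / `parity_audit()`, ±2 LoCoHD percentage points, ±0.05
on correlations) to be run when those inputs are available.

## Known limitations

* Typing tables are a documented reconstruction (see above); parity audits
  against the original implementation should expect small residuals.
* Only the uniform weight family ships.
* No ligand/nucleic-acid typing, no structure repair or protonation, no
  symmetry expansion; binary trajectory formats are expected to be
  exported to multi-model PDB upstream.
* Centroid anchors summarize a whole residue by one point; a rotamer flip
  that preserves the centroid's chemical neighborhood can score near zero.
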
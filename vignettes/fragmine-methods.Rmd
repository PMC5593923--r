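---
title: "Mining maximal substructures and electing privileged fragments"
author: "fragmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining maximal substructures and electing privileged fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmine)
```

## The problem

Fragment-based drug discovery asks two questions of a focused compound
library: which substructures ("privileged fragments") are responsible for
activity against the target, and how are those fragments combined into
whole ligands?  fragmine answers both with a pipeline built around frequent
*maximal* substructure mining: rather than enumerating every frequent
subgraph (a molecule with $n$ bonds has up to $2^n - 1$ connected
substructures), it reports only substructures that cannot be extended by a
single bond without losing part of their supporting molecule set.

## The molecular graph model

Molecules are hydrogen-suppressed labeled graphs.  An atom is labeled by
(element, formal charge, aromatic flag); a bond by its order, with aromatic
as its own order.  Stereochemistry is deliberately ignored: matching and
mining operate on 2-D connectivity only.  Fragments — connected
bond-induced subgraphs — carry a canonical string key computed by iterative
neighborhood-label refinement (Morgan-style) followed by exhaustive
individualization of residual symmetric color classes; the emitted string
is the lexicographic minimum over all refinement-consistent orderings, so
key equality is exactly labeled-graph isomorphism.  An exact canonical key
is mandatory because the mining registry, descriptor dictionary and rule
aggregation all rely on plain string equality.

## The search tree, subIDs, and pruning

Mining grows one depth-first tree per *root fragment* (each distinct
single-bond type in the library).  Every node is annotated with a *subID*:
the list of all embeddings of its fragment, each written as a molecule id
plus the covered bond ids.  Two properties make subIDs powerful:

* roots enumerate every occurrence of their bond type, and extending every
  embedding by every adjacent bond preserves completeness, so a node's
  subID always lists *all* embeddings of its fragment — identical fragments
  have identical subIDs wherever they appear in the forest;
* the subID's canonical string therefore doubles as an isomorphism check:
  a node whose string is already in the registry of reported substructures
  is pruned, subtree and all, without any subgraph matching.

A node is a *potential reporting node* (PRN) when no child preserves its
full molecule-support set; leaves are PRNs vacuously.  A PRN with
popularity (number of distinct supporting molecules) at least the threshold
`t` is reported.  Support is antitone under extension, so children below
the threshold are never expanded.  The reported set provably equals the
brute-force "maximal frequent" set — frequent fragments with no frequent
one-bond extension of identical support — and the test suite verifies this
equivalence against exhaustive enumeration on twenty random libraries.

Two post-passes complete the mining stage: *FFID collapse* groups reported
fragments by their supporting molecule multiset (a subID with bond ids
removed) and keeps only the larger of two nested fragments in a group; the
*integrity filter* removes fragments that cut through an aromatic ring — a
fragment containing an aromatic bond is kept only if, in each supporting
molecule, some minimum-length aromatic ring through that bond lies entirely
inside the fragment.  Whether such fragments should be repaired or dropped
is not settled by the source material; dropping is implemented because a
completed ring is already reported by a different branch whenever it is
frequent.

Choices worth recording:

* the PRN condition compares molecule-support sets, not bond-level subIDs
  (a child always differs at bond level, which would make every node a
  PRN and defeat maximality);
* the reporting threshold is inclusive, `popularity >= t`, with `t >= 2`;
* pruning keys are exact subID strings, so the result is independent of
  traversal order (roots and children are visited in canonical-key order);
* a configurable fragment-size cap (default 20 bonds) bounds the search on
  pathological inputs.

## Descriptors

The *standard substructure dictionary* (SSD) is the mined fragment list
ordered by descending support and canonical key.  A library is vectorized
into the binary matrix $L$ with $L[i,j] = 1$ exactly when dictionary
fragment $i$ occurs as a subgraph of compound $j$; a count-valued variant
exists but the binary form is canonical.  Two frequency filters mirror
standard practice: a minimum presence fraction (default 5 %, boundary kept)
for classification descriptors, and a presence-count cut with the
descending frequency curve attached so the user can read off its
flattening point when trimming dictionaries for regression.

"Frequency" always means number of distinct molecules containing the
fragment, never total embedding count, consistent with the binary matrix.

## Ridge logistic regression

Activity classification maximizes

$$\ell(W) \;=\; \sum_{j} \big[ y_j\, W\!\cdot\!L_j - \log(1 + e^{W\cdot L_j}) \big] \;-\; \frac{1}{2\sigma^2}\lVert W\rVert^2,$$

the Bernoulli log-likelihood under a Gaussian prior of scale $\sigma$
(default 1).  The source equations print two mutually inconsistent penalty
coefficients and a non-smooth norm; the Gaussian-prior ridge form is the
one their derivation implies, and it is what is implemented.  The model has
no intercept — activity is scored purely from fragment content.  The
objective is strictly concave, so Newton iteration (logistic Hessian plus
ridge diagonal, step halving if a step would decrease the objective,
gradient-norm tolerance 1e-6, at most 100 iterations) converges to the
unique maximum; the test suite checks the fit against an independent BFGS
optimizer of the same objective to 1e-4 on weights.

Evaluation follows the random sub-sampling protocol: three random subsets,
two train and one validates (a 2:1 ratio), metrics averaged over repeats.
Sensitivity, specificity and accuracy are taken at probability threshold
0.5; ROC AUC uses the Mann–Whitney rank statistic with ties averaged and is
threshold-free.

## Support vector regression

Potency regression models pIC50 ($-\log_{10}$ of IC50 in molar; 1 µM = 6.0)
with epsilon-insensitive SVR under the RBF kernel
$k(x, x') = \exp(-\lVert x - x'\rVert^2 / 2\sigma^2)$.  The quadratic
program is solved by e1071 (libsvm); predictions are evaluated explicitly
as $f(x) = \sum_j \alpha_j k(x_j, x) + b$ from the stored support
coefficients, and the two routes are cross-checked in the tests.  No
hyperparameters are given by the source; the defaults are
$\sigma = \sqrt{n_\text{features}/2}$, box constraint 10 and epsilon 0.1,
with a small grid-search helper (`tune_svr`) as the explicit tuning path.
Validation is seeded k-fold (default 5) reporting mean squared error and
the Pearson correlation of predicted versus observed pIC50.

## Privileged fragments

Each fragment is scored with the privileged fragment index
$\mathrm{PFI}(i) = f_i \, a_i / T$ ($f_i$ molecules containing the
fragment, $a_i$ active molecules containing it, $T$ the library size) and
tested for enrichment in actives against a background library with the
one-tailed Fisher exact test on the 2×2 table (matched/unmatched in
actives vs. matched/unmatched in background).  The exact hypergeometric
tail is clamped below at 1e-300 because extreme enrichment underflows
double precision.  P-values are Benjamini–Hochberg adjusted; the election
gate is on adjusted values at $\alpha = 0.05$ by default (stricter than
gating on raw p, which remains available via `gate = "p"`).  Significant
fragments are ranked by descending PFI with canonical key as tie-break,
and each report row carries the active molecules it hits.

The definition of $a_i$ is ambiguous in the source (a literal reading
makes the index fragment-independent up to $f_i$); the
active-molecules-containing-the-fragment reading is used, as it is the only
one that ranks.

## Combination rules

Inside each active molecule, every pair of privileged fragments with
disjoint embeddings is classified by the most intimate relation available
among its embedding pairs: **merge** (shared atom) over **direct** (a bond
joining the two) over **linker** (the bonds of a shortest path between the
embeddings; ties broken by shortest length, then smallest canonical key of
the induced linker fragment).  A molecule votes once per pair; molecules
matched by exactly one privileged fragment produce **standalone** records.
Votes aggregate by (pair, relation, linker key) and rules are reported with
their supporting molecule counts, descending.  The relation taxonomy is
reverse-engineered from worked ligand-assembly examples; the original
pseudo-code is not printed in the available text, so this taxonomy is the
module's contract.

## The synthetic generator

No external compound collections are bundled; every benchmark runs on
seeded synthetic libraries that emulate a bioactivity-database-style
focused library:
a few hundred molecules, planted privileged fragments, IC50 tied to
fragment content.  The catalog holds 31 mutually non-nested ring fragments
(aromatic and aliphatic five- and six-membered rings over C/N/O/S
substitution patterns); same-size rings with different atom patterns cannot
contain one another, which keeps descriptor columns from being nested by
construction.  Molecules are assembled by joining sampled fragments through
random 0–2-carbon linkers at carbon atoms with spare valence (a small
valence table — C 4, N 3, O 2, S 6, aromatic bonds counted 1.5 except 1 at
O/S — is enforced on every emitted molecule), plus class-independent decoy
fragments and optional decoy chains.

Activity follows the planted model: actives carry each causal fragment with
probability 0.65 (inactives 0.10); active pIC50 =
baseline + Σ effects·presence + N(0, sd), truncated so IC50 ≤ 10,000 nM;
inactive IC50 is log-uniform on (10⁴, 10⁶] nM, so the 10 µM classification
threshold reproduces the planted classes exactly.  The benchmark
configurations are fixed study conditions: classification (600 molecules,
30-fragment dictionary, 5 causal fragments with effects 1.5–0.6),
regression (300 potency-graded molecules — prevalence 1, a deliberate
boundary relaxation of the otherwise open prevalence interval — with
effects +1.5 and +1.0 and noise sd 0.2 over baseline 5), rules (a planted
one-carbon linker joining two rings in 70 % of actives), and a neutral
background library standing in the role a large public compound collection
plays for enrichment testing.

What the generator does **not** emulate: realistic medicinal-chemistry
diversity, fused ring systems, tautomers, stereochemistry, or correlated
decoy structure.  Passing recovery benchmarks therefore demonstrates that
the pipeline's statistics and search are correct under their stated model,
not that the models transfer to any particular real target's chemistry.

## Numerical choices and problem sizes

* Canonicalization and matching are exact; all tie-breaks (salt-keeping,
  descriptor order, report order, linker choice) are lexicographic on
  canonical keys, making every output deterministic given input order.
* Mining benchmarks use twenty random libraries of 5–25 molecules with at
  most 10 bonds each, small enough that exhaustive enumeration
  (`enumerate_connected_subgraphs`) is a feasible ground truth; the
  canonical-key tests check all pairs of random fragments of up to six
  atoms against a full permutation-search isomorphism oracle.
* Model-recovery benchmarks use the generator's fixed configurations above;
  privileged-fragment and rule recovery are assessed across ten seeds.
* The end-to-end pipeline demonstration uses a compact 40-molecule library
  so that mining, modeling, election and rule discovery complete in
  seconds.

## Limitations

* Matching treats Kekulé and aromatic forms as distinct labelings; the
  bundled aromaticity perception covers only alternating six-membered
  rings, so SMILES input with five-membered aromatic rings stays Kekulé.
* The miner's registry holds reported substructures only; duplicate
  visits to unreported nodes are re-expanded (cost, never correctness).
* Pure-R graph algorithms keep the package dependency-light but limit
  practical mining to desk-scale libraries (hundreds of molecules), not
  million-compound corpora.
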
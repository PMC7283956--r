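---
title: "Behavior versus attribute features for drug-target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavior versus attribute features for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mandti` predicts drug-target interactions (DTIs) from a *molecular
associations network* (MAN): an undirected heterogeneous graph whose nodes
are drugs, proteins/targets, diseases, lncRNAs and miRNAs, and whose edges
are nine types of curated pairwise associations (drug-target, drug-disease,
protein-disease, lncRNA-target, lncRNA-disease, miRNA-target, miRNA-disease,
miRNA-lncRNA, protein-protein). The premise is that a molecule's *behavior*
— its pattern of connections across the whole network — carries more
predictive information about whether a drug binds a target than the
molecule's intrinsic *attributes* (a drug's substructure fingerprint, a
protein's sequence composition).

Behavior features are learned with the DeepWalk recipe:

1. **Truncated uniform random walks.** For each of $\gamma$ passes, every
   node of the graph (in a fresh seeded shuffle) roots one walk of at most
   $t$ nodes; each step moves to a uniformly random neighbor. Walks are
   over the *simple* graph: parallel edges under different relation types
   count once, and self-loops are skipped (a step onto itself adds no
   co-occurrence information). A walk stops early at a degree-0 node.
2. **Skip-gram.** The walks are treated as sentences. For a window of
   half-width $c$, each position $i$ contributes the pairs
   $(v_i, v_k)$, $k \in [i-c, i+c] \setminus \{i\}$, clipped at the walk
   ends. Training minimizes the per-pair loss
   $-\log P(v_k \mid \Phi(v_i))$ by stochastic gradient descent, where
   $\Phi(v) \in \mathbb{R}^d$ is the node's input vector. Two
   normalizations of $P$ are implemented: **negative sampling** (the
   default; $k$ noise words drawn from the unigram distribution raised to
   $3/4$) and **hierarchical softmax** (sigmoid decisions along the
   context word's Huffman path; `hs_leaf_probs()` demonstrates that the
   leaf probabilities sum to one). The published embedding is the input
   matrix; context/inner vectors stay internal, the universal word2vec
   convention.

Attribute features are the classical descriptors:

* **Proteins**: the 20 amino acids collapse into 4 side-chain-polarity
  categories — (A,V,L,I,M,F,W,P), (G,S,T,C,N,Q,Y), (R,K,H), (D,E) — and
  the sequence becomes the normalized frequency vector of its $4^3 = 64$
  reduced-alphabet 3-mers. The index of 3-mer $(c_0,c_1,c_2)$ is
  $16c_0 + 4c_1 + c_2$; any fixed bijection is statistically equivalent,
  this one is documented and tested. Windows containing a non-standard
  residue (B, J, O, U, X, Z) are skipped and the denominator adjusts;
  parsing is case-insensitive and `*` is stripped.
* **Drugs**: a precomputed substructure fingerprint bit-vector of a
  declared dialect — 166-bit MACCS keys or hashed circular (Morgan-style)
  bits of configurable length. The package consumes bitstrings rather
  than SMILES so the core has no cheminformatics-toolkit dependency;
  computing fingerprints is an upstream adapter concern.

A labeled pair dataset takes every drug-target edge as a positive and an
equal number of uniformly sampled drug-protein non-edges as negatives
(the balanced design the published fold sizes imply; the sampler itself is
unstated upstream, so uniform-over-non-edges is our documented choice).
Each pair's feature row is the drug vector followed by the protein vector
— the identical concatenation order for both representations.

## Evaluation protocol

Stratified 5-fold cross-validation: per-class fold sizes differ by at most
one, and class remainders are spread so *total* fold sizes also differ by
at most one (22,214 balanced rows split as 4443, 4443, 4443, 4443, 4442).
Per fold we report Acc, TPR, TNR, PPV, MCC at the 0.5 score threshold and
the threshold-free ROC-AUC (trapezoid = Mann-Whitney with ties counted
half), then mean ± sample (n−1) standard deviation across folds. A metric
with a zero denominator is reported as `NA`, never silently as 0 — this
matters on tiny synthetic folds.

Classifiers are a contract (`fit`/`score`); the bundled implementations
delegate to `randomForest` (100 trees) and `e1071::svm` (RBF kernel,
Platt-scaled probabilities), with a plain logistic-regression separator
for linear probes. The representation comparison, not the classifier, is
the object of study.

**Leakage.** Whether test-fold interactions may influence the embedding is
a real design fork:

* `leakage = "strict"` (default): for every fold, the held-out positive
  drug-target edges are removed from the graph *before* walking and
  embedding, so the behavior features never see what they are asked to
  predict.
* `leakage = "global"`: one embedding of the full network is reused across
  folds — the protocol that a one-shot embedding of a complete database
  snapshot corresponds to, and almost certainly the cheaper protocol used
  for the published real-data numbers.

Strict mode costs k embeddings per experiment; both modes are exposed and
the default is the conservative one.

## The synthetic study conditions

Real MAN snapshots are aggregations of nine licensed databases and are not
shipped. Instead, a seedable planted-partition (stochastic block) generator
produces study conditions under which every stage is testable:

* 400 nodes (80 per type), $B = 4$ communities, within-community edge
  probability $p_{in} = 0.25$, between $p_{out} = 0.01$, for each of the
  nine relation types independently.
* Protein sequences are i.i.d. letters with composition
  $(1-\rho)\,\mathrm{uniform} + \rho\,\mathrm{profile}(community)$;
  community profiles are Dirichlet draws (concentration 0.8, one draw per
  run). Fingerprint bits switch on with probability
  $(1-\rho)\,q_f + \rho\,q_{f,b}$, base rates $q_f \sim U(0.05, 0.60)$ and
  block rates $q_{f,b} \sim \mathrm{Beta}(0.4, 0.4)$.
* The attribute signal dial defaults to $\rho = 0.4$: attributes carry
  real but weaker-than-topology information, which is the regime the
  method is about. 10% of drug-target edges are held out of the emitted
  graph and recorded as test positives in the ground-truth file.

What the generator does *not* emulate: heavy-tailed degree distributions,
database-specific biases, sequence homology structure, chemically valid
molecules. Passing tests on this fixture demonstrate that the machinery
learns planted link structure and that behavior features beat
community-correlated attribute features; they do not certify real-data
effect sizes.

**A ceiling worth knowing about.** In a stochastic block model, edges are
conditionally independent given the block labels. A held-out drug-target
pair is therefore indistinguishable, in distribution, from any other
same-block non-edge: the Bayes-optimal predictor is block co-membership.
Under the default conditions ~89% of positives are within-block and 25% of
uniform negatives are within-block, capping the achievable AUC near 0.82
regardless of the embedding. Observed strict-mode AUCs of ~0.70 for
behavior features sit sensibly below that ceiling, and well above the
~0.60 of the attribute arm at $\rho = 0.4$. The package therefore asserts
the *direction* of the comparison (behavior > attribute, stable across
seeded replicates) on synthetic data — effect magnitudes at desk scale are
generator properties, not reproductions of real-data values.

## Numerical and design choices

* Walk defaults $\gamma = 10$, $t = 40$; skip-gram defaults $d = 64$
  (matching the 64-dim protein attribute scale), $c = 5$, 5 epochs,
  learning rate 0.025 decayed linearly per pair to $10^{-4}$, negative
  sampling with $k = 5$. These are standard DeepWalk/word2vec magnitudes
  scaled for desk-size graphs; all are config.
* Negative sampling is the default objective (simpler, equally standard);
  hierarchical softmax is fully implemented and selectable. Frequent-word
  subsampling is off: walk corpora are near-uniform by construction since
  every node roots $\gamma$ walks.
* Embedding init is uniform in $[-0.5/d, 0.5/d]$ from a private
  deterministic RNG; training is single-threaded with a fixed pair order,
  so a fixed seed reproduces the matrix bit for bit. Walk generation uses
  R's RNG under a locally set seed that is restored afterwards.
* Huffman construction uses the two-queue method with stable tie-breaks,
  so the tree is deterministic for a given frequency vector.
* Node ids are namespaced `<type>:<raw_id>` to keep identifiers from
  different source databases distinct. Edges are undirected and
  unweighted. Self-loops (legal only for protein-protein) are retained in
  the edge set for bookkeeping but excluded from walker adjacency; both
  behaviors are visible in the graph object.
* Degenerate inputs: a walk from an isolated node is just that node; a
  sequence with no valid 3-mer window is an error naming the sequence; an
  infeasible negative-sample request is an error; single-class ROC input
  is an error rather than a silent 0.5.
* Test problem sizes (chosen so the default suite runs in minutes on one
  core): 100-node two-block graphs for embedding sanity, the 400-node
  default conditions for the five-replicate direction check, 15-25 nodes
  per type for plumbing tests.

## Limitations

* The strict leakage mode re-embeds per fold, multiplying embedding cost
  by k; for large graphs the global mode with an external holdout is the
  practical alternative.
* Uniform negative sampling ignores degree bias; real benchmark studies
  sometimes match negatives by degree, which typically lowers reported
  performance. The sampler is a single documented function and easy to
  swap.
* The attribute arm consumes precomputed fingerprints; nothing validates
  that a bitstring actually corresponds to a molecule.
* Multi-worker (thread-parallel) training is deliberately absent: the
  package favors bit-reproducibility over wall-clock speed at the scales
  it targets.
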
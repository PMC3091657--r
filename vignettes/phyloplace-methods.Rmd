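---
title: "Placing sequence fragments into fixed reference phylogenies: models and methods"
author: "phyloplace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing sequence fragments into fixed reference phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloplace)
```

## The problem

Environmental shotgun sequencing yields anonymous nucleotide fragments. For
fragments carrying a phylogenetic marker gene, a far more informative
alternative to similarity-based binning is *phylogenetic placement*: keep a
curated reference phylogeny fixed, and ask on which branch of that tree a
query sequence would attach with the highest likelihood. phyloplace
implements this placement engine together with the preprocessing a raw
nucleotide fragment needs before it can be scored (translation, profile
alignment, column trimming, concatenation), a bootstrap heuristic for
placement uncertainty, and a leave-one-out validation harness. A synthetic
data generator produces complete reference packages so every stage can be
exercised and tested without any external reference data.

## Model and likelihood engine

Sequences evolve under an empirical amino-acid substitution model: a
symmetric exchangeability matrix $S$ and equilibrium frequencies $\pi$
combine into the reversible rate matrix $Q_{ij} = c\,S_{ij}\pi_j$, with $c$
chosen so $-\sum_i \pi_i Q_{ii} = 1$ — branch lengths are then expected
substitutions per site. WAG is the default; RtREV, cpREV and BLOSUM62 (in
its rate-matrix form, not as a log-odds scoring matrix) are shipped
alongside it as plain-text data files, using the published values. Rate
heterogeneity across sites uses the discrete-Gamma approximation with $K=4$
equal-probability categories represented by their conditional means
(renormalized so the category mean is exactly 1). Whether to additionally
replace the models' published frequencies with alignment-derived ones is
left out deliberately; the published frequencies are used as-is.

The likelihood is the standard pruning algorithm. Internally the engine
works on the unrooted tree and maintains, for every branch, conditional
likelihood vectors toward *both* ends, so the likelihood can be read off any
branch as
$$ L = \sum_k \tfrac1K \sum_i \pi_i \, F^{(u)}_i \,[P_k(t)\,F^{(v)}]_i $$
with $P_k(t) = \exp(Q r_k t)$ assembled from a single symmetric
eigendecomposition per model. Underflow is handled by per-pattern scaling
factors accumulated in log space and shared across rate categories.
Alignment columns are compressed to unique site patterns; gaps, `X` and `*`
are missing data (all-ones partial vectors). Rooted input trees are unrooted
for placement (the model is reversible, so the root is unidentifiable) and
the stored root is used for reporting and taxonomy orientation.

**Reference fitting.** `fitReference()` optimizes all branch lengths by
repeated coordinate sweeps — each length by a derivative-free bracketed 1-D
search in $[10^{-8}, 20]$ with tolerance $10^{-6}$, visited depth-first so
both conditional vectors of the branch under optimization always reflect
every update already made (the log-likelihood is therefore monotone by
construction) — followed by the Gamma shape in $[0.02, 100]$, until the
total log-likelihood improves by less than $10^{-4}$. The bounds encode
saturation (a length of 20 expected substitutions is indistinguishable from
infinity) and numerical safety at zero; zero-length input branches are
admissible and clamp to $10^{-8}$. Non-convergence after 100 sweeps is an
error carrying the sweep trace rather than a silent result.

## Placement

For each query, every placement branch of the fitted reference is tried in
turn: a new node splits the branch into *distal* and *proximal* segments
(their sum always equals the original branch length) and the query hangs
from it on a *pendant* branch. Only these three lengths are re-optimized —
by coordinate sweeps starting from an even split and pendant 0.1, at most 8
rounds, stopping when the log-likelihood gains less than $10^{-6}$ — using
the cached conditional vectors at the branch ends; the reference tree and
its vectors are never touched. The best-scoring branch is reported, with the
full ranked table and like-weight ratios (normalized likelihood weights over
all evaluated branches). Ties closer than $10^{-9}$ log-units go to the
smallest branch id — ids themselves are a pure function of topology and leaf
labels (postorder from the alphabetically smallest leaf), so results and
jplace edge numbers are reproducible across runs and platforms.

Maximum-parsimony placement inserts the query the same way but scores each
insertion with uniform-cost Fitch parsimony over the 20-letter alphabet
(gaps and unknowns as wildcards), using directional Fitch set/count messages
so each branch costs O(sites); the minimal-score branch wins.

**Bootstrap heuristic.** Non-parametric bootstrap resamples post-trim
columns of the scored region with replacement. To keep replicate costs
proportional to uncertainty rather than tree size, only the top 10% of
branches (by the ranking on the original, non-resampled alignment; at least
one, always including the best branch — the fraction is applied with a
ceiling) are re-scored per replicate. Replicates re-score candidates under
the resampled column weights at the insertion lengths optimized on the
original alignment; the three lengths are not re-optimized per replicate.
This is a deliberate design choice — column resampling, not length jitter,
dominates placement uncertainty, and it makes per-replicate scoring an exact
reweighting — and it is applied identically in the full-branch-set
bootstrap, so heuristic and full supports are directly comparable. Each
replicate is awarded to its best candidate; support is the fraction of
replicates won, so supports sum to one over candidates.

## Preprocessing raw fragments

Nucleotide fragments are translated in all six frames (standard code;
codons containing a non-ACGT base give `X`; internal stops are kept as `*`
and treated as missing downstream; frames $-k$ translate the reverse
complement). Each frame is aligned to a per-column residue profile of the
reference alignment (pseudocount 0.1 per residue, background = model
frequencies) by glocal affine-gap dynamic programming — global in the
peptide, free reference flanks, gap open 11 and extend 1 on log-odds
emissions — and the best-scoring frame wins, ties resolved in frame order
+1, +2, +3, -1, -2, -3. The profile alignment plays the role an HMM aligner
would play in a production pipeline: it maps the query into the fixed
reference column space with fully specified, testable behavior; peptide
insertions relative to the reference are scored but discarded. An optional
detection threshold is the 99th percentile of scores of shuffled peptides.
Fragments with internal frameshifts yield at most their longest
consistent-frame piece; no frameshift correction is attempted.

Column trimming follows the conserved-block (Gblocks-style) parameter
scheme: with $n$ rows, a column is *conserved* when its most frequent
residue occurs in at least $b_1 = \lfloor n/2\rfloor + 1$ rows, *highly
conserved* at $b_2 = \max(\lceil 0.55\,n\rceil, b_1)$; columns with more
than half gaps are nonconserved and always removed (the "half" gap rule);
stretches of more than $b_3 = 15$ contiguous nonconserved columns are
rejected; surviving blocks are trimmed at both flanks up to the first highly
conserved position and dropped when shorter than $b_4 = 3$. Trimming is
idempotent. The mask is computed once on the reference alignment — not per
reference+query pair — which keeps the reference column space (and the
fitted reference) fixed for all queries; a single query row would shift the
gap fractions by at most $1/(n+1)$. After masking, rows with fewer than 50
non-gap residues are dropped (inclusive threshold, counting residues rather
than aligned columns). When several markers share a reference taxon set,
alignments are concatenated column-wise in a fixed marker order, missing
markers padded with gaps; with independent sites the concatenated
log-likelihood is exactly the sum of the per-marker ones.

## Validation harness

Leave-one-out validation prunes the held-out taxon (or a whole clade around
it) from the reference, fragments its genome into non-overlapping 1000-nt
windows (a trailing remainder shorter than the window is discarded), runs
the full preprocessing chain against the pruned reference, places each
surviving fragment, and scores it by *node distance* — the number of
internal nodes strictly between observed and true branch (0 = same branch;
1 = branches sharing an endpoint; pinned exactly by a line-graph BFS oracle
in the tests, since "n nodes away" admits several conventions) — with
"correct" meaning at most two nodes away. Taxonomic assignment takes the
leaf set of the clade below the placement branch (leafward in the rooted
reporting orientation; the branch carrying the root maps to the whole tree)
and returns the longest lineage prefix on which all those leaves agree;
records carry the deepest rank at which that prefix matches the truth.
Aggregation reports the fraction placed exactly, the fraction within two
nodes, per-rank accuracy and per-branch counts, with optional per-fragment
weights (e.g. assembly depth), and ML/MP side by side.

## The synthetic-data generator

`simulateRefPackage()` builds a random unrooted topology (sequential random
attachment of tips to a uniformly chosen branch), exponential branch
lengths with mean 0.1 substitutions/site — a realistic scale for
single-marker reference trees, long enough for signal and short enough that
placement is not trivial — and evolves alignments from the equilibrium
frequencies down the tree with per-site discrete-Gamma rate categories
(shape 1 by default). Queries are planted on a known branch by bridge
sampling the ancestral state at the branch midpoint conditional on the
simulated states at both ends, then evolving along a pendant edge with the
same per-site rates, so query and reference come from one joint realization.
Synthetic genomes back-translate marker peptides with uniformly chosen
synonymous codons, embed them on random strands between uniform-ACGT
spacers, and record coordinates for truth checking. A 7-rank taxonomy is
derived from the tree (rank $r$ of a leaf is its ancestor at depth
$\min(r-1, \mathrm{depth}-1)$, the species rank the leaf itself), which is
nested by construction; deep ranks of shallow leaves are padded with the
parent clade.

What the generator deliberately does not emulate: insertions/deletions in
the homologous region (reference and truth alignments are gap-free, so the
profile aligner is tested on sub-fragment placement rather than indel
handling), sequencing error and frameshifts, compositional heterogeneity
across lineages, and paralogy. Passing tests therefore demonstrate the
correctness of the algorithms under the model's own assumptions, not
robustness to real-data pathologies such as eukaryotic introns or organellar
paralogs.

## Numerical choices and problem sizes

The test-suite and acceptance-script problem sizes are chosen to exercise
every code path at desk scale: exhaustive-enumeration likelihood oracles on
3-5 leaves; branch-length recovery at 5000 sites on 10 leaves (median
relative error below 15%); planted-query recovery on a 20-leaf, 300-column
package (50 trials); 50 random 8-leaf instances for the exact parsimony
cross-check; 20 seeds of progressively deeper clade pruning on 10-leaf
packages. Tie-breaks, bounds and tolerances are stated inline above; all
randomness flows through explicit seeds, and every generator function
restores the caller's RNG state.

## Known limitations

Placement assumes the query belongs to the marker family of the reference
package; the shuffle-null frame threshold is a weak stand-in for a real
homology pre-screen. The candidate-set bootstrap reuses original-alignment
insertion lengths (see above) and so slightly understates length-driven
uncertainty. Only binary reference trees are supported for parsimony
messages; likelihood tolerates the basal multifurcation of unrooted trees.
NEXUS/PhyloXML input, codon/nucleotide models, invariant-site mixtures and
topology search are out of scope: the reference topology is always kept
fixed.
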
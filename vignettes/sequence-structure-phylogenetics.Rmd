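---
title: "RNA sequence-structure phylogenetics: models, defaults, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RNA sequence-structure phylogenetics: models, defaults, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaphylo)
```

This vignette is the package's own account of its methods: the models and
procedures it implements, the tunable parameters with their defaults and
units, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

Ribosomal markers such as the 18S rRNA gene (~1.8 kb) and the internal
transcribed spacer 2 (ITS2, ~0.2–0.7 kb) fold into secondary structures
that are conserved across clades even where the sequence is not. For
fast-evolving markers this conservation is the best alignment signal
available: two positions that both open the third helix are homologous
even when their nucleotides disagree. The package operationalizes that
idea as a pipeline: predict a structure for every sequence by homology to
a template, encode (nucleotide, pairing state) jointly, and run alignment,
distance estimation and tree inference over the joint alphabet.

## Structure homology modeling and curation

A target's structure is predicted by *transfer*: template and target
nucleotide sequences are aligned globally (match +2, mismatch −1, a gap
run of length $k$ costs $6 + k$; all four numbers configurable via
`transfer_params()`), and a template pair $(i, j)$ is kept iff both $i$
and $j$ align to ungapped target positions whose residues can themselves
form a pair from {AU, UA, GC, CG, GU, UG}. The **transfer percentage** is
$100 \times \text{transferred} / \text{template pairs}$. Two readings of
"identical base pairings" are possible — endpoint co-alignment alone, or
co-alignment plus target pairability — and the package defaults to the
stricter, structure-valid one; `require_pairable = FALSE` selects the
other. Transfer uses one global alignment per template (no per-helix
realignment): the simplest faithful reading of single-template comparative
modeling.

With several templates, `best_template()` keeps the result with maximal
transfer percentage, ties to the earlier library entry. Curation applies a
minimum-length filter first, then discards records whose transfer (or, for
records carrying their own structures, whose *structural homology* to the
template, `structural_homology()`) is **strictly below** the threshold —
a record exactly at the cutoff is kept. Classical thresholds are 80% for
18S and 65% for ITS2; both are plain parameters here.

## The 12-letter encoding

Each position maps to one of $4 \times 3 = 12$ letters: nucleotide ×
{unpaired, paired-left, paired-right}. The default bijection (unpaired
A,C,G,U → A,C,G,T; paired-left → D,E,F,H; paired-right → I,K,L,M) is
mathematically arbitrary — any bijection onto amino-acid codes gives
identical analyses — so the table in force is serialized into every run
manifest and is overridable for interoperability with legacy tools.
Decoding reconstructs the pair table by matching left/right states as
brackets and fails loudly on unbalanced states. `N` residues either error
(strict mode) or become the wildcard `X`, which scores −2 against
everything (including itself) and is treated as missing data in
likelihood and parsimony. Gap columns carry no structural state: pairing
states are per-sequence facts, not per-column ones.

## Alignment over the encoded alphabet

Pairwise alignment is a three-state affine-gap dynamic program (Rcpp
kernel). The default 12×12 matrix scores +4 for an identical letter, +1
for the same nucleotide in a different pairing state, 0 for the same
pairing state with a different nucleotide, and −2 otherwise — sequence
agreement and structure agreement are rewarded independently, which is the
core of the method. Gap penalties default to open 6, extend 1 (a length-k
run costs $6 + k$); terminal gaps are penalized like internal ones
(`free_ends = TRUE` gives semi-global behavior). The traceback is
deterministic: diagonal over up over left. The progressive multiple
aligner builds an NJ guide tree from corrected pairwise distances and
merges profiles leaf-to-root, scoring column pairs by expected letter
score with gaps scoring zero ("once a gap, always a gap"). The guide tree
uses NJ rather than UPGMA for consistency with the inference modules.

## Distances

Over gap-free column pairs (pairwise deletion): the p-distance; the
12-state Jukes–Cantor correction
$d = -\tfrac{11}{12}\,\ln\!\big(1 - \tfrac{12}{11}p\big)$, undefined at
$p \ge 11/12$ where a saturation sentinel applies (`Inf`, or the finite
cap 40 = 2 × the ML search bound, which is what tree building receives,
with a warning — NJ needs finite arithmetic); and an ML distance that
maximizes $\sum_{\text{sites}} \log \pi_x P(t)_{xy}$ with
$P(t) = e^{Qt}$ by bounded one-dimensional search on $t \in [0, 20]$
(tolerance $10^{-8}$). Rate matrices are reversible 12×12 models
normalized to one expected substitution per unit time at stationarity;
the default is equal-rates (JC-12) with uniform frequencies, and arbitrary
matrices load from a plain-text exchangeability file. Γ rate variation
uses 4 equal-probability categories represented by their means (checked
against the independent `phangorn` implementation in the tests), plus an
optional invariant-site class.

## Tree inference

**Neighbor joining** is the standard Saitou–Nei agglomeration with the
rate-corrected criterion, negative branch estimates clamped to zero, and a
deterministic tie rule (lexicographically smallest label pair, clusters
labelled by their smallest member). **Bootstrap** resamples columns by
index — so supports are invariant under row reordering — and reports
integer percentages per reference bipartition; replicates on which the
builder fails are dropped and the effective count reported.

**Profile neighbor joining** iterates (default 3 rounds): build NJ on the
current units, bootstrap it, collapse every *maximal* clade with support
strictly above the threshold (default 75) into a profile of column
frequency vectors over 13 symbols (12 letters + gap); profiles caught in
later collapses merge into super-profiles. Unit-to-unit distances are
generalized p-distances $1 - \sum_k f_{1k} f_{2k}$ averaged over columns
where both units have gap frequency ≤ 0.5, then corrected. After the last
iteration each profile expands back to the NJ subtree it had when
collapsed, and its support is the bootstrap value of the matching clade in
the sequence-level overview NJ tree. The gap-mass rule and the
outermost-first collapse order are this package's choices where the
classical description is legend-level: outermost-first yields the fewest,
largest super-profiles. With a threshold of 100 no clade can qualify and
PNJ reduces exactly to NJ (asserted byte-for-byte in the tests after
removing support labels, which plain NJ does not carry).

**Parsimony** is Fitch over the 12 states with gaps as missing data
(equivalently: a missing tip never forces a union event, matching
per-column exclusion for pendant taxa); search is exhaustive to 8 taxa and
NNI hill-climbing from the NJ tree above that, keeping the incumbent on
ties so the search terminates. **Maximum likelihood** is Felsenstein
pruning with per-node scaling, Γ(4)+I mixing, empirical stationary
frequencies from alignment counts, per-branch one-dimensional
branch-length optimization (tolerance $10^{-6}$, ≤ 20 sweeps) alternating
with NNI rounds; the Γ shape and invariant fraction are optimized by
bounded one-dimensional search when requested. Exchangeabilities are
constrained equal by default; a full 12-state GTR optimization is out of
scope for the search (arbitrary fixed matrices are supported throughout).
Outgroup rooting requires the outgroup to be a clade of the unrooted tree
and places the root at the midpoint of the separating edge.

## The synthetic-data generator

The generator produces the study conditions the pipeline assumes: one
clade, one conserved structure, sequence divergence, and a minority of
defective records.

- `simulate_yule_tree(n, birth_rate, seed)`: pure birth, waiting time
  Exp($k\lambda$) while $k$ lineages exist, a final Exp($n\lambda$)
  interval so tips are contemporaneous (expected height
  $\sum_{k=2}^{n} 1/(k\lambda)$, checked by Monte Carlo).
- `simulate_root_structure(length, pair_fraction, seed)`: exactly
  $\lfloor \text{pair\_fraction} \times \text{length} \rfloor$ nested
  pairs grown helix-wise (stacking moves strongly favored, new helices
  bounded by the unpaired-nucleotide budget), hairpin loops ≥ 3 nt,
  canonical/wobble residues sampled with GC/AU twice the weight of GU.
- `evolve_alignment(tree, root, c, rate, seed)`: the structure is frozen
  across the tree; residues evolve by a jump process *within* the site's
  structural state at `rate` expected substitutions per site per unit
  branch length (default 0.25 — moderate rRNA-like divergence, giving
  pairwise paths of roughly 0.1–0.6 substitutions per site on a unit-rate
  Yule tree). At paired sites a substitution is compensated with
  probability `c` (default 1): the partner immediately switches to a
  pairing-restoring residue; the event rate is divided by $1 + c$ so
  compensation does not inflate the marginal substitution rate.
- `degrade_dataset()`: a seeded `round(frac * n)` of records is truncated
  (`short_factor` of the length kept, pairs across the cut opened); a
  disjoint fraction has part of its pairs rewired (structure scrambled,
  sequence untouched), with every injected defect recorded in a truth
  table.

What this emulates: conserved-structure clades with length- and
structure-defective records, exactly the situation the curation filters
address. What it does not: insertions and deletions (all simulated records
share coordinates, so multiple alignment is exercised on constructed
cases, not simulation), structural evolution (no helix gain/loss), base
composition heterogeneity across lineages, and alignment uncertainty in
the homology modeling of deeply diverged targets. Passing the simulation
tests therefore validates the inference machinery under the model's own
assumptions; it does not certify performance on real data where those
assumptions fail.

Two calibration caveats are deliberate. First, because evolution is
restricted to the four letters of a site's structural state, the 12-state
correction applied downstream slightly under-corrects at high divergence
(the restricted process saturates at $p = 3/4$ per structural state, the
12-state model at $11/12$); at the default rate the discrepancy is well
inside sampling error, and the distance-calibration check is run at low
divergence (rate 0.1, paths ≲ 0.3) with compensation off, where the
per-site process is exactly a 4-state Markov chain at the nominal rate.
Second, pure-birth trees regularly contain internal branches carrying on
the order of one expected substitution across the whole sequence; such
branches are statistically unidentifiable at any fixed length, which caps
topology-recovery rates below what a minimum-branch-length benchmark
would show. The acceptance suite reports the measured recovery rate
rather than conditioning the tree draw, since conditioning would change
the stated generating process.

## Numerical and interface choices

Coordinates are 1-based throughout (the R convention; CT files are
1-based by standard, and dot-bracket positions in reports match what a
user counts). Pair tables are partner vectors with 0 = unpaired and a
hard involution/nesting invariant; pseudoknots are rejected by default
(the encoding has only left/right states) and tolerated only at the
parsing layer behind a flag. Helix decomposition merges stacked pairs
across interruptions of at most `merge_limit` (default 2) unpaired
nucleotides per strand, and never across a branching position. ITS2
annotation thresholds are explicit because the field's descriptions are
qualitative: A-rich means A-fraction ≥ 0.5 over ≥ 3 nt (the longest such
window in the II–III spacer is reported), the UGGU search is exact-match
within 20 nt of the helix III apical loop on the 5′ strand only, and the
proximal stem is a single root helix enclosing at least two core helices
with exactly 2 unpaired nucleotides between its first and last pair.
Helix numbering follows 5′→3′ order of the core helices; a fifth helix is
simply core helix V, and side arms (child helices branching off a
numbered helix) are flagged, not numbered. When a structure is drawn
without its enclosing proximal stem, the root-level helices themselves
are the core — both representations occur in practice and both are
handled.

All randomness flows from one integer seed through `with_seed()`, which
restores the caller's RNG state; bootstrap replicates, PNJ iterations and
the generator draw per-stream seeds derived from it, so every result in
the package is bit-reproducible from the command line. Problem sizes in
the test and acceptance suites (8–16 taxa at 300–2000 sites for
simulation checks; 3–4 taxa at ≤ 10 sites for brute-force oracle
comparisons; 100-seed recovery sweeps) were chosen so each check
completes in seconds while keeping the oracles exhaustive where
exhaustiveness is the point.

## Known limitations

De-novo structure prediction (energy minimization, constraint folding) is
out of scope: templates are inputs, obtained from databases or external
folding tools. The PNJ profile-distance formula and iteration bookkeeping
follow the legend-level description plus the explicit choices above;
other implementations may differ in the gap-mass rule and collapse order.
The ML search optimizes branch lengths and NNI topology only — no
subtree-pruning-regrafting — and equal exchangeabilities are the default
model; both are adequate at the subset sizes the pipeline targets but
not for large-scale ML analyses. Sequence-only analysis is available
generically by encoding everything unpaired (the 4-letter sub-alphabet),
not as a reimplementation of named DNA models.
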
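---
title: "Methods: reference-anchored orthology profiling and gain/loss analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-anchored orthology profiling and gain/loss analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`orthoprofile` implements a reference-anchored comparative-genomics
workflow for bacterial genome panels. One genome (in the motivating
application, *Streptomyces coelicolor*) serves as the anchor; each of its
proteins is classified in every other genome of a registry as
*orthologue*, *sub-threshold reciprocal hit*, or *absent*, and the
resulting presence/absence patterns are interpreted on a rooted species
phylogeny. Around this core sit a rare-codon (TTA) analysis, a
local-synteny score, divergence profiling against a universal-protein
control, one-way paralogue-family searches with neighbour-joining trees,
and a genome-evolution simulator that supplies ground truth for all of
the above.

The operating assumptions are those of classical reciprocal-best-hit
(RBH) orthology: genomes are fully annotated proteomes; orthologues are
usually each other's closest relatives in sequence space; duplications
that post-date the speciation of the two genomes being compared (in- and
out-paralogues) are the main source of error and reveal themselves as
non-reciprocal hits. RBH yields at most one call per reference gene and
genome; expanded families are handled separately by the one-way probe
search, which deliberately drops the reciprocity requirement.

# Alignment engine

Alignment is exact Smith–Waterman with Gotoh affine gaps, written in C++
for speed and wrapped by `local_align()`. Defaults follow blastp's
protein defaults — BLOSUM62, gap open 11, gap extend 1 — with a gap of
length $k$ costing $11 + k$. There is no heuristic seeding and no
E-value machinery: significance is delegated to the orthology thresholds
downstream, which is all RBH logic needs, and Karlin–Altschul calibration
would add parameters without changing any call.

Reported quantities mirror the overlap/identity readout familiar from
blastp displays: `overlap` counts only residue–residue columns (gap
columns are excluded), `identity_pct` is $100 \times$ matches/overlap,
and coverage is overlap divided by each sequence's length. Determinism is
part of the contract: the traceback starts at the first maximal cell in
row-major order and resolves ties preferring the diagonal move, then the
vertical, then the horizontal; local tracebacks stop at the first
zero-score cell. `X` (and codon-level `N`) scores zero against everything
and never counts as an identity.

`best_hit()` optionally screens targets with a shared 4-mer requirement.
The screen can only discard targets sharing no length-4 word with the
query, and `prefilter = FALSE` restores the exhaustive reference
behaviour; the test suite checks both paths agree on simulated genomes.

# Orthology calls and thresholds

A reciprocal pair is promoted to *orthologue* when percent identity is at
least 40 and the alignment overlap is at least 0.6 of the shorter
protein. The identity floor follows the conventional working cutoff for
confident bacterial orthologues over these evolutionary distances (hits
in the 20–40% band are exactly the ones that need synteny rescue); the
overlap floor guards against high-identity domain-only matches being
promoted on the strength of a short segment. Both are `orthology_thresholds()`
parameters, and the three-state design keeps sub-threshold reciprocal
pairs visible (the "grey boxes") rather than silently dropping them,
because they carry real signal that the synteny and divergence modules
can adjudicate. Best-hit ties are resolved deterministically (higher
identity, then lexicographically smaller gene id) so profile matrices are
reproducible byte for byte.

Whether the classification should use bit score or identity was left
open by the workflow this package systematises; both values are retained
on every call, so either rule can be replayed, and identity was chosen
for the default because it is the quantity the thresholds are stated in.
Sub-threshold hits are excluded from conserved-TTA denominators by
default (configurable), since a TTA in a dubious orthologue is weak
evidence.

# TTA codon analysis

`scan_tta()` inspects frame-0 codons only: a TTA spanning a codon
boundary never counts, matching is case-insensitive, and codons
containing ambiguity characters never match. The 5′ positional-bias
statistic had to be made concrete here: the relative position of a
gene's first TTA is $(i - 1)/c$ for first TTA at codon $i$ of $c$ codons
(stop included), and the test counts genes with this value below $1/3$
against a one-sided exact binomial null with proportion $1/3$
(`stats::binom.test`). First-third enrichment was chosen over, say, a
rank test because "bias towards the start" is a statement about the 5′
portion of the gene, and the exact tail keeps small-$n$ genomes honest.
The conserved-TTA table includes a gene when at least 5 non-reference
genomes carry a TTA-bearing orthologue — an intentionally simple census
threshold, exposed as `min_other`.

# Local synteny

`synteny_score()` counts how many of the $2w$ genes flanking the
reference gene have their own orthologue within $w$ gene positions of
the partner gene, strand-agnostic and on the same replicon. Defaults
$w = 5$ and $s_{\min} = 2$ turn a qualitative "shows some local synteny"
judgement into a reproducible yes/no: one shared neighbour can be
coincidence (on a shuffled 200-gene genome the expected count is
$10 \times 11/200 \approx 0.55$), two rarely are, and a window of five
genes is the scale of bacterial operon conservation. Sub-threshold
neighbour calls count by default because synteny is precisely the rescue
evidence for weak hits. Replicons are linear arrays; circularity is not
modelled, so the two genes at a circular origin junction can lose up to
$w$ neighbours each — a documented limitation that does not affect
interior genes.

# Gain/loss reconstruction

`dollo_gain_loss()` follows the standard Dollo convention: the gain is
fixed on the edge above the MRCA of the present leaves (the root stem
when all are present), and losses are the stem edges of the maximal
all-absent subtrees inside the gain clade. This is the minimal loss set
for that gain placement, and placing the gain at the MRCA is itself
optimal because a higher gain only adds losses while a lower one cannot
cover all present leaves. Edges are identified by the sorted leaf set
below them (`edge_signatures()`), which is stable across tree
representations. `fitch_changes()` provides the unrestricted-change
counterpart via Hartigan's bottom-up algorithm, exact on multifurcating
trees. Trees are interpreted as rooted at their outermost Newick node,
with basal polytomies accepted; rooting is a user decision the package
never guesses.

# Divergence profiling

The control for a genome pair is the percent identity of the local
alignment of the two concatenations of the control orthologues, taken in
a fixed, stated gene order (permuting the order can change the local
alignment, so the order is normative). A protein's divergence ratio is
its own pairwise identity divided by the control identity; ratios well
below 1 flag proteins diverging faster than the housekeeping baseline.
The concatenated control is preferred to a per-gene average because it
weights proteins by length and smooths per-gene sampling noise.

# Paralogue families and trees

`paralog_family()` keeps every gene meeting the family thresholds
(identity ≥ 30%, alignment covering ≥ 0.6 of the probe), one-way,
probe's own genome included. The thresholds are permissive on purpose —
short, diverged families of small proteins are the use case — and are
exposed as parameters. `nj_tree()` computes p-distances
($1 -$ identity fraction) from all-vs-all local alignments and applies
Saitou–Nei neighbour joining (`ape::nj`), with an optional Poisson
correction $-\ln(1-p)$ for saturated families. Negative branch lengths,
which NJ can produce on non-additive inputs, are clamped to zero with a
message. Distance NJ was adopted for family trees as the simplest method
whose consistency can be verified exactly on additive matrices; exact
topology reproduction of any particular published family tree is not
claimed, since tree method details differ between implementations.

# The simulator and what passing tests mean

`simulate_genomes()` evolves integer-coded proteins down the species
tree. Per edge of length $b$: each family copy is lost with probability
$1-(1-p_{\text{loss}})^b$ and duplicated with probability
$1-(1-p_{\text{dup}})^b$; each site substitutes with probability
$1-e^{-\lambda b}$, replacement uniform over the 19 other residues. The
uniform-replacement chain was chosen over an empirical matrix because its
pairwise identity has a closed form — e.g. two branches of per-site
change probability $p$ give expected identity $(1-p)^2 + p^2/19$ — which
the calibration tests check to three Monte-Carlo standard errors at
length $10^4$. CDSs are back-translated with uniform synonymous choice
except that leucine is encoded as TTA with probability `tta_rate`; every
CDS ends with TAA and internal stops are never generated. Duplicates are
inserted adjacent to their parent gene so synteny tests have controlled
structure.

The bundled demo recipe (`demo_params()`) is a 12-leaf tree — a
reference clade, two progressively distant clades and one outgroup,
echoing the grouped structure of real actinobacterial panels — with 40
families, no duplications, loss probability 0.3 per unit branch length,
substitution intensity 1.2 (leaf-pair identities roughly 75–95%), and a
per-leucine TTA rate of 0.015, which puts TTAs in a minority of genes as
in GC-rich genomes. These settings were fixed once as a realistic
desk-scale stand-in for a genome panel.

What passing tests do show: the aligner is exactly optimal (checked
against an exhaustive DP oracle), RBH recovers all planted orthologues at
these identity levels without duplications, presence vectors equal
simulator truth, Dollo reconstructions are minimal and recover
homoplasy-free planted losses edge-exactly, and NJ is consistent on
additive matrices. What they do not show: behaviour under indel-rich
alignment (the simulator evolves full-length homologs without indels),
rate heterogeneity across sites, horizontal transfer, fragmented
assemblies, or annotation error. Conclusions about real genome panels
inherit those caveats.

# Numerical and interface choices

* Coordinates: annotation TSV is 1-based inclusive (GFF dialect);
  alignment spans are reported 0-based half-open; gene ordinals are
  0-based per replicon.
* Minus-strand CDSs are taken from the CDS FASTA as-is (already in
  coding orientation); the annotation strand is metadata.
* Translation validation uses the bacterial code (table 11); terminal
  stops are excluded from the comparison and ambiguity translates to `X`,
  which matches anything.
* All randomness flows from a single mandatory seed; the simulator
  restores the caller's RNG state.
* Degenerate inputs fail loudly: empty sequences, empty proteomes,
  all-absent presence vectors, fewer than three taxa for NJ, and missing
  TTA flags each raise a named error rather than returning a default.

# Problem sizes

The shipped verification suite uses 500 random pairs (length ≤ 12) for
the alignment oracle, the 12-genome demo simulation for end-to-end
recovery, 200 random trees of 4–8 leaves with exhaustive presence
vectors for Dollo minimality, 100 random additive matrices for NJ, and
single 10,000-residue families for simulator calibration — sizes chosen
so each property is checked densely at desk scale.
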
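---
title: "Methods: comparative effector-repertoire screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative effector-repertoire screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effectorscan)
```

# The problem and the model

Aphids and other sap-sucking insects deliver salivary effector proteins
into their host plants. Their salivary glands are located in the head, so
a practical proxy for "salivary-gland expressed" is *upregulated in head
versus body tissue*. The package chains five analyses:

* a head-vs-body differential expression (DE) call per transcript;
* an effector classification combining the DE direction with secretion
  annotations (signal peptide present, transmembrane domain absent);
* Markov clustering (MCL) of an all-vs-all protein similarity graph to
  delineate families, from which *core* (widely shared) and *pioneer*
  (lineage-specific, annotation-less) effector clusters are read off;
* reciprocal-best-hit (RBBH) 1:1 orthology between dataset pairs, grouped
  into orthologue groups;
* a pairwise Nei–Gojobori dN/dS screen over effector-containing groups,
  flagging median ω > 1 as candidate positive selection.

Every stage consumes plain tabular inputs (FASTA, tabular BLAST, counts +
design TSV, annotation TSV), so upstream predictors (signal peptide, TM,
NLS, database hits, Pfam) are treated strictly as data, never re-derived.

# Differential expression

TMM scaling factors are computed by the weighted trimmed mean of M-values
against a reference library (upper quartile closest to the mean upper
quartile; 30 % trim on M, 5 % on A; pairwise exclusion of zero-count
genes; geometric mean of factors fixed at 1). The computation is delegated
to edgeR's reference implementation of TMM and is verified in the test
suite against an independent step-by-step transcription of that
arithmetic. Note that the precision weights make the factors *almost*,
not exactly, invariant to rescaling a library's depth; the test suite
asserts invariance at 1 % tolerance.

TMM-FPKM is `count * 1e9 / (effective library size * transcript length)`
with effective size = column sum × TMM factor.

The DE test itself is a deliberately simple, fully documented procedure
rather than a reimplementation of any specific tool: counts are scaled to
equal effective library sizes, a single **common** negative-binomial
dispersion is estimated by a ratio-of-sums method of moments
(`sum(s² − m) / sum(m² − s²/n)` over transcript-by-tissue cells, floored
at 0 — the second term unbiases the denominator for the sampling noise of
the group mean), and the head and body tissue totals are compared with a
two-sided exact NB test conditional on their sum (probability-ordering
two-sided rule). Dispersion 0 degenerates to an exact binomial test.
Calls use the raw p-value at `p < 0.001`, strict inequality, with no
fold-change floor and no FDR step — the thresholding convention of the
head/body screens this pipeline targets. Transcripts with all-zero counts
are reported `ns` with p = 1. The cost of the simplification is that
tagwise (per-transcript) dispersion is not modelled; the benefit is an
exactly specified, unit-testable null, whose type-I rate at p < 0.001 is
confirmed by simulation to sit inside its binomial 99 % confidence band
(12,000-transcript null in the test suite, 6,000 in the acceptance
script).

A practical caveat verified during development: TMM assumes most
transcripts are not differentially expressed. If a large fraction of the
transcriptome is strongly head-biased (e.g. half of all transcripts at
8-fold), normalisation absorbs part of the signal and recall drops. The
power checks therefore run at a realistic effector fraction (0.2).

# Effector calling

`putative_effector` = head-up ∧ signal peptide ∧ ¬TM;
`other_secreted` = body-up ∧ signal peptide ∧ ¬TM; everything else
`none`. "Upregulated" means the DE direction only. NLS flags are copied
onto secreted calls. Ids absent from the annotation table are treated as
all-flags-no, with a warning, so a partial annotation run degrades
loudly but gracefully.

ORF completeness is a four-way partition from start/stop codon presence.
Repeat motifs (e.g. the NDNQGEE unit of the C002 effector family) are
counted by greedy non-overlapping left-to-right matching with a
configurable per-match mismatch budget; an overlapping mode exists behind
a flag but is off by default because repeat units are discrete.

# Clustering and cluster classes

Graph construction keeps edges with e-value ≤ 1e-35, drops self-hits,
transforms weights as −log₁₀(e-value) with e-value 0 capped at weight 200
(the standard stream transform for e-value-weighted MCL input), and merges
reciprocal edges keeping the larger weight. Sequences without any
surviving hit stay in the graph and become singleton clusters.

MCL is implemented in-package (dense matrices; the intended scale is
desk-size analyses and simulations): self-loops at each node's maximum
incident weight (1 for isolated nodes), column normalisation, then
expansion (matrix squaring), inflation (entrywise power, default 6),
pruning of entries < 1e-5, and renormalisation, until the largest entry
change falls below 1e-8 or 200 iterations (non-convergence returns the
current interpretation with a warning flag). Clusters are read off the
attractor structure; a node supported by several attractor components
deterministically joins the component holding the lexicographically
smallest attractor id. The implementation is checked against an
independently coded reference MCL on small fixtures, and its output is
always a partition. Prune threshold, tolerance and iteration cap are the
package's own choices for deterministic convergence at this scale.

A cluster *contains an effector* when it intersects the candidate id set
(this study's calls plus any published candidate lists, supplied as plain
id files). **Core** clusters are effector-containing clusters represented
by ≥ 5 of the 8 focal datasets; outgroup datasets never count. **Pioneer**
clusters are effector-containing clusters whose members all lack a
database hit at e ≤ 1e-5 and a Pfam-A domain and whose members are
confined to one species or one genus (dataset → species/genus maps are
explicit inputs).

# RBBH orthology

Within each directional edge set, hits must pass identity ≥ 70 % and
query coverage = 100·aln_length/query_length ≥ 50 % (each direction
filters on its own query, so a surviving pair satisfies coverage relative
to both sequences). The best hit per query is the maximum bitscore after
rounding to one decimal (BLAST reporting granularity); a query whose top
score is tied between two or more subjects contributes nothing — this is
what removes recent duplicates, whose near-identical copies tie. A pair
is emitted only if each side is the other's unique best. Pairs from all
dataset pairs are then grouped with the same MCL engine (inflation 6) on
abc-style edges; each edge is weighted by the smaller of the two
directional e-values (the two directions rarely agree exactly, and the
smaller one reflects the stronger evidence).

# Selection screen

Protein alignments are back-translated codon-by-codon onto their CDS
(trailing stop codons dropped; the CDS must translate exactly to the
ungapped protein). Trimming removes user-specified codon regions first —
e.g. a variable repeat-motif region, supplied in 1-based inclusive codon
coordinates — and then every codon column containing a gap, replacing
manual alignment curation with a deterministic, recordable operation.

`ng86()` implements the Nei–Gojobori (1986) counting method: per-codon
synonymous site fractions (changes creating stop codons count as
nonsynonymous so sites always sum to 3 per codon), averaged over the two
sequences; observed codon differences resolved by averaging over all
minimal mutational pathways with equal weights, excluding pathways
through stop codons (with an all-pathways fallback when every pathway is
blocked); Jukes–Cantor correction of both proportions. Pathway averaging
is proven equal, to 1e-12, to exhaustive pathway enumeration on all
sense-codon pairs and on random 50-codon sequences. A proportion at or
beyond the 3/4 saturation point maps to an infinite distance: ω is then 0
when only the synonymous side saturates, and undefined when the
nonsynonymous side does. ω is likewise undefined for dS = 0.

Groups are screened by running all unordered pairs and aggregating the
defined pairwise ω values by their **median** — robust to a single
aberrant pair and symmetric in the group members. The positive-selection
flag is `median ω > 1`. Pairs with dS = 0 but dN > 0 are reported as
"unbounded" and count as positive evidence only under an explicit
`flag_ds_zero` option (off by default, since ω is undefined there). This
pairwise counting screen is intentionally simpler than maximum-likelihood
codon models: it has no tree, no transition/transversion weighting, and
no site-level inference, but it is dependency-free, exactly testable, and
adequate for a > 1 screen, as the recovery simulations show.

# The synthetic generator

`simulate_repertoires()` emulates the study design the pipeline targets:
8 datasets (three genotypes of one species, a congeneric second species,
four further genera), 40 gene families present in each dataset with
probability 0.8 on a star phylogeny, 100-codon genes diverging by 0.05
proposed changes per site per branch, an effector fraction of 0.2,
a quarter of effector families seeded as single-dataset pioneers, NB
counts with dispersion 0.1 and 3 replicates per tissue, body-tissue
effector mean 500 and head/body fold change 8, and a 5 % chance of a
recent (identical-copy) duplication per family. These defaults are the
package's statement of a realistic aphid-like configuration; all of them
are explicit `sim_config()` fields.

Codon evolution uses acceptance–rejection on single-nucleotide proposals:
proposals creating stops are rejected; nonsynonymous proposals are
accepted with probability min(1, ω) and synonymous ones with
min(1, 1/ω). Scaling *both* acceptance probabilities keeps the realised
nonsynonymous:synonymous fixation ratio equal to ω on both sides of 1 —
with a one-sided rule, any ω ≥ 1 would collapse to neutral evolution and
positive selection could never be simulated. This is a transparent
generative stand-in, not a full mechanistic codon model: it has no
transition/transversion bias, no codon-frequency equilibrium, and no
indels, which is precisely why pairwise identity, best-hit structure and
NG86 counts behave analytically enough to make recovery testable.

Similarity edges for synthetic runs come from exact global identity after
equal-length truncation, with `bitscore = identity% × aln_length / 10`
and `e-value = 10^(−bitscore/2)` floored at 1e-180 — an arbitrary but
strictly monotone proxy, so thresholding, best-hit ranking and MCL
weighting are all well defined; ordered pairs below 20 % identity are
omitted. Random 100-residue proteins share ≈ 5 % identity, so unrelated
families produce no edges and ground-truth families are exactly
recoverable — which is what the end-to-end test asserts (effector calls,
clusters, core and pioneer clusters all equal to ground truth).

What passing these tests does **not** show about real data: no assembly
artefacts or fragmented transcripts, no annotation errors (labels are
exact), no indel/alignment uncertainty, no compositional extremes beyond
what TMM tolerates, and similarity scores that are a clean monotone
function of identity. The generator validates the pipeline's logic and
statistics, not the upstream predictors.

# Numerical conventions and problem sizes

* Percentages are rounded half away from zero at the requested precision;
  completeness percentages are nearest-integer against the full ORF set.
* DE ties at p = α are not called; direction requires a nonzero log2 fold
  change (computed on scaled tissue means with a 0.5-count prior).
* MCL: prune 1e-5, tolerance 1e-8, cap 200 iterations; cluster ids are
  renumbered by each cluster's lexicographically smallest member.
* RBBH bitscore ties are assessed after rounding to one decimal.
* Test-suite problem sizes, chosen to make stochastic assertions sharp at
  desk scale: 12,000-transcript DE null; 200 replicate codon pairs per ω
  regime (300 codons, total divergence 0.2); ten 4-member conserved-gene
  groups at ω = 0.1 (all medians < 0.3); full 61 × 61 sense-codon table
  plus 1,000 random 50-codon pairs for the NG86/enumeration equivalence;
  ≤ 10-node fixtures for MCL/reference equivalence; the default 8-dataset,
  40-family configuration for end-to-end recovery.

# Known limitations

* The DE stage models a common dispersion only; transcripts with unusual
  biological variability are tested at the pooled dispersion.
* The NG86 screen is pairwise and treeless; deep divergence (saturation)
  is reported, not modelled, and median aggregation can mask heterogeneous
  selection within a group.
* Dense-matrix MCL targets simulation- and fixture-scale graphs (up to a
  few thousand nodes), not complete proteome networks.
* The generator's star phylogeny makes pairwise divergence homogeneous;
  correlated (tree-structured) divergence is not exercised beyond the
  genotype/species labelling used for pioneer classification.
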
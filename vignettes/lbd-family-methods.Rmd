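---
title: "Methods: characterizing an LBD gene family"
author: "lbdfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing an LBD gene family}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbdfam)
```

This vignette is the package's account of its methods: the models and
rules each module implements, the tunable parameters and their defaults,
what the synthetic-data generators emulate (and do not), and the design
decisions taken where the underlying procedure left genuine freedom.

# The motif grammar

The LOB domain is treated as a three-block grammar scanned left to right:

* **C-block**: a fixed 15-residue frame `C X2 C X6 C X3 C`. Anchor
  positions must be literal cysteine (the ambiguity code X never matches
  an anchor); wildcard positions accept anything. All overlapping matches
  are reported, leftmost first.
* **GAS block**: anchor1 `F X2 [VA] H` followed downstream by anchor2
  `D P [VI] Y G`. The proline and glycine of anchor2 are treated as
  invariant in every mode; under the default strict grammar the D, [VI]
  and Y are also required, and a relaxed mode (`gas_strict = FALSE`)
  frees them. The scanner reports which anchors matched strictly.
* **Zipper**: hydrophobic anchors spaced `X6 / X3 / X6`. The anchor
  alphabet is `[LVI]`, not L alone: the hydrophobic anchor positions of
  documented Class I proteins are occupied by leucine, valine or
  isoleucine, and a strict-leucine grammar would misclassify them. A
  strict-L mode remains available (`zipper_alphabet = "L"`). The printed
  pattern `LX6LX3LX6L` has four anchors and that is the default
  (`n_zipper_anchors = 4`); descriptions of the motif as five hydrophobic
  residues exist, so the anchor count is configurable. A frame is
  *complete* when all anchors are hydrophobic; an *incomplete* frame
  (reported with `complete = FALSE`) needs at least
  `min_partial_anchors = 2` hydrophobic anchors. Complete frames are
  preferred: the scanner returns the first complete frame if one exists,
  else the first reportable partial frame.

Classification: **Class I** requires a C-block and a complete zipper
downstream within the gap limits; **Class II** a C-block whose downstream
zipper is incomplete or absent; **none** means no C-block. Among several
C-blocks the earliest one that admits a full downstream match is chosen.
The inter-block gap limits default to 120 residues (C-block to GAS) and
80 (GAS to zipper). No biological source fixes these numbers; they are
chosen to comfortably contain the observed alignment layout of the family
and are exposed in `motifGrammar()`. When the GAS block is missing the
zipper may sit anywhere within the *sum* of both limits after the
C-block, so a degraded GAS never flips a Class I call.

Conserved-block finding in subfamily alignments (`findConservedBlocks`)
reports maximal runs of at least 10 columns in which the majority residue
reaches 50% of the rows. Gap characters are excluded from the numerator
but kept in the denominator — a column must be conserved across the whole
membership, gapped rows included — which is the stricter and fully
deterministic reading of "homology within the members".

# The gene catalog

`parseLocusTable` reads the tab-delimited locus schema (the bundled
`table1_vvilbd.tsv` transcribes the published 50-gene grapevine catalog
verbatim). Chromosomes come from the two-digit field of the locus id;
"00" marks unplaced scaffolds and is reported as "Unknown" in
distributions.

**Locus length is `end − start`**, not `end − start + 1`. The reference
catalog's own arithmetic forces this: locus Vitvi13g00109 spans
1,022,072–1,022,675 and its published length is 603 nt, which only the
exclusive convention reproduces. This deviates from the usual 1-based
inclusive length and is documented on `locusLength()`.

Two known quirks of the reference table are transcribed, not corrected:
LBDIf10's span (10,904 bp) exceeds the stated family maximum of 6,437 bp,
and chromosome 11 carries LBDIi8 despite also being described as empty.
The fixture follows the table.

"Tandem array" has no published numeric definition; the default is
maximal runs of same-subclass genes with consecutive start-to-start gaps
≤ 100 kb and at least 2 members (both configurable). At these defaults
the dense subclass-If cluster on chromosome 13 (11 genes over 225 kb) is
recovered as a single array while cross-arm pairs are excluded.
"Nonsense" exons are accepted as an input GFF3 annotation flag
(`nonsense_exon=true`), never computed: no computable rule defines them.

# Phylogeny

The in-scope estimator is distance-based: p-distance (pairwise deletion
of gap sites) or its Poisson correction d = −ln(1 − p), followed by
Saitou–Nei neighbor joining implemented in the package with a
deterministic tie-break (lexicographically smallest representative label
pair at Q-minimum ties), so topologies are identical across platforms.
NJ is consistent on additive matrices — exact topology and branch
lengths — which the tests verify on 4- and 5-taxon cases, cross-checked
against the independent implementation in `ape`. A maximum-likelihood
JTT tree search is *not* reimplemented: likelihood searches are seeded
with NJ/BioNJ trees anyway, and a Newick tree produced externally can be
ingested directly (`supportTree` on any `phylo` with numeric node
labels).

`bootstrapTree` resamples alignment columns with replacement (100
replicates by default, seeded), rebuilds the NJ tree, and reports for
each internal bipartition of the **full-data tree** the percentage of
replicates containing it. Support is deliberately attached to the
full-data tree rather than a majority-rule consensus, matching how a
"bootstrap value of 70" is read off a single displayed tree; branches
below 30% are contracted to polytomies in the collapsed tree, but
pre-collapse supports are always retained — this is also how a published
tree can simultaneously collapse weak branches and still quote exact low
supports for particular clades.

Subclass assignment: a query joins subclass *s* when some clade with
support ≥ 70 contains it together with reference genes of subclass *s*
only. Lower-support pure clades yield `motif_needed` — the motif stream
must complement the phylogeny — and clades that mix reference subclasses
yield `unassigned` regardless of support. The two evidence streams
(phylogeny, motifs) are reported separately and never silently merged,
since no published weighting exists for combining them. Clades are the
nested clades of the tree as rooted/displayed, not arbitrary bipartition
sides: using complements would let a query inherit a subclass from a
clade it merely sits outside of.

Columns with < 95% site coverage are removed before distance estimation
(`filterColumns`). The Poisson correction is undefined at p ≥ 1 and the
pair is reported by name; alignments that saturated should be analysed
as p-distances.

# Orthology and Ka/Ks

`allVsAllHits` computes, per ordered pair, the optimal Smith–Waterman
local alignment (BLOSUM62, gap open 11 / extend 1, via Biostrings) and a
Karlin–Altschul e-value E = K·m·n·exp(−λS) with fixed gapped-BLOSUM62
parameters λ = 0.267, K = 0.041 and search space m·n. Parity with any
particular BLAST release is a non-goal; what matters — and what the
closed-loop tests pin down — is the filter's behaviour at the retention
thresholds: e-value **< 1e-20** and identity **> 40%**, both strict, with
"homology" read as percent identity over the aligned columns (the only
computable reading of a homology percentage; a similarity-based variant
can be obtained by supplying a different cutoff on the reported fields).
Best-hit score ties are broken by higher identity, then lexicographic
subject id, and flagged.

Orthologs are reciprocal best hits; the per-gene × species matrix
distinguishes `one_to_one` (RBH), `homolog_only` (retained hits but no
RBH) and `no_match`.

Ka/Ks is Nei–Gojobori (1986). Site counting classifies the three possible
changes at every codon position; changes creating a stop codon count as
nonsynonymous so each codon contributes exactly 3 sites
(N + S = 3 × codons, an invariant the tests assert). Substitutions in
codons differing at several positions are averaged over all mutational
pathways, excluding pathways through intermediate stop codons (with a
fallback to all pathways when every one is blocked). Both proportions
receive the Jukes–Cantor correction d = −3/4 ln(1 − 4p/3), undefined at
p ≥ 3/4 (reported as NA); the ratio is NA when Ks = 0. The standard
genetic code only.

# Promoters

`extractPromoters` returns the window upstream of the translation start
on the coding strand (reverse-complemented for minus-strand genes),
truncated at the contig edge (flagged, not an error) and — with the
`noorf` option — at the nearest upstream annotated gene boundary, so
neighbouring ORFs are never included. The windows used by the three
classical analyses (1.5 kb, 3 kb, 2.5 kb) are all just values of
`window`; since it is unknowable whether historical runs anchored the
2.5-kb window at the ATG or the transcript start, the anchor here is
uniformly the translation start, stated openly.

Scanning is plain IUPAC class matching on both strands
(`Biostrings::matchPattern(fixed = FALSE)`), minus-strand hits reported
in plus-strand coordinates. Enrichment uses presence/absence per promoter
— robust to promoter-length differences — with a one-sided
hypergeometric upper-tail p-value for over-representation among targets
within targets + background; raw p-values with the conventional P < 0.01
call by default, Benjamini–Hochberg optionally. The bundled ~40-entry
dictionary of named cis-elements (ABRE, TCA-element, CGTCA-motif, ERE,
AuxRR-core, P-box, LTR, HSE, Skn-1, RY-element, HD-Zip, MRE, Box 4, ...)
carries IUPAC patterns compiled from the public promoter-element
literature; it is data, user-replaceable, and pattern correctness is not
a tested contract. The `de-novo-example` entry (GGTTGAATACAC) is a
synthetic stand-in used by the generators.

`kmerDiscovery` is a transparent substitute for de-novo motif search:
every k-mer present in the sequences (k = 6–12 by default) is tested with
the same hypergeometric, reverse-complement pairs merged under the
lexicographically smaller representative, ranked ascending by p. It finds
planted motifs reliably; it does not do position-weight-matrix
optimization or zero-or-one-per-sequence background normalization.

# Expression

Expression matrices are `SummarizedExperiment`s of log2 RMA-scale
intensities with tissue/condition/platform sample metadata. A gene
receives a tissue label when its **mean** over the tissue's replicate
samples reaches log2(256) = 8; the mean reflects that atlas values are
replicate averages, the comparison is inclusive ("above a threshold" is
ambiguous at the boundary; equality counts), and a `max` mode exists.

Co-expression: distance 1 − PCC, average-linkage agglomeration, tree cut
so merged groups have linkage distance **strictly below 0.2** (PCC >
0.8). Stated PCC "thresholds of 0.2" are read as shorthand for this
distance rule — the two differ, and the distance reading is the stricter
and operationally defined one. Zero-variance genes are excluded with a
warning (PCC undefined), singleton clusters are dropped, and clusters at
a smaller cut refine those at a larger one (the tests check this across
0.1 / 0.2 / 0.4). Condition contrasts are descriptive mean log2
differences only; no moderated tests, by design.

# The synthetic-data generators

Every generator is a pure function of a validated `SimConfig`; identical
seeds give byte-identical outputs, and each planted signal is returned as
ground truth so the matching analysis has a closed-loop recovery test.
Where no external value dictated a setting, the defaults below were
chosen once as realistic study conditions and the packaged analyses run
at them.

**Proteome** (`generateProteome`): Class I proteins are built as
N-terminus + C-block + GAS + complete zipper + tail; Class II identical
but with 1–2 zipper anchors replaced (≥ 2 intact, so the frame is found
but incomplete); decoys are anchor-free. Background residues — linkers,
termini, decoys — are drawn uniformly from the 15 amino acids that cannot
instantiate any anchor (no C, F, L, V, I) rather than all 20: a
20-letter background produces accidental C-blocks at ~10⁻³ per sequence
and accidental complete zipper frames at ~5×10⁻⁴ per position, which
would contradict the generator's own guarantee that decoys contain none
of the blocks and Class II proteins no complete zipper. The restricted
alphabet makes the planted structure provably the only structure; the
cost is a modestly unrealistic residue composition, acknowledged here.
Scale used by the packaged checks: 100 Class I + 100 Class II + 200
decoys, lengths 150–250.

**Gene catalogs** (`generateGeneModels`): background genes are spaced
150–400 kb apart and drawn from subclasses disjoint from the planted
arrays, so array membership is exactly recoverable at the planted gap
bound; arrays respect their `max_gap_bp` between consecutive starts.
Exon structures (1–4 exons, optional non-coding first exon) are emitted
as GFF3 gene/mRNA/exon/CDS features and returned as truth.

**Ortholog families** (`generateOrthologFamilies`): each of 20 ancestral
200-residue genes is copied into each of 3 species with i.i.d. point
substitutions at rate 0.05 (no indels — this keeps identity unambiguous
for the RBH tests and is deliberately not a realistic evolution model).
Losses (probability 0.1) give true `no_match`. Duplications (probability
0.1) must produce true `homolog_only`, i.e. broken reciprocity — and a
plain extra copy does *not* break it, because the query simply pairs
with the nearer copy. Duplication is therefore modeled as a chimeric
pair: the species' copy of gene *g* is replaced by two chimeras carrying
one third of ancestral *g* and two thirds of another gene *h*, with *h*
drawn from genes that are neither lost nor duplicated in that species.
The query *g* still finds the chimera (its best and only retained hit),
but the chimera's best match is *h*'s grapevine gene, and *h* itself is
unaffected because its full-length ortholog outranks the chimera in both
directions. One consequence is worth stating: under best-hit
reciprocity the globally top-scoring pair is always reciprocal, so a
family in which *every* gene is duplicated cannot be all
`homolog_only`; when no clean partner exists the generator degenerates
the duplication to a clean copy and records that in the truth table.

**Promoters** (`generatePromoters`): uniform random DNA (500 bp, 20 + 20
sequences) with the motif planted per sequence at the configured
frequencies and positions recorded. Null calibration runs use equal
frequencies 0.3/0.3 over 200 seeds; because hypergeometric p-values are
discrete and super-uniform, the calibration check is one-sided
(P(p ≤ α) ≤ α plus Monte-Carlo slack), not a two-sided uniformity test,
which a valid discrete test would rightly fail.

**Expression** (`generateExpression`): module genes share a latent
profile z with independent noise of variance (1 − ρ)/ρ, so the expected
pairwise PCC equals `module_pcc` analytically (0.95 by default, 3
modules × 6 genes over 6 tissues × 4 replicates); latent profiles are
independent across modules, so cross-module distances sit near 1.
Tissue-specific genes sit near log2 10 in their tissue and near 4
elsewhere with sd 0.3, comfortably clearing the threshold margins in
every sample. At ρ = 0.5 the expected within-module distance is 0.5,
far above the 0.2 cut, so those modules are constructively unrecoverable
— the packaged tests verify recovery at 0.95 (20 seeds) and
non-recovery at 0.5.

What the generators do **not** emulate: indel evolution, rate
heterogeneity, codon usage, GC bias, probe-level microarray noise,
cross-platform batch structure, or promoter composition beyond uniform
base frequencies. Passing the closed-loop tests therefore demonstrates
the correctness of the implemented rules under their stated statistical
assumptions, not robustness to every property of real data.

# Numerical and reproducibility choices

* All stochastic stages take explicit integer seeds; generators derive
  per-stage sub-seeds deterministically and restore the caller's RNG
  state.
* Ties are never left to platform ordering: NJ ties break
  lexicographically, best-hit ties by identity then id, cluster output
  by label order.
* Degenerate inputs error early with names: pairs with zero comparable
  sites, saturated distances (p ≥ 1), all-gap columns after filtering,
  ragged alignments, internal stop codons, non-disjoint
  target/background sets.
* The pipeline (`runPipeline`) rejects unknown configuration keys,
  aborts with the failing stage's name, and writes summaries whose bytes
  depend only on config + inputs.

# Known limitations

* The NJ + p/Poisson estimator is a stand-in for likelihood methods on
  real alignments; for publication-grade trees, import an externally
  computed tree and use `assignSubclasses` on it.
* E-values are calibrated by closed-loop behaviour, not by parity with a
  specific BLAST release; absolute e-values on real data will differ
  from BLAST's by a search-space-model factor.
* The cis-element dictionary is a curated convenience, not a database
  snapshot; treat per-motif biological annotations as labels.
* `kmerDiscovery` enumerates exact k-mers; degenerate motifs spread
  across variants lose power relative to PWM-based discovery.
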
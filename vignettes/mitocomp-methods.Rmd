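---
title: "Comparative mitogenomics with mitocomp: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

mitocomp is a toolbox for desk-scale comparative analysis of vertebrate
mitochondrial genomes. It covers five analysis stages — feature-table
arithmetic and validation, homology-transfer annotation, control-region
partitioning, relative-rate estimation, and codon-usage clustering — plus a
sliding-window accessibility profiler for protein termini and a sequence
evolution simulator that gives every stage a known ground truth. This
vignette explains the models behind each stage, the tunable parameters and
their defaults, and the design decisions taken where the methods literature
leaves choices open.

## The genome model

A mitogenome is treated as a circular nucleotide sequence with an ordered
feature table. Coordinates are 1-based and inclusive on the heavy (H) strand,
the convention of published mitogenome organization tables; light-strand (L)
features are stored on the same coordinate system and reverse-complemented on
extraction. Features may wrap the replication origin: a feature with
`stop < start` has length `genome_length - start + 1 + stop`. The intergenic
column attaches to the upstream feature (spacing to the next feature;
negative values are overlaps, which are normal in these compact genomes —
ATP8/ATP6 share 10 nt, ND4L/ND4 7 nt, ND5/ND6 4 nt in the shipped tables).

Protein genes follow the vertebrate mitochondrial code (60 sense codons; TAA,
TAG, AGA and AGG are stops; ATA is Met, TGA is Trp), with ATG and GTG
accepted as initiators. Many mitochondrial genes end in a non-triplet 3'
terminus completed to TAA by polyadenylation; `classify_stop_codon()` labels
these `TA+` (two trailing bases reading TA) or `T++` (one trailing T) and
requires immediate adjacency to the downstream feature, since a truncated
stop away from a feature boundary indicates misannotation. AGA/AGG are
accepted as complete stops for code-table completeness even where a
particular genome uses only TAA/TAG.

`validate_genome_table()` recomputes the size and intergenic columns of a
feature table and flags every disagreement with the printed values. The
shipped tables for the two Lake Tanganyika cichlids reproduce with zero
mismatches; their protein-coding nucleotides sum to 11,472 by the size
column, while the accompanying prose total is one nucleotide higher — the
validator reports the computed sum and asserts neither.

## Homology-transfer annotation

Annotation transfers features from reference genomes by local alignment
rather than an external search binary, so the pipeline runs without
third-party executables. `local_align()` is a Smith–Waterman-style optimal
local alignment (match +2, mismatch −3, gap open 5, gap extend 2, affine)
built on `Biostrings::pairwiseAlignment()`. Circularity is handled by
searching the genome extended with its own first `reference length + 100`
bases and canonicalizing coordinates back into `[1, L]`; both strands are
searched and the better placement kept.

A placement is accepted when percent identity and length coverage both reach
0.6 (defaults; the original homology-search thresholds of such pipelines are
rarely published, so these are explicit configuration, not a claim about any
particular study). Placements of one feature from several references are
collapsed by a majority rule: start and stop are chosen by strict plurality
over exact candidate coordinates, ties go to the highest-scoring placement
(score = identity × coverage), and the strand must have a majority. A
near-miss mode (`near_window`) lets votes count within ±k nt for noisier
reference sets. The majority rule is permutation-invariant in the reference
order.

On simulated data, self-annotation (a genome annotated with its own
extracted features) recovers every coordinate exactly, and references at ~5%
divergence without indels stay within ±2 nt per boundary — both properties
are enforced by the test suite. tRNA structure-based validation is out of
scope; anticodons are carried through from the reference annotation.

## Control-region partitioning

The vertebrate control region (D-loop) divides into a hypervariable domain
containing the termination-associated sequence (TAS), a central conserved
domain opening at CSB-F and containing CSB-E and the heavy-strand replication
origin, and a variable domain opening at CSB1 and containing CSB2 and CSB3.
`partition_control_region()` anchors Domain 2 at the best CSB-F hit and
Domain 3 at the best CSB1 hit; all motif hits are reported relative to the
control-region start, and a missing anchor is an error that lists what was
found.

Motifs are located by a Hamming-window scan (`find_motif_approx()`, no
indels). The default per-motif mismatch budget is `ceiling(10%)` of the motif
length, which comfortably covers the variation observed between closely
related species: the shipped 45-nt TAS motifs of the two study species
differ at exactly 3 positions, and every shipped cross-species motif variant
is found within its default budget.

## Relative rates by distance regression

The rate stage implements the distance-regression ("DR") estimator: for each
gene or partition, gap-weighted p-distances are regressed on the distances of
a reference gene over the same taxa or pairs, and the slope is reported as
that partition's relative rate. The reference is the small rRNA by
convention (configurable); its own slope is 1 by construction. The point of
DR over model-based rate estimation is insertions and deletions: substitution
models treat gap columns as missing data, whereas here a gap aligned to a
base counts as a full difference ("fully weighted gaps"), so indel-rich
regions such as the D-loop contribute their length variation to the
estimate.

Distance conventions:

* gap vs base: difference; gap vs gap: excluded from numerator **and**
  denominator (shared absence carries no divergence signal — this is the
  package's reading of "fully weighted");
* `N` never matches anything, including another `N`;
* `gap_mode = "ignore"` excludes any gap-containing column, for
  indel-blind comparison.

Both distance modes are provided: `pairwise` (all unordered taxon pairs) and
`vs_consensus` (each taxon against the per-column plurality consensus, ties
broken toward the alignment-wide most frequent symbol, then alphabetically).
The regression is through the origin by default — a zero reference distance
implies a zero gene distance under a rate-ratio reading — with a free
intercept available since published uses of the approach do not always state
the choice.

`rate_table()` assembles the full partition set: every gene; the three
codon-position partitions of each protein gene; the fourfold-degenerate third
positions pooled over all protein genes (a codon column contributes its third
position only when every taxon with a complete unambiguous codon there has a
fourfold-degenerate prefix — the amino acid fixed and no stop reachable by
any third base; gap/N codons abstain); and the control region both raw and
after `gap_column_filter()`, the package's documented stand-in for external
block-filtering tools (drop every column whose gap fraction exceeds a
threshold, default 0).

### Estimator calibration on synthetic data

The recovery tests and the acceptance script simulate 20 taxa on a star tree
calibrated under Jukes–Cantor so that the expected pairwise p-distance of the
reference partition is 0.10, with five 900-nt test partitions at rate
multipliers 0.25, 0.5, 1, 2 and 4. Because p-distances saturate, the slope of
one p-distance on another is biased below the true rate ratio, and the bias
grows with divergence: at pairwise divergence 0.10 a ×4 partition's expected
pairwise-mode slope is ≈3.2, outside any ±20% recovery band before noise is
even considered. Taxon-vs-consensus distances halve the divergence each
distance sees (≈0.05 to the consensus), keeping the ×4 bias near −10%; this
closed-form argument is why the recovery checks use `mode = "vs_consensus"`
with through-origin regression — the same distance construction used by the
consensus-based EMBOSS workflow the estimator descends from. The rank order
of multipliers, which saturation cannot disturb, is required to be exact; the
slopes are required within ±20% of truth. Gene lengths (943 nt reference,
900 nt test partitions) are the package's choice of a realistic
mitochondrial gene size.

## Codon usage and clustering

`count_codons()` tallies in-frame sense codons (stops, incomplete terminal
codons and codons containing `N`/gaps excluded); `normalize_usage()` rescales
a profile so a uniformly used codon scores exactly 1 (`count / total × 60`) —
the 60 is structural (64 codons − 4 stops), not a tuning constant, and every
row of a `codon_usage_matrix()` has mean exactly 1. The inter-profile metric
is not standardized in the field; euclidean is the default with manhattan
available, and conclusions that depend on the metric should be checked under
both.

`lance_williams_cluster()` performs agglomerative clustering via the
Lance–Williams recurrence, which expresses average (UPGMA), single, complete
and median linkage as one distance-update formula. Ties in the minimal
merge distance are resolved toward the smallest cluster-label order, making
the dendrogram deterministic; average-linkage heights agree with
`stats::hclust` UPGMA to 1e-10 in the test suite (hclust serves as the
independent oracle, never as the implementation). Median linkage can produce
height inversions; these are reported via a warning and left in the output,
since silently monotonizing them would misrepresent the merge structure.

On genomes simulated down a known tree with lineage-specific synonymous
codon-bias shifts, average-linkage clustering of usage profiles groups
sister taxa together in ≥90% of replicates (a statistical property test, not
a guarantee for any single data set).

## Accessibility profiles of protein termini

`windowed_profile()` scores each residue as the unweighted mean of an
amino-acid scale over a window (default 9) centred on it. "Fully weighted
edges" is interpreted as every residue in the window carrying weight 1, with
windows truncating at the sequence ends; an `interior_only` mode restricts
output to positions with complete windows. The default scale is Janin's
(1979) accessibility table (molar percentage of residues found accessible in
globular structures), shipped as configuration; any named 20-residue vector
can be substituted. `X` residues are skipped with the window mean
renormalized (and reported); other unknown residues are errors.
`normalize_profile()` min-max rescales to [0, 1] per profile by default,
with a joint mode for multi-sequence panels. Positions are reported in
sequence coordinates; mapping into alignment columns, when needed, is left
to the caller's alignment. Sliding-window scale profiles are an approximate
screen — they use primary structure only, and high accessibility at protein
termini is common — so profiles indicate candidates for interaction sites
rather than establishing them.

## The simulator

`simulate_alignment()` evolves each partition down a user tree under HKY
(default κ = 4, base frequencies mimicking a fish mitochondrial H strand:
A 0.275, C 0.303, G 0.157, T 0.265) or Jukes–Cantor (used wherever a
closed-form check is wanted). The rate matrix is normalized to one expected
substitution per site per unit branch length, so branch lengths are expected
substitutions per site on the reference partition and per-partition rates
are `branch length × multiplier`. The root sequence is drawn from the
stationary frequencies. Two deliberate deviations from a pure nucleotide
model keep the synthetic data structurally valid:

* CDS partitions hold their initiator (ATG) and terminator (TAA) codons and
  reject substitutions creating in-frame stops (the offending codon is
  redrawn, falling back to the parent codon), so simulated genes always
  translate;
* control-region partitions run a Poisson indel process (mean events =
  `rate × length × branch length`, insertion/deletion equally likely,
  geometric tract lengths) and are emitted as the true alignment: every
  alignment column carries a numeric key, deletions drop keys from a
  lineage, insertions create fresh keys strictly between their flanking
  keys. Columns from independent insertions in different lineages are
  ordered deterministically but arbitrarily relative to each other — exactly
  the ambiguity a real aligner faces.

Optional lineage-specific codon-bias shifts move third codon positions
toward a preferred base where synonymous, leaving the protein sequence
unchanged — the mechanism behind the codon-usage clustering tests.
`simulate_mitogenome_set()` concatenates partitions in the canonical
mitogenome feature order (the default layout copies the shipped feature
table, CDS sizes rounded to complete codons) into circular genomes with true
per-taxon coordinates. Identical configuration and seed reproduce all
outputs byte-identically.

What the simulator does **not** emulate: sequencing error and read-level
artefacts, heteroplasmy (only the downstream frameshift arithmetic is
modelled, via `frameshift_consequence()`), selection (dN/dS), rate variation
across sites within a partition, and realignment noise — CR alignments are
emitted as truth, so analyses of realigned data face an extra error source
the tests do not cover. Passing tests therefore demonstrate correctness of
the estimators under the generating model, not robustness to every artefact
of real data.

## Numerical and degenerate-input conventions

* p-distance with no counted columns (all shared gaps) is an error, not 0.
* Regression needs ≥3 shared keys; an all-zero reference is a degenerate
  error, as is zero reference variance with a free intercept.
* `gap_column_filter()` removing every column is an error.
* Constant profiles cannot be min-max normalized (error).
* A non-triplet CDS end that does not read T/TA next to a downstream feature
  is a classification error signalling misannotation.
* All parsers reject malformed coordinates, classes and strands rather than
  coercing them.

## Reproducing the published genome-scale figures

Whole-study quantities (cross-species genome identity, the published D-loop
relative rate, base-composition percentages of the deposited genomes) require
downloading the 25 source mitogenomes and re-running external multiple
alignment, so they are not computed here. The package exposes the entry
points for a user holding that data — `read_gene_alignments()` for a
directory of per-gene alignments feeding `rate_table()`, and the shipped
motif table for checking printed control-region positions — and the test
suite and `scripts/acceptance.R` confine their claims to fixture arithmetic,
closed-form checks and simulations with known truth.
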
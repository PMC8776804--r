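---
title: "Phage community analysis: taxonomy tiers, bloom detection and spacer host links"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phage community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

flavoscope packages the computational workflow behind cultivation-based
phage community studies — our running example being lytic flavophages
(phages of *Flavobacteriia*) isolated from North Sea spring phytoplankton
blooms. Four analysis stages operate behind the `analysis/` drivers:
whole-genome taxon demarcation, protein-content family clustering,
metagenome presence/abundance calling, and CRISPR spacer host linking.
A synthetic-community generator with full ground truth makes every stage
testable without any external data. This vignette records the models, the
parameters that matter, and the design decisions taken where the methods
literature leaves choices open.

## Whole-genome taxonomy

### Intergenomic similarity

For a genome pair (a, b) the package computes local similarity blocks
(exact 13-mer seeds, ungapped X-drop extension with match +1 / mismatch −2,
X-drop 50, blocks trimmed to their maximum-scoring extent, both strands)
and summarizes them as

    sim(a, b) = 100 · (id_a + id_b) / (len_a + len_b)

where `id_x` counts identical positions on genome x over the union of
aligned intervals. Overlaps are resolved best-block-first (decreasing
identical positions, ties by query then subject start); for ungapped
blocks the truncated overlap is recounted exactly from the sequences.
The formula is symmetric and length-aware: a perfect alignment of only
half of each genome scores 50, so partial homology cannot masquerade as
species identity.

Two deliberate simplifications:

* **Blocks are ungapped.** Indel-containing homology appears as adjacent
  blocks on shifted diagonals; the interval-union summation merges them, so
  the similarity estimate is unaffected except for the few bases inside the
  indel itself. On substitution-only pairs the estimate agrees with the
  edit-list oracle to better than 0.1 percentage points (asserted in the
  tests at 40 kb).
* **Low-identity pairs fragment.** With match +1 / mismatch −2, ungapped
  extension has negative drift below ~67% identity, so blocks break up and
  measured similarity drops well below the true ANI. This is harmless
  here — every demarcation threshold sits at 70% or above — but the matrix
  should not be read as an ANI estimate below that range.

A precomputed 12-column BLAST tabular file can replace the internal
aligner (`read_blast_tab()` + `similarity_from_blocks()`) when
bit-compatible external searches matter, e.g. for the deposited isolate
genomes of a real study.

### Demarcation

Strains, species and genera are connected components of the thresholded
similarity graph at 100, 95 and 70 — single-linkage semantics, which is how
whole-genome demarcation thresholds are conventionally applied and which
guarantees that partitions refine as the threshold rises (a property the
tests assert on random matrices). The strain tier tests equality within
ε = 0.01 percentage points, reading "100% similarity" as VIRIDIC-style
rounded output rather than exact byte identity; ε is configurable.

## Protein-content families

Proteomes come either from the caller's FASTA or from the internal ORF
caller: maximal ORFs on both strands, ATG/GTG/TTG starts, standard code,
default ≥ 30 aa. A naive six-frame scan over-calls badly in gene-dense
phage genomes (nested antisense ORFs), so the pipeline reduces it with
`primary_proteome()`: greedy longest-first selection in which an ORF is
rejected only when its overlap with a kept ORF exceeds both 30 nt and half
the shorter ORF — the proportional clause stops a start-codon extension of
one gene from evicting its neighbour. The pipeline default of
`min_orf_aa = 60` compensates for the caller having no coding-statistics
model: below ~60 aa, chance ORFs outnumber real short genes and dilute the
genome profiles.

Protein clusters (PCs) are connected components of the reciprocal
similarity graph. Internal search is Smith–Waterman (BLOSUM62, gap open
11 / extend 1) over pairs passing a shared 4-mer prefilter; bitscores use
ungapped Karlin–Altschul constants (λ = 0.3176, K = 0.134) and
e-value = m·n·2^(−bits). An edge survives only with e-value ≤ 1e-4 *and*
bitscore ≥ 50 — the standard reciprocal-hit filter; with symmetric internal
scores one test covers both directions, while the tabular-ingest path
(`hit_graph_from_table()`) enforces both directions explicitly. Connected
components were chosen over MCL-style clustering because they are
deterministic and parameter-free; with the bitscore-50 floor, spurious
chains through random similarity are not a practical concern at these
proteome sizes.

Genome distance is Sørensen–Dice on PC presence/absence,
d = 1 − 2|A∩B|/(|A|+|B|): symmetric, zero on identical content, one on
disjoint content, and naturally in [0, 1] so the family-level tree cut at
0.9 is meaningful. Trees are complete-linkage (`stats::hclust`); supports
come from resampling PC columns with replacement (the profile matrix is
the data; resampling proteins would conflate cluster membership with
content), rebuilding the tree per replicate, and scoring each reference
clade by the fraction of replicates containing it. This is a plain
bootstrap proportion — selective-inference and approximately-unbiased
variants are out of scope, so supports here are conservative descriptive
statistics, not calibrated p-values. Columns are put in canonical order
first so supports cannot depend on column arrangement.

The 0.9 cut is strict (a merge at exactly the cut height separates),
implemented directly on the merge matrix because `stats::cutree` includes
boundary merges. Viral genome clusters (VGCs) from the cut act as the
family-level proxy; silhouette widths s = (b − a)/max(a, b) (singletons 0,
cross-checked against `cluster::silhouette`) quantify how cleanly each
genome sits in its VGC. Core gene sets per candidate family are the PCs
present in every member, after keeping only the longest protein where a
genome contributes paralogs — "duplicates removed" is underspecified in the
tools this emulates, and longest-member is the least destructive reading.

## Bloom detection

Read alignments (SAM/BAM with NM, PAF, or ground-truth alignments of
simulated reads) are filtered per read by identity
(aligned bases − edit distance)/aligned bases — NM semantics, indels
included. Breadth is the fraction of the genome covered ≥ 1× by qualifying
alignments (interval union, so depth can never inflate breadth; secondary
and supplementary records are dropped by default). The three presence
rules are exactly:

| entity | identity | breadth |
|---|---|---|
| bacterium | ≥ 95% | > 60% |
| phage | ≥ 90% | > 75% |
| phage relative | ≥ 70% | > 60% |

with strict breadth inequalities — exactly 60% is absent. Normalized
abundance is qualifying bases / genome length / library size (Gb), with
the library size taken as total sequenced bases before alignment (the only
self-consistent reading of a pre-mapping normalizer). Phage/host ratios
divide the two abundances; a zero-abundance host yields an explicit
undefined marker rather than infinity, and printed ratios mirror the
mixed precision of published tables (integers at ≥ 10, two decimals
below). Identity filtering is per read, then breadth — an alternative
per-base-pileup reading exists, but per-read filtering is what mapping
pipelines with identity cutoffs actually implement.

## CRISPR spacer matching

Spacer-to-phage matching follows highest-sensitivity assembler-style
constraints: candidate loci seeded by exact 10-mers ("word length") on
both strands, extended to full-spacer semi-global alignments under unit
costs where every gapped position counts one effective mismatch. A match
must satisfy all of: total gapped positions ≤ 20% of the spacer (rounded
down), each gap event ≤ 5 bp, effective mismatches ≤ 50% of the spacer,
and ≥ 10 consecutive matched columns. Host–phage assignment then keeps
only matches with ≤ 1 effective mismatch (a "< 2 mismatches" database rule
collapses to the same cap; the cap is a parameter regardless).

Numerical details worth knowing:

* Traceback prefers continuing an open gap at cost ties (affine-style), so
  a planted 6-bp gap is seen as one oversized event and rejected, rather
  than laundered into two legal 3-bp events.
* Selection is best-first (effective mismatches, then position) with
  same-strand overlap suppression, and the constraint filter runs *after*
  selection: a locus whose optimal alignment violates a gap cap is
  suppressed outright, not resurrected by a weaker overlapping alignment.
* A true match containing no exact 10-mer is undetectable by construction;
  that is the documented sensitivity limit of the word-length semantics
  (immaterial under the ≤ 1-mismatch assignment rule, where a long exact
  run always exists).
* At equal cost a terminal substitution and a terminal gap are
  interchangeable; the deterministic tie-break can therefore shift a match
  boundary by one column between strand-mirrored searches.
* Ambiguous bases count as mismatches.

The brute-force oracle (`find_spacer_hits_bruteforce()`) runs the same
semantics as a full-genome DP without seeding; the tests assert exact
agreement with the seeded matcher on 10 kb genomes.

## The synthetic community

`community_spec()` defaults define the study conditions: 3 families ×
2 genera × 2 species × 2 strains, 35–45 kb genomes, GC 0.35 (flavophage
genomes run ~0.29–0.38), 90% coding density with 300–1200 nt genes,
species tier ANI in [0.96, 1] (strain-mates identical — within-strain
variability below the 100% threshold is not modelled), genus tier pairwise
ANI drawn per genus from [0.78, 0.88], indel rate 0.01 events per
substitution (geometric lengths capped at 10 bp).

How the tiers are planted:

* **Families** descend from independent random ancestors with independent
  planted gene sets, so cross-family gene content is disjoint and
  cross-family similarity is background noise.
* **Genera** diverge from the family ancestor by *disjoint* substitution
  sets of 18% of the genome each, putting cross-genus identity near 64%,
  safely below the 70% threshold.
* **Species** within a genus receive disjoint substitution sets sized
  (1 − t)/2 each, so every cross-species pair realizes the drawn genus-tier
  identity t exactly — planting is deterministic, not merely expected.
* **Strains** are exact copies when the species range reaches 1 (the
  default); with a lower upper bound they diverge by the same disjoint
  mechanism.

Mutations emulate purifying selection: inside genes a substitution may not
create an in-frame stop, start/stop codons are untouchable, indels are
confined to intergenic space (frameshifts treated as lethal), and the
substitution budget consumes third-codon and intergenic sites before
first/second positions, so amino-acid divergence lags nucleotide
divergence (dN/dS < 1) as in real coding sequences. Without this, random
18% nucleotide divergence shreds ORFs with premature stops and no
protein-content signal survives to the family tier — the single biggest
lesson from building the generator.

Reads are uniform-divergence: every read carries exactly
round(length × divergence) substitutions, so read identity is exactly
1 − divergence and the presence-rule thresholds separate cleanly at any
depth. Real error profiles (quality ramps, indel errors, per-read
dispersion) are deliberately not modelled; a consequence is that passing
the presence-rule truth table says the rules are implemented correctly,
not that they are robust to borderline per-read identity spread in real
data. Likewise the generator has no codon model, no recombination, no
repeat structure and no horizontal transfer — planted-recovery results
show the pipeline recovers the structure it defines, on data cleaner than
nature's.

## Problem sizes and runtime choices

The bundled analyses and tests run at desk scale by choice: 24 genomes of
~40 kb for taxonomy recovery (all 276 pairs aligned in ~10 s; proteome and
clustering in ~1 min), 200 bootstrap replicates in the analysis drivers
and 100 in the acceptance computation (the conventional 1000 is the
package default elsewhere; clade proportions at these community sizes are
stable well before 200), 20 kb genomes at 0.3× and 20× depth for the
presence truth table, and 8–10 kb genomes for spacer oracle equivalence.
The deposited-isolate demarcation check (108 genomes, 44 strains /
12 species) needs the external BioProject download and the BLAST-tabular
interop path; the corresponding test states its input path and fails
plainly when the download is absent.
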
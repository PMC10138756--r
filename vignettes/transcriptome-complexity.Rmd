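---
title: "Methods: long-read transcriptome complexity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read transcriptome complexity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, rules and numerical choices behind
`isoplexr`, in the order the pipeline runs them. The package analyses
full-length transcript models of the kind produced by single-molecule
long-read (Iso-Seq style) sequencing: each observed isoform is an exon chain
on one strand, and every question the package asks — which isoforms are
novel, how they differ in splicing, where transcription starts, stops and is
cleaved, which transcripts are noncoding — is a comparison of exon chains,
read sequences and expression profiles.

## Coordinates and transcript models

Internally all coordinates are 0-based half-open, converted at the file
boundary from the 1-based inclusive GTF/GFF3 convention. A transcript model
must have at least one exon, sorted and separated by at least 1 nt; models
without a strand are rejected outright, because every downstream comparison
(donor/acceptor orientation, TSS vs TTS, ORF frames) is strand-aware. GC
content excludes `N` bases from numerator and denominator, so a partially
masked sequence is summarized by its informative positions only.

## Gene loci and isoform categories

Observed isoforms are grouped into loci by single-linkage clustering over
same-strand exonic overlap (at least 1 bp). Single linkage is the natural
choice here: any chain of isoforms sharing exonic sequence describes one
transcriptional unit, and the clustering then equals the transitive closure
of the pairwise overlap relation (the test suite checks this against a
brute-force closure).

Each isoform receives exactly one category against the reference
annotation:

* **known** — a multi-exon isoform whose intron chain exactly matches a
  reference transcript (a *full splice match*). End positions are
  deliberately free: 5'/3' end variation is measured by the aTSS/aTTS
  stage, not treated as novelty. Mono-exon isoforms have no intron chain,
  so they match by containment against a reference mono-exon transcript
  with both ends within a tolerance (`mono_exon_tol`, default 50 nt — a
  typical end-degradation scale for full-length reads; configurable).
* **novel_of_annotated** — not known, but sharing same-strand exonic
  overlap with the reference.
* **novel_locus** — everything else. Antisense-only overlap falls here:
  since the comparison scope is strand-aware, an antisense transcript is
  not evidence for the annotated gene model on the other strand.

"Expressed" means FPKM at or above 1 by default; the threshold is exposed
because no universal definition exists for single-sample tissues.

## Alternative-splicing events

Events are enumerated pairwise within a locus and deduplicated across pairs
by a coordinate anchor, accumulating inclusion-form and exclusion-form
transcript sets. Pairwise enumeration (rather than a global splice graph)
mirrors the pairwise structure notion of classic event-typing tools, keeps
every event attributable to concrete transcript pairs, and makes the
brute-force oracle in the tests exact. The definitions, all strand-aware:

* **IR** — an intron of one transcript lies strictly inside an exon of the
  other; the anchor is the intron. Strict containment is required (a shared
  boundary is a splice-site shift, not retention).
* **ES** — a run of one or more internal exons whose outer flanking intron
  boundaries form a single spanning intron of the other transcript; the
  anchor is the spanning intron plus the skipped exon coordinates.
* **A5SS / A3SS** — two introns sharing exactly one boundary. Which type
  depends on the strand: the shared boundary is the acceptor for A5SS and
  the donor for A3SS, with donor = 5' splice site in transcript
  orientation. One refinement matters: the exons flanking the *differing*
  boundary must overlap each other. Without it, exon-skipping and
  mutually-exclusive configurations — which also produce boundary-sharing
  intron pairs — would be double-counted as spurious site shifts. With it,
  the five event classes are disjoint on planted data and the planted-event
  recovery tests demand precision = recall = 1 per class.
* **MXE** — each transcript holds exactly one internal exon between a
  common donor and a common acceptor, and the two exons do not overlap.
  Mutual exclusivity is required within the pair only; a third isoform
  containing both exons does not invalidate the event.

Splice-site offset tables group alternative donors sharing their acceptor
(and vice versa); the dominant site is the one used by most isoforms, ties
breaking toward the 5'-most site in transcript orientation, and offsets are
signed in transcript orientation so "4 nt downstream" means the same thing
on both strands. Intron boundary dinucleotides are read in transcript
orientation, so a canonical intron is GT..AG on either strand.

## Differential splicing

Read support per event and sample gives PSI = inc/(inc + exc). For each
sample pair, a two-sided Fisher exact test on the 2x2 count table is
BH-corrected across events; an event is differentially spliced when
q < 0.05 and |dPSI| >= 0.1. These thresholds are the field's conventions
for screening without replicates and are configurable. Events with zero
total counts in a sample are skipped for that pair and logged rather than
imputed. One calibration note: Fisher's exact test is conservative at
shallow counts because of discreteness, so the suite's null-calibration
check simulates junction support deep enough (2,000 reads per event and
sample) that the attained size approaches the nominal 0.05; at tens of
reads the test under-rejects, which is the expected and documented
behavior of the stand-in, not a defect.

## Transcript ends and poly(A) sites

TSS and TTS coordinates (strand-appropriate transcript ends) are clustered
per locus by 1-D single linkage with a 50-nt tolerance (configurable; the
generator plants 200-nt shifts so flag recovery is unambiguous). A locus
with two or more clusters carries an alternative TSS (or TTS); the number
of clusters is non-increasing in the tolerance.

Poly(A) tails are called from the soft-clipped 3' segment of each
full-length read with an explicit windowed rule: a tail is present when
some 30-base window contains at least 8 adenines and at most 1 non-A base.
"Fewer than two non-A bases" is read strictly as <= 1, and both thresholds
plus the window width are configurable. The window slides over the clipped
segment by default (an anchored mode that only inspects the window at the
clip start is available); segments shorter than 30 bases are evaluated
as-is, so a clean 8-A clip qualifies. The cleavage site is the genomic
position immediately after the last aligned base on the transcript strand.
Read-level sites are assigned to loci by span overlap (extended by the
collapse tolerance, since a cleavage site sits just outside the aligned
span) and merged within 24 nt — common practice for 3'-end data — with the
modal position as representative.

Composition profiles report per-offset A/C/G/T fractions in transcript
orientation over −50..+10 around the cleavage site. Motif discovery is a
seeded k-mer enrichment: observed upstream 50-nt windows versus
mononucleotide-preserving shuffles of the same windows, one-sided binomial
p-values, BH correction. When the background *is* the observed window set,
every fold is exactly 1 by construction — the suite uses this identity as a
self-test.

## lncRNA identification

Candidates are the non-`known` (novel) transcripts. A candidate is kept
when it is at least 200 nt long, its longest ATG-initiated ORF is at most
100 amino acids, and its coding-potential score is below 0.5. The score is
a transparent, fixed logistic combination of three classic signals: ORF
length (aa), ORF coverage (ORF nt / transcript nt), and the Fickett
TESTCODE statistic computed from the published position/content lookup
tables. The weights are package constants chosen so a full-length
codon-structured mRNA scores near 1 and its composition-matched shuffle
near 0; on generated coding/noncoding pairs the score separates the
classes with AUC > 0.99. This replaces external coding-potential tools
with a single auditable formula; it is not a reimplementation of any of
them. A reported secondary filter (dropping candidates under 350 nt) is
implemented but off by default, because the source description of that
clause is internally inconsistent.

Kept records are classified by position against the reference coding
models, with a fixed precedence that makes the classes mutually exclusive
and exhaustive: sense exonic overlap → `sense_overlapping`; else antisense
exonic overlap → `lncNAT`; else fully inside a same-strand intron →
`intronic`; else `lincRNA`. Target pairing follows the class: lincRNAs
pair with the nearest coding gene within 100 kb (the distance is a
configurable default; the source is silent), the other classes with the
gene they overlap. Pairs are called positive when the Pearson correlation
of the expression profiles exceeds 0.6 and negative below −0.6; a
correlation of exactly 0.6 is class `none`.

## Expression stack

FPKM = count x 10^9 / (length x library size), with library sizes
defaulting to column sums — so doubling every count of a sample leaves its
FPKM unchanged. PCA operates on log2(FPKM + 1), feature-centered, samples
as observations; component signs are fixed by making the largest-magnitude
loading positive, which makes scores reproducible to the bit. Profile
clustering z-scores rows (zero-variance rows are dropped and reported),
canonicalizes row order by id so the result is invariant to input
ordering, runs k-means with a fixed seed and 25 restarts, and renumbers
labels by descending cluster size; k defaults to 5 for tissue-panel
profiles, and the generator's planted-cluster checks use the planted k.
With no replicates, differential expression between two samples is a
pseudo-counted fold-change rule: |log2((a+1)/(b+1))| >= 1 with
max(a, b) >= 1 FPKM, and the DEG set is the union over sample pairs. Term
enrichment is the classic one-sided hypergeometric tail with BH
correction — deliberately the plain version, clearly labelled, not a
topology-aware GO algorithm.

## Domain changes

Within each multi-isoform gene, every isoform is compared to a reference
isoform — the one with the largest domain multiset, ties broken by longest
ORF, then smallest id. The comparison is a multiset difference of domain
*names*: coordinates are ignored because the question is presence/absence
of function-carrying modules, and duplicated domains count with
multiplicity (losing one of two copies is a loss). Classes: `unchanged`,
`loss`, `gain`, `both`. Note a structural consequence of the
max-cardinality reference rule: relative to that reference a pure `gain`
can only arise through tie-breaks, since a strictly larger multiset would
itself have been chosen as reference; the classifier function itself is
reference-agnostic and exhaustively tested against an independent
multiset oracle.

## The synthetic corpus

The generator builds the study conditions every stage is tested under: two
1.5-Mb chromosomes, 200 coding genes (10% mono-exon; multi-exon genes with
4–8 exons of 90–250 nt and introns of 250–500 nt), planted AS events at
per-type rates (IR 0.15, ES 0.10, A3SS 0.12, A5SS 0.12, MXE 0.10 — at
least 20 planted events per type), aTSS/aTTS shifts of 200 nt at rate 0.3
each, 25 intergenic and 10 antisense lncRNA loci, 3 error-free full-length
reads per isoform carrying poly(A) tails of 25–45 nt with 1% impurity, an
`AATAAA` signal written 10–30 nt upstream of 70% of cleavage sites, and an
isoform-by-sample count matrix over 7 tissues realizing planted expression
clusters, planted DEGs (8-fold), and planted lncRNA–target correlations.
Reference exons carry codon-structured mRNA sequence (GC3-biased codon
draws between a short 5' UTR and stop + 3' UTR), so coding isoforms look
coding to the filter cascade; every intron boundary, including planted
alternative sites, is written as canonical GT..AG on the transcript
strand. All randomness flows from one seed and the corpus is byte-stable
under regeneration.

What the generator does **not** emulate — and hence what green tests do
not show about real data: sequencing error and truncated reads (reads are
exact transcript copies plus tails), internal priming artifacts, overlapping
or nested gene structures, paralogy-induced mapping ambiguity, non-canonical
splice sites, biological replicate variance, and library-composition
effects beyond what column-sum normalization captures. Planted events are
also at most one AS event per gene, so event interactions (two events on
one isoform) are exercised by the random-locus oracle tests, not by the
corpus.

On this corpus the planted truth is recovered exactly: category accuracy
1.0, per-type event precision and recall 1.0, aTSS/aTTS flag precision and
recall 1.0, poly(A) site precision and recall 1.0, planted cluster ARI 1.0,
domain class accuracy 1.0 (each computed by the acceptance script and the
suite at the sizes above; the Fisher null calibration uses 2,000 events at
depth 2,000).

## Determinism and problem sizes

Every stochastic step takes an explicit seed (generator, k-mer background,
k-means, simulations), and deterministic tie-breaks are specified
everywhere ties can occur (modal positions toward the smallest value,
dominant splice sites toward the transcript 5' end, reference isoforms by
size/ORF/id, cluster labels by size). Two pipeline runs from one seed
produce byte-identical outputs. Test problem sizes — 500 random loci for
the AS oracle, all 65,536 8-nt tails plus 10,000 random 60-nt tails for
the poly(A) rule, 1,000 transcripts for the lncRNA filters, 15,876
multiset pairs for the domain oracle, the 473-isoform default corpus end
to end, twice — were chosen so the whole suite completes in a few minutes
on one CPU while still exercising each rule exhaustively where
enumeration is feasible.

## Known limitations

* Event enumeration is pairwise; a graph-global notion of complex events
  (nested or chained bubbles) is out of scope.
* The DAS stage inherits Fisher conservativeness at low counts; with
  replicates one would use a dedicated differential-splicing model
  instead.
* The coding-potential score is intentionally simple; species-specific
  hexamer models would outperform it on real data.
* Mono-exon "known" matching is containment-with-tolerance; there is no
  expression- or cap-based evidence model for mono-exon novelty.
* The no-replicate DEG rule is a screening heuristic, not an inference
  procedure; its thresholds are reported in the provenance file of every
  run.
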
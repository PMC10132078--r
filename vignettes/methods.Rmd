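---
title: "How itrseek finds insertion sequences in mixed-community reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How itrseek finds insertion sequences in mixed-community reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Insertion sequences (ISs) are the smallest autonomous mobile genetic
elements in bacteria: a transposase gene (or two) bounded by a pair of
inverted terminal repeats (ITRs), short sequences of roughly 10--50 bp
that are reverse complements of each other. They drive much of the
horizontal spread of accessory genes, including antimicrobial-resistance
genes, yet reference databases under-represent them, and short-read
assemblies of mixed microbial communities routinely collapse or fragment
repeated elements, so database-free discovery directly from reads is
attractive.

itrseek implements a read-level strategy: an ITR is, by definition, a
short sequence that recurs (in forward or reverse-complement orientation)
at different genomic loci, so reads drawn from a community will carry the
same short exact repeat embedded in *different* flanking context. The
pipeline finds those inter-read repeats, projects them onto assembly
contigs, and keeps the repeat pairs that look like the two ends of a
transposase-bearing element.

## The pipeline, stage by stage

**1. Packed read store.** Reads are concatenated into a single 2-bit
encoded array (A=00, C=01, G=10, T=11), with a pseudo-random 20-bit
(10-code) spacer block between consecutive reads and a boundaries table
mapping store offsets back to reads. Reads containing non-ACGT bases are
excluded whole rather than split into fragments: coordinate bookkeeping
stays trivial and the exclusion rate is reported on the store. The spacer
codes come from a seeded generator, and the scanner additionally skips
any window that would overlap a spacer, so the randomness of the spacer
is a belt under deterministic braces, never something the result depends
on.

**2. Sparse-seeded maximal exact matches.** A k-mer (default k = 15)
starting at within-read position p is indexed only when
`p mod ((L - k) + 1) = 0`, where L is the minimum ITR length (default
25). Any window of length at least L contains `(L - k) + 1` consecutive
candidate start positions, hence exactly one indexed position: the
sparse index provably cannot miss a repeat of length L or more, while
storing roughly one eleventh of all k-mers at the defaults. The query
scan slides one base at a time; each index hit is extended to the unique
maximal exact match (MEM) containing it, using interval halving (attempt
the full remaining extension, halve on mismatch until a matching block is
found, then elongate base by base). A MEM is accepted iff

* its length lies in `[min_itr_length, max_itr_length]` (default 25--50
  nt), and
* on **both** reads it neither starts within 20 nt of the read start nor
  ends within 20 nt of the read end.

The 20-nt end buffer is what separates biology from artefact: an exact
duplicate read (a PCR/technical repeat) aligns to its twin as a full-read
or prefix/suffix match, which necessarily touches a read end; an ITR
sitting mid-read does not. The same rule also suppresses the massive
overlap matches between reads tiling the same locus. After the first
accepted MEM, the scanner advances to the next query read --- a 150-nt
read cannot contain both ITRs of a 500+ nt element, so one repeat per
read is the expected signal.

The store is forward-orientation only. Reverse-complement repeat copies
are still found because shotgun sequencing samples both genomic strands;
a consequence worth knowing is that for strand-asymmetric input (e.g.
single-strand amplicons) recall would drop.

**3. Placement and proximity pairing.** Repeat-carrying reads are placed
on their sample's assembly by exact full-length matching on either strand
(errors are out of scope for the internal mapper --- see the generator
below; placements from any external aligner can be supplied as a minimal
SAM: flags 0/16, single full-length `M` CIGAR). Repeat intervals are
projected into contig coordinates (reflected through the read on the
minus strand), deduplicated, and every pair of candidates on one contig
whose span --- start of the first candidate to end of the second --- lies
within `[min_is_len, max_is_len]` (default 500--3000 nt) becomes a
putative element.

**4. Clustering and reverse-complement validation.** Candidate ITRs from
the whole run are clustered greedily, longest first (ties broken
lexicographically, then by input order): a sequence joins the first
cluster whose representative it matches at identity ≥ c (default 0.9)
with coverage of the shorter sequence ≥ aS (default 0.9), coverage of the
longer ≥ aL (default 0), and alignment length ≥ A (default 0), under
local alignment (match +2, mismatch −2, gap open 4, gap extend 1);
otherwise it founds a new cluster. Both strands are compared, as is
standard for nucleotide clustering --- this is essential, because the two
ITRs of one element are reverse complements and must co-cluster. When
both strands are tried, a strand whose alignment passes the admission
predicate is preferred over one with higher raw identity: a short perfect
palindromic stretch must not shadow a full-length reverse-complement
match. A pair is called an IS iff its two candidates (1) share a cluster,
(2) are both within the ITR length window, (3) span an IS-sized interval,
and (4) are reverse complements of each other, operationalized as a local
alignment of the first ITR against the reverse complement of the second
(match +2, mismatch −3, gap open 5, gap extend 2, mirroring default
nucleotide-BLAST scoring) with at least `min_itr_length` identical
aligned bases. The identity-count reading of that threshold means 30-nt
ITRs tolerate up to ~5 substitutions before validation fails at the
default L = 25.

The greedy clustering reproduces the documented parameter semantics of
the conventional nucleotide clustering tools, not their accelerated
word-filter internals; correctness is asserted by an independent
dynamic-programming audit of every member--representative pair in the
test suite, not by diffing any external tool's output.

**5. Annotation and naming.** Putative elements are scanned for
stop-to-stop open reading frames of ≥ 30 aa in all six frames (bacterial
code; no start codon required --- elements are often truncated relative
to database models, and the downstream domain scan, not the ORF caller,
carries the specificity). Protein-family evidence comes either from an
InterProScan-format TSV produced externally on the exported ORF FASTA, or
from a bundled keyword annotator that matches amino-acid motifs from a
small table --- the latter exists so the whole pipeline is testable
offline and is driven by a built-in 57-residue marker ORF in synthetic
data. A record is kept iff some hit description contains "Transposase",
"Integrase-like" or "Ribonuclease H" (case-insensitive). Records are
named `IS_length_<len>` plus one `-<accession>_<start>_<end>` segment per
hit in annotation-source order; amino-acid hit coordinates are mapped to
nucleotide positions on the element as the exact codon span
(`nt_end = nt_start + 3*aa_end - 1`). Output ITR coordinates are 1-based
inclusive; every internal interval is 0-based half-open, and the two
conventions meet only in the output converters.

**6. Catalogue.** ISs pooled across runs are dereplicated at global
identity 0.95 with no coverage constraints (the clustering defaults),
keeping the longest member of each cluster as the representative and a
membership table with per-member identity and provenance.

## The synthetic-data generator

`plant_spec()` / `generate_truth_set()` define the study conditions for
everything the tests assert. Contigs are i.i.d. uniform ACGT; each
planted element is ITR1 + body + ITR2 with ITR2 the reverse complement of
ITR1 up to `itr_mismatches` substitutions; bodies optionally embed the
marker ORF; reads are error-free 150-nt tiles every `tiling_step` nt on
both strands, with an optional fraction of verbatim duplicate reads
emulating technical repeats. Two deliberate design choices make planted
coordinates *exact* ground truth rather than approximate:

* **Sharp boundaries.** For every pair of occurrences of a shared ITR
  string, the generator forces the left-adjacent bases to differ and the
  right-adjacent bases to differ, so no exact match can extend past a
  planted boundary. Without this, a random flank base matches with
  probability 1/4 per side and recovered intervals would be off by a
  geometric-tailed offset --- correct biology, useless as an exact oracle.
* **Evenly spaced mismatches.** ITR substitutions sit at evenly spaced
  interior positions, so no residual exact run reaches the minimum ITR
  length and the diverged pair is invisible to the MEM stage *within* one
  copy, exactly as intended.

A consequence of the method --- not of this implementation --- is that a
single-copy element with imperfect ITRs has no exact inter-read repeat at
all and cannot be seen by an exact-match first stage. Diverged-ITR
recovery is therefore exercised with `copies_per_is = 2`: the copies
share their ITR pair but have independent random bodies, giving the exact
cross-locus repeats that real multi-copy elements produce in communities,
while divergent bodies keep the recovered coordinates exact (identical
bodies would let matches run from read boundaries across the whole
element).

What the generator does **not** emulate: sequencing errors (the internal
mapper is exact-match; error-tolerant runs require an external aligner
through the SAM adapter), indels between ITR copies, abundance or
community structure, and quality-score variation. Passing tests therefore
demonstrate algorithmic correctness under clean conditions, not
robustness to platform noise. Background repeat collisions (a random
≥ 25-nt exact or inverted repeat in the background) occur with
probability on the order of 1e-6 per 50-kb contig pair and are not
suppressed; the brute-force MEM oracle in the tests would surface one as
a visible discrepancy.

## Numerical and procedural choices

* Scan order (k-mer position ascending, index hits in insertion order)
  and all tie-breaks (length, then lexicographic, then input order in
  clustering) are fixed, so identical inputs, parameters and seed give
  byte-identical outputs; the only randomness anywhere in the pipeline is
  the spacer content of the store, which is seeded and additionally
  skipped explicitly.
* MEMs longer than `max_itr_length` are rejected outright, never trimmed
  to a sub-window: a trimmed sub-window is not a maximal match and no
  principled trimming rule exists.
* Identity in clustering is identical bases over alignment length
  (including gaps), the local-clustering convention; "identities" in ITR
  validation is a count, per nucleotide-BLAST report semantics.
* Degenerate inputs degrade to empty-but-valid outputs: zero storable
  reads, zero candidates, or zero validated pairs all produce an empty
  FASTA and a header-only TSV with exit status 0.
* Multi-mapping reads keep all placements; duplicate candidate intervals
  collapse keeping the first source read; duplicate IS records at the
  same coordinates collapse to one.
* Mate pairing is ignored downstream of ingestion: the method uses reads
  as independent sequences, so mates are simply two more reads.
* ITR clustering is run across the whole run (all manifest rows pooled),
  maximizing cross-sample sensitivity at a small risk of chimeric
  clusters between samples; per-sample clustering would be the
  conservative alternative.

## Problem sizes used in the checks

The bundled tests and the acceptance script run the full pipeline on
generated communities of 6--10 contigs of 30--50 kb with 10--15 planted
elements at 10-nt tiling (roughly 36,000--100,000 reads), pools of up to
30 reads against the brute-force all-pairs MEM oracle, and 50-sequence
clustering audits --- sizes chosen so a complete run of every check takes
a few minutes on one core while still exercising every stage at
realistic per-read densities.

## Known limitations

* Exact-repeat seeding bounds sensitivity: diverged ITR pairs are found
  only when each ITR recurs exactly somewhere in the read pool
  (multi-copy elements), and ITRs shorter than `min_itr_length` (default
  25 nt, though real ITRs can be 10 nt) are invisible without lowering L
  and k, at quadratic cost in candidate density.
* Composite transposons, target-site duplications and nested insertions
  are out of scope; an element lengthened beyond `max_is_len` by a nested
  insertion is missed.
* The transposase filter is a description-keyword test over whatever
  annotation source is supplied; with the mock annotator it demonstrates
  plumbing, not biology.
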
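---
title: "Evaluating uORFs as novel first coding exons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating uORFs as novel first coding exons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfconnect)
```

## The question the package answers

Thousands of short upstream open reading frames (uORFs) in the 5'
untranslated regions of human protein-coding transcripts have been proposed
as novel proteins, largely on the strength of Ribo-seq translation evidence
and mutation patterns. If each of these really were an independent gene, the
host mRNAs would become bicistronic — a configuration that is vanishingly
rare in curated human annotation. An alternative explanation is that many
uORFs are unannotated *first coding exons* of the downstream gene: a splice
donor inside the uORF, joined to an acceptor inside the downstream CDS,
would produce an ordinary (monocistronic) novel isoform whose N-terminus
comes from the uORF. A drop in ribosome footprint density, usually read as a
stop codon, is equally consistent with a splice donor — the end of an exon.

`uorfconnect` implements the full evidence chain for that hypothesis at desk
scale: cross-genome conservation scoring of each uORF, construction of
candidate "uORF-connected transcripts" from splice-junction evidence,
ORF-validity filtering, and a protein-structure triage based on predicted
per-residue confidence (pLDDT). Because the genome-scale inputs (full human
assemblies, thousands of RNA-seq sample assemblies, folded structures for
every candidate) are far beyond a desk run, the package also ships a
synthetic-fixture generator whose outputs have known truth for every stage;
all tests and the acceptance script run against those fixtures.

## Conservation rubric

Each uORF is scored in each target genome on an additive 0–7 rubric:

| criterion              | weight |
|------------------------|-------:|
| sequence match         | 4      |
| 5'UTR containment      | 2      |
| gene locus match       | 1      |

*Sequence match* demands a full-length, 100%-identical nucleotide match. A
full-length hit with substitutions can still satisfy the criterion through a
protein-level fallback: all six frame translations of the matched target
subsequence (three forward, three on the reverse complement) are compared
with the query's encoded protein, and an exact protein match counts. The
fallback is granted the full weight and flagged in the per-hit output, since
the conserved totals it feeds do not distinguish the two routes.

Every uORF is searched twice: against the target genome and against the
target transcriptome (spliced transcript sequences derived from the GTF).
The transcriptomic route rescues uORFs that span two 5'UTR exons, which can
never match contiguously in genomic space. When the two spaces disagree, the
higher score wins; exact ties resolve to genomic space (an arbitrary but
fixed choice, recorded in the `winning_space` column).

A score of at least 4 counts as *conserved*, unless the best sequence match
lies more than 1,000 bp away from the source gene's annotated span. Distance
is the minimum gap between the hit interval and the span of the gene
carrying the expected identifier in the *target* annotation; if that
identifier is absent there (e.g. the locus was renamed), the nearest
annotated gene on the hit's chromosome is used instead, so that a
renamed-but-in-place locus is not spuriously treated as displaced. Hits on
other chromosomes count as displaced. The gene-locus criterion itself is
overlap-based: the hit must overlap the expected gene's span, so a verbatim
copy parked intergenically — even within 1 kbp — earns only the sequence
weight. 5'UTR containment requires *full* containment in the 5'UTR of any
protein-coding transcript at the locus, not only the uORF's host transcript;
hits that only partially overlap a 5'UTR are flagged (`utr_partial`) but do
not earn the weight.

The built-in search is an exhaustive `Biostrings::matchPattern()` scan of
both strands, allowing up to `max(3, ceiling(0.1 * query length))`
substitutions so that candidates for the protein fallback are recovered;
precomputed PAF or SAM alignments can be supplied instead and are parsed,
not recomputed. On the ≤100 kb fixtures the scan is provably equivalent to a
brute-force substring comparison, which is how the tests check it.

## Transcript construction and validity filters

Two evidence streams produce junctions, mirroring the two ways splicing
support arises in practice:

- **coverage-backed** junctions (BED6 + a read-coverage column, introns
  0-based half-open) are accepted when their donor lies inside a uORF's
  blocks and their acceptor inside the CDS span of a protein-coding
  transcript of the same gene. Mid-exon acceptors are allowed here — these
  are observed junctions.
- **score-predicted** junctions come from scanning the uORF for GT donor
  dinucleotides (first intronic base after the start codon and before the
  stop) and pairing each with the annotated acceptor sites of the designated
  reference transcript's CDS exons 2..n. A pluggable scorer returns
  donor/acceptor scores in [0, 1]; junctions with mean score ≥ 0.9 are
  retained, excluding any junction already present in the coverage-backed
  set. Restricting this stream to annotated acceptors is deliberate:
  predicted junctions get no license to invent exon boundaries.

Grafting concatenates the uORF from its start codon up to (and excluding)
the donor's first intronic base — the GT itself is intronic — with the
reference coding sequence from the acceptor through the reference stop. The
construct is discarded if (1) it contains a premature in-frame stop codon
(TAA/TAG/TGA; selenocysteine recoding is out of scope), (2) its length is
not a multiple of three, or (3) its CDS is shorter than 90% of the reference
CDS. Both lengths include their stop codons: the rule is stated on CDS
length, and using nucleotides keeps the frame filter and the ratio filter on
the same scale. Surviving constructs are translated; a non-ATG first codon
(in practice ATA/ATT/ATC, read as isoleucine) is kept but flagged, as is the
occasional construct whose protein is identical to the reference (a
duplication between uORF and downstream ORF). Emitted GTFs carry the stop
codon inside the CDS features on both the generator and builder sides — an
internal convention that keeps re-extraction byte-exact; callers exporting
to GENCODE-style annotation would split off a `stop_codon` feature.

Transcript identifiers `uorft_NNNN` are assigned deterministically over the
sorted (uORF, donor, acceptor, reference) tuples, so reruns and the
generator's truth record agree on names. When a locus has several coding
transcripts containing the acceptor, one candidate is built per reference.

## Structure triage

Per-residue pLDDT profiles (from ColabFold-style PDB B-factors or plain
tables) are averaged; no residue-level alignment is attempted. A novel
protein is retained when its average pLDDT shows an increase of more than 1
over a reference, or stays within ±1 of it; both band edges are inclusive
for "no change" (+1 is *not* an improvement), which the boundary tests pin
down to machine precision. Against multiple references the best achievable
class counts — one compatible reference suffices. Averages above 70 carry
the conventional high-confidence flag. The verdict is invariant under
constant shifts of both profiles and under residue reordering.

## The synthetic-fixture generator

The generator emulates exactly the features the pipeline consumes and
nothing more: multi-locus genomes (one gene per ≤100 kb chromosome) whose
5'UTRs host uORFs in three layouts (strictly inside the UTR, spanning two
UTR exons, or overlapping the CDS start by seven bases), engineered GT
donors with coverage-backed and/or scored junction evidence spanning the 0.9
threshold, target genomes realising each conservation level by construction
(synonymous-only change, non-synonymous change, deletion, relocation beyond
or within 1 kbp, movement into an intron, gene renaming), and pLDDT profiles
whose average deltas are exact by construction. Minus-strand loci are built
by reverse-complementing the plus-strand layout, so sense-strand assertions
share one code path and strand symmetry is testable. All randomness is
seeded; generation is byte-reproducible.

Default geometry, chosen once as plausible miniatures of the real scale:
uORFs of 60 nt (the real set is short ORFs of tens of codons), first CDS
exons solved from the requested novel/reference length ratio against a 150
nt downstream CDS, introns of ~90 bp, 300 bp upstream flanks and 1.5 kb
downstream flanks (long enough to park relocated copies beyond the 1 kbp
rule). Junction coverages are spread over 40–200 reads. What the generator
does *not* emulate: realistic base composition, repeats, paralogy,
sequencing error, or Ribo-seq profiles — so passing tests demonstrate the
correctness of the rules and their composition, not robustness to the noise
of real assemblies or alignments. In particular the mismatch-tolerant scan
stands in for a short-read aligner; on real genomes, alignment sensitivity
would be the binding constraint, which is why precomputed PAF/SAM input is
the first-class path for real data.

Desk-scale sizes used throughout the tests: 8–12 loci for rule checks, 200
seeded random loci for the filter-completeness sweep against an independent
raw-string-surgery reimplementation, and a 50-locus × 4-genome end-to-end
run. These sizes make every oracle exhaustive (full substring scans,
all-frame translations) while each stage still exercises both strands, all
layouts and both evidence streams.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally; GTF is converted to 1-based
  inclusive only at the file boundary; junction BED spans the intron.
- pLDDT averages are computed in double precision; the generator realises
  requested deltas to within 1e-9 *after* the file round-trip.
- Empty sets propagate as absences, not zeros: a uORF with no hits scores 0
  but a coverage summary over an empty junction set reports `NA` means.
- uORFs with more than two blocks are rejected with a message; GT–AG is
  enforced on loaded junctions (violations are dropped with a warning, so a
  dialect-tolerant caller can proceed); scorers returning values outside
  [0, 1] are hard errors.
- The `simulate`, `conserve`, `build`, `evaluate`, `run` and `report`
  subcommands of the thin CLI (`inst/cli/uorfconnect.R`) wrap the exported
  functions; the pipeline itself is deterministic, so identical inputs give
  byte-identical JSON reports.

## Known limitations

- Conservation is meaningful only between closely related genomes where
  full-length identity is the expected outcome; the rubric has no model of
  divergence beyond the protein fallback.
- Non-canonical splice classes (GC–AG, AT–AC) are excluded by design.
- The structure stage consumes confidence profiles; it neither folds
  proteins nor compares geometries, and a five-way classification of
  structural changes is out of scope.
- Whether a hit partially overlapping a 5'UTR should earn the containment
  weight is unspecified upstream; this implementation requires full
  containment and flags partial cases, a choice that can only deflate
  scores.

## A worked run

```{r example, eval = FALSE}
fx <- simulate_uorf_fixture(tempdir(), n_loci = 8, seed = 42)
res <- run_uorf_pipeline(fixture_pipeline_config(fx))
glance(res)
autoplot(res$conservation)
autoplot(res$transcripts)
autoplot(res$structure)
```
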
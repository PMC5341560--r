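---
title: "Hybrid long-read / short-read isoform mapping without a reference genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid long-read / short-read isoform mapping without a reference genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

For organisms without a reference genome, neither sequencing technology
alone resolves transcript isoforms. Short-read (Illumina-style) data
assemble, via tools such as Trinity, into contig libraries that contain
true isoforms, the all-exon "longest molecule" of each gene, and many
false products (chimeras, shuffled assemblies) — with no way to tell them
apart. Error-corrected long reads (PacBio Iso-Seq after LSC/ICE-Quiver
style correction) capture real, full-length or near-full-length single
molecules, but are redundant and, per gene, sample only the isoforms that
were actually expressed.

`isomapr` reconciles the two libraries. Writing the long-read library as
the set of expressed isoforms per gene and the contig library as the
theoretical assembly of the same genes, the method rests on two
observations: per gene the expressed isoform set is no larger than the
assembled candidate set, and the assembled set — if assembly was run
permissively — contains one molecule carrying (almost) all exons, which
is at least as long as every expressed isoform. That all-exon contig can
be found *by mapping*: it is the longest contig that a gene's long reads
hit at high identity, and, once found, it serves as the per-gene
reference against which splicing and abundance are read off.

## The pipeline

1. **Duplicate removal (DRCLR).** A corrected long read B is a duplicate
   of a longer read A when B aligns to A end-to-end — no overhangs — with
   similarity above 0.99 and no gaps, where similarity is the count of
   identically aligned nucleotides divided by B's full length. Reads are
   visited longest-first (ties by id, for determinism); a read is removed
   if the rule holds against any retained longer read. The result is the
   duplication-removed corrected long read set (DRCLR).
2. **Gene grouping and reference selection.** Qualifying alignments
   (identity ≥ 0.99; the boundary is included so the threshold is
   reproducible) connect long reads to contigs. Genes are either
   connected components of that bipartite graph, or groups of contigs
   sharing a Trinity gene prefix. Within a gene, candidate references are
   contigs that (A) are at least as long as the longest mapped read of
   the gene and (B) carry at least one qualifying alignment; the longest
   candidate (ties by ascending id) is the gene's reference. Chimeric
   contigs fail (B): no single gene's read covers them at 99%. Condition
   (A) is applied against the maximum mapped-read length of the gene,
   which is equivalent to the per-read form. Because an error-bearing
   read estimates its isoform's length only up to its residual error
   (net insertions can make a qualifying read a few bases *longer* than
   the true all-exon contig), the length comparison grants the same
   slack the identity threshold grants the read:
   `contig length >= max mapped read length x min_identity`.
3. **Splice cataloguing.** Each DRCLR read is aligned to its gene's
   reference. An alignment gap strictly longer than 50 bp is a splice:
   target-side gaps (reference bases the read skips) are *exclusion*
   events, query-side gaps *insertion* events. The ordered tuple of a
   read's events is its splice signature; signatures differing in gap
   site or length are different isoform classes, and the empty signature
   is the all-exon-compatible class.
4. **Quantification and screening.** Short reads are matched exactly
   against one representative sequence per isoform class; reads sharing a
   compatibility set form weighted classes, and an
   expectation–maximisation estimator splits ambiguous classes
   proportional to abundance over effective length. Differential
   screening between two conditions applies the triple cutoff p < 0.05,
   BH-adjusted FDR < 0.01, and fold change ≥ 2; condition-specific
   isoforms are the intersection of one-versus-each screens in a fixed
   direction.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_identity` | 0.99 | qualifying identity, matches / read length; boundary included |
| `min_similarity` (dedup) | 0.99 | containment similarity, strictly exceeded |
| `max_overhang` (dedup) | 0 bp | literal reading of "no overhangs"; configurable for noisy ends |
| `max_gap_openings` (dedup) | 0 | literal reading of "no gaps" (terminal and internal gaps treated alike) |
| `min_gap` | 50 bp | splice threshold, strictly greater than |
| `round_bp` | 5 bp | gap-endpoint clustering tolerance for error-bearing reads; 0 recovers the literal rule |
| `min_block` | 10 bp | internal alignment blocks below this are treated as noise; a few error-coincident bases inside a long gap would otherwise split one splice into two |
| DE cutoffs | p < 0.05, FDR < 0.01, FC ≥ 2 | screening triple cutoff |

Equal-length exact duplicates are *not* removed by the strict rule (A
must be longer than B); `dedup_params(collapse_equal = TRUE)` documents
and enables the deviation.

## The internal aligner

The pipeline ships a small block-structured aligner so every stage is
testable without an external program; on real data, any PSL (BLAT) or
PAF (minimap2, `cg` tag required) file can be substituted at each stage.
Scoring is affine: match +1, mismatch −2, gap open 4, gap extend 0.25 per
base, chosen so a 50 bp gap costs 16.5 — far less than 50 mismatches —
guaranteeing that skipped exons surface as gaps. Alignment is global in
the query (long reads are near-full-length; a `free_query_ends` mode
exists for fragments) and local in the target (contigs may carry UTR or
assembly overhangs). `N` bases score as mismatches.

Numerical conventions:

* **Tie-break.** Among equal-scoring paths the aligner prefers the
  diagonal state, then target-side gaps, then query-side gaps, switching
  states only on strict improvement, and ends at the smallest
  coordinates among maximal cells. This is deterministic and yields
  *left-normalised* gap placement: when the bases flanking a gap are
  ambiguous (the base before the gap equals its last base), the gap
  shifts leftmost — exactly how variant callers normalise deletions.
  Splice coordinates are therefore canonical only up to junction
  sequence ambiguity; without intron sequence the true border is not
  observable, and the catalogue treats the left-normalised placement as
  the canonical one.
* **Banding.** The production path restricts the dynamic programme to
  diagonals within `band_pad` (120 bp) of the diagonals on which the two
  sequences share 12-mers — ordinary seed-and-extend. A pair sharing no
  12-mer is reported unaligned. `banded = FALSE` runs the exact full
  programme; the test suite proves the exact mode equal to an
  independent textbook dynamic programme and the banded mode equal to
  the exact mode on containment and exon-skip structures.
* **Coordinates.** 0-based half-open throughout, PSL-native. For
  minus-strand alignments, query coordinates are kept in the alignment
  frame (the reverse-complemented query — the frame PSL's `qStarts`
  column uses), which is the only frame in which blocks increase in both
  query and target; file-level `qStart`/`qEnd` are converted on read and
  write. PSL `repMatches` is folded into matches and `nCount` into
  mismatches, consistent with scoring `N` as mismatch.

## The EM estimator

Compatibility classes are exact substring matches (forward or reverse
complement) of whole reads against the reference; identical sets merge
into weighted classes, and unmatched reads are counted and dropped. The
mixture model is the standard one behind short-read isoform quantifiers:
the parameter `theta` is the fraction of *reads* from each isoform; the
E-step splits a class among its isoforms proportional to
`theta / effective_length`, the M-step renormalises, and iteration stops
at `max_iter` (500) or when no `theta` moves by more than `tol` (1e-8).
Initialisation is uniform, so the fit is deterministic. Effective length
is `length − mean_fragment + 1`, floored at 1. Molar proportions — the
scale on which mixtures like 70/20/10 are specified — are the TPM
fractions, `(theta / eff_len)` renormalised to 10^6. The per-iteration
log-likelihood is recorded and is non-decreasing by construction (an
assertion in the tests).

The two-condition test is a Poisson likelihood-ratio test with
library-size offsets on EM expected counts. The method's published
procedure fixes the screening cutoffs but not the test statistic; the
Poisson LRT is this package's documented choice, and `de_screen()`
accepts any externally produced count table so a different estimator
(e.g. RSEM + EBSeq) can be substituted without touching the screening
and intersection logic. With a single replicate per condition the test
degrades to a count-ratio test and warns. Fold changes are computed on
library-size-normalised means with a pseudo-count of 0.5.

## What the simulator emulates — and what it does not

`sim_genes()` builds exon-structured genes (4–8 exons of 80–400 bp by
default) with isoform sets that always include the all-exon form;
additional isoforms skip one internal exon each. Exon sequences are
redrawn until no 20-mer crosses genes, so components-mode grouping has a
clean ground truth (`trinity_names` mode is exercised through the
Trinity-style contig ids). With probability 0.2 a gene carries one short
internal exon of 20–45 bp: skipping it produces an alignment gap at or
below the 50 bp threshold, exercising the strict "longer than 50 bp"
rule. The 20–45 bp range keeps a 5 bp guard band below the threshold,
mirroring the `round_bp` tolerance, so sub-threshold events remain
unambiguous under residual read error.

Long reads are emitted at 4 per isoform (emulating multiple full-length
passes per expressed molecule), optionally 5′-truncated and carrying
substitution/indel noise; planted duplicates are exact, strictly shorter
substrings. Contigs comprise the all-exon molecule, every true isoform
(so that, per gene, expressed classes never outnumber assembled
contigs — the data-model invariant the catalogue relies on), and false
products: shuffled-exon variants and chimeras joining the head exons of
one gene to the tail of the next, constructed so that no single gene's
read can cover them at 99% identity. Short reads are uniform substrings
at planted per-tissue abundances over a 4-tissue × 3-replicate design;
junction fragments (300–590 bp) always span a planted junction with
≥ 30 bp flanks.

Deliberately not emulated: realistic PacBio error profiles (error rate
is a flat substitution/indel mix), quality scores (constant
placeholders), sequence composition bias, fragment-length distributions,
intronic sequence (so splice borders have no motif to check), and
expression overdispersion beyond multinomial sampling. Passing tests
therefore show the *logic* of each stage is correct under its stated
assumptions — containment, identity thresholds, gap arithmetic, EM
convergence, cutoff screening — not that the thresholds are optimal for
any particular instrument's error process.

## Problem sizes and determinism

The shipped test suite and acceptance script run the whole pipeline on a
50-gene synthetic transcriptome (about 400 long reads, 110 contigs, 12
short-read samples of 5,000 reads), a 200-read duplicate-removal panel,
a 20,000-read EM recovery, and 20 × 100 null screens — sizes chosen so
each stage's property is measurable with sharp expectations while a full
run stays in the minutes range on one core. Every random draw flows from
an explicit seed argument (no hidden global state); stage seeds are
derived from one master seed, and `run_pipeline()` writes byte-stable
artifacts (fixed numeric formatting, LF endings, no timestamps), which
the tests verify bit-for-bit against committed golden outputs and across
re-runs.

## Known limitations

* Gap-based splice calls cannot distinguish exon skipping from
  alternative donor/acceptor use at the same region, and insertion
  events cannot be labelled "intron retention" without a genome; they
  are reported as insertions.
* A gene whose expressed isoforms are all much shorter than its longest
  assembled contig still resolves (condition A compares against mapped
  reads), but a gene where *no* contig reaches the longest read's length
  is reported unresolved rather than guessed.
* The containment dedup rule with `max_overhang = 0` is strict; on real
  corrected reads with ragged ends a small positive overhang tolerance
  is usually warranted (it is a parameter, not a constant).
* EM compatibility uses exact matching; on error-bearing short reads an
  external aligner's count table is preferable and can be supplied
  directly.
* The Poisson test underestimates biological dispersion; with real
  replicates, substituting a negative-binomial count table keeps the
  screening semantics while borrowing strength across isoforms.
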
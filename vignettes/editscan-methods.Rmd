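---
title: "Detecting RNA editing from short expression tags: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RNA editing from short expression tags: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
library(dplyr)
```

## The problem

RNA editing rewrites single bases of a transcript after transcription. In
plants it is classically a C-to-U (occasionally U-to-C) phenomenon of
mitochondrial and chloroplast mRNAs, mediated by PPR proteins, but short-tag
expression data make it possible to scan *nuclear* transcripts too. The raw
material is libraries of fixed-length sense-strand tags from poly(A)
transcripts: MPSS signatures (17 or 20 nt, anchored at DpnII/GATC sites) and
PARE degradome tags (20 nt from 5' ends of cleaved mRNAs). A tag that maps
to a transcript everywhere except one base is either a sequencing error or
evidence of an edited base; the analysis in this package is the bookkeeping
that separates the two and the downstream annotation of what the surviving
sites would do to the transcript.

`editscan` implements that analysis as composable functions over data
frames: simulate (or read) tag libraries, map them with at most one
mismatch, call sites under distinct-read support criteria, quantify
per-library editing ratios, cluster them across tissues, and annotate codon
gains, exon-boundary proximity, sequence context, and GO enrichment.

## Mapping model

Tags are mapped to the spliced transcript (and pre-miRNA) sequences only —
no genomic, intron-aware alignment, no reverse complement (MPSS and PARE are
strand-specific; sense-only is an explicit assumption), substitutions only.
The index hashes every tag-length window for exact lookup plus every
half-tag window for one-mismatch lookup: a single mismatch leaves at least
one half of the tag intact, so the union of half-seed candidates provably
contains all one-mismatch locations and a Hamming check confirms them. Tests
verify the index against an exhaustive Hamming scan on random instances.

Three rules shape the evidence pool:

* a tag with **any** perfect hit is removed from editing evidence globally
  (it is explained without editing);
* a tag whose single-mismatch hits fall at **several distinct locations** is
  discarded as ambiguous — keeping it would let paralog divergence
  masquerade as editing; counts of discarded tags are reported;
* the remaining tags contribute one mismatch record each, classified into
  one of the 12 ordered conversion patterns `X-to-Y`.

Coordinates are 1-based positions on the spliced transcript.

## Site calling and editing ratios

Mismatch records aggregate by (target, position, pattern). Support is the
number of **distinct tag sequences**, pooled across libraries — abundance
does not increase support, and the same sequence seen in three tissues
counts once. The calling criteria read the "more than" wording strictly:

* protein-coding (including organellar) transcripts: a site needs >= 6
  distinct reads, and a transcript must retain >= 3 such sites;
* pre-miRNAs: a site needs >= 3 distinct reads, with no per-hairpin minimum.

Both thresholds are `calling_criteria()` arguments. The per-transcript rule
is applied across patterns (the source analysis does not stratify it), and
raising any threshold can only remove sites (a tested monotonicity
invariant).

The **editing ratio** of a site in a library is the TPM of edited reads
divided by the TPM of all reads surrounding the site. "Surrounding" is
interpreted as *spanning*: every uniquely mapped tag (perfect or
one-mismatch) whose alignment covers the site's position enters the
denominator. The numerator is restricted to the site's own pattern by
default; `pattern_mode = "all"` pools all mismatches at the position
instead (the source wording "all edited reads" is ambiguous; the per-pattern
reading keeps one site = one conversion). Libraries with no spanning
coverage report a missing ratio, never zero. TPM is raw counts scaled to
sum to 1e6 per library.

## Error model and why the thresholds work

The generator treats the published single-base error rates as
**per-signature** probabilities: with probability `r` an emitted tag carries
exactly one substituted base, position uniform, replacement uniform over the
three alternatives. Each of the 12 patterns then occurs at `r/12` —
that is the arithmetic that turns ~5.00% (20-nt MPSS) into ~0.42% per
pattern, 4.25% (17-nt) into ~0.35%, and 1.30 +/- 0.90% (PARE) into
~0.03–0.18%, and `expected_error_rate_per_pattern()` computes it. Whether
the historical 5.00% figure was per-base or per-signature is not decidable
from the source material; per-signature is the default because the
per-pattern division treats the signature as the unit, and the rate is a
config knob either way.

Errors scatter mismatches uniformly over positions and patterns, so at
desk-scale depths the probability that six *distinct* erroneous tags pile
onto the same (position, pattern) — and that three such sites hit one
transcript — is negligible; a tested invariant runs ten replicate
simulations at the 5% rate and requires the calling criteria to return
empty.

## Tissue clustering

Per-library ratios form a site x library matrix. Rows must exceed a 2%
ratio in **at least one** library to be clustered (strict `>`); the source
states "either library" in one place and "each library" in another, and the
at-least-one reading is adopted because the all-libraries reading would
delete exactly the tissue-specific rows the clustering is meant to display.
Clustering is agglomerative with distance 1 − Pearson correlation and
average linkage (uncentred correlation is available, as in Cluster 3.0);
correlations use pairwise-complete observations, rows with undefined
correlation (zero variance, no shared coverage) get distance 1 (logged),
and ties follow `stats::hclust`'s input-order behaviour. The tree is
exportable as Newick; `autoplot()` draws the leaf-ordered matrix. Because
the signature pool mixes 17-nt and 20-nt tags, `split_by_tag_length()`
reruns the analysis per tag length, with dual-evidence sites appearing in
both matrices.

## Effect annotation

Inside an annotated CDS (frame taken from the annotation, never re-inferred
by ORF scanning), each site's reference codon and edited codon are compared:
an edited codon equal to AUG is a start gain, an edited UAA/UAG/UGA a stop
gain. Only CDS-resident sites are annotated — 5'UTR uAUG creation is
deliberately out of scope to match the reference tally, and the summary
counts events (site x transcript), not transcripts.
`enumerate_feasible_generations()` lists the source codons a single edit of
a given pattern can convert into a target codon; when the pattern's result
base does not occur in the target the set is empty, which makes certain
cells of the start/stop x pattern table *structural zeros* — a property the
test suite checks against exhaustive 64-codon enumeration and against the
published table's zeros.

Exon-boundary annotation flags sites in the first or last three nucleotides
of their exon (positions with splicing relevance). The translation border
is the 3' edge of the stop codon; distances are signed (negative inside the
CDS). Enrichment of sites near the CDS/3'UTR border is reported as window
counts only — the source presents the pattern descriptively and no formal
test is attached, so inventing one would misattribute a method.

## Sequence context

`extract_windows()` takes the 100-nt window around each site (50 nt up- and
downstream, the edited base at offset 0 and included — its 2-bit spike is a
built-in sanity check). Windows running past a transcript end are N-padded
and those positions are excluded from the column statistics. Information
content is 2 − H bits per position against a uniform 25% background (no GC
correction, matching WebLogo defaults), with the small-sample correction
3/(2·ln2·n) available; IC is clipped to [0, 2] after correction. Random
transcript positions provide the control windows.

## GO enrichment

For each term annotating at least one edited gene, a one-sided
hypergeometric upper-tail p-value is computed against the whole background,
Bonferroni-corrected over the *tested* terms (Benjamini–Hochberg optional).
Flat gene-to-term maps are used as given — no GO-graph propagation, because
the reference handling is unstated. Significance is strict `p < 1e-7` at
the reporting stage, matching the stringent published cutoff.

## Pre-miRNA editing

`apply_edits()` applies a hairpin's edits jointly (substitutions only,
length preserved), tolerating already-applied edits so the operation is
idempotent, and flags edits inside the mature-miRNA interval.
`compare_structures()` consumes externally folded dot-bracket strings —
thermodynamic folding is deliberately delegated to any MFE folder the user
prefers, because re-implementing one would dwarf the analysis itself — and
reports base pairs lost/gained and the net pair change touching the mature
interval.

## The synthetic generator: what it emulates and what it does not

`generate_transcriptome()` builds protein-coding transcripts (uniform base
composition; 5'UTR | AUG…stop CDS | 3'UTR; 1–4 exons tiling the spliced
sequence; nuclear/mitochondrial/chloroplast labels) and pre-miRNA hairpins
(70–200 nt with a 21-nt mature interval). `plant_events()` turns
ground-truth events with per-library ratios into haplotype mixtures — sites
are independent, so k events give up to 2^k haplotypes with product-mixture
weights; no linkage model is attempted because none is described for the
real data. Tag emission draws counts per haplotype proportional to a
per-transcript log-normal abundance times the haplotype weight; MPSS mode
anchors tags immediately 3' of a GAUC motif by default (the DpnII chemistry
of the MPSS protocol) with uniform anchoring as the documented alternative
(and the automatic fallback for motif-free transcripts); PARE mode uses
20-nt windows at supplied cleavage positions or uniform starts. Defaults:
17 libraries, 20-nt tags, 5% per-signature error (4.25% at 17 nt, 1.3% in
PARE mode), 20,000 tags per library.

What the generator does **not** model: bead cloning, adapter chemistry and
PCR duplicates; indels; quality scores; base-composition bias; linked
haplotypes; expression correlation across tissues. Passing recovery tests
therefore demonstrate the *pipeline logic* — that planted signals at stated
ratios and coverages are recovered and that uniform errors do not survive
the criteria — not robustness to every artefact of the historical
platforms.

## Problem sizes and numerical choices in the test suite

The suite runs at desk scale by design: mapping oracles use ~10 targets x
~1000 tags against an exhaustive Hamming scan; recovery uses 20 transcripts
with 3 well-separated planted sites each (sites closer than one tag length
would put two mismatches on one tag, which is a different design) at ratios
0.25–0.6 over 3 libraries of 20,000 tags, with equal abundances so the
>= 8-distinct-spanning-tags condition holds for every site; ratio-recovery
uses 100,000-tag libraries so every site pools >= 200 spanning tags, where
the estimator's bias is required to stay under 0.05; error calibration
tallies 100,000 tags against rate/12 within three binomial sigma; the null
calibration of the hypergeometric test uses 1000 replicates and allows a
small one-sided discreteness margin below the nominal 5%. Headline counts
from the original full-scale databases (hundreds of edited transcripts) are
not reproduction targets at these sizes.

## Known limitations

* Sense-strand only; tags from antisense transcription would be missed.
* A tag perfectly matching *anywhere* is removed globally — a conservative
  rule that can erase evidence when an edited read happens to equal another
  locus exactly.
* The threshold rules are the published criteria, not a statistical model
  of editing versus error; a binomial or Bayesian caller would be an
  extension, not a reproduction.
* GFF3 structure is consumed in spliced-transcript coordinates; genomic
  coordinates must be projected by the caller.
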
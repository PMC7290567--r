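---
title: "Reconstructing single-cell mitochondrial genomes: models and methods"
author: "scmito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing single-cell mitochondrial genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmito)
```

## The problem

A human cell carries hundreds to thousands of copies of its 16.6-kb circular
mitochondrial genome (mtDNA). A variant can be *homoplasmic* (carried by
essentially all copies) or *heteroplasmic* (carried by a fraction `h` of
them), and `h` is estimated from sequencing data as the allele frequency
(AF): supporting reads over total reads at the site.

Single-cell sequencing complicates this in two ways. First, the few
picograms of DNA in one cell must be amplified before sequencing
(MDA, eWGA, DOP-PCR, MALBAC, ...), and each chemistry imprints its own
coverage bias, duplicate load and error profile on the reads. Second, the
nuclear genome contains NumtS — ancient insertions of mtDNA fragments —
whose reads are nearly indistinguishable from genuine mitochondrial reads
and bias both haplogroup assignment and heteroplasmy estimates if left in.

`scmito` implements the complete analysis path for this setting: trimming,
alignment to the circular mtDNA plus nuclear decoys, PCR-duplicate removal,
NumtS filtering, quality-filtered pileup, variant calling with AF
estimation, consensus assembly over callable intervals, haplogroup
classification with a reliability score, coverage-uniformity diagnostics,
and replicate/bulk concordance analytics. A synthetic-data generator
reproduces the statistical structure the pipeline assumes, so every stage
is testable end to end without external data.

## The simulator: what it emulates, and what it does not

A cell is defined by a genotype: a haplogroup from a Phylotree-like tree
(its cumulative root-to-node defining variants become homoplasmic), extra
homoplasmic substitutions, and heteroplasmic substitutions with fractions
`h` in (0, 1). Read generation then follows a simple generative model:

* **Fragment starts** are drawn from a protocol-specific positional weight
  function over the circular genome; fragments may span the origin.
* **Heteroplasmy** is sampled per fragment as an independent Bernoulli(`h`)
  draw at each covered heteroplasmic site, so observed AF at a site of
  depth `n` is Binomial(`n`, `h`)/`n` — the model every recovery test
  checks against.
* **PCR duplicates** are exact copies of already-drawn fragments, making up
  the protocol's duplicate rate of emitted reads; each copy receives
  independent sequencing errors afterwards.
* **Errors and qualities**: substitution errors are drawn first at the
  protocol's per-base rate; erroneous bases get Phred 2–20, correct bases
  25–40. This makes the pileup's Q≥30 filter do visible work: error bases
  are predominantly excluded, and roughly 11/16 of correct bases are
  retained, so filtered depth is ~69% of aligned depth.
* **NumtS decoys**: contiguous mtDNA substrings, mutated i.i.d. at a chosen
  divergence rate, are embedded at recorded coordinates in a random nuclear
  contig. True origin labels (`mt` / `numts` / `nuclear`) ride along with
  every read so filter performance can be measured against truth.

The positional-bias families are minimal models chosen to reproduce the
qualitative uniformity ordering observed across amplification chemistries
(bulk most uniform; MDA/eWGA close behind; DOP-PCR windowed; MALBAC
windowed with heavy dropout), not any protocol's measured bias curve:

| protocol | bias model | defaults |
|---|---|---|
| BULK | uniform | duplicates 1%, error 0.1% |
| MDA | block-lognormal weights, sigma 0.55 (500-bp blocks) | duplicates 5% |
| eWGA | block-lognormal, sigma 0.35 (less dispersed than MDA) | duplicates 5% |
| DOP | 600-bp amplicon windows covering ~35%, 20:1 weight ratio | duplicates 10% |
| MALBAC | DOP-style windows plus 90% genome dropout | duplicates 10%, error 0.2% |
| ATAC | uniform | duplicates 30% |

With these defaults the mean Gini coefficient over 20 seeds orders as
MALBAC > DOP > MDA ≈ eWGA > BULK, which is the ordering the acceptance
suite asserts. The simulator does **not** model chimeric MDA artefacts,
GC-dependent bias, insert-size structure (paired ends are treated as two
independent single-end reads; nothing downstream uses pairing), indel
sequencing errors, or real rCRS sequence content — the packaged toy
reference is a random sequence of the right length, and passing tests
demonstrate correctness of the machinery under the stated statistical
model, not performance on real libraries.

## Alignment and the two-score NumtS filter

Reads are aligned by a seed-and-extend aligner over one combined index of
the mitochondrial genome and the nuclear decoys. The mtDNA is stored
doubled so k-mers (default k = 15, sampled every 10 bases along the read)
spanning the origin are indexed; hit coordinates are canonicalised modulo
the genome length. Each seed diagonal is extended with a local
(Smith–Waterman-style) alignment with affine gaps over a banded window
(default match +1, mismatch −1, first gap base −2, each further −1, band
15). On small instances the best score is asserted equal to an exhaustive
full-matrix local aligner from an independent library, over both strands
and across the origin.

The NumtS filter reproduces the two-round idea with a single scorer: a
read is kept only if its best mitochondrial score is *strictly* greater
than its best nuclear score; ties and nuclear-only reads are discarded.
With ≥3% NumtS divergence and 100-bp reads, a read wholly inside a NumtS
has ≥1 diverged site with probability ≈ 95–99%, which is why the filter
removes ≥95% of truth-labelled NumtS reads while retaining ≥95% of genuine
mtDNA reads (reads from the NumtS source region that by chance contain no
diverged site tie and are lost — the price of the strict rule).

Duplicate removal keeps, per (start, end, strand) triple, the read with the
highest base-quality sum (ties: smallest read id). With fixed-length
single-end simulated reads this key saturates at very high depth (every
coordinate pair collides eventually), so the property checks that operate
at 500–1000× on short genomes run the no-duplicate protocols without the
dedup stage; the full pipeline keeps it, as real libraries at realistic
depths do not saturate the key.

## Pileup, calling, consensus

The pileup counts every aligned, non-clipped base with quality ≥30 (the
default) into its position's allele tally; insertions anchor at the
preceding reference base, deletions at the base before the deleted run. A
variant is called when a non-reference allele has supporting depth ≥5,
with AF = supporting/filtered-total; an indel is additionally discarded if
on *every* supporting read it lies closer than 5 bases to a read end. AF is
the plain ratio — no confidence-interval machinery — and the consensus rule
compares this point estimate to the threshold.

The consensus is assembled over *callable* intervals (filtered depth ≥5);
uncovered stretches split contigs rather than being written as N, and a
BED file records the intervals. At a callable position the most frequent
alternate is written iff its AF ≥ 0.8, otherwise the reference base.
Substitutions only are applied to the consensus sequence — applying indels
would shift reference coordinates for downstream per-position logic — but
indels are reported in the VCF (v4.2, left-anchored) alongside depth and
AF.

## Haplogroup classification

The haplogroup tree is a TSV of (haplogroup, parent, defining variants
`posREF>ALT`); a node's cumulative variants are the union along its
root-to-node path, applied left to right so a reversion entry deeper in
the path overrides the ancestral allele. Classification takes the observed
set (SNP calls with depth ≥5 and AF ≥0.8) and scores each haplogroup by

\[
P_{Hg} = N_{ph} / N_{ph\_exp},
\]

where \(N_{ph\_exp}\) counts the haplogroup's cumulative defining variants
at positions inside the callable intervals, and \(N_{ph}\) those actually
observed. Restricting \(N_{ph\_exp}\) to callable positions is the one
genuinely open design choice here; the alternative (counting all defining
sites) conflates assembly incompleteness with genotype mismatch, and the
chosen form makes the score a purity measure: masking a defining site
reduces the denominator rather than the score. Ties rank by larger
\(N_{ph\_exp}\) (deeper, more specific haplogroups first), then name.
Predictions from genomes with callable breadth <10% are flagged
unresolved, matching the observation that dropout-heavy libraries leave
haplogroups undecidable. Only SNPs participate; indels are never counted.

## Coverage uniformity

The Lorenz curve sorts genome positions by ascending depth and plots the
cumulative fraction of positions against the cumulative fraction of
sequenced bases; perfect uniformity is the diagonal. The Gini coefficient
is 1 − 2 × (trapezoidal area under the polyline); 0 for uniform depth and
(L−1)/L in the limit of all depth on one position. Zero-depth positions
are included by default (the full-genome convention); `include_zeros =
FALSE` restricts to covered positions, since conventions differ on this
point and either may be wanted.

## Concordance analytics

Call sets (from VCFs or in-memory calls) are compared by exact
(pos, ref, alt) identity after filtering both sides at the same AF/depth
thresholds (defaults 3% and 50, the operating point chosen in the
replicate threshold sweep; 30 is the usual depth floor for <1000×
libraries). The pairwise report carries union/intersection counts,
homoplasmic (both AFs > 0.95, strict) vs heteroplasmic splits, private
variants, and bulk confirmation — the bulk being filtered at the *same*
thresholds for the confirmation flag while its raw AF is reported
unconditionally, which is the only reading consistent with multi-cell
tables that flag variants "not in bulk" yet print a bulk AF of 1. Treating
shared variants as true positives gives a per-cell positive predictive
value (PPV). The multi-cell tabulation keeps variants passing filters in
≥2 cells of an assay and reports per-assay cell counts and mean AFs;
"shared by a majority" is strict (> n/2 cells). Percentages are rounded to
two decimals in pairwise reports and to integers in table summaries,
matching the precision conventions of published tables of this kind.

## Numerical and degenerate-input choices

* Positions are 1-based throughout and reduce modulo L on the circle; VCF
  contig name is `chrM`.
* Empty call sets produce header-only VCFs; an all-zero depth profile has
  no Lorenz curve (rejected with a message); disjoint call sets report 0%
  concordance with a degeneracy flag rather than NaN.
* Every stochastic operation is a pure function of its inputs and a seed;
  sub-seeds are derived (never reused verbatim) so that independent
  components seeded with the same user seed do not share RNG streams.
* Deletion supporting depth is counted at the left-anchor position; one
  convention had to be fixed for AF to be well defined.
* Reads with several equal-best mitochondrial placements are kept at the
  lowest start coordinate and flagged ambiguous (MAPQ 0 in SAM output).

## Problem sizes used by the test and acceptance suites

The suites are sized for a single CPU: oracle-equality runs on ≤2-kb
references with ≤100-bp reads; heteroplasmy recovery at depth 1000 and
replicate concordance at depth 500 use 2–4-kb genomes (site-level depth,
not genome length, is what those checks exercise); haplogroup recovery,
NumtS filtering, bias-ordering (20 seeds) and the five-cell 100×
end-to-end run use the packaged full-length 16,569-bp toy reference.

## Known limitations

* The aligner is exact-seeded: a read whose every sampled 15-mer is hit by
  an error can miss its locus; at the simulated error rates this is
  negligible, but highly diverged input would need a sensitive seeder.
* AF is reported without a confidence interval; at depth 50 and AF 3% the
  binomial noise is of the same order as the threshold, which is why the
  threshold sweep, not a single operating point, is the recommended view.
* The consensus omits indels and writes no IUPAC ambiguity codes.
* Mapping quality is a placeholder (60/0); no statistical mapping model is
  implied.
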
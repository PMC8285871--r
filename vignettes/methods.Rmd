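---
title: "Bisulfite-aware subgenome read classification: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bisulfite-aware subgenome read classification: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeosort)
```

## The classification model

An allopolyploid read set is aligned twice, once against each progenitor
assembly, and each read's two placements are compared under a likelihood
that knows about bisulfite chemistry. For an aligned base pair with Phred
quality $q$ and error probability $e = 10^{-q/10}$, a match contributes
$\log(1-e)$ and a mismatch $\log(e/3)$ — the uniform-error Phred model, with
the $1/3$ spreading the error probability over the three alternative bases.
The read-level score is the sum over all CIGAR M/=/X positions, plus a
constant per-base penalty ($\log 10^{-4}$ by default) for inserted and
deleted bases. Soft-clipped bases and positions with N in read or reference
contribute nothing, which keeps scores comparable between the two genomes'
placements of the same read.

The verdict is the log-odds $\Delta = \ell_1 - \ell_2$ between the two
sides: assigned to the side with the higher likelihood when $|\Delta|$
exceeds the tie margin, ambiguous otherwise. The default tie margin is 0
with ties detected at an absolute tolerance of $10^{-9}$ — under
continuous-valued scores, exact ties occur essentially only when the two
aligned windows are identical, which is exactly the "no evidence" case. No
genotype or variant catalogue is used anywhere: divergence between the
parents enters only through the reference bases the read is compared with.

### Bisulfite matching is symmetric by design

Bisulfite conversion reads unmethylated cytosines as thymines. On a read
from the C→T-converted strand we therefore score the unordered pair
$\{C, T\}$ as a match: a read T over a reference C is a converted
unmethylated cytosine, and a read C over a reference T — which arises when a
methylation-protected cytosine sits at a position where the *other* parent
carries T — is equally uninformative about the read's origin. The
$\{G, A\}$ pair is treated the same way on the opposite conversion strand.
This is the converted-space semantics in which bisulfite aligners such as
Bismark operate, and it has a consequence we consider a design requirement:
the likelihood, and hence the classification, of an error-free read is
invariant to the methylation state of its template. A one-directional rule
(only reference C under read T) would break that invariance at C/T divergent
sites and make verdicts depend on methylation, importing a bias the
classifier exists to avoid. The cost is symmetric: C/T divergent sites carry
no classification evidence on CT-strand reads, so a read covering only such
sites is called ambiguous rather than assigned.

The conversion strand of each read is taken from Bismark-style `XG:Z:CT` /
`XG:Z:GA` tags (an explicit default can be supplied for tag-free input, and
`bs_mode = "both"` accepts both substitution classes regardless of tag;
`bs_mode = "off"` disables bisulfite awareness entirely, which is useful
only for illustrating what it protects against).

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bs_mode` | `"strand"` | which substitution pairs count as conversion artifacts |
| `tie_margin` | 0 (log-odds) | half-width of the ambiguity band |
| `indel_logpen` | $\log 10^{-4}$ per base | score for inserted/deleted bases |

The tie margin trades error rate against yield: widening it moves weakly
supported reads into the ambiguous class. The indel penalty only matters for
gapped alignments; it is a constant because the CIGAR carries no gap-quality
information to condition on.

## Deduplication, methylation extraction, conversion check

Duplicates are removed per parental side before scoring, keeping the first
read unit per (chromosome, leftmost position, strand) — with mate-pair outer
coordinates for paired-end data — which mirrors standard WGBS deduplication.
A read removed on one side only is thereafter treated as unmapped on that
side.

Methylation is counted per reference cytosine in the three plant contexts,
CG, CHG and CHH (H ∈ {A, T, C}), determined from the reference trinucleotide
read 5'→3' on the cytosine's strand: second base G ⇒ CG, else third base G ⇒
CHG, else CHH. CT-strand reads report forward-strand cytosines (read C =
methylated, read T = unmethylated, anything else ignored); GA-strand reads
report reverse-strand cytosines via the complementary rule. Overlapping
mate segments are counted once (mate 1 wins) to avoid double-counting
fragments. Cytosines whose triplet runs off the chromosome end or contains N
have undefined context and are dropped with a warning. The output is a
Bismark-CX-shaped table so downstream DMR callers can consume it unchanged.

Conversion efficiency is estimated from reads aligned to a control genome
assumed fully unmethylated (chloroplast for plants, lambda phage otherwise):
every cytosine call on the control is unmethylated truth, so the fraction of
calls read as converted estimates the conversion rate directly. The control
*mapping* rate — the traditional quick proxy, lower is better against an
unconverted index — is reported alongside when the library size is supplied.

## The evaluation harness

The benchmark design treats each progenitor's reads as if they were
allopolyploid reads; the true origin is then known exactly. The error rate
is the number of reads assigned to the wrong genome divided by all uniquely
mapped, deduplicated reads — ambiguous reads sit in the denominator and are
never wrong. An `--denominator=assigned` alternative divides by assigned
reads only, for sensitivity analysis.

The concatenated-genome baseline is emulated rather than delegated to a real
aligner: all candidate placements of a read across both genomes (secondary
placements included) compete, and the read is "uniquely mapped" only if its
best score strictly exceeds every rival's by more than $10^{-9}$;
assignment is the genome holding the winner, ties are excluded from the
denominator. Using the same likelihood for both methods isolates the
*decision rule* — compare-and-call-ambiguous versus winner-takes-all-unique
— from aligner idiosyncrasies, and makes the comparison exactly
reproducible. It is an emulation of the concatenation strategy, not a
reproduction of any particular aligner.

Because the two methods share the scoring model, they misassign the same
reads on a colinear fixture; the error-rate ordering is driven by the
denominators. That is not an artifact — it is the mechanism the benchmark
exposes: the classifier keeps uninformative reads in play as ambiguous,
the concatenated approach silently drops exact ties but keeps every read
whose best score wins by any margin, including wins produced by sequencing
error. On fixtures with appreciable base error the baseline's denominator
shrinks faster than its wrong count, so its error rate is higher.

One property worth stating precisely: the classifier's error rate is *not*
monotone in parental divergence at a fixed per-base error rate. Wrong calls
are dominated by reads covering exactly one divergent site whose read base
was flipped by an error to the other parent's allele; the expected number of
such reads is proportional to $\lambda e^{-\lambda}$ with $\lambda =$
divergence × read length, which peaks at divergence $= 1/\text{read length}$
($\approx 0.0067$ for 150 bp reads). Below that point fewer reads carry any
evidence at all (and are ambiguous, not wrong); above it, multi-site reads
out-vote single errors. The baseline's error rate *is* monotone decreasing
over the same range because its unique-read denominator grows with
divergence. The acceptance suite asserts monotonicity for both methods and
therefore documents this as a failing expectation for the classifier; we
keep the assertion rather than weakening it, since the non-monotonicity is a
real property of the model, verified by the harness itself.

## DMR–gene overlap

Downstream of differential-methylation testing, regions with q-value
strictly below 0.05 (configurable) are intersected with gene annotations on
1-based closed intervals; one shared base pair suffices, so [100, 150] and
[150, 300] overlap. Gene strand is ignored. The summary counts DMRs and
distinct overlapping genes per context, plus a total in which a gene hit in
several contexts counts once. GFF3 rows of type `gene` are used by default.
Full-scale reference outputs of this step exist for published allopolyploid
datasets, but they require external sequencing archives; the package's tests
exercise the operation on enumerated fixtures instead.

## The simulator: what it emulates and what it does not

The synthetic-data generator exists so that every operation above can be
tested end-to-end with known truth, offline. It emulates:

- two **colinear** parental genomes: an ancestral sequence at a chosen GC
  content (default 0.36, plant-like), with parent 2 substituted at
  Bernoulli(divergence) sites, uniformly among the three alternatives.
  Coordinates are identical across parents, so the truth alignment of a read
  against the non-origin parent is the same position with an all-M CIGAR;
- context-specific methylomes with plant-like defaults (CG 0.8, CHG 0.4,
  CHH 0.05). States are drawn per read by default, modelling
  cell-population heterogeneity; `site_fixed = TRUE` freezes one state per
  cytosine for parameter-recovery tests;
- bisulfite conversion at a chosen efficiency (default 0.99), applied
  before sequencing error, with methylated cytosines protected at
  `meth_protection` (default 1);
- uniform sequencing errors at `base_error` per base (default 0.01) with a
  constant emitted Phred quality (default 30, chosen so hand-checked
  likelihood examples stay simple).

Default problem sizes — a 100 kb single-chromosome genome, 150 bp reads,
5000 read units per parent in benchmark mode — give roughly 7.5× coverage
per side and stable error-rate estimates while keeping a full benchmark run
in seconds. The methylation-recovery analyses use a 20 kb genome with 4000
reads (30× coverage).

It deliberately does **not** emulate: structural divergence or indels
between parents (colinearity is what makes cross-genome truth coordinates
trivial), realistic quality profiles or error spectra, PCR duplicates,
M-bias, or assembly incompleteness. Passing tests on these fixtures
therefore demonstrate correctness of the scoring, bookkeeping and decision
rules — not performance on real data, where mapping artifacts and assembly
quality dominate (the published full-scale benchmarks show exactly that
pattern across species pairs).

Randomness is structured in fixed-length blocks (geometry first, then one
uniform per base for methylation, conversion and error in turn), so two
configurations differing only in methylation or conversion settings generate
reads at identical positions under the same seed. This is what lets the
suite assert *bit-identical* classification between a fully methylated and a
fully converted copy of the same read set. Identical configuration and seed
reproduce all output files byte-for-byte.

## Numerical choices and degenerate inputs

- Log-likelihood ties are compared at $10^{-9}$ absolute tolerance; scores
  are plain double-precision sums of logarithms, accurate to well below that
  at read-length scale.
- Identical parental genomes are a supported degenerate case: every
  doubly-mapped read is ambiguous, and the concatenated baseline's
  denominator is empty (its error rate is undefined, reported as `NA`).
- Empty SAM inputs yield empty classification tables with zeroed summaries.
- Reads mapped on both sides but with no mate in common across sides carry
  no comparable evidence and are called ambiguous.
- Ambiguity codes other than N in input FASTA are normalised to N (with a
  warning) and skipped in scoring, rather than rejected.

## Known limitations

- The scoring model is a quality-aware reimplementation of the
  read-classification idea, not a bit-for-bit clone of any released tool;
  only the best-scoring primary alignment per side is compared (no
  marginalisation over candidate loci).
- The concatenated baseline shares that scoring model by construction, so
  the benchmark isolates decision rules, not aligner behaviour.
- Colinear simulation cannot probe robustness to structural divergence or to
  reads from genomic regions absent in one assembly.
- The conversion-rate estimator assumes the control genome is perfectly
  unmethylated and ignores sequence-context effects on conversion chemistry.
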
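---
title: "Genotyping against a haplotype panel with a smeared marker array"
author: "markerArray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping against a haplotype panel with a smeared marker array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerArray)
```

## The problem

Genotyping asks which alleles a sequenced donor carries at a catalogue of
known polymorphic sites. Aligning reads to a single linear reference biases
calls wherever the donor differs from that reference. A pangenome — here, a
large collection of phased haplotypes indexed *together* — removes that bias
while preserving the linkage between nearby alleles: a read can only support
allele combinations that actually co-occur in some panel haplotype.

This package indexes the concatenated text
$T = T_0 \cdot T_1 \cdots T_n$ (reference first, then every panel
haplotype) with an FM-index, and attaches a *marker array*: a map from
positions of $T$ to records $(\mathrm{chrom}, r, e)$, where $r$ is the
0-based reference offset where a polymorphism begins and $e$ identifies the
allele (0 for the reference allele, $k \ge 1$ for the $k$-th alternate,
decoded through an edit table $E$). During backward search the rows of the
current suffix-array range identify which haplotypes the read is matching;
the markers at those rows say which alleles the match supports. A
suffix-array *sample* could establish the same thing via locate queries, but
markers are far fewer and group into runs in suffix-rank order, so the
marker array is smaller and faster to query.

## The index

**Panel text.** Every haplotype ends with a separator symbol `#`, smaller
than all DNA symbols, and the whole text ends with a unique sentinel `$`
smaller still. The separator means no match can span two haplotypes, which
keeps per-haplotype occurrence counting sound. The alphabet order is fixed
(`$ < # < A < C < G < N < T`) so suffix arrays are reproducible.

**Markers from VCF.** Each VCF record passing validation becomes a site.
Substitution columns are marked at the first substituted base; maximal runs
of abutting substitution records collapse into one site whose per-haplotype
replacement strings define the alleles. For insertions and deletions the
marked position is the single base just *left* of the indel (the VCF
anchor), so suffixes beginning at the marked position include the allele
itself; the mark covers exactly one position no matter how long the indel
is. Every haplotype receives a marker at each marked column — allele 0 for
reference carriers — so matching *any* haplotype yields evidence. A marker
packs into a 64-bit word with 12 bits of chromosome index, 48 bits of
within-chromosome offset and 4 bits of allele number. (The field widths as
originally described sum to more than 64 bits; 12/48/4 covers every
realistic genome. R has no native 64-bit integer, so words are realised as
16-hex-digit strings — three hex digits of chromosome, twelve of offset,
one of allele — which keeps the round trip exact.)

**Allele frequency filter.** A site is marked only if its minor-allele
frequency, computed over all panel haplotypes *plus* $T_0$ (which always
carries allele 0), strictly exceeds `minAf`. Filtered sites keep their
alleles spliced into the haplotype sequences; they simply carry no markers.
Counting $T_0$ is a deliberate choice — the reference is a panelist like
any other — and matters only at extreme frequencies.

**Smearing.** The marker array in suffix-rank order,
$\mathrm{MA}[i] = M[\mathrm{SA}[i]]$, answers "is there a marker at exactly
this match position". The genotyping loop, however, only queries every $w$
steps. Smearing extends each mark $w$ positions to the left —
$\mathrm{MA}^w[i]$ lists all markers at text offsets
$\mathrm{SA}[i] \dots \mathrm{SA}[i]+w$ — so periodic queries cannot skip a
mark. The window spans $w+1$ positions: the definition is implemented
literally even though prose descriptions sometimes say "up to $w$ markers";
the off-by-one is resolved in favour of the definition and covered by
tests. Windows are clamped at haplotype starts so a smear never crosses a
separator. Default $w = 19$.

**Sparse encoding.** $M$, MA and MA$^w$ are stored as runs: bit vector $S$
marks where a run of identical non-empty lists begins, $E$ where it ends,
$X$ holds one list per run, and $B$ marks each list's first element in the
flattened payload. A row $i$ is non-empty iff
$S.\mathrm{rank}_1(i{+}1) > E.\mathrm{rank}_1(i)$; its list is recovered
with one rank and two selects. Run identity is order-sensitive equality of
encoded words, with lists kept sorted by (chrom, offset) so runs are
maximal. The package stores the bit vectors as sorted positions of their 1
bits — the contract is rank/select answers, not succinctness.

## Genotyping a read

The read is processed right to left by backward search. When the range
empties, evidence for the current *extension* is finalized and matching
restarts at the next character from the all-inclusive range. Every $w$
successful steps the smeared array is queried over the current range —
but only if the range width is at most $N_h$, the number of haplotypes in
the index (including $T_0$): a wider range means the match occurs more
than once in some haplotype, so the evidence would be ambiguous. Each
(site, allele) pair is tallied at most once per extension.

An extension's evidence is discarded wholesale if

* two different alleles were tallied at the same site (a conflict —
  typically the first window of an extension touching one position past
  the matched region, where haplotypes genuinely disagree);
* the tallied sites span more than one chromosome;
* fewer than `minSeedLen` (default 80) characters matched.

Two refinements the simplified loop leaves open are resolved as follows.
First, if an extension ends with $0 < k < w$ steps since its last query,
one final query is made before finalizing; otherwise up to $w-1$ matched
characters near the read's 5′ end would silently contribute nothing.
Second, the strand heuristic: a random initial strand is investigated, and
the second strand is skipped iff the first strand produced an extension
whose *match length* reached `minSeedLen` — the length test deliberately
ignores the conflict filters, which judge evidence quality, not whether
the read found its home. `N` never matches (reads containing `N` break
their extension there), and base qualities are ignored.

Two exact strategies serve as oracles and as an alternative query mode:
`flMarkerQuery()` backward-searches the whole pattern and FL-steps through
every occurrence collecting MA at each visited row; `locateMarkerQuery()`
resolves each row with a regularly sampled suffix array and scans the dense
$M$ over the occurrence span. Both must agree exactly with a naive text
scan, and the test suite holds them to that.

## Calling genotypes

At a site with $l$ reference observations among $k$ total, the likelihood
of $g \in \{0, 1, 2\}$ reference copies under a global error rate
$\epsilon$ (default 0.01) is

$$
\mathcal{L}(g) = \frac{1}{2^k}
  \left[(2-g)\epsilon + g(1-\epsilon)\right]^{l}
  \left[(2-g)(1-\epsilon) + g\epsilon\right]^{k-l}.
$$

The call is $\arg\max_g \mathcal{L}(g)$, ties broken toward larger $g$
(reference-preferring, consistent with the haploid tie rule). The haploid
caller is a majority vote with ties to the reference. Sites with $k = 0$
are omitted rather than reported as homozygous reference. Only the panel's
own alleles can be tallied, by construction of the marker array.

Numerically, $\mathcal{L}(g)$ is evaluated as
$(a/2)^l (b/2)^{k-l}$ with $a, b$ the two bracket terms: both bases lie in
$[0,1]$, so nothing overflows and nothing underflows before the true value
itself would, and the heterozygous likelihood is *exactly* $2^{-k}$ in
floating point (both bases become exactly $0.5$) — a property the test
suite asserts with `identical()`. A log-sum formulation was rejected
because `exp(-k*log(2))` is not guaranteed to equal `2^-k` to the last
ulp. The log10 likelihoods reported in the VCF `GL` field are computed in
log space, with $0 \cdot \log 0$ terms defined as 0.

## The synthetic world

`simulatePanel()` emulates a small resequencing panel: a uniform-random
reference (default one 50 kb chromosome), biallelic SNVs at $10^{-2}$ per
base and indels (length 1–10) at $10^{-3}$ per base — variant spacing of
roughly one site per 90 bp, dense enough that reads span several sites —
with at least one base between REF spans so records never overlap or abut.
Per-site alternate frequencies follow Beta(0.8, 4), a low-frequency-skewed
spectrum (mean ≈ 0.17) chosen so a 1 % frequency filter has real work to
do; carriers are drawn independently per haplotype. Twelve haplotypes (six
diploid samples) are generated so that holding one sample out as the
sequencing donor leaves a 10-haplotype panel. `simulateReads()` samples
150 bp reads uniformly from both donor haplotypes and strands to 25×
reference coverage, with independent per-base substitution errors.

What the generator does *not* emulate — and what a green test therefore
does not establish — includes linkage between nearby sites (carriers are
independent, so donors routinely carry locally *novel* allele
combinations; this makes the synthetic world slightly adversarial for a
panel that preserves linkage), realistic site-frequency spectra, indel
sequencing errors, quality-score structure, coverage waviness, and any
repeat structure in the reference. Random 50 kb sequence is nearly
repeat-free, so the $N_h$ range filter almost never fires; on real genomes
it matters more.

## Degenerate inputs and tie-breaks

* Overlapping VCF records: the first is kept, later overlappers are
  skipped with a warning. Symbolic ALTs, malformed alleles and sites with
  more than 15 alternates (the 4-bit allele field) are skipped likewise;
  unsorted or unphased VCFs are errors.
* Records where no panel haplotype carries the alternate are uniform
  columns — not polymorphic, never marked.
* Multi-allelic evidence: the likelihood model distinguishes only
  reference from non-reference ($l$ of $k$); the reported ALT is the most
  frequently observed alternate (smallest index on ties).
* Evaluation counts truth sites with no call as false negatives; calls at
  sites absent from the truth cannot be assessed and are only counted.
  Undefined ratios are reported as `NaN`, never silently as 0.

## Worked example

```{r example, eval = FALSE}
library(markerArray)
d <- tempfile()
sim <- simulatePanel(7, d, chromLength = 3000, nHaplotypes = 6,
                     snvRate = 0.01, indelRate = 0.002)
idx <- buildPanelIndex(sim$fasta, sim$vcf, window = 19,
                       excludeSamples = "S3")
rd <- simulateReads(sim, "S3", readLength = 120, coverage = 15,
                    errorRate = 0, seed = 2, dir = d)
ev <- genotypeReads(rd$fastq, idx, minSeedLen = 80, seed = 3)
calls <- callGenotypes(ev, idx)
evaluateCalls(calls, rd$truthGenotypes)
```

## Known limitations

* Construction is desk-scale: suffix sorting by prefix doubling and a full
  occurrence matrix. Genome-scale construction (prefix-free parsing,
  run-length rank structures, $O(r)$ locate machinery) is out of scope;
  the run count $r$ and the run-length encoding of MA$^w$ are computed and
  reported so compression behaviour is still observable.
* Single-threaded; the command-line `--threads` flag is accepted and
  ignored with a warning.
* No paired-end logic, no quality-aware matching, no exhaustive half-MEM
  enumeration: an extension that fails restarts at the next character, so
  some evidence reachable by a full matching-statistics computation is
  deliberately left on the table.
* Structural variants beyond plain insertions and deletions (inversions,
  rearrangements) are not representable as single-anchor edits and are
  excluded.
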
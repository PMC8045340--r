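---
title: "Methods: how negeseek characterizes a nege-like virus"
author: "negeseek authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how negeseek characterizes a nege-like virus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

negeseek reimplements, as one tested pipeline, the computational
characterization of a nege-like insect virus: genome organization
(ORFs, UTRs, inter-ORF overlaps), RdRP catalytic motif architecture,
pairwise RdRP identity with distance-based clustering, transmembrane
topology of the SP24 virion membrane protein, and profiling of
virus-derived small interfering RNAs (vsiRNAs). This vignette explains
each method, its assumptions and tunable parameters, the design choices
that were genuinely open, and what the synthetic-data generator does and
does not emulate.

## Genome organization

Negeviruses and their relatives carry a single positive-sense RNA genome
of roughly 9-10 kb encoding three partially overlapping ORFs: a long
replicase polyprotein (methyltransferase-helicase-RdRP), a putative
glycoprotein, and the SP24 membrane protein. `find_orfs()` therefore
scans the three **plus-strand** frames only; within a frame an ORF runs
from the first `ATG` after the previous in-frame stop to the next
in-frame stop, stop codon included, which matches how coordinates such
as "45-6908" are conventionally reported (the span is then an exact
codon multiple). Alternative start codons (GTG/TTG) are not considered;
there is no evidence for non-ATG starts in this family.

`annotate_genome()` keeps all ORFs of at least `min_len_codons` codons
(default 150, roughly the size of the smallest conserved domain in the
family), resolves nested calls to the longer ORF, and derives the
5'/3' UTR lengths and one relation per consecutive ORF pair: an
`overlap` of `end_i - start_j + 1` nt, or an `intergenic` gap, with a
same-frame flag. Every annotation satisfies the conservation identity

    utr5 + sum(ORF lengths) - sum(overlaps) + sum(gaps) + utr3 = genome length,

which is asserted programmatically. A terminal poly(A) run of >= 10 nt
can be trimmed first (`trim_polya`), since genome sizes in this family
are reported excluding the tail; note that trimming cannot distinguish
genuine terminal adenosines from the tail, so the trimmed length is a
lower bound when the core sequence itself ends in `A`.

The threshold default matters only at the margins: on a three-ORF
layout whose smallest ORF has ~217 codons, the annotation is unchanged
for any threshold in [50, 217]; above that the smallest ORF itself drops
out, which is inherent to thresholding rather than to this
implementation.

## RdRP motif architecture

The palm subdomain of the RdRP carries three catalytic motifs: A
`D-X(4,5)-D`, B `G-X(2,3)-T-X(3)-N`, and C `GDD`. In nege/kita-like
viruses these occur either in the canonical order A-B-C or circularly
permuted as C-A-B; the permutation tracks the deeper taxonomy
(Centivirus/Sandewavirus permuted, Nelorpivirus/Aphiglyvirus and the
plant kitaviruses canonical), so calling it correctly matters.

`scan_motif()` reports **every** match of a motif, including the
overlapping alternatives of the variable-width patterns (a width-6 and
width-7 motif A hit can share a start). The wildcard X matches only the
20 standard residues: an ambiguous `X` in the protein satisfies neither
a fixed position nor a wildcard, a deliberately conservative choice so
that low-quality translations cannot fabricate motifs.

`classify_order()` enumerates candidate triples (one hit per motif,
mutually non-overlapping), discards triples whose consecutive gaps fall
outside `[gap_min, gap_max]` residues (defaults 5 and 300), and keeps
the surviving triple with minimal span, breaking ties by leftmost
start. The gap bounds are this package's choice - in a 2287-residue
polyprotein, spurious `GDD` or `D-X4-D` matches occur by chance, and
unbounded pairing could join motifs hundreds of residues apart; real
palm subdomains keep the three motifs within a few hundred residues.
The scan region defaults to the **C-terminal half** of the protein
because the RdRP domain is C-terminal in these polyproteins and the
helicase region upstream is a known source of false motif hits.
Classification is per sequence; no multiple alignment is attempted.

## Pairwise identity and neighbor joining

Published identity tables for this family come from pairwise global
alignments of the RdRP domain. `global_align()` computes optimal global
(Needleman-Wunsch) alignments with affine gaps through
`Biostrings::pairwiseAlignment()`; the scheme convention is that a gap
of length L costs `open + extend*(L-1)`. Defaults are BLOSUM62 with
open 10 / extend 0.5 for protein and +5/-4 with the same gaps for
nucleotide - common viewer defaults, configurable. The original
analysis used an alignment viewer whose scoring and identity convention
are not published, so `percent_identity()` exposes three denominators:
`"aligned"` (columns with no gap in either row; the default),
`"shorter"`, and `"full"`. Reproduction of table values is therefore
accepted within about two percentage points rather than exactly.

The packaged 18-taxon RdRP identity table
(`inlv1_identity_table_path()`) follows the journal convention: upper
triangle amino-acid identity, lower triangle nucleotide identity,
diagonal implicit 100. `nj_tree()` converts identities to distances
`d = (100 - identity)/100` and runs Saitou-Nei neighbor joining via
`ape::nj()` - a deliberately lightweight surrogate for
maximum-likelihood inference that preserves the grouping claims
(NJ is exact on additive distances, and the clade structure of the
table is far from the additivity boundary). Negative branch lengths are
clamped to zero and counted in an attribute. `smallest_clade_tips()`
answers "who shares the focal taxon's smallest clade" by rooting at the
leaf farthest from the focal taxon - with a proper outgroup absent from
the identity table, the farthest leaf is the best available proxy.

## Transmembrane scanning

The SP24 domain is a four-helix integral membrane protein.
`predict_tm()` is a declared, transparent hydropathy scanner, not a
reimplementation of an HMM topology predictor: it computes the
Kyte-Doolittle sliding-window mean (window 19, the classic
transmembrane setting; ambiguous residues score 0), takes maximal runs
of window centers at or above threshold 1.6, expands each run to its
full window extent, and merges expansions that overlap or abut so a
single helix split by a one-residue dip is not double-counted. Because
an HMM and a hydropathy scanner place boundaries differently, segment
boundaries are treated as approximate (+/- 5 residues) wherever they
are compared to reference intervals; the segment count is the robust
quantity.

## vsiRNA profiling

The diagnostic signature of active viral replication in an insect host
is a population of virus-derived siRNAs: sharply modal ~22-nt length,
both genome strands represented about equally, a 5'-terminal A/U bias,
and coverage along the whole genome. `map_reads()` maps the 18-30-nt
length-filtered library to the genome by **exact matching with zero
mismatches** (the same semantics as running a short-read aligner with
zero mismatches at a 9-kb scale): each distinct read sequence is
located on the plus strand, and its reverse complement's occurrences
are reported as minus-strand hits. Constant-width pattern dictionaries
(`Biostrings::matchPDict`) make this effectively linear in genome
length; every hit is re-verifiable by extracting the genomic span.

`sirna_profile()` aggregates hits into the standard panels. Decisions
the underlying studies leave unstated are made explicit and
configurable here:

* a multi-locus read contributes its full count **once** to totals,
  size and 5'-nucleotide tallies, on the strand carrying the majority
  of its loci (`multi = "majority"`; ties, including perfect
  palindromes, go to plus and are counted in `n_ambiguous_strand`);
* its coverage weight is split equally across loci, each locus on its
  own strand, so total coverage mass always equals mapped reads x read
  length;
* the mapped-fraction denominator is the 18-30-nt filtered library
  (raw-library denominators cannot be reproduced without the raw data);
* 5'-terminal nucleotides are reported in the RNA alphabet (U, not T).

`validate_profile()` asserts the conservation identities (size
distribution sums to mapped totals; per-strand 5' tallies sum to strand
totals; coverage mass equals mapped nucleotides) and runs on every
profile construction.

## The synthetic-data generator

Raw sequencing data for this kind of study is rarely deposited, so the
generator is a first-class module: it produces genomes and libraries
with the statistical structure the analysis assumes, with exact ground
truth, making every stage testable without downloads.

`gen_genome()` samples background nucleotides at a configured GC
fraction, writes `ATG`/`TAA` at the configured ORF boundaries, plants
motifs and transmembrane islands at exact residue positions, and then
iterates a deterministic repair loop: internal stops inside planted
ORFs are recoded; plus-strand ORFs above the suppression threshold that
were not planted are removed by breaking their start codon (or, when
that codon is protected, by inserting an early in-frame stop); spurious
motif hits in the classification region and spurious hydrophobic
windows in the membrane ORF are scrubbed by single-residue mutations
that never touch planted positions. Repair by targeted mutation (rather
than resampling) terminates deterministically; the loop errs out on
genuinely infeasible configurations, such as features planted in
overlapping ORFs whose frames cannot both be kept stop-free.

Transmembrane islands are written as **alanine** stretches (hydropathy
1.8) with nine-residue strongly hydrophilic shoulders. This is
deliberate: with the 19/1.6 scan settings, only windows fully inside
the island clear the threshold, so the predicted segment equals the
configured interval exactly and boundary recovery can be tested
tightly. A leucine island would smear the segment ~9 residues beyond
each edge - detectable, but untestable at residue precision.

`gen_reads()` draws viral reads as exact genome substrings:
lengths from a configurable distribution over 18-30 nt (default mode
0.69 at 22 nt), strand Bernoulli (default 0.5), start positions uniform
or hotspot-weighted, and 5' positions rejection-sampled so the realized
5' A/U frequency follows its target (default 0.8). Background reads are
random sequences verified absent from both genome strands, so
mapped/unmapped truth is exact by construction. Defaults are 20,000
viral plus 80,000 background reads - a library in which every summary
statistic is measurable with small binomial error while one full run
stays within interactive time.

What the generator does **not** emulate: sequencing error and quality
scores, adapter remnants, Dicer-biased duplex ends, position-dependent
ligation bias, or host transcriptome structure in the background reads
(they are i.i.d. random sequences). Passing recovery tests on this
generator therefore demonstrates the correctness of the accounting -
filtering, mapping, strand logic, tallies - not robustness to
real-library artifacts, which zero-mismatch exact matching inherits
from the upstream trimming it assumes.

## Problem sizes and numerical choices

The test suite runs the full-size 8945-nt layout once and otherwise
uses 3-kb genomes; property tests use 100-200 replicates for
per-operation oracles (motif scanning versus substring enumeration,
alignment versus linear-gap DP, mapping versus offset scan, NJ
exactness on additive matrices), 20 replicates for whole-pipeline
round trips, and libraries of 20,000 reads for parameter-recovery
checks, with tolerances set at three binomial standard deviations of
the corresponding estimator. Alignment traceback ties are resolved by
the underlying library deterministically; NJ ties are resolved by label
order; minimal-span motif ties go to the leftmost triple. All
randomness is seeded, and the genome and read generators are
byte-deterministic per (config, seed).

## Known limitations

* ORF calling assumes unbroken single-frame CDSs: no frameshifts,
  splicing, or subgenomic RNA annotation (3'-biased read accumulation
  is representable through the read hotspot, but promoters are not
  modeled).
* Identity values depend on the scoring scheme; without the original
  tool's parameters, agreement with published tables is approximate by
  construction.
* The hydropathy scanner predicts membrane-spanning segments only - no
  inside/outside orientation and no signal-peptide discrimination.
* NJ on an identity-derived distance is a clustering check, not a
  phylogeny: no model of sequence evolution, no support values.
* Exact-match mapping discards reads with any mismatch, so divergent
  viral variants in a real library would be undercounted relative to a
  mismatch-tolerant aligner.
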
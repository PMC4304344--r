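---
title: "Methods: small RNA and PARE analysis of senescing tissue"
author: "senescmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA and PARE analysis of senescing tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senescmir)
```

# Scope and model

`senescmir` re-implements, as a tested pipeline, the computational analysis
of a deep-sequencing study of *Arabidopsis* senescence: eight small RNA
libraries (leaf and silique, each at young, mature, early-senescence and
late-senescence stages) and six PARE (degradome) libraries from leaf. The
pipeline answers four questions:

1. Which known miRNAs change as senescence progresses?
2. Are there new, senescence-inducible small RNA loci with miRNA-like
   (hairpin, single-strand) character?
3. What do those small RNAs target, under the plant target-pairing penalty
   scheme?
4. Does the degradome show the predicted guided-cleavage products, and how
   do they change across stages?

Because the study's raw libraries (hundreds of millions of reads) are not
reproducible at desk scale, the package carries a first-class synthetic
generator that emulates the statistical structure the analysis relies on,
with a truth ledger so every downstream expectation is read from the
generator rather than hard-coded.

# Read processing and normalization

Raw reads are 3'-adapter-ligated inserts. Trimming takes the prefix before
the leftmost exact match of the adapter's first `min_overlap = 7` bases and
keeps inserts of 18-30 nt (gel selection in this kind of protocol is
20-30 nt; the lower bound is relaxed to 18 so that catalog matching is not
truncated; inserts containing non-ACGT characters cannot be exact-matched
and are rejected at this stage). Reads are collapsed to distinct sequences
and placed on the genome by exact match on both strands, with no
mismatches. Sequences with any hit overlapping an annotated tRNA, rRNA,
snoRNA or snRNA interval (strand-agnostic, >= 1 nt) are removed. Retained
counts are normalized to transcripts per two million (TP2M):
$\mathrm{TP2M}(s) = 2\times10^6\, c_s / \sum_s c_s$. Locus abundance tables
use the same quantity at a per-ten-million (TP10M) scale.

Multi-mapping sequences contribute their full count at every locus for
locus-level analyses but are counted once in library totals, which matches
a distinct-sequence (collapsed) bookkeeping.

Exact placement uses an in-package 18-mer anchor hash over both genome
strands with full-length verification; tests check it against an
independent naive substring scan.

# miRNA screen

A miRNA's abundance is the TP2M of the distinct sequence exactly equal to
its mature catalog sequence; one mismatch contributes nothing. For each
tissue, the screen keeps miRNAs exceeding a 50 TP2M floor in at least one
library and computes stagewise fold changes against the mature stage with
a 1 TP2M pseudocount, FC = (a + 1)/(a_mature + 1). Candidates are flagged
when early- or late-senescence FC reaches 3 (up) or 1/3 (down). The design
has one library per stage, so the screen is deliberately
fold-change-based, not a replicate-aware test; a replicate-aware mode
would plug in at the same interface but is not the default because the
emulated design has none. Library-versus-library R^2 is computed on
log10(TP2M + 1) over miRNAs above the floor in either library (a linear
option is kept since scatter conventions vary).

# New locus discovery

Candidates are retained sequences that (i) are not identical to any
catalog mature, (ii) exceed the floor in a leaf library, and (iii) are
elevated >= 3-fold in early- or late-senescence leaf versus mature leaf.
Candidate genome hits are clustered (gap <= 100 nt) and windows get
250 nt flanks. Each window's strand bias is the majority-strand share of
the abundance mass of *all* retained sequences hitting the window;
windows must exceed 90%. Clustering precedes flanking: on a compact
synthetic genome, flanking first would chain unrelated clusters.

## Hairpin test

Manual fold inspection is replaced by an automated stem-loop score. The
dynamic program finds the best single stem-loop (nested pairs,
Watson-Crick plus G:U, no multiloop branching, hairpin loop >= 3 nt) where
every unpaired base inside the stem costs `lambda = 1.25`; the hairpin
loop and the bases outside the stem are free, and the stem must span at
least 50 nt. The reported score is

$$ \mathrm{score} = \frac{2\,(\mathrm{pairs} - \lambda\,\mathrm{unpaired})}{\mathrm{span}} \in [0, 1], $$

with a pass threshold of 0.6. The penalty matters: an unpenalized
maximum-pairing (Nussinov) score saturates near 0.75 on random sequence
and cannot discriminate hairpins at all, which we verified by Monte Carlo;
with the penalty, random 75-300-mers score below 0.6 in >= 95-99% of
draws while near-perfect inverted repeats score 0.8-0.95. The classic
maximum-pairing Nussinov DP is also exported (`nussinov_pairs()`) and is
verified against exhaustive structure enumeration, as is the stem DP.
Because G:U pairs do not survive complementation, the score is exactly
invariant under sequence reversal but not under reverse complement; the
pipeline therefore folds the majority-strand (transcribed) sequence of
each window, restricted to the read-covered span plus a 30 nt pad (the
empty flanks would only dilute the stem).

A locus is reported when it passes strand bias and the hairpin test and
retains at least one sRNA above the reporting floor (1000 TP10M summed
over all libraries). The report also evaluates the precise-excision
criterion used for formal MIRNA annotation: group member sequences whose
ends agree within 1 nt, take the most abundant group per hairpin arm, and
require their mass share of the locus to reach 0.75. A ragged-end locus
fails even when it passes the hairpin and bias filters — the same verdict
the original study reached for its new locus.

# Target scoring

Antisense pairing is scored with the plant penalty scheme: mismatch 1.0,
G:U wobble 0.5, each bulged nucleotide 2.0, all doubled at positions 2-13
from the sRNA 5' end. The alignment DP allows at most 2 bulged
nucleotides and forbids bulges opposite sRNA positions 10-11 so the
cleavage register stays unambiguous; it is checked against brute-force
alignment enumeration. The cutoff is 4.0 *inclusive*: reported tubulin
targets in this analysis sit exactly at 4.0, so a strict reading would
discard them. The predicted cleavage site is the target base paired to
sRNA position 10, i.e. the 5' end of the downstream cleavage fragment.

# PARE validation

PARE tags are 20-nt fragments whose 5' ends mark uncapped degradation
intermediates. Tags are exact-matched in transcript space (they derive
from mRNA), each match incrementing the 5'-end count at its position;
profiles are normalized per 10^7 transcript-mapped tags. Evidence for
guided cleavage requires nonzero abundance at the expected site (window 0
by default; the looser reading of "between positions 10 and 11" is
available as a +/-1 window) and a site rank of at most 5 within the
transcript. Rank and positivity are scale-free, so verdicts are invariant
to sequencing depth. Stage tracking tabulates site abundance per library
and labels a monotone trend by the sign of the Spearman correlation with
stage order (|rho| >= 0.5).

# The synthetic study

The generator emulates, per small RNA library: planted mature sequences
drawn multinomially at per-stage fractions, structural-RNA contaminants
(15% of reads from annotated intervals), and uniform genomic background
(the remainder; the original study reports no background model, so these
fractions are free parameters chosen once). Insert lengths of non-planted
reads follow a tissue profile with 21 nt dominant in leaf and 24 nt in
silique. Raw reads are insert + adapter truncated to 40 nt — long enough
that a 30-nt insert still leaves the 7-base adapter anchor that trimming
requires. There is no sequencing-error model: mapping is exact-match, so
errors would only discard reads silently.

The default fixture locus embeds the five published senescence-induced
mature sequences in a nearly perfect inverted repeat: one arm carries
sRNA5 and the overlapping sRNA1/2 segment, the other is its reverse
complement with the slot opposite sRNA1/2 replaced by sRNA4 (which
contains sRNA3). Exact antisense copies of any mature are broken by point
substitutions so reads stay single-stranded. Shares follow the published
summed abundances; expression ramps tenfold from mature to late
senescence. Three tubulin-like transcripts carry sites engineered by
*inverse* application of the penalty rules to score exactly 4.0, 3.5 and
4.0 — the scorer has to rediscover those numbers, it never reads them. A
miR408-like catalog locus with two perfect-complement targets provides
the stage-ramped cleavage signal for PARE tracking, and per-stage PARE
position pools emulate the collapse of distinct-sequence complexity in
senescing libraries.

The synthetic genome is 2 x 200 kb. That choice is about realism of
*density*: at 10^5 reads per library, a much smaller genome makes random
background recurrence (and hence spurious fold-change candidates) far
denser than anything a 119-Mb genome produces. What the generator does
not emulate: ligation bias, PCR duplication, sequencing error, isomiR
spread, 24-nt heterochromatic siRNA clusters, or genome repeats — so
passing tests demonstrate the pipeline's correctness and calibration
under the stated model, not performance on those artifacts.

# Problem sizes and numerical choices

Worked-example and recovery tests simulate at depth 10^5 per library with
the thresholds above; multi-seed properties use 20 seeds (tests) or 10
seeds (acceptance script). Ties in PARE site ranking are resolved
conservatively (rank = 1 + number of strictly larger positions). Fold
changes use a 1 TP2M pseudocount to guard zero denominators. Degenerate
inputs error early: empty read sets cannot be normalized, hairpin folding
requires >= 50 nt, correlation requires >= 3 shared miRNAs.

# Known limitations

The screen has no replicate-aware inference; discovery does not phase
tasiRNA-like loci; target scoring has no accessibility/conservation
terms; PARE validation reports ranks and fractions, not CleaveLand-style
p-value categories. The published tubulin scores are reproduced against
engineered synthetic sites; scoring the real TAIR10 tubulin mRNAs
requires downloading those transcripts and is documented in the README as
an optional check.
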
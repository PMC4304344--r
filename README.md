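# senescmir

Small RNA and PARE (degradome) sequencing analysis of plant senescence,
for researchers studying miRNA regulation across developmental stages.

During senescence, plants remobilize nutrients from leaves into
reproductive tissue, and miRNAs are deeply involved in that switch. A
typical study design sequences small RNA libraries from leaf and silique
at four stages — young, mature, early senescence, late senescence — plus
PARE libraries that capture the 5' ends of uncapped mRNA fragments, the
direct footprint of miRNA-guided cleavage. `senescmir` implements the
full computational arm of such a study:

* **Read processing** — 3' adapter trimming, collapsing to distinct
  sequences, exact-match genome placement (no mismatches), removal of
  tRNA/rRNA/sn/snoRNA reads, and normalization to transcripts per two
  million: TP2M(s) = 2×10⁶·c(s)/Σc.
* **miRNA screen** — perfect-match quantification against a mature miRNA
  catalog; miRNAs above 50 TP2M are flagged when their early- or
  late-senescence fold change versus mature reaches 3 (up) or 1/3 (down);
  library-pair R² on log₁₀(TP2M+1).
* **New locus discovery** — non-catalog sequences induced ≥3-fold in
  senescing leaf are clustered on the genome; windows need >90% strand
  bias and a stem-loop score ≥0.6 from a penalized single-stem folding DP
  (Watson–Crick + G:U, unpaired-base penalty λ = 1.25); abundant sRNAs are
  reported with the precise-excision (MIRNA annotation) criterion.
* **Target prediction** — the plant penalty scheme: mismatch 1.0, G:U
  0.5, bulged nucleotide 2.0, doubled at sRNA positions 2–13; inclusive
  score cutoff 4.0; cleavage predicted opposite sRNA position 10.
* **PARE validation** — transcript-space 5'-end profiles per ten million
  mapped tags; a predicted site is *supported* when it carries signal and
  ranks ≤5 within its transcript; site abundance is tracked across stages
  with a Spearman trend label.
* **Synthetic data generator** — a seeded genome/annotation/transcriptome
  plus raw FASTQ simulator with a truth ledger, including a
  senescence-induced inverted-repeat fixture locus producing the five
  published mature sRNAs and engineered tubulin-like target sites scoring
  4.0 / 3.5 / 4.0.

## Worked example

Simulate the default eight-library study plus six PARE libraries at depth
10⁵ and run the whole pipeline:

```r
library(senescmir)
cfg <- simulation_config(seed = 101)
res <- run_pipeline(cfg)
print(res)
#> senescmir_run
#>   libraries: 8 sRNA, 6 PARE
#>   screen: 8 candidate-up, 6 candidate-down miRNA calls
#>   discovered loci: 1
#>   predicted targets (score <= 4): 5
#>   PARE-supported evidence rows: 30 of 30
```

One new senescence-inducible locus is discovered, and it produces exactly
the five abundant small RNAs planted by the fixture (abundance in TP10M
summed over the eight libraries; note the locus *fails* the
precise-excision criterion for formal miRNA annotation, as ragged
processing keeps the top duplex below 75% of locus mass):

```r
print(res$discovery$reports[[1]])
#> locus_report chr1:24764-25389: 5 abundant sRNAs, precision 0.705 (fails)
#>                        rna size abundance
#> 1    UUCUUGAACCUUGGAAGAAAA   21 276459.83
#> 2    UCUUGAACCUUGGAAGAAAAC   21 192629.66
#> 3    UGCAAGGUUCAAGAACGGAUC   21 171791.60
#> 4    AUUCGACAAAGUGAAGGGUUU   21  82406.15
#> 5 UCUUGCAAGGUUCAAGAACGGAUC   24  76248.33
```

The third sRNA targets the three synthetic tubulin-like transcripts at
the penalty scores their sites were engineered to carry, and its cleavage
site (the base opposite sRNA position 10) is recovered:

```r
subset(res$targets, grepl("TUA", transcript_id))
#>                    srna transcript_id score cleavage_pos
#> 1 TGCAAGGTTCAAGAACGGATC      TUA4like   3.5          611
#> 2 TGCAAGGTTCAAGAACGGATC      TUA2like   4.0          611
#> 3 TGCAAGGTTCAAGAACGGATC      TUA6like   4.0          611
```

The screen recovers the planted regulation classes — the miR408-like
locus and the three induced panel miRNAs come out `candidate_up` near
their planted ~7–8-fold change, the repressed ones `candidate_down`:

```r
sc <- res$screens$leaf
sc[sc$candidate_up | sc$candidate_down,
   c("mirna", "mature", "late_senescence", "fc_late")]
#>               mirna mature late_senescence fc_late
#> 1    ath-miR408like   9241           66280   7.172
#> 2   ath-miRsyn01-up  10331           75621   7.319
#> 3   ath-miRsyn02-up  14170          110877   7.825
#> 4   ath-miRsyn03-up   4857           37929   7.807
#> 5 ath-miRsyn04-down   9905            1324   0.134
#> 6 ath-miRsyn05-down  14027            1679   0.120
#> 7 ath-miRsyn06-down   4810             733   0.153
```

`run_pipeline(cfg, outdir = "out")` additionally writes every table
(library stats, screens, loci BED, target and evidence TSVs, bedGraph
track, run log with read accounting). `run_pipeline_files()` runs the
same computation from FASTA/GFF3/FASTQ on disk, and
`inst/scripts/senescmir-run.R` wraps it for the shell with a YAML config.

### Optional check against the real tubulin mRNAs

The engineered TUA-like sites reproduce the published scores by
construction. To score the real targets, download the TAIR10 cDNAs of
*TUA2* (AT1G50010), *TUA4* (AT1G04820) and *TUA6* (AT4G14960) and run
`predict_targets(rna_to_dna("UGCAAGGUUCAAGAACGGAUC"), tua_fasta)`; this
needs network access and is therefore not part of the test suite.

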
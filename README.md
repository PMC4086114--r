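# RBPScan

Predicts and maps RNA-binding protein (RBP) binding sites on query RNA
sequences. RBPs recognize short degenerate motifs, so raw motif scanning
drowns in false positives; RBPScan calls sites with a clustering-aware
**Weighted-Rank (WR)** statistic calibrated against per-motif,
per-genomic-region empirical backgrounds, and optionally filters
non-conserved intergenic calls with a conservation track.

## Method at a glance

For a motif with floored column probabilities `p_i(b)`, every window of the
motif size gets the min–max normalized log-odds match score

    S = sum_i log2( p_i(b_i) / 0.25 ),   score = (S − S_min) / (S_max − S_min)

Match scores are converted to empirical p-values against a background score
sample built per motif and region class (splice flanks, internal exons,
5'/3' UTR exons, ncRNA, mid-intron/intergenic). Windows passing the
*significant* threshold (medium stringency: p < 0.005) become anchors; each
anchor is re-scored over a 50-nt window by

    WR = match(anchor) × (1 + min(1, Σ_{q∈C} match(q) / N)),  N = 50 − k + 1

where `C` are *suboptimal* neighbors (p < 0.01) whose k-mer centers lie
within 25 nt. The WR score is tested against the region's background WR
mean and sd with a one-tailed normal Z-score; sites with `p < 0.05` are
reported. For organisms without a background corpus, thresholds come from
the exact analytic score distribution of the motif (per-column convolution,
validated against exhaustive enumeration). Mid-intron/intergenic sites can
additionally be removed when the mean conservation of their 50-nt
environment falls below the average over intronic splice-flank regions.

A seeded fixture generator (`generateFixtures()`) and a CLIP-style
enrichment protocol (`ablationCompare()`, one-tailed Fisher's exact test on
strong vs weak binder sets) make the whole pipeline testable end to end
without external downloads.

## Worked example

```r
library(RBPScan)
m  <- parseIUPACConsensus("UGCAUG", "fox1", protein = "FOX1")
fx <- generateFixtures(m, seed = 1, nStrong = 100, nWeak = 100)
bg <- buildBackground(m, fx$background$mid_intron_intergenic)
cfg <- runConfig(backgrounds = list(fox1 = bg),
                 annotation = fx$annotation, track = fx$track, seed = 1)
res <- runPipeline(rbind(fx$strong, fx$weak), m, cfg)
head(res$sites[, c("seqId", "anchorOffset", "kmer", "matchScore",
                   "wrScore", "z", "p")])
```

```
        seqId anchorOffset   kmer matchScore  wrScore        z            p
1 strong_0001           59 UGCAUG          1 1.037037 4.681534 1.423679e-06
2 strong_0002           32 UGCAUG          1 1.055556 5.137507 1.392034e-07
3 strong_0004           34 UGCAUG          1 1.055556 5.137507 1.392034e-07
4 strong_0005           78 UGCAUG          1 1.037037 4.681534 1.423679e-06
5 strong_0006           55 UGCAUG          1 1.037037 4.681534 1.423679e-06
6 strong_0007           79 UGCAUG          1 1.037037 4.681534 1.423679e-06
```

Each row is one called binding site: the planted consensus copies score
`matchScore = 1`, their WR scores exceed 1 because single-mismatch copies
cluster inside the 50-nt window, and the one-tailed normal p-values against
the intergenic background are far below the 0.05 acceptance rule. The run
report for this batch counts 200 records, 23,000 scanned windows, 346
anchors and 80 surviving sites (84 before conservation filtering — the
filter removed 4 weak-set false positives in non-conserved loci).
`writeSummary()` and `writeBedGraph()` produce the 1-based summary TSV and
the 0-based BedGraph track.

A command-line front end over the same functions ships at
`inst/scripts/rbpscan.R` with `scan`, `build-background`, `fixtures` and
`enrich` subcommands.

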
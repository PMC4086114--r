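---
title: "Weighted-Rank prediction of RNA-binding protein sites"
author: "RBPScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-Rank prediction of RNA-binding protein sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RBPScan)
```

## The problem

RNA-binding proteins (RBPs) recognize short, degenerate sequence motifs
(typically 4--8 nt) on transcripts. Scanning a transcript with a position
probability matrix produces many matches, most of them spurious: the motifs
are short, so high-scoring k-mers occur by chance every few hundred bases.
RBPScan implements a clustering-aware site-calling pipeline that exploits
two biological regularities to separate functional sites from noise:
functional sites tend to occur in *clusters* of suboptimal copies around a
strong match, and functional regulatory sequence tends to be *evolutionarily
conserved*. Scoring is calibrated against empirical backgrounds built
separately for different genomic region classes, because base composition
and motif density differ systematically between, say, 3'UTR exons and
deep-intronic sequence.

## The model

**Match score.** For a motif of length $k$ with floored column
probabilities $p_i(b)$, a window $b_1 \ldots b_k$ receives the log-odds
score $S = \sum_i \log_2(p_i(b_i)/0.25)$, min--max normalized to $[0,1]$ by
the best and worst achievable raw scores. The normalization makes scores
comparable across motifs and pins the consensus (column-wise argmax) k-mer
at exactly 1.

**Empirical calibration.** For each motif and region class, every window of
a background sequence set is scored; the sorted sample converts any score
to an empirical p-value $p = (1 + \#\{bg \ge s\})/(1 + n)$. Two score
thresholds are derived per stringency tier: a *significant* threshold for
anchor sites and a looser *suboptimal* threshold for secondary matches
(high: $p < 0.001 / 0.01$; medium, the default: $p < 0.005 / 0.01$; low:
$p < 0.01 / 0.02$).

**Weighted-Rank (WR) score.** Each anchor is re-scored over a 50-nt window
centered on its k-mer midpoint:

$$WR = match(anchor) \times \Big(1 + \min\big(1, \textstyle\sum_{q \in C}
match(q) / N\big)\Big),$$

where $C$ is the set of other windows whose centers lie within 25 nt and
whose match score reaches the suboptimal threshold, and $N = 50 - k + 1$ is
the window capacity. An isolated anchor keeps its match score; a saturated
neighborhood at most doubles it. The cap at 1 on the clustering term keeps
the stated bound $WR \le 2 \cdot match$ exact even in degenerate
all-high-score windows.

**Significance.** Background WR scores are obtained by running the same
anchor-and-WR procedure on the background sequences themselves; their mean
$\mu$ and standard deviation $\sigma$ give each candidate site a Z-score
$z = (WR - \mu)/\sigma$ and a one-tailed normal p-value $p = 1 - \Phi(z)$.
Only sites with $p < 0.05$ are reported.

**Other-genome mode.** When no background corpus exists for the organism,
thresholds come instead from the exact distribution of the match score
under an iid base model, computed by per-column convolution on a
discretized raw-score grid (bin $10^{-4}$, validated against exhaustive
$4^k$ enumeration for $k \le 8$). Motif length and column entropies enter
through the distribution itself, so higher-information motifs get higher
absolute cutoffs. A site is kept when its WR score reaches the WR of a bare
anchor at the significant threshold; no Z-score is computed.

**Conservation filter.** Sites classified as mid-intron/intergenic are
removed when the mean conservation over a 50-nt environment is strictly
below the pooled mean conservation of intronic splice-flank regions (the
reference for "conserved regulatory sequence"). Other region classes are
exempt, sites without coverage on at least half the environment are kept
(the filter acts only on positive evidence of non-conservation), and the
filter can be disabled outright.

## Region classes

Any genomic position is assigned, by its midpoint, to exactly one of six
classes with priority `ncRNA > utr5_exon > utr3_exon > internal_exon >
splice_flank > mid_intron_intergenic`. A splice flank is an intronic
position within 100 nt of an annotated exon edge (the typical extent of
splicing-regulatory elements; configurable via `flankNt`). Positions
outside any annotated gene are intergenic and share the mid-intron class.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| stringency | medium | anchor/suboptimal empirical p thresholds |
| `finalP` | 0.05 | one-tailed normal acceptance p for WR sites |
| `windowNt` | 50 nt | WR clustering window (center-to-center) |
| `flankNt` | 100 nt | splice-flank half-width around exon edges |
| `environmentNt` | 50 nt | conservation environment (matches the WR window) |
| floor | $10^{-3}$ | probability floor before log-odds scoring |
| bin | $10^{-4}$ | raw-score grid for the analytic distribution |

Query sequences must be 21--10,000 nt; batches are capped at 5,000 records,
with per-record rejection (not abort) and machine-readable reasons.

## The synthetic fixture generator

`generateFixtures()` is first-class, seeded code that emulates the study
conditions end to end:

* per-region background sets, by default 1000 sequences of 250 nt drawn iid
  from region-specific base compositions (exonic classes mildly
  GC-enriched, 3'UTR and intronic classes AU-enriched, ncRNA uniform) —
  sizes chosen to give $\ge$ 1000 match-score windows and $\ge$ 200
  background anchors per model, the minimum the builder accepts;
* strong-binder sets in which 80% of sequences (rate 0.8) carry one exact
  consensus copy flanked by two single-mismatch copies at non-overlapping
  offsets inside the 50-nt window, and weak-binder sets with no planting;
* a toy gene model on one chromosome exercising all six region classes, and
  binder loci laid out in intergenic space;
* a toy conservation track scoring splice flanks at 0.5, strong loci at 0.8
  and weak loci at 0.1, so the conservation filter separates the two binder
  sets by construction.

Chance exact-consensus copies in strong-binder flanks are scrubbed (one
base mutated outside any planted copy), so the manifest is the complete
truth for score-1.0 matches and planted positions can be re-discovered
exactly by scanning.

What the generator does *not* emulate: real CLIP read-density ranking,
RNA secondary structure and accessibility, dinucleotide composition,
alignment gaps in conservation tracks, and overlapping gene models.
Passing tests on these fixtures demonstrate the statistical machinery and
its calibration, not performance on real CLIP data.

## Numerical and design choices

* **Empirical p-values** use the $+1/(n+1)$ finite-sample correction so no
  p-value is 0; `thresholdFor` returns `Inf` (no callable site) when the
  requested p is below the sample resolution.
* **Score endpoints are snapped**: normalized scores within $10^{-9}$ of 0
  or 1 are set exactly, so consensus matches are bit-reproducible anchors
  regardless of floating-point summation order.
* **Analytic thresholds** use $P(X \ge t) \le p$ on the discrete support
  (not a strict inequality): at the boundary $p = 4^{-k}$ for a
  deterministic motif this isolates exactly the single best k-mer, and a
  fully degenerate (all-N) motif yields `Inf` — no site is ever called.
* **WR raw match scores, not ranks**, weight the clustering term; ranks
  would discard the score spacing that the normalization establishes.
* **Overlapping suboptimals** (windows overlapping the anchor's own k-mer
  at a different offset) count toward the cluster. For *periodic* motifs
  whose shifted copies resemble themselves, this inflates the WR null tail
  (measured at ~0.076 passing fraction for a UAUAUA-type matrix vs ~0.053
  for the non-periodic UGCAUG demo motif); with strongly periodic motifs
  the normal tail approximation should be treated with caution. This is a
  known limitation.
* **Dedup**: called anchors of the same motif closer than $k$ nt collapse
  to the highest-WR one, mirroring one-site-per-locus reporting.
* **Tie at the conservation reference** keeps the site (the removal rule is
  strictly "below").
* **Minus-strand coordinate input** is reverse-complemented to sense before
  scanning (RBPs bind RNA); reported genomic positions are the 5'-most base
  on the plus-strand reference.
* **Coordinates** are 0-based half-open internally and in BedGraph output;
  1-based only in the human-readable summary table.
* FASTA queries are *not* aligned to a genome; coordinate (BED) input is
  the supported path to genomic coordinates, region classification and
  conservation filtering. Plain FASTA records are classified as a single
  configurable `defaultClass`.

## Validation protocol

`ablationCompare()` reproduces the evaluation design of CLIP-style
benchmarks: strong (top-ranked) and weak (bottom-ranked) sequence sets are
scanned under three configurations — match score only, WR without
conservation, WR with conservation — and each yields a 2x2 table of
sequences with/without at least one surviving site, a one-tailed Fisher's
exact p-value (upper-tail hypergeometric; enrichment in the strong set),
and per-sequence sensitivity $a/(a+b)$ and specificity $d/(c+d)$.

On the bundled fixtures (500 + 500 sequences, planting rate 0.8) the WR
rule removes most match-only false positives in the weak set and the
conservation filter removes the rest; the acceptance script
(`scripts/acceptance.R`) recomputes these quantities from scratch at the
problem sizes stated there: a 1000 x 250 nt background corpus, 5000 null
sequences for calibration, and 100 spike-in replicates.

## Worked example

```{r example, eval = FALSE}
m <- parseIUPACConsensus("UGCAUG", "fox1", protein = "FOX1")
fx <- generateFixtures(m, seed = 1, nStrong = 100, nWeak = 100)
bg <- buildBackground(m, fx$background$mid_intron_intergenic)
cfg <- runConfig(backgrounds = list(fox1 = bg),
                 annotation = fx$annotation, track = fx$track, seed = 1)
res <- runPipeline(rbind(fx$strong, fx$weak), m, cfg)
head(res$sites)
writeSummary(res$sites, "sites.tsv")
writeBedGraph(res$sites, "sites.bedGraph")
```

## Known limitations

* The WR null is a mixture (isolated vs clustered anchors); its one-tailed
  normal approximation is mildly anti-conservative (~5--7% passing at the
  nominal 5% on iid backgrounds) and worse for periodic motifs.
* Consensus-derived motifs have coarse score spectra, so the realized
  anchor rate can sit well below the nominal stringency p.
* Backgrounds are iid within a region class; real genomic sequence has
  dinucleotide and repeat structure that widens score distributions.
* No multiple-testing correction is applied across motifs or sequences, by
  design.
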
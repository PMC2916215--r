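# protistTurnover

Seasonal turnover statistics for deeply sequenced protist amplicon time
series.

Single-time-point surveys of microbial eukaryotes systematically
understate diversity: a small guild of abundant taxa is present all
year, while most taxa are rare and confined to one or a few sampling
dates. This package implements the complete analysis chain used to
demonstrate that pattern on 454-style SSU rRNA (V3) amplicon series —
from raw tagged reads to the occupancy–abundance statistics — plus a
seeded simulator that generates whole runs with known ground truth, so
the pipeline can be exercised and validated without any external data.
It is aimed at microbial ecologists analysing amplicon time series and
at methodologists studying how read filtering shapes rare-biosphere
inference.

## What it computes

* **Read preparation** (`clipReads()`, `qualityFilter()`):
  demultiplexing by exact 4-bp tags, mutation-free PCR-primer matching
  (IUPAC-aware), homopolymer-tolerant adapter clipping, and the
  four-criterion filter — no Ns, mean Phred > 24 over the clipped read,
  ≥ 200 bp including primers, and ≥ 2 exact copies of the raw read in
  the whole dataset.
* **OTU construction** (`dereplicate()`, `matchAcrossSamples()`):
  exact-sequence OTUs within samples; across samples two sequences are
  one OTU iff they differ by indels alone (zero substitutions), i.e. a
  100%-identity match in which gaps are not considered. The result is an
  `OtuTable`, a `SummarizedExperiment` carrying the OTU × sample counts
  and representative sequences.
* **Analytic rarefaction** (`expectedRichness()`,
  `rarefactionCurves()`): the exact hypergeometric (Hurlbert)
  expectation

  E[S_g] = Σᵢ (1 − C(T−cᵢ, g) / C(T, g)),

  computed in log space, per sample and for the pooled dataset.
* **Turnover statistics** (`subsampleEqualDepth()`, `occupancyStats()`,
  `occupancyClassSummary()`, `slopeStatistics()`,
  `slopeOccupancyCorrelation()`): equal-depth subsampling; per-OTU
  occupancy N, total reads n and mean abundance when present A = n/N;
  occupancy-class summaries with one-way ANOVA + Tukey HSD; the slope m
  of each OTU's descending sorted log₁₀ counts against rank; and the
  Pearson correlation between m and N — the quantitative statement that
  rare taxa are seasonal while abundant taxa are stable.
* **Morphotype affiliation** (`affiliate()`,
  `lineageRelativeAbundance()`): matching OTUs to lineage-annotated
  reference sequences within one substitution (no indels) and per-sample
  lineage fractions.
* **Simulation** (`CommunityDesign()`, `simulateCommunity()`,
  `simulateReads()`): a two-guild community (persistent-abundant vs
  rare-seasonal) emitted as tagged 454-style reads with substitution,
  N-call and homopolymer-indel errors and per-read quality profiles.
* **Orchestration** (`runPipeline()`): all stages end to end from a
  list or YAML configuration, with TSV/FASTA/JSON outputs and a
  checksummed provenance manifest; byte-identical under a fixed seed.

## Worked example

Simulate a small seasonal run, prepare the reads, build the OTU table
and compute the turnover statistics:

```r
library(protistTurnover)

design <- CommunityDesign(nPersistent = 50L, nSeasonal = 150L,
                          readsPerSample = 3000L, seed = 42L)
truth  <- simulateCommunity(design)
layout <- ReadLayout()
reads  <- simulateReads(truth, ErrorModel(), layout, seed = 43L)

prep <- qualityFilter(clipReads(reads, layout),
                      rawCorpus = as.character(reads))
prep
#> PreparedReads: 15748 accepted / 30000 raw reads (10 samples)
#>   rejected: no_tag=465, mutated_primer=1097, indel_at_primer_junction=14,
#>             contains_N=463, low_quality=4446, too_short=5504, singleton=2263

tab <- matchAcrossSamples(dereplicateBySample(prep))
tab
#> OtuTable: 172 OTUs x 10 samples, 15748 reads

sub <- subsampleEqualDepth(tab, seed = 44L)
occ <- occupancyStats(sub)
mean(occ$N == 1)                       # share of single-sample OTUs
#> 0.285
mean(occ$A[occ$N == 10])               # mean abundance when present:
#> 34.0                                 #   taxa found in all 10 samples ...
mean(occ$A[occ$N == 1])                # ... vs single-sample taxa
#> 3.7

corr <- slopeOccupancyCorrelation(slopeStatistics(sub))
sprintf("r = %.3f (p = %.2g, n = %d)", corr$r, corr$p, corr$n)
#> "r = 0.546 (p = 1.3e-08, n = 94)"
```

About half of the raw reads survive the stringent filter; 28.5% of the
OTUs are confined to a single sample yet the ever-present OTUs carry an
order of magnitude more reads per occupied sample (34.0 vs 3.7), and
the positive slope–occupancy correlation shows that abundance profiles
flatten as occupancy grows. Pooling all samples roughly doubles the
richness of the deepest single sample in this small run
(`rarefactionCurves()`; 172 vs 76–87 OTUs), the rarefaction signature of
genuine between-sample turnover.

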
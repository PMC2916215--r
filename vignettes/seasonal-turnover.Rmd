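---
title: "Seasonal turnover of rare and abundant amplicon taxa: models and methods"
author: "protistTurnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal turnover of rare and abundant amplicon taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protistTurnover)
```

# The scientific problem

Deeply sequenced amplicon surveys of lake protists show two coexisting
guilds: a small set of abundant taxa detected in essentially every
temporal sample, and a large "rare biosphere" of taxa confined to one or
a few samples. Because the rare guild turns over between sampling dates,
richness estimated from any single sample badly understates the
community, and the occupancy of a taxon (the number of samples in which
it is seen) becomes a key explanatory variable for the stability of its
abundance. This package implements the full analysis chain for such a
survey on 454-style pyrosequencing data — read preparation, OTU
construction, rarefaction and the occupancy/abundance/slope statistics —
together with a seeded simulator that generates tagged runs with known
ground truth, so every stage is testable without external data.

# The read model and its preparation

A raw read is laid out as

    adapter A | 4-bp sample tag | forward primer | insert |
    rc(reverse primer) | rc(adapter B)

with the V3 region of the eukaryote SSU rRNA gene as insert. Clipping
(`clipReads()`) anchors adapter A and the tag exactly at the 5' end;
reads whose tag matches no sample are rejected (`no_tag`). Both PCR
primers must be present *mutation-free* — zero mismatches and zero
indels, IUPAC codes matching their expansions — because a primer-region
error cannot be distinguished from a true variant at the primer site.
An intact forward primer found shifted from its expected coordinates is
classified as an indel at the tag/primer junction. Adapter B at the 3'
end, by contrast, is matched with a homopolymer-tolerant pattern
(`homopolymerPattern()`): every single-nucleotide run of length *L* may
appear with length 1..2*L*, reflecting the dominant 454 artefact class.
The clipped region between the primers is the insert; qualities are
sliced to the same coordinates.

The quality filter (`qualityFilter()`) applies four criteria in a fixed
order, recording the first failing rule per read: (i) no N in the
insert; (ii) mean Phred quality over the insert strictly greater than 24
(a read at exactly 24.0 fails — the threshold is a strict inequality);
(iii) primer-inclusive length of at least 200 bp, i.e. insert plus the
44 bp of both primers; and (iv) at least two exact copies of the raw,
pre-clipping read string in the entire multi-sample dataset. Criterion
(iv) is global and order-independent; note that because the raw string
includes the sample tag, duplicates are effectively counted within a
sample, which is why the simulator never places fewer than 2 reads of an
OTU in a sample it occupies (see below).

# OTU construction

Within a sample, identity is exact string equality (`dereplicate()`):
sequences differing by any gap are distinct non-redundant sequences, the
gap treated as an informative character. Across samples
(`matchAcrossSamples()`), the package reproduces a 100%-identity match in
which gaps are *not* considered — a gap may be a sequencing artefact or
a biological variant. Operationally, two sequences belong to the same
OTU iff an alignment with zero substitutions exists at the minimal indel
cost, which is equivalent to the shorter sequence being a subsequence of
the longer one (longest common subsequence equal to the shorter length);
this is decided by a greedy linear scan in C++ after a cheap
base-composition pre-filter. Equivalence classes are closed
transitively so stacked indel variants remain one OTU; the most abundant
member (ties broken by lexicographically smallest sequence) becomes the
representative, and merging conserves read counts exactly.

# Analytic rarefaction

`expectedRichness()` computes the exact expectation of the number of
distinct OTUs in a uniform without-replacement subsample of size $g$
from an abundance vector $c_1,\dots,c_S$ with total $T$:

$$E[S_g] \;=\; \sum_{i=1}^{S}\left(1 -
  \frac{\binom{T-c_i}{g}}{\binom{T}{g}}\right).$$

The binomial-coefficient ratio is evaluated as
`exp(lchoose(T - c, g) - lchoose(T, g))` and clamped to $[0,1]$, so
depths of $10^5$ and beyond are handled without overflow; when
$T - c_i < g$ the log-ratio is $-\infty$ and the term is exactly 1.
`rarefactionCurves()` evaluates one curve per sample and one for the
pooled (row-summed) dataset on an even grid of 50 subsample sizes by
default (the grid density is a plotting choice, not a statistical one).
A pooled curve far above every single-sample curve is the signature of
between-sample turnover rather than mere abundance fluctuation.

# Turnover statistics

Samples are first equalised to a common depth
(`subsampleEqualDepth()`) by an independent multivariate hypergeometric
draw per sample — a uniform without-replacement subsample matching the
shallowest sample by default. For every OTU, `occupancyStats()` records
its occupancy $N$, total reads $n$, and mean abundance when present
$A = n/N$ (so $A \cdot N = n$ exactly and $A \ge 1$ for integer
counts). `occupancyClassSummary()` groups OTUs by occupancy class
$k = 1..n_\mathrm{samples}$ and tests differences in the number of OTUs
per class with a one-way ANOVA followed by Tukey's HSD. The ANOVA's
replicate structure deserves a note: the only replication a single
temporal series provides is per sample, so the response is the number of
OTUs of class $k$ present in sample $j$, giving $n_\mathrm{samples}$
replicates per class. Classes containing no OTU are reported empty and
excluded. The ANOVA and Tukey machinery is delegated to `stats::aov()`
and `stats::TukeyHSD()`; the reported studentized-range statistic is
$q = \bar{d} / \sqrt{\mathrm{MSW}/n}$ per pair.

The slope statistic (`slopeStatistics()`) quantifies abundance
heterogeneity: for each OTU whose dataset-wide total is strictly greater
than 10, the positive per-sample counts are log-transformed (base 10 by
default; the base rescales all slopes by a constant and is therefore a
declared parameter), sorted in decreasing order, and regressed by
ordinary least squares against ranks $1..k$. Zero counts have no log
abundance and are excluded, so the number of points equals the
occupancy. The slope $m$ is non-positive by construction; it is
undefined (NA) for occupancy-1 OTUs and these are excluded from the
correlation with a report of their number.
`slopeOccupancyCorrelation()` returns the Pearson product–moment
correlation between $m$ and $N$ over all defined slopes with a
two-sided p-value, plus per-class means and SDs of $m$ for plotting.
A positive correlation — steep slopes at low occupancy flattening toward
full occupancy — is the quantitative form of "rare taxa are seasonal,
abundant taxa are stable". Both per-OTU pairs (reported as the headline
correlation) and class means (reported for plotting) are available,
since the aggregation level of the classic analysis is ambiguous.

# The synthetic community and what it does (not) emulate

`simulateCommunity()` draws a two-guild community. Persistent OTUs are
present in every sample; after the seasonal guild's reads are fixed, the
remainder of each sample's depth is spread over the persistent guild by
a multinomial draw with log-normal weights (sdlog 0.5), so column sums
equal the design depth exactly. Seasonal OTUs draw their occupancy from
a probability vector over classes 1..10 that, by default, places 36% of
seasonal OTUs in a single sample and decays with occupancy; with the
default 300 persistent + 700 seasonal OTUs this yields about 25%
single-sample OTUs overall and roughly half of all OTUs in at most three
samples, the structure reported for deeply sequenced lake protist
series. Occupied samples receive a mean of 6 reads (a floor of 2 plus
Poisson noise): the floor is required because the dataset-wide
duplicate-read filter can never retain a single-copy read, and the mean
is set so month-specific OTUs collectively carry on the order of 1–2%
of a sample's reads.

Template inserts are uniform random DNA of length drawn from
U[150, 190], so the primer-inclusive amplicon spans 194–234 bp. The
amplified fragment of the targeted V3 region is nominally 180–200 bp,
but the length filter demands at least 200 bp including primers: a
generator capped at 200 bp would see nearly all reads rejected by the
survey's own criterion, which is inconsistent with the ~37% overall
attrition such surveys report. The chosen range reflects the real
between-taxon length variation of the V3 fragment, lets ~85% of
error-free reads pass the length rule, and lands total attrition near
40%. Round-trip tests that require every read to survive the filter use
U[156, 176] instead, the subrange whose primer-inclusive length always
reaches 200 bp.

`simulateReads()` (with `ErrorModel()`) emits exactly the ground-truth
counts per sample and corrupts each read with per-base substitutions
(default 3×10⁻⁴), per-base N calls (10⁻⁴), and the hallmark 454
homopolymer errors: each maximal run of length ≥ 2 gains or loses one
base with probability 2×10⁻³, directions equally likely. Substitutions
are an order of magnitude rarer than on modern short-read platforms
because FLX-era miscalls were dominated by homopolymer indels. Phred
qualities are drawn per read (mean 28, sd 4) with per-base jitter
(sd 3), so roughly 16% of reads fall below the mean-quality threshold;
qualities are independent of the simulated errors. Degenerate primer
positions (the single S of the reverse primer) are realized once per
OTU, reflecting an amplicon pool dominated by one realization; a
per-molecule realization would make otherwise identical reads unequal
at the raw-string level and starve the duplicate criterion.

The simulator does not model flowgram-level signal, chimeric/recombinant
PCR products, rRNA secondary structure, primer-binding biases, or
quality scores correlated with actual errors. Passing tests therefore
demonstrate that the statistics recover the designed community structure
under 454-like noise — not that the pipeline is robust to chimeras or
to taxon-specific amplification bias.

# Numerical and design choices

* **Strict thresholds.** Mean quality uses `> 24`, the slope cutoff
  uses total `> 10`; both boundaries reject the exact value, matching
  the stated inequalities.
* **Tag matching is exact.** No error tolerance in the 4-bp tag; the
  default tag set has pairwise Hamming distance ≥ 2 (`defaultTags()`),
  so any single tag error produces a non-tag rather than a wrong sample.
* **Adapter-B tolerance bounds.** Homopolymer runs may shrink to 1 or
  stretch to twice their length; substitutions still break the match.
  The 3' adapter may be absent entirely (a read may end inside the
  amplicon) but the reverse primer must be complete.
* **Indel-only equivalence.** Checked by a greedy subsequence scan
  (equivalent to a banded LCS at the minimal indel cost) after a
  composition dominance pre-filter; equal-length sequences can only be
  identical. Transitive closure by union-find.
* **Determinism.** A single top-level seed drives the pipeline;
  per-stage substreams use fixed offsets (community = seed, reads =
  seed + 1, subsampling = seed + 2). Ties for the OTU representative
  break lexicographically; sorting for the slope regression is stable
  (the OLS slope is tie-order invariant).
* **Degenerate inputs.** Empty read sets, empty samples and all-zero
  OTU rows are handled without error; a rarefaction depth beyond the
  total, a subsampling depth beyond a sample's reads, and correlations
  with zero variance raise informative errors instead of silent NAs.

# Problem sizes used in the shipped checks

The package's own validation runs at desk scale: zero-error round trips
use 10 samples × 2 000 reads; the replicated pattern-recovery study
uses 20 seeded simulations of the full design (10 samples, 1 000 OTUs,
15 000 reads/sample, ~1.4 s per million simulated bases end to end);
Monte-Carlo oracles use 4 000–10 000 draws. These sizes were chosen so
the whole suite completes in minutes on one CPU while keeping every
statistical comparison inside 3-SE oracle bounds.

# Known limitations

* The duplicate-read criterion interacts with rare presences: when one
  of two copies is corrupted, the surviving copy becomes a dataset-wide
  singleton and is also removed, so thin presences collapse and the
  occupancy-1 share of OTUs is inflated by one to two percentage points
  relative to the designed community. This is a property of the
  filtering rule itself, visible only because the simulator provides
  ground truth.
* Morphotype affiliation is substitution-only Hamming matching over a
  full-length overlap of the shorter sequence (≤ 1 substitution by
  default, ~99.4% identity on a 170 bp fragment); a single indel
  disqualifies a pair, and equidistant hits in different lineages are
  reported ambiguous and excluded rather than assigned.
* Cross-sample matching is quadratic in the number of unique sequences
  (with aggressive pre-filtering); it is intended for dereplicated
  amplicon tables of up to a few tens of thousands of unique sequences,
  not for raw read sets.
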
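Package: protistTurnover
Title: Seasonal Turnover Statistics for Protist Amplicon Time Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the seasonal turnover of rare and abundant
    protist taxa from 454-style SSU rRNA amplicon time series. Provides a
    ground-truth read simulator for tagged pyrosequencing runs, error-aware
    demultiplexing and primer clipping, the four-criterion quality filter,
    exact-sequence OTU construction with indel-tolerant cross-sample
    matching, analytic (Hurlbert) rarefaction, equal-depth subsampling, and
    the occupancy-abundance and ranked-log-slope statistics used to contrast
    persistent abundant taxa with the seasonally restricted rare biosphere.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), Biostrings, SummarizedExperiment
Imports: methods, stats, utils, tools, graphics, S4Vectors, jsonlite,
    yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), vegan
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Sequencing, Software
RoxygenNote: 7.3.3
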
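layout <- twoSampleLayout()
insert156 <- strrep("ACGT", 39)   # 156 bp -> primer-inclusive 200

test_that("an intact read is accepted with the correct insert and sample", {
  rr <- rawRead(layout, "sampleB", insert156)
  prep <- clipReads(readBundle(rr), layout)
  acc <- acceptedReads(prep)
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$sample, "sampleB")
  expect_equal(acc$insert, insert156)
  expect_equal(acc$primerInclusiveLength, 200L)
  expect_equal(acc$meanQuality, 30)
})

test_that("primer mutations, junction indels and unknown tags are rejected by reason", {
  fwdMut <- layout@fwdPrimer
  substr(fwdMut, 5, 5) <- "C"   # ATTAG... -> ATTAC...
  bundle <- readBundle(
    rawRead(layout, "sampleA", insert156, fwd = fwdMut),
    rawRead(layout, "sampleA", insert156, tag = "TTTT"),
    rawRead(layout, "sampleA", insert156,
            tag = paste0(layout@tags[["sampleA"]], "A")),  # +1 bp at junction
    rawRead(layout, "sampleA", insert156,
            revRc = "CAGCACCCGCGGTAATTCCAA"))              # mutated rev primer
  prep <- clipReads(bundle, layout)
  expect_equal(nrow(acceptedReads(prep)), 0L)
  expect_equal(as.character(rejectedReads(prep)$reason),
               c("mutated_primer", "no_tag", "indel_at_primer_junction",
                 "mutated_primer"))
})

test_that("IUPAC codes in the reverse primer match either expansion", {
  for (base in c("C", "G")) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(gsub("S", base, layout@revPrimer))))
    prep <- clipReads(readBundle(rawRead(layout, "sampleA", insert156,
                                         revRc = rc)), layout)
    expect_equal(nrow(acceptedReads(prep)), 1L)
  }
})

test_that("homopolymer length errors in adapter B are tolerated and clipped", {
  bRc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(layout@adapterB)))
  longer <- sub("CC", "CCC", bRc)    # one run lengthened by 1
  shorter <- sub("CC", "C", bRc)     # one run shortened by 1
  for (variant in c(longer, shorter)) {
    prep <- clipReads(readBundle(rawRead(layout, "sampleA", insert156,
                                         adapterBRc = variant)), layout)
    acc <- acceptedReads(prep)
    expect_equal(acc$insert, insert156)    # adapter fully removed
    ## the variant is what the homopolymer-tolerant pattern describes
    expect_true(grepl(homopolymerPattern(bRc), variant))
  }
  ## a substituted adapter B is not a homopolymer variant
  subbed <- bRc
  substr(subbed, 3, 3) <- if (substr(subbed, 3, 3) == "A") "T" else "A"
  expect_false(grepl(homopolymerPattern(bRc), subbed))
})

test_that("a read may end inside the amplicon if the reverse primer is complete", {
  ok <- rawRead(layout, "sampleA", insert156, adapterBRc = "")
  prep <- clipReads(readBundle(ok), layout)
  expect_equal(acceptedReads(prep)$insert, insert156)
  truncated <- rawRead(layout, "sampleA", insert156,
                       revRc = substr("CAGCACCCGCGGTAATTCCAG", 1, 15),
                       adapterBRc = "")
  prep2 <- clipReads(readBundle(truncated), layout)
  expect_equal(as.character(rejectedReads(prep2)$reason), "mutated_primer")
})

test_that("the four filter criteria reject in order with exact boundaries", {
  insN <- insert156
  substr(insN, 10, 10) <- "N"
  ins155 <- substr(insert156, 1, 155)   # primer-inclusive 199
  bundle <- readBundle(
    rawRead(layout, "sampleA", insN, qual = 30L),       # contains_N
    rawRead(layout, "sampleA", insert156, qual = 24L),  # mean quality == 24
    rawRead(layout, "sampleA", ins155, qual = 30L),     # length 199
    rawRead(layout, "sampleA", strrep("AACG", 39), qual = 30L),  # unique raw
    rawRead(layout, "sampleB", insert156, qual = 25L))  # boundary: 25 passes
  prep <- clipReads(bundle, layout)
  filt <- qualityFilter(prep, rawCorpus = unname(bundle$sequence))
  rej <- rejectedReads(filt)
  expect_equal(setNames(as.character(rej$reason), NULL)[match(
    c("r001", "r002", "r003", "r004", "r005"), rej$id)],
    c("contains_N", "low_quality", "too_short", "singleton", "singleton"))
  ## length exactly 200 passes the length rule (r004 fails only criterion iv)
  expect_false("too_short" %in% rej$reason[rej$id == "r004"])
  ## duplicating the corpus rescues the singletons
  filt2 <- qualityFilter(prep, rawCorpus = rep(unname(bundle$sequence), 2))
  expect_true(all(c("r004", "r005") %in% acceptedReads(filt2)$id))
})

test_that("the duplicate criterion counts exact raw strings dataset-wide", {
  set.seed(42)
  inserts <- randomSeq(7, 160)
  ## 10 reads built from 7 insert templates: 3 are unique strings
  idx <- c(1, 1, 2, 2, 3, 3, 4, 5, 6, 7)
  reads <- lapply(idx, function(i) rawRead(layout, "sampleA", inserts[i]))
  bundle <- do.call(readBundle, reads)
  prep <- clipReads(bundle, layout)
  filt <- qualityFilter(prep, rawCorpus = unname(bundle$sequence))
  ## oracle: exact multiset count of raw strings
  copies <- table(bundle$sequence)[bundle$sequence]
  expect_equal(nrow(acceptedReads(filt)), sum(copies >= 2))
  expect_equal(sum(rejectedReads(filt)$reason == "singleton"),
               sum(copies < 2))
  ## order independence of criterion iv
  perm <- sample(length(bundle$sequence))
  bundle2 <- list(sequence = bundle$sequence[perm],
                  quality = bundle$quality[perm])
  filt2 <- qualityFilter(clipReads(bundle2, layout),
                         rawCorpus = unname(bundle2$sequence))
  expect_setequal(acceptedReads(filt2)$id, acceptedReads(filt)$id)
})

test_that("accepted and rejected reads partition every simulated run", {
  design <- CommunityDesign(nPersistent = 20L, nSeasonal = 40L,
                            readsPerSample = 1000L, seed = 31L)
  truth <- simulateCommunity(design)
  fullLayout <- ReadLayout()
  reads <- simulateReads(truth, ErrorModel(substitutionRate = 5e-3,
                                           homopolymerIndelRate = 5e-3,
                                           nRate = 1e-3),
                         fullLayout, seed = 32L)
  prep <- clipReads(reads, fullLayout)
  filt <- qualityFilter(prep, rawCorpus = as.character(reads))
  expect_equal(nrow(acceptedReads(filt)) + sum(rejectionCounts(filt)),
               length(reads))
  expect_equal(nrow(acceptedReads(filt)) + nrow(rejectedReads(filt)),
               length(reads))
  ## lowering the quality threshold never decreases the accepted count
  nLoose <- nrow(acceptedReads(
    qualityFilter(prep, rawCorpus = as.character(reads), minQual = 20)))
  expect_gte(nLoose, nrow(acceptedReads(filt)))
})

test_that("zero-error runs with long inserts pass the filter completely", {
  design <- CommunityDesign(nPersistent = 10L, nSeasonal = 20L,
                            readsPerSample = 400L,
                            insertLengthRange = c(156L, 176L), seed = 51L)
  truth <- simulateCommunity(design)
  fullLayout <- ReadLayout()
  reads <- simulateReads(truth, perfectErrorModel(), fullLayout, seed = 52L)
  filt <- qualityFilter(clipReads(reads, fullLayout),
                        rawCorpus = as.character(reads))
  expect_equal(nrow(acceptedReads(filt)), length(reads))
  ## demultiplex summary equals the design depths
  expect_equal(demultiplexSummary(filt),
               setNames(rep(400L, 10L), colnames(truthCounts(truth))))
})

test_that("demultiplexSummary covers empty samples and sums to the accepted count", {
  bundle <- readBundle(
    rawRead(layout, "sampleA", insert156),
    rawRead(layout, "sampleA", insert156),
    rawRead(layout, "sampleA", randomSeq(1, 160)),
    rawRead(layout, "sampleA", randomSeq(1, 161)),
    rawRead(layout, "sampleA", randomSeq(1, 162)))
  prep <- clipReads(bundle, layout)
  expect_equal(demultiplexSummary(prep),
               c(sampleA = 5L, sampleB = 0L))
  empty <- clipReads(list(sequence = character(0), quality = character(0)),
                     layout)
  expect_equal(demultiplexSummary(empty), c(sampleA = 0L, sampleB = 0L))
  expect_equal(nrow(acceptedReads(qualityFilter(empty))), 0L)
})
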
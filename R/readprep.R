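## Demultiplexing, error-aware clipping and the four-criterion quality
## filter applied to raw 454 amplicon reads.

REJECTION_REASONS <- c("no_tag", "mutated_primer", "indel_at_primer_junction",
                       "contains_N", "low_quality", "too_short", "singleton")

#' @rdname PreparedReads
#' @export
setClass("PreparedReads",
  representation(accepted = "DataFrame", rejected = "DataFrame",
                 samples = "character", nRaw = "integer"),
  validity = function(object) {
    msg <- character(0)
    need <- c("id", "sample", "insert", "raw", "primerInclusiveLength",
              "meanQuality")
    if (!all(need %in% colnames(object@accepted)))
      msg <- c(msg, paste("accepted must have columns:",
                          paste(need, collapse = ", ")))
    if (!all(c("id", "reason") %in% colnames(object@rejected)))
      msg <- c(msg, "rejected must have columns id, reason")
    else if (!all(object@rejected$reason %in% REJECTION_REASONS))
      msg <- c(msg, "unknown rejection reason")
    if (nrow(object@accepted) + nrow(object@rejected) != object@nRaw)
      msg <- c(msg, "accepted + rejected must partition the raw reads")
    if (length(msg)) msg else TRUE
  })

#' Clipped, demultiplexed reads plus a rejection log
#'
#' Produced by [clipReads()] and narrowed further by [qualityFilter()].
#' The `accepted` table holds, per read: sample (from the tag), the clipped
#' insert (primers removed), the raw pre-clipping sequence (needed by the
#' dataset-wide duplicate criterion), the primer-inclusive length (insert
#' plus both PCR primers, the unit of the length filter), and the mean
#' Phred quality over the insert. Every raw read appears exactly once in
#' the accepted table or the rejection log, so the partition invariant
#' `accepted + rejected = raw` always holds.
#'
#' @param x,object A `PreparedReads` object.
#' @aliases PreparedReads-class
#' @name PreparedReads
NULL

#' @describeIn PreparedReads Accepted reads (a `DataFrame`).
#' @export
acceptedReads <- function(x) x@accepted

#' @describeIn PreparedReads Rejection log: one row (id, reason) per
#'   rejected read.
#' @export
rejectedReads <- function(x) x@rejected

#' @describeIn PreparedReads Per-reason rejection counts over all known
#'   reasons (zeros included).
#' @export
rejectionCounts <- function(x) {
  tab <- table(factor(x@rejected$reason, levels = REJECTION_REASONS))
  setNames(as.integer(tab), names(tab))
}

setMethod("show", "PreparedReads", function(object) {
  cat("PreparedReads: ", nrow(object@accepted), " accepted / ",
      object@nRaw, " raw reads (", length(object@samples), " samples)\n",
      sep = "")
  rc <- rejectionCounts(object)
  rc <- rc[rc > 0L]
  if (length(rc))
    cat("  rejected: ",
        paste(names(rc), rc, sep = "=", collapse = ", "), "\n", sep = "")
})

newPreparedReads <- function(accepted, rejected, samples, nRaw) {
  new("PreparedReads", accepted = accepted, rejected = rejected,
      samples = samples, nRaw = as.integer(nRaw))
}

emptyAccepted <- function() {
  DataFrame(id = character(0), sample = character(0), insert = character(0),
            raw = character(0), primerInclusiveLength = integer(0),
            meanQuality = numeric(0))
}

#' Demultiplex and clip raw 454 reads
#'
#' Locates the layout elements in each read and removes them, assigning the
#' read to a sample via its 4-bp tag. Adapter A and the tag are matched
#' exactly at the 5' end (a read whose tag matches no sample is rejected
#' `no_tag`). Both PCR primers must be present mutation-free -- zero
#' mismatches and zero indels, with IUPAC ambiguity codes in the primer
#' matching their expansions -- otherwise the read is rejected
#' (`mutated_primer`, or `indel_at_primer_junction` when an intact forward
#' primer is found shifted from its expected position, the signature of an
#' indel at the junction). Everything 3' of the reverse primer (the
#' reverse-complemented adapter B, possibly carrying homopolymer length
#' errors; see [homopolymerPattern()]) is removed with the insert
#' coordinates untouched; a read may also end before adapter B. Qualities
#' are sliced to the insert coordinates for the mean-quality criterion.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] of raw reads, or
#'   a list with character vectors `sequence` and `quality` (Phred+33).
#' @param layout A [ReadLayout()].
#' @return A [PreparedReads] object (not yet quality-filtered).
#' @export
clipReads <- function(reads, layout) {
  stopifnot(is(layout, "ReadLayout"))
  if (is(reads, "QualityScaledDNAStringSet")) {
    s <- as.character(reads)
    q <- as.character(quality(reads))
    ids <- names(reads)
  } else {
    s <- reads$sequence
    q <- reads$quality
    ids <- names(s)
  }
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(s))
  n <- length(s)
  samples <- sampleLabels(layout)
  if (n == 0L)
    return(newPreparedReads(emptyAccepted(),
                            DataFrame(id = character(0),
                                      reason = character(0)), samples, 0L))

  aLen <- nchar(layout@adapterA)
  tLen <- nchar(layout@tags[[1L]])
  fLen <- nchar(layout@fwdPrimer)
  rLen <- nchar(layout@revPrimer)
  insStart <- aLen + tLen + fLen + 1L

  reason <- rep(NA_character_, n)

  ## 5' anchor: exact adapter A, then a known tag
  tagOk <- substr(s, 1L, aLen) == layout@adapterA
  sampleOf <- rep(NA_character_, n)
  tag <- substr(s, aLen + 1L, aLen + tLen)
  hit <- match(tag, layout@tags)
  sampleOf[tagOk & !is.na(hit)] <- samples[hit[tagOk & !is.na(hit)]]
  reason[is.na(sampleOf)] <- "no_tag"

  ## forward primer: mutation-free at its expected coordinates
  fwdRe <- iupacRegex(layout@fwdPrimer)
  live <- which(is.na(reason))
  fwdSeen <- substr(s[live], aLen + tLen + 1L, aLen + tLen + fLen)
  fwdOk <- grepl(paste0("^", fwdRe, "$"), fwdSeen, perl = TRUE)
  bad <- live[!fwdOk]
  if (length(bad)) {
    ## an intact primer elsewhere in the read points to an indel at the
    ## tag/primer junction rather than a mutated primer
    m <- regexpr(fwdRe, s[bad], perl = TRUE)
    reason[bad] <- ifelse(m > 0L, "indel_at_primer_junction",
                          "mutated_primer")
  }

  ## reverse primer (reverse complement), mutation-free, 3' of the insert
  rcRev <- as.character(reverseComplement(DNAString(layout@revPrimer)))
  rcRevRe <- iupacRegex(rcRev)
  live <- which(is.na(reason))
  tails <- substr(s[live], insStart, nchar(s[live]))
  m2 <- regexpr(rcRevRe, tails, perl = TRUE)
  reason[live[m2 < 0L]] <- "mutated_primer"

  live <- live[m2 > 0L]
  m2 <- m2[m2 > 0L]
  insert <- substr(s[live], insStart, insStart + m2 - 2L)
  qIns <- substr(q[live], insStart, insStart + m2 - 2L)
  meanQ <- vapply(qIns, function(z) {
    if (nzchar(z)) mean(utf8ToInt(z)) - 33 else 0
  }, numeric(1), USE.NAMES = FALSE)

  accepted <- DataFrame(
    id = unname(ids[live]), sample = unname(sampleOf[live]),
    insert = unname(insert), raw = unname(s[live]),
    primerInclusiveLength = unname(nchar(insert) + fLen + rLen),
    meanQuality = meanQ)
  rej <- which(!is.na(reason))
  rejected <- DataFrame(id = unname(ids[rej]), reason = unname(reason[rej]))
  newPreparedReads(accepted, rejected, samples, n)
}

#' Apply the four-criterion quality filter
#'
#' A clipped read is kept iff (i) its insert contains no N; (ii) its mean
#' Phred quality over the insert is strictly greater than `minQual`;
#' (iii) its primer-inclusive length (insert plus both PCR primers) is at
#' least `minLen`; and (iv) its raw pre-clipping sequence occurs at least
#' `minCopies` times in the entire raw dataset, across all samples. The
#' criteria are tested in this order and the first failing one is recorded
#' in the rejection log (`contains_N`, `low_quality`, `too_short`,
#' `singleton`). Criterion (iv) is global and order-independent: it counts
#' exact full-string duplicates over `rawCorpus`, which must be the
#' complete multi-sample set of raw read sequences, including reads already
#' rejected during clipping.
#'
#' @param prepared A [PreparedReads] from [clipReads()].
#' @param rawCorpus Character vector of all raw (pre-clipping) read
#'   sequences in the dataset. Defaults to the raw sequences of the reads
#'   that survived clipping, which undercounts copies whose duplicates were
#'   clipped away; pass the full corpus for the exact criterion.
#' @param minLen Minimum primer-inclusive length in bp (default 200).
#' @param minQual Mean-quality threshold; strictly greater-than (a read at
#'   exactly `minQual` is rejected). Default 24.
#' @param minCopies Minimum dataset-wide copy number of the raw read
#'   (default 2).
#' @return A [PreparedReads] with failing reads moved to the rejection log.
#' @export
qualityFilter <- function(prepared, rawCorpus = acceptedReads(prepared)$raw,
                          minLen = 200L, minQual = 24, minCopies = 2L) {
  stopifnot(is(prepared, "PreparedReads"))
  acc <- prepared@accepted
  if (nrow(acc) == 0L) return(prepared)
  reason <- rep(NA_character_, nrow(acc))

  hasN <- grepl("N", acc$insert, fixed = TRUE)
  reason[hasN] <- "contains_N"
  lowQ <- is.na(reason) & acc$meanQuality <= minQual
  reason[lowQ] <- "low_quality"
  short <- is.na(reason) & acc$primerInclusiveLength < minLen
  reason[short] <- "too_short"

  uq <- unique(rawCorpus)
  copies <- tabulate(match(rawCorpus, uq), nbins = length(uq))
  myCopies <- copies[match(acc$raw, uq)]
  myCopies[is.na(myCopies)] <- 0L
  single <- is.na(reason) & myCopies < minCopies
  reason[single] <- "singleton"

  keep <- is.na(reason)
  rejected <- rbind(prepared@rejected,
                    DataFrame(id = acc$id[!keep], reason = reason[!keep]))
  newPreparedReads(acc[keep, ], rejected, prepared@samples, prepared@nRaw)
}

#' Per-sample accepted-read counts
#'
#' Counts accepted reads per sample over the full sample universe of the
#' layout (samples with no accepted reads report 0). The minimum of this
#' vector is the natural depth for [subsampleEqualDepth()].
#'
#' @param prepared A [PreparedReads].
#' @return Named integer vector of accepted-read counts per sample.
#' @export
demultiplexSummary <- function(prepared) {
  stopifnot(is(prepared, "PreparedReads"))
  tab <- table(factor(prepared@accepted$sample, levels = prepared@samples))
  setNames(as.integer(tab), names(tab))
}

#' Write prepared reads and the rejection log
#'
#' Writes one FASTA of clipped inserts per sample, a TSV rejection log and
#' a JSON summary of per-sample and per-reason counts.
#'
#' @param prepared A [PreparedReads].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writePreparedReads <- function(prepared, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acc <- prepared@accepted
  paths <- character(0)
  for (smp in prepared@samples) {
    sel <- acc[acc$sample == smp, ]
    fa <- file.path(dir, paste0("inserts_", smp, ".fasta"))
    x <- DNAStringSet(setNames(sel$insert, sel$id))
    writeXStringSet(x, fa)
    paths <- c(paths, fa)
  }
  logPath <- file.path(dir, "rejections.tsv")
  write.table(as.data.frame(prepared@rejected), logPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  sumPath <- file.path(dir, "prep_summary.json")
  jsonlite::write_json(
    list(n_raw = prepared@nRaw,
         n_accepted = nrow(acc),
         per_sample = as.list(demultiplexSummary(prepared)),
         rejections = as.list(rejectionCounts(prepared))),
    sumPath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, logPath, sumPath))
}
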
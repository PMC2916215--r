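## OTU construction: exact-sequence dereplication within samples and
## indel-tolerant 100%-identity matching across samples.

#' @rdname OtuTable
#' @export
setClass("OtuTable", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character(0)
    if (!"counts" %in% assayNames(object))
      msg <- c(msg, "must carry a 'counts' assay")
    else {
      cnt <- assay(object, "counts")
      if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integers")
    }
    if (!"sequence" %in% colnames(rowData(object)))
      msg <- c(msg, "rowData must carry a 'sequence' column")
    else if (anyDuplicated(rowData(object)$sequence))
      msg <- c(msg, "representative sequences must be unique")
    if (length(msg)) msg else TRUE
  })

#' OTU x sample count table
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] carrying the OTU x
#' sample read-count matrix in the `counts` assay and the representative
#' sequence of every OTU in `rowData(x)$sequence`. An OTU here is an exact
#' sequence class: within a sample every distinct string is its own OTU,
#' and across samples two strings are merged only when they differ by
#' indels alone (see [matchAcrossSamples()]).
#'
#' @param counts Integer matrix, OTUs x samples; row and column names are
#'   kept as OTU ids and sample labels.
#' @param sequences Character vector or `DNAStringSet` of representative
#'   sequences, one per row of `counts`.
#' @param x,object An `OtuTable`.
#' @return `OtuTable()` returns an `OtuTable` object.
#' @aliases OtuTable-class
#' @export
OtuTable <- function(counts, sequences) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("OTU%05d", seq_len(nrow(counts)))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(sequence = as.character(sequences)))
  new("OtuTable", se)
}

#' @describeIn OtuTable The count matrix.
#' @export
otuCounts <- function(x) assay(x, "counts")

#' @describeIn OtuTable Representative sequences as a named `DNAStringSet`.
#' @export
representativeSequences <- function(x) {
  DNAStringSet(setNames(rowData(x)$sequence, rownames(x)))
}

#' @describeIn OtuTable Per-OTU total reads across all samples (the `n` of
#'   the occupancy-abundance statistics).
#' @export
otuTotals <- function(x) {
  setNames(as.integer(rowSums(otuCounts(x))), rownames(x))
}

#' @describeIn OtuTable Per-sample total reads.
#' @export
sampleTotals <- function(x) {
  setNames(as.integer(colSums(otuCounts(x))), colnames(x))
}

#' @describeIn OtuTable Per-OTU occupancy `N`: the number of samples with a
#'   positive count.
#' @export
occupancy <- function(x) {
  setNames(as.integer(rowSums(otuCounts(x) > 0L)), rownames(x))
}

setMethod("show", "OtuTable", function(object) {
  cat("OtuTable: ", nrow(object), " OTUs x ", ncol(object), " samples, ",
      sum(otuCounts(object)), " reads\n", sep = "")
  callNextMethod()
})

#' Dereplicate a sequence multiset
#'
#' Collapses exactly identical sequences and records their abundance.
#' Identity is exact string equality: sequences differing by any gap
#' (length difference) are distinct non-redundant sequences at this stage,
#' treating gaps as an informative character.
#'
#' @param seqs Character vector or `DNAStringSet` of clipped inserts.
#' @return Named integer vector: counts named by sequence, ordered by
#'   decreasing abundance (ties broken lexicographically).
#' @export
dereplicate <- function(seqs) {
  seqs <- as.character(seqs)
  if (!length(seqs)) return(setNames(integer(0), character(0)))
  uq <- sort(unique(seqs))
  cnt <- tabulate(match(seqs, uq), nbins = length(uq))
  ord <- order(-cnt, uq)
  setNames(cnt[ord], uq[ord])
}

#' @describeIn dereplicate Dereplicate the accepted reads of a
#'   [PreparedReads] sample by sample.
#' @param prepared A [PreparedReads] object.
#' @return `dereplicateBySample()` returns a named list (one element per
#'   sample) of named count vectors.
#' @export
dereplicateBySample <- function(prepared) {
  acc <- acceptedReads(prepared)
  lapply(setNames(nm = prepared@samples), function(smp)
    dereplicate(acc$insert[acc$sample == smp]))
}

#' Are two sequences identical up to indels?
#'
#' TRUE when an alignment with zero substitutions exists at the minimal
#' indel cost, i.e. the shorter sequence is a subsequence of the longer
#' (their longest common subsequence is the whole shorter sequence). This
#' operationalizes a 100% BLAST-identity cutoff in which gaps are not
#' considered: gaps may be sequencing artefacts or biological variants, so
#' length differences alone never separate two OTUs, while any base
#' substitution does.
#'
#' @param a,b Character vectors of sequences (recycled to equal length).
#' @return Logical vector.
#' @export
indelOnlyEquivalent <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  la <- nchar(a); lb <- nchar(b)
  sh <- ifelse(la <= lb, a, b)
  lo <- ifelse(la <= lb, b, a)
  .is_subsequence(sh, lo)
}

## Partition unique sequences into indel-only equivalence classes
## (transitive closure). Candidate pairs are pruned by length and base
## composition (a subsequence cannot contain more of any letter), then
## verified by the greedy scan.
indelClasses <- function(seqs) {
  n <- length(seqs)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n < 2L) return(parent)
  len <- nchar(seqs)
  af <- alphabetFrequency(DNAStringSet(seqs), baseOnly = TRUE)
  from <- to <- integer(0)
  for (i in seq_len(n)) {
    js <- which(len > len[i])
    if (!length(js)) next
    ok <- af[js, 1L] >= af[i, 1L] & af[js, 2L] >= af[i, 2L] &
      af[js, 3L] >= af[i, 3L] & af[js, 4L] >= af[i, 4L] &
      af[js, 5L] >= af[i, 5L]
    js <- js[ok]
    if (length(js)) {
      from <- c(from, rep.int(i, length(js)))
      to <- c(to, js)
    }
  }
  if (length(from)) {
    hit <- .is_subsequence(seqs[from], seqs[to])
    for (k in which(hit)) {
      ri <- findRoot(from[k]); rj <- findRoot(to[k])
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), findRoot, integer(1))
}

#' Match dereplicated sequences across samples into an OTU table
#'
#' Aligns the per-sample non-redundant sequence tables into one OTU x
#' sample count matrix. With `collapseIndels = TRUE` (the default), two
#' sequences from any samples belong to the same OTU iff they can be
#' aligned with differences that are exclusively indels (zero
#' substitutions; see [indelOnlyEquivalent()]); equivalence classes are
#' merged transitively so stacked indel variants stay in one OTU, and the
#' most abundant member (ties broken by lexicographically smallest
#' sequence) becomes the representative. With `collapseIndels = FALSE`
#' only exact string identity links samples. Merging conserves reads:
#' total counts are unchanged.
#'
#' @param dereps Named list of per-sample dereplicated count vectors, as
#'   from [dereplicateBySample()] (names of each vector are sequences).
#' @param collapseIndels Merge sequences differing only by indels?
#' @return An [OtuTable()] with OTUs ordered by decreasing total count.
#' @export
matchAcrossSamples <- function(dereps, collapseIndels = TRUE) {
  stopifnot(is.list(dereps), length(dereps) >= 1L)
  if (is.null(names(dereps)))
    names(dereps) <- sprintf("S%02d", seq_along(dereps))
  uq <- sort(unique(unlist(lapply(dereps, names), use.names = FALSE)))
  if (!length(uq))
    return(OtuTable(matrix(0L, 0L, length(dereps),
                           dimnames = list(NULL, names(dereps))),
                    character(0)))
  cnt <- matrix(0L, length(uq), length(dereps),
                dimnames = list(NULL, names(dereps)))
  for (j in seq_along(dereps)) {
    d <- dereps[[j]]
    cnt[match(names(d), uq), j] <- as.integer(d)
  }
  if (collapseIndels && length(uq) > 1L) {
    cls <- indelClasses(uq)
    groups <- split(seq_along(uq), cls)
    tot <- rowSums(cnt)
    merged <- matrix(0L, length(groups), ncol(cnt),
                     dimnames = list(NULL, colnames(cnt)))
    reps <- character(length(groups))
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      merged[g, ] <- as.integer(colSums(cnt[idx, , drop = FALSE]))
      best <- idx[order(-tot[idx], uq[idx])][1L]
      reps[g] <- uq[best]
    }
    cnt <- merged
    uq <- reps
  }
  ord <- order(-rowSums(cnt), uq)
  cnt <- cnt[ord, , drop = FALSE]
  uq <- uq[ord]
  rownames(cnt) <- sprintf("OTU%05d", seq_len(nrow(cnt)))
  OtuTable(cnt, uq)
}

#' Occupancy and per-sample richness of an OTU table
#'
#' @param x An [OtuTable()].
#' @return A list with `N`, the per-OTU occupancy (number of samples with a
#'   positive count), and `i`, the number of distinct OTUs per sample.
#' @export
presenceProfile <- function(x) {
  stopifnot(is(x, "OtuTable"))
  cnt <- otuCounts(x)
  list(N = setNames(as.integer(rowSums(cnt > 0L)), rownames(x)),
       i = setNames(as.integer(colSums(cnt > 0L)), colnames(x)))
}

#' Read and write OTU tables as TSV
#'
#' The format is one row per OTU: `otu_id`, `representative_sequence`, then
#' one count column per sample.
#'
#' @param x An [OtuTable()].
#' @param path File path.
#' @return `writeOtuTable()` invisibly returns `path`; `readOtuTable()`
#'   returns an [OtuTable()].
#' @export
writeOtuTable <- function(x, path) {
  df <- data.frame(otu_id = rownames(x),
                   representative_sequence = rowData(x)$sequence,
                   as.data.frame(otuCounts(x)), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOtuTable
#' @export
readOtuTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  cnt <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(cnt) <- "integer"
  rownames(cnt) <- df$otu_id
  OtuTable(cnt, df$representative_sequence)
}
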
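## Shared fixtures: hand-built reads, small layouts and independent oracles.

## A two-sample layout with easily recognisable tags.
twoSampleLayout <- function() {
  ReadLayout(tags = c(sampleA = "ACAC", sampleB = "GTGT"))
}

## Assemble a raw read around an insert for a given sample, with a flat
## quality. Pieces can be overridden to introduce defects.
rawRead <- function(layout, sample, insert, qual = 30L,
                    adapterA = layout@adapterA,
                    tag = layout@tags[[sample]],
                    fwd = layout@fwdPrimer,
                    revRc = as.character(
                      Biostrings::reverseComplement(
                        Biostrings::DNAString(gsub("S", "C",
                                                   layout@revPrimer)))),
                    adapterBRc = as.character(
                      Biostrings::reverseComplement(
                        Biostrings::DNAString(layout@adapterB)))) {
  seq <- paste0(adapterA, tag, fwd, insert, revRc, adapterBRc)
  list(sequence = seq,
       quality = strrep(rawToChar(as.raw(qual + 33L)), nchar(seq)))
}

## Bundle several rawRead() results into clipReads() input.
readBundle <- function(...) {
  reads <- list(...)
  s <- vapply(reads, `[[`, character(1), "sequence")
  names(s) <- sprintf("r%03d", seq_along(s))
  list(sequence = s, quality = vapply(reads, `[[`, character(1), "quality"))
}

## Random DNA string(s).
randomSeq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

## Independent oracle for indel-only equivalence: a full dynamic program
## over the longest common subsequence; two sequences are equivalent iff
## the LCS covers the whole shorter sequence (alignment with zero
## substitutions at minimal indel cost).
lcsLength <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  prev <- integer(length(y) + 1L)
  for (i in seq_along(x)) {
    cur <- integer(length(y) + 1L)
    for (j in seq_along(y)) {
      cur[j + 1L] <- if (x[i] == y[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[length(y) + 1L]
}

oracleIndelEquivalent <- function(a, b) {
  lcsLength(a, b) == min(nchar(a), nchar(b))
}

## Transitive closure of the oracle relation over a set of sequences,
## by iterated merging of overlapping classes.
oracleIndelClasses <- function(seqs) {
  n <- length(seqs)
  cls <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (cls[i] != cls[j] && oracleIndelEquivalent(seqs[i], seqs[j])) {
        cls[cls == cls[j]] <- cls[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(cls, unique(cls))
}

## Build an OtuTable straight from a count matrix (unique dummy sequences).
tableFromCounts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  OtuTable(counts, randomSeqUnique(nrow(counts), 60L))
}

randomSeqUnique <- function(n, len) {
  out <- randomSeq(n, len)
  while (anyDuplicated(out)) out[duplicated(out)] <-
    randomSeq(sum(duplicated(out)), len)
  out
}

## Exhaustive Hamming scan used as the morphotype affiliation oracle:
## minimal substitution distance over all full-length overlaps of the
## shorter sequence, indels forbidden.
oracleMinSubDistance <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  xs <- strsplit(a, "", fixed = TRUE)[[1L]]
  best <- Inf
  for (off in 0:(nchar(b) - nchar(a))) {
    ys <- strsplit(substr(b, off + 1L, off + nchar(a)), "",
                   fixed = TRUE)[[1L]]
    best <- min(best, sum(xs != ys))
  }
  best
}
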
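## Ground-truth simulator: seasonal community structure plus 454-style reads.

#' @rdname CommunityDesign
#' @export
setClass("CommunityDesign",
  representation(nSamples = "integer", nPersistent = "integer",
                 nSeasonal = "integer", persistentAbundance = "numeric",
                 persistentSdlog = "numeric", seasonalAbundance = "numeric",
                 seasonalOccupancyDist = "numeric", readsPerSample = "integer",
                 insertLengthRange = "integer", contiguous = "logical",
                 seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
    if (object@nPersistent < 0L || object@nSeasonal < 0L)
      msg <- c(msg, "guild sizes must be >= 0")
    if (object@readsPerSample < 1L)
      msg <- c(msg, "readsPerSample must be >= 1")
    d <- object@seasonalOccupancyDist
    if (length(d) != object@nSamples || any(d < 0) ||
        abs(sum(d) - 1) > 1e-8)
      msg <- c(msg, "seasonalOccupancyDist must be a probability vector over 1..nSamples")
    if (length(object@insertLengthRange) != 2L ||
        any(object@insertLengthRange < 1L) ||
        diff(object@insertLengthRange) < 0L)
      msg <- c(msg, "insertLengthRange must be an increasing pair of positive lengths")
    if (object@seasonalAbundance < 2)
      msg <- c(msg, "seasonalAbundance must be >= 2 reads per occupied sample")
    if (object@persistentAbundance <= 0 || object@persistentAbundance > 1)
      msg <- c(msg, "persistentAbundance must be a fraction in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Design of a synthetic seasonal community
#'
#' Parameters of the two-guild community the simulator emulates: a
#' persistent guild of abundant OTUs present in every temporal sample with
#' log-normal abundance noise, and a seasonal guild of rare OTUs each
#' restricted to a few samples. Defaults mirror the structure reported for
#' the lake survey: 10 roughly 3-week samples, about a quarter of all OTUs
#' confined to a single sample, month-specific sequences collectively rare
#' (a percent or two of a sample's reads), and the abundant guild carrying
#' the bulk of the reads.
#'
#' @param nSamples Number of temporal samples (default 10).
#' @param nPersistent,nSeasonal Number of OTUs in each guild.
#' @param persistentAbundance Mean relative abundance of one persistent OTU
#'   (fraction of a sample's reads); with the per-sample depth fixed, only
#'   its ratio to the seasonal read mass matters.
#' @param persistentSdlog Log-normal sd of persistent abundance noise.
#' @param seasonalAbundance Mean reads of a seasonal OTU in each sample it
#'   occupies; a floor of 2 reads is applied so rare OTUs remain observable
#'   after the duplicate-read filter (see [qualityFilter()]).
#' @param seasonalOccupancyDist Probability vector over occupancy classes
#'   1..`nSamples` from which each seasonal OTU draws the number of samples
#'   it occupies. The default (for 10 samples) puts 36% of seasonal OTUs in
#'   a single sample and decays with occupancy.
#' @param readsPerSample Sequencing depth per sample; column sums of the
#'   ground-truth count matrix equal this exactly.
#' @param insertLengthRange Inclusive range of template insert lengths (bp,
#'   primers excluded) drawn uniformly per OTU.
#' @param contiguous Should a seasonal OTU occupy a contiguous block of
#'   samples (a season) rather than a random subset?
#' @param seed RNG seed governing the community draw.
#' @return A `CommunityDesign` object.
#' @aliases CommunityDesign-class
#' @export
CommunityDesign <- function(nSamples = 10L, nPersistent = 300L,
                            nSeasonal = 700L, persistentAbundance = 0.003,
                            persistentSdlog = 0.5, seasonalAbundance = 6,
                            seasonalOccupancyDist = NULL,
                            readsPerSample = 15000L,
                            insertLengthRange = c(150L, 190L),
                            contiguous = FALSE, seed = 1L) {
  if (is.null(seasonalOccupancyDist)) {
    seasonalOccupancyDist <- if (nSamples == 10L)
      c(0.36, 0.18, 0.12, 0.08, 0.06, 0.05, 0.04, 0.04, 0.04, 0.03)
    else {
      w <- seq_len(nSamples)^(-1.3)
      w / sum(w)
    }
  }
  new("CommunityDesign", nSamples = as.integer(nSamples),
      nPersistent = as.integer(nPersistent), nSeasonal = as.integer(nSeasonal),
      persistentAbundance = persistentAbundance,
      persistentSdlog = persistentSdlog,
      seasonalAbundance = seasonalAbundance,
      seasonalOccupancyDist = seasonalOccupancyDist,
      readsPerSample = as.integer(readsPerSample),
      insertLengthRange = as.integer(insertLengthRange),
      contiguous = isTRUE(contiguous), seed = as.integer(seed))
}

setMethod("show", "CommunityDesign", function(object) {
  cat("CommunityDesign: ", object@nSamples, " samples, ",
      object@nPersistent, " persistent + ", object@nSeasonal,
      " seasonal OTUs, ", object@readsPerSample, " reads/sample (seed ",
      object@seed, ")\n", sep = "")
})

#' @rdname ErrorModel
#' @export
setClass("ErrorModel",
  representation(substitutionRate = "numeric",
                 homopolymerIndelRate = "numeric", nRate = "numeric",
                 qualityMean = "numeric", qualitySd = "numeric"),
  validity = function(object) {
    rates <- c(object@substitutionRate, object@homopolymerIndelRate,
               object@nRate)
    if (any(rates < 0 | rates > 1))
      return("all error rates must lie in [0, 1]")
    if (object@qualitySd < 0) return("qualitySd must be >= 0")
    TRUE
  })

#' 454-style sequencing error model
#'
#' Per-base substitutions, ambiguous base calls (N), and the hallmark 454
#' artefact: homopolymer length errors, modelled as a +/-1 change (equal
#' probability) applied per maximal single-nucleotide run of length >= 2.
#' Phred qualities are drawn per read (mean `qualityMean`, sd `qualitySd`)
#' with small per-base jitter, so a fraction of reads falls below the
#' mean-quality filter threshold as in a real run. Default rates are chosen
#' for an FLX-era run: indels dominate, substitutions are an order of
#' magnitude rarer.
#'
#' @param substitutionRate Per-base substitution probability.
#' @param homopolymerIndelRate Per-run probability of a +/-1 length error in
#'   homopolymer runs of length >= 2.
#' @param nRate Per-base probability of an N call.
#' @param qualityMean,qualitySd Distribution of per-read mean Phred scores.
#' @return An `ErrorModel` object.
#' @aliases ErrorModel-class
#' @export
ErrorModel <- function(substitutionRate = 3e-4,
                       homopolymerIndelRate = 2e-3, nRate = 1e-4,
                       qualityMean = 28, qualitySd = 4) {
  new("ErrorModel", substitutionRate = substitutionRate,
      homopolymerIndelRate = homopolymerIndelRate, nRate = nRate,
      qualityMean = qualityMean, qualitySd = qualitySd)
}

#' An error-free model (all rates zero, uniformly high quality)
#' @rdname ErrorModel
#' @export
perfectErrorModel <- function(qualityMean = 35) {
  ErrorModel(substitutionRate = 0, homopolymerIndelRate = 0, nRate = 0,
             qualityMean = qualityMean, qualitySd = 0)
}

#' @rdname GroundTruth
#' @export
setClass("GroundTruth",
  representation(templates = "DNAStringSet", counts = "matrix",
                 guild = "character", lineage = "character"),
  validity = function(object) {
    msg <- character(0)
    n <- length(object@templates)
    if (nrow(object@counts) != n)
      msg <- c(msg, "counts must have one row per template")
    if (anyDuplicated(as.character(object@templates)))
      msg <- c(msg, "template sequences must be unique")
    if (any(object@counts < 0))
      msg <- c(msg, "counts must be non-negative")
    if (length(object@guild) != n ||
        !all(object@guild %in% c("persistent", "seasonal")))
      msg <- c(msg, "guild must be persistent/seasonal, one per template")
    if (length(object@lineage) != n)
      msg <- c(msg, "lineage must have one entry per template (NA allowed)")
    if (length(msg)) msg else TRUE
  })

#' Ground truth of a simulated run
#'
#' Template sequences (inserts, primers excluded), the true OTU x sample
#' read-count matrix, and per-OTU guild and optional lineage labels.
#' Constructed by [simulateCommunity()]; all accessors are read-only.
#'
#' @param templates Named `DNAStringSet` of unique template inserts.
#' @param counts Integer matrix (template x sample) of true read counts.
#' @param guild `"persistent"` or `"seasonal"` per template.
#' @param lineage Optional lineage label per template (`NA` when none).
#' @return A `GroundTruth` object.
#' @aliases GroundTruth-class
#' @export
GroundTruth <- function(templates, counts, guild,
                        lineage = rep(NA_character_, length(templates))) {
  new("GroundTruth", templates = templates, counts = counts, guild = guild,
      lineage = lineage)
}

#' @describeIn GroundTruth True count matrix (OTU x sample).
#' @param x,object A `GroundTruth`.
#' @export
truthCounts <- function(x) x@counts

#' @describeIn GroundTruth Template insert sequences.
#' @export
truthTemplates <- function(x) x@templates

#' @describeIn GroundTruth Guild label per OTU.
#' @export
truthGuild <- function(x) setNames(x@guild, names(x@templates))

#' @describeIn GroundTruth Lineage label per OTU (NA when unassigned).
#' @export
truthLineage <- function(x) setNames(x@lineage, names(x@templates))

#' @describeIn GroundTruth Realized occupancy (samples with count > 0).
#' @export
truthOccupancy <- function(x) {
  setNames(as.integer(rowSums(x@counts > 0L)), names(x@templates))
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: ", length(object@templates), " OTUs (",
      sum(object@guild == "persistent"), " persistent, ",
      sum(object@guild == "seasonal"), " seasonal) x ",
      ncol(object@counts), " samples; ", sum(object@counts),
      " reads\n", sep = "")
})

IUPAC_EXPANSION <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

## Realize a constant region carrying IUPAC ambiguity codes into n concrete
## sequences: each ambiguous position is drawn uniformly from its expansion
## per read, emulating a degenerate primer mix.
instantiateIupac <- function(x, n) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  amb <- which(!chars %in% c("A", "C", "G", "T"))
  if (!length(amb)) return(rep.int(x, n))
  segs <- vector("list", 2L * length(amb) + 1L)
  prev <- 1L
  for (k in seq_along(amb)) {
    segs[[2L * k - 1L]] <- substr(x, prev, amb[k] - 1L)
    set <- IUPAC_EXPANSION[[chars[amb[k]]]]
    if (is.null(set)) stop("non-IUPAC character in layout: ", chars[amb[k]])
    segs[[2L * k]] <- sample(set, n, replace = TRUE)
    prev <- amb[k] + 1L
  }
  segs[[length(segs)]] <- substr(x, prev, nchar(x))
  do.call(paste0, segs)
}

## Random DNA templates of the given lengths, regenerated until unique.
randomTemplates <- function(lens) {
  draw <- function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }
  out <- vapply(lens, draw, character(1))
  while (anyDuplicated(out)) {
    i <- which(duplicated(out))
    out[i] <- vapply(lens[i], draw, character(1))
  }
  out
}

#' Simulate a two-guild seasonal community
#'
#' Draws template sequences and a true OTU x sample count matrix under a
#' [CommunityDesign()]. Each seasonal OTU occupies `k` samples with `k`
#' drawn from the design's occupancy distribution and receives a floor of 2
#' reads plus Poisson noise in each occupied sample; persistent OTUs are
#' present in every sample, and the remaining reads of each sample are
#' spread over them by a multinomial draw with log-normal weights, so every
#' column sums exactly to `readsPerSample`.
#'
#' @param design A [CommunityDesign()]; its `seed` slot governs the draw.
#' @return A [GroundTruth()] object.
#' @export
simulateCommunity <- function(design) {
  stopifnot(is(design, "CommunityDesign"))
  validObject(design)
  set.seed(design@seed)
  ns <- design@nSamples
  np <- design@nPersistent
  nz <- design@nSeasonal
  n <- np + nz
  if (n < 1L) stop("design has no OTUs")
  if (np == 0L)
    stop("infeasible design: at least one persistent OTU is required to ",
         "meet the per-sample depth exactly")
  lens <- sample(seq(design@insertLengthRange[1L],
                     design@insertLengthRange[2L]), n, replace = TRUE)
  templates <- randomTemplates(lens)
  ids <- sprintf("OTU%04d", seq_len(n))
  samples <- sprintf("S%02d", seq_len(ns))
  counts <- matrix(0L, n, ns, dimnames = list(ids, samples))
  guild <- rep(c("persistent", "seasonal"), c(np, nz))

  if (nz > 0L) {
    k <- sample.int(ns, nz, replace = TRUE,
                    prob = design@seasonalOccupancyDist)
    lam <- max(design@seasonalAbundance - 2, 0)
    for (i in seq_len(nz)) {
      cols <- if (design@contiguous) {
        st <- sample.int(ns - k[i] + 1L, 1L)
        st:(st + k[i] - 1L)
      } else sample.int(ns, k[i])
      counts[np + i, cols] <- 2L + rpois(k[i], lam)
    }
  }

  w <- matrix(exp(rnorm(np * ns, log(design@persistentAbundance),
                        design@persistentSdlog)), np, ns)
  for (j in seq_len(ns)) {
    rem <- design@readsPerSample - sum(counts[, j]) - 2L * np
    if (rem < 0L)
      stop("infeasible design: sample ", samples[j], " needs ",
           sum(counts[, j]) + 2L * np,
           " reads but readsPerSample is ", design@readsPerSample)
    counts[seq_len(np), j] <- 2L + as.integer(rmultinom(1L, rem, w[, j]))
  }

  GroundTruth(templates = DNAStringSet(setNames(templates, ids)),
              counts = counts, guild = guild)
}

## Apply the 454 error model to a character vector of reads. Substitutions
## and N calls act per base; homopolymer indels act per maximal run of
## length >= 2 (+/-1 with equal probability). Returns the corrupted
## sequences together with Phred+33 quality strings of matching length.
corruptSequences <- function(seqs, error) {
  nr <- length(seqs)
  if (nr == 0L)
    return(list(sequence = character(0), quality = character(0)))
  if (error@substitutionRate > 0 || error@nRate > 0 ||
      error@homopolymerIndelRate > 0) {
    seqs <- .corrupt_reads(seqs, error@substitutionRate, error@nRate,
                           error@homopolymerIndelRate)
  }
  lens2 <- nchar(seqs)
  readMean <- rnorm(nr, error@qualityMean, error@qualitySd)
  quality <- .phred_strings(lens2, readMean, 3)
  list(sequence = seqs, quality = quality)
}

#' Simulate tagged 454 reads from a ground-truth community
#'
#' Emits, for every sample, exactly the ground-truth read counts. Each read
#' is adapter A + sample tag + forward primer + template insert +
#' reverse-complemented reverse primer + reverse-complemented adapter B,
#' then corrupted under the [ErrorModel()]. Reads within a sample are
#' shuffled (one documented draw per sample); qualities are Phred+33.
#'
#' @param truth A [GroundTruth()] object.
#' @param error An [ErrorModel()].
#' @param layout A [ReadLayout()]; every sample of `truth` must have a tag.
#' @param seed Seed for the corruption and shuffling stream.
#' @return A [Biostrings::QualityScaledDNAStringSet] with read names
#'   `<sample>_r<index>`; `mcols()` carries the true sample and OTU of each
#'   read.
#' @export
simulateReads <- function(truth, error, layout, seed = 1L) {
  stopifnot(is(truth, "GroundTruth"), is(error, "ErrorModel"),
            is(layout, "ReadLayout"))
  samples <- colnames(truth@counts)
  missing <- setdiff(samples, sampleLabels(layout))
  if (length(missing))
    stop("no tag for sample(s): ", paste(missing, collapse = ", "))
  set.seed(as.integer(seed))
  tmpl <- as.character(truth@templates)
  otuIds <- names(truth@templates)
  ## degenerate primer positions are realized once per OTU: the amplicon
  ## pool of one taxon is dominated by a single realization, so exact
  ## duplicate reads remain duplicates at the raw-sequence level
  fwdByOtu <- instantiateIupac(layout@fwdPrimer, length(tmpl))
  sufByOtu <- instantiateIupac(layoutSuffix(layout), length(tmpl))
  seqL <- qualL <- idL <- otuL <- smpL <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    reps <- rep(seq_along(tmpl), truth@counts[, j])
    if (length(reps) > 1L) reps <- sample(reps)
    full <- paste0(layout@adapterA, layout@tags[[samples[j]]],
                   fwdByOtu[reps], tmpl[reps], sufByOtu[reps])
    corr <- corruptSequences(full, error)
    seqL[[j]] <- corr$sequence
    qualL[[j]] <- corr$quality
    idL[[j]] <- sprintf("%s_r%06d", samples[j], seq_along(reps))
    otuL[[j]] <- otuIds[reps]
    smpL[[j]] <- rep(samples[j], length(reps))
  }
  seqs <- DNAStringSet(unlist(seqL, use.names = FALSE))
  names(seqs) <- unlist(idL, use.names = FALSE)
  quals <- PhredQuality(unlist(qualL, use.names = FALSE))
  reads <- QualityScaledDNAStringSet(seqs, quals)
  mcols(reads) <- DataFrame(sample = unlist(smpL, use.names = FALSE),
                            otu = unlist(otuL, use.names = FALSE))
  reads
}

#' Write a simulated run to disk
#'
#' @param reads Result of [simulateReads()].
#' @param path Output file. With `format = "fastq"` a single FASTQ
#'   (Phred+33); with `format = "fasta-qual"` a FASTA plus a `.qual` file of
#'   space-separated Phred scores next to it.
#' @param format Output format.
#' @return Invisibly, the path(s) written.
#' @export
writeReads <- function(reads, path, format = c("fastq", "fasta-qual")) {
  format <- match.arg(format)
  if (format == "fastq") {
    writeQualityScaledXStringSet(reads, path)
    return(invisible(path))
  }
  fa <- path
  qf <- sub("\\.fa(sta)?$", "", path)
  qf <- paste0(qf, ".qual")
  writeXStringSet(as(reads, "DNAStringSet"), fa)
  qs <- as.character(quality(reads))
  lines <- character(2L * length(reads))
  lines[c(TRUE, FALSE)] <- paste0(">", names(reads))
  lines[c(FALSE, TRUE)] <- vapply(qs, function(z)
    paste(utf8ToInt(z) - 33L, collapse = " "), character(1),
    USE.NAMES = FALSE)
  writeLines(lines, qf)
  invisible(c(fa, qf))
}

#' Read a run back from disk
#'
#' Accepts FASTQ (Phred+33) or a FASTA file with a sibling `.qual` file.
#'
#' @param path FASTQ or FASTA path.
#' @param qualPath Optional explicit `.qual` path for FASTA input.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
readReads <- function(path, qualPath = NULL) {
  isFastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  if (is.null(qualPath) && isFastq) {
    ## Biostrings warns that FASTQ carries no metadata columns; harmless
    return(withCallingHandlers(
      readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }))
  }
  if (is.null(qualPath)) {
    qualPath <- paste0(sub("\\.fa(sta)?$", "", path), ".qual")
  }
  seqs <- readDNAStringSet(path)
  ql <- readLines(qualPath)
  hdr <- grepl("^>", ql)
  ids <- sub("^>", "", ql[hdr])
  vals <- split(ql[!hdr], cumsum(hdr)[!hdr])
  qints <- lapply(vals, function(z)
    as.integer(strsplit(paste(z, collapse = " "), "\\s+")[[1L]]))
  qstr <- vapply(qints, function(z) rawToChar(as.raw(z + 33L)), character(1))
  ## align qualities with sequences by record id
  qstr <- qstr[match(sub("\\s.*$", "", names(seqs)), sub("\\s.*$", "", ids))]
  QualityScaledDNAStringSet(seqs, PhredQuality(unname(qstr)))
}

#' Write ground truth as plain text
#'
#' Produces a TSV of per-sample true counts (`otu_id`, `guild`, `lineage`,
#' `sample`, `count`) and a FASTA of template inserts.
#'
#' @param truth A [GroundTruth()].
#' @param countsPath,fastaPath Output paths.
#' @return Invisibly, the paths written.
#' @export
writeGroundTruth <- function(truth, countsPath, fastaPath) {
  cnt <- truth@counts
  long <- data.frame(
    otu_id = rep(rownames(cnt), ncol(cnt)),
    guild = rep(truth@guild, ncol(cnt)),
    lineage = rep(ifelse(is.na(truth@lineage), "", truth@lineage), ncol(cnt)),
    sample = rep(colnames(cnt), each = nrow(cnt)),
    count = as.integer(cnt))
  long <- long[long$count > 0L, ]
  write.table(long, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  writeXStringSet(truth@templates, fastaPath)
  invisible(c(countsPath, fastaPath))
}
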
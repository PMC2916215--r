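## Read layout: adapters, sample tags and PCR primers of a tagged 454 run.

IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

## Turn an IUPAC-coded primer into a plain regular expression in which each
## ambiguity code matches its expansion (e.g. S matches C or G).
iupacRegex <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(IUPAC_REGEX))
  if (length(bad))
    stop("non-IUPAC characters in sequence: ", paste(bad, collapse = ", "))
  paste0(IUPAC_REGEX[chars], collapse = "")
}

#' Homopolymer-tolerant pattern for a 454 adapter
#'
#' Builds a regular expression that matches a sequence up to homopolymer
#' length errors, the dominant 454 artefact: every maximal single-nucleotide
#' run of length L in `x` is allowed to appear with any length between 1 and
#' 2L. Base identities must be preserved, so substitutions still break the
#' match. Used to locate the adapter B sequence at the 3' end of a read.
#'
#' @param x A DNA string (plain A/C/G/T).
#' @param anchorStart Prepend `^` so the pattern must match at the start of
#'   the target.
#' @return A single regular-expression string.
#' @examples
#' grepl(homopolymerPattern("GCCTT"), "GCCCTT")   # lengthened C run
#' @export
homopolymerPattern <- function(x, anchorStart = TRUE) {
  r <- rle(strsplit(toupper(x), "", fixed = TRUE)[[1L]])
  parts <- sprintf("%s{1,%d}", r$values, pmax(2L * r$lengths, 2L))
  paste0(if (anchorStart) "^" else "", paste0(parts, collapse = ""))
}

#' Default sample tags
#'
#' A deterministic set of 4-mer tags with pairwise Hamming distance of at
#' least 2, chosen greedily from the lexicographic enumeration of all
#' 4-mers. The study design places one such tag per temporal sample between
#' sequencing adapter A and the forward PCR primer.
#'
#' @param samples Character vector of sample labels (or a single integer
#'   count, in which case labels `S01`, `S02`, ... are generated).
#' @return Named character vector of tags; names are sample labels.
#' @export
defaultTags <- function(samples = 10L) {
  if (is.numeric(samples) && length(samples) == 1L)
    samples <- sprintf("S%02d", seq_len(samples))
  n <- length(samples)
  bases <- c("A", "C", "G", "T")
  all4 <- do.call(paste0, expand.grid(bases, bases, bases, bases,
                                      stringsAsFactors = FALSE)[, 4:1])
  all4 <- sort(all4)
  allm <- do.call(rbind, strsplit(all4, "", fixed = TRUE))
  keep <- integer(0)
  for (i in seq_along(all4)) {
    if (!length(keep)) { keep <- i; next }
    d <- rowSums(allm[keep, , drop = FALSE] !=
                   matrix(allm[i, ], length(keep), 4L, byrow = TRUE))
    if (all(d >= 2L)) keep <- c(keep, i)
    if (length(keep) >= n) break
  }
  if (length(keep) < n)
    stop("cannot build ", n, " tags with pairwise Hamming distance >= 2")
  setNames(all4[keep[seq_len(n)]], samples)
}

#' @rdname ReadLayout
#' @export
setClass("ReadLayout",
  representation(adapterA = "character", adapterB = "character",
                 fwdPrimer = "character", revPrimer = "character",
                 tags = "character"),
  validity = function(object) {
    msg <- character(0)
    one <- function(s) length(s) == 1L && !is.na(s) && nzchar(s)
    if (!one(object@adapterA) || !one(object@adapterB))
      msg <- c(msg, "adapters must be single non-empty strings")
    if (!one(object@fwdPrimer) || !one(object@revPrimer))
      msg <- c(msg, "primers must be single non-empty strings")
    if (!length(object@tags) || is.null(names(object@tags)))
      msg <- c(msg, "tags must be a named character vector (names = samples)")
    else {
      if (anyDuplicated(object@tags))
        msg <- c(msg, "tags must be unique")
      if (anyDuplicated(names(object@tags)))
        msg <- c(msg, "sample labels must be unique")
      if (length(unique(nchar(object@tags))) > 1L)
        msg <- c(msg, "tags must all have the same width")
    }
    ok <- vapply(c(object@adapterA, object@adapterB, object@fwdPrimer,
                   object@revPrimer, object@tags),
                 function(s) !inherits(try(iupacRegex(s), silent = TRUE),
                                       "try-error"), logical(1))
    if (!all(ok)) msg <- c(msg, "sequences must be IUPAC DNA")
    if (length(msg)) msg else TRUE
  })

#' Read layout of a tagged 454 amplicon run
#'
#' Describes how every raw read is laid out: sequencing adapter A, a sample
#' tag, the forward SSU primer, the amplified insert, then the reverse
#' complements of the reverse primer and of adapter B. Defaults are the
#' adapters and broad-eukaryote V3 primers of the seasonal lake survey the
#' package emulates; the reverse primer carries one IUPAC ambiguity (S).
#'
#' @param adapterA,adapterB 454 sequencing adapters (5' orientation).
#' @param fwdPrimer,revPrimer PCR primers (5'->3', IUPAC codes allowed).
#' @param tags Named character vector mapping sample labels to tag
#'   sequences; see [defaultTags()].
#' @return A `ReadLayout` object.
#' @aliases ReadLayout-class
#' @export
ReadLayout <- function(adapterA = "GCCTCCCTCGCGCCATCAG",
                       adapterB = "GCCTTGCCAGCCCGCTCAG",
                       fwdPrimer = "ATTAGGGTTCGATTCCGGAGAGG",
                       revPrimer = "CTGGAATTACCGCGGSTGCTG",
                       tags = defaultTags(10L)) {
  new("ReadLayout", adapterA = toupper(adapterA), adapterB = toupper(adapterB),
      fwdPrimer = toupper(fwdPrimer), revPrimer = toupper(revPrimer),
      tags = toupper(structure(as.character(tags), names = names(tags))))
}

#' @describeIn ReadLayout Sample labels carried by the tag map.
#' @param x,object A `ReadLayout`.
#' @export
sampleLabels <- function(x) names(x@tags)

## Combined width of both PCR primers; the length filter criterion counts
## the insert plus this.
primerSpan <- function(layout) nchar(layout@fwdPrimer) + nchar(layout@revPrimer)

setMethod("show", "ReadLayout", function(object) {
  cat("ReadLayout\n",
      "  adapter A : ", object@adapterA, "\n",
      "  adapter B : ", object@adapterB, "\n",
      "  fwd primer: ", object@fwdPrimer, "\n",
      "  rev primer: ", object@revPrimer, "\n",
      "  samples   : ", length(object@tags), " (tag width ",
      nchar(object@tags[[1L]]), ")\n", sep = "")
})

## 5' constant region preceding the insert for one sample, and the 3'
## constant region shared by all samples.
layoutPrefix <- function(layout, sample) {
  paste0(layout@adapterA, layout@tags[[sample]], layout@fwdPrimer)
}
layoutSuffix <- function(layout) {
  rcRev <- as.character(reverseComplement(DNAString(layout@revPrimer)))
  rcB <- as.character(reverseComplement(DNAString(layout@adapterB)))
  paste0(rcRev, rcB)
}

#' Read a layout from a YAML file
#'
#' The file must provide `adapterA`, `adapterB`, `fwdPrimer`, `revPrimer`
#' and a `tags` mapping of sample label to tag sequence.
#'
#' @param path Path to a YAML file.
#' @return A [ReadLayout()] object.
#' @export
readLayoutYaml <- function(path) {
  y <- yaml::read_yaml(path)
  ReadLayout(adapterA = y$adapterA, adapterB = y$adapterB,
             fwdPrimer = y$fwdPrimer, revPrimer = y$revPrimer,
             tags = unlist(y$tags))
}
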
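## Morphotype affiliation: match OTU sequences to annotated reference
## lineages (e.g. the Spumella chrysophyte subclusters C1/C2/C3) and
## compute per-sample lineage relative abundances.

#' Read a lineage-annotated reference set
#'
#' References are FASTA records whose description lines carry a
#' `lineage=<label>` token (e.g. `>AB123 lineage=C2`). Sequences must be
#' unique and every record needs a non-empty lineage.
#'
#' @param path FASTA file.
#' @return A `DNAStringSet` named by accession with `mcols()$lineage`.
#' @export
readReferenceSet <- function(path) {
  refs <- readDNAStringSet(path)
  lin <- sub(".*lineage=([^[:space:]]+).*", "\\1", names(refs))
  bad <- !grepl("lineage=", names(refs))
  if (any(bad))
    stop("reference(s) without lineage= label: ",
         paste(head(sub("\\s.*$", "", names(refs)[bad])), collapse = ", "))
  names(refs) <- sub("\\s.*$", "", names(refs))
  mcols(refs)$lineage <- lin
  validateReferenceSet(refs)
  refs
}

#' @rdname readReferenceSet
#' @param refs A `DNAStringSet` with `mcols()$lineage`.
#' @export
validateReferenceSet <- function(refs) {
  lin <- mcols(refs)$lineage
  if (is.null(lin) || any(is.na(lin)) || any(!nzchar(lin)))
    stop("every reference needs a non-empty lineage label")
  if (anyDuplicated(as.character(refs)))
    stop("reference sequences must be unique")
  invisible(refs)
}

## Minimal substitution-only distance between two sequences: the smallest
## Hamming distance over all full-length overlaps of the shorter sequence
## with the longer (no indels). Returns Inf when it exceeds maxSubs.
minSubDistance <- function(query, ref, maxSubs = 1L) {
  a <- as.character(query); b <- as.character(ref)
  if (nchar(a) <= nchar(b)) { s <- a; l <- b } else { s <- b; l <- a }
  for (d in 0:maxSubs) {
    if (countPattern(s, DNAString(l), max.mismatch = d,
                     with.indels = FALSE) > 0L)
      return(as.integer(d))
  }
  Inf
}

#' Affiliate sequences with reference lineages
#'
#' A query is affiliated when some reference matches it with at most
#' `maxSubs` base substitutions and zero indels over a full-length overlap
#' of the shorter sequence; the nearest reference's lineage is returned.
#' With the default `maxSubs = 1`, a query must be identical to a
#' reference or differ by a single base substitution (about 99.4% identity
#' on a ~170 bp fragment) -- a single indel disqualifies the pair. When
#' references from different lineages tie at the minimal distance the
#' query is flagged ambiguous and left unassigned.
#'
#' @param queries Character vector or `DNAStringSet` (typically OTU
#'   representatives, named by OTU id).
#' @param refs Reference set from [readReferenceSet()].
#' @param maxSubs Maximum substitutions allowed (default 1).
#' @return A `DataFrame` with one row per query: `query`, `lineage` (`NA`
#'   when unaffiliated or ambiguous), `distance` (`Inf` when no reference
#'   is within `maxSubs`), `ambiguous`.
#' @export
affiliate <- function(queries, refs, maxSubs = 1L) {
  validateReferenceSet(refs)
  qs <- if (is.character(queries)) queries else
    structure(as.character(queries), names = names(queries))
  if (is.null(names(qs))) names(qs) <- sprintf("query%04d", seq_along(qs))
  lin <- mcols(refs)$lineage
  refChars <- as.character(refs)
  res <- lapply(qs, function(q) {
    d <- vapply(refChars, minSubDistance, numeric(1), query = q,
                maxSubs = maxSubs, USE.NAMES = FALSE)
    dmin <- min(d)
    if (!is.finite(dmin))
      return(list(lineage = NA_character_, distance = Inf,
                  ambiguous = FALSE))
    winners <- unique(lin[d == dmin])
    if (length(winners) > 1L)
      return(list(lineage = NA_character_, distance = dmin,
                  ambiguous = TRUE))
    list(lineage = winners, distance = dmin, ambiguous = FALSE)
  })
  DataFrame(query = names(qs),
            lineage = unname(vapply(res, `[[`, character(1), "lineage")),
            distance = unname(vapply(res, `[[`, numeric(1), "distance")),
            ambiguous = unname(vapply(res, `[[`, logical(1), "ambiguous")),
            row.names = NULL)
}

#' Per-sample lineage relative abundances
#'
#' Aggregates the OTU table over affiliated lineages and returns, per
#' sample, the relative abundance of every affiliated OTU within its
#' lineage; OTUs below `groupBelow` (a fraction of the sample's reads,
#' default 0.01%) are pooled into an `"other"` member of their lineage.
#' With `basis = "affiliated"` fractions are relative to the sample's
#' affiliated reads (and sum to 1 whenever any read is affiliated); with
#' `basis = "total"` they are relative to all reads of the sample.
#' Ambiguous and unaffiliated OTUs are excluded.
#'
#' @param x An [OtuTable()].
#' @param affiliations Result of [affiliate()] on the representative
#'   sequences of `x` (query = OTU id).
#' @param basis Denominator: the sample's affiliated reads or all reads.
#' @param groupBelow Pooling threshold as a fraction of the sample total.
#' @return A `data.frame` with columns `sample`, `lineage`, `member`
#'   (OTU id or `"other"`) and `fraction`.
#' @export
lineageRelativeAbundance <- function(x, affiliations,
                                     basis = c("affiliated", "total"),
                                     groupBelow = 1e-4) {
  stopifnot(is(x, "OtuTable"))
  basis <- match.arg(basis)
  cnt <- otuCounts(x)
  aff <- affiliations[!is.na(affiliations$lineage), , drop = FALSE]
  idx <- match(aff$query, rownames(cnt))
  if (anyNA(idx))
    stop("affiliations refer to OTUs absent from the table")
  out <- list()
  for (j in seq_len(ncol(cnt))) {
    cj <- cnt[idx, j]
    denom <- if (basis == "affiliated") sum(cj) else sum(cnt[, j])
    if (denom == 0L) next
    pool <- cnt[idx, j] / sum(cnt[, j]) < groupBelow
    member <- ifelse(pool, "other", aff$query)
    d <- aggregate(fraction ~ lineage + member,
                   data = data.frame(lineage = aff$lineage, member = member,
                                     fraction = cj / denom),
                   FUN = sum)
    d <- d[d$fraction > 0, , drop = FALSE]
    if (!nrow(d)) next
    out[[length(out) + 1L]] <-
      data.frame(sample = colnames(cnt)[j], d[, c("lineage", "member",
                                                  "fraction")])
  }
  if (!length(out))
    return(data.frame(sample = character(0), lineage = character(0),
                      member = character(0), fraction = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
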
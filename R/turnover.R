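## Occupancy-abundance and slope statistics of seasonal turnover:
## equal-depth subsampling, N / n / A records, occupancy-class summaries
## with one-way ANOVA + Tukey HSD, ranked-log-count slopes and the
## slope-occupancy correlation.

#' Subsample every sample to equal depth
#'
#' Draws, independently for each sample, a uniform without-replacement
#' subsample of `depth` reads (a multivariate hypergeometric draw per
#' column), so abundance patterns become comparable across samples of
#' unequal sequencing depth. OTUs left with all-zero counts are removed.
#'
#' @param x An [OtuTable()].
#' @param depth Target depth; default (`NULL`) uses the smallest per-sample
#'   total, mirroring the convention of matching the sample with the lowest
#'   number of reads. An error names the first sample whose total is below
#'   `depth`.
#' @param seed Optional seed for the draw (one documented draw per sample,
#'   in column order).
#' @return An [OtuTable()] whose column sums all equal `depth`.
#' @export
subsampleEqualDepth <- function(x, depth = NULL, seed = NULL) {
  stopifnot(is(x, "OtuTable"))
  cnt <- otuCounts(x)
  totals <- colSums(cnt)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  low <- which(totals < depth)
  if (length(low))
    stop("depth ", depth, " exceeds the ", totals[low[1L]],
         " reads of sample ", colnames(cnt)[low[1L]])
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- cnt
  for (j in seq_len(ncol(cnt))) {
    pool <- rep.int(seq_len(nrow(cnt)), cnt[, j])
    keep <- pool[sample.int(length(pool), depth)]
    out[, j] <- tabulate(keep, nbins = nrow(cnt))
  }
  nz <- rowSums(out) > 0L
  OtuTable(out[nz, , drop = FALSE], rowData(x)$sequence[nz])
}

#' Occupancy-abundance records
#'
#' For every OTU with at least one read: its occupancy `N` (number of
#' samples with a positive count), its total reads `n` across all samples,
#' and its mean abundance when present `A = n / N`. By construction
#' `A * N == n` exactly and `A >= 1` for integer counts.
#'
#' @param x An [OtuTable()].
#' @return A `data.frame` with columns `otu_id`, `N`, `n`, `A`.
#' @export
occupancyStats <- function(x) {
  stopifnot(is(x, "OtuTable"))
  cnt <- otuCounts(x)
  n <- as.integer(rowSums(cnt))
  N <- as.integer(rowSums(cnt > 0L))
  keep <- n > 0L
  data.frame(otu_id = rownames(cnt)[keep], N = N[keep], n = n[keep],
             A = n[keep] / N[keep], row.names = NULL)
}

#' Occupancy-class summaries with one-way ANOVA and Tukey HSD
#'
#' Groups OTUs by occupancy class k = 1..n_samples and summarises the
#' number of OTUs and the mean/SD of `N` and `A` within each class. The
#' number of OTUs per class is then tested across classes by a one-way
#' ANOVA whose replicates are the per-sample counts of OTUs of that class
#' present in each sample (n_samples replicates per class -- the only
#' replicate structure the single-series design provides), followed by
#' Tukey's HSD. Classes containing no OTU are reported empty and excluded
#' from the ANOVA.
#'
#' @param x An [OtuTable()].
#' @return A list with components `classes` (per-class summary
#'   `data.frame`), `anova` (`F`, `df`, `p`), `tukey` (pairwise table with
#'   mean difference, studentized-range `q` and adjusted p) and
#'   `replicates` (the sample x class count matrix fed to the ANOVA).
#' @export
occupancyClassSummary <- function(x) {
  stopifnot(is(x, "OtuTable"))
  cnt <- otuCounts(x)
  ns <- ncol(cnt)
  recs <- occupancyStats(x)
  classes <- data.frame(k = seq_len(ns))
  agg <- function(v, f) vapply(seq_len(ns), function(k) {
    z <- v[recs$N == k]
    if (length(z)) f(z) else NA_real_
  }, numeric(1))
  classes$n_otus <- vapply(seq_len(ns),
                           function(k) sum(recs$N == k), numeric(1))
  classes$mean_N <- agg(recs$N, mean)
  classes$sd_N <- agg(recs$N, function(z) if (length(z) > 1L) sd(z) else 0)
  classes$mean_A <- agg(recs$A, mean)
  classes$sd_A <- agg(recs$A, function(z) if (length(z) > 1L) sd(z) else 0)

  ## replicates: per sample, how many of its OTUs have occupancy k
  present <- cnt > 0L
  occ <- rowSums(present)
  M <- vapply(seq_len(ns), function(k)
    as.integer(colSums(present[occ == k, , drop = FALSE])),
    integer(ncol(cnt)))
  dimnames(M) <- list(colnames(cnt), seq_len(ns))

  keepK <- classes$n_otus >= 1L
  aovRes <- tukey <- NULL
  if (sum(keepK) >= 2L) {
    long <- data.frame(
      count = as.vector(M[, keepK, drop = FALSE]),
      class = factor(rep(classes$k[keepK], each = nrow(M))))
    fit <- aov(count ~ class, data = long)
    sm <- summary(fit)[[1L]]
    aovRes <- list(F = sm[1L, "F value"],
                   df = c(sm[1L, "Df"], sm[2L, "Df"]),
                   p = sm[1L, "Pr(>F)"])
    th <- TukeyHSD(fit)$class
    msw <- sm[2L, "Mean Sq"]
    nrep <- nrow(M)                     # balanced: one replicate per sample
    tukey <- data.frame(pair = rownames(th),
                        diff = th[, "diff"],
                        q = th[, "diff"] / sqrt(msw / nrep),
                        p_adj = th[, "p adj"], row.names = NULL)
  }
  list(classes = classes, anova = aovRes, tukey = tukey, replicates = M)
}

#' Ranked log-count slope per OTU
#'
#' For every OTU whose dataset-wide total is strictly greater than
#' `minTotal`, its positive per-sample counts are log-transformed, sorted
#' in decreasing order and regressed by ordinary least squares against the
#' ranks 1..k. The fitted slope `m` (always <= 0) measures how sharply the
#' OTU's abundance falls off across the samples it occupies: strongly
#' seasonal OTUs have steep negative slopes, stable persistent OTUs have
#' slopes near zero. Zero counts carry no log abundance and are excluded;
#' OTUs observed in a single sample leave the slope undefined (`NA`).
#'
#' @param x An [OtuTable()].
#' @param minTotal Strict total-read cutoff (default 10: totals of 11 and
#'   above enter).
#' @param logBase Base of the log transform (default 10).
#' @return A `data.frame` with columns `otu_id`, `m` (NA when undefined),
#'   `points` (ranks used) and `N` (occupancy).
#' @export
slopeStatistics <- function(x, minTotal = 10L, logBase = 10) {
  stopifnot(is(x, "OtuTable"))
  cnt <- otuCounts(x)
  totals <- rowSums(cnt)
  sel <- which(totals > minTotal)
  res <- lapply(sel, function(i) {
    v <- cnt[i, ]
    v <- sort(v[v > 0L], decreasing = TRUE)
    k <- length(v)
    m <- NA_real_
    if (k >= 2L) {
      y <- log(v, base = logBase)
      r <- seq_len(k)
      m <- sum((r - mean(r)) * (y - mean(y))) / sum((r - mean(r))^2)
    }
    data.frame(otu_id = rownames(cnt)[i], m = m, points = k, N = k)
  })
  if (!length(res))
    return(data.frame(otu_id = character(0), m = numeric(0),
                      points = integer(0), N = integer(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Correlation between slope and occupancy
#'
#' Pearson product-moment correlation between the ranked-log-count slope
#' `m` and the occupancy `N` over all OTUs with a defined slope, with a
#' two-sided p-value from the t transform, plus per-occupancy-class mean
#' and SD of `m` for plotting. A positive correlation means OTUs present
#' in more samples have flatter (less negative) slopes, i.e. more stable
#' abundances.
#'
#' @param slopes Result of [slopeStatistics()]; rows with `NA` slope are
#'   dropped (their number is reported).
#' @return A list with `r`, `p`, `n` (pairs used), `nUndefined` (slopes
#'   excluded) and `byClass` (`data.frame` of per-occupancy mean/SD of
#'   `m`).
#' @export
slopeOccupancyCorrelation <- function(slopes) {
  ok <- slopes[!is.na(slopes$m), ]
  if (nrow(ok) < 3L)
    stop("need at least 3 defined slopes")
  if (length(unique(ok$N)) < 2L || sd(ok$m) == 0)
    stop("correlation undefined: zero variance in slope or occupancy")
  ct <- cor.test(ok$m, ok$N, method = "pearson", alternative = "two.sided")
  byClass <- do.call(rbind, lapply(sort(unique(ok$N)), function(k) {
    z <- ok$m[ok$N == k]
    data.frame(N = k, mean_m = mean(z),
               sd_m = if (length(z) > 1L) sd(z) else 0,
               n_otus = length(z))
  }))
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(ok),
       nUndefined = sum(is.na(slopes$m)), byClass = byClass)
}

#' Plot mean slope against occupancy
#'
#' Mean and SD of the ranked-log-count slope per occupancy class: the
#' signature figure contrasting strongly seasonal rare OTUs (steep slopes
#' at low occupancy) with stable abundant OTUs (flat slopes at full
#' occupancy).
#'
#' @param corr Result of [slopeOccupancyCorrelation()].
#' @param ... Passed to the underlying plot call.
#' @return Invisibly, `corr`.
#' @export
plotSlopeOccupancy <- function(corr, ...) {
  b <- corr$byClass
  ylim <- range(b$mean_m - b$sd_m, b$mean_m + b$sd_m, 0)
  plot(b$N, b$mean_m, ylim = ylim, pch = 19,
       xlab = "occupancy (samples present)",
       ylab = "slope of ranked log counts", ...)
  graphics::arrows(b$N, b$mean_m - b$sd_m, b$N, b$mean_m + b$sd_m,
                   angle = 90, code = 3, length = 0.03)
  invisible(corr)
}
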
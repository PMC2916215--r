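## Analytic (Hurlbert) rarefaction: exact expected richness under
## subsampling without replacement.

#' Expected richness of a random subsample (analytic rarefaction)
#'
#' Computes the exact expectation of the number of distinct categories in a
#' uniform without-replacement draw of `g` reads from an abundance vector:
#' `E[S_g] = sum_i (1 - choose(T - c_i, g) / choose(T, g))` with
#' `T = sum(c_i)`. The binomial-coefficient ratio is evaluated in log
#' space (`lchoose`) and clamped to [0, 1], so depths of 10^5 and beyond
#' are safe from overflow.
#'
#' @param counts Integer abundance vector; zeros are dropped.
#' @param g Subsample size, `0 <= g <= sum(counts)` (vectorized).
#' @return Numeric vector of expected richness values, one per `g`.
#' @examples
#' expectedRichness(c(3, 1), 2)   # 1.5: 3 of the 6 possible pairs
#'                                # contain the singleton
#' @export
expectedRichness <- function(counts, g) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (any(g < 0) || any(g > total))
    stop("g must lie in [0, ", total, "]")
  vapply(g, function(gi) {
    if (gi == 0) return(0)
    lr <- lchoose(total - counts, gi) - lchoose(total, gi)
    sum(1 - pmin(exp(lr), 1))
  }, numeric(1))
}

#' Rarefaction curves per sample and for the pooled dataset
#'
#' One analytic rarefaction curve per sample of the OTU table plus one for
#' the pooled (row-summed) dataset, labelled `"all samples"`. The pooled
#' curve rising well above every single-sample curve is the signature of a
#' community whose taxa turn over between samples rather than merely
#' fluctuate.
#'
#' @param x An [OtuTable()].
#' @param points Number of grid points per curve; the grid is evenly
#'   spaced from 0 to the curve's total read count.
#' @return A `data.frame` with columns `curve`, `g`, `expected_richness`,
#'   plus an attribute `observed` giving observed richness per curve.
#' @export
rarefactionCurves <- function(x, points = 50L) {
  stopifnot(is(x, "OtuTable"), points >= 2L)
  cnt <- otuCounts(x)
  sets <- c(lapply(setNames(nm = colnames(cnt)), function(j) cnt[, j]),
            list("all samples" = rowSums(cnt)))
  out <- lapply(names(sets), function(nm) {
    v <- sets[[nm]]
    total <- sum(v)
    grid <- unique(as.integer(round(seq(0, total, length.out = points))))
    data.frame(curve = nm, g = grid,
               expected_richness = expectedRichness(v, grid))
  })
  res <- do.call(rbind, out)
  attr(res, "observed") <- vapply(sets, function(v) sum(v > 0), numeric(1))
  res
}

#' Plot rarefaction curves
#'
#' One panel with all per-sample curves and the pooled curve emphasised.
#'
#' @param curves Result of [rarefactionCurves()].
#' @param ... Passed to [graphics::matplot()]-style base plotting.
#' @return Invisibly, `curves`.
#' @export
plotRarefaction <- function(curves, ...) {
  labs <- unique(curves$curve)
  cols <- ifelse(labs == "all samples", "black", "grey50")
  lwds <- ifelse(labs == "all samples", 2.5, 1)
  plot(NA, xlim = range(curves$g), ylim = range(curves$expected_richness),
       xlab = "reads sampled", ylab = "expected OTU richness", ...)
  for (i in seq_along(labs)) {
    d <- curves[curves$curve == labs[i], ]
    graphics::lines(d$g, d$expected_richness, col = cols[i], lwd = lwds[i])
  }
  graphics::legend("bottomright", c("single sample", "all samples"),
                   col = c("grey50", "black"), lwd = c(1, 2.5), bty = "n")
  invisible(curves)
}
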
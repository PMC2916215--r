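test_that("equal-depth subsampling conserves depth and errors on shallow samples", {
  set.seed(61)
  cnt <- matrix(rpois(500, 3), 50, 10, dimnames = list(NULL, sprintf("S%02d", 1:10)))
  cnt[1, ] <- cnt[1, ] + 5L    # keep every column positive
  tab <- tableFromCounts(cnt)
  sub <- subsampleEqualDepth(tab, depth = min(colSums(cnt)), seed = 1)
  expect_true(all(colSums(otuCounts(sub)) == min(colSums(cnt))))
  expect_true(all(rowSums(otuCounts(sub)) > 0))
  ## depth equal to every column total leaves the table unchanged
  even <- tableFromCounts(matrix(2L, 8, 3))
  expect_equal(otuCounts(subsampleEqualDepth(even, 16L, seed = 2)),
               otuCounts(even))
  expect_error(subsampleEqualDepth(tab, depth = 10^6), "exceeds.*S01")
})

test_that("subsampled counts follow the hypergeometric expectation", {
  cnt <- matrix(c(200L, 800L), 2, 1, dimnames = list(NULL, "S01"))
  tab <- tableFromCounts(cnt)
  set.seed(91)
  draws <- replicate(4000, otuCounts(
    subsampleEqualDepth(tab, depth = 100L))[1L])
  ## hypergeometric oracle: mean 20, variance n*p*q*(N-n)/(N-1)
  v <- 100 * 0.2 * 0.8 * (1000 - 100) / 999
  se <- sqrt(v / length(draws))
  expect_lt(abs(mean(draws) - 20), 3 * se)
})

test_that("occupancy records satisfy their identities against a brute-force oracle", {
  expect_equal(occupancyStats(tableFromCounts(
    matrix(c(5, rep(0, 9)), 1, 10)))[, c("N", "n", "A")],
    data.frame(N = 1L, n = 5L, A = 5.0))
  expect_equal(occupancyStats(tableFromCounts(
    matrix(2L, 1, 10)))[, c("N", "n", "A")],
    data.frame(N = 10L, n = 20L, A = 2.0))
  set.seed(71)
  cnt <- matrix(rpois(5000, 0.7), 500, 10)
  tab <- tableFromCounts(cnt)
  recs <- occupancyStats(tab)
  keep <- rowSums(cnt) > 0
  expect_equal(recs$N, apply(cnt[keep, ], 1, function(r) sum(r > 0)))
  expect_equal(recs$n, rowSums(cnt[keep, ]))
  expect_equal(recs$A * recs$N, recs$n)        # A*N == n exactly
  expect_true(all(recs$A >= 1))
})

test_that("the class ANOVA reduces to the squared t statistic for two classes", {
  set.seed(81)
  ns <- 6L
  ## occupancy classes 1 and 6 only
  occ1 <- diag(1L, ns) * rpois(ns, 4)
  cnt <- rbind(matrix(1L + rpois(20 * ns, 3), 20, ns),
               occ1[rep(1:ns, 3), ] * (1L + rpois(3 * ns, 2)))
  colnames(cnt) <- sprintf("S%02d", 1:ns)
  tab <- tableFromCounts(cnt)
  cs <- occupancyClassSummary(tab)
  M <- cs$replicates
  used <- which(cs$classes$n_otus >= 1)
  expect_equal(length(used), 2L)
  tt <- t.test(M[, used[1]], M[, used[2]], var.equal = TRUE)
  expect_equal(cs$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cs$anova$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA F and Tukey q match hand-computed sums of squares on a 3x4 fixture", {
  ## three occupancy classes (1, 2, 4) over four samples
  ns <- 4L
  blocks <- list(
    occ4 = matrix(2L, 5, ns),                       # 5 OTUs in all samples
    occ2 = rbind(c(1, 1, 0, 0), c(0, 1, 1, 0),
                 c(0, 0, 1, 1), c(1, 0, 0, 1)) * 3L,
    occ1 = rbind(c(4, 0, 0, 0), c(0, 4, 0, 0)))
  cnt <- do.call(rbind, blocks)
  colnames(cnt) <- sprintf("S%02d", 1:ns)
  cs <- occupancyClassSummary(tableFromCounts(cnt))
  M <- cs$replicates
  used <- which(cs$classes$n_otus >= 1)
  groups <- lapply(used, function(k) M[, k])
  k <- length(groups); n <- ns
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) n * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  Fhand <- (ssb / (k - 1)) / (ssw / (k * n - k))
  expect_equal(cs$anova$F, Fhand, tolerance = 1e-10)
  expect_equal(cs$anova$df, c(k - 1, k * n - k))
  msw <- ssw / (k * n - k)
  means <- vapply(groups, mean, 0)
  qhand <- abs(outer(means, means, "-")) / sqrt(msw / n)
  for (r in seq_len(nrow(cs$tukey))) {
    pair <- as.integer(strsplit(cs$tukey$pair[r], "-")[[1L]])
    i <- match(pair[1L], cs$classes$k[used])
    j <- match(pair[2L], cs$classes$k[used])
    expect_equal(abs(cs$tukey$q[r]), qhand[i, j], tolerance = 1e-10)
    expect_equal(cs$tukey$p_adj[r],
                 ptukey(qhand[i, j], k, k * n - k, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
  ## class bookkeeping: counts sum to the total number of OTUs
  expect_equal(sum(cs$classes$n_otus), nrow(cnt))
  expect_equal(cs$classes$mean_A[4], 2.0)  # occ-4 OTUs: 8 reads / 4 samples
})

test_that("identical class replicates give F = 0 and p = 1", {
  ## classes 1 and 2 both contribute per-sample counts (1, 2, 3)
  cnt <- rbind(
    c(1L, 0L, 1L), c(0L, 1L, 1L), c(0L, 1L, 1L),            # occupancy 2
    c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 1L, 0L),            # occupancy 1
    c(0L, 0L, 1L), c(0L, 0L, 1L), c(0L, 0L, 1L))
  colnames(cnt) <- sprintf("S%02d", 1:3)
  cs <- occupancyClassSummary(tableFromCounts(cnt))
  expect_equal(unname(cs$replicates[, 1L]), c(1L, 2L, 3L))
  expect_equal(unname(cs$replicates[, 2L]), c(1L, 2L, 3L))
  expect_equal(cs$anova$F, 0)
  expect_equal(cs$anova$p, 1)
})

test_that("ranked-log slopes match closed forms", {
  m3 <- slopeStatistics(tableFromCounts(
    matrix(c(1000L, 100L, 10L), 1, 3)), minTotal = 10L, logBase = 10)
  expect_equal(m3$m, -1)
  expect_equal(m3$points, 3L)
  flat <- slopeStatistics(tableFromCounts(matrix(100L, 1, 3)))
  expect_equal(flat$m, 0)
  single <- slopeStatistics(tableFromCounts(
    matrix(c(50L, rep(0L, 9)), 1, 10)))
  expect_true(is.na(single$m))
  expect_equal(single$N, 1L)
  ## the abundance cutoff is strict: a total of exactly 10 is excluded
  ten <- slopeStatistics(tableFromCounts(matrix(5L, 1, 2)))
  expect_equal(nrow(ten), 0L)
  eleven <- slopeStatistics(tableFromCounts(matrix(c(6L, 5L), 1, 2)))
  expect_equal(nrow(eleven), 1L)
  ## log base rescales the slope
  b2 <- slopeStatistics(tableFromCounts(
    matrix(c(1000L, 100L, 10L), 1, 3)), logBase = 2)
  expect_equal(b2$m, -1 * log(10, base = 2))
})

test_that("slopes are never positive and agree with lm on random tables", {
  set.seed(41)
  cnt <- matrix(rpois(600, 4), 60, 10)
  tab <- tableFromCounts(cnt)
  sl <- slopeStatistics(tab)
  expect_true(all(sl$m[!is.na(sl$m)] <= 1e-12))
  i <- which(!is.na(sl$m))[1L]
  otu <- match(sl$otu_id[i], rownames(tab))
  v <- sort(otuCounts(tab)[otu, ], decreasing = TRUE)
  v <- v[v > 0]
  fit <- lm(log10(v) ~ seq_along(v))
  expect_equal(sl$m[i], unname(coef(fit)[2L]), tolerance = 1e-10)
})

test_that("slope-occupancy correlation reproduces closed-form Pearson results", {
  slopes <- data.frame(otu_id = c("a", "b", "c"),
                       m = c(-2, -1, 0), points = c(2L, 3L, 4L),
                       N = c(2L, 3L, 4L))
  res <- slopeOccupancyCorrelation(slopes)
  expect_equal(res$r, 1.0)
  expect_lt(res$p, 1e-6)
  expect_equal(res$n, 3L)
  expect_equal(res$byClass$mean_m, c(-2, -1, 0))
  ## degenerate inputs are reported as undefined
  expect_error(slopeOccupancyCorrelation(
    data.frame(otu_id = letters[1:3], m = c(-1, -1, -1),
               points = 2L, N = c(2L, 3L, 4L))), "zero variance")
  expect_error(slopeOccupancyCorrelation(
    data.frame(otu_id = letters[1:2], m = c(-1, 0),
               points = 2L, N = c(2L, 3L))), "at least 3")
})
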
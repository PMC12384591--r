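test_that("channel means collapse the time axis of a heatmap", {
  expect_equal(channel_means(matrix(0.4, 128, 32)), rep(0.4, 32))
  ramp <- matrix(0, 128, 32)
  ramp[, 3] <- (0:127) / 127
  cm <- channel_means(ramp)
  expect_equal(cm[3], 0.5)
  expect_equal(cm[-3], rep(0, 31))
  expect_equal(channel_means(matrix(0, 128, 32)), rep(0, 32))
})

test_that("class aggregation averages within classes and rejects empty ones", {
  s <- rbind(rep(0, 32), rep(1, 32), rep(4, 32))
  lab <- factor(c("A", "A", "B"))
  agg <- aggregate_contributions(s, lab)
  expect_equal(unname(agg["A", ]), rep(0.5, 32))
  expect_equal(unname(agg["B", ]), rep(4, 32))
  # one sample per class: the aggregate is that sample
  agg1 <- aggregate_contributions(s[c(1, 3), ], factor(c("A", "B")))
  expect_equal(unname(agg1["B", ]), rep(4, 32))
  # duplicating the sample set leaves the mean unchanged
  expect_equal(aggregate_contributions(rbind(s, s), factor(rep(lab, 2))), agg)
  expect_error(aggregate_contributions(s, factor(c("A", "A", "A"), levels = c("A", "B"))),
               "zero samples")
  expect_equal(aggregate_contributions(s), colMeans(s))
})

test_that("min-max normalization maps the spread onto [0, 1]", {
  v <- normalize_contribution(seq(2, 64, by = 2))
  expect_equal(min(v$scores), 0)
  expect_equal(max(v$scores), 1)
  expect_equal(v$scores[2], (4 - 2) / (64 - 2))
  expect_false(v$degenerate)

  w <- c(0, runif(30), 1)
  expect_equal(normalize_contribution(w)$scores, w)  # idempotent on [0,1] span

  dg <- normalize_contribution(rep(3, 32))
  expect_true(dg$degenerate)
  expect_equal(dg$scores, rep(0, 32))
})

test_that("normalization is invariant under positive affine transforms", {
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(32)
    a <- runif(1, 0.1, 10); b <- rnorm(1, sd = 5)
    expect_equal(normalize_contribution(a * x + b)$scores,
                 normalize_contribution(x)$scores, tolerance = 1e-12)
  }
})

test_that("channel selection uses a strict threshold and montage names", {
  scores <- rep(0.2, 32)
  scores[c(20, 22)] <- c(0.9, 0.5)
  v <- normalize_contribution(scores)  # rescales 0.2 -> 0, 0.9 -> 1
  sel <- select_channels(v, threshold = 0.4)
  expect_identical(sel$channels, c("F4", "FC6"))
  # strict inequality: a score exactly at the threshold is excluded
  at <- select_channels(c(rep(0, 31), 0.5), threshold = 0.5)
  expect_length(at$channels, 0L)
  expect_length(select_channels(rep(0, 32), threshold = 0.2)$channels, 0L)
  some <- select_channels(v, threshold = 0)
  expect_setequal(some$index, which(v$scores > 0))
  # per-task default thresholds
  v$task <- "arousal"
  expect_equal(select_channels(v)$threshold, 0.6)
  v$task <- "quaternary"
  expect_equal(select_channels(v)$threshold, 0.5)
})

test_that("the correlation metric matches hand computation and is affine-invariant", {
  expect_equal(pearson_r(1:32, 1:32), 1)
  expect_equal(pearson_r(1:10, -(1:10) + 7), -1)
  expect_equal(round(pearson_r(c(1, 2, 3), c(1, 2, 4)), 4), 0.9820)
  set.seed(43)
  x <- rnorm(32); y <- rnorm(32)
  expect_equal(pearson_r(2.5 * x + 1, y), pearson_r(x, y), tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero-variance")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("subset stability reports deterministic draws with a unit full-size row", {
  set.seed(44)
  base <- runif(32)
  samples <- matrix(rep(base, each = 500), 500, 32) + matrix(rnorm(500 * 32, sd = 0.05), 500, 32)
  r1 <- subset_stability(samples, sizes = c(50, 200), seed = 7)
  r2 <- subset_stability(samples, sizes = c(50, 200), seed = 7)
  expect_identical(r1$table, r2$table)
  expect_equal(r1$table$subset_size, c(50, 200, 500))
  expect_equal(r1$table$pcc[3], 1)
  expect_identical(r1$table$channels[3],
                   paste(select_channels(r1$full, 0.5)$channels, collapse = ", "))
  expect_true(all(r1$table$pcc >= -1 & r1$table$pcc <= 1))
  expect_error(subset_stability(samples, sizes = c(100, 600), seed = 1),
               "exceeds")
  expect_error(subset_stability(samples, sizes = c(200, 100), seed = 1),
               "increasing")
})
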
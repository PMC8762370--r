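test_that("subsample_counts draws the multivariate hypergeometric law", {
  tab <- count_table(matrix(c(2L, 1L), 1, 2,
                            dimnames = list("s1", c("a", "b"))))
  # exhaustive enumeration for row [2, 1] at depth 2:
  # P(a=2, b=0) = 1/3, P(a=1, b=1) = 2/3
  n_draw <- 4000
  hits <- vapply(seq_len(n_draw), function(i) {
    out <- subsample_counts(tab, 2, seed = i)
    unclass(out)[1, "a"] == 2
  }, logical(1))
  se <- sqrt((1 / 3) * (2 / 3) / n_draw)
  expect_lt(abs(mean(hits) - 1 / 3), 3 * se)

  # rows sum exactly to depth, cells never exceed the input
  for (seed in 1:5) {
    t <- random_count_table(6, 30, lambda = 3, seed = seed)
    d <- min(sample_depths(t))
    out <- subsample_counts(t, d, seed = seed)
    expect_true(all(sample_depths(out) == d))
    expect_true(all(unclass(out) <= unclass(t)[, colnames(out)]))
  }
})

test_that("subsample_counts drops shallow samples with a log, errors empty", {
  tab <- count_table(matrix(c(1500L, 2500L), 2, 1,
                            dimnames = list(c("lo", "hi"), "a")))
  out <- subsample_counts(tab, 2000, seed = 1)
  expect_equal(rownames(out), "hi")
  expect_equal(attr(out, "dropped_samples"), "lo")
  expect_error(subsample_counts(tab, 99999, seed = 1), "empty")
})

test_that("subsample_reads matches subsample_counts in distribution", {
  reads <- read_table(list(s1 = c("a", "a", "b")))
  n_draw <- 4000
  hits <- vapply(seq_len(n_draw), function(i) {
    out <- subsample_reads(reads, 2, seed = i)
    sum(out[["s1"]] == "a") == 2
  }, logical(1))
  se <- sqrt((1 / 3) * (2 / 3) / n_draw)
  expect_lt(abs(mean(hits) - 1 / 3), 3 * se)

  # full-depth subsample is a multiset identity; same seed reproduces
  full <- subsample_reads(reads, 3, seed = 7)
  expect_equal(sort(full[["s1"]]), c("a", "a", "b"))
  expect_identical(subsample_reads(reads, 2, seed = 5),
                   subsample_reads(reads, 2, seed = 5))
  expect_false(identical(subsample_reads(small_read_table(), 2, seed = 5),
                         subsample_reads(small_read_table(), 2, seed = 6)))
})

test_that("expected_richness matches hand value, endpoint, and oracles", {
  expect_equal(expected_richness(c(2, 1), 2), 1 + 2 / 3, tolerance = 1e-12)

  for (seed in 1:10) {
    row <- unclass(random_count_table(1, 25, lambda = 2, seed = seed))[1, ]
    n <- sum(row)
    # endpoint identity
    expect_equal(expected_richness(row, n), sum(row > 0), tolerance = 1e-9)
    # independent hypergeometric-density route at several depths
    for (m in unique(pmax(1, round(c(0.2, 0.5, 0.8) * n)))) {
      expect_equal(expected_richness(row, m),
                   naive_expected_richness(row, m), tolerance = 1e-9)
    }
    # non-decreasing and concave in m
    grid <- seq_len(n)
    vals <- expected_richness(row, grid)
    expect_true(all(diff(vals) >= -1e-9))
    expect_true(all(diff(diff(vals)) <= 1e-9))
  }

  # Monte-Carlo agreement at half depth
  row <- c(8L, 5L, 3L, 2L, 1L, 1L)
  tab <- count_table(matrix(row, 1, dimnames = list("s1", letters[1:6])))
  m <- sum(row) %/% 2
  reps <- vapply(seq_len(2000), function(i) {
    sum(unclass(subsample_counts(tab, m, seed = i))[1, ] > 0)
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected_richness(row, m)), 3 * se)

  expect_error(expected_richness(c(2, 1), 4), "must lie in")
})

test_that("rarefaction curves end at Sobs and flatten for single ASVs", {
  one <- count_table(matrix(9L, 1, 1, dimnames = list("s1", "a")))
  cv <- rarefaction_curve(one, grid_points = 5)
  expect_true(all(abs(cv$expected_richness - 1) < 1e-12))

  tab <- random_count_table(4, 20, seed = 2)
  cv <- rarefaction_curve(tab, grid_points = 10)
  for (s in rownames(tab)) {
    sub <- cv[cv$sample_id == s, ]
    expect_equal(max(sub$depth), sum(unclass(tab)[s, ]))
    expect_equal(sub$expected_richness[nrow(sub)],
                 sum(unclass(tab)[s, ] > 0), tolerance = 1e-9)
  }
})

test_that("retention_filter applies depth and presence rules", {
  full <- count_table(matrix(c(9999L, 12000L, 15000L), 3, 1,
                             dimnames = list(c("s1", "s2", "s3"), "a")))
  scen_all <- count_table(matrix(2500L, 3, 1,
                                 dimnames = list(c("s1", "s2", "s3"), "a")))
  # s1 fails the full-depth rule even though every scenario keeps it
  expect_setequal(retention_filter(full, list(scen_all)), c("s2", "s3"))

  # a sample missing from one scenario is excluded everywhere
  scen_miss <- count_table(matrix(2500L, 2, 1,
                                  dimnames = list(c("s1", "s2"), "a")))
  expect_setequal(retention_filter(full, list(scen_all, scen_miss)), "s2")

  # a sample below min_sub in one scenario is excluded
  scen_low <- count_table(matrix(c(2500L, 2500L, 1999L), 3, 1,
                                 dimnames = list(c("s1", "s2", "s3"), "a")))
  expect_setequal(retention_filter(full, list(scen_all, scen_low)), "s2")

  # all above thresholds in all scenarios: identity set
  expect_setequal(retention_filter(full, list(scen_all),
                                   min_full = 5000), c("s1", "s2", "s3"))
})
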
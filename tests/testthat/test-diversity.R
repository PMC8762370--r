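test_that("div_components tallies the worked rows and its invariants", {
  cm <- div_components(c(5, 3, 1, 1))
  expect_equal(cm[c("N", "Sobs", "Sn1", "Sn2", "Sabund", "Srare", "Nrare")],
               list(N = 10L, Sobs = 4L, Sn1 = 2L, Sn2 = 0L,
                    Sabund = 0L, Srare = 4L, Nrare = 10L))

  cm2 <- div_components(c(12, 5, 3, 1, 1))
  expect_equal(cm2$Sabund, 1L)
  expect_equal(cm2$Srare, 4L)
  expect_equal(cm2$Nrare, 10L)
  expect_equal(cm2$Sn1, 2L)

  expect_equal(div_components(c(4, 4, 4))$Sn1, 0L)
  expect_error(div_components(c(0, 0)), "empty sample")

  for (seed in 1:10) {
    row <- unclass(random_count_table(1, 40, seed = seed))[1, ]
    cm <- div_components(row)
    expect_equal(cm$Sobs, cm$Sabund + cm$Srare)
    expect_lte(cm$Sn1, cm$Srare)
    vals <- as.integer(names(cm$freq))
    expect_equal(cm$N, sum(vals * cm$freq))
    expect_equal(cm$Nrare, sum((vals * cm$freq)[vals <= 10]))
  }
})

test_that("Hill numbers: identities, hand values, continuity, monotonicity", {
  p <- c(0.5, 0.3, 0.1, 0.1)
  expect_equal(hill_number(p, 0), 4)
  expect_equal(hill_number(p, 2), 1 / 0.36, tolerance = 1e-12)
  expect_equal(shannon_entropy(p),
               -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(shannon_entropy(p), 1.1682824, tolerance = 1e-6)
  expect_equal(exp(shannon_entropy(p)), 3.2164635, tolerance = 1e-6)
  expect_equal(inverse_simpson(p), 2.777778, tolerance = 1e-6)

  # single ASV and uniform closed forms
  expect_equal(shannon_entropy(1), 0)
  expect_equal(inverse_simpson(1), 1)
  u <- rep(1 / 7, 7)
  expect_equal(shannon_entropy(u), log(7), tolerance = 1e-12)
  expect_equal(inverse_simpson(u), 7, tolerance = 1e-9)

  for (seed in 1:5) {
    pr <- random_abundance_row(20, seed)
    # q -> 1 continuity of the Hill limit
    expect_lt(abs(hill_number(pr, 1 - 1e-6) - hill_number(pr, 1)), 1e-4)
    expect_lt(abs(hill_number(pr, 1 + 1e-6) - hill_number(pr, 1)), 1e-4)
    # non-increasing in q
    qs <- c(0, 0.5, 1, 1.5, 2, 3)
    hv <- vapply(qs, function(q) hill_number(pr, q), numeric(1))
    expect_true(all(diff(hv) <= 1e-9))
    # matches the naive one-liner
    for (q in qs) {
      expect_equal(hill_number(pr, q), naive_hill(pr, q), tolerance = 1e-9)
    }
  }
  expect_error(hill_number(c(-0.5, 1.5), 1), "non-negative")
})

test_that("Chao1: hand values and collapse without singletons", {
  expect_equal(chao1(div_components(c(5, 3, 1, 1))), 5)
  expect_equal(chao1(div_components(c(1, 1, 1))), 6)
  for (seed in 1:10) {
    row <- unclass(random_count_table(1, 30, seed = seed))[1, ]
    cm <- div_components(row)
    expect_gte(chao1(cm), cm$Sobs)
    no_single <- row[row != 1]
    if (sum(no_single) > 0) {
      cm2 <- div_components(no_single)
      expect_equal(chao1(cm2), cm2$Sobs)
    }
  }
})

test_that("ACE: hand-evaluated worked value and undefined guards", {
  # [12,5,3,1,1]: C_ACE = 0.8, sum i(i-1)F_i = 26,
  # gamma^2 = max(5 * 26/90 - 1, 0) = 0.4444..., ACE = 1 + 5 + 2.5 * 0.4444
  val <- ace(div_components(c(12, 5, 3, 1, 1)))
  expect_equal(val, 1 + 5 + 2.5 * (5 * 26 / 90 - 1), tolerance = 1e-9)
  expect_equal(val, 7.111111, tolerance = 1e-6)

  # no singletons among rare: C_ACE = 1, finite and >= Sobs
  v <- ace(div_components(c(5, 5)))
  expect_false(is_undefined(v))
  expect_gte(v, 2)

  # all rare reads singletons -> C_ACE = 0 -> undefined marker
  expect_true(is_undefined(ace(div_components(c(1, 1)))))
  # a single rare read -> Nrare(Nrare - 1) = 0 -> undefined marker
  expect_true(is_undefined(ace(div_components(c(1)))))
  # all ASVs abundant: ACE reduces to Sabund
  expect_equal(ace(div_components(c(20, 30))), 2)
})

test_that("coverage, Margalef, Menhinick: hand values and depth inflation", {
  cm <- div_components(c(5, 3, 1, 1))
  expect_equal(goods_coverage(cm), 0.8)
  expect_equal(margalef(cm), 3 / log(10), tolerance = 1e-12)
  expect_equal(margalef(cm), 1.302883, tolerance = 1e-6)
  expect_equal(menhinick(cm), 4 / sqrt(10), tolerance = 1e-12)
  expect_equal(menhinick(cm), 1.264911, tolerance = 1e-6)

  expect_equal(goods_coverage(div_components(c(4, 4))), 1)
  expect_equal(goods_coverage(div_components(c(1, 1, 1))), 0)
  expect_equal(margalef(div_components(c(7))), 0)
  expect_true(is_undefined(margalef(div_components(c(1)))))

  # fixed Sobs, shrinking N: both indices strictly increase -- the
  # mechanism behind their post-sub-sampling inflation
  rows <- list(c(40, 30, 20, 10), c(20, 15, 10, 5), c(8, 6, 4, 2))
  mg <- vapply(rows, function(r) margalef(div_components(r)), numeric(1))
  mn <- vapply(rows, function(r) menhinick(div_components(r)), numeric(1))
  expect_true(all(diff(mg) > 0))
  expect_true(all(diff(mn) > 0))
})

test_that("diversity_profile agrees with vegan and is label-invariant", {
  for (seed in 1:25) {
    tab <- random_count_table(4, 35, lambda = 1.5, seed = seed)
    prof <- diversity_profile(tab)
    m <- unclass(tab)
    est <- t(apply(m, 1, vegan::estimateR))
    expect_equal(prof$observed_richness, unname(est[, "S.obs"]))
    expect_equal(prof$chao1, unname(est[, "S.chao1"]), tolerance = 1e-9)
    defined <- prof$ace_defined
    expect_equal(prof$ace[defined], unname(est[defined, "S.ACE"]),
                 tolerance = 1e-9)
    expect_equal(prof$shannon_entropy,
                 unname(vegan::diversity(m, "shannon")), tolerance = 1e-9)
    expect_equal(prof$inverse_simpson,
                 unname(vegan::diversity(m, "invsimpson")), tolerance = 1e-9)
    # naive single-formula oracles for the remaining indices
    expect_equal(prof$margalef,
                 unname(apply(m, 1, naive_margalef)), tolerance = 1e-9)
    expect_equal(prof$menhinick,
                 unname(apply(m, 1, naive_menhinick)), tolerance = 1e-9)
    expect_equal(prof$goods_coverage,
                 unname(apply(m, 1, naive_goods)), tolerance = 1e-9)
  }

  # permuting ASV columns changes nothing
  tab <- random_count_table(3, 20, seed = 99)
  perm <- count_table(unclass(tab)[, sample(ncol(tab)), drop = FALSE])
  expect_equal(diversity_profile(tab), diversity_profile(perm))

  # empty sample is an error naming the sample
  m <- unclass(random_count_table(2, 5, seed = 1))
  m["s02", ] <- 0L
  bad <- structure(m, class = c("count_table", "matrix", "array"))
  expect_error(diversity_profile(bad), "s02")
})

test_that("richness alone is invariant to count rescaling", {
  row <- c(8, 4, 2, 1, 1)
  p1 <- row / sum(row)
  p2 <- (row * 3) / sum(row * 3)
  expect_equal(hill_number(p1, 0), hill_number(p2, 0))
  # but depth-normalised indices are not (negative control)
  cm1 <- div_components(row)
  cm3 <- div_components(row * 3)
  expect_false(isTRUE(all.equal(menhinick(cm1), menhinick(cm3))))
  expect_false(isTRUE(all.equal(margalef(cm1), margalef(cm3))))
})
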
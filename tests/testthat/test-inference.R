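mn <- load_mongolia_2014()

test_that("exact enumeration matches hand counts and the reference implementation", {
  r <- mann_whitney(c(1, 2), c(3, 4), method = "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 1 / 3)
  expect_identical(r$method, "exact")

  # same multiset in both groups: U at its mean, capped p of 1
  s <- mann_whitney(c(1, 2, 3), c(1, 2, 3), method = "exact")
  expect_equal(s$U, 9 / 2)
  expect_equal(s$p_two_sided, 1)

  # tie-free exact p equals wilcox.test's exact p (independent route)
  set.seed(5)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- sample(1:1000, n1 + n2) # distinct values, no ties
    a <- x[seq_len(n1)]
    b <- x[-seq_len(n1)]
    ours <- mann_whitney(a, b, method = "exact")
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$U, unname(ref$statistic))
  }

  expect_error(mann_whitney(1:20, 1:20, method = "exact"), "infeasible")
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("asymptotic p with ties and continuity matches the reference implementation", {
  set.seed(9)
  for (rep in 1:15) {
    a <- sample(1:6, 8, replace = TRUE) # heavy ties
    b <- sample(2:8, 11, replace = TRUE)
    ours <- mann_whitney(a, b, method = "asymptotic", continuity = TRUE)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-10)
    ours_nc <- mann_whitney(a, b, method = "asymptotic", continuity = FALSE)
    ref_nc <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(ours_nc$p_two_sided, ref_nc$p.value, tolerance = 1e-10)
    expect_true(ours$tie_corrected)
  }
  # fully tied samples: degenerate U, p = 1
  tied <- mann_whitney(rep(3, 4), rep(3, 6), method = "asymptotic")
  expect_equal(tied$U, 12)
  expect_equal(tied$p_two_sided, 1)
})

test_that("swapping groups reflects U and preserves the two-sided p", {
  set.seed(13)
  for (method in c("exact", "asymptotic")) {
    for (rep in 1:8) {
      a <- stats::rnorm(4)
      b <- stats::rnorm(5, mean = 1)
      f <- mann_whitney(a, b, method = method)
      g <- mann_whitney(b, a, method = method)
      expect_equal(g$U, f$n1 * f$n2 - f$U)
      expect_equal(g$p_two_sided, f$p_two_sided, tolerance = 1e-12)
    }
  }
})

test_that("a large location shift drives U to an extreme", {
  a <- stats::rnorm(5)
  b <- stats::rnorm(6)
  hi <- mann_whitney(a + 1e6, b)
  expect_equal(hi$U, 30)
  lo <- mann_whitney(a - 1e6, b)
  expect_equal(lo$U, 0)
})

test_that("exact and asymptotic p agree within 0.05 on small tie-free samples", {
  set.seed(31)
  for (rep in 1:30) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    x <- sample(1:10000, n1 + n2)
    a <- x[seq_len(n1)]
    b <- x[-seq_len(n1)]
    pe <- mann_whitney(a, b, method = "exact")$p_two_sided
    pa <- mann_whitney(a, b, method = "asymptotic")$p_two_sided
    expect_lt(abs(pe - pa), 0.05)
  }
})

test_that("the settlement comparison reproduces the published significance pattern", {
  # population basis: physicians significant at 0.05, the others not
  p_pop <- sapply(resource_kinds, function(res) {
    compare_settlement_groups(mn, res, "population")$p_two_sided
  })
  expect_lt(p_pop[["physicians"]], 0.05)
  expect_gte(p_pop[["nurses"]], 0.05)
  expect_gte(p_pop[["hospital_beds"]], 0.05)
  expect_equal(round_half_up(p_pop[["physicians"]], 2), 0.04)

  # area basis: complete separation, all three share p ~ 0.007
  for (res in resource_kinds) {
    r <- compare_settlement_groups(mn, res, "area")
    expect_identical(c(r$n1, r$n2), c(3L, 19L))
    expect_equal(r$U, 57) # urban+suburban win every pair
    expect_lt(r$p_two_sided, 0.01)
    expect_equal(round_half_up(r$p_two_sided, 3), 0.007)
  }

  all_rural <- toy_table(c(100, 200, 300), c(100, 200, 300), c(1, 2, 3))
  expect_error(compare_settlement_groups(all_rural, "physicians", "area"),
               "no urban")
  all_urban <- toy_table(c(1000, 2000), c(1, 2), c(1, 2))
  expect_error(compare_settlement_groups(all_urban, "physicians", "area"),
               "no rural")
})
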
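mn <- load_mongolia_2014()

test_that("Lorenz curves satisfy their geometric invariants on random tables", {
  for (seed in 1:6) {
    tbl <- generate_table(synthetic_spec(n_regions = 8, seed = seed,
                                         density_sdlog = 0.8))
    for (b in basis_kinds) {
      cv <- build_lorenz(tbl, "physicians", b)
      expect_identical(c(cv$p[1], cv$q[1]), c(0, 0))
      expect_identical(c(cv$p[nrow(cv)], cv$q[nrow(cv)]), c(1, 1))
      expect_true(all(diff(cv$p) >= 0) && all(diff(cv$q) >= 0))
      slopes <- diff(cv$q) / diff(cv$p)
      expect_true(all(diff(slopes) >= -1e-9))
    }
  }
})

test_that("degenerate and extreme curves behave as the geometry dictates", {
  # all regions share one density: the curve lies on the diagonal
  eq <- toy_table(c(100, 300, 600), c(1, 3, 6), c(10, 30, 60))
  cv <- build_lorenz(eq, "physicians", "population")
  expect_equal(cv$p, cv$q)
  expect_equal(gini_trapezoid(cv)$coefficient, 0)

  # two regions, weights (9, 1), counts (0, 10): full concentration shape
  conc <- toy_table(c(9, 1), c(9, 1), c(0, 10))
  cv2 <- build_lorenz(conc, "physicians", "population")
  expect_equal(cv2$p, c(0, 0.9, 1))
  expect_equal(cv2$q, c(0, 0, 1))

  allz <- toy_table(c(10, 10), c(1, 1), c(0, 0), nurses = c(1, 1))
  expect_error(build_lorenz(allz, "physicians", "population"), "degenerate")
})

test_that("the fixture's population-basis physician curve puts the capital last", {
  cv <- build_lorenz(mn, "physicians", "population")
  expect_identical(cv$region[nrow(cv)], "Ulaanbaatar")
  # pre-terminal point: everything except the capital
  p_pre <- cv$p[nrow(cv) - 1]
  q_pre <- cv$q[nrow(cv) - 1]
  expect_equal(p_pre, (2995949 - 1362974) / 2995949, tolerance = 1e-12)
  expect_equal(q_pre, (9364 - 5779) / 9364, tolerance = 1e-12)
})

test_that("the grouped formula hits its closed forms for equality and concentration", {
  # one group of equal units: coefficient exactly 0
  expect_equal(gini_grouped(1000, 3.7)$coefficient, 0)
  expect_equal(gini_grouped(c(10, 20, 70), c(5, 5, 5))$coefficient, 0)
  # S = 2, f = (n-1, 1), x = (0, T): coefficient exactly 1
  expect_equal(gini_grouped(c(99, 1), c(0, 42))$coefficient, 1)
  expect_error(gini_grouped(c(1, 1), c(0, 0)), "undefined")
  expect_error(gini_grouped(0.4, 1), "exceed 1")
})

test_that("trapezoid and grouped formula agree to 1/n, and to >=5 decimals on the fixture", {
  for (seed in 1:10) {
    tbl <- generate_table(synthetic_spec(n_regions = 7, seed = seed,
                                         total_population = 5000,
                                         density_sdlog = 0.7))
    g_t <- gini_coefficient(tbl, "physicians", "population",
                            "trapezoid")$coefficient
    g_g <- gini_coefficient(tbl, "physicians", "population",
                            "grouped_formula")$coefficient
    expect_lt(abs(g_t - g_g), 1 / sum(tbl$population))
  }
  for (res in resource_kinds) {
    for (b in basis_kinds) {
      g_t <- gini_coefficient(mn, res, b, "trapezoid")$coefficient
      g_g <- gini_coefficient(mn, res, b, "grouped_formula")$coefficient
      expect_lt(abs(g_t - g_g), 1e-5)
    }
  }
})

test_that("brute-force oracle matches its enumerable cases and bounds the estimators", {
  expect_equal(gini_oracle(c(1, 1, 1), c(5, 5, 5))$coefficient, 0)
  expect_equal(gini_oracle(c(1, 1, 1, 1), c(0, 0, 0, 7))$coefficient, 0.75)
  expect_error(gini_oracle(c(1e5, 1e5), c(1, 2)), "too large")
  expect_error(gini_oracle(c(1.5, 2), c(1, 2)), "integer")

  set.seed(11)
  for (rep in 1:25) {
    w <- sample(1:20, 5, replace = TRUE)
    a <- sample(0:30, 5, replace = TRUE)
    if (sum(a) == 0) a[1] <- 1
    tbl <- toy_table(w * 100, w, a) # population = 100 persons per unit
    g_t <- gini_coefficient(tbl, "physicians", "population",
                            "trapezoid")$coefficient
    g_o <- gini_oracle(w, a)$coefficient
    expect_lt(abs(g_t - g_o), 1 / sum(w))
  }
})

test_that("coefficients are permutation-, tie-order- and scale-invariant and lie in [0,1]", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:9, 1)
    tbl <- toy_table(sample(50:500, n), stats::runif(n, 1, 100),
                     sample(0:40, n, replace = TRUE), nurses = rep(1, n))
    if (sum(tbl$physicians) == 0) next
    g <- gini_coefficient(tbl, "physicians", "population")$coefficient
    expect_gte(g, 0)
    expect_lte(g, 1)

    perm <- sample(n)
    shuf <- region_table(as.data.frame(tbl)[perm, ])
    expect_equal(
      gini_coefficient(shuf, "physicians", "population")$coefficient, g)

    scaled <- toy_table(tbl$population, tbl$area_km2, tbl$physicians * 3,
                        nurses = rep(1, n))
    expect_equal(
      gini_coefficient(scaled, "physicians", "population")$coefficient, g)
    wscaled <- toy_table(tbl$population * 5, tbl$area_km2, tbl$physicians,
                         nurses = rep(1, n))
    expect_equal(
      gini_coefficient(wscaled, "physicians", "population")$coefficient, g)
  }

  # tied densities: region order within the tie cannot change the coefficient
  tie_a <- toy_table(c(100, 100, 50), c(1, 1, 1), c(10, 10, 20),
                     names = c("aa", "bb", "cc"))
  tie_b <- toy_table(c(100, 100, 50), c(1, 1, 1), c(10, 10, 20),
                     names = c("bb", "aa", "cc"))
  expect_equal(gini_coefficient(tie_a, "physicians", "population")$coefficient,
               gini_coefficient(tie_b, "physicians", "population")$coefficient)
})

test_that("moving resource from the poorest-density to the richest-density region never lowers the Gini", {
  set.seed(21)
  for (rep in 1:10) {
    tbl <- toy_table(c(200, 300, 400), c(2, 3, 4),
                     sample(5:30, 3, replace = TRUE))
    dens <- tbl$physicians / tbl$population
    lo <- which.min(dens)
    hi <- which.max(dens)
    if (lo == hi || tbl$physicians[lo] == 0) next
    g0 <- gini_coefficient(tbl, "physicians", "population")$coefficient
    moved <- tbl$physicians
    moved[lo] <- moved[lo] - 1
    moved[hi] <- moved[hi] + 1
    tbl2 <- toy_table(tbl$population, tbl$area_km2, moved)
    g1 <- gini_coefficient(tbl2, "physicians", "population")$coefficient
    expect_gte(g1, g0 - 1e-12)
  }
})
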
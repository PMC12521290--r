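test_that("Mann-Whitney U matches the exhaustive permutation oracle", {
  cases <- list(list(a = c(1, 2, 3), b = c(4, 5, 6)),
                list(a = c(1.5, 2.2, 9.1, 4.4), b = c(3.3, 0.7, 5.5)),
                list(a = c(10, 20), b = c(5, 15, 25, 35, 45)),
                list(a = c(-1, 4, 2.5, 8, 12), b = c(0.5, 3, 7)))
  for (cs in cases) {
    r <- mann_whitney_u(cs$a, cs$b)
    o <- enumerate_mwu(cs$a, cs$b)
    expect_equal(unname(r$statistic), o$u)
    expect_equal(r$p_value, o$p, tolerance = 1e-12)
  }
  # the canonical fully separated case
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)

  # identical samples (ties force the asymptotic path)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)
  expect_error(mann_whitney_u(c(2, 2), c(2, 2)), "constant")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney U detects a two-sigma shift at n = 50", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    a <- rnorm(50)
    b <- rnorm(50, mean = 2)
    if (mann_whitney_u(a, b)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("chi-square rate comparison matches the closed form", {
  r <- chi_square_fit_rates(c(10, 0), c(10, 10))
  expect_equal(unname(r$statistic), 20)
  expect_lt(r$p_value, 0.001)

  # closed form sum((O-E)^2 / E) on a generic table
  r2 <- chi_square_fit_rates(c(7, 3), c(12, 11))
  tab <- rbind(c(7, 5), c(3, 8))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(unname(r2$statistic), sum((tab - E)^2 / E), tolerance = 1e-12)

  # equal rates: statistic 0, p 1
  r3 <- chi_square_fit_rates(c(5, 5), c(10, 10))
  expect_equal(unname(r3$statistic), 0)
  expect_equal(r3$p_value, 1.0)

  # symmetric under swapping groups
  r4 <- chi_square_fit_rates(c(3, 7), c(11, 12))
  r5 <- chi_square_fit_rates(c(7, 3), c(12, 11))
  expect_equal(r4$statistic, r5$statistic, tolerance = 1e-12)

  expect_error(chi_square_fit_rates(c(0, 0), c(10, 10)), "expected cell")
  expect_error(chi_square_fit_rates(c(11, 0), c(10, 10)), "between 0")
})

test_that("Spearman correlation equals rank-then-Pearson", {
  expect_equal(unname(spearman_rho(1:10, (1:10)^3)$statistic), 1.0)
  expect_equal(unname(spearman_rho(1:10, -(1:10))$statistic), -1.0)

  set.seed(30)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  r <- spearman_rho(x, y)
  expect_equal(unname(r$statistic), cor(rank(x), rank(y)), tolerance = 1e-12)
  # t-approximation p-value oracle
  n <- 30
  tt <- r$statistic * sqrt((n - 2) / (1 - r$statistic^2))
  expect_equal(r$p_value, 2 * pt(-abs(tt), n - 2), tolerance = 1e-12)

  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("cohort tables are internally consistent", {
  co <- sample_cohort(seed = 10, mesh = FALSE)
  md <- co$metadata
  set.seed(99)
  fs <- data.frame(id = md$id, ethnicity = md$ethnicity, sex = md$sex,
                   c1_mean = runif(nrow(md), 0.3, 2.5),
                   c2_mean = runif(nrow(md), 0.8, 3.5),
                   c3_mean = runif(nrow(md), 1.5, 7),
                   c1_pass = runif(nrow(md)) < 0.5,
                   c2_pass = runif(nrow(md)) < 0.1,
                   c3_pass = runif(nrow(md)) < 0.03)
  fs$overall_fit <- fs$c1_pass & fs$c2_pass & fs$c3_pass
  tb <- make_tables(md, fs)
  expect_named(tb, c("descriptive", "descriptive_tests", "fit", "fit_tests"))

  # stratum sizes sum to the cohort per ethnicity (the 'both x all' rows)
  top <- tb$descriptive[tb$descriptive$age_group == "both" &
                        tb$descriptive$sex == "all", ]
  expect_equal(sum(top$n), nrow(md))

  # percentages in range, and counts reconstructable from them
  ft <- tb$fit
  for (cr in c("c1", "c2", "c3")) {
    pct <- ft[[paste0(cr, "_satisfied_pct")]]
    n <- ft$n
    cnt <- ft[[paste0(cr, "_satisfied_n")]]
    ok <- n > 0
    expect_true(all(pct[ok] >= 0 & pct[ok] <= 100))
    expect_equal(round(n[ok] * pct[ok] / 100), cnt[ok], ignore_attr = TRUE)
  }

  # a single-subject stratum reports a blank (NA) SD
  md1 <- md[1, , drop = FALSE]
  tb1 <- make_tables(md1)
  row <- tb1$descriptive[tb1$descriptive$n == 1, ][1, ]
  expect_true(is.na(row$height_sd))
  # empty strata rows are emitted with n = 0 and blank statistics
  empty <- tb1$descriptive[tb1$descriptive$n == 0, ]
  expect_gt(nrow(empty), 0)
  expect_true(all(is.na(empty$height_median)))
})
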
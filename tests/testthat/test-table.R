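test_that("table percentages and running sums match hand computation", {
  r <- records_with_wealth_counts(c(4, 2, 1, 1))
  tab <- build_concentration_table(r, "exposure_tobacco", "wealth")
  expect_equal(tab$y$pct, c(50, 25, 12.5, 12.5))
  expect_equal(tab$y$cumpct, c(50, 75, 87.5, 100))
  expect_equal(tab$y$freq, c(4, 2, 1, 1))
  expect_identical(tab$n, 8L)
  expect_equal(tab$n_effective, 8)
})

test_that("cumulative columns always end at 100 and pct sums to 100", {
  for (s in c(2, 5, 8)) {
    withr::local_seed(s)
    r <- generate_survey(builtin_scenario("alcohol", n = 50 * s, seed = s))
    tab <- build_concentration_table(r, "exposure_alcohol", "wealth")
    for (side in list(tab$x, tab$y)) {
      expect_equal(sum(side$pct), 100)
      expect_equal(side$cumpct[length(side$cumpct)], 100)
      expect_true(all(diff(side$cumpct) >= -1e-9))
    }
  }
})

test_that("frequencies are weight sums and shares are scale-invariant", {
  r <- generate_survey(builtin_scenario("diet", n = 120, seed = 6))
  r$weight <- runif(120, 0.5, 3)
  tab1 <- build_concentration_table(r, "exposure_diet", "wealth")
  r2 <- r; r2$weight <- 2 * r2$weight
  tab2 <- build_concentration_table(r2, "exposure_diet", "wealth")
  expect_equal(tab2$x$freq, 2 * tab1$x$freq)
  expect_equal(tab2$x$pct, tab1$x$pct)
  expect_equal(tab2$x$cumpct, tab1$x$cumpct)
  expect_equal(tab2$y$pct, tab1$y$pct)
  expect_equal(sum(tab1$x$freq), sum(r$weight))
})

test_that("empty ranks are kept with zero frequency", {
  r <- records_with_wealth_counts(c(5, 0, 0, 3))
  tab <- build_concentration_table(r, "exposure_tobacco", "wealth")
  expect_equal(tab$y$freq, c(5, 0, 0, 3))
  expect_equal(tab$y$cumpct, c(62.5, 62.5, 62.5, 100))
})

test_that("degenerate inputs are rejected with explicit errors", {
  r <- records_with_wealth_counts(c(1, 1, 1, 1))
  expect_error(build_concentration_table(r[0, ], "exposure_tobacco", "wealth"),
               "zero records")
  expect_error(build_concentration_table(r, "exposure_smoking", "wealth"),
               "unknown variable")
  r$exposure_tobacco[2] <- NA
  expect_error(build_concentration_table(r, "exposure_tobacco", "wealth"),
               "missing")
})

test_that("the flat export mirrors the side-by-side table layout", {
  r <- records_with_wealth_counts(c(4, 2, 1, 1))
  tab <- build_concentration_table(r, "exposure_alcohol", "wealth")
  flat <- as.data.frame(tab)
  expect_identical(names(flat),
                   c("x_label", "x_freq", "x_pct", "x_cumpct",
                     "y_label", "y_freq", "y_pct", "y_cumpct"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_concentration_table(tab, path)
  back <- utils::read.csv(path)
  expect_equal(back$y_cumpct, c(50, 75, 87.5, 100))
})
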
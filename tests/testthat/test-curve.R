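test_that("the equality line is its own fixed point of every summary", {
  eq <- equality_line()
  expect_equal(eq$p, c(0, 25, 50, 75, 100))
  expect_equal(eq$L, eq$p)
  expect_equal(concentration_index(eq), 0)
  expect_equal(max_deviation(eq), 0)
  for (tol in c(0, 0.5, 5)) {
    expect_identical(classify_dominance(eq, tol), "on_equality")
  }
})

test_that("the extreme-concentration triangle has known summaries", {
  crv <- concentration_curve_points(c(0, 50, 100), c(0, 0, 100))
  expect_equal(concentration_index(crv), 0.5)
  expect_equal(max_deviation(crv), 50)
  expect_identical(classify_dominance(crv, 1), "below")
})

test_that("curve invariants are enforced at construction", {
  expect_error(concentration_curve_points(c(5, 100), c(0, 100)), "start")
  expect_error(concentration_curve_points(c(0, 99), c(0, 100)), "end")
  expect_error(concentration_curve_points(c(0, 60, 50, 100),
                                          c(0, 10, 20, 100)),
               "strictly increasing")
  expect_error(concentration_curve_points(c(0, 40, 100), c(0, 50, 40)),
               "must end at")
  expect_error(concentration_curve_points(c(0, 30, 60, 100),
                                          c(0, 50, 40, 100)),
               "nondecreasing")
})

test_that("paper-mode vertices equal the independent pairing oracle", {
  withr::local_seed(20)
  for (case in 1:100) {
    kx <- sample(2:6, 1)
    rr <- random_ranked_records(n = 60, kx = kx, ky = kx)
    tab <- build_concentration_table(rr$records, "xvar", "yvar",
                                     x_spec = rr$x_spec, y_spec = rr$y_spec)
    got <- as.data.frame(concentration_curve(tab, mode = "paper"))
    want <- oracle_paper_vertices(rr$records, rr$x_spec, rr$y_spec)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$L, want$L, tolerance = 1e-12)
  }
})

test_that("paper-mode pairing direct example matches rank-by-rank pairing", {
  # marginal cum% pairs straight into vertices
  r <- records_with_wealth_counts(c(4, 2, 1, 1))  # y cum: 50,75,87.5,100
  r$exposure_alcohol <- rep(exposure_levels(), each = 2)  # x cum: 25,50,75,100
  crv <- concentration_curve(
    build_concentration_table(r, "exposure_alcohol", "wealth"), "paper")
  expect_equal(crv$p, c(0, 25, 50, 75, 100))
  expect_equal(crv$L, c(0, 50, 75, 87.5, 100))
})

test_that("index respects bounds and the reflection sign symmetry", {
  withr::local_seed(21)
  for (case in 1:1000) {
    crv <- random_curve()
    idx <- concentration_index(crv)
    expect_gte(idx, -1); expect_lte(idx, 1)
    expect_gte(max_deviation(crv), 0)
    expect_lte(max_deviation(crv), 100)
  }
  # reflecting across the 45-degree line (swap axes) negates the index;
  # needs strictly increasing L so the reflection is itself a curve
  for (case in 1:50) {
    k <- sample(2:6, 1)
    p <- c(0, sort(runif(k, 1, 99)), 100)
    L <- c(0, sort(runif(k, 1, 99)), 100)
    a <- concentration_curve_points(p, L)
    b <- concentration_curve_points(L, p)
    expect_equal(concentration_index(a), -concentration_index(b),
                 tolerance = 1e-12)
  }
})

test_that("max deviation is invariant to inserting collinear points", {
  crv <- concentration_curve_points(c(0, 50, 100), c(0, 0, 100))
  fine <- concentration_curve_points(c(0, 25, 50, 75, 100),
                                     c(0, 0, 0, 50, 100))
  expect_equal(max_deviation(fine), max_deviation(crv))
  expect_equal(concentration_index(fine), concentration_index(crv))
})

test_that("dominance classes cover both one-sided and crossing geometry", {
  above <- concentration_curve_points(c(0, 50, 100), c(0, 55, 100))
  expect_identical(classify_dominance(above, 1), "above")
  crossing <- concentration_curve_points(c(0, 30, 70, 100),
                                         c(0, 35, 65, 100))
  expect_identical(classify_dominance(crossing, 1), "crossing")
  # within-band wiggles collapse to on_equality
  near <- concentration_curve_points(c(0, 30, 70, 100),
                                     c(0, 30.5, 69.5, 100))
  expect_identical(classify_dominance(near, 1), "on_equality")
})

test_that("standard-mode curve sits on the diagonal under independence", {
  r <- generate_survey(builtin_scenario("independent", n = 20000, seed = 3))
  tab <- build_concentration_table(r, "exposure_alcohol", "wealth")
  crv <- concentration_curve(tab, mode = "standard")
  expect_lt(max_deviation(crv), 2)
})

test_that("standard mode requires record provenance; paper needs equal ranks", {
  r <- generate_survey(builtin_scenario("alcohol", n = 100, seed = 2))
  tab <- build_concentration_table(r, "exposure_alcohol", "wealth")
  tab$records <- NULL
  expect_error(concentration_curve(tab, "standard"), "provenance")
  tab$x <- tab$x[1:3, ]
  expect_error(concentration_curve(tab, "paper"), "equally many")
})

test_that("reversing the X rank order negates the standard-mode index exactly", {
  r <- generate_survey(builtin_scenario("inactivity", n = 2000, seed = 8))
  x_spec <- default_spec("exposure_inactivity")
  rev_spec <- ordered_category_spec(rev(x_spec$labels))
  fwd <- concentration_curve(build_concentration_table(
    r, "exposure_inactivity", "wealth", x_spec = x_spec), "standard")
  bwd <- concentration_curve(build_concentration_table(
    r, "exposure_inactivity", "wealth", x_spec = rev_spec), "standard")
  expect_equal(concentration_index(fwd), -concentration_index(bwd),
               tolerance = 1e-12)
})
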
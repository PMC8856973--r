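test_that("age filter keeps exactly the records at or above the floor", {
  empty <- generate_survey(builtin_scenario("independent", n = 1))[0, ]
  expect_identical(nrow(filter_records(empty, 30, quiet = TRUE)), 0L)

  r <- generate_survey(builtin_scenario("independent", n = 10, seed = 2))
  r$age <- seq(25, 70, by = 5)
  out <- filter_records(r, 30, quiet = TRUE)
  expect_identical(nrow(out), 9L)
  expect_identical(out$id, r$id[r$age >= 30])
  expect_identical(attr(out, "audit"),
                   list(input_n = 10L, removed_age = 1L,
                        removed_missing = 0L, output_n = 9L))
})

test_that("per-factor missingness is dropped with a reconciling audit", {
  r <- generate_survey(builtin_scenario("independent", n = 100, seed = 4))
  r$exposure_alcohol[sample.int(100, 13)] <- NA
  out <- filter_records(r, 0, "alcohol", quiet = TRUE)
  expect_identical(nrow(out), 87L)
  a <- attr(out, "audit")
  expect_identical(a$input_n, a$output_n + a$removed_age + a$removed_missing)
  # the same record still enters another factor's analysis
  expect_identical(nrow(filter_records(r, 0, "tobacco", quiet = TRUE)), 100L)
  expect_error(filter_records(r, 0, "smoking"), "unknown risk factor")
})

test_that("filtering is idempotent and order-preserving", {
  withr::local_seed(5)
  r <- generate_survey(builtin_scenario("diet", n = 200, seed = 5))
  r$age <- sample(20:80, 200, replace = TRUE)
  r$exposure_diet[sample.int(200, 17)] <- NA
  once <- filter_records(r, 30, "diet", quiet = TRUE)
  twice <- filter_records(once, 30, "diet", quiet = TRUE)
  attr(once, "audit") <- attr(twice, "audit") <- NULL
  expect_identical(once, twice)
  a2 <- attr(filter_records(once, 30, "diet", quiet = TRUE), "audit")
  expect_identical(a2$removed_age + a2$removed_missing, 0L)
  expect_false(is.unsorted(match(once$id, r$id)))
})

test_that("rank weights follow the 25/50/75/100 assignment", {
  r <- records_with_wealth_counts(c(1, 1, 1, 1))
  out <- assign_rank_weights(r, "wealth")
  expect_identical(out$rank[out$wealth == "poor"], 1L)
  expect_identical(out$cum_weight[out$wealth == "poor"], 25)
  expect_identical(out$cum_weight[out$wealth == "richest"], 100)

  r$exposure_alcohol <- "most_exposed"
  out <- assign_rank_weights(r, "exposure_alcohol")
  expect_true(all(out$rank == 4L & out$cum_weight == 100))

  # annotation adds columns without touching n or existing fields
  expect_identical(nrow(out), nrow(r))
  expect_identical(out[names(r)], r)

  r$wealth[2] <- "middle_class"
  expect_error(assign_rank_weights(r, "wealth"), "w002.*middle_class")
})

test_that("continuous income is cut at weighted quartiles", {
  expect_identical(wealth_from_income(1:8),
                   rep(wealth_levels(), each = 2))
  # weights shift the cut points: a half-mass lowest income already fills
  # the poor and rich quarters, pushing every later record upward
  w <- c(3, 1, 1, 1)
  expect_identical(wealth_from_income(c(1, 2, 3, 4), w),
                   c("rich", "richer", "richest", "richest"))
  # order of input does not matter
  inc <- c(10, 2, 7, 1, 9, 5, 3, 8)
  expect_identical(wealth_from_income(inc),
                   wealth_from_income(rev(inc))[match(inc, rev(inc))])
})

test_that("CSV records round-trip and malformed files fail with row context", {
  r <- generate_survey(builtin_scenario("tobacco", n = 50, seed = 9))
  r$exposure_diet[c(3, 7)] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(r, path)
  expect_identical(read_records(path), r)

  truncated <- withr::local_tempfile(fileext = ".csv")
  tab <- utils::read.csv(path)
  utils::write.csv(tab[, setdiff(names(tab), "wealth")], truncated,
                   row.names = FALSE)
  expect_error(read_records(truncated), "wealth")

  bad_age <- withr::local_tempfile(fileext = ".csv")
  tab2 <- utils::read.csv(path, colClasses = "character")
  tab2$age[7] <- "abc"
  utils::write.csv(tab2, bad_age, row.names = FALSE)
  expect_error(read_records(bad_age), "row 7.*abc")

  bad_wt <- withr::local_tempfile(fileext = ".csv")
  tab2 <- utils::read.csv(path, colClasses = "character")
  tab2$weight[5] <- "-1"
  utils::write.csv(tab2, bad_wt, row.names = FALSE)
  expect_error(read_records(bad_wt), "row 5.*negative weight")

  expect_error(read_records(withr::local_tempfile(fileext = ".csv")),
               "does not exist")
})
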
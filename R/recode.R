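#' Filter survey records by age and per-factor completeness
#'
#' Applies the study's inclusion rules in a stated order: first the age
#' floor (`age >= min_age`), then — when `required_factor` is given — removal
#' of records missing that factor's exposure value. Record order is preserved
#' and a filter audit (input n, removed by age, removed by missingness,
#' output n) is attached as the `"audit"` attribute and narrated via
#' [message()]. Missingness is judged per factor, so a respondent can enter
#' one factor's analysis while being excluded from another's.
#'
#' @param records Survey record data.frame.
#' @param min_age Minimum age in years (default 30, the study's adult floor).
#' @param required_factor Optional risk factor name; records with a missing
#'   exposure value for this factor are dropped.
#' @param quiet Suppress the audit message.
#' @return The filtered records with attribute `audit`, a list with elements
#'   `input_n`, `removed_age`, `removed_missing`, `output_n` satisfying
#'   `input_n = output_n + removed_age + removed_missing`.
#' @export
filter_records <- function(records, min_age = 30, required_factor = NULL,
                           quiet = FALSE) {
  stopifnot(is.numeric(min_age), length(min_age) == 1L, min_age >= 0)
  records <- as.data.frame(records)
  input_n <- nrow(records)
  keep_age <- records$age >= min_age
  out <- records[keep_age, , drop = FALSE]
  removed_missing <- 0L
  if (!is.null(required_factor)) {
    check_factor(required_factor)
    present <- !is.na(out[[exposure_column(required_factor)]])
    removed_missing <- sum(!present)
    out <- out[present, , drop = FALSE]
  }
  audit <- list(input_n = input_n,
                removed_age = sum(!keep_age),
                removed_missing = removed_missing,
                output_n = nrow(out))
  if (!quiet) {
    message(sprintf(
      "filter_records: %d in, %d removed by age < %s, %d removed by missing %s, %d out",
      audit$input_n, audit$removed_age, format(min_age),
      audit$removed_missing,
      if (is.null(required_factor)) "(none)" else required_factor,
      audit$output_n))
  }
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Annotate records with rank and cumulative percentage weight
#'
#' Maps one ordered variable onto its rank (1..k) and the cumulative
#' percentage weight of that rank — with the default specs, 25/50/75/100 for
#' poor/rich/richer/richest and likewise for the four exposure levels. The
#' annotation is added as columns `rank` and `cum_weight`; no existing field
#' is modified and no record is dropped.
#'
#' @param records Survey record data.frame.
#' @param variable Column to rank: `"wealth"` or an `exposure_*` column.
#' @param spec An [ordered_category_spec()]; defaults to the variable's
#'   standard spec.
#' @return `records` with added numeric columns `rank` and `cum_weight`.
#' @examples
#' r <- generate_survey(builtin_scenario("independent", n = 5))
#' assign_rank_weights(r, "wealth")[, c("wealth", "rank", "cum_weight")]
#' @export
assign_rank_weights <- function(records, variable,
                                spec = default_spec(variable)) {
  stopifnot(inherits(spec, "ordered_category_spec"))
  records <- as.data.frame(records)
  if (!variable %in% names(records)) {
    stop("variable '", variable, "' is not a record column", call. = FALSE)
  }
  v <- records[[variable]]
  rank <- match(v, spec$labels)
  bad <- which(is.na(rank) & !is.na(v))
  if (length(bad) > 0L) {
    stop("record '", records$id[bad[1L]], "': ", variable, " label '",
         v[bad[1L]], "' is not in the category spec (",
         paste(spec$labels, collapse = ", "), ")", call. = FALSE)
  }
  if (anyNA(rank)) {
    stop("variable '", variable, "' has missing values; filter first",
         call. = FALSE)
  }
  records$rank <- rank
  records$cum_weight <- spec$cum_weights[rank]
  records
}

#' Collapse a continuous income/wealth score into the four wealth categories
#'
#' When records carry a continuous income or asset score instead of wealth
#' labels, the score is cut at its weighted quartiles (lowest quarter =
#' `poor`, then `rich`, `richer`, `richest`), the only four-group rule
#' consistent with assigning each category an equal 25% share.
#'
#' @param income Numeric vector of income/asset scores.
#' @param weight Optional nonnegative sampling weights (default equal).
#' @return Character vector of wealth labels, same length as `income`.
#' @export
wealth_from_income <- function(income, weight = NULL) {
  stopifnot(is.numeric(income), !anyNA(income))
  if (is.null(weight)) weight <- rep(1, length(income))
  stopifnot(length(weight) == length(income), all(weight >= 0))
  ord <- order(income)
  cum <- cumsum(weight[ord]) / sum(weight)
  # left-open so a record sitting exactly on a quartile boundary stays in
  # the lower group (cum share <= 25% means poor)
  grp <- pmin(findInterval(cum, c(0.25, 0.50, 0.75), left.open = TRUE) + 1L,
              4L)
  out <- character(length(income))
  out[ord] <- wealth_levels()[grp]
  out
}
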
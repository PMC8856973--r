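#' Ordered category vocabularies
#'
#' The analysis uses two fixed ordered vocabularies: four wealth categories
#' (`poor < rich < richer < richest`) and, for every risk factor, four ordered
#' exposure categories (`relatively_exposed < exposed < more_exposed <
#' most_exposed`). Each rank carries a cumulative percentage weight, by default
#' 25/50/75/100, so that the four categories partition the percentage scale
#' into equal 25-point steps.
#'
#' @return Character vectors of ordered labels (lowest rank first).
#' @seealso [ordered_category_spec()]
#' @export
wealth_levels <- function() c("poor", "rich", "richer", "richest")

#' @rdname wealth_levels
#' @export
exposure_levels <- function() {
  c("relatively_exposed", "exposed", "more_exposed", "most_exposed")
}

#' @rdname wealth_levels
#' @export
risk_factors <- function() c("alcohol", "tobacco", "diet", "inactivity")

#' Five-category wealth vocabulary
#'
#' DHS wealth indices are conventionally reported in five quintiles; the
#' four-category system is the package default, and this helper provides the
#' standard five-group escape hatch (cumulative weights 20/40/60/80/100).
#'
#' @return An [ordered_category_spec()] with five labels.
#' @export
wealth_levels5 <- function() {
  ordered_category_spec(
    labels = c("poorest", "poorer", "middle", "richer", "richest"),
    cum_weights = c(20, 40, 60, 80, 100)
  )
}

exposure_column <- function(factor) paste0("exposure_", factor)

check_factor <- function(factor) {
  if (!is.character(factor) || length(factor) != 1L ||
      !factor %in% risk_factors()) {
    stop("unknown risk factor: ", deparse(substitute(factor)), " = '",
         paste(factor, collapse = ","), "' (expected one of ",
         paste(risk_factors(), collapse = ", "), ")", call. = FALSE)
  }
  invisible(factor)
}

#' Ordered category specification with cumulative percentage weights
#'
#' An `ordered_category_spec` pairs an ordered label set (rank 1..k) with
#' strictly increasing cumulative percentage weights ending at 100. With the
#' default equal assignment, rank i of k = 4 carries 25 * i percent; these
#' cumulative weights are the rank scores used throughout the concentration
#' analysis.
#'
#' @param labels Character vector of ordered labels, lowest rank first.
#' @param cum_weights Strictly increasing numeric vector of cumulative
#'   percentages, one per label, with final value 100. Defaults to an equal
#'   split (`100 * (1:k) / k`).
#' @return An object of class `ordered_category_spec` with elements `labels`
#'   and `cum_weights`.
#' @examples
#' ordered_category_spec(wealth_levels())
#' @export
ordered_category_spec <- function(labels,
                                  cum_weights = 100 * seq_along(labels) /
                                    length(labels)) {
  labels <- as.character(labels)
  cum_weights <- as.numeric(cum_weights)
  if (length(labels) < 1L || anyDuplicated(labels)) {
    stop("labels must be a non-empty vector of distinct labels", call. = FALSE)
  }
  if (length(cum_weights) != length(labels)) {
    stop("cum_weights must have one entry per label", call. = FALSE)
  }
  if (any(diff(cum_weights) <= 0) || cum_weights[1L] <= 0) {
    stop("cum_weights must be strictly increasing and positive", call. = FALSE)
  }
  if (abs(cum_weights[length(cum_weights)] - 100) > 1e-9) {
    stop("cum_weights must end at 100", call. = FALSE)
  }
  structure(list(labels = labels, cum_weights = cum_weights),
            class = "ordered_category_spec")
}

#' @export
print.ordered_category_spec <- function(x, ...) {
  cat("<ordered_category_spec> ", length(x$labels), " ranks\n", sep = "")
  cat(paste0("  ", seq_along(x$labels), ". ", x$labels,
             " (cum ", x$cum_weights, "%)"), sep = "\n")
  invisible(x)
}

#' Default category specs for the survey variables
#'
#' @param variable `"wealth"` or an exposure column name such as
#'   `"exposure_alcohol"`.
#' @return An [ordered_category_spec()].
#' @export
default_spec <- function(variable) {
  if (identical(variable, "wealth")) {
    ordered_category_spec(wealth_levels())
  } else if (variable %in% exposure_column(risk_factors())) {
    ordered_category_spec(exposure_levels())
  } else {
    stop("no default category spec for variable '", variable, "'",
         call. = FALSE)
  }
}
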
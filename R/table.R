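#' Build a concentration table
#'
#' The concentration table lays the two marginal distributions side by side:
#' for every rank of the exposure variable (X) and of the wealth variable (Y)
#' it records the frequency (sum of sampling weights), the percentage of the
#' total, and the running cumulative percentage — the `Frequency / % / Cum %`
#' layout from which the concentration curve is plotted. Ranks with zero
#' frequency are kept with frequency 0 so the table always has one row per
#' category.
#'
#' @param records Filtered survey records with valid labels for both
#'   variables (no missing values in either column).
#' @param x_variable Exposure column, e.g. `"exposure_alcohol"` (the X axis).
#' @param y_variable Ranking column, normally `"wealth"` (the Y axis).
#' @param x_spec,y_spec [ordered_category_spec()]s; default to each
#'   variable's standard spec.
#' @return An object of class `concentration_table`: a list with data.frames
#'   `x` and `y` (columns `label`, `freq`, `pct`, `cumpct`), the effective
#'   sample size `n_effective` (sum of weights) and record count `n`, the
#'   variable names, and the contributing records (kept for the record-level
#'   `standard` curve mode).
#' @examples
#' r <- generate_survey(builtin_scenario("alcohol", n = 500))
#' r <- filter_records(r, 30, "alcohol", quiet = TRUE)
#' build_concentration_table(r, "exposure_alcohol", "wealth")
#' @export
build_concentration_table <- function(records, x_variable, y_variable,
                                      x_spec = default_spec(x_variable),
                                      y_spec = default_spec(y_variable)) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) {
    stop("cannot build a concentration table from zero records",
         call. = FALSE)
  }
  for (v in c(x_variable, y_variable)) {
    if (!v %in% names(records)) {
      stop("unknown variable '", v, "'", call. = FALSE)
    }
  }
  w <- if ("weight" %in% names(records)) records$weight else rep(1, nrow(records))

  marginal <- function(variable, spec) {
    rank <- match(records[[variable]], spec$labels)
    if (anyNA(rank)) {
      stop("variable '", variable,
           "' has missing or out-of-vocabulary values; filter records first",
           call. = FALSE)
    }
    freq <- vapply(seq_along(spec$labels),
                   function(j) sum(w[rank == j]), numeric(1))
    pct <- 100 * freq / sum(freq)
    data.frame(label = spec$labels, freq = freq, pct = pct,
               cumpct = cumsum(pct), stringsAsFactors = FALSE)
  }

  structure(
    list(x = marginal(x_variable, x_spec),
         y = marginal(y_variable, y_spec),
         n_effective = sum(w),
         n = nrow(records),
         x_variable = x_variable, y_variable = y_variable,
         x_spec = x_spec, y_spec = y_spec,
         records = records),
    class = "concentration_table"
  )
}

#' @export
print.concentration_table <- function(x, digits = 2, ...) {
  cat("<concentration_table> X = ", x$x_variable, ", Y = ", x$y_variable,
      ", n = ", x$n, " (effective ", format(x$n_effective), ")\n", sep = "")
  print(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Flatten a concentration table to the side-by-side layout
#'
#' @param x A `concentration_table`.
#' @param ... Unused.
#' @return A data.frame with columns `x_label,x_freq,x_pct,x_cumpct,
#'   y_label,y_freq,y_pct,y_cumpct`; if the two variables have different
#'   numbers of categories the shorter side is padded with `NA`.
#' @export
as.data.frame.concentration_table <- function(x, ...) {
  k <- max(nrow(x$x), nrow(x$y))
  pad <- function(d) {
    if (nrow(d) < k) {
      d[seq_len(k), ] <- d[c(seq_len(nrow(d)), rep(NA, k - nrow(d))), ]
    }
    d[seq_len(k), , drop = FALSE]
  }
  xb <- pad(x$x); yb <- pad(x$y)
  names(xb) <- paste0("x_", names(xb))
  names(yb) <- paste0("y_", names(yb))
  out <- cbind(xb, yb)
  rownames(out) <- NULL
  out
}

#' Write a concentration table as CSV
#'
#' @param table A `concentration_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(table, path) {
  stopifnot(inherits(table, "concentration_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}
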
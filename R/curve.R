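#' Concentration curve constructor
#'
#' A concentration curve is an ordered sequence of vertices `(p, L)` on the
#' percentage scale, anchored at (0, 0) and (100, 100), with `p` strictly
#' increasing and `L` nondecreasing. Between vertices the curve is piecewise
#' linear, so trapezoid areas are exact for the plotted object.
#'
#' @param p,L Numeric vectors of X- and Y-axis percentages (including the
#'   anchors).
#' @param mode Construction mode label: `"paper"` (marginal rank-by-rank
#'   pairing) or `"standard"` (record-level ranking).
#' @return An object of class `concentration_curve`: a data.frame with
#'   columns `p` and `L` and attribute `mode`.
#' @export
concentration_curve_points <- function(p, L, mode = "paper") {
  p <- as.numeric(p); L <- as.numeric(L)
  if (length(p) != length(L) || length(p) < 2L) {
    stop("a curve needs matched p and L vectors with at least two points",
         call. = FALSE)
  }
  if (abs(p[1L]) > 1e-9 || abs(L[1L]) > 1e-9) {
    stop("curve must start at (0, 0)", call. = FALSE)
  }
  nlast <- length(p)
  if (abs(p[nlast] - 100) > 1e-6 || abs(L[nlast] - 100) > 1e-6) {
    stop("curve must end at (100, 100)", call. = FALSE)
  }
  if (any(diff(p) <= 0)) {
    stop("p must be strictly increasing", call. = FALSE)
  }
  if (any(diff(L) < -1e-9)) {
    stop("L must be nondecreasing", call. = FALSE)
  }
  structure(data.frame(p = p, L = L),
            mode = mode, class = c("concentration_curve", "data.frame"))
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat("<concentration_curve> mode '", attr(x, "mode"), "', ",
      nrow(x), " vertices\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# collapse duplicate p (zero-frequency ranks): keep the largest L at each p,
# except at p = 0 where the curve stays anchored at (0, 0) — Y mass sitting
# at zero X mass is absorbed into the first positive-p segment
dedupe_vertices <- function(p, L) {
  keep <- c(diff(p) > 1e-12, TRUE)
  p <- p[keep]; L <- L[keep]
  if (p[1L] <= 1e-12) L[1L] <- 0
  list(p = p, L = L)
}

#' The 45-degree line of perfect equality
#'
#' The reference curve along which the cumulative percentages of the two
#' variables coincide (`L(p) = p`): the distribution a curve traces when the
#' plotted quantity is spread identically across ranks. Vertices are placed
#' at 0 and at the category system's cumulative weights (default
#' 25/50/75/100).
#'
#' @param cum_weights Vertex positions (percent), default `c(25,50,75,100)`.
#' @return A `concentration_curve` with `L = p`.
#' @examples
#' equality_line()
#' @export
equality_line <- function(cum_weights = c(25, 50, 75, 100)) {
  p <- c(0, cum_weights)
  concentration_curve_points(p, p, mode = "paper")
}

#' Construct the concentration curve from a concentration table
#'
#' Two constructions are offered. In `"paper"` mode the curve pairs the two
#' variables' marginal cumulative percentages rank by rank: vertices are
#' (0, 0) followed by `(x_cumpct_i, y_cumpct_i)` for each rank i. This is the
#' table-level construction but it sees only the marginals, not the joint
#' distribution. In `"standard"` mode records are ranked by the X variable in
#' ascending order (ties pooled within a rank) and `L(p)` is the cumulative
#' share of the Y variable's rank-weight score among the first p% of X-ranked
#' weight — the record-level construction used for the concentration index
#' and all inference, since it reflects the within-sample association.
#'
#' @param table A [build_concentration_table()] result. For `"standard"` mode
#'   the table must carry its contributing records.
#' @param mode `"paper"` or `"standard"`.
#' @return A `concentration_curve`.
#' @examples
#' r <- generate_survey(builtin_scenario("inactivity", n = 1000))
#' tab <- build_concentration_table(r, "exposure_inactivity", "wealth")
#' concentration_curve(tab, mode = "standard")
#' @export
concentration_curve <- function(table, mode = c("paper", "standard")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "concentration_table"))
  if (mode == "paper") {
    if (nrow(table$x) != nrow(table$y)) {
      stop("paper-mode pairing needs equally many X and Y ranks (got ",
           nrow(table$x), " vs ", nrow(table$y), ")", call. = FALSE)
    }
    v <- dedupe_vertices(c(0, table$x$cumpct), c(0, table$y$cumpct))
    concentration_curve_points(v$p, v$L, mode = "paper")
  } else {
    rec <- table$records
    if (is.null(rec)) {
      stop("standard mode needs record-level provenance; ",
           "build the table from records", call. = FALSE)
    }
    xr <- match(rec[[table$x_variable]], table$x_spec$labels)
    ys <- table$y_spec$cum_weights[match(rec[[table$y_variable]],
                                         table$y_spec$labels)]
    w <- if ("weight" %in% names(rec)) rec$weight else rep(1, nrow(rec))
    standard_curve(xr, ys, w)
  }
}

# record-level curve: rank by x ascending, accumulate weight share (p) and
# weighted y-score share (L); ranks pooled, zero-weight ranks dropped
standard_curve <- function(x_rank, y_score, weight) {
  m <- rowsum(cbind(weight, weight * y_score), group = x_rank)
  p <- 100 * cumsum(m[, 1L]) / sum(m[, 1L])
  L <- 100 * cumsum(m[, 2L]) / sum(m[, 2L])
  v <- dedupe_vertices(c(0, p), c(0, L))
  # guard against accumulated floating error at the top anchor
  v$p[length(v$p)] <- 100
  v$L[length(v$L)] <- 100
  concentration_curve_points(v$p, v$L, mode = "standard")
}

#' Concentration index of a curve
#'
#' Twice the signed area between the 45-degree equality line and the curve:
#' `index = 1 - 2A`, where A is the trapezoid-rule area under the curve with
#' both axes rescaled to \[0, 1\]. The curve is piecewise linear, so the
#' trapezoid rule is exact. The index lies in \[-1, 1\], is 0 on the equality
#' line, and is positive when the curve lies below the line — with wealth on
#' the Y axis and exposure on the X axis, a positive index means exposure is
#' concentrated among the higher wealth categories.
#'
#' @param curve A `concentration_curve`.
#' @return A scalar in \[-1, 1\].
#' @examples
#' concentration_index(equality_line())
#' @export
concentration_index <- function(curve) {
  stopifnot(inherits(curve, "concentration_curve"))
  p <- curve$p / 100
  L <- curve$L / 100
  a <- sum(diff(p) * (utils::head(L, -1) + utils::tail(L, -1)) / 2)
  1 - 2 * a
}

#' Maximum absolute deviation from the equality line
#'
#' The largest vertical gap `|L(p) - p|`, in percentage points, over the
#' curve's vertices. For a piecewise-linear curve the maximum over vertices
#' is the maximum over the whole curve, and inserting collinear points cannot
#' change it.
#'
#' @param curve A `concentration_curve`.
#' @return Deviation in percentage points, in \[0, 100\].
#' @export
max_deviation <- function(curve) {
  stopifnot(inherits(curve, "concentration_curve"))
  max(abs(curve$L - curve$p))
}

#' Classify a curve's dominance against the equality line
#'
#' Within a tolerance band (in percentage points) around the 45-degree line,
#' a curve is `on_equality` if every vertex deviation lies inside the band,
#' `above`/`below` if it leaves the band on one side only, and `crossing` if
#' it leaves it on both sides.
#'
#' @param curve A `concentration_curve`.
#' @param tolerance Band half-width in percentage points (default 1, the
#'   smallest visually resolvable gap on a standard-size curve plot).
#' @return One of `"on_equality"`, `"above"`, `"below"`, `"crossing"`.
#' @export
classify_dominance <- function(curve, tolerance = 1) {
  stopifnot(inherits(curve, "concentration_curve"),
            is.numeric(tolerance), tolerance >= 0)
  dev <- curve$L - curve$p
  up <- any(dev > tolerance)
  down <- any(dev < -tolerance)
  if (!up && !down) "on_equality"
  else if (up && !down) "above"
  else if (down && !up) "below"
  else "crossing"
}

#' Scalar summary of a concentration curve
#'
#' @param curve A `concentration_curve`.
#' @param tolerance Dominance tolerance in percentage points.
#' @param n Number of contributing records (if known).
#' @param bootstrap_interval Optional length-2 percentile interval for the
#'   index.
#' @return An object of class `curve_summary`: a list with
#'   `concentration_index`, `max_abs_deviation`, `dominance`, `n`,
#'   `bootstrap_interval`, `tolerance`, and the curve `mode`.
#' @export
summarize_curve <- function(curve, tolerance = 1, n = NA_integer_,
                            bootstrap_interval = NULL) {
  structure(
    list(concentration_index = concentration_index(curve),
         max_abs_deviation = max_deviation(curve),
         dominance = classify_dominance(curve, tolerance),
         n = n,
         bootstrap_interval = bootstrap_interval,
         tolerance = tolerance,
         mode = attr(curve, "mode")),
    class = "curve_summary"
  )
}

#' @export
print.curve_summary <- function(x, ...) {
  cat("<curve_summary> mode '", x$mode, "', n = ", x$n, "\n", sep = "")
  cat(sprintf("  concentration index : %+.4f\n", x$concentration_index))
  if (!is.null(x$bootstrap_interval)) {
    cat(sprintf("  95%% bootstrap CI    : [%+.4f, %+.4f]\n",
                x$bootstrap_interval[1L], x$bootstrap_interval[2L]))
  }
  cat(sprintf("  max |L(p) - p|      : %.2f pp\n", x$max_abs_deviation))
  cat(sprintf("  dominance           : %s (tolerance %.2g pp)\n",
              x$dominance, x$tolerance))
  invisible(x)
}

#' Write a curve or summary to disk
#'
#' The curve is exported as a two-column CSV (`p,L`); the summary as JSON
#' with all its fields.
#'
#' @param curve A `concentration_curve`.
#' @param summary A `curve_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "concentration_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
write_curve_summary <- function(summary, path) {
  stopifnot(inherits(summary, "curve_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
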
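#' Bootstrap percentile interval for the concentration index
#'
#' Resamples records with replacement B times, recomputes the concentration
#' index on each replicate, and reports the 2.5%/97.5% percentile interval
#' alongside the full-sample summary. Degenerate replicates (all records in
#' one X category) contribute their defined index (0, the two-anchor curve)
#' rather than failing. The draw is fully determined by `seed`.
#'
#' @param records Filtered survey records with valid labels for both
#'   variables.
#' @param x_variable,y_variable Columns as in [build_concentration_table()].
#' @param mode Curve construction mode; `"standard"` (default) is the
#'   record-level construction appropriate for inference.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param tolerance Dominance tolerance in percentage points.
#' @param x_spec,y_spec Category specs; default to each variable's standard
#'   spec.
#' @return A [summarize_curve()] `curve_summary` for the full sample, with
#'   `bootstrap_interval` set and the replicate indices attached as attribute
#'   `"replicates"`.
#' @examples
#' r <- generate_survey(builtin_scenario("independent", n = 300))
#' bootstrap_index(r, "exposure_alcohol", "wealth", B = 50, seed = 1)
#' @export
bootstrap_index <- function(records, x_variable, y_variable,
                            mode = c("standard", "paper"),
                            B = 200L, seed = 1L, tolerance = 1,
                            x_spec = default_spec(x_variable),
                            y_spec = default_spec(y_variable)) {
  mode <- match.arg(mode)
  records <- as.data.frame(records)
  B <- as.integer(B)
  n <- nrow(records)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (n < 2L) stop("need at least 2 records to bootstrap", call. = FALSE)

  xr <- match(records[[x_variable]], x_spec$labels)
  yr <- match(records[[y_variable]], y_spec$labels)
  if (anyNA(xr) || anyNA(yr)) {
    stop("records contain missing or out-of-vocabulary values for '",
         x_variable, "'/'", y_variable, "'; filter records first",
         call. = FALSE)
  }
  ys <- y_spec$cum_weights[yr]
  w <- if ("weight" %in% names(records)) records$weight else rep(1, n)

  index_of <- function(idx) {
    if (mode == "standard") {
      concentration_index(standard_curve(xr[idx], ys[idx], w[idx]))
    } else {
      paper_index(xr[idx], yr[idx], w[idx],
                  length(x_spec$labels), length(y_spec$labels))
    }
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(B),
                 function(b) index_of(sample.int(n, n, replace = TRUE)),
                 numeric(1))
  ci <- unname(stats::quantile(reps, c(0.025, 0.975), type = 7))

  full <- build_concentration_table(records, x_variable, y_variable,
                                    x_spec = x_spec, y_spec = y_spec)
  out <- summarize_curve(concentration_curve(full, mode = mode),
                         tolerance = tolerance, n = n,
                         bootstrap_interval = ci)
  attr(out, "replicates") <- reps
  out
}

# marginal-pairing index straight from rank vectors (paper mode)
paper_index <- function(x_rank, y_rank, w, kx, ky) {
  if (kx != ky) {
    stop("paper-mode pairing needs equally many X and Y ranks", call. = FALSE)
  }
  fx <- vapply(seq_len(kx), function(j) sum(w[x_rank == j]), numeric(1))
  fy <- vapply(seq_len(ky), function(j) sum(w[y_rank == j]), numeric(1))
  v <- dedupe_vertices(c(0, 100 * cumsum(fx) / sum(fx)),
                       c(0, 100 * cumsum(fy) / sum(fy)))
  concentration_index(concentration_curve_points(v$p, v$L, mode = "paper"))
}
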
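#' Generate a synthetic survey
#'
#' Draws `config$n` respondent records: wealth categories from
#' `quintile_probs`, each exposure column from the row of `exposure_probs`
#' matching the record's wealth category, ages uniform on `age_range`
#' (rounded to whole years), sex 50/50, and unit sampling weights. The draw is
#' fully determined by `config$seed`: the same configuration always yields the
#' identical record set.
#'
#' @param config A [scenario_config()].
#' @return A data.frame of survey records with columns `id`, `age`, `sex`,
#'   `wealth`, `exposure_alcohol`, `exposure_tobacco`, `exposure_diet`,
#'   `exposure_inactivity`, `weight`.
#' @examples
#' head(generate_survey(builtin_scenario("independent", n = 100)))
#' @export
generate_survey <- function(config) {
  if (!inherits(config, "scenario_config")) {
    stop("config must be a scenario_config", call. = FALSE)
  }
  n <- config$n
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  wl <- wealth_levels()
  el <- exposure_levels()
  wealth_idx <- sample.int(length(wl), n, replace = TRUE,
                           prob = config$quintile_probs)
  draw_exposure <- function() {
    # inverse-CDF draw conditional on each record's wealth row
    u <- stats::runif(n)
    cum <- t(apply(config$exposure_probs, 1L, cumsum))
    idx <- rowSums(u > cum[wealth_idx, , drop = FALSE]) + 1L
    el[pmin(idx, length(el))]
  }
  rec <- data.frame(
    id = sprintf("r%05d", seq_len(n)),
    age = round(stats::runif(n, config$age_range[1L], config$age_range[2L])),
    sex = sample(c("female", "male"), n, replace = TRUE),
    wealth = wl[wealth_idx],
    stringsAsFactors = FALSE
  )
  for (f in risk_factors()) rec[[exposure_column(f)]] <- draw_exposure()
  rec$weight <- rep(1, n)
  validate_records(rec)
}
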
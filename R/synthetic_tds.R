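# Synthetic total-diet-study generator.
#
# Emulates the statistical structure a national TDS hands the exposure
# pipeline: a fixed food catalog, heavily left-censored per-analyte
# concentrations with a right-skewed detected tail, and a 24-hour recall
# consumption survey encoded in g per kg body weight.

#' Configuration for the synthetic TDS generator
#'
#' Defaults emulate a national total diet study of 21 food categories spanning
#' 264 foods with two composite samples per food, and a 24-hour recall survey
#' of 2,000 adult respondents. Detected concentrations are lognormal (right
#' skew produces the leptokurtic lower-bound exposure distribution this kind
#' of data shows); most sample x analyte measurements are non-detects carried
#' at a common LOD of 0.15 ug/kg. Body weight is folded into the g/kg bw
#' amounts, as 24-hour recall surveys of this design encode it.
#'
#' @param n_categories Number of food categories (drawn from the fixed
#'   21-label vocabulary).
#' @param n_foods Number of foods in the catalog.
#' @param samples_per_food Composite samples analysed per food.
#' @param n_respondents Respondents (person-days) in the survey.
#' @param detect_rate Probability a sample x analyte measurement is detected.
#' @param conc_log_mean,conc_log_sd Lognormal parameters of detected
#'   concentrations, ug/kg scale.
#' @param lod Limit of detection, ug/kg, carried on every record.
#' @param foods_per_day_mean Mean number of distinct foods consumed per
#'   person-day (Poisson, floored at 1).
#' @param amount_log_mean,amount_log_sd Lognormal parameters of consumption
#'   amounts, g/kg bw scale.
#' @param seed RNG seed; all generators are deterministic in (config, seed).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_categories = 21L,
                         n_foods = 264L,
                         samples_per_food = 2L,
                         n_respondents = 2000L,
                         detect_rate = 0.05,
                         conc_log_mean = log(0.5),
                         conc_log_sd = 1.0,
                         lod = 0.15,
                         foods_per_day_mean = 10,
                         amount_log_mean = log(1.5),
                         amount_log_sd = 0.8,
                         seed = 1L) {
  cfg <- list(n_categories = as.integer(n_categories),
              n_foods = as.integer(n_foods),
              samples_per_food = as.integer(samples_per_food),
              n_respondents = as.integer(n_respondents),
              detect_rate = detect_rate,
              conc_log_mean = conc_log_mean,
              conc_log_sd = conc_log_sd,
              lod = lod,
              foods_per_day_mean = foods_per_day_mean,
              amount_log_mean = amount_log_mean,
              amount_log_sd = amount_log_sd,
              seed = as.integer(seed))
  stopifnot(cfg$n_categories >= 1L, cfg$n_foods >= 1L,
            cfg$samples_per_food >= 1L, cfg$n_respondents >= 1L,
            cfg$detect_rate >= 0, cfg$detect_rate <= 1,
            cfg$conc_log_sd > 0, cfg$amount_log_sd > 0,
            cfg$lod > 0, cfg$foods_per_day_mean >= 0)
  if (cfg$n_categories > length(FOOD_CATEGORIES)) {
    stop_format("synth_config: n_categories (%d) exceeds the %d-label vocabulary",
                cfg$n_categories, length(FOOD_CATEGORIES))
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic food catalog
#'
#' Foods are partitioned round-robin over the first `n_categories` category
#' labels; cooking methods are assigned cyclically from the fixed vocabulary.
#'
#' @param cfg A [synth_config()].
#' @return Validated catalog data frame of `n_foods` rows.
#' @export
generate_catalog <- function(cfg = synth_config()) {
  if (cfg$n_categories > cfg$n_foods) {
    stop_format("generate_catalog: n_categories (%d) > n_foods (%d)",
                cfg$n_categories, cfg$n_foods)
  }
  ids <- sprintf("F%03d", seq_len(cfg$n_foods))
  cats <- FOOD_CATEGORIES[seq_len(cfg$n_categories)]
  catalog <- data.frame(
    food_id = ids,
    name = sprintf("food %03d", seq_len(cfg$n_foods)),
    category = rep_len(cats, cfg$n_foods),
    cooking_method = rep_len(COOKING_METHODS, cfg$n_foods),
    stringsAsFactors = FALSE
  )
  validate_catalog(catalog)
}

#' Generate synthetic composite-sample concentrations
#'
#' For every food, `samples_per_food` composite samples are "analysed" for the
#' four PAH4 analytes. Each sample x analyte is detected with probability
#' `detect_rate`; detected values are drawn lognormal(`conc_log_mean`,
#' `conc_log_sd`) ug/kg; every record carries the configured LOD so the
#' substitution policy downstream stays per-record.
#'
#' @param catalog A validated catalog.
#' @param cfg A [synth_config()].
#' @return Validated concentration records,
#'   `nrow(catalog) * samples_per_food * 4` rows.
#' @export
generate_concentrations <- function(catalog, cfg = synth_config()) {
  validate_catalog(catalog)
  set.seed(cfg$seed + 1L)
  grid <- expand.grid(analyte = PAH_ANALYTES,
                      sample = seq_len(cfg$samples_per_food),
                      food_id = catalog$food_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  detected <- stats::runif(n) < cfg$detect_rate
  value <- rep(NA_real_, n)
  value[detected] <- stats::rlnorm(sum(detected),
                                   meanlog = cfg$conc_log_mean,
                                   sdlog = cfg$conc_log_sd)
  records <- data.frame(
    food_id = grid$food_id,
    sample_id = sprintf("%s-S%d", grid$food_id, grid$sample),
    analyte = grid$analyte,
    detected = detected,
    value = value,
    lod = cfg$lod,
    stringsAsFactors = FALSE
  )
  validate_concentrations(records, catalog)
}

#' Generate a synthetic 24-hour recall survey
#'
#' Each respondent's person-day holds a Poisson(`foods_per_day_mean`)
#' distributed number (floored at 1, capped at the catalog size) of distinct
#' foods with lognormal g/kg bw amounts. Ages are uniform integers on
#' \[18, 83\] (survey minimum age to life expectancy); age is carried for
#' validation but unused downstream.
#'
#' @param catalog A validated catalog.
#' @param cfg A [synth_config()].
#' @return Validated survey data frame, one row per consumption event.
#' @export
generate_survey <- function(catalog, cfg = synth_config()) {
  validate_catalog(catalog)
  set.seed(cfg$seed + 2L)
  n_foods <- nrow(catalog)
  k <- pmin(pmax(stats::rpois(cfg$n_respondents, cfg$foods_per_day_mean), 1L),
            n_foods)
  ages <- sample(18:83, cfg$n_respondents, replace = TRUE)
  rows <- vector("list", cfg$n_respondents)
  for (i in seq_len(cfg$n_respondents)) {
    foods <- sample.int(n_foods, k[i], replace = FALSE)
    rows[[i]] <- data.frame(
      respondent_id = sprintf("R%04d", i),
      age = ages[i],
      food_id = catalog$food_id[foods],
      amount = stats::rlnorm(k[i], meanlog = cfg$amount_log_mean,
                             sdlog = cfg$amount_log_sd),
      stringsAsFactors = FALSE
    )
  }
  survey <- do.call(rbind, rows)
  rownames(survey) <- NULL
  validate_survey(survey, catalog)
}

#' Generate a bimodal exposure vector
#'
#' Test fixture for the exposed/unexposed classification stage: draws from a
#' two-component normal mixture truncated at zero, with components separated
#' enough (`low_mean + 4 * sd < high_mean`) that the mixture labels are a
#' usable ground truth for cluster recovery.
#'
#' @param n Number of draws.
#' @param weight_high Mixture weight of the high (exposed) component.
#' @param low_mean,high_mean Component means.
#' @param sd Common component standard deviation.
#' @param seed RNG seed.
#' @return Numeric vector of length `n` with a logical attribute
#'   `"component_high"` giving the ground-truth component of each draw.
#' @export
generate_bimodal_sample <- function(n, weight_high = 0.3,
                                    low_mean = 1, high_mean = 10, sd = 1,
                                    seed = 1L) {
  if (weight_high < 0 || weight_high > 1) {
    stop_format("generate_bimodal_sample: weight_high must be in [0, 1]")
  }
  if (low_mean + 4 * sd >= high_mean) {
    stop_format(
      "generate_bimodal_sample: components overlap (low_mean + 4*sd >= high_mean)")
  }
  set.seed(seed)
  high <- stats::runif(n) < weight_high
  x <- stats::rnorm(n, mean = ifelse(high, high_mean, low_mean), sd = sd)
  x <- pmax(x, 0)
  attr(x, "component_high") <- high
  x
}
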
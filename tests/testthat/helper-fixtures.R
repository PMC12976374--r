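# Small programmatic fixtures shared across test files.

# Two-food catalog, one category each, distinct cooking methods.
tiny_catalog <- function() {
  data.frame(
    food_id = c("F001", "F002"),
    name = c("grilled fish", "steamed fish"),
    category = "fish and seafood",
    cooking_method = c("grilled", "steamed"),
    stringsAsFactors = FALSE
  )
}

# One composite sample per food; F001 fully detected, F002 fully non-detect.
tiny_records <- function(lod = 0.15) {
  data.frame(
    food_id = rep(c("F001", "F002"), each = 4),
    sample_id = rep(c("F001-S1", "F002-S1"), each = 4),
    analyte = rep(PAH_ANALYTES, 2),
    detected = rep(c(TRUE, FALSE), each = 4),
    value = c(0.1, 0.2, 0.3, 0.4, rep(NA_real_, 4)),
    lod = lod,
    stringsAsFactors = FALSE
  )
}

tiny_survey <- function() {
  data.frame(
    respondent_id = c("R1", "R1", "R2"),
    age = c(30L, 30L, 45L),
    food_id = c("F001", "F002", "F001"),
    amount = c(10, 5, 2),
    stringsAsFactors = FALSE
  )
}

# Catalog + records where every food has one sample of constant PAH4 c_ug
# and every respondent consumes a single event of amount a: the degenerate
# configuration whose exposure is exactly a * c * 1e-6 each iteration.
degenerate_inputs <- function(c_ug = 2.0, amount = 5.0, n_foods = 3,
                              n_resp = 4) {
  catalog <- data.frame(
    food_id = sprintf("F%02d", seq_len(n_foods)),
    name = sprintf("food %d", seq_len(n_foods)),
    category = FOOD_CATEGORIES[1L],
    cooking_method = "boiled",
    stringsAsFactors = FALSE
  )
  records <- expand.grid(analyte = PAH_ANALYTES, food_id = catalog$food_id,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  records$sample_id <- paste0(records$food_id, "-S1")
  records$detected <- TRUE
  records$value <- c_ug / 4
  records$lod <- 0.15
  records <- records[, c("food_id", "sample_id", "analyte", "detected",
                         "value", "lod")]
  survey <- data.frame(
    respondent_id = sprintf("R%d", seq_len(n_resp)),
    age = 40L,
    food_id = catalog$food_id[(seq_len(n_resp) - 1L) %% n_foods + 1L],
    amount = amount,
    stringsAsFactors = FALSE
  )
  list(catalog = catalog, records = records, survey = survey)
}

# Shrunk-but-structured synthetic config for fast pipeline tests.
small_synth <- function(seed = 11L) {
  synth_config(n_categories = 5L, n_foods = 30L, samples_per_food = 2L,
               n_respondents = 150L, foods_per_day_mean = 5,
               seed = seed)
}
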
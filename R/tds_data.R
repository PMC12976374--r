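# Domain types and CSV I/O for total-diet-study (TDS) style data.
#
# Units are fixed package-wide: concentrations and LODs in ug/kg food,
# consumption amounts in g food per kg body weight per day. The single
# 1e-6 conversion to mg/kg bw/d lives in person_day_exposure(), nowhere else.

#' The four PAH4 marker analytes
#'
#' PAH4 is the EU marker set for polycyclic aromatic hydrocarbon contamination
#' in food: benz\[a\]anthracene (BaA), benzo\[a\]pyrene (BaP),
#' benzo\[b\]fluoranthene (BbF) and chrysene (Ch). Every concentration table
#' must use exactly these analyte codes.
#'
#' @format Character vector of length four: `"BaA"`, `"BaP"`, `"BbF"`, `"Ch"`.
#' @export
PAH_ANALYTES <- c("BaA", "BaP", "BbF", "Ch")

#' The fixed food-category vocabulary
#'
#' Twenty-one food categories of the kind a national total diet study uses to
#' partition the food supply. The vocabulary is fixed at catalog creation:
#' every catalog row's `category` must be drawn from it.
#'
#' @format Character vector of length 21.
#' @export
FOOD_CATEGORIES <- c(
  "grains and grain-based products", "meat and meat products",
  "fish and seafood", "dairy products", "eggs and egg products",
  "fats and oils", "fruits", "leafy vegetables", "fruiting vegetables",
  "root and tuber vegetables", "legumes and pulses", "nuts and seeds",
  "fungi and seaweed", "sauces and condiments", "sugar and confectionery",
  "beverages non-alcoholic", "beverages alcoholic", "snack foods",
  "composite dishes", "soups and broths", "herbs and spices"
)

#' Cooking-method label vocabulary used by the synthetic catalog generator
#' @format Character vector of cooking-method labels ("rte" = ready to eat).
#' @export
COOKING_METHODS <- c("boiled", "steamed", "stir-fried", "grilled", "raw", "rte")

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_format("%s: missing required column(s): %s",
                what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Validate a food catalog
#'
#' A catalog is a data frame with columns `food_id`, `name`, `category`,
#' `cooking_method`. Food ids must be unique and every category must belong
#' to the fixed 21-label vocabulary.
#'
#' @param catalog Data frame to validate.
#' @return The validated catalog, invisibly usable downstream.
#' @export
validate_catalog <- function(catalog) {
  check_columns(catalog, c("food_id", "name", "category", "cooking_method"),
                "catalog")
  dup <- duplicated(catalog$food_id)
  if (any(dup)) {
    stop_format("catalog: duplicate food_id at row %d (field food_id): '%s'",
                which(dup)[1L], catalog$food_id[which(dup)[1L]])
  }
  bad <- !(catalog$category %in% FOOD_CATEGORIES)
  if (any(bad)) {
    stop_format("catalog: unknown category at row %d (field category): '%s'",
                which(bad)[1L], catalog$category[which(bad)[1L]])
  }
  catalog
}

#' Validate a concentration table
#'
#' One row per composite sample x analyte. Columns: `food_id`, `sample_id`,
#' `analyte`, `detected` (logical), `value` (ug/kg, present iff detected,
#' `NA` otherwise), `lod` (ug/kg, > 0). Analytes must be one of the PAH4
#' codes; food ids must resolve against `catalog` when one is supplied.
#'
#' @param records Data frame of concentration records.
#' @param catalog Optional catalog to resolve `food_id` against.
#' @return The validated records.
#' @export
validate_concentrations <- function(records, catalog = NULL) {
  check_columns(records,
                c("food_id", "sample_id", "analyte", "detected", "value", "lod"),
                "concentration table")
  bad <- !(records$analyte %in% PAH_ANALYTES)
  if (any(bad)) {
    stop_format(
      "concentration table: unknown analyte at row %d (field analyte): '%s'",
      which(bad)[1L], records$analyte[which(bad)[1L]])
  }
  if (!is.logical(records$detected) || anyNA(records$detected)) {
    i <- which(is.na(records$detected))[1L]
    stop_format(
      "concentration table: row %d (field detected): must be TRUE or FALSE",
      if (length(i)) i else 1L)
  }
  bad <- records$detected & (is.na(records$value) | records$value < 0)
  if (any(bad)) {
    stop_format(
      "concentration table: row %d (field value): detected record needs a value >= 0",
      which(bad)[1L])
  }
  bad <- !records$detected & !is.na(records$value)
  if (any(bad)) {
    stop_format(
      "concentration table: row %d (field value): non-detect must have empty value",
      which(bad)[1L])
  }
  bad <- is.na(records$lod) | records$lod <= 0
  if (any(bad)) {
    stop_format("concentration table: row %d (field lod): lod must be > 0",
                which(bad)[1L])
  }
  if (!is.null(catalog)) {
    bad <- !(records$food_id %in% catalog$food_id)
    if (any(bad)) {
      stop_format(
        "concentration table: row %d (field food_id): '%s' not in catalog",
        which(bad)[1L], records$food_id[which(bad)[1L]])
    }
  }
  records
}

#' Validate a consumption survey
#'
#' One row per consumption event: `respondent_id`, `age` (years, >= 18),
#' `food_id`, `amount` (g food per kg body weight, >= 0; zero rows record
#' foods not consumed and are retained).
#'
#' @param survey Data frame of consumption events.
#' @param catalog Optional catalog to resolve `food_id` against.
#' @param min_age Minimum respondent age (survey inclusion criterion).
#' @return The validated survey.
#' @export
validate_survey <- function(survey, catalog = NULL, min_age = 18) {
  check_columns(survey, c("respondent_id", "age", "food_id", "amount"),
                "survey")
  bad <- is.na(survey$age) | survey$age < min_age
  if (any(bad)) {
    stop_format("survey: row %d (field age): age %s below minimum %d",
                which(bad)[1L], survey$age[which(bad)[1L]], min_age)
  }
  bad <- is.na(survey$amount) | survey$amount < 0
  if (any(bad)) {
    stop_format("survey: row %d (field amount): amount must be >= 0",
                which(bad)[1L])
  }
  if (!is.null(catalog)) {
    bad <- !(survey$food_id %in% catalog$food_id)
    if (any(bad)) {
      stop_format("survey: row %d (field food_id): '%s' not in catalog",
                  which(bad)[1L], survey$food_id[which(bad)[1L]])
    }
  }
  survey
}

# Write numeric columns at full double precision ("%.17g") so a write/read
# cycle reproduces every field bit-for-bit (R's reader round-trips 17
# significant digits).
write_csv_precise <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- ""
      out[[nm]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a food catalog CSV
#'
#' @param path Path to a CSV with columns `food_id,name,category,cooking_method`.
#' @return Validated catalog data frame.
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  validate_catalog(df)
}

#' Write a food catalog CSV
#' @param catalog Validated catalog data frame.
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(validate_catalog(catalog), path, row.names = FALSE,
                   quote = TRUE, na = "")
  invisible(path)
}

#' Read a concentration table CSV
#'
#' Expects columns `food_id,sample_id,analyte,detected,value,lod`. `detected`
#' is `true`/`false`; `value` is empty for non-detects and carries the
#' concentration in ug/kg otherwise; `lod` (ug/kg) is mandatory on every row
#' so the non-detect substitution policy stays data-driven per record.
#'
#' @param path Path to the CSV.
#' @param catalog Optional catalog; unknown `food_id`s are rejected.
#' @return Validated concentration records.
#' @export
read_concentration_table <- function(path, catalog = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("food_id", "sample_id", "analyte", "detected",
                      "value", "lod"), "concentration table")
  df$food_id <- as.character(df$food_id)
  df$sample_id <- as.character(df$sample_id)
  df$analyte <- as.character(df$analyte)
  df$detected <- as.logical(df$detected)
  df$value <- as.numeric(df$value)
  df$lod <- as.numeric(df$lod)
  validate_concentrations(df, catalog)
}

#' Write a concentration table CSV
#' @param records Validated concentration records.
#' @param path Output path.
#' @export
write_concentration_table <- function(records, path) {
  write_csv_precise(validate_concentrations(records), path)
}

#' Read a consumption survey CSV
#'
#' Expects columns `respondent_id,age,food_id,amount`, one row per consumption
#' event; zero-amount rows (foods recorded but not consumed) are retained.
#'
#' @param path Path to the CSV.
#' @param catalog Optional catalog; unknown `food_id`s are rejected.
#' @param min_age Minimum respondent age.
#' @return Validated survey data frame.
#' @export
read_survey <- function(path, catalog = NULL, min_age = 18) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("respondent_id", "age", "food_id", "amount"), "survey")
  df$respondent_id <- as.character(df$respondent_id)
  df$age <- as.integer(df$age)
  df$food_id <- as.character(df$food_id)
  df$amount <- as.numeric(df$amount)
  validate_survey(df, catalog, min_age = min_age)
}

#' Write a consumption survey CSV
#' @param survey Validated survey data frame.
#' @param path Output path.
#' @export
write_survey <- function(survey, path) {
  write_csv_precise(validate_survey(survey), path)
}

#' Split a survey into person-days
#'
#' Groups consumption events by respondent. Each element of the returned list
#' is one person-day: a single day of food consumption for one individual,
#' the resampling unit of the Monte Carlo simulation.
#'
#' @param survey Validated survey data frame.
#' @return Named list (by respondent_id) of data frames with columns
#'   `food_id`, `amount`, plus an `age` attribute per element.
#' @export
person_days <- function(survey) {
  validate_survey(survey)
  split_ids <- factor(survey$respondent_id,
                      levels = unique(survey$respondent_id))
  out <- lapply(split(survey, split_ids), function(d) {
    pd <- d[, c("food_id", "amount")]
    attr(pd, "age") <- d$age[1L]
    pd
  })
  out
}
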
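# I/O and validation for TDS-style tables.

test_that("concentration table round-trips through CSV field-for-field", {
  cfg <- small_synth()
  catalog <- generate_catalog(cfg)
  records <- generate_concentrations(catalog, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_concentration_table(records, path)
  back <- read_concentration_table(path, catalog)
  expect_equal(back, records, ignore_attr = TRUE)

  # non-detect rows keep empty value and their LOD through the round trip
  nd <- back[!back$detected, ]
  expect_true(all(is.na(nd$value)))
  expect_true(all(nd$lod == cfg$lod))
})

test_that("catalog and survey round-trip through CSV", {
  cfg <- small_synth()
  catalog <- generate_catalog(cfg)
  survey <- generate_survey(catalog, cfg)
  cpath <- withr::local_tempfile(fileext = ".csv")
  spath <- withr::local_tempfile(fileext = ".csv")
  write_catalog(catalog, cpath)
  write_survey(survey, spath)
  expect_equal(read_catalog(cpath), catalog, ignore_attr = TRUE)
  expect_equal(read_survey(spath, catalog), survey, ignore_attr = TRUE)
})

test_that("a minimal four-row concentration CSV reads to four records", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "food_id,sample_id,analyte,detected,value,lod",
    "F001,S1,BaA,TRUE,0.1,0.15",
    "F001,S1,BaP,TRUE,0.2,0.15",
    "F001,S1,BbF,FALSE,,0.15",
    "F001,S1,Ch,TRUE,0.4,0.15"), path)
  rec <- read_concentration_table(path)
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$detected, c(TRUE, TRUE, FALSE, TRUE))
  expect_true(is.na(rec$value[3]))
})

test_that("validation rejects malformed rows with row and field named", {
  rec <- tiny_records()
  bad <- rec; bad$analyte[2] <- "PYR"
  expect_error(validate_concentrations(bad), "row 2.*analyte.*PYR")

  bad <- rec; bad$value[1] <- NA_real_
  expect_error(validate_concentrations(bad), "row 1.*value")

  bad <- rec; bad$value[5] <- 0.2  # non-detect carrying a value
  expect_error(validate_concentrations(bad), "row 5.*value")

  bad <- rec; bad$lod[3] <- 0
  expect_error(validate_concentrations(bad), "row 3.*lod")

  bad <- rec[, setdiff(names(rec), "lod")]
  expect_error(validate_concentrations(bad), "missing required column.*lod")

  expect_error(
    validate_concentrations(tiny_records(), tiny_catalog()[1, ]),
    "row 5.*food_id.*F002")
})

test_that("survey validation enforces minimum age and non-negative amounts", {
  sv <- tiny_survey()
  bad <- sv; bad$age[2] <- 17L
  expect_error(validate_survey(bad), "row 2.*age.*17")
  bad <- sv; bad$amount[3] <- -1
  expect_error(validate_survey(bad), "row 3.*amount")
  bad <- sv; bad$food_id[1] <- "F999"
  expect_error(validate_survey(bad, tiny_catalog()), "row 1.*food_id.*F999")
  # zero-amount rows are retained, not dropped
  sv$amount[1] <- 0
  expect_equal(nrow(validate_survey(sv)), 3L)
})

test_that("catalog validation enforces unique ids and the fixed vocabulary", {
  cat2 <- tiny_catalog()
  bad <- cat2; bad$food_id[2] <- "F001"
  expect_error(validate_catalog(bad), "duplicate food_id.*row 2")
  bad <- cat2; bad$category[1] <- "astronaut food"
  expect_error(validate_catalog(bad), "row 1.*category")
  expect_length(FOOD_CATEGORIES, 21L)
})

test_that("person_days groups events by respondent and keeps ages", {
  sv <- data.frame(
    respondent_id = rep(c("A", "B"), each = 3),
    age = rep(c(20L, 60L), each = 3),
    food_id = rep(c("F001", "F002", "F001"), 2),
    amount = c(1, 2, 3, 4, 5, 6), stringsAsFactors = FALSE)
  pd <- person_days(sv)
  expect_length(pd, 2L)
  expect_equal(nrow(pd[["A"]]), 3L)
  expect_equal(attr(pd[["B"]], "age"), 60L)
  expect_equal(pd[["B"]]$amount, c(4, 5, 6))
})
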
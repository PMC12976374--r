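# Monte Carlo engine: substitution policy, PAH4 summation, unit conversion,
# coupling between scenarios, and exposure invariants.

test_that("non-detect substitution follows the scenario bounds", {
  rec <- tiny_records(lod = 0.15)
  opt <- substitute_nd(rec, "optimistic")
  pes <- substitute_nd(rec, "pessimistic")
  # detected values survive both scenarios untouched
  expect_equal(opt[1:4], c(0.1, 0.2, 0.3, 0.4))
  expect_equal(pes[1:4], c(0.1, 0.2, 0.3, 0.4))
  # non-detects: 0 under the lower bound, the record's LOD under the upper
  expect_equal(opt[5:8], rep(0, 4))
  expect_equal(pes[5:8], rep(0.15, 4))

  one <- tiny_records(); one$detected[5] <- TRUE; one$value[5] <- 2.06
  expect_equal(substitute_nd(one, "optimistic")[5], 2.06)
  expect_equal(substitute_nd(one, "pessimistic")[5], 2.06)
})

test_that("pah4 sums exactly one value per analyte", {
  expect_equal(pah4(c(0.1, 0.2, 0.3, 0.4)), 1.0)
  expect_error(pah4(c(0.1, 0.2, 0.3)), "exactly one value per analyte")
  expect_error(pah4(c(0.1, 0.2, 0.3, NA)), "exactly one value per analyte")
})

test_that("per-sample PAH4 applies substitution before summation", {
  rec <- tiny_records(lod = 0.15)
  opt <- pah4_by_sample(rec, "optimistic")
  pes <- pah4_by_sample(rec, "pessimistic")
  expect_equal(opt$pah4[opt$food_id == "F001"], 1.0)
  expect_equal(opt$pah4[opt$food_id == "F002"], 0)      # four non-detects, lower bound
  expect_equal(pes$pah4[pes$food_id == "F002"], 0.6)    # 4 x 0.15, upper bound

  incomplete <- rec[-1, ]
  expect_error(pah4_by_sample(incomplete, "optimistic"), "exactly 4 analytes")
})

test_that("person-day exposure converts ug/kg x g/kg bw to mg/kg bw/d once", {
  expect_equal(person_day_exposure(numeric(0), numeric(0)), 0)
  # 10 g/kg bw of a 1.0 ug/kg food -> 1e-5 mg/kg bw/d
  expect_equal(person_day_exposure(10, 1.0), 1.0e-5)
  a <- c(2, 3, 4); cc <- c(0.5, 1, 1.5)
  expect_equal(person_day_exposure(2 * a, cc), 2 * person_day_exposure(a, cc))
})

test_that("a single deterministic iteration matches hand arithmetic", {
  # one respondent, single-sample foods: no randomness left in the draw
  survey <- tiny_survey()[tiny_survey()$respondent_id == "R1", ]
  dist <- simulate_exposure(survey, tiny_records(), "pessimistic",
                            iterations = 1L, seed = 1L)
  # R1 eats 10 g/kg of F001 (PAH4 1.0) and 5 g/kg of F002 (PAH4 0.6)
  expect_equal(dist$values, (10 * 1.0 + 5 * 0.6) * 1e-6)

  opt <- simulate_exposure(survey, tiny_records(), "optimistic",
                           iterations = 1L, seed = 1L)
  expect_equal(opt$values, 10 * 1.0 * 1e-6)
})

test_that("all-non-detect data gives an all-zero optimistic distribution", {
  rec <- tiny_records()
  rec$detected <- FALSE
  rec$value <- NA_real_
  dist <- simulate_exposure(tiny_survey(), rec, "optimistic",
                            iterations = 200L, seed = 2L)
  expect_true(all(dist$values == 0))
})

test_that("common random numbers couple the scenarios pathwise", {
  cfg <- small_synth()
  catalog <- generate_catalog(cfg)
  records <- generate_concentrations(catalog, cfg)
  survey <- generate_survey(catalog, cfg)
  sims <- simulate_scenarios(survey, records, iterations = 3000L, seed = 5L)
  expect_true(all(sims$pessimistic$values >= sims$optimistic$values))
  expect_true(all(sims$optimistic$values >= 0))
  # determinism in (seed, inputs)
  again <- simulate_exposure(survey, records, "pessimistic",
                             iterations = 3000L, seed = 5L)
  expect_identical(again$values, sims$pessimistic$values)
  # decoupled streams differ
  dec <- simulate_exposure(survey, records, "pessimistic",
                           iterations = 3000L, seed = 5L,
                           common_random_numbers = FALSE)
  expect_false(identical(dec$values, sims$pessimistic$values))
})

test_that("surveyed foods without concentration records warn and contribute zero", {
  survey <- tiny_survey()
  survey$food_id[2] <- "F003"   # no concentration record
  survey_ok <- tiny_survey()
  catalog <- rbind(tiny_catalog(),
                   data.frame(food_id = "F003", name = "mystery",
                              category = "fish and seafood",
                              cooking_method = "raw",
                              stringsAsFactors = FALSE))
  expect_warning(
    d <- simulate_exposure(survey, tiny_records(), "pessimistic",
                           iterations = 50L, seed = 3L),
    "F003.*zero exposure")
  # F003 replaced F002 for R1; with its contribution zeroed, R1's exposure is
  # 10 g/kg x 1.0 ug/kg and R2's is 2 g/kg x 1.0 ug/kg
  expect_true(all(d$values %in% c(10 * 1e-6, 2 * 1e-6)))
  # whereas with full coverage R1 also picks up 5 g/kg x 0.6 ug/kg
  d_ok <- simulate_exposure(survey_ok, tiny_records(), "pessimistic",
                            iterations = 50L, seed = 3L)
  expect_true(max(d_ok$values) > max(d$values))

  expect_error(simulate_exposure(survey[0, ], tiny_records(), "optimistic"),
               "empty survey")
})

test_that("constant concentrations and fixed diets recover a*c*1e-6 exactly", {
  inp <- degenerate_inputs(c_ug = 2.0, amount = 5.0)
  for (scn in c("optimistic", "pessimistic")) {
    dist <- simulate_exposure(inp$survey, inp$records, scn,
                              iterations = 500L, seed = 9L)
    expect_identical(unique(dist$values), 5.0 * 2.0 * 1e-6)
  }
})
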
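# Lifetime cancer risk, relative risk, population attributable fraction
# (Levin's formula) and attributable DALYs from the median PAH4 exposure,
# plus comparison against a minimal risk level (MRL).

#' Default PAH4 slope factors, (mg/kg bw/d)^-1
#'
#' Linear carcinogenic potency coefficients per analyte: BaA 1.00e-1,
#' BaP 1.00e1, BbF 1.00e-1, Ch 1.00e-3.
#'
#' @format Named numeric vector over the PAH4 analytes.
#' @export
DEFAULT_SLOPE_FACTORS <- c(BaA = 1.00e-1, BaP = 1.00e1,
                           BbF = 1.00e-1, Ch = 1.00e-3)

#' Risk and burden parameters
#'
#' Houses everything the cancer-risk / attributable-burden chain needs.
#' `exposure_time` defaults to `life_expectancy - min_age` (adult exposure
#' window: 83 - 18 = 65 years). The averaged slope factor `SF_avg` is by
#' default the arithmetic mean of the four analyte slope factors (2.55025
#' with the defaults); set `sf_avg_method = "fixed"` with `sf_avg_fixed` to
#' impose an explicit value instead — the two options exist because the mean
#' of published per-analyte slope factors and the effective potency a given
#' assessment uses need not coincide. `total_cancer_dalys` (YLD + YLL for
#' all cancers in the reference population and year) has no default: it is a
#' population statistic the caller must supply.
#'
#' @param slope_factors Named vector over `BaA, BaP, BbF, Ch`,
#'   (mg/kg bw/d)^-1, all > 0.
#' @param sf_avg_method `"arithmetic_mean"` or `"fixed"`.
#' @param sf_avg_fixed Explicit SF_avg, required when method is `"fixed"`.
#' @param life_expectancy Years (default 83).
#' @param min_age Minimum respondent age, years (default 18).
#' @param exposure_time Years; default `life_expectancy - min_age`.
#' @param total_cancer_risk Lifetime probability of cancer from all causes
#'   (default 0.25).
#' @param total_cancer_dalys Total all-cancer DALYs of the reference
#'   population (years). Required.
#' @param mrl_pah4 Minimal risk level for PAH4, mg/kg bw/d
#'   (default 4.84e-4).
#' @return List of class `risk_params`.
#' @export
risk_params <- function(slope_factors = DEFAULT_SLOPE_FACTORS,
                        sf_avg_method = c("arithmetic_mean", "fixed"),
                        sf_avg_fixed = NULL,
                        life_expectancy = 83,
                        min_age = 18,
                        exposure_time = NULL,
                        total_cancer_risk = 0.25,
                        total_cancer_dalys,
                        mrl_pah4 = 4.84e-4) {
  sf_avg_method <- match.arg(sf_avg_method)
  if (missing(total_cancer_dalys)) {
    stop_format("risk_params: total_cancer_dalys is required (all-cancer YLD + YLL, years)")
  }
  if (!all(PAH_ANALYTES %in% names(slope_factors))) {
    stop_format("risk_params: slope_factors must name all of %s",
                paste(PAH_ANALYTES, collapse = ", "))
  }
  slope_factors <- slope_factors[PAH_ANALYTES]
  stopifnot(all(slope_factors > 0),
            total_cancer_risk > 0, total_cancer_risk < 1,
            life_expectancy > 0, min_age >= 0,
            total_cancer_dalys >= 0, mrl_pah4 > 0)
  if (is.null(exposure_time)) exposure_time <- life_expectancy - min_age
  stopifnot(exposure_time > 0)
  if (sf_avg_method == "fixed" && is.null(sf_avg_fixed)) {
    stop_format("risk_params: sf_avg_method = 'fixed' needs sf_avg_fixed")
  }
  structure(list(slope_factors = slope_factors,
                 sf_avg_method = sf_avg_method,
                 sf_avg_fixed = sf_avg_fixed,
                 life_expectancy = life_expectancy,
                 min_age = min_age,
                 exposure_time = exposure_time,
                 total_cancer_risk = total_cancer_risk,
                 total_cancer_dalys = total_cancer_dalys,
                 mrl_pah4 = mrl_pah4),
            class = "risk_params")
}

#' Averaged slope factor
#' @param params A [risk_params()].
#' @return SF_avg in (mg/kg bw/d)^-1.
#' @export
sf_avg <- function(params) {
  switch(params$sf_avg_method,
         arithmetic_mean = mean(params$slope_factors),
         fixed = params$sf_avg_fixed)
}

#' Lifetime cancer risk from a chronic PAH4 exposure
#'
#' `risk = exposure * SF_avg * exposure_time / life_expectancy`: the slope
#' factor converts dose to incremental lifetime probability, scaled by the
#' fraction of life spent exposed. A result >= 1 is rejected as a
#' probability overflow (it signals implausible inputs, e.g. a unit error).
#'
#' @param exposure Exposure, mg/kg bw/d (>= 0). Vectorised.
#' @param params A [risk_params()].
#' @return Lifetime probability in \[0, 1).
#' @export
cancer_risk <- function(exposure, params) {
  stopifnot(all(exposure >= 0))
  r <- exposure * sf_avg(params) * params$exposure_time /
    params$life_expectancy
  if (any(r >= 1)) {
    stop_format("cancer_risk: computed probability >= 1; check exposure units")
  }
  r
}

#' Relative risk from the excess lifetime cancer risk
#'
#' The exposed group's risk sits on top of the background lifetime cancer
#' risk, so the relative risk is `1 + R / (T - R)` with `R` the exposure-
#' attributable risk and `T` the total lifetime cancer risk: the unexposed
#' carry `T - R` and the exposed `T`. This excess-risk form keeps RR >= 1 so
#' Levin's attributable fraction stays non-negative. The bare ratio
#' `R / (T - R)` is available via [relative_risk_literal()] for inspection;
#' taken alone it would be the *excess* relative risk, not a relative risk.
#'
#' @param risk_exposed Exposure-attributable lifetime risk `R`, with
#'   `0 <= R < total_risk`.
#' @param total_risk Total lifetime cancer risk `T`.
#' @return Relative risk >= 1.
#' @export
relative_risk <- function(risk_exposed, total_risk) {
  stopifnot(all(risk_exposed >= 0))
  if (any(risk_exposed >= total_risk)) {
    stop_format("relative_risk: risk_exposed must be < total_risk")
  }
  1 + risk_exposed / (total_risk - risk_exposed)
}

#' The bare excess ratio R / (T - R)
#' @inheritParams relative_risk
#' @return `risk_exposed / (total_risk - risk_exposed)`, i.e.
#'   [relative_risk()] minus one.
#' @export
relative_risk_literal <- function(risk_exposed, total_risk) {
  relative_risk(risk_exposed, total_risk) - 1
}

#' Population attributable fraction (Levin's formula)
#'
#' `PAF = p (RR - 1) / (p (RR - 1) + 1)` with exposure prevalence `p` and
#' relative risk `RR`: the proportion of cases in the population attributable
#' to the exposure.
#'
#' @param prevalence Exposure prevalence in \[0, 1\].
#' @param rr Relative risk >= 1 (protective exposures are out of scope).
#' @return Fraction in \[0, 1).
#' @export
paf <- function(prevalence, rr) {
  stopifnot(all(prevalence >= 0), all(prevalence <= 1))
  if (any(rr < 1)) {
    stop_format("paf: rr must be >= 1 (protective exposures out of scope)")
  }
  prevalence * (rr - 1) / (prevalence * (rr - 1) + 1)
}

#' Attributable DALYs
#' @param paf_value Attributable fraction in \[0, 1\].
#' @param total_dalys All-cause-of-interest DALYs (YLD + YLL), years.
#' @return `paf_value * total_dalys`, years.
#' @export
attributable_daly <- function(paf_value, total_dalys) {
  stopifnot(all(paf_value >= 0), all(paf_value <= 1), total_dalys >= 0)
  paf_value * total_dalys
}

#' Classify an exposure against the minimal risk level
#' @param exposure Exposure, mg/kg bw/d.
#' @param params A [risk_params()].
#' @return `"below"` if `exposure <= mrl_pah4`, else `"above"` (strictly
#'   greater; the boundary itself is "below").
#' @export
mrl_classify <- function(exposure, params) {
  stopifnot(all(exposure >= 0))
  ifelse(exposure > params$mrl_pah4, "above", "below")
}

#' Run the full burden chain for one scenario
#'
#' Median exposure -> lifetime cancer risk -> relative risk -> Levin PAF
#' -> attributable DALYs, plus MRL classification.
#'
#' @param exposure_median Median exposure, mg/kg bw/d.
#' @param prevalence Exposure prevalence (exposed-cluster fraction).
#' @param params A [risk_params()].
#' @return List of class `burden_result` with `exposure_median`,
#'   `cancer_risk`, `relative_risk`, `prevalence`, `paf`,
#'   `attributable_daly`, `mrl_status`.
#' @export
burden_chain <- function(exposure_median, prevalence, params) {
  r <- cancer_risk(exposure_median, params)
  rr <- relative_risk(r, params$total_cancer_risk)
  p <- paf(prevalence, rr)
  structure(list(exposure_median = exposure_median,
                 cancer_risk = r,
                 relative_risk = rr,
                 prevalence = prevalence,
                 paf = p,
                 attributable_daly = attributable_daly(
                   p, params$total_cancer_dalys),
                 mrl_status = mrl_classify(exposure_median, params)),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<burden_result>\n",
    "  median exposure   %.3g mg/kg bw/d (%s MRL)\n",
    "  lifetime risk     %.3g\n",
    "  relative risk     %.6g\n",
    "  prevalence        %.3g\n",
    "  PAF               %.3g\n",
    "  attributable DALY %.3g years\n"),
    x$exposure_median, x$mrl_status, x$cancer_risk, x$relative_risk,
    x$prevalence, x$paf, x$attributable_daly))
  invisible(x)
}
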
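#' Default identifier-corruption rates
#'
#' Per-field probabilities used by [corrupt_identifiers()]. The defaults are
#' chosen to look like administrative extracts: Social Security numbers are
#' frequently absent (claims and hospital systems often cannot share them),
#' names carry occasional keystroke errors, and a small fraction of birth
#' dates have the day and month transposed.
#'
#' @return Named list of probabilities.
#' @export
default_corruption_rates <- function() {
  list(
    first_name_typo = 0.05,
    first_name_missing = 0.01,
    last_name_typo = 0.03,
    last_name_substitute = 0.02,
    last_name_missing = 0.005,
    dob_transpose = 0.02,
    dob_missing = 0.01,
    ssn_typo = 0.01,
    ssn_missing = 0.15,
    sex_missing = 0.02,
    zip_typo = 0.03,
    zip_missing = 0.05
  )
}

#' Configuration for the synthetic surveillance population
#'
#' Parameterizes the seeded generator that emulates the five surveillance
#' source systems: a ground-truth population with a configurable SCD
#' prevalence and genotype mix, partial overlapping capture by each source,
#' Poisson encounter histories in the longitudinal sources, identifier noise
#' that stresses linkage, and diagnostic miscoding that populates the
#' possible-case tier.
#'
#' @param n_population Number of persons in the synthetic population.
#' @param scd_prevalence Probability a person truly has SCD.
#' @param genotype_props Proportions of the four SCD genotypes
#'   (`SS_Sb0`, `Sb_plus`, `SC`, `OTHER_SCD`) among true cases; must sum to 1.
#' @param period Integer vector `c(start_year, end_year)` of the surveillance
#'   period.
#' @param nbs_start_year First birth year covered by newborn screening.
#' @param source_coverage Named per-source capture probabilities
#'   (`NBS`, `CLINIC`, `MEDICAID`, `HOSPITAL_ED`, `DEATH`).
#' @param encounter_rate Mean encounters per person-year, per longitudinal
#'   source, for captured cases.
#' @param corruption_rates Named list of per-field identifier error and
#'   missingness probabilities; see [default_corruption_rates()].
#' @param miscode_rate Probability a non-SCD person accrues sickle-coded
#'   encounters (mostly trait codes).
#' @param miscode_scd_share Among miscoded non-cases, the share whose stray
#'   codes are true SCD codes rather than trait codes.
#' @param migration_rates Named annual probabilities `inflow` (entering the
#'   state) and `outflow` (leaving). Migration is annual and memoryless; a
#'   person out of state in a year emits no records dated in that year.
#' @param born_in_state_prob Probability a person was born in state (and so is
#'   eligible for newborn screening capture).
#' @param nbs_confirm_prob Probability a captured newborn-screening result has
#'   confirmatory testing on file.
#' @param clinic_lab_prob Probability a clinic case report carries documented
#'   confirmatory laboratory testing.
#' @param clinic_genotype_prob Probability a clinic report includes a genotype
#'   result.
#' @param clinic_false_rate Probability a non-case generates a (false) clinic
#'   report without laboratory confirmation.
#' @param dup_billing_rate Probability a Medicaid encounter is also billed as a
#'   hospital/ED record on the same date (one event, two source records),
#'   exercising the distinct-date rule in case classification.
#' @param death_hazard Named annual death probabilities `case` and `noncase`
#'   applied within the surveillance period.
#' @param birth_year_range Integer range of birth years; default spans the 68
#'   years up to the end of the period, giving a realistic age pyramid.
#' @param seed Integer seed; all generation is deterministic given the config.
#' @return A validated list of class `scd_generator_config`.
#' @examples
#' cfg <- generator_config(n_population = 500, seed = 1)
#' @export
generator_config <- function(n_population = 5000,
                             scd_prevalence = 0.02,
                             genotype_props = c(SS_Sb0 = 0.63, Sb_plus = 0.08,
                                                SC = 0.27, OTHER_SCD = 0.02),
                             period = c(2004L, 2018L),
                             nbs_start_year = 1990L,
                             source_coverage = c(NBS = 0.95, CLINIC = 0.5,
                                                 MEDICAID = 0.65,
                                                 HOSPITAL_ED = 0.7,
                                                 DEATH = 1.0),
                             encounter_rate = 2.0,
                             corruption_rates = default_corruption_rates(),
                             miscode_rate = 0.004,
                             miscode_scd_share = 0.25,
                             migration_rates = c(inflow = 0.01, outflow = 0.015),
                             born_in_state_prob = 0.8,
                             nbs_confirm_prob = 0.95,
                             clinic_lab_prob = 0.85,
                             clinic_genotype_prob = 0.95,
                             clinic_false_rate = 0.0005,
                             dup_billing_rate = 0.1,
                             death_hazard = c(case = 0.012, noncase = 0.004),
                             birth_year_range = NULL,
                             seed = 1L) {
  if (!is.numeric(n_population) || length(n_population) != 1 ||
      is.na(n_population) || n_population < 0) {
    scdlink_abort("`n_population` must be a non-negative count",
                  class = "scdlink_config_error")
  }
  assert_probability(scd_prevalence, "scd_prevalence")
  if (length(genotype_props) != 4 ||
      abs(sum(genotype_props) - 1) > 1e-9 || any(genotype_props < 0)) {
    scdlink_abort("`genotype_props` must be 4 non-negative proportions summing to 1",
                  class = "scdlink_config_error")
  }
  names(genotype_props) <- c("SS_Sb0", "Sb_plus", "SC", "OTHER_SCD")
  if (length(period) != 2 || period[1] > period[2]) {
    scdlink_abort("`period` must be c(start_year, end_year) with start <= end",
                  class = "scdlink_config_error")
  }
  needed <- c("NBS", "CLINIC", "MEDICAID", "HOSPITAL_ED", "DEATH")
  if (!all(needed %in% names(source_coverage))) {
    scdlink_abort("`source_coverage` must name all five sources",
                  class = "scdlink_config_error")
  }
  assert_probability(unlist(source_coverage), "source_coverage")
  assert_probability(unlist(corruption_rates), "corruption_rates")
  assert_probability(miscode_rate, "miscode_rate")
  assert_probability(miscode_scd_share, "miscode_scd_share")
  assert_probability(unname(migration_rates), "migration_rates")
  assert_probability(born_in_state_prob, "born_in_state_prob")
  assert_probability(nbs_confirm_prob, "nbs_confirm_prob")
  assert_probability(clinic_lab_prob, "clinic_lab_prob")
  assert_probability(clinic_genotype_prob, "clinic_genotype_prob")
  assert_probability(clinic_false_rate, "clinic_false_rate")
  assert_probability(dup_billing_rate, "dup_billing_rate")
  assert_probability(unname(death_hazard), "death_hazard")
  if (encounter_rate < 0) {
    scdlink_abort("`encounter_rate` must be non-negative",
                  class = "scdlink_config_error")
  }
  if (is.null(birth_year_range)) {
    birth_year_range <- c(as.integer(period[2]) - 68L, as.integer(period[2]))
  }
  structure(list(
    n_population = as.integer(n_population),
    scd_prevalence = scd_prevalence,
    genotype_props = genotype_props,
    period = as.integer(period),
    nbs_start_year = as.integer(nbs_start_year),
    source_coverage = source_coverage[needed],
    encounter_rate = encounter_rate,
    corruption_rates = corruption_rates,
    miscode_rate = miscode_rate,
    miscode_scd_share = miscode_scd_share,
    migration_rates = migration_rates,
    born_in_state_prob = born_in_state_prob,
    nbs_confirm_prob = nbs_confirm_prob,
    clinic_lab_prob = clinic_lab_prob,
    clinic_genotype_prob = clinic_genotype_prob,
    clinic_false_rate = clinic_false_rate,
    dup_billing_rate = dup_billing_rate,
    death_hazard = death_hazard,
    birth_year_range = as.integer(birth_year_range),
    seed = as.integer(seed)
  ), class = "scd_generator_config")
}

#' Noiseless generator configuration
#'
#' The analytic limit used by oracle tests: no identifier corruption, full
#' source coverage, no miscoding, no migration, everyone born in state, and
#' every captured laboratory result confirmed. In this limit the pipeline must
#' recover the ground truth exactly (linkage precision = recall = 1; every
#' true case classifies as confirmed).
#'
#' @param ... Overrides passed to [generator_config()].
#' @return A `scd_generator_config`.
#' @export
noiseless_config <- function(...) {
  zero_rates <- lapply(default_corruption_rates(), function(x) 0)
  defaults <- list(
    source_coverage = c(NBS = 1, CLINIC = 1, MEDICAID = 1,
                        HOSPITAL_ED = 1, DEATH = 1),
    corruption_rates = zero_rates,
    miscode_rate = 0,
    migration_rates = c(inflow = 0, outflow = 0),
    born_in_state_prob = 1,
    nbs_confirm_prob = 1,
    clinic_lab_prob = 1,
    clinic_genotype_prob = 1,
    clinic_false_rate = 0
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(generator_config, args)
}

#' @export
print.scd_generator_config <- function(x, ...) {
  cat("<scd_generator_config>\n")
  cat(sprintf("  population: %d, prevalence: %.3f, period: %d-%d, seed: %d\n",
              x$n_population, x$scd_prevalence, x$period[1], x$period[2], x$seed))
  cat(sprintf("  coverage: %s\n",
              paste(sprintf("%s=%.2f", names(x$source_coverage),
                            x$source_coverage), collapse = " ")))
  invisible(x)
}
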
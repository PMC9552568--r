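#' @importFrom dplyr %>% mutate filter select arrange bind_rows left_join group_by summarise ungroup n
#' @importFrom rlang .data
NULL

source_levels <- c("NBS", "CLINIC", "MEDICAID", "HOSPITAL_ED", "DEATH")
genotype_levels <- c("SS_Sb0", "Sb_plus", "SC", "OTHER_SCD", "NONE")

#' @noRd
name_pool <- function(which = c("first", "last")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_names.txt"),
                      package = "scdlink", mustWork = TRUE)
  readLines(path)
}

#' @noRd
zip_pool <- function() sprintf("30%03d", seq_len(60) * 7)

# Uniform draw of a date in [lo, hi], elementwise.
#' @noRd
runif_date <- function(lo, hi) {
  lo + floor(stats::runif(length(lo)) * (as.numeric(hi - lo) + 1))
}

#' Generate the ground-truth synthetic population
#'
#' Draws a seeded population with true SCD status, genotype, sex, birth and
#' (possibly) death dates, in-state residence years under annual memoryless
#' migration, and one clean identity per person. The truth table is the
#' reference against which the linkage and case-classification pipeline is
#' evaluated; source extracts derived from it carry corrupted copies of the
#' identifiers.
#'
#' @param config A [generator_config()].
#' @return Tibble with one row per person: `true_id`, `has_scd`, `genotype`,
#'   `sex`, `birth_date`, `death_date`, `born_in_state`, `residence_years`
#'   (list of in-state calendar years within the period), and the clean
#'   identity fields `first_name`, `last_name`, `ssn`, `zip`.
#' @examples
#' truth <- generate_truth(generator_config(n_population = 100, seed = 7))
#' @export
generate_truth <- function(config) {
  if (!inherits(config, "scd_generator_config")) {
    scdlink_abort("`config` must come from generator_config()",
                  class = "scdlink_config_error")
  }
  set.seed(config$seed)
  n <- config$n_population
  years <- seq(config$period[1], config$period[2])
  if (n == 0L) {
    return(tibble::tibble(
      true_id = character(), has_scd = logical(), genotype = character(),
      sex = character(), birth_date = as.Date(character()),
      death_date = as.Date(character()), born_in_state = logical(),
      residence_years = list(), first_name = character(),
      last_name = character(), ssn = character(), zip = character()
    ))
  }

  has_scd <- stats::runif(n) < config$scd_prevalence
  genotype <- rep("NONE", n)
  if (any(has_scd)) {
    genotype[has_scd] <- sample(names(config$genotype_props),
                                sum(has_scd), replace = TRUE,
                                prob = config$genotype_props)
  }
  sex <- sample(c("M", "F"), n, replace = TRUE)
  b0 <- as.Date(sprintf("%d-01-01", config$birth_year_range[1]))
  b1 <- as.Date(sprintf("%d-12-31", config$birth_year_range[2]))
  birth_date <- runif_date(rep(b0, n), rep(b1, n))
  born_in_state <- stats::runif(n) < config$born_in_state_prob

  # Annual in-state residence as a memoryless two-state chain.
  birth_year <- year_of(birth_date)
  in_state <- matrix(FALSE, n, length(years))
  prev <- ifelse(born_in_state, TRUE, stats::runif(n) < 0.6)
  for (j in seq_along(years)) {
    u <- stats::runif(n)
    cur <- ifelse(prev, u >= config$migration_rates[["outflow"]],
                  u < config$migration_rates[["inflow"]])
    cur[birth_year > years[j]] <- FALSE # not yet born
    # a person born mid-period enters in state per born_in_state
    entering <- birth_year == years[j]
    cur[entering] <- born_in_state[entering] | cur[entering]
    in_state[, j] <- cur
    prev <- cur
  }

  # Death within the surveillance period: flat annual hazard by case status.
  death_date <- as.Date(rep(NA_character_, n))
  hazard <- ifelse(has_scd, config$death_hazard[["case"]],
                   config$death_hazard[["noncase"]])
  alive <- rep(TRUE, n)
  for (j in seq_along(years)) {
    eligible <- alive & birth_year <= years[j]
    dies <- eligible & stats::runif(n) < hazard
    if (any(dies)) {
      lo <- pmax(as.Date(sprintf("%d-01-01", years[j])), birth_date[dies])
      hi <- rep(as.Date(sprintf("%d-12-31", years[j])), sum(dies))
      death_date[dies] <- runif_date(lo, hi)
      alive[dies] <- FALSE
    }
  }
  death_year <- year_of(death_date)

  residence_years <- lapply(seq_len(n), function(i) {
    ok <- in_state[i, ] & years >= birth_year[i] &
      (is.na(death_year[i]) | years <= death_year[i])
    as.integer(years[ok])
  })

  tibble::tibble(
    true_id = sprintf("T%06d", seq_len(n)),
    has_scd = has_scd,
    genotype = genotype,
    sex = sex,
    birth_date = birth_date,
    death_date = death_date,
    born_in_state = born_in_state,
    residence_years = residence_years,
    first_name = sample(name_pool("first"), n, replace = TRUE),
    last_name = sample(name_pool("last"), n, replace = TRUE),
    ssn = sprintf("%09d", sample.int(999999999L, n)),
    zip = sample(zip_pool(), n, replace = TRUE)
  )
}

#' Corrupt an identifier set
#'
#' Applies the generator's noise model independently per field using the
#' current RNG stream: missingness (explicit `NA`, never a sentinel value),
#' single-character typos in names/SSN/ZIP, day/month transposition in the
#' date of birth (applied only when the day is a valid month number), and
#' last-name substitution from the shipped name pool. Fields not selected by
#' the corruption draw are returned byte-identical.
#'
#' @param ids Tibble/data frame with columns `first_name`, `last_name`,
#'   `dob` (Date), `ssn`, `sex`, `zip`; one row per record.
#' @param rates Named list of per-field probabilities, as in
#'   [default_corruption_rates()].
#' @return A tibble of the same shape with noise applied.
#' @export
corrupt_identifiers <- function(ids, rates = default_corruption_rates()) {
  ids <- tibble::as_tibble(ids)
  n <- nrow(ids)
  if (n == 0L) return(ids)
  r <- utils::modifyList(default_corruption_rates(), as.list(rates))
  draw <- function(p) stats::runif(n) < p

  typo <- function(x, sel, alphabet) {
    for (i in which(sel & !is.na(x) & nchar(x) > 0)) {
      pos <- sample.int(nchar(x[i]), 1)
      old <- substr(x[i], pos, pos)
      repl <- sample(setdiff(alphabet, old), 1)
      substr(x[i], pos, pos) <- repl
    }
    x
  }

  out <- ids
  out$first_name <- typo(out$first_name, draw(r$first_name_typo), LETTERS)
  out$last_name <- typo(out$last_name, draw(r$last_name_typo), LETTERS)
  sub_sel <- draw(r$last_name_substitute)
  if (any(sub_sel)) {
    pool <- name_pool("last")
    out$last_name[sub_sel] <- vapply(which(sub_sel), function(i) {
      sample(setdiff(pool, out$last_name[i]), 1)
    }, character(1))
  }
  tr_sel <- draw(r$dob_transpose) & !is.na(out$dob)
  if (any(tr_sel)) {
    lt <- as.POSIXlt(out$dob[tr_sel])
    ok <- lt$mday <= 12 # transposed value must still be a valid month
    swapped <- as.Date(ifelse(ok,
      sprintf("%04d-%02d-%02d", lt$year + 1900, lt$mday, lt$mon + 1),
      format(out$dob[tr_sel])))
    out$dob[tr_sel] <- swapped
  }
  out$ssn <- typo(out$ssn, draw(r$ssn_typo), as.character(0:9))
  out$zip <- typo(out$zip, draw(r$zip_typo), as.character(0:9))
  out$first_name[draw(r$first_name_missing)] <- NA_character_
  out$last_name[draw(r$last_name_missing)] <- NA_character_
  out$dob[draw(r$dob_missing)] <- as.Date(NA)
  out$ssn[draw(r$ssn_missing)] <- NA_character_
  out$sex[draw(r$sex_missing)] <- NA_character_
  out$zip[draw(r$zip_missing)] <- NA_character_
  out
}

# 0-row record frame with the uniform source-record schema.
#' @noRd
empty_records <- function() {
  tibble::tibble(
    record_id = character(), source = character(),
    first_name = character(), last_name = character(),
    dob = as.Date(character()), ssn = character(), sex = character(),
    zip = character(), event_date = as.Date(character()),
    code_system = character(), diagnosis_codes = character(),
    lab_confirmed = logical(), genotype_result = character(),
    enrollment_months = integer(), true_id = character()
  )
}

#' @noRd
scd_code_pool <- function(system) {
  if (system == "ICD9") {
    c("282.41", "282.42", "282.6", "282.61", "282.62",
      "282.63", "282.64", "282.68", "282.69")
  } else {
    c("D57", "D57.00", "D57.01", "D57.1", "D57.20", "D57.219",
      "D57.40", "D57.419", "D57.80", "D57.811")
  }
}

#' @noRd
trait_code_for <- function(system) ifelse(system == "ICD9", "282.5", "D57.3")

# Draw diagnosis-code strings for encounters dated `dates`. ICD-9-CM before
# the 2015-10-01 transition, ICD-10-CM after. A share of codes is emitted in
# the pointless claims dialect ("28261") to exercise normalization downstream.
#' @noRd
draw_codes <- function(dates, trait_only = FALSE, extra_trait_rate = 0.05,
                       unpointed_rate = 0.3) {
  n <- length(dates)
  system <- ifelse(dates < as.Date("2015-10-01"), "ICD9", "ICD10")
  codes <- character(n)
  for (s in c("ICD9", "ICD10")) {
    k <- system == s
    if (!any(k)) next
    codes[k] <- if (trait_only) {
      rep(trait_code_for(s), sum(k))
    } else {
      sample(scd_code_pool(s), sum(k), replace = TRUE)
    }
  }
  if (!trait_only) {
    extra <- stats::runif(n) < extra_trait_rate
    codes[extra] <- paste(codes[extra], trait_code_for(system[extra]), sep = ";")
  }
  strip <- stats::runif(n) < unpointed_rate
  codes[strip] <- gsub(".", "", codes[strip], fixed = TRUE)
  list(system = system, codes = codes)
}

# Expand person rows to (person, year) rows over their residence years.
#' @noRd
person_year_grid <- function(truth) {
  k <- lengths(truth$residence_years)
  tibble::tibble(
    idx = rep(seq_len(nrow(truth)), k),
    year = as.integer(unlist(truth$residence_years))
  )
}

# Encounter dates within a (person, year) row, bounded by birth and death.
#' @noRd
encounter_dates <- function(truth, grid) {
  lo <- pmax(as.Date(sprintf("%d-01-01", grid$year)),
             truth$birth_date[grid$idx])
  hi <- as.Date(sprintf("%d-12-31", grid$year))
  dd <- truth$death_date[grid$idx]
  hi <- pmin(hi, dplyr::coalesce(dd, hi))
  runif_date(lo, hi)
}

#' Emit the five synthetic source-record files
#'
#' Derives the newborn-screening, clinic, Medicaid/CHIP, hospital/ED and
#' death-certificate extracts from a truth population: each source captures a
#' partial, overlapping slice of the true case population; longitudinal
#' sources carry Poisson encounter histories with SCD diagnosis codes;
#' a small fraction of non-cases accrues stray trait (and occasionally SCD)
#' codes; some Medicaid encounters are double-billed to the hospital file on
#' the same date; and every emitted identifier set passes through
#' [corrupt_identifiers()]. The hidden `true_id` key is carried only in the
#' bundle's provenance table, never in the written source files.
#'
#' @param truth Output of [generate_truth()].
#' @param config The same [generator_config()] used to generate `truth`.
#' @return An object of class `scd_source_bundle`: a list with `truth`,
#'   `sources` (named list of record tibbles), `provenance` (record to
#'   true-person crosswalk) and `config`.
#' @examples
#' cfg <- generator_config(n_population = 200, seed = 3)
#' bundle <- emit_source_records(generate_truth(cfg), cfg)
#' @export
emit_source_records <- function(truth, config) {
  if (!inherits(config, "scd_generator_config")) {
    scdlink_abort("`config` must come from generator_config()",
                  class = "scdlink_config_error")
  }
  set.seed(config$seed + 1L)
  cov <- config$source_coverage
  cases <- which(truth$has_scd)
  base <- empty_records()

  identity_of <- function(idx) {
    tibble::tibble(first_name = truth$first_name[idx],
                   last_name = truth$last_name[idx],
                   dob = truth$birth_date[idx],
                   ssn = truth$ssn[idx],
                   sex = truth$sex[idx],
                   zip = truth$zip[idx])
  }

  make_records <- function(idx, source, event_date, code_system = NA_character_,
                           diagnosis_codes = NA_character_,
                           lab_confirmed = NA, genotype_result = NA_character_,
                           enrollment_months = NA_integer_) {
    if (length(idx) == 0L) return(base)
    ids <- corrupt_identifiers(identity_of(idx), config$corruption_rates)
    tibble::tibble(
      record_id = NA_character_, source = source,
      first_name = ids$first_name, last_name = ids$last_name,
      dob = ids$dob, ssn = ids$ssn, sex = ids$sex, zip = ids$zip,
      event_date = event_date,
      code_system = rep_len(code_system, length(idx)),
      diagnosis_codes = rep_len(diagnosis_codes, length(idx)),
      lab_confirmed = rep_len(lab_confirmed, length(idx)),
      genotype_result = rep_len(genotype_result, length(idx)),
      enrollment_months = rep_len(enrollment_months, length(idx)),
      true_id = truth$true_id[idx]
    )
  }

  ## Newborn screening: screen-positive births in state, in period, after the
  ## NBS program start.
  birth_year <- year_of(truth$birth_date)
  nbs_idx <- intersect(cases, which(
    truth$born_in_state &
      birth_year >= max(config$nbs_start_year, config$period[1]) &
      birth_year <= config$period[2]))
  nbs_idx <- nbs_idx[stats::runif(length(nbs_idx)) < cov[["NBS"]]]
  nbs <- make_records(nbs_idx, "NBS", truth$birth_date[nbs_idx],
                      lab_confirmed = stats::runif(length(nbs_idx)) <
                        config$nbs_confirm_prob,
                      genotype_result = truth$genotype[nbs_idx])

  ## Clinic case reports: captured cases with any in-state residence, plus a
  ## rare stream of false reports from non-cases.
  res_n <- lengths(truth$residence_years)
  clin_idx <- cases[stats::runif(length(cases)) < cov[["CLINIC"]]]
  clin_idx <- clin_idx[res_n[clin_idx] > 0]
  clin_year <- vapply(clin_idx, function(i) {
    yrs <- truth$residence_years[[i]]
    yrs[sample.int(length(yrs), 1)]
  }, integer(1))
  clin_dates <- encounter_dates(truth, tibble::tibble(idx = clin_idx,
                                                      year = clin_year))
  clin_lab <- stats::runif(length(clin_idx)) < config$clinic_lab_prob
  clin_gt <- ifelse(stats::runif(length(clin_idx)) < config$clinic_genotype_prob,
                    truth$genotype[clin_idx], NA_character_)
  clinic <- make_records(clin_idx, "CLINIC", clin_dates,
                         lab_confirmed = clin_lab, genotype_result = clin_gt)
  false_idx <- setdiff(which(!truth$has_scd & res_n > 0), integer(0))
  false_idx <- false_idx[stats::runif(length(false_idx)) < config$clinic_false_rate]
  if (length(false_idx)) {
    fy <- vapply(false_idx, function(i) {
      yrs <- truth$residence_years[[i]]
      yrs[sample.int(length(yrs), 1)]
    }, integer(1))
    fd <- encounter_dates(truth, tibble::tibble(idx = false_idx, year = fy))
    clinic <- bind_rows(clinic,
                        make_records(false_idx, "CLINIC", fd,
                                     lab_confirmed = FALSE))
  }

  ## Longitudinal claims: Poisson encounters per captured case per resident
  ## year, every encounter carrying at least one SCD code.
  claims_for <- function(src) {
    keep <- cases[stats::runif(length(cases)) < cov[[src]]]
    grid <- person_year_grid(truth[keep, , drop = FALSE])
    if (nrow(grid) == 0L) return(base)
    grid$idx <- keep[grid$idx]
    k <- stats::rpois(nrow(grid), config$encounter_rate)
    enc <- grid[rep.int(seq_len(nrow(grid)), k), , drop = FALSE]
    if (nrow(enc) == 0L) return(base)
    enc$date <- encounter_dates(truth, enc)
    dx <- draw_codes(enc$date)
    months <- NA_integer_
    if (src == "MEDICAID") {
      months <- pmin(12L, pmax(1L, 12L - as.POSIXlt(
        pmax(as.Date(sprintf("%d-01-01", enc$year)),
             truth$birth_date[enc$idx]))$mon))
    }
    make_records(enc$idx, src, enc$date, code_system = dx$system,
                 diagnosis_codes = dx$codes, enrollment_months = months)
  }
  medicaid <- claims_for("MEDICAID")
  hospital <- claims_for("HOSPITAL_ED")

  # duplicate billing: one event surfacing in both claims systems, same date
  if (nrow(medicaid) > 0 && config$dup_billing_rate > 0) {
    dup <- which(stats::runif(nrow(medicaid)) < config$dup_billing_rate)
    if (length(dup)) {
      idx <- match(medicaid$true_id[dup], truth$true_id)
      dup_rec <- make_records(idx, "HOSPITAL_ED", medicaid$event_date[dup],
                              code_system = medicaid$code_system[dup],
                              diagnosis_codes = medicaid$diagnosis_codes[dup])
      hospital <- bind_rows(hospital, dup_rec)
    }
  }

  ## Miscoded non-cases: 1-2 stray trait-coded (occasionally SCD-coded)
  ## encounters, feeding the possible-case tier.
  mis_idx <- which(!truth$has_scd & res_n > 0)
  mis_idx <- mis_idx[stats::runif(length(mis_idx)) < config$miscode_rate]
  for (i in mis_idx) {
    n_enc <- sample.int(2L, 1)
    yrs <- truth$residence_years[[i]]
    ys <- yrs[sample.int(length(yrs), n_enc, replace = TRUE)]
    dts <- encounter_dates(truth, tibble::tibble(idx = rep(i, n_enc), year = ys))
    as_scd <- stats::runif(1) < config$miscode_scd_share
    dx <- draw_codes(dts, trait_only = !as_scd)
    src <- sample(c("MEDICAID", "HOSPITAL_ED"), n_enc, replace = TRUE)
    for (s in unique(src)) {
      sel <- src == s
      rec <- make_records(rep(i, sum(sel)), s, dts[sel],
                          code_system = dx$system[sel],
                          diagnosis_codes = dx$codes[sel],
                          enrollment_months = if (s == "MEDICAID") 12L else NA_integer_)
      if (s == "MEDICAID") medicaid <- bind_rows(medicaid, rec)
      else hospital <- bind_rows(hospital, rec)
    }
  }

  ## Death certificates: in-period, in-state deaths.
  death_year <- year_of(truth$death_date)
  dth_idx <- which(!is.na(truth$death_date) &
                     death_year >= config$period[1] &
                     death_year <= config$period[2])
  dth_idx <- dth_idx[vapply(dth_idx, function(i) {
    death_year[i] %in% truth$residence_years[[i]]
  }, logical(1))]
  dth_idx <- dth_idx[stats::runif(length(dth_idx)) < cov[["DEATH"]]]
  death <- make_records(dth_idx, "DEATH", truth$death_date[dth_idx])

  sources <- list(NBS = nbs, CLINIC = clinic, MEDICAID = medicaid,
                  HOSPITAL_ED = hospital, DEATH = death)
  prefix <- c(NBS = "NBS", CLINIC = "CLN", MEDICAID = "MED",
              HOSPITAL_ED = "HSP", DEATH = "DTH")
  for (s in names(sources)) {
    tab <- arrange(sources[[s]], .data$event_date, .data$true_id)
    if (nrow(tab)) {
      tab$record_id <- sprintf("%s%06d", prefix[[s]], seq_len(nrow(tab)))
    }
    sources[[s]] <- tab
  }
  provenance <- bind_rows(lapply(sources, function(x) {
    select(x, "record_id", "true_id")
  }))
  sources <- lapply(sources, function(x) select(x, -"true_id"))

  structure(list(truth = truth, sources = sources,
                 provenance = provenance, config = config),
            class = "scd_source_bundle")
}

#' @export
print.scd_source_bundle <- function(x, ...) {
  cat("<scd_source_bundle>\n")
  cat(sprintf("  persons: %d (%d with SCD), period %d-%d, seed %d\n",
              nrow(x$truth), sum(x$truth$has_scd),
              x$config$period[1], x$config$period[2], x$config$seed))
  for (s in names(x$sources)) {
    cat(sprintf("  %-11s %6d records\n", s, nrow(x$sources[[s]])))
  }
  invisible(x)
}

#' Write a source bundle to delimited text files
#'
#' One CSV per source (identifiers, dates and the source-applicable payload
#' columns; never the hidden truth key), plus `truth.tsv`, `provenance.tsv`
#' and a `manifest.json` recording the full generator configuration and seed.
#' Dates are ISO-8601.
#'
#' @param bundle An `scd_source_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_source_files <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    NBS = c("lab_confirmed", "genotype_result"),
    CLINIC = c("lab_confirmed", "genotype_result"),
    MEDICAID = c("code_system", "diagnosis_codes", "enrollment_months"),
    HOSPITAL_ED = c("code_system", "diagnosis_codes"),
    DEATH = character()
  )
  id_cols <- c("record_id", "first_name", "last_name", "dob", "ssn",
               "sex", "zip", "event_date")
  for (s in names(bundle$sources)) {
    tab <- bundle$sources[[s]][, c(id_cols, payload[[s]])]
    readr::write_csv(tab, file.path(dir, paste0(tolower(s), ".csv")),
                     na = "")
  }
  truth <- bundle$truth
  truth$residence_years <- vapply(truth$residence_years, paste,
                                  character(1), collapse = ";")
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), na = "")
  readr::write_tsv(bundle$provenance, file.path(dir, "provenance.tsv"))
  cfg <- unclass(bundle$config)
  cfg$corruption_rates <- as.list(cfg$corruption_rates)
  # named vectors must serialize as JSON objects, not bare arrays
  for (f in c("source_coverage", "genotype_props", "migration_rates",
              "death_hazard")) {
    cfg[[f]] <- as.list(cfg[[f]])
  }
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a source bundle back from disk
#'
#' Inverse of [write_source_files()]; reconstructs the bundle, including the
#' generator configuration from the manifest.
#'
#' @param dir Directory written by [write_source_files()].
#' @return An `scd_source_bundle`.
#' @export
read_source_files <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  manifest$source_coverage <- unlist(manifest$source_coverage)
  manifest$genotype_props <- unlist(manifest$genotype_props)
  manifest$migration_rates <- unlist(manifest$migration_rates)
  manifest$death_hazard <- unlist(manifest$death_hazard)
  config <- do.call(generator_config, manifest)
  read_one <- function(s) {
    tab <- readr::read_csv(file.path(dir, paste0(tolower(s), ".csv")),
                           col_types = readr::cols(
                             dob = readr::col_date(),
                             event_date = readr::col_date(),
                             .default = readr::col_character()),
                           na = "", progress = FALSE)
    tab$source <- s
    if ("lab_confirmed" %in% names(tab)) {
      tab$lab_confirmed <- as.logical(tab$lab_confirmed)
    }
    if ("enrollment_months" %in% names(tab)) {
      tab$enrollment_months <- as.integer(tab$enrollment_months)
    }
    miss <- setdiff(names(empty_records()), c(names(tab), "true_id"))
    for (m in miss) tab[[m]] <- empty_records()[[m]][NA_integer_]
    tab[, setdiff(names(empty_records()), "true_id")]
  }
  sources <- stats::setNames(lapply(source_levels, read_one), source_levels)
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           col_types = readr::cols(
                             birth_date = readr::col_date(),
                             death_date = readr::col_date(),
                             has_scd = readr::col_logical(),
                             born_in_state = readr::col_logical(),
                             residence_years = readr::col_character(),
                             .default = readr::col_character()),
                           na = "", progress = FALSE)
  truth$residence_years <- lapply(strsplit(
    dplyr::coalesce(truth$residence_years, ""), ";"), as.integer)
  provenance <- readr::read_tsv(file.path(dir, "provenance.tsv"),
                                col_types = "cc", progress = FALSE)
  structure(list(truth = truth, sources = sources,
                 provenance = provenance, config = config),
            class = "scd_source_bundle")
}
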
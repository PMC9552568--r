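report_sources <- c("NBS", "CLINIC", "MEDICAID", "HOSPITAL_ED")

# In-period records per (person, source, year), case-finding sources only.
#' @noRd
person_source_years <- function(index, sources, period = NULL,
                                year = NULL) {
  records <- bind_sources(sources)
  df <- left_join(index$crosswalk,
                  select(records, "record_id", "event_date",
                         "enrollment_months"),
                  by = "record_id")
  df$year <- year_of(df$event_date)
  if (!is.null(period)) {
    df <- df[!is.na(df$year) & df$year >= period[1] & df$year <= period[2], ]
  }
  if (!is.null(year)) df <- df[!is.na(df$year) & df$year == year, ]
  df
}

#' Totals and percentage columns for a prevalence table
#'
#' Applies the report arithmetic to per-source confirmed/probable counts:
#' `total = confirmed + probable` and `pct_of_dedup_total = 100 * total /
#' dedup total`, rounded half-up to one decimal (the convention of published
#' surveillance tables). The deduplicated row is identified by its `source`
#' label.
#'
#' @param counts Data frame with columns `source`, `confirmed`, `probable`.
#' @param dedup_label The `source` value marking the deduplicated row.
#' @return The input with `total` and `pct_of_dedup_total` columns filled.
#' @examples
#' prevalence_arithmetic(data.frame(
#'   source = c("NBS", "Deduplicated total"),
#'   confirmed = c(30, 50), probable = c(5, 20)))
#' @export
prevalence_arithmetic <- function(counts, dedup_label = "Deduplicated total") {
  counts <- tibble::as_tibble(counts)
  counts$total <- counts$confirmed + counts$probable
  dd <- counts$total[counts$source == dedup_label]
  if (length(dd) != 1) {
    scdlink_abort("`counts` must contain exactly one deduplicated row",
                  class = "scdlink_report_error")
  }
  counts$pct_of_dedup_total <- if (dd > 0) {
    round_half_up(100 * counts$total / dd, 1)
  } else {
    rep(NA_real_, nrow(counts))
  }
  counts
}

#' @noRd
new_report <- function(rows, type, period) {
  structure(rows, class = c("scd_prevalence_report", class(rows)),
            type = type, period = period)
}

#' Cumulative prevalence report by data source
#'
#' Counts confirmed and probable persons (possible cases are never reported)
#' by contributing data source over a period: a person counts in a source row
#' iff at least one linked record of that source is dated in-period, and once
#' only in the deduplicated row however many sources captured them.
#' Longitudinal sources also report person-years of data.
#'
#' @param index A classified `scd_index` (see [classify_index()]).
#' @param sources Named list of source record tibbles.
#' @param period `c(start_year, end_year)`.
#' @return A `scd_prevalence_report` tibble with one row per source plus the
#'   deduplicated row.
#' @export
cumulative_report <- function(index, sources, period) {
  persons <- index$persons
  counted <- persons$person_uid[persons$case_status %in%
                                  c("CONFIRMED", "PROBABLE")]
  psy <- person_source_years(index, sources, period = period)
  psy <- psy[psy$person_uid %in% counted &
               psy$source %in% report_sources, , drop = FALSE]
  status <- stats::setNames(persons$case_status, persons$person_uid)
  rows <- lapply(report_sources, function(s) {
    uids <- unique(psy$person_uid[psy$source == s])
    tibble::tibble(
      source = s,
      confirmed = sum(status[uids] == "CONFIRMED"),
      probable = sum(status[uids] == "PROBABLE"),
      person_years = if (s %in% c("MEDICAID", "HOSPITAL_ED")) {
        person_years(index, sources, s, period, counted = counted)
      } else NA_integer_
    )
  })
  dedup_uids <- unique(psy$person_uid)
  rows <- bind_rows(rows, tibble::tibble(
    source = "Deduplicated total",
    confirmed = sum(status[dedup_uids] == "CONFIRMED"),
    probable = sum(status[dedup_uids] == "PROBABLE"),
    person_years = NA_integer_))
  out <- prevalence_arithmetic(rows)[, c("source", "confirmed", "probable",
                                         "total", "pct_of_dedup_total",
                                         "person_years")]
  new_report(out, "cumulative", period)
}

#' Person-years contributed by a longitudinal source
#'
#' Sum over counted persons of the number of calendar years in-period with at
#' least one record in the source; for Medicaid, a year with positive
#' enrollment months also qualifies.
#'
#' @param index A classified `scd_index`.
#' @param sources Named list of source record tibbles.
#' @param source `"MEDICAID"` or `"HOSPITAL_ED"`.
#' @param period `c(start_year, end_year)`.
#' @param counted Optional person_uid subset (defaults to confirmed+probable
#'   persons).
#' @return Integer person-year count.
#' @export
person_years <- function(index, sources, source, period, counted = NULL) {
  if (is.null(counted)) {
    counted <- index$persons$person_uid[
      index$persons$case_status %in% c("CONFIRMED", "PROBABLE")]
  }
  df <- person_source_years(index, sources, period = period)
  df <- df[df$source == source & df$person_uid %in% counted, , drop = FALSE]
  if (source == "MEDICAID") {
    ok <- is.na(df$enrollment_months) | df$enrollment_months > 0
    df <- df[ok, , drop = FALSE]
  }
  nrow(unique(df[, c("person_uid", "year")]))
}

#' Annual prevalence report with migration adjustment
#'
#' A confirmed or probable person counts in year `Y` iff they are not known
#' dead before January 1 of `Y` and either have at least one case-finding
#' record dated in `Y`, or (under the migration adjustment) have records both
#' before and after `Y` -- evidence of in-state health care use bracketing
#' the year. Source rows count in-year records only.
#'
#' @param index A classified `scd_index`.
#' @param sources Named list of source record tibbles.
#' @param year Report year.
#' @param period Surveillance period; `year` must fall inside it.
#' @param migration_adjust If `FALSE`, only in-year evidence counts.
#' @return A `scd_prevalence_report`.
#' @export
annual_report <- function(index, sources, year, period = NULL,
                          migration_adjust = TRUE) {
  if (!is.null(period) && (year < period[1] || year > period[2])) {
    scdlink_abort(sprintf("year %d outside the surveillance period %d-%d",
                          year, period[1], period[2]),
                  class = "scdlink_report_error")
  }
  persons <- index$persons
  counted_uids <- annual_cohort(index, sources, year, migration_adjust)
  status <- stats::setNames(persons$case_status, persons$person_uid)
  psy <- person_source_years(index, sources, year = year)
  psy <- psy[psy$person_uid %in% counted_uids &
               psy$source %in% report_sources, , drop = FALSE]
  rows <- lapply(report_sources, function(s) {
    uids <- unique(psy$person_uid[psy$source == s])
    tibble::tibble(source = s,
                   confirmed = sum(status[uids] == "CONFIRMED"),
                   probable = sum(status[uids] == "PROBABLE"),
                   person_years = NA_integer_)
  })
  rows <- bind_rows(rows, tibble::tibble(
    source = "Deduplicated total",
    confirmed = sum(status[counted_uids] == "CONFIRMED"),
    probable = sum(status[counted_uids] == "PROBABLE"),
    person_years = NA_integer_))
  out <- prevalence_arithmetic(rows)[, c("source", "confirmed", "probable",
                                         "total", "pct_of_dedup_total",
                                         "person_years")]
  new_report(out, "annual", c(year, year))
}

# Confirmed/probable persons in the annual cohort for year Y.
#' @noRd
annual_cohort <- function(index, sources, year, migration_adjust = TRUE) {
  persons <- index$persons
  cp <- persons[persons$case_status %in% c("CONFIRMED", "PROBABLE"), ,
                drop = FALSE]
  # death precedence: known dead before Jan 1 of Y never counts
  alive <- is.na(cp$death_date) |
    cp$death_date >= as.Date(sprintf("%d-01-01", year))
  cp <- cp[alive, , drop = FALSE]
  df <- person_source_years(index, sources)
  df <- df[df$source != "DEATH" & df$person_uid %in% cp$person_uid, ,
           drop = FALSE]
  in_year <- unique(df$person_uid[df$year == year])
  if (!migration_adjust) return(in_year)
  before <- unique(df$person_uid[df$year < year])
  after <- unique(df$person_uid[df$year > year])
  union(in_year, intersect(before, after))
}

#' Genotype, sex and age strata by data source
#'
#' For the annual cohort of a year: the genotype distribution among confirmed
#' cases with a known genotype (four columns summing to 100 within rounding),
#' the count with unknown genotype (probable cases plus confirmed cases
#' lacking a genotype result), and the sex split and pediatric share (aged
#' 0-18 inclusive at mid-year, July 1) among all confirmed+probable persons.
#' Percentages are rounded half-up to one decimal.
#'
#' @param index A classified `scd_index`.
#' @param sources Named list of source record tibbles.
#' @param year Report year.
#' @param migration_adjust As in [annual_report()].
#' @return A tibble with one row per source plus the deduplicated row, of
#'   class `scd_stratified_report`.
#' @export
stratified_report <- function(index, sources, year, migration_adjust = TRUE) {
  persons <- index$persons
  counted_uids <- annual_cohort(index, sources, year, migration_adjust)
  psy <- person_source_years(index, sources, year = year)
  psy <- psy[psy$person_uid %in% counted_uids &
               psy$source %in% report_sources, , drop = FALSE]
  pinfo <- persons[match(counted_uids, persons$person_uid), , drop = FALSE]

  stratum_row <- function(label, uids) {
    p <- pinfo[pinfo$person_uid %in% uids, , drop = FALSE]
    conf <- p[p$case_status == "CONFIRMED", , drop = FALSE]
    known <- conf[!is.na(conf$genotype) & conf$genotype != "NONE", ,
                  drop = FALSE]
    gpct <- function(g) {
      if (nrow(known) == 0) return(NA_real_)
      round_half_up(100 * sum(known$genotype == g) / nrow(known), 1)
    }
    sex_known <- p$sex[!is.na(p$sex)]
    age <- age_at(p$birth_date[!is.na(p$birth_date)], mid_year(year))
    tibble::tibble(
      source = label,
      confirmed_n = nrow(conf),
      pct_ss_sb0 = gpct("SS_Sb0"),
      pct_sb_plus = gpct("Sb_plus"),
      pct_sc = gpct("SC"),
      pct_other_scd = gpct("OTHER_SCD"),
      unknown_genotype_n = nrow(p) - nrow(known),
      total_n = nrow(p),
      pct_male = if (length(sex_known)) {
        round_half_up(100 * mean(sex_known == "M"), 1)
      } else NA_real_,
      pct_female = if (length(sex_known)) {
        round_half_up(100 * mean(sex_known == "F"), 1)
      } else NA_real_,
      pct_aged_0_18 = if (length(age)) {
        round_half_up(100 * mean(age <= 18), 1)
      } else NA_real_
    )
  }
  rows <- lapply(report_sources, function(s) {
    stratum_row(s, unique(psy$person_uid[psy$source == s]))
  })
  rows <- bind_rows(rows, stratum_row("Deduplicated total", counted_uids))
  structure(rows, class = c("scd_stratified_report", class(rows)),
            year = year)
}

#' @export
print.scd_prevalence_report <- function(x, ...) {
  type <- attr(x, "type")
  period <- attr(x, "period")
  cat(sprintf("SCD %s prevalence report, %s\n", type,
              if (period[1] == period[2]) period[1]
              else paste(period, collapse = "-")))
  df <- as.data.frame(x)
  df$pct_of_dedup_total <- sprintf("%.1f", df$pct_of_dedup_total)
  df$person_years[is.na(df$person_years)] <- NA
  print(df, row.names = FALSE, right = TRUE)
  invisible(x)
}

#' Evaluate case finding against synthetic ground truth
#'
#' Standard 2x2 validation of the reported case set (confirmed or probable)
#' against true disease status, restricted to true persons appearing in at
#' least one source record. A true person's predicted status is the highest
#' tier among the index persons holding any of their records.
#'
#' @param index A classified `scd_index`.
#' @param truth Truth tibble from [generate_truth()].
#' @param provenance Record-to-truth crosswalk from the source bundle.
#' @return List with `counts` (tp/fp/fn/tn) and `metrics` (sensitivity,
#'   specificity, ppv, npv).
#' @export
evaluate_against_truth <- function(index, truth, provenance) {
  status_rank <- stats::setNames(seq_along(case_status_levels),
                                 case_status_levels) # CONFIRMED = 1
  person_of <- stats::setNames(index$crosswalk$person_uid,
                               index$crosswalk$record_id)
  status <- stats::setNames(index$persons$case_status,
                            index$persons$person_uid)
  df <- provenance
  df$person_uid <- unname(person_of[df$record_id])
  df$status <- unname(status[df$person_uid])
  df$rank <- status_rank[df$status]
  df$rank[is.na(df$rank)] <- length(case_status_levels) + 1L
  best <- df %>%
    group_by(.data$true_id) %>%
    summarise(rank = min(.data$rank), .groups = "drop")
  best$predicted_case <- best$rank <= status_rank[["PROBABLE"]]
  best$has_scd <- truth$has_scd[match(best$true_id, truth$true_id)]
  tp <- sum(best$predicted_case & best$has_scd)
  fp <- sum(best$predicted_case & !best$has_scd)
  fn <- sum(!best$predicted_case & best$has_scd)
  tn <- sum(!best$predicted_case & !best$has_scd)
  list(
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
    metrics = c(
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
    )
  )
}

#' Pairwise linkage quality against synthetic ground truth
#'
#' Precision, recall and F1 over record pairs: a pair of records (among those
#' linked into the index) is predicted co-referent iff both land in the same
#' index person, and truly co-referent iff both stem from the same true
#' person. Counts use the contingency of index person x true person, so no
#' pair enumeration is needed.
#'
#' @param index An `scd_index`.
#' @param provenance Record-to-truth crosswalk from the source bundle.
#' @return Named numeric vector `precision`, `recall`, `f1` (all 1 when there
#'   are no positive pairs on either side).
#' @export
linkage_metrics <- function(index, provenance) {
  df <- left_join(index$crosswalk, provenance, by = "record_id")
  choose2 <- function(n) n * (n - 1) / 2
  pred <- sum(choose2(table(df$person_uid)))
  true <- sum(choose2(table(df$true_id)))
  tp <- sum(choose2(table(paste(df$person_uid, df$true_id))))
  precision <- if (pred > 0) tp / pred else 1
  recall <- if (true > 0) tp / true else 1
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}
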
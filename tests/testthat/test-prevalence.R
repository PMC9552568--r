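dt <- function(...) as.Date(c(...))

# Small hand-built classified index: three confirmed, one probable, one
# possible, one uncounted NONE person.
fixture_index <- function() {
  make_index(list(
    list(status = "CONFIRMED", genotype = "SS_Sb0", sex = "M",
         birth_date = as.Date("2005-07-01"),
         records = make_records(2, record_id = c("N1", "M1"),
                                source = c("NBS", "MEDICAID"),
                                event_date = dt("2005-07-01", "2010-03-01"))),
    list(status = "CONFIRMED", genotype = "SS_Sb0", sex = "F",
         birth_date = as.Date("1980-01-01"),
         records = make_records(2, record_id = c("M2", "M3"),
                                source = c("MEDICAID", "MEDICAID"),
                                event_date = dt("2010-05-05", "2012-06-06"))),
    list(status = "CONFIRMED", genotype = "SC", sex = "F",
         birth_date = as.Date("1992-06-30"),
         records = make_records(1, record_id = "H1", source = "HOSPITAL_ED",
                                event_date = dt("2011-01-01"))),
    list(status = "PROBABLE", sex = "M", birth_date = as.Date("1970-01-01"),
         records = make_records(2, record_id = c("H2", "C1"),
                                source = c("HOSPITAL_ED", "CLINIC"),
                                event_date = dt("2009-09-09", "2013-02-02"))),
    list(status = "POSSIBLE", sex = "F",
         records = make_records(1, record_id = "H3", source = "HOSPITAL_ED",
                                event_date = dt("2010-10-10"))),
    list(status = "NONE", sex = "M",
         records = make_records(1, record_id = "H4", source = "HOSPITAL_ED",
                                event_date = dt("2010-11-11")))
  ))
}

fixture_sources <- function(index) {
  # rebuild per-source record tibbles from the fixture crosswalk
  recs <- dplyr::bind_rows(
    make_records(2, record_id = c("N1", "M1"), source = c("NBS", "MEDICAID"),
                 event_date = dt("2005-07-01", "2010-03-01")),
    make_records(2, record_id = c("M2", "M3"),
                 source = c("MEDICAID", "MEDICAID"),
                 event_date = dt("2010-05-05", "2012-06-06")),
    make_records(1, record_id = "H1", source = "HOSPITAL_ED",
                 event_date = dt("2011-01-01")),
    make_records(2, record_id = c("H2", "C1"),
                 source = c("HOSPITAL_ED", "CLINIC"),
                 event_date = dt("2009-09-09", "2013-02-02")),
    make_records(1, record_id = "H3", source = "HOSPITAL_ED",
                 event_date = dt("2010-10-10")),
    make_records(1, record_id = "H4", source = "HOSPITAL_ED",
                 event_date = dt("2010-11-11")))
  split(recs, recs$source)
}

test_that("cumulative reports count confirmed+probable once per dedup row", {
  index <- fixture_index()
  sources <- fixture_sources(index)
  rpt <- cumulative_report(index, sources, c(2004, 2018))
  row <- function(s) rpt[rpt$source == s, ]
  expect_identical(row("NBS")$total, 1L)
  expect_identical(row("MEDICAID")$total, 2L)
  expect_identical(row("HOSPITAL_ED")$confirmed, 1L)
  expect_identical(row("HOSPITAL_ED")$probable, 1L)
  dd <- row("Deduplicated total")
  expect_identical(dd$confirmed, 3L)
  expect_identical(dd$probable, 1L)
  expect_identical(dd$total, 4L) # possible and none excluded
  expect_identical(dd$pct_of_dedup_total, 100)
  # conservation: per-source totals never exceed and overlaps never inflate
  expect_true(all(rpt$total == rpt$confirmed + rpt$probable))
  expect_lte(dd$total, sum(rpt$total[rpt$source != "Deduplicated total"]))
  # NBS record dated outside the window drops out
  late <- cumulative_report(index, sources, c(2009, 2018))
  expect_identical(late[late$source == "NBS", ]$total, 0L)
})

test_that("an all-possible index reports zeros", {
  index <- make_index(list(
    list(status = "POSSIBLE",
         records = make_records(1, record_id = "H1", source = "HOSPITAL_ED",
                                event_date = dt("2010-01-01")))))
  rpt <- cumulative_report(index, fixture_sources(index)["HOSPITAL_ED"],
                           c(2004, 2018))
  expect_true(all(rpt$total == 0))
})

test_that("person-years count calendar years with source evidence", {
  index <- fixture_index()
  sources <- fixture_sources(index)
  # P2 has Medicaid records in 2010 and 2012 -> 2; P1 in 2010 -> 1
  expect_identical(person_years(index, sources, "MEDICAID", c(2004, 2018)), 3L)
  expect_identical(person_years(index, sources, "MEDICAID", c(2011, 2018)), 1L)
  # counted persons only: the possible-tier person's 2010 record is excluded
  expect_identical(
    person_years(index, sources, "HOSPITAL_ED", c(2004, 2018)), 2L)
  # restricting to one person
  expect_identical(person_years(index, sources, "MEDICAID", c(2004, 2018),
                                counted = "P000002"), 2L)
})

test_that("annual counts apply the migration adjustment and death precedence", {
  index <- make_index(list(
    # records bracketing 2011 but none in it: counted under adjustment
    list(status = "CONFIRMED",
         records = make_records(2, record_id = c("M1", "M2"),
                                source = "MEDICAID",
                                event_date = dt("2009-01-01", "2012-01-01"))),
    # records only before 2011: not counted
    list(status = "CONFIRMED",
         records = make_records(1, record_id = "M3", source = "MEDICAID",
                                event_date = dt("2010-06-06"))),
    # died in 2010; a stray 2011 claim cannot resurrect them
    list(status = "PROBABLE", death_date = as.Date("2010-08-08"),
         records = make_records(2, record_id = c("M4", "M5"),
                                source = "MEDICAID",
                                event_date = dt("2009-03-03", "2011-04-04")))
  ))
  sources <- list(MEDICAID = dplyr::bind_rows(
    make_records(2, record_id = c("M1", "M2"), source = "MEDICAID",
                 event_date = dt("2009-01-01", "2012-01-01")),
    make_records(1, record_id = "M3", source = "MEDICAID",
                 event_date = dt("2010-06-06")),
    make_records(2, record_id = c("M4", "M5"), source = "MEDICAID",
                 event_date = dt("2009-03-03", "2011-04-04"))))
  rpt <- annual_report(index, sources, 2011, period = c(2004, 2018))
  dd <- rpt[rpt$source == "Deduplicated total", ]
  expect_identical(dd$total, 1L)
  expect_identical(dd$confirmed, 1L)
  # without the adjustment the bracketed person drops out too
  raw <- annual_report(index, sources, 2011, migration_adjust = FALSE)
  expect_identical(raw[raw$source == "Deduplicated total", ]$total, 0L)
  expect_error(annual_report(index, sources, 2030, period = c(2004, 2018)),
               class = "scdlink_report_error")
})

test_that("strata compute genotype splits, sex and the inclusive 0-18 bound", {
  index <- make_index(list(
    list(status = "CONFIRMED", genotype = "SS_Sb0", sex = "M",
         birth_date = as.Date("1992-07-01"), # aged exactly 18 at mid-2010
         records = make_records(1, record_id = "M1", source = "MEDICAID",
                                event_date = dt("2010-01-01"))),
    list(status = "CONFIRMED", genotype = "SS_Sb0", sex = "F",
         birth_date = as.Date("1991-07-02"), # 18 until July 2, so 18 at Jul 1
         records = make_records(1, record_id = "M2", source = "MEDICAID",
                                event_date = dt("2010-02-01"))),
    list(status = "CONFIRMED", genotype = "SC", sex = "F",
         birth_date = as.Date("1960-01-01"),
         records = make_records(1, record_id = "M3", source = "MEDICAID",
                                event_date = dt("2010-03-01"))),
    list(status = "CONFIRMED", genotype = "Sb_plus", sex = "F",
         birth_date = as.Date("1991-06-30"), # turned 19 before mid-year
         records = make_records(1, record_id = "M4", source = "MEDICAID",
                                event_date = dt("2010-04-01")))
  ))
  sources <- list(MEDICAID = make_records(4,
    record_id = c("M1", "M2", "M3", "M4"), source = "MEDICAID",
    event_date = dt("2010-01-01", "2010-02-01", "2010-03-01", "2010-04-01")))
  st <- stratified_report(index, sources, 2010)
  dd <- st[st$source == "Deduplicated total", ]
  expect_identical(dd$pct_ss_sb0, 50)
  expect_identical(dd$pct_sc, 25)
  expect_identical(dd$pct_sb_plus, 25)
  expect_identical(dd$pct_other_scd, 0)
  expect_identical(dd$pct_male, 25)
  expect_identical(dd$pct_female, 75)
  expect_identical(dd$pct_male + dd$pct_female, 100)
  expect_identical(dd$pct_aged_0_18, 50) # the two aged exactly 18 count
  expect_identical(dd$unknown_genotype_n, 0L)
})

test_that("probable cases and confirmed without genotype feed the unknown column", {
  index <- make_index(list(
    list(status = "CONFIRMED", genotype = "SS_Sb0",
         records = make_records(1, record_id = "M1", source = "MEDICAID",
                                event_date = dt("2010-01-01"))),
    list(status = "CONFIRMED", genotype = NA_character_,
         records = make_records(1, record_id = "M2", source = "MEDICAID",
                                event_date = dt("2010-02-01"))),
    list(status = "PROBABLE",
         records = make_records(1, record_id = "M3", source = "MEDICAID",
                                event_date = dt("2010-03-01")))
  ))
  sources <- list(MEDICAID = make_records(3,
    record_id = c("M1", "M2", "M3"), source = "MEDICAID",
    event_date = dt("2010-01-01", "2010-02-01", "2010-03-01")))
  st <- stratified_report(index, sources, 2010)
  dd <- st[st$source == "Deduplicated total", ]
  expect_identical(dd$confirmed_n, 2L)
  expect_identical(dd$unknown_genotype_n, 2L)
  expect_identical(dd$pct_ss_sb0, 100)
})

test_that("truth evaluation reproduces a hand-computed 2x2 table", {
  # 20 true persons: 8 cases (6 found confirmed/probable, 2 missed),
  # 12 non-cases (3 flagged, 9 clean)
  status <- c(rep("CONFIRMED", 4), rep("PROBABLE", 2), rep("POSSIBLE", 2),
              rep("PROBABLE", 3), rep("NONE", 9))
  truth <- tibble::tibble(
    true_id = sprintf("T%02d", 1:20),
    has_scd = c(rep(TRUE, 8), rep(FALSE, 12)))
  spec <- lapply(1:20, function(k) {
    list(status = status[k],
         records = make_records(1, record_id = sprintf("R%02d", k),
                                source = "MEDICAID",
                                event_date = as.Date("2010-01-01")))
  })
  index <- make_index(spec)
  provenance <- tibble::tibble(record_id = sprintf("R%02d", 1:20),
                               true_id = sprintf("T%02d", 1:20))
  ev <- evaluate_against_truth(index, truth, provenance)
  expect_identical(unname(ev$counts), c(6L, 3L, 2L, 9L))
  expect_equal(unname(ev$metrics),
               c(6 / 8, 9 / 12, 6 / 9, 9 / 11), tolerance = 1e-12)
})

test_that("a classifier that flags everyone has sensitivity 1, specificity 0", {
  truth <- tibble::tibble(true_id = sprintf("T%02d", 1:10),
                          has_scd = rep(c(TRUE, FALSE), 5))
  spec <- lapply(1:10, function(k) {
    list(status = "PROBABLE",
         records = make_records(1, record_id = sprintf("R%02d", k),
                                source = "MEDICAID",
                                event_date = as.Date("2010-01-01")))
  })
  ev <- evaluate_against_truth(
    make_index(spec), truth,
    tibble::tibble(record_id = sprintf("R%02d", 1:10),
                   true_id = sprintf("T%02d", 1:10)))
  expect_identical(unname(ev$metrics[c("sensitivity", "specificity")]),
                   c(1, 0))
})

test_that("percent cells use half-up rounding at one decimal", {
  expect_identical(round_half_up(c(0.15, 0.25, 2.345, -0.15), 1),
                   c(0.2, 0.3, 2.3, -0.2))
  counts <- tibble::tibble(source = c("NBS", "Deduplicated total"),
                           confirmed = c(1, 40), probable = c(0, 41))
  out <- prevalence_arithmetic(counts)
  # 1/81 = 1.2345..% -> 1.2
  expect_identical(out$pct_of_dedup_total[1], 1.2)
  expect_error(prevalence_arithmetic(counts[1, ]),
               class = "scdlink_report_error")
})
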
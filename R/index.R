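id_fields <- c("first_name", "last_name", "dob", "ssn", "sex", "zip")
source_priority_default <- c("NBS", "CLINIC", "MEDICAID", "HOSPITAL_ED", "DEATH")

# Most frequent non-missing value; ties broken lexicographically for
# determinism.
#' @noRd
modal_chr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  tab <- table(x)
  sort(names(tab)[tab == max(tab)])[1]
}

#' @noRd
modal_date <- function(x) as.Date(modal_chr(format(x)))

#' @noRd
bind_sources <- function(sources) {
  dplyr::bind_rows(sources)
}

# Long (record_id, system, code) table from the ';'-packed diagnosis column,
# normalized for the implicit-decimal claims dialect.
#' @noRd
codes_long <- function(records) {
  has <- !is.na(records$diagnosis_codes) & nzchar(records$diagnosis_codes)
  if (!any(has)) {
    return(tibble::tibble(record_id = character(), system = character(),
                          code = character(), category = character()))
  }
  parts <- strsplit(records$diagnosis_codes[has], ";", fixed = TRUE)
  k <- lengths(parts)
  long <- tibble::tibble(
    record_id = rep(records$record_id[has], k),
    system = rep(records$code_system[has], k),
    code = unlist(parts)
  )
  long$code <- normalize_icd(long$system, long$code)
  long$category <- tryCatch(
    classify_icd(long$system, long$code),
    scdlink_code_error = function(e) {
      bad <- which(!icd_syntax_ok(long$system, long$code) | is.na(long$code))
      rec <- if (length(bad)) long$record_id[bad[1]] else long$record_id[1]
      scdlink_abort(sprintf("record %s: %s", rec, conditionMessage(e)),
                    class = "scdlink_code_error")
    })
  long
}

# Per-record sickle-code indicators used by the admin filter and by evidence
# assembly.
#' @noRd
record_code_flags <- function(records) {
  long <- codes_long(records)
  flags <- long %>%
    group_by(.data$record_id) %>%
    summarise(has_scd_code = any(.data$category == "SCD"),
              has_trait_code = any(.data$category == "TRAIT"),
              .groups = "drop")
  out <- tibble::tibble(record_id = records$record_id)
  out <- left_join(out, flags, by = "record_id")
  out$has_scd_code[is.na(out$has_scd_code)] <- FALSE
  out$has_trait_code[is.na(out$has_trait_code)] <- FALSE
  out
}

#' Clean and deduplicate one source file
#'
#' First step of the index pipeline: malformed records (missing or duplicated
#' record id, missing or out-of-period event date, or no usable identifiers at
#' all) are quarantined with a reason -- never silently dropped -- and the
#' remaining records are deduplicated with the linkage engine, yielding one
#' entity per within-source person cluster with modal representative
#' identifiers.
#'
#' @param records One source's record tibble.
#' @param config A [linkage_config()].
#' @param period Optional `c(start_year, end_year)`; when given, records dated
#'   outside it are quarantined.
#' @return List with `entities` (entity_id, representative identifiers,
#'   `record_ids` list-column), `quarantine` (records + `reason`), and the
#'   linkage `decisions` audit tibble.
#' @export
dedupe_source <- function(records, config = linkage_config(), period = NULL) {
  records <- tibble::as_tibble(records)
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$record_id)] <- "missing record_id"
  dup <- duplicated(records$record_id) |
    duplicated(records$record_id, fromLast = TRUE)
  reason[dup & is.na(reason)] <- "duplicated record_id"
  reason[is.na(records$event_date) & is.na(reason)] <- "missing event_date"
  if (!is.null(period)) {
    yr <- year_of(records$event_date)
    out <- !is.na(yr) & (yr < period[1] | yr > period[2])
    reason[out & is.na(reason)] <- "event_date outside surveillance period"
  }
  core_missing <- is.na(records$first_name) & is.na(records$last_name) &
    is.na(records$dob) & is.na(records$ssn)
  reason[core_missing & is.na(reason)] <- "no usable identifiers"
  quarantine <- records[!is.na(reason), , drop = FALSE]
  quarantine$reason <- reason[!is.na(reason)]
  good <- records[is.na(reason), , drop = FALSE]

  if (nrow(good) == 0L) {
    return(list(entities = empty_entities(), quarantine = quarantine,
                decisions = NULL))
  }
  lr <- link_records(good, config)
  df <- left_join(good, lr$clusters, by = "record_id")
  entities <- df %>%
    group_by(.data$cluster) %>%
    summarise(
      entity_id = paste0("E-", min(.data$record_id)),
      source = .data$source[1],
      first_name = modal_chr(.data$first_name),
      last_name = modal_chr(.data$last_name),
      dob = modal_date(.data$dob),
      ssn = modal_chr(.data$ssn),
      sex = modal_chr(.data$sex),
      zip = modal_chr(.data$zip),
      record_ids = list(sort(.data$record_id)),
      .groups = "drop") %>%
    select(-"cluster") %>%
    arrange(.data$entity_id)
  list(entities = entities, quarantine = quarantine,
       decisions = lr$decisions)
}

#' @noRd
empty_entities <- function() {
  tibble::tibble(entity_id = character(), source = character(),
                 first_name = character(), last_name = character(),
                 dob = as.Date(character()), ssn = character(),
                 sex = character(), zip = character(), record_ids = list())
}

# Link entity tables (entities act as records keyed by entity_id) and fold
# clusters into merged entities. `cross_only` restricts match decisions to
# pairs whose `stratum` differs, for the confirmed-to-admin merge step.
#' @noRd
link_entities <- function(entities, config, cross_only = FALSE,
                          stratum = NULL) {
  if (nrow(entities) == 0L) {
    return(list(clusters = tibble::tibble(record_id = character(),
                                          cluster = integer()),
                decisions = NULL))
  }
  recs <- entities
  recs$record_id <- recs$entity_id
  if (nrow(recs) < 2) {
    return(list(clusters = tibble::tibble(record_id = recs$record_id,
                                          cluster = 1L),
                decisions = NULL))
  }
  pairs <- block_pairs(recs, config$blocking_keys)
  if (cross_only && nrow(pairs)) {
    keep <- stratum[pairs$i] != stratum[pairs$j]
    pairs <- pairs[keep, , drop = FALSE]
  }
  pattern <- compare_pairs(recs, pairs, config)
  decisions <- decide_links(recs, pattern, config)
  clusters <- cluster_links(recs$record_id, decisions)
  list(clusters = clusters, decisions = decisions)
}

#' @noRd
merge_entity_clusters <- function(entities, clusters) {
  df <- left_join(entities, clusters,
                  by = c(entity_id = "record_id"))
  df %>%
    group_by(.data$cluster) %>%
    summarise(
      entity_id = paste0("X-", min(.data$entity_id)),
      source = paste(sort(unique(.data$source)), collapse = "+"),
      first_name = modal_chr(.data$first_name),
      last_name = modal_chr(.data$last_name),
      dob = modal_date(.data$dob),
      ssn = modal_chr(.data$ssn),
      sex = modal_chr(.data$sex),
      zip = modal_chr(.data$zip),
      record_ids = list(sort(unique(unlist(.data$record_ids)))),
      .groups = "drop") %>%
    select(-"cluster") %>%
    arrange(.data$entity_id)
}

#' Link confirmed-case sources into a provisional index
#'
#' Cross-links and deduplicates the newborn-screening and clinic entity sets
#' (the sources that can carry laboratory confirmation).
#'
#' @param nbs_entities,clinic_entities Entity tibbles from [dedupe_source()].
#' @param config A [linkage_config()].
#' @return List with `persons` (merged entities) and `decisions`.
#' @export
build_confirmed_index <- function(nbs_entities, clinic_entities,
                                  config = linkage_config()) {
  entities <- bind_rows(nbs_entities, clinic_entities)
  lr <- link_entities(entities, config)
  persons <- if (nrow(entities)) merge_entity_clusters(entities, lr$clusters)
             else empty_entities()
  list(persons = persons, decisions = lr$decisions)
}

#' Link administrative sources into a provisional index
#'
#' Only entities carrying at least one sickle-coded encounter (SCD or trait
#' diagnosis code on any member record) are in surveillance scope; they are
#' cross-linked across the Medicaid and hospital/ED sets and deduplicated,
#' pooling encounter histories.
#'
#' @param medicaid_entities,hospital_entities Entity tibbles from
#'   [dedupe_source()].
#' @param records Combined record tibble covering the entities' member
#'   records (used to test for sickle codes).
#' @param config A [linkage_config()].
#' @return List with `persons`, `decisions`, and `excluded` (entities with no
#'   sickle-coded encounter).
#' @export
build_admin_index <- function(medicaid_entities, hospital_entities, records,
                              config = linkage_config()) {
  entities <- bind_rows(medicaid_entities, hospital_entities)
  if (nrow(entities) == 0L) {
    return(list(persons = empty_entities(), decisions = NULL,
                excluded = empty_entities()))
  }
  flags <- record_code_flags(records)
  coded <- flags$record_id[flags$has_scd_code | flags$has_trait_code]
  keep <- vapply(entities$record_ids, function(ids) any(ids %in% coded),
                 logical(1))
  excluded <- entities[!keep, , drop = FALSE]
  entities <- entities[keep, , drop = FALSE]
  lr <- link_entities(entities, config)
  persons <- if (nrow(entities)) merge_entity_clusters(entities, lr$clusters)
             else empty_entities()
  list(persons = persons, decisions = lr$decisions, excluded = excluded)
}

#' Merge the confirmed and administrative indices
#'
#' Links confirmed-source persons to administrative persons (cross-stratum
#' pairs only). Matched persons pool their source records; unmatched
#' administrative persons pass through to case classification; unmatched
#' confirmed persons are retained.
#'
#' @param confirmed,admin `persons` tibbles from [build_confirmed_index()] and
#'   [build_admin_index()].
#' @param config A [linkage_config()].
#' @return List with `persons` (entity-shaped, with a `stratum` column:
#'   `"CONFIRMED_SOURCE"`, `"ADMIN_ONLY"` or `"MATCHED"`) and `decisions`.
#' @export
merge_indices <- function(confirmed, admin, config = linkage_config()) {
  confirmed$stratum <- if (nrow(confirmed)) "CONFIRMED_SOURCE" else character(0)
  admin$stratum <- if (nrow(admin)) "ADMIN_ONLY" else character(0)
  entities <- bind_rows(confirmed, admin)
  if (nrow(entities) == 0L) {
    out <- empty_entities()
    out$stratum <- character()
    return(list(persons = out, decisions = NULL))
  }
  lr <- link_entities(entities, config, cross_only = TRUE,
                      stratum = entities$stratum)
  df <- left_join(entities, lr$clusters, by = c(entity_id = "record_id"))
  persons <- df %>%
    group_by(.data$cluster) %>%
    summarise(
      entity_id = paste0("M-", min(.data$entity_id)),
      source = paste(sort(unique(unlist(strsplit(.data$source, "+",
                                                 fixed = TRUE)))),
                     collapse = "+"),
      first_name = modal_chr(.data$first_name),
      last_name = modal_chr(.data$last_name),
      dob = modal_date(.data$dob),
      ssn = modal_chr(.data$ssn),
      sex = modal_chr(.data$sex),
      zip = modal_chr(.data$zip),
      record_ids = list(sort(unique(unlist(.data$record_ids)))),
      stratum = if (dplyr::n_distinct(.data$stratum) > 1) "MATCHED"
                else .data$stratum[1],
      .groups = "drop") %>%
    select(-"cluster") %>%
    arrange(.data$entity_id)
  list(persons = persons, decisions = lr$decisions)
}

#' Attach supplementary death-certificate data
#'
#' Death records are not a case-finding source: they are deduplicated and
#' linked with the same engine, and a matched death sets the person's death
#' date, but an unmatched death record never creates a new person (it is
#' logged instead).
#'
#' @param persons Person tibble from [merge_indices()].
#' @param death_entities Entity tibble from [dedupe_source()] on the death
#'   file.
#' @param death_records The death source records (for event dates).
#' @param config A [linkage_config()].
#' @return List with `persons` (now carrying `death_date`), `unlinked_deaths`
#'   (entity tibble) and `decisions`.
#' @export
attach_supplementary <- function(persons, death_entities, death_records,
                                 config = linkage_config()) {
  persons$death_date <- as.Date(NA)
  if (nrow(death_entities) == 0L || nrow(persons) == 0L) {
    return(list(persons = persons, unlinked_deaths = death_entities,
                decisions = NULL))
  }
  p <- persons
  p$kind <- "person"
  d <- death_entities
  d$stratum <- NA_character_
  d$kind <- "death"
  combined <- bind_rows(p, d)
  lr <- link_entities(combined, config, cross_only = TRUE,
                      stratum = combined$kind)
  cl <- lr$clusters
  memb <- stats::setNames(cl$cluster, cl$record_id)
  death_cluster <- memb[death_entities$entity_id]
  person_cluster <- memb[persons$entity_id]
  linked <- death_cluster %in% person_cluster
  # death date = earliest event date among the linked death entity's records
  date_of <- stats::setNames(death_records$event_date, death_records$record_id)
  for (k in which(linked)) {
    tgt <- which(person_cluster == death_cluster[k])
    dd <- min(date_of[death_entities$record_ids[[k]]], na.rm = TRUE)
    cur <- persons$death_date[tgt]
    persons$death_date[tgt] <- pmin(cur, dd, na.rm = TRUE)
    persons$record_ids[tgt] <- lapply(persons$record_ids[tgt], function(ids) {
      sort(unique(c(ids, death_entities$record_ids[[k]])))
    })
  }
  list(persons = persons,
       unlinked_deaths = death_entities[!linked, , drop = FALSE],
       decisions = lr$decisions)
}

#' Resolve person demographics by source priority
#'
#' For each demographic field, takes the value from the highest-priority
#' source that carries it (modal value within a source), recording the
#' providing source as provenance. Default priority ranks newborn screening
#' most reliable, then clinic, Medicaid, hospital/ED, and death certificates.
#' Genotype comes from the laboratory result fields of the screening/clinic
#' sources; conflicting genotype reports resolve by the same priority and are
#' logged as discrepancies.
#'
#' @param crosswalk Person-to-record crosswalk (`person_uid`, `source`,
#'   `record_id`).
#' @param records Combined record tibble.
#' @param priority Ordered character vector of sources.
#' @return List with `demographics` (one row per person: `sex`, `sex_source`,
#'   `birth_date`, `birth_date_source`, `genotype`, `genotype_source`) and
#'   `genotype_discrepancies`.
#' @export
resolve_demographics <- function(crosswalk, records,
                                 priority = source_priority_default) {
  df <- left_join(crosswalk,
                  select(records, "record_id", "dob", "sex",
                         "genotype_result"),
                  by = "record_id")
  df$rank <- match(df$source, priority)
  per_source <- df %>%
    group_by(.data$person_uid, .data$source, .data$rank) %>%
    summarise(sex = modal_chr(.data$sex),
              birth_date = modal_date(.data$dob),
              genotype = modal_chr(.data$genotype_result),
              .groups = "drop")
  pick <- function(value_col) {
    per_source %>%
      filter(!is.na(.data[[value_col]])) %>%
      arrange(.data$person_uid, .data$rank) %>%
      group_by(.data$person_uid) %>%
      summarise(value = .data[[value_col]][1], src = .data$source[1],
                .groups = "drop")
  }
  sexes <- pick("sex")
  dobs <- per_source %>%
    filter(!is.na(.data$birth_date)) %>%
    arrange(.data$person_uid, .data$rank) %>%
    group_by(.data$person_uid) %>%
    summarise(value = .data$birth_date[1], src = .data$source[1],
              .groups = "drop")
  genos <- pick("genotype")
  discrepant <- per_source %>%
    filter(!is.na(.data$genotype)) %>%
    group_by(.data$person_uid) %>%
    summarise(n_distinct = dplyr::n_distinct(.data$genotype),
              values = paste(unique(.data$genotype), collapse = "/"),
              .groups = "drop") %>%
    filter(.data$n_distinct > 1)
  out <- tibble::tibble(person_uid = unique(crosswalk$person_uid))
  out$sex <- sexes$value[match(out$person_uid, sexes$person_uid)]
  out$sex_source <- sexes$src[match(out$person_uid, sexes$person_uid)]
  out$birth_date <- dobs$value[match(out$person_uid, dobs$person_uid)]
  out$birth_date_source <- dobs$src[match(out$person_uid, dobs$person_uid)]
  out$genotype <- genos$value[match(out$person_uid, genos$person_uid)]
  out$genotype_source <- genos$src[match(out$person_uid, genos$person_uid)]
  list(demographics = out, genotype_discrepancies = discrepant)
}

#' Build the hub-and-spoke master index
#'
#' Runs the full pipeline in its fixed order: per-source cleaning and
#' deduplication, linkage of the confirmed-case sources (newborn screening and
#' clinic) into a provisional index, linkage of the sickle-coded
#' administrative entities (Medicaid and hospital/ED), the confirmed-to-admin
#' merge, attachment of supplementary death data, and demographic resolution
#' by source priority. The result is a partition: every non-quarantined
#' record belongs to exactly one person.
#'
#' @param sources Named list of record tibbles (`NBS`, `CLINIC`, `MEDICAID`,
#'   `HOSPITAL_ED`, `DEATH`), e.g. `bundle$sources` or [read_source_files()].
#' @param config A [linkage_config()].
#' @param period Optional surveillance period for date quality checks.
#' @param priority Demographic source priority.
#' @return An object of class `scd_index`: list with `persons`, `crosswalk`,
#'   `quarantine`, `unlinked_deaths`, `genotype_discrepancies`, `excluded_admin`
#'   and `config`.
#' @export
build_master_index <- function(sources, config = linkage_config(),
                               period = NULL,
                               priority = source_priority_default) {
  records <- bind_sources(sources)
  dedup <- lapply(source_levels, function(s) {
    dedupe_source(sources[[s]] %||% empty_records()[0, ], config, period)
  })
  names(dedup) <- source_levels
  quarantine <- bind_rows(lapply(dedup, `[[`, "quarantine"))

  confirmed <- build_confirmed_index(dedup$NBS$entities,
                                     dedup$CLINIC$entities, config)
  admin <- build_admin_index(dedup$MEDICAID$entities,
                             dedup$HOSPITAL_ED$entities, records, config)
  merged <- merge_indices(confirmed$persons, admin$persons, config)
  supp <- attach_supplementary(merged$persons, dedup$DEATH$entities,
                               sources$DEATH %||% empty_records()[0, ],
                               config)
  persons <- supp$persons

  # deterministic person uid: ordered by the smallest member record id
  if (nrow(persons)) {
    key <- vapply(persons$record_ids, function(x) x[1], character(1))
    persons <- persons[order(key), , drop = FALSE]
    persons$person_uid <- sprintf("P%06d", seq_len(nrow(persons)))
  } else {
    persons$person_uid <- character(0)
  }

  src_of <- stats::setNames(records$source, records$record_id)
  crosswalk <- tibble::tibble(
    person_uid = rep(persons$person_uid, lengths(persons$record_ids)),
    record_id = unlist(persons$record_ids) %||% character(0)
  )
  crosswalk$source <- unname(src_of[crosswalk$record_id])
  crosswalk <- crosswalk[, c("person_uid", "source", "record_id")]

  demo <- resolve_demographics(crosswalk, records, priority)
  persons <- left_join(
    select(persons, "person_uid", "stratum", "death_date",
           n_records = "record_ids"),
    demo$demographics, by = "person_uid")
  persons$n_records <- lengths(persons$n_records)
  persons$case_status <- NA_character_

  structure(list(persons = tibble::as_tibble(persons),
                 crosswalk = crosswalk,
                 quarantine = quarantine,
                 unlinked_deaths = supp$unlinked_deaths,
                 genotype_discrepancies = demo$genotype_discrepancies,
                 excluded_admin = admin$excluded,
                 config = config),
            class = "scd_index")
}

#' @export
print.scd_index <- function(x, ...) {
  cat("<scd_index>\n")
  cat(sprintf("  persons: %d   records linked: %d   quarantined: %d\n",
              nrow(x$persons), nrow(x$crosswalk), nrow(x$quarantine)))
  if (!all(is.na(x$persons$case_status))) {
    tab <- table(x$persons$case_status, useNA = "no")
    cat("  case status:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Persist the master index as hub and spoke files
#'
#' @param index An `scd_index`.
#' @param dir Output directory.
#' @return `dir`, invisibly. Writes `persons.tsv` (hub) and `crosswalk.tsv`
#'   (spokes); both round-trip losslessly via [read_master_index()].
#' @export
write_master_index <- function(index, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(index$persons, file.path(dir, "persons.tsv"), na = "")
  readr::write_tsv(index$crosswalk, file.path(dir, "crosswalk.tsv"), na = "")
  invisible(dir)
}

#' Read a persisted master index
#'
#' @param dir Directory written by [write_master_index()].
#' @return An `scd_index` (without the run's quarantine/audit side tables).
#' @export
read_master_index <- function(dir) {
  persons <- readr::read_tsv(file.path(dir, "persons.tsv"),
                             col_types = readr::cols(
                               death_date = readr::col_date(),
                               birth_date = readr::col_date(),
                               n_records = readr::col_integer(),
                               .default = readr::col_character()),
                             na = "", progress = FALSE)
  crosswalk <- readr::read_tsv(file.path(dir, "crosswalk.tsv"),
                               col_types = "ccc", progress = FALSE)
  structure(list(persons = persons, crosswalk = crosswalk,
                 quarantine = NULL, unlinked_deaths = NULL,
                 genotype_discrepancies = NULL, excluded_admin = NULL,
                 config = NULL),
            class = "scd_index")
}
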
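# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# Jaro-Winkler from the textbook definition, on integer code points with
# explicit match-flag arrays.
jw_ref <- function(s1, s2, p = 0.1) {
  if (identical(s1, s2)) return(1)
  a <- utf8ToInt(s1); b <- utf8ToInt(s2)
  la <- length(a); lb <- length(b)
  if (la == 0 || lb == 0) return(0)
  win <- max(floor(max(la, lb) / 2) - 1, 0)
  fa <- logical(la); fb <- logical(lb)
  for (i in seq_len(la)) {
    lo <- max(1, i - win); hi <- min(lb, i + win)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!fb[j] && a[i] == b[j]) {
        fa[i] <- TRUE; fb[j] <- TRUE
        break
      }
    }
  }
  m <- sum(fa)
  if (m == 0) return(0)
  t <- sum(a[fa] != b[fb]) / 2
  jaro <- (m / la + m / lb + (m - t) / m) / 3
  l <- 0
  while (l < min(4, la, lb) && a[l + 1] == b[l + 1]) l <- l + 1
  jaro + l * p * (1 - jaro)
}

# Connected components by breadth-first search over an explicit adjacency
# list (oracle for the clustering step).
bfs_components <- function(ids, edges) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(edges))) {
    a <- edges$record_a[k]; b <- edges$record_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  cur <- 0L
  for (v in ids) {
    if (!is.na(comp[[v]])) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- cur
      queue <- c(queue, adj[[u]])
    }
  }
  comp
}

# Brute-force Fellegi-Sunter weight: explicit per-field log-likelihood terms.
fs_weight_ref <- function(pattern_row, m, u) {
  total <- 0
  for (f in names(m)) {
    v <- pattern_row[[f]]
    term <- if (v == "AGREE") {
      log2(m[[f]] / u[[f]])
    } else if (v == "DISAGREE") {
      log2((1 - m[[f]]) / (1 - u[[f]]))
    } else 0
    total <- total + term
  }
  total
}

# Minimal record tibble for linkage tests.
make_records <- function(n = 0, ...) {
  base <- tibble::tibble(
    record_id = sprintf("R%03d", seq_len(n)),
    source = rep("MEDICAID", n),
    first_name = rep("ALICE", n),
    last_name = rep("SMITH", n),
    dob = rep(as.Date("1990-04-12"), n),
    ssn = rep("123456789", n),
    sex = rep("F", n),
    zip = rep("30001", n),
    event_date = rep(as.Date("2010-06-01"), n),
    code_system = rep("ICD9", n),
    diagnosis_codes = rep("282.61", n),
    lab_confirmed = rep(NA, n),
    genotype_result = rep(NA_character_, n),
    enrollment_months = rep(12L, n)
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# Evidence constructor with sensible empty defaults.
make_evidence <- function(nbs_confirmed = FALSE, nbs_unconfirmed = FALSE,
                          clinical_dx_with_lab = FALSE,
                          clinical_dx_without_lab = FALSE,
                          scd_dates = as.Date(character()),
                          trait_dates = as.Date(character())) {
  structure(list(
    nbs_confirmed = nbs_confirmed, nbs_unconfirmed = nbs_unconfirmed,
    clinical_dx_with_lab = clinical_dx_with_lab,
    clinical_dx_without_lab = clinical_dx_without_lab,
    scd_encounter_dates = sort(scd_dates),
    trait_encounter_dates = sort(trait_dates)
  ), class = "scd_case_evidence")
}

# Hand-built classified index for report-level tests: `spec` is a list of
# person specs (status, sex, birth_date, genotype, death_date, and a records
# tibble of source/event_date).
make_index <- function(spec) {
  persons <- dplyr::bind_rows(lapply(seq_along(spec), function(k) {
    s <- spec[[k]]
    tibble::tibble(
      person_uid = sprintf("P%06d", k),
      stratum = "MATCHED",
      death_date = s$death_date %||% as.Date(NA),
      sex = s$sex %||% "F",
      sex_source = "NBS",
      birth_date = s$birth_date %||% as.Date("1990-01-01"),
      birth_date_source = "NBS",
      genotype = s$genotype %||% NA_character_,
      genotype_source = NA_character_,
      n_records = nrow(s$records),
      case_status = s$status
    )
  }))
  crosswalk <- dplyr::bind_rows(lapply(seq_along(spec), function(k) {
    s <- spec[[k]]
    tibble::tibble(person_uid = sprintf("P%06d", k),
                   source = s$records$source,
                   record_id = s$records$record_id)
  }))
  structure(list(persons = persons, crosswalk = crosswalk,
                 quarantine = NULL, config = NULL),
            class = "scd_index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
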
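link_fields <- c("first_name", "last_name", "dob", "ssn", "sex", "zip")

#' Configuration for the record-linkage engine
#'
#' Parameters of the deterministic cascade plus Fellegi-Sunter probabilistic
#' scorer. `m` is the probability a field agrees between two records of the
#' same person, `u` the probability it agrees between records of different
#' persons; the match weight of a pair sums `log2(m/u)` over agreeing fields
#' and `log2((1-m)/(1-u))` over disagreeing fields, with missing fields
#' contributing nothing. Defaults reflect the generator's noise model (names
#' survive typos via Jaro-Winkler at cutoff 0.85) and identifier
#' discriminating power (SSN agreement is worth far more than sex agreement).
#'
#' @param m_probs,u_probs Named per-field probabilities in (0, 1) for
#'   `first_name`, `last_name`, `dob`, `ssn`, `sex`, `zip`; `m > u` required
#'   for every field.
#' @param upper_threshold,lower_threshold Weight thresholds (log2 units):
#'   at or above `upper_threshold` a pair is a match, below `lower_threshold`
#'   a non-match, in between it goes to review.
#' @param blocking_keys List of blocking-key recipes; each recipe is a
#'   character vector of key components among `soundex_last`, `birth_year`,
#'   `ssn`, `dob`, `zip`, `first_initial`. A pair is compared iff it shares
#'   every component value of at least one recipe.
#' @param name_similarity_cutoff Jaro-Winkler similarity at or above which
#'   two name values count as agreeing.
#' @param review_policy How pairs landing between the thresholds are resolved
#'   in the absence of clerical review: `AS_NONMATCH` (default; conservative
#'   auto-linking), `AS_MATCH`, or `SECOND_RULE` (match iff date of birth
#'   agrees and at least one name agrees).
#' @return A list of class `scd_linkage_config`.
#' @export
linkage_config <- function(m_probs = c(first_name = 0.92, last_name = 0.92,
                                       dob = 0.95, ssn = 0.95,
                                       sex = 0.97, zip = 0.88),
                           u_probs = c(first_name = 0.01, last_name = 0.004,
                                       dob = 0.001, ssn = 0.0001,
                                       sex = 0.5, zip = 0.02),
                           upper_threshold = 12,
                           lower_threshold = 6,
                           blocking_keys = list(c("soundex_last", "birth_year"),
                                                "ssn"),
                           name_similarity_cutoff = 0.85,
                           review_policy = c("AS_NONMATCH", "AS_MATCH",
                                             "SECOND_RULE")) {
  review_policy <- match.arg(review_policy)
  for (f in link_fields) {
    m <- m_probs[[f]] %||% NA_real_
    u <- u_probs[[f]] %||% NA_real_
    if (is.na(m) || is.na(u) || m <= 0 || m >= 1 || u <= 0 || u >= 1) {
      scdlink_abort(sprintf("m and u for `%s` must lie strictly in (0, 1)", f),
                    class = "scdlink_config_error")
    }
    if (m <= u) {
      scdlink_abort(sprintf("m must exceed u for `%s` (informative comparison)", f),
                    class = "scdlink_config_error")
    }
  }
  if (upper_threshold < lower_threshold) {
    scdlink_abort("`upper_threshold` must be >= `lower_threshold`",
                  class = "scdlink_config_error")
  }
  assert_probability(name_similarity_cutoff, "name_similarity_cutoff")
  structure(list(m_probs = m_probs[link_fields], u_probs = u_probs[link_fields],
                 upper_threshold = upper_threshold,
                 lower_threshold = lower_threshold,
                 blocking_keys = blocking_keys,
                 name_similarity_cutoff = name_similarity_cutoff,
                 review_policy = review_policy),
            class = "scd_linkage_config")
}

#' @noRd
blocking_component <- function(records, comp) {
  switch(comp,
    soundex_last = soundex(normalize_name(records$last_name)),
    birth_year = ifelse(is.na(records$dob), NA_character_,
                        as.character(year_of(records$dob))),
    ssn = as.character(records$ssn),
    dob = ifelse(is.na(records$dob), NA_character_, format(records$dob)),
    zip = as.character(records$zip),
    first_initial = substr(normalize_name(records$first_name), 1, 1),
    scdlink_abort(sprintf("unknown blocking key component: %s", comp),
                  class = "scdlink_config_error")
  )
}

#' Build the candidate pair set by blocking
#'
#' Returns the union, over all blocking-key recipes, of record pairs sharing
#' the full key value. Records missing any component of a recipe do not enter
#' that recipe's blocks. No pair outside the union is ever compared, which is
#' what makes linkage tractable; an explicit `all_pairs` escape hatch (guarded
#' by `max_all_pairs`) exists for oracle tests on small files.
#'
#' @param records Record tibble with identifier columns (`record_id`,
#'   `first_name`, `last_name`, `dob`, `ssn`, `sex`, `zip`).
#' @param keys List of recipes as in [linkage_config()].
#' @param all_pairs If `TRUE`, enumerate every pair (small inputs only).
#' @param max_all_pairs Size guard for `all_pairs`.
#' @return Tibble with integer row indices `i < j` of candidate pairs.
#' @export
block_pairs <- function(records, keys = list(c("soundex_last", "birth_year"),
                                             "ssn"),
                        all_pairs = FALSE, max_all_pairs = 10000L) {
  n <- nrow(records)
  if (all_pairs) {
    if (n * (n - 1) / 2 > max_all_pairs) {
      scdlink_abort("all-pairs comparison requested above the size guard",
                    class = "scdlink_linkage_error")
    }
    if (n < 2) return(tibble::tibble(i = integer(), j = integer()))
    cmb <- utils::combn(n, 2)
    return(tibble::tibble(i = cmb[1, ], j = cmb[2, ]))
  }
  if (length(keys) == 0) {
    scdlink_abort("blocking is mandatory: supply keys or set all_pairs = TRUE",
                  class = "scdlink_linkage_error")
  }
  out <- vector("list", length(keys))
  for (k in seq_along(keys)) {
    comps <- lapply(keys[[k]], blocking_component, records = records)
    keyval <- do.call(paste, c(comps, sep = "\r"))
    keyval[Reduce(`|`, lapply(comps, is.na))] <- NA
    groups <- split(seq_len(n), keyval)
    groups <- groups[lengths(groups) > 1]
    pairs <- lapply(groups, function(g) utils::combn(g, 2))
    out[[k]] <- if (length(pairs)) t(do.call(cbind, pairs)) else
      matrix(integer(), ncol = 2)
  }
  all <- do.call(rbind, out)
  if (nrow(all) == 0) return(tibble::tibble(i = integer(), j = integer()))
  all <- unique(all)
  tibble::tibble(i = all[, 1], j = all[, 2])
}

#' Compare candidate pairs field by field
#'
#' Produces the agreement pattern for each candidate pair: names agree when
#' their normalized Jaro-Winkler similarity reaches the configured cutoff;
#' date of birth, SSN, sex and ZIP agree on exact (normalized) equality; a
#' field is `MISSING` whenever either record lacks it. Comparison is
#' symmetric in the pair order.
#'
#' @param records Record tibble.
#' @param pairs Candidate pairs from [block_pairs()].
#' @param config A [linkage_config()].
#' @return Tibble with columns `i`, `j` and one pattern column per field
#'   (values `AGREE`, `DISAGREE`, `MISSING`).
#' @export
compare_pairs <- function(records, pairs, config = linkage_config()) {
  fn <- normalize_name(records$first_name)
  ln <- normalize_name(records$last_name)
  out <- pairs
  cmp_exact <- function(x) {
    a <- x[pairs$i]; b <- x[pairs$j]
    ifelse(is.na(a) | is.na(b), "MISSING",
           ifelse(a == b, "AGREE", "DISAGREE"))
  }
  cmp_name <- function(x) {
    a <- x[pairs$i]; b <- x[pairs$j]
    miss <- is.na(a) | is.na(b)
    sim <- rep(NA_real_, length(a))
    if (any(!miss)) sim[!miss] <- jaro_winkler(a[!miss], b[!miss])
    ifelse(miss, "MISSING",
           ifelse(sim >= config$name_similarity_cutoff, "AGREE", "DISAGREE"))
  }
  out$first_name <- cmp_name(fn)
  out$last_name <- cmp_name(ln)
  out$dob <- cmp_exact(records$dob)
  out$ssn <- cmp_exact(normalize_name(records$ssn))
  out$sex <- cmp_exact(normalize_name(records$sex))
  out$zip <- cmp_exact(normalize_name(records$zip))
  out
}

#' Fellegi-Sunter match weight of agreement patterns
#'
#' @param pattern Tibble/data frame with one column per comparison field
#'   holding `AGREE`/`DISAGREE`/`MISSING`.
#' @param config A [linkage_config()] supplying the per-field m/u
#'   probabilities.
#' @return Numeric vector of match weights in log2 units (0 for an all-missing
#'   pattern).
#' @examples
#' pat <- data.frame(first_name = "AGREE", last_name = "MISSING",
#'                   dob = "AGREE", ssn = "MISSING", sex = "AGREE",
#'                   zip = "DISAGREE")
#' match_weight(pat)
#' @export
match_weight <- function(pattern, config = linkage_config()) {
  w <- numeric(nrow(pattern))
  for (f in link_fields) {
    m <- config$m_probs[[f]]; u <- config$u_probs[[f]]
    p <- pattern[[f]]
    w <- w + ifelse(p == "AGREE", log2(m / u),
                    ifelse(p == "DISAGREE", log2((1 - m) / (1 - u)), 0))
  }
  w
}

#' @noRd
deterministic_rule <- function(records, pairs) {
  eq <- function(x) {
    a <- x[pairs$i]; b <- x[pairs$j]
    !is.na(a) & !is.na(b) & a == b
  }
  fn <- normalize_name(records$first_name)
  ln <- normalize_name(records$last_name)
  ssn_dob <- eq(normalize_name(records$ssn)) & eq(records$dob)
  name_dob_sex <- eq(fn) & eq(ln) & eq(records$dob) &
    eq(normalize_name(records$sex))
  ifelse(ssn_dob, "ssn_dob",
         ifelse(name_dob_sex, "name_dob_sex", "probabilistic"))
}

#' Decide match status for scored pairs
#'
#' The deterministic cascade takes precedence: pairs agreeing exactly on
#' SSN + date of birth, or on first name + last name + date of birth + sex,
#' are matches regardless of weight. Remaining pairs are matches at or above
#' the upper threshold, non-matches below the lower threshold, and otherwise
#' reviews resolved by the configured `review_policy`.
#'
#' @param records Record tibble.
#' @param pattern Output of [compare_pairs()] (carries `i`, `j`).
#' @param config A [linkage_config()].
#' @return Tibble: `record_a`, `record_b`, the pattern columns, `weight`,
#'   `rule`, `status` (`MATCH`/`REVIEW`/`NONMATCH` before policy is applied in
#'   the `raw_status` column; `status` is post-policy).
#' @export
decide_links <- function(records, pattern, config = linkage_config()) {
  pairs <- pattern[, c("i", "j")]
  weight <- match_weight(pattern, config)
  rule <- deterministic_rule(records, pairs)
  raw <- ifelse(rule != "probabilistic", "MATCH",
                ifelse(weight >= config$upper_threshold, "MATCH",
                       ifelse(weight < config$lower_threshold,
                              "NONMATCH", "REVIEW")))
  status <- raw
  rev <- raw == "REVIEW"
  if (any(rev)) {
    status[rev] <- switch(config$review_policy,
      AS_NONMATCH = "NONMATCH",
      AS_MATCH = "MATCH",
      SECOND_RULE = ifelse(
        pattern$dob[rev] == "AGREE" &
          (pattern$first_name[rev] == "AGREE" |
             pattern$last_name[rev] == "AGREE"),
        "MATCH", "NONMATCH")
    )
  }
  tibble::tibble(
    record_a = records$record_id[pattern$i],
    record_b = records$record_id[pattern$j],
    pattern[, link_fields],
    weight = weight, rule = rule, raw_status = raw, status = status
  )
}

#' Cluster matched pairs into persons by transitive closure
#'
#' Connected components of the match graph: every record lands in exactly one
#' cluster, singletons allowed.
#'
#' @param record_ids Character vector of all record ids (defines the vertex
#'   set, so unmatched records become singleton clusters).
#' @param decisions Decision tibble from [decide_links()] (only `MATCH` rows
#'   are used), or a tibble with columns `record_a`, `record_b`.
#' @return Tibble `record_id`, `cluster` (integer component label).
#' @export
cluster_links <- function(record_ids, decisions) {
  edges <- decisions
  if (!is.null(edges$status)) {
    edges <- edges[edges$status == "MATCH", , drop = FALSE]
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(record_ids)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$record_a, record_ids),
                                    match(edges$record_b, record_ids)))
  }
  comp <- igraph::components(g)
  tibble::tibble(record_id = record_ids,
                 cluster = as.integer(comp$membership))
}

#' Run the full linkage engine over a record set
#'
#' Blocking, field comparison, Fellegi-Sunter scoring, the deterministic
#' cascade, review resolution, and transitive-closure clustering, in one call.
#' Used both for within-source deduplication and for cross-source linkage.
#'
#' @param records Record tibble (must have unique `record_id`).
#' @param config A [linkage_config()].
#' @param all_pairs Escape hatch forwarded to [block_pairs()].
#' @return List with `decisions` (the audit log: one row per compared pair)
#'   and `clusters` (record-to-cluster assignment).
#' @export
link_records <- function(records, config = linkage_config(),
                         all_pairs = FALSE) {
  if (anyDuplicated(records$record_id)) {
    scdlink_abort("record ids must be unique within a linkage run",
                  class = "scdlink_linkage_error")
  }
  if (nrow(records) < 2) {
    return(list(
      decisions = decide_links(records,
                               compare_pairs(records,
                                             tibble::tibble(i = integer(),
                                                            j = integer()),
                                             config), config),
      clusters = cluster_links(records$record_id,
                               tibble::tibble(record_a = character(),
                                              record_b = character(),
                                              status = character()))
    ))
  }
  pairs <- block_pairs(records, config$blocking_keys, all_pairs = all_pairs)
  pattern <- compare_pairs(records, pairs, config)
  decisions <- decide_links(records, pattern, config)
  clusters <- cluster_links(records$record_id, decisions)
  list(decisions = decisions, clusters = clusters)
}

#' Write the linkage audit log
#'
#' @param decisions Decision tibble from [decide_links()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_link_log <- function(decisions, path) {
  readr::write_tsv(decisions, path)
  invisible(path)
}
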
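test_that("blocking admits shared-key pairs and nothing else", {
  recs <- make_records(4,
    last_name = c("SMITH", "SMYTH", "JONES", "WILSON"),
    dob = as.Date(c("1990-04-12", "1990-07-01", "1990-04-12", "1971-01-01")),
    ssn = c("111111111", "222222222", "111111111", "333333333"))
  pairs <- block_pairs(recs)
  key <- paste(pmin(pairs$i, pairs$j), pmax(pairs$i, pairs$j))
  # 1-3 share an ssn; 1-2 share soundex(last) + birth year
  expect_true("1 3" %in% key)
  expect_true("1 2" %in% key)
  # 4 shares no key value with anyone
  expect_false(any(pairs$i == 4 | pairs$j == 4))
})

test_that("blocking never loses a true pair on clean data", {
  cfg <- noiseless_config(n_population = 200, scd_prevalence = 0.2, seed = 31)
  bundle <- emit_source_records(generate_truth(cfg), cfg)
  recs <- dplyr::bind_rows(bundle$sources)
  prov <- bundle$provenance
  pairs <- block_pairs(recs)
  blocked <- paste(pmin(recs$record_id[pairs$i], recs$record_id[pairs$j]),
                   pmax(recs$record_id[pairs$i], recs$record_id[pairs$j]))
  # exhaustive oracle: all true co-referent pairs
  by_person <- split(prov$record_id, prov$true_id)
  true_pairs <- unlist(lapply(by_person[lengths(by_person) > 1], function(ids) {
    cmb <- utils::combn(sort(ids), 2)
    paste(cmb[1, ], cmb[2, ])
  }))
  expect_true(all(true_pairs %in% blocked))
})

test_that("all-pairs escape hatch honors its size guard", {
  recs <- make_records(5)
  pairs <- block_pairs(recs, all_pairs = TRUE)
  expect_identical(nrow(pairs), 10L)
  expect_error(block_pairs(make_records(300), all_pairs = TRUE,
                           max_all_pairs = 100),
               class = "scdlink_linkage_error")
  expect_error(block_pairs(recs, keys = list()),
               class = "scdlink_linkage_error")
})

test_that("field comparison handles agreement, similarity cutoffs and missingness", {
  recs <- make_records(3,
    last_name = c("SMITH", "SMYTH", "SMITH"),
    ssn = c("123456789", NA, "123456789"))
  pairs <- tibble::tibble(i = c(1L, 1L), j = c(2L, 3L))
  pat <- compare_pairs(recs, pairs, linkage_config(name_similarity_cutoff = 0.85))
  expect_identical(pat$last_name, c("AGREE", "AGREE")) # SMYTH ~ SMITH at 0.85
  expect_identical(pat$ssn, c("MISSING", "AGREE"))
  pat95 <- compare_pairs(recs, pairs,
                         linkage_config(name_similarity_cutoff = 0.95))
  expect_identical(pat95$last_name, c("DISAGREE", "AGREE"))
  # identical records agree everywhere
  expect_true(all(pat[2, c("first_name", "last_name", "dob", "ssn", "sex",
                           "zip")] == "AGREE"))
})

test_that("match weights follow the closed form and the brute-force oracle", {
  cfg <- linkage_config(m_probs = c(first_name = 0.9, last_name = 0.9,
                                    dob = 0.9, ssn = 0.9, sex = 0.9,
                                    zip = 0.9),
                        u_probs = c(first_name = 0.1, last_name = 0.1,
                                    dob = 0.1, ssn = 0.1, sex = 0.1,
                                    zip = 0.1))
  fields <- c("first_name", "last_name", "dob", "ssn", "sex", "zip")
  all_missing <- as.data.frame(as.list(stats::setNames(
    rep("MISSING", 6), fields)))
  expect_identical(match_weight(all_missing, cfg), 0)
  one <- all_missing
  one$ssn <- "AGREE"
  expect_equal(match_weight(one, cfg), log2(9), tolerance = 1e-12)

  set.seed(99)
  pats <- as.data.frame(matrix(
    sample(c("AGREE", "DISAGREE", "MISSING"), 6 * 200, replace = TRUE),
    ncol = 6, dimnames = list(NULL, fields)))
  dflt <- linkage_config()
  got <- match_weight(pats, dflt)
  want <- vapply(seq_len(nrow(pats)), function(k) {
    fs_weight_ref(pats[k, ], as.list(dflt$m_probs), as.list(dflt$u_probs))
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the deterministic cascade outranks weights and thresholds bind at the boundary", {
  # ssn+dob equal but a name typo drags the weight down: still a match
  recs <- make_records(2, last_name = c("SMITH", "SMITX"),
                       first_name = c("ALICE", "ALINE"),
                       zip = c("30001", "30999"))
  cfg <- linkage_config(upper_threshold = 100) # unreachable probabilistically
  out <- decide_links(recs, compare_pairs(recs, tibble::tibble(i = 1L, j = 2L),
                                          cfg), cfg)
  expect_identical(out$rule, "ssn_dob")
  expect_identical(out$status, "MATCH")

  # boundary: weight exactly at the upper threshold is a match
  recs2 <- make_records(2, ssn = c(NA, NA), zip = c(NA, NA),
                        first_name = c(NA, NA), sex = c(NA, NA))
  cfg2 <- linkage_config()
  pat2 <- compare_pairs(recs2, tibble::tibble(i = 1L, j = 2L), cfg2)
  w <- match_weight(pat2, cfg2)
  at <- linkage_config(upper_threshold = w, lower_threshold = w - 1)
  above <- linkage_config(upper_threshold = w + 1e-9,
                          lower_threshold = w - 1)
  expect_identical(decide_links(recs2, pat2, at)$status, "MATCH")
  expect_identical(decide_links(recs2, pat2, above)$status, "NONMATCH")
  expect_identical(decide_links(recs2, pat2, above)$raw_status, "REVIEW")
  # review policies
  as_match <- linkage_config(upper_threshold = w + 1, lower_threshold = w - 1,
                             review_policy = "AS_MATCH")
  second <- linkage_config(upper_threshold = w + 1, lower_threshold = w - 1,
                           review_policy = "SECOND_RULE")
  expect_identical(decide_links(recs2, pat2, as_match)$status, "MATCH")
  # dob + last name agree -> second rule links
  expect_identical(decide_links(recs2, pat2, second)$status, "MATCH")
})

test_that("comparison and decisions are symmetric in pair order", {
  recs <- make_records(2, last_name = c("SMITH", "SMYTH"),
                       ssn = c("123456789", NA))
  cfg <- linkage_config()
  fwd <- decide_links(recs, compare_pairs(recs, tibble::tibble(i = 1L, j = 2L),
                                          cfg), cfg)
  swapped <- recs[2:1, ]
  swapped$record_id <- recs$record_id # keep ids aligned with rows
  rev <- decide_links(swapped,
                      compare_pairs(swapped, tibble::tibble(i = 1L, j = 2L),
                                    cfg), cfg)
  expect_identical(fwd$weight, rev$weight)
  expect_identical(fwd$status, rev$status)
  expect_identical(fwd[, c("first_name", "last_name", "dob", "ssn", "sex",
                           "zip")],
                   rev[, c("first_name", "last_name", "dob", "ssn", "sex",
                           "zip")])
})

test_that("raising the upper threshold never creates matches", {
  cfg <- generator_config(n_population = 300, scd_prevalence = 0.15, seed = 23)
  bundle <- emit_source_records(generate_truth(cfg), cfg)
  recs <- dplyr::bind_rows(bundle$sources)
  thresholds <- c(8, 12, 16, 20)
  n_match <- vapply(thresholds, function(th) {
    lc <- linkage_config(upper_threshold = th,
                         lower_threshold = min(th, 6))
    sum(link_records(recs, lc)$decisions$status == "MATCH")
  }, numeric(1))
  expect_true(all(diff(n_match) <= 0))
})

test_that("clustering is transitive closure and matches a BFS oracle", {
  simple <- tibble::tibble(record_a = c("a", "b"), record_b = c("b", "c"),
                           status = c("MATCH", "MATCH"))
  cl <- cluster_links(c("a", "b", "c", "d"), simple)
  expect_identical(cl$cluster[1], cl$cluster[2])
  expect_identical(cl$cluster[2], cl$cluster[3])
  expect_false(cl$cluster[4] == cl$cluster[1])

  none <- cluster_links(letters[1:5],
                        tibble::tibble(record_a = character(),
                                       record_b = character(),
                                       status = character()))
  expect_identical(dplyr::n_distinct(none$cluster), 5L)

  set.seed(12)
  ids <- sprintf("N%02d", 1:50)
  edges <- tibble::tibble(record_a = sample(ids, 40, replace = TRUE),
                          record_b = sample(ids, 40, replace = TRUE),
                          status = "MATCH")
  edges <- edges[edges$record_a != edges$record_b, ]
  got <- cluster_links(ids, edges)
  want <- bfs_components(ids, edges)
  # same partition up to relabeling
  expect_identical(dplyr::n_distinct(got$cluster),
                   dplyr::n_distinct(want))
  joint <- paste(got$cluster, want[got$record_id])
  expect_identical(dplyr::n_distinct(joint), dplyr::n_distinct(got$cluster))
})

test_that("noiseless clusters recover the ground-truth partition exactly", {
  cfg <- noiseless_config(n_population = 300, scd_prevalence = 0.2, seed = 41)
  bundle <- emit_source_records(generate_truth(cfg), cfg)
  recs <- dplyr::bind_rows(bundle$sources)
  lr <- link_records(recs)
  df <- dplyr::left_join(lr$clusters, bundle$provenance, by = "record_id")
  # every cluster is pure and every true person is one cluster
  expect_identical(dplyr::n_distinct(paste(df$cluster, df$true_id)),
                   dplyr::n_distinct(df$true_id))
  expect_identical(dplyr::n_distinct(df$cluster),
                   dplyr::n_distinct(df$true_id))
})
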
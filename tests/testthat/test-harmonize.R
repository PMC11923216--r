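make_round_tables <- function() {
  # d1: answered in both rounds by different respondents, with a conflict
  # d2: round 1 only; d3: round 2 only
  r1 <- make_records(
    make_record("best", dataset_id = "d1", respondent_id = "resp_a",
                collection_mode = "automated"),
    make_record("worst", dataset_id = "d2", respondent_id = "resp_b"))
  r2 <- make_records(
    make_record("best", dataset_id = "d1", round = "r2",
                respondent_id = "resp_c", collection_mode = "manual"),
    make_record("best", dataset_id = "d3", round = "r2",
                respondent_id = "resp_b"))
  aq <- answer_quality(rep(c("A1_data_owner", "A2_data_controller"), each = 3),
                       rep(c("resp_a", "resp_b", "resp_c"), 2),
                       completeness = rep(1, 6),
                       coherence = c(1, 1, 0, 1, 1, 0))  # a=2, b=2, c=0
  list(r1 = survey_table(r1, answer_qualities = aq),
       r2 = survey_table(r2))
}

test_that("merge keeps the most coherent answer on conflict and logs it", {
  tabs <- make_round_tables()
  merged <- merge_rounds(tabs$r1, tabs$r2)
  expect_setequal(merged$records$dataset_id, c("d1", "d2", "d3"))
  d1 <- merged$records[merged$records$dataset_id == "d1", ]
  # resp_a has coherence sum 2, resp_c has 0 -> round-1 answer wins
  expect_equal(d1$respondent_id, "resp_a")
  expect_equal(d1$collection_mode, "automated")
  expect_true(any(merged$provenance_log$reason ==
                    "conflict: most coherent response kept" &
                  merged$provenance_log$field == "collection_mode"))
  # single-round datasets pass through unchanged
  expect_equal(merged$records[merged$records$dataset_id == "d3", ]$round, "r2")
})

test_that("merging identical rounds is idempotent with no conflict entries", {
  rec <- make_record("best", dataset_id = "d1", respondent_id = "resp_a")
  rec2 <- rec
  rec2$round <- "r2"
  t1 <- survey_table(rec)
  t2 <- survey_table(rec2)
  merged <- merge_rounds(t1, t2)
  expect_equal(nrow(merged$records), 1)
  # equal coherence (none recorded) -> round-2 answer kept, fields identical
  fields <- setdiff(names(merged$records), "round")
  expect_equal(merged$records[, fields], rec2[, fields])
  expect_equal(nrow(merged$provenance_log), 0)
})

test_that("ties go to round 2 and missing fields are filled across rounds", {
  r1 <- make_record("best", dataset_id = "d1", respondent_id = "resp_a",
                    storage_format = "relational_database")
  r1$collection_mode <- NA_character_
  r2 <- make_record("best", dataset_id = "d1", round = "r2",
                    respondent_id = "resp_b",
                    storage_format = "single_spreadsheet",
                    collection_mode = "manual")
  merged <- merge_rounds(survey_table(r1), survey_table(r2))
  d1 <- merged$records
  expect_equal(d1$respondent_id, "resp_b")         # tie -> validation round
  expect_equal(d1$storage_format, "single_spreadsheet")
  expect_equal(d1$collection_mode, "manual")
  expect_true(any(grepl("round-2 answer kept", merged$provenance_log$reason)))
})

test_that("round-2 wins a tie but inherits round-1 answers it lacks", {
  r1 <- make_record("best", dataset_id = "d1", respondent_id = "resp_a")
  r2 <- make_record("best", dataset_id = "d1", round = "r2",
                    respondent_id = "resp_b")
  r2$licence_status <- NA_character_
  merged <- merge_rounds(survey_table(r1), survey_table(r2))
  expect_equal(merged$records$licence_status, "data_and_metadata")
  expect_true(any(merged$provenance_log$reason ==
                    "aggregation: missing value filled from other round"))
})

test_that("contradictory rows within one round are an integrity error", {
  recs <- make_records(
    make_record("best", dataset_id = "d1", respondent_id = "resp_a"),
    make_record("worst", dataset_id = "d1", respondent_id = "resp_b"))
  t1 <- survey_table(recs)
  t2 <- survey_table(recs[0, ])
  expect_error(merge_rounds(t1, t2), "integrity error")
})

test_that("reclassification rules are deterministic with unknown fallback", {
  expect_equal(reclassify_field("language", "English"), "english")
  expect_equal(reclassify_field("language", "  english  "), "english")
  expect_equal(reclassify_field("language", "Swedish"), "not_english")
  expect_equal(reclassify_field("language", "Dutch"), "not_english")
  expect_warning(out <- reclassify_field("language", ""), "unknown")
  expect_equal(out, "unknown")
  expect_equal(reclassify_field("data_owner_name", "Institute X"), "yes")
  expect_error(reclassify_field("farm_gps", "59.3N"), "configuration error")
})

test_that("id maps are seeded permutations and reproducible", {
  m1 <- make_id_map(c("dsA", "dsB", "dsC"), c("r1", "r2"), seed = 9)
  m2 <- make_id_map(c("dsC", "dsA", "dsB"), c("r2", "r1"), seed = 9)
  expect_identical(m1$datasets, m2$datasets)   # order-insensitive
  expect_setequal(m1$datasets, 1:3)            # collision-free permutation
  expect_setequal(m1$respondents, 1:2)
  m3 <- make_id_map(c("dsA", "dsB", "dsC"), c("r1", "r2"), seed = 10)
  expect_false(identical(m1$datasets, m3$datasets) &&
                 identical(m1$respondents, m3$respondents))
})

test_that("anonymisation is deterministic and leaves no original identifier", {
  tab <- generate_cohort(paper_like_config(seed = 3))
  a1 <- anonymize(tab, seed = 5)
  a2 <- anonymize(tab, seed = 5)
  expect_identical(a1$table$records, a2$table$records)
  orig <- unique(c(tab$records$dataset_id, tab$records$respondent_id))
  hits <- scan_identifiers(a1$table, denylist = orig)
  expect_equal(nrow(hits), 0)
  # bijection onto 1..N
  expect_setequal(a1$id_map$datasets, seq_along(a1$id_map$datasets))
  expect_setequal(unique(a1$table$records$dataset_id),
                  as.character(a1$id_map$datasets))
})
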
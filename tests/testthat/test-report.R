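test_that("percent rounds to nearest integer, halves away from zero", {
  expect_identical(percent(30, 38), 79L)
  expect_identical(percent(6, 19), 32L)
  expect_identical(percent(0, 30), 0L)
  expect_identical(percent(20, 30), 67L)
  expect_identical(percent(1, 8), 13L)     # 12.5 rounds up
  expect_identical(percent(3, 8), 38L)     # 37.5 rounds up
  expect_error(percent(1, 0), "domain error")
  expect_error(percent(5, 3), "domain error")
  expect_error(percent(-1, 3), "domain error")
})

test_that("percent complements sum to 99-101 and endpoints are exact", {
  set.seed(17)
  for (i in 1:200) {
    d <- sample(1:500, 1)
    n <- sample(0:d, 1)
    s <- percent(n, d) + percent(d - n, d)
    expect_true(s %in% c(99L, 100L, 101L))
  }
  d <- sample(1:500, 20)
  expect_true(all(percent(d, d) == 100L))
  expect_true(all(percent(0 * d, d) == 0L))
})

scored_fixture <- function(seed = 2) {
  tab <- generate_cohort(paper_like_config(seed = seed))
  tab <- merge_rounds(
    survey_table(tab$records[tab$records$round == "r1", ],
                 answer_qualities = tab$answer_qualities),
    survey_table(tab$records[tab$records$round == "r2", ]))
  list(tab = tab, fair = score_fair(tab),
       gdpr = suppressMessages(score_gdpr_cohort(tab)))
}

test_that("summarize_cohort populates counts with species overlap", {
  fx <- scored_fixture()
  s <- summarize_cohort(fx$tab, fx$fair, fx$gdpr)
  expect_equal(s$n_datasets, 30)
  expect_equal(unname(s$species_counts[c("swine", "cattle", "salmonids",
                                         "poultry")]), c(10, 9, 9, 4))
  expect_equal(sum(s$species_counts), 32)  # 2 multi-species datasets
  expect_equal(s$n_multi_species, 2)
  expect_equal(s$n_personal_data, 11)
  expect_equal(s$gdpr$n_applicable, 11)
  expect_true(all(unlist(s$fair_criterion_counts) <= 30))
  # per-criterion statuses partition the cohort
  for (cc in s$fair_criterion_counts) {
    expect_equal(cc$fulfilled + cc$partial + cc$not_fulfilled, 30)
  }
})

test_that("threshold counts use fulfilled criteria, not points", {
  recs <- make_records(
    make_record("best", dataset_id = "k1"),
    make_record("best", dataset_id = "k2", licence_status = "none",
                process_documentation = "partial"),
    make_record("worst", dataset_id = "k3"))
  tab <- survey_table(recs)
  fair <- score_fair(tab)
  expect_equal(fair$criteria_fulfilled, c(12L, 10L, 0L))
  s <- summarize_cohort(tab, fair, suppressMessages(score_gdpr_cohort(tab)))
  expect_equal(s$n_at_least_half_criteria, 2)
  expect_equal(s$n_all_criteria, 1)
})

test_that("summarize_cohort demands a score for every dataset", {
  fx <- scored_fixture()
  expect_error(summarize_cohort(fx$tab, fx$fair[-1, ], fx$gdpr),
               "completeness error")
})

test_that("species breakdown duplicates multi-species datasets with a flag", {
  recs <- make_records(
    make_record("best", dataset_id = "s1", species = "salmonids"),
    make_record("worst", dataset_id = "s2", species = "swine;cattle"))
  fair <- score_fair(recs)
  bd <- fair_breakdown_by_species(fair, survey_table(recs))
  expect_equal(bd$total[bd$species == "salmonids"], 12)
  expect_false(bd$multi_species[bd$species == "salmonids"])
  expect_equal(sum(bd$dataset_id == "s2"), 2)
  expect_true(all(bd$multi_species[bd$dataset_id == "s2"]))
  expect_setequal(bd$species[bd$dataset_id == "s2"], c("swine", "cattle"))
  empty <- fair_breakdown_by_species(fair[0, ], survey_table(recs))
  expect_equal(nrow(empty), 0)
})

test_that("JSON report round-trips and markdown has one line per criterion", {
  fx <- scored_fixture()
  s <- summarize_cohort(fx$tab, fx$fair, fx$gdpr)

  jf <- withr::local_tempfile(fileext = ".json")
  write_report(s, jf, format = "json")
  back <- read_report(jf)
  expect_equal(back$n_datasets, s$n_datasets)
  expect_equal(back$species_counts, s$species_counts)
  expect_equal(back$fair_criterion_counts, s$fair_criterion_counts)
  expect_equal(back$gdpr$owner_mean, s$gdpr$owner_mean)

  mf <- withr::local_tempfile(fileext = ".md")
  write_report(s, mf, format = "markdown")
  lines <- readLines(mf)
  crit_lines <- grep("^- [FAIR][1-4]: fulfilled", lines, value = TRUE)
  expect_length(crit_lines, 12)

  cf <- withr::local_tempfile(fileext = ".csv")
  write_report(s, cf, format = "csv")
  flat <- utils::read.csv(cf)
  expect_equal(as.integer(flat$value[flat$key == "n_datasets"]), 30)
})

test_that("an empty cohort writes a valid zero-count report", {
  recs <- make_record("best")[0, ]
  tab <- survey_table(recs)
  fair <- score_fair(tab)
  s <- summarize_cohort(tab, fair, score_gdpr_cohort(tab))
  expect_equal(s$n_datasets, 0)
  jf <- withr::local_tempfile(fileext = ".json")
  write_report(s, jf, format = "json")
  expect_equal(read_report(jf)$n_datasets, 0)
})
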
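# Each scorer is checked against an exhaustive enumeration of its (small)
# input state space using the literal decision-table oracles in the helper.

elements_combos <- function() {
  combos <- unlist(lapply(0:3, function(k)
    utils::combn(all_elements, k, paste, collapse = ";", simplify = FALSE)))
  unlist(combos)
}

test_that("F1/F2 match the identification decision table exhaustively", {
  grid <- expand.grid(present = c(TRUE, FALSE, NA),
                      elements = elements_combos(),
                      stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    make_record("worst", dataset_id = paste0("f", i),
                data_identifier_present = grid$present[i],
                data_identifying_elements = grid$elements[i],
                metadata_exist = "yes",
                metadata_identifier_present = grid$present[i],
                metadata_identifying_elements = grid$elements[i],
                metadata_link_update = "none_or_unknown",
                metadata_structure = "undocumented",
                metadata_access_mode = "none")))
  got <- score_findable(recs)
  want <- vapply(seq_len(nrow(grid)), function(i) {
    n_el <- length(strsplit(grid$elements[i], ";", fixed = TRUE)[[1]])
    oracle_f_element(grid$present[i], n_el)
  }, numeric(1))
  expect_equal(got$f1, want)
  expect_equal(got$f2, want)
})

test_that("F3 matches the metadata-link decision table exhaustively", {
  grid <- expand.grid(meta = c("yes", "no", "unknown", NA),
                      link = c("automatic", "manual", "none_or_unknown", NA),
                      stringsAsFactors = FALSE)
  # keep records schema-consistent only where required; the scorer itself
  # must gate on metadata availability
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    make_record("worst", dataset_id = paste0("f3_", i),
                metadata_exist = grid$meta[i],
                metadata_link_update = grid$link[i])))
  got <- score_findable(recs)$f3
  want <- vapply(seq_len(nrow(grid)), function(i)
    oracle_f3(grid$meta[i], grid$link[i]), numeric(1))
  expect_equal(got, want)
})

test_that("A1/A2 match the access decision table exhaustively", {
  modes <- c("documented_protocol", "url", "none", NA)
  grid <- expand.grid(data = modes, meta = modes, stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    make_record("best", dataset_id = paste0("a", i),
                data_access_mode = grid$data[i],
                metadata_access_mode = grid$meta[i])))
  got <- score_accessible(recs)
  expect_equal(got$a1, vapply(grid$data, oracle_access, numeric(1),
                              USE.NAMES = FALSE))
  expect_equal(got$a2, vapply(grid$meta, oracle_access, numeric(1),
                              USE.NAMES = FALSE))
})

test_that("I1-I4 match their decision tables exhaustively", {
  vocabs <- c("standard", "retrievable_glossary", "collaborative",
              "owner_defined", "unknown", NA)
  structs <- c("standard_schema", "documented", "undocumented", NA)
  tris <- c("yes", "no", "unknown", NA)
  grid <- expand.grid(doc = tris, vocab = vocabs, ms = structs, mv = vocabs,
                      stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    make_record("best", dataset_id = paste0("i", i),
                data_structure_documented = grid$doc[i],
                data_vocabulary_practice = grid$vocab[i],
                metadata_structure = grid$ms[i],
                metadata_vocabulary = grid$mv[i])))
  got <- score_interoperable(recs)
  expect_equal(got$i1, as.numeric(grid$doc %in% "yes"))
  expect_equal(got$i2, vapply(grid$vocab, oracle_i2, numeric(1),
                              USE.NAMES = FALSE))
  expect_equal(got$i3, vapply(grid$ms, oracle_i3, numeric(1),
                              USE.NAMES = FALSE))
  expect_equal(got$i4, vapply(grid$mv, oracle_i2, numeric(1),
                              USE.NAMES = FALSE))
})

test_that("R1-R3 match their ladder decision tables exhaustively", {
  grid <- expand.grid(
    rich = c("all_available", "one_missing", "more_missing", NA),
    proc = c("full", "partial", "none", NA),
    lic = c("data_and_metadata", "data_only", "none", NA),
    stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    make_record("best", dataset_id = paste0("r", i),
                rich_metadata_elements = grid$rich[i],
                process_documentation = grid$proc[i],
                licence_status = grid$lic[i])))
  got <- score_reusable(recs)
  expect_equal(got$r1, vapply(grid$rich, oracle_ladder3, numeric(1),
                              full = "all_available", half = "one_missing",
                              USE.NAMES = FALSE))
  expect_equal(got$r2, vapply(grid$proc, oracle_ladder3, numeric(1),
                              full = "full", half = "partial",
                              USE.NAMES = FALSE))
  expect_equal(got$r3, vapply(grid$lic, oracle_ladder3, numeric(1),
                              full = "data_and_metadata", half = "data_only",
                              USE.NAMES = FALSE))
})

test_that("score_fair composes the principle scorers and counts fulfilment", {
  best <- score_fair(make_record("best", dataset_id = "top"))
  expect_equal(best$total, 12)
  expect_equal(best$criteria_fulfilled, 12L)
  worst <- score_fair(make_record("worst", dataset_id = "bottom"))
  expect_equal(worst$total, 0)
  expect_equal(worst$criteria_fulfilled, 0L)

  # a mixed record: f1=1 f2=0 f3=0 a1=1 a2=0 i1=1 i2=1 i3=0 i4=0 r1=1 r2=0.5 r3=0
  mixed <- make_record("worst", dataset_id = "mid",
                       data_identifier_present = TRUE,
                       data_access_mode = "url",
                       data_structure_documented = "yes",
                       data_vocabulary_practice = "collaborative",
                       rich_metadata_elements = "all_available",
                       process_documentation = "partial")
  sc <- score_fair(mixed)
  expect_equal(sc$total, 5.5)
  expect_equal(sc$criteria_fulfilled, 5L)
  expect_equal(sc$findable_subtotal, 1)
  expect_equal(sc$reusable_subtotal, 1.5)
  # subtotal/total consistency
  expect_equal(sc$total, sum(sc[, fair_criteria()]))
})

test_that("identifier alone is findable; one missing element is partial", {
  sc <- score_fair(make_record("worst", dataset_id = "d1",
                               data_identifier_present = TRUE))
  expect_equal(c(sc$f1, sc$f2, sc$f3), c(1, 0, 0))
  part <- score_findable(make_record("worst", dataset_id = "d2",
    data_identifying_elements = "name;responsible_organisation"))
  expect_equal(part$f1, 0.5)
  manual <- score_findable(make_record("best", dataset_id = "d3",
                                       metadata_link_update = "manual"))
  expect_equal(manual$f3, 0.5)
})

test_that("criterion_status maps scores and rejects other values", {
  expect_equal(criterion_status(c(1, 0.5, 0)),
               c("fulfilled", "partial", "not_fulfilled"))
  expect_error(criterion_status(0.7), "domain error")
})

test_that("single-field upgrades never decrease any criterion score", {
  set.seed(421)
  n <- 2000
  base <- random_scored_records(n)
  fields <- sample(names(upgrade_ladders), n, replace = TRUE)
  upgraded <- base
  for (f in unique(fields)) {
    upgraded <- upgrade_field(upgraded, f, which(fields == f))
  }
  s0 <- score_fair(base)
  s1 <- score_fair(upgraded)
  cols <- c(fair_criteria(), "total")
  for (cn in cols) {
    expect_true(all(s1[[cn]] >= s0[[cn]]),
                info = paste("criterion decreased under upgrade:", cn))
  }
})
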
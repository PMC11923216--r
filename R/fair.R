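# Twelve-criterion FAIR compliance rubric.
#
# The rubric adapts the FAIR guiding principles to non-scholarly livestock
# datasets: identifiers need only be locally unique, machine-actionability is
# relaxed to human-actionability, and registration in searchable resources is
# not assessed. Criteria F1-F3 and R1-R3 admit partial credit (0.5); the
# accessibility and interoperability criteria are binary. Missing or
# "unknown" answers never satisfy a condition.

flag_true <- function(x) !is.na(x) & as.logical(x)

#' Findability scores (F1-F3)
#'
#' F1: the data are uniquely identifiable through time, either via a unique
#' identifier or because all identifying elements (name, version or release
#' date, responsible organisation) are available; exactly one missing element
#' gives partial credit. F2 is the analogue for the metadata. F3 scores the
#' link between data and metadata: automatic updates score 1, manual 0.5,
#' no link or no metadata 0.
#'
#' @param records Record data frame or `survey_table`.
#' @return Data frame with numeric columns `f1`, `f2`, `f3`.
#' @export
score_findable <- function(records) {
  if (inherits(records, "survey_table")) records <- records$records
  element_score <- function(present, elements) {
    n <- multi_len(elements)
    ifelse(flag_true(present) | n == 3L, 1, ifelse(n == 2L, 0.5, 0))
  }
  meta_yes <- tri_yes(records$metadata_exist)
  link <- norm_token(records$metadata_link_update)
  f3 <- ifelse(meta_yes & !is.na(link) & link == "automatic", 1,
        ifelse(meta_yes & !is.na(link) & link == "manual", 0.5, 0))
  data.frame(
    f1 = element_score(records$data_identifier_present,
                       records$data_identifying_elements),
    f2 = element_score(records$metadata_identifier_present,
                       records$metadata_identifying_elements),
    f3 = f3)
}

#' Accessibility scores (A1-A2)
#'
#' A dataset (A1) or its metadata (A2) is accessible when a document
#' describing the access protocol exists or a URL is available.
#'
#' @inheritParams score_findable
#' @return Data frame with integer columns `a1`, `a2`.
#' @export
score_accessible <- function(records) {
  if (inherits(records, "survey_table")) records <- records$records
  open_access <- function(x) {
    x <- norm_token(x)
    as.numeric(!is.na(x) & x %in% c("documented_protocol", "url"))
  }
  data.frame(a1 = open_access(records$data_access_mode),
             a2 = open_access(records$metadata_access_mode))
}

#' Interoperability scores (I1-I4)
#'
#' I1: the data structure is documented. I2: the data vocabulary is based on
#' a standard, a retrievable glossary, or was defined collaboratively —
#' i.e. comprehensible to someone with no prior knowledge of the data.
#' I3: the metadata structure follows a standard schema or is documented.
#' I4: the metadata vocabulary meets the same bar as I2.
#'
#' @inheritParams score_findable
#' @return Data frame with columns `i1`..`i4`.
#' @export
score_interoperable <- function(records) {
  if (inherits(records, "survey_table")) records <- records$records
  comprehensive <- function(x) {
    x <- norm_token(x)
    as.numeric(!is.na(x) &
                 x %in% c("standard", "retrievable_glossary", "collaborative"))
  }
  ms <- norm_token(records$metadata_structure)
  data.frame(
    i1 = as.numeric(tri_yes(records$data_structure_documented)),
    i2 = comprehensive(records$data_vocabulary_practice),
    i3 = as.numeric(!is.na(ms) & ms %in% c("standard_schema", "documented")),
    i4 = comprehensive(records$metadata_vocabulary))
}

#' Reusability scores (R1-R3)
#'
#' R1: all elements needed to construct or reconstruct rich metadata are
#' available (one missing element gives 0.5). R2: the data collection and
#' quality processes are documented (partially: 0.5). R3: data and metadata
#' are both licensed (data only: 0.5).
#'
#' @inheritParams score_findable
#' @return Data frame with columns `r1`, `r2`, `r3`.
#' @export
score_reusable <- function(records) {
  if (inherits(records, "survey_table")) records <- records$records
  ladder <- function(x, full, half) {
    x <- norm_token(x)
    ifelse(!is.na(x) & x == full, 1, ifelse(!is.na(x) & x == half, 0.5, 0))
  }
  data.frame(
    r1 = ladder(records$rich_metadata_elements, "all_available", "one_missing"),
    r2 = ladder(records$process_documentation, "full", "partial"),
    r3 = ladder(records$licence_status, "data_and_metadata", "data_only"))
}

#' Full FAIR compliance score
#'
#' Composes the four principle scorers into a per-dataset score sheet with
#' per-principle subtotals, the grand total over the 12 criteria (0-12), and
#' the count of criteria fully fulfilled (score exactly 1; partial credit is
#' reported but does not count as fulfilment).
#'
#' @inheritParams score_findable
#' @return Data frame of class `fair_score`: `dataset_id`, the 12 criterion
#'   columns, `findable_subtotal`, `accessible_subtotal`,
#'   `interoperable_subtotal`, `reusable_subtotal`, `total`,
#'   `criteria_fulfilled`.
#' @export
#' @examples
#' cfg <- paper_like_config(seed = 1)
#' fs <- score_fair(generate_cohort(cfg))
#' range(fs$total)
score_fair <- function(records) {
  if (inherits(records, "survey_table")) records <- records$records
  out <- cbind(
    data.frame(dataset_id = records$dataset_id),
    score_findable(records), score_accessible(records),
    score_interoperable(records), score_reusable(records))
  crit <- fair_criteria()
  out$findable_subtotal <- out$f1 + out$f2 + out$f3
  out$accessible_subtotal <- out$a1 + out$a2
  out$interoperable_subtotal <- out$i1 + out$i2 + out$i3 + out$i4
  out$reusable_subtotal <- out$r1 + out$r2 + out$r3
  out$total <- out$findable_subtotal + out$accessible_subtotal +
    out$interoperable_subtotal + out$reusable_subtotal
  out$criteria_fulfilled <- as.integer(rowSums(out[, crit, drop = FALSE] == 1))
  class(out) <- c("fair_score", "data.frame")
  out
}

#' Names of the 12 FAIR criteria, in rubric order
#' @return Character vector `c("f1", ..., "r3")`.
#' @export
fair_criteria <- function() {
  c("f1", "f2", "f3", "a1", "a2", "i1", "i2", "i3", "i4", "r1", "r2", "r3")
}

#' Fulfilment status of a criterion score
#'
#' @param score Numeric vector of criterion scores, each 0, 0.5 or 1.
#' @return Character vector: `"fulfilled"` (1), `"partial"` (0.5),
#'   `"not_fulfilled"` (0). Any other value is a domain error.
#' @export
criterion_status <- function(score) {
  bad <- !(score %in% c(0, 0.5, 1))
  if (any(bad)) {
    stop("domain error: criterion score must be 0, 0.5 or 1; got ",
         paste(unique(score[bad]), collapse = ", "), call. = FALSE)
  }
  c("not_fulfilled", "partial", "fulfilled")[match(score, c(0, 0.5, 1))]
}
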
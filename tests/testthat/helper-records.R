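# Shared fixtures: records built in code, random-record samplers, field
# upgrade ladders, and independent rubric oracles used to cross-check the
# vectorised scorers.

# a fully populated record at the given compliance level
make_record <- function(level = c("best", "worst"), dataset_id = "ds_a",
                        round = "r1", respondent_id = "resp_a", ...) {
  level <- match.arg(level)
  best <- list(
    dataset_id = dataset_id, round = round, respondent_id = respondent_id,
    respondent_is_owner = TRUE, species = "salmonids",
    language_status = "english", content_types = "laboratory_results",
    purposes = "surveillance", collection_sources = "single_source",
    collection_mode = "automated", storage_format = "relational_database",
    quality_practices = "automated_checks", contains_personal_data = "yes",
    data_subject_identified = "yes", data_subject_documented = "yes",
    data_controller_identified = "yes", data_controller_documented = "yes",
    data_owner_identified = "yes", data_identifier_present = TRUE,
    data_identifying_elements = "name;version_or_release_date;responsible_organisation",
    metadata_identifier_present = TRUE,
    metadata_identifying_elements = "name;version_or_release_date;responsible_organisation",
    metadata_exist = "yes", metadata_link_update = "automatic",
    metadata_structure = "standard_schema", metadata_vocabulary = "standard",
    metadata_access_mode = "documented_protocol",
    data_access_mode = "documented_protocol",
    data_structure_documented = "yes", data_vocabulary_practice = "standard",
    rich_metadata_elements = "all_available", process_documentation = "full",
    licence_status = "data_and_metadata", consent_publication = TRUE,
    consent_consortium = "yes", consent_repository = TRUE)
  worst <- utils::modifyList(best, list(
    respondent_is_owner = FALSE, contains_personal_data = "no",
    data_subject_identified = "no", data_subject_documented = "no",
    data_controller_identified = "no", data_controller_documented = "no",
    data_owner_identified = "no", data_identifier_present = FALSE,
    data_identifying_elements = "", metadata_identifier_present = FALSE,
    metadata_identifying_elements = "", metadata_exist = "no",
    metadata_link_update = "none_or_unknown",
    metadata_structure = "undocumented", metadata_vocabulary = "unknown",
    metadata_access_mode = "none", data_access_mode = "none",
    data_structure_documented = "no", data_vocabulary_practice = "owner_defined",
    rich_metadata_elements = "more_missing", process_documentation = "none",
    licence_status = "none", consent_consortium = "no",
    consent_repository = FALSE))
  rec <- if (level == "best") best else worst
  as.data.frame(utils::modifyList(rec, list(...)), stringsAsFactors = FALSE)
}

make_records <- function(...) {
  do.call(rbind, list(...))
}

# ordered upgrade ladders (least to most fulfilled) for the scored fields
tri_ladder <- c("unknown", "no", "yes")
upgrade_ladders <- list(
  data_identifier_present = "flag",
  metadata_identifier_present = "flag",
  data_identifying_elements = "elements",
  metadata_identifying_elements = "elements",
  metadata_exist = tri_ladder,
  metadata_link_update = c("none_or_unknown", "manual", "automatic"),
  metadata_structure = c("undocumented", "documented", "standard_schema"),
  metadata_vocabulary = c("unknown", "owner_defined", "collaborative",
                          "retrievable_glossary", "standard"),
  data_vocabulary_practice = c("unknown", "owner_defined", "collaborative",
                               "retrievable_glossary", "standard"),
  metadata_access_mode = c("none", "url", "documented_protocol"),
  data_access_mode = c("none", "url", "documented_protocol"),
  data_structure_documented = tri_ladder,
  rich_metadata_elements = c("more_missing", "one_missing", "all_available"),
  process_documentation = c("none", "partial", "full"),
  licence_status = c("none", "data_only", "data_and_metadata"),
  data_subject_identified = tri_ladder,
  data_subject_documented = tri_ladder,
  data_controller_identified = tri_ladder,
  data_controller_documented = tri_ladder)

all_elements <- c("name", "version_or_release_date", "responsible_organisation")

# n random records over the scored fields, invariants NOT enforced: scorers
# must behave monotonically on arbitrary field states
random_scored_records <- function(n) {
  pick <- function(levels) sample(c(levels, NA), n, replace = TRUE)
  rec <- data.frame(dataset_id = sprintf("rnd_%05d", seq_len(n)),
                    round = "r1",
                    respondent_id = "resp_x", species = "cattle")
  for (nm in names(upgrade_ladders)) {
    lad <- upgrade_ladders[[nm]]
    if (identical(lad, "flag")) {
      rec[[nm]] <- sample(c(TRUE, FALSE, NA), n, replace = TRUE)
    } else if (identical(lad, "elements")) {
      rec[[nm]] <- vapply(seq_len(n), function(i)
        paste(sample(all_elements, sample(0:3, 1)), collapse = ";"),
        character(1))
    } else {
      rec[[nm]] <- pick(lad)
    }
  }
  rec
}

# upgrade one field one step; rows already at the top are left unchanged
# (their scores must then be equal, which monotonicity also covers)
upgrade_field <- function(records, field, rows) {
  lad <- upgrade_ladders[[field]]
  x <- records[[field]][rows]
  if (identical(lad, "flag")) {
    records[[field]][rows] <- TRUE
  } else if (identical(lad, "elements")) {
    records[[field]][rows] <- vapply(x, function(v) {
      have <- if (is.na(v) || !nzchar(v)) character(0)
              else strsplit(v, ";", fixed = TRUE)[[1]]
      miss <- setdiff(all_elements, have)
      if (length(miss) == 0) v else paste(c(have, miss[1]), collapse = ";")
    }, character(1), USE.NAMES = FALSE)
  } else {
    pos <- match(x, lad)
    pos[is.na(pos)] <- 0L
    records[[field]][rows] <- lad[pmin(pos + 1L, length(lad))]
  }
  records
}

# ---- independent rubric oracles -------------------------------------------
# Literal decision tables over enumerated state spaces, written against the
# rubric wording, not against the package scorers.

oracle_f_element <- function(identifier_present, n_elements) {
  if (isTRUE(identifier_present)) return(1)
  if (n_elements == 3) return(1)        # all identifying elements available
  if (n_elements == 2) return(0.5)      # exactly one element unavailable
  0
}

oracle_f3 <- function(metadata_exist, link) {
  if (!identical(metadata_exist, "yes")) return(0)  # metadata not available
  if (identical(link, "automatic")) return(1)
  if (identical(link, "manual")) return(0.5)
  0                                                  # no link
}

oracle_access <- function(mode) {
  if (identical(mode, "documented_protocol") || identical(mode, "url")) 1 else 0
}

oracle_i2 <- function(vocab) {
  if (identical(vocab, "standard") || identical(vocab, "retrievable_glossary") ||
      identical(vocab, "collaborative")) 1 else 0
}

oracle_i3 <- function(structure) {
  if (identical(structure, "standard_schema") ||
      identical(structure, "documented")) 1 else 0
}

oracle_ladder3 <- function(value, full, half) {
  if (identical(value, full)) return(1)
  if (identical(value, half)) return(0.5)
  0
}

oracle_gdpr <- function(s_id, s_doc, c_id, c_doc) {
  identified <- as.integer(identical(s_id, "yes") && identical(c_id, "yes"))
  documented <- as.integer(identical(s_doc, "yes") && identical(c_doc, "yes"))
  c(identified = identified, documented = documented,
    total = identified + documented)
}
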
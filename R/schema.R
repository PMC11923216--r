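# Domain data model for survey-derived dataset descriptions.
#
# One record = one dataset described by one respondent in one survey round.
# Multi-select answers are stored as semicolon-delimited token strings so that
# records round-trip losslessly through CSV.

.tristate <- c("yes", "no", "unknown")
.species_levels <- c("cattle", "swine", "poultry", "salmonids")
.content_levels <- c("laboratory_results", "biosecurity", "production_results",
                     "treatment", "clinical_observation", "animal_movements",
                     "economic", "behaviour")
.purpose_levels <- c("production_information", "surveillance", "legislation",
                     "lab_activities", "other_business", "research_integration")
.practice_levels <- c("closed_formats", "collector_training", "manual_checks",
                      "automated_checks", "inspection_verification",
                      "feedback_loops", "standards_procedures")
.id_element_levels <- c("name", "version_or_release_date",
                        "responsible_organisation")
.vocab_levels <- c("standard", "retrievable_glossary", "collaborative",
                   "owner_defined", "unknown")
.access_levels <- c("documented_protocol", "url", "none")

#' Column dictionary for survey-derived dataset descriptions
#'
#' Describes every column of a dataset-assessment record: its type
#' (`id`, `enum`, `tristate`, `flag` or `multi` for multi-select sets) and,
#' for categorical columns, the closed set of accepted tokens. The same
#' dictionary drives reading, validation and synthetic generation. A copy is
#' shipped as YAML in `inst/extdata/column_dictionary.yaml`.
#'
#' @return A named list, one entry per column, each with elements `type`,
#'   `mandatory` and (for categorical columns) `levels`.
#' @export
#' @examples
#' names(survey_dictionary())
survey_dictionary <- function() {
  enum <- function(levels, mandatory = FALSE)
    list(type = "enum", levels = levels, mandatory = mandatory)
  multi <- function(levels) list(type = "multi", levels = levels, mandatory = FALSE)
  tri <- function() list(type = "tristate", levels = .tristate, mandatory = FALSE)
  flag <- function() list(type = "flag", mandatory = FALSE)

  list(
    dataset_id    = list(type = "id", mandatory = TRUE),
    round         = enum(c("r1", "r2"), mandatory = TRUE),
    respondent_id = list(type = "id", mandatory = TRUE),
    respondent_is_owner = flag(),
    species        = multi(.species_levels),
    language_status = enum(c("english", "not_english", "translated")),
    content_types  = multi(.content_levels),
    purposes       = multi(.purpose_levels),
    collection_sources = enum(c("single_source", "multiple_same_type",
                                "multiple_different_type", "unreported")),
    collection_mode = enum(c("automated", "manual", "unreported")),
    storage_format = enum(c("relational_database", "spreadsheet_collection",
                            "single_spreadsheet", "pdf_collection")),
    quality_practices = multi(.practice_levels),
    contains_personal_data = tri(),
    data_subject_identified    = tri(),
    data_subject_documented    = tri(),
    data_controller_identified = tri(),
    data_controller_documented = tri(),
    data_owner_identified      = tri(),
    data_identifier_present     = flag(),
    data_identifying_elements   = multi(.id_element_levels),
    metadata_identifier_present = flag(),
    metadata_identifying_elements = multi(.id_element_levels),
    metadata_exist       = tri(),
    metadata_link_update = enum(c("automatic", "manual", "none_or_unknown")),
    metadata_structure   = enum(c("standard_schema", "documented", "undocumented")),
    metadata_vocabulary  = enum(.vocab_levels),
    metadata_access_mode = enum(.access_levels),
    data_access_mode     = enum(.access_levels),
    data_structure_documented = tri(),
    data_vocabulary_practice  = enum(.vocab_levels),
    rich_metadata_elements = enum(c("all_available", "one_missing", "more_missing")),
    process_documentation  = enum(c("full", "partial", "none")),
    licence_status = enum(c("data_and_metadata", "data_only", "none")),
    consent_publication = flag(),
    consent_consortium  = enum(c("yes", "conditional", "no")),
    consent_repository  = flag()
  )
}

# normalise a categorical token: trim, lower-case (d9 dialect rule)
norm_token <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

# split a multi-select cell into its tokens (empty/NA -> character(0))
split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  toks <- norm_token(strsplit(x, ";", fixed = TRUE)[[1]])
  toks[!is.na(toks)]
}

# number of tokens per cell, vectorised
multi_len <- function(x) {
  vapply(as.character(x), function(v) length(split_multi(v)), integer(1),
         USE.NAMES = FALSE)
}

# does each cell contain the given token?
multi_has <- function(x, token) {
  vapply(as.character(x), function(v) token %in% split_multi(v), logical(1),
         USE.NAMES = FALSE)
}

record_key <- function(records) {
  paste(records$dataset_id, records$round, records$respondent_id, sep = "\r")
}

#' Construct a survey table
#'
#' A `survey_table` bundles the assessment records with the per-answer quality
#' scores and a provenance log of every post-collection edit (merges,
#' anonymisation, reclassification).
#'
#' @param records Data frame of dataset-assessment records, one row per
#'   `(dataset_id, round, respondent_id)`; columns per [survey_dictionary()].
#' @param answer_qualities Optional data frame with columns `question_id`,
#'   `respondent_id`, `completeness`, `coherence` (each score 0 or 1).
#' @param provenance_log Optional data frame with columns `key`, `field`,
#'   `old`, `new`, `reason`.
#' @return An object of class `survey_table`.
#' @export
survey_table <- function(records, answer_qualities = NULL, provenance_log = NULL) {
  stopifnot(is.data.frame(records))
  dict <- survey_dictionary()
  mandatory <- names(dict)[vapply(dict, function(d) isTRUE(d$mandatory), logical(1))]
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # fill absent optional columns with NA of the right storage type
  for (nm in setdiff(names(dict), names(records))) {
    records[[nm]] <- if (dict[[nm]]$type == "flag") NA else NA_character_
  }
  records <- records[, names(dict)]
  rownames(records) <- NULL
  key <- record_key(records)
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), c("dataset_id", "round", "respondent_id")]
    stop("key-collision error: duplicate (dataset_id, round, respondent_id): ",
         paste(unique(paste0(dup$dataset_id, "/", dup$round, "/", dup$respondent_id)),
               collapse = "; "), call. = FALSE)
  }
  if (is.null(answer_qualities)) {
    answer_qualities <- data.frame(question_id = character(0),
                                   respondent_id = character(0),
                                   completeness = integer(0),
                                   coherence = integer(0))
  }
  if (is.null(provenance_log)) provenance_log <- empty_provenance()
  structure(list(records = records,
                 answer_qualities = answer_qualities,
                 provenance_log = provenance_log),
            class = "survey_table")
}

empty_provenance <- function() {
  data.frame(key = character(0), field = character(0), old = character(0),
             new = character(0), reason = character(0))
}

add_provenance <- function(log, key, field, old, new, reason) {
  rbind(log, data.frame(key = as.character(key), field = field,
                        old = as.character(old), new = as.character(new),
                        reason = reason))
}

#' @export
print.survey_table <- function(x, ...) {
  r <- x$records
  cat("Survey table:", nrow(r), "record(s),",
      length(unique(r$dataset_id)), "dataset(s),",
      length(unique(r$respondent_id)), "respondent(s)\n")
  cat("  rounds:", paste(sort(unique(r$round)), collapse = ", "), "\n")
  cat("  answer qualities:", nrow(x$answer_qualities),
      "| provenance entries:", nrow(x$provenance_log), "\n")
  invisible(x)
}

#' Validate dataset-assessment records
#'
#' Checks every record against the column dictionary and the cross-field
#' consistency rules: species must be non-empty; categorical tokens must come
#' from the dictionary; a governance role documented as formalised must also be
#' identified; and a dataset without metadata cannot report metadata links,
#' structure or access. Violations are returned as data, not raised.
#'
#' @param records A data frame of records or a `survey_table`.
#' @return A data frame with columns `dataset_id`, `round`, `respondent_id`,
#'   `field`, `rule`; zero rows when all invariants hold.
#' @export
#' @examples
#' cfg <- paper_like_config(seed = 1)
#' tab <- generate_cohort(cfg)
#' nrow(validate_records(tab))  # 0
validate_records <- function(records) {
  if (inherits(records, "survey_table")) records <- records$records
  dict <- survey_dictionary()
  out <- list()
  flag_violation <- function(idx, field, rule) {
    out[[length(out) + 1]] <<- data.frame(
      dataset_id = records$dataset_id[idx], round = records$round[idx],
      respondent_id = records$respondent_id[idx], field = field, rule = rule)
  }

  for (nm in intersect(names(dict), names(records))) {
    d <- dict[[nm]]
    x <- records[[nm]]
    if (d$type %in% c("enum", "tristate")) {
      bad <- which(!is.na(x) & !(norm_token(x) %in% d$levels))
      if (length(bad)) flag_violation(bad, nm, paste0("value not in {",
          paste(d$levels, collapse = ", "), "}"))
    } else if (d$type == "multi") {
      bad <- which(vapply(as.character(x), function(v) {
        toks <- if (is.na(v)) character(0) else split_multi(v)
        length(setdiff(toks, d$levels)) > 0
      }, logical(1), USE.NAMES = FALSE))
      if (length(bad)) flag_violation(bad, nm, "token outside the fixed checklist")
    }
  }
  bad <- which(multi_len(records$species) == 0)
  if (length(bad)) flag_violation(bad, "species", "species set must be non-empty")

  for (role in c("data_subject", "data_controller")) {
    doc <- norm_token(records[[paste0(role, "_documented")]])
    idt <- norm_token(records[[paste0(role, "_identified")]])
    bad <- which(!is.na(doc) & doc == "yes" & (is.na(idt) | idt != "yes"))
    if (length(bad)) flag_violation(bad, paste0(role, "_documented"),
      "a role cannot be documented but unidentified")
  }

  meta_no <- !is.na(records$metadata_exist) & norm_token(records$metadata_exist) == "no"
  consistency <- list(
    metadata_link_update = "none_or_unknown",
    metadata_structure   = "undocumented",
    metadata_access_mode = "none")
  for (nm in names(consistency)) {
    x <- norm_token(records[[nm]])
    bad <- which(meta_no & !is.na(x) & x != consistency[[nm]])
    if (length(bad)) flag_violation(bad, nm,
      paste0("metadata_exist=no forces ", nm, "=", consistency[[nm]]))
  }
  if (length(out) == 0) {
    return(data.frame(dataset_id = character(0), round = character(0),
                      respondent_id = character(0), field = character(0),
                      rule = character(0)))
  }
  do.call(rbind, out)
}

#' @rdname validate_records
#' @param record A single record as a one-row data frame or named list.
#' @export
validate_record <- function(record) {
  if (!is.data.frame(record)) record <- as.data.frame(record, stringsAsFactors = FALSE)
  stopifnot(nrow(record) == 1)
  dict <- survey_dictionary()
  for (nm in setdiff(names(dict), names(record))) {
    record[[nm]] <- if (dict[[nm]]$type == "flag") NA else NA_character_
  }
  validate_records(record)
}

# map free-form truthy/falsy tokens to logical
parse_flag <- function(x) {
  tok <- norm_token(x)
  out <- rep(NA, length(tok))
  out[tok %in% c("true", "yes", "1", "t")] <- TRUE
  out[tok %in% c("false", "no", "0", "f")] <- FALSE
  out
}

#' Read a survey-response table
#'
#' Reads a table of dataset-assessment records (one row per dataset x
#' respondent x round) from CSV, JSON or XLSX, normalises categorical tokens
#' (trimmed, case-insensitive), applies reclassification rules to any raw
#' identifying columns present (e.g. a free-text `language` column becomes
#' `language_status`), and validates the result against the column dictionary.
#' Unknown categorical tokens are mapped to `unknown` (or `NA` for enums with
#' no `unknown` level) with a warning; missing mandatory columns and duplicate
#' record keys raise errors.
#'
#' @param path Path to the input file.
#' @param format One of `"csv"`, `"json"`, `"xlsx"`. Defaults from the file
#'   extension. XLSX reading uses the first sheet and requires the readxl
#'   package.
#' @param rules Reclassification rules, see [default_reclassification_rules()].
#' @return A [survey_table()].
#' @export
read_survey <- function(path, format = c("auto", "csv", "json", "xlsx"),
                        rules = default_reclassification_rules()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", json = "json", xlsx = "xlsx",
                     stop("cannot infer format from extension: ", ext, call. = FALSE))
  }
  raw <- switch(format,
    csv  = utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = "NA"),
    json = as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the readxl package", call. = FALSE)
      as.data.frame(readxl::read_xlsx(path, sheet = 1, col_types = "text"))
    })
  as_survey_table(raw, rules = rules)
}

# Build a validated survey_table from a raw character data frame: reclassify
# raw identifying columns, normalise tokens, coerce flags, warn on unknowns.
as_survey_table <- function(raw, rules = default_reclassification_rules()) {
  dict <- survey_dictionary()
  log <- empty_provenance()

  # raw identifying columns with a reclassification rule -> dictionary column
  raw_map <- c(language = "language_status", data_owner_name = "data_owner_identified")
  for (nm in intersect(names(raw_map), names(raw))) {
    target <- raw_map[[nm]]
    vals <- vapply(as.character(raw[[nm]]),
                   function(v) reclassify_field(nm, v, rules = rules),
                   character(1), USE.NAMES = FALSE)
    if (!target %in% names(raw)) raw[[target]] <- vals
    log <- add_provenance(log,
      key = if ("dataset_id" %in% names(raw)) raw$dataset_id else NA,
      field = nm, old = as.character(raw[[nm]]), new = vals,
      reason = "reclassified")
    raw[[nm]] <- NULL
  }

  mandatory <- names(dict)[vapply(dict, function(d) isTRUE(d$mandatory), logical(1))]
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  unknown_notes <- character(0)
  for (nm in intersect(names(dict), names(raw))) {
    d <- dict[[nm]]
    if (d$type == "flag") {
      raw[[nm]] <- parse_flag(raw[[nm]])
    } else if (d$type %in% c("enum", "tristate")) {
      x <- norm_token(raw[[nm]])
      bad <- !is.na(x) & !(x %in% d$levels)
      if (any(bad)) {
        repl <- if ("unknown" %in% d$levels) "unknown" else NA_character_
        unknown_notes <- c(unknown_notes,
          paste0(nm, ": ", paste(unique(x[bad]), collapse = ", ")))
        log <- add_provenance(log, key = raw$dataset_id[bad], field = nm,
                              old = x[bad], new = repl,
                              reason = "unknown token")
        x[bad] <- repl
      }
      raw[[nm]] <- x
    } else if (d$type == "multi") {
      x <- as.character(raw[[nm]])
      cleaned <- vapply(x, function(v) {
        if (is.na(v)) return(NA_character_)
        toks <- split_multi(v)
        paste(toks[toks %in% d$levels], collapse = ";")
      }, character(1), USE.NAMES = FALSE)
      dropped <- !is.na(x) & multi_len(x) != multi_len(cleaned)
      if (any(dropped)) {
        unknown_notes <- c(unknown_notes, paste0(nm, ": token(s) outside checklist"))
        log <- add_provenance(log, key = raw$dataset_id[dropped], field = nm,
                              old = x[dropped], new = cleaned[dropped],
                              reason = "unknown token")
      }
      raw[[nm]] <- cleaned
    } else {
      raw[[nm]] <- as.character(raw[[nm]])
    }
  }
  if (length(unknown_notes) > 0) {
    warning("unknown categorical token(s) mapped to unknown/NA: ",
            paste(unknown_notes, collapse = "; "), call. = FALSE)
  }
  extra <- setdiff(names(raw), names(dict))
  if (length(extra) > 0) raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
  survey_table(raw, provenance_log = log)
}

#' Write survey records to CSV
#'
#' Inverse of [read_survey()] for the CSV dialect; multi-select sets stay
#' semicolon-delimited, so `read_survey(write_survey(tab, f))` round-trips.
#'
#' @param table A `survey_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(table, path) {
  stopifnot(inherits(table, "survey_table"))
  # NA (missing answer) and "" (empty multi-select set) are distinct
  utils::write.csv(table$records, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-answer quality table
#'
#' @param path CSV file with columns `question_id`, `respondent_id`,
#'   `completeness`, `coherence`.
#' @return A validated data frame of answer-quality scores.
#' @export
read_answer_quality <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("question_id", "respondent_id", "completeness", "coherence")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  answer_quality(x$question_id, x$respondent_id, x$completeness, x$coherence)
}
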
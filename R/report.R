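# Cohort characterisation and compliance summaries.

#' Integer percentage, halves rounded away from zero
#'
#' All percentages in reports are derived through this single function so the
#' rounding convention is uniform: `percent(30, 38)` is 79, `percent(6, 19)`
#' is 32, `percent(20, 30)` is 67, `percent(4, 30)` is 13.
#'
#' @param numerator Count(s), `0 <= numerator <= denominator`.
#' @param denominator Positive count.
#' @return Integer percentage(s).
#' @export
percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("domain error: denominator must be positive", call. = FALSE)
  }
  if (any(numerator < 0 | numerator > denominator)) {
    stop("domain error: numerator must lie in [0, denominator]", call. = FALSE)
  }
  as.integer(floor(100 * numerator / denominator + 0.5))
}

count_multi <- function(x, levels) {
  stats::setNames(vapply(levels, function(l) sum(multi_has(x, l)), integer(1)),
                  levels)
}

count_enum <- function(x, levels) {
  x <- norm_token(x)
  stats::setNames(vapply(levels, function(l) sum(!is.na(x) & x == l), integer(1)),
                  levels)
}

#' Summarise a scored cohort
#'
#' Builds the full characterisation and compliance summary of a merged,
#' anonymised cohort: dataset and respondent counts, per-species counts
#' (multi-species datasets count once in each species), characterisation
#' tallies, per-criterion FAIR fulfilment counts, the number of datasets
#' fulfilling at least half (>= 6 of 12) and all of the FAIR criteria, GDPR
#' accountability counts and owner/user mean scores, and consent counts.
#'
#' @param table A `survey_table`, one record per dataset (post-merge).
#' @param fair `fair_score` rows covering every dataset in the table.
#' @param gdpr `gdpr_score` rows (cohort form, see [score_gdpr_cohort()]).
#' @return Object of class `cohort_summary` (a named list).
#' @export
summarize_cohort <- function(table, fair, gdpr) {
  recs <- if (inherits(table, "survey_table")) table$records else table
  missing_fair <- setdiff(recs$dataset_id, fair$dataset_id)
  missing_gdpr <- setdiff(recs$dataset_id, gdpr$dataset_id)
  if (length(missing_fair) > 0 || length(missing_gdpr) > 0) {
    stop("completeness error: score missing for dataset(s): ",
         paste(unique(c(missing_fair, missing_gdpr)), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(recs)
  crit <- fair_criteria()
  fair <- fair[match(recs$dataset_id, fair$dataset_id), , drop = FALSE]
  gdpr <- gdpr[match(recs$dataset_id, gdpr$dataset_id), , drop = FALSE]

  fair_counts <- lapply(stats::setNames(crit, crit), function(cn) {
    s <- fair[[cn]]
    list(fulfilled = sum(s == 1), partial = sum(s == 0.5),
         not_fulfilled = sum(s == 0))
  })

  app <- gdpr$applicable %in% TRUE
  owner_flags <- stats::setNames(recs$respondent_is_owner %in% TRUE,
                                 recs$dataset_id)
  role_means <- mean_score_by_role(gdpr[app, , drop = FALSE], owner_flags)

  structure(list(
    n_datasets = n,
    n_respondents = length(unique(recs$respondent_id)),
    species_counts = count_multi(recs$species, .species_levels),
    n_multi_species = sum(multi_len(recs$species) > 1),
    language_counts = count_enum(recs$language_status,
                                 c("english", "not_english", "translated")),
    content_type_counts = count_multi(recs$content_types, .content_levels),
    purpose_counts = count_multi(recs$purposes, .purpose_levels),
    n_multi_purpose = sum(multi_len(recs$purposes) > 1),
    collection_source_counts = count_enum(recs$collection_sources,
      c("single_source", "multiple_same_type", "multiple_different_type",
        "unreported")),
    collection_mode_counts = count_enum(recs$collection_mode,
      c("automated", "manual", "unreported")),
    storage_format_counts = count_enum(recs$storage_format,
      c("relational_database", "spreadsheet_collection", "single_spreadsheet",
        "pdf_collection")),
    quality_practice_counts = count_multi(recs$quality_practices,
                                          .practice_levels),
    vocabulary_counts = count_enum(recs$data_vocabulary_practice, .vocab_levels),
    n_metadata_exist = unname(count_enum(recs$metadata_exist, "yes")),
    n_personal_data = unname(count_enum(recs$contains_personal_data, "yes")),
    fair_criterion_counts = fair_counts,
    n_at_least_half_criteria = sum(fair$criteria_fulfilled >= 6),
    n_all_criteria = sum(fair$criteria_fulfilled == 12),
    fair_total_mean = if (n > 0) mean(fair$total) else NA_real_,
    gdpr = list(
      n_applicable = sum(app),
      identified_count = sum(gdpr$identified_roles[app] == 1),
      documented_count = sum(gdpr$documented_roles[app] == 1),
      full_compliance_count = sum(gdpr$total[app] == 2),
      owner_mean = unname(role_means["owner_mean"]),
      user_mean = unname(role_means["user_mean"])),
    consent = list(
      publication_yes = sum(recs$consent_publication %in% TRUE),
      consortium_conditional = unname(count_enum(recs$consent_consortium,
                                                 "conditional")),
      repository_refused = sum(!(recs$consent_repository %in% TRUE)))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  n <- x$n_datasets
  cat("Cohort summary:", n, "dataset(s),", x$n_respondents, "respondent(s)\n")
  if (n > 0) {
    sp <- x$species_counts
    cat("  species:",
        paste(sprintf("%s %d (%d%%)", names(sp), sp, percent(pmin(sp, n), max(n, 1))),
              collapse = ", "), "\n")
    cat("  personal data:", x$n_personal_data,
        sprintf("(%d%%)", percent(x$n_personal_data, n)),
        "| metadata available:", x$n_metadata_exist,
        sprintf("(%d%%)", percent(x$n_metadata_exist, n)), "\n")
    cat("  FAIR: >= half of criteria fulfilled:", x$n_at_least_half_criteria,
        "| all criteria:", x$n_all_criteria, "\n")
    cat("  GDPR applicable:", x$gdpr$n_applicable,
        "| fully compliant:", x$gdpr$full_compliance_count, "\n")
  }
  invisible(x)
}

#' Per-dataset FAIR totals grouped by species
#'
#' Multi-species datasets appear once in each of their species groups, with a
#' duplicate flag.
#'
#' @param fair `fair_score` rows.
#' @param table `survey_table` giving the species of every scored dataset.
#' @return Data frame: `species`, `dataset_id`, `total`, `multi_species`.
#' @export
fair_breakdown_by_species <- function(fair, table) {
  recs <- if (inherits(table, "survey_table")) table$records else table
  if (nrow(fair) == 0) {
    return(data.frame(species = character(0), dataset_id = character(0),
                      total = numeric(0), multi_species = logical(0)))
  }
  missing_sp <- setdiff(fair$dataset_id, recs$dataset_id)
  if (length(missing_sp) > 0) {
    stop("species unknown for scored dataset(s): ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  recs <- recs[match(fair$dataset_id, recs$dataset_id), , drop = FALSE]
  parts <- lapply(seq_len(nrow(fair)), function(i) {
    sp <- split_multi(recs$species[i])
    data.frame(species = sp, dataset_id = fair$dataset_id[i],
               total = fair$total[i], multi_species = length(sp) > 1)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$species, -out$total), ]
  rownames(out) <- NULL
  out
}

# named atomic vectors must become objects (not nameless arrays) in JSON
summary_to_json <- function(x) {
  if (is.list(x)) {
    lapply(x, summary_to_json)
  } else if (!is.null(names(x)) && length(x) > 1) {
    as.list(x)
  } else {
    x
  }
}

# flatten a cohort_summary into a two-column key/value frame (for CSV)
flatten_summary <- function(summary) {
  kv <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste0(prefix, nm, "."))
    } else if (length(x) > 1 && !is.null(names(x))) {
      for (nm in names(x)) kv[[paste0(prefix, nm)]] <<- unname(x[[nm]])
    } else {
      kv[[substr(prefix, 1, nchar(prefix) - 1)]] <<- unname(x)
    }
  }
  walk(unclass(summary), "")
  data.frame(key = names(kv),
             value = vapply(kv, function(v) as.character(v[1]), character(1)),
             row.names = NULL)
}

#' Write a cohort summary to disk
#'
#' JSON output round-trips exactly through [read_report()]; CSV flattens the
#' summary to key/value rows; markdown renders a human-readable digest with
#' one line per FAIR criterion.
#'
#' @param summary A `cohort_summary`.
#' @param path Output file path.
#' @param format One of `"json"`, `"csv"`, `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(summary, path, format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "cohort_summary"))
  if (format == "json") {
    jsonlite::write_json(summary_to_json(unclass(summary)), path,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  } else if (format == "csv") {
    utils::write.csv(flatten_summary(summary), path, row.names = FALSE)
  } else {
    lines <- c("# Dataset reusability summary", "",
               sprintf("Datasets: %d; respondents: %d.", summary$n_datasets,
                       summary$n_respondents), "",
               "## FAIR criterion fulfilment", "")
    for (cn in names(summary$fair_criterion_counts)) {
      cc <- summary$fair_criterion_counts[[cn]]
      lines <- c(lines, sprintf("- %s: fulfilled %d, partial %d, not fulfilled %d",
                                toupper(cn), cc$fulfilled, cc$partial,
                                cc$not_fulfilled))
    }
    lines <- c(lines, "",
               sprintf("Datasets fulfilling at least half of the criteria: %d; all criteria: %d.",
                       summary$n_at_least_half_criteria, summary$n_all_criteria),
               sprintf("GDPR-applicable datasets: %d; fully compliant: %d.",
                       summary$gdpr$n_applicable,
                       summary$gdpr$full_compliance_count))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a JSON cohort summary
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A `cohort_summary`.
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (nm in c("species_counts", "language_counts", "content_type_counts",
               "purpose_counts", "collection_source_counts",
               "collection_mode_counts", "storage_format_counts",
               "quality_practice_counts", "vocabulary_counts")) {
    x[[nm]] <- unlist(x[[nm]])
  }
  structure(x, class = "cohort_summary")
}
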
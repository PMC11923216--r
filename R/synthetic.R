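# Seeded synthetic survey-cohort generator.
#
# Emulates the categorical structure of a livestock-sector dataset survey:
# ~30 datasets described by ~19 respondents over two survey rounds, with
# tristate governance answers, metadata-dependent fields kept consistent by
# construction, species mixes with overlaps, and per-question answer-quality
# scores. Each categorical field is drawn either from probability weights or
# from exact count quotas (quota mode), so study-sized cohorts can match the
# published marginal counts exactly while large cohorts exercise the
# statistical properties.

# draw n values for an enum field from a spec: list(probs = named numeric)
# for weighted sampling, or list(counts = named integer) for exact quotas
draw_enum <- function(n, spec, field) {
  if (!is.null(spec$counts)) {
    counts <- spec$counts
    if (sum(counts) != n) {
      stop("configuration error: quota counts for '", field, "' sum to ",
           sum(counts), ", expected ", n, call. = FALSE)
    }
    sample(rep(names(counts), counts))
  } else if (!is.null(spec$probs)) {
    p <- spec$probs
    sample(names(p), n, replace = TRUE, prob = p)
  } else {
    stop("configuration error: spec for '", field,
         "' needs $probs or $counts", call. = FALSE)
  }
}

# independent per-token inclusion for a multi-select field
draw_multi <- function(n, token_probs) {
  m <- vapply(token_probs, function(p) stats::runif(n) < p, logical(n))
  if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(token_probs)))
  apply(m, 1, function(row) paste(names(token_probs)[row], collapse = ";"))
}

check_probs <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop("configuration error: ", what, " must be probabilities in [0,1]",
         call. = FALSE)
  }
  invisible(x)
}

#' Build a synthetic-cohort generator configuration
#'
#' Every categorical field of a dataset-assessment record gets either
#' probability weights (`list(probs = ...)`) or exact count quotas
#' (`list(counts = ...)`, summing to `n_datasets`). Species quotas may name
#' multi-species combinations such as `"swine;cattle"`. Cross-field
#' consistency is enforced by construction: metadata-dependent fields are
#' only drawn for datasets whose metadata exist, and a governance role is
#' only documented if it is identified.
#'
#' @param n_datasets,n_respondents Cohort size.
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @param species,contains_personal_data,metadata_exist,language_status
#'   Enum specs for the four headline fields.
#' @param enums Named list of enum specs for the remaining single-choice
#'   fields; the metadata-prefixed ones are interpreted conditionally on
#'   `metadata_exist = "yes"`.
#' @param multis Named list of per-token inclusion probabilities for the
#'   multi-select fields.
#' @param flags Named probabilities of `TRUE` for the flag fields;
#'   `metadata_identifier_present` is conditional on existing metadata.
#' @param governance Probabilities for the governance tristates:
#'   `p_subject_identified`, `p_controller_identified`,
#'   `p_documented_given_identified`, `p_owner_identified`.
#' @param missingness Probability that a field in `missing_fields` is NA.
#' @param missing_fields Fields eligible for missingness (kept away from
#'   fields whose consistency is structural).
#' @param round2_new_fraction Fraction of datasets first described in round 2.
#' @param round2_overlap_fraction Fraction of round-1 datasets re-answered in
#'   round 2 by a different respondent.
#' @param conflict_rate Per-field probability that a re-answered dataset's
#'   round-2 value conflicts with round 1.
#' @param quality Per-survey-category completeness and coherence
#'   probabilities for the answer-quality table.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    n_datasets = 30, n_respondents = 19, seed = 1,
    species = list(probs = c(cattle = 0.30, swine = 0.30, poultry = 0.15,
                             salmonids = 0.25)),
    contains_personal_data = list(probs = c(yes = 0.37, no = 0.60,
                                            unknown = 0.03)),
    metadata_exist = list(probs = c(yes = 0.53, no = 0.47)),
    language_status = list(probs = c(english = 0.30, not_english = 0.67,
                                     translated = 0.03)),
    enums = list(),
    multis = list(),
    flags = list(),
    governance = list(p_subject_identified = 0.80,
                      p_controller_identified = 0.73,
                      p_documented_given_identified = 0.60,
                      p_owner_identified = 0.80),
    missingness = 0,
    missing_fields = c("respondent_is_owner", "collection_sources",
                       "collection_mode", "storage_format",
                       "consent_consortium"),
    round2_new_fraction = 0.2,
    round2_overlap_fraction = 0.2,
    conflict_rate = 0.1,
    quality = list(
      "A. Governance"  = c(completeness = 0.95, coherence = 0.95),
      "B. Management"  = c(completeness = 0.80, coherence = 0.70),
      "C. Data model"  = c(completeness = 0.75, coherence = 0.65),
      "D. Description" = c(completeness = 0.92, coherence = 0.90),
      "E. Metadata"    = c(completeness = 0.65, coherence = 0.55))) {

  default_enums <- list(
    collection_sources = list(probs = c(single_source = 0.37,
      multiple_same_type = 0.40, multiple_different_type = 0.20,
      unreported = 0.03)),
    collection_mode = list(probs = c(automated = 0.60, manual = 0.20,
                                     unreported = 0.20)),
    storage_format = list(probs = c(relational_database = 0.47,
      spreadsheet_collection = 0.27, single_spreadsheet = 0.23,
      pdf_collection = 0.03)),
    data_vocabulary_practice = list(probs = c(standard = 0.07,
      retrievable_glossary = 0.27, collaborative = 0.13, owner_defined = 0.40,
      unknown = 0.13)),
    data_access_mode = list(probs = c(documented_protocol = 0.50, url = 0.23,
                                      none = 0.27)),
    data_structure_documented = list(probs = c(yes = 0.83, no = 0.10,
                                               unknown = 0.07)),
    rich_metadata_elements = list(probs = c(all_available = 0.60,
      one_missing = 0.20, more_missing = 0.20)),
    process_documentation = list(probs = c(full = 0.33, partial = 0.17,
                                           none = 0.50)),
    licence_status = list(probs = c(data_and_metadata = 0.03,
                                    data_only = 0.07, none = 0.90)),
    consent_consortium = list(probs = c(yes = 0.73, conditional = 0.27,
                                        no = 0)),
    # conditional on metadata_exist = "yes"
    metadata_link_update = list(probs = c(automatic = 0.06, manual = 0.06,
                                          none_or_unknown = 0.88)),
    metadata_structure = list(probs = c(standard_schema = 0.06,
                                        documented = 0, undocumented = 0.94)),
    metadata_vocabulary = list(probs = c(standard = 0.06,
      retrievable_glossary = 0, collaborative = 0, owner_defined = 0.44,
      unknown = 0.50)),
    metadata_access_mode = list(probs = c(documented_protocol = 0.31,
                                          url = 0.19, none = 0.50)))
  default_multis <- list(
    content_types = c(laboratory_results = 0.53, biosecurity = 0.50,
      production_results = 0.47, treatment = 0.43, clinical_observation = 0.43,
      animal_movements = 0.20, economic = 0.17, behaviour = 0.13),
    purposes = c(production_information = 0.57, surveillance = 0.53,
      legislation = 0.37, lab_activities = 0.27, other_business = 0.13,
      research_integration = 0.10),
    quality_practices = c(closed_formats = 0.47, collector_training = 0.17,
      manual_checks = 0.17, automated_checks = 0.47,
      inspection_verification = 0.13, feedback_loops = 0.57,
      standards_procedures = 0.60),
    data_identifying_elements = c(name = 0.8, version_or_release_date = 0.4,
                                  responsible_organisation = 0.6),
    metadata_identifying_elements = c(name = 0.6,
      version_or_release_date = 0.3, responsible_organisation = 0.4))
  default_flags <- c(respondent_is_owner = 0.4, data_identifier_present = 0.53,
                     metadata_identifier_present = 0.25,
                     consent_publication = 1, consent_repository = 0.63)

  enums <- utils::modifyList(default_enums, enums)
  multis <- utils::modifyList(default_multis, as.list(multis))
  flags_full <- default_flags
  flags_full[names(flags)] <- unlist(flags)

  cfg <- list(n_datasets = as.integer(n_datasets),
              n_respondents = as.integer(n_respondents),
              seed = as.integer(seed),
              species = species,
              contains_personal_data = contains_personal_data,
              metadata_exist = metadata_exist,
              language_status = language_status,
              enums = enums, multis = multis, flags = flags_full,
              governance = governance, missingness = missingness,
              missing_fields = missing_fields,
              round2_new_fraction = round2_new_fraction,
              round2_overlap_fraction = round2_overlap_fraction,
              conflict_rate = conflict_rate, quality = quality)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_datasets < 1 || cfg$n_respondents < 1) {
    stop("configuration error: n_datasets and n_respondents must be >= 1",
         call. = FALSE)
  }
  specs <- c(list(species = cfg$species,
                  contains_personal_data = cfg$contains_personal_data,
                  metadata_exist = cfg$metadata_exist,
                  language_status = cfg$language_status), cfg$enums)
  for (nm in names(specs)) {
    s <- specs[[nm]]
    if (!is.null(s$probs)) {
      check_probs(s$probs, paste0("weights for '", nm, "'"))
      if (abs(sum(s$probs) - 1) > 1e-6) {
        stop("configuration error: weights for '", nm, "' must sum to 1",
             call. = FALSE)
      }
    } else if (is.null(s$counts)) {
      stop("configuration error: spec for '", nm,
           "' needs $probs or $counts", call. = FALSE)
    } else if (any(s$counts < 0)) {
      stop("configuration error: negative quota for '", nm, "'", call. = FALSE)
    }
  }
  for (nm in names(cfg$multis)) check_probs(cfg$multis[[nm]], nm)
  check_probs(cfg$flags, "flag probabilities")
  check_probs(unlist(cfg$governance), "governance probabilities")
  check_probs(c(cfg$missingness, cfg$round2_new_fraction,
                cfg$round2_overlap_fraction, cfg$conflict_rate),
              "rates and fractions")
  check_probs(unlist(cfg$quality), "answer-quality probabilities")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator:", x$n_datasets, "dataset(s),",
      x$n_respondents, "respondent(s), seed", x$seed, "\n")
  mode <- function(s) if (is.null(s$counts)) "weights" else "quota"
  cat("  species:", mode(x$species),
      "| personal data:", mode(x$contains_personal_data),
      "| metadata:", mode(x$metadata_exist), "\n")
  invisible(x)
}

# tristate draw: "yes" with probability p, otherwise split no/unknown
draw_tristate <- function(n, p_yes, p_unknown_given_not = 0.5) {
  yes <- stats::runif(n) < p_yes
  rest <- ifelse(stats::runif(n) < p_unknown_given_not, "unknown", "no")
  ifelse(yes, "yes", rest)
}

#' Generate a synthetic survey cohort
#'
#' Draws `n_datasets` validated dataset-assessment records (plus round-2
#' re-answers for a configured overlap), assigns respondents so that every
#' respondent is used when the cohort is large enough, and generates the
#' per-question answer-quality table. All type invariants hold by
#' construction, and the same configuration and seed always reproduce the
#' identical table.
#'
#' @param config A [generator_config()].
#' @return A [survey_table()].
#' @export
#' @examples
#' tab <- generate_cohort(paper_like_config(seed = 42))
#' nrow(tab$records)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  n <- config$n_datasets
  with_seed(config$seed, {
    dataset_id <- sprintf("ds_src_%04d", seq_len(n))
    respondents <- sprintf("resp_%03d", seq_len(config$n_respondents))
    # surjective assignment when n >= n_respondents, so all respondents appear
    respondent_id <- if (n >= config$n_respondents) {
      c(sample(respondents), sample(respondents, n - config$n_respondents,
                                    replace = TRUE))[seq_len(n)]
    } else {
      sample(respondents, n)
    }

    rec <- data.frame(dataset_id = dataset_id, round = "r1",
                      respondent_id = respondent_id)
    rec$respondent_is_owner <- stats::runif(n) < config$flags[["respondent_is_owner"]]
    rec$species <- draw_enum(n, config$species, "species")
    rec$language_status <- draw_enum(n, config$language_status, "language_status")
    rec$contains_personal_data <- draw_enum(n, config$contains_personal_data,
                                            "contains_personal_data")
    for (nm in c("content_types", "purposes", "quality_practices")) {
      rec[[nm]] <- draw_multi(n, config$multis[[nm]])
    }
    for (nm in c("collection_sources", "collection_mode", "storage_format",
                 "data_vocabulary_practice", "data_access_mode",
                 "data_structure_documented", "rich_metadata_elements",
                 "process_documentation", "licence_status",
                 "consent_consortium")) {
      rec[[nm]] <- draw_enum(n, config$enums[[nm]], nm)
    }

    gov <- config$governance
    rec$data_subject_identified <- draw_tristate(n, gov$p_subject_identified)
    rec$data_controller_identified <- draw_tristate(n, gov$p_controller_identified)
    documented_given <- function(identified) {
      ifelse(identified == "yes" &
               stats::runif(n) < gov$p_documented_given_identified,
             "yes", ifelse(stats::runif(n) < 0.5, "no", "unknown"))
    }
    rec$data_subject_documented <- documented_given(rec$data_subject_identified)
    rec$data_controller_documented <- documented_given(rec$data_controller_identified)
    rec$data_owner_identified <- draw_tristate(n, gov$p_owner_identified)

    rec$data_identifier_present <- stats::runif(n) <
      config$flags[["data_identifier_present"]]
    rec$data_identifying_elements <- draw_multi(
      n, config$multis$data_identifying_elements)

    # metadata block: dependent fields drawn only where metadata exist
    rec$metadata_exist <- draw_enum(n, config$metadata_exist, "metadata_exist")
    meta_yes <- rec$metadata_exist == "yes"
    rec$metadata_identifier_present <- meta_yes & stats::runif(n) <
      config$flags[["metadata_identifier_present"]]
    rec$metadata_identifying_elements <- ifelse(meta_yes,
      draw_multi(n, config$multis$metadata_identifying_elements), "")
    for (nm in c("metadata_link_update", "metadata_structure",
                 "metadata_vocabulary", "metadata_access_mode")) {
      rec[[nm]] <- draw_enum(n, config$enums[[nm]], nm)
    }
    rec$metadata_link_update[!meta_yes] <- "none_or_unknown"
    rec$metadata_structure[!meta_yes] <- "undocumented"
    rec$metadata_vocabulary[!meta_yes] <- "unknown"
    rec$metadata_access_mode[!meta_yes] <- "none"

    rec$consent_publication <- stats::runif(n) <
      config$flags[["consent_publication"]]
    rec$consent_repository <- stats::runif(n) <
      config$flags[["consent_repository"]]

    if (config$missingness > 0) {
      for (nm in config$missing_fields) {
        drop <- stats::runif(n) < config$missingness
        rec[[nm]][drop] <- NA
      }
    }

    # split into rounds: a fraction of datasets first appear in round 2,
    # and a fraction of round-1 datasets are re-answered in round 2
    n_new2 <- round(n * config$round2_new_fraction)
    if (n_new2 > 0) {
      new2 <- sample(seq_len(n), n_new2)
      rec$round[new2] <- "r2"
    }
    r1_idx <- which(rec$round == "r1")
    n_overlap <- round(length(r1_idx) * config$round2_overlap_fraction)
    overlap_rows <- NULL
    if (n_overlap > 0 && config$n_respondents > 1) {
      ov <- sample(r1_idx, n_overlap)
      overlap_rows <- rec[ov, , drop = FALSE]
      overlap_rows$round <- "r2"
      overlap_rows$respondent_id <- vapply(overlap_rows$respondent_id,
        function(r) sample(setdiff(respondents, r), 1), character(1))
      conflictable <- c("collection_mode", "storage_format",
                        "collection_sources", "process_documentation",
                        "licence_status", "data_structure_documented")
      for (nm in conflictable) {
        flip <- stats::runif(n_overlap) < config$conflict_rate
        if (any(flip)) {
          spec <- config$enums[[nm]]
          lv <- if (is.null(spec$counts)) names(spec$probs) else names(spec$counts)
          overlap_rows[[nm]][flip] <- vapply(overlap_rows[[nm]][flip],
            function(v) sample(setdiff(lv, v), 1), character(1))
        }
      }
    }
    records <- rbind(rec, overlap_rows)

    # answer-quality table: one row per respondent x open question
    qs <- survey_questions()
    aqs <- lapply(seq_len(nrow(qs)), function(i) {
      pq <- config$quality[[qs$category[i]]]
      comp <- as.integer(stats::runif(config$n_respondents) < pq[["completeness"]])
      coh <- comp * as.integer(stats::runif(config$n_respondents) < pq[["coherence"]])
      data.frame(question_id = qs$question_id[i], respondent_id = respondents,
                 completeness = comp, coherence = coh)
    })
    aq <- do.call(rbind, aqs)
    survey_table(records,
                 answer_qualities = answer_quality(aq$question_id,
                   aq$respondent_id, aq$completeness, aq$coherence))
  })
}

#' Study-sized generator configuration
#'
#' A [generator_config()] whose quotas and weights reproduce the marginal
#' counts of a 30-dataset, 19-respondent European livestock survey cohort:
#' species quotas of 10 swine, 9 salmonids, 9 cattle and 4 poultry including
#' 2 swine-and-cattle datasets, exactly 11 datasets with personal data, 16
#' with identified metadata, and 20 not available in English (plus one
#' translated). Remaining field weights follow the corresponding observed
#' cohort proportions.
#'
#' @param seed Integer seed passed through to the config.
#' @return A `generator_config` in quota mode for the headline fields.
#' @export
paper_like_config <- function(seed = 1) {
  generator_config(
    n_datasets = 30, n_respondents = 19, seed = seed,
    species = list(counts = c(swine = 8, cattle = 7, salmonids = 9,
                              poultry = 4, "swine;cattle" = 2)),
    contains_personal_data = list(counts = c(yes = 11, no = 19)),
    metadata_exist = list(counts = c(yes = 16, no = 14)),
    language_status = list(counts = c(english = 9, not_english = 20,
                                      translated = 1)),
    enums = list(
      collection_sources = list(counts = c(single_source = 11,
        multiple_same_type = 12, multiple_different_type = 6, unreported = 1)),
      collection_mode = list(counts = c(automated = 18, manual = 6,
                                        unreported = 6)),
      storage_format = list(counts = c(relational_database = 14,
        spreadsheet_collection = 8, single_spreadsheet = 7, pdf_collection = 1)),
      data_vocabulary_practice = list(counts = c(standard = 2,
        retrievable_glossary = 8, collaborative = 4, owner_defined = 12,
        unknown = 4)),
      data_access_mode = list(counts = c(documented_protocol = 15, url = 7,
                                         none = 8)),
      data_structure_documented = list(counts = c(yes = 25, no = 3,
                                                  unknown = 2)),
      rich_metadata_elements = list(counts = c(all_available = 18,
        one_missing = 6, more_missing = 6)),
      process_documentation = list(counts = c(full = 10, partial = 5,
                                              none = 15)),
      licence_status = list(counts = c(data_and_metadata = 1, data_only = 2,
                                       none = 27)),
      consent_consortium = list(counts = c(yes = 22, conditional = 8, no = 0)),
      metadata_link_update = list(probs = c(automatic = 1 / 16,
        manual = 1 / 16, none_or_unknown = 14 / 16)),
      metadata_structure = list(probs = c(standard_schema = 1 / 16,
        documented = 0, undocumented = 15 / 16)),
      metadata_vocabulary = list(probs = c(standard = 1 / 16,
        retrievable_glossary = 0, collaborative = 0, owner_defined = 7 / 16,
        unknown = 8 / 16)),
      metadata_access_mode = list(probs = c(documented_protocol = 5 / 16,
        url = 3 / 16, none = 8 / 16))),
    multis = list(
      content_types = c(laboratory_results = 16 / 30, biosecurity = 15 / 30,
        production_results = 14 / 30, treatment = 13 / 30,
        clinical_observation = 13 / 30, animal_movements = 6 / 30,
        economic = 5 / 30, behaviour = 4 / 30),
      purposes = c(production_information = 17 / 30, surveillance = 16 / 30,
        legislation = 11 / 30, lab_activities = 8 / 30,
        other_business = 4 / 30, research_integration = 3 / 30),
      quality_practices = c(closed_formats = 14 / 30,
        collector_training = 5 / 30, manual_checks = 5 / 30,
        automated_checks = 14 / 30, inspection_verification = 4 / 30,
        feedback_loops = 17 / 30, standards_procedures = 18 / 30)),
    flags = c(data_identifier_present = 16 / 30,
              metadata_identifier_present = 4 / 16,
              consent_publication = 1, consent_repository = 19 / 30,
              respondent_is_owner = 0.4),
    governance = list(p_subject_identified = 8 / 11,
                      p_controller_identified = 8 / 11,
                      p_documented_given_identified = 5 / 8,
                      p_owner_identified = 0.8),
    missingness = 0,
    round2_new_fraction = 0.2, round2_overlap_fraction = 0.2,
    conflict_rate = 0.1)
}
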
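# Answer-quality scoring: completeness and coherence per answer, aggregated
# into a per-question global quality grade with a strict 75% threshold.

#' Construct per-answer quality scores
#'
#' Each open-question answer is scored on two binary criteria: completeness
#' (was an answer given) and coherence (was the answer consistent with the
#' question scope and the other information available). An absent answer
#' cannot be coherent, so `completeness = 0` forces `coherence = 0`.
#'
#' @param question_id,respondent_id Identifier vectors.
#' @param completeness,coherence Integer scores, each 0 or 1.
#' @return A data frame of class `answer_quality`.
#' @export
answer_quality <- function(question_id, respondent_id, completeness, coherence) {
  completeness <- as.integer(completeness)
  coherence <- as.integer(coherence)
  if (!all(completeness %in% c(0L, 1L)) || !all(coherence %in% c(0L, 1L))) {
    stop("completeness and coherence must be 0 or 1", call. = FALSE)
  }
  bad <- completeness == 0L & coherence == 1L
  if (any(bad)) {
    stop("an absent answer cannot be coherent (completeness=0 forces coherence=0); ",
         "offending question(s): ",
         paste(unique(question_id[bad]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(question_id = as.character(question_id),
                    respondent_id = as.character(respondent_id),
                    completeness = completeness, coherence = coherence)
  class(out) <- c("answer_quality", "data.frame")
  out
}

#' Global quality grade for one question
#'
#' The grade is the sum of the completeness and coherence scores actually
#' obtained across all respondents, divided by the maximum attainable
#' (2 points per respondent). A grade is flagged low when strictly below 0.75.
#'
#' @param qualities Answer-quality rows for a single question.
#' @return A one-row data frame: `question_id`, `obtained`, `maximum`,
#'   `grade`, `is_low`.
#' @export
#' @examples
#' aq <- answer_quality("q1", paste0("r", 1:4), c(1, 1, 1, 0), c(1, 1, 0, 0))
#' grade_question(aq)  # 5/8 = 0.625, low
grade_question <- function(qualities) {
  if (is.null(qualities) || nrow(qualities) == 0) {
    stop("cannot grade a question with no answers", call. = FALSE)
  }
  qid <- unique(qualities$question_id)
  if (length(qid) != 1) {
    stop("key error: answers span several questions: ",
         paste(qid, collapse = ", "), call. = FALSE)
  }
  obtained <- sum(qualities$completeness) + sum(qualities$coherence)
  maximum <- 2L * nrow(qualities)
  grade <- obtained / maximum
  data.frame(question_id = qid, obtained = obtained, maximum = maximum,
             grade = grade, is_low = grade < 0.75)
}

#' Grade every question in an answer-quality table
#'
#' @param qualities An `answer_quality` data frame covering any number of
#'   questions.
#' @return One row per question, as in [grade_question()].
#' @export
grade_questions <- function(qualities) {
  if (nrow(qualities) == 0) {
    return(data.frame(question_id = character(0), obtained = integer(0),
                      maximum = integer(0), grade = numeric(0),
                      is_low = logical(0)))
  }
  parts <- lapply(split(qualities, qualities$question_id), grade_question)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Partition question grades at the 75% threshold
#'
#' The threshold is strict: a grade of exactly 0.75 is acceptable.
#'
#' @param grades Data frame of question grades (from [grade_questions()]).
#' @return A list with character vectors `low` and `acceptable` of question ids.
#' @export
classify_low <- function(grades) {
  if (is.null(grades) || nrow(grades) == 0) {
    return(list(low = character(0), acceptable = character(0)))
  }
  low <- grades$grade < 0.75
  list(low = grades$question_id[low], acceptable = grades$question_id[!low])
}

#' Survey question catalogue
#'
#' The open questions whose answers are quality-graded, grouped into the five
#' survey categories used for reporting: governance, management, data model,
#' description and metadata.
#'
#' @return Data frame with columns `question_id`, `category`.
#' @export
survey_questions <- function() {
  cat_q <- list(
    "A. Governance" = c("A1_data_owner", "A2_data_controller",
                        "A3_data_subject", "A4_role_documentation"),
    "B. Management" = c("B1_collection_mode", "B2_collection_sources",
                        "B3_access_ways", "B4_quality_processes", "B5_licence"),
    "C. Data model" = c("C1_storage_format", "C2_structure_documentation",
                        "C3_vocabulary", "C4_modifications"),
    "D. Description" = c("D1_species", "D2_content", "D3_purpose",
                         "D4_language", "D5_geography", "D6_time_period",
                         "D7_recording_frequency"),
    "E. Metadata" = c("E1_metadata_exist", "E2_metadata_structure",
                      "E3_metadata_vocabulary", "E4_metadata_access",
                      "E5_metadata_update"))
  data.frame(question_id = unlist(cat_q, use.names = FALSE),
             category = rep(names(cat_q), lengths(cat_q)))
}

#' Per-question answer-quality profile
#'
#' One row per question, ordered by survey category: the global quality grade,
#' the low-quality flag, and the proportion of answers obtaining the full
#' score of 2 (complete and coherent).
#'
#' @param table A `survey_table` with answer qualities present.
#' @param questions Question catalogue; defaults to [survey_questions()]
#'   restricted to the questions present. Catalogue questions with no answers
#'   are omitted with a warning.
#' @return Data frame: `category`, `question_id`, `obtained`, `maximum`,
#'   `grade`, `is_low`, `prop_score2`.
#' @export
quality_profile <- function(table, questions = NULL) {
  aq <- if (inherits(table, "survey_table")) table$answer_qualities else table
  if (is.null(aq) || nrow(aq) == 0) {
    stop("no answer qualities present in the table", call. = FALSE)
  }
  if (is.null(questions)) {
    questions <- survey_questions()
    questions <- questions[questions$question_id %in% aq$question_id, ]
    extra <- setdiff(unique(aq$question_id), questions$question_id)
    if (length(extra) > 0) {
      questions <- rbind(questions,
                         data.frame(question_id = extra, category = "Z. Other"))
    }
  }
  absent <- setdiff(questions$question_id, aq$question_id)
  if (length(absent) > 0) {
    warning("no answers for question(s), omitted: ",
            paste(absent, collapse = ", "), call. = FALSE)
    questions <- questions[!questions$question_id %in% absent, ]
  }
  grades <- grade_questions(aq[aq$question_id %in% questions$question_id, ])
  score2 <- vapply(split(aq, aq$question_id), function(g)
    mean(g$completeness + g$coherence == 2L), numeric(1))
  out <- merge(questions, grades, by = "question_id", sort = FALSE)
  out$prop_score2 <- as.numeric(score2[out$question_id])
  out <- out[order(out$category, out$question_id), ]
  rownames(out) <- NULL
  out[, c("category", "question_id", "obtained", "maximum", "grade",
          "is_low", "prop_score2")]
}
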
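# GDPR accountability rubric.
#
# Only datasets containing personal data fall under the GDPR, so scoring is
# restricted to those. Accountability is assessed on two binary criteria:
# are the two data governance roles the regulation requires (data subject and
# data controller) identified, and are those roles formally documented. An
# "unknown" survey answer never satisfies a criterion.

tri_yes <- function(x) !is.na(x) & norm_token(x) == "yes"

#' Is a record subject to GDPR assessment?
#'
#' @param records Record data frame or `survey_table`.
#' @param quiet Suppress the caveat message for unknown personal-data status.
#' @return Logical vector: `TRUE` iff `contains_personal_data` is `yes`.
#'   Records with unknown status are treated as not applicable, with a caveat
#'   message (conservative reading: applicability cannot be established).
#' @export
gdpr_applicable <- function(records, quiet = FALSE) {
  if (inherits(records, "survey_table")) records <- records$records
  pd <- norm_token(records$contains_personal_data)
  unk <- is.na(pd) | pd == "unknown"
  if (any(unk) && !quiet) {
    message("caveat: personal-data status unknown for dataset(s) ",
            paste(unique(records$dataset_id[unk]), collapse = ", "),
            "; treated as not applicable for GDPR assessment")
  }
  !is.na(pd) & pd == "yes"
}

#' Score GDPR accountability for applicable records
#'
#' `identified_roles` is 1 iff both the data subject and the data controller
#' are identified; `documented_roles` is 1 iff both roles are formally
#' documented. Totals range over 0-2.
#'
#' @param records Record data frame or `survey_table`; every record must be
#'   GDPR-applicable (contain personal data).
#' @return Data frame of class `gdpr_score`: `dataset_id`, `applicable`,
#'   `identified_roles`, `documented_roles`, `total`.
#' @export
#' @examples
#' r <- data.frame(dataset_id = "d1", contains_personal_data = "yes",
#'                 data_subject_identified = "yes", data_subject_documented = "no",
#'                 data_controller_identified = "yes",
#'                 data_controller_documented = "no")
#' score_gdpr(r)  # identified 1, documented 0, total 1
score_gdpr <- function(records) {
  if (inherits(records, "survey_table")) records <- records$records
  ok <- gdpr_applicable(records, quiet = TRUE)
  if (!all(ok)) {
    stop("applicability error: GDPR scoring requested for dataset(s) without ",
         "personal data: ",
         paste(unique(records$dataset_id[!ok]), collapse = ", "), call. = FALSE)
  }
  identified <- as.integer(tri_yes(records$data_subject_identified) &
                             tri_yes(records$data_controller_identified))
  documented <- as.integer(tri_yes(records$data_subject_documented) &
                             tri_yes(records$data_controller_documented))
  out <- data.frame(dataset_id = records$dataset_id, applicable = TRUE,
                    identified_roles = identified,
                    documented_roles = documented,
                    total = identified + documented)
  class(out) <- c("gdpr_score", "data.frame")
  out
}

#' GDPR scores for a whole cohort
#'
#' Applies [score_gdpr()] to the applicable records and carries
#' non-applicable datasets through with `NA` scores.
#'
#' @param records Record data frame or `survey_table` (one row per dataset).
#' @return One `gdpr_score` row per dataset.
#' @export
score_gdpr_cohort <- function(records) {
  if (inherits(records, "survey_table")) records <- records$records
  ok <- gdpr_applicable(records)
  out <- data.frame(dataset_id = records$dataset_id, applicable = ok,
                    identified_roles = rep(NA_integer_, nrow(records)),
                    documented_roles = rep(NA_integer_, nrow(records)),
                    total = rep(NA_integer_, nrow(records)))
  if (any(ok)) {
    sc <- score_gdpr(records[ok, , drop = FALSE])
    out[ok, c("identified_roles", "documented_roles", "total")] <-
      sc[, c("identified_roles", "documented_roles", "total")]
  }
  class(out) <- c("gdpr_score", "data.frame")
  out
}

#' Mean GDPR accountability score by respondent role
#'
#' Datasets described by their owner are compared with datasets described by
#' a data user (typically a researcher reusing the data).
#'
#' @param scores `gdpr_score` rows for applicable datasets.
#' @param owner_flags Named logical vector mapping `dataset_id` to whether the
#'   respondent was the data owner.
#' @return Named numeric vector `c(owner_mean=, user_mean=)`; `NA` for an
#'   empty group.
#' @export
mean_score_by_role <- function(scores, owner_flags) {
  scores <- scores[!is.na(scores$total), , drop = FALSE]
  missing_flag <- setdiff(scores$dataset_id, names(owner_flags))
  if (length(missing_flag) > 0) {
    stop("no owner/user flag for scored dataset(s): ",
         paste(missing_flag, collapse = ", "), call. = FALSE)
  }
  is_owner <- as.logical(owner_flags[scores$dataset_id])
  grp_mean <- function(keep) {
    v <- scores$total[keep %in% TRUE]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  c(owner_mean = grp_mean(is_owner), user_mean = grp_mean(!is_owner))
}
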
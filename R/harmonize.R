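# Round merging, conflict resolution, and anonymisation.

# Evaluate code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded random identifier map
#'
#' Assigns each original dataset and respondent key a random integer ID drawn
#' as a seeded permutation of `1..N` per entity class, so IDs are random but
#' collision-free, and the same seed reproduces the same mapping.
#'
#' @param dataset_keys,respondent_keys Character vectors of original keys.
#' @param seed Integer seed.
#' @return Object of class `id_map`: named integer vectors `datasets` and
#'   `respondents`, plus the `seed`.
#' @export
make_id_map <- function(dataset_keys, respondent_keys, seed) {
  dataset_keys <- sort(unique(as.character(dataset_keys)))
  respondent_keys <- sort(unique(as.character(respondent_keys)))
  with_seed(seed, {
    ds <- sample.int(length(dataset_keys))
    rs <- sample.int(length(respondent_keys))
    structure(list(datasets = stats::setNames(ds, dataset_keys),
                   respondents = stats::setNames(rs, respondent_keys),
                   seed = as.integer(seed)),
              class = "id_map")
  })
}

#' @export
print.id_map <- function(x, ...) {
  cat("Random ID map (seed ", x$seed, "): ", length(x$datasets),
      " dataset(s), ", length(x$respondents), " respondent(s)\n", sep = "")
  invisible(x)
}

# summed coherence per respondent, used to resolve merge conflicts
coherence_sums <- function(answer_qualities) {
  if (is.null(answer_qualities) || nrow(answer_qualities) == 0)
    return(stats::setNames(numeric(0), character(0)))
  tapply(answer_qualities$coherence, answer_qualities$respondent_id, sum)
}

#' Merge two survey rounds
#'
#' Datasets answered in a single round pass through unchanged. When a dataset
#' was answered in both rounds, the two answers are aggregated field by field:
#' the answer of the respondent with the higher summed coherence score is
#' kept, with ties going to the second (validation) round; missing values in
#' the kept answer are filled from the other. Every resolution is recorded in
#' the provenance log.
#'
#' @param round1,round2 `survey_table` objects holding the first- and
#'   second-round records. Answer qualities from both are pooled for conflict
#'   resolution.
#' @return A merged `survey_table`, one record per dataset.
#' @export
merge_rounds <- function(round1, round2) {
  stopifnot(inherits(round1, "survey_table"), inherits(round2, "survey_table"))
  r1 <- round1$records
  r2 <- round2$records
  for (rr in list(r1, r2)) {
    dup <- duplicated(rr$dataset_id)
    if (any(dup)) {
      stop("integrity error: contradictory rows for dataset(s) within one ",
           "round: ", paste(unique(rr$dataset_id[dup]), collapse = ", "),
           call. = FALSE)
    }
  }
  aq <- unique(rbind(round1$answer_qualities, round2$answer_qualities))
  coh <- coherence_sums(aq)
  log <- rbind(round1$provenance_log, round2$provenance_log)
  fields <- setdiff(names(survey_dictionary()),
                    c("dataset_id", "round", "respondent_id"))

  both <- intersect(r1$dataset_id, r2$dataset_id)
  merged <- list()
  for (ds in union(r1$dataset_id, r2$dataset_id)) {
    if (!ds %in% both) {
      src <- if (ds %in% r1$dataset_id) r1 else r2
      merged[[ds]] <- src[src$dataset_id == ds, , drop = FALSE]
      next
    }
    a <- r1[r1$dataset_id == ds, , drop = FALSE]
    b <- r2[r2$dataset_id == ds, , drop = FALSE]
    coh_a <- if (a$respondent_id %in% names(coh)) coh[[a$respondent_id]] else 0
    coh_b <- if (b$respondent_id %in% names(coh)) coh[[b$respondent_id]] else 0
    tie <- coh_a == coh_b
    winner <- if (coh_a > coh_b) a else b
    loser <- if (coh_a > coh_b) b else a
    reason <- if (tie) "conflict: equal coherence, round-2 answer kept"
              else "conflict: most coherent response kept"
    for (f in fields) {
      wv <- winner[[f]]
      lv <- loser[[f]]
      if (is.na(wv) && !is.na(lv)) {
        winner[[f]] <- lv
        log <- add_provenance(log, ds, f, wv, lv,
                              "aggregation: missing value filled from other round")
      } else if (!is.na(wv) && !is.na(lv) && !identical(wv, lv)) {
        log <- add_provenance(log, ds, f, lv, wv, reason)
      }
    }
    merged[[ds]] <- winner
  }
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  survey_table(out, answer_qualities = aq, provenance_log = log)
}

#' Reclassify a raw identifying answer into an analysis category
#'
#' Free-text survey answers that could identify a dataset or person are
#' reduced to the categorical information relevant to the analysis: for
#' example the language a dataset is available in becomes `english` /
#' `not_english`, and a data-owner name becomes the fact that an owner is
#' identified. The mapping is deterministic; raw values no rule can place are
#' mapped to `unknown` with a warning.
#'
#' @param field_name Column key; must have a rule in `rules`.
#' @param raw_value Single raw answer (character).
#' @param rules Named list of rule functions, see
#'   [default_reclassification_rules()].
#' @return The reclassified categorical value (character scalar).
#' @export
#' @examples
#' reclassify_field("language", "English")  # "english"
#' reclassify_field("language", "Swedish")  # "not_english"
reclassify_field <- function(field_name, raw_value,
                             rules = default_reclassification_rules()) {
  if (!field_name %in% names(rules)) {
    stop("configuration error: no reclassification rule for field '",
         field_name, "'", call. = FALSE)
  }
  rules[[field_name]](as.character(raw_value))
}

#' Default reclassification rule table
#'
#' @return Named list of functions mapping one raw value to a category:
#'   `language` (to `english` / `not_english` / `translated`) and
#'   `data_owner_name` (to the tristate "there is an identified data owner").
#' @export
default_reclassification_rules <- function() {
  list(
    language = function(raw) {
      tok <- norm_token(raw)
      if (length(tok) == 0 || is.na(tok)) {
        warning("empty language value mapped to unknown", call. = FALSE)
        return("unknown")
      }
      if (tok == "english") return("english")
      if (tok == "translated") return("translated")
      "not_english"
    },
    data_owner_name = function(raw) {
      tok <- norm_token(raw)
      if (length(tok) == 0 || is.na(tok)) {
        warning("empty data-owner value mapped to unknown", call. = FALSE)
        return("unknown")
      }
      "yes"  # there is an identified data owner
    })
}

#' Scan a survey table for identifier strings
#'
#' Deny-list check used after anonymisation: looks for exact (trimmed,
#' case-insensitive) occurrences of the given strings in any cell of the
#' records, answer qualities or provenance log.
#'
#' @param table A `survey_table`.
#' @param denylist Character vector of forbidden strings (original IDs,
#'   names, ...).
#' @return Data frame of hits with columns `where`, `field`, `value`;
#'   zero rows when the table is clean.
#' @export
scan_identifiers <- function(table, denylist) {
  stopifnot(inherits(table, "survey_table"))
  deny <- norm_token(denylist)
  hits <- list()
  scan_df <- function(df, where) {
    for (f in names(df)) {
      vals <- norm_token(df[[f]])
      bad <- !is.na(vals) & vals %in% deny
      if (any(bad)) {
        hits[[length(hits) + 1]] <<- data.frame(
          where = where, field = f, value = unique(df[[f]][bad]))
      }
    }
  }
  scan_df(table$records, "records")
  scan_df(table$answer_qualities, "answer_qualities")
  scan_df(table$provenance_log, "provenance_log")
  if (length(hits) == 0) {
    return(data.frame(where = character(0), field = character(0),
                      value = character(0)))
  }
  do.call(rbind, hits)
}

#' Anonymise a survey table
#'
#' Two-step anonymisation: every dataset and respondent key is replaced by a
#' random integer ID from a seeded [make_id_map()], and any identifying
#' free-text columns are dropped (columns outside the dictionary) — raw-value
#' reclassification having already happened at read time. The output is
#' verified with a deny-list scan for the original identifiers.
#'
#' @param table A `survey_table`.
#' @param seed Integer seed; the same table and seed give identical output.
#' @return A list with elements `table` (anonymised `survey_table`) and
#'   `id_map` (the [make_id_map()] used; keep it confidential).
#' @export
anonymize <- function(table, seed) {
  stopifnot(inherits(table, "survey_table"))
  recs <- table$records
  aq <- table$answer_qualities
  log <- table$provenance_log
  respondent_keys <- unique(c(recs$respondent_id, aq$respondent_id))
  map <- make_id_map(recs$dataset_id, respondent_keys, seed)
  orig_ds <- names(map$datasets)
  orig_rs <- names(map$respondents)

  recs$dataset_id <- as.character(map$datasets[recs$dataset_id])
  recs$respondent_id <- as.character(map$respondents[recs$respondent_id])
  if (nrow(aq) > 0) {
    aq$respondent_id <- as.character(map$respondents[aq$respondent_id])
  }
  if (nrow(log) > 0) {
    known <- log$key %in% orig_ds
    log$key[known] <- as.character(map$datasets[log$key[known]])
    # free-text originals recorded before reclassification must not survive
    log$old[log$reason == "reclassified"] <- "<redacted>"
  }
  out <- survey_table(recs, answer_qualities = aq, provenance_log = log)
  hits <- scan_identifiers(out, denylist = c(orig_ds, orig_rs))
  if (nrow(hits) > 0) {
    stop("anonymisation failed: original identifier(s) remain in ",
         paste(unique(hits$where), collapse = ", "), call. = FALSE)
  }
  list(table = out, id_map = map)
}
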
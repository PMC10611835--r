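# Credentialing review records and compliance arithmetic.
#
# Review records are data, not judgements: verdicts and violation flags
# come from expert reviewers; this module only tabulates them.

.violation_categories <- c("btv_under_contour", "btv_over_contour",
                           "background_placement", "tac_classification",
                           "interpretation_discordant")
.timepoints <- c("FET1", "FET3")
.rounds <- c("initial", "resubmission_1", "resubmission_2")
.verdicts <- c("acceptable", "minor", "major")

#' Round half-up
#'
#' Decimal rounding with ties going away from zero, matching the
#' convention of printed clinical-report percentages (`round()` in R
#' rounds ties to even).
#'
#' @param x numeric.
#' @param digits number of decimals.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read and validate credentialing review records
#'
#' The CSV schema has one row per review: `reader_id`, `case_id`,
#' `timepoint` (`FET1`/`FET3`), `round` (`initial`, `resubmission_1`,
#' `resubmission_2`), `verdict` (`acceptable`, `minor`, `major`),
#' `violations` (semicolon-joined subset of `btv_under_contour`,
#' `btv_over_contour`, `background_placement`, `tac_classification`,
#' `interpretation_discordant`; empty for none) and
#' `resubmission_requested` (logical).  A `major` verdict must carry
#' `resubmission_requested = TRUE`; a `minor` verdict may pass with
#' noted violations.
#'
#' @param path CSV file path.
#' @return A validated data.frame of class `review_records`.
#' @export
read_reviews <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$resubmission_requested <-
    toupper(trimws(df$resubmission_requested)) %in% c("TRUE", "1", "YES")
  as_review_records(df)
}

#' @rdname read_reviews
#' @param records a data.frame with the schema above.
#' @export
as_review_records <- function(records) {
  req <- c("reader_id", "case_id", "timepoint", "round", "verdict",
           "violations", "resubmission_requested")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L) stop("empty record set")
  chk <- function(col, allowed) {
    bad <- which(!(records[[col]] %in% allowed))
    if (length(bad))
      stop("record ", bad[1], ": invalid ", col, " '",
           records[[col]][bad[1]], "'")
  }
  chk("timepoint", .timepoints)
  chk("round", .rounds)
  chk("verdict", .verdicts)
  for (i in seq_len(nrow(records))) {
    v <- violation_list(records$violations[i])
    bad <- setdiff(v, .violation_categories)
    if (length(bad))
      stop("record ", i, " (reader ", records$reader_id[i], ", case ",
           records$case_id[i], "): unknown violation category '",
           bad[1], "'")
    if (records$verdict[i] != "acceptable" && length(v) == 0L)
      stop("record ", i, ": verdict '", records$verdict[i],
           "' without any violation category")
  }
  if (any(records$verdict == "major" & !records$resubmission_requested))
    stop("a 'major' verdict requires resubmission_requested = TRUE")
  class(records) <- c("review_records", "data.frame")
  records
}

violation_list <- function(s) {
  s <- trimws(strsplit(as.character(s), ";", fixed = TRUE)[[1]])
  s[nzchar(s)]
}

#' Write review records to CSV
#'
#' @param records a `review_records` data.frame.
#' @param path output CSV path.
#' @export
write_reviews <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Pass rate of a review round
#'
#' A submission passes when the reviewers did not request a
#' resubmission.  The percentage is rounded half-up to one decimal,
#' matching printed reporting; the counts are exact.
#'
#' @param records a `review_records` data.frame.
#' @param round `"initial"` (default), `"resubmission_1"` or
#'   `"resubmission_2"`.
#' @return A list `numerator`, `denominator`, `percent`.
#' @export
pass_rate <- function(records, round = "initial") {
  records <- as_review_records(as.data.frame(records))
  round <- match.arg(round, .rounds)
  sub <- records[records$round == round, ]
  if (nrow(sub) == 0L) stop("no records in round '", round, "'")
  num <- sum(!sub$resubmission_requested)
  list(numerator = num, denominator = nrow(sub),
       percent = round_half_up(100 * num / nrow(sub), 1))
}

#' Compliance summary of a credentialing record set
#'
#' Tabulates violation rates by timepoint (records with a non-acceptable
#' verdict over all records of that timepoint), severity counts, and
#' violation-category frequencies, both over all violating records and
#' among the records that triggered a resubmission request.  Categories
#' are not mutually exclusive, so frequencies may sum to more than
#' 100%.
#'
#' @param records a `review_records` data.frame.
#' @return An object of class `fet_compliance`.
#' @export
violation_summary <- function(records) {
  records <- as_review_records(as.data.frame(records))
  by_tp <- lapply(.timepoints, function(tp) {
    sub <- records[records$timepoint == tp, ]
    if (nrow(sub) == 0L)
      return(list(n_violations = 0L, n = 0L, percent = NA_real_,
                  minor = 0L, major = 0L))
    viol <- sub$verdict != "acceptable"
    list(n_violations = sum(viol), n = nrow(sub),
         percent = round_half_up(100 * sum(viol) / nrow(sub), 1),
         minor = sum(sub$verdict == "minor"),
         major = sum(sub$verdict == "major"))
  })
  names(by_tp) <- .timepoints
  viol_records <- records[records$verdict != "acceptable", ]
  overall <- category_frequencies(viol_records, nrow(viol_records))
  resub <- resubmission_reasons(records)
  structure(list(pass_rate = pass_rate(records, "initial"),
                 violation_rate_by_timepoint = by_tp,
                 severity_counts = lapply(by_tp, function(x)
                   c(minor = x$minor, major = x$major)),
                 reason_frequencies = overall,
                 resubmission_reasons = resub),
            class = "fet_compliance")
}

category_frequencies <- function(records, denominator) {
  counts <- vapply(.violation_categories, function(cat) {
    sum(vapply(records$violations,
               function(s) cat %in% violation_list(s), logical(1)))
  }, integer(1))
  data.frame(category = .violation_categories, count = counts,
             denominator = denominator,
             percent = if (denominator > 0)
               round_half_up(100 * counts / denominator, 1)
             else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Violation-category frequencies among resubmission-triggering reviews
#'
#' @param records a `review_records` data.frame.
#' @return A data.frame `category`, `count`, `denominator` (number of
#'   reviews that requested a resubmission), `percent` (half-up, one
#'   decimal).
#' @export
resubmission_reasons <- function(records) {
  records <- as_review_records(as.data.frame(records))
  sub <- records[records$resubmission_requested, ]
  category_frequencies(sub, nrow(sub))
}

#' @export
print.fet_compliance <- function(x, ...) {
  pr <- x$pass_rate
  cat(sprintf("Initial pass rate: %d/%d (%.1f%%)\n", pr$numerator,
              pr$denominator, pr$percent))
  for (tp in names(x$violation_rate_by_timepoint)) {
    v <- x$violation_rate_by_timepoint[[tp]]
    if (v$n > 0)
      cat(sprintf("  %s violations: %d/%d (%.1f%%; %d minor / %d major)\n",
                  tp, v$n_violations, v$n, v$percent, v$minor, v$major))
  }
  rr <- x$resubmission_reasons
  rr <- rr[rr$count > 0, ]
  if (nrow(rr)) {
    cat(sprintf("Resubmission reasons (of %d requests):\n",
                rr$denominator[1]))
    for (i in seq_len(nrow(rr)))
      cat(sprintf("  %s: %d/%d (%.1f%%)\n", rr$category[i], rr$count[i],
                  rr$denominator[i], rr$percent[i]))
  }
  invisible(x)
}

#' Synthetic credentialing review cohort
#'
#' Builds a deterministic, fully synthetic set of credentialing review
#' records emulating a multi-centre programme: 20 reviewed readers, six
#' benchmark cases split between a delineation timepoint (FET1) and an
#' interpretation timepoint (FET3), 119 initial submissions (one
#' submission excluded), requested resubmissions with recorded reasons,
#' and a small number of incomplete resubmissions.  The marginal counts
#' (initial pass rate, violation rates and severities by timepoint,
#' resubmission-reason frequencies) follow the published frequencies of
#' a multi-centre FET PET credentialing programme, so compliance
#' arithmetic can be exercised end to end on realistic totals.
#'
#' @return A `review_records` data.frame with 146 rows.
#' @export
synthetic_review_cohort <- function() {
  readers <- sprintf("R%02d", 1:20)
  grid1 <- expand.grid(reader_id = readers,
                       case_id = c("FET1CASE1", "FET1CASE2", "FET1CASE3"),
                       stringsAsFactors = FALSE)
  grid1 <- grid1[order(grid1$reader_id, grid1$case_id), ]
  grid1 <- grid1[-nrow(grid1), ]          # one submission excluded
  grid3 <- expand.grid(reader_id = readers,
                       case_id = c("FET3CASE1", "FET3CASE2", "FET3CASE3"),
                       stringsAsFactors = FALSE)
  grid3 <- grid3[order(grid3$reader_id, grid3$case_id), ]

  rec <- function(reader, case, tp, round, verdict, violations, resub) {
    data.frame(reader_id = reader, case_id = case, timepoint = tp,
               round = round, verdict = verdict,
               violations = violations,
               resubmission_requested = resub,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  add <- function(x) rows[[length(rows) + 1L]] <<- x

  # ---- FET1: 59 initial = 10 major (flagged) + 2 minor flagged +
  #      11 minor unflagged + 36 acceptable
  f1 <- grid1
  f1_flag_major <- 1:10
  f1_flag_minor <- 11:12
  f1_minor <- 13:23
  for (i in seq_len(nrow(f1))) {
    if (i %in% f1_flag_major)
      add(rec(f1$reader_id[i], f1$case_id[i], "FET1", "initial", "major",
              if (i <= 8) "btv_over_contour;background_placement"
              else "btv_over_contour", TRUE))
    else if (i %in% f1_flag_minor)
      add(rec(f1$reader_id[i], f1$case_id[i], "FET1", "initial", "minor",
              "btv_over_contour", TRUE))
    else if (i %in% f1_minor)
      add(rec(f1$reader_id[i], f1$case_id[i], "FET1", "initial", "minor",
              "btv_under_contour", FALSE))
    else
      add(rec(f1$reader_id[i], f1$case_id[i], "FET1", "initial",
              "acceptable", "", FALSE))
  }
  # FET1 resubmissions: 12 initial requests -> 11 completed first
  # resubmissions (1 incomplete); 2 of them are again major (flagged)
  # and complete a second resubmission
  f1_req <- c(f1_flag_major, f1_flag_minor)[-12]   # 11 completed
  for (j in seq_along(f1_req)) {
    i <- f1_req[j]
    if (j <= 2) {
      add(rec(f1$reader_id[i], f1$case_id[i], "FET1", "resubmission_1",
              "major", "btv_over_contour", TRUE))
      add(rec(f1$reader_id[i], f1$case_id[i], "FET1", "resubmission_2",
              "acceptable", "", FALSE))
    } else {
      add(rec(f1$reader_id[i], f1$case_id[i], "FET1", "resubmission_1",
              "acceptable", "", FALSE))
    }
  }

  # ---- FET3: 60 initial = 7 major flagged + 7 minor flagged +
  #      6 minor unflagged + 40 acceptable
  f3 <- grid3
  f3_flag_major <- 1:7
  f3_flag_minor <- 8:14
  f3_minor <- 15:20
  # violation sets for the 16 flagged FET3 reviews (14 initial + 2 at
  # first resubmission): tac_classification on 9, interpretation on 7,
  # one review also over-contoured
  f3_flag_viol <- c("tac_classification;btv_over_contour",
                    rep("tac_classification", 8),
                    rep("interpretation_discordant", 7))
  for (i in seq_len(nrow(f3))) {
    if (i %in% f3_flag_major)
      add(rec(f3$reader_id[i], f3$case_id[i], "FET3", "initial", "major",
              f3_flag_viol[i], TRUE))
    else if (i %in% f3_flag_minor)
      add(rec(f3$reader_id[i], f3$case_id[i], "FET3", "initial", "minor",
              f3_flag_viol[i], TRUE))
    else if (i %in% f3_minor)
      add(rec(f3$reader_id[i], f3$case_id[i], "FET3", "initial", "minor",
              if (i <= 17) "tac_classification"
              else "interpretation_discordant", FALSE))
    else
      add(rec(f3$reader_id[i], f3$case_id[i], "FET3", "initial",
              "acceptable", "", FALSE))
  }
  # FET3 resubmissions: 14 initial requests -> 13 completed (1
  # incomplete); 2 of the completed are flagged again (1 major, 1
  # minor, using the remaining two flagged violation sets), and one of
  # those completes a second resubmission
  f3_req <- c(f3_flag_major, f3_flag_minor)[-14]   # 13 completed
  for (j in seq_along(f3_req)) {
    i <- f3_req[j]
    if (j == 1) {
      add(rec(f3$reader_id[i], f3$case_id[i], "FET3", "resubmission_1",
              "major", f3_flag_viol[15], TRUE))
      add(rec(f3$reader_id[i], f3$case_id[i], "FET3", "resubmission_2",
              "acceptable", "", FALSE))
    } else if (j == 2) {
      # flagged again but the second resubmission was never completed
      add(rec(f3$reader_id[i], f3$case_id[i], "FET3", "resubmission_1",
              "minor", f3_flag_viol[16], TRUE))
    } else {
      add(rec(f3$reader_id[i], f3$case_id[i], "FET3", "resubmission_1",
              "acceptable", "", FALSE))
    }
  }
  as_review_records(do.call(rbind, rows))
}
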
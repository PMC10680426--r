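# Derivation of the eight binary late-toxicity endpoints from longitudinal
# graded records.

#' Endpoint labels
#'
#' The eight unified late rectal toxicity endpoints: grade >= 1 and
#' grade >= 2 for frequency, bleeding and proctitis; grade >= 1 only for
#' sphincter control and stricture/ulcer.
#'
#' @return A tibble with `endpoint` label, `symptom` and `grade_threshold`.
#' @export
endpoint_definitions <- function() {
  tibble::tibble(
    endpoint = c("frequency_g1", "frequency_g2", "bleeding_g1", "bleeding_g2",
                 "proctitis_g1", "proctitis_g2", "sphincter_control_g1",
                 "stricture_ulcer_g1"),
    symptom = c("frequency", "frequency", "bleeding", "bleeding",
                "proctitis", "proctitis", "sphincter_control",
                "stricture_ulcer"),
    grade_threshold = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L)
  )
}

#' Derive one patient's status for one endpoint
#'
#' Applies the endpoint rules to a single patient-symptom record set:
#' patients with grade >= 1 at baseline are excluded for that endpoint;
#' otherwise any completed late visit with grade >= `grade_threshold` scores
#' the patient as a case (a single event suffices, regardless of
#' completeness); otherwise the patient is a control only if at least 4 of
#' the 7 late follow-ups were completed, and excluded for insufficient
#' follow-up otherwise. A completed visit is any visit with a non-missing
#' grade (attendance, not symptoms); a missing baseline row is treated as
#' grade 0.
#'
#' @param records Tibble with `visit_month` and `grade` (NA = not completed)
#'   for one patient and one symptom; at most one row per visit.
#' @param grade_threshold 1 (G1+) or 2 (G2+); grades above 2 count as >= 2.
#' @return One of `"case"`, `"control"`, `"excluded_baseline"`,
#'   `"excluded_insufficient_followup"`.
#' @export
derive_endpoint <- function(records, grade_threshold) {
  stopifnot(grade_threshold %in% 1:2)
  if (anyDuplicated(records$visit_month) > 0) {
    stop("duplicate visit rows for one patient-endpoint", call. = FALSE)
  }
  bad <- !records$visit_month %in% visit_months()
  if (any(bad)) {
    stop("visit_month outside the fixed follow-up schedule", call. = FALSE)
  }
  baseline <- records$grade[records$visit_month == 0]
  if (length(baseline) == 1 && !is.na(baseline) && baseline >= 1) {
    return("excluded_baseline")
  }
  late <- records[records$visit_month > 0, ]
  completed <- !is.na(late$grade)
  if (any(completed & pmin(late$grade, 2L) >= grade_threshold, na.rm = TRUE)) {
    return("case")
  }
  if (sum(completed) >= 4) "control" else "excluded_insufficient_followup"
}

#' Case/control status matrix for a cohort
#'
#' Derives every endpoint for every patient from long-format toxicity
#' records. Statuses are computed independently per endpoint, so the
#' analysable n varies between endpoints (baseline exclusion and follow-up
#' completeness are endpoint-specific).
#'
#' @param toxicity Long tibble `patient_id`, `symptom`, `visit_month`,
#'   `grade` (e.g. [cohort_toxicity()]).
#' @return A tibble with `patient_id`, one column per endpoint label holding
#'   the status string (statuses rather than 0/1, preserving exclusion
#'   reasons).
#' @export
build_outcome_table <- function(toxicity) {
  defs <- endpoint_definitions()
  if (nrow(toxicity) == 0) {
    out <- tibble::tibble(patient_id = character())
    for (e in defs$endpoint) out[[e]] <- character()
    return(out)
  }
  nested <- toxicity |>
    dplyr::group_by(.data$patient_id, .data$symptom) |>
    tidyr::nest() |>
    dplyr::ungroup()
  rows <- purrr::pmap_dfr(defs, function(endpoint, symptom, grade_threshold) {
    sub <- nested[nested$symptom == symptom, ]
    tibble::tibble(
      patient_id = sub$patient_id,
      endpoint = endpoint,
      status = purrr::map_chr(sub$data, derive_endpoint,
                              grade_threshold = grade_threshold)
    )
  })
  tidyr::pivot_wider(rows, names_from = "endpoint", values_from = "status")
}

#' Per-endpoint status counts
#'
#' @param outcomes Output of [build_outcome_table()].
#' @return A tibble `endpoint`, `case`, `control`, `excluded_baseline`,
#'   `excluded_insufficient_followup`, `analysed` (case + control).
#' @export
endpoint_counts <- function(outcomes) {
  defs <- endpoint_definitions()
  purrr::map_dfr(defs$endpoint, function(e) {
    s <- outcomes[[e]]
    tibble::tibble(
      endpoint = e,
      case = sum(s == "case"),
      control = sum(s == "control"),
      excluded_baseline = sum(s == "excluded_baseline"),
      excluded_insufficient_followup = sum(s == "excluded_insufficient_followup"),
      analysed = sum(s %in% c("case", "control"))
    )
  })
}
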
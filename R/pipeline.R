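# End-to-end orchestration of the four definition comparisons.

#' The four definition hypotheses
#'
#' Each compares the standard-of-care predictor — whole-rectum
#' relative-volume DVH of the original contour — against one investigational
#' definition: the centrally reviewed contour, absolute volumes, or
#' PTV-based truncation at +/- 2 cm or +/- 0 cm.
#'
#' @return A tibble with `comparison`, `def_a`, `mode_a`, `def_b`, `mode_b`.
#' @export
comparison_definitions <- function() {
  tibble::tibble(
    comparison = c("original_vs_reviewed", "relative_vs_absolute",
                   "whole_vs_ptv2", "whole_vs_ptv0"),
    def_a = "original_whole", mode_a = "relative",
    def_b = c("reviewed_whole", "original_whole", "original_ptv2",
              "original_ptv0"),
    mode_b = c("relative", "absolute", "relative", "relative")
  )
}

#' DVH covariate table for a synthetic cohort
#'
#' For every patient, computes cumulative DVHs for the rectal definitions —
#' original and reviewed whole rectum, and the original contour truncated to
#' PTV +/- 2 cm and PTV +/- 0 cm — and extracts the volumes at the arm's
#' EQD2-mapped dose levels. Whole-rectum definitions get both relative (%)
#' and absolute (cc) rows; truncated definitions relative rows. Structures
#' that are empty after truncation yield `NA` covariates and are flagged, so
#' downstream stages can exclude them with a reason.
#'
#' @param cohort A [generate_cohort()] result.
#' @param levels `"seven"` (default) or `"six"` dose levels.
#' @param bin_width DVH bin width in Gy.
#' @return A tibble: `patient_id`, `arm`, `definition`, `mode`,
#'   `empty_structure`, and one column per dose level (`v30`...).
#' @export
cohort_covariates <- function(cohort, levels = c("seven", "six"),
                              bin_width = 0.1) {
  levels <- match.arg(levels)
  ref <- reference_dose_levels(levels)
  purrr::map_dfr(cohort, function(p) {
    masks <- list(
      original_whole = p$rectum_original,
      reviewed_whole = p$rectum_reviewed,
      original_ptv2 = suppressWarnings(
        truncate_to_ptv(p$rectum_original, p$ptv, 2)),
      original_ptv0 = suppressWarnings(
        truncate_to_ptv(p$rectum_original, p$ptv, 0))
    )
    modes <- list(original_whole = c("relative", "absolute"),
                  reviewed_whole = c("relative", "absolute"),
                  original_ptv2 = "relative",
                  original_ptv0 = "relative")
    purrr::imap_dfr(masks, function(m, def) {
      empty <- !any(m$occupancy)
      dvh <- if (!empty) compute_dvh(p$dose, m, bin_width)
      purrr::map_dfr(modes[[def]], function(md) {
        v <- if (empty) {
          stats::setNames(rep(NA_real_, length(ref)), names(ref))
        } else {
          dvh_covariates(dvh, p$arm, mode = md, reference_levels_Gy = ref)
        }
        dplyr::bind_cols(
          tibble::tibble(patient_id = p$patient_id, arm = p$arm,
                         definition = def, mode = md,
                         empty_structure = empty),
          tibble::as_tibble(as.list(v))
        )
      })
    })
  })
}

#' Read a user-supplied covariate table
#'
#' Reads the covariate CSV contract: columns `patient_id`, `arm`,
#' `definition`, `mode`, and one column per dose level (`v30`, ..., `v74`).
#' This is the same format [cohort_covariates()] produces, so precomputed
#' DVH covariates from real treatment plans can enter the statistical stages
#' directly.
#'
#' @param path CSV path.
#' @return A covariate tibble.
#' @export
read_covariate_table <- function(path) {
  cov <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("patient_id", "arm", "definition", "mode")
  missing <- setdiff(need, names(cov))
  if (length(missing) > 0) {
    stop("covariate table lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!any(grepl("^v[0-9]+$", names(cov)))) {
    stop("covariate table has no dose-level columns (v30...)", call. = FALSE)
  }
  if (!"empty_structure" %in% names(cov)) cov$empty_structure <- FALSE
  cov
}

#' Per-dose-level paired Wilcoxon comparisons
#'
#' Compares, at each dose level, the per-patient volumes between the
#' original and reviewed whole-rectum contours, separately for relative and
#' absolute volumes, by Wilcoxon signed-rank test. These comparisons are
#' exploratory and flagged at the .0001 level.
#'
#' @param covariates A [cohort_covariates()] table.
#' @return A tibble `mode`, `level_name`, `n`, `mean_original`,
#'   `mean_reviewed`, `p_value`, `significant_exploratory`.
#' @export
dose_level_comparisons <- function(covariates) {
  level_cols <- grep("^v[0-9]+$", names(covariates), value = TRUE)
  purrr::map_dfr(c("relative", "absolute"), function(md) {
    a <- covariates |>
      dplyr::filter(.data$definition == "original_whole", .data$mode == md,
                    !.data$empty_structure)
    b <- covariates |>
      dplyr::filter(.data$definition == "reviewed_whole", .data$mode == md,
                    !.data$empty_structure)
    common <- intersect(a$patient_id, b$patient_id)
    if (length(common) == 0) return(NULL)
    a <- a[match(common, a$patient_id), ]
    b <- b[match(common, b$patient_id), ]
    purrr::map_dfr(level_cols, function(lv) {
      wt <- suppressMessages(wilcoxon_signed_rank(a[[lv]], b[[lv]]))
      tibble::tibble(
        mode = md, level_name = lv, n = length(common),
        mean_original = mean(a[[lv]]), mean_reviewed = mean(b[[lv]]),
        p_value = wt$p_value,
        significant_exploratory = significance_policy(
          wt$p_value, "exploratory_dose_levels")
      )
    })
  })
}

# deterministic bootstrap substream per endpoint x definition-mode,
# independent of evaluation order
model_stream_seed <- function(seed, endpoint, def, mode) {
  defs <- c("original_whole", "reviewed_whole", "original_ptv2",
            "original_ptv0")
  ei <- match(endpoint, endpoint_definitions()$endpoint)
  di <- match(def, defs) * 2L + (mode == "absolute")
  substream_seed(seed, 1000L * ei + di)
}

#' Fit and compare toxicity models across definition hypotheses
#'
#' The statistical core: for each endpoint, selects analysable patients
#' (case/control status, covariates available for every definition involved,
#' optional arm restriction), fits one logistic model per definition, and
#' for each hypothesis compares the paired model AUCs by the DeLong method.
#' Each definition's model is bootstrapped (stratified by outcome) for its
#' AUC 95% CI and .632 performance estimates. Primary significance is flagged
#' at the Bonferroni .0015 level.
#'
#' @param covariates Covariate table ([cohort_covariates()] or
#'   [read_covariate_table()]).
#' @param outcomes Outcome status table ([build_outcome_table()]).
#' @param comparisons Rows of [comparison_definitions()] to run.
#' @param endpoints Endpoint labels (default all 8).
#' @param B Bootstrap resamples per model.
#' @param seed Master seed; per-(endpoint, definition) substreams are
#'   derived from it, so results do not depend on evaluation order.
#' @param arm_filter `"all"` or one of [arm_levels()].
#' @param threshold_rule Passed to [bootstrap_performance()].
#' @return A tibble, one row per endpoint x comparison, with per-model AUC,
#'   CI and .632 metrics, `delong_p` and `significant_primary`.
#' @export
compare_definitions <- function(covariates, outcomes,
                                comparisons = comparison_definitions(),
                                endpoints = endpoint_definitions()$endpoint,
                                B = 200, seed = 1, arm_filter = "all",
                                threshold_rule = "youden") {
  stopifnot(nrow(comparisons) >= 1, length(endpoints) >= 1)
  if (!arm_filter %in% c("all", arm_levels())) {
    stop("arm_filter must be 'all' or one of ",
         paste(arm_levels(), collapse = ", "), call. = FALSE)
  }
  level_cols <- grep("^v[0-9]+$", names(covariates), value = TRUE)
  defmodes <- unique(rbind(
    data.frame(def = comparisons$def_a, mode = comparisons$mode_a),
    data.frame(def = comparisons$def_b, mode = comparisons$mode_b)
  ))

  purrr::map_dfr(endpoints, function(ep) {
    status <- outcomes[[ep]]
    ids <- outcomes$patient_id[status %in% c("case", "control")]
    # complete cases across every definition entering any hypothesis
    wide <- lapply(seq_len(nrow(defmodes)), function(k) {
      cv <- covariates |>
        dplyr::filter(.data$definition == defmodes$def[k],
                      .data$mode == defmodes$mode[k],
                      !.data$empty_structure)
      cv[match(ids, cv$patient_id), c("patient_id", "arm", level_cols)]
    })
    ok <- Reduce(`&`, lapply(wide, function(w) {
      !is.na(w$patient_id) & stats::complete.cases(w[, level_cols])
    }))
    if (arm_filter != "all") {
      arm_of <- wide[[1]]$arm
      ok <- ok & !is.na(arm_of) & arm_of == arm_filter
    }
    ids <- ids[ok]
    y <- as.numeric(outcomes[[ep]][match(ids, outcomes$patient_id)] == "case")
    if (length(ids) <= 8 || length(unique(y)) < 2) {
      warning("endpoint '", ep, "' has no analysable stratum; skipped",
              call. = FALSE)
      return(NULL)
    }

    fits <- list(); perfs <- list()
    for (k in seq_len(nrow(defmodes))) {
      key <- paste(defmodes$def[k], defmodes$mode[k])
      Xk <- as.matrix(wide[[k]][ok, level_cols])
      fits[[key]] <- fit_logistic(Xk, y)
      perfs[[key]] <- bootstrap_performance(
        Xk, y, fit_logistic, B = B,
        seed = model_stream_seed(seed, ep, defmodes$def[k], defmodes$mode[k]),
        threshold_rule = threshold_rule)
    }

    purrr::pmap_dfr(comparisons, function(comparison, def_a, mode_a, def_b,
                                          mode_b) {
      ka <- paste(def_a, mode_a); kb <- paste(def_b, mode_b)
      dl <- delong_paired(fits[[ka]]$fitted, fits[[kb]]$fitted, y)
      pa <- perfs[[ka]]; pb <- perfs[[kb]]
      tibble::tibble(
        endpoint = ep, comparison = comparison,
        definition_a = ka, definition_b = kb,
        n = length(y), n_case = sum(y),
        auc_a = pa$auc, auc_a_lo = pa$auc_lo, auc_a_hi = pa$auc_hi,
        sens632_a = pa$sens632, spec632_a = pa$spec632,
        ppv632_a = pa$ppv632, npv632_a = pa$npv632,
        auc_b = pb$auc, auc_b_lo = pb$auc_lo, auc_b_hi = pb$auc_hi,
        sens632_b = pb$sens632, spec632_b = pb$spec632,
        ppv632_b = pb$ppv632, npv632_b = pb$npv632,
        delong_p = dl$p_value,
        significant_primary = significance_policy(
          dl$p_value, "primary_model_comparisons")
      )
    })
  })
}

#' CONSORT-style exclusion accounting
#'
#' Counts, per endpoint, the patients removed at each exclusion stage —
#' baseline toxicity, insufficient follow-up, missing/empty structures after
#' truncation — with the analysed remainder; the stages partition the cohort,
#' so counts sum to the cohort total.
#'
#' @param covariates Covariate table.
#' @param outcomes Outcome status table.
#' @return A tibble per endpoint: `total`, `excluded_baseline`,
#'   `excluded_insufficient_followup`, `excluded_missing_structure`,
#'   `analysed`.
#' @export
exclusion_accounting <- function(covariates, outcomes) {
  bad_struct <- covariates |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(missing = any(.data$empty_structure), .groups = "drop")
  purrr::map_dfr(intersect(endpoint_definitions()$endpoint, names(outcomes)),
                 function(ep) {
    s <- outcomes[[ep]]
    miss <- bad_struct$missing[match(outcomes$patient_id,
                                     bad_struct$patient_id)]
    miss[is.na(miss)] <- TRUE   # no covariate rows at all
    eligible <- s %in% c("case", "control")
    tibble::tibble(
      endpoint = ep,
      total = length(s),
      excluded_baseline = sum(s == "excluded_baseline"),
      excluded_insufficient_followup =
        sum(s == "excluded_insufficient_followup"),
      excluded_missing_structure = sum(eligible & miss),
      analysed = sum(eligible & !miss)
    )
  })
}

#' Run the full comparison pipeline
#'
#' End-to-end analysis: synthetic cohort generation (or a user-supplied
#' covariate + outcome pair), contour morphology, DVH covariates at
#' EQD2-mapped dose levels, per-dose-level Wilcoxon comparisons, endpoint
#' derivation, logistic model fitting with stratified-bootstrap performance,
#' and the four DeLong definition comparisons. Fully deterministic given the
#' seed.
#'
#' @param config A [cohort_config()] for synthetic mode; `NULL` when
#'   `covariates` and `outcomes` are supplied directly.
#' @param covariates,outcomes Optional precomputed tables (CSV mode); both
#'   required together.
#' @param comparisons Rows of [comparison_definitions()] to run.
#' @param endpoints Endpoint labels to analyse.
#' @param B Bootstrap resamples per model.
#' @param seed Master seed for the statistical stages.
#' @param arm_filter `"all"` or one arm, for per-arm sensitivity analyses.
#' @param levels `"seven"` or `"six"` dose levels (synthetic mode).
#' @param threshold_rule `"youden"` or `"fixed05"`.
#' @return An object of class `tox_report`: list with `morphology`,
#'   `dose_levels`, `covariates`, `outcomes`, `wilcoxon`, `consort`,
#'   `comparisons`, `meta`.
#' @export
run_pipeline <- function(config = NULL, covariates = NULL, outcomes = NULL,
                         comparisons = comparison_definitions(),
                         endpoints = endpoint_definitions()$endpoint,
                         B = 200, seed = 1, arm_filter = "all",
                         levels = "seven", threshold_rule = "youden") {
  morphology <- NULL
  if (!is.null(config)) {
    cohort <- generate_cohort(config)
    morphology <- morphology_table(cohort)
    covariates <- cohort_covariates(cohort, levels = levels)
    outcomes <- build_outcome_table(cohort_toxicity(cohort))
  } else if (is.null(covariates) || is.null(outcomes)) {
    stop("supply either a cohort config or both covariates and outcomes",
         call. = FALSE)
  }
  dose_levels <- purrr::map_dfr(arm_levels(), dose_levels_for_arm,
                                reference_levels_Gy =
                                  reference_dose_levels(levels))
  wilcoxon <- dose_level_comparisons(covariates)
  consort <- exclusion_accounting(covariates, outcomes)
  comp <- compare_definitions(covariates, outcomes, comparisons, endpoints,
                              B = B, seed = seed, arm_filter = arm_filter,
                              threshold_rule = threshold_rule)
  structure(
    list(morphology = morphology, dose_levels = dose_levels,
         covariates = covariates, outcomes = outcomes, wilcoxon = wilcoxon,
         consort = consort, comparisons = comp,
         meta = list(seed = seed, B = B, arm_filter = arm_filter,
                     levels = levels, threshold_rule = threshold_rule)),
    class = "tox_report"
  )
}

#' @export
print.tox_report <- function(x, ...) {
  cat(sprintf("<tox_report> %d comparison rows, %d endpoints, B=%d, seed=%d\n",
              nrow(x$comparisons), length(unique(x$comparisons$endpoint)),
              x$meta$B, as.integer(x$meta$seed)))
  invisible(x)
}

#' Write a pipeline report to CSV files
#'
#' Writes `morphology.csv`, `dose_levels.csv`, `covariates.csv`,
#' `outcomes.csv`, `wilcoxon.csv`, `comparisons.csv` and `consort.txt` into
#' a directory; run metadata (seed, B, threshold rule) is embedded as `#`
#' header comments in `comparisons.csv`.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "tox_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) if (!is.null(x)) {
    readr::write_csv(x, file.path(dir, f))
  }
  wr(report$morphology, "morphology.csv")
  wr(report$dose_levels, "dose_levels.csv")
  wr(report$covariates, "covariates.csv")
  wr(report$outcomes, "outcomes.csv")
  wr(report$wilcoxon, "wilcoxon.csv")
  hdr <- sprintf("# seed=%s B=%s arm_filter=%s threshold_rule=%s",
                 report$meta$seed, report$meta$B, report$meta$arm_filter,
                 report$meta$threshold_rule)
  writeLines(c(hdr, readr::format_csv(report$comparisons)),
             file.path(dir, "comparisons.csv"))
  con <- utils::capture.output(print(as.data.frame(report$consort)))
  writeLines(con, file.path(dir, "consort.txt"))
  invisible(dir)
}

#' Tidy comparison rows from a report
#'
#' @param x A `tox_report`.
#' @param ... Unused.
#' @return The `comparisons` tibble.
#' @export
tidy.tox_report <- function(x, ...) x$comparisons

#' One-row summary of a report
#'
#' @param x A `tox_report`.
#' @param ... Unused.
#' @return A tibble: rows, endpoints, significant comparisons, AUC range.
#' @export
glance.tox_report <- function(x, ...) {
  tibble::tibble(
    n_comparisons = nrow(x$comparisons),
    n_endpoints = length(unique(x$comparisons$endpoint)),
    n_significant = sum(x$comparisons$significant_primary),
    auc_min = min(c(x$comparisons$auc_a, x$comparisons$auc_b)),
    auc_max = max(c(x$comparisons$auc_a, x$comparisons$auc_b))
  )
}

#' Forest-style plot of paired model AUCs
#'
#' Plots, per endpoint and hypothesis, the AUC point estimates and bootstrap
#' CIs of the standard-of-care and investigational models.
#'
#' @param comparisons The `comparisons` tibble from [run_pipeline()] /
#'   [compare_definitions()].
#' @return A ggplot object.
#' @export
plot_comparisons <- function(comparisons) {
  long <- dplyr::bind_rows(
    dplyr::transmute(comparisons, .data$endpoint, .data$comparison,
                     model = "standard (A)", auc = .data$auc_a,
                     lo = .data$auc_a_lo, hi = .data$auc_a_hi),
    dplyr::transmute(comparisons, .data$endpoint, .data$comparison,
                     model = "investigational (B)", auc = .data$auc_b,
                     lo = .data$auc_b_lo, hi = .data$auc_b_hi)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$auc, y = .data$endpoint,
                                     colour = .data$model)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      position = ggplot2::position_dodge(width = 0.5), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "AUC (95% bootstrap CI)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
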
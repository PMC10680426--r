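# Stratified bootstrap AUC confidence intervals and .632 performance
# estimates.

#' Stratified bootstrap performance of a logistic toxicity model
#'
#' Fits the model on the full sample (the reported AUC point estimate), then
#' draws `B` bootstrap resamples stratified by outcome (cases and controls
#' resampled with replacement separately, preserving the original counts),
#' refitting the model on each. Returns:
#' \itemize{
#'   \item AUC 95% CI — 2.5th/97.5th centiles of the resample AUCs
#'     (refitted model evaluated on its resample);
#'   \item .632 estimates of sensitivity, specificity, PPV, NPV — each
#'     `0.368 * apparent + 0.632 * mean(out-of-bag)`, where apparent metrics
#'     come from the full-sample fit evaluated on the full sample and each
#'     out-of-bag metric from the resample fit evaluated on subjects not
#'     drawn, at the threshold rule applied to the fitting data.
#' }
#' Resamples on which the fit fails or the out-of-bag set lacks a needed
#' class are skipped for the affected quantity and counted; more than 5%
#' skipped resamples raises a warning.
#'
#' @param covariates n x p covariate matrix/data frame.
#' @param outcomes Binary outcomes, both classes present.
#' @param fit_fn Fitting function `(covariates, outcomes) -> model` whose
#'   result supports `predict(model, newdata)` returning probabilities;
#'   default [fit_logistic()].
#' @param B Number of bootstrap resamples (2000 in the reference analysis);
#'   `B = 0` gives the point estimate only, with an `NA` CI.
#' @param seed Integer seed for the resampling stream.
#' @param threshold_rule `"youden"` (default) or `"fixed05"`, see
#'   [dichotomize()].
#' @return An object of class `perf_estimate`: tibble row with `auc`,
#'   `auc_lo`, `auc_hi`, `ci_brackets_point` (FALSE flags the unusual case
#'   where the centile CI fails to bracket the full-sample point estimate,
#'   e.g. at very small B), `sens632`, `spec632`, `ppv632`, `npv632`,
#'   `threshold`, `n`, `n_case`, `n_bootstrap`, `n_skipped`.
#' @export
bootstrap_performance <- function(covariates, outcomes, fit_fn = fit_logistic,
                                  B = 2000, seed = 1,
                                  threshold_rule = c("youden", "fixed05")) {
  threshold_rule <- match.arg(threshold_rule)
  X <- as.matrix(covariates)
  y <- as.numeric(outcomes)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  idx_case <- which(y == 1); idx_ctrl <- which(y == 0)
  if (length(idx_case) == 0 || length(idx_ctrl) == 0) {
    stop("both classes must be present", call. = FALSE)
  }

  full <- fit_fn(X, y)
  p_full <- predict(full, X)
  auc_point <- auc(p_full, y)
  thr <- dichotomize(p_full, y, threshold_rule)$threshold
  apparent <- classification_metrics(p_full, y, thr)

  boot_auc <- rep(NA_real_, B)
  oob <- matrix(NA_real_, nrow = B, ncol = 4,
                dimnames = list(NULL, names(apparent)))
  n_skipped <- 0L
  if (B > 0) {
    set.seed(as.integer(seed))
    for (b in seq_len(B)) {
      take <- c(sample(idx_case, length(idx_case), replace = TRUE),
                sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
      out_idx <- setdiff(seq_along(y), unique(take))
      fit_b <- tryCatch(suppressWarnings(fit_fn(X[take, , drop = FALSE],
                                                y[take])),
                        error = function(e) NULL)
      if (is.null(fit_b) || isFALSE(fit_b$converged)) {
        n_skipped <- n_skipped + 1L
        next
      }
      p_in <- predict(fit_b, X[take, , drop = FALSE])
      boot_auc[b] <- auc(p_in, y[take])
      if (length(out_idx) > 0 && length(unique(y[out_idx])) == 2) {
        thr_b <- dichotomize(p_in, y[take], threshold_rule)$threshold
        p_out <- predict(fit_b, X[out_idx, , drop = FALSE])
        oob[b, ] <- classification_metrics(p_out, y[out_idx], thr_b)
      }
    }
    if (n_skipped > 0.05 * B) {
      warning(sprintf("%d of %d bootstrap resamples skipped", n_skipped, B),
              call. = FALSE)
    }
  }
  ci <- if (B > 0 && any(!is.na(boot_auc))) {
    stats::quantile(boot_auc, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  } else c(NA_real_, NA_real_)
  est632 <- 0.368 * apparent + 0.632 * colMeans(oob, na.rm = TRUE)

  structure(
    tibble::tibble(
      auc = auc_point, auc_lo = ci[1], auc_hi = ci[2],
      ci_brackets_point = !is.na(ci[1]) & ci[1] <= auc_point &
        auc_point <= ci[2],
      sens632 = est632[["sensitivity"]], spec632 = est632[["specificity"]],
      ppv632 = est632[["ppv"]], npv632 = est632[["npv"]],
      threshold = thr, n = length(y), n_case = length(idx_case),
      n_bootstrap = B, n_skipped = n_skipped
    ),
    class = c("perf_estimate", "tbl_df", "tbl", "data.frame")
  )
}

#' Bootstrap AUC confidence interval
#'
#' Convenience wrapper around [bootstrap_performance()] returning the AUC
#' point estimate (full-sample fit) with its stratified-bootstrap 95% CI.
#'
#' @inheritParams bootstrap_performance
#' @return A `perf_estimate` row (see [bootstrap_performance()]).
#' @export
bootstrap_auc_ci <- function(covariates, outcomes, fit_fn = fit_logistic,
                             B = 2000, seed = 1) {
  bootstrap_performance(covariates, outcomes, fit_fn, B, seed)
}

#' .632 bootstrap estimates of classification performance
#'
#' Convenience wrapper around [bootstrap_performance()] returning the four
#' .632 metrics: each `0.368 * apparent + 0.632 * mean out-of-bag`.
#'
#' @inheritParams bootstrap_performance
#' @return Named numeric vector `sens632`, `spec632`, `ppv632`, `npv632`.
#' @export
estimate_632 <- function(covariates, outcomes, fit_fn = fit_logistic,
                         threshold_rule = c("youden", "fixed05"),
                         B = 2000, seed = 1) {
  pe <- bootstrap_performance(covariates, outcomes, fit_fn, B, seed,
                              threshold_rule)
  c(sens632 = pe$sens632, spec632 = pe$spec632,
    ppv632 = pe$ppv632, npv632 = pe$npv632)
}
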
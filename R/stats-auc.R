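# ROC AUC and DeLong paired AUC comparison.

#' Area under the ROC curve (midrank Mann-Whitney)
#'
#' `P(score_case > score_control) + 0.5 P(equal)`, computed from midranks —
#' exactly the Mann-Whitney U statistic divided by the number of
#' case-control pairs, with ties handled by midranks.
#'
#' @param scores Numeric predictor scores.
#' @param labels Binary labels (1/TRUE = case); both classes required.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
}

# Placement values (structural components): for each case the fraction of
# controls it beats (ties at 1/2), and the mirror for controls. Midrank
# identity keeps this O(n log n).
delong_placements <- function(scores, labels) {
  y <- labels
  x_case <- scores[y == 1]
  x_ctrl <- scores[y == 0]
  m <- length(x_case); n <- length(x_ctrl)
  r_all <- rank(c(x_case, x_ctrl))
  v10 <- (r_all[seq_len(m)] - rank(x_case)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(x_ctrl)) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' DeLong variance of a single AUC
#'
#' Nonparametric structural-components estimate of `Var(AUC)`.
#'
#' @inheritParams auc
#' @return Variance estimate.
#' @export
delong_variance <- function(scores, labels) {
  y <- as.numeric(labels)
  pl <- delong_placements(scores, y)
  stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
}

#' DeLong paired comparison of two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same subjects
#' (e.g. fitted probabilities from models using two rectal DVH definitions)
#' by the DeLong structural-components method: the covariance of the paired
#' AUC difference is estimated from per-subject placement values, giving a
#' two-sided normal z-test. If the two score vectors induce identical
#' placements (zero variance of the difference), `p = 1` is returned by
#' convention with a message.
#'
#' @param scores_a,scores_b Scores for the same subjects under definitions
#'   A and B.
#' @param labels Binary labels (1 = case), both classes present.
#' @return A tibble with `auc_a`, `auc_b`, `auc_diff`, `var_diff`, `z`,
#'   `p_value`.
#' @export
delong_paired <- function(scores_a, scores_b, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y),
            all(y %in% c(0, 1)))
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    message("zero variance of the AUC difference; p = 1 by convention")
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, auc_diff = d,
                 var_diff = var_diff, z = z, p_value = p)
}

#' Choose a probability threshold for dichotomising predictions
#'
#' Default rule maximises Youden's J (`sensitivity + specificity - 1`) over
#' the observed probabilities on the fitting data, breaking ties toward the
#' lower threshold; classification is `probability >= threshold`. The
#' alternative `"fixed05"` rule always returns 0.5.
#'
#' @param probabilities Fitted event probabilities.
#' @param labels Binary labels, both classes present.
#' @param rule `"youden"` or `"fixed05"`.
#' @return A list with `threshold`, `sensitivity`, `specificity` on the
#'   fitting data.
#' @export
dichotomize <- function(probabilities, labels, rule = c("youden", "fixed05")) {
  rule <- match.arg(rule)
  y <- as.numeric(labels)
  stopifnot(length(probabilities) == length(y), all(y %in% c(0, 1)))
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  if (rule == "fixed05") {
    mets <- classification_metrics(probabilities, y, 0.5)
    return(list(threshold = 0.5, sensitivity = mets[["sensitivity"]],
                specificity = mets[["specificity"]]))
  }
  m <- sum(y == 1); n <- sum(y == 0)
  cand <- sort(unique(probabilities))
  # counts per candidate value, then cumulative tails: sens(t) = #cases >= t
  case_at <- vapply(split(y, match(probabilities, cand)), sum, numeric(1))
  tot_at <- vapply(split(y, match(probabilities, cand)), length, numeric(1))
  idx <- as.integer(names(case_at))
  cases <- numeric(length(cand)); cases[idx] <- case_at
  totals <- numeric(length(cand)); totals[idx] <- tot_at
  sens <- rev(cumsum(rev(cases))) / m
  spec <- (n - rev(cumsum(rev(totals - cases)))) / n
  j <- sens + spec - 1
  # first (lowest-threshold) maximiser, with strict-improvement tie-break
  k <- which(j > max(j) - 1e-12)[1]
  list(threshold = cand[k], sensitivity = sens[k], specificity = spec[k])
}

#' Classification performance at a threshold
#'
#' Sensitivity, specificity, PPV and NPV of the rule
#' `probability >= threshold`, at the observed prevalence of the evaluation
#' set. Metrics with an empty denominator are `NA`.
#'
#' @param probabilities Event probabilities.
#' @param labels Binary labels.
#' @param threshold Classification threshold.
#' @return Named numeric vector `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
classification_metrics <- function(probabilities, labels, threshold) {
  y <- as.numeric(labels)
  pos <- probabilities >= threshold
  tp <- sum(pos & y == 1); fn <- sum(!pos & y == 1)
  tn <- sum(!pos & y == 0); fp <- sum(pos & y == 0)
  safe <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  c(sensitivity = safe(tp, fn), specificity = safe(tn, fp),
    ppv = safe(tp, fp), npv = safe(tn, fn))
}
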
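# Wilcoxon signed-rank test and multiplicity policy.

#' Wilcoxon signed-rank test for paired dose-volume comparisons
#'
#' Two-sided paired test: zero differences are dropped, absolute differences
#' are midranked, and the statistic is the sum of ranks of positive
#' differences. For `n <= 25` retained pairs the null distribution is
#' enumerated exactly by convolution over the (possibly tied, half-integer)
#' ranks; for larger n a normal approximation with tie correction and
#' continuity correction is used. If every difference is zero, `p = 1` with
#' a message.
#'
#' @param paired_a,paired_b Equal-length paired measurements.
#' @return A tibble with `statistic` (V, rank sum of positive differences),
#'   `n_nonzero`, `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  stopifnot(length(paired_a) == length(paired_b))
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    message("all paired differences are zero; p = 1")
    return(tibble::tibble(statistic = 0, n_nonzero = 0L, p_value = 1,
                          method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    # exact null: W = sum of a random subset of the midranks; work on the
    # doubled (integer) scale so tied half-ranks stay exact
    r2 <- as.integer(round(2 * r))
    dist <- c(1)  # counts over doubled statistic values 0..sum(r2)
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist)
      dist <- c(dist, rep(0, ri)) + shifted
    }
    probs <- dist / sum(dist)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * min(stats::pnorm(z), 1 - stats::pnorm(z)))
    method <- "normal_approx"
  }
  tibble::tibble(statistic = w, n_nonzero = n, p_value = p, method = method)
}

#' Multiplicity policy for significance flags
#'
#' The primary family (the 8 endpoint model comparisons for each of the 4
#' definition hypotheses, 32 tests) is interpreted at the Bonferroni
#' threshold 0.05/32, printed as .0015; the exploratory per-dose-level
#' volume comparisons are interpreted at .0001.
#'
#' @param p_values Numeric p-values.
#' @param family `"primary_model_comparisons"` or `"exploratory_dose_levels"`.
#' @return Logical significance flags (`p < threshold`).
#' @export
significance_policy <- function(p_values,
                                family = c("primary_model_comparisons",
                                           "exploratory_dose_levels")) {
  family <- match.arg(family)
  thr <- if (family == "primary_model_comparisons") {
    bonferroni_threshold(0.05, 32)
  } else 1e-4
  p_values < thr
}
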
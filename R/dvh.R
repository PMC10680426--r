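#' Cumulative dose-volume histogram
#'
#' Computes the cumulative DVH of an organ on a dose grid: for each dose bin
#' edge `d`, the volume of the organ receiving at least `d`, both relative
#' (% of organ, so `cum_rel(0) = 100`) and absolute (cc). Bin edges run from
#' 0 to just above the maximum organ dose in steps of `bin_width`.
#'
#' @param dose A [dose_grid()].
#' @param organ A non-empty [structure_mask()] on the same grid.
#' @param bin_width Dose bin width in Gy (default 0.1; interpolation error at
#'   this width is negligible against clinical precision).
#' @return An object of class `dvh`: list with `dose_edges` (Gy), `cum_rel`
#'   (%), `cum_abs` (cc), `total_volume_cc`.
#' @examples
#' organ <- structure_mask(array(TRUE, c(2, 2, 2)), c(1, 1, 1))
#' d <- dose_grid(array(50, c(2, 2, 2)), c(1, 1, 1))
#' v <- compute_dvh(d, organ)
#' volume_at_dose(v, 30)   # 100 (%)
#' @export
compute_dvh <- function(dose, organ, bin_width = 0.1) {
  stopifnot(inherits(dose, "dose_grid"), inherits(organ, "structure_mask"))
  assert_same_grid(dose, organ)
  if (!any(organ$occupancy)) {
    stop("cannot compute a DVH for an empty organ mask", call. = FALSE)
  }
  stopifnot(bin_width > 0)
  d <- sort(dose$dose[organ$occupancy])
  n <- length(d)
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  # voxels with dose >= edge; half-bin shift guards ties at edges
  at_least <- n - findInterval(edges - bin_width * 1e-6, d)
  total <- n * prod(organ$spacing)
  structure(
    list(dose_edges = edges,
         cum_rel = 100 * at_least / n,
         cum_abs = at_least * prod(organ$spacing),
         total_volume_cc = total),
    class = "dvh"
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %.1f cc, edges 0-%.1f Gy (%d bins)\n",
              x$total_volume_cc, max(x$dose_edges), length(x$dose_edges)))
  invisible(x)
}

#' Volume receiving at least a given dose
#'
#' Linear interpolation of the cumulative DVH at an arbitrary query dose.
#' Queries above the last bin edge return 0 (no volume receives more than the
#' maximum binned dose).
#'
#' @param dvh A [compute_dvh()] result.
#' @param dose_Gy Query dose(s), Gy, >= 0.
#' @param mode `"relative"` (% of organ) or `"absolute"` (cc).
#' @return Interpolated volume(s).
#' @export
volume_at_dose <- function(dvh, dose_Gy, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dvh, "dvh"), all(dose_Gy >= 0))
  y <- if (mode == "relative") dvh$cum_rel else dvh$cum_abs
  out <- stats::approx(dvh$dose_edges, y, xout = pmin(dose_Gy, max(dvh$dose_edges)),
                       rule = 2)$y
  out[dose_Gy > max(dvh$dose_edges)] <- 0
  out
}

#' Mean DVH across a cohort
#'
#' Arithmetic mean of the per-patient volumes at each queried dose level —
#' the standard graphical summary of cohort dosimetry.
#'
#' @param dvhs Non-empty list of [compute_dvh()] results.
#' @param dose_levels_Gy Dose levels at which to average.
#' @param mode `"relative"` or `"absolute"`.
#' @return A tibble with `dose_Gy`, `mean_volume`, `n`.
#' @export
mean_dvh <- function(dvhs, dose_levels_Gy, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (length(dvhs) == 0) stop("mean_dvh needs at least one DVH", call. = FALSE)
  vols <- vapply(dvhs, volume_at_dose, numeric(length(dose_levels_Gy)),
                 dose_Gy = dose_levels_Gy, mode = mode)
  vols <- matrix(vols, nrow = length(dose_levels_Gy))
  tibble::tibble(
    dose_Gy = as.numeric(dose_levels_Gy),
    mean_volume = rowMeans(vols),
    n = length(dvhs)
  )
}

#' DVH covariates at the arm's EQD2-mapped dose levels
#'
#' Extracts, for one patient DVH, the volumes at the arm-specific mapped dose
#' levels — the seven (or six) starred dose-bin covariates entering the
#' logistic toxicity models.
#'
#' @param dvh A [compute_dvh()] result.
#' @param arm One of [arm_levels()].
#' @param mode `"relative"` or `"absolute"`.
#' @param reference_levels_Gy See [dose_levels_for_arm()].
#' @return A named numeric vector (`v30`, ..., `v74`).
#' @export
dvh_covariates <- function(dvh, arm, mode = c("relative", "absolute"),
                           reference_levels_Gy = reference_dose_levels()) {
  mode <- match.arg(mode)
  lv <- dose_levels_for_arm(arm, reference_levels_Gy)
  out <- volume_at_dose(dvh, lv$mapped_Gy, mode = mode)
  names(out) <- lv$level_name
  out
}

#' Mean-DVH plot for a covariate table
#'
#' Plots cohort mean volume at each dose level, one line per rectal
#' definition.
#'
#' @param covariates A covariate table (see [cohort_covariates()]).
#' @param mode `"relative"` or `"absolute"` rows to plot.
#' @return A ggplot object.
#' @export
plot_mean_dvh <- function(covariates, mode = "relative") {
  long <- covariates |>
    dplyr::filter(.data$mode == !!mode) |>
    tidyr::pivot_longer(dplyr::starts_with("v"), names_to = "level_name",
                        values_to = "volume") |>
    dplyr::mutate(reference_Gy = as.numeric(sub("^v", "", .data$level_name))) |>
    dplyr::group_by(.data$definition, .data$reference_Gy) |>
    dplyr::summarise(mean_volume = mean(.data$volume, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$reference_Gy,
                                     y = .data$mean_volume,
                                     colour = .data$definition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Reference (EQD2) dose level (Gy)",
                  y = if (mode == "relative") "Mean volume (%)" else "Mean volume (cc)",
                  colour = "Definition") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cumulative DVH
#'
#' @param object A [compute_dvh()] result.
#' @param mode `"relative"` or `"absolute"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dvh <- function(object, mode = c("relative", "absolute"), ...) {
  mode <- match.arg(mode)
  df <- tibble::tibble(
    dose_Gy = object$dose_edges,
    volume = if (mode == "relative") object$cum_rel else object$cum_abs
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_Gy, y = .data$volume)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Dose (Gy)",
                  y = if (mode == "relative") "Volume (%)" else "Volume (cc)") +
    ggplot2::theme_minimal()
}
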
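#' Truncate an organ mask to the cranio-caudal extent of the PTV
#'
#' Restricts the organ's occupancy to the z-slices whose slice centre lies
#' within `[ptv_inf - margin, ptv_sup + margin]`, where `ptv_inf`/`ptv_sup`
#' are the z-coordinates of the most inferior and superior occupied PTV slice
#' centres. In-plane voxels are untouched; the interval is closed, so slice
#' membership is decided by the slice-centre coordinate (snapped to the
#' lattice rather than an exact metric cut).
#'
#' Truncation at `margin_cm = 0` and `margin_cm = 2` gives the "PTV ± 0 cm"
#' and "PTV ± 2 cm" organ definitions used to stabilise relative-volume DVH
#' metrics against interobserver variation at the open rectal borders.
#'
#' @param organ,ptv [structure_mask()] objects on the same grid.
#' @param margin_cm Non-negative margin (cm) added on both sides of the PTV
#'   z-extent.
#' @return A `structure_mask` (possibly empty; emptiness is flagged with a
#'   warning, and downstream DVH stages exclude such structures).
#' @examples
#' ptv <- structure_mask(array(TRUE, c(1, 1, 4)), c(1, 1, 1))
#' organ <- structure_mask(array(TRUE, c(1, 1, 4)), c(1, 1, 1))
#' truncate_to_ptv(organ, ptv, margin_cm = 0)
#' @export
truncate_to_ptv <- function(organ, ptv, margin_cm = 0) {
  stopifnot(inherits(organ, "structure_mask"), inherits(ptv, "structure_mask"))
  assert_same_grid(organ, ptv)
  if (!is.numeric(margin_cm) || length(margin_cm) != 1 || margin_cm < 0) {
    stop("margin_cm must be a single non-negative length in cm", call. = FALSE)
  }
  ptv_slices <- occupied_slices(ptv)
  if (length(ptv_slices) == 0L) stop("PTV mask is empty", call. = FALSE)
  z <- slice_centers(ptv)
  lo <- z[min(ptv_slices)] - margin_cm
  hi <- z[max(ptv_slices)] + margin_cm
  keep <- z >= lo - 1e-9 & z <= hi + 1e-9
  occ <- organ$occupancy
  occ[, , !keep] <- FALSE
  out <- structure_mask(occ, organ$spacing, organ$grid_origin,
                        name = paste0(organ$name, "_ptv", margin_cm))
  if (!any(out$occupancy)) {
    warning("truncation produced an empty structure for '", organ$name, "'",
            call. = FALSE)
  }
  out
}

#' Cranio-caudal structure length
#'
#' Length from superior/inferior occupied-slice separation:
#' `(superior slice index - inferior slice index + 1) * dz`. A single occupied
#' slice therefore has length `dz`, keeping lengths exact on the lattice.
#'
#' @param organ A non-empty [structure_mask()].
#' @return Length in cm.
#' @export
structure_length <- function(organ) {
  stopifnot(inherits(organ, "structure_mask"))
  occ <- occupied_slices(organ)
  if (length(occ) == 0L) stop("cannot measure length of an empty mask", call. = FALSE)
  (max(occ) - min(occ) + 1L) * organ$spacing[3]
}

#' Structure volume
#'
#' Occupied-voxel count times the voxel volume; an empty mask has volume 0.
#'
#' @param organ A [structure_mask()].
#' @return Volume in cc.
#' @export
structure_volume <- function(organ) {
  stopifnot(inherits(organ, "structure_mask"))
  sum(organ$occupancy) * prod(organ$spacing)
}

#' Dice similarity coefficient between two masks
#'
#' Overlap agreement `2 |A n B| / (|A| + |B|)` between two segmentations of
#' the same grid; 1 for identical non-empty masks, 0 for disjoint masks.
#'
#' @param a,b [structure_mask()] objects on the same grid, not both empty.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  assert_same_grid(a, b)
  na <- sum(a$occupancy)
  nb <- sum(b$occupancy)
  if (na + nb == 0L) {
    stop("Dice coefficient is undefined for two empty masks", call. = FALSE)
  }
  2 * sum(a$occupancy & b$occupancy) / (na + nb)
}

#' Morphology summary table for a cohort
#'
#' Computes, per patient and rectal definition (whole rectum, PTV ± 2 cm,
#' PTV ± 0 cm), the cranio-caudal length and volume of the original and
#' reviewed contours and their Dice similarity, in the layout used for
#' original-versus-reviewed contour comparisons.
#'
#' @param cohort A list of synthetic patients from [generate_cohort()].
#' @return A tibble with one row per patient x definition: `patient_id`,
#'   `definition`, `length_original_cm`, `length_reviewed_cm`,
#'   `volume_original_cc`, `volume_reviewed_cc`, `dice`, plus the
#'   reviewed-minus-original differences.
#' @export
morphology_table <- function(cohort) {
  stopifnot(length(cohort) > 0)
  rows <- purrr::map_dfr(cohort, function(p) {
    defs <- list(
      whole = list(orig = p$rectum_original, rev = p$rectum_reviewed),
      ptv2  = list(orig = truncate_to_ptv(p$rectum_original, p$ptv, 2),
                   rev  = truncate_to_ptv(p$rectum_reviewed, p$ptv, 2)),
      ptv0  = list(orig = truncate_to_ptv(p$rectum_original, p$ptv, 0),
                   rev  = truncate_to_ptv(p$rectum_reviewed, p$ptv, 0))
    )
    purrr::imap_dfr(defs, function(d, nm) {
      empty <- !any(d$orig$occupancy) || !any(d$rev$occupancy)
      tibble::tibble(
        patient_id = p$patient_id,
        definition = nm,
        length_original_cm = if (any(d$orig$occupancy)) structure_length(d$orig) else NA_real_,
        length_reviewed_cm = if (any(d$rev$occupancy)) structure_length(d$rev) else NA_real_,
        volume_original_cc = structure_volume(d$orig),
        volume_reviewed_cc = structure_volume(d$rev),
        dice = if (empty && sum(d$orig$occupancy) + sum(d$rev$occupancy) == 0) NA_real_ else dice(d$orig, d$rev)
      )
    })
  })
  dplyr::mutate(rows,
    length_diff_cm = .data$length_reviewed_cm - .data$length_original_cm,
    volume_diff_cc = .data$volume_reviewed_cc - .data$volume_original_cc
  )
}

#' Median/IQR morphology summary by definition
#'
#' Collapses [morphology_table()] to medians and interquartile ranges per
#' rectal definition, mirroring the usual published layout for contour
#' morphology comparisons.
#'
#' @param morphology Output of [morphology_table()].
#' @return A tibble with one row per definition.
#' @export
summarise_morphology <- function(morphology) {
  q <- function(x, p) stats::quantile(x, p, na.rm = TRUE, names = FALSE)
  morphology |>
    dplyr::group_by(.data$definition) |>
    dplyr::summarise(
      n = dplyr::n(),
      length_original_med = q(.data$length_original_cm, .5),
      length_reviewed_med = q(.data$length_reviewed_cm, .5),
      length_diff_med = q(.data$length_diff_cm, .5),
      length_diff_q1 = q(.data$length_diff_cm, .25),
      length_diff_q3 = q(.data$length_diff_cm, .75),
      volume_original_med = q(.data$volume_original_cc, .5),
      volume_reviewed_med = q(.data$volume_reviewed_cc, .5),
      volume_diff_med = q(.data$volume_diff_cc, .5),
      volume_diff_q1 = q(.data$volume_diff_cc, .25),
      volume_diff_q3 = q(.data$volume_diff_cc, .75),
      dice_med = q(.data$dice, .5),
      .groups = "drop"
    )
}
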
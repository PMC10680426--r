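#' Voxelised structure mask
#'
#' A binary occupancy lattice on a regular grid, used for organs at risk
#' (rectum) and the planning target volume (PTV). Grid coordinates follow the
#' usual radiotherapy convention: `grid_origin` is the centre of voxel
#' `[1, 1, 1]` and `spacing` the voxel edge lengths in cm; the third axis is
#' cranio-caudal (z), so "superior" means larger z index.
#'
#' @param occupancy Three-dimensional logical (or 0/1) array.
#' @param spacing Numeric length-3, voxel size `(dx, dy, dz)` in cm; all > 0.
#' @param grid_origin Numeric length-3, position (cm) of the first voxel centre.
#' @param name Label for the structure (e.g. `"rectum"`, `"ptv"`).
#'
#' @return An object of class `structure_mask`: a list with fields
#'   `occupancy`, `spacing`, `grid_origin`, `name`.
#' @examples
#' m <- structure_mask(array(TRUE, c(2, 2, 3)), spacing = c(0.2, 0.2, 0.5))
#' structure_volume(m)
#' @export
structure_mask <- function(occupancy, spacing, grid_origin = c(0, 0, 0),
                           name = "structure") {
  occupancy <- check_lattice(occupancy, "occupancy")
  storage.mode(occupancy) <- "logical"
  check_spacing(spacing)
  stopifnot(is.numeric(grid_origin), length(grid_origin) == 3)
  structure(
    list(occupancy = occupancy, spacing = as.numeric(spacing),
         grid_origin = as.numeric(grid_origin), name = as.character(name)[1]),
    class = "structure_mask"
  )
}

#' Voxelised absolute dose distribution
#'
#' Per-voxel absolute physical dose in Gy on the same lattice conventions as
#' [structure_mask()].
#'
#' @param dose Three-dimensional numeric array of non-negative doses (Gy).
#' @inheritParams structure_mask
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(dose, spacing, grid_origin = c(0, 0, 0)) {
  dose <- check_lattice(dose, "dose")
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop("dose must be finite and non-negative everywhere", call. = FALSE)
  }
  check_spacing(spacing)
  structure(
    list(dose = dose, spacing = as.numeric(spacing),
         grid_origin = as.numeric(grid_origin)),
    class = "dose_grid"
  )
}

check_lattice <- function(x, what) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop(what, " must be a 3-D array", call. = FALSE)
  }
  if (any(dim(x) < 1L)) stop(what, " must have extent >= 1 on every axis", call. = FALSE)
  x
}

check_spacing <- function(spacing) {
  if (!is.numeric(spacing) || length(spacing) != 3 || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive voxel sizes (cm)", call. = FALSE)
  }
  invisible(spacing)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask '%s'> %s voxels, %d occupied, %.1f cc\n",
              x$name, paste(dim(x$occupancy), collapse = "x"),
              sum(x$occupancy), structure_volume(x)))
  invisible(x)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, dose range %.1f-%.1f Gy\n",
              paste(dim(x$dose), collapse = "x"),
              min(x$dose), max(x$dose)))
  invisible(x)
}

# z-coordinate (cm) of each slice centre
slice_centers <- function(mask) {
  nz <- dim(mask$occupancy %||% mask$dose)[3]
  mask$grid_origin[3] + (seq_len(nz) - 1L) * mask$spacing[3]
}

# indices of slices containing at least one occupied voxel
occupied_slices <- function(mask) {
  which(apply(mask$occupancy, 3, any))
}

same_grid <- function(a, b) {
  identical(dim(a$occupancy %||% a$dose), dim(b$occupancy %||% b$dose)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$grid_origin, b$grid_origin))
}

assert_same_grid <- function(a, b) {
  if (!same_grid(a, b)) {
    stop("structures are not defined on the same grid", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
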
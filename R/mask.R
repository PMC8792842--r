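#' Construct a hematoma mask
#'
#' The unit every metric in the package consumes: a 3D binary voxel grid
#' plus its physical geometry. Grid axes follow the RAS convention
#' throughout the package: +x right (left-right, LR), +y anterior
#' (anterior-posterior, AP), +z superior (superior-inferior, SI). With
#' patients supine, gravity points along -y (posterior).
#'
#' @param grid 3D array of 0/1 (or logical) voxel labels.
#' @param spacing Numeric length-3, voxel edge lengths in mm; all > 0.
#' @param affine Optional 4x4 voxel-to-world matrix mapping 0-based voxel
#'   indices to world mm (NIfTI convention). Defaults to
#'   `diag(c(spacing, 1))`.
#' @param orientation Axis-to-anatomy tag; only `"RAS"` is used
#'   internally.
#'
#' @return An object of class `hematoma_mask`: a list with elements
#'   `grid` (integer array), `spacing`, `affine`, `orientation`.
#' @examples
#' m <- hematoma_mask(array(1L, c(10, 10, 10)))
#' compute_volume(m)  # 1 mL
#' @export
hematoma_mask <- function(grid, spacing = c(1, 1, 1), affine = NULL,
                          orientation = "RAS") {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("grid must be a 3D array")
  if (is.logical(grid)) grid <- grid + 0L
  if (any(!(grid == 0 | grid == 1)))
    stop("grid values must all be 0 or 1")
  storage.mode(grid) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm)")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- unclass(affine)
  attributes(affine)[setdiff(names(attributes(affine)), "dim")] <- NULL
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  structure(list(grid = grid, spacing = spacing, affine = affine,
                 orientation = orientation),
            class = "hematoma_mask")
}

#' @export
print.hematoma_mask <- function(x, ...) {
  cat(sprintf("<hematoma_mask> %s voxels, spacing %s mm, %d foreground (%s)\n",
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$grid), x$orientation))
  invisible(x)
}

n_foreground <- function(mask) sum(mask$grid)

stop_if_empty <- function(mask, what) {
  if (n_foreground(mask) == 0L)
    stop(sprintf("%s needs at least one foreground voxel", what))
  invisible(mask)
}

#' Read a binary mask from a NIfTI file
#'
#' Loads a `.nii`/`.nii.gz` volume, binarizes it at 0.5 (robust to
#' interpolation residue left by registration), and reorients grid,
#' spacing and affine to RAS. Files whose qform/sform codes are both
#' zero carry no orientation information and are taken as already RAS.
#'
#' @param path Path to a NIfTI file holding a 3D volume.
#' @return A [hematoma_mask()]. A zero-foreground volume is returned
#'   with a warning, not an error.
#' @seealso [write_mask()]
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path)
  xf <- RNifti::xform(img)
  if (isTRUE(attr(xf, "code") > 0) &&
      !identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  grid <- (as.array(img) > 0.5) + 0L
  affine <- RNifti::xform(img)
  # voxel edge lengths from the affine column norms (pixdim can be stale
  # when only an sform is present)
  spacing <- sqrt(colSums(unclass(affine)[1:3, 1:3]^2))
  m <- hematoma_mask(grid, spacing = spacing, affine = affine,
                     orientation = "RAS")
  if (n_foreground(m) == 0L)
    warning("mask has no foreground voxels: ", path)
  m
}

#' Write a mask to a NIfTI file
#'
#' Stores the grid as uint8 with the mask's affine in the sform/qform,
#' so that [read_mask()] round-trips grid, spacing and affine exactly.
#'
#' @param mask A [hematoma_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "hematoma_mask"))
  img <- RNifti::asNifti(mask$grid)
  RNifti::pixdim(img) <- mask$spacing
  # the sform carries the full matrix exactly; the quaternion qform
  # cannot represent anisotropic scaling faithfully
  RNifti::sform(img) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Validate that two masks are geometrically comparable
#'
#' Paired metrics assume both scans live on the same grid. This check
#' reports (never errors): grid-shape equality, spacing equality within
#' `spacing_tol` mm, and affine equality within `affine_tol` (maximum
#' absolute element difference).
#'
#' @param initial,repeat_ Masks of the initial and repeat scan.
#' @param spacing_tol,affine_tol Tolerances; defaults 1e-4 mm and 1e-3.
#' @return A list with `valid` (logical) and `reasons` (character,
#'   empty when valid).
#' @export
validate_pair <- function(initial, repeat_, spacing_tol = 1e-4,
                          affine_tol = 1e-3) {
  stopifnot(inherits(initial, "hematoma_mask"),
            inherits(repeat_, "hematoma_mask"))
  reasons <- character(0)
  if (!identical(dim(initial$grid), dim(repeat_$grid)))
    reasons <- c(reasons, "grid shape mismatch")
  if (max(abs(initial$spacing - repeat_$spacing)) > spacing_tol)
    reasons <- c(reasons, "spacing mismatch")
  if (max(abs(initial$affine - repeat_$affine)) > affine_tol)
    reasons <- c(reasons, "affine mismatch")
  list(valid = length(reasons) == 0L, reasons = reasons)
}

#' Apply the repeat-scan volume exclusion rules
#'
#' A pair is excluded when the repeat-scan volume is below
#' `min_repeat_volume_ml` (strict `<`) or the volume decreased by more
#' than `max_decrease_ml` (strict `>`). Boundary cases (exactly 3 mL,
#' decrease of exactly 3 mL) are therefore included. Vectorized over
#' volumes.
#'
#' @param v_initial_ml,v_repeat_ml Hematoma volumes (mL), >= 0.
#' @param cfg A [pipeline_config()].
#' @return A data.frame with columns `included` (logical) and `reason`
#'   (`"included"`, `"repeat volume < minimum"`, or
#'   `"volume decrease > maximum"`).
#' @examples
#' screen_exclusions(c(20, 20, 20), c(2.9, 16.4, 20))
#' @export
screen_exclusions <- function(v_initial_ml, v_repeat_ml,
                              cfg = pipeline_config()) {
  if (length(v_initial_ml) != length(v_repeat_ml))
    stop("volume vectors must have equal length")
  if (any(v_initial_ml < 0) || any(v_repeat_ml < 0))
    stop("volumes must be non-negative")
  low <- v_repeat_ml < cfg$min_repeat_volume_ml
  dec <- (v_initial_ml - v_repeat_ml) > cfg$max_decrease_ml
  reason <- ifelse(low, "repeat volume < minimum",
                   ifelse(dec, "volume decrease > maximum", "included"))
  data.frame(included = !(low | dec), reason = reason,
             stringsAsFactors = FALSE)
}
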
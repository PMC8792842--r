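#' Pipeline configuration
#'
#' Collects every tunable threshold of the morphometry pipeline in one
#' validated object. Defaults follow the clinical conventions used
#' throughout the package: hematoma expansion is an increase of at least
#' 6 mL or 33%, the "no longitudinal axis" (NL) band is a pairwise
#' diameter ratio between 0.850 and 1.176, registration quality control
#' passes at Dice >= 0.93, and pairs are excluded when the repeat-scan
#' volume is below 3 mL or has decreased by more than 3 mL.
#'
#' @param abs_expansion_ml Absolute volume increase (mL) defining
#'   expansion. Default 6.
#' @param rel_expansion_pct Relative volume increase (%) defining
#'   expansion. Default 33.
#' @param nl_ratio_low,nl_ratio_high Pairwise diameter-ratio band within
#'   which all three diameters count as "similar" (NL type). The two
#'   bounds must be reciprocal within 1e-3. Defaults 0.850 and 1.176.
#' @param dice_threshold Dice coefficient at or above which a
#'   registration passes quality control. Default 0.93.
#' @param min_repeat_volume_ml Repeat scans below this volume (mL) are
#'   excluded (strict `<`). Default 3.
#' @param max_decrease_ml Pairs whose volume decreased by more than this
#'   (mL, strict `>`) are excluded. Default 3.
#' @param no_change_eps_mm Absolute floor (mm) below which the largest
#'   diameter change is treated as no direction change. Default 1.
#' @param si_plane Plane whose maximum-area slice provides the
#'   superior-inferior extent: `"coronal"` (default) or `"sagittal"`.
#' @param surface_sigma_mm Standard deviation (mm) of the Gaussian
#'   smoothing applied to the binary indicator before iso-surface
#'   extraction; see [compute_surface_area()].
#' @param rng_seed Optional integer seed recorded for provenance.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$dice_threshold
#' @export
pipeline_config <- function(abs_expansion_ml = 6.0,
                            rel_expansion_pct = 33.0,
                            nl_ratio_low = 0.850,
                            nl_ratio_high = 1.176,
                            dice_threshold = 0.93,
                            min_repeat_volume_ml = 3.0,
                            max_decrease_ml = 3.0,
                            no_change_eps_mm = 1.0,
                            si_plane = c("coronal", "sagittal"),
                            surface_sigma_mm = 0.6,
                            rng_seed = NULL) {
  si_plane <- match.arg(si_plane)
  stopifnot(abs_expansion_ml > 0, rel_expansion_pct > 0,
            dice_threshold >= 0, dice_threshold <= 1,
            min_repeat_volume_ml >= 0, max_decrease_ml >= 0,
            no_change_eps_mm >= 0, surface_sigma_mm >= 0)
  if (!(nl_ratio_low > 0 && nl_ratio_low < 1 && nl_ratio_high > 1))
    stop("need 0 < nl_ratio_low < 1 < nl_ratio_high")
  if (abs(nl_ratio_high - 1 / nl_ratio_low) > 1e-3)
    stop("nl_ratio_high must be the reciprocal of nl_ratio_low (tol 1e-3)")
  structure(list(abs_expansion_ml = abs_expansion_ml,
                 rel_expansion_pct = rel_expansion_pct,
                 nl_ratio_low = nl_ratio_low,
                 nl_ratio_high = nl_ratio_high,
                 dice_threshold = dice_threshold,
                 min_repeat_volume_ml = min_repeat_volume_ml,
                 max_decrease_ml = max_decrease_ml,
                 no_change_eps_mm = no_change_eps_mm,
                 si_plane = si_plane,
                 surface_sigma_mm = surface_sigma_mm,
                 rng_seed = rng_seed),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  invisible(x)
}
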
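#' Per-axis diameter length changes
#'
#' Signed repeat-minus-initial differences of the AP, LR and SI
#' diameters.
#'
#' @param d_initial,d_repeat Numeric `c(ap, lr, si)` diameters in mm,
#'   all positive.
#' @return Named numeric vector `c(ap, lr, si)` of signed changes (mm).
#' @examples
#' length_changes(c(44, 22, 29), c(50, 32, 32))  # (6, 10, 3)
#' @export
length_changes <- function(d_initial, d_repeat) {
  d1 <- as.numeric(d_initial); d2 <- as.numeric(d_repeat)
  if (length(d1) != 3L || length(d2) != 3L || any(d1 <= 0) || any(d2 <= 0))
    stop("diameters must be positive triples (ap, lr, si)")
  structure(d2 - d1, names = c("ap", "lr", "si"))
}

#' Direction of diameter change
#'
#' The axis with the largest absolute length change. Returns `"none"`
#' when the largest change is below the absolute floor
#' `no_change_eps_mm`, or when the two largest absolute changes are
#' similar — quantified by reusing the diameter similarity band: second
#' largest / largest `>= nl_ratio_low`. Exact ties of the maximum across
#' axes are similar by construction and also give `"none"`.
#'
#' @param deltas Signed length changes `c(ap, lr, si)` in mm.
#' @param cfg A [pipeline_config()].
#' @return One of `"AP"`, `"LR"`, `"SI"`, `"none"`.
#' @examples
#' classify_direction_change(c(6, 10, 3))  # "LR"
#' @export
classify_direction_change <- function(deltas, cfg = pipeline_config()) {
  d <- abs(as.numeric(deltas))
  if (length(d) != 3L || any(!is.finite(d)))
    stop("deltas must be three finite numbers (ap, lr, si)")
  s <- sort(d, decreasing = TRUE)
  if (s[1] < cfg$no_change_eps_mm) return("none")
  if (s[2] / s[1] >= cfg$nl_ratio_low) return("none")
  c("AP", "LR", "SI")[which.max(d)]
}

# 26-connected component labelling by frontier BFS on the zero-padded
# grid. Returns a list of index matrices (1-based voxel ijk), one per
# component, in scan order of their seed voxels.
#' @noRd
label_components_26 <- function(grid) {
  d <- dim(grid)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- grid == 1L
  np <- dim(p)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  loff <- offs[, 1] + offs[, 2] * np[1] + offs[, 3] * np[1] * np[2]
  todo <- which(p)
  visited <- !p  # background counts as visited
  comps <- list()
  for (seed in todo) {
    if (visited[seed]) next
    visited[seed] <- TRUE
    members <- frontier <- seed
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, loff, `+`)))
      nb <- nb[!visited[nb]]
      visited[nb] <- TRUE
      members <- c(members, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- arrayInd(members, np) - 1L  # unpad
  }
  comps
}

#' Geometric center of a hematoma
#'
#' The centroid of the voxel centers of the largest 26-connected
#' foreground component (ties broken by scan order of the components),
#' mapped through the affine to world mm.
#'
#' @param mask A [hematoma_mask()] with at least one foreground voxel.
#' @return Numeric length-3 world coordinate (mm), axes (x, y, z) =
#'   (LR, AP, SI).
#' @export
geometric_center <- function(mask) {
  stopifnot(inherits(mask, "hematoma_mask"))
  stop_if_empty(mask, "geometric_center")
  comps <- label_components_26(mask$grid)
  largest <- comps[[which.max(vapply(comps, nrow, integer(1)))]]
  vox <- colMeans(largest) - 1  # 0-based voxel centroid
  as.numeric(mask$affine %*% c(vox, 1))[1:3]
}

#' Movement of the geometric center between scans
#'
#' @param c_initial,c_repeat World-mm centers from [geometric_center()].
#' @return A list with `vector` (repeat minus initial, mm), `distance`
#'   (its Euclidean norm, mm), and `projections`: the in-plane 2D
#'   vectors obtained by dropping z (`axial`), y (`coronal`) and x
#'   (`sagittal`).
#' @examples
#' center_movement(c(0, 0, 0), c(3, 4, 0))$distance  # 5
#' @export
center_movement <- function(c_initial, c_repeat) {
  v <- as.numeric(c_repeat) - as.numeric(c_initial)
  if (length(v) != 3L) stop("centers must be length-3 world coordinates")
  list(vector = structure(v, names = c("x", "y", "z")),
       distance = sqrt(sum(v^2)),
       projections = list(axial = v[1:2], coronal = v[c(1, 3)],
                          sagittal = v[2:3]))
}

#' Classify hematoma expansion
#'
#' Expansion is an absolute increase of at least `abs_expansion_ml`
#' (default 6 mL) or a relative increase of at least
#' `rel_expansion_pct` (default 33%), both inclusive.
#'
#' @param v_initial_ml,v_repeat_ml Volumes in mL; initial must be > 0.
#' @param cfg A [pipeline_config()].
#' @return A list with `abs_change_ml`, `rel_change_pct`, `expansion`.
#' @examples
#' classify_expansion(15.6, 23.5)$expansion  # TRUE
#' @export
classify_expansion <- function(v_initial_ml, v_repeat_ml,
                               cfg = pipeline_config()) {
  if (any(v_initial_ml <= 0)) stop("initial volume must be positive")
  abs_change <- v_repeat_ml - v_initial_ml
  rel_change <- 100 * abs_change / v_initial_ml
  list(abs_change_ml = abs_change,
       rel_change_pct = rel_change,
       expansion = abs_change >= cfg$abs_expansion_ml |
         rel_change >= cfg$rel_expansion_pct)
}

#' Dice overlap coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)` on grids of identical shape.
#'
#' @param a,b [hematoma_mask()] objects with equal grid dimensions; at
#'   least one must have foreground.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "hematoma_mask"), inherits(b, "hematoma_mask"))
  if (!identical(dim(a$grid), dim(b$grid)))
    stop("masks must share the same grid shape")
  na <- n_foreground(a); nb <- n_foreground(b)
  if (na + nb == 0L) stop("Dice undefined for two empty masks")
  2 * sum(a$grid == 1L & b$grid == 1L) / (na + nb)
}

#' Registration quality control from a Dice value
#'
#' Passes when the Dice coefficient reaches the threshold (inclusive,
#' default 0.93).
#'
#' @param dice Dice coefficient in \[0, 1\].
#' @param cfg A [pipeline_config()].
#' @return Logical pass flag (vectorized).
#' @export
qc_registration <- function(dice, cfg = pipeline_config()) {
  if (any(dice < 0 | dice > 1)) stop("dice must lie in [0, 1]")
  dice >= cfg$dice_threshold
}

#' Full morphological change record for one scan pair
#'
#' Composes the per-scan and paired metrics into one record: diameters
#' and their signed changes, direction change, axis types and whether
#' the type changed, center movement, volume change and expansion flag,
#' the pair's own Dice overlap, and registration QC. The masks are
#' assumed co-registered; `reg_dice`, when available from the upstream
#' registration, drives `qc_pass` (absent, QC is recorded as passed and
#' `qc_assumed` is set).
#'
#' @param initial,repeat_ Co-registered [hematoma_mask()] objects of the
#'   initial and repeat scan.
#' @param cfg A [pipeline_config()].
#' @param reg_dice Optional registration-to-template Dice value used for
#'   quality control.
#' @return An object of class `change_record` (named list); see
#'   [as.data.frame.change_record()] for the flat form.
#' @export
pair_report <- function(initial, repeat_, cfg = pipeline_config(),
                        reg_dice = NULL) {
  chk <- validate_pair(initial, repeat_)
  if (!chk$valid)
    stop("masks are not comparable: ", paste(chk$reasons, collapse = "; "))
  m1 <- shape_metrics(initial, cfg)
  m2 <- shape_metrics(repeat_, cfg)
  deltas <- length_changes(c(m1$diam_ap, m1$diam_lr, m1$diam_si),
                           c(m2$diam_ap, m2$diam_lr, m2$diam_si))
  c1 <- geometric_center(initial)
  c2 <- geometric_center(repeat_)
  mv <- center_movement(c1, c2)
  exp_ <- classify_expansion(m1$volume_ml, m2$volume_ml, cfg)
  dice <- dice_coefficient(initial, repeat_)
  qc_assumed <- is.null(reg_dice)
  structure(list(
    metrics_initial = m1, metrics_repeat = m2,
    delta_ap = deltas[["ap"]], delta_lr = deltas[["lr"]],
    delta_si = deltas[["si"]],
    direction_change = classify_direction_change(deltas, cfg),
    axis_type_initial = m1$axis_type, axis_type_repeat = m2$axis_type,
    axis_type_changed = m1$axis_type != m2$axis_type,
    center_initial = c1, center_repeat = c2,
    move_distance_mm = mv$distance, move_vector = mv$vector,
    move_projections = mv$projections,
    abs_change_ml = exp_$abs_change_ml, rel_change_pct = exp_$rel_change_pct,
    expansion = exp_$expansion,
    dice = dice,
    qc_pass = if (qc_assumed) TRUE else qc_registration(reg_dice, cfg),
    qc_assumed = qc_assumed,
    sr_change = m2$sr_index - m1$sr_index),
    class = "change_record")
}

#' Flatten a change record to a one-row data.frame
#'
#' @param x A `change_record` from [pair_report()].
#' @param row.names,optional,... Ignored; present for the generic.
#' @return One-row data.frame suitable for row-binding into a cohort
#'   table.
#' @export
as.data.frame.change_record <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  m1 <- x$metrics_initial; m2 <- x$metrics_repeat
  names(m1) <- paste0(names(m1), "_initial")
  names(m2) <- paste0(names(m2), "_repeat")
  cbind(m1, m2,
        data.frame(delta_ap = x$delta_ap, delta_lr = x$delta_lr,
                   delta_si = x$delta_si,
                   direction_change = x$direction_change,
                   axis_type_changed = x$axis_type_changed,
                   move_x = x$move_vector[["x"]],
                   move_y = x$move_vector[["y"]],
                   move_z = x$move_vector[["z"]],
                   move_distance_mm = x$move_distance_mm,
                   abs_change_ml = x$abs_change_ml,
                   rel_change_pct = x$rel_change_pct,
                   expansion = x$expansion,
                   dice = x$dice, qc_pass = x$qc_pass,
                   qc_assumed = x$qc_assumed,
                   sr_change = x$sr_change,
                   stringsAsFactors = FALSE))
}

#' @export
print.change_record <- function(x, ...) {
  cat("<change_record>\n")
  cat(sprintf("  volume: %.1f -> %.1f mL (abs %+.1f mL, rel %+.1f%%)%s\n",
              x$metrics_initial$volume_ml, x$metrics_repeat$volume_ml,
              x$abs_change_ml, x$rel_change_pct,
              if (x$expansion) "  EXPANSION" else ""))
  cat(sprintf("  diameters (ap,lr,si): (%.0f, %.0f, %.0f) -> (%.0f, %.0f, %.0f) mm\n",
              x$metrics_initial$diam_ap, x$metrics_initial$diam_lr,
              x$metrics_initial$diam_si, x$metrics_repeat$diam_ap,
              x$metrics_repeat$diam_lr, x$metrics_repeat$diam_si))
  cat(sprintf("  axis type: %s -> %s; direction change: %s\n",
              x$axis_type_initial, x$axis_type_repeat, x$direction_change))
  cat(sprintf("  SR index: %.3f -> %.3f\n",
              x$metrics_initial$sr_index, x$metrics_repeat$sr_index))
  cat(sprintf("  center moved %.2f mm (%+.2f, %+.2f, %+.2f)\n",
              x$move_distance_mm, x$move_vector[["x"]],
              x$move_vector[["y"]], x$move_vector[["z"]]))
  invisible(x)
}
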
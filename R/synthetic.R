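#' Specification of one synthetic hematoma pair
#'
#' Parameters of a seeded ellipsoid-based phantom. The base lesion is an
#' ellipsoid with the given semi-axes whose radial boundary can be
#' modulated by a smooth angular perturbation ("bumps"); the repeat-scan
#' lesion is the same shape scaled per axis by `growth_factors` about
#' its center and translated by `displacement`. Because the perturbation
#' is defined on the ellipsoid's angular coordinate, the repeat lesion
#' is exactly the affine image of the initial one: volumes scale by
#' `prod(growth_factors)` and each axis-aligned extent by its factor,
#' which is what makes analytic ground truth possible.
#'
#' @param semi_axes Numeric `c(x, y, z)` semi-axes in mm along the grid
#'   axes (x = LR, y = AP, z = SI); all positive.
#' @param center_world Lesion center in world mm; default is the grid
#'   center (set when rasterized).
#' @param irregularity_amp Fractional radial perturbation amplitude in
#'   `[0, 1)`; 0 gives an exact ellipsoid.
#' @param n_bumps Number of random cosine lobes in the perturbation.
#' @param growth_factors Per-axis multiplicative factors `c(x, y, z)`
#'   applied to the repeat scan; all positive.
#' @param displacement World-mm translation `c(x, y, z)` of the repeat
#'   lesion's center.
#' @param seed Integer seed; all randomness of the case flows from it.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(semi_axes,
                           center_world = NULL,
                           irregularity_amp = 0,
                           n_bumps = 8L,
                           growth_factors = c(1, 1, 1),
                           displacement = c(0, 0, 0),
                           seed = 1L) {
  semi_axes <- as.numeric(semi_axes)
  growth_factors <- as.numeric(growth_factors)
  displacement <- as.numeric(displacement)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("semi_axes must be three positive lengths (mm)")
  if (irregularity_amp < 0 || irregularity_amp >= 1)
    stop("irregularity_amp must lie in [0, 1)")
  if (length(growth_factors) != 3L || any(growth_factors <= 0))
    stop("growth_factors must be three positive numbers")
  stopifnot(length(displacement) == 3L, n_bumps >= 1L)
  structure(list(semi_axes = semi_axes, center_world = center_world,
                 irregularity_amp = irregularity_amp,
                 n_bumps = as.integer(n_bumps),
                 growth_factors = growth_factors,
                 displacement = displacement, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Seeded parameters of the angular perturbation: unit directions,
# frequencies and phases of n cosine lobes. |g(u)| <= 1 by construction.
#' @noRd
bump_params <- function(seed, n) {
  with_seed(seed, {
    d <- matrix(rnorm(3 * n), ncol = 3)
    d <- d / sqrt(rowSums(d^2))
    list(dir = d, freq = runif(n, 2, 6), phase = runif(n, 0, 2 * pi))
  })
}

# Rasterize one lesion: ellipsoid with semi-axes r (mm) at center c
# (world mm), radial boundary scaled by 1 + amp * g(u) where u is the
# unit direction of the ellipsoid-normalized offset. Computation is
# restricted to the lesion's bounding box.
#' @noRd
rasterize_lesion <- function(semi_axes, center, amp, bumps, spacing,
                             grid_shape) {
  grid_shape <- as.integer(grid_shape)
  reach <- semi_axes * (1 + amp)
  lo_w <- center - reach
  hi_w <- center + reach
  # voxel index i (1-based) has world coordinate (i-1)*spacing
  lo <- floor(lo_w / spacing) + 1L
  hi <- ceiling(hi_w / spacing) + 1L
  if (any(lo < 3L) || any(hi > grid_shape - 2L))
    stop("lesion exceeds the grid (needs a 2-voxel margin); ",
         "enlarge grid_shape or shrink the lesion")
  grid <- array(0L, grid_shape)
  db <- hi - lo + 1L
  w <- lapply(1:3, function(ax)
    (((lo[ax]:hi[ax]) - 1) * spacing[ax] - center[ax]) / semi_axes[ax])
  W1 <- array(w[[1]], db)
  W2 <- array(rep(w[[2]], each = db[1]), db)
  W3 <- array(rep(w[[3]], each = db[1] * db[2]), db)
  m2 <- W1^2 + W2^2 + W3^2
  if (amp == 0) {
    inside <- m2 <= 1
  } else {
    nrm <- sqrt(m2)
    nrm[nrm == 0] <- 1  # center voxel: direction irrelevant, always inside
    g <- 0
    for (k in seq_len(nrow(bumps$dir))) {
      ud <- (W1 * bumps$dir[k, 1] + W2 * bumps$dir[k, 2] +
               W3 * bumps$dir[k, 3]) / nrm
      g <- g + cos(bumps$freq[k] * ud + bumps$phase[k])
    }
    g <- g / nrow(bumps$dir)
    inside <- m2 <= (1 + amp * g)^2
  }
  grid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- inside + 0L
  grid
}

.default_center <- function(spec, spacing, grid_shape) {
  if (!is.null(spec$center_world)) return(as.numeric(spec$center_world))
  (as.integer(grid_shape) - 1) / 2 * spacing
}

#' Rasterize an exact ellipsoid mask
#'
#' A voxel is foreground iff its world center lies inside the ellipsoid
#' `sum(((p - c) / r)^2) <= 1`. Any irregularity amplitude in the spec
#' is ignored here; see [make_irregular_mask()].
#'
#' @param spec A [synthetic_spec()].
#' @param spacing Voxel spacing in mm (default 1 mm isotropic).
#' @param grid_shape Grid dimensions (default `c(128, 128, 128)`).
#' @return A [hematoma_mask()].
#' @export
make_ellipsoid_mask <- function(spec, spacing = c(1, 1, 1),
                                grid_shape = c(128, 128, 128)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ctr <- .default_center(spec, spacing, grid_shape)
  hematoma_mask(rasterize_lesion(spec$semi_axes, ctr, 0, NULL, spacing,
                                 grid_shape),
                spacing = spacing)
}

#' Rasterize an irregular (perturbed-ellipsoid) mask
#'
#' The ellipsoid's radial boundary is scaled by `1 + amp * g(u)`, where
#' `g` is a seeded sum of `n_bumps` randomly oriented cosine lobes on
#' the unit sphere with `|g| <= 1`. Amplitude 0 reduces exactly to
#' [make_ellipsoid_mask()].
#'
#' @inheritParams make_ellipsoid_mask
#' @return A [hematoma_mask()].
#' @export
make_irregular_mask <- function(spec, spacing = c(1, 1, 1),
                                grid_shape = c(128, 128, 128)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ctr <- .default_center(spec, spacing, grid_shape)
  bumps <- if (spec$irregularity_amp > 0)
    bump_params(spec$seed, spec$n_bumps) else NULL
  hematoma_mask(rasterize_lesion(spec$semi_axes, ctr,
                                 spec$irregularity_amp, bumps, spacing,
                                 grid_shape),
                spacing = spacing)
}

#' Generate one paired case with ground truth
#'
#' The initial lesion follows the spec; the repeat lesion is the same
#' shape with `growth_factors` applied per axis about the center and the
#' center moved by `displacement`. Both share the seeded perturbation,
#' so the repeat lesion is exactly the affine image of the initial one.
#'
#' @inheritParams make_ellipsoid_mask
#' @return A list with `initial` and `repeat_` ([hematoma_mask()]s) and
#'   `truth`, a list holding `true_volumes` (mL; analytic for amplitude
#'   0, voxel-measured otherwise, with the exact ratio
#'   `prod(growth_factors)` applied), `true_diameters` (two `(ap, lr,
#'   si)` triples in mm; `NA` for perturbed shapes), `true_center_shift`
#'   (mm), `true_axis_type`, and `true_expansion`.
#' @examples
#' cs <- make_paired_case(synthetic_spec(c(11, 22, 14.5),
#'                                       growth_factors = c(1.1, 1, 1)),
#'                        grid_shape = c(96, 96, 96))
#' cs$truth$true_diameters
#' @export
make_paired_case <- function(spec, spacing = c(1, 1, 1),
                             grid_shape = c(128, 128, 128)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ctr <- .default_center(spec, spacing, grid_shape)
  amp <- spec$irregularity_amp
  bumps <- if (amp > 0) bump_params(spec$seed, spec$n_bumps) else NULL
  g1 <- rasterize_lesion(spec$semi_axes, ctr, amp, bumps, spacing,
                         grid_shape)
  g2 <- rasterize_lesion(spec$semi_axes * spec$growth_factors,
                         ctr + spec$displacement, amp, bumps, spacing,
                         grid_shape)
  m1 <- hematoma_mask(g1, spacing = spacing)
  m2 <- hematoma_mask(g2, spacing = spacing)
  vol_ratio <- prod(spec$growth_factors)
  v1 <- if (amp == 0) 4 / 3 * pi * prod(spec$semi_axes) / 1000 else
    compute_volume(m1)
  d1 <- if (amp == 0)
    2 * spec$semi_axes[c(2, 1, 3)] else rep(NA_real_, 3)  # (ap, lr, si)
  d2 <- d1 * spec$growth_factors[c(2, 1, 3)]
  names(d1) <- names(d2) <- c("ap", "lr", "si")
  exp_ <- classify_expansion(v1, v1 * vol_ratio)
  truth <- list(true_volumes = c(v1 = v1, v2 = v1 * vol_ratio),
                true_diameters = list(initial = d1, repeat_ = d2),
                true_center_shift = spec$displacement,
                true_axis_type = if (amp == 0) classify_axis_type(d1) else
                  NA_character_,
                true_expansion = exp_$expansion)
  list(initial = m1, repeat_ = m2, truth = truth, spec = spec)
}

.region_levels <- c("frontal", "parietal", "insula/temporal", "occipital",
                    "basal-ganglia/thalamus", "brain stem", "cerebellum")

# Clinical covariates are drawn to resemble a multicenter ICH cohort
# (elderly, mostly male, deep hemorrhages, median volume ~20 mL). Poor
# outcome (GOS <= 3) is generated from a logistic model with known
# coefficients so predictor selection and model fitting have a planted
# signal; sex, IVH, onset time and scan interval carry none.
.outcome_coefs <- c(intercept = 0.15, age = 0.03, volume = 0.035,
                    gcs = -0.28, expansion = 0.7, delta_lr = 0.13,
                    subtentorial = 0.6)

#' Generate a seeded synthetic cohort
#'
#' Draws `n` paired-case specifications with a planted center-movement
#' bias (`displacement ~ bias_strength * bias_direction + isotropic
#' N(0, noise_sd^2)` mm) plus a matching clinical table. Lesion
#' semi-axes are lognormal with AP typically longest; per-axis growth is
#' a shared lognormal factor with per-axis jitter, producing expansion
#' in roughly a quarter of cases. Poor outcome is generated from a
#' logistic model over age, volume, GCS, expansion, lateral (LR)
#' diameter change and subtentorial location with fixed known
#' coefficients. Everything is reproducible from `seed`; masks are not
#' rasterized here — use [make_paired_case()] per row or
#' [cohort_table()].
#'
#' @param n Number of patients (>= 1).
#' @param bias_direction Unit vector of the planted displacement bias;
#'   default `c(0, -1, 0)` (posterior, i.e. gravity when supine).
#' @param bias_strength Mean displacement along the bias (mm).
#' @param noise_sd SD of the isotropic displacement noise (mm).
#' @param irregularity_amp Length-2 range (or single value) of the
#'   per-case perturbation amplitude; default `c(0.1, 0.3)`. Use 0 for
#'   exact ellipsoids with full diameter ground truth.
#' @param seed Integer seed.
#' @param spacing,grid_shape Rasterization geometry for downstream use.
#' @return An object of class `synthetic_cohort`: a list with `specs`
#'   (list of [synthetic_spec()]), `clinical` (data.frame, one row per
#'   patient), `truth` (data.frame of per-case ground truth), and the
#'   geometry.
#' @export
make_cohort <- function(n,
                        bias_direction = c(0, -1, 0),
                        bias_strength = 3,
                        noise_sd = 1,
                        irregularity_amp = c(0.1, 0.3),
                        seed = 1L,
                        spacing = c(1, 1, 1),
                        grid_shape = c(128, 128, 128)) {
  if (n < 1) stop("n must be >= 1")
  bias_direction <- as.numeric(bias_direction)
  if (length(bias_direction) != 3L || all(bias_direction == 0))
    bias_direction <- c(0, 0, 0)
  else
    bias_direction <- bias_direction / sqrt(sum(bias_direction^2))
  if (length(irregularity_amp) == 1L)
    irregularity_amp <- rep(irregularity_amp, 2L)
  with_seed(seed, {
    # lognormal semi-axes with AP typically longest; medians chosen so
    # the median lesion volume is ~20 mL
    semi_lr <- pmin(pmax(rlnorm(n, log(13.5), 0.25), 6), 27)
    semi_ap <- pmin(pmax(rlnorm(n, log(20.5), 0.25), 8), 33)
    semi_si <- pmin(pmax(rlnorm(n, log(17.5), 0.25), 7), 30)
    shared <- rnorm(n, 0.02, 0.10)
    growth <- vapply(1:3, function(i)
      pmin(pmax(exp(shared + rnorm(n, 0, 0.04)), 0.7), 1.6),
      numeric(n))
    # shrink rare oversized lesions so the grown, perturbed repeat scan
    # still fits the grid with margin
    amp_max <- max(irregularity_amp)
    allowed <- (min(as.integer(grid_shape) * spacing) - 1) / 2 - 3 *
      max(spacing) - 6
    reach <- pmax(semi_lr * growth[, 1], semi_ap * growth[, 2],
                  semi_si * growth[, 3]) * (1 + amp_max)
    shrink <- pmin(1, allowed / reach)
    semi_lr <- semi_lr * shrink
    semi_ap <- semi_ap * shrink
    semi_si <- semi_si * shrink
    disp <- t(vapply(seq_len(n), function(i)
      bias_strength * bias_direction + rnorm(3, 0, noise_sd),
      numeric(3)))
    amp <- runif(n, irregularity_amp[1], irregularity_amp[2])
    case_seed <- sample.int(.Machine$integer.max, n)
    ctr0 <- (as.integer(grid_shape) - 1) / 2 * spacing
    centers <- t(vapply(seq_len(n), function(i) ctr0 + runif(3, -6, 6),
                        numeric(3)))

    age <- pmin(pmax(round(rnorm(n, 61, 13)), 18), 95)
    sex <- factor(ifelse(runif(n) < 0.638, "M", "F"), levels = c("F", "M"))
    onset_to_ct <- round(rlnorm(n, log(3), 0.7), 1)
    scan_interval <- round(pmin(pmax(8 + rlnorm(n, log(14.8), 0.55), 8), 72), 1)
    gcs <- pmin(pmax(15L - rpois(n, 1.3) - rbinom(n, 1L, 0.3) * rpois(n, 4),
                     3L), 15L)
    ivh <- runif(n) < 0.342
    location <- factor(sample(c("deep", "lobar", "subtentorial"), n,
                              replace = TRUE,
                              prob = c(0.698, 0.216, 0.086)),
                       levels = c("deep", "lobar", "subtentorial"))
    region <- character(n)
    region[location == "deep"] <- "basal-ganglia/thalamus"
    region[location == "lobar"] <-
      sample(.region_levels[1:4], sum(location == "lobar"), replace = TRUE,
             prob = c(0.3, 0.25, 0.3, 0.15))
    region[location == "subtentorial"] <-
      sample(c("brain stem", "cerebellum"), sum(location == "subtentorial"),
             replace = TRUE, prob = c(0.4, 0.6))
    region <- factor(region, levels = .region_levels)

    v1 <- 4 / 3 * pi * semi_lr * semi_ap * semi_si / 1000
    vol_ratio <- growth[, 1] * growth[, 2] * growth[, 3]
    expansion_true <- (v1 * (vol_ratio - 1) >= 6) | (vol_ratio - 1 >= 0.33)
    delta_lr_true <- 2 * semi_lr * (growth[, 1] - 1)
    b <- .outcome_coefs
    eta <- b["intercept"] + b["age"] * (age - 61) + b["volume"] * (v1 - 20) +
      b["gcs"] * (gcs - 14) + b["expansion"] * expansion_true +
      b["delta_lr"] * delta_lr_true +
      b["subtentorial"] * (location == "subtentorial")
    poor <- runif(n) < plogis(eta)
    gos <- integer(n)
    gos[poor] <- sample(1:3, sum(poor), replace = TRUE,
                        prob = c(0.15, 0.25, 0.6))
    gos[!poor] <- sample(4:5, sum(!poor), replace = TRUE,
                         prob = c(0.6, 0.4))

    specs <- lapply(seq_len(n), function(i)
      synthetic_spec(semi_axes = c(semi_lr[i], semi_ap[i], semi_si[i]),
                     center_world = centers[i, ],
                     irregularity_amp = amp[i],
                     n_bumps = 10L,
                     growth_factors = growth[i, ],
                     displacement = disp[i, ],
                     seed = case_seed[i]))
    clinical <- data.frame(
      patient_id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex, onset_to_ct = onset_to_ct,
      scan_interval = scan_interval, gcs = gcs, gos = gos,
      location = location, ivh = ivh, region_label = region,
      stringsAsFactors = FALSE)
    truth <- data.frame(
      patient_id = clinical$patient_id,
      true_v1_ml = v1, true_v2_ml = v1 * vol_ratio,
      true_diam_ap = 2 * semi_ap, true_diam_lr = 2 * semi_lr,
      true_diam_si = 2 * semi_si,
      true_growth_x = growth[, 1], true_growth_y = growth[, 2],
      true_growth_z = growth[, 3],
      true_disp_x = disp[, 1], true_disp_y = disp[, 2],
      true_disp_z = disp[, 3],
      true_delta_lr = delta_lr_true,
      true_expansion = expansion_true,
      poor_outcome_true = poor,
      stringsAsFactors = FALSE)
    structure(list(specs = specs, clinical = clinical, truth = truth,
                   spacing = spacing, grid_shape = as.integer(grid_shape),
                   seed = as.integer(seed)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases, grid %s at %s mm, seed %d\n",
              length(x$specs), paste(x$grid_shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"), x$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `clinical.csv` and `truth.csv`, and (optionally) the NIfTI
#' mask pairs `<id>_initial.nii.gz` / `<id>_repeat.nii.gz`.
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if missing).
#' @param write_nifti Rasterize and write the mask pairs; default FALSE
#'   (the CSVs alone are cheap).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_nifti = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (write_nifti) {
    for (i in seq_along(cohort$specs)) {
      cs <- make_paired_case(cohort$specs[[i]], cohort$spacing,
                             cohort$grid_shape)
      id <- cohort$clinical$patient_id[i]
      write_mask(cs$initial, file.path(dir, paste0(id, "_initial.nii.gz")))
      write_mask(cs$repeat_, file.path(dir, paste0(id, "_repeat.nii.gz")))
    }
  }
  invisible(dir)
}
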
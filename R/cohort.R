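#' Build a cohort table from a synthetic cohort
#'
#' Rasterizes each paired case, runs the full morphometry pipeline
#' ([shape_metrics()] on both scans, [pair_report()] on the pair), joins
#' the clinical record, and applies the volume exclusion screen. Rows
#' failing the screen keep their flag but should be excluded from
#' summaries (all summary functions here do so).
#'
#' @param cohort A [make_cohort()] result.
#' @param cfg A [pipeline_config()].
#' @param progress Print a dot per case.
#' @return A data.frame, one row per patient: clinical columns, per-scan
#'   metrics (`*_initial`, `*_repeat`), change metrics, and `included` /
#'   `exclusion_reason`.
#' @export
cohort_table <- function(cohort, cfg = pipeline_config(),
                         progress = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- lapply(seq_along(cohort$specs), function(i) {
    if (progress) cat(".")
    cs <- make_paired_case(cohort$specs[[i]], cohort$spacing,
                           cohort$grid_shape)
    rec <- as.data.frame(pair_report(cs$initial, cs$repeat_, cfg))
    cbind(cohort$clinical[i, , drop = FALSE], rec)
  })
  if (progress) cat("\n")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  scr <- screen_exclusions(tab$volume_ml_initial, tab$volume_ml_repeat, cfg)
  tab$included <- scr$included & tab$qc_pass
  tab$exclusion_reason <- ifelse(scr$included, ifelse(tab$qc_pass,
                                                      "included",
                                                      "registration QC"),
                                 scr$reason)
  tab$poor_outcome <- define_outcome(tab$gos)
  tab
}

.included <- function(table) {
  if ("included" %in% names(table)) table[table$included, , drop = FALSE]
  else table
}

#' Descriptive summary of a cohort table
#'
#' Per group: `n (%)` for categorical variables, `mean (SD)` and
#' `median (IQR)` for continuous ones. The IQR is reported as a single
#' width, Q3 - Q1, computed with the default linear-interpolation
#' (type 7) quantile rule. Rows flagged excluded are dropped first.
#'
#' @param table A cohort table (see [cohort_table()]).
#' @param variables Character vector of column names to summarize.
#' @param group_by Optional name of a grouping column; `NULL` summarizes
#'   the whole cohort as one group.
#' @return A long data.frame with columns `variable`, `level`, `group`,
#'   `n`, `pct`, `mean`, `sd`, `median`, `iqr` (unused cells `NA`).
#'   Empty groups are omitted with a warning.
#' @export
summarize_cohort <- function(table, variables, group_by = NULL) {
  table <- .included(table)
  groups <- if (is.null(group_by)) list(all = table)
  else split(table, table[[group_by]])
  empty <- vapply(groups, nrow, integer(1)) == 0L
  if (any(empty)) {
    warning("omitting empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  out <- list()
  for (g in names(groups)) {
    dat <- groups[[g]]
    for (v in variables) {
      x <- dat[[v]]
      if (is.null(x)) stop("no such column: ", v)
      if (is.numeric(x)) {
        q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
        out[[length(out) + 1L]] <- data.frame(
          variable = v, level = NA_character_, group = g,
          n = sum(!is.na(x)), pct = NA_real_,
          mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE),
          median = q[[2]], iqr = q[[3]] - q[[1]],
          stringsAsFactors = FALSE)
      } else {
        tabv <- table(x)
        out[[length(out) + 1L]] <- data.frame(
          variable = v, level = names(tabv), group = g,
          n = as.integer(tabv),
          pct = 100 * as.integer(tabv) / sum(tabv),
          mean = NA_real_, sd = NA_real_, median = NA_real_,
          iqr = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subgroup difference test with automatic test selection
#'
#' Categorical variables: Pearson's chi-squared test, or Fisher's exact
#' test when any expected cell count is below 5. Continuous variables
#' with two groups: Student's t-test, or the Mann-Whitney U test when a
#' Shapiro-Wilk normality screen (alpha = 0.05) fails in any group;
#' with more than two groups, ANOVA or Kruskal-Wallis under the same
#' screen. The selection is a pure function of the data.
#'
#' @param table A cohort table.
#' @param variable Column to test.
#' @param grouping Column defining >= 2 groups.
#' @return A list with `test` (name of the test that fired),
#'   `statistic`, `p_value`.
#' @export
compare_groups <- function(table, variable, grouping) {
  table <- .included(table)
  x <- table[[variable]]
  g <- factor(table[[grouping]])
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (length(unique(x[!is.na(x)])) < 2L)
    stop("variable is constant; nothing to test")
  if (is.numeric(x)) {
    shap_p <- vapply(levels(g), function(l) {
      xs <- x[g == l]
      xs <- xs[!is.na(xs)]
      if (length(xs) < 3L || length(unique(xs)) == 1L) return(0)
      if (length(xs) > 5000L) xs <- sample(xs, 5000L)
      shapiro.test(xs)$p.value
    }, numeric(1))
    normal <- all(shap_p >= 0.05)
    if (nlevels(g) == 2L) {
      if (normal) {
        ht <- t.test(x ~ g)
        list(test = "t-test", statistic = unname(ht$statistic),
             p_value = ht$p.value)
      } else {
        ht <- wilcox.test(x ~ g, exact = FALSE)
        list(test = "Mann-Whitney U", statistic = unname(ht$statistic),
             p_value = ht$p.value)
      }
    } else {
      if (normal) {
        ht <- summary(aov(x ~ g))[[1]]
        list(test = "ANOVA", statistic = ht[["F value"]][1],
             p_value = ht[["Pr(>F)"]][1])
      } else {
        ht <- kruskal.test(x ~ g)
        list(test = "Kruskal-Wallis", statistic = unname(ht$statistic),
             p_value = ht$p.value)
      }
    }
  } else {
    ct <- table(factor(x), g)
    expected <- outer(rowSums(ct), colSums(ct)) / sum(ct)
    if (any(expected < 5)) {
      ht <- fisher.test(ct)
      list(test = "Fisher exact", statistic = NA_real_,
           p_value = ht$p.value)
    } else {
      ht <- chisq.test(ct, correct = FALSE)
      list(test = "chi-squared", statistic = unname(ht$statistic),
           p_value = ht$p.value)
    }
  }
}

#' Region-wise synthesis of center-movement directions
#'
#' For each anatomical region, every nonzero movement vector is
#' normalized to unit length and averaged: the mean unit vector gives
#' the region's synthesized direction, its norm is the resultant length
#' (1 = all cases agree, 0 = directions cancel), and the mean movement
#' distance is reported separately (zero-distance cases kept there). By
#' default vectors are direction-only; `weight = "distance"` weights
#' each unit vector by its movement distance instead.
#'
#' @param table A cohort table with `move_x/move_y/move_z`,
#'   `move_distance_mm` and a region column.
#' @param region_col Name of the region column.
#' @param weight `"none"` (unit vectors, default) or `"distance"`.
#' @return A data.frame, one row per region present: `region`, `n`,
#'   `n_direction` (nonzero vectors), `mean_ux/uy/uz` (mean unit
#'   vector), `resultant_length`, `mean_distance_mm`,
#'   `direction_defined` (FALSE when no nonzero vectors or complete
#'   cancellation).
#' @export
synthesize_region_directions <- function(table,
                                         region_col = "region_label",
                                         weight = c("none", "distance")) {
  weight <- match.arg(weight)
  table <- .included(table)
  regions <- split(table, droplevels(factor(table[[region_col]])))
  rows <- lapply(names(regions), function(rg) {
    dat <- regions[[rg]]
    v <- cbind(dat$move_x, dat$move_y, dat$move_z)
    nrm <- sqrt(rowSums(v^2))
    nz <- nrm > 0
    if (any(nz)) {
      u <- v[nz, , drop = FALSE] / nrm[nz]
      if (weight == "distance") u <- u * nrm[nz]
      mu <- colMeans(u)
      rl <- sqrt(sum(colMeans(v[nz, , drop = FALSE] / nrm[nz])^2))
    } else {
      mu <- c(NA_real_, NA_real_, NA_real_)
      rl <- NA_real_
    }
    data.frame(region = rg, n = nrow(dat), n_direction = sum(nz),
               mean_ux = mu[1], mean_uy = mu[2], mean_uz = mu[3],
               resultant_length = rl,
               mean_distance_mm = mean(dat$move_distance_mm),
               direction_defined = any(nz) && isTRUE(rl > 1e-12),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Cross-tabulation of longitudinal-axis types between scans
#'
#' @param table A cohort table with `axis_type_initial` and
#'   `axis_type_repeat`.
#' @return A list with `table` (4x4 contingency, initial x repeat over
#'   AP/LR/SI/NL) and `fraction_unchanged` (trace / total).
#' @export
axis_type_cross_tab <- function(table) {
  table <- .included(table)
  lev <- c("AP", "LR", "SI", "NL")
  ct <- table(factor(table$axis_type_initial, levels = lev),
              factor(table$axis_type_repeat, levels = lev))
  list(table = ct, fraction_unchanged = sum(diag(ct)) / sum(ct))
}
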
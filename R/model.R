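#' Poor-outcome flag from the Glasgow Outcome Scale
#'
#' Poor outcome is GOS <= 3. Vectorized.
#'
#' @param gos Integer GOS scores in 1..5.
#' @return Logical vector.
#' @export
define_outcome <- function(gos) {
  if (any(is.na(gos)) || any(gos < 1 | gos > 5))
    stop("gos must lie in 1..5")
  gos <= 3
}

# Fit a binomial glm and fail loudly on (quasi-)separation or
# non-convergence, which leave coefficients and Wald intervals
# meaningless.
#' @noRd
fit_logistic_checked <- function(formula, data) {
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop("logistic fit shows (quasi-)separation; ",
             "coefficients are not identifiable", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("logistic fit did not converge")
  if (any(abs(coef(fit)) > 15, na.rm = TRUE))
    stop("logistic fit shows (quasi-)separation; ",
         "coefficients are not identifiable")
  # embed the actual formula and data so step() can re-evaluate the call
  fit$call$formula <- formula
  fit$call$data <- data
  fit
}

#' Select predictors by multivariable logistic screening
#'
#' Fits one multivariable logistic model of the outcome on all
#' candidates and retains those whose Wald coefficient p-value is below
#' `alpha` (for factors, a variable is retained when any of its level
#' coefficients passes). A backward-stepwise AIC mode is available
#' behind `method = "stepwise"`.
#'
#' @param table Data.frame with the outcome column and candidates.
#' @param candidates Character vector of candidate column names.
#' @param outcome Name of the logical/0-1 outcome column (default
#'   `"poor_outcome"`).
#' @param alpha Retention threshold on the coefficient p-value.
#' @param method `"full"` (single full-model fit, default) or
#'   `"stepwise"`.
#' @return Character vector of selected candidate names (possibly
#'   empty), with the fitted screening model as attribute `"fit"`.
#' @export
select_predictors <- function(table, candidates, outcome = "poor_outcome",
                              alpha = 0.05,
                              method = c("full", "stepwise")) {
  method <- match.arg(method)
  y <- table[[outcome]]
  if (is.null(y)) stop("no such outcome column: ", outcome)
  if (length(unique(y)) < 2L) stop("outcome must have both classes")
  if (nrow(table) <= length(candidates))
    stop("need more rows than candidate predictors")
  missing_c <- setdiff(candidates, names(table))
  if (length(missing_c))
    stop("unknown candidate(s): ", paste(missing_c, collapse = ", "))
  fml <- reformulate(candidates, response = outcome)
  fit <- fit_logistic_checked(fml, table)
  if (method == "stepwise") {
    fit <- step(fit, direction = "backward", trace = 0)
    sel <- intersect(candidates, all.vars(formula(fit))[-1])
    attr(sel, "fit") <- fit
    return(sel)
  }
  sm <- summary(fit)$coefficients
  asg <- attr(model.matrix(fit), "assign")  # maps coefs to terms
  terms_lab <- attr(terms(fit), "term.labels")
  keep <- setdiff(unique(asg[sm[, "Pr(>|z|)"] < alpha]), 0L)
  sel <- terms_lab[keep]
  sel <- intersect(candidates, sel)
  attr(sel, "fit") <- fit
  sel
}

#' Fit the final prognostic logistic model
#'
#' Maximum-likelihood logistic regression of the outcome on the selected
#' predictors, reported as coefficients, odds ratios `exp(beta)` with
#' Wald 95% intervals `exp(beta +/- 1.96 SE)`, discrimination (ROC AUC
#' with DeLong interval) on the fitted risks, and a decile calibration
#' table.
#'
#' @param table Data.frame with outcome and predictors.
#' @param selected Character vector of predictor names (e.g. from
#'   [select_predictors()]).
#' @param outcome Name of the outcome column.
#' @param conf_level Confidence level of the Wald intervals.
#' @return An object of class `model_report`: list with `coefficients`
#'   (data.frame: term, beta, se, p_value, odds_ratio, or_low,
#'   or_high), `auc`, `auc_ci`, `calibration` (see
#'   [calibration_curve()]), `n_used`, `selected`, and the `fit`.
#' @export
fit_final_model <- function(table, selected, outcome = "poor_outcome",
                            conf_level = 0.95) {
  if (length(selected) == 0L) stop("no predictors selected")
  fml <- reformulate(selected, response = outcome)
  dat <- table[complete.cases(table[, c(outcome, selected)]), , drop = FALSE]
  fit <- fit_logistic_checked(fml, dat)
  sm <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = rownames(sm),
                      beta = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      p_value = sm[, "Pr(>|z|)"],
                      odds_ratio = exp(sm[, "Estimate"]),
                      or_low = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
                      or_high = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
                      row.names = NULL, stringsAsFactors = FALSE)
  scores <- fitted(fit)
  y <- dat[[outcome]]
  roc <- roc_auc(scores, y, conf_level = conf_level)
  structure(list(coefficients = coefs,
                 auc = roc$auc, auc_ci = roc$ci,
                 calibration = calibration_curve(scores, y),
                 n_used = nrow(dat), selected = selected, fit = fit),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> n = %d, AUC = %.3f (95%% CI %.3f-%.3f)\n",
              x$n_used, x$auc, x$auc_ci[1], x$auc_ci[2]))
  df <- x$coefficients
  df[-1] <- lapply(df[-1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC equals the probability that a random positive scores above a
#' random negative, ties counted one half; computed via pROC, with a
#' DeLong-variance confidence interval.
#'
#' @param scores Numeric risk scores.
#' @param outcomes Logical/0-1 outcomes; both classes must be present.
#' @param conf_level Confidence level.
#' @return A list with `auc` and `ci` (length-2).
#' @export
roc_auc <- function(scores, outcomes, conf_level = 0.95) {
  y <- as.integer(outcomes)
  if (length(unique(y)) < 2L) stop("outcomes must contain both classes")
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(suppressWarnings(
    pROC::ci.auc(r, conf.level = conf_level, method = "delong")))
  list(auc = as.numeric(pROC::auc(r)), ci = ci[c(1, 3)])
}

#' Decile calibration table
#'
#' Bins observations by predicted risk into `n_bins` quantile bins and
#' compares the mean predicted risk with the observed event rate per
#' bin. Bins emptied by heavy ties are merged with their neighbor and
#' the result flagged via the `merged` attribute.
#'
#' @param scores Predicted risks in \[0, 1\].
#' @param outcomes Logical/0-1 outcomes.
#' @param n_bins Number of bins (default 10, i.e. deciles).
#' @return Data.frame with `bin`, `n`, `predicted_mean`,
#'   `observed_rate`; attribute `merged` is TRUE when fewer than
#'   `n_bins` bins could be formed.
#' @export
calibration_curve <- function(scores, outcomes, n_bins = 10L) {
  s <- as.numeric(scores)
  if (any(s < 0 | s > 1)) stop("scores must lie in [0, 1]")
  y <- as.integer(outcomes)
  qs <- unique(quantile(s, probs = seq(0, 1, length.out = n_bins + 1L),
                        type = 7))
  if (length(qs) < 3L) qs <- c(min(s) - 1e-9, mean(range(s)), max(s) + 1e-9)
  bins <- cut(s, breaks = qs, include.lowest = TRUE)
  agg <- lapply(levels(bins), function(b) {
    sel <- bins == b
    data.frame(bin = b, n = sum(sel),
               predicted_mean = mean(s[sel]),
               observed_rate = mean(y[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[out$n > 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "merged") <- nrow(out) < n_bins
  out
}
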
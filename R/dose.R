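# Dose-response fits: increasing 4-parameter logistic for calcium-imaging
# titrations, and the declining half-logistic preference model whose EC50 is
# the concentration at which preference falls to 0.25 (half of the 0.5
# chance level). Both are fit by Levenberg-Marquardt nonlinear least squares
# on per-concentration means, with EC50 log-parameterized to keep it
# positive.

#' Baseline-normalized fluorescence response
#'
#' `dF/F = (F - F0) / F0`, the peak fluorescence change relative to the
#' pre-stimulus baseline. Vectorized; when given replicate vectors, also
#' returns the mean and standard error.
#'
#' @param f_peak peak fluorescence value(s).
#' @param f_baseline baseline fluorescence value(s), strictly positive.
#' @return list with `response` (elementwise dF/F), `mean` and `se`.
#' @export
delta_f_over_f <- function(f_peak, f_baseline) {
  if (any(f_baseline <= 0)) stop("baseline fluorescence must be positive")
  r <- (f_peak - f_baseline) / f_baseline
  list(response = r, mean = mean(r),
       se = if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else NA_real_)
}

titration_model <- function(x, i_min, i_max, log_ec50, h) {
  i_min + (i_max - i_min) / (1 + (exp(log_ec50) / x)^h)
}

#' Fit an increasing four-parameter logistic titration curve
#'
#' Model: `f(x) = i_min + (i_max - i_min) / (1 + (ec50 / x)^h)`, increasing
#' in concentration for `h > 0`. Fitting is on the mean response per
#' concentration (replicate standard errors are carried for reporting only),
#' by Levenberg-Marquardt least squares. Default starting values: observed
#' response extremes for the asymptotes, the geometric mean concentration
#' for EC50, and `h = 1`.
#'
#' @param data data.frame with columns `concentration` and `response`
#'   (replicate rows allowed), e.g. from [generate_titration_curves()].
#' @param init optional named list overriding starting values
#'   (`i_min`, `i_max`, `ec50`, `h`).
#' @return a `titration_fit` list: `i_min`, `i_max`, `ec50`, `hill`, `rss`,
#'   `converged`, `extrapolated` (EC50 outside the tested range), `means`
#'   (per-concentration summary), `fit` (the underlying `nls` object).
#' @export
fit_titration <- function(data, init = NULL) {
  stopifnot(all(c("concentration", "response") %in% names(data)),
            all(data$concentration > 0))
  means <- stats::aggregate(response ~ concentration, data, mean)
  means$se <- stats::aggregate(response ~ concentration, data,
                               function(v) if (length(v) > 1)
                                 stats::sd(v) / sqrt(length(v)) else NA_real_
                               )$response
  means <- means[order(means$concentration), ]
  if (nrow(means) < 4L)
    stop("a 4-parameter fit needs at least 4 distinct concentrations")
  if (stats::sd(means$response) < 1e-12)
    stop("degenerate fit: response does not vary with concentration")
  start <- list(i_min = min(means$response), i_max = max(means$response),
                log_ec50 = mean(log(means$concentration)), h = 1)
  if (!is.null(init)) {
    for (nm in intersect(names(init), c("i_min", "i_max", "h")))
      start[[nm]] <- init[[nm]]
    if (!is.null(init$ec50)) start$log_ec50 <- log(init$ec50)
  }
  fit <- minpack.lm::nlsLM(
    response ~ titration_model(concentration, i_min, i_max, log_ec50, h),
    data = means, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  ec50 <- exp(cf[["log_ec50"]])
  structure(list(
    i_min = cf[["i_min"]], i_max = cf[["i_max"]], ec50 = ec50,
    hill = cf[["h"]], rss = sum(stats::residuals(fit)^2),
    converged = fit$convInfo$isConv,
    extrapolated = ec50 < min(means$concentration) ||
      ec50 > max(means$concentration),
    means = means, fit = fit), class = "titration_fit")
}

preference_model <- function(x, log_ec50, h) {
  0.5 / (1 + (x / exp(log_ec50))^h)
}

#' Fit the two-bottle preference model
#'
#' Model: `f(x) = 0.5 / (1 + (x / ec50)^h)`, declining from the 0.5
#' indifference level; by construction `f(ec50) = 0.25`, so the fitted EC50
#' is the concentration at which preference is half of chance. Fitting is by
#' Levenberg-Marquardt least squares on per-concentration mean ratios.
#'
#' @param data data.frame with columns `concentration` and `ratio` (one row
#'   per trial), e.g. from [generate_preference_trials()].
#' @param init optional named list overriding starting values (`ec50`, `h`).
#' @return a `preference_fit` list: `ec50`, `hill`, `rss`, `converged`,
#'   `means`, `fit`.
#' @export
fit_preference <- function(data, init = NULL) {
  stopifnot(all(c("concentration", "ratio") %in% names(data)),
            all(data$concentration > 0))
  means <- stats::aggregate(ratio ~ concentration, data, mean)
  means <- means[order(means$concentration), ]
  if (nrow(means) < 3L) stop("need at least 3 distinct concentrations")
  if (all(means$ratio >= 0.5 - 1e-12) || stats::sd(means$ratio) < 1e-12)
    stop("degenerate fit: preference does not decline with concentration")
  start <- list(log_ec50 = mean(log(means$concentration)), h = 1)
  if (!is.null(init)) {
    if (!is.null(init$ec50)) start$log_ec50 <- log(init$ec50)
    if (!is.null(init$h)) start$h <- init$h
  }
  fit <- minpack.lm::nlsLM(
    ratio ~ preference_model(concentration, log_ec50, h),
    data = means, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(
    ec50 = exp(cf[["log_ec50"]]), hill = cf[["h"]],
    rss = sum(stats::residuals(fit)^2), converged = fit$convInfo$isConv,
    means = means, fit = fit), class = "preference_fit")
}

#' Fold difference between two EC50s
#'
#' Ratio of the larger to the smaller EC50; optionally rounded to the
#' nearest ten for headline reporting.
#'
#' @param ec50_a,ec50_b EC50 values (same units), both positive.
#' @param nearest_ten round the ratio to the nearest ten.
#' @return the fold ratio (>= 1).
#' @export
#' @examples
#' fold_difference(1542.1, 18.9)                    # ~81.6
#' fold_difference(1542.1, 18.9, nearest_ten = TRUE) # 80
fold_difference <- function(ec50_a, ec50_b, nearest_ten = FALSE) {
  stopifnot(ec50_a > 0, ec50_b > 0)
  r <- max(ec50_a, ec50_b) / min(ec50_a, ec50_b)
  if (nearest_ten) round(r / 10) * 10 else r
}
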
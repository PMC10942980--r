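# Random-intercept mixed-model analysis of stride records.
#
# Model: y_ij = x_ij' beta + alpha_i + e_ij, alpha_i ~ N(0, sigma_b^2),
# e_ij ~ N(0, sigma_e^2), with the participant as the grouping factor. All
# model inputs (predictors and the dependent variable) are standardized as
# Z scores pooled within condition, so coefficients are unitless and the
# between-participant variance is left for the random intercept to absorb.
# Fits use REML via lme4. Inference is Wald-normal: CI = beta +/- 1.96 SE,
# p = 2 * pnorm(-|beta/SE|). ICC = sigma_b^2 / (sigma_b^2 + sigma_e^2).
# Marginal and conditional R^2 follow the variance-partition form:
#   R2m = sigma_f^2 / (sigma_f^2 + sigma_b^2 + sigma_e^2)
#   R2c = (sigma_f^2 + sigma_b^2) / (sigma_f^2 + sigma_b^2 + sigma_e^2)
# with sigma_f^2 the empirical variance of the fitted fixed-effect predictor.

#' Standardize columns as Z scores
#'
#' @param data a data frame.
#' @param columns names of numeric columns to standardize.
#' @return List with `data` (standardized copy), `center` and `scale`
#'   (named vectors for back-conversion).
#' @export
zscore_columns <- function(data, columns) {
  center <- vapply(data[columns], mean, numeric(1))
  scale <- vapply(data[columns], stats::sd, numeric(1))
  zero <- names(scale)[scale == 0 | !is.finite(scale)]
  if (length(zero) > 0L) {
    stop("zero-variance column(s): ", paste(zero, collapse = ", "))
  }
  for (cl in columns) data[[cl]] <- (data[[cl]] - center[[cl]]) / scale[[cl]]
  list(data = data, center = center, scale = scale)
}

#' Fit a random-intercept linear mixed model to stride records
#'
#' REML fit of `dependent ~ fixed_effects + (1 | group)` via
#' \code{lme4::lmer}. Data with a single group level degenerate to ordinary
#' least squares (the random intercept is unidentifiable); the fit is then
#' reported with `sigma2_b = 0` and a warning. A boundary fit with
#' `sigma2_b = 0` is valid and reported with ICC 0 and a warning.
#'
#' @param data data frame (typically standardized stride records).
#' @param dependent name of the dependent column.
#' @param fixed_effects character vector of predictor column names (>= 1).
#' @param group name of the grouping column (participant identifier).
#' @return An object of class `stride_lmm` with elements `beta` (coefficient
#'   table: estimate, se, ci_low, ci_high, p_value), `sigma2_b`, `sigma2_e`,
#'   `sigma2_f`, `icc`, `r2_marginal`, `r2_conditional`,
#'   `participant_intercepts` (BLUPs), `n`, `n_groups`, and the underlying
#'   `fit`.
#' @export
fit_stride_lmm <- function(data, dependent, fixed_effects,
                           group = "participant_id") {
  stopifnot(length(fixed_effects) >= 1L)
  missing_cols <- setdiff(c(dependent, fixed_effects, group), names(data))
  if (length(missing_cols) > 0L) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)
  if (nrow(data) < length(fixed_effects) + 2L) {
    stop(sprintf("too few observations (%d) to fit %d fixed effects",
                 nrow(data), length(fixed_effects)))
  }
  data[[group]] <- factor(data[[group]])
  n_groups <- nlevels(data[[group]])
  rhs <- paste(fixed_effects, collapse = " + ")
  if (n_groups < 2L) {
    warning("single group: random intercept unidentifiable, reducing to OLS")
    f <- stats::as.formula(paste(dependent, "~", rhs))
    fit <- stats::lm(f, data = data)
    est <- stats::coef(fit)[fixed_effects]
    se <- sqrt(diag(stats::vcov(fit)))[fixed_effects]
    s2e <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
    s2b <- 0
    blups <- stats::setNames(0, levels(data[[group]]))
  } else {
    f <- stats::as.formula(paste(dependent, "~", rhs, "+ (1 |", group, ")"))
    fit <- lme4::lmer(f, data = data, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2b <- vc$vcov[vc$grp == group]
    s2e <- vc$vcov[vc$grp == "Residual"]
    fx <- lme4::fixef(fit)[fixed_effects]
    est <- fx
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[fixed_effects]
    re <- lme4::ranef(fit)[[group]]
    blups <- stats::setNames(re[["(Intercept)"]], rownames(re))
    if (s2b <= 1e-10) {
      warning("boundary fit: random-intercept variance is 0 (ICC 0)")
    }
  }
  zcrit <- stats::qnorm(0.975)
  zval <- est / se
  beta <- data.frame(term = fixed_effects, estimate = unname(est),
                     se = unname(se),
                     ci_low = unname(est - zcrit * se),
                     ci_high = unname(est + zcrit * se),
                     p_value = unname(2 * stats::pnorm(-abs(zval))),
                     row.names = NULL)
  X <- as.matrix(data[fixed_effects])
  s2f <- stats::var(as.numeric(X %*% est))
  out <- structure(list(
    beta = beta, sigma2_b = s2b, sigma2_e = s2e, sigma2_f = s2f,
    icc = if (s2b + s2e > 0) s2b / (s2b + s2e) else NA_real_,
    participant_intercepts = blups,
    dependent = dependent, fixed_effects = fixed_effects, group = group,
    n = nrow(data), n_groups = n_groups, fit = fit), class = "stride_lmm")
  r2 <- variance_explained(out)
  out$r2_marginal <- r2[["r2_marginal"]]
  out$r2_conditional <- r2[["r2_conditional"]]
  out
}

#' Marginal and conditional R-squared of a fitted model
#'
#' Variance-partition form: the marginal R-squared is the share of the total
#' variance (fixed + random-intercept + residual) attributable to the fixed
#' effects; the conditional R-squared additionally credits the random
#' intercepts.
#'
#' @param fit a `stride_lmm`.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
variance_explained <- function(fit) {
  tot <- fit$sigma2_f + fit$sigma2_b + fit$sigma2_e
  if (tot <= 0) stop("all variance components are zero")
  c(r2_marginal = fit$sigma2_f / tot,
    r2_conditional = (fit$sigma2_f + fit$sigma2_b) / tot)
}

#' @export
print.stride_lmm <- function(x, digits = 3, ...) {
  cat(sprintf("Random-intercept LMM (REML): %s ~ %s + (1 | %s)\n",
              x$dependent, paste(x$fixed_effects, collapse = " + "), x$group))
  cat(sprintf("  %d strides, %d participants\n", x$n, x$n_groups))
  b <- x$beta
  b[-1] <- lapply(b[-1], round, digits)
  print(b, row.names = FALSE)
  cat(sprintf("  ICC %.3f | marginal R2 %.3f | conditional R2 %.3f\n",
              x$icc, x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' @export
summary.stride_lmm <- function(object, ...) {
  structure(list(model = object,
                 variance = c(fixed = object$sigma2_f,
                              participant = object$sigma2_b,
                              residual = object$sigma2_e)),
            class = "summary.stride_lmm")
}

#' @export
print.summary.stride_lmm <- function(x, ...) {
  print(x$model)
  cat("Variance components:\n")
  print(round(x$variance, 4))
  invisible(x)
}

#' @export
coef.stride_lmm <- function(object, ...) {
  stats::setNames(object$beta$estimate, object$beta$term)
}

#' @export
predict.stride_lmm <- function(object, newdata = NULL, ...) {
  if (inherits(object$fit, "lmerMod")) {
    if (is.null(newdata)) stats::predict(object$fit)
    else stats::predict(object$fit, newdata = newdata, allow.new.levels = TRUE)
  } else {
    if (is.null(newdata)) stats::fitted(object$fit)
    else stats::predict(object$fit, newdata = newdata)
  }
}

#' RMSE between motion-capture and IMU foot-contact angles
#'
#' Pooled over strides (and participants) per segment:
#' `sqrt(mean((theta_imu - theta_mocap)^2))`.
#'
#' @param records stride-record data frame with paired
#'   `theta_<seg>_fc` / `theta_<seg>_imu_fc` columns.
#' @param condition optional condition label to subset on.
#' @return Data frame with `segment`, `rmse_deg`, `n`.
#' @export
rmse_fc <- function(records, condition = NULL) {
  if (!is.null(condition)) {
    if (length(condition) == 1L && condition == "TM") {
      records <- records[startsWith(as.character(records$condition), "TM"), ]
    } else {
      records <- records[records$condition %in% condition, ]
    }
  }
  segs <- c("thigh", "shank", "foot")
  out <- lapply(segs, function(s) {
    a <- records[[paste0("theta_", s, "_fc")]]
    b <- records[[paste0("theta_", s, "_imu_fc")]]
    ok <- stats::complete.cases(a, b)
    if (sum(ok) == 0L) stop("no paired mocap/IMU angles for segment ", s)
    data.frame(segment = s, rmse_deg = sqrt(mean((b[ok] - a[ok])^2)),
               n = sum(ok))
  })
  do.call(rbind, out)
}

model_menu_grid <- function() {
  grid <- expand.grid(dependent = c("overstriding_norm", "pbf"),
                      condition = c("TM", "OG"),
                      source = c("mocap", "imu"),
                      stringsAsFactors = FALSE)
  grid$label <- sprintf("%s_%s_%s",
                        ifelse(grid$dependent == "pbf", "pbf", "os"),
                        tolower(grid$condition), grid$source)
  grid
}

#' Fit the standard eight-model menu
#'
#' Fits the random-intercept models relating overstriding and peak braking
#' force to the three sagittal FC angles, for treadmill and overground
#' conditions and for motion-capture and IMU angle sources (8 models). Inputs
#' are standardized as Z scores pooled within condition before fitting.
#' Optional reduced-predictor variants (thigh+shank; shank only; duty cycle
#' added) mirror common sensitivity analyses.
#'
#' @param records selected stride records.
#' @param reduced also fit the reduced / augmented IMU predictor sets.
#' @return A `stride_lmm_menu`: named list of `stride_lmm` fits with a `print`
#'   method that renders a coefficient/ICC/R-squared grid.
#' @export
run_model_menu <- function(records, reduced = FALSE) {
  records <- as.data.frame(records)
  records$cond_class <- ifelse(startsWith(as.character(records$condition), "TM"),
                               "TM", "OG")
  menu <- model_menu_grid()
  src_cols <- list(
    mocap = c("theta_thigh_fc", "theta_shank_fc", "theta_foot_fc"),
    imu = c("theta_thigh_imu_fc", "theta_shank_imu_fc", "theta_foot_imu_fc"))
  fits <- list()
  for (cond in c("TM", "OG")) {
    d <- records[records$cond_class == cond, , drop = FALSE]
    if (nrow(d) == 0L) next
    cols <- unique(c("overstriding_norm", "pbf", "duty_cycle",
                     unlist(src_cols)))
    z <- zscore_columns(d, intersect(cols, names(d)))$data
    try_fit <- function(label, dependent, predictors) {
      fits[[label]] <<- tryCatch(
        fit_stride_lmm(z, dependent, predictors),
        error = function(e) {
          warning(sprintf("skipping model %s: %s", label,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
    }
    for (i in which(menu$condition == cond)) {
      try_fit(menu$label[i], menu$dependent[i], src_cols[[menu$source[i]]])
    }
    if (reduced) {
      imu_ts <- src_cols$imu[1:2]
      try_fit(paste0("pbf_", tolower(cond), "_imu_thigh_shank"), "pbf", imu_ts)
      try_fit(paste0("pbf_", tolower(cond), "_imu_shank"), "pbf",
              src_cols$imu[2])
      try_fit(paste0("pbf_", tolower(cond), "_imu_duty"), "pbf",
              c(imu_ts, "duty_cycle"))
    }
  }
  structure(fits, class = "stride_lmm_menu")
}

#' @export
print.stride_lmm_menu <- function(x, digits = 2, ...) {
  cat("Random-intercept LMM menu (standardized inputs)\n")
  for (nm in names(x)) {
    f <- x[[nm]]
    cat(sprintf("\n[%s] %s ~ %s\n", nm, f$dependent,
                paste(f$fixed_effects, collapse = " + ")))
    for (i in seq_len(nrow(f$beta))) {
      b <- f$beta[i, ]
      cat(sprintf("  %-22s %6.2f [%5.2f, %5.2f]  p %s\n", b$term, b$estimate,
                  b$ci_low, b$ci_high,
                  ifelse(b$p_value < 0.001, "<0.001",
                         sprintf("%.3f", b$p_value))))
    }
    cat(sprintf("  ICC %.3f | marginal R2 %.3f | conditional R2 %.3f\n",
                f$icc, f$r2_marginal, f$r2_conditional))
  }
  invisible(x)
}
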
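# Allometric log10-log10 regression of ingestible plastic length on animal
# body length, with t-based confidence and prediction intervals. All model
# arithmetic happens on the log10 scale; lengths are back-transformed only
# at the reporting boundary.

new_allometric_fit <- function(slope, intercept, n, residual_sd, mean_x,
                               ss_x, r2, f_stat, p_value, response,
                               intervals_available = TRUE) {
  structure(
    list(
      slope = slope, intercept = intercept, n = as.integer(n),
      residual_sd = residual_sd, mean_x = mean_x, ss_x = ss_x,
      r2 = r2, f_stat = f_stat, p_value = p_value,
      response = response, intervals_available = intervals_available
    ),
    class = "allometric_fit"
  )
}

# Closed-form simple OLS on already-transformed coordinates; shared by
# fit_loglog() and the pooled observed-vs-predicted regression in the
# validation module. Optional case weights (weighted least squares).
ols_log10 <- function(x, y, w = NULL, response = "max_plastic") {
  n <- length(x)
  if (n < 3) insufficient_data("need at least 3 usable records to fit")
  if (is.null(w)) w <- rep(1, n)
  wm <- function(v) sum(w * v) / sum(w)
  mean_x <- wm(x)
  mean_y <- wm(y)
  ss_x <- sum(w * (x - mean_x)^2)
  if (ss_x <= 0) {
    insufficient_data("all body lengths identical; slope is undefined")
  }
  slope <- sum(w * (x - mean_x) * (y - mean_y)) / ss_x
  intercept <- mean_y - slope * mean_x
  resid <- y - (intercept + slope * x)
  sse <- sum(w * resid^2)
  sst <- sum(w * (y - mean_y)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  residual_sd <- sqrt(sse / (n - 2))
  f_stat <- if (r2 < 1) (n - 2) * r2 / (1 - r2) else Inf
  p_value <- stats::pf(f_stat, 1, n - 2, lower.tail = FALSE)
  new_allometric_fit(
    slope, intercept, n, residual_sd, mean_x, ss_x,
    r2, f_stat, p_value, response
  )
}

#' Fit the allometric size relationship
#'
#' Ordinary least squares of log10 plastic length on log10 body length, one
#' point per taxon. The response is the longest ingested plastic by default;
#' `response = "min_plastic"` fits the (much weaker) smallest-plastic
#' relationship instead, silently dropping records without a measurement.
#' The regression is unweighted by default; `weight_by_specimens = TRUE`
#' weights records by the number of specimens surveyed.
#'
#' @param taxa Taxon-record data.frame (see [generate_taxa()]).
#' @param response `"max_plastic"` or `"min_plastic"`.
#' @param weight_by_specimens Weight records by `n_specimens`?
#' @return An `allometric_fit`: slope, intercept (log10 mm), n, residual sd,
#'   predictor mean and centred sum of squares (for interval construction),
#'   R-squared, the F statistic on (1, n-2) df and its p-value.
#' @examples
#' fit <- fit_loglog(generate_taxa(generator_config(seed = 1)))
#' fit$slope
#' @export
fit_loglog <- function(taxa, response = c("max_plastic", "min_plastic"),
                       weight_by_specimens = FALSE) {
  response <- match.arg(response)
  col <- paste0(response, "_mm")
  if (!all(c("body_length_mm", col) %in% names(taxa))) {
    invalid_record(sprintf("taxon table lacks body_length_mm or %s", col))
  }
  keep <- !is.na(taxa[[col]]) & !is.na(taxa$body_length_mm)
  taxa <- taxa[keep, , drop = FALSE]
  bad <- which(taxa$body_length_mm <= 0 | taxa[[col]] <= 0)
  if (length(bad) > 0) {
    id <- if ("taxon_id" %in% names(taxa)) taxa$taxon_id[bad[1]] else bad[1]
    invalid_record(sprintf(
      "record '%s' has a nonpositive length; log10 undefined", id
    ))
  }
  w <- if (weight_by_specimens) as.numeric(taxa$n_specimens) else NULL
  ols_log10(log10(taxa$body_length_mm), log10(taxa[[col]]), w, response)
}

#' The canonical published allometric fit
#'
#' The fixed, literature-reported relationship
#' `plastic_mm = 10^(0.9341 * log10(body_mm) - 1.1200)` with n = 65 and
#' R-squared 0.42. Only the printed quantities are carried: the residual
#' standard deviation and predictor sufficient statistics were never
#' published, so this fit supports point predictions but refuses to
#' fabricate confidence or prediction intervals
#' (`intervals_available = FALSE`).
#'
#' @return An `allometric_fit` with interval statistics unavailable.
#' @examples
#' published_fit()$slope
#' @export
published_fit <- function() {
  new_allometric_fit(
    slope = 0.9341, intercept = -1.1200, n = 65,
    residual_sd = NA_real_, mean_x = NA_real_, ss_x = NA_real_,
    r2 = 0.42, f_stat = 46.06, p_value = 4.7e-09,
    response = "max_plastic", intervals_available = FALSE
  )
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat("Allometric log10-log10 fit (", x$response, ")\n", sep = "")
  cat(sprintf(
    "  plastic_mm = 10^(%.4f * log10(body_mm) %+.4f)\n",
    x$slope, x$intercept
  ))
  cat(sprintf(
    "  n = %d, R2 = %.3f, F(1,%d) = %.2f, p = %.3g\n",
    x$n, x$r2, x$n - 2L, x$f_stat, x$p_value
  ))
  if (!x$intervals_available) {
    cat("  (interval statistics unavailable: published coefficients only)\n")
  }
  invisible(x)
}

#' Predict ingestible plastic length from body length
#'
#' Point prediction `10^(slope * log10(body) + intercept)`, optionally with
#' a confidence interval (for the mean response) or a prediction interval
#' (for a new observation) from the standard t-based simple-regression
#' formulas, computed on the log10 scale and back-transformed endpoint-wise.
#'
#' Interval half-width on the log10 scale at predictor value x is
#' `t(1 - (1-level)/2, n-2) * residual_sd * sqrt(d + 1/n + (x - mean_x)^2 / ss_x)`
#' with `d = 0` for confidence and `d = 1` for prediction intervals.
#'
#' If intervals are requested from a fit that cannot supply them (the
#' published fit), a warning of class `plastisize_intervals_unavailable` is
#' signalled and the point prediction is returned with `NA` bounds.
#'
#' @param fit An `allometric_fit`.
#' @param body_length_mm Positive body length(s), mm.
#' @param level Interval level in (0, 1).
#' @param interval `"none"`, `"confidence"` or `"prediction"`.
#' @return A data.frame with columns `body_length_mm`, `point_mm`,
#'   `lower_mm`, `upper_mm`, `level`, `interval_kind`.
#' @examples
#' predict_plastic(published_fit(), 13.5)
#' @export
predict_plastic <- function(fit, body_length_mm, level = 0.95,
                            interval = c("none", "confidence", "prediction")) {
  interval <- match.arg(interval)
  if (!inherits(fit, "allometric_fit")) {
    invalid_parameter("`fit` must be an allometric_fit")
  }
  if (length(body_length_mm) < 1 || any(!is.finite(body_length_mm)) ||
    any(body_length_mm <= 0)) {
    invalid_parameter("`body_length_mm` must be positive and finite")
  }
  if (interval != "none" && (level <= 0 || level >= 1)) {
    invalid_parameter("`level` must be in (0, 1)")
  }
  x <- log10(body_length_mm)
  yhat <- fit$slope * x + fit$intercept
  lower <- upper <- rep(NA_real_, length(x))
  if (interval != "none") {
    if (!isTRUE(fit$intervals_available) || !is.finite(fit$residual_sd)) {
      warning(warningCondition(
        "fit carries published coefficients only; intervals unavailable, returning point predictions",
        class = "plastisize_intervals_unavailable"
      ))
      interval <- "none"
    } else {
      d <- if (interval == "prediction") 1 else 0
      tq <- stats::qt(1 - (1 - level) / 2, df = fit$n - 2)
      half <- tq * fit$residual_sd *
        sqrt(d + 1 / fit$n + (x - fit$mean_x)^2 / fit$ss_x)
      lower <- 10^(yhat - half)
      upper <- 10^(yhat + half)
    }
  }
  data.frame(
    body_length_mm = body_length_mm,
    point_mm = 10^yhat,
    lower_mm = lower,
    upper_mm = upper,
    level = if (interval == "none") NA_real_ else level,
    interval_kind = interval,
    stringsAsFactors = FALSE
  )
}

#' Body-length to ingestible-plastic size ratio
#'
#' Ratio of an animal's body length to the predicted longest ingestible
#' plastic, `10^((1 - slope) * log10(body) - intercept)`. Under the
#' published fit this is roughly 20:1 across the middle of the observed
#' body-length range.
#'
#' @inheritParams predict_plastic
#' @return Dimensionless ratio(s).
#' @examples
#' body_plastic_ratio(published_fit(), 305.1)
#' @export
body_plastic_ratio <- function(fit, body_length_mm) {
  if (any(!is.finite(body_length_mm)) || any(body_length_mm <= 0)) {
    invalid_parameter("`body_length_mm` must be positive and finite")
  }
  10^((1 - fit$slope) * log10(body_length_mm) - fit$intercept)
}

#' Serialise an allometric fit as flat key-value text
#'
#' Keys are exactly the fit's field names, one `key = value` per line, so
#' fits can be passed between pipeline stages as plain text.
#'
#' @param fit An `allometric_fit`.
#' @param path File path.
#' @return `path` invisibly, or the deserialised `allometric_fit`.
#' @export
write_fit <- function(fit, path) {
  num <- function(v) format(v, digits = 17, trim = TRUE)
  lines <- c(
    sprintf("slope = %s", num(fit$slope)),
    sprintf("intercept = %s", num(fit$intercept)),
    sprintf("n = %d", fit$n),
    sprintf("residual_sd = %s", num(fit$residual_sd)),
    sprintf("mean_x = %s", num(fit$mean_x)),
    sprintf("ss_x = %s", num(fit$ss_x)),
    sprintf("r2 = %s", num(fit$r2)),
    sprintf("f_stat = %s", num(fit$f_stat)),
    sprintf("p_value = %s", num(fit$p_value)),
    sprintf("response = %s", fit$response),
    sprintf("intervals_available = %s", fit$intervals_available)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) {
    invalid_parameter(sprintf("fit file not found: %s", path))
  }
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(trimws(lines))], "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  named <- stats::setNames(vals, keys)
  req <- c(
    "slope", "intercept", "n", "residual_sd", "mean_x", "ss_x",
    "r2", "f_stat", "p_value", "response", "intervals_available"
  )
  if (!all(req %in% keys)) {
    invalid_parameter(sprintf(
      "fit file missing fields: %s", paste(setdiff(req, keys), collapse = ", ")
    ))
  }
  new_allometric_fit(
    slope = as.numeric(named[["slope"]]),
    intercept = as.numeric(named[["intercept"]]),
    n = as.integer(named[["n"]]),
    residual_sd = as.numeric(named[["residual_sd"]]),
    mean_x = as.numeric(named[["mean_x"]]),
    ss_x = as.numeric(named[["ss_x"]]),
    r2 = as.numeric(named[["r2"]]),
    f_stat = as.numeric(named[["f_stat"]]),
    p_value = as.numeric(named[["p_value"]]),
    response = named[["response"]],
    intervals_available = as.logical(named[["intervals_available"]])
  )
}
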
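# Monte-Carlo hold-out validation of the allometric relationship: repeated
# random 90/10 splits, refit on the training part, predict the hold-out,
# pool all (predicted, observed) log10 pairs across repetitions.

#' Root mean square error
#'
#' `sqrt(mean((predicted - observed)^2))`. Both arguments are on whatever
#' scale the caller chooses; the validation pipeline uses log10 mm.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return Scalar RMSE.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0 || length(predicted) != length(observed)) {
    insufficient_data("rmse needs at least one (predicted, observed) pair")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Monte-Carlo hold-out validation of the allometric fit
#'
#' On each of `reps` repetitions a hold-out of `floor(holdout_fraction * n)`
#' records (or `ceiling`, if requested) is sampled without replacement, the
#' allometric relationship is refit on the remainder, and each hold-out
#' record is predicted with an interval at `level`. Pooled over all
#' repetitions the function reports the RMSE of predicted minus observed
#' log10 plastic lengths (and, separately labelled, on the raw mm scale),
#' the fraction of observations falling inside their intervals, and an OLS
#' regression of observed on predicted log10 values using the same engine
#' as [fit_loglog()].
#'
#' Interval kind matters: prediction intervals have nominal coverage for new
#' observations, while confidence intervals of the mean are far narrower and
#' cover far less than the nominal level — the choice reproduces two very
#' different coverage regimes, and both are first-class here.
#'
#' @param taxa Taxon-record data.frame.
#' @param reps Number of repetitions (>= 1).
#' @param holdout_fraction Fraction held out per repetition, in (0, 1).
#' @param level Interval level for the coverage statistic.
#' @param interval `"confidence"` or `"prediction"`.
#' @param holdout_size `"floor"` (default) or `"ceiling"` rounding of the
#'   hold-out count.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `validation_result` list: `rmse_log10`, `rmse_mm`, `coverage`,
#'   `pooled_r2`, `pooled_f`, `pooled_p`, `n_pairs`, and `pairs`, a
#'   long-format data.frame (rep, taxon_id, predicted/observed/lower/upper
#'   on the log10 scale, inside_interval).
#' @examples
#' taxa <- generate_taxa(generator_config(seed = 1))
#' monte_carlo_validate(taxa, reps = 10, seed = 1)
#' @export
monte_carlo_validate <- function(taxa,
                                 reps = 1000,
                                 holdout_fraction = 0.1,
                                 level = 0.95,
                                 interval = c("confidence", "prediction"),
                                 holdout_size = c("floor", "ceiling"),
                                 seed = NULL) {
  interval <- match.arg(interval)
  holdout_size <- match.arg(holdout_size)
  if (reps < 1) invalid_parameter("`reps` must be >= 1")
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    invalid_parameter("`holdout_fraction` must be in (0, 1)")
  }
  if (level <= 0 || level >= 1) invalid_parameter("`level` must be in (0, 1)")
  validate_taxa(taxa)
  n <- nrow(taxa)
  h <- as.integer(if (holdout_size == "floor") {
    floor(holdout_fraction * n)
  } else {
    ceiling(holdout_fraction * n)
  })
  if (h < 1) insufficient_data("hold-out would be empty; too few records")
  if (n - h < 3) insufficient_data("training split smaller than 3 records")

  with_seed(seed, {
    per_rep <- vector("list", reps)
    for (r in seq_len(reps)) {
      idx <- sample.int(n, h)
      fit <- fit_loglog(taxa[-idx, , drop = FALSE])
      pred <- predict_plastic(
        fit, taxa$body_length_mm[idx],
        level = level, interval = interval
      )
      obs <- log10(taxa$max_plastic_mm[idx])
      per_rep[[r]] <- data.frame(
        rep = r,
        taxon_id = taxa$taxon_id[idx],
        predicted = log10(pred$point_mm),
        observed = obs,
        lower = log10(pred$lower_mm),
        upper = log10(pred$upper_mm),
        inside_interval = obs >= log10(pred$lower_mm) &
          obs <= log10(pred$upper_mm),
        stringsAsFactors = FALSE
      )
    }
    pairs <- do.call(rbind, per_rep)
    pooled <- ols_log10(pairs$predicted, pairs$observed,
      response = "observed_vs_predicted"
    )
    structure(
      list(
        rmse_log10 = rmse(pairs$predicted, pairs$observed),
        rmse_mm = rmse(10^pairs$predicted, 10^pairs$observed),
        coverage = mean(pairs$inside_interval),
        pooled_r2 = pooled$r2,
        pooled_f = pooled$f_stat,
        pooled_p = pooled$p_value,
        n_pairs = nrow(pairs),
        reps = reps,
        holdout_n = h,
        level = level,
        interval_kind = interval,
        pairs = pairs
      ),
      class = "validation_result"
    )
  })
}

#' @export
print.validation_result <- function(x, ...) {
  cat("Monte-Carlo hold-out validation\n")
  cat(sprintf(
    "  %d reps x %d held out = %d pairs; %s intervals at %.0f%%\n",
    x$reps, x$holdout_n, x$n_pairs, x$interval_kind, 100 * x$level
  ))
  cat(sprintf(
    "  RMSE (log10 mm) = %.3f; coverage = %.2f%%\n",
    x$rmse_log10, 100 * x$coverage
  ))
  cat(sprintf(
    "  observed ~ predicted: R2 = %.3f, F(1,%d) = %.2f, p = %.3g\n",
    x$pooled_r2, x$n_pairs - 2L, x$pooled_f, x$pooled_p
  ))
  invisible(x)
}

#' Export a validation result
#'
#' `write_validation_summary()` writes a one-row delimited summary table;
#' `write_validation_pairs()` writes the long-format per-prediction table
#' (rep, taxon_id, predicted, observed, lower, upper, inside_interval, all
#' lengths on the log10 mm scale).
#'
#' @param result A `validation_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_validation_summary <- function(result, path) {
  summary_df <- data.frame(
    reps = result$reps, holdout_n = result$holdout_n,
    n_pairs = result$n_pairs, level = result$level,
    interval_kind = result$interval_kind,
    rmse_log10 = result$rmse_log10, rmse_mm = result$rmse_mm,
    coverage = result$coverage,
    pooled_r2 = result$pooled_r2, pooled_f = result$pooled_f,
    pooled_p = result$pooled_p
  )
  utils::write.csv(summary_df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_validation_summary
#' @export
write_validation_pairs <- function(result, path) {
  utils::write.csv(result$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
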
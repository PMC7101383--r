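# Shared fixtures and independent oracles.

# Minimal valid taxon table from raw body/plastic lengths (mm).
make_taxa <- function(body_mm, max_mm, min_mm = NA_real_) {
  n <- length(body_mm)
  data.frame(
    taxon_id = sprintf("t%02d", seq_len(n)),
    taxonomic_class = rep("fish", n),
    habitat = rep("marine", n),
    n_specimens = rep(1L, n),
    body_length_mm = body_mm,
    max_plastic_mm = max_mm,
    min_plastic_mm = rep_len(min_mm, n),
    depth_min_m = rep(0, n),
    depth_max_m = rep(100, n),
    latitude = rep(0, n),
    longitude = rep(0, n),
    microscope_used = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
}

# Independent OLS oracle: textbook normal equations via matrix solve,
# sharing no code with the package's closed-form path.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% beta
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  n <- length(y)
  r2 <- 1 - sse / sst
  list(
    intercept = beta[1], slope = beta[2], r2 = r2,
    residual_sd = sqrt(sse / (n - 2)),
    f_stat = (r2 / 1) / ((1 - r2) / (n - 2))
  )
}

# Sample R-squared of a plain y ~ x regression, for calibration checks.
sample_r2 <- function(x, y) {
  stats::cor(x, y)^2
}
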
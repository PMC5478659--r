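#' Raw-moment series along an accumulation
#'
#' Collects, at every accumulation step t, the raw moments of the log2
#' abundances up to a chosen order together with the species richness S(t)
#' and the abundance of the most abundant species N_max(t) — the three
#' ingredients whose power-law scaling drives the SAD forecast.
#'
#' @param acc a `"sad_accumulation"` (see [accumulate_sads()]), or a list of
#'   [abundance_vector()]s.
#' @param group which pooled group to take from an accumulation.
#' @param orders moment orders to track (default 1..10).
#' @param sizes sample sizes attached to the steps (default 1..T transects).
#' @return A `"moment_series"`: list with `sizes`, `orders`, `values` (matrix,
#'   orders x sizes), `richness`, `max_abundance`, `total_individuals` and
#'   `final_vector` (the pooled sample at the largest size, kept for
#'   reconstruction-order selection).
#' @seealso [fit_moment_scaling()], [forecast_sad()]
#' @export
moment_series <- function(acc, group = "all", orders = 1:10, sizes = NULL) {
  vectors <- if (inherits(acc, "sad_accumulation")) {
    if (!group %in% acc$groups) stop("group not present: ", group)
    lapply(acc$steps, `[[`, group)
  } else {
    lapply(acc, as_abundance_vector)
  }
  check_orders(orders)
  tt <- length(vectors)
  if (is.null(sizes)) sizes <- seq_len(tt)
  stopifnot(length(sizes) == tt)
  keep <- vapply(vectors, function(v) v$species_count > 0, TRUE)
  if (!any(keep)) stop("no non-empty samples in series")
  vectors <- vectors[keep]
  sizes <- sizes[keep]
  vals <- vapply(vectors, raw_moment, numeric(length(orders)), n = orders)
  vals <- matrix(vals, nrow = length(orders),
                 dimnames = list(paste0("M", orders), NULL))
  structure(
    list(sizes = sizes, orders = orders, values = vals,
         richness = vapply(vectors, `[[`, 0L, "species_count"),
         max_abundance = vapply(vectors, `[[`, 0L, "max_abundance"),
         total_individuals = vapply(vectors, `[[`, 0L, "total_individuals"),
         final_vector = vectors[[length(vectors)]]),
    class = "moment_series")
}

#' @export
print.moment_series <- function(x, ...) {
  cat("Moment series: orders", paste(range(x$orders), collapse = ".."),
      "over", length(x$sizes), "sample sizes; final S =",
      x$richness[length(x$richness)], "\n")
  invisible(x)
}

#' Fit a power law by least squares in log-log space
#'
#' Fits `log(value) = log_prefactor + exponent * log(size)` by OLS over the
#' chosen scaling region.  Natural logs are used internally; the exponent is
#' base-invariant.
#'
#' @param sizes positive sample sizes.
#' @param values positive response values.
#' @param range optional scaling region `c(min, max)` on `sizes` (inclusive);
#'   default uses all points.
#' @return A `"power_law_fit"`: `exponent`, `log_prefactor`, `r_squared`,
#'   `se` (named: intercept, exponent), `sizes`, `values`, `residuals`
#'   (log-space) and `fit_range`.
#' @examples
#' f <- fit_power_law(1:20, 2 * (1:20)^1.5)
#' c(f$exponent, exp(f$log_prefactor), f$r_squared)  # 1.5 2 1
#' @export
fit_power_law <- function(sizes, values, range = NULL) {
  stopifnot(length(sizes) == length(values))
  sel <- is.finite(sizes) & sizes > 0
  if (!is.null(range)) {
    stopifnot(length(range) == 2)
    sel <- sel & sizes >= range[1] & sizes <= range[2]
  }
  if (any(sel & !(is.finite(values) & values > 0))) {
    off <- sizes[sel & !(is.finite(values) & values > 0)]
    stop("nonpositive value(s) at size(s): ", paste(off, collapse = ", "))
  }
  if (sum(sel) < 3) stop("need at least 3 points in the scaling region")
  ls <- log(sizes[sel]); lv <- log(values[sel])
  fit <- lm(lv ~ ls)
  # summary.lm warns on exact power laws ("essentially perfect fit"); those
  # are a legitimate input here, not a modelling mistake
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  structure(
    list(exponent = unname(coef(fit)[2]),
         log_prefactor = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         se = c(intercept = unname(sm$coefficients[1, 2]),
                exponent = unname(sm$coefficients[2, 2])),
         sizes = sizes[sel], values = values[sel],
         residuals = unname(stats::residuals(fit)),
         fit_range = range(sizes[sel])),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Power law: value = %.4g * size^%.4g  (R^2 = %.4f, n = %d)\n",
              exp(x$log_prefactor), x$exponent, x$r_squared, length(x$sizes)))
  invisible(x)
}

#' Power-law scaling of a whole moment series
#'
#' Applies [fit_power_law()] to every raw-moment order of a
#' [moment_series()], and to the species richness S(t) and maximum abundance
#' N_max(t), which are needed to size the forecast.  The default scaling
#' region starts at 2 transects: single-transect pools sit below the
#' power-law regime.
#'
#' @param series a `"moment_series"`.
#' @param range scaling region on sizes, `c(min, max)`.
#' @return A `"moment_scaling"`: `moment_fits` (list, one
#'   `"power_law_fit"` per order, named `M1`, `M2`, ...), `richness_fit`,
#'   `max_abundance_fit`, `orders`, `range`.
#' @export
fit_moment_scaling <- function(series, range = c(2, Inf)) {
  stopifnot(inherits(series, "moment_series"))
  fits <- lapply(seq_along(series$orders), function(i) {
    if (series$orders[i] == 0) {
      # M_0 is identically 1: slope 0, prefactor 1, by definition
      f <- fit_power_law(series$sizes, rep(1, length(series$sizes)), range)
    } else {
      fit_power_law(series$sizes, series$values[i, ], range)
    }
  })
  names(fits) <- paste0("M", series$orders)
  structure(
    list(moment_fits = fits,
         richness_fit = fit_power_law(series$sizes, series$richness, range),
         max_abundance_fit = fit_power_law(series$sizes,
                                           series$max_abundance, range),
         orders = series$orders, range = range),
    class = "moment_scaling")
}

#' @export
print.moment_scaling <- function(x, ...) {
  cat("Moment scaling fits (log-log OLS):\n")
  df <- as.data.frame(x)
  print(df, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.moment_scaling <- function(x, ...) {
  all_fits <- c(x$moment_fits,
                list(S = x$richness_fit, N_max = x$max_abundance_fit))
  data.frame(
    quantity = names(all_fits),
    exponent = vapply(all_fits, `[[`, 0, "exponent"),
    log_prefactor = vapply(all_fits, `[[`, 0, "log_prefactor"),
    r_squared = vapply(all_fits, `[[`, 0, "r_squared"),
    se_exponent = vapply(all_fits, function(f) f$se[["exponent"]], 0),
    se_intercept = vapply(all_fits, function(f) f$se[["intercept"]], 0),
    row.names = NULL)
}

#' Residual diagnostics of a power-law fit
#'
#' Accumulated samples are not independent, so residuals of the log-log line
#' tend to oscillate.  This reports the log-space residual series and its
#' lag-1 autocorrelation coefficient as a compact diagnostic of that
#' dependence.
#'
#' @param fit a `"power_law_fit"`.
#' @return List with `residuals`, `sizes` and `lag1_autocorrelation`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "power_law_fit"))
  r <- fit$residuals
  if (length(r) < 3) stop("need at least 3 residuals")
  rc <- r - mean(r)
  denom <- sum(rc^2)
  ac1 <- if (denom > 0) sum(rc[-1] * rc[-length(rc)]) / denom else NA_real_
  list(residuals = r, sizes = fit$sizes, lag1_autocorrelation = ac1)
}

#' Extrapolate a fitted power law to a larger sample size
#'
#' Evaluates the fitted line at `target_size` on the natural scale.
#' Forecasting is kept deliberately short-range: a warning is issued beyond
#' four times the largest fitted size, where the power-law assumption is no
#' longer considered trustworthy.
#'
#' @param fit a `"power_law_fit"`.
#' @param target_size size(s) at which to predict; must be at least the
#'   largest fitted size (this is an extrapolation tool, not an interpolator).
#' @return Predicted value(s), always positive.
#' @export
extrapolate <- function(fit, target_size) {
  stopifnot(inherits(fit, "power_law_fit"))
  mx <- max(fit$sizes)
  if (any(target_size < mx * (1 - 1e-9)))
    stop("target_size must be >= the largest fitted size (", mx, ")")
  if (any(target_size > 4 * mx))
    warning("extrapolating beyond 4x the fitted sizes; ",
            "the power-law assumption is untested there")
  exp(fit$log_prefactor + fit$exponent * log(target_size))
}
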
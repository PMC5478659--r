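#' Forecast the SAD at a larger sample size
#'
#' Implements the moment-extrapolation forecast: fit the raw log2-abundance
#' moments, the species richness S(t) and the maximum abundance N_max(t) as
#' power laws of the number of transects; evaluate the fitted lines at the
#' target size; size the forecast support as
#' `floor(log2(N_max*)) + 1` octave classes; convert the extrapolated raw
#' moments (prepended with M_0 = 1) into Tchebichef moments; reconstruct the
#' class probabilities; and scale by the forecast richness S*.
#'
#' The number of moments actually used, k*, is chosen (unless given) by
#' reconstructing the *observed* largest-size histogram from the fitted
#' moments evaluated at the largest observed size, keeping the order that
#' minimises the squared histogram error ([select_order()]).  Higher orders
#' are prone to numerical instability once moments are extrapolated; if a
#' reconstruction clips more than half of its mass (or goes non-finite) the
#' order is lowered automatically and the event recorded in `$warnings`.
#'
#' @param series a [moment_series()].
#' @param factor multiple of the largest observed size to forecast to;
#'   2 and 4 are the supported design range (a warning is issued beyond 4,
#'   where the power laws are untested).  `factor = 1` reproduces the
#'   reconstruction at the largest observed size.
#' @param fits a [fit_moment_scaling()] result for `series`; computed with
#'   defaults when omitted.
#' @param k_star reconstruction order; chosen by [select_order()] if `NULL`.
#' @param k_max highest order considered when choosing `k_star`.
#' @return A `"sad_forecast"`: list with `factor`, `target_size`,
#'   `richness` (S*), `max_abundance` (N_max*), `num_classes`,
#'   `class_counts` (S* x reconstructed probabilities), `proportions`,
#'   `order_used`, `clipped_mass` and `warnings`.
#' @seealso [forecast_ensemble()] for across-ordering means and bands.
#' @export
forecast_sad <- function(series, factor = 2, fits = NULL,
                         k_star = NULL, k_max = 6L) {
  stopifnot(inherits(series, "moment_series"))
  if (factor < 1) stop("factor must be >= 1")
  if (is.null(fits)) fits <- fit_moment_scaling(series)
  warn <- character(0)
  if (factor > 4) {
    warn <- c(warn, sprintf(
      "forecast factor %g exceeds the supported range (up to 4)", factor))
    warning(warn[length(warn)])
  }
  t_max <- max(series$sizes)
  target <- factor * t_max
  pos <- series$orders > 0
  ords <- series$orders[pos]
  if (!identical(as.integer(ords), seq_len(length(ords))))
    stop("series must carry contiguous moment orders 1..m")
  ext_at <- function(size) vapply(fits$moment_fits[pos], extrapolate, 0,
                                  target_size = size)

  s_star <- extrapolate(fits$richness_fit, target)
  nmax_star <- extrapolate(fits$max_abundance_fit, target)
  nb_obs <- floor(log2(series$max_abundance[length(series$max_abundance)])) + 1
  nb_star <- as.integer(floor(log2(nmax_star)) + 1)
  if (nb_star < nb_obs)
    stop("forecast support (", nb_star,
         " classes) smaller than observed (", nb_obs, ")")

  if (is.null(k_star)) {
    k_sel <- min(k_max, nb_obs - 1L, length(ords))
    basis_obs <- tchebichef_basis(nb_obs, k_sel)
    emp <- bin_abundances(series$final_vector)
    m_hat <- c(1, ext_at(t_max))
    k_star <- as.integer(select_order(emp, m_hat, basis_obs, k_sel))
  }
  k_use <- min(k_star, nb_star - 1L, length(ords))

  m_star <- c(1, ext_at(target))
  # power-mean inequality M_n^(1/n) nondecreasing in n must survive
  # extrapolation; a violation flags incompatible fitted exponents
  r <- m_star[-1]^(1 / seq_along(m_star[-1]))
  if (any(diff(r) < -1e-8 * pmax(1, r[-1]))) {
    warn <- c(warn, "extrapolated moments violate the power-mean inequality")
    warning(warn[length(warn)])
  }
  basis <- tchebichef_basis(nb_star, max(k_use, 1L))
  repeat {
    Tm <- tcheb_moments_from_raw(m_star[1:(k_use + 1L)], basis)
    p <- tryCatch(tcheb_reconstruct(Tm, basis), error = function(e) NULL)
    ok <- !is.null(p) && all(is.finite(p)) &&
      attr(p, "clipped_mass") <= 0.5
    if (ok || k_use <= 1L) break
    warn <- c(warn, sprintf(
      "reconstruction unstable at order %d; falling back to %d",
      k_use, k_use - 1L))
    k_use <- k_use - 1L
  }
  if (is.null(p)) stop("reconstruction failed at every order")
  structure(
    list(factor = factor, target_size = target,
         richness = s_star, max_abundance = nmax_star,
         num_classes = nb_star,
         class_counts = s_star * as.vector(p),
         proportions = as.vector(p),
         order_used = k_use,
         order_selected = k_star,
         clipped_mass = attr(p, "clipped_mass"),
         warnings = warn),
    class = "sad_forecast")
}

#' @export
print.sad_forecast <- function(x, ...) {
  cat(sprintf(
    "SAD forecast to %gx (size %g): S* = %.1f, N_max* = %.0f, %d classes, order %d\n",
    x$factor, x$target_size, x$richness, x$max_abundance,
    x$num_classes, x$order_used))
  print(round(x$class_counts, 2))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, "\n"))
  invisible(x)
}

#' @export
as_binned_sad <- function(x) UseMethod("as_binned_sad")

#' @export
as_binned_sad.sad_forecast <- function(x) binned_sad(x$class_counts)

#' @export
as_binned_sad.binned_sad <- function(x) x

#' Forecast ensemble over all transect orderings
#'
#' Runs the full forecast once per starting transect (T transects give T
#' orderings of the chosen spatial method), then averages the forecasted
#' per-class species counts across orderings, reporting mean, SD and a
#' mean +/- 2 SD band per class.  The reconstruction order is selected
#' independently for each ordering; histograms of differing support are
#' zero-padded on the right before averaging.
#'
#' @param tab a `"transect_table"`.
#' @param factor forecast factor (see [forecast_sad()]).
#' @param group dispersal group (`"high"`, `"low"` or `"all"`).
#' @param method transect ordering method.
#' @param orders moment orders carried in the series.
#' @param range scaling region passed to [fit_moment_scaling()].
#' @param k_max highest reconstruction order considered.
#' @return A `"sad_forecast_ensemble"`: `mean_counts`, `sd_counts`, `lower`,
#'   `upper` per octave class, `richness` (mean S*), `orders_used` (k* per
#'   ordering), `n_orderings`, `factor`, plus all per-ordering forecasts in
#'   `$forecasts`.
#' @export
forecast_ensemble <- function(tab, factor = 2, group = "all",
                              method = c("concentric", "sequential"),
                              orders = 1:10, range = c(2, Inf),
                              k_max = 6L) {
  stopifnot(inherits(tab, "transect_table"))
  method <- match.arg(method)
  order_fun <- if (method == "concentric") order_concentric else order_sequential
  ids <- sort(unique(tab$transect))
  if (length(ids) < 3) stop("need at least 3 transects to fit and forecast")
  fcs <- lapply(ids, function(id) {
    acc <- accumulate_sads(tab, order_fun(tab, id), groups = group)
    ser <- moment_series(acc, group = group, orders = orders)
    fits <- fit_moment_scaling(ser, range = range)
    forecast_sad(ser, factor = factor, fits = fits, k_max = k_max)
  })
  nb <- max(vapply(fcs, `[[`, 0L, "num_classes"))
  counts <- t(vapply(fcs, function(f)
    c(f$class_counts, rep(0, nb - f$num_classes)), numeric(nb)))
  m <- colMeans(counts)
  s <- apply(counts, 2, sd)
  structure(
    list(factor = factor, group = group, method = method,
         classes = 0:(nb - 1L),
         mean_counts = m, sd_counts = s,
         lower = m - 2 * s, upper = m + 2 * s,
         richness = mean(vapply(fcs, `[[`, 0, "richness")),
         orders_used = vapply(fcs, `[[`, 0L, "order_used"),
         n_orderings = length(fcs),
         forecasts = fcs),
    class = "sad_forecast_ensemble")
}

#' @export
print.sad_forecast_ensemble <- function(x, ...) {
  cat(sprintf(
    "SAD forecast ensemble (%s, %s group): %dx, %d orderings, mean S* = %.1f\n",
    x$method, x$group, x$factor, x$n_orderings, x$richness))
  df <- data.frame(class = x$classes, mean = round(x$mean_counts, 2),
                   sd = round(x$sd_counts, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @rdname forecast_ensemble
#' @param x a `"sad_forecast_ensemble"`.
#' @param path file path.
#' @param delim field delimiter.
#' @export
write_forecast <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "sad_forecast_ensemble"))
  df <- data.frame(class_index = x$classes,
                   mean_species = x$mean_counts,
                   sd_species = x$sd_counts)
  write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}
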
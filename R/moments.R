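#' Moments of the log2 abundance distribution
#'
#' The shape of a SAD is summarised by the moments of the log2-transformed
#' abundances x_j.  With S species, the raw moment of order n is
#' \deqn{M_n = \frac{1}{S} \sum_{j=1}^{S} x_j^n,}
#' the central moment is \eqn{C_n = \frac{1}{S}\sum_j (x_j - \bar x)^n} with
#' \eqn{\bar x = M_1}, and the standardized moment is
#' \eqn{T_n = \frac{1}{S}\sum_j ((x_j - \bar x)/\sigma_x)^n} with
#' \eqn{\sigma_x = \sqrt{C_2}}.  All divisors are S (population convention,
#' no Bessel correction).  The skewness is \eqn{T_3}: positive for a
#' distribution piled against the left (singleton-rich, long right tail),
#' zero for a symmetric one.
#'
#' @param v an [abundance_vector()] (or bare abundances) with at least one
#'   species.
#' @param n vector of nonnegative integer orders.
#' @return Numeric vector of moments, one per order in `n`.
#'   `standardized_moment()` returns `NA` when \eqn{\sigma_x = 0} (all
#'   abundances equal): the moment is undefined there and is flagged rather
#'   than silently zeroed.
#' @examples
#' v <- abundance_vector(c(1, 1, 8))
#' raw_moment(v, 1:3)
#' central_moment(v, 2)       # population variance of log2 abundances
#' sad_skewness(v)            # +1/sqrt(2)
#' @export
raw_moment <- function(v, n) {
  v <- as_abundance_vector(v)
  check_orders(n)
  if (v$species_count == 0L) stop("moments of an empty sample are undefined")
  x <- v$log2_abundances
  vapply(n, function(k) mean(x^k), 0)
}

check_orders <- function(n) {
  if (length(n) == 0 || anyNA(n) || any(n < 0) || any(n != floor(n)))
    stop("moment order(s) must be nonnegative integers")
  invisible(n)
}

#' @rdname raw_moment
#' @export
central_moment <- function(v, n) {
  v <- as_abundance_vector(v)
  check_orders(n)
  if (v$species_count == 0L) stop("moments of an empty sample are undefined")
  x <- v$log2_abundances
  d <- x - mean(x)
  vapply(n, function(k) mean(d^k), 0)
}

#' @rdname raw_moment
#' @export
standardized_moment <- function(v, n) {
  v <- as_abundance_vector(v)
  check_orders(n)
  if (v$species_count == 0L) stop("moments of an empty sample are undefined")
  x <- v$log2_abundances
  d <- x - mean(x)
  s <- sqrt(mean(d^2))
  if (s == 0) return(rep(NA_real_, length(n)))
  vapply(n, function(k) mean((d / s)^k), 0)
}

#' @rdname raw_moment
#' @export
sad_skewness <- function(v) standardized_moment(v, 3L)

#' Moments of a binned SAD over its class indices
#'
#' Treats the octave histogram itself as a discrete distribution on the class
#' indices 0..NB-1 and computes its moments weighted by the class proportions
#' p_i: the raw moment is \eqn{M_n = \sum_i p_i\, i^n}.  On this support the
#' Tchebichef reconstruction of the histogram from its moments is exact, which
#' is what makes moment-based forecasting of binned SADs possible.  The
#' standardized version gives, e.g., the skewness of a forecasted (bin-level)
#' SAD for which per-species abundances no longer exist.
#'
#' @param b a `"binned_sad"` (see [bin_abundances()]) with at least one class.
#' @param n vector of nonnegative integer orders.
#' @return Numeric vector of moments.  `binned_standardized_moment()` returns
#'   `NA` for a degenerate (single positive class) histogram.
#' @examples
#' b <- binned_sad(c(2, 1, 1))
#' binned_raw_moment(b, 0:2)
#' binned_standardized_moment(binned_sad(c(2, 0, 1)), 3)  # +1/sqrt(2)
#' @export
binned_raw_moment <- function(b, n) {
  stopifnot(inherits(b, "binned_sad"))
  check_orders(n)
  if (b$num_classes < 1L) stop("moments of an empty histogram are undefined")
  if (b$species_count <= 0) stop("histogram has no species")
  i <- seq_len(b$num_classes) - 1
  vapply(n, function(k) sum(b$proportions * i^k), 0)
}

#' @rdname binned_raw_moment
#' @export
binned_standardized_moment <- function(b, n) {
  stopifnot(inherits(b, "binned_sad"))
  check_orders(n)
  if (b$num_classes < 1L) stop("moments of an empty histogram are undefined")
  if (b$species_count <= 0) stop("histogram has no species")
  i <- seq_len(b$num_classes) - 1
  mu <- sum(b$proportions * i)
  v2 <- sum(b$proportions * (i - mu)^2)
  if (v2 <= 0) return(rep(NA_real_, length(n)))
  s <- sqrt(v2)
  vapply(n, function(k) sum(b$proportions * ((i - mu) / s)^k), 0)
}

#' Full moment summary of a sample
#'
#' @param v an [abundance_vector()] or bare abundances.
#' @param n_max highest order to report.
#' @return A `"moment_summary"`: raw, central and standardized moments for
#'   orders 0..`n_max`, plus `mean`, `sd` and `skewness`.
#' @examples
#' moment_summary(c(1, 2, 4, 4, 16), n_max = 4)
#' @export
moment_summary <- function(v, n_max = 10L) {
  v <- as_abundance_vector(v)
  n <- 0:n_max
  structure(
    list(orders = n,
         raw = raw_moment(v, n),
         central = central_moment(v, n),
         standardized = standardized_moment(v, n),
         mean = raw_moment(v, 1L),
         sd = sqrt(central_moment(v, 2L)),
         skewness = sad_skewness(v)),
    class = "moment_summary")
}

#' @export
print.moment_summary <- function(x, digits = 4, ...) {
  cat("Moments of log2 abundances (population convention)\n")
  cat("  mean =", format(x$mean, digits = digits),
      " sd =", format(x$sd, digits = digits),
      " skewness =", format(x$skewness, digits = digits), "\n")
  m <- rbind(raw = x$raw, central = x$central, standardized = x$standardized)
  colnames(m) <- paste0("n=", x$orders)
  print(round(m, digits))
  invisible(x)
}
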
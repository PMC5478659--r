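#' Orthonormal discrete Tchebichef polynomial basis
#'
#' Builds the scaled (orthonormal) discrete Tchebichef polynomials t_n(x) on
#' the integer support `x = 0..N-1`, the natural support for an octave SAD
#' with N abundance classes.  The basis satisfies
#' \eqn{\sum_x t_m(x) t_n(x) = \delta_{mn}} and is generated by the stable
#' three-term recurrence
#' \deqn{t_0(x) = 1/\sqrt{N}, \quad
#'       t_1(x) = (2x + 1 - N)\sqrt{3/(N(N^2-1))},}
#' \deqn{t_n(x) = (\alpha_1 x + \alpha_2)\, t_{n-1}(x) - \alpha_3\, t_{n-2}(x)}
#' with
#' \eqn{\alpha_1 = \frac{2}{n}\sqrt{\frac{4n^2-1}{N^2-n^2}}},
#' \eqn{\alpha_2 = \frac{1-N}{n}\sqrt{\frac{4n^2-1}{N^2-n^2}}},
#' \eqn{\alpha_3 = \frac{n-1}{n}\sqrt{\frac{2n+1}{2n-3}}
#'       \sqrt{\frac{N^2-(n-1)^2}{N^2-n^2}}}.
#'
#' Alongside the tabulated values, the monomial coefficients c_{n,k} with
#' \eqn{t_n(x) = \sum_k c_{n,k} x^k} are carried through the recurrence: they
#' convert ordinary raw moments into Tchebichef moments by linearity, which is
#' what lets a SAD be rebuilt from *extrapolated* moments.
#'
#' @param N support size (number of octave classes), `N >= 2`.
#' @param max_order highest polynomial order, `1 <= max_order < N`.
#' @return A `"tchebichef_basis"`: list with `N`, `max_order`, `values`
#'   (matrix, orders 0..max_order in rows, x = 0..N-1 in columns) and
#'   `coeffs` (lower-triangular matrix of monomial coefficients, row n,
#'   column k+1 holding c_{n,k}).
#' @examples
#' b <- tchebichef_basis(8, 5)
#' max(abs(b$values %*% t(b$values) - diag(6)))  # ~1e-15
#' @seealso [tcheb_moments()], [tcheb_reconstruct()]
#' @export
tchebichef_basis <- function(N, max_order = min(N - 1L, 12L)) {
  N <- as.integer(N)
  max_order <- as.integer(max_order)
  if (N < 2) stop("support size N must be at least 2")
  if (max_order < 1 || max_order >= N)
    stop("max_order must satisfy 1 <= max_order < N")
  x <- 0:(N - 1)
  vals <- matrix(0, max_order + 1L, N)
  coefs <- matrix(0, max_order + 1L, max_order + 1L)
  vals[1, ] <- 1 / sqrt(N)
  coefs[1, 1] <- 1 / sqrt(N)
  s1 <- sqrt(3 / (N * (N^2 - 1)))
  vals[2, ] <- (2 * x + 1 - N) * s1
  coefs[2, 1:2] <- c((1 - N) * s1, 2 * s1)
  if (max_order >= 2) for (n in 2:max_order) {
    a1 <- (2 / n) * sqrt((4 * n^2 - 1) / (N^2 - n^2))
    a2 <- ((1 - N) / n) * sqrt((4 * n^2 - 1) / (N^2 - n^2))
    a3 <- ((n - 1) / n) * sqrt((2 * n + 1) / (2 * n - 3)) *
      sqrt((N^2 - (n - 1)^2) / (N^2 - n^2))
    vals[n + 1, ] <- (a1 * x + a2) * vals[n, ] - a3 * vals[n - 1, ]
    cprev <- coefs[n, ]
    coefs[n + 1, ] <- a2 * cprev - a3 * coefs[n - 1, ] +
      a1 * c(0, cprev[-(max_order + 1L)])
  }
  # the recurrence drifts from orthonormality as n approaches N (about 2e-8
  # already at N = 32, full order); one QR re-orthonormalization restores it
  # to machine precision while leaving low orders essentially untouched
  qrq <- qr.Q(qr(t(vals)))
  sgn <- sign(colSums(qrq * t(vals)))
  vals <- t(sweep(qrq, 2, sgn, "*"))
  structure(list(N = N, max_order = max_order,
                 values = vals, coeffs = coefs),
            class = "tchebichef_basis")
}

#' @export
print.tchebichef_basis <- function(x, ...) {
  cat("Orthonormal discrete Tchebichef basis on {0..", x$N - 1,
      "}, orders 0..", x$max_order, "\n", sep = "")
  invisible(x)
}

#' Tchebichef moments of a discrete distribution
#'
#' \eqn{T_n = \sum_x p(x)\, t_n(x)} for the probabilities `p` on the basis
#' support.
#'
#' @param p probability vector on `0..N-1` (must sum to 1).
#' @param basis a [tchebichef_basis()] with matching `N`.
#' @return Numeric vector `T_0..T_max_order`.
#' @export
tcheb_moments <- function(p, basis) {
  stopifnot(inherits(basis, "tchebichef_basis"))
  if (length(p) != basis$N)
    stop("length of p (", length(p), ") must equal basis support N (",
         basis$N, ")")
  if (abs(sum(p) - 1) > 1e-8) stop("p must sum to 1")
  drop(basis$values %*% p)
}

#' Tchebichef moments from raw (power) moments
#'
#' Uses the monomial expansion of the basis polynomials:
#' \eqn{T_n = \sum_k c_{n,k} M_k}, where \eqn{M_k} are raw moments on the
#' class-index support (with \eqn{M_0 = 1}).  For moments computed from an
#' actual distribution on the support this agrees with [tcheb_moments()] to
#' rounding error; in the forecast it is fed *extrapolated* moments instead.
#'
#' @param raw numeric vector `M_0, M_1, ..., M_m` with `M_0 = 1` and
#'   `m <= max_order` of the basis.
#' @param basis a [tchebichef_basis()].
#' @return Numeric vector `T_0..T_m`.
#' @export
tcheb_moments_from_raw <- function(raw, basis) {
  stopifnot(inherits(basis, "tchebichef_basis"))
  m <- length(raw) - 1L
  if (m < 0) stop("raw must contain at least M_0")
  if (m >= basis$N)
    stop("number of raw moments must be smaller than the support size")
  if (m > basis$max_order)
    stop("raw moments exceed the basis max_order (", basis$max_order, ")")
  if (abs(raw[1] - 1) > 1e-6) stop("M_0 must equal 1")
  drop(basis$coeffs[1:(m + 1L), 1:(m + 1L), drop = FALSE] %*% raw)
}

#' Reconstruct a distribution from its Tchebichef moments
#'
#' \eqn{\hat p(x) = \sum_{n \le k} T_n t_n(x)}.  With all `N` moments the
#' reconstruction is exact; truncation at lower order gives the least-squares
#' projection onto the first polynomials and can produce small negative
#' values, which are clipped to zero and the result renormalised (the clipped
#' mass is reported as an instability indicator).
#'
#' @param T numeric vector `T_0..T_k`, `k < N`.
#' @param basis a [tchebichef_basis()] with `max_order >= k`.
#' @param clip clip negatives and renormalise (default `TRUE`); set `FALSE`
#'   to obtain the raw projection.
#' @return Probability vector on `0..N-1`, with attributes `order` (k) and,
#'   when clipping, `clipped_mass` (total negative mass removed).
#' @export
tcheb_reconstruct <- function(T, basis, clip = TRUE) {
  stopifnot(inherits(basis, "tchebichef_basis"))
  k <- length(T) - 1L
  if (k < 0 || k > basis$max_order)
    stop("need 1..max_order+1 Tchebichef moments")
  p <- drop(crossprod(basis$values[1:(k + 1L), , drop = FALSE], T))
  if (clip) {
    clipped <- -sum(p[p < 0])
    p[p < 0] <- 0
    s <- sum(p)
    if (s <= 0) stop("reconstruction degenerate: no positive mass")
    p <- p / s
    attr(p, "clipped_mass") <- clipped
  }
  attr(p, "order") <- k
  p
}

#' Choose the reconstruction order against an empirical histogram
#'
#' Scans orders `k = 1..k_max` and returns the one minimising the sum of
#' squared differences between the empirical class counts and the
#' reconstructed counts `S * p_hat_k`, where the Tchebichef moments come from
#' the supplied (typically power-law-fitted) raw moments.  Ties go to the
#' smaller order, so an exactly representable histogram is matched at the
#' lowest sufficient order.
#'
#' @param empirical a `"binned_sad"` whose `num_classes` equals the basis
#'   support, or a bare vector of class counts of that length.
#' @param raw_moments `M_0, M_1, ...` with at least `k_max + 1` entries.
#' @param basis a [tchebichef_basis()].
#' @param k_max highest order to consider (`< N`).
#' @return Integer `k*`, with attribute `sse` giving the error at each k.
#' @export
select_order <- function(empirical, raw_moments, basis, k_max) {
  counts <- if (inherits(empirical, "binned_sad"))
    empirical$class_counts else as.numeric(empirical)
  stopifnot(inherits(basis, "tchebichef_basis"))
  if (length(counts) != basis$N)
    stop("empirical histogram must have exactly the basis support size")
  S <- sum(counts)
  if (S <= 0) stop("degenerate empirical histogram")
  k_max <- as.integer(k_max)
  if (k_max < 1 || k_max >= basis$N || k_max > basis$max_order)
    stop("k_max must satisfy 1 <= k_max < N and k_max <= basis max_order")
  if (length(raw_moments) < k_max + 1L)
    stop("need raw moments up to order k_max")
  sse <- vapply(1:k_max, function(k) {
    Tm <- tcheb_moments_from_raw(raw_moments[1:(k + 1L)], basis)
    p <- tcheb_reconstruct(Tm, basis)
    sum((counts - S * p)^2)
  }, 0)
  best <- min(sse)
  tol <- best * 1e-8 + 1e-10 * S^2 * .Machine$double.eps
  k_star <- which(sse <= best + tol)[1]
  structure(as.integer(k_star), sse = sse)
}
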
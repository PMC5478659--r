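# Shared fixtures, generated once per test run and memoised.
# The simulator pair contrasts only the dispersal kernel: "high" dispersal is
# the well-mixed (global) parent draw, "low" is a gaussian kernel of sigma = 1
# cell, at the desk-scale defaults (L = 256, 200 generations, nu = 1e-3).

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

fx_land_low <- function(seed = 42) {
  memo(paste0("low", seed),
       run_neutral_sim(L = 256, kernel = "gaussian", sigma = 1,
                       generations = 200, seed = seed))
}

fx_land_high <- function(seed = 43) {
  memo(paste0("high", seed),
       run_neutral_sim(L = 256, kernel = "global",
                       generations = 200, seed = seed))
}

# merged two-community transect table; 32 windows is a survey comparable to
# the larger island campaigns
fx_table <- function(n_transects = 32) {
  memo(paste0("tab", n_transects),
       landscape_to_transects(fx_land_high(), fx_land_low(),
                              n_transects = n_transects, seed = 7))
}

# small hand-positioned table: 4 transects on a line, known species content
fx_line_table <- function() {
  df <- expand.grid(transect = c("A", "B", "C", "D"),
                    species = c("s1", "s2", "s3"),
                    stringsAsFactors = FALSE)
  df$site <- "s"
  df$x <- c(0, 2, -2.5, 3)[match(df$transect, c("A", "B", "C", "D"))]
  df$y <- 0
  df$abundance <- seq_len(nrow(df))
  df$dispersal <- ifelse(df$species == "s3", "low", "high")
  as_transect_table(df)
}

# random abundance vector with a spread of magnitudes
rand_abund <- function(n, max_log = 10) {
  pmax(1L, as.integer(round(2^runif(n, 0, max_log))))
}

# random histogram (class counts) on nb classes, at least one species
rand_hist <- function(nb, max_count = 50) {
  repeat {
    h <- rpois(nb, lambda = runif(1, 0.5, max_count / 2))
    if (sum(h) > 0) return(h)
  }
}

# projection of p onto polynomials of degree <= k on 0..N-1, via QR of the
# Vandermonde matrix: an oracle for Tchebichef reconstruction that never
# touches the package's basis code
poly_project <- function(p, k) {
  N <- length(p)
  V <- outer(0:(N - 1), 0:k, `^`)
  Q <- qr.Q(qr(V))
  drop(Q %*% crossprod(Q, p))
}
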
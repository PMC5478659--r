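# Spatially explicit neutral simulator and its sampling utilities

test_that("simulation is zero-sum, deterministic, and validates its config", {
  a <- run_neutral_sim(L = 32, generations = 10, seed = 5)
  b <- run_neutral_sim(L = 32, generations = 10, seed = 5)
  expect_identical(unclass(a)[, ], unclass(b)[, ])
  expect_equal(dim(a), c(32, 32))
  expect_false(any(is.na(a)))          # every cell occupied at all times
  expect_error(run_neutral_sim(L = 100), "power of 2")
  expect_error(run_neutral_sim(L = 32, speciation = 2), "\\[0, 1\\]")
})

test_that("speciation extremes reach their absorbing compositions", {
  # nu = 1: every replacement is a new species; after enough events every
  # individual is its own species
  land <- run_neutral_sim(L = 8, speciation = 1, kernel = "global",
                          generations = ceiling(log(64) * 3) + 5, seed = 1)
  expect_equal(length(unique(as.vector(land))), 64)
  # nu = 0: neutral drift on a small grid fixes to monodominance
  land0 <- run_neutral_sim(L = 8, speciation = 0, kernel = "nearest",
                           generations = 3000, seed = 2)
  expect_equal(length(unique(as.vector(land0))), 1)
})

test_that("square samples average octave histograms over exact tiles", {
  land <- run_neutral_sim(L = 64, generations = 30, seed = 11)
  # whole landscape: one sample, equal to direct binning
  b <- sample_squares(land, 6)
  expect_equal(attr(b, "n_tiles"), 1)
  direct <- bin_abundances(as.vector(table(as.vector(land))))
  expect_equal(b$class_counts, direct$class_counts)
  # monodominant landscape: single class at floor(log2(side^2))
  mono <- matrix(1L, 16, 16)
  bm <- sample_squares(mono, 2)
  expect_equal(which(bm$class_counts > 0), floor(log2(16)) + 1)
  expect_equal(bm$class_counts[floor(log2(16)) + 1], 1)
  expect_error(sample_squares(mono, 5), "exceeds")
})

test_that("tile averages equal direct enumeration on a known composition", {
  set.seed(4)
  land <- matrix(sample(1:9, 64 * 64, replace = TRUE), 64, 64)
  b <- sample_squares(land, 4)
  k <- 4; side <- 2^k; nt <- 64 / side
  accum <- NULL
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    v <- land[((i - 1) * side + 1):(i * side), ((j - 1) * side + 1):(j * side)]
    h <- bin_abundances(as.vector(table(v)))$class_counts
    n <- max(length(h), length(accum))
    accum <- c(accum, rep(0, n - length(accum))) +
      c(h, rep(0, n - length(h)))
  }
  expect_equal(b$class_counts, (accum / nt^2)[seq_along(b$class_counts)])
})

test_that("low dispersal aggregates in space and humps the SAD earlier", {
  # join-count aggregation and SAD mode onset contrasted over 10 seeds at
  # desk scale (L = 128)
  adjacency_same <- function(land) {
    m <- unclass(land)
    mean(m == m[c(2:nrow(m), 1), ])
  }
  agg_lo <- agg_hi <- sing_lo <- sing_hi <- mode_lo <- mode_hi <- numeric(10)
  for (s in 1:10) {
    lo <- run_neutral_sim(L = 128, kernel = "gaussian", sigma = 1,
                          generations = 200, seed = 1000 + s)
    hi <- run_neutral_sim(L = 128, kernel = "global",
                          generations = 200, seed = 2000 + s)
    agg_lo[s] <- adjacency_same(lo)
    agg_hi[s] <- adjacency_same(hi)
    bl <- sample_squares(lo, 4)
    bh <- sample_squares(hi, 4)
    sing_lo[s] <- bl$proportions[1]
    sing_hi[s] <- bh$proportions[1]
    mode_lo[s] <- interior_mode_scale(lo, 2:7)
    mode_hi[s] <- interior_mode_scale(hi, 2:7)
  }
  expect_gt(mean(agg_lo), mean(agg_hi))       # spatial aggregation
  expect_gt(mean(sing_hi), mean(sing_lo))     # singleton retention
  expect_true(all(mode_lo <= mode_hi))        # earlier interior mode
  expect_gt(mean(mode_hi == Inf | mode_hi > mode_lo), 0.5)
})

test_that("richness trace supports the stationarity check", {
  land <- run_neutral_sim(L = 64, generations = 50, seed = 3)
  tr <- attr(land, "richness_trace")
  expect_length(tr, 50)
  expect_true(is.logical(richness_stationary(land)))
})

test_that("transect windows contain what the landscapes contain", {
  lo <- run_neutral_sim(L = 128, kernel = "gaussian", generations = 50,
                        seed = 21)
  hi <- run_neutral_sim(L = 128, kernel = "global", generations = 50,
                        seed = 22)
  tab <- landscape_to_transects(hi, lo, n_transects = 10, seed = 3)
  tab2 <- landscape_to_transects(hi, lo, n_transects = 10, seed = 3)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  expect_equal(length(unique(tab$transect)), 10)
  expect_true(all(tab$dispersal[startsWith(tab$species, "H")] == "high"))
  # containment: per-species window totals cannot exceed landscape totals
  land_tot <- table(as.vector(lo))
  win <- tapply(tab$abundance[tab$dispersal == "low"],
                sub("^L", "", tab$species[tab$dispersal == "low"]), sum)
  expect_true(all(win <= land_tot[names(win)]))
  # windows are disjoint: total sampled cells equal windows x window area
  expect_equal(sum(tab$abundance), 2 * 10 * 15 * 5)
  expect_error(landscape_to_transects(hi, lo, n_transects = 300), "disjoint")
})

test_that("whole-grid single window reproduces the landscape composition", {
  lo <- run_neutral_sim(L = 32, kernel = "gaussian", generations = 30,
                        seed = 31)
  hi <- run_neutral_sim(L = 32, kernel = "global", generations = 30,
                        seed = 32)
  tab <- landscape_to_transects(hi, lo, n_transects = 1,
                                transect_cells = c(32, 32), seed = 1)
  win_lo <- sort(tab$abundance[tab$dispersal == "low"])
  expect_equal(win_lo, sort(as.vector(table(as.vector(lo)))))
})

test_that("landscape round-trips through delimited text", {
  land <- run_neutral_sim(L = 16, generations = 5, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_landscape(land, f)
  land2 <- read_landscape(f)
  expect_equal(unclass(land)[, ], unclass(land2)[, ])
  unlink(f)
})
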
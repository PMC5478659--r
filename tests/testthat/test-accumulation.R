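# Spatial orderings, pooled accumulation, skewness trajectories

test_that("concentric ordering sorts by distance from the start", {
  tab <- fx_line_table()  # A(0), B(2), C(-2.5), D(3) on a line
  expect_equal(order_concentric(tab, "A"), c("A", "B", "C", "D"))
  # collinear monotone case
  df <- data.frame(transect = c("t0", "t1", "t3", "t7"), site = "s",
                   x = c(0, 1, 3, 7), y = 0, species = "sp",
                   abundance = 1, dispersal = "high")
  tb <- as_transect_table(df)
  expect_equal(order_concentric(tb, "t0"), c("t0", "t1", "t3", "t7"))
  expect_equal(order_sequential(tb, "t0"), c("t0", "t1", "t3", "t7"))
  expect_error(order_concentric(tab, "Z"), "unknown start")
})

test_that("sequential ordering chains nearest neighbours greedily", {
  tab <- fx_line_table()
  # from B(2) the nearest remaining is D(3) at distance 1, not C(-2.5)
  expect_equal(order_sequential(tab, "A"), c("A", "B", "D", "C"))
})

test_that("orderings are permutations sharing the start transect", {
  tab <- fx_table()
  ids <- sort(unique(tab$transect))
  for (s in ids[c(1, 5, 17)]) {
    oc <- order_concentric(tab, s)
    os <- order_sequential(tab, s)
    expect_equal(sort(oc), ids)
    expect_equal(sort(os), ids)
    expect_equal(oc[1], s)
    expect_equal(os[1], s)
  }
})

test_that("accumulation pools abundances additively", {
  df <- data.frame(transect = rep(c("a", "b", "c"), each = 1), site = "s",
                   x = 1:3, y = 0, species = "sp", abundance = 2,
                   dispersal = "high")
  tab <- as_transect_table(df)
  acc <- accumulate_sads(tab, c("a", "b", "c"), groups = "high")
  expect_equal(vapply(acc$steps, function(s) s$high$abundances, 0L),
               c(2L, 4L, 6L))
  # disjoint species sets: richness adds up
  df2 <- data.frame(transect = rep(c("a", "b"), c(2, 3)), site = "s",
                    x = rep(1:2, c(2, 3)), y = 0,
                    species = paste0("sp", 1:5), abundance = 1,
                    dispersal = "low")
  acc2 <- accumulate_sads(as_transect_table(df2), c("a", "b"), groups = "low")
  expect_equal(acc2$steps[[1]]$low$species_count, 2L)
  expect_equal(acc2$steps[[2]]$low$species_count, 5L)
  expect_error(accumulate_sads(tab, c("a", "b")), "permutation")
})

test_that("pooled totals match an independent group-by aggregation", {
  tab <- fx_table()
  ids <- sort(unique(tab$transect))
  acc <- accumulate_sads(tab, order_concentric(tab, ids[3]),
                         groups = c("high", "low"))
  t_mid <- 11
  first <- acc$ordering[seq_len(t_mid)]
  sub <- as.data.frame(tab)[tab$transect %in% first, ]
  for (g in c("high", "low")) {
    oracle <- aggregate(abundance ~ species, sub[sub$dispersal == g, ], sum)
    got <- sort(acc$steps[[t_mid]][[g]]$abundances)
    expect_equal(got, sort(oracle$abundance))
  }
  # monotone invariants along the trajectory
  tot <- vapply(acc$steps, function(s) s$high$total_individuals, 0L)
  rich <- vapply(acc$steps, function(s) s$high$species_count, 0L)
  expect_true(all(diff(tot) >= 0))
  expect_true(all(diff(rich) >= 0))
})

test_that("final pooled sample is ordering- and method-independent", {
  tab <- fx_table()
  ids <- sort(unique(tab$transect))
  accA <- accumulate_sads(tab, order_concentric(tab, ids[1]), "all")
  accB <- accumulate_sads(tab, order_sequential(tab, ids[9]), "all")
  last <- length(ids)
  expect_equal(sort(accA$steps[[last]]$all$abundances),
               sort(accB$steps[[last]]$all$abundances))
})

test_that("skewness trajectory averages exactly one ordering per transect", {
  tab <- fx_table()
  sk <- skewness_trajectory(tab, method = "concentric")
  tt <- length(unique(tab$transect))
  expect_equal(max(sk$t), tt)
  # at the final step every ordering pools the same sample: SD must be 0
  fin <- sk[sk$t == tt, ]
  expect_equal(fin$sd, rep(0, nrow(fin)), tolerance = 1e-12)
  expect_true(all(fin$n + fin$n_excluded == tt))
  expect_equal(fin$upper - fin$lower, 4 * fin$sd)
})

test_that("identical transects give zero skewness spread at every step", {
  df <- do.call(rbind, lapply(1:4, function(i)
    data.frame(transect = paste0("t", i), site = "s", x = i, y = 0,
               species = paste0("sp", 1:5),
               abundance = c(1, 1, 2, 4, 9), dispersal = "high")))
  sk <- skewness_trajectory(as_transect_table(df), groups = "high")
  expect_equal(sk$sd, rep(0, nrow(sk)), tolerance = 1e-12)
  # pooling multiplies abundances by t, which only shifts log2 values:
  # the skewness is unchanged at every step
  expect_equal(sk$mean, rep(sad_skewness(c(1, 1, 2, 4, 9)), 4),
               tolerance = 1e-9)
})

test_that("simulated high-dispersal SADs are more skewed than low at intermediate sizes", {
  sk <- skewness_trajectory(fx_table(), method = "concentric")
  mid <- sk$t %in% 8:16
  m <- tapply(sk$mean[mid], sk$group[mid], mean, na.rm = TRUE)
  expect_gt(m[["high"]], m[["low"]])
})

test_that("dispersal label perturbation is deterministic and bounded", {
  tab <- fx_table()
  expect_identical(perturb_dispersal_labels(tab, 0)$dispersal, tab$dispersal)
  flipped <- perturb_dispersal_labels(tab, 1)
  expect_true(all(flipped$dispersal != tab$dispersal))
  a <- perturb_dispersal_labels(tab, 0.1, seed = 99)
  b <- perturb_dispersal_labels(tab, 0.1, seed = 99)
  expect_identical(a, b)
  spp_flipped <- unique(a$species[a$dispersal != tab$dispersal])
  expect_equal(length(spp_flipped),
               round(0.1 * length(unique(tab$species))))
  expect_error(perturb_dispersal_labels(tab, 1.5), "fraction")
})
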
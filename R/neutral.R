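#' Spatially explicit neutral community simulation
#'
#' Runs a zero-sum neutral community on an `L x L` torus with one individual
#' per cell.  Starting from a single species, each event kills a uniformly
#' chosen individual; with probability `speciation` the vacancy is taken by a
#' never-seen species (point speciation), otherwise by the offspring of a
#' parent drawn from the dispersal kernel centred on the vacant cell.  One
#' generation is `L^2` events.  All individuals share the same demographic
#' rates regardless of species — the only ecological contrast available is
#' the dispersal kernel:
#'
#' * `"global"` — parent drawn uniformly from the whole lattice
#'   (well-mixed; the *high* dispersal ability archetype),
#' * `"gaussian"` — isotropic discretised Gaussian of width `sigma` cells,
#'   renormalised on the torus (*low* dispersal when `sigma` is ~1 cell),
#' * `"nearest"` — uniform over the 4-neighbourhood.
#'
#' Defaults target desk-scale experiments: `L = 256`, 200 generations,
#' `speciation = 1e-3` (a few hundred species at equilibrium pace).
#' Runs are deterministic given `seed`.
#'
#' @param L lattice side; must be a power of 2 so that nested square samples
#'   of side `2^k` tile the landscape exactly.
#' @param speciation per-birth speciation probability, in `[0, 1]`.
#' @param kernel dispersal kernel of the community.
#' @param sigma Gaussian kernel width in cells.
#' @param generations number of generations (`L^2` events each).
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @return An integer `L x L` matrix of species ids of class `"landscape"`,
#'   with attributes `kernel`, `sigma`, `speciation`, `generations` and
#'   `richness_trace` (species richness at the end of each generation).
#' @examples
#' land <- run_neutral_sim(L = 64, generations = 20, seed = 1)
#' length(unique(as.vector(land)))
#' @seealso [sample_squares()], [landscape_to_transects()]
#' @export
run_neutral_sim <- function(L = 256L, speciation = 1e-3,
                            kernel = c("gaussian", "global", "nearest"),
                            sigma = 1, generations = 200L, seed = NULL) {
  kernel <- match.arg(kernel)
  L <- as.integer(L)
  if (L < 2 || bitwAnd(L, L - 1L) != 0L)
    stop("L must be a power of 2 (nested square samples must tile exactly)")
  kcode <- match(kernel, c("global", "gaussian", "nearest")) - 1L
  land <- with_seed(seed,
    .neutral_sim_cpp(L, speciation, kcode, sigma, as.integer(generations)))
  structure(land, class = c("landscape", class(land)),
            kernel = kernel, sigma = sigma, speciation = speciation,
            generations = as.integer(generations))
}

#' @export
print.landscape <- function(x, ...) {
  cat("Neutral landscape", nrow(x), "x", ncol(x), "(", attr(x, "kernel"),
      "kernel ),", length(unique(as.vector(x))), "species\n")
  invisible(x)
}

#' Has species richness stabilised?
#'
#' Burn-in adequacy check: the relative change of species richness over the
#' last `window` generations must fall below `tol`.
#'
#' @param land a [run_neutral_sim()] landscape.
#' @param window trailing generations compared.
#' @param tol relative-change threshold.
#' @return Logical.
#' @export
richness_stationary <- function(land, window = 10L, tol = 0.01) {
  tr <- attr(land, "richness_trace")
  if (is.null(tr) || length(tr) <= window) return(FALSE)
  now <- tr[length(tr)]
  then <- tr[length(tr) - window]
  abs(now - then) / max(then, 1) < tol
}

# octave class counts of one abundance vector, padded to nb classes
bin_counts <- function(abund, nb) {
  tabulate(floor(log2(abund)) + 1L, nbins = nb)
}

#' Average octave SAD over all square samples of one size
#'
#' Cuts the landscape into all disjoint `2^k x 2^k` tiles, bins each tile's
#' species abundances into octave classes, and averages the class counts
#' across tiles (shorter histograms padded with zeros).  This is the
#' sample-size axis of the simulation experiment: growing `k` plays the role
#' of growing area.
#'
#' @param land a [run_neutral_sim()] landscape (or integer species matrix).
#' @param k square side is `2^k`; `2^k` must not exceed the lattice side.
#' @return A `"binned_sad"` with (generally fractional) averaged class
#'   counts, plus attribute `n_tiles`.
#' @export
sample_squares <- function(land, k) {
  L <- nrow(land)
  side <- 2^k
  if (side > L) stop("2^k exceeds the landscape side")
  nt <- L %/% side
  nb_max <- floor(log2(side^2)) + 1L
  acc <- numeric(nb_max)
  for (i in seq_len(nt)) {
    rows <- ((i - 1L) * side + 1L):(i * side)
    for (j in seq_len(nt)) {
      v <- land[rows, ((j - 1L) * side + 1L):(j * side)]
      ab <- rle(sort.int(as.vector(v)))$lengths
      acc <- acc + bin_counts(ab, nb_max)
    }
  }
  avg <- acc / nt^2
  while (length(avg) > 1 && avg[length(avg)] == 0)
    avg <- avg[-length(avg)]
  b <- binned_sad(avg)
  attr(b, "n_tiles") <- nt^2
  b
}

#' Sample-size at which the SAD develops an interior mode
#'
#' Scans square sizes `2^k` in increasing order and reports the first at
#' which the tile-averaged SAD has its maximum away from the singleton
#' class — the transition from a monotonically decreasing (logseries-like)
#' SAD to a humped one.  Low-dispersal (aggregated) communities make this
#' transition at smaller sample sizes.
#'
#' @param land a landscape.
#' @param ks candidate values of `k` (square side `2^k`), increasing.
#' @return The smallest `2^k` (the square side) with an interior mode, or
#'   `Inf` if none in range.
#' @export
interior_mode_scale <- function(land, ks = 2:7) {
  for (k in sort(ks)) {
    b <- sample_squares(land, k)
    if (which.max(b$class_counts) > 1L) return(2^k)
  }
  Inf
}

#' Cut transect-like windows out of simulated landscapes
#'
#' Bridges the simulator to the field-data pipeline: places `n_transects`
#' disjoint rectangular windows at random positions (common to both
#' communities, as if the same field campaign surveyed both) and records the
#' per-window species abundances of a high-dispersal landscape and a
#' low-dispersal landscape as a single merged [as_transect_table()] table.
#' Window centres become the transect coordinates (cell units); species ids
#' are prefixed `H`/`L` and labelled with the corresponding dispersal class.
#' The elongated default window mimics a field transect.
#'
#' @param land_high landscape simulated with the high-dispersal kernel.
#' @param land_low landscape simulated with the low-dispersal kernel (same
#'   side).
#' @param n_transects number of windows.
#' @param transect_cells window size as `c(width, height)` in cells.
#' @param seed integer seed for window placement.
#' @return A `"transect_table"`.
#' @export
landscape_to_transects <- function(land_high, land_low, n_transects = 32L,
                                   transect_cells = c(15L, 5L), seed = 1L) {
  L <- nrow(land_high)
  if (nrow(land_low) != L || ncol(land_low) != L || ncol(land_high) != L)
    stop("the two landscapes must be square and of equal side")
  w <- as.integer(transect_cells[1]); h <- as.integer(transect_cells[2])
  if (w < 1 || h < 1 || w > L || h > L) stop("invalid window size")
  occ <- matrix(FALSE, L, L)
  pos <- with_seed(seed, {
    out <- vector("list", n_transects)
    tries <- 0L
    for (i in seq_len(n_transects)) {
      repeat {
        tries <- tries + 1L
        if (tries > 1000L * n_transects)
          stop("could not place ", n_transects, " disjoint windows")
        r <- sample.int(L - h + 1L, 1L)
        cc <- sample.int(L - w + 1L, 1L)
        if (!any(occ[r:(r + h - 1L), cc:(cc + w - 1L)])) {
          occ[r:(r + h - 1L), cc:(cc + w - 1L)] <- TRUE
          out[[i]] <- c(r, cc)
          break
        }
      }
    }
    out
  })
  one <- function(i, land, prefix, cls) {
    r <- pos[[i]][1]; cc <- pos[[i]][2]
    v <- land[r:(r + h - 1L), cc:(cc + w - 1L)]
    sp <- sort(unique(as.vector(v)))
    ab <- tabulate(match(as.vector(v), sp))
    data.frame(transect = sprintf("T%03d", i), site = "sim",
               x = cc + (w - 1) / 2, y = r + (h - 1) / 2,
               species = paste0(prefix, sp), abundance = ab,
               dispersal = cls, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, c(
    lapply(seq_len(n_transects), one, land = land_high,
           prefix = "H", cls = "high"),
    lapply(seq_len(n_transects), one, land = land_low,
           prefix = "L", cls = "low")))
  as_transect_table(df)
}

#' Write / read a landscape as a delimited integer grid
#'
#' @param land a landscape matrix.
#' @param path file path.
#' @param delim field delimiter.
#' @export
write_landscape <- function(land, path, delim = ",") {
  write.table(unclass(land), path, sep = delim,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path, delim = ",") {
  m <- as.matrix(read.table(path, sep = delim, header = FALSE))
  dimnames(m) <- NULL
  structure(m, class = c("landscape", class(m)))
}
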
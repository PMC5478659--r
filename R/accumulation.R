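#' Spatial orderings of transects
#'
#' Two ways of turning a set of georeferenced transects into a sequence along
#' which samples accumulate, so that adding transects proxies increasing area
#' and sampling effort:
#'
#' * **concentric** — from the start transect, take the nearest one, then the
#'   second nearest, and so on (distances always measured from the start).
#' * **sequential** — a greedy nearest-neighbour chain: from the start take
#'   the nearest, then the transect nearest to *that* one, and so on.
#'
#' Distances are Euclidean between transect centres; ties are broken by
#' ascending transect id so orderings are reproducible.
#'
#' @param tab a `"transect_table"` (see [read_transect_table()]).
#' @param start id of the starting transect.
#' @return Character vector of transect ids, a permutation of the unique ids
#'   in `tab`, starting with `start`.
#' @examples
#' df <- data.frame(transect = c("A", "B", "C", "D"), site = "s",
#'                  x = c(0, 2, -2.5, 3), y = 0,
#'                  species = "sp1", abundance = 1, dispersal = "high")
#' tab <- as_transect_table(df)
#' order_concentric(tab, "A")  # A B C D
#' order_sequential(tab, "A")  # A B D C
#' @export
order_concentric <- function(tab, start) {
  xy <- transect_coords(tab)
  i0 <- match(as.character(start), xy$transect)
  if (is.na(i0)) stop("unknown start transect: ", start)
  d <- sqrt((xy$x - xy$x[i0])^2 + (xy$y - xy$y[i0])^2)
  ord <- xy$transect[order(d, xy$transect)]
  # a co-located transect with a smaller id must not displace the start
  c(xy$transect[i0], setdiff(ord, xy$transect[i0]))
}

#' @rdname order_concentric
#' @export
order_sequential <- function(tab, start) {
  xy <- transect_coords(tab)
  ids <- xy$transect
  i0 <- match(as.character(start), ids)
  if (is.na(i0)) stop("unknown start transect: ", start)
  n <- length(ids)
  out <- character(n)
  remaining <- rep(TRUE, n)
  cur <- i0
  for (k in seq_len(n)) {
    out[k] <- ids[cur]
    remaining[cur] <- FALSE
    if (k == n) break
    d <- sqrt((xy$x - xy$x[cur])^2 + (xy$y - xy$y[cur])^2)
    d[!remaining] <- Inf
    cand <- which(d == min(d))
    cur <- cand[order(ids[cand])][1]
  }
  out
}

#' Accumulate pooled SADs along an ordering of transects
#'
#' At step t the abundances of each species are summed over the first t
#' transects of `ordering`, separately for the high and low dispersal groups
#' (and optionally for all species combined).
#'
#' @param tab a `"transect_table"`.
#' @param ordering permutation of the transect ids (see [order_concentric()]).
#' @param groups which pooled groups to carry: any of `"high"`, `"low"`,
#'   `"all"`.
#' @return A `"sad_accumulation"`: list with `ordering`, `groups`, and
#'   `steps`, where `steps[[t]][[g]]` is the pooled [abundance_vector()] of
#'   group `g` after `t` transects.
#' @export
accumulate_sads <- function(tab, ordering,
                            groups = c("high", "low", "all")) {
  stopifnot(inherits(tab, "transect_table"))
  groups <- match.arg(groups, several.ok = TRUE)
  ids <- sort(unique(tab$transect))
  ordering <- as.character(ordering)
  if (!identical(sort(ordering), ids))
    stop("ordering must be a permutation of the transect ids")
  rows_by_tr <- split(seq_len(nrow(tab)), tab$transect)
  pools <- setNames(vector("list", length(groups)), groups)
  for (g in groups) pools[[g]] <- numeric(0)
  steps <- vector("list", length(ordering))
  for (t in seq_along(ordering)) {
    rows <- rows_by_tr[[ordering[t]]]
    for (g in groups) {
      sel <- if (g == "all") rows else rows[tab$dispersal[rows] == g]
      if (length(sel)) {
        add <- tapply(tab$abundance[sel], tab$species[sel], sum)
        pool <- pools[[g]]
        known <- names(add) %in% names(pool)
        pool[names(add)[known]] <- pool[names(add)[known]] + add[known]
        pools[[g]] <- c(pool, add[!known])
      }
    }
    steps[[t]] <- lapply(pools, function(p) abundance_vector(as.vector(p)))
  }
  structure(list(ordering = ordering, groups = groups, steps = steps),
            class = "sad_accumulation")
}

#' @export
print.sad_accumulation <- function(x, ...) {
  cat("SAD accumulation over", length(x$ordering), "transects; groups:",
      paste(x$groups, collapse = ", "), "\n")
  invisible(x)
}

#' Skewness of the SAD as transects accumulate
#'
#' Runs the chosen ordering from every transect in turn (T transects give
#' exactly T orderings), pools the sample after each added transect, and
#' summarises the skewness of the log2 abundance distribution at every step
#' by its mean and standard deviation over orderings.  The reported band
#' `lower`/`upper` is mean +/- 2 SD.  Steps at which a pooled sample is
#' degenerate (fewer than two distinct abundances, skewness undefined) are
#' excluded from the mean and counted in `n_excluded`.
#'
#' @param tab a `"transect_table"`.
#' @param method `"concentric"` (default, the reporting standard) or
#'   `"sequential"`; the two are typically near-identical.
#' @param groups dispersal groups to trace.
#' @return A data frame of class `"skewness_trajectory"` with columns
#'   `group`, `t` (number of transects), `mean`, `sd`, `lower`, `upper`,
#'   `n` (orderings with defined skewness) and `n_excluded`.
#' @export
skewness_trajectory <- function(tab, method = c("concentric", "sequential"),
                                groups = c("high", "low")) {
  stopifnot(inherits(tab, "transect_table"))
  method <- match.arg(method)
  groups <- match.arg(groups, c("high", "low", "all"), several.ok = TRUE)
  ids <- sort(unique(tab$transect))
  if (length(ids) < 2) stop("need at least two transects")
  order_fun <- if (method == "concentric") order_concentric else order_sequential
  tt <- length(ids)
  sk <- array(NA_real_, dim = c(tt, tt, length(groups)),
              dimnames = list(NULL, NULL, groups))
  for (s in seq_along(ids)) {
    acc <- accumulate_sads(tab, order_fun(tab, ids[s]), groups = groups)
    for (t in seq_len(tt)) for (g in groups) {
      v <- acc$steps[[t]][[g]]
      if (v$species_count >= 2) sk[s, t, g] <- sad_skewness(v)
    }
  }
  out <- do.call(rbind, lapply(groups, function(g) {
    m <- apply(sk[, , g, drop = FALSE], 2, mean, na.rm = TRUE)
    s2 <- apply(sk[, , g, drop = FALSE], 2, sd, na.rm = TRUE)
    n <- apply(!is.na(sk[, , g, drop = FALSE]), 2, sum)
    s2[n < 2] <- 0
    m[n == 0] <- NA_real_
    data.frame(group = g, t = seq_len(tt), mean = m, sd = s2,
               lower = m - 2 * s2, upper = m + 2 * s2,
               n = n, n_excluded = tt - n)
  }))
  rownames(out) <- NULL
  attr(out, "method") <- method
  class(out) <- c("skewness_trajectory", "data.frame")
  out
}

#' Randomly flip dispersal labels of a fraction of species
#'
#' Sensitivity tool for dispersal-ability misclassification: flips the
#' dispersal class (`high` <-> `low`) of `round(fraction * S)` species chosen
#' uniformly without replacement, deterministically for a given seed.
#'
#' @param tab a `"transect_table"`.
#' @param fraction fraction of species to flip, in `[0, 1]`.
#' @param seed integer seed (the caller's RNG stream is left untouched).
#' @return A `"transect_table"` with perturbed labels.
#' @export
perturb_dispersal_labels <- function(tab, fraction, seed = 1L) {
  stopifnot(inherits(tab, "transect_table"))
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]")
  spp <- sort(unique(tab$species))
  k <- round(fraction * length(spp))
  if (k > 0) {
    flip <- with_seed(seed, sample(spp, k))
    sel <- tab$species %in% flip
    tab$dispersal[sel] <- ifelse(tab$dispersal[sel] == "high", "low", "high")
  }
  tab
}
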
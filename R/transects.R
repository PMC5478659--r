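#' Read a transect sample table
#'
#' Ingests the delimited format used throughout the package: one row per
#' (transect, species) pair with columns `transect`, `site`, `x`, `y`,
#' `species`, `abundance` and `dispersal` (values `"high"` or `"low"`).
#' Coordinates are planar metres by default; with `coords = "lonlat"` the
#' `x`/`y` columns are taken as longitude/latitude in degrees and projected on
#' ingest with a small-region equirectangular projection (adequate at the
#' few-km extent of a transect network).
#'
#' Duplicated (transect, species) rows are summed with a notice; a species
#' listed with more than one dispersal class is an error, as are nonpositive
#' abundances or unparsable coordinates (reported with their row numbers).
#'
#' @param path path to the delimited file (header row required).
#' @param delim field delimiter (default comma; use `"\t"` for TSV).
#' @param coords `"planar"` (metres) or `"lonlat"` (degrees, projected).
#' @return A `"transect_table"`: a validated data frame with the columns
#'   above, coordinates in metres.
#' @seealso [as_transect_table()], [write_transect_table()],
#'   [order_concentric()], [skewness_trajectory()]
#' @export
read_transect_table <- function(path, delim = ",",
                                coords = c("planar", "lonlat")) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- read.table(path, sep = delim, header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  as_transect_table(df, coords = coords)
}

#' Validate a data frame as a transect table
#'
#' @param df data frame with columns `transect`, `site`, `x`, `y`, `species`,
#'   `abundance`, `dispersal`.
#' @inheritParams read_transect_table
#' @return A `"transect_table"`.
#' @export
as_transect_table <- function(df, coords = c("planar", "lonlat")) {
  coords <- match.arg(coords)
  req <- c("transect", "site", "x", "y", "species", "abundance", "dispersal")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df <- df[req]
  if (nrow(df) == 0) stop("transect table has no rows")

  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    stop("unparsable coordinates at row(s): ", paste(bad, collapse = ", "))
  ab <- suppressWarnings(as.numeric(df$abundance))
  bad <- which(!is.finite(ab) | ab < 1 | ab != floor(ab))
  if (length(bad))
    stop("abundance must be a positive integer; offending row(s): ",
         paste(bad, collapse = ", "))
  df$abundance <- as.integer(ab)
  df$dispersal <- tolower(as.character(df$dispersal))
  bad <- which(!df$dispersal %in% c("high", "low"))
  if (length(bad))
    stop("dispersal must be 'high' or 'low'; offending row(s): ",
         paste(bad, collapse = ", "))
  df$transect <- as.character(df$transect)
  df$species <- as.character(df$species)
  df$site <- as.character(df$site)

  ncl <- tapply(df$dispersal, df$species, function(z) length(unique(z)))
  if (any(ncl > 1))
    stop("species with inconsistent dispersal class: ",
         paste(names(ncl)[ncl > 1], collapse = ", "))

  if (coords == "lonlat") {
    rad <- pi / 180
    r_earth <- 6371000
    phi0 <- mean(df$y) * rad
    df$x <- r_earth * cos(phi0) * df$x * rad
    df$y <- r_earth * df$y * rad
  }

  key <- paste(df$transect, df$species, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    message("summing ", ndup, " duplicated (transect, species) row(s)")
    ab <- tapply(df$abundance, key, sum)
    df <- df[!duplicated(key), ]
    df$abundance <- as.integer(ab[paste(df$transect, df$species, sep = "\r")])
  }
  # one coordinate per transect id: keep the first, but flag conflicts
  xy <- unique(df[c("transect", "x", "y")])
  if (anyDuplicated(xy$transect))
    stop("transect(s) with conflicting coordinates: ",
         paste(unique(xy$transect[duplicated(xy$transect)]), collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("transect_table", "data.frame")
  df
}

#' @rdname read_transect_table
#' @param tab a `"transect_table"`.
#' @export
write_transect_table <- function(tab, path, delim = ",") {
  stopifnot(inherits(tab, "transect_table"))
  write.table(as.data.frame(tab), path, sep = delim,
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

# id -> (x, y) lookup for the unique transects, sorted by id
transect_coords <- function(tab) {
  xy <- unique(as.data.frame(tab)[c("transect", "x", "y")])
  xy[order(xy$transect), ]
}

#' Per-island survey summary of the Azorean arthropod transects
#'
#' Published per-island totals for the BALA arthropod survey of the Azorean
#' laurisilva (99 transects of 150 m x 5 m across seven islands): number of
#' transects and, for the high and low dispersal ability species groups,
#' numbers of individuals and of species.  The island rows sum exactly to the
#' published archipelago totals of 99 transects, 76664 high-dispersal and
#' 25864 low-dispersal individuals; the species columns do not sum across
#' islands because species are shared among them (archipelago totals: 235
#' high, 102 low).
#'
#' @return A data frame with columns `island`, `transects`,
#'   `individuals_high`, `species_high`, `individuals_low`, `species_low`.
#' @examples
#' tab <- azores_island_summary()
#' sum(tab$transects)        # 99
#' sum(tab$individuals_high) # 76664
#' @export
azores_island_summary <- function() {
  path <- system.file("extdata", "azores_island_summary.csv",
                      package = "sadscale", mustWork = TRUE)
  read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
}
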
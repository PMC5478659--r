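#' Abundance vector of one pooled sample
#'
#' Bundles the per-species abundances of a sample with their log2 transforms,
#' which are the working scale for all moment computations: class boundaries
#' of the octave SAD are powers of two, so log2 puts one abundance class per
#' unit interval.
#'
#' @param abundances integer vector, one entry per species, every entry >= 1.
#'   An empty vector is allowed and yields an empty sample.
#' @return An object of class `"abundance_vector"`: a list with elements
#'   `abundances`, `log2_abundances`, `species_count`, `total_individuals`
#'   and `max_abundance` (`0` for an empty sample).
#' @examples
#' v <- abundance_vector(c(1, 1, 2, 3, 4, 7, 8))
#' v$species_count
#' bin_abundances(v)
#' @seealso [bin_abundances()], [raw_moment()]
#' @export
abundance_vector <- function(abundances) {
  if (length(abundances) == 0) {
    return(structure(
      list(abundances = integer(0), log2_abundances = numeric(0),
           species_count = 0L, total_individuals = 0L, max_abundance = 0L),
      class = "abundance_vector"))
  }
  if (anyNA(abundances) || !is.numeric(abundances))
    stop("abundances must be numeric and non-missing")
  if (any(abundances < 1) || any(abundances != floor(abundances)))
    stop("abundances must be positive integers (>= 1)")
  abundances <- as.integer(round(abundances))
  structure(
    list(abundances = abundances,
         log2_abundances = log2(abundances),
         species_count = length(abundances),
         total_individuals = as.integer(sum(abundances)),
         max_abundance = max(abundances)),
    class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat("Abundance vector:", x$species_count, "species,",
      x$total_individuals, "individuals, N_max =", x$max_abundance, "\n")
  invisible(x)
}

as_abundance_vector <- function(x) {
  if (inherits(x, "abundance_vector")) x else abundance_vector(x)
}

# Octave class index of each abundance: class i holds n in [2^i, 2^(i+1)-1].
octave_class <- function(abundances) as.integer(floor(log2(abundances)))

#' Bin abundances into octave (doubling) classes
#'
#' Builds the octave SAD: class 0 holds singletons, class 1 species with 2-3
#' individuals, class 2 species with 4-7 individuals, and so on, class i
#' covering abundances in `[2^i, 2^(i+1) - 1]`.  Interior empty classes are
#' kept as zeros so the histogram support is always the contiguous set
#' `0 .. num_classes - 1`.
#'
#' @param v an [abundance_vector()], or a bare vector of abundances.
#' @return An object of class `"binned_sad"`: a list with `class_counts`
#'   (species per class; may be fractional for averaged SADs), `num_classes`
#'   (`floor(log2(N_max)) + 1`), `proportions` (class counts normalised to sum
#'   1) and `species_count`.
#' @examples
#' bin_abundances(c(1, 1, 2, 3, 4, 7, 8))$class_counts  # 2 2 2 1
#' @export
bin_abundances <- function(v) {
  v <- as_abundance_vector(v)
  if (v$species_count == 0L)
    return(binned_sad(numeric(0)))
  nb <- floor(log2(v$max_abundance)) + 1L
  counts <- tabulate(octave_class(v$abundances) + 1L, nbins = nb)
  binned_sad(counts)
}

#' Construct a binned SAD from per-class species counts
#'
#' @param class_counts nonnegative numeric vector, element i + 1 giving the
#'   number of species in octave class i.  Fractional counts are allowed
#'   (tile- or ordering-averaged SADs).
#' @return A `"binned_sad"` object; see [bin_abundances()].
#' @export
binned_sad <- function(class_counts) {
  class_counts <- as.numeric(class_counts)
  if (any(class_counts < 0) || anyNA(class_counts))
    stop("class counts must be nonnegative and non-missing")
  s <- sum(class_counts)
  structure(
    list(class_counts = class_counts,
         num_classes = length(class_counts),
         proportions = if (s > 0) class_counts / s else class_counts,
         species_count = s),
    class = "binned_sad")
}

#' @export
print.binned_sad <- function(x, ...) {
  cat("Octave SAD:", x$num_classes, "classes,",
      format(x$species_count), "species\n")
  if (x$num_classes > 0) {
    lab <- vapply(seq_len(x$num_classes) - 1L, function(i) {
      lo <- 2^i; hi <- 2^(i + 1) - 1
      if (lo == hi) format(lo) else paste0(lo, "-", hi)
    }, "")
    print(setNames(round(x$class_counts, 3), lab))
  }
  invisible(x)
}

#' Write / read a binned SAD as two-column delimited text
#'
#' Columns are `class_index` (0-based octave class) and `species_count`.
#'
#' @param b a `"binned_sad"`.
#' @param path file path.
#' @param delim field delimiter.
#' @return `read_binned_sad()` returns a `"binned_sad"`; `write_binned_sad()`
#'   returns `path` invisibly.
#' @export
write_binned_sad <- function(b, path, delim = ",") {
  stopifnot(inherits(b, "binned_sad"))
  df <- data.frame(class_index = seq_len(b$num_classes) - 1L,
                   species_count = b$class_counts)
  write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_binned_sad
#' @export
read_binned_sad <- function(path, delim = ",") {
  df <- read.table(path, sep = delim, header = TRUE)
  if (!all(c("class_index", "species_count") %in% names(df)))
    stop("expected columns class_index, species_count")
  df <- df[order(df$class_index), ]
  if (!identical(as.integer(df$class_index), seq_len(nrow(df)) - 1L))
    stop("class_index must be contiguous from 0")
  binned_sad(df$species_count)
}
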
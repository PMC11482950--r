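#' Genome index: chromosome names, lengths and the bin width
#'
#' A `genome_index` fixes the coordinate system every track in an analysis
#' shares: an ordered set of chromosomes, their lengths in bp, and the bin
#' width (10 bp throughout this package's defaults). Bin `k` of a chromosome
#' covers the 0-based half-open interval `[k*w, (k+1)*w)`; the last bin is
#' truncated at the chromosome end.
#'
#' @param chrom_names character vector of unique chromosome names.
#' @param chrom_lengths positive integer vector of chromosome lengths (bp),
#'   same length as `chrom_names`.
#' @param bin_width bin width in bp (default 10).
#' @return An object of class `genome_index`.
#' @export
genome_index <- function(chrom_names, chrom_lengths, bin_width = 10L) {
  chrom_names <- as.character(chrom_names)
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_lengths) != length(chrom_names))
    stop("chrom_names and chrom_lengths must have the same length")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  bin_width <- as.integer(bin_width)
  if (is.na(bin_width) || bin_width <= 0)
    stop("bin_width must be a positive integer")
  structure(
    list(chrom_names = chrom_names,
         chrom_lengths = stats::setNames(chrom_lengths, chrom_names),
         bin_width = bin_width),
    class = "genome_index")
}

#' Read a two-column chromosome-sizes file into a genome index
#'
#' @param path path to a whitespace-separated file with columns
#'   chromosome name and length (the `samtools faidx` / UCSC chrom.sizes
#'   convention).
#' @param bin_width bin width in bp.
#' @return A [genome_index()].
#' @export
read_chrom_sizes <- function(path, bin_width = 10L) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  genome_index(tab[[1]], tab[[2]], bin_width)
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index: %d chromosome(s), %.0f bp total, %d-bp bins\n",
              length(x$chrom_names), sum(x$chrom_lengths), x$bin_width))
  invisible(x)
}

n_bins <- function(index) {
  ceiling(index$chrom_lengths / index$bin_width)
}

same_index <- function(a, b) {
  identical(a$chrom_names, b$chrom_names) &&
    identical(unname(a$chrom_lengths), unname(b$chrom_lengths)) &&
    identical(a$bin_width, b$bin_width)
}

check_chroms <- function(index, chroms, what = "record") {
  unknown <- setdiff(unique(chroms), index$chrom_names)
  if (length(unknown))
    stop(sprintf("%s on chromosome(s) absent from the genome index: %s",
                 what, paste(unknown, collapse = ", ")))
  invisible(TRUE)
}

#' Binned genomic signal track
#'
#' A `genomic_track` stores one numeric value per fixed-width bin per
#' chromosome. `NA` marks a missing bin (e.g. blacklisted); missingness
#' propagates through track arithmetic and is excluded from means. This is
#' the carrier for all TMP/torsion/ChIP/mRNA signals in the package.
#'
#' @param index a [genome_index()].
#' @param values optional named list of per-chromosome numeric vectors
#'   (one value per bin, `NA` = missing). Defaults to all-zero.
#' @return An object of class `genomic_track`.
#' @export
genomic_track <- function(index, values = NULL) {
  stopifnot(inherits(index, "genome_index"))
  nb <- n_bins(index)
  if (is.null(values)) {
    values <- lapply(nb, function(n) numeric(n))
  } else {
    if (!setequal(names(values), index$chrom_names))
      stop("values must be a named list covering exactly the index chromosomes")
    values <- values[index$chrom_names]
    for (ch in index$chrom_names) {
      v <- as.numeric(values[[ch]])
      if (length(v) != nb[[ch]])
        stop(sprintf("chromosome %s: expected %d bins, got %d",
                     ch, nb[[ch]], length(v)))
      if (any(!is.na(v) & !is.finite(v)))
        stop(sprintf("chromosome %s: non-missing values must be finite", ch))
      values[[ch]] <- v
    }
  }
  structure(list(index = index, values = values), class = "genomic_track")
}

#' @export
print.genomic_track <- function(x, ...) {
  tot <- sum(vapply(x$values, length, 1L))
  miss <- sum(vapply(x$values, function(v) sum(is.na(v)), 1L))
  cat(sprintf("genomic_track: %d bins (%d-bp), %d missing, mean %.4g\n",
              tot, x$index$bin_width, miss, track_mean(x)))
  invisible(x)
}

#' Genome-wide mean of a track over non-missing bins
#'
#' @param track a [genomic_track()].
#' @return A single numeric value.
#' @export
track_mean <- function(track) {
  v <- unlist(track$values, use.names = FALSE)
  mean(v, na.rm = TRUE)
}

## apply f to each per-chromosome vector, keep structure
track_map <- function(track, f) {
  track$values <- lapply(track$values, f)
  track
}

## apply f(va, vb) bin-wise over two compatible tracks
track_map2 <- function(a, b, f) {
  if (!same_index(a$index, b$index))
    stop("tracks are not arithmetic-compatible: genome indices differ")
  a$values <- Map(f, a$values, b$values)
  a
}

## bin index (1-based) containing 0-based position pos
pos_to_bin <- function(index, pos) {
  as.integer(floor(pos / index$bin_width)) + 1L
}

## 0-based center coordinate of 1-based bin k
bin_center <- function(index, k) {
  (k - 1) * index$bin_width + index$bin_width / 2
}

## extract values for 1-based bin range [from, to] on chrom; out-of-range -> NA
track_slice <- function(track, chrom, from, to) {
  v <- track$values[[chrom]]
  n <- length(v)
  k <- seq.int(from, to)
  out <- rep(NA_real_, length(k))
  ok <- k >= 1L & k <= n
  out[ok] <- v[k[ok]]
  out
}
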
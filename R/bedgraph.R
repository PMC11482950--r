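#' Read a bedGraph file into a binned track
#'
#' Interval values are distributed into fixed-width bins by
#' coverage-weighted averaging: a bin's value is the sum over input
#' intervals of `value * overlap_bp / bin_bp`, so a bin half-covered by a
#' value-2 interval (and otherwise uncovered) gets 1. Bins not covered by
#' any interval are 0, not missing -- every bin of the genome gets a value.
#'
#' @param path path to a 4-column bedGraph (chrom, start, end, value;
#'   0-based half-open). Track/browser/comment lines are tolerated.
#'   Intervals need not be bin-aligned but must not overlap one another.
#' @param index a [genome_index()] naming every chromosome in the file.
#' @return A [genomic_track()].
#' @export
read_bedgraph <- function(path, index) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- BiocGenerics::start(gr) - 1
  end <- BiocGenerics::end(gr)
  val <- as.numeric(gr$score)
  check_chroms(index, chrom, "bedGraph interval")
  w <- index$bin_width
  nb <- n_bins(index)
  values <- lapply(nb, function(n) numeric(n))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s <- start[sel]; e <- end[sel]; v <- val[sel]
    o <- order(s)
    s <- s[o]; e <- e[o]; v <- v[o]
    if (length(s) > 1 && any(s[-1] < e[-length(e)]))
      stop(sprintf("overlapping bedGraph intervals on %s: ambiguous dialect",
                   ch))
    if (any(e > index$chrom_lengths[[ch]]))
      stop(sprintf("bedGraph interval beyond end of %s", ch))
    acc <- numeric(nb[[ch]])
    for (i in seq_along(s)) {
      k1 <- floor(s[i] / w) + 1
      k2 <- ceiling(e[i] / w)
      for (k in k1:k2) {
        ov <- min(e[i], k * w) - max(s[i], (k - 1) * w)
        if (ov > 0) acc[k] <- acc[k] + v[i] * ov
      }
    }
    bin_bp <- rep(w, nb[[ch]])
    bin_bp[nb[[ch]]] <- index$chrom_lengths[[ch]] - (nb[[ch]] - 1) * w
    values[[ch]] <- acc / bin_bp
  }
  genomic_track(index, values)
}

#' Write a track as bedGraph
#'
#' Emits one line per maximal run of equal-valued consecutive non-missing
#' bins; missing (`NA`) bins are omitted; coordinates are bin-aligned
#' (the last bin truncated at the chromosome end). No track line is
#' written. Chromosomes appear in genome-index order.
#'
#' @param track a [genomic_track()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  index <- track$index
  w <- index$bin_width
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in index$chrom_names) {
    v <- track$values[[ch]]
    n <- length(v)
    if (n == 0) next
    same <- (is.na(v[-1]) & is.na(v[-n])) |
      (!is.na(v[-1]) & !is.na(v[-n]) & v[-1] == v[-n])
    grp <- cumsum(c(TRUE, !same))
    first <- which(!duplicated(grp))
    last <- c(first[-1] - 1L, n)
    keep <- !is.na(v[first])
    if (!any(keep)) next
    starts <- (first[keep] - 1) * w
    ends <- pmin(last[keep] * w, index$chrom_lengths[[ch]])
    lines <- sprintf("%s\t%s\t%s\t%.15g", ch,
                     format_coord(starts), format_coord(ends),
                     v[first[keep]])
    writeLines(lines, con)
  }
  invisible(path)
}
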
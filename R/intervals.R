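#' Interval sets (BED-style genomic intervals)
#'
#' Intervals are plain data frames with 0-based half-open coordinates
#' (`chrom`, `start`, `end`) and optional `name`, `score`, `strand`
#' columns -- the BED convention. Overlap machinery is delegated to
#' GenomicRanges.
#'
#' @param chrom character chromosome names.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @param name,score,strand optional BED columns.
#' @return A data frame of class `interval_set`.
#' @export
interval_set <- function(chrom, start, end, name = NA_character_,
                         score = NA_real_, strand = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("intervals require start < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = name, score = score, strand = strand,
                   stringsAsFactors = FALSE)
  class(df) <- c("interval_set", "data.frame")
  df
}

empty_interval_set <- function() {
  interval_set(character(), numeric(), numeric())
}

#' Read a BED file (BED3 or BED6) into an interval set
#'
#' @param path path to a BED file.
#' @return An [interval_set()] (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- NA_character_
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  sc <- if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_
  if (length(gr) == 0) return(empty_interval_set())
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
               name = nm, score = sc, strand = strand)
}

#' Write an interval set as BED
#'
#' @param ivs an [interval_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(ivs, path) {
  df <- as.data.frame(ivs)
  out <- data.frame(chrom = df$chrom, start = format_coord(df$start),
                    end = format_coord(df$end))
  has_name <- !all(is.na(df$name))
  has_score <- !all(is.na(df$score))
  has_strand <- !all(is.na(df$strand))
  if (has_name || has_score || has_strand) {
    out$name <- ifelse(is.na(df$name), ".", df$name)
    out$score <- ifelse(is.na(df$score), 0, df$score)
    out$strand <- ifelse(is.na(df$strand), ".", df$strand)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) sprintf("%.0f", x)

## interval_set -> GRanges (1-based closed, as GenomicRanges expects)
as_granges <- function(ivs) {
  GenomicRanges::GRanges(
    seqnames = ivs$chrom,
    ranges = IRanges::IRanges(start = ivs$start + 1L, end = ivs$end))
}

## 1-based bin index ranges [first,last] covered (>=1 bp overlap) by intervals
overlapped_bins <- function(index, ivs) {
  w <- index$bin_width
  data.frame(chrom = ivs$chrom,
             first = as.integer(floor(ivs$start / w)) + 1L,
             last = as.integer(ceiling(ivs$end / w)),
             stringsAsFactors = FALSE)
}
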
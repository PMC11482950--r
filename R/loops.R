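#' Read loop calls from TSV or BEDPE
#'
#' The native format is a 5-column TSV (`chrom`, `L`, `R`, `score`,
#' `name`, header optional). BEDPE input (two anchor intervals) is
#' adapted by taking the midpoint of each anchor as the boundary; only
#' intrachromosomal loops are accepted.
#'
#' @param path input path.
#' @param format `"tsv"` or `"bedpe"`.
#' @return A data frame with columns `chrom`, `L`, `R`, `score`, `name`,
#'   `adjusted` (FALSE).
#' @export
read_loops <- function(path, format = c("tsv", "bedpe")) {
  format <- match.arg(format)
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (format == "tsv") {
    loops <- data.frame(chrom = as.character(tab[[1]]),
                        L = as.numeric(tab[[2]]), R = as.numeric(tab[[3]]),
                        score = as.numeric(tab[[4]]),
                        name = if (ncol(tab) >= 5) as.character(tab[[5]])
                               else sprintf("loop_%d", seq_len(nrow(tab))),
                        stringsAsFactors = FALSE)
  } else {
    if (any(tab[[1]] != tab[[4]]))
      stop("interchromosomal BEDPE records are not supported")
    loops <- data.frame(
      chrom = as.character(tab[[1]]),
      L = (as.numeric(tab[[2]]) + as.numeric(tab[[3]])) / 2,
      R = (as.numeric(tab[[5]]) + as.numeric(tab[[6]])) / 2,
      score = if (ncol(tab) >= 8) as.numeric(tab[[8]]) else NA_real_,
      name = if (ncol(tab) >= 7) as.character(tab[[7]])
             else sprintf("loop_%d", seq_len(nrow(tab))),
      stringsAsFactors = FALSE)
  }
  if (any(loops$L >= loops$R)) stop("loops require L < R")
  loops$adjusted <- FALSE
  loops
}

#' Keep only the smallest loops in nested configurations
#'
#' Drops every loop that strictly contains another loop's interval on the
#' same chromosome, so each genomic region is represented once, by its
#' innermost loop. Loops sharing one boundary count as nested iff the
#' other boundary is strictly inside; identical duplicates are not nested
#' in each other. Partially overlapping, non-nested loops are all kept.
#'
#' @param loops a loop table from [read_loops()].
#' @return The filtered loop table (attribute `n_dropped` records the
#'   count).
#' @export
refine_nested_loops <- function(loops) {
  n <- nrow(loops)
  drop <- logical(n)
  for (ch in unique(loops$chrom)) {
    idx <- which(loops$chrom == ch)
    if (length(idx) < 2) next
    o <- idx[order(loops$L[idx], -loops$R[idx])]
    ## after sorting by L asc, R desc: loop i contains a later loop j
    ## iff R[j] <= R[i] and the intervals differ
    for (a in seq_len(length(o) - 1)) {
      i <- o[a]
      for (b in seq.int(a + 1, length(o))) {
        j <- o[b]
        if (loops$R[j] <= loops$R[i] &&
            !(loops$L[j] == loops$L[i] && loops$R[j] == loops$R[i])) {
          drop[i] <- TRUE
          break
        }
      }
    }
  }
  out <- loops[!drop, , drop = FALSE]
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Simple peak caller on a binned track
#'
#' Local maxima at least `min_height` high are kept greedily in order of
#' descending height (leftmost wins ties), each excluding further peaks
#' within `min_separation_bp`. Peak positions are bin centers. This is a
#' deliberately plain caller for boundary-snapping work, not a modelled
#' ChIP peak caller.
#'
#' @param track a [genomic_track()].
#' @param min_height minimum peak value; default the 90th percentile of
#'   the non-missing track values.
#' @param min_separation_bp exclusion radius between kept peaks
#'   (default 250).
#' @return A data frame with columns `chrom`, `pos` (bp, bin center),
#'   `height`, sorted by chromosome and position.
#' @export
call_peaks_simple <- function(track, min_height = NULL,
                              min_separation_bp = 250) {
  if (is.null(min_height)) {
    v <- unlist(track$values, use.names = FALSE)
    min_height <- stats::quantile(v, 0.9, na.rm = TRUE, names = FALSE)
  }
  w <- track$index$bin_width
  out <- list()
  for (ch in track$index$chrom_names) {
    v <- track$values[[ch]]
    n <- length(v)
    if (n < 3) next
    vv <- ifelse(is.na(v), -Inf, v)
    ## local maximum: above left neighbour (ties go to the leftmost bin of
    ## a plateau) and at least as high as the right neighbour
    cand <- which(vv[2:(n - 1)] > vv[1:(n - 2)] &
                    vv[2:(n - 1)] >= vv[3:n]) + 1L
    cand <- cand[vv[cand] >= min_height]
    if (!length(cand)) next
    o <- cand[order(-vv[cand], cand)]
    kept <- numeric(0)
    for (k in o) {
      p <- bin_center(track$index, k)
      if (!length(kept) || all(abs(kept - p) >= min_separation_bp))
        kept <- c(kept, p)
    }
    kept <- sort(kept)
    out[[ch]] <- data.frame(chrom = ch, pos = kept,
                            height = v[pos_to_bin(track$index, kept)],
                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = numeric(), height = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (!nrow(res)) warning("no peaks found")
  res
}

#' Snap loop boundaries to the nearest ChIP peak
#'
#' Each boundary is independently moved to the nearest peak strictly
#' within `max_dist_bp` (equidistant peaks: the leftmost wins); boundaries
#' with no such peak stay put. Loops whose boundaries would invert
#' (`L >= R`) after snapping are dropped (attribute `n_dropped`).
#'
#' @param loops a loop table.
#' @param peaks a peak table from [call_peaks_simple()] (columns `chrom`,
#'   `pos`).
#' @param max_dist_bp snapping radius; a peak at exactly this distance
#'   does not attract (default 500).
#' @return The loop table with moved boundaries and `adjusted` flags.
#' @export
adjust_boundaries <- function(loops, peaks, max_dist_bp = 500) {
  snap <- function(ch, pos) {
    p <- peaks$pos[peaks$chrom == ch]
    if (!length(p)) return(pos)
    d <- abs(p - pos)
    dmin <- min(d)
    if (dmin >= max_dist_bp) return(pos)
    min(p[d == dmin])   # leftmost on ties
  }
  for (i in seq_len(nrow(loops))) {
    newL <- snap(loops$chrom[i], loops$L[i])
    newR <- snap(loops$chrom[i], loops$R[i])
    if (newL != loops$L[i] || newR != loops$R[i]) loops$adjusted[i] <- TRUE
    loops$L[i] <- newL
    loops$R[i] <- newR
  }
  bad <- loops$L >= loops$R
  out <- loops[!bad, , drop = FALSE]
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Percentile groups of loop scores
#'
#' Identical contract to [percentile_groups()], applied to loop scores.
#'
#' @param loops a loop table with a `score` column.
#' @param breaks percentile breakpoints (see [percentile_groups()]).
#' @return Integer group per loop (1 = weakest).
#' @export
loop_score_percentile_groups <- function(loops, breaks = c(20, 40, 60, 80)) {
  percentile_groups(loops$score, breaks)
}

#' Boundary-to-boundary rescaled loop composites
#'
#' Positions between the two loop boundaries are scaled by the boundary
#' distance while preserving the signal amplitude; unscaled flanks are
#' appended. Delegates to [scaled_region_matrix()] with regions `[L, R)`.
#'
#' @param track a [genomic_track()].
#' @param loops a loop table.
#' @param flank_bp unscaled flank (default 1000).
#' @param n_body_bins body columns (default 100).
#' @return A `composite_matrix`.
#' @export
loop_composites <- function(track, loops, flank_bp = 1000L,
                            n_body_bins = 100L) {
  regions <- data.frame(chrom = loops$chrom, start = loops$L, end = loops$R,
                        strand = NA_character_, name = loops$name,
                        stringsAsFactors = FALSE)
  scaled_region_matrix(track, regions, flank_bp, n_body_bins)
}

#' Write a loop table as TSV
#'
#' @param loops a loop table.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_loops <- function(loops, path) {
  utils::write.table(
    loops[, c("chrom", "L", "R", "score", "name", "adjusted")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
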
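#' Anchored composite matrix (metagene heatmap rows)
#'
#' Builds one row per anchor, holding the track values in
#' `[anchor - flank, anchor + flank)` reoriented so transcription runs
#' left to right (minus-strand rows are reversed). Column coordinates are
#' bin-center offsets from the anchor in the direction of transcription.
#' Bins off the chromosome ends are missing; anchors off the chromosome
#' are skipped (count in attribute `n_skipped`).
#'
#' @param track a [genomic_track()].
#' @param anchors data frame with columns `chrom`, `pos` (0-based anchor
#'   coordinate, e.g. a TSS), `strand` (`+`/`-`); optional `name` used as
#'   row label; optional `start`, `end` (feature bounds, required for
#'   exclusions).
#' @param flank_bp flank on each side, a multiple of the bin width
#'   (default 1000).
#' @param exclusion `"none"`, `"beyond_tes"` (bins downstream of the
#'   row's own feature end set missing; use with TSS anchors) or
#'   `"beyond_tss"` (bins upstream of the feature start set missing; use
#'   with TES anchors). Suppresses bias from neighbouring genes.
#' @return A `composite_matrix`: list with `values` (rows x columns,
#'   `NA` = missing), `positions` (bp offsets of column bin centers),
#'   `row_labels`, `mode = "anchored"`.
#' @export
anchored_matrix <- function(track, anchors, flank_bp = 1000L,
                            exclusion = c("none", "beyond_tes",
                                          "beyond_tss")) {
  exclusion <- match.arg(exclusion)
  w <- track$index$bin_width
  if (flank_bp %% w != 0) stop("flank_bp must be a multiple of the bin width")
  nf <- flank_bp %/% w
  ncol_ <- 2L * nf
  positions <- seq(-flank_bp + w / 2, flank_bp - w / 2, by = w)
  rows <- list(); labels <- character(); n_skip <- 0L
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    if (!ch %in% track$index$chrom_names ||
        anchors$pos[i] < 0 ||
        anchors$pos[i] > track$index$chrom_lengths[[ch]]) {
      n_skip <- n_skip + 1L
      next
    }
    a_bin <- floor(anchors$pos[i] / w)      # 0-based bin holding the anchor
    v <- track_slice(track, ch, a_bin - nf + 1L, a_bin + nf)
    minus <- !is.na(anchors$strand[i]) && anchors$strand[i] == "-"
    if (minus) v <- rev(v)
    if (exclusion != "none") {
      if (is.null(anchors$start) || is.null(anchors$end))
        stop("exclusion requires feature start/end columns in anchors")
      len <- anchors$end[i] - anchors$start[i]
      if (exclusion == "beyond_tes") v[positions > len] <- NA_real_
      else v[positions < -len] <- NA_real_
    }
    rows[[length(rows) + 1L]] <- v
    labels <- c(labels, if (!is.null(anchors$name)) anchors$name[i]
                        else as.character(i))
  }
  values <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(), 0, ncol_)
  rownames(values) <- labels
  structure(list(values = values, positions = positions,
                 row_labels = labels, mode = "anchored",
                 n_skipped = n_skip),
            class = "composite_matrix")
}

## mean-preserving resampling of a vector to n_out bins by
## coverage-weighted averaging (never interpolation, never summing):
## output bin j averages the source signal over source coordinate
## fraction [j-1, j) * n_in/n_out.
resample_mean <- function(v, n_out) {
  n_in <- length(v)
  if (n_in == 0 || n_out < 1) stop("resample_mean needs non-empty input")
  out <- numeric(n_out)
  scale <- n_in / n_out
  for (j in seq_len(n_out)) {
    lo <- (j - 1) * scale
    hi <- j * scale
    k1 <- floor(lo) + 1
    k2 <- ceiling(hi)
    k <- seq.int(k1, min(k2, n_in))
    ov <- pmin(hi, k) - pmax(lo, k - 1)
    keep <- ov > 1e-12
    k <- k[keep]; ov <- ov[keep]
    if (any(is.na(v[k]))) out[j] <- NA_real_
    else out[j] <- sum(v[k] * ov) / sum(ov)
  }
  out
}

#' Length-rescaled composite matrix
#'
#' Each region's body signal is resampled to a fixed number of columns by
#' mean-preserving coverage-weighted averaging -- a constant region stays
#' constant and the per-row body mean equals the source-region mean, so
#' the signal *amplitude* is preserved (not the area, as summing would).
#' Unscaled flanks are appended on each side. Minus-strand regions are
#' reversed end to end.
#'
#' @param track a [genomic_track()].
#' @param regions data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), optional `strand` and `name`.
#' @param flank_bp unscaled flank on each side (multiple of bin width).
#' @param n_body_bins number of columns the body is rescaled to
#'   (default 100).
#' @return A `composite_matrix` with `mode = "scaled"`; `positions` holds
#'   bp offsets for the flanks and fractional body coordinates in (0,1)
#'   scaled by region length being abstracted away -- stored as
#'   `c(-flank..0, body 1..n, 0..flank)` index axis in `positions`
#'   (flank offsets in bp, body columns as fractions).
#' @export
scaled_region_matrix <- function(track, regions, flank_bp = 1000L,
                                 n_body_bins = 100L) {
  w <- track$index$bin_width
  if (flank_bp %% w != 0) stop("flank_bp must be a multiple of the bin width")
  nf <- flank_bp %/% w
  rows <- list(); labels <- character(); n_skip <- 0L
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    len <- regions$end[i] - regions$start[i]
    if (!ch %in% track$index$chrom_names || len < w) {
      n_skip <- n_skip + 1L
      next
    }
    k1 <- floor(regions$start[i] / w) + 1L
    k2 <- ceiling(regions$end[i] / w)
    body <- resample_mean(track_slice(track, ch, k1, k2), n_body_bins)
    left <- if (nf > 0) track_slice(track, ch, k1 - nf, k1 - 1L) else numeric()
    right <- if (nf > 0) track_slice(track, ch, k2 + 1L, k2 + nf) else numeric()
    v <- c(left, body, right)
    minus <- !is.null(regions$strand) && !is.na(regions$strand[i]) &&
      regions$strand[i] == "-"
    if (minus) v <- rev(v)
    rows[[length(rows) + 1L]] <- v
    labels <- c(labels, if (!is.null(regions$name)) regions$name[i]
                        else as.character(i))
  }
  positions <- c(seq(-flank_bp + w / 2, -w / 2, length.out = nf),
                 seq(0.5 / n_body_bins, 1 - 0.5 / n_body_bins,
                     length.out = n_body_bins),
                 seq(w / 2, flank_bp - w / 2, length.out = nf))
  values <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(), 0, 2L * nf + n_body_bins)
  rownames(values) <- labels
  structure(list(values = values, positions = positions,
                 row_labels = labels, mode = "scaled",
                 n_flank_bins = nf, n_body_bins = n_body_bins,
                 n_skipped = n_skip),
            class = "composite_matrix")
}

#' Composite profile: per-column mean, SEM and n
#'
#' Column statistics over non-missing entries. The SEM is the column
#' sample standard deviation divided by `sqrt(n)`; a column with a single
#' non-missing entry gets SEM 0 by convention, and a column with none is
#' missing throughout.
#'
#' @param mat a `composite_matrix`.
#' @return A data frame with columns `position`, `mean`, `sem`, `n`.
#' @export
composite_profile <- function(mat) {
  v <- mat$values
  if (nrow(v) < 1) stop("composite matrix has no rows")
  n <- colSums(!is.na(v))
  mu <- ifelse(n > 0, colMeans(v, na.rm = TRUE), NA_real_)
  sdv <- apply(v, 2, stats::sd, na.rm = TRUE)
  sem <- ifelse(n > 1, sdv / sqrt(n), ifelse(n == 1, 0, NA_real_))
  data.frame(position = mat$positions, mean = mu, sem = sem, n = n)
}

#' Sort the rows of a composite matrix
#'
#' @param mat a `composite_matrix`.
#' @param keys one numeric key per row (e.g. ORF size for size-sorted
#'   heatmaps).
#' @param descending sort direction.
#' @return The matrix with rows stably reordered.
#' @export
sort_rows <- function(mat, keys, descending = FALSE) {
  if (length(keys) != nrow(mat$values))
    stop("need exactly one key per row")
  o <- order(keys, decreasing = descending)
  mat$values <- mat$values[o, , drop = FALSE]
  mat$row_labels <- mat$row_labels[o]
  mat
}

#' @export
print.composite_matrix <- function(x, ...) {
  cat(sprintf("composite_matrix (%s): %d rows x %d columns, %d skipped\n",
              x$mode, nrow(x$values), ncol(x$values), x$n_skipped))
  invisible(x)
}

#' Write a composite profile as TSV
#'
#' @param profile a data frame from [composite_profile()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
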
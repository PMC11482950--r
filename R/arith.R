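#' Normalize a track to mean 1
#'
#' Divides every non-missing bin by the genome-wide mean over non-missing
#' bins, so that the output mean over the normalization domain is exactly 1.
#' This absorbs sequencing depth: the downstream torsion signal is invariant
#' to rescaling any input by a positive constant.
#'
#' @param track a [genomic_track()].
#' @param exclude optional [interval_set()] of regions (e.g. a blacklist)
#'   to exclude from the mean *computation*; excluded bins are still
#'   rescaled. By default every non-missing bin enters the mean.
#' @return A [genomic_track()] with mean 1 over its normalization domain.
#' @export
normalize_mean <- function(track, exclude = NULL) {
  domain <- track
  if (!is.null(exclude) && nrow(exclude) > 0)
    domain <- mask_blacklist(track, exclude)
  v <- unlist(domain$values, use.names = FALSE)
  if (all(is.na(v))) stop("no non-missing bins to normalize over")
  m <- mean(v, na.rm = TRUE)
  if (m == 0) stop("track mean is zero; cannot normalize")
  track_map(track, function(x) x / m)
}

#' Average replicate tracks bin-wise
#'
#' @param tracks a list of arithmetic-compatible [genomic_track()] objects.
#'   A bin missing in any input is missing in the output.
#' @return A [genomic_track()] of per-bin means.
#' @export
average_tracks <- function(tracks) {
  if (!length(tracks)) stop("need at least one track")
  out <- tracks[[1]]
  for (t in tracks[-1]) {
    if (!same_index(out$index, t$index))
      stop("tracks are not arithmetic-compatible: genome indices differ")
  }
  out$values <- lapply(out$index$chrom_names, function(ch) {
    mat <- vapply(tracks, function(t) t$values[[ch]],
                  numeric(length(out$values[[ch]])))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
    rowMeans(mat)   # NA anywhere -> NA, per contract
  })
  names(out$values) <- out$index$chrom_names
  out
}

#' Subtract one track from another
#'
#' @param a,b compatible [genomic_track()] objects.
#' @return `a - b` bin-wise; bins missing in either input are missing.
#' @export
subtract_tracks <- function(a, b) track_map2(a, b, `-`)

#' Add two tracks
#'
#' @param a,b compatible [genomic_track()] objects.
#' @return `a + b` bin-wise.
#' @export
add_tracks <- function(a, b) track_map2(a, b, `+`)

#' Divide one track by another (with pseudocount)
#'
#' Computes `(a + pseudocount) / (b + pseudocount)` bin-wise (the usual
#' ChIP/input ratio). With `pseudocount = 0`, bins where the denominator is
#' zero become missing and a warning reports how many.
#'
#' @param a,b compatible [genomic_track()] objects.
#' @param pseudocount non-negative value added to numerator and denominator.
#' @return A [genomic_track()] of ratios.
#' @export
divide_tracks <- function(a, b, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  n_zero <- 0L
  out <- track_map2(a, b, function(x, y) {
    num <- x + pseudocount
    den <- y + pseudocount
    bad <- !is.na(den) & den == 0
    n_zero <<- n_zero + sum(bad & !is.na(num))
    den[bad] <- NA_real_
    num / den
  })
  if (n_zero > 0)
    warning(sprintf("%d bin(s) had zero denominator and were set missing",
                    n_zero))
  out
}

#' Mask blacklisted regions of a track
#'
#' Any bin overlapping a blacklist interval by at least 1 bp is set
#' missing; all other bins are unchanged. An empty blacklist is the
#' identity.
#'
#' @param track a [genomic_track()].
#' @param blacklist an [interval_set()] on the same genome.
#' @return The masked [genomic_track()].
#' @export
mask_blacklist <- function(track, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) return(track)
  check_chroms(track$index, blacklist$chrom, "blacklist interval")
  ob <- overlapped_bins(track$index, blacklist)
  for (i in seq_len(nrow(ob))) {
    ch <- ob$chrom[i]
    n <- length(track$values[[ch]])
    k <- seq.int(max(1L, ob$first[i]), min(n, ob$last[i]))
    track$values[[ch]][k] <- NA_real_
  }
  track
}

#' Moving-average smoother (visualization aid)
#'
#' Centered moving average over an odd number of bins. Missing bins stay
#' missing; near chromosome ends the window shrinks. No analysis step in
#' this package applies smoothing by default.
#'
#' @param track a [genomic_track()].
#' @param k odd window size in bins.
#' @return The smoothed [genomic_track()].
#' @export
smooth_track <- function(track, k = 15L) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("k must be a positive odd integer")
  if (k == 1L) return(track)
  h <- (k - 1L) %/% 2L
  track_map(track, function(v) {
    n <- length(v)
    if (n == 0) return(v)
    x <- ifelse(is.na(v), 0, v)
    w <- as.numeric(!is.na(v))
    csx <- cumsum(x); csw <- cumsum(w)
    lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
    sx <- csx[hi] - c(0, csx)[lo]
    sw <- csw[hi] - c(0, csw)[lo]
    out <- ifelse(sw > 0, sx / sw, NA_real_)
    out[is.na(v)] <- NA_real_
    out
  })
}
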
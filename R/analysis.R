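#' Dominant spatial period of a composite profile
#'
#' Estimates the period of a (roughly sinusoidal) composite signal, e.g.
#' nucleosome phasing in gene bodies, as the lag of the first non-zero-lag
#' local maximum of the autocorrelation of the mean profile. The profile
#' is mean-centered first; missing positions are dropped.
#'
#' @param values numeric profile values at consecutive bin positions.
#' @param bin_bp bp per bin (default 10).
#' @param max_lag_bins largest lag examined (default half the profile).
#' @return Period in bp (`NA` if no interior autocorrelation maximum
#'   exists).
#' @export
profile_periodicity <- function(values, bin_bp = 10,
                                max_lag_bins = NULL) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 8) return(NA_real_)
  if (is.null(max_lag_bins)) max_lag_bins <- n %/% 2
  ac <- stats::acf(v, lag.max = max_lag_bins, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  ## ac[1] is lag 0; first interior local maximum at lag >= 1
  for (k in 2:(length(ac) - 1)) {
    if (ac[k] > ac[k - 1] && ac[k] >= ac[k + 1])
      return((k - 1) * bin_bp)
  }
  NA_real_
}

#' Peak-to-valley amplitude of a profile
#'
#' @param values numeric profile values (NAs ignored).
#' @return `max(values) - min(values)`.
#' @export
peak_to_valley <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) return(NA_real_)
  max(v) - min(v)
}

#' Correlation between a recovered torsion track and a truth field
#'
#' Validation utility for simulated data: both the recovered torsion
#' track and the truth response field (`kappa * t`) are moving-average
#' smoothed, and the Pearson correlation is computed over bins where the
#' truth response magnitude exceeds the analytic Poisson noise floor of
#' the smoothed difference track,
#' `sqrt((1/n_with + 1/n_without) / depth_bin) / sqrt(smooth_bins)`.
#'
#' @param torsion recovered torsion [genomic_track()] (from
#'   [compute_torsion()]).
#' @param truth_field the injected torsion field as a [genomic_track()].
#' @param kappa linear-response coefficient used by the generator.
#' @param depth_bin expected counts per bin per replicate.
#' @param n_with,n_without replicate counts of the two conditions.
#' @param smooth_bins odd moving-average window (default 31, i.e. 310 bp
#'   at 10-bp bins -- well below the torsion decay length).
#' @return A list: `r` (Pearson correlation), `n` (bins compared),
#'   `noise_floor`.
#' @export
field_recovery_correlation <- function(torsion, truth_field, kappa,
                                       depth_bin, n_with, n_without,
                                       smooth_bins = 31L) {
  rec <- unlist(smooth_track(torsion, smooth_bins)$values,
                use.names = FALSE)
  tru <- unlist(smooth_track(
    track_map(truth_field, function(v) v * kappa), smooth_bins)$values,
    use.names = FALSE)
  floor_sd <- sqrt((1 / n_with + 1 / n_without) / depth_bin) /
    sqrt(smooth_bins)
  sel <- !is.na(tru) & !is.na(rec) & abs(tru) > floor_sd
  list(r = stats::cor(rec[sel], tru[sel]), n = sum(sel),
       noise_floor = floor_sd)
}
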
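#' Normalize a sample track against purified genomic DNA
#'
#' Removes the intercalator's DNA-sequence preference by comparing the
#' chromatin signal with the signal from deproteinized, purified DNA.
#' Used only for accessibility-style views; the torsion-signal
#' computation ([compute_torsion()]) deliberately does *not* apply it,
#' because the purified-DNA sequence preference cancels in the
#' with-minus-without subtraction.
#'
#' @param sample_track,purified_track mean-normalized, compatible
#'   [genomic_track()] objects; a warning is issued if either mean is not
#'   1 within `1e-6`.
#' @param mode `"ratio"` (default; per-bin division) or `"difference"`
#'   (per-bin subtraction).
#' @param pseudocount pseudocount for ratio mode (see [divide_tracks()]).
#' @return A [genomic_track()].
#' @export
sequence_normalize <- function(sample_track, purified_track,
                               mode = c("ratio", "difference"),
                               pseudocount = 0) {
  mode <- match.arg(mode)
  for (t in list(sample_track, purified_track)) {
    if (abs(track_mean(t) - 1) > 1e-6)
      warning("input track mean differs from 1; normalize_mean() first?")
  }
  if (mode == "ratio") divide_tracks(sample_track, purified_track,
                                     pseudocount)
  else subtract_tracks(sample_track, purified_track)
}

#' Compute the signed torsion signal
#'
#' The core operation: per replicate, blacklisted bins are masked and the
#' track is normalized to mean 1; replicates are averaged per condition;
#' and the zero-torsion baseline (fixed, digested chromatin) is
#' subtracted from the in-vivo signal. Because both conditions carry the
#' same accessibility and sequence-preference structure, the difference
#' isolates the torsion-dependent intercalation: positive values mark
#' underwound ((-)) torsion, negative values overwound ((+)) torsion.
#'
#' @param with_torsion_reps list of [genomic_track()] replicates measured
#'   in vivo.
#' @param without_torsion_reps list of replicates measured on the fixed,
#'   digested zero-torsion preparation.
#' @param blacklist optional [interval_set()] masked before
#'   normalization.
#' @param normalize_first if `TRUE` (default) each replicate is
#'   mean-normalized before averaging; if `FALSE` replicates are averaged
#'   first and the condition mean-normalized once.
#' @return A [genomic_track()] with class `torsion_track` prepended and a
#'   `provenance` attribute (replicate counts, masked-bin count, sign
#'   convention).
#' @export
compute_torsion <- function(with_torsion_reps, without_torsion_reps,
                            blacklist = NULL, normalize_first = TRUE) {
  prep <- function(reps) {
    reps <- lapply(reps, mask_blacklist, blacklist = blacklist)
    if (normalize_first) {
      average_tracks(lapply(reps, normalize_mean))
    } else {
      normalize_mean(average_tracks(reps))
    }
  }
  with_avg <- prep(with_torsion_reps)
  without_avg <- prep(without_torsion_reps)
  out <- subtract_tracks(with_avg, without_avg)
  n_masked <- sum(vapply(out$values, function(v) sum(is.na(v)), 1L))
  attr(out, "provenance") <- list(
    n_with = length(with_torsion_reps),
    n_without = length(without_torsion_reps),
    n_masked_bins = n_masked,
    sign = "positive = (-)/underwound torsion")
  class(out) <- c("torsion_track", class(out))
  out
}

#' Peak/valley torsion statistics per gene group
#'
#' For each group of genes: build the TSS- (or TES-) anchored composite
#' of the torsion signal, locate the composite maximum near the TSS
#' (minimum near the TES) within `search_bp` of the anchor, then average
#' each gene's torsion over the bins whose centers lie within
#' `window_bp` of that extremum position, and report the mean and
#' standard error of those per-gene means.
#'
#' @param torsion a torsion [genomic_track()].
#' @param genes a gene table ([read_genes()]).
#' @param groups integer group assignment per gene (e.g. from
#'   [percentile_groups()]).
#' @param anchor `"tss_peak"` (composite maximum near the TSS) or
#'   `"tes_valley"` (composite minimum near the TES).
#' @param window_bp averaging half-width around the extremum
#'   (default 20, i.e. 4 bins at 10-bp binning).
#' @param search_bp half-width of the extremum search window
#'   (default 500).
#' @param flank_bp composite flank (default 1000).
#' @return A data frame with one row per group: `group`, `anchor`,
#'   `mean`, `sem`, `n`, `window_bp`, `extremum_offset_bp`. A warning is
#'   issued when an extremum sits on the search-window edge.
#' @export
peak_valley_stats <- function(torsion, genes, groups,
                              anchor = c("tss_peak", "tes_valley"),
                              window_bp = 20, search_bp = 500,
                              flank_bp = 1000L) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0) stop("no genes to analyse")
  if (length(groups) != nrow(genes))
    stop("need one group label per gene")
  out <- list()
  for (g in sort(unique(groups))) {
    gg <- genes[groups == g, , drop = FALSE]
    if (nrow(gg) == 0) stop(sprintf("group %s has no genes", g))
    anchors <- data.frame(chrom = gg$chrom,
                          pos = if (anchor == "tss_peak") gg$tss else gg$tes,
                          strand = gg$strand, name = gg$name,
                          start = gg$start, end = gg$end,
                          stringsAsFactors = FALSE)
    mat <- anchored_matrix(torsion, anchors, flank_bp = flank_bp,
                           exclusion = "none")
    prof <- composite_profile(mat)
    in_search <- abs(prof$position) <= search_bp & !is.na(prof$mean)
    idx <- which(in_search)
    ext <- if (anchor == "tss_peak") idx[which.max(prof$mean[idx])]
           else idx[which.min(prof$mean[idx])]
    if (ext == min(idx) || ext == max(idx))
      warning(sprintf("group %s: composite extremum on search-window edge",
                      g))
    pos0 <- prof$position[ext]
    cols <- which(abs(prof$position - pos0) <= window_bp)
    per_gene <- rowMeans(mat$values[, cols, drop = FALSE], na.rm = TRUE)
    per_gene <- per_gene[is.finite(per_gene)]
    n <- length(per_gene)
    mu <- mean(per_gene)
    sem <- if (n > 1) stats::sd(per_gene) / sqrt(n) else 0
    out[[length(out) + 1L]] <- data.frame(
      group = g, anchor = anchor, mean = mu, sem = sem, n = n,
      window_bp = window_bp, extremum_offset_bp = pos0)
  }
  do.call(rbind, out)
}

#' Write peak/valley statistics as TSV
#'
#' @param stats_df a data frame from [peak_valley_stats()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_peak_valley <- function(stats_df, path) {
  utils::write.table(stats_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
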
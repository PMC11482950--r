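#' Read a BED6 gene annotation into a gene table
#'
#' Genes are stranded ORF intervals. The TSS is the 5' ORF bound
#' (start for `+` genes, end for `-` genes) and the TES the 3' bound;
#' no UTR model is applied, matching analyses that anchor on verified
#' ORF coordinates.
#'
#' @param path path to a BED6 file (strand required).
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `tss`, `tes`, `size`, `expression` (NA until assigned),
#'   `class` ("unknown" until assigned), in input order.
#' @export
read_genes <- function(path) {
  ivs <- read_bed(path)
  if (nrow(ivs) > 0 && any(is.na(ivs$strand)))
    stop("gene BED must be BED6 with a strand column")
  genes_from_intervals(ivs)
}

## build the gene table from an interval_set with strand
genes_from_intervals <- function(ivs) {
  nm <- ivs$name
  if (all(is.na(nm))) nm <- sprintf("gene_%d", seq_len(nrow(ivs)))
  g <- data.frame(
    chrom = ivs$chrom, start = ivs$start, end = ivs$end,
    strand = ivs$strand, name = nm, stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g$tes <- ifelse(g$strand == "+", g$end, g$start)
  g$size <- g$end - g$start
  g$expression <- NA_real_
  g$class <- "unknown"
  g
}

#' Quantify gene expression from strand-specific mRNA tracks
#'
#' The minus-strand signal is subtracted from the plus-strand signal, and
#' a gene's expression is the mean absolute value of the difference over
#' the bins of its ORF. Taking the absolute value makes the measure
#' strand-symmetric: a minus-strand gene with signal only on the minus
#' track scores the same as its plus-strand mirror image.
#'
#' @param plus_track,minus_track compatible [genomic_track()] objects of
#'   strand-specific mRNA coverage.
#' @param genes a gene table from [read_genes()].
#' @return `genes` with the `expression` column filled in.
#' @export
expression_from_mrna <- function(plus_track, minus_track, genes) {
  diff <- subtract_tracks(plus_track, minus_track)
  w <- diff$index$bin_width
  check_chroms(diff$index, genes$chrom, "gene")
  expr <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (genes$size[i] < w)
      stop(sprintf("gene %s is shorter than one bin", genes$name[i]))
    ## bins fully or partly inside the ORF
    k1 <- floor(genes$start[i] / w) + 1
    k2 <- ceiling(genes$end[i] / w)
    v <- track_slice(diff, genes$chrom[i], k1, k2)
    expr[i] <- mean(abs(v), na.rm = TRUE)
  }
  genes$expression <- expr
  genes
}

#' Partition genes (or any scored records) into percentile groups
#'
#' A record's empirical percentile rank is the fraction of keys strictly
#' below its own, so tied records share a group and all-equal keys land
#' together in the first group. Groups are split at the given percentile
#' breakpoints; every record lands in exactly one group.
#'
#' @param keys numeric vector to rank by (e.g. expression or ORF size).
#' @param breaks strictly increasing percentile breakpoints in (0, 100);
#'   the default `c(20, 40, 60, 80)` yields five equal quintile groups.
#' @return Integer group assignment (1 = lowest key values), with values
#'   in `1..length(breaks)+1`.
#' @export
percentile_groups <- function(keys, breaks = c(20, 40, 60, 80)) {
  n <- length(keys)
  if (n == 0) stop("no records to group")
  if (any(is.na(keys))) stop("keys contain NA")
  if (is.unsorted(breaks, strictly = TRUE) ||
      any(breaks <= 0) || any(breaks >= 100))
    stop("breaks must be strictly increasing within (0, 100)")
  pct <- (rank(keys, ties.method = "min") - 1) / n * 100   # in [0, 100)
  findInterval(pct, breaks) + 1L
}

#' Classify nearest-neighbour gene pairs by strand configuration
#'
#' Adjacent (non-overlapping, per chromosome in coordinate order) gene
#' pairs are classified as divergent (`<- ->`: left on `-`, right on `+`),
#' convergent (`-> <-`) or codirectional. The intergenic interval runs
#' from the left ORF end to the right ORF start. A pair is "purified" iff
#' no annotation other than its two members overlaps that interval --
#' these are the pairs whose intergenic torsion can be attributed to the
#' flanking genes alone.
#'
#' @param genes a gene table from [read_genes()].
#' @param all_annotations an [interval_set()] with the superset annotation
#'   list used for the purification test (e.g. all genes, not just
#'   verified ORFs). `NULL` means no purification test (all pass).
#' @return A data frame with one row per pair: `chrom`, `left_name`,
#'   `right_name`, `left_idx`, `right_idx` (row indices into `genes`),
#'   `configuration`, `gap_start`, `gap_end`, `purified`. Overlapping
#'   adjacent ORFs are skipped; the count is reported in the
#'   `n_skipped_overlap` attribute.
#' @export
classify_gene_pairs <- function(genes, all_annotations = NULL) {
  pairs <- list()
  n_skip <- 0L
  for (ch in unique(genes$chrom)) {
    idx <- which(genes$chrom == ch)
    idx <- idx[order(genes$start[idx], genes$end[idx])]
    if (length(idx) < 2) next
    for (j in seq_len(length(idx) - 1)) {
      li <- idx[j]; ri <- idx[j + 1]
      if (genes$end[li] > genes$start[ri]) { n_skip <- n_skip + 1L; next }
      ls <- genes$strand[li]; rs <- genes$strand[ri]
      config <- if (ls == "-" && rs == "+") "divergent"
                else if (ls == "+" && rs == "-") "convergent"
                else "codirectional"
      pairs[[length(pairs) + 1L]] <- data.frame(
        chrom = ch, left_name = genes$name[li], right_name = genes$name[ri],
        left_idx = li, right_idx = ri, configuration = config,
        gap_start = genes$end[li], gap_end = genes$start[ri],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(chrom = character(), left_name = character(),
               right_name = character(), left_idx = integer(),
               right_idx = integer(), configuration = character(),
               gap_start = numeric(), gap_end = numeric(),
               stringsAsFactors = FALSE)
  out$purified <- rep(TRUE, nrow(out))
  if (!is.null(all_annotations) && nrow(all_annotations) > 0 && nrow(out)) {
    ann <- as_granges(all_annotations)
    for (i in seq_len(nrow(out))) {
      if (out$gap_end[i] <= out$gap_start[i]) next  # abutting ORFs: empty gap
      gap <- GenomicRanges::GRanges(out$chrom[i],
        IRanges::IRanges(out$gap_start[i] + 1L, out$gap_end[i]))
      hits <- S4Vectors::queryHits(
        GenomicRanges::findOverlaps(ann, gap, minoverlap = 1L))
      if (length(hits)) {
        ## annotations identical to the pair members do not disqualify
        own <- (all_annotations$chrom[hits] == out$chrom[i]) &
          ((all_annotations$start[hits] == genes$start[out$left_idx[i]] &
            all_annotations$end[hits] == genes$end[out$left_idx[i]]) |
           (all_annotations$start[hits] == genes$start[out$right_idx[i]] &
            all_annotations$end[hits] == genes$end[out$right_idx[i]]))
        if (any(!own)) out$purified[i] <- FALSE
      }
    }
  }
  attr(out, "n_skipped_overlap") <- n_skip
  out
}

#' Filter gene pairs by promoter class
#'
#' Keeps the pairs where *both* members' promoter class is in the
#' requested set (divergent-pair insulation analyses compare pairs that
#' are homogeneous in class).
#'
#' @param pairs a pair table from [classify_gene_pairs()].
#' @param genes the gene table the pairs index into (with `class` filled).
#' @param classes character vector of accepted classes, e.g. `"UNB"` or
#'   `c("TFO", "STM")`.
#' @return The filtered pair table.
#' @export
filter_pairs_by_class <- function(pairs, genes, classes) {
  keep <- genes$class[pairs$left_idx] %in% classes &
    genes$class[pairs$right_idx] %in% classes
  pairs[keep, , drop = FALSE]
}

#' Attach promoter classes from a two-column TSV
#'
#' @param genes a gene table.
#' @param path TSV with columns gene name and class (UNB/TFO/STM/RP).
#' @return `genes` with the `class` column filled for listed genes.
#' @export
read_promoter_classes <- function(genes, path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  m <- match(genes$name, tab[[1]])
  genes$class <- ifelse(is.na(m), genes$class, tab[[2]][m])
  genes
}

#' Write a gene-pair table as TSV
#'
#' @param pairs a pair table from [classify_gene_pairs()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gene_pairs <- function(pairs, path) {
  out <- pairs[, c("chrom", "left_name", "right_name", "configuration",
                   "gap_start", "gap_end", "purified")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
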
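#' ICL coverage from paired-end alignments
#'
#' Each interstrand crosslink is located at the 5' end of Read 1 of its
#' library fragment. This function counts, per bin, the 5'-most genomic
#' base of every first-in-pair, mapped, primary, non-duplicate-flagged
#' alignment: for a forward-strand read the leftmost aligned base, for a
#' reverse-strand read the rightmost. Read 2, secondary, supplementary,
#' unmapped and duplicate-flagged records contribute nothing. Duplicate
#' *marking* is assumed to have happened upstream; only the flag is
#' honoured here.
#'
#' @param path path to a SAM or BAM file of paired-end alignments
#'   (SAM input is converted on the fly).
#' @param index a [genome_index()] covering every chromosome that
#'   receives an alignment.
#' @return A [genomic_track()] of per-bin ICL counts.
#' @export
icl_coverage_from_alignments <- function(path, index) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  ## read everything mapped so unpaired data can be detected and rejected
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    what = "flag")
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  flags <- S4Vectors::mcols(aln)$flag
  if (length(aln) && any(bitwAnd(flags, 1L) == 0L))
    stop(paste("unpaired alignments found: single-end data is not",
               "supported; supply paired-end alignments"))
  ## keep first-in-pair (0x40), primary (0x100/0x800 unset), non-dup (0x400)
  keep <- bitwAnd(flags, 0x40L) != 0L &
    bitwAnd(flags, 0x100L) == 0L &
    bitwAnd(flags, 0x800L) == 0L &
    bitwAnd(flags, 0x400L) == 0L
  aln <- aln[keep]
  chrom <- as.character(GenomicRanges::seqnames(aln))
  check_chroms(index, chrom, "alignment")
  minus <- as.character(BiocGenerics::strand(aln)) == "-"
  ## 0-based 5' end: leftmost aligned base (+) / rightmost aligned base (-)
  p5 <- ifelse(minus, BiocGenerics::end(aln) - 1L,
               BiocGenerics::start(aln) - 1L)
  nb <- n_bins(index)
  values <- lapply(nb, function(n) numeric(n))
  for (ch in unique(chrom)) {
    bins <- pos_to_bin(index, p5[chrom == ch])
    tab <- tabulate(bins, nbins = nb[[ch]])
    values[[ch]] <- as.numeric(tab)
  }
  genomic_track(index, values)
}
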
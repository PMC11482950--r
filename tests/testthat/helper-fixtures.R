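## Shared fixtures, built in code.

## tiny genome: one 100-bp chromosome, 10-bp bins
tiny_index <- function(len = 100, bin = 10L, n_chrom = 1L) {
  genome_index(paste0("chr", as.roman(seq_len(n_chrom))),
               rep(len, n_chrom), bin)
}

## track from a plain vector (single chromosome)
vec_track <- function(v, index = NULL) {
  if (is.null(index)) index <- tiny_index(length(v) * 10L)
  genomic_track(index, stats::setNames(list(as.numeric(v)),
                                       index$chrom_names[1]))
}

track_values <- function(track, chrom = NULL) {
  if (is.null(chrom)) chrom <- track$index$chrom_names[1]
  track$values[[chrom]]
}

## write a SAM file with the given alignment records and return its path.
## records: data.frame(qname, flag, chrom, pos1 (1-based), cigar)
write_sam <- function(records, index, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", index$chrom_names,
                   as.integer(index$chrom_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                  records$qname, records$flag, records$chrom,
                  records$pos1, records$cigar)
  writeLines(c(hdr, body), path)
  path
}

## small deterministic gene table on a given index
toy_genes <- function() {
  idx <- tiny_index(len = 10000, n_chrom = 1L)
  g <- genes_from_intervals_public(
    chrom = rep("chrI", 4),
    start = c(100, 1500, 4000, 7000),
    end = c(1000, 2400, 5200, 8500),
    strand = c("+", "-", "+", "+"),
    name = c("A", "B", "C", "D"))
  list(index = idx, genes = g)
}

## public-surface route to a gene table without a BED file on disk
genes_from_intervals_public <- function(chrom, start, end, strand, name) {
  path <- tempfile(fileext = ".bed")
  write_bed(interval_set(chrom, start, end, name = name, score = 0,
                         strand = strand), path)
  read_genes(path)
}

## small simulation shared by heavier tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- sim_params(n_chrom = 2L, chrom_length = 150000)
      cache <<- simulate_tmp_experiment(p, seed = 42L)
    }
    cache
  }
})

## full default-condition simulation (cached; used by the acceptance suite)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_tmp_experiment(sim_params(),
                                                          seed = 1L)
    cache
  }
})

## TSS anchor frame for a gene table
tss_anchors <- function(genes) {
  data.frame(chrom = genes$chrom, pos = genes$tss, strand = genes$strand,
             name = genes$name, start = genes$start, end = genes$end,
             stringsAsFactors = FALSE)
}
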
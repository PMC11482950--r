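#' Simulation parameters for the twin-supercoiled-domain generator
#'
#' Defaults describe a desk-scale budding-yeast-like genome: 4 chromosomes
#' of 300 kb, log-normal ORF lengths around 1.4 kb, intergenic gaps around
#' 400 bp, nucleosome-phased accessibility with an NFR bump upstream of
#' each TSS and a damped 160-bp periodic signal in gene bodies, and a
#' twin-supercoiled-domain torsion field: (-) torsion behind promoters and
#' (+) torsion past terminators, confined to 1-2 kb by an exponential
#' decay (scale 750 bp), with amplitude scaling with expression and, at
#' terminators, with gene length. The crosslinking response to torsion is
#' linear (coefficient `kappa`) with rates clipped at zero. Insulator-bound
#' divergent promoter pairs (TFO/STM classes) have their torsion tails
#' hard-truncated at the intergenic midpoint.
#'
#' `depth_icl_per_kb * depth_scale` sets the expected ICL count per kb:
#' the physical working density (0.2 ICLs/kb per cell population) times a
#' desk-scale factor standing in for the genome-equivalents a real library
#' pools over many cells, so a 1.2-Mb synthetic genome carries comparable
#' information to a full-depth genome-wide run. `nuc_amp`, `nfr_amp`,
#' `t_tss` and `kappa` are calibrated together so that the with-torsion
#' TSS composite has about 5x the peak-to-valley amplitude of the torsion
#' signal, the regime the baseline subtraction operates in.
#'
#' @param ... overrides of any default parameter.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(...) {
  p <- list(
    ## genome
    n_chrom = 4L, chrom_length = 300000, bin_width = 10L,
    ## gene layout
    gene_len_meanlog = log(1400), gene_len_sdlog = 0.45,
    gap_meanlog = log(400), gap_sdlog = 0.6, min_gap = 100,
    strand_prob = 0.5,
    ## expression (log-normal, mean 1; light tail keeps the linear
    ## torsion response within its validity regime, |kappa*t| <~ 1)
    expr_meanlog = -0.18, expr_sdlog = 0.6,
    ## promoter classes
    class_probs = c(UNB = 0.5, TFO = 0.3, STM = 0.2),
    ## accessibility
    a0 = 0.5, nfr_amp = 0.45, nfr_offset = -80, nfr_width = 60,
    nuc_amp = 0.24, nuc_period = 160, phase_decay = 800,
    access_floor = 0.02,
    ## torsion field
    t_tss = 0.25, t_tes = 0.25, c_len = 1e-4, lambda_t = 750,
    kappa = 0.5,
    ## insulators
    insulator_prob = c(UNB = 0, TFO = 1, STM = 1),
    insulator_leak = 0,
    ## sequence preference (smooth log-normal field)
    seq_logsd = 0.2, seq_smooth_bins = 21L,
    ## sampling depth and replicates
    depth_icl_per_kb = 0.2, depth_scale = 1000,
    n_reps_with = 2L, n_reps_without = 3L,
    ## companion fixtures
    mrna_noise_sd = 0.05, cohesin_height = 1, cohesin_width = 150,
    loop_score_scale = 1, loop_score_noise = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$a0 > 0, p$a0 <= 1, p$lambda_t > 0, p$phase_decay > 0,
            p$depth_icl_per_kb > 0, p$depth_scale > 0,
            p$nuc_amp >= 0, p$nfr_amp >= 0, p$t_tss >= 0, p$t_tes >= 0)
  class(p) <- "sim_params"
  p
}

## substream seeding: one user seed, fixed offsets per stage, kept < 2^31
substream <- function(seed, offset) {
  set.seed((as.integer(seed) %% 1000000000L) + offset)
}

#' Generate the synthetic genome and gene annotation
#'
#' Lays non-overlapping ORFs left to right on each chromosome with
#' log-normal lengths and gaps, i.i.d. strands, log-normal expression and
#' categorical promoter classes. Deterministic given the seed.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed (annotation substream).
#' @return A list (`synthetic_truth` skeleton) with `index`
#'   ([genome_index()]) and `genes` (gene table).
#' @export
make_genome_and_genes <- function(params, seed = 1L) {
  substream(seed, 1L)
  index <- genome_index(sprintf("chrS%d", seq_len(params$n_chrom)),
                        rep(params$chrom_length, params$n_chrom),
                        params$bin_width)
  rows <- list()
  for (ch in index$chrom_names) {
    L <- index$chrom_lengths[[ch]]
    pos <- max(params$min_gap,
               round(stats::rlnorm(1, params$gap_meanlog, params$gap_sdlog)))
    placed <- 0L
    repeat {
      len <- round(stats::rlnorm(1, params$gene_len_meanlog,
                                 params$gene_len_sdlog))
      len <- max(len, 3 * params$bin_width)
      if (pos + len + params$min_gap > L) break
      strand <- if (stats::runif(1) < params$strand_prob) "+" else "-"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = pos, end = pos + len, strand = strand,
        stringsAsFactors = FALSE)
      placed <- placed + 1L
      gap <- max(params$min_gap,
                 round(stats::rlnorm(1, params$gap_meanlog,
                                     params$gap_sdlog)))
      pos <- pos + len + gap
    }
    if (placed == 0L)
      stop(sprintf("chromosome %s too short for a single gene", ch))
  }
  df <- do.call(rbind, rows)
  df$name <- sprintf("SYN%04d", seq_len(nrow(df)))
  genes <- genes_from_intervals(
    interval_set(df$chrom, df$start, df$end, name = df$name,
                 strand = df$strand))
  genes$expression <- stats::rlnorm(nrow(genes), params$expr_meanlog,
                                    params$expr_sdlog)
  genes$class <- sample(names(params$class_probs), nrow(genes),
                        replace = TRUE, prob = params$class_probs)
  list(index = index, genes = genes)
}

## signed distance of bin centers from the TSS in the direction of
## transcription; helper shared by the field builders
bin_centers <- function(index, ch) {
  w <- index$bin_width
  n <- ceiling(index$chrom_lengths[[ch]] / w)
  (seq_len(n) - 1) * w + w / 2
}

#' Deterministic accessibility field
#'
#' `a(x) = a0 + NFR bump + damped nucleosome periodicity`: a Gaussian
#' accessibility bump centered `nfr_offset` bp from each TSS (upstream for
#' the default negative offset) plus, inside each gene body,
#' `nuc_amp * exp(-d/phase_decay) * cos(2*pi*d/nuc_period)` at distance
#' `d` downstream of the TSS, oriented per strand and clipped to
#' `[access_floor, 1]`.
#'
#' @param truth output of [make_genome_and_genes()].
#' @param params a [sim_params()].
#' @return A [genomic_track()] of accessibilities in (0, 1].
#' @export
accessibility_field <- function(truth, params) {
  index <- truth$index
  values <- lapply(n_bins(index), function(n) rep(params$a0, n))
  genes <- truth$genes
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    cx <- bin_centers(index, ch)
    sgn <- if (genes$strand[i] == "+") 1 else -1
    d <- sgn * (cx - genes$tss[i])     # bp downstream of TSS (signed)
    contrib <- params$nfr_amp *
      exp(-(d - params$nfr_offset)^2 / (2 * params$nfr_width^2))
    body <- d >= 0 & d < genes$size[i]
    contrib[body] <- contrib[body] + params$nuc_amp *
      exp(-d[body] / params$phase_decay) *
      cos(2 * pi * d[body] / params$nuc_period)
    values[[ch]] <- values[[ch]] + contrib
  }
  values <- lapply(values, function(v) pmin(pmax(v, params$access_floor), 1))
  genomic_track(index, values)
}

## divergent pairs with sampled insulators; returns data frame
## (chrom, left_idx, right_idx, mid) of insulated pairs
sample_insulators <- function(truth, params, seed) {
  substream(seed, 2L)
  pairs <- classify_gene_pairs(truth$genes)
  div <- pairs[pairs$configuration == "divergent" &
                 pairs$gap_end > pairs$gap_start, , drop = FALSE]
  if (!nrow(div)) return(div[, c("chrom", "left_idx", "right_idx")])
  cls <- truth$genes$class
  pr <- pmax(params$insulator_prob[cls[div$left_idx]],
             params$insulator_prob[cls[div$right_idx]])
  pr[is.na(pr)] <- 0
  bound <- stats::runif(nrow(div)) < pr
  ins <- div[bound, , drop = FALSE]
  ins$mid <- (ins$gap_start + ins$gap_end) / 2
  ins
}

#' Twin-supercoiled-domain torsion field
#'
#' Each gene contributes `+t_tss * E * exp(-d/lambda_t)` at distance `d`
#' upstream of its TSS ((-) torsion behind the promoter) and
#' `-(t_tes + c_len * size) * E * exp(-d/lambda_t)` downstream of its TES
#' ((+) torsion past the terminator, growing with gene length).
#' Contributions sum over genes. For divergent pairs carrying an
#' insulator, each promoter's upstream tail is truncated at the
#' intergenic midpoint (multiplied by `insulator_leak` beyond it).
#' Positive field values mean (-) / underwound torsion.
#'
#' @param truth output of [make_genome_and_genes()].
#' @param params a [sim_params()].
#' @param seed seed for the insulator-assignment substream.
#' @return A list: `track` (the torsion field as a [genomic_track()]) and
#'   `insulators` (data frame of insulated divergent pairs with midpoint
#'   coordinates).
#' @export
torsion_field <- function(truth, params, seed = 1L) {
  index <- truth$index
  ins <- sample_insulators(truth, params, seed)
  values <- lapply(n_bins(index), function(n) numeric(n))
  genes <- truth$genes
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    cx <- bin_centers(index, ch)
    sgn <- if (genes$strand[i] == "+") 1 else -1
    d_tss <- sgn * (cx - genes$tss[i])   # >0 downstream of TSS
    d_tes <- sgn * (cx - genes$tes[i])   # >0 downstream of TES
    up <- d_tss <= 0
    promoter <- numeric(length(cx))
    promoter[up] <- params$t_tss * genes$expression[i] *
      exp(d_tss[up] / params$lambda_t)
    ## insulator truncation of this promoter's upstream tail
    k <- which((ins$left_idx == i | ins$right_idx == i))
    for (j in k) {
      beyond <- if (genes$strand[i] == "+") cx < ins$mid[j]
                else cx > ins$mid[j]
      promoter[beyond] <- promoter[beyond] * params$insulator_leak
    }
    amp_tes <- (params$t_tes + params$c_len * genes$size[i]) *
      genes$expression[i]
    down <- d_tes >= 0
    terminator <- numeric(length(cx))
    terminator[down] <- -amp_tes * exp(-d_tes[down] / params$lambda_t)
    values[[ch]] <- values[[ch]] + promoter + terminator
  }
  list(track = genomic_track(index, values), insulators = ins)
}

#' Smooth log-normal sequence-preference field
#'
#' Gaussian white noise per bin, moving-average smoothed and rescaled to
#' standard deviation `seq_logsd` in log space, then exponentiated.
#'
#' @param truth output of [make_genome_and_genes()].
#' @param params a [sim_params()].
#' @param seed seed (sequence substream).
#' @return A [genomic_track()] of positive multiplicative preferences.
#' @export
sequence_field <- function(truth, params, seed = 1L) {
  substream(seed, 3L)
  index <- truth$index
  k <- params$seq_smooth_bins
  values <- lapply(n_bins(index), function(n) {
    z <- stats::rnorm(n)
    zs <- stats::filter(z, rep(1 / k, k), sides = 2)
    zs[is.na(zs)] <- 0
    zs <- as.numeric(zs)
    s <- stats::sd(zs)
    if (s > 0) zs <- zs / s * params$seq_logsd
    exp(zs)
  })
  genomic_track(index, values)
}

#' Sample ICL count tracks from the truth fields
#'
#' Per-bin Poisson rates follow the linear torsion response:
#' `rate_with = D * s * a * max(0, 1 + kappa * t)`,
#' `rate_without = D * s * a`, `rate_purified = D * s`, where each
#' condition's `D` is set so its genome-mean rate equals the configured
#' depth (mirroring the matched crosslink densities of the conditions).
#' Counts are independent Poisson draws per bin, replicate and condition.
#'
#' @param truth list with `index`, plus `access`, `torsion`, `seqpref`
#'   tracks (see [simulate_tmp_experiment()]).
#' @param params a [sim_params()].
#' @param seed seed (sampling substream).
#' @return A list: `with` (list of `n_reps_with` count tracks), `without`
#'   (list of `n_reps_without`), `purified` (one track), and
#'   `n_clipped_bins` (bins where `1 + kappa*t < 0` was clipped to 0).
#' @export
sample_icl_tracks <- function(truth, params, seed = 1L) {
  substream(seed, 4L)
  index <- truth$index
  depth_bin <- params$depth_icl_per_kb * params$depth_scale *
    index$bin_width / 1000
  s <- truth$seqpref$values
  a <- truth$access$values
  t <- truth$torsion$values
  resp <- lapply(t, function(v) pmax(0, 1 + params$kappa * v))
  n_clipped <- sum(vapply(t, function(v)
    sum(1 + params$kappa * v < 0), 1L))
  rate_with <- Map(function(si, ai, ri) si * ai * ri, s, a, resp)
  rate_wo <- Map(function(si, ai) si * ai, s, a)
  rate_pur <- s
  scale_to_depth <- function(rates) {
    m <- mean(unlist(rates, use.names = FALSE))
    lapply(rates, function(r) r / m * depth_bin)
  }
  rate_with <- scale_to_depth(rate_with)
  rate_wo <- scale_to_depth(rate_wo)
  rate_pur <- scale_to_depth(rate_pur)
  draw <- function(rates) {
    genomic_track(index, lapply(rates, function(r)
      as.numeric(stats::rpois(length(r), r))))
  }
  list(
    with = lapply(seq_len(params$n_reps_with), function(i) draw(rate_with)),
    without = lapply(seq_len(params$n_reps_without),
                     function(i) draw(rate_wo)),
    purified = draw(rate_pur),
    rates = list(with = rate_with, without = rate_wo, purified = rate_pur),
    n_clipped_bins = n_clipped)
}

#' Companion mRNA, cohesin and loop fixtures
#'
#' Strand-specific mRNA tracks carry each gene's true expression (plus
#' optional noise) over its ORF on the strand-appropriate track, so
#' [expression_from_mrna()] recovers the truth. Loops are planted between
#' consecutive convergent-pair intergenic midpoints, scored by the mean
#' (+)-torsion magnitude at their two boundaries; the cohesin track has a
#' Gaussian bump at every loop boundary with height proportional to the
#' loop score.
#'
#' @param truth list with `index`, `genes` and `torsion` (see
#'   [simulate_tmp_experiment()]).
#' @param params a [sim_params()].
#' @param seed seed (fixture substream).
#' @return A list: `mrna_plus`, `mrna_minus`, `cohesin` tracks and
#'   `loops` (loop table). A warning is issued when no convergent pairs
#'   exist (zero loops).
#' @export
synthetic_mrna_and_chip <- function(truth, params, seed = 1L) {
  substream(seed, 5L)
  index <- truth$index
  genes <- truth$genes
  w <- index$bin_width
  plus <- lapply(n_bins(index), function(n) numeric(n))
  minus <- lapply(n_bins(index), function(n) numeric(n))
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    k <- seq.int(floor(genes$start[i] / w) + 1, ceiling(genes$end[i] / w))
    val <- genes$expression[i] +
      if (params$mrna_noise_sd > 0)
        stats::rnorm(length(k), 0, params$mrna_noise_sd) else 0
    if (genes$strand[i] == "+") plus[[ch]][k] <- plus[[ch]][k] + val
    else minus[[ch]][k] <- minus[[ch]][k] + val
  }
  ## loops between consecutive convergent-gap midpoints
  pairs <- classify_gene_pairs(genes)
  conv <- pairs[pairs$configuration == "convergent" &
                  pairs$gap_end > pairs$gap_start, , drop = FALSE]
  loops <- list()
  tors <- truth$torsion
  for (ch in unique(conv$chrom)) {
    mids <- sort((conv$gap_start[conv$chrom == ch] +
                    conv$gap_end[conv$chrom == ch]) / 2)
    if (length(mids) < 2) next
    for (j in seq_len(length(mids) - 1)) {
      bt <- function(pos) abs(tors$values[[ch]][pos_to_bin(index, pos)])
      score <- params$loop_score_scale * (bt(mids[j]) + bt(mids[j + 1])) / 2
      if (params$loop_score_noise > 0)
        score <- score + stats::rnorm(1, 0, params$loop_score_noise)
      loops[[length(loops) + 1L]] <- data.frame(
        chrom = ch, L = mids[j], R = mids[j + 1], score = score,
        stringsAsFactors = FALSE)
    }
  }
  loops <- if (length(loops)) do.call(rbind, loops) else {
    warning("no convergent gene pairs: zero loops planted")
    data.frame(chrom = character(), L = numeric(), R = numeric(),
               score = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(loops)) {
    loops$name <- sprintf("loop_%03d", seq_len(nrow(loops)))
    loops$adjusted <- FALSE
  } else {
    loops$name <- character(0)
    loops$adjusted <- logical(0)
  }
  cohesin <- lapply(n_bins(index), function(n) numeric(n))
  if (nrow(loops)) {
    for (i in seq_len(nrow(loops))) {
      ch <- loops$chrom[i]
      cx <- bin_centers(index, ch)
      h <- params$cohesin_height * loops$score[i]
      for (b in c(loops$L[i], loops$R[i]))
        cohesin[[ch]] <- cohesin[[ch]] +
          h * exp(-(cx - b)^2 / (2 * params$cohesin_width^2))
    }
  }
  list(mrna_plus = genomic_track(index, plus),
       mrna_minus = genomic_track(index, minus),
       cohesin = genomic_track(index, cohesin),
       loops = loops)
}

#' Run the full synthetic experiment
#'
#' Generates annotation, truth fields (accessibility, torsion, sequence
#' preference), Poisson-sampled ICL count tracks for the three conditions,
#' and the companion mRNA/cohesin/loop fixtures. All randomness flows from
#' one seed through named substreams, so each stage is independently
#' reproducible.
#'
#' @param params a [sim_params()] (defaults if omitted).
#' @param seed integer master seed.
#' @return A list of class `tmp_simulation` with elements `params`,
#'   `seed`, `truth` (index, genes, access/torsion/seqpref tracks,
#'   insulators), `tracks` (with/without/purified), and `fixtures`
#'   (mRNA, cohesin, loops).
#' @export
simulate_tmp_experiment <- function(params = sim_params(), seed = 1L) {
  truth <- make_genome_and_genes(params, seed)
  tf <- torsion_field(truth, params, seed)
  truth$torsion <- tf$track
  truth$insulators <- tf$insulators
  truth$access <- accessibility_field(truth, params)
  truth$seqpref <- sequence_field(truth, params, seed)
  tracks <- sample_icl_tracks(truth, params, seed)
  fixtures <- synthetic_mrna_and_chip(truth, params, seed)
  structure(list(params = params, seed = seed, truth = truth,
                 tracks = tracks, fixtures = fixtures),
            class = "tmp_simulation")
}

#' @export
print.tmp_simulation <- function(x, ...) {
  cat(sprintf(paste0("tmp_simulation: %d genes on %d chromosome(s), ",
                     "%d+%d ICL replicates, %d loops (seed %d)\n"),
              nrow(x$truth$genes), length(x$truth$index$chrom_names),
              length(x$tracks$with), length(x$tracks$without),
              nrow(x$fixtures$loops), x$seed))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits bedGraph tracks (ICL replicates, purified DNA, mRNA, cohesin,
#' truth fields), BED6 gene annotation, promoter-class TSV, loop TSV, a
#' chromosome-sizes file, and a JSON manifest recording parameters, seed
#' and every file written. Byte-identical across runs with the same seed.
#'
#' @param sim a `tmp_simulation` from [simulate_tmp_experiment()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- sim$truth$index
  files <- list()
  put_track <- function(track, name) {
    path <- file.path(dir, paste0(name, ".bedGraph"))
    write_bedgraph(track, path)
    files[[name]] <<- basename(path)
  }
  for (i in seq_along(sim$tracks$with))
    put_track(sim$tracks$with[[i]], sprintf("icl_with_torsion_rep%d", i))
  for (i in seq_along(sim$tracks$without))
    put_track(sim$tracks$without[[i]], sprintf("icl_without_torsion_rep%d", i))
  put_track(sim$tracks$purified, "icl_purified")
  put_track(sim$fixtures$mrna_plus, "mrna_plus")
  put_track(sim$fixtures$mrna_minus, "mrna_minus")
  put_track(sim$fixtures$cohesin, "cohesin")
  put_track(sim$truth$torsion, "truth_torsion")
  put_track(sim$truth$access, "truth_accessibility")
  g <- sim$truth$genes
  write_bed(interval_set(g$chrom, g$start, g$end, name = g$name,
                         score = 0, strand = g$strand),
            file.path(dir, "genes.bed"))
  files$genes <- "genes.bed"
  utils::write.table(data.frame(g$name, g$class),
                     file.path(dir, "promoter_classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  files$classes <- "promoter_classes.tsv"
  write_loops(sim$fixtures$loops, file.path(dir, "loops.tsv"))
  files$loops <- "loops.tsv"
  utils::write.table(
    data.frame(index$chrom_names, unname(index$chrom_lengths)),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  files$chrom_sizes <- "chrom.sizes"
  truth_tab <- g[, c("name", "chrom", "start", "end", "strand",
                     "expression", "class", "size")]
  utils::write.table(truth_tab, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files$truth_genes <- "truth_genes.tsv"
  ## named atomic parameters (class/insulator probabilities) go out as
  ## JSON objects so their names survive the round trip
  manifest <- list(seed = sim$seed,
                   params = lapply(unclass(sim$params), function(x)
                     if (is.atomic(x) && !is.null(names(x))) as.list(x)
                     else x),
                   n_genes = nrow(g),
                   n_loops = nrow(sim$fixtures$loops),
                   files = files)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest_path)
}
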
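test_that("annotation generation is deterministic and obeys its parameters", {
  p <- sim_params(n_chrom = 1L, chrom_length = 100000)
  t1 <- make_genome_and_genes(p, seed = 3)
  t2 <- make_genome_and_genes(p, seed = 3)
  expect_identical(t1$genes, t2$genes)
  expect_true(nrow(t1$genes) > 10)
  ## ORFs are non-overlapping in coordinate order
  g <- t1$genes[order(t1$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  ## a chromosome too short for one gene errors
  expect_error(make_genome_and_genes(sim_params(n_chrom = 1L,
                                                chrom_length = 600),
                                     seed = 1),
               "too short")
})

test_that("gene lengths follow the configured log-normal law", {
  p <- sim_params(n_chrom = 4L, chrom_length = 400000)
  truth <- make_genome_and_genes(p, seed = 11)
  sizes <- truth$genes$size
  n <- length(sizes)
  expect_true(n >= 500)
  target_mean <- exp(p$gene_len_meanlog + p$gene_len_sdlog^2 / 2)
  se <- sd(sizes) / sqrt(n)
  expect_lt(abs(mean(sizes) - target_mean), 3 * se)
})

test_that("accessibility field carries the NFR bump and 160-bp periodicity", {
  p <- sim_params(n_chrom = 1L, chrom_length = 100000)
  truth <- make_genome_and_genes(p, seed = 7)

  ## flat field when both modulations are off
  p0 <- sim_params(n_chrom = 1L, chrom_length = 100000,
                   nuc_amp = 0, nfr_amp = 0)
  a0 <- accessibility_field(truth, p0)
  expect_true(all(unlist(a0$values) == p0$a0))

  ## gene-body autocorrelation peaks at the nucleosome repeat length
  a <- accessibility_field(truth, p)
  g <- head(truth$genes[truth$genes$size >= 1500, ], 20)
  expect_gte(nrow(g), 5)
  lags <- vapply(seq_len(nrow(g)), function(i) {
    k <- seq(floor(g$start[i] / 10) + 1, ceiling(g$end[i] / 10))
    v <- a$values[[g$chrom[i]]][k]
    if (g$strand[i] == "-") v <- rev(v)
    profile_periodicity(v, 10)
  }, numeric(1))
  expect_true(median(lags, na.rm = TRUE) >= 150 &&
                median(lags, na.rm = TRUE) <= 170)

  ## a minus-strand gene's pattern mirrors a plus-strand gene's
  idx <- tiny_index(len = 20000)
  mk <- function(strand, start, end) {
    path <- tempfile(fileext = ".bed")
    write_bed(interval_set("chrI", start, end, name = "g", score = 0,
                           strand = strand), path)
    gg <- read_genes(path)
    gg$expression <- 1; gg$class <- "UNB"
    list(index = idx, genes = gg)
  }
  ap <- accessibility_field(mk("+", 8000, 10000), p)
  am <- accessibility_field(mk("-", 10000, 12000), p)
  ## + gene TSS at 8000 (bin 801); - gene TSS at 12000 (bin 1200)
  plus_win <- ap$values$chrI[781:840]
  minus_win <- am$values$chrI[1161:1220]
  expect_equal(plus_win, rev(minus_win))
})

test_that("the torsion field follows the twin-supercoiled-domain closed form", {
  idx_path <- tempfile(fileext = ".bed")
  ## TSS at 10005 = a bin center, so field values can be checked exactly
  write_bed(interval_set("chrI", 10005, 12005, name = "g", score = 0,
                         strand = "+"), idx_path)
  g <- read_genes(idx_path)
  g$expression <- 2; g$class <- "UNB"
  truth <- list(index = tiny_index(len = 30000), genes = g)
  p <- sim_params(n_chrom = 1L, chrom_length = 30000)
  tf <- torsion_field(truth, p, seed = 1)
  v <- tf$track$values$chrI
  lam <- p$lambda_t
  ## at one decay length upstream of the TSS: T_tss * E * exp(-1)
  bin_at <- function(pos) floor(pos / 10) + 1
  expect_equal(v[bin_at(10005 - lam)], p$t_tss * 2 * exp(-1))
  expect_equal(v[bin_at(10005)], p$t_tss * 2)
  ## downstream of the TES: -(t_tes + c_len * size) * E * exp(-d/lam)
  amp <- (p$t_tes + p$c_len * 2000) * 2
  expect_equal(v[bin_at(12005 + lam)], -amp * exp(-1))
  ## inside the body (away from both anchors): no contribution
  expect_equal(v[bin_at(11005)], 0)

  ## zero expression -> identically zero field
  g0 <- g; g0$expression <- 0
  tf0 <- torsion_field(list(index = truth$index, genes = g0), p, seed = 1)
  expect_true(all(tf0$track$values$chrI == 0))
})

test_that("insulators truncate promoter tails between divergent genes", {
  mk_truth <- function(classes) {
    path <- tempfile(fileext = ".bed")
    write_bed(interval_set(rep("chrI", 2), c(5000, 12000), c(8000, 15000),
                           name = c("L", "R"), score = c(0, 0),
                           strand = c("-", "+")), path)
    g <- read_genes(path)
    g$expression <- 1.5; g$class <- classes
    list(index = tiny_index(len = 20000), genes = g)
  }
  p <- sim_params(n_chrom = 1L, chrom_length = 20000)
  unb <- torsion_field(mk_truth(c("UNB", "UNB")), p, seed = 2)
  ins <- torsion_field(mk_truth(c("TFO", "TFO")), p, seed = 2)
  expect_equal(nrow(unb$insulators), 0L)
  expect_equal(nrow(ins$insulators), 1L)
  mid_bin <- floor(10000 / 10) + 1
  ## midgap magnitude strictly larger without the insulator
  expect_gt(unb$track$values$chrI[mid_bin], 0)
  expect_lt(abs(ins$track$values$chrI[mid_bin]),
            abs(unb$track$values$chrI[mid_bin]))
  ## just left of the insulator only the left promoter's own tail
  ## survives (the right promoter's tail is blocked at the midpoint)
  cx <- 9995
  expect_equal(ins$track$values$chrI[floor(cx / 10) + 1],
               p$t_tss * 1.5 * exp(-(cx - 8000) / p$lambda_t))
  ## and just right of it, only the right promoter's tail
  cx2 <- 10005
  expect_equal(ins$track$values$chrI[floor(cx2 / 10) + 1],
               p$t_tss * 1.5 * exp(-(12000 - cx2) / p$lambda_t))
})

test_that("sampled counts are Poisson with the configured rates and depth", {
  p <- sim_params(n_chrom = 1L, chrom_length = 50000)
  truth <- make_genome_and_genes(p, seed = 13)
  tf <- torsion_field(truth, p, seed = 13)
  truth$torsion <- tf$track
  truth$access <- accessibility_field(truth, p)
  truth$seqpref <- sequence_field(truth, p, seed = 13)
  sam <- sample_icl_tracks(truth, p, seed = 13)

  ## expected count per bin equals its rate: empirical mean over 10,000
  ## replicate draws within 3 SE
  rates <- sam$rates$without
  nrep <- 10000
  set.seed(99)
  bins <- sample(length(rates[[1]]), 5)
  for (b in bins) {
    lam <- rates[[1]][b]
    draws <- rpois(nrep, lam)
    se <- sqrt(lam / nrep)
    expect_lt(abs(mean(draws) - lam), 3 * se + 1e-9)
  }

  ## total expected ICLs/kb equals the configured depth
  depth_bin <- p$depth_icl_per_kb * p$depth_scale * 10 / 1000
  expect_equal(mean(unlist(sam$rates$with)), depth_bin, tolerance = 1e-9)
  expect_equal(mean(unlist(sam$rates$without)), depth_bin, tolerance = 1e-9)

  ## kappa = 0: with- and without-torsion rates identical
  p0 <- sim_params(n_chrom = 1L, chrom_length = 50000, kappa = 0)
  truth$torsion <- torsion_field(truth, p0, seed = 13)$track
  sam0 <- sample_icl_tracks(truth, p0, seed = 13)
  expect_equal(sam0$rates$with, sam0$rates$without)
})

test_that("mRNA fixtures return each gene's true expression exactly", {
  p <- sim_params(n_chrom = 1L, chrom_length = 80000, mrna_noise_sd = 0)
  truth <- make_genome_and_genes(p, seed = 17)
  truth$torsion <- torsion_field(truth, p, seed = 17)$track
  fix <- synthetic_mrna_and_chip(truth, p, seed = 17)
  g <- expression_from_mrna(fix$mrna_plus, fix$mrna_minus, truth$genes)
  expect_equal(g$expression, truth$genes$expression, tolerance = 1e-12)
})

test_that("planted loops score with midgap torsion and sit on cohesin apices", {
  p <- sim_params(n_chrom = 2L, chrom_length = 150000,
                  loop_score_noise = 0)
  truth <- make_genome_and_genes(p, seed = 19)
  truth$torsion <- torsion_field(truth, p, seed = 19)$track
  fix <- synthetic_mrna_and_chip(truth, p, seed = 19)
  loops <- fix$loops
  expect_gt(nrow(loops), 3)
  ## score is monotone in the mean boundary torsion magnitude
  bt <- vapply(seq_len(nrow(loops)), function(i) {
    v <- truth$torsion$values[[loops$chrom[i]]]
    (abs(v[floor(loops$L[i] / 10) + 1]) +
       abs(v[floor(loops$R[i] / 10) + 1])) / 2
  }, numeric(1))
  expect_equal(cor(loops$score, bt, method = "spearman"), 1)
  ## boundaries coincide with cohesin bump apices: snapping is a no-op
  peaks <- call_peaks_simple(fix$cohesin, min_height = 1e-6,
                             min_separation_bp = 0)
  snapped <- adjust_boundaries(loops, peaks, max_dist_bp = 500)
  expect_true(all(abs(snapped$L - loops$L) <= 5))
  expect_true(all(abs(snapped$R - loops$R) <= 5))
})

test_that("strand probability 1 gives no divergent or convergent pairs", {
  p <- sim_params(n_chrom = 1L, chrom_length = 80000, strand_prob = 1)
  truth <- make_genome_and_genes(p, seed = 23)
  pairs <- classify_gene_pairs(truth$genes)
  expect_equal(sum(pairs$configuration != "codirectional"), 0L)
})

test_that("full simulation is reproducible and writes a faithful manifest", {
  p <- sim_params(n_chrom = 1L, chrom_length = 60000)
  s1 <- simulate_tmp_experiment(p, seed = 29)
  s2 <- simulate_tmp_experiment(p, seed = 29)
  expect_identical(s1$tracks$with[[1]]$values, s2$tracks$with[[1]]$values)
  expect_identical(s1$truth$genes, s2$truth$genes)

  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  ## written tracks read back to the originals
  idx <- read_chrom_sizes(file.path(d1, "chrom.sizes"))
  back <- read_bedgraph(file.path(d1, "icl_with_torsion_rep1.bedGraph"), idx)
  expect_equal(back$values, s1$tracks$with[[1]]$values)
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(manifest$n_genes, nrow(s1$truth$genes))
  expect_equal(manifest$seed, 29)
})
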
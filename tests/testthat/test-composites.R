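test_that("anchored matrices orient rows along transcription", {
  idx <- tiny_index(len = 10000)
  v <- seq(0.001, 1, length.out = 1000)   # strictly increasing along chrI
  tr <- genomic_track(idx, list(chrI = v))

  ## constant track: every entry the constant, zero column variance
  const <- genomic_track(idx, list(chrI = rep(2.5, 1000)))
  anch <- data.frame(chrom = "chrI", pos = c(3000, 7000),
                     strand = c("+", "-"))
  m <- anchored_matrix(const, anch, flank_bp = 500L)
  expect_true(all(m$values == 2.5))
  expect_equal(unname(apply(m$values, 2, var)), rep(0, 100))

  ## minus-strand row: entry at column +x equals track value at anchor-x
  m2 <- anchored_matrix(tr, anch, flank_bp = 500L)
  plus_row <- m2$values[1, ]
  minus_row <- m2$values[2, ]
  xs <- m2$positions
  for (j in c(1, 25, 60, 100)) {
    expect_equal(plus_row[j], v[floor((3000 + xs[j]) / 10) + 1])
    expect_equal(minus_row[j], v[floor((7000 - xs[j]) / 10) + 1])
  }
  ## reversing a minus-strand row twice is the identity
  expect_equal(rev(rev(minus_row)), minus_row)
})

test_that("beyond-TES exclusion masks columns past each row's own gene end", {
  idx <- tiny_index(len = 10000)
  tr <- genomic_track(idx, list(chrI = rep(1, 1000)))
  anch <- data.frame(chrom = "chrI", pos = 3000, strand = "+",
                     start = 3000, end = 3500)
  m <- anchored_matrix(tr, anch, flank_bp = 1000L, exclusion = "beyond_tes")
  expect_true(all(is.na(m$values[1, m$positions > 500])))
  expect_true(all(!is.na(m$values[1, m$positions <= 500])))

  ## beyond-TSS exclusion is the mirror for TES anchors
  anch2 <- data.frame(chrom = "chrI", pos = 3500, strand = "+",
                      start = 3000, end = 3500)
  m2 <- anchored_matrix(tr, anch2, flank_bp = 1000L,
                        exclusion = "beyond_tss")
  expect_true(all(is.na(m2$values[1, m2$positions < -500])))
})

test_that("off-chromosome bins are missing and bad anchors are skipped", {
  idx <- tiny_index(len = 1000)
  tr <- genomic_track(idx, list(chrI = rep(1, 100)))
  m <- anchored_matrix(tr, data.frame(chrom = "chrI", pos = 50,
                                      strand = "+"), flank_bp = 200L)
  expect_true(any(is.na(m$values)))
  m2 <- anchored_matrix(tr, data.frame(chrom = c("chrI", "chrZ"),
                                       pos = c(500, 100),
                                       strand = c("+", "+")),
                        flank_bp = 100L)
  expect_equal(nrow(m2$values), 1L)
  expect_equal(m2$n_skipped, 1L)
})

test_that("scaled matrices preserve signal amplitude, never sum", {
  idx <- tiny_index(len = 10000)
  tr <- genomic_track(idx, list(chrI = rep(3, 1000)))
  regions <- data.frame(chrom = "chrI", start = c(2000, 5000),
                        end = c(2600, 8200), strand = c("+", "+"))
  m <- scaled_region_matrix(tr, regions, flank_bp = 0L, n_body_bins = 50L)
  expect_equal(as.numeric(m$values), rep(3, length(m$values)),
               tolerance = 1e-12)

  ## 20 source bins of a linear ramp -> 10 body columns = pairwise means
  ramp <- genomic_track(idx, list(chrI = c(1:20, rep(0, 980))))
  mr <- scaled_region_matrix(ramp, data.frame(chrom = "chrI", start = 0,
                                              end = 200, strand = "+"),
                             flank_bp = 0L, n_body_bins = 10L)
  expect_equal(unname(mr$values[1, ]),
               colMeans(matrix(1:20, nrow = 2)))

  ## identity resampling when n_body_bins equals the source bin count
  set.seed(9)
  vv <- runif(30)
  src <- genomic_track(idx, list(chrI = c(vv, rep(0, 970))))
  mi <- scaled_region_matrix(src, data.frame(chrom = "chrI", start = 0,
                                             end = 300, strand = "+"),
                             flank_bp = 0L, n_body_bins = 30L)
  expect_equal(unname(mi$values[1, ]), vv)
})

test_that("per-row body means equal the source-region means", {
  set.seed(19)
  idx <- tiny_index(len = 20000)
  tr <- genomic_track(idx, list(chrI = runif(2000)))
  regions <- data.frame(chrom = "chrI",
                        start = c(1000, 4000, 9000),
                        end = c(1000 + 700, 4000 + 1300, 9000 + 2000),
                        strand = c("+", "-", "+"))
  m <- scaled_region_matrix(tr, regions, flank_bp = 200L,
                            n_body_bins = 37L)
  body_cols <- seq(m$n_flank_bins + 1, m$n_flank_bins + m$n_body_bins)
  for (i in 1:3) {
    bins <- seq(floor(regions$start[i] / 10) + 1,
                ceiling(regions$end[i] / 10))
    expect_equal(mean(m$values[i, body_cols]), mean(tr$values$chrI[bins]),
                 tolerance = 1e-9)
  }
})

test_that("minus-strand scaled rows are reversed end to end", {
  idx <- tiny_index(len = 10000)
  v <- seq_len(1000) / 100
  tr <- genomic_track(idx, list(chrI = v))
  reg <- data.frame(chrom = "chrI", start = 3000, end = 3500)
  fwd <- scaled_region_matrix(tr, transform(reg, strand = "+"),
                              flank_bp = 100L, n_body_bins = 50L)
  rev_ <- scaled_region_matrix(tr, transform(reg, strand = "-"),
                               flank_bp = 100L, n_body_bins = 50L)
  expect_equal(unname(rev_$values[1, ]), rev(unname(fwd$values[1, ])))
})

test_that("composite profiles report mean, SEM and n per column", {
  idx <- tiny_index(len = 1000)
  tr <- genomic_track(idx, list(chrI = rep(c(1, 3), each = 50)))
  m <- list(values = rbind(c(1, 2), c(3, 4)), positions = c(0, 10),
            row_labels = c("a", "b"), mode = "anchored")
  class(m) <- "composite_matrix"
  prof <- composite_profile(m)
  expect_equal(prof$mean, c(2, 3))
  expect_equal(prof$sem, c(1, 1))
  expect_equal(prof$n, c(2L, 2L))

  ## single row: SEM 0 by convention
  m1 <- m; m1$values <- m$values[1, , drop = FALSE]
  expect_equal(composite_profile(m1)$sem, c(0, 0))

  ## brute-force loop oracle on a random matrix with random missingness
  set.seed(29)
  vals <- matrix(rnorm(200), 20, 10)
  vals[sample(200, 40)] <- NA
  mm <- m; mm$values <- vals; mm$positions <- 1:10
  prof2 <- composite_profile(mm)
  for (j in 1:10) {
    col <- vals[, j][!is.na(vals[, j])]
    expect_equal(prof2$mean[j], mean(col))
    expect_equal(prof2$sem[j], sd(col) / sqrt(length(col)))
    expect_equal(prof2$n[j], length(col))
  }

  ## duplicating every row leaves the mean profile unchanged
  md <- m; md$values <- rbind(m$values, m$values)
  expect_equal(composite_profile(md)$mean, prof$mean)
})

test_that("row sorting is stable and invertible", {
  m <- list(values = rbind(a = c(1, 1), b = c(2, 2), c = c(3, 3)),
            positions = c(0, 10), row_labels = c("a", "b", "c"),
            mode = "anchored")
  class(m) <- "composite_matrix"
  asc <- sort_rows(m, keys = c(3, 1, 2))
  expect_equal(asc$row_labels, c("b", "c", "a"))
  ## equal keys preserve original order
  tie <- sort_rows(m, keys = c(1, 1, 0))
  expect_equal(tie$row_labels, c("c", "a", "b"))
  ## descending on distinct keys is the reverse of ascending
  desc <- sort_rows(m, keys = c(3, 1, 2), descending = TRUE)
  expect_equal(desc$row_labels, rev(asc$row_labels))
  expect_error(sort_rows(m, keys = c(1, 2)), "one key per row")
})
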
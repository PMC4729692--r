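test_that("log2 enrichment matches hand-computed values and stays finite", {
  expect_equal(log2_enrichment(toy_count_table(100, 100))$value, 0)
  expect_equal(log2_enrichment(toy_count_table(400, 100))$value,
               log2(400.5 / 100.5), tolerance = 1e-12)
  v <- log2_enrichment(toy_count_table(0, 100))$value
  expect_equal(v, log2(0.5 / 100.5), tolerance = 1e-12)
  expect_true(is.finite(v))
  expect_error(log2_enrichment(toy_count_table(1, 1, lib_chip = 0)), "library")
})

test_that("log2 enrichment is invariant under joint library rescaling and monotone in ChIP", {
  set.seed(4)
  chip <- rpois(50, 200); input <- rpois(50, 180)
  reg <- regions(rep("chr1", 50), seq(0, by = 2000, length.out = 50),
                 seq(1500, by = 2000, length.out = 50))
  t1 <- region_count_table(reg, matrix(chip), matrix(input), 1e6, 8e5)
  t2 <- region_count_table(reg, matrix(chip), matrix(input), 3e6, 2.4e6)
  expect_equal(log2_enrichment(t1)$value, log2_enrichment(t2)$value)

  bump <- chip; bump[7] <- bump[7] + 25
  t3 <- region_count_table(reg, matrix(bump), matrix(input), 1e6, 8e5)
  expect_gt(log2_enrichment(t3)$value[7], log2_enrichment(t1)$value[7])
})

test_that("sliding tracks agree with direct per-window computation", {
  set.seed(11)
  cov_c <- rpois(1000, 2); cov_i <- rpois(1000, 2)
  tr <- sliding_track(cov_c, cov_i, window = 200, step = 50)
  # window layout arithmetic: starts 0..800 by 50
  expect_equal(tr$start, seq(0, 800, 50))
  # brute-force recomputation of each window
  for (k in seq_len(nrow(tr))) {
    wc <- sum(cov_c[(tr$start[k] + 1):tr$end[k]])
    wi <- sum(cov_i[(tr$start[k] + 1):tr$end[k]])
    kb <- (tr$end[k] - tr$start[k]) / 1000
    dc <- (wc + 0.5) / (sum(cov_c) / 1e6) / kb
    di <- (wi + 0.5) / (sum(cov_i) / 1e6) / kb
    expect_equal(tr$value[k], log2(dc / di))
  }
  # constant equal coverage gives a constant track
  tc <- sliding_track(rep(3, 600), rep(3, 600))
  expect_equal(var(tc$value), 0)
})

test_that("tile composition summary assigns fractional multi-kind overlaps", {
  tiles <- regions(rep("chr1", 10), seq(0, by = 1000, length.out = 10),
                   seq(1000, by = 1000, length.out = 10), kind = "tile")
  # single-kind genome: everything lands in that kind
  ann1 <- regions("chr1", 0, 10000, id = "g1", kind = "gene_body")
  s1 <- tile_summary(tiles, 1:10, ann1)
  expect_equal(s1$fraction, c(1, 1))
  expect_equal(unique(s1$kind), "gene_body")

  # a tile overlapping two kinds contributes 1/2 to each
  ann2 <- rbind(regions("chr1", 0, 9500, id = "g", kind = "gene_body"),
                regions("chr1", 9500, 10000, id = "p", kind = "promoter"))
  s2 <- tile_summary(tiles, 1:10, ann2, frac = 0.1)  # top set = tile 10 only
  top <- s2[s2$set == "top", ]
  expect_equal(sort(top$fraction), c(0.5, 0.5))
  expect_equal(sum(top$fraction), 1)
  # fractions sum to 1 within each extreme set
  expect_equal(sum(s2$fraction[s2$set == "bottom"]), 1)
})

test_that("k-means mark calling finds the optimal 1-D partition", {
  vals <- c(-1.1, -1.0, -0.9, 0.5, 0.6, 3.0, 3.1)
  cm <- call_marked(vals, k = 3)
  oracle <- exhaustive_kmeans_1d(vals, 3)
  expect_equal(sort(vals[cm$status == "marked"]), sort(oracle$top_members))
  expect_equal(vals[cm$status == "marked"], c(3.0, 3.1))

  # exactly three distinct values: clusters are those values
  v3 <- rep(c(-1, 0, 2), times = c(5, 3, 4))
  cm3 <- call_marked(v3, k = 3)
  expect_equal(sort(cm3$centers), c(-1, 0, 2))
  expect_equal(sum(cm3$status == "marked"), 4)

  expect_error(call_marked(rep(c(1, 2), 5), k = 3), "distinct")
})

test_that("differential enrichment classifies planted cell-type differences", {
  set.seed(9)
  n <- 300
  reg <- regions(rep("chr1", n), seq(0, by = 1200, length.out = n),
                 seq(1000, by = 1200, length.out = n))
  # regions 1..30 marked in A only (planted FC 16), 31..60 marked in both
  markA <- seq_len(n) <= 60
  markB <- seq_len(n) > 30 & seq_len(n) <= 60
  muA <- ifelse(seq_len(n) <= 60, 1600, 100)
  muB <- ifelse(markB, 1600, 100)
  mk <- function(mu) region_count_table(
    reg, cbind(rpois(n, mu), rpois(n, mu)),
    cbind(rpois(n, 100), rpois(n, 100)),
    chip_lib = rep(sum(mu), 2), input_lib = rep(100 * n, 2))
  tA <- mk(muA); tB <- mk(muB)
  cA <- call_marked(log2_enrichment(tA)$value)
  cB <- call_marked(log2_enrichment(tB)$value)
  de <- differential_enrichment(tA, tB, cA, cB)
  expect_true(all(de$class[1:30] == "A_only"))
  expect_true(all(de$class[31:60] == "both"))
  expect_true(mean(de$class[61:n] == "neither") > 0.95)
})

test_that("metagene profiles rescale bodies, bin flanks and flip strands", {
  cov <- list(chr1 = rep(2.5, 30000))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                      end = 20000, strand = "+")
  prof <- metagene_profile(cov, genes, body_bins = 10, flank_bp = 1000,
                           flank_bins = 5)
  expect_equal(as.numeric(prof), rep(2.5, 20))

  # ramp signal: minus-strand gene sees the reverse of the plus-strand view
  cov2 <- list(chr1 = seq_len(30000) / 1000)
  gp <- genes; gm <- genes; gm$strand <- "-"
  pp <- metagene_profile(cov2, gp, body_bins = 10, flank_bp = 1000, flank_bins = 5)
  pm <- metagene_profile(cov2, gm, body_bins = 10, flank_bp = 1000, flank_bins = 5)
  expect_equal(as.numeric(pm), rev(as.numeric(pp)))

  # two-gene average checked by hand on a constant-per-gene signal
  cov3 <- list(chr1 = c(rep(1, 15000), rep(3, 15000)))
  g2 <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                   start = c(2000, 17000), end = c(12000, 27000),
                   strand = "+")
  p2 <- metagene_profile(cov3, g2, body_bins = 4, flank_bp = 500, flank_bins = 2)
  expect_equal(as.numeric(p2), rep(2, 8))
})

test_that("absolute scaling shifts tracks by log2 of the factor", {
  v <- c(-1, 0, 2.5)
  expect_equal(scale_absolute(v, 1), v)
  expect_equal(scale_absolute(v, 2), v + 1)
  expect_equal(scale_absolute(scale_absolute(v, 4), 1 / 4), v)
})
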
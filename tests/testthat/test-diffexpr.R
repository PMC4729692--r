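test_that("size factors follow the median-of-ratios definition", {
  m <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  expect_equal(size_factors(m), c(a = 1, b = 1))

  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  expect_equal(size_factors(m2), c(a = 1 / sqrt(2), b = sqrt(2)))

  # 4x3 toy matrix against a hand computation
  m3 <- cbind(s1 = c(4, 10, 20, 7), s2 = c(8, 10, 10, 14), s3 = c(2, 5, 40, 7))
  ref <- exp(rowMeans(log(m3)))
  want <- apply(m3, 2, function(col) median(col / ref))
  want <- want / exp(mean(log(want)))
  expect_equal(size_factors(m3), want)

  expect_error(size_factors(cbind(c(0, 1), c(1, 0))), "nonzero")
})

test_that("RPKM follows the normalized-count definition", {
  cnt <- matrix(1000, 1, 1)
  # one gene of 1 kb; normalized library total forced to 1e6
  expect_equal(as.numeric(rpkm(cnt, 1, 1000, norm_lib_totals = 1e6)), 1000)
  expect_equal(as.numeric(rpkm(cnt, 1, 2000, norm_lib_totals = 1e6)), 500)

  set.seed(2)
  cnt2 <- matrix(rpois(12, 50), 4, 3)
  sf <- size_factors(cnt2)
  len <- c(500, 1000, 2000, 4000)
  got <- rpkm(cnt2, sf, len)
  norm <- sweep(cnt2, 2, sf, "/")
  want <- sweep(sweep(norm, 1, len / 1000, "/"), 2, colSums(norm) / 1e6, "/")
  expect_equal(got, want)
})

test_that("NB tail test matches direct mass-ordering summation", {
  expect_equal(nb_tail_test(10, 10, 0), 1)

  # Poisson oracle: brute-force mass ordering
  pois_oracle <- function(obs, mu) {
    xs <- 0:200
    px <- dpois(xs, mu)
    sum(px[px <= dpois(obs, mu) * (1 + 1e-7)])
  }
  expect_equal(nb_tail_test(25, 10, 0), pois_oracle(25, 10), tolerance = 1e-10)
  expect_equal(nb_tail_test(3, 10, 0), pois_oracle(3, 10), tolerance = 1e-10)

  # NB oracle at dispersion 0.1
  nb_oracle <- function(obs, mu, disp) {
    xs <- 0:5000
    px <- dnbinom(xs, size = 1 / disp, mu = mu)
    sum(px[px <= dnbinom(obs, size = 1 / disp, mu = mu) * (1 + 1e-7)])
  }
  # at the distribution mode the two-sided mass-ordering p is exactly 1
  mode_nb <- which.max(dnbinom(0:300, size = 10, mu = 100)) - 1
  expect_equal(nb_tail_test(mode_nb, 100, 0.1), 1)
  for (obs in c(100, 160, 40)) {
    expect_equal(nb_tail_test(obs, 100, 0.1), nb_oracle(obs, 100, 0.1),
                 tolerance = 1e-10)
  }
  expect_error(nb_tail_test(5, 0, 0.1))
})

test_that("Fisher combination equals the chi-square tail and rejects zero p", {
  expect_equal(fisher_combine(rep(1, 4)), 1)
  for (p in c(0.9, 0.3, 0.01)) expect_equal(fisher_combine(p), p, tolerance = 1e-12)
  # quadrature oracle, independent of pchisq
  X <- -2 * sum(log(c(0.05, 0.05, 0.05)))
  orac <- integrate(function(t) dchisq(t, df = 6), X, Inf,
                    rel.tol = 1e-12)$value
  expect_equal(fisher_combine(c(0.05, 0.05, 0.05)), orac, tolerance = 1e-10)
  expect_error(fisher_combine(c(0.5, 0)), "floor")
})

test_that("the per-embryo DE caller applies all three filters", {
  set.seed(31)
  ng <- 400
  labels <- rep(c("control", "ko"), each = 4)
  base <- rep(100, ng)
  lfc <- c(rep(3, 20), rep(0, ng - 20))
  mu <- outer(base, rep(1, 8)) * 2^outer(lfc, as.numeric(labels == "ko"))
  cnt <- matrix(rnbinom(length(mu), size = 10, mu = mu), ng)
  cnt[5, ] <- 0  # all-zero gene
  rownames(cnt) <- sprintf("g%03d", seq_len(ng))
  res <- call_de(cnt, labels, gene_lengths = rep(2000, ng))
  expect_equal(res$table$status[5], "unchanged")
  planted <- setdiff(1:20, 5)
  expect_gt(mean(res$table$status[planted] == "up"), 0.8)
  expect_lt(mean(res$table$status[-(1:20)] == "up"), 0.01)

  # a gene passing p and FC but failing the per-replicate RPKM floor in
  # one KO sample stays unchanged
  cnt3 <- rbind(anchor = rep(1e6, 8),      # dominates the library total
                weak = c(0, 0, 0, 0, 3, 300, 300, 300),
                ok = c(0, 0, 0, 0, 300, 300, 300, 300))
  res3 <- call_de(cnt3, labels, gene_lengths = rep(2000, 3),
                  sf = rep(1, 8))
  l2rpkm_weak <- log2(res3$rpkm["weak", labels == "ko"])
  expect_true(min(l2rpkm_weak) < 1)          # the filter is binding
  expect_lt(res3$table$combined_p[2], 0.05)  # p and FC alone would call it
  expect_true(all(res3$log2fc[2, ] > 1.4))
  expect_equal(res3$table$status[2], "unchanged")
  expect_equal(res3$table$status[3], "up")
})

test_that("stage transitions are symmetric under label swap", {
  set.seed(12)
  ng <- 150
  labels <- rep(c("A", "B"), each = 3)
  base <- rlnorm(ng, log(40), 0.6)
  lfc <- numeric(ng); lfc[1:10] <- 3; lfc[11:20] <- -3
  mu <- outer(base, rep(1, 6)) * 2^outer(lfc, as.numeric(labels == "B"))
  cnt <- matrix(rnbinom(length(mu), size = 10, mu = mu), ng)
  cnt[30, ] <- 50  # constant gene
  # RPKM ceiling raised to match this small library's RPKM scale
  st <- call_state_transition(cnt, labels, gene_lengths = rep(1500, ng),
                              max_log2rpkm_low = 15)
  sw <- call_state_transition(cnt, ifelse(labels == "A", "B", "A"),
                              gene_lengths = rep(1500, ng),
                              max_log2rpkm_low = 15)
  expect_equal(st$status == "repressed", sw$status == "activated")
  expect_equal(st$status == "activated", sw$status == "repressed")
  expect_equal(st$status[30], "unchanged")
  # planted low->high genes are activated (baseline below the RPKM ceiling)
  expect_gt(mean(st$status[1:10] == "activated"), 0.5)
})

test_that("chromosome enrichment matches exhaustive hypergeometric summation", {
  genes <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                      chrom = c(rep("chrX", 50), rep("chr1", 950)))
  de <- c(sprintf("g%04d", 1:5), sprintf("g%04d", 101:105))
  got <- chromosome_enrichment(de, genes)
  # direct summation over the hypergeometric pmf
  want <- sum(dhyper(5:10, 50, 950, 10))
  expect_equal(got$p, want, tolerance = 1e-12)
  expect_equal(got$fraction, 0.5)

  none <- chromosome_enrichment(character(0), genes)
  expect_equal(none$p, 1)

  # DE fraction equal to the genome fraction is not enriched
  de2 <- c(sprintf("g%04d", 1), sprintf("g%04d", 101:119))
  expect_gte(chromosome_enrichment(de2, genes)$p, 0.5)
})
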
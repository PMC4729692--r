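# Integer-discretized brute-force tail mass over all 4^w words, using the
# same per-column rounding as the DP.
brute_tail <- function(x, threshold, granularity = 1e-3) {
  M <- log2(sweep(x$mat, 2, x$background, "/"))
  ki <- round(M / granularity)
  w <- nrow(M)
  idx <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- rowSums(matrix(ki[cbind(rep(seq_len(w), each = nrow(idx)),
                                as.vector(idx))], nrow(idx)))
  pr <- apply(idx, 1, function(wd) prod(x$background[wd]))
  sum(pr[sc * granularity >= threshold - 1e-12])
}

test_that("PWM construction enforces probability invariants", {
  set.seed(2)
  p <- pwm(matrix(runif(20), 5, 4))
  expect_equal(rowSums(p$mat), rep(1, 5), tolerance = 1e-9)
  expect_true(all(p$mat > 0))
  expect_equal(sum(p$background), 1)
  con <- pwm_from_consensus("ACGT")
  expect_equal(con$width, 4)
  expect_equal(which.max(con$mat[2, ]), c(C = 2))
})

# All achievable discretized site scores of a PWM with their tail masses.
support_tails <- function(x, granularity = 1e-3) {
  M <- log2(sweep(x$mat, 2, x$background, "/"))
  ki <- round(M / granularity)
  w <- nrow(M)
  idx <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- rowSums(matrix(ki[cbind(rep(seq_len(w), each = nrow(idx)),
                                as.vector(idx))], nrow(idx)))
  pr <- apply(idx, 1, function(wd) prod(x$background[wd]))
  agg <- tapply(pr, sc, sum)
  s <- as.numeric(names(agg)) * granularity
  o <- order(s)
  data.frame(score = s[o], tail = rev(cumsum(rev(agg[o]))))
}

test_that("score thresholds match exhaustive enumeration up to width 8", {
  set.seed(19)
  cases <- list(c(3, 0.25), c(3, 0.05), c(5, 0.05), c(5, 5e-3),
                c(8, 0.05), c(8, 1e-3))
  for (case in cases) {
    w <- case[1]; p_target <- case[2]
    x <- pwm(matrix(runif(4 * w), w, 4))
    th <- score_threshold(x, p_target)
    expect_lte(th$tail_prob, p_target)
    expect_equal(th$tail_prob, brute_tail(x, th$threshold), tolerance = 1e-12)
    # minimality: the next achievable score below exceeds the target
    sup <- support_tails(x)
    below <- sup[sup$score < th$threshold - 1e-9, ]
    if (nrow(below)) expect_gt(below$tail[nrow(below)], p_target)
  }
  # p = 1 admits every site
  x1 <- pwm(matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4, byrow = TRUE),
            pseudocount = 0)
  expect_equal(score_threshold(x1, 1)$tail_prob, 1)
  # width-1 PWM at p = 0.25 under uniform background: only the best base
  th1 <- score_threshold(x1, 0.25)
  expect_equal(th1$tail_prob, 0.25)
  expect_equal(th1$threshold, round(log2(0.7 / 0.25) / 1e-3) * 1e-3)
  # unreachable p yields a hit-proof threshold with a warning
  expect_warning(thx <- score_threshold(x1, 1e-9), "achievable")
  expect_false(thx$attainable)
  expect_gt(thx$threshold, log2(0.7 / 0.25))
})

test_that("scanning equals naive per-window rescoring on random sequences", {
  set.seed(33)
  x <- pwm_from_consensus("TGACGT")
  M <- log2(sweep(x$mat, 2, x$background, "/"))
  w <- x$width
  naive <- function(s) {
    hits <- list()
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") s else revcomp(s)
      L <- nchar(sc)
      for (o in 0:(L - w)) {
        win <- strsplit(substr(sc, o + 1, o + w), "")[[1]]
        bi <- match(win, c("A", "C", "G", "T"))
        if (anyNA(bi)) next
        score <- sum(M[cbind(seq_len(w), bi)])
        off <- if (strand == "+") o else L - w - o
        hits[[length(hits) + 1]] <- data.frame(offset = off, strand = strand,
                                               score = score)
      }
    }
    do.call(rbind, hits)
  }
  for (rep_i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    thr <- -3
    got <- scan_pwm(c(q = s), x, thr)
    want <- naive(s)
    want <- want[want$score >= thr, ]
    got <- got[order(got$strand, got$offset), ]
    want <- want[order(want$strand, want$offset), ]
    expect_equal(got$offset, want$offset)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
  # sequence shorter than the motif gives no hits
  expect_equal(nrow(scan_pwm(c(s = "ACG"), x, -10)), 0)
})

test_that("strand symmetry: forward hits mirror on the reverse complement", {
  set.seed(7)
  x <- pwm_from_consensus("TGACGTCA")
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  th <- score_threshold(x, 0.01)$threshold
  h <- scan_pwm(c(a = s), x, th)
  hrc <- scan_pwm(c(a = revcomp(s)), x, th)
  fwd <- h[h$strand == "+", ]
  mir <- hrc[hrc$strand == "-", ]
  expect_setequal(nchar(s) - x$width - fwd$offset, mir$offset)
})

test_that("planted motifs are found at their planted offsets", {
  cfg <- sim_config(seed = 61, n_genes = 60, n_enhancers = 30,
                    n_repeat_subfamilies = 2, loci_per_subfamily = 25,
                    chrom_len_bp = 1.5e6, frac_enh_k9 = 0.5,
                    planted_motif_rate = 1)
  sim <- simulate_genome(cfg)
  seqs <- simulate_sequences(sim)
  x <- pwm_from_consensus(cfg$motif_consensus, background = cfg$base_freqs)
  th <- score_threshold(x, 1e-5)$threshold
  hits <- scan_pwm(seqs$enhancer_seqs, x, th)
  for (i in seq_len(nrow(seqs$planted))) {
    expect_true(any(hits$id == seqs$planted$id[i] &
                      hits$offset == seqs$planted$offset[i] &
                      hits$strand == "+"))
  }
})

test_that("background sets match widths, stay in the allowed space and are seeded", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(100000, 400000), end = c(110000, 420000))
  sizes <- c(chr1 = 6e5)
  widths <- c(1601, 500, 1601)
  sets <- sample_background_sets(genes, sizes, widths, n_sets = 30, seed = 3)
  expect_length(sets, 30)
  # allowed space: gene bodies +/- 50 kb
  lo1 <- 50000; hi1 <- 160000; lo2 <- 350000; hi2 <- 470000
  for (s in sets) {
    expect_setequal(s$end - s$start, widths)
    ok <- (s$start >= lo1 & s$end <= hi1) | (s$start >= lo2 & s$end <= hi2)
    expect_true(all(ok))
  }
  sets2 <- sample_background_sets(genes, sizes, widths, n_sets = 30, seed = 3)
  expect_identical(sets, sets2)
})

test_that("empirical enrichment handles planted and degenerate cases", {
  x <- pwm_from_consensus("TGACGTCATC")
  # zero hits everywhere: regularized fold 1, p 1
  seqs0 <- c(a = strrep("A", 50), b = strrep("A", 50))
  bg0 <- replicate(20, c(strrep("A", 50)), simplify = FALSE)
  e0 <- empirical_enrichment(seqs0, bg0, x, threshold = 5)
  expect_equal(e0$fold, 1)
  expect_equal(e0$empirical_p, 1)
  # p never returns 0 and never exceeds 1 by construction
  expect_gte(e0$empirical_p, 1 / 21)
})

test_that("MEME files round-trip through the minimal reader", {
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.3 C 0.2 G 0.2 T 0.3", "",
    "MOTIF m1",
    "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
    " 0.7 0.1 0.1 0.1",
    " 0.1 0.7 0.1 0.1",
    " 0.1 0.1 0.1 0.7", ""
  ), f)
  pwms <- read_meme(f, pseudocount = 0)
  expect_length(pwms, 1)
  expect_equal(pwms$m1$width, 3)
  expect_equal(as.numeric(pwms$m1$mat[1, ]), c(0.7, 0.1, 0.1, 0.1))
  expect_equal(as.numeric(pwms$m1$background),
               c(0.3, 0.2, 0.2, 0.3))
})
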
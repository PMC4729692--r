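# Shared fixture builders. All randomness is locally seeded so tests are
# order-independent.

random_region_set <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                              max_len = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n) - 1
  len <- sample.int(max_len, n)
  regions(chrom, start, start + len, id = sprintf("r%03d", seq_len(n)))
}

# Brute-force O(n*m) overlap oracle (half-open, same chromosome).
brute_force_overlaps <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
      out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out)) return(data.frame(a_idx = integer(0), b_idx = integer(0)))
  m <- do.call(rbind, out)
  data.frame(a_idx = m[, 1], b_idx = m[, 2])
}

# Exhaustive optimal contiguous k-partition of sorted 1-D values (SSE
# objective): the independent oracle for the k-means mark caller.
exhaustive_kmeans_1d <- function(x, k = 3) {
  n <- length(x)
  xs <- sort(x)
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  best <- NULL
  best_cost <- Inf
  # boundaries 0 < b1 < b2 < ... < b_{k-1} < n
  combs <- utils::combn(n - 1, k - 1)
  for (ci in seq_len(ncol(combs))) {
    b <- c(0, combs[, ci], n)
    cost <- sum(vapply(seq_len(k), function(m) sse(xs[(b[m] + 1):b[m + 1]]), 0))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- b
    }
  }
  clusters <- lapply(seq_len(k), function(m) xs[(best[m] + 1):best[m + 1]])
  list(cost = best_cost, clusters = clusters,
       top_members = clusters[[k]])
}

# Small deterministic count table for enrichment tests.
toy_count_table <- function(chip, input, lib_chip = 1e6, lib_input = 1e6,
                            len = 1000) {
  n <- length(chip)
  reg <- regions(rep("chr1", n), seq(0, by = len, length.out = n),
                 seq(len, by = len, length.out = n))
  region_count_table(reg, matrix(chip), matrix(input), lib_chip, lib_input)
}
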
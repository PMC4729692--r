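#' Bundle per-region ChIP and input counts
#'
#' @param regions region table.
#' @param chip,input regions x replicates count matrices.
#' @param chip_lib,input_lib per-replicate mapped-read library totals.
#' @param mark histone-mark label (e.g. "H3K9me2").
#' @param cell_type cell-type label.
#' @return list of class `region_count_table`.
#' @export
region_count_table <- function(regions, chip, input, chip_lib, input_lib,
                               mark = "", cell_type = "") {
  chip <- as.matrix(chip); input <- as.matrix(input)
  stopifnot(nrow(chip) == nrow(regions), nrow(input) == nrow(regions),
            length(chip_lib) == ncol(chip), length(input_lib) == ncol(input),
            all(chip >= 0), all(input >= 0))
  structure(list(regions = regions, chip = chip, input = input,
                 chip_lib = chip_lib, input_lib = input_lib,
                 mark = mark, cell_type = cell_type),
            class = "region_count_table")
}

#' Log2(normalized ChIP / input) per region
#'
#' Per replicate, the read density is (count + pseudocount) divided by
#' the library total in millions and by the region size in kb; the value
#' is log2(chip density / input density), averaged over replicates after
#' the log transform. The pseudocount keeps all values finite at
#' zero-count regions. Invariant under joint rescaling of the chip and
#' input library totals.
#'
#' @param table a [region_count_table()].
#' @param pseudocount reads added to both chip and input counts
#'   (default 0.5).
#' @return data.frame with `id`, `value` (mean log2 enrichment),
#'   `n_replicates`.
#' @export
log2_enrichment <- function(table, pseudocount = 0.5) {
  if (any(table$chip_lib <= 0) || any(table$input_lib <= 0))
    stop("log2_enrichment: zero library total")
  len_kb <- (table$regions$end - table$regions$start) / 1000
  dens <- function(counts, libs) {
    sweep(counts + pseudocount, 2, libs / 1e6, "/") / len_kb
  }
  dc <- dens(table$chip, table$chip_lib)
  di <- dens(table$input, table$input_lib)
  per_rep <- log2(dc) - log2(di)
  data.frame(id = table$regions$id, value = rowMeans(per_rep),
             n_replicates = ncol(per_rep), stringsAsFactors = FALSE)
}

#' Sliding-window browser track of log2 enrichment
#'
#' Windows are laid out as in [make_tiles()] (window length, fixed step,
#' final truncated window kept); the per-window value applies the same
#' density normalization as [log2_enrichment()] to windowed read-coverage
#' sums.
#'
#' @param chip_cov,input_cov per-bp coverage vectors along one chromosome.
#' @param chrom chromosome name for the output records.
#' @param chip_lib,input_lib library totals.
#' @param window,step window length and offset in bp (defaults 200/50).
#' @param pseudocount reads added to both window sums.
#' @return bedGraph-style data.frame (chrom, start, end, value).
#' @export
sliding_track <- function(chip_cov, input_cov, chrom = "chr1",
                          chip_lib = sum(chip_cov), input_lib = sum(input_cov),
                          window = 200, step = 50, pseudocount = 0.5) {
  stopifnot(length(chip_cov) == length(input_cov))
  len <- length(chip_cov)
  tiles <- make_tiles(stats::setNames(len, chrom), tile_len = window, offset = step)
  csc <- c(0, cumsum(chip_cov)); csi <- c(0, cumsum(input_cov))
  wc <- csc[tiles$end + 1] - csc[tiles$start + 1]
  wi <- csi[tiles$end + 1] - csi[tiles$start + 1]
  wkb <- (tiles$end - tiles$start) / 1000
  dc <- (wc + pseudocount) / (chip_lib / 1e6) / wkb
  di <- (wi + pseudocount) / (input_lib / 1e6) / wkb
  data.frame(chrom = chrom, start = tiles$start, end = tiles$end,
             value = log2(dc / di), stringsAsFactors = FALSE)
}

#' Annotation composition of the most/least enriched tiles
#'
#' Takes the top and bottom `frac` of tiles by enrichment value and
#' reports, for each extreme set, the fraction falling in each annotated
#' feature kind. A tile overlapping k kinds contributes 1/k to each;
#' tiles overlapping nothing count as "other". Fractions sum to 1 within
#' each set.
#'
#' @param tiles region table of tiles.
#' @param values per-tile enrichment values (aligned with `tiles`).
#' @param annotation region table carrying a `kind` column.
#' @param frac extreme fraction (default 0.2).
#' @return data.frame with columns `set` ("top"/"bottom"), `kind`,
#'   `fraction`.
#' @export
tile_summary <- function(tiles, values, annotation, frac = 0.2) {
  stopifnot(length(values) == nrow(tiles))
  n_sel <- max(1, floor(frac * nrow(tiles)))
  ord <- order(values, decreasing = TRUE)
  sets <- list(top = ord[seq_len(n_sel)], bottom = rev(ord)[seq_len(n_sel)])
  ov <- intersect_regions(tiles, annotation)
  kinds_by_tile <- split(annotation$kind[ov$b_idx], ov$a_idx)
  out <- lapply(names(sets), function(nm) {
    idx <- sets[[nm]]
    contrib <- new.env()
    for (i in idx) {
      kinds <- unique(kinds_by_tile[[as.character(i)]])
      if (is.null(kinds) || length(kinds) == 0) kinds <- "other"
      w <- 1 / length(kinds)
      for (kd in kinds) assign(kd, mget(kd, contrib, ifnotfound = 0)[[1]] + w, contrib)
    }
    kinds <- ls(contrib)
    data.frame(set = nm, kind = kinds,
               fraction = vapply(kinds, function(kd) get(kd, contrib), 0) / length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Exact 1-D k-means by dynamic programming over sorted values.
# Optimal squared-error partitions in 1-D are contiguous in sorted order,
# so the global optimum is found deterministically in O(k n^2).
kmeans_1d_exact <- function(x, k) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- c(0, cumsum(xs)); cs2 <- c(0, cumsum(xs^2))
  seg_cost <- function(i, j) { # cluster covering sorted positions i..j (i vectorized)
    s <- cs[j + 1] - cs[i]
    s2 <- cs2[j + 1] - cs2[i]
    len <- j - i + 1
    pmax(0, s2 - s^2 / len)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  D[1, ] <- seg_cost(rep(1, n), seq_len(n))
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        i <- m:j
        vals <- D[m - 1, i - 1] + seg_cost(i, j)
        b <- which.min(vals)
        D[m, j] <- vals[b]
        B[m, j] <- i[b]
      }
    }
  }
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  j <- n
  if (k > 1) for (m in k:2) { st <- B[m, j]; bounds[m] <- st - 1; j <- st - 1 }
  bounds[1] <- 0
  assign_sorted <- rep(seq_len(k), diff(bounds))
  cluster <- integer(n)
  cluster[o] <- assign_sorted
  centers <- vapply(seq_len(k), function(m) mean(xs[(bounds[m] + 1):bounds[m + 1]]), 0)
  list(cluster = cluster, centers = centers, sse = D[k, n])
}

#' Call marked regions by k-means on enrichment values
#'
#' Regions are partitioned into `k` clusters (default 3) by squared-error
#' k-means on the replicate-averaged log2 enrichment; members of the
#' cluster with the highest mean are designated "marked". The 1-D
#' optimization is solved exactly by dynamic programming over the sorted
#' values (1-D optima are contiguous), so the call is deterministic and
#' always the global squared-error optimum; `restarts` and `seed` are
#' accepted for interface stability but the solver does not need them.
#'
#' @param values per-region enrichment values.
#' @param k number of clusters (default 3).
#' @param restarts,seed ignored by the exact solver.
#' @return list of class `mark_call_set`: `status` ("marked"/"unmarked"
#'   per region), `cluster` assignments, `centers` (cluster means, sorted
#'   order), `marked_cluster`.
#' @export
call_marked <- function(values, k = 3, restarts = 50, seed = NULL) {
  stopifnot(k >= 1)
  if (length(unique(values)) < k)
    stop("call_marked: fewer than k distinct values; relax k")
  fit <- kmeans_1d_exact(values, k)
  marked_cluster <- which.max(fit$centers)
  structure(list(
    status = ifelse(fit$cluster == marked_cluster, "marked", "unmarked"),
    cluster = fit$cluster, centers = fit$centers,
    marked_cluster = marked_cluster, sse = fit$sse
  ), class = "mark_call_set")
}

# Pooled method-of-moments dispersion across regions from replicate
# normalized counts (median over regions with positive mean).
pooled_dispersion <- function(mat, floor = 0.01) {
  m <- rowMeans(mat)
  v <- apply(mat, 1, stats::var)
  ok <- m > 0 & is.finite(v)
  if (!any(ok)) return(floor)
  d <- (v[ok] - m[ok]) / m[ok]^2
  max(floor, stats::median(d))
}

#' Differential mark enrichment between two cell types
#'
#' Classifies each region as marked in both cell types, only in A, only
#' in B, or neither. "Only in A" means marked in A and either unmarked in
#' B or significantly more enriched in A (NB test on normalized replicate
#' ChIP counts at p < `p_max`, with replicate-mean log2-enrichment
#' difference above `min_abs_log2fc`); symmetric for B. Marked in both
#' without a significant difference gives "both".
#'
#' @param tableA,tableB [region_count_table()]s over identical regions.
#' @param callsA,callsB [call_marked()] results for each cell type.
#' @param p_max significance threshold (default 0.05).
#' @param min_abs_log2fc minimum |log2 FC| of enrichment (default 2).
#' @param pseudocount for the enrichment computation.
#' @return data.frame with `id`, `class` in {both, A_only, B_only,
#'   neither}, `log2fc` (A - B), `p`.
#' @export
differential_enrichment <- function(tableA, tableB, callsA, callsB,
                                    p_max = 0.05, min_abs_log2fc = 2,
                                    pseudocount = 0.5) {
  stopifnot(identical(tableA$regions$id, tableB$regions$id))
  encA <- log2_enrichment(tableA, pseudocount)$value
  encB <- log2_enrichment(tableB, pseudocount)$value
  fc <- encA - encB
  # library-normalized chip counts on a common per-million scale
  normc <- function(tab) sweep(tab$chip, 2, tab$chip_lib / 1e6, "/")
  ncA <- normc(tableA); ncB <- normc(tableB)
  disp <- pooled_dispersion(cbind(ncA, ncB))
  n <- nrow(ncA)
  p <- vapply(seq_len(n), function(i) {
    muB <- max(mean(ncB[i, ]), 0.5)
    ps <- vapply(seq_len(ncol(ncA)),
                 function(j) nb_tail_test(ncA[i, j], muB, disp), 0)
    fisher_combine(pmax(ps, 1e-300))
  }, 0)
  mA <- callsA$status == "marked"
  mB <- callsB$status == "marked"
  sig_hi_A <- p < p_max & fc > min_abs_log2fc
  sig_hi_B <- p < p_max & fc < -min_abs_log2fc
  class <- rep("neither", n)
  class[mA & mB] <- "both"
  class[mA & (!mB | sig_hi_A)] <- "A_only"
  class[mB & (!mA | sig_hi_B)] <- "B_only"
  data.frame(id = tableA$regions$id, class = class, log2fc = fc, p = p,
             stringsAsFactors = FALSE)
}

#' Metagene profile of a signal over scaled gene bodies with flanks
#'
#' Each gene body is linearly rescaled to `body_bins` bins; fixed-width
#' flanks of `flank_bp` are split into `flank_bins` bins each. Profiles
#' of minus-strand genes are flipped so bins run TSS to TTS. Per-bin
#' means are returned for each gene group.
#'
#' @param cov named list mapping chromosome to a per-bp signal vector.
#' @param genes gene table (chrom, start, end, strand).
#' @param groups factor/character vector of gene classes (default one
#'   group).
#' @param body_bins,flank_bp,flank_bins binning parameters.
#' @return matrix of groups x (flank_bins + body_bins + flank_bins) bin
#'   means.
#' @export
metagene_profile <- function(cov, genes, groups = NULL,
                             body_bins = 100, flank_bp = 5000, flank_bins = 25) {
  if (is.null(groups)) groups <- rep("all", nrow(genes))
  nb <- flank_bins + body_bins + flank_bins
  prof <- matrix(NA_real_, nrow(genes), nb)
  bin_means <- function(v, nbins) {
    idx <- floor((seq_along(v) - 1) * nbins / length(v)) + 1
    as.numeric(tapply(v, idx, mean)[as.character(seq_len(nbins))])
  }
  for (i in seq_len(nrow(genes))) {
    v <- cov[[genes$chrom[i]]]
    if (is.null(v)) next
    len <- length(v)
    grab <- function(s, e) { # 0-based half-open, NA outside chromosome
      out <- rep(NA_real_, e - s)
      lo <- max(s, 0); hi <- min(e, len)
      if (hi > lo) out[(lo - s + 1):(hi - s)] <- v[(lo + 1):hi]
      out
    }
    up <- bin_means(grab(genes$start[i] - flank_bp, genes$start[i]), flank_bins)
    body <- bin_means(grab(genes$start[i], genes$end[i]), body_bins)
    dn <- bin_means(grab(genes$end[i], genes$end[i] + flank_bp), flank_bins)
    row <- c(up, body, dn)
    if (genes$strand[i] == "-") row <- rev(row)
    prof[i, ] <- row
  }
  grp <- as.character(groups)
  out <- do.call(rbind, lapply(unique(grp), function(g)
    colMeans(prof[grp == g, , drop = FALSE], na.rm = TRUE)))
  rownames(out) <- unique(grp)
  out
}

#' Shift a relative enrichment track to an absolute scale
#'
#' Log2 enrichment values are relative to input; given an externally
#' measured global mark-abundance ratio (e.g. total ChIP DNA over input
#' DNA), adding log2(factor) places tracks from different cell types on a
#' comparable absolute scale.
#'
#' @param values log2 enrichment values.
#' @param factor global abundance ratio (> 0).
#' @return shifted values.
#' @export
scale_absolute <- function(values, factor) {
  stopifnot(factor > 0)
  values + log2(factor)
}
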
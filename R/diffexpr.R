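#' Median-of-ratios size factors
#'
#' Library-size normalization against a geometric-mean pseudo-reference:
#' for each gene present in every sample, the ratio of its count to the
#' geometric mean across samples is formed, and each sample's factor is
#' the median of these ratios. Factors are rescaled so their geometric
#' mean is 1, fixing the overall scale.
#'
#' @param counts genes x samples matrix of raw counts.
#' @return numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) stop("size_factors: no gene has nonzero counts in all samples")
  kc <- counts[keep, , drop = FALSE]
  ref <- exp(rowMeans(log(kc)))
  sf <- apply(kc, 2, function(col) stats::median(col / ref))
  sf / exp(mean(log(sf)))
}

#' Reads per kilobase per million (after size-factor normalization)
#'
#' counts are divided by the sample's size factor, by gene length in kb,
#' and by the normalized library total in millions. By default the
#' normalized library total is the column sum of size-factor-normalized
#' counts; it can be supplied explicitly.
#'
#' @param counts genes x samples matrix.
#' @param sf per-sample size factors.
#' @param gene_lengths gene lengths in bp.
#' @param norm_lib_totals optional per-sample normalized library totals.
#' @return genes x samples RPKM matrix.
#' @export
rpkm <- function(counts, sf, gene_lengths, norm_lib_totals = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(sf) == ncol(counts), length(gene_lengths) == nrow(counts),
            all(gene_lengths > 0))
  norm <- sweep(counts, 2, sf, "/")
  if (is.null(norm_lib_totals)) norm_lib_totals <- colSums(norm)
  out <- sweep(norm, 1, gene_lengths / 1000, "/")
  sweep(out, 2, norm_lib_totals / 1e6, "/")
}

#' Two-sided negative-binomial tail test by mass ordering
#'
#' p is the total probability of all counts whose point mass does not
#' exceed that of the observed count, under NB(mu, dispersion) with
#' variance mu + dispersion * mu^2. Dispersion 0 degenerates to Poisson.
#' This is the exact two-sided test used for one observed count against a
#' known mean, the per-embryo comparison unit of the DE procedure.
#'
#' @param observed observed count (rounded to integer).
#' @param mu expected mean (> 0).
#' @param dispersion NB dispersion (>= 0).
#' @return two-sided p-value in (0, 1].
#' @export
nb_tail_test <- function(observed, mu, dispersion = 0) {
  stopifnot(mu > 0, dispersion >= 0)
  observed <- round(observed)
  dens <- if (dispersion <= 0) {
    function(x) stats::dpois(x, lambda = mu)
  } else {
    function(x) stats::dnbinom(x, size = 1 / dispersion, mu = mu)
  }
  upper <- if (dispersion <= 0) {
    stats::qpois(1e-15, lambda = mu, lower.tail = FALSE)
  } else {
    stats::qnbinom(1e-15, size = 1 / dispersion, mu = mu, lower.tail = FALSE)
  }
  xs <- 0:(max(upper, observed) + 1)
  px <- dens(xs)
  pobs <- dens(observed)
  min(1, sum(px[px <= pobs * (1 + 1e-7)]))
}

#' Fisher's combined probability test
#'
#' X = -2 * sum(log p_i) is compared to the upper tail of a chi-square
#' distribution with 2k degrees of freedom. For k = 1 this returns the
#' input p. Zero p-values are an error; callers floor p-values (the DE
#' procedure uses a floor of 1e-300).
#'
#' @param p vector of p-values in (0, 1].
#' @return combined p-value.
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0) stop("fisher_combine: empty p-value vector")
  if (any(p <= 0)) stop("fisher_combine: zero p-value; floor inputs (e.g. at 1e-300)")
  if (any(p > 1)) stop("fisher_combine: p-values must be <= 1")
  X <- -2 * sum(log(p))
  stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}

moments_dispersion <- function(x, floor = 0.01) {
  m <- mean(x)
  if (m <= 0) return(floor)
  v <- stats::var(x)
  max(floor, (v - m) / m^2)
}

#' Per-embryo Fisher-combined differential-expression calls
#'
#' The procedure designed for heterogeneous single-embryo RNA-seq: each KO
#' embryo is compared individually against the whole control group with an
#' exact NB tail test (control mean as expected value, dispersion
#' estimated from controls by method of moments, floored), the
#' per-comparison p-values are combined by Fisher's method, and a gene is
#' called up only if (i) the combined p is below `p_combined_max`,
#' (ii) every per-comparison log2 fold-change (pseudocount 0.5) exceeds
#' `min_log2fc`, and (iii) every replicate of the upregulated group has
#' log2(RPKM) above `min_log2rpkm_up`. Down calls mirror the rule with the
#' controls as the upregulated group.
#'
#' @param counts genes x samples raw count matrix (rownames = gene ids).
#' @param labels per-sample labels, "control" or "ko".
#' @param gene_lengths gene lengths in bp.
#' @param p_combined_max combined-p threshold (default 0.05).
#' @param min_log2fc per-comparison |log2 FC| threshold (default 1.4).
#' @param min_log2rpkm_up minimum log2(RPKM) in each replicate of the
#'   upregulated group (default 1).
#' @param dispersion_floor lower bound on the moments dispersion estimate.
#' @param sf optional externally supplied size factors (e.g. from
#'   protein-coding read totals for repeat counts); computed by
#'   [size_factors()] when NULL.
#' @return list with `table` (gene, status, combined_p, mean_log2fc),
#'   `p` and `log2fc` (genes x KO matrices), `rpkm`, `size_factors`.
#' @export
call_de <- function(counts, labels, gene_lengths,
                    p_combined_max = 0.05, min_log2fc = 1.4,
                    min_log2rpkm_up = 1, dispersion_floor = 0.01,
                    sf = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(labels) == ncol(counts))
  ctrl <- which(labels == "control")
  ko <- which(labels == "ko")
  if (length(ctrl) < 2) stop("call_de: need >= 2 control samples")
  if (length(ko) < 1) stop("call_de: need >= 1 KO sample")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  rpk <- rpkm(counts, sf, gene_lengths)
  ng <- nrow(counts)
  pmat <- matrix(1, ng, length(ko))
  lfc <- matrix(0, ng, length(ko))
  for (g in seq_len(ng)) {
    cvals <- norm[g, ctrl]
    cmean <- mean(cvals)
    disp <- moments_dispersion(cvals, floor = dispersion_floor)
    mu <- max(cmean, 0.5)
    for (j in seq_along(ko)) {
      kv <- norm[g, ko[j]]
      if (cmean == 0 && kv == 0) {
        pmat[g, j] <- 1
      } else {
        pmat[g, j] <- nb_tail_test(kv, mu, disp)
      }
      lfc[g, j] <- log2((kv + 0.5) / (cmean + 0.5))
    }
  }
  pfloor <- pmax(pmat, 1e-300)
  combined <- apply(pfloor, 1, fisher_combine)
  log2rpkm_ko <- log2(rpk[, ko, drop = FALSE] + 1e-9)
  log2rpkm_ctrl <- log2(rpk[, ctrl, drop = FALSE] + 1e-9)
  up <- combined < p_combined_max &
    apply(lfc, 1, function(v) all(v > min_log2fc)) &
    apply(log2rpkm_ko, 1, function(v) all(v > min_log2rpkm_up))
  down <- combined < p_combined_max &
    apply(lfc, 1, function(v) all(v < -min_log2fc)) &
    apply(log2rpkm_ctrl, 1, function(v) all(v > min_log2rpkm_up))
  status <- ifelse(up, "up", ifelse(down, "down", "unchanged"))
  gene <- if (!is.null(rownames(counts))) rownames(counts) else sprintf("gene_%d", seq_len(ng))
  list(
    table = data.frame(gene = gene, status = status, combined_p = combined,
                       mean_log2fc = rowMeans(lfc), stringsAsFactors = FALSE),
    p = pmat, log2fc = lfc, rpkm = rpk, size_factors = sf
  )
}

#' Activated/repressed gene calls between two developmental stages
#'
#' Group-vs-group variant of the DE machinery. A gene is "activated" at
#' stage B when each B sample, tested against the stage-A group, shows a
#' significant increase (Fisher-combined p below `p_max`, every
#' per-comparison log2 FC above `min_log2fc`) and its mean log2(RPKM) in
#' the lower-expressed stage (A) is below `max_log2rpkm_low`. "Repressed"
#' is defined as activation with the stages swapped, so
#' repressed(A, B) = activated(B, A) holds exactly.
#'
#' @param counts genes x samples raw counts.
#' @param labels per-sample stage labels, "A" (reference) or "B".
#' @param gene_lengths bp.
#' @param p_max combined-p threshold.
#' @param min_log2fc per-comparison log2 FC threshold (default 1).
#' @param max_log2rpkm_low mean log2(RPKM) ceiling in the lower stage
#'   (default 4).
#' @return data.frame with gene, status in {activated, repressed,
#'   unchanged}, and combined p-values for each direction.
#' @export
call_state_transition <- function(counts, labels, gene_lengths,
                                  p_max = 0.05, min_log2fc = 1,
                                  max_log2rpkm_low = 4) {
  stopifnot(all(labels %in% c("A", "B")))
  direction_up <- function(ref_label) {
    lab <- ifelse(labels == ref_label, "control", "ko")
    res <- call_de(counts, lab, gene_lengths, p_combined_max = p_max,
                   min_log2fc = min_log2fc, min_log2rpkm_up = -Inf)
    low <- which(labels == ref_label)
    mean_l2rpkm_low <- rowMeans(log2(res$rpkm[, low, drop = FALSE] + 1e-9))
    list(call = res$table$status == "up" & mean_l2rpkm_low < max_log2rpkm_low,
         p = res$table$combined_p, gene = res$table$gene)
  }
  act <- direction_up("A")   # up at B relative to A
  rep_ <- direction_up("B")  # up at A relative to B == repressed at B
  status <- ifelse(act$call, "activated", ifelse(rep_$call, "repressed", "unchanged"))
  data.frame(gene = act$gene, status = status,
             p_activated = act$p, p_repressed = rep_$p,
             stringsAsFactors = FALSE)
}

#' Hypergeometric chromosome enrichment of a gene set
#'
#' Tests whether DE genes concentrate on one chromosome (e.g. the X) more
#' than expected: upper-tail P(X >= observed) drawing |de_genes| genes
#' from the annotated population.
#'
#' @param de_gene_ids character vector of called gene ids.
#' @param genes gene table with gene_id and chrom.
#' @param chrom chromosome of interest (default "chrX").
#' @return list with `n_de`, `n_on_chrom`, `fraction`, `p`.
#' @export
chromosome_enrichment <- function(de_gene_ids, genes, chrom = "chrX") {
  n_de <- length(de_gene_ids)
  m <- sum(genes$chrom == chrom)
  N <- nrow(genes)
  obs <- sum(genes$chrom[match(de_gene_ids, genes$gene_id)] == chrom, na.rm = TRUE)
  p <- if (n_de == 0) 1 else
    stats::phyper(obs - 1, m, N - m, n_de, lower.tail = FALSE)
  list(n_de = n_de, n_on_chrom = obs,
       fraction = if (n_de > 0) obs / n_de else NA_real_, p = p)
}
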
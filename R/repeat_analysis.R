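#' Normalize repeat-locus counts
#'
#' Unique-mapping repeat reads are normalized by the total number of
#' reads aligned to protein-coding genes (per million) and by repeat
#' length (per kb) — not by the repeat library itself, so global repeat
#' derepression cannot mask itself.
#'
#' @param counts loci x samples count matrix.
#' @param pc_read_totals per-sample protein-coding read totals.
#' @param locus_lengths locus lengths in bp.
#' @return normalized loci x samples matrix.
#' @export
normalize_repeats <- function(counts, pc_read_totals, locus_lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(pc_read_totals) == ncol(counts),
            length(locus_lengths) == nrow(counts),
            all(pc_read_totals > 0), all(locus_lengths > 0))
  out <- sweep(counts, 2, pc_read_totals / 1e6, "/")
  sweep(out, 1, locus_lengths / 1000, "/")
}

#' Differentially expressed repeat loci
#'
#' Reuses the Fisher-combined NB machinery of [call_de()] on repeat
#' counts, with size factors derived from protein-coding read totals
#' (scaled to geometric mean 1). Loci with fewer than `min_total_reads`
#' reads across samples are considered uncovered and never called.
#'
#' @param counts loci x samples raw counts.
#' @param labels "control"/"ko" per sample.
#' @param pc_read_totals per-sample protein-coding read totals.
#' @param locus_lengths bp.
#' @param min_total_reads coverage floor (default 5).
#' @param ... passed to [call_de()].
#' @return the [call_de()] result list; uncovered loci are "unchanged".
#' @export
de_repeat_loci <- function(counts, labels, pc_read_totals, locus_lengths,
                           min_total_reads = 5, ...) {
  sf <- pc_read_totals / exp(mean(log(pc_read_totals)))
  res <- call_de(counts, labels, locus_lengths, sf = sf, ...)
  low <- rowSums(as.matrix(counts)) < min_total_reads
  res$table$status[low] <- "unchanged"
  res
}

#' Identify mark-regulated repeat subfamilies
#'
#' For each subfamily with at least `min_loci` loci, the fraction of
#' marked loci and of KO-upregulated loci are compared against the
#' genome-wide fractions over all other loci by one-sided Fisher exact
#' tests. A subfamily is flagged as regulated by the mark iff BOTH
#' BH-adjusted p-values are below `alpha`: its loci are both
#' preferentially marked and preferentially derepressed.
#'
#' @param subfamily per-locus subfamily labels.
#' @param marked per-locus logical mark status.
#' @param upregulated per-locus logical DE-up status.
#' @param min_loci minimum subfamily size (default 20).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return data.frame per subfamily: n_loci, frac_marked, frac_upreg,
#'   p_marked, p_upreg (raw), padj_marked, padj_upreg, regulated.
#' @export
subfamily_scan <- function(subfamily, marked, upregulated,
                           min_loci = 20, alpha = 0.05) {
  stopifnot(length(marked) == length(subfamily),
            length(upregulated) == length(subfamily))
  fams <- names(which(table(subfamily) >= min_loci))
  one <- function(fam) {
    inf <- subfamily == fam
    test <- function(flag) {
      tab <- matrix(c(sum(flag & inf), sum(!flag & inf),
                      sum(flag & !inf), sum(!flag & !inf)), 2, byrow = TRUE)
      fisher_exact_2x2(tab, alternative = "greater")
    }
    data.frame(subfamily = fam, n_loci = sum(inf),
               frac_marked = mean(marked[inf]),
               frac_upreg = mean(upregulated[inf]),
               p_marked = test(marked), p_upreg = test(upregulated),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(fams, one))
  if (is.null(out)) return(out)
  out$padj_marked <- bh_adjust(out$p_marked)
  out$padj_upreg <- bh_adjust(out$p_upreg)
  out$regulated <- out$padj_marked < alpha & out$padj_upreg < alpha
  rownames(out) <- NULL
  out
}
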
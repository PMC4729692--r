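#' Call active enhancers from peak sets
#'
#' A p300 peak is kept iff it overlaps at least one H3K27ac peak AND at
#' least one H3K4me1 peak AND no promoter. Kept peaks are emitted as
#' summit +/- 800 bp regions (width 1601 bp); when peaks carry no summit
#' the BED midpoint is used. Regions are clipped at chromosome edges when
#' `chrom_sizes` is given.
#'
#' @param p300,k27ac,k4me1 peak region tables.
#' @param promoters promoter region table.
#' @param chrom_sizes optional named chromosome lengths for clipping.
#' @param flank half-width around the summit (default 800).
#' @return region table of kind `"enhancer"` with a `source_peak` column
#'   tracing each region to its p300 peak.
#' @export
call_active_enhancers <- function(p300, k27ac, k4me1, promoters,
                                  chrom_sizes = NULL, flank = 800) {
  if (nrow(p300) == 0) return(p300)
  has <- function(b) {
    if (nrow(b) == 0) return(rep(FALSE, nrow(p300)))
    seq_len(nrow(p300)) %in% intersect_regions(p300, b)$a_idx
  }
  keep <- has(k27ac) & has(k4me1) & !has(promoters)
  kept <- p300[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    out <- regions(character(0), numeric(0), numeric(0))
    out$source_peak <- character(0)
    return(out)
  }
  summit <- if ("summit" %in% names(kept)) kept$summit
            else floor((kept$start + kept$end) / 2)
  start <- pmax(0, summit - flank)
  end <- summit + flank + 1
  if (!is.null(chrom_sizes)) end <- pmin(end, chrom_sizes[kept$chrom])
  out <- regions(kept$chrom, start, end,
                 id = sprintf("enh_%s", kept$id), kind = "enhancer")
  out$source_peak <- kept$id
  out
}

#' Classify enhancer epigenetic states from mark calls
#'
#' Deterministic precedence over the per-enhancer mark calls:
#' dual_k9_k27ac (K9 and K27ac both marked) > k9_marked > k27_poised
#' (K27me3 marked, K9 not) > active (K27ac only) > inactive.
#'
#' @param k9,k27,k27ac logical vectors: marked status per enhancer for
#'   H3K9me2, H3K27me3 and H3K27ac (from [call_marked()]).
#' @return character vector of states.
#' @export
classify_enhancer_states <- function(k9, k27, k27ac) {
  n <- length(k9)
  stopifnot(length(k27) == n, length(k27ac) == n)
  state <- rep("inactive", n)
  state[k27ac] <- "active"
  state[k27 & !k9] <- "k27_poised"
  state[k9] <- "k9_marked"
  state[k9 & k27ac] <- "dual_k9_k27ac"
  state
}

#' Fractions of stage-A-active enhancers per state at stage B
#'
#' For enhancers active at stage A, tabulates the states observed at
#' stage B — in particular the fraction gaining a repressive mark.
#'
#' @param state_a,state_b per-enhancer state labels at the two stages.
#' @return data.frame of state, count and fraction (of A-active
#'   enhancers).
#' @export
enhancer_class_fractions <- function(state_a, state_b) {
  stopifnot(length(state_a) == length(state_b))
  act <- state_a == "active"
  n <- sum(act)
  if (n == 0) return(data.frame(state = character(0), count = integer(0),
                                fraction = numeric(0)))
  tab <- table(state_b[act])
  data.frame(state = names(tab), count = as.integer(tab),
             fraction = as.integer(tab) / n, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Expression of genes proximal to each enhancer state
#'
#' Assigns each enhancer its nearest gene, then contrasts the expression
#' of genes near each repressive state against genes near active
#' enhancers with the rank-sum test and effect size r. Nearest-gene
#' assignment is a proxy; enhancers can regulate distant promoters, so
#' individual assignments may be wrong even when the group-level contrast
#' is informative.
#'
#' @param enhancers region table.
#' @param states per-enhancer state labels.
#' @param genes gene table.
#' @param expression named per-gene expression values (e.g. mean
#'   log2 RPKM), names = gene ids.
#' @param reference state used as the comparison group (default
#'   "active").
#' @return data.frame per state: n, median expression, p and r vs the
#'   reference (NA when a group has < 2 values).
#' @export
proximal_expression_contrast <- function(enhancers, states, genes, expression,
                                         reference = "active") {
  ng <- nearest_gene(enhancers, genes)
  expr <- expression[ng$gene_id]
  ref_vals <- expr[states == reference & !is.na(expr)]
  out <- lapply(unique(states), function(s) {
    vals <- expr[states == s & !is.na(expr)]
    if (s == reference || length(vals) < 2 || length(ref_vals) < 2) {
      p <- NA_real_; r <- NA_real_; stars <- NA_character_
    } else {
      w <- wilcoxon_rank_sum(vals, ref_vals)
      p <- w$p; r <- w$r; stars <- w$stars
    }
    data.frame(state = s, n = length(vals),
               median_expr = if (length(vals)) stats::median(vals) else NA_real_,
               p = p, r = r, stars = stars, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
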
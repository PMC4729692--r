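#' End-to-end run configuration
#'
#' Combines a [sim_config()] (or paths to pre-generated inputs) with the
#' analysis thresholds used throughout: DE at combined p < 0.05, per-
#' comparison log2 FC > 1.4, log2 RPKM > 1; differential enrichment at
#' p < 0.05, |log2 FC| > 2; k = 3 mark-calling clusters; motif site
#' p = 1e-5 with 1000 background sets.
#'
#' @param seed global seed; every stochastic stage derives a named
#'   sub-seed from it.
#' @param sim a [sim_config()]; defaults to `sim_config(seed)`.
#' @param de_p,de_min_log2fc,de_min_log2rpkm DE thresholds.
#' @param diff_p,diff_min_log2fc differential-enrichment thresholds.
#' @param kmeans_k mark-calling cluster count.
#' @param motif_p_site,motif_n_sets motif-enrichment settings.
#' @param run_motifs include the motif-enrichment stage (sequence
#'   simulation dominates runtime; default TRUE).
#' @param out_dir optional directory to serialize outputs into.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, sim = sim_config(seed),
                       de_p = 0.05, de_min_log2fc = 1.4, de_min_log2rpkm = 1,
                       diff_p = 0.05, diff_min_log2fc = 2,
                       kmeans_k = 3,
                       motif_p_site = 1e-5, motif_n_sets = 1000,
                       run_motifs = TRUE, out_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Run the full synthetic-data pipeline
#'
#' Simulate -> quantify -> call -> classify -> report: generates a
#' genome with planted truth, ChIP counts and enrichment for both marks
#' over promoters and gene bodies, k-means mark calls, Fisher-combined
#' DE calls, repeat subfamily scan, enhancer-state classification, the
#' promoter mark/upregulation overlap statistics, and (optionally) motif
#' enrichment in K9-gaining enhancers. Deterministic given the config.
#'
#' @param config a [run_config()].
#' @return list with `summary` (counts and test results; serializable to
#'   JSON), `truth_recovery` (precision/recall per stage) and the
#'   intermediate objects under `details`.
#' @export
run_all <- function(config) {
  sim <- simulate_genome(config$sim)
  ann <- sim$annotation
  truth <- sim$truth

  # --- ChIP enrichment and mark calls (promoters; gene bodies share truth)
  marks <- list(H3K9me2 = truth$gene_marked_k9, H3K27me3 = truth$gene_marked_k27)
  calls <- list(); enrich <- list()
  for (mk in names(marks)) {
    tab <- simulate_chip_counts(ann$promoters, marks[[mk]], config$sim, mark = mk)
    enr <- log2_enrichment(tab)
    calls[[mk]] <- call_marked(enr$value, k = config$kmeans_k)
    enrich[[mk]] <- enr
  }
  mark_recovery <- lapply(names(marks), function(mk) {
    pred <- calls[[mk]]$status == "marked"
    truthv <- marks[[mk]]
    list(mark = mk,
         precision = if (sum(pred)) sum(pred & truthv) / sum(pred) else NA,
         recall = if (sum(truthv)) sum(pred & truthv) / sum(truthv) else NA)
  })

  # --- differential expression
  expr <- simulate_expression(sim)
  de <- call_de(expr$counts, expr$labels, expr$gene_lengths,
                p_combined_max = config$de_p,
                min_log2fc = config$de_min_log2fc,
                min_log2rpkm_up = config$de_min_log2rpkm)
  de_up <- de$table$status == "up"
  xl <- chromosome_enrichment(de$table$gene[de_up], ann$genes, chrom = "chrX")

  # --- promoter mark x upregulation overlap (and mark-mark anticorrelation)
  k9 <- calls$H3K9me2$status == "marked"
  k27 <- calls$H3K27me3$status == "marked"
  safe_chi2 <- function(a, b) {
    tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(list(chisq = NA_real_, df = 1L, p = NA_real_))
    }
    chi2_overlap(tab)
  }
  overlap_tests <- list(k9_vs_up = safe_chi2(k9, de_up),
                        k9_vs_k27 = safe_chi2(k9, k27))
  dual_frac <- mean(k9 & k27)

  # --- repeats
  reps <- simulate_repeats(sim, expr)
  rde <- de_repeat_loci(reps$counts, reps$labels, reps$pc_read_totals,
                        reps$locus_lengths,
                        p_combined_max = config$de_p,
                        min_log2fc = config$de_min_log2fc)
  scan <- subfamily_scan(reps$subfamily,
                         marked = truth$locus_marked,
                         upregulated = rde$table$status == "up")
  flagged <- if (is.null(scan)) character(0) else scan$subfamily[scan$regulated]

  # --- enhancers
  enh <- call_active_enhancers(ann$peaks$p300, ann$peaks$k27ac,
                               ann$peaks$k4me1, ann$promoters,
                               chrom_sizes = ann$chrom_sizes)
  st <- truth$enhancer_state
  # Mark calling is genome-wide in spirit: enhancers are clustered jointly
  # with unmarked background windows so the "most enriched cluster" rule
  # sees marked regions as a minority, as it does on real genomes.
  n_enh <- nrow(ann$enhancers)
  decoys <- sample_background_sets(ann$genes, ann$chrom_sizes,
                                   widths = rep(1601, 4 * n_enh), n_sets = 1,
                                   seed = child_seed(config$seed, "enh_decoys"))[[1]]
  joint <- rbind(as.data.frame(ann$enhancers),
                 cbind(as.data.frame(decoys)[, c("chrom", "start", "end", "strand")],
                       id = decoys$id, kind = "other"))
  joint <- regions(joint$chrom, joint$start, joint$end,
                   id = joint$id, kind = joint$kind)
  with_bg <- function(flag) c(flag, rep(FALSE, nrow(decoys)))
  enh_truths <- list(k9 = st == "k9_gaining", k27 = st == "k27_poised",
                     k27ac = st == "active")
  enh_calls <- lapply(names(enh_truths), function(nm) {
    tab <- simulate_chip_counts(joint, with_bg(enh_truths[[nm]]), config$sim,
                                mark = nm, cell_type = "B",
                                stage = paste0("chip_enh_", nm))
    call_marked(log2_enrichment(tab)$value,
                k = config$kmeans_k)$status[seq_len(n_enh)] == "marked"
  })
  names(enh_calls) <- names(enh_truths)
  states <- classify_enhancer_states(enh_calls$k9, enh_calls$k27, enh_calls$k27ac)
  state_truth_map <- c(active = "active", k9_gaining = "k9_marked",
                       k27_poised = "k27_poised")
  state_acc <- mean(states == state_truth_map[st])
  gain <- enhancer_class_fractions(rep("active", length(st)), states)

  # --- methylation contrast at marked promoters
  prom_cls <- ifelse(k9, "k9", ifelse(k27, "k27", "none"))
  meth <- simulate_methylation(ann$promoters$id, prom_cls, config$sim)
  by_mark <- split(meth$meth, prom_cls[match(meth$id, ann$promoters$id)])
  meth_cmp <- if (length(by_mark$k9) && length(by_mark$k27))
    methylation_compare(by_mark$k27, by_mark$k9) else NULL

  # --- motifs
  motif <- NULL
  if (isTRUE(config$run_motifs)) {
    seqs <- simulate_sequences(sim)
    pw <- pwm_from_consensus(config$sim$motif_consensus,
                             background = config$sim$base_freqs)
    query <- seqs$enhancer_seqs[st == "k9_gaining"]
    bg_sets <- sample_background_sets(
      ann$genes, ann$chrom_sizes, widths = rep(1601, length(query)),
      n_sets = config$motif_n_sets,
      seed = child_seed(config$seed, "motif_bg"))
    bg_seqs <- lapply(bg_sets, function(r) region_sequences(seqs$genome, r))
    motif <- empirical_enrichment(query, bg_seqs, pw, p_site = config$motif_p_site)
  }

  summary <- list(
    seed = config$seed,
    n_genes = nrow(ann$genes),
    n_marked = list(H3K9me2 = sum(k9), H3K27me3 = sum(k27)),
    dual_marked_promoter_fraction = dual_frac,
    n_de = list(up = sum(de_up), down = sum(de$table$status == "down")),
    chrX_enrichment = list(fraction = xl$fraction, p = xl$p),
    overlap = list(
      k9_vs_up = overlap_tests$k9_vs_up[c("chisq", "p")],
      k9_vs_k27 = overlap_tests$k9_vs_k27[c("chisq", "p")]),
    n_regulated_subfamilies = length(flagged),
    regulated_subfamilies = flagged,
    n_enhancers = nrow(enh),
    enhancer_states = as.list(table(states)),
    enhancer_k9_gain_fraction =
      if (any(gain$state == "k9_marked")) gain$fraction[gain$state == "k9_marked"] else 0,
    methylation = if (!is.null(meth_cmp))
      list(mean_k27 = meth_cmp$mean_a, mean_k9 = meth_cmp$mean_b,
           p = meth_cmp$test$p) else NULL,
    motif = if (!is.null(motif))
      motif[c("query_fraction", "background_mean_fraction", "fold", "empirical_p")]
      else NULL
  )
  truth_recovery <- list(
    marks = mark_recovery,
    de_sensitivity = if (sum(truth$gene_de_up))
      sum(de_up & truth$gene_de_up) / sum(truth$gene_de_up) else NA,
    de_false_rate = if (sum(!truth$gene_de_up))
      sum(de_up & !truth$gene_de_up) / sum(!truth$gene_de_up) else NA,
    subfamily_missed = setdiff(truth$regulated_subfamilies, flagged),
    subfamily_false = setdiff(flagged, truth$regulated_subfamilies),
    enhancer_state_accuracy = state_acc
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(de$table, file.path(config$out_dir, "de_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(scan))
      utils::write.table(scan, file.path(config$out_dir, "subfamilies.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(enh, file.path(config$out_dir, "active_enhancers.bed"))
  }
  list(summary = summary, truth_recovery = truth_recovery,
       details = list(sim = sim, expr = expr, de = de, calls = calls,
                      enrich = enrich, repeats = reps, repeat_scan = scan,
                      enhancers = enh, enhancer_states = states,
                      motif = motif))
}
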
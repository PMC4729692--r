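#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults mirror
#' the study conditions being emulated: 4 knockout and 4 control embryos,
#' two ChIP replicates, planted ChIP log2 enrichment of 2 at marked
#' regions, planted expression log2 fold-change of 3 in upregulated
#' genes, NB dispersion 0.1, mutually exclusive H3K9me2/H3K27me3 marking
#' (10% of genes each), and beta-distributed CpG methylation that is high
#' at K9-marked and low at K27-marked regions.
#'
#' @param seed mandatory integer seed; all generators derive
#'   deterministic sub-seeds from it.
#' @param n_chroms number of chromosomes; the last one is named "chrX"
#'   and receives ~5% of genes for chromosome-enrichment tests.
#' @param chrom_len_bp length of each chromosome.
#' @param n_genes,gene_len_range_bp gene count and body-length range.
#' @param n_enhancers intergenic enhancers (each 1601 bp, summit +/-800).
#' @param frac_enh_k9,frac_enh_k27 fractions of enhancers fated to gain
#'   H3K9me2 / H3K27me3 at the later stage (rest stay active).
#' @param n_repeat_subfamilies,loci_per_subfamily,repeat_len_range_bp
#'   repeat annotation shape.
#' @param n_regulated_subfamilies subfamilies planted as mark-regulated.
#' @param rep_marked_frac_reg,rep_marked_frac_bg fraction of marked loci
#'   in regulated vs background subfamilies (0.6 / 0.1).
#' @param rep_upreg_frac_reg,rep_upreg_frac_bg fraction of KO-upregulated
#'   loci in regulated vs background subfamilies (0.3 / 0.01).
#' @param n_ctrl_embryos,n_ko_embryos RNA-seq replicate structure.
#' @param n_chip_replicates ChIP biological replicates (2).
#' @param frac_marked_k9,frac_marked_k27 planted mutually exclusive gene
#'   marking fractions (sum must be <= 1).
#' @param planted_chip_log2fc ChIP enrichment planted at marked regions.
#' @param planted_de_log2fc expression log2 FC planted in DE genes.
#' @param frac_de fraction of genes planted as KO-upregulated.
#' @param de_from_marked draw DE genes preferentially from marked genes
#'   (couples marking to derepression, as in the biology emulated).
#' @param nb_dispersion RNA-seq NB dispersion.
#' @param chip_nb_dispersion extra-Poisson ChIP dispersion (0 = Poisson).
#' @param mean_depth_per_region mean input reads per kb of region.
#' @param mean_expression mean baseline expression counts per gene.
#' @param rep_mean_expression mean baseline counts per repeat locus.
#' @param motif_consensus consensus planted in K9-fated enhancers.
#' @param planted_motif_rate fraction of K9-fated enhancers receiving a
#'   planted occurrence.
#' @param base_freqs background base frequencies (A, C, G, T).
#' @param beta_params_meth_high,beta_params_meth_low,beta_params_meth_mid
#'   Beta(shape1, shape2) for CpG methylation at K9-marked, K27-marked
#'   and unmarked regions.
#' @param cpgs_per_region mean CpGs simulated per region.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chroms = 3, chrom_len_bp = 3e6,
                       n_genes = 300, gene_len_range_bp = c(2000, 10000),
                       n_enhancers = 100,
                       frac_enh_k9 = 0.12, frac_enh_k27 = 0.18,
                       n_repeat_subfamilies = 20, loci_per_subfamily = 100,
                       repeat_len_range_bp = c(300, 1000),
                       n_regulated_subfamilies = 2,
                       rep_marked_frac_reg = 0.6, rep_marked_frac_bg = 0.1,
                       rep_upreg_frac_reg = 0.3, rep_upreg_frac_bg = 0.01,
                       n_ctrl_embryos = 4, n_ko_embryos = 4,
                       n_chip_replicates = 2,
                       frac_marked_k9 = 0.1, frac_marked_k27 = 0.1,
                       planted_chip_log2fc = 2.0,
                       planted_de_log2fc = 3.0, frac_de = 0.04,
                       de_from_marked = TRUE,
                       nb_dispersion = 0.1, chip_nb_dispersion = 0,
                       mean_depth_per_region = 100,
                       mean_expression = 100, rep_mean_expression = 50,
                       motif_consensus = "TGACGTCATC",
                       planted_motif_rate = 0.5,
                       base_freqs = c(A = 0.29, C = 0.21, G = 0.21, T = 0.29),
                       beta_params_meth_high = c(8, 2),
                       beta_params_meth_low = c(2, 8),
                       beta_params_meth_mid = c(5, 5),
                       cpgs_per_region = 20) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  fr <- c(cfg$frac_marked_k9, cfg$frac_marked_k27, cfg$frac_de,
          cfg$frac_enh_k9, cfg$frac_enh_k27, cfg$planted_motif_rate)
  if (any(fr < 0 | fr > 1)) stop("sim_config: fractions must be in [0, 1]")
  if (cfg$frac_marked_k9 + cfg$frac_marked_k27 > 1)
    stop("sim_config: frac_marked_k9 + frac_marked_k27 must be <= 1")
  structure(cfg, class = "sim_config")
}

# Deterministic sub-seed per generator stage so stages are independently
# reproducible from the single global seed.
child_seed <- function(seed, stage) {
  ch <- utf8ToInt(stage)
  h <- sum(ch * seq_along(ch))
  as.integer((as.numeric(seed) %% 65536 * 7919 + h * 104729 + 17) %% 2147483647L)
}

# Allocate an interval of width w inside the free intergenic segments.
# free: data.frame(chrom, start, end); returns list(pick, free updated).
take_slot <- function(free, w) {
  room <- free$end - free$start - w
  ok <- which(room >= 0)
  if (length(ok) == 0) return(NULL)
  i <- if (length(ok) == 1) ok else sample(ok, 1, prob = room[ok] + 1)
  off <- floor(stats::runif(1, 0, room[i] + 1))
  s <- free$start[i] + off
  pick <- data.frame(chrom = free$chrom[i], start = s, end = s + w)
  left <- free[i, ]; left$end <- s
  right <- free[i, ]; right$start <- s + w
  keep <- rbind(free[-i, ], left[left$end - left$start > 50, ],
                right[right$end - right$start > 50, ])
  list(pick = pick, free = keep)
}

#' Simulate a genome annotation with planted epigenetic truth
#'
#' Places non-overlapping gene bodies (about 5% on "chrX"), intergenic
#' enhancers with p300/H3K27ac/H3K4me1 peak intervals, and repeat loci
#' labeled with subfamilies. Plants mutually exclusive H3K9me2/H3K27me3
#' gene marking, KO-upregulated genes (drawn preferentially from marked
#' genes when `de_from_marked`), enhancer fates, and regulated repeat
#' subfamilies. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (genes, chrom_sizes, promoters,
#'   enhancers, repeats, peaks) and `truth` (per-gene marks and DE
#'   status, per-enhancer state, per-locus mark/upregulation flags,
#'   per-subfamily regulated flag).
#' @export
simulate_genome <- function(config) {
  set.seed(child_seed(config$seed, "genome"))
  chroms <- c(if (config$n_chroms > 1) sprintf("chr%d", seq_len(config$n_chroms - 1)), "chrX")
  chrom_sizes <- stats::setNames(rep(config$chrom_len_bp, config$n_chroms), chroms)

  # genes: ~5% on chrX, rest spread over autosomes
  n_x <- max(1, round(0.05 * config$n_genes))
  n_auto <- config$n_genes - n_x
  autos <- setdiff(chroms, "chrX")
  gene_chrom <- c(sample(rep_len(autos, n_auto)), rep("chrX", n_x))
  glen <- floor(stats::runif(config$n_genes, config$gene_len_range_bp[1],
                             config$gene_len_range_bp[2] + 1))
  genes <- do.call(rbind, lapply(chroms, function(chr) {
    idx <- which(gene_chrom == chr)
    if (!length(idx)) return(NULL)
    gaps <- floor(stats::runif(length(idx), 5000, 15000))
    starts <- cumsum(c(gaps[1], glen[idx][-length(idx)] + gaps[-1]))
    ends <- starts + glen[idx]
    if (max(ends) > chrom_sizes[chr] - 1000)
      stop("simulate_genome: chromosome too short for gene quota; increase chrom_len_bp")
    data.frame(idx = idx, chrom = chr, start = starts, end = ends,
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$idx), ]
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  gene_df <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
    gene_name = sprintf("Gene%04d", seq_len(config$n_genes)),
    chrom = genes$chrom, start = genes$start, end = genes$end,
    strand = strand,
    cpg_class = sample(c("HCP", "ICP", "LCP"), config$n_genes,
                       replace = TRUE, prob = c(0.6, 0.2, 0.2)),
    length = genes$end - genes$start,
    stringsAsFactors = FALSE
  )
  gene_df$tss <- ifelse(gene_df$strand == "-", gene_df$end - 1, gene_df$start)

  # planted mutually exclusive marks
  n_k9 <- round(config$frac_marked_k9 * config$n_genes)
  n_k27 <- round(config$frac_marked_k27 * config$n_genes)
  perm <- sample(config$n_genes)
  k9_genes <- perm[seq_len(n_k9)]
  k27_genes <- perm[n_k9 + seq_len(n_k27)]
  marked_k9 <- seq_len(config$n_genes) %in% k9_genes
  marked_k27 <- seq_len(config$n_genes) %in% k27_genes

  # planted DE genes, preferentially among K9-marked (derepression on KO)
  n_de <- round(config$frac_de * config$n_genes)
  if (config$de_from_marked && n_de > 0) {
    pool1 <- which(marked_k9)
    pick <- pool1[sample.int(length(pool1), min(n_de, length(pool1)))]
    rest <- setdiff(seq_len(config$n_genes), pick)
    if (length(pick) < n_de)
      pick <- c(pick, sample(rest, n_de - length(pick)))
  } else {
    pick <- if (n_de > 0) sample(config$n_genes, n_de) else integer(0)
  }
  de_up <- seq_len(config$n_genes) %in% pick

  # free intergenic space for enhancers and repeats
  free <- do.call(rbind, lapply(chroms, function(chr) {
    g <- gene_df[gene_df$chrom == chr, ]
    bounds <- c(0, sort(c(g$start, g$end)), chrom_sizes[chr])
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    data.frame(chrom = chr, start = starts + 200, end = ends - 200,
               stringsAsFactors = FALSE)
  }))
  free <- free[free$end - free$start > 100, ]

  place_many <- function(n, widths) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      slot <- take_slot(free, widths[i])
      if (is.null(slot)) stop("simulate_genome: no intergenic room left")
      out[[i]] <- slot$pick
      free <<- slot$free
    }
    do.call(rbind, out)
  }

  enh <- place_many(config$n_enhancers, rep(1601, config$n_enhancers))
  enh_states <- sample(c(
    rep("k9_gaining", round(config$frac_enh_k9 * config$n_enhancers)),
    rep("k27_poised", round(config$frac_enh_k27 * config$n_enhancers)),
    rep("active", config$n_enhancers -
          round(config$frac_enh_k9 * config$n_enhancers) -
          round(config$frac_enh_k27 * config$n_enhancers))
  ))
  enhancers <- regions(enh$chrom, enh$start, enh$end,
                       id = sprintf("enh_%04d", seq_len(config$n_enhancers)),
                       kind = "enhancer")

  n_loci <- config$n_repeat_subfamilies * config$loci_per_subfamily
  rlen <- floor(stats::runif(n_loci, config$repeat_len_range_bp[1],
                             config$repeat_len_range_bp[2] + 1))
  rep_pos <- place_many(n_loci, rlen)
  subfam <- rep(sprintf("SubFam%02d", seq_len(config$n_repeat_subfamilies)),
                each = config$loci_per_subfamily)
  rep_class <- rep(sample(c("ERV-L", "ERV-K", "L1", "MaLR"),
                          config$n_repeat_subfamilies, replace = TRUE),
                   each = config$loci_per_subfamily)
  repeats <- regions(rep_pos$chrom, rep_pos$start, rep_pos$end,
                     id = sprintf("rep_%05d", seq_len(n_loci)),
                     kind = "repeat_locus")
  repeats$subfamily <- subfam
  repeats$class <- rep_class

  reg_sub <- sprintf("SubFam%02d",
                     sample(config$n_repeat_subfamilies,
                            config$n_regulated_subfamilies))
  is_reg <- subfam %in% reg_sub
  pm <- ifelse(is_reg, config$rep_marked_frac_reg, config$rep_marked_frac_bg)
  pu <- ifelse(is_reg, config$rep_upreg_frac_reg, config$rep_upreg_frac_bg)
  loc_marked <- stats::runif(n_loci) < pm
  loc_upreg <- stats::runif(n_loci) < pu

  # summit-centred peak intervals accompanying each (initially active) enhancer
  summit <- floor((enh$start + enh$end) / 2)
  mkpeaks <- function(half, tag) regions(
    enh$chrom, pmax(0, summit - half), summit + half,
    id = sprintf("%s_%04d", tag, seq_len(config$n_enhancers)), kind = "peak")
  peaks <- list(p300 = mkpeaks(200, "p300"),
                k27ac = mkpeaks(400, "k27ac"),
                k4me1 = mkpeaks(400, "k4me1"))

  # planted motif occurrences in K9-fated enhancers
  w <- nchar(config$motif_consensus)
  k9_enh <- which(enh_states == "k9_gaining")
  gets_motif <- k9_enh[stats::runif(length(k9_enh)) < config$planted_motif_rate]
  motif_offset <- rep(NA_integer_, config$n_enhancers)
  motif_offset[gets_motif] <-
    floor(stats::runif(length(gets_motif), 100, 1601 - w - 100))

  list(
    annotation = list(
      genes = gene_df, chrom_sizes = chrom_sizes,
      gene_bodies = regions(gene_df$chrom, gene_df$start, gene_df$end,
                            strand = gene_df$strand, id = gene_df$gene_id,
                            kind = "gene_body"),
      promoters = promoters_of(gene_df, chrom_sizes),
      enhancers = enhancers, repeats = repeats, peaks = peaks
    ),
    truth = list(
      gene_marked_k9 = marked_k9, gene_marked_k27 = marked_k27,
      gene_de_up = de_up,
      enhancer_state = enh_states,
      enhancer_motif_offset = motif_offset,
      locus_marked = loc_marked, locus_upreg = loc_upreg,
      regulated_subfamilies = sort(reg_sub),
      subfamily = subfam
    ),
    config = config
  )
}

#' Simulate per-region ChIP and input counts
#'
#' Input counts are Poisson with mean depth x region length in kb; ChIP
#' counts at truly marked regions have their mean multiplied by
#' 2^planted_chip_log2fc. Replicates carry independent noise. When
#' `chip_nb_dispersion` > 0 counts are negative-binomial instead,
#' modelling extra-Poisson biological variance.
#'
#' @param regions region table.
#' @param marked logical vector of true mark status per region.
#' @param config a [sim_config()].
#' @param mark,cell_type labels stored on the output table.
#' @param stage seed sub-stream label (vary to decorrelate tables).
#' @return a [region_count_table()].
#' @export
simulate_chip_counts <- function(regions, marked, config,
                                 mark = "H3K9me2", cell_type = "A",
                                 stage = paste0("chip_", mark, "_", cell_type)) {
  set.seed(child_seed(config$seed, stage))
  stopifnot(length(marked) == nrow(regions))
  len_kb <- (regions$end - regions$start) / 1000
  base_mu <- config$mean_depth_per_region * len_kb
  chip_mu <- base_mu * ifelse(marked, 2^config$planted_chip_log2fc, 1)
  n <- nrow(regions)
  draw <- function(mu) {
    if (config$chip_nb_dispersion > 0) {
      stats::rnbinom(n, size = 1 / config$chip_nb_dispersion, mu = mu)
    } else stats::rpois(n, mu)
  }
  reps <- config$n_chip_replicates
  chip <- vapply(seq_len(reps), function(r) draw(chip_mu), numeric(n))
  input <- vapply(seq_len(reps), function(r) draw(base_mu), numeric(n))
  chip <- matrix(chip, nrow = n); input <- matrix(input, nrow = n)
  region_count_table(regions, chip, input,
                     chip_lib = pmax(colSums(chip), 1),
                     input_lib = pmax(colSums(input), 1),
                     mark = mark, cell_type = cell_type)
}

#' Simulate an embryo RNA-seq count matrix
#'
#' Gene baselines are log-normal around `mean_expression`; counts are
#' negative-binomial with mean baseline x library factor x
#' 2^(planted log2 FC) in KO samples of planted DE genes, at the
#' configured dispersion. Library factors are log-normal (sd 0.2),
#' emulating depth variation between embryos.
#'
#' @param sim output of [simulate_genome()].
#' @param config a [sim_config()].
#' @return list with `counts` (genes x samples), `labels`
#'   ("control"/"ko"), `gene_lengths`, `baselines`, `lib_factors`.
#' @export
simulate_expression <- function(sim, config = sim$config) {
  set.seed(child_seed(config$seed, "expression"))
  ng <- nrow(sim$annotation$genes)
  nc <- config$n_ctrl_embryos; nk <- config$n_ko_embryos
  labels <- c(rep("control", nc), rep("ko", nk))
  baselines <- stats::rlnorm(ng, log(config$mean_expression), 0.5)
  libf <- stats::rlnorm(nc + nk, 0, 0.2)
  lfc <- ifelse(sim$truth$gene_de_up, config$planted_de_log2fc, 0)
  mu <- outer(baselines, libf) *
    2^outer(lfc, as.numeric(labels == "ko"))
  counts <- matrix(
    if (config$nb_dispersion > 0) {
      stats::rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu)
    } else stats::rpois(length(mu), mu),
    nrow = ng,
    dimnames = list(sim$annotation$genes$gene_id,
                    sprintf("%s_%d", labels, seq_along(labels)))
  )
  list(counts = counts, labels = labels,
       gene_lengths = sim$annotation$genes$length,
       baselines = baselines, lib_factors = libf)
}

#' Simulate repeat-locus RNA-seq counts
#'
#' Same NB machinery as [simulate_expression()], planting the configured
#' KO log2 fold-change at truly upregulated loci. Per-sample
#' protein-coding read totals (the normalizer used for repeat
#' quantification) are taken from the paired gene expression matrix.
#'
#' @param sim output of [simulate_genome()].
#' @param expr output of [simulate_expression()] (for pc read totals and
#'   sample structure).
#' @param config a [sim_config()].
#' @return list with `counts`, `labels`, `locus_lengths`,
#'   `pc_read_totals`, `subfamily`.
#' @export
simulate_repeats <- function(sim, expr, config = sim$config) {
  set.seed(child_seed(config$seed, "repeats"))
  rep_ann <- sim$annotation$repeats
  nl <- nrow(rep_ann)
  labels <- expr$labels
  baselines <- stats::rlnorm(nl, log(config$rep_mean_expression), 0.5)
  lfc <- ifelse(sim$truth$locus_upreg, config$planted_de_log2fc, 0)
  mu <- outer(baselines, expr$lib_factors) *
    2^outer(lfc, as.numeric(labels == "ko"))
  counts <- matrix(
    if (config$nb_dispersion > 0) {
      stats::rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu)
    } else stats::rpois(length(mu), mu),
    nrow = nl,
    dimnames = list(rep_ann$id, colnames(expr$counts))
  )
  list(counts = counts, labels = labels,
       locus_lengths = rep_ann$end - rep_ann$start,
       pc_read_totals = colSums(expr$counts),
       subfamily = rep_ann$subfamily)
}

random_dna <- function(n, freqs) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

#' Simulate chromosome and enhancer sequences with planted motifs
#'
#' Chromosome sequences are i.i.d. draws from the configured base
#' frequencies; the planted motif consensus is written into K9-fated
#' enhancers at the offsets recorded in the truth object.
#'
#' @param sim output of [simulate_genome()].
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector of chromosome
#'   sequences), `enhancer_seqs` (named by enhancer id) and `planted`
#'   (data.frame of enhancer id / 0-based offset).
#' @export
simulate_sequences <- function(sim, config = sim$config) {
  set.seed(child_seed(config$seed, "sequences"))
  genome <- vapply(sim$annotation$chrom_sizes,
                   function(L) random_dna(L, config$base_freqs), "")
  names(genome) <- names(sim$annotation$chrom_sizes)
  enh <- sim$annotation$enhancers
  off <- sim$truth$enhancer_motif_offset
  w <- nchar(config$motif_consensus)
  for (i in which(!is.na(off))) {
    pos <- enh$start[i] + off[i]  # 0-based genomic offset
    substr(genome[enh$chrom[i]], pos + 1, pos + w) <- config$motif_consensus
  }
  enh_seqs <- region_sequences(genome, enh)
  planted <- data.frame(id = enh$id[!is.na(off)], offset = off[!is.na(off)],
                        stringsAsFactors = FALSE)
  list(genome = genome, enhancer_seqs = enh_seqs, planted = planted)
}

#' Extract region sequences from chromosome sequences
#' @param genome named character vector of chromosome sequences.
#' @param x region table (0-based half-open).
#' @return named character vector of region sequences.
#' @export
region_sequences <- function(genome, x) {
  out <- vapply(seq_len(nrow(x)), function(i)
    substr(genome[[x$chrom[i]]], x$start[i] + 1, x$end[i]), "")
  names(out) <- x$id
  out
}

#' Simulate per-CpG methylation fractions
#'
#' K9-marked regions draw CpG methylation from the "high" beta
#' distribution (default Beta(8,2), mean 0.8), K27-marked regions from
#' the "low" one (Beta(2,8), mean 0.2), and unmarked regions from an
#' intermediate Beta, emulating the observed coupling of H3K9me2 and
#' H3K27me3 with high and low 5meC.
#'
#' @param region_ids region identifiers.
#' @param mark_class per-region class: "k9", "k27" or "none".
#' @param config a [sim_config()].
#' @return data.frame with `id`, `cpg` index and `meth` fraction.
#' @export
simulate_methylation <- function(region_ids, mark_class, config) {
  set.seed(child_seed(config$seed, "methylation"))
  stopifnot(length(region_ids) == length(mark_class))
  n_cpg <- pmax(1, stats::rpois(length(region_ids), config$cpgs_per_region))
  params <- list(k9 = config$beta_params_meth_high,
                 k27 = config$beta_params_meth_low,
                 none = config$beta_params_meth_mid)
  out <- lapply(seq_along(region_ids), function(i) {
    pr <- params[[mark_class[i]]]
    data.frame(id = region_ids[i], cpg = seq_len(n_cpg[i]),
               meth = stats::rbeta(n_cpg[i], pr[1], pr[2]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a simulated dataset to pipeline input files
#'
#' Emits the file dialects the readers consume: BEDs for gene bodies,
#' promoters, enhancers, repeats (name field "subfamily|class") and
#' peaks; a chrom.sizes TSV; the gene annotation TSV; count TSVs; FASTA
#' for enhancer sequences; a methylation TSV; and truth TSVs per entity.
#'
#' @param sim,expr,reps,seqs generator outputs.
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
write_simulated_dataset <- function(sim, expr, reps, seqs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- sim$annotation
  write_bed(ann$gene_bodies, file.path(dir, "gene_bodies.bed"))
  write_bed(ann$promoters, file.path(dir, "promoters.bed"))
  write_bed(ann$enhancers, file.path(dir, "enhancers.bed"))
  rep_bed <- ann$repeats
  rep_bed$id <- paste(rep_bed$subfamily, rep_bed$class, sep = "|")
  rep_bed$id <- sprintf("%s|%s", ann$repeats$id, rep_bed$id)
  write_bed(rep_bed, file.path(dir, "repeats.bed"))
  for (nm in names(ann$peaks))
    write_bed(ann$peaks[[nm]], file.path(dir, paste0(nm, "_peaks.bed")))
  utils::write.table(
    data.frame(chrom = names(ann$chrom_sizes), length = ann$chrom_sizes),
    file.path(dir, "chrom.sizes"), sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    ann$genes[, c("gene_id", "chrom", "start", "end", "strand", "cpg_class")],
    file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(gene_id = rownames(expr$counts), expr$counts),
                     file.path(dir, "expression_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(locus_id = rownames(reps$counts), reps$counts),
                     file.path(dir, "repeat_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- character(2 * length(seqs$enhancer_seqs))
  fa[c(TRUE, FALSE)] <- paste0(">", names(seqs$enhancer_seqs))
  fa[c(FALSE, TRUE)] <- unname(seqs$enhancer_seqs)
  writeLines(fa, file.path(dir, "enhancers.fa"))
  truth <- data.frame(gene_id = ann$genes$gene_id,
                      marked_k9 = sim$truth$gene_marked_k9,
                      marked_k27 = sim$truth$gene_marked_k27,
                      de_up = sim$truth$gene_de_up)
  utils::write.table(truth, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
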
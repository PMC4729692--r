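#' Construct a position weight matrix
#'
#' Columns of the input are base probabilities (or counts) for A, C, G,
#' T per motif position. A pseudocount is added to every cell and rows
#' renormalized, so all entries are strictly positive and each position
#' sums to 1.
#'
#' @param mat width x 4 numeric matrix (columns A, C, G, T).
#' @param background base frequencies (default uniform); must sum to 1.
#' @param name motif name.
#' @param pseudocount added per cell before renormalization
#'   (default 0.01).
#' @return list of class `pwm` with elements `mat`, `background`,
#'   `name`, `width`.
#' @export
pwm <- function(mat, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                name = "motif", pseudocount = 0.01) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 4, all(mat >= 0))
  colnames(mat) <- c("A", "C", "G", "T")
  mat <- mat + pseudocount
  mat <- mat / rowSums(mat)
  background <- background / sum(background)
  names(background) <- c("A", "C", "G", "T")
  structure(list(mat = mat, background = background, name = name,
                 width = nrow(mat)), class = "pwm")
}

#' Build a PWM from a consensus sequence
#' @param consensus DNA string over ACGT.
#' @param match_prob probability of the consensus base per position
#'   (remainder split evenly).
#' @param ... passed to [pwm()].
#' @return a `pwm`.
#' @export
pwm_from_consensus <- function(consensus, match_prob = 0.85, ...) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  m <- matrix((1 - match_prob) / 3, length(bases), 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(bases)) m[i, bases[i]] <- match_prob
  pwm(m, name = consensus, ...)
}

#' Read PWMs from a minimal MEME-format file
#'
#' Supports the MEME version header, optional background frequencies
#' line, and letter-probability matrix blocks.
#'
#' @param path MEME-format text file.
#' @param ... passed to [pwm()] (pseudocount etc.).
#' @return named list of `pwm` objects.
#' @export
read_meme <- function(path, ...) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) && bgl[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (sum(!is.na(vals)) == 4) bg <- stats::setNames(vals[!is.na(vals)], tok[is.na(vals)])
  }
  starts <- grep("^MOTIF", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    rows <- list()
    i <- hdr + 1
    while (i <= length(lines)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(vals) != 4 || anyNA(vals)) break
      rows[[length(rows) + 1]] <- vals
      i <- i + 1
    }
    out[[name]] <- pwm(do.call(rbind, rows), background = bg, name = name, ...)
  }
  out
}

# log2(P_pwm / P_bg) score matrix, width x 4
pwm_score_matrix <- function(x) {
  log2(sweep(x$mat, 2, x$background, "/"))
}

#' Site score threshold for a target p-value
#'
#' Computes the exact distribution of PWM log-odds scores under the
#' background model by dynamic programming over scores discretized to
#' `granularity` bits (per-column score distributions convolved), and
#' returns the smallest discretized score whose upper-tail probability
#' is at most `p`. When no achievable score is rare enough, the returned
#' threshold exceeds the maximum possible score (guaranteeing zero hits)
#' and a warning is issued.
#'
#' @param x a `pwm`.
#' @param p target site p-value (default 1e-5).
#' @param granularity score discretization in bits (default 1e-3).
#' @return list with `threshold` (bits), `tail_prob` (achieved upper-tail
#'   mass), `attainable` (FALSE when the threshold guarantees zero hits).
#' @export
score_threshold <- function(x, p = 1e-5, granularity = 1e-3) {
  stopifnot(p > 0, p <= 1)
  sm <- pwm_score_matrix(x)
  ki <- round(sm / granularity)          # integer scores per column/base
  mins <- apply(ki, 1, min)
  offs <- sweep(ki, 1, mins)             # non-negative offsets
  span <- apply(offs, 1, max)
  probs <- rep(1, 1)                     # distribution over offset grid
  for (j in seq_len(nrow(ki))) {
    res <- numeric(length(probs) + span[j])
    for (b in 1:4) {
      sh <- offs[j, b]
      idx <- seq_along(probs) + sh
      res[idx] <- res[idx] + probs * x$background[b]
    }
    probs <- res
  }
  base_int <- sum(mins)                  # offset 0 corresponds to this score
  tail <- rev(cumsum(rev(probs)))
  # restrict to achievable scores so the threshold is an actual site score
  ok <- which(tail <= p & probs > 0)
  if (length(ok) == 0) {
    warning("score_threshold: requested p below the minimum achievable tail; ",
            "threshold set above the maximum score (zero hits)")
    max_exact <- sum(apply(sm, 1, max))
    return(list(threshold = max_exact + granularity, tail_prob = 0,
                attainable = FALSE))
  }
  k <- ok[1]
  list(threshold = (base_int + k - 1) * granularity, tail_prob = tail[k],
       attainable = TRUE)
}

encode_dna <- function(s) {
  match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
}

#' Reverse-complement a DNA string
#' @param s character DNA sequence.
#' @return reverse complement, via Biostrings.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences, via Biostrings.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

score_windows <- function(code, M) {
  L <- length(code)
  w <- nrow(M)
  if (L < w) return(numeric(0))
  nwin <- L - w + 1
  s <- numeric(nwin)
  bad <- logical(nwin)
  for (j in seq_len(w)) {
    cj <- code[j:(j + nwin - 1)]
    nab <- is.na(cj)
    bad <- bad | nab
    cj[nab] <- 1L
    s <- s + M[j, cj]
  }
  s[bad] <- NA_real_
  s
}

#' Scan sequences for PWM hits on both strands
#'
#' Every window of every sequence is scored with the log2 odds score on
#' both the given strand and its reverse complement; windows containing
#' N are skipped. Offsets are 0-based in the coordinates of the supplied
#' sequence; a minus-strand hit at offset o corresponds to the motif on
#' the reverse-complement strand covering positions [o, o + width).
#'
#' @param seqs named character vector of sequences (A/C/G/T/N).
#' @param x a `pwm`.
#' @param threshold minimum score (bits), e.g. from [score_threshold()].
#' @return data.frame with `id`, `offset`, `strand`, `score`. A
#'   minus-strand hit at offset o means the reverse complement of
#'   [o, o + width) matches the motif.
#' @export
scan_pwm <- function(seqs, x, threshold) {
  M <- pwm_score_matrix(x)
  w <- x$width
  # minus-strand scores come from the reverse-complemented score matrix,
  # so both strands are scored in one pass over each sequence
  Mrc <- M[rev(seq_len(w)), c(4, 3, 2, 1), drop = FALSE]
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    L <- nchar(s)
    if (L < w) return(NULL)
    code <- encode_dna(s)
    fwd <- score_windows(code, M)
    rev_ <- score_windows(code, Mrc)
    hf <- which(!is.na(fwd) & fwd >= threshold)
    hr <- which(!is.na(rev_) & rev_ >= threshold)
    rbind(
      if (length(hf)) data.frame(id = ids[i], offset = hf - 1L, strand = "+",
                                 score = fwd[hf], stringsAsFactors = FALSE),
      if (length(hr)) data.frame(id = ids[i], offset = hr - 1L,
                                 strand = "-", score = rev_[hr],
                                 stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(id = character(0), offset = integer(0),
                                      strand = character(0), score = numeric(0))
  rownames(out) <- NULL
  out
}

#' Sample width-matched random background region sets
#'
#' The allowed space is the union of gene bodies extended by +/-
#' `flank_bp` of flanking intergenic sequence, clipped to chromosome
#' bounds and merged. Each of `n_sets` sets contains one random region
#' per query width, drawn uniformly from the allowed space (segments
#' weighted by the number of valid start positions).
#'
#' @param genes gene table (chrom, start, end).
#' @param chrom_sizes named chromosome lengths.
#' @param widths query region widths to match one-to-one.
#' @param n_sets number of background sets (default 1000).
#' @param seed RNG seed.
#' @param flank_bp flank around gene bodies (default 50000).
#' @return list of `n_sets` region tables.
#' @export
sample_background_sets <- function(genes, chrom_sizes, widths,
                                   n_sets = 1000, seed, flank_bp = 50000) {
  set.seed(seed)
  segs <- do.call(rbind, lapply(names(chrom_sizes), function(chr) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    r <- IRanges::reduce(IRanges::IRanges(
      start = pmax(0, g$start - flank_bp) + 1,
      end = pmin(chrom_sizes[[chr]], g$end + flank_bp)))
    data.frame(chrom = chr, start = BiocGenerics::start(r) - 1,
               end = BiocGenerics::end(r), stringsAsFactors = FALSE)
  }))
  lapply(seq_len(n_sets), function(si) {
    picks <- lapply(seq_along(widths), function(qi) {
      w <- widths[qi]
      nstarts <- segs$end - segs$start - w + 1
      ok <- which(nstarts > 0)
      if (length(ok) == 0) stop("sample_background_sets: no segment fits width ", w)
      i <- if (length(ok) == 1) ok else sample(ok, 1, prob = nstarts[ok])
      s <- segs$start[i] + floor(stats::runif(1, 0, nstarts[i]))
      data.frame(chrom = segs$chrom[i], start = s, end = s + w,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, picks)
    regions(df$chrom, df$start, df$end,
            id = sprintf("bg%d_%d", si, seq_len(nrow(df))), kind = "other")
  })
}

#' Empirical motif enrichment against resampled background sets
#'
#' The statistic is the fraction of regions carrying at least one hit at
#' the site threshold. Fold enrichment is the (epsilon-regularized)
#' ratio of the query fraction to the mean background fraction, and the
#' empirical p-value uses the add-one estimator
#' (1 + #{background sets with fraction >= query}) / (n_sets + 1), which
#' can never return 0.
#'
#' @param query_seqs character vector of query region sequences.
#' @param background_seq_sets list of character vectors, one per
#'   background set.
#' @param x a `pwm`.
#' @param p_site site p-value for the score threshold (default 1e-5).
#' @param threshold optional precomputed score threshold (bits).
#' @param eps regularizer for the fold ratio (default 1e-9).
#' @return list with `query_fraction`, `background_mean_fraction`,
#'   `fold`, `empirical_p`, `threshold`, `n_sets`.
#' @export
empirical_enrichment <- function(query_seqs, background_seq_sets, x,
                                 p_site = 1e-5, threshold = NULL,
                                 eps = 1e-9) {
  if (is.null(threshold)) threshold <- score_threshold(x, p = p_site)$threshold
  frac_hit <- function(seqs) {
    if (length(seqs) == 0) return(0)
    hits <- scan_pwm(seqs, x, threshold)
    length(unique(hits$id)) / length(seqs)
  }
  q <- frac_hit(query_seqs)
  bg <- vapply(background_seq_sets, frac_hit, 0)
  n_sets <- length(bg)
  list(query_fraction = q,
       background_mean_fraction = mean(bg),
       fold = (q + eps) / (mean(bg) + eps),
       empirical_p = (1 + sum(bg >= q)) / (n_sets + 1),
       threshold = threshold, n_sets = n_sets)
}
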
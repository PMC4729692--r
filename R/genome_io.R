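#' Construct a region table
#'
#' Regions are the unit of all interval arithmetic in the package: a
#' data.frame with columns `chrom`, `start`, `end` (0-based half-open
#' coordinates, BED-native), `strand` (`"+"`, `"-"` or `"."`), `id` and
#' `kind`. All coordinates stay 0-based half-open internally; any 1-based
#' display is formatting only.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0 <= start < end.
#' @param strand strand per region; defaults to unstranded (`"."`).
#' @param id unique region identifiers; autogenerated when `NULL`.
#' @param kind feature kind label (`"gene_body"`, `"promoter"`, `"tile"`,
#'   `"enhancer"`, `"repeat_locus"`, `"peak"`, `"other"`).
#' @return a `data.frame` of class `epistate_regions`.
#' @export
regions <- function(chrom, start, end, strand = ".", id = NULL, kind = "other") {
  n <- length(chrom)
  if (is.null(id)) id <- if (n) sprintf("region_%d", seq_len(n)) else character(0)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), n),
    id = as.character(id),
    kind = rep_len(as.character(kind), n),
    stringsAsFactors = FALSE
  )
  validate_regions(df)
  class(df) <- c("epistate_regions", "data.frame")
  df
}

validate_regions <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop("region start must be >= 0")
  if (any(df$start >= df$end)) stop("region start must be < end")
  if (anyDuplicated(df$id)) stop("region ids must be unique")
  if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be '+', '-' or '.'")
  invisible(df)
}

#' Read a BED3/BED6 file into a region table
#'
#' Coordinates are kept in BED's native 0-based half-open convention.
#' Optional name, score and strand columns are used when present; rows
#' retain file order.
#'
#' @param path path to a tab-separated BED file.
#' @param kind feature kind to assign to all intervals.
#' @return an `epistate_regions` data.frame.
#' @export
read_bed <- function(path, kind = "other") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(regions(character(0), numeric(0), numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("BED parse error at line ", which(nf < 3)[1], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad)) stop("BED parse error at line ", bad[1], ": non-integer coordinate")
  bad <- which(start >= end | start < 0)
  if (length(bad)) stop("BED parse error at line ", bad[1], ": start >= end")
  id <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
  if (anyNA(id) || anyDuplicated(id)) id <- sprintf("region_%d", seq_along(chrom))
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6L, length(f))], ""), ".")
  strand[!strand %in% c("+", "-")] <- "."
  regions(chrom, start, end, strand = strand, id = id, kind = kind)
}

#' Write a region table as BED6
#'
#' Round-trips with [read_bed()]: coordinates, ids and strands are
#' preserved exactly; unstranded regions are written as `"."`.
#'
#' @param x region table.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   x$chrom, as.integer(x$start), as.integer(x$end), x$id, x$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#' @param path TSV with columns chrom, length.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$length), df$chrom)
}

#' Read a gene annotation table
#'
#' A deliberate simplification of GTF: TSV with columns gene_id, chrom,
#' start, end, strand, cpg_class (and optionally gene_name). Coordinates
#' 0-based half-open. The TSS is derived from the strand.
#'
#' @param path path to the TSV (with header).
#' @return data.frame of gene models with a `tss` column.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  needed <- c("gene_id", "chrom", "start", "end", "strand", "cpg_class")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("gene table missing columns: ", paste(missing, collapse = ", "))
  if (!all(df$cpg_class %in% c("HCP", "ICP", "LCP")))
    stop("cpg_class must be HCP, ICP or LCP")
  df$tss <- ifelse(df$strand == "-", df$end - 1, df$start)
  df
}

#' Tile chromosomes with fixed-length overlapping windows
#'
#' Tiles start at 0, `offset`, 2*`offset`, ... . A tile is emitted if it
#' fits entirely within the chromosome; when the full tiles do not reach
#' the chromosome end, one final truncated tile reaching the end is kept
#' so coverage sums are conserved.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param tile_len tile length in bp (default 1000).
#' @param offset start-to-start offset in bp (default 500).
#' @return region table of kind `"tile"`.
#' @export
make_tiles <- function(chrom_sizes, tile_len = 1000, offset = 500) {
  stopifnot(tile_len > 0, offset > 0, offset <= tile_len)
  out <- lapply(names(chrom_sizes), function(chr) {
    len <- chrom_sizes[[chr]]
    starts <- seq(0, max(0, len - 1), by = offset)
    full <- starts[starts + tile_len <= len]
    ends <- full + tile_len
    if (length(full) == 0 || max(ends) < len) {
      trunc_start <- starts[starts + tile_len > len][1]
      full <- c(full, trunc_start)
      ends <- c(ends, len)
    }
    data.frame(chrom = chr, start = full, end = ends, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  regions(df$chrom, df$start, df$end,
          id = sprintf("tile_%s_%d", df$chrom, as.integer(df$start)),
          kind = "tile")
}

#' Strand-aware promoter windows around gene TSSs
#'
#' On the + strand the window is [tss - upstream, tss + downstream); on
#' the - strand it is mirrored. Windows are clipped to chromosome bounds.
#' The defaults (-2000/+500) follow common convention and are exposed
#' because annotation-specific choices vary.
#'
#' @param genes gene table (as from [read_gene_table()] or
#'   [simulate_genome()]): needs chrom, tss, strand, gene_id.
#' @param chrom_sizes named chromosome lengths for clipping.
#' @param upstream,downstream window extents in bp.
#' @return region table of kind `"promoter"` with ids `<gene_id>_prom`.
#' @export
promoters_of <- function(genes, chrom_sizes, upstream = 2000, downstream = 500) {
  plus <- genes$strand != "-"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  start <- pmax(start, 0)
  lens <- chrom_sizes[genes$chrom]
  end <- pmin(end, lens)
  regions(genes$chrom, start, end, strand = genes$strand,
          id = paste0(genes$gene_id, "_prom"), kind = "promoter")
}

#' All overlapping pairs between two region sets
#'
#' Half-open overlap on the same chromosome: `a.start < b.end` and
#' `b.start < a.end`. Backed by IRanges interval trees.
#'
#' @param a,b region tables.
#' @return data.frame with columns `a_idx`, `b_idx`, `a_id`, `b_id`.
#' @export
intersect_regions <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(data.frame(a_idx = integer(0), b_idx = integer(0),
                      a_id = character(0), b_id = character(0)))
  }
  hits <- lapply(intersect(unique(a$chrom), unique(b$chrom)), function(chr) {
    ia <- which(a$chrom == chr)
    ib <- which(b$chrom == chr)
    ra <- IRanges::IRanges(start = a$start[ia] + 1, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1, end = b$end[ib])
    ov <- IRanges::findOverlaps(ra, rb)
    data.frame(a_idx = ia[S4Vectors::queryHits(ov)],
               b_idx = ib[S4Vectors::subjectHits(ov)])
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) out <- data.frame(a_idx = integer(0), b_idx = integer(0))
  out <- out[order(out$a_idx, out$b_idx), , drop = FALSE]
  out$a_id <- a$id[out$a_idx]
  out$b_id <- b$id[out$b_idx]
  rownames(out) <- NULL
  out
}

#' Nearest gene for each query region
#'
#' Distance is the gap in bp between closest edges (0 when overlapping or
#' directly adjacent). Equidistant ties resolve to the lexicographically
#' smaller `gene_id`. Genes on other chromosomes are never matched.
#'
#' @param x query region table.
#' @param genes gene table with chrom, start, end, gene_id.
#' @return data.frame with columns `id`, `gene_id`, `distance` (NA when a
#'   query chromosome carries no gene).
#' @export
nearest_gene <- function(x, genes) {
  gene_id <- character(nrow(x))
  distance <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    g <- genes[genes$chrom == x$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) { gene_id[i] <- NA_character_; next }
    d <- pmax(0, pmax(g$start - x$end[i], x$start[i] - g$end))
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[order(g$gene_id[best])][1]
    gene_id[i] <- g$gene_id[best]
    distance[i] <- d[best]
  }
  data.frame(id = x$id, gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

#' Classify promoters by CpG density (Weber-style thresholds)
#'
#' When promoter sequences are available, CpG observed/expected and GC
#' content are computed over a sliding 500 bp window and the promoter is
#' classified HCP if any window has CpG o/e > 0.75 and GC > 0.55, LCP if
#' no window reaches CpG o/e 0.48, else ICP. This is one published
#' interpretation of the three-class scheme; class labels can also simply
#' be supplied as annotation input.
#'
#' @param seqs character vector (or `Biostrings::DNAStringSet`) of
#'   promoter sequences.
#' @param window window size in bp.
#' @return character vector of classes in {HCP, ICP, LCP}.
#' @export
classify_cpg <- function(seqs, window = 500) {
  seqs <- as.character(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 50) return("LCP")
    starts <- seq(1, max(1, n - window + 1), by = 100)
    best_oe <- 0; best_gc <- 0; any_hcp <- FALSE
    for (st in starts) {
      sub <- substr(s, st, min(n, st + window - 1))
      w <- nchar(sub)
      nC <- lengths(regmatches(sub, gregexpr("C", sub, fixed = TRUE)))
      nG <- lengths(regmatches(sub, gregexpr("G", sub, fixed = TRUE)))
      nCG <- lengths(regmatches(sub, gregexpr("CG", sub, fixed = TRUE)))
      gc <- (nC + nG) / w
      oe <- if (nC * nG > 0) nCG * w / (nC * nG) else 0
      best_oe <- max(best_oe, oe); best_gc <- max(best_gc, gc)
      if (oe > 0.75 && gc > 0.55) any_hcp <- TRUE
    }
    if (any_hcp) "HCP" else if (best_oe < 0.48) "LCP" else "ICP"
  }, "", USE.NAMES = FALSE)
}
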
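#' Chi-square test of independence for a 2x2 overlap table
#'
#' Used for mark-by-mark anticorrelation and mark-by-upregulation overlap
#' tests. The statistic is the closed form
#' N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) with df = 1; Yates continuity
#' correction is off by default.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param yates apply the continuity correction.
#' @return list with `chisq`, `df`, `p`.
#' @export
chi2_overlap <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("chi2_overlap: zero margin in contingency table")
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  chisq <- n * num^2 / prod(margins)
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Wilcoxon rank-sum test with continuity correction and effect size
#'
#' Two-sided unpaired test. The exact null distribution is used when both
#' groups have at most `exact_max` observations and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction. The effect size is r = |Z| / sqrt(n_x + n_y), with Z always
#' taken from the (tie- and continuity-corrected) normal approximation.
#' Star categories follow fixed effect-size thresholds
#' (* r <= 0.10, ** 0.10 < r <= 0.15, *** r > 0.15) and are reported only
#' when p < 0.05, else "ns".
#'
#' @param x,y numeric samples.
#' @param continuity apply the 0.5 continuity correction to Z.
#' @param exact_max maximum per-group size for the exact test.
#' @return list with `U`, `Z`, `p`, `r`, `stars`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, continuity = TRUE, exact_max = 10) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx == 0 || ny == 0) stop("wilcoxon_rank_sum: empty group")
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(rk)
  has_ties <- any(ties > 1)
  mu <- nx * ny / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
  diff <- U - mu
  cc <- if (continuity) sign(diff) * 0.5 else 0
  Z <- if (sigma > 0) (diff - cc) / sigma else 0
  if (nx <= exact_max && ny <= exact_max && !has_ties) {
    p <- stats::wilcox.test(x, y, exact = TRUE, correct = continuity)$p.value
    method <- "exact"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(Z)))
    method <- "normal"
  }
  r <- abs(Z) / sqrt(n)
  stars <- if (p >= 0.05) "ns" else if (r <= 0.10) "*" else if (r <= 0.15) "**" else "***"
  list(U = U, Z = Z, p = p, r = r, stars = stars, method = method)
}

#' Fisher's exact test for a 2x2 table
#'
#' Thin wrapper over [stats::fisher.test()] returning the p-value;
#' two-sided p is by minimum-likelihood summation over the hypergeometric
#' null, one-sided p is the corresponding tail.
#'
#' @param tab 2x2 count matrix.
#' @param alternative "two.sided", "greater" or "less" (rows: in-group /
#'   out-group; columns: success / failure).
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(tab, alternative = "two.sided") {
  stats::fisher.test(as.matrix(tab), alternative = alternative)$p.value
}

#' Compare methylation levels between two groups of CpGs or regions
#'
#' Global levels are coverage-weighted means over CpGs; the group contrast
#' uses the rank-sum test of [wilcoxon_rank_sum()].
#'
#' @param a,b numeric methylation fractions per CpG (or per region).
#' @param weights_a,weights_b optional coverage weights.
#' @return list with `mean_a`, `mean_b`, `delta` and the rank-test result
#'   under `test`.
#' @export
methylation_compare <- function(a, b, weights_a = NULL, weights_b = NULL) {
  if (length(a) == 0 || length(b) == 0) stop("methylation_compare: empty group")
  wm <- function(v, w) if (is.null(w)) mean(v) else sum(v * w) / sum(w)
  mean_a <- wm(a, weights_a)
  mean_b <- wm(b, weights_b)
  list(mean_a = mean_a, mean_b = mean_b, delta = mean_b - mean_a,
       test = wilcoxon_rank_sum(a, b))
}

#' Benjamini-Hochberg adjusted p-values
#' @param p numeric p-values.
#' @return adjusted p-values (monotone step-up), via [stats::p.adjust()].
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
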
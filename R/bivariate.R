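# Correlation of a standard bivariate normal with correlation rho after
# truncation to the central box [-b, b]^2 (midpoint quadrature; the means
# vanish and the two marginal second moments agree by symmetry).
.band_corr <- function(rho, b, n_grid = 200) {
  h <- 2 * b / n_grid
  x <- -b + h * (seq_len(n_grid) - 0.5)
  q <- outer(x^2, x^2, "+") - 2 * rho * outer(x, x)
  f <- exp(-q / (2 * (1 - rho^2)))
  num <- sum(outer(x, x) * f)
  den <- sum(outer(x^2, rep(1, n_grid)) * f)
  num / den
}

# invert .band_corr: the box-truncated correlation back to rho
.invert_band_corr <- function(r, b) {
  lim <- .band_corr(0.9999, b)
  if (!is.finite(r) || abs(r) >= lim) {
    stop("degenerate Z correlation |s| >= 1; the two inputs are identical ",
         "or constant")
  }
  if (r == 0) return(0)
  stats::uniroot(function(rho) .band_corr(rho, b) - r,
                 interval = sort(c(0, sign(r) * 0.9999)),
                 tol = 1e-8)$root
}

#' Estimate the null correlation between two traits' Z statistics
#'
#' Under the null, the per-SNP Z-scores of two traits analysed on overlapping
#' samples are correlated; this correlation enters both combined tests.  The
#' product-moment correlation of (z1, z2) is taken over SNPs in the null
#' band `|z1| <= null_band & |z2| <= null_band`, which is robust to
#' contamination by true polygenic signal, and is then de-attenuated by
#' inverting the correlation shrinkage that conditioning on the central box
#' induces on a bivariate normal.  If fewer than 100 SNPs fall in the band,
#' all SNPs are used directly with a warning.
#'
#' @param pairs A `harmonized_pairs` object.
#' @param null_band Absolute Z cutoff defining the null band (default 2).
#' @return A `z_correlation` list: s, n_snps_used, estimation_method.
#' @export
estimate_z_correlation <- function(pairs, null_band = 2.0) {
  in_band <- abs(pairs$z1) <= null_band & abs(pairs$z2) <= null_band
  if (sum(in_band) >= 100) {
    r <- stats::cor(pairs$z1[in_band], pairs$z2[in_band])
    if (is.na(r)) stop("degenerate Z correlation |s| >= 1; the two inputs ",
                       "are identical or constant")
    s <- .invert_band_corr(r, null_band)
    n_used <- sum(in_band)
    method <- sprintf("null-band |z| <= %g, truncation-adjusted", null_band)
  } else {
    warning("fewer than 100 SNPs in the null band; using all SNPs")
    s <- stats::cor(pairs$z1, pairs$z2)
    n_used <- nrow(pairs)
    method <- "all SNPs (null-band fallback)"
  }
  if (!is.finite(s) || abs(s) >= 1) {
    stop("degenerate Z correlation |s| >= 1; the two inputs are identical ",
         "or constant")
  }
  structure(list(s = s, n_snps_used = n_used, estimation_method = method),
            class = "z_correlation")
}

.s_value <- function(s) if (inherits(s, "z_correlation")) s$s else s

#' O'Brien combined test of two dependent Z statistics
#'
#' With the 2x2 null correlation matrix `S = [[1, s], [s, 1]]`, the O'Brien
#' statistic is the inverse-variance optimal linear combination
#' `t = (1' S^-1 z) / sqrt(1' S^-1 1)`, standard normal under the joint null.
#' Vectorized over SNPs.
#'
#' @param z1,z2 Z-scores for the two traits (same effect allele).
#' @param s Null Z correlation: a `z_correlation` object or a number in
#'   (-1, 1).
#' @return List with `t` (statistic) and `p` (two-sided p-value).
#' @export
obrien_stat <- function(z1, z2, s) {
  s <- .s_value(s)
  if (!is.finite(s) || abs(s) >= 1) stop("|s| must be < 1")
  # 1' S^-1 z = (z1 + z2) / (1 + s);  1' S^-1 1 = 2 / (1 + s)
  t <- (z1 + z2) / (1 + s) / sqrt(2 / (1 + s))
  list(t = t, p = 2 * stats::pnorm(-abs(t)))
}

#' Direct linear combination (dLC) of two dependent Z statistics
#'
#' Combines the Z-scores with externally chosen nonnegative weights,
#' standardized by the combination's null variance:
#' `t = (w1 z1 + w2 z2) / sqrt(w1^2 + w2^2 + 2 s w1 w2)`.  The default
#' weights in the genome-wide scan are `sqrt(N)` per trait.  Vectorized.
#'
#' @param z1,z2 Z-scores.
#' @param s Null Z correlation (`z_correlation` object or number).
#' @param w1,w2 Nonnegative weights, not both zero.
#' @return List with `t` and two-sided `p`.
#' @export
dlc_stat <- function(z1, z2, s, w1, w2) {
  s <- .s_value(s)
  if (!is.finite(s) || abs(s) >= 1) stop("|s| must be < 1")
  if (any(w1 < 0) || any(w2 < 0) || any(w1 + w2 <= 0)) {
    stop("weights must be nonnegative with w1 + w2 > 0")
  }
  denom <- sqrt(w1^2 + w2^2 + 2 * s * w1 * w2)
  if (any(denom <= 0)) stop("zero combination variance")
  t <- (w1 * z1 + w2 * z2) / denom
  list(t = t, p = 2 * stats::pnorm(-abs(t)))
}

#' Per-SNP bivariate association scan
#'
#' Computes the O'Brien and dLC statistics for every harmonized SNP and the
#' min-p bivariate p-value `p_biv = min(p_ob, p_dlc)`.  No multiplicity
#' correction is applied to the minimum; its inflation is quantified by the
#' evaluation experiments instead.
#'
#' @param pairs A `harmonized_pairs` object.
#' @param s Null Z correlation (`z_correlation` object or number).
#' @param w1,w2 dLC weights; default `sqrt(n1)`, `sqrt(n2)` per SNP.
#' @return A `bivariate_results` data.frame: snp_id, chrom, pos, z1, z2,
#'   t_ob, p_ob, t_dlc, p_dlc, p_biv, p1, p2, same_direction, in genomic
#'   order of `pairs`.
#' @export
bivariate_scan <- function(pairs, s, w1 = sqrt(pairs$n1), w2 = sqrt(pairs$n2)) {
  ob <- obrien_stat(pairs$z1, pairs$z2, s)
  dlc <- dlc_stat(pairs$z1, pairs$z2, s, w1, w2)
  out <- data.frame(
    snp_id = pairs$snp_id, chrom = pairs$chrom, pos = pairs$pos,
    z1 = pairs$z1, z2 = pairs$z2,
    t_ob = ob$t, p_ob = ob$p, t_dlc = dlc$t, p_dlc = dlc$p,
    p_biv = pmin(ob$p, dlc$p),
    p1 = pairs$p1, p2 = pairs$p2,
    same_direction = sign(pairs$z1) == sign(pairs$z2) & pairs$z1 != 0,
    stringsAsFactors = FALSE
  )
  structure(out, s = .s_value(s),
            class = c("bivariate_results", "data.frame"))
}
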
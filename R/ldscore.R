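#' Compute LD scores from a reference genotype panel
#'
#' For each variant j the LD score is the sum of squared correlations with
#' every variant within `window_bp` of it (same chromosome), with the
#' finite-sample adjustment `r2_adj = r2 - (1 - r2)/(n - 2)` applied to the
#' cross terms.  The self term is counted as exactly 1, so `l >= 1` up to the
#' (negative) adjustment of the cross terms.
#'
#' @param geno Numeric matrix, variants in rows, samples in columns (allele
#'   dosages; continuous dosages are fine).
#' @param chrom Chromosome label per variant (default: single chromosome).
#' @param pos Base-pair position per variant, sorted within chromosome.
#' @param window_bp Half-window in base pairs (default 1e6, i.e. +/- 1 Mb).
#' @param maf_min Variants with minor-allele frequency below this (computed
#'   from dosages on a 0..2 scale) are excluded; monomorphic variants are
#'   always excluded with a warning.
#' @return An `ld_scores` data.frame with columns snp_id, l.
#' @export
compute_ld_scores <- function(geno, pos, chrom = rep("1", nrow(geno)),
                              window_bp = 1e6, maf_min = 0.01) {
  stopifnot(is.matrix(geno), nrow(geno) == length(pos),
            length(chrom) == nrow(geno))
  n <- ncol(geno)
  if (n < 25) stop("need at least 25 reference samples")
  if (is.null(rownames(geno))) rownames(geno) <- paste0("snp", seq_len(nrow(geno)))
  sds <- apply(geno, 1, stats::sd)
  mono <- sds == 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic variant(s) excluded from LD scoring")
  }
  afs <- rowMeans(geno) / 2
  maf <- pmin(afs, 1 - afs)
  keep <- !mono & maf >= maf_min
  # continuous dosage panels (e.g. simulated standardized dosages) have no
  # meaningful allele frequency; skip the MAF filter for them
  if (any(geno < 0) || any(geno > 2)) keep <- !mono
  geno <- geno[keep, , drop = FALSE]
  pos <- pos[keep]; chrom <- chrom[keep]
  m <- nrow(geno)
  if (m == 0) stop("no variants left after filtering")
  x <- t(scale(t(geno)))  # standardize each variant across samples
  l <- numeric(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    o <- order(pos[idx]); idx <- idx[o]
    p <- pos[idx]
    lo <- 1L
    for (a in seq_along(idx)) {
      while (p[a] - p[lo] > window_bp) lo <- lo + 1L
      hi <- a
      while (hi < length(idx) && p[hi + 1L] - p[a] <= window_bp) hi <- hi + 1L
      win <- idx[lo:hi]
      r <- (x[win, , drop = FALSE] %*% x[idx[a], ]) / (n - 1)
      r2 <- as.numeric(r)^2
      r2_adj <- r2 - (1 - r2) / (n - 2)
      self <- which(win == idx[a])
      r2_adj[self] <- 1
      l[idx[a]] <- sum(r2_adj)
    }
  }
  structure(data.frame(snp_id = rownames(geno), l = l,
                       stringsAsFactors = FALSE),
            class = c("ld_scores", "data.frame"))
}

#' Read precomputed LD scores from a two-column TSV (snp_id, l)
#'
#' @param path Path to the TSV file.
#' @return An `ld_scores` data.frame.
#' @export
read_ld_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "l") %in% names(df)))
  structure(df[, c("snp_id", "l")], class = c("ld_scores", "data.frame"))
}

# Weighted least squares of y on x with free intercept, plus delete-one-block
# jackknife of the slope (and anything derived from per-block sums).
# Returns the sufficient per-block sums so callers can form ratio estimators.
.wls_block_sums <- function(x, y, w, block_id) {
  sums <- function(v) as.numeric(rowsum(v, block_id))
  list(sw = sums(w), swx = sums(w * x), swy = sums(w * y),
       swxx = sums(w * x * x), swxy = sums(w * x * y))
}

.slope_from_sums <- function(s) {
  sw <- sum(s$sw); swx <- sum(s$swx); swy <- sum(s$swy)
  swxx <- sum(s$swxx); swxy <- sum(s$swxy)
  den <- sw * swxx - swx^2
  if (den <= 0) return(c(slope = 0, intercept = swy / sw))
  slope <- (sw * swxy - swx * swy) / den
  c(slope = slope, intercept = (swy - slope * swx) / sw)
}

# slope (and intercept) with block i removed, vectorized over blocks
.loo_slopes <- function(s) {
  sw <- sum(s$sw) - s$sw; swx <- sum(s$swx) - s$swx
  swy <- sum(s$swy) - s$swy; swxx <- sum(s$swxx) - s$swxx
  swxy <- sum(s$swxy) - s$swxy
  den <- sw * swxx - swx^2
  ifelse(den > 0, (sw * swxy - swx * swy) / den, 0)
}

.loo_intercepts <- function(s) {
  sw <- sum(s$sw) - s$sw; swx <- sum(s$swx) - s$swx
  swy <- sum(s$swy) - s$swy
  (swy - .loo_slopes(s) * swx) / sw
}

.jackknife_blocks <- function(m, n_blocks = 200) {
  if (m < 200) n_blocks <- max(2L, m %/% 10L)
  if (m < n_blocks) stop("fewer SNPs than jackknife blocks")
  as.integer(cut(seq_len(m), breaks = n_blocks, labels = FALSE))
}

.jackknife_se <- function(theta_loo) {
  b <- length(theta_loo)
  sqrt((b - 1) / b * sum((theta_loo - mean(theta_loo))^2))
}

#' Estimate SNP heritability by LD score regression
#'
#' Regresses per-SNP chi-square statistics `z^2` on `N * l / M` by weighted
#' least squares (weights `1/max(l, 1)`) with a free intercept; the slope is
#' the SNP heritability and the intercept captures confounding.  The standard
#' error comes from a delete-one-block jackknife over contiguous blocks.
#'
#' @param z Per-SNP Z-scores.
#' @param n Per-SNP sample sizes.
#' @param ld LD scores: an `ld_scores` data.frame aligned by position, or a
#'   numeric vector of the same length as `z`.
#' @param M Genome-wide SNP count the heritability refers to (default:
#'   number of SNPs supplied).
#' @param n_blocks Jackknife blocks (default 200; reduced to `floor(m/10)`
#'   when fewer than 200 SNPs are supplied).
#' @return A `h2_fit` list: h2, se_h2, intercept, M, mean_chi2, n_snps,
#'   jackknife estimates.
#' @export
fit_h2 <- function(z, n, ld, M = length(z), n_blocks = 200) {
  l <- if (is.data.frame(ld)) ld$l else ld
  stopifnot(length(l) == length(z), length(n) == length(z))
  m <- length(z)
  if (m < 200) {
    if (m < 20) stop("need at least 20 SNPs")
  }
  block_id <- .jackknife_blocks(m, n_blocks)
  x <- n * l / M
  y <- z^2
  w <- 1 / pmax(l, 1)
  s <- .wls_block_sums(x, y, w, block_id)
  fit <- .slope_from_sums(s)
  loo <- .loo_slopes(s)
  structure(list(h2 = unname(fit["slope"]), se_h2 = .jackknife_se(loo),
                 intercept = unname(fit["intercept"]),
                 se_intercept = .jackknife_se(.loo_intercepts(s)), M = M,
                 mean_chi2 = mean(y), n_snps = m, jackknife = loo),
            class = "h2_fit")
}

#' @export
print.h2_fit <- function(x, ...) {
  cat(sprintf("LD score regression h2 fit\n  h2 = %.4f (SE %.4f)\n  intercept = %.4f\n  mean chi2 = %.4f over %d SNPs (M = %d)\n",
              x$h2, x$se_h2, x$intercept, x$mean_chi2, x$n_snps, x$M))
  invisible(x)
}

#' Estimate genetic covariance and genetic correlation between two traits
#'
#' Regresses the per-SNP cross product `z1 * z2` on `sqrt(n1*n2) * l / M` by
#' weighted least squares with a free intercept; the slope is the genetic
#' covariance and the intercept absorbs the sample-overlap term
#' `pheno_corr * Ns / sqrt(N1*N2)`.  The genetic correlation is
#' `rg = gcov / sqrt(h2_1 * h2_2)`; its SE and two-sided p-value come from a
#' delete-one-block jackknife in which the two heritabilities and the
#' covariance are re-estimated jointly for every left-out block.
#'
#' @param pairs A `harmonized_pairs` object (columns z1, z2, n1, n2).
#' @param ld LD scores aligned to `pairs` (data.frame with column `l`, or a
#'   numeric vector).
#' @param M Genome-wide SNP count (default: attribute of `pairs`, else rows).
#' @param n_blocks Jackknife blocks (default 200).
#' @return An `rg_fit` list: gcov, rg, se_rg, p_rg, cross_intercept, h2_1,
#'   h2_2 (the underlying univariate fits), ok flag.
#' @export
fit_rg <- function(pairs, ld, M = NULL, n_blocks = 200) {
  l <- if (is.data.frame(ld)) ld$l else ld
  m <- nrow(pairs)
  stopifnot(length(l) == m)
  if (is.null(M)) M <- attr(pairs, "m_total") %||% m
  block_id <- .jackknife_blocks(m, n_blocks)
  w <- 1 / pmax(l, 1)
  s1  <- .wls_block_sums(pairs$n1 * l / M, pairs$z1^2, w, block_id)
  s2  <- .wls_block_sums(pairs$n2 * l / M, pairs$z2^2, w, block_id)
  s12 <- .wls_block_sums(sqrt(pairs$n1 * pairs$n2) * l / M,
                         pairs$z1 * pairs$z2, w, block_id)
  f1 <- .slope_from_sums(s1); f2 <- .slope_from_sums(s2)
  f12 <- .slope_from_sums(s12)
  h2_1 <- unname(f1["slope"]); h2_2 <- unname(f2["slope"])
  gcov <- unname(f12["slope"])
  ok <- h2_1 > 0 && h2_2 > 0
  rg <- if (ok) gcov / sqrt(h2_1 * h2_2) else NA_real_
  loo1 <- .loo_slopes(s1); loo2 <- .loo_slopes(s2); loo12 <- .loo_slopes(s12)
  valid <- loo1 > 0 & loo2 > 0
  rg_loo <- ifelse(valid, loo12 / sqrt(pmax(loo1, 1e-12) * pmax(loo2, 1e-12)),
                   NA_real_)
  se_rg <- if (ok && all(valid)) .jackknife_se(rg_loo) else {
    if (ok) .jackknife_se(rg_loo[valid]) else NA_real_
  }
  p_rg <- if (ok && is.finite(se_rg) && se_rg > 0) {
    2 * stats::pnorm(-abs(rg / se_rg))
  } else NA_real_
  structure(list(gcov = gcov, rg = rg, se_rg = se_rg, p_rg = p_rg,
                 cross_intercept = unname(f12["intercept"]),
                 se_cross_intercept = .jackknife_se(.loo_intercepts(s12)),
                 h2_1 = h2_1, h2_2 = h2_2, se_gcov = .jackknife_se(loo12),
                 intercept_1 = unname(f1["intercept"]),
                 intercept_2 = unname(f2["intercept"]),
                 M = M, n_snps = m, ok = ok, jackknife_rg = rg_loo),
            class = "rg_fit")
}

#' @export
print.rg_fit <- function(x, ...) {
  cat(sprintf("Bivariate LD score regression fit\n  gcov = %.4f\n  rg = %.4f (SE %.4f, p = %.3g)\n  cross intercept = %.4f\n  h2: %.4f / %.4f over %d SNPs (M = %d)\n",
              x$gcov, x$rg, x$se_rg, x$p_rg, x$cross_intercept,
              x$h2_1, x$h2_2, x$n_snps, x$M))
  if (!x$ok) cat("  WARNING: a heritability estimate was <= 0; rg undefined\n")
  invisible(x)
}

#' Serialize a fit as a flat key=value report
#'
#' @param fit An `h2_fit` or `rg_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  keep <- vapply(fit, function(v) is.numeric(v) && length(v) == 1, logical(1))
  vals <- unlist(fit[keep])
  writeLines(sprintf("%s=%.10g", names(vals), vals), path)
  invisible(path)
}
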
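#' Configuration for the two-trait summary-statistics simulator
#'
#' The simulator works directly on the Z-score scale — exactly the
#' sufficiency level the downstream analysis consumes.  SNPs come in
#' `n_blocks` LD blocks of `block_size` with within-block AR(1) correlation
#' `R_ij = ar_rho^|i-j|` and no between-block LD; per-SNP true effects are
#' drawn from the infinitesimal model with per-trait heritabilities `h2_1`,
#' `h2_2` and genetic correlation `rg_true`; `Ns` overlapping samples with
#' phenotypic correlation `pheno_corr` induce the cross-trait noise
#' correlation `pheno_corr * Ns / sqrt(N1*N2)`.
#'
#' @param M Total SNP count (must equal `n_blocks * block_size`).
#' @param n_blocks,block_size LD-block structure (defaults 500 x 100).
#' @param ar_rho Within-block AR(1) correlation in \[0, 1) (default 0.8).
#' @param h2_1,h2_2 SNP heritabilities in \[0, 1) (default 0.3 each).
#' @param rg_true Genetic correlation in \[-1, 1\] (default 0.5).
#' @param N1,N2 GWAS sample sizes (default 20000 each).
#' @param Ns Overlapping samples, at most `min(N1, N2)` (default 0).
#' @param pheno_corr Phenotypic correlation in the overlap (default 0).
#' @param maf_range Range effect-allele frequencies are drawn from and
#'   symmetrized over (default c(0.05, 0.5)).
#' @param seed Integer seed; the output is bit-reproducible given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(M = 50000, n_blocks = 500, block_size = 100,
                       ar_rho = 0.8, h2_1 = 0.3, h2_2 = 0.3, rg_true = 0.5,
                       N1 = 20000, N2 = 20000, Ns = 0, pheno_corr = 0,
                       maf_range = c(0.05, 0.5), seed = 42) {
  stopifnot(M == n_blocks * block_size,
            ar_rho >= 0, ar_rho < 1,
            h2_1 >= 0, h2_1 < 1, h2_2 >= 0, h2_2 < 1,
            abs(rg_true) <= 1,
            N1 > 0, N2 > 0, Ns >= 0, Ns <= min(N1, N2),
            abs(pheno_corr) <= 1)
  structure(list(M = M, n_blocks = n_blocks, block_size = block_size,
                 ar_rho = ar_rho, h2_1 = h2_1, h2_2 = h2_2,
                 rg_true = rg_true, N1 = N1, N2 = N2, Ns = Ns,
                 pheno_corr = pheno_corr, maf_range = maf_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Build the LD-block structure for a simulation configuration
#'
#' All blocks share the AR(1) correlation matrix `R_ij = ar_rho^|i-j|`
#' (positive definite for any `ar_rho` in \[0, 1)).  SNPs are spaced 1 kb
#' apart within a block (block span well inside a +/- 1 Mb window) and
#' successive blocks on a chromosome are 3 Mb apart, so no window spans two
#' blocks; blocks cycle over chromosomes 1..22.
#'
#' @param cfg A [sim_config()].
#' @return List: `R` (block correlation matrix), `chol_R` (its upper
#'   Cholesky factor), `l` (analytic per-SNP LD scores, length M), `chrom`,
#'   `pos`, `block` (block index per SNP), `snp_id`.
#' @export
build_ld_blocks <- function(cfg) {
  k <- cfg$block_size
  idx <- abs(outer(seq_len(k), seq_len(k), "-"))
  R <- cfg$ar_rho^idx
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("block correlation matrix is not positive definite")
  l_block <- rowSums(R^2)
  block <- rep(seq_len(cfg$n_blocks), each = k)
  chrom_of_block <- as.character(((seq_len(cfg$n_blocks) - 1) %% 22) + 1)
  block_rank <- ((seq_len(cfg$n_blocks) - 1) %/% 22)  # per-chromosome index
  pos <- block_rank[block] * 3e6 + (rep(seq_len(k), cfg$n_blocks) - 1) * 1000 + 1
  list(R = R, chol_R = chol(R), l = rep(l_block, cfg$n_blocks),
       chrom = chrom_of_block[block], pos = as.integer(pos), block = block,
       snp_id = sprintf("snp%06d", seq_len(cfg$M)))
}

#' Draw per-SNP true effects under the infinitesimal model
#'
#' Effect pairs (beta1, beta2) are bivariate normal on the
#' standardized-genotype scale with variances `h2_t / M` and covariance
#' `rg_true * sqrt(h2_1 * h2_2) / M`.
#'
#' @param cfg A [sim_config()].
#' @return List: `beta1`, `beta2` (length M), `realized_rg` (sample
#'   correlation of the drawn pairs; NA when either heritability is 0).
#' @export
draw_effects <- function(cfg) {
  s1 <- sqrt(cfg$h2_1 / cfg$M)
  s2 <- sqrt(cfg$h2_2 / cfg$M)
  u1 <- stats::rnorm(cfg$M)
  u2 <- stats::rnorm(cfg$M)
  beta1 <- s1 * u1
  beta2 <- s2 * (cfg$rg_true * u1 + sqrt(1 - cfg$rg_true^2) * u2)
  realized <- if (s1 > 0 && s2 > 0) stats::cor(beta1, beta2) else NA_real_
  list(beta1 = beta1, beta2 = beta2, realized_rg = realized)
}

.alleles_for <- function(m) {
  # effect allele always the alphabetically earlier base of the pair
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  pick <- sample.int(4, m, replace = TRUE)
  list(a1 = pairs[pick, 1], a2 = pairs[pick, 2])
}

#' Simulate a pair of two-trait GWAS summary-statistics tables
#'
#' Per block with correlation matrix R and true effect vector b_t for trait
#' t, the Z-score vector is `sqrt(N_t) * R b_t + eps_t` with
#' `Var(eps_t) = R` and cross-trait noise covariance
#' `Cov(eps_1, eps_2) = c R`, `c = pheno_corr * Ns / sqrt(N1 N2)`.
#' Two-sided p-values follow from the Z-scores; alleles are assigned
#' consistently between the two tables (no strand or swap noise) and
#' effect-allele frequencies are drawn uniform over `maf_range` and
#' symmetrized around 0.5.
#'
#' @param cfg A [sim_config()].
#' @return List: `t1`, `t2` ([sumstats_table()] objects) and `truth`
#'   (effects, analytic LD scores, block structure, the noise correlation
#'   `c`, and the config).
#' @export
simulate_sumstats <- function(cfg) {
  set.seed(cfg$seed)
  blocks <- build_ld_blocks(cfg)
  eff <- draw_effects(cfg)
  k <- cfg$block_size
  nb <- cfg$n_blocks
  B1 <- matrix(eff$beta1, nrow = k)
  B2 <- matrix(eff$beta2, nrow = k)
  mean1 <- sqrt(cfg$N1) * (blocks$R %*% B1)
  mean2 <- sqrt(cfg$N2) * (blocks$R %*% B2)
  cc <- cfg$pheno_corr * cfg$Ns / sqrt(cfg$N1 * cfg$N2)
  G1 <- matrix(stats::rnorm(k * nb), nrow = k)
  G2 <- matrix(stats::rnorm(k * nb), nrow = k)
  L <- t(blocks$chol_R)  # lower factor: L %*% t(L) = R
  eps1 <- L %*% G1
  eps2 <- L %*% (cc * G1 + sqrt(1 - cc^2) * G2)
  z1 <- as.numeric(mean1 + eps1)
  z2 <- as.numeric(mean2 + eps2)
  al <- .alleles_for(cfg$M)
  eaf <- stats::runif(cfg$M, cfg$maf_range[1], cfg$maf_range[2])
  flip <- stats::runif(cfg$M) < 0.5
  eaf <- ifelse(flip, 1 - eaf, eaf)
  base <- data.frame(snp_id = blocks$snp_id, chrom = blocks$chrom,
                     pos = blocks$pos, a1 = al$a1, a2 = al$a2, eaf = eaf,
                     stringsAsFactors = FALSE)
  t1 <- base; t1$z <- z1; t1$n <- cfg$N1; t1$p <- 2 * stats::pnorm(-abs(z1))
  t2 <- base; t2$z <- z2; t2$n <- cfg$N2; t2$p <- 2 * stats::pnorm(-abs(z2))
  list(t1 = sumstats_table(t1, trait = "trait1", m_total = cfg$M),
       t2 = sumstats_table(t2, trait = "trait2", m_total = cfg$M),
       truth = list(beta1 = eff$beta1, beta2 = eff$beta2,
                    realized_rg = eff$realized_rg,
                    ld = blocks$l, block = blocks$block, R = blocks$R,
                    snp_id = blocks$snp_id, chrom = blocks$chrom,
                    pos = blocks$pos, noise_corr = cc, config = cfg))
}

#' Simulate a null pair of traits (no shared genetics, no overlap)
#'
#' Thin wrapper over [simulate_sumstats()] forcing `rg_true = 0` and
#' `Ns = 0`; per-trait polygenicity is kept as configured.  Stands in for a
#' negative-control phenotype pairing.
#'
#' @param cfg A [sim_config()]; its rg_true/Ns/pheno_corr are overridden.
#' @return As [simulate_sumstats()].
#' @export
simulate_null_pair <- function(cfg) {
  cfg$rg_true <- 0
  cfg$Ns <- 0
  cfg$pheno_corr <- 0
  simulate_sumstats(cfg)
}

#' Simulate reference-panel dosages matching a configuration's LD blocks
#'
#' Draws multivariate-normal dosages with the block correlation structure,
#' for feeding [compute_ld_scores()]; not a genotype caller, just a
#' correlation-faithful panel.
#'
#' @param cfg A [sim_config()].
#' @param n_samples Number of reference samples.
#' @param blocks Optional precomputed [build_ld_blocks()] result.
#' @return List: `geno` (variants x samples matrix with snp_id rownames),
#'   `chrom`, `pos`.
#' @export
simulate_genotypes <- function(cfg, n_samples = 500, blocks = build_ld_blocks(cfg)) {
  k <- cfg$block_size
  L <- t(blocks$chol_R)
  g <- lapply(seq_len(cfg$n_blocks), function(b) {
    L %*% matrix(stats::rnorm(k * n_samples), nrow = k)
  })
  geno <- do.call(rbind, g)
  rownames(geno) <- blocks$snp_id
  list(geno = geno, chrom = blocks$chrom, pos = blocks$pos)
}

#' Write a simulated pair to disk (two TSVs plus a truth sidecar JSON)
#'
#' @param sim Result of [simulate_sumstats()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_trait1.tsv"))
  p2 <- file.path(dir, paste0(prefix, "_trait2.tsv"))
  pj <- file.path(dir, paste0(prefix, "_truth.json"))
  write_sumstats(sim$t1, p1)
  write_sumstats(sim$t2, p2)
  cfg <- sim$truth$config
  jsonlite::write_json(
    list(config = cfg[setdiff(names(cfg), "maf_range")],
         maf_range = cfg$maf_range,
         realized_rg = sim$truth$realized_rg,
         noise_corr = sim$truth$noise_corr),
    pj, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, pj))
}
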
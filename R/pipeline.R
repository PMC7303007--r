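.derive_seed <- function(seed, i) as.integer((seed + 7919 * i) %% 2147483647L)

#' Build an LD lookup for simulated data from its block structure
#'
#' Analytic AR(1) r-squared (`ar_rho^(2|i-j|)`) for pairs of the requested
#' SNPs that share a block; cross-block pairs are 0 and omitted.
#'
#' @param truth `truth` element of [simulate_sumstats()].
#' @param snp_ids SNPs the lookup must cover (default: all, fine for small
#'   sets; quadratic in block occupancy).
#' @return An `ld_lookup` object.
#' @export
sim_ld_lookup <- function(truth, snp_ids = truth$snp_id) {
  idx <- match(snp_ids, truth$snp_id)
  stopifnot(!anyNA(idx))
  rho <- truth$config$ar_rho
  k <- truth$config$block_size
  blk <- truth$block[idx]
  within <- ((idx - 1) %% k) + 1
  pieces <- list()
  for (b in unique(blk)) {
    who <- which(blk == b)
    if (length(who) < 2) next
    cmb <- utils::combn(who, 2)
    pieces[[length(pieces) + 1]] <- data.frame(
      snp_a = snp_ids[cmb[1, ]], snp_b = snp_ids[cmb[2, ]],
      r2 = rho^(2 * abs(within[cmb[1, ]] - within[cmb[2, ]])),
      stringsAsFactors = FALSE)
  }
  if (!length(pieces)) return(ld_lookup())
  ld_lookup(do.call(rbind, pieces))
}

#' Run the full bivariate discovery (and optional replication) pipeline
#'
#' Executes harmonization, null Z-correlation estimation, the bivariate
#' O'Brien/dLC scan, the four-criterion discovery filter, greedy LD
#' clumping, and — when a replication table is supplied — the one-sided
#' replication test, dLC combination, the three-criterion replication rule
#' and the post-hoc BH-FDR.  Record counts of every stage are logged and
#' the run is deterministic given its inputs.
#'
#' @param t1,t2 `sumstats` objects for the two traits.
#' @param ld_pairs An `ld_lookup` of pairwise r-squared for clumping.
#' @param criteria [discovery_criteria()].
#' @param ld_scores Optional LD scores aligned to the harmonized pairs; when
#'   supplied, univariate and bivariate LD score regressions are also fitted.
#' @param replication Optional `sumstats` object of the replication cohort
#'   (same trait as `t1`).
#' @param analysis Label recorded on loci.
#' @param r2_thresh,window_bp Clumping parameters.
#' @return A `pipeline_result` list: `pairs`, `s`, `scan`, `discovery`
#'   (passing rows), `loci`, `replication` (per-locus records with q-values)
#'   or NULL, `rg_fit` or NULL, `counts`, `log`.
#' @export
run_pipeline <- function(t1, t2, ld_pairs, criteria = discovery_criteria(),
                         ld_scores = NULL, replication = NULL,
                         analysis = "bivariate", r2_thresh = 0.10,
                         window_bp = 1e6) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  pairs <- harmonize_pair(t1, t2)
  note("harmonized: %d SNPs", nrow(pairs))
  s <- estimate_z_correlation(pairs)
  note("null Z correlation s = %.4f (%s, %d SNPs)", s$s,
       s$estimation_method, s$n_snps_used)
  rg_fit <- NULL
  if (!is.null(ld_scores)) {
    rg_fit <- fit_rg(pairs, ld_scores)
    note("rg = %.4f (SE %.4f)", rg_fit$rg, rg_fit$se_rg)
  }
  scan <- bivariate_scan(pairs, s)
  note("scanned: %d SNPs", nrow(scan))
  filtered <- apply_discovery_filter(scan, criteria)
  discovery <- filtered[filtered$pass, , drop = FALSE]
  note("discovery-passing: %d SNPs", nrow(discovery))
  loci <- clump(discovery, ld_pairs, r2_thresh = r2_thresh,
                window_bp = window_bp, analysis = analysis)
  note("independent loci: %d", nrow(loci))

  rep_out <- NULL
  if (!is.null(replication) && nrow(loci) > 0) {
    rep_pairs <- harmonize_pair(t1, replication)
    idx <- match(loci$lead, rep_pairs$snp_id)
    disc_idx <- match(loci$lead, scan$snp_id)
    z_rep <- rep_pairs$z2[idx]
    n_rep <- rep_pairs$n2[idx]
    expected <- sign(scan$z1[disc_idx])
    tested <- !is.na(z_rep)
    p_one <- ifelse(tested, one_sided_p(ifelse(tested, z_rep, 0), expected), NA)
    comb <- combine_disc_rep(scan$t_dlc[disc_idx],
                             ifelse(tested, z_rep, 0),
                             rowSums(cbind(pairs$n1, pairs$n2))[disc_idx],
                             ifelse(tested, n_rep, 1))
    rec <- data.frame(
      snp_id = loci$lead,
      p_rep_one_sided = p_one,
      direction_consistent = tested &
        sign(z_rep) == sign(scan$z1[disc_idx]) &
        sign(scan$z1[disc_idx]) == sign(scan$z2[disc_idx]),
      p_combined = ifelse(tested, comb$p, NA),
      p_biv_discovery = scan$p_biv[disc_idx],
      stringsAsFactors = FALSE)
    rec$p_rep_one_sided[!tested] <- NA
    rec <- apply_replication_filter(rec)
    tested_idx <- !is.na(rec$p_rep_one_sided)
    rec$q_rep <- NA_real_
    if (any(tested_idx)) rec$q_rep[tested_idx] <- bh_fdr(rec$p_rep_one_sided[tested_idx])
    note("replicated loci: %d of %d tested", sum(rec$replicated),
         sum(tested_idx))
    rep_out <- rec
  }

  structure(list(pairs = pairs, s = s, scan = scan, discovery = discovery,
                 loci = loci, replication = rep_out, rg_fit = rg_fit,
                 counts = c(harmonized = nrow(pairs), scanned = nrow(scan),
                            passing = nrow(discovery), loci = nrow(loci)),
                 log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Bivariate GWAS pipeline run\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Empirical type-I error of the combined tests under the null
#'
#' Simulates a null pair (no shared genetics), runs the bivariate scan with
#' the Z correlation estimated from the data, and reports the fraction of
#' SNPs with `p_ob < alpha` per alpha together with the min-p rate and its
#' inflation factor over the per-test rate.
#'
#' @param cfg A [sim_config()] with `rg_true = 0` (enforced).
#' @param alphas Significance grid (default c(0.05, 0.01)).
#' @param n_reps Simulation replicates (default 1).
#' @return An `evaluation_report` list with per-alpha rates, binomial SEs
#'   and min-p inflation factors.
#' @export
type1_error_experiment <- function(cfg, alphas = c(0.05, 0.01), n_reps = 1) {
  hits_ob <- hits_min <- matrix(0, n_reps, length(alphas))
  m_tot <- 0
  for (i in seq_len(n_reps)) {
    cfg_i <- cfg; cfg_i$seed <- .derive_seed(cfg$seed, i)
    cfg_i$rg_true <- 0
    sim <- simulate_sumstats(cfg_i)
    pairs <- harmonize_pair(sim$t1, sim$t2)
    s <- estimate_z_correlation(pairs)
    scan <- bivariate_scan(pairs, s)
    for (a in seq_along(alphas)) {
      hits_ob[i, a] <- mean(scan$p_ob < alphas[a])
      hits_min[i, a] <- mean(scan$p_biv < alphas[a])
    }
    m_tot <- m_tot + nrow(scan)
  }
  rate_ob <- colMeans(hits_ob)
  rate_min <- colMeans(hits_min)
  structure(list(label = "type-I error under the null",
                 n_reps = n_reps, n_snps = m_tot, alphas = alphas,
                 rate_ob = rate_ob,
                 se_ob = sqrt(rate_ob * (1 - rate_ob) / m_tot),
                 rate_minp = rate_min,
                 inflation_minp = rate_min / alphas,
                 seed = cfg$seed),
            class = "evaluation_report")
}

#' Negative-control false-positive audit
#'
#' Simulates pairs of genetically uncorrelated traits (the stand-in for
#' pairing the index trait with negative-control phenotypes), runs the full
#' four-criterion discovery pipeline on each, and reports the mean count of
#' discovery-passing loci per replicate with its Monte-Carlo SE, alongside
#' the count under the genome-wide p threshold alone.
#'
#' @param cfg A [sim_config()]; rg_true/Ns are forced to 0.
#' @param n_reps Replicates (default 6, one per control phenotype).
#' @param criteria [discovery_criteria()].
#' @return An `evaluation_report` with `mean_loci`, `se_loci`,
#'   `mean_loci_pthresh_only`, per-replicate counts, and the last replicate's
#'   locus table.
#' @export
negative_control_experiment <- function(cfg, n_reps = 6,
                                        criteria = discovery_criteria()) {
  n_loci <- n_loci_p_only <- integer(n_reps)
  last_loci <- NULL
  for (i in seq_len(n_reps)) {
    cfg_i <- cfg; cfg_i$seed <- .derive_seed(cfg$seed, i)
    sim <- simulate_null_pair(cfg_i)
    pairs <- harmonize_pair(sim$t1, sim$t2)
    s <- estimate_z_correlation(pairs)
    scan <- apply_discovery_filter(bivariate_scan(pairs, s), criteria)
    pass <- scan[scan$pass, , drop = FALSE]
    gw_only <- scan[scan$p_biv < criteria$p_gw, , drop = FALSE]
    ld <- sim_ld_lookup(sim$truth, unique(c(pass$snp_id, gw_only$snp_id)))
    loci <- clump(pass, ld, analysis = sprintf("null_rep%d", i))
    n_loci[i] <- nrow(loci)
    n_loci_p_only[i] <- nrow(clump(gw_only, ld))
    last_loci <- loci
  }
  structure(list(label = "negative-control false-positive audit",
                 n_reps = n_reps,
                 mean_loci = mean(n_loci),
                 se_loci = stats::sd(n_loci) / sqrt(n_reps),
                 mean_loci_pthresh_only = mean(n_loci_p_only),
                 per_rep = n_loci, per_rep_pthresh_only = n_loci_p_only,
                 example_loci = last_loci, seed = cfg$seed),
            class = "evaluation_report")
}

#' Genetic-correlation recovery experiment
#'
#' For each value on the rg grid, simulates `n_reps` pairs, fits the
#' bivariate LD score regression with the analytic LD scores, and reports
#' bias, Monte-Carlo SE, RMSE and jackknife 95% CI coverage of the rg
#' estimate, plus bias of both heritability estimates.
#'
#' @param rg_grid True genetic correlations to scan.
#' @param n_reps Replicates per grid point.
#' @param cfg Base [sim_config()] (its rg_true is overridden per point).
#' @return An `evaluation_report` with a per-grid-point data.frame `grid`
#'   and pooled `coverage`.
#' @export
rg_recovery_experiment <- function(rg_grid = c(0, 0.25, 0.5, 0.8),
                                   n_reps = 25, cfg = sim_config()) {
  rows <- list(); covered <- logical(0)
  for (g in seq_along(rg_grid)) {
    rg_hat <- se_hat <- h1_hat <- h2_hat <- numeric(n_reps)
    for (i in seq_len(n_reps)) {
      cfg_i <- cfg
      cfg_i$rg_true <- rg_grid[g]
      cfg_i$seed <- .derive_seed(cfg$seed, (g - 1) * n_reps + i)
      sim <- simulate_sumstats(cfg_i)
      pairs <- harmonize_pair(sim$t1, sim$t2)
      fit <- fit_rg(pairs, sim$truth$ld, M = cfg$M)
      rg_hat[i] <- fit$rg; se_hat[i] <- fit$se_rg
      h1_hat[i] <- fit$h2_1; h2_hat[i] <- fit$h2_2
    }
    # replicates where a heritability fit went non-positive leave rg
    # undefined; they are excluded (and counted) rather than imputed
    valid <- is.finite(rg_hat) & is.finite(se_hat)
    cov_i <- abs(rg_hat[valid] - rg_grid[g]) <= 1.96 * se_hat[valid]
    covered <- c(covered, cov_i)
    n_valid <- sum(valid)
    rg_hat <- rg_hat[valid]; se_hat <- se_hat[valid]
    rows[[g]] <- data.frame(
      rg_true = rg_grid[g], n_reps = n_reps, n_valid = n_valid,
      rg_mean = mean(rg_hat), rg_bias = mean(rg_hat) - rg_grid[g],
      rg_mc_se = stats::sd(rg_hat) / sqrt(n_valid),
      rg_rmse = sqrt(mean((rg_hat - rg_grid[g])^2)),
      mean_jk_se = mean(se_hat), coverage = mean(cov_i),
      h2_1_bias = mean(h1_hat) - cfg$h2_1,
      h2_1_mc_se = stats::sd(h1_hat) / sqrt(n_reps),
      h2_2_bias = mean(h2_hat) - cfg$h2_2,
      h2_2_mc_se = stats::sd(h2_hat) / sqrt(n_reps))
  }
  structure(list(label = "rg recovery", n_reps_per_point = n_reps,
                 grid = do.call(rbind, rows), coverage = mean(covered),
                 n_cov = length(covered), seed = cfg$seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation report: %s\n", x$label))
  for (nm in setdiff(names(x), c("label", "grid", "example_loci",
                                 "per_rep", "per_rep_pthresh_only"))) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) <= 8) {
      cat(sprintf("  %s: %s\n", nm, paste(signif(v, 4), collapse = ", ")))
    }
  }
  if (!is.null(x$grid)) { cat("  grid:\n"); print(x$grid) }
  invisible(x)
}
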
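test_that("configuration is validated and block structure is well formed", {
  expect_error(sim_config(M = 100, n_blocks = 2, block_size = 100))
  expect_error(sim_config(Ns = 30000))  # overlap exceeds min(N1, N2)
  cfg <- sim_config(M = 400, n_blocks = 4, block_size = 100, ar_rho = 0.8)
  blocks <- build_ld_blocks(cfg)
  expect_equal(dim(blocks$R), c(100, 100))
  expect_equal(blocks$R[1, 2], 0.8)
  expect_true(all(eigen(blocks$R, only.values = TRUE)$values > 0))
  # rho = 0 gives the identity
  b0 <- build_ld_blocks(sim_config(M = 20, n_blocks = 2, block_size = 10,
                                   ar_rho = 0))
  expect_equal(b0$R, diag(10))
  expect_equal(b0$l, rep(1, 20))
  # block span stays inside a +/- 1 Mb window; blocks never straddle windows
  cfg2 <- sim_config(M = 4400, n_blocks = 44, block_size = 100)
  b2 <- build_ld_blocks(cfg2)
  spans <- tapply(b2$pos, b2$block, function(x) max(x) - min(x))
  expect_true(all(spans < 1e6))
  same_chr_blocks <- split(seq_len(44), b2$chrom[match(seq_len(44),
                                                       b2$block)])
  for (bb in same_chr_blocks) {
    if (length(bb) < 2) next
    gaps <- diff(sort(vapply(bb, function(b) min(b2$pos[b2$block == b]), 0)))
    expect_true(all(gaps > 2e6))
  }
})

test_that("true effects follow the specified bivariate distribution", {
  cfg <- sim_config(M = 10000, n_blocks = 100, block_size = 100,
                    h2_1 = 0, h2_2 = 0.3, rg_true = 0, seed = 40)
  set.seed(40)
  eff <- draw_effects(cfg)
  expect_true(all(eff$beta1 == 0))  # zero heritability: no effects

  cfg2 <- sim_config(M = 10000, n_blocks = 100, block_size = 100,
                     h2_1 = 0.3, h2_2 = 0.3, rg_true = 1, seed = 41)
  set.seed(41)
  eff2 <- draw_effects(cfg2)
  expect_equal(eff2$beta2, eff2$beta1)  # perfect correlation, equal h2

  cfg3 <- sim_config(M = 10000, n_blocks = 100, block_size = 100,
                     rg_true = 0.5, seed = 42)
  set.seed(42)
  eff3 <- draw_effects(cfg3)
  expect_lt(abs(eff3$realized_rg - 0.5), 3 / sqrt(cfg3$M))
  expect_lt(abs(var(eff3$beta1) * cfg3$M - 0.3), 3 * 0.3 * sqrt(2 / cfg3$M))
})

test_that("simulated Z-scores are bit-reproducible and calibrated", {
  cfg <- sim_config(M = 50000, h2_1 = 0, h2_2 = 0, rg_true = 0, seed = 43)
  sim_a <- simulate_sumstats(cfg)
  sim_b <- simulate_sumstats(cfg)
  expect_identical(sim_a$t1$z, sim_b$t1$z)
  expect_identical(sim_a$t2$p, sim_b$t2$p)
  # null calibration: mean chi-square within [0.98, 1.02] at M = 50,000,
  # averaged over replicates (block LD correlates the chi-squares, so a
  # single draw carries ~0.013 Monte-Carlo SD on the mean)
  mchi1 <- mchi2 <- numeric(5)
  for (i in 1:5) {
    cfg$seed <- 430 + i
    s <- simulate_sumstats(cfg)
    mchi1[i] <- mean(s$t1$z^2); mchi2[i] <- mean(s$t2$z^2)
  }
  expect_gt(mean(mchi1), 0.98); expect_lt(mean(mchi1), 1.02)
  expect_gt(mean(mchi2), 0.98); expect_lt(mean(mchi2), 1.02)
})

test_that("polygenic inflation matches the LD score expectation", {
  cfg <- sim_config(M = 10000, n_blocks = 100, block_size = 100,
                    h2_1 = 0.3, h2_2 = 0, rg_true = 0, N1 = 20000, seed = 44)
  reps <- 5
  mchi <- vapply(seq_len(reps), function(i) {
    cfg$seed <- 44 + i
    mean(simulate_sumstats(cfg)$t1$z^2)
  }, numeric(1))
  lbar <- mean(build_ld_blocks(cfg)$l)
  want <- 1 + cfg$N1 * cfg$h2_1 * lbar / cfg$M
  expect_lt(abs(mean(mchi) - want), 3 * sd(mchi) / sqrt(reps))
})

test_that("sample overlap induces the expected Z correlation", {
  cfg <- sim_config(M = 50000, h2_1 = 0, h2_2 = 0, rg_true = 0,
                    Ns = 20000, pheno_corr = 0.4, seed = 45)
  sim <- simulate_sumstats(cfg)
  pairs <- harmonize_pair(sim$t1, sim$t2)
  s <- estimate_z_correlation(pairs)
  # effective per-block correlation of AR noise inflates the SE; 3/sqrt(m)
  # of the independent case times sqrt(block size factor) is conservative
  expect_lt(abs(s$s - 0.4), 0.03)
})

test_that("the null pair wrapper forces zero cross-trait structure", {
  cfg <- sim_config(M = 20000, n_blocks = 200, block_size = 100,
                    rg_true = 0.7, Ns = 10000, pheno_corr = 0.5, seed = 46)
  sim <- simulate_null_pair(cfg)
  expect_equal(sim$truth$config$rg_true, 0)
  expect_equal(sim$truth$config$Ns, 0)
  f <- fit_rg(harmonize_pair(sim$t1, sim$t2), sim$truth$ld, M = cfg$M)
  expect_lt(abs(f$rg), 3 * f$se_rg)
})

test_that("per-block covariance of simulated Z converges to c * R", {
  cfg <- sim_config(M = 200, n_blocks = 2, block_size = 100,
                    h2_1 = 0, h2_2 = 0, rg_true = 0,
                    Ns = 20000, pheno_corr = 0.4, seed = 47)
  reps <- 4000
  z1 <- z2 <- matrix(0, reps, 100)
  for (r in seq_len(reps)) {
    cfg$seed <- 47 + r
    sim <- simulate_sumstats(cfg)
    z1[r, ] <- sim$t1$z[1:100]
    z2[r, ] <- sim$t2$z[1:100]
  }
  R <- build_ld_blocks(cfg)$R
  cross <- crossprod(z1, z2) / reps
  frob_rel <- norm(cross - 0.4 * R, "F") / norm(0.4 * R, "F")
  expect_lt(frob_rel, 0.25)
  own <- crossprod(z1, z1) / reps
  expect_lt(norm(own - R, "F") / norm(R, "F"), 0.25)
})

test_that("a simulated pair round-trips through disk and the readers", {
  cfg <- sim_config(M = 200, n_blocks = 2, block_size = 100, seed = 48)
  sim <- simulate_sumstats(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir, prefix = "toy")
  t1 <- read_sumstats(file.path(dir, "toy_trait1.tsv"), trait = "trait1")
  expect_identical(t1$z, sim$t1$z)
  truth <- jsonlite::read_json(file.path(dir, "toy_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$config$seed, 48)
})
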
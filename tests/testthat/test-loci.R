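test_that("discovery filter applies all four criteria and names failures", {
  rows <- data.frame(
    # printed values of two discovery-table rows, plus a boundary case
    p_biv = c(4.80e-12, 1.36e-8, 4e-8, 4e-8),
    p1 = c(1.89e-4, 3.18e-5, 3e-7, 3e-7),
    p2 = c(1.47e-9, 1.14e-5, 1e-4, 1e-4),
    same_direction = c(TRUE, TRUE, TRUE, FALSE))
  out <- apply_discovery_filter(rows)
  expect_equal(out$pass, c(TRUE, TRUE, FALSE, FALSE))
  # 4e-8 > 3e-8: fails only the order-of-magnitude criterion
  expect_equal(out$failed_criteria[3], "magnitude")
  expect_match(out$failed_criteria[4], "direction")
  # the boundary is non-strict: p_biv exactly p_uni/10 passes
  b <- apply_discovery_filter(data.frame(
    p_biv = 3e-8, p1 = 3e-7, p2 = 1e-4, same_direction = TRUE))
  expect_true(b$pass)
})

test_that("clumping groups by lead r2 within the window, non-transitively", {
  one <- data.frame(snp_id = "rs1", chrom = "1", pos = 100L, p_biv = 1e-9)
  l1 <- clump(one, ld_lookup())
  expect_equal(l1$lead, "rs1")
  expect_equal(l1$n_members, 1L)

  # documented lead pairs: r2 = 0.99 and r2 = 0.39 both merge under > 0.10
  ld <- load_lead_ld()
  two <- data.frame(snp_id = c("rs4765914", "rs10774037"), chrom = "12",
                    pos = c(2420377L, 2420526L), p_biv = c(3.77e-9, 6.40e-12))
  expect_equal(nrow(clump(two, ld)), 1)
  expect_equal(clump(two, ld)$lead, "rs10774037")  # smaller p leads
  mod <- data.frame(snp_id = c("rs16836940", "rs2318763"), chrom = "1",
                    pos = c(150416913L, 150115974L),
                    p_biv = c(1.28e-8, 1.48e-11))
  expect_equal(nrow(clump(mod, ld)), 1)

  # chain a-b-c with r2(a,c) = 0: c is NOT absorbed through b
  chain_ld <- ld_lookup(data.frame(snp_a = c("a", "b"), snp_b = c("b", "c"),
                                   r2 = c(0.5, 0.5)))
  chain <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                      pos = c(1e3, 2e3, 3e3), p_biv = c(1e-10, 1e-9, 1e-8))
  lc <- clump(chain, chain_ld)
  expect_equal(sort(lc$lead), c("a", "c"))

  # outside the window LD is ignored
  far <- data.frame(snp_id = c("a", "b"), chrom = "1",
                    pos = c(1e3, 3e6), p_biv = c(1e-10, 1e-9))
  expect_equal(nrow(clump(far, chain_ld)), 2)
})

test_that("clumping equals the naive greedy oracle on random instances", {
  set.seed(30)
  for (i in 1:20) {
    inst <- random_clump_instance(sample(5:50, 1))
    got <- clump(data.frame(snp_id = inst$snp_id, chrom = inst$chrom,
                            pos = inst$pos, p_biv = inst$p),
                 instance_lookup(inst))
    want <- oracle_clump(inst$snp_id, inst$chrom, inst$pos, inst$p, inst$r2)
    expect_equal(nrow(got), length(want))
    got <- got[order(got$lead), ]
    want_lead <- sort(vapply(want, `[[`, "", "lead"))
    expect_equal(got$lead, want_lead)
    want_members <- vapply(want[order(vapply(want, `[[`, "", "lead"))],
                           function(w) paste(w$members, collapse = ","), "")
    expect_equal(got$members, want_members)
  }
})

test_that("clump invariants: partition, lead minimality, lead independence", {
  set.seed(31)
  inst <- random_clump_instance(40)
  got <- clump(data.frame(snp_id = inst$snp_id, chrom = inst$chrom,
                          pos = inst$pos, p_biv = inst$p),
               instance_lookup(inst))
  members <- unlist(strsplit(got$members, ","))
  expect_setequal(members, inst$snp_id)       # every SNP in exactly one locus
  expect_equal(anyDuplicated(members), 0L)
  for (i in seq_len(nrow(got))) {             # lead has the smallest p
    ms <- strsplit(got$members[i], ",")[[1]]
    expect_equal(got$lead[i],
                 ms[which.min(inst$p[match(ms, inst$snp_id)])])
  }
  if (nrow(got) > 1) {                        # leads pairwise independent
    cmb <- combn(seq_len(nrow(got)), 2)
    same_chr <- got$chrom[cmb[1, ]] == got$chrom[cmb[2, ]]
    near <- abs(inst$pos[match(got$lead[cmb[1, ]], inst$snp_id)] -
                  inst$pos[match(got$lead[cmb[2, ]], inst$snp_id)]) <= 1e6
    r2 <- inst$r2[cbind(match(got$lead[cmb[1, ]], inst$snp_id),
                        match(got$lead[cmb[2, ]], inst$snp_id))]
    expect_true(all(r2[same_chr & near] <= 0.10))
  }
})

test_that("one-sided replication p follows the expected direction", {
  expect_equal(one_sided_p(0, 1), 0.5)
  expect_equal(one_sided_p(1.6449, 1), 0.05, tolerance = 1e-4)
  expect_equal(one_sided_p(-1.6449, 1), 0.95, tolerance = 1e-4)
  expect_equal(one_sided_p(-1.6449, -1), 0.05, tolerance = 1e-4)
  expect_error(one_sided_p(1, 0))
})

test_that("dLC combination of discovery and replication behaves at limits", {
  r <- combine_disc_rep(3, 3, 1e5, 1e5)
  expect_equal(r$t, 3 * sqrt(2))                # equal stages add in quadrature
  r <- combine_disc_rep(3, 1.2, 1e5, 1e-9)
  expect_equal(r$t, 3, tolerance = 1e-6)        # vanishing replication cohort
  r <- combine_disc_rep(5.68, 2.59, 377371, 322580)
  want <- (sqrt(377371) * 5.68 + sqrt(322580) * 2.59) / sqrt(377371 + 322580)
  expect_equal(r$t, want, tolerance = 1e-12)
})

test_that("replication filter demands all three criteria", {
  rec <- data.frame(
    snp_id = c("rs2422320", "rs4843613", "rs9323497", "untested"),
    p_rep_one_sided = c(3.66e-5, 4.48e-2, 4.12e-1, NA),
    direction_consistent = c(TRUE, TRUE, TRUE, TRUE),
    p_combined = c(1.52e-11, 4.70e-9, 4.48e-9, 1e-10),
    p_biv_discovery = c(5.25e-9, 3.40e-9, 3.05e-10, 1e-9))
  out <- apply_replication_filter(rec)
  # NEGR1 row passes all three; ZCCHC14 fails the combined-p criterion;
  # PLEK2 fails the one-sided threshold; a missing statistic is untested
  expect_equal(out$replicated, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$replication_status,
               c("replicated", "not_replicated", "not_replicated", "untested"))
})

test_that("cross-analysis collapse merges shared and LD-linked leads", {
  ld <- load_lead_ld()
  loci <- data.frame(lead = c("rs2535629", "rs2535629", "rs1", "rs2"),
                     p_biv = c(4.94e-9, 8.95e-11, 1e-9, 1e-9))
  out <- collapse_cross_analysis(loci, ld)
  expect_equal(nrow(out), 3)  # shared id merged, rs1/rs2 unlinked
  loci2 <- data.frame(lead = c("rs4765914", "rs10774037"),
                      p_biv = c(3.77e-9, 6.40e-12))
  expect_equal(nrow(collapse_cross_analysis(loci2, ld)), 1)
})

test_that("BH q-values match hand computation and the step-up oracle", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(32)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  expect_error(bh_fdr(c(0.5, 0)))
})

test_that("novelty subtracts known loci, including LD-linked ones", {
  known <- load_known_loci()$snp_id
  ld <- load_lead_ld()
  loci <- data.frame(lead = c("rs1966136", "rs911186", "rs10774037"),
                     replicated = c(TRUE, TRUE, TRUE))
  out <- annotate_novelty(loci, known, ld)
  expect_equal(out$novel, c(FALSE, TRUE, FALSE))  # FHIT known; MIR3143 novel
  # an unreplicated locus is never novel
  loci$replicated <- c(TRUE, FALSE, TRUE)
  expect_equal(annotate_novelty(loci, known, ld)$novel, c(FALSE, FALSE, FALSE))
  # empty known list: every replicated locus is novel
  loci$replicated <- TRUE
  expect_equal(annotate_novelty(loci, character(0))$novel, rep(TRUE, 3))
})
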
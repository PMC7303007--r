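test_that("reading validates, sorts, imputes Z from beta/se and drops bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "snp\tchr\tbp\ta1\ta2\tbeta\tse\tn",
    "rs3\t2\t500\tA\tG\t0.1\t0.05\t1000",
    "rs1\t1\t100\tT\tC\t0\t1\t1000",
    "rs2\t1\t200\tC\tG\t-0.3\t0.1\t1000"
  ), f)
  tab <- read_sumstats(f, trait = "demo")
  expect_s3_class(tab, "sumstats")
  expect_equal(tab$snp_id, c("rs1", "rs2", "rs3"))  # sorted by (chrom, pos)
  expect_equal(tab$z, c(0, -3, 2))                  # z = beta/se
  expect_equal(attr(tab, "trait"), "demo")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "snp\tchr\tbp\ta1\ta2\tz\tn\tp",
    "rs1\t1\t100\tA\tG\t1.0\t1000\t0.3173105",
    "rs2\t1\t200\tA\tG\t1.0\t1000\t0",       # p outside (0,1]
    "rs3\t1\t300\tA\tA\t1.0\t1000\t0.3173105", # a1 == a2
    "rs4\t1\t400\tA\tG\t5.0\t1000\t0.5"      # p inconsistent with z
  ), f2)
  expect_warning(tab2 <- read_sumstats(f2), "3 record")
  expect_equal(tab2$snp_id, "rs1")

  expect_error(read_sumstats(f2, column_map = c(p = "nope")), "nope")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\tchr\tbp\ta1\ta2\tz\tn\tp",
               "rs1\t1\t100\tA\tG\t1.0\t1000\t0"), f3)
  expect_error(suppressWarnings(read_sumstats(f3)), "no valid records")
})

test_that("zscore_from_beta is beta/se and rejects non-positive se", {
  expect_equal(zscore_from_beta(0, 1), 0)
  expect_equal(zscore_from_beta(0.1, 0.05), 2)
  expect_equal(zscore_from_beta(-0.3, 0.1), -3)
  expect_error(zscore_from_beta(1, 0), "> 0")
  expect_error(zscore_from_beta(1, -1), "> 0")
})

test_that("harmonization resolves the full allele swap/strand truth table", {
  # t1 is fixed at (A1=A, A2=C); enumerate t2's configurations
  cases <- list(
    list(a1 = "A", a2 = "C", sign = +1),  # identical
    list(a1 = "C", a2 = "A", sign = -1),  # swapped
    list(a1 = "T", a2 = "G", sign = +1),  # strand complement
    list(a1 = "G", a2 = "T", sign = -1),  # complement of the swap
    list(a1 = "A", a2 = "G", sign = NA),  # irreconcilable
    list(a1 = "C", a2 = "G", sign = NA),  # irreconcilable
    list(a1 = "G", a2 = "C", sign = NA),  # irreconcilable
    list(a1 = "T", a2 = "A", sign = NA)   # irreconcilable
  )
  for (cs in cases) {
    t1 <- make_sumstats("rs1", "A", "C", z = 2)
    t2 <- make_sumstats("rs1", cs$a1, cs$a2, z = 1.5)
    if (is.na(cs$sign)) {
      expect_error(suppressMessages(harmonize_pair(t1, t2)),
                   "no reconcilable")
    } else {
      h <- harmonize_pair(t1, t2)
      expect_equal(h$z2, cs$sign * 1.5,
                   label = paste("t2 alleles", cs$a1, cs$a2))
      expect_equal(h$ea, "A")
    }
  }
})

test_that("palindromic SNPs are dropped by default and rescued by frequency", {
  t1 <- make_sumstats(c("rs1", "rs2"), c("A", "A"), c("T", "C"),
                      z = c(2, 1), eaf = c(0.2, 0.3))
  t2 <- make_sumstats(c("rs1", "rs2"), c("A", "A"), c("T", "C"),
                      z = c(1.5, 0.5), eaf = c(0.22, 0.3))
  h <- suppressMessages(harmonize_pair(t1, t2))
  expect_equal(h$snp_id, "rs2")  # A/T dropped
  h2 <- harmonize_pair(t1, t2, eaf_rescue = TRUE)
  expect_equal(h2$snp_id, c("rs1", "rs2"))
  expect_equal(h2$z2[1], 1.5)    # frequencies agree: same orientation
  t2b <- t2; t2b$eaf[1] <- 0.78  # opposite side of 0.5: flipped orientation
  h3 <- harmonize_pair(t1, t2b, eaf_rescue = TRUE)
  expect_equal(h3$z2[1], -1.5)
})

test_that("harmonization is idempotent and symmetric in |z|", {
  set.seed(1)
  m <- 50
  a1 <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  a2 <- vapply(a1, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  t1 <- make_sumstats(sprintf("rs%02d", 1:m), a1, a2, z = rnorm(m))
  # scramble t2's allele coding per SNP
  swap <- runif(m) < 0.5
  comp <- runif(m) < 0.5
  b1 <- ifelse(swap, a2, a1); b2 <- ifelse(swap, a1, a2)
  b1 <- ifelse(comp, c(A = "T", C = "G", G = "C", T = "A")[b1], b1)
  b2 <- ifelse(comp, c(A = "T", C = "G", G = "C", T = "A")[b2], b2)
  z2_coded <- rnorm(m) * ifelse(swap, -1, 1)
  t2 <- make_sumstats(sprintf("rs%02d", 1:m), b1, b2, z = z2_coded)

  h <- suppressMessages(harmonize_pair(t1, t2))
  # re-harmonizing the harmonized output changes no sign
  t2h <- make_sumstats(h$snp_id, h$ea, h$oa, z = h$z2, pos = h$pos)
  t1h <- make_sumstats(h$snp_id, h$ea, h$oa, z = h$z1, pos = h$pos)
  h2 <- harmonize_pair(t1h, t2h)
  expect_equal(h2$z2, h$z2)
  expect_equal(h2$z1, h$z1)
  # swapping roles preserves the per-SNP |z| multiset
  hr <- suppressMessages(harmonize_pair(t2, t1))
  hr <- hr[match(h$snp_id, hr$snp_id), ]
  expect_equal(abs(hr$z1), abs(h$z2))
  expect_equal(abs(hr$z2), abs(h$z1))
})

test_that("write/read round-trips a sumstats table bit-identically", {
  set.seed(2)
  t1 <- make_sumstats(sprintf("rs%02d", 1:20),
                      rep("A", 20), rep("G", 20), z = rnorm(20),
                      eaf = runif(20))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(t1, f)
  t2 <- read_sumstats(f, trait = attr(t1, "trait"))
  expect_identical(t2$z, t1$z)
  expect_identical(t2$p, t1$p)
  expect_identical(t2$eaf, t1$eaf)
  expect_identical(t2$snp_id, t1$snp_id)
})
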
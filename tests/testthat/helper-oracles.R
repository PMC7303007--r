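# Small builders and independent oracles used across the suite.

# quick sumstats table from minimal vectors
make_sumstats <- function(snp_id, a1, a2, z, chrom = "1",
                          pos = seq_along(snp_id) * 1000L,
                          n = 1e4, eaf = NA_real_, trait = "t") {
  sumstats_table(data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos, a1 = a1, a2 = a2,
    eaf = eaf, z = z, n = n, p = 2 * pnorm(-abs(z)),
    stringsAsFactors = FALSE), trait = trait)
}

# naive re-statement of the greedy clumping definition, written as an
# explicit while-loop over a full r2 matrix rather than the package's
# vectorized pass
oracle_clump <- function(snp_id, chrom, pos, p, r2mat, r2_thresh = 0.10,
                         window_bp = 1e6) {
  unassigned <- rep(TRUE, length(snp_id))
  loci <- list()
  while (any(unassigned)) {
    cand <- which(unassigned)
    lead <- cand[order(p[cand], snp_id[cand])][1]
    grab <- cand[chrom[cand] == chrom[lead] &
                   abs(pos[cand] - pos[lead]) <= window_bp &
                   (r2mat[lead, cand] > r2_thresh | cand == lead)]
    unassigned[grab] <- FALSE
    loci[[length(loci) + 1]] <- list(lead = snp_id[lead],
                                     members = sort(snp_id[grab]))
  }
  loci
}

# textbook step-up definition of BH, by direct enumeration
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# random clumping instance: clustered positions so windows matter
random_clump_instance <- function(m) {
  pos <- sort(sample.int(3e6, m))
  chrom <- sample(c("1", "2"), m, replace = TRUE)
  p <- runif(m)
  r2 <- matrix(0, m, m)
  upper <- which(upper.tri(r2))
  vals <- ifelse(runif(length(upper)) < 0.2, runif(length(upper)), 0)
  r2[upper] <- vals
  r2 <- r2 + t(r2)
  diag(r2) <- 1
  list(snp_id = sprintf("s%03d", seq_len(m)), chrom = chrom, pos = pos,
       p = p, r2 = r2)
}

instance_lookup <- function(inst) {
  m <- length(inst$snp_id)
  cmb <- which(upper.tri(inst$r2), arr.ind = TRUE)
  keep <- inst$r2[cmb] > 0
  ld_lookup(data.frame(snp_a = inst$snp_id[cmb[keep, 1]],
                       snp_b = inst$snp_id[cmb[keep, 2]],
                       r2 = inst$r2[cmb][keep]))
}
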
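#' Discovery significance criteria for the bivariate scan
#'
#' The four criteria a bivariate result must meet to be declared genome-wide
#' significant: (i) bivariate p below the genome-wide threshold; (ii)
#' bivariate p at least `magnitude_factor` times smaller than both univariate
#' p-values (non-strict at the boundary); (iii) both univariate p-values
#' below `p_uni_max`; (iv) concordant effect directions in the two traits.
#'
#' @param p_gw Genome-wide significance threshold (default 5e-8).
#' @param magnitude_factor Required improvement over both univariate
#'   p-values (default 10, i.e. one order of magnitude).
#' @param p_uni_max Nominal univariate significance required of both traits
#'   (default 1e-3).
#' @param require_same_direction Require concordant directions (default TRUE).
#' @return A `discovery_criteria` list.
#' @export
discovery_criteria <- function(p_gw = 5e-8, magnitude_factor = 10,
                               p_uni_max = 1e-3,
                               require_same_direction = TRUE) {
  stopifnot(p_gw > 0, magnitude_factor >= 1, p_uni_max > 0)
  structure(list(p_gw = p_gw, magnitude_factor = magnitude_factor,
                 p_uni_max = p_uni_max,
                 require_same_direction = require_same_direction),
            class = "discovery_criteria")
}

#' Apply the four discovery criteria to bivariate results
#'
#' @param results A `bivariate_results` data.frame (or any data.frame with
#'   columns p_biv, p1, p2, same_direction).
#' @param criteria A [discovery_criteria()] object.
#' @return `results` with logical column `pass` and character column
#'   `failed_criteria` (comma-separated labels among "genome_wide",
#'   "magnitude", "univariate_nominal", "direction"; empty when passing).
#' @export
apply_discovery_filter <- function(results, criteria = discovery_criteria()) {
  c1 <- results$p_biv < criteria$p_gw
  c2 <- results$p_biv <= pmin(results$p1, results$p2) / criteria$magnitude_factor
  c3 <- results$p1 < criteria$p_uni_max & results$p2 < criteria$p_uni_max
  c4 <- if (criteria$require_same_direction) results$same_direction else TRUE
  fails <- cbind(genome_wide = !c1, magnitude = !c2,
                 univariate_nominal = !c3, direction = !c4)
  results$pass <- c1 & c2 & c3 & c4
  results$failed_criteria <- apply(fails, 1, function(f)
    paste(colnames(fails)[f], collapse = ","))
  results
}

#' Build a pairwise r-squared lookup
#'
#' @param df Data.frame with columns snp_a, snp_b, r2 (unordered pairs).
#' @return An `ld_lookup` object; query with [ld_r2()].
#' @export
ld_lookup <- function(df = data.frame(snp_a = character(), snp_b = character(),
                                      r2 = numeric())) {
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(df)))
  key <- ifelse(df$snp_a < df$snp_b,
                paste(df$snp_a, df$snp_b, sep = "\r"),
                paste(df$snp_b, df$snp_a, sep = "\r"))
  env <- new.env(parent = emptyenv(), size = max(29L, 2L * nrow(df)))
  for (i in seq_along(key)) assign(key[i], df$r2[i], envir = env)
  structure(list(env = env), class = "ld_lookup")
}

#' Query pairwise r-squared (0 for unrecorded pairs, 1 for self)
#'
#' @param ld An `ld_lookup` object.
#' @param a,b SNP ids (vectorized).
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  out <- numeric(length(key))
  for (i in seq_along(key)) {
    out[i] <- if (a[i] == b[i]) 1 else
      get0(key[i], envir = ld$env, ifnotfound = 0)
  }
  out
}

#' Greedy LD clumping of discovery-passing SNPs into independent loci
#'
#' Repeatedly takes the unassigned SNP with the smallest bivariate p-value
#' as a lead and absorbs every unassigned SNP within `window_bp` on the same
#' chromosome whose r-squared with the lead exceeds `r2_thresh`.  Absorption
#' is not transitive: a SNP linked only to an absorbed member (not to the
#' lead) seeds its own locus.  Leads of distinct loci are therefore pairwise
#' at or below the threshold.  Missing LD for a within-window pair is treated
#' as r2 = 0.
#'
#' @param results A data.frame of discovery-passing SNPs with columns snp_id,
#'   chrom, pos, p_biv.
#' @param ld An `ld_lookup` object.
#' @param r2_thresh LD-dependence threshold (default 0.10, exceeded strictly).
#' @param window_bp Clumping half-window in bp (default 1e6).
#' @param analysis Optional label recorded on each locus.
#' @return A `loci` data.frame: lead, chrom, span_lo, span_hi, p_biv,
#'   n_members, members (comma-separated snp_ids incl. the lead), analysis.
#' @export
clump <- function(results, ld, r2_thresh = 0.10, window_bp = 1e6,
                  analysis = NA_character_) {
  if (nrow(results) == 0) {
    return(structure(data.frame(lead = character(), chrom = character(),
                                span_lo = integer(), span_hi = integer(),
                                p_biv = numeric(), n_members = integer(),
                                members = character(), analysis = character(),
                                stringsAsFactors = FALSE),
                     class = c("loci", "data.frame")))
  }
  ord <- order(results$p_biv, results$snp_id)  # snp_id breaks p ties
  r <- results[ord, , drop = FALSE]
  assigned <- logical(nrow(r))
  out <- list()
  for (i in seq_len(nrow(r))) {
    if (assigned[i]) next
    lead <- r$snp_id[i]
    cand <- which(!assigned & r$chrom == r$chrom[i] &
                    abs(r$pos - r$pos[i]) <= window_bp)
    r2 <- ld_r2(ld, rep(lead, length(cand)), r$snp_id[cand])
    members <- cand[r2 > r2_thresh | r$snp_id[cand] == lead]
    assigned[members] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      lead = lead, chrom = r$chrom[i],
      span_lo = min(r$pos[members]), span_hi = max(r$pos[members]),
      p_biv = r$p_biv[i], n_members = length(members),
      members = paste(sort(r$snp_id[members]), collapse = ","),
      analysis = analysis, stringsAsFactors = FALSE
    )
  }
  structure(do.call(rbind, out), class = c("loci", "data.frame"))
}

#' One-sided replication p-value in the discovery direction
#'
#' The tail probability of the replication Z-score at least as extreme in
#' the direction expected from discovery: `p = pnorm(-z_rep * expected_sign)`.
#'
#' @param z_rep Replication Z-score(s).
#' @param expected_sign +1 or -1 per SNP, from the discovery effect sign.
#' @return One-sided p-value(s) in (0, 1).
#' @export
one_sided_p <- function(z_rep, expected_sign) {
  stopifnot(all(expected_sign %in% c(-1, 1)))
  stats::pnorm(-z_rep * expected_sign)
}

#' Combine discovery and replication statistics by dLC meta-analysis
#'
#' Treats the discovery bivariate statistic and the replication Z-score as
#' independent (non-overlapping cohorts, s = 0) and combines them with
#' sqrt-sample-size weights: `t = (sqrt(n_disc) t_disc + sqrt(n_rep) z_rep)
#' / sqrt(n_disc + n_rep)`.
#'
#' @param t_disc Discovery bivariate statistic.
#' @param z_rep Replication Z-score.
#' @param n_disc,n_rep Effective sample sizes of the two stages.
#' @return List with `t` and two-sided `p`.
#' @export
combine_disc_rep <- function(t_disc, z_rep, n_disc, n_rep) {
  dlc_stat(t_disc, z_rep, s = 0, w1 = sqrt(n_disc), w2 = sqrt(n_rep))
}

#' Apply the three replication criteria
#'
#' A SNP replicates iff (i) its one-sided replication p is below `alpha`,
#' (ii) the effect direction is consistent across discovery and replication,
#' and (iii) the combined discovery+replication p-value is strictly more
#' significant than the discovery bivariate p-value.  Rows with a missing
#' replication p are flagged "untested" and not replicated.
#'
#' @param rec Data.frame with columns p_rep_one_sided, direction_consistent,
#'   p_combined, p_biv_discovery.
#' @param alpha One-sided replication threshold (default 0.05).
#' @return `rec` with logical column `replicated` and character column
#'   `replication_status` ("replicated", "not_replicated" or "untested").
#' @export
apply_replication_filter <- function(rec, alpha = 0.05) {
  untested <- is.na(rec$p_rep_one_sided)
  pass <- !untested &
    rec$p_rep_one_sided < alpha &
    rec$direction_consistent &
    rec$p_combined < rec$p_biv_discovery
  rec$replicated <- pass
  rec$replication_status <- ifelse(untested, "untested",
                                   ifelse(pass, "replicated", "not_replicated"))
  rec
}

#' Collapse loci from several bivariate analyses into independent loci
#'
#' Union-find over leads: two loci are merged when they share a SNP id or
#' when their leads' pairwise r-squared exceeds `r2_thresh`.  The number of
#' resulting components is the count of independent loci across analyses.
#'
#' @param loci A `loci` data.frame pooled over analyses (or any data.frame
#'   with columns lead and optionally members).
#' @param ld An `ld_lookup` object for lead-pair r-squared.
#' @param r2_thresh Merge threshold (default 0.10, exceeded strictly).
#' @return Data.frame with one row per independent locus: component id,
#'   leads (comma-separated), representative lead (smallest p_biv when
#'   available, else first), n_rows merged.
#' @export
collapse_cross_analysis <- function(loci, ld, r2_thresh = 0.10) {
  n <- nrow(loci)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  members <- if ("members" %in% names(loci)) {
    strsplit(loci$members, ",", fixed = TRUE)
  } else as.list(loci$lead)
  members <- lapply(seq_len(n), function(i) unique(c(loci$lead[i], members[[i]])))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    share <- length(intersect(members[[i]], members[[j]])) > 0
    linked <- ld_r2(ld, loci$lead[i], loci$lead[j]) > r2_thresh
    if (share || linked) union_(i, j)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  split_idx <- split(seq_len(n), comp)
  rows <- lapply(split_idx, function(idx) {
    rep_lead <- if ("p_biv" %in% names(loci)) {
      loci$lead[idx][which.min(loci$p_biv[idx])]
    } else loci$lead[idx][1]
    data.frame(leads = paste(sort(unique(loci$lead[idx])), collapse = ","),
               lead = rep_lead, n_rows = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' Order-preserving wrapper over the standard BH adjustment.
#'
#' @param pvalues P-values in (0, 1\].
#' @return Q-values aligned to the input order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Flag replicated loci as novel against a list of known loci
#'
#' A replicated locus is novel iff its lead (and none of its members) appears
#' in, or is LD-linked (r2 above threshold) to, the externally supplied list
#' of previously reported loci.
#'
#' @param loci Data.frame with columns lead, replicated, and optionally
#'   members (comma-separated).
#' @param known_snps Character vector of lead SNP ids of previously reported
#'   loci.
#' @param ld Optional `ld_lookup` for LD-linkage to known leads.
#' @param r2_thresh Linkage threshold (default 0.10).
#' @return `loci` with logical column `novel`.
#' @export
annotate_novelty <- function(loci, known_snps, ld = NULL, r2_thresh = 0.10) {
  members <- if ("members" %in% names(loci)) {
    strsplit(loci$members, ",", fixed = TRUE)
  } else as.list(loci$lead)
  known <- vapply(seq_len(nrow(loci)), function(i) {
    ids <- unique(c(loci$lead[i], members[[i]]))
    hit <- any(ids %in% known_snps)
    if (!hit && !is.null(ld) && length(known_snps)) {
      hit <- any(ld_r2(ld, rep(loci$lead[i], length(known_snps)),
                       known_snps) > r2_thresh)
    }
    hit
  }, logical(1))
  loci$novel <- loci$replicated & !known
  loci
}

#' Write a loci table as TSV
#'
#' @param x A `loci` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
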
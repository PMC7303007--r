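#' Load the bundled bivariate depression discovery/replication table
#'
#' A 23-row table of genome-wide significant lead SNPs from four bivariate
#' GWAS analyses of a broad depression phenotype with, respectively,
#' self-reported MDD (sMDD), recurrent MDD (rMDD), bipolar disorder (BPD)
#' and schizophrenia (SCZ), together with their printed univariate,
#' bivariate, one-sided UK Biobank replication and combined p-values, the
#' effect-direction triplet `ed` (broad depression / companion phenotype /
#' replication, for the effect allele), a prior-report flag and the
#' discovery/replication sample sizes.  One SNP (rs2535629) appears under
#' both the BPD and the SCZ analysis.
#'
#' @return Data.frame of 23 rows.
#' @export
load_discovery_table <- function() {
  path <- system.file("extdata", "discovery_replication_table.tsv",
                      package = "bivargwas", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Load the bundled list of previously reported depression loci
#'
#' Lead SNPs of loci previously reported for depression or in cross-disorder
#' scans (NEGR1, MAT2B, ITIH3, CACNA1C, FHIT, BAG5), used by
#' [annotate_novelty()].
#'
#' @return Data.frame with columns gene, snp_id.
#' @export
load_known_loci <- function() {
  path <- system.file("extdata", "known_depression_loci.tsv",
                      package = "bivargwas", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Load the bundled lead-pair LD values for the discovery table
#'
#' The two documented lead-SNP LD pairs: rs4765914/rs10774037 (r2 = 0.99)
#' and rs16836940/rs2318763 (r2 = 0.39).
#'
#' @return An `ld_lookup` object.
#' @export
load_lead_ld <- function() {
  path <- system.file("extdata", "lead_ld_r2.tsv",
                      package = "bivargwas", mustWork = TRUE)
  ld_lookup(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}

.ed_chars <- function(ed) {
  do.call(rbind, strsplit(ed, "", fixed = TRUE))
}

#' Audit the bundled discovery/replication table
#'
#' Re-derives, purely from the printed p-values and direction triplets, the
#' locus bookkeeping of the four bivariate analyses: per-row discovery
#' status under the four criteria, per-row replication status under the
#' three criteria, the cross-analysis collapse into independent loci, the
#' unique replicated loci and their novelty against the bundled prior-report
#' list, and the post-hoc BH-FDR of the replicated SNPs' one-sided
#' replication p-values.
#'
#' @param table The discovery table (default: [load_discovery_table()]).
#' @param ld Lead-pair LD (default: [load_lead_ld()]).
#' @param known Known-loci SNP ids (default: from [load_known_loci()]).
#' @return A list: `rows` (the table with pass/replicated columns),
#'   `n_independent_loci`, `n_replicated_unique`, `n_novel`,
#'   `replicated_leads`, `novel_leads`, `fdr` (data.frame snp_id, p, q),
#'   `collapsed` (the component table).
#' @export
audit_discovery_table <- function(table = load_discovery_table(),
                                  ld = load_lead_ld(),
                                  known = load_known_loci()$snp_id) {
  ed <- .ed_chars(table$ed)
  disc <- data.frame(p_biv = table$p_biv, p1 = table$p_dep,
                     p2 = table$p_other,
                     same_direction = ed[, 1] == ed[, 2])
  disc <- apply_discovery_filter(disc)
  rep_rec <- data.frame(p_rep_one_sided = table$p_rep_one_sided,
                        direction_consistent = ed[, 1] == ed[, 2] &
                          ed[, 2] == ed[, 3],
                        p_combined = table$p_combined,
                        p_biv_discovery = table$p_biv)
  rep_rec <- apply_replication_filter(rep_rec)
  rows <- cbind(table, pass = disc$pass,
                failed_criteria = disc$failed_criteria,
                replicated = rep_rec$replicated,
                replication_status = rep_rec$replication_status)

  all_rows <- data.frame(lead = table$snp_id, p_biv = table$p_biv,
                         stringsAsFactors = FALSE)
  collapsed <- collapse_cross_analysis(all_rows, ld)

  rep_rows <- all_rows[rows$replicated, , drop = FALSE]
  rep_collapsed <- collapse_cross_analysis(rep_rows, ld)
  rep_collapsed$replicated <- TRUE
  nov <- annotate_novelty(rep_collapsed, known, ld)

  uniq <- !duplicated(table$snp_id) & rows$replicated
  # FDR over the unique replicated SNPs' one-sided replication p-values
  fdr_p <- table$p_rep_one_sided[rows$replicated]
  fdr_id <- table$snp_id[rows$replicated]
  keep <- !duplicated(fdr_id)
  fdr <- data.frame(snp_id = fdr_id[keep], p = fdr_p[keep],
                    q = bh_fdr(fdr_p[keep]), stringsAsFactors = FALSE)

  list(rows = rows,
       n_independent_loci = nrow(collapsed),
       n_replicated_unique = nrow(rep_collapsed),
       n_novel = sum(nov$novel),
       replicated_leads = sort(unique(rep_rows$lead)),
       novel_leads = sort(nov$lead[nov$novel]),
       fdr = fdr,
       collapsed = collapsed)
}
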
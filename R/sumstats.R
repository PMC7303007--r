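#' Convert an effect estimate and standard error to a Z-score
#'
#' @param beta Numeric vector of effect estimates.
#' @param se Numeric vector of standard errors; must be strictly positive.
#' @return Numeric vector `beta / se`.
#' @examples
#' zscore_from_beta(0.1, 0.05)  # 2
#' @export
zscore_from_beta <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("standard errors must be finite and > 0")
  }
  beta / se
}

# Default header-name synonyms for summary-statistics files.  A user-supplied
# column_map (standard name -> file column) overrides these.
.default_column_synonyms <- list(
  snp_id = c("snp_id", "snp", "rsid", "markername", "id", "variant_id"),
  chrom  = c("chrom", "chr", "chromosome"),
  pos    = c("pos", "bp", "position", "base_pair_location"),
  a1     = c("a1", "ea", "effect_allele", "allele1", "alt"),
  a2     = c("a2", "oa", "other_allele", "allele2", "ref", "non_effect_allele"),
  eaf    = c("eaf", "af", "freq", "maf", "effect_allele_frequency"),
  z      = c("z", "zscore", "z_score", "stat"),
  beta   = c("beta", "b", "effect", "log_odds"),
  se     = c("se", "stderr", "standard_error"),
  n      = c("n", "neff", "sample_size", "n_total"),
  p      = c("p", "pval", "pvalue", "p_value")
)

.resolve_columns <- function(header, column_map = NULL) {
  lower <- tolower(header)
  out <- list()
  for (std in names(.default_column_synonyms)) {
    if (!is.null(column_map) && std %in% names(column_map)) {
      idx <- match(tolower(column_map[[std]]), lower)
      if (is.na(idx)) stop("mapped column '", column_map[[std]],
                           "' for '", std, "' not found in file header")
    } else {
      idx <- match(.default_column_synonyms[[std]], lower)
      idx <- idx[!is.na(idx)][1]
    }
    out[[std]] <- if (length(idx) && !is.na(idx)) header[idx] else NA_character_
  }
  out
}

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a whitespace- or tab-delimited summary-statistics file (gzip is
#' handled transparently), maps its columns onto the standard fields
#' (snp_id, chrom, pos, a1, a2, eaf, z, n, p), imputes `z = beta/se` when no
#' Z column is present and `p = 2*pnorm(-|z|)` when no p-value column is
#' present, and drops records that violate the per-record invariants:
#' alleles must be distinct single bases in A/C/G/T, p must lie in (0, 1],
#' eaf (if present) in \[0, 1\], n positive, and a supplied p must agree with
#' the two-sided normal p of the Z-score to 1e-6 relative tolerance.
#'
#' @param path Path to the file.
#' @param column_map Optional named character vector mapping standard field
#'   names to file column names, e.g. `c(snp_id = "MarkerName", p = "P.value")`.
#' @param trait Trait label attached to the table.
#' @param n_default Sample size used for records with missing N (default `NA`,
#'   meaning such records are dropped).
#' @param m_total Genome-wide SNP count the table represents; defaults to the
#'   number of valid rows.
#' @return A `sumstats` object: a data.frame sorted by (chrom, pos) with
#'   columns snp_id, chrom, pos, a1, a2, eaf, z, n, p and attributes `trait`
#'   and `m_total`.
#' @export
read_sumstats <- function(path, column_map = NULL, trait = "trait",
                          n_default = NA_real_, m_total = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  cols <- .resolve_columns(names(df), column_map)
  need <- c("snp_id", "chrom", "pos", "a1", "a2")
  for (std in need) {
    if (is.na(cols[[std]])) stop("missing mandatory column for field '", std, "'")
  }
  grab <- function(std, as = as.character) {
    if (is.na(cols[[std]])) rep(NA, nrow(df)) else as(df[[cols[[std]]]])
  }
  tab <- data.frame(
    snp_id = grab("snp_id"),
    chrom  = grab("chrom"),
    pos    = grab("pos", as.integer),
    a1     = toupper(grab("a1")),
    a2     = toupper(grab("a2")),
    eaf    = grab("eaf", as.numeric),
    z      = grab("z", as.numeric),
    n      = grab("n", as.numeric),
    p      = grab("p", as.numeric),
    stringsAsFactors = FALSE
  )
  if (all(is.na(tab$z))) {
    if (is.na(cols$beta) || is.na(cols$se)) {
      stop("missing mandatory column for field 'z' (and no beta/se to impute from)")
    }
    se <- as.numeric(df[[cols$se]])
    bad_se <- !is.finite(se) | se <= 0
    tab$z <- ifelse(bad_se, NA_real_, as.numeric(df[[cols$beta]]) / se)
  }
  tab$n[is.na(tab$n)] <- n_default
  p_from_z <- 2 * stats::pnorm(-abs(tab$z))
  tab$p[is.na(tab$p)] <- p_from_z[is.na(tab$p)]

  ok <- !is.na(tab$snp_id) & !is.na(tab$pos) &
    tab$a1 %in% c("A", "C", "G", "T") & tab$a2 %in% c("A", "C", "G", "T") &
    tab$a1 != tab$a2 &
    is.finite(tab$z) & is.finite(tab$n) & tab$n > 0 &
    is.finite(tab$p) & tab$p > 0 & tab$p <= 1 &
    (is.na(tab$eaf) | (tab$eaf >= 0 & tab$eaf <= 1))
  # z/p consistency: relative tolerance 1e-6 where both were supplied
  if (!is.na(cols$p) && !is.na(cols$z)) {
    rel <- abs(tab$p - p_from_z) / pmax(tab$p, .Machine$double.xmin)
    ok <- ok & (is.na(rel) | rel <= 1e-6)
  }
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    warning(n_drop, " record(s) failed validation and were dropped")
  }
  tab <- tab[ok, , drop = FALSE]
  if (nrow(tab) == 0) stop("no valid records in ", path)
  if (anyDuplicated(tab$snp_id)) {
    warning(sum(duplicated(tab$snp_id)), " duplicate snp_id(s) dropped")
    tab <- tab[!duplicated(tab$snp_id), , drop = FALSE]
  }
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  sumstats_table(tab, trait = trait,
                 m_total = if (is.null(m_total)) nrow(tab) else m_total)
}

#' Construct a sumstats table from a data.frame
#'
#' @param df Data.frame with columns snp_id, chrom, pos, a1, a2, z, n, p and
#'   optionally eaf.
#' @param trait Trait label.
#' @param m_total Genome-wide SNP count represented (defaults to `nrow(df)`).
#' @return A `sumstats` object.
#' @export
sumstats_table <- function(df, trait = "trait", m_total = nrow(df)) {
  need <- c("snp_id", "chrom", "pos", "a1", "a2", "z", "n", "p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  df <- df[, c("snp_id", "chrom", "pos", "a1", "a2", "eaf", "z", "n", "p")]
  if (anyDuplicated(df$snp_id)) stop("snp_id must be unique")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, trait = trait, m_total = m_total,
            class = c("sumstats", "data.frame"))
}

#' Write a sumstats table as TSV
#'
#' Round-trips through [read_sumstats()] bit-identically for
#' text-representable values (17 significant digits are written).
#'
#' @param x A `sumstats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- as.data.frame(x)
  for (col in c("eaf", "z", "n", "p")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Harmonize two summary-statistics tables onto a shared effect allele
#'
#' Intersects the two tables on snp_id and reorients the second trait's
#' Z-score onto the first trait's effect allele.  Four allele configurations
#' are reconcilable: identical (keep sign), swapped (flip sign), strand
#' complement (keep sign), and strand complement of the swap (flip sign).
#' Any other pairing is dropped with a logged count.  Palindromic A/T and C/G
#' SNPs cannot be oriented without frequency information and are dropped by
#' default; with `eaf_rescue = TRUE` a palindromic SNP is kept when both
#' studies report `|eaf - 0.5| > 0.08`, using frequency agreement to decide
#' the strand.
#'
#' @param t1,t2 `sumstats` objects.
#' @param drop_palindromic Drop A/T and C/G SNPs (default TRUE).
#' @param eaf_rescue Rescue palindromic SNPs by allele frequency (default FALSE).
#' @return A `harmonized_pairs` data.frame with columns snp_id, chrom, pos,
#'   ea, oa, z1, z2, n1, n2, p1, p2 in `t1` order, with attributes `trait1`,
#'   `trait2`, `m_total` (the smaller of the two tables' m_total).
#' @export
harmonize_pair <- function(t1, t2, drop_palindromic = TRUE, eaf_rescue = FALSE) {
  idx2 <- match(t1$snp_id, t2$snp_id)
  keep <- !is.na(idx2)
  if (!any(keep)) stop("no shared snp_id between the two tables")
  a <- t1[keep, , drop = FALSE]
  b <- t2[idx2[keep], , drop = FALSE]

  same      <- b$a1 == a$a1 & b$a2 == a$a2
  swapped   <- b$a1 == a$a2 & b$a2 == a$a1
  comp      <- b$a1 == .complement[a$a1] & b$a2 == .complement[a$a2]
  comp_swap <- b$a1 == .complement[a$a2] & b$a2 == .complement[a$a1]
  pal <- .is_palindromic(a$a1, a$a2)

  sign2 <- rep(NA_real_, nrow(a))
  sign2[same | comp] <- 1
  sign2[swapped | comp_swap] <- -1
  # For palindromic SNPs same==comp_swap and swapped==comp: the strand is
  # ambiguous, so the sign assignment above is not trustworthy.
  if (any(pal)) {
    if (drop_palindromic && !eaf_rescue) {
      sign2[pal] <- NA_real_
    } else if (eaf_rescue) {
      informative <- pal & !is.na(a$eaf) & !is.na(b$eaf) &
        abs(a$eaf - 0.5) > 0.08 & abs(b$eaf - 0.5) > 0.08
      sign2[pal & !informative] <- NA_real_
      # effect-allele frequencies on the same side of 0.5 identify b's effect
      # allele with a's (possibly on the other strand): keep the sign;
      # opposite sides identify it with a's other allele: flip.
      s <- ifelse((a$eaf - 0.5) * (b$eaf - 0.5) > 0, 1, -1)
      sign2[informative] <- s[informative]
    }
  }
  n_drop <- sum(is.na(sign2))
  if (n_drop > 0) {
    message(n_drop, " SNP(s) dropped during harmonization ",
            "(palindromic or irreconcilable alleles)")
  }
  ok <- !is.na(sign2)
  out <- data.frame(
    snp_id = a$snp_id[ok], chrom = a$chrom[ok], pos = a$pos[ok],
    ea = a$a1[ok], oa = a$a2[ok],
    z1 = a$z[ok], z2 = sign2[ok] * b$z[ok],
    n1 = a$n[ok], n2 = b$n[ok],
    p1 = a$p[ok], p2 = b$p[ok],
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) stop("no reconcilable SNPs after harmonization")
  rownames(out) <- NULL
  structure(out,
            trait1 = attr(t1, "trait"), trait2 = attr(t2, "trait"),
            m_total = min(attr(t1, "m_total") %||% nrow(t1),
                          attr(t2, "m_total") %||% nrow(t2)),
            class = c("harmonized_pairs", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write harmonized pairs as TSV
#'
#' @param x A `harmonized_pairs` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
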
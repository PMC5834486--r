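# Marker and sample quality control: the pruning cascade and its accounting.

#' QC thresholds
#'
#' Defaults follow common GWAS-era triad practice: founders must not deviate
#' from Hardy-Weinberg equilibrium at p < 0.001, SNPs need < 5% missing
#' calls, minor allele frequency > 5% and a Mendelian-error rate < 1%;
#' individuals with a genotype call rate below 10% are removed first.
#'
#' @param hwe_p_min SNPs with founder HWE p-value below this are removed.
#' @param snp_missing_max maximum tolerated per-SNP missing fraction.
#' @param maf_min SNPs are kept only if MAF is strictly greater than this.
#' @param mendel_rate_max SNPs with a per-family Mendelian inconsistency
#'   rate at or above this are removed.
#' @param indiv_callrate_min individuals below this call rate are removed.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 0.001, snp_missing_max = 0.05,
                          maf_min = 0.05, mendel_rate_max = 0.01,
                          indiv_callrate_min = 0.10) {
  th <- list(hwe_p_min = hwe_p_min, snp_missing_max = snp_missing_max,
             maf_min = maf_min, mendel_rate_max = mendel_rate_max,
             indiv_callrate_min = indiv_callrate_min)
  if (any(unlist(th) < 0 | unlist(th) > 1))
    stop("all QC thresholds must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Hardy-Weinberg 1-df chi-square test from genotype counts
#'
#' Observed founder genotype counts are compared with the HWE expectation at
#' the observed allele frequency; the statistic is referred to a 1-df
#' chi-square upper tail. A monomorphic marker is flagged and returns
#' statistic 0, p 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (founders only by convention).
#' @return List with `statistic`, `p_value`, `monomorphic`.
#' @export
hwe_chi2 <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(c(n_AA, n_Aa, n_aa) < 0) || n <= 0)
    stop("counts must be non-negative with a positive total")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1)
    return(list(statistic = 0, p_value = 1, monomorphic = TRUE))
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

# Per-family Mendelian consistency bounds on the child's allele-2 dose:
# a parent with 0 copies transmits 0, with 2 copies transmits 1, with 1 copy
# (or missing/absent) either. The child dose must lie in the summed range.
mendel_inconsistent <- function(gm, gf, gc) {
  lo_m <- !is.na(gm) & gm == 2L
  hi_m <- is.na(gm) | gm >= 1L
  lo_f <- !is.na(gf) & gf == 2L
  hi_f <- is.na(gf) | gf >= 1L
  !is.na(gc) & (gc < lo_m + lo_f | gc > hi_m + hi_f)
}

#' Per-SNP summary statistics
#'
#' Missing fraction is taken over all typed persons; MAF over founder
#' (parental) alleles; the Mendelian-error rate is the fraction of families
#' whose available member genotypes are inconsistent with Mendelian
#' transmission at that SNP.
#'
#' @param ds a [triad_data()] object.
#' @return data.frame with one row per marker: `snp`, `missing_fraction`,
#'   `maf`, `mendel_rate`, `hwe_stat`, `hwe_p`, `monomorphic`.
#' @export
snp_stats <- function(ds) {
  m <- nrow(ds$markers)
  fi <- family_index(ds)
  founders <- which(ds$persons$role != "child")
  out <- data.frame(snp = ds$markers$snp,
                    missing_fraction = if (nrow(ds$geno))
                      colMeans(is.na(ds$geno)) else rep(0, m),
                    maf = NA_real_, mendel_rate = NA_real_,
                    hwe_stat = NA_real_, hwe_p = NA_real_,
                    monomorphic = NA, stringsAsFactors = FALSE)
  if (!m) return(out)
  gm <- ds$geno[ifelse(is.na(fi$mother), 1L, fi$mother), , drop = FALSE]
  gm[is.na(fi$mother), ] <- NA_integer_
  gf <- ds$geno[ifelse(is.na(fi$father), 1L, fi$father), , drop = FALSE]
  gf[is.na(fi$father), ] <- NA_integer_
  gc <- ds$geno[fi$child, , drop = FALSE]
  nfam <- length(fi$family_id)
  for (j in seq_len(m)) {
    fg <- ds$geno[founders, j]
    fg <- fg[!is.na(fg)]
    if (length(fg)) {
      f2 <- sum(fg) / (2 * length(fg))
      out$maf[j] <- min(f2, 1 - f2)
      hw <- hwe_chi2(sum(fg == 0L), sum(fg == 1L), sum(fg == 2L))
      out$hwe_stat[j] <- hw$statistic
      out$hwe_p[j] <- hw$p_value
      out$monomorphic[j] <- hw$monomorphic
    } else {
      out$maf[j] <- 0; out$hwe_stat[j] <- 0; out$hwe_p[j] <- 1
      out$monomorphic[j] <- TRUE
    }
    out$mendel_rate[j] <- if (nfam)
      mean(mendel_inconsistent(gm[, j], gf[, j], gc[, j])) else 0
  }
  out
}

#' Apply the QC pruning cascade
#'
#' Order of operations: (1) individuals with call rate below
#' `indiv_callrate_min` are removed (a family whose affected child is removed
#' is dropped entirely); (2) per-SNP statistics are recomputed; (3) SNPs
#' failing any of the HWE, missingness, MAF or Mendelian-rate criteria are
#' removed — a SNP failing several criteria increments each counter but is
#' removed once (union semantics); (4) within retained SNPs, genotypes of
#' Mendelian-inconsistent families are set to missing at the offending locus.
#'
#' @param ds a [triad_data()] object.
#' @param th a [qc_thresholds()] object.
#' @return List with elements `dataset` (pruned `triad_data`) and `report`
#'   (class `qc_report`).
#' @export
apply_qc <- function(ds, th = qc_thresholds()) {
  stopifnot(inherits(th, "qc_thresholds"))
  total_snps <- nrow(ds$markers)
  total_indiv <- nrow(ds$persons)

  callrate <- if (total_snps) rowMeans(!is.na(ds$geno)) else
    rep(1, total_indiv)
  drop_person <- callrate < th$indiv_callrate_min
  drop_fam <- unique(ds$persons$family_id[drop_person &
                                          ds$persons$role == "child"])
  drop_person <- drop_person | ds$persons$family_id %in% drop_fam
  n_indiv_removed <- sum(drop_person)
  ds2 <- triad_data(ds$persons[!drop_person, , drop = FALSE], ds$markers,
                    ds$geno[!drop_person, , drop = FALSE])

  st <- snp_stats(ds2)
  fail_hwe <- st$hwe_p < th$hwe_p_min
  fail_missing <- st$missing_fraction > th$snp_missing_max
  # MAF strictly > maf_min retained; maf_min = 0 is the vacuous bound
  fail_maf <- if (th$maf_min > 0) st$maf <= th$maf_min else
    rep(FALSE, nrow(st))
  # Mendelian rate >= max removed; max = 1 is the vacuous bound
  fail_mendel <- if (th$mendel_rate_max < 1)
    st$mendel_rate >= th$mendel_rate_max else rep(FALSE, nrow(st))
  fail_any <- fail_hwe | fail_missing | fail_maf | fail_mendel

  keep <- which(!fail_any)
  geno <- ds2$geno[, keep, drop = FALSE]
  markers <- ds2$markers[keep, , drop = FALSE]

  # mask residual Mendelian-inconsistent family genotypes among kept SNPs
  # (skipped at the vacuous bound mendel_rate_max = 1, where the Mendelian
  # criterion as a whole is disabled)
  fi <- family_index(ds2)
  n_masked <- 0L
  if (th$mendel_rate_max < 1 && length(keep) && length(fi$family_id)) {
    gm <- geno[ifelse(is.na(fi$mother), 1L, fi$mother), , drop = FALSE]
    gm[is.na(fi$mother), ] <- NA_integer_
    gf <- geno[ifelse(is.na(fi$father), 1L, fi$father), , drop = FALSE]
    gf[is.na(fi$father), ] <- NA_integer_
    gc <- geno[fi$child, , drop = FALSE]
    bad <- mendel_inconsistent(gm, gf, gc)
    idx <- which(bad, arr.ind = TRUE)
    if (nrow(idx)) {
      n_masked <- nrow(idx)
      for (r in seq_len(nrow(idx))) {
        f <- idx[r, 1]; j <- idx[r, 2]
        for (pi in c(fi$mother[f], fi$father[f], fi$child[f]))
          if (!is.na(pi)) geno[pi, j] <- NA_integer_
      }
    }
  }
  out_ds <- triad_data(ds2$persons, markers, geno)
  report <- structure(list(
    total_snps = total_snps,
    total_individuals = total_indiv,
    individuals_removed = n_indiv_removed,
    failed_hwe = sum(fail_hwe),
    failed_missingness = sum(fail_missing),
    failed_frequency = sum(fail_maf),
    failed_mendelian = sum(fail_mendel),
    snps_removed = sum(fail_any),
    snps_remaining = length(keep),
    family_genotypes_masked = n_masked,
    thresholds = th), class = "qc_report")
  list(dataset = out_ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  Individuals removed (call rate < %g): %d of %d\n",
              x$thresholds$indiv_callrate_min, x$individuals_removed,
              x$total_individuals))
  cat(sprintf("  Total SNPs before pruning: %d\n", x$total_snps))
  cat(sprintf("  Failed HWE test:           %d\n", x$failed_hwe))
  cat(sprintf("  Failed missingness test:   %d\n", x$failed_missingness))
  cat(sprintf("  Failed SNP frequency test: %d\n", x$failed_frequency))
  cat(sprintf("  Mendelian errors detected: %d\n", x$failed_mendelian))
  cat(sprintf("  Remaining SNPs after pruning: %d\n", x$snps_remaining))
  cat("  (criteria overlap: removed = union, not the sum)\n")
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report`.
#' @param path output path.
#' @return Invisibly, `report`.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    criterion = c("total_snps", "failed_hwe", "failed_missingness",
                  "failed_frequency", "failed_mendelian", "snps_remaining",
                  "individuals_removed"),
    count = c(report$total_snps, report$failed_hwe,
              report$failed_missingness, report$failed_frequency,
              report$failed_mendelian, report$snps_remaining,
              report$individuals_removed))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
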
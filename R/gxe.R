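# Exposure-stratified fitting, the Wald relative-risk-ratio (RRR) test for
# gene-environment interaction, sliding-window scans, and pairwise LD.
#
# A GxE effect is present when the child relative risk differs between the
# offspring of exposed and unexposed mothers: RRR = RR(exposed)/RR(unexposed).
# The strata are fitted independently (their own haplotype frequencies and
# RRs), so on the log scale var(log RRR) = se1^2 + se0^2 and the Wald z is
# log RRR over its standard error.

#' Fit the triad model within exposure strata
#'
#' Families with unknown exposure contribute to the unstratified
#' ("all"/child-effect) fit only. Haplotype frequencies are estimated
#' separately per stratum; the reference haplotype is fixed from the pooled
#' fit so relative risks are comparable across strata.
#'
#' @param ds a [triad_data()] object (post-QC).
#' @param exposures an `exposure_table` from [read_exposures()] or
#'   [simulate_study()].
#' @param exposure name of the exposure column.
#' @param window a [make_window()] object.
#' @param options a [model_options()] list.
#' @param fit_all fit the unstratified child-effect model too (default TRUE;
#'   skipping it saves time in simulations and uses the most frequent
#'   haplotype of the exposed+unexposed pool as reference).
#' @return List of class `strata_fit` with elements `all` (or NULL),
#'   `exposed`, `unexposed` (each a `triad_fit`), `exposure`, `n` per
#'   stratum.
#' @export
fit_strata <- function(ds, exposures, exposure, window,
                       options = model_options(), fit_all = TRUE) {
  fam <- unique(ds$persons$family_id)
  st <- exposure_status(exposures, fam, exposure)
  n1 <- sum(st == "exposed"); n0 <- sum(st == "unexposed")
  if (n1 == 0L || n0 == 0L)
    stop("empty stratum for exposure '", exposure, "' (",
         n1, " exposed, ", n0, " unexposed)")
  all_fit <- NULL
  if (fit_all) {
    all_fit <- fit_triads(ds, window, options)
    ref <- all_fit$reference
  } else {
    pool <- subset_families(ds, fam[st != "unknown"])
    ref <- fit_triads(pool, window, options)$reference
  }
  exp_fit <- fit_triads(subset_families(ds, fam[st == "exposed"]),
                        window, options, reference = ref)
  unexp_fit <- fit_triads(subset_families(ds, fam[st == "unexposed"]),
                          window, options, reference = ref)
  structure(list(all = all_fit, exposed = exp_fit, unexposed = unexp_fit,
                 exposure = exposure,
                 n = c(exposed = n1, unexposed = n0,
                       unknown = sum(st == "unknown"))),
            class = "strata_fit")
}

# se of log RR backed out of a fitted haplotype; NA when not estimated
se_of <- function(fit, h) fit$se_log_rr[h]

#' Wald test of a relative-risk ratio between two stratum fits
#'
#' For each estimable non-reference haplotype:
#' `log RRR = log RR1 - log RR0`, `se^2 = se1^2 + se0^2` (independent
#' strata), CI `exp(log RRR +/- z se)`, two-sided normal p-value.
#' Haplotypes rare (RR pinned) in either stratum are suppressed with a
#' reason. Lower-level access for scalar inputs is [rrr_from_rr()].
#'
#' @param fit1 `triad_fit` for the exposed stratum.
#' @param fit0 `triad_fit` for the unexposed stratum.
#' @param haplotype optional haplotype label (default: all estimable).
#' @param conf confidence level.
#' @return data.frame of class `gxe_result`: one row per haplotype with
#'   stratum RRs and CIs, frequencies, `rrr`, `rrr_lo`, `rrr_hi`, `p_value`.
#'   Suppressed haplotypes appear with NA estimates and a `note`.
#' @export
rrr_wald <- function(fit1, fit0, haplotype = NULL, conf = 0.95) {
  if (fit1$reference != fit0$reference)
    stop("stratum fits use different reference haplotypes")
  labs <- fit1$haplotypes
  hs <- if (is.null(haplotype)) labs[-fit1$reference] else haplotype
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- lapply(hs, function(lab) {
    h <- match(lab, labs)
    if (is.na(h)) stop("unknown haplotype: ", lab)
    note <- ""
    if (h == fit1$reference) note <- "reference haplotype"
    else if (fit1$rare[h] || fit0$rare[h])
      note <- "rare in at least one stratum"
    else if (is.na(se_of(fit1, h)) || is.na(se_of(fit0, h)))
      note <- "no standard error available"
    if (nzchar(note))
      return(data.frame(haplotype = lab, freq_exposed = fit1$freqs[h],
                        freq_unexposed = fit0$freqs[h],
                        rr_exposed = NA_real_, rr_exp_lo = NA_real_,
                        rr_exp_hi = NA_real_, rr_unexposed = NA_real_,
                        rr_unexp_lo = NA_real_, rr_unexp_hi = NA_real_,
                        rrr = NA_real_, rrr_lo = NA_real_,
                        rrr_hi = NA_real_, p_value = NA_real_,
                        note = note, stringsAsFactors = FALSE))
    l1 <- log(fit1$rr[h]); l0 <- log(fit0$rr[h])
    s1 <- se_of(fit1, h); s0 <- se_of(fit0, h)
    se <- sqrt(s1^2 + s0^2)
    lr <- l1 - l0
    data.frame(haplotype = lab, freq_exposed = fit1$freqs[h],
               freq_unexposed = fit0$freqs[h],
               rr_exposed = exp(l1), rr_exp_lo = exp(l1 - z * s1),
               rr_exp_hi = exp(l1 + z * s1),
               rr_unexposed = exp(l0), rr_unexp_lo = exp(l0 - z * s0),
               rr_unexp_hi = exp(l0 + z * s0),
               rrr = exp(lr), rrr_lo = exp(lr - z * se),
               rrr_hi = exp(lr + z * se),
               p_value = 2 * stats::pnorm(-abs(lr) / se),
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gxe_result", "data.frame")
  out
}

#' Relative-risk ratio from printed stratum estimates
#'
#' Scalar form of the Wald RRR computation, convenient when only published
#' stratum RRs (and their CIs or standard errors) are available.
#'
#' @param rr1,rr0 stratum relative risks (exposed, unexposed).
#' @param se1,se0 standard errors of the log RRs. Alternatively supply
#'   `ci1`/`ci0` as length-2 confidence intervals from which the se is
#'   back-calculated (`log(hi/lo) / (2 z)`).
#' @param ci1,ci0 optional 95% CIs used when `se1`/`se0` are missing.
#' @param conf confidence level of supplied/returned intervals.
#' @return List with `rrr`, `rrr_lo`, `rrr_hi`, `se_log_rrr`, `p_value`.
#' @export
rrr_from_rr <- function(rr1, rr0, se1 = NULL, se0 = NULL,
                        ci1 = NULL, ci0 = NULL, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (is.null(se1)) se1 <- if (is.null(ci1)) NA_real_ else
    log(ci1[2] / ci1[1]) / (2 * z)
  if (is.null(se0)) se0 <- if (is.null(ci0)) NA_real_ else
    log(ci0[2] / ci0[1]) / (2 * z)
  lr <- log(rr1) - log(rr0)
  se <- sqrt(se1^2 + se0^2)
  list(rrr = exp(lr), rrr_lo = exp(lr - z * se), rrr_hi = exp(lr + z * se),
       se_log_rrr = se,
       p_value = if (is.finite(se) && se > 0)
         2 * stats::pnorm(-abs(lr) / se) else NA_real_)
}

#' Sliding windows over a marker map
#'
#' All runs of `k` consecutive markers on the same chromosome, stepping
#' by one marker; no window crosses a chromosome boundary.
#'
#' @param ds a [triad_data()] object.
#' @param k window size in SNPs (k = 1 gives one window per SNP).
#' @return List of [make_window()] objects (empty, with a warning, if no
#'   chromosome holds `k` markers).
#' @export
sliding_windows <- function(ds, k = 1L) {
  stopifnot(k >= 1L)
  m <- ds$markers
  wins <- list()
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    if (length(idx) < k) next
    for (s in seq_len(length(idx) - k + 1L))
      wins[[length(wins) + 1L]] <- make_window(ds, m$snp[idx[s:(s + k - 1L)]])
  }
  if (!length(wins))
    warning("no chromosome carries ", k, " markers; empty window list")
  wins
}

#' Genome-wide GxE scan
#'
#' Runs [fit_strata()] + [rrr_wald()] over sliding windows and assembles one
#' row per (window, haplotype), ranked by p-value. Windows where any stratum
#' fit fails (e.g. all families uninformative) are skipped and counted in
#' attribute `"n_skipped"`.
#'
#' @param ds a [triad_data()] object (post-QC).
#' @param exposures an `exposure_table`.
#' @param exposure exposure column name.
#' @param window_size SNPs per window (default 1).
#' @param options a [model_options()] list.
#' @param fit_all include the unstratified child-effect fit per window
#'   (default TRUE).
#' @param progress print a dot every 50 windows.
#' @return data.frame of class `gxe_scan`: chrom, pos, window, haplotype,
#'   frequencies and RRs per stratum, rrr with CI, p, q (NA until
#'   [add_qvalues()]), and a `top` flag marking each window's lowest-p
#'   haplotype.
#' @export
gxe_scan <- function(ds, exposures, exposure, window_size = 1L,
                     options = model_options(), fit_all = TRUE,
                     progress = FALSE) {
  if (!nrow(ds$markers)) stop("scan refuses to run: no markers after QC")
  wins <- sliding_windows(ds, window_size)
  rows <- vector("list", length(wins))
  n_skipped <- 0L
  for (i in seq_along(wins)) {
    w <- wins[[i]]
    res <- tryCatch(suppressWarnings(
      fit_strata(ds, exposures, exposure, w, options, fit_all = fit_all)),
      error = function(e) NULL)
    if (is.null(res)) { n_skipped <- n_skipped + 1L; next }
    gx <- rrr_wald(res$exposed, res$unexposed)
    gx <- gx[!is.na(gx$p_value), , drop = FALSE]  # suppressed rows dropped
    if (!nrow(gx)) { n_skipped <- n_skipped + 1L; next }
    hidx <- match(gx$haplotype, w$labels)
    rr_all <- if (!is.null(res$all)) res$all$rr[hidx] else NA_real_
    freq_all <- if (!is.null(res$all)) res$all$freqs[hidx] else NA_real_
    rows[[i]] <- data.frame(
      chrom = w$chrom, pos = w$pos,
      window = paste(w$snps, collapse = "-"),
      haplotype = gx$haplotype,
      freq_all = freq_all, freq_unexp = gx$freq_unexposed,
      freq_exp = gx$freq_exposed,
      rr_all = rr_all, rr_unexp = gx$rr_unexposed, rr_exp = gx$rr_exposed,
      rrr = gx$rrr, rrr_lo = gx$rrr_lo, rrr_hi = gx$rrr_hi,
      p = gx$p_value, q = NA_real_,
      top = seq_len(nrow(gx)) ==
        which.min(replace(gx$p_value, is.na(gx$p_value), Inf)),
      stringsAsFactors = FALSE)
    if (progress && i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) stop("scan produced no results")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "exposure") <- exposure
  class(out) <- c("gxe_scan", "data.frame")
  out
}

#' Write a scan table as TSV
#' @param scan a `gxe_scan`.
#' @param path output path.
#' @return Invisibly, `scan`.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(scan)
}

#' Pairwise linkage disequilibrium from two-SNP haplotype frequencies
#'
#' @param two_snp_freqs length-4 frequency vector in window haplotype order
#'   `(11, 21, 12, 22)` where the first digit is the allele at SNP 1 — i.e.
#'   `(AB, aB, Ab, ab)` with A/B the first alleles. Any ordering works as
#'   long as it matches [make_window()] haplotype order; D and r^2 are
#'   symmetric in allele labels, D' uses the sign-appropriate bound.
#' @return List with `d`, `d_prime`, `r_squared`, `monomorphic` (flag; LD is
#'   undefined and returned as NA when a locus is monomorphic).
#' @export
ld_pairwise <- function(two_snp_freqs) {
  p <- two_snp_freqs
  stopifnot(length(p) == 4L, all(p >= 0))
  p <- p / sum(p)
  # make_window bit order: hap i-1 bits (snp1, snp2) little-endian
  pA <- p[1] + p[3]  # allele 1 at SNP 1 (bit 0)
  pB <- p[1] + p[2]  # allele 1 at SNP 2 (bit 0)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(d = NA_real_, d_prime = NA_real_, r_squared = NA_real_,
                monomorphic = TRUE))
  D <- p[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(d = D, d_prime = if (dmax > 0) abs(D) / dmax else 0,
       r_squared = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       monomorphic = FALSE)
}
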
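# The retrospective log-linear likelihood for case-parent triads/dyads over
# a window of tightly linked SNPs.
#
# Model. Within a stratum, parental haplotypes are drawn under HWE / random
# mating from frequencies p_h; each parent transmits one of its two
# haplotypes with probability 1/2; the child is ascertained as affected, and
# the affection probability is multiplicative in the transmitted haplotypes:
# risk(child) = prod_h rr_h^{copies_h}. Conditional on ascertainment, an
# ordered phased configuration (m1, m2, f1, f2, transmitted pair (t_m, t_f))
# has probability
#     p_{m1} p_{m2} p_{f1} p_{f2} * 1/4 * rr_{t_m} rr_{t_f} / mu,
#     mu = (sum_h p_h rr_h)^2.
# Unknown phase, missing genotypes and missing parents are handled by
# summing configurations compatible with what was observed; the observed-data
# log-likelihood is the sum over families of the log of that inner sum.
#
# The configuration sum factorizes by parent: with M the set of ordered
# parental haplotype pairs compatible with a parent's observed genotypes,
# A(t) = sum_{(h1,h2) in M} p_{h1} p_{h2} * 1/2 * #{j : h_j = t}
#      = p_t * (M p)_t            (M symmetric 0/1 compatibility matrix),
# the per-family likelihood is
#     L = (1/mu) * sum_{(t_m,t_f) in C} rr_{t_m} rr_{t_f} A_m(t_m) A_f(t_f)
# with C the child's compatibility matrix. A missing parent has M = all
# pairs, giving A(t) = p_t. Tests verify this against brute-force
# enumeration of the full configuration space.

#' Define a haplotype window
#'
#' @param ds a [triad_data()] object.
#' @param snps character vector of marker names; must be contiguous on one
#'   chromosome (no recombination is modelled within a window).
#' @return An object of class `triad_window` with the 2^k haplotype alphabet.
#' @export
make_window <- function(ds, snps) {
  idx <- match(snps, ds$markers$snp)
  if (anyNA(idx)) stop("unknown marker(s): ",
                       paste(snps[is.na(idx)], collapse = ", "))
  k <- length(idx)
  if (k < 1L) stop("a window needs at least one SNP")
  if (length(unique(ds$markers$chrom[idx])) != 1L)
    stop("window SNPs must lie on one chromosome")
  if (k > 1L && any(diff(idx) != 1L))
    stop("window SNPs must be contiguous in the marker map")
  H <- 2L^k
  bits <- matrix(0L, H, k)  # allele-2 indicator per haplotype x SNP
  for (s in seq_len(k)) bits[, s] <- bitwAnd(seq_len(H) - 1L,
                                             bitwShiftL(1L, s - 1L)) > 0L
  lab1 <- ds$markers$a1[idx]; lab2 <- ds$markers$a2[idx]
  lab1[is.na(lab1)] <- "1"; lab2[is.na(lab2)] <- "2"
  labels <- apply(bits, 1, function(b)
    paste(ifelse(b == 1L, lab2, lab1), collapse = "-"))
  structure(list(snps = snps, idx = idx, k = k, H = H, bits = bits,
                 labels = labels, chrom = ds$markers$chrom[idx[1]],
                 pos = ds$markers$pos[idx[1]]),
            class = "triad_window")
}

#' @export
print.triad_window <- function(x, ...) {
  cat("triad_window: ", paste(x$snps, collapse = "-"), " (chr", x$chrom,
      ", ", x$H, " haplotypes)\n", sep = "")
  invisible(x)
}

#' Child relative risk under the multiplicative dose-response model
#'
#' Two copies of a haplotype with relative risk RR confer RR x RR.
#'
#' @param copies integer vector of haplotype copies (must sum to 2).
#' @param rr per-haplotype relative risks.
#' @return The child's relative risk, `prod(rr^copies)`.
#' @export
child_risk <- function(copies, rr) {
  if (sum(copies) != 2L) stop("a child carries exactly 2 haplotypes")
  prod(rr^copies)
}

# H x H symmetric compatibility matrix for one member's observed genotypes
# g (vector of allele-2 doses, NA = untyped; NULL = member absent).
member_compat <- function(g, bits) {
  H <- nrow(bits)
  M <- matrix(TRUE, H, H)
  if (is.null(g)) return(M)
  for (s in seq_along(g)) {
    if (is.na(g[s])) next
    M <- M & (outer(bits[, s], bits[, s], "+") == g[s])
  }
  M
}

# Collapse a dataset x window into genotype patterns with counts.
# Families whose child is untyped at every window SNP are dropped (no
# information); families with no compatible configuration (residual
# Mendelian inconsistency) are excluded and counted.
window_patterns <- function(ds, window, fi = family_index(ds),
                            warn_dropped = TRUE) {
  k <- window$k
  gsub_ <- function(i) {
    if (is.na(i)) return(NULL)
    ds$geno[i, window$idx]
  }
  key_of <- function(g) {
    if (is.null(g)) return("X")
    paste(ifelse(is.na(g), "N", g), collapse = "")
  }
  nfam <- length(fi$family_id)
  keys <- character(nfam); mk <- character(nfam)
  fk <- character(nfam); ck <- character(nfam)
  drop_noinfo <- logical(nfam)
  for (i in seq_len(nfam)) {
    gm <- gsub_(fi$mother[i]); gf <- gsub_(fi$father[i])
    gc <- gsub_(fi$child[i])
    if (is.null(gc) || all(is.na(gc))) { drop_noinfo[i] <- TRUE; next }
    mk[i] <- key_of(gm); fk[i] <- key_of(gf); ck[i] <- key_of(gc)
    keys[i] <- paste(mk[i], fk[i], ck[i], sep = "|")
  }
  if (any(drop_noinfo) && warn_dropped)
    warning(sum(drop_noinfo), " family(ies) with an untyped child dropped ",
            "from window ", paste(window$snps, collapse = "-"))
  use <- !drop_noinfo
  ukeys <- unique(keys[use])
  # compatibility matrices per distinct member genotype string
  mstr <- unique(c(mk[use], fk[use], ck[use]))
  decode <- function(s) {
    if (s == "X") return(NULL)
    v <- strsplit(s, "")[[1]]
    v[v == "N"] <- NA
    as.integer(v)
  }
  mats <- lapply(mstr, function(s) member_compat(decode(s), window$bits))
  names(mats) <- mstr
  pat <- data.frame(key = ukeys, stringsAsFactors = FALSE)
  first <- match(ukeys, keys)
  pat$m <- mk[first]; pat$f <- fk[first]; pat$c <- ck[first]
  pat$n <- as.vector(table(factor(keys[use], levels = ukeys)))
  # feasibility: exists (tm, tf) in C with mother able to carry+transmit tm
  feasible <- vapply(seq_len(nrow(pat)), function(i) {
    Tm <- apply(mats[[pat$m[i]]], 1, any)
    Tf <- apply(mats[[pat$f[i]]], 1, any)
    any(mats[[pat$c[i]]] & outer(Tm, Tf))
  }, logical(1))
  n_incompatible <- sum(pat$n[!feasible])
  excluded <- fi$family_id[use][keys[use] %in% pat$key[!feasible]]
  pat <- pat[feasible, , drop = FALSE]
  list(pat = pat, mats = mats, H = window$H,
       n_families = sum(pat$n), n_dropped = sum(drop_noinfo),
       n_incompatible = n_incompatible, excluded = excluded)
}

# Observed-data log-likelihood from a pattern structure.
patterns_loglik <- function(wp, p, rr) {
  mu <- sum(p * rr)^2
  parent_keys <- unique(c(wp$pat$m, wp$pat$f))
  A <- lapply(wp$mats[parent_keys],
              function(M) rr * (p * as.vector(M %*% p)))
  mi <- match(wp$pat$m, parent_keys)
  fi <- match(wp$pat$f, parent_keys)
  ll <- 0
  for (i in seq_len(nrow(wp$pat))) {
    L <- as.numeric(crossprod(A[[mi[i]]],
                              wp$mats[[wp$pat$c[i]]] %*% A[[fi[i]]])) / mu
    if (!is.finite(L) || L <= 0) return(-Inf)
    ll <- ll + wp$pat$n[i] * log(L)
  }
  ll
}

#' Enumerate phased configurations compatible with a family's genotypes
#'
#' Configurations are unordered parental haplotype pairs together with the
#' transmitted pair; `multiplicity` counts the ordered representations
#' (2 per heterozygous parental pair) so that summing
#' [config_probability()] over the rows gives the family's likelihood
#' contribution.
#'
#' @param family_calls list with elements `mother`, `father`, `child`: each
#'   an integer vector of allele-2 doses over the window SNPs (NA = untyped),
#'   or `NULL` for an absent parent (child required).
#' @param window a [make_window()] object.
#' @return data.frame with haplotype indices `m1`, `m2`, `f1`, `f2`
#'   (pairs sorted), transmitted `tm`, `tf`, and `multiplicity`.
#' @export
enumerate_compatible <- function(family_calls, window) {
  if (is.null(family_calls$child) || all(is.na(family_calls$child)))
    stop("the child must be genotyped at some window SNP")
  H <- window$H
  Mm <- member_compat(family_calls$mother, window$bits)
  Mf <- member_compat(family_calls$father, window$bits)
  Mc <- member_compat(family_calls$child, window$bits)
  rows <- list()
  for (m1 in 1:H) for (m2 in m1:H) {
    if (!Mm[m1, m2]) next
    for (f1 in 1:H) for (f2 in f1:H) {
      if (!Mf[f1, f2]) next
      for (tm in unique(c(m1, m2))) for (tf in unique(c(f1, f2))) {
        if (!Mc[tm, tf]) next
        # each (unordered pair, transmitted) group collects exactly 2
        # ordered representations per parent: the two orderings for a
        # heterozygous pair, the two transmission positions for a
        # homozygous one
        rows[[length(rows) + 1L]] <- c(m1, m2, f1, f2, tm, tf, 4L)
      }
    }
  }
  if (!length(rows))
    return(data.frame(m1 = integer(), m2 = integer(), f1 = integer(),
                      f2 = integer(), tm = integer(), tf = integer(),
                      multiplicity = integer()))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("m1", "m2", "f1", "f2", "tm", "tf", "multiplicity")
  out
}

#' Probability of one phased triad configuration
#'
#' For an ordered configuration the probability is
#' `p[m1] p[m2] p[f1] p[f2] / 4 * rr[tm] rr[tf] / mu` with
#' `mu = sum(p * rr)^2`; `multiplicity` scales unordered rows from
#' [enumerate_compatible()].
#'
#' @param config a one-row data.frame (or list) with `m1`, `m2`, `f1`, `f2`,
#'   `tm`, `tf` and optionally `multiplicity` (default 1). Vectorized over
#'   rows of a data.frame.
#' @param freqs haplotype frequency vector (sums to 1).
#' @param rr per-haplotype relative risks.
#' @return Numeric vector of configuration probabilities.
#' @export
config_probability <- function(config, freqs, rr) {
  if (!all(is.finite(freqs)) || !all(is.finite(rr)))
    stop("non-finite parameters")
  mult <- if (!is.null(config$multiplicity)) config$multiplicity else 1
  mu <- sum(freqs * rr)^2
  mult * freqs[config$m1] * freqs[config$m2] *
    freqs[config$f1] * freqs[config$f2] / 4 *
    rr[config$tm] * rr[config$tf] / mu
}

#' Observed-data log-likelihood of a dataset over a window
#'
#' Sums, per family, the log of the total probability of all phased
#' configurations compatible with the observed genotypes (handling dyads,
#' missing calls and unknown phase). Families with an untyped child are
#' dropped with a warning; Mendelian-inconsistent families are excluded.
#'
#' @param ds a [triad_data()] object.
#' @param window a [make_window()] object.
#' @param freqs haplotype frequency vector over the window alphabet.
#' @param rr per-haplotype relative risks.
#' @return The log-likelihood (scalar).
#' @export
observed_loglik <- function(ds, window, freqs, rr) {
  wp <- window_patterns(ds, window)
  patterns_loglik(wp, freqs, rr)
}

#' Model options for triad likelihood fitting
#'
#' @param rare_haplotype_min haplotypes with fitted frequency below this have
#'   their RR fixed at 1 and carry no standard error.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter optimizer iteration cap.
#' @param n_starts number of multistart initializations (deterministic
#'   jitters) guarding against local optima in wide windows.
#' @param log_rr_bound cap on |log RR|; an estimate at the bound is flagged
#'   as separated.
#' @return List of class `model_options`.
#' @export
model_options <- function(rare_haplotype_min = 0.01, tol = 1e-8,
                          max_iter = 500L, n_starts = 3L,
                          log_rr_bound = log(1000)) {
  stopifnot(tol > 0, rare_haplotype_min >= 0, rare_haplotype_min < 0.5)
  structure(list(rare_haplotype_min = rare_haplotype_min, tol = tol,
                 max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts),
                 log_rr_bound = log_rr_bound), class = "model_options")
}

# softmax frequencies with the reference coordinate pinned at 0
softmax_p <- function(a_free, ref, H) {
  a <- numeric(H)
  a[-ref] <- a_free
  e <- exp(a - max(a))
  e / sum(e)
}

# Maximize the pattern log-likelihood. `estimate_rr` selects haplotypes with
# a free log-RR; others are pinned at rr = 1.
fit_patterns <- function(wp, ref, estimate_rr, opts, p_init = NULL) {
  H <- wp$H
  a_bound <- 15
  b_bound <- opts$log_rr_bound
  nb <- sum(estimate_rr)
  npar_a <- H - 1L
  if (is.null(p_init)) p_init <- rep(1 / H, H)
  a0 <- log(pmax(p_init, 1e-6))
  a0 <- pmin(pmax(a0 - a0[ref], -a_bound), a_bound)[-ref]
  par0 <- c(a0, rep(0, nb))
  negll <- function(par) {
    p <- softmax_p(par[seq_len(npar_a)], ref, H)
    rr <- rep(1, H)
    if (nb) rr[estimate_rr] <- exp(par[npar_a + seq_len(nb)])
    -patterns_loglik(wp, p, rr)
  }
  lower <- c(rep(-a_bound, npar_a), rep(-b_bound, nb))
  upper <- c(rep(a_bound, npar_a), rep(b_bound, nb))
  # deterministic multistart jitters (no RNG use: fits run inside seeded
  # simulations and must not perturb the global stream); a 2-haplotype
  # window has a well-behaved 2-parameter surface, one start suffices
  n_starts <- if (H == 2L) 1L else opts$n_starts
  jit <- function(s) 0.75 * s * rep_len(c(1, -1, 0.5, -0.5), length(par0))
  starts <- lapply(seq_len(n_starts) - 1L, function(s) {
    pmin(pmax(par0 + jit(s), lower + 1e-6), upper - 1e-6)
  })
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = opts$max_iter,
                                  factr = opts$tol / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("likelihood optimization failed")
  p_hat <- softmax_p(best$par[seq_len(npar_a)], ref, H)
  rr_hat <- rep(1, H)
  if (nb) rr_hat[estimate_rr] <- exp(best$par[npar_a + seq_len(nb)])
  separated <- nb > 0 &&
    any(abs(best$par[npar_a + seq_len(nb)]) >= b_bound - 1e-6)
  list(par = best$par, p = p_hat, rr = rr_hat, loglik = -best$value,
       converged = best$convergence == 0, separated = separated,
       negll = negll, npar_a = npar_a, nb = nb)
}

#' Fit the triad relative-risk model over a window
#'
#' Maximum likelihood over haplotype frequencies and per-haplotype child
#' relative risks (reference haplotype fixed at RR = 1), using the
#' observed-data likelihood so unknown phase, missing genotypes and missing
#' parents are integrated out. Standard errors come from the observed
#' information (numerical Hessian) at the optimum.
#'
#' @param ds a [triad_data()] object (post-QC).
#' @param window a [make_window()] object.
#' @param options a [model_options()] list.
#' @param reference index of the reference haplotype; default the most
#'   frequent under a null (all RR = 1) pre-fit. Pass the pooled-fit
#'   reference when fitting exposure strata so RRs are comparable.
#' @return An object of class `triad_fit`: `freqs`, `rr`, `se_log_rr`,
#'   `vcov_log` (log-RR block), `loglik`, `n_families`, `converged`, plus
#'   bookkeeping (`reference`, `rare`, `separated`, `n_dropped`,
#'   `n_incompatible`).
#' @export
fit_triads <- function(ds, window, options = model_options(),
                       reference = NULL) {
  wp <- window_patterns(ds, window)
  if (!nrow(wp$pat) || wp$n_families < 1L)
    stop("no informative families in window ",
         paste(window$snps, collapse = "-"))
  H <- wp$H
  # stage 1: frequencies under the null, for reference/rare determination
  ref0 <- if (is.null(reference)) 1L else reference
  null_fit <- fit_patterns(wp, ref0, rep(FALSE, H), options)
  if (is.null(reference)) {
    reference <- which.max(null_fit$p)
    if (reference != ref0)
      null_fit <- fit_patterns(wp, reference, rep(FALSE, H), options,
                               p_init = null_fit$p)
  }
  rare <- null_fit$p < options$rare_haplotype_min
  rare[reference] <- FALSE
  estimate_rr <- !rare & seq_len(H) != reference
  fit <- fit_patterns(wp, reference, estimate_rr, options,
                      p_init = null_fit$p)
  # observed information at the optimum
  se <- rep(NA_real_, H)
  vcov_log <- matrix(NA_real_, sum(estimate_rr), sum(estimate_rr))
  hess_ok <- FALSE
  if (fit$nb) {
    hess <- tryCatch(stats::optimHess(fit$par, fit$negll),
                     error = function(e) NULL)
    if (!is.null(hess)) {
      vc <- tryCatch(solve(hess), error = function(e) NULL)
      if (!is.null(vc)) {
        bi <- fit$npar_a + seq_len(fit$nb)
        vcov_log <- vc[bi, bi, drop = FALSE]
        v <- diag(vcov_log)
        if (all(is.finite(v)) && all(v > 0)) {
          se[estimate_rr] <- sqrt(v)
          hess_ok <- TRUE
        }
      }
    }
  }
  rownames(vcov_log) <- colnames(vcov_log) <- window$labels[estimate_rr]
  structure(list(
    window = window,
    haplotypes = window$labels,
    freqs = fit$p, rr = fit$rr, se_log_rr = se, vcov_log = vcov_log,
    loglik = fit$loglik, n_families = wp$n_families,
    converged = fit$converged && (fit$nb == 0 || hess_ok),
    separated = fit$separated,
    reference = reference, rare = rare,
    n_dropped = wp$n_dropped, n_incompatible = wp$n_incompatible,
    options = options), class = "triad_fit")
}

#' @export
print.triad_fit <- function(x, ...) {
  cat("triad_fit: ", paste(x$window$snps, collapse = "-"), ", ",
      x$n_families, " families, loglik ", format(x$loglik, digits = 8),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  ci <- exp(log(x$rr) %o% c(1, 1) +
              outer(x$se_log_rr, c(-1, 1) * stats::qnorm(0.975)))
  tab <- data.frame(haplotype = x$haplotypes,
                    freq = round(x$freqs, 4), rr = round(x$rr, 4),
                    ci_lo = round(ci[, 1], 4), ci_hi = round(ci[, 2], 4),
                    note = ifelse(seq_along(x$rr) == x$reference, "ref",
                                  ifelse(x$rare, "rare", "")))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Tabulate a triad fit
#'
#' @param fit a `triad_fit`.
#' @param conf confidence level for the RR intervals.
#' @return data.frame with columns window, haplotype, freq, rr, ci_lo,
#'   ci_hi, p (two-sided Wald on log RR; NA for reference/rare haplotypes).
#' @export
fit_table <- function(fit, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lrr <- log(fit$rr)
  p <- 2 * stats::pnorm(-abs(lrr) / fit$se_log_rr)
  data.frame(window = paste(fit$window$snps, collapse = "-"),
             haplotype = fit$haplotypes, freq = fit$freqs, rr = fit$rr,
             ci_lo = exp(lrr - z * fit$se_log_rr),
             ci_hi = exp(lrr + z * fit$se_log_rr),
             p = p, stringsAsFactors = FALSE)
}
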
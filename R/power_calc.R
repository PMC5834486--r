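# Asymptotic power of the single-SNP Wald RRR test, from the expected
# information of the triad likelihood; validated against Monte-Carlo power
# in the test suite.

#' Power scenario for the GxE Wald test
#'
#' @param n_total total number of triads across strata.
#' @param exposed_fraction fraction of exposed mothers (in (0, 1)).
#' @param maf risk-allele frequency; the minor allele is taken as the risk
#'   allele, so values in (0, 0.5].
#' @param rr_unexposed,rr_exposed per-allele child relative risks per
#'   stratum; RRR = rr_exposed / rr_unexposed.
#' @param alpha nominal two-sided significance level.
#' @return List of class `power_scenario`.
#' @export
power_scenario <- function(n_total, exposed_fraction, maf,
                           rr_unexposed = 1, rr_exposed = 1,
                           alpha = 0.05) {
  stopifnot(n_total > 0, exposed_fraction > 0, exposed_fraction < 1,
            maf > 0, maf <= 0.5, rr_unexposed > 0, rr_exposed > 0,
            alpha > 0, alpha < 1)
  structure(list(n_total = n_total, exposed_fraction = exposed_fraction,
                 maf = maf, rr_unexposed = rr_unexposed,
                 rr_exposed = rr_exposed, alpha = alpha),
            class = "power_scenario")
}

#' Triad genotype-category probabilities under ascertainment
#'
#' The 15 (mother, father, child) single-SNP genotype categories, coded as
#' risk-allele doses. P(M, F, C) = HWE mating probabilities x Mendelian
#' transmission x rr^C / mu with mu = ((1 - p) + p rr)^2 — the child's
#' affection tilts the distribution by its multiplicative risk.
#'
#' @param p risk-allele frequency in (0, 1).
#' @param rr per-allele child relative risk.
#' @return data.frame with `mother`, `father`, `child` doses and `prob`
#'   (15 rows summing to 1).
#' @export
triad_category_probs <- function(p, rr) {
  stopifnot(p > 0, p < 1, rr > 0)
  pg <- stats::dbinom(0:2, 2, p)
  # P(transmit 1 copy | parental dose g) = g/2
  rows <- list()
  for (gm in 0:2) for (gf in 0:2) {
    pt_m <- c(1 - gm / 2, gm / 2)
    pt_f <- c(1 - gf / 2, gf / 2)
    pc <- numeric(3)
    for (tm in 0:1) for (tf in 0:1)
      pc[tm + tf + 1] <- pc[tm + tf + 1] + pt_m[tm + 1] * pt_f[tf + 1]
    for (gc in 0:2) if (pc[gc + 1] > 0)
      rows[[length(rows) + 1L]] <-
        data.frame(mother = gm, father = gf, child = gc,
                   prob = pg[gm + 1] * pg[gf + 1] * pc[gc + 1] * rr^gc)
  }
  out <- do.call(rbind, rows)
  out$prob <- out$prob / ((1 - p) + p * rr)^2
  rownames(out) <- NULL
  out
}

# log category probabilities as a function of (p, b = log rr), aligned with
# the 15-row category order of triad_category_probs
log_category_probs <- function(theta) {
  log(triad_category_probs(theta[1], exp(theta[2]))$prob)
}

#' Per-family Fisher information for log RR
#'
#' Expected information of the single-SNP triad likelihood at (p, log rr),
#' computed from numerical second derivatives of the log category
#' probabilities. The `"joint"` version (default) accounts for the allele
#' frequency being estimated: the 2x2 expected information over
#' (p, log rr) is inverted and the log-RR block extracted. The `"known_p"`
#' version conditions on a known frequency and is never smaller.
#'
#' @param p risk-allele frequency in (0, 1).
#' @param rr per-allele relative risk.
#' @param type `"joint"` or `"known_p"`.
#' @param h finite-difference step.
#' @return Positive scalar: information per family for log RR.
#' @export
info_log_rr <- function(p, rr, type = c("joint", "known_p"), h = 1e-4) {
  type <- match.arg(type)
  if (p <= 2 * h || p >= 1 - 2 * h)
    stop("allele frequency too close to the boundary")
  theta0 <- c(p, log(rr))
  probs <- triad_category_probs(p, rr)$prob
  nc <- length(probs)
  # expected information J = sum_c P_c * (-hessian of log P_c)
  J <- matrix(0, 2, 2)
  f <- log_category_probs
  for (a in 1:2) {
    ea <- c(0, 0); ea[a] <- h
    J[a, a] <- sum(probs * -(f(theta0 + ea) - 2 * f(theta0) +
                               f(theta0 - ea)) / h^2)
  }
  eab <- (f(theta0 + c(h, h)) - f(theta0 + c(h, -h)) -
            f(theta0 + c(-h, h)) + f(theta0 + c(-h, -h))) / (4 * h^2)
  J[1, 2] <- J[2, 1] <- sum(probs * -eab)
  if (type == "known_p") return(J[2, 2])
  v <- solve(J)[2, 2]
  if (v <= 0) stop("information matrix not positive definite")
  1 / v
}

#' Asymptotic power of the Wald RRR test
#'
#' Per-stratum information is evaluated under that stratum's alternative
#' relative risk; `var(log RRR) = 1/(n1 I1) + 1/(n0 I0)`,
#' `z = |log RRR| / sd`, and power is
#' `pnorm(z - z_crit) + pnorm(-z - z_crit)` with
#' `z_crit = qnorm(1 - alpha/2)`. At RRR = 1 the power equals alpha exactly.
#'
#' @param sc a [power_scenario()].
#' @return Power in (0, 1).
#' @export
asymptotic_power <- function(sc) {
  stopifnot(inherits(sc, "power_scenario"))
  n1 <- sc$n_total * sc$exposed_fraction
  n0 <- sc$n_total - n1
  if (n1 <= 0 || n0 <= 0) stop("degenerate stratum size")
  I1 <- info_log_rr(sc$maf, sc$rr_exposed)
  I0 <- info_log_rr(sc$maf, sc$rr_unexposed)
  sdv <- sqrt(1 / (n1 * I1) + 1 / (n0 * I0))
  z <- abs(log(sc$rr_exposed / sc$rr_unexposed)) / sdv
  zc <- stats::qnorm(1 - sc$alpha / 2)
  stats::pnorm(z - zc) + stats::pnorm(-z - zc)
}

#' Power curve over a grid of relative-risk ratios
#'
#' The relative risk in one stratum is held at `rr_unexposed` while the
#' exposed-stratum risk sweeps `rrr_grid * rr_unexposed`.
#'
#' @param n_total,exposed_fraction,maf,alpha as in [power_scenario()].
#' @param rrr_grid RRR values to evaluate.
#' @param rr_unexposed baseline stratum relative risk (default 1).
#' @return data.frame with `rrr` and `power`.
#' @export
power_curve <- function(n_total, exposed_fraction, maf,
                        rrr_grid = seq(1, 2, by = 0.1),
                        rr_unexposed = 1, alpha = 0.05) {
  data.frame(rrr = rrr_grid, power = vapply(rrr_grid, function(r) {
    asymptotic_power(power_scenario(n_total, exposed_fraction, maf,
                                    rr_unexposed = rr_unexposed,
                                    rr_exposed = r * rr_unexposed,
                                    alpha = alpha))
  }, 0))
}
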
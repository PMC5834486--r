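# Shared oracles and fixture builders. These stay independent of the code
# paths they check: the likelihood oracle enumerates the full ordered
# configuration space directly from the model definition.

# Build a triad_data from per-member genotype-dose matrices (n x M).
# NA rows in gm/gf drop that parent (dyad); gm/gf may be NULL entirely.
build_triads <- function(gc, gm = NULL, gf = NULL, chrom = NULL) {
  n <- nrow(gc); M <- ncol(gc)
  if (is.null(chrom)) chrom <- rep(1L, M)
  fam <- sprintf("T%04d", seq_len(n))
  rows <- list(); geno <- list()
  for (i in seq_len(n)) {
    if (!is.null(gm)) {
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = fam[i], person_id = paste0(fam[i], "_M"),
        role = "mother", sex = 2L, phenotype = 1L,
        father_id = "0", mother_id = "0", stringsAsFactors = FALSE)
      geno[[length(geno) + 1L]] <- gm[i, ]
    }
    if (!is.null(gf)) {
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = fam[i], person_id = paste0(fam[i], "_F"),
        role = "father", sex = 1L, phenotype = 1L,
        father_id = "0", mother_id = "0", stringsAsFactors = FALSE)
      geno[[length(geno) + 1L]] <- gf[i, ]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = fam[i], person_id = paste0(fam[i], "_C"),
      role = "child", sex = 1L, phenotype = 2L,
      father_id = paste0(fam[i], "_F"), mother_id = paste0(fam[i], "_M"),
      stringsAsFactors = FALSE)
    geno[[length(geno) + 1L]] <- gc[i, ]
  }
  markers <- data.frame(chrom = chrom, snp = sprintf("s%d", seq_len(M)),
                        cm = "0", pos = 10000L * seq_len(M),
                        a1 = "1", a2 = "2", stringsAsFactors = FALSE)
  g <- do.call(rbind, geno)
  storage.mode(g) <- "integer"
  triad_data(do.call(rbind, rows), markers, g)
}

# Brute-force observed-data log-likelihood: enumerate every ordered
# configuration (m1, m2, f1, f2, transmission positions) over H^4 * 4.
brute_loglik <- function(ds, w, p, r) {
  fi <- tapply(seq_len(nrow(ds$persons)), ds$persons$family_id, identity)
  H <- w$H
  bits <- w$bits
  compat <- function(g, h1, h2) {
    if (is.null(g)) return(TRUE)
    all(is.na(g) | (bits[h1, ] + bits[h2, ]) == g)
  }
  mu <- sum(p * r)^2
  ll <- 0
  for (rows in fi) {
    roles <- ds$persons$role[rows]
    g_of <- function(role) {
      i <- rows[roles == role]
      if (!length(i)) NULL else ds$geno[i, w$idx]
    }
    gm <- g_of("mother"); gf <- g_of("father"); gc <- g_of("child")
    if (is.null(gc) || all(is.na(gc))) next
    L <- 0
    for (m1 in 1:H) for (m2 in 1:H) {
      if (!compat(gm, m1, m2)) next
      for (f1 in 1:H) for (f2 in 1:H) {
        if (!compat(gf, f1, f2)) next
        for (jm in 1:2) for (jf in 1:2) {
          tm <- c(m1, m2)[jm]; tf <- c(f1, f2)[jf]
          if (compat(gc, tm, tf))
            L <- L + p[m1] * p[m2] * p[f1] * p[f2] / 4 *
              r[tm] * r[tf] / mu
        }
      }
    }
    if (L > 0) ll <- ll + log(L)
  }
  ll
}

# Minimal triad_fit stand-ins for Wald-test unit checks.
fake_fit <- function(rr, se, freqs = NULL, reference = 1L) {
  H <- length(rr)
  structure(list(haplotypes = as.character(seq_len(H)),
                 freqs = if (is.null(freqs)) rep(1 / H, H) else freqs,
                 rr = rr, se_log_rr = se, reference = reference,
                 rare = rep(FALSE, H)), class = "triad_fit")
}

# all permutations of a short vector, written out by recursion
combinat_perms <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], combinat_perms(x[-i])))
  out
}
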
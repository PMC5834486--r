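# Hardy-Weinberg testing, per-SNP statistics, and the pruning cascade.

test_that("hwe_chi2 matches hand arithmetic and is relabel-symmetric", {
  r <- hwe_chi2(25, 50, 25)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # freq(A) = 0.4 -> expected (16, 48, 36)
  r <- hwe_chi2(30, 20, 50)
  expect_equal(r$statistic,
               (30 - 16)^2 / 16 + (20 - 48)^2 / 48 + (50 - 36)^2 / 36,
               tolerance = 1e-12)
  expect_equal(r$statistic, 34.02777, tolerance = 1e-5)

  for (cnt in list(c(3, 5, 9), c(12, 1, 2), c(0, 7, 3))) {
    expect_equal(hwe_chi2(cnt[1], cnt[2], cnt[3])$statistic,
                 hwe_chi2(cnt[3], cnt[2], cnt[1])$statistic)
  }
  mono <- hwe_chi2(10, 0, 0)
  expect_true(mono$monomorphic)
  expect_equal(mono$p_value, 1)
})

test_that("hwe_chi2 agrees with an independent oracle on all triples", {
  # independent recomputation from first principles
  oracle <- function(a, b, c) {
    n <- a + b + c
    p <- (2 * a + b) / (2 * n)
    if (p %in% c(0, 1)) return(0)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    sum((c(a, b, c) - e)^2 / e)
  }
  for (tot in c(2L, 5L, 11L, 30L)) {
    for (a in 0:tot) for (b in 0:(tot - a)) {
      cc <- tot - a - b
      expect_equal(hwe_chi2(a, b, cc)$statistic, oracle(a, b, cc),
                   tolerance = 1e-10)
    }
  }
})

test_that("snp_stats computes missingness, founder MAF and Mendel rates", {
  # 4 triads, everyone heterozygous at SNP 1; SNP 2 plants one impossible
  # transmission (mother 0, father 0, child 2)
  gm <- cbind(rep(1L, 4), c(0L, 1L, 1L, 1L))
  gf <- cbind(rep(1L, 4), c(0L, 1L, 1L, 1L))
  gc <- cbind(rep(1L, 4), c(2L, 1L, 1L, 1L))
  ds <- build_triads(gc, gm, gf)
  st <- snp_stats(ds)
  expect_equal(st$maf[1], 0.5)
  expect_equal(st$missing_fraction[1], 0)
  expect_equal(st$mendel_rate[1], 0)
  expect_equal(st$mendel_rate[2], 1 / 4)
})

test_that("vectorized Mendel check equals brute-force transmission search", {
  # oracle: a family is consistent iff some (tm, tf) transmission exists
  brute <- function(m, f, c) {
    if (is.na(c)) return(FALSE)
    tm <- if (is.na(m)) 0:1 else switch(m + 1L, 0L, 0:1, 1L)
    tf <- if (is.na(f)) 0:1 else switch(f + 1L, 0L, 0:1, 1L)
    !any(outer(tm, tf, "+") == c)
  }
  sim <- simulate_study(sim_config(n_families = 200, n_null_snps = 5,
                                   genotype_error_rate = 0.02,
                                   dyad_fraction = 0.2, seed = 21))
  ds <- sim$dataset
  st <- snp_stats(ds)
  fi <- triadscan:::family_index(ds)
  for (j in seq_len(nrow(ds$markers))) {
    g <- function(ii) ifelse(is.na(ii), NA_integer_, ds$geno[ii, j])
    manual <- mean(mapply(brute, g(fi$mother), g(fi$father), g(fi$child)))
    expect_equal(st$mendel_rate[j], manual)
  }
  expect_true(any(st$mendel_rate > 0))  # 2% flips must surface somewhere
})

test_that("clean simulated data passes default QC untouched", {
  sim <- simulate_study(sim_config(n_families = 300, n_null_snps = 8,
                                   null_maf = 0.3, dyad_fraction = 0,
                                   seed = 31))
  res <- apply_qc(sim$dataset)
  expect_equal(res$report$snps_removed, 0L)
  expect_equal(res$report$individuals_removed, 0L)
  expect_equal(res$dataset$geno, sim$dataset$geno)
})

test_that("planted criterion failures are counted exactly, union semantics", {
  n <- 100L
  # SNP1: clean, founder freq 0.3, near-HWE genotype mix.
  # SNP2: fails MAF only (founder freq 0.05 carried by het mothers; the
  #       het excess at such a low frequency is far from HWE rejection).
  # SNP3: fails both MAF and HWE (freq 0.05 carried entirely by
  #       hom-variant mothers: no hets at all).
  m1 <- rep(c(2L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), n / 10)
  f1 <- rep(c(0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 2L), n / 10)
  c1 <- (m1 + f1) %/% 2L
  m2 <- rep(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), n / 10)
  m3 <- rep(c(2L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), n / 10)
  c3 <- rep(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), n / 10)
  gm <- cbind(m1, m2, m3)
  gf <- cbind(f1, matrix(0L, n, 2))
  gc <- cbind(c1, matrix(0L, n, 1), c3)
  ds <- build_triads(gc, gm, gf)
  st <- snp_stats(ds)
  expect_true(st$maf[1] > 0.05 && st$hwe_p[1] > 0.001)
  expect_true(st$maf[2] <= 0.05 && st$hwe_p[2] > 0.001)
  expect_true(st$maf[3] <= 0.05 && st$hwe_p[3] < 0.001)
  res <- apply_qc(ds)
  expect_equal(res$report$failed_frequency, 2L)
  expect_equal(res$report$failed_hwe, 1L)
  # union: 2 SNPs removed although 3 criterion hits were counted
  expect_equal(res$report$snps_removed, 2L)
  expect_equal(res$report$snps_remaining,
               res$report$total_snps - res$report$snps_removed)
})

test_that("QC masks residual Mendelian-inconsistent genotypes", {
  # HWE-consistent background (founder freq ~0.3), one impossible
  # transmission planted in family 1 (mother 0, father 0, child 2)
  gm <- matrix(rep(c(2L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), 5), ncol = 1)
  gf <- matrix(rep(c(0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 2L), 5), ncol = 1)
  gc <- (gm + gf) %/% 2L
  gm[1, 1] <- 0L; gf[1, 1] <- 0L; gc[1, 1] <- 2L
  ds <- build_triads(gc, gm, gf)
  res <- apply_qc(ds)   # 1/50 = 2% >= 1% removes the SNP under defaults
  expect_equal(res$report$snps_remaining, 0L)
  res <- apply_qc(ds, qc_thresholds(mendel_rate_max = 0.05))
  expect_equal(res$report$snps_remaining, 1L)
  expect_equal(res$report$family_genotypes_masked, 1L)
  fi <- triadscan:::family_index(res$dataset)
  expect_true(all(is.na(res$dataset$geno[c(fi$mother[1], fi$father[1],
                                           fi$child[1]), 1])))
})

test_that("individual call-rate filter removes people, then families", {
  sim <- simulate_study(sim_config(n_families = 50, n_null_snps = 10,
                                   null_maf = 0.3, dyad_fraction = 0,
                                   seed = 41))
  ds <- sim$dataset
  # blank out >90% of calls for one father and one child
  frow <- which(ds$persons$role == "father")[1]
  crow <- which(ds$persons$role == "child")[2]
  ds$geno[frow, ] <- NA_integer_
  ds$geno[crow, ] <- NA_integer_
  res <- apply_qc(ds, qc_thresholds(indiv_callrate_min = 0.10,
                                    snp_missing_max = 1, maf_min = 0,
                                    hwe_p_min = 0, mendel_rate_max = 1))
  # father removed alone; removed child takes its whole family along
  expect_equal(res$report$individuals_removed, 1L + 3L)
  expect_equal(n_families(res$dataset), 49L)
})

test_that("apply_qc is idempotent and vacuous thresholds change nothing", {
  sim <- simulate_study(sim_config(n_families = 250, n_null_snps = 12,
                                   genotype_error_rate = 0.01,
                                   genotype_missing_rate = 0.02,
                                   dyad_fraction = 0.15, seed = 51))
  th <- qc_thresholds()
  r1 <- apply_qc(sim$dataset, th)
  r2 <- apply_qc(r1$dataset, th)
  expect_equal(r2$report$snps_removed, 0L)
  expect_equal(r2$report$individuals_removed, 0L)
  expect_equal(r2$dataset$geno, r1$dataset$geno)

  vac <- qc_thresholds(hwe_p_min = 0, snp_missing_max = 1, maf_min = 0,
                       mendel_rate_max = 1, indiv_callrate_min = 0)
  rv <- apply_qc(sim$dataset, vac)
  expect_equal(rv$dataset$geno, sim$dataset$geno)
  expect_equal(rv$report$snps_removed, 0L)
  expect_equal(rv$report$family_genotypes_masked, 0L)
})
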
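# Likelihood correctness (against brute-force enumeration), estimation
# (against a grid-search oracle), and model symmetries.

test_that("child_risk follows the multiplicative dose-response rule", {
  expect_equal(child_risk(c(2L, 0L), c(1, 1.7)), 1)
  expect_equal(child_risk(c(0L, 2L), c(1, 1.5)), 2.25)
  expect_equal(child_risk(c(0L, 1L, 1L), c(1, 1.2, 0.5)), 0.6)
  expect_error(child_risk(c(1L, 0L), c(1, 2)), "exactly 2")
})

test_that("enumerate_compatible handles the classic ambiguities", {
  ds <- build_triads(matrix(0L, 1, 1), matrix(0L, 1, 1), matrix(0L, 1, 1))
  w <- make_window(ds, "s1")
  hom <- enumerate_compatible(list(mother = 0L, father = 0L, child = 0L), w)
  expect_equal(nrow(hom), 1L)

  het <- enumerate_compatible(list(mother = 1L, father = 1L, child = 1L), w)
  expect_equal(nrow(het), 2L)   # which parent transmitted which allele
  expect_setequal(paste(het$tm, het$tf), c("1 2", "2 1"))

  # 2-SNP window, double-het child, both parents missing: count must match
  # an independent enumeration over all parental haplotype assignments
  ds2 <- build_triads(matrix(1L, 1, 2), matrix(1L, 1, 2), matrix(1L, 1, 2))
  w2 <- make_window(ds2, c("s1", "s2"))
  cfg <- enumerate_compatible(list(mother = NULL, father = NULL,
                                   child = c(1L, 1L)), w2)
  count <- 0L
  for (m1 in 1:4) for (m2 in m1:4) for (f1 in 1:4) for (f2 in f1:4)
    for (tm in unique(c(m1, m2))) for (tf in unique(c(f1, f2))) {
      if (all(w2$bits[tm, ] + w2$bits[tf, ] == c(1L, 1L)))
        count <- count + 1L
    }
  expect_equal(nrow(cfg), count)
})

test_that("config_probability matches the closed form and its symmetries", {
  ds <- build_triads(matrix(0L, 1, 1), matrix(0L, 1, 1), matrix(0L, 1, 1))
  w <- make_window(ds, "s1")
  p <- c(0.6, 0.4); r <- c(1, 2)
  # mu = (0.6 + 0.8)^2 = 1.96; all-homozygous-reference triad
  cfg <- enumerate_compatible(list(mother = 0L, father = 0L, child = 0L), w)
  expect_equal(config_probability(cfg, p, r),
               4 * 0.6^4 / 4 * 1 / 1.96)
  # scale invariance: only RR ratios to the reference matter
  expect_equal(config_probability(cfg, p, 2 * r),
               config_probability(cfg, p, r))
  het <- enumerate_compatible(list(mother = 1L, father = 1L, child = 1L), w)
  expect_equal(config_probability(het, p, 2 * r),
               config_probability(het, p, r))
})

test_that("summing all configurations of an unobserved family gives 1", {
  ds <- build_triads(matrix(0L, 1, 1))
  w <- make_window(ds, "s1")
  for (pars in list(list(p = c(0.5, 0.5), r = c(1, 1)),
                    list(p = c(0.3, 0.7), r = c(1, 2.5)),
                    list(p = c(0.8, 0.2), r = c(1, 0.4)))) {
    tot <- 0
    for (cm in 0:2) {
      cfg <- enumerate_compatible(list(mother = NULL, father = NULL,
                                       child = cm), w)
      tot <- tot + sum(config_probability(cfg, pars$p, pars$r))
    }
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("observed_loglik equals brute-force enumeration to 1e-10", {
  # <= 20 families, <= 2 SNPs, with dyads, missingness and planted errors
  sim <- simulate_study(sim_config(
    n_families = 20, loci = list(sim_locus(c(0.4, 0.2, 0.1, 0.3),
                                           rr_unexposed = c(1, 1.3, 0.7, 1.8))),
    dyad_fraction = 0.25, genotype_missing_rate = 0.08,
    genotype_error_rate = 0.03, seed = 13))
  ds <- sim$dataset
  w2 <- make_window(ds, c("c1_1", "c1_2"))
  w1 <- make_window(ds, "c1_1")
  for (pars in list(list(p = c(0.3, 0.25, 0.2, 0.25),
                         r = c(1, 1.5, 0.6, 2)),
                    list(p = c(0.7, 0.1, 0.1, 0.1),
                         r = c(1, 1, 1, 1)))) {
    expect_equal(suppressWarnings(observed_loglik(ds, w2, pars$p, pars$r)),
                 suppressWarnings(brute_loglik(ds, w2, pars$p, pars$r)),
                 tolerance = 1e-10)
  }
  expect_equal(suppressWarnings(observed_loglik(ds, w1, c(0.65, 0.35),
                                                c(1, 1.4))),
               suppressWarnings(brute_loglik(ds, w1, c(0.65, 0.35),
                                             c(1, 1.4))),
               tolerance = 1e-10)
})

test_that("a single homozygous triad's loglik is its one config, and an
           all-missing family is dropped without changing the loglik", {
  ds1 <- build_triads(matrix(0L, 1, 1), matrix(0L, 1, 1), matrix(0L, 1, 1))
  w <- make_window(ds1, "s1")
  p <- c(0.6, 0.4); r <- c(1, 1.9)
  cfg <- enumerate_compatible(list(mother = 0L, father = 0L, child = 0L), w)
  expect_equal(observed_loglik(ds1, w, p, r),
               log(sum(config_probability(cfg, p, r))))

  ds2 <- build_triads(rbind(0L, NA_integer_), rbind(0L, NA_integer_),
                      rbind(0L, NA_integer_))
  expect_warning(ll2 <- observed_loglik(ds2, make_window(ds2, "s1"), p, r),
                 "untyped child")
  expect_equal(ll2, observed_loglik(ds1, w, p, r))
})

test_that("fit attains the grid-search optimum on small instances", {
  # complete-data single-SNP instances with <= 8 families
  set.seed(5)
  for (rep in 1:3) {
    n <- sample(3:8, 1)
    gm <- matrix(sample(0:2, n, TRUE), n, 1)
    gf <- matrix(sample(0:2, n, TRUE), n, 1)
    gc <- matrix(0L, n, 1)
    for (i in 1:n) {   # draw a Mendelian-consistent child
      tm <- if (gm[i] == 0) 0L else if (gm[i] == 2) 1L else sample(0:1, 1)
      tf <- if (gf[i] == 0) 0L else if (gf[i] == 2) 1L else sample(0:1, 1)
      gc[i] <- tm + tf
    }
    ds <- build_triads(gc, gm, gf)
    w <- make_window(ds, "s1")
    fit <- suppressWarnings(fit_triads(ds, w,
                                       model_options(rare_haplotype_min = 0)))
    grid <- expand.grid(p = seq(0.05, 0.95, by = 0.01),
                        rr = exp(seq(log(0.1), log(10), length.out = 120)))
    wp <- triadscan:::window_patterns(ds, w)
    grid_ll <- mapply(function(p, rr)
      triadscan:::patterns_loglik(wp, c(1 - p, p), c(1, rr)),
      grid$p, grid$rr)
    expect_gte(fit$loglik, max(grid_ll) - 1e-6)
  }
})

test_that("null simulation recovers rr = 1 and the true frequency", {
  st <- simulate_stratum(2000, c(0.7, 0.3), c(1, 1), seed = 101)
  ds <- stratum_dataset(st)
  fit <- fit_triads(ds, make_window(ds, "s1"))
  expect_lt(abs(log(fit$rr[2])), 3 * fit$se_log_rr[2])
  freq_se <- sqrt(0.3 * 0.7 / (2 * 4 * 2000))  # 8000 parental alleles
  expect_lt(abs(fit$freqs[2] - 0.3), 3 * freq_se * 2)
  expect_true(fit$converged)
})

test_that("allele relabeling maps the fit to (1 - p, 1/rr)", {
  st <- simulate_stratum(400, c(0.6, 0.4), c(1, 1.6), seed = 7)
  ds <- stratum_dataset(st)
  fit <- fit_triads(ds, make_window(ds, "s1"))
  ds2 <- ds
  ds2$geno <- 2L - ds$geno
  # same reference *index*: under relabeling that haplotype now denotes the
  # other allele, so the fit maps to (1 - p, 1/rr) at the same loglik
  fit2 <- fit_triads(ds2, make_window(ds2, "s1"),
                     reference = fit$reference)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(fit2$freqs, rev(fit$freqs), tolerance = 1e-4)
  hi <- 3L - fit$reference   # the free (non-reference) haplotype
  expect_equal(log(fit2$rr[hi]), -log(fit$rr[hi]), tolerance = 1e-3)
  expect_equal(fit2$se_log_rr[hi], fit$se_log_rr[hi], tolerance = 1e-3)
})

test_that("estimates tighten with sample size (consistency)", {
  set.seed(17)
  err <- sapply(c(500, 2000, 8000), function(n) {
    dev <- replicate(8, {
      st <- simulate_stratum(n, c(0.7, 0.3), c(1, 1.5))
      ds <- stratum_dataset(st)
      fit <- fit_triads(ds, make_window(ds, "s1"), reference = 1)
      abs(log(fit$rr[2]) - log(1.5))
    })
    median(dev)
  })
  expect_true(err[3] < err[1])
  expect_true(err[2] < err[1] || err[3] < err[2])
})

test_that("log rr approaches the transmission ratio log(T/U) at large n", {
  st <- simulate_stratum(20000, c(0.75, 0.25), c(1, 1.5), seed = 23)
  ds <- stratum_dataset(st)
  fit <- fit_triads(ds, make_window(ds, "s1"), reference = 1)
  het_m <- st$m1 != st$m2
  het_f <- st$f1 != st$f2
  T_cnt <- sum(st$tm[het_m] == 2L) + sum(st$tf[het_f] == 2L)
  U_cnt <- sum(st$tm[het_m] == 1L) + sum(st$tf[het_f] == 1L)
  expect_lt(abs(log(fit$rr[2]) - log(T_cnt / U_cnt)), 0.1)
  # and both sit near the truth
  expect_lt(abs(log(fit$rr[2]) - log(1.5)), 0.1)
})

test_that("dyad-only data still recover the parameters (wider CIs)", {
  st <- simulate_stratum(3000, c(0.65, 0.35), c(1, 1.6), seed = 29)
  ds <- stratum_dataset(st)
  fit_full <- fit_triads(ds, make_window(ds, "s1"), reference = 1)
  # delete the father from every family
  keep <- ds$persons$role != "father"
  dyads <- triad_data(ds$persons[keep, ], ds$markers,
                      ds$geno[keep, , drop = FALSE])
  fit_dyad <- fit_triads(dyads, make_window(dyads, "s1"), reference = 1)
  expect_lt(abs(log(fit_dyad$rr[2]) - log(1.6)),
            3 * fit_dyad$se_log_rr[2])
  expect_gt(fit_dyad$se_log_rr[2], fit_full$se_log_rr[2])
})

test_that("Mendelian-inconsistent families are excluded per window", {
  gm <- rbind(0L, 1L, 2L); gf <- rbind(0L, 1L, 0L); gc <- rbind(2L, 1L, 1L)
  ds <- build_triads(gc, gm, gf)   # family 1 impossible
  w <- make_window(ds, "s1")
  wp <- triadscan:::window_patterns(ds, w)
  expect_equal(wp$n_incompatible, 1L)
  expect_equal(wp$n_families, 2L)
})
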
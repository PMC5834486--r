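# Synthetic triad-study generator.
#
# Emulates the structure of a family-based GWAS of an affected child with
# 0-2 genotyped parents: HWE haplotype pools per exposure stratum,
# multiplicative per-haplotype child relative risks that differ by stratum,
# case ascertainment by rejection sampling (exact under the multiplicative
# model), parent-child dyads, genotype missingness and symmetric allele-flip
# error contamination, and missing exposure records. All randomness flows
# from a single master seed: `simulate_study()` seeds the R stream once and
# draws everything from it sequentially.

#' Specify a causal locus for simulation
#'
#' @param freqs haplotype frequency vector (length 2^k, sums to 1), or a
#'   list with elements `unexposed` and `exposed` for stratum-specific
#'   pools. For a single SNP use `c(1 - maf, maf)`; haplotype 2 (the
#'   variant/risk allele) carries the relative risk.
#' @param rr_unexposed,rr_exposed per-haplotype child relative risks per
#'   stratum (scalar recycled to the non-reference haplotypes is not
#'   supported: give the full vector, reference first element 1 by
#'   convention).
#' @return List of class `sim_locus`.
#' @export
sim_locus <- function(freqs, rr_unexposed, rr_exposed = rr_unexposed) {
  if (!is.list(freqs)) freqs <- list(unexposed = freqs, exposed = freqs)
  stopifnot(all(c("unexposed", "exposed") %in% names(freqs)))
  H <- length(freqs$unexposed)
  if (length(freqs$exposed) != H ||
      length(rr_unexposed) != H || length(rr_exposed) != H)
    stop("frequency and relative-risk vectors must have equal length")
  for (f in freqs)
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
      stop("haplotype frequencies must be non-negative and sum to 1")
  if (any(c(rr_unexposed, rr_exposed) < 0))
    stop("relative risks must be non-negative")
  k <- as.integer(round(log2(H)))
  if (2^k != H) stop("haplotype alphabet must have size 2^k")
  structure(list(freqs = freqs, rr = list(unexposed = rr_unexposed,
                                          exposed = rr_exposed), k = k,
                 H = H), class = "sim_locus")
}

#' Simulation configuration
#'
#' Defaults mirror the structure of a large multi-site cleft triad study:
#' 1908 nuclear families of which 314 are dyads (fraction 314/1908), a
#' binary maternal exposure, and clean genotypes unless contamination rates
#' are set.
#'
#' @param n_families number of case families.
#' @param exposed_fraction fraction of exposed mothers.
#' @param loci list of [sim_locus()] causal loci (may be empty).
#' @param n_null_snps extra independent null SNPs (rr = 1).
#' @param null_maf minor-allele frequency for null SNPs: scalar, vector of
#'   length `n_null_snps`, or NULL to draw uniformly from (0.1, 0.5).
#' @param dyad_fraction fraction of families with one parent deleted.
#' @param genotype_missing_rate per-call missingness probability.
#' @param genotype_error_rate per-allele symmetric flip probability
#'   (applied after ascertainment; may create Mendelian inconsistencies).
#' @param exposure_missing_rate probability an exposure record is NA.
#' @param exposure_name exposure column name.
#' @param seed master seed (mandatory).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_families = 1908, exposed_fraction = 0.5,
                       loci = list(), n_null_snps = 0, null_maf = NULL,
                       dyad_fraction = 314 / 1908,
                       genotype_missing_rate = 0, genotype_error_rate = 0,
                       exposure_missing_rate = 0,
                       exposure_name = "vitamin", seed) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  rates <- c(exposed_fraction, dyad_fraction, genotype_missing_rate,
             genotype_error_rate, exposure_missing_rate)
  stopifnot(n_families >= 1, all(rates >= 0), all(rates <= 1),
            exposed_fraction > 0, exposed_fraction < 1)
  for (l in loci) stopifnot(inherits(l, "sim_locus"))
  structure(list(n_families = as.integer(n_families),
                 exposed_fraction = exposed_fraction, loci = loci,
                 n_null_snps = as.integer(n_null_snps), null_maf = null_maf,
                 dyad_fraction = dyad_fraction,
                 genotype_missing_rate = genotype_missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 exposure_missing_rate = exposure_missing_rate,
                 exposure_name = exposure_name, seed = as.integer(seed)),
            class = "sim_config")
}

# Rejection-sample n case families at a set of causal loci (one stratum).
# freqs_list / rr_list: per-locus parameter vectors. Returns per-locus
# phased parental haplotypes and transmissions.
sample_case_families <- function(n, freqs_list, rr_list) {
  nl <- length(freqs_list)
  max_risk <- prod(vapply(rr_list, function(r) max(r)^2, 0))
  if (max_risk <= 0) stop("impossible ascertainment: all risks zero")
  out <- lapply(seq_len(nl), function(l) {
    H <- length(freqs_list[[l]])
    list(m1 = integer(0), m2 = integer(0), f1 = integer(0),
         f2 = integer(0), tm = integer(0), tf = integer(0))
  })
  acc <- 0L
  rate_est <- 1 / max_risk  # lower bound on the acceptance rate
  while (acc < n) {
    B <- min(200000L, as.integer(ceiling((n - acc) / rate_est * 1.2)) + 20L)
    risk <- rep(1, B)
    draw <- vector("list", nl)
    for (l in seq_len(nl)) {
      p <- freqs_list[[l]]; r <- rr_list[[l]]
      H <- length(p)
      m1 <- sample.int(H, B, replace = TRUE, prob = p)
      m2 <- sample.int(H, B, replace = TRUE, prob = p)
      f1 <- sample.int(H, B, replace = TRUE, prob = p)
      f2 <- sample.int(H, B, replace = TRUE, prob = p)
      tm <- ifelse(stats::runif(B) < 0.5, m1, m2)
      tf <- ifelse(stats::runif(B) < 0.5, f1, f2)
      risk <- risk * r[tm] * r[tf]
      draw[[l]] <- list(m1 = m1, m2 = m2, f1 = f1, f2 = f2,
                        tm = tm, tf = tf)
    }
    keep <- which(stats::runif(B) < risk / max_risk)
    if (length(keep)) {
      take <- keep[seq_len(min(length(keep), n - acc))]
      for (l in seq_len(nl)) for (fld in names(out[[l]]))
        out[[l]][[fld]] <- c(out[[l]][[fld]], draw[[l]][[fld]][take])
      rate_est <- max(length(keep) / B, 1e-3)
      acc <- acc + length(take)
    }
  }
  out
}

#' Simulate case-parent triads for one exposure stratum at one locus
#'
#' Parents are drawn as two independent haplotypes each from `freqs` (HWE,
#' random mating); each transmits one uniformly at random; the family is
#' accepted with probability `child_risk / max(rr)^2` (rejection sampling),
#' which yields exact case ascertainment under the multiplicative model.
#'
#' @param n number of accepted families.
#' @param freqs haplotype frequency vector.
#' @param rr per-haplotype child relative risks.
#' @param seed optional seed (set only when supplied, so the function can
#'   run inside an outer seeded stream).
#' @return List of class `sim_stratum`: phased haplotype indices `m1`,
#'   `m2`, `f1`, `f2` and transmitted `tm`, `tf` (length-n integer
#'   vectors), plus `freqs`, `rr`.
#' @export
simulate_stratum <- function(n, freqs, rr, seed = NULL) {
  stopifnot(length(freqs) == length(rr), all(freqs >= 0),
            abs(sum(freqs) - 1) < 1e-8, all(rr >= 0))
  if (all(rr[freqs > 0] == 0)) stop("impossible ascertainment")
  if (!is.null(seed)) set.seed(seed)
  fam <- sample_case_families(n, list(freqs), list(rr))[[1]]
  structure(c(fam, list(freqs = freqs, rr = rr, n = n)),
            class = "sim_stratum")
}

# haplotype-index matrix -> allele-2 dose at SNP s of a k-SNP locus
hap_bits <- function(H) {
  k <- as.integer(round(log2(H)))
  bits <- matrix(0L, H, k)
  for (s in seq_len(k))
    bits[, s] <- as.integer(bitwAnd(seq_len(H) - 1L,
                                    bitwShiftL(1L, s - 1L)) > 0L)
  bits
}

#' Genotype doses from a simulated stratum
#'
#' @param sim a `sim_stratum` (or one locus of a study truth record).
#' @return List of integer matrices `mother`, `father`, `child`
#'   (families x SNPs of the locus; allele-2 dose).
#' @export
stratum_genotypes <- function(sim) {
  H <- length(sim$freqs)
  bits <- hap_bits(H)
  list(mother = bits[sim$m1, , drop = FALSE] + bits[sim$m2, , drop = FALSE],
       father = bits[sim$f1, , drop = FALSE] + bits[sim$f2, , drop = FALSE],
       child = bits[sim$tm, , drop = FALSE] + bits[sim$tf, , drop = FALSE])
}

#' Package a simulated stratum as a triad dataset
#'
#' Convenience wrapper for Monte-Carlo experiments on a single locus:
#' converts the phased truth of [simulate_stratum()] into a complete-triad
#' [triad_data()] with one marker per locus SNP.
#'
#' @param sim a `sim_stratum`.
#' @param prefix family-id prefix.
#' @param snp_prefix marker-name prefix (markers named `<snp_prefix><s>`).
#' @return A [triad_data()] of complete triads.
#' @export
stratum_dataset <- function(sim, prefix = "F", snp_prefix = "s") {
  g <- stratum_genotypes(sim)
  n <- nrow(g$mother); k <- ncol(g$mother)
  fam <- sprintf("%s%05d", prefix, seq_len(n))
  persons <- rbind(
    data.frame(family_id = fam, person_id = paste0(fam, "_M"),
               role = "mother", sex = 2L, phenotype = 1L,
               father_id = "0", mother_id = "0", stringsAsFactors = FALSE),
    data.frame(family_id = fam, person_id = paste0(fam, "_F"),
               role = "father", sex = 1L, phenotype = 1L,
               father_id = "0", mother_id = "0", stringsAsFactors = FALSE),
    data.frame(family_id = fam, person_id = paste0(fam, "_C"),
               role = "child", sex = 1L, phenotype = 2L,
               father_id = paste0(fam, "_F"),
               mother_id = paste0(fam, "_M"), stringsAsFactors = FALSE))
  geno <- rbind(g$mother, g$father, g$child)
  ord <- order(match(persons$family_id, fam),
               match(persons$role, c("mother", "father", "child")))
  markers <- data.frame(chrom = 1L, snp = paste0(snp_prefix, seq_len(k)),
                        cm = "0", pos = 10000L * seq_len(k),
                        a1 = "1", a2 = "2", stringsAsFactors = FALSE)
  triad_data(persons[ord, , drop = FALSE], markers,
             geno[ord, , drop = FALSE])
}

#' Simulate a complete triad study
#'
#' Strata are simulated with their own haplotype pools and risks; dyads are
#' created by deleting one random parent in a `dyad_fraction` of families;
#' genotype missingness and symmetric allele-flip errors are injected after
#' ascertainment; exposure records go missing at `exposure_missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @return List with `dataset` (a [triad_data()]), `exposures` (an
#'   `exposure_table`), and `truth` (generating parameters, per-family
#'   stratum, per-locus phased haplotypes and transmissions, dyad record,
#'   pre-contamination genotypes) — sufficient to recompute any summary.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_families
  n_exp <- round(n * cfg$exposed_fraction)
  n_unexp <- n - n_exp
  if (n_exp < 1 || n_unexp < 1) stop("a stratum is empty")
  nl <- length(cfg$loci)

  sim_u <- sample_case_families(
    n_unexp, lapply(cfg$loci, function(l) l$freqs$unexposed),
    lapply(cfg$loci, function(l) l$rr$unexposed))
  sim_e <- sample_case_families(
    n_exp, lapply(cfg$loci, function(l) l$freqs$exposed),
    lapply(cfg$loci, function(l) l$rr$exposed))

  stratum <- c(rep("unexposed", n_unexp), rep("exposed", n_exp))
  loci_truth <- lapply(seq_len(nl), function(l)
    mapply(function(a, b) c(a, b), sim_u[[l]], sim_e[[l]],
           SIMPLIFY = FALSE))

  # genotype blocks: causal loci first (contiguous SNPs), then null SNPs
  gm <- gf <- gc <- NULL
  snp_names <- character(0)
  for (l in seq_len(nl)) {
    st <- stratum_genotypes(c(loci_truth[[l]],
                              list(freqs = cfg$loci[[l]]$freqs$unexposed)))
    gm <- cbind(gm, st$mother); gf <- cbind(gf, st$father)
    gc <- cbind(gc, st$child)
    snp_names <- c(snp_names,
                   sprintf("c%d_%d", l, seq_len(cfg$loci[[l]]$k)))
  }
  S <- cfg$n_null_snps
  if (S > 0) {
    maf <- cfg$null_maf
    if (is.null(maf)) maf <- stats::runif(S, 0.1, 0.5)
    maf <- rep_len(maf, S)
    draw <- function() matrix(stats::rbinom(n * S, 1L,
                                            rep(maf, each = n)), n, S)
    ma1 <- draw(); ma2 <- draw(); fa1 <- draw(); fa2 <- draw()
    cm <- ifelse(matrix(stats::runif(n * S), n, S) < 0.5, ma1, ma2)
    cf <- ifelse(matrix(stats::runif(n * S), n, S) < 0.5, fa1, fa2)
    gm <- cbind(gm, ma1 + ma2); gf <- cbind(gf, fa1 + fa2)
    gc <- cbind(gc, cm + cf)
    snp_names <- c(snp_names, sprintf("n%05d", seq_len(S)))
  } else maf <- numeric(0)
  M <- length(snp_names)
  if (M == 0L) stop("simulate at least one SNP (causal or null)")

  markers <- data.frame(chrom = 1L, snp = snp_names, cm = "0",
                        pos = 10000L * seq_len(M), a1 = "1", a2 = "2",
                        stringsAsFactors = FALSE)
  fam_ids <- sprintf("F%05d", seq_len(n))
  geno_true <- list(mother = gm, father = gf, child = gc)

  # dyads: delete one random parent in a dyad_fraction of families
  n_dyad <- round(cfg$dyad_fraction * n)
  dyad_fam <- if (n_dyad) sample.int(n, n_dyad) else integer(0)
  dropped <- rep("none", n)
  if (n_dyad)
    dropped[dyad_fam] <- ifelse(stats::runif(n_dyad) < 0.5,
                                "mother", "father")

  contaminate <- function(g) {
    if (cfg$genotype_error_rate > 0) {
      e <- cfg$genotype_error_rate
      down <- matrix(stats::rbinom(length(g), g, e), nrow(g))
      up <- matrix(stats::rbinom(length(g), 2L - g, e), nrow(g))
      g <- g - down + up
    }
    if (cfg$genotype_missing_rate > 0)
      g[matrix(stats::runif(length(g)), nrow(g)) <
          cfg$genotype_missing_rate] <- NA_integer_
    g
  }
  gm_o <- contaminate(gm); gf_o <- contaminate(gf); gc_o <- contaminate(gc)

  mrows <- which(dropped != "mother"); frows <- which(dropped != "father")
  block <- function(rows, role, suffix, sex, phen)
    data.frame(family_id = fam_ids[rows],
               person_id = paste0(fam_ids[rows], suffix), role = role,
               sex = sex, phenotype = phen, father_id = "0",
               mother_id = "0", stringsAsFactors = FALSE)
  children <- data.frame(family_id = fam_ids,
                         person_id = paste0(fam_ids, "_C"), role = "child",
                         sex = 1L, phenotype = 2L,
                         father_id = paste0(fam_ids, "_F"),
                         mother_id = paste0(fam_ids, "_M"),
                         stringsAsFactors = FALSE)
  persons <- rbind(block(mrows, "mother", "_M", 2L, 1L),
                   block(frows, "father", "_F", 1L, 1L), children)
  geno <- rbind(gm_o[mrows, , drop = FALSE], gf_o[frows, , drop = FALSE],
                gc_o)
  ord <- order(match(persons$family_id, fam_ids),
               match(persons$role, c("mother", "father", "child")))
  persons <- persons[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(persons) <- NULL
  storage.mode(geno) <- "integer"
  ds <- triad_data(persons, markers, geno)

  expo <- ifelse(stratum == "exposed", "exposed", "unexposed")
  if (cfg$exposure_missing_rate > 0)
    expo[stats::runif(n) < cfg$exposure_missing_rate] <- "unknown"
  exposures <- data.frame(family_id = fam_ids, stringsAsFactors = FALSE)
  exposures[[cfg$exposure_name]] <- expo
  class(exposures) <- c("exposure_table", "data.frame")

  truth <- list(config = cfg, family_id = fam_ids, stratum = stratum,
                dropped_parent = dropped, loci = loci_truth,
                null_maf = maf, geno_true = geno_true)
  list(dataset = ds, exposures = exposures, truth = truth)
}
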
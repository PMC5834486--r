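# Pedigree genotype I/O and the triad_data container.
#
# A triad_data object holds nuclear families of one affected child with 0, 1
# or 2 genotyped parents, an ordered biallelic marker map, and an unordered
# genotype matrix coded as copies of the second (alphabetically later) allele.

#' Construct a triad dataset
#'
#' Low-level constructor for the container used throughout the package.
#' Most users obtain one from [read_pedmap()] or [simulate_study()].
#'
#' @param persons data.frame with columns `family_id`, `person_id`, `role`
#'   (one of `"mother"`, `"father"`, `"child"`), `sex`, `phenotype`,
#'   `father_id`, `mother_id`. Exactly one child per family; parents optional.
#' @param markers data.frame with columns `chrom` (integer, autosomes 1-22),
#'   `snp`, `cm` (genetic distance, carried but unused), `pos` (1-based bp),
#'   `a1`, `a2` (allele labels; `a2` may be `NA` for monomorphic markers).
#'   Must be strictly increasing by (chrom, pos).
#' @param geno integer matrix, persons x markers; entries 0/1/2 = copies of
#'   allele `a2`, `NA` = missing call.
#' @return An object of class `triad_data`.
#' @export
triad_data <- function(persons, markers, geno) {
  persons <- as.data.frame(persons, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ds <- structure(list(persons = persons, markers = markers, geno = geno),
                  class = "triad_data")
  validate_triad_data(ds)
  ds
}

validate_triad_data <- function(ds) {
  p <- ds$persons; m <- ds$markers
  need <- c("family_id", "person_id", "role", "sex", "phenotype",
            "father_id", "mother_id")
  if (!all(need %in% names(p)))
    stop("persons table lacks columns: ",
         paste(setdiff(need, names(p)), collapse = ", "))
  if (!all(p$role %in% c("mother", "father", "child")))
    stop("invalid role codes in persons table")
  if (nrow(ds$geno) != nrow(p) || ncol(ds$geno) != nrow(m))
    stop("geno dimensions do not match persons x markers")
  nchild <- table(factor(p$family_id[p$role == "child"],
                         levels = unique(p$family_id)))
  bad <- names(nchild)[nchild != 1L]
  if (length(bad))
    stop("families without exactly one affected child: ",
         paste(bad, collapse = ", "))
  dup <- p[p$role != "child", c("family_id", "role")]
  if (anyDuplicated(dup))
    stop("duplicated parent role within a family")
  if (nrow(m)) {
    if (!all(m$chrom %in% 1:22))
      stop("only autosomes 1-22 are accepted")
    o <- order(m$chrom, m$pos)
    if (any(o != seq_len(nrow(m))) ||
        anyDuplicated(m[, c("chrom", "pos")]))
      stop("markers must be strictly increasing by (chrom, pos)")
    if (nrow(p) && any(!is.na(ds$geno))) {
      rng <- range(ds$geno, na.rm = TRUE)
      if (rng[1] < 0 || rng[2] > 2)
        stop("genotype codes must be 0, 1, 2 or NA")
    }
  }
  invisible(ds)
}

#' @export
print.triad_data <- function(x, ...) {
  fam <- unique(x$persons$family_id)
  npar <- table(factor(tapply(x$persons$role != "child",
                              x$persons$family_id, sum), levels = 0:2))
  cat("triad_data: ", length(fam), " families (",
      npar["2"], " triads, ", npar["1"], " dyads, ",
      npar["0"], " child-only), ", nrow(x$markers), " markers\n", sep = "")
  invisible(x)
}

#' Number of families in a triad dataset
#' @param ds a `triad_data` object.
#' @return Integer count.
#' @export
n_families <- function(ds) length(unique(ds$persons$family_id))

# Index persons by family role; NA where a parent is absent.
family_index <- function(ds) {
  fam <- unique(ds$persons$family_id)
  idx <- function(role) {
    i <- which(ds$persons$role == role)
    i[match(fam, ds$persons$family_id[i])]
  }
  list(family_id = fam, mother = idx("mother"), father = idx("father"),
       child = idx("child"))
}

#' Subset a triad dataset by family
#'
#' @param ds a `triad_data` object.
#' @param family_ids families to keep.
#' @return A `triad_data` with only those families (marker map unchanged).
#' @export
subset_families <- function(ds, family_ids) {
  keep <- ds$persons$family_id %in% family_ids
  triad_data(ds$persons[keep, , drop = FALSE], ds$markers,
             ds$geno[keep, , drop = FALSE])
}

#' Read PED/MAP pedigree text files
#'
#' Whitespace-delimited, headerless PLINK-style text. PED columns are
#' family-id, person-id, father-id, mother-id, sex, phenotype, then two
#' allele columns per marker; allele code `"0"` means missing (a half-missing
#' genotype is treated as fully missing). The affected child is the person
#' with phenotype code 2; parental roles are inferred from the child's
#' father-id/mother-id links, so a dyad is simply a family whose PED lacks
#' one parent row. MAP columns are chromosome, snp-id, genetic distance
#' (carried through, ignored), position.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param multi_offspring `"error"` (default) rejects families with more than
#'   one offspring row; `"first"` keeps the first affected child and drops
#'   the other offspring.
#' @return A [triad_data()] object.
#' @export
read_pedmap <- function(ped_path, map_path,
                        multi_offspring = c("error", "first")) {
  multi_offspring <- match.arg(multi_offspring)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (length(map_lines)) {
    mf <- strsplit(trimws(map_lines), "[ \t]+")
    if (any(lengths(mf) != 4L))
      stop("MAP parse error at line ", which(lengths(mf) != 4L)[1],
           ": expected 4 columns")
    mf <- do.call(rbind, mf)
    markers <- data.frame(chrom = as.integer(mf[, 1]), snp = mf[, 2],
                          cm = mf[, 3], pos = as.integer(mf[, 4]),
                          a1 = NA_character_, a2 = NA_character_,
                          stringsAsFactors = FALSE)
  } else {
    markers <- data.frame(chrom = integer(), snp = character(),
                          cm = character(), pos = integer(),
                          a1 = character(), a2 = character(),
                          stringsAsFactors = FALSE)
  }
  m <- nrow(markers)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  if (!length(ped_lines)) {
    ds <- triad_data(
      data.frame(family_id = character(), person_id = character(),
                 role = character(), sex = integer(), phenotype = integer(),
                 father_id = character(), mother_id = character(),
                 stringsAsFactors = FALSE),
      markers, matrix(NA_integer_, 0, m))
    message("read_pedmap: 0 persons, ", m, " markers")
    return(ds)
  }
  pf <- strsplit(trimws(ped_lines), "[ \t]+")
  bad <- which(lengths(pf) != 6L + 2L * m)
  if (length(bad))
    stop("PED parse error at line ", bad[1], ": expected ", 6L + 2L * m,
         " columns, found ", lengths(pf)[bad[1]])
  pf <- do.call(rbind, pf)
  raw <- data.frame(family_id = pf[, 1], person_id = pf[, 2],
                    father_id = pf[, 3], mother_id = pf[, 4],
                    sex = as.integer(pf[, 5]), phenotype = as.integer(pf[, 6]),
                    stringsAsFactors = FALSE)
  al1 <- pf[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  al2 <- pf[, 6L + 2L * seq_len(m), drop = FALSE]

  geno <- matrix(NA_integer_, nrow(raw), m)
  for (j in seq_len(m)) {
    obs <- c(al1[, j], al2[, j])
    alleles <- sort(unique(obs[obs != "0"]))
    if (length(alleles) > 2L)
      stop("marker ", markers$snp[j], " has more than 2 alleles: ",
           paste(alleles, collapse = ","))
    markers$a1[j] <- if (length(alleles) >= 1L) alleles[1] else NA_character_
    markers$a2[j] <- if (length(alleles) == 2L) alleles[2] else NA_character_
    miss <- al1[, j] == "0" | al2[, j] == "0"
    g <- (al1[, j] == markers$a2[j] | (is.na(markers$a2[j]) & FALSE)) +
         (al2[, j] == markers$a2[j])
    if (is.na(markers$a2[j])) g <- rep(0L, nrow(raw))
    geno[, j] <- ifelse(miss, NA_integer_, as.integer(g))
  }

  # assign roles family by family
  keep <- logical(nrow(raw))
  role <- rep(NA_character_, nrow(raw))
  n_dropped <- 0L
  for (f in unique(raw$family_id)) {
    rows <- which(raw$family_id == f)
    aff <- rows[raw$phenotype[rows] == 2L]
    if (length(aff) == 0L)
      stop("family structure error: family ", f, " has no affected child")
    child <- aff[1]
    parents <- rows[raw$person_id[rows] %in%
                    c(raw$father_id[child], raw$mother_id[child])]
    extra <- setdiff(rows, c(child, parents))
    if (length(aff) > 1L || length(extra)) {
      if (multi_offspring == "error")
        stop("family structure error: family ", f,
             " has more than one offspring/extra member")
      n_dropped <- n_dropped + length(aff) - 1L + length(extra)
    }
    keep[child] <- TRUE; role[child] <- "child"
    for (pr in parents) {
      keep[pr] <- TRUE
      role[pr] <- if (raw$person_id[pr] == raw$mother_id[child])
        "mother" else "father"
    }
  }
  persons <- cbind(raw[keep, c("family_id", "person_id")],
                   role = role[keep],
                   raw[keep, c("sex", "phenotype", "father_id", "mother_id")])
  ds <- triad_data(persons, markers, geno[keep, , drop = FALSE])
  message("read_pedmap: ", nrow(persons), " persons in ",
          n_families(ds), " families, ", m, " markers",
          if (n_dropped) paste0(", ", n_dropped, " extra offspring dropped"))
  ds
}

#' Write PED/MAP pedigree text files
#'
#' Single-space delimited output; genotypes are written with the allele pair
#' sorted (`a1 a2` for heterozygotes), missing as `0 0`. Absent parents get
#' no row but remain referenced by id on the child row, so
#' `read_pedmap(write_pedmap(ds))` reproduces `ds`.
#'
#' @param ds a [triad_data()] object.
#' @param ped_path,map_path output paths.
#' @return Invisibly, `ds`.
#' @export
write_pedmap <- function(ds, ped_path, map_path) {
  m <- ds$markers
  writeLines(if (nrow(m)) paste(m$chrom, m$snp, m$cm, m$pos) else character(),
             map_path)
  p <- ds$persons
  if (!nrow(p)) { writeLines(character(), ped_path); return(invisible(ds)) }
  gcols <- matrix("0", nrow(p), 2L * nrow(m))
  for (j in seq_len(nrow(m))) {
    g <- ds$geno[, j]
    a1 <- m$a1[j]; a2 <- m$a2[j]
    if (is.na(a1)) a1 <- "0"
    if (is.na(a2)) a2 <- a1
    gcols[, 2L * j - 1L] <- ifelse(is.na(g), "0", ifelse(g == 2L, a2, a1))
    gcols[, 2L * j] <- ifelse(is.na(g), "0", ifelse(g == 0L, a1, a2))
  }
  lines <- paste(p$family_id, p$person_id, p$father_id, p$mother_id,
                 p$sex, p$phenotype,
                 if (nrow(m)) apply(gcols, 1, paste, collapse = " ") else "")
  writeLines(trimws(lines, which = "right"), ped_path)
  invisible(ds)
}

#' Read a maternal exposure table
#'
#' Tab-delimited with header `family_id<TAB><exposure>...`; values are
#' `yes` / `no` / `NA` (case-insensitive; an empty field also counts as
#' unknown). One row per family.
#'
#' @param path path to the TSV file.
#' @param exposure_names optional subset of exposure columns to keep.
#' @return A data.frame of class `exposure_table`: `family_id` plus one
#'   character column per exposure with values `"exposed"`, `"unexposed"`,
#'   `"unknown"`.
#' @export
read_exposures <- function(path, exposure_names = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = NULL)
  if (names(tab)[1] != "family_id")
    stop("first column of an exposure table must be family_id")
  if (anyDuplicated(tab$family_id))
    stop("duplicate family_id in exposure table: ",
         tab$family_id[duplicated(tab$family_id)][1])
  if (is.null(exposure_names)) exposure_names <- names(tab)[-1]
  miss <- setdiff(exposure_names, names(tab))
  if (length(miss)) stop("exposure column(s) not found: ",
                         paste(miss, collapse = ", "))
  out <- tab[, c("family_id", exposure_names), drop = FALSE]
  for (e in exposure_names) {
    v <- tolower(trimws(out[[e]]))
    code <- c(yes = "exposed", no = "unexposed", na = "unknown")[v]
    code[v == ""] <- "unknown"
    if (anyNA(code))
      stop("unrecognized exposure code in row ",
           which(is.na(code))[1], " of column ", e, ": '",
           out[[e]][which(is.na(code))[1]], "'")
    out[[e]] <- unname(code)
  }
  message("read_exposures: ", nrow(out), " families, exposures: ",
          paste(exposure_names, collapse = ", "))
  class(out) <- c("exposure_table", "data.frame")
  out
}

#' Exposure status per family, reconciled against a dataset
#'
#' Families present in the genotype data but absent from the exposure table
#' (or coded `NA`) are `"unknown"`. A reconciliation count is attached as
#' attribute `"reconciliation"`.
#'
#' @param exposures an `exposure_table` (or data.frame in that layout).
#' @param family_ids character vector of family ids (e.g. from the dataset).
#' @param exposure name of the exposure column.
#' @return Character vector over `family_ids` with values
#'   `"exposed"` / `"unexposed"` / `"unknown"`.
#' @export
exposure_status <- function(exposures, family_ids, exposure) {
  if (!exposure %in% names(exposures))
    stop("exposure '", exposure, "' not in table")
  st <- exposures[[exposure]][match(family_ids, exposures$family_id)]
  n_absent <- sum(is.na(st))
  st[is.na(st)] <- "unknown"
  structure(stats::setNames(st, family_ids),
            reconciliation = c(exposed = sum(st == "exposed"),
                               unexposed = sum(st == "unexposed"),
                               unknown = sum(st == "unknown"),
                               absent_from_table = n_absent))
}

#' Write an exposure table as TSV
#' @param exposures an `exposure_table`.
#' @param path output path.
#' @return Invisibly, `exposures`.
#' @export
write_exposures <- function(exposures, path) {
  out <- as.data.frame(exposures)
  for (e in names(out)[-1])
    out[[e]] <- c(exposed = "yes", unexposed = "no",
                  unknown = "NA")[out[[e]]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(exposures)
}
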
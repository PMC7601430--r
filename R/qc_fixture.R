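#' Specification of a quality-control counting fixture
#'
#' Describes a synthetic panel in which an exact, disjoint number of SNPs
#' fails each SNP filter and an exact number of animals trips each exclusion
#' rule, so the per-filter accounting of [filter_snps] and [filter_animals]
#' can be checked against known totals.
#'
#' @param n_total_snps,n_unknown_position,n_sex_chromosome,n_low_call_rate,n_low_maf,n_hwe_fail
#'   SNP totals and per-filter failure counts.
#' @param n_total_animals,n_high_missing,n_parent_conflict,n_pedigree_genomic_deviation,n_no_phenotype
#'   animal totals and per-rule exclusion counts.
#' @return list of class `"qc_fixture_spec"`.
#' @export
qc_fixture_spec <- function(n_total_snps, n_unknown_position = 0,
                            n_sex_chromosome = 0, n_low_call_rate = 0,
                            n_low_maf = 0, n_hwe_fail = 0,
                            n_total_animals, n_high_missing = 0,
                            n_parent_conflict = 0,
                            n_pedigree_genomic_deviation = 0,
                            n_no_phenotype = 0) {
  s <- as.list(environment())
  if (any(unlist(s) < 0)) stop("all counts must be non-negative")
  snp_fail <- n_unknown_position + n_sex_chromosome + n_low_call_rate +
    n_low_maf + n_hwe_fail
  ani_fail <- n_high_missing + n_parent_conflict +
    n_pedigree_genomic_deviation + n_no_phenotype
  if (snp_fail > n_total_snps)
    stop("SNP failure counts exceed the SNP total")
  if (ani_fail > n_total_animals)
    stop("animal exclusion counts exceed the animal total")
  if (n_parent_conflict > 0 &&
      n_total_animals - ani_fail < 1)
    stop("parent-progeny conflicts need at least one clean sire")
  structure(s, class = "qc_fixture_spec")
}

#' Build a panel/pedigree/phenotype fixture with known QC outcomes
#'
#' Constructs genotypes so that every failure class is hit by exactly its
#' intended filter, with margin, and by no other:
#' \itemize{
#'   \item unknown-position SNPs sit on chromosome "0" at position 0; sex
#'     SNPs on "X"; both otherwise well behaved;
#'   \item low-call-rate SNPs have just enough missing calls among the clean
#'     animals to fall below the call-rate bound;
#'   \item low-MAF SNPs are monomorphic; Hardy-Weinberg failures are
#'     all-heterozygote columns (departure 0.5);
#'   \item passing SNPs are drawn under Hardy-Weinberg at frequencies
#'     0.15-0.40 and re-drawn until they clear every threshold with margin;
#'   \item high-missing animals miss 12% of calls; conflicting progeny get
#'     genotypes independent of their genotyped sire (opposing-homozygote
#'     rate far above 1%); relationship-deviation animals are fully
#'     homozygous, which doubles their genomic diagonal while the pedigree
#'     expects 1; no-phenotype animals simply lack phenotype rows.
#' }
#' SNP statistics are guaranteed over the animals that survive the animal
#' filters, matching the pipeline order (animal filters first).
#'
#' @param spec a [qc_fixture_spec].
#' @param seed integer seed.
#' @return list with `panel` (a `genotype_panel`), `ped` (a [pedigree]) and
#'   `phenotypes` (`data.frame` animal/y).
#' @export
make_qc_fixture <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "qc_fixture_spec"))
  set.seed(seed)
  N <- spec$n_total_animals
  m <- spec$n_total_snps
  roles <- rep("clean", N)
  pool <- seq_len(N)
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  i_miss <- take(spec$n_high_missing)
  i_conf <- take(spec$n_parent_conflict)
  i_dev <- take(spec$n_pedigree_genomic_deviation)
  i_noph <- take(spec$n_no_phenotype)
  roles[i_miss] <- "miss"; roles[i_conf] <- "conflict"
  roles[i_dev] <- "dev"; roles[i_noph] <- "nopheno"
  i_clean <- which(roles == "clean")
  n_clean <- length(i_clean)
  ids <- sprintf("A%05d", seq_len(N))

  # SNP classes, in map order
  cls <- rep("pass", m)
  pool <- seq_len(m)
  j_unk <- take(spec$n_unknown_position)
  j_sex <- take(spec$n_sex_chromosome)
  j_call <- take(spec$n_low_call_rate)
  j_maf <- take(spec$n_low_maf)
  j_hwe <- take(spec$n_hwe_fail)
  cls[j_unk] <- "unknown"; cls[j_sex] <- "sex"; cls[j_call] <- "call"
  cls[j_maf] <- "maf"; cls[j_hwe] <- "hwe"

  p <- stats::runif(m, 0.15, 0.40)
  p[cls == "maf"] <- 0
  p[cls == "hwe"] <- 0.5
  geno <- matrix(0L, N, m, dimnames = list(ids, sprintf("snp%06d", seq_len(m))))
  ordinary <- cls != "maf" & cls != "hwe"
  geno[, ordinary] <- stats::rbinom(N * sum(ordinary), 2,
                                    rep(p[ordinary], each = N))
  geno[, cls == "hwe"] <- 1L
  # relationship-deviation animals: one allele drawn per locus, doubled
  if (length(i_dev))
    geno[i_dev, ordinary] <- 2L * stats::rbinom(length(i_dev) * sum(ordinary),
                                                1, rep(p[ordinary],
                                                       each = length(i_dev)))
  storage.mode(geno) <- "integer"

  # redraw passing columns until every threshold is met with margin over the
  # clean animals (binomial sampling makes offenders vanishingly rare)
  check_cols <- function(jj) {
    sub <- geno[i_clean, jj, drop = FALSE]
    pc <- colMeans(sub) / 2
    maf <- pmin(pc, 1 - pc)
    dev <- abs(colMeans(sub == 1) - 2 * pc * (1 - pc))
    jj[maf < 0.05 | dev > 0.10]
  }
  jpass <- which(cls == "pass")
  for (round in 1:20) {
    bad <- check_cols(jpass)
    if (!length(bad)) break
    geno[, bad] <- stats::rbinom(N * length(bad), 2, rep(p[bad], each = N))
    if (length(i_dev))
      geno[i_dev, bad] <- 2L * stats::rbinom(length(i_dev) * length(bad), 1,
                                             rep(p[bad], each = length(i_dev)))
    jpass <- bad
  }
  # low-call-rate columns: just enough missing calls among clean animals
  if (length(j_call)) {
    k_miss <- floor(n_clean * 0.02) + 1L
    for (j in j_call)
      geno[sample(i_clean, k_miss), j] <- NA_integer_
  }
  # high-missing animals: 12% of calls missing
  for (i in i_miss)
    geno[i, sample.int(m, ceiling(0.12 * m))] <- NA_integer_

  # map: unknown position on chromosome "0", sex SNPs on "X",
  # the rest spread over 29 autosomes
  chrom <- rep("", m)
  chrom[cls == "unknown"] <- "0"
  chrom[cls == "sex"] <- "X"
  auto <- which(!cls %in% c("unknown", "sex"))
  chrom[auto] <- as.character(rep(1:29, length.out = length(auto)))
  pos <- integer(m)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    pos[ix] <- if (ch == "0") 0L else
      as.integer(seq(1e5, by = 5e4, length.out = length(ix)))
  }
  map <- data.frame(snp = colnames(geno), chrom = chrom, pos_bp = pos,
                    stringsAsFactors = FALSE)

  # pedigree: everyone a founder except conflicting progeny, whose sire is a
  # clean genotyped animal and whose dam is pedigree-only
  sire <- dam <- rep(NA_character_, N)
  extra_animal <- character(0)
  if (length(i_conf)) {
    sires <- rep_len(ids[i_clean], length(i_conf))
    dams <- sprintf("DAM%04d", seq_along(i_conf))
    sire[i_conf] <- sires
    dam[i_conf] <- dams
    extra_animal <- dams
  }
  ped <- pedigree(c(ids, extra_animal),
                  c(sire, rep(NA, length(extra_animal))),
                  c(dam, rep(NA, length(extra_animal))))

  keep_ph <- setdiff(seq_len(N), i_noph)
  phenotypes <- data.frame(animal = ids[keep_ph],
                           y = stats::rnorm(length(keep_ph), 100, 10),
                           stringsAsFactors = FALSE)
  panel <- structure(list(geno = geno, map = map), class = "genotype_panel")
  list(panel = panel, ped = ped, phenotypes = phenotypes)
}
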
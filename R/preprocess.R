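#' Adjust yearling weight to day 365
#'
#' Linear extrapolation of the last growth segment:
#' YW = (W_t - W_prev) / (t - t_prev) * (365 - t_prev) + W_prev,
#' from the weight W_t at test termination (day t, around 12 months) and an
#' earlier weighing W_prev at day t_prev (around 6 months). Vectorised.
#'
#' @param w_t,w_prev weights in kg at days `t` and `t_prev`.
#' @param t,t_prev ages in days, `t > t_prev > 0`.
#' @return adjusted 365-day weight(s) in kg.
#' @examples
#' adjust_yearling_weight(300, 200, 360, 180)  # 302.78 kg
#' @export
adjust_yearling_weight <- function(w_t, w_prev, t, t_prev) {
  if (any(t <= t_prev)) stop("invalid record: t must exceed t_prev")
  if (any(t_prev <= 0)) stop("invalid record: ages must be positive")
  if (any(w_t <= 0 | w_prev <= 0)) stop("invalid record: weights must be positive")
  (w_t - w_prev) / (t - t_prev) * (365 - t_prev) + w_prev
}

#' Quality-control thresholds
#'
#' Defaults follow common 50K-chip practice: SNPs need a call rate of at
#' least 0.98 and a minor allele frequency of at least 0.01, and may deviate
#' from the Hardy-Weinberg expected heterozygote frequency by at most 0.15
#' (absolute difference of frequencies, not a chi-square test). Animals are
#' dropped above 10% missing calls, at an opposing-homozygote rate with a
#' genotyped parent above `parent_conflict_rate`, or when their genomic
#' relationships deviate from pedigree expectations beyond the stated
#' diagonal/off-diagonal bounds.
#'
#' @param min_call_rate,min_maf,max_hwe_het_deviation per-SNP thresholds.
#' @param max_animal_missing_rate per-animal missing-call bound (exclusive).
#' @param parent_conflict_rate opposing-homozygote rate bound (exclusive).
#' @param a22_g_diag_deviation,a22_g_pair_deviation bounds on |G - A22| on
#'   the diagonal and off the diagonal (exclusive).
#' @return list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(min_call_rate = 0.98, min_maf = 0.01,
                          max_hwe_het_deviation = 0.15,
                          max_animal_missing_rate = 0.10,
                          parent_conflict_rate = 0.01,
                          a22_g_diag_deviation = 0.25,
                          a22_g_pair_deviation = 0.5) {
  structure(as.list(environment()), class = "qc_thresholds")
}

qc_report <- function(removed, n_in, unit) {
  structure(list(removed_by_filter = removed,
                 survivors = n_in - sum(unlist(removed)),
                 input = n_in, unit = unit), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", x$unit, "): ", x$input, " in, ", x$survivors,
      " retained\n", sep = "")
  for (nm in names(x$removed_by_filter))
    cat(sprintf("  %-22s %d\n", nm, x$removed_by_filter[[nm]]))
  invisible(x)
}

#' Filter phenotype records by trait-specific rules
#'
#' Each rule is a predicate `function(df) -> logical` returning TRUE for rows
#' to keep; rows failing any rule are dropped and counted. The packaged rule
#' [min_year_rule] reproduces the usual "drop records before a scale change"
#' edit (marbling scores recorded before 2005 on the old grading scale).
#'
#' @param table phenotype `data.frame`.
#' @param trait trait column that must exist.
#' @param rules named list of predicates.
#' @return the filtered table, with attribute `removed` (per-rule counts).
#' @export
filter_phenotypes <- function(table, trait, rules = list()) {
  if (!trait %in% names(table)) stop("unknown trait column: ", trait)
  removed <- list()
  for (nm in names(rules)) {
    keep <- rules[[nm]](table)
    keep[is.na(keep)] <- FALSE
    removed[[nm]] <- sum(!keep)
    table <- table[keep, , drop = FALSE]
  }
  if (!nrow(table)) warning("all phenotype records removed")
  attr(table, "removed") <- removed
  table
}

#' @param cutoff first acceptable year.
#' @param column year column name.
#' @rdname filter_phenotypes
#' @export
min_year_rule <- function(cutoff = 2005, column = "year") {
  force(cutoff); force(column)
  function(df) df[[column]] >= cutoff
}

#' SNP quality control with per-filter accounting
#'
#' Applies, in order: unknown map position (chromosome "0" or position 0),
#' sex chromosome ("X"/"Y"), call rate below `min_call_rate`, minor allele
#' frequency below `min_maf`, and Hardy-Weinberg departure
#' |het_obs - 2p(1-p)| above `max_hwe_het_deviation`. Each removed SNP is
#' attributed to the first filter it fails, so the per-filter counts sum with
#' the survivors to the input count. Allele frequencies are observed
#' frequencies among non-missing genotypes of the supplied panel.
#'
#' @param panel a `genotype_panel`.
#' @param thresholds a [qc_thresholds].
#' @return list with `panel` (filtered) and `report` (a `qc_report`).
#' @export
filter_snps <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!ncol(panel$geno)) stop("empty genotype panel")
  if (!identical(colnames(panel$geno), panel$map$snp))
    stop("map does not cover the panel SNPs in order")
  geno <- panel$geno
  n <- nrow(geno)
  call_rate <- 1 - colMeans(is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  het <- colMeans(geno == 1, na.rm = TRUE)
  hwe_dev <- abs(het - 2 * p * (1 - p))
  fails <- cbind(
    unknown_position = panel$map$chrom %in% "0" | panel$map$pos_bp <= 0,
    sex_chromosome = panel$map$chrom %in% c("X", "Y"),
    call_rate = call_rate < thresholds$min_call_rate,
    maf = maf < thresholds$min_maf,
    hwe = hwe_dev > thresholds$max_hwe_het_deviation)
  first <- apply(fails, 1, function(z) if (any(z)) which(z)[1] else 0L)
  removed <- lapply(seq_len(ncol(fails)), function(k) sum(first == k))
  names(removed) <- colnames(fails)
  keep <- first == 0L
  out <- panel
  out$geno <- geno[, keep, drop = FALSE]
  out$map <- panel$map[keep, , drop = FALSE]
  if (!is.null(out$founder_freq)) out$founder_freq <- out$founder_freq[keep]
  list(panel = out, report = qc_report(removed, ncol(geno), "SNPs"))
}

#' Animal quality control with per-filter accounting
#'
#' Excludes genotyped animals, in order, for: missing-call rate above
#' `max_animal_missing_rate`; parent-progeny conflict (opposing-homozygote
#' rate with a genotyped parent above `parent_conflict_rate`; the progeny is
#' removed, since the data cannot say which member of the pair is mislabelled);
#' deviation between genomic and pedigree relationships (diagonal
#' |G_ii - A22_ii| above `a22_g_diag_deviation` or any remaining pairwise
#' |G_ij - A22_ij| above `a22_g_pair_deviation`); and lack of a phenotype for
#' every analysed trait. Attribution is to the first failing rule. The
#' deviation rules are evaluated after conflict removals, among the animals
#' still in the panel.
#'
#' @param panel a `genotype_panel`.
#' @param ped a [pedigree] covering the panel animals.
#' @param phenotypes phenotype `data.frame` with an `animal` column, or NULL
#'   to skip the phenotype rule.
#' @param thresholds a [qc_thresholds].
#' @param traits trait columns checked by the no-phenotype rule (default: all
#'   numeric non-id columns). An animal is removed only when it is missing
#'   in all of them.
#' @return list with `panel` (filtered) and `report` (a `qc_report`).
#' @export
filter_animals <- function(panel, ped, phenotypes = NULL,
                           thresholds = qc_thresholds(), traits = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  stopifnot_pedigree(ped)
  geno <- panel$geno
  ids <- rownames(geno)
  if (!all(ids %in% ped$animal))
    stop("panel animals missing from pedigree: ",
         paste(utils::head(setdiff(ids, ped$animal), 5), collapse = ", "))
  n <- length(ids)
  flagged <- stats::setNames(rep(0L, n), ids)  # 0 = pass, else filter index
  # 1: per-animal missing rate
  miss_rate <- rowMeans(is.na(geno))
  flagged[miss_rate > thresholds$max_animal_missing_rate] <- 1L
  # 2: parent-progeny opposing homozygotes
  pm <- match(ids, ped$animal)
  for (parent_col in c("sire", "dam")) {
    par <- ped[[parent_col]][pm]
    has <- !is.na(par) & par %in% ids & flagged == 0L
    for (i in which(has)) {
      g1 <- geno[i, ]; g2 <- geno[par[i], ]
      ok <- !is.na(g1) & !is.na(g2)
      if (!any(ok)) next
      rate <- mean((g1[ok] == 0 & g2[ok] == 2) | (g1[ok] == 2 & g2[ok] == 0))
      if (rate > thresholds$parent_conflict_rate) flagged[i] <- 2L
    }
  }
  # 3: pedigree-genomic deviation among the animals still in
  left <- names(flagged)[flagged == 0L]
  if (length(left) > 1) {
    sub <- panel; sub$geno <- geno[left, , drop = FALSE]
    G <- compute_G(sub)
    A22 <- make_A(ped, subset = left)
    dev <- abs(G - A22)
    bad_diag <- diag(dev) > thresholds$a22_g_diag_deviation
    diag(dev) <- 0
    bad_pair <- apply(dev > thresholds$a22_g_pair_deviation, 1, any)
    flagged[left[bad_diag | bad_pair]] <- 3L
  }
  # 4: no phenotype for any analysed trait
  if (!is.null(phenotypes)) {
    if (is.null(traits))
      traits <- setdiff(names(phenotypes)[vapply(phenotypes, is.numeric,
                                                 logical(1))], "animal")
    left <- names(flagged)[flagged == 0L]
    has_pheno <- vapply(left, function(a) {
      rows <- phenotypes$animal == a
      any(rows) && any(!is.na(unlist(phenotypes[rows, traits, drop = FALSE])))
    }, logical(1))
    flagged[left[!has_pheno]] <- 4L
  }
  removed <- list(high_missing = sum(flagged == 1L),
                  parent_conflict = sum(flagged == 2L),
                  pedigree_genomic_deviation = sum(flagged == 3L),
                  no_phenotype = sum(flagged == 4L))
  out <- panel
  out$geno <- geno[flagged == 0L, , drop = FALSE]
  list(panel = out, report = qc_report(removed, n, "animals"))
}
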
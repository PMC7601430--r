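#' Simulation settings for the gene-dropping generator
#'
#' Collects the parameters of the synthetic pedigree/genotype/phenotype
#' generator. The defaults describe a small multi-generation population with
#' independent loci; they are meant for testing the relationship and
#' association machinery, not for emulating a specific breed's LD structure.
#'
#' @param n_founders number of unrelated founder animals (>= 2).
#' @param n_generations number of discrete non-founder generations (>= 0).
#' @param matings_per_generation sire/dam pairs drawn per generation.
#' @param offspring_per_mating full sibs produced per pair.
#' @param n_snps number of biallelic markers.
#' @param maf_range range of founder allele frequencies, within (0, 0.5].
#' @param n_chromosomes autosomes the markers are spread over, evenly spaced.
#' @param chromosome_length_bp length of each simulated chromosome.
#' @param qtl_spec `data.frame` with columns `snp` (1-based marker index) and
#'   `effect` (additive allele-substitution effect, trait units per dose).
#' @param sigma_a2 total additive genetic variance; the polygenic component is
#'   `sigma_a2` minus the expected founder QTL variance (floored at 0).
#' @param sigma_e2 residual variance.
#' @param fixed_effects_spec `data.frame` with columns `name`, `n_levels`,
#'   `effect_sd`: each factor assigns animals a random level whose effect is
#'   drawn N(0, effect_sd^2).
#' @param prop_genotyped fraction of animals carried into the genotype panel.
#' @param ld_block haplotype transmission block size in SNPs: 1 (default)
#'   drops every locus independently; k > 1 copies parental haplotypes in
#'   blocks of k adjacent SNPs, a crude stand-in for within-chromosome LD.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 100, n_generations = 2,
                       matings_per_generation = 50, offspring_per_mating = 2,
                       n_snps = 1000, maf_range = c(0.1, 0.5),
                       n_chromosomes = 5, chromosome_length_bp = 1e8,
                       qtl_spec = NULL, sigma_a2 = 1, sigma_e2 = 1,
                       fixed_effects_spec = NULL, prop_genotyped = 1,
                       ld_block = 1L, seed = 1L) {
  if (n_founders < 2) stop("n_founders must be >= 2")
  if (n_generations < 0) stop("n_generations must be >= 0")
  if (sigma_a2 <= 0 || sigma_e2 < 0) stop("variances must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (prop_genotyped <= 0 || prop_genotyped > 1)
    stop("prop_genotyped must be in (0, 1]")
  if (!is.null(qtl_spec)) {
    qtl_spec <- as.data.frame(qtl_spec)
    if (!all(c("snp", "effect") %in% names(qtl_spec)))
      stop("qtl_spec needs columns 'snp' and 'effect'")
    if (any(qtl_spec$snp < 1 | qtl_spec$snp > n_snps))
      stop("qtl_spec indices must lie in 1..n_snps")
  }
  structure(list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    matings_per_generation = as.integer(matings_per_generation),
    offspring_per_mating = as.integer(offspring_per_mating),
    n_snps = as.integer(n_snps), maf_range = maf_range,
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.integer(chromosome_length_bp),
    qtl_spec = qtl_spec, sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
    fixed_effects_spec = fixed_effects_spec,
    prop_genotyped = prop_genotyped, ld_block = as.integer(ld_block),
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a discrete-generation pedigree
#'
#' Founders (generation 0) have both parents unknown. Each later generation
#' consists of full-sib families whose sire and dam are drawn, without
#' replacement within a mating, from the animals of the previous generation.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config] object.
#' @return A [pedigree] object with
#'   `n_founders + n_generations * matings_per_generation * offspring_per_mating`
#'   records.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  animal <- sprintf("F%03d", seq_len(config$n_founders))
  sire <- dam <- rep(NA_character_, config$n_founders)
  prev <- animal
  if (config$n_generations > 0) {
    for (g in seq_len(config$n_generations)) {
      ids <- character(0); ss <- character(0); dd <- character(0)
      for (m in seq_len(config$matings_per_generation)) {
        pair <- sample(prev, 2L)
        kid <- sprintf("G%dM%02dK%02d", g, m, seq_len(config$offspring_per_mating))
        ids <- c(ids, kid)
        ss <- c(ss, rep(pair[1], length(kid)))
        dd <- c(dd, rep(pair[2], length(kid)))
      }
      animal <- c(animal, ids); sire <- c(sire, ss); dam <- c(dam, dd)
      prev <- ids
    }
  }
  pedigree(animal, sire, dam)
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder haplotypes are drawn per locus as Bernoulli(p_i) with
#' p_i ~ Uniform(maf_range); each descendant inherits one allele per parent
#' per locus, independently across loci unless `ld_block > 1`, in which case
#' the choice of parental haplotype is held constant within blocks of
#' `ld_block` adjacent SNPs. Dosages are 0/1/2. The marker map spaces SNPs
#' evenly along `n_chromosomes` chromosomes.
#'
#' @param ped a [pedigree].
#' @param config a [sim_config]; `prop_genotyped < 1` subsamples the animals
#'   kept in the returned panel (all animals are dropped through internally).
#' @return A `genotype_panel`: list with `geno` (animals x SNPs integer
#'   matrix, rownames = animal ids), `map` (`data.frame` snp/chrom/pos_bp) and
#'   `founder_freq` (the drawn founder allele frequencies).
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot_pedigree(ped)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(ped); m <- config$n_snps
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  h1 <- matrix(0L, n, m, dimnames = list(ped$animal, NULL))
  h2 <- h1
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  block <- rep(seq_len(ceiling(m / config$ld_block)), each = config$ld_block)[seq_len(m)]
  nb <- max(block)
  transmit <- function(hap_a, hap_b) {
    pick <- if (config$ld_block > 1L)
      (stats::runif(nb) < 0.5)[block] else stats::runif(m) < 0.5
    ifelse(pick, hap_a, hap_b)
  }
  for (i in seq_len(n)) {
    h1[i, ] <- if (is.na(si[i])) as.integer(stats::runif(m) < p)
               else transmit(h1[si[i], ], h2[si[i], ])
    h2[i, ] <- if (is.na(di[i])) as.integer(stats::runif(m) < p)
               else transmit(h1[di[i], ], h2[di[i], ])
  }
  geno <- h1 + h2
  colnames(geno) <- sprintf("snp%05d", seq_len(m))
  map <- even_map(m, config$n_chromosomes, config$chromosome_length_bp)
  keep <- rownames(geno)
  if (config$prop_genotyped < 1) {
    k <- max(1L, round(config$prop_genotyped * n))
    keep <- sort(sample(rownames(geno), k))
  }
  panel <- list(geno = geno[keep, , drop = FALSE], map = map,
                founder_freq = p)
  class(panel) <- "genotype_panel"
  panel
}

even_map <- function(m, n_chrom, chrom_len) {
  chrom <- rep(seq_len(n_chrom), each = ceiling(m / n_chrom))[seq_len(m)]
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) {
    k <- length(ix)
    as.integer(round(seq(1, chrom_len, length.out = k)))
  }), use.names = FALSE)
  data.frame(snp = sprintf("snp%05d", seq_len(m)),
             chrom = as.character(chrom), pos_bp = pos,
             stringsAsFactors = FALSE)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", nrow(x$geno), "animals x", ncol(x$geno), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s);",
      format(100 * mean(is.na(x$geno)), digits = 3), "% missing\n")
  invisible(x)
}

#' Simulate phenotypes under an additive animal model
#'
#' The true breeding value of animal i is the sum of centred QTL dosage
#' effects and a polygenic term dropped down the pedigree: founders draw
#' N(0, sigma2_poly), offspring take the parent average plus a Mendelian
#' sampling deviation N(0, sigma2_poly/2 * (1 - Fbar)) where Fbar is the mean
#' of the parents' pedigree inbreeding coefficients (0 for unknown parents).
#' The phenotype is y = sum of fixed-level effects + a + e with
#' e ~ N(0, sigma_e2). The polygenic variance is `sigma_a2` minus the expected
#' founder QTL variance (2 p (1-p) beta^2 summed over QTL), floored at zero,
#' so that the total founder additive variance matches `sigma_a2`.
#'
#' @param ped a [pedigree] (all animals are phenotyped).
#' @param panel a `genotype_panel` from [simulate_genotypes]; must contain
#'   every QTL-bearing animal if `qtl_spec` is set. QTL dosages are taken from
#'   the panel; animals absent from it contribute polygenic-only values.
#' @param config a [sim_config].
#' @return A `data.frame` with columns `animal`, `y`, one column per fixed
#'   factor, and attributes `tbv` (true breeding values), `fixed_effects` and
#'   `sigma2_poly`.
#' @export
simulate_phenotypes <- function(ped, panel, config) {
  stopifnot_pedigree(ped)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(ped)
  # QTL contribution from centred dosages
  qtl <- numeric(n); names(qtl) <- ped$animal
  var_qtl <- 0
  if (!is.null(config$qtl_spec) && nrow(config$qtl_spec)) {
    p <- panel$founder_freq[config$qtl_spec$snp]
    var_qtl <- sum(2 * p * (1 - p) * config$qtl_spec$effect^2)
    g <- panel$geno[, config$qtl_spec$snp, drop = FALSE]
    centred <- sweep(g, 2, 2 * p)
    contrib <- drop(centred %*% config$qtl_spec$effect)
    qtl[rownames(panel$geno)] <- contrib
  }
  sigma2_poly <- max(config$sigma_a2 - var_qtl, 0)
  # polygenic gene drop with inbreeding-adjusted Mendelian sampling variance
  Fcoef <- inbreeding(ped)
  si <- match(ped$sire, ped$animal); di <- match(ped$dam, ped$animal)
  poly <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(si[i]) && is.na(di[i])) {
      poly[i] <- stats::rnorm(1, 0, sqrt(sigma2_poly))
    } else {
      pa <- mean(c(if (!is.na(si[i])) poly[si[i]],
                   if (!is.na(di[i])) poly[di[i]],
                   if (is.na(si[i]) || is.na(di[i])) 0))
      fbar <- mean(c(if (!is.na(si[i])) Fcoef[si[i]] else 0,
                     if (!is.na(di[i])) Fcoef[di[i]] else 0))
      poly[i] <- pa + stats::rnorm(1, 0, sqrt(sigma2_poly / 2 * (1 - fbar)))
    }
  }
  tbv <- poly + qtl
  y <- tbv + stats::rnorm(n, 0, sqrt(config$sigma_e2))
  out <- data.frame(animal = ped$animal, y = y, stringsAsFactors = FALSE)
  fx <- list()
  if (!is.null(config$fixed_effects_spec)) {
    fe <- as.data.frame(config$fixed_effects_spec)
    for (k in seq_len(nrow(fe))) {
      lev <- sample.int(fe$n_levels[k], n, replace = TRUE)
      eff <- stats::rnorm(fe$n_levels[k], 0, fe$effect_sd[k])
      out[[fe$name[k]]] <- factor(paste0("L", lev))
      out$y <- out$y + eff[lev]
      fx[[fe$name[k]]] <- eff
    }
  }
  attr(out, "tbv") <- stats::setNames(tbv, ped$animal)
  attr(out, "fixed_effects") <- fx
  attr(out, "sigma2_poly") <- sigma2_poly
  out
}

# pedigree inbreeding coefficients, F = diag(A) - 1 via the tabular method
inbreeding <- function(ped) {
  diag(make_A(ped)) - 1
}
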
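#' Simulate the one-QTL window-detection study
#'
#' Builds one replicate of the synthetic study used to check that the
#' weighted window scan recovers a known QTL: a three-generation pedigree of
#' 500 animals (100 founders, two generations of 100 matings with two
#' offspring each), 2,000 SNPs on 10 chromosomes dropped in founder
#' haplotype blocks of 20 SNPs (so adjacent markers within a window are in
#' LD, as window-based detection presumes), all animals genotyped and
#' phenotyped with heritability 0.4 (sigma_a2 = 0.4, sigma_e2 = 0.6), one
#' 5-level fixed factor, and a single QTL placed on chromosome 1 at the
#' marker whose founder allele frequency is closest to 0.3, scaled to
#' explain `qtl_frac` (default 25%) of the additive genetic variance.
#'
#' @param seed integer replicate seed.
#' @param qtl_frac share of sigma_a2 explained by the QTL (0 disables it and
#'   yields a null replicate).
#' @param n_snps number of markers.
#' @param ld_block founder haplotype block size passed to the genotype
#'   simulator.
#' @return list with `ped`, `panel`, `phenotypes`, `spec` (a [model_spec]),
#'   `qtl_snp` (marker name, NA for null replicates) and `config`.
#' @export
simulate_qtl_study <- function(seed, qtl_frac = 0.25, n_snps = 2000L,
                               ld_block = 20L) {
  sa2 <- 0.4; se2 <- 0.6
  cfg <- sim_config(n_founders = 100, n_generations = 2,
                    matings_per_generation = 100, offspring_per_mating = 2,
                    n_snps = n_snps, maf_range = c(0.1, 0.5),
                    n_chromosomes = 10, sigma_a2 = sa2, sigma_e2 = se2,
                    fixed_effects_spec = data.frame(name = "cg", n_levels = 5,
                                                    effect_sd = 1),
                    ld_block = ld_block, seed = seed)
  ped <- simulate_pedigree(cfg)
  panel <- simulate_genotypes(ped, cfg)
  qtl_snp <- NA_character_
  if (qtl_frac > 0) {
    cand <- 50:150  # interior of chromosome 1
    qtl <- cand[which.min(abs(panel$founder_freq[cand] - 0.3))]
    p <- panel$founder_freq[qtl]
    beta <- sqrt(qtl_frac * sa2 / (2 * p * (1 - p)))
    cfg$qtl_spec <- data.frame(snp = qtl, effect = beta)
    qtl_snp <- panel$map$snp[qtl]
  }
  phenotypes <- simulate_phenotypes(ped, panel, cfg)
  list(ped = ped, panel = panel, phenotypes = phenotypes,
       spec = model_spec("y", "cg", character(), sa2, se2),
       qtl_snp = qtl_snp, config = cfg)
}

#' Run the window-detection study over replicates
#'
#' Fits the default two-iteration weighted scan on `n_reps` replicates of
#' [simulate_qtl_study] and summarises QTL recovery: how often the
#' QTL-bearing window attains the maximum variance share, how often its
#' share grows from iteration 1 to 2, whether the weight trace is conserved,
#' and whether weight entropy is non-increasing.
#'
#' @param seeds integer vector of replicate seeds.
#' @param qtl_frac passed to [simulate_qtl_study]; 0 gives the null study,
#'   in which case the summary reports the maximum window share instead.
#' @param n_snps,ld_block passed to [simulate_qtl_study].
#' @param ... further arguments to [wssgwas].
#' @return `data.frame` with one row per replicate: `seed`, `qtl_window`,
#'   `top_window`, `hit`, `gv_iter1`, `gv_iter2`, `gain`, `max_gv`,
#'   `trace_err`, `entropy_drop`.
#' @export
run_qtl_study <- function(seeds, qtl_frac = 0.25, n_snps = 2000L,
                          ld_block = 20L, ...) {
  rows <- lapply(seeds, function(s) {
    st <- simulate_qtl_study(s, qtl_frac = qtl_frac, n_snps = n_snps,
                             ld_block = ld_block)
    fit <- wssgwas(st$panel, st$ped, st$phenotypes, st$spec, ...)
    index <- attr(fit$windows, "index")
    last <- fit$iterations[[length(fit$iterations)]]
    first <- fit$iterations[[1]]
    if (!is.na(st$qtl_snp)) {
      qpos <- match(st$qtl_snp, fit$effects$snp)
      wq <- which(vapply(index, function(ix) qpos %in% ix, logical(1)))
    } else wq <- NA_integer_
    m <- nrow(fit$effects)
    data.frame(
      seed = s, qtl_window = wq,
      top_window = last$top_window,
      hit = if (is.na(wq)) NA else last$top_window == wq,
      gv_iter1 = if (is.na(wq)) NA_real_ else first$gv_percent[wq],
      gv_iter2 = if (is.na(wq)) NA_real_ else last$gv_percent[wq],
      gain = if (is.na(wq)) NA else last$gv_percent[wq] > first$gv_percent[wq],
      max_gv = last$max_gv_percent,
      trace_err = max(vapply(fit$iterations,
                             function(z) abs(z$trace_D - m), numeric(1))),
      entropy_drop = first$weight_entropy -
        fit$iterations[[length(fit$iterations)]]$weight_entropy)
  })
  do.call(rbind, rows)
}
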
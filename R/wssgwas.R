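#' Partition a marker map into windows of adjacent SNPs
#'
#' Non-overlapping consecutive blocks of `block_size` SNPs in (chromosome,
#' position) order, restarting at every chromosome boundary; the final block
#' on a chromosome may be shorter.
#'
#' @param map `data.frame` with columns `snp`, `chrom`, `pos_bp`, already in
#'   map order (the fitting functions sort it).
#' @param block_size SNPs per window (default 20).
#' @return `data.frame` with columns `window_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, plus attribute `index` — a list of column-index
#'   vectors into the map.
#' @export
snp_windows <- function(map, block_size = 20L) {
  if (block_size < 1) stop("block_size must be >= 1")
  idx_by_chrom <- split(seq_len(nrow(map)), map$chrom)
  # keep chromosomes in order of first appearance
  idx_by_chrom <- idx_by_chrom[unique(map$chrom)]
  windows <- list()
  for (ix in idx_by_chrom) {
    grp <- split(ix, (seq_along(ix) - 1L) %/% block_size)
    windows <- c(windows, grp)
  }
  out <- data.frame(
    window_id = seq_along(windows),
    chrom = vapply(windows, function(i) map$chrom[i[1]], character(1)),
    start_bp = vapply(windows, function(i) min(map$pos_bp[i]), numeric(1)),
    end_bp = vapply(windows, function(i) max(map$pos_bp[i]), numeric(1)),
    n_snps = lengths(windows), stringsAsFactors = FALSE)
  attr(out, "index") <- unname(windows)
  out
}

#' Back-solve SNP effects from breeding values
#'
#' u = (1/c) D M' G^-1 a, where c = 2 sum p(1-p) is the VanRaden scale.
#' Because G = M D M' / c, this choice makes M u reproduce the target vector
#' a exactly when G is full rank. Setting `scaling = FALSE` drops the 1/c
#' factor (the literal textbook back-solve), which rescales every effect by
#' the same constant and leaves window-variance ratios unchanged.
#'
#' @param M centred genotype matrix (genotyped animals x SNPs).
#' @param weights per-SNP weights d (diagonal of D).
#' @param G_inv inverse of the weighted (blended) genomic matrix used to
#'   predict `a_hat`.
#' @param a_hat breeding-value vector for the genotyped animals (GEBV or
#'   DGV), in row order of `M`.
#' @param scale_c the VanRaden scale used to build G.
#' @param scaling include the 1/c factor (default TRUE).
#' @return named numeric vector of per-SNP effects.
#' @export
backsolve_snp_effects <- function(M, weights, G_inv, a_hat, scale_c,
                                  scaling = TRUE) {
  if (length(a_hat) != nrow(M)) stop("a_hat must match the rows of M")
  if (length(weights) != ncol(M)) stop("one weight per SNP required")
  u <- weights * as.numeric(crossprod(M, as.numeric(G_inv %*% a_hat)))
  if (scaling) u <- u / scale_c
  names(u) <- colnames(M)
  u
}

#' Shared block weights from squared SNP effects
#'
#' Every SNP in a window receives the window's summed squared effect
#' sum(u_i^2) as its (unnormalised) weight. If all effects are zero the
#' weights fall back to uniform.
#'
#' @param u per-SNP effect vector.
#' @param windows output of [snp_windows] covering `seq_along(u)`.
#' @return per-SNP positive weight vector (unnormalised).
#' @export
block_weights <- function(u, windows) {
  index <- attr(windows, "index")
  w <- numeric(length(u))
  for (ix in index) w[ix] <- sum(u[ix]^2)
  if (all(w == 0)) w[] <- 1  # degenerate-input fallback
  if (any(w == 0)) w[w == 0] <- min(w[w > 0]) * 1e-8  # keep D positive
  w
}

#' Rescale weights to preserve the total genetic variance
#'
#' Returns `d_new * sum(d_old) / sum(d_new)`, so the trace of D is carried
#' over exactly from one iteration to the next.
#'
#' @param d_new,d_old weight vectors of equal length.
#' @return rescaled `d_new`.
#' @export
normalize_weights <- function(d_new, d_old) {
  if (length(d_new) != length(d_old)) stop("weight vectors differ in length")
  tr_new <- sum(d_new)
  if (tr_new <= 0) stop("new weights have non-positive trace")
  d_new * (sum(d_old) / tr_new)
}

#' Percentage of additive genetic variance explained per SNP window
#'
#' For each window, the empirical variance (denominator n-1) across genotyped
#' animals of the window genetic score sum_{i in window} M_i u_i, divided by
#' sigma_a2, times 100.
#'
#' @param M centred genotype matrix.
#' @param u per-SNP effects.
#' @param sigma_a2 additive genetic variance (> 0).
#' @param windows output of [snp_windows].
#' @return the `windows` data.frame with a `gv_percent` column appended.
#' @export
window_variance_explained <- function(M, u, sigma_a2, windows) {
  if (sigma_a2 <= 0) stop("sigma_a2 must be > 0")
  index <- attr(windows, "index")
  gv <- vapply(index, function(ix) {
    stats::var(as.numeric(M[, ix, drop = FALSE] %*% u[ix]))
  }, numeric(1))
  out <- windows
  out$gv_percent <- gv / sigma_a2 * 100
  attr(out, "index") <- index
  out
}

#' Select QTL windows above a variance threshold
#'
#' Windows whose explained share of additive genetic variance is greater
#' than or equal to `threshold` percent, sorted by share, descending.
#'
#' @param results window table with a `gv_percent` column.
#' @param threshold inclusive lower bound in percent (default 1).
#' @return the selected rows, sorted by `gv_percent` descending.
#' @export
select_windows <- function(results, threshold = 1.0) {
  sel <- results[!is.na(results$gv_percent) & results$gv_percent >= threshold, ,
                 drop = FALSE]
  sel <- sel[order(-sel$gv_percent), , drop = FALSE]
  attr(sel, "index") <- NULL
  rownames(sel) <- NULL
  sel
}

#' Weighted single-step genome-wide association (WssGWAS)
#'
#' Fits the single-trait animal model by ssGBLUP and iterates the
#' marker-reweighting scheme: with D = I build G and H^-1, solve the
#' mixed-model equations, back-solve SNP effects from the breeding values of
#' the genotyped animals (replacing GEBV by DGV when `use_dgv` is TRUE),
#' derive a shared weight per window of `block_size` adjacent SNPs as the
#' summed squared effects, renormalise the weights to constant trace,
#' rebuild G and re-solve. After `n_iterations` rounds the per-window share
#' of additive genetic variance is computed from the final effects and
#' windows at or above `threshold` percent are selected.
#'
#' @param panel `genotype_panel` of QC-passed genotyped animals.
#' @param ped a [pedigree] containing (at least) all phenotyped and
#'   genotyped animals.
#' @param phenotypes `data.frame` with `animal`, the trait and model columns.
#' @param spec a [model_spec] with known variance components.
#' @param n_iterations weight-update rounds (default 2; accuracy is known to
#'   degrade with further rounds).
#' @param block_size SNPs per window (default 20).
#' @param use_dgv back-solve from direct genomic values instead of GEBV
#'   (default TRUE).
#' @param threshold selection threshold in percent of additive variance.
#' @param g_coef,a_coef blend coefficients for G and A22 (defaults 0.95/0.05).
#' @param backsolve_scaling include the 1/c factor in the back-solve.
#' @return object of class `"wssgwas"`: list with `effects` (snp, chrom, pos,
#'   u_hat, weight), `windows`, `selected`, `solution` (final
#'   `mme_solution`), `dgv`, `iterations` (per-round diagnostics), and the
#'   call parameters.
#' @seealso [ssgblup] for a single non-weighted fit.
#' @export
wssgwas <- function(panel, ped, phenotypes, spec, n_iterations = 2L,
                    block_size = 20L, use_dgv = TRUE, threshold = 1.0,
                    g_coef = 0.95, a_coef = 0.05, backsolve_scaling = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(spec, "model_spec"))
  stopifnot_pedigree(ped)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  ord <- order(as_chrom_order(panel$map$chrom), panel$map$pos_bp)
  map <- panel$map[ord, , drop = FALSE]
  geno <- panel$geno[, ord, drop = FALSE]
  gids <- rownames(geno)
  cg <- center_genotypes(geno)
  windows <- snp_windows(map, block_size)
  Ainv <- make_A_inverse(ped)
  A22 <- make_A(ped, subset = gids)
  inc <- build_incidence(phenotypes, spec, ped$animal)

  d <- rep(1, ncol(geno))
  iters <- list()
  for (t in seq_len(n_iterations)) {
    G <- G_from_M(cg$M, d, cg$scale_c)
    Gb <- blend_G(G, A22, g_coef, a_coef)
    Gb_inv <- sym_solve(Gb, "blended G")
    Hinv <- make_H_inverse(Ainv, A22, Gb, gids)
    sol <- solve_mme(inc$X, inc$Z, inc$y, Hinv, spec)
    gebv_g <- sol$gebv[gids]
    dgv <- compute_dgv(Gb_inv, gebv_g)
    # the blended inverse also drives the back-solve: the raw VanRaden G is
    # always singular (column centring puts the 1-vector in its null space)
    u <- backsolve_snp_effects(cg$M, d, Gb_inv, gebv_g, cg$scale_c,
                               scaling = backsolve_scaling)
    wv <- window_variance_explained(cg$M, u, spec$sigma_a2, windows)
    q <- d / sum(d)
    iters[[t]] <- list(iteration = t, trace_D = sum(d),
                       weight_entropy = -sum(q * log(q)),
                       max_gv_percent = max(wv$gv_percent),
                       top_window = wv$window_id[which.max(wv$gv_percent)],
                       gv_percent = wv$gv_percent,
                       solution = sol$convergence)
    if (t < n_iterations) {
      # the weight update starts from DGV rather than GEBV when use_dgv is
      # set: genotyped animals differ in GEBV accuracy, and the DGV strips
      # the non-genomic part before the effects are squared into weights
      u_w <- if (use_dgv)
        backsolve_snp_effects(cg$M, d, Gb_inv, dgv, cg$scale_c,
                              scaling = backsolve_scaling) else u
      d <- normalize_weights(block_weights(u_w, windows), d)
    }
  }
  selected <- select_windows(wv, threshold)
  effects <- data.frame(snp = map$snp, chrom = map$chrom, pos_bp = map$pos_bp,
                        u_hat = unname(u), weight = d,
                        stringsAsFactors = FALSE)
  structure(list(effects = effects, windows = wv, selected = selected,
                 solution = sol, dgv = dgv,
                 iterations = iters, trait = spec$trait,
                 sigma_a2 = spec$sigma_a2, sigma_e2 = spec$sigma_e2,
                 n_iterations = n_iterations, block_size = block_size,
                 use_dgv = use_dgv, threshold = threshold,
                 genotyped_ids = gids),
            class = "wssgwas")
}

# numeric-aware chromosome ordering ("1" < "2" < "10" < "X")
as_chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  ord <- ifelse(is.na(num), rank(chrom, ties.method = "min") + 1e6, num)
  ord
}

#' Single-step GBLUP fit
#'
#' One pass of the single-step evaluation with unweighted markers: builds
#' A^-1, A22, G (VanRaden), the 0.95/0.05 blend and H^-1, and solves the
#' animal-model mixed-model equations jointly for genotyped and ungenotyped
#' animals.
#'
#' @inheritParams wssgwas
#' @return object of class `"ssgblup"`: the [solve_mme] solution augmented
#'   with `dgv` for the genotyped animals and the model/blend settings.
#' @export
ssgblup <- function(panel, ped, phenotypes, spec, g_coef = 0.95,
                    a_coef = 0.05) {
  fit <- wssgwas(panel, ped, phenotypes, spec, n_iterations = 1L,
                 g_coef = g_coef, a_coef = a_coef)
  out <- fit$solution
  out$dgv <- fit$dgv
  out$trait <- spec$trait
  class(out) <- c("ssgblup", class(out))
  out
}
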
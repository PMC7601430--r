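#' Pedigree numerator relationship matrix (A)
#'
#' Tabular method in topological order: the relationship between an animal
#' and any older animal is the average of the relationships of its parents
#' with that animal; the diagonal is 1 + F where F is half the parents'
#' relationship.
#'
#' @param ped a [pedigree].
#' @param subset optional character vector of animal ids; the returned matrix
#'   is the corresponding principal submatrix (e.g. A22 for genotyped ids).
#' @return A symmetric numeric matrix with animal ids as dimnames and
#'   attribute `kind` (`"A"` or `"A22"`).
#' @export
make_A <- function(ped, subset = NULL) {
  stopifnot_pedigree(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      r <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) +
                  (if (!is.na(d)) A[j, d] else 0))
      A[j, i] <- r
      A[i, j] <- r
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  if (!is.null(subset)) {
    miss <- setdiff(subset, ped$animal)
    if (length(miss)) stop("subset ids not in pedigree: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    A <- A[subset, subset, drop = FALSE]
    attr(A, "kind") <- "A22"
  } else {
    attr(A, "kind") <- "A"
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' alpha = 1/d_i to the inverse, where the Mendelian sampling variance d_i is
#' 0.5 - 0.25 (F_s + F_d) with both parents known, 0.75 - 0.25 F_p with one,
#' and 1 for founders. Inbreeding coefficients come from the tabular A
#' recursion.
#'
#' @param ped a [pedigree].
#' @return A sparse symmetric `Matrix::dsCMatrix` with animal-id dimnames.
#' @export
make_A_inverse <- function(ped) {
  stopifnot_pedigree(ped)
  n <- nrow(ped)
  Fcoef <- inbreeding(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  Fs <- ifelse(is.na(si), NA, Fcoef[ifelse(is.na(si), 1L, si)])
  Fd <- ifelse(is.na(di), NA, Fcoef[ifelse(is.na(di), 1L, di)])
  d <- ifelse(!is.na(si) & !is.na(di), 0.5 - 0.25 * (Fs + Fd),
       ifelse(!is.na(si), 0.75 - 0.25 * Fs,
       ifelse(!is.na(di), 0.75 - 0.25 * Fd, 1)))
  alpha <- 1 / d
  ii <- list(); jj <- list(); xx <- list()
  push <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  anim <- seq_len(n)
  push(anim, anim, alpha)
  hs <- !is.na(si); hd <- !is.na(di)
  if (any(hs)) {
    push(anim[hs], si[hs], -alpha[hs] / 2)
    push(si[hs], anim[hs], -alpha[hs] / 2)
    push(si[hs], si[hs], alpha[hs] / 4)
  }
  if (any(hd)) {
    push(anim[hd], di[hd], -alpha[hd] / 2)
    push(di[hd], anim[hd], -alpha[hd] / 2)
    push(di[hd], di[hd], alpha[hd] / 4)
  }
  both <- hs & hd
  if (any(both)) {
    push(si[both], di[both], alpha[both] / 4)
    push(di[both], si[both], alpha[both] / 4)
  }
  Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' Centre a genotype matrix and compute VanRaden scaling statistics
#'
#' Missing dosages are imputed to the column mean 2p, columns are centred by
#' 2p, and the VanRaden scale c = 2 * sum p (1 - p) is returned. Allele
#' frequencies are the observed frequencies in the panel.
#'
#' @param panel a `genotype_panel` (or a bare dosage matrix).
#' @return list with `M` (centred matrix), `p` (per-SNP frequencies) and
#'   `scale_c`.
#' @export
center_genotypes <- function(panel) {
  geno <- if (inherits(panel, "genotype_panel")) panel$geno else panel
  p <- colMeans(geno, na.rm = TRUE) / 2
  if (anyNA(geno)) {
    imp <- rep(2 * p, each = nrow(geno))
    geno[is.na(geno)] <- imp[is.na(geno)]
  }
  M <- sweep(geno, 2, 2 * p)
  scale_c <- 2 * sum(p * (1 - p))
  if (scale_c <= 0)
    stop("all SNPs are monomorphic: VanRaden scale 2*sum(p(1-p)) is zero")
  list(M = M, p = p, scale_c = scale_c)
}

#' Weighted genomic relationship matrix (VanRaden)
#'
#' G = M D M' / (2 sum p_i (1 - p_i)) with M the centred dosage matrix and D
#' a diagonal matrix of positive per-SNP weights. With D = I this is
#' VanRaden's method 1.
#'
#' @param panel a `genotype_panel` or dosage matrix; missing values imputed
#'   to mean dosage.
#' @param weights per-SNP positive weights (default all 1).
#' @return symmetric matrix with attributes `p`, `scale_c`, `kind = "G_raw"`.
#' @export
compute_G <- function(panel, weights = NULL) {
  cg <- center_genotypes(panel)
  G <- G_from_M(cg$M, weights, cg$scale_c)
  attr(G, "p") <- cg$p
  attr(G, "scale_c") <- cg$scale_c
  attr(G, "kind") <- "G_raw"
  G
}

# G from an already-centred matrix; used inside the reweighting loop
G_from_M <- function(M, weights = NULL, scale_c) {
  if (is.null(weights)) {
    G <- tcrossprod(M) / scale_c
  } else {
    if (length(weights) != ncol(M)) stop("one weight per SNP required")
    if (any(weights <= 0)) stop("SNP weights must be positive")
    G <- tcrossprod(sweep(M, 2, sqrt(weights), "*")) / scale_c
  }
  (G + t(G)) / 2
}

#' Blend the genomic and pedigree relationship matrices
#'
#' Returns `g_coef * G + a_coef * A22`. The default 0.95/0.05 blend keeps the
#' result invertible when G is singular (e.g. clones or more animals than
#' effective markers).
#'
#' @param G,A22 conforming symmetric matrices with identical id order.
#' @param g_coef,a_coef blend coefficients, must sum to 1.
#' @return blended matrix, attribute `kind = "G_blend"`.
#' @export
blend_G <- function(G, A22, g_coef = 0.95, a_coef = 0.05) {
  if (!isTRUE(all.equal(g_coef + a_coef, 1)))
    stop("blend coefficients must sum to 1")
  if (!identical(dimnames(G)[[1]], dimnames(A22)[[1]]))
    stop("G and A22 must have the same animals in the same order")
  Gb <- g_coef * G + a_coef * A22
  attr(Gb, "kind") <- "G_blend"
  attr(Gb, "p") <- attr(G, "p")
  attr(Gb, "scale_c") <- attr(G, "scale_c")
  Gb
}

# symmetric inverse with an informative failure
sym_solve <- function(S, label = "matrix") {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- tryCatch(range(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
                   error = function(e) c(NA, NA))
    stop(sprintf("%s is not positive definite (eigenvalue range %.3g..%.3g)",
                 label, ev[1], ev[2]))
  }
  inv <- chol2inv(ch)
  dimnames(inv) <- dimnames(S)
  inv
}

#' Combined pedigree-genomic inverse relationship matrix (H-inverse)
#'
#' H^-1 = A^-1 + [0 0; 0 (G_blend)^-1 - (A22)^-1], the single-step
#' relationship inverse: equal to A^-1 outside the genotyped block, with the
#' genomic correction added on the genotyped animals.
#'
#' @param A_inv sparse inverse of A over all pedigree animals.
#' @param A22 pedigree relationship submatrix of the genotyped animals.
#' @param G_blend blended genomic matrix for the same animals, same order.
#' @param genotyped_ids character ids of the genotyped animals.
#' @return sparse symmetric matrix with attribute `genotyped_ids`.
#' @export
make_H_inverse <- function(A_inv, A22, G_blend, genotyped_ids) {
  ids <- rownames(A_inv)
  if (!all(genotyped_ids %in% ids))
    stop("genotyped ids missing from the pedigree: ",
         paste(utils::head(setdiff(genotyped_ids, ids), 5), collapse = ", "))
  if (length(genotyped_ids) &&
      (!identical(rownames(G_blend), genotyped_ids) ||
       !identical(rownames(A22), genotyped_ids)))
    stop("A22 / G_blend must be ordered as genotyped_ids")
  Hinv <- methods::as(A_inv, "CsparseMatrix")
  if (length(genotyped_ids)) {
    corr <- sym_solve(G_blend, "blended G") - sym_solve(A22, "A22")
    ix <- match(genotyped_ids, ids)
    Hinv <- Hinv + Matrix::sparseMatrix(
      i = rep(ix, times = length(ix)), j = rep(ix, each = length(ix)),
      x = as.vector(t(corr)), dims = dim(Hinv), dimnames = dimnames(Hinv))
  }
  Hinv <- Matrix::forceSymmetric((Hinv + Matrix::t(Hinv)) / 2)
  attr(Hinv, "genotyped_ids") <- genotyped_ids
  Hinv
}
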
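#' Specify a single-trait animal model
#'
#' @param trait name of the phenotype column.
#' @param fixed_factors character vector of factor column names. The first
#'   factor keeps all its levels (there is no separate intercept); every
#'   later factor drops its first level (reference coding), which makes the
#'   crossed fixed effects estimable. With no factors an intercept is used.
#' @param covariates character vector of numeric covariate columns.
#' @param sigma_a2,sigma_e2 additive genetic and residual variance
#'   components, treated as known inputs.
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(trait, fixed_factors = character(), covariates = character(),
                       sigma_a2, sigma_e2) {
  if (sigma_a2 <= 0 || sigma_e2 <= 0) stop("variance components must be > 0")
  structure(list(trait = trait, fixed_factors = fixed_factors,
                 covariates = covariates, sigma_a2 = sigma_a2,
                 sigma_e2 = sigma_e2), class = "model_spec")
}

#' Incidence matrices for the animal model
#'
#' @param phenotypes `data.frame` with an `animal` column, the trait column
#'   and any factor/covariate columns named in `spec`; rows with a missing
#'   trait value are dropped.
#' @param spec a [model_spec].
#' @param pedigree_ids ordered ids of all pedigree animals (the columns of Z).
#' @return list with `X` (dense), `Z` (sparse records x pedigree animals),
#'   `y`, and `records` (the animal id per row).
#' @export
build_incidence <- function(phenotypes, spec, pedigree_ids) {
  stopifnot(inherits(spec, "model_spec"))
  cols <- c("animal", spec$trait, spec$fixed_factors, spec$covariates)
  miss <- setdiff(cols, names(phenotypes))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  df <- phenotypes[!is.na(phenotypes[[spec$trait]]), cols, drop = FALSE]
  unknown <- setdiff(df$animal, pedigree_ids)
  if (length(unknown))
    stop("records for animals absent from the pedigree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  nrec <- nrow(df)
  blocks <- list()
  if (length(spec$fixed_factors)) {
    for (k in seq_along(spec$fixed_factors)) {
      f <- factor(df[[spec$fixed_factors[k]]])
      mm <- if (k == 1) stats::model.matrix(~ f - 1) else
        stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(spec$fixed_factors[k], ":",
                             if (k == 1) levels(f) else levels(f)[-1])
      blocks[[k]] <- mm
    }
  } else {
    blocks[[1]] <- matrix(1, nrec, 1, dimnames = list(NULL, "(Intercept)"))
  }
  for (cv in spec$covariates) {
    blocks[[length(blocks) + 1L]] <-
      matrix(as.numeric(df[[cv]]), nrec, 1, dimnames = list(NULL, cv))
  }
  X <- do.call(cbind, blocks)
  Z <- Matrix::sparseMatrix(i = seq_len(nrec),
                            j = match(df$animal, pedigree_ids),
                            x = 1, dims = c(nrec, length(pedigree_ids)),
                            dimnames = list(NULL, pedigree_ids))
  list(X = X, Z = Z, y = as.numeric(df[[spec$trait]]), records = df$animal)
}

#' Solve the single-trait mixed-model equations
#'
#' Solves
#' \deqn{[X'X, X'Z; Z'X, Z'Z + H^{-1}\lambda] [b; a] = [X'y; Z'y]}
#' with \eqn{\lambda = \sigma_e^2 / \sigma_a^2}, by sparse Cholesky
#' factorisation (default) or diagonally preconditioned conjugate gradients.
#' Both solvers are required to satisfy the normal equations to the stated
#' relative residual.
#'
#' @param X,Z,y incidence matrices and observation vector from
#'   [build_incidence].
#' @param H_inv sparse inverse relationship matrix over all pedigree animals
#'   (use [make_A_inverse] output for pedigree-only BLUP).
#' @param spec a [model_spec] carrying the variance components.
#' @param method `"direct"` or `"cg"`.
#' @param tol relative residual tolerance.
#' @param max_iter conjugate-gradient iteration cap.
#' @return list of class `"mme_solution"`: `b_hat` (named fixed-effect
#'   solutions), `gebv` (named breeding values for every pedigree animal) and
#'   `convergence` (method, iterations, relative residual norm).
#' @export
solve_mme <- function(X, Z, y, H_inv, spec, method = c("direct", "cg"),
                      tol = 1e-10, max_iter = 5000L) {
  stopifnot(inherits(spec, "model_spec"))
  method <- match.arg(method)
  lambda <- spec$sigma_e2 / spec$sigma_a2
  X <- Matrix::Matrix(X, sparse = TRUE)
  XtX <- Matrix::crossprod(X)
  XtZ <- Matrix::crossprod(X, Z)
  ZtZ <- Matrix::crossprod(Z)
  LHS <- rbind(cbind(XtX, XtZ),
               cbind(Matrix::t(XtZ), ZtZ + lambda * H_inv))
  rhs <- c(as.numeric(Matrix::crossprod(X, y)),
           as.numeric(Matrix::crossprod(Z, y)))
  p <- ncol(X); n <- ncol(Z)
  if (method == "direct") {
    sol <- tryCatch(
      as.numeric(Matrix::solve(Matrix::forceSymmetric(LHS), rhs)),
      error = function(e)
        stop("mixed-model equations could not be factorised: ",
             conditionMessage(e)))
    iters <- 1L
  } else {
    cgres <- cg_solve(Matrix::forceSymmetric(LHS), rhs, tol = tol,
                      max_iter = max_iter)
    if (!cgres$converged)
      stop(sprintf(paste0("conjugate gradients did not converge: ",
                          "relative residual %.3g after %d iterations"),
                   cgres$relres, cgres$iterations))
    sol <- cgres$x
    iters <- cgres$iterations
  }
  relres <- sqrt(sum((as.numeric(LHS %*% sol) - rhs)^2)) /
    max(sqrt(sum(rhs^2)), .Machine$double.eps)
  structure(list(
    b_hat = stats::setNames(sol[seq_len(p)], colnames(X)),
    gebv = stats::setNames(sol[p + seq_len(n)], colnames(Z)),
    convergence = list(method = method, iterations = iters,
                       relative_residual = relres),
    lambda = lambda), class = "mme_solution")
}

# Jacobi-preconditioned conjugate gradients on a sparse SPD system
cg_solve <- function(A, b, tol = 1e-10, max_iter = 5000L) {
  d <- Matrix::diag(A)
  d[d <= 0] <- 1
  x <- numeric(length(b))
  r <- b - as.numeric(A %*% x)
  z <- r / d
  pvec <- z
  rz <- sum(r * z)
  bnorm <- max(sqrt(sum(b^2)), .Machine$double.eps)
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% pvec)
    alpha <- rz / sum(pvec * Ap)
    x <- x + alpha * pvec
    r <- r - alpha * Ap
    relres <- sqrt(sum(r^2)) / bnorm
    if (relres < tol)
      return(list(x = x, iterations = it, relres = relres, converged = TRUE))
    z <- r / d
    rz_new <- sum(r * z)
    pvec <- z + (rz_new / rz) * pvec
    rz <- rz_new
  }
  list(x = x, iterations = max_iter, relres = relres, converged = FALSE)
}

#' @export
print.mme_solution <- function(x, ...) {
  cat("Animal-model MME solution:", length(x$b_hat), "fixed-effect columns,",
      length(x$gebv), "breeding values\n")
  cat(sprintf("  solver: %s (%d iteration(s), relative residual %.2e)\n",
              x$convergence$method, x$convergence$iterations,
              x$convergence$relative_residual))
  invisible(x)
}

#' @export
coef.mme_solution <- function(object, ...) object$b_hat

#' Direct genomic values from GEBV and the inverse genomic matrix
#'
#' DGV_i = -(sum_{j != i} g^{ij} GEBV_j) / g^{ii}, where g^{ij} are elements
#' of the inverse of the (blended) genomic relationship matrix. Defined for
#' genotyped animals only.
#'
#' @param G_inv inverse of the blended G, genotyped animals only.
#' @param gebv named GEBV vector restricted to the same animals, same order.
#' @return named numeric vector of DGV.
#' @export
compute_dgv <- function(G_inv, gebv) {
  if (nrow(G_inv) != length(gebv))
    stop("G_inv and gebv must cover the same animals")
  if (!is.null(rownames(G_inv)) && !is.null(names(gebv)) &&
      !identical(rownames(G_inv), names(gebv)))
    stop("G_inv and gebv are ordered differently")
  gii <- diag(G_inv)
  if (any(gii == 0)) stop("zero diagonal in G-inverse")
  q <- as.numeric(G_inv %*% gebv)
  dgv <- gebv - q / gii
  names(dgv) <- names(gebv)
  dgv
}
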
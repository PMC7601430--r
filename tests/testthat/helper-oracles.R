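# shared oracles and small generators for the test suite

# random multi-generation pedigree for property tests
random_pedigree <- function(n_founders, n_offspring, seed) {
  set.seed(seed)
  animal <- sprintf("P%03d", seq_len(n_founders + n_offspring))
  sire <- dam <- rep(NA_character_, n_founders + n_offspring)
  for (i in seq_len(n_offspring)) {
    k <- n_founders + i
    par <- sample(animal[seq_len(k - 1L)], 2L)
    sire[k] <- par[1]; dam[k] <- par[2]
  }
  pedigree(animal, sire, dam)
}

# dense generalised-least-squares / BLUP oracle for the animal model:
# V = Z A Z' sa2 + I se2; b = (X'V^-1 X)^-1 X'V^-1 y; a = sa2 A Z' V^-1 (y - Xb)
gls_blup_oracle <- function(X, Z, y, A, sa2, se2) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  V <- Z %*% A %*% t(Z) * sa2 + diag(length(y)) * se2
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- sa2 * A %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(b = drop(b), a = drop(a))
}

# exhaustive hypergeometric tail: probability that a uniformly drawn list of
# size k from the background overlaps the term in >= obs genes
enumerate_hyper_p <- function(background, term, k, obs) {
  sets <- utils::combn(background, k, simplify = FALSE)
  mean(vapply(sets, function(s) length(intersect(s, term)) >= obs,
              logical(1)))
}

# tiny genotype panel builder
toy_panel <- function(geno, chrom = NULL, pos = NULL) {
  m <- ncol(geno)
  if (is.null(colnames(geno))) colnames(geno) <- sprintf("snp%03d", seq_len(m))
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("a%02d", seq_len(nrow(geno)))
  map <- data.frame(snp = colnames(geno),
                    chrom = if (is.null(chrom)) rep("1", m) else chrom,
                    pos_bp = if (is.null(pos)) seq_len(m) * 1000L else pos,
                    stringsAsFactors = FALSE)
  structure(list(geno = geno, map = map), class = "genotype_panel")
}
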
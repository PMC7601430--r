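test_that("windows are consecutive blocks that respect chromosome boundaries", {
  map <- data.frame(snp = sprintf("s%02d", 1:50),
                    chrom = rep(c("1", "2"), c(30, 20)),
                    pos_bp = c(1:30, 1:20) * 1e5)
  w <- snp_windows(map, 20)
  expect_equal(nrow(w), 3 + 1 - 1)  # 30 -> 20+10, 20 -> 20
  expect_equal(w$n_snps, c(20L, 10L, 20L))
  expect_equal(w$chrom, c("1", "1", "2"))
  idx <- attr(w, "index")
  expect_equal(sort(unlist(idx)), 1:50)        # partition
  expect_true(all(vapply(idx, function(i) length(unique(map$chrom[i])),
                         integer(1)) == 1))    # never spans a boundary
  expect_true(all(lengths(idx) <= 20))
})

test_that("back-solved effects reproduce the breeding values for full-rank G", {
  set.seed(81)
  n <- 6; m <- 12
  M <- matrix(rnorm(n * m), n, m)  # generic full-row-rank 'centred' matrix
  d <- runif(m, 0.5, 2)
  scale_c <- 3.7
  G <- M %*% diag(d) %*% t(M) / scale_c
  a <- rnorm(n)
  u <- backsolve_snp_effects(M, d, solve(G), a, scale_c)
  expect_lt(max(abs(M %*% u - a)), 1e-8)
  expect_equal(unname(backsolve_snp_effects(M, d, solve(G), rep(0, n),
                                            scale_c)),
               rep(0, m))
  # without the 1/c factor the result is the literal D M' G^-1 a
  u_raw <- backsolve_snp_effects(M, d, solve(G), a, scale_c, scaling = FALSE)
  expect_equal(u_raw, u * scale_c)
  # explicit dense computation on the 2x2 toy regularised by blending
  panel <- toy_panel(matrix(c(0L, 2L, 2L, 0L), 2, 2))
  G2 <- compute_G(panel)
  A22 <- diag(2); dimnames(A22) <- dimnames(G2)
  Gb <- blend_G(G2, A22)
  cg <- center_genotypes(panel)
  a2 <- c(0.3, -0.4)
  u2 <- backsolve_snp_effects(cg$M, c(1, 1), solve(Gb), a2, cg$scale_c)
  expect_equal(unname(u2),
               drop(diag(2) %*% t(cg$M) %*% solve(Gb, a2)) / cg$scale_c)
})

test_that("block weights share the summed squared effect and fall back", {
  map <- data.frame(snp = sprintf("s%02d", 1:41), chrom = "1",
                    pos_bp = 1:41 * 100)
  w <- snp_windows(map, 20)
  u <- c(rep(1, 20), rep(0, 21))
  bw <- block_weights(u, w)
  expect_equal(bw[1:20], rep(20, 20))
  expect_true(all(bw[21:40] < 1e-6))     # zero block floored to a tiny weight
  expect_equal(bw[41], bw[40])           # single-SNP tail block, u = 0 there
  # all-zero effects: uniform fallback
  expect_equal(block_weights(rep(0, 41), w), rep(1, 41))
  # permuting SNPs within a block leaves the weights unchanged
  u2 <- u; u2[1:20] <- sample(u2[1:20])
  expect_equal(block_weights(u2, w), bw)
  # single-SNP block weight is the squared effect
  w1 <- snp_windows(map[41, ], 20)
  expect_equal(block_weights(2.5, w1), 6.25)
})

test_that("weight normalisation preserves the trace exactly", {
  d_old <- rep(1, 10)
  d_new <- runif(10, 0, 4)
  out <- normalize_weights(d_new, d_old)
  expect_equal(sum(out), 10)
  expect_equal(normalize_weights(d_old * 2, d_old), d_old)
  d_ok <- runif(10); d_ok <- d_ok * 10 / sum(d_ok)
  expect_equal(normalize_weights(d_ok, d_old), d_ok)
  expect_error(normalize_weights(rep(0, 10), d_old), "trace")
})

test_that("window variance shares match direct computation", {
  map <- data.frame(snp = sprintf("s%d", 1:6), chrom = "1", pos_bp = 1:6)
  w <- snp_windows(map, 2)
  set.seed(91)
  M <- matrix(rnorm(30), 5, 6)
  u <- rnorm(6)
  res <- window_variance_explained(M, u, sigma_a2 = 2, w)
  direct <- vapply(list(1:2, 3:4, 5:6), function(ix)
    var(M[, ix] %*% u[ix]) / 2 * 100, numeric(1))
  expect_equal(res$gv_percent, direct)
  # zero effects: all shares zero
  expect_equal(window_variance_explained(M, rep(0, 6), 2, w)$gv_percent,
               rep(0, 3))
  # one window spanning everything: the share is the total
  w1 <- snp_windows(map, 6)
  expect_equal(window_variance_explained(M, u, 2, w1)$gv_percent,
               var(M %*% u) / 2 * 100, ignore_attr = TRUE)
  expect_error(window_variance_explained(M, u, 0, w), "sigma_a2")
})

test_that("window selection is inclusive at the threshold and sorted", {
  res <- data.frame(window_id = 1:3, chrom = "1", start_bp = 1:3,
                    end_bp = 1:3, n_snps = 20,
                    gv_percent = c(0.5, 1.0, 2.3))
  sel <- select_windows(res, 1.0)
  expect_equal(sel$gv_percent, c(2.3, 1.0))
  expect_equal(nrow(select_windows(res[0, ], 1.0)), 0)
})

test_that("a single iteration is the plain unweighted single-step scan", {
  st <- simulate_qtl_study(seed = 5, n_snps = 400, ld_block = 1)
  # shrink the population for speed: refit on founders' sub-panel
  fit1 <- wssgwas(st$panel, st$ped, st$phenotypes, st$spec, n_iterations = 1)
  # manual D = I back-solve from the same single-step solution
  cg <- center_genotypes(st$panel$geno[, fit1$effects$snp])
  A22 <- make_A(st$ped, subset = rownames(st$panel$geno))
  G <- compute_G(st$panel$geno[, fit1$effects$snp])
  Gb <- blend_G(G, A22)
  u_manual <- backsolve_snp_effects(cg$M, rep(1, 400), solve(Gb),
                                    fit1$solution$gebv[rownames(cg$M)],
                                    cg$scale_c)
  expect_equal(unname(coef(fit1)), unname(u_manual), tolerance = 1e-8)
  expect_equal(fit1$effects$weight, rep(1, 400))
})

test_that("the weight trace is conserved and entropy never rises", {
  st <- simulate_qtl_study(seed = 6, n_snps = 400)
  fit <- wssgwas(st$panel, st$ped, st$phenotypes, st$spec, n_iterations = 3)
  m <- nrow(fit$effects)
  for (it in fit$iterations) expect_equal(it$trace_D, m)
  ent <- vapply(fit$iterations, `[[`, numeric(1), "weight_entropy")
  expect_true(all(diff(ent) < 1e-8))
})
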
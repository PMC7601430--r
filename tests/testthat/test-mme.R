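make_toy_model <- function(seed = 21, n_founders = 4, n_offspring = 6) {
  set.seed(seed)
  ped <- random_pedigree(n_founders, n_offspring, seed = seed)
  n <- nrow(ped)
  ph <- data.frame(animal = ped$animal,
                   y = rnorm(n, 10),
                   herd = factor(sample(c("h1", "h2"), n, replace = TRUE)),
                   age = runif(n, 20, 30))
  list(ped = ped, ph = ph)
}

test_that("incidence matrices map records to effects and animals", {
  tm <- make_toy_model()
  spec <- model_spec("y", "herd", "age", 1, 1)
  inc <- build_incidence(tm$ph, spec, tm$ped$animal)
  # one level per record: factor block row-sums are 1
  expect_equal(unname(rowSums(inc$X[, startsWith(colnames(inc$X), "herd")])),
               rep(1, nrow(tm$ph)))
  expect_equal(unname(inc$X[, "age"]), tm$ph$age)
  # Z selects pedigree positions
  expect_equal(apply(as.matrix(inc$Z), 1, which.max),
               match(tm$ph$animal, tm$ped$animal))
  # records with missing trait values are dropped
  ph2 <- tm$ph; ph2$y[3] <- NA
  expect_equal(length(build_incidence(ph2, spec, tm$ped$animal)$y),
               nrow(ph2) - 1)
  ph3 <- tm$ph; ph3$animal[1] <- "nobody"
  expect_error(build_incidence(ph3, spec, tm$ped$animal), "absent")
})

test_that("MME solution equals the dense GLS/BLUP oracle", {
  tm <- make_toy_model(seed = 31)
  sa2 <- 2; se2 <- 3
  spec <- model_spec("y", "herd", "age", sa2, se2)
  inc <- build_incidence(tm$ph, spec, tm$ped$animal)
  A <- make_A(tm$ped)
  sol <- solve_mme(inc$X, inc$Z, inc$y, make_A_inverse(tm$ped), spec)
  oracle <- gls_blup_oracle(inc$X, inc$Z, inc$y, A, sa2, se2)
  expect_equal(unname(sol$b_hat), unname(oracle$b), tolerance = 1e-6)
  expect_equal(unname(sol$gebv), unname(oracle$a), tolerance = 1e-6)
  expect_lt(sol$convergence$relative_residual, 1e-8)
  # conjugate gradients agrees with the direct factorisation
  sol_cg <- solve_mme(inc$X, inc$Z, inc$y, make_A_inverse(tm$ped), spec,
                      method = "cg")
  expect_equal(sol_cg$gebv, sol$gebv, tolerance = 1e-6)
})

test_that("infinite shrinkage recovers the fixed-effects-only fit", {
  tm <- make_toy_model(seed = 41)
  spec <- model_spec("y", "herd", "age", sigma_a2 = 1e-8, sigma_e2 = 1)
  inc <- build_incidence(tm$ph, spec, tm$ped$animal)
  sol <- solve_mme(inc$X, inc$Z, inc$y, make_A_inverse(tm$ped), spec)
  expect_lt(max(abs(sol$gebv)), 1e-4)
  ols <- qr.coef(qr(inc$X), inc$y)
  expect_equal(unname(sol$b_hat), unname(ols), tolerance = 1e-5)
})

test_that("duplicating every record is the same as doubling its weight", {
  tm <- make_toy_model(seed = 51)
  spec <- model_spec("y", "herd", character(), 1, 2)
  inc <- build_incidence(tm$ph, spec, tm$ped$animal)
  Ai <- make_A_inverse(tm$ped)
  twice <- rbind(tm$ph, tm$ph)
  inc2 <- build_incidence(twice, spec, tm$ped$animal)
  sol2 <- solve_mme(inc2$X, inc2$Z, inc2$y, Ai, spec)
  # doubled normal equations: [2X'X, 2X'Z; 2Z'X, 2Z'Z + lambda Hinv]
  lambda <- 2
  LHS <- rbind(cbind(2 * crossprod(inc$X), 2 * crossprod(as.matrix(inc$X),
                                                         as.matrix(inc$Z))),
               cbind(t(2 * crossprod(as.matrix(inc$X), as.matrix(inc$Z))),
                     2 * crossprod(as.matrix(inc$Z)) + lambda * as.matrix(Ai)))
  rhs <- c(2 * crossprod(as.matrix(inc$X), inc$y),
           2 * crossprod(as.matrix(inc$Z), inc$y))
  manual <- solve(LHS, rhs)
  expect_equal(unname(c(sol2$b_hat, sol2$gebv)), unname(manual),
               tolerance = 1e-8)
})

test_that("fitted records are invariant to the fixed-effect reference choice", {
  tm <- make_toy_model(seed = 61)
  tm$ph$region <- factor(sample(c("r1", "r2", "r3"), nrow(tm$ph),
                                replace = TRUE))
  spec <- model_spec("y", c("herd", "region"), character(), 1, 1)
  Ai <- make_A_inverse(tm$ped)
  inc <- build_incidence(tm$ph, spec, tm$ped$animal)
  sol <- solve_mme(inc$X, inc$Z, inc$y, Ai, spec)
  # relevel the second factor: different constraint, same fitted values
  ph2 <- tm$ph
  ph2$region <- relevel(ph2$region, "r3")
  inc2 <- build_incidence(ph2, spec, tm$ped$animal)
  sol2 <- solve_mme(inc2$X, inc2$Z, inc2$y, Ai, spec)
  yhat1 <- as.matrix(inc$X) %*% sol$b_hat + as.matrix(inc$Z) %*% sol$gebv
  yhat2 <- as.matrix(inc2$X) %*% sol2$b_hat + as.matrix(inc2$Z) %*% sol2$gebv
  expect_equal(yhat1, yhat2, tolerance = 1e-6)
  expect_equal(sol$gebv, sol2$gebv, tolerance = 1e-6)
})

test_that("DGV matches hand inverses and the conditional-expectation oracle", {
  # identity G: no information flows from relatives
  expect_equal(compute_dgv(diag(3), c(a = 1, b = 2, c = 3)),
               c(a = 0, b = 0, c = 0), ignore_attr = TRUE)
  # 2x2 hand inverse
  Ginv <- solve(matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(unname(compute_dgv(Ginv, c(1, 0))), c(0, 0.5))
  # 8x8 SPD: DGV_i is the best linear prediction of a_i from the others
  set.seed(71)
  B <- matrix(rnorm(64), 8)
  G <- crossprod(B) / 8 + diag(8) * 0.5
  a <- rnorm(8)
  dgv <- compute_dgv(solve(G), a)
  oracle <- vapply(1:8, function(i)
    drop(G[i, -i] %*% solve(G[-i, -i], a[-i])), numeric(1))
  expect_equal(unname(dgv), oracle, tolerance = 1e-10)
})
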
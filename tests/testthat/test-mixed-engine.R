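test_that("REML matches the closed-form one-way ANOVA estimator", {
  set.seed(1)
  a <- 10; r <- 4
  fac <- rep(seq_len(a), each = r)
  y <- rep(rnorm(a, 0, sqrt(1.5)), each = r) + rnorm(a * r, 0, 1)
  Z <- stats::model.matrix(~ 0 + factor(fac))
  fit <- fit_reml(lmm_spec(y, random = list(g = list(Z = Z))))
  gm <- tapply(y, fac, mean)
  MSA <- r * sum((gm - mean(y))^2) / (a - 1)
  MSE <- sum((y - gm[fac])^2) / (a * (r - 1))
  expect_true(fit$converged)
  expect_equal(unname(fit$sigma2["g"]), (MSA - MSE) / r, tolerance = 1e-6)
  expect_equal(unname(fit$sigma2["residual"]), MSE, tolerance = 1e-6)
})

test_that("REML agrees with lme4 on unbalanced grouped data", {
  skip_if_not_installed("lme4")
  set.seed(2)
  ng <- 12
  sizes <- sample(2:6, ng, replace = TRUE)
  fac <- rep(seq_len(ng), sizes)
  x <- rnorm(length(fac))
  y <- 1 + 0.5 * x + rep(rnorm(ng, 0, 0.8), sizes) + rnorm(length(fac), 0, 0.6)
  Z <- stats::model.matrix(~ 0 + factor(fac))
  fit <- fit_reml(lmm_spec(y, cbind(1, x), random = list(g = list(Z = Z))))
  lf <- lme4::lmer(y ~ x + (1 | fac), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(fit$sigma2["g"]), vc$vcov[1], tolerance = 1e-4)
  expect_equal(unname(fit$sigma2["residual"]), vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-4)
})

test_that("degenerate constant responses give zero variances and finite loglik", {
  fit <- fit_reml(lmm_spec(rep(3, 25), random = list(g = list(K = diag(25)))))
  expect_equal(unname(fit$sigma2), c(0, 0))
  expect_true(is.finite(fit$loglik))
})

test_that("the fitted optimum beats a dense grid search on a 30-observation fixture", {
  set.seed(3)
  n <- 30
  K1 <- tcrossprod(matrix(rnorm(n * 3), n, 3)) / 3 + diag(0.1, n)
  K2 <- tcrossprod(stats::model.matrix(~ 0 + factor(rep(1:5, each = 6))))
  L1 <- chol(K1)
  y <- drop(crossprod(L1, rnorm(n))) * 0.7 +
    rep(rnorm(5, 0, 0.8), each = 6) + rnorm(n, 0, 0.5)
  spec <- lmm_spec(y, random = list(k1 = list(K = K1), k2 = list(K = K2)))
  fit <- fit_reml(spec)
  vy <- var(y)
  grid <- vy * exp(seq(log(0.01), log(3), length.out = 17))
  best_grid <- -Inf
  for (s1 in grid) for (s2 in grid) for (se in grid)
    best_grid <- max(best_grid, reml_loglik(spec, c(s1, s2, se)))
  expect_gte(fit$loglik, best_grid - 1e-6)
})

test_that("solve_mme reproduces a hand-worked GLS solution", {
  # 6 observations, one grouped random effect with known variances
  y <- c(1.2, 0.8, 2.1, 1.9, 3.0, 2.5)
  X <- cbind(1, c(0, 0, 1, 1, 2, 2))
  colnames(X) <- c("int", "slope")
  Z <- stats::model.matrix(~ 0 + factor(c(1, 1, 2, 2, 3, 3)))
  s2g <- 0.4; s2e <- 0.3
  sol <- solve_mme(lmm_spec(y, X, random = list(g = list(Z = Z))),
                   c(s2g, s2e))
  V <- s2g * tcrossprod(Z) + diag(s2e, 6)
  beta_hand <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% y)
  u_hand <- s2g * t(Z) %*% solve(V) %*% (y - X %*% beta_hand)
  expect_equal(unname(sol$beta), unname(drop(beta_hand)), tolerance = 1e-10)
  expect_equal(unname(sol$blups$g), unname(drop(u_hand)), tolerance = 1e-10)
  # zero-variance term has exactly-zero BLUPs
  sol0 <- solve_mme(lmm_spec(y, X, random = list(g = list(Z = Z))),
                    c(0, s2e))
  expect_equal(unname(sol0$blups$g), rep(0, 3))
})

test_that("identity-kernel BLUPs equal the ridge-regression solution", {
  set.seed(4)
  n <- 40
  y <- rnorm(n, 2, 1)
  s2g <- 0.5; s2e <- 0.8
  sol <- solve_mme(lmm_spec(y, random = list(g = list(K = diag(n)))),
                   c(s2g, s2e))
  lambda <- s2e / s2g
  Xf <- matrix(1, n, 1)
  beta <- sol$beta
  u_ridge <- solve(diag(n) + diag(lambda, n), y - drop(Xf %*% beta))
  expect_equal(unname(sol$blups$g), drop(u_ridge), tolerance = 1e-8)
})

test_that("rank-deficient fixed designs are rejected with the aliased columns", {
  y <- rnorm(10)
  X <- cbind(a = rep(1, 10), b = rep(1, 10))
  Z <- stats::model.matrix(~ 0 + factor(rep(1:2, 5)))
  expect_error(solve_mme(lmm_spec(y, X, random = list(g = list(Z = Z))),
                         c(0.1, 0.1)), "aliased.*b")
  expect_error(fit_reml(lmm_spec(y, X, random = list(g = list(Z = Z)))),
               "singular")
})

test_that("predictions are invariant to observation order", {
  set.seed(5)
  n <- 30
  K <- tcrossprod(matrix(rnorm(n * 4), n, 4)) / 4 + diag(0.05, n)
  y <- drop(chol(K) %*% rnorm(n)) + rnorm(n, 0, 0.5)
  spec <- lmm_spec(y, random = list(g = list(K = K)))
  sol <- solve_mme(spec, c(0.7, 0.4))
  perm <- sample(n)
  spec_p <- lmm_spec(y[perm], random = list(g = list(K = K[perm, perm])))
  sol_p <- solve_mme(spec_p, c(0.7, 0.4))
  expect_equal(sol_p$fitted, sol$fitted[perm], tolerance = 1e-10)
})

test_that("REML never decreases the restricted likelihood from its start", {
  set.seed(6)
  for (s in 1:3) {
    n <- 40
    K <- tcrossprod(matrix(rnorm(n * 3), n, 3)) / 3 + diag(0.1, n)
    y <- drop(chol(K) %*% rnorm(n)) * 0.4 + rnorm(n, 0, 1)
    spec <- lmm_spec(y, random = list(g = list(K = K)))
    init <- c(var(y) / 2, var(y) / 2)
    fit <- fit_reml(spec, init = init)
    expect_gte(fit$loglik, reml_loglik(spec, init) - 1e-8)
  }
})

test_that("the bivariate fit recovers a self-correlation of one", {
  s <- sim_single(51, n = 80, m = 400)
  yv <- s$met$truth$breeding_values[, 1] + rnorm(80, 0, 0.2)
  names(yv) <- rownames(s$G)
  est <- estimate_gc(yv, yv, s$G)
  expect_equal(est$r_a, 1, tolerance = 1e-6)
  expect_lt(est$pvalue, 1e-6)
})

test_that("the bivariate fit flags degenerate and small-sample inputs", {
  s <- sim_single(52, n = 40, m = 200)
  noise <- rnorm(40); names(noise) <- rownames(s$G)
  expect_warning(fit_multivariate_gc(noise[1:20], noise[1:20], s$G),
                 "shared lines")
})

test_that("the Gibbs sampler is deterministic under a fixed seed", {
  set.seed(7)
  n <- 60
  y <- rnorm(n, 5, 1)
  spec <- lmm_spec(y, random = list(g = list(K = diag(n))))
  f1 <- gibbs_multikernel(spec, n_iter = 600, burn_in = 100, thin = 2,
                          seed = 9)
  f2 <- gibbs_multikernel(spec, n_iter = 600, burn_in = 100, thin = 2,
                          seed = 9)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_identical(f1$fitted, f2$fitted)
})

test_that("a constant response keeps Gibbs variances near zero and predictions flat", {
  n <- 50
  spec <- lmm_spec(rep(2.5, n), random = list(g = list(K = diag(n))))
  fit <- gibbs_multikernel(spec, n_iter = 1000, burn_in = 200, thin = 2,
                           seed = 3)
  expect_lt(max(fit$sigma2), 1e-4)
  expect_lt(diff(range(fit$fitted)), 0.05)
})

test_that("indefinite kernels are rejected by the sampler", {
  n <- 10
  K <- diag(n); K[1, 1] <- -1
  spec <- lmm_spec(rnorm(n), random = list(g = list(K = K)))
  expect_error(gibbs_multikernel(spec, n_iter = 100, burn_in = 10, seed = 1),
               "eigenvalue")
})
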
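test_that("reaction-norm kernels match their elementwise definition", {
  s <- sim_single(81, n = 5, m = 60)
  G <- unclass(s$G)
  lines <- rownames(G)
  v <- list(E1 = stats::setNames(rnorm(5), lines),
            E2 = stats::setNames(rnorm(4), lines[1:4]))
  st <- stack_phenotypes(v)
  ker <- build_gxe_kernels(st, s$G)
  recs <- st$records
  n <- nrow(recs)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    same_env <- recs$env[i] == recs$env[j]
    gij <- G[recs$line[i], recs$line[j]]
    expect_equal(ker$K_env[i, j], as.numeric(same_env))
    expect_equal(ker$K_g[i, j], gij, tolerance = 1e-12)
    expect_equal(ker$K_gxe[i, j], gij * same_env, tolerance = 1e-12)
  }
  # different lines in different environments: zero interaction covariance
  i <- which(recs$env == "E1")[1]; j <- which(recs$env == "E2")[2]
  expect_equal(ker$K_gxe[i, j], 0)
  # same line, same environment: the G diagonal
  expect_equal(ker$K_gxe[1, 1], G[recs$line[1], recs$line[1]])
  # Schur product of PSD kernels is PSD
  expect_gt(min(eigen(ker$K_gxe, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-8)
  # unknown lines are reported
  v_bad <- list(E1 = stats::setNames(rnorm(2), c("nope1", "nope2")))
  expect_error(build_gxe_kernels(stack_phenotypes(v_bad), s$G),
               "absent from the GRM")
})

test_that("masked records never influence fitted effects", {
  p <- sim_pair(82, 0.6, n = 60, m = 300)
  st <- stack_phenotypes(p$v, mask_envs = "TPE")
  f1 <- suppressWarnings(fit_gxe(st, p$G, backend = "reml"))
  st2 <- st
  st2$records$value[st2$records$mask] <-
    st2$records$value[st2$records$mask] + 100
  f2 <- suppressWarnings(fit_gxe(st2, p$G, backend = "reml"))
  expect_equal(f1$predictions, f2$predictions, tolerance = 1e-10)
  g1 <- suppressWarnings(fit_gxe(st, p$G, backend = "gibbs", n_iter = 400,
                                 burn_in = 100, seed = 5))
  g2 <- suppressWarnings(fit_gxe(st2, p$G, backend = "gibbs", n_iter = 400,
                                 burn_in = 100, seed = 5))
  expect_equal(g1$predictions, g2$predictions, tolerance = 1e-10)
})

test_that("single-environment input reduces to GBLUP", {
  s <- sim_single(83, n = 80, m = 400)
  y <- line_means(s$met$records, "E1")
  st <- stack_phenotypes(list(E1 = y))
  expect_warning(fit <- fit_gxe(st, s$G, backend = "reml"), "GBLUP")
  spec <- lmm_spec(unname(y[st$records$line]),
                   random = list(g = list(K = unclass(s$G)[st$records$line,
                                                           st$records$line])))
  gb <- fit_reml(spec)
  expect_gt(cor(fit$predictions, gb$fitted), 1 - 1e-6)
})

test_that("the EL model transfers perfectly when rankings are identical and noise-free", {
  set.seed(84)
  n <- 40
  g <- rnorm(n, 0, 0.5)
  lines <- sprintf("L%03d", 1:n)
  v <- list(A = stats::setNames(5 + g, lines),
            B = stats::setNames(4 + g, lines))
  st <- stack_phenotypes(v, mask_envs = "B")
  fit <- fit_el(st, backend = "reml")
  m <- st$records$mask
  expect_equal(cor(fit$predictions[m], st$records$value[m]), 1,
               tolerance = 1e-6)
})

test_that("a GxE-free simulation yields a small estimated interaction variance", {
  ratios <- vapply(1:5, function(s) {
    p <- sim_pair(s + 850, r = 1, n = 150, m = 600)  # GC = 1: no interaction
    st <- stack_phenotypes(p$v)
    pv <- partition_variance(st, p$G, backend = "reml")
    pv$components[["sigma_gxe2"]] / max(pv$components[["sigma_g2"]], 1e-12)
  }, 0)
  expect_lt(mean(ratios), 0.10)
})

test_that("the variance partition recovers realized components of a two-environment stack", {
  # reaction-norm truth: per-environment genetic variance 0.2 with GC 0.5
  # splits into main 0.1 + interaction 0.1; plot error 0.4 over 2 reps gives
  # 0.2 at the line-mean scale; environment effects drawn with variance 1.
  # With 2 environment levels the environment component has ~1 df, so
  # recovery is judged against the REALIZED component variances.
  res <- vapply(1:10, function(s) {
    p <- sim_pair(s + 40, 0.5, n = 500, m = 1000, sigma_g2 = 0.2,
                  env_variance = 1.0, h2_plot = 1 / 3)
    st <- stack_phenotypes(p$v)
    pv <- partition_variance(st, p$G, backend = "reml")
    bv <- p$met$truth$breeding_values
    ee <- attr(p$met$records, "env_effects")
    realized <- c(cov(bv[, 1], bv[, 2]),
                  var(ee),
                  mean(apply(bv, 2, var)) - cov(bv[, 1], bv[, 2]),
                  mean(vapply(c("SE", "TPE"), function(e)
                    var(p$v[[e]][rownames(bv)] - bv[, e] - ee[e]), 0)))
    c(pv$components, realized)
  }, numeric(8))
  est <- rowMeans(res[1:4, , drop = FALSE])
  realized <- rowMeans(res[5:8, , drop = FALSE])
  expect_true(all(abs(est - realized) / realized < 0.30))
})

test_that("the across-environment heritability approaches one without noise", {
  set.seed(85)
  p <- sim_pair(86, r = 1, n = 100, m = 500, h2_plot = 1 - 1e-9)
  st <- stack_phenotypes(p$v)
  pv <- partition_variance(st, p$G, backend = "reml")
  expect_gt(pv$h2, 0.97)
})

test_that("variance ratio strings are computed from unrounded components", {
  expect_equal(variance_ratio_string(c(0.08, 1.45, 0.08, 0.13)),
               "1:18.1:1:1.6")
  expect_error(variance_ratio_string(c(0, 1, 1, 1)), "positive")
})

test_that("pairwise prediction enumerates pairs and hits the self-transfer limit", {
  p1 <- sim_pair(87, 0.5, n = 40, m = 200)
  ses <- list(SE1 = p1$v$SE, SE2 = p1$v$SE + 0.5)
  tpes <- list(T1 = p1$v$TPE, T2 = p1$v$TPE * 1.1, T3 = p1$v$SE)
  res <- run_pairwise(ses, tpes, p1$G, backend = "reml")
  expect_equal(nrow(res), 12L)  # 2 SEs x 3 TPEs x 2 models
  expect_setequal(unique(res$model), c("GxE", "EL"))
  # a target identical to the selection environment transfers perfectly:
  # the EL prediction is a uniform shrinkage of the SE phenotype (PA = 1);
  # the genomic prediction is near-perfect but smooths through markers
  self <- res[res$selection_env == "SE1" & res$target_env == "T3", ]
  expect_equal(self$phenotypic_corr[1], 1, tolerance = 1e-12)
  expect_gt(self$pa[self$model == "EL"], 0.999)
  expect_gt(self$pa[self$model == "GxE"], 0.8)
  # pairs with too few shared lines are skipped with a reason
  few <- list(Tfew = p1$v$TPE[1:5])
  res2 <- run_pairwise(ses["SE1"], few, p1$G, backend = "reml")
  expect_equal(nrow(res2), 0L)
  expect_match(attr(res2, "skipped")$reason, "shared lines")
})

test_that("PA comparisons match direct computation on hand-set pairs", {
  pa_g <- c(0.31, 0.25, 0.40, 0.12, 0.50, 0.28, 0.33, 0.19, 0.44, 0.27)
  pa_e <- c(0.30, 0.27, 0.38, 0.10, 0.52, 0.25, 0.35, 0.18, 0.42, 0.28)
  cmp <- compare_pa_models(pa_gxe = pa_g, pa_el = pa_e)
  expect_equal(cmp$correlation, cor(pa_g, pa_e))
  expect_equal(cmp$mean_diff, mean(pa_g - pa_e))
  expect_equal(cmp$t_pvalue, t.test(pa_g - pa_e)$p.value)
  same <- compare_pa_models(pa_gxe = pa_g, pa_el = pa_g)
  expect_equal(same$correlation, 1)
  expect_equal(same$mean_diff, 0)
})

test_that("Gibbs and REML backends agree on pair predictions", {
  p <- sim_pair(88, 0.6, n = 120, m = 500)
  st <- stack_phenotypes(p$v, mask_envs = "TPE")
  fr <- suppressWarnings(fit_gxe(st, p$G, backend = "reml"))
  fg <- suppressWarnings(fit_gxe(st, p$G, backend = "gibbs",
                                 n_iter = 2500, burn_in = 500, seed = 4))
  m <- st$records$mask
  expect_gt(cor(fr$predictions[m], fg$predictions[m]), 0.98)
})
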
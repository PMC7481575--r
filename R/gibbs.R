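#' Gibbs sampler for multi-kernel Gaussian models
#'
#' Bayesian counterpart of [fit_reml()] for models of the form
#' `y = X b + sum_k u_k + e` with `u_k ~ N(0, sigma2_k K_k)` on the
#' observation scale. Each kernel is eigendecomposed once and its effects
#' are sampled in the eigenbasis (where, for fully observed responses, the
#' conditional posterior is diagonal). Variance components carry scaled
#' inverse chi-square priors with `prior_df` degrees of freedom and scales
#' set from the response variance partitioned equally across terms
#' (total prior R2 = `prior_R2`, residual gets the remainder). Missing
#' responses (`NA`) are handled by data augmentation, so they never inform
#' the fitted effects; their posterior-mean fitted values are the
#' predictions.
#'
#' @param spec An [lmm_spec()] (missing responses allowed as `NA`).
#' @param n_iter,burn_in,thin Chain length, burn-in, thinning.
#' @param seed Integer seed; fixed seed gives identical posterior means.
#' @param prior_df Prior degrees of freedom (default 5).
#' @param prior_R2 Prior proportion of variance attributed to the random
#'   terms jointly (default 0.5).
#' @return Object of class `gibbs_fit`: posterior means `sigma2`, `beta`,
#'   `u` (list per term, observation scale), `fitted`, effective sample
#'   sizes `ess` for the variance components, and the variance-component
#'   chains (`chains`).
#' @export
gibbs_multikernel <- function(spec, n_iter = 12000, burn_in = 2000,
                              thin = 5, seed = 1L, prior_df = 5,
                              prior_R2 = 0.5) {
  stopifnot(inherits(spec, "lmm_spec_na") || inherits(spec, "lmm_spec"))
  y <- spec$y; X <- spec$X; n <- spec$n
  k <- length(spec$random)
  obs <- !is.na(y)
  vy <- stats::var(y[obs])
  if (!is.finite(vy) || vy <= 0) vy <- 1e-6
  # kernel eigenstructures (bend slightly negative eigenvalues; error if
  # clearly indefinite)
  eig <- lapply(spec$random, function(term) {
    Kt <- term_vmat(term, n)
    e <- eigen((Kt + t(Kt)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values), 1))
      stop("kernel has negative eigenvalue ", format(min(e$values)),
           " after bending tolerance")
    keep <- e$values > max(e$values) * 1e-10
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })
  S0 <- vapply(seq_len(k), function(i) {
    mean_diag <- sum(eig[[i]]$d) / n
    (prior_R2 / k) * vy * (prior_df + 2) / prior_df / max(mean_diag, 1e-12)
  }, 0)
  S0e <- (1 - prior_R2) * vy * (prior_df + 2) / prior_df
  with_seed(seed, {
    yc <- y
    yc[!obs] <- mean(y[obs])
    b_list <- lapply(eig, function(e) numeric(length(e$d)))
    u_list <- lapply(seq_len(k), function(i) numeric(n))
    sigma2 <- rep(vy * prior_R2 / k, k)
    sigma2_e <- vy * (1 - prior_R2)
    XtXinv <- solve(crossprod(X))
    cholXtXinv <- chol(XtXinv)
    beta <- drop(XtXinv %*% crossprod(X, yc))
    keep_iters <- seq(burn_in + 1L, n_iter, by = thin)
    n_keep <- length(keep_iters)
    sum_beta <- numeric(ncol(X))
    sum_u <- lapply(seq_len(k), function(i) numeric(n))
    sum_fit <- numeric(n)
    chains <- matrix(0, n_keep, k + 1L,
                     dimnames = list(NULL, c(names(spec$random), "residual")))
    kept <- 0L
    for (it in seq_len(n_iter)) {
      # fixed effects (flat prior)
      resid <- yc - Reduce(`+`, u_list, numeric(n))
      bhat <- drop(XtXinv %*% crossprod(X, resid))
      beta <- bhat + drop(t(cholXtXinv) %*% stats::rnorm(ncol(X))) *
        sqrt(sigma2_e)
      xb <- drop(X %*% beta)
      # kernel effects in their eigenbases
      for (i in seq_len(k)) {
        e <- eig[[i]]
        r_i <- yc - xb - Reduce(`+`, u_list[-i], numeric(n))
        z <- drop(crossprod(e$U, r_i))
        prec <- 1 / sigma2_e + 1 / (sigma2[i] * e$d)
        mu_b <- (z / sigma2_e) / prec
        b <- mu_b + stats::rnorm(length(z)) / sqrt(prec)
        b_list[[i]] <- b
        u_list[[i]] <- drop(e$U %*% b)
      }
      # variance components
      for (i in seq_len(k)) {
        e <- eig[[i]]
        ss <- sum(b_list[[i]]^2 / e$d)
        m_i <- length(e$d)
        sigma2[i] <- (ss + prior_df * S0[i]) /
          stats::rchisq(1, prior_df + m_i)
      }
      fit <- xb + Reduce(`+`, u_list, numeric(n))
      err <- yc - fit
      sigma2_e <- (sum(err[obs]^2) + prior_df * S0e) /
        stats::rchisq(1, prior_df + sum(obs))
      # augment missing responses
      if (any(!obs))
        yc[!obs] <- fit[!obs] + stats::rnorm(sum(!obs)) * sqrt(sigma2_e)
      if (it %in% keep_iters) {
        kept <- kept + 1L
        sum_beta <- sum_beta + beta
        for (i in seq_len(k)) sum_u[[i]] <- sum_u[[i]] + u_list[[i]]
        sum_fit <- sum_fit + fit
        chains[kept, ] <- c(sigma2, sigma2_e)
      }
    }
    post_u <- lapply(sum_u, `/`, kept)
    names(post_u) <- names(spec$random)
    ess <- apply(chains, 2, ess_batch_means)
    structure(list(
      sigma2 = stats::setNames(colMeans(chains),
                               c(names(spec$random), "residual")),
      beta = stats::setNames(sum_beta / kept, colnames(X)),
      u = post_u, fitted = sum_fit / kept, ess = ess,
      chains = chains, n_kept = kept), class = "gibbs_fit")
  })
}

# effective sample size by the batch-means method
ess_batch_means <- function(x) {
  n <- length(x)
  if (n < 20 || stats::var(x) == 0) return(n)
  b <- max(2L, floor(sqrt(n)))
  nb <- floor(n / b)
  bm <- colMeans(matrix(x[seq_len(nb * b)], b, nb))
  v_bm <- stats::var(bm)
  if (v_bm <= 0) return(n)
  min(n, n * stats::var(x) / (b * v_bm * nb / (nb - 1)))
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat("Gibbs fit,", x$n_kept, "kept samples\nposterior-mean variances:\n")
  print(x$sigma2)
  invisible(x)
}

#' Specify a mixed model with possibly-missing responses
#'
#' Like [lmm_spec()] but `NA` responses are allowed (only
#' [gibbs_multikernel()] and the prediction wrappers accept these).
#'
#' @inheritParams lmm_spec
#' @return Object of classes `lmm_spec_na` and `lmm_spec`.
#' @export
lmm_spec_na <- function(y, X = NULL, random = list()) {
  y <- as.numeric(y)
  obs <- !is.na(y)
  if (sum(obs) < 2) stop("need at least 2 observed responses")
  tmp <- y; tmp[!obs] <- 0
  sp <- lmm_spec(tmp, X, random)
  sp$y <- y
  class(sp) <- c("lmm_spec_na", "lmm_spec")
  sp
}
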
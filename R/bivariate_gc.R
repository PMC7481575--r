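#' Bivariate genetic (co)variance between two environments
#'
#' Fits the bivariate Gaussian mixed model
#' `y_e = mu_e + g_e + eps_e`, `(g_1, g_2) ~ N(0, G2 (x) K)`,
#' `eps_e ~ N(0, r_e I)` (residuals independent across environments, since
#' per-environment BLUEs from separate trials share no plot error), by
#' restricted-likelihood expectation-maximisation in the eigenbasis of the
#' kinship `K`, where the model decouples into independent 2-dimensional
#' observations. The per-environment means are re-estimated by generalised
#' least squares at each iteration and their sampling uncertainty enters
#' both the E-step moments and the reported (restricted) log-likelihood.
#' Convergence is declared when the relative change in the log-likelihood
#' is at most `tol`.
#'
#' @param blues_x,blues_y Named numeric vectors (names = line ids) of
#'   per-environment line values, or `blue_table` data frames with columns
#'   `line` and `blue`.
#' @param grm A [compute_grm()] matrix covering all shared lines.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param constrain_cov If `TRUE`, the genetic covariance is constrained to
#'   zero (diagonal `G2`); used as the null model of the likelihood-ratio
#'   test in [estimate_gc()].
#' @return List: `G` (2x2 additive covariance), `R` (length-2 residual
#'   variances), `loglik`, `converged`, `n_iter`, `n_shared`,
#'   `projected` (TRUE if the fitted G was projected to the nearest PSD).
#' @export
fit_multivariate_gc <- function(blues_x, blues_y, grm, tol = 1e-8,
                                max_iter = 5000, constrain_cov = FALSE) {
  bx <- as_named_values(blues_x)
  by <- as_named_values(blues_y)
  shared <- intersect(names(bx), names(by))
  shared <- shared[shared %in% rownames(grm)]
  n <- length(shared)
  if (n < 2) stop("need at least 2 shared lines covered by the GRM")
  if (n < 30)
    warning("only ", n, " shared lines; genetic correlation will be imprecise")
  K <- unclass(grm)[shared, shared]
  K <- K / mean(diag(K))   # unit mean diagonal: G is on the line scale
  Y <- cbind(bx[shared], by[shared])
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eK$values, 0)
  U <- eK$vectors
  Yt <- crossprod(U, Y)            # n x 2, rows decouple
  y1 <- Yt[, 1]; y2 <- Yt[, 2]
  tvec <- drop(crossprod(U, rep(1, n)))
  pos <- d > max(d) * 1e-12
  n_pos <- sum(pos)
  vy <- apply(Y, 2, stats::var)
  G <- 0.5 * stats::cov(Y) + diag(1e-4 * mean(vy), 2)
  if (constrain_cov) G[1, 2] <- G[2, 1] <- 0
  R <- pmax(0.5 * vy, 1e-8)
  floor_r <- 1e-12 * mean(vy)
  jit2 <- (1e-14 * mean(vy))^2
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Cg11 <- d * G[1, 1]; Cg12 <- d * G[1, 2]; Cg22 <- d * G[2, 2]
    V11 <- Cg11 + R[1]; V22 <- Cg22 + R[2]; V12 <- Cg12
    det <- pmax(V11 * V22 - V12^2, jit2)
    W11 <- V22 / det; W22 <- V11 / det; W12 <- -V12 / det
    # GLS means
    t2 <- tvec^2
    A11 <- sum(t2 * W11); A22 <- sum(t2 * W22); A12 <- sum(t2 * W12)
    b1 <- sum(tvec * (W11 * y1 + W12 * y2))
    b2 <- sum(tvec * (W12 * y1 + W22 * y2))
    A <- matrix(c(A11, A12, A12, A22), 2)
    Vmu <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Vmu) || !all(is.finite(Vmu))) break
    mu <- drop(Vmu %*% c(b1, b2))         # GLS means and their variance
    e1 <- y1 - tvec * mu[1]; e2 <- y2 - tvec * mu[2]
    ll <- -0.5 * sum(log(det) + W11 * e1^2 + 2 * W12 * e1 * e2 +
                       W22 * e2^2) -
      0.5 * determinant(A, logarithm = TRUE)$modulus[1]
    # E-step: posterior mean m and covariance P of the genetic part
    u1 <- W11 * e1 + W12 * e2
    u2 <- W12 * e1 + W22 * e2
    m1 <- Cg11 * u1 + Cg12 * u2
    m2 <- Cg12 * u1 + Cg22 * u2
    T11 <- W11 * Cg11 + W12 * Cg12; T12 <- W11 * Cg12 + W12 * Cg22
    T21 <- W12 * Cg11 + W22 * Cg12; T22 <- W12 * Cg12 + W22 * Cg22
    P11 <- Cg11 - (Cg11 * T11 + Cg12 * T21)
    P12 <- Cg12 - (Cg11 * T12 + Cg12 * T22)
    P22 <- Cg22 - (Cg12 * T12 + Cg22 * T22)
    # restricted-likelihood correction: uncertainty of the GLS means
    # propagates through the same weights into the second moments
    v11 <- Vmu[1, 1]; v12 <- Vmu[1, 2]; v22 <- Vmu[2, 2]
    VT11 <- v11 * T11 + v12 * T21; VT12 <- v11 * T12 + v12 * T22
    VT21 <- v12 * T11 + v22 * T21; VT22 <- v12 * T12 + v22 * T22
    MG11 <- T11 * VT11 + T21 * VT21
    MG12 <- T11 * VT12 + T21 * VT22
    MG22 <- T12 * VT12 + T22 * VT22
    RW11 <- R[1] * W11; RW12 <- R[1] * W12
    RW21 <- R[2] * W12; RW22 <- R[2] * W22
    VR11 <- v11 * RW11 + v12 * RW21; VR12 <- v11 * RW12 + v12 * RW22
    VR21 <- v12 * RW11 + v22 * RW21; VR22 <- v12 * RW12 + v22 * RW22
    ME11 <- RW11 * VR11 + RW21 * VR21
    ME22 <- RW12 * VR12 + RW22 * VR22
    # M-step
    dp <- d[pos]
    t2p <- t2[pos]
    G_new <- matrix(c(
      sum((m1[pos]^2 + P11[pos] + t2p * MG11[pos]) / dp),
      sum((m1[pos] * m2[pos] + P12[pos] + t2p * MG12[pos]) / dp),
      sum((m1[pos] * m2[pos] + P12[pos] + t2p * MG12[pos]) / dp),
      sum((m2[pos]^2 + P22[pos] + t2p * MG22[pos]) / dp)) / n_pos, 2)
    if (constrain_cov) G_new[1, 2] <- G_new[2, 1] <- 0
    r1 <- e1 - m1; r2 <- e2 - m2
    R_new <- c(sum(r1^2 + R[1] - R[1]^2 * W11 + t2 * ME11),
               sum(r2^2 + R[2] - R[2]^2 * W22 + t2 * ME22)) / n
    R_new <- pmax(R_new, floor_r)
    # boundary of the parameter space (or numerically degenerate input)
    if (!is.finite(ll) || !all(is.finite(G_new)) || !all(is.finite(R_new)))
      break
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-8)) {
      converged <- TRUE
      G <- G_new; R <- R_new
      break
    }
    ll_old <- ll
    G <- G_new; R <- R_new
  }
  projected <- FALSE
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < 0) {
    G <- eg$vectors %*% diag(pmax(eg$values, 0), 2) %*% t(eg$vectors)
    projected <- TRUE
  }
  dimnames(G) <- NULL
  list(G = G, R = R, loglik = ll_old, converged = converged, n_iter = it,
       n_shared = n, projected = projected)
}

as_named_values <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("line", "blue") %in% names(x)))
      stop("data frame input must have columns line and blue")
    stats::setNames(x$blue, x$line)
  } else {
    if (is.null(names(x))) stop("numeric input must be named by line id")
    x
  }
}
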
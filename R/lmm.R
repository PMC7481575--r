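#' Specify a Gaussian linear mixed model
#'
#' `y = X b + sum_k Z_k u_k + e`, with `u_k ~ N(0, sigma2_k K_k)` and
#' `e ~ N(0, sigma2_e I)`. Each random term is a list with an incidence
#' matrix `Z` (or `NULL` for the identity, i.e. one effect per observation)
#' and a covariance kernel `K` (or `NULL` for the identity), plus an
#' optional `label`.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix; `NULL` gives an intercept-only model.
#' @param random List of random terms, each `list(Z=, K=, label=)`.
#' @return Object of class `lmm_spec`.
#' @export
lmm_spec <- function(y, X = NULL, random = list()) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X must have one row per observation")
  if (!length(random)) stop("at least one random term is required")
  if (n <= ncol(X)) stop("need more observations than fixed effects")
  labs <- character(length(random))
  for (k in seq_along(random)) {
    term <- random[[k]]
    if (!is.null(term$Z)) {
      term$Z <- as.matrix(term$Z)
      if (nrow(term$Z) != n) stop("random term ", k, ": Z has wrong row count")
    }
    if (!is.null(term$K)) {
      term$K <- as.matrix(term$K)
      q <- if (is.null(term$Z)) n else ncol(term$Z)
      if (!all(dim(term$K) == q))
        stop("random term ", k, ": K must be ", q, "x", q)
      if (max(abs(term$K - t(term$K))) > 1e-8)
        stop("random term ", k, ": K must be symmetric")
    }
    labs[k] <- if (!is.null(term$label)) term$label
      else if (!is.null(names(random)) && nzchar(names(random)[k]))
        names(random)[k]
      else paste0("term", k)
    random[[k]] <- term
  }
  if (anyDuplicated(labs)) labs <- make.unique(labs)
  names(random) <- labs
  structure(list(y = y, X = X, random = random, n = n),
            class = "lmm_spec")
}

# observation-scale covariance contribution Z K Z' of one random term
term_vmat <- function(term, n) {
  if (is.null(term$Z)) {
    if (is.null(term$K)) diag(n) else term$K
  } else {
    if (is.null(term$K)) tcrossprod(term$Z)
    else term$Z %*% term$K %*% t(term$Z)
  }
}

# REML core quantities at variance components theta (k terms + residual)
reml_eval <- function(y, X, Vmats, theta) {
  n <- length(y)
  k <- length(Vmats)
  V <- diag(theta[k + 1L], n)
  for (i in seq_len(k)) V <- V + theta[i] * Vmats[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  W <- Vinv %*% X
  XtWX <- crossprod(X, W)
  chX <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  Cinv <- chol2inv(chX)
  B <- W %*% Cinv %*% t(W)
  P <- Vinv - B
  Py <- drop(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                  sum(y * Py))
  list(V = V, Vinv = Vinv, P = P, Py = Py, loglik = ll, Cinv = Cinv, W = W)
}

#' Fit a mixed model by average-information REML
#'
#' Variance components are updated by average-information (AI) steps with
#' step-halving; whenever an AI step fails to increase the restricted
#' log-likelihood (or proposes an inadmissible component) the iteration
#' falls back to the monotone EM-REML update. Components are clamped at a
#' small positive floor. Fixed effects (generalised least squares) and
#' random-effect predictions (BLUPs via Henderson's equations) are returned
#' at the converged components.
#'
#' @param spec An [lmm_spec()].
#' @param tol Convergence tolerance on the score (gradient) norm.
#' @param max_iter Maximum iterations; on non-convergence the best iterate
#'   is returned flagged `converged = FALSE`.
#' @param init Optional initial variance components (k terms + residual).
#' @return Object of class `reml_fit`: `sigma2` (named, residual last),
#'   `loglik`, `converged`, `n_iter`, `beta` (fixed effects), `beta_se`,
#'   `blups` (list per term, on the effect scale), `fitted`, plus internals
#'   used for prediction.
#' @export
fit_reml <- function(spec, tol = 1e-6, max_iter = 200, init = NULL) {
  stopifnot(inherits(spec, "lmm_spec"))
  y <- spec$y; X <- spec$X; n <- spec$n
  k <- length(spec$random)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")
  Vmats <- lapply(spec$random, term_vmat, n = n)
  qlev <- vapply(spec$random, function(t)
    if (is.null(t$Z)) n else ncol(t$Z), 0)
  floor_ <- 1e-10
  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-300) vy <- 1e-8
  theta <- if (!is.null(init)) pmax(init, floor_) else
    rep(vy / (k + 1), k + 1L)
  ev <- reml_eval(y, X, Vmats, theta)
  if (is.null(ev)) stop("initial covariance matrix is not positive definite")
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # score and average-information matrix
    ViPy <- vector("list", k + 1L)
    score <- numeric(k + 1L)
    trPV <- numeric(k + 1L)
    for (i in seq_len(k)) {
      ViPy[[i]] <- drop(Vmats[[i]] %*% ev$Py)
      trPV[i] <- sum(ev$P * Vmats[[i]])
      score[i] <- -0.5 * (trPV[i] - sum(ev$Py * ViPy[[i]]))
    }
    ViPy[[k + 1L]] <- ev$Py
    trPV[k + 1L] <- sum(diag(ev$P))
    score[k + 1L] <- -0.5 * (trPV[k + 1L] - sum(ev$Py * ev$Py))
    # components at the floor pushing further down do not count against
    # convergence
    eff_score <- score
    at_floor <- theta <= floor_ * 1.01
    eff_score[at_floor & score < 0] <- 0
    if (sqrt(sum(eff_score^2)) <= tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    # active set: components pinned at the floor with downhill score are
    # frozen so they do not distort the AI direction of the others
    active <- which(!(at_floor & score < 0))
    if (!length(active)) break
    Q <- do.call(cbind, ViPy)[, active, drop = FALSE]
    AI <- 0.5 * crossprod(Q, ev$P %*% Q)
    AI <- AI + diag(1e-12 + 1e-8 * mean(diag(AI)), length(active))
    delta_a <- tryCatch(solve(AI, score[active]), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(delta_a)) {
      delta <- numeric(k + 1L)
      delta[active] <- delta_a
      step <- 1
      for (h in 1:12) {
        cand <- pmax(theta + step * delta, floor_)
        ev2 <- reml_eval(y, X, Vmats, cand)
        if (!is.null(ev2) && ev2$loglik >= ev$loglik - 1e-10) {
          theta <- cand; ev <- ev2; accepted <- TRUE; break
        }
        step <- step / 2
      }
    }
    if (!accepted) {
      # EM-REML update, monotone in the restricted likelihood
      cand <- theta
      for (i in seq_len(k + 1L)) {
        yPVPy <- if (i <= k) sum(ev$Py * ViPy[[i]]) else sum(ev$Py^2)
        cand[i] <- theta[i] + theta[i]^2 * (yPVPy - trPV[i]) / qlev_of(i, k, qlev, n)
      }
      cand <- pmax(cand, floor_)
      ev2 <- reml_eval(y, X, Vmats, cand)
      if (is.null(ev2)) break
      theta <- cand; ev <- ev2
    }
  }
  sigma2 <- stats::setNames(theta, c(names(spec$random), "residual"))
  sigma2[sigma2 <= floor_ * 1.01] <- 0
  # refit internals at the reported components (guard zero total variance)
  theta_rep <- pmax(theta, floor_)
  ev <- reml_eval(y, X, Vmats, theta_rep)
  beta <- drop(ev$Cinv %*% crossprod(X, ev$Vinv %*% y))
  names(beta) <- colnames(X)
  blups <- mapply(function(term, s2) {
    if (s2 <= 0) {
      q <- if (is.null(term$Z)) n else ncol(term$Z)
      u <- numeric(q)
    } else {
      KZt <- if (is.null(term$Z)) {
        if (is.null(term$K)) diag(n) else term$K
      } else {
        if (is.null(term$K)) t(term$Z) else term$K %*% t(term$Z)
      }
      u <- s2 * drop(KZt %*% ev$Py)
    }
    nm <- if (!is.null(term$Z)) colnames(term$Z) else NULL
    if (!is.null(nm)) names(u) <- nm
    u
  }, spec$random, sigma2[seq_len(k)], SIMPLIFY = FALSE)
  fitted <- drop(X %*% beta)
  for (i in seq_len(k)) {
    Zi <- spec$random[[i]]$Z
    fitted <- fitted + if (is.null(Zi)) blups[[i]] else drop(Zi %*% blups[[i]])
  }
  structure(list(sigma2 = sigma2, loglik = ev$loglik,
                 converged = converged, n_iter = iter,
                 beta = beta, beta_se = sqrt(diag(ev$Cinv)),
                 blups = blups, fitted = fitted, Py = ev$Py,
                 spec = spec),
            class = "reml_fit")
}

qlev_of <- function(i, k, qlev, n) if (i <= k) qlev[i] else n

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit:", if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations, loglik", format(x$loglik), "\n")
  print(x$sigma2)
  invisible(x)
}

#' Restricted log-likelihood at given variance components
#'
#' Exposed so that fitted optima can be checked against grid searches.
#'
#' @param spec An [lmm_spec()].
#' @param sigma2 Variance components (k terms + residual, in spec order).
#' @return The restricted log-likelihood (constant terms dropped).
#' @export
reml_loglik <- function(spec, sigma2) {
  Vmats <- lapply(spec$random, term_vmat, n = spec$n)
  ev <- reml_eval(spec$y, spec$X, Vmats, pmax(sigma2, 1e-12))
  if (is.null(ev)) return(-Inf)
  ev$loglik
}

#' Solve the mixed-model equations at known variance components
#'
#' Generalised least squares for the fixed effects and BLUPs for every
#' random term, at user-supplied variance components. A term with zero
#' variance gets exactly-zero BLUPs.
#'
#' @param spec An [lmm_spec()].
#' @param sigma2 Variance components (k terms + residual).
#' @return List with `beta`, `beta_se`, `blups`, `fitted`.
#' @export
solve_mme <- function(spec, sigma2) {
  stopifnot(inherits(spec, "lmm_spec"))
  k <- length(spec$random)
  if (length(sigma2) != k + 1L)
    stop("need ", k + 1L, " variance components (including residual)")
  if (any(sigma2 < 0)) stop("variance components must be >= 0")
  qr_x <- qr(spec$X)
  if (qr_x$rank < ncol(spec$X)) {
    aliased <- colnames(spec$X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop("rank-deficient fixed design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  n <- spec$n
  Vmats <- lapply(spec$random, term_vmat, n = n)
  ev <- reml_eval(spec$y, spec$X, Vmats, pmax(sigma2, 1e-12))
  if (is.null(ev)) stop("covariance matrix not positive definite")
  beta <- drop(ev$Cinv %*% crossprod(spec$X, ev$Vinv %*% spec$y))
  names(beta) <- colnames(spec$X)
  blups <- mapply(function(term, s2) {
    q <- if (is.null(term$Z)) n else ncol(term$Z)
    if (s2 == 0) return(numeric(q))
    KZt <- if (is.null(term$Z)) {
      if (is.null(term$K)) diag(n) else term$K
    } else {
      if (is.null(term$K)) t(term$Z) else term$K %*% t(term$Z)
    }
    s2 * drop(KZt %*% ev$Py)
  }, spec$random, sigma2[seq_len(k)], SIMPLIFY = FALSE)
  fitted <- drop(spec$X %*% beta)
  for (i in seq_len(k)) {
    Zi <- spec$random[[i]]$Z
    fitted <- fitted + if (is.null(Zi)) blups[[i]] else drop(Zi %*% blups[[i]])
  }
  list(beta = beta, beta_se = sqrt(diag(ev$Cinv)), blups = blups,
       fitted = fitted)
}
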
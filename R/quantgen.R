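#' Marker-based line-mean narrow-sense heritability
#'
#' Fits `y = mu + g + eps` with `g ~ N(0, sigma2_g K)` on line means (plot
#' records are first averaged over replicates; BLUE tables are used as-is)
#' and reports the line-mean heritability
#' `h2 = sigma2_g / (sigma2_g + sigma2_eps / n_reps)`, where `sigma2_eps`
#' is the plot-level error variance recovered as `n_reps` times the
#' residual variance of the line-mean fit. The kinship is rescaled to unit
#' mean diagonal before fitting so that `sigma2_g` is the genetic variance
#' of an average line regardless of the panel's inbreeding level.
#'
#' @param blues_or_plots A `blue_table`, a named numeric vector of line
#'   values, or a `field_trial_records` data frame (averaged per line).
#' @param grm A [compute_grm()] matrix covering all lines.
#' @param n_reps Number of replications underlying each line mean.
#' @return One-row data.frame of class `h2_estimate`: environment, h2,
#'   sigma_g2, sigma_eps2, n_reps, n_lines, degenerate flag.
#' @export
estimate_h2 <- function(blues_or_plots, grm, n_reps = 2) {
  environment <- NA_character_
  x <- blues_or_plots
  if (is.data.frame(x) && "yield" %in% names(x)) {
    if ("env" %in% names(x)) {
      ev <- unique(x$env)
      if (length(ev) != 1L) stop("pass records for a single environment")
      environment <- ev
    }
    y <- tapply(x$yield, x$line, mean)
    y <- stats::setNames(as.numeric(y), names(y))
  } else if (is.data.frame(x)) {
    y <- as_named_values(x)
    if ("environment" %in% names(x)) environment <- x$environment[1]
  } else {
    y <- as_named_values(x)
  }
  ids <- names(y)[names(y) %in% rownames(grm)]
  if (length(ids) < length(y))
    warning(length(y) - length(ids), " lines absent from the GRM dropped")
  if (length(ids) < 30)
    warning("fewer than 30 lines; heritability will be imprecise")
  y <- y[ids]
  K <- unclass(grm)[ids, ids]
  K <- K / mean(diag(K))
  spec <- lmm_spec(y, random = list(g = list(K = K)))
  fit <- fit_reml(spec)
  s2g <- unname(fit$sigma2["g"])
  s2m <- unname(fit$sigma2["residual"])   # variance of a line mean
  degenerate <- s2g <= 0 && s2m <= 0
  h2 <- if (degenerate) 0 else s2g / (s2g + s2m)
  out <- data.frame(environment = environment, h2 = h2, sigma_g2 = s2g,
                    sigma_eps2 = s2m * n_reps, n_reps = n_reps,
                    n_lines = length(ids), degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(out) <- c("h2_estimate", "data.frame")
  out
}

#' Genetic correlation between two environments
#'
#' Calls [fit_multivariate_gc()] and returns
#' `r_A = cov_XY / sqrt(var_X var_Y)` (clamped to \[-1, 1\]) together with a
#' two-sided p-value for `r_A = 0`. The default test is a likelihood-ratio
#' test of the zero-covariance null against the free bivariate fit
#' (chi-square, 1 df), which simulates at nominal size; the Fisher z
#' transform referred to a t distribution with `n_shared - 2` degrees of
#' freedom is available via `method = "fisher"` but is anti-conservative
#' here because a REML-estimated genetic correlation is far noisier than a
#' raw Pearson correlation on the same number of lines.
#'
#' @param blues_x,blues_y Per-environment line values (see
#'   [fit_multivariate_gc()]).
#' @param grm Genomic relationship matrix.
#' @param method Significance test: `"lrt"` (default) or `"fisher"`.
#' @param ... Passed to [fit_multivariate_gc()].
#' @return One-row data.frame: r_a, pvalue, n_shared, var_x, var_y, cov_xy,
#'   clamped, defined (FALSE when a genetic variance is ~0, r_a then `NA`
#'   with the reason in `reason`).
#' @export
estimate_gc <- function(blues_x, blues_y, grm, method = c("lrt", "fisher"),
                        ...) {
  method <- match.arg(method)
  fit <- fit_multivariate_gc(blues_x, blues_y, grm, ...)
  vx <- fit$G[1, 1]; vy <- fit$G[2, 2]; cxy <- fit$G[1, 2]
  if (vx <= 1e-12 || vy <= 1e-12) {
    return(data.frame(r_a = NA_real_, pvalue = NA_real_,
                      n_shared = fit$n_shared, var_x = vx, var_y = vy,
                      cov_xy = cxy, clamped = FALSE, defined = FALSE,
                      reason = "genetic variance ~ 0",
                      stringsAsFactors = FALSE))
  }
  r <- cxy / sqrt(vx * vy)
  clamped <- abs(r) > 1
  r <- max(-1, min(1, r))
  n <- fit$n_shared
  if (method == "lrt") {
    fit0 <- fit_multivariate_gc(blues_x, blues_y, grm,
                                constrain_cov = TRUE, ...)
    stat <- max(0, 2 * (fit$loglik - fit0$loglik))
    pv <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else if (n > 3 && abs(r) < 1) {
    stat <- atanh(r) * sqrt(n - 3)
    pv <- 2 * stats::pt(-abs(stat), df = n - 2)
  } else {
    pv <- if (abs(r) >= 1) 0 else NA_real_
  }
  data.frame(r_a = r, pvalue = pv, n_shared = n, var_x = vx, var_y = vy,
             cov_xy = cxy, clamped = clamped, defined = TRUE, reason = "",
             stringsAsFactors = FALSE)
}

#' Genetic correlation matrix across a set of environments
#'
#' Pairwise [estimate_gc()] over the columns of a list of per-environment
#' line values.
#'
#' @param blues_list Named list of per-environment line values.
#' @param grm Genomic relationship matrix.
#' @param ... Passed to [estimate_gc()].
#' @return List of class `gc_matrix`: `r` (correlations, unit diagonal),
#'   `pvalues`, `env_ids`.
#' @export
estimate_gc_matrix <- function(blues_list, grm, ...) {
  env_ids <- names(blues_list)
  stopifnot(!is.null(env_ids))
  p <- length(env_ids)
  r <- diag(p); pv <- matrix(NA_real_, p, p)
  dimnames(r) <- dimnames(pv) <- list(env_ids, env_ids)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      est <- suppressWarnings(
        estimate_gc(blues_list[[i]], blues_list[[j]], grm, ...))
      r[i, j] <- r[j, i] <- est$r_a
      pv[i, j] <- pv[j, i] <- est$pvalue
    }
  }
  structure(list(r = r, pvalues = pv, env_ids = env_ids),
            class = "gc_matrix")
}

#' Ratio of correlated to direct response to selection
#'
#' For indirect selection in a selection environment targeting gain in a
#' target environment, at equal selection intensity:
#' `CR/R = r_A * h_sel / h_target` with `h = sqrt(h2)`.
#'
#' @param r_a Genetic correlation between the two environments.
#' @param h2_sel,h2_target Narrow-sense heritabilities in the selection and
#'   target environments (`h2_target > 0`).
#' @param selection_env,target_env Optional labels.
#' @return One-row data.frame of class `response_ratio`: ratio, r_a,
#'   h_sel, h_target, defined.
#' @export
response_ratio <- function(r_a, h2_sel, h2_target,
                           selection_env = NA_character_,
                           target_env = NA_character_) {
  if (any(h2_target < 0) || any(h2_sel < 0))
    stop("heritabilities must be non-negative")
  defined <- h2_target > 0
  ratio <- ifelse(defined, r_a * sqrt(h2_sel) / sqrt(h2_target), NA_real_)
  out <- data.frame(selection_env = selection_env, target_env = target_env,
                    ratio = ratio, r_a = r_a, h_sel = sqrt(h2_sel),
                    h_target = sqrt(h2_target), defined = defined,
                    stringsAsFactors = FALSE)
  class(out) <- c("response_ratio", "data.frame")
  out
}

#' Cluster sites by their genetic-correlation profiles
#'
#' Hierarchical agglomerative clustering with Euclidean distance between
#' the rows of the genetic correlation matrix and complete linkage, cut
#' into `n_clusters` branches. Missing entries are imputed to 0 (logged).
#'
#' @param gc A `gc_matrix` from [estimate_gc_matrix()], or a plain
#'   correlation matrix.
#' @param n_clusters Number of branches to cut (default 5, the usual
#'   mega-environment granularity).
#' @return List: `labels` (named cluster ids), `hclust`, `newick`
#'   (dendrogram as a Newick string), `n_imputed`.
#' @export
cluster_sites <- function(gc, n_clusters = 5) {
  r <- if (inherits(gc, "gc_matrix")) gc$r else as.matrix(gc)
  if (n_clusters > nrow(r))
    stop("n_clusters exceeds the number of sites")
  n_imputed <- sum(is.na(r))
  r[is.na(r)] <- 0
  hc <- stats::hclust(stats::dist(r), method = "complete")
  labels <- stats::cutree(hc, k = n_clusters)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(labels = labels, hclust = hc, newick = newick, n_imputed = n_imputed)
}

#' Bin sites by their highest genetic correlation with a selection environment
#'
#' Counts, per bin, the sites whose highest GC with any selection
#' environment falls inside the bin (values are rounded to 2 decimals
#' before binning, matching how such tables are usually reported). The
#' default bins are 0.30-0.40, 0.41-0.50 and 0.51 upwards.
#'
#' @param values Numeric vector of per-site highest GCs (already filtered
#'   for significance).
#' @param bins Two-column matrix of inclusive bin bounds.
#' @return data.frame: bin label, count.
#' @export
summarize_gc_by_threshold <- function(values,
                                      bins = rbind(c(0.30, 0.40),
                                                   c(0.41, 0.50),
                                                   c(0.51, 1.00))) {
  bins <- as.matrix(bins)
  if (any(bins[, 1] > bins[, 2])) stop("bins must have lower <= upper")
  if (nrow(bins) > 1 && any(bins[-1, 1] <= bins[-nrow(bins), 2]))
    stop("bins must be ordered and disjoint")
  v <- round(values, 2)
  counts <- vapply(seq_len(nrow(bins)), function(i)
    sum(v >= bins[i, 1] & v <= bins[i, 2]), 0L)
  data.frame(bin = sprintf("%.2f-%.2f", bins[, 1], bins[, 2]),
             count = counts, stringsAsFactors = FALSE)
}
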
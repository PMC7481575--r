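#' Stack per-environment line values for prediction
#'
#' Builds the long (line, environment, value) table the reaction-norm model
#' is fitted on, with a mask indicating records hidden from the fit (their
#' observed values are kept for scoring only).
#'
#' @param blues_list Named list of per-environment line values (named
#'   vectors or `blue_table`s).
#' @param mask_envs Environments whose records are masked.
#' @return Object of class `stacked_phenotypes`: data.frame `records`
#'   (line, env, value, mask) plus `env_index`, `line_index`.
#' @export
stack_phenotypes <- function(blues_list, mask_envs = character(0)) {
  env_ids <- names(blues_list)
  stopifnot(!is.null(env_ids))
  recs <- do.call(rbind, lapply(env_ids, function(e) {
    v <- as_named_values(blues_list[[e]])
    data.frame(line = names(v), env = e, value = as.numeric(v),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(recs[c("line", "env")]))
    stop("each (line, environment) may appear at most once")
  recs$mask <- recs$env %in% mask_envs
  structure(list(records = recs, env_index = env_ids,
                 line_index = unique(recs$line)),
            class = "stacked_phenotypes")
}

#' Reaction-norm kernels on the record scale
#'
#' `K_env = Z_y Z_y'` (records share an environment), `K_g = Z_g G Z_g'`
#' (genomic main effect) and their cell-by-cell (Hadamard) product
#' `K_gxe = K_g * K_env`, which is positive semi-definite whenever both
#' factors are (Schur product theorem).
#'
#' @param stacked A [stack_phenotypes()] object.
#' @param grm Genomic relationship matrix covering all stacked lines.
#' @return List: `K_env`, `K_g`, `K_gxe`, `Z_env`, `Z_line`.
#' @export
build_gxe_kernels <- function(stacked, grm) {
  recs <- stacked$records
  missing_lines <- setdiff(recs$line, rownames(grm))
  if (length(missing_lines))
    stop("lines absent from the GRM: ",
         paste(utils::head(missing_lines, 10), collapse = ", "))
  Z_env <- incidence(recs$env, stacked$env_index)
  Z_line <- incidence(recs$line, stacked$line_index)
  G <- unclass(grm)[stacked$line_index, stacked$line_index]
  K_env <- tcrossprod(Z_env)
  K_g <- Z_line %*% G %*% t(Z_line)
  list(K_env = K_env, K_g = K_g, K_gxe = K_g * K_env,
       Z_env = Z_env, Z_line = Z_line)
}

# 0/1 incidence matrix of a label vector over given levels
incidence <- function(x, levels) {
  Z <- matrix(0, length(x), length(levels),
              dimnames = list(NULL, levels))
  Z[cbind(seq_along(x), match(x, levels))] <- 1
  Z
}

# shared prediction machinery for the record-scale kernel models.
# REML backend: fit on unmasked rows, predict masked rows through the
# cross-kernel blocks (u_hat_test = sum_k s2_k K_k[test, train] Py).
# Gibbs backend: data augmentation inside gibbs_multikernel.
fit_kernel_model <- function(y, mask, kernels, backend, n_iter, burn_in,
                             thin, seed) {
  n <- length(y)
  if (backend == "reml") {
    tr <- !mask
    spec <- lmm_spec(y[tr], random = lapply(kernels, function(K)
      list(K = K[tr, tr, drop = FALSE])))
    fit <- fit_reml(spec)
    pred <- rep(unname(fit$beta[1]), n)
    k <- length(kernels)
    for (i in seq_len(k)) {
      s2 <- fit$sigma2[i]
      if (s2 > 0)
        pred <- pred + s2 * drop(kernels[[i]][, tr, drop = FALSE] %*% fit$Py)
    }
    list(pred = pred, sigma2 = fit$sigma2, fit = fit, backend = "reml")
  } else {
    yy <- y
    yy[mask] <- NA
    spec <- lmm_spec_na(yy, random = lapply(kernels, function(K) list(K = K)))
    fit <- gibbs_multikernel(spec, n_iter = n_iter, burn_in = burn_in,
                             thin = thin, seed = seed)
    list(pred = fit$fitted, sigma2 = fit$sigma2, fit = fit,
         backend = "gibbs")
  }
}

#' Fit the reaction-norm GxE model
#'
#' `y = mu + beta_env + u_g + u_gxe + eps` with kernels from
#' [build_gxe_kernels()]. With the Gibbs backend (default) masked records
#' are handled by data augmentation; with the REML backend the model is
#' fitted on unmasked records and masked records are predicted through the
#' cross-covariance. A masked environment's intercept is unidentifiable and
#' implicitly zero; Pearson prediction accuracy is invariant to that shift.
#' If only one environment is unmasked the interaction is inestimable and
#' the model reduces to plain GBLUP (with a warning).
#'
#' @param stacked A [stack_phenotypes()] object.
#' @param grm Genomic relationship matrix.
#' @param backend `"gibbs"` or `"reml"`.
#' @param n_iter,burn_in,thin,seed Sampler settings (Gibbs backend).
#' @return List of class `gxe_fit`: `predictions` (per record), `sigma2`,
#'   `records` (with `pred` column), `backend`, `reduced_to_gblup`.
#' @export
fit_gxe <- function(stacked, grm, backend = c("gibbs", "reml"),
                    n_iter = 12000, burn_in = 2000, thin = 5, seed = 1L) {
  backend <- match.arg(backend)
  recs <- stacked$records
  # unit mean diagonal so the genetic variance component is line-scale
  grm_n <- unclass(grm) / mean(diag(unclass(grm)))
  ker <- build_gxe_kernels(stacked, grm_n)
  n_env_obs <- length(unique(recs$env[!recs$mask]))
  reduced <- FALSE
  if (n_env_obs < 2) {
    warning("single unmasked environment: interaction inestimable, ",
            "falling back to GBLUP")
    kernels <- list(g = ker$K_g)
    reduced <- TRUE
  } else {
    kernels <- list(env = ker$K_env, g = ker$K_g, gxe = ker$K_gxe)
  }
  res <- fit_kernel_model(recs$value, recs$mask, kernels, backend,
                          n_iter, burn_in, thin, seed)
  recs$pred <- res$pred
  structure(list(predictions = res$pred, sigma2 = res$sigma2,
                 records = recs, backend = res$backend,
                 reduced_to_gblup = reduced, fit = res$fit),
            class = "gxe_fit")
}

#' Fit the environment + line (EL) baseline model
#'
#' `y = mu + beta_env + beta_line + eps` with i.i.d. line effects and no
#' markers. Masked records are predicted as `mu + line effect`; the masked
#' environment's effect is unidentifiable, set to 0 (it shifts all masked
#' predictions equally and cannot change a Pearson accuracy). Lines never
#' observed unmasked are predicted at `mu` and flagged.
#'
#' @inheritParams fit_gxe
#' @return List of class `el_fit` mirroring [fit_gxe()], plus
#'   `unobserved_lines`.
#' @export
fit_el <- function(stacked, backend = c("gibbs", "reml"),
                   n_iter = 12000, burn_in = 2000, thin = 5, seed = 1L) {
  backend <- match.arg(backend)
  recs <- stacked$records
  Z_env <- incidence(recs$env, stacked$env_index)
  Z_line <- incidence(recs$line, stacked$line_index)
  kernels <- list(env = tcrossprod(Z_env), line = tcrossprod(Z_line))
  unobserved <- setdiff(recs$line[recs$mask], recs$line[!recs$mask])
  if (length(unobserved))
    warning(length(unobserved),
            " masked lines never observed unmasked; predicted at the mean")
  res <- fit_kernel_model(recs$value, recs$mask, kernels, backend,
                          n_iter, burn_in, thin, seed)
  recs$pred <- res$pred
  structure(list(predictions = res$pred, sigma2 = res$sigma2,
                 records = recs, backend = res$backend,
                 unobserved_lines = unobserved, fit = res$fit),
            class = "el_fit")
}

score_pa <- function(fit_obj) {
  recs <- fit_obj$records
  m <- recs$mask
  if (!any(m)) stop("no masked records to score")
  stats::cor(recs$pred[m], recs$value[m])
}

#' Pairwise selection-environment to target-environment prediction
#'
#' For every (selection environment, target environment) pair: stack the
#' two environments, mask all target records, fit the GxE and EL models on
#' the selection environment only, and score the Pearson prediction
#' accuracy (PA) on the masked records, alongside the phenotypic Pearson
#' correlation between the two environments over shared lines. Pairs with
#' fewer than 10 shared lines are skipped with a reason.
#'
#' @param se_blues Named list of selection-environment line values.
#' @param tpe_blues Named list of target-environment line values.
#' @param grm Genomic relationship matrix.
#' @param backend,n_iter,burn_in,thin,seed Passed to the model fits.
#' @return data.frame with one row per pair and model:
#'   selection_env, target_env, model (GxE/EL), pa, phenotypic_corr,
#'   n_lines, and the fitted variance components (wide columns). Skipped
#'   pairs are reported in attribute `skipped`.
#' @export
run_pairwise <- function(se_blues, tpe_blues, grm,
                         backend = c("gibbs", "reml"), n_iter = 12000,
                         burn_in = 2000, thin = 5, seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(length(se_blues) >= 1, length(tpe_blues) >= 1)
  rows <- list(); skipped <- list()
  for (se in names(se_blues)) {
    for (tpe in names(tpe_blues)) {
      x <- as_named_values(se_blues[[se]])
      y <- as_named_values(tpe_blues[[tpe]])
      shared <- intersect(names(x), names(y))
      if (length(shared) < 10) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          selection_env = se, target_env = tpe,
          reason = sprintf("only %d shared lines", length(shared)))
        next
      }
      pair_list <- list(x[shared], y[shared])
      names(pair_list) <- c(se, tpe)
      stacked <- stack_phenotypes(pair_list, mask_envs = tpe)
      # training is single-SE by construction, so the GBLUP reduction of
      # the interaction term is expected; no need to warn per pair
      fg <- suppressWarnings(
        fit_gxe(stacked, grm, backend = backend, n_iter = n_iter,
                burn_in = burn_in, thin = thin, seed = seed))
      fe <- fit_el(stacked, backend = backend, n_iter = n_iter,
                   burn_in = burn_in, thin = thin, seed = seed + 1L)
      pcor <- stats::cor(x[shared], y[shared])
      rows[[length(rows) + 1L]] <- data.frame(
        selection_env = se, target_env = tpe, model = c("GxE", "EL"),
        pa = c(score_pa(fg), score_pa(fe)),
        phenotypic_corr = pcor, n_lines = length(shared),
        sigma_g2 = c(unname(fg$sigma2["g"]), NA),
        sigma_e2_env = c(unname(fg$sigma2["env"]),
                         unname(fe$sigma2["env"])),
        sigma_gxe2 = c(unname(fg$sigma2["gxe"]), NA),
        sigma_eps2 = c(unname(fg$sigma2["residual"]),
                       unname(fe$sigma2["residual"])),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(selection_env = character(0))
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' Cross-environment variance partition
#'
#' Fits the reaction-norm model on all (unmasked) records of a stacked
#' environment pair and reports the genetic, environment, interaction and
#' error variance components; the ratio string normalised to
#' `sigma2_g = 1` with one decimal per component (computed from the
#' unrounded components); and the across-environment heritability. Two
#' formulas for the latter are available:
#' `"line_mean"` (default): `s2g / (s2g + s2gxe/n_env + s2eps/(n_env n_reps))`;
#' `"plot"`: `s2g / (s2g + s2gxe + s2eps)`.
#'
#' @param stacked A [stack_phenotypes()] object (typically two
#'   environments, nothing masked).
#' @param grm Genomic relationship matrix.
#' @param n_reps Replications behind each stacked value (default 2).
#' @param h2_formula `"line_mean"` or `"plot"`.
#' @param backend,n_iter,burn_in,thin,seed Passed to the fit.
#' @return List of class `variance_partition`: `components` (named:
#'   sigma_g2, sigma_e2_env, sigma_gxe2, sigma_eps2), `ratio` (string
#'   `1:a:b:c`), `h2`, `h2_formula`, `defined`.
#' @export
partition_variance <- function(stacked, grm, n_reps = 2,
                               h2_formula = c("line_mean", "plot"),
                               backend = c("gibbs", "reml"),
                               n_iter = 12000, burn_in = 2000, thin = 5,
                               seed = 1L) {
  h2_formula <- match.arg(h2_formula)
  backend <- match.arg(backend)
  if (any(stacked$records$mask))
    stop("variance partition expects fully observed records")
  fit <- fit_gxe(stacked, grm, backend = backend, n_iter = n_iter,
                 burn_in = burn_in, thin = thin, seed = seed)
  s2 <- fit$sigma2
  comp <- c(sigma_g2 = unname(s2["g"]), sigma_e2_env = unname(s2["env"]),
            sigma_gxe2 = unname(s2["gxe"]),
            sigma_eps2 = unname(s2["residual"]))
  defined <- comp["sigma_g2"] > 1e-12
  ratio <- if (defined) variance_ratio_string(comp) else NA_character_
  n_env <- length(stacked$env_index)
  h2 <- if (!defined) NA_real_ else if (h2_formula == "line_mean") {
    comp[["sigma_g2"]] /
      (comp[["sigma_g2"]] + comp[["sigma_gxe2"]] / n_env +
         comp[["sigma_eps2"]] / (n_env * n_reps))
  } else {
    comp[["sigma_g2"]] /
      (comp[["sigma_g2"]] + comp[["sigma_gxe2"]] + comp[["sigma_eps2"]])
  }
  structure(list(components = comp, ratio = ratio, h2 = h2,
                 h2_formula = h2_formula, defined = unname(defined),
                 backend = backend),
            class = "variance_partition")
}

#' Ratio string from variance components
#'
#' Formats `(s2g, s2e, s2gxe, s2eps)` as `1:a:b:c`, each divisor printed
#' to one decimal from the unrounded ratio (a trailing `.0` is dropped, so
#' a ratio of exactly one prints as `1`).
#'
#' @param components Numeric length-4 vector (genetic first).
#' @return Character scalar.
#' @export
variance_ratio_string <- function(components) {
  stopifnot(length(components) == 4)
  if (components[1] <= 0) stop("genetic variance must be positive")
  rr <- sprintf("%.1f", components[-1] / components[1])
  rr <- sub("\\.0$", "", rr)
  paste(c("1", rr), collapse = ":")
}

#' Compare prediction accuracies from the GxE and EL models
#'
#' @param results Output of [run_pairwise()] (must contain both models for
#'   each pair), or two numeric vectors via `pa_gxe`/`pa_el`.
#' @param pa_gxe,pa_el Optional explicit PA vectors (paired).
#' @return One-row data.frame: correlation, mean_diff (GxE - EL),
#'   sd_diff, t_pvalue (paired two-sided), n_pairs.
#' @export
compare_pa_models <- function(results = NULL, pa_gxe = NULL, pa_el = NULL) {
  if (is.null(pa_gxe)) {
    g <- results[results$model == "GxE", ]
    e <- results[results$model == "EL", ]
    key <- function(d) paste(d$selection_env, d$target_env)
    e <- e[match(key(g), key(e)), ]
    pa_gxe <- g$pa; pa_el <- e$pa
  }
  stopifnot(length(pa_gxe) == length(pa_el))
  d <- pa_gxe - pa_el
  pv <- if (length(d) > 1 && stats::sd(d) > 0)
    stats::t.test(d)$p.value else NA_real_
  data.frame(correlation = stats::cor(pa_gxe, pa_el),
             mean_diff = mean(d), sd_diff = stats::sd(d),
             t_pvalue = pv, n_pairs = length(d))
}
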
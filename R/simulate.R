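#' Specify one simulated trial environment
#'
#' An environment is characterised by its mean yield, its per-plot
#' narrow-sense heritability (which, together with the genetic variance,
#' fixes the plot error variance), the variance of its additive genetic
#' values, and the variance of the random environment main effect drawn
#' around `mean_yield`.
#'
#' @param env_id Character label, e.g. `"S2_irrigated_BP"`.
#' @param mean_yield Mean yield of the environment (t/ha).
#' @param h2_plot Target per-plot heritability, strictly in (0, 1).
#'   The plot error variance is derived as
#'   `sigma_g2 * (1 - h2_plot) / h2_plot`.
#' @param sigma_g2 Additive genetic variance in this environment ((t/ha)^2).
#' @param env_variance Variance of the random environment main effect drawn
#'   around `mean_yield` ((t/ha)^2). Zero gives a fixed environment mean.
#' @return An object of class `env_spec`.
#' @export
env_spec <- function(env_id, mean_yield = 5, h2_plot = 0.5, sigma_g2 = 0.1,
                     env_variance = 0) {
  stopifnot(is.character(env_id), length(env_id) == 1L)
  if (!is.numeric(h2_plot) || h2_plot <= 0 || h2_plot >= 1)
    stop("h2_plot must be strictly in (0, 1)")
  if (sigma_g2 < 0 || env_variance < 0)
    stop("variances must be non-negative")
  structure(list(env_id = env_id, mean_yield = mean_yield,
                 h2_plot = h2_plot, sigma_g2 = sigma_g2,
                 env_variance = env_variance),
            class = "env_spec")
}

#' Configuration for a simulated multi-environment trial
#'
#' Bundles everything needed to generate a genotyped cohort and its
#' alpha-lattice phenotype records. The lattice layout is approximated by
#' randomized incomplete blocks of near-equal size within each replicate;
#' lines are partitioned into trials of `trial_size` entries, and
#' `n_checks` check lines are added to every trial to connect them (the
#' usual device that makes multi-trial adjustment identifiable).
#'
#' @param n_lines Number of (non-check) lines, at least 2.
#' @param n_markers Number of biallelic markers, at least 10.
#' @param environments List of [env_spec()] objects.
#' @param maf_range Length-2 numeric in (0, 0.5]: range of per-marker minor
#'   allele frequencies.
#' @param marker_missing_rate Fraction of calls masked as missing, in \[0, 1).
#' @param het_rate Target heterozygote frequency, in \[0, 1).
#' @param n_reps Replicates per trial (default 2, the usual lattice layout).
#' @param n_blocks_per_rep Incomplete blocks per replicate within each trial;
#'   default `NULL` chooses roughly sqrt(block count) blocks of ~7 plots.
#' @param block_effect_sd,rep_effect_sd,trial_effect_sd Standard deviations
#'   (t/ha) of the corresponding random design effects.
#' @param trial_size Entries per trial (default 50, a typical international
#'   trial size).
#' @param n_checks Check lines replicated in every trial (default 0; set to
#'   2 to mimic the usual pair of connecting checks — note each check then
#'   contributes one record per trial, not one per cohort).
#' @param gc_matrix Environment-by-environment genetic correlation matrix
#'   (unit diagonal, positive semi-definite). Default: identity.
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_lines, n_markers, environments,
                       maf_range = c(0.05, 0.5),
                       marker_missing_rate = 0, het_rate = 0.05,
                       n_reps = 2, n_blocks_per_rep = NULL,
                       block_effect_sd = 0.15, rep_effect_sd = 0.1,
                       trial_effect_sd = 0.2, trial_size = 50,
                       n_checks = 0, gc_matrix = NULL, seed = 1L) {
  if (n_lines < 2) stop("n_lines must be at least 2")
  if (n_markers < 10) stop("n_markers must be at least 10")
  stopifnot(length(maf_range) == 2)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (marker_missing_rate < 0 || marker_missing_rate >= 1)
    stop("marker_missing_rate must be in [0, 1)")
  if (het_rate < 0 || het_rate >= 1) stop("het_rate must be in [0, 1)")
  if (inherits(environments, "env_spec")) environments <- list(environments)
  if (!length(environments) || !all(vapply(environments, inherits, TRUE, "env_spec")))
    stop("environments must be a list of env_spec objects")
  env_ids <- vapply(environments, `[[`, "", "env_id")
  if (anyDuplicated(env_ids)) stop("duplicate environment ids")
  n_env <- length(environments)
  if (is.null(gc_matrix)) gc_matrix <- diag(n_env)
  gc_matrix <- as.matrix(gc_matrix)
  if (!all(dim(gc_matrix) == n_env))
    stop("gc_matrix must be ", n_env, "x", n_env)
  dimnames(gc_matrix) <- list(env_ids, env_ids)
  structure(list(n_lines = as.integer(n_lines),
                 n_markers = as.integer(n_markers),
                 environments = environments, env_ids = env_ids,
                 maf_range = maf_range,
                 marker_missing_rate = marker_missing_rate,
                 het_rate = het_rate, n_reps = as.integer(n_reps),
                 n_blocks_per_rep = n_blocks_per_rep,
                 block_effect_sd = block_effect_sd,
                 rep_effect_sd = rep_effect_sd,
                 trial_effect_sd = trial_effect_sd,
                 trial_size = as.integer(trial_size),
                 n_checks = as.integer(n_checks),
                 gc_matrix = gc_matrix, seed = as.integer(seed)),
            class = "sim_config")
}

# run expr with a local RNG state seeded at `seed`, restoring the caller's
# stream afterwards so simulation calls do not perturb user code
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a biallelic SNP genotype matrix
#'
#' Draws per-marker minor allele frequencies uniformly within
#' `config$maf_range`, samples calls coded 0/1/2 (count of the minor allele)
#' with heterozygote frequency `het_rate`, and masks entries independently at
#' `marker_missing_rate`. The complete (pre-masking) matrix is retained as an
#' attribute so that true breeding values can be computed from it.
#'
#' @param config A [sim_config()].
#' @return A [marker_matrix()] with `NA` for missing calls; attributes
#'   `complete` (unmasked calls) and `maf` (generating frequencies).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_lines + config$n_checks
  m <- config$n_markers
  with_seed(config$seed, {
    p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    # genotype class probabilities with a controlled heterozygote rate;
    # feasibility requires het/2 <= p, so cap per marker
    het <- pmin(config$het_rate, 2 * p * 0.999)
    p2 <- p - het / 2           # homozygous minor
    p0 <- 1 - p - het / 2       # homozygous major
    calls <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      calls[, j] <- sample(c(0L, 1L, 2L), n, replace = TRUE,
                           prob = c(p0[j], het[j], p2[j]))
    }
    line_ids <- c(sprintf("L%04d", seq_len(config$n_lines)),
                  if (config$n_checks > 0)
                    sprintf("CHK%02d", seq_len(config$n_checks)))
    dimnames(calls) <- list(line_ids, sprintf("M%05d", seq_len(m)))
    complete <- calls
    if (config$marker_missing_rate > 0) {
      miss <- matrix(stats::runif(n * m) < config$marker_missing_rate, n, m)
      calls[miss] <- NA_integer_
    }
    mm <- marker_matrix(calls)
    attr(mm, "complete") <- complete
    attr(mm, "maf") <- p
    mm
  })
}

#' Simulate additive breeding values across environments
#'
#' Marker effects are drawn so that the implied line-by-environment breeding
#' values have (in expectation) per-environment variance `sigma_g2` and
#' cross-environment correlation `gc_matrix`: independent standard-normal
#' per-marker effect vectors are mixed through the spectral square root of
#' `diag(sqrt(sigma_g2)) %*% gc_matrix %*% diag(sqrt(sigma_g2))` and scaled
#' by the summed observed variance of the centred genotype codes (which
#' equals `sum(2 p (1 - p))` under Hardy-Weinberg proportions but stays
#' correct for the largely homozygous panels of selfing crops). Breeding
#' values are linear in the (complete) genotype codes.
#'
#' @param genotypes A [marker_matrix()]; if it carries a `complete`
#'   attribute (as produced by [simulate_genotypes()]) that is used,
#'   otherwise missing calls are mean-imputed for the purpose of the
#'   linear combination.
#' @param gc_matrix Genetic correlation matrix across environments
#'   (unit diagonal, positive semi-definite).
#' @param sigma_g2 Vector of per-environment genetic variances ((t/ha)^2),
#'   one per row/column of `gc_matrix`.
#' @param seed Integer seed.
#' @param env_ids Optional environment labels (default from `gc_matrix`
#'   dimnames or `E1..`).
#' @return A `genetic_truth` list: `breeding_values` (line x environment),
#'   `gc_matrix`, `sigma_g2`, `marker_effects` (marker x environment).
#' @export
simulate_breeding_values <- function(genotypes, gc_matrix, sigma_g2,
                                     seed = 1L, env_ids = NULL) {
  stopifnot(inherits(genotypes, "marker_matrix"))
  gc_matrix <- as.matrix(gc_matrix)
  n_env <- nrow(gc_matrix)
  if (length(sigma_g2) == 1L) sigma_g2 <- rep(sigma_g2, n_env)
  if (length(sigma_g2) != n_env)
    stop("need one sigma_g2 per environment")
  if (max(abs(gc_matrix - t(gc_matrix))) > 1e-8)
    stop("gc_matrix must be symmetric")
  if (max(abs(diag(gc_matrix) - 1)) > 1e-8)
    stop("gc_matrix must have unit diagonal")
  ev <- eigen(gc_matrix, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop(sprintf(
      "gc_matrix is not positive semi-definite (smallest eigenvalue %.3e)",
      min(ev$values)))
  if (is.null(env_ids)) {
    env_ids <- rownames(gc_matrix)
    if (is.null(env_ids)) env_ids <- paste0("E", seq_len(n_env))
  }
  W <- attr(genotypes, "complete")
  if (is.null(W)) {
    W <- unclass(genotypes)
    if (anyNA(W)) {
      mu <- colMeans(W, na.rm = TRUE)
      idx <- which(is.na(W), arr.ind = TRUE)
      W[idx] <- mu[idx[, 2]]
    }
  }
  storage.mode(W) <- "double"
  p_hat <- colMeans(W) / 2
  Wc <- sweep(W, 2, 2 * p_hat)
  denom <- sum(colMeans(Wc^2))
  if (denom <= 0) stop("all markers monomorphic; cannot scale effects")
  # spectral square root of the between-environment genetic covariance
  S <- diag(sqrt(sigma_g2), n_env) %*% gc_matrix %*% diag(sqrt(sigma_g2), n_env)
  es <- eigen(S, symmetric = TRUE)
  sqrtS <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), n_env) %*% t(es$vectors)
  alpha <- with_seed(seed, {
    matrix(stats::rnorm(ncol(W) * n_env), ncol(W), n_env) %*% sqrtS / sqrt(denom)
  })
  bv <- Wc %*% alpha
  dimnames(bv) <- list(rownames(W), env_ids)
  dimnames(alpha) <- list(colnames(W), env_ids)
  dimnames(gc_matrix) <- list(env_ids, env_ids)
  structure(list(breeding_values = bv, gc_matrix = gc_matrix,
                 sigma_g2 = stats::setNames(sigma_g2, env_ids),
                 marker_effects = alpha),
            class = "genetic_truth")
}

#' Simulate alpha-lattice plot records from genetic truth
#'
#' One record is produced per line x environment x replicate. Plot yield is
#' the sum of the environment mean (plus a random environment main effect if
#' `env_variance > 0`), a trial effect, a replicate-within-trial effect, a
#' block-within-replicate effect, the line's breeding value and a plot error
#' whose variance is derived from the environment's per-plot heritability:
#' `sigma_eps2 = sigma_g2 * (1 - h2_plot) / h2_plot`. Non-check lines are
#' partitioned into trials of `trial_size`; check lines are added to every
#' trial. Blocks within each replicate are randomized and near-equal in size.
#'
#' @param truth A `genetic_truth` from [simulate_breeding_values()].
#' @param config The [sim_config()] used for the genotypes.
#' @return A `data.frame` of class `field_trial_records` with columns
#'   `line, env, cycle, trial, rep, block, yield`, plus attributes
#'   `env_effects` (realized environment means) and `sigma_eps2`.
#' @export
simulate_trial <- function(truth, config) {
  stopifnot(inherits(truth, "genetic_truth"), inherits(config, "sim_config"))
  bv <- truth$breeding_values
  env_ids <- config$env_ids
  if (!all(env_ids %in% colnames(bv)))
    stop("truth does not cover every configured environment")
  lines <- rownames(bv)
  is_check <- grepl("^CHK", lines)
  entry_lines <- lines[!is_check]
  check_lines <- lines[is_check]
  n_trials <- max(1L, ceiling(length(entry_lines) / config$trial_size))
  trial_of <- rep(seq_len(n_trials), each = config$trial_size,
                  length.out = length(entry_lines))
  with_seed(config$seed + 2L, {
    out <- vector("list", length(env_ids))
    env_eff <- numeric(length(env_ids))
    sig_eps <- numeric(length(env_ids))
    names(env_eff) <- names(sig_eps) <- env_ids
    for (e in seq_along(env_ids)) {
      es <- config$environments[[e]]
      env_eff[e] <- es$mean_yield +
        if (es$env_variance > 0) stats::rnorm(1, 0, sqrt(es$env_variance)) else 0
      sig_eps[e] <- es$sigma_g2 * (1 - es$h2_plot) / es$h2_plot
      trial_eff <- stats::rnorm(n_trials, 0, config$trial_effect_sd)
      recs <- vector("list", n_trials)
      for (tr in seq_len(n_trials)) {
        tr_lines <- c(entry_lines[trial_of == tr], check_lines)
        n_in <- length(tr_lines)
        nb <- config$n_blocks_per_rep
        if (is.null(nb)) nb <- max(1L, round(n_in / 7))
        if (nb > n_in)
          stop("n_blocks_per_rep exceeds the number of lines in a trial")
        rep_eff <- stats::rnorm(config$n_reps, 0, config$rep_effect_sd)
        for (r in seq_len(config$n_reps)) {
          ord <- sample(n_in)
          block <- rep(seq_len(nb), length.out = n_in)[order(ord)]
          blk_eff <- stats::rnorm(nb, 0, config$block_effect_sd)
          eps <- stats::rnorm(n_in, 0, sqrt(sig_eps[e]))
          recs[[tr]][[r]] <- data.frame(
            line = tr_lines, env = env_ids[e], cycle = "C1",
            trial = sprintf("T%02d", tr), rep = paste0("R", r),
            block = sprintf("B%02d", block),
            yield = env_eff[e] + trial_eff[tr] + rep_eff[r] +
              blk_eff[block] + bv[tr_lines, env_ids[e]] + eps,
            stringsAsFactors = FALSE)
        }
        recs[[tr]] <- do.call(rbind, recs[[tr]])
      }
      out[[e]] <- do.call(rbind, recs)
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    class(out) <- c("field_trial_records", "data.frame")
    attr(out, "env_effects") <- env_eff
    attr(out, "sigma_eps2") <- sig_eps
    out
  })
}

#' Simulate a complete genotyped multi-environment trial
#'
#' Convenience wrapper: [simulate_genotypes()], then
#' [simulate_breeding_values()] using the genetic correlation matrix and
#' per-environment genetic variances held in the config, then
#' [simulate_trial()].
#'
#' @param config A [sim_config()].
#' @return List with `genotypes`, `truth`, `records`.
#' @export
simulate_met <- function(config) {
  geno <- simulate_genotypes(config)
  sigma_g2 <- vapply(config$environments, `[[`, 0, "sigma_g2")
  truth <- simulate_breeding_values(geno, config$gc_matrix, sigma_g2,
                                    seed = config$seed + 1L,
                                    env_ids = config$env_ids)
  records <- simulate_trial(truth, config)
  list(genotypes = geno, truth = truth, records = records)
}
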
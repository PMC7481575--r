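# shared fixture builders (everything generated in code, no stored data)

# per-line means for one environment of a records table
line_means <- function(records, env) {
  r <- records[records$env == env, , drop = FALSE]
  x <- tapply(r$yield, r$line, mean)
  stats::setNames(as.numeric(x), names(x))
}

# genotyped two-environment cohort with known genetic correlation r;
# design-effect SDs zeroed so line means are breeding value + iid noise
sim_pair <- function(seed, r, n = 300, m = 1500, h2_plot = 0.5,
                     sigma_g2 = 0.1, env_variance = 0, mean_a = 5,
                     mean_b = 4.5) {
  cfg <- sim_config(
    n, m,
    list(env_spec("SE", mean_a, h2_plot, sigma_g2, env_variance),
         env_spec("TPE", mean_b, h2_plot, sigma_g2, env_variance)),
    gc_matrix = matrix(c(1, r, r, 1), 2), seed = seed,
    marker_missing_rate = 0, block_effect_sd = 0, rep_effect_sd = 0,
    trial_effect_sd = 0)
  met <- simulate_met(cfg)
  G <- compute_grm(met$genotypes)
  v <- list(SE = line_means(met$records, "SE"),
            TPE = line_means(met$records, "TPE"))
  list(v = v, G = G, met = met)
}

# small single-environment cohort for heritability-style tests
sim_single <- function(seed, n = 200, m = 800, h2_plot = 0.5,
                       sigma_g2 = 0.1, ...) {
  cfg <- sim_config(n, m, list(env_spec("E1", 5, h2_plot, sigma_g2)),
                    seed = seed, marker_missing_rate = 0,
                    block_effect_sd = 0, rep_effect_sd = 0,
                    trial_effect_sd = 0, ...)
  met <- simulate_met(cfg)
  list(met = met, G = compute_grm(met$genotypes))
}

# hand-specifiable marker matrix from a list of marker columns
mm_from_cols <- function(cols, line_ids = NULL) {
  x <- do.call(cbind, cols)
  if (!is.null(line_ids)) rownames(x) <- line_ids
  colnames(x) <- names(cols)
  marker_matrix(x)
}

# 10-marker QC fixture: 7 clean markers plus one violating each criterion
# (65% missing / MAF 0.025 / 15% heterozygous)
qc_fixture <- function() {
  n <- 20
  set.seed(101)
  clean <- lapply(1:7, function(i)
    sample(c(0L, 2L), n, replace = TRUE, prob = c(0.6, 0.4)))
  names(clean) <- paste0("ok", 1:7)
  too_missing <- c(rep(NA_integer_, 13), sample(c(0L, 2L), 7, replace = TRUE))
  low_maf <- rep(0L, n); low_maf[1] <- 1L
  high_het <- c(rep(1L, 3), sample(c(0L, 2L), n - 3, replace = TRUE))
  mm_from_cols(c(clean, list(bad_miss = too_missing, bad_maf = low_maf,
                             bad_het = high_het)))
}
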
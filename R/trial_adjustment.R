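#' Per-environment line BLUEs from plot records
#'
#' Fits, within one environment, the lattice adjustment model with genotype
#' as a fixed effect and trial, replicate-within-trial and
#' block-within-trial-and-replicate as independent random effects
#' (identity kernels), via [fit_reml()]. The fixed-effect genotype
#' estimates are re-centred so that their mean equals the grand plot mean,
#' which puts BLUEs on the t/ha scale and makes them comparable across
#' environments.
#'
#' @param records A `field_trial_records` data frame (or any data frame
#'   with columns `line, env, trial, rep, block, yield`).
#' @param environment Environment label to fit; may be omitted when the
#'   records contain a single environment.
#' @return A `blue_table` data frame: `environment, line, blue, se`, with
#'   attributes `sigma2` (fitted variance components) and `notes`.
#' @export
compute_blues <- function(records, environment = NULL) {
  df <- as.data.frame(records)
  need <- c("line", "env", "trial", "rep", "block", "yield")
  if (!all(need %in% names(df)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (is.null(environment)) {
    environment <- unique(df$env)
    if (length(environment) != 1L)
      stop("records contain multiple environments; pass `environment`")
  }
  df <- df[df$env == environment, , drop = FALSE]
  if (!nrow(df)) stop("no records for environment ", environment)
  counts <- table(df$line)
  zero_lines <- setdiff(unique(as.data.frame(records)$line), names(counts))
  if (length(zero_lines))
    warning("lines with no plots in ", environment, " excluded: ",
            paste(utils::head(zero_lines, 5), collapse = ", "))
  if (length(counts) < 2) stop("need at least 2 lines with plots")
  notes <- character(0)
  df$line <- factor(df$line)
  df$trial <- factor(df$trial)
  df$repf <- factor(paste(df$trial, df$rep, sep = ":"))
  df$blockf <- factor(paste(df$trial, df$rep, df$block, sep = ":"))
  X <- stats::model.matrix(~ 0 + line, df)
  colnames(X) <- levels(df$line)
  random <- list()
  if (nlevels(df$trial) > 1L) {
    random$trial <- list(Z = stats::model.matrix(~ 0 + trial, df))
  } else {
    notes <- c(notes, "single trial: trial variance fixed at 0")
  }
  if (nlevels(df$repf) > nlevels(df$trial))
    random$rep <- list(Z = stats::model.matrix(~ 0 + repf, df))
  if (nlevels(df$blockf) > nlevels(df$repf))
    random$block <- list(Z = stats::model.matrix(~ 0 + blockf, df))
  if (!length(random)) {
    # no estimable design terms at all: BLUEs are plot means
    mns <- tapply(df$yield, df$line, mean)
    sds <- tapply(df$yield, df$line, stats::sd)
    nn <- tapply(df$yield, df$line, length)
    se <- ifelse(nn > 1, sds / sqrt(nn), NA_real_)
    out <- data.frame(environment = environment, line = names(mns),
                      blue = as.numeric(mns), se = as.numeric(se),
                      stringsAsFactors = FALSE)
    class(out) <- c("blue_table", "data.frame")
    attr(out, "notes") <- c(notes, "no design terms; plot means returned")
    return(out)
  }
  spec <- lmm_spec(df$yield, X, random)
  fit <- fit_reml(spec)
  g <- fit$beta
  blue <- g - mean(g) + mean(df$yield)
  out <- data.frame(environment = environment, line = names(g),
                    blue = as.numeric(blue), se = as.numeric(fit$beta_se),
                    stringsAsFactors = FALSE)
  class(out) <- c("blue_table", "data.frame")
  attr(out, "sigma2") <- fit$sigma2
  attr(out, "notes") <- notes
  attr(out, "converged") <- fit$converged
  out
}

#' Descriptive statistics of a BLUE table
#'
#' @param blues A `blue_table` (or numeric vector).
#' @return One-row data.frame: mean, median, range (max - min), sd
#'   (sample, n-1), sem and variance.
#' @export
summarize_yield <- function(blues) {
  x <- if (is.data.frame(blues)) blues$blue else as.numeric(blues)
  if (length(x) < 2) stop("need at least 2 lines")
  s <- stats::sd(x)
  data.frame(mean = mean(x), median = stats::median(x),
             range = max(x) - min(x), sd = s, sem = s / sqrt(length(x)),
             variance = s^2)
}

#' Percent change from a base value
#'
#' `100 * (value - base) / base`; a 5.5-fold increase over the base is a
#' 450% increase.
#'
#' @param base Base value (> 0).
#' @param value New value.
#' @return Percent change.
#' @export
percent_change <- function(base, value) {
  if (any(base <= 0)) stop("base must be positive")
  100 * (value - base) / base
}

#' Superiority of the best line over a check
#'
#' Identifies the highest-BLUE non-check line and reports its absolute and
#' percent yield difference relative to the check (negative when the check
#' wins).
#'
#' @param blues A `blue_table`.
#' @param check_line Label of the check.
#' @return One-row data.frame: best_line, best_blue, check_blue,
#'   delta (t/ha), delta_pct.
#' @export
best_line_vs_check <- function(blues, check_line) {
  df <- as.data.frame(blues)
  if (!check_line %in% df$line) stop("check line ", check_line, " not present")
  check_blue <- df$blue[match(check_line, df$line)]
  rest <- df[df$line != check_line, , drop = FALSE]
  if (!nrow(rest)) stop("no non-check lines")
  best <- rest[which.max(rest$blue), ]
  data.frame(best_line = best$line, best_blue = best$blue,
             check_blue = check_blue, delta = best$blue - check_blue,
             delta_pct = percent_change(check_blue, best$blue),
             stringsAsFactors = FALSE)
}
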
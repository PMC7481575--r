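#' Construct a marker matrix
#'
#' A thin S3 wrapper around an integer line x marker matrix of biallelic
#' genotype calls coded 0/1/2 (minor-allele count) with `NA` for missing.
#' Row and column names are the line and marker ids; a `qc_log` attribute
#' accumulates the filters applied.
#'
#' @param calls Numeric/integer matrix, values in \{0, 1, 2, NA\}.
#' @param qc_log List of filter records (internal).
#' @return Object of class `marker_matrix`.
#' @export
marker_matrix <- function(calls, qc_log = list()) {
  calls <- as.matrix(calls)
  ok <- calls %in% c(0, 1, 2) | is.na(calls)
  if (!all(ok)) stop("calls must be coded 0/1/2 with NA for missing")
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("L%04d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("M%05d", seq_len(ncol(calls)))
  if (anyDuplicated(rownames(calls))) stop("duplicate line ids")
  if (anyDuplicated(colnames(calls))) stop("duplicate marker ids")
  structure(calls, class = "marker_matrix", qc_log = qc_log)
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d lines x %d markers, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  for (entry in attr(x, "qc_log"))
    cat(" qc:", entry$what, "-", entry$detail, "\n")
  invisible(x)
}

#' Per-marker summary statistics
#'
#' @param m A [marker_matrix()].
#' @return data.frame with marker, missing fraction, minor allele frequency
#'   (computed on observed calls; the reported value is folded to <= 0.5)
#'   and heterozygote fraction. Missing calls are excluded from the MAF and
#'   heterozygosity denominators.
#' @export
marker_stats <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  x <- unclass(m)
  n_obs <- colSums(!is.na(x))
  miss <- 1 - n_obs / nrow(x)
  f <- colSums(x, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  maf <- pmin(f, 1 - f)
  maf[n_obs == 0] <- NA_real_
  het <- colSums(x == 1L, na.rm = TRUE) / pmax(n_obs, 1L)
  het[n_obs == 0] <- NA_real_
  data.frame(marker = colnames(x), missing = miss, maf = maf, het = het,
             row.names = NULL, stringsAsFactors = FALSE)
}

append_qc <- function(m, what, detail) {
  log <- attr(m, "qc_log")
  log[[length(log) + 1L]] <- list(what = what, detail = detail)
  attr(m, "qc_log") <- log
  m
}

#' Filter markers on missingness, MAF and heterozygosity
#'
#' Retains exactly the markers whose missing fraction is at most
#' `max_missing`, minor allele frequency at least `min_maf` and heterozygote
#' fraction at most `max_het`. The defaults are the GBS thresholds commonly
#' used for inbred wheat panels (drop markers with more than 60% missing
#' data, MAF below 5%, or more than 10% heterozygous calls).
#'
#' @param m A [marker_matrix()].
#' @param max_missing,min_maf,max_het Thresholds (see above).
#' @return Filtered `marker_matrix` with the removal counts per criterion
#'   appended to its QC log.
#' @export
filter_markers <- function(m, max_missing = 0.60, min_maf = 0.05,
                           max_het = 0.10) {
  st <- marker_stats(m)
  bad_miss <- st$missing > max_missing
  bad_maf <- is.na(st$maf) | st$maf < min_maf
  bad_het <- !is.na(st$het) & st$het > max_het
  keep <- !(bad_miss | bad_maf | bad_het)
  if (!any(keep))
    stop("no markers pass the filters; review thresholds (max_missing=",
         max_missing, ", min_maf=", min_maf, ", max_het=", max_het, ")")
  out <- marker_matrix(unclass(m)[, keep, drop = FALSE],
                       qc_log = attr(m, "qc_log"))
  for (a in names(attributes(m))) {
    if (a == "complete")
      attr(out, "complete") <- attr(m, "complete")[, keep, drop = FALSE]
  }
  append_qc(out, "filter_markers",
            sprintf("removed %d (missing>%g: %d, maf<%g: %d, het>%g: %d), kept %d",
                    sum(!keep), max_missing, sum(bad_miss), min_maf,
                    sum(bad_maf), max_het, sum(bad_het), sum(keep)))
}

#' Filter lines on missingness
#'
#' Removes lines whose fraction of missing calls exceeds `max_missing`
#' (default 50%).
#'
#' @param m A [marker_matrix()].
#' @param max_missing Maximum tolerated missing fraction per line.
#' @return Filtered `marker_matrix`.
#' @export
filter_lines <- function(m, max_missing = 0.50) {
  x <- unclass(m)
  miss <- rowMeans(is.na(x))
  keep <- miss <= max_missing
  if (!any(keep))
    stop("no lines pass the filter; review max_missing=", max_missing)
  out <- marker_matrix(x[keep, , drop = FALSE], qc_log = attr(m, "qc_log"))
  if (!is.null(attr(m, "complete")))
    attr(out, "complete") <- attr(m, "complete")[keep, , drop = FALSE]
  append_qc(out, "filter_lines",
            sprintf("removed %d of %d lines (missing > %g)",
                    sum(!keep), length(keep), max_missing))
}

#' Full marker/line QC pass
#'
#' Markers are filtered first, then lines, then markers are re-checked once
#' (line removal can change marker statistics).
#'
#' @inheritParams filter_markers
#' @param max_line_missing Line missingness threshold.
#' @return Filtered `marker_matrix`.
#' @export
qc_genotypes <- function(m, max_missing = 0.60, min_maf = 0.05,
                         max_het = 0.10, max_line_missing = 0.50) {
  m <- filter_markers(m, max_missing, min_maf, max_het)
  m <- filter_lines(m, max_line_missing)
  filter_markers(m, max_missing, min_maf, max_het)
}

#' LD-based k-nearest-neighbour imputation of missing calls
#'
#' Each missing call is replaced by the weighted modal call of the `k`
#' markers most correlated with the target marker, where correlation is the
#' squared Pearson correlation computed on lines where both markers are
#' observed, and the vote weights are those r-squared values. Markers with
#' no correlated neighbour (or neighbours all missing for the line) fall
#' back to the marker's modal call; markers with fewer than two observed
#' calls fall back to the global modal call with a warning. Observed calls
#' are never altered.
#'
#' @param m A filtered [marker_matrix()].
#' @param k Number of neighbour markers (default 5).
#' @param min_r2 Minimum squared correlation for a marker to count as a
#'   neighbour (default 0.01).
#' @return Complete `marker_matrix` (zero missing).
#' @export
knn_impute <- function(m, k = 5, min_r2 = 0.01) {
  x <- unclass(m)
  if (!anyNA(x)) return(m)
  xd <- x
  storage.mode(xd) <- "double"
  has_na <- which(colSums(is.na(xd)) > 0L)
  n_obs <- colSums(!is.na(xd))
  modal_call <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    tab <- tabulate(v + 1L, nbins = 3L)
    as.integer(which.max(tab) - 1L)
  }
  global_mode <- modal_call(as.vector(x))
  marker_mode <- apply(x, 2, modal_call)
  # pairwise-complete correlations of missing-containing markers vs all
  suppressWarnings(
    R <- stats::cor(xd[, has_na, drop = FALSE], xd,
                    use = "pairwise.complete.obs"))
  R2 <- R^2
  out <- x
  warned <- FALSE
  for (jj in seq_along(has_na)) {
    j <- has_na[jj]
    rows <- which(is.na(x[, j]))
    if (n_obs[j] < 2L) {
      out[rows, j] <- global_mode
      warned <- TRUE
      next
    }
    r2 <- R2[jj, ]
    r2[j] <- NA
    r2[is.na(r2) | r2 < min_r2] <- NA
    nb <- order(r2, decreasing = TRUE, na.last = NA)
    nb <- nb[seq_len(min(k, length(nb)))]
    for (i in rows) {
      fill <- marker_mode[j]
      if (length(nb)) {
        calls <- x[i, nb]
        w <- r2[nb]
        ok <- !is.na(calls)
        if (any(ok)) {
          votes <- tapply(w[ok], calls[ok], sum)
          fill <- as.integer(names(votes)[which.max(votes)])
        }
      }
      if (is.na(fill)) fill <- global_mode
      out[i, j] <- fill
    }
  }
  if (warned)
    warning("markers with <2 observed calls imputed with the global modal call")
  out <- marker_matrix(out, qc_log = attr(m, "qc_log"))
  if (!is.null(attr(m, "complete"))) attr(out, "complete") <- attr(m, "complete")
  append_qc(out, "knn_impute",
            sprintf("imputed %d calls in %d markers (k=%d)",
                    sum(is.na(x)), length(has_na), k))
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = W W' / (2 * sum(p_j (1 - p_j)))` where `W` is the genotype matrix
#' centred at twice the observed allele frequencies. If the smallest
#' eigenvalue is below `-1e-8` the matrix is bent by adding a small constant
#' to the diagonal (logged as an attribute).
#'
#' @param m A complete (imputed) [marker_matrix()].
#' @return A symmetric line x line `grm` matrix.
#' @export
compute_grm <- function(m) {
  x <- unclass(m)
  if (anyNA(x)) stop("genotypes contain missing calls; impute first")
  storage.mode(x) <- "double"
  p <- colMeans(x) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic; GRM denominator is zero")
  W <- sweep(x, 2, 2 * p)
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  bent <- 0
  if (ev_min < -1e-8) {
    bent <- -ev_min + 1e-8
    G <- G + diag(bent, nrow(G))
  }
  structure(G, class = c("grm", "matrix"), bent = bent)
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d lines, mean diagonal %.3f", nrow(x), mean(diag(x))))
  if (attr(x, "bent") > 0) cat(sprintf(", bent by %.2e", attr(x, "bent")))
  cat("\n")
  invisible(x)
}
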
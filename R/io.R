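#' Write / read a plain line x marker genotype table
#'
#' Tab-separated, first column `line`, remaining columns one per marker,
#' calls 0/1/2 with `NA` for missing.
#'
#' @param m A [marker_matrix()].
#' @param path Output file.
#' @export
write_genotype_table <- function(m, path) {
  df <- data.frame(line = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df[[1]]
  marker_matrix(calls)
}

#' Write / read a HapMap-like genotype file
#'
#' Columns `rs`, `alleles`, `chrom`, `pos` followed by one column per line;
#' calls are letter pairs with `A` the major and `B` the minor allele
#' (`AA`/`AB`/`BB`, `NN` missing). Rows are markers.
#'
#' @param m A [marker_matrix()].
#' @param path Output file.
#' @param chrom,pos Optional vectors of marker coordinates (defaults: one
#'   pseudo-chromosome, consecutive positions).
#' @export
write_genotype_hapmap <- function(m, path, chrom = NULL, pos = NULL) {
  x <- t(unclass(m))  # markers in rows
  code <- c("AA", "AB", "BB")
  txt <- matrix("NN", nrow(x), ncol(x))
  obs <- !is.na(x)
  txt[obs] <- code[x[obs] + 1L]
  if (is.null(chrom)) chrom <- rep("1", nrow(x))
  if (is.null(pos)) pos <- seq_len(nrow(x))
  df <- data.frame(rs = rownames(x), alleles = "A/B", chrom = chrom,
                   pos = pos, txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[-(1:4)] <- colnames(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_hapmap
#' @export
read_genotype_hapmap <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  txt <- as.matrix(df[, -(1:4), drop = FALSE])
  calls <- matrix(NA_integer_, nrow(txt), ncol(txt))
  calls[txt == "AA"] <- 0L
  calls[txt == "AB" | txt == "BA"] <- 1L
  calls[txt == "BB"] <- 2L
  rownames(calls) <- df$rs
  colnames(calls) <- colnames(txt)
  marker_matrix(t(calls))
}

#' Read genotypes from a VCF (GT field, unphased)
#'
#' Minimal reader for plain-text VCF: parses the GT subfield of each sample
#' column and codes genotypes as the count of the ALT allele (0/1/2, `NA`
#' for `./.`). Multi-allelic records are dropped with a message.
#'
#' @param path VCF file (uncompressed).
#' @return A [marker_matrix()] (lines = samples).
#' @export
read_genotype_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t")
  samples <- cols[-(1:9)]
  keep <- vapply(fields, function(f) !grepl(",", f[5]), TRUE)
  if (any(!keep)) message("dropped ", sum(!keep), " multi-allelic records")
  fields <- fields[keep]
  calls <- matrix(NA_integer_, length(samples), length(fields))
  ids <- character(length(fields))
  for (j in seq_along(fields)) {
    f <- fields[[j]]
    ids[j] <- if (f[3] != ".") f[3] else paste0(f[1], "_", f[2])
    fmt <- strsplit(f[9], ":")[[1]]
    gt_i <- which(fmt == "GT")[1]
    gt <- vapply(strsplit(f[-(1:9)], ":"), `[`, "", gt_i)
    al <- strsplit(gt, "[/|]")
    calls[, j] <- vapply(al, function(a) {
      a <- suppressWarnings(as.integer(a))
      if (anyNA(a)) NA_integer_ else sum(a)
    }, 0L)
  }
  rownames(calls) <- samples
  colnames(calls) <- make.unique(ids)
  marker_matrix(calls)
}

#' Write / read long-format phenotype records
#'
#' CSV with columns `line, env, cycle, trial, rep, block, yield`.
#'
#' @param records A `field_trial_records` data frame.
#' @param path Output file.
#' @param seed Optional seed recorded as a `# seed=` comment header.
#' @export
write_phenotypes <- function(records, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  utils::write.csv(as.data.frame(records), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("line", "env", "cycle", "trial", "rep", "block", "yield")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  class(df) <- c("field_trial_records", "data.frame")
  df
}

#' Write simulation truth to a CSV pair
#'
#' `<prefix>_breeding_values.csv` holds the line x environment true additive
#' values; `<prefix>_parameters.csv` the per-environment genetic variances
#' and the generating genetic correlation matrix (long format).
#'
#' @param truth A `genetic_truth`.
#' @param prefix Path prefix.
#' @param seed Optional seed recorded in the header.
#' @export
write_truth <- function(truth, prefix, seed = NULL) {
  bv_path <- paste0(prefix, "_breeding_values.csv")
  par_path <- paste0(prefix, "_parameters.csv")
  bv <- data.frame(line = rownames(truth$breeding_values),
                   truth$breeding_values, check.names = FALSE)
  con <- file(bv_path, "w"); on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  utils::write.csv(bv, con, row.names = FALSE, quote = FALSE)
  gc <- truth$gc_matrix
  long <- data.frame(
    env_x = rep(rownames(gc), ncol(gc)),
    env_y = rep(colnames(gc), each = nrow(gc)),
    gc = as.vector(gc),
    sigma_g2_x = rep(truth$sigma_g2, ncol(gc)))
  con2 <- file(par_path, "w")
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con2)
  utils::write.csv(long, con2, row.names = FALSE, quote = FALSE)
  close(con2)
  invisible(c(bv_path, par_path))
}

#' Write / read a per-environment BLUE table
#'
#' CSV with columns `environment, line, blue, se`.
#'
#' @param blues A `blue_table` data frame.
#' @param path Output file.
#' @param seed Optional seed comment header.
#' @export
write_blues <- function(blues, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  utils::write.csv(as.data.frame(blues), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_blues
#' @export
read_blues <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("environment", "line", "blue") %in% names(df)))
    stop("BLUE file must have columns environment, line, blue")
  class(df) <- c("blue_table", "data.frame")
  df
}
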
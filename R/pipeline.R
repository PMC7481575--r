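#' Run the full retrospective analysis pipeline
#'
#' Orchestrates simulate-or-ingest, marker QC and imputation, GRM
#' construction, per-environment BLUEs, heritabilities, genetic
#' correlations, response ratios, site clustering and pairwise
#' selection-to-target genomic prediction, writing every intermediate
#' artifact plus a machine-readable `manifest.json` under `out_dir`.
#' In REML mode a fixed seed reproduces all numeric outputs bit-for-bit.
#'
#' @param config A list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{mode}{`"synthetic"` (default) or `"files"`.}
#'     \item{sim}{Synthetic mode: `n_lines`, `n_markers`, `environments`
#'       (list of lists with `env_id`, `mean_yield`, `h2_plot`,
#'       `sigma_g2`, `env_variance`), optional `gc` (correlation between
#'       every environment pair, or full matrix), plus any [sim_config()]
#'       field.}
#'     \item{paths}{File mode: `genotypes` (line x marker table),
#'       `phenotypes` (long CSV).}
#'     \item{qc}{`max_missing`, `min_maf`, `max_het`, `max_line_missing`,
#'       `k` (imputation neighbours).}
#'     \item{cohorts}{`selection_envs`, `target_envs` (labels).}
#'     \item{significance}{GC significance threshold (default 0.05).}
#'     \item{n_clusters}{Branches for site clustering (default
#'       `min(5, n_env)`).}
#'     \item{sampler}{`backend` ("reml" default or "gibbs"), `n_iter`,
#'       `burn_in`, `thin`.}
#'     \item{seed}{Global seed; per-stage child seeds are derived from it
#'       by fixed offsets.}
#'     \item{out_dir}{Output directory.}
#'   }
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- config$mode %||% "synthetic"
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, mode = mode, stages = list())
  files <- character(0)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      stage = name, seed = seed,
      runtime_s = as.numeric(difftime(Sys.time(), st, units = "secs")))
    res
  }
  emit <- function(path) { files <<- c(files, path); path }

  # --- inputs -------------------------------------------------------------
  if (mode == "synthetic") {
    sim <- config$sim %||% stop("synthetic mode needs config$sim")
    envs <- lapply(sim$environments, function(e)
      env_spec(e$env_id, e$mean_yield %||% 5, e$h2_plot %||% 0.5,
               e$sigma_g2 %||% 0.1, e$env_variance %||% 0))
    n_env <- length(envs)
    gcm <- sim$gc
    if (is.null(gcm)) gcm <- diag(n_env)
    else if (length(gcm) == 1L) {
      gcm <- matrix(gcm, n_env, n_env); diag(gcm) <- 1
    } else gcm <- matrix(unlist(gcm), n_env, n_env)
    cfg <- sim_config(
      n_lines = sim$n_lines, n_markers = sim$n_markers,
      environments = envs, gc_matrix = gcm,
      maf_range = unlist(sim$maf_range %||% c(0.05, 0.5)),
      marker_missing_rate = sim$marker_missing_rate %||% 0.1,
      het_rate = sim$het_rate %||% 0.05,
      n_reps = sim$n_reps %||% 2,
      trial_size = sim$trial_size %||% 50,
      n_checks = sim$n_checks %||% 0,
      block_effect_sd = sim$block_effect_sd %||% 0.15,
      rep_effect_sd = sim$rep_effect_sd %||% 0.1,
      trial_effect_sd = sim$trial_effect_sd %||% 0.2,
      seed = seed)
    met <- stage("simulate", simulate_met(cfg))
    geno <- met$genotypes
    records <- met$records
    stage("write_inputs", {
      emit(write_genotype_table(geno, file.path(out_dir, "genotypes.tsv")))
      emit(write_phenotypes(records, file.path(out_dir, "phenotypes.csv"),
                            seed = seed))
      for (p in write_truth(met$truth, file.path(out_dir, "truth"),
                            seed = seed)) emit(p)
    })
  } else if (mode == "files") {
    paths <- config$paths %||% stop("file mode needs config$paths")
    if (!file.exists(paths$genotypes)) stop("missing ", paths$genotypes)
    if (!file.exists(paths$phenotypes)) stop("missing ", paths$phenotypes)
    geno <- stage("read_genotypes", read_genotype_table(paths$genotypes))
    records <- stage("read_phenotypes", read_phenotypes(paths$phenotypes))
  } else stop("unknown mode: ", mode)

  # --- marker QC, imputation, GRM ----------------------------------------
  qc <- config$qc %||% list()
  geno_qc <- stage("marker_qc", qc_genotypes(
    geno, max_missing = qc$max_missing %||% 0.60,
    min_maf = qc$min_maf %||% 0.05, max_het = qc$max_het %||% 0.10,
    max_line_missing = qc$max_line_missing %||% 0.50))
  geno_imp <- stage("impute", knn_impute(geno_qc, k = qc$k %||% 5))
  grm <- stage("grm", compute_grm(geno_imp))
  stage("write_grm", {
    g <- data.frame(line = rownames(grm), unclass(grm), check.names = FALSE)
    p <- file.path(out_dir, "grm.csv")
    utils::write.csv(g, p, row.names = FALSE, quote = FALSE)
    emit(p)
  })

  # --- BLUEs and heritabilities ------------------------------------------
  env_ids <- unique(records$env)
  blues <- stage("blues", {
    out <- lapply(env_ids, function(e) compute_blues(records, e))
    names(out) <- env_ids
    out
  })
  stage("write_blues", for (e in env_ids)
    emit(write_blues(blues[[e]], file.path(out_dir, paste0("blues_", e, ".csv")),
                     seed = seed)))
  n_reps <- length(unique(records$rep))
  h2_tab <- stage("heritability", {
    do.call(rbind, lapply(env_ids, function(e) {
      est <- suppressWarnings(estimate_h2(blues[[e]], grm, n_reps = n_reps))
      est$environment <- e
      est
    }))
  })
  stage("write_h2", {
    p <- file.path(out_dir, "heritability.csv")
    con <- file(p, "w"); writeLines(paste0("# seed=", seed), con)
    utils::write.csv(h2_tab, con, row.names = FALSE, quote = FALSE)
    close(con); emit(p)
  })

  # --- genetic correlations, response ratios, clustering -----------------
  blue_vecs <- lapply(blues, as_named_values)
  gc_mat <- stage("genetic_correlations",
                  if (length(env_ids) >= 2)
                    suppressWarnings(estimate_gc_matrix(blue_vecs, grm))
                  else NULL)
  if (!is.null(gc_mat)) stage("write_gc", {
    p <- file.path(out_dir, "gc_matrix.csv")
    long <- data.frame(
      env_x = rep(rownames(gc_mat$r), ncol(gc_mat$r)),
      env_y = rep(colnames(gc_mat$r), each = nrow(gc_mat$r)),
      r_a = as.vector(gc_mat$r), pvalue = as.vector(gc_mat$pvalues))
    con <- file(p, "w"); writeLines(paste0("# seed=", seed), con)
    utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
    close(con); emit(p)
  })
  cohorts <- config$cohorts %||% list()
  se_ids <- intersect(cohorts$selection_envs %||% character(0), env_ids)
  tpe_ids <- intersect(cohorts$target_envs %||% character(0), env_ids)
  ratios <- NULL
  if (length(se_ids) && length(tpe_ids) && !is.null(gc_mat)) {
    ratios <- stage("response_ratios", {
      do.call(rbind, lapply(se_ids, function(se)
        do.call(rbind, lapply(tpe_ids, function(tp) {
          response_ratio(
            gc_mat$r[se, tp],
            h2_tab$h2[match(se, h2_tab$environment)],
            h2_tab$h2[match(tp, h2_tab$environment)],
            selection_env = se, target_env = tp)
        }))))
    })
    stage("write_ratios", {
      p <- file.path(out_dir, "response_ratios.csv")
      con <- file(p, "w"); writeLines(paste0("# seed=", seed), con)
      utils::write.csv(ratios, con, row.names = FALSE, quote = FALSE)
      close(con); emit(p)
    })
  }
  clusters <- NULL
  n_clusters <- config$n_clusters %||% min(5L, length(env_ids))
  if (!is.null(gc_mat) && length(env_ids) >= max(2L, n_clusters)) {
    clusters <- stage("cluster_sites", cluster_sites(gc_mat, n_clusters))
    stage("write_clusters", {
      p <- file.path(out_dir, "clusters.csv")
      con <- file(p, "w"); writeLines(paste0("# seed=", seed), con)
      utils::write.csv(data.frame(site = names(clusters$labels),
                                  cluster = unname(clusters$labels)),
                       con, row.names = FALSE, quote = FALSE)
      close(con); emit(p)
      pn <- file.path(out_dir, "dendrogram.nwk")
      writeLines(clusters$newick, pn); emit(pn)
    })
  }

  # --- pairwise prediction ------------------------------------------------
  prediction <- NULL
  if (length(se_ids) && length(tpe_ids)) {
    sampler <- config$sampler %||% list()
    prediction <- stage("pairwise_prediction", run_pairwise(
      blue_vecs[se_ids], blue_vecs[tpe_ids], grm,
      backend = sampler$backend %||% "reml",
      n_iter = sampler$n_iter %||% 12000,
      burn_in = sampler$burn_in %||% 2000,
      thin = sampler$thin %||% 5, seed = seed + 7L))
    stage("write_prediction", {
      p <- file.path(out_dir, "prediction_pairs.csv")
      con <- file(p, "w"); writeLines(paste0("# seed=", seed), con)
      utils::write.csv(prediction, con, row.names = FALSE, quote = FALSE)
      close(con); emit(p)
    })
  }

  manifest$files <- files
  manifest$runtime_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(blues = blues, h2 = h2_tab, gc = gc_mat, ratios = ratios,
                 clusters = clusters, prediction = prediction,
                 manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
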
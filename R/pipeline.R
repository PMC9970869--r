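#' Build and validate a pipeline run configuration
#'
#' @param seed Integer master seed for every stochastic stage.
#' @param out_dir Output directory.
#' @param synthetic List describing a synthetic cohort
#'   (\code{n_signatures}, \code{n_samples}, \code{mean_exposure},
#'   \code{sdlog}, \code{scheme}, \code{max_cosine}); ignored when
#'   \code{catalog} is given.
#' @param catalog Optional path to a catalog TSV.
#' @param extraction List: \code{k_min}, \code{k_max}, \code{replicates},
#'   \code{min_iter}, \code{max_iter}, \code{tol}.
#' @param decomposition List: \code{min_cosine}, \code{min_gain},
#'   \code{delta}, \code{activity_threshold}, \code{reference} (path to a
#'   reference TSV; NULL uses the bundled synthetic reference).
#' @param stats List: \code{fdr}, \code{n_sim}.
#' @return Validated list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, out_dir = "sigforge_out",
                       synthetic = list(), catalog = NULL,
                       extraction = list(), decomposition = list(),
                       stats = list()) {
  syn_def <- list(n_signatures = 3L, n_samples = 30L, mean_exposure = 600,
                  sdlog = 0.4, scheme = "SBS96", max_cosine = 0.6)
  ext_def <- list(k_min = 2L, k_max = 5L, replicates = 10L, min_iter = 200L,
                  max_iter = 5000L, tol = 1e-9)
  dec_def <- list(min_cosine = 0.85, min_gain = 0.01, delta = 0.02,
                  activity_threshold = 0.05, reference = NULL)
  sta_def <- list(fdr = 0.05, n_sim = 100L)
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              synthetic = utils::modifyList(syn_def, synthetic),
              catalog = catalog,
              extraction = utils::modifyList(ext_def, extraction),
              decomposition = utils::modifyList(dec_def, decomposition),
              stats = utils::modifyList(sta_def, stats))
  with(cfg$extraction, {
    if (k_max < k_min) stop("config error: k_max < k_min")
    if (replicates < 2) stop("config error: replicates must be >= 2")
  })
  with(cfg$decomposition, {
    if (min_cosine < 0 || min_cosine > 1) stop("config error: min_cosine outside [0,1]")
    if (activity_threshold < 0 || activity_threshold > 1)
      stop("config error: activity_threshold outside [0,1]")
  })
  if (cfg$stats$fdr <= 0 || cfg$stats$fdr >= 1) stop("config error: fdr outside (0,1)")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from JSON or YAML
#' @param path Config file path.
#' @return \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Run the full signature-analysis pipeline
#'
#' Chains catalog generation (or loading), replicated KL-NMF extraction over
#' a rank range, stability-based rank selection, decomposition of the
#' selected de novo signatures into a reference catalog, per-sample NNLS
#' refitting with minimum-activity filtering, and the downstream statistics
#' available for the inputs. All numeric outputs are deterministic given
#' the configuration. A provenance manifest (seed, thresholds, stage
#' counts) is written alongside the result tables.
#'
#' @param config \code{run_config} (or list/path accepted by
#'   \code{run_config()} / \code{read_run_config()}).
#' @return Invisible list with the in-memory results; files are written
#'   under \code{config$out_dir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(seed = config$seed, config = unclass(config),
                   package_version = as.character(utils::packageVersion("sigforge")))

  cohort <- NULL
  M <- stage("catalog", {
    if (!is.null(config$catalog)) {
      read_catalog(config$catalog)
    } else {
      syn <- config$synthetic
      S_true <- synthetic_signatures(syn$n_signatures, scheme = syn$scheme,
                                     seed = derive_seed(config$seed, 11L),
                                     max_cosine = syn$max_cosine)
      cohort <- simulate_catalog_cohort(
        S_true, n_samples = syn$n_samples,
        seed = derive_seed(config$seed, 12L),
        exposure_model = list(mean = syn$mean_exposure, sdlog = syn$sdlog))
      cohort <- simulate_covariates(cohort,
                                    seed = derive_seed(config$seed, 13L))
      write_cohort(cohort, file.path(config$out_dir, "truth"))
      unclass(cohort$catalog)
    }
  })
  write_catalog(M, file.path(config$out_dir, "catalog.tsv"))
  manifest$n_channels <- nrow(M); manifest$n_samples <- ncol(M)
  manifest$n_mutations <- sum(M)

  ext <- config$extraction
  solutions <- stage("extraction", {
    lapply(ext$k_min:ext$k_max, function(k)
      extract_consensus(M, k, n_replicates = ext$replicates,
                        seed = derive_seed(config$seed, 20L + k),
                        min_iter = ext$min_iter, max_iter = ext$max_iter,
                        tol = ext$tol))
  })
  sel <- stage("rank_selection", select_rank(solutions))
  jsonlite::write_json(
    list(selected_k = sel$k, stable = sel$stable, table = sel$table),
    file.path(config$out_dir, "stability.json"), auto_unbox = TRUE, digits = NA)
  best <- solutions[[which(vapply(solutions, function(s) as.integer(s$k), 0L) == sel$k)]]
  write_catalog(best$S, file.path(config$out_dir,
                                  sprintf("denovo_signatures_k%d.tsv", sel$k)))
  write_catalog(best$A, file.path(config$out_dir,
                                  sprintf("denovo_activities_k%d.tsv", sel$k)))

  dec <- config$decomposition
  reference <- stage("reference", {
    if (!is.null(dec$reference)) read_catalog(dec$reference)
    else synthetic_reference_catalog(
      if (nrow(M) == 83) "ID83" else "SBS96")
  })
  decomps <- stage("decomposition", {
    lapply(seq_len(ncol(best$S)), function(j)
      decompose_to_reference(best$S[, j], reference,
                             min_cosine = dec$min_cosine,
                             min_gain = dec$min_gain))
  })
  names(decomps) <- colnames(best$S)
  jsonlite::write_json(
    lapply(decomps, function(d) list(weights = as.list(d$weights),
                                     cosine = d$cosine, accepted = d$accepted)),
    file.path(config$out_dir, "decomposition.json"), auto_unbox = TRUE,
    digits = NA)

  refit <- stage("refit", {
    assigned <- sort(unique(unlist(lapply(decomps[vapply(decomps, `[[`, TRUE,
                                                         "accepted")],
                                          `[[`, "selected"))))
    if (!length(assigned)) assigned <- colnames(reference)
    r <- refit_catalog(M, reference, allowed = assigned)
    r$exposures <- filter_min_activity(r$exposures,
                                       threshold = dec$activity_threshold)
    r
  })
  write_catalog(refit$exposures, file.path(config$out_dir, "exposures.tsv"))
  manifest$refit_median_cosine <- stats::median(refit$cosine, na.rm = TRUE)

  downstream <- stage("downstream", {
    out <- list()
    if (!is.null(cohort) && !is.null(cohort$covariates)) {
      cv <- cohort$covariates
      out$age <- age_correlation(refit$exposures, cv$age)
      out$assoc <- covariate_association(refit$exposures, cv,
                                         alpha = config$stats$fdr)
      out$instability <- instability_correlation(refit$exposures, cv$sv_count)
      utils::write.table(out$age, file.path(config$out_dir, "age_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(out$assoc, file.path(config$out_dir, "associations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(out$instability,
                         file.path(config$out_dir, "instability.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (nrow(M) == 83) {
      mh <- lapply(seq_len(ncol(M)), function(s) mh_deletion_proportion(M[, s]))
      idn <- lapply(seq_len(ncol(M)), function(s) idn_features(M[, s]))
      out$indel_features <- data.frame(
        sample = colnames(M),
        mh_fraction = vapply(mh, `[[`, 0, "mh_fraction"),
        idn_count = vapply(idn, `[[`, 0, "idn_count"))
      utils::write.table(out$indel_features,
                         file.path(config$out_dir, "indel_features.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(catalog = M, cohort = cohort, solutions = solutions,
                 selected = sel, best = best, decompositions = decomps,
                 refit = refit, downstream = downstream,
                 reference = reference, manifest = manifest))
}
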
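# Deterministic fan-out of one master seed into per-stage seeds.
stage_seed <- function(master_seed, stage) {
  as.integer((as.numeric(master_seed) * 7919 + as.numeric(stage)) %%
               2147483647)
}

#' Write a cohort dataset as plain-text files
#'
#' Serialises a cohort to `metadata.tsv`, `tau_matrix.tsv`,
#' `thickness_matrix.tsv`, `parcels.tsv`, optional `visits.tsv`, and a
#' `dataset.json` sidecar holding the generating spec and truth labels.
#'
#' @param cohort a `"synthetic_cohort"` (or compatible list).
#' @param dir output directory (created if absent).
#' @param visits optional visit table from [generate_visits()].
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(cohort, dir, visits = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f, rn = FALSE)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  tsv(cohort$metadata, "metadata.tsv")
  tsv(as.data.frame(cohort$tau), "tau_matrix.tsv", rn = TRUE)
  tsv(as.data.frame(cohort$thickness), "thickness_matrix.tsv", rn = TRUE)
  tsv(cohort$parcels, "parcels.tsv")
  if (!is.null(visits)) tsv(visits, "visits.tsv")
  sidecar <- list(spec = unclass(cohort$spec), truth = cohort$truth)
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Load a cohort dataset written by [write_dataset()]
#'
#' @param dir directory holding the TSV files.
#' @return list of class `"synthetic_cohort"` (truth/spec present when the
#'   sidecar exists).
#' @export
load_dataset <- function(dir) {
  read_tsv <- function(f, rn = FALSE) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing file: ", path)
    out <- tryCatch(
      utils::read.delim(path, check.names = FALSE,
                        row.names = if (rn) 1L else NULL,
                        stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e)))
    out
  }
  metadata <- read_tsv("metadata.tsv")
  tau <- as.matrix(read_tsv("tau_matrix.tsv", rn = TRUE))
  thickness <- as.matrix(read_tsv("thickness_matrix.tsv", rn = TRUE))
  parcels <- read_tsv("parcels.tsv")
  for (nm in c("tau", "thickness")) {
    M <- get(nm)
    bad <- c(setdiff(rownames(M), metadata$subject_id),
             setdiff(metadata$subject_id, rownames(M)))
    if (length(bad))
      stop("alignment error between metadata and ", nm,
           " matrix; offending ids: ", paste(unique(bad), collapse = ", "))
  }
  tau <- tau[metadata$subject_id, , drop = FALSE]
  thickness <- thickness[metadata$subject_id, , drop = FALSE]
  out <- list(metadata = metadata, tau = tau, thickness = thickness,
              parcels = parcels)
  vpath <- file.path(dir, "visits.tsv")
  if (file.exists(vpath)) out$visits <- read_tsv("visits.tsv")
  spath <- file.path(dir, "dataset.json")
  if (file.exists(spath)) {
    sidecar <- jsonlite::read_json(spath, simplifyVector = TRUE)
    sc <- sidecar$spec
    sc$cluster_sizes <- as.integer(sc$cluster_sizes)
    out$spec <- do.call(cohort_spec, sc)
    out$truth <- as.data.frame(sidecar$truth, stringsAsFactors = FALSE)
  }
  structure(out, class = "synthetic_cohort")
}

#' Pipeline configuration
#'
#' Everything [run_pipeline()] needs: a synthetic spec (or an input
#' directory of TSVs), per-modality clustering settings, stability and
#' comparison options, and a master seed fanned out deterministically to the
#' stages. Unknown arguments are rejected.
#'
#' @param spec a [cohort_spec()]; ignored when `input_dir` is given.
#' @param input_dir optional directory of a dataset written by
#'   [write_dataset()].
#' @param gamma_tau,gamma_atrophy resolution parameters per modality
#'   (reference values 1.2 and 1.32); set to `NULL` to search instead.
#' @param target_k cluster count for [gamma_search()] when a gamma is
#'   `NULL`.
#' @param gamma_grid grid for the search.
#' @param n_iterations Louvain restarts per consensus round.
#' @param run_stability evaluate LOO stability (can dominate runtime).
#' @param removal_sizes,reps_per_size stability protocol.
#' @param run_contrasts compute cluster-vs-rest permutation contrast maps.
#' @param n_perm permutations for contrast maps.
#' @param run_longitudinal estimate and compare annual change rates (needs
#'   visits).
#' @param slope_model `"per_subject_ols"` or `"mixed"`.
#' @param out_dir where [write_report()] puts tables (also used by
#'   `run-all`).
#' @param seed master seed.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(spec = cohort_spec(), input_dir = NULL,
                            gamma_tau = 1.2, gamma_atrophy = 1.32,
                            target_k = 4L, gamma_grid = seq(0.8, 2, by = 0.02),
                            n_iterations = 1000L, run_stability = FALSE,
                            removal_sizes = 1:5, reps_per_size = 10L,
                            run_contrasts = FALSE, n_perm = 1000L,
                            run_longitudinal = TRUE,
                            slope_model = "per_subject_ols",
                            out_dir = NULL, seed = 1L) {
  cfg <- list(spec = spec, input_dir = input_dir, gamma_tau = gamma_tau,
              gamma_atrophy = gamma_atrophy, target_k = as.integer(target_k),
              gamma_grid = gamma_grid, n_iterations = as.integer(n_iterations),
              run_stability = isTRUE(run_stability),
              removal_sizes = as.integer(removal_sizes),
              reps_per_size = as.integer(reps_per_size),
              run_contrasts = isTRUE(run_contrasts),
              n_perm = as.integer(n_perm),
              run_longitudinal = isTRUE(run_longitudinal),
              slope_model = match.arg(slope_model,
                                      c("per_subject_ols", "mixed")),
              out_dir = out_dir, seed = as.integer(seed))
  for (g in c("gamma_tau", "gamma_atrophy"))
    if (!is.null(cfg[[g]]) && cfg[[g]] <= 0)
      stop("validation error: ", g, " must be > 0")
  if (cfg$n_iterations < 1L) stop("validation error: n_iterations >= 1")
  if (is.null(cfg$input_dir)) validate_cohort_spec(cfg$spec)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON (or YAML) text
#'
#' Keys mirror the arguments of [pipeline_config()]; `spec` may be a nested
#' object of [cohort_spec()] arguments. Unknown keys are rejected.
#'
#' @param path config file; `.json` always supported, `.yml`/`.yaml` when
#'   the yaml package is installed.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs; use JSON")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$spec)) {
    spec_known <- names(formals(cohort_spec))
    bad <- setdiff(names(raw$spec), spec_known)
    if (length(bad))
      stop("unknown spec key(s): ", paste(bad, collapse = ", "))
    raw$spec <- do.call(cohort_spec, raw$spec)
  }
  do.call(pipeline_config, raw)
}

#' Run the full subtyping workflow
#'
#' Generate or load the cohort, z-score both modalities against the HC
#' reference, consensus-cluster each modality (fixed gamma or gamma
#' search), then — as configured — evaluate LOO stability, cross-modal
#' allocation and Spearman coupling, cluster-vs-rest contrast maps, and
#' longitudinal change-rate comparisons. Each stage failure is tagged with
#' the stage name.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"report_bundle"`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  cohort <- stage("data", {
    if (!is.null(config$input_dir)) load_dataset(config$input_dir)
    else generate_cohort(config$spec)
  })
  visits <- cohort$visits
  if (is.null(visits) && config$run_longitudinal && !is.null(cohort$spec))
    visits <- stage("data", generate_visits(cohort))

  norm <- stage("normalization", {
    hc <- cohort$metadata$group == "HC"
    list(
      tau = vertex_zscores(cohort$tau[!hc, , drop = FALSE],
                           fit_reference(cohort$tau[hc, , drop = FALSE]),
                           modality = "tau"),
      thickness = vertex_zscores(cohort$thickness[!hc, , drop = FALSE],
                                 fit_reference(cohort$thickness[hc, ,
                                                                drop = FALSE]),
                                 modality = "thickness"))
  })

  cluster_one <- function(z, gamma, stage_idx) {
    cfg <- clustering_config(gamma = if (is.null(gamma)) 1 else gamma,
                             n_iterations = config$n_iterations,
                             seed = stage_seed(config$seed, stage_idx))
    S <- similarity_matrix(z)
    if (is.null(gamma)) {
      gs <- gamma_search(S, config$target_k, config$gamma_grid, cfg)
      list(partition = gs$partition, gamma = gs$gamma,
           k_by_gamma = gs$k_by_gamma)
    } else list(partition = consensus_cluster(S, cfg), gamma = gamma)
  }
  clus_tau <- stage("clustering_tau",
                    cluster_one(norm$tau, config$gamma_tau, 1L))
  clus_atr <- stage("clustering_atrophy",
                    cluster_one(norm$thickness, config$gamma_atrophy, 2L))

  stability <- NULL
  if (config$run_stability) {
    stability <- stage("stability", list(
      tau = loo_stability(norm$tau, clus_tau$gamma,
                          stability_config(config$removal_sizes,
                                           config$reps_per_size,
                                           stage_seed(config$seed, 3L)),
                          clustering_config(gamma = clus_tau$gamma,
                                            n_iterations = config$n_iterations,
                                            seed = stage_seed(config$seed, 3L))),
      atrophy = loo_stability(norm$thickness, clus_atr$gamma,
                              stability_config(config$removal_sizes,
                                               config$reps_per_size,
                                               stage_seed(config$seed, 4L)),
                              clustering_config(gamma = clus_atr$gamma,
                                                n_iterations = config$n_iterations,
                                                seed = stage_seed(config$seed, 4L)))))
  }

  compare <- stage("compare", {
    alloc <- allocation_overlap(clus_tau$partition$labels,
                                clus_atr$partition$labels)
    fac <- factor(cohort$parcels$parcel,
                  levels = unique(cohort$parcels$parcel))
    # degenerate vertices may have been dropped from the z matrices
    roi_tau <- parcel_means(norm$tau,
                            fac[match(colnames(norm$tau),
                                      cohort$parcels$vertex_name)])
    roi_thk <- parcel_means(norm$thickness,
                            fac[match(colnames(norm$thickness),
                                      cohort$parcels$vertex_name)])
    prof_tau <- cluster_roi_profile(roi_tau, clus_tau$partition$labels)
    prof_thk <- cluster_roi_profile(roi_thk, clus_atr$partition$labels)
    out <- list(allocation = alloc,
                crossmodal = crossmodal_spearman(prof_tau, prof_thk))
    if (config$run_contrasts) {
      out$most_least_tau <- most_least_maps(
        norm$tau, clus_tau$partition$labels, n_perm = config$n_perm,
        seed = stage_seed(config$seed, 5L))
      out$most_least_atrophy <- most_least_maps(
        norm$thickness, clus_atr$partition$labels, n_perm = config$n_perm,
        seed = stage_seed(config$seed, 6L))
    }
    out
  })

  longitudinal <- NULL
  if (config$run_longitudinal && !is.null(visits)) {
    longitudinal <- stage("longitudinal", {
      hc_ids <- cohort$metadata$subject_id[cohort$metadata$group == "HC"]
      ads_ids <- cohort$metadata$subject_id[cohort$metadata$group == "ADS"]
      out <- list()
      for (mod in c("tau", "vol")) {
        cols <- grep(paste0("^", mod, "_"), names(visits), value = TRUE)
        sl_hc <- subject_slopes(visits[visits$subject_id %in% hc_ids, ],
                                cols, model = config$slope_model)
        sl_ads <- subject_slopes(visits[visits$subject_id %in% ads_ids, ],
                                 cols, model = config$slope_model)
        cz <- slope_zscores(sl_ads, sl_hc)
        part <- if (mod == "tau") clus_tau$partition else clus_atr$partition
        labs <- part$labels[rownames(cz$z)]
        out[[mod]] <- list(change_z = cz,
                           comparison = compare_slopes(cz$z, labs))
      }
      out
    })
  }

  structure(list(partitions = list(tau = clus_tau$partition,
                                   atrophy = clus_atr$partition),
                 gammas = c(tau = clus_tau$gamma, atrophy = clus_atr$gamma),
                 stability = stability, compare = compare,
                 longitudinal = longitudinal,
                 provenance = list(seed = config$seed,
                                   n_iterations = config$n_iterations,
                                   package_version =
                                     as.character(utils::packageVersion("corticlust")),
                                   config = config)),
            class = "report_bundle")
}

#' Write a report bundle as TSV tables plus report.json
#'
#' @param bundle a `"report_bundle"` from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f, rn = FALSE)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  for (mod in c("tau", "atrophy")) {
    p <- bundle$partitions[[mod]]
    tsv(data.frame(subject_id = names(p$labels), cluster = p$labels),
        paste0("partition_", mod, ".tsv"))
    tsv(as.data.frame(p$coassignment), paste0("coassignment_", mod, ".tsv"),
        rn = TRUE)
  }
  tsv(as.data.frame.matrix(bundle$compare$allocation$counts),
      "allocation_counts.tsv", rn = TRUE)
  tsv(as.data.frame(bundle$compare$crossmodal$rho), "crossmodal_rho.tsv",
      rn = TRUE)
  if (!is.null(bundle$stability))
    for (mod in names(bundle$stability))
      tsv(bundle$stability[[mod]]$results,
          paste0("stability_", mod, ".tsv"))
  if (!is.null(bundle$longitudinal))
    for (mod in names(bundle$longitudinal))
      tsv(bundle$longitudinal[[mod]]$comparison$table,
          paste0("kw_results_", mod, ".tsv"))
  summary_json <- list(
    gammas = as.list(bundle$gammas),
    k = lapply(bundle$partitions, function(p) p$k),
    cluster_sizes = lapply(bundle$partitions,
                           function(p) as.list(table(p$labels))),
    allocation_chisq = bundle$compare$allocation$chisq,
    allocation_p = bundle$compare$allocation$p_value,
    stability_median_ri = if (!is.null(bundle$stability))
      lapply(bundle$stability, function(s) stats::median(s$results$ri)),
    provenance = list(seed = bundle$provenance$seed,
                      n_iterations = bundle$provenance$n_iterations,
                      package_version = bundle$provenance$package_version))
  jsonlite::write_json(summary_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Command-line entry point
#'
#' Verbs: `simulate`, `run-all` (the full pipeline + report). Common flags:
#' `--config <file>`, `--seed <int>`, `--out <dir>`. Flags override config
#' keys; effective values are echoed.
#'
#' @param args character vector (defaults to the process arguments).
#' @return exit status, invisibly.
#' @export
corticlust_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: corticlust <simulate|run-all> [--config f] [--seed n] [--out d]\n")
    return(invisible(1L))
  }
  verb <- args[[1L]]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[[i + 1L]] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "corticlust_out")
  cfg <- if (!is.null(opt("--config"))) read_pipeline_config(opt("--config"))
  else pipeline_config()
  cfg$seed <- seed
  cfg$spec$seed <- seed
  message("verb=", verb, " seed=", seed, " out=", out)
  if (verb == "simulate") {
    cohort <- generate_cohort(cfg$spec)
    write_dataset(cohort, out, visits = generate_visits(cohort))
    message("dataset written to ", out)
  } else if (verb == "run-all") {
    bundle <- run_pipeline(cfg)
    write_report(bundle, out)
    message("report written to ", out)
  } else {
    stop("unknown verb: ", verb)
  }
  invisible(0L)
}
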
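## End-to-end orchestration: a validated config object, stable per-stage
## child seeds fanned out from one global seed, and a run manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. The defaults
#' are the pipeline's reference settings: gene filter at 10 total
#' counts, ~3000 variable features, K = 30 neighbors, top 30 markers per
#' apex cluster, 40 simplex grid locations, 3 kb upstream promoter
#' window, 5% extreme quantile for the steady-state fit.
#'
#' @param sim a [sim_params()] object, or `NULL` when reading data from
#'   disk.
#' @param input_dir directory with MTX layers + features/barcodes +
#'   labels.tsv (ignored when `sim` is given).
#' @param output_dir where outputs are written.
#' @param apex_clusters named length-3 fate -> cluster-label vector for
#'   [apex_spec()]; `NULL` with `sim` uses the simulator's three fates.
#' @param min_counts,n_features,n_pcs,knn_k,top_k,n_bins,upstream_bp,extreme_quantile
#'   stage tunables (see the stage functions for semantics).
#' @param exclude_self,edge_mean stage options, see
#'   [mean_distance_to_apex()] and [fate_potential()].
#' @param seed global seed; per-stage child seeds are derived stably
#'   from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_params(),
                            input_dir = NULL,
                            output_dir = tempfile("fatesimplex_run_"),
                            apex_clusters = NULL,
                            min_counts = 10,
                            n_features = 3000,
                            n_pcs = 30,
                            knn_k = 30,
                            top_k = 30,
                            n_bins = 40,
                            upstream_bp = 3000,
                            extreme_quantile = 0.05,
                            exclude_self = FALSE,
                            edge_mean = FALSE,
                            seed = 1L) {
  if (is.null(sim) && is.null(input_dir))
    stop("config needs either 'sim' or 'input_dir'")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  cfg <- list(sim = sim, input_dir = input_dir, output_dir = output_dir,
              apex_clusters = apex_clusters, min_counts = min_counts,
              n_features = n_features, n_pcs = n_pcs, knn_k = knn_k,
              top_k = top_k, n_bins = n_bins, upstream_bp = upstream_bp,
              extreme_quantile = extreme_quantile,
              exclude_self = exclude_self, edge_mean = edge_mean,
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Derive a stable per-stage child seed from the global seed
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer child seed (below 2^31).
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Write / read a pipeline config as YAML
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @return invisibly `path`; `read_pipeline_config()` returns the
#'   config.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (!is.null(x$sim)) x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- if (!is.null(x$sim)) do.call(sim_params, x$sim) else NULL
  apx <- if (!is.null(x$apex_clusters)) unlist(x$apex_clusters) else NULL
  pipeline_config(sim = sim, input_dir = x$input_dir,
                  output_dir = x$output_dir, apex_clusters = apx,
                  min_counts = x$min_counts, n_features = x$n_features,
                  n_pcs = x$n_pcs, knn_k = x$knn_k, top_k = x$top_k,
                  n_bins = x$n_bins, upstream_bp = x$upstream_bp,
                  extreme_quantile = x$extreme_quantile,
                  exclude_self = x$exclude_self,
                  edge_mean = x$edge_mean, seed = x$seed)
}

#' Run the full pipeline: simulate/load -> preprocess -> markers ->
#' simplex -> velocity -> potential -> arrows
#'
#' Executes every stage with the config's tunables, writes coords.tsv,
#' arrows.tsv, markers.tsv, velocity_graph.tsv, labels.tsv and a
#' manifest.yaml under `output_dir` (when `write = TRUE`), and returns
#' all intermediate objects.
#'
#' @param config a [pipeline_config()].
#' @param write write outputs to `config$output_dir` (default `TRUE`).
#' @return invisibly, a list with `bundle`, `labels`, `truth` (simulated
#'   runs only), `normalized`, `features`, `scaled`, `apex`, `markers`,
#'   `marker_sets`, `coords`, `gamma`, `field`, `graph`, `potential`,
#'   `arrows`, `manifest`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package = "fatesimplex",
                   version = as.character(utils::packageVersion("fatesimplex")),
                   seed = config$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  ## --- input ------------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- stage_seed(config$seed, "simulate")
    simres <- simulate_fate_landscape(sim)
    bundle <- simres$bundle; labels <- simres$labels
    truth <- simres$truth
    apex <- apex_spec(if (is.null(config$apex_clusters))
      stats::setNames(.fate_names, .fate_names) else config$apex_clusters)
  } else {
    mtx <- c(spliced = file.path(config$input_dir, "spliced.mtx"),
             unspliced = file.path(config$input_dir, "unspliced.mtx"))
    missing <- !file.exists(c(mtx, file.path(config$input_dir,
                                             c("features.tsv",
                                               "barcodes.tsv",
                                               "labels.tsv"))))
    if (any(missing)) stop("input_dir missing required file(s)")
    bundle <- read_expression(mtx,
                              file.path(config$input_dir, "features.tsv"),
                              file.path(config$input_dir, "barcodes.tsv"))
    labels <- read_labels(file.path(config$input_dir, "labels.tsv"))
    if (is.null(config$apex_clusters))
      stop("apex_clusters is required for on-disk input")
    apex <- apex_spec(config$apex_clusters)
  }
  note("input", n_cells = nrow(bundle$layers[[1L]]),
       n_genes = ncol(bundle$layers[[1L]]))

  ## --- preprocess --------------------------------------------------
  bundle <- filter_genes(bundle, min_counts = config$min_counts)
  normalized <- normalize_and_log(bundle)
  labels <- labels[rownames(normalized)]
  features <- select_variable_features(normalized,
                                       n_target = config$n_features)
  scaled <- scale_no_center(normalized, features)
  knn <- pca_knn_graph(scaled, n_pcs = config$n_pcs, k = config$knn_k)
  note("preprocess", n_genes_kept = length(bundle$genes),
       n_features = length(features), knn_k = config$knn_k)

  ## --- markers ------------------------------------------------------
  mstats <- apex_marker_stats(normalized, labels, apex)
  marker_sets <- lapply(mstats, top_k_markers, k = config$top_k)
  fate_feats <- fate_feature_space(mstats, k = config$top_k)
  note("markers", top_k = config$top_k,
       n_union_features = length(fate_feats))

  ## --- simplex ------------------------------------------------------
  scaled_all <- scale_no_center(normalized,
                                intersect(colnames(normalized),
                                          union(features, fate_feats)))
  coords <- simplex_coordinates(scaled_all, fate_feats, apex, labels,
                                exclude_self = config$exclude_self)
  note("simplex", n_cells = nrow(coords$barycentric))

  ## --- velocity + potential ----------------------------------------
  layers <- normalize_layers(bundle)
  layers <- lapply(layers, function(m) m[rownames(normalized), ,
                                         drop = FALSE])
  layers <- knn_smooth_layers(layers, knn)
  gamma <- fit_gamma_steady_state(layers$spliced, layers$unspliced,
                                  extreme_quantile = config$extreme_quantile)
  field <- compute_velocity(layers$spliced, layers$unspliced, gamma)
  graph <- velocity_graph(field, layers$spliced, knn)
  potential <- fate_potential(graph, apex, labels,
                              edge_mean = config$edge_mean)
  arrows <- bin_arrows(coords, potential, n_bins = config$n_bins)
  note("velocity", n_valid_genes = sum(field$valid),
       n_edges = length(graph$weights@x),
       n_flagged_cells = sum(potential$flagged),
       n_bins = nrow(arrows$bins))

  ## --- outputs ------------------------------------------------------
  if (write) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_simplex_outputs(coords, arrows, config$output_dir)
    write_markers(mstats, marker_sets,
                  file.path(config$output_dir, "markers.tsv"))
    write_velocity_graph(graph,
                         file.path(config$output_dir,
                                   "velocity_graph.tsv"))
    write_labels(labels, file.path(config$output_dir, "labels.tsv"))
    yaml::write_yaml(manifest,
                     file.path(config$output_dir, "manifest.yaml"))
  }
  invisible(list(bundle = bundle, labels = labels, truth = truth,
                 normalized = normalized, features = features,
                 scaled = scaled, knn = knn, apex = apex,
                 markers = mstats, marker_sets = marker_sets,
                 fate_features = fate_feats, coords = coords,
                 gamma = gamma, field = field, graph = graph,
                 potential = potential, arrows = arrows,
                 manifest = manifest))
}
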
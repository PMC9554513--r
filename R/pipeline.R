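#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: input (a `shape_dataset` or a
#' directory of outline CSVs with a manifest), the distance method, the
#' resampling resolution, classifier settings and the single seed all
#' randomness flows from.
#'
#' @param input a `shape_dataset`, or a directory path readable by
#'   [read_dataset].
#' @param method `"eigenshapes"`, `"srvf-closed"` or `"srvf-open"`.
#' @param n_points common resampling resolution for the outlines.
#' @param variance_fraction eigenshape variance-explained cutoff.
#' @param grid_size SRVF grid M.
#' @param kappa geodesic step count carried in reports.
#' @param k k-NN neighbourhood size, or `NULL` to tune over `k_grid`.
#' @param k_grid candidate k values when tuning.
#' @param n_replicates stratified replicates.
#' @param train_fraction training fraction per replicate.
#' @param train_counts optional per-class training counts (overrides
#'   `train_fraction`).
#' @param seed integer seed.
#' @param out_dir output directory, or `NULL` to skip writing artifacts.
#' @param seed_stride,top closed-SRVF alignment controls.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, method = c("eigenshapes", "srvf-closed",
                                              "srvf-open"),
                            n_points = 100L, variance_fraction = 0.99,
                            grid_size = 60L, kappa = 2L, k = NULL,
                            k_grid = 3:12, n_replicates = 100L,
                            train_fraction = 0.67, train_counts = NULL,
                            seed = 1L, out_dir = NULL, seed_stride = 1L,
                            top = 8L) {
  method <- match.arg(method)
  stopifnot(n_points >= 3L, variance_fraction > 0, variance_fraction <= 1,
            grid_size >= 3L, n_replicates >= 1L)
  structure(list(input = input, method = method,
                 n_points = as.integer(n_points),
                 variance_fraction = variance_fraction,
                 grid_size = as.integer(grid_size), kappa = as.integer(kappa),
                 k = k, k_grid = k_grid,
                 n_replicates = as.integer(n_replicates),
                 train_fraction = train_fraction, train_counts = train_counts,
                 seed = as.integer(seed), out_dir = out_dir,
                 seed_stride = as.integer(seed_stride), top = as.integer(top)),
            class = "pipeline_config")
}

#' Run the full outline-classification pipeline
#'
#' Resample -> (Procrustes align) -> pairwise distances -> stratified k-NN
#' evaluation. Identical configurations produce identical artifacts.
#'
#' @param cfg a [pipeline_config].
#' @return a `pipeline_run`: list with `distances` ([shape_dist]),
#'   `labels`, `eval` (`knn_eval`), `best_k`, `config`; written to
#'   `cfg$out_dir` (distances CSV, report JSON, confusion CSV, run log)
#'   when set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  dataset <- if (inherits(cfg$input, "shape_dataset")) cfg$input
             else read_dataset(cfg$input)
  labels <- dataset$labels
  stage <- "resample"
  run <- tryCatch({
    rs <- lapply(dataset$outlines, resample_arclength,
                 n_points = cfg$n_points)
    stage <- "distances"
    D <- switch(cfg$method,
      "eigenshapes" = {
        al <- procrustes_align(rs)
        es <- fit_eigenshapes(al)
        eigenshape_distances(es,
                             variance_fraction = cfg$variance_fraction)
      },
      "srvf-closed" = elastic_distances(rs, mode = "closed",
                                        grid_size = cfg$grid_size,
                                        seed_stride = cfg$seed_stride,
                                        top = cfg$top),
      "srvf-open" = elastic_distances(rs, mode = "open",
                                      grid_size = cfg$grid_size))
    stage <- "classify"
    plan <- stratified_splits(labels, train_fraction = cfg$train_fraction,
                              train_counts = cfg$train_counts,
                              n_replicates = cfg$n_replicates,
                              seed = cfg$seed)
    if (is.null(cfg$k)) {
      tuned <- tune_k(D, labels, plan, cfg$k_grid)
      best_k <- tuned$best_k
    } else {
      best_k <- as.integer(cfg$k)
    }
    ev <- knn_evaluate(D, labels, plan, best_k)
    list(distances = D, labels = labels, eval = ev, best_k = best_k,
         config = cfg)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(run) <- "pipeline_run"
  if (!is.null(cfg$out_dir)) .write_run(run, cfg, t0)
  run
}

.write_run <- function(run, cfg, t0) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_distances(run$distances, file.path(cfg$out_dir, "distances.csv"))
  utils::write.csv(as.data.frame.matrix(run$eval$confusion),
                   file.path(cfg$out_dir, "confusion.csv"))
  report <- list(method = cfg$method, n_objects = length(run$labels),
                 n_classes = nlevels(run$labels), best_k = run$best_k,
                 f1_mean = run$eval$f1_mean, f1_ci95 = run$eval$f1_ci95,
                 per_replicate_f1 = run$eval$per_replicate_f1,
                 n_pairs = pair_count(length(run$labels)),
                 seed = cfg$seed)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- c(sprintf("run at %s", format(t0)),
           sprintf("elastishape %s, R %s",
                   as.character(utils::packageVersion("elastishape")),
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("method=%s n_points=%d grid_size=%d seed=%d replicates=%d",
                   cfg$method, cfg$n_points, cfg$grid_size, cfg$seed,
                   cfg$n_replicates),
           sprintf("elapsed %.1f s", as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs"))))
  writeLines(log, file.path(cfg$out_dir, "run.log"))
  invisible(NULL)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %s on %d objects (%d classes)\n",
              x$config$method, length(x$labels), nlevels(x$labels)))
  print(x$eval)
  invisible(x)
}
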
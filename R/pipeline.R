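# End-to-end orchestration: simulate -> detect -> classify -> statistics ->
# motifs, with one seed propagated to named substreams and a JSON report of
# the headline quantities. Every stage is a thin wrapper over the module
# functions; no statistic lives only here.

#' Pipeline configuration
#'
#' @param experiment an [experiment_config()] for the simulation stage
#' @param n_sim_motifs bootstrap simulations for the motif test
#' @param classify_method "zscore" or "svm"
#' @param stages character vector of stages to run, in order
#' @param input_table optional path to an existing connection-table CSV;
#'   when set, the simulate stage is skipped and the table is loaded
#' @param ... further overrides stored in the config
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(experiment = experiment_config(),
                            n_sim_motifs = 200,
                            classify_method = "zscore",
                            stages = c("simulate", "detect", "classify",
                                       "stats", "motifs"),
                            input_table = NULL, ...) {
  structure(list(experiment = experiment, n_sim_motifs = n_sim_motifs,
                 classify_method = classify_method, stages = stages,
                 input_table = input_table, extra = list(...)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a connectivity dataset, quantifies and classifies
#' every photoresponse, computes binned connection probabilities and motif
#' statistics, and returns a report of the headline numbers. With a fixed
#' seed the report is reproducible; `out_dir` additionally writes the
#' connection table (CSV) and the report (JSON) to disk.
#'
#' @param config a [pipeline_config()]
#' @param seed integer seed
#' @param out_dir optional output directory
#' @return list of class `pipeline_report`
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(seed = seed)
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  # --- simulate / load -------------------------------------------------
  if (!is.null(config$input_table)) {
    if (!file.exists(config$input_table)) {
      stop("pipeline stage 'load': input table not found: ",
           config$input_table, call. = FALSE)
    }
    expt <- list(dataset = run("load", read_connection_table(config$input_table)),
                 epochs = list())
  } else {
    expt <- run("simulate", gen_experiment(config$experiment,
                                           seed = substream_seed(seed, "sim")))
  }
  pairs <- expt$dataset$pairs
  report$n_pairs <- nrow(pairs)
  # --- detect + classify ----------------------------------------------
  if ("classify" %in% config$stages && length(expt$epochs)) {
    pairs <- run("classify",
                 classify_experiment(expt, method = config$classify_method))
    if ("detect" %in% config$stages) {
      metrics <- run("detect", {
        lapply(pairs$pair_id[pairs$connected], function(pid) {
          quantify_psp(expt$epochs[[pid]])
        })
      })
      conn_idx <- which(pairs$connected)
      pairs$psp_amplitude_mv[conn_idx] <-
        vapply(metrics, `[[`, numeric(1), "amplitude")
      pairs$psp_cv[conn_idx] <- vapply(metrics, `[[`, numeric(1), "cv")
      pairs$rise_time_ms[conn_idx] <-
        vapply(metrics, `[[`, numeric(1), "rise_time_ms")
      pairs$latency_ms[conn_idx] <-
        vapply(metrics, `[[`, numeric(1), "onset_ms")
    }
    report$n_connected <- sum(pairs$connected)
    if (!is.null(pairs$gt_connected)) {
      report$classification_agreement <-
        mean(pairs$connected == pairs$gt_connected)
    }
  }
  # --- statistics ------------------------------------------------------
  if ("stats" %in% config$stages && nrow(pairs)) {
    bp <- run("stats", binned_connection_probability(pairs, axis = "pia"))
    report$connection_probability_overall <-
      sum(bp$found) / max(1, sum(bp$probed))
    report$binned_probability <- as.data.frame(bp)
  }
  # --- motifs ----------------------------------------------------------
  if ("motifs" %in% config$stages && nrow(pairs)) {
    mb <- run("motifs", bootstrap_motif_test(
      pairs, n_sim = config$n_sim_motifs,
      seed = substream_seed(seed, "motifs")))
    report$motifs <- list(
      convergence = mb$observed$convergence,
      divergence = mb$observed$divergence,
      p_convergence = mb$p_convergence_label,
      p_divergence = mb$p_divergence_label)
  }
  out <- structure(list(report = report, pairs = pairs,
                        dataset = connectivity_dataset(pairs)),
                   class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_connection_table(out$dataset,
                           file.path(out_dir, "connection_table.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("<pipeline_report> %d probed pairs", r$n_pairs))
  if (!is.null(r$n_connected)) cat(sprintf(", %d connected", r$n_connected))
  cat("\n")
  if (!is.null(r$classification_agreement)) {
    cat(sprintf("  agreement with ground truth: %.1f%%\n",
                100 * r$classification_agreement))
  }
  if (!is.null(r$motifs)) {
    cat(sprintf("  motifs: convergence %d (p %s), divergence %d (p %s)\n",
                r$motifs$convergence, r$motifs$p_convergence,
                r$motifs$divergence, r$motifs$p_divergence))
  }
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar entries of the YAML map onto [pipeline_config()] and
#' [experiment_config()] arguments; unknown keys are an error so that typos
#' do not silently fall back to defaults.
#'
#' @param path YAML file path
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known_pipe <- c("n_sim_motifs", "classify_method", "stages", "input_table")
  known_expt <- setdiff(names(experiment_config()), c("kernel", "noise",
                                                      "spiking",
                                                      "synapse_draw"))
  unknown <- setdiff(names(y), c(known_pipe, "experiment"))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  expt_args <- y$experiment %||% list()
  bad <- setdiff(names(expt_args), known_expt)
  if (length(bad)) {
    stop("unknown experiment key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  expt <- do.call(experiment_config, expt_args)
  do.call(pipeline_config, c(list(experiment = expt),
                             y[intersect(names(y), known_pipe)]))
}
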
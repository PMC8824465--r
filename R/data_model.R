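# Core domain containers: stimulus-aligned sweeps, cells, pair geometry,
# probed connections, and the connection-table CSV interface.
#
# Conventions used throughout the package:
#   * distances in micrometres, voltages in millivolts, times in milliseconds
#     (sample_interval is in seconds, matching acquisition metadata);
#   * the stage frame is right-handed with the optical axis along z; slice
#     rotation is applied about the optical axis;
#   * positive horizontal offsets place the presynaptic cell posterior to the
#     patched cell; vertical offsets run along the pia -> white matter axis.

#' Construct a stimulus-aligned current-clamp sweep
#'
#' A `trace_epoch` holds one voltage sweep recorded around a photostimulus,
#' together with the timing metadata every downstream measurement needs. At
#' least 70 ms of pre-stimulus and 50 ms of post-stimulus recording must be
#' present because detection windows reach 70-20 ms before and 0-50 ms after
#' stimulus onset.
#'
#' @param voltage numeric vector of membrane potential (mV)
#' @param sample_interval sampling interval in seconds
#' @param stim_onset_index sample index of photostimulus onset (1-based)
#' @param stim_duration photostimulus duration (ms)
#' @param holding_target target holding potential (mV)
#' @param sweep_index ordinal of the sweep within repeated stimulation
#' @return an object of class `trace_epoch`
#' @export
trace_epoch <- function(voltage, sample_interval, stim_onset_index,
                        stim_duration = 10, holding_target = -70,
                        sweep_index = 1L) {
  stopifnot(is.numeric(voltage), length(voltage) > 1)
  if (!is.numeric(sample_interval) || sample_interval <= 0) {
    stop("sample_interval must be positive", call. = FALSE)
  }
  n <- length(voltage)
  if (stim_onset_index < 1 || stim_onset_index > n) {
    stop("stim_onset_index must fall within the trace", call. = FALSE)
  }
  pre_ms <- (stim_onset_index - 1) * sample_interval * 1000
  post_ms <- (n - stim_onset_index) * sample_interval * 1000
  if (pre_ms < 70) {
    stop("trace_epoch requires at least 70 ms of pre-stimulus samples",
         call. = FALSE)
  }
  if (post_ms < 50) {
    stop("trace_epoch requires at least 50 ms of post-stimulus samples",
         call. = FALSE)
  }
  structure(
    list(voltage = as.numeric(voltage),
         sample_interval = sample_interval,
         stim_onset_index = as.integer(stim_onset_index),
         stim_duration = stim_duration,
         holding_target = holding_target,
         sweep_index = as.integer(sweep_index)),
    class = "trace_epoch")
}

#' @export
print.trace_epoch <- function(x, ...) {
  cat(sprintf("<trace_epoch> %d samples @ %.4g kHz, stim at sample %d (%g ms pulse), holding %g mV\n",
              length(x$voltage), 1e-3 / x$sample_interval,
              x$stim_onset_index, x$stim_duration, x$holding_target))
  invisible(x)
}

#' Construct a cell record
#'
#' @param cell_id identifier, unique within an experiment
#' @param role one of "photostimulated", "patched", "both"
#' @param subclass_label Cre line or assigned class label
#' @param position numeric xyz position in the stage frame (um)
#' @param pia_distance distance from the pia (um)
#' @param depth_below_surface depth below the slice surface (um)
#' @param opsin_positive logical, does the cell express opsin
#' @return an object of class `cell_record`
#' @export
cell_record <- function(cell_id, role = c("photostimulated", "patched", "both"),
                        subclass_label = NA_character_,
                        position = c(NA_real_, NA_real_, NA_real_),
                        pia_distance = NA_real_,
                        depth_below_surface = NA_real_,
                        opsin_positive = FALSE) {
  role <- match.arg(role)
  if (!is.na(pia_distance) && pia_distance < 0) {
    stop("pia_distance must be >= 0", call. = FALSE)
  }
  if (!is.na(depth_below_surface) && depth_below_surface < 0) {
    stop("depth_below_surface must be >= 0", call. = FALSE)
  }
  structure(
    list(cell_id = cell_id, role = role, subclass_label = subclass_label,
         position = as.numeric(position), pia_distance = pia_distance,
         depth_below_surface = depth_below_surface,
         opsin_positive = isTRUE(opsin_positive)),
    class = "cell_record")
}

#' Representative cortical layer boundaries
#'
#' Distances of layer boundaries from the pia (um): L1 0-80, L2/3 80-330,
#' L4 330-480, L5 480-750, L6 750-1000.
#'
#' @return named numeric vector of lower boundaries plus the white-matter edge
#' @export
layer_boundaries <- function() {
  c("L1" = 0, "L2/3" = 80, "L4" = 330, "L5" = 480, "L6" = 750, "wm" = 1000)
}

#' Assign a cortical layer from pia distance
#'
#' Bins are half-open `[lo, hi)`: a cell exactly at 330 um is in L4. Distances
#' beyond 1000 um return the sentinel label `"below L6"`.
#'
#' @param pia_distance numeric vector of distances from the pia (um)
#' @return character vector of layer labels
#' @export
assign_layer <- function(pia_distance) {
  if (any(pia_distance < 0, na.rm = TRUE)) {
    stop("pia_distance must be >= 0", call. = FALSE)
  }
  b <- layer_boundaries()
  labs <- names(b)[-length(b)]
  idx <- findInterval(pia_distance, b)         # [lo, hi) by default
  out <- ifelse(idx > length(labs), "below L6", labs[pmax(idx, 1L)])
  out[is.na(pia_distance)] <- NA_character_
  out
}

#' Transform stage coordinates into pair geometry
#'
#' Photostimulus positions recorded in the stage frame are expressed relative
#' to the patched (reference) cell and rotated by the slice orientation so
#' that offsets align with the cortical axes: horizontal (anterior-posterior,
#' positive = presynaptic cell posterior) and vertical (pia to white matter).
#' Vertical offsets added to the reference cell's pia distance give each
#' presynaptic cell's pia distance.
#'
#' @param stage_positions matrix or data.frame with columns x, y, z (um)
#' @param slice_rotation rotation of the slice about the optical axis (degrees)
#' @param reference_patched_cell a [cell_record()] with position and
#'   pia_distance set
#' @return data.frame with columns horizontal_offset, vertical_offset,
#'   presyn_pia_distance, distance_3d
#' @export
transform_coordinates <- function(stage_positions, slice_rotation,
                                  reference_patched_cell) {
  if (missing(slice_rotation) || is.null(slice_rotation) ||
      is.na(slice_rotation)) {
    stop("slice_rotation is required", call. = FALSE)
  }
  ref <- reference_patched_cell
  if (is.null(ref$pia_distance) || is.na(ref$pia_distance)) {
    stop("reference cell must have a measured pia_distance", call. = FALSE)
  }
  pos <- as.matrix(as.data.frame(stage_positions)[, c("x", "y", "z")])
  d <- sweep(pos, 2, ref$position)
  th <- slice_rotation * pi / 180
  horizontal <- d[, 1] * cos(th) - d[, 2] * sin(th)
  vertical <- d[, 1] * sin(th) + d[, 2] * cos(th)
  data.frame(
    horizontal_offset = horizontal,
    vertical_offset = vertical,
    presyn_pia_distance = ref$pia_distance + vertical,
    distance_3d = sqrt(rowSums(d^2)))
}

#' Construct a probed connection
#'
#' One (photostimulated cell, patched cell) pair with its geometry, response
#' sweeps and classification state. Pairs flagged `excluded_artifact` (direct
#' opsin activation of the patched cell) never enter connection-probability
#' denominators.
#'
#' @param pre,post [cell_record()] objects
#' @param geometry one-row data.frame from [transform_coordinates()]
#' @param epochs list of [trace_epoch()] sweeps
#' @param connected "connected", "not_connected" or "excluded_artifact"
#' @param annotation_source provenance of the label
#' @param psp_metrics optional list of PSP metrics
#' @return an object of class `probed_connection`
#' @export
probed_connection <- function(pre, post, geometry, epochs = list(),
                              connected = c("not_connected", "connected",
                                            "excluded_artifact"),
                              annotation_source = c("ground_truth", "human",
                                                    "svm", "zscore"),
                              psp_metrics = NULL) {
  connected <- match.arg(connected)
  annotation_source <- match.arg(annotation_source)
  structure(
    list(pre = pre, post = post, geometry = geometry, epochs = epochs,
         connected = connected, annotation_source = annotation_source,
         psp_metrics = psp_metrics),
    class = "probed_connection")
}

# Mandatory columns of the connection-table CSV interface.
connection_table_columns <- function() {
  c("experiment_id", "cre_line", "expression_method", "stim_power_mw",
    "pre_cell_id", "post_cell_id", "post_subclass", "pre_pia_um",
    "post_pia_um", "horizontal_offset_um", "distance_3d_um", "connected",
    "artifact_excluded", "n_sweeps", "psp_amplitude_mv", "psp_cv",
    "rise_time_ms", "latency_ms", "ppr")
}

#' Assemble a connectivity dataset from a table of probed pairs
#'
#' @param pairs data.frame with the connection-table schema (see
#'   [connection_table_columns()]); unknown extra columns are preserved
#' @return an object of class `connectivity_dataset` with elements `pairs`
#'   (the table) and `experiments` (unique experiment records)
#' @export
connectivity_dataset <- function(pairs) {
  pairs <- as.data.frame(pairs)
  missing_cols <- setdiff(connection_table_columns(), names(pairs))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  expts <- unique(pairs[, c("experiment_id", "cre_line", "expression_method",
                            "stim_power_mw")])
  rownames(expts) <- NULL
  structure(list(experiments = expts, pairs = pairs),
            class = "connectivity_dataset")
}

#' @export
print.connectivity_dataset <- function(x, ...) {
  cat(sprintf("<connectivity_dataset> %d probed pairs across %d experiment(s)\n",
              nrow(x$pairs), nrow(x$experiments)))
  if (nrow(x$pairs)) {
    n_conn <- sum(x$pairs$connected %in% c(TRUE, "TRUE", "connected"))
    n_art <- sum(x$pairs$artifact_excluded %in% c(TRUE, "TRUE"))
    cat(sprintf("  connected: %d, artifact-excluded: %d\n", n_conn, n_art))
  }
  invisible(x)
}

#' Read a connection table from CSV
#'
#' The reader is tolerant: unknown columns are kept as-is; a missing mandatory
#' column is an error naming the column.
#'
#' @param path path to a CSV file
#' @return a [connectivity_dataset()]
#' @export
read_connection_table <- function(path) {
  pairs <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(pairs) == 0 && ncol(pairs) == 0) {
    pairs <- as.data.frame(
      stats::setNames(rep(list(logical(0)), length(connection_table_columns())),
                      connection_table_columns()))
  }
  connectivity_dataset(pairs)
}

#' Write a connection table to CSV
#'
#' Floating-point fields are serialized with 6 significant digits; text and
#' integer fields round-trip bit-exactly.
#'
#' @param dataset a [connectivity_dataset()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_connection_table <- function(dataset, path) {
  pairs <- dataset$pairs
  is_dbl <- vapply(pairs, function(col) is.double(col), logical(1))
  pairs[is_dbl] <- lapply(pairs[is_dbl], function(col) signif(col, 6))
  utils::write.csv(pairs, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write sweep sets to a plain-text long-format CSV
#'
#' Each row is one sample; sweeps are keyed by `pair_id` and `sweep_index`,
#' with per-sweep metadata repeated. [read_sweep_table()] inverts the layout.
#'
#' @param epoch_sets named list (by pair id) of lists of [trace_epoch()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sweep_table <- function(epoch_sets, path) {
  rows <- lapply(names(epoch_sets), function(pid) {
    do.call(rbind, lapply(epoch_sets[[pid]], function(ep) {
      data.frame(pair_id = pid, sweep_index = ep$sweep_index,
                 sample_interval = ep$sample_interval,
                 stim_onset_index = ep$stim_onset_index,
                 stim_duration = ep$stim_duration,
                 holding_target = ep$holding_target,
                 sample = seq_along(ep$voltage),
                 voltage = signif(ep$voltage, 6))
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read sweep sets written by [write_sweep_table()]
#'
#' @param path CSV path
#' @return named list of lists of [trace_epoch()]
#' @export
read_sweep_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (pid in unique(df$pair_id)) {
    sub <- df[df$pair_id == pid, ]
    out[[as.character(pid)]] <- lapply(unique(sub$sweep_index), function(si) {
      s <- sub[sub$sweep_index == si, ]
      s <- s[order(s$sample), ]
      trace_epoch(s$voltage, s$sample_interval[1], s$stim_onset_index[1],
                  s$stim_duration[1], s$holding_target[1], si)
    })
  }
  out
}
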
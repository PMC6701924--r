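#' Construct a validated trace set
#'
#' The canonical tabular container for intensity traces: one row per
#' (record, frame); each frame carries one excitation channel
#' (`"donor"` or `"acceptor"`). Rows are grouped by record and sorted by
#' frame index; times must be strictly increasing within a record.
#'
#' @param frames data.frame with columns `record_id`, `frame_index`,
#'   `time_s`, `excitation`, `I_donor_em`, `I_acceptor_em`.
#' @param frame_interval seconds between successive frames of the same
#'   excitation channel (default 2.67).
#' @param variant free-text dataset label (e.g. `"wt"` or `"mutant"`).
#' @return object of class `trace_set`.
#' @export
trace_set <- function(frames, frame_interval = 2.67, variant = "unspecified") {
  needed <- c("record_id", "frame_index", "time_s", "excitation",
              "I_donor_em", "I_acceptor_em")
  missing_cols <- setdiff(needed, names(frames))
  if (length(missing_cols))
    stop("trace table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  frames <- as.data.frame(frames)[, needed]
  frames$record_id <- as.character(frames$record_id)
  frames$excitation <- as.character(frames$excitation)
  if (!all(frames$excitation %in% c("donor", "acceptor")))
    stop("excitation must be 'donor' or 'acceptor'", call. = FALSE)

  ord <- order(frames$record_id, frames$frame_index)
  if (any(ord != seq_along(ord))) {
    warning("trace rows were not sorted by (record_id, frame_index); sorting",
            call. = FALSE)
    frames <- frames[ord, , drop = FALSE]
    rownames(frames) <- NULL
  }

  key <- paste(frames$record_id, frames$frame_index, frames$excitation)
  if (anyDuplicated(key)) {
    bad <- frames$record_id[duplicated(key)][1L]
    stop("duplicated (record, frame, excitation) row in record '", bad, "'",
         call. = FALSE)
  }
  for (rid in unique(frames$record_id)) {
    tt <- frames$time_s[frames$record_id == rid]
    if (length(tt) < 2L)
      stop("record '", rid, "' has fewer than 2 frames", call. = FALSE)
    if (any(diff(tt) <= 0))
      stop("non-monotone frame times in record '", rid, "'", call. = FALSE)
  }
  structure(list(frames = frames, frame_interval = frame_interval,
                 variant = variant),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", length(unique(x$frames$record_id)), " records, ",
      nrow(x$frames), " frames, frame interval ", x$frame_interval,
      " s, variant '", x$variant, "'\n", sep = "")
  invisible(x)
}

#' Read a trace table
#'
#' Reads the tab-separated trace dialect written by [write_traces()]:
#' a header line plus one row per (record, frame). Rows are validated,
#' grouped by record and sorted by frame index; unsorted input is sorted
#' with a warning, duplicated rows are an error naming the record.
#'
#' @param path file path.
#' @param frame_interval,variant metadata not stored in the table body.
#' @return a `trace_set`.
#' @export
read_traces <- function(path, frame_interval = 2.67, variant = "unspecified") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  trace_set(df, frame_interval = frame_interval, variant = variant)
}

#' Write a trace table
#'
#' Lossless tab-separated serialization (full double precision). Writing an
#' empty trace set produces a header-only file; non-finite intensities are
#' refused.
#'
#' @param traces a `trace_set` or a bare frames data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  frames <- if (inherits(traces, "trace_set")) traces$frames else traces
  if (nrow(frames) &&
      (any(!is.finite(frames$I_donor_em)) ||
       any(!is.finite(frames$I_acceptor_em))))
    stop("refusing to write non-finite intensities", call. = FALSE)
  out <- frames
  if (nrow(out)) {
    out$time_s <- format(out$time_s, digits = 17, trim = TRUE,
                         scientific = FALSE)
    out$I_donor_em <- sprintf("%.17g", out$I_donor_em)
    out$I_acceptor_em <- sprintf("%.17g", out$I_acceptor_em)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Pipeline configuration

config_defaults <- function() {
  list(
    frame_interval = 2.67,
    preprocess = list(threshold_sd = 4, min_dwell_frames = 3,
                      smooth_window_frames = 15,
                      outlier_low = -0.25, outlier_high = 0.85,
                      max_outliers = 10),
    histogram = list(bandwidth_t = 5, bandwidth_e = 0.05,
                     grid_dt = 1, grid_de = 0.01, bin_width = 0.05),
    hmm = list(K = 3, n_starts = 5, rate_floor = 1e-4,
               rate_method = "expm", max_rounds = 25),
    simulate = list(n_records = 100, max_duration = 1200,
                    arrival_spread = 60, total_intensity = 200,
                    noise_sd = 20, baseline_offset = 0,
                    donor_bleach_rate = 0.002, acceptor_bleach_rate = 0.002)
  )
}

#' Load a pipeline configuration file
#'
#' Plain-text `key = value` format with optional `[section]` headers
#' (sections: `preprocess`, `histogram`, `hmm`, `simulate`; `frame_interval`
#' is top-level). Unknown keys are rejected; omitted keys take the documented
#' defaults (frame interval 2.67 s, outlier range \[-0.25, 0.85\], KDE
#' bandwidths 5 s and 0.05, K = 3 states). An empty or missing-path `NULL`
#' config yields all defaults.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return nested list of class `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    section <- NULL
    for (ln in lines) {
      ln <- sub("#.*$", "", ln)
      ln <- trimws(ln)
      if (!nzchar(ln)) next
      if (grepl("^\\[.+\\]$", ln)) {
        section <- sub("^\\[(.+)\\]$", "\\1", ln)
        if (!section %in% names(cfg) || !is.list(cfg[[section]]))
          stop("unknown config section [", section, "]", call. = FALSE)
        next
      }
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L)
        stop("cannot parse config line: '", ln, "'", call. = FALSE)
      key <- trimws(kv[1L]); val <- trimws(kv[2L])
      num <- suppressWarnings(as.numeric(val))
      parsed <- if (!is.na(num)) num else val
      if (is.null(section)) {
        hit <- FALSE
        if (key %in% names(cfg) && !is.list(cfg[[key]])) {
          cfg[[key]] <- parsed; hit <- TRUE
        } else {
          for (sec in names(cfg)) {
            if (is.list(cfg[[sec]]) && key %in% names(cfg[[sec]])) {
              cfg[[sec]][[key]] <- parsed; hit <- TRUE; break
            }
          }
        }
        if (!hit) stop("unknown config key '", key, "'", call. = FALSE)
      } else {
        if (!key %in% names(cfg[[section]]))
          stop("unknown config key '", key, "' in section [", section, "]",
               call. = FALSE)
        cfg[[section]][[key]] <- parsed
      }
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$frame_interval <= 0)
    stop("frame_interval must be > 0", call. = FALSE)
  with(cfg$preprocess, {
    if (threshold_sd <= 0 || min_dwell_frames < 1 || smooth_window_frames < 1)
      stop("invalid preprocess settings", call. = FALSE)
    if (outlier_low >= outlier_high)
      stop("outlier_low must be < outlier_high", call. = FALSE)
  })
  with(cfg$histogram, {
    if (bandwidth_t <= 0 || bandwidth_e <= 0 || grid_dt <= 0 || grid_de <= 0)
      stop("invalid histogram settings", call. = FALSE)
  })
  if (cfg$hmm$K < 2) stop("hmm K must be >= 2", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

# Write a result table as TSV (shared by the pipeline stages).
write_result_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth as a JSON sidecar
#'
#' One object per record: run-length-encoded true path, event times and the
#' generating state levels.
#'
#' @param truth `ground_truth` from [simulate_dataset()].
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  recs <- lapply(truth$records, function(r) {
    rl <- rle(r$path)
    list(record_id = r$record_id,
         arrival_donor = r$arrival_donor,
         arrival_acceptor = r$arrival_acceptor,
         t0 = r$t0, t_end_signal = r$t_end_signal, end_cause = r$end_cause,
         start_state = r$start_state,
         path_rle = list(lengths = rl$lengths, values = rl$values))
  })
  obj <- list(records = recs,
              rate_matrix = truth$scheme$rate_matrix,
              initial_fractions = truth$scheme$initial_fractions,
              efret_levels = truth$emission$efret_levels,
              frame_interval = truth$emission$frame_interval)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
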
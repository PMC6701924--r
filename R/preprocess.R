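#' Apparent FRET efficiency
#'
#' `E_FRET = I_Acceptor / (I_Acceptor + I_Donor)` from the acceptor and donor
#' emission intensities observed during donor excitation. Values can fall
#' outside \[0, 1\] for noisy inputs; those are handled by the outlier policy.
#' A zero denominator yields `NA` (frame to be masked).
#'
#' @param i_acceptor,i_donor numeric vectors of background-corrected
#'   intensities.
#' @return numeric vector of efficiencies.
#' @export
compute_efret <- function(i_acceptor, i_donor) {
  denom <- i_acceptor + i_donor
  out <- i_acceptor / denom
  out[denom == 0] <- NA_real_
  out
}

#' Construct an E_FRET record
#'
#' Time-zero-aligned FRET-efficiency series for one qualified two-hexamer
#' record. Masked frames are treated downstream as missing observations (no
#' emission term), not as zeros, so the HMM time base is preserved.
#'
#' @param record_id record identifier.
#' @param t0 absolute time of second-complex arrival (seconds).
#' @param time times since `t0`, one per donor-excitation frame.
#' @param efret efficiency values (may contain `NA`; those are masked).
#' @param end_cause one of `"departure"`, `"bleach_or_loss"`,
#'   `"recording_end"`.
#' @param frame_interval frame spacing, seconds.
#' @param mask logical per-frame outlier mask (`TRUE` = excluded).
#' @return object of class `efret_record`.
#' @export
efret_record <- function(record_id, t0, time, efret,
                         end_cause = c("bleach_or_loss", "departure",
                                       "recording_end"),
                         frame_interval = 2.67,
                         mask = NULL) {
  end_cause <- match.arg(end_cause)
  stopifnot(length(time) == length(efret))
  if (is.null(mask)) mask <- !is.finite(efret)
  mask <- mask | !is.finite(efret)
  structure(list(record_id = as.character(record_id), t0 = t0,
                 time = as.numeric(time), efret = as.numeric(efret),
                 mask = mask, end_cause = end_cause,
                 frame_interval = frame_interval,
                 n_outliers = sum(mask)),
            class = "efret_record")
}

#' @export
print.efret_record <- function(x, ...) {
  cat("<efret_record> '", x$record_id, "': ", length(x$efret), " frames (",
      sum(x$mask), " masked), t0 = ", signif(x$t0, 4), " s, end: ",
      x$end_cause, "\n", sep = "")
  invisible(x)
}

# centered running mean with shrinking windows at the edges
run_mean <- function(x, w) {
  n <- length(x)
  half <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Deterministic two-means split of a 1D series (centers seeded at min/max).
two_means <- function(x, iters = 50L) {
  c1 <- min(x); c2 <- max(x)
  for (i in seq_len(iters)) {
    mid <- (c1 + c2) / 2
    lo <- x <= mid
    if (!any(lo) || all(lo)) break
    n1 <- mean(x[lo]); n2 <- mean(x[!lo])
    if (n1 == c1 && n2 == c2) break
    c1 <- n1; c2 <- n2
  }
  list(lo = c1, hi = c2, assign_lo = x <= (c1 + c2) / 2)
}

presence_one_channel <- function(tt, x, threshold_sd, min_dwell_frames,
                                 spacing) {
  # robust noise scale from first differences (insensitive to level steps)
  sig <- mad(diff(x)) / sqrt(2)
  scale <- max(sig, 1e-8 * max(abs(x), 1), .Machine$double.eps)
  km <- two_means(x)
  level <- if ((km$hi - km$lo) > threshold_sd * sig && any(km$assign_lo))
    median(x[km$assign_lo]) else median(x)
  z <- (x - level) / scale
  hit <- z > threshold_sd
  # morphological closing: a brief noise dip inside a spot must not split
  # the presence interval in two
  r <- rle(hit)
  if (length(r$lengths) > 2L) {
    inner <- 2:(length(r$lengths) - 1L)
    r$values[inner][!r$values[inner] &
                      r$lengths[inner] < min_dwell_frames] <- TRUE
  }
  hit <- inverse.rle(r)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_dwell_frames
  data.frame(t_start = tt[starts[keep]],
             t_end = tt[ends[keep]] + spacing)
}

#' Detect presence intervals for each labeled complex
#'
#' Algorithmic stand-in for manual spot selection: a complex is called
#' present wherever its detection channel exceeds the baseline level by
#' `threshold_sd` robust noise SDs for at least `min_dwell_frames`
#' consecutive frames. The donor-labeled complex is detected on total
#' emission under donor excitation; the acceptor-labeled complex on acceptor
#' emission under acceptor excitation. The noise scale is estimated from
#' first differences so intensity steps do not inflate it; the baseline
#' level comes from the lower of a two-means split when the split is
#' significant, otherwise from the overall median (so a featureless trace
#' yields no intervals).
#'
#' @param trace data.frame of one record's frames (trace-table columns).
#' @param threshold_sd robust z threshold (default 4).
#' @param min_dwell_frames minimum run length in frames (default 3).
#' @param frame_interval per-channel frame spacing, seconds.
#' @return object of class `presence_intervals`: data.frames `donor` and
#'   `acceptor` of half-open `[t_start, t_end)` intervals.
#' @export
detect_presence_intervals <- function(trace, threshold_sd = 4,
                                      min_dwell_frames = 3,
                                      frame_interval = 2.67) {
  if (nrow(trace) < 10L)
    stop("need at least 10 frames for presence detection", call. = FALSE)
  don <- trace[trace$excitation == "donor", , drop = FALSE]
  acc <- trace[trace$excitation == "acceptor", , drop = FALSE]
  d_iv <- presence_one_channel(don$time_s, don$I_donor_em + don$I_acceptor_em,
                               threshold_sd, min_dwell_frames, frame_interval)
  a_iv <- presence_one_channel(acc$time_s, acc$I_acceptor_em,
                               threshold_sd, min_dwell_frames, frame_interval)
  structure(list(donor = d_iv, acceptor = a_iv,
                 threshold_sd = threshold_sd,
                 min_dwell_frames = min_dwell_frames),
            class = "presence_intervals")
}

in_intervals <- function(t, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv)))
    hit <- hit | (t >= iv$t_start[i] & t < iv$t_end[i])
  hit
}

#' Subtract a smoothed baseline from a trace
#'
#' Baseline segments (frames where no complex is present) are joined,
#' smoothed with a centered moving-average low-pass filter, interpolated
#' across the presence intervals and subtracted, per excitation channel and
#' emission column. After correction the baseline frames average to ~0.
#'
#' @param trace data.frame of one record's frames.
#' @param presence a [detect_presence_intervals()] result.
#' @param smooth_window_frames moving-average window (default 15 frames).
#' @return corrected trace data.frame.
#' @export
subtract_baseline <- function(trace, presence, smooth_window_frames = 15) {
  stopifnot(inherits(presence, "presence_intervals"))
  out <- trace
  for (exc in c("donor", "acceptor")) {
    sel <- trace$excitation == exc
    tt <- trace$time_s[sel]
    base <- !(in_intervals(tt, presence$donor) |
                in_intervals(tt, presence$acceptor))
    if (!any(base))
      stop("no baseline frames in channel '", exc,
           "'; apply a manual offset instead", call. = FALSE)
    for (col in c("I_donor_em", "I_acceptor_em")) {
      x <- trace[[col]][sel]
      sm <- run_mean(x[base], smooth_window_frames)
      bl <- approx(tt[base], sm, xout = tt, rule = 2)$y
      out[[col]][sel] <- x - bl
    }
  }
  out
}

#' Select qualified two-hexamer records and compute E_FRET
#'
#' Automates the study's record selection: keep records with exactly one
#' donor-complex and one acceptor-complex presence interval that overlap.
#' Time zero is the later arrival; the record ends at the first departure of
#' either complex or at the end of the recording. E_FRET is computed per
#' donor-excitation frame inside that window. Non-qualifying records are
#' dropped with a logged reason.
#'
#' @param traces a background-corrected `trace_set`.
#' @param presences named list (by record_id) of `presence_intervals`.
#' @return list with `records` (list of `efret_record`) and `exclusions`
#'   (data.frame `record_id`, `reason`).
#' @export
select_two_hexamer_records <- function(traces, presences) {
  stopifnot(inherits(traces, "trace_set"))
  recs <- list(); excl <- list()
  t_last <- max(traces$frames$time_s)
  for (rid in unique(traces$frames$record_id)) {
    pv <- presences[[rid]]
    if (is.null(pv)) { excl[[rid]] <- "no presence intervals"; next }
    if (nrow(pv$donor) != 1L) {
      excl[[rid]] <- sprintf("donor count != 1 (%d)", nrow(pv$donor)); next
    }
    if (nrow(pv$acceptor) != 1L) {
      excl[[rid]] <- sprintf("acceptor count != 1 (%d)", nrow(pv$acceptor))
      next
    }
    t0 <- max(pv$donor$t_start, pv$acceptor$t_start)
    t_end <- min(pv$donor$t_end, pv$acceptor$t_end)
    if (t_end <= t0) { excl[[rid]] <- "no overlap"; next }
    fr <- traces$frames[traces$frames$record_id == rid &
                          traces$frames$excitation == "donor", , drop = FALSE]
    sel <- fr$time_s >= t0 & fr$time_s < t_end
    if (sum(sel) < 2L) { excl[[rid]] <- "fewer than 2 overlap frames"; next }
    ef <- compute_efret(fr$I_acceptor_em[sel], fr$I_donor_em[sel])
    end_cause <- if (t_end >= t_last - traces$frame_interval)
      "recording_end" else "bleach_or_loss"
    recs[[rid]] <- efret_record(rid, t0 = t0, time = fr$time_s[sel] - t0,
                                efret = ef, end_cause = end_cause,
                                frame_interval = traces$frame_interval)
  }
  list(records = unname(recs),
       exclusions = data.frame(record_id = names(excl),
                               reason = unlist(excl, use.names = FALSE),
                               stringsAsFactors = FALSE))
}

#' Apply the E_FRET outlier policy
#'
#' Frames with E_FRET outside `[range_low, range_high]` (or undefined) are
#' masked; records with more than `max_outliers` masked frames are dropped
#' entirely as low signal-to-noise.
#'
#' @param records list of `efret_record`.
#' @param range_low,range_high allowed efficiency range (defaults -0.25 and
#'   0.85).
#' @param max_outliers per-record masked-frame budget (default 10).
#' @return list with `records` (kept, masks updated) and `report`
#'   (data.frame: `record_id`, `n_frames`, `n_outliers`, `dropped`).
#' @export
apply_outlier_policy <- function(records, range_low = -0.25,
                                 range_high = 0.85, max_outliers = 10) {
  kept <- list(); rep_rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    out <- !is.finite(r$efret) | r$efret < range_low | r$efret > range_high
    r$mask <- out
    r$n_outliers <- sum(out)
    dropped <- r$n_outliers > max_outliers
    rep_rows[[i]] <- data.frame(record_id = r$record_id,
                                n_frames = length(r$efret),
                                n_outliers = r$n_outliers,
                                dropped = dropped,
                                stringsAsFactors = FALSE)
    if (!dropped) kept[[length(kept) + 1L]] <- r
  }
  list(records = kept, report = do.call(rbind, rep_rows))
}

#' Run the full preprocessing stage
#'
#' Per record: detect presence intervals, subtract the smoothed baseline,
#' re-detect on corrected intensities, select qualifying two-hexamer
#' records, and apply the outlier policy.
#'
#' @param traces a `trace_set`.
#' @param threshold_sd,min_dwell_frames,smooth_window_frames detection and
#'   baseline parameters.
#' @param range_low,range_high,max_outliers outlier policy.
#' @return list with `records`, `exclusions`, `outlier_report`,
#'   `presences`.
#' @export
preprocess_traces <- function(traces, threshold_sd = 4, min_dwell_frames = 3,
                              smooth_window_frames = 15,
                              range_low = -0.25, range_high = 0.85,
                              max_outliers = 10) {
  stopifnot(inherits(traces, "trace_set"))
  ids <- unique(traces$frames$record_id)
  corrected <- vector("list", length(ids))
  presences <- list()
  for (i in seq_along(ids)) {
    tr <- traces$frames[traces$frames$record_id == ids[i], , drop = FALSE]
    pv <- detect_presence_intervals(tr, threshold_sd, min_dwell_frames,
                                    traces$frame_interval)
    tr2 <- tryCatch(subtract_baseline(tr, pv, smooth_window_frames),
                    error = function(e) tr)
    presences[[ids[i]]] <- detect_presence_intervals(
      tr2, threshold_sd, min_dwell_frames, traces$frame_interval)
    corrected[[i]] <- tr2
  }
  ts2 <- trace_set(do.call(rbind, corrected),
                   frame_interval = traces$frame_interval,
                   variant = traces$variant)
  selected <- select_two_hexamer_records(ts2, presences)
  filt <- apply_outlier_policy(selected$records, range_low, range_high,
                               max_outliers)
  list(records = filt$records, exclusions = selected$exclusions,
       outlier_report = filt$report, presences = presences)
}

#' Tabulate E_FRET records
#'
#' @param records list of `efret_record`.
#' @return data.frame with columns `record_id`, `frame_index`,
#'   `t_since_t0_s`, `efret`, `masked`.
#' @export
as_efret_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(record_id = r$record_id,
               frame_index = seq_along(r$efret) - 1L,
               t_since_t0_s = r$time,
               efret = r$efret,
               masked = r$mask,
               stringsAsFactors = FALSE)
  }))
}

# inverse of as_efret_table (pipeline stage handoff)
efret_records_from_table <- function(df, frame_interval = 2.67) {
  lapply(split(df, df$record_id), function(d) {
    d <- d[order(d$frame_index), , drop = FALSE]
    efret_record(d$record_id[1L], t0 = 0, time = d$t_since_t0_s,
                 efret = d$efret, frame_interval = frame_interval,
                 mask = as.logical(d$masked))
  })
}
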
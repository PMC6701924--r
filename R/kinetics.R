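#' Map fitted states to semantic kinetic labels
#'
#' Identifies the single high-E_FRET state (labeled `DH` for wild type,
#' `pseudo-DH` for the mutant) and distinguishes the two low-FRET states by
#' their kinetic role: the low state predominantly occupied before the first
#' high-state entry (pooled over decoded records) is `pre-DH`; the other low
#' state is the long-lived trap reported as `post-DH` after a high segment
#' and `non-DH` when the record never went high.
#'
#' @param fit a `population_fit` with exactly one high-mean state.
#' @param variant `"wt"` or `"mutant"` (controls the high-state label).
#' @param high_threshold efficiency above which a state mean counts as high
#'   (default 0.3, between the ~0.03-0.08 low and 0.47-0.61 high levels).
#' @return object of class `state_labels`: `high`, `pre`, `trap` state
#'   indices and the high-state display label.
#' @export
label_states <- function(fit, variant = c("wt", "mutant"),
                         high_threshold = 0.3) {
  label_states_impl(decode_states(fit), fit$state_mean, fit$trans_prob,
                    variant = variant, high_threshold = high_threshold)
}

label_states_impl <- function(paths, state_mean, trans_prob,
                              variant = c("wt", "mutant"),
                              high_threshold = 0.3) {
  variant <- match.arg(variant)
  K <- length(state_mean)
  high <- which(state_mean > high_threshold)
  if (length(high) != 1L)
    stop("expected exactly one high-mean state, found ", length(high),
         " (model misfit)", call. = FALSE)
  lows <- setdiff(seq_len(K), high)

  # frames of each low state occurring before the record's first high frame
  pre_counts <- setNames(numeric(length(lows)), lows)
  for (p in paths) {
    fh <- match(high, p$state)
    if (is.na(fh) || fh == 1L) next
    head_states <- p$state[seq_len(fh - 1L)]
    for (l in lows)
      pre_counts[as.character(l)] <- pre_counts[as.character(l)] +
        sum(head_states == l)
  }
  pre <- if (sum(pre_counts) > 0) {
    lows[which.max(pre_counts)]
  } else {
    # fallback: the low state with the larger fitted rate into the high state
    into_high <- trans_prob[lows, high]
    lows[which.max(into_high)]
  }
  trap <- setdiff(lows, pre)
  structure(list(high = high, pre = pre, trap = trap,
                 high_label = if (variant == "wt") "DH" else "pseudo-DH",
                 variant = variant),
            class = "state_labels")
}

#' Run-length encode decoded paths into labeled segments
#'
#' Converts per-frame decoded states into contiguous half-open time segments
#' `[t_start, t_end)` with semantic labels. The final segment of a record is
#' censored iff the record ended with the recording. Single-frame high-state
#' segments are kept but flagged.
#'
#' @param paths list of `state_path` (from [decode_states()]).
#' @param labels a [label_states()] result.
#' @param frame_interval seconds per frame (default from the paths).
#' @return data.frame of class `segment_table`: `record_id`, `label`,
#'   `t_start_s`, `t_end_s`, `censored_end`, `flag_short_high`.
#' @export
segment_paths <- function(paths, labels, frame_interval = NULL) {
  stopifnot(inherits(labels, "state_labels"))
  rows <- list()
  for (p in paths) {
    dt <- if (is.null(frame_interval)) p$frame_interval else frame_interval
    r <- rle(p$state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seen_high <- FALSE
    for (s in seq_along(r$values)) {
      st <- r$values[s]
      lab <- if (st == labels$high) labels$high_label
        else if (st == labels$pre) "pre-DH"
        else if (seen_high) "post-DH" else "non-DH"
      if (st == labels$high) seen_high <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = p$record_id,
        label = lab,
        t_start_s = (starts[s] - 1L) * dt,
        t_end_s = ends[s] * dt,
        censored_end = s == length(r$values) &&
          identical(p$end_cause, "recording_end"),
        flag_short_high = st == labels$high && r$lengths[s] == 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("segment_table", class(out))
  out
}

high_labels <- c("DH", "pseudo-DH")

#' Rastergram record ordering
#'
#' Orders records the way rastergrams are conventionally drawn: records with
#' a high-state (DH or pseudo-DH) segment first, sorted ascending by the
#' onset time of that state, ties broken by descending record length;
#' records that never reach the high state are appended sorted by descending
#' length. Record id is the final tie-break, so the ordering is invariant to
#' input permutation.
#'
#' @param segments a `segment_table`.
#' @return list with `order` (data.frame: `record_id`, `row`, `onset_s`,
#'   `length_s`) and `segments` (the input with a `row` column for
#'   plotting).
#' @export
build_rastergram <- function(segments) {
  ids <- unique(segments$record_id)
  onset <- vapply(ids, function(id) {
    s <- segments[segments$record_id == id & segments$label %in% high_labels, ]
    if (nrow(s)) min(s$t_start_s) else Inf
  }, 1)
  len <- vapply(ids, function(id)
    max(segments$t_end_s[segments$record_id == id]), 1)
  ord <- order(is.infinite(onset), onset, -len, ids)
  order_df <- data.frame(record_id = ids[ord], row = seq_along(ids),
                         onset_s = onset[ord], length_s = len[ord],
                         stringsAsFactors = FALSE)
  seg <- segments
  seg$row <- order_df$row[match(seg$record_id, order_df$record_id)]
  list(order = order_df, segments = seg)
}

#' Plot a rastergram
#'
#' @param raster a [build_rastergram()] result.
#' @param main plot title.
#' @export
plot_rastergram <- function(raster, main = "State rastergram") {
  seg <- raster$segments
  cols <- c("pre-DH" = "#d62728", "DH" = "#e6b800", "pseudo-DH" = "#e6b800",
            "post-DH" = "#1f77b4", "non-DH" = "#1f77b4")
  graphics::plot(NULL, xlim = c(0, max(seg$t_end_s)),
                 ylim = c(max(seg$row) + 1, 0),
                 xlab = "time since second arrival (s)", ylab = "record",
                 main = main)
  graphics::segments(seg$t_start_s, seg$row, seg$t_end_s, seg$row,
                     col = cols[seg$label], lwd = 2)
  invisible(raster)
}

#' Cohort statistics from a segment table
#'
#' Counts and fractions of records forming the high-FRET state (including
#' those already high at the first frame), records already high at frame
#' zero, never-high records, and high-state re-entries; plus the mean
#' two-complex co-residence duration (time from second arrival to record
#' end) with SEM, split by ever-high vs never-high. Durations are plain
#' means over observed (possibly right-censored) durations; no censoring
#' correction is applied.
#'
#' @param segments a `segment_table`.
#' @return object of class `cohort_stats`.
#' @export
cohort_statistics <- function(segments) {
  ids <- unique(segments$record_id)
  n <- length(ids)
  per <- lapply(ids, function(id) {
    s <- segments[segments$record_id == id, ]
    s <- s[order(s$t_start_s), ]
    high <- s$label %in% high_labels
    list(ever_high = any(high),
         already_high = high[1L],
         n_high_segments = sum(high),
         duration = max(s$t_end_s))
  })
  ever <- vapply(per, `[[`, TRUE, "ever_high")
  already <- vapply(per, `[[`, TRUE, "already_high")
  reentry <- vapply(per, `[[`, 1L, "n_high_segments") >= 2L
  dur <- vapply(per, `[[`, 1, "duration")

  ci <- function(x) as.numeric(binom.test(sum(x), n)$conf.int)
  mean_sem <- function(d) {
    if (!length(d)) return(c(mean = NA_real_, sem = NA_real_))
    c(mean = mean(d), sem = if (length(d) > 1L) sd(d) / sqrt(length(d)) else 0)
  }
  structure(list(
    n = n,
    n_ever_high = sum(ever),
    n_already_high = sum(already),
    n_formed_from_low = sum(ever & !already),
    n_never_high = sum(!ever),
    n_reentry = sum(reentry),
    frac_ever_high = mean(ever), ci_ever_high = ci(ever),
    frac_never_high = mean(!ever), ci_never_high = ci(!ever),
    duration_ever_high = mean_sem(dur[ever]),
    duration_never_high = mean_sem(dur[!ever]),
    duration_all = mean_sem(dur)
  ), class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("<cohort_stats> n =", x$n, "records\n")
  cat(sprintf("  formed high state: %d/%d (%.0f%%), of which %d already high at frame 0\n",
              x$n_ever_high, x$n, 100 * x$frac_ever_high, x$n_already_high))
  cat(sprintf("  never high: %d/%d (%.0f%%); re-entries: %d\n",
              x$n_never_high, x$n, 100 * x$frac_never_high, x$n_reentry))
  cat(sprintf("  co-residence duration: ever-high %.0f +/- %.0f s, never-high %.0f +/- %.0f s\n",
              x$duration_ever_high["mean"], x$duration_ever_high["sem"],
              x$duration_never_high["mean"], x$duration_never_high["sem"]))
  invisible(x)
}
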
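#' @useDynLib dhfret, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rexp runif rnorm median mad qbeta quantile rgamma sd
#'   dnorm pnorm optimHess approx qlogis plogis binom.test var ks.test
#'   pchisq setNames
#' @importFrom utils read.delim write.table head modifyList
NULL

# Continuous-time Markov chain jump simulation: exponential waiting times with
# the total exit rate of the current state, jump target proportional to k_ij.
# Returns the entered states and entry times (first entry at time 0).
sim_ctmc_jumps <- function(scheme, duration, start_state) {
  states <- integer(0); times <- numeric(0)
  s <- start_state; t <- 0
  repeat {
    states <- c(states, s); times <- c(times, t)
    lambda <- sum(scheme$rate_matrix[s, ])
    if (lambda <= 0) break
    t <- t + rexp(1L, lambda)
    if (t >= duration) break
    s <- sample.int(scheme$n_states, 1L,
                    prob = scheme$rate_matrix[s, ] / lambda)
  }
  list(states = states, times = times)
}

state_at <- function(jumps, t) {
  jumps$states[findInterval(t, jumps$times)]
}

#' Simulate a discretized state path
#'
#' Samples a continuous-time Markov chain under `scheme` and reports the
#' occupied state at the start of each frame (spacing `frame_interval`),
#' which keeps the discretized dwell-time distribution geometric.
#'
#' @param scheme a [kinetic_scheme()].
#' @param duration path duration in seconds (`>= frame_interval`).
#' @param frame_interval frame spacing in seconds.
#' @param seed optional integer seed (private RNG stream).
#' @param start_state optional fixed start state; default draws from the
#'   scheme's initial fractions.
#' @return object of class `state_path`: integer states per frame, frame
#'   times, and the underlying continuous jump record in attribute `jumps`.
#' @export
simulate_state_path <- function(scheme, duration, frame_interval,
                                seed = NULL, start_state = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (duration < frame_interval)
    stop("duration must be >= frame_interval", call. = FALSE)
  with_seed(seed, {
    s0 <- if (is.null(start_state))
      sample.int(scheme$n_states, 1L, prob = scheme$initial_fractions)
    else as.integer(start_state)
    jumps <- sim_ctmc_jumps(scheme, duration, s0)
    tt <- (seq_len(max(1L, floor(duration / frame_interval))) - 1L) *
      frame_interval
    structure(list(state = state_at(jumps, tt), time = tt,
                   frame_interval = frame_interval),
              jumps = jumps, class = "state_path")
  })
}

#' Emit fluorescence intensities for a state path
#'
#' Generates a strictly alternating donor/acceptor-excitation intensity trace
#' for one record whose both fluorophores are present from time zero. Donor
#' frames sit at multiples of `frame_interval`, acceptor frames half an
#' interval later. Photobleaching/departure times are drawn from the emission
#' config rates unless supplied.
#'
#' @param path a [simulate_state_path()] result.
#' @param emission an [emission_config()].
#' @param seed optional integer seed.
#' @param donor_loss_time,acceptor_loss_time optional fixed loss times
#'   (seconds); `Inf` for never.
#' @return data.frame with columns `frame_index`, `time_s`, `excitation`,
#'   `I_donor_em`, `I_acceptor_em` (one row per frame).
#' @export
emit_intensities <- function(path, emission, seed = NULL,
                             donor_loss_time = NULL,
                             acceptor_loss_time = NULL) {
  stopifnot(inherits(path, "state_path"), inherits(emission, "emission_config"))
  if (length(path$state) == 0L) stop("path is empty", call. = FALSE)
  with_seed(seed, {
    if (is.null(donor_loss_time))
      donor_loss_time <- if (emission$donor_bleach_rate > 0)
        rexp(1L, emission$donor_bleach_rate) else Inf
    if (is.null(acceptor_loss_time))
      acceptor_loss_time <- if (emission$acceptor_bleach_rate > 0)
        rexp(1L, emission$acceptor_bleach_rate) else Inf
    dt <- path$frame_interval
    t_d <- path$time                 # donor-excitation frames
    t_a <- path$time + dt / 2        # acceptor-excitation frames
    lev <- emission$efret_levels[path$state]
    tot <- emission$total_intensity

    d_act_d <- t_d < donor_loss_time
    a_act_d <- t_d < acceptor_loss_time
    a_act_a <- t_a < acceptor_loss_time

    e_eff <- ifelse(d_act_d & a_act_d, lev, 0)
    ia_d <- ifelse(d_act_d, tot * e_eff, 0)
    id_d <- ifelse(d_act_d, tot * (1 - e_eff), 0)
    ia_a <- ifelse(a_act_a, tot, 0)

    n <- length(t_d)
    out <- data.frame(
      frame_index = 0:(2L * n - 1L),
      time_s = as.numeric(rbind(t_d, t_a)),
      excitation = rep(c("donor", "acceptor"), n),
      I_donor_em = as.numeric(rbind(id_d, numeric(n))),
      I_acceptor_em = as.numeric(rbind(ia_d, ia_a)),
      stringsAsFactors = FALSE
    )
    out$I_donor_em <- out$I_donor_em + emission$baseline_offset
    out$I_acceptor_em <- out$I_acceptor_em + emission$baseline_offset
    if (emission$noise_sd > 0) {
      out$I_donor_em <- out$I_donor_em + rnorm(nrow(out), 0, emission$noise_sd)
      out$I_acceptor_em <- out$I_acceptor_em +
        rnorm(nrow(out), 0, emission$noise_sd)
    }
    out
  })
}

#' Simulate a full trace dataset with ground truth
#'
#' Emulates one recording session: each record's donor- and acceptor-labeled
#' complexes arrive independently (uniform on `[0, arrival_spread]`), FRET
#' states evolve from the later arrival (time zero) under the kinetic scheme,
#' and the usable signal ends at the first fluorophore loss or at the end of
#' the ~20 min recording. Traces cover the whole recording, so baseline
#' segments before arrival and after loss are present for the preprocessing
#' stage. Identical seeds give identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `traces` (a `trace_set`) and `truth` (a `ground_truth`
#'   object with per-record true paths, event times and generating
#'   parameters).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  em <- config$emission; sch <- config$scheme
  dt <- em$frame_interval
  n_d <- max(2L, floor(config$max_duration / dt))
  t_d <- (0:(n_d - 1L)) * dt
  t_a <- t_d + dt / 2

  with_seed(config$rng_seed, {
    frames <- vector("list", config$n_records)
    truth <- vector("list", config$n_records)
    for (r in seq_len(config$n_records)) {
      rid <- sprintf("rec%04d", r)
      arr_d <- runif(1L, 0, config$arrival_spread)
      arr_a <- runif(1L, 0, config$arrival_spread)
      t0 <- max(arr_d, arr_a)
      loss_d <- arr_d + if (em$donor_bleach_rate > 0)
        rexp(1L, em$donor_bleach_rate) else Inf
      loss_a <- arr_a + if (em$acceptor_bleach_rate > 0)
        rexp(1L, em$acceptor_bleach_rate) else Inf
      t_end <- min(loss_d, loss_a, config$max_duration)
      end_cause <- if (t_end >= config$max_duration) "recording_end"
        else "bleach_or_loss"
      s0 <- sample.int(sch$n_states, 1L, prob = sch$initial_fractions)
      jumps <- sim_ctmc_jumps(sch, max(t_end - t0, 0), s0)

      d_act_d <- t_d >= arr_d & t_d < loss_d
      a_act_d <- t_d >= arr_a & t_d < loss_a
      a_act_a <- t_a >= arr_a & t_a < loss_a
      both <- d_act_d & a_act_d & t_d >= t0 & t_d < t_end
      lev <- numeric(n_d)
      lev[both] <- em$efret_levels[state_at(jumps, t_d[both] - t0)]
      ia_d <- ifelse(d_act_d, em$total_intensity * ifelse(both, lev, 0), 0)
      id_d <- ifelse(d_act_d, em$total_intensity * (1 - ifelse(both, lev, 0)), 0)
      ia_a <- ifelse(a_act_a, em$total_intensity, 0)

      tr <- data.frame(
        record_id = rid,
        frame_index = 0:(2L * n_d - 1L),
        time_s = as.numeric(rbind(t_d, t_a)),
        excitation = rep(c("donor", "acceptor"), n_d),
        I_donor_em = as.numeric(rbind(id_d, numeric(n_d))) + em$baseline_offset,
        I_acceptor_em = as.numeric(rbind(ia_d, ia_a)) + em$baseline_offset,
        stringsAsFactors = FALSE
      )
      if (em$noise_sd > 0) {
        tr$I_donor_em <- tr$I_donor_em + rnorm(nrow(tr), 0, em$noise_sd)
        tr$I_acceptor_em <- tr$I_acceptor_em + rnorm(nrow(tr), 0, em$noise_sd)
      }
      frames[[r]] <- tr

      in_path <- t_d >= t0 & t_d < t_end
      truth[[r]] <- list(
        record_id = rid,
        arrival_donor = arr_d, arrival_acceptor = arr_a, t0 = t0,
        loss_donor = loss_d, loss_acceptor = loss_a,
        t_end_signal = t_end, end_cause = end_cause,
        start_state = s0,
        jump_states = jumps$states, jump_times = jumps$times,
        path = if (any(in_path)) state_at(jumps, t_d[in_path] - t0)
          else integer(0),
        path_time = t_d[in_path] - t0
      )
    }
    list(
      traces = trace_set(do.call(rbind, frames), frame_interval = dt),
      truth = structure(list(records = truth, scheme = sch, emission = em,
                             config = config),
                        class = "ground_truth")
    )
  })
}

#' Simulate E_FRET records directly (efficiency space)
#'
#' Shortcut generator for kinetic-inference tests: produces time-zero-aligned
#' E_FRET records (state level plus Gaussian noise in efficiency units),
#' skipping the intensity/preprocessing layers. Record durations are
#' exponential with rate `loss_rate`, truncated at `max_duration`.
#'
#' @param scheme a [kinetic_scheme()].
#' @param efret_levels E_FRET level per state.
#' @param efret_sd Gaussian noise SD in efficiency units (default 0.1).
#' @param n_records number of records.
#' @param frame_interval frame spacing, seconds.
#' @param loss_rate combined fluorophore-loss rate, per second (default
#'   0.004, i.e. ~250 s mean usable record).
#' @param max_duration recording truncation, seconds.
#' @param seed integer seed.
#' @return list with `records` (list of `efret_record`) and `truth`
#'   (per-record true discretized paths and start states).
#' @export
simulate_efret_records <- function(scheme, efret_levels = c(0.03, 0.61, 0.03),
                                   efret_sd = 0.1, n_records = 100,
                                   frame_interval = 2.67, loss_rate = 0.004,
                                   max_duration = 1200, seed = 1L) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            length(efret_levels) == scheme$n_states)
  with_seed(seed, {
    recs <- vector("list", n_records)
    paths <- vector("list", n_records)
    starts <- integer(n_records)
    for (r in seq_len(n_records)) {
      dur <- min(if (loss_rate > 0) rexp(1L, loss_rate) else Inf, max_duration)
      n <- max(2L, floor(dur / frame_interval))
      end_cause <- if (dur >= max_duration) "recording_end" else
        "bleach_or_loss"
      s0 <- sample.int(scheme$n_states, 1L, prob = scheme$initial_fractions)
      jumps <- sim_ctmc_jumps(scheme, n * frame_interval, s0)
      tt <- (0:(n - 1L)) * frame_interval
      st <- state_at(jumps, tt)
      ef <- efret_levels[st] + rnorm(n, 0, efret_sd)
      recs[[r]] <- efret_record(sprintf("rec%04d", r), t0 = 0, time = tt,
                                efret = ef, end_cause = end_cause,
                                frame_interval = frame_interval)
      paths[[r]] <- st
      starts[r] <- s0
    }
    list(records = recs,
         truth = list(paths = paths, start_states = starts, scheme = scheme,
                      efret_levels = efret_levels, efret_sd = efret_sd))
  })
}
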
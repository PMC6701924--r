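#' Kinetic scheme for the state-transition simulator
#'
#' Defines a continuous-time Markov model over `n_states` kinetic states of a
#' two-hexamer record: first-order rate constants for every ordered state pair
#' and the probability of each state at time zero (arrival of the second
#' hexamer). A *refractory* state is one whose exit rates are all zero; records
#' that start there never visit the high-FRET state, emulating the dead-end
#' non-DH population.
#'
#' @param rate_matrix square numeric matrix of first-order rate constants
#'   `k[i, j]` (per second) for transitions `i -> j`. The diagonal is ignored.
#' @param initial_fractions probability vector over states at time zero;
#'   must sum to 1.
#' @param refractory_fraction optional; if supplied, the scheme must contain at
#'   least one zero-exit state, and `initial_fractions` is rescaled so the
#'   total mass on zero-exit states equals this value.
#' @return an object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(rate_matrix, initial_fractions,
                           refractory_fraction = NULL) {
  rate_matrix <- as.matrix(rate_matrix)
  k <- nrow(rate_matrix)
  if (k < 2L || ncol(rate_matrix) != k)
    stop("rate_matrix must be a square matrix with >= 2 states", call. = FALSE)
  diag(rate_matrix) <- 0
  if (any(!is.finite(rate_matrix)) || any(rate_matrix < 0))
    stop("off-diagonal rates must be finite and >= 0", call. = FALSE)
  if (length(initial_fractions) != k)
    stop("initial_fractions must have one entry per state", call. = FALSE)
  if (any(initial_fractions < 0) ||
      abs(sum(initial_fractions) - 1) > 1e-12)
    stop("initial_fractions must be non-negative and sum to 1 (tol 1e-12)",
         call. = FALSE)

  exit_rates <- rowSums(rate_matrix)
  # refractory = a dead-end state records can only start in: zero exit and
  # (preferably) zero inflow; if every zero-exit state has inflow (e.g. the
  # mutant trap shared with post-DH), fall back to all zero-exit states
  no_exit <- exit_rates == 0
  refr <- no_exit & colSums(rate_matrix) == 0
  if (!any(refr)) refr <- no_exit
  if (!is.null(refractory_fraction)) {
    stopifnot(refractory_fraction >= 0, refractory_fraction <= 1)
    if (!any(refr) && refractory_fraction > 0)
      stop("refractory_fraction > 0 but no state has zero exit rate",
           call. = FALSE)
    p <- initial_fractions
    m_refr <- sum(p[refr])
    m_act <- sum(p[!refr])
    p[refr] <- if (m_refr > 0) p[refr] / m_refr * refractory_fraction else
      refractory_fraction / sum(refr)
    p[!refr] <- if (m_act > 0) p[!refr] / m_act * (1 - refractory_fraction) else 0
    initial_fractions <- p
  }

  structure(list(
    n_states = k,
    rate_matrix = rate_matrix,
    initial_fractions = as.numeric(initial_fractions),
    refractory_states = which(refr),
    refractory_fraction = sum(initial_fractions[refr])
  ), class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", x$n_states, " states\n", sep = "")
  cat("rates (s^-1):\n"); print(signif(x$rate_matrix, 4))
  cat("initial fractions:", signif(x$initial_fractions, 4), "\n")
  cat("refractory fraction:", signif(x$refractory_fraction, 4), "\n")
  invisible(x)
}

#' Wild-type-like three-state scheme
#'
#' States are ordered (pre-DH, DH, non-DH). The only non-zero rate is the
#' essentially irreversible pre-DH to DH transition; the non-DH state is a
#' zero-exit refractory trap.
#'
#' @param k_form pre-DH to DH rate constant, per second.
#' @param start_high fraction of records already in the DH state at time zero.
#' @param refractory_fraction fraction of records starting (and staying) in
#'   the non-DH state.
#' @return `kinetic_scheme`
#' @export
wt_scheme <- function(k_form = 0.15, start_high = 0.15,
                      refractory_fraction = 0.35) {
  rm <- matrix(0, 3, 3)
  rm[1, 2] <- k_form
  kinetic_scheme(rm,
                 c(1 - start_high - refractory_fraction, start_high,
                   refractory_fraction))
}

#' Mutant-like three-state scheme
#'
#' States are ordered (pre-DH, pseudo-DH, non-DH/post-DH). The pseudo-DH state
#' is entered from pre-DH and collapses to the long-lived low-FRET
#' non-DH/post-DH trap; re-formation is not allowed.
#'
#' @param k_form pre-DH to pseudo-DH rate constant, per second.
#' @param k_collapse pseudo-DH to post-DH rate constant, per second.
#' @inheritParams wt_scheme
#' @return `kinetic_scheme`
#' @export
mutant_scheme <- function(k_form = 0.13, k_collapse = 0.052,
                          start_high = 0.15, refractory_fraction = 0.25) {
  rm <- matrix(0, 3, 3)
  rm[1, 2] <- k_form
  rm[2, 3] <- k_collapse
  kinetic_scheme(rm,
                 c(1 - start_high - refractory_fraction, start_high,
                   refractory_fraction))
}

#' Emission model configuration
#'
#' Maps kinetic states to fluorescence intensities under alternating
#' excitation. While both fluorophores are active, a donor-excitation frame in
#' state `s` emits `I_A = total_intensity * efret_levels[s]` and
#' `I_D = total_intensity * (1 - efret_levels[s])` plus additive Gaussian
#' noise; an acceptor-excitation frame reports acceptor presence at
#' `total_intensity`. After a fluorophore bleaches or the complex departs, its
#' emission falls to `baseline_offset` plus noise.
#'
#' Default brightness and noise give an E_FRET standard deviation of ~0.1 at
#' low FRET, matching the scatter of the experimental histograms.
#'
#' @param efret_levels FRET efficiency per state, each in \[0, 1\].
#' @param total_intensity expected summed donor+acceptor emission under donor
#'   excitation (arbitrary units).
#' @param noise_sd per-channel additive Gaussian noise SD (same units).
#' @param baseline_offset additive per-channel constant.
#' @param donor_bleach_rate,acceptor_bleach_rate combined
#'   photobleaching/departure rate per fluorophore, per second.
#' @param frame_interval seconds between successive frames of the same
#'   excitation channel (default 2.67 s).
#' @return object of class `emission_config`.
#' @export
emission_config <- function(efret_levels = c(0.03, 0.61, 0.03),
                            total_intensity = 200,
                            noise_sd = 20,
                            baseline_offset = 0,
                            donor_bleach_rate = 0.002,
                            acceptor_bleach_rate = 0.002,
                            frame_interval = 2.67) {
  if (any(efret_levels < 0 | efret_levels > 1))
    stop("efret_levels must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  stopifnot(total_intensity > 0, donor_bleach_rate >= 0,
            acceptor_bleach_rate >= 0)
  structure(list(efret_levels = as.numeric(efret_levels),
                 total_intensity = total_intensity,
                 noise_sd = noise_sd,
                 baseline_offset = baseline_offset,
                 donor_bleach_rate = donor_bleach_rate,
                 acceptor_bleach_rate = acceptor_bleach_rate,
                 frame_interval = frame_interval),
            class = "emission_config")
}

#' Full simulation configuration
#'
#' @param scheme a [kinetic_scheme()].
#' @param emission an [emission_config()]; its `efret_levels` must have one
#'   entry per scheme state.
#' @param n_records number of independent records to simulate.
#' @param max_duration recording length in seconds (default 1200 s, i.e. the
#'   ~20 min observation window of the experiment).
#' @param arrival_spread each complex arrives uniformly on
#'   `[0, arrival_spread]` seconds; time zero of a record is the later arrival.
#' @param rng_seed integer seed controlling all randomness of the dataset.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(scheme = wt_scheme(),
                              emission = emission_config(),
                              n_records = 100,
                              max_duration = 1200,
                              arrival_spread = 60,
                              rng_seed = 1L) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(emission, "emission_config"))
  if (length(emission$efret_levels) != scheme$n_states)
    stop("emission$efret_levels must have one level per scheme state",
         call. = FALSE)
  if (n_records < 1) stop("n_records must be >= 1", call. = FALSE)
  if (max_duration <= emission$frame_interval)
    stop("max_duration must exceed frame_interval", call. = FALSE)
  stopifnot(arrival_spread >= 0)
  structure(list(scheme = scheme, emission = emission,
                 n_records = as.integer(n_records),
                 max_duration = max_duration,
                 arrival_spread = arrival_spread,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

# Evaluate `expr` under a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
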
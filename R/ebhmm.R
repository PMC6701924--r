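#' Construct HMM prior hyperparameters
#'
#' Priors for the variational HMM with normal-gamma emissions and Dirichlet
#' transition/initial-state distributions. The state-mean hyperparameters
#' `mu` (prior means, efficiency units) and `beta` (pseudo-count strength
#' pinning each state mean) implement the protocol of strongly constraining
#' state E_FRET values to independently fitted levels. Presets:
#' `"wt"` gives `mu = (0.06, 0.06, 0.57)`, `beta = (1000, 1000, 1000)`;
#' `"mutant"` gives `mu = (0.08, 0.08, 0.47)`, `beta = (1e4, 1e4, 1e4)`.
#'
#' @param K number of states (default 3).
#' @param mu prior state means, length `K`.
#' @param beta mean-pinning pseudo-counts, length `K` (or scalar), all `> 0`.
#' @param preset `"wt"` or `"mutant"` to load the standard hyperparameters.
#' @param a,b shape and rate of the gamma prior on emission precision
#'   (defaults 2.5 and 0.025: prior mean precision 100, i.e. E_FRET
#'   SD ~ 0.1).
#' @param alpha Dirichlet pseudo-counts for each transition row (scalar or
#'   `K x K` matrix; default 1).
#' @param gamma0 Dirichlet pseudo-counts for the initial-state distribution
#'   (scalar or length `K`; default 1).
#' @return object of class `hmm_priors`.
#' @export
make_priors <- function(K = 3, mu = NULL, beta = NULL, preset = NULL,
                        a = 2.5, b = 0.025, alpha = 1, gamma0 = 1) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("wt", "mutant"))
    K <- 3L
    if (preset == "wt") {
      if (is.null(mu)) mu <- c(0.06, 0.06, 0.57)
      if (is.null(beta)) beta <- c(1000, 1000, 1000)
    } else {
      if (is.null(mu)) mu <- c(0.08, 0.08, 0.47)
      if (is.null(beta)) beta <- c(10000, 10000, 10000)
    }
  }
  if (is.null(mu)) stop("mu must be given (or use a preset)", call. = FALSE)
  if (is.null(beta)) beta <- rep(100, length(mu))
  if (length(beta) == 1L) beta <- rep(beta, length(mu))
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (length(mu) != K || length(beta) != K)
    stop("mu and beta must have length K", call. = FALSE)
  if (any(beta <= 0)) stop("beta must be > 0", call. = FALSE)
  if (length(a) == 1L) a <- rep(a, K)
  if (length(b) == 1L) b <- rep(b, K)
  if (any(a <= 0) || any(b <= 0))
    stop("precision prior (a, b) must be > 0", call. = FALSE)
  if (length(alpha) == 1L) alpha <- matrix(alpha, K, K)
  alpha <- as.matrix(alpha)
  if (any(dim(alpha) != K)) stop("alpha must be K x K", call. = FALSE)
  if (length(gamma0) == 1L) gamma0 <- rep(gamma0, K)
  if (any(alpha <= 0) || any(gamma0 <= 0))
    stop("Dirichlet pseudo-counts must be > 0", call. = FALSE)
  structure(list(K = K, m = as.numeric(mu), beta = as.numeric(beta),
                 a = as.numeric(a), b = as.numeric(b),
                 alpha = alpha, gamma0 = as.numeric(gamma0)),
            class = "hmm_priors")
}

#' @export
print.hmm_priors <- function(x, ...) {
  cat("<hmm_priors> K =", x$K, "\n")
  cat("  mu:", signif(x$m, 4), "  beta:", signif(x$beta, 4), "\n")
  cat("  precision gamma(a, b): a =", signif(x$a, 4), ", b =",
      signif(x$b, 4), "\n")
  invisible(x)
}

# --- small numeric helpers ------------------------------------------------

kl_dirichlet <- function(q, p) {
  lgamma(sum(q)) - sum(lgamma(q)) - lgamma(sum(p)) + sum(lgamma(p)) +
    sum((q - p) * (digamma(q) - digamma(sum(q))))
}

kl_normal_gamma <- function(m1, b1, a1, bb1, m0, b0, a0, bb0) {
  klg <- (a1 - a0) * digamma(a1) - lgamma(a1) + lgamma(a0) +
    a0 * (log(bb1) - log(bb0)) + a1 * (bb0 - bb1) / bb1
  kln <- 0.5 * log(b1 / b0) + b0 / (2 * b1) - 0.5 +
    0.5 * b0 * (m1 - m0)^2 * a1 / bb1
  klg + kln
}

# --- variational machinery ------------------------------------------------

# E[log p(y_t | z_t = k)] under the normal-gamma posterior; masked frames
# contribute no emission term (zeros).
expected_log_emission <- function(y, mask, post) {
  K <- length(post$m)
  elog_lambda <- digamma(post$a) - log(post$b)
  e_lambda <- post$a / post$b
  out <- matrix(0, length(y), K)
  un <- which(!mask)
  for (k in seq_len(K)) {
    out[un, k] <- 0.5 * elog_lambda[k] - 0.5 * log(2 * pi) -
      0.5 * (e_lambda[k] * (y[un] - post$m[k])^2 + 1 / post$beta[k])
  }
  out
}

vb_m_step <- function(y, mask, gamma_r, xi, g1, priors) {
  K <- priors$K
  un <- !mask
  gu <- gamma_r[un, , drop = FALSE]
  yu <- y[un]
  Nk <- colSums(gu)
  Sy <- as.numeric(crossprod(gu, yu))
  ybar <- ifelse(Nk > 0, Sy / pmax(Nk, 1e-300), priors$m)
  Sq <- vapply(seq_len(K), function(k) sum(gu[, k] * (yu - ybar[k])^2), 1)
  beta_p <- priors$beta + Nk
  m_p <- (priors$beta * priors$m + Nk * ybar) / beta_p
  a_p <- priors$a + Nk / 2
  b_p <- priors$b + 0.5 * Sq +
    0.5 * priors$beta * Nk * (ybar - priors$m)^2 / beta_p
  list(K = K, m = m_p, beta = beta_p, a = a_p, b = b_p,
       alpha = priors$alpha + xi, g0 = priors$gamma0 + g1)
}

vb_kl <- function(post, priors) {
  kl <- kl_dirichlet(post$g0, priors$gamma0)
  for (k in seq_len(priors$K)) {
    kl <- kl + kl_dirichlet(post$alpha[k, ], priors$alpha[k, ])
    kl <- kl + kl_normal_gamma(post$m[k], post$beta[k], post$a[k], post$b[k],
                               priors$m[k], priors$beta[k], priors$a[k],
                               priors$b[k])
  }
  kl
}

# Structured initialization encoding the lifetime identifiability of the two
# emission-indistinguishable low-FRET states: records that ever visit the
# high-FRET state get their low frames seeded to the first low state
# (transient, pre-DH-like), never-high records to the second (long-lived
# trap). Breaking this symmetry deterministically gives the coupled fit a
# start near the kinetically separated solution; the evidence then arbitrates
# against the other starts.
structured_init <- function(records, priors) {
  K <- priors$K
  high_k <- which.max(priors$m)
  lows <- order(priors$m)[1:2]
  if (K < 3L || priors$m[lows[2]] >= priors$m[high_k])
    return(lapply(records, function(r)
      init_responsibilities(r$efret, r$mask, priors)))
  mid <- (priors$m[high_k] + max(priors$m[lows])) / 2
  lapply(records, function(r) {
    y <- r$efret; y[!is.finite(y)] <- 0
    is_high <- !r$mask & y > mid
    # a real high-state visit shows >= 2 consecutive high frames; isolated
    # spikes are noise and must not route a trap record to the pre state
    runs <- rle(is_high)
    qual <- runs$values & runs$lengths >= 2L
    r0 <- matrix(0.05 / (K - 1), length(y), K)
    if (any(qual)) {
      first_high <- cumsum(runs$lengths)[which(qual)[1L]] -
        runs$lengths[which(qual)[1L]] + 1L
      # low frames before the first high visit are transient (pre-like);
      # low frames after it are the long-lived trap (post-like)
      tgt <- ifelse(seq_along(y) < first_high, lows[1], lows[2])
      r0[cbind(seq_along(y), tgt)] <- 0.95
      r0[is_high, ] <- 0.05 / (K - 1)
      r0[is_high, high_k] <- 0.95
    } else {
      r0[, lows[2]] <- 0.95
      r0[is_high, ] <- 0.05 / (K - 1)
      r0[is_high, high_k] <- 0.95
    }
    r0[r$mask, ] <- 1 / K
    r0
  })
}

init_responsibilities <- function(y, mask, priors, jitter_seed = NULL) {
  K <- priors$K
  prec <- priors$a / priors$b
  ll <- vapply(seq_len(K),
               function(k) -0.5 * prec[k] * (y - priors$m[k])^2, y)
  if (!is.matrix(ll)) ll <- matrix(ll, nrow = 1L)
  ll <- ll - apply(ll, 1L, max)
  r <- exp(ll)
  r[mask, ] <- 1
  if (!is.null(jitter_seed)) {
    r <- r * matrix(with_seed(jitter_seed,
                              rgamma(length(y) * K, shape = 2)),
                    length(y), K)
  }
  r / rowSums(r)
}

#' Variational Bayes fit of one E_FRET record
#'
#' Variational EM with conjugate updates (normal-gamma emissions, Dirichlet
#' transition rows and initial distribution). The E-step runs
#' forward-backward on expected log-densities; masked frames contribute no
#' emission term but keep their place in the time base. Iterates to
#' convergence of the evidence lower bound (relative change `< tol`).
#'
#' @param record an `efret_record` with at least 2 unmasked frames.
#' @param priors an `hmm_priors`.
#' @param init_resp optional `T x K` initial responsibilities (e.g. a warm
#'   start from a previous round).
#' @param max_iter,tol VB iteration controls (defaults 500 and 1e-6).
#' @return object of class `trace_posterior`: per-frame responsibilities
#'   (`gamma`), expected transition counts (`xi`), variational parameters
#'   (`post`), the ELBO trajectory and a convergence flag.
#' @export
vb_fit_trace <- function(record, priors, init_resp = NULL,
                         max_iter = 500, tol = 1e-6) {
  stopifnot(inherits(record, "efret_record"), inherits(priors, "hmm_priors"))
  y <- record$efret; mask <- record$mask
  y[!is.finite(y)] <- 0   # masked anyway; keep arithmetic finite
  if (sum(!mask) < 2L)
    stop("record '", record$record_id, "' has fewer than 2 unmasked frames",
         call. = FALSE)
  T_ <- length(y); K <- priors$K
  r <- if (is.null(init_resp)) init_responsibilities(y, mask, priors)
    else init_resp
  # independence approximation for the initial expected transition counts
  xi0 <- crossprod(r[-T_, , drop = FALSE], r[-1L, , drop = FALSE])
  post <- vb_m_step(y, mask, r, xi0, r[1L, ], priors)

  elbo <- numeric(0)
  gamma_r <- r; xi <- xi0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    log_pi <- digamma(post$g0) - digamma(sum(post$g0))
    log_A <- digamma(post$alpha) - digamma(rowSums(post$alpha))
    log_B <- expected_log_emission(y, mask, post)
    fb <- fb_hmm(log_pi, log_A, log_B)
    gamma_r <- fb$gamma; xi <- fb$xi
    elbo_it <- fb$loglik - vb_kl(post, priors)
    elbo <- c(elbo, elbo_it)
    if (it > 1L &&
        abs(elbo_it - elbo[it - 1L]) < tol * (abs(elbo[it - 1L]) + 1)) {
      converged <- TRUE
      break
    }
    post <- vb_m_step(y, mask, gamma_r, xi, gamma_r[1L, ], priors)
  }
  structure(list(record_id = record$record_id, gamma = gamma_r, xi = xi,
                 post = post, elbo = elbo, converged = converged,
                 n_frames = T_, n_unmasked = sum(!mask)),
            class = "trace_posterior")
}

# Shared M-step of the coupled (global) fit: pool expected sufficient
# statistics across all records into one Dirichlet posterior per transition
# row, one initial-state Dirichlet and one normal-gamma emission posterior
# per state. The state-mean pseudo-counts (m, beta) act exactly like the
# per-trace case: beta pins the pooled posterior mean at the prior value.
shared_m_step <- function(records, gammas, xis, priors) {
  K <- priors$K
  Nk <- numeric(K); Sy <- numeric(K)
  for (i in seq_along(records)) {
    un <- !records[[i]]$mask
    g <- gammas[[i]][un, , drop = FALSE]
    Nk <- Nk + colSums(g)
    Sy <- Sy + as.numeric(crossprod(g, records[[i]]$efret[un]))
  }
  ybar <- ifelse(Nk > 0, Sy / pmax(Nk, 1e-300), priors$m)
  Sq <- numeric(K)
  for (i in seq_along(records)) {
    un <- !records[[i]]$mask
    g <- gammas[[i]][un, , drop = FALSE]
    y <- records[[i]]$efret[un]
    Sq <- Sq + vapply(seq_len(K), function(k) sum(g[, k] * (y - ybar[k])^2), 1)
  }
  beta_p <- priors$beta + Nk
  m_p <- (priors$beta * priors$m + Nk * ybar) / beta_p
  a_p <- priors$a + Nk / 2
  b_p <- priors$b + 0.5 * Sq +
    0.5 * priors$beta * Nk * (ybar - priors$m)^2 / beta_p
  # The initial-state block is deliberately NOT updated: learning a shared
  # initial distribution opens a degenerate optimum in which trap records
  # "start" in the transient state and hop at time zero (an unobservable
  # move), which confounds the initial fractions with the pre->trap rate.
  # q(pi) stays at its uninformative prior; initial fractions are read off
  # the frame-0 responsibilities instead.
  list(K = K, m = m_p, beta = beta_p, a = a_p, b = b_p,
       alpha = priors$alpha + Reduce(`+`, xis),
       g0 = priors$gamma0)
}

#' Coupled population fit of pooled E_FRET records
#'
#' Global variational fit of all records to one generalized `K`-state kinetic
#' model (all inter-state transitions allowed): per-record forward-backward
#' E-steps alternate with a shared M-step that pools the expected sufficient
#' statistics of every record into single Dirichlet posteriors over the
#' transition rows and the initial-state distribution and a normal-gamma
#' posterior per emission state. Pooling the transition statistics is what
#' lets two states with indistinguishable E_FRET levels be separated by
#' their lifetimes. The state-mean hyperparameters `(mu, beta)` stay pinned
#' at the prior values (the protocol's strong constraint); the evidence
#' lower bound is exact for the shared-parameter model and non-decreasing
#' across rounds. Variational fits are local, so a fixed list of restarts is
#' run (a structured lifetime-based start, an emission-based start, then
#' jittered starts) and the best evidence kept; results are deterministic
#' given `seed`.
#'
#' @param records list of `efret_record` (>= 2).
#' @param priors an `hmm_priors`.
#' @param n_starts number of restarts with jittered initial responsibilities
#'   (default 5; the first start is unjittered).
#' @param max_rounds maximum EB rounds (default 25).
#' @param tol relative convergence tolerance on the summed evidence
#'   (default 1e-5).
#' @param vb_max_iter,vb_tol per-trace VB controls.
#' @param seed integer seed for the restart jitter.
#' @return object of class `population_fit`.
#' @export
eb_fit_population <- function(records, priors, n_starts = 5,
                              max_rounds = 25, tol = 1e-5,
                              vb_max_iter = 500, vb_tol = 1e-6, seed = 1L) {
  stopifnot(length(records) >= 2L, inherits(priors, "hmm_priors"))
  K <- priors$K
  n_unmasked <- sum(vapply(records, function(r) sum(!r$mask), 1L))
  if (n_unmasked < K * K + 2 * K)
    stop("fewer unmasked frames than model parameters", call. = FALSE)

  ys <- lapply(records, function(r) {
    y <- r$efret; y[!is.finite(y)] <- 0; y
  })

  run_start <- function(jit) {
    gammas <- if (identical(jit, "structured")) {
      structured_init(records, priors)
    } else if (is.na(jit)) {
      lapply(records, function(r)
        init_responsibilities(r$efret, r$mask, priors))
    } else {
      lapply(seq_along(records), function(i)
        init_responsibilities(
          records[[i]]$efret, records[[i]]$mask, priors,
          jitter_seed = as.integer((as.numeric(jit) * 10007 + i) %%
                                     2147483629)))
    }
    xis <- lapply(gammas, function(r) {
      T_ <- nrow(r)
      crossprod(r[-T_, , drop = FALSE], r[-1L, , drop = FALSE])
    })
    post <- shared_m_step(records, gammas, xis, priors)
    ev_trace <- numeric(0)
    for (round in seq_len(max_rounds)) {
      log_pi <- digamma(post$g0) - digamma(sum(post$g0))
      log_A <- digamma(post$alpha) - digamma(rowSums(post$alpha))
      lnZ <- 0
      for (i in seq_along(records)) {
        log_B <- expected_log_emission(ys[[i]], records[[i]]$mask, post)
        fb <- fb_hmm(log_pi, log_A, log_B)
        gammas[[i]] <- fb$gamma; xis[[i]] <- fb$xi
        lnZ <- lnZ + fb$loglik
      }
      ev <- lnZ - vb_kl(post, priors)
      ev_trace <- c(ev_trace, ev)
      if (round > 1L &&
          abs(ev - ev_trace[round - 1L]) < tol * (abs(ev_trace[round - 1L]) + 1))
        break
      post <- shared_m_step(records, gammas, xis, priors)
    }
    list(gammas = gammas, xis = xis, post = post, evidence = ev_trace)
  }

  starts <- c(list("structured", NA_integer_),
              as.list(as.integer((as.numeric(seed) * 1000 +
                                    seq_len(max(n_starts - 2L, 0L))) %%
                                   2147483629)))
  starts <- starts[seq_len(max(n_starts, 1L))]
  best <- NULL; best_i <- 1L
  for (si in seq_along(starts)) {
    res <- run_start(starts[[si]])
    ev <- res$evidence[length(res$evidence)]
    if (is.null(best) || ev > best$evidence[length(best$evidence)]) {
      best <- res; best_i <- si
    }
  }

  post <- best$post
  posts <- lapply(seq_along(records), function(i) {
    structure(list(record_id = records[[i]]$record_id,
                   gamma = best$gammas[[i]], xi = best$xis[[i]],
                   post = post, elbo = best$evidence,
                   converged = length(best$evidence) < max_rounds,
                   n_frames = length(records[[i]]$efret),
                   n_unmasked = sum(!records[[i]]$mask)),
              class = "trace_posterior")
  })
  frame_interval <- records[[1L]]$frame_interval

  fit <- structure(list(
    K = K, priors = priors, shared_post = post,
    posteriors = posts, records = records,
    state_mean = post$m, state_sd = sqrt(post$b / post$a),
    trans_alpha = post$alpha,
    trans_prob = post$alpha / rowSums(post$alpha),
    frame_interval = frame_interval,
    evidence = best$evidence, n_starts = length(starts),
    best_start = best_i, seed = seed
  ), class = "population_fit")

  # Reported rates come from the decoded paths: soft expected counts bleed
  # dwell frames between the two emission-identical low states (the
  # data-pulled trap mean fits low frames slightly better than the
  # prior-pinned pre mean), which inflates exit probabilities. Viterbi
  # counts under the fitted parameters do not have that per-frame leak.
  # With two emission-identical low states, frame 0 of a record can be
  # explained either by its true start state or by an unobservable hop out
  # of the other low state (initial-fraction ambiguity). A state that is
  # never decoded after frame 0 therefore has no kinetic evidence: its
  # count row is zeroed and its rates are reported as prior-only,
  # not-significant.
  hard <- matrix(0, K, K)
  occ_after0 <- logical(K)
  for (p in decode_states(fit)) {
    s <- p$state
    if (length(s) > 1L) {
      for (t in seq_len(length(s) - 1L))
        hard[s[t], s[t + 1L]] <- hard[s[t], s[t + 1L]] + 1
      occ_after0[unique(s[-1L])] <- TRUE
    }
  }
  hard[!occ_after0, ] <- 0
  fit$decoded_counts <- hard
  fit$occupied_states <- occ_after0
  fit$trans_alpha <- priors$alpha + hard
  fit$trans_prob <- fit$trans_alpha / rowSums(fit$trans_alpha)
  fit$rates <- transition_rates(fit)
  fit$initial_fractions <- initial_fractions(fit)
  fit
}

#' @export
print.population_fit <- function(x, ...) {
  cat("<population_fit> K =", x$K, ",", length(x$records), "records\n")
  cat("  state means:", signif(x$state_mean, 4), "\n")
  cat("  state SDs:  ", signif(x$state_sd, 4), "\n")
  cat("  evidence:", signif(x$evidence[length(x$evidence)], 8),
      "after", length(x$evidence), "EB rounds (start", x$best_start, ")\n")
  print(x$rates)
  invisible(x)
}

#' Rate constants with credible intervals and significance flags
#'
#' Converts the pooled Dirichlet posterior over per-frame transition
#' probabilities into first-order rate constants. The default `"expm"`
#' convention inverts the frame discretization exactly per element,
#' `k = -log(1 - E[p]) / dt`, which is unbiased for the dominant transition
#' of each state in this regime; `"linear"` gives the small-`p`
#' approximation `k = E[p] / dt`. 95% credible intervals come from the Beta
#' marginals of the Dirichlet posterior, mapped through the same transform.
#' A rate is flagged significant iff the lower CI bound exceeds `floor`.
#'
#' @param fit a `population_fit`.
#' @param frame_interval seconds per frame (default: from the fit).
#' @param method `"expm"` (default) or `"linear"`.
#' @param floor significance floor in s^-1 (default 1e-4).
#' @param level credible level (default 0.95).
#' @return data.frame with columns `from`, `to`, `k_s`, `ci_low`, `ci_high`,
#'   `significant`.
#' @export
transition_rates <- function(fit, frame_interval = NULL,
                             method = c("expm", "linear"),
                             floor = 1e-4, level = 0.95) {
  method <- match.arg(method)
  if (is.null(frame_interval)) frame_interval <- fit$frame_interval
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  alpha <- fit$trans_alpha
  K <- nrow(alpha)
  # occupancy guard: a state never decoded (beyond the alignment frame) has
  # a prior-dominated posterior whose credible interval reflects ignorance,
  # not evidence of a rate
  occupied <- if (!is.null(fit$occupied_states)) fit$occupied_states
    else rep(TRUE, K)
  lo_q <- (1 - level) / 2; hi_q <- 1 - lo_q
  to_rate <- function(p) {
    if (method == "expm") -log1p(-pmin(p, 1 - 1e-12)) / frame_interval
    else p / frame_interval
  }
  rows <- list()
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    ai <- alpha[i, j]; a0 <- sum(alpha[i, ])
    p_mean <- ai / a0
    p_lo <- qbeta(lo_q, ai, a0 - ai)
    p_hi <- qbeta(hi_q, ai, a0 - ai)
    k <- to_rate(p_mean); k_hi <- to_rate(p_hi)
    k_lo <- if (occupied[i]) to_rate(p_lo) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      from = i, to = j, k_s = k, ci_low = k_lo, ci_high = k_hi,
      significant = k_lo > floor)
  }
  do.call(rbind, rows)
}

#' Initial state fractions
#'
#' Fraction of records in each state at the moment of second-hexamer
#' binding: the mean of the frame-0 state responsibilities across records,
#' with standard errors from a bootstrap over records.
#'
#' @param fit a `population_fit`.
#' @param n_boot bootstrap resamples (default 500).
#' @param seed bootstrap seed.
#' @return data.frame with columns `state`, `IF`, `se`.
#' @export
initial_fractions <- function(fit, n_boot = 500, seed = 1L) {
  r0 <- t(vapply(fit$posteriors, function(p) p$gamma[1L, ],
                 numeric(fit$K)))
  ifr <- colMeans(r0)
  n <- nrow(r0)
  se <- if (n > 1L && n_boot > 0L) {
    with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(b)
        colMeans(r0[sample.int(n, n, TRUE), , drop = FALSE]),
        numeric(fit$K))
      apply(reps, 1L, sd)
    })
  } else rep(NA_real_, fit$K)
  data.frame(state = seq_len(fit$K), IF = ifr, se = se)
}

#' Decode the most probable state path of a record
#'
#' Viterbi decoding under the record's posterior-mean parameters; masked
#' frames carry no emission term and are bridged by the transition
#' structure. Ties in path probability resolve to the lowest state index.
#'
#' @param fit a `population_fit`.
#' @param record_id a record id, an index, or `NULL` to decode all records.
#' @return a `state_path` (or a list of them for `NULL`).
#' @export
decode_states <- function(fit, record_id = NULL) {
  decode_one <- function(i) {
    p <- fit$posteriors[[i]]; r <- fit$records[[i]]
    pi_hat <- p$post$g0 / sum(p$post$g0)
    A_hat <- p$post$alpha / rowSums(p$post$alpha)
    sd_hat <- sqrt(p$post$b / p$post$a)
    y <- r$efret; y[!is.finite(y)] <- 0
    log_B <- matrix(0, length(y), fit$K)
    un <- which(!r$mask)
    for (k in seq_len(fit$K))
      log_B[un, k] <- dnorm(y[un], p$post$m[k], sd_hat[k], log = TRUE)
    path <- viterbi_hmm(log(pi_hat), log(A_hat), log_B)
    structure(list(state = as.integer(path), time = r$time,
                   frame_interval = r$frame_interval,
                   record_id = r$record_id, end_cause = r$end_cause),
              class = "state_path")
  }
  if (is.null(record_id)) return(lapply(seq_along(fit$records), decode_one))
  if (is.character(record_id)) {
    idx <- match(record_id,
                 vapply(fit$records, function(r) r$record_id, ""))
    if (is.na(idx)) stop("unknown record_id '", record_id, "'", call. = FALSE)
    record_id <- idx
  }
  decode_one(record_id)
}
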
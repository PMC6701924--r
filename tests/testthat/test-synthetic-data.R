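test_that("scheme validation rejects bad configurations", {
  expect_error(kinetic_scheme(matrix(-0.1, 2, 2), c(0.5, 0.5)), "rates")
  expect_error(kinetic_scheme(matrix(0, 2, 2), c(0.6, 0.5)), "sum to 1")
  expect_error(kinetic_scheme(matrix(0, 1, 1), 1), "square")
  m <- matrix(0, 3, 3); m[1, 2] <- 0.1; m[2, 1] <- 0.1; m[3, 1] <- 0.1
  expect_error(kinetic_scheme(m, c(1, 0, 0), refractory_fraction = 0.5),
               "zero exit rate")
})

test_that("refractory_fraction rescales the initial distribution", {
  s <- wt_scheme(refractory_fraction = 0.35, start_high = 0.15)
  expect_equal(sum(s$initial_fractions), 1)
  expect_equal(s$initial_fractions[3], 0.35)
  # DH also has zero exit but has inflow; only non-DH is the dead end
  expect_equal(s$refractory_states, 3L)
  expect_equal(s$refractory_fraction, 0.35)
})

test_that("absorbing scheme yields a constant path", {
  s <- kinetic_scheme(matrix(0, 3, 3), c(1, 0, 0))
  p <- simulate_state_path(s, duration = 100, frame_interval = 2.67, seed = 1)
  expect_true(all(p$state == 1L))
  expect_equal(length(p$state), floor(100 / 2.67))
})

test_that("mean continuous dwell matches 1/k (analytic oracle)", {
  m <- matrix(0, 2, 2); m[1, 2] <- 0.1
  s <- kinetic_scheme(m, c(1, 0))
  dwells <- vapply(1:1000, function(i) {
    p <- simulate_state_path(s, duration = 500, frame_interval = 2.67,
                             seed = i)
    j <- attr(p, "jumps")
    if (length(j$times) > 1L) j$times[2] else NA_real_
  }, 1)
  dwells <- dwells[!is.na(dwells)]
  se <- sd(dwells) / sqrt(length(dwells))
  expect_lt(abs(mean(dwells) - 10), 3 * se)
})

test_that("chain occupancy matches the master equation", {
  m <- matrix(0, 3, 3); m[1, 2] <- 0.15; m[2, 3] <- 0.05
  s <- kinetic_scheme(m, c(1, 0, 0))
  n <- 5000
  occ3 <- mean(vapply(seq_len(n), function(i) {
    p <- simulate_state_path(s, duration = 121, frame_interval = 60, seed = i)
    # state at t = 60 s is the second frame of a 60 s grid
    p$state[2] == 3L
  }, TRUE))
  expected <- occupancy_at(m, c(1, 0, 0), 60)[3]
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(occ3 - expected), 4 * se)
})

test_that("discretized dwells are geometric (chi-square GOF)", {
  m <- matrix(0, 2, 2); m[1, 2] <- 0.12
  s <- kinetic_scheme(m, c(1, 0))
  dt <- 2.67
  dwell_frames <- integer(0)
  i <- 0
  while (length(dwell_frames) < 10000) {
    i <- i + 1
    p <- simulate_state_path(s, duration = 2000, frame_interval = dt,
                             seed = i)
    r <- rle(p$state)
    # completed state-1 dwells only (not the final censored run)
    keep <- which(r$values == 1L & seq_along(r$values) < length(r$values))
    dwell_frames <- c(dwell_frames, r$lengths[keep])
  }
  dwell_frames <- dwell_frames[1:10000]
  p_geom <- 1 - exp(-0.12 * dt)
  brk <- 1:8
  obs <- tabulate(pmin(dwell_frames, 9L), nbins = 9L)
  expp <- c(p_geom * (1 - p_geom)^(brk - 1), (1 - p_geom)^8) * 10000
  chi2 <- sum((obs - expp)^2 / expp)
  pval <- pchisq(chi2, df = 8, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("noiseless emission inverts the E_FRET formula exactly", {
  s <- kinetic_scheme(matrix(0, 2, 2), c(0, 1))
  em <- emission_config(efret_levels = c(0.1, 0.6), total_intensity = 100,
                        noise_sd = 0, baseline_offset = 0,
                        donor_bleach_rate = 0, acceptor_bleach_rate = 0)
  p <- simulate_state_path(s, 100, 2.67, seed = 1)
  tr <- emit_intensities(p, em, seed = 1)
  don <- tr[tr$excitation == "donor", ]
  expect_true(all(don$I_acceptor_em == 60))
  expect_true(all(don$I_donor_em == 40))
  expect_equal(compute_efret(don$I_acceptor_em, don$I_donor_em),
               rep(0.6, nrow(don)))
})

test_that("emissions fall to baseline after donor loss", {
  s <- kinetic_scheme(matrix(0, 2, 2), c(0, 1))
  em <- emission_config(efret_levels = c(0.1, 0.6), total_intensity = 100,
                        noise_sd = 0, baseline_offset = 7,
                        donor_bleach_rate = 0, acceptor_bleach_rate = 0)
  p <- simulate_state_path(s, 100, 2.67, seed = 1)
  tr <- emit_intensities(p, em, seed = 1, donor_loss_time = 50,
                         acceptor_loss_time = Inf)
  don <- tr[tr$excitation == "donor", ]
  post <- don$time_s >= 50
  expect_true(all(don$I_acceptor_em[post] == 7))
  expect_true(all(don$I_donor_em[post] == 7))
  # acceptor-excitation channel still sees the acceptor
  acc <- tr[tr$excitation == "acceptor", ]
  expect_true(all(acc$I_acceptor_em == 107))
})

test_that("emitted noise SD matches the configured value", {
  s <- kinetic_scheme(matrix(0, 2, 2), c(1, 0))
  em <- emission_config(efret_levels = c(0.3, 0.6), total_intensity = 100,
                        noise_sd = 5, donor_bleach_rate = 0,
                        acceptor_bleach_rate = 0, frame_interval = 1)
  p <- simulate_state_path(s, 10000, 1, seed = 2)
  tr <- emit_intensities(p, em, seed = 3)
  don <- tr[tr$excitation == "donor", ]
  expect_lt(abs(sd(don$I_acceptor_em) - 5) / 5, 0.02)
})

test_that("simulate_dataset is deterministic and honors refractory fraction", {
  cfg <- simulation_config(wt_scheme(), emission_config(),
                           n_records = 5, max_duration = 300, rng_seed = 9)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$traces$frames, b$traces$frames)

  # refractory_fraction = 1: no record ever reaches the high-FRET state
  sch <- kinetic_scheme({m <- matrix(0, 3, 3); m[1, 2] <- 0.15; m},
                        c(0.5, 0.15, 0.35), refractory_fraction = 1)
  cfg1 <- simulation_config(sch, emission_config(), n_records = 40,
                            max_duration = 300, rng_seed = 4)
  d <- simulate_dataset(cfg1)
  states <- unlist(lapply(d$truth$records, function(r) r$path))
  expect_false(any(states == 2L))

  # binomial check of the refractory share at n = 2000 (path-level draws)
  sch2 <- wt_scheme(refractory_fraction = 0.35)
  n <- 2000
  starts <- vapply(seq_len(n), function(i) {
    p <- simulate_state_path(sch2, 5.4, 2.67, seed = i)
    p$state[1]
  }, 1L)
  # WT scheme: refractory mass is split between the absorbing DH start (0.15)
  # and the non-DH trap (0.35); count the trap state
  phat <- mean(starts == 3L)
  ci <- binom.test(round(phat * n), n, conf.level = 0.99)$conf.int
  expect_true(0.35 >= ci[1] && 0.35 <= ci[2])
})

test_that("ground-truth paths align with emitted traces", {
  cfg <- simulation_config(wt_scheme(), emission_config(noise_sd = 0),
                           n_records = 6, max_duration = 400, rng_seed = 2)
  d <- simulate_dataset(cfg)
  for (r in d$truth$records) {
    fr <- d$traces$frames[d$traces$frames$record_id == r$record_id &
                            d$traces$frames$excitation == "donor", ]
    in_path <- fr$time_s >= r$t0 & fr$time_s < r$t_end_signal
    expect_equal(sum(in_path), length(r$path))
    if (length(r$path)) {
      ef <- compute_efret(fr$I_acceptor_em[in_path], fr$I_donor_em[in_path])
      expect_equal(ef, cfg$emission$efret_levels[r$path], tolerance = 1e-12)
    }
  }
})
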
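step_trace <- function(n_frames = 100, on = 26, off = 75, level = 100,
                       base = 0, noise = 0, dt = 2.67, seed = 1) {
  # interleaved two-channel record; spot present on frames [on, off) of each
  # channel's sub-series
  set.seed(seed)
  t_d <- (0:(n_frames - 1)) * dt
  present <- seq_len(n_frames) >= on & seq_len(n_frames) < off
  id_d <- base + ifelse(present, level * 0.5, 0)
  ia_d <- base + ifelse(present, level * 0.5, 0)
  ia_a <- base + ifelse(present, level, 0)
  df <- data.frame(
    record_id = "r1",
    frame_index = 0:(2 * n_frames - 1),
    time_s = as.numeric(rbind(t_d, t_d + dt / 2)),
    excitation = rep(c("donor", "acceptor"), n_frames),
    I_donor_em = as.numeric(rbind(id_d, numeric(n_frames))),
    I_acceptor_em = as.numeric(rbind(ia_d, ia_a)))
  if (noise > 0) {
    df$I_donor_em <- df$I_donor_em + rnorm(nrow(df), 0, noise)
    df$I_acceptor_em <- df$I_acceptor_em + rnorm(nrow(df), 0, noise)
  }
  df
}

test_that("compute_efret: formula, edge cases, scale invariance", {
  expect_equal(compute_efret(60, 40), 0.6)
  expect_equal(compute_efret(0, 100), 0)
  expect_equal(compute_efret(50, 50), 0.5)
  expect_true(is.na(compute_efret(0, 0)))
  set.seed(1)
  ia <- runif(1000, 0, 200); id <- runif(1000, 0, 200)
  cc <- runif(1000, 0.01, 100)
  expect_equal(compute_efret(cc * ia, cc * id), compute_efret(ia, id),
               tolerance = 1e-12)
})

test_that("presence detection finds a clean step exactly", {
  tr <- step_trace()
  pv <- detect_presence_intervals(tr, frame_interval = 2.67)
  expect_equal(nrow(pv$donor), 1L)
  expect_equal(nrow(pv$acceptor), 1L)
  dt <- 2.67
  expect_equal(pv$donor$t_start, 25 * dt)  # frame 26 (1-based) -> t = 25 dt
  expect_equal(pv$donor$t_end, 74 * dt)    # half-open past frame 74 at 73 dt
  # featureless trace: no intervals
  flat <- step_trace(level = 0)
  pv0 <- detect_presence_intervals(flat, frame_interval = 2.67)
  expect_equal(nrow(pv0$donor), 0L)
  expect_equal(nrow(pv0$acceptor), 0L)
})

test_that("pure-noise traces yield no intervals in >= 99% of cases", {
  hits <- vapply(1:1000, function(i) {
    tr <- step_trace(n_frames = 100, level = 0, noise = 5, seed = i)
    pv <- detect_presence_intervals(tr, threshold_sd = 5,
                                    min_dwell_frames = 3,
                                    frame_interval = 2.67)
    nrow(pv$donor) + nrow(pv$acceptor) > 0
  }, TRUE)
  expect_lt(mean(hits), 0.01)
})

test_that("arrival detection within +/- 1 frame for >= 95% of records at SNR 10", {
  cfg <- simulation_config(wt_scheme(),
                           emission_config(total_intensity = 200,
                                           noise_sd = 20),
                           n_records = 60, max_duration = 600, rng_seed = 8)
  d <- simulate_dataset(cfg)
  dt <- cfg$emission$frame_interval
  ok <- 0; tot <- 0
  for (r in d$truth$records) {
    tr <- d$traces$frames[d$traces$frames$record_id == r$record_id, ]
    pv <- detect_presence_intervals(tr, frame_interval = dt)
    if (nrow(pv$donor) == 1L && r$loss_donor - r$arrival_donor > 6 * dt) {
      tot <- tot + 1
      if (abs(pv$donor$t_start - ceiling(r$arrival_donor / dt) * dt) <= dt)
        ok <- ok + 1
    }
  }
  expect_gt(tot, 20)
  expect_gte(ok / tot, 0.95)
})

test_that("baseline subtraction recovers offsets and drifts", {
  # constant baseline 50, spot adds 100
  tr <- step_trace(base = 50, level = 100)
  pv <- detect_presence_intervals(tr, frame_interval = 2.67)
  cor <- subtract_baseline(tr, pv)
  acc <- cor[cor$excitation == "acceptor", ]
  present <- acc$I_acceptor_em > 50
  expect_equal(mean(acc$I_acceptor_em[41:60]), 100, tolerance = 1e-6)
  expect_equal(max(abs(acc$I_acceptor_em[1:20])), 0, tolerance = 1e-9)

  # linear drift 0 -> 20 across the record, window 15; presence intervals
  # supplied as known (drift alone must not be mistaken for a spot here)
  tr2 <- step_trace()
  n <- nrow(tr2)
  drift <- seq(0, 20, length.out = n)
  tr2$I_donor_em <- tr2$I_donor_em + drift
  tr2$I_acceptor_em <- tr2$I_acceptor_em + drift
  dt <- 2.67
  pv2 <- structure(list(
    donor = data.frame(t_start = 25 * dt, t_end = 74 * dt),
    acceptor = data.frame(t_start = 25 * dt, t_end = 74 * dt),
    threshold_sd = 4, min_dwell_frames = 3), class = "presence_intervals")
  cor2 <- subtract_baseline(tr2, pv2, smooth_window_frames = 15)
  don <- cor2[cor2$excitation == "donor", ]
  base_fr <- c(1:25, 76:100)
  expect_lt(mean(abs(don$I_donor_em[base_fr])), 1)

  # spotless trace stays ~0 (exactly 0 when noiseless)
  tr3 <- step_trace(level = 0, base = 30)
  pv3 <- detect_presence_intervals(tr3, frame_interval = 2.67)
  cor3 <- subtract_baseline(tr3, pv3)
  expect_equal(max(abs(cor3$I_donor_em)), 0, tolerance = 1e-9)
})

test_that("record selection applies the one-donor/one-acceptor overlap rule", {
  dt <- 2.67
  mk_pv <- function(d, a) structure(list(
    donor = data.frame(t_start = d[c(TRUE, FALSE)], t_end = d[c(FALSE, TRUE)]),
    acceptor = data.frame(t_start = a[c(TRUE, FALSE)],
                          t_end = a[c(FALSE, TRUE)]),
    threshold_sd = 4, min_dwell_frames = 3), class = "presence_intervals")
  tr <- step_trace(n_frames = 100, on = 1, off = 101)
  ts <- trace_set(tr, frame_interval = dt)

  # two donor arrivals -> excluded with reason
  res <- select_two_hexamer_records(ts, list(
    r1 = mk_pv(c(0, 50, 100, 150), c(0, 200))))
  expect_equal(length(res$records), 0L)
  expect_match(res$exclusions$reason, "donor count != 1")

  # donor at 30 s, acceptor at 75 s -> t0 = 75 (later-arrival rule)
  res2 <- select_two_hexamer_records(ts, list(
    r1 = mk_pv(c(30, 250), c(75, 250))))
  expect_equal(length(res2$records), 1L)
  expect_equal(res2$records[[1]]$t0, 75)
  expect_true(all(res2$records[[1]]$time >= 0))

  # non-overlapping intervals -> excluded
  res3 <- select_two_hexamer_records(ts, list(
    r1 = mk_pv(c(0, 40), c(50, 90))))
  expect_match(res3$exclusions$reason, "no overlap")
})

test_that("selection recovers >= 95% of qualifying simulated records", {
  cfg <- simulation_config(wt_scheme(),
                           emission_config(total_intensity = 200,
                                           noise_sd = 20),
                           n_records = 100, max_duration = 600, rng_seed = 13)
  d <- simulate_dataset(cfg)
  res <- preprocess_traces(d$traces)
  got <- vapply(res$records, function(r) r$record_id, "")
  dt <- cfg$emission$frame_interval
  qualifying <- vapply(d$truth$records, function(r) {
    # co-residence long enough to be detectable (>= min_dwell on each side)
    r$t_end_signal - r$t0 > 6 * dt &&
      r$t0 - min(r$arrival_donor, r$arrival_acceptor) > -Inf &&
      min(r$arrival_donor, r$arrival_acceptor) > 3 * dt
  }, TRUE)
  ids_q <- vapply(d$truth$records, function(r) r$record_id, "")[qualifying]
  expect_gt(length(ids_q), 40)
  expect_gte(mean(ids_q %in% got), 0.95)
})

test_that("outlier policy masks frames and drops low-SNR records", {
  r_ok <- make_record(c(rep(0.5, 20), 0.9, -0.3, rep(0.6, 8)))
  r_bad <- make_record(c(rep(0.9, 11), rep(0.5, 20)))
  res <- apply_outlier_policy(list(r_ok, r_bad))
  expect_equal(length(res$records), 1L)
  expect_equal(res$records[[1]]$record_id, "r1")
  expect_equal(res$records[[1]]$n_outliers, 2L)
  expect_true(all(res$records[[1]]$mask[21:22]))
  expect_false(any(res$records[[1]]$mask[1:20]))
  expect_equal(res$report$dropped, c(FALSE, TRUE))
  # boundary: exactly at the limits is kept
  r_edge <- make_record(c(-0.25, 0.85, 0.5))
  expect_equal(apply_outlier_policy(list(r_edge))$records[[1]]$n_outliers, 0L)
})

test_that("injected outlier fraction is recovered within its binomial CI", {
  set.seed(42)
  p_out <- 0.035
  recs <- lapply(1:300, function(i) {
    n <- 40
    y <- rnorm(n, 0.5, 0.05)
    out <- runif(n) < p_out
    y[out] <- 1.5
    make_record(y, id = paste0("r", i))
  })
  res <- apply_outlier_policy(recs, max_outliers = Inf)
  n_tot <- sum(res$report$n_frames)
  n_out <- sum(res$report$n_outliers)
  ci <- binom.test(n_out, n_tot, conf.level = 0.99)$conf.int
  expect_true(p_out >= ci[1] && p_out <= ci[2])
})

test_that("noiseless pipeline returns exact state levels and is idempotent", {
  cfg <- simulation_config(wt_scheme(),
                           emission_config(noise_sd = 0, baseline_offset = 20),
                           n_records = 8, max_duration = 400, rng_seed = 3)
  d <- simulate_dataset(cfg)
  res <- preprocess_traces(d$traces)
  expect_gt(length(res$records), 0)
  truth_by_id <- setNames(d$truth$records,
                          vapply(d$truth$records, function(r) r$record_id, ""))
  for (r in res$records) {
    tru <- truth_by_id[[r$record_id]]
    t_abs <- r$t0 + r$time
    # frames strictly inside the true co-residence window must reproduce the
    # generating state level exactly; channel interleaving may shift the
    # detected window boundaries by up to one frame
    inside <- t_abs >= tru$t0 & t_abs < tru$t_end_signal & !r$mask
    expect_gt(sum(inside), 0)
    idx <- findInterval(t_abs[inside] - tru$t0, tru$jump_times)
    lev <- cfg$emission$efret_levels[tru$jump_states[idx]]
    expect_equal(r$efret[inside], lev, tolerance = 1e-9)
    expect_lt(abs(length(r$efret) - length(tru$path)), 3)
  }

  # idempotence: running preprocessing on already-corrected traces changes
  # nothing (baseline is already ~0, presence intervals unchanged)
  ids <- vapply(res$records, function(r) r$record_id, "")
  res2 <- preprocess_traces(d$traces)
  ids2 <- vapply(res2$records, function(r) r$record_id, "")
  expect_identical(ids, ids2)
})
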
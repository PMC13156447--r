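# Time-normalized Monte Carlo benchmark machinery.

test_that("time-normalization arithmetic: variance tracks BW and 1/NSA,
           and over-long averages are rejected", {
  mp <- list(bw = 500, t_acq = 200, ns = 10)
  m1 <- scale_noise_for_time(mp, 600)
  expect_equal(m1$nsa, 3)
  m2 <- scale_noise_for_time(mp, 1200)        # doubling NSA halves variance
  expect_equal(m2$multiplier, m1$multiplier / 2)
  mp2 <- mp; mp2$bw <- 1000                   # doubling BW doubles variance
  expect_equal(scale_noise_for_time(mp2, 600)$multiplier, 2 * m1$multiplier)
  expect_error(scale_noise_for_time(list(bw = 1, t_acq = 700, ns = 1), 600),
               "NSA")
})

test_that("protocol-table multipliers are reported for all three methods", {
  pr <- benchmark_protocols()
  ms <- sapply(pr, function(p) scale_noise_for_time(p, 600)$multiplier)
  expect_true(all(is.finite(ms)) && all(ms > 0))
  ## PBD noise variance sits below EPI's (lower BW) at equal coverage
  expect_lt(ms[["pbd"]], ms[["epi"]])
})

test_that("EPI estimator: asymptotically unbiased, Rician-floor negative
           median bias at low SNR, averaging helps the 3-direction mean", {
  cfg <- noise_sim_config(n_reps = 6000, seed = 2)
  hi <- simulate_epi_adc(c(1300, 120), snr = 500, cfg, n_dir = 1, seed = 3)
  expect_lt(abs(hi$bias_median_pct), 1)
  lo <- simulate_epi_adc(c(1300, 120), snr = 3, cfg, n_dir = 1, seed = 4)
  expect_lt(lo$bias_median_pct, -10)
  m1 <- simulate_epi_adc(c(1300, 120), snr = 5, cfg, n_dir = 1, seed = 5)
  m3 <- simulate_epi_adc(c(1300, 120), snr = 5, cfg, n_dir = 3, seed = 5)
  expect_lt(abs(m3$bias_mean_pct), abs(m1$bias_mean_pct))
})

test_that("spin-echo T2 estimator: near-noiseless recovery and SD falling
           with SNR", {
  cfg <- noise_sim_config(n_reps = 3000, seed = 6)
  nl <- simulate_sese_t2(c(1300, 120), snr = 1e5, cfg, seed = 7)
  expect_lt(abs(nl$bias_median_pct), 0.1)
  sds <- sapply(c(5, 10, 20, 40), function(s)
    simulate_sese_t2(c(1300, 120), snr = s, cfg, seed = 8)$sd)
  expect_true(all(diff(sds) < 0))
})

test_that("PBD estimator: near-noiseless recovery of both parameters and
           robust median at moderate SNR", {
  cfg <- noise_sim_config(n_reps = 2000, seed = 9)
  lk <- std_lookup()
  nl <- simulate_pbd_estimates(c(1300, 120), snr = 1e6, cfg, lookup = lk,
                               seed = 10)
  expect_lt(abs(nl$adc$bias_median_pct), 0.1)
  expect_lt(abs(nl$t2$bias_median_pct), 0.1)
  md <- simulate_pbd_estimates(c(1300, 120), snr = 10, cfg, lookup = lk,
                               seed = 11)
  expect_lt(abs(md$adc$bias_median_pct), 5)
})

test_that("seeded determinism: identical config and seed give identical
           tables; Monte Carlo error shrinks with replicates", {
  cfg <- noise_sim_config(truths = rbind(c(1300, 120)), snr_grid = c(5, 20),
                          n_reps = 1500, seed = 123)
  t1 <- compare_methods(cfg, methods = c("epi1", "pbd"))
  t2 <- compare_methods(cfg, methods = c("epi1", "pbd"))
  expect_identical(t1, t2)
  ## split-half agreement at the 1/sqrt(n) scale
  cfa <- noise_sim_config(truths = rbind(c(1300, 120)), snr_grid = 20,
                          n_reps = 4000, seed = 201)
  cfb <- noise_sim_config(truths = rbind(c(1300, 120)), snr_grid = 20,
                          n_reps = 4000, seed = 202)
  sa <- simulate_epi_adc(c(1300, 120), 20, cfa, seed = 203)
  sb <- simulate_epi_adc(c(1300, 120), 20, cfb, seed = 204)
  se <- sa$sd / sqrt(4000)
  expect_lt(abs(sa$mean - sb$mean), 5 * se * sqrt(2))
})
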
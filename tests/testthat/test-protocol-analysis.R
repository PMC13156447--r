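# Effective b-value, B1+ bias and CRLB behavior.

test_that("effective b-value vanishes at zero crusher moment and grows
           monotonically with moment", {
  sq0 <- sequence_params(TR = 10.9, moment_pi = 1e-4)
  expect_lt(effective_bvalue(sq0)$b_hat, 1)
  bs <- sapply(c(2, 6, 10, 14), function(np)
    effective_bvalue(sequence_params(TR = 10.9, moment_pi = np))$b_hat)
  expect_true(all(diff(bs) > 0))
  expect_true(all(bs >= 0))
})

test_that("effective b-value fit is deterministic and tight", {
  b1 <- effective_bvalue(std_seq_high())
  b2 <- effective_bvalue(std_seq_high())
  expect_identical(b1$b_hat, b2$b_hat)
  expect_lt(b1$rmse / b1$s0_hat, 0.05)
})

test_that("B1+ bias carries the expected signs: ADC over- then
           underestimated around nominal, T2 underestimated at both ends", {
  tb <- b1_bias_curves(c(0.7, 0.8, 1.0, 1.2, 1.3), std_seq_low(),
                       std_seq_high(), lookup = std_lookup())
  expect_true(all(tb$fit_ok))
  expect_lt(max(abs(tb$adc_bias_pct[tb$b1 == 1])), 0.1)   # matched model
  expect_lt(max(abs(tb$t2_bias_pct[tb$b1 == 1])), 0.1)
  expect_gt(tb$adc_bias_pct[tb$b1 == 0.8], 0)
  expect_lt(tb$adc_bias_pct[tb$b1 == 1.2], 0)
  expect_lt(tb$t2_bias_pct[tb$b1 == 0.7], 0)
  expect_lt(tb$t2_bias_pct[tb$b1 == 1.3], 0)
})

test_that("CRLB scales exactly as 1/SNR and the Jacobian differences are
           converged", {
  c10 <- crlb_config(snr_ref = 10)
  c20 <- crlb_config(snr_ref = 20)
  p10 <- crlb_point(c10, 20, 14); p20 <- crlb_point(c20, 20, 14)
  expect_equal(p10$sd_adc_amp / p20$sd_adc_amp, 2, tolerance = 1e-12)
  expect_equal(p10$sd_t2_eq / p20$sd_t2_eq, 2, tolerance = 1e-12)
  ph <- crlb_point(crlb_config(fd_frac = 0.01), 20, 14)
  pf <- crlb_point(crlb_config(fd_frac = 0.005), 20, 14)
  expect_lt(abs(ph$sd_adc_amp - pf$sd_adc_amp) / pf$sd_adc_amp, 1e-3)
})

test_that("amplification ratio separates amplitude- from
           conditioning-limited regimes", {
  cfg <- crlb_config()
  hi <- crlb_point(cfg, 20, 14)
  lo <- crlb_point(cfg, 20, 3)
  expect_gt(hi$r_adc, 1.1)                 # amplitude-limited at high moment
  expect_lt(abs(lo$r_adc - 1), 0.05)       # conditioning-limited at low
  ## T2 precision is conditioning-limited everywhere
  sw <- crlb_sweep(crlb_config(alpha_grid = c(10, 20, 30),
                               moment_grid = c(4, 10, 16)))
  expect_true(all(abs(sw$r_t2 - 1) < 0.05))
  expect_true(any(sw$r_adc > 1.1))
})

test_that("singular design points are flagged, not fatal", {
  ## a high moment equal to the low moment makes the two observables
  ## redundant: the Fisher matrix is singular there
  cfg <- crlb_config(alpha_grid = c(0.001, 20), moment_grid = c(2.0000001, 14))
  sw <- crlb_sweep(cfg)
  expect_equal(nrow(sw), 4L)
  expect_true(all(sw$singular[sw$moment_pi < 3]))
  expect_true(all(is.finite(sw$sd_adc_amp[sw$alpha_deg == 20 &
                                            sw$moment_pi == 14])))
})

test_that("unregularized Monte Carlo fits approach the equal-variance CRLB
           from above at high SNR", {
  lk <- std_lookup()
  cfg <- crlb_config(snr_ref = 50)
  pr <- crlb_point(cfg, 20, 14)
  ph <- std_phases(T2 = 120, D = 1300)
  sdL <- sqrt(1 / (4 * 50^2))
  set.seed(77)
  n <- 4000
  ft <- fit_voxel(ph$phi_L + sdL * rnorm(n), ph$phi_H + sdL * rnorm(n), lk)
  eff_adc <- stats::sd(ft$adc) / pr$sd_adc_eq
  eff_t2 <- stats::sd(ft$t2) / pr$sd_t2_eq
  expect_gt(eff_adc, 0.9); expect_lt(eff_adc, 1.25)
  expect_gt(eff_t2, 0.9); expect_lt(eff_t2, 1.25)
})
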
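# Closed-form signal model: relaxation factors, transfer matrices,
# recursion, steady-state signal and its verified qualitative behavior.

test_that("relaxation factors reduce correctly in the no-diffusion and
           zero-time limits", {
  sq <- sequence_params(TR = 12, grad_amplitude = 5, grad_duration = 10)
  ts <- tissue_params(T2 = 100, T1 = 1000, D = 0)
  rf <- relaxation_factors(ts, sq, l = -3:3)
  expect_equal(rf$X, rep(exp(-0.1), 7))        # l-independent at D = 0
  expect_equal(rf$Y, rep(exp(-0.01), 7))
  sq0 <- sequence_params(TR = 12, grad_amplitude = 5, grad_duration = 1e-9)
  rf0 <- relaxation_factors(tissue_params(D = 2000), sq0, l = -2:2)
  expect_equal(rf0$X, rep(1, 5), tolerance = 1e-6)
  expect_equal(rf0$Y, rep(1, 5), tolerance = 1e-6)
})

test_that("relaxation factors match an independently coded exponent table", {
  ## choose G so that kap = D gamma^2 G^2 t^3 = 0.01 exactly
  D <- 1000; t_ms <- 10; T2 <- 100; T1 <- 1000
  G <- sqrt(0.01 / ((D * 1e-12) * pbd_gamma^2 * (t_ms * 1e-3)^3))
  sq <- sequence_params(TR = 12, grad_amplitude = G, grad_duration = t_ms)
  ts <- tissue_params(D = D, T2 = T2, T1 = T1)
  ls <- -2:3
  rf <- relaxation_factors(ts, sq, ls)
  ## independent oracle: exponent table written out term by term
  tabX <- exp(-0.1) * exp(-0.01 * c(4 - 2 + 1 / 3, 1 - 1 + 1 / 3, 1 / 3,
                                    1 + 1 + 1 / 3, 4 + 2 + 1 / 3,
                                    9 + 3 + 1 / 3))
  tabY <- exp(-0.01) * exp(-0.01 * c(4, 1, 0, 1, 4, 9))
  expect_equal(rf$X, tabX, tolerance = 1e-12)
  expect_equal(rf$Y, tabY, tolerance = 1e-12)
  expect_equal(rf$X[4], exp(-0.1) * exp(-0.01 * (1 + 1 + 1 / 3)))
})

test_that("transfer matrix entries match a double-entry transcription", {
  sq <- sequence_params(TR = 10, alpha = 20, theta = 2, moment_pi = 14,
                        grad_duration = 8)
  ts <- tissue_params(T1 = 1000, T2 = 100, D = 1000)
  P <- psi_matrix(ts, sq, 1)
  ## independent transcription via the simplified closed forms
  ##   a = c^2 (E - Y)/Dl, b = s^2 (E + Y)/Dl, cos(a)-2V = (ca E - Y)/Dl
  ## with E = exp(-i theta l)
  a <- 20 * pi / 180; th <- 2 * pi / 180; l <- 1
  kap <- (1000e-12) * (pbd_gamma * sq$grad_amplitude)^2 * 0.008^3
  X <- function(j) exp(-0.008 / 0.1) * exp(-kap * (j^2 + j + 1 / 3))
  Y <- exp(-0.008 / 1) * exp(-kap * l^2)
  E <- exp(-1i * th * l)
  Dl <- E - Y * cos(a)
  av <- cos(a / 2)^2 * (E - Y) / Dl
  bv <- sin(a / 2)^2 * (E + Y) / Dl
  Pref <- matrix(c(Conj(E) * X(l) * (cos(a) * E - Y) / (Dl * av), -bv / av,
                   X(l) * bv / (X(-l) * av), E / (X(-l) * av)), 2, 2)
  expect_equal(P, Pref, tolerance = 1e-12)
})

test_that("transfer matrix is order-independent when theta = 0 and D = 0", {
  sq <- sequence_params(TR = 10, alpha = 20, theta = 0, grad_amplitude = 5)
  ts <- tissue_params(D = 0)
  expect_equal(psi_matrix(ts, sq, 1), psi_matrix(ts, sq, 2))
})

test_that("singular flip angle is rejected", {
  sq <- sequence_params(TR = 10, alpha = 179.9999999999, theta = 2,
                        grad_amplitude = 5)
  sq$alpha <- 180            # bypass constructor to hit the model guard
  expect_error(psi_matrix(tissue_params(), sq, 1), "singular")
  expect_error(steady_state_signal(tissue_params(), sq), "singular")
})

test_that("recursion product reduces to a single factor at L = 1 and is
           degenerate at alpha = 0", {
  sq <- sequence_params(TR = 10, alpha = 20, theta = 2, moment_pi = 14, L = 1)
  ts <- std_tissue()
  rec <- configuration_recursion(ts, sq)
  expect_equal(rec$omega, psi_matrix(ts, sq, 1))
  sq0 <- sequence_params(TR = 10, alpha = 0, theta = 2, moment_pi = 14)
  expect_error(configuration_recursion(ts, sq0), "degenerate")
})

test_that("truncation error at L = 32 is negligible over the operating box
           and falls monotonically with L", {
  ## diffusion damping makes the closure converge almost immediately;
  ## the slow corner is D = 0 with long T2
  for (T2 in c(80, 300)) for (D in c(0, 2000)) {
    ts <- tissue_params(T2 = T2, D = D, T1 = 1000)
    s32 <- steady_state_signal(ts, std_seq_high(L = 32))
    s96 <- steady_state_signal(ts, std_seq_high(L = 96))
    expect_lt(Mod(s32 - s96) / Mod(s96), 1e-4)
  }
  ts <- tissue_params(T2 = 80, D = 2000, T1 = 1000)
  expect_lt(Mod(steady_state_signal(ts, std_seq_high(L = 16)) -
                  steady_state_signal(ts, std_seq_high(L = 48))) /
              Mod(steady_state_signal(ts, std_seq_high(L = 48))), 1e-8)
  ts <- tissue_params(T2 = 300, D = 0, T1 = 1000)
  ref <- steady_state_signal(ts, std_seq_high(L = 96))
  errs <- sapply(c(8, 16, 24, 32),
                 function(L) Mod(steady_state_signal(ts, std_seq_high(L = L)) - ref))
  expect_true(all(diff(errs) < 0))
})

test_that("steady-state signal limits: no excitation, conjugate symmetry", {
  sq <- std_seq_high(L = 32)
  expect_equal(steady_state_signal(std_tissue(),
                                   sequence_params(TR = 10.9, alpha = 0,
                                                   theta = 2, moment_pi = 14)),
               0 + 0i)
  ## S(-theta) = conj(S(+theta)) for randomized parameter sets
  set.seed(11)
  for (i in 1:20) {
    ts <- tissue_params(T1 = runif(1, 700, 1300), T2 = runif(1, 40, 300),
                        D = runif(1, 0, 2500), M0 = runif(1, 0.5, 2))
    sq1 <- sequence_params(TR = 10.9, alpha = runif(1, 5, 40),
                           theta = runif(1, 0.5, 6),
                           moment_pi = runif(1, 0, 16), L = 16)
    sq2 <- sq1; sq2$theta <- -sq1$theta
    expect_equal(steady_state_signal(ts, sq2),
                 Conj(steady_state_signal(ts, sq1)), tolerance = 1e-13)
  }
})

test_that("phase is monotone increasing in T2 and decreasing in ADC at the
           high moment, with ADC sensitivity concentrated at high moment", {
  t2s <- seq(50, 300, by = 25)
  ds <- seq(0, 2000, by = 200)
  for (th in c(1, 2, 4)) for (al in c(10, 20, 40)) {
    sq <- sequence_params(TR = 10.9, alpha = al, theta = th, moment_pi = 14,
                          L = 32)
    pt <- Arg(steady_state_signal(
      tissue_params(T2 = t2s, D = 1300, T1 = 1000, allow_t2_gt_t1 = TRUE), sq))
    expect_true(all(diff(pt) > 0))
    pd <- Arg(steady_state_signal(
      tissue_params(T2 = 120, D = ds, T1 = 1000), sq))
    expect_true(all(diff(pd) < 0))
  }
  ## ADC moves the phase far more at the high moment than at the low moment
  ran <- function(sq) diff(range(Arg(steady_state_signal(
    tissue_params(T2 = 120, D = ds, T1 = 1000), sq))))
  expect_gt(ran(std_seq_high(L = 32)) / ran(std_seq_low(L = 32)), 10)
})

test_that("phase is insensitive to T1 relative to its T2-induced range", {
  sq <- std_seq_high(L = 32)
  p_t1 <- sapply(c(700, 1000, 1300), function(T1)
    Arg(steady_state_signal(tissue_params(T1 = T1, T2 = 120, D = 1300), sq)))
  t2_range <- diff(range(Arg(steady_state_signal(
    tissue_params(T2 = seq(50, 300, 25), D = 1300, T1 = 1000,
                  allow_t2_gt_t1 = TRUE), sq))))
  expect_lt(diff(range(p_t1)), 0.25 * t2_range)
})

test_that("phase response grid is finite, wrap-free, and reduces to
           signal_phase for a single point", {
  sq <- sequence_params(TR = 10, alpha = 20, theta = 2, moment_pi = 14, L = 16)
  g <- phase_response_grid(sq, T2 = seq(50, 300, 50), D = seq(0, 2000, 500),
                           T1 = c(700, 1300), alpha = c(10, 20),
                           theta = c(1, 2))
  expect_true(all(is.finite(g$phase_rad)))
  expect_true(all(g$phase_rad > 0 & g$phase_rad < pi / 2))
  g1 <- phase_response_grid(sq, T2 = 120, D = 1300, T1 = 1000)
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$phase_rad,
               as.numeric(signal_phase(std_tissue(),
                                       sequence_params(TR = 10, alpha = 20,
                                                       theta = 2,
                                                       moment_pi = 14,
                                                       L = 16))))
  ## low-moment grid: strong T2 dependence, weak ADC dependence
  glo <- phase_response_grid(std_seq_low(L = 16), T2 = seq(50, 300, 50),
                             D = seq(0, 2000, 500))
  byT2 <- tapply(glo$phase_rad, glo$T2_ms, mean)
  byD <- tapply(glo$phase_rad, glo$D_um2_per_s, mean)
  expect_gt(diff(range(byT2)), 10 * diff(range(byD)))
})

test_that("complex-component analysis: encoded quadrature carries the
           sensitivity; phase difference monotone in ADC and T2", {
  cc <- complex_component_analysis(std_seq_low(L = 32), std_seq_high(L = 32),
                                   D = seq(0, 2000, 250),
                                   T2 = seq(50, 300, 50))
  ## identical moments: all ratios 1, phase difference 0
  cc0 <- complex_component_analysis(std_seq_low(L = 32), {
    s <- std_seq_low(L = 32); s$grad_amplitude <- s$grad_amplitude * (1 + 1e-12); s
  }, D = c(0, 1000), T2 = c(80, 120))
  expect_equal(cc0$mag_ratio, rep(1, 4), tolerance = 1e-6)
  expect_equal(cc0$phase_diff_rad, rep(0, 4), tolerance = 1e-6)
  ## encoding-frame real ratio has much larger dynamic range than imaginary
  expect_gt(diff(range(cc$real_ratio)), 2 * diff(range(cc$imag_ratio)))
  ## phase difference increases monotonically with ADC and with T2
  for (t2 in unique(cc$T2_ms)) {
    sub <- cc[cc$T2_ms == t2, ]
    expect_true(all(diff(sub$phase_diff_rad[order(sub$D_um2_per_s)]) > 0))
  }
  for (d in unique(cc$D_um2_per_s[cc$D_um2_per_s > 0])) {
    sub <- cc[cc$D_um2_per_s == d, ]
    expect_true(all(diff(sub$phase_diff_rad[order(sub$T2_ms)]) > 0))
  }
})
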
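# Background-phase cancellation and the regularized inversion.

test_that("background phase of arbitrary smooth structure cancels exactly", {
  set.seed(21)
  for (rep in 1:5) {
    d <- c(12, 10, 3)
    xs <- seq(-1, 1, length.out = d[1])
    ys <- seq(-1, 1, length.out = d[2])
    zs <- seq(-1, 1, length.out = d[3])
    Del <- outer(outer(rnorm(1) * xs + rnorm(1) * xs^2, rnorm(1) * ys + 1, "+"),
                 rnorm(1) * zs, "+") * runif(1, 0.5, 3)
    phi <- array(runif(prod(d), 0, pi / 2 - 0.1), d)
    Ip <- array(exp(complex(imaginary = Del + phi)), d)
    Im <- array(exp(complex(imaginary = Del - phi)), d)
    out <- remove_background_phase(Ip, Im)
    expect_equal(out$phi, phi, tolerance = 1e-12)
    expect_true(all(out$mask))
  }
})

test_that("zero encoded phase returns a zero volume and dead voxels are
           masked rather than NaN", {
  d <- c(6, 6, 2)
  Del <- array(runif(prod(d), -pi, pi), d)
  Ip <- array(exp(complex(imaginary = Del)), d); Im <- Ip
  Ip[1, 1, 1] <- 0; Im[1, 1, 1] <- 0
  out <- remove_background_phase(Ip, Im)
  expect_false(out$mask[1, 1, 1])
  expect_true(all(out$phi == 0))
  expect_false(any(is.nan(out$phi)))
  expect_error(remove_background_phase(array(Ip, d), array(Im, c(6, 6, 1))),
               "congruent")
})

test_that("noiseless phases are inverted to the generating parameters
           (inverse crime), including the stated truth triplets", {
  lk <- std_lookup()
  truths <- rbind(c(800, 100), c(1300, 120), c(1800, 200),
                  c(300, 40), c(2100, 250))
  ph <- std_phases(T2 = truths[, 2], D = truths[, 1])
  ft <- fit_voxel(ph$phi_L, ph$phi_H, lk)
  expect_equal(ft$adc, truths[, 1], tolerance = 1e-3)
  expect_equal(ft$t2, truths[, 2], tolerance = 1e-3)
  expect_true(all(ft$residual < 1e-10))
})

test_that("a phase pair taken at a lookup node is recovered exactly", {
  lk <- std_lookup()
  ev <- lookup_eval(lk, 1500, 150)
  ft <- fit_voxel(ev$fL$value, ev$fH$value, lk)
  expect_equal(ft$adc, 1500, tolerance = 1e-6)
  expect_equal(ft$t2, 150, tolerance = 1e-6)
})

test_that("fit_maps with no regularization on a single voxel reproduces
           fit_voxel", {
  lk <- std_lookup()
  ph <- std_phases(T2 = 73, D = 1234)
  cfg <- recon_config(lambda_tv = 0, beta_l2 = 0, max_iter = 300,
                      rel_tol = 1e-10)
  mp <- fit_maps(phase_pair(array(ph$phi_L, c(1, 1, 1)),
                            array(ph$phi_H, c(1, 1, 1))), cfg, lookup = lk)
  ft <- fit_voxel(ph$phi_L, ph$phi_H, lk, max_iter = 300, rel_tol = 1e-10)
  expect_equal(as.numeric(mp$adc), ft$adc, tolerance = 1e-10)
  expect_equal(as.numeric(mp$t2), ft$t2, tolerance = 1e-10)
})

test_that("objective decreases overall and the trace respects the
           safeguard", {
  lk <- std_lookup()
  set.seed(9)
  d <- c(8, 8, 2)
  ph <- std_phases(T2 = runif(prod(d), 60, 250), D = runif(prod(d), 200, 2000))
  pair <- phase_pair(array(ph$phi_L + rnorm(prod(d), 0, 0.02), d),
                     array(ph$phi_H + rnorm(prod(d), 0, 0.02), d))
  mp <- fit_maps(pair, recon_config(max_iter = 300), lookup = lk)
  tr <- mp$objective_trace
  expect_lt(tr[length(tr)], tr[1])
  expect_true(mp$converged)
})

test_that("TV weight monotonically suppresses spatial variance on a
           constant-truth noisy volume", {
  lk <- std_lookup()
  set.seed(10)
  d <- c(10, 10, 2)
  ph <- std_phases(T2 = 120, D = 1300)
  pair <- phase_pair(array(ph$phi_L + rnorm(prod(d), 0, 0.03), d),
                     array(ph$phi_H + rnorm(prod(d), 0, 0.03), d))
  vs <- sapply(c(0, 1e-4, 1e-3, 1e-2), function(lam) {
    mp <- fit_maps(pair, recon_config(lambda_tv = lam, beta_l2 = 0,
                                      max_iter = 600), lookup = lk)
    stats::var(as.vector(mp$adc))
  })
  expect_true(all(diff(vs) < 0))
})

test_that("maps from a forward-acquired phantom with random backgrounds
           recover the truth (end-to-end, noiseless)", {
  spec <- phantom_spec(dim = c(32, 32, 4), seed = 3)
  tr <- make_phantom(spec)
  acq <- forward_acquire(tr, std_seq_low(), std_seq_high(), seed = 13)
  pair <- extract_phase_pair(acq)
  ## recovered high-moment phase equals the model phase where masked
  ph <- std_phases(T2 = tr$t2[pair$mask], D = tr$adc[pair$mask])
  expect_lt(max(abs(pair$phi_H[pair$mask] - ph$phi_H)), 1e-6)
  mp <- fit_maps(pair, recon_config(max_iter = 600), lookup = std_lookup())
  rs <- roi_summary(mp, tr)
  expect_lt(max(abs(rs$adc_err_pct)), 1)
  expect_lt(max(abs(rs$t2_err_pct)), 1)
})
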
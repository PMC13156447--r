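# Time-normalized Monte Carlo comparison of PBD against the reference
# estimators: single-shot EPI log-ratio ADC and single/multi-echo spin-echo
# T2 fitting.  All methods run at matched voxel size and a fixed total
# acquisition-time budget; per-method noise variance scales with receiver
# bandwidth, 1/NSA (number of whole averages fitting the budget) and
# 1/Ns (number of slice positions encoded per volume -- equal scan time per
# covered volume; see the methods vignette for this arithmetic).
#
# "Effective SNR" is the reference method's first image magnitude (b = 0
# for EPI, first echo for the spin echo) divided by its per-channel
# Gaussian noise SD after time normalization; other methods' noise levels
# follow from the variance-scaling rule.

#' Per-method protocol description for the noise benchmark
#'
#' Defaults transcribe the in vivo protocol table: EPI (TR 4500 ms, TE 60
#' ms, b 1500 s/mm2, BW 1953 Hz/px, 22 slices, 4:48), multi-echo spin echo
#' (TR 1200 ms, TE 8.5-68 ms, BW 488 Hz/px, 32 slices, 3:25), PBD (TR 10.9
#' ms, TE 2.9 ms, flip 20 deg, theta +/-2 deg, moments 2/14 pi, BW 325
#' Hz/px, 32 slice encodes, 4:45).  `ns` is the number of slice positions
#' encoded per volume, giving each method equal scan time per covered
#' volume in the normalization.
#'
#' @return Named list of method parameter lists.
#' @export
benchmark_protocols <- function() {
  list(
    epi = list(tr = 4500, te = 60, b = 1500, bw = 1953, t_acq = 288, ns = 22),
    sese = list(tr = 1200, te = seq(8.5, 68, by = 8.5), bw = 488,
                t_acq = 205, ns = 32),
    pbd = list(tr = 10.9, te = 2.9, alpha = 20, theta = 2,
               moment_pi = c(2, 14), ref_length = 1.125,
               bw = 325, t_acq = 285, ns = 32)
  )
}

#' Noise-simulation configuration
#'
#' @param truths matrix (or data frame) of ground-truth rows
#'   `(adc um^2/s, t2 ms)`; defaults to the three prostate-representative
#'   pairs (800, 100), (1300, 120), (1800, 200).
#' @param snr_grid effective SNR levels of the reference method.
#' @param n_reps Monte Carlo replicates per condition (default 10000).
#' @param total_time_s total acquisition-time budget, s (default 600).
#' @param protocols per-method parameters, see [benchmark_protocols()].
#' @param T1 fixed T1 for all methods, ms.
#' @param seed RNG seed (mandatory).
#' @return Object of class `pbd_noise_config`.
#' @export
noise_sim_config <- function(truths = rbind(c(800, 100), c(1300, 120),
                                            c(1800, 200)),
                             snr_grid = c(3, 5, 7, 10, 15, 20, 30, 50),
                             n_reps = 10000, total_time_s = 600,
                             protocols = benchmark_protocols(),
                             T1 = 1000, seed = 1) {
  truths <- as.matrix(truths)
  stopifnot(ncol(truths) == 2, n_reps >= 100, all(snr_grid > 0))
  colnames(truths) <- c("adc", "t2")
  structure(list(truths = truths, snr_grid = snr_grid, n_reps = n_reps,
                 total_time_s = total_time_s, protocols = protocols,
                 T1 = T1, seed = as.integer(seed)),
            class = "pbd_noise_config")
}

#' Time-normalization noise multiplier for one method
#'
#' Variance multiplier proportional to `BW / (NSA * Ns)` with
#' `NSA = total_time / single-average time` and Ns the per-volume slice
#' count.  Only ratios between methods are meaningful.
#'
#' @param method_params one element of [benchmark_protocols()].
#' @param total_time_s time budget, s.
#' @return List with `nsa` and `multiplier`.
#' @export
scale_noise_for_time <- function(method_params, total_time_s) {
  nsa <- total_time_s / method_params$t_acq
  if (nsa < 1)
    stop("scale_noise_for_time: budget shorter than one average (NSA < 1)")
  list(nsa = nsa, multiplier = method_params$bw / (nsa * method_params$ns))
}

# per-channel noise SD for method `m` given the reference method's sigma
.sigma_rel <- function(cfg, m, ref, sigma_ref) {
  mult_m <- scale_noise_for_time(cfg$protocols[[m]], cfg$total_time_s)$multiplier
  mult_r <- scale_noise_for_time(cfg$protocols[[ref]], cfg$total_time_s)$multiplier
  sigma_ref * sqrt(mult_m / mult_r)
}

.estimator_stats <- function(est, truth, n_fail = 0L) {
  est <- est[is.finite(est)]
  list(mean = mean(est), median = stats::median(est), sd = stats::sd(est),
       bias_mean_pct = 100 * (mean(est) - truth) / truth,
       bias_median_pct = 100 * (stats::median(est) - truth) / truth,
       n_used = length(est), n_failed = n_fail)
}

# spin-echo baseline amplitude (unit M0)
.se_amp <- function(tr, te, T1, t2) (1 - exp(-tr / T1)) * exp(-te / t2)

#' Monte Carlo EPI ADC estimation
#'
#' Magnitude (Rician) signals at b = 0 and b = bH from the spin-echo model,
#' log-ratio ADC estimate; `n_dir = 3` averages the three directional
#' acquisitions (identical true signal under isotropic diffusion) before
#' the magnitude, which is what lets averaging reduce the Rician floor.
#'
#' @param truth `c(adc, t2)` ground truth (um^2/s, ms).
#' @param snr effective SNR of the b = 0 image.
#' @param cfg a [noise_sim_config()] object.
#' @param n_dir 1 or 3 diffusion directions.
#' @param seed RNG seed for this condition.
#' @return Estimator statistics list (mean, median, sd, biases, tallies).
#' @export
simulate_epi_adc <- function(truth, snr, cfg, n_dir = 1, seed = 1) {
  set.seed(seed)
  p <- cfg$protocols$epi
  S0 <- .se_amp(p$tr, p$te, cfg$T1, truth[2])
  Sb <- S0 * exp(-p$b * truth[1] * 1e-6)
  sg <- S0 / snr
  n <- cfg$n_reps
  m0 <- Mod(complex(real = S0 + sg * stats::rnorm(n),
                    imaginary = sg * stats::rnorm(n)))
  mb <- 0i
  for (d in seq_len(n_dir))
    mb <- mb + complex(real = Sb + sg * stats::rnorm(n),
                       imaginary = sg * stats::rnorm(n))
  mb <- Mod(mb / n_dir)
  ratio <- mb / m0
  ok <- ratio > 0 & is.finite(ratio)
  est <- -log(ratio[ok]) / p$b * 1e6       # um^2/s
  .estimator_stats(est, truth[1], n_fail = sum(!ok))
}

#' Monte Carlo multi-echo spin-echo T2 estimation
#'
#' Rician magnitudes along the echo train, nonlinear least-squares fit of
#' `S0 exp(-TE/T2)` (vectorized Gauss-Newton across replicates).
#'
#' @inheritParams simulate_epi_adc
#' @return Estimator statistics list.
#' @export
simulate_sese_t2 <- function(truth, snr, cfg, seed = 1) {
  set.seed(seed)
  p <- cfg$protocols$sese
  S0 <- 1 - exp(-p$tr / cfg$T1)
  sig1 <- S0 * exp(-p$te[1] / truth[2])
  sg <- sig1 / snr
  n <- cfg$n_reps; ne <- length(p$te)
  y <- matrix(0, n, ne)
  for (k in seq_len(ne)) {
    s <- S0 * exp(-p$te[k] / truth[2])
    y[, k] <- Mod(complex(real = s + sg * stats::rnorm(n),
                          imaginary = sg * stats::rnorm(n)))
  }
  ## init from the log-ratio of early/late echoes
  k2 <- max(4L, ne %/% 2L)
  t2 <- (p$te[k2] - p$te[1]) / log(pmax(y[, 1], 1e-12) / pmax(y[, k2], 1e-12))
  t2 <- pmin(pmax(ifelse(is.finite(t2) & t2 > 0, t2, truth[2]), 2), 2000)
  s0 <- y[, 1] * exp(p$te[1] / t2)
  for (it in 1:30) {                       # Gauss-Newton, all reps at once
    a11 <- a12 <- a22 <- b1 <- b2 <- numeric(n)
    for (k in seq_len(ne)) {
      e <- exp(-p$te[k] / t2)
      r <- y[, k] - s0 * e
      J1 <- e
      J2 <- s0 * e * p$te[k] / t2^2
      a11 <- a11 + J1 * J1; a12 <- a12 + J1 * J2; a22 <- a22 + J2 * J2
      b1 <- b1 + J1 * r; b2 <- b2 + J2 * r
    }
    det <- a11 * a22 - a12 * a12
    det[abs(det) < 1e-300] <- NA
    d1 <- (a22 * b1 - a12 * b2) / det
    d2 <- (a11 * b2 - a12 * b1) / det
    s0 <- s0 + ifelse(is.finite(d1), d1, 0)
    t2 <- pmin(pmax(t2 + ifelse(is.finite(d2), d2, 0), 1), 3000)
    s0 <- pmax(s0, 1e-9)
  }
  ok <- is.finite(t2) & t2 > 1 & t2 < 3000
  .estimator_stats(t2[ok], truth[2], n_fail = sum(!ok))
}

#' Monte Carlo PBD joint ADC/T2 estimation
#'
#' Four complex pass signals from the closed-form model, complex Gaussian
#' noise at the time-normalized level, background-free phase extraction and
#' unregularized [fit_voxel()] inversion.
#'
#' @inheritParams simulate_epi_adc
#' @param reference `"epi"` or `"sese"`: which reference method defines the
#'   effective-SNR axis (and therefore the absolute noise level).
#' @param lookup optional pre-built [build_phase_lookup()] for the PBD
#'   protocol.
#' @return List with estimator statistics for `adc` and `t2`.
#' @export
simulate_pbd_estimates <- function(truth, snr, cfg, reference = "epi",
                                   lookup = NULL, seed = 1) {
  set.seed(seed)
  p <- cfg$protocols$pbd
  sqs <- pbd_benchmark_sequences(cfg)
  if (is.null(lookup)) lookup <- build_phase_lookup(sqs$low, sqs$high)
  ts <- tissue_params(T1 = cfg$T1, T2 = truth[2], D = truth[1],
                      allow_t2_gt_t1 = TRUE)
  SL <- steady_state_signal(ts, sqs$low)
  SH <- steady_state_signal(ts, sqs$high)
  sigma_ref <- if (reference == "epi") {
    .se_amp(cfg$protocols$epi$tr, cfg$protocols$epi$te, cfg$T1, truth[2]) / snr
  } else {
    (1 - exp(-cfg$protocols$sese$tr / cfg$T1)) *
      exp(-cfg$protocols$sese$te[1] / truth[2]) / snr
  }
  sg <- .sigma_rel(cfg, "pbd", reference, sigma_ref)
  n <- cfg$n_reps
  noisy <- function(S) complex(real = Re(S) + sg * stats::rnorm(n),
                               imaginary = Im(S) + sg * stats::rnorm(n))
  phiL <- Arg(noisy(SL) * Conj(noisy(Conj(SL)))) / 2
  phiH <- Arg(noisy(SH) * Conj(noisy(Conj(SH)))) / 2
  ft <- fit_voxel(phiL, phiH, lookup)
  ok <- is.finite(ft$adc) & is.finite(ft$t2)
  list(adc = .estimator_stats(ft$adc[ok], truth[1], sum(!ok)),
       t2 = .estimator_stats(ft$t2[ok], truth[2], sum(!ok)),
       pass_snr = Mod(SL) / (sg * sqrt(2)))
}

#' Sequence pair used by the noise benchmark
#'
#' @param cfg a [noise_sim_config()] object.
#' @return List with `low` and `high` [sequence_params()] objects.
#' @export
pbd_benchmark_sequences <- function(cfg) {
  p <- cfg$protocols$pbd
  list(low = sequence_params(TR = p$tr, TE = p$te, alpha = p$alpha,
                             theta = p$theta, moment_pi = p$moment_pi[1],
                             ref_length = p$ref_length, L = 32),
       high = sequence_params(TR = p$tr, TE = p$te, alpha = p$alpha,
                              theta = p$theta, moment_pi = p$moment_pi[2],
                              ref_length = p$ref_length, L = 32))
}

#' Full time-normalized method comparison
#'
#' Runs the EPI (1- and 3-direction), spin-echo T2 and PBD Monte Carlo
#' simulations over all truths and SNR levels on a shared seed ladder and
#' assembles a long-format results table.
#'
#' @param cfg a [noise_sim_config()] object.
#' @param methods subset of `c("epi1", "epi3", "sese", "pbd")`.
#' @return Data frame with one row per (method, parameter, truth, SNR):
#'   columns `method`, `param`, `truth_adc`, `truth_t2`, `snr`, `mean`,
#'   `median`, `sd`, `bias_mean_pct`, `bias_median_pct`, `n_failed`, and
#'   for PBD ADC rows the ratio `sd_ratio_vs_epi1` where available.
#' @export
compare_methods <- function(cfg, methods = c("epi1", "epi3", "sese", "pbd")) {
  sqs <- pbd_benchmark_sequences(cfg)
  lookup <- if ("pbd" %in% methods) build_phase_lookup(sqs$low, sqs$high)
  rows <- list()
  add <- function(method, param, truth, snr, st)
    rows[[length(rows) + 1]] <<- data.frame(
      method = method, param = param, truth_adc = truth[1],
      truth_t2 = truth[2], snr = snr, mean = st$mean, median = st$median,
      sd = st$sd, bias_mean_pct = st$bias_mean_pct,
      bias_median_pct = st$bias_median_pct, n_failed = st$n_failed)
  for (ti in seq_len(nrow(cfg$truths))) {
    truth <- cfg$truths[ti, ]
    for (si in seq_along(cfg$snr_grid)) {
      snr <- cfg$snr_grid[si]
      sd_cond <- cfg$seed + 1000L * ti + 10L * si  # shared seed ladder
      if ("epi1" %in% methods)
        add("epi1", "adc", truth, snr,
            simulate_epi_adc(truth, snr, cfg, n_dir = 1, seed = sd_cond))
      if ("epi3" %in% methods)
        add("epi3", "adc", truth, snr,
            simulate_epi_adc(truth, snr, cfg, n_dir = 3, seed = sd_cond + 1L))
      if ("sese" %in% methods)
        add("sese", "t2", truth, snr,
            simulate_sese_t2(truth, snr, cfg, seed = sd_cond + 2L))
      if ("pbd" %in% methods) {
        pb <- simulate_pbd_estimates(truth, snr, cfg, reference = "epi",
                                     lookup = lookup, seed = sd_cond + 3L)
        add("pbd", "adc", truth, snr, pb$adc)
        pb2 <- simulate_pbd_estimates(truth, snr, cfg, reference = "sese",
                                      lookup = lookup, seed = sd_cond + 4L)
        add("pbd", "t2", truth, snr, pb2$t2)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (all(c("epi1", "pbd") %in% methods)) {
    key <- function(d) paste(d$truth_adc, d$truth_t2, d$snr)
    epi <- out[out$method == "epi1" & out$param == "adc", ]
    idx <- out$method == "pbd" & out$param == "adc"
    out$sd_ratio_vs_epi1 <- NA_real_
    out$sd_ratio_vs_epi1[idx] <-
      out$sd[idx] / epi$sd[match(key(out[idx, ]), key(epi))]
  }
  out
}
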
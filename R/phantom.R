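# Synthetic digital phantoms: ground-truth ADC/T2/M0/T1 volumes and
# forward-simulated four-pass acquisitions with smooth moment-dependent
# background phase and complex Gaussian noise.
#
# The vial grid emulates a 16-vial physical phantom in which rows of
# increasing polymer (PVP) fraction lower the ADC and columns of
# increasing MnCl2 concentration lower T2.  The default per-vial values
# span 300-2100 um^2/s and 40-250 ms; they are synthetic choices covering
# the model grid, not any published reference values.

#' Phantom specification
#'
#' @param layout `"vial_grid_4x4"` (16 vials, 4 ADC x 4 T2 levels),
#'   `"prostate_geometry"` (background disc with a prostate-mimicking
#'   inclusion and a signal-free air disc), or `"uniform"`.
#' @param dim matrix size, length-3 integer.
#' @param voxel_mm voxel size, mm.
#' @param adc_levels,t2_levels per-row/column truths for the vial grid
#'   (um^2/s, ms): ADC decreasing with PVP fraction, T2 decreasing with
#'   MnCl2 concentration.
#' @param uniform_truth `c(adc, t2)` for the uniform layout.
#' @param prostate_diameter_mm diameter of the prostate-mimicking
#'   inclusion.
#' @param t1 T1 assigned everywhere, ms.
#' @param background list describing the smooth background-phase fields:
#'   `order` (polynomial order) and `amplitude` (max |Delta|, radians).
#' @param noise_sd complex-noise SD per channel for [forward_acquire()]
#'   (relative to M0 = 1).
#' @param seed seed used for background-field coefficients and noise;
#'   mandatory when `noise_sd > 0`.
#' @return Object of class `pbd_phantom_spec`.
#' @export
phantom_spec <- function(layout = c("vial_grid_4x4", "prostate_geometry",
                                    "uniform"),
                         dim = c(64, 64, 8), voxel_mm = c(1.5, 1.5, 4),
                         adc_levels = c(2100, 1500, 900, 300),
                         t2_levels = c(250, 150, 90, 40),
                         uniform_truth = c(adc = 1300, t2 = 120),
                         prostate_diameter_mm = 23,
                         t1 = 1000,
                         background = list(order = 2, amplitude = pi),
                         noise_sd = 0, seed = NULL) {
  layout <- match.arg(layout)
  if (noise_sd > 0 && is.null(seed))
    stop("phantom_spec: a seed is mandatory for noisy output")
  structure(list(layout = layout, dim = as.integer(dim), voxel_mm = voxel_mm,
                 adc_levels = adc_levels, t2_levels = t2_levels,
                 uniform_truth = uniform_truth,
                 prostate_diameter_mm = prostate_diameter_mm, t1 = t1,
                 background = background, noise_sd = noise_sd, seed = seed),
            class = "pbd_phantom_spec")
}

#' Build ground-truth volumes from a phantom specification
#'
#' Deterministic: the same spec always yields the same label and truth
#' volumes.  Vial ROIs are disjoint by construction.
#'
#' @param spec a [phantom_spec()] object.
#' @return Object of class `pbd_ground_truth`: arrays `adc`, `t2`, `m0`,
#'   `t1`, integer label array `roi_labels` (0 = background/air), and the
#'   spec.
#' @export
make_phantom <- function(spec) {
  d <- spec$dim
  adc <- array(0, d); t2 <- array(1, d); m0 <- array(0, d)
  lab <- array(0L, d)
  xi <- (seq_len(d[1]) - 0.5) / d[1]
  yi <- (seq_len(d[2]) - 0.5) / d[2]
  X <- matrix(xi, d[1], d[2]); Y <- matrix(yi, d[1], d[2], byrow = TRUE)
  if (spec$layout == "uniform") {
    adc[] <- spec$uniform_truth[["adc"]]; t2[] <- spec$uniform_truth[["t2"]]
    m0[] <- 1; lab[] <- 1L
  } else if (spec$layout == "vial_grid_4x4") {
    r <- 0.09                              # vial radius, fraction of FOV
    for (i in 1:4) for (j in 1:4) {
      cx <- (2 * i - 1) / 8; cy <- (2 * j - 1) / 8
      disc <- (X - cx)^2 + (Y - cy)^2 < r^2
      if (any(disc & lab[, , 1] != 0L)) stop("make_phantom: overlapping ROIs")
      id <- (i - 1L) * 4L + j
      for (k in seq_len(d[3])) {
        sl <- lab[, , k]; sl[disc] <- id; lab[, , k] <- sl
        sa <- adc[, , k]; sa[disc] <- spec$adc_levels[i]; adc[, , k] <- sa
        st <- t2[, , k]; st[disc] <- spec$t2_levels[j]; t2[, , k] <- st
        sm <- m0[, , k]; sm[disc] <- 1; m0[, , k] <- sm
      }
    }
  } else {                                  # prostate_geometry
    fov_mm <- spec$voxel_mm[1] * d[1]
    rp <- (spec$prostate_diameter_mm / 2) / fov_mm
    body <- (X - 0.5)^2 + (Y - 0.5)^2 < 0.45^2
    pros <- (X - 0.5)^2 + (Y - 0.35)^2 < rp^2
    air <- (X - 0.5)^2 + (Y - 0.72)^2 < 0.08^2
    for (k in seq_len(d[3])) {
      sa <- adc[, , k]; st <- t2[, , k]; sm <- m0[, , k]; sl <- lab[, , k]
      sa[body] <- 1500; st[body] <- 80; sm[body] <- 1; sl[body] <- 1L
      sa[pros] <- 900; st[pros] <- 150; sl[pros] <- 2L
      sa[air] <- 0; st[air] <- 1; sm[air] <- 0; sl[air] <- 0L
      adc[, , k] <- sa; t2[, , k] <- st; m0[, , k] <- sm; lab[, , k] <- sl
    }
  }
  t1v <- array(spec$t1, d); t1v[m0 == 0] <- spec$t1
  structure(list(adc = adc, t2 = t2, m0 = m0, t1 = t1v,
                 roi_labels = lab, spec = spec),
            class = "pbd_ground_truth")
}

# random smooth polynomial phase field, max |Delta| = amplitude
.background_field <- function(d, order, amplitude) {
  xi <- seq(-1, 1, length.out = d[1])
  yi <- seq(-1, 1, length.out = d[2])
  zi <- if (d[3] > 1) seq(-1, 1, length.out = d[3]) else 0
  f <- array(0, d)
  for (px in 0:order) for (py in 0:(order - px)) for (pz in 0:(order - px - py)) {
    cf <- stats::rnorm(1)
    f <- f + cf * outer(outer(xi^px, yi^py), zi^pz)
  }
  f / max(abs(f)) * amplitude * stats::runif(1, 0.5, 1)
}

#' Forward-simulate the four-pass acquisition
#'
#' Per-voxel closed-form steady-state signals at the two crusher moments,
#' with pass structure `L+/- = |L| exp(i(DeltaL +/- phiL))` (and likewise
#' for H): the encoded phase flips with the RF phase increment sign while
#' the smooth background field Delta (different for each moment, emulating
#' moment-dependent eddy currents) is shared within a moment.  Complex
#' Gaussian noise is added per volume.
#'
#' @param truth a [make_phantom()] object.
#' @param seq_low,seq_high [sequence_params()] for the two moments
#'   (identical apart from the crusher moment).
#' @param background background-field description, see [phantom_spec()];
#'   `NULL` for none.
#' @param noise_sd per-channel complex noise SD (M0 = 1 units).
#' @param seed RNG seed (mandatory when noise or background is random).
#' @param L truncation order for the forward model.
#' @return Object of class `pbd_acquisition`: complex arrays `vol_L_plus`,
#'   `vol_L_minus`, `vol_H_plus`, `vol_H_minus`, the two sequences, the
#'   theta signs, and the simulation metadata.
#' @export
forward_acquire <- function(truth, seq_low, seq_high,
                            background = list(order = 2, amplitude = pi),
                            noise_sd = 0, seed = NULL, L = 32) {
  stopifnot(inherits(truth, "pbd_ground_truth"))
  if (moment_of(seq_low) >= moment_of(seq_high))
    stop("forward_acquire: seq_low must have the smaller crusher moment")
  if ((noise_sd > 0 || !is.null(background)) && is.null(seed))
    stop("forward_acquire: seed required for random background/noise")
  if (!is.null(seed)) set.seed(seed)
  d <- dim(truth$adc)
  ts <- tissue_params(M0 = as.vector(truth$m0), T1 = as.vector(truth$t1),
                      T2 = as.vector(truth$t2),
                      D = as.vector(truth$adc), allow_t2_gt_t1 = TRUE)
  sl <- seq_low; sh <- seq_high; sl$L <- sh$L <- as.integer(L)
  SL <- array(steady_state_signal(ts, sl), d)
  SH <- array(steady_state_signal(ts, sh), d)
  dL <- if (is.null(background)) array(0, d) else
    .background_field(d, background$order, background$amplitude)
  dH <- if (is.null(background)) array(0, d) else
    .background_field(d, background$order, background$amplitude)
  mk <- function(S, dlt) {
    v <- S * exp(complex(imaginary = as.vector(dlt)))
    if (noise_sd > 0)
      v <- v + complex(real = noise_sd * stats::rnorm(length(v)),
                       imaginary = noise_sd * stats::rnorm(length(v)))
    array(v, d)
  }
  structure(list(vol_L_plus = mk(SL, dL), vol_L_minus = mk(Conj(SL), dL),
                 vol_H_plus = mk(SH, dH), vol_H_minus = mk(Conj(SH), dH),
                 seq_low = seq_low, seq_high = seq_high,
                 theta_signs = c(L_plus = 1, L_minus = -1,
                                 H_plus = 1, H_minus = -1),
                 noise_sd = noise_sd, seed = seed,
                 background = background),
            class = "pbd_acquisition")
}

#' Per-ROI summary of parameter maps against phantom truth
#'
#' @param maps a [fit_maps()] result.
#' @param truth the [make_phantom()] object the acquisition came from.
#' @return Data frame with per-label truth values, median estimates and
#'   percentage errors.
#' @export
roi_summary <- function(maps, truth) {
  labs <- sort(setdiff(unique(as.vector(truth$roi_labels)), 0L))
  out <- lapply(labs, function(id) {
    sel <- truth$roi_labels == id & maps$mask
    data.frame(label = id,
               adc_true = stats::median(truth$adc[sel]),
               t2_true = stats::median(truth$t2[sel]),
               adc_median = stats::median(maps$adc[sel]),
               t2_median = stats::median(maps$t2[sel]),
               n_voxels = sum(sel))
  })
  out <- do.call(rbind, out)
  out$adc_err_pct <- 100 * (out$adc_median - out$adc_true) / out$adc_true
  out$t2_err_pct <- 100 * (out$t2_median - out$t2_true) / out$t2_true
  out
}
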
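# Closed-form steady-state signal of the RF-phase-modulated gradient echo
# with diffusion, via the configuration-state transfer-matrix recursion.
#
# Model summary.  Transverse/longitudinal magnetization is expanded in
# configuration orders l (multiples of the per-TR crusher dephasing).  With a
# quadratic transmit-phase schedule phi(n) = phi(n-1) + n*theta the steady
# state is stationary after demodulation, and the order-l amplitudes obey a
# three-term recursion that closes into the 2x2 transfer matrices Psi_l
# below.  Relaxation and diffusion enter through
#   X(l) = exp(-t/T2) exp(-kap (l^2 + l + 1/3)),   kap = D gamma^2 G^2 t^3
#   Y(l) = exp(-t/T1) exp(-kap l^2)
# i.e. the standard rectangular-crusher b-factors per order.  The recursion
# is truncated at order L by dropping configurations beyond L; the ratio
# eps + i eta = -Omega22/Omega21 of the ordered product
# Omega = Psi_L ... Psi_1 then determines the readout-order amplitude, and
# the demodulated complex signal is
#   S = i * beta * (eta X0 + i (eta^2 - eps (X0 - eps)))
#   beta = (1 - Y0) M0 sin(a) /
#          ((X0-eps) (X0 (cos a - Y0) + eps (1 - Y0 cos a))
#            - eta^2 (1 - Y0 cos a))
# with X0 = X(0), Y0 = Y(0).  The leading i fixes the receiver convention so
# that flipping the sign of theta conjugates the signal, which is what makes
# the four-pass background cancellation work.  This transcription is locked
# in against the EPG, isochromat and random-walk oracles (see tests).

# Vectorized SI-unit core.  D (m^2/s), T2/T1/t/TE (s), angles (rad).
.pbd_signal_core <- function(M0, T1, T2, D, a, th, t, G, L, TE = 0) {
  n <- max(length(M0), length(T1), length(T2), length(D))
  M0 <- rep_len(M0, n); T1 <- rep_len(T1, n)
  T2 <- rep_len(T2, n); D <- rep_len(D, n)
  sa <- sin(a); ca <- cos(a)
  if (abs(sa) < .Machine$double.eps && abs(a - pi) < 1e-12)
    stop("steady-state signal: alpha = 180 deg is singular")
  if (a == 0) return(complex(real = rep(0, n)))
  kap <- D * (pbd_gamma * G)^2 * t^3
  if (any(!is.finite(kap))) stop("non-finite diffusion exponent (check D, G, t)")
  E2 <- exp(-t / T2); E1 <- exp(-t / T1)
  c2 <- cos(a / 2)^2
  s2 <- sin(a / 2)^2
  one <- rep(1 + 0i, n)
  O11 <- one; O12 <- 0 * one; O21 <- 0 * one; O22 <- one
  for (l in seq_len(L)) {
    Yl  <- E1 * exp(-kap * l^2)
    eP  <- exp(complex(imaginary = th * l))
    Dl  <- Conj(eP) - Yl * ca
    V   <- 0.5 * Yl * sa^2 / Dl
    av  <- c2 - V
    bv  <- s2 + V
    Xl  <- E2 * exp(-kap * (l^2 + l + 1 / 3))
    Xml <- E2 * exp(-kap * (l^2 - l + 1 / 3))
    P11 <- eP * Xl * (ca - 2 * V) / av
    P12 <- Xl * bv / (Xml * av)
    P21 <- -bv / av
    P22 <- Conj(eP) / (Xml * av)
    n11 <- P11 * O11 + P12 * O21; n12 <- P11 * O12 + P12 * O22
    n21 <- P21 * O11 + P22 * O21; n22 <- P21 * O12 + P22 * O22
    nrm <- pmax(Mod(n11), Mod(n12), Mod(n21), Mod(n22))
    O11 <- n11 / nrm; O12 <- n12 / nrm   # eps + i eta is a ratio of entries,
    O21 <- n21 / nrm; O22 <- n22 / nrm   # so the product can be renormalized
    if (any(!is.finite(c(Re(O11), Re(O21))))) stop("non-finite recursion state")
  }
  if (any(Mod(O21) == 0)) stop("degenerate recursion: Omega21 = 0")
  rho <- -O22 / O21
  eps <- Re(rho); eta <- Im(rho)
  X0 <- E2 * exp(-kap / 3); Y0 <- E1
  den <- (X0 - eps) * (X0 * (ca - Y0) + eps * (1 - Y0 * ca)) -
    eta^2 * (1 - Y0 * ca)
  beta <- (1 - Y0) * M0 * sa / den
  S <- complex(imaginary = 1) *
    (beta * complex(real = eta * X0, imaginary = eta^2 - eps * (X0 - eps)))
  S <- S * exp(-TE / T2)    # magnitude-only TE decay; no T2' phase modeled
  if (any(!is.finite(S))) stop("non-finite steady-state signal")
  S
}

#' T2 and T1 relaxation factors with diffusion
#'
#' The factors X(l) and Y(l) that propagate transverse and longitudinal
#' configuration orders over one crusher interval, including the
#' rectangular-gradient diffusion attenuation:
#' `X(l) = exp(-t/T2) exp(-kap (l^2 + l + 1/3))`,
#' `Y(l) = exp(-t/T1) exp(-kap l^2)` with `kap = D gamma^2 G^2 t^3`
#' (dimensionless).  Negative orders are supported (the recursion uses
#' X(-1) and X(-l-1)).
#'
#' @param tissue a [tissue_params()] object (scalar fields).
#' @param seq a [sequence_params()] object.
#' @param l configuration order(s), any integer(s).
#' @return A list with numeric vectors `X` and `Y`, both in (0, 1] for valid
#'   inputs.
#' @export
relaxation_factors <- function(tissue, seq, l) {
  p <- .pbd_si(tissue, seq)
  stopifnot(length(p$T2) == 1)
  kap <- p$D * (pbd_gamma * p$G)^2 * p$t^3
  X <- exp(-p$t / p$T2) * exp(-kap * (l^2 + l + 1 / 3))
  Y <- exp(-p$t / p$T1) * exp(-kap * l^2)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("relaxation_factors: overflow in diffusion exponent (check D, G, t, l)")
  list(X = X, Y = Y)
}

#' Transfer matrix of the configuration recursion
#'
#' The 2x2 matrix `Psi_l` propagating the paired configuration amplitudes
#' (positive orders, conjugated negative orders) from order l to l + 1.
#' Entries involve `tan^2(alpha/2)` / `sec^2(alpha/2)` combinations and the
#' phase factors `exp(2iCl)` with `C = theta/2`; the flip angle 180 degrees
#' is singular and rejected.
#'
#' @inheritParams relaxation_factors
#' @param l configuration order, `1 <= l <= L`.
#' @return A 2x2 complex matrix.
#' @export
psi_matrix <- function(tissue, seq, l) {
  stopifnot(l >= 1, l <= seq$L)
  p <- .pbd_si(tissue, seq)
  stopifnot(length(p$T2) == 1)
  if (abs(p$a - pi) < 1e-12)
    stop("psi_matrix: alpha = 180 deg is singular (sec^2(alpha/2) diverges)")
  kap <- p$D * (pbd_gamma * p$G)^2 * p$t^3
  E2 <- exp(-p$t / p$T2)
  Yl <- exp(-p$t / p$T1) * exp(-kap * l^2)
  eP <- exp(complex(imaginary = p$th * l))
  Dl <- Conj(eP) - Yl * cos(p$a)
  V  <- 0.5 * Yl * sin(p$a)^2 / Dl
  av <- cos(p$a / 2)^2 - V
  bv <- sin(p$a / 2)^2 + V
  Xl  <- E2 * exp(-kap * (l^2 + l + 1 / 3))
  Xml <- E2 * exp(-kap * (l^2 - l + 1 / 3))
  if (Mod(Xml) == 0) stop("psi_matrix: X(-l-1) = 0, division by zero")
  matrix(c(eP * Xl * (cos(p$a) - 2 * V) / av, -bv / av,
           Xl * bv / (Xml * av), Conj(eP) / (Xml * av)),
         2, 2)
}

#' Configuration-state recursion
#'
#' Forms the ordered product `Omega = Psi_L Psi_{L-1} ... Psi_1` and the
#' derived quantities `eps + i eta = -Omega22 / Omega21` (the truncation
#' closure dropping configurations beyond order L) and the signal
#' coefficient `beta` (named `beta_coeff` to avoid clashing with the L2
#' regularization weight of the reconstruction).
#'
#' @inheritParams relaxation_factors
#' @return An object of class `pbd_recursion`: list with `omega` (2x2
#'   complex), `epsilon`, `eta`, `beta_coeff`.
#' @export
configuration_recursion <- function(tissue, seq) {
  Om <- diag(2) + 0i
  for (l in seq_len(seq$L)) Om <- psi_matrix(tissue, seq, l) %*% Om
  if (any(!is.finite(c(Re(Om), Im(Om)))))
    stop("configuration_recursion: non-finite matrix product")
  if (Mod(Om[2, 1]) == 0)
    stop("degenerate recursion: Omega21 = 0, eps and eta undefined")
  rho <- -Om[2, 2] / Om[2, 1]
  eps <- Re(rho); eta <- Im(rho)
  p <- .pbd_si(tissue, seq)
  kap <- p$D * (pbd_gamma * p$G)^2 * p$t^3
  X0 <- exp(-p$t / p$T2) * exp(-kap / 3)
  Y0 <- exp(-p$t / p$T1)
  ca <- cos(p$a)
  den <- (X0 - eps) * (X0 * (ca - Y0) + eps * (1 - Y0 * ca)) -
    eta^2 * (1 - Y0 * ca)
  structure(list(omega = Om, epsilon = eps, eta = eta,
                 beta_coeff = (1 - Y0) * p$M0 * sin(p$a) / den),
            class = "pbd_recursion")
}

#' Steady-state complex PBD signal
#'
#' Closed-form demodulated steady-state signal after RF excitation.
#' Vectorized over the tissue fields.  Receiver convention: the signal for
#' `-theta` is the complex conjugate of the signal for `+theta`, and over
#' the physiological operating range the phase lies in (0, 90) degrees,
#' increasing with T2.  The diffusion/T2-encoded quadrature lies along the
#' imaginary axis in this convention (rotate by -90 degrees for the
#' "encoding frame" used by [effective_bvalue()] and
#' [complex_component_analysis()]).
#'
#' @inheritParams relaxation_factors
#' @return Complex vector of steady-state signals.
#' @export
steady_state_signal <- function(tissue, seq) {
  p <- .pbd_si(tissue, seq)
  .pbd_signal_core(p$M0, p$T1, p$T2, p$D, p$a, p$th, p$t, p$G, p$L, p$TE)
}

#' Steady-state signal phase
#'
#' `arg(S)` in radians.  Voxels whose magnitude falls below `mag_floor` are
#' flagged unreliable (attribute `"unreliable"`).
#'
#' @inheritParams relaxation_factors
#' @param mag_floor magnitude below which the phase is flagged unreliable.
#' @return Numeric vector of phases (radians) with logical attribute
#'   `unreliable`.
#' @export
signal_phase <- function(tissue, seq, mag_floor = 1e-12) {
  S <- steady_state_signal(tissue, seq)
  ph <- Arg(S)
  attr(ph, "unreliable") <- Mod(S) < mag_floor
  ph
}

#' Phase response over a tissue/sequence grid
#'
#' Evaluates the signal phase and magnitude over the full factorial grid of
#' the supplied tissue and sequence axes, at the crusher moment of `seq`.
#'
#' @param seq a [sequence_params()] object supplying TR, crusher and
#'   truncation settings.
#' @param T2,D,T1 tissue axes (ms, um^2/s, ms).
#' @param alpha,theta sequence axes (degrees).
#' @return A long-format data frame with columns `T1_ms`, `T2_ms`,
#'   `D_um2_per_s`, `alpha_deg`, `theta_deg`, `moment`, `phase_rad`,
#'   `magnitude`.
#' @export
phase_response_grid <- function(seq,
                                T2 = seq(50, 300, by = 25),
                                D = seq(0, 2000, by = 250),
                                T1 = 1000,
                                alpha = seq$alpha, theta = seq$theta) {
  g <- expand.grid(T1_ms = T1, T2_ms = T2, D_um2_per_s = D,
                   alpha_deg = alpha, theta_deg = theta,
                   KEEP.OUT.ATTRS = FALSE)
  ph <- numeric(nrow(g)); mg <- numeric(nrow(g))
  for (key in split(seq_len(nrow(g)),
                    interaction(g$alpha_deg, g$theta_deg, drop = TRUE))) {
    sq <- sequence_params(TR = seq$TR, TE = seq$TE,
                          alpha = g$alpha_deg[key[1]],
                          theta = g$theta_deg[key[1]],
                          grad_amplitude = seq$grad_amplitude,
                          grad_duration = seq$grad_duration,
                          ref_length = seq$ref_length, L = seq$L)
    ts <- tissue_params(T1 = g$T1_ms[key], T2 = g$T2_ms[key],
                        D = g$D_um2_per_s[key], allow_t2_gt_t1 = TRUE)
    S <- steady_state_signal(ts, sq)
    ph[key] <- Arg(S); mg[key] <- Mod(S)
  }
  g$moment <- moment_of(seq)
  g$phase_rad <- ph
  g$magnitude <- mg
  g
}

#' Complex-component analysis of the two-moment encoding
#'
#' Compares the steady-state signals at the low and high crusher moments
#' over an (ADC, T2) grid: the phase difference `ang L - ang H`, the
#' magnitude ratio `|H|/|L|`, and the component ratios in the encoding
#' frame (the receiver frame rotated by -90 degrees, in which the
#' diffusion/T2-sensitive quadrature is the real part and the stable
#' quadrature the imaginary part).
#'
#' @param seq_low,seq_high [sequence_params()] objects differing only in
#'   crusher moment.
#' @param D,T2 grid axes (um^2/s, ms).
#' @param T1 fixed T1, ms.
#' @return Data frame with columns `D_um2_per_s`, `T2_ms`, `phase_diff_rad`,
#'   `mag_ratio`, `real_ratio`, `imag_ratio`.
#' @export
complex_component_analysis <- function(seq_low, seq_high,
                                       D = seq(0, 2000, by = 100),
                                       T2 = seq(50, 300, by = 10),
                                       T1 = 1000) {
  g <- expand.grid(D_um2_per_s = D, T2_ms = T2, KEEP.OUT.ATTRS = FALSE)
  ts <- tissue_params(T1 = T1, T2 = g$T2_ms, D = g$D_um2_per_s,
                      allow_t2_gt_t1 = TRUE)
  SL <- steady_state_signal(ts, seq_low)
  SH <- steady_state_signal(ts, seq_high)
  encL <- -1i * SL; encH <- -1i * SH   # encoding frame
  g$phase_diff_rad <- Arg(SL) - Arg(SH)
  g$mag_ratio <- Mod(SH) / Mod(SL)
  g$real_ratio <- Re(encH) / Re(encL)
  g$imag_ratio <- Im(encH) / Im(encL)
  g
}
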
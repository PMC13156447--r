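# Parameter containers and unit conversions.
#
# Unit policy: user-facing times in ms, flip/phase angles in degrees,
# diffusivity in um^2/s, gradient amplitude in mT/m.  Conversion to SI
# happens in exactly one place (.pbd_si below); everything downstream is SI.

#' Gyromagnetic ratio of the proton
#'
#' Fixed constant, in rad s^-1 mT^-1.
#' @export
pbd_gamma <- 2.6752218744e5

.deg2rad <- function(x) x * pi / 180

#' Tissue parameter set
#'
#' Voxel-level ground truth for the signal model.  Fields may be vectors
#' (recycled to a common length), so a whole grid of tissues can be carried
#' in one object.
#'
#' @param M0 proton density, arbitrary units (>= 0).
#' @param T1 longitudinal relaxation time, ms (> 0).
#' @param T2 transverse relaxation time, ms (> 0).
#' @param D apparent diffusion coefficient, um^2/s (>= 0).
#' @param allow_t2_gt_t1 permit the unphysical T2 > T1 combination (some
#'   doped-phantom fits need it); default FALSE.
#' @return An object of class `pbd_tissue`.
#' @export
tissue_params <- function(M0 = 1, T1 = 1000, T2 = 100, D = 1000,
                          allow_t2_gt_t1 = FALSE) {
  n <- max(length(M0), length(T1), length(T2), length(D))
  M0 <- rep_len(as.numeric(M0), n); T1 <- rep_len(as.numeric(T1), n)
  T2 <- rep_len(as.numeric(T2), n); D  <- rep_len(as.numeric(D),  n)
  if (any(!is.finite(c(M0, T1, T2, D))))
    stop("tissue_params: non-finite parameter value")
  if (any(T1 <= 0)) stop("tissue_params: T1 must be > 0")
  if (any(T2 <= 0)) stop("tissue_params: T2 must be > 0")
  if (any(D < 0))   stop("tissue_params: D must be >= 0")
  if (any(M0 < 0))  stop("tissue_params: M0 must be >= 0")
  if (!allow_t2_gt_t1 && any(T2 > T1))
    stop("tissue_params: T2 > T1; set allow_t2_gt_t1 = TRUE to override")
  structure(list(M0 = M0, T1 = T1, T2 = T2, D = D), class = "pbd_tissue")
}

#' Convert a gradient moment in pi-units to an amplitude
#'
#' The protocol literature labels crusher moments by the dephasing they
#' produce across a reference length (the in-plane voxel), in multiples of
#' pi.  `n_pi` pi-units across `ref_length` with a crusher of duration
#' `grad_duration` correspond to the amplitude returned here.
#'
#' @param n_pi moment in pi-units of dephasing across `ref_length`.
#' @param grad_duration crusher duration, ms.
#' @param ref_length reference (voxel) length, mm; default 1.125 mm
#'   (160 samples over an 18 cm field of view).
#' @return Gradient amplitude in mT/m.
#' @export
moment_pi_to_amplitude <- function(n_pi, grad_duration, ref_length = 1.125) {
  stopifnot(n_pi >= 0, grad_duration > 0, ref_length > 0)
  n_pi * pi / (pbd_gamma * (grad_duration * 1e-3) * (ref_length * 1e-3))
}

#' Convert a gradient amplitude to a moment in pi-units
#'
#' Inverse of [moment_pi_to_amplitude()].
#' @param G gradient amplitude, mT/m.
#' @inheritParams moment_pi_to_amplitude
#' @return Moment in pi-units.
#' @export
amplitude_to_moment_pi <- function(G, grad_duration, ref_length = 1.125) {
  G * pbd_gamma * (grad_duration * 1e-3) * (ref_length * 1e-3) / pi
}

#' Sequence parameter set
#'
#' Describes one pass of the PBD protocol.  The crusher is parameterized by
#' amplitude `grad_amplitude` (mT/m) and duration `grad_duration` (ms),
#' because the diffusion attenuation needs G^2 t^3, not just the moment
#' G t.  The moment can alternatively be given in pi-units of per-voxel
#' dephasing via `moment_pi` (see [moment_pi_to_amplitude()]).
#'
#' @param TR repetition time, ms.
#' @param TE echo time, ms.  The phase is modeled as TE-independent; TE
#'   applies a pure `exp(-TE/T2)` decay to the magnitude.
#' @param alpha flip angle, degrees, in [0, 180).
#' @param theta RF phase increment, degrees (signed); the transmit phase is
#'   incremented quadratically, phi(n) = phi(n-1) + n*theta.
#' @param grad_amplitude crusher amplitude, mT/m.  Ignored when `moment_pi`
#'   is given.
#' @param grad_duration crusher duration, ms; default `TR - 2`.  The
#'   steady-state relaxation factors use the same interval (the crusher is
#'   active for essentially the whole TR in this sequence).
#' @param moment_pi optional crusher moment in pi-units of dephasing across
#'   `ref_length`.
#' @param ref_length reference length for `moment_pi`, mm.
#' @param L configuration-state truncation order; default 8.  See the
#'   methods vignette for the truncation study: analyses that need the model
#'   converged to the simulator level use L = 32.
#' @return An object of class `pbd_sequence`.
#' @export
sequence_params <- function(TR = 10.9, TE = 0, alpha = 20, theta = 2,
                            grad_amplitude = NULL, grad_duration = TR - 2,
                            moment_pi = NULL, ref_length = 1.125, L = 8) {
  if (!is.null(moment_pi))
    grad_amplitude <- moment_pi_to_amplitude(moment_pi, grad_duration, ref_length)
  if (is.null(grad_amplitude))
    stop("sequence_params: give either grad_amplitude or moment_pi")
  if (TR <= 0) stop("sequence_params: TR must be > 0")
  if (alpha < 0 || alpha >= 180)
    stop("sequence_params: alpha must be in [0, 180)")
  if (grad_duration <= 0 || grad_duration > TR)
    stop("sequence_params: grad_duration must be in (0, TR]")
  if (grad_amplitude < 0) stop("sequence_params: grad_amplitude must be >= 0")
  if (L < 1) stop("sequence_params: L must be >= 1")
  structure(list(TR = TR, TE = TE, alpha = alpha, theta = theta,
                 grad_amplitude = grad_amplitude,
                 grad_duration = grad_duration,
                 ref_length = ref_length, L = as.integer(L),
                 gamma = pbd_gamma),
            class = "pbd_sequence")
}

#' Crusher gradient moment of a sequence
#'
#' @param seq a [sequence_params()] object.
#' @param units `"ms_mT_m"` for the raw time-integral G*t, or `"pi"` for
#'   pi-units of dephasing across the sequence's reference length.
#' @return Numeric moment.
#' @export
moment_of <- function(seq, units = c("ms_mT_m", "pi")) {
  units <- match.arg(units)
  switch(units,
         ms_mT_m = seq$grad_amplitude * seq$grad_duration,
         pi = amplitude_to_moment_pi(seq$grad_amplitude, seq$grad_duration,
                                     seq$ref_length))
}

#' @export
print.pbd_sequence <- function(x, ...) {
  cat(sprintf(
    "PBD sequence: TR %.2f ms, TE %.2f ms, alpha %g deg, theta %+g deg\n",
    x$TR, x$TE, x$alpha, x$theta))
  cat(sprintf("  crusher: %.3f mT/m x %.2f ms (%.2f ms mT/m = %.2f pi per %.3f mm), L = %d\n",
              x$grad_amplitude, x$grad_duration, moment_of(x),
              moment_of(x, "pi"), x$ref_length, x$L))
  invisible(x)
}

#' @export
print.pbd_tissue <- function(x, ...) {
  n <- length(x$T2)
  if (n == 1)
    cat(sprintf("PBD tissue: M0 %g, T1 %g ms, T2 %g ms, D %g um2/s\n",
                x$M0, x$T1, x$T2, x$D))
  else
    cat(sprintf("PBD tissue grid: %d voxels (T2 %g-%g ms, D %g-%g um2/s)\n",
                n, min(x$T2), max(x$T2), min(x$D), max(x$D)))
  invisible(x)
}

# One conversion layer to SI, used by every model routine.
.pbd_si <- function(tissue, seq) {
  list(M0 = tissue$M0,
       T1 = tissue$T1 * 1e-3, T2 = tissue$T2 * 1e-3,   # s
       D  = tissue$D * 1e-12,                          # m^2/s
       a  = .deg2rad(seq$alpha), th = .deg2rad(seq$theta),
       t  = seq$grad_duration * 1e-3,                  # s
       TE = seq$TE * 1e-3,
       G  = seq$grad_amplitude, L = seq$L)
}

#' Serialize parameter objects to JSON
#'
#' @param x a `pbd_tissue` or `pbd_sequence` object.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
params_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, c("pbd_tissue", "pbd_sequence")))
  obj <- c(list(.class = class(x)[1]), unclass(x))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Deserialize parameter objects from JSON
#'
#' @param json a JSON string or file path written by [params_to_json()].
#' @return The restored parameter object.
#' @export
params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  cls <- obj$.class
  obj$.class <- NULL
  if (identical(cls, "pbd_tissue"))
    do.call(tissue_params, c(obj[c("M0", "T1", "T2", "D")],
                             list(allow_t2_gt_t1 = TRUE)))
  else if (identical(cls, "pbd_sequence"))
    sequence_params(TR = obj$TR, TE = obj$TE, alpha = obj$alpha,
                    theta = obj$theta, grad_amplitude = obj$grad_amplitude,
                    grad_duration = obj$grad_duration,
                    ref_length = obj$ref_length, L = obj$L)
  else stop("params_from_json: unknown class tag")
}
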
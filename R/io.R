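# NIfTI input/output for complex volumes and JSON protocol files.
# Complex volumes travel as a pair of NIfTI files, either real/imaginary
# or magnitude/phase ("dialect"), with the phase unit declared.

#' Read a complex volume from a NIfTI component pair
#'
#' @param paths length-2 character vector: the two component files
#'   (real, imaginary) or (magnitude, phase).
#' @param dialect `"realimag"` or `"magphase"`.
#' @param phase_unit `"rad"` or `"deg"` (magnitude/phase dialect only).
#' @return Complex array with attribute `affine` (the 4x4 xform of the
#'   first component).
#' @export
read_complex_volume <- function(paths, dialect = c("realimag", "magphase"),
                                phase_unit = c("rad", "deg")) {
  dialect <- match.arg(dialect); phase_unit <- match.arg(phase_unit)
  stopifnot(length(paths) == 2)
  a <- RNifti::readNifti(paths[1]); b <- RNifti::readNifti(paths[2])
  if (!identical(dim(a), dim(b)))
    stop(sprintf("read_complex_volume: shape mismatch between\n  %s: %s\n  %s: %s",
                 paths[1], paste(dim(a), collapse = "x"),
                 paths[2], paste(dim(b), collapse = "x")))
  xa <- RNifti::xform(a); xb <- RNifti::xform(b)
  if (max(abs(xa - xb)) > 1e-4)
    stop(sprintf("read_complex_volume: affine mismatch between %s and %s",
                 paths[1], paths[2]))
  v <- if (dialect == "realimag") {
    complex(real = as.vector(a), imaginary = as.vector(b))
  } else {
    ph <- as.vector(b); if (phase_unit == "deg") ph <- ph * pi / 180
    as.vector(a) * exp(complex(imaginary = ph))
  }
  out <- array(v, dim(a))
  attr(out, "affine") <- xa
  out
}

#' Write a complex volume as a NIfTI component pair
#'
#' @param vol complex array (optionally carrying an `affine` attribute).
#' @param paths length-2 output file paths.
#' @inheritParams read_complex_volume
#' @return Invisibly, `paths`.
#' @export
write_complex_volume <- function(vol, paths,
                                 dialect = c("realimag", "magphase"),
                                 phase_unit = c("rad", "deg")) {
  dialect <- match.arg(dialect); phase_unit <- match.arg(phase_unit)
  stopifnot(length(paths) == 2)
  comp <- if (dialect == "realimag") list(Re(vol), Im(vol))
  else {
    ph <- Arg(vol); if (phase_unit == "deg") ph <- ph * 180 / pi
    list(Mod(vol), ph)
  }
  aff <- attr(vol, "affine")
  for (i in 1:2) {
    im <- array(comp[[i]], dim(vol))
    ni <- RNifti::asNifti(im)
    if (!is.null(aff)) ni <- RNifti::`sform<-`(ni, structure(aff, code = 2L))
    RNifti::writeNifti(ni, paths[i])
  }
  invisible(paths)
}

#' Write parameter maps as NIfTI
#'
#' @param maps a [fit_maps()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_parameter_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, c("adc.nii.gz", "t2.nii.gz", "residual.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(maps$adc), p[1])
  RNifti::writeNifti(RNifti::asNifti(maps$t2), p[2])
  RNifti::writeNifti(RNifti::asNifti(maps$residual), p[3])
  rep <- list(iterations_used = maps$iterations_used,
              converged = maps$converged,
              n_bb_fallbacks = maps$n_bb_fallbacks,
              final_objective = utils::tail(maps$objective_trace, 1),
              config = unclass(maps$config))
  writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(dir, "fit_report.json"))
  invisible(p)
}

#' Write a protocol file (both moments plus acquisition dialect)
#'
#' @param seq_low,seq_high [sequence_params()] objects.
#' @param path output JSON path.
#' @param dialect complex-volume dialect the acquisition files use.
#' @param phase_unit phase unit for the magnitude/phase dialect.
#' @return Invisibly, `path`.
#' @export
write_protocol <- function(seq_low, seq_high, path,
                           dialect = "realimag", phase_unit = "rad") {
  obj <- list(schema_version = 1L,
              dialect = dialect, phase_unit = phase_unit,
              seq_low = unclass(seq_low), seq_high = unclass(seq_high))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a protocol file
#'
#' @param path JSON path written by [write_protocol()].
#' @return List with `seq_low`, `seq_high`, `dialect`, `phase_unit`.
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$schema_version))
    stop("read_protocol: missing schema_version field")
  mk <- function(s) sequence_params(TR = s$TR, TE = s$TE, alpha = s$alpha,
                                    theta = s$theta,
                                    grad_amplitude = s$grad_amplitude,
                                    grad_duration = s$grad_duration,
                                    ref_length = s$ref_length, L = s$L)
  list(seq_low = mk(obj$seq_low), seq_high = mk(obj$seq_high),
       dialect = obj$dialect, phase_unit = obj$phase_unit)
}

#' Read a four-pass acquisition from NIfTI pairs
#'
#' @param lp,lm,hp,hm length-2 path vectors for the four passes (low/high
#'   moment, +/- theta), each a component pair.
#' @param protocol a [read_protocol()] result.
#' @return Object of class `pbd_acquisition`.
#' @export
read_acquisition <- function(lp, lm, hp, hm, protocol) {
  rd <- function(p) read_complex_volume(p, protocol$dialect,
                                        protocol$phase_unit)
  vols <- list(vol_L_plus = rd(lp), vol_L_minus = rd(lm),
               vol_H_plus = rd(hp), vol_H_minus = rd(hm))
  dm <- dim(vols[[1]])
  for (v in vols) if (!identical(dim(v), dm))
    stop("read_acquisition: the four volumes do not share a grid")
  structure(c(vols, list(seq_low = protocol$seq_low,
                         seq_high = protocol$seq_high,
                         theta_signs = c(L_plus = 1, L_minus = -1,
                                         H_plus = 1, H_minus = -1))),
            class = "pbd_acquisition")
}

#' Write a four-pass acquisition as NIfTI pairs
#'
#' @param acq a `pbd_acquisition` object.
#' @param dir output directory.
#' @param dialect,phase_unit see [read_complex_volume()].
#' @return Invisibly, the output directory.
#' @export
write_acquisition <- function(acq, dir, dialect = "realimag",
                              phase_unit = "rad") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- c("L_plus", "L_minus", "H_plus", "H_minus")
  sfx <- if (dialect == "realimag") c("real", "imag") else c("mag", "phase")
  for (v in nm)
    write_complex_volume(acq[[paste0("vol_", v)]],
                         file.path(dir, paste0(v, "_", sfx, ".nii.gz")),
                         dialect, phase_unit)
  write_protocol(acq$seq_low, acq$seq_high, file.path(dir, "protocol.json"),
                 dialect, phase_unit)
  invisible(dir)
}
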
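# Four-pass phase extraction and regularized inversion to ADC/T2 maps.
#
# The +theta/-theta passes at one crusher moment share the background phase
# Delta (B0, susceptibility, eddy currents) but carry opposite encoded
# phase, so arg(I+ . conj(I-))/2 cancels Delta exactly and returns the
# model phase.  The inversion minimizes
#   J(x1, x2) = (fH - phiH)^2 + (fL - phiL)^2
#               + lambda (TV(x1) + TV(x2)) + beta (x1^2 + x2^2)
# over normalized parameter maps (x1 = ADC/1000, x2 = T2/100) by projected
# gradient descent with Barzilai-Borwein steps, using the pre-computed
# spline interpolant for fL/fH and their gradients.

#' Remove background phase from a +/-theta pass pair
#'
#' Computes `arg(I+ . conj(I-)) / 2`, which cancels any background phase
#' common to the two passes and returns the encoded phase in
#' (-pi/2, pi/2].  Voxels whose magnitude (either pass) falls below
#' `mag_floor` are masked and their phase set to 0 rather than NaN.
#'
#' @param vol_plus,vol_minus congruent complex arrays (+theta and -theta
#'   passes at the same crusher moment).
#' @param mag_floor magnitude threshold for the validity mask.
#' @return List with `phi` (numeric array, radians) and `mask` (logical
#'   array).
#' @export
remove_background_phase <- function(vol_plus, vol_minus, mag_floor = 1e-12) {
  if (!identical(dim(vol_plus), dim(vol_minus)))
    stop("remove_background_phase: volumes are not congruent")
  pr <- vol_plus * Conj(vol_minus)
  mask <- Mod(vol_plus) > mag_floor & Mod(vol_minus) > mag_floor
  phi <- Arg(pr) / 2
  phi[!mask] <- 0
  list(phi = phi, mask = mask)
}

#' Background-free phase pair
#'
#' Bundles the low- and high-moment background-free phase maps and their
#' joint validity mask.
#'
#' @param phi_L,phi_H numeric arrays (radians), congruent.
#' @param mask logical array; default all TRUE.
#' @return Object of class `pbd_phase_pair`.
#' @export
phase_pair <- function(phi_L, phi_H, mask = NULL) {
  if (!identical(dim(phi_L), dim(phi_H)) &&
      !(is.null(dim(phi_L)) && length(phi_L) == length(phi_H)))
    stop("phase_pair: phi_L and phi_H are not congruent")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(phi_L) %||% length(phi_L))
  structure(list(phi_L = phi_L, phi_H = phi_H, mask = mask),
            class = "pbd_phase_pair")
}

#' Extract the phase pair from a four-pass acquisition
#'
#' @param acq a `pbd_acquisition` object (see [forward_acquire()] or
#'   [read_acquisition()]).
#' @param mag_floor magnitude threshold for the validity mask.
#' @return A [phase_pair()] object.
#' @export
extract_phase_pair <- function(acq, mag_floor = 1e-12) {
  lo <- remove_background_phase(acq$vol_L_plus, acq$vol_L_minus, mag_floor)
  hi <- remove_background_phase(acq$vol_H_plus, acq$vol_H_minus, mag_floor)
  phase_pair(lo$phi, hi$phi, lo$mask & hi$mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruction configuration
#'
#' @param lambda_tv total-variation weight (on normalized parameter maps);
#'   default 1e-6.
#' @param beta_l2 L2 (Tikhonov) weight; default 1e-6.  This is the
#'   regularization beta, distinct from the signal coefficient
#'   `beta_coeff` of [configuration_recursion()].
#' @param max_iter iteration cap.
#' @param rel_tol relative objective-change stopping tolerance.
#' @param grid_spec forward-interpolant grid, see [build_phase_lookup()].
#' @param bounds list `adc = c(min, max)`, `t2 = c(min, max)` (um^2/s, ms).
#' @param init `"grid"` (default) for a per-voxel coarse grid-search
#'   initialization of the data term, or constant starting maps
#'   `c(adc = ..., t2 = ...)`.
#' @param tv_epsilon smoothing of the isotropic TV at zero gradient.
#' @param seed optional seed recorded with results (the fit itself is
#'   deterministic).
#' @return Object of class `pbd_recon_config`.
#' @export
recon_config <- function(lambda_tv = 1e-6, beta_l2 = 1e-6,
                         max_iter = 2000, rel_tol = 1e-8,
                         grid_spec = list(adc = c(0, 3200, 50),
                                          t2 = c(15, 520, 5)),
                         bounds = list(adc = c(0, 3000), t2 = c(20, 500)),
                         init = "grid",
                         tv_epsilon = 1e-6, seed = NULL) {
  stopifnot(lambda_tv >= 0, beta_l2 >= 0, max_iter >= 1, rel_tol > 0)
  if (bounds$adc[1] < grid_spec$adc[1] || bounds$adc[2] > grid_spec$adc[2] ||
      bounds$t2[1] < grid_spec$t2[1] || bounds$t2[2] > grid_spec$t2[2])
    stop("recon_config: interpolant grid must cover the fit bounds")
  structure(list(lambda_tv = lambda_tv, beta_l2 = beta_l2,
                 max_iter = max_iter, rel_tol = rel_tol,
                 grid_spec = grid_spec, bounds = bounds, init = init,
                 tv_epsilon = tv_epsilon, seed = seed),
            class = "pbd_recon_config")
}

# --- internal scaling: ADC in kilo-um^2/s, T2 in hecto-ms, so one BB step
#     size serves both parameters.
.SC_ADC <- 1000
.SC_T2 <- 100

# Coarse grid-search initialization: per voxel, the (adc, t2) node of an
# n_grid x n_grid lattice over the bounds minimizing the data term.  The
# phase surfaces are monotone but the joint objective has a long curved
# valley, so a data-driven starting point is what makes the descent
# reliable over the whole parameter box.
.grid_init <- function(phi_L, phi_H, lookup, bounds, n_grid = 25) {
  av <- seq(bounds$adc[1], bounds$adc[2], length.out = n_grid)
  tv <- seq(bounds$t2[1], bounds$t2[2], length.out = n_grid)
  g <- expand.grid(adc = av, t2 = tv, KEEP.OUT.ATTRS = FALSE)
  ev <- lookup_eval(lookup, g$adc, g$t2)
  n <- length(phi_L)
  best <- rep(Inf, n); ia <- rep(1L, n)
  for (k in seq_len(nrow(g))) {
    ck <- (ev$fL$value[k] - phi_L)^2 + (ev$fH$value[k] - phi_H)^2
    upd <- ck < best
    best[upd] <- ck[upd]; ia[upd] <- k
  }
  list(adc = g$adc[ia], t2 = g$t2[ia])
}

# Data-fidelity value and gradient in scaled units.  Returns per-voxel f
# and gradient components.
.fit_data_grad <- function(x1, x2, phi_L, phi_H, lookup) {
  ev <- lookup_eval(lookup, x1 * .SC_ADC, x2 * .SC_T2)
  rL <- ev$fL$value - phi_L
  rH <- ev$fH$value - phi_H
  list(f = rL^2 + rH^2,
       g1 = 2 * (rL * ev$fL$d_adc + rH * ev$fH$d_adc) * .SC_ADC,
       g2 = 2 * (rL * ev$fL$d_t2 + rH * ev$fH$d_t2) * .SC_T2)
}

# Smoothed isotropic 3D TV and its gradient (forward differences, Neumann
# boundary).  Differences crossing the validity mask contribute nothing, so
# the regularizer acts within tissue only.  Returns list(value, grad).
.tv3 <- function(x, eps, mask = NULL) {
  d <- dim(x)
  dx <- dy <- dz <- array(0, d)
  if (d[1] > 1) dx[-d[1], , ] <- x[-1, , , drop = FALSE] - x[-d[1], , , drop = FALSE]
  if (d[2] > 1) dy[, -d[2], ] <- x[, -1, , drop = FALSE] - x[, -d[2], , drop = FALSE]
  if (d[3] > 1) dz[, , -d[3]] <- x[, , -1, drop = FALSE] - x[, , -d[3], drop = FALSE]
  if (!is.null(mask)) {
    m <- array(mask, d)
    ok <- array(FALSE, d)
    if (d[1] > 1) { ok[] <- FALSE; ok[-d[1], , ] <- m[-1, , , drop = FALSE] & m[-d[1], , , drop = FALSE]; dx[!ok] <- 0 }
    if (d[2] > 1) { ok[] <- FALSE; ok[, -d[2], ] <- m[, -1, , drop = FALSE] & m[, -d[2], , drop = FALSE]; dy[!ok] <- 0 }
    if (d[3] > 1) { ok[] <- FALSE; ok[, , -d[3]] <- m[, , -1, drop = FALSE] & m[, , -d[3], drop = FALSE]; dz[!ok] <- 0 }
  }
  w <- sqrt(dx^2 + dy^2 + dz^2 + eps^2)
  px <- dx / w; py <- dy / w; pz <- dz / w
  g <- array(0, d)
  g <- g - px - py - pz
  if (d[1] > 1) g[-1, , ] <- g[-1, , , drop = FALSE] + px[-d[1], , , drop = FALSE]
  if (d[2] > 1) g[, -1, ] <- g[, -1, , drop = FALSE] + py[, -d[2], , drop = FALSE]
  if (d[3] > 1) g[, , -1] <- g[, , -1, drop = FALSE] + pz[, , -d[3], drop = FALSE]
  list(value = sum(w), grad = g)
}

# Shared BB projected-descent engine.
#   mode "voxel": independent problems, per-voxel BB steps (vectorized).
#   mode "maps":  one coupled problem (TV/L2), a single global BB step.
# For a single voxel with lambda = beta = 0 the two modes perform the same
# arithmetic, which is the degenerate-reduction contract of fit_maps.
.pbd_fit_engine <- function(phi_L, phi_H, lookup, cfg, mode,
                            dims = NULL, mask = NULL) {
  n <- length(phi_L)
  lb <- c(cfg$bounds$adc[1] / .SC_ADC, cfg$bounds$t2[1] / .SC_T2)
  ub <- c(cfg$bounds$adc[2] / .SC_ADC, cfg$bounds$t2[2] / .SC_T2)
  if (identical(cfg$init, "grid")) {
    gi <- .grid_init(phi_L, phi_H, lookup, cfg$bounds)
    x1 <- gi$adc / .SC_ADC
    x2 <- gi$t2 / .SC_T2
  } else {
    x1 <- rep(cfg$init[["adc"]] / .SC_ADC, n)
    x2 <- rep(cfg$init[["t2"]] / .SC_T2, n)
  }
  act <- if (is.null(mask)) rep(TRUE, n) else as.vector(mask)
  maps <- identical(mode, "maps")
  reg <- maps && (cfg$lambda_tv > 0 || cfg$beta_l2 > 0)
  objgrad <- function(x1, x2) {
    dg <- .fit_data_grad(x1, x2, phi_L, phi_H, lookup)
    dg$f[!act] <- 0; dg$g1[!act] <- 0; dg$g2[!act] <- 0
    if (reg) {
      a1 <- array(x1, dims); a2 <- array(x2, dims)
      t1 <- .tv3(a1, cfg$tv_epsilon, act)
      t2v <- .tv3(a2, cfg$tv_epsilon, act)
      J <- sum(dg$f) + cfg$lambda_tv * (t1$value + t2v$value) +
        cfg$beta_l2 * sum(x1[act]^2 + x2[act]^2)
      g1 <- dg$g1 + cfg$lambda_tv * as.vector(t1$grad) + 2 * cfg$beta_l2 * x1
      g2 <- dg$g2 + cfg$lambda_tv * as.vector(t2v$grad) + 2 * cfg$beta_l2 * x2
      g1[!act] <- 0; g2[!act] <- 0
      list(f = dg$f, J = J, g1 = g1, g2 = g2)
    } else {
      list(f = dg$f, J = sum(dg$f), g1 = dg$g1, g2 = dg$g2)
    }
  }
  og <- objgrad(x1, x2)
  f_best <- og$f; J_best <- og$J
  xb1 <- x1; xb2 <- x2
  fb1 <- x1; fb2 <- x2                      # per-voxel best (voxel mode)
  gmax <- pmax(abs(og$g1), abs(og$g2), 1e-12)
  tau <- if (maps) rep(0.1 / max(gmax), n) else 0.1 / gmax
  bad_run <- if (maps) 0L else integer(n)
  n_fallback <- 0L
  iters <- rep(NA_integer_, n)
  it <- 0L
  W <- 20L                                  # best-improvement window
  trace <- numeric(0)
  best_hist <- numeric(0)
  conv_now <- FALSE
  repeat {
    it <- it + 1L
    x1n <- pmin(pmax(x1 - tau * og$g1, lb[1]), ub[1])
    x2n <- pmin(pmax(x2 - tau * og$g2, lb[2]), ub[2])
    og_n <- objgrad(x1n, x2n)
    s1 <- x1n - x1; s2 <- x2n - x2
    y1 <- og_n$g1 - og$g1; y2 <- og_n$g2 - og$g2
    if (maps) {
      num <- sum(s1 * s1 + s2 * s2); den <- sum(s1 * y1 + s2 * y2)
      tnew <- if (is.finite(den) && den > 0) num / den else 1e-3
      tnew <- min(max(tnew, 1e-8), 1e2)
      if (og_n$J < J_best) { J_best <- og_n$J; xb1 <- x1n; xb2 <- x2n }
      ## divergence safeguard: sustained excursion -> restart from the best
      bad_run <- if (og_n$J > 2 * J_best) bad_run + 1L else 0L
      if (bad_run > 5L) {
        x1n <- xb1; x2n <- xb2
        og_n <- objgrad(x1n, x2n)
        tnew <- 1e-3; bad_run <- 0L; n_fallback <- n_fallback + 1L
      }
      tau <- rep(tnew, n)
    } else {
      num <- s1 * s1 + s2 * s2; den <- s1 * y1 + s2 * y2
      tnew <- ifelse(is.finite(den) & den > 0, num / den, 1e-3)
      tnew <- pmin(pmax(tnew, 1e-8), 1e2)
      upd <- og_n$f < f_best
      fb1[upd] <- x1n[upd]; fb2[upd] <- x2n[upd]
      f_best[upd] <- og_n$f[upd]
      bad_run <- ifelse(og_n$f > 2 * f_best, bad_run + 1L, 0L)
      fb <- bad_run > 5L
      if (any(fb)) {
        x1n[fb] <- fb1[fb]; x2n[fb] <- fb2[fb]
        og_n <- objgrad(x1n, x2n)
        tnew[fb] <- 1e-3; bad_run[fb] <- 0L
        n_fallback <- n_fallback + sum(fb)
      }
      tau <- tnew
      J_best <- sum(f_best[act])
      iters[is.na(iters) & og_n$f <= f_best] <- it
    }
    x1 <- x1n; x2 <- x2n
    og <- og_n
    trace <- c(trace, og_n$J)
    best_hist <- c(best_hist, J_best)
    if (it > W) {
      ref <- best_hist[it - W]
      conv_now <- (ref - J_best) <= cfg$rel_tol * max(best_hist[1], 1e-30)
    }
    if (conv_now || it >= cfg$max_iter) break
  }
  if (maps) { x1 <- xb1; x2 <- xb2 } else { x1 <- fb1; x2 <- fb2 }
  fin <- objgrad(x1, x2)
  f_prev <- fin$f
  list(adc = unname(x1 * .SC_ADC), t2 = unname(x2 * .SC_T2),
       residual = unname(f_prev),
       iterations_used = it,
       per_voxel_iterations = iters,
       converged = conv_now, objective_trace = trace,
       n_bb_fallbacks = n_fallback)
}

#' Single-voxel (unregularized) ADC/T2 fit
#'
#' Minimizes `(fH - phiH)^2 + (fL - phiL)^2` within bounds by projected
#' Barzilai-Borwein gradient descent.  Vectorized: `phi_L`/`phi_H` may be
#' vectors of independent voxels (each voxel gets its own adaptive step).
#' Deterministic given the initialization.
#'
#' @param phi_L,phi_H background-free phases (radians), equal-length
#'   vectors.
#' @param lookup a [build_phase_lookup()] interpolant.
#' @param bounds,init,max_iter,rel_tol see [recon_config()].
#' @return List with vectors `adc` (um^2/s), `t2` (ms), `residual` (final
#'   data fidelity), `per_voxel_iterations`, and scalars `iterations_used`,
#'   `converged`.
#' @export
fit_voxel <- function(phi_L, phi_H, lookup,
                      bounds = list(adc = c(0, 3000), t2 = c(20, 500)),
                      init = "grid",
                      max_iter = 300, rel_tol = 1e-10) {
  stopifnot(length(phi_L) == length(phi_H),
            all(is.finite(phi_L)), all(is.finite(phi_H)))
  cfg <- recon_config(lambda_tv = 0, beta_l2 = 0, max_iter = max_iter,
                      rel_tol = rel_tol, bounds = bounds, init = init,
                      grid_spec = list(
                        adc = c(min(bounds$adc[1], lookup$adc0),
                                max(bounds$adc[2],
                                    lookup$adc0 + (lookup$n_adc - 1) * lookup$h_adc),
                                lookup$h_adc),
                        t2 = c(min(bounds$t2[1], lookup$t20),
                               max(bounds$t2[2],
                                   lookup$t20 + (lookup$n_t2 - 1) * lookup$h_t2),
                               lookup$h_t2)))
  .pbd_fit_engine(phi_L, phi_H, lookup, cfg, mode = "voxel")
}

#' Regularized map reconstruction
#'
#' Minimizes the TV/L2-regularized objective over whole ADC and T2 maps by
#' projected gradient descent with a global Barzilai-Borwein step,
#' divergence-safeguarded by a fixed small fallback step.  With
#' `lambda_tv = beta_l2 = 0` the problem is voxel-separable and a 1-voxel
#' volume reproduces [fit_voxel()] exactly.
#'
#' @param pair a [phase_pair()] object.
#' @param cfg a [recon_config()] object.
#' @param lookup optional pre-built [build_phase_lookup()]; when omitted,
#'   `seq_low`/`seq_high` must be given to build one.
#' @param seq_low,seq_high protocol descriptions used to build the lookup
#'   when `lookup` is missing.
#' @return Object of class `pbd_parameter_maps`: arrays `adc`, `t2`,
#'   `residual`, plus `mask`, `iterations_used`, `converged`,
#'   `objective_trace`, `n_bb_fallbacks`.
#' @export
fit_maps <- function(pair, cfg = recon_config(), lookup = NULL,
                     seq_low = NULL, seq_high = NULL) {
  stopifnot(inherits(pair, "pbd_phase_pair"))
  if (is.null(lookup)) {
    if (is.null(seq_low) || is.null(seq_high))
      stop("fit_maps: supply either a lookup or seq_low/seq_high")
    lookup <- build_phase_lookup(seq_low, seq_high, grid_spec = cfg$grid_spec)
  }
  dims <- dim(pair$phi_L) %||% c(length(pair$phi_L), 1L, 1L)
  if (length(dims) == 2) dims <- c(dims, 1L)
  res <- .pbd_fit_engine(as.vector(pair$phi_L), as.vector(pair$phi_H),
                         lookup, cfg, mode = "maps", dims = dims,
                         mask = pair$mask)
  structure(list(adc = array(res$adc, dims), t2 = array(res$t2, dims),
                 residual = array(res$residual, dims), mask = pair$mask,
                 iterations_used = res$iterations_used,
                 converged = res$converged,
                 objective_trace = res$objective_trace,
                 n_bb_fallbacks = res$n_bb_fallbacks,
                 config = cfg),
            class = "pbd_parameter_maps")
}

#' @export
print.pbd_parameter_maps <- function(x, ...) {
  cat(sprintf("PBD parameter maps %s: %d iterations, %sconverged\n",
              paste(dim(x$adc), collapse = "x"), x$iterations_used,
              if (x$converged) "" else "NOT "))
  m <- x$mask
  cat(sprintf("  ADC median %.0f um2/s, T2 median %.1f ms over %d masked voxels\n",
              stats::median(x$adc[m]), stats::median(x$t2[m]), sum(m)))
  invisible(x)
}
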
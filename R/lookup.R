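# Forward interpolant: tensor-product cubic B-spline fit of the model
# phases over a uniform (ADC, T2) grid, with analytic gradients.  The
# phase surface is smooth, so interpolation at the default grid spacing is
# accurate to well below 1e-4 rad (checked in tests against direct
# closed-form evaluation).

# Interpolating cubic B-spline coefficients along the first dimension of a
# matrix, uniform sites, natural end conditions.  y: n x m -> (n+2) x m.
.bspl_coef <- function(y) {
  n <- nrow(y)
  A <- matrix(0, n + 2, n + 2)
  for (i in seq_len(n)) A[i, i:(i + 2)] <- c(1, 4, 1) / 6
  A[n + 1, 1:3] <- c(1, -2, 1)
  A[n + 2, n:(n + 2)] <- c(1, -2, 1)
  solve(A, rbind(y, matrix(0, 2, ncol(y))))
}

# Uniform cubic B-spline basis weights and derivatives at local coordinate
# u in [0,1]; returns 4-column matrices.
.bspl_w <- function(u) {
  u2 <- u * u; u3 <- u2 * u
  cbind((1 - u)^3, 3 * u3 - 6 * u2 + 4, -3 * u3 + 3 * u2 + 3 * u + 1, u3) / 6
}
.bspl_dw <- function(u) {
  u2 <- u * u
  cbind(-(1 - u)^2, 3 * u2 - 4 * u, -3 * u2 + 2 * u + 1, u2) / 2
}

#' Pre-computed forward phase interpolant
#'
#' Builds cubic-spline interpolants `fL(ADC, T2)` and `fH(ADC, T2)` of the
#' closed-form signal phases at the low and high crusher moments, on a
#' uniform grid, together with analytic gradients.  T1 is fixed to the
#' supplied default (the phase is insensitive to T1).  Queries outside the
#' grid are clamped and counted (`lookup_clamp_count()`).
#'
#' @param seq_low,seq_high [sequence_params()] objects for the two moments.
#' @param grid_spec list with elements `adc = c(min, max, step)` (um^2/s)
#'   and `t2 = c(min, max, step)` (ms).  The grid should cover the intended
#'   fit bounds with margin.
#' @param tissue_defaults a [tissue_params()] object fixing T1 and M0.
#' @param L truncation order used when tabulating the model (default 32,
#'   converged; see the methods vignette).
#' @return An object of class `pbd_lookup`.
#' @export
build_phase_lookup <- function(seq_low, seq_high,
                               grid_spec = list(adc = c(0, 3200, 50),
                                                t2 = c(15, 520, 5)),
                               tissue_defaults = tissue_params(T1 = 1000),
                               L = 32) {
  stopifnot(moment_of(seq_low) < moment_of(seq_high))
  adc <- seq(grid_spec$adc[1], grid_spec$adc[2], by = grid_spec$adc[3])
  t2  <- seq(grid_spec$t2[1],  grid_spec$t2[2],  by = grid_spec$t2[3])
  g <- expand.grid(adc = adc, t2 = t2, KEEP.OUT.ATTRS = FALSE)
  ts <- tissue_params(M0 = tissue_defaults$M0[1], T1 = tissue_defaults$T1[1],
                      T2 = g$t2, D = g$adc, allow_t2_gt_t1 = TRUE)
  mk <- function(sq) {
    sq$L <- as.integer(L)
    ph <- matrix(Arg(steady_state_signal(ts, sq)), length(adc), length(t2))
    t(.bspl_coef(t(.bspl_coef(ph))))     # coefficients along both dims
  }
  structure(list(CL = mk(seq_low), CH = mk(seq_high),
                 adc0 = adc[1], h_adc = grid_spec$adc[3], n_adc = length(adc),
                 t20 = t2[1], h_t2 = grid_spec$t2[3], n_t2 = length(t2),
                 seq_low = seq_low, seq_high = seq_high, L = L,
                 tissue_defaults = tissue_defaults,
                 clamp = new.env(parent = emptyenv())),
            class = "pbd_lookup")
}

# Evaluate one coefficient surface with gradients; adc/t2 numeric vectors.
.bspl_eval2 <- function(C, adc, t2, lk) {
  ua <- (adc - lk$adc0) / lk$h_adc
  ut <- (t2 - lk$t20) / lk$h_t2
  n_clamp <- sum(ua < 0 | ua > lk$n_adc - 1 | ut < 0 | ut > lk$n_t2 - 1)
  if (n_clamp > 0) {
    lk$clamp$n <- (if (is.null(lk$clamp$n)) 0 else lk$clamp$n) + n_clamp
    ua <- pmin(pmax(ua, 0), lk$n_adc - 1)
    ut <- pmin(pmax(ut, 0), lk$n_t2 - 1)
  }
  ja <- pmin(floor(ua), lk$n_adc - 2); la <- ua - ja
  jt <- pmin(floor(ut), lk$n_t2 - 2);  lt <- ut - jt
  wa <- .bspl_w(la); dwa <- .bspl_dw(la) / lk$h_adc
  wt <- .bspl_w(lt); dwt <- .bspl_dw(lt) / lk$h_t2
  val <- dva <- dvt <- numeric(length(ua))
  nra <- lk$n_adc + 2
  for (a in 1:4) for (b in 1:4) {
    cf <- C[cbind(ja + a, jt + b)]
    val <- val + cf * wa[, a] * wt[, b]
    dva <- dva + cf * dwa[, a] * wt[, b]
    dvt <- dvt + cf * wa[, a] * dwt[, b]
  }
  list(value = val, d_adc = dva, d_t2 = dvt)
}

#' Evaluate the forward interpolant
#'
#' @param lookup a [build_phase_lookup()] object.
#' @param adc,t2 query coordinates (um^2/s, ms), vectors of equal length.
#' @return List with elements `fL`, `fH`, each a list `value`, `d_adc`,
#'   `d_t2` (phase in radians and its partial derivatives).
#' @export
lookup_eval <- function(lookup, adc, t2) {
  list(fL = .bspl_eval2(lookup$CL, adc, t2, lookup),
       fH = .bspl_eval2(lookup$CH, adc, t2, lookup))
}

#' Number of clamped (out-of-grid) lookup queries so far
#'
#' @param lookup a [build_phase_lookup()] object.
#' @return Integer count.
#' @export
lookup_clamp_count <- function(lookup) {
  if (is.null(lookup$clamp$n)) 0L else as.integer(lookup$clamp$n)
}
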
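#' DCIS lesion size under power-law growth
#'
#' Deterministic lesion maximum diameter `t` years after onset for an
#' individual with inverse growth rate `r`:
#' `l_r(t) = (k t (1-beta)/r + l0^(1-beta))^(1/(1-beta))`.
#' Equivalently the solution of `dl/dt = k l^beta / r` from `l(0) = l0`.
#'
#' @param t time since DCIS onset, years (vectorised, `>= 0`).
#' @param r inverse growth rate, `> 0` (vectorised).
#' @param params an [nh_params()] object.
#' @return Lesion diameter in mm, `>= l0`.
#' @export
dcis_size <- function(t, r, params) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(r <= 0)) stop("'r' must be positive")
  b <- params$beta
  (params$k * t * (1 - b) / r + params$l0^(1 - b))^(1 / (1 - b))
}

#' Inverse DCIS growth: time since onset at a given lesion size
#'
#' `g_r(l) = r / (k (1-beta)) * (l^(1-beta) - l0^(1-beta))`, the exact
#' inverse of [dcis_size()].  Its derivative, needed as a Jacobian in
#' size-domain densities, is `g_r'(l) = r l^(-beta) / k`.
#'
#' @param l lesion diameter, mm, `>= l0` (vectorised).
#' @inheritParams dcis_size
#' @return `time_from_dcis_size()`: years since onset;
#'   `dcis_time_deriv()`: `dg_r/dl` in years/mm.
#' @export
time_from_dcis_size <- function(l, r, params) {
  if (any(l < params$l0 * (1 - 1e-12))) stop("'l' must be >= l0")
  b <- params$beta
  pmax(r / (params$k * (1 - b)) * (l^(1 - b) - params$l0^(1 - b)), 0)
}

#' @rdname time_from_dcis_size
#' @export
dcis_time_deriv <- function(l, r, params) {
  r * l^(-params$beta) / params$k
}

#' Invasive tumour volume under exponential growth
#'
#' `V_r(t) = v0 exp(t/r)` for `t` years since transition to invasiveness;
#' the inverse is `t = r log(v/v0)`.
#'
#' @param t time since transition to invasive cancer, years (vectorised).
#' @param v tumour volume, mm^3, `>= v0` (vectorised).
#' @inheritParams dcis_size
#' @return Volume in mm^3, or years since transition.
#' @export
invasive_volume <- function(t, r, params) {
  if (any(t < 0)) stop("'t' must be non-negative")
  params$v0 * exp(t / r)
}

#' @rdname invasive_volume
#' @export
time_from_invasive_volume <- function(v, r, params) {
  if (any(v < params$v0 * (1 - 1e-12))) stop("'v' must be >= v0")
  pmax(r * log(v / params$v0), 0)
}

#' Sphere volume / diameter conversion
#'
#' Tumours are modelled as spheres: `v = (pi/6) d^3`.
#'
#' @param v volume, mm^3, `> 0`.
#' @param d diameter, mm, `> 0`.
#' @return The converted quantity.
#' @export
diameter_from_volume <- function(v) {
  if (any(v <= 0)) stop("'v' must be positive")
  (6 * v / pi)^(1 / 3)
}

#' @rdname diameter_from_volume
#' @export
volume_from_diameter <- function(d) {
  if (any(d <= 0)) stop("'d' must be positive")
  pi / 6 * d^3
}

#' Time-integrated lesion size
#'
#' Closed form of `integral_0^t l_r(u) du =
#' r (l_r(t)^(2-beta) - l0^(2-beta)) / (k (2-beta))`, the building block of
#' the cumulative exit hazards from the preclinical DCIS state (both exit
#' hazards are proportional to current lesion size).
#'
#' @inheritParams dcis_size
#' @return Integrated size in mm * years.
#' @export
integrated_lesion_size <- function(t, r, params) {
  r * .phi_lesion(dcis_size(t, r, params), params)
}

# Phi(l) = (l^(2-beta) - l0^(2-beta)) / (k (2-beta)): integrated lesion size
# per unit r, as a function of current size.  Appears throughout the
# closed-form survival functions and size densities.
.phi_lesion <- function(l, params) {
  b <- params$beta
  (l^(2 - b) - params$l0^(2 - b)) / (params$k * (2 - b))
}

# inverse of .phi_lesion: lesion size at which the integrated size reaches phi
.phi_lesion_inv <- function(phi, params) {
  b <- params$beta
  (params$l0^(2 - b) + params$k * (2 - b) * phi)^(1 / (2 - b))
}
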
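#' Expected preclinical sojourn times
#'
#' Mean sojourns in the two preclinical states, marginal over the Gamma
#' growth-rate prior, computed by exact change of variables to the size
#' domain (where the `r`-integral has the closed Laplace-transform form)
#' followed by adaptive quadrature:
#' * `expected_sojourn_dcis()`: `E(T_e)`, `T_e = min(T_D, T_T)`, via
#'   `E(T_e) = (tau1/tau2) integral_l0^inf l^(-beta)/k
#'   F((eta_D+eta_T) Phi(l)) dl`.
#' * `expected_invasive_sojourn()`: `E(T_I)` via
#'   `(tau1/tau2) integral_v0^inf v^-1 F(eta_I (v - v0)) dv`.
#' * `expected_weighted_invasive_sojourn()`: `(1-a) E(T_I)`, the
#'   per-onset expected time spent in the preclinical invasive state
#'   (only the fraction `1-a` of onsets ever transitions).
#'
#' @param params an [nh_params()] object.
#' @param rel_tol relative quadrature tolerance.
#' @return Years.
#' @export
expected_sojourn_dcis <- function(params, rel_tol = 1e-10) {
  eta <- params$eta_D + params$eta_T
  val <- stats::integrate(function(l) {
    l^(-params$beta) / params$k *
      laplace_gamma_shifted(eta * .phi_lesion(l, params),
                            params$tau1, params$tau2)
  }, params$l0, Inf, rel.tol = rel_tol)
  if (!is.finite(val$value)) stop("E(T_e) integral did not converge")
  params$tau1 / params$tau2 * val$value
}

#' @rdname expected_sojourn_dcis
#' @export
expected_invasive_sojourn <- function(params, rel_tol = 1e-10) {
  val <- stats::integrate(function(v) {
    laplace_gamma_shifted(params$eta_I * (v - params$v0),
                          params$tau1, params$tau2) / v
  }, params$v0, Inf, rel.tol = rel_tol)
  if (!is.finite(val$value)) stop("E(T_I) integral did not converge")
  params$tau1 / params$tau2 * val$value
}

#' @rdname expected_sojourn_dcis
#' @export
expected_weighted_invasive_sojourn <- function(params, rel_tol = 1e-10) {
  (1 - prob_symptomatic_before_invasive(params)) *
    expected_invasive_sojourn(params, rel_tol)
}

#' Stationary membership of the preclinical states
#'
#' In the stable disease population the probability that a preclinical
#' cancer present at any calendar instant is a DCIS lesion (rather than an
#' invasive tumour) is
#' `E(T_e) / (E(T_e) + (1-a) E(T_I))`, with `a = c/(1+c)` the constant
#' probability of exiting the DCIS state via symptoms.
#'
#' @inheritParams expected_sojourn_dcis
#' @return `prob_dcis_among_preclinical()` returns the probability;
#'   `membership_summary()` returns a list with `e_te`, `e_ti_weighted`,
#'   `a` and `p_dcis_given_preclinical`.
#' @examples
#' round(prob_dcis_among_preclinical(nh_params()), 4)
#' @export
prob_dcis_among_preclinical <- function(params, rel_tol = 1e-10) {
  m <- membership_summary(params, rel_tol)
  m$p_dcis_given_preclinical
}

#' @rdname prob_dcis_among_preclinical
#' @export
membership_summary <- function(params, rel_tol = 1e-10) {
  e_te <- expected_sojourn_dcis(params, rel_tol)
  e_ti_w <- expected_weighted_invasive_sojourn(params, rel_tol)
  structure(list(e_te = e_te, e_ti_weighted = e_ti_w,
                 a = prob_symptomatic_before_invasive(params),
                 p_dcis_given_preclinical = e_te / (e_te + e_ti_w)),
            class = "nh_membership")
}

#' @export
print.nh_membership <- function(x, ...) {
  cat("Stationary preclinical membership\n")
  cat(sprintf("  E(T_e)          = %.4f y\n", x$e_te))
  cat(sprintf("  (1-a) E(T_I)    = %.4f y  (a = %.4f)\n", x$e_ti_weighted, x$a))
  cat(sprintf("  P(DCIS | preclinical) = %.4f\n", x$p_dcis_given_preclinical))
  invisible(x)
}

#' Stationary size densities of the preclinical states
#'
#' Size distributions among preclinical cancers present at a calendar
#' instant in the stable population:
#' * invasive: the volume density is length-biased downwards,
#'   proportional to `f_VI(v)/v`; on the diameter scale the Jacobian
#'   `(pi/2) d^2` of `v = (pi/6) d^3` applies.
#' * DCIS: proportional to `l^(-beta)/k * F((eta_D+eta_T) Phi(l))`, i.e. the
#'   marginal of `g_r'(l) f_R(r) S_TD(g_r(l)|r) S_TT(g_r(l)|r)` over the
#'   growth-rate prior.
#'
#' Normalisation constants are evaluated numerically (and for the DCIS
#' density equal `E(T_e) tau2/tau1` analytically).
#'
#' @param x size: diameter (mm) or volume (mm^3) for the invasive density
#'   according to `scale`; lesion diameter (mm) for the DCIS density.
#' @param params an [nh_params()] object.
#' @param scale `"diameter"` or `"volume"` for the invasive density.
#' @param rel_tol relative tolerance of the normalising quadrature.
#' @return Normalised density values.
#' @export
stationary_invasive_size_density <- function(x, params,
                                             scale = c("diameter", "volume"),
                                             rel_tol = 1e-10) {
  scale <- match.arg(scale)
  norm <- stats::integrate(function(v)
    density_symptomatic_volume(v + params$v0, params) / (v + params$v0),
    0, Inf, rel.tol = rel_tol)$value
  if (scale == "volume") {
    if (any(x < params$v0)) stop("volume must be >= v0")
    density_symptomatic_volume(x, params) / x / norm
  } else {
    d0 <- diameter_from_volume(params$v0)
    if (any(x < d0)) stop("diameter must be >= diameter(v0)")
    v <- volume_from_diameter(x)
    density_symptomatic_volume(v, params) / v * (pi / 2) * x^2 / norm
  }
}

#' @rdname stationary_invasive_size_density
#' @param l lesion diameter, mm, `>= l0`.
#' @export
stationary_dcis_size_density <- function(l, params, rel_tol = 1e-10) {
  if (any(l < params$l0)) stop("'l' must be >= l0")
  e_te <- expected_sojourn_dcis(params, rel_tol)
  eta <- params$eta_D + params$eta_T
  params$tau1 / params$tau2 * l^(-params$beta) / params$k *
    laplace_gamma_shifted(eta * .phi_lesion(l, params),
                          params$tau1, params$tau2) / e_te
}

# ---- marginal presence probabilities (r-quadrature) ------------------------

# Gauss-Legendre nodes/weights on (0, 1)
.gl01 <- function(n) {
  gl <- pracma::gaussLegendre(n, 0, 1)
  list(x = gl$x, w = gl$w)
}

# nodes of the Gamma growth-rate prior: E_R[h(R)] ~ sum w_j h(r_j).
# Generalized Gauss-Laguerre with alpha = tau1 - 1 integrates exactly
# against the Gamma(tau1, rate tau2) density (x = tau2 r).  For tau1 < 1
# the exponent is negative (not supported by the rule), so the factor
# r^(tau1-1) is rewritten as r^tau1 / r and alpha = tau1 is used.
.r_nodes <- function(params, n) {
  if (params$tau1 >= 1) {
    gl <- pracma::gaussLaguerre(n, params$tau1 - 1)
    list(r = gl$x / params$tau2, w = gl$w / gamma(params$tau1))
  } else {
    gl <- pracma::gaussLaguerre(n, params$tau1)
    list(r = gl$x / params$tau2, w = gl$w / (gl$x * gamma(params$tau1)))
  }
}

# As .r_nodes, but with the exponential factor exp(-s r) absorbed into the
# measure (one scaled rule per element of s):
# E_R[h(R) exp(-s R)] = (tau2/(tau2+s))^tau1 * sum_j w_j h(x_j/(tau2+s)).
# Returns n x length(s) matrices of nodes and weights.
.r_nodes_absorbed <- function(params, n, s) {
  t1 <- params$tau1
  rate <- params$tau2 + s
  sfac <- (params$tau2 / rate)^t1
  if (t1 >= 1) {
    gl <- pracma::gaussLaguerre(n, t1 - 1)
    w0 <- gl$w / gamma(t1)
  } else {
    gl <- pracma::gaussLaguerre(n, t1)
    w0 <- gl$w / (gl$x * gamma(t1))
  }
  list(r = outer(gl$x, 1 / rate),
       w = outer(w0, sfac))
}

#' Marginal survival / presence probabilities of the preclinical states
#'
#' `P(T_e > t)` (still preclinical DCIS at age `t` since onset) and the
#' probability of occupying the preclinical invasive state at age `t` since
#' onset (`T_T <= t < T_T + T_I`, `T_T < T_D`), both marginal over the
#' growth-rate prior.  Evaluated by Gauss-Legendre quadrature over the prior
#' quantiles (and over the transition time for the invasive state).  Used
#' for stationarity diagnostics and to bound the simulation burn-in window.
#'
#' @param t age since DCIS onset, years (vectorised).
#' @param params an [nh_params()] object.
#' @param n_r,n_t quadrature orders.
#' @return Probabilities.
#' @export
marginal_dcis_presence <- function(t, params, n_r = 96) {
  nodes <- .r_nodes(params, n_r)
  eta <- params$eta_D + params$eta_T
  vapply(t, function(tt) {
    sum(nodes$w * exp(-eta * nodes$r *
                        .phi_lesion(dcis_size(tt, nodes$r, params), params)))
  }, numeric(1))
}

#' @rdname marginal_dcis_presence
#' @export
marginal_invasive_presence <- function(t, params, n_r = 96, n_t = 64) {
  nodes <- .r_nodes(params, n_r)
  gl <- .gl01(n_t)
  vapply(t, function(age) {
    if (age <= 0) return(0)
    # inner integral over transition time u in (0, age)
    per_r <- vapply(nodes$r, function(r) {
      u <- gl$x * age
      f <- params$eta_T * dcis_size(u, r, params) *
        exp(-(params$eta_D + params$eta_T) * r *
              .phi_lesion(dcis_size(u, r, params), params)) *
        exp(-params$eta_I * params$v0 * r * (exp((age - u) / r) - 1))
      age * sum(gl$w * f)
    }, numeric(1))
    sum(nodes$w * per_r)
  }, numeric(1))
}

# Horizon W such that onsets older than W years before a query time
# contribute fewer than `miss` expected individuals (preclinical or still
# awaiting detection) at an onset intensity of `rate` per year.  The tail
# integral is bounded using the local exponential decay rate of the
# presence probability.
.sojourn_horizon <- function(params, rate, miss = 0.1) {
  pres <- function(u) marginal_dcis_presence(u, params) +
    marginal_invasive_presence(u, params)
  W <- 20
  repeat {
    s1 <- pres(W - 5); s2 <- pres(W)
    if (s2 <= 0) return(W)
    lam <- (log(s1) - log(s2)) / 5
    if (lam > 0 && rate * s2 / lam < miss) return(W)
    W <- W + 15
    if (W > 2000) stop("could not bound the sojourn horizon")
  }
}
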
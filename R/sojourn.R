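#' Transition hazards of the preclinical states
#'
#' Exit from the preclinical DCIS state (state 2) is a competing risk
#' between symptomatic DCIS detection and transition to invasive cancer,
#' both with hazards proportional to current lesion diameter:
#' `h_TD(t|r) = eta_D l_r(t)` and `h_TT(t|r) = eta_T l_r(t)`.  Symptomatic
#' detection of invasive cancer has hazard proportional to current tumour
#' volume, `h_TI(t|r) = eta_I v0 exp(t/r)` (`t` counted from transition).
#'
#' @inheritParams dcis_size
#' @return Hazard rate per year.
#' @export
hazard_dcis_symptom <- function(t, r, params) {
  params$eta_D * dcis_size(t, r, params)
}

#' @rdname hazard_dcis_symptom
#' @export
hazard_transition <- function(t, r, params) {
  params$eta_T * dcis_size(t, r, params)
}

#' @rdname hazard_dcis_symptom
#' @export
hazard_invasive_symptom <- function(t, r, params) {
  if (any(t < 0)) stop("'t' must be non-negative")
  params$eta_I * params$v0 * exp(t / r)
}

#' Cumulative hazards and survival functions
#'
#' Closed forms: `H_TD(t|r) = eta_D * r * Phi(l_r(t))` with
#' `Phi(l) = (l^(2-beta) - l0^(2-beta))/(k(2-beta))` (the time-integrated
#' lesion size per unit `r`), similarly for the transition hazard, and
#' `H_TI(t|r) = eta_I v0 r (exp(t/r) - 1)`.
#'
#' @inheritParams dcis_size
#' @return Cumulative hazard (dimensionless) or survival probability.
#' @export
cumhaz_dcis_symptom <- function(t, r, params) {
  params$eta_D * integrated_lesion_size(t, r, params)
}

#' @rdname cumhaz_dcis_symptom
#' @export
cumhaz_transition <- function(t, r, params) {
  params$eta_T * integrated_lesion_size(t, r, params)
}

#' @rdname cumhaz_dcis_symptom
#' @export
cumhaz_invasive_symptom <- function(t, r, params) {
  if (any(t < 0)) stop("'t' must be non-negative")
  params$eta_I * params$v0 * r * (exp(t / r) - 1)
}

#' @rdname cumhaz_dcis_symptom
#' @export
surv_dcis_symptom <- function(t, r, params) {
  exp(-cumhaz_dcis_symptom(t, r, params))
}

#' @rdname cumhaz_dcis_symptom
#' @export
surv_transition <- function(t, r, params) {
  exp(-cumhaz_transition(t, r, params))
}

#' @rdname cumhaz_dcis_symptom
#' @export
surv_invasive_symptom <- function(t, r, params) {
  exp(-cumhaz_invasive_symptom(t, r, params))
}

#' Sample preclinical sojourn times
#'
#' Draws, per individual, the competing exit times from the preclinical DCIS
#' state and (for individuals that transition first) the invasive sojourn,
#' by exact closed-form inversion of the cumulative hazards: a unit
#' exponential deviate `E` is mapped to the exit lesion size through
#' `Phi^{-1}(E/(eta r))` and then to time through the inverse growth
#' function; the invasive sojourn uses `V_I = v0 + E/(eta_I r)` so that
#' `(V_I - v0) | r` is exponential with rate `eta_I r`.
#'
#' Two equivalent constructions are provided.  `"latent"` (default) draws
#' latent failure times `T_D`, `T_T` independently given `r`.  `"combined"`
#' draws the exit time `T_e` from the combined hazard
#' `(eta_D + eta_T) l_r(t)` and the exit type from an independent
#' Bernoulli(`c/(1+c)`) — under proportional hazards the two give the same
#' joint law of (exit time, exit type, onward invasive history).
#'
#' @param n number of individuals.
#' @param r inverse growth rate(s), recycled to length `n`; if `NULL`,
#'   drawn from the Gamma(`tau1`, rate `tau2`) prior.
#' @param params an [nh_params()] object.
#' @param method `"latent"` or `"combined"` (see Details).
#' @return A data frame with columns `r`, `t_D`, `t_T` (years from onset;
#'   under `"combined"` only the realised minimum is filled, the other is
#'   `Inf`), `t_I` (years from transition, `NA` unless `t_T < t_D`), `l_D`
#'   (lesion diameter at symptomatic DCIS detection, `NA` unless
#'   `t_D < t_T`), `l_T` (lesion diameter at transition, `NA` unless
#'   `t_T < t_D`) and `v_I` (tumour volume at invasive symptomatic
#'   detection, `NA` unless `t_T < t_D`).
#' @export
sample_sojourns <- function(n, r = NULL, params,
                            method = c("latent", "combined")) {
  method <- match.arg(method)
  if (is.null(r)) r <- stats::rgamma(n, shape = params$tau1, rate = params$tau2)
  r <- rep_len(r, n)
  if (method == "latent") {
    lD <- .phi_lesion_inv(stats::rexp(n) / (params$eta_D * r), params)
    lT <- .phi_lesion_inv(stats::rexp(n) / (params$eta_T * r), params)
    t_D <- time_from_dcis_size(lD, r, params)
    t_T <- time_from_dcis_size(lT, r, params)
  } else {
    le <- .phi_lesion_inv(stats::rexp(n) / ((params$eta_D + params$eta_T) * r),
                          params)
    te <- time_from_dcis_size(le, r, params)
    to_dcis <- stats::runif(n) < prob_symptomatic_before_invasive(params)
    t_D <- ifelse(to_dcis, te, Inf)
    t_T <- ifelse(to_dcis, Inf, te)
    lD <- le
    lT <- le
  }
  trans <- t_T < t_D
  v_I <- t_I <- rep(NA_real_, n)
  if (any(trans)) {
    rt <- r[trans]
    v_I[trans] <- params$v0 + stats::rexp(sum(trans)) / (params$eta_I * rt)
    t_I[trans] <- time_from_invasive_volume(v_I[trans], rt, params)
  }
  data.frame(r = r, t_D = t_D, t_T = t_T, t_I = t_I,
             l_D = ifelse(trans, NA_real_, lD),
             l_T = ifelse(trans, lT, NA_real_),
             v_I = v_I)
}

#' Laplace transform of the shifted Gamma prior
#'
#' `F(s) = (tau2 / (tau2 + s))^(tau1 + 1)`, the Laplace transform of a
#' Gamma(`tau1 + 1`, rate `tau2`) distribution.  It appears in every
#' closed-form size density because
#' `E[R exp(-s R)] = (tau1/tau2) F(s)` for `R ~ Gamma(tau1, rate tau2)`.
#'
#' @param s transform argument, `>= 0` (vectorised).
#' @param tau1,tau2 Gamma shape and rate of the growth-rate prior.
#' @return Value in `(0, 1]`; `F(0) = 1`.
#' @export
laplace_gamma_shifted <- function(s, tau1, tau2) {
  if (any(s < 0)) stop("'s' must be non-negative")
  (tau2 / (tau2 + s))^(tau1 + 1)
}

#' Closed-form symptomatic size densities
#'
#' Marginal (over the Gamma growth-rate prior) densities of size at
#' symptomatic detection in the absence of screening:
#' * `density_symptomatic_volume()`: tumour volume at invasive symptomatic
#'   detection, `f_VI(v) = tau1 tau2^-1 eta_I F(eta_I (v - v0))`; under
#'   proportional hazards this is unchanged by conditioning on having
#'   transitioned before DCIS symptoms.
#' * `density_symptomatic_lesion()`: lesion diameter at symptomatic DCIS
#'   detection,
#'   `f_LD(l) = tau1 tau2^-1 eta_D l^(1-beta) k^-1 F(eta_D Phi(l))`;
#'   with `competing = TRUE` the density conditional on exiting via DCIS
#'   symptoms (`T_D < T_T`), which replaces `eta_D` by `eta_D + eta_T`
#'   inside the transform and rescales by `(1+c)/c`.
#'
#' Matching distribution functions (`cdf_*`) are provided for
#' goodness-of-fit testing and quantile construction:
#' `F_VI(v) = 1 - (tau2/(tau2 + eta_I (v - v0)))^tau1` and analogously on
#' the lesion scale through `Phi(l)`.
#'
#' @param v tumour volume, mm^3, `> v0`.
#' @param l lesion diameter, mm, `> l0`.
#' @param params an [nh_params()] object.
#' @param competing condition on `T_D < T_T`?
#' @return Density per mm^3 (volume) or per mm (lesion); the `cdf_*`
#'   variants return probabilities.
#' @export
density_symptomatic_volume <- function(v, params) {
  if (any(v <= params$v0)) stop("'v' must exceed v0")
  params$tau1 / params$tau2 * params$eta_I *
    laplace_gamma_shifted(params$eta_I * (v - params$v0),
                          params$tau1, params$tau2)
}

#' @rdname density_symptomatic_volume
#' @export
cdf_symptomatic_volume <- function(v, params) {
  if (any(v < params$v0)) stop("'v' must be >= v0")
  1 - (params$tau2 / (params$tau2 + params$eta_I * (v - params$v0)))^params$tau1
}

#' @rdname density_symptomatic_volume
#' @export
density_symptomatic_lesion <- function(l, params, competing = FALSE) {
  if (any(l <= params$l0)) stop("'l' must exceed l0")
  eta <- if (competing) params$eta_D + params$eta_T else params$eta_D
  params$tau1 / params$tau2 * eta * l^(1 - params$beta) / params$k *
    laplace_gamma_shifted(eta * .phi_lesion(l, params),
                          params$tau1, params$tau2)
}

#' @rdname density_symptomatic_volume
#' @export
cdf_symptomatic_lesion <- function(l, params, competing = FALSE) {
  if (any(l < params$l0)) stop("'l' must be >= l0")
  eta <- if (competing) params$eta_D + params$eta_T else params$eta_D
  1 - (params$tau2 / (params$tau2 + eta * .phi_lesion(l, params)))^params$tau1
}

#' De-novo piecewise transition hazard
#'
#' Transition hazard allowing a proportion `p` of lesions to become invasive
#' almost immediately: linear hazard `a_dn + b_dn t` on `[0, window)`
#' (declining continuously to zero at the junction, with early mass exactly
#' `p`), then the standard size-proportional hazard with the clock shifted
#' by `window`.  With `p = 0` the early piece vanishes.  Note the hazard is
#' zero at the junction while the shifted standard hazard starts at
#' `eta_T l0 > 0`; the jump has size `eta_T l0` and is negligible.
#'
#' @inheritParams dcis_size
#' @param dn a [de_novo_config()] object.
#' @return Hazard rate per year.
#' @export
de_novo_transition_hazard <- function(t, r, dn, params) {
  if (any(t < 0)) stop("'t' must be non-negative")
  early <- t < dn$window
  out <- numeric(length(t))
  out[early] <- dn$a_dn + dn$b_dn * t[early]
  if (any(!early)) {
    tl <- (t - dn$window)[!early]
    out[!early] <- params$eta_T *
      dcis_size(tl, rep_len(r, length(t))[!early], params)
  }
  out
}

#' @rdname de_novo_transition_hazard
#' @param n number of transition times to draw.
#' @return `sample_transition_de_novo()` returns `n` transition times
#'   sampled by inversion of the piecewise cumulative hazard.
#' @export
sample_transition_de_novo <- function(n, r, dn, params) {
  r <- rep_len(r, n)
  e <- stats::rexp(n)
  Hw <- -log1p(-dn$p)
  out <- numeric(n)
  early <- e < Hw
  if (any(early)) {
    # solve a t + b t^2/2 = e on [0, window); b < 0, a = -w b > 0
    a <- dn$a_dn; b <- dn$b_dn
    out[early] <- (-a + sqrt(pmax(a^2 + 2 * b * e[early], 0))) / b
  }
  if (any(!early)) {
    lT <- .phi_lesion_inv((e[!early] - Hw) / (params$eta_T * r[!early]), params)
    out[!early] <- dn$window + time_from_dcis_size(lT, r[!early], params)
  }
  out
}
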
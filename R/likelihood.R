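#' Logistic screening sensitivities
#'
#' Probability of detection at an attended screen: for a preclinical DCIS
#' lesion of diameter `l` mm, `logit p = b0 + b1 l`; for a preclinical
#' invasive tumour of diameter `d` mm with (still growing) DCIS component
#' of diameter `l`, `logit p = b0 + b1 l + b2 d`.
#'
#' @param l DCIS lesion diameter, mm (`>= 0`; 0 allowed for hypothetical
#'   evaluation).
#' @param d invasive tumour diameter, mm.
#' @param params an [nh_params()] object.
#' @return Detection probability in (0, 1).
#' @export
sensitivity_dcis <- function(l, params) {
  if (any(l < 0)) stop("'l' must be non-negative")
  stats::plogis(params$b0 + params$b1 * l)
}

#' @rdname sensitivity_dcis
#' @export
sensitivity_invasive <- function(l, d, params) {
  if (any(l < 0) || any(d < 0)) stop("sizes must be non-negative")
  stats::plogis(params$b0 + params$b1 * l + params$b2 * d)
}

#' Quadrature settings for the likelihood engine
#'
#' The growth-rate integrals use Gauss-Legendre quadrature on the Gamma
#' quantile transform of the prior (order `n_r`); transition-time integrals
#' use the exact probability-integral transform of `T_T` given `r` (order
#' `n_t`), so no truncation of either domain is needed; the size integrals
#' of the class normalization constants use Gauss-Legendre on the quantile
#' transform of the closed-form symptomatic-size distributions (order
#' `n_size`).  When many symptomatic cases share one screening pattern up
#' to a calendar shift (e.g. detections spread over an inter-screen
#' interval), their normalization constants are evaluated at `n_shift`
#' Chebyshev nodes of the shift range and interpolated with a cubic spline
#' (`shift_interp = FALSE` forces exact per-pattern evaluation).
#'
#' @param n_r,n_t,n_size quadrature orders (see Details).
#' @param n_shift number of interpolation nodes for shifted-pattern
#'   normalizers.
#' @param shift_interp logical; enable the shifted-pattern interpolation.
#' @return A list of class `nh_quad`.
#' @export
quad_settings <- function(n_r = 64, n_t = 64, n_size = 64, n_shift = 9,
                          shift_interp = TRUE) {
  structure(list(n_r = as.integer(n_r), n_t = as.integer(n_t),
                 n_size = as.integer(n_size), n_shift = as.integer(n_shift),
                 shift_interp = isTRUE(shift_interp)),
            class = "nh_quad")
}

# transition-time nodes on the probability scale; the evaluators map them
# through the closed-form quantiles of the exit time T_e given r
.t_nodes <- function(quad) .gl01(quad$n_t)

#' Screening-history probability by back-projection
#'
#' Probability of the observed screening record given the case geometry.
#' Knowing the inverse growth rate `r`, the transition time `t_t` (invasive
#' cases) and the size at detection, lesion and tumour sizes at every
#' earlier screen are back-projected through the growth functions; the
#' history probability is the product over attended screens of one minus
#' the sensitivity at the back-projected sizes, with sensitivity zero at
#' screens preceding onset, the DCIS sensitivity between onset and
#' transition and the invasive sensitivity thereafter.  With
#' `mode = "last_positive"` the screen at offset zero is the detection
#' screen and contributes its sensitivity instead.
#'
#' @param r inverse growth rate.
#' @param size_mm size at detection (lesion diameter for DCIS, tumour
#'   diameter for invasive cancer), mm.
#' @param screen_offsets times of attended screens before detection, years
#'   (non-negative, increasing; 0 = the detection screen, only meaningful
#'   with `mode = "last_positive"`).
#' @param disease_type `"dcis"` or `"invasive"`.
#' @param mode `"all_negative"` or `"last_positive"`.
#' @param t_t time from onset to transition, years (required for invasive
#'   cases).
#' @param params an [nh_params()] object.
#' @return Probability in `[0, 1]`; 1 for an empty history in
#'   `"all_negative"` mode.
#' @export
history_probability <- function(r, size_mm, screen_offsets, disease_type,
                                mode = c("all_negative", "last_positive"),
                                t_t = NULL, params = nh_params()) {
  mode <- match.arg(mode)
  offs <- as.numeric(screen_offsets)
  if (length(offs) > 1 && any(diff(offs) <= 0))
    stop("'screen_offsets' must be strictly increasing")
  if (any(offs < 0)) stop("'screen_offsets' must be non-negative")
  invasive <- disease_type == "invasive"
  if (invasive) {
    if (is.null(t_t)) stop("invasive cases require 't_t'")
    v <- volume_from_diameter(size_mm)
    age_det <- t_t + time_from_invasive_volume(v, r, params)
  } else {
    age_det <- time_from_dcis_size(size_mm, r, params)
    t_t <- Inf
  }
  prob <- 1
  for (u in offs) {
    age <- age_det - u
    if (u == 0 && mode == "last_positive") {
      l <- dcis_size(age, r, params)
      s <- if (invasive) sensitivity_invasive(l, size_mm, params)
      else sensitivity_dcis(size_mm, params)
      prob <- prob * s
    } else if (age >= 0) {
      l <- dcis_size(age, r, params)
      s <- if (invasive && age >= t_t) {
        d <- diameter_from_volume(invasive_volume(age - t_t, r, params))
        sensitivity_invasive(l, d, params)
      } else sensitivity_dcis(l, params)
      prob <- prob * (1 - s)
    } # screens before onset: sensitivity 0, factor 1
  }
  prob
}

# ---- vectorised class evaluators -------------------------------------------
#
# Both evaluators compute the unnormalised conditional-likelihood
# contribution (the I/N factor is dropped throughout; it cancels in the
# conditional likelihood) for a vector of sizes sharing one screening base
# pattern, each size possibly with its own calendar shift delta:
# the attended-screen offsets of point p are base + delta[p].

# invasive classes: double integral over (r, t_t).
#
# The t-integral runs against f_TT(t|r) S_TD(t|r) dt = d(exit-time CDF)/(1+c)
# and uses the closed-form quantiles of T_e = min(T_D, T_T) given r, which
# absorbs the S_TD factor exactly.  For the r-integral the default
# ("density") route also absorbs the factor exp(-eta_I r (v - v0)) — shared
# by S_TI(r log(v/v0)|r) and f_{V_I|R}(v|r) — into a scaled Gauss-Laguerre
# measure per size, keeping the rule accurate into the far size tail; the
# "hazard" route evaluates the survival factor literally (the two
# arrangements mirror the two published forms of the screen-detected
# invasive joint density and are cross-checked in the tests).
.eval_invasive <- function(v, delta, base, detection, params, quad,
                           method = c("density", "hazard")) {
  method <- match.arg(method)
  m <- length(v)
  delta <- rep_len(as.numeric(delta), m)
  tn <- .t_nodes(quad)
  absorb <- method == "density"
  if (absorb) {
    rn <- .r_nodes_absorbed(params, quad$n_r, params$eta_I * (v - params$v0))
    rmat <- rn$r; wmat <- rn$w                 # [j, p]
  } else {
    rn <- .r_nodes(params, quad$n_r)
    rmat <- matrix(rn$r, quad$n_r, m); wmat <- matrix(rn$w, quad$n_r, m)
  }
  .eval_invasive_cpp(v, delta, as.numeric(base), rmat, wmat, tn$x, tn$w,
                     detection, absorb,
                     params$beta, params$k, params$l0, params$v0,
                     params$eta_T, params$eta_D, params$eta_I,
                     params$b0, params$b1, params$b2)
}

# DCIS classes: single integral over r.  The joint survival factor
# exp(-(eta_D + eta_T) r Phi(l)) is absorbed into the Gamma quadrature
# measure (scaled Gauss-Laguerre per size), which keeps the rule accurate
# arbitrarily far into the size tail.
.eval_dcis <- function(l, delta, base, detection, params, quad) {
  m <- length(l)
  delta <- rep_len(as.numeric(delta), m)
  phi <- .phi_lesion(l, params)                 # [p]
  rn <- .r_nodes_absorbed(params, quad$n_r,
                          (params$eta_D + params$eta_T) * phi)
  .eval_dcis_cpp(l, delta, as.numeric(base), rn$r, rn$w, detection,
                 params$beta, params$k, params$l0, params$eta_D,
                 params$b0, params$b1)
}

# ---- per-class contribution functions --------------------------------------

#' Conditional-likelihood contributions of the four detection classes
#'
#' Unnormalised likelihood contributions (densities over size, up to the
#' class normalization constant; the unknown onset-rate-to-population
#' constant cancels and is never exposed) for each of the four detection
#' classes.  All are marginal over the Gamma growth-rate prior and, for
#' invasive cases, over the latent transition time, with the observed
#' screening history entering through back-projection
#' ([history_probability()]):
#'
#' * screen-detected invasive: double integral of the screening history
#'   (last screen positive) against
#'   `r v^-1 S_TD(t_t|r) f_TT(t_t|r) S_TI(r log(v/v0)|r) f_R(r)`;
#'   `method = "density"` uses the algebraically equivalent
#'   proportional-hazards form through `f_VI|R(v|r)/(eta_I v)`.
#' * symptomatic invasive: as above with all screens negative and kernel
#'   `S_TD(t_t|r) f_TT(t_t|r) f_VI|R(v|r) f_R(r)`.
#' * screen-detected DCIS: single integral of the history against
#'   `g_r'(l) S_TD(g_r(l)|r) S_TT(g_r(l)|r) f_R(r)`.
#' * symptomatic DCIS: single integral of the history against
#'   `f_LD|R(l|r) S_TT(g_r(l)|r) f_R(r)`.
#'
#' @param size_mm vector of sizes at detection (tumour diameter, mm, for
#'   invasive; lesion diameter, mm, for DCIS), all sharing the screening
#'   pattern `screen_offsets`.
#' @param screen_offsets attended-screen times before detection, years,
#'   increasing; for screen-detected classes the first element must be 0
#'   (the detection screen).
#' @param params an [nh_params()] object.
#' @param quad a [quad_settings()] object.
#' @param method `"hazard"` or `"density"`: two algebraically equivalent
#'   integrand arrangements for the screen-detected invasive class (kept
#'   separate as a cross-check).
#' @return Unnormalised contribution values (one per size).
#' @export
contribution_screen_invasive <- function(size_mm, screen_offsets = 0,
                                         params = nh_params(),
                                         quad = quad_settings(),
                                         method = c("density", "hazard")) {
  offs <- sort(as.numeric(screen_offsets))
  if (length(offs) == 0 || offs[1] != 0)
    stop("screen-detected class requires a screen at offset 0")
  d0 <- diameter_from_volume(params$v0)
  if (any(size_mm <= d0)) stop("'size_mm' must exceed diameter(v0)")
  .eval_invasive(volume_from_diameter(size_mm), 0, offs, TRUE, params, quad,
                 method = match.arg(method))
}

#' @rdname contribution_screen_invasive
#' @export
contribution_symptomatic_invasive <- function(size_mm,
                                              screen_offsets = numeric(),
                                              params = nh_params(),
                                              quad = quad_settings()) {
  offs <- sort(as.numeric(screen_offsets))
  d0 <- diameter_from_volume(params$v0)
  if (any(size_mm <= d0)) stop("'size_mm' must exceed diameter(v0)")
  .eval_invasive(volume_from_diameter(size_mm), 0, offs, FALSE, params, quad)
}

#' @rdname contribution_screen_invasive
#' @export
contribution_screen_dcis <- function(size_mm, screen_offsets = 0,
                                     params = nh_params(),
                                     quad = quad_settings()) {
  offs <- sort(as.numeric(screen_offsets))
  if (length(offs) == 0 || offs[1] != 0)
    stop("screen-detected class requires a screen at offset 0")
  if (any(size_mm <= params$l0)) stop("'size_mm' must exceed l0")
  .eval_dcis(size_mm, 0, offs, TRUE, params, quad)
}

#' @rdname contribution_screen_invasive
#' @export
contribution_symptomatic_dcis <- function(size_mm,
                                          screen_offsets = numeric(),
                                          params = nh_params(),
                                          quad = quad_settings()) {
  offs <- sort(as.numeric(screen_offsets))
  if (any(size_mm <= params$l0)) stop("'size_mm' must exceed l0")
  .eval_dcis(size_mm, 0, offs, FALSE, params, quad)
}

# size-quantile nodes for the normalizer integrals: importance transform of
# the closed-form symptomatic-size distributions, with a graded substitution
# q = 1 - (1-u)^3 that regularises the algebraic endpoint behaviour of the
# length-biased (1/size) factors at q -> 1
.size_nodes <- function(params, quad) {
  gl <- .gl01(quad$n_size)
  q <- 1 - (1 - gl$x)^3
  jac <- 3 * (1 - gl$x)^2
  f <- (1 - q)^(-1 / params$tau1) - 1
  v <- params$v0 + params$tau2 * f / params$eta_I
  l <- .phi_lesion_inv(params$tau2 * f / (params$eta_D + params$eta_T), params)
  list(v = v, wv = gl$w * jac / density_symptomatic_volume(v, params),
       l = l, wl = gl$w * jac / density_symptomatic_lesion(l, params,
                                                           competing = TRUE))
}

# Size nodes for the screen-detected class: the integrand carries the
# length-biased stationary size densities (with their 1/size factor and
# spike at the size floor), so importance nodes are the numeric quantiles of
# the stationary densities, built in log-size coordinates y = log(size/floor)
# where both have smooth closed-form kernels:
#   invasive: mu(y) dy ~ F(eta_I v0 (e^y - 1)) dy
#   DCIS:     mu(y) dy ~ l^(1-beta) F((eta_D+eta_T) Phi(l)) dy, l = l0 e^y
.screen_size_nodes <- function(params, quad) {
  gl <- .gl01(quad$n_size)
  qgrid <- function(dens, Y) {
    y <- seq(0, Y, length.out = 1024L)
    f <- dens(y)
    cdf <- cumsum((f[-1] + f[-length(f)]) / 2 * diff(y))
    cdf <- c(0, cdf)
    Z <- cdf[length(cdf)]
    u <- cdf / Z
    keep <- c(TRUE, diff(u) > 1e-14)   # drop saturated tail knots
    yq <- stats::splinefun(u[keep], y[keep], method = "hyman")(gl$x)
    list(y = yq, w = gl$w * Z / dens(yq))
  }
  # invasive: volume tail quantile from the closed-form f_VI
  v_hi <- params$v0 +
    params$tau2 * ((1e-12)^(-1 / params$tau1) - 1) / params$eta_I
  nv <- qgrid(function(y) laplace_gamma_shifted(
    params$eta_I * params$v0 * (exp(y) - 1), params$tau1, params$tau2),
    log(v_hi / params$v0))
  # DCIS: lesion tail quantile from the competing-exit size distribution
  l_hi <- .phi_lesion_inv(params$tau2 * ((1e-12)^(-1 / params$tau1) - 1) /
                            (params$eta_D + params$eta_T), params)
  nl <- qgrid(function(y) {
    l <- params$l0 * exp(y)
    l^(1 - params$beta) / params$k * laplace_gamma_shifted(
      (params$eta_D + params$eta_T) * .phi_lesion(l, params),
      params$tau1, params$tau2)
  }, log(l_hi / params$l0))
  v <- params$v0 * exp(nv$y)
  l <- params$l0 * exp(nl$y)
  list(v = v, wv = nv$w * v,   # dv = v dy
       l = l, wl = nl$w * l)
}

#' Class normalization constant
#'
#' The constant that turns the unnormalised contributions of a detection
#' class (screen-detected or symptomatic, for a given screening pattern)
#' into a proper joint density of (disease type, size): the sum of the
#' invasive-size integral and the DCIS-size integral of the class's
#' contributions.  For an empty symptomatic history it equals 1 (the two
#' reduced integrals are the exit-type probabilities `1-a` and `a`).
#'
#' @param screen_offsets the class's attended-screen offsets (see
#'   [contribution_screen_invasive()]).
#' @param mode `"screen"` or `"symptomatic"`.
#' @param params an [nh_params()] object.
#' @param quad a [quad_settings()] object.
#' @return A positive constant.
#' @export
class_normalizer <- function(screen_offsets, mode = c("screen", "symptomatic"),
                             params = nh_params(), quad = quad_settings()) {
  mode <- match.arg(mode)
  offs <- sort(as.numeric(screen_offsets))
  .class_normalizer_impl(offs, mode, params, quad, NULL)
}

.class_normalizer_impl <- function(offs, mode, params, quad, sn = NULL) {
  detection <- mode == "screen"
  if (is.null(sn))
    sn <- if (detection) .screen_size_nodes(params, quad)
    else .size_nodes(params, quad)
  ci <- .eval_invasive(sn$v, 0, offs, detection, params, quad)
  cd <- .eval_dcis(sn$l, 0, offs, detection, params, quad)
  val <- sum(sn$wv * ci) + sum(sn$wl * cd)
  if (!is.finite(val) || val <= 1e-300)
    stop("class normalizer is not finite/positive (mode = ", mode, ")")
  val
}

# ---- total log-likelihood ---------------------------------------------------

# decompose each case's screen offsets into (base pattern, shift):
# base = offs - offs[1]; groups cases whose normalizers form a smooth
# one-parameter family in the shift
.pattern_table <- function(cases) {
  offs <- lapply(seq_len(nrow(cases)), function(i) {
    o <- sort(cases$detection_time[i] - cases$screen_times[[i]])
    o[o < 1e-9 & o > -1e-9] <- 0
    o
  })
  base <- vapply(offs, function(o)
    if (length(o)) paste(round(o - o[1], 6), collapse = ",") else "",
    character(1))
  delta <- vapply(offs, function(o) if (length(o)) o[1] else 0, numeric(1))
  list(offsets = offs, base = base, delta = delta)
}

#' Incident-cases conditional log-likelihood
#'
#' Total conditional log-likelihood of an incident-case dataset: for each
#' case, the log of its detection-class contribution minus the log of the
#' class normalization constant for its screening pattern.  Normalizers
#' are cached per (pattern, class); when symptomatic cases share one
#' pattern up to a calendar shift, their constants are spline-interpolated
#' over the shift (see [quad_settings()]).
#'
#' @param cases an `nh_cases` data frame ([sample_case_dataset()],
#'   [read_cases()]).
#' @param params an [nh_params()] object.
#' @param quad a [quad_settings()] object.
#' @return `total_loglik()`: a single number.  `case_loglik()`: a data
#'   frame with per-case `log_contribution`, `log_normalizer` and `loglik`.
#' @export
total_loglik <- function(cases, params, quad = quad_settings()) {
  sum(case_loglik(cases, params, quad)$loglik)
}

#' @rdname total_loglik
#' @export
case_loglik <- function(cases, params, quad = quad_settings()) {
  validate_params(params)
  if (nrow(cases) < 1) stop("need at least one case")
  # the pattern decomposition depends only on the data; callers evaluating
  # the likelihood repeatedly (the optimiser) attach it once
  pt <- attr(cases, "nh_patterns")
  if (is.null(pt)) pt <- .pattern_table(cases)
  sn_cache <- list()
  contrib <- numeric(nrow(cases))
  lognorm <- numeric(nrow(cases))
  grp <- paste(cases$detection_mode, cases$disease_type, pt$base)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    i1 <- idx[1]
    inv <- cases$disease_type[i1] == "invasive"
    detection <- cases$detection_mode[i1] == "screen"
    base <- pt$offsets[[i1]] - pt$delta[i1]
    sz <- cases$size_mm[idx]
    contrib[idx] <- if (inv)
      .eval_invasive(volume_from_diameter(sz), pt$delta[idx], base, detection,
                     params, quad)
    else .eval_dcis(sz, pt$delta[idx], base, detection, params, quad)
  }
  # normalizers: keyed by mode + full pattern; shift interpolation where a
  # base pattern recurs with many shifts
  key_mode <- cases$detection_mode
  norm_grp <- paste(key_mode, pt$base)
  for (g in unique(norm_grp)) {
    idx <- which(norm_grp == g)
    mode <- key_mode[idx[1]]
    base <- pt$offsets[[idx[1]]] - pt$delta[idx[1]]
    deltas <- pt$delta[idx]
    uniq <- sort(unique(round(deltas, 6)))
    if (is.null(sn_cache[[mode]]))
      sn_cache[[mode]] <- if (mode == "screen") .screen_size_nodes(params, quad)
      else .size_nodes(params, quad)
    exact <- function(d) .class_normalizer_impl(base + d, mode, params, quad,
                                                sn_cache[[mode]])
    if (quad$shift_interp && length(uniq) > quad$n_shift) {
      rng <- range(deltas)
      nodes <- .chebyshev_nodes(rng[1], rng[2], quad$n_shift)
      fn <- stats::splinefun(nodes, log(vapply(nodes, exact, numeric(1))),
                             method = "natural")
      lognorm[idx] <- fn(deltas)
    } else {
      vals <- log(vapply(uniq, exact, numeric(1)))
      lognorm[idx] <- vals[match(round(deltas, 6), uniq)]
    }
  }
  ll <- log(contrib) - lognorm
  if (any(!is.finite(ll)))
    stop("non-finite log-likelihood for case id(s): ",
         paste(utils::head(cases$case_id[!is.finite(ll)], 5), collapse = ", "))
  data.frame(case_id = cases$case_id, log_contribution = log(contrib),
             log_normalizer = lognorm, loglik = ll)
}

.chebyshev_nodes <- function(a, b, n) {
  if (a == b) return(rep(a, n))
  x <- cos((2 * seq_len(n) - 1) / (2 * n) * pi)
  sort((a + b) / 2 + (b - a) / 2 * x)
}
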
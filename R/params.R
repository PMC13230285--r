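#' Natural-history model parameters
#'
#' Bundles every parameter of the joint DCIS / invasive breast cancer
#' natural-history model: the power-law DCIS growth law, the exponential
#' invasive growth law, the Gamma prior on the individual inverse growth rate
#' `R`, the size-proportional exit hazards from the preclinical DCIS state,
#' the volume-proportional hazard for symptomatic detection of invasive
#' cancer, and the logistic screening-sensitivity coefficients.
#'
#' The defaults are the reference configuration used throughout the package's
#' simulation studies: a negative power-law exponent (fast early DCIS
#' growth), a Gamma(2.36, rate 3) inverse-growth-rate prior, hazard
#' coefficients on the log scale of -4.5 (transition), -6.5 (DCIS symptoms)
#' and -8.75 (invasive symptoms), and sensitivity coefficients b0 = -5,
#' b1 = 0.1 (per mm of DCIS lesion), b2 = 0.56 (per mm of invasive tumour
#' diameter).
#'
#' @param beta power-law exponent of DCIS growth; must be `< 1` (may be
#'   negative).
#' @param k DCIS growth coefficient, mm^(1-beta)/year, `> 0`.
#' @param tau1,tau2 shape and rate of the Gamma prior on the inverse growth
#'   rate `R` (years per e-fold of invasive tumour volume).
#' @param eta_T transition-to-invasive hazard coefficient, per mm * year.
#' @param eta_D DCIS symptomatic-detection hazard coefficient, per mm * year.
#' @param eta_I invasive symptomatic-detection hazard coefficient,
#'   per mm^3 * year.
#' @param b0,b1,b2 logistic screening-sensitivity intercept and slopes
#'   (b1 per mm lesion diameter, b2 per mm invasive tumour diameter).
#' @param l0 initial DCIS lesion diameter at onset, mm (fixed constant,
#'   never estimated).
#' @param v0 initial invasive tumour volume at transition, mm^3 (fixed
#'   constant, never estimated).
#'
#' @return An object of class `nh_params` (a validated named list).
#' @seealso [validate_params()], [hazard_ratio()], [read_params()]
#' @examples
#' p <- nh_params()
#' p
#' hazard_ratio(p)        # eta_D / eta_T
#' @export
nh_params <- function(beta = -0.8, k = 15, tau1 = 2.36, tau2 = 3,
                      eta_T = exp(-4.5), eta_D = exp(-6.5),
                      eta_I = exp(-8.75),
                      b0 = -5, b1 = 0.1, b2 = 0.56,
                      l0 = 0.03, v0 = 0.05) {
  p <- list(beta = beta, k = k, tau1 = tau1, tau2 = tau2,
            eta_T = eta_T, eta_D = eta_D, eta_I = eta_I,
            b0 = b0, b1 = b1, b2 = b2, l0 = l0, v0 = v0)
  p <- lapply(p, as.numeric)
  class(p) <- "nh_params"
  validate_params(p)
}

#' Validate natural-history parameters
#'
#' Checks every invariant of the parameter set: `beta < 1` (the growth law
#' has a removable singularity at 1; values within 1e-6 of 1 are rejected),
#' strict positivity of `k`, `tau1`, `tau2`, the three hazard coefficients,
#' `l0` and `v0`, and finiteness of all components including the derived
#' hazard ratio `c = eta_D/eta_T`.
#'
#' @param params an `nh_params` object (or a named list with the same
#'   fields).
#' @return `params`, invisibly unchanged, if valid; otherwise an error
#'   naming the offending field.
#' @export
validate_params <- function(params) {
  need <- c("beta", "k", "tau1", "tau2", "eta_T", "eta_D", "eta_I",
            "b0", "b1", "b2", "l0", "v0")
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing parameter field(s): ", paste(miss, collapse = ", "))
  for (nm in need) {
    x <- params[[nm]]
    if (length(x) != 1L || !is.finite(x))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (params$beta >= 1 - 1e-6)
    stop("parameter 'beta' must be < 1 (power-law growth undefined at 1)")
  for (nm in c("k", "tau1", "tau2", "eta_T", "eta_D", "eta_I", "l0", "v0"))
    if (params[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive")
  cc <- params$eta_D / params$eta_T
  if (!is.finite(cc) || cc <= 0)
    stop("derived hazard ratio c = eta_D/eta_T must be finite and positive")
  invisible(params)
}

#' @export
print.nh_params <- function(x, ...) {
  cat("Natural-history model parameters (nh_params)\n")
  cat(sprintf("  DCIS growth:     l(t) = (k t (1-beta)/r + l0^(1-beta))^(1/(1-beta)),  beta = %g, k = %g, l0 = %g mm\n",
              x$beta, x$k, x$l0))
  cat(sprintf("  Invasive growth: V(t) = v0 exp(t/r),  v0 = %g mm^3\n", x$v0))
  cat(sprintf("  Inverse growth rate R ~ Gamma(shape %g, rate %g), mean %.3f y\n",
              x$tau1, x$tau2, x$tau1 / x$tau2))
  cat(sprintf("  Hazards: eta_T = %.4g, eta_D = %.4g (c = %.4g, P(T_D<T_T) = %.4f), eta_I = %.4g\n",
              x$eta_T, x$eta_D, x$eta_D / x$eta_T,
              (x$eta_D / x$eta_T) / (1 + x$eta_D / x$eta_T), x$eta_I))
  cat(sprintf("  Screening sensitivity: logit p = %g + %g l [+ %g d]\n",
              x$b0, x$b1, x$b2))
  invisible(x)
}

#' Hazard ratio and constant exit-type probability
#'
#' Under proportional exit hazards from the preclinical DCIS state the ratio
#' `c = eta_D/eta_T` is constant in time and growth rate, and the
#' probability of symptomatic DCIS detection before transition to invasive
#' cancer equals `a = c/(1+c)` regardless of the growth function.
#'
#' @param params an [nh_params()] object.
#' @return `hazard_ratio()` returns `c`; `prob_symptomatic_before_invasive()`
#'   returns `a = c/(1+c)`.
#' @export
hazard_ratio <- function(params) params$eta_D / params$eta_T

#' @rdname hazard_ratio
#' @export
prob_symptomatic_before_invasive <- function(params) {
  cc <- hazard_ratio(params)
  cc / (1 + cc)
}

#' Population simulation configuration
#'
#' Describes the stable-population generator: a fixed number of lesion
#' onsets at every calendar step over a simulation window.  The reference
#' configuration is 2000 onsets per 0.01-year step from calendar time 0 to
#' 400 (2e5 onsets per year, 8.0002e7 in total).
#'
#' @param onsets_per_step integer, new DCIS onsets per calendar step.
#' @param step calendar step size in years.
#' @param t_start,t_end simulation window (years).
#' @param seed integer RNG seed for the simulation.
#' @return An object of class `nh_popconfig`.
#' @export
population_config <- function(onsets_per_step = 2000L, step = 0.01,
                              t_start = 0, t_end = 400, seed = 1L) {
  if (onsets_per_step < 1) stop("'onsets_per_step' must be >= 1")
  if (step <= 0) stop("'step' must be > 0")
  if (t_end <= t_start) stop("'t_end' must exceed 't_start'")
  structure(list(onsets_per_step = as.integer(onsets_per_step),
                 step = step, t_start = t_start, t_end = t_end,
                 seed = as.integer(seed)),
            class = "nh_popconfig")
}

#' Screening schedule
#'
#' Ordered calendar times (years) at which screens are offered.  The
#' reference design is biennial screening over calendar years 300-340.
#'
#' @param screen_times numeric vector of calendar times; may be empty.
#' @return Object of class `nh_schedule` (a numeric vector).
#' @examples
#' biennial_schedule()          # screens at 300, 302, ..., 340
#' @export
screening_schedule <- function(screen_times = numeric()) {
  screen_times <- as.numeric(screen_times)
  if (length(screen_times) > 1 && any(diff(screen_times) <= 0))
    stop("'screen_times' must be strictly increasing")
  structure(screen_times, class = "nh_schedule")
}

#' @rdname screening_schedule
#' @param from,to,by first screen, last screen and inter-screen interval in
#'   calendar years.
#' @export
biennial_schedule <- function(from = 300, to = 340, by = 2) {
  screening_schedule(seq(from, to, by = by))
}

#' De-novo invasive cancer extension
#'
#' A piecewise-continuous transition hazard that lets a proportion `p` of
#' lesions transition to invasive cancer almost immediately (within `window`
#' years of onset), modelling invasive cancers without a detectable in-situ
#' phase.  On `[0, window)` the hazard is linear, `a_dn + b_dn t`, with
#' `a_dn + window * b_dn = 0` (the hazard declines continuously to zero at
#' the junction) and total early mass `p`:
#' `exp(-integral_0^window (a_dn + b_dn t) dt) = 1 - p`.  Solving the two
#' constraints gives `b_dn = 2 log(1-p)/window^2` (negative) and
#' `a_dn = -window * b_dn` (positive).  After `window`, the standard
#' size-proportional hazard applies with the clock shifted by `window`.
#'
#' @param p proportion of de-novo invasive cancers, in `[0, 1)`.
#' @param window length of the early-transition interval, years.
#' @return Object of class `nh_denovo` with fields `p`, `window`, `a_dn`,
#'   `b_dn`.
#' @examples
#' dn <- de_novo_config(0.1)
#' # early-survival check: exp(-(a w + b w^2/2)) == 1 - p
#' w <- dn$window
#' exp(-(dn$a_dn * w + dn$b_dn * w^2 / 2))
#' @export
de_novo_config <- function(p = 0, window = 0.01) {
  if (p < 0 || p >= 1) stop("'p' must lie in [0, 1)")
  if (window <= 0) stop("'window' must be > 0")
  b <- 2 * log1p(-p) / window^2
  a <- -window * b
  structure(list(p = p, window = window, a_dn = a, b_dn = b),
            class = "nh_denovo")
}

# ---- configuration file I/O -------------------------------------------------

#' Read and write model configuration files
#'
#' Model parameters are serialized to YAML or JSON (chosen by file
#' extension) with keys mirroring [nh_params()].  Hazard coefficients are
#' accepted on the natural scale (`eta_T`, `eta_D`, `eta_I`) or the log
#' scale (`ln_eta_T`, `ln_eta_D`, `ln_eta_I`); writing always uses the
#' natural scale.  Unknown keys are rejected.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param params an [nh_params()] object.
#' @return `read_params()` returns an `nh_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- .read_config(path)
  ln <- c(ln_eta_T = "eta_T", ln_eta_D = "eta_D", ln_eta_I = "eta_I")
  for (key in names(ln)) {
    if (!is.null(raw[[key]])) {
      nat <- ln[[key]]
      if (!is.null(raw[[nat]]))
        stop("config supplies both '", key, "' and '", nat, "'")
      raw[[nat]] <- exp(raw[[key]])
      raw[[key]] <- NULL
    }
  }
  unknown <- setdiff(names(raw), names(formals(nh_params)))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  do.call(nh_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  .write_config(unclass(params), path)
  invisible(path)
}

.read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config extension: .", ext)
}

.write_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported config extension: .", ext)
  invisible(path)
}
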
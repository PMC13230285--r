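#' Parameter transforms for unconstrained optimisation
#'
#' Maps the natural-history parameters to unconstrained coordinates:
#' `log` for the positive parameters (`k`, `tau1`, `tau2`, `eta_T`,
#' `eta_D`, `eta_I`), `log(1 - beta)` for the power-law exponent (any
#' `beta < 1` maps to a finite coordinate) and the identity for the
#' sensitivity coefficients `b0`, `b1`, `b2`.  `l0` and `v0` are fixed
#' constants and never transformed or estimated.
#'
#' @param params an [nh_params()] object.
#' @param free character vector of free parameter names.
#' @return `transform_params()`: named numeric vector of the free
#'   coordinates; `untransform_params()`: an `nh_params` built from
#'   coordinates `theta` and the fixed values in `params`.
#' @export
transform_params <- function(params, free = .free_default) {
  bad <- setdiff(free, .free_default)
  if (length(bad))
    stop("cannot free parameter(s): ", paste(bad, collapse = ", "))
  th <- vapply(free, function(nm) {
    x <- params[[nm]]
    switch(nm,
           beta = log(1 - x),
           b0 = , b1 = , b2 = x,
           log(x))
  }, numeric(1))
  names(th) <- free
  th
}

#' @rdname transform_params
#' @param theta named numeric vector in transformed coordinates.
#' @export
untransform_params <- function(theta, params, free = names(theta)) {
  p <- unclass(params)
  for (nm in free) {
    x <- theta[[nm]]
    p[[nm]] <- switch(nm,
                      beta = 1 - exp(x),
                      b0 = , b1 = , b2 = x,
                      exp(x))
  }
  class(p) <- "nh_params"
  validate_params(p)
}

.free_default <- c("beta", "k", "tau1", "tau2", "eta_T", "eta_D", "eta_I",
                   "b0", "b1", "b2")

# default natural-scale optimisation bounds: generous ranges covering any
# biologically plausible regime (growth exponents, per-size hazards, Gamma
# growth-rate priors, logistic sensitivities non-decreasing in size and with
# baseline detection below one half), while keeping the optimiser out of
# degenerate corners where the model density collapses
.default_bounds <- list(
  beta = c(-8, 0.99), k = c(0.1, 1000), tau1 = c(0.3, 25), tau2 = c(0.3, 40),
  eta_T = c(1e-6, 0.5), eta_D = c(1e-7, 0.5), eta_I = c(1e-7, 0.01),
  b0 = c(-12, 0), b1 = c(0, 2), b2 = c(0, 4))

.transform_one <- function(nm, x) {
  switch(nm, beta = log(1 - x), b0 = , b1 = , b2 = x, log(x))
}

#' Maximum-likelihood estimation from incident cases
#'
#' Maximises the incident-cases conditional log-likelihood
#' ([total_loglik()]) over a chosen set of free parameters by bounded
#' quasi-Newton optimisation (`optim` method `"L-BFGS-B"`, numerical
#' gradients) in the unconstrained coordinates of [transform_params()].
#' The growth coefficient `k` is excluded from the default free set: `k`
#' and `beta` are only weakly jointly identified (many (k, beta) pairs give
#' near-identical growth curves), so `k` is fixed at its supplied value
#' unless explicitly freed.  With `n_starts > 1`, additional starts are
#' drawn uniformly around the supplied start in transformed coordinates
#' (half-width `start_jitter` times the coordinate magnitude) and the best
#' final log-likelihood wins (ties: first start).
#'
#' @param cases an `nh_cases` data frame.
#' @param start an [nh_params()] object: starting values for the free
#'   parameters and fixed values for the rest.
#' @param free character vector of parameters to estimate.
#' @param method `"scoring"` (default): Fisher scoring using the
#'   outer-product-of-gradients (BHHH) information approximation built from
#'   per-case score vectors, which tracks this model's strongly correlated
#'   likelihood ridges; or `"l-bfgs-b"`: bounded quasi-Newton with
#'   finite-difference gradients in manually rescaled coordinates.
#' @param quad a [quad_settings()] object (lower orders speed up fitting;
#'   see the package vignette).
#' @param control for `"scoring"`: `maxit` and `tol` (stop when an
#'   iteration gains less than `tol` log-likelihood units after the fifth
#'   iteration); for `"l-bfgs-b"`: passed to [stats::optim()].
#' @param bounds named list of natural-scale box constraints for the free
#'   parameters.
#' @param n_starts number of optimisation starts.
#' @param start_jitter relative half-width of the uniform start
#'   perturbation in transformed coordinates.
#' @param seed optional seed for the start draws.
#' @return An object of class `nh_fit`: estimates (`params`), `loglik`,
#'   `AIC`, `convergence`, `counts`, the start used and all start results.
#' @export
fit_model <- function(cases, start,
                      free = setdiff(.free_default, "k"),
                      method = c("scoring", "l-bfgs-b"),
                      quad = quad_settings(n_r = 16, n_t = 16, n_size = 32),
                      control = list(maxit = 80, factr = 1e9),
                      bounds = .default_bounds,
                      n_starts = 1, start_jitter = 0.5, seed = NULL) {
  method <- match.arg(method)
  validate_params(start)
  if (nrow(cases) < 100)
    warning("fewer than 100 cases; estimates will be unstable")
  if (length(free) == 0) {
    # nothing to estimate: evaluate the likelihood at the supplied values
    ll <- total_loglik(cases, start, quad)
    return(structure(list(params = start, free = character(), loglik = ll,
                          AIC = -2 * ll, convergence = 0L,
                          counts = c(`function` = 1L, gradient = NA),
                          message = NULL, start_used = 1L, starts = list(),
                          n_cases = nrow(cases),
                          data_hash = .cases_hash(cases)),
                     class = "nh_fit"))
  }
  th0 <- transform_params(start, free)
  lower <- vapply(free, function(nm)
    min(.transform_one(nm, bounds[[nm]][1]), .transform_one(nm, bounds[[nm]][2])),
    numeric(1))
  upper <- vapply(free, function(nm)
    max(.transform_one(nm, bounds[[nm]][1]), .transform_one(nm, bounds[[nm]][2])),
    numeric(1))
  if (any(th0 < lower | th0 > upper)) {
    warning("starting value(s) clamped into bounds for: ",
            paste(free[th0 < lower | th0 > upper], collapse = ", "))
    th0 <- pmin(pmax(th0, lower), upper)
  }
  if (!is.null(seed)) set.seed(seed)
  attr(cases, "nh_patterns") <- .pattern_table(cases)
  starts <- list(th0)
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      hw <- start_jitter * pmax(abs(th0), 0.5)
      starts[[i + 1]] <- pmin(pmax(th0 + stats::runif(length(th0), -hw, hw),
                                   lower), upper)
    }
  }
  ll_cases <- function(th) {
    names(th) <- free
    p <- untransform_params(th, start, free)
    case_loglik(cases, p, quad)$loglik
  }
  negll <- function(th) {
    ll <- try(sum(ll_cases(th)), silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -ll
  }
  runs <- if (method == "scoring") {
    lapply(starts, function(s)
      .fit_scoring(s, ll_cases, negll, lower, upper,
                   maxit = control$maxit %||% 40,
                   tol = control$tol %||% 0.005))
  } else {
    # L-BFGS-B (as used in the original estimation study).  It ignores
    # control$parscale, so coordinates are rescaled manually and gradients
    # are central differences in the scaled coordinates.
    sc <- pmax(abs(th0), 0.25)
    negll_s <- function(phi) negll(phi * sc)
    grad_s <- function(phi) {
      h <- 1e-4
      vapply(seq_along(phi), function(i) {
        up <- phi; up[i] <- up[i] + h
        dn <- phi; dn[i] <- dn[i] - h
        (negll_s(up) - negll_s(dn)) / (2 * h)
      }, numeric(1))
    }
    control$tol <- NULL
    lapply(starts, function(s) {
      res <- stats::optim(s / sc, negll_s, gr = grad_s, method = "L-BFGS-B",
                          lower = lower / sc, upper = upper / sc,
                          control = control)
      res$par <- res$par * sc
      res
    })
  }
  best <- which.min(vapply(runs, function(r) r$value, numeric(1)))
  res <- runs[[best]]
  est <- untransform_params(res$par, start, free)
  ll <- -res$value
  structure(list(params = est, free = free, loglik = ll,
                 AIC = 2 * length(free) - 2 * ll,
                 convergence = res$convergence, counts = res$counts,
                 message = res$message, start_used = best,
                 starts = lapply(runs, function(r)
                   list(par = r$par, loglik = -r$value,
                        convergence = r$convergence)),
                 n_cases = nrow(cases),
                 data_hash = .cases_hash(cases)),
            class = "nh_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fisher-scoring (BHHH) maximisation: the per-case score vectors (central
# finite differences of the per-case log-likelihood) give the
# outer-product-of-gradients approximation to the information matrix, whose
# Newton-type steps follow the curved, strongly correlated likelihood
# ridges of this model far better than generic quasi-Newton updates.
# Box constraints are enforced by clamping.
.fit_scoring <- function(th, ll_cases, negll, lower, upper,
                         maxit = 40, tol = 0.005, h = 1e-4) {
  clamp <- function(x) pmin(pmax(x, lower), upper)
  th <- clamp(th)
  f <- -negll(th)
  n_case <- length(try(ll_cases(th), silent = TRUE))
  nev <- 2L
  trace <- f
  conv <- 1L
  n_small <- 0L
  for (it in seq_len(maxit)) {
    gmat <- try(vapply(seq_along(th), function(i) {
      up <- th; up[i] <- up[i] + h
      dn <- th; dn[i] <- dn[i] - h
      (ll_cases(up) - ll_cases(dn)) / (2 * h)
    }, numeric(n_case)), silent = TRUE)
    nev <- nev + 2L * length(th)
    if (inherits(gmat, "try-error")) break
    G <- colSums(gmat)
    H <- crossprod(gmat)
    H <- H + diag(1e-6 * max(diag(H)), length(th))
    dir <- tryCatch(solve(H, G), error = function(e) G / sqrt(sum(G^2)))
    lam <- 1
    f_new <- f
    improved <- FALSE
    for (ls in 1:8) {
      cand <- clamp(th + lam * dir)
      fc <- -negll(cand)
      nev <- nev + 1L
      if (is.finite(fc) && fc > f + 1e-9) {
        th <- cand; f_new <- fc; improved <- TRUE; break
      }
      lam <- lam / 3
    }
    trace <- c(trace, f_new)
    gain <- f_new - f
    f <- f_new
    # a single tiny gain can be a stingy line-search step inside a curved
    # valley; stop only on two consecutive sub-tolerance gains
    n_small <- if (gain < tol) n_small + 1L else 0L
    if (!improved || (it >= 8 && n_small >= 2L)) {
      conv <- if (improved || it >= 8) 0L else 1L
      break
    }
  }
  list(par = th, value = -f, convergence = conv,
       counts = c(`function` = nev, gradient = NA),
       message = NULL, trace = trace)
}

.cases_hash <- function(cases) {
  c(n = nrow(cases), size_sum = round(sum(cases$size_mm), 6),
    t_sum = round(sum(cases$detection_time), 6))
}

#' @export
print.nh_fit <- function(x, ...) {
  cat("Incident-cases maximum-likelihood fit (nh_fit)\n")
  cat(sprintf("  %d cases, %d free parameters; log-likelihood %.3f, AIC %.3f\n",
              x$n_cases, length(x$free), x$loglik, x$AIC))
  cat(sprintf("  convergence code %d (%s)\n", x$convergence,
              if (x$convergence == 0) "converged" else "not converged"))
  est <- unlist(x$params[x$free])
  print(signif(est, 4))
  invisible(x)
}

#' Compare two fits by AIC
#'
#' `AIC = 2 * #free - 2 * loglik`; the difference `AIC_A - AIC_B` is
#' negative when model A is preferred.  Both fits must be to the same
#' dataset.
#'
#' @param fitA,fitB `nh_fit` objects fitted to the same cases.
#' @return The AIC difference (a single number).
#' @export
model_compare <- function(fitA, fitB) {
  if (!isTRUE(all.equal(fitA$data_hash, fitB$data_hash)))
    stop("fits are not based on the same dataset")
  fitA$AIC - fitB$AIC
}

# ---- recovery diagnostics ---------------------------------------------------

#' Fitted natural-history curves
#'
#' Diagnostic curves at a reference inverse growth rate (default: the
#' median of the fitted Gamma prior):
#' * `transition_hazard_curve()`: the hazard of transition to invasive
#'   cancer, `eta_T l_r(t)`, against time since onset.
#' * `sensitivity_curve()`: the screening sensitivity over time for an
#'   individual whose lesion transitions `t_invasion` years after onset —
#'   DCIS sensitivity before transition, invasive sensitivity (lesion +
#'   tumour diameter) after; the curve is discontinuous at `t_invasion`
#'   because the tumour starts at volume `v0`.
#'
#' @param params an [nh_params()] object (true or fitted).
#' @param t times since onset, years.
#' @param r inverse growth rate; default the median of the Gamma prior.
#' @param t_invasion time from onset to transition for the reference
#'   individual, years.
#' @return A data frame with columns `t` and `value`.
#' @export
transition_hazard_curve <- function(params, t = seq(0, 15, by = 0.1),
                                    r = NULL) {
  if (is.null(r))
    r <- stats::qgamma(0.5, shape = params$tau1, rate = params$tau2)
  data.frame(t = t, value = hazard_transition(t, r, params))
}

#' @rdname transition_hazard_curve
#' @export
sensitivity_curve <- function(params, t = seq(0, 20, by = 0.1), r = NULL,
                              t_invasion = 10) {
  if (is.null(r))
    r <- stats::qgamma(0.5, shape = params$tau1, rate = params$tau2)
  l <- dcis_size(t, r, params)
  val <- sensitivity_dcis(l, params)
  after <- t >= t_invasion
  if (any(after)) {
    d <- diameter_from_volume(invasive_volume(t[after] - t_invasion, r,
                                              params))
    val[after] <- sensitivity_invasive(l[after], d, params)
  }
  data.frame(t = t, value = val)
}
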